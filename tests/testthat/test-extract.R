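test_that("CIGAR walk assigns reference coordinates to CpG calls", {
  # plain match: query index k -> pos + k - 1
  r <- map_calls_to_reference(10L, "5M", "Z..z.")
  expect_equal(r$refpos, c(10L, 13L))
  expect_equal(r$call, c("Z", "z"))

  # deletion creates a novel CpG: C at 100, deleted base, G at 102 — the
  # call on the C is emitted at 100 although the reference has no CpG there
  r <- map_calls_to_reference(100L, "1M1D1M", "Z.")
  expect_equal(r$refpos, 100L)
  expect_equal(r$call, "Z")

  # non-CpG contexts are ignored
  r <- map_calls_to_reference(10L, "5M", "..H..")
  expect_equal(nrow(r), 0L)

  # calls on inserted/soft-clipped bases have no reference coordinate:
  # query bases 3-4 are inserted, so the Z there is dropped and the final
  # z (query base 5) sits at reference 12
  r <- map_calls_to_reference(10L, "2M2I2M", "z.Z.z.")
  expect_equal(r$refpos, c(10L, 12L))
  expect_equal(attr(r, "dropped"), 1L)

  # length mismatch is a hard error naming the read
  expect_error(map_calls_to_reference(10L, "4M", "Z..z.", qname = "bad1"),
               "bad1")
})

test_that("strand assignment merges both strands onto the forward C", {
  expect_equal(assign_strand(57L, "CT"), 57L)
  expect_equal(assign_strand(58L, "GA"), 57L)
  expect_error(assign_strand(57L, "XX"), "conversion strand")

  # forward 3 Z + 2 z at p, reverse 2 Z + 2 z at p+1 -> one site (p, 5, 4)
  p <- 40L
  aln <- aln_fixture(
    pos = c(rep(p, 5L), rep(p + 1L, 4L)),
    cigar = rep("1M", 9L),
    xm = c("Z", "Z", "Z", "z", "z", "Z", "Z", "z", "z"),
    xg = c(rep("CT", 5L), rep("GA", 4L)))
  ct <- tabulate_counts(aln)
  expect_equal(nrow(ct), 1L)
  expect_equal(ct$pos, p)
  expect_equal(ct$meth, 5L)
  expect_equal(ct$unmeth, 4L)
})

test_that("alignment parsing keeps primary mapped reads and counts the rest", {
  sam <- tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6\tSO:unsorted",
    "@SQ\tSN:chrT\tLN:1000",
    "r1\t0\tchrT\t10\t42\t3M\t*\t0\t0\tCGA\tIII\tXM:Z:Z..\tXG:Z:CT",
    "r2\t256\tchrT\t10\t42\t3M\t*\t0\t0\tCGA\tIII\tXM:Z:Z..\tXG:Z:CT",
    "r3\t0\tchrT\t50\t42\t3M\t*\t0\t0\tCGA\tIII\tXM:Z:z..\tXG:Z:CT"), sam)
  aln <- read_bismark_alignments(sam)
  expect_equal(length(aln$pos), 2L)
  expect_equal(aln$log$secondary, 1L)
  expect_equal(aln$log$kept, 2L)
})

test_that("tabulation sums calls per site and sorts by header order", {
  aln <- aln_fixture(pos = c(100L, 100L, 20L), cigar = rep("2M", 3L),
                     xm = c("Z.", "Z.", "z."), xg = rep("CT", 3L),
                     chrom = c("chr2", "chr2", "chr1"),
                     chrom_levels = c("chr2", "chr1"))
  ct <- tabulate_counts(aln)
  # chromosome order follows the header (chr2 before chr1), then position
  expect_equal(ct$chrom, c("chr2", "chr1"))
  expect_equal(ct$pos, c(100L, 20L))
  expect_equal(ct$meth, c(2L, 0L))
  expect_equal(ct$unmeth, c(0L, 1L))

  expect_equal(nrow(tabulate_counts(aln_fixture(
    pos = integer(0), cigar = character(0), xm = character(0),
    xg = character(0)))), 0L)
})

test_that("overlap deduplication drops the second mate's shared calls", {
  # properly paired mates fully overlapping one CpG, both methylated
  aln <- new_bis_aln(qname = c("p1", "p1"), flag = c(99L, 147L),
                     chrom = c("chrT", "chrT"), pos = c(10L, 10L),
                     cigar = c("5M", "5M"), xm = c("Z....", "Z...."),
                     xg = c("CT", "CT"))
  expect_equal(tabulate_counts(aln, dedup_overlap = TRUE)$meth, 1L)
  expect_equal(tabulate_counts(aln, dedup_overlap = FALSE)$meth, 2L)

  # partially overlapping mates: only the shared window is clipped
  aln2 <- new_bis_aln(qname = c("p1", "p1"), flag = c(99L, 147L),
                      chrom = c("chrT", "chrT"), pos = c(10L, 13L),
                      cigar = c("5M", "5M"), xm = c("Z..Z.", ".Z..Z"),
                      xg = c("CT", "CT"))
  ct <- tabulate_counts(aln2)
  expect_equal(ct$pos, c(10L, 13L, 17L))
  expect_equal(ct$meth, c(1L, 1L, 1L))
})

test_that("count tables round-trip through their writer and reader", {
  ct <- count_fixture(pos = c(57L, 90L), meth = c(5L, 0L), unmeth = c(4L, 3L))
  path <- tempfile(fileext = ".tsv")
  write_count_table(ct, path)
  lines <- readLines(path)
  expect_equal(lines[1], "chrom\tpos\ttotal\tmeth\tunmeth")
  expect_equal(lines[2], "chrT\t57\t9\t5\t4")
  back <- read_count_table(path)
  expect_equal(back$pos, ct$pos)
  expect_equal(back$meth, ct$meth)
  expect_equal(back$unmeth, ct$unmeth)

  # empty table -> header-only file
  write_count_table(count_fixture(integer(0), integer(0), integer(0)), path)
  expect_equal(length(readLines(path)), 1L)

  cov <- tempfile(fileext = ".cov")
  write_bismark_coverage(ct, cov)
  expect_equal(readLines(cov)[1], paste("chrT", 57, 57,
                                        100 * 5 / 9, 5, 4, sep = "\t"))
})

test_that("linkage patterns tally per-read joint methylation", {
  iv <- data.frame(chrom = "chrT", start = 10L, end = 30L)
  # one read methylated at both of the interval's two sites
  one <- aln_fixture(pos = 10L, cigar = "11M", xm = "Z.........Z", xg = "CT")
  lp <- extract_linkage_patterns(one, iv)
  expect_equal(lp$pattern, "MM")
  expect_equal(lp$count, 1L)

  # identical patterns tally; partial coverage shows as '-'
  two <- aln_fixture(pos = c(10L, 10L, 20L), cigar = rep("11M", 3L),
                     xm = c("Z.........z", "Z.........z", "Z.........."),
                     xg = rep("CT", 3L))
  lp <- extract_linkage_patterns(two, iv)
  expect_equal(lp$pattern[lp$count == 2L], "Mu")
  expect_true("-M" %in% lp$pattern)
  expect_equal(sum(lp$count), 3L)

  expect_error(extract_linkage_patterns(
    one, data.frame(chrom = "chrT", start = 30L, end = 10L)),
    "malformed interval")
})

test_that("perfectly correlated sites produce only all-M or all-u patterns", {
  set.seed(42)
  n <- 60L
  state <- sample(c(TRUE, FALSE), n, replace = TRUE)
  xm <- ifelse(state, "Z....Z....Z", "z....z....z")
  aln <- aln_fixture(pos = rep(100L, n), cigar = rep("11M", n), xm = xm,
                     xg = rep("CT", n))
  lp <- extract_linkage_patterns(
    aln, data.frame(chrom = "chrT", start = 90L, end = 120L))
  expect_setequal(lp$pattern, c("MMM", "uuu"))
  expect_equal(sum(lp$count), n)
})

test_that("strand-merge is idempotent across strand re-expression", {
  # a CT-strand dataset and the same calls re-expressed as GA-strand reads
  # one base to the right give identical tables
  set.seed(7)
  pos <- sort(sample(50:400, 30))
  xm <- sample(c("Z", "z"), 30, replace = TRUE)
  ct_aln <- aln_fixture(pos = pos, cigar = rep("1M", 30), xm = xm,
                        xg = rep("CT", 30))
  ga_aln <- aln_fixture(pos = pos + 1L, cigar = rep("1M", 30), xm = xm,
                        xg = rep("GA", 30))
  expect_identical(tabulate_counts(ct_aln), tabulate_counts(ga_aln))
})

test_that("novel CpG sites absent from the reference are still reported", {
  cfg <- sim_config(seed = 31, chrom_len = 6000, mean_depth = 0.5,
                    samples = c(s = 0.5), n_novel = 2L, novel_depth = 6L)
  ref <- make_reference(cfg)
  sim <- simulate_reads(cfg, ref, dir = tempdir())
  ct <- tabulate_counts(read_bismark_alignments(sim$sam[["s"]]))
  expect_true(length(ref$novel_loci) >= 1L)
  expect_true(all(ref$novel_loci %in% ct$pos))
  expect_false(any(ref$novel_loci %in% ref$cpg_pos))
})

test_that("extraction recovers the simulator's truth table exactly", {
  for (seed in c(3L, 17L)) {
    cfg <- sim_config(seed = seed, chrom_len = 8000, mean_depth = 6,
                      paired_frac = 0.4, samples = c(s = 0.35),
                      n_novel = 1L, novel_depth = 4L,
                      junk_unmapped = 2L, junk_secondary = 2L)
    sim <- simulate_reads(cfg, make_reference(cfg), dir = tempdir())
    ct <- tabulate_counts(read_bismark_alignments(sim$sam[["s"]]))
    tr <- sim$truth[["s"]]
    expect_equal(ct$pos, tr$pos)
    expect_equal(ct$meth, tr$meth)
    expect_equal(ct$unmeth, tr$unmeth)
    # call conservation: table totals equal delivered calls after dedup
    expect_equal(sum(ct$meth) + sum(ct$unmeth),
                 sum(tr$meth) + sum(tr$unmeth))
  }
})
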