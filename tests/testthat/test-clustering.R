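test_that("single-linkage cuts the sorted list at gaps exceeding max_dist", {
  expect_equal(single_linkage(c(100L, 150L, 260L), 100),
               list(c(100L, 150L), 260L))
  expect_equal(single_linkage(42L, 10), list(42L))
  expect_equal(single_linkage(integer(0), 10), list())
  expect_error(single_linkage(c(5L, 3L), 10), "strictly increasing")
})

test_that("single-linkage equals the transitive-closure oracle", {
  skip_if_not_installed("igraph")
  set.seed(99)
  for (rep in 1:25) {
    n <- sample(1:60, 1)
    pos <- sort(sample.int(5000, n))
    d <- sample(c(1, 10, 50, 100, 300), 1)
    expect_identical(single_linkage(pos, d), slc_oracle(pos, d))
  }
})

test_that("oversized clusters split recursively at the largest gap", {
  # spans <= max_len are untouched
  p <- c(100L, 250L, 500L)
  expect_equal(split_oversized(p, 500), list(p))

  # 40 sites spanning 1400 bp split into >= 3 subregions, each <= 500 bp
  set.seed(4)
  pos <- sort(sample(1000:2400, 40))
  pos[1] <- 1000L; pos[40] <- 2400L
  parts <- split_oversized(pos, 500)
  expect_gte(length(parts), 3L)
  expect_true(all(vapply(parts, function(q) max(q) - min(q), numeric(1))
                  <= 500))
  expect_equal(unlist(parts), pos)  # membership and order preserved

  # leftmost tie-break: equal largest gaps split at the first
  tie <- c(0L, 300L, 600L)
  expect_equal(split_oversized(tie, 500), list(0L, c(300L, 600L)))

  # with a huge bound, splitting is the identity
  expect_equal(split_oversized(pos, 1e9), list(pos))
})

test_that("splitting composed with clustering reduces to pure SLC as x grows", {
  skip_if_not_installed("igraph")
  set.seed(12)
  for (rep in 1:10) {
    pos <- sort(sample.int(20000, sample(5:200, 1)))
    d <- sample(c(30, 100, 500), 1)
    cl <- single_linkage(pos, d)
    split_all <- unlist(lapply(cl, split_oversized, max_len = 1e9),
                        recursive = FALSE)
    expect_identical(split_all, slc_oracle(pos, d))
  }
})

test_that("increasing max_dist never increases the cluster count", {
  set.seed(5)
  pos <- sort(sample.int(10000, 300))
  counts <- vapply(c(10, 50, 100, 200, 500, 1000),
                   function(d) length(single_linkage(pos, d)), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("sample joining is a full outer join that round-trips", {
  t1 <- count_fixture(pos = c(10L, 50L), meth = c(3L, 1L), unmeth = c(0L, 4L))
  t2 <- count_fixture(pos = c(50L, 80L), meth = c(2L, 2L), unmeth = c(2L, 0L))
  mat <- join_samples(list(a = t1, b = t2))
  expect_equal(mat$sites$pos, c(10L, 50L, 80L))
  expect_equal(mat$N[, "a"], c(3L, 5L, NA))
  expect_equal(mat$N[, "b"], c(NA, 4L, 2L))

  # identity for a single table, and split_samples inverts the join
  expect_equal(join_samples(list(x = t1))$N[, "x"], c(3L, 5L))
  back <- split_samples(mat)
  expect_equal(back$a$pos, t1$pos)
  expect_equal(back$a$meth, t1$meth)
  expect_equal(back$b$unmeth, t2$unmeth)

  dup <- count_fixture(pos = c(10L, 10L), meth = c(1L, 1L), unmeth = c(1L, 1L))
  expect_error(join_samples(list(d = dup)), "unsorted or has duplicate")
})

test_that("site validity depends on coverage only", {
  t1 <- count_fixture(pos = c(10L, 20L, 30L), meth = c(0L, 3L, 1L),
                      unmeth = c(2L, 0L, 2L))
  t2 <- count_fixture(pos = c(10L, 20L), meth = c(2L, 1L), unmeth = c(0L, 1L))
  mat <- join_samples(list(a = t1, b = t2))

  # coverage 2 everywhere at site 10, r=3 -> removed; site 30 covered >= 3
  # in exactly one of two samples is kept with s=1
  f <- filter_valid_sites(mat, cluster_params(min_reads = 3, min_samples = 1))
  expect_equal(f$sites$pos, c(20L, 30L))

  # redistributing meth vs unmeth at fixed coverage changes nothing
  t1b <- count_fixture(pos = c(10L, 20L, 30L), meth = c(2L, 0L, 3L),
                       unmeth = c(0L, 3L, 0L))
  t2b <- count_fixture(pos = c(10L, 20L), meth = c(0L, 2L), unmeth = c(2L, 0L))
  f2 <- filter_valid_sites(join_samples(list(a = t1b, b = t2b)),
                           cluster_params(min_reads = 3, min_samples = 1))
  expect_equal(f2$sites, f$sites)
})

test_that("region building applies the site, span and count filters", {
  # two clusters; the second has per-sample totals (25, 19) and m=20 drops it
  t1 <- count_fixture(pos = c(10L, 40L, 70L, 1000L, 1030L, 1060L),
                      meth = c(4L, 4L, 4L, 9L, 8L, 8L),
                      unmeth = c(4L, 4L, 4L, 0L, 0L, 0L))
  t2 <- count_fixture(pos = c(10L, 40L, 70L, 1000L, 1030L, 1060L),
                      meth = c(4L, 4L, 4L, 3L, 3L, 0L),
                      unmeth = c(4L, 4L, 4L, 4L, 3L, 6L))
  mat <- join_samples(list(a = t1, b = t2))
  reg <- build_regions(mat, cluster_params())
  expect_equal(nrow(reg), 1L)
  expect_equal(reg$start, 10L)
  expect_equal(reg$end, 70L)
  expect_equal(reg$a_N, 24L)
  expect_equal(reg$a_X, 12L)

  # clusters below min_cpg are dropped
  few <- join_samples(list(a = count_fixture(pos = c(10L, 40L),
                                             meth = c(30L, 30L),
                                             unmeth = c(0L, 0L))))
  expect_equal(nrow(build_regions(few, cluster_params())), 0L)

  # empty matrix -> empty region set
  empty <- join_samples(list(a = count_fixture(integer(0), integer(0),
                                               integer(0))))
  expect_equal(nrow(build_regions(empty, cluster_params())), 0L)
})

test_that("full clustering matches a straight-line reference implementation", {
  set.seed(21)
  pos <- sort(sample.int(30000, 400))
  meth <- rbinom(400, 20, 0.4)
  tabs <- list(s1 = count_fixture(pos = pos, meth = meth, unmeth = 20L - meth))
  par <- cluster_params(min_reads = 3, min_samples = 1, max_dist = 100,
                        min_cpg = 3, max_len = 500, min_total = 20)
  got <- cluster_sites(tabs, par)

  # independent re-statement of the rules
  keep <- rep(TRUE, length(pos))          # all sites have coverage 20 >= 3
  cl <- split(pos, cumsum(c(1, diff(pos) > 100)))
  ref_rows <- list()
  for (p in cl) {
    stack <- list(p); parts <- list()
    while (length(stack)) {
      q <- stack[[1]]; stack <- stack[-1]
      if (length(q) < 2 || max(q) - min(q) <= 500) {
        parts <- c(parts, list(q)); next
      }
      g <- which.max(diff(q))
      stack <- c(list(q[1:g], q[(g + 1):length(q)]), stack)
    }
    for (q in parts) {
      if (length(q) < 3) next
      N <- 20L * length(q)
      if (N < 20) next
      ref_rows <- c(ref_rows, list(data.frame(
        start = min(q), end = max(q), n_cpg = length(q), N = N,
        X = sum(meth[match(q, pos)]))))
    }
  }
  ref <- do.call(rbind, ref_rows)
  expect_equal(got$start, ref$start)
  expect_equal(got$end, ref$end)
  expect_equal(got$n_cpg, ref$n_cpg)
  expect_equal(got$s1_N, ref$N)
  expect_equal(got$s1_X, ref$X)
  # span bound holds after splitting
  expect_true(all(got$end - got$start <= 500))
})

test_that("clustering is blind to methylation levels", {
  set.seed(33)
  pos <- sort(sample.int(20000, 250))
  N1 <- rpois(250, 8) + 1L; N2 <- rpois(250, 8) + 1L
  redistribute <- function(N) {
    m <- rbinom(length(N), N, runif(1))
    count_fixture(pos = pos, meth = m, unmeth = N - m)
  }
  base <- cluster_sites(list(a = redistribute(N1), b = redistribute(N2)))
  for (k in 1:5) {
    alt <- cluster_sites(list(a = redistribute(N1), b = redistribute(N2)))
    expect_equal(alt[c("chrom", "start", "end", "n_cpg", "a_N", "b_N")],
                 base[c("chrom", "start", "end", "n_cpg", "a_N", "b_N")])
  }
})

test_that("the biseq preset reproduces pure single-linkage clusters", {
  skip_if_not_installed("igraph")
  set.seed(8)
  pos <- sort(sample.int(20000, 300))
  m <- rbinom(300, 5, 0.5)
  tabs <- list(s = count_fixture(pos = pos, meth = m, unmeth = 5L - m))
  par <- cluster_params(preset = "biseq")
  expect_equal(par$max_len, 1e9)
  expect_equal(par$min_cpg, 5L)
  got <- cluster_sites(tabs, par)
  oracle <- Filter(function(q) length(q) >= 5, slc_oracle(pos, par$max_dist))
  expect_equal(got$start, vapply(oracle, min, numeric(1)))
  expect_equal(got$end, vapply(oracle, max, numeric(1)))
})

test_that("region tables round-trip through their writer and reader", {
  t1 <- count_fixture(pos = c(10L, 40L, 70L), meth = c(4L, 4L, 4L),
                      unmeth = c(4L, 4L, 4L))
  reg <- cluster_sites(list(a = t1, b = t1))
  path <- tempfile(fileext = ".tsv")
  write_region_table(reg, path)
  hdr <- strsplit(readLines(path, 1), "\t")[[1]]
  expect_equal(hdr, c("chrom", "start", "end", "CpG",
                      "a_N", "a_X", "a_mu", "b_N", "b_X", "b_mu"))
  back <- read_region_table(path)
  expect_equal(back$start, reg$start)
  expect_equal(back$a_N, reg$a_N)
  expect_equal(back$b_X, reg$b_X)
  expect_equal(attr(back, "samples"), c("a", "b"))

  # empty region set -> header-only file
  write_region_table(reg[0, ], path)
  expect_equal(length(readLines(path)), 1L)
  expect_equal(nrow(read_region_table(path)), 0L)
})
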