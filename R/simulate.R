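#' Simulation configuration
#'
#' Settings for the seeded generators of toy references, bisulfite reads and
#' beta-binomial region counts. The seed fully determines every output.
#'
#' Read-level settings emulate a directional bisulfite library: reads carry
#' a Bismark-style methylation-call string (`XM`, CpG calls `z`/`Z`) and
#' conversion-strand tag (`XG`, `CT`/`GA`); an optional set of loci carries
#' reads with a 1-bp deletion that creates a novel CpG site absent from the
#' reference CpG list. Count-level settings draw per-region replicate
#' totals from a shifted negative binomial and methylated counts from a
#' beta-binomial with dispersion `phi` parameterized as the intra-class
#' correlation.
#'
#' @param seed Integer seed.
#' @param chrom Chromosome name.
#' @param chrom_len Reference length in bp (default 50000).
#' @param cpg_spacing Mean gap between planted CpG sites in bp (default 50;
#'   `Inf` plants none).
#' @param read_len Read length (default 50).
#' @param mean_depth Mean per-base read depth (default 20).
#' @param paired_frac Fraction of reads generated as overlapping proper
#'   pairs (default 0).
#' @param frag_len Mean fragment length for pairs (default 80).
#' @param samples Named numeric vector: baseline per-site methylation
#'   probability per sample.
#' @param dmr_window Optional `list(start=, end=, prob=named vector)`
#'   overriding the per-sample methylation probability inside one window
#'   (used to engineer a known DMR).
#' @param n_novel Number of deletion-created novel CpG loci (default 0).
#' @param novel_depth Reads per sample over each novel locus (default 0).
#' @param novel_prob Methylation probability at novel loci (default 0.9).
#' @param junk_unmapped,junk_secondary Extra unmapped / secondary records
#'   per sample, exercising the alignment filters (default 0).
#' @param n_regions,groups,mean_N,size_N,mu,phi,diff_size,diff_frac
#'   Count-level settings: number of regions; named integer vector of
#'   replicates per group; mean and NB size of per-replicate totals
#'   (`N = 1 + NB`); named per-group baseline methylation fraction;
#'   intra-class dispersion; injected difference and the fraction of
#'   regions receiving it (added to the last group).
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L, chrom = "chrS", chrom_len = 50000L,
                       cpg_spacing = 50, read_len = 50L, mean_depth = 20,
                       paired_frac = 0, frag_len = 80L,
                       samples = c(s1 = 0.3), dmr_window = NULL,
                       n_novel = 0L, novel_depth = 0L, novel_prob = 0.9,
                       junk_unmapped = 0L, junk_secondary = 0L,
                       n_regions = 5000L, groups = c(ctrl = 3L, case = 3L),
                       mean_N = 30, size_N = 10, mu = c(ctrl = 0.1, case = 0.1),
                       phi = 0.05, diff_size = 0.3, diff_frac = 0.1) {
  stopifnot(all(samples >= 0 & samples <= 1), all(mu >= 0 & mu <= 1),
            phi >= 0, phi < 1, paired_frac >= 0, paired_frac <= 1,
            diff_frac >= 0, diff_frac <= 1)
  structure(as.list(environment()), class = "sim_config")
}

#' Generate a toy reference with known CpG positions
#'
#' Builds a CpG-free random background and plants `CG` dinucleotides at
#' recorded positions with approximately geometric spacing, plus optional
#' `CAG` loci whose adenine deletion creates a novel CpG site. The recorded
#' CpG list equals the set of `CG` dinucleotides in the sequence by
#' construction.
#'
#' @param config A [sim_config()] object.
#' @return List `chrom`, `seq` (single string), `cpg_pos` (1-based C
#'   positions), `novel_loci` (C positions of `CAG` loci).
#' @export
make_reference <- function(config) {
  set.seed(config$seed)
  len <- config$chrom_len
  base <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
  # remove accidental CpGs: G of any CG -> T (cannot create a new CG)
  cg <- which(base[-len] == "C" & base[-1L] == "G")
  if (length(cg)) base[cg + 1L] <- "T"

  cpg <- integer(0)
  if (is.finite(config$cpg_spacing) && config$cpg_spacing > 0) {
    gaps <- 2L + stats::rgeom(ceiling(2 * len / config$cpg_spacing),
                              1 / max(config$cpg_spacing - 2, 1))
    pos <- 10L + cumsum(gaps)
    cpg <- pos[pos < len - 10L]
    base[cpg] <- "C"
    base[cpg + 1L] <- "G"
  }

  novel <- integer(0)
  if (config$n_novel > 0 && length(cpg) > 1L) {
    # place CAG loci midway inside the largest inter-CpG gaps
    gaps <- diff(cpg)
    ord <- order(gaps, decreasing = TRUE)
    take <- ord[seq_len(min(config$n_novel, sum(gaps >= 12L)))]
    novel <- sort(cpg[take] + gaps[take] %/% 2L)
    base[novel] <- "C"; base[novel + 1L] <- "A"; base[novel + 2L] <- "G"
  }
  list(chrom = config$chrom, seq = paste(base, collapse = ""),
       cpg_pos = cpg, novel_loci = novel)
}

# one SAM line
.sam_line <- function(qname, flag, chrom, pos, mapq, cigar, rnext, pnext,
                      tlen, seq, xm, xg) {
  paste(qname, flag, chrom, pos, mapq, cigar, rnext, pnext, tlen, seq,
        strrep("I", nchar(seq)),
        paste0("XM:Z:", xm), paste0("XG:Z:", xg), sep = "\t")
}

# Build XM strings for a block of same-length reads: a character matrix is
# filled "." and call positions set, then pasted column-wise.
.xm_strings <- function(n_reads, read_len, rid, qidx, state) {
  m <- matrix(".", nrow = n_reads, ncol = read_len)
  if (length(rid)) m[cbind(rid, qidx)] <- ifelse(state, "Z", "z")
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

#' Simulate Bismark-dialect bisulfite reads
#'
#' Writes one SAM file per sample (header + reads with `XM`/`XG` tags) and
#' returns the ground-truth per-site call counts actually delivered —
#' i.e. after discounting the overlapping portion of second mates, so the
#' truth equals what [tabulate_counts()] must recover exactly. Methylation
#' states are Bernoulli draws from the configured per-site probabilities;
#' for proper pairs the state is drawn once per fragment. Optional reads
#' over `CAG` loci carry a 1-bp deletion whose call string marks a
#' methylation call at the novel CpG site.
#'
#' @param config A [sim_config()] object.
#' @param ref Reference from [make_reference()].
#' @param dir Output directory for the SAM files (default `tempdir()`).
#' @return List `sam` (named paths), `truth` (named list of count tables in
#'   [tabulate_counts()] layout), `ref`.
#' @export
simulate_reads <- function(config, ref, dir = tempdir()) {
  set.seed(config$seed + 1L)
  rl <- config$read_len
  len <- config$chrom_len
  cpg <- ref$cpg_pos
  novel <- ref$novel_loci
  refbase <- strsplit(ref$seq, "")[[1L]]
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              paste0("@SQ\tSN:", ref$chrom, "\tLN:", len))

  site_prob <- function(sample, positions) {
    p <- rep(config$samples[[sample]], length(positions))
    w <- config$dmr_window
    if (!is.null(w)) {
      inw <- positions >= w$start & positions <= w$end
      p[inw] <- w$prob[[sample]]
    }
    p
  }

  out_paths <- character(0)
  truths <- list()
  for (sample in names(config$samples)) {
    n_reads <- ceiling(config$mean_depth * len / rl)
    n_pairs <- floor(n_reads * config$paired_frac / 2)
    n_single <- n_reads - 2L * n_pairs
    lines <- character(0)
    tt_pos <- integer(0); tt_meth <- logical(0)

    ## --- single-end reads ------------------------------------------------
    if (n_single > 0L) {
      start <- sample.int(len - rl + 1L, n_single, replace = TRUE)
      xg <- sample(c("CT", "GA"), n_single, replace = TRUE)
      # covered CpG indices: CT reads call at the C, GA reads at the G (C+1)
      call_at <- function(i) {
        off <- if (xg[i] == "GA") 1L else 0L
        j <- which(cpg + off >= start[i] & cpg + off <= start[i] + rl - 1L)
        j
      }
      covered <- lapply(seq_len(n_single), call_at)
      nper <- lengths(covered)
      rid <- rep.int(seq_len(n_single), nper)
      sidx <- unlist(covered, use.names = FALSE)
      qidx <- cpg[sidx] + (xg[rid] == "GA") - start[rid] + 1L
      state <- stats::rbinom(length(sidx), 1L,
                             site_prob(sample, cpg[sidx])) == 1L
      xm <- .xm_strings(n_single, rl, rid, qidx, state)
      seqs <- substring(ref$seq, start, start + rl - 1L)
      flags <- ifelse(xg == "GA", 16L, 0L)
      lines <- c(lines, .sam_line(
        paste0(sample, "_r", seq_len(n_single)), flags, ref$chrom, start,
        42L, paste0(rl, "M"), "*", 0L, 0L, seqs, xm, xg))
      tt_pos <- c(tt_pos, cpg[sidx])
      tt_meth <- c(tt_meth, state)
    }

    ## --- proper pairs (overlapping mates) --------------------------------
    if (n_pairs > 0L) {
      flen <- pmax(rl, round(stats::rnorm(n_pairs, config$frag_len, 5)))
      fstart <- sample.int(len - max(flen), n_pairs, replace = TRUE)
      xg <- sample(c("CT", "GA"), n_pairs, replace = TRUE)
      for (i in seq_len(n_pairs)) {
        off <- if (xg[i] == "GA") 1L else 0L
        s1 <- fstart[i]; s2 <- fstart[i] + flen[i] - rl
        frag_sites <- which(cpg + off >= s1 & cpg + off <= s2 + rl - 1L)
        st <- stats::rbinom(length(frag_sites), 1L,
                            site_prob(sample, cpg[frag_sites])) == 1L
        in1 <- cpg[frag_sites] + off <= s1 + rl - 1L
        in2 <- cpg[frag_sites] + off >= s2
        q1 <- cpg[frag_sites][in1] + off - s1 + 1L
        q2 <- cpg[frag_sites][in2] + off - s2 + 1L
        xm1 <- .xm_strings(1L, rl, rep(1L, sum(in1)), q1, st[in1])
        xm2 <- .xm_strings(1L, rl, rep(1L, sum(in2)), q2, st[in2])
        qn <- paste0(sample, "_p", i)
        lines <- c(lines,
          .sam_line(qn, 99L, ref$chrom, s1, 42L, paste0(rl, "M"), "=",
                    s2, flen[i], substring(ref$seq, s1, s1 + rl - 1L),
                    xm1, xg[i]),
          .sam_line(qn, 147L, ref$chrom, s2, 42L, paste0(rl, "M"), "=",
                    s1, -flen[i], substring(ref$seq, s2, s2 + rl - 1L),
                    xm2, xg[i]))
        # truth: mate 1 in full, mate 2 only outside mate 1's span
        keep2 <- in2 & (cpg[frag_sites] + off > s1 + rl - 1L)
        tt_pos <- c(tt_pos, cpg[frag_sites][in1], cpg[frag_sites][keep2])
        tt_meth <- c(tt_meth, st[in1], st[keep2])
      }
    }

    ## --- deletion reads over novel CpG loci (CT strand) -------------------
    if (config$novel_depth > 0L && length(novel)) {
      for (q in novel) {
        for (k in seq_len(config$novel_depth)) {
          a <- 10L + ((k - 1L) %% 20L)       # query bases up to and incl. C
          start <- q - a + 1L
          b <- rl - a
          cigar <- paste0(a, "M1D", b, "M")
          # genuine CpGs covered on either side of the deletion
          left  <- which(cpg >= start & cpg <= q - 1L)
          right <- which(cpg >= q + 2L & cpg <= q + 1L + b)
          qidx <- c(cpg[left] - start + 1L, cpg[right] - start, a)
          pr <- c(site_prob(sample, cpg[left]), site_prob(sample, cpg[right]),
                  config$novel_prob)
          st <- stats::rbinom(length(qidx), 1L, pr) == 1L
          xm <- .xm_strings(1L, rl, rep(1L, length(qidx)), qidx, st)
          seqs <- paste0(substring(ref$seq, start, q),
                         substring(ref$seq, q + 2L, q + 1L + b))
          lines <- c(lines, .sam_line(
            paste0(sample, "_n", q, "_", k), 0L, ref$chrom, start, 42L,
            cigar, "*", 0L, 0L, seqs, xm, "CT"))
          tt_pos <- c(tt_pos, cpg[left], cpg[right], q)
          tt_meth <- c(tt_meth, st)
        }
      }
    }

    ## --- junk records exercising the filters ------------------------------
    if (config$junk_unmapped > 0L) {
      for (k in seq_len(config$junk_unmapped)) {
        lines <- c(lines, paste(paste0(sample, "_u", k), 4L, "*", 0L, 0L,
                                "*", "*", 0L, 0L,
                                paste(rep("A", rl), collapse = ""),
                                paste(rep("I", rl), collapse = ""),
                                sep = "\t"))
      }
    }
    if (config$junk_secondary > 0L && length(cpg)) {
      for (k in seq_len(config$junk_secondary)) {
        lines <- c(lines, .sam_line(
          paste0(sample, "_x", k), 256L, ref$chrom, cpg[1L], 42L,
          paste0(rl, "M"), "*", 0L, 0L,
          substring(ref$seq, cpg[1L], cpg[1L] + rl - 1L),
          paste(rep(".", rl), collapse = ""), "CT"))
      }
    }

    path <- file.path(dir, paste0("sim_", sample, ".sam"))
    writeLines(c(header, lines), path)
    out_paths[sample] <- path

    tt <- data.table::data.table(pos = tt_pos, meth = tt_meth)
    tt <- tt[, list(meth = sum(meth), unmeth = sum(!meth)), keyby = pos]
    truth <- data.frame(chrom = ref$chrom, pos = tt$pos,
                        meth = as.integer(tt$meth),
                        unmeth = as.integer(tt$unmeth),
                        stringsAsFactors = FALSE)
    attr(truth, "chrom_order") <- ref$chrom
    truths[[sample]] <- truth
  }
  list(sam = out_paths, truth = truths, ref = ref)
}

#' Simulate a beta-binomial region count table
#'
#' Per region and replicate, totals are `N = 1 + NB(size_N, mean_N - 1)`
#' and methylated counts are beta-binomial: `p ~ Beta(a, b)` with
#' `a = mu (1-phi)/phi`, `b = (1-mu)(1-phi)/phi` (so `phi` is the
#' intra-class correlation; `phi = 0` degenerates to `Binomial(N, mu)`),
#' then `X ~ Binomial(N, p)`. A seeded fraction `diff_frac` of regions has
#' `diff_size` added to the last group's `mu` (clamped to `[0, 1]`);
#' the truth labels record which.
#'
#' @param config A [sim_config()] object.
#' @return List `regions` (region table in [build_regions()] layout, one
#'   nominal 5-CpG region per row), `truth` (data.frame `region`,
#'   `is_diff`, `<group>_mu`), `groups` (named list mapping group to
#'   sample names).
#' @export
simulate_region_counts <- function(config) {
  set.seed(config$seed)
  ng <- config$n_regions
  groups <- config$groups
  stopifnot(!is.null(names(groups)), all(groups >= 1L))
  diff_group <- names(groups)[length(groups)]

  is_diff <- rep(FALSE, ng)
  n_diff <- round(config$diff_frac * ng)
  if (n_diff > 0L) is_diff[sample.int(ng, n_diff)] <- TRUE

  regions <- data.frame(chrom = "sim",
                        start = seq_len(ng) * 1000L,
                        end = seq_len(ng) * 1000L + 100L,
                        n_cpg = 5L, stringsAsFactors = FALSE)
  truth <- data.frame(region = seq_len(ng), is_diff = is_diff)
  samples <- character(0)
  group_map <- list()
  for (g in names(groups)) {
    mu_g <- rep(config$mu[[g]], ng)
    if (g == diff_group) {
      mu_g[is_diff] <- pmin(pmax(mu_g[is_diff] + config$diff_size, 0), 1)
    }
    truth[[paste0(g, "_mu")]] <- mu_g
    reps <- paste0(g, "_", seq_len(groups[[g]]))
    group_map[[g]] <- reps
    for (s in reps) {
      N <- 1L + stats::rnbinom(ng, size = config$size_N,
                               mu = config$mean_N - 1)
      if (config$phi > 0) {
        a <- mu_g * (1 - config$phi) / config$phi
        b <- (1 - mu_g) * (1 - config$phi) / config$phi
        p <- ifelse(mu_g <= 0, 0, ifelse(mu_g >= 1, 1, NA))
        todo <- is.na(p)
        p[todo] <- stats::rbeta(sum(todo), a[todo], b[todo])
      } else {
        p <- mu_g
      }
      regions[[paste0(s, "_N")]] <- N
      regions[[paste0(s, "_X")]] <- stats::rbinom(ng, N, p)
    }
    samples <- c(samples, reps)
  }
  attr(regions, "samples") <- samples
  list(regions = regions, truth = truth, groups = group_map)
}
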