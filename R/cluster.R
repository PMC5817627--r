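#' Clustering parameters
#'
#' Parameters controlling which CpG sites are valid and how they are grouped
#' into regions. Defaults: a site is valid when at least `min_samples`
#' samples cover it with `min_reads` reads or more; valid sites within
#' `max_dist` bp join a cluster; clusters longer than `max_len` bp are split
#' at their largest internal gaps; emitted regions need at least `min_cpg`
#' member sites and a summed methylation count of at least `min_total` in
#' every sample. The `"biseq"` preset reproduces BiSeq-style pure
#' single-linkage clusters (no length splitting, five-site minimum, no
#' count filters).
#'
#' @param min_reads Per-site per-sample coverage minimum (`r`, default 3).
#' @param min_samples Samples that must meet `min_reads` (`s`, default 1).
#' @param max_dist Maximum gap in bp joining adjacent valid sites
#'   (`d`, default 100).
#' @param min_cpg Minimum member sites per region (`c`, default 3).
#' @param max_len Maximum region span in bp before splitting
#'   (`x`, default 500).
#' @param min_total Minimum summed meth+unmeth per sample per region
#'   (`m`, default 20).
#' @param preset Optional named preset; `"biseq"` sets
#'   `min_reads = 1, min_samples = 1, min_total = 1, max_len = 1e9,
#'   min_cpg = 5`.
#' @return A `cluster_params` list.
#' @export
cluster_params <- function(min_reads = 3L, min_samples = 1L, max_dist = 100L,
                           min_cpg = 3L, max_len = 500, min_total = 20L,
                           preset = NULL) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, "biseq")
    min_reads <- 1L; min_samples <- 1L; min_total <- 1L
    max_len <- 1e9; min_cpg <- 5L
  }
  p <- list(min_reads = as.integer(min_reads),
            min_samples = as.integer(min_samples),
            max_dist = as.numeric(max_dist),
            min_cpg = as.integer(min_cpg),
            max_len = as.numeric(max_len),
            min_total = as.integer(min_total))
  if (any(vapply(p, function(v) v < 1, logical(1)))) {
    stop("all clustering parameters must be positive")
  }
  structure(p, class = "cluster_params")
}

#' Join per-sample count tables into a site-by-sample matrix
#'
#' Full outer join on (chrom, pos); sites absent from a sample are missing
#' (`NA`) there. Chromosome order follows first appearance across the input
#' tables.
#'
#' @param tables List of count tables ([read_count_table()] /
#'   [tabulate_counts()] output), each sorted and unique per site.
#' @param samples Sample names; defaults to `names(tables)`.
#' @return A `site_matrix`: list with `sites` (data.frame `chrom`, `pos`),
#'   integer matrices `X` (methylated) and `N` (total, `NA` = absent), and
#'   `samples`, `chrom_order`.
#' @export
join_samples <- function(tables, samples = names(tables)) {
  stopifnot(length(tables) >= 1L)
  if (is.null(samples)) samples <- paste0("sample", seq_along(tables))
  chrom_order <- unique(unlist(lapply(tables, function(t) unique(t$chrom))))
  for (k in seq_along(tables)) {
    t <- tables[[k]]
    f <- factor(t$chrom, levels = chrom_order)
    o <- order(as.integer(f), t$pos)
    if (is.unsorted(o, strictly = TRUE) ||
        anyDuplicated(paste(t$chrom, t$pos))) {
      stop("count table '", samples[k], "' is unsorted or has duplicate sites")
    }
  }
  long <- data.table::rbindlist(lapply(seq_along(tables), function(k) {
    t <- tables[[k]]
    data.table::data.table(sample = samples[k], chrom = t$chrom,
                           pos = t$pos, X = t$meth, N = t$meth + t$unmeth)
  }))
  long[, chromf := factor(chrom, levels = chrom_order)]
  long[, sample := factor(sample, levels = samples)]
  wX <- data.table::dcast(long, chromf + pos ~ sample, value.var = "X",
                          drop = c(TRUE, FALSE))
  wN <- data.table::dcast(long, chromf + pos ~ sample, value.var = "N",
                          drop = c(TRUE, FALSE))
  data.table::setorder(wX, chromf, pos)
  data.table::setorder(wN, chromf, pos)
  X <- as.matrix(wX[, -(1:2)]); storage.mode(X) <- "integer"
  N <- as.matrix(wN[, -(1:2)]); storage.mode(N) <- "integer"
  colnames(X) <- colnames(N) <- samples
  structure(list(sites = data.frame(chrom = as.character(wX$chromf),
                                    pos = wX$pos, stringsAsFactors = FALSE),
                 X = X, N = N, samples = samples,
                 chrom_order = chrom_order),
            class = "site_matrix")
}

#' @export
print.site_matrix <- function(x, ...) {
  cat("site_matrix:", nrow(x$sites), "CpG sites x",
      length(x$samples), "samples\n")
  invisible(x)
}

#' Split a site matrix back into per-sample count tables
#'
#' Inverse of [join_samples()]: missing cells disappear from the per-sample
#' tables.
#'
#' @param mat A `site_matrix`.
#' @return Named list of count tables.
#' @export
split_samples <- function(mat) {
  out <- lapply(seq_along(mat$samples), function(k) {
    keep <- !is.na(mat$N[, k])
    df <- data.frame(chrom = mat$sites$chrom[keep], pos = mat$sites$pos[keep],
                     meth = mat$X[keep, k],
                     unmeth = mat$N[keep, k] - mat$X[keep, k],
                     stringsAsFactors = FALSE)
    attr(df, "chrom_order") <- mat$chrom_order
    df
  })
  names(out) <- mat$samples
  out
}

#' Keep CpG sites meeting the coverage criteria
#'
#' A site is valid when at least `min_samples` samples cover it with
#' `min_reads` or more reads. Methylation levels are never consulted, so
#' site selection cannot bias the downstream differential test.
#'
#' @param mat A `site_matrix`.
#' @param params A [cluster_params()] object.
#' @return The filtered `site_matrix`.
#' @export
filter_valid_sites <- function(mat, params = cluster_params()) {
  covered <- !is.na(mat$N) & mat$N >= params$min_reads
  keep <- rowSums(covered) >= params$min_samples
  mat$sites <- mat$sites[keep, , drop = FALSE]
  rownames(mat$sites) <- NULL
  mat$X <- mat$X[keep, , drop = FALSE]
  mat$N <- mat$N[keep, , drop = FALSE]
  mat
}

#' Single-linkage clustering of positions on one chromosome
#'
#' Adjacent sites whose gap is at most `max_dist` share a cluster; clusters
#' are maximal, i.e. the sorted list is cut at every gap exceeding
#' `max_dist`.
#'
#' @param pos Strictly increasing positions.
#' @param max_dist Maximum joining gap in bp.
#' @return List of position vectors, one per cluster, in order.
#' @export
single_linkage <- function(pos, max_dist) {
  if (length(pos) == 0L) return(list())
  if (is.unsorted(pos, strictly = TRUE)) {
    stop("positions must be strictly increasing")
  }
  grp <- cumsum(c(TRUE, diff(pos) > max_dist))
  unname(split(pos, grp))
}

#' Split an oversized cluster at its largest internal gaps
#'
#' Recursively bisects at the largest internal gap (leftmost on ties) until
#' every sub-cluster spans at most `max_len` bp; membership and order are
#' preserved, and clusters already within the bound are returned unchanged.
#' This limits the chaining effect of single-linkage clustering, in which
#' an extended series of intermediate sites merges distant sites into one
#' region.
#'
#' @param pos Sorted member positions of one cluster.
#' @param max_len Maximum allowed span (last - first) in bp.
#' @return List of position vectors, in order.
#' @export
split_oversized <- function(pos, max_len) {
  if (length(pos) == 0L) return(list())
  out <- list()
  stack <- list(pos)
  while (length(stack)) {
    p <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    if (length(p) < 2L || p[length(p)] - p[1L] <= max_len) {
      out[[length(out) + 1L]] <- p
    } else {
      g <- which.max(diff(p))  # leftmost largest gap
      stack[[length(stack) + 1L]] <- p[(g + 1L):length(p)]
      stack[[length(stack) + 1L]] <- p[1L:g]
    }
  }
  out
}

#' Build regions from a filtered site matrix
#'
#' Clusters valid sites per chromosome ([single_linkage()]), splits
#' oversized clusters ([split_oversized()]), drops clusters with fewer than
#' `min_cpg` sites, aggregates per-sample methylated (`X`) and total (`N`)
#' counts over member sites (missing cells contribute zero), and drops
#' regions whose summed total in any sample is below `min_total`.
#'
#' @param mat A `site_matrix` already filtered with [filter_valid_sites()].
#' @param params A [cluster_params()] object.
#' @return data.frame `chrom`, `start`, `end` (positions of the first/last
#'   member CpG, 1-based inclusive), `n_cpg`, then `<sample>_N` and
#'   `<sample>_X` per sample; attributes `samples` and `sites` (list of
#'   member positions).
#' @export
build_regions <- function(mat, params = cluster_params()) {
  samples <- mat$samples
  empty <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), n_cpg = integer(0))
  for (s in samples) {
    empty[[paste0(s, "_N")]] <- integer(0)
    empty[[paste0(s, "_X")]] <- integer(0)
  }
  attr(empty, "samples") <- samples
  attr(empty, "sites") <- list()
  if (nrow(mat$sites) == 0L) return(empty)

  rows <- list(); members <- list()
  for (ch in unique(mat$sites$chrom)) {
    idx <- which(mat$sites$chrom == ch)
    pos <- mat$sites$pos[idx]
    for (cl in single_linkage(pos, params$max_dist)) {
      for (sub in split_oversized(cl, params$max_len)) {
        if (length(sub) < params$min_cpg) next
        ridx <- idx[match(sub, pos)]
        N <- colSums(mat$N[ridx, , drop = FALSE], na.rm = TRUE)
        if (any(N < params$min_total)) next
        X <- colSums(mat$X[ridx, , drop = FALSE], na.rm = TRUE)
        rec <- data.frame(chrom = ch, start = sub[1L],
                          end = sub[length(sub)], n_cpg = length(sub),
                          stringsAsFactors = FALSE)
        for (k in seq_along(samples)) {
          rec[[paste0(samples[k], "_N")]] <- as.integer(N[k])
          rec[[paste0(samples[k], "_X")]] <- as.integer(X[k])
        }
        rows[[length(rows) + 1L]] <- rec
        members[[length(members) + 1L]] <- sub
      }
    }
  }
  if (length(rows) == 0L) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "samples") <- samples
  attr(out, "sites") <- members
  out
}

#' Cluster count tables into regions
#'
#' Convenience composition: [join_samples()] (if given tables),
#' [filter_valid_sites()], then [build_regions()].
#'
#' @param tables Named list of count tables, or a `site_matrix`.
#' @param params A [cluster_params()] object.
#' @return Region data.frame (see [build_regions()]).
#' @export
cluster_sites <- function(tables, params = cluster_params()) {
  mat <- if (inherits(tables, "site_matrix")) tables else join_samples(tables)
  build_regions(filter_valid_sites(mat, params), params)
}

# --- region-table I/O -------------------------------------------------------

#' Write a region table
#'
#' Tab-delimited with header: `chrom`, `start`, `end`, `CpG`, then per
#' sample `<s>_N`, `<s>_X`, `<s>_mu` (`X/N`; `NA` when `N` is zero).
#'
#' @param regions Region data.frame from [build_regions()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_region_table <- function(regions, path) {
  samples <- attr(regions, "samples")
  if (is.null(samples)) samples <- .region_samples(regions)
  df <- data.frame(chrom = regions$chrom, start = regions$start,
                   end = regions$end, CpG = regions$n_cpg)
  for (s in samples) {
    N <- regions[[paste0(s, "_N")]]
    X <- regions[[paste0(s, "_X")]]
    df[[paste0(s, "_N")]] <- N
    df[[paste0(s, "_X")]] <- X
    df[[paste0(s, "_mu")]] <- ifelse(N > 0, X / N, NA_real_)
  }
  ok <- tryCatch({
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stop("cannot write region table to ", path)
  invisible(path)
}

.region_samples <- function(regions) {
  nm <- names(regions)
  sub("_N$", "", nm[grepl("_N$", nm)])
}

#' Read a region table
#'
#' @param path Path written by [write_region_table()].
#' @return Region data.frame with columns `chrom`, `start`, `end`, `n_cpg`
#'   and per-sample `_N`/`_X` columns; attribute `samples`.
#' @export
read_region_table <- function(path) {
  if (!file.exists(path)) stop("region table not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = c(chrom = "character"),
                          stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "CpG")
  if (!all(need %in% names(df))) {
    stop("malformed region table ", path)
  }
  samples <- sub("_N$", "", names(df)[grepl("_N$", names(df))])
  out <- data.frame(chrom = df$chrom, start = as.integer(df$start),
                    end = as.integer(df$end), n_cpg = as.integer(df$CpG),
                    stringsAsFactors = FALSE)
  for (s in samples) {
    out[[paste0(s, "_N")]] <- as.integer(df[[paste0(s, "_N")]])
    out[[paste0(s, "_X")]] <- as.integer(df[[paste0(s, "_X")]])
  }
  attr(out, "samples") <- samples
  out
}
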