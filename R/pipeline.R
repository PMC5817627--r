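#' Read BED intervals
#'
#' BED files are 0-based half-open; coordinates are converted to the
#' 1-based inclusive convention used throughout the package (conversion
#' happens only at this boundary, via `rtracklayer`).
#'
#' @param path BED file path.
#' @return data.frame `chrom`, `start`, `end` (1-based inclusive).
#' @export
read_bed_intervals <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  gr <- rtracklayer::import(path, format = "BED")
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr),  # already 1-based inclusive
             end = GenomicRanges::end(gr), stringsAsFactors = FALSE)
}

.log_msg <- function(verbose, ...) {
  if (verbose) message("[dmrkit] ", ...)
}

#' Run the extraction stage
#'
#' Converts each alignment file into a sorted per-CpG count table;
#' optionally writes a Bismark-coverage-style file and a linkage-pattern
#' report over user-specified intervals. A summary of record and call
#' attrition is logged to standard error.
#'
#' @param inputs Character vector of SAM/BAM paths.
#' @param outputs Count-table output paths (same length).
#' @param dedup_overlap Clip second-mate overlaps (default `TRUE`).
#' @param min_mapq Minimum mapping quality (default 0 = off).
#' @param intervals Optional BED path or data.frame for linkage patterns.
#' @param linkage_out Output path for the linkage report (required when
#'   `intervals` given).
#' @param coverage_out Optional Bismark-coverage-style output paths.
#' @param verbose Log per-stage counters (default `TRUE`).
#' @return Invisibly, the list of count tables.
#' @export
run_extract <- function(inputs, outputs, dedup_overlap = TRUE, min_mapq = 0L,
                        intervals = NULL, linkage_out = NULL,
                        coverage_out = NULL, verbose = TRUE) {
  stopifnot(length(inputs) == length(outputs))
  if (!is.null(intervals) && is.character(intervals)) {
    intervals <- read_bed_intervals(intervals)
  }
  tables <- vector("list", length(inputs))
  link <- list()
  for (k in seq_along(inputs)) {
    aln <- read_bismark_alignments(inputs[k], min_mapq = min_mapq)
    .log_msg(verbose, "extract ", inputs[k], ": ", aln$log$records,
             " records, ", aln$log$kept, " used (",
             aln$log$unmapped, " unmapped, ", aln$log$secondary,
             " secondary, ", aln$log$supplementary, " supplementary, ",
             aln$log$low_mapq, " low MAPQ, ", aln$log$missing_tags,
             " missing tags)")
    counts <- tabulate_counts(aln, dedup_overlap = dedup_overlap)
    lg <- attr(counts, "log")
    .log_msg(verbose, "extract ", inputs[k], ": ", lg$calls_total,
             " CpG calls, ", lg$calls_dropped_noref,
             " without reference coordinate, ", lg$calls_dedup_removed,
             " removed as mate overlap; ", nrow(counts), " sites")
    write_count_table(counts, outputs[k])
    tables[[k]] <- counts
    if (!is.null(intervals)) {
      lp <- extract_linkage_patterns(aln, intervals,
                                     dedup_overlap = dedup_overlap)
      if (nrow(lp)) lp <- cbind(sample = basename(inputs[k]), lp)
      link[[k]] <- lp
    }
  }
  if (!is.null(intervals)) {
    if (is.null(linkage_out)) stop("intervals given but no linkage_out")
    lp <- do.call(rbind, link[lengths(link) > 0])
    if (is.null(lp)) {
      lp <- data.frame(sample = character(0), chrom = character(0),
                       start = integer(0), end = integer(0),
                       sites = integer(0), pattern = character(0),
                       count = integer(0))
    }
    utils::write.table(lp, linkage_out, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
  }
  if (!is.null(coverage_out)) {
    stopifnot(length(coverage_out) == length(inputs))
    for (k in seq_along(inputs)) {
      write_bismark_coverage(tables[[k]], coverage_out[k])
    }
  }
  invisible(tables)
}

#' Run the clustering stage
#'
#' Joins per-sample count tables, selects valid sites, clusters them into
#' regions and writes the region table.
#'
#' @param count_paths Named character vector (names = sample names) of
#'   count-table paths.
#' @param output Region-table output path.
#' @param params A [cluster_params()] object.
#' @param verbose Log attrition (default `TRUE`).
#' @return Invisibly, the region data.frame.
#' @export
run_cluster <- function(count_paths, output, params = cluster_params(),
                        verbose = TRUE) {
  if (is.null(names(count_paths)) || any(names(count_paths) == "")) {
    names(count_paths) <- sub("\\.[^.]*$", "", basename(count_paths))
  }
  tables <- lapply(count_paths, read_count_table)
  mat <- join_samples(tables, names(count_paths))
  valid <- filter_valid_sites(mat, params)
  regions <- build_regions(valid, params)
  .log_msg(verbose, "cluster: ", nrow(mat$sites), " sites, ",
           nrow(valid$sites), " valid, ", nrow(regions), " regions")
  write_region_table(regions, output)
  invisible(regions)
}

#' Run the differential-methylation stage
#'
#' Reads a region table, tests all pairwise group comparisons and writes
#' the DMR table (and optionally BED files of the flagged regions).
#'
#' @param region_path Region-table path.
#' @param groups Named list mapping group names to sample names.
#' @param output DMR-table output path.
#' @param params A [test_params()] object.
#' @param bed_out Optional BED output path (first comparison).
#' @param verbose Log counts (default `TRUE`).
#' @return Invisibly, the DMR data.frame.
#' @export
run_test <- function(region_path, groups, output, params = test_params(),
                     bed_out = NULL, verbose = TRUE) {
  regions <- read_region_table(region_path)
  dmr <- call_dmrs(regions, groups, params)
  for (comp in attr(dmr, "comparisons")) {
    .log_msg(verbose, "test ", comp, ": ", nrow(dmr), " regions tested, ",
             sum(dmr[[paste0(comp, "_dmr")]], na.rm = TRUE), " DMRs")
  }
  write_dmr_table(dmr, output)
  if (!is.null(bed_out)) write_dmr_bed(dmr, bed_out)
  invisible(dmr)
}

#' Run the full pipeline
#'
#' `extract` then `cluster` then `test`, composable with the individual
#' stage functions (running the stages separately produces byte-identical
#' outputs).
#'
#' @param inputs Named character vector (names = sample names) of SAM/BAM
#'   paths.
#' @param groups Named list mapping group names to sample names.
#' @param out_dir Output directory for intermediate and final tables.
#' @param cluster_par A [cluster_params()] object.
#' @param test_par A [test_params()] object.
#' @param dedup_overlap,min_mapq Passed to [run_extract()].
#' @param verbose Log attrition (default `TRUE`).
#' @return Invisibly, the DMR data.frame.
#' @export
run_all <- function(inputs, groups, out_dir,
                    cluster_par = cluster_params(), test_par = test_params(),
                    dedup_overlap = TRUE, min_mapq = 0L, verbose = TRUE) {
  if (is.null(names(inputs)) || any(names(inputs) == "")) {
    names(inputs) <- sub("\\.[^.]*$", "", basename(inputs))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  counts <- file.path(out_dir, paste0(names(inputs), "_counts.tsv"))
  names(counts) <- names(inputs)
  run_extract(inputs, counts, dedup_overlap = dedup_overlap,
              min_mapq = min_mapq, verbose = verbose)
  regions_path <- file.path(out_dir, "regions.tsv")
  run_cluster(counts, regions_path, cluster_par, verbose = verbose)
  run_test(regions_path, groups, file.path(out_dir, "dmrs.tsv"),
           test_par, verbose = verbose)
}

#' Validate a pipeline table file
#'
#' Checks column layout, 1-based positive coordinates, count sanity and
#' sortedness (chromosome blocks with strictly increasing positions for
#' count tables; non-overlapping ordered regions for region tables).
#' Returns `TRUE` or a diagnostic string naming the first offending line
#' (1-based, counting the header).
#'
#' @param path File path.
#' @param schema `"counts"` or `"regions"`.
#' @return `TRUE`, or a character diagnostic.
#' @export
validate_table <- function(path, schema = c("counts", "regions")) {
  schema <- match.arg(schema)
  if (!file.exists(path)) stop("cannot read ", path)
  df <- tryCatch(
    suppressWarnings(
      utils::read.table(path, header = TRUE, sep = "\t",
                        colClasses = c(chrom = "character"),
                        stringsAsFactors = FALSE)),
    error = function(e) NULL)
  if (is.null(df)) return(paste0(path, ": not a tab-delimited table"))
  line <- function(i) i + 1L  # header offset

  if (schema == "counts") {
    need <- c("chrom", "pos", "total", "meth", "unmeth")
    if (!all(need %in% names(df))) {
      return(paste0(path, ": line 1: expected columns ",
                    paste(need, collapse = ", ")))
    }
    if (nrow(df) == 0L) return(TRUE)
    bad <- which(df$pos < 1)[1L]
    if (!is.na(bad)) return(paste0(path, ": line ", line(bad),
                                   ": non-positive position"))
    bad <- which(df$meth < 0 | df$unmeth < 0 |
                 df$total != df$meth + df$unmeth | df$total < 1)[1L]
    if (!is.na(bad)) return(paste0(path, ": line ", line(bad),
                                   ": inconsistent counts"))
    ch <- factor(df$chrom, levels = unique(df$chrom))
    o <- diff(as.integer(ch)) < 0
    if (any(o)) return(paste0(path, ": line ", line(which(o)[1L] + 1L),
                              ": chromosome blocks interleaved"))
    same <- diff(as.integer(ch)) == 0
    bad <- which(same & diff(df$pos) <= 0)[1L]
    if (!is.na(bad)) return(paste0(path, ": line ", line(bad + 1L),
                                   ": positions out of order"))
    return(TRUE)
  }

  need <- c("chrom", "start", "end", "CpG")
  if (!all(need %in% names(df))) {
    return(paste0(path, ": line 1: expected columns ",
                  paste(need, collapse = ", ")))
  }
  if (nrow(df) == 0L) return(TRUE)
  bad <- which(df$start < 1 | df$end < df$start | df$CpG < 1)[1L]
  if (!is.na(bad)) return(paste0(path, ": line ", line(bad),
                                 ": bad region coordinates"))
  ch <- factor(df$chrom, levels = unique(df$chrom))
  same <- diff(as.integer(ch)) == 0
  bad <- which(same & diff(df$start) <= 0)[1L]
  if (!is.na(bad)) return(paste0(path, ": line ", line(bad + 1L),
                                 ": regions out of order"))
  TRUE
}
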