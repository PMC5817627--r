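#' Read Bismark-style bisulfite alignments
#'
#' Parses a SAM or BAM file produced by a bisulfite aligner in the Bismark
#' dialect: each primary alignment carries a per-base methylation-call string
#' (tag `XM`, with `z`/`Z` marking un/methylated CpG calls) and a conversion
#' strand (tag `XG`, `CT` or `GA`). Unmapped, secondary and supplementary
#' records are skipped and counted; mapped primary records lacking the `XM`
#' or `XG` tag are skipped with a warning counter.
#'
#' @param path Path to a SAM or BAM file (SAM is converted internally).
#' @param min_mapq Minimum mapping quality; `0` (the default) disables the
#'   filter.
#' @return A `bis_aln` object: parallel vectors `qname`, `flag`, `chrom`,
#'   `pos`, `cigar`, `xm`, `xg`, plus `chrom_levels` (chromosome order taken
#'   from the alignment header) and a `log` list of record counters.
#' @export
read_bismark_alignments <- function(path, min_mapq = 0L) {
  if (!file.exists(path)) stop("alignment file not found: ", path)
  bam <- path
  if (!grepl("\\.bam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile("dmrkit_aln_"),
                            overwrite = TRUE, indexDestination = FALSE)
  }
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar"),
    tag  = c("XM", "XG"))
  rec <- Rsamtools::scanBam(bam, param = param)[[1L]]

  flag <- rec$flag
  n <- length(flag)
  unmapped  <- bitwAnd(flag, 4L) > 0L
  secondary <- bitwAnd(flag, 256L) > 0L
  suppl     <- bitwAnd(flag, 2048L) > 0L
  mapq <- rec$mapq
  lowq <- !unmapped & !is.na(mapq) & mapq < min_mapq

  xm <- rec$tag$XM
  xg <- rec$tag$XG
  if (is.null(xm)) xm <- rep(NA_character_, n)
  if (is.null(xg)) xg <- rep(NA_character_, n)
  primary <- !unmapped & !secondary & !suppl
  no_tag <- primary & !lowq & (is.na(xm) | is.na(xg))
  if (any(no_tag)) {
    warning(sum(no_tag), " mapped primary read(s) lack XM/XG tags; skipped")
  }
  keep <- primary & !lowq & !no_tag

  bad_xg <- keep & !(xg %in% c("CT", "GA"))
  if (any(bad_xg)) {
    stop("unknown conversion strand (XG) '", xg[which(bad_xg)[1L]],
         "' on read ", rec$qname[which(bad_xg)[1L]])
  }

  new_bis_aln(
    qname = rec$qname[keep],
    flag  = flag[keep],
    chrom = as.character(rec$rname[keep]),
    pos   = rec$pos[keep],
    cigar = rec$cigar[keep],
    xm    = xm[keep],
    xg    = xg[keep],
    chrom_levels = levels(rec$rname),
    log = list(records = n, kept = sum(keep), unmapped = sum(unmapped),
               secondary = sum(secondary), supplementary = sum(suppl),
               low_mapq = sum(lowq), missing_tags = sum(no_tag)))
}

#' Construct a `bis_aln` object from parsed fields
#'
#' Low-level constructor used by [read_bismark_alignments()] and by the
#' test suite to build alignment sets without touching the filesystem.
#'
#' @param qname,flag,chrom,pos,cigar,xm,xg Parallel per-read vectors.
#' @param chrom_levels Chromosome names in output order (defaults to order
#'   of first appearance).
#' @param log Optional list of parsing counters.
#' @return A `bis_aln` object.
#' @export
new_bis_aln <- function(qname, flag, chrom, pos, cigar, xm, xg,
                        chrom_levels = unique(chrom), log = list()) {
  n <- length(pos)
  stopifnot(length(qname) == n, length(flag) == n, length(chrom) == n,
            length(cigar) == n, length(xm) == n, length(xg) == n)
  structure(list(qname = as.character(qname), flag = as.integer(flag),
                 chrom = as.character(chrom), pos = as.integer(pos),
                 cigar = as.character(cigar), xm = as.character(xm),
                 xg = as.character(xg),
                 chrom_levels = as.character(chrom_levels), log = log),
            class = "bis_aln")
}

#' @export
print.bis_aln <- function(x, ...) {
  cat("bis_aln:", length(x$pos), "reads on",
      length(x$chrom_levels), "chromosome(s)\n")
  invisible(x)
}

# --- CIGAR arithmetic -------------------------------------------------------

.cigar_split <- function(cigar) {
  len <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1L]])
  op  <- regmatches(cigar, gregexpr("[MIDNSHP=X]", cigar))[[1L]]
  if (length(len) != length(op) || length(op) == 0L)
    stop("malformed CIGAR: ", cigar)
  list(len = len, op = op)
}

.cigar_query_len <- function(cigar) {
  cs <- .cigar_split(cigar)
  sum(cs$len[cs$op %in% c("M", "I", "S", "=", "X")])
}

.cigar_ref_len <- function(cigar) {
  cs <- .cigar_split(cigar)
  sum(cs$len[cs$op %in% c("M", "D", "N", "=", "X")])
}

# Reference coordinate of every query base: M/=/X consume both, I/S consume
# query only (NA reference), D/N consume reference only, H/P consume neither.
.cigar_query_to_ref <- function(cigar, pos) {
  cs <- .cigar_split(cigar)
  out <- integer(0)
  ref <- pos
  for (k in seq_along(cs$op)) {
    l <- cs$len[k]
    switch(cs$op[k],
      M = , `=` = , X = { out <- c(out, ref + seq_len(l) - 1L); ref <- ref + l },
      I = , S = { out <- c(out, rep(NA_integer_, l)) },
      D = , N = { ref <- ref + l },
      H = , P = NULL)
  }
  out
}

#' Map a read's CpG methylation calls to reference coordinates
#'
#' Walks the CIGAR string to assign each CpG-context call (`z`/`Z`) in the
#' methylation-call string a reference coordinate. Calls on inserted or
#' soft-clipped bases have no reference coordinate and are dropped; calls in
#' other contexts (`x/X/h/H/u/U/.`) are ignored. Because coordinates come
#' from the alignment (not from a reference CpG list), CpG sites created by
#' variants or deletions are emitted at their reference positions.
#'
#' @param pos 1-based leftmost reference position of the alignment.
#' @param cigar CIGAR string.
#' @param call_string Per-query-base methylation-call string (Bismark `XM`).
#' @param qname Read name used in error messages.
#' @return A data.frame with columns `refpos` (1-based) and `call`
#'   (`"z"`/`"Z"`); attribute `dropped` counts calls lost to I/S bases.
#' @export
map_calls_to_reference <- function(pos, cigar, call_string, qname = "read") {
  if (nchar(call_string) != .cigar_query_len(cigar)) {
    stop("CIGAR/call-string length mismatch on ", qname,
         " (cigar ", cigar, ", ", nchar(call_string), " calls)")
  }
  m <- gregexpr("[zZ]", call_string)[[1L]]
  if (m[1L] == -1L) {
    out <- data.frame(refpos = integer(0), call = character(0))
    attr(out, "dropped") <- 0L
    return(out)
  }
  qidx <- as.integer(m)
  call <- substring(call_string, qidx, qidx)
  refmap <- if (grepl("^[0-9]+M$", cigar)) pos + seq_len(nchar(call_string)) - 1L
            else .cigar_query_to_ref(cigar, pos)
  refpos <- refmap[qidx]
  drop <- is.na(refpos)
  out <- data.frame(refpos = refpos[!drop], call = call[!drop],
                    stringsAsFactors = FALSE)
  attr(out, "dropped") <- sum(drop)
  out
}

#' Canonicalize a call position to the forward-strand cytosine
#'
#' Both strands of a CpG are merged onto the forward-strand C: calls from
#' CT-conversion reads (cytosine on the forward strand) keep their position,
#' calls from GA-conversion reads sit on the G of the forward-strand CpG and
#' are shifted left by one base.
#'
#' @param pos Reference position(s) of the call.
#' @param conv_strand `"CT"` or `"GA"`, recycled along `pos`.
#' @return Canonical forward-strand C position(s).
#' @export
assign_strand <- function(pos, conv_strand) {
  if (!all(conv_strand %in% c("CT", "GA"))) {
    stop("unknown conversion strand: ",
         paste(unique(setdiff(conv_strand, c("CT", "GA"))), collapse = ", "))
  }
  as.integer(pos) - (conv_strand == "GA")
}

# Per-call table for an alignment set: read index, chrom, canonical CpG
# position, methylated flag. Applies CIGAR mapping, strand merging and
# (optionally) clipping of the second mate's overlap with the first.
.cpg_calls <- function(aln, dedup_overlap = TRUE) {
  n <- length(aln$pos)
  counters <- list(calls_total = 0L, calls_dropped_noref = 0L,
                   calls_dedup_removed = 0L)
  if (n == 0L) {
    return(list(calls = data.table::data.table(
      rid = integer(0), chrom = character(0), pos = integer(0),
      meth = logical(0)), counters = counters))
  }
  simple <- grepl("^[0-9]+M$", aln$cigar)
  if (any(simple)) {
    mlen <- rep(NA_integer_, n)
    mlen[simple] <- as.integer(sub("M$", "", aln$cigar[simple]))
    bad <- simple & mlen != nchar(aln$xm)
    if (any(bad)) {
      stop("CIGAR/call-string length mismatch on ",
           aln$qname[which(bad)[1L]])
    }
  }

  mm <- gregexpr("[zZ]", aln$xm)
  idx <- lapply(mm, function(v) if (v[1L] == -1L) integer(0) else as.integer(v))
  nper <- lengths(idx)
  rid <- rep.int(seq_len(n), nper)
  qidx <- unlist(idx, use.names = FALSE)
  if (length(qidx) == 0L) {
    return(list(calls = data.table::data.table(
      rid = integer(0), chrom = character(0), pos = integer(0),
      meth = logical(0)), counters = counters))
  }
  call <- substring(aln$xm[rid], qidx, qidx)
  counters$calls_total <- length(qidx)

  refpos <- integer(length(qidx))
  is_simple <- simple[rid]
  refpos[is_simple] <- aln$pos[rid[is_simple]] + qidx[is_simple] - 1L
  cx_rows <- which(!is_simple)
  if (length(cx_rows)) {
    for (rows in split(cx_rows, rid[cx_rows])) {
      i <- rid[rows[1L]]
      if (nchar(aln$xm[i]) != .cigar_query_len(aln$cigar[i])) {
        stop("CIGAR/call-string length mismatch on ", aln$qname[i])
      }
      map <- .cigar_query_to_ref(aln$cigar[i], aln$pos[i])
      refpos[rows] <- map[qidx[rows]]
    }
  }

  ok <- !is.na(refpos)
  counters$calls_dropped_noref <- sum(!ok)
  rid <- rid[ok]; refpos <- refpos[ok]; call <- call[ok]

  if (dedup_overlap && length(rid)) {
    flag <- aln$flag
    paired_proper <- bitwAnd(flag, 1L) > 0L & bitwAnd(flag, 2L) > 0L
    first  <- paired_proper & bitwAnd(flag, 64L) > 0L
    second <- paired_proper & bitwAnd(flag, 128L) > 0L
    if (any(second) && any(first)) {
      f_idx <- which(first)
      reflen <- integer(length(f_idx))
      fs <- grepl("^[0-9]+M$", aln$cigar[f_idx])
      reflen[fs] <- as.integer(sub("M$", "", aln$cigar[f_idx][fs]))
      reflen[!fs] <- vapply(aln$cigar[f_idx][!fs], .cigar_ref_len, integer(1))
      m1 <- match(aln$qname[rid], aln$qname[f_idx])
      is2 <- second[rid] & !is.na(m1)
      same_chrom <- is2 & aln$chrom[rid] == aln$chrom[f_idx][m1]
      lo <- aln$pos[f_idx][m1]
      hi <- lo + reflen[m1] - 1L
      clip <- same_chrom & refpos >= lo & refpos <= hi
      clip[is.na(clip)] <- FALSE
      counters$calls_dedup_removed <- sum(clip)
      rid <- rid[!clip]; refpos <- refpos[!clip]; call <- call[!clip]
    }
  }

  pos <- assign_strand(refpos, aln$xg[rid])
  list(calls = data.table::data.table(rid = rid, chrom = aln$chrom[rid],
                                      pos = pos, meth = call == "Z"),
       counters = counters)
}

#' Tabulate per-CpG methylation counts for one sample
#'
#' Sums methylated and unmethylated CpG calls per canonical site (the two
#' strands of each CpG are merged onto the forward-strand C) and returns a
#' table sorted by chromosome (alignment-header order) and 1-based position.
#' When `dedup_overlap` is on, calls from the overlapping portion of the
#' second mate of a properly-paired fragment are discarded so that one
#' fragment never contributes twice at a site.
#'
#' @param aln A `bis_aln` object.
#' @param dedup_overlap Clip the second mate's overlap (default `TRUE`).
#' @return A data.frame with columns `chrom`, `pos`, `meth`, `unmeth`;
#'   attributes `chrom_order` and `log` (call counters).
#' @export
tabulate_counts <- function(aln, dedup_overlap = TRUE) {
  cc <- .cpg_calls(aln, dedup_overlap = dedup_overlap)
  calls <- cc$calls
  if (nrow(calls) == 0L) {
    out <- data.frame(chrom = character(0), pos = integer(0),
                      meth = integer(0), unmeth = integer(0))
    attr(out, "chrom_order") <- aln$chrom_levels
    attr(out, "log") <- cc$counters
    return(out)
  }
  calls[, chromf := factor(chrom, levels = aln$chrom_levels)]
  tab <- calls[, list(meth = sum(meth), unmeth = sum(!meth)),
               keyby = list(chromf, pos)]
  out <- data.frame(chrom = as.character(tab$chromf), pos = tab$pos,
                    meth = as.integer(tab$meth),
                    unmeth = as.integer(tab$unmeth),
                    stringsAsFactors = FALSE)
  attr(out, "chrom_order") <- aln$chrom_levels
  attr(out, "log") <- cc$counters
  out
}

#' Extract per-read joint methylation patterns over intervals
#'
#' For each interval, every read contributing at least one CpG call inside
#' it yields one pattern over the interval's observed CpG positions:
#' `M` methylated, `u` unmethylated, `-` site not covered by the read.
#' Identical patterns are tallied. Spatial linkage of methylation along
#' single molecules is informative about cell-subpopulation structure.
#'
#' @param aln A `bis_aln` object.
#' @param intervals data.frame with columns `chrom`, `start`, `end`
#'   (1-based inclusive), sorted and non-overlapping per chromosome.
#' @param dedup_overlap Clip the second mate's overlap (default `TRUE`).
#' @return data.frame `chrom`, `start`, `end`, `sites` (number of CpG
#'   positions observed in the interval), `pattern`, `count`.
#' @export
extract_linkage_patterns <- function(aln, intervals, dedup_overlap = TRUE) {
  stopifnot(all(c("chrom", "start", "end") %in% names(intervals)))
  if (any(intervals$start > intervals$end)) {
    i <- which(intervals$start > intervals$end)[1L]
    stop("malformed interval: ", intervals$chrom[i], ":",
         intervals$start[i], "-", intervals$end[i])
  }
  calls <- .cpg_calls(aln, dedup_overlap = dedup_overlap)$calls
  res <- vector("list", nrow(intervals))
  for (i in seq_len(nrow(intervals))) {
    sel <- calls[chrom == intervals$chrom[i] &
                 pos >= intervals$start[i] & pos <= intervals$end[i]]
    if (nrow(sel) == 0L) next
    sites <- sort(unique(sel$pos))
    sel[, col := match(pos, sites)]
    pats <- sel[, {
      chars <- rep("-", length(sites))
      chars[col] <- ifelse(meth, "M", "u")
      list(pattern = paste(chars, collapse = ""))
    }, by = rid]
    tal <- pats[, list(count = .N), by = pattern]
    data.table::setorder(tal, -count, pattern)
    res[[i]] <- data.frame(chrom = intervals$chrom[i],
                           start = intervals$start[i],
                           end = intervals$end[i],
                           sites = length(sites),
                           pattern = tal$pattern,
                           count = tal$count, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res[!vapply(res, is.null, logical(1))])
  if (is.null(out)) {
    out <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), sites = integer(0),
                      pattern = character(0), count = integer(0))
  }
  out
}

# --- count-table I/O --------------------------------------------------------

#' Write a per-CpG count table
#'
#' Tab-delimited with header; columns `chrom`, `pos` (1-based), `total`,
#' `meth`, `unmeth`.
#'
#' @param counts Count table from [tabulate_counts()] (sorted).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(counts, path) {
  df <- data.frame(chrom = counts$chrom, pos = counts$pos,
                   total = counts$meth + counts$unmeth,
                   meth = counts$meth, unmeth = counts$unmeth)
  ok <- tryCatch({
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stop("cannot write count table to ", path)
  invisible(path)
}

#' Read a per-CpG count table
#'
#' @param path Path written by [write_count_table()].
#' @return data.frame `chrom`, `pos`, `meth`, `unmeth` with attribute
#'   `chrom_order` (order of first appearance).
#' @export
read_count_table <- function(path) {
  if (!file.exists(path)) stop("count table not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = c(chrom = "character"),
                          stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "total", "meth", "unmeth")
  if (!all(need %in% names(df))) {
    stop("malformed count table ", path, ": expected columns ",
         paste(need, collapse = ", "))
  }
  out <- data.frame(chrom = df$chrom, pos = as.integer(df$pos),
                    meth = as.integer(df$meth),
                    unmeth = as.integer(df$unmeth),
                    stringsAsFactors = FALSE)
  attr(out, "chrom_order") <- unique(out$chrom)
  out
}

#' Write counts in Bismark-coverage style
#'
#' Headerless lines `chrom`, `start`, `end` (both the 1-based C position),
#' methylation percentage, `meth`, `unmeth` — for interoperability with
#' tools expecting Bismark `.cov` files.
#'
#' @param counts Count table from [tabulate_counts()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bismark_coverage <- function(counts, path) {
  total <- counts$meth + counts$unmeth
  df <- data.frame(chrom = counts$chrom, start = counts$pos,
                   end = counts$pos,
                   pct = ifelse(total > 0, 100 * counts$meth / total, 0),
                   meth = counts$meth, unmeth = counts$unmeth)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
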