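# Shared fixture builders: everything is generated in code at test time.

# Minimal single-end alignment set on one chromosome.
aln_fixture <- function(pos, cigar, xm, xg, flag = rep(0L, length(pos)),
                        qname = sprintf("r%d", seq_along(pos)),
                        chrom = rep("chrT", length(pos)),
                        chrom_levels = "chrT") {
  new_bis_aln(qname = qname, flag = flag, chrom = chrom, pos = pos,
              cigar = cigar, xm = xm, xg = xg, chrom_levels = chrom_levels)
}

# Count table from a compact spec matrix: rows (pos, meth, unmeth).
count_fixture <- function(pos, meth, unmeth, chrom = "chrT") {
  if (length(chrom) == 1L) chrom <- rep(chrom, length(pos))
  df <- data.frame(chrom = chrom, pos = as.integer(pos),
                   meth = as.integer(meth), unmeth = as.integer(unmeth),
                   stringsAsFactors = FALSE)
  attr(df, "chrom_order") <- unique(df$chrom)
  df
}

# Independent O(n^2) transitive-closure single-linkage oracle (pairs within
# d are edges; clusters are connected components via igraph).
slc_oracle <- function(pos, d) {
  n <- length(pos)
  if (n == 0L) return(list())
  adj <- abs(outer(pos, pos, "-")) <= d
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           diag = FALSE)
  comp <- igraph::components(g)$membership
  out <- lapply(split(seq_len(n), comp), function(ix) sort(pos[ix]))
  out <- unname(out)
  out[order(sapply(out, function(x) x[1]))]
}

# Independent BH step-up oracle: q_(k) = min_{j>=k} m p_(j) / j, capped at 1.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- rev(cummin(rev(p[o] * m / seq_len(m))))
  pmin(q, 1)[order(o)]
}

# Per-region beta-binomial maximum-likelihood dispersion (oracle for the
# moment estimator), profiling at the pooled mean.
bb_ml_phi <- function(x, n) {
  mu <- sum(x) / sum(n)
  if (mu <= 0 || mu >= 1) return(NA_real_)
  nll <- function(ph) {
    a <- mu * (1 - ph) / ph
    b <- (1 - mu) * (1 - ph) / ph
    -sum(lbeta(x + a, n - x + b) - lbeta(a, b))
  }
  stats::optimize(nll, c(1e-6, 0.9))$minimum
}
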