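#' Differential-test parameters
#'
#' Thresholds applied when flagging a tested region as a DMR: the absolute
#' difference of group methylation fractions must reach `min_diff`, and the
#' Wald p-value and BH q-value must not exceed `max_p` / `max_q`. Defaults
#' follow the pipeline's standard setting (difference at least 10%,
#' p and q at most 0.05).
#'
#' @param min_diff Minimum |difference| of weighted methylation fractions
#'   (default 0.10).
#' @param max_p Maximum Wald p-value (default 0.05).
#' @param max_q Maximum BH q-value (default 0.05; set to 1 to disable).
#' @param phi_floor Smallest dispersion distinguishable from zero on the
#'   log scale (default 1e-4).
#' @return A `test_params` list.
#' @export
test_params <- function(min_diff = 0.10, max_p = 0.05, max_q = 0.05,
                        phi_floor = 1e-4) {
  stopifnot(min_diff >= 0, min_diff <= 1, max_p >= 0, max_p <= 1,
            max_q >= 0, max_q <= 1, phi_floor > 0)
  structure(list(min_diff = min_diff, max_p = max_p, max_q = max_q,
                 phi_floor = phi_floor), class = "test_params")
}

# Vectorized group estimates over regions (rows) x replicates (cols).
# Returns mu (weighted methylation fraction), phi_raw (signed
# method-of-moments dispersion; NA when undefined), df (replicates with
# coverage minus one) and testable flag.
.group_estimates <- function(X, N) {
  X <- as.matrix(X); N <- as.matrix(N)
  X[is.na(X)] <- 0L
  N[is.na(N)] <- 0L
  Ntot <- rowSums(N)
  n_used <- rowSums(N > 0)
  mu <- ifelse(Ntot > 0, rowSums(X) / Ntot, NA_real_)

  W <- N / ifelse(Ntot > 0, Ntot, 1)          # w_i = N_i / sum(N)
  P <- ifelse(N > 0, X / N, NA_real_)
  R2 <- (P - mu)^2
  R2[is.na(R2)] <- 0
  S <- rowSums(W * R2)
  WW <- W - W^2
  Nsafe <- ifelse(N > 0, N, 1)
  A <- rowSums(ifelse(N > 0, WW / Nsafe, 0))
  B <- rowSums(ifelse(N > 0, WW * (N - 1) / Nsafe, 0))
  # the plug-in mu(1-mu) is biased down by Var(mu_hat) = mu(1-mu) (A2+B2 phi)
  A2 <- rowSums(ifelse(N > 0, W^2 / Nsafe, 0))
  B2 <- rowSums(ifelse(N > 0, W^2 * (N - 1) / Nsafe, 0))

  m <- mu * (1 - mu)
  phi <- ifelse(n_used >= 2 & !is.na(mu) & m > 0 & B > 0,
                (S / m - A) / B, NA_real_)
  list(mu = mu, phi_raw = phi, df = pmax(n_used - 1, 0),
       testable = Ntot > 0, A = A, B = B, A2 = A2, B2 = B2)
}

#' Estimate a group's methylation level and raw dispersion for one region
#'
#' The methylation fraction is the coverage-weighted mean
#' `mu = sum(X_i)/sum(N_i)`. The beta-binomial dispersion `phi` (the
#' intra-replicate correlation) is estimated by the method of moments on
#' the coverage-weighted residual variance across replicates, solving
#' `E[sum w_i (p_i - mu)^2] = sum (w_i - w_i^2) mu(1-mu)(1+(N_i-1)phi)/N_i`
#' with `w_i = N_i/sum(N)` (the subtraction of `w_i^2` accounts exactly for
#' `mu` being estimated from the same data). The raw estimate is left
#' signed — sampling noise can push it below zero — and is shrunk before
#' use by [shrink_dispersion()]. With a single replicate, or with `mu` at
#' the boundary, the dispersion is undefined (`NA`) and the region is
#' flagged for full shrinkage to the prior.
#'
#' @param X Methylated counts per replicate.
#' @param N Total counts per replicate.
#' @return A `group_estimate` list: `mu`, `phi_raw`, `phi` (set after
#'   shrinkage; initialized to `phi_raw`), `df`, `N`, `X`, `testable`.
#' @export
estimate_group <- function(X, N) {
  stopifnot(length(X) == length(N), all(X >= 0, na.rm = TRUE),
            all(X <= N, na.rm = TRUE))
  e <- .group_estimates(matrix(X, nrow = 1), matrix(N, nrow = 1))
  structure(list(mu = e$mu, phi_raw = e$phi_raw, phi = e$phi_raw,
                 df = e$df, N = as.numeric(N), X = as.numeric(X),
                 testable = e$testable), class = "group_estimate")
}

#' Shrink per-region dispersions toward an empirical prior
#'
#' Empirical-Bayes shrinkage of log-dispersions across regions, treating the
#' region dispersions of a group as draws from a shared log-normal prior.
#' The prior location is the replication-weighted mean of the signed raw
#' estimates on the natural scale (where the moment estimator is unbiased),
#' floored at `phi_floor`. Each region's log estimate is bias-corrected and
#' Each region's log estimate carries a sampling variance from scaled
#' chi-square theory (`trigamma` at half the residual degrees of freedom,
#' as in moderated-variance analyses), so the precision weight grows with
#' replication; the prior scale is the excess spread of the log estimates
#' over that sampling noise. The shrunken value is the precision-weighted
#' combination of log estimate and prior location; regions with undefined
#' raw estimates receive the prior location. With fewer than two defined
#' estimates a fixed fallback prior (location `log(0.01)`, scale 1) is
#' used.
#'
#' The raw moment estimator divides by the plug-in `mu(1-mu)`, which is
#' biased down by `Var(mu_hat)`; correcting this region by region would be
#' unstable (the correction is nonlinear in a noisy quantity), so when the
#' pooled moment coefficients are supplied via `moment_coef` the correction
#' is applied once to the pooled prior location, where sampling noise is
#' negligible.
#'
#' @param phi_raw Signed raw dispersion estimates (NA = undefined).
#' @param df Residual degrees of freedom per region (replicates with
#'   coverage minus one).
#' @param prior Optional `list(location=, scale=)` overriding the empirical
#'   fit (log scale).
#' @param phi_floor Lower floor for dispersions (default 1e-4).
#' @param moment_coef Optional pooled moment coefficients
#'   `list(A=, B=, A2=, B2=)` (df-weighted means of the per-region values
#'   from the moment fit) enabling the pooled denominator-bias correction
#'   of the prior location.
#' @return Vector of shrunken dispersions; attribute `prior` records the
#'   location and scale used.
#' @export
shrink_dispersion <- function(phi_raw, df = rep(1, length(phi_raw)),
                              prior = NULL, phi_floor = 1e-4,
                              moment_coef = NULL) {
  stopifnot(length(df) == length(phi_raw))
  df <- as.numeric(df)
  defined <- !is.na(phi_raw) & df >= 1
  # non-positive raw estimates are pure sampling noise around small phi:
  # they inform the prior location (natural scale) but carry no usable
  # log-scale observation, so they take the prior location directly
  positive <- defined & !is.na(phi_raw) & phi_raw > phi_floor

  if (is.null(prior)) {
    if (sum(defined) < 2L) {
      prior <- list(location = log(0.01), scale = 1)
    } else {
      m_nat <- stats::weighted.mean(phi_raw[defined], w = df[defined])
      if (!is.null(moment_coef) && moment_coef$B > 0) {
        # invert E[phi_raw] = ((A + B phi)/(1 - A2 - B2 phi) - A)/B at the
        # pooled mean: r = A + B m_nat, phi = (r (1-A2) - A)/(B + r B2)
        r <- moment_coef$A + moment_coef$B * m_nat
        m_nat <- (r * (1 - moment_coef$A2) - moment_coef$A) /
          (moment_coef$B + r * moment_coef$B2)
      }
      location <- log(max(m_nat, phi_floor))
      if (sum(positive) >= 2L) {
        lp <- log(phi_raw[positive])
        s2 <- trigamma(df[positive] / 2)
        v <- stats::weighted.mean(
          (lp - stats::weighted.mean(lp, df[positive]))^2, df[positive])
        tau2 <- max(v - stats::weighted.mean(s2, df[positive]), 0)
      } else {
        tau2 <- 0
      }
      prior <- list(location = location, scale = sqrt(tau2))
    }
  }
  tau2 <- prior$scale^2
  out <- rep(exp(prior$location), length(phi_raw))
  if (any(positive)) {
    lp <- log(phi_raw[positive])
    s2 <- trigamma(df[positive] / 2)
    post <- if (is.infinite(tau2)) lp
            else if (tau2 == 0) rep(prior$location, length(lp))
            else (lp / s2 + prior$location / tau2) / (1 / s2 + 1 / tau2)
    out[positive] <- exp(post)
  }
  out <- pmin(pmax(out, 0), 1 - 1e-6)
  attr(out, "prior") <- prior
  out
}

# Model variance of the weighted group mean:
# var(mu) = mu(1-mu) * sum w_i^2 (1 + (N_i - 1) phi) / N_i ,  w_i = N_i/sum(N)
# mu is clamped to [1/(2 sum N), 1 - 1/(2 sum N)] so boundary estimates keep
# a nonzero variance.
.group_var <- function(mu, phi, N) {
  N <- N[N > 0]
  if (length(N) == 0L || is.na(mu)) return(NA_real_)
  Ntot <- sum(N)
  w <- N / Ntot
  eps <- 1 / (2 * Ntot)
  muc <- min(max(mu, eps), 1 - eps)
  muc * (1 - muc) * sum(w^2 * (1 + (N - 1) * phi) / N)
}

#' Wald test of a methylation difference between two groups
#'
#' The statistic is the difference of the groups' weighted methylation
#' fractions divided by the model standard error,
#' `wald = (mu_A - mu_B) / sqrt(var_A + var_B)`, with each variance given
#' by the beta-binomial form `mu(1-mu) sum w_i^2 (1+(N_i-1) phi)/N_i`; the
#' p-value is two-sided normal. With dispersion zero and single replicates
#' this reduces exactly to the (unpooled) two-proportion z-test. Degenerate
#' comparisons (zero variance after clamping) return `p = 1` with a flag.
#'
#' @param estA,estB `group_estimate` objects (see [estimate_group()]); the
#'   `phi` element (shrunken dispersion) is used.
#' @return List `diff`, `wald`, `p`, `degenerate`.
#' @export
wald_test <- function(estA, estB) {
  if (!isTRUE(estA$testable) || !isTRUE(estB$testable)) {
    return(list(diff = NA_real_, wald = NA_real_, p = NA_real_,
                degenerate = FALSE))
  }
  vA <- .group_var(estA$mu, estA$phi, estA$N)
  vB <- .group_var(estB$mu, estB$phi, estB$N)
  d <- estA$mu - estB$mu
  v <- vA + vB
  if (!is.finite(v) || v <= 0) {
    return(list(diff = d, wald = 0, p = 1, degenerate = TRUE))
  }
  w <- d / sqrt(v)
  list(diff = d, wald = w, p = 2 * stats::pnorm(-abs(w)), degenerate = FALSE)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up adjusted p-values controlling the false discovery rate,
#' computed within each pairwise comparison separately by the caller.
#' `NA` p-values are left `NA` and do not count toward the number of tests.
#'
#' @param pvalues Vector of p-values in `[0, 1]` (NAs allowed).
#' @return Vector of q-values.
#' @export
adjust_fdr <- function(pvalues) {
  ok <- !is.na(pvalues)
  out <- rep(NA_real_, length(pvalues))
  out[ok] <- stats::p.adjust(pvalues[ok], method = "BH")
  out
}

#' Test regions for differential methylation between sample groups
#'
#' For every unordered pair of groups: per-region group estimates
#' ([estimate_group()]), empirical-Bayes dispersion shrinkage across regions
#' ([shrink_dispersion()], per group), Wald tests ([wald_test()]) and BH
#' correction within the comparison ([adjust_fdr()]). A region is flagged a
#' DMR for a comparison when `|diff| >= min_diff`, `p <= max_p` and
#' `q <= max_q`. Regions untestable for a comparison (a group without
#' coverage) carry missing statistics rather than being dropped, so row
#' sets align across comparisons.
#'
#' @param regions Region data.frame ([build_regions()] or
#'   [read_region_table()]).
#' @param groups Named list mapping each group name to its sample names
#'   (each sample in at most one group; at least two groups, each
#'   non-empty).
#' @param params A [test_params()] object.
#' @return data.frame with `chrom`, `start`, `end`, `n_cpg`, one `<g>_mu`
#'   column per group, and per comparison `<A>_vs_<B>_{diff,wald,p,q,dmr}`;
#'   attributes `groups` and `comparisons`.
#' @export
call_dmrs <- function(regions, groups, params = test_params()) {
  if (length(groups) < 2L) stop("need at least two groups")
  if (is.null(names(groups)) || any(names(groups) == "")) {
    stop("groups must be named")
  }
  if (any(lengths(groups) == 0L)) {
    stop("group with zero samples: ",
         paste(names(groups)[lengths(groups) == 0L], collapse = ", "))
  }
  all_s <- unlist(groups)
  if (anyDuplicated(all_s)) {
    stop("sample assigned to more than one group: ",
         paste(unique(all_s[duplicated(all_s)]), collapse = ", "))
  }
  samples <- attr(regions, "samples")
  if (is.null(samples)) samples <- .region_samples(regions)
  missing_s <- setdiff(all_s, samples)
  if (length(missing_s)) {
    stop("sample(s) not in region table: ", paste(missing_s, collapse = ", "))
  }

  nr <- nrow(regions)
  est <- lapply(groups, function(ss) {
    X <- as.matrix(regions[paste0(ss, "_X")])
    N <- as.matrix(regions[paste0(ss, "_N")])
    e <- .group_estimates(X, N)
    def <- !is.na(e$phi_raw) & e$df >= 1
    coef <- if (sum(def) >= 2L) {
      list(A = stats::weighted.mean(e$A[def], e$df[def]),
           B = stats::weighted.mean(e$B[def], e$df[def]),
           A2 = stats::weighted.mean(e$A2[def], e$df[def]),
           B2 = stats::weighted.mean(e$B2[def], e$df[def]))
    } else NULL
    e$phi <- shrink_dispersion(e$phi_raw, e$df, phi_floor = params$phi_floor,
                               moment_coef = coef)
    e$X <- X; e$N <- N
    e
  })

  out <- data.frame(chrom = regions$chrom, start = regions$start,
                    end = regions$end, n_cpg = regions$n_cpg,
                    stringsAsFactors = FALSE)
  for (g in names(groups)) out[[paste0(g, "_mu")]] <- est[[g]]$mu

  pairs <- utils::combn(names(groups), 2, simplify = FALSE)
  for (pr in pairs) {
    a <- est[[pr[1L]]]; b <- est[[pr[2L]]]
    d <- wald <- p <- rep(NA_real_, nr)
    for (i in seq_len(nr)) {
      if (!a$testable[i] || !b$testable[i]) next
      Na <- a$N[i, ]; Nb <- b$N[i, ]
      Na[is.na(Na)] <- 0; Nb[is.na(Nb)] <- 0
      vA <- .group_var(a$mu[i], a$phi[i], Na)
      vB <- .group_var(b$mu[i], b$phi[i], Nb)
      d[i] <- a$mu[i] - b$mu[i]
      v <- vA + vB
      if (!is.finite(v) || v <= 0) {
        wald[i] <- 0; p[i] <- 1
      } else {
        wald[i] <- d[i] / sqrt(v)
        p[i] <- 2 * stats::pnorm(-abs(wald[i]))
      }
    }
    q <- adjust_fdr(p)
    dmr <- !is.na(d) & !is.na(p) & !is.na(q) &
      abs(d) >= params$min_diff & p <= params$max_p & q <= params$max_q
    key <- paste0(pr[1L], "_vs_", pr[2L])
    out[[paste0(key, "_diff")]] <- d
    out[[paste0(key, "_wald")]] <- wald
    out[[paste0(key, "_p")]] <- p
    out[[paste0(key, "_q")]] <- q
    out[[paste0(key, "_dmr")]] <- dmr
  }
  attr(out, "groups") <- groups
  attr(out, "comparisons") <- vapply(pairs, paste, collapse = "_vs_",
                                     character(1))
  out
}

#' Write a DMR table
#'
#' Tab-delimited with header, in the column layout of [call_dmrs()].
#'
#' @param dmr DMR data.frame from [call_dmrs()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dmr_table <- function(dmr, path) {
  ok <- tryCatch({
    utils::write.table(dmr, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stop("cannot write DMR table to ", path)
  invisible(path)
}

#' Export DMR intervals as BED
#'
#' Writes the regions flagged as DMRs for one comparison in BED format
#' (0-based half-open: `start - 1`, `end`), name
#' `<comparison>|diff=<value>`, score `min(1000, -10 log10 p)`.
#'
#' @param dmr DMR data.frame from [call_dmrs()].
#' @param path Output path.
#' @param comparison Comparison key (e.g. `"ctrl_vs_case"`); defaults to
#'   the first one.
#' @return `path`, invisibly.
#' @export
write_dmr_bed <- function(dmr, path, comparison = NULL) {
  comps <- attr(dmr, "comparisons")
  if (is.null(comparison)) comparison <- comps[1L]
  flag <- dmr[[paste0(comparison, "_dmr")]]
  if (is.null(flag)) stop("unknown comparison: ", comparison)
  sel <- which(flag)
  p <- dmr[[paste0(comparison, "_p")]][sel]
  df <- data.frame(chrom = dmr$chrom[sel],
                   start = dmr$start[sel] - 1L,  # BED is 0-based half-open
                   end = dmr$end[sel],
                   name = sprintf("%s|diff=%.4f", comparison,
                                  dmr[[paste0(comparison, "_diff")]][sel]),
                   score = pmin(1000, round(-10 * log10(pmax(p, 1e-100)))))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
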