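#' Estimate the genomic inflation factor
#'
#' `lambda_gc = median(z^2) / qchisq(0.5, 1)`, the ratio of the observed
#' median association chi-square to its null median (0.4549...). Values
#' below 1 are clamped to 1 so that correction never inflates significance.
#'
#' @param z vector of association z-scores (at least 100 finite values).
#' @return scalar `lambda_gc >= 1`.
#' @export
estimate_lambda_gc <- function(z) {
  z <- z[is.finite(z)]
  if (length(z) < 100) stop("need at least 100 finite z-scores for lambda_gc")
  max(1, median(z^2) / .CHISQ1_MEDIAN)
}

#' Apply genomic control to a summary-statistics table
#'
#' Divides z-scores by `sqrt(lambda_gc)` and recomputes two-sided p-values
#' from the corrected z. Idempotent up to numerical tolerance: re-estimating
#' lambda on the corrected table gives 1.
#'
#' @param ss summary-statistics table with a `Z` column.
#' @return list of class `gc_result` with elements `lambda_gc` and `table`
#'   (the corrected table; SNP identity, order, and alleles untouched).
#' @export
apply_genomic_control <- function(ss) {
  lambda <- estimate_lambda_gc(ss$Z)
  out <- copy(ss)
  if (lambda > 1) {
    out[, Z := Z / sqrt(lambda)]
    out[, P := z_to_p(Z)]
  }
  structure(list(lambda_gc = lambda, table = out), class = "gc_result")
}

# correlation of a standard bivariate normal doubly truncated to the box
# |z1| < t, |z2| < t; by symmetry both truncated means are zero, so the
# correlation is E[z1 z2; box] / E[z1^2; box]
.trunc_cor <- function(rho, t) {
  if (rho == 0) return(0)
  s <- sqrt(1 - rho^2)
  m11 <- integrate(function(z) {
    a <- (-t - rho * z) / s; b <- (t - rho * z) / s
    z * dnorm(z) * (rho * z * (pnorm(b) - pnorm(a)) - s * (dnorm(b) - dnorm(a)))
  }, -t, t, rel.tol = 1e-10)$value
  m20 <- integrate(function(z) {
    a <- (-t - rho * z) / s; b <- (t - rho * z) / s
    z^2 * dnorm(z) * (pnorm(b) - pnorm(a))
  }, -t, t, rel.tol = 1e-10)$value
  m11 / m20
}

# invert the truncation attenuation: find rho whose truncated correlation
# matches the observed one
.debias_trunc_cor <- function(r_obs, t) {
  lim <- 1 - 1e-6
  bound <- .trunc_cor(lim, t)
  if (abs(r_obs) >= bound) return(sign(r_obs))
  uniroot(function(rho) .trunc_cor(rho, t) - r_obs,
          lower = -lim, upper = lim, tol = 1e-9)$root
}

#' Estimate the null z-score correlation between two traits
#'
#' Shared control samples induce correlation between the two traits'
#' z-scores even at null SNPs. The raw estimate is the sample correlation of
#' (z1, z2) restricted to SNPs that look null in both traits (|z| below
#' `z_threshold` in each), optionally after one random LD-pruning pass to
#' reduce dependence between neighbouring SNPs. Restricting to the box
#' |z| < t attenuates a bivariate-normal correlation, so the raw value is
#' debiased by inverting the exact truncated-normal correlation curve; the
#' returned `rho` estimates the untruncated null correlation.
#'
#' @param z1,z2 z-score vectors aligned on the same SNPs.
#' @param z_threshold |z| cutoff defining the null set (default 2).
#' @param panel optional [ld_panel()]; when given, one random pruning pass at
#'   `prune_r2` precedes the null restriction.
#' @param prune_r2 r-squared threshold for the pruning pass (default 0.8).
#' @param seed seed for the pruning pass.
#' @return list of class `overlap_model` with `rho`, `n_null`, `z_threshold`.
#'   Errors if fewer than 100 null SNPs remain or the estimate is degenerate
#'   (|rho| indistinguishable from 1).
#' @export
estimate_null_correlation <- function(z1, z2, z_threshold = 2, panel = NULL,
                                      prune_r2 = 0.8, seed = 1L) {
  stopifnot(length(z1) == length(z2))
  keep <- rep(TRUE, length(z1))
  if (!is.null(panel)) keep <- random_prune(panel, prune_r2, seed)
  nul <- keep & abs(z1) < z_threshold & abs(z2) < z_threshold &
    is.finite(z1) & is.finite(z2)
  n_null <- sum(nul)
  if (n_null < 100) stop("fewer than 100 null SNPs for overlap estimation")
  r_raw <- cor(z1[nul], z2[nul])
  if (!is.finite(r_raw)) stop("degenerate null correlation estimate")
  rho <- .debias_trunc_cor(r_raw, z_threshold)
  if (abs(rho) >= 1 - 1e-8)
    stop("degenerate null correlation estimate (|rho| ~ 1)")
  structure(list(rho = rho, rho_raw = r_raw, n_null = n_null,
                 z_threshold = z_threshold),
            class = "overlap_model")
}

#' Decorrelate a z-score pair for sample overlap
#'
#' Applies the symmetric inverse square root of the 2x2 correlation matrix
#' `[[1, rho], [rho, 1]]` to each SNP's (z1, z2) pair. This maps a
#' unit-variance pair with correlation `rho` to an uncorrelated unit-variance
#' pair, and treats the two traits symmetrically (exchangeability is required
#' by the symmetric conjunction statistic downstream).
#'
#' @param z1,z2 aligned z-score vectors.
#' @param model an `overlap_model` from [estimate_null_correlation()], or a
#'   bare correlation value.
#' @return list with decorrelated `z1`, `z2`.
#' @export
decorrelate_overlap <- function(z1, z2, model) {
  rho <- if (inherits(model, "overlap_model")) model$rho else as.numeric(model)
  if (!is.finite(rho) || abs(rho) >= 1) stop("invalid overlap model")
  # C^{-1/2} = [[a, b], [b, a]] via the eigenvalues 1 +/- rho
  a <- (1 / sqrt(1 + rho) + 1 / sqrt(1 - rho)) / 2
  b <- (1 / sqrt(1 + rho) - 1 / sqrt(1 - rho)) / 2
  list(z1 = a * z1 + b * z2, z2 = b * z1 + a * z2)
}
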