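#' Strata definition for conditional Q-Q enrichment
#'
#' Nested strata of the conditioning trait, defined by descending p-value
#' cutoffs; the first cutoff must be 1 (the all-SNPs stratum). The
#' truncation bounds curve emission at the genome-wide-significance tail.
#'
#' @param thresholds strictly decreasing p cutoffs, first equal to 1
#'   (default `c(1, 0.1, 0.01, 0.001)`).
#' @param truncation maximum -log10 p of the primary trait emitted in
#'   curves (default 7.3, i.e. p = 5e-8).
#' @return list of class `qq_strata`.
#' @export
qq_strata <- function(thresholds = c(1, 0.1, 0.01, 0.001), truncation = 7.3) {
  stopifnot(thresholds[1] == 1, all(diff(thresholds) < 0), truncation > 0)
  structure(list(thresholds = thresholds, truncation = truncation),
            class = "qq_strata")
}

#' Stratified Q-Q enrichment curves
#'
#' For each pruning mask and each conditioning stratum `{p2 < t}` (the
#' `t = 1` stratum keeps all SNPs), computes the empirical quantile curve of
#' observed -log10 p1 among kept stratum members against -log10 of the
#' uniform plotting positions `(i - 0.5) / n`, interpolates each mask's
#' curve onto a common theoretical grid, and averages across masks. Points
#' with observed -log10 p1 at or beyond the truncation are dropped from the
#' emitted curves (display only; FDR estimation is unaffected). Increasing
#' leftward deflection across strata indicates shared polygenic
#' architecture.
#'
#' @param p1 primary-trait p-values.
#' @param p2 conditioning-trait p-values, aligned.
#' @param strata a [qq_strata()].
#' @param ensemble a `prune_ensemble` aligned with the SNPs, or `NULL` for a
#'   single all-SNPs pass.
#' @param grid_size number of theoretical grid points (default 200).
#' @return `data.table` of class `qq_curves` with columns `THRESHOLD`,
#'   `EXPECTED`, `OBSERVED`, `N_MEAN` (mean kept stratum size across masks)
#'   and `UNSTABLE` (stratum smaller than 50 SNPs in some mask).
#' @export
stratified_qq <- function(p1, p2, strata = qq_strata(), ensemble = NULL,
                          grid_size = 200L) {
  stopifnot(length(p1) == length(p2))
  masks <- if (is.null(ensemble)) matrix(TRUE, length(p1), 1) else
    ensemble$masks
  x1 <- -log10(pmax(p1, .P_FLOOR))
  tmax <- -log10(0.5 / length(p1))
  tg <- seq(0, tmax, length.out = grid_size)
  out <- list()
  for (t in strata$thresholds) {
    in_stratum <- if (t >= 1) rep(TRUE, length(p2)) else p2 < t
    obs_acc <- numeric(grid_size)
    n_acc <- 0
    k_used <- 0L
    n_min <- Inf
    unstable <- FALSE
    for (k in seq_len(ncol(masks))) {
      sel <- in_stratum & masks[, k]
      n_s <- sum(sel)
      if (n_s < 50) unstable <- TRUE
      if (n_s < 2) next
      o <- sort(x1[sel])                       # ascending observed quantiles
      e <- -log10((n_s:1 - 0.5) / n_s)         # matching ascending expected
      obs_acc <- obs_acc + approx(e, o, xout = tg, rule = 2)$y
      n_acc <- n_acc + n_s
      n_min <- min(n_min, n_s)
      k_used <- k_used + 1L
    }
    if (k_used == 0L) next
    # curves end at the sparsest mask's extreme plotting position; beyond it
    # the empirical quantile function has no support
    support <- tg <= -log10(0.5 / n_min) + 1e-9
    if (unstable)
      message(sprintf("stratified_qq: stratum p < %g below 50 SNPs; curve unstable", t))
    out[[length(out) + 1L]] <- data.table(
      THRESHOLD = t, EXPECTED = tg[support],
      OBSERVED = (obs_acc / k_used)[support],
      N_MEAN = n_acc / k_used, UNSTABLE = unstable)
  }
  curves <- rbindlist(out)
  curves <- curves[OBSERVED < strata$truncation]
  setattr(curves, "class", c("qq_curves", class(curves)))
  curves[]
}

#' Base-graphics stratified Q-Q plot
#'
#' @param curves a `qq_curves` table from [stratified_qq()].
#' @param main plot title.
#' @export
plot_qq <- function(curves, main = "Stratified Q-Q") {
  ths <- sort(unique(curves$THRESHOLD), decreasing = TRUE)
  cols <- grDevices::hcl.colors(length(ths), "Dark 2")
  lim <- c(0, max(curves$OBSERVED, curves$EXPECTED))
  graphics::plot(NA, xlim = lim, ylim = lim, xlab = "expected -log10 p",
                 ylab = "observed -log10 p", main = main)
  graphics::abline(0, 1, lty = 3)
  for (i in seq_along(ths)) {
    cc <- curves[curves$THRESHOLD == ths[i], ]
    graphics::lines(cc$EXPECTED, cc$OBSERVED, col = cols[i], lwd = 2)
  }
  graphics::legend("topleft", legend = sprintf("p2 < %g", ths),
                   col = cols, lwd = 2, bty = "n")
  invisible(curves)
}

#' LD-score-based fold-enrichment test of a SNP stratum
#'
#' Weighted least-squares regression of chi-square statistics (`z^2`) on an
#' intercept, the total LD score, and the stratum-restricted LD score
#' (per-SNP sum of r-squared to stratum members). The fitted per-SNP
#' heritability contribution is `tau_total + tau_stratum` inside the stratum
#' and `tau_total` outside; fold enrichment is the stratum's share of
#' heritability divided by its share of SNPs,
#' `E = M (b_t + b_s) / (M b_t + m_s b_s)` with `M` panel SNPs and `m_s`
#' stratum SNPs. Standard errors come from a delete-block jackknife over
#' contiguous SNP blocks; the p-value is one-sided for enrichment (`E > 1`).
#'
#' When the overall polygenic signal is absent (non-positive fitted LD-score
#' slope) the ratio is undefined and the result is flagged non-informative
#' (`informative = FALSE`, `estimate = NA`) instead of returning a spurious
#' fold change.
#'
#' @param z z-score vector aligned with the panel SNPs.
#' @param panel an [ld_panel()] (provides pairwise r-squared for the
#'   stratum-restricted LD score).
#' @param stratum_mask logical vector marking stratum members; must be a
#'   nonempty strict subset.
#' @param n_blocks jackknife block count (default 200).
#' @param ld_sc total LD scores (default: taken from the panel).
#' @return list of class `enrichment_result`: `estimate`, `se`, `p`,
#'   `n_stratum`, `informative`.
#' @export
fold_enrichment_ldsc <- function(z, panel, stratum_mask, n_blocks = 200L,
                                 ld_sc = ld_scores(panel)) {
  M <- length(z)
  stopifnot(M == length(stratum_mask), M == length(ld_sc))
  m_s <- sum(stratum_mask)
  if (m_s == 0 || m_s == M) stop("stratum must be a nonempty strict subset")
  ell_s <- as.numeric(panel$r2 %*% as.numeric(stratum_mask))
  X <- cbind(1, ld_sc, ell_s)
  y <- z^2
  w <- 1 / pmax(ld_sc, 1)
  coefs <- function(xtx, xty)
    tryCatch(as.numeric(solve(xtx, xty)),
             error = function(e) rep(NA_real_, 3))
  E_of <- function(b) {
    denom <- M * b[2] + m_s * b[3]
    if (!all(is.finite(b)) || b[2] <= 0 || denom <= 0) return(NA_real_)
    M * (b[2] + b[3]) / denom
  }
  Xw <- X * w
  xtx <- crossprod(Xw, X); xty <- crossprod(Xw, y)
  b_full <- coefs(xtx, xty)
  E <- E_of(b_full)
  # delete-block jackknife over contiguous blocks in panel order
  n_blocks <- min(n_blocks, M)
  blk <- ceiling(seq_len(M) / (M / n_blocks))
  Eb <- numeric(n_blocks); slope_b <- numeric(n_blocks)
  for (b in seq_len(n_blocks)) {
    sel <- blk == b
    xtx_b <- xtx - crossprod(Xw[sel, , drop = FALSE], X[sel, , drop = FALSE])
    xty_b <- xty - crossprod(Xw[sel, , drop = FALSE], y[sel])
    cb <- coefs(xtx_b, xty_b)
    slope_b[b] <- cb[2]
    Eb[b] <- E_of(cb)
  }
  jack_se <- function(v) {
    v <- v[is.finite(v)]
    if (length(v) < 2) return(NA_real_)
    sqrt((length(v) - 1) / length(v) * sum((v - mean(v))^2))
  }
  # the overall polygenic slope must be positive and distinguishable from
  # zero, otherwise the heritability-share ratio is undefined-stable
  slope_se <- jack_se(slope_b)
  informative <- is.finite(E) && is.finite(b_full[2]) && b_full[2] > 0 &&
    is.finite(slope_se) && b_full[2] > 2 * slope_se
  if (!informative)
    return(structure(list(estimate = NA_real_, se = NA_real_, p = NA_real_,
                          n_stratum = m_s, informative = FALSE),
                     class = "enrichment_result"))
  se <- jack_se(Eb)
  p <- if (is.finite(se) && se > 0) pnorm((E - 1) / se, lower.tail = FALSE)
  else NA_real_
  structure(list(estimate = E, se = se, p = p, n_stratum = m_s,
                 informative = TRUE),
            class = "enrichment_result")
}

#' Bonferroni adjustment
#'
#' `min(1, p * n_tests)` elementwise. The conventional correction for the
#' stratified enrichment tests is `n_tests = 12` (four secondary traits
#' times three strata).
#'
#' @param p p-value vector.
#' @param n_tests number of tests (`>= 1`).
#' @return adjusted p-values capped at 1.
#' @export
bonferroni_adjust <- function(p, n_tests) {
  stopifnot(n_tests >= 1)
  pmin(1, p * n_tests)
}

#' Fold-enrichment table over conditioning strata
#'
#' Runs [fold_enrichment_ldsc()] for each proper stratum (`p2 < t`, skipping
#' the all-SNPs cutoff `t = 1`) and Bonferroni-adjusts the p-values.
#'
#' @param z1 primary-trait z-scores aligned with the panel.
#' @param p2 conditioning-trait p-values, aligned.
#' @param panel an [ld_panel()].
#' @param strata a [qq_strata()].
#' @param n_tests Bonferroni factor (default 12: four secondary traits times
#'   three strata).
#' @param n_blocks jackknife block count.
#' @return `data.table` with one row per stratum: `THRESHOLD`, `N_STRATUM`,
#'   `FOLD_ENRICHMENT`, `SE`, `P`, `P_ADJ`, `INFORMATIVE`.
#' @export
stratum_enrichment <- function(z1, p2, panel, strata = qq_strata(),
                               n_tests = 12L, n_blocks = 200L) {
  ths <- strata$thresholds[strata$thresholds < 1]
  rows <- lapply(ths, function(t) {
    mask <- p2 < t
    if (sum(mask) == 0 || sum(mask) == length(mask))
      return(data.table(THRESHOLD = t, N_STRATUM = sum(mask),
                        FOLD_ENRICHMENT = NA_real_, SE = NA_real_,
                        P = NA_real_, P_ADJ = NA_real_, INFORMATIVE = FALSE))
    e <- fold_enrichment_ldsc(z1, panel, mask, n_blocks = n_blocks)
    data.table(THRESHOLD = t, N_STRATUM = e$n_stratum,
               FOLD_ENRICHMENT = e$estimate, SE = e$se, P = e$p,
               P_ADJ = if (is.na(e$p)) NA_real_ else
                 bonferroni_adjust(e$p, n_tests),
               INFORMATIVE = e$informative)
  })
  rbindlist(rows)
}
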