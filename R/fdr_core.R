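#' Configuration for conditional/conjunction FDR estimation
#'
#' @param fdr_level discovery threshold on the conjunction FDR (default 0.01,
#'   one expected false positive per 100 reported findings).
#' @param grid ascending -log10 p breakpoints used for surface nodes on both
#'   axes (default 201 equally spaced points over 0-20, resolving
#'   genome-wide-significant tails at 0.1 spacing).
#' @param pi0 assumed null proportion; fixed at 1 by default (conservative
#'   upper bound on the FDR).
#' @return list of class `fdr_config`.
#' @export
fdr_config <- function(fdr_level = 0.01, grid = seq(0, 20, length.out = 201),
                       pi0 = 1) {
  stopifnot(fdr_level > 0, fdr_level < 1, all(diff(grid) > 0),
            pi0 > 0, pi0 <= 1)
  structure(list(fdr_level = fdr_level, grid = grid, pi0 = pi0),
            class = "fdr_config")
}

#' Empirical tail-area FDR
#'
#' `FDR(p_i) = pi0 * p_i / Fhat(p_i)` where `Fhat` is the empirical cdf with
#' inclusive ties (the count of `p <= p_i` over N); the estimated probability
#' that a SNP is null given its p-value is at most the observed one. Results
#' are clamped to (0, 1].
#'
#' @param p p-value vector, values in (0, 1].
#' @param pi0 null proportion (default 1).
#' @return FDR vector, same length and order as `p`.
#' @export
marginal_fdr <- function(p, pi0 = 1) {
  if (length(p) == 0) stop("empty p-value vector")
  stopifnot(all(p > 0), all(p <= 1))
  pmin(1, pi0 * p * length(p) / frankv(p, ties.method = "max"))
}

#' Empirical conditional FDR
#'
#' The tail-area FDR of trait 1 evaluated within the stratum of SNPs whose
#' trait-2 p-value is at most the SNP's own:
#' `condFDR_i = pi0 * p1_i / Fhat(p1_i | p2 <= p2_i)` with
#' `Fhat = #{p1_j <= p1_i & p2_j <= p2_i} / #{p2_j <= p2_i}`. All
#' comparisons are inclusive, so the conditioning stratum always contains the
#' SNP itself and the estimator is well defined at duplicated p-values.
#'
#' @param p1 primary-trait p-values (the trait whose FDR is estimated).
#' @param p2 conditioning-trait p-values, aligned with `p1`.
#' @param pi0 null proportion (default 1).
#' @return conditional FDR vector clamped to (0, 1].
#' @export
cond_fdr <- function(p1, p2, pi0 = 1) {
  stopifnot(length(p1) == length(p2), length(p1) > 0,
            all(p1 > 0), all(p1 <= 1), all(p2 > 0), all(p2 <= 1))
  n12 <- count_joint_leq(p1, p2)
  n2 <- frankv(p2, ties.method = "max")
  pmin(1, pi0 * p1 * n2 / n12)
}

# Node-level condFDR values for one pruning mask, on the -log10 grid.
# ix, iy: findInterval of the -log10 p values against the grid (0..G).
# Returns G x G matrix; nodes with an empty joint count are NA.
.surface_node_values <- function(ix, iy, grid, pi0) {
  G <- length(grid)
  tab <- matrix(tabulate(ix + 1L + (G + 1L) * iy, nbins = (G + 1L)^2),
                G + 1L, G + 1L)
  # suffix sums: S[u, v] = #{ix >= u - 1, iy >= v - 1}
  rcs <- function(m) apply(m, 2, function(col) rev(cumsum(rev(col))))
  S <- t(rcs(t(rcs(tab))))
  n12 <- S[-1, -1, drop = FALSE]              # joint counts at nodes (a, b)
  n2 <- S[1, -1]                              # stratum sizes at y nodes
  v <- pi0 * 10^(-grid) * sweep(1 / n12, 2, n2, `*`)
  v[!is.finite(v)] <- NA_real_                # empty stratum or joint count
  pmin(v, 1)
}

# last-observation-carried-forward down a matrix's rows (flat extension
# along the primary axis), then across columns for fully-empty strata
.fill_flat <- function(v) {
  v <- apply(v, 2, function(col) {
    if (all(is.na(col))) return(col)
    i <- cumsum(!is.na(col)); i[i == 0] <- NA
    col[which(!is.na(col))[i]]
  })
  for (b in seq_len(ncol(v))[-1])
    if (all(is.na(v[, b]))) v[, b] <- v[, b - 1]
  v
}

#' Build an ensemble-averaged conditional FDR surface
#'
#' Evaluates the conditional FDR estimator of `p1` given `p2` at every node
#' of a 2-D -log10 p grid, separately for each random pruning mask (only
#' kept SNPs enter the empirical counts), averages node values across masks,
#' and enforces monotone nonincrease along the primary axis by cumulative
#' minimum. Nodes beyond the data support take the nearest supported value
#' (flat extension). Off-node lookups use bilinear interpolation in -log10 p
#' space via [lookup_surface()].
#'
#' @param p1,p2 aligned p-value vectors (primary, conditioning).
#' @param config an [fdr_config()].
#' @param ensemble a [build_prune_ensemble()] result aligned with the SNP
#'   order, or `NULL` for a single all-SNPs evaluation.
#' @param orientation label recording which trait is conditioned.
#' @return list of class `fdr_surface` with `grid_x`, `grid_y`, `values`
#'   (primary-axis nodes in rows) and `orientation`.
#' @export
build_fdr_surface <- function(p1, p2, config = fdr_config(), ensemble = NULL,
                              orientation = "p1|p2") {
  stopifnot(length(p1) == length(p2))
  grid <- config$grid
  x <- -log10(pmax(p1, .P_FLOOR))
  y <- -log10(pmax(p2, .P_FLOOR))
  ix <- findInterval(x, grid)
  iy <- findInterval(y, grid)
  masks <- if (is.null(ensemble)) {
    matrix(TRUE, length(p1), 1)
  } else {
    stopifnot(nrow(ensemble$masks) == length(p1))
    ensemble$masks
  }
  acc <- matrix(0, length(grid), length(grid))
  for (k in seq_len(ncol(masks))) {
    m <- masks[, k]
    v <- .fill_flat(.surface_node_values(ix[m], iy[m], grid, config$pi0))
    acc <- acc + v
  }
  v <- acc / ncol(masks)
  v <- apply(v, 2, cummin)                    # monotone along primary axis
  structure(list(grid_x = grid, grid_y = grid, values = v,
                 orientation = orientation),
            class = "fdr_surface")
}

#' Look up conditional FDR values on a fitted surface
#'
#' Bilinear interpolation in -log10 p space; coordinates outside the grid
#' are clamped to its boundary (flat extension).
#'
#' @param surface an `fdr_surface`.
#' @param p1,p2 p-values on the surface's primary and conditioning axes.
#' @return interpolated condFDR values in (0, 1].
#' @export
lookup_surface <- function(surface, p1, p2) {
  gx <- surface$grid_x; gy <- surface$grid_y
  x <- pmin(pmax(-log10(pmax(p1, .P_FLOOR)), gx[1]), gx[length(gx)])
  y <- pmin(pmax(-log10(pmax(p2, .P_FLOOR)), gy[1]), gy[length(gy)])
  ia <- pmin(pmax(findInterval(x, gx), 1L), length(gx) - 1L)
  ib <- pmin(pmax(findInterval(y, gy), 1L), length(gy) - 1L)
  tx <- (x - gx[ia]) / (gx[ia + 1L] - gx[ia])
  ty <- (y - gy[ib]) / (gy[ib + 1L] - gy[ib])
  v <- surface$values
  G <- nrow(v)
  at <- function(a, b) v[cbind(a, b)]
  out <- (1 - tx) * (1 - ty) * at(ia, ib) + tx * (1 - ty) * at(ia + 1L, ib) +
    (1 - tx) * ty * at(ia, ib + 1L) + tx * ty * at(ia + 1L, ib + 1L)
  pmin(pmax(out, .P_FLOOR), 1)
}

#' Conjunction FDR of a trait pair
#'
#' `conjFDR_i = max(condFDR(p1|p2)_i, condFDR(p2|p1)_i)`: the estimated
#' probability of being null for either trait or both, given that both
#' p-values are at most the observed ones. The maximum makes the statistic
#' symmetric in the two traits, so low values require joint association.
#'
#' With an ensemble, each conditional component comes from its own
#' monotonized, ensemble-averaged surface (node evaluation on pruned SNPs,
#' then interpolation assigns values to all SNPs including pruned ones).
#' Without an ensemble (`ensemble = NULL`, the exact mode), the per-SNP
#' empirical estimator [cond_fdr()] is evaluated directly in both
#' orientations.
#'
#' @param p1,p2 aligned p-value vectors.
#' @param config an [fdr_config()].
#' @param ensemble a `prune_ensemble` aligned with the SNPs, or `NULL`.
#' @return `data.table` of class `conj_result` with columns `CONDFDR1`
#'   (trait 1 given trait 2), `CONDFDR2`, `CONJFDR`, `DISCOVERY`
#'   (`CONJFDR < fdr_level`).
#' @export
conj_fdr <- function(p1, p2, config = fdr_config(), ensemble = NULL) {
  stopifnot(length(p1) == length(p2))
  if (is.null(ensemble)) {
    c12 <- cond_fdr(p1, p2, config$pi0)
    c21 <- cond_fdr(p2, p1, config$pi0)
  } else {
    s12 <- build_fdr_surface(p1, p2, config, ensemble, "p1|p2")
    s21 <- build_fdr_surface(p2, p1, config, ensemble, "p2|p1")
    c12 <- lookup_surface(s12, p1, p2)
    c21 <- lookup_surface(s21, p2, p1)
  }
  conj <- pmax(c12, c21)
  out <- data.table(CONDFDR1 = c12, CONDFDR2 = c21, CONJFDR = conj,
                    DISCOVERY = conj < config$fdr_level)
  setattr(out, "class", c("conj_result", class(out)))
  setattr(out, "fdr_level", config$fdr_level)
  out[]
}

#' Tabulate conjunction FDR discoveries
#'
#' @param conj a `conj_result` aligned with the tables.
#' @param ss1,ss2 the two traits' aligned summary-statistics tables.
#' @param fdr_level discovery threshold (default: the level stored on
#'   `conj`).
#' @return `data.table` with columns `SNP`, `CHR`, `BP`, `A1`, `A2`,
#'   `P_TRAIT1`, `P_TRAIT2`, `Z_TRAIT1`, `Z_TRAIT2`, `CONJFDR`, sorted by
#'   ascending `CONJFDR`; empty when nothing passes.
#' @export
call_discoveries <- function(conj, ss1, ss2,
                             fdr_level = attr(conj, "fdr_level")) {
  stopifnot(nrow(conj) == nrow(ss1), nrow(ss1) == nrow(ss2),
            identical(ss1$SNP, ss2$SNP))
  out <- data.table(SNP = ss1$SNP, CHR = ss1$CHR, BP = ss1$BP,
                    A1 = ss1$A1, A2 = ss1$A2,
                    P_TRAIT1 = ss1$P, P_TRAIT2 = ss2$P,
                    Z_TRAIT1 = ss1$Z, Z_TRAIT2 = ss2$Z,
                    CONJFDR = conj$CONJFDR)
  out <- out[CONJFDR < fdr_level]
  setorder(out, CONJFDR, P_TRAIT1, SNP)
  out[]
}
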