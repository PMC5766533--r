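#' Simulation studies of pipeline operating characteristics
#'
#' These functions run the package's standard calibration and recovery
#' experiments on synthetic data and return summary statistics. They define
#' the study conditions once so that tests, scripts, and documentation all
#' exercise identical settings.
#'
#' * `study_null_calibration()`: fully null, independent trait pairs
#'   (default 20,000 SNPs in 25-SNP LD blocks). Reports the mean false
#'   discovery proportion among conjunction-FDR calls at the 0.01 level
#'   (every call is false under the null).
#' * `study_recovery()`: sparse pleiotropic architecture — 10,000 SNPs in
#'   5-SNP blocks, 0.3% shared causal variants, 0.1% private causal variants
#'   per trait, shared effect-size correlation 0.95, per-trait heritability
#'   0.0096 at n = 50,000 (per-causal noncentrality about 12, below
#'   single-trait discovery power). Discoveries are clumped into loci; a
#'   locus is true when one of its members lies in an LD block containing a
#'   shared causal variant. Reports locus-level FDP and the distinct shared
#'   blocks recovered by conjunction calling versus marginal tail-FDR
#'   calling on each single trait at the same nominal level.
#' * `study_qq_ordering()`: dense shared architecture; reports stratum
#'   deflection ordering violations beyond the theoretical quantile 2 and
#'   the between-strata gap under independence at two problem sizes.
#' * `study_enrichment_recovery()`: single-trait LD-score regression with a
#'   planted 2x per-SNP-heritability stratum and a random stratum of equal
#'   size (50,000 SNPs); reports pooled estimates and standard errors.
#'
#' @param n_reps number of simulation replicates.
#' @param seed base seed; replicate seeds are derived from it.
#' @param n_iter pruning iterations used for ensemble-based estimation.
#' @return a list of summary statistics; see each function's details.
#' @name studies
NULL

#' @rdname studies
#' @export
study_null_calibration <- function(n_reps = 100L, seed = 1L, n_iter = 100L) {
  fdp <- numeric(n_reps)
  n_disc <- integer(n_reps)
  for (r in seq_len(n_reps)) {
    ps <- sim_params(m_blocks = 800L, block_size = 25L,
                     seed = seed * 1000L + r)
    sim <- simulate_panel(ps)
    pair <- simulate_gwas_pair(sim, ps)
    ens <- build_prune_ensemble(sim$panel, n_iter, 0.8,
                                base_seed = seed * 2000L + r)
    cj <- conj_fdr(pair$ss1$P, pair$ss2$P, fdr_config(), ens)
    n_disc[r] <- sum(cj$DISCOVERY)
    fdp[r] <- n_disc[r] / max(sum(cj$DISCOVERY), 1)  # all-null: V = R
  }
  list(mean_fdp = mean(fdp), n_discoveries = n_disc,
       n_snps = 800L * 25L, n_reps = n_reps)
}

# study conditions for the shared-architecture recovery experiment
.recovery_params <- function(seed)
  sim_params(m_blocks = 2000L, block_size = 5L, h2_1 = 0.0096, h2_2 = 0.0096,
             pi_shared = 0.003, pi_1 = 0.001, pi_2 = 0.001,
             effect_corr = 0.95, seed = seed)

# distinct shared blocks covered by clumped loci called from `score < level`
.locus_yield <- function(score, level, ss1, truth, panel, shared_blocks,
                         clump_r2 = 0.2) {
  hit <- which(score < level)
  if (!length(hit))
    return(list(true = 0L, n_loci_true = 0L, n_loci_false = 0L))
  hits <- data.table(SNP = ss1$SNP[hit], CONJFDR = score[hit],
                     P_TRAIT1 = ss1$P[hit])
  loci <- clump_loci(hits, panel, clump_r2)
  blk <- truth$BLOCK[match(ss1$SNP, truth$SNP)]
  member_blocks <- lapply(strsplit(loci$MEMBERS, ","), function(ids)
    unique(blk[match(ids, ss1$SNP)]))
  is_true <- vapply(member_blocks, function(b) any(b %in% shared_blocks),
                    logical(1))
  covered <- unique(unlist(member_blocks[is_true]))
  list(true = sum(covered %in% shared_blocks),
       n_loci_true = sum(is_true), n_loci_false = sum(!is_true))
}

#' @rdname studies
#' @export
study_recovery <- function(n_reps = 20L, seed = 1L, n_iter = 100L) {
  level <- 0.01
  out <- matrix(0, n_reps, 5,
                dimnames = list(NULL, c("conj_true", "conj_false_loci",
                                        "conj_true_loci", "m1_true",
                                        "m2_true")))
  for (r in seq_len(n_reps)) {
    ps <- .recovery_params(seed * 1000L + r)
    sim <- simulate_panel(ps)
    pair <- simulate_gwas_pair(sim, ps)
    ens <- build_prune_ensemble(sim$panel, n_iter, 0.8,
                                base_seed = seed * 3000L + r)
    cj <- conj_fdr(pair$ss1$P, pair$ss2$P, fdr_config(fdr_level = level), ens)
    truth <- pair$truth
    shared_blocks <- unique(truth$BLOCK[truth$SHARED])
    yc <- .locus_yield(cj$CONJFDR, level, pair$ss1, truth, sim$panel,
                       shared_blocks)
    y1 <- .locus_yield(marginal_fdr(pair$ss1$P), level, pair$ss1, truth,
                       sim$panel, shared_blocks)
    y2 <- .locus_yield(marginal_fdr(pair$ss2$P), level, pair$ss1, truth,
                       sim$panel, shared_blocks)
    out[r, ] <- c(yc$true, yc$n_loci_false, yc$n_loci_true, y1$true, y2$true)
  }
  fdp <- out[, "conj_false_loci"] /
    pmax(out[, "conj_false_loci"] + out[, "conj_true_loci"], 1)
  list(locus_fdp = mean(fdp),
       conj_yield = mean(out[, "conj_true"]),
       marginal_yield_trait1 = mean(out[, "m1_true"]),
       marginal_yield_trait2 = mean(out[, "m2_true"]),
       per_rep = out, n_reps = n_reps)
}

#' @rdname studies
#' @export
study_qq_ordering <- function(seed = 1L, n_iter = 100L) {
  # dense shared architecture: ordered deflections across strata
  ps <- sim_params(m_blocks = 800L, block_size = 25L, h2_1 = 0.1, h2_2 = 0.1,
                   pi_shared = 0.05, pi_1 = 0.01, pi_2 = 0.01,
                   effect_corr = 0.9, seed = seed)
  sim <- simulate_panel(ps)
  pair <- simulate_gwas_pair(sim, ps)
  ens <- build_prune_ensemble(sim$panel, n_iter, 0.8, base_seed = seed + 1L)
  qq <- stratified_qq(pair$ss1$P, pair$ss2$P,
                      qq_strata(truncation = Inf), ens)
  w <- data.table::dcast(qq[qq$EXPECTED > 2], EXPECTED ~ THRESHOLD,
                         value.var = "OBSERVED")
  w <- w[stats::complete.cases(w)]
  viol <- c(sum(w[["0.1"]] < w[["1"]]),
            sum(w[["0.01"]] < w[["0.1"]]),
            sum(w[["0.001"]] < w[["0.01"]] - 0.1))  # slack: sparsest stratum
  # independence: maximum between-strata gap over the quantile range both
  # problem sizes populate well (extreme order statistics have scale-free
  # noise in -log10 units, so the comparison is made on a fixed range)
  gap <- function(m_blocks, s) {
    p0 <- sim_params(m_blocks = m_blocks, block_size = 10L, seed = s)
    s0 <- simulate_panel(p0)
    pr <- simulate_gwas_pair(s0, p0)
    q0 <- stratified_qq(pr$ss1$P, pr$ss2$P, qq_strata(c(1, 0.1)), NULL)
    v <- data.table::dcast(q0[q0$EXPECTED <= 2], EXPECTED ~ THRESHOLD,
                           value.var = "OBSERVED")
    v <- v[stats::complete.cases(v)]
    max(abs(v[["0.1"]] - v[["1"]]))
  }
  list(n_points = nrow(w), ordering_violations = sum(viol),
       gap_small = gap(500L, seed + 2L), gap_large = gap(5000L, seed + 2L))
}

#' @rdname studies
#' @export
study_enrichment_recovery <- function(n_reps = 20L, seed = 1L) {
  ps <- sim_params(m_blocks = 2000L, block_size = 25L, seed = seed)
  sim <- simulate_panel(ps)
  m <- 2000L * 25L
  res <- matrix(0, n_reps, 4,
                dimnames = list(NULL, c("E2", "SE2", "E1", "SE1")))
  for (r in seq_len(n_reps)) {
    strat <- with_seed(seed * 100L + r,
                       sample(c(TRUE, FALSE), m, TRUE, prob = c(0.05, 0.95)))
    z2 <- simulate_trait_z(sim, ps, n = 50000, h2 = 0.3,
                           var_weights = 1 + strat, seed = seed * 200L + r)
    zr <- simulate_trait_z(sim, ps, n = 50000, h2 = 0.3, var_weights = 1,
                           seed = seed * 300L + r)
    e2 <- fold_enrichment_ldsc(z2, sim$panel, strat)
    e1 <- fold_enrichment_ldsc(zr, sim$panel, strat)
    res[r, ] <- c(e2$estimate, e2$se, e1$estimate, e1$se)
  }
  list(planted_mean = mean(res[, "E2"]), planted_mean_se = mean(res[, "SE2"]),
       random_mean = mean(res[, "E1"]), random_mean_se = mean(res[, "SE1"]),
       per_rep = res, n_reps = n_reps)
}
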