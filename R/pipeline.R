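#' Configuration of a full conjunction-FDR run
#'
#' @param sumstats1,sumstats2 paths to the two traits' summary-statistics
#'   files, or in-memory tables (canonical columns). Ignored when
#'   `simulate` is given.
#' @param ld path to a PLINK-style `.ld` file (ignored when `simulate` or
#'   `panel` is given).
#' @param ref reference SNP set table or path; ignored when `simulate` is
#'   given.
#' @param panel optional pre-built [ld_panel()].
#' @param simulate optional [sim_params()]; when given, the input pair and
#'   panel are generated by [simulate_panel()] / [simulate_gwas_pair()].
#' @param exclude list of regions to exclude before FDR fitting; defaults to
#'   the MHC. Use `list()` to disable.
#' @param strata a [qq_strata()].
#' @param prune_r2 pruning threshold (default 0.8).
#' @param prune_iter pruning iterations (default 100).
#' @param clump_r2 clumping threshold for independent loci (default 0.2).
#' @param fdr_level conjunction FDR discovery threshold (default 0.01).
#' @param overlap_adjust decorrelate the z pair for sample overlap
#'   (default TRUE).
#' @param min_coverage minimum reference-coverage fraction per trait
#'   (default 0.2); lower coverage aborts the run.
#' @param seed integer seed driving every stochastic stage.
#' @param out_dir output directory, or `NULL` to skip writing files.
#' @return list of class `run_config`.
#' @export
run_config <- function(sumstats1 = NULL, sumstats2 = NULL, ld = NULL,
                       ref = NULL, panel = NULL, simulate = NULL,
                       exclude = list(region_mhc()), strata = qq_strata(),
                       prune_r2 = 0.8, prune_iter = 100L, clump_r2 = 0.2,
                       fdr_level = 0.01, overlap_adjust = TRUE,
                       min_coverage = 0.2, seed = 1L, out_dir = NULL) {
  stopifnot(prune_r2 > 0, prune_r2 <= 1, clump_r2 > 0, clump_r2 <= 1,
            fdr_level > 0, fdr_level < 1, prune_iter >= 1)
  structure(list(sumstats1 = sumstats1, sumstats2 = sumstats2, ld = ld,
                 ref = ref, panel = panel, simulate = simulate,
                 exclude = exclude, strata = strata, prune_r2 = prune_r2,
                 prune_iter = as.integer(prune_iter), clump_r2 = clump_r2,
                 fdr_level = fdr_level, overlap_adjust = overlap_adjust,
                 min_coverage = min_coverage, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "run_config")
}

.stage_error <- function(stage, msg)
  stop(sprintf("[%s] %s (code: E_%s)", stage, msg, toupper(stage)),
       call. = FALSE)

#' Check summary-statistics coverage of the reference panel
#'
#' Mirrors the exclusion of low-coverage studies: a study whose aligned
#' table covers less than `min_fraction` of the reference SNPs is unfit for
#' enrichment/FDR analysis.
#'
#' @param ss aligned summary-statistics table.
#' @param ref reference SNP set.
#' @param min_fraction minimum coverage fraction (default 0.2; 0 disables).
#' @return list with `pass`, `fraction`, `n_overlap`, `n_ref`.
#' @export
coverage_check <- function(ss, ref, min_fraction = 0.2) {
  n_overlap <- sum(ss$SNP %chin% ref$SNP)
  fraction <- n_overlap / nrow(ref)
  list(pass = fraction >= min_fraction, fraction = fraction,
       n_overlap = n_overlap, n_ref = nrow(ref))
}

#' Run the full conjunction-FDR workflow
#'
#' Stages, in order: input (read or simulate), harmonization to the
#' reference, coverage check, genomic control per trait, sample-overlap
#' decorrelation, region exclusion (MHC by default; the FDR model is fitted
#' only after exclusion), random-pruning ensemble, stratified Q-Q curves and
#' fold-enrichment tests, conjunction FDR via ensemble-averaged surfaces,
#' discovery calling, and clumping into independent loci. All stochastic
#' stages derive their seeds from `config$seed`, so a run is a pure function
#' of (inputs, config, seed) and repeated runs write byte-identical tables.
#'
#' When `config$out_dir` is set, writes `qq_curves.tsv`, `enrichment.tsv`,
#' `conjfdr.tsv`, `loci.tsv`, and `provenance.json` (every constant, seed,
#' estimate and post-filter SNP count used in the run).
#'
#' @param config a [run_config()].
#' @return (invisibly) list with `ss1`, `ss2`, `qq`, `enrichment`, `conj`,
#'   `discoveries`, `loci`, `provenance`, and `truth` for simulated runs.
#' @export
run_conjunction_analysis <- function(config) {
  stopifnot(inherits(config, "run_config"))
  prov <- list(seed = config$seed,
               prune_r2 = config$prune_r2, prune_iter = config$prune_iter,
               clump_r2 = config$clump_r2, fdr_level = config$fdr_level,
               strata = config$strata$thresholds,
               truncation = config$strata$truncation)

  # --- input ---------------------------------------------------------------
  truth <- NULL
  if (!is.null(config$simulate)) {
    sim <- simulate_panel(config$simulate)
    pair <- simulate_gwas_pair(sim, config$simulate)
    ss1 <- pair$ss1; ss2 <- pair$ss2; truth <- pair$truth
    ref <- sim$ref; panel <- sim$panel
  } else {
    if (is.null(config$sumstats1) || is.null(config$sumstats2))
      .stage_error("input", "two summary-statistics inputs are required")
    get_ss <- function(x) if (is.character(x)) read_sumstats(x) else
      as.data.table(x)
    ss1 <- get_ss(config$sumstats1)
    ss2 <- get_ss(config$sumstats2)
    ref <- if (is.character(config$ref)) {
      r <- fread(config$ref)
      reference_snps(r$SNP, r$CHR, r$BP, r$A1, r$A2)
    } else if (!is.null(config$ref)) as.data.table(config$ref)
    else .stage_error("input", "a reference SNP set is required")
    panel <- if (!is.null(config$panel)) config$panel
    else if (!is.null(config$ld)) load_ld(config$ld, ref)
    else .stage_error("input", "an LD panel or .ld file is required")
  }
  prov$n_ref <- nrow(ref)

  # --- harmonize -----------------------------------------------------------
  cov1 <- coverage_check(ss1, ref, config$min_coverage)
  cov2 <- coverage_check(ss2, ref, config$min_coverage)
  if (!cov1$pass || !cov2$pass)
    .stage_error("harmonize", sprintf(
      "reference coverage below %.2f (trait1 %.3f, trait2 %.3f)",
      config$min_coverage, cov1$fraction, cov2$fraction))
  ss1 <- align_to_reference(ss1, ref)
  ss2 <- align_to_reference(ss2, ref)
  common <- intersect(ss1$SNP, ss2$SNP)
  if (length(common) == 0) .stage_error("harmonize", "no common SNPs")
  ss1 <- ss1[SNP %chin% common]
  ss2 <- ss2[SNP %chin% common]
  stopifnot(identical(ss1$SNP, ss2$SNP))
  panel <- subset_panel(panel, ss1$SNP)
  prov$coverage_trait1 <- cov1$fraction
  prov$coverage_trait2 <- cov2$fraction
  prov$n_harmonized <- nrow(ss1)

  # --- genomic control -----------------------------------------------------
  gc_try <- function(ss) tryCatch(apply_genomic_control(ss),
                                  error = function(e)
                                    .stage_error("gc", conditionMessage(e)))
  gc1 <- gc_try(ss1)
  gc2 <- gc_try(ss2)
  ss1 <- gc1$table; ss2 <- gc2$table
  prov$lambda_gc_trait1 <- gc1$lambda_gc
  prov$lambda_gc_trait2 <- gc2$lambda_gc

  # --- sample-overlap decorrelation ---------------------------------------
  if (isTRUE(config$overlap_adjust)) {
    om <- tryCatch(
      estimate_null_correlation(ss1$Z, ss2$Z, panel = panel,
                                prune_r2 = config$prune_r2,
                                seed = config$seed + 101L),
      error = function(e) .stage_error("overlap", conditionMessage(e)))
    dz <- decorrelate_overlap(ss1$Z, ss2$Z, om)
    ss1[, Z := dz$z1][, P := z_to_p(Z)]
    ss2[, Z := dz$z2][, P := z_to_p(Z)]
    prov$overlap_rho <- om$rho
    prov$overlap_n_null <- om$n_null
  } else prov$overlap_rho <- NA_real_

  # --- region exclusion (refit everything downstream on the remainder) ----
  if (length(config$exclude)) {
    ss1 <- exclude_region(ss1, config$exclude)
    ss2 <- exclude_region(ss2, config$exclude)
    panel <- subset_panel(panel, ss1$SNP)
  }
  prov$n_after_exclusion <- nrow(ss1)

  # --- pruning ensemble ----------------------------------------------------
  ensemble <- build_prune_ensemble(panel, config$prune_iter, config$prune_r2,
                                   base_seed = config$seed + 211L)
  prov$prune_mean_kept <- mean(colSums(ensemble$masks))

  # --- stratified Q-Q + enrichment ----------------------------------------
  qq <- stratified_qq(ss1$P, ss2$P, config$strata, ensemble)
  enr <- stratum_enrichment(ss1$Z, ss2$P, panel, config$strata)

  # --- conjunction FDR, discoveries, loci ---------------------------------
  fcfg <- fdr_config(fdr_level = config$fdr_level)
  conj <- conj_fdr(ss1$P, ss2$P, fcfg, ensemble)
  disc <- call_discoveries(conj, ss1, ss2, config$fdr_level)
  loci <- if (nrow(disc)) clump_loci(disc, panel, config$clump_r2) else
    cbind(copy(disc), data.table(N_SNPS = integer(), MEMBERS = character()))
  prov$n_discovery_snps <- nrow(disc)
  prov$n_loci <- nrow(loci)

  # --- outputs -------------------------------------------------------------
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    wt <- function(x, f) fwrite(x, file.path(config$out_dir, f), sep = "\t",
                                quote = FALSE, na = "NA")
    wt(qq, "qq_curves.tsv")
    wt(enr, "enrichment.tsv")
    per_snp <- data.table(SNP = ss1$SNP, CHR = ss1$CHR, BP = ss1$BP,
                          P_TRAIT1 = ss1$P, P_TRAIT2 = ss2$P,
                          CONDFDR1 = conj$CONDFDR1, CONDFDR2 = conj$CONDFDR2,
                          CONJFDR = conj$CONJFDR)
    wt(per_snp, "conjfdr.tsv")
    wt(loci, "loci.tsv")
    jsonlite::write_json(prov, file.path(config$out_dir, "provenance.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(list(ss1 = ss1, ss2 = ss2, qq = qq, enrichment = enr,
                 conj = conj, discoveries = disc, loci = loci,
                 provenance = prov, truth = truth))
}
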