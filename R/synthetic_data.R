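#' Parameters for the paired-GWAS simulator
#'
#' Defines a block-structured LD panel and a four-component causal mixture
#' (shared / trait-1-only / trait-2-only / null) for a pair of traits, with
#' optional genomic inflation and correlated null noise from overlapping
#' control samples.
#'
#' @param m_blocks number of LD blocks.
#' @param block_size SNPs per block.
#' @param rho_ld within-block correlation decay: the signed allelic
#'   correlation between SNPs at distance k within a block is `rho_ld^k`,
#'   so r-squared decays as `rho_ld^(2k)`.
#' @param n1,n2 per-trait GWAS sample sizes.
#' @param h2_1,h2_2 per-trait heritabilities in `[0, 1)`.
#' @param pi_shared,pi_1,pi_2 fractions of SNPs causal for both traits /
#'   trait 1 only / trait 2 only (must sum to at most 1).
#' @param effect_corr correlation of shared causal effect sizes in
#'   `[-1, 1]`; values below 1 mix concordant and discordant effect
#'   directions across the two traits.
#' @param rho_overlap cross-trait correlation of the null noise component
#'   (shared controls).
#' @param lambda_inflation multiplicative inflation of z-squared (genomic
#'   inflation; z is scaled by its square root).
#' @param seed integer seed; all outputs are deterministic given the seed.
#' @return list of class `sim_params`.
#' @export
sim_params <- function(m_blocks = 200L, block_size = 25L, rho_ld = 0.9,
                       n1 = 50000, n2 = 50000, h2_1 = 0, h2_2 = 0,
                       pi_shared = 0, pi_1 = 0, pi_2 = 0, effect_corr = 0.5,
                       rho_overlap = 0, lambda_inflation = 1, seed = 1L) {
  p <- list(m_blocks = as.integer(m_blocks), block_size = as.integer(block_size),
            rho_ld = rho_ld, n1 = n1, n2 = n2, h2_1 = h2_1, h2_2 = h2_2,
            pi_shared = pi_shared, pi_1 = pi_1, pi_2 = pi_2,
            effect_corr = effect_corr, rho_overlap = rho_overlap,
            lambda_inflation = lambda_inflation, seed = as.integer(seed))
  stopifnot(p$m_blocks >= 1, p$block_size >= 1,
            p$rho_ld >= 0, p$rho_ld < 1,
            p$h2_1 >= 0, p$h2_1 < 1, p$h2_2 >= 0, p$h2_2 < 1,
            p$pi_shared >= 0, p$pi_1 >= 0, p$pi_2 >= 0,
            p$pi_shared + p$pi_1 + p$pi_2 <= 1,
            abs(p$effect_corr) <= 1, abs(p$rho_overlap) < 1,
            p$lambda_inflation > 0)
  n_snp <- p$m_blocks * p$block_size
  for (tr in 1:2) {
    h2 <- if (tr == 1) p$h2_1 else p$h2_2
    m_c <- n_snp * (p$pi_shared + if (tr == 1) p$pi_1 else p$pi_2)
    # expected per-causal effect variance h2 / m_c must stay below 1
    if (h2 > 0 && (m_c == 0 || h2 / m_c > 1))
      stop("per-causal-variance exceeds 1; reduce h2 or increase polygenicity")
  }
  structure(p, class = "sim_params")
}

# signed within-block correlation template and its Cholesky factor
.block_template <- function(block_size, rho_ld) {
  k <- abs(outer(seq_len(block_size), seq_len(block_size), `-`))
  R <- rho_ld^k
  list(R = R, L = t(chol(R)))
}

#' Simulate a block-LD reference panel
#'
#' Lays `m_blocks` blocks of `block_size` SNPs across synthetic chromosomes
#' 1-22 (blocks 2 Mb apart starting at 20 Mb, SNPs 5 kb apart within a
#' block). Within a block the r-squared between SNPs at distance k is
#' `rho_ld^(2k)`; blocks are mutually independent. Allele pairs are drawn
#' deterministically from the non-strand-ambiguous pairs.
#'
#' @param params a [sim_params()].
#' @return list with `ref` (a [reference_snps()] table) and `panel`
#'   (an [ld_panel()]), plus the `block` assignment vector.
#' @export
simulate_panel <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  B <- params$m_blocks; s <- params$block_size
  n <- B * s
  block <- rep(seq_len(B), each = s)
  per_chrom <- ceiling(B / 22)
  chr_of_block <- ((seq_len(B) - 1L) %/% per_chrom) + 1L
  pos_in_chrom <- ((seq_len(B) - 1L) %% per_chrom)
  bp <- 20e6 + pos_in_chrom[block] * 2e6 + (seq_len(n) - (block - 1L) * s - 1L) * 5000
  snp <- sprintf("snp%06d", seq_len(n))
  pairs <- matrix(c("A", "G", "A", "C", "T", "G", "T", "C"), ncol = 2,
                  byrow = TRUE)
  pick <- with_seed(params$seed, sample.int(4, n, replace = TRUE))
  ref <- reference_snps(snp, chr_of_block[block], bp,
                        pairs[pick, 1], pairs[pick, 2])
  # ref is sorted by (CHR, BP) which preserves block-contiguous order
  ord <- match(ref$SNP, snp)
  block <- block[ord]
  if (params$rho_ld == 0 || s == 1) {
    panel <- ld_panel(ref$SNP)
  } else {
    tmpl <- .block_template(s, params$rho_ld)
    iu <- which(upper.tri(tmpl$R), arr.ind = TRUE)
    r2u <- tmpl$R[iu]^2
    # replicate template pairs across blocks (positions are block-contiguous)
    offs <- rep((seq_len(B) - 1L) * s, each = nrow(iu))
    ii <- rep(iu[, 1], B) + offs
    jj <- rep(iu[, 2], B) + offs
    panel <- ld_panel(ref$SNP, ii, jj, rep(r2u, B))
  }
  list(ref = ref, panel = panel, block = block)
}

# z = sqrt(n) * R %*% beta + noise, computed blockwise with the shared
# template; noise optionally correlated across a trait pair.
.block_mult <- function(M, v, B, s) {
  if (s == 1) return(as.numeric(M) * v)
  as.numeric(M %*% matrix(v, nrow = s, ncol = B))
}

#' Simulate a single trait's z-scores on a panel
#'
#' Infinitesimal architecture: every SNP carries a causal effect
#' `beta_j ~ N(0, sigma2_j)` with `sigma2_j` proportional to `var_weights`
#' and normalized so the total equals `h2`; marginal z-scores are
#' `sqrt(n) R beta + eps`, `eps ~ N(0, R)` blockwise. Used for
#' enrichment-calibration studies where a stratum's per-SNP heritability is
#' multiplied by a known factor.
#'
#' @param sim a [simulate_panel()] result.
#' @param params the [sim_params()] used to build the panel.
#' @param n GWAS sample size.
#' @param h2 trait heritability.
#' @param var_weights per-SNP effect-variance weights (recycled; default 1).
#' @param seed integer seed.
#' @return numeric z-score vector aligned with `sim$ref`.
#' @export
simulate_trait_z <- function(sim, params, n, h2, var_weights = 1, seed = 1L) {
  s <- params$block_size; B <- params$m_blocks
  m <- B * s
  w <- rep_len(var_weights, m)
  sigma2 <- if (h2 > 0) h2 * w / sum(w) else numeric(m) * 0
  tmpl <- .block_template(s, params$rho_ld)
  with_seed(seed, {
    beta <- rnorm(m, 0, sqrt(sigma2))
    eps <- .block_mult(tmpl$L, rnorm(m), B, s)
    sqrt(n) * .block_mult(tmpl$R, beta, B, s) + eps
  })
}

#' Simulate a GWAS summary-statistics pair with ground truth
#'
#' Causal SNPs are drawn from the four-component mixture
#' (`pi_shared`, `pi_1`, `pi_2`, null). Shared causal effects are bivariate
#' normal with correlation `effect_corr` (allowing concordant and discordant
#' directions); per-trait effect variances are set so the expected total
#' equals the trait heritability. Marginal z-scores follow the standard
#' infinitesimal mapping `E[z] = sqrt(n) R beta` with blockwise LD-correlated
#' noise, cross-trait noise correlation `rho_overlap` (shared controls), and
#' a final `sqrt(lambda_inflation)` scaling (genomic inflation). P-values
#' are two-sided normal tails.
#'
#' @param sim a [simulate_panel()] result.
#' @param params a [sim_params()].
#' @return list with `ss1`, `ss2` (summary-statistics tables aligned to the
#'   panel), and `truth` (`data.table`: per-SNP causal indicators, shared
#'   indicator, true effects, block assignment).
#' @export
simulate_gwas_pair <- function(sim, params) {
  stopifnot(inherits(params, "sim_params"))
  ref <- sim$ref
  s <- params$block_size; B <- params$m_blocks
  m <- B * s
  tmpl <- .block_template(s, params$rho_ld)
  res <- with_seed(params$seed + 1L, {
    u <- runif(m)
    shared <- u < params$pi_shared
    only1 <- !shared & u < params$pi_shared + params$pi_1
    only2 <- !shared & !only1 & u < params$pi_shared + params$pi_1 + params$pi_2
    causal1 <- shared | only1
    causal2 <- shared | only2
    beta1 <- numeric(m); beta2 <- numeric(m)
    m1 <- sum(causal1); m2 <- sum(causal2)
    sd1 <- if (m1 > 0 && params$h2_1 > 0) sqrt(params$h2_1 / m1) else 0
    sd2 <- if (m2 > 0 && params$h2_2 > 0) sqrt(params$h2_2 / m2) else 0
    ec <- params$effect_corr
    xs <- rnorm(sum(shared)); ys <- rnorm(sum(shared))
    beta1[shared] <- sd1 * xs
    beta2[shared] <- sd2 * (ec * xs + sqrt(1 - ec^2) * ys)
    beta1[only1] <- sd1 * rnorm(sum(only1))
    beta2[only2] <- sd2 * rnorm(sum(only2))
    rho <- params$rho_overlap
    u1 <- rnorm(m); u2 <- rnorm(m)
    eps1 <- .block_mult(tmpl$L, u1, B, s)
    eps2 <- .block_mult(tmpl$L, rho * u1 + sqrt(1 - rho^2) * u2, B, s)
    z1 <- sqrt(params$n1) * .block_mult(tmpl$R, beta1, B, s) + eps1
    z2 <- sqrt(params$n2) * .block_mult(tmpl$R, beta2, B, s) + eps2
    list(z1 = z1 * sqrt(params$lambda_inflation),
         z2 = z2 * sqrt(params$lambda_inflation),
         causal1 = causal1, causal2 = causal2, shared = shared,
         beta1 = beta1, beta2 = beta2)
  })
  mk <- function(z, n) data.table(SNP = ref$SNP, CHR = ref$CHR, BP = ref$BP,
                                  A1 = ref$A1, A2 = ref$A2, Z = z,
                                  P = z_to_p(z), N = n)
  truth <- data.table(SNP = ref$SNP, BLOCK = sim$block,
                      CAUSAL1 = res$causal1, CAUSAL2 = res$causal2,
                      SHARED = res$shared, BETA1 = res$beta1,
                      BETA2 = res$beta2)
  list(ss1 = mk(res$z1, params$n1), ss2 = mk(res$z2, params$n2),
       truth = truth)
}
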