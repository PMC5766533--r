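test_that("marginal FDR matches direct counting on the worked table", {
  ex <- example5()
  # smallest p = 0.01 has empirical cdf 1/5, so FDR = 0.05
  expect_equal(marginal_fdr(ex$p1)[1], 0.05)
  expect_equal(marginal_fdr(ex$p1), oracle_marginal_fdr(ex$p1))
  # degenerate ties: all p equal gives FDR = p
  expect_equal(marginal_fdr(rep(0.2, 10)), rep(0.2, 10))
  expect_error(marginal_fdr(numeric(0)), "empty")
})

test_that("conditional FDR matches the worked example and reduces to marginal", {
  ex <- example5()
  # SNP 1: stratum {p2 <= 0.04} has 3 SNPs, one of which has p1 <= 0.01
  expect_equal(cond_fdr(ex$p1, ex$p2)[1], 0.03)
  # conditioning on a constant stratum of 1 recovers the marginal FDR
  expect_equal(cond_fdr(ex$p1, rep(1, 5)), marginal_fdr(ex$p1))
})

test_that("fast conditional FDR equals the brute-force oracle exactly", {
  set.seed(101)
  for (r in 1:30) {
    n <- sample(20:400, 1)
    # duplicated values exercise the inclusive-tie handling
    p1 <- sample(pmin(1, round(runif(n), 3) + 1e-4), n, replace = TRUE)
    p2 <- sample(pmin(1, round(runif(n), 3) + 1e-4), n, replace = TRUE)
    expect_identical(cond_fdr(p1, p2), oracle_cond_fdr(p1, p2))
    expect_identical(marginal_fdr(p1), oracle_marginal_fdr(p1))
  }
})

test_that("uniform null p-values give mean FDR near one", {
  set.seed(7)
  p <- runif(100000)
  expect_equal(mean(marginal_fdr(p)), 1, tolerance = 0.02)
})

test_that("independent conditioning leaves the conditional FDR marginal", {
  set.seed(8)
  n <- 50000
  p1 <- runif(n); p2 <- runif(n)
  expect_lt(mean(abs(cond_fdr(p1, p2) - marginal_fdr(p1))), 0.02)
})

test_that("surface lookups reproduce the direct estimator at its own nodes", {
  ex <- example5()
  grid <- sort(unique(c(0, -log10(ex$p1), -log10(ex$p2), 2)))
  cfg <- fdr_config(grid = grid)
  s <- build_fdr_surface(ex$p1, ex$p2, cfg, ensemble = NULL)
  # monotonization cannot raise values, and at these data the direct
  # estimator is already monotone along the grid
  expect_equal(lookup_surface(s, ex$p1, ex$p2), cond_fdr(ex$p1, ex$p2),
               tolerance = 1e-12)
})

test_that("averaging identical masks equals the single-mask surface", {
  set.seed(9)
  p1 <- runif(500); p2 <- runif(500)
  cfg <- fdr_config(grid = seq(0, 6, length.out = 61))
  mask <- rep(TRUE, 500)
  e1 <- structure(list(masks = matrix(mask, ncol = 1)), class = "prune_ensemble")
  e2 <- structure(list(masks = matrix(rep(mask, 2), ncol = 2)),
                  class = "prune_ensemble")
  s1 <- build_fdr_surface(p1, p2, cfg, e1)
  s2 <- build_fdr_surface(p1, p2, cfg, e2)
  expect_equal(s1$values, s2$values)
})

test_that("built surfaces are monotone nonincreasing along the primary axis", {
  ps <- sim_params(m_blocks = 200, block_size = 25, h2_1 = 0.05, h2_2 = 0.05,
                   pi_shared = 0.02, seed = 33)
  sim <- simulate_panel(ps)
  pair <- simulate_gwas_pair(sim, ps)
  ens <- build_prune_ensemble(sim$panel, 10, 0.8, base_seed = 3)
  s <- build_fdr_surface(pair$ss1$P, pair$ss2$P, fdr_config(), ens)
  expect_true(all(apply(s$values, 2, function(col) all(diff(col) <= 1e-12))))
  expect_true(all(s$values > 0 & s$values <= 1))
})

test_that("conjunction FDR is symmetric and bounded by its components", {
  ex <- example5()
  cj <- conj_fdr(ex$p1, ex$p2)
  # worked example: components 0.03 and 0.04, conjunction 0.04
  expect_equal(cj$CONDFDR1[1], 0.03)
  expect_equal(cj$CONDFDR2[1], 0.04)
  expect_equal(cj$CONJFDR[1], 0.04)
  expect_equal(cj$CONJFDR, oracle_conj_fdr(ex$p1, ex$p2))
  # swapping traits leaves the conjunction unchanged
  swapped <- conj_fdr(ex$p2, ex$p1)
  expect_equal(swapped$CONJFDR, cj$CONJFDR)
  # identical traits collapse the two components
  same <- conj_fdr(ex$p1, ex$p1)
  expect_equal(same$CONDFDR1, same$CONDFDR2)
  expect_equal(same$CONJFDR, same$CONDFDR1)
  # conjunction dominates each component
  set.seed(10)
  q1 <- runif(300); q2 <- runif(300)
  cj2 <- conj_fdr(q1, q2)
  expect_true(all(cj2$CONJFDR >= cj2$CONDFDR1 - 1e-15))
  expect_true(all(cj2$CONJFDR >= cj2$CONDFDR2 - 1e-15))
})

test_that("surface-based conjunction is symmetric under trait swap", {
  ps <- sim_params(m_blocks = 100, block_size = 10, h2_1 = 0.02, h2_2 = 0.02,
                   pi_shared = 0.01, seed = 44)
  sim <- simulate_panel(ps)
  pair <- simulate_gwas_pair(sim, ps)
  ens <- build_prune_ensemble(sim$panel, 5, 0.8, base_seed = 4)
  a <- conj_fdr(pair$ss1$P, pair$ss2$P, fdr_config(), ens)
  b <- conj_fdr(pair$ss2$P, pair$ss1$P, fdr_config(), ens)
  expect_equal(a$CONJFDR, b$CONJFDR, tolerance = 1e-12)
})

test_that("discovery tables are sorted, complete, and possibly empty", {
  ex <- example5()
  mk <- function(p) data.table::data.table(
    SNP = sprintf("s%d", seq_along(p)), CHR = 1L, BP = seq_along(p) * 100L,
    A1 = "A", A2 = "G", Z = -qnorm(p / 2), P = p)
  ss1 <- mk(ex$p1); ss2 <- mk(ex$p2)
  cj <- conj_fdr(ex$p1, ex$p2, fdr_config(fdr_level = 0.05))
  disc <- call_discoveries(cj, ss1, ss2)
  expect_equal(disc$SNP, "s1")
  expect_named(disc, c("SNP", "CHR", "BP", "A1", "A2", "P_TRAIT1", "P_TRAIT2",
                       "Z_TRAIT1", "Z_TRAIT2", "CONJFDR"))
  none <- call_discoveries(cj, ss1, ss2, fdr_level = 1e-6)
  expect_equal(nrow(none), 0)
})
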