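test_that("LD loading builds symmetric structure with implied self-r2", {
  snps <- c("s1", "s2", "s3")
  f <- tempfile(fileext = ".ld")
  writeLines(c("SNP_A\tSNP_B\tR2", "s1\ts2\t0.9"), f)
  panel <- load_ld(f, snps)
  expect_equal(as.numeric(panel$r2[1, 2]), 0.9)
  expect_equal(as.numeric(panel$r2[2, 1]), 0.9)
  expect_equal(unname(ld_scores(panel)), c(1.9, 1.9, 1.0))
  # empty pair file: full independence
  f0 <- tempfile(fileext = ".ld")
  writeLines("SNP_A\tSNP_B\tR2", f0)
  expect_equal(unname(ld_scores(load_ld(f0, snps))), c(1, 1, 1))
  # unknown ids skipped with a message
  f1 <- tempfile(fileext = ".ld")
  writeLines(c("SNP_A\tSNP_B\tR2", "s1\tzz\t0.5", "s1\ts3\t0.4"), f1)
  expect_message(p1 <- load_ld(f1, snps), "unknown")
  expect_equal(as.numeric(p1$r2[1, 3]), 0.4)
  # conflicting duplicates name the pair; r2 out of range errors
  f2 <- tempfile(fileext = ".ld")
  writeLines(c("SNP_A\tSNP_B\tR2", "s1\ts2\t0.5", "s2\ts1\t0.6"), f2)
  expect_error(load_ld(f2, snps), "s1|s2")
  f3 <- tempfile(fileext = ".ld")
  writeLines(c("SNP_A\tSNP_B\tR2", "s1\ts2\t1.5"), f3)
  expect_error(load_ld(f3, snps), "outside")
})

test_that("pruning keeps everything under independence and one per clique", {
  free <- tiny_panel(sprintf("s%d", 1:40))
  expect_true(all(random_prune(free, 0.8, seed = 7)))
  # 5-SNP clique at r2 = 1: exactly one kept, uniformly over seeds
  cl <- expand.grid(a = 1:5, b = 1:5)
  cl <- cl[cl$a < cl$b, ]
  clique <- tiny_panel(sprintf("s%d", 1:5),
                       list(a = sprintf("s%d", cl$a),
                            b = sprintf("s%d", cl$b), r2 = rep(1, nrow(cl))))
  picks <- vapply(1:2000, function(s) which(random_prune(clique, 0.8, s)),
                  integer(1))
  expect_true(all(tabulate(picks, 5) > 0))
  gof <- chisq.test(tabulate(picks, 5), p = rep(0.2, 5))
  expect_gt(gof$p.value, 0.01)
})

test_that("chain pruning yields exactly the two order-dependent solutions", {
  chain <- tiny_panel(c("s1", "s2", "s3"),
                      list(a = c("s1", "s2", "s1"), b = c("s2", "s3", "s3"),
                           r2 = c(0.9, 0.9, 0.1)))
  sols <- unique(vapply(1:60, function(s)
    paste(which(random_prune(chain, 0.8, s)), collapse = ","), character(1)))
  expect_setequal(sols, c("2", "1,3"))
})

test_that("pruning masks satisfy no-kept-pair and maximality invariants", {
  set.seed(30)
  for (rep in 1:25) {
    n <- sample(20:60, 1)
    npair <- sample(10:80, 1)
    a <- sample(n, npair, TRUE); b <- sample(n, npair, TRUE)
    ok <- a != b
    pr <- data.frame(a = pmin(a, b)[ok], b = pmax(a, b)[ok],
                     r2 = runif(sum(ok)))
    pr <- pr[!duplicated(pr[c("a", "b")]), ]
    snps <- sprintf("s%d", 1:n)
    panel <- tiny_panel(snps, list(a = snps[pr$a], b = snps[pr$b], r2 = pr$r2))
    thr <- runif(1, 0.2, 0.9)
    keep <- random_prune(panel, thr, seed = rep)
    R <- as.matrix(panel$r2)
    kept <- which(keep)
    off <- R[kept, kept, drop = FALSE]; diag(off) <- 0
    expect_true(all(off <= thr))
    for (d in which(!keep))
      expect_true(any(R[d, kept] > thr))
  }
})

test_that("prune ensembles are deterministic and degenerate correctly", {
  p <- sim_params(m_blocks = 20, block_size = 10, seed = 2)
  panel <- simulate_panel(p)$panel
  e1 <- build_prune_ensemble(panel, 5, 0.8, base_seed = 99)
  e2 <- build_prune_ensemble(panel, 5, 0.8, base_seed = 99)
  expect_identical(e1$masks, e2$masks)
  expect_identical(e1$seeds, e2$seeds)
  # n_iter = 1 equals a single prune with the derived seed
  e3 <- build_prune_ensemble(panel, 1, 0.8, base_seed = 5)
  expect_identical(e3$masks[, 1], random_prune(panel, 0.8, e3$seeds[1]))
  # independence panel: every mask keeps everything
  free <- tiny_panel(sprintf("s%d", 1:30))
  ef <- build_prune_ensemble(free, 4, 0.8, base_seed = 1)
  expect_true(all(ef$masks))
})

test_that("greedy clumping follows ranking and absorbs by r2", {
  panel <- tiny_panel(c("a", "b", "c", "d"),
                      list(a = c("a", "c", "a"), b = c("b", "d", "c"),
                           r2 = c(0.3, 0.25, 0.05)))
  hits <- data.table::data.table(SNP = c("a", "b", "c", "d"),
                                 CONJFDR = c(0.001, 0.005, 0.002, 0.008),
                                 P_TRAIT1 = c(1e-6, 1e-4, 5e-6, 1e-3))
  loci <- clump_loci(hits, panel, 0.2)
  expect_equal(loci$SNP, c("a", "c"))
  expect_setequal(strsplit(loci$MEMBERS[1], ",")[[1]], c("a", "b"))
  expect_setequal(strsplit(loci$MEMBERS[2], ",")[[1]], c("c", "d"))
  # invariant to input row order
  loci2 <- clump_loci(hits[c(3, 1, 4, 2)], panel, 0.2)
  expect_equal(as.data.frame(loci), as.data.frame(loci2))
  # single hit clumps to itself; two correlated hits merge under the better lead
  expect_equal(clump_loci(hits[1], panel, 0.2)$MEMBERS, "a")
  two <- clump_loci(hits[SNP %in% c("a", "b")], panel, 0.2)
  expect_equal(two$SNP, "a")
  expect_equal(two$N_SNPS, 2L)
})

test_that("LD scores are additive over disjoint pair sets", {
  snps <- sprintf("s%d", 1:6)
  pA <- tiny_panel(snps, list(a = "s1", b = "s2", r2 = 0.5))
  pB <- tiny_panel(snps, list(a = "s3", b = "s4", r2 = 0.7))
  pAB <- tiny_panel(snps, list(a = c("s1", "s3"), b = c("s2", "s4"),
                               r2 = c(0.5, 0.7)))
  expect_equal(ld_scores(pAB) - 1, (ld_scores(pA) - 1) + (ld_scores(pB) - 1))
})
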