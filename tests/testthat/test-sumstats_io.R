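test_that("reading reconstructs missing statistics and validates rows", {
  f <- write_sumstats_file(data.frame(
    SNP = c("rs1", "rs2", "rs3", "rs4", "rs5", "rs6"),
    CHR = c(1, 1, 2, 2, 3, 3),
    BP = c(100, 200, 300, 400, 500, 600),
    A1 = c("A", "A", "C", "G", "A", "A"),
    A2 = c("G", "C", "T", "T", "X", "A"),
    Z = c(0, NA, 2.5, NA, 1.0, 1.0),
    P = c(NA, 0.05, NA, NA, 0.5, 0.5),
    BETA = c(0, -1, 1, 2, 1, 1)))
  ss <- suppressMessages(read_sumstats(f, column_map = list(sign = "BETA")))
  # rs5 has a non-ACGT allele, rs6 identical alleles, rs4 neither z nor p
  expect_setequal(ss$SNP, c("rs1", "rs2", "rs3"))
  expect_equal(attr(ss, "n_dropped"), 3)
  # z = 0 gives two-sided p = 1
  expect_equal(ss[SNP == "rs1", P], 1.0)
  # p = 0.05 with negative sign gives the inverse-normal z
  expect_equal(ss[SNP == "rs2", Z], qnorm(0.025), tolerance = 1e-12)
  # missing p reconstructed from z
  expect_equal(ss[SNP == "rs3", P], 2 * pnorm(-2.5), tolerance = 1e-12)
})

test_that("a z-score reported to two decimals reproduces a deep-tail p", {
  # lead-SNP example: z = 11.77 for the lung-cancer trait corresponds to
  # the printed p = 5.302e-32; z rounding bounds the -log10 discrepancy
  p_from_z <- 2 * pnorm(-11.77)
  expect_lt(abs(log10(p_from_z) - log10(5.302e-32)), 0.03)
})

test_that("inconsistent z/p pairs are resolved in favour of z", {
  f <- write_sumstats_file(data.frame(
    SNP = c("a", "b"), CHR = 1, BP = c(1, 2), A1 = "A", A2 = "G",
    Z = c(2.0, 3.0), P = c(2 * pnorm(-2), 0.5)))
  ss <- suppressMessages(read_sumstats(f))
  expect_equal(ss$P, 2 * pnorm(-c(2, 3)), tolerance = 1e-12)
})

test_that("reading fails when most rows are invalid", {
  f <- write_sumstats_file(data.frame(
    SNP = c("a", "b", "c"), CHR = 1, BP = 1:3, A1 = c("A", "A", "A"),
    A2 = c("A", "A", "G"), Z = 1, P = 0.5))
  expect_error(read_sumstats(f), "failed validation")
})

test_that("write/read round-trip preserves all fields", {
  set.seed(1)
  n <- 50
  ss <- data.table::data.table(
    SNP = sprintf("rs%d", 1:n), CHR = sample(1:22, n, TRUE),
    BP = sample.int(1e8, n), A1 = "A", A2 = "G",
    Z = rnorm(n), N = 1000)
  ss[, P := 2 * pnorm(-abs(Z))]
  f <- tempfile()
  write_sumstats(ss, f)
  back <- read_sumstats(f)
  expect_identical(back$SNP, ss$SNP)
  expect_identical(back$A1, ss$A1)
  expect_equal(back$Z, ss$Z, tolerance = 1e-12)
  expect_equal(back$P, ss$P, tolerance = 1e-12)
})

test_that("allele harmonization matches, swaps, complements, and drops", {
  ref <- ref_from(c("s1", "s2", "s3", "s4", "s5"), chr = rep(1L, 5),
                  bp = 1:5 * 100, a1 = c("A", "A", "A", "A", "A"),
                  a2 = c("G", "G", "G", "G", "T"))
  ss <- data.table::data.table(
    SNP = c("s1", "s2", "s3", "s4", "s5", "s9"),
    CHR = 1L, BP = c(1:5 * 100, 900),
    A1 = c("A", "G", "T", "C", "A", "A"),
    A2 = c("G", "A", "C", "T", "T", "G"),
    Z = c(2.5, 2.5, 1.0, 1.0, 1.0, 1.0),
    P = 2 * pnorm(-abs(c(2.5, 2.5, 1.0, 1.0, 1.0, 1.0))))
  out <- suppressMessages(align_to_reference(ss, ref))
  # identical alleles unchanged; swapped flips sign; T/C vs A/G matches by
  # complement; C/T vs A/G is complement+swap; A/T ambiguous dropped; s9
  # not in reference
  expect_identical(out$SNP, c("s1", "s2", "s3", "s4"))
  expect_equal(out$Z, c(2.5, -2.5, 1.0, -1.0))
  expect_true(all(out$A1 == "A" & out$A2 == "G"))
  expect_equal(attr(out, "coverage"), 4 / 5)
})

test_that("alignment is idempotent and errors on zero overlap", {
  ref <- ref_from(c("s1", "s2"), c(1L, 1L), c(100L, 200L), c("A", "C"),
                  c("G", "T"))
  ss <- data.table::data.table(SNP = c("s1", "s2"), CHR = 1L,
                               BP = c(100L, 200L), A1 = c("G", "C"),
                               A2 = c("A", "T"), Z = c(1, 2),
                               P = 2 * pnorm(-c(1, 2)))
  once <- suppressMessages(align_to_reference(ss, ref))
  twice <- suppressMessages(align_to_reference(once, ref))
  expect_equal(as.data.frame(once), as.data.frame(twice))
  none <- data.table::data.table(SNP = "zz", CHR = 1L, BP = 5L, A1 = "A",
                                 A2 = "G", Z = 1, P = 0.3)
  expect_error(suppressMessages(align_to_reference(none, ref)), "overlap")
})

test_that("region exclusion is inclusive on both boundaries", {
  ss <- data.table::data.table(
    SNP = c("in_mid", "at_start", "at_end", "other_chr", "outside"),
    CHR = c(6L, 15L, 15L, 7L, 6L),
    BP = c(30000000L, 78686690L, 79231478L, 30000000L, 29528317L),
    A1 = "A", A2 = "G", Z = 1, P = 0.3)
  mhc <- suppressMessages(exclude_region(ss, region_mhc()))
  expect_false("in_mid" %in% mhc$SNP)
  expect_true("other_chr" %in% mhc$SNP)
  expect_true("outside" %in% mhc$SNP)  # one bp left of the MHC start
  chrna <- suppressMessages(exclude_region(ss, region_chrna()))
  expect_false("at_start" %in% chrna$SNP)
  expect_false("at_end" %in% chrna$SNP)
  # excluded set does not intersect the region
  both <- suppressMessages(exclude_region(ss, list(region_mhc(), region_chrna())))
  r <- region_mhc()
  expect_equal(nrow(both[CHR == r$chrom & BP >= r$start & BP <= r$end]), 0)
})

test_that("region parsing accepts printed coordinate syntax and BED", {
  r <- parse_region("chr6:29,528,318-33,373,649")
  expect_equal(r$chrom, 6L)
  expect_equal(r$start, 29528318)
  expect_equal(r$end, 33373649)
  expect_error(parse_region("chr6:10-5"), "start > end")
  bed <- tempfile(fileext = ".bed")
  writeLines(c("track name=test", "chr6\t29528317\t33373649\tMHC"), bed)
  regs <- read_bed_regions(bed)
  expect_length(regs, 1)
  # BED 0-based half-open becomes 1-based inclusive
  expect_equal(regs[[1]]$start, 29528318)
  expect_equal(regs[[1]]$end, 33373649)
})
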