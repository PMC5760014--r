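test_that("read_sumstats loads well-formed files and enforces row invariants", {
  path <- write_sumstats_file(c(
    "rs1\t1\t1000\tA\tG\t0.5\t0.1",
    "rs2\t1\t2000\tC\tT\t0.01\t-0.2",
    "rs3\t2\t3000\tA\tC\t1.0\t0.0"))
  s <- read_sumstats(path)
  expect_s3_class(s, "sumstats")
  expect_equal(nrow(s), 3L)
  expect_equal(attr(s, "load_report")$n_dropped_invalid, 0L)
  expect_equal(attr(s, "load_report")$n_dropped_duplicate, 0L)

  # p = 0 row dropped and counted
  path0 <- write_sumstats_file(c(
    "rs1\t1\t1000\tA\tG\t0\t0.1",
    "rs2\t1\t2000\tC\tT\t0.5\t0.2"))
  s0 <- read_sumstats(path0)
  expect_equal(nrow(s0), 1L)
  expect_equal(attr(s0, "load_report")$n_dropped_invalid, 1L)

  # duplicate rsID: first kept; count cross-checked against raw line count
  pathd <- write_sumstats_file(c(
    "rs1\t1\t1000\tA\tG\t0.5\t0.1",
    "rs1\t1\t1000\tA\tG\t0.2\t0.9",
    "rs2\t1\t2000\tC\tT\t0.5\t0.2"))
  sd <- read_sumstats(pathd)
  n_lines <- length(readLines(pathd)) - 1L   # independent oracle
  expect_equal(nrow(sd), n_lines - 1L)
  expect_equal(attr(sd, "load_report")$n_dropped_duplicate, 1L)
  expect_equal(sd[sd$snp == "rs1", ]$pval, 0.5)  # first occurrence wins
})

test_that("read_sumstats fails hard on missing columns and empty tables", {
  bad <- tempfile(fileext = ".tsv")
  writeLines(c("SNP\tCHR\tBP\tA1\tA2\tBETA", "rs1\t1\t1\tA\tG\t0.1"), bad)
  expect_error(read_sumstats(bad), "P")
  allbad <- write_sumstats_file("rs1\t1\t1000\tA\tA\t0.5\t0.1")
  expect_error(read_sumstats(allbad), "no valid rows")
})

test_that("odds ratios are log-transformed on read", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("SNP\tCHR\tBP\tA1\tA2\tP\tOR", "rs1\t1\t1000\tA\tG\t0.5\t2.0"), path)
  s <- read_sumstats(path, dialect = sumstats_dialect(or = "OR", beta = NULL))
  expect_equal(s$beta, log(2))
})

test_that("write/read round-trip is byte-identical in the canonical dialect", {
  sim <- simulate_pair(sim_params(m_snps = 200, block_size = 10, seed = 3),
                       ld_table = FALSE)
  f1 <- tempfile(fileext = ".tsv"); f2 <- tempfile(fileext = ".tsv")
  write_sumstats(sim$s1, f1)
  write_sumstats(read_sumstats(f1, trait = "trait1"), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("harmonize_pair aligns swapped alleles and drops unresolvable ones", {
  s1 <- sumstats(c("rs1", "rs2", "rs3"), "1", c(1, 2, 3) * 1000,
                 c("A", "A", "A"), c("G", "G", "G"),
                 c(0.1, 0.2, 0.3), c(0.3, 0.5, -0.2), trait = "t1")
  # rs1 swapped (G,A) with OR 2.0 on log scale; rs2 identical; rs3 mismatched
  s2 <- sumstats(c("rs1", "rs2", "rs3"), "1", c(1, 2, 3) * 1000,
                 c("G", "A", "A"), c("A", "G", "C"),
                 c(0.5, 0.6, 0.7), c(log(2), 0.4, 0.9), trait = "t2")
  pair <- harmonize_pair(s1, s2)
  expect_equal(nrow(pair), 2L)
  expect_equal(pair[pair$snp == "rs1", ]$beta2, -log(2))   # flipped
  expect_equal(pair[pair$snp == "rs2", ]$beta2, 0.4)       # untouched
  expect_equal(attr(pair, "provenance")$n_dropped_unresolvable, 1L)
})

test_that("palindromic variants are dropped by default, kept on request", {
  s1 <- sumstats(c("rs1", "rs2"), "1", c(1000, 2000), c("A", "C"), c("T", "G"),
                 c(0.1, 0.2), c(0.3, 0.5), trait = "t1")
  s2 <- sumstats(c("rs1", "rs2"), "1", c(1000, 2000), c("A", "C"), c("T", "G"),
                 c(0.5, 0.6), c(0.1, 0.4), trait = "t2")
  expect_error(harmonize_pair(s1, s2), "no variants survive")
  pair <- harmonize_pair(s1, s2, drop_palindromic = FALSE)
  expect_equal(nrow(pair), 2L)
})

test_that("harmonization is idempotent and symmetric in the variant set", {
  sim <- simulate_pair(sim_params(m_snps = 500, block_size = 10, seed = 11),
                       ld_table = FALSE)
  pair <- harmonize_pair(sim$s1, sim$s2)
  again <- harmonize_pair(pair_side(pair, 1L), pair_side(pair, 2L))
  expect_equal(as.data.frame(again), as.data.frame(pair))

  swapped <- harmonize_pair(sim$s2, sim$s1)
  expect_equal(sort(swapped$snp), sort(pair$snp))
  expect_equal(swapped[order(snp)]$p1, pair[order(snp)]$p2)
  expect_equal(swapped[order(snp)]$beta2, pair[order(snp)]$beta1)
})

test_that("harmonize_pair errors on an empty intersection", {
  s1 <- sumstats("rs1", "1", 1000, "A", "G", 0.5, 0.1)
  s2 <- sumstats("rs9", "1", 1000, "A", "G", 0.5, 0.1)
  expect_error(harmonize_pair(s1, s2), "no shared variants")
})

test_that("genomic correction matches the direct median chi-square oracle", {
  set.seed(42)
  p <- runif(50000)
  s <- sumstats(sprintf("rs%d", seq_along(p)), "1", seq_along(p), "A", "G",
                p, rep(0, length(p)))
  corrected <- genomic_correction(s)
  lam_oracle <- median(qchisq(p, 1, lower.tail = FALSE)) / qchisq(0.5, 1)
  expect_equal(attr(corrected, "lambda"), lam_oracle)
  expect_gte(lam_oracle, 0.97)
  expect_lte(lam_oracle, 1.03)
})

test_that("lambda = 1 is a fixed point and doubling chi-squares gives lambda 2", {
  base_chi <- rep(qchisq(0.5, 1), 200)
  p_fix <- pchisq(base_chi, 1, lower.tail = FALSE)
  s_fix <- sumstats(sprintf("rs%d", 1:200), "1", 1:200, "A", "G", p_fix,
                    rep(0, 200))
  out <- genomic_correction(s_fix)
  expect_equal(attr(out, "lambda"), 1)
  expect_identical(out$pval, s_fix$pval)

  p_dbl <- pchisq(2 * base_chi, 1, lower.tail = FALSE)
  s_dbl <- sumstats(sprintf("rs%d", 1:200), "1", 1:200, "A", "G", p_dbl,
                    rep(0, 200))
  out2 <- genomic_correction(s_dbl)
  expect_equal(attr(out2, "lambda"), 2)
  # corrected chi-squares are halved, i.e. back to the fixed-point p-values
  expect_equal(out2$pval, p_fix, tolerance = 1e-12)
})

test_that("genomic correction preserves p-value ranks and warns when tiny", {
  set.seed(5)
  p <- runif(500)^2          # inflated
  s <- sumstats(sprintf("rs%d", seq_along(p)), "1", seq_along(p), "A", "G",
                p, rep(0, length(p)))
  out <- genomic_correction(s)
  expect_gt(attr(out, "lambda"), 1)
  expect_identical(order(out$pval), order(s$pval))

  tiny <- sumstats(sprintf("rs%d", 1:10), "1", 1:10, "A", "G",
                   runif(10), rep(0, 10))
  expect_warning(out_tiny <- genomic_correction(tiny), "lambda forced to 1")
  expect_equal(attr(out_tiny, "lambda"), 1)
})
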