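test_that("cis pairing uses a strict 1-Mb TSS window and matches brute force", {
  genes <- gene_annotation(chrom = c("1", "1", "1", "2"),
                           start = c(1e6, 5e6, 9e6, 1e6),
                           end = c(1.1e6, 5.2e6, 9.1e6, 1.3e6),
                           name = c("g1", "g2", "g3", "g4"),
                           strand = c("+", "-", "+", "+"))
  variants <- data.frame(snp = sprintf("v%d", 1:5), chrom = c("1", "1", "1", "1", "2"),
                         pos = c(1e6, 2000001, 5.2e6, 8.5e6, 1e6))
  pairs <- cis_pairs(variants, genes)
  expect_true(any(pairs$snp == "v1" & pairs$gene == "g1"))   # exactly at TSS
  expect_equal(pairs[pairs$snp == "v1" & pairs$gene == "g1", ]$distance, 0)
  # v2 sits at TSS(g1) + 1,000,001: outside the inclusive 1e6 bound
  expect_false(any(pairs$snp == "v2" & pairs$gene == "g1"))
  # minus-strand TSS is the interval end: v3 at 5.2e6 hits g2 at distance 0
  expect_equal(pairs[pairs$snp == "v3" & pairs$gene == "g2", ]$distance, 0)

  # exhaustive scan oracle
  tss <- ifelse(genes$strand == "-", genes$end, genes$start)
  manual <- do.call(rbind, lapply(1:5, function(i) {
    hit <- genes$chrom == variants$chrom[i] & abs(variants$pos[i] - tss) <= 1e6
    if (any(hit)) data.frame(snp = variants$snp[i], gene = genes$name[hit])
  }))
  expect_equal(nrow(pairs), nrow(manual))
  expect_setequal(paste(pairs$snp, pairs$gene), paste(manual$snp, manual$gene))
})

test_that("noiseless additive fit is exact with the smallest positive p", {
  dosage <- c(0, 1, 2, 0, 1, 2, 1, 0)
  fit <- ancova_additive(2 * dosage + 1, dosage)
  expect_equal(fit$slope, 2, tolerance = 1e-12)
  expect_equal(fit$p, .Machine$double.xmin)
})

test_that("without covariates the ANCOVA equals the closed-form simple regression", {
  set.seed(51)
  for (rep in 1:5) {
    dosage <- rbinom(30, 2, 0.4)
    y <- 0.5 * dosage + rnorm(30)
    fit <- ancova_additive(y, dosage)
    # closed form, computed independently
    n <- 30
    sxx <- sum((dosage - mean(dosage))^2)
    b <- sum((dosage - mean(dosage)) * (y - mean(y))) / sxx
    resid <- y - mean(y) - b * (dosage - mean(dosage))
    se <- sqrt(sum(resid^2) / (n - 2) / sxx)
    tval <- b / se
    p <- 2 * pt(-abs(tval), df = n - 2)
    expect_equal(fit$slope, b, tolerance = 1e-10)
    expect_equal(fit$t, tval, tolerance = 1e-10)
    expect_equal(fit$p, p, tolerance = 1e-10)
  }
})

test_that("ANCOVA adjusts covariates and flags degenerate designs without failing", {
  set.seed(52)
  dosage <- rbinom(40, 2, 0.5)
  age <- rnorm(40, 60, 8)
  y <- 1.5 * dosage + 0.2 * age + rnorm(40)
  fit <- ancova_additive(y, dosage, covariates = data.frame(age = age))
  expect_equal(fit$slope, 1.5, tolerance = 0.5)
  expect_true(is.na(fit$error))

  const <- ancova_additive(rnorm(10), rep(1, 10))
  expect_equal(const$error, "constant dosage")
  expect_true(is.na(const$p))
})

test_that("permuted dosages give uniform ANCOVA p-values", {
  fails <- 0L
  for (seed in 1:10) {
    set.seed(seed)
    dosage <- rbinom(40, 2, 0.3)
    p <- replicate(500, ancova_additive(rnorm(40), sample(dosage))$p)
    if (suppressWarnings(ks.test(p, "punif"))$p.value < 0.01) fails <- fails + 1L
  }
  expect_lte(fails, 2L)
})

test_that("ANCOVA slope and test are invariant to expression location shifts", {
  set.seed(53)
  dosage <- rbinom(25, 2, 0.4)
  y <- 0.7 * dosage + rnorm(25)
  f0 <- ancova_additive(y, dosage)
  f1 <- ancova_additive(y + 100, dosage)
  expect_equal(f1$slope, f0$slope, tolerance = 1e-10)
  expect_equal(f1$t, f0$t, tolerance = 1e-10)
  expect_equal(f1$p, f0$p, tolerance = 1e-10)
})

test_that("the Bonferroni gate is strict at the boundary", {
  res <- data.table::data.table(p = c(3.9e-5, 1e-12, 3.8999e-5, 0.5, NA))
  out <- bonferroni_gate(res)
  expect_identical(out$pass, c(FALSE, TRUE, TRUE, FALSE, FALSE))
  expect_equal(sum(out$pass), sum(res$p < 3.9e-5, na.rm = TRUE))  # enumeration
})

test_that("differential expression handles degenerate and missing genes", {
  vals <- rbind(gene1 = c(1, 1, 1, 2, 2, 2),
                gene2 = c(3, 3, 3, 3, 3, 3))
  mat <- expression_matrix(vals, group = rep(c("a", "b"), each = 3))
  de <- differential_expression(mat, "a", "b", genes = c("gene2", "ghost"))
  expect_equal(de[de$gene == "gene2", ]$p, 1)           # equal constant groups
  expect_false(de[de$gene == "ghost", ]$available)      # N/A record
  expect_true(is.na(de[de$gene == "ghost", ]$p))
})

test_that("swapping the groups negates the statistic and preserves p exactly", {
  sx <- simulate_expression(n_samples = c(11, 17), n_genes = 20, de_shift = 1,
                            noise_sd = 1, seed = 54)
  ab <- differential_expression(sx$mat, "control", "FTD-U")
  ba <- differential_expression(sx$mat, "FTD-U", "control")
  expect_equal(ba$statistic, -ab$statistic)
  expect_identical(ba$p, ab$p)
})

test_that("an FTD-sized unbalanced cohort detects 3-sigma shifts with 80% power", {
  sx <- simulate_expression(n_samples = c(11, 17), n_genes = 300, de_shift = 3,
                            noise_sd = 1, seed = 55)
  de <- differential_expression(sx$mat, "control", "FTD-U")
  expect_gte(mean(de$p[sx$truth$is_de] <= 0.05), 0.8)
})

test_that("cell-type assignment is an argmax with canonical tie-breaking", {
  profile <- rbind(
    gA = c(neurons = 1, `microglia/macrophages` = 60),
    gB = c(neurons = 5, `microglia/macrophages` = 5),
    gC = c(neurons = 0, `microglia/macrophages` = 0))
  out <- cell_type_assignment(profile, genes = c("gA", "gB", "gC", "gD"))
  expect_equal(out$assignment$cell_type,
               c("microglia/macrophages",
                 "neurons",              # tie: neurons precede microglia
                 "neurons",              # all-zero row ties at 0
                 "not found"))           # absent from profile
  expect_equal(as.integer(out$counts["not found"]), 1L)
})

test_that("assignment is invariant to positive per-gene rescaling and counts match enumeration", {
  set.seed(56)
  types <- cell_type_order()[c(1, 2, 7)]   # neurons, fetal astro, microglia
  profile <- matrix(runif(27), 9, 3,
                    dimnames = list(sprintf("g%d", 1:9), types))
  profile[1:5, 3] <- 10   # 5 genes peak in microglia
  profile[6:7, 1] <- 10   # 2 in neurons
  profile[8:9, 2] <- 10   # 2 in fetal astrocytes
  out <- cell_type_assignment(profile)
  manual <- apply(profile, 1, function(r) colnames(profile)[which.max(r)])
  expect_equal(out$assignment$cell_type, unname(manual))
  expect_equal(as.integer(out$counts[c("neurons", "fetal astrocytes",
                                       "microglia/macrophages")]),
               c(2L, 2L, 5L))

  scaled <- profile * rep(runif(9, 0.1, 10), 3)  # per-gene positive rescale
  expect_equal(cell_type_assignment(scaled)$assignment$cell_type,
               out$assignment$cell_type)
})
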