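test_that("clumping keeps one of the fixture's perfectly linked pair by tie rule", {
  fx <- table2_fixture()
  rec <- fixture_records(fx)
  out <- ld_clump(rec, ld = attr(fx, "ld"))
  # equal conjunction FDR and equal primary p: lexicographic rsID decides
  expect_true(out[out$snp == "rs204989", ]$lead)
  expect_true(out[out$snp == "rs204991", ]$pruned)
  expect_equal(sum(out$pruned), 1L)
})

test_that("an empty LD table prunes nothing", {
  rec <- fixture_records()
  out <- ld_clump(rec, ld = ld_table(character(), character(), numeric()))
  expect_true(all(out$lead))
  out2 <- ld_clump(rec, ld = NULL)
  expect_true(all(out2$lead))
})

test_that("a fully linked block collapses to exactly one lead, regardless of input order", {
  ids <- sprintf("rs%d", 1:5)
  combos <- t(combn(5, 2))
  ld <- ld_table(ids[combos[, 1]], ids[combos[, 2]], rep(0.9, nrow(combos)))
  rec <- data.table::data.table(snp = ids, chr = "1",
                                conj_fdr = c(0.01, 0.02, 0.03, 0.04, 0.045),
                                p1 = runif(5), sign1 = 1, sign2 = 1)
  ref <- ld_clump(rec, ld)
  expect_equal(sum(ref$lead), 1L)
  expect_true(ref[ref$snp == "rs1", ]$lead)  # best ranked wins
  for (i in 1:5) {                            # order invariance
    shuffled <- rec[sample(5), ]
    out <- ld_clump(shuffled, ld)
    expect_equal(out$snp[out$lead], ref$snp[ref$lead])
  }
})

test_that("region exclusion removes position hits, flank hits, and LD partners", {
  s <- function(p) sumstats(sprintf("rs%d", 1:4), c("6", "6", "6", "2"),
                            c(30e6, 35.5e6, 40e6, 5e6), "A", "G",
                            rep(p, 4), rep(0.1, 4))
  pair <- harmonize_pair(s(0.5), s(0.4))
  ld <- ld_table("rs1", "rs3", 0.3)   # rs3 is 5 Mb away but linked to rs1
  out <- exclude_region_ld(pair, hla_region(), ld)
  expect_equal(out$snp, "rs4")
  rep <- attr(out, "removal_report")
  expect_equal(rep$n_position, 2L)    # rs1 inside, rs2 within the 1-Mb flank
  expect_equal(rep$n_ld, 1L)          # rs3 via LD only

  # no variants in or near the region and no LD links: identity
  far <- exclude_region_ld(pair, region("9", 1e6, 2e6),
                           ld_table(character(), character(), numeric()))
  expect_equal(far$snp, pair$snp)
  expect_equal(far$p1, pair$p1)
  expect_equal(attr(far, "removal_report")$n_removed, 0L)

  # LD propagation removes a superset of the position-only rule
  pos_only <- exclude_region_ld(pair, hla_region(), ld = NULL)
  expect_true(all(setdiff(pair$snp, pos_only$snp) %in%
                  setdiff(pair$snp, out$snp)))
})

test_that("direction concordance is a sign comparison", {
  fx <- table2_fixture()
  cls <- direction_concordance(fx$sign1, fx$sign2)
  expect_equal(cls[fx$snp == "rs9268877"], "discordant")   # +/-
  expect_equal(cls[fx$snp == "rs3117097"], "concordant")   # +/+
  expect_equal(cls[fx$snp == "rs17427887"], "concordant")  # -/-
  expect_equal(sum(cls == "discordant"), 5L)
  expect_warning(direction_concordance(0, 1), "zero effect")
})

test_that("nearest gene annotation honours containment and tie rules", {
  ann <- gene_annotation(chrom = c("1", "1", "1"),
                         start = c(100, 500, 900),
                         end = c(200, 600, 1000),
                         name = c("gA", "gB", "gC"))
  expect_equal(nearest_gene("1", 150, ann), "gA")          # inside
  expect_equal(nearest_gene("1", 350, ann), "gA")          # equidistant: smaller start
  expect_equal(nearest_gene("2", 150, ann), "none")        # empty chromosome

  # brute-force oracle over random queries
  set.seed(41)
  for (pos in sample(1:1200, 20)) {
    d <- pmax(0, pmax(ann$start - pos, pos - ann$end))
    ord <- order(d, ann$start, ann$name)
    expect_equal(nearest_gene("1", pos, ann), ann$name[ord[1]])
  }
})

test_that("the locus filter reproduces the published 21 -> 15 -> 8 counts", {
  fx <- table2_fixture()
  rep <- locus_filter_report(fixture_records(fx), ld = attr(fx, "ld"))
  expect_equal(rep$n_input, 21L)
  expect_equal(rep$n_discordant, 5L)
  expect_equal(rep$n_pruned, 1L)
  expect_equal(rep$n_surviving, 15L)
  expect_equal(unname(rep$n_surviving_by_chr["6"]), 8L)
  expect_equal(rep$n_input,
               rep$n_discordant + rep$n_pruned + rep$n_surviving)
})

test_that("LD tables validate their inputs and round-trip through text", {
  expect_error(ld_table("a", "b", 1.5), "r2")
  ld <- ld_table(c("rs1", "rs2"), c("rs3", "rs4"), c(0.5, 0.9), dprime = c(1, 1))
  f <- tempfile(fileext = ".tsv")
  data.table::fwrite(ld, f, sep = "\t")
  back <- read_ld_table(f)
  expect_equal(as.data.frame(back), as.data.frame(ld))
})

test_that("BED intervals convert to 1-based inclusive coordinates", {
  f <- tempfile(fileext = ".bed")
  writeLines(c("chr6\t999\t2000\tgeneX\t0\t+", "chr6\t5000\t6000\tgeneY\t0\t-"), f)
  bed <- read_bed(f)
  expect_equal(bed$start, c(1000, 5001))
  expect_equal(bed$end, c(2000, 6000))
  expect_equal(bed$strand, c("+", "-"))
})
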