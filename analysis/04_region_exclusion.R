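#!/usr/bin/env Rscript
# Region-exclusion sensitivity analysis (the HLA-style re-analysis): when one
# genomic region drives the cross-trait enrichment, dropping every variant in
# the region, within 1 Mb of it, or in LD (r2 > 0.2) with a removed variant
# should collapse the fold-enrichment curves. Demonstrated on a dataset with
# a single planted pleiotropic block, the clean analog of the published
# before/after comparison; the main simulated study (01-03) spreads its
# pleiotropic blocks genome-wide, so no single region dominates there.

suppressPackageStartupMessages({library(pleioconj); library(data.table)})
dir.create("results/analysis", recursive = TRUE, showWarnings = FALSE)

m <- 20000L; bs <- 50L
classes <- rep("00", m); classes[1:bs] <- "11"     # block 1, chromosome 1
sim <- simulate_pair(sim_params(m_snps = m, block_size = bs, rho_effect = 1,
                                seed = 42), classes = classes)
pair <- harmonize_pair(sim$s1, sim$s2)
reg <- region("1", 1, bs * 1000 + 1, name = "planted block")

before <- fold_enrichment(pair, strata = c(0, 1, 2))
after <- excluded_region_rerun(pair, reg, sim$ld, window = 1e5,
                               strata = c(0, 1, 2))
fwrite(before, "results/analysis/enrichment_planted.tsv", sep = "\t")
fwrite(after, "results/analysis/enrichment_planted_excluded.tsv", sep = "\t")

mb <- attr(before, "max_fe"); ma <- attr(after, "max_fe")
cat(sprintf("excluded %s:%d-%d plus flanks and LD partners\n",
            reg$chrom, reg$start, reg$end))
cat("max fold enrichment per stratum, before vs after exclusion:\n")
print(round(rbind(before = mb, after = ma), 2))
drop <- (max(mb[c("1", "2")]) - max(ma[c("1", "2")], na.rm = TRUE)) /
  max(mb[c("1", "2")])
cat(sprintf("max enrichment over strict strata drops by %.0f%%\n", 100 * drop))
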