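#!/usr/bin/env Rscript
# Generate the synthetic study inputs: a pair of GWAS summary-statistic sets
# with block LD, a four-component causal mixture (null / trait-specific /
# pleiotropic), and the pairwise LD table. Writes the canonical tab-delimited
# sumstats files that the downstream steps read back, plus the ground truth
# for later evaluation.

suppressPackageStartupMessages(library(pleioconj))

dir.create("results/analysis", recursive = TRUE, showWarnings = FALSE)

params <- sim_params(m_snps = 50000L, block_size = 50L, rho_effect = 0.8,
                     seed = 20260926 %% 1000L)
sim <- simulate_pair(params)

write_sumstats(sim$s1, "results/analysis/trait1.tsv")
write_sumstats(sim$s2, "results/analysis/trait2.tsv")
data.table::fwrite(sim$ld, "results/analysis/ld.tsv", sep = "\t")
data.table::fwrite(sim$truth, "results/analysis/truth.tsv", sep = "\t")

cls <- table(sim$truth$class)
cat(sprintf("simulated %d variants in %d-SNP blocks (r_within = %.2f)\n",
            params$m_snps, params$block_size, params$r_within))
cat(sprintf("causal classes: %s\n",
            paste(names(cls), cls, sep = "=", collapse = "  ")))
cat(sprintf("pleiotropic blocks: %d of %d\n",
            length(unique(sim$truth$block[sim$truth$class == "11"])),
            max(sim$truth$block)))
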