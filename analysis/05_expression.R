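#!/usr/bin/env Rscript
# Functional follow-up of pleiotropic loci, on synthetic fixtures shaped like
# the real follow-up data: (a) the published 21-locus table filtered by sign
# concordance and LD; (b) cis-eQTL additive-model tests with a Bonferroni
# gate; (c) pooled-region differential expression in an 11-control / 17-case
# cohort; (d) assignment of genes to the brain cell type that expresses them
# most highly.

suppressPackageStartupMessages({library(pleioconj); library(data.table)})
dir.create("results/analysis", recursive = TRUE, showWarnings = FALSE)

## (a) published locus table
fx <- table2_fixture()
rec <- data.table(snp = fx$snp, chr = as.character(fx$chr),
                  conj_fdr = fx$min_conj_fdr, p1 = fx$ftd_p,
                  sign1 = fx$sign1, sign2 = fx$sign2, in_region = fx$in_hla)
rep <- locus_filter_report(rec, ld = attr(fx, "ld"))
fwrite(rep$survivors, "results/analysis/table2_survivors.tsv", sep = "\t")
cat(sprintf("published table: %d loci -> %d after sign filter and LD dedup; %d on chr 6\n",
            rep$n_input, rep$n_surviving,
            as.integer(rep$n_surviving_by_chr["6"])))

## (b) cis-eQTL: planted slope, additive model, Bonferroni gate at 3.9e-5
sx <- simulate_expression(n_samples = c(11L, 17L), n_genes = 40L,
                          eqtl_slope = 2, de_shift = 1.2, noise_sd = 1,
                          prop_eqtl = 0.5, prop_de = 0.5, seed = 7)
eqtl <- rbindlist(lapply(seq_len(40L), function(g)
  cbind(gene = rownames(sx$mat$values)[g],
        ancova_additive(sx$mat$values[g, ], sx$dosage[g, ]))))
eqtl <- bonferroni_gate(eqtl)
fwrite(eqtl, "results/analysis/eqtl.tsv", sep = "\t")
cat(sprintf("cis-eQTL: %d of %d genes pass Bonferroni p < 3.9e-5 (%d carry a true eQTL)\n",
            sum(eqtl$pass), nrow(eqtl), sum(sx$truth$is_eqtl)))

## (c) pooled-region differential expression, control vs FTD-U
de <- differential_expression(sx$mat, "control", "FTD-U")
fwrite(de, "results/analysis/diffexpr.tsv", sep = "\t")
cat(sprintf("differential expression: %d of %d genes at p <= 0.05 (%d truly shifted)\n",
            sum(de$significant, na.rm = TRUE), nrow(de), sum(sx$truth$is_de)))

## (d) cell-type assignment over the eight surveyed CNS classes
set.seed(8)
types <- cell_type_order()
genes <- c(head(rep$survivors$snp, 5), "geneX")
profile <- matrix(rexp(5 * length(types), rate = 0.2), 5, length(types),
                  dimnames = list(genes[1:5], types))
profile[1:3, "microglia/macrophages"] <- profile[1:3, "microglia/macrophages"] + 50
assign <- cell_type_assignment(profile, genes = genes)   # geneX: not found
fwrite(assign$assignment, "results/analysis/cell_types.tsv", sep = "\t")
cat("genes per most-expressing cell type:\n")
print(assign$counts)
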