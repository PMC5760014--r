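#!/usr/bin/env Rscript
# Conjunction-FDR locus discovery: per-variant conditional FDRs in both
# directions (lookup tables estimated on a randomly LD-pruned subset),
# conjunction FDR as their maximum, selection at conjFDR < 0.05, greedy
# LD-rank clumping to lead variants, and the Manhattan-ready table.

suppressPackageStartupMessages({library(pleioconj); library(data.table)})

pair_dt <- fread("results/analysis/pair.tsv",
                 colClasses = list(character = c("snp", "chr", "a1", "a2")))
pair <- harmonize_pair(
  sumstats(pair_dt$snp, pair_dt$chr, pair_dt$bp, pair_dt$a1, pair_dt$a2,
           pair_dt$p1, pair_dt$beta1, trait = "trait1"),
  sumstats(pair_dt$snp, pair_dt$chr, pair_dt$bp, pair_dt$a1, pair_dt$a2,
           pair_dt$p2, pair_dt$beta2, trait = "trait2"))
ld <- read_ld_table("results/analysis/ld.tsv")

cj <- conj_fdr(pair, ld = ld)
fwrite(cj, "results/analysis/conjfdr.tsv", sep = "\t")
cat(sprintf("variants at conjunction FDR < 0.05: %d of %d\n",
            sum(cj$flagged), nrow(cj)))

flagged <- cj[cj$flagged, ]
rec <- data.table(snp = flagged$snp, chr = flagged$chr, bp = flagged$bp,
                  conj_fdr = flagged$conj_fdr, p1 = flagged$p1,
                  sign1 = sign(pair$beta1[match(flagged$snp, pair$snp)]),
                  sign2 = sign(pair$beta2[match(flagged$snp, pair$snp)]))
report <- locus_filter_report(rec, ld = ld[id_a %in% rec$snp & id_b %in% rec$snp])
fwrite(report$survivors, "results/analysis/loci.tsv", sep = "\t")
fwrite(manhattan_table(cj, lead = report$survivors$snp),
       "results/analysis/manhattan.tsv", sep = "\t")

cat(sprintf("locus filter: %d selected, %d discordant removed, %d LD-pruned, %d lead loci\n",
            report$n_input, report$n_discordant, report$n_pruned,
            report$n_surviving))

# evaluate against the generating truth
truth <- fread("results/analysis/truth.tsv",
               colClasses = list(character = c("snp", "chr")))
lead_blocks <- truth$block[match(report$survivors$snp, truth$snp)]
b11 <- unique(truth$block[truth$class == "11"])
cat(sprintf("lead loci tagging a truly pleiotropic block: %d of %d (block recall %.2f)\n",
            length(intersect(lead_blocks, b11)), report$n_surviving,
            length(intersect(lead_blocks, b11)) / length(b11)))
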