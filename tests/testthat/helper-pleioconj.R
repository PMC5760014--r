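# shared fixtures built in code

null_mixture <- c(p00 = 1, p10 = 0, p01 = 0, p11 = 0)

# independent (no-LD) global-null parameters
null_params <- function(m = 20000L, seed = 1L, lambda_inflate = 1) {
  sim_params(m_snps = m, block_size = 1L, r_within = 0,
             mixture = null_mixture, lambda_inflate = lambda_inflate,
             seed = seed)
}

# write a small canonical sumstats file, return its path
write_sumstats_file <- function(lines, path = tempfile(fileext = ".tsv")) {
  writeLines(c("SNP\tCHR\tBP\tA1\tA2\tP\tBETA", lines), path)
  path
}

# a tiny deterministic harmonized pair built directly from vectors
toy_pair <- function(p1, p2, chr = "1", bp = seq_along(p1) * 1000) {
  n <- length(p1)
  s1 <- sumstats(sprintf("rs%d", 1:n), chr, bp, "A", "G", p1, rep(0.1, n),
                 trait = "t1")
  s2 <- sumstats(sprintf("rs%d", 1:n), chr, bp, "A", "G", p2, rep(0.1, n),
                 trait = "t2")
  harmonize_pair(s1, s2)
}

# records table in the shape locus_filter_report expects, from the fixture
fixture_records <- function(fx = table2_fixture()) {
  data.table::data.table(snp = fx$snp, chr = as.character(fx$chr),
                         conj_fdr = fx$min_conj_fdr, p1 = fx$ftd_p,
                         sign1 = fx$sign1, sign2 = fx$sign2,
                         in_region = fx$in_hla)
}
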