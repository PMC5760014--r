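#' Simulation parameters for paired GWAS summary statistics
#'
#' Defines the generating model used for calibration and power studies:
#' variants are grouped into LD blocks with exchangeable correlation
#' `r_within` among z-scores, each variant is assigned a causal class from a
#' four-component mixture (null `p00`, trait-1-only `p10`, trait-2-only
#' `p01`, pleiotropic `p11`), causal log-odds effects are Gaussian with
#' standard deviation `sigma_beta`, and pleiotropic effect pairs have
#' correlation `rho_effect`. Observed z-scores are the block-smeared
#' noncentrality `sqrt(n_t) * (R %*% beta_t)` plus exchangeable-correlated
#' noise, optionally variance-inflated by `lambda_inflate` to emulate
#' genomic inflation.
#'
#' Defaults describe a mid-sized case-control pair: 20,000 variants in blocks
#' of 50 with within-block correlation 0.8, a 0.2% pleiotropic and 0.5%
#' per-trait-specific causal rate, per-allele effect s.d. 0.05 on the
#' log-odds scale, effective sample sizes of 10,000, and pleiotropic effect
#' correlation 0.8.
#'
#' @param m_snps Number of variants.
#' @param block_size Variants per LD block (last block may be shorter).
#' @param r_within Within-block z-score correlation, in \[0, 1).
#' @param mixture Length-4 probability vector `(p00, p10, p01, p11)`
#'   summing to 1 (tolerance 1e-12).
#' @param sigma_beta Causal effect s.d. per trait (scalar or length 2).
#' @param rho_effect Correlation of pleiotropic effect pairs, in \[-1, 1\].
#' @param n1,n2 Effective sample sizes.
#' @param lambda_inflate Variance inflation factor (>= 1) applied to the
#'   noise component.
#' @param seed Integer seed; identical seeds give byte-identical output.
#' @return A `sim_params` list.
#' @export
sim_params <- function(m_snps = 20000L, block_size = 50L, r_within = 0.8,
                       mixture = c(p00 = 0.988, p10 = 0.005, p01 = 0.005, p11 = 0.002),
                       sigma_beta = 0.05, rho_effect = 0.8,
                       n1 = 10000, n2 = 10000, lambda_inflate = 1, seed = 1L) {
  if (abs(sum(mixture) - 1) > 1e-12) stop("mixture must sum to 1")
  if (any(mixture < 0)) stop("mixture probabilities must be non-negative")
  if (r_within < 0 || r_within >= 1) stop("r_within must lie in [0, 1)")
  if (abs(rho_effect) > 1) stop("rho_effect must lie in [-1, 1]")
  if (lambda_inflate < 1) stop("lambda_inflate must be >= 1")
  sigma_beta <- rep(sigma_beta, length.out = 2L)
  structure(list(m_snps = as.integer(m_snps), block_size = as.integer(block_size),
                 r_within = r_within, mixture = mixture, sigma_beta = sigma_beta,
                 rho_effect = rho_effect, n1 = n1, n2 = n2,
                 lambda_inflate = lambda_inflate, seed = as.integer(seed)),
            class = "sim_params")
}

#' Simulate a harmonized pair of GWAS summary statistics
#'
#' Draws causal classes and effects per [sim_params()], builds block-smeared
#' z-scores with exchangeable within-block correlation, and returns the two
#' traits' summary statistics together with the generating truth and the
#' implied pairwise LD table (within-block pairs at `r2 = r_within^2`).
#' Positions are laid out one block per 10-Mb segment, cycling over
#' chromosomes 1-22, so that a block can be excised with a genomic interval.
#' P-values are two-sided normal tail probabilities.
#'
#' @param params A [sim_params()] object.
#' @param classes Optional per-variant causal class override, a character
#'   vector in `c("00","10","01","11")` of length `m_snps`; used to plant
#'   signal in chosen blocks.
#' @param ld_table Build the within-block LD pair table (can be large;
#'   default `TRUE`).
#' @return A list with elements `s1`, `s2` (`sumstats`), `truth` (data.table
#'   `snp, chr, bp, block, class, beta1, beta2`), and `ld` (an `ld_table` or
#'   `NULL`).
#' @export
simulate_pair <- function(params = sim_params(), classes = NULL, ld_table = TRUE) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed)
  m <- params$m_snps
  bs <- params$block_size
  r <- params$r_within

  block <- rep(seq_len(ceiling(m / bs)), each = bs)[seq_len(m)]
  n_block <- max(block)
  within <- sequence(tabulate(block))

  if (is.null(classes)) {
    classes <- sample(c("00", "10", "01", "11"), m, replace = TRUE,
                      prob = params$mixture)
  } else {
    stopifnot(length(classes) == m, all(classes %in% c("00", "10", "01", "11")))
  }

  sb <- params$sigma_beta
  beta1 <- numeric(m)
  beta2 <- numeric(m)
  i10 <- classes == "10"; i01 <- classes == "01"; i11 <- classes == "11"
  beta1[i10] <- rnorm(sum(i10), 0, sb[1])
  beta2[i01] <- rnorm(sum(i01), 0, sb[2])
  if (any(i11)) {
    k <- sum(i11)
    z_a <- rnorm(k); z_b <- rnorm(k)
    rho <- params$rho_effect
    beta1[i11] <- sb[1] * z_a
    beta2[i11] <- sb[2] * (rho * z_a + sqrt(1 - rho^2) * z_b)
  }

  # exchangeable smear: (R beta)_i = (1 - r) beta_i + r * block sum
  smear <- function(beta) {
    bsum <- rowsum(beta, block)[block]
    (1 - r) * beta + r * bsum
  }
  mu1 <- sqrt(params$n1) * smear(beta1)
  mu2 <- sqrt(params$n2) * smear(beta2)

  # exchangeable noise: sqrt(r) * shared block draw + sqrt(1 - r) * individual
  noise <- function() {
    g <- rnorm(n_block)[block]
    sqrt(params$lambda_inflate) * (sqrt(r) * g + sqrt(1 - r) * rnorm(m))
  }
  z1 <- mu1 + noise()
  z2 <- mu2 + noise()

  p1 <- 2 * pnorm(-abs(z1))
  p2 <- 2 * pnorm(-abs(z2))
  p1[p1 == 0] <- .Machine$double.xmin
  p2[p2 == 0] <- .Machine$double.xmin

  chr <- as.character(((block - 1L) %% 22L) + 1L)
  bp <- ((block - 1L) %/% 22L) * 1e7 + within * 1000
  snp <- sprintf("rs%07d", seq_len(m))

  s1 <- sumstats(snp, chr, bp, "A", "G", p1, z1 / sqrt(params$n1), trait = "trait1")
  s2 <- sumstats(snp, chr, bp, "A", "G", p2, z2 / sqrt(params$n2), trait = "trait2")
  truth <- data.table::data.table(snp = snp, chr = chr, bp = bp, block = block,
                                  class = classes, beta1 = beta1, beta2 = beta2)

  ld <- NULL
  if (ld_table && r > 0 && bs > 1L) {
    # vectorized within-block pair enumeration: a full-block index template
    # offset per block (the last, possibly short, block handled separately)
    tmpl <- which(upper.tri(matrix(0, bs, bs)), arr.ind = TRUE)
    n_full <- m %/% bs
    off <- rep((seq_len(n_full) - 1L) * bs, each = nrow(tmpl))
    ia <- rep(tmpl[, 1L], n_full) + off
    ib <- rep(tmpl[, 2L], n_full) + off
    rest <- m - n_full * bs
    if (rest > 1L) {
      tl <- which(upper.tri(matrix(0, rest, rest)), arr.ind = TRUE)
      ia <- c(ia, tl[, 1L] + n_full * bs)
      ib <- c(ib, tl[, 2L] + n_full * bs)
    }
    ld <- ld_table(snp[ia], snp[ib], r2 = rep(r^2, length(ia)))
  } else if (ld_table) {
    ld <- ld_table(character(), character(), numeric())
  }

  list(s1 = s1, s2 = s2, truth = truth, ld = ld)
}

#' Simulate an expression matrix with planted eQTL and group effects
#'
#' Generates a genes x samples matrix for a two-group design with samples
#' assigned round-robin to three brain regions, per-gene genotype dosages
#' `~ Binomial(2, maf)`, and expression
#' `baseline + eqtl_slope * dosage + de_shift * group + N(0, noise_sd)`.
#' Fractions `prop_eqtl` / `prop_de` of genes carry the eQTL / group effect;
#' the truth record marks which.
#'
#' @param n_samples Samples per group; a scalar for balanced groups or a
#'   length-2 vector (e.g. `c(11, 17)` for an 11-control / 17-case cohort).
#' @param n_genes Number of genes.
#' @param eqtl_slope Additive expression change per dosage unit.
#' @param de_shift Mean shift of the second group.
#' @param noise_sd Residual s.d.
#' @param maf Minor-allele frequency of the simulated dosages.
#' @param prop_eqtl,prop_de Fractions of genes carrying each effect.
#' @param group_labels Two group labels; the shift applies to the second.
#' @param seed Integer seed.
#' @return A list with `mat` (an [expression_matrix()]), `dosage` (genes x
#'   samples integer matrix), and `truth` (data.table `gene, is_eqtl, is_de`).
#' @export
simulate_expression <- function(n_samples = 14L, n_genes = 100L,
                                eqtl_slope = 0, de_shift = 0, noise_sd = 1,
                                maf = 0.3, prop_eqtl = 1, prop_de = 1,
                                group_labels = c("control", "FTD-U"),
                                seed = 1L) {
  n_samples <- rep(as.integer(n_samples), length.out = 2L)
  stopifnot(all(n_samples >= 2L), n_genes >= 2L)
  set.seed(seed)
  n_tot <- sum(n_samples)
  genes <- sprintf("gene%03d", seq_len(n_genes))
  group <- rep(group_labels, times = n_samples)
  region <- rep_len(c("frontal", "hippocampus", "cerebellum"), n_tot)

  is_eqtl <- seq_len(n_genes) <= round(prop_eqtl * n_genes)
  is_de <- seq_len(n_genes) <= round(prop_de * n_genes)

  dosage <- matrix(rbinom(n_genes * n_tot, 2L, maf), n_genes, n_tot,
                   dimnames = list(genes, NULL))
  baseline <- 5
  vals <- baseline +
    dosage * (eqtl_slope * is_eqtl) +
    outer(de_shift * is_de, as.numeric(group == group_labels[2L])) +
    matrix(rnorm(n_genes * n_tot, 0, noise_sd), n_genes, n_tot)
  dimnames(vals) <- list(genes, sprintf("s%03d", seq_len(n_tot)))

  mat <- expression_matrix(vals, group = group, region = region)
  truth <- data.table::data.table(gene = genes, is_eqtl = is_eqtl, is_de = is_de)
  list(mat = mat, dosage = dosage, truth = truth)
}

#' Published cross-trait locus table fixture
#'
#' Loads the packaged 21-row table of loci jointly associated with
#' frontotemporal dementia and immune-mediated disease at conjunction
#' FDR < 0.05 (SNP, chromosome, nearest gene, reference immune disease and
#' p-value, minimum conjunction FDR, FTD p-value, direction-of-effect pair,
#' and an extended-MHC membership flag). The one in-table LD fact — the
#' rs204989/rs204991 pair at D' = 1, r^2 = 1 — is attached as the `"ld"`
#' attribute (all other pairs are treated as unlinked).
#'
#' @return A data.table of 21 locus records with attribute `ld`
#'   (an `ld_table`).
#' @export
table2_fixture <- function() {
  path <- system.file("extdata", "ftd_immune_loci.tsv", package = "pleioconj",
                      mustWork = TRUE)
  dt <- data.table::fread(path, sep = "\t", colClasses = list(
    character = c("snp", "nearest_gene", "immune_disease", "direction")))
  dt[, `:=`(immune_p = as.numeric(immune_p),
            min_conj_fdr = as.numeric(min_conj_fdr),
            ftd_p = as.numeric(ftd_p))]
  sg <- parse_direction(dt$direction)
  dt[, `:=`(sign1 = sg[, 1L], sign2 = sg[, 2L])]
  ld <- ld_table("rs204989", "rs204991", r2 = 1, dprime = 1)
  data.table::setattr(dt, "ld", ld)
  dt[]
}
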