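#' @import data.table
#' @importFrom stats pnorm pchisq qchisq median rnorm rbinom runif complete.cases
#' @importFrom utils head
NULL

#' Canonical column dialect for summary-statistics files
#'
#' Maps internal field names to the column headers of a tab-delimited
#' summary-statistics file. Either an `or` or a `beta` column must be mapped;
#' odds ratios are log-transformed on read so that effects are always carried
#' on the log-odds scale.
#'
#' @param snp,chr,bp,a1,a2,p Column names for rsID, chromosome, position,
#'   effect allele, other allele and p-value.
#' @param or Column name holding odds ratios, or `NULL`.
#' @param beta Column name holding signed log-odds effects, or `NULL`.
#' @return A named list usable as the `dialect` argument of [read_sumstats()].
#' @export
sumstats_dialect <- function(snp = "SNP", chr = "CHR", bp = "BP",
                             a1 = "A1", a2 = "A2", p = "P",
                             or = NULL, beta = "BETA") {
  if (is.null(or) && is.null(beta))
    stop("dialect must map either an 'or' or a 'beta' column")
  list(snp = snp, chr = chr, bp = bp, a1 = a1, a2 = a2, p = p,
       or = or, beta = beta)
}

new_sumstats <- function(dt, trait, lambda = NULL, load_report = NULL) {
  data.table::setDT(dt)
  data.table::setattr(dt, "trait", trait)
  data.table::setattr(dt, "lambda", lambda)
  data.table::setattr(dt, "load_report", load_report)
  data.table::setattr(dt, "class", c("sumstats", class(dt)))
  dt
}

#' Read and validate one trait's GWAS summary statistics
#'
#' Reads a delimited text file with a header, renames columns according to
#' `dialect`, log-transforms odds ratios to signed log-odds effects, and drops
#' rows violating the record invariants: p-value outside (0, 1], missing
#' fields, identical effect/other alleles, or a duplicated rsID (the first
#' occurrence is kept). Dropped rows are counted in a load report attached as
#' the `"load_report"` attribute.
#'
#' @param path Path to a tab- (or otherwise) delimited text file.
#' @param dialect Column mapping from [sumstats_dialect()].
#' @param trait Trait label stored on the result.
#' @param sep Field separator passed to [data.table::fread()].
#' @return A `sumstats` object: a `data.table` with columns
#'   `snp, chr, bp, a1, a2, pval, beta` and attributes `trait`, `lambda`
#'   (genomic-control factor once applied) and `load_report`.
#' @export
read_sumstats <- function(path, dialect = sumstats_dialect(), trait = basename(path),
                          sep = "\t") {
  raw <- data.table::fread(path, sep = sep, header = TRUE,
                           colClasses = list(character = c(dialect$snp, dialect$chr,
                                                           dialect$a1, dialect$a2)))
  eff_col <- if (!is.null(dialect$beta) && dialect$beta %in% names(raw)) {
    dialect$beta
  } else if (!is.null(dialect$or) && dialect$or %in% names(raw)) {
    dialect$or
  } else {
    miss <- if (!is.null(dialect$beta)) dialect$beta else dialect$or
    stop("missing required column: ", miss)
  }
  need <- c(dialect$snp, dialect$chr, dialect$bp, dialect$a1, dialect$a2, dialect$p)
  absent <- setdiff(need, names(raw))
  if (length(absent))
    stop("missing required column: ", paste(absent, collapse = ", "))

  dt <- raw[, c(need, eff_col), with = FALSE]
  data.table::setnames(dt, c("snp", "chr", "bp", "a1", "a2", "pval", "beta"))
  if (identical(eff_col, dialect$or)) dt[, beta := log(beta)]
  dt[, `:=`(bp = as.numeric(bp), pval = as.numeric(pval), beta = as.numeric(beta),
            a1 = toupper(a1), a2 = toupper(a2))]

  n_in <- nrow(dt)
  ok <- complete.cases(dt[, .(snp, chr, bp, a1, a2, pval, beta)]) &
    dt$pval > 0 & dt$pval <= 1 & dt$a1 != dt$a2
  n_invalid <- sum(!ok)
  dt <- dt[ok]
  dup <- duplicated(dt$snp)       # keep first occurrence
  n_dup <- sum(dup)
  dt <- dt[!dup]
  if (nrow(dt) == 0L) stop("no valid rows in ", path)

  report <- list(n_read = n_in, n_dropped_invalid = n_invalid,
                 n_dropped_duplicate = n_dup, n_kept = nrow(dt))
  new_sumstats(dt, trait = trait, load_report = report)
}

#' Write summary statistics in the canonical dialect
#'
#' Writes tab-delimited text with columns `SNP CHR BP A1 A2 P BETA`. Writing
#' then re-reading with [read_sumstats()] reproduces the file byte-identically
#' on a second write.
#'
#' @param s A `sumstats` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(s, path) {
  out <- data.table::as.data.table(s)[, .(SNP = snp, CHR = chr, BP = bp,
                                          A1 = a1, A2 = a2, P = pval, BETA = beta)]
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}

#' Construct a sumstats object from vectors
#'
#' In-memory constructor used by the simulator and by tests.
#'
#' @param snp,chr,bp,a1,a2,pval,beta Per-variant fields.
#' @param trait Trait label.
#' @return A validated `sumstats` object.
#' @export
sumstats <- function(snp, chr, bp, a1, a2, pval, beta, trait = "trait") {
  dt <- data.table::data.table(snp = as.character(snp), chr = as.character(chr),
                               bp = as.numeric(bp), a1 = toupper(as.character(a1)),
                               a2 = toupper(as.character(a2)),
                               pval = as.numeric(pval), beta = as.numeric(beta))
  if (anyDuplicated(dt$snp)) stop("duplicate variant ids")
  if (any(dt$pval <= 0 | dt$pval > 1)) stop("p-values must lie in (0, 1]")
  if (any(dt$a1 == dt$a2)) stop("effect and other allele must differ")
  new_sumstats(dt, trait = trait)
}

is_palindromic <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

new_paired_stats <- function(dt, traits, provenance) {
  data.table::setDT(dt)
  data.table::setattr(dt, "traits", traits)
  data.table::setattr(dt, "provenance", provenance)
  data.table::setattr(dt, "class",
                      c("paired_stats", setdiff(class(dt), "paired_stats")))
  dt
}

#' Harmonize two traits' summary statistics to a common variant set
#'
#' Intersects the two sets by rsID and aligns trait 2's effect to trait 1's
#' effect allele: when trait 2's (effect, other) alleles are swapped relative
#' to trait 1, its log-odds effect is negated. Variants whose allele pairs
#' cannot be reconciled are dropped and counted, as are strand-ambiguous
#' palindromic (A/T, C/G) variants unless `drop_palindromic = FALSE`.
#' After harmonization the two effect signs are directly comparable, so
#' direction-of-effect concordance is a sign comparison.
#'
#' @param s1,s2 `sumstats` objects for the primary and secondary trait.
#' @param drop_palindromic Drop strand-ambiguous variants (default `TRUE`).
#' @return A `paired_stats` data.table with columns
#'   `snp, chr, bp, a1, a2, p1, p2, beta1, beta2` and attributes `traits`
#'   and `provenance` (intersection and drop counts). Re-harmonizing the two
#'   sides of the result is a no-op.
#' @export
harmonize_pair <- function(s1, s2, drop_palindromic = TRUE) {
  t1 <- data.table::as.data.table(s1)
  t2 <- data.table::as.data.table(s2)
  m <- merge(t1, t2, by = "snp", suffixes = c("_1", "_2"))
  if (nrow(m) == 0L) stop("no shared variants between the two traits")
  n_inter <- nrow(m)

  same <- m$a1_1 == m$a1_2 & m$a2_1 == m$a2_2
  swap <- m$a1_1 == m$a2_2 & m$a2_1 == m$a1_2
  pal <- is_palindromic(m$a1_1, m$a2_1)
  keep <- (same | swap) & !(drop_palindromic & pal)
  n_unresolved <- sum(!(same | swap))
  n_pal <- sum((same | swap) & drop_palindromic & pal)

  m <- m[keep]
  if (nrow(m) == 0L) stop("no variants survive allele harmonization")
  swap <- swap[keep]
  out <- data.table::data.table(
    snp = m$snp, chr = m$chr_1, bp = m$bp_1, a1 = m$a1_1, a2 = m$a2_1,
    p1 = m$pval_1, p2 = m$pval_2, beta1 = m$beta_1,
    beta2 = ifelse(swap, -m$beta_2, m$beta_2))
  data.table::setkey(out, snp)
  new_paired_stats(out,
                   traits = c(attr(s1, "trait"), attr(s2, "trait")),
                   provenance = list(n_intersected = n_inter,
                                     n_dropped_unresolvable = n_unresolved,
                                     n_dropped_palindromic = n_pal,
                                     n_kept = nrow(out)))
}

#' Extract one side of a harmonized pair as a sumstats object
#'
#' @param pair A `paired_stats` object.
#' @param which 1 or 2.
#' @return A `sumstats` object sharing the pair's allele coding.
#' @export
pair_side <- function(pair, which = 1L) {
  stopifnot(which %in% c(1L, 2L))
  dt <- data.table::as.data.table(pair)
  traits <- attr(pair, "traits")
  if (which == 1L)
    sumstats(dt$snp, dt$chr, dt$bp, dt$a1, dt$a2, dt$p1, dt$beta1, trait = traits[1])
  else
    sumstats(dt$snp, dt$chr, dt$bp, dt$a1, dt$a2, dt$p2, dt$beta2, trait = traits[2])
}

#' Genomic-control inflation correction
#'
#' Estimates the genomic inflation factor lambda as the median of the 1-df
#' chi-square statistics implied by the p-values divided by the median of a
#' central 1-df chi-square (`qchisq(0.5, 1)` = 0.4549). When lambda exceeds 1
#' every chi-square is deflated by lambda and the p-values are recomputed;
#' otherwise the p-values are left untouched. The estimate is stored in the
#' `"lambda"` attribute either way. Correction preserves the rank order of
#' p-values exactly.
#'
#' @param s A `sumstats` object with at least 100 variants (below that the
#'   median is unstable: a warning is issued and lambda is forced to 1).
#' @return A corrected `sumstats` object.
#' @export
genomic_correction <- function(s) {
  dt <- data.table::copy(data.table::as.data.table(s))
  if (nrow(dt) < 100L) {
    warning("fewer than 100 variants; lambda forced to 1")
    return(new_sumstats(dt, trait = attr(s, "trait"), lambda = 1,
                        load_report = attr(s, "load_report")))
  }
  chisq <- qchisq(dt$pval, df = 1, lower.tail = FALSE)
  lambda <- median(chisq) / qchisq(0.5, df = 1)
  if (lambda > 1) {
    dt[, pval := pchisq(chisq / lambda, df = 1, lower.tail = FALSE)]
    dt[pval == 0, pval := .Machine$double.xmin]
  }
  new_sumstats(dt, trait = attr(s, "trait"), lambda = lambda,
               load_report = attr(s, "load_report"))
}

#' @export
print.sumstats <- function(x, ...) {
  cat(sprintf("<sumstats> trait=%s  variants=%d  lambda=%s\n",
              attr(x, "trait"), nrow(x),
              if (is.null(attr(x, "lambda"))) "uncorrected"
              else format(attr(x, "lambda"), digits = 4)))
  NextMethod()
}

#' @export
print.paired_stats <- function(x, ...) {
  tr <- attr(x, "traits")
  cat(sprintf("<paired_stats> %s vs %s  variants=%d\n", tr[1], tr[2], nrow(x)))
  NextMethod()
}
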