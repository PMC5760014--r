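#' Expression matrix with sample annotation
#'
#' Genes x samples continuous values (assumed already normalized and on a
#' log-like scale by upstream processing) with per-sample group and region
#' labels, e.g. control / FTD-U brains sampled in frontal cortex,
#' hippocampus and cerebellum.
#'
#' @param values Numeric matrix, rows = genes (rownames required),
#'   cols = samples.
#' @param group Per-sample group labels (no missing values).
#' @param region Per-sample region labels.
#' @param covariates Optional per-sample numeric covariate data.frame.
#' @return An `expression_matrix` list.
#' @export
expression_matrix <- function(values, group, region = NULL, covariates = NULL) {
  stopifnot(is.matrix(values), !is.null(rownames(values)))
  if (anyDuplicated(rownames(values))) stop("gene identifiers must be unique")
  if (length(group) != ncol(values)) stop("one group label per sample required")
  if (anyNA(group)) stop("missing group labels")
  if (is.null(region)) region <- rep("all", ncol(values))
  structure(list(values = values, group = as.character(group),
                 region = as.character(region), covariates = covariates),
            class = "expression_matrix")
}

#' Candidate cis variant-gene pairs
#'
#' Pairs each variant with every gene whose transcription start site (the
#' interval start on the + strand, the end on the - strand) lies within
#' `window` bp on the same chromosome (inclusive bound).
#'
#' @param variants data.frame with columns `snp, chrom, pos`.
#' @param genes A [gene_annotation()] with strand.
#' @param window Cis window in bp (default 1 Mb).
#' @return data.table `snp, gene, distance` (absolute bp to TSS).
#' @export
cis_pairs <- function(variants, genes, window = 1e6) {
  v <- data.table::as.data.table(variants)
  g <- data.table::copy(data.table::as.data.table(genes))
  g[, tss := ifelse(strand == "-", end, start)]
  out <- vector("list", nrow(v))
  for (i in seq_len(nrow(v))) {
    gc <- g[chrom == v$chrom[i]]
    d <- abs(v$pos[i] - gc$tss)
    hit <- d <= window
    if (any(hit))
      out[[i]] <- data.table::data.table(snp = v$snp[i], gene = gc$name[hit],
                                         distance = d[hit])
  }
  res <- data.table::rbindlist(out)
  if (nrow(res) == 0L)
    res <- data.table::data.table(snp = character(), gene = character(),
                                  distance = numeric())
  res[]
}

#' Additive-model ANCOVA test of a cis-eQTL
#'
#' Fits `expression ~ dosage (+ covariates)` by least squares and reports
#' the dosage slope, its t statistic and two-sided p-value — the additive
#' (per-allele) genotype-expression association test, with covariates
#' adjusted as in an analysis of covariance. A perfect fit reports the
#' smallest positive double rather than p = 0.
#'
#' @param expr Per-sample expression values.
#' @param dosage Per-sample allele dosages (0/1/2).
#' @param covariates Optional numeric data.frame of per-sample covariates.
#' @return One-row data.table `slope, t, p, n, error` (`error` is a message
#'   string for degenerate fits, e.g. constant dosage, with NA statistics —
#'   flagged per pair, never fatal).
#' @export
ancova_additive <- function(expr, dosage, covariates = NULL) {
  n <- length(expr)
  k <- if (is.null(covariates)) 0L else ncol(covariates)
  bad <- NULL
  if (length(dosage) != n) bad <- "expr and dosage lengths differ"
  else if (length(unique(dosage)) < 2L) bad <- "constant dosage"
  else if (n <= k + 2L) bad <- "too few samples for covariate count"
  if (!is.null(bad))
    return(data.table::data.table(slope = NA_real_, t = NA_real_, p = NA_real_,
                                  n = n, error = bad))
  dat <- data.frame(expr = expr, dosage = dosage)
  if (k > 0L) dat <- cbind(dat, covariates)
  fit <- stats::lm(expr ~ ., data = dat)
  cf <- suppressWarnings(summary(fit))$coefficients  # perfect fits handled below
  slope <- cf["dosage", "Estimate"]
  tval <- cf["dosage", "t value"]
  p <- cf["dosage", "Pr(>|t|)"]
  if (is.nan(tval)) { # zero residual variance: perfect fit
    tval <- sign(slope) * Inf
    p <- .Machine$double.xmin
  }
  if (p == 0) p <- .Machine$double.xmin
  data.table::data.table(slope = slope, t = tval, p = p, n = n,
                         error = NA_character_)
}

#' Bonferroni significance gate for eQTL results
#'
#' Flags results passing a pre-specified Bonferroni-corrected threshold,
#' strict inequality (`p < alpha`; `p == alpha` fails).
#'
#' @param results data.table with a `p` column.
#' @param alpha Corrected threshold (default 3.9e-5).
#' @return `results` with a logical `pass` column.
#' @export
bonferroni_gate <- function(results, alpha = 3.9e-5) {
  dt <- data.table::as.data.table(results)
  dt[, pass := !is.na(p) & p < alpha]
  dt[]
}

#' Pooled-region two-group differential expression
#'
#' Pools samples across regions (treating them as independent, to maximise
#' power at small per-region sample sizes) and applies a two-sided Welch
#' two-sample t-test per gene. Genes requested but absent from the matrix
#' are reported with NA statistics ("not available"). Degenerate genes with
#' zero variance in both groups get p = 1 when the group means are equal
#' and the smallest positive double otherwise. Significance is marked at
#' `p <= 0.05`.
#'
#' @param mat An [expression_matrix()].
#' @param group_a,group_b Group labels to compare.
#' @param genes Genes to test (default: all rows of `mat`).
#' @param region_covariate If `TRUE`, fit `expression ~ group + region`
#'   instead and report the group contrast (alternative to plain pooling).
#' @return data.table `gene, statistic, p, mean_a, mean_b, significant,
#'   available`. Swapping the two groups negates the statistic and leaves
#'   p unchanged.
#' @export
differential_expression <- function(mat, group_a, group_b, genes = NULL,
                                    region_covariate = FALSE) {
  stopifnot(inherits(mat, "expression_matrix"))
  ia <- mat$group == group_a
  ib <- mat$group == group_b
  if (sum(ia) < 2L || sum(ib) < 2L)
    stop("both groups need >= 2 samples after pooling regions")
  if (is.null(genes)) genes <- rownames(mat$values)

  res <- lapply(genes, function(g) {
    if (!g %in% rownames(mat$values))
      return(data.table::data.table(gene = g, statistic = NA_real_, p = NA_real_,
                                    mean_a = NA_real_, mean_b = NA_real_,
                                    significant = NA, available = FALSE))
    xa <- mat$values[g, ia]; xb <- mat$values[g, ib]
    if (region_covariate) {
      idx <- ia | ib
      dat <- data.frame(expr = mat$values[g, idx],
                        grp = factor(mat$group[idx], levels = c(group_b, group_a)),
                        region = factor(mat$region[idx]))
      fit <- stats::lm(expr ~ grp + region, data = dat)
      cf <- summary(fit)$coefficients
      stat <- cf[2L, "t value"]; p <- cf[2L, "Pr(>|t|)"]
    } else {
      tt <- tryCatch(stats::t.test(xa, xb), error = function(e) NULL)
      if (is.null(tt)) {        # essentially constant data
        stat <- 0
        p <- if (isTRUE(all.equal(mean(xa), mean(xb)))) 1 else .Machine$double.xmin
      } else {
        stat <- unname(tt$statistic); p <- tt$p.value
      }
    }
    data.table::data.table(gene = g, statistic = stat, p = p,
                           mean_a = mean(xa), mean_b = mean(xb),
                           significant = p <= 0.05, available = TRUE)
  })
  data.table::rbindlist(res)
}

#' Canonical brain cell-type order
#'
#' The eight surveyed central-nervous-system cell classes, in the order used
#' for deterministic tie-breaking.
#'
#' @return Character vector of 9 type labels (fetal and mature astrocytes
#'   are separate classes).
#' @export
cell_type_order <- function() {
  c("neurons", "fetal astrocytes", "mature astrocytes",
    "oligodendrocyte precursor cells", "newly formed oligodendrocytes",
    "myelinating oligodendrocytes", "microglia/macrophages",
    "endothelial", "pericytes")
}

#' Assign each gene to its most-expressing brain cell type
#'
#' Per gene, the assigned class is the argmax of mean expression over cell
#' types (fragments-per-kilobase-per-million or comparable non-negative
#' units); ties are broken by the canonical order of [cell_type_order()].
#' Genes absent from the profile (or all-NA) are reported as `"not found"`.
#' The assignment is invariant to positive rescaling of a gene's row.
#'
#' @param profile Numeric matrix, rows = genes (rownames), cols = cell types
#'   (colnames from [cell_type_order()], any subset/order).
#' @param genes Genes to assign (default: all profile rows).
#' @return A list with `assignment` (data.table `gene, cell_type`) and
#'   `counts` (named integer vector of genes per assigned type, including
#'   `"not found"` when applicable).
#' @export
cell_type_assignment <- function(profile, genes = NULL) {
  stopifnot(is.matrix(profile), ncol(profile) >= 1L, !is.null(colnames(profile)))
  if (any(profile < 0, na.rm = TRUE)) stop("profile values must be >= 0")
  if (is.null(genes)) genes <- rownames(profile)
  canon <- cell_type_order()
  col_rank <- match(colnames(profile), canon)
  if (anyNA(col_rank))
    stop("unknown cell type: ",
         paste(colnames(profile)[is.na(col_rank)], collapse = ", "))

  assigned <- vapply(genes, function(g) {
    if (!g %in% rownames(profile)) return("not found")
    row <- profile[g, ]
    if (all(is.na(row))) return("not found")
    mx <- max(row, na.rm = TRUE)
    tied <- which(!is.na(row) & row == mx)
    colnames(profile)[tied[which.min(col_rank[tied])]]
  }, character(1), USE.NAMES = FALSE)

  counts <- table(factor(assigned, levels = c(canon, "not found")))
  counts <- counts[counts > 0L]
  list(assignment = data.table::data.table(gene = genes, cell_type = assigned),
       counts = counts)
}
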