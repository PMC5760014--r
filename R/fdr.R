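#' Direct empirical conditional FDR
#'
#' The conditional FDR of a primary-trait p-value `p1` given a secondary
#' p-value `p2` is estimated, with a conservative null proportion of 1, as
#' `min(1, p1 / F(p1 | p2))` where `F(p1 | p2)` is the empirical fraction of
#' variants in the stratum `{pval2 <= p2}` whose primary p-value is `<= p1`
#' (inclusive comparisons throughout). An empty stratum returns 1.
#'
#' This is the brute-force estimator used as the oracle for the binned
#' lookup; it is exact but O(m) per query.
#'
#' @param p1,p2 Query p-values in (0, 1] (recycled to a common length).
#' @param pair A [harmonize_pair()] result supplying the empirical joint
#'   distribution.
#' @return A numeric vector of conditional FDR values in \[0, 1\].
#' @export
cond_fdr_direct <- function(p1, p2, pair) {
  stopifnot(nrow(pair) > 0L)
  n <- max(length(p1), length(p2))
  p1 <- rep_len(p1, n); p2 <- rep_len(p2, n)
  pv1 <- pair$p1; pv2 <- pair$p2
  out <- numeric(n)
  for (i in seq_len(n)) {
    in_str <- pv2 <= p2[i]
    n_str <- sum(in_str)
    if (n_str == 0L) { out[i] <- 1; next }
    fhat <- sum(pv1[in_str] <= p1[i]) / n_str
    out[i] <- if (fhat == 0) 1 else min(1, p1[i] / fhat)
  }
  out
}

#' Exact per-variant conditional FDR for every variant in a pair
#'
#' Evaluates [cond_fdr_direct()] at each variant's own (p1, p2) in
#' O(m log m) with a Fenwick (binary indexed) tree sweep over p2-sorted
#' variants, counting p1 values no larger than each query. Used for null
#' calibration checks where the full per-variant direct estimate is wanted
#' without binning error.
#'
#' @param pair A `paired_stats` object.
#' @param swap If `TRUE`, condition trait 1 on trait 2 swapped (i.e. return
#'   condFDR of p2 given p1).
#' @param cap Cap the estimate at 1 (the FDR reading; default). `cap = FALSE`
#'   returns the raw ratio `p1 / F(p1 | p2)`, whose null expectation is 1 —
#'   the quantity used for calibration diagnostics.
#' @return Numeric vector aligned with `pair` rows.
#' @export
cond_fdr_snps <- function(pair, swap = FALSE, cap = TRUE) {
  p1 <- if (swap) pair$p2 else pair$p1
  p2 <- if (swap) pair$p1 else pair$p2
  m <- length(p1)
  r1 <- data.table::frank(p1, ties.method = "dense")
  nr <- max(r1)
  tree <- integer(nr)

  fen_add <- function(i) {
    while (i <= nr) { tree[i] <<- tree[i] + 1L; i <- i + bitwAnd(i, -i) }
  }
  fen_count <- function(i) {
    s <- 0L
    while (i > 0L) { s <- s + tree[i]; i <- i - bitwAnd(i, -i) }
    s
  }

  ord <- order(p2, method = "radix")
  out <- numeric(m)
  k <- 1L
  inserted <- 0L
  while (k <= m) {
    # insert the whole tie group of equal p2 before querying it (<= stratum)
    j <- k
    while (j < m && p2[ord[j + 1L]] == p2[ord[k]]) j <- j + 1L
    for (t in k:j) fen_add(r1[ord[t]])
    inserted <- inserted + (j - k + 1L)
    for (t in k:j) {
      i <- ord[t]
      fhat <- fen_count(r1[i]) / inserted
      raw <- if (fhat == 0) 1 else p1[i] / fhat
      out[i] <- if (cap) min(1, raw) else raw
    }
    k <- j + 1L
  }
  out
}

#' Build a binned two-dimensional conditional-FDR lookup table
#'
#' Bins both traits' p-values on the -log10 scale over \[0, `max_log10p`\]
#' (p floored at `10^-max_log10p`) and evaluates the direct conditional-FDR
#' estimator at every grid vertex: entry `(i, j)` is the conditional FDR of
#' `p1 = 10^-x1[i]` given the cumulative secondary stratum
#' `{pval2 <= 10^-x2[j]}`. Optional monotonization applies a running minimum
#' along each axis in the direction of increasing significance, so values
#' are non-increasing in -log10 p1 within a stratum and non-increasing with
#' stratum stringency.
#'
#' @param pair A `paired_stats` object (a warning is issued below 1,000
#'   variants, where the empirical cdf is coarse).
#' @param n_bins Number of bins per axis (>= 2); the grid has `n_bins + 1`
#'   vertices per axis.
#' @param max_log10p Upper edge on the -log10 p axis (default 20).
#' @param monotonize Apply the running-minimum monotonization (default
#'   `TRUE`).
#' @param swap Build the lookup for trait 2 given trait 1 instead.
#' @param subset Optional variant ids: the empirical cdfs are estimated on
#'   these variants only (typically a randomly LD-pruned subset from
#'   [ld_prune_random()], so each LD block contributes one observation).
#' @return An `fdr_lookup` object: list with `x1`, `x2` (vertex positions on
#'   the -log10 scale), `fdr` (matrix, rows = x1, cols = x2), `occupancy`
#'   (variants per stratum), and flags.
#' @export
build_lookup <- function(pair, n_bins = 200L, max_log10p = 20, monotonize = TRUE,
                         swap = FALSE, subset = NULL) {
  if (n_bins < 2L) stop("n_bins must be >= 2")
  use <- if (is.null(subset)) rep(TRUE, nrow(pair)) else pair$snp %in% subset
  if (sum(use) < 1000L)
    warning("fewer than 1,000 variants; conditional-FDR lookup will be noisy")
  p1 <- if (swap) pair$p2[use] else pair$p1[use]
  p2 <- if (swap) pair$p1[use] else pair$p2[use]

  x1 <- seq(0, max_log10p, length.out = n_bins + 1L)
  x2 <- x1
  q1 <- 10^(-x1)
  q2 <- 10^(-x2)

  # sort once; counts of {p <= q} via findInterval on the sorted vector
  s1 <- sort(p1)
  ord2 <- order(p2, method = "radix")
  p2s <- p2[ord2]
  p1_by_p2 <- p1[ord2]

  n_str <- findInterval(q2, p2s)          # variants with p2 <= q2[j]
  fdr <- matrix(1, nrow = n_bins + 1L, ncol = n_bins + 1L)
  for (j in seq_along(q2)) {
    ns <- n_str[j]
    if (ns == 0L) { fdr[, j] <- 1; next }
    str_p1 <- sort(p1_by_p2[seq_len(ns)])
    fh <- findInterval(q1, str_p1) / ns
    v <- ifelse(fh == 0, 1, pmin(1, q1 / fh))
    fdr[, j] <- v
  }

  if (monotonize) {
    # non-increasing along increasing -log10 p1 (rows, within each stratum)
    fdr <- apply(fdr, 2L, cummin)
    # non-increasing along increasing stratum stringency (cols)
    fdr <- t(apply(fdr, 1L, cummin))
  }

  structure(list(x1 = x1, x2 = x2, fdr = fdr, occupancy = n_str,
                 monotonized = monotonize, swap = swap,
                 n_variants = length(p1)),
            class = "fdr_lookup")
}

#' Interpolate a conditional-FDR lookup at query points
#'
#' Bilinear interpolation on the -log10 grid; queries are clamped to the
#' grid edges (no extrapolation beyond the most significant bin).
#'
#' @param lookup An [build_lookup()] result.
#' @param p1,p2 Query p-values (recycled).
#' @return Numeric vector of interpolated conditional FDR values.
#' @export
lookup_interp <- function(lookup, p1, p2) {
  n <- max(length(p1), length(p2))
  x <- pmin(pmax(-log10(rep_len(p1, n)), lookup$x1[1]), max(lookup$x1))
  y <- pmin(pmax(-log10(rep_len(p2, n)), lookup$x2[1]), max(lookup$x2))
  gx <- lookup$x1; gy <- lookup$x2
  i <- pmin(findInterval(x, gx), length(gx) - 1L)
  j <- pmin(findInterval(y, gy), length(gy) - 1L)
  wx <- (x - gx[i]) / (gx[i + 1L] - gx[i])
  wy <- (y - gy[j]) / (gy[j + 1L] - gy[j])
  f <- lookup$fdr
  f11 <- f[cbind(i, j)];     f21 <- f[cbind(i + 1L, j)]
  f12 <- f[cbind(i, j + 1L)]; f22 <- f[cbind(i + 1L, j + 1L)]
  (1 - wx) * (1 - wy) * f11 + wx * (1 - wy) * f21 +
    (1 - wx) * wy * f12 + wx * wy * f22
}

#' Conjunction FDR across two traits
#'
#' The conjunction FDR — the posterior probability that a variant is null
#' for either trait or both, given both observed p-values — is estimated per
#' variant as the maximum of the two conditional FDRs, each interpolated
#' from its binned lookup. Variants with conjunction FDR below `threshold`
#' are flagged as jointly associated.
#'
#' When an LD table is supplied, the empirical cdfs behind the lookups are
#' estimated on a randomly LD-pruned variant subset ([ld_prune_random()]):
#' without pruning, an associated LD block contributes once per variant and
#' the inflated conditional cdfs make mild joint signal look stronger than
#' one locus of evidence warrants.
#'
#' @param pair A `paired_stats` object.
#' @param lookup12 Lookup for trait 1 given trait 2 (`swap = FALSE`).
#' @param lookup21 Lookup for trait 2 given trait 1 (`swap = TRUE`). Both
#'   built from `pair`; built automatically when `NULL`.
#' @param threshold Selection threshold (default 0.05: five expected false
#'   discoveries per 100 reported).
#' @param n_bins Bin count used when lookups are built here.
#' @param ld Optional [ld_table()] enabling LD-pruned cdf estimation.
#' @param r2_thresh Pruning threshold (default 0.2).
#' @param prune_seed Seed for the random pruning scan order.
#' @return A `conj_result` data.table with columns `snp, chr, bp, p1, p2,
#'   cond_fdr1, cond_fdr2, conj_fdr, flagged`.
#' @export
conj_fdr <- function(pair, lookup12 = NULL, lookup21 = NULL, threshold = 0.05,
                     n_bins = 200L, ld = NULL, r2_thresh = 0.2, prune_seed = 1L) {
  subset <- if (!is.null(ld)) ld_prune_random(pair$snp, ld, r2_thresh, prune_seed)
  if (is.null(lookup12)) lookup12 <- build_lookup(pair, n_bins = n_bins,
                                                  subset = subset)
  if (is.null(lookup21)) lookup21 <- build_lookup(pair, n_bins = n_bins,
                                                  swap = TRUE, subset = subset)
  cf1 <- lookup_interp(lookup12, pair$p1, pair$p2)
  cf2 <- lookup_interp(lookup21, pair$p2, pair$p1)
  out <- data.table::data.table(
    snp = pair$snp, chr = pair$chr, bp = pair$bp,
    p1 = pair$p1, p2 = pair$p2,
    cond_fdr1 = cf1, cond_fdr2 = cf2,
    conj_fdr = pmax(cf1, cf2))
  out[, flagged := conj_fdr < threshold]
  data.table::setattr(out, "threshold", threshold)
  data.table::setattr(out, "class", c("conj_result", class(out)))
  out[]
}

#' @export
print.fdr_lookup <- function(x, ...) {
  cat(sprintf("<fdr_lookup> %d x %d vertices on -log10 p in [0, %g]%s, %d variants\n",
              length(x$x1), length(x$x2), max(x$x1),
              if (x$monotonized) ", monotonized" else "", x$n_variants))
  invisible(x)
}
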