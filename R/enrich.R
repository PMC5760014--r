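#' Stratified fold-enrichment curve
#'
#' Measures pleiotropic enrichment of the primary trait as a function of
#' secondary-trait association: for a threshold grid `t` on -log10 p1 and
#' cumulative secondary strata `{-log10 p2 >= c}`, the fold enrichment is
#'
#'   `FE(t, c) = Pr(-log10 p1 >= t | stratum c) / Pr(-log10 p1 >= t)`
#'
#' i.e. the tail fraction within the stratum relative to the tail fraction
#' over all variants. The all-variant baseline (`c = 0`) is identically 1;
#' an upward deflection with increasing `c` indicates shared signal. The
#' grid is capped below the genome-wide significance point (-log10 p = 7.3
#' by default) to focus on sub-threshold polygenic signal. Grid points where
#' the all-variant tail is empty are marked undefined; an empty stratum
#' yields a flagged all-`NA` curve rather than an error.
#'
#' @param pair A `paired_stats` object (inflation-corrected upstream).
#' @param strata Secondary-trait cutoffs on -log10 p2 (default 0:3).
#' @param grid Thresholds on -log10 p1 (default 301 points on \[0, 7.3\]).
#' @return An `enrichment_curve`: a long data.table with columns
#'   `t, stratum, fe, n_tail, n_stratum, defined`, and attributes `strata`,
#'   `grid`, `max_fe` (named per-stratum maxima over defined points) and
#'   `empty_strata`.
#' @export
fold_enrichment <- function(pair, strata = c(0, 1, 2, 3),
                            grid = seq(0, 7.3, length.out = 301)) {
  stopifnot(nrow(pair) > 0L)
  x1 <- -log10(pair$p1)
  x2 <- -log10(pair$p2)
  m <- length(x1)

  tail_frac <- function(x, t_grid) {
    # fraction with x >= t for each t; counts via sorted vector
    xs <- sort(x)
    n_ge <- length(xs) - findInterval(t_grid, xs, left.open = TRUE)
    n_ge
  }

  base_tail <- tail_frac(x1, grid)
  out <- vector("list", length(strata))
  for (k in seq_along(strata)) {
    c_k <- strata[k]
    in_str <- x2 >= c_k
    n_str <- sum(in_str)
    if (n_str == 0L) {
      out[[k]] <- data.table::data.table(t = grid, stratum = c_k, fe = NA_real_,
                                         n_tail = 0L, n_stratum = 0L,
                                         defined = FALSE)
      next
    }
    str_tail <- tail_frac(x1[in_str], grid)
    defined <- base_tail > 0L
    fe <- ifelse(defined, (str_tail / n_str) / (base_tail / m), NA_real_)
    out[[k]] <- data.table::data.table(t = grid, stratum = c_k, fe = fe,
                                       n_tail = str_tail, n_stratum = n_str,
                                       defined = defined)
  }
  curve <- data.table::rbindlist(out)
  max_fe <- vapply(strata, function(c_k)
    suppressWarnings(max(curve[stratum == c_k & defined == TRUE, fe], na.rm = TRUE)),
    numeric(1))
  max_fe[!is.finite(max_fe)] <- NA_real_
  names(max_fe) <- as.character(strata)
  data.table::setattr(curve, "strata", strata)
  data.table::setattr(curve, "grid", grid)
  data.table::setattr(curve, "max_fe", max_fe)
  data.table::setattr(curve, "empty_strata",
                      strata[vapply(strata, function(c_k)
                        curve[stratum == c_k, all(n_stratum == 0L)], logical(1))])
  data.table::setattr(curve, "class", c("enrichment_curve", class(curve)))
  curve[]
}

#' Stratified true-discovery-rate surface
#'
#' Reads an enrichment curve in terms of the true discovery rate: within
#' each secondary stratum, the stratified Bayes FDR at threshold `t` is
#' `FDR(t, c) = p(t) / F_c(p(t))` (capped at 1), where `p(t) = 10^-t` and
#' `F_c` is the stratum's empirical cdf of the primary p-value; the TDR is
#' `1 - FDR`. Enrichment (a larger stratum cdf at fixed `t`) therefore maps
#' directly to a higher true-discovery rate.
#'
#' @param curve An [fold_enrichment()] result.
#' @param pair The `paired_stats` object the curve was built from.
#' @return A long data.table `t, stratum, fdr, tdr, n_cdf, n_stratum`.
#' @export
enrichment_to_tdr <- function(curve, pair) {
  strata <- attr(curve, "strata")
  grid <- attr(curve, "grid")
  x2 <- -log10(pair$p2)
  p_t <- 10^(-grid)
  out <- vector("list", length(strata))
  for (k in seq_along(strata)) {
    in_str <- x2 >= strata[k]
    n_str <- sum(in_str)
    if (n_str == 0L) {
      out[[k]] <- data.table::data.table(t = grid, stratum = strata[k],
                                         fdr = NA_real_, tdr = NA_real_,
                                         n_cdf = 0L, n_stratum = 0L)
      next
    }
    ps <- sort(pair$p1[in_str])
    n_cdf <- findInterval(p_t, ps)           # p1 <= p(t) within stratum
    fdr <- ifelse(n_cdf > 0L, pmin(1, p_t / (n_cdf / n_str)), 1)
    out[[k]] <- data.table::data.table(t = grid, stratum = strata[k],
                                       fdr = fdr, tdr = 1 - fdr,
                                       n_cdf = n_cdf, n_stratum = n_str)
  }
  data.table::rbindlist(out)
}

#' Re-run fold enrichment after excising a genomic region and its LD
#'
#' Removes every variant inside `region`, within `window` of its boundary,
#' or in LD (`r2 > r2_thresh`) with any removed variant — the named-region
#' sensitivity re-analysis (e.g. dropping the extended MHC to test whether
#' it drives the enrichment) — then recomputes the curve on what remains.
#'
#' @param pair A `paired_stats` object.
#' @param region A `region()` interval.
#' @param ld An `ld_table`.
#' @param window Flank distance in bp (default 1 Mb).
#' @param r2_thresh LD pruning threshold (default 0.2).
#' @inheritParams fold_enrichment
#' @return An `enrichment_curve` on the filtered pair; errors if nothing
#'   survives the exclusion.
#' @export
excluded_region_rerun <- function(pair, region, ld, window = 1e6, r2_thresh = 0.2,
                                  strata = c(0, 1, 2, 3),
                                  grid = seq(0, 7.3, length.out = 301)) {
  kept <- exclude_region_ld(pair, region, ld, window = window,
                            r2_thresh = r2_thresh)
  if (nrow(kept) == 0L) stop("region exclusion removed every variant")
  fold_enrichment(kept, strata = strata, grid = grid)
}
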