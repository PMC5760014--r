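#' Pipeline configuration
#'
#' Bundles every tunable of the end-to-end analysis. Inputs are either two
#' summary-statistics file paths (plus optional LD table path) or a
#' [sim_params()] object for a fully simulated run.
#'
#' @param sumstats1,sumstats2 Paths to the two traits' summary-statistics
#'   files (canonical dialect), or `NULL` when simulating.
#' @param ld_path Path to a 3-column LD table, or `NULL`.
#' @param sim A [sim_params()] object, or `NULL` when reading files.
#' @param dialect Column mapping for file input.
#' @param strata Fold-enrichment secondary cutoffs.
#' @param fdr_threshold Conjunction FDR selection threshold, in (0, 1).
#' @param n_bins Lookup bins per axis.
#' @param r2_thresh Clumping / exclusion LD threshold, in \[0, 1\].
#' @param window Region-exclusion flank in bp (>= 0).
#' @param exclude Optional named [region()] triggering the exclusion rerun.
#' @param out_dir Output directory.
#' @param seed Integer seed recorded in the manifest.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(sumstats1 = NULL, sumstats2 = NULL, ld_path = NULL,
                            sim = NULL, dialect = sumstats_dialect(),
                            strata = c(0, 1, 2, 3), fdr_threshold = 0.05,
                            n_bins = 200L, r2_thresh = 0.2, window = 1e6,
                            exclude = NULL, out_dir = tempfile("pleioconj_run_"),
                            seed = 1L) {
  if (is.null(sim) && (is.null(sumstats1) || is.null(sumstats2)))
    stop("provide either two sumstats paths or a sim_params object")
  if (fdr_threshold <= 0 || fdr_threshold >= 1)
    stop("fdr_threshold must lie in (0, 1)")
  if (r2_thresh < 0 || r2_thresh > 1) stop("r2_thresh must lie in [0, 1]")
  if (window < 0) stop("window must be >= 0")
  structure(list(sumstats1 = sumstats1, sumstats2 = sumstats2, ld_path = ld_path,
                 sim = sim, dialect = dialect, strata = strata,
                 fdr_threshold = fdr_threshold, n_bins = as.integer(n_bins),
                 r2_thresh = r2_thresh, window = window, exclude = exclude,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
}

#' Run the full cross-trait pleiotropy pipeline
#'
#' Executes read/simulate -> genomic-control correction -> harmonization ->
#' stratified fold enrichment -> conditional/conjunction FDR -> LD clumping
#' of flagged loci -> locus report, plus the optional region-exclusion
#' enrichment rerun. All tables are written tab-delimited under
#' `config$out_dir` together with a JSON manifest carrying the
#' configuration, seed and an md5 checksum per output; rerunning the same
#' configuration reproduces every table byte-identically.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the run directory, the locus report, the
#'   enrichment curve(s), the conjunction FDR table and the manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  ld <- NULL
  if (!is.null(config$sim)) {
    sim <- run_stage("simulate", simulate_pair(config$sim))
    s1 <- sim$s1; s2 <- sim$s2; ld <- sim$ld
  } else {
    s1 <- run_stage("read", read_sumstats(config$sumstats1, config$dialect,
                                          trait = "trait1"))
    s2 <- run_stage("read", read_sumstats(config$sumstats2, config$dialect,
                                          trait = "trait2"))
    if (!is.null(config$ld_path))
      ld <- run_stage("read", read_ld_table(config$ld_path))
  }

  s1 <- run_stage("correct", genomic_correction(s1))
  s2 <- run_stage("correct", genomic_correction(s2))
  pair <- run_stage("harmonize", harmonize_pair(s1, s2))

  curve <- run_stage("enrich", fold_enrichment(pair, strata = config$strata))
  conj <- run_stage("conjfdr", conj_fdr(pair, threshold = config$fdr_threshold,
                                        n_bins = config$n_bins, ld = ld,
                                        r2_thresh = config$r2_thresh,
                                        prune_seed = config$seed))

  flagged <- conj[conj$flagged, ]
  records <- data.table::data.table(snp = flagged$snp, chr = flagged$chr,
                                    bp = flagged$bp, conj_fdr = flagged$conj_fdr,
                                    p1 = flagged$p1,
                                    sign1 = sign(pair[match(flagged$snp, pair$snp), beta1]),
                                    sign2 = sign(pair[match(flagged$snp, pair$snp), beta2]))
  report <- run_stage("report",
    suppressWarnings(locus_filter_report(records, ld = ld,
                                         region = config$exclude,
                                         threshold = config$fdr_threshold,
                                         r2_thresh = config$r2_thresh)))

  curve_excl <- NULL
  if (!is.null(config$exclude))
    curve_excl <- run_stage("exclude",
      excluded_region_rerun(pair, config$exclude, ld,
                            window = config$window,
                            r2_thresh = config$r2_thresh,
                            strata = config$strata))

  paths <- c(enrichment = "enrichment.tsv", conjfdr = "conjfdr.tsv",
             loci = "loci.tsv", manhattan = "manhattan.tsv")
  f <- function(p) file.path(config$out_dir, p)
  data.table::fwrite(curve, f(paths["enrichment"]), sep = "\t")
  data.table::fwrite(conj, f(paths["conjfdr"]), sep = "\t")
  data.table::fwrite(report$survivors, f(paths["loci"]), sep = "\t")
  data.table::fwrite(manhattan_table(conj, lead = report$survivors$snp),
                     f(paths["manhattan"]), sep = "\t")
  if (!is.null(curve_excl)) {
    paths <- c(paths, exclusion = "enrichment_excluded.tsv")
    data.table::fwrite(curve_excl, f("enrichment_excluded.tsv"), sep = "\t")
  }

  cfg_json <- jsonlite::toJSON(config[setdiff(names(config), "dialect")],
                               auto_unbox = TRUE, null = "null", force = TRUE)
  manifest <- list(
    config = jsonlite::fromJSON(cfg_json),
    config_hash = unname(md5_string(as.character(cfg_json))),
    seed = if (!is.null(config$sim)) config$sim$seed else config$seed,
    lambda = c(attr(s1, "lambda"), attr(s2, "lambda")),
    n_variants = nrow(pair),
    counts = report[c("n_input", "n_discordant", "n_pruned", "n_surviving")],
    outputs = vapply(paths, function(p) unname(tools::md5sum(f(p))), character(1)))
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE,
                              null = "null"),
             f("manifest.json"))

  invisible(list(out_dir = config$out_dir, report = report, curve = curve,
                 curve_excluded = curve_excl, conj = conj, manifest = manifest))
}

md5_string <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(x, tf)
  tools::md5sum(tf)
}
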