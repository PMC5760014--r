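#' Pairwise LD table
#'
#' A sparse symmetric map of variant pairs to squared correlation. Self
#' pairs are implicit at `r2 = 1`; symmetry is handled at query time.
#'
#' @param id_a,id_b Variant id vectors.
#' @param r2 Squared correlation per pair, in \[0, 1\].
#' @param dprime Optional D' per pair.
#' @return An `ld_table` data.table with columns `id_a, id_b, r2` (and
#'   `dprime` when supplied).
#' @export
ld_table <- function(id_a, id_b, r2, dprime = NULL) {
  stopifnot(length(id_a) == length(id_b), length(id_a) == length(r2))
  if (length(r2) && (any(r2 < 0) || any(r2 > 1))) stop("r2 must lie in [0, 1]")
  dt <- data.table::data.table(id_a = as.character(id_a),
                               id_b = as.character(id_b),
                               r2 = as.numeric(r2))
  if (!is.null(dprime)) dt[, dprime := as.numeric(dprime)]
  data.table::setattr(dt, "class", c("ld_table", class(dt)))
  dt[]
}

#' Read a 3-column LD table from delimited text
#'
#' @param path File with header columns `id_a, id_b, r2` (optional `dprime`).
#' @return An `ld_table`.
#' @export
read_ld_table <- function(path) {
  dt <- data.table::fread(path, colClasses = list(character = c("id_a", "id_b")))
  ld_table(dt$id_a, dt$id_b, dt$r2, dprime = if ("dprime" %in% names(dt)) dt$dprime)
}

# symmetric adjacency above a threshold, as integer indices into `ids`:
# element [[i]] holds the positions of ids[i]'s LD partners (absent = none)
ld_adjacency <- function(ld, r2_thresh, ids) {
  if (is.null(ld) || nrow(ld) == 0L) return(NULL)
  keep <- ld$r2 > r2_thresh
  if (!any(keep)) return(NULL)
  ai <- match(ld$id_a[keep], ids)
  bi <- match(ld$id_b[keep], ids)
  ok <- !is.na(ai) & !is.na(bi)
  if (!any(ok)) return(NULL)
  ai <- ai[ok]; bi <- bi[ok]
  adj <- vector("list", length(ids))
  grouped <- split(c(bi, ai), c(ai, bi))
  adj[as.integer(names(grouped))] <- grouped
  adj
}

#' Genomic interval
#'
#' 1-based inclusive interval with an optional name; the packaged default
#' region is the extended MHC.
#'
#' @param chrom Chromosome label.
#' @param start,end 1-based inclusive bounds.
#' @param name Optional region name.
#' @return A `region` list.
#' @export
region <- function(chrom, start, end, name = NA_character_) {
  stopifnot(start <= end, start >= 1)
  structure(list(chrom = as.character(chrom), start = as.numeric(start),
                 end = as.numeric(end), name = name), class = "region")
}

#' Default extended-MHC exclusion region
#'
#' chr6:25,000,000-35,000,000 (GRCh37), the conventional extended-MHC
#' interval used when excising HLA-driven signal.
#'
#' @return A [region()].
#' @export
hla_region <- function() region("6", 25e6, 35e6, name = "HLA")

#' Greedy LD-rank clumping of ranked locus records
#'
#' Scans records in rank order (ascending conjunction FDR, ties broken by
#' the primary-trait p-value, then lexicographic rsID) and prunes any record
#' in LD at `r2 > r2_thresh` with an already retained (higher-ranked)
#' record. Retained records are the lead variants, one per correlated set.
#' The result is a deterministic function of the total rank order, not of
#' input row order.
#'
#' @param records A data.table/data.frame with columns `snp`, `conj_fdr`,
#'   and `p1` (extra columns are carried through).
#' @param ld An [ld_table()] (`NULL` or empty means no pruning).
#' @param r2_thresh Pruning threshold (default 0.2).
#' @return The records in rank order with logical columns `lead` and
#'   `pruned` (`lead == !pruned`).
#' @export
ld_clump <- function(records, ld = NULL, r2_thresh = 0.2) {
  dt <- data.table::as.data.table(records)
  stopifnot(all(c("snp", "conj_fdr", "p1") %in% names(dt)))
  data.table::setorderv(dt, c("conj_fdr", "p1", "snp"))
  adj <- ld_adjacency(ld, r2_thresh, dt$snp)
  retained <- logical(nrow(dt))
  pruned <- logical(nrow(dt))
  for (i in seq_len(nrow(dt))) {
    friends <- if (is.null(adj)) NULL else adj[[i]]
    if (!is.null(friends) && any(retained[friends])) pruned[i] <- TRUE
    else retained[i] <- TRUE
  }
  dt[, `:=`(pruned = pruned, lead = !pruned)]
  dt[]
}

#' Random LD pruning to an approximately independent variant subset
#'
#' Scans variants in a seeded random order and keeps each one unless it is
#' in LD (`r2 > r2_thresh`) with an already kept variant. Used to build
#' empirical cdfs on one representative per correlated set, so that a
#' multi-variant LD block does not count once per variant. The caller's RNG
#' state is left untouched.
#'
#' @param ids Variant ids.
#' @param ld An [ld_table()].
#' @param r2_thresh LD threshold (default 0.2).
#' @param seed Seed for the scan order (default 1).
#' @return Character vector of kept ids.
#' @export
ld_prune_random <- function(ids, ld, r2_thresh = 0.2, seed = 1L) {
  if (is.null(ld) || nrow(ld) == 0L) return(ids)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  ord <- sample.int(length(ids))
  adj <- ld_adjacency(ld, r2_thresh, ids)
  if (is.null(adj)) return(ids)
  keep <- logical(length(ids))
  for (i in ord) {
    friends <- adj[[i]]
    if (is.null(friends) || !any(keep[friends])) keep[i] <- TRUE
  }
  ids[keep]
}

#' Exclude a genomic region, its flanks, and everything in LD with it
#'
#' Removes (a) variants inside `region`, (b) variants within `window` bp of
#' its boundary, and (c) variants in LD at `r2 > r2_thresh` with any variant
#' removed by (a) or (b). The removal report is attached as the
#' `"removal_report"` attribute. By construction the removed set is a
#' superset of the position-only rule.
#'
#' @param pair A `paired_stats` object.
#' @param region A [region()] on a chromosome present in `pair`.
#' @param ld An [ld_table()] (`NULL` means no LD propagation).
#' @param window Flank distance in bp (default 1 Mb).
#' @param r2_thresh LD threshold (default 0.2).
#' @return The filtered `paired_stats`.
#' @export
exclude_region_ld <- function(pair, region, ld = NULL, window = 1e6,
                              r2_thresh = 0.2) {
  stopifnot(inherits(region, "region"))
  by_pos <- pair$chr == region$chrom &
    pair$bp >= region$start - window & pair$bp <= region$end + window
  removed <- pair$snp[by_pos]
  by_ld <- logical(nrow(pair))
  if (!is.null(ld) && nrow(ld) > 0L && length(removed)) {
    keep <- ld$r2 > r2_thresh
    hit_a <- keep & (ld$id_a %in% removed)
    hit_b <- keep & (ld$id_b %in% removed)
    linked <- setdiff(unique(c(ld$id_b[hit_a], ld$id_a[hit_b])), removed)
    by_ld <- pair$snp %in% linked
  }
  drop <- by_pos | by_ld
  out <- pair[!drop]
  out <- new_paired_stats(out, traits = attr(pair, "traits"),
                          provenance = attr(pair, "provenance"))
  data.table::setattr(out, "removal_report",
                      list(n_position = sum(by_pos), n_ld = sum(by_ld),
                           n_removed = sum(drop), n_kept = nrow(out)))
  out
}

#' Parse direction-of-effect strings
#'
#' Converts strings such as `"+/-"` into sign pairs.
#'
#' @param x Character vector like `"+/+"`, `"-/+"`.
#' @return Integer matrix with columns `sign1`, `sign2` (+1/-1).
#' @export
parse_direction <- function(x) {
  parts <- strsplit(x, "/", fixed = TRUE)
  bad <- lengths(parts) != 2L
  if (any(bad)) stop("malformed direction string: ", x[which(bad)[1]])
  to_sign <- function(s) {
    s <- trimws(s)
    out <- ifelse(s == "+", 1L, ifelse(s == "-", -1L, NA_integer_))
    if (anyNA(out)) stop("direction symbols must be '+' or '-'")
    out
  }
  cbind(sign1 = to_sign(vapply(parts, `[`, "", 1L)),
        sign2 = to_sign(vapply(parts, `[`, "", 2L)))
}

#' Direction-of-effect concordance
#'
#' After allele harmonization the two traits' effect signs are directly
#' comparable; a locus is discordant when the signs differ (opposite risk
#' directions). Zero effects are classified concordant with a warning.
#'
#' @param sign1,sign2 Signed effects (any magnitude; only signs are used).
#' @return Character vector, `"concordant"` or `"discordant"`.
#' @export
direction_concordance <- function(sign1, sign2) {
  if (any(sign1 == 0 | sign2 == 0))
    warning("zero effect treated as concordant")
  ifelse(sign(sign1) * sign(sign2) < 0, "discordant", "concordant")
}

#' Gene annotation from BED-style intervals
#'
#' Reads 0-based half-open BED text (`chrom start end name [score strand]`)
#' into 1-based inclusive intervals.
#'
#' @param path BED file path (no header).
#' @return A data.table `chrom, start, end, name, strand` (1-based
#'   inclusive).
#' @export
read_bed <- function(path) {
  dt <- data.table::fread(path, header = FALSE)
  if (ncol(dt) < 4L) stop("BED file needs at least 4 columns (chrom start end name)")
  out <- data.table::data.table(chrom = as.character(dt[[1L]]),
                                start = as.numeric(dt[[2L]]) + 1,
                                end = as.numeric(dt[[3L]]),
                                name = as.character(dt[[4L]]),
                                strand = if (ncol(dt) >= 6L) as.character(dt[[6L]])
                                         else "+")
  if (anyDuplicated(out$name)) stop("gene names must be unique")
  if (any(out$start > out$end)) stop("malformed interval (start > end)")
  out
}

#' Gene annotation constructor
#'
#' @param chrom,start,end,name,strand Interval fields, 1-based inclusive.
#' @return A data.table annotation usable by [nearest_gene()] and
#'   [cis_pairs()].
#' @export
gene_annotation <- function(chrom, start, end, name, strand = "+") {
  dt <- data.table::data.table(chrom = as.character(chrom),
                               start = as.numeric(start), end = as.numeric(end),
                               name = as.character(name),
                               strand = rep_len(as.character(strand), length(name)))
  if (anyDuplicated(dt$name)) stop("gene names must be unique")
  if (any(dt$start > dt$end)) stop("malformed interval (start > end)")
  dt
}

#' Nearest gene to a genomic position
#'
#' Distance to an interval is 0 inside it, otherwise the gap to the nearer
#' bound. Ties are broken by smaller interval start, then name; a chromosome
#' with no annotated genes returns the sentinel `"none"`.
#'
#' @param chrom,pos Query position(s); recycled to a common length.
#' @param ann A [gene_annotation()] table.
#' @return Character vector of gene names.
#' @export
nearest_gene <- function(chrom, pos, ann) {
  n <- max(length(chrom), length(pos))
  chrom <- rep_len(as.character(chrom), n); pos <- rep_len(as.numeric(pos), n)
  out <- character(n)
  ann <- as.data.frame(ann)
  for (i in seq_len(n)) {
    g <- ann[ann$chrom == chrom[i], , drop = FALSE]
    if (nrow(g) == 0L) { out[i] <- "none"; next }
    d <- pmax(0, pmax(g$start - pos[i], pos[i] - g$end))
    ord <- order(d, g$start, g$name)
    out[i] <- g$name[ord[1L]]
  }
  out
}

#' Locus filter report: direction concordance then LD dedup
#'
#' Applies the post-selection locus filter to conjunction-FDR-selected
#' records: drops loci whose two effect signs disagree, then LD-clumps the
#' concordant remainder ranked by conjunction FDR (ties by primary p, then
#' rsID), and tabulates survivors overall, per chromosome of interest, and
#' within a named region when membership is available (a `in_region`
#' logical column or a [region()] plus positions).
#'
#' @param records Locus records with columns `snp, chr, conj_fdr, p1,
#'   sign1, sign2` (optional `bp`, `in_region`).
#' @param ld An [ld_table()] of known LD facts.
#' @param region Optional [region()] evaluated against `chr`/`bp` when
#'   `in_region` is absent.
#' @param threshold Conjunction FDR selection threshold (default 0.05).
#' @param r2_thresh LD pruning threshold (default 0.2).
#' @return A list: `n_input`, `n_discordant`, `n_pruned`, `n_surviving`,
#'   `n_surviving_by_chr` (named table), `n_surviving_in_region`
#'   (NA when membership is unknown), and `survivors` (data.table).
#' @export
locus_filter_report <- function(records, ld = NULL, region = NULL,
                                threshold = 0.05, r2_thresh = 0.2) {
  dt <- data.table::as.data.table(records)
  stopifnot(all(c("snp", "chr", "conj_fdr", "p1", "sign1", "sign2") %in% names(dt)))
  dt <- dt[conj_fdr < threshold]
  n_input <- nrow(dt)
  conc <- direction_concordance(dt$sign1, dt$sign2)
  n_disc <- sum(conc == "discordant")
  dt <- dt[conc == "concordant"]
  clumped <- ld_clump(dt, ld = ld, r2_thresh = r2_thresh)
  n_pruned <- sum(clumped$pruned)
  surv <- clumped[lead == TRUE]

  in_region <- if ("in_region" %in% names(surv)) {
    surv$in_region
  } else if (!is.null(region) && "bp" %in% names(surv)) {
    surv$chr == region$chrom & surv$bp >= region$start & surv$bp <= region$end
  } else NULL

  list(n_input = n_input,
       n_discordant = n_disc,
       n_pruned = n_pruned,
       n_surviving = nrow(surv),
       n_surviving_by_chr = table(surv$chr),
       n_surviving_in_region = if (is.null(in_region)) NA_integer_
                               else sum(in_region),
       survivors = surv)
}

#' Manhattan-ready conjunction FDR table
#'
#' @param conj A [conj_fdr()] result.
#' @param lead Optional character vector of lead rsIDs to flag.
#' @return data.table `snp, chr, bp, neglog10_conj_fdr, lead`.
#' @export
manhattan_table <- function(conj, lead = character()) {
  data.table::data.table(snp = conj$snp, chr = conj$chr, bp = conj$bp,
                         neglog10_conj_fdr = -log10(pmax(conj$conj_fdr, 1e-300)),
                         lead = conj$snp %in% lead)
}
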