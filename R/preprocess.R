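#' Remove features of mitochondrial or chloroplast origin
#'
#' Drops every feature whose lineage contains "mitochondria" or "chloroplast"
#' (case-insensitive, any rank) and reports the per-sample fraction of
#' sequences removed. 16S surveys of food-contact surfaces routinely carry
#' large organellar fractions (cutting boards especially), so the report is
#' worth inspecting before trusting downstream compositions.
#'
#' @param counts samples x features count matrix.
#' @param taxonomy tibble with `feature_id` and the seven rank columns.
#' @param keep_unknown keep features that have no taxonomy row (default:
#'   error).
#' @return list with `counts` (filtered matrix), `report` (tibble:
#'   `sample_id`, `fraction_removed`), and `removed` (dropped feature ids).
#' @export
filter_organelles <- function(counts, taxonomy, keep_unknown = FALSE) {
  validate_count_table(counts)
  feats <- colnames(counts)
  known <- feats %in% taxonomy$feature_id
  if (!all(known) && !keep_unknown) {
    abort(paste0("feature(s) without lineage: ",
                 paste(utils::head(feats[!known], 10), collapse = ", "),
                 "; set keep_unknown = TRUE to keep them"))
  }
  tax <- taxonomy[match(feats[known], taxonomy$feature_id), TAXONOMIC_RANKS]
  organelle <- rep(FALSE, length(feats))
  organelle[known] <- apply(tax, 1, function(r) {
    any(grepl("mitochondria|chloroplast", r, ignore.case = TRUE))
  })
  removed_counts <- if (any(organelle)) {
    rowSums(counts[, organelle, drop = FALSE])
  } else rep(0, nrow(counts))
  totals <- rowSums(counts)
  frac <- unname(ifelse(totals > 0, removed_counts / totals, 0))
  kept <- counts[, !organelle, drop = FALSE]
  emptied <- rowSums(kept) == 0 & totals > 0
  if (any(emptied)) {
    abort(paste0("sample(s) emptied by organelle removal: ",
                 paste(rownames(counts)[emptied], collapse = ", ")))
  }
  list(counts = kept,
       report = tibble(sample_id = rownames(counts), fraction_removed = frac),
       removed = feats[organelle])
}

#' Remove low-count and single-sample features
#'
#' Drops features whose grand total is below `min_total` or that are present
#' (count > 0) in fewer than `min_samples` samples. Samples are never dropped
#' here.
#'
#' @param counts samples x features count matrix.
#' @param min_total minimum grand total to keep a feature (default 10).
#' @param min_samples minimum number of samples with a nonzero count
#'   (default 2).
#' @return filtered count matrix.
#' @export
filter_low_count <- function(counts, min_total = 10, min_samples = 2) {
  validate_count_table(counts)
  if (min_total < 0 || min_samples < 0) abort("thresholds must be >= 0")
  keep <- colSums(counts) >= min_total & colSums(counts > 0) >= min_samples
  counts[, keep, drop = FALSE]
}

#' Collapse features to a taxonomic level
#'
#' Features sharing the same lineage prefix through `level` are summed. The
#' grouping key (and resulting feature identifier) is the full
#' semicolon-joined prefix, so identically named genera in different families
#' never merge. Features unassigned below some rank keep the explicit
#' `"unassigned"` labels in their key: a feature known only to family level
#' therefore collapses to a family-level taxon, which is why genus-level
#' (L6) tables from such data mix genera and families. Display names (the
#' deepest assigned rank) are attached as the `"display_name"` attribute and
#' retrievable with [taxon_display_names()].
#'
#' @param counts samples x features count matrix.
#' @param taxonomy tibble with `feature_id` and the seven rank columns.
#' @param level rank depth to collapse to, 1 (domain) .. 7 (species);
#'   default 6 (genus).
#' @return samples x taxa count matrix; grand total is conserved exactly.
#' @export
collapse_taxonomy <- function(counts, taxonomy, level = 6) {
  validate_count_table(counts)
  if (!(level %in% 1:7)) abort("level must be in 1..7")
  tax <- taxonomy_for(taxonomy, colnames(counts))
  pref <- as.matrix(tax[, TAXONOMIC_RANKS[seq_len(level)], drop = FALSE])
  key <- apply(pref, 1, paste, collapse = ";")
  groups <- unique(key)
  out <- matrix(0, nrow = nrow(counts), ncol = length(groups),
                dimnames = list(rownames(counts), groups))
  for (g in groups) {
    out[, g] <- rowSums(counts[, key == g, drop = FALSE])
  }
  display <- vapply(groups, function(g) {
    r <- strsplit(g, ";", fixed = TRUE)[[1]]
    assigned <- which(r != "unassigned")
    if (length(assigned) == 0) "unassigned" else r[max(assigned)]
  }, character(1))
  attr(out, "display_name") <- display
  out
}

#' @rdname collapse_taxonomy
#' @param collapsed a matrix produced by [collapse_taxonomy()].
#' @return named character vector: full lineage key -> display name.
#' @export
taxon_display_names <- function(collapsed) {
  d <- attr(collapsed, "display_name")
  if (is.null(d)) {
    d <- stats::setNames(colnames(collapsed), colnames(collapsed))
  }
  d
}

#' Convert counts to relative abundances
#'
#' @param counts samples x features matrix; every sample total must be > 0.
#' @return matrix of the same shape, each row summing to 1.
#' @export
to_relative <- function(counts) {
  validate_feature_table(counts)
  totals <- rowSums(counts)
  if (any(totals == 0)) {
    abort(paste0("sample(s) with zero total: ",
                 paste(rownames(counts)[totals == 0], collapse = ", ")))
  }
  sweep(counts, 1, totals, "/")
}

#' Rarefy a count table to fixed depth
#'
#' Samples with fewer sequences than `depth` are excluded (and listed);
#' remaining samples are subsampled without replacement (multivariate
#' hypergeometric, via [vegan::rrarefy()]) to exactly `depth`. Deterministic
#' for a fixed `seed`.
#'
#' @param counts samples x features count matrix.
#' @param depth target sequence depth (default 10000).
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @return list with `counts` (rarefied matrix) and `excluded`
#'   (character vector of dropped sample ids).
#' @export
rarefy_counts <- function(counts, depth = 10000, seed = NULL) {
  validate_count_table(counts)
  if (depth < 1) abort("depth must be >= 1")
  totals <- rowSums(counts)
  keep <- totals >= depth
  if (!any(keep)) abort("no samples retained: depth exceeds all sample totals")
  sub <- counts[keep, , drop = FALSE]
  draw <- function() {
    # suppress vegan's "observed counts" heuristic warning on tables whose
    # smallest nonzero count exceeds 1
    out <- suppressWarnings(vegan::rrarefy(sub, depth))
    storage.mode(out) <- "double"
    out
  }
  rare <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  list(counts = rare, excluded = rownames(counts)[!keep])
}

#' Abundance filter on relative abundances
#'
#' Keeps features whose arithmetic mean relative abundance across samples
#' exceeds `mean_thresh` OR whose maximum in any single sample exceeds
#' `max_thresh` (both strictly greater). Remaining values are NOT
#' renormalised.
#'
#' @param relab samples x features relative-abundance matrix.
#' @param mean_thresh mean threshold (default 0.01, i.e. 1%).
#' @param max_thresh single-sample maximum threshold (default 0.05).
#' @return filtered relative-abundance matrix.
#' @export
abundance_filter <- function(relab, mean_thresh = 0.01, max_thresh = 0.05) {
  validate_feature_table(relab, "relative-abundance table")
  if (mean_thresh < 0 || mean_thresh > 1 || max_thresh < 0 || max_thresh > 1) {
    abort("thresholds must be in [0, 1]")
  }
  keep <- colMeans(relab) > mean_thresh |
    apply(relab, 2, max) > max_thresh
  relab[, keep, drop = FALSE]
}

#' Centred log-ratio (CLR) transform
#'
#' Maps each sample's composition to log abundances centred on the sample's
#' mean log abundance, so Euclidean methods (PCA, clustering) become
#' appropriate for compositional data. Zeros must be replaced first; the
#' default strategy adds a pseudocount of half the smallest nonzero value in
#' the whole table to every cell and renormalises rows.
#'
#' @param relab samples x features relative-abundance matrix.
#' @param zero_strategy `"half_min"` (default, see above) or `"pseudocount"`
#'   (add `pseudocount` to every cell).
#' @param pseudocount value added under `zero_strategy = "pseudocount"`.
#' @return matrix of CLR values; every row sums to 0.
#' @export
clr_transform <- function(relab, zero_strategy = c("half_min", "pseudocount"),
                          pseudocount = NULL) {
  zero_strategy <- match.arg(zero_strategy)
  validate_feature_table(relab, "relative-abundance table")
  if (ncol(relab) < 2) abort("CLR is undefined for a single-feature table")
  x <- relab
  if (any(x == 0)) {
    delta <- switch(zero_strategy,
      half_min = min(x[x > 0]) / 2,
      pseudocount = {
        if (is.null(pseudocount) || pseudocount <= 0) {
          abort("pseudocount must be a positive number")
        }
        pseudocount
      })
    x <- x + delta
  }
  x <- sweep(x, 1, rowSums(x), "/")
  lx <- log(x)
  sweep(lx, 1, rowMeans(lx), "-")
}
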