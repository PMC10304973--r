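#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble
NULL

#' Canonical taxonomic ranks
#'
#' The seven ranks used throughout the package, in fixed order. Lineages are
#' always padded to these seven ranks; absent deeper ranks are stored as the
#' explicit label `"unassigned"`.
#' @export
TAXONOMIC_RANKS <- c("domain", "phylum", "class", "order", "family",
                     "genus", "species")

#' Allowed sample types and the utensil/surface category rule
#'
#' Kitchen studies of this design sample up to seven object types per
#' household. `sample_category()` maps each type to its derived category:
#' sponges and cloths are cleaning utensils, everything else is a surface.
#' @export
SAMPLE_TYPES <- c("sponge", "cloth", "sink", "cutting_board", "tap_handle",
                  "countertop", "handles")

#' @rdname SAMPLE_TYPES
#' @param sample_type character vector of sample types.
#' @return character vector, `"cleaning_utensil"` or `"surface"`.
#' @export
sample_category <- function(sample_type) {
  bad <- setdiff(unique(sample_type), SAMPLE_TYPES)
  if (length(bad) > 0) {
    abort(paste0("unknown sample type(s): ", paste(bad, collapse = ", "),
                 "; allowed: ", paste(SAMPLE_TYPES, collapse = ", ")))
  }
  ifelse(sample_type %in% c("sponge", "cloth"), "cleaning_utensil", "surface")
}

validate_feature_table <- function(counts, what = "feature table") {
  if (!is.matrix(counts)) abort(paste0(what, " must be a matrix"))
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    abort(paste0(what, " must have sample (row) and feature (column) names"))
  }
  if (anyDuplicated(rownames(counts))) abort("duplicate sample identifiers")
  if (anyDuplicated(colnames(counts))) abort("duplicate feature identifiers")
  if (nrow(counts) == 0) abort("no samples")
  if (ncol(counts) == 0) abort("no features")
  if (any(!is.finite(counts)) || any(counts < 0)) {
    abort(paste0(what, " must contain non-negative finite values"))
  }
  invisible(counts)
}

validate_value_table <- function(values, what = "value table") {
  if (!is.matrix(values)) abort(paste0(what, " must be a matrix"))
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    abort(paste0(what, " must have sample (row) and feature (column) names"))
  }
  if (anyDuplicated(rownames(values))) abort("duplicate sample identifiers")
  if (anyDuplicated(colnames(values))) abort("duplicate feature identifiers")
  if (any(!is.finite(values))) abort(paste0(what, " must be finite"))
  invisible(values)
}

validate_count_table <- function(counts) {
  validate_feature_table(counts)
  if (any(counts != round(counts))) abort("counts must be integers")
  invisible(counts)
}

#' Read a feature (sOTU) count table from TSV
#'
#' Reads a tab-separated count table in either orientation and returns the
#' canonical samples x features integer matrix. QIIME-style exports
#' (`# Constructed from biom file` comment line, `#OTU ID` header) are
#' tolerated. Identifiers are kept verbatim and compared case-sensitively.
#'
#' @param path path to a TSV file.
#' @param orientation `"features_as_rows"` (QIIME export convention) or
#'   `"samples_as_rows"`.
#' @return numeric matrix, samples in rows, features in columns.
#' @export
read_feature_table <- function(path,
                               orientation = c("features_as_rows",
                                               "samples_as_rows")) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^# ", lines)]           # biom-style comment lines
  if (length(lines) < 2) abort("no samples: file has no data rows")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1]]
  ncol_expected <- length(header)
  if (ncol_expected < 2) abort("no samples: header has no data columns")
  ids_col <- character(length(fields) - 1L)
  vals <- matrix(NA_real_, nrow = length(fields) - 1L, ncol = ncol_expected - 1L)
  for (i in seq_along(ids_col)) {
    row <- fields[[i + 1L]]
    if (length(row) != ncol_expected) {
      abort(sprintf("malformed row %d: expected %d fields, got %d",
                    i, ncol_expected, length(row)))
    }
    ids_col[i] <- row[1]
    v <- suppressWarnings(as.numeric(row[-1]))
    if (anyNA(v)) {
      j <- which(is.na(v))[1]
      abort(sprintf("cell at row '%s', column '%s' does not parse as a number",
                    row[1], header[j + 1L]))
    }
    vals[i, ] <- v
  }
  m <- vals
  rownames(m) <- ids_col
  colnames(m) <- header[-1]
  if (orientation == "features_as_rows") m <- t(m)
  if (any(m < 0) || any(m != round(m))) {
    abort("counts must be non-negative integers")
  }
  validate_count_table(m)
  m
}

#' Write a feature table as TSV
#'
#' Inverse of [read_feature_table()]: identifiers, values and ordering
#' round-trip exactly. Output is UTF-8, tab-delimited, LF-terminated.
#'
#' @param counts samples x features matrix.
#' @param path output path.
#' @param orientation orientation to write in (see [read_feature_table()]).
#' @param id_header header label for the identifier column.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(counts, path,
                                orientation = c("features_as_rows",
                                                "samples_as_rows"),
                                id_header = "#OTU ID") {
  orientation <- match.arg(orientation)
  validate_feature_table(counts)
  m <- if (orientation == "features_as_rows") t(counts) else counts
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(c(id_header, colnames(m)), collapse = "\t"), con, sep = "\n")
  body <- vapply(seq_len(nrow(m)), function(i) {
    paste(c(rownames(m)[i], format(m[i, ], scientific = FALSE, trim = TRUE)),
          collapse = "\t")
  }, character(1))
  writeLines(body, con, sep = "\n")
  invisible(path)
}

strip_rank_prefix <- function(x) {
  trimws(sub("^[a-zA-Z]__", "", trimws(x)))
}

#' Parse lineage strings into the canonical 7-rank frame
#'
#' @param lineage character vector of semicolon-delimited lineage strings
#'   (SILVA-style `d__...;p__...` prefixes or plain names).
#' @param sep rank separator within a lineage string.
#' @return tibble with one column per rank in [TAXONOMIC_RANKS]; missing or
#'   empty ranks are `"unassigned"`.
#' @export
parse_lineage <- function(lineage, sep = ";") {
  parts <- strsplit(lineage, sep, fixed = TRUE)
  rows <- lapply(parts, function(p) {
    p <- strip_rank_prefix(p)
    p[p == "" | is.na(p) | tolower(p) == "unassigned"] <- "unassigned"
    length(p) <- length(TAXONOMIC_RANKS)        # pad with NA
    p[is.na(p)] <- "unassigned"
    p
  })
  out <- do.call(rbind, rows)
  colnames(out) <- TAXONOMIC_RANKS
  as_tibble(out)
}

#' Read a taxonomy assignment table
#'
#' @param path TSV with a feature-id column and a lineage column (optional
#'   confidence column).
#' @param feature_col,lineage_col,confidence_col column names or indices.
#' @param sep separator between ranks inside the lineage string.
#' @return tibble: `feature_id`, the seven rank columns, `confidence`
#'   (NA when absent).
#' @export
read_taxonomy <- function(path, feature_col = 1, lineage_col = 2,
                          confidence_col = NULL, sep = ";") {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "")
  fid <- as.character(df[[feature_col]])
  if (anyDuplicated(fid)) {
    abort(paste0("duplicate feature id(s) in taxonomy: ",
                 paste(unique(fid[duplicated(fid)]), collapse = ", ")))
  }
  ranks <- parse_lineage(as.character(df[[lineage_col]]), sep = sep)
  conf <- if (!is.null(confidence_col)) as.numeric(df[[confidence_col]]) else NA_real_
  dplyr::bind_cols(tibble(feature_id = fid), ranks, tibble(confidence = conf))
}

#' Look up lineages for a set of features, erroring on absentees
#' @param taxonomy tibble from [read_taxonomy()] or [parse_lineage()] plus ids.
#' @param feature_ids ids that must all be present.
#' @return the matching rows, in `feature_ids` order.
#' @export
taxonomy_for <- function(taxonomy, feature_ids) {
  miss <- setdiff(feature_ids, taxonomy$feature_id)
  if (length(miss) > 0) {
    abort(paste0("feature id(s) missing from taxonomy: ",
                 paste(utils::head(miss, 10), collapse = ", "),
                 if (length(miss) > 10) sprintf(" (and %d more)", length(miss) - 10)))
  }
  taxonomy[match(feature_ids, taxonomy$feature_id), , drop = FALSE]
}

#' Read sample metadata
#'
#' Requires columns `sample_id`, `country`, `household` and `sample_type`;
#' derives `category` with [sample_category()]. Unknown sample types are
#' rejected.
#'
#' @param path TSV file.
#' @return tibble with the five metadata columns.
#' @export
read_sample_metadata <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  req <- c("sample_id", "country", "household", "sample_type")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0) {
    abort(paste0("metadata is missing required column(s): ",
                 paste(miss, collapse = ", ")))
  }
  if (anyDuplicated(df$sample_id)) abort("duplicate sample_id in metadata")
  out <- as_tibble(df[req])
  out$sample_id <- as.character(out$sample_id)
  out$category <- sample_category(out$sample_type)
  out
}

#' Write sample metadata as TSV
#' @param metadata tibble as returned by [read_sample_metadata()].
#' @param path output path.
#' @export
write_sample_metadata <- function(metadata, path) {
  utils::write.table(metadata, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8", eol = "\n")
  invisible(path)
}

check_metadata_coverage <- function(counts, metadata) {
  miss <- setdiff(rownames(counts), metadata$sample_id)
  if (length(miss) > 0) {
    abort(paste0("sample(s) without metadata: ", paste(miss, collapse = ", ")))
  }
  metadata[match(rownames(counts), metadata$sample_id), , drop = FALSE]
}

#' Read a rooted phylogenetic tree (Newick)
#'
#' @param path Newick file. The tree must be rooted, with unique tip labels.
#' @param fill_missing_lengths if `TRUE`, absent branch lengths are replaced
#'   with zero instead of raising an error.
#' @return an [ape::read.tree()] `phylo` object.
#' @export
read_phylo_tree <- function(path, fill_missing_lengths = FALSE) {
  tree <- tryCatch(ape::read.tree(path),
                   error = function(e) abort(paste0("Newick parse error: ",
                                                    conditionMessage(e))))
  if (is.null(tree)) abort("Newick parse error: no tree in file")
  validate_phylo_tree(tree, fill_missing_lengths = fill_missing_lengths)
}

#' @rdname read_phylo_tree
#' @param tree a `phylo` object to validate.
#' @export
validate_phylo_tree <- function(tree, fill_missing_lengths = FALSE) {
  if (!inherits(tree, "phylo")) abort("tree must be a 'phylo' object")
  if (anyDuplicated(tree$tip.label)) abort("tree tip labels are not unique")
  if (!ape::is.rooted(tree)) abort("tree must be rooted")
  if (is.null(tree$edge.length)) {
    if (!fill_missing_lengths) abort("tree has no branch lengths")
    tree$edge.length <- rep(0, nrow(tree$edge))
  }
  if (anyNA(tree$edge.length)) {
    if (!fill_missing_lengths) abort("tree has missing branch lengths")
    tree$edge.length[is.na(tree$edge.length)] <- 0
  }
  if (any(tree$edge.length < 0)) abort("tree has negative branch lengths")
  tree
}

#' Check that a tree covers a table's features
#'
#' Warns (listing the orphans) when tips are present in the tree but not in
#' the table; errors when table features are missing from the tree.
#' @param tree `phylo` object.
#' @param counts samples x features matrix.
#' @param error_on_missing error (default) or warn when features lack tips.
#' @return character vector of orphan tips, invisibly.
#' @export
check_tree_coverage <- function(tree, counts, error_on_missing = TRUE) {
  feats <- colnames(counts)
  missing <- setdiff(feats, tree$tip.label)
  if (length(missing) > 0) {
    msg <- paste0("feature(s) missing from tree: ",
                  paste(utils::head(missing, 10), collapse = ", "))
    if (error_on_missing) abort(msg) else warn(msg)
  }
  orphans <- setdiff(tree$tip.label, feats)
  if (length(orphans) > 0) {
    warn(paste0("tree tip(s) not present in table: ",
                paste(utils::head(orphans, 10), collapse = ", "),
                if (length(orphans) > 10)
                  sprintf(" (and %d more)", length(orphans) - 10)))
  }
  invisible(orphans)
}

#' Round half-up at a given number of decimals
#'
#' `round()` in R rounds half to even; printed report tables in this field
#' round half away from zero. Computation is always done on unrounded values;
#' this helper is for display only.
#' @param x numeric vector.
#' @param digits decimal places.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Display rounding for percentages: one decimal below 10, integer above
#' @param x percentages.
#' @export
display_pct <- function(x) {
  ifelse(abs(x) < 10, round_half_up(x, 1), round_half_up(x, 0))
}

#' Summarise a count table
#'
#' Totals and per-sample / per-feature means computed on unrounded values
#' (use [round_half_up()] for report display).
#'
#' @param counts samples x features count matrix.
#' @return one-row tibble: `n_samples`, `n_features`, `total_sequences`,
#'   `mean_per_sample`, `min_per_sample`, `max_per_sample`, `mean_per_feature`.
#' @export
dataset_summary <- function(counts) {
  validate_count_table(counts)
  rs <- rowSums(counts)
  tibble(
    n_samples = nrow(counts),
    n_features = ncol(counts),
    total_sequences = sum(counts),
    mean_per_sample = sum(counts) / nrow(counts),
    min_per_sample = min(rs),
    max_per_sample = max(rs),
    mean_per_feature = sum(counts) / ncol(counts)
  )
}

#' Write a distance matrix as square TSV
#' @param d a `dist` object with labels.
#' @param path output path.
#' @export
write_distance_matrix <- function(d, path) {
  m <- as.matrix(d)
  df <- data.frame(sample_id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8", eol = "\n")
  invisible(path)
}
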