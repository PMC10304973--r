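#' Observed features per sample
#'
#' @param counts samples x features matrix (or a single sample's vector).
#' @return named integer vector: number of features with count > 0.
#' @export
observed_features <- function(counts) {
  if (is.null(dim(counts))) return(sum(counts > 0))
  rowSums(counts > 0)
}

#' Shannon diversity per sample
#'
#' Shannon entropy of the count composition, in `base` (default 2, the
#' convention of QIIME-style alpha diversity).
#'
#' @param counts samples x features matrix (or a single sample's vector).
#' @param base logarithm base.
#' @return named numeric vector.
#' @export
shannon_index <- function(counts, base = 2) {
  m <- if (is.null(dim(counts))) matrix(counts, nrow = 1) else counts
  if (any(rowSums(m) == 0)) abort("zero-total sample: Shannon is undefined")
  h <- vegan::diversity(m, index = "shannon", base = base)
  if (is.null(dim(counts))) unname(h) else h
}

#' Faith's phylogenetic diversity per sample
#'
#' Total branch length of the minimal subtree connecting a sample's observed
#' features, including the path to the root (toggle with `include_root`).
#'
#' @param counts samples x features matrix; all observed features must be
#'   tips of `tree`.
#' @param tree rooted `phylo` object.
#' @param include_root include the root in the spanning subtree (default
#'   TRUE, the convention of phylogenetic pipelines rooted at a common
#'   outgroup).
#' @return named numeric vector of PD values.
#' @export
faith_pd <- function(counts, tree, include_root = TRUE) {
  m <- if (is.null(dim(counts))) {
    matrix(counts, nrow = 1, dimnames = list("s", names(counts)))
  } else counts
  observed <- colnames(m)[colSums(m > 0) > 0]
  missing <- setdiff(observed, tree$tip.label)
  if (length(missing) > 0) {
    abort(paste0("observed feature(s) missing from tree: ",
                 paste(utils::head(missing, 10), collapse = ", ")))
  }
  pruned <- if (length(setdiff(tree$tip.label, colnames(m))) > 0) {
    ape::keep.tip(tree, intersect(tree$tip.label, colnames(m)))
  } else tree
  res <- picante::pd(m[, pruned$tip.label, drop = FALSE], pruned,
                     include.root = include_root)
  stats::setNames(res$PD, rownames(m))
}

#' Alpha diversity with iterated rarefaction
#'
#' For each sample at or above `depth`, rarefies `iterations` times and
#' averages the metric; samples below depth are excluded and listed in the
#' `"excluded"` attribute.
#'
#' @param counts samples x features count matrix.
#' @param metric `"observed_features"`, `"shannon"` or `"faith_pd"`.
#' @param depth rarefaction depth (default 10000).
#' @param iterations number of independent rarefactions averaged (default 10).
#' @param seed integer seed for reproducibility.
#' @param tree rooted `phylo`, required for `"faith_pd"`.
#' @param base Shannon log base.
#' @return tibble: `sample_id`, `metric`, `value`, `depth`, `iterations`.
#' @export
alpha_rarefaction <- function(counts,
                              metric = c("observed_features", "shannon",
                                         "faith_pd"),
                              depth = 10000, iterations = 10, seed = NULL,
                              tree = NULL, base = 2) {
  metric <- match.arg(metric)
  if (iterations < 1) abort("iterations must be >= 1")
  if (metric == "faith_pd" && is.null(tree)) {
    abort("faith_pd requires a tree")
  }
  fn <- switch(metric,
    observed_features = function(m) observed_features(m),
    shannon = function(m) shannon_index(m, base = base),
    faith_pd = function(m) faith_pd(m, tree))
  run <- function() {
    first <- rarefy_counts(counts, depth = depth)
    acc <- fn(first$counts)
    if (iterations > 1) {
      for (i in seq_len(iterations - 1)) {
        acc <- acc + fn(rarefy_counts(counts, depth = depth)$counts)
      }
    }
    list(values = acc / iterations, excluded = first$excluded)
  }
  res <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  out <- tibble(sample_id = names(res$values), metric = metric,
                value = unname(res$values), depth = depth,
                iterations = iterations)
  attr(out, "excluded") <- res$excluded
  out
}

#' Expected observed features under rarefaction (closed form)
#'
#' The expectation of the number of features with a nonzero count after
#' subsampling a sample of total N to depth d without replacement:
#' sum over features of 1 - choose(N - n_i, d) / choose(N, d).
#'
#' @param x a single sample's count vector.
#' @param depth rarefaction depth.
#' @return expected observed-feature count.
#' @export
expected_observed_features <- function(x, depth) {
  N <- sum(x)
  if (depth > N) abort("depth exceeds the sample total")
  x <- x[x > 0]
  sum(1 - exp(lchoose(N - x, depth) - lchoose(N, depth)))
}

#' Beta diversity distance matrix
#'
#' Jaccard (presence/absence), Bray-Curtis, and unweighted / weighted
#' (non-normalised) UniFrac. Tables should be rarefied to common depth
#' first; [run_pipeline()] enforces this.
#'
#' @param counts samples x features count matrix.
#' @param metric one of `"jaccard"`, `"bray_curtis"`,
#'   `"unweighted_unifrac"`, `"weighted_unifrac"`.
#' @param tree rooted `phylo` covering all observed features (UniFrac only).
#' @param normalized normalise weighted UniFrac by its maximum (default
#'   FALSE, matching the common pipeline default).
#' @return a `dist` object with sample labels.
#' @export
beta_diversity <- function(counts,
                           metric = c("jaccard", "bray_curtis",
                                      "unweighted_unifrac",
                                      "weighted_unifrac"),
                           tree = NULL, normalized = FALSE) {
  metric <- match.arg(metric)
  validate_feature_table(counts)
  if (metric %in% c("unweighted_unifrac", "weighted_unifrac")) {
    if (is.null(tree)) abort(paste0(metric, " requires a tree"))
    observed <- colnames(counts)[colSums(counts > 0) > 0]
    missing <- setdiff(observed, tree$tip.label)
    if (length(missing) > 0) {
      abort(paste0("observed feature(s) missing from tree: ",
                   paste(utils::head(missing, 10), collapse = ", ")))
    }
    shared <- intersect(tree$tip.label, colnames(counts))
    ptree <- if (length(shared) < length(tree$tip.label)) {
      ape::keep.tip(tree, shared)
    } else tree
    ps <- phyloseq::phyloseq(
      phyloseq::otu_table(counts[, shared, drop = FALSE],
                          taxa_are_rows = FALSE),
      phyloseq::phy_tree(ptree))
    d <- phyloseq::UniFrac(ps, weighted = (metric == "weighted_unifrac"),
                           normalized = normalized)
  } else {
    d <- switch(metric,
      jaccard = vegan::vegdist(counts, method = "jaccard", binary = TRUE),
      bray_curtis = vegan::vegdist(counts, method = "bray"))
  }
  d
}

validate_distance_matrix <- function(d) {
  m <- as.matrix(d)
  if (nrow(m) != ncol(m)) abort("distance matrix must be square")
  if (max(abs(m - t(m))) > 1e-12) abort("distance matrix is not symmetric")
  if (any(diag(m) != 0)) abort("distance matrix diagonal must be zero")
  if (any(m < -1e-12)) abort("distances must be non-negative")
  m
}

sign_fix_axes <- function(scores) {
  for (j in seq_len(ncol(scores))) {
    i <- which.max(abs(scores[, j]))
    if (scores[i, j] < 0) scores[, j] <- -scores[, j]
  }
  scores
}

#' Principal-coordinate analysis
#'
#' Classical metric MDS: eigendecomposition of the double-centred -D^2/2
#' matrix. Negative eigenvalues are retained in the report but excluded from
#' the proportion-explained denominator; each axis is sign-fixed so its
#' largest-magnitude coordinate is positive.
#'
#' @param d a `dist` object (or symmetric matrix with zero diagonal).
#' @return object of class `kc_ordination`: `$scores` (tibble with
#'   `sample_id` and `Axis1..k`), `$eigenvalues`, `$prop_explained`.
#' @export
pcoa_ordination <- function(d) {
  m <- validate_distance_matrix(d)
  n <- nrow(m)
  fit <- suppressWarnings(stats::cmdscale(stats::as.dist(m), k = n - 1,
                                          eig = TRUE))
  eig <- fit$eig
  pos <- which(eig > max(eig) * 1e-10)
  pts <- fit$points[, seq_along(pos), drop = FALSE]
  pts <- sign_fix_axes(pts)
  colnames(pts) <- paste0("Axis", seq_len(ncol(pts)))
  prop <- eig[pos] / sum(eig[pos])
  structure(list(
    scores = dplyr::bind_cols(tibble(sample_id = rownames(m)),
                              as_tibble(pts)),
    eigenvalues = eig,
    prop_explained = prop,
    method = "pcoa"
  ), class = "kc_ordination")
}

#' @export
print.kc_ordination <- function(x, ...) {
  cat(sprintf("<%s ordination> %d samples, %d axes\n", x$method,
              nrow(x$scores), ncol(x$scores) - 1L))
  k <- min(3, length(x$prop_explained))
  cat("proportion explained:",
      paste0(sprintf("%.1f%%", 100 * x$prop_explained[seq_len(k)]),
             collapse = ", "),
      if (length(x$prop_explained) > k) "...", "\n")
  invisible(x)
}

#' Ordination scatter plot
#'
#' @param object a `kc_ordination`.
#' @param metadata optional sample metadata tibble (joined on `sample_id`).
#' @param colour,shape metadata column names used for aesthetics.
#' @param axes which two axes to plot.
#' @param ... unused.
#' @return a ggplot.
#' @importFrom ggplot2 autoplot
#' @exportS3Method ggplot2::autoplot
autoplot.kc_ordination <- function(object, metadata = NULL, colour = NULL,
                                   shape = NULL, axes = c(1, 2), ...) {
  df <- object$scores
  if (!is.null(metadata)) df <- dplyr::left_join(df, metadata, by = "sample_id")
  ax <- paste0("Axis", axes)
  lab <- if (object$method == "pcoa" || object$method == "pca") {
    sprintf("%s (%.1f%%)", ax, 100 * object$prop_explained[axes])
  } else ax
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data[[ax[1]]],
                                        y = .data[[ax[2]]]))
  if (!is.null(colour)) p <- p + ggplot2::aes(colour = .data[[colour]])
  if (!is.null(shape)) p <- p + ggplot2::aes(shape = .data[[shape]])
  p + ggplot2::geom_point() +
    ggplot2::labs(x = lab[1], y = lab[2]) +
    ggplot2::theme_minimal()
}

#' @export
ggplot2::autoplot

#' @rdname autoplot.kc_ordination
#' @param x a `kc_ordination`.
#' @export
plot_scores <- function(x, metadata = NULL, colour = NULL, shape = NULL,
                        axes = c(1, 2)) {
  autoplot.kc_ordination(x, metadata = metadata, colour = colour,
                         shape = shape, axes = axes)
}
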