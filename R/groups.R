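#' Per country x sample-type group means
#'
#' Averages each taxon over all samples of a given country and sample type.
#' Combinations with no samples (e.g. no sponges collected in one country)
#' are omitted, never zero-filled, and listed in `$missing`.
#'
#' @param values samples x taxa matrix (CLR values or relative abundances).
#' @param metadata sample metadata covering every sample.
#' @return a `group_mean_matrix`: `$means` (taxa x cells matrix, cell names
#'   `"country:sample_type"`), `$cells` (tibble with per-cell `n`), and
#'   `$missing` (tibble of absent combinations).
#' @export
group_means <- function(values, metadata) {
  validate_value_table(values)
  meta <- check_metadata_coverage(values, metadata)
  cell <- paste(meta$country, meta$sample_type, sep = ":")
  means <- t(rowsum(values, cell) / as.vector(table(cell)[sort(unique(cell))]))
  cells <- dplyr::count(tibble(country = meta$country,
                               sample_type = meta$sample_type,
                               cell = cell),
                        .data$country, .data$sample_type, .data$cell,
                        name = "n")
  means <- means[, cells$cell, drop = FALSE]
  all_combo <- tidyr::expand_grid(country = unique(meta$country),
                                  sample_type = unique(meta$sample_type))
  missing <- dplyr::anti_join(all_combo, cells,
                              by = c("country", "sample_type"))
  structure(list(means = means, cells = cells, missing = missing),
            class = "group_mean_matrix")
}

#' @export
print.group_mean_matrix <- function(x, ...) {
  cat(sprintf("<group means> %d taxa x %d cells (%d combinations absent)\n",
              nrow(x$means), ncol(x$means), nrow(x$missing)))
  invisible(x)
}

#' Euclidean complete-linkage clustering of a group-mean matrix
#'
#' Rows (taxa) and columns (country x sample-type cells) are clustered with
#' complete linkage on Euclidean distances; columns are standardised to zero
#' mean and unit variance first when `scale_columns = TRUE`. Labels are
#' sorted lexicographically before clustering so ties break deterministically.
#'
#' @param x a `group_mean_matrix` or a plain taxa x cells matrix.
#' @param scale_columns standardise columns before clustering (default TRUE).
#' @return list of class `kc_clustering` with `$rows` and `$cols`
#'   ([stats::hclust] objects) and the `$matrix` used.
#' @export
hierarchical_cluster <- function(x, scale_columns = TRUE) {
  m <- if (inherits(x, "group_mean_matrix")) x$means else x
  if (nrow(m) < 2 || ncol(m) < 2) abort("need at least 2 rows and 2 columns")
  if (!is.null(rownames(m))) m <- m[order(rownames(m)), , drop = FALSE]
  if (!is.null(colnames(m))) m <- m[, order(colnames(m)), drop = FALSE]
  if (scale_columns) {
    sds <- apply(m, 2, stats::sd)
    if (any(sds == 0)) {
      abort(paste0("constant column(s) cannot be scaled: ",
                   paste(colnames(m)[sds == 0], collapse = ", ")))
    }
    m <- scale(m)
  }
  rows <- stats::hclust(stats::dist(m, method = "euclidean"),
                        method = "complete")
  cols <- stats::hclust(stats::dist(t(m), method = "euclidean"),
                        method = "complete")
  structure(list(rows = rows, cols = cols, matrix = m),
            class = "kc_clustering")
}

#' Group-mean heatmap with clustered ordering
#' @param clustering a `kc_clustering` from [hierarchical_cluster()].
#' @return a ggplot tile heatmap with dendrogram leaf ordering.
#' @export
plot_group_heatmap <- function(clustering) {
  m <- clustering$matrix
  m <- m[clustering$rows$order, clustering$cols$order, drop = FALSE]
  df <- as_tibble(as.table(m), .name_repair = ~c("taxon", "cell", "value"))
  df$taxon <- factor(df$taxon, levels = rownames(m))
  df$cell <- factor(df$cell, levels = colnames(m))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cell, y = .data$taxon,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2() +
    ggplot2::labs(x = NULL, y = NULL, fill = "scaled\nmean") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Principal-component analysis of CLR values
#'
#' Column-centred SVD (no scaling). Axes are sign-fixed so the
#' largest-magnitude loading on each axis is positive.
#'
#' @param clr samples x taxa CLR matrix.
#' @return `kc_ordination` with `$scores`, `$loadings`, `$eigenvalues`
#'   (per-axis variances) and `$prop_explained`.
#' @export
pca_clr <- function(clr) {
  if (nrow(clr) < 2) abort("PCA needs at least 2 samples")
  if (ncol(clr) < 2) abort("PCA needs at least 2 taxa")
  fit <- stats::prcomp(clr, center = TRUE, scale. = FALSE)
  flip <- vapply(seq_len(ncol(fit$rotation)), function(j) {
    i <- which.max(abs(fit$rotation[, j]))
    fit$rotation[i, j] < 0
  }, logical(1))
  fit$rotation[, flip] <- -fit$rotation[, flip, drop = FALSE]
  fit$x[, flip] <- -fit$x[, flip, drop = FALSE]
  scores <- fit$x
  colnames(scores) <- paste0("Axis", seq_len(ncol(scores)))
  vars <- fit$sdev^2
  structure(list(
    scores = dplyr::bind_cols(tibble(sample_id = rownames(clr)),
                              as_tibble(scores)),
    loadings = fit$rotation,
    eigenvalues = vars,
    prop_explained = vars / sum(vars),
    method = "pca"
  ), class = "kc_ordination")
}

#' PERMANOVA on a distance matrix
#'
#' Permutational multivariate analysis of variance: pseudo-F from the
#' among/within partition of squared distances, with a permutation p-value
#' (add-one estimator for sampled permutation sets). Backed by
#' [vegan::adonis2()].
#'
#' @param d a `dist` object.
#' @param grouping factor-like vector of group labels, aligned with the
#'   distance matrix labels.
#' @param n_perm number of permutations (default 999).
#' @param seed integer seed for the permutation stream.
#' @param drop_singletons drop groups with a single sample instead of
#'   erroring.
#' @return object of class `kc_permanova`; see [tidy()] and [glance()].
#' @export
permanova <- function(d, grouping, n_perm = 999, seed = NULL,
                      drop_singletons = FALSE) {
  m <- validate_distance_matrix(d)
  grouping <- as.character(grouping)
  if (length(grouping) != nrow(m)) {
    abort("grouping length must match the distance matrix")
  }
  sizes <- table(grouping)
  if (any(sizes < 2)) {
    if (drop_singletons) {
      keep <- grouping %in% names(sizes)[sizes >= 2]
      m <- m[keep, keep, drop = FALSE]
      grouping <- grouping[keep]
      sizes <- table(grouping)
    } else {
      abort(paste0("group(s) with a single sample: ",
                   paste(names(sizes)[sizes < 2], collapse = ", "),
                   "; set drop_singletons = TRUE to drop them"))
    }
  }
  if (length(sizes) < 2) abort("need at least 2 groups")
  df <- data.frame(group = grouping)
  run <- function() vegan::adonis2(stats::as.dist(m) ~ group, data = df,
                                   permutations = n_perm)
  fit <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  structure(list(
    f = fit$F[1],
    r2 = fit$R2[1],
    p_value = fit$`Pr(>F)`[1],
    df_model = fit$Df[1],
    df_residual = fit$Df[2],
    n_perm = n_perm,
    n_samples = nrow(m),
    n_groups = length(sizes),
    table = fit
  ), class = "kc_permanova")
}

#' @export
print.kc_permanova <- function(x, ...) {
  cat(sprintf(
    "PERMANOVA: pseudo-F = %.3f, R2 = %.3f, p = %.4g (%d permutations)\n",
    x$f, x$r2, x$p_value, x$n_perm))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname permanova
#' @param x a `kc_permanova`.
#' @param ... unused.
#' @exportS3Method generics::tidy
tidy.kc_permanova <- function(x, ...) {
  tibble(term = c("group", "residual"),
         df = c(x$df_model, x$df_residual),
         statistic = c(x$f, NA_real_),
         R2 = c(x$r2, 1 - x$r2),
         p.value = c(x$p_value, NA_real_))
}

#' @rdname permanova
#' @exportS3Method generics::glance
glance.kc_permanova <- function(x, ...) {
  tibble(statistic = x$f, R2 = x$r2, p.value = x$p_value,
         n_perm = x$n_perm, n_samples = x$n_samples, n_groups = x$n_groups)
}

# vectorised one-way F statistics for every column of X given grouping g
oneway_f_stats <- function(X, g) {
  n <- nrow(X)
  k <- length(unique(g))
  ng <- as.vector(table(g)[sort(unique(g))])
  S <- rowsum(X, g)                      # k x T group sums
  grand <- colSums(X)
  ssb <- colSums(S^2 / ng) - grand^2 / n
  sst <- colSums(X^2) - grand^2 / n
  ssw <- pmax(sst - ssb, 0)
  f <- (ssb / (k - 1)) / (ssw / (n - k))
  list(f = f, ssb = ssb, sst = sst)
}

#' Screen taxa for country differences within each sample type
#'
#' For each sample type (restricted to countries contributing at least
#' `min_cell_n` samples of that type), runs a per-taxon one-way permutation
#' F-test of country on CLR values, with Benjamini-Hochberg FDR control
#' within the sample type. This permutation screen is this package's
#' substitute for rotation-test MANOVA machinery: it answers the same
#' question (which taxa differ between countries, per sample type) with a
#' self-contained permutation null. The per-sample-type percentage of
#' variance explained by country (summed across taxa) is attached as the
#' `"variance_explained"` attribute.
#'
#' @param clr samples x taxa CLR matrix.
#' @param metadata sample metadata covering every sample.
#' @param min_cell_n minimum samples per country x sample-type cell
#'   (default 5).
#' @param n_perm permutations per sample type (default 999).
#' @param seed integer seed.
#' @return tibble: `sample_type`, `taxon`, `statistic` (F), `p_value`,
#'   `q_value`, `sig_fdr05`, `sig_fdr01`.
#' @export
screen_country_effects <- function(clr, metadata, min_cell_n = 5,
                                   n_perm = 999, seed = NULL) {
  validate_value_table(clr, "CLR table")
  meta <- check_metadata_coverage(clr, metadata)
  run <- function() {
    res <- list(); varex <- list()
    for (st in unique(meta$sample_type)) {
      idx <- meta$sample_type == st
      cn_tab <- table(meta$country[idx])
      ok_countries <- names(cn_tab)[cn_tab >= min_cell_n]
      if (length(ok_countries) < 2) {
        warn(paste0("sample type '", st, "' skipped: fewer than 2 countries ",
                    "with >= ", min_cell_n, " samples"))
        next
      }
      use <- idx & meta$country %in% ok_countries
      X <- clr[use, , drop = FALSE]
      g <- meta$country[use]
      obs <- oneway_f_stats(X, g)
      exceed <- rep(0L, ncol(X))
      for (b in seq_len(n_perm)) {
        fb <- oneway_f_stats(X, sample(g))$f
        exceed <- exceed + (fb >= obs$f)
      }
      p <- (1 + exceed) / (1 + n_perm)
      q <- stats::p.adjust(p, method = "BH")
      res[[st]] <- tibble(sample_type = st, taxon = colnames(X),
                          statistic = unname(obs$f), p_value = unname(p),
                          q_value = unname(q),
                          sig_fdr05 = unname(q < 0.05),
                          sig_fdr01 = unname(q < 0.01))
      varex[[st]] <- tibble(sample_type = st,
                            pct_var_country = 100 * sum(obs$ssb) / sum(obs$sst),
                            n_samples = sum(use),
                            n_countries = length(ok_countries))
    }
    out <- dplyr::bind_rows(res)
    attr(out, "variance_explained") <- dplyr::bind_rows(varex)
    out
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Linear mixed model with a household random intercept
#'
#' Fits `response ~ country + sample_type + (1 | household)` by REML
#' ([lme4::lmer()]). Used for alpha-diversity values and for the CLR
#' abundance of individual (core) taxa; the household intercept absorbs the
#' dependence of samples taken in the same kitchen.
#'
#' @param data tibble with the response column plus `country`,
#'   `sample_type`, `household` (households must be nested in countries).
#' @param response name of the response column.
#' @return object of class `household_model`; see [tidy()], [glance()] and
#'   [marginal_means()].
#' @export
fit_household_model <- function(data, response) {
  req <- c(response, "country", "sample_type", "household")
  miss <- setdiff(req, names(data))
  if (length(miss) > 0) {
    abort(paste0("data is missing column(s): ", paste(miss, collapse = ", ")))
  }
  nest <- tapply(data$country, data$household,
                 function(x) length(unique(x)))
  if (any(nest > 1)) {
    abort(paste0("household(s) spanning multiple countries: ",
                 paste(names(nest)[nest > 1], collapse = ", ")))
  }
  if (length(unique(data$country)) < 2) abort("need >= 2 countries")
  if (length(unique(data$sample_type)) < 2) abort("need >= 2 sample types")
  df <- as.data.frame(data)
  df$.y <- df[[response]]
  fit <- lme4::lmer(.y ~ country + sample_type + (1 | household), data = df,
                    REML = TRUE)
  vc <- as.data.frame(lme4::VarCorr(fit))
  var_household <- vc$vcov[vc$grp == "household"]
  var_residual <- vc$vcov[vc$grp == "Residual"]
  structure(list(fit = fit, response = response,
                 var_household = var_household,
                 var_residual = var_residual,
                 household_share = 100 * var_household /
                   (var_household + var_residual)),
            class = "household_model")
}

#' @export
print.household_model <- function(x, ...) {
  cat(sprintf("<household mixed model> response: %s\n", x$response))
  cat(sprintf("household variance share: %.1f%% of (household + residual)\n",
              x$household_share))
  invisible(x)
}

#' @rdname fit_household_model
#' @param x a `household_model`.
#' @param ... unused.
#' @exportS3Method generics::tidy
tidy.household_model <- function(x, ...) {
  cf <- summary(x$fit)$coefficients
  tibble(term = rownames(cf), estimate = cf[, "Estimate"],
         std.error = cf[, "Std. Error"], statistic = cf[, "t value"])
}

#' @rdname fit_household_model
#' @exportS3Method generics::glance
glance.household_model <- function(x, ...) {
  tibble(var_household = x$var_household, var_residual = x$var_residual,
         household_share_pct = x$household_share,
         n_obs = stats::nobs(x$fit),
         n_households = lme4::ngrps(x$fit)[["household"]])
}

#' Estimated marginal means for a model factor
#'
#' Model-based group means over the observed design cells with equal cell
#' weights, with 95% confidence intervals.
#'
#' @param model a `household_model`.
#' @param factor `"country"` or `"sample_type"`.
#' @param level confidence level (default 0.95).
#' @return tibble: `level`, `emmean`, `se`, `lower`, `upper`.
#' @export
marginal_means <- function(model, factor = c("country", "sample_type"),
                           level = 0.95) {
  factor <- match.arg(factor)
  em <- emmeans::emmeans(model$fit, specs = factor, level = level)
  df <- as.data.frame(em)
  tibble(level = as.character(df[[factor]]), emmean = df$emmean,
         se = df$SE, lower = df$lower.CL, upper = df$upper.CL)
}
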