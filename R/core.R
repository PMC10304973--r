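#' Core-microbiota criteria
#'
#' Three filters jointly define the core: `mean` (arithmetic mean relative
#' abundance across all samples strictly above `mean_thresh`), `mean_max`
#' (mean above `meanmax_mean_thresh` OR maximum in any single sample above
#' `meanmax_max_thresh`), and `occurrence` (present, abundance > 0, in at
#' least one sample of every group — households by default). A taxon passing
#' all three is core. By construction, passing `mean` implies passing
#' `mean_max`.
#'
#' @param mean_thresh threshold for the mean criterion (default 0.01).
#' @param meanmax_mean_thresh,meanmax_max_thresh thresholds for the
#'   mean-or-max criterion (defaults 0.01 and 0.05).
#' @param group metadata column defining the occurrence units (default
#'   `"household"`).
#' @return a `core_criteria` list.
#' @export
core_criteria <- function(mean_thresh = 0.01, meanmax_mean_thresh = 0.01,
                          meanmax_max_thresh = 0.05, group = "household") {
  th <- c(mean_thresh, meanmax_mean_thresh, meanmax_max_thresh)
  if (any(th < 0 | th > 1)) abort("thresholds must be in [0, 1]")
  structure(list(mean_thresh = mean_thresh,
                 meanmax_mean_thresh = meanmax_mean_thresh,
                 meanmax_max_thresh = meanmax_max_thresh,
                 group = group),
            class = "core_criteria")
}

#' Evaluate the three core-microbiota criteria
#'
#' @param relab samples x taxa relative-abundance matrix (typically the full
#'   genus-level table, before any abundance filter).
#' @param metadata sample metadata covering every sample in `relab`.
#' @param criteria a [core_criteria()] object.
#' @return a `core_result` tibble, one row per taxon: `taxon`, `mean_relab`,
#'   `max_relab`, `pct_samples_present`, logical `passes_mean`,
#'   `passes_meanmax`, `passes_occurrence`, `is_core`, and `venn_region`
#'   (`"none"` for taxa passing nothing).
#' @export
evaluate_core_criteria <- function(relab, metadata,
                                   criteria = core_criteria()) {
  validate_feature_table(relab, "relative-abundance table")
  meta <- check_metadata_coverage(relab, metadata)
  grp <- meta[[criteria$group]]
  if (is.null(grp)) abort(paste0("metadata has no column '", criteria$group, "'"))
  if (anyNA(grp)) abort("grouping column contains missing values")
  groups <- unique(grp)
  means <- colMeans(relab)
  maxs <- apply(relab, 2, max)
  present <- relab > 0
  pct_present <- 100 * colMeans(present)
  # occurrence: every group has >= 1 sample where the taxon is present
  grp_present <- rowsum((present) * 1, grp) > 0      # groups x taxa
  occ <- colSums(grp_present) == length(groups)

  f1 <- means > criteria$mean_thresh
  f2 <- means > criteria$meanmax_mean_thresh | maxs > criteria$meanmax_max_thresh
  f3 <- occ
  stopifnot(all(!f1 | f2))   # structural: mean criterion implies mean-or-max

  region <- dplyr::case_when(
    f1 & f2 & f3 ~ "mean+mean_max+occurrence",
    f1 & f2 & !f3 ~ "mean+mean_max",
    !f1 & f2 & f3 ~ "mean_max+occurrence",
    !f1 & f2 & !f3 ~ "mean_max",
    !f1 & !f2 & f3 ~ "occurrence",
    TRUE ~ "none")

  out <- tibble(
    taxon = colnames(relab),
    mean_relab = unname(means),
    max_relab = unname(maxs),
    pct_samples_present = unname(pct_present),
    passes_mean = unname(f1),
    passes_meanmax = unname(f2),
    passes_occurrence = unname(f3),
    is_core = unname(f1 & f2 & f3),
    venn_region = region
  )
  class(out) <- c("core_result", class(out))
  attr(out, "criteria") <- criteria
  attr(out, "n_groups") <- length(groups)
  out
}

#' Venn partition of criterion membership
#'
#' Counts taxa in each of the seven regions of the three-criterion Venn
#' diagram. Because the mean criterion implies the mean-or-max criterion,
#' the `mean`-only and `mean+occurrence` regions are structurally empty;
#' they are reported (as zeros) and asserted.
#'
#' @param result a `core_result` from [evaluate_core_criteria()].
#' @return tibble: `region`, `n_taxa`.
#' @export
venn_partition <- function(result) {
  regions <- c("mean", "mean_max", "occurrence",
               "mean+mean_max", "mean+occurrence", "mean_max+occurrence",
               "mean+mean_max+occurrence")
  counts <- vapply(regions, function(r) sum(result$venn_region == r),
                   integer(1))
  # structurally empty regions never receive taxa
  stopifnot(counts[["mean"]] == 0L, counts[["mean+occurrence"]] == 0L)
  tibble(region = regions, n_taxa = unname(counts))
}

#' Occurrence and abundance summary for selected taxa
#'
#' Per taxon: mean and maximum relative abundance (percent), percentage of
#' all samples and of all households where it is present (abundance > 0),
#' and a per-country breakdown of households/samples present. Mirrors the
#' occurrence accounting used for tracking sparse, pathogen-associated taxa.
#'
#' @param table samples x taxa matrix, counts or relative abundances
#'   (converted to relative internally when rows do not sum to 1).
#' @param metadata sample metadata covering every sample.
#' @param taxa taxa to summarise (must exist in `table`).
#' @return tibble with one row per taxon; the per-country breakdown is the
#'   `by_country` list-column (tibbles with `country`,
#'   `n_households_present`, `n_households_total`, `n_samples_present`,
#'   `n_samples_total`).
#' @export
taxon_occurrence_summary <- function(table, metadata, taxa) {
  validate_feature_table(table)
  unknown <- setdiff(taxa, colnames(table))
  if (length(unknown) > 0) {
    abort(paste0("unknown taxon(a): ", paste(unknown, collapse = ", ")))
  }
  meta <- check_metadata_coverage(table, metadata)
  relab <- if (max(abs(rowSums(table) - 1)) > 1e-6) to_relative(table) else table

  n_samples <- nrow(table)
  hh <- unique(meta$household)
  n_households <- length(hh)
  countries <- unique(meta$country)
  hh_country <- meta[!duplicated(meta$household), c("household", "country")]

  per_taxon <- lapply(taxa, function(tx) {
    pres <- relab[, tx] > 0
    hh_pres <- tapply(pres, meta$household, any)
    by_country <- dplyr::bind_rows(lapply(countries, function(cn) {
      in_cn <- meta$country == cn
      cn_hh <- hh_country$household[hh_country$country == cn]
      tibble(country = cn,
             n_households_present = sum(hh_pres[cn_hh], na.rm = TRUE),
             n_households_total = length(cn_hh),
             n_samples_present = sum(pres & in_cn),
             n_samples_total = sum(in_cn))
    }))
    tibble(
      taxon = tx,
      mean_relab_pct = 100 * mean(relab[, tx]),
      max_relab_pct = 100 * max(relab[, tx]),
      n_samples_present = sum(pres),
      pct_samples = 100 * sum(pres) / n_samples,
      n_households_present = sum(hh_pres),
      pct_households = 100 * sum(hh_pres) / n_households,
      by_country = list(by_country)
    )
  })
  out <- dplyr::bind_rows(per_taxon)
  attr(out, "n_samples") <- n_samples
  attr(out, "n_households") <- n_households
  out
}

#' Format an occurrence summary for display
#'
#' Renders [taxon_occurrence_summary()] the way report tables print it:
#' percentages half-up rounded (one decimal below 10, integers above) and
#' per-country occurrence as `"households/samples"` strings (`"0"` when
#' absent).
#'
#' @param summary tibble from [taxon_occurrence_summary()].
#' @return tibble with display columns, one per country.
#' @export
format_occurrence <- function(summary) {
  base <- dplyr::transmute(
    summary,
    taxon = .data$taxon,
    mean_relab_pct = signif(.data$mean_relab_pct, 2),
    max_relab_pct = signif(.data$max_relab_pct, 2),
    pct_samples = display_pct(.data$pct_samples),
    pct_households = display_pct(.data$pct_households)
  )
  cc <- purrr::map(summary$by_country, function(bc) {
    vals <- ifelse(bc$n_samples_present == 0, "0",
                   paste0(bc$n_households_present, "/", bc$n_samples_present))
    stats::setNames(as.list(vals), bc$country)
  })
  dplyr::bind_cols(base, dplyr::bind_rows(cc))
}

#' Core taxa summary table
#'
#' One row per core taxon with mean relative abundance (percent) and the
#' percentage of samples where it is present, sorted by descending mean.
#'
#' @param result a `core_result`.
#' @param display_names optional named vector mapping taxon ids to display
#'   names (see [taxon_display_names()]).
#' @return tibble: `taxon`, `display_name`, `mean_relab_pct`, `pct_samples`.
#' @export
core_summary <- function(result, display_names = NULL) {
  core <- dplyr::filter(result, .data$is_core)
  nm <- if (is.null(display_names)) {
    core$taxon
  } else {
    unname(display_names[core$taxon])
  }
  out <- tibble(taxon = core$taxon,
                display_name = nm,
                mean_relab_pct = 100 * core$mean_relab,
                pct_samples = core$pct_samples_present)
  dplyr::arrange(out, dplyr::desc(.data$mean_relab_pct), .data$taxon)
}

#' Venn region bar chart
#' @param result a `core_result`.
#' @return a ggplot of taxa counts per Venn region.
#' @export
plot_venn_counts <- function(result) {
  v <- venn_partition(result)
  v$region <- factor(v$region, levels = v$region)
  ggplot2::ggplot(v, ggplot2::aes(x = .data$region, y = .data$n_taxa)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "criteria passed", y = "number of taxa") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
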