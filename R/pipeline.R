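#' Pipeline configuration
#'
#' All defaults equal the analysis settings of the study design this package
#' implements: rarefaction depth 10,000 with 10 iterations for alpha
#' diversity, feature filters at total >= 10 and presence in >= 2 samples,
#' the 1% mean / 5% max abundance filter, genus-level (L6) collapse, CLR
#' with half-minimum zero replacement, and the three core criteria of
#' [core_criteria()].
#'
#' @param rarefaction_depth depth for rarefaction-based exclusion and
#'   diversity (default 10000).
#' @param alpha_iterations rarefaction iterations averaged per alpha metric.
#' @param min_total,min_samples low-count filter thresholds.
#' @param mean_thresh,max_thresh abundance-filter thresholds.
#' @param collapse_level taxonomic collapse level (6 = genus).
#' @param clr_zero_strategy zero-replacement strategy for [clr_transform()].
#' @param alpha_metrics,beta_metrics diversity metrics to compute.
#' @param criteria a [core_criteria()] object.
#' @param seed integer seed for all stochastic stages.
#' @param output_dir optional directory; when set, every stage writes its
#'   output as TSV plus a JSON provenance record.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(rarefaction_depth = 10000, alpha_iterations = 10,
                            min_total = 10, min_samples = 2,
                            mean_thresh = 0.01, max_thresh = 0.05,
                            collapse_level = 6,
                            clr_zero_strategy = "half_min",
                            alpha_metrics = c("observed_features", "shannon",
                                              "faith_pd"),
                            beta_metrics = c("jaccard", "bray_curtis",
                                             "unweighted_unifrac",
                                             "weighted_unifrac"),
                            criteria = core_criteria(),
                            seed = 1, output_dir = NULL) {
  structure(list(rarefaction_depth = rarefaction_depth,
                 alpha_iterations = alpha_iterations,
                 min_total = min_total, min_samples = min_samples,
                 mean_thresh = mean_thresh, max_thresh = max_thresh,
                 collapse_level = collapse_level,
                 clr_zero_strategy = clr_zero_strategy,
                 alpha_metrics = alpha_metrics, beta_metrics = beta_metrics,
                 criteria = criteria, seed = seed, output_dir = output_dir),
            class = "pipeline_config")
}

stage_provenance <- function(dir, stage, params, object) {
  if (is.null(dir)) return(invisible(NULL))
  rec <- list(stage = stage, params = params,
              hash = rlang::hash(object),
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(rec, file.path(dir, paste0(stage, ".provenance.json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Run the full analysis pipeline
#'
#' Executes the stages in the canonical order: organelle filter ->
#' low-count filter -> rarefaction-based sample exclusion -> genus collapse
#' -> relative abundance -> alpha/beta diversity (on the rarefied table) ->
#' abundance filter -> CLR -> core criteria -> group analyses. Any stage
#' error aborts with the stage name.
#'
#' @param counts samples x features sOTU count matrix.
#' @param taxonomy taxonomy tibble (see [read_taxonomy()]).
#' @param metadata sample metadata tibble.
#' @param tree rooted `phylo` over the features (required for phylogenetic
#'   metrics; pass `NULL` to skip them).
#' @param config a [pipeline_config()].
#' @return a `pipeline_result` list with every stage output plus `$report`,
#'   a tibble of per-stage sample/feature counts.
#' @export
run_pipeline <- function(counts, taxonomy, metadata, tree = NULL,
                         config = pipeline_config()) {
  out <- list(config = config)
  report <- list()
  dir <- config$output_dir
  if (!is.null(dir) && !dir.exists(dir)) dir.create(dir, recursive = TRUE)
  note <- function(stage, m) {
    report[[length(report) + 1]] <<- tibble(stage = stage,
                                            n_samples = nrow(m),
                                            n_features = ncol(m))
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", stage,
                    conditionMessage(e)))
    })
  }
  note("input", counts)

  org <- run_stage("organelle_filter",
                   filter_organelles(counts, taxonomy))
  out$organelle_report <- org$report
  note("organelle_filter", org$counts)
  stage_provenance(dir, "organelle_filter", list(), org$counts)

  lowc <- run_stage("low_count_filter",
                    filter_low_count(org$counts, config$min_total,
                                     config$min_samples))
  note("low_count_filter", lowc)

  rar <- run_stage("rarefaction",
                   rarefy_counts(lowc, config$rarefaction_depth,
                                 seed = config$seed))
  out$excluded_samples <- rar$excluded
  out$rarefied <- rar$counts
  note("rarefaction", rar$counts)
  # shallow samples are removed from the unrarefied table too
  retained <- lowc[rownames(rar$counts), , drop = FALSE]
  retained <- retained[, colSums(retained) > 0, drop = FALSE]
  out$counts_sotu <- retained

  l6 <- run_stage("collapse",
                  collapse_taxonomy(retained, taxonomy,
                                    config$collapse_level))
  out$counts_l6 <- l6
  note("collapse", l6)

  relab <- run_stage("relative", to_relative(l6))
  out$relab_l6 <- relab
  note("relative", relab)

  meta <- check_metadata_coverage(relab, metadata)
  out$metadata <- meta

  out$alpha <- run_stage("alpha_diversity", {
    dplyr::bind_rows(lapply(config$alpha_metrics, function(mt) {
      if (mt == "faith_pd" && is.null(tree)) return(NULL)
      alpha_rarefaction(retained, metric = mt,
                        depth = config$rarefaction_depth,
                        iterations = config$alpha_iterations,
                        seed = config$seed, tree = tree)
    }))
  })

  out$beta <- run_stage("beta_diversity", {
    res <- list()
    for (mt in config$beta_metrics) {
      if (grepl("unifrac", mt) && is.null(tree)) next
      res[[mt]] <- beta_diversity(rar$counts, metric = mt, tree = tree)
    }
    res
  })
  out$pcoa <- lapply(out$beta, pcoa_ordination)

  filt <- run_stage("abundance_filter",
                    abundance_filter(relab, config$mean_thresh,
                                     config$max_thresh))
  out$relab_filtered <- filt
  note("abundance_filter", filt)

  clr <- run_stage("clr", clr_transform(filt,
                                        zero_strategy = config$clr_zero_strategy))
  out$clr <- clr
  note("clr", clr)

  out$core <- run_stage("core_criteria",
                        evaluate_core_criteria(relab, meta, config$criteria))
  out$venn <- venn_partition(out$core)
  out$core_table <- core_summary(out$core,
                                 display_names = taxon_display_names(l6))

  out$pca <- run_stage("pca", pca_clr(clr))
  out$group_means <- run_stage("group_means", group_means(clr, meta))

  report <- dplyr::bind_rows(report)
  out$report <- report
  if (!is.null(dir)) {
    write_feature_table(l6, file.path(dir, "counts_l6.tsv"))
    utils::write.table(as.data.frame(out$core), file.path(dir, "core_result.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE, eol = "\n")
    jsonlite::write_json(as.list(stats::setNames(out$venn$n_taxa,
                                                 out$venn$region)),
                         file.path(dir, "venn_counts.json"),
                         auto_unbox = TRUE)
    utils::write.table(report, file.path(dir, "stage_report.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE, eol = "\n")
    stage_provenance(dir, "pipeline",
                     list(seed = config$seed,
                          depth = config$rarefaction_depth), out$core)
  }
  class(out) <- "pipeline_result"
  out
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline result>\n")
  print(x$report)
  cat(sprintf("core taxa: %d\n", sum(x$core$is_core)))
  invisible(x)
}
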