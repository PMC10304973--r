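#' Study design for the synthetic generator
#'
#' Describes the sampling frame the simulator emulates: five countries,
#' 14-15 households each, up to seven sample types per household with
#' type-specific inclusion probabilities (set from the observed per-type
#' sampling rates of a five-country kitchen survey), one country contributing
#' no cleaning utensils (so downstream code must handle absent
#' country x sample-type cells), and log-normal sequencing depths around
#' 50,000 reads.
#'
#' @param countries country labels.
#' @param households_per_country households simulated per country.
#' @param sample_types sample types collected.
#' @param inclusion_prob named per-type probability that a household
#'   contributes that type.
#' @param missing_cells tibble of `country`, `sample_type` combinations that
#'   are never sampled.
#' @param depth_meanlog,depth_sdlog log-normal sequencing-depth parameters.
#' @param n_taxa number of bacterial genera simulated.
#' @return a `study_design` list.
#' @export
study_design <- function(
    countries = c("France", "Hungary", "Norway", "Portugal", "Romania"),
    households_per_country = 15,
    sample_types = SAMPLE_TYPES,
    inclusion_prob = c(sponge = 0.54, cloth = 0.43, sink = 0.69,
                       cutting_board = 0.47, tap_handle = 0.72,
                       countertop = 0.72, handles = 0.51),
    missing_cells = tibble(country = "Hungary",
                           sample_type = c("sponge", "cloth")),
    depth_meanlog = log(50000), depth_sdlog = 0.6,
    n_taxa = 60) {
  if (households_per_country < 1) abort("need >= 1 household per country")
  if (!all(sample_types %in% names(inclusion_prob))) {
    abort("inclusion_prob must cover every sample type")
  }
  structure(list(countries = countries,
                 households_per_country = households_per_country,
                 sample_types = sample_types,
                 inclusion_prob = inclusion_prob[sample_types],
                 missing_cells = missing_cells,
                 depth_meanlog = depth_meanlog, depth_sdlog = depth_sdlog,
                 n_taxa = n_taxa),
            class = "study_design")
}

#' Community model for the synthetic generator
#'
#' Defines the planted community structure:
#' * `core_shares` — baseline compositional shares of the planted core
#'   genera (ubiquitous, high abundance; defaults follow the mean relative
#'   abundances reported for the eight core kitchen taxa).
#' * `common_shares` — abundant genera structurally absent from
#'   `common_absent_households` households each, so they pass abundance
#'   criteria but fail occurrence.
#' * blooms — genera at trace abundance in a minority of samples with one
#'   planted single-sample spike above the max-abundance threshold.
#' * rares — "pathogen-like" genera present in a few percent of samples at
#'   low abundance, the first of which dominates one designated sample
#'   (the 43%-in-one-sponge motif).
#' * remaining genera are fillers on a steeply decaying rank-abundance ramp
#'   (`filler_share_range`), emulating the rapid drop-off in mean abundance
#'   below the top taxa so that no filler approaches the 1% mean criterion.
#'
#' Per-sample compositions are `softmax(log baseline + country effect +
#' sample-type effect + household intercept + noise)`; counts are
#' Dirichlet-multinomial with precision `dirichlet_precision` (larger =
#' less overdispersion) at the sample's depth. Organelle (mitochondria +
#' chloroplast) contamination is injected per sample type.
#'
#' @param core_shares,common_shares baseline shares of planted core and
#'   abundant-but-not-ubiquitous genera.
#' @param common_absent_households households (per common genus) with
#'   structural absence.
#' @param n_bloom,bloom_presence_prob,bloom_base_share,bloom_spike_range
#'   bloom configuration.
#' @param n_rare,rare_presence_prob,rare_within_share,rare_dominant_share
#'   rare-taxon configuration.
#' @param filler_share_range baseline shares of the most and least abundant
#'   filler genus; intermediate fillers follow a geometric ramp.
#' @param country_effect_sd,sample_type_effect_sd,household_sd,noise_sd
#'   log-scale effect standard deviations. The household default (0.3) puts
#'   the household share of (household + residual) log-scale variance at
#'   50%, which lands the CLR-scale share — after counting noise — in the
#'   tens of percent observed for kitchen taxa.
#' @param dirichlet_precision Dirichlet-multinomial precision.
#' @param organelle_fraction named per-sample-type mean organelle fraction
#'   (cutting boards carry the most).
#' @param max_sotus_per_genus genera are split into 1..`max_sotus_per_genus`
#'   sOTU features.
#' @return a `community_model` list.
#' @export
community_model <- function(
    core_shares = c(0.342, 0.107, 0.073, 0.071, 0.055, 0.035, 0.021, 0.018),
    common_shares = c(0.023, 0.019, 0.015, 0.012),
    common_absent_households = 3,
    n_bloom = 5, bloom_presence_prob = 0.15, bloom_base_share = 5e-4,
    bloom_spike_range = c(0.08, 0.35),
    n_rare = 4, rare_presence_prob = 0.05, rare_within_share = 0.005,
    rare_dominant_share = 0.43,
    filler_share_range = c(0.003, 2e-4),
    country_effect_sd = 0.3, sample_type_effect_sd = 0.3,
    household_sd = 0.3, noise_sd = 0.3,
    dirichlet_precision = 200,
    organelle_fraction = c(sponge = 0.01, cloth = 0.01, sink = 0.01,
                           cutting_board = 0.12, tap_handle = 0.02,
                           countertop = 0.03, handles = 0.02),
    max_sotus_per_genus = 3) {
  if (any(c(country_effect_sd, sample_type_effect_sd, household_sd,
            noise_sd) < 0)) {
    abort("effect scales must be >= 0")
  }
  if (dirichlet_precision <= 0) abort("dirichlet_precision must be > 0")
  structure(list(core_shares = core_shares, common_shares = common_shares,
                 common_absent_households = common_absent_households,
                 n_bloom = n_bloom, bloom_presence_prob = bloom_presence_prob,
                 bloom_base_share = bloom_base_share,
                 bloom_spike_range = bloom_spike_range,
                 n_rare = n_rare, rare_presence_prob = rare_presence_prob,
                 rare_within_share = rare_within_share,
                 rare_dominant_share = rare_dominant_share,
                 filler_share_range = filler_share_range,
                 country_effect_sd = country_effect_sd,
                 sample_type_effect_sd = sample_type_effect_sd,
                 household_sd = household_sd, noise_sd = noise_sd,
                 dirichlet_precision = dirichlet_precision,
                 organelle_fraction = organelle_fraction,
                 max_sotus_per_genus = max_sotus_per_genus),
            class = "community_model")
}

rdirichlet_row <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  # structural zeros (alpha == 0) stay exactly zero
  g[alpha == 0] <- 0
  s <- sum(g)
  if (s == 0) abort("degenerate Dirichlet draw: all-zero alpha")
  g / s
}

#' Simulate a complete multi-country household surface study
#'
#' Generates a feature (sOTU) count table, taxonomy, sample metadata, a
#' rooted random-coalescent tree over the sOTUs, and the planted ground
#' truth. Fully deterministic given `seed`.
#'
#' @param design a [study_design()].
#' @param model a [community_model()].
#' @param seed integer seed.
#' @return a `kitchen_study` list: `counts`, `taxonomy`, `metadata`, `tree`,
#'   `truth`.
#' @export
simulate_kitchen_study <- function(design = study_design(),
                                   model = community_model(),
                                   seed = 1) {
  n_core <- length(model$core_shares)
  n_common <- length(model$common_shares)
  n_special <- n_core + n_common + model$n_bloom + model$n_rare
  if (n_special > design$n_taxa) {
    abort(sprintf("planted sets (%d taxa) exceed n_taxa (%d)",
                  n_special, design$n_taxa))
  }
  withr::with_seed(seed, simulate_kitchen_study_impl(design, model))
}

simulate_kitchen_study_impl <- function(design, model) {
  countries <- design$countries
  n_core <- length(model$core_shares)
  n_common <- length(model$common_shares)
  n_filler <- design$n_taxa - n_core - n_common - model$n_bloom - model$n_rare

  # ---- genus-level community skeleton -----------------------------------
  genus_names <- c(sprintf("Core_%02d", seq_len(n_core)),
                   sprintf("Common_%02d", seq_len(n_common)),
                   sprintf("Bloom_%02d", seq_len(model$n_bloom)),
                   sprintf("Rare_%02d", seq_len(model$n_rare)),
                   sprintf("Filler_%02d", seq_len(n_filler)))
  role <- rep(c("core", "common", "bloom", "rare", "filler"),
              c(n_core, n_common, model$n_bloom, model$n_rare, n_filler))
  # filler shares: geometric rank-abundance ramp, keeping every filler well
  # below the 1% mean criterion even after between-sample noise
  filler_shares <- if (n_filler > 0) {
    exp(seq(log(model$filler_share_range[1]),
            log(model$filler_share_range[2]), length.out = n_filler))
  } else numeric(0)
  base_share <- c(model$core_shares, model$common_shares,
                  rep(model$bloom_base_share, model$n_bloom),
                  rep(model$rare_within_share, model$n_rare),
                  filler_shares)
  base_share <- base_share / sum(base_share)
  names(base_share) <- genus_names

  # ---- design: households and samples -----------------------------------
  hh <- tibble(
    country = rep(countries, each = design$households_per_country),
    household = paste0(rep(substr(toupper(countries), 1, 2),
                           each = design$households_per_country), "_H",
                       sprintf("%02d", seq_len(design$households_per_country)))
  )
  rows <- list()
  for (i in seq_len(nrow(hh))) {
    allowed <- design$sample_types
    blocked <- design$missing_cells$sample_type[
      design$missing_cells$country == hh$country[i]]
    allowed <- setdiff(allowed, blocked)
    take <- allowed[stats::runif(length(allowed)) <
                      design$inclusion_prob[allowed]]
    if (length(take) == 0) take <- sample(allowed, 1)
    rows[[i]] <- tibble(country = hh$country[i], household = hh$household[i],
                        sample_type = take)
  }
  metadata <- dplyr::bind_rows(rows)
  metadata$sample_id <- paste0(metadata$household, "_", metadata$sample_type)
  metadata$category <- sample_category(metadata$sample_type)
  metadata <- metadata[, c("sample_id", "country", "household", "sample_type",
                           "category")]
  n_samples <- nrow(metadata)

  # ---- log-scale effects -------------------------------------------------
  n_genus <- length(genus_names)
  ceff <- matrix(stats::rnorm(length(countries) * n_genus,
                              sd = model$country_effect_sd),
                 nrow = length(countries),
                 dimnames = list(countries, genus_names))
  teff <- matrix(stats::rnorm(length(design$sample_types) * n_genus,
                              sd = model$sample_type_effect_sd),
                 nrow = length(design$sample_types),
                 dimnames = list(design$sample_types, genus_names))
  heff <- matrix(stats::rnorm(nrow(hh) * n_genus, sd = model$household_sd),
                 nrow = nrow(hh), dimnames = list(hh$household, genus_names))
  eps <- matrix(stats::rnorm(n_samples * n_genus, sd = model$noise_sd),
                nrow = n_samples,
                dimnames = list(metadata$sample_id, genus_names))

  eta <- matrix(rep(log(base_share), each = n_samples), nrow = n_samples,
                dimnames = list(metadata$sample_id, genus_names)) +
    ceff[metadata$country, , drop = FALSE] +
    teff[metadata$sample_type, , drop = FALSE] +
    heff[metadata$household, , drop = FALSE] + eps
  comp <- exp(eta)

  # ---- presence masks and planted spikes --------------------------------
  bloom_idx <- which(role == "bloom")
  rare_idx <- which(role == "rare")
  common_idx <- which(role == "common")
  for (j in bloom_idx) {
    present <- stats::runif(n_samples) < model$bloom_presence_prob
    if (!any(present)) present[sample.int(n_samples, 1)] <- TRUE
    comp[!present, j] <- 0
  }
  for (j in rare_idx) {
    present <- stats::runif(n_samples) < model$rare_presence_prob
    if (!any(present)) present[sample.int(n_samples, 1)] <- TRUE
    comp[!present, j] <- 0
  }
  # common taxa: wiped from a few whole households each
  for (j in common_idx) {
    gone <- sample(hh$household, model$common_absent_households)
    comp[metadata$household %in% gone, j] <- 0
  }
  comp <- comp / rowSums(comp)
  # single-sample blooms above the max-abundance threshold
  spikes <- list()
  for (j in bloom_idx) {
    s <- sample(which(comp[, j] > 0), 1)
    frac <- stats::runif(1, model$bloom_spike_range[1],
                         model$bloom_spike_range[2])
    comp[s, ] <- comp[s, ] * (1 - frac) / (1 - comp[s, j])
    comp[s, j] <- frac
    spikes[[genus_names[j]]] <- list(sample_id = metadata$sample_id[s],
                                     share = frac)
  }
  # one rare taxon dominates one designated sample
  if (length(rare_idx) > 0) {
    j <- rare_idx[1]
    s <- sample(which(comp[, j] > 0), 1)
    frac <- model$rare_dominant_share
    comp[s, ] <- comp[s, ] * (1 - frac) / (1 - comp[s, j])
    comp[s, j] <- frac
    spikes[[genus_names[j]]] <- list(sample_id = metadata$sample_id[s],
                                     share = frac)
  }

  # ---- split genera into sOTUs ------------------------------------------
  n_sotu_per_genus <- ifelse(role %in% c("bloom", "rare"), 1L,
                             sample(seq_len(model$max_sotus_per_genus),
                                    n_genus, replace = TRUE))
  sotu_genus <- rep(seq_len(n_genus), n_sotu_per_genus)
  sotu_ids <- unlist(lapply(seq_len(n_genus), function(g) {
    sprintf("sotu_%s_%d", tolower(genus_names[g]),
            seq_len(n_sotu_per_genus[g]))
  }))
  split_frac <- unlist(lapply(n_sotu_per_genus, function(k) {
    w <- stats::rgamma(k, shape = 5)
    w / sum(w)
  }))
  comp_sotu <- comp[, sotu_genus, drop = FALSE] *
    matrix(rep(split_frac, each = n_samples), nrow = n_samples)
  colnames(comp_sotu) <- sotu_ids

  # ---- organelle contamination ------------------------------------------
  org_ids <- c("sotu_mitochondria_1", "sotu_chloroplast_1")
  org_mean <- model$organelle_fraction[metadata$sample_type]
  org_frac <- stats::rbeta(n_samples, shape1 = 0.8,
                           shape2 = 0.8 * (1 - org_mean) / org_mean)
  full_comp <- cbind(comp_sotu * (1 - org_frac),
                     matrix(c(org_frac * 0.7, org_frac * 0.3),
                            ncol = 2, dimnames = list(NULL, org_ids)))

  # ---- Dirichlet-multinomial counts -------------------------------------
  depths <- pmax(1000L, as.integer(round(stats::rlnorm(
    n_samples, design$depth_meanlog, design$depth_sdlog))))
  theta <- model$dirichlet_precision
  counts <- matrix(0, nrow = n_samples, ncol = ncol(full_comp),
                   dimnames = list(metadata$sample_id, colnames(full_comp)))
  for (s in seq_len(n_samples)) {
    p <- rdirichlet_row(theta * full_comp[s, ])
    counts[s, ] <- stats::rmultinom(1, depths[s], p)[, 1]
  }

  # ---- taxonomy and tree -------------------------------------------------
  n_phyla <- 6
  genus_phylum <- sample.int(n_phyla, n_genus, replace = TRUE)
  lineage_of <- function(g) {
    k <- genus_phylum[g]
    sprintf("d__Bacteria;p__Phylum_%02d;c__Class_%02d;o__Order_%02d;f__Family_%s;g__%s",
            k, k, k, genus_names[g], genus_names[g])
  }
  lineages <- vapply(sotu_genus, lineage_of, character(1))
  # one common genus is left unassigned at genus rank to exercise
  # family-level collapse labels
  if (n_common > 0) {
    fam_only <- which(sotu_genus == common_idx[1])
    lineages[fam_only] <- sub(";g__.*$", ";g__unassigned",
                              lineages[fam_only])
  }
  tax_tbl <- dplyr::bind_cols(
    tibble(feature_id = c(sotu_ids, org_ids)),
    parse_lineage(c(
      lineages,
      "d__Bacteria;p__Proteobacteria;c__Alphaproteobacteria;o__Rickettsiales;f__Mitochondria;g__Mitochondria",
      "d__Bacteria;p__Cyanobacteria;c__Cyanobacteriia;o__Chloroplast;f__Chloroplast;g__Chloroplast")),
    tibble(confidence = NA_real_))

  tree <- ape::rcoal(ncol(full_comp), tip.label = colnames(full_comp))
  tree$edge.length <- tree$edge.length / mean(tree$edge.length)

  # ---- ground truth ------------------------------------------------------
  key_of <- function(g) {
    parse_row <- parse_lineage(lineage_of(g))
    paste(unlist(parse_row[1, TAXONOMIC_RANKS[1:6]]), collapse = ";")
  }
  keys <- vapply(seq_len(n_genus), key_of, character(1))
  if (n_common > 0) {
    keys[common_idx[1]] <- sub(";[^;]*$", ";unassigned", keys[common_idx[1]])
  }
  truth <- list(
    core_taxa = keys[role == "core"],
    common_taxa = keys[role == "common"],
    bloom_taxa = keys[role == "bloom"],
    rare_taxa = keys[role == "rare"],
    filler_taxa = keys[role == "filler"],
    genus_display = stats::setNames(genus_names, keys),
    organelle_features = org_ids,
    spikes = spikes,
    variance_components = list(
      household_sd = model$household_sd, noise_sd = model$noise_sd,
      country_effect_sd = model$country_effect_sd,
      sample_type_effect_sd = model$sample_type_effect_sd,
      household_share_pct = 100 * model$household_sd^2 /
        (model$household_sd^2 + model$noise_sd^2)),
    expected_composition = comp,
    depths = stats::setNames(depths, metadata$sample_id)
  )

  structure(list(counts = counts, taxonomy = tax_tbl, metadata = metadata,
                 tree = tree, truth = truth),
            class = "kitchen_study")
}

#' @export
print.kitchen_study <- function(x, ...) {
  cat(sprintf("<kitchen_study> %d samples, %d sOTUs, %d countries, %d households\n",
              nrow(x$counts), ncol(x$counts),
              length(unique(x$metadata$country)),
              length(unique(x$metadata$household))))
  invisible(x)
}

#' Write a simulated study as a fixture directory
#'
#' Emits exactly the formats the readers consume: `feature_table.tsv`
#' (features as rows), `taxonomy.tsv`, `metadata.tsv`, `tree.nwk`, plus
#' `ground_truth.json`.
#'
#' @param study a `kitchen_study`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_feature_table(study$counts, file.path(dir, "feature_table.tsv"),
                      orientation = "features_as_rows")
  tax_out <- tibble(
    `Feature ID` = study$taxonomy$feature_id,
    Taxon = apply(study$taxonomy[, TAXONOMIC_RANKS], 1, function(r) {
      paste0(substr(TAXONOMIC_RANKS, 1, 1), "__", r, collapse = ";")
    }))
  utils::write.table(tax_out, file.path(dir, "taxonomy.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, eol = "\n")
  write_sample_metadata(study$metadata, file.path(dir, "metadata.tsv"))
  ape::write.tree(study$tree, file.path(dir, "tree.nwk"))
  truth <- study$truth
  truth$expected_composition <- NULL          # regenerable from the seed
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Compare a recovered core set with the planted truth
#'
#' @param truth the `$truth` element of a `kitchen_study`.
#' @param result a `core_result` from [evaluate_core_criteria()] computed on
#'   the same taxon universe (genus-level collapse keys).
#' @return one-row tibble: `sensitivity`, `specificity`, `exact_match`,
#'   `n_recovered`, `n_planted`.
#' @export
evaluate_core_recovery <- function(truth, result) {
  planted <- truth$core_taxa
  universe <- result$taxon
  missing <- setdiff(planted, universe)
  if (length(missing) > 0) {
    abort(paste0("taxon universe mismatch; planted core not in result: ",
                 paste(missing, collapse = ", ")))
  }
  recovered <- result$taxon[result$is_core]
  tp <- length(intersect(recovered, planted))
  non_core <- setdiff(universe, planted)
  tn <- length(setdiff(non_core, recovered))
  tibble(sensitivity = tp / length(planted),
         specificity = tn / length(non_core),
         exact_match = setequal(recovered, planted),
         n_recovered = length(recovered),
         n_planted = length(planted))
}
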