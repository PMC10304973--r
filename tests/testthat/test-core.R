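make_core_fixture <- function() {
  # 8 samples, 4 households across 2 countries
  meta <- tibble::tibble(
    sample_id = paste0("s", 1:8),
    country = rep(c("Norway", "France"), each = 4),
    household = rep(c("H1", "H2", "H3", "H4"), each = 2),
    sample_type = rep(c("sponge", "sink"), 4),
    category = sample_category(rep(c("sponge", "sink"), 4))
  )
  relab <- cbind(
    ubiquitous = rep(0.34, 8),                       # core
    bloomer = c(0.06, rep(0.0006, 5), 0, 0),         # high max, absent in H4
    thin_everywhere = rep(0.005, 8),                 # occurrence only
    nothing = rep(0.0004, 8)
  )
  relab <- cbind(relab, filler = 1 - rowSums(relab))
  rownames(relab) <- meta$sample_id
  list(relab = relab, meta = meta)
}

test_that("core criteria combine mean, mean-or-max and per-household occurrence", {
  fx <- make_core_fixture()
  res <- evaluate_core_criteria(fx$relab, fx$meta)
  r <- function(t) res[res$taxon == t, ]

  expect_true(r("ubiquitous")$is_core)
  expect_equal(r("ubiquitous")$venn_region, "mean+mean_max+occurrence")
  expect_equal(r("ubiquitous")$mean_relab, 0.34)
  expect_equal(r("ubiquitous")$pct_samples_present, 100)

  # high single-sample max, low mean, absent from one household
  b <- r("bloomer")
  expect_false(b$passes_mean)
  expect_true(b$passes_meanmax)
  expect_false(b$passes_occurrence)
  expect_equal(b$venn_region, "mean_max")

  t3 <- r("thin_everywhere")
  expect_false(t3$passes_meanmax)
  expect_true(t3$passes_occurrence)
  expect_equal(t3$venn_region, "occurrence")

  expect_equal(r("nothing")$venn_region, "occurrence")  # present everywhere

  # mean criterion implies mean-or-max on every run
  expect_true(all(!res$passes_mean | res$passes_meanmax))
})

test_that("zero thresholds pass every present taxon; core shrinks with thresholds", {
  fx <- make_core_fixture()
  zero <- evaluate_core_criteria(fx$relab, fx$meta,
                                 core_criteria(0, 0, 0))
  expect_true(all(zero$passes_mean))
  expect_true(all(zero$passes_meanmax))

  sizes <- vapply(c(0, 0.01, 0.1, 0.5), function(th) {
    sum(evaluate_core_criteria(fx$relab, fx$meta,
                               core_criteria(th, th, th))$is_core)
  }, numeric(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("venn partition is exhaustive with structurally empty regions", {
  fx <- make_core_fixture()
  res <- evaluate_core_criteria(fx$relab, fx$meta)
  v <- venn_partition(res)
  expect_equal(sum(v$n_taxa), sum(res$venn_region != "none"))
  expect_equal(v$n_taxa[v$region == "mean"], 0)
  expect_equal(v$n_taxa[v$region == "mean+occurrence"], 0)

  # with maximal thresholds and every taxon missing from some household,
  # nothing passes anything
  relab_none <- cbind(x = c(0, 0, rep(0.5, 6)), y = c(rep(0.5, 6), 0, 0))
  relab_none <- cbind(relab_none, z = 1 - rowSums(relab_none))
  relab_none[3:4, "z"] <- 0
  relab_none[3:4, "x"] <- relab_none[3:4, "x"] + 0.5
  rownames(relab_none) <- fx$meta$sample_id
  none <- evaluate_core_criteria(relab_none, fx$meta,
                                 core_criteria(1, 1, 1))
  expect_equal(sum(venn_partition(none)$n_taxa), 0)
})

test_that("occurrence summaries reproduce report-table accounting", {
  # study-shaped fixture: 302 samples, 74 households, 5 countries with the
  # published per-country sample/household layout
  layout <- tibble::tibble(
    country = c("France", "Hungary", "Norway", "Portugal", "Romania"),
    n_households = c(15, 14, 15, 15, 15),
    n_samples = c(66, 29, 63, 64, 80))
  meta <- dplyr::bind_rows(purrr::pmap(layout, function(country, n_households,
                                                        n_samples) {
    hh <- sprintf("%s_H%02d", substr(country, 1, 2), seq_len(n_households))
    tibble::tibble(
      sample_id = sprintf("%s_s%03d", substr(country, 1, 2),
                          seq_len(n_samples)),
      country = country,
      household = rep(hh, length.out = n_samples),
      sample_type = "sink", category = "surface")
  }))
  expect_equal(nrow(meta), 302)
  expect_equal(length(unique(meta$household)), 74)

  # plant a sparse taxon with the published per-country presence pattern:
  # households 2/2/4/1/3, samples 2/2/6/1/3
  tab <- matrix(0, nrow = 302, ncol = 2,
                dimnames = list(meta$sample_id, c("sparse", "bulk")))
  tab[, "bulk"] <- 1000
  plant <- function(country, households, samples) {
    idx <- which(meta$country == country)
    hh <- unique(meta$household[idx])[seq_len(households)]
    cand <- idx[meta$household[idx] %in% hh]
    cand[seq_len(samples)]
  }
  rows <- c(plant("France", 2, 2), plant("Hungary", 2, 2),
            plant("Norway", 4, 6), plant("Portugal", 1, 1),
            plant("Romania", 3, 3))
  tab[rows, "sparse"] <- 5

  s <- taxon_occurrence_summary(tab, meta, "sparse")
  expect_equal(s$n_samples_present, 14)
  expect_equal(s$n_households_present, 12)
  expect_equal(display_pct(s$pct_samples), 4.6)    # 14/302
  expect_equal(display_pct(s$pct_households), 16)  # 12/74
  bc <- s$by_country[[1]]
  expect_equal(bc$n_samples_present, c(2, 2, 6, 1, 3))
  expect_equal(bc$n_households_present, c(2, 2, 4, 1, 3))
  # per-country presence sums to the global counts
  expect_equal(sum(bc$n_samples_present), s$n_samples_present)
  expect_equal(sum(bc$n_households_present), s$n_households_present)
  expect_equal(sum(bc$n_samples_total), 302)
  expect_equal(sum(bc$n_households_total), 74)

  fmt <- format_occurrence(s)
  expect_equal(fmt$France, "2/2")
  expect_equal(fmt$Portugal, "1/1")

  # a taxon present everywhere
  s2 <- taxon_occurrence_summary(tab, meta, "bulk")
  expect_equal(s2$pct_samples, 100)
  expect_equal(s2$pct_households, 100)

  expect_error(taxon_occurrence_summary(tab, meta, "ghost"), "unknown taxon")
})

test_that("household occurrence pattern 7/0/0/3/6 gives 22% of households", {
  meta <- tibble::tibble(
    sample_id = paste0("s", 1:74),
    country = rep(c("France", "Hungary", "Norway", "Portugal", "Romania"),
                  c(15, 14, 15, 15, 15)),
    household = paste0("H", 1:74),
    sample_type = "sink", category = "surface")
  tab <- matrix(10, nrow = 74, ncol = 2,
                dimnames = list(meta$sample_id, c("taxon", "bulk")))
  tab[, "taxon"] <- 0
  present_hh <- c(which(meta$country == "France")[1:7],
                  which(meta$country == "Portugal")[1:3],
                  which(meta$country == "Romania")[1:6])
  tab[present_hh, "taxon"] <- 2
  s <- taxon_occurrence_summary(tab, meta, "taxon")
  expect_equal(s$n_households_present, 16)
  expect_equal(display_pct(s$pct_households), 22)   # 16/74
  fmt <- format_occurrence(s)
  expect_equal(fmt$Hungary, "0")
})

test_that("core summary sorts by mean abundance and is sample-order stable", {
  fx <- make_core_fixture()
  res <- evaluate_core_criteria(fx$relab, fx$meta)
  cs <- core_summary(res)
  expect_true(all(diff(cs$mean_relab_pct) <= 0))
  core_row <- cs[cs$taxon == "ubiquitous", ]
  expect_equal(core_row$mean_relab_pct, 34)
  expect_equal(core_row$pct_samples, 100)

  perm <- sample(nrow(fx$relab))
  res2 <- evaluate_core_criteria(fx$relab[perm, ],
                                 fx$meta[perm, ])
  expect_equal(core_summary(res2), cs)

  # spreadsheet-style recomputation on a 10-sample fixture
  set.seed(21)
  rel <- to_relative(random_count_table(10, 6))
  meta10 <- toy_metadata(rel)
  res3 <- evaluate_core_criteria(rel, meta10)
  cs3 <- core_summary(res3)
  for (tx in cs3$taxon) {
    expect_equal(cs3$mean_relab_pct[cs3$taxon == tx],
                 100 * mean(rel[, tx]))
    expect_equal(cs3$pct_samples[cs3$taxon == tx],
                 100 * mean(rel[, tx] > 0))
  }
})

test_that("occurrence on the unfiltered table is a superset of the filtered one", {
  set.seed(22)
  st <- small_study(seed = 22)
  l6 <- collapse_taxonomy(st$counts, st$taxonomy, 6)
  rel <- to_relative(l6)
  full <- evaluate_core_criteria(rel, st$metadata)
  filt <- abundance_filter(rel)
  sub <- evaluate_core_criteria(filt, st$metadata)
  shared <- intersect(full$taxon, sub$taxon)
  occ_full <- full$passes_occurrence[match(shared, full$taxon)]
  occ_sub <- sub$passes_occurrence[match(shared, sub$taxon)]
  expect_true(all(occ_full >= occ_sub))
})
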