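test_that("group means average per country x sample-type cell and list absences", {
  meta <- tibble::tibble(
    sample_id = paste0("s", 1:6),
    country = c("Norway", "Norway", "Norway", "Hungary", "Hungary", "Hungary"),
    household = paste0("H", 1:6),
    sample_type = c("sponge", "sponge", "sink", "sink", "sink", "countertop"),
    category = sample_category(c("sponge", "sponge", "sink", "sink", "sink",
                                 "countertop")))
  vals <- matrix(c(1, 3, 5, 7, 9, 11,
                   2, 2, 2, 4, 4, 10), ncol = 2,
                 dimnames = list(meta$sample_id, c("t1", "t2")))
  gm <- group_means(vals, meta)
  expect_equal(gm$means["t1", "Norway:sponge"], 2)       # mean of 1, 3
  expect_equal(gm$means["t1", "Hungary:sink"], 8)        # mean of 7, 9
  expect_equal(gm$means["t2", "Hungary:countertop"], 10) # single sample
  # Hungarian sponges never sampled -> absent, not zero-filled
  expect_false("Hungary:sponge" %in% colnames(gm$means))
  expect_true(any(gm$missing$country == "Hungary" &
                    gm$missing$sample_type == "sponge"))
  # brute-force recomputation
  for (cell in colnames(gm$means)) {
    parts <- strsplit(cell, ":", fixed = TRUE)[[1]]
    idx <- meta$country == parts[1] & meta$sample_type == parts[2]
    expect_equal(gm$means[, cell], colMeans(vals[idx, , drop = FALSE]))
  }
})

test_that("complete-linkage clustering matches hand-traced merges", {
  # 1-D points 0, 1, 10, 11: merge {a,b} at 1, {c,d} at 1, all at 11
  m <- matrix(c(0, 1, 10, 11), ncol = 1,
              dimnames = list(c("a", "b", "c", "d"), "x"))
  m <- cbind(m, m)  # need >= 2 columns
  colnames(m) <- c("x", "y")
  cl <- hierarchical_cluster(m, scale_columns = FALSE)
  h <- cl$rows
  expect_equal(sort(h$height), sort(c(sqrt(2), sqrt(2), 11 * sqrt(2))))
  expect_true(all(diff(h$height) >= 0))          # monotone heights
  groups2 <- stats::cutree(h, k = 2)
  expect_equal(unname(groups2), c(1, 1, 2, 2))

  # identical rows merge first at height 0
  m2 <- rbind(p = c(1, 2), q = c(1, 2), r = c(5, 9))
  cl2 <- hierarchical_cluster(m2, scale_columns = FALSE)
  expect_equal(cl2$rows$height[1], 0)

  # cophenetic distances dominate pairwise distances under complete linkage
  set.seed(31)
  m3 <- matrix(rnorm(40), 8, 5,
               dimnames = list(paste0("r", 1:8), paste0("c", 1:5)))
  cl3 <- hierarchical_cluster(m3, scale_columns = FALSE)
  expect_true(all(stats::cophenetic(cl3$rows) >= stats::dist(m3) - 1e-9))

  # leaf partition is invariant to input row permutation
  perm <- sample(8)
  cl4 <- hierarchical_cluster(m3[perm, ], scale_columns = FALSE)
  expect_equal(stats::cutree(cl3$rows, k = 3),
               stats::cutree(cl4$rows, k = 3)[names(stats::cutree(cl3$rows, k = 3))])

  # constant columns cannot be scaled
  m4 <- cbind(m3, const = 1)
  expect_error(hierarchical_cluster(m4), "const")
})

test_that("PCA matches the analytic eigendecomposition and conserves variance", {
  set.seed(32)
  n <- 200
  z <- matrix(rnorm(2 * n), n, 2) %*% chol(matrix(c(4, 1.2, 1.2, 1), 2))
  clr <- cbind(z, -rowSums(z))      # 3 columns summing to zero, CLR-like
  dimnames(clr) <- list(paste0("s", 1:n), c("a", "b", "c"))
  ord <- pca_clr(clr)
  # total variance conserved
  expect_equal(sum(ord$eigenvalues),
               sum(apply(clr, 2, stats::var)), tolerance = 1e-10)
  # axes match the eigenvectors of the sample covariance
  ev <- eigen(stats::cov(clr))
  for (j in 1:2) {
    v <- ev$vectors[, j]
    w <- ord$loadings[, j]
    expect_equal(abs(sum(v * w)), 1, tolerance = 1e-8)
    expect_equal(ord$eigenvalues[j], ev$values[j], tolerance = 1e-8)
  }
  # duplicated sample gets identical scores
  clr2 <- rbind(clr, clr[1, , drop = FALSE])
  rownames(clr2) <- c(rownames(clr), "dup")
  ord2 <- pca_clr(clr2)
  sc <- as.matrix(ord2$scores[, -1])
  rownames(sc) <- ord2$scores$sample_id
  expect_equal(sc["dup", ], sc["s1", ])

  expect_error(pca_clr(clr[1, , drop = FALSE]), "2 samples")
})

test_that("PERMANOVA pseudo-F matches the exhaustive oracle and detects structure", {
  set.seed(33)
  pts <- matrix(rnorm(12), 6, 2, dimnames = list(paste0("s", 1:6), NULL))
  d <- dist(pts)
  g <- c("a", "a", "a", "b", "b", "b")
  fit <- permanova(d, g, n_perm = 719, seed = 1)
  expect_equal(fit$f, oracle_permanova_f(d, g), tolerance = 1e-10)
  # exhaustive p on 6 samples
  expect_equal(fit$p_value, oracle_permanova_exhaustive_p(d, g),
               tolerance = 0.05)

  # two well-separated clusters reach the minimal p at 999 permutations
  far <- rbind(matrix(rnorm(20, 0), 10), matrix(rnorm(20, 30), 10))
  rownames(far) <- paste0("s", 1:20)
  g2 <- rep(c("a", "b"), each = 10)
  fit2 <- permanova(dist(far), g2, n_perm = 999, seed = 2)
  expect_equal(fit2$p_value, 0.001)
  expect_gt(fit2$r2, 0.9)

  # tidy/glance interface
  td <- generics::tidy(fit2)
  expect_equal(td$term, c("group", "residual"))
  expect_equal(sum(td$R2), 1)
  gl <- generics::glance(fit2)
  expect_equal(gl$n_groups, 2)

  expect_error(permanova(d, c("a", "a", "a", "a", "a", "b")), "single sample")
  fit3 <- permanova(d, c("a", "a", "a", "b", "b", "c"), n_perm = 99,
                    seed = 1, drop_singletons = TRUE)
  expect_equal(fit3$n_samples, 5)
})

test_that("country screening flags planted shifts and controls the FDR", {
  set.seed(34)
  n_per <- 8; countries <- c("A", "B", "C")
  meta <- tibble::tibble(
    sample_id = paste0("s", 1:(3 * n_per)),
    country = rep(countries, each = n_per),
    household = paste0("H", 1:(3 * n_per)),
    sample_type = "sink", category = "surface")
  n_taxa <- 20
  clr <- matrix(rnorm(nrow(meta) * n_taxa), nrow(meta), n_taxa,
                dimnames = list(meta$sample_id, paste0("t", 1:n_taxa)))
  shifted <- paste0("t", 1:5)
  clr[meta$country == "B", shifted] <- clr[meta$country == "B", shifted] + 3
  res <- screen_country_effects(clr, meta, min_cell_n = 5, n_perm = 499,
                                seed = 3)
  expect_true(all(res$sig_fdr05[res$taxon %in% shifted]))
  expect_lt(sum(res$sig_fdr05[!res$taxon %in% shifted]), 4)
  ve <- attr(res, "variance_explained")
  expect_equal(ve$n_countries, 3)
  expect_true(ve$pct_var_country > 0 && ve$pct_var_country < 100)
  # q-values are monotone in p within a sample type
  o <- order(res$p_value)
  expect_true(all(diff(res$q_value[o]) >= -1e-12))

  # null data: no flags expected
  clr0 <- matrix(rnorm(nrow(meta) * n_taxa), nrow(meta), n_taxa,
                 dimnames = dimnames(clr))
  res0 <- screen_country_effects(clr0, meta, min_cell_n = 5, n_perm = 499,
                                 seed = 4)
  expect_lt(sum(res0$sig_fdr05), 3)

  # sample types below the cell-size floor are skipped with a warning
  meta2 <- meta; meta2$sample_type <- rep(c("sink", "sponge"), length.out = nrow(meta2))
  w <- testthat::capture_warnings(
    screen_country_effects(clr, meta2, min_cell_n = 25, n_perm = 49, seed = 5))
  expect_true(any(grepl("skipped", w)))
})

test_that("BH adjustment in the screen matches the step-up definition", {
  p <- c(0.001, 0.008, 0.039, 0.041, 0.042, 0.06, 0.074, 0.205, 0.212, 0.216)
  manual <- rev(cummin(rev(p * length(p) / seq_along(p))))
  expect_equal(stats::p.adjust(p, "BH"), manual)
})

test_that("household mixed model recovers variance shares and marginal means", {
  simulate_mm <- function(share, n_hh = 30, n_per = 4, seed = 1) {
    withr::with_seed(seed, {
      sd_h <- sqrt(share); sd_e <- sqrt(1 - share)
      meta <- tibble::tibble(
        country = rep(rep(c("A", "B", "C"), each = n_hh / 3), each = n_per),
        household = rep(paste0("H", 1:n_hh), each = n_per),
        sample_type = rep(c("sponge", "sink", "countertop", "cloth"), n_hh))
      ce <- c(A = 0, B = 1, C = -1)
      te <- c(sponge = 0, sink = 0.5, countertop = -0.5, cloth = 0.2)
      b <- rnorm(n_hh, sd = sd_h)
      meta$y <- ce[meta$country] + te[meta$sample_type] +
        b[as.integer(factor(meta$household, levels = paste0("H", 1:n_hh)))] +
        rnorm(nrow(meta), sd = sd_e)
      meta
    })
  }
  dat <- simulate_mm(0.3, n_hh = 75, n_per = 4, seed = 7)
  fit <- fit_household_model(dat, "y")
  gl <- generics::glance(fit)
  expect_equal(gl$n_households, 75)
  expect_lt(abs(gl$household_share_pct - 30), 15)   # single replicate

  # zero household variance: estimated share collapses
  dat0 <- simulate_mm(0, n_hh = 75, n_per = 4, seed = 8)
  fit0 <- fit_household_model(dat0, "y")
  expect_lt(fit0$household_share, 5)

  # balanced design: marginal means equal raw group means
  em <- marginal_means(fit, "country")
  raw <- tapply(dat$y, dat$country, mean)
  expect_equal(em$emmean, as.numeric(raw[em$level]), tolerance = 1e-6)
  expect_true(all(em$lower < em$emmean & em$emmean < em$upper))

  td <- generics::tidy(fit)
  expect_true("countryB" %in% td$term)

  bad <- dat; bad$country[1] <- "B"
  expect_error(fit_household_model(bad, "y"), "spanning multiple countries")
  expect_error(fit_household_model(dplyr::select(dat, -"sample_type"), "y"),
               "missing column")
})
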