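# Independent brute-force oracles used to cross-check the package's
# implementations. Everything here is written from first principles (naive
# loops over pairs, edges and permutations) and never calls the package
# functions it is used to verify.

random_count_table <- function(n_samples, n_features, max_count = 50,
                               zero_prob = 0.3) {
  m <- matrix(stats::rbinom(n_samples * n_features, max_count, 0.4) *
                (stats::runif(n_samples * n_features) > zero_prob),
              nrow = n_samples,
              dimnames = list(paste0("s", seq_len(n_samples)),
                              paste0("f", seq_len(n_features))))
  # no all-zero samples
  for (i in which(rowSums(m) == 0)) m[i, 1] <- 1
  m
}

oracle_bray <- function(x, y) sum(abs(x - y)) / sum(x + y)

oracle_jaccard <- function(x, y) {
  a <- x > 0; b <- y > 0
  1 - sum(a & b) / sum(a | b)
}

# tips below each edge of an ape phylo, by naive recursion
edge_tip_sets <- function(tree) {
  n_tip <- length(tree$tip.label)
  children <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  below <- function(node) {
    if (node <= n_tip) return(tree$tip.label[node])
    unlist(lapply(children[[as.character(node)]], function(e) {
      below(tree$edge[e, 2])
    }))
  }
  lapply(seq_len(nrow(tree$edge)), function(e) below(tree$edge[e, 2]))
}

oracle_weighted_unifrac <- function(x, y, tree) {
  sets <- edge_tip_sets(tree)
  tot_x <- sum(x); tot_y <- sum(y)
  s <- 0
  for (e in seq_along(sets)) {
    px <- sum(x[sets[[e]]]) / tot_x
    py <- sum(y[sets[[e]]]) / tot_y
    s <- s + tree$edge.length[e] * abs(px - py)
  }
  s
}

oracle_unweighted_unifrac <- function(x, y, tree) {
  sets <- edge_tip_sets(tree)
  uniq <- 0; tot <- 0
  for (e in seq_along(sets)) {
    inx <- sum(x[sets[[e]]]) > 0
    iny <- sum(y[sets[[e]]]) > 0
    if (inx || iny) tot <- tot + tree$edge.length[e]
    if (xor(inx, iny)) uniq <- uniq + tree$edge.length[e]
  }
  uniq / tot
}

oracle_faith_pd <- function(x, tree) {
  sets <- edge_tip_sets(tree)
  present <- names(x)[x > 0]
  s <- 0
  for (e in seq_along(sets)) {
    if (any(sets[[e]] %in% present)) s <- s + tree$edge.length[e]
  }
  s
}

# Anderson's pseudo-F from a distance matrix and a grouping
oracle_permanova_f <- function(d, g) {
  m <- as.matrix(d)
  n <- nrow(m)
  k <- length(unique(g))
  sst <- sum(m[upper.tri(m)]^2) / n
  ssw <- 0
  for (lev in unique(g)) {
    idx <- which(g == lev)
    sub <- m[idx, idx, drop = FALSE]
    ssw <- ssw + sum(sub[upper.tri(sub)]^2) / length(idx)
  }
  ((sst - ssw) / (k - 1)) / (ssw / (n - k))
}

# exhaustive permutation p-value for the pseudo-F on small n
oracle_permanova_exhaustive_p <- function(d, g) {
  perms <- combinat_permutations(length(g))
  f_obs <- oracle_permanova_f(d, g)
  fs <- apply(perms, 1, function(idx) oracle_permanova_f(d, g[idx]))
  mean(fs >= f_obs - 1e-12)
}

combinat_permutations <- function(n) {
  if (n == 1) return(matrix(1))
  sub <- combinat_permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, sub + (sub >= i))
  }))
}

toy_tree <- function() {
  ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1):0;")
}

toy_metadata <- function(counts) {
  n <- nrow(counts)
  tibble::tibble(
    sample_id = rownames(counts),
    country = rep(c("Norway", "France"), length.out = n),
    household = paste0("H", ceiling(seq_len(n) / 2)),
    sample_type = rep(c("sponge", "sink"), length.out = n),
    category = sample_category(rep(c("sponge", "sink"), length.out = n))
  )
}

small_study <- function(seed = 42, n_taxa = 30,
                        households_per_country = 4) {
  simulate_kitchen_study(
    design = study_design(households_per_country = households_per_country,
                          n_taxa = n_taxa,
                          depth_meanlog = log(5000), depth_sdlog = 0.3),
    model = community_model(n_bloom = 2, n_rare = 2),
    seed = seed)
}
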