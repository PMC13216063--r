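test_that("functional entropy matches closed forms and conventions", {
  expect_equal(functional_entropy(rep(5, 1000))$e, log(1000),
               tolerance = 1e-12)
  expect_equal(functional_entropy(c(100, 0, 0, 0))$e, 0, tolerance = 1e-12)
  expect_equal(functional_entropy(c(3, 1))$e,
               -(0.75 * log(0.75) + 0.25 * log(0.25)), tolerance = 1e-12)
  expect_equal(sum(functional_entropy(c(2, 3, 5))$p), 1)
  expect_error(functional_entropy(c(0, 0)), "undefined")
  expect_error(functional_entropy(c(-1, 2)), "nonnegative")
})

test_that("entropy is bounded by [0, log K] over random response profiles", {
  set.seed(5)
  for (i in 1:50) {
    k <- sample(2:30, 1)
    counts <- rpois(k, lambda = sample(1:20, 1))
    if (sum(counts) == 0) counts[1] <- 1
    e <- functional_entropy(counts)$e
    expect_gte(e, 0)
    expect_lte(e, log(k) + 1e-12)
  }
})

test_that("an untrained network answers near-uniformly across classes", {
  un <- cats_network(32, 20, c(16, 16), seed = 15)
  eval_set <- fx_hyperfit()$holdout_set
  e <- entropy_distribution(un, eval_set, n_points = 30, sampler = "normal",
                            seed = 16)
  expect_lt(abs(mean(e, na.rm = TRUE) - log(8)) / log(8), 0.10)
  expect_length(entropy_distribution(un, eval_set, n_points = 1,
                                     sampler = "normal", seed = 17), 1)
})

test_that("basis one-hot probes are counted per hyper-category", {
  hw <- fx_hyper()
  fit <- fx_hyperfit()
  eval_set <- fit$holdout_set
  bs <- basis_specificity(fit$network, eval_set, hw$hyper_map)
  expect_equal(dim(bs), c(20L, 2L))
  expect_true(all(bs >= 0))
  # trained fixture: some basis dimension concentrates its Yes mass
  active <- bs[rowSums(bs) > 0, , drop = FALSE]
  frac <- apply(active, 1, function(r) max(r) / sum(r))
  expect_gt(max(frac), 0.7)
  # untrained instance: near-uniform profiles (fixed-seed desk analogue),
  # and far less hyper-category concentration than the trained instance
  un <- cats_network(32, 20, c(16, 16), seed = 46)
  bs_un <- basis_specificity(un, eval_set, hw$hyper_map)
  busy <- bs_un[rowSums(bs_un) > 40, , drop = FALSE]
  ratio <- apply(busy, 1, function(r) max(r) / max(1, min(r)))
  expect_lt(max(ratio), 2)
  frac_un <- apply(busy, 1, function(r) max(r) / sum(r))
  expect_gt(max(frac), max(frac_un))
  # unmapped class is an error listing the offender
  expect_error(basis_specificity(fit$network, eval_set,
                                 hw$hyper_map[-1, ]),
               hw$hyper_map$class_id[1])
})

test_that("a degenerate always-No head yields a zero count matrix", {
  net <- cats_network(8, 4, c(6, 6), seed = 3)
  L <- net$L
  net$ts[[L]]$W[] <- 0
  net$ts[[L]]$b <- c(10, -10)   # No score always wins
  w <- list(a = matrix(rnorm(40), 10, 4 * 2), b = matrix(rnorm(80), 10, 8))
  w <- list(a = matrix(rnorm(80), 10, 8), b = matrix(rnorm(80), 10, 8))
  hm <- data.frame(class_id = c("a", "b"), hyper_category = c("H1", "H2"))
  bs <- basis_specificity(net, w, hm)
  expect_true(all(bs == 0))
})

test_that("RDM construction honors its metric definitions", {
  v <- rbind(a = c(1, 2, 3), b = c(1, 2, 3), c = c(3, 2, 1))
  r <- rdm_from_vectors(v, "pearson")
  expect_equal(r["a", "b"], 0, tolerance = 1e-12)
  expect_equal(r["a", "c"], 2, tolerance = 1e-12)  # perfect anticorrelation
  expect_equal(diag(unclass(r)), rep(0, 3), ignore_attr = TRUE)
  v2 <- rbind(a = c(1, 2, 3), b = c(1, 2, 4), c = c(9, 1, 2))
  r2 <- rdm_from_vectors(v2, "pearson")
  expect_equal(r2["a", "b"], 1 - 0.98198, tolerance = 1e-4)
  expect_error(rdm_from_vectors(rbind(a = c(1, 1, 1), b = c(1, 2, 3),
                                      c = c(2, 1, 1)), "pearson"), "a")
  rc <- rdm_from_vectors(rbind(a = c(1, 0), b = c(0, 1), c = c(1, 1)),
                         "cosine")
  expect_equal(rc["a", "b"], 1, tolerance = 1e-12)  # orthogonal vectors
  expect_error(rdm_from_vectors(rbind(a = c(0, 0), b = c(0, 1),
                                      c = c(1, 1)), "cosine"), "zero")
  re <- rdm_from_vectors(v2, "euclidean")
  expect_equal(re["a", "b"], 1, tolerance = 1e-12)
  # symmetry and zero diagonal across metrics
  for (m in c("pearson", "cosine", "euclidean")) {
    set.seed(8)
    rr <- rdm_from_vectors(matrix(rnorm(50), 10, 5), m)
    expect_equal(unclass(rr), t(unclass(rr)))
    expect_true(all(diag(unclass(rr)) == 0))
  }
})

test_that("concept clustering uses cosine distance with UPGMA linkage", {
  con <- rbind(u = c(1, 0), v = c(1, 0.01), w = c(0, 1))
  hc <- hcluster_concepts(con)
  # first merge joins the two near-parallel vectors
  first <- sort(hc$hclust$labels[-hc$hclust$merge[1, ]])
  expect_equal(first, c("u", "v"))
  expect_lt(hc$hclust$height[1], 1e-4)
  # identical vectors merge at height 0
  hc2 <- hcluster_concepts(rbind(a = c(1, 2), b = c(1, 2), c = c(2, -1)))
  expect_equal(hc2$hclust$height[1], 0, tolerance = 1e-12)
  expect_equal(unname(hc2$distance["a", "c"]), 1, tolerance = 1e-12)
  expect_error(hcluster_concepts(rbind(a = c(0, 0), b = c(1, 2))), "zero")
  cl <- hcluster_concepts(con, k = 2)$clusters
  expect_equal(unname(cl["u"]), unname(cl["v"]))
  expect_false(cl["u"] == cl["w"])
  # UPGMA height between {u,v} and w equals the mean of the two distances
  d_uw <- hc$distance["u", "w"]; d_vw <- hc$distance["v", "w"]
  expect_equal(hc$hclust$height[2], mean(c(d_uw, d_vw)), tolerance = 1e-12)
})

test_that("best-match retains the maximum correlation per reference dim", {
  set.seed(12)
  cm <- matrix(rnorm(40 * 6), 40, 6)
  ref <- cbind(copy = cm[, 4], noise = rnorm(40))
  bm <- best_match_dimensions(ref, cm)
  expect_equal(bm$best_dim[1], 4)
  expect_equal(bm$best_r[1], 1, tolerance = 1e-12)
  # permutation equivariance: permuting concept dims permutes the argmax
  perm <- c(3, 1, 6, 2, 5, 4)
  bmp <- best_match_dimensions(ref, cm[, perm])
  expect_equal(bmp$best_r, bm$best_r, tolerance = 1e-12)
  expect_equal(perm[bmp$best_dim], bm$best_dim)
  expect_error(best_match_dimensions(cbind(rep(1, 40)), cm), "constant")
})

test_that("best-match null distribution matches the brute-force max-of-d null", {
  # independent reference dims against d_c = 20 concept dims
  set.seed(33)
  n_items <- 60; d_c <- 20; reps <- 400
  cm <- matrix(rnorm(n_items * d_c), n_items, d_c)
  via_fn <- best_match_dimensions(matrix(rnorm(n_items * reps), n_items),
                                  cm)$best_r
  brute <- replicate(reps, {
    x <- rnorm(n_items)
    max(as.numeric(cor(x, cm)))
  })
  expect_gt(suppressWarnings(ks.test(via_fn, brute)$p.value), 0.01)
})

test_that("critical correlation thresholds follow the t quantile formula", {
  expect_equal(critical_r(8, 0.05, 2),
               qt(0.975, 8) / sqrt(qt(0.975, 8)^2 + 8), tolerance = 1e-12)
  expect_equal(critical_r(8, 0.05, 2), 0.632, tolerance = 1e-3)
  expect_lt(critical_r(1e8, 0.05, 2), 0.001)
  # strictly decreasing in df and in alpha
  dfs <- c(5, 10, 50, 200, 1000)
  expect_true(all(diff(vapply(dfs, critical_r, numeric(1),
                              alpha = 0.05)) < 0))
  alphas <- c(0.001, 0.01, 0.05, 0.2)
  expect_true(all(diff(vapply(alphas, function(a) critical_r(100, a),
                              numeric(1))) < 0))
  expect_error(critical_r(0, 0.05), "df")
  expect_error(critical_r(10, 1.5), "alpha")
  # significance flags agree with the exact t-test of a Pearson r
  set.seed(2)
  n <- 30
  cm <- matrix(rnorm(n * 5), n, 5)
  ref <- matrix(rnorm(n * 20), n, 20)
  bm <- best_match_dimensions(ref, cm, alpha = 0.05)
  pvals <- vapply(seq_len(20), function(i) {
    r <- bm$best_r[i]
    tt <- r * sqrt((n - 2) / (1 - r^2))
    2 * pt(tt, n - 2, lower.tail = FALSE)
  }, numeric(1))
  expect_equal(bm$significant, pvals < 0.05)
})

test_that("k-means on vectorized RDMs recovers planted structure", {
  t1 <- random_rdm(10, 1)
  t2 <- random_rdm(10, 2)
  set.seed(3)
  noisy <- function(m, sd) {
    n <- m
    ut <- upper.tri(n)
    n[ut] <- pmax(n[ut] + rnorm(sum(ut), sd = sd), 0)
    n[lower.tri(n)] <- t(n)[lower.tri(n)]
    n
  }
  rdms <- c(lapply(1:15, function(i) noisy(t1, 0.2)),
            lapply(1:15, function(i) noisy(t2, 0.2)))
  cl <- kmeans_rdm_groups(rdms, k = 2, seed = 4)
  truth <- rep(1:2, each = 15)
  agree <- max(mean(cl == truth), mean(cl == 3 - truth))
  expect_gt(agree, 0.9)
  # exact duplicates split perfectly
  cl2 <- kmeans_rdm_groups(c(rep(list(t1), 3), rep(list(t2), 3)), 2, seed = 5)
  expect_equal(length(unique(cl2[1:3])), 1)
  expect_equal(length(unique(cl2[4:6])), 1)
  expect_false(cl2[1] == cl2[4])
  expect_equal(kmeans_rdm_groups(list(t1, t2), 1), c(1L, 1L))
  expect_error(kmeans_rdm_groups(list(t1), 2), "at least k")
})
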