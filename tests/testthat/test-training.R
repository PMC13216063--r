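mini_world <- function() {
  fx("mini_world", function() {
    generate_class_features(n_classes = 4, feature_dim = 16,
                            samples_per_class = 30, seed = 2)
  })
}

test_that("triplet building pairs the stated fractions with Yes/No labels", {
  w <- list(a = matrix(rnorm(10 * 4), 10, 4), b = matrix(rnorm(10 * 4), 10, 4))
  con <- init_concepts(c("a", "b"), 3, seed = 1)
  tr <- build_triplets(w, con, negative_fraction = 0.5, seed = 7)
  expect_equal(sum(tr$label == "Yes"), 10)
  expect_equal(sum(tr$label == "No"), 10)
  expect_true(all(tr$concept_id[tr$label == "No"] !=
                    tr$true_id[tr$label == "No"]))
  expect_true(all(tr$concept_id[tr$label == "Yes"] ==
                    tr$true_id[tr$label == "Yes"]))
  # boundary: no negatives
  tr0 <- build_triplets(w, con, negative_fraction = 0, seed = 7)
  expect_true(all(tr0$label == "Yes"))
  # single class cannot host negative pairings
  expect_error(build_triplets(w["a"], con, negative_fraction = 0.5),
               "at least 2 classes")
})

test_that("negative concepts are drawn uniformly over the other classes", {
  set.seed(3)
  w <- setNames(lapply(1:3, function(i) matrix(rnorm(3000 * 2), 3000, 2)),
                c("a", "b", "c"))
  con <- init_concepts(names(w), 2, seed = 1)
  tr <- build_triplets(w, con, negative_fraction = 0.5, seed = 9)
  for (cl in names(w)) {
    neg <- tr$concept_id[tr$label == "No" & tr$true_id == cl]
    freqs <- table(neg) / length(neg)
    expect_true(all(abs(freqs - 0.5) < 0.03))
  }
})

test_that("concept noise has the stated uniform moments and is seeded", {
  v <- numeric(1e5)
  noisy <- inject_noise(v, amplitude = 0.1, seed = 4)
  expect_lt(abs(mean(noisy)), 0.002)
  expect_lt(abs(var(noisy) - 0.1^2 / 3) / (0.1^2 / 3), 0.05)
  expect_identical(inject_noise(1:5, 0.1, seed = 8),
                   inject_noise(1:5, 0.1, seed = 8))
  expect_identical(inject_noise(c(1, 2), 0), c(1, 2))
  expect_error(inject_noise(1, -0.1), "amplitude")
})

test_that("each phase updates only its own parameter group (byte-level)", {
  w <- mini_world()$features_by_class
  net <- cats_network(16, 4, c(8, 8), seed = 10)
  con <- init_concepts(names(w), 4, seed = 11)
  tr <- build_triplets(w, con, 0.5, seed = 12)
  cfg <- cats_train_config(seed = 13)
  # network phase: weights (incl. running stats) move, concepts do not
  set.seed(14)
  resn <- catsnet:::run_epoch(net, con, tr, cfg, update = "network",
                              opt_net = catsnet:::adam_new())
  expect_gt(max(abs(resn$net$ts[[1]]$W - net$ts[[1]]$W)), 0)
  expect_identical(serialize(resn$concepts, NULL), serialize(con, NULL))
  # concept phase: concepts move; every weight tensor AND every batch-norm
  # running statistic stays byte-identical
  set.seed(14)
  resc <- catsnet:::run_epoch(net, con, tr, cfg, update = "concepts",
                              opt_con = catsnet:::adam_new())
  expect_gt(max(abs(resc$concepts - con)), 0)
  expect_identical(serialize(resc$net, NULL), serialize(net, NULL))
  # and the phase is deterministic under the ambient seed
  set.seed(14)
  resc2 <- catsnet:::run_epoch(net, con, tr, cfg, update = "concepts",
                               opt_con = catsnet:::adam_new())
  expect_identical(resc$concepts, resc2$concepts)
})

test_that("empty triplet sets are no-ops", {
  w <- mini_world()$features_by_class
  net <- cats_network(16, 4, c(8, 8), seed = 30)
  con <- init_concepts(names(w), 4, seed = 31)
  empty <- structure(list(features = matrix(numeric(0), 0, 16),
                          true_id = character(0), concept_id = character(0),
                          label = factor(character(0),
                                         levels = c("No", "Yes"))),
                     class = "cats_triplets")
  cfg <- cats_train_config(seed = 32)
  resn <- train_network_phase(net, con, empty, cfg)
  expect_identical(serialize(resn$net, NULL), serialize(net, NULL))
  expect_length(resn$losses, 0)
  resc <- train_concept_phase(net, con, empty, cfg)
  expect_identical(resc$concepts, con)
})

test_that("training descends: later epochs have lower loss on separable data", {
  fit <- fx_fit8()
  h <- fit$history
  first <- h$loss[h$epoch == 1 & h$phase == "network"]
  last <- h$loss[h$epoch == max(h$epoch) & h$phase == "network"]
  expect_lt(last, first)
})

test_that("swapped concepts are repaired by a concept phase", {
  w <- mini_world()$features_by_class
  fit <- fx("mini_fit", function() {
    catsnet(mini_world()$features_by_class, d_c = 4, hidden = c(8, 8),
            config = cats_train_config(seed = 40), holdout = 0.2)
  })
  con_sw <- fit$concepts
  cls <- rownames(con_sw)
  con_sw[c(cls[1], cls[2]), ] <- con_sw[c(cls[2], cls[1]), ]
  tr <- build_triplets(w, con_sw, 0.5, seed = 41)
  cfg <- cats_train_config(seed = 42, lr_concept = 5e-2)
  labels <- as.integer(tr$label)
  loss_with <- function(con) {
    fw <- cats_forward(fit$network, tr$features,
                       con[tr$concept_id, , drop = FALSE])
    catsnet:::softmax_xent(fw$scores, labels)$loss
  }
  l0 <- loss_with(con_sw)
  set.seed(43)
  res <- train_concept_phase(fit$network, con_sw, tr, cfg)
  expect_lt(loss_with(res$concepts), l0)
})

test_that("zero-epoch runs return their inputs unchanged", {
  w <- mini_world()$features_by_class
  net <- cats_network(16, 4, c(8, 8), seed = 50)
  con <- init_concepts(names(w), 4, seed = 51)
  res <- train_alternating(net, con, w, cats_train_config(epochs = 0,
                                                          seed = 52))
  expect_identical(serialize(res$net, NULL), serialize(net, NULL))
  expect_identical(res$concepts, con)
  expect_equal(nrow(res$history), 0)
})

test_that("alternating runs are reproducible from the seed", {
  w <- mini_world()$features_by_class
  cfg <- cats_train_config(epochs = 2, seed = 60)
  run <- function() {
    net <- cats_network(16, 4, c(8, 8), seed = 61)
    con <- init_concepts(names(w), 4, seed = 62)
    train_alternating(net, con, w, cfg, holdout_features_by_class = w)
  }
  r1 <- run()
  r2 <- run()
  expect_identical(r1$history, r2$history)
  expect_identical(r1$concepts, r2$concepts)
})

test_that("an untrained instance scores at chance on balanced evaluation", {
  w <- fx_world8()$features_by_class
  net <- cats_network(32, 8, c(16, 16), seed = 70)
  con <- init_concepts(names(w), 8, seed = 71)
  ev <- evaluate_concepts(net, con, w, seed = 72)
  # balanced labels; 8 * 2 * 200 = 3200 judgments, 3 s.e. ~ 0.027
  expect_lt(abs(ev$macro - 0.5), 0.05)
})

test_that("evaluation rejects categories without concepts", {
  w <- mini_world()$features_by_class
  net <- cats_network(16, 4, c(8, 8), seed = 80)
  con <- init_concepts(names(w)[-1], 4, seed = 81)
  expect_error(evaluate_concepts(net, con, w), "missing from the concept set")
})

test_that("concept noise at training does not hurt noisy-probe robustness", {
  # fixed-seed qualitative probe: accuracy under perturbed test concepts,
  # trained with noise vs without
  w <- mini_world()$features_by_class
  fit_noise <- catsnet(w, d_c = 4, hidden = c(8, 8),
                       config = cats_train_config(seed = 90,
                                                  noise_amplitude = 0.1))
  fit_clean <- catsnet(w, d_c = 4, hidden = c(8, 8),
                       config = cats_train_config(seed = 90,
                                                  noise_amplitude = 0))
  probe_acc <- function(fit) {
    con <- inject_noise(fit$concepts, 0.1, seed = 91)
    evaluate_concepts(fit$network, con, fit$holdout_set, seed = 92)$macro
  }
  expect_gte(probe_acc(fit_noise) + 0.02, probe_acc(fit_clean))
})

test_that("the fitted model object behaves like a classed R model", {
  fit <- fx_fit8()
  expect_s3_class(fit, "catsnet")
  expect_output(print(fit), "holdout macro accuracy")
  expect_output(print(summary(fit)), "final losses")
  expect_identical(coef(fit), fit$concepts)
  cls <- rownames(fit$concepts)[1]
  x <- fx_world8()$features_by_class[[cls]][1:5, ]
  dec <- predict(fit, x, cls)
  expect_s3_class(dec, "factor")
  sc <- predict(fit, x, cls, type = "scores")
  expect_equal(dim(sc), c(5L, 2L))
  expect_error(predict(fit, x, "no_such_class"), "unknown category")
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})
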