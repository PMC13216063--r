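comm_world <- function() {
  fx("comm_world", function() {
    generate_class_features(n_classes = 6, feature_dim = 16,
                            samples_per_class = 40,
                            level_scales = c(6, 3, 1), seed = 55)
  })
}

comm_fit <- function() {
  fx("comm_fit", function() {
    catsnet(comm_world()$features_by_class, d_c = 4, hidden = c(12, 12),
            config = cats_train_config(seed = 56))
  })
}

test_that("repelling loss evaluates its closed forms", {
  expect_equal(repelling_loss(c(1, 2), rbind(c(1, 2)), tau = 0.5), 1,
               tolerance = 1e-12)
  expect_equal(repelling_loss(c(0.5), rbind(0, 1), tau = 1),
               2 * exp(-0.25), tolerance = 1e-12)
  expect_lt(repelling_loss(c(100, 100), rbind(c(0, 0), c(1, 1)), tau = 1),
            1e-10)
  expect_equal(repelling_loss(c(1, 2), matrix(numeric(0), 0, 2)), 0)
  expect_error(repelling_loss(1, rbind(0), tau = 0), "tau")
})

test_that("repelling loss is invariant to rigid rotation of all concepts", {
  set.seed(1)
  C <- rnorm(4)
  old <- matrix(rnorm(20), 5, 4)
  theta <- 0.7
  R <- diag(4)
  R[1:2, 1:2] <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2)
  expect_equal(repelling_loss(as.numeric(C %*% R), old %*% R, tau = 0.3),
               repelling_loss(C, old, tau = 0.3), tolerance = 1e-12)
})

test_that("repelling gradient matches finite differences", {
  set.seed(2)
  C <- rnorm(3)
  old <- matrix(rnorm(12), 4, 3)
  g <- catsnet:::repelling_grad(C, old, tau = 0.8)
  eps <- 1e-6
  for (k in 1:3) {
    Cp <- C; Cp[k] <- C[k] + eps
    Cm <- C; Cm[k] <- C[k] - eps
    fd <- (repelling_loss(Cp, old, 0.8) - repelling_loss(Cm, old, 0.8)) /
      (2 * eps)
    expect_equal(g[k], fd, tolerance = 1e-6)
  }
})

test_that("concept expansion produces the requested count of working vectors", {
  fit <- comm_fit()
  world <- comm_world()
  cl <- rownames(fit$concepts)[2]
  xm <- world$features_by_class[[cl]]
  old <- do.call(rbind, lapply(setdiff(names(world$features_by_class), cl),
                               function(oc)
                                 world$features_by_class[[oc]][1, ,
                                                               drop = FALSE]))
  ec <- expand_concepts(fit$network, fit$concepts, cl,
                        shots = list(new = xm[1:2, ], old = old),
                        config = repelling_config(steps = 200),
                        n_expanded = 3, seed = 57)
  expect_equal(dim(ec), c(3L, 4L))
  expect_length(attr(ec, "final_loss"), 3)
  # pure cross-entropy fit classifies its own shot Yes
  ec2 <- expand_concepts(fit$network, fit$concepts, cl,
                         shots = list(new = xm[1:2, ]),
                         config = repelling_config(alpha = 0, beta = 0,
                                                   steps = 400),
                         n_expanded = 2, seed = 58)
  dec <- cats_decide(fit$network, xm[1:2, ], ec2[1, ])
  expect_true(all(dec == "Yes"))
  # the reference decomposition: 1 learned + 96 expanded = 97 per category
  ec97 <- expand_concepts(fit$network, fit$concepts, cl,
                          shots = list(new = xm[1:2, ], old = old),
                          config = repelling_config(steps = 5),
                          n_expanded = 96, seed = 59)
  expect_equal(nrow(rbind(fit$concepts[cl, , drop = FALSE], ec97)), 97L)
})

test_that("a strong repelling weight pushes expansions away from old concepts", {
  fit <- comm_fit()
  world <- comm_world()
  cl <- rownames(fit$concepts)[1]
  xm <- world$features_by_class[[cl]]
  old_con <- fit$concepts[setdiff(rownames(fit$concepts), cl), ]
  min_d2 <- function(beta) {
    ec <- expand_concepts(fit$network, fit$concepts, cl,
                          shots = list(new = xm[1:2, ]),
                          config = repelling_config(alpha = 0, beta = beta,
                                                    tau = 5, steps = 200),
                          n_expanded = 4, seed = 60)
    mean(apply(ec, 1, function(v)
      min(rowSums(sweep(old_con, 2, v)^2))))
  }
  expect_gt(min_d2(5), min_d2(0))
})

test_that("translation fitting follows the learning-rate schedule", {
  set.seed(3)
  Y <- matrix(rnorm(6 * 4), 6, 4, dimnames = list(letters[1:6], NULL))
  tb <- setNames(lapply(rownames(Y), function(cl)
    Y[rep(cl, 3), , drop = FALSE] + rnorm(12, sd = 0.05)), rownames(Y))
  tr <- fit_translation(tb, Y, translation_config(hidden_layers = 2,
                                                  hidden_width = 16,
                                                  dropout = 0, epochs = 25,
                                                  lr = 1e-3), seed = 4)
  expect_equal(tr$lr_history[1], 1e-3)
  expect_equal(tr$lr_history[11], 1e-3 * 0.5)
  expect_equal(tr$lr_history[25], 1e-3 * 0.5^2)
  expect_error(fit_translation(tb, Y[1:3, ], translation_config()),
               "do not match")
})

test_that("the translation can represent a near-identity mapping", {
  set.seed(5)
  Y <- matrix(rnorm(10 * 4), 10, 4,
              dimnames = list(paste0("k", 1:10), NULL))
  tb <- setNames(lapply(rownames(Y), function(cl)
    Y[rep(cl, 8), , drop = FALSE] +
      matrix(rnorm(32, sd = 0.02), 8, 4)), rownames(Y))
  tr <- fit_translation(tb, Y, translation_config(hidden_layers = 2,
                                                  hidden_width = 32,
                                                  dropout = 0, epochs = 80,
                                                  lr = 1e-2), seed = 6)
  pred <- predict(tr, Y)
  rel <- sqrt(mean((pred - Y)^2) / mean(Y^2))
  expect_lt(rel, 0.05)
  # dropout masks are seeded: identical refits coincide exactly
  tr2 <- fit_translation(tb, Y, translation_config(hidden_layers = 2,
                                                   hidden_width = 32,
                                                   dropout = 0.2,
                                                   epochs = 10, lr = 1e-2),
                         seed = 7)
  tr3 <- fit_translation(tb, Y, translation_config(hidden_layers = 2,
                                                   hidden_width = 32,
                                                   dropout = 0.2,
                                                   epochs = 10, lr = 1e-2),
                         seed = 7)
  expect_identical(tr2$layers, tr3$layers)
})

test_that("layer-wise RDMs are perfectly self-correlated at the input", {
  set.seed(8)
  Y <- matrix(rnorm(8 * 3), 8, 3, dimnames = list(paste0("k", 1:8), NULL))
  tb <- setNames(lapply(rownames(Y), function(cl)
    Y[rep(cl, 6), , drop = FALSE] + rnorm(18, sd = 0.02)), rownames(Y))
  tr <- fit_translation(tb, Y, translation_config(hidden_layers = 3,
                                                  hidden_width = 24,
                                                  dropout = 0, epochs = 80,
                                                  lr = 1e-2), seed = 9)
  probes <- matrix(rnorm(20 * 3), 20, 3)
  lp <- layer_rdm_preservation(tr, probes)
  expect_equal(lp$correlations$rho[1], 1, tolerance = 1e-12)
  expect_equal(nrow(lp$correlations), 3 + 2)  # input, hidden x3, output
  # identity-task translation preserves structure through every layer
  lp2 <- layer_rdm_preservation(tr, Y + matrix(rnorm(24, sd = 0.01), 8, 3))
  expect_true(all(lp2$correlations$rho > 0.8))
  expect_error(layer_rdm_preservation(tr, probes[1:2, ]), "at least 3")
})

test_that("an untrained deep translation decorrelates deep layers", {
  set.seed(10)
  cfg <- translation_config(hidden_layers = 8, hidden_width = 4,
                            dropout = 0, epochs = 0, lr = 1e-3)
  Y <- matrix(rnorm(5 * 4), 5, 4, dimnames = list(paste0("k", 1:5), NULL))
  tb <- setNames(lapply(rownames(Y), function(cl)
    Y[cl, , drop = FALSE]), rownames(Y))
  tr <- fit_translation(tb, Y, cfg, seed = 11)
  set.seed(99)
  probes <- rbind(diag(4) * 3,  # orthogonal probes plus random fill
                  matrix(rnorm(4 * 46), 46, 4))
  lp <- layer_rdm_preservation(tr, probes)
  deep <- utils::tail(lp$correlations$rho, 2)
  expect_true(all(abs(deep) < 0.3))
})

test_that("transmission refuses a held-out class seen by the translation", {
  set.seed(12)
  Y <- matrix(rnorm(5 * 3), 5, 3, dimnames = list(paste0("k", 1:5), NULL))
  tb <- setNames(lapply(rownames(Y), function(cl) Y[cl, , drop = FALSE]),
                 rownames(Y))
  tr <- fit_translation(tb, Y, translation_config(hidden_layers = 1,
                                                  hidden_width = 8,
                                                  dropout = 0, epochs = 2),
                        seed = 13)
  net <- cats_network(6, 3, c(4, 4), seed = 14)
  w <- setNames(lapply(1:5, function(i) matrix(rnorm(24), 4, 6)),
                rownames(Y))
  expect_error(transmit_and_evaluate(Y, net, tr, "k1", w),
               "protocol violation")
})

test_that("an identity protocol transfers at the teacher's own accuracy", {
  # translation = near-exact identity fit, student = teacher: transfer
  # accuracy equals the teacher's own holdout accuracy for that class
  fit <- comm_fit()
  world <- comm_world()
  d1 <- rownames(fit$concepts)[3]
  Yall <- fit$concepts
  shared <- setdiff(rownames(Yall), d1)
  tb <- setNames(lapply(shared, function(cl)
    Yall[rep(cl, 20), , drop = FALSE] +
      matrix(rnorm(80, sd = 1e-4), 20, 4)), shared)
  tr <- fit_translation(tb, Yall[shared, ],
                        translation_config(hidden_layers = 1,
                                           hidden_width = 64, dropout = 0,
                                           epochs = 150, lr = 1e-2),
                        seed = 15)
  res <- transmit_and_evaluate(Yall, fit$network, tr, d1,
                               world$features_by_class, seed = 16)
  direct <- {
    pos <- world$features_by_class[[d1]]
    set.seed(16)
    neg_pool <- do.call(rbind, world$features_by_class[shared])
    neg <- neg_pool[sample.int(nrow(neg_pool), nrow(pos)), ]
    (sum(cats_decide(fit$network, pos, Yall[d1, ]) == "Yes") +
       sum(cats_decide(fit$network, neg, Yall[d1, ]) == "No")) /
      (2 * nrow(pos))
  }
  expect_lt(abs(res$accuracy - direct), 0.15)
})
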