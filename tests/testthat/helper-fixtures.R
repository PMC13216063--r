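# Shared fixtures, built once per test run and memoized. All synthetic,
# all seeded.

.fx_cache <- new.env(parent = emptyenv())

fx <- function(name, builder) {
  if (is.null(.fx_cache[[name]])) .fx_cache[[name]] <- builder()
  .fx_cache[[name]]
}

# 8-class hierarchical feature world (the training-criterion conditions)
fx_world8 <- function() {
  fx("world8", function() {
    generate_class_features(n_classes = 8, feature_dim = 32,
                            samples_per_class = 200, seed = 11)
  })
}

# alternating 5-epoch fit on the 8-class world
fx_fit8 <- function() {
  fx("fit8", function() {
    catsnet(fx_world8()$features_by_class, d_c = 8, hidden = c(16, 16),
            config = cats_train_config(seed = 5))
  })
}

# two-hyper-category world and a reference-dimension (d_c = 20) fit,
# used by the concept-space probes
fx_hyper <- function() {
  fx("hyper", function() {
    make_hypercategory_world(n_hyper = 2, classes_per_hyper = 4,
                             feature_dim = 32, samples_per_class = 100,
                             seed = 13)
  })
}

fx_hyperfit <- function() {
  fx("hyperfit", function() {
    catsnet(fx_hyper()$features_by_class, d_c = 20, hidden = c(16, 16),
            config = cats_train_config(seed = 14))
  })
}

# small untrained network with biases and running stats jittered off the
# exact ReLU kinks (for gradient checks)
fx_generic_net <- function(feature_dim = 6, d_c = 3, hidden = c(5, 4),
                           seed = 77) {
  set.seed(seed)
  net <- cats_network(feature_dim, d_c, hidden)
  for (l in seq_len(net$L)) {
    net$ts[[l]]$b <- stats::rnorm(length(net$ts[[l]]$b), sd = 0.1)
    net$ca[[l]]$b <- stats::rnorm(length(net$ca[[l]]$b), sd = 0.1)
    if (l < net$L) {
      net$ts[[l]]$rm <- stats::rnorm(length(net$ts[[l]]$rm), sd = 0.1)
      net$ts[[l]]$rv <- stats::runif(length(net$ts[[l]]$rv), 0.5, 1.5)
      net$ca[[l]]$rm <- stats::rnorm(length(net$ca[[l]]$rm), sd = 0.1)
      net$ca[[l]]$rv <- stats::runif(length(net$ca[[l]]$rv), 0.5, 1.5)
    }
  }
  net
}

# independent standard forward pass of the ungated task-solving perceptron,
# written against the layer equations directly (oracle for the
# identity-gate equivalence)
ts_only_forward <- function(net, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  h <- x
  for (l in seq_len(net$L)) {
    ts <- net$ts[[l]]
    o <- h %*% t(ts$W) + matrix(ts$b, nrow(h), length(ts$b), byrow = TRUE)
    if (l < net$L) {
      xhat <- sweep(sweep(o, 2, ts$rm, "-"), 2, 1 / sqrt(ts$rv + 1e-5), "*")
      h <- pmax(sweep(sweep(xhat, 2, ts$gamma, "*"), 2, ts$beta, "+"), 0)
    } else {
      h <- o
    }
  }
  h
}

# random symmetric zero-diagonal RDM from random embeddings
random_rdm <- function(n_items, seed) {
  set.seed(seed)
  as.matrix(stats::dist(matrix(stats::rnorm(n_items * 4), n_items, 4)))
}
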