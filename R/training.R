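#' Training configuration
#'
#' Collects the tunable settings of the alternating two-phase optimization.
#' Defaults follow the reference procedure: 5 epochs, uniform concept noise
#' of amplitude 0.1, half of the samples paired with a non-corresponding
#' concept, adaptive-moment optimization with learning rate 1e-3 for the
#' network phase and 1e-2 for the concept phase.
#'
#' @param epochs number of alternating rounds (each = one network-learning
#'   pass followed by one concept-learning pass).
#' @param noise_amplitude half-width of the uniform noise injected into each
#'   concept element during training (never at evaluation).
#' @param negative_fraction fraction of samples paired with a wrong concept
#'   and the label `No`; must lie in `[0, 1)`.
#' @param lr_network,lr_concept Adam learning rates for the two phases.
#' @param batch_size minibatch size (must be >= 2 for batch normalization).
#' @param seed integer seed controlling triplet building, noise and batching.
#' @param mode `"alternating"` (phases in turn) or `"joint"` (both parameter
#'   groups updated simultaneously).
#' @param resample_negatives rebuild the triplet set with fresh random
#'   negative assignments each epoch (default) or freeze the first set.
#' @param concept_init `"normal"` (standard normal entries) or `"uniform"`
#'   (entries in `[-1, 1]`) for the initial concept vectors.
#' @param concept_init_scale multiplier on the initial concept vectors.
#'   1 reproduces the reference initialization; small values (e.g. 0.1) let
#'   the gradient-driven geometry dominate the initial random geometry,
#'   which matters when concept-space structure itself is analyzed after
#'   only a few desk-scale epochs.
#' @return a list of class `cats_train_config`.
#' @export
cats_train_config <- function(epochs = 5L, noise_amplitude = 0.1,
                              negative_fraction = 0.5,
                              lr_network = 1e-3, lr_concept = 1e-2,
                              batch_size = 32L, seed = 1L,
                              mode = c("alternating", "joint"),
                              resample_negatives = TRUE,
                              concept_init = c("normal", "uniform"),
                              concept_init_scale = 1) {
  mode <- match.arg(mode)
  concept_init <- match.arg(concept_init)
  if (concept_init_scale <= 0) {
    stop("concept_init_scale must be > 0", call. = FALSE)
  }
  if (negative_fraction < 0 || negative_fraction >= 1) {
    stop("negative_fraction must lie in [0, 1)", call. = FALSE)
  }
  if (noise_amplitude < 0) stop("noise_amplitude must be >= 0", call. = FALSE)
  if (epochs < 0) stop("epochs must be >= 0", call. = FALSE)
  if (batch_size < 2) stop("batch_size must be >= 2", call. = FALSE)
  structure(list(epochs = as.integer(epochs),
                 noise_amplitude = noise_amplitude,
                 negative_fraction = negative_fraction,
                 lr_network = lr_network, lr_concept = lr_concept,
                 batch_size = as.integer(batch_size), seed = as.integer(seed),
                 mode = mode, resample_negatives = resample_negatives,
                 concept_init = concept_init,
                 concept_init_scale = concept_init_scale),
            class = "cats_train_config")
}

#' Random initial concept vectors
#'
#' One concept vector per category, sampled in a `d_c`-dimensional real
#' vector space (standard normal by default, uniform on `[-1,1]` optional).
#'
#' @param class_ids character vector of category labels.
#' @param d_c concept length.
#' @param init `"normal"` or `"uniform"`.
#' @param seed optional integer seed.
#' @return matrix with one named row per category.
#' @export
init_concepts <- function(class_ids, d_c, init = c("normal", "uniform"),
                          seed = NULL) {
  init <- match.arg(init)
  if (!is.null(seed)) set.seed(seed)
  k <- length(class_ids)
  vals <- if (init == "normal") stats::rnorm(k * d_c) else
    stats::runif(k * d_c, -1, 1)
  matrix(vals, k, d_c, dimnames = list(class_ids, NULL))
}

#' Build the feature-concept-label triplet dataset
#'
#' Converts per-class feature vectors into the triplet training units: a
#' `1 - negative_fraction` share of each class's samples is paired with the
#' class's own concept and the label `Yes`; the rest are paired with the
#' concept of a uniformly drawn different class and labelled `No`.
#'
#' @param features_by_class named list of `n_i x feature_dim` matrices.
#' @param concepts concept matrix with one named row per class (only the
#'   row names are consulted here; concept values are looked up at train
#'   time so that the concept-learning phase always sees current vectors).
#' @param negative_fraction fraction of `No` pairings per class.
#' @param seed optional integer seed; the assignment is deterministic
#'   given it.
#' @return list of class `cats_triplets` with elements `features` (stacked
#'   matrix), `true_id`, `concept_id`, `label` (factor `No`/`Yes`).
#' @export
build_triplets <- function(features_by_class, concepts,
                           negative_fraction = 0.5, seed = NULL) {
  classes <- names(features_by_class)
  if (is.null(classes) || any(!nzchar(classes))) {
    stop("features_by_class must be a named list", call. = FALSE)
  }
  missing <- setdiff(classes, rownames(concepts))
  if (length(missing)) {
    stop("no concept for class(es): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (length(classes) < 2L && negative_fraction > 0) {
    stop("negative sampling needs at least 2 classes", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  feats <- vector("list", length(classes))
  true_id <- concept_id <- vector("list", length(classes))
  label <- vector("list", length(classes))
  for (i in seq_along(classes)) {
    cl <- classes[i]
    xm <- features_by_class[[cl]]
    if (is.null(dim(xm))) xm <- matrix(xm, nrow = 1L)
    n <- nrow(xm)
    n_neg <- round(n * negative_fraction)
    neg_rows <- if (n_neg > 0) sample.int(n, n_neg) else integer(0)
    cid <- rep(cl, n)
    if (n_neg > 0) {
      others <- setdiff(classes, cl)
      cid[neg_rows] <- others[sample.int(length(others), n_neg,
                                         replace = TRUE)]
    }
    feats[[i]] <- xm
    true_id[[i]] <- rep(cl, n)
    concept_id[[i]] <- cid
    label[[i]] <- ifelse(cid == cl, "Yes", "No")
  }
  structure(list(features = do.call(rbind, feats),
                 true_id = unlist(true_id),
                 concept_id = unlist(concept_id),
                 label = factor(unlist(label), levels = c("No", "Yes"))),
            class = "cats_triplets")
}

#' @export
print.cats_triplets <- function(x, ...) {
  cat(sprintf("triplet set: %d samples (%d Yes / %d No), %d classes\n",
              length(x$label), sum(x$label == "Yes"), sum(x$label == "No"),
              length(unique(x$true_id))))
  invisible(x)
}

#' Inject uniform noise into concept vectors
#'
#' Perturbs each element independently by a `Uniform(-amplitude, amplitude)`
#' draw; the input is not modified. Noise is used during both training
#' phases and never at evaluation.
#'
#' @param concept numeric vector or matrix of concept values.
#' @param amplitude noise half-width (>= 0).
#' @param seed optional integer seed.
#' @return perturbed copy with the same shape.
#' @export
inject_noise <- function(concept, amplitude, seed = NULL) {
  if (amplitude < 0) stop("noise amplitude must be >= 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  if (amplitude == 0) return(concept)
  concept + stats::runif(length(concept), -amplitude, amplitude)
}

## one pass over the triplets; `update` selects which parameter group moves.
## Concept lookups index the current concept matrix by concept_id, so both
## phases and the joint mode share this loop.
run_epoch <- function(net, concepts, triplets, config, update = c("network",
                      "concepts", "both"), opt_net = NULL, opt_con = NULL,
                      epoch_tag = NA_integer_) {
  update <- match.arg(update)
  n <- length(triplets$label)
  losses <- numeric(0)
  if (n == 0L) {
    return(list(net = net, concepts = concepts, losses = losses,
                opt_net = opt_net, opt_con = opt_con))
  }
  ord <- sample.int(n)
  labels <- as.integer(triplets$label)  # 1 = No, 2 = Yes
  bs <- config$batch_size
  nb <- ceiling(n / bs)
  batches <- lapply(seq_len(nb),
                    function(i) ord[((i - 1L) * bs + 1L):min(i * bs, n)])
  ## batch normalization cannot form statistics on a single sample; fold a
  ## trailing singleton batch into its predecessor
  last <- length(batches)
  if (last > 1L && length(batches[[last]]) == 1L) {
    batches[[last - 1L]] <- c(batches[[last - 1L]], batches[[last]])
    batches[[last]] <- NULL
  }
  training_bn <- update %in% c("network", "both")
  for (bi in seq_along(batches)) {
    idx <- batches[[bi]]
    if (length(idx) == 1L && training_bn) {
      stop("cannot train with batch size 1 (degenerate batch statistics)",
           call. = FALSE)
    }
    c0 <- concepts[triplets$concept_id[idx], , drop = FALSE]
    c0 <- inject_noise(c0, config$noise_amplitude)
    fw <- cats_forward(net, triplets$features[idx, , drop = FALSE], c0,
                       training = training_bn)
    net <- fw$net
    sx <- softmax_xent(fw$scores, labels[idx])
    if (!is.finite(sx$loss)) {
      stop(sprintf("training diverged (non-finite loss) at epoch %s, batch %d",
                   epoch_tag, bi), call. = FALSE)
    }
    losses <- c(losses, sx$loss)
    gr <- cats_grads(net, fw$cache, sx$dscores)
    if (update %in% c("network", "both")) {
      st <- adam_step(opt_net, trainable_params(net), trainable_grads(gr),
                      config$lr_network)
      opt_net <- st$state
      net <- set_trainable_params(net, st$params)
    }
    if (update %in% c("concepts", "both")) {
      cgrad <- concepts * 0
      agg <- rowsum(gr$dC0, triplets$concept_id[idx])
      cgrad[rownames(agg), ] <- agg
      st <- adam_step(opt_con, concepts, cgrad, config$lr_concept)
      opt_con <- st$state
      concepts <- st$params
    }
  }
  list(net = net, concepts = concepts, losses = losses,
       opt_net = opt_net, opt_con = opt_con)
}

#' Network-learning phase
#'
#' One epoch in which the concept vectors fed to the CA module are held
#' fixed while all network parameters of both modules are updated by
#' back-propagated cross-entropy gradients. Uniform noise is injected into
#' the concept inputs; the concept matrix itself is returned untouched.
#'
#' @param net a `cats_network`.
#' @param concepts concept matrix (rows named by class).
#' @param triplets a `cats_triplets` set.
#' @param config a `cats_train_config`.
#' @param opt_state optional Adam state carried across epochs.
#' @return list with updated `net`, per-batch `losses`, and `opt_state`.
#' @export
train_network_phase <- function(net, concepts, triplets, config,
                                opt_state = NULL) {
  if (is.null(opt_state)) opt_state <- adam_new()
  res <- run_epoch(net, concepts, triplets, config, update = "network",
                   opt_net = opt_state)
  list(net = res$net, losses = res$losses, opt_state = res$opt_net)
}

#' Concept-learning phase
#'
#' Mirror image of the network phase: all network parameters are frozen
#' (byte-identical before and after, including normalization statistics,
#' which run in inference mode) and only the concept vectors move along the
#' back-propagated gradients.
#'
#' @inheritParams train_network_phase
#' @return list with updated `concepts`, per-batch `losses`, `opt_state`.
#' @export
train_concept_phase <- function(net, concepts, triplets, config,
                                opt_state = NULL) {
  if (is.null(opt_state)) opt_state <- adam_new()
  res <- run_epoch(net, concepts, triplets, config, update = "concepts",
                   opt_con = opt_state)
  list(concepts = res$concepts, losses = res$losses, opt_state = res$opt_con)
}

#' Alternating two-phase training
#'
#' Runs `config$epochs` rounds; in each round the triplet set is rebuilt
#' (fresh random negative assignment unless `resample_negatives = FALSE`),
#' one network-learning phase is run, then one concept-learning phase. In
#' `mode = "joint"` a single loop updates both parameter groups
#' simultaneously. The run is fully reproducible from `config$seed`.
#'
#' @inheritParams train_network_phase
#' @param features_by_class named list of training feature matrices.
#' @param holdout_features_by_class optional held-out features; per-epoch
#'   macro accuracy is recorded when given.
#' @return list with `net`, `concepts`, and `history` (data frame of epoch,
#'   phase, mean loss, holdout accuracy).
#' @export
train_alternating <- function(net, concepts, features_by_class, config,
                              holdout_features_by_class = NULL) {
  set.seed(config$seed)
  history <- data.frame(epoch = integer(0), phase = character(0),
                        loss = numeric(0), holdout_accuracy = numeric(0))
  if (config$epochs == 0L) {
    return(list(net = net, concepts = concepts, history = history))
  }
  opt_net <- adam_new()
  opt_con <- adam_new()
  triplets <- NULL
  for (ep in seq_len(config$epochs)) {
    if (is.null(triplets) || config$resample_negatives) {
      triplets <- build_triplets(features_by_class, concepts,
                                 config$negative_fraction)
    }
    if (config$mode == "alternating") {
      res <- run_epoch(net, concepts, triplets, config, "network",
                       opt_net = opt_net, epoch_tag = ep)
      net <- res$net; opt_net <- res$opt_net
      loss_net <- mean(res$losses)
      res <- run_epoch(net, concepts, triplets, config, "concepts",
                       opt_con = opt_con, epoch_tag = ep)
      concepts <- res$concepts; opt_con <- res$opt_con
      loss_con <- mean(res$losses)
      acc <- NA_real_
      if (!is.null(holdout_features_by_class)) {
        acc <- evaluate_concepts(net, concepts,
                                 holdout_features_by_class)$macro
      }
      history <- rbind(history,
                       data.frame(epoch = ep,
                                  phase = c("network", "concept"),
                                  loss = c(loss_net, loss_con),
                                  holdout_accuracy = c(NA_real_, acc)))
    } else {
      res <- run_epoch(net, concepts, triplets, config, "both",
                       opt_net = opt_net, opt_con = opt_con, epoch_tag = ep)
      net <- res$net; concepts <- res$concepts
      opt_net <- res$opt_net; opt_con <- res$opt_con
      acc <- NA_real_
      if (!is.null(holdout_features_by_class)) {
        acc <- evaluate_concepts(net, concepts,
                                 holdout_features_by_class)$macro
      }
      history <- rbind(history,
                       data.frame(epoch = ep, phase = "joint",
                                  loss = mean(res$losses),
                                  holdout_accuracy = acc))
    }
  }
  list(net = net, concepts = concepts, history = history)
}

#' Per-category judgment accuracy
#'
#' Evaluates a trained instance on a balanced triplet set: every evaluation
#' sample is judged once against its own concept (correct answer `Yes`) and
#' once against a uniformly drawn non-corresponding concept (correct answer
#' `No`). No noise is added to the concept vectors. Accuracy is reported per
#' category and as the macro mean.
#'
#' @param net a `cats_network`.
#' @param concepts concept matrix.
#' @param eval_features_by_class named list of evaluation feature matrices.
#' @param seed optional seed for the negative assignment.
#' @return list with `per_class` (named accuracies) and `macro`.
#' @export
evaluate_concepts <- function(net, concepts, eval_features_by_class,
                              seed = NULL) {
  classes <- names(eval_features_by_class)
  missing <- setdiff(classes, rownames(concepts))
  if (length(missing)) {
    stop("class(es) missing from the concept set: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  acc <- numeric(length(classes))
  names(acc) <- classes
  for (cl in classes) {
    xm <- eval_features_by_class[[cl]]
    if (is.null(dim(xm))) xm <- matrix(xm, nrow = 1L)
    n <- nrow(xm)
    others <- setdiff(classes, cl)
    wrong <- others[sample.int(length(others), n, replace = TRUE)]
    yes_dec <- cats_decide(net, xm, concepts[rep(cl, n), , drop = FALSE])
    no_dec <- cats_decide(net, xm, concepts[wrong, , drop = FALSE])
    acc[cl] <- (sum(yes_dec == "Yes") + sum(no_dec == "No")) / (2 * n)
  }
  list(per_class = acc, macro = mean(acc))
}

#' Fit a concept-gated network to labelled feature data
#'
#' The top-level fitting interface: splits off a per-class holdout set,
#' initializes the dual network and one random concept vector per category,
#' runs the alternating (or joint) two-phase optimization, and evaluates
#' per-category Yes/No judgment accuracy on the holdout.
#'
#' @param features_by_class named list of `n_i x feature_dim` matrices, one
#'   per category (e.g. backbone embeddings, or the synthetic generator's
#'   output).
#' @param d_c concept-vector length (20 in the reference setup).
#' @param hidden TS hidden-layer widths.
#' @param config a [cats_train_config()].
#' @param holdout fraction of each class reserved for evaluation.
#' @return an object of class `catsnet` with components `network`,
#'   `concepts`, `history`, `eval`, `config`, `dims`.
#' @examples
#' world <- generate_class_features(n_classes = 4, feature_dim = 16,
#'                                  samples_per_class = 40, seed = 2)
#' fit <- catsnet(world$features_by_class, d_c = 4, hidden = c(8, 8),
#'                config = cats_train_config(epochs = 2, seed = 3))
#' fit
#' @export
catsnet <- function(features_by_class, d_c = 20L, hidden = c(100L, 100L),
                    config = cats_train_config(), holdout = 0.25) {
  stopifnot(is.list(features_by_class), length(features_by_class) >= 2L)
  feature_dim <- ncol(features_by_class[[1L]])
  set.seed(config$seed)
  train_set <- eval_set <- list()
  for (cl in names(features_by_class)) {
    xm <- features_by_class[[cl]]
    n <- nrow(xm)
    n_hold <- if (holdout > 0) max(1L, round(n * holdout)) else 0L
    hold <- if (n_hold > 0) sample.int(n, n_hold) else integer(0)
    train_set[[cl]] <- xm[setdiff(seq_len(n), hold), , drop = FALSE]
    if (n_hold > 0) eval_set[[cl]] <- xm[hold, , drop = FALSE]
  }
  net <- cats_network(feature_dim, d_c, hidden)
  concepts <- init_concepts(names(features_by_class), d_c,
                            init = config$concept_init) *
    (config$concept_init_scale %||% 1)
  fit <- train_alternating(net, concepts, train_set, config,
                           holdout_features_by_class =
                             if (length(eval_set)) eval_set else NULL)
  ev <- if (length(eval_set)) {
    evaluate_concepts(fit$net, fit$concepts, eval_set)
  } else NULL
  structure(list(network = fit$net, concepts = fit$concepts,
                 history = fit$history, eval = ev, config = config,
                 dims = list(feature_dim = feature_dim, d_c = d_c,
                             hidden = hidden),
                 holdout_set = if (length(eval_set)) eval_set else NULL,
                 call = match.call()),
            class = "catsnet")
}

#' @export
print.catsnet <- function(x, ...) {
  cat("Concept-gated network fit\n")
  cat("  TS module:", paste(x$network$dims_ts, collapse = "-"),
      "| concept length:", x$dims$d_c, "\n")
  cat("  categories:", nrow(x$concepts),
      "| epochs:", x$config$epochs, "| mode:", x$config$mode, "\n")
  if (!is.null(x$eval)) {
    cat(sprintf("  holdout macro accuracy: %.3f\n", x$eval$macro))
  }
  invisible(x)
}

#' @export
summary.catsnet <- function(object, ...) {
  res <- list(dims = object$dims, config = object$config,
              history = object$history, eval = object$eval,
              n_classes = nrow(object$concepts))
  class(res) <- "summary.catsnet"
  res
}

#' @export
print.summary.catsnet <- function(x, ...) {
  cat("Concept-gated network fit\n")
  cat("  feature dim:", x$dims$feature_dim, "| hidden:",
      paste(x$dims$hidden, collapse = "-"), "| d_c:", x$dims$d_c, "\n")
  cat("  classes:", x$n_classes, "| mode:", x$config$mode,
      "| epochs:", x$config$epochs, "\n")
  if (nrow(x$history)) {
    cat("  final losses by phase:\n")
    tail_h <- x$history[x$history$epoch == max(x$history$epoch), ]
    for (i in seq_len(nrow(tail_h))) {
      cat(sprintf("    %s: %.4f\n", tail_h$phase[i], tail_h$loss[i]))
    }
  }
  if (!is.null(x$eval)) {
    cat(sprintf("  holdout macro accuracy: %.3f\n", x$eval$macro))
    print(round(x$eval$per_class, 3))
  }
  invisible(x)
}

#' @export
coef.catsnet <- function(object, ...) object$concepts

#' Predict Yes/No judgments from a fitted network
#'
#' @param object a `catsnet` fit.
#' @param features feature matrix (rows = samples) or single vector.
#' @param concept a category id (row of `coef(object)`) or an explicit
#'   concept vector; recycled over the batch.
#' @param type `"decision"` for the factor of judgments, `"scores"` for the
#'   raw 2-column score matrix (`No`, `Yes`).
#' @param ... unused.
#' @return factor or matrix according to `type`.
#' @export
predict.catsnet <- function(object, features, concept,
                            type = c("decision", "scores"), ...) {
  type <- match.arg(type)
  if (is.character(concept) && length(concept) == 1L) {
    if (!concept %in% rownames(object$concepts)) {
      stop("unknown category id: ", concept, call. = FALSE)
    }
    concept <- object$concepts[concept, ]
  }
  fw <- cats_forward(object$network, features, concept, training = FALSE)
  if (type == "decision") fw$decision else {
    colnames(fw$scores) <- c("No", "Yes")
    fw$scores
  }
}

#' @export
plot.catsnet <- function(x, ...) {
  h <- x$history
  if (!nrow(h)) {
    warning("no training history to plot")
    return(invisible(x))
  }
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  phases <- unique(h$phase)
  cols <- stats::setNames(seq_along(phases) + 1L, phases)
  graphics::plot(NA, xlim = range(h$epoch), ylim = range(h$loss),
                 xlab = "epoch", ylab = "mean cross-entropy loss",
                 main = "training loss")
  for (ph in phases) {
    hh <- h[h$phase == ph, ]
    graphics::lines(hh$epoch, hh$loss, col = cols[ph], type = "b", pch = 16)
  }
  graphics::legend("topright", legend = phases, col = cols, lty = 1, bty = "n")
  acc <- h[!is.na(h$holdout_accuracy), ]
  if (nrow(acc)) {
    graphics::plot(acc$epoch, acc$holdout_accuracy, type = "b", pch = 16,
                   ylim = c(0, 1), xlab = "epoch", ylab = "macro accuracy",
                   main = "holdout accuracy")
    graphics::abline(h = 0.5, lty = 2)
  }
  invisible(x)
}
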