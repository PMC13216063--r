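#' Repelling loss between a candidate concept and existing concepts
#'
#' `L_rep(C, C_old, tau) = sum_i exp(-||C_i - C||^2 / tau)`: an
#' exponential-of-negative-squared-distance penalty that pushes a newly
#' optimized concept vector away from the already-learned ones. It depends
#' only on pairwise distances, so it is invariant to rigid rotations of the
#' whole concept set. An empty `C_old` gives 0.
#'
#' @param concept numeric vector, the candidate concept `C`.
#' @param old_concepts matrix of existing concepts (rows), possibly empty.
#' @param tau temperature (> 0); default 0.01.
#' @return nonnegative scalar.
#' @examples
#' repelling_loss(c(0.5), rbind(0, 1), tau = 1)  # 2 * exp(-0.25)
#' @export
repelling_loss <- function(concept, old_concepts, tau = 0.01) {
  if (tau <= 0) stop("tau must be > 0", call. = FALSE)
  if (is.null(old_concepts) || NROW(old_concepts) == 0L) return(0)
  old_concepts <- matrix(old_concepts, ncol = length(concept))
  d2 <- rowSums(sweep(old_concepts, 2L, concept)^2)
  sum(exp(-d2 / tau))
}

## gradient of the repelling loss with respect to the candidate concept
repelling_grad <- function(concept, old_concepts, tau) {
  if (is.null(old_concepts) || NROW(old_concepts) == 0L) {
    return(numeric(length(concept)))
  }
  old_concepts <- matrix(old_concepts, ncol = length(concept))
  diff <- sweep(old_concepts, 2L, concept)       # rows: C_i - C
  w <- exp(-rowSums(diff^2) / tau)
  colSums(diff * w) * (2 / tau)
}

#' Configuration for repelling-loss concept expansion
#'
#' Reference hyperparameters of the few-shot concept-expansion objective
#' `L = L_CE(x_new, Yes | C) + alpha L_CE(x_old, No | C)
#'    + beta L_rep(C, C_old, tau)`.
#'
#' @param tau repelling temperature (> 0).
#' @param alpha weight of the old-shot (label `No`) cross-entropy term.
#' @param beta weight of the repelling term.
#' @param lr Adam learning rate for the concept updates.
#' @param n_new_shots positive shots drawn from the target class.
#' @param n_old_shots_per_class negative shots per other class.
#' @param steps optimization steps per expansion run.
#' @return list of class `cats_repelling_config`.
#' @export
repelling_config <- function(tau = 0.01, alpha = 0.5, beta = 0.001,
                             lr = 0.01, n_new_shots = 2L,
                             n_old_shots_per_class = 1L, steps = 600L) {
  if (tau <= 0) stop("tau must be > 0", call. = FALSE)
  structure(list(tau = tau, alpha = alpha, beta = beta, lr = lr,
                 n_new_shots = as.integer(n_new_shots),
                 n_old_shots_per_class = as.integer(n_old_shots_per_class),
                 steps = as.integer(steps)),
            class = "cats_repelling_config")
}

#' Expand a class's concept by few-shot concept-only optimization
#'
#' With the network parameters frozen, optimizes `n_expanded` fresh
#' randomly initialized concept vectors for `target_class`, each minimizing
#' the combined objective: cross-entropy of the new-class shots toward
#' `Yes`, `alpha`-weighted cross-entropy of old-class shots toward `No`,
#' and the `beta`-weighted repelling loss against all other classes'
#' concepts. All `n_expanded` candidates are optimized jointly as one batch
#' (they are mutually independent).
#'
#' @param net a trained `cats_network` (frozen).
#' @param concepts concept matrix; rows other than `target_class` act as
#'   `C_old` for the repelling term.
#' @param target_class class id being expanded.
#' @param shots list with `new` (matrix of positive feature rows) and
#'   optionally `old` (matrix of negative feature rows); when `old` is
#'   missing the `alpha` term is dropped.
#' @param config a [repelling_config()].
#' @param n_expanded number of expansion vectors to produce.
#' @param seed optional integer seed (fresh random init per vector).
#' @param init_mean,init_sd location and scale of the random initialization
#'   of each expansion vector. The defaults (`0`, `1`) are the standard
#'   normal; passing the moments of the learned concept set keeps the
#'   expansions in-distribution, which matters when the learned concepts
#'   occupy a small region of the concept space.
#' @return matrix `n_expanded x d_c` with attribute `final_loss`.
#' @export
expand_concepts <- function(net, concepts, target_class, shots,
                            config = repelling_config(), n_expanded = 1L,
                            seed = NULL, init_mean = 0, init_sd = 1) {
  if (!is.null(seed)) set.seed(seed)
  d_c <- net$d_c
  old <- concepts[setdiff(rownames(concepts), target_class), , drop = FALSE]
  x_new <- shots$new
  if (is.null(dim(x_new))) x_new <- matrix(x_new, nrow = 1L)
  x_old <- shots$old
  if (!is.null(x_old) && is.null(dim(x_old))) x_old <- matrix(x_old, nrow = 1L)
  n_new <- nrow(x_new)
  n_old <- if (is.null(x_old)) 0L else nrow(x_old)
  X <- rbind(x_new, if (n_old) x_old)
  lab1 <- c(rep(2L, n_new), rep(1L, n_old))       # Yes for new, No for old
  wts1 <- c(rep(1 / n_new, n_new),
            if (n_old) rep(config$alpha / n_old, n_old))
  m <- nrow(X)
  Xb <- X[rep(seq_len(m), n_expanded), , drop = FALSE]
  labs <- rep(lab1, n_expanded)
  wts <- rep(wts1, n_expanded)
  group <- rep(seq_len(n_expanded), each = m)
  C <- matrix(stats::rnorm(n_expanded * d_c), n_expanded, d_c)
  C <- sweep(sweep(C, 2L, rep_len(init_sd, d_c), "*"),
             2L, rep_len(init_mean, d_c), "+")
  opt <- adam_new()
  final_loss <- numeric(n_expanded)
  for (step in seq_len(config$steps)) {
    C0 <- C[group, , drop = FALSE]
    fw <- cats_forward(net, Xb, C0, training = FALSE)
    mx <- apply(fw$scores, 1L, max)
    es <- exp(fw$scores - mx)
    p <- es / rowSums(es)
    idx <- cbind(seq_len(nrow(p)), labs)
    ce_terms <- -log(pmax(p[idx], 1e-300)) * wts
    dscores <- p
    dscores[idx] <- dscores[idx] - 1
    dscores <- dscores * wts
    if (any(!is.finite(ce_terms))) {
      stop("concept expansion diverged (non-finite loss) at step ", step,
           call. = FALSE)
    }
    gr <- cats_grads(net, fw$cache, dscores)
    cgrad <- rowsum(gr$dC0, group)
    rep_losses <- numeric(n_expanded)
    if (config$beta > 0 && nrow(old)) {
      for (i in seq_len(n_expanded)) {
        rep_losses[i] <- repelling_loss(C[i, ], old, config$tau)
        cgrad[i, ] <- cgrad[i, ] +
          config$beta * repelling_grad(C[i, ], old, config$tau)
      }
    }
    final_loss <- as.numeric(rowsum(ce_terms, group)) +
      config$beta * rep_losses
    st <- adam_step(opt, C, cgrad, config$lr)
    opt <- st$state
    C <- st$params
  }
  rownames(C) <- paste0(target_class, "_exp", seq_len(n_expanded))
  attr(C, "final_loss") <- final_loss
  C
}

#' Configuration of the concept-translation network
#'
#' Reference settings: 10 hidden layers of 500 ReLU units, dropout 0.3 on
#' hidden activations during fitting only, mean-squared-error loss, Adam at
#' learning rate 1e-4 decayed by 0.5 every 10 epochs, 200 epochs. Tests and
#' the desk-scale protocol use a shrunken variant.
#'
#' @param hidden_layers number of hidden layers.
#' @param hidden_width units per hidden layer.
#' @param dropout dropout probability on hidden activations, in `[0, 1)`.
#' @param epochs training epochs.
#' @param lr initial Adam learning rate.
#' @param lr_decay multiplicative decay factor.
#' @param lr_decay_every epochs between decays.
#' @param batch_size minibatch size.
#' @return list of class `cats_translation_config`.
#' @export
translation_config <- function(hidden_layers = 10L, hidden_width = 500L,
                               dropout = 0.3, epochs = 200L, lr = 1e-4,
                               lr_decay = 0.5, lr_decay_every = 10L,
                               batch_size = 32L) {
  if (dropout < 0 || dropout >= 1) {
    stop("dropout must lie in [0, 1)", call. = FALSE)
  }
  structure(list(hidden_layers = as.integer(hidden_layers),
                 hidden_width = as.integer(hidden_width),
                 dropout = dropout, epochs = as.integer(epochs), lr = lr,
                 lr_decay = lr_decay,
                 lr_decay_every = as.integer(lr_decay_every),
                 batch_size = as.integer(batch_size)),
            class = "cats_translation_config")
}

#' Fit the teacher-to-student concept translation network
#'
#' Trains a feed-forward ReLU regressor mapping each teacher concept vector
#' (typically the expanded set, many per class) to the corresponding single
#' student concept vector, minimizing mean squared error under the stated
#' learning-rate schedule with dropout active only during fitting.
#'
#' @param teacher_by_class named list: per class, a matrix of teacher
#'   concept vectors (original + expansions).
#' @param student_concepts matrix of student concepts with rows named by
#'   the same classes.
#' @param config a [translation_config()].
#' @param seed integer seed (controls init, batching, dropout masks).
#' @return object of class `cats_translation` with `layers`, `classes`,
#'   `loss_history` (per epoch), `lr_history`.
#' @export
fit_translation <- function(teacher_by_class, student_concepts,
                            config = translation_config(), seed = 1L) {
  cls <- names(teacher_by_class)
  missing <- setdiff(cls, rownames(student_concepts))
  if (length(missing) || is.null(cls)) {
    stop("teacher/student class sets do not match: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  set.seed(seed)
  X <- do.call(rbind, lapply(cls, function(cl) {
    m <- teacher_by_class[[cl]]
    if (is.null(dim(m))) matrix(m, nrow = 1L) else m
  }))
  Y <- do.call(rbind, lapply(cls, function(cl) {
    m <- teacher_by_class[[cl]]
    n <- if (is.null(dim(m))) 1L else nrow(m)
    matrix(student_concepts[cl, ], n, ncol(student_concepts), byrow = TRUE)
  }))
  d_in <- ncol(X); d_out <- ncol(Y)
  dims <- c(d_in, rep(config$hidden_width, config$hidden_layers), d_out)
  nlay <- length(dims) - 1L
  layers <- lapply(seq_len(nlay), function(l) {
    list(W = matrix(stats::rnorm(dims[l + 1L] * dims[l],
                                 sd = sqrt(2 / dims[l])),
                    dims[l + 1L], dims[l]),
         b = numeric(dims[l + 1L]))
  })
  opt <- adam_new()
  n <- nrow(X)
  loss_history <- numeric(config$epochs)
  lr_history <- numeric(config$epochs)
  for (ep in seq_len(config$epochs)) {
    lr <- config$lr * config$lr_decay^((ep - 1L) %/% config$lr_decay_every)
    lr_history[ep] <- lr
    ord <- sample.int(n)
    bs <- config$batch_size
    nb <- ceiling(n / bs)
    ep_loss <- 0
    for (bi in seq_len(nb)) {
      idx <- ord[((bi - 1L) * bs + 1L):min(bi * bs, n)]
      xb <- X[idx, , drop = FALSE]
      acts <- vector("list", nlay)
      masks <- vector("list", nlay)
      h <- xb
      for (l in seq_len(nlay)) {
        o <- h %*% t(layers[[l]]$W) +
          matrix(layers[[l]]$b, nrow(h), dims[l + 1L], byrow = TRUE)
        if (l < nlay) {
          h <- relu(o)
          if (config$dropout > 0) {
            keep <- matrix(stats::rbinom(length(h), 1L,
                                         1 - config$dropout) /
                             (1 - config$dropout),
                           nrow(h), ncol(h))
            h <- h * keep
            masks[[l]] <- keep * (o > 0)
          } else {
            masks[[l]] <- (o > 0) * 1
          }
        } else {
          h <- o
        }
        acts[[l]] <- h
      }
      err <- h - Y[idx, , drop = FALSE]
      ep_loss <- ep_loss + sum(err^2)
      dout <- 2 * err / length(err)
      grads <- vector("list", nlay)
      for (l in rev(seq_len(nlay))) {
        inp <- if (l == 1L) xb else acts[[l - 1L]]
        grads[[l]] <- list(W = t(dout) %*% inp, b = colSums(dout))
        if (l > 1L) {
          dout <- (dout %*% layers[[l]]$W) * masks[[l - 1L]]
        }
      }
      st <- adam_step(opt, layers, grads, lr)
      opt <- st$state
      layers <- st$params
    }
    loss_history[ep] <- ep_loss / (n * d_out)
  }
  structure(list(layers = layers, dims = dims, classes = cls,
                 config = config, loss_history = loss_history,
                 lr_history = lr_history),
            class = "cats_translation")
}

#' @export
print.cats_translation <- function(x, ...) {
  cat("concept translation network:", paste(x$dims, collapse = "-"), "\n")
  cat(sprintf("  trained on %d classes, %d epochs, final MSE %.4g\n",
              length(x$classes), length(x$loss_history),
              utils::tail(x$loss_history, 1)))
  invisible(x)
}

#' Map concepts through a fitted translation network
#'
#' Forward pass without dropout. With `capture_layers = TRUE` the
#' activations at the input layer, every post-ReLU hidden layer, and the
#' output layer are returned (the material of the semantic-preservation
#' analysis).
#'
#' @param object a `cats_translation`.
#' @param newdata concept matrix (rows) or single vector.
#' @param capture_layers logical.
#' @param ... unused.
#' @return translated matrix, or a list of layer activations.
#' @export
predict.cats_translation <- function(object, newdata,
                                     capture_layers = FALSE, ...) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1L)
  nlay <- length(object$layers)
  h <- newdata
  layers_out <- list(input = h)
  for (l in seq_len(nlay)) {
    o <- h %*% t(object$layers[[l]]$W) +
      matrix(object$layers[[l]]$b, nrow(h), length(object$layers[[l]]$b),
             byrow = TRUE)
    h <- if (l < nlay) relu(o) else o
    layers_out[[if (l < nlay) paste0("hidden_", l) else "output"]] <- h
  }
  if (capture_layers) layers_out else h
}

#' Transmit a held-out concept and evaluate the student
#'
#' Maps the teacher's concept for the held-out class through the trained
#' translation network and evaluates the student network's balanced Yes/No
#' judgments on held-out-class versus other-class features using only the
#' transferred vector. Raises a protocol-violation error if the held-out
#' class was part of the translation training set.
#'
#' @param teacher_concepts teacher concept matrix.
#' @param student_net the student `cats_network`.
#' @param translation a fitted `cats_translation`.
#' @param d1_class the held-out class id.
#' @param eval_features_by_class named list of evaluation features
#'   (must include `d1_class` and at least one other class).
#' @param seed optional seed for the negative draw.
#' @return list with `accuracy`, `concept` (the transferred vector),
#'   `n_eval`.
#' @export
transmit_and_evaluate <- function(teacher_concepts, student_net, translation,
                                  d1_class, eval_features_by_class,
                                  seed = NULL) {
  if (d1_class %in% translation$classes) {
    stop("protocol violation: held-out class '", d1_class,
         "' was in the translation training set", call. = FALSE)
  }
  if (!d1_class %in% rownames(teacher_concepts)) {
    stop("teacher has no concept for class ", d1_class, call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  transferred <- as.numeric(predict(translation,
                                    teacher_concepts[d1_class, ]))
  pos <- eval_features_by_class[[d1_class]]
  if (is.null(pos)) stop("no evaluation features for ", d1_class,
                         call. = FALSE)
  if (is.null(dim(pos))) pos <- matrix(pos, nrow = 1L)
  others <- setdiff(names(eval_features_by_class), d1_class)
  neg_pool <- do.call(rbind, eval_features_by_class[others])
  n <- nrow(pos)
  neg <- neg_pool[sample.int(nrow(neg_pool), n,
                             replace = nrow(neg_pool) < n), , drop = FALSE]
  dec_pos <- cats_decide(student_net, pos, transferred)
  dec_neg <- cats_decide(student_net, neg, transferred)
  acc <- (sum(dec_pos == "Yes") + sum(dec_neg == "No")) / (2 * n)
  list(accuracy = acc, concept = transferred, n_eval = 2L * n)
}

#' Layer-wise RDM preservation through the translation network
#'
#' Captures activations at the input, every post-ReLU hidden layer, and the
#' output while translating a set of probe concepts; builds a Euclidean RDM
#' per layer and reports each layer's Spearman correlation with the
#' input-layer RDM.
#'
#' @param translation a fitted `cats_translation`.
#' @param probe_concepts matrix of at least 3 probe concept vectors.
#' @return list with `correlations` (data frame: layer, rho) and `rdms`.
#' @export
layer_rdm_preservation <- function(translation, probe_concepts) {
  if (NROW(probe_concepts) < 3L) {
    stop("need at least 3 probe concepts", call. = FALSE)
  }
  acts <- predict(translation, probe_concepts, capture_layers = TRUE)
  rdms <- lapply(acts, function(a) as.matrix(stats::dist(a)))
  base <- rdms[[1L]]
  rho <- vapply(rdms, function(r) spearman_rdm(base, r), numeric(1))
  list(correlations = data.frame(layer = names(rdms), rho = unname(rho),
                                 row.names = NULL),
       rdms = rdms)
}

#' Run the full synthetic teacher-to-student communication protocol
#'
#' For each round: generate a hierarchically structured feature world;
#' train a teacher on all classes and a student on all but the held-out
#' class (cycled across rounds); expand the teacher's concepts by few-shot
#' repelling-loss optimization; fit the translation network on the shared
#' classes only; transmit the held-out concept and measure the student's
#' balanced judgment accuracy. A scrambled-translation control — the
#' translation refit with its class-to-concept outputs deranged, which
#' destroys the mapping — can be evaluated alongside.
#'
#' The defaults are the desk-scale protocol: 16 classes, 4-dimensional
#' concepts, small concept initialization (so the learned, world-driven
#' concept geometry dominates the random initial geometry after few
#' epochs), expansion vectors initialized at each class's learned concept
#' with a gentle optimization schedule (so the translation's training
#' clouds stay in the region it is queried in), and a 3 x 64 translation
#' network without dropout. The methods vignette motivates each choice;
#' reference-scale settings remain available through the config arguments.
#'
#' @param n_rounds number of teacher-student rounds.
#' @param n_classes classes in the synthetic world.
#' @param d_c concept length.
#' @param feature_dim,samples_per_class,level_scales,hidden world and
#'   network sizes (see [generate_class_features()]).
#' @param n_expanded expansion vectors per class (in addition to the
#'   original, mirroring the 1 + 96 = 97 reference decomposition at desk
#'   scale).
#' @param train_config a [cats_train_config()] template (the seed is
#'   re-derived per round).
#' @param trans_config a [translation_config()].
#' @param expand_config a [repelling_config()].
#' @param scrambled_control also evaluate the deranged-output translation.
#' @param seed master seed.
#' @return object of class `cats_communication`: data frame `rounds`
#'   (round, holdout class, transfer accuracy, scrambled accuracy, teacher
#'   and student holdout accuracy, concept-space Spearman rho), plus the
#'   summary t-test of transfer accuracy against chance 0.5.
#' @export
run_communication_rounds <- function(n_rounds = 20L, n_classes = 16L,
                                     d_c = 4L, feature_dim = 32L,
                                     samples_per_class = 60L,
                                     level_scales = c(8, 4, 1),
                                     hidden = c(16L, 16L),
                                     n_expanded = 6L,
                                     train_config = cats_train_config(
                                       concept_init_scale = 0.1),
                                     trans_config = translation_config(
                                       hidden_layers = 3L, hidden_width = 64L,
                                       epochs = 60L, lr = 1e-2, dropout = 0),
                                     expand_config = repelling_config(
                                       lr = 0.001, steps = 300L),
                                     scrambled_control = TRUE,
                                     seed = 1L) {
  set.seed(seed)
  round_seeds <- sample.int(2^31 - 1, n_rounds)
  rows <- vector("list", n_rounds)
  for (rd in seq_len(n_rounds)) {
    rs <- round_seeds[rd]
    world <- generate_class_features(n_classes = n_classes,
                                     feature_dim = feature_dim,
                                     samples_per_class = samples_per_class,
                                     level_scales = level_scales,
                                     seed = rs)
    classes <- names(world$features_by_class)
    d1 <- classes[((rd - 1L) %% n_classes) + 1L]
    cfg_t <- train_config; cfg_t$seed <- rs + 1L
    cfg_s <- train_config; cfg_s$seed <- rs + 2L
    teacher <- catsnet(world$features_by_class, d_c = d_c, hidden = hidden,
                       config = cfg_t)
    student <- catsnet(world$features_by_class[setdiff(classes, d1)],
                       d_c = d_c, hidden = hidden, config = cfg_s)
    shared <- setdiff(classes, d1)
    ## structural similarity of the two concept spaces over shared classes
    rho_struct <- spearman_rdm(
      rdm_from_vectors(teacher$concepts[shared, ], "cosine"),
      rdm_from_vectors(student$concepts[shared, ], "cosine"))
    ## teacher-side concept expansion on the shared classes (translation
    ## training data) using few-shot draws from the training features;
    ## expansions are initialized from the learned concept distribution so
    ## they populate the region the translation will be queried in
    set.seed(rs + 3L)
    concept_scale <- apply(teacher$concepts, 2L, stats::sd)
    teacher_by_class <- list()
    for (cl in shared) {
      xm <- world$features_by_class[[cl]]
      new_idx <- sample.int(nrow(xm), expand_config$n_new_shots)
      old_feats <- do.call(rbind, lapply(setdiff(classes, cl), function(oc) {
        om <- world$features_by_class[[oc]]
        om[sample.int(nrow(om), expand_config$n_old_shots_per_class), ,
           drop = FALSE]
      }))
      exp_c <- expand_concepts(teacher$network, teacher$concepts, cl,
                               shots = list(new = xm[new_idx, , drop = FALSE],
                                            old = old_feats),
                               config = expand_config,
                               n_expanded = n_expanded,
                               init_mean = teacher$concepts[cl, ],
                               init_sd = 0.3 * concept_scale)
      teacher_by_class[[cl]] <- rbind(teacher$concepts[cl, , drop = FALSE],
                                      exp_c)
    }
    translation <- fit_translation(teacher_by_class,
                                   student$concepts,
                                   config = trans_config, seed = rs + 4L)
    eval_set <- world$features_by_class
    tr <- transmit_and_evaluate(teacher$concepts, student$network,
                                translation, d1, eval_set, seed = rs + 5L)
    scr_acc <- NA_real_
    if (scrambled_control) {
      ## destroyed mapping: refit the translation with the student-side
      ## targets deranged across classes, so the map carries no class
      ## correspondence
      set.seed(rs + 6L)
      perm <- sample(length(shared))
      while (any(perm == seq_along(shared))) perm <- sample(length(shared))
      scr_targets <- student$concepts
      scr_targets[shared, ] <- student$concepts[shared[perm], ]
      scr_trans <- fit_translation(teacher_by_class, scr_targets,
                                   config = trans_config, seed = rs + 7L)
      scr <- transmit_and_evaluate(teacher$concepts, student$network,
                                   scr_trans, d1, eval_set, seed = rs + 8L)
      scr_acc <- scr$accuracy
    }
    rows[[rd]] <- data.frame(round = rd, holdout = d1,
                             transfer_accuracy = tr$accuracy,
                             scrambled_accuracy = scr_acc,
                             teacher_accuracy = teacher$eval$macro,
                             student_accuracy = student$eval$macro,
                             concept_space_rho = rho_struct)
  }
  rounds <- do.call(rbind, rows)
  tt <- stats::t.test(rounds$transfer_accuracy, mu = 0.5,
                      alternative = "greater")
  structure(list(rounds = rounds,
                 mean_transfer = mean(rounds$transfer_accuracy),
                 t = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value),
            class = "cats_communication")
}

#' @export
print.cats_communication <- function(x, ...) {
  cat(sprintf("communication protocol: %d rounds\n", nrow(x$rounds)))
  cat(sprintf("  mean transfer accuracy %.4f (chance 0.5), t(%d) = %.2f, one-tailed p = %.2g\n",
              x$mean_transfer, x$df, x$t, x$p))
  if (!all(is.na(x$rounds$scrambled_accuracy))) {
    cat(sprintf("  scrambled-translation control: %.4f\n",
                mean(x$rounds$scrambled_accuracy, na.rm = TRUE)))
  }
  invisible(x)
}
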