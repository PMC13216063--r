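#' Hierarchically structured class features emulating backbone embeddings
#'
#' Places class means at the leaves of a binary tree by accumulating
#' independent Gaussian displacements per tree level (siblings share all
#' but the last displacement, so siblings are nearer than cousins), then
#' draws i.i.d. normal samples around each mean. The analytic ground truth
#' returned is the Euclidean RDM between the generated class means.
#'
#' @param n_classes number of classes (>= 2).
#' @param feature_dim embedding dimensionality.
#' @param samples_per_class draws per class.
#' @param level_scales standard deviation of the per-entry displacement at
#'   each tree level, root to leaf; recycled to the tree depth. Larger
#'   scales at shallow levels give a stronger between-class hierarchy.
#' @param within_sd within-class sample standard deviation.
#' @param seed integer seed; the generator is a pure function of its
#'   arguments.
#' @return list with `features_by_class` (named list of matrices),
#'   `class_means`, `rdm` (ground-truth `cats_rdm`), `paths` (leaf codes).
#' @export
generate_class_features <- function(n_classes = 8L, feature_dim = 32L,
                                    samples_per_class = 200L,
                                    level_scales = c(6, 3), within_sd = 1,
                                    seed = 1L) {
  stopifnot(n_classes >= 2L, all(level_scales > 0), within_sd >= 0)
  set.seed(seed)
  depth <- max(1L, ceiling(log2(n_classes)))
  scales <- if (depth <= length(level_scales)) level_scales[seq_len(depth)]
            else c(level_scales,
                   rep(level_scales[length(level_scales)],
                       depth - length(level_scales)))
  classes <- sprintf("c%02d", seq_len(n_classes))
  ## binary codes of the leaves; prefix at level l identifies the ancestor
  codes <- vapply(seq_len(n_classes) - 1L, function(i) {
    paste(rev(as.integer(intToBits(i))[seq_len(depth)]), collapse = "")
  }, character(1))
  disp <- new.env(parent = emptyenv())
  node_disp <- function(prefix, scale) {
    if (is.null(disp[[prefix]])) {
      disp[[prefix]] <- stats::rnorm(feature_dim, sd = scale)
    }
    disp[[prefix]]
  }
  means <- matrix(0, n_classes, feature_dim, dimnames = list(classes, NULL))
  for (i in seq_len(n_classes)) {
    for (l in seq_len(depth)) {
      means[i, ] <- means[i, ] +
        node_disp(paste0("L", l, ":", substr(codes[i], 1L, l)), scales[l])
    }
  }
  features_by_class <- stats::setNames(lapply(seq_len(n_classes), function(i) {
    means[rep(i, samples_per_class), , drop = FALSE] +
      matrix(stats::rnorm(samples_per_class * feature_dim, sd = within_sd),
             samples_per_class, feature_dim)
  }), classes)
  rdm <- as.matrix(stats::dist(means))
  rdm <- structure(rdm, class = c("cats_rdm", class(rdm)),
                   metric = "euclidean")
  list(features_by_class = features_by_class, class_means = means,
       rdm = rdm, paths = stats::setNames(codes, classes))
}

#' Subject and model-instance RDM ensembles with known signal and noise
#'
#' Generates a ground-truth signal RDM (from random item embeddings unless
#' one is supplied) and two ensembles around it: subject RDMs = signal +
#' independent symmetric noise of standard deviation `noise_sd`, and
#' model-instance RDMs = signal + noise of `instance_noise_sd`. Noise is
#' drawn on the upper triangle, mirrored, clipped so dissimilarities stay
#' nonnegative, and the diagonal is forced to zero.
#'
#' @param n_items items per RDM.
#' @param n_subjects number of subject RDMs.
#' @param noise_sd subject noise standard deviation (>= 0).
#' @param n_model_instances number of model-instance RDMs.
#' @param instance_noise_sd instance noise standard deviation (>= 0).
#' @param signal optional signal RDM; generated when `NULL`.
#' @param seed integer seed.
#' @return list with `subjects`, `instances` (lists of matrices), `signal`.
#' @export
generate_rdm_ensemble <- function(n_items = 12L, n_subjects = 20L,
                                  noise_sd = 0.2, n_model_instances = 10L,
                                  instance_noise_sd = 0.1, signal = NULL,
                                  seed = 1L) {
  stopifnot(noise_sd >= 0, instance_noise_sd >= 0)
  set.seed(seed)
  if (is.null(signal)) {
    emb <- matrix(stats::rnorm(n_items * 5L), n_items, 5L)
    signal <- as.matrix(stats::dist(emb))
    signal <- signal / mean(signal[lower.tri(signal)])
  } else {
    signal <- unclass(as.matrix(signal))
    n_items <- nrow(signal)
  }
  rownames(signal) <- colnames(signal) <- paste0("item_", seq_len(n_items))
  add_noise <- function(sd) {
    noisy <- signal
    ut <- upper.tri(noisy)
    noise <- stats::rnorm(sum(ut), sd = sd)
    noisy[ut] <- noisy[ut] + noise
    noisy[lower.tri(noisy)] <- t(noisy)[lower.tri(noisy)]
    noisy[noisy < 0] <- 0
    diag(noisy) <- 0
    noisy
  }
  subjects <- lapply(seq_len(n_subjects), function(s) add_noise(noise_sd))
  instances <- lapply(seq_len(n_model_instances),
                      function(i) add_noise(instance_noise_sd))
  list(subjects = subjects, instances = instances, signal = signal)
}

#' Two-level world with hyper-category structure
#'
#' A special case of the hierarchical generator whose top level is the
#' hyper-category: hyper-category centers are widely separated, classes
#' scatter around their center, so within-hyper distances are smaller than
#' between-hyper distances by construction. Also emits the two-column
#' class-to-hyper-category mapping table that the basis-specificity
#' analysis requires.
#'
#' @param n_hyper number of hyper-categories.
#' @param classes_per_hyper classes per hyper-category.
#' @param feature_dim,samples_per_class,within_sd as in
#'   [generate_class_features()].
#' @param hyper_scale,class_scale per-entry displacement standard
#'   deviations of the two levels.
#' @param seed integer seed.
#' @return list with `features_by_class`, `hyper_map` (data frame
#'   `class_id`, `hyper_category`), `class_means`, `rdm`.
#' @export
make_hypercategory_world <- function(n_hyper = 2L, classes_per_hyper = 4L,
                                     feature_dim = 32L,
                                     samples_per_class = 100L,
                                     hyper_scale = 6, class_scale = 3,
                                     within_sd = 1, seed = 1L) {
  stopifnot(n_hyper >= 1L, classes_per_hyper >= 1L)
  set.seed(seed)
  hypers <- sprintf("H%d", seq_len(n_hyper))
  n_classes <- n_hyper * classes_per_hyper
  classes <- sprintf("c%02d", seq_len(n_classes))
  hyper_of <- rep(hypers, each = classes_per_hyper)
  centers <- matrix(stats::rnorm(n_hyper * feature_dim, sd = hyper_scale),
                    n_hyper, feature_dim, dimnames = list(hypers, NULL))
  means <- centers[hyper_of, , drop = FALSE] +
    matrix(stats::rnorm(n_classes * feature_dim, sd = class_scale),
           n_classes, feature_dim)
  rownames(means) <- classes
  features_by_class <- stats::setNames(lapply(seq_len(n_classes), function(i) {
    means[rep(i, samples_per_class), , drop = FALSE] +
      matrix(stats::rnorm(samples_per_class * feature_dim, sd = within_sd),
             samples_per_class, feature_dim)
  }), classes)
  rdm <- as.matrix(stats::dist(means))
  rdm <- structure(rdm, class = c("cats_rdm", class(rdm)),
                   metric = "euclidean")
  list(features_by_class = features_by_class,
       hyper_map = data.frame(class_id = classes, hyper_category = hyper_of,
                              stringsAsFactors = FALSE),
       class_means = means, rdm = rdm)
}
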