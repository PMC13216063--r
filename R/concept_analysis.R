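#' Functional entropy of a Yes-response profile
#'
#' Shannon entropy (natural log) of the normalized per-class counts of
#' `Yes` responses elicited by one concept vector:
#' `e = -sum(p_i log p_i)` with `p_i = c_i / sum_j c_j` and the limit
#' convention `0 log 0 = 0`. Low entropy means the vector selects a few
#' specific categories; a maximally unselective vector approaches `log K`.
#'
#' @param counts nonnegative integer vector of per-class `Yes` counts.
#' @return list with `e` (entropy, nats) and `p` (probability vector).
#' @examples
#' functional_entropy(c(3, 1))$e   # -(0.75 log 0.75 + 0.25 log 0.25)
#' @export
functional_entropy <- function(counts) {
  if (any(counts < 0) || any(!is.finite(counts))) {
    stop("counts must be finite and nonnegative", call. = FALSE)
  }
  total <- sum(counts)
  if (total <= 0) {
    stop("functional entropy is undefined for all-zero counts",
         call. = FALSE)
  }
  p <- counts / total
  nz <- p > 0
  list(e = -sum(p[nz] * log(p[nz])), p = p)
}

## count Yes decisions per true class for one concept vector
yes_counts <- function(net, concept, eval_features_by_class) {
  vapply(eval_features_by_class, function(xm) {
    if (is.null(dim(xm))) xm <- matrix(xm, nrow = 1L)
    sum(cats_decide(net, xm, concept) == "Yes")
  }, numeric(1))
}

#' Entropy distribution over sampled concept-space points
#'
#' Samples `n_points` concept vectors, runs each over the evaluation set,
#' and computes the functional entropy of the resulting per-class
#' Yes-counts. Sampling from the trained concept space (`"trained"`) draws
#' from a kernel-density estimate of the learned concept vectors (a random
#' learned concept plus Gaussian jitter of `bandwidth` times the per-dim
#' concept standard deviation), so the sample respects the clustered
#' occupancy of the space; the random baseline samplers are `"normal"`
#' (standard normal, the default baseline) and `"uniform"` (on `[-1, 1]`).
#' Points that elicit no `Yes` response at all have undefined entropy and
#' are returned as `NA`.
#'
#' @param net a `cats_network`.
#' @param eval_features_by_class named list of evaluation features.
#' @param n_points number of sampled concept vectors.
#' @param sampler `"trained"`, `"normal"`, or `"uniform"`.
#' @param concepts learned concept matrix (required for `"trained"`).
#' @param bandwidth kernel bandwidth for the `"trained"` sampler, as a
#'   fraction of the per-dimension standard deviation of the concept set.
#' @param seed optional integer seed.
#' @return numeric vector of entropies (possibly with `NA`s).
#' @export
entropy_distribution <- function(net, eval_features_by_class,
                                 n_points = 100L,
                                 sampler = c("normal", "uniform", "trained"),
                                 concepts = NULL, bandwidth = 0.3,
                                 seed = NULL) {
  sampler <- match.arg(sampler)
  if (!is.null(seed)) set.seed(seed)
  d <- net$d_c
  pts <- switch(sampler,
    normal = matrix(stats::rnorm(n_points * d), n_points, d),
    uniform = matrix(stats::runif(n_points * d, -1, 1), n_points, d),
    trained = {
      if (is.null(concepts)) {
        stop("sampler = 'trained' needs the learned concept matrix",
             call. = FALSE)
      }
      centers <- concepts[sample.int(nrow(concepts), n_points,
                                     replace = TRUE), , drop = FALSE]
      h <- bandwidth * apply(concepts, 2L, stats::sd)
      centers + matrix(stats::rnorm(n_points * d), n_points, d) *
        rep(h, each = n_points)
    })
  apply(pts, 1L, function(v) {
    cnt <- yes_counts(net, v, eval_features_by_class)
    if (sum(cnt) == 0) NA_real_ else functional_entropy(cnt)$e
  })
}

#' Hyper-category specificity of concept-space basis vectors
#'
#' Feeds each canonical one-hot vector of the concept space (dimensions
#' `1..d_c`) as the concept and counts `Yes` decisions per hyper-category
#' over the evaluation set. The class-to-hyper-category assignment is a
#' user-supplied two-column table.
#'
#' @param net a `cats_network`.
#' @param eval_features_by_class named list of evaluation features.
#' @param hyper_map data frame with columns `class_id` and `hyper_category`
#'   covering every class in the evaluation set.
#' @return integer matrix `d_c x n_hyper` of `Yes` counts.
#' @export
basis_specificity <- function(net, eval_features_by_class, hyper_map) {
  stopifnot(all(c("class_id", "hyper_category") %in% names(hyper_map)))
  classes <- names(eval_features_by_class)
  unmapped <- setdiff(classes, hyper_map$class_id)
  if (length(unmapped)) {
    stop("class(es) missing from hyper_map: ",
         paste(unmapped, collapse = ", "), call. = FALSE)
  }
  hyper_of <- stats::setNames(as.character(hyper_map$hyper_category),
                              hyper_map$class_id)
  hypers <- sort(unique(hyper_of[classes]))
  d <- net$d_c
  out <- matrix(0L, d, length(hypers),
                dimnames = list(paste0("dim_", seq_len(d)), hypers))
  for (j in seq_len(d)) {
    onehot <- numeric(d)
    onehot[j] <- 1
    cnt <- yes_counts(net, onehot, eval_features_by_class)
    agg <- tapply(cnt, hyper_of[classes], sum)
    out[j, names(agg)] <- as.integer(agg)
  }
  out
}

#' Representational dissimilarity matrix from item vectors
#'
#' Builds an item-by-item RDM under the Pearson distance
#' (`1 - Pearson correlation`), cosine distance, or Euclidean distance.
#'
#' @param vectors matrix with one named row per item (or a named list of
#'   equal-length vectors).
#' @param metric `"pearson"`, `"cosine"`, or `"euclidean"`.
#' @return symmetric matrix of class `cats_rdm` with zero diagonal and a
#'   `metric` attribute.
#' @export
rdm_from_vectors <- function(vectors,
                             metric = c("pearson", "cosine", "euclidean")) {
  metric <- match.arg(metric)
  if (is.list(vectors) && !is.data.frame(vectors)) {
    vectors <- do.call(rbind, vectors)
  }
  vectors <- as.matrix(vectors)
  if (nrow(vectors) < 3L) stop("need at least 3 items", call. = FALSE)
  if (ncol(vectors) < 2L) stop("vectors must have length >= 2", call. = FALSE)
  items <- rownames(vectors)
  if (is.null(items)) items <- paste0("item_", seq_len(nrow(vectors)))
  if (metric == "pearson") {
    sds <- apply(vectors, 1L, stats::sd)
    if (any(sds == 0)) {
      stop("constant vector(s) under the Pearson metric: ",
           paste(items[sds == 0], collapse = ", "), call. = FALSE)
    }
    d <- 1 - stats::cor(t(vectors))
  } else if (metric == "cosine") {
    nrm <- sqrt(rowSums(vectors^2))
    if (any(nrm == 0)) {
      stop("zero vector(s) under the cosine metric: ",
           paste(items[nrm == 0], collapse = ", "), call. = FALSE)
    }
    d <- 1 - (vectors %*% t(vectors)) / outer(nrm, nrm)
  } else {
    d <- as.matrix(stats::dist(vectors))
  }
  d <- (d + t(d)) / 2
  diag(d) <- 0
  dimnames(d) <- list(items, items)
  structure(d, class = c("cats_rdm", class(d)), metric = metric)
}

#' @export
print.cats_rdm <- function(x, ...) {
  cat(sprintf("RDM: %d items, metric = %s\n", nrow(x),
              attr(x, "metric") %||% "unknown"))
  print(round(unclass(x), 3)[seq_len(min(6L, nrow(x))),
                             seq_len(min(6L, ncol(x))), drop = FALSE])
  if (nrow(x) > 6L) cat("...\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## upper-triangle vectorization (row-major over i < j), used everywhere
utvec <- function(m) {
  m <- unclass(as.matrix(m))
  m[lower.tri(m)]  # for symmetric m this is the row-major upper triangle
}

#' Hierarchical clustering of the concept set
#'
#' Agglomerative clustering of the concept vectors under cosine distance
#' with unweighted average (UPGMA) linkage. Rows are sorted by category
#' label first so merge order is reproducible under relabeling of the
#' input order.
#'
#' @param concepts concept matrix with named rows (>= 2, no zero vectors).
#' @param h optional dendrogram height at which to cut flat clusters.
#' @param k optional number of flat clusters.
#' @return list with `hclust` (a [stats::hclust] tree), `distance` (the
#'   cosine distance matrix), and `clusters` (named integer vector, present
#'   when `h` or `k` was given).
#' @export
hcluster_concepts <- function(concepts, h = NULL, k = NULL) {
  stopifnot(nrow(concepts) >= 2L)
  if (is.null(rownames(concepts))) {
    rownames(concepts) <- paste0("c", seq_len(nrow(concepts)))
  }
  concepts <- concepts[order(rownames(concepts)), , drop = FALSE]
  nrm <- sqrt(rowSums(concepts^2))
  if (any(nrm == 0)) {
    stop("zero concept vector(s): ",
         paste(rownames(concepts)[nrm == 0], collapse = ", "), call. = FALSE)
  }
  d <- 1 - (concepts %*% t(concepts)) / outer(nrm, nrm)
  d <- (d + t(d)) / 2
  diag(d) <- 0
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  out <- list(hclust = hc, distance = d)
  if (!is.null(h) || !is.null(k)) {
    out$clusters <- stats::cutree(hc, k = k, h = h)
  }
  out
}

#' Best-matching concept dimension for reference dimensions
#'
#' For each column of a reference embedding (items x R), computes the
#' Pearson correlation with every concept dimension (items x d_c) and
#' retains the maximum as the best-match score, together with the index of
#' the winning dimension and its significance against [critical_r()].
#'
#' @param reference_dims numeric matrix, items x R (same item order as
#'   `concept_matrix`).
#' @param concept_matrix numeric matrix, items x d_c.
#' @param alpha significance level for the critical-r flag (two-tailed).
#' @return data frame with `reference_dim`, `best_r`, `best_dim`,
#'   `significant`.
#' @export
best_match_dimensions <- function(reference_dims, concept_matrix,
                                  alpha = 0.05) {
  reference_dims <- as.matrix(reference_dims)
  concept_matrix <- as.matrix(concept_matrix)
  n <- nrow(reference_dims)
  if (n != nrow(concept_matrix)) {
    stop("item counts differ between reference and concept matrices",
         call. = FALSE)
  }
  if (n < 3L) stop("need at least 3 items", call. = FALSE)
  const_ref <- apply(reference_dims, 2L, stats::sd) == 0
  const_con <- apply(concept_matrix, 2L, stats::sd) == 0
  if (any(const_ref) || any(const_con)) {
    stop("constant column(s): ",
         paste(c(which(const_ref), which(const_con)), collapse = ", "),
         call. = FALSE)
  }
  r <- stats::cor(reference_dims, concept_matrix)
  best <- apply(r, 1L, max)
  idx <- apply(r, 1L, which.max)
  rcrit <- critical_r(n - 2L, alpha, tails = 2L)
  data.frame(reference_dim = colnames(reference_dims) %||%
               paste0("ref_", seq_len(ncol(reference_dims))),
             best_r = unname(best), best_dim = unname(idx),
             significant = unname(best) > rcrit,
             row.names = NULL)
}

#' Critical Pearson correlation at a given significance level
#'
#' The threshold `r* = t* / sqrt(t*^2 + df)` where `t*` is the critical
#' Student-t quantile at level `alpha` with `df` degrees of freedom
#' (`df = n - 2` items). For `df = 330` and two-tailed `alpha = 0.05` this
#' gives the 0.107-0.108 significance radius used to flag best-match
#' correlations.
#'
#' @param df degrees of freedom (>= 1).
#' @param alpha significance level in `(0, 1)`.
#' @param tails 1 or 2.
#' @return the critical correlation value.
#' @export
critical_r <- function(df, alpha = 0.05, tails = 2L) {
  if (df < 1) stop("df must be >= 1", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  if (!tails %in% c(1L, 2L)) stop("tails must be 1 or 2", call. = FALSE)
  tcrit <- stats::qt(1 - alpha / tails, df)
  tcrit / sqrt(tcrit^2 + df)
}

#' K-means grouping of model RDMs
#'
#' Vectorizes each RDM's upper triangle and clusters the vectors with
#' k-means (multiple restarts, seeded).
#'
#' @param model_rdms list of RDMs over the same items.
#' @param k number of groups.
#' @param seed integer seed.
#' @param nstart number of random restarts.
#' @return integer vector of group labels, one per RDM.
#' @export
kmeans_rdm_groups <- function(model_rdms, k, seed = 1L, nstart = 20L) {
  if (length(model_rdms) < k) {
    stop("need at least k RDMs", call. = FALSE)
  }
  X <- do.call(rbind, lapply(model_rdms, utvec))
  if (k == 1L) return(rep(1L, nrow(X)))
  set.seed(seed)
  stats::kmeans(X, centers = k, nstart = nstart)$cluster
}
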