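#' Construct an untrained concept-gated dual network
#'
#' Builds the paired task-solving (TS) and concept-abstraction (CA)
#' perceptrons. The TS module maps a feature vector through
#' `feature_dim -> hidden[1] -> ... -> 2` affine layers with batch
#' normalization and ReLU on the hidden layers and a raw 2-score output head
#' (`No` at position 1, `Yes` at position 2). The CA module maps a
#' `d_c`-dimensional concept vector through a parallel chain whose layer-`l`
#' pre-activation has the same width as the TS layer-`l` input; its sigmoid
#' squashing produces the gating vector `g_l` in `(0,1)` that multiplies the
#' TS layer-`l` input elementwise, while the normalized and rectified
#' pre-activation is passed on as the next CA-chain input.
#'
#' The reference configuration is TS `[2048-100-100-2]` gated at the
#' `[2048, 100, 100]` inputs by CA `[d_c-2048-100-100]`; all sizes are
#' configurable and small instances are used throughout the examples.
#'
#' @param feature_dim width of the input feature vector (TS input).
#' @param d_c concept-vector length (CA input); 20 in the reference setup.
#' @param hidden integer vector of TS hidden-layer widths.
#' @param seed optional integer seed for weight initialization.
#' @return an object of class `cats_network`.
#' @examples
#' net <- cats_network(feature_dim = 8, d_c = 4, hidden = c(6, 6), seed = 1)
#' net
#' @export
cats_network <- function(feature_dim, d_c, hidden = c(100, 100), seed = NULL) {
  stopifnot(feature_dim >= 1, d_c >= 1, all(hidden >= 1))
  if (!is.null(seed)) set.seed(seed)
  dims_ts <- c(feature_dim, hidden, 2L)
  L <- length(dims_ts) - 1L
  dims_ca_in <- c(d_c, dims_ts[seq_len(L - 1L)])
  init_lin <- function(n_in, n_out) {
    list(W = matrix(stats::rnorm(n_out * n_in, sd = sqrt(2 / n_in)),
                    n_out, n_in),
         b = numeric(n_out))
  }
  add_bn <- function(layer, width) {
    layer$gamma <- rep(1, width)
    layer$beta <- numeric(width)
    layer$rm <- numeric(width)
    layer$rv <- rep(1, width)
    layer
  }
  ts <- vector("list", L)
  ca <- vector("list", L)
  for (l in seq_len(L)) {
    ts[[l]] <- init_lin(dims_ts[l], dims_ts[l + 1L])
    if (l < L) ts[[l]] <- add_bn(ts[[l]], dims_ts[l + 1L])
    ca[[l]] <- init_lin(dims_ca_in[l], dims_ts[l])
    if (l < L) ca[[l]] <- add_bn(ca[[l]], dims_ts[l])
  }
  structure(list(ts = ts, ca = ca, d_c = d_c, dims_ts = dims_ts, L = L),
            class = "cats_network")
}

#' @export
print.cats_network <- function(x, ...) {
  cat("Concept-gated dual network\n")
  cat("  TS module:", paste(x$dims_ts, collapse = "-"), "\n")
  cat("  CA module:", paste(c(x$d_c, x$dims_ts[seq_len(x$L - 1L)], ""),
                            collapse = "-"),
      "-> gates at [", paste(x$dims_ts[seq_len(x$L)], collapse = ", "), "]\n")
  invisible(x)
}

#' Forward pass of the concept-gated network
#'
#' Runs a batch of feature vectors, each paired with a concept vector,
#' through the gated architecture. In training mode, batch normalization
#' uses batch statistics and updates the running statistics; in inference
#' mode the stored running statistics are used and the pass is fully
#' deterministic.
#'
#' @param net a `cats_network`.
#' @param x numeric matrix `n x feature_dim` (rows are samples), or a single
#'   feature vector.
#' @param concept numeric matrix `n x d_c` of per-sample concept vectors, or
#'   a single concept vector recycled over the batch.
#' @param training logical; batch-statistics mode (weights' running
#'   statistics are updated as a side effect, returned in `$net`).
#' @param capture logical; if `TRUE`, return the full activation trace
#'   (inputs `x_l`, gated inputs `z_l`, gates `g_l`, CA-chain inputs `c_l`,
#'   scores).
#' @param gate_override optional list of gate matrices replacing the
#'   computed `g_l` (used e.g. to force identity gates).
#' @return list with `scores` (`n x 2`), `decision` (factor `"No"`/`"Yes"`,
#'   ties decided `"No"`), `net`, and when requested `trace` and `cache`.
#' @export
cats_forward <- function(net, x, concept, training = FALSE, capture = FALSE,
                         gate_override = NULL) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  if (is.null(dim(concept))) {
    concept <- matrix(concept, nrow = nrow(x), ncol = length(concept),
                      byrow = TRUE)
  }
  if (ncol(x) != net$dims_ts[1L]) {
    stop(sprintf("feature length %d does not match network input %d",
                 ncol(x), net$dims_ts[1L]), call. = FALSE)
  }
  if (ncol(concept) != net$d_c) {
    stop(sprintf("concept length %d does not match d_c = %d",
                 ncol(concept), net$d_c), call. = FALSE)
  }
  if (nrow(concept) != nrow(x)) {
    stop("feature and concept batches differ in size", call. = FALSE)
  }
  L <- net$L
  cache <- vector("list", L)
  x_prev <- x
  c_prev <- concept
  scores <- NULL
  for (l in seq_len(L)) {
    ca <- net$ca[[l]]
    a <- c_prev %*% t(ca$W) + matrix(ca$b, nrow(x), length(ca$b), byrow = TRUE)
    g <- sigmoid(a)
    if (!is.null(gate_override) && !is.null(gate_override[[l]])) {
      g <- gate_override[[l]]
      if (is.null(dim(g))) g <- matrix(g, nrow(x), length(g), byrow = TRUE)
    }
    z <- x_prev * g
    ts <- net$ts[[l]]
    o <- z %*% t(ts$W) + matrix(ts$b, nrow(x), length(ts$b), byrow = TRUE)
    cache[[l]] <- list(x_prev = x_prev, c_prev = c_prev, a = a, g = g, z = z)
    if (l < L) {
      bnt <- bn_forward(o, ts, training)
      net$ts[[l]] <- bnt$layer
      x_next <- relu(bnt$out)
      bnc <- bn_forward(a, ca, training)
      net$ca[[l]] <- bnc$layer
      c_next <- relu(bnc$out)
      cache[[l]]$bn_ts <- bnt
      cache[[l]]$bn_ca <- bnc
      cache[[l]]$mask_ts <- bnt$out > 0
      cache[[l]]$mask_ca <- bnc$out > 0
      x_prev <- x_next
      c_prev <- c_next
    } else {
      scores <- o
    }
  }
  decision <- factor(ifelse(scores[, 2L] > scores[, 1L], "Yes", "No"),
                     levels = c("No", "Yes"))
  out <- list(scores = scores, decision = decision, net = net)
  if (capture) {
    out$trace <- list(
      x = lapply(cache, `[[`, "x_prev"),
      z = lapply(cache, `[[`, "z"),
      g = lapply(cache, `[[`, "g"),
      c = lapply(cache, `[[`, "c_prev"),
      scores = scores)
    out$cache <- cache
  } else {
    out$cache <- cache
  }
  out
}

## Backward pass: given d(loss)/d(scores), return gradients for every
## trainable tensor (W/b of layer l; gamma/beta picked up while unwinding
## layer l+1) plus the gradient with respect to the concept inputs.
cats_grads <- function(net, cache, dscores) {
  L <- net$L
  raw_ts <- vector("list", L)
  raw_ca <- vector("list", L)
  dO <- dscores
  dA_chain <- NULL
  dC0 <- NULL
  dX0 <- NULL
  for (l in rev(seq_len(L))) {
    cc <- cache[[l]]
    ts <- net$ts[[l]]
    ca <- net$ca[[l]]
    raw_ts[[l]]$W <- t(dO) %*% cc$z
    raw_ts[[l]]$b <- colSums(dO)
    dZ <- dO %*% ts$W
    dXprev <- dZ * cc$g
    dG <- dZ * cc$x_prev
    dA <- dG * cc$g * (1 - cc$g)
    if (!is.null(dA_chain)) dA <- dA + dA_chain
    raw_ca[[l]]$W <- t(dA) %*% cc$c_prev
    raw_ca[[l]]$b <- colSums(dA)
    dCprev <- dA %*% ca$W
    if (l > 1L) {
      prev <- cache[[l - 1L]]
      bb <- bn_backward(dXprev * prev$mask_ts, prev$bn_ts,
                        net$ts[[l - 1L]]$gamma)
      dO <- bb$dx
      raw_ts[[l - 1L]]$gamma <- bb$dgamma
      raw_ts[[l - 1L]]$beta <- bb$dbeta
      cb <- bn_backward(dCprev * prev$mask_ca, prev$bn_ca,
                        net$ca[[l - 1L]]$gamma)
      dA_chain <- cb$dx
      raw_ca[[l - 1L]]$gamma <- cb$dgamma
      raw_ca[[l - 1L]]$beta <- cb$dbeta
    } else {
      dC0 <- dCprev
      dX0 <- dXprev
    }
  }
  list(ts = raw_ts, ca = raw_ca, dC0 = dC0, dX0 = dX0)
}

#' Yes/No judgment for feature-concept pairs
#'
#' Inference-mode forward pass returning the binary decision for each row.
#' Equal scores (a measure-zero event) are decided `"No"`.
#'
#' @inheritParams cats_forward
#' @return factor vector of `"No"`/`"Yes"` decisions.
#' @export
cats_decide <- function(net, x, concept) {
  cats_forward(net, x, concept, training = FALSE)$decision
}

## extract the trainable-parameter sub-structure (W, b, gamma, beta)
trainable_params <- function(net) {
  take <- function(layer) layer[intersect(names(layer),
                                          c("W", "b", "gamma", "beta"))]
  list(ts = lapply(net$ts, take), ca = lapply(net$ca, take))
}

set_trainable_params <- function(net, params) {
  for (l in seq_along(net$ts)) {
    for (nm in names(params$ts[[l]])) net$ts[[l]][[nm]] <- params$ts[[l]][[nm]]
    for (nm in names(params$ca[[l]])) net$ca[[l]][[nm]] <- params$ca[[l]][[nm]]
  }
  net
}

trainable_grads <- function(grads) {
  take <- function(layer) layer[intersect(names(layer),
                                          c("W", "b", "gamma", "beta"))]
  list(ts = lapply(grads$ts, take), ca = lapply(grads$ca, take))
}

#' Save / load a network checkpoint
#'
#' Serializes every weight and normalization tensor together with the layer
#' metadata into a single binary container. The round trip is bit-exact:
#' reloading and re-running the forward pass reproduces scores identically.
#'
#' @param net a `cats_network`.
#' @param path file path.
#' @param concepts optional concept matrix saved alongside the weights.
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   returns a list with `net` and (possibly `NULL`) `concepts`.
#' @export
save_checkpoint <- function(net, path, concepts = NULL) {
  stopifnot(inherits(net, "cats_network"))
  obj <- list(format = "catsnet-checkpoint", version = 1L,
              d_c = net$d_c, dims_ts = net$dims_ts, L = net$L,
              ts = net$ts, ca = net$ca, concepts = concepts)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "catsnet-checkpoint")) {
    stop("not a catsnet checkpoint: ", path, call. = FALSE)
  }
  net <- structure(list(ts = obj$ts, ca = obj$ca, d_c = obj$d_c,
                        dims_ts = obj$dims_ts, L = obj$L),
                   class = "cats_network")
  list(net = net, concepts = obj$concepts)
}
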