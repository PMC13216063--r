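#' Numerically stable logistic sigmoid
#'
#' Elementwise `1 / (1 + exp(-a))`, evaluated so that arguments with
#' magnitude up to about 1e3 neither overflow nor underflow, and clipped to
#' the open interval at double precision (`[1e-15, 1 - 1e-15]`) so gating
#' signals never saturate to exactly 0 or 1. This is the squashing function
#' that turns concept-abstraction pre-activations into multiplicative
#' gating signals in `(0, 1)`.
#'
#' @param a numeric vector or matrix; all entries must be finite.
#' @return object of the same shape with entries strictly in `(0, 1)`.
#' @examples
#' sigmoid(0)        # 0.5
#' sigmoid(log(3))   # 0.75
#' @export
sigmoid <- function(a) {
  if (!is.numeric(a) || any(!is.finite(a))) {
    stop("sigmoid: input must be finite numeric", call. = FALSE)
  }
  out <- a
  pos <- a >= 0
  out[pos] <- 1 / (1 + exp(-a[pos]))
  ea <- exp(a[!pos])
  out[!pos] <- ea / (1 + ea)
  pmin(pmax(out, 1e-15), 1 - 1e-15)
}

#' Apply a multiplicative gate to a layer input
#'
#' Hadamard (elementwise) product `x * g`. The gate vector is expected to
#' come from a sigmoid and hence lie in `(0, 1)`, but any numeric gate is
#' accepted; only the lengths are checked.
#'
#' @param x numeric vector, the layer input.
#' @param g numeric vector of the same length, the gating signal.
#' @return numeric vector `x * g`.
#' @examples
#' apply_gating(c(2, 3), c(0.5, 1))  # c(1, 3)
#' @export
apply_gating <- function(x, g) {
  if (length(x) != length(g)) {
    stop(sprintf("apply_gating: length mismatch (%d vs %d)",
                 length(x), length(g)), call. = FALSE)
  }
  x * g
}

relu <- function(x) pmax(x, 0)

## --- batch normalization over the rows of an n x d activation matrix ----
## Training mode uses biased batch statistics and updates running statistics
## with momentum; inference mode standardizes with the stored running
## statistics (a fixed affine map, so it stays differentiable).

bn_forward <- function(x, layer, training, eps = 1e-5, momentum = 0.1) {
  n <- nrow(x)
  if (training) {
    if (n < 2L) {
      stop("batch normalization needs batches of size >= 2 in training mode",
           call. = FALSE)
    }
    mu <- colMeans(x)
    v <- colMeans(x^2) - mu^2
    v[v < 0] <- 0
    invstd <- 1 / sqrt(v + eps)
    xhat <- sweep(sweep(x, 2L, mu, "-"), 2L, invstd, "*")
    layer$rm <- (1 - momentum) * layer$rm + momentum * mu
    layer$rv <- (1 - momentum) * layer$rv + momentum * v * n / (n - 1)
  } else {
    invstd <- 1 / sqrt(layer$rv + eps)
    xhat <- sweep(sweep(x, 2L, layer$rm, "-"), 2L, invstd, "*")
  }
  out <- sweep(sweep(xhat, 2L, layer$gamma, "*"), 2L, layer$beta, "+")
  list(out = out, xhat = xhat, invstd = invstd, training = training,
       layer = layer)
}

bn_backward <- function(dout, cache, gamma) {
  dgamma <- colSums(dout * cache$xhat)
  dbeta <- colSums(dout)
  dxhat <- sweep(dout, 2L, gamma, "*")
  if (cache$training) {
    n <- nrow(dout)
    m1 <- matrix(colMeans(dxhat), n, ncol(dout), byrow = TRUE)
    m2 <- matrix(colMeans(dxhat * cache$xhat), n, ncol(dout), byrow = TRUE)
    dx <- sweep(dxhat - m1 - cache$xhat * m2, 2L, cache$invstd, "*")
  } else {
    dx <- sweep(dxhat, 2L, cache$invstd, "*")
  }
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

## --- Adam optimizer over nested lists of numeric arrays ------------------
## `grads` must mirror a sub-structure of `params` (matching names); leaves
## absent from `grads` (e.g. running statistics) are left untouched.

adam_new <- function() list(t = 0L, m = NULL, v = NULL)

zero_like <- function(g) {
  if (is.list(g)) lapply(g, zero_like) else g * 0
}

.adam_rec <- function(p, g, m, v, lr, b1, b2, eps, bc1, bc2) {
  if (is.list(g)) {
    keys <- if (is.null(names(g))) seq_along(g) else names(g)
    for (nm in keys) {
      if (is.null(g[[nm]])) next
      res <- .adam_rec(p[[nm]], g[[nm]], m[[nm]], v[[nm]],
                       lr, b1, b2, eps, bc1, bc2)
      p[[nm]] <- res$p; m[[nm]] <- res$m; v[[nm]] <- res$v
    }
    return(list(p = p, m = m, v = v))
  }
  m <- b1 * m + (1 - b1) * g
  v <- b2 * v + (1 - b2) * g * g
  p <- p - lr * (m / bc1) / (sqrt(v / bc2) + eps)
  list(p = p, m = m, v = v)
}

adam_step <- function(state, params, grads, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  if (is.null(state$m)) {
    state$m <- zero_like(grads)
    state$v <- zero_like(grads)
  }
  res <- .adam_rec(params, grads, state$m, state$v, lr, beta1, beta2, eps,
                   1 - beta1^state$t, 1 - beta2^state$t)
  state$m <- res$m
  state$v <- res$v
  list(params = res$p, state = state)
}

## softmax cross-entropy on a n x 2 score matrix; labels are 1 (No) / 2 (Yes)
softmax_xent <- function(scores, labels) {
  mx <- apply(scores, 1L, max)
  es <- exp(scores - mx)
  p <- es / rowSums(es)
  n <- nrow(scores)
  idx <- cbind(seq_len(n), labels)
  loss <- -mean(log(pmax(p[idx], 1e-300)))
  dscores <- p
  dscores[idx] <- dscores[idx] - 1
  list(loss = loss, dscores = dscores / n, prob = p)
}
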