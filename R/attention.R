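#' Gating-weighted gradient class-activation map
#'
#' Computes neuron-importance weights
#' `alpha_k = g_{1,k} * mean_ij(d y_Yes / d A^k_ij)` — the global
#' average-pooled gradients of the pre-softmax `Yes` score, scaled by the
#' first-layer gating signal — and the localization map
#' `L = ReLU(sum_k alpha_k A^k)`.
#'
#' @param feature_stack numeric array `u x v x K` of convolutional feature
#'   maps.
#' @param grad_of_yes numeric array `u x v x K` with the gradients of the
#'   `Yes` score with respect to each feature-map pixel.
#' @param g1 numeric vector of length `K`: the first-layer gating signal.
#' @param out_size optional `c(u_out, v_out)`; when given, the map is also
#'   returned linearly (bilinearly) rescaled to that size.
#' @return list of class `cats_cam` with `alpha` (length-`K` weights),
#'   `map` (`u x v`, nonnegative), and `map_scaled` when requested.
#' @examples
#' A <- array(2, c(1, 1, 1)); G <- array(3, c(1, 1, 1))
#' gated_gradcam(A, G, g1 = 0.5)$map   # ReLU(0.5 * 3 * 2) = 3
#' @export
gated_gradcam <- function(feature_stack, grad_of_yes, g1, out_size = NULL) {
  da <- dim(feature_stack)
  if (length(da) != 3L || !identical(da, dim(grad_of_yes))) {
    stop("feature_stack and grad_of_yes must be u x v x K arrays of equal dim",
         call. = FALSE)
  }
  K <- da[3L]
  if (length(g1) != K) {
    stop(sprintf("gating vector length %d does not match K = %d",
                 length(g1), K), call. = FALSE)
  }
  alpha <- g1 * apply(grad_of_yes, 3L, mean)
  amat <- matrix(feature_stack, da[1L] * da[2L], K)
  pre <- matrix(amat %*% alpha, da[1L], da[2L])
  map <- pmax(pre, 0)
  out <- list(alpha = alpha, map = map, pre_relu = pre)
  if (!is.null(out_size)) {
    out$map_scaled <- bilinear_rescale(map, out_size[1L], out_size[2L])
  }
  class(out) <- "cats_cam"
  out
}

#' @export
print.cats_cam <- function(x, ...) {
  cat(sprintf("gated CAM: %d x %d map, %d feature maps, max = %.4g\n",
              nrow(x$map), ncol(x$map), length(x$alpha), max(x$map)))
  invisible(x)
}

## bilinear (align-corners) rescaling of a matrix
bilinear_rescale <- function(m, out_u, out_v) {
  u <- nrow(m); v <- ncol(m)
  ui <- if (out_u == 1L || u == 1L) rep(1, out_u) else
    seq(1, u, length.out = out_u)
  vi <- if (out_v == 1L || v == 1L) rep(1, out_v) else
    seq(1, v, length.out = out_v)
  u0 <- pmin(floor(ui), u - 1L + (u == 1L)); u1 <- pmin(u0 + 1L, u)
  v0 <- pmin(floor(vi), v - 1L + (v == 1L)); v1 <- pmin(v0 + 1L, v)
  fu <- ui - u0; fv <- vi - v0
  out <- matrix(0, out_u, out_v)
  for (i in seq_len(out_u)) {
    r <- (1 - fu[i]) * m[u0[i], ] + fu[i] * m[u1[i], ]
    out[i, ] <- (1 - fv) * r[v0] + fv * r[v1]
  }
  out
}

#' Global-average-pooling backbone adapter
#'
#' The built-in adapter for the attribution path: each convolutional
#' feature map is global average-pooled into one feature entry, so the
#' gradient of any score with respect to map `k` is the constant map
#' `dscore/dx0_k / Z` with `Z = u * v` pixels.
#'
#' @return list with `pool(A)` (maps a `u x v x K` stack to a length-`K`
#'   feature vector) and `spread(dx0, dims)` (maps a feature-gradient
#'   vector back to per-pixel gradient maps).
#' @export
gap_adapter <- function() {
  list(
    name = "global-average-pool",
    pool = function(A) apply(A, 3L, mean),
    spread = function(dx0, dims) {
      Z <- dims[1L] * dims[2L]
      array(rep(dx0 / Z, each = Z), dims)
    })
}

#' Gradients of the Yes score with respect to feature maps
#'
#' Differentiates the pre-softmax `Yes` score through the adapter's pooling
#' and the gated network's forward pass, returning one gradient map per
#' convolutional feature map.
#'
#' @param net a `cats_network` whose feature input width equals the number
#'   of maps `K`.
#' @param concept concept vector configuring the network.
#' @param feature_stack `u x v x K` array.
#' @param adapter a backbone adapter; the built-in [gap_adapter()] by
#'   default. It must provide `pool` and `spread` functions.
#' @return list with `grads` (`u x v x K` array), `g1` (first-layer gating
#'   vector), `scores`.
#' @export
compute_yes_gradients <- function(net, concept, feature_stack,
                                  adapter = gap_adapter()) {
  if (!is.function(adapter$pool) || !is.function(adapter$spread)) {
    stop("adapter lacks gradient capability (pool/spread functions)",
         call. = FALSE)
  }
  da <- dim(feature_stack)
  x0 <- adapter$pool(feature_stack)
  if (length(x0) != net$dims_ts[1L]) {
    stop(sprintf("pooled feature length %d does not match network input %d",
                 length(x0), net$dims_ts[1L]), call. = FALSE)
  }
  fw <- cats_forward(net, x0, concept, training = FALSE, capture = TRUE)
  dscores <- matrix(c(0, 1), 1L)       # pre-softmax Yes score
  gr <- cats_grads(net, fw$cache, dscores)
  list(grads = adapter$spread(as.numeric(gr$dX0), da),
       g1 = as.numeric(fw$trace$g[[1L]]),
       scores = fw$scores)
}

#' One-call gated CAM for a configured network
#'
#' Convenience wrapper: pools the feature stack, runs the configured
#' forward pass, differentiates the `Yes` score, and assembles the
#' gating-weighted localization map.
#'
#' @inheritParams compute_yes_gradients
#' @param out_size optional output size for the rescaled map.
#' @return a `cats_cam` object.
#' @export
cats_cam <- function(net, concept, feature_stack, adapter = gap_adapter(),
                     out_size = NULL) {
  gy <- compute_yes_gradients(net, concept, feature_stack, adapter)
  gated_gradcam(feature_stack, gy$grads, gy$g1, out_size = out_size)
}
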