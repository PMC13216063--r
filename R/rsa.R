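## tie-averaged ranks of an RDM's upper-triangle vector
rdm_ranks <- function(rdm) rank(utvec(rdm), ties.method = "average")

check_same_items <- function(...) {
  ns <- vapply(list(...), nrow, integer(1))
  if (length(unique(ns)) != 1L) {
    stop("RDMs are not over the same items", call. = FALSE)
  }
  ns[1L]
}

#' Spearman correlation between two RDMs
#'
#' Spearman's rank correlation over the upper-triangle vectors of the two
#' matrices, with tie-averaged ranks.
#'
#' @param rdm_a,rdm_b symmetric dissimilarity matrices over the same items
#'   (>= 4 items).
#' @return the correlation coefficient.
#' @export
spearman_rdm <- function(rdm_a, rdm_b) {
  n <- check_same_items(rdm_a, rdm_b)
  if (n < 4L) stop("need at least 4 items", call. = FALSE)
  va <- utvec(rdm_a); vb <- utvec(rdm_b)
  if (stats::sd(va) == 0 || stats::sd(vb) == 0) {
    stop("degenerate (constant) RDM", call. = FALSE)
  }
  stats::cor(va, vb, method = "spearman")
}

#' Partial Spearman correlation between RDMs, controlling for a covariate
#'
#' Rank-transforms the upper-triangle vectors of all three RDMs and applies
#' the first-order partial correlation
#' `r_ab.c = (r_ab - r_ac r_bc) / sqrt((1 - r_ac^2)(1 - r_bc^2))`,
#' the form used to control a neural-model comparison for low-level feature
#' structure.
#'
#' @param rdm_a,rdm_b the two RDMs being correlated.
#' @param covariate_rdm the RDM partialled out.
#' @return the partial correlation coefficient.
#' @export
partial_spearman_rdm <- function(rdm_a, rdm_b, covariate_rdm) {
  check_same_items(rdm_a, rdm_b, covariate_rdm)
  ra <- rdm_ranks(rdm_a); rb <- rdm_ranks(rdm_b); rc <- rdm_ranks(covariate_rdm)
  if (stats::sd(ra) == 0 || stats::sd(rb) == 0 || stats::sd(rc) == 0) {
    stop("degenerate (constant) RDM in partial correlation", call. = FALSE)
  }
  r_ab <- stats::cor(ra, rb)
  r_ac <- stats::cor(ra, rc)
  r_bc <- stats::cor(rb, rc)
  if (abs(r_ac) >= 1 - 1e-12 || abs(r_bc) >= 1 - 1e-12) {
    stop("covariate RDM is collinear with an input RDM", call. = FALSE)
  }
  (r_ab - r_ac * r_bc) / sqrt((1 - r_ac^2) * (1 - r_bc^2))
}

#' Mantel permutation test for RDM association
#'
#' Observed Spearman correlation between the two RDMs, with a null built by
#' jointly permuting the rows and columns (item labels) of the second RDM.
#' The permutation p-value uses the add-one rule
#' `p = (1 + #(null >= observed)) / (1 + n_perm)`; the two-tailed version
#' doubles the smaller tail (capped at 1).
#'
#' @param rdm_a,rdm_b RDMs over the same >= 4 items.
#' @param n_perm number of permutations (>= 99); the reference analyses use
#'   10,000.
#' @param seed optional integer seed.
#' @param tails 1 (association greater than chance) or 2.
#' @return list with `rho`, `p`, `n_perm`, `null` (the permuted
#'   correlations).
#' @export
mantel_test <- function(rdm_a, rdm_b, n_perm = 10000L, seed = NULL,
                        tails = 1L) {
  n <- check_same_items(rdm_a, rdm_b)
  if (n < 4L) stop("need at least 4 items for a Mantel test", call. = FALSE)
  if (n_perm < 99L) stop("n_perm must be >= 99", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  a <- unclass(as.matrix(rdm_a)); b <- unclass(as.matrix(rdm_b))
  ra <- rank(a[lower.tri(a)], ties.method = "average")
  obs <- stats::cor(ra, rank(b[lower.tri(b)], ties.method = "average"))
  null <- numeric(n_perm)
  for (i in seq_len(n_perm)) {
    p <- sample.int(n)
    bp <- b[p, p]
    null[i] <- stats::cor(ra, rank(bp[lower.tri(bp)],
                                   ties.method = "average"))
  }
  p_hi <- (1 + sum(null >= obs)) / (1 + n_perm)
  if (tails == 1L) {
    pval <- p_hi
  } else {
    p_lo <- (1 + sum(null <= obs)) / (1 + n_perm)
    pval <- min(1, 2 * min(p_hi, p_lo))
  }
  list(rho = obs, p = pval, n_perm = n_perm, null = null)
}

#' Fisher-z transform and its inverse
#'
#' `fisher_z` is `atanh` with inputs clipped to magnitude `1 - 1e-7` so
#' that perfect correlations map to a large finite value;
#' `fisher_z_inverse` is `tanh`.
#'
#' @param rho correlation value(s), `|rho| <= 1`.
#' @param z z-domain value(s).
#' @return transformed value(s).
#' @export
fisher_z <- function(rho) {
  if (any(abs(rho) > 1, na.rm = TRUE)) {
    stop("|rho| must be <= 1", call. = FALSE)
  }
  atanh(pmin(pmax(rho, -1 + 1e-7), 1 - 1e-7))
}

#' @rdname fisher_z
#' @export
fisher_z_inverse <- function(z) tanh(z)

#' Split-half reliability of the group-mean RDM
#'
#' Over many random 50/50 splits of the subjects, correlates (Spearman) the
#' two half-sample mean RDMs, averages the correlations in the Fisher-z
#' domain, back-transforms, and applies the Spearman-Brown correction
#' `2r / (1 + r)`. With an odd subject count the extra subject joins a
#' random half each split.
#'
#' @param subject_rdms list of >= 4 subject RDMs over the same items.
#' @param n_splits number of random splits (reference default 1,000).
#' @param seed optional integer seed.
#' @return the corrected group reliability (scalar, with the per-split
#'   correlations as attribute `splits`).
#' @export
split_half_reliability <- function(subject_rdms, n_splits = 1000L,
                                   seed = NULL) {
  S <- length(subject_rdms)
  if (S < 4L) stop("need at least 4 subjects", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  vs <- do.call(rbind, lapply(subject_rdms, utvec))
  rs <- numeric(n_splits)
  half <- S %/% 2L
  for (i in seq_len(n_splits)) {
    ord <- sample.int(S)
    h1 <- ord[seq_len(half)]
    h2 <- ord[(half + 1L):S]         # extra subject (if any) lands here
    m1 <- colMeans(vs[h1, , drop = FALSE])
    m2 <- colMeans(vs[h2, , drop = FALSE])
    rs[i] <- stats::cor(rank(m1), rank(m2))
  }
  r <- fisher_z_inverse(mean(fisher_z(rs)))
  out <- 2 * r / (1 + r)
  attr(out, "splits") <- rs
  out
}

clip_rel <- function(x) pmin(pmax(x, 0), 1 - 1e-7)

#' z-domain noise ceiling for model-subject RDM correlations
#'
#' Bounds the achievable mean Fisher-z correlation between a single model
#' instance's RDM and single-subject RDMs, combining subject-side
#' measurement reliability and model-instance variability:
#' * `rel_group`: split-half reliability of the group-mean RDM
#'   ([split_half_reliability()]);
#' * `rel_s = r(X_s, mean(X_-s))^2 / rel_group` per subject (leave-one-out,
#'   Spearman, used as an equality plug-in of the stated lower bound);
#' * `rel_model`: leave-one-out instance correlations, Fisher-z averaged
#'   and back-transformed;
#' * `NC_z = mean_s atanh(sqrt(rel_s * rel_model))`.
#'
#' All reliabilities are clipped to `[0, 1 - 1e-7]` (negative intermediate
#' correlations clip to 0) so the square roots and `atanh` stay defined.
#'
#' @param subject_rdms list of >= 3 subject RDMs.
#' @param model_rdms list of >= 3 model-instance RDMs over the same items.
#' @param rel_group optionally injected group reliability (skips the
#'   split-half computation).
#' @param n_splits splits for [split_half_reliability()].
#' @param seed optional integer seed.
#' @param rel_s,rel_model optionally injected reliabilities (test hook /
#'   closed-form checks); when both are given the RDM lists may be `NULL`.
#' @return object of class `cats_noise_ceiling`: `rel_group`, `rel_s`,
#'   `rel_model`, `nc_z`.
#' @export
noise_ceiling <- function(subject_rdms = NULL, model_rdms = NULL,
                          rel_group = NULL, n_splits = 200L, seed = NULL,
                          rel_s = NULL, rel_model = NULL) {
  if (is.null(rel_s)) {
    if (length(subject_rdms) < 3L) {
      stop("need at least 3 subject RDMs", call. = FALSE)
    }
    if (is.null(rel_group)) {
      rel_group <- as.numeric(split_half_reliability(subject_rdms, n_splits,
                                                     seed = seed))
    }
    if (rel_group <= 0) stop("degenerate group reliability", call. = FALSE)
    vs <- do.call(rbind, lapply(subject_rdms, utvec))
    S <- nrow(vs)
    r_loo <- vapply(seq_len(S), function(s) {
      mloo <- colMeans(vs[-s, , drop = FALSE])
      if (stats::sd(mloo) == 0 || stats::sd(vs[s, ]) == 0) {
        stop("degenerate (constant) subject or mean RDM", call. = FALSE)
      }
      stats::cor(rank(vs[s, ]), rank(mloo))
    }, numeric(1))
    rel_s <- clip_rel(clip_rel(r_loo)^2 / rel_group)
  } else {
    rel_s <- clip_rel(rel_s)
    if (is.null(rel_group)) rel_group <- NA_real_
  }
  if (is.null(rel_model)) {
    if (length(model_rdms) < 3L) {
      stop("need at least 3 model-instance RDMs", call. = FALSE)
    }
    vm <- do.call(rbind, lapply(model_rdms, utvec))
    M <- nrow(vm)
    r_i <- vapply(seq_len(M), function(i) {
      mloo <- colMeans(vm[-i, , drop = FALSE])
      if (stats::sd(mloo) == 0 || stats::sd(vm[i, ]) == 0) {
        stop("degenerate (constant) model-instance or mean RDM",
             call. = FALSE)
      }
      stats::cor(rank(vm[i, ]), rank(mloo))
    }, numeric(1))
    rel_model <- clip_rel(fisher_z_inverse(mean(fisher_z(r_i))))
  } else {
    rel_model <- clip_rel(rel_model)
  }
  nc_z <- mean(atanh(sqrt(rel_s * rel_model)))
  structure(list(rel_group = rel_group, rel_s = rel_s,
                 rel_model = rel_model, nc_z = nc_z),
            class = "cats_noise_ceiling")
}

#' @export
print.cats_noise_ceiling <- function(x, ...) {
  cat(sprintf("noise ceiling: NC_z = %.4f\n", x$nc_z))
  cat(sprintf("  rel_group = %.4f | rel_model = %.4f | rel_s in [%.4f, %.4f]\n",
              x$rel_group, x$rel_model, min(x$rel_s), max(x$rel_s)))
  invisible(x)
}

#' Group-level t statistics on per-model correlation values
#'
#' One-sample (against a scalar baseline) or paired t-test on Fisher-z
#' correlation values, with Cohen's d and the 95% confidence interval. A
#' zero-variance input yields an explicit degenerate result rather than a
#' silent NaN.
#'
#' @param x numeric vector of per-model (or per-subject) values.
#' @param baseline scalar null value (one-sample case).
#' @param paired optional numeric vector of the same length; when given a
#'   paired test of `x - paired` against 0 is run.
#' @param tails 1 or 2.
#' @return list with `t`, `df`, `p`, `cohen_d`, `ci`, `mean`, and
#'   `degenerate`.
#' @export
group_level_tests <- function(x, baseline = 0, paired = NULL, tails = 2L) {
  if (length(x) < 2L) stop("need n >= 2", call. = FALSE)
  d <- if (is.null(paired)) x - baseline else {
    if (length(paired) != length(x)) {
      stop("paired vector length mismatch", call. = FALSE)
    }
    x - paired
  }
  n <- length(d)
  s <- stats::sd(d)
  if (s == 0) {
    return(list(t = NA_real_, df = n - 1L, p = NA_real_,
                cohen_d = NA_real_, ci = c(mean(d), mean(d)),
                mean = mean(d), degenerate = TRUE))
  }
  tval <- mean(d) / (s / sqrt(n))
  df <- n - 1L
  p <- if (tails == 1L) stats::pt(tval, df, lower.tail = FALSE) else
    2 * stats::pt(abs(tval), df, lower.tail = FALSE)
  half <- stats::qt(0.975, df) * s / sqrt(n)
  list(t = tval, df = df, p = p, cohen_d = mean(d) / s,
       ci = c(mean(d) - half, mean(d) + half), mean = mean(d),
       degenerate = FALSE)
}
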