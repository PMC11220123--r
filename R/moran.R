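#' Spatial weights from a contiguity edge list
#'
#' Builds a symmetric binary neighbour matrix from an edge list and
#' optionally row-standardises it. Duplicate and reversed edges are
#' collapsed; isolated units are an error (their row cannot be
#' standardised and they carry no spatial information).
#'
#' @param edges two-column data.frame or matrix of unit labels (one
#'   neighbour pair per row).
#' @param labels character vector of all unit labels, fixing the matrix
#'   order.
#' @param style `"W"` (row-standardised, default) or `"B"` (binary).
#' @return object of class `spatial_weights`: list with `labels`, `W`
#'   (n x n matrix, zero diagonal), `style`, `source`.
#' @export
contiguity_weights <- function(edges, labels, style = c("W", "B")) {
  style <- match.arg(style)
  edges <- as.matrix(edges)[, 1:2, drop = FALSE]
  n <- length(labels)
  ia <- match(edges[, 1], labels); ib <- match(edges[, 2], labels)
  if (anyNA(ia) || anyNA(ib))
    stop("edge list mentions units not in `labels`: ",
         paste(unique(c(edges[, 1][is.na(ia)], edges[, 2][is.na(ib)])), collapse = ", "))
  if (any(ia == ib)) stop("self-neighbour edges are not allowed")
  W <- matrix(0, n, n, dimnames = list(labels, labels))
  W[cbind(ia, ib)] <- 1
  W[cbind(ib, ia)] <- 1
  iso <- labels[rowSums(W) == 0]
  if (length(iso)) stop("isolated unit(s) with no neighbours: ",
                        paste(iso, collapse = ", "))
  finish_weights(W, labels, style, source = "contiguity")
}

#' Spatial weights from k nearest neighbours
#'
#' Each unit is linked to its `k` nearest neighbours by Euclidean distance
#' on the supplied planar coordinates; distance ties are broken by label
#' order. The resulting relation is directed (not necessarily symmetric),
#' as usual for knn weights.
#'
#' @param coords numeric matrix n x 2 of planar coordinates.
#' @param k number of neighbours, `1 <= k < n`.
#' @param labels unit labels (defaults to rownames of `coords`).
#' @param style `"W"` (row-standardised) or `"B"` (binary).
#' @return a `spatial_weights` object with exactly `k` nonzero entries per
#'   row.
#' @export
knn_weights <- function(coords, k = 5, labels = rownames(coords),
                        style = c("W", "B")) {
  style <- match.arg(style)
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (is.null(labels)) labels <- sprintf("unit%02d", seq_len(n))
  if (k < 1 || k >= n) stop("k must satisfy 1 <= k < n")
  D <- as.matrix(stats::dist(coords))
  W <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n)) {
    ord <- order(D[i, -i], seq_len(n - 1L))  # ties by label position
    nb <- setdiff(seq_len(n), i)[ord][seq_len(k)]
    W[i, nb] <- 1
  }
  finish_weights(W, labels, style, source = sprintf("knn(k=%d)", k))
}

finish_weights <- function(W, labels, style, source) {
  diag(W) <- 0
  if (style == "W") W <- W / rowSums(W)
  structure(list(labels = labels, W = W, style = style, source = source),
            class = "spatial_weights")
}

#' @export
print.spatial_weights <- function(x, ...) {
  cat(sprintf("Spatial weights: %d units, style %s, source %s\n",
              length(x$labels), x$style, x$source))
  cat(sprintf("  links: %d, sum of weights S0 = %.4f\n",
              sum(x$W > 0), sum(x$W)))
  invisible(x)
}

moran_prepare <- function(x, weights) {
  if (!inherits(weights, "spatial_weights")) stop("weights must be spatial_weights")
  n <- length(weights$labels)
  if (length(x) != n) stop("x must have one value per spatial unit")
  if (anyNA(x) || any(!is.finite(x))) stop("x contains missing values")
  if (n < 3L) stop("Moran's I needs at least 3 units")
  if (stats::sd(x) == 0) stop("Moran's I is undefined for a constant variable")
  list(n = n, W = weights$W, z = x - mean(x))
}

moran_stat <- function(z, W) {
  n <- length(z)
  s2 <- sum(z^2) / n
  sum(W * outer(z, z)) / (s2 * sum(W))
}

#' Global Moran's I with analytic and permutation inference
#'
#' `I = sum_ij w_ij (x_i - xbar)(x_j - xbar) / (S^2 sum_ij w_ij)` with
#' `S^2 = (1/n) sum_i (x_i - xbar)^2`. The expectation under spatial
#' randomness is `-1/(n-1)`; the analytic z-test uses the randomisation
#' variance, and the permutation p-value is
#' `(1 + #{permutations at least as extreme}) / (n_perm + 1)`, two-sided
#' by default on `|I - E[I]|`.
#'
#' @param x numeric vector aligned with the weight labels.
#' @param weights a `spatial_weights` object.
#' @param n_perm number of random permutations (0 disables permutation
#'   inference).
#' @param seed RNG seed for the permutations.
#' @param alternative `"two.sided"` or `"greater"`.
#' @return object of class `moran_global`: list with `I`, `expectation`,
#'   `variance`, `z`, `p_norm`, `p_perm`, `n_perm`, `seed`,
#'   `alternative`.
#' @export
global_moran <- function(x, weights, n_perm = 999, seed = NULL,
                         alternative = c("two.sided", "greater")) {
  alternative <- match.arg(alternative)
  pr <- moran_prepare(x, weights)
  n <- pr$n; W <- pr$W; z <- pr$z
  I <- moran_stat(z, W)
  EI <- -1 / (n - 1)

  # randomisation variance (nonfree sampling)
  S0 <- sum(W)
  S1 <- 0.5 * sum((W + t(W))^2)
  S2 <- sum((rowSums(W) + colSums(W))^2)
  m2 <- sum(z^2) / n
  m4 <- sum(z^4) / n
  b2 <- m4 / m2^2
  VI <- (n * ((n^2 - 3 * n + 3) * S1 - n * S2 + 3 * S0^2) -
           b2 * ((n^2 - n) * S1 - 2 * n * S2 + 6 * S0^2)) /
    ((n - 1) * (n - 2) * (n - 3) * S0^2) - EI^2
  zscore <- (I - EI) / sqrt(VI)
  p_norm <- switch(alternative,
                   two.sided = 2 * stats::pnorm(abs(zscore), lower.tail = FALSE),
                   greater = stats::pnorm(zscore, lower.tail = FALSE))

  p_perm <- NA_real_
  if (n_perm > 0) {
    if (n_perm < 99) stop("use at least 99 permutations")
    if (!is.null(seed)) set.seed(seed)
    Iperm <- vapply(seq_len(n_perm), function(b) {
      zp <- z[sample.int(n)]
      moran_stat(zp, W)
    }, 0)
    extreme <- switch(alternative,
                      two.sided = abs(Iperm - EI) >= abs(I - EI) - 1e-15,
                      greater = Iperm >= I - 1e-15)
    p_perm <- (1 + sum(extreme)) / (n_perm + 1)
  }
  structure(list(I = I, expectation = EI, variance = VI, z = zscore,
                 p_norm = p_norm, p_perm = p_perm, n_perm = n_perm,
                 seed = seed, alternative = alternative),
            class = "moran_global")
}

#' @export
print.moran_global <- function(x, ...) {
  cat(sprintf("Global Moran's I = %.4f (E[I] = %.4f, z = %.3f)\n",
              x$I, x$expectation, x$z))
  cat(sprintf("  p (normal approx) = %.4g; p (%d permutations) = %.4g [%s]\n",
              x$p_norm, x$n_perm, x$p_perm, x$alternative))
  invisible(x)
}

#' Permutation significance of global Moran's I
#'
#' Convenience wrapper around [global_moran] returning just the inferential
#' quantities.
#'
#' @inheritParams global_moran
#' @return list with `p_norm`, `p_perm`, `z`.
#' @export
moran_significance <- function(x, weights, n_perm = 999, seed = NULL,
                               alternative = c("two.sided", "greater")) {
  g <- global_moran(x, weights, n_perm = n_perm, seed = seed,
                    alternative = match.arg(alternative))
  list(p_norm = g$p_norm, p_perm = g$p_perm, z = g$z)
}

#' Local Moran's I with cluster-quadrant classification
#'
#' `I_i = (x_i - xbar) / S^2 * sum_j w_ij (x_j - xbar)` with
#' `S^2 = (1/n) sum_i (x_i - xbar)^2`. Under this scaling the local values
#' satisfy `sum_i I_i = I_global * sum_ij w_ij` exactly. Each unit is
#' assigned a quadrant from the signs of its centred value and its centred
#' spatial lag: high-high, high-low, low-high or low-low. Conditional
#' permutation (holding unit i fixed, permuting the rest) yields a
#' per-unit p-value.
#'
#' @inheritParams global_moran
#' @param n_perm conditional permutations per unit (0 disables).
#' @return data.frame of class `moran_local`: `unit`, `I_i`, `quadrant`,
#'   `p_perm`.
#' @export
local_moran <- function(x, weights, n_perm = 999, seed = NULL) {
  pr <- moran_prepare(x, weights)
  n <- pr$n; W <- pr$W; z <- pr$z
  s2 <- sum(z^2) / n
  lag <- drop(W %*% z)
  Ii <- z * lag / s2
  quadrant <- ifelse(z >= 0,
                     ifelse(lag >= 0, "high-high", "high-low"),
                     ifelse(lag >= 0, "low-high", "low-low"))
  p_perm <- rep(NA_real_, n)
  if (n_perm > 0) {
    if (!is.null(seed)) set.seed(seed)
    for (i in seq_len(n)) {
      wi <- W[i, -i]
      zi <- z[i]
      others <- z[-i]
      Ib <- vapply(seq_len(n_perm), function(b)
        zi * sum(wi * others[sample.int(n - 1L)]) / s2, 0)
      p_perm[i] <- (1 + sum(abs(Ib) >= abs(Ii[i]) - 1e-15)) / (n_perm + 1)
    }
  }
  out <- data.frame(unit = weights$labels, I_i = Ii, quadrant = quadrant,
                    p_perm = p_perm, stringsAsFactors = FALSE)
  class(out) <- c("moran_local", class(out))
  out
}
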