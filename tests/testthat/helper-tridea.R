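# shared toy fixtures and independent oracles

# 1 input, 1 output: B is enveloped by A at half its input use
toy1 <- list(X = matrix(c(2, 4, 3), ncol = 1),
             Y = matrix(c(2, 2, 3), ncol = 1))

# 2 inputs, 1 output: D matches B radially but carries input-1 excess
toy2 <- list(X = matrix(c(1, 3, 4, 3, 1, 1), ncol = 2),
             Y = matrix(c(1, 1, 1), ncol = 1))

small_panel <- function(seed = 11, ...) {
  generate_panel(sim_config(n_dmus = 8, n_years = 3, seed = seed, ...))
}

# closed-form CRS score for 1-input/1-output data
crs_ratio_oracle <- function(x, y, k) (y[k] / x[k]) / max(y / x)

# brute-force VRS input-oriented score over a lambda grid (3 DMUs):
# theta(lambda) = max_i (sum lambda x)_i / x0_i over feasible lambda
vrs_grid_oracle <- function(X, Y, k, step = 0.002) {
  l1 <- seq(0, 1, by = step)
  best <- Inf
  for (a in l1) {
    b <- seq(0, 1 - a, by = step)
    lam <- cbind(a, b, 1 - a - b)
    ok <- lam %*% Y >= Y[k, ] - 1e-12
    if (!any(ok)) next
    lx <- lam[ok, , drop = FALSE] %*% X
    theta <- apply(sweep(lx, 2, X[k, ], "/"), 1, max)
    best <- min(best, min(theta))
  }
  best
}

# composed-error density of eps = v + u (v ~ N(0, sv^2), u ~ halfN(su^2))
# by direct numerical convolution
composed_density_oracle <- function(eps, sv, su) {
  f <- function(u) dnorm(eps - u, 0, sv) * 2 * dnorm(u, 0, su)
  integrate(f, 0, Inf, rel.tol = 1e-10)$value
}

# E[u | eps] by quadrature over the same convolution
jlms_oracle <- function(eps, sv, su) {
  num <- integrate(function(u) u * dnorm(eps - u, 0, sv) * 2 * dnorm(u, 0, su),
                   0, Inf, rel.tol = 1e-10)$value
  num / composed_density_oracle(eps, sv, su)
}

# double-loop global Moran oracle with the S^2 = (1/n) sum z^2 scaling
moran_loop_oracle <- function(x, W) {
  n <- length(x)
  z <- x - mean(x)
  s2 <- sum(z^2) / n
  acc <- 0
  for (i in 1:n) for (j in 1:n) acc <- acc + W[i, j] * z[i] * z[j]
  acc / (s2 * sum(W))
}

# 2x2 rook lattice weights (cells 11, 12, 21, 22)
rook2x2 <- function(style = "B") {
  edges <- data.frame(a = c("c11", "c11", "c12", "c21"),
                      b = c("c12", "c21", "c22", "c22"))
  contiguity_weights(edges, c("c11", "c12", "c21", "c22"), style = style)
}
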