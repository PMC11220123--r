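test_that("radial scores match hand-solved toy LPs", {
  # B(4,2) against A(2,2): A delivers B's output with half the input
  vrs <- solve_radial(toy1$X, toy1$Y, target = 2, frontier = "vrs")
  expect_equal(vrs$theta, 0.5, tolerance = 1e-9)
  expect_equal(vrs$lambda, c(1, 0, 0), tolerance = 1e-9)
  crs <- solve_radial(toy1$X, toy1$Y, target = 2, frontier = "crs")
  expect_equal(crs$theta, crs_ratio_oracle(toy1$X[, 1], toy1$Y[, 1], 2),
               tolerance = 1e-9)
  # a DMU alone is its own frontier
  expect_equal(solve_radial(toy1$X[1, , drop = FALSE],
                            toy1$Y[1, , drop = FALSE], 1, "vrs")$theta, 1)
  expect_equal(solve_radial(toy1$X[1, , drop = FALSE],
                            toy1$Y[1, , drop = FALSE], 1, "crs")$theta, 1)
})

test_that("CRS scores equal the single-ratio closed form on 1x1 data", {
  set.seed(101)
  for (rep in 1:20) {
    n <- sample(3:10, 1)
    x <- exp(rnorm(n, 1, 0.7)); y <- exp(rnorm(n, 0.5, 0.7))
    for (k in seq_len(n)) {
      th <- solve_radial(cbind(x), cbind(y), k, "crs")$theta
      expect_equal(th, crs_ratio_oracle(x, y, k), tolerance = 1e-8)
    }
  }
})

test_that("VRS scores agree with a brute-force lambda-grid oracle in 2D", {
  set.seed(202)
  for (rep in 1:5) {
    X <- matrix(exp(rnorm(6, 1, 0.5)), 3, 2)
    Y <- matrix(exp(rnorm(3, 0.5, 0.5)), 3, 1)
    for (k in 1:3) {
      th <- solve_radial(X, Y, k, "vrs")$theta
      expect_equal(th, vrs_grid_oracle(X, Y, k), tolerance = 2e-3)
      expect_lte(th, 1 + 1e-12)
    }
  }
})

test_that("VRS envelops at least as tightly as CRS", {
  set.seed(303)
  X <- matrix(exp(rnorm(12, 1, 0.6)), 6, 2)
  Y <- matrix(exp(rnorm(12, 0.5, 0.6)), 6, 2)
  for (k in 1:6) {
    expect_gte(solve_radial(X, Y, k, "vrs")$theta,
               solve_radial(X, Y, k, "crs")$theta - 1e-9)
  }
})

test_that("phase-2 slacks expose non-radial dominance", {
  # D(4,1) is radially efficient under VRS but B(3,1) dominates input 1
  th <- solve_radial(toy2$X, toy2$Y, 3, "vrs")$theta
  expect_equal(th, 1, tolerance = 1e-9)
  sl <- max_slacks(toy2$X, toy2$Y, 3, th, "vrs")
  expect_equal(sl$input_slacks, c(1, 0), tolerance = 1e-8)
  expect_equal(sl$output_slacks, 0, tolerance = 1e-8)
  # a strongly efficient DMU has zero slacks
  thA <- solve_radial(toy2$X, toy2$Y, 1, "vrs")$theta
  slA <- max_slacks(toy2$X, toy2$Y, 1, thA, "vrs")
  expect_equal(unname(c(slA$input_slacks, slA$output_slacks)), c(0, 0, 0),
               tolerance = 1e-8)
})

test_that("slack values are invariant to peer reordering", {
  perm <- c(2, 3, 1)
  th <- solve_radial(toy2$X, toy2$Y, 3, "vrs")$theta
  sl <- max_slacks(toy2$X, toy2$Y, 3, th, "vrs")
  thp <- solve_radial(toy2$X[perm, ], toy2$Y[perm, , drop = FALSE],
                      which(perm == 3), "vrs")$theta
  slp <- max_slacks(toy2$X[perm, ], toy2$Y[perm, , drop = FALSE],
                    which(perm == 3), thp, "vrs")
  expect_equal(sl$input_slacks, slp$input_slacks, tolerance = 1e-8)
})

test_that("returns-to-scale classification follows the CRS weight sum", {
  expect_equal(classify_rts(c(0.5, 0.5)), "crs")
  expect_equal(classify_rts(c(0.4, 0.4)), "irs")
  expect_equal(classify_rts(c(0.8, 0.4)), "drs")
  # tolerance band: sums within tau of 1 count as crs
  expect_equal(classify_rts(1 + 1e-7 / 2, tol = 1e-6), "crs")
  expect_equal(classify_rts(1 - 1e-7 / 2, tol = 1e-6), "crs")
  expect_error(classify_rts(c(-0.1, 0.5)), "nonnegative")
  # toy: B's CRS reference is A scaled by y_B/y_A = 1 -> crs;
  # shrinking B's output to 1.8 shrinks the weight sum to 0.9 -> irs
  lam <- solve_radial(toy1$X, toy1$Y, 2, "crs")$lambda
  expect_equal(sum(lam), 1, tolerance = 1e-9)
  expect_equal(classify_rts(lam), "crs")
  Y2 <- toy1$Y; Y2[2, 1] <- 1.8
  lam2 <- solve_radial(toy1$X, Y2, 2, "crs")$lambda
  expect_equal(sum(lam2), 0.9, tolerance = 1e-9)
  expect_equal(classify_rts(lam2), "irs")
})

test_that("panel DEA decomposes TE into PTE x SE with a nonempty frontier", {
  g <- small_panel()
  d <- run_dea_by_year(g$panel)
  s <- d$scores
  expect_equal(nrow(s), 8 * 3)
  expect_true(all(s$te > 0 & s$te <= s$pte + 1e-9 & s$pte <= 1))
  expect_equal(s$se, s$te / s$pte, tolerance = 1e-12)
  expect_true(all(tapply(s$pte, s$year, max) == 1))
  expect_true(all(d$slacks$slack >= 0))
})

test_that("radial scores are units invariant", {
  g <- small_panel()
  d <- run_dea_by_year(g$panel)
  p <- g$panel
  inputs2 <- p$inputs; inputs2[, , 1] <- inputs2[, , 1] * 1000
  outputs2 <- p$outputs; outputs2[, , 2] <- outputs2[, , 2] / 50
  p2 <- panel_data(p$dmu_ids, p$years, inputs2, outputs2, p$env, p$regions)
  d2 <- run_dea_by_year(p2)
  expect_equal(d2$scores$te, d$scores$te, tolerance = 1e-8)
  expect_equal(d2$scores$pte, d$scores$pte, tolerance = 1e-8)
})

test_that("adding a dominated DMU changes no other score", {
  set.seed(404)
  X <- matrix(exp(rnorm(10, 1, 0.5)), 5, 2)
  Y <- matrix(exp(rnorm(10, 0.5, 0.5)), 5, 2)
  base <- vapply(1:5, function(k) solve_radial(X, Y, k, "vrs")$theta, 0)
  # dominated: more of every input, less of every output than DMU 1
  Xd <- rbind(X, X[1, ] * 1.5); Yd <- rbind(Y, Y[1, ] * 0.5)
  with_dom <- vapply(1:5, function(k) solve_radial(Xd, Yd, k, "vrs")$theta, 0)
  expect_equal(with_dom, base, tolerance = 1e-9)
})

test_that("a panel of identical DMUs is fully efficient", {
  x <- array(rep(c(5, 7, 3), each = 6), c(3, 2, 3))
  y <- array(rep(c(4, 2), each = 6), c(3, 2, 2))
  p <- panel_data(c("a", "b", "c"), 2000:2001, x, y)
  d <- run_dea_by_year(p)
  expect_true(all(d$scores$te == 1 & d$scores$pte == 1 & d$scores$se == 1))
  expect_true(all(d$slacks$slack < 1e-8))
})

test_that("mean_scores averages per-DMU period means arithmetically", {
  s <- data.frame(dmu = rep(c("a", "b"), each = 2), year = c(1, 2, 1, 2),
                  te = c(0.4, 0.6, 1, 1), pte = c(0.8, 1, 1, 1),
                  se = c(0.5, 0.6, 1, 1))
  m <- mean_scores(s)
  expect_equal(unname(m["te"]), mean(c(0.5, 1)))
  expect_equal(unname(m["pte"]), mean(c(0.9, 1)))
  s2 <- s; s2$te <- s2$pte <- s2$se <- 0.7
  expect_equal(unname(mean_scores(s2)), c(0.7, 0.7, 0.7))
  expect_error(mean_scores(s[0, ]), "no efficiency")
})

test_that("positivity is enforced at load time", {
  X <- toy1$X; X[1] <- 0
  expect_error(solve_radial(X, toy1$Y, 1, "crs"), "positive")
  expect_error(panel_data(c("a", "b"), 2000,
                          array(c(1, -1), c(2, 1, 1)),
                          array(1, c(2, 1, 1))), "positive")
})
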