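test_that("composed-error likelihood nests the Gaussian regression at gamma = 0", {
  set.seed(21)
  n <- 40
  Z <- cbind(1, rnorm(n), runif(n))
  y <- drop(Z %*% c(2, 1, -1)) + rnorm(n, 0, 0.5)
  b_ols <- qr.solve(Z, y)
  res <- y - drop(Z %*% b_ols)
  s2 <- mean(res^2)
  ll_gauss <- sum(dnorm(res, 0, sqrt(s2), log = TRUE))
  expect_equal(sfa_loglikelihood(b_ols, s2, 0, y, Z), ll_gauss,
               tolerance = 1e-10)
})

test_that("composed-error likelihood matches the convolution quadrature oracle", {
  # tiny fixed dataset, hand-set residual structure
  Z <- cbind(1, c(-1, -0.5, 0, 0.5, 1))
  beta <- c(1, 2)
  slacks <- drop(Z %*% beta) + c(0.3, -0.2, 0.8, 1.5, -0.6)
  sv <- 0.6; su <- 0.9
  sigma_sq <- sv^2 + su^2
  gamma <- su^2 / sigma_sq
  ll <- sfa_loglikelihood(beta, sigma_sq, gamma, slacks, Z)
  eps <- slacks - drop(Z %*% beta)
  ll_oracle <- sum(log(vapply(eps, composed_density_oracle, 0, sv = sv, su = su)))
  expect_equal(ll, ll_oracle, tolerance = 1e-8)
})

test_that("likelihood obeys the scale change-of-variables identity", {
  set.seed(22)
  n <- 30
  Z <- cbind(1, rnorm(n))
  beta <- c(1, 0.5)
  slacks <- drop(Z %*% beta) + rnorm(n, 0, 0.4) + abs(rnorm(n, 0, 0.6))
  sv <- 0.4; su <- 0.6; s2 <- sv^2 + su^2; g <- su^2 / s2
  ll1 <- sfa_loglikelihood(beta, s2, g, slacks, Z)
  cc <- 3.7  # scale data and both error scales by c: loglik drops by n log c
  ll2 <- sfa_loglikelihood(beta * cc, s2 * cc^2, g, slacks * cc, Z)
  expect_equal(ll2, ll1 - n * log(cc), tolerance = 1e-8)
})

test_that("JLMS conditional inefficiency matches quadrature and is monotone", {
  expect_equal(jlms_conditional_mu(c(-2, 0, 3), 1, 0), c(0, 0, 0))
  expect_equal(jlms_conditional_mu(0, 1, 1), jlms_oracle(0, 1, 1),
               tolerance = 1e-6)
  for (eps in c(-1.5, -0.2, 0.4, 2)) {
    expect_equal(jlms_conditional_mu(eps, 0.7, 1.2),
                 jlms_oracle(eps, 0.7, 1.2), tolerance = 1e-6)
  }
  expect_gt(jlms_conditional_mu(1, 1, 1), jlms_conditional_mu(-1, 1, 1))
  expect_true(all(jlms_conditional_mu(seq(-3, 3, 0.5), 0.5, 0.8) > 0))
})

test_that("pure-noise data yield a near-zero inefficiency share and OLS betas", {
  set.seed(23)
  n <- 400
  env <- cbind(rnorm(n), runif(n))
  y <- 1 + 2 * env[, 1] - env[, 2] + rnorm(n, 0, 0.5)
  fit <- fit_sfa(y, env)
  expect_lt(fit$gamma, 0.35)
  b_ols <- stats::coef(stats::lm(y ~ env))
  expect_equal(unname(fit$beta), unname(b_ols), tolerance = 0.05)
  expect_gte(fit$loglik, fit$loglik_ols - 1e-6)
  lr <- lr_test_gamma(fit)
  expect_gte(lr$lr_stat, 0)
})

test_that("SFA recovers known frontier parameters at n = 2000", {
  set.seed(24)
  n <- 2000
  z <- rnorm(n)
  sv <- 0.5; su <- 1.0
  y <- 1 + 2 * z + rnorm(n, 0, sv) + abs(rnorm(n, 0, su))
  fit <- fit_sfa(y, cbind(z))
  # 3 Monte-Carlo standard errors: se(beta1) ~ sd(eps)/sqrt(n)
  mc_se <- sqrt(sv^2 + su^2 * (1 - 2 / pi)) / sqrt(n)
  expect_lt(abs(fit$beta[2] - 2), 3 * mc_se)
  expect_lt(abs(fit$beta[1] - 1), 0.15)
  g_true <- su^2 / (su^2 + sv^2)  # 0.8
  expect_lt(abs(fit$gamma - g_true), 0.1)
  expect_lt(abs(fit$sigma_mu - su), 0.15)
  # strong inefficiency is detected by the mixed chi-squared LR test
  expect_true(lr_test_gamma(fit)$reject)
})

test_that("LR statistic is invariant to affine rescaling of the environment", {
  set.seed(25)
  n <- 300
  env <- cbind(rnorm(n, 10, 2), runif(n, 0, 100))
  y <- 2 + 0.5 * env[, 1] + 0.05 * env[, 2] + rnorm(n, 0, 0.4) +
    abs(rnorm(n, 0, 0.8))
  f1 <- fit_sfa(y, env)
  env2 <- cbind(3 * env[, 1] - 5, env[, 2] / 10 + 2)
  f2 <- fit_sfa(y, env2)
  expect_equal(f1$lr_stat, f2$lr_stat, tolerance = 0.02)
  expect_equal(f1$loglik, f2$loglik, tolerance = 0.01)
})

test_that("input adjustment follows the max-based formula", {
  # two observations, one input: fitted f = (10, 30), nu_hat = (2, -1)
  # adjustments: (max f - f) + (max nu - nu) = (20, 0) + (0, 3) = (20, 3)
  p <- panel_data(c("a", "b"), 2000,
                  array(c(100, 200), c(2, 1, 1)),
                  array(c(1, 1), c(2, 1, 1)),
                  env = array(c(0, 1), c(2, 1, 1)))
  fit <- structure(list(
    input_name = "input1", beta = c(10, 20), gamma = 0.5,
    obs = data.frame(dmu = c("a", "b"), year = c(2000L, 2000L),
                     fitted = c(10, 30), nu_hat = c(2, -1))),
    class = "sfa_fit")
  adj <- adjust_inputs(p, list(fit))
  expect_equal(unname(adj$inputs[, 1, 1]), c(120, 203))
  # invariant to a constant shift of all fitted values
  fit2 <- fit; fit2$obs$fitted <- fit$obs$fitted + 55
  adj2 <- adjust_inputs(p, list(fit2))
  expect_equal(adj2$inputs, adj$inputs)
})

test_that("identical environments and noise leave inputs unchanged", {
  p <- panel_data(c("a", "b", "c"), 2000,
                  array(c(10, 20, 30), c(3, 1, 1)),
                  array(1, c(3, 1, 1)))
  fit <- structure(list(
    input_name = "input1",
    obs = data.frame(dmu = c("a", "b", "c"), year = 2000L,
                     fitted = c(7, 7, 7), nu_hat = c(0.3, 0.3, 0.3))),
    class = "sfa_fit")
  adj <- adjust_inputs(p, list(fit))
  expect_equal(adj$inputs, p$inputs)
})

test_that("adjusted inputs dominate the originals with equality at the double max", {
  g <- small_panel(seed = 31)
  d <- run_dea_by_year(g$panel)
  ef <- tridea:::env_design(g$panel)
  in_names <- dimnames(g$panel$inputs)[[3]]
  fits <- lapply(in_names, function(nm) {
    sl <- d$slacks[d$slacks$input == nm, ]
    key <- match(paste(ef$dmu, ef$year), paste(sl$dmu, sl$year))
    fit_sfa(sl$slack[key], ef$Z, dmu = ef$dmu, year = ef$year, input_name = nm)
  })
  adj <- adjust_inputs(g$panel, fits)
  expect_true(all(adj$inputs >= g$panel$inputs - 1e-9))
  # force one observation to attain both maxima: it must keep its input
  f <- fits[[1]]
  i_max <- which.max(f$obs$fitted)
  f$obs$nu_hat[i_max] <- max(f$obs$nu_hat) # now the double-max observation
  adj2 <- adjust_inputs(g$panel, replace(fits, 1, list(f)))
  delta <- adj2$inputs[, , 1] - g$panel$inputs[, , 1]
  idx <- cbind(match(f$obs$dmu[i_max], g$panel$dmu_ids),
               match(f$obs$year[i_max], g$panel$years))
  expect_equal(delta[idx], 0)
  expect_true(all(delta >= -1e-9))
})

test_that("constant slacks give the degenerate no-adjustment fit", {
  fit <- fit_sfa(rep(0, 20), cbind(rnorm(20)))
  expect_equal(fit$gamma, 0)
  expect_equal(fit$lr_stat, 0)
  expect_true(all(fit$obs$cond_mu == 0) && all(fit$obs$nu_hat == 0))
})
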