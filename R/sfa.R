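#' Composed-error log-likelihood for a slack frontier regression
#'
#' Log-likelihood of the model `S_i = Z_i' beta + v_i + u_i`, where `v` is
#' Gaussian noise N(0, sigma_v^2) and `u >= 0` is half-normal inefficiency
#' |N(0, sigma_u^2)|. Because slacks are a "bad" (input excess), the
#' one-sided component enters with a positive sign, the cost-frontier
#' orientation. The variance is parameterised as `sigma_sq = sigma_v^2 +
#' sigma_u^2` and `gamma = sigma_u^2 / sigma_sq`; at `gamma = 0` the
#' likelihood reduces to the Gaussian regression likelihood with variance
#' `sigma_sq`.
#'
#' @param beta coefficient vector (conformable with `ncol(env)`).
#' @param sigma_sq total variance, `> 0`.
#' @param gamma inefficiency variance share in `[0, 1)`.
#' @param slacks numeric response vector.
#' @param env design matrix including the intercept column.
#' @return the log-likelihood (scalar).
#' @export
sfa_loglikelihood <- function(beta, sigma_sq, gamma, slacks, env) {
  env <- as.matrix(env)
  if (length(beta) != ncol(env)) stop("beta does not match ncol(env)")
  if (!all(is.finite(c(beta, sigma_sq, gamma)))) stop("non-finite parameters")
  if (sigma_sq <= 0) stop("sigma_sq must be positive")
  if (gamma < 0 || gamma >= 1) stop("gamma must lie in [0, 1)")
  eps <- slacks - drop(env %*% beta)
  sigma <- sqrt(sigma_sq)
  lam <- sqrt(gamma / (1 - gamma))
  sum(log(2) - log(sigma) + stats::dnorm(eps / sigma, log = TRUE) +
        stats::pnorm(eps * lam / sigma, log.p = TRUE))
}

# internal: loglik on the unconstrained scale (beta, log sigma_sq, logit gamma)
sfa_negloglik_trans <- function(par, slacks, env) {
  k <- ncol(env)
  beta <- par[seq_len(k)]
  sigma_sq <- exp(par[k + 1L])
  gamma <- stats::plogis(par[k + 2L])
  eps <- slacks - drop(env %*% beta)
  sigma <- sqrt(sigma_sq)
  lam <- sqrt(gamma / (1 - gamma))
  ll <- sum(log(2) - log(sigma) + stats::dnorm(eps / sigma, log = TRUE) +
              stats::pnorm(eps * lam / sigma, log.p = TRUE))
  if (!is.finite(ll)) ll <- -1e10
  -ll
}

#' Fit a stochastic frontier regression of input slacks on environment
#'
#' Maximum-likelihood estimation of the composed-error regression used in
#' the second stage of three-stage DEA: each input's total slack is
#' regressed on the environmental covariates; the residual splits into
#' symmetric noise and one-sided (half-normal) inefficiency. Estimation is
#' by BFGS on the transformed parameters `(beta, log sigma^2, logit gamma)`
#' with multi-start: OLS coefficients combined with a grid of starting
#' values for gamma.
#'
#' After fitting, each composite residual is decomposed with the JLMS
#' conditional expectation ([jlms_conditional_mu]) into an inefficiency
#' part `E[u|eps]` and a noise part `nu_hat = eps - E[u|eps]`.
#'
#' @param slacks numeric vector of slack values (one per DMU-year).
#' @param env design matrix of environmental covariates *without*
#'   intercept; an intercept column is added internally.
#' @param dmu,year optional vectors labelling each observation.
#' @param input_name optional label of the input the slacks belong to.
#' @param gamma_grid starting values for the inefficiency share.
#' @return object of class `sfa_fit`: list with `beta`, `beta_se`,
#'   `sigma_sq`, `gamma`, `sigma_v`, `sigma_mu`, `loglik`, `loglik_ols`,
#'   `lr_stat`, `converged`, and `obs` (per-observation data.frame with
#'   `fitted`, `eps`, `cond_mu`, `nu_hat`).
#' @export
fit_sfa <- function(slacks, env, dmu = NULL, year = NULL, input_name = NULL,
                    gamma_grid = seq(0.05, 0.95, by = 0.10)) {
  env <- as.matrix(env)
  n <- length(slacks)
  if (nrow(env) != n) stop("slacks and env have different lengths")
  if (n < ncol(env) + 2L) stop("too few observations for the SFA regression")
  Z <- cbind(`(Intercept)` = 1, env)
  if (qr(Z)$rank < ncol(Z)) stop("environmental design matrix is rank deficient")

  # a constant response carries no frontier information (e.g. every DMU
  # exactly efficient, all slacks zero): return the degenerate no-effect fit
  if (stats::sd(slacks) == 0) {
    obs <- data.frame(
      dmu = if (is.null(dmu)) rep(NA_character_, n) else as.character(dmu),
      year = if (is.null(year)) rep(NA_integer_, n) else year,
      slack = slacks, fitted = rep(slacks[1], n), eps = rep(0, n),
      cond_mu = rep(0, n), nu_hat = rep(0, n), stringsAsFactors = FALSE)
    beta <- c(slacks[1], rep(0, ncol(env)))
    names(beta) <- colnames(Z)
    return(structure(list(input_name = input_name, beta = beta,
                          beta_se = stats::setNames(rep(NA_real_, ncol(Z)), colnames(Z)),
                          sigma_sq = .Machine$double.eps, gamma = 0,
                          sigma_v = sqrt(.Machine$double.eps), sigma_mu = 0,
                          loglik = NA_real_, loglik_ols = NA_real_,
                          lr_stat = 0, converged = TRUE, obs = obs),
                     class = "sfa_fit"))
  }

  ols <- stats::lm.fit(Z, slacks)
  res <- ols$residuals
  s2_ols <- sum(res^2) / n
  ll_ols <- sum(stats::dnorm(res, 0, sqrt(s2_ols), log = TRUE))

  k <- ncol(Z)
  best <- NULL
  for (g0 in gamma_grid) {
    s2_0 <- s2_ols / (1 - 2 * g0 / pi)     # Var(eps) = sigma^2 (1 - 2 gamma / pi)
    b0 <- ols$coefficients
    b0[1] <- b0[1] - sqrt(2 / pi) * sqrt(g0 * s2_0)  # OLS intercept absorbs E[u]
    par0 <- c(b0, log(s2_0), stats::qlogis(g0))
    opt <- tryCatch(
      stats::optim(par0, sfa_negloglik_trans, slacks = slacks, env = Z,
                   method = "BFGS", control = list(maxit = 500, reltol = 1e-12)),
      error = function(e) NULL)
    if (is.null(opt)) next
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best)) stop("SFA maximum-likelihood estimation failed from every start")

  par <- best$par
  beta <- par[seq_len(k)]; names(beta) <- colnames(Z)
  sigma_sq <- exp(par[k + 1L])
  gamma <- stats::plogis(par[k + 2L])
  loglik <- -best$value
  # MLE must weakly dominate OLS (gamma = 0 is inside the closure)
  if (loglik < ll_ols - 1e-6) {
    beta <- ols$coefficients; names(beta) <- colnames(Z)
    sigma_sq <- s2_ols; gamma <- 0; loglik <- ll_ols
  }
  sigma_mu <- sqrt(gamma * sigma_sq)
  sigma_v <- sqrt((1 - gamma) * sigma_sq)

  # standard errors from the numerical Hessian on the transformed scale,
  # delta method back to (beta); variance parameters reported without SEs
  beta_se <- rep(NA_real_, k)
  H <- tryCatch(stats::optimHess(par, sfa_negloglik_trans, slacks = slacks, env = Z),
                error = function(e) NULL)
  if (!is.null(H)) {
    V <- tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(V)) {
      d <- diag(V)[seq_len(k)]
      beta_se <- sqrt(pmax(d, 0))
      beta_se[d <= 0] <- NA_real_
    }
  }
  names(beta_se) <- colnames(Z)

  fitted <- drop(Z %*% beta)
  eps <- slacks - fitted
  cond_mu <- jlms_conditional_mu(eps, sigma_v, sigma_mu)
  obs <- data.frame(
    dmu = if (is.null(dmu)) rep(NA_character_, n) else as.character(dmu),
    year = if (is.null(year)) rep(NA_integer_, n) else year,
    slack = slacks, fitted = fitted, eps = eps,
    cond_mu = cond_mu, nu_hat = eps - cond_mu,
    stringsAsFactors = FALSE)

  structure(list(input_name = input_name, beta = beta, beta_se = beta_se,
                 sigma_sq = sigma_sq, gamma = gamma,
                 sigma_v = sigma_v, sigma_mu = sigma_mu,
                 loglik = loglik, loglik_ols = ll_ols,
                 lr_stat = max(2 * (loglik - ll_ols), 0),
                 converged = best$convergence == 0L, obs = obs),
            class = "sfa_fit")
}

#' @export
print.sfa_fit <- function(x, ...) {
  cat("Stochastic frontier regression of input slacks",
      if (!is.null(x$input_name)) paste0(" [", x$input_name, "]"), "\n", sep = "")
  tab <- data.frame(estimate = signif(x$beta, 5), std_error = signif(x$beta_se, 4))
  print(tab)
  cat(sprintf("sigma^2 = %.6g  gamma = %.4f  loglik = %.4f  LR(gamma=0) = %.4f\n",
              x$sigma_sq, x$gamma, x$loglik, x$lr_stat))
  invisible(x)
}

#' Likelihood-ratio test for the inefficiency variance share
#'
#' Tests `gamma = 0` (no one-sided inefficiency; the frontier regression
#' collapses to OLS) against `gamma > 0`. Because the null pins the
#' parameter to the boundary, the statistic is referred to the 50:50
#' mixture of a point mass at zero and chi-squared with 1 df; the 5%
#' critical value is 2.706.
#'
#' @param fit an `sfa_fit` object.
#' @param alpha test level.
#' @return list with `lr_stat`, `p_value`, `critical`, `reject`.
#' @export
lr_test_gamma <- function(fit, alpha = 0.05) {
  lr <- fit$lr_stat
  p <- if (lr <= 0) 1 else 0.5 * stats::pchisq(lr, df = 1, lower.tail = FALSE)
  crit <- stats::qchisq(1 - 2 * alpha, df = 1)
  list(lr_stat = lr, p_value = p, critical = crit, reject = lr > crit)
}

#' JLMS conditional expectation of inefficiency given the residual
#'
#' For the composed error `eps = v + u` (v Gaussian, u half-normal), the
#' conditional distribution of `u | eps` is normal truncated at zero with
#' mean `mu_star = eps * sigma_mu^2 / sigma^2` and standard deviation
#' `sigma_star = sigma_mu * sigma_v / sigma`; its expectation is
#' `mu_star + sigma_star * phi(mu_star/sigma_star) / Phi(mu_star/sigma_star)`.
#' This is the standard device for splitting a composite residual into an
#' inefficiency part and a noise part.
#'
#' @param eps composite residual(s).
#' @param sigma_v noise standard deviation, `> 0`.
#' @param sigma_mu inefficiency standard deviation, `>= 0`.
#' @return `E[u | eps]`, same length as `eps`; strictly positive when
#'   `sigma_mu > 0`, zero when `sigma_mu = 0`.
#' @export
jlms_conditional_mu <- function(eps, sigma_v, sigma_mu) {
  if (any(!is.finite(eps))) stop("non-finite residuals")
  if (sigma_v <= 0) stop("sigma_v must be positive")
  if (sigma_mu < 0) stop("sigma_mu must be nonnegative")
  if (sigma_mu == 0) return(rep(0, length(eps)))
  s2 <- sigma_v^2 + sigma_mu^2
  mu_star <- eps * sigma_mu^2 / s2
  sig_star <- sigma_mu * sigma_v / sqrt(s2)
  z <- mu_star / sig_star
  # inverse Mills ratio, computed on the log scale for stability far in
  # the lower tail
  mills <- exp(stats::dnorm(z, log = TRUE) - stats::pnorm(z, log.p = TRUE))
  mu_star + sig_star * mills
}

#' Adjust panel inputs for environment and noise
#'
#' The third-stage input correction: every DMU-year is moved to the least
#' favourable observed environment and the worst observed luck, input by
#' input, via
#' `X_adj = X + [max(f) - f] + [max(nu_hat) - nu_hat]`,
#' where `f` is the fitted environmental effect on the slack and `nu_hat`
#' the estimated noise component. Maxima are taken over the pooled
#' DMU-year sample per input. Adjusted inputs are never below the
#' originals, and the observation attaining both maxima keeps its input
#' unchanged. Outputs and environment are untouched.
#'
#' @param panel the original [panel_data].
#' @param fits list of `sfa_fit` objects, one per input, in input order;
#'   each must carry `dmu`/`year` labels covering the panel.
#' @return a new [panel_data] with adjusted inputs; the fits are attached
#'   as attribute `"sfa_fits"`.
#' @export
adjust_inputs <- function(panel, fits) {
  stopifnot(inherits(panel, "panel_data"))
  m <- dim(panel$inputs)[3]
  if (length(fits) != m) stop("need one sfa_fit per input (", m, ")")
  adj <- panel$inputs
  for (j in seq_len(m)) {
    f <- fits[[j]]
    if (!inherits(f, "sfa_fit")) stop("fits[[", j, "]] is not an sfa_fit")
    o <- f$obs
    idx_d <- match(o$dmu, panel$dmu_ids)
    idx_t <- match(o$year, panel$years)
    if (anyNA(idx_d) || anyNA(idx_t))
      stop("sfa_fit observations do not align with the panel")
    delta <- (max(o$fitted) - o$fitted) + (max(o$nu_hat) - o$nu_hat)
    adj[cbind(idx_d, idx_t, j)] <- adj[cbind(idx_d, idx_t, j)] + delta
  }
  out <- panel_data(panel$dmu_ids, panel$years, inputs = adj,
                    outputs = panel$outputs, env = panel$env,
                    regions = panel$regions)
  attr(out, "sfa_fits") <- fits
  out
}
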