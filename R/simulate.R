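#' Configuration for the synthetic panel generator
#'
#' Defaults mirror the structure of a provincial primary-healthcare panel:
#' 31 DMUs over 9 years, 3 inputs (institutions, personnel, beds), 2
#' outputs (consultations, admissions, unit ten-thousand) and 4
#' environmental covariates (GDP per capita, population density,
#' urbanization rate, government health expenditure). Inefficiency is
#' input-oriented: observed inputs are the efficient bundle inflated by
#' `exp(u)`, with `u = max(0, delta'Z_std + spatial + half-normal)` —
#' an environmental component linear in the standardised covariates, a
#' spatially autocorrelated SAR component over the neighbour graph, and an
#' i.i.d. half-normal draw. Independent per-input noise `exp(v)`,
#' `v ~ N(0, sigma_v^2)`, plays the role of random disturbance.
#'
#' @param n_dmus number of DMUs (31 uses the built-in province fixture).
#' @param n_years number of consecutive years.
#' @param start_year first year.
#' @param sigma_mu scale of the half-normal inefficiency component.
#' @param sigma_v standard deviation of per-input log-scale noise.
#' @param delta length-4 effect of the standardised environmental
#'   covariates on log-inefficiency (positive = inefficiency-increasing =
#'   slack-increasing).
#' @param rho spatial autocorrelation of the SAR inefficiency component,
#'   in `[0, 1)`.
#' @param spatial_sd innovation scale of the SAR component.
#' @param g technical-change factor per year: the efficient input bundle
#'   shrinks by `1/g` each year (`g > 1` is frontier progress).
#' @param seed RNG seed (required).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_dmus = 31, n_years = 9, start_year = 2012,
                       sigma_mu = 0.3, sigma_v = 0.1,
                       delta = c(gdp_pc = -0.08, pop_density = -0.05,
                                 urbanization = 0.08, gov_health_exp = 0.05),
                       rho = 0.4, spatial_sd = 0.1, g = 1.0, seed) {
  if (missing(seed)) stop("a seed is required")
  stopifnot(n_dmus >= 2, n_years >= 1, sigma_mu >= 0, sigma_v >= 0,
            rho >= 0, rho < 1, spatial_sd >= 0, g > 0, length(delta) == 4)
  structure(list(n_dmus = as.integer(n_dmus), n_years = as.integer(n_years),
                 start_year = as.integer(start_year), sigma_mu = sigma_mu,
                 sigma_v = sigma_v, delta = delta, rho = rho,
                 spatial_sd = spatial_sd, g = g, seed = as.integer(seed)),
            class = "sim_config")
}

#' The 31-unit provincial fixture
#'
#' Labels, three-region scheme (11 east / 8 central / 12 west), land-border
#' contiguity (with the Hainan-Guangdong strait crossing added so the
#' graph is connected) and approximate capital-city coordinates
#' (longitude, latitude) for China's 31 mainland provincial units.
#'
#' @return list with `labels` (31), `regions` (named character),
#'   `edges` (two-column data.frame of contiguity pairs), `coords`
#'   (31 x 2 matrix).
#' @export
province_fixture <- function() {
  reg <- c(
    Beijing = "east", Tianjin = "east", Hebei = "east", Shanxi = "central",
    `Inner Mongolia` = "west", Liaoning = "east", Jilin = "central",
    Heilongjiang = "central", Shanghai = "east", Jiangsu = "east",
    Zhejiang = "east", Anhui = "central", Fujian = "east",
    Jiangxi = "central", Shandong = "east", Henan = "central",
    Hubei = "central", Hunan = "central", Guangdong = "east",
    Guangxi = "west", Hainan = "east", Chongqing = "west",
    Sichuan = "west", Guizhou = "west", Yunnan = "west", Tibet = "west",
    Shaanxi = "west", Gansu = "west", Qinghai = "west", Ningxia = "west",
    Xinjiang = "west")
  edges <- matrix(c(
    "Beijing", "Hebei", "Beijing", "Tianjin", "Tianjin", "Hebei",
    "Hebei", "Liaoning", "Hebei", "Inner Mongolia", "Hebei", "Shanxi",
    "Hebei", "Henan", "Hebei", "Shandong",
    "Shanxi", "Inner Mongolia", "Shanxi", "Shaanxi", "Shanxi", "Henan",
    "Inner Mongolia", "Heilongjiang", "Inner Mongolia", "Jilin",
    "Inner Mongolia", "Liaoning", "Inner Mongolia", "Shaanxi",
    "Inner Mongolia", "Ningxia", "Inner Mongolia", "Gansu",
    "Liaoning", "Jilin", "Jilin", "Heilongjiang",
    "Shanghai", "Jiangsu", "Shanghai", "Zhejiang",
    "Jiangsu", "Zhejiang", "Jiangsu", "Anhui", "Jiangsu", "Shandong",
    "Zhejiang", "Anhui", "Zhejiang", "Jiangxi", "Zhejiang", "Fujian",
    "Anhui", "Jiangxi", "Anhui", "Henan", "Anhui", "Hubei",
    "Anhui", "Shandong",
    "Fujian", "Jiangxi", "Fujian", "Guangdong",
    "Jiangxi", "Guangdong", "Jiangxi", "Hunan", "Jiangxi", "Hubei",
    "Shandong", "Henan",
    "Henan", "Shaanxi", "Henan", "Hubei",
    "Hubei", "Shaanxi", "Hubei", "Chongqing", "Hubei", "Hunan",
    "Hunan", "Chongqing", "Hunan", "Guizhou", "Hunan", "Guangxi",
    "Hunan", "Guangdong",
    "Guangdong", "Guangxi", "Guangdong", "Hainan",
    "Guangxi", "Guizhou", "Guangxi", "Yunnan",
    "Chongqing", "Shaanxi", "Chongqing", "Guizhou", "Chongqing", "Sichuan",
    "Sichuan", "Shaanxi", "Sichuan", "Gansu", "Sichuan", "Qinghai",
    "Sichuan", "Tibet", "Sichuan", "Yunnan", "Sichuan", "Guizhou",
    "Guizhou", "Yunnan",
    "Yunnan", "Tibet",
    "Tibet", "Xinjiang", "Tibet", "Qinghai",
    "Shaanxi", "Gansu", "Shaanxi", "Ningxia",
    "Gansu", "Xinjiang", "Gansu", "Qinghai", "Gansu", "Ningxia",
    "Qinghai", "Xinjiang"), ncol = 2, byrow = TRUE)
  coords <- matrix(c(
    116.4, 39.9, 117.2, 39.1, 114.5, 38.0, 112.6, 37.9, 111.7, 40.8,
    123.4, 41.8, 125.3, 43.9, 126.6, 45.8, 121.5, 31.2, 118.8, 32.1,
    120.2, 30.3, 117.3, 31.9, 119.3, 26.1, 115.9, 28.7, 117.0, 36.7,
    113.6, 34.8, 114.3, 30.6, 113.0, 28.2, 113.3, 23.1, 108.3, 22.8,
    110.3, 20.0, 106.5, 29.6, 104.1, 30.7, 106.7, 26.6, 102.7, 25.0,
    91.1, 29.7, 108.9, 34.3, 103.8, 36.1, 101.8, 36.6, 106.2, 38.5,
    87.6, 43.8), ncol = 2, byrow = TRUE,
    dimnames = list(names(reg), c("lon", "lat")))
  list(labels = names(reg), regions = reg,
       edges = data.frame(unit_a = edges[, 1], unit_b = edges[, 2],
                          stringsAsFactors = FALSE),
       coords = coords)
}

#' Generate a synthetic panel with known ground truth
#'
#' Draws a balanced panel whose statistical structure matches the
#' assumptions of the three-stage analysis: a smooth monotone production
#' frontier (Cobb-Douglas input requirement per input, shifting by the
#' technical-change factor `g` each year), environmental covariates with
#' realistic scales, and input-oriented inefficiency combining an
#' environmental effect, a spatially autocorrelated SAR field over the
#' neighbour graph, and an i.i.d. half-normal component.
#'
#' @param config a [sim_config].
#' @return list with `panel` (a [panel_data]), `truth` (data.frame of
#'   per-DMU-year true inefficiency `u` and efficiency `exp(-u)` plus the
#'   parameters as attributes), `weights` (the `spatial_weights` used for
#'   the SAR field), and `fixture` info.
#' @export
generate_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_dmus; nT <- config$n_years
  years <- config$start_year + seq_len(nT) - 1L

  if (n == 31L) {
    fx <- province_fixture()
    labels <- fx$labels; regions <- fx$regions; coords <- fx$coords
    Wgt <- contiguity_weights(fx$edges, labels)
  } else {
    labels <- sprintf("DMU%02d", seq_len(n))
    regions <- NULL
    coords <- cbind(lon = stats::runif(n, 0, 10), lat = stats::runif(n, 0, 10))
    rownames(coords) <- labels
    Wgt <- knn_weights(coords, k = min(5L, n - 1L), labels = labels)
  }

  # environmental covariates: DMU-level base, mild deterministic drift
  gdp0 <- exp(stats::rnorm(n, log(5e4), 0.5))
  dens0 <- exp(stats::rnorm(n, log(300), 1.0))
  urb0 <- stats::runif(n, 25, 85)
  gov0 <- exp(stats::rnorm(n, log(40), 0.6))
  tgrid <- seq_len(nT) - 1L
  env <- array(NA_real_, c(n, nT, 4),
               dimnames = list(labels, years,
                               c("gdp_pc", "pop_density", "urbanization",
                                 "gov_health_exp")))
  for (ti in seq_len(nT)) {
    env[, ti, 1] <- gdp0 * 1.06^tgrid[ti] * exp(stats::rnorm(n, 0, 0.02))
    env[, ti, 2] <- dens0 * exp(stats::rnorm(n, 0, 0.01))
    env[, ti, 3] <- pmin(pmax(urb0 + 0.7 * tgrid[ti] +
                                stats::rnorm(n, 0, 0.5), 20), 95)
    env[, ti, 4] <- gov0 * 1.08^tgrid[ti] * exp(stats::rnorm(n, 0, 0.03))
  }

  # outputs: per-DMU scale with slow growth (ten-thousand units)
  cons0 <- exp(stats::rnorm(n, log(8000), 0.8))
  admi0 <- exp(stats::rnorm(n, log(250), 0.8))
  outputs <- array(NA_real_, c(n, nT, 2),
                   dimnames = list(labels, years,
                                   c("consultations", "admissions")))
  for (ti in seq_len(nT)) {
    outputs[, ti, 1] <- cons0 * 1.015^tgrid[ti] * exp(stats::rnorm(n, 0, 0.03))
    outputs[, ti, 2] <- admi0 * 1.015^tgrid[ti] * exp(stats::rnorm(n, 0, 0.03))
  }

  # spatially autocorrelated inefficiency field (constant over years):
  # (I - rho W)^{-1} applied to iid normals
  sar <- drop(solve(diag(n) - config$rho * Wgt$W,
                    stats::rnorm(n, 0, config$spatial_sd)))

  # inefficiency u >= 0: standardised-environment effect + SAR + half-normal
  u <- matrix(NA_real_, n, nT)
  for (ti in seq_len(nT)) {
    Zs <- scale(matrix(env[, ti, ], n, 4))
    u[, ti] <- pmax(0, drop(Zs %*% config$delta) + sar +
                      abs(stats::rnorm(n, 0, config$sigma_mu)))
  }

  # efficient input bundle from the inverted frontier: a convex CES output
  # aggregate (so that frontier points are undominated by convex
  # combinations, hence VRS-efficient) with a U-shaped scale term — most
  # productive scale size at Q = q_ref, increasing returns below it,
  # decreasing above. The frontier improves by factor g per year.
  inputs <- array(NA_real_, c(n, nT, 3),
                  dimnames = list(labels, years,
                                  c("institutions", "personnel", "beds")))
  base_coef <- c(institutions = 2.5, personnel = 9.0, beds = 4.0)
  q_ref <- 5000
  for (ti in seq_len(nT)) {
    Q <- sqrt(0.6 * outputs[, ti, 1]^2 + 0.4 * (30 * outputs[, ti, 2])^2)
    q <- Q / q_ref
    g_scale <- q_ref * (0.15 + 0.85 * q + 0.15 * q^2)
    for (j in 1:3) {
      noise <- exp(stats::rnorm(n, 0, config$sigma_v))
      inputs[, ti, j] <- base_coef[j] * g_scale / config$g^tgrid[ti] *
        exp(u[, ti]) * noise
    }
  }

  panel <- panel_data(labels, years, inputs = inputs, outputs = outputs,
                      env = env, regions = unname(regions[labels]))
  truth <- data.frame(
    dmu = rep(labels, times = nT),
    year = rep(years, each = n),
    u = as.vector(u), efficiency = exp(-as.vector(u)),
    stringsAsFactors = FALSE)
  attr(truth, "params") <- config
  list(panel = panel, truth = truth, weights = Wgt,
       fixture = list(labels = labels, regions = regions, coords = coords))
}
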