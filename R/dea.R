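#' Input-oriented radial efficiency of one DMU
#'
#' Solves the envelopment linear program of the CCR (constant returns,
#' `frontier = "crs"`) or BCC (variable returns, `frontier = "vrs"`) model:
#' minimise theta subject to `sum_j lambda_j x_j <= theta * x_target`,
#' `sum_j lambda_j y_j >= y_target`, `lambda >= 0` (VRS adds
#' `sum_j lambda_j = 1`). Columns are rescaled by their means before
#' solving — radial scores are units-invariant, so this only conditions
#' the LP.
#'
#' @param inputs numeric matrix, DMUs in rows, inputs in columns; positive.
#' @param outputs numeric matrix, DMUs in rows, outputs in columns; positive.
#' @param target row index of the DMU under evaluation.
#' @param frontier `"crs"` or `"vrs"`.
#' @return list with `theta` (radial score) and `lambda` (reference weights,
#'   one per peer DMU).
#' @examples
#' X <- matrix(c(2, 4, 3), ncol = 1)
#' Y <- matrix(c(2, 2, 3), ncol = 1)
#' solve_radial(X, Y, target = 2, frontier = "vrs")$theta  # 0.5
#' @export
solve_radial <- function(inputs, outputs, target,
                         frontier = c("crs", "vrs")) {
  frontier <- match.arg(frontier)
  dat <- check_dea_matrices(inputs, outputs, target)
  lp <- radial_lp(dat$X, dat$Y, target, frontier)
  if (lp$status != 0L)
    stop("internal error: radial envelopment LP did not solve (status ",
         lp$status, ")")
  lam <- lp$x[-1L]
  lam[lam < 0] <- 0
  list(theta = lp$objval, lambda = lam)
}

check_dea_matrices <- function(inputs, outputs, target = 1L) {
  X <- as.matrix(inputs); Y <- as.matrix(outputs)
  if (nrow(X) != nrow(Y)) stop("inputs and outputs must cover the same DMUs")
  if (any(X <= 0) || any(Y <= 0))
    stop("DEA requires strictly positive inputs and outputs")
  if (target < 1L || target > nrow(X)) stop("invalid target DMU index")
  list(X = X, Y = Y)
}

# envelopment LP in mean-rescaled units; theta is variable 1
radial_lp <- function(X, Y, target, frontier, point_x = NULL, point_y = NULL) {
  cx <- colMeans(X); cy <- colMeans(Y)
  X <- sweep(X, 2L, cx, "/"); Y <- sweep(Y, 2L, cy, "/")
  x0 <- if (is.null(point_x)) X[target, ] else point_x / cx
  y0 <- if (is.null(point_y)) Y[target, ] else point_y / cy
  n <- nrow(X); m <- ncol(X); s <- ncol(Y)
  A <- rbind(cbind(-x0, t(X)), cbind(rep(0, s), t(Y)))
  dir <- c(rep("<=", m), rep(">=", s))
  b <- c(rep(0, m), y0)
  if (frontier == "vrs") {
    A <- rbind(A, c(0, rep(1, n))); dir <- c(dir, "="); b <- c(b, 1)
  }
  lp_solve_simplex(c(1, rep(0, n)), A, dir, b)
}

#' Phase-2 slack maximisation at a fixed radial score
#'
#' With theta fixed at its phase-1 optimum, maximises the sum of input and
#' output slacks over the envelopment constraints
#' `sum_j lambda_j x_j + s_minus = theta * x_target`,
#' `sum_j lambda_j y_j - s_plus = y_target`. This resolves the
#' non-uniqueness of phase-1 reference weights: a radially efficient DMU is
#' strongly efficient iff all phase-2 slacks are zero.
#'
#' @inheritParams solve_radial
#' @param theta the phase-1 radial score for the same data and frontier.
#' @return list with `input_slacks` (length m), `output_slacks` (length s)
#'   and `lambda`, all in original data units.
#' @export
max_slacks <- function(inputs, outputs, target, theta,
                       frontier = c("crs", "vrs")) {
  frontier <- match.arg(frontier)
  dat <- check_dea_matrices(inputs, outputs, target)
  X <- dat$X; Y <- dat$Y
  cx <- colMeans(X); cy <- colMeans(Y)
  Xs <- sweep(X, 2L, cx, "/"); Ys <- sweep(Y, 2L, cy, "/")
  n <- nrow(X); m <- ncol(X); s <- ncol(Y)
  # variables: lambda (n), s_minus (m), s_plus (s)
  A <- rbind(cbind(t(Xs), diag(m), matrix(0, m, s)),
             cbind(t(Ys), matrix(0, s, m), -diag(s)))
  dir <- rep("=", m + s)
  b <- c(theta * Xs[target, ], Ys[target, ])
  if (frontier == "vrs") {
    A <- rbind(A, c(rep(1, n), rep(0, m + s))); dir <- c(dir, "="); b <- c(b, 1)
  }
  cvec <- c(rep(0, n), rep(-1, m + s))  # maximise total slack
  lp <- lp_solve_simplex(cvec, A, dir, b)
  if (lp$status != 0L)
    stop("internal error: slack-maximisation LP did not solve (status ",
         lp$status, ")")
  sol <- lp$x
  sl_in <- pmax(sol[n + seq_len(m)], 0) * cx
  sl_out <- pmax(sol[n + m + seq_len(s)], 0) * cy
  list(input_slacks = sl_in, output_slacks = sl_out,
       lambda = pmax(sol[seq_len(n)], 0))
}

#' Classify returns to scale from CRS reference weights
#'
#' The sum of the optimal CRS envelopment weights determines the scale
#' regime of the evaluated DMU: below 1 means increasing returns (the DMU
#' operates below most-productive scale), above 1 decreasing returns, and a
#' sum of 1 (within tolerance `tol`) constant returns.
#'
#' @param lambda nonnegative reference weights from the CRS optimum.
#' @param tol tolerance band around 1.
#' @return `"irs"`, `"crs"` or `"drs"`.
#' @export
classify_rts <- function(lambda, tol = 1e-6) {
  if (any(lambda < 0)) stop("reference weights must be nonnegative")
  s <- sum(lambda)
  if (s < 1 - tol) "irs" else if (s > 1 + tol) "drs" else "crs"
}

#' Run radial DEA over every DMU-year of a panel
#'
#' For each year (contemporaneous frontier; or one pooled frontier over all
#' DMU-years with `frontier_scope = "pooled"`), evaluates every DMU under
#' both CRS and VRS, decomposes technical efficiency as TE = PTE x SE, and
#' classifies returns to scale from the CRS weight sum. Input slacks for
#' the second-stage frontier regression are taken from the VRS phase-2
#' solution, by default as total input excess: radial contraction
#' shortfall `(1 - theta) * x` plus the phase-2 slack.
#'
#' @param panel a [panel_data] object.
#' @param frontier_scope `"per_year"` (each year evaluated against its own
#'   frontier) or `"pooled"` (all DMU-years form one frontier).
#' @param slack_definition `"radial_plus_slack"` (default) or
#'   `"slack_only"`.
#' @param tol efficiency tie tolerance: scores within `tol` of 1 are
#'   reported as exactly 1.
#' @return list of class `dea_result` with `scores` (data.frame: dmu, year,
#'   te, pte, se, rts) and `slacks` (data.frame: dmu, year, input, slack).
#' @export
run_dea_by_year <- function(panel,
                            frontier_scope = c("per_year", "pooled"),
                            slack_definition = c("radial_plus_slack", "slack_only"),
                            tol = 1e-6) {
  stopifnot(inherits(panel, "panel_data"))
  frontier_scope <- match.arg(frontier_scope)
  slack_definition <- match.arg(slack_definition)
  n <- length(panel$dmu_ids); yrs <- panel$years
  m <- dim(panel$inputs)[3]
  in_names <- dimnames(panel$inputs)[[3]]
  scores <- NULL; slacks <- NULL
  if (frontier_scope == "pooled") {
    Xall <- apply(panel$inputs, 3L, identity)   # (n*T) x m, dmu fastest
    Yall <- apply(panel$outputs, 3L, identity)
  }
  for (ti in seq_along(yrs)) {
    Xy <- matrix(panel$inputs[, ti, ], n, m)
    Yy <- matrix(panel$outputs[, ti, ], n, dim(panel$outputs)[3])
    if (frontier_scope == "per_year") { Xf <- Xy; Yf <- Yy }
    else { Xf <- Xall; Yf <- Yall }
    for (i in seq_len(n)) {
      crs <- radial_point(Xf, Yf, Xy[i, ], Yy[i, ], "crs")
      vrs <- radial_point(Xf, Yf, Xy[i, ], Yy[i, ], "vrs")
      te <- snap_one(min(crs$theta, 1), tol)
      pte <- snap_one(min(max(vrs$theta, te), 1), tol)
      ph2 <- max_slacks_point(Xf, Yf, Xy[i, ], Yy[i, ], vrs$theta, "vrs")
      rts <- classify_rts(crs$lambda, tol)
      scores <- rbind(scores, data.frame(
        dmu = panel$dmu_ids[i], year = yrs[ti], te = te, pte = pte,
        se = te / pte, rts = rts, stringsAsFactors = FALSE))
      excess <- if (slack_definition == "radial_plus_slack")
        (1 - vrs$theta) * Xy[i, ] + ph2$input_slacks else ph2$input_slacks
      slacks <- rbind(slacks, data.frame(
        dmu = panel$dmu_ids[i], year = yrs[ti], input = in_names,
        slack = pmax(excess, 0), stringsAsFactors = FALSE))
    }
  }
  rownames(scores) <- rownames(slacks) <- NULL
  structure(list(scores = scores, slacks = slacks,
                 frontier_scope = frontier_scope,
                 slack_definition = slack_definition),
            class = "dea_result")
}

# evaluate an arbitrary point against a frontier set (used for within-year,
# pooled and cross-period evaluation alike)
radial_point <- function(Xf, Yf, x0, y0, frontier) {
  lp <- radial_lp(Xf, Yf, target = NA, frontier, point_x = x0, point_y = y0)
  if (lp$status == 1L) return(list(theta = NA_real_, lambda = NULL, infeasible = TRUE))
  if (lp$status != 0L) stop("radial LP failed with status ", lp$status)
  list(theta = lp$objval, lambda = pmax(lp$x[-1L], 0), infeasible = FALSE)
}

max_slacks_point <- function(Xf, Yf, x0, y0, theta, frontier) {
  cx <- colMeans(Xf); cy <- colMeans(Yf)
  Xs <- sweep(Xf, 2L, cx, "/"); Ys <- sweep(Yf, 2L, cy, "/")
  x0s <- x0 / cx; y0s <- y0 / cy
  n <- nrow(Xs); m <- ncol(Xs); s <- ncol(Ys)
  A <- rbind(cbind(t(Xs), diag(m), matrix(0, m, s)),
             cbind(t(Ys), matrix(0, s, m), -diag(s)))
  dir <- rep("=", m + s)
  b <- c(theta * x0s, y0s)
  if (frontier == "vrs") {
    A <- rbind(A, c(rep(1, n), rep(0, m + s))); dir <- c(dir, "="); b <- c(b, 1)
  }
  lp <- lp_solve_simplex(c(rep(0, n), rep(-1, m + s)), A, dir, b)
  if (lp$status != 0L)
    stop("slack LP failed with status ", lp$status)
  list(input_slacks = pmax(lp$x[n + seq_len(m)], 0) * cx,
       output_slacks = pmax(lp$x[n + m + seq_len(s)], 0) * cy,
       lambda = pmax(lp$x[seq_len(n)], 0))
}

snap_one <- function(theta, tol = 1e-6) if (theta >= 1 - tol) 1 else theta

#' Mean efficiency scores across DMUs
#'
#' Per-DMU scores are first averaged over the period, then averaged
#' arithmetically across DMUs — the convention of reported mean rows in
#' provincial efficiency tables.
#'
#' @param scores a data.frame with columns `dmu`, `te`, `pte`, `se`
#'   (e.g. the `scores` element of [run_dea_by_year]).
#' @param digits rounding for reporting (default 3); use `NULL` for full
#'   precision.
#' @return named numeric vector with elements `te`, `pte`, `se`.
#' @export
mean_scores <- function(scores, digits = 3) {
  if (!nrow(scores)) stop("no efficiency records")
  per_dmu <- aggregate(scores[, c("te", "pte", "se")],
                       by = list(dmu = scores$dmu), FUN = mean)
  out <- colMeans(per_dmu[, c("te", "pte", "se")])
  if (!is.null(digits)) out <- round(out, digits)
  out
}

#' Per-DMU period-average efficiency
#'
#' @param scores the `scores` data.frame of a [run_dea_by_year] result.
#' @return data.frame with one row per DMU: mean te, pte, se over the
#'   period, and the modal returns-to-scale class.
#' @export
dmu_mean_scores <- function(scores) {
  agg <- aggregate(scores[, c("te", "pte", "se")],
                   by = list(dmu = scores$dmu), FUN = mean)
  rts <- vapply(split(scores$rts, scores$dmu), function(r)
    names(sort(table(r), decreasing = TRUE))[1L], "")
  agg$rts <- rts[agg$dmu]
  agg[order(match(agg$dmu, unique(scores$dmu))), ]
}
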