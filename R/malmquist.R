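#' Radial distance of a point to a given period's technology
#'
#' Input-oriented radial efficiency of an arbitrary (x, y) point measured
#' against the frontier spanned by `frontier_inputs`/`frontier_outputs`.
#' Within-period this equals [solve_radial]; across periods the score can
#' exceed 1 (the point lies outside the other period's technology). Under
#' VRS a cross-period evaluation can be infeasible, in which case `NA` is
#' returned with a warning rather than silently substituting CRS.
#'
#' @param point_inputs,point_outputs numeric vectors for the evaluated point.
#' @param frontier_inputs,frontier_outputs matrices spanning the technology.
#' @param frontier `"crs"` or `"vrs"`.
#' @return the radial distance (positive scalar, possibly `> 1`), or `NA`
#'   if infeasible under VRS.
#' @export
cross_distance <- function(point_inputs, point_outputs,
                           frontier_inputs, frontier_outputs,
                           frontier = c("crs", "vrs")) {
  frontier <- match.arg(frontier)
  Xf <- as.matrix(frontier_inputs); Yf <- as.matrix(frontier_outputs)
  if (any(Xf <= 0) || any(Yf <= 0) || any(point_inputs <= 0) ||
      any(point_outputs <= 0))
    stop("DEA requires strictly positive data")
  r <- radial_point(Xf, Yf, point_inputs, point_outputs, frontier)
  if (isTRUE(r$infeasible)) {
    warning("VRS cross-period evaluation infeasible; distance set to NA")
    return(NA_real_)
  }
  r$theta
}

#' Malmquist productivity components for one DMU and year pair
#'
#' Computes the geometric-mean Malmquist index between periods t and t+1
#' with its standard decomposition. With `D^a(b)` the CRS radial distance
#' of the period-b observation to the period-a frontier:
#' `EFFCH = D^{t+1}(t+1) / D^t(t)`,
#' `TECHCH = sqrt( (D^t(t+1)/D^{t+1}(t+1)) * (D^t(t)/D^{t+1}(t)) )`,
#' `TFPCH = EFFCH * TECHCH`. Pure efficiency change `PECH` is the analogous
#' VRS own-period ratio and `SECH = EFFCH / PECH`.
#'
#' @param X_t,Y_t input and output matrices of period t (DMUs in rows).
#' @param X_t1,Y_t1 the same for period t+1 (identical row order).
#' @param dmu row index of the DMU.
#' @return one-row data.frame: the four CRS distances, two VRS own-period
#'   distances, and effch, techch, pech, sech, tfpch.
#' @export
malmquist_components <- function(X_t, Y_t, X_t1, Y_t1, dmu) {
  X_t <- as.matrix(X_t); Y_t <- as.matrix(Y_t)
  X_t1 <- as.matrix(X_t1); Y_t1 <- as.matrix(Y_t1)
  d_t_t <- radial_point(X_t, Y_t, X_t[dmu, ], Y_t[dmu, ], "crs")$theta
  d_t_t1 <- radial_point(X_t, Y_t, X_t1[dmu, ], Y_t1[dmu, ], "crs")$theta
  d_t1_t <- radial_point(X_t1, Y_t1, X_t[dmu, ], Y_t[dmu, ], "crs")$theta
  d_t1_t1 <- radial_point(X_t1, Y_t1, X_t1[dmu, ], Y_t1[dmu, ], "crs")$theta
  v_t <- radial_point(X_t, Y_t, X_t[dmu, ], Y_t[dmu, ], "vrs")
  v_t1 <- radial_point(X_t1, Y_t1, X_t1[dmu, ], Y_t1[dmu, ], "vrs")
  v_t_th <- if (isTRUE(v_t$infeasible)) NA_real_ else v_t$theta
  v_t1_th <- if (isTRUE(v_t1$infeasible)) NA_real_ else v_t1$theta
  effch <- d_t1_t1 / d_t_t
  techch <- sqrt((d_t_t1 / d_t1_t1) * (d_t_t / d_t1_t))
  pech <- v_t1_th / v_t_th
  data.frame(d_t_t = d_t_t, d_t_t1 = d_t_t1, d_t1_t = d_t1_t,
             d_t1_t1 = d_t1_t1, vrs_t = v_t_th, vrs_t1 = v_t1_th,
             effch = effch, techch = techch, pech = pech,
             sech = effch / pech, tfpch = effch * techch)
}

#' Malmquist decomposition over all adjacent year pairs of a panel
#'
#' @param panel a [panel_data].
#' @return data.frame of class `malmquist_result`: one row per DMU and
#'   adjacent year pair with columns `dmu`, `period`, `effch`, `techch`,
#'   `pech`, `sech`, `tfpch`.
#' @export
run_malmquist <- function(panel) {
  stopifnot(inherits(panel, "panel_data"))
  yrs <- panel$years
  if (length(yrs) < 2L) stop("Malmquist needs at least two years")
  n <- length(panel$dmu_ids)
  m <- dim(panel$inputs)[3]; s <- dim(panel$outputs)[3]
  out <- NULL
  for (ti in seq_len(length(yrs) - 1L)) {
    X_t <- matrix(panel$inputs[, ti, ], n, m)
    Y_t <- matrix(panel$outputs[, ti, ], n, s)
    X_t1 <- matrix(panel$inputs[, ti + 1L, ], n, m)
    Y_t1 <- matrix(panel$outputs[, ti + 1L, ], n, s)
    for (i in seq_len(n)) {
      rec <- malmquist_components(X_t, Y_t, X_t1, Y_t1, i)
      out <- rbind(out, cbind(
        data.frame(dmu = panel$dmu_ids[i],
                   period = sprintf("%d-%d", yrs[ti], yrs[ti + 1L]),
                   stringsAsFactors = FALSE),
        rec))
    }
  }
  rownames(out) <- NULL
  class(out) <- c("malmquist_result", class(out))
  out
}

#' Geometric-mean summary of Malmquist components
#'
#' Components are summarised with geometric means (the index is
#' multiplicative, so the decomposition identities survive aggregation).
#' Records with a missing component (VRS cross-period infeasibility) are
#' excluded, with a message reporting the count.
#'
#' @param records data.frame with columns `dmu`, `period` and the five
#'   component columns (e.g. from [run_malmquist]).
#' @param by grouping: `"year_pair"`, `"dmu"` or `"overall"`.
#' @return data.frame of geometric means per group.
#' @export
summarize_malmquist <- function(records, by = c("year_pair", "dmu", "overall")) {
  by <- match.arg(by)
  comp <- c("effch", "techch", "pech", "sech", "tfpch")
  if (!nrow(records)) stop("no Malmquist records")
  ok <- stats::complete.cases(records[, comp])
  if (any(!ok)) message(sum(!ok), " record(s) with missing components excluded")
  rec <- records[ok, ]
  if (any(as.matrix(rec[, comp]) <= 0)) stop("nonpositive Malmquist component")
  key <- switch(by, year_pair = rec$period, dmu = rec$dmu,
                overall = rep("overall", nrow(rec)))
  gm <- function(v) exp(mean(log(v)))
  out <- aggregate(rec[, comp], by = list(group = key), FUN = gm)
  names(out)[1] <- switch(by, year_pair = "period", dmu = "dmu", overall = "group")
  out
}
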