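#' Construct a balanced DMU x year panel
#'
#' The central data container: a balanced panel of decision-making units
#' (DMUs) observed over consecutive years, carrying strictly positive input
#' and output quantities plus environmental covariates that are outside
#' managerial control. All downstream stages (radial DEA, stochastic-frontier
#' slack adjustment, Malmquist decomposition, spatial autocorrelation)
#' consume this object.
#'
#' @param dmu_ids character vector of unique DMU labels, length n.
#' @param years integer vector of consecutive years (step 1), length T.
#' @param inputs numeric array n x T x m, strictly positive.
#' @param outputs numeric array n x T x s, strictly positive.
#' @param env numeric array n x T x q of environmental covariates (may be
#'   any sign).
#' @param regions optional character vector, length n, a region label per
#'   DMU (e.g. "east"/"central"/"west").
#' @return An object of class `panel_data`: a list with elements
#'   `dmu_ids`, `years`, `regions`, `inputs`, `outputs`, `env`.
#' @examples
#' p <- generate_panel(sim_config(n_dmus = 5, n_years = 3, seed = 1))$panel
#' p
#' @export
panel_data <- function(dmu_ids, years, inputs, outputs, env = NULL,
                       regions = NULL) {
  dmu_ids <- as.character(dmu_ids)
  years <- as.integer(years)
  n <- length(dmu_ids)
  nT <- length(years)
  if (anyDuplicated(dmu_ids)) stop("duplicate DMU labels")
  if (n < 2L) stop("a panel needs at least 2 DMUs")
  if (nT < 1L) stop("a panel needs at least 1 year")
  if (nT > 1L && any(diff(years) != 1L))
    stop("years must be strictly increasing with step 1")
  inputs <- check_panel_array(inputs, n, nT, "inputs", positive = TRUE)
  outputs <- check_panel_array(outputs, n, nT, "outputs", positive = TRUE)
  if (!is.null(env)) env <- check_panel_array(env, n, nT, "env", positive = FALSE)
  if (!is.null(regions)) {
    regions <- as.character(regions)
    if (length(regions) != n) stop("regions must have one label per DMU")
  }
  name_dims <- function(a, stem) {
    dn <- dimnames(a)
    v <- if (is.null(dn) || is.null(dn[[3]]))
      sprintf("%s%d", stem, seq_len(dim(a)[3])) else dn[[3]]
    dimnames(a) <- list(dmu_ids, years, v)
    a
  }
  inputs <- name_dims(inputs, "input")
  outputs <- name_dims(outputs, "output")
  if (!is.null(env)) env <- name_dims(env, "env")
  structure(list(dmu_ids = dmu_ids, years = years, regions = regions,
                 inputs = inputs, outputs = outputs, env = env),
            class = "panel_data")
}

check_panel_array <- function(a, n, nT, what, positive) {
  a <- as.array(a)
  if (length(dim(a)) != 3L || dim(a)[1] != n || dim(a)[2] != nT)
    stop(sprintf("%s must be an n x T x k array (%d x %d x k)", what, n, nT))
  if (anyNA(a) || any(!is.finite(a)))
    stop(sprintf("%s contains missing or non-finite cells", what))
  if (positive && any(a <= 0)) {
    bad <- which(a <= 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("%s must be strictly positive (first violation at dmu %d, year index %d, column %d)",
                 what, bad[1], bad[2], bad[3]))
  }
  a
}

#' @export
print.panel_data <- function(x, ...) {
  cat(sprintf("Balanced panel: %d DMUs x %d years (%d-%d)\n",
              length(x$dmu_ids), length(x$years), min(x$years), max(x$years)))
  cat(sprintf("  inputs: %d (%s)\n", dim(x$inputs)[3],
              paste(dimnames(x$inputs)[[3]], collapse = ", ")))
  cat(sprintf("  outputs: %d (%s)\n", dim(x$outputs)[3],
              paste(dimnames(x$outputs)[[3]], collapse = ", ")))
  if (!is.null(x$env))
    cat(sprintf("  environment: %d (%s)\n", dim(x$env)[3],
                paste(dimnames(x$env)[[3]], collapse = ", ")))
  if (!is.null(x$regions))
    cat("  regions:", paste(sprintf("%s=%d", names(table(x$regions)),
                                    table(x$regions)), collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.data.frame.panel_data <- function(x, ...) {
  n <- length(x$dmu_ids); nT <- length(x$years)
  grid <- expand.grid(dmu = x$dmu_ids, year = x$years,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  flat <- function(a) {
    k <- dim(a)[3]
    m <- matrix(a, n * nT, k)
    colnames(m) <- dimnames(a)[[3]]
    m
  }
  df <- cbind(grid, as.data.frame(flat(x$inputs)), as.data.frame(flat(x$outputs)))
  if (!is.null(x$env)) df <- cbind(df, as.data.frame(flat(x$env)))
  if (!is.null(x$regions))
    df <- cbind(df[, 1:2], region = rep(x$regions, times = nT),
                df[, -(1:2), drop = FALSE])
  df[order(match(df$dmu, x$dmu_ids), df$year), , drop = FALSE]
}

panel_var_names <- list(
  inputs = c("institutions", "personnel", "beds"),
  outputs = c("consultations", "admissions"),
  env = c("gdp_pc", "pop_density", "urbanization", "gov_health_exp"))

#' Read a panel from a long-format CSV
#'
#' Expected header: `dmu,year,region,institutions,personnel,beds,`
#' `consultations,admissions,gdp_pc,pop_density,urbanization,gov_health_exp`
#' (the `region` and environmental columns are optional). One row per
#' DMU-year; the panel must be balanced and inputs/outputs strictly
#' positive. Violations are reported with the offending cell.
#'
#' @param path path to a CSV file.
#' @return a [panel_data] object.
#' @export
read_panel <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("dmu", "year", panel_var_names$inputs, panel_var_names$outputs)
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("panel CSV is missing columns: ", paste(miss, collapse = ", "))
  dmus <- unique(df$dmu)
  years <- sort(unique(as.integer(df$year)))
  key <- paste(df$dmu, df$year)
  full <- as.vector(outer(dmus, years, paste))
  gap <- setdiff(full, key)
  if (length(gap)) stop("panel is unbalanced; missing cell(s): ",
                        paste(utils::head(gap, 5), collapse = "; "))
  if (anyDuplicated(key)) stop("duplicate DMU-year rows in panel CSV")
  # year-major order so each n x T slice fills column by column
  df <- df[order(df$year, match(df$dmu, dmus)), ]
  n <- length(dmus); nT <- length(years)
  grab <- function(cols) {
    a <- array(NA_real_, c(n, nT, length(cols)),
               dimnames = list(dmus, years, cols))
    for (j in seq_along(cols)) a[, , j] <- matrix(df[[cols[j]]], n, nT)
    a
  }
  env_cols <- intersect(panel_var_names$env, names(df))
  regions <- if ("region" %in% names(df)) df$region[df$year == years[1]] else NULL
  panel_data(dmus, years,
             inputs = grab(panel_var_names$inputs),
             outputs = grab(panel_var_names$outputs),
             env = if (length(env_cols)) grab(env_cols) else NULL,
             regions = regions)
}

#' Write a panel to a long-format CSV
#'
#' Inverse of [read_panel]: `write_panel` then `read_panel` reproduces the
#' panel exactly.
#'
#' @param panel a [panel_data] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  utils::write.csv(as.data.frame(panel), path, row.names = FALSE)
  invisible(path)
}
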