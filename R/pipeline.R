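#' Run the full three-stage efficiency analysis
#'
#' Stage 1: radial DEA (CRS and VRS) over the raw panel. Stage 2: one
#' stochastic-frontier regression per input of its total slack on the
#' environmental covariates, followed by the max-based input adjustment
#' that places every DMU in the least favourable environment with the
#' worst observed luck. Stage 3: DEA re-run on the adjusted inputs with
#' the original outputs. Optionally, Malmquist decomposition between
#' adjacent years (on adjusted inputs by default) and global/local Moran's
#' I per year on the stage-3 technical efficiency.
#'
#' An identity audit runs at the end: TE = PTE x SE in both stages,
#' TFPCH = EFFCH x TECHCH and EFFCH = PECH x SECH record-wise, and the sum
#' of local Moran values against the global statistic. Violations abort.
#'
#' @param panel a [panel_data] with environmental covariates.
#' @param weights optional `spatial_weights` aligned with the panel DMUs;
#'   when `NULL` and the panel matches the 31-unit province fixture, the
#'   fixture contiguity weights are used; otherwise the spatial analysis
#'   is skipped.
#' @param config list of options: `frontier_scope` ("per_year"/"pooled"),
#'   `slack_definition` ("radial_plus_slack"/"slack_only"),
#'   `malmquist_source` ("adjusted"/"raw"), `malmquist` (logical),
#'   `moran` (logical), `n_perm`, `seed`.
#' @return object of class `three_stage_result` with elements `stage1`,
#'   `sfa_fits`, `adjusted_panel`, `stage3`, `malmquist`,
#'   `malmquist_summary`, `moran` (per-year list), `lisa` (per-year list),
#'   `regional`, `config`.
#' @export
run_three_stage <- function(panel, weights = NULL, config = list()) {
  stopifnot(inherits(panel, "panel_data"))
  if (is.null(panel$env)) stop("three-stage analysis needs environmental covariates")
  cfg <- utils::modifyList(list(
    frontier_scope = "per_year", slack_definition = "radial_plus_slack",
    malmquist_source = "adjusted", malmquist = TRUE, moran = TRUE,
    n_perm = 999, seed = 1L), config)

  stage1 <- run_dea_by_year(panel, frontier_scope = cfg$frontier_scope,
                            slack_definition = cfg$slack_definition)

  in_names <- dimnames(panel$inputs)[[3]]
  env_flat <- env_design(panel)
  fits <- lapply(seq_along(in_names), function(j) {
    sl <- stage1$slacks[stage1$slacks$input == in_names[j], ]
    key <- match(paste(env_flat$dmu, env_flat$year), paste(sl$dmu, sl$year))
    fit_sfa(sl$slack[key], env_flat$Z, dmu = env_flat$dmu,
            year = env_flat$year, input_name = in_names[j])
  })
  names(fits) <- in_names

  adjusted <- adjust_inputs(panel, fits)
  stage3 <- run_dea_by_year(adjusted, frontier_scope = cfg$frontier_scope,
                            slack_definition = cfg$slack_definition)

  malm <- malm_sum <- NULL
  if (isTRUE(cfg$malmquist) && length(panel$years) > 1L) {
    src <- if (cfg$malmquist_source == "adjusted") adjusted else panel
    malm <- run_malmquist(src)
    malm_sum <- summarize_malmquist(malm, by = "year_pair")
  }

  if (is.null(weights) && isTRUE(cfg$moran)) {
    fx <- province_fixture()
    if (length(panel$dmu_ids) == 31L && all(panel$dmu_ids == fx$labels))
      weights <- contiguity_weights(fx$edges, fx$labels)
  }
  moran <- lisa <- NULL
  if (isTRUE(cfg$moran) && !is.null(weights)) {
    if (!all(weights$labels == panel$dmu_ids))
      stop("spatial weights are not aligned with the panel DMUs")
    moran <- list(); lisa <- list()
    for (ti in seq_along(panel$years)) {
      yr <- panel$years[ti]
      x <- stage3$scores$te[stage3$scores$year == yr]
      moran[[as.character(yr)]] <-
        global_moran(x, weights, n_perm = cfg$n_perm, seed = cfg$seed + ti)
      lisa[[as.character(yr)]] <-
        local_moran(x, weights, n_perm = cfg$n_perm, seed = cfg$seed + ti)
    }
  }

  regional <- if (!is.null(panel$regions))
    regional_summary(stage1$scores, stage3$scores,
                     stats::setNames(panel$regions, panel$dmu_ids)) else NULL

  res <- structure(list(stage1 = stage1, sfa_fits = fits,
                        adjusted_panel = adjusted, stage3 = stage3,
                        malmquist = malm, malmquist_summary = malm_sum,
                        moran = moran, lisa = lisa, regional = regional,
                        config = cfg),
                   class = "three_stage_result")
  audit_identities(res)
  res
}

audit_identities <- function(res, tol = 1e-9) {
  for (st in list(res$stage1$scores, res$stage3$scores)) {
    if (max(abs(st$te - st$pte * st$se)) > 1e-7)
      stop("identity audit failed: TE != PTE * SE")
  }
  if (!is.null(res$malmquist)) {
    m <- res$malmquist[stats::complete.cases(res$malmquist), ]
    if (max(abs(m$tfpch - m$effch * m$techch)) > tol)
      stop("identity audit failed: TFPCH != EFFCH * TECHCH")
    if (max(abs(m$effch - m$pech * m$sech)) > 1e-7)
      stop("identity audit failed: EFFCH != PECH * SECH")
  }
  invisible(TRUE)
}

env_design <- function(panel) {
  n <- length(panel$dmu_ids); nT <- length(panel$years)
  q <- dim(panel$env)[3]
  Z <- matrix(panel$env, n * nT, q)
  colnames(Z) <- dimnames(panel$env)[[3]]
  list(Z = Z, dmu = rep(panel$dmu_ids, times = nT),
       year = rep(panel$years, each = n))
}

#' @export
print.three_stage_result <- function(x, ...) {
  m1 <- mean_scores(x$stage1$scores); m3 <- mean_scores(x$stage3$scores)
  cat("Three-stage DEA result\n")
  cat(sprintf("  stage 1 means: TE %.3f  PTE %.3f  SE %.3f\n", m1[1], m1[2], m1[3]))
  cat(sprintf("  stage 3 means: TE %.3f  PTE %.3f  SE %.3f\n", m3[1], m3[2], m3[3]))
  if (!is.null(x$malmquist_summary)) {
    ov <- summarize_malmquist(x$malmquist, by = "overall")
    cat(sprintf("  Malmquist (geometric means): TFPCH %.3f  EFFCH %.3f  TECHCH %.3f\n",
                ov$tfpch, ov$effch, ov$techch))
  }
  if (!is.null(x$moran)) {
    Is <- vapply(x$moran, function(g) g$I, 0)
    cat(sprintf("  global Moran's I on stage-3 TE: %.3f to %.3f over %d years\n",
                min(Is), max(Is), length(Is)))
  }
  invisible(x)
}

#' Regional before/after efficiency summary
#'
#' Unweighted arithmetic means of per-DMU period-average scores within
#' each region, for stage 1 and stage 3, with a direction marker for the
#' TE change.
#'
#' @param scores_stage1,scores_stage3 `scores` data.frames from
#'   [run_dea_by_year].
#' @param scheme named character vector mapping DMU label to region.
#' @param digits reporting precision.
#' @return data.frame with one row per region plus an overall row.
#' @export
regional_summary <- function(scores_stage1, scores_stage3, scheme, digits = 3) {
  p1 <- dmu_mean_scores(scores_stage1)
  p3 <- dmu_mean_scores(scores_stage3)
  if (anyNA(scheme[p1$dmu])) {
    bad <- p1$dmu[is.na(scheme[p1$dmu])]
    stop("DMU(s) not covered by the region scheme: ", paste(bad, collapse = ", "))
  }
  groups <- c(split(seq_len(nrow(p1)), scheme[p1$dmu]),
              list(overall = seq_len(nrow(p1))))
  out <- do.call(rbind, lapply(names(groups), function(g) {
    i <- groups[[g]]
    data.frame(region = g,
               te_before = round(mean(p1$te[i]), digits),
               pte_before = round(mean(p1$pte[i]), digits),
               se_before = round(mean(p1$se[i]), digits),
               te_after = round(mean(p3$te[i]), digits),
               pte_after = round(mean(p3$pte[i]), digits),
               se_after = round(mean(p3$se[i]), digits),
               stringsAsFactors = FALSE)
  }))
  out$direction <- ifelse(out$te_after < out$te_before, "down",
                          ifelse(out$te_after > out$te_before, "up", "same"))
  out
}

#' Competition ranking of DMUs by technical efficiency
#'
#' Rank 1 is the highest TE; ties share the smallest rank and the next
#' distinct score receives rank (number of better-or-tied DMUs + 1) —
#' "1, 1, 1, 4, ..." style.
#'
#' @param te numeric vector of per-DMU scores (or a `scores` data.frame,
#'   in which case per-DMU period means of `te` are ranked).
#' @return integer ranks aligned with the input.
#' @export
rank_dmus <- function(te) {
  if (is.data.frame(te)) te <- dmu_mean_scores(te)$te
  if (!length(te)) stop("no scores to rank")
  rank(-te, ties.method = "min")
}

paired_stats <- function(x, y) {
  d <- x - y
  if (all(abs(d) < 1e-12)) {
    wil_p <- 1; flag <- "identical"
  } else {
    wil_p <- stats::wilcox.test(x, y, paired = TRUE, exact = FALSE)$p.value
    flag <- ""
  }
  # paired d = mean(diff)/sd(diff); a constant nonzero shift has zero
  # spread, reported as a signed infinity rather than an error
  cohens_d <- if (stats::sd(d) == 0) {
    if (mean(d) == 0) 0 else sign(mean(d)) * Inf
  } else mean(d) / stats::sd(d)
  sp <- stats::cor.test(x, y, method = "spearman", exact = FALSE)
  list(wilcoxon_p = wil_p, cohens_d = cohens_d,
       spearman_rho = unname(sp$estimate), spearman_p = sp$p.value,
       flag = flag)
}

#' Sensitivity of stage-3 scores to dropping a variable
#'
#' Re-runs the three-stage analysis with one input or environmental
#' variable removed at a time and compares the per-DMU mean stage-3 TE
#' vector against the full model with paired statistics: Wilcoxon
#' signed-rank p, Cohen's d on the paired differences, and the Spearman
#' rank correlation. Dropping an environmental variable only alters stage
#' 2; dropping an input removes it from every stage.
#'
#' @param panel a [panel_data].
#' @param weights optional `spatial_weights` (unused by the statistics;
#'   passed through to [run_three_stage]).
#' @param config passed to [run_three_stage]; Malmquist and Moran are
#'   disabled internally for speed.
#' @param drop_candidates character vector of input and/or environmental
#'   variable names to drop one at a time; defaults to all inputs and the
#'   non-GDP environmental variables.
#' @return data.frame: dropped variable, mean stage-3 TE, Wilcoxon p,
#'   Cohen's d, Spearman rho and its p. The first row is the full model.
#' @export
sensitivity_analysis <- function(panel, weights = NULL, config = list(),
                                 drop_candidates = NULL) {
  cfg <- utils::modifyList(config, list(malmquist = FALSE, moran = FALSE))
  in_names <- dimnames(panel$inputs)[[3]]
  env_names <- dimnames(panel$env)[[3]]
  if (is.null(drop_candidates))
    drop_candidates <- c(in_names, setdiff(env_names, "gdp_pc"))
  full <- run_three_stage(panel, weights, cfg)
  base <- dmu_mean_scores(full$stage3$scores)$te
  out <- data.frame(dropped = "none", mean_te = round(mean(base), 3),
                    wilcoxon_p = NA_real_, cohens_d = NA_real_,
                    spearman_rho = NA_real_, spearman_p = NA_real_,
                    stringsAsFactors = FALSE)
  for (v in drop_candidates) {
    reduced <- drop_variable(panel, v, in_names, env_names)
    r <- run_three_stage(reduced, weights, cfg)
    te <- dmu_mean_scores(r$stage3$scores)$te
    st <- paired_stats(base, te)
    out <- rbind(out, data.frame(
      dropped = v, mean_te = round(mean(te), 3),
      wilcoxon_p = st$wilcoxon_p, cohens_d = st$cohens_d,
      spearman_rho = st$spearman_rho, spearman_p = st$spearman_p,
      stringsAsFactors = FALSE))
  }
  out
}

drop_variable <- function(panel, v, in_names, env_names) {
  if (v %in% in_names) {
    keep <- setdiff(in_names, v)
    if (!length(keep)) stop("cannot drop the last input")
    panel_data(panel$dmu_ids, panel$years,
               inputs = panel$inputs[, , keep, drop = FALSE],
               outputs = panel$outputs, env = panel$env,
               regions = panel$regions)
  } else if (v %in% env_names) {
    keep <- setdiff(env_names, v)
    if (length(keep) < 1L) stop("cannot drop the last environmental variable")
    panel_data(panel$dmu_ids, panel$years, inputs = panel$inputs,
               outputs = panel$outputs,
               env = panel$env[, , keep, drop = FALSE],
               regions = panel$regions)
  } else stop("unknown variable: ", v)
}

#' Stability of efficiency scores between consecutive years
#'
#' @param scores a `scores` data.frame (e.g. stage 3 of
#'   [run_three_stage]).
#' @return data.frame with one row per adjacent year pair: Wilcoxon
#'   signed-rank p, Cohen's d, Spearman rho and its p.
#' @export
year_stability <- function(scores) {
  yrs <- sort(unique(scores$year))
  if (length(yrs) < 2L) stop("need at least two years")
  dmus <- unique(scores$dmu)
  out <- NULL
  for (i in seq_len(length(yrs) - 1L)) {
    a <- scores[scores$year == yrs[i], ]
    b <- scores[scores$year == yrs[i + 1L], ]
    if (!identical(sort(a$dmu), sort(b$dmu))) stop("misaligned DMU sets")
    x <- a$te[match(dmus, a$dmu)]
    y <- b$te[match(dmus, b$dmu)]
    st <- paired_stats(x, y)
    out <- rbind(out, data.frame(
      period = sprintf("%d-%d", yrs[i], yrs[i + 1L]),
      wilcoxon_p = st$wilcoxon_p, cohens_d = st$cohens_d,
      spearman_rho = st$spearman_rho, spearman_p = st$spearman_p,
      stringsAsFactors = FALSE))
  }
  out
}

#' Write all report files for a three-stage result
#'
#' Emits: `efficiency.csv` (per-DMU stage-1/stage-3 mean scores, RTS and
#' competition ranks), `sfa.csv` (per-input frontier coefficients and
#' variance parameters), `malmquist.csv` and `malmquist_summary.csv`,
#' `moran.csv` (per-year global statistics), `lisa_<year>.csv`,
#' `regions.csv`, a `config.yaml` echo and `run.log`.
#'
#' @param result a `three_stage_result`.
#' @param outdir output directory (created if absent).
#' @return invisible character vector of the files written.
#' @export
write_reports <- function(result, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  put <- function(df, name) {
    path <- file.path(outdir, name)
    utils::write.csv(df, path, row.names = FALSE)
    files <<- c(files, path)
  }

  p1 <- dmu_mean_scores(result$stage1$scores)
  p3 <- dmu_mean_scores(result$stage3$scores)
  eff <- data.frame(
    dmu = p1$dmu,
    te_stage1 = round(p1$te, 3), pte_stage1 = round(p1$pte, 3),
    se_stage1 = round(p1$se, 3), rts_stage1 = p1$rts,
    rank_stage1 = rank_dmus(p1$te),
    te_stage3 = round(p3$te, 3), pte_stage3 = round(p3$pte, 3),
    se_stage3 = round(p3$se, 3), rts_stage3 = p3$rts,
    rank_stage3 = rank_dmus(p3$te), stringsAsFactors = FALSE)
  eff$compare <- ifelse(eff$rank_stage3 > eff$rank_stage1, "up",
                        ifelse(eff$rank_stage3 < eff$rank_stage1, "down", "same"))
  put(eff, "efficiency.csv")

  sfa <- do.call(rbind, lapply(result$sfa_fits, function(f) {
    data.frame(input = f$input_name,
               term = c(names(f$beta), "sigma_sq", "gamma", "loglik", "lr_stat"),
               estimate = c(f$beta, f$sigma_sq, f$gamma, f$loglik, f$lr_stat),
               std_error = c(f$beta_se, rep(NA_real_, 4)),
               stringsAsFactors = FALSE)
  }))
  put(sfa, "sfa.csv")

  if (!is.null(result$malmquist)) {
    put(result$malmquist[, c("dmu", "period", "effch", "techch", "pech",
                             "sech", "tfpch")], "malmquist.csv")
    ms <- result$malmquist_summary
    ms[, -1] <- round(ms[, -1], 3)
    put(ms, "malmquist_summary.csv")
  }
  if (!is.null(result$moran)) {
    mg <- do.call(rbind, lapply(names(result$moran), function(yr) {
      g <- result$moran[[yr]]
      data.frame(year = as.integer(yr), I = g$I, expectation = g$expectation,
                 z = g$z, p_norm = g$p_norm, p_perm = g$p_perm)
    }))
    put(mg, "moran.csv")
    for (yr in names(result$lisa)) put(result$lisa[[yr]], sprintf("lisa_%s.csv", yr))
  }
  if (!is.null(result$regional)) put(result$regional, "regions.csv")

  yaml::write_yaml(result$config, file.path(outdir, "config.yaml"))
  files <- c(files, file.path(outdir, "config.yaml"))
  log_lines <- c(
    sprintf("dmus=%d years=%d", length(unique(result$stage1$scores$dmu)),
            length(unique(result$stage1$scores$year))),
    sprintf("stage1 mean TE=%.4f stage3 mean TE=%.4f",
            mean_scores(result$stage1$scores, digits = NULL)[1],
            mean_scores(result$stage3$scores, digits = NULL)[1]),
    sprintf("sfa gamma: %s", paste(sprintf("%s=%.3f", names(result$sfa_fits),
            vapply(result$sfa_fits, function(f) f$gamma, 0)), collapse = " ")))
  writeLines(log_lines, file.path(outdir, "run.log"))
  files <- c(files, file.path(outdir, "run.log"))
  invisible(files)
}
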