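#' Published provincial efficiency reference table
#'
#' Per-province mean technical, pure technical and scale efficiency of
#' China's primary-healthcare system over 2012-2020, before (stage 1) and
#' after (stage 3) the environmental adjustment, with returns-to-scale
#' class and competition rank, as reported in the published three-stage
#' DEA study the package's report layer mirrors. Used by the test suite to
#' check that the aggregation conventions (arithmetic means, regional
#' means, competition ranks, the TE = PTE x SE identity) reproduce the
#' published summary rows.
#'
#' @return data.frame with 31 rows and columns `province`, `region`,
#'   `te_stage1`, ..., `rank_stage3`, `compare`.
#' @export
reference_efficiency <- function() {
  utils::read.csv(system.file("extdata", "provincial_efficiency.csv",
                              package = "tridea"),
                  stringsAsFactors = FALSE)
}

#' Published yearly Malmquist reference table
#'
#' Year-pair geometric means of the Malmquist components (EFFCH, TECHCH,
#' PECH, SECH, TFPCH) for the same provincial panel, 2012-2020. Used to
#' check that geometric-mean aggregation and the multiplicative
#' decomposition identities reproduce the published mean row.
#'
#' @return data.frame with 8 rows and columns `period`, `effch`,
#'   `techch`, `pech`, `sech`, `tfpch`.
#' @export
reference_malmquist <- function() {
  utils::read.csv(system.file("extdata", "malmquist_yearly.csv",
                              package = "tridea"),
                  stringsAsFactors = FALSE)
}
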