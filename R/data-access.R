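# Bundled reference tables from a published 20-case nasopharyngeal
# carcinoma (NPC) VMAT study: per-case dose-gradient regressions, the
# re-delineation cohort (same observer, two time points, 0.3 cm banding),
# and the two-group illustrative comparison (uniform expansion vs displaced
# reference at equal reference volume). They serve as printed inputs for
# cohort summaries and as cross-checks of the coefficient arithmetic.

#' Bundled reference tables
#'
#' Three small tables from a published NPC/VMAT validation cohort ship with
#' the package:
#' \describe{
#' \item{`gradient_cohort()`}{Per-case linear dose-gradient fits
#'   (`PCT = B0 + B1 * d_PCT`) over the rapid fall-off region of 20
#'   whole-body VMAT DVHs, with standard errors, R^2, and PTV volumes.
#'   Feeding its `B0`/`B1` columns to [summarize_cohort()] reproduces the
#'   cohort mean model (101.637, -28.369), the 8.85% CV of `B1`, and the
#'   0.834 correlation of `B1` with PTV volume.}
#' \item{`redelineation_cohort()`}{20 GTV pairs delineated twice by one
#'   observer; structure volumes, intersections, and the reported classic
#'   and equivalent-volume coefficients at 0.3 cm banding.}
#' \item{`illustrative_groups()`}{The two-group worked comparison: one
#'   reference drawn by uniform 0.6-cm-scale expansion of the standard, one
#'   displaced reference of equal volume, with reported intersection,
#'   equivalent volumes (`EV_Std`/`EV_Ref` include the intersection), and
#'   all four coefficients.}
#' }
#'
#' @return A data frame.
#' @name reference_tables
NULL

ccev_extdata <- function(file) {
  path <- system.file("extdata", file, package = "ccev", mustWork = TRUE)
  utils::read.csv(path)
}

#' @rdname reference_tables
#' @export
gradient_cohort <- function() ccev_extdata("gradient_cohort.csv")

#' @rdname reference_tables
#' @export
redelineation_cohort <- function() ccev_extdata("redelineation_cohort.csv")

#' @rdname reference_tables
#' @export
illustrative_groups <- function() ccev_extdata("illustrative_groups.csv")
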