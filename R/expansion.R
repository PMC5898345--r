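#' Spend the implementation gap on expanding the package
#'
#' Appraises the alternative use of the spending gap: instead of investing
#' in implementation of included interventions, fund the beyond-threshold
#' interventions (ICER above k). Candidates are every excluded,
#' cost-incurring intervention, taken in ascending-ICER order and -- by the
#' paper's own accounting -- evaluated at their *observed* implementation
#' levels; they are added while their cumulative actual cost stays within
#' the gap (the fill stops at the first candidate that does not fit).
#'
#' @param iv The full [interventions()] table.
#' @param econ An [economy_params()] object (or scalar k).
#' @param package An `hbp_package`; defaults to threshold selection at
#'   `econ`'s k.
#' @param gap Budget for additions, USD; defaults to [spending_gap()] of the
#'   package.
#' @param level `"actual"` (default) to cost and credit additions at their
#'   observed implementation levels, or `"full"` for a sensitivity run.
#' @return An object of class `expansion_report` with `added_ids`,
#'   `gap_spent`, `added_dalys`, `total_dalys_with_expansion`
#'   (package actual DALYs + additions), `forgone_vs_implementation`
#'   (package full-implementation DALYs minus the expansion-route total) and
#'   `strengthening_potential`.
#' @examples
#' ex <- expand_package(malawi_interventions(), economy_params(61))
#' ex
#' @export
expand_package <- function(iv, econ = economy_params(), package = NULL,
                           gap = NULL, level = c("actual", "full")) {
  econ <- as_economy(econ)
  level <- match.arg(level)
  if (is.null(package)) package <- hbp_select(iv, econ)
  rep <- scaleup_report(iv, econ, package)
  if (is.null(gap)) gap <- rep$spending_gap

  cand <- iv[!iv$id %in% package$included_ids & !iv$cost_saving, ]
  added <- cand[0, ]
  if (nrow(cand) && gap > 0) {
    cand <- rank_by_icer(cand)
    cost <- if (level == "actual") cand$cost_full * cand$level else cand$cost_full
    cum <- cumsum(cost)
    n_add <- match(TRUE, cum > gap, nomatch = nrow(cand) + 1L) - 1L
    added <- cand[seq_len(n_add), ]
  }
  vm_add <- if (nrow(added))
    value_metrics(added, if (level == "actual") "actual" else "full", econ)
  else NULL
  added_dalys <- if (is.null(vm_add)) 0 else sum(vm_add$total_dalys)
  gap_spent <- if (is.null(vm_add)) 0 else sum(vm_add$total_cost)
  total_with <- rep$total_dalys_actual + added_dalys

  structure(list(
    added_ids = added$id,
    additions = added,
    level = level,
    gap = gap,
    gap_spent = gap_spent,
    added_dalys = added_dalys,
    added_net_dalys = if (is.null(vm_add)) 0 else sum(vm_add$net_dalys),
    total_dalys_with_expansion = total_with,
    forgone_vs_implementation = rep$total_dalys_full - total_with,
    strengthening_potential = rep$strengthening_potential
  ), class = "expansion_report")
}

#' Break-even fraction of implementation efforts
#'
#' The share of the system-strengthening potential that implementation
#' investments would need to realise to match the health gained by package
#' expansion. If implementation policies can deliver more than this
#' fraction, investing in implementation beats expansion.
#'
#' @param report An `expansion_report`.
#' @param strengthening_potential Positive DALY potential; defaults to the
#'   one recorded in `report`.
#' @return Fraction in \[0,1\] (multiply by 100 to report as a percentage).
#' @export
breakeven_fraction <- function(report,
                               strengthening_potential = report$strengthening_potential) {
  stopifnot(inherits(report, "expansion_report"))
  if (!is.numeric(strengthening_potential) || strengthening_potential <= 0)
    stop("break-even fraction is undefined for non-positive strengthening potential",
         call. = FALSE)
  report$added_dalys / strengthening_potential
}

#' @export
print.expansion_report <- function(x, ...) {
  cat("Package-expansion report\n")
  cat(sprintf("  additions evaluated at %s implementation\n", x$level))
  cat(sprintf("  gap available: $%s; spent on additions: $%s\n",
              format(round(x$gap), big.mark = ","),
              format(round(x$gap_spent), big.mark = ",")))
  cat(sprintf("  interventions added: %d\n", length(x$added_ids)))
  cat(sprintf("  DALYs averted by additions: %s\n",
              format(round(x$added_dalys), big.mark = ",")))
  cat(sprintf("  total DALYs with expansion: %s\n",
              format(round(x$total_dalys_with_expansion), big.mark = ",")))
  cat(sprintf("  forgone vs implementation route: %s DALYs\n",
              format(round(x$forgone_vs_implementation), big.mark = ",")))
  if (x$strengthening_potential > 0)
    cat(sprintf("  break-even fraction: %.1f%%\n",
                100 * breakeven_fraction(x)))
  invisible(x)
}
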