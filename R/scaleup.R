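#' Value of scaling an intervention from observed to full implementation
#'
#' For each intervention, the component-wise difference between value
#' metrics at full implementation and at the observed level: the extra DALYs
#' averted, extra spend required, extra net DALYs, and the financial value
#' of closing the implementation gap. The financial value doubles as a
#' budget ceiling: it is the most that could be spent on removing the
#' constraints to full implementation while remaining a cost-effective use
#' of resources.
#'
#' @inheritParams hbp_select
#' @return A `value_metrics` table of deltas (`implementation` holds
#'   `1 - level`), one row per intervention in input order.
#' @examples
#' sv <- scaleup_value(malawi_interventions(), economy_params(61))
#' @export
scaleup_value <- function(iv, econ = economy_params()) {
  metric_delta(value_metrics(iv, "full", econ),
               value_metrics(iv, "actual", econ))
}

#' Rank interventions by the financial value of scaling them up
#'
#' Descending financial value of moving from observed to full
#' implementation; fully implemented interventions (zero delta) follow all
#' positive deltas, and negative deltas (interventions whose expansion would
#' cost the system health) come last. Ties are broken by name, then id.
#'
#' @inheritParams hbp_select
#' @return A data.frame with intervention identifiers, observed level, and
#'   the four delta columns, ranked.
#' @export
rank_by_scaleup_value <- function(iv, econ = economy_params()) {
  d <- scaleup_value(iv, econ)
  ord <- order(-d$financial_value, iv$name, iv$id)
  out <- data.frame(rank = seq_len(nrow(iv)),
                    id = iv$id[ord],
                    name = iv$name[ord],
                    level = iv$level[ord],
                    delta_dalys = d$total_dalys[ord],
                    delta_cost = d$total_cost[ord],
                    delta_net_dalys = d$net_dalys[ord],
                    scaleup_financial_value = d$financial_value[ord],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Scale-up report over a benefits package
#'
#' Aggregates the implementation shortfall across a package: the spending
#' gap (full-implementation cost minus actual spend), total DALYs averted at
#' each level, and the system-strengthening potential (the DALYs that full
#' implementation would add).
#'
#' @param iv The full [interventions()] table.
#' @param econ An [economy_params()] object (or scalar k).
#' @param package An `hbp_package` defining "the package"; defaults to the
#'   threshold selection at `econ`'s k.
#' @return An object of class `scaleup_report`: per-intervention deltas plus
#'   `spending_gap` (USD), `total_dalys_full`, `total_dalys_actual`,
#'   `strengthening_potential` (DALYs).
#' @examples
#' rep <- scaleup_report(malawi_interventions(), economy_params(61))
#' rep
#' @export
scaleup_report <- function(iv, econ = economy_params(), package = NULL) {
  econ <- as_economy(econ)
  if (is.null(package)) package <- hbp_select(iv, econ)
  members <- iv[iv$id %in% package$included_ids, ]
  full <- value_metrics(members, "full", econ)
  actual <- value_metrics(members, "actual", econ)
  delta <- metric_delta(full, actual)
  structure(list(
    package = package,
    per_intervention = list(full = full, actual = actual, delta = delta),
    spending_gap = sum(delta$total_cost),
    total_dalys_full = sum(full$total_dalys),
    total_dalys_actual = sum(actual$total_dalys),
    strengthening_potential = sum(full$total_dalys) - sum(actual$total_dalys)
  ), class = "scaleup_report")
}

#' Spending gap of a package
#'
#' Full-implementation cost minus actual spend over the package members.
#'
#' @inheritParams scaleup_report
#' @param package An `hbp_package`; defaults to threshold selection.
#' @return Scalar USD; non-negative whenever all levels are in \[0,1\].
#' @export
spending_gap <- function(iv, econ = economy_params(), package = NULL) {
  scaleup_report(iv, econ, package)$spending_gap
}

#' System-strengthening potential of a package
#'
#' Total DALYs averted at full implementation minus at observed
#' implementation, summed over package members: the most health that
#' policies relaxing implementation constraints could add.
#'
#' @inheritParams spending_gap
#' @return A list with `dalys_full`, `dalys_actual`, `potential`.
#' @export
strengthening_potential <- function(iv, econ = economy_params(), package = NULL) {
  rep <- scaleup_report(iv, econ, package)
  list(dalys_full = rep$total_dalys_full,
       dalys_actual = rep$total_dalys_actual,
       potential = rep$strengthening_potential)
}

#' @export
print.scaleup_report <- function(x, ...) {
  cat("Scale-up report\n")
  cat(sprintf("  package: %d interventions\n",
              length(x$package$included_ids)))
  cat(sprintf("  spending gap (full - actual): $%s\n",
              format(round(x$spending_gap), big.mark = ",")))
  cat(sprintf("  DALYs averted, full implementation:   %s\n",
              format(round(x$total_dalys_full), big.mark = ",")))
  cat(sprintf("  DALYs averted, actual implementation: %s\n",
              format(round(x$total_dalys_actual), big.mark = ",")))
  cat(sprintf("  system-strengthening potential:       %s DALYs\n",
              format(round(x$strengthening_potential), big.mark = ",")))
  invisible(x)
}
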