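#' Rank interventions by cost-effectiveness ratio
#'
#' Cost-saving interventions first, then ascending ICER. Transcribed league
#' tables print ICERs rounded to the dollar, so distinct ratios can collide;
#' if the table carries an `icer_rank` column (the published
#' cost-effectiveness rank, as [malawi_interventions()] does) it breaks such
#' ties first. Remaining ties are broken by display name, then id, so the
#' ordering is always deterministic.
#'
#' @param iv An [interventions()] table.
#' @return The table reordered, with an integer `icer_order` column (1 =
#'   most cost-effective).
#' @export
rank_by_icer <- function(iv) {
  if (!nrow(iv)) stop("intervention list is empty", call. = FALSE)
  key <- ifelse(iv$cost_saving, -Inf, iv$icer)
  printed <- if ("icer_rank" %in% names(iv)) iv$icer_rank else rep(0L, nrow(iv))
  ord <- order(key, printed, iv$name, iv$id)
  out <- iv[ord, ]
  out$icer_order <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Frontier table behind the cost-effectiveness plot
#'
#' One row per intervention in ICER order with the reciprocal ratio (bar
#' height), total full-implementation cost (bar width) and the exact
#' cumulative cost over unrounded costs (bar position).
#'
#' @param iv An [interventions()] table (any order; ranked internally).
#' @return A data.frame with columns `rank`, `id`, `name`, `icer`,
#'   `cost_saving`, `dalys_per_1000`, `cost_full`, `cumulative_cost`.
#' @export
frontier_table <- function(iv) {
  r <- rank_by_icer(iv)
  data.frame(rank = r$icer_order,
             id = r$id,
             name = r$name,
             icer = r$icer,
             cost_saving = r$cost_saving,
             dalys_per_1000 = dalys_per_1000(ifelse(r$cost_saving, NA, r$icer),
                                             r$cost_saving),
             cost_full = r$cost_full,
             cumulative_cost = cumsum(r$cost_full),
             stringsAsFactors = FALSE)
}

new_hbp_package <- function(included, k, label, budget_cap = NA_real_) {
  included$cumulative_cost <- cumsum(included$cost_full)
  vm <- if (nrow(included)) value_metrics(included, "full", economy_params(k, numeric(0)))
        else NULL
  structure(list(
    label = label,
    k = k,
    interventions = included,
    included_ids = included$id,
    budget = if (nrow(included)) sum(included$cost_full) else 0,
    budget_cap = budget_cap,
    total_dalys = if (is.null(vm)) 0 else sum(vm$total_dalys),
    total_net_dalys = if (is.null(vm)) 0 else sum(vm$net_dalys)
  ), class = "hbp_package")
}

#' Select a benefits package at a cost-effectiveness threshold
#'
#' Includes every cost-saving intervention plus every intervention whose
#' ICER does not exceed the health opportunity cost `k`: precisely the set
#' whose members each add non-negative net health. The budget is an output
#' -- the total full-implementation cost of the included set -- not an input
#' constraint; see [select_budget()] for budget-capped selection.
#'
#' @param iv An [interventions()] table.
#' @param econ An [economy_params()] object (or scalar k).
#' @param label Optional scenario label from `econ$threshold_scenarios`; if
#'   supplied, that scenario's value is used as the threshold instead of
#'   `econ$k_usd_per_daly`.
#' @return An object of class `hbp_package` with elements `label`, `k`,
#'   `interventions` (included rows in ICER order with a `cumulative_cost`
#'   column), `included_ids`, `budget` (USD at full implementation),
#'   `total_dalys`, `total_net_dalys` (both at full implementation, net
#'   DALYs evaluated at the selecting `k`).
#' @examples
#' pkg <- hbp_select(malawi_interventions(), economy_params(61))
#' pkg
#' @export
hbp_select <- function(iv, econ = economy_params(), label = NULL) {
  econ <- as_economy(econ)
  k <- econ$k_usd_per_daly
  if (!is.null(label)) {
    if (!label %in% names(econ$threshold_scenarios))
      stop("unknown threshold scenario label: ", label, call. = FALSE)
    k <- econ$threshold_scenarios[[label]]
  }
  if (!nrow(iv))
    return(new_hbp_package(iv, k, label %||% "k"))
  r <- rank_by_icer(iv)
  keep <- r$cost_saving | r$icer <= k
  new_hbp_package(r[keep, ], k, label %||% "k")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Package budgets across threshold scenarios
#'
#' Runs [hbp_select()] once per labelled scenario and returns each package's
#' full-implementation budget.
#'
#' @inheritParams hbp_select
#' @return Named numeric vector of budgets (USD), one per scenario label.
#' @export
budget_at_thresholds <- function(iv, econ = economy_params()) {
  econ <- as_economy(econ)
  vapply(names(econ$threshold_scenarios), function(lab)
    hbp_select(iv, econ, lab)$budget, numeric(1))
}

#' League table by net DALYs averted
#'
#' Ranks interventions by the net health they generate -- the scale measure
#' that a cost-effectiveness ratio alone cannot give, since it ignores the
#' size of the eligible population. An intervention with a middling ICER but
#' a large caseload can outrank nearly every ratio-ordered competitor.
#'
#' @inheritParams hbp_select
#' @param level `"full"` or `"actual"` implementation (passed to
#'   [value_metrics()]).
#' @return A data.frame in descending net-DALY order (ties by name, then id)
#'   with columns `rank`, `id`, `name`, `icer`, `cost_saving`, `icer_order`,
#'   and the four value-metric columns.
#' @export
league_table <- function(iv, econ = economy_params(), level = "full") {
  r <- rank_by_icer(iv)
  vm <- value_metrics(r, level, econ)
  ord <- order(-vm$net_dalys, r$name, r$id)
  out <- data.frame(rank = seq_len(nrow(r)),
                    id = r$id[ord],
                    name = r$name[ord],
                    icer = r$icer[ord],
                    cost_saving = r$cost_saving[ord],
                    icer_order = r$icer_order[ord],
                    vm[ord, c("implementation", "total_cost", "total_dalys",
                              "net_dalys", "financial_value")],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Budget-capped package selection
#'
#' Health-maximising selection of whole interventions under an explicit
#' budget, with optional forced inclusions and exclusions (donor
#' conditionalities, equity or continuum-of-care commitments).
#'
#' The default `"greedy"` method takes cost-saving interventions and forced
#' inclusions first, then fills the remaining budget in ascending-ICER order,
#' stopping at the first candidate that no longer fits; with indivisible
#' interventions this is a lower bound on the attainable net health (the
#' knapsack optimum may differ). `"exact"` enumerates all feasible subsets
#' (only practical for ~20 interventions or fewer) and returns the net-DALY
#' maximising one; ties resolve to the cheaper, then lexicographically
#' earlier, subset.
#'
#' @inheritParams hbp_select
#' @param budget Budget cap, USD, applied to full-implementation costs.
#' @param forced_in,forced_out Character vectors of intervention ids that
#'   must / must not be included. Must be disjoint.
#' @param method `"greedy"` (default) or `"exact"`.
#' @return An `hbp_package`; its `budget` element is the cost actually
#'   committed (<= `budget`), with the cap recorded in `budget_cap`.
#' @export
select_budget <- function(iv, econ = economy_params(), budget,
                          forced_in = character(), forced_out = character(),
                          method = c("greedy", "exact")) {
  econ <- as_economy(econ)
  method <- match.arg(method)
  stopifnot(is.numeric(budget), length(budget) == 1L, !is.na(budget))
  if (length(intersect(forced_in, forced_out)))
    stop("forced_in and forced_out must be disjoint", call. = FALSE)
  unknown <- setdiff(c(forced_in, forced_out), iv$id)
  if (length(unknown))
    stop("unknown intervention id(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  iv <- iv[!iv$id %in% forced_out, ]
  if (!nrow(iv)) return(new_hbp_package(iv, econ$k_usd_per_daly, "budget", budget))
  r <- rank_by_icer(iv)

  forced_cost <- sum(r$cost_full[r$id %in% forced_in])
  if (forced_cost > budget)
    stop("infeasible scenario: forced inclusions cost ",
         format(forced_cost, big.mark = ","), " against a budget of ",
         format(budget, big.mark = ","), call. = FALSE)

  if (method == "greedy") {
    keep <- r$id %in% forced_in | r$cost_saving
    spent <- sum(r$cost_full[keep])
    for (i in seq_len(nrow(r))) {
      if (keep[i]) next
      if (spent + r$cost_full[i] <= budget) {
        keep[i] <- TRUE
        spent <- spent + r$cost_full[i]
      } else break
    }
    return(new_hbp_package(r[keep, ], econ$k_usd_per_daly, "budget", budget))
  }

  # exact enumeration
  n <- nrow(r)
  if (n > 20L)
    stop("exact enumeration is limited to 20 interventions", call. = FALSE)
  vm <- value_metrics(r, "full", econ)
  must <- r$id %in% forced_in
  best <- NULL; best_net <- -Inf; best_cost <- Inf
  for (mask in 0:(2^n - 1L)) {
    sel <- as.logical(bitwAnd(mask, 2^(seq_len(n) - 1L)))
    if (any(must & !sel)) next
    cost <- sum(r$cost_full[sel])
    if (cost > budget) next
    net <- sum(vm$net_dalys[sel])
    if (net > best_net + 1e-9 ||
        (abs(net - best_net) <= 1e-9 && cost < best_cost - 1e-9)) {
      best <- sel; best_net <- net; best_cost <- cost
    }
  }
  new_hbp_package(r[best, ], econ$k_usd_per_daly, "budget", budget)
}

#' @export
print.hbp_package <- function(x, ...) {
  cat("Health benefits package\n")
  cat(sprintf("  threshold: $%g per DALY averted%s\n", x$k,
              if (!is.null(x$label) && nzchar(x$label) && x$label != "k")
                sprintf(" (scenario %s)", x$label) else ""))
  if (!is.na(x$budget_cap))
    cat(sprintf("  budget cap: $%s\n", format(round(x$budget_cap), big.mark = ",")))
  cat(sprintf("  interventions included: %d\n", length(x$included_ids)))
  cat(sprintf("  budget (full implementation): $%s\n",
              format(round(x$budget), big.mark = ",")))
  cat(sprintf("  total DALYs averted (full implementation): %s\n",
              format(round(x$total_dalys), big.mark = ",")))
  cat(sprintf("  total net DALYs averted: %s\n",
              format(round(x$total_net_dalys), big.mark = ",")))
  invisible(x)
}

#' @export
summary.hbp_package <- function(object, ...) {
  print(object)
  if (nrow(object$interventions)) {
    cat("\nIncluded interventions (ICER order):\n")
    df <- object$interventions
    show <- data.frame(rank = seq_len(nrow(df)),
                       id = df$id,
                       name = substr(df$name, 1, 48),
                       icer = ifelse(df$cost_saving, "cost saving",
                                     format(df$icer)),
                       cost_full = round(df$cost_full),
                       cumulative = round(df$cumulative_cost))
    print(show, row.names = FALSE)
  }
  invisible(object)
}

#' Plot the cost-effectiveness frontier
#'
#' Bar chart in ICER order: bar height is DALYs averted per $1000, bar width
#' the intervention's total full-implementation cost, so the horizontal axis
#' is cumulative spend. Vertical dashed lines mark the budgets implied by
#' each threshold scenario.
#'
#' @param x An [interventions()] table or an `hbp_package`.
#' @param econ An [economy_params()] supplying threshold scenarios to mark.
#' @param ... Passed to [graphics::plot.default()] (e.g. `main`).
#' @return Invisibly, the [frontier_table()] used.
#' @export
plot_frontier <- function(x, econ = economy_params(), ...) {
  iv <- if (inherits(x, "hbp_package")) x$interventions else x
  ft <- frontier_table(iv)
  h <- ft$dalys_per_1000
  h[is.na(h)] <- max(h, na.rm = TRUE)   # cost-savers drawn at plot ceiling
  x0 <- c(0, ft$cumulative_cost[-nrow(ft)])
  graphics::plot(NA, xlim = c(0, max(ft$cumulative_cost)), ylim = c(0, max(h)),
                 xlab = "Cumulative cost (USD, full implementation)",
                 ylab = "DALYs averted per $1000", ...)
  graphics::rect(x0, 0, ft$cumulative_cost, h, col = "grey80", border = "grey40")
  econ <- as_economy(econ)
  for (lab in names(econ$threshold_scenarios)) {
    b <- hbp_select(iv, econ, lab)$budget
    graphics::abline(v = b, lty = 2)
    graphics::mtext(lab, at = b, side = 3, cex = 0.8)
  }
  invisible(ft)
}

#' @export
plot.hbp_package <- function(x, ...) {
  plot_frontier(x$interventions, economy_params(x$k, numeric(0)), ...)
}
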