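#' Describe a donor-conditionality (or policy) scenario
#'
#' A scenario forces interventions into or out of the package, optionally
#' attaches earmarked additional resources, and may carry a matched-funding
#' offer. Non-health objectives (equity, continuum of care,
#' complementarities) are expressed the same way: force the intervention in
#' and measure the net health forgone.
#'
#' @param forced_in,forced_out Character vectors of intervention ids that
#'   must / must not be in the package (disjoint).
#' @param budget_delta Additional earmarked resources attached to the
#'   condition, USD (0 for a pure restriction).
#' @param matched Optional list `list(intervention_id =, donor_share =)`
#'   with `donor_share` in (0, 1].
#' @return An object of class `donor_scenario`.
#' @export
donor_scenario <- function(forced_in = character(), forced_out = character(),
                           budget_delta = 0, matched = NULL) {
  if (length(intersect(forced_in, forced_out)))
    stop("forced_in and forced_out must be disjoint", call. = FALSE)
  stopifnot(is.numeric(budget_delta), length(budget_delta) == 1L)
  if (!is.null(matched)) {
    stopifnot(is.list(matched),
              !is.null(matched$intervention_id), !is.null(matched$donor_share))
    if (matched$donor_share <= 0 || matched$donor_share > 1)
      stop("donor_share must lie in (0, 1]", call. = FALSE)
  }
  structure(list(forced_in = as.character(forced_in),
                 forced_out = as.character(forced_out),
                 budget_delta = budget_delta,
                 matched = matched),
            class = "donor_scenario")
}

#' Health-maximising package under a donor scenario
#'
#' Selects the best package attainable with `budget + budget_delta` while
#' honouring the scenario's forced inclusions and exclusions: forced
#' interventions are funded first, the rest of the budget is filled from
#' non-excluded candidates (see [select_budget()] for the fill rule and the
#' `"exact"` alternative).
#'
#' @inheritParams select_budget
#' @param scenario A [donor_scenario()].
#' @return An `hbp_package`.
#' @export
constrained_package <- function(iv, econ = economy_params(), scenario,
                                budget, method = c("greedy", "exact")) {
  stopifnot(inherits(scenario, "donor_scenario"))
  select_budget(iv, econ, budget + scenario$budget_delta,
                forced_in = scenario$forced_in,
                forced_out = scenario$forced_out,
                method = match.arg(method))
}

#' Minimum health opportunity cost of a donor condition
#'
#' Compares the health generated by the unconstrained health-maximising
#' package at the given budget with the best package honouring the
#' scenario. The difference in total net DALYs is the minimum health the
#' condition costs the system ("minimum" because constraints beyond those
#' modelled can only make it worse); multiplied by k it is the financial
#' cost.
#'
#' @inheritParams constrained_package
#' @return A list with `dalys_unconstrained`, `dalys_constrained` (total net
#'   DALYs of each package), `health_cost_dalys`, `financial_cost_usd`, and
#'   both packages.
#' @export
conditionality_cost <- function(iv, econ = economy_params(), scenario,
                                budget, method = c("greedy", "exact")) {
  econ <- as_economy(econ)
  method <- match.arg(method)
  unc <- select_budget(iv, econ, budget, method = method)
  con <- constrained_package(iv, econ, scenario, budget, method = method)
  health_cost <- unc$total_net_dalys - con$total_net_dalys
  list(dalys_unconstrained = unc$total_net_dalys,
       dalys_constrained = con$total_net_dalys,
       health_cost_dalys = health_cost,
       financial_cost_usd = health_cost * econ$k_usd_per_daly,
       unconstrained = unc,
       constrained = con)
}

#' Appraise a matched-funding offer
#'
#' Under matching, the donor bears `donor_share` of an intervention's cost
#' and the health system the remainder. The offer is worth accepting only if
#' the DALYs the intervention averts exceed the health forgone by the
#' system's own contribution: `net = dalys - (1 - share) * cost / k`.
#'
#' @param iv A single-row [interventions()] table (or one row of it), the
#'   intervention on offer.
#' @param donor_share Fraction of cost the donor pays, in (0, 1].
#' @param econ An [economy_params()] object (or scalar k).
#' @param level Implementation level at which to evaluate; defaults to 1.
#' @return A list with `net_dalys_to_system` and `recommend`
#'   (`"accept"`/`"reject"`; a zero net is a matter of indifference and is
#'   reported as `"reject"` since it frees no health).
#' @export
evaluate_matched_funding <- function(iv, donor_share, econ = economy_params(),
                                     level = 1) {
  econ <- as_economy(econ)
  if (nrow(iv) != 1L)
    stop("evaluate one intervention at a time", call. = FALSE)
  if (donor_share <= 0 || donor_share > 1)
    stop("donor_share must lie in (0, 1]", call. = FALSE)
  system_cost <- (1 - donor_share) * iv$cost_full * level
  net <- iv$dalys_full * level - system_cost / econ$k_usd_per_daly
  list(net_dalys_to_system = net,
       system_cost_usd = system_cost,
       recommend = if (net > 0) "accept" else "reject")
}
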