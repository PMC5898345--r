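#' Generate a synthetic intervention set
#'
#' Draws self-consistent intervention records that emulate the empirical
#' spread of published league tables: ICERs log-uniform over several orders
#' of magnitude (straddling realistic opportunity-cost thresholds),
#' caseloads log-uniform from thousands to millions, per-case health effects
#' log-uniform, and implementation levels Beta-distributed over (0, 1).
#' Records are consistent by construction:
#' `cost_full = icer * dalys_per_case * cases` and
#' `dalys_full = dalys_per_case * cases`, so the net-DALY sign rule
#' (positive net health iff ICER < k) holds exactly.
#'
#' A small fraction of interventions are cost-saving: their ICER is
#' undefined and their total cost is negative (a per-case saving drawn
#' log-uniform from `saving_range`).
#'
#' @param n Number of interventions.
#' @param icer_range Length-2 positive bounds, USD/DALY, log-uniform.
#' @param cases_range Length-2 positive bounds for annual caseload,
#'   log-uniform.
#' @param dalys_per_case_range Length-2 positive bounds for DALYs averted
#'   per case, log-uniform.
#' @param impl_shape Length-2 Beta shape parameters for implementation
#'   levels.
#' @param p_cost_saving Probability a record is cost-saving.
#' @param saving_range Length-2 positive bounds for per-case savings (USD)
#'   of cost-saving records, log-uniform.
#' @param seed Optional integer; if given, the draw is deterministic and the
#'   caller's RNG state is left untouched.
#' @return An [interventions()] table of `n` rows.
#' @examples
#' iv <- simulate_interventions(10, seed = 1)
#' @export
simulate_interventions <- function(n = 50,
                                   icer_range = c(1, 2000),
                                   cases_range = c(1e3, 1e7),
                                   dalys_per_case_range = c(0.005, 30),
                                   impl_shape = c(2, 2),
                                   p_cost_saving = 0.02,
                                   saving_range = c(0.5, 50),
                                   seed = NULL) {
  stopifnot(n >= 0,
            length(icer_range) == 2L, all(icer_range > 0), diff(icer_range) >= 0,
            length(cases_range) == 2L, all(cases_range > 0), diff(cases_range) >= 0,
            length(dalys_per_case_range) == 2L, all(dalys_per_case_range > 0),
            diff(dalys_per_case_range) >= 0,
            length(impl_shape) == 2L, all(impl_shape > 0),
            p_cost_saving >= 0, p_cost_saving <= 1,
            length(saving_range) == 2L, all(saving_range > 0))
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
            else assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  if (n == 0L) {
    return(interventions(data.frame(id = character(), name = character(),
                                    icer = numeric(), cost_saving = logical(),
                                    cases = numeric(), cost_full = numeric(),
                                    dalys_full = numeric(), level = numeric())))
  }
  runif_log <- function(n, range) exp(stats::runif(n, log(range[1]), log(range[2])))
  icer <- runif_log(n, icer_range)
  cases <- runif_log(n, cases_range)
  dpc <- runif_log(n, dalys_per_case_range)
  level <- stats::rbeta(n, impl_shape[1], impl_shape[2])
  saving <- stats::rbinom(n, 1, p_cost_saving) == 1

  cost_full <- icer * dpc * cases
  cost_full[saving] <- -runif_log(sum(saving), saving_range) * cases[saving]
  icer[saving] <- NA_real_

  interventions(data.frame(
    id = sprintf("s%03d", seq_len(n)),
    name = sprintf("Synthetic intervention %03d", seq_len(n)),
    icer = icer,
    cost_saving = saving,
    cases = cases,
    cost_full = cost_full,
    dalys_full = dpc * cases,
    level = level,
    stringsAsFactors = FALSE))
}
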