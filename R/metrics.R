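#' DALYs averted per $1000 spent
#'
#' The reciprocal cost-effectiveness ratio used as the bar height on the
#' frontier plot: an intervention with an ICER of `icer` USD/DALY averts
#' `1000 / icer` DALYs per $1000 spent on it.
#'
#' @param icer Positive ICER(s), USD per DALY averted. Cost-saving
#'   interventions have no defined ratio; pass their rows through the
#'   `cost_saving` argument to receive `NA` with a warning-free branch.
#' @param cost_saving Optional logical vector marking cost-saving entries;
#'   those positions return `NA_real_` (the ratio is undefined).
#' @return Numeric vector, unrounded; reporting layers may round to integers
#'   as league tables conventionally do.
#' @examples
#' dalys_per_1000(22)   # ~45 DALYs per $1000
#' @export
dalys_per_1000 <- function(icer, cost_saving = NULL) {
  icer <- as.numeric(icer)
  if (is.null(cost_saving)) cost_saving <- rep(FALSE, length(icer))
  if (length(cost_saving) != length(icer))
    stop("'cost_saving' must match 'icer' in length", call. = FALSE)
  bad <- !cost_saving & (!is.finite(icer) | icer <= 0)
  if (any(bad))
    stop("icer must be positive and finite for cost-incurring interventions",
         call. = FALSE)
  out <- 1000 / icer
  out[cost_saving] <- NA_real_
  out
}

#' Per-intervention value metrics at an implementation level
#'
#' Computes, for each intervention, the quantities that value it against the
#' rest of the health system:
#' \describe{
#'   \item{total_cost}{`cost_full * level`, USD.}
#'   \item{total_dalys}{`dalys_full * level`, DALYs averted.}
#'   \item{net_dalys}{`total_dalys - total_cost / k`: health gained minus the
#'     health the same money would buy elsewhere. A negative cost (a
#'     cost-saving intervention) therefore *adds* health, because the savings
#'     fund other care.}
#'   \item{financial_value}{`net_dalys * k`, USD: the extra budget other
#'     services would need to deliver the same net health.}
#' }
#' Costs and DALYs scale linearly with the implementation level (constant
#' returns to coverage).
#'
#' @param iv An [interventions()] table (or a single-row data.frame of it).
#' @param level Implementation fraction(s) in \[0,1\]: a scalar recycled to
#'   all rows, a vector of length `nrow(iv)`, `"full"` (all 1), or
#'   `"actual"` (each row's own observed `level`, the default).
#' @param econ An [economy_params()] object (or scalar k).
#' @return A data.frame of class `value_metrics` with columns
#'   `intervention_id`, `implementation`, `total_cost`, `total_dalys`,
#'   `net_dalys`, `financial_value`, and attribute `k`.
#' @examples
#' iv <- malawi_interventions()
#' head(value_metrics(iv, "full", economy_params(61)))
#' @export
value_metrics <- function(iv, level = "actual", econ = economy_params()) {
  econ <- as_economy(econ)
  k <- econ$k_usd_per_daly
  if (is.character(level)) {
    level <- match.arg(level, c("actual", "full"))
    level <- if (level == "full") rep(1, nrow(iv)) else iv$level
  }
  level <- as.numeric(level)
  if (length(level) == 1L) level <- rep(level, nrow(iv))
  if (length(level) != nrow(iv))
    stop("'level' must be scalar or one value per intervention", call. = FALSE)
  if (any(!is.finite(level)) || any(level < 0 | level > 1))
    stop("implementation level must lie in [0, 1]", call. = FALSE)

  total_cost <- iv$cost_full * level
  total_dalys <- iv$dalys_full * level
  net_dalys <- total_dalys - total_cost / k
  out <- data.frame(intervention_id = iv$id,
                    implementation = level,
                    total_cost = total_cost,
                    total_dalys = total_dalys,
                    net_dalys = net_dalys,
                    financial_value = net_dalys * k,
                    stringsAsFactors = FALSE)
  attr(out, "k") <- k
  class(out) <- c("value_metrics", "data.frame")
  out
}

#' Rescale full-implementation metrics to a partial level
#'
#' Multiplies the cost and DALY components of metrics computed at full
#' implementation by `level` and recomputes net DALYs and financial value
#' from the scaled components. Under the linear coverage model this equals
#' scaling every field directly; recomputation keeps the
#' `financial_value = net_dalys * k` identity exact.
#'
#' @param full A `value_metrics` table computed at implementation 1.
#' @param level Fraction(s) in \[0,1\].
#' @return A `value_metrics` table at the requested level.
#' @export
scale_metrics <- function(full, level) {
  stopifnot(inherits(full, "value_metrics"))
  if (any(full$implementation != 1))
    stop("'full' must be computed at implementation level 1", call. = FALSE)
  level <- as.numeric(level)
  if (length(level) == 1L) level <- rep(level, nrow(full))
  if (any(!is.finite(level)) || any(level < 0 | level > 1))
    stop("implementation level must lie in [0, 1]", call. = FALSE)
  k <- attr(full, "k")
  out <- full
  out$implementation <- level
  out$total_cost <- full$total_cost * level
  out$total_dalys <- full$total_dalys * level
  out$net_dalys <- out$total_dalys - out$total_cost / k
  out$financial_value <- out$net_dalys * k
  out
}

#' Component-wise difference of two value-metric tables
#'
#' `full - actual`, matched by `intervention_id`. This is the "value of
#' moving" operation: applied to metrics at full and observed implementation
#' it yields the DALYs, cost, net DALYs and financial value gained by closing
#' the implementation gap for each intervention.
#'
#' @param full,actual `value_metrics` tables over the same interventions.
#' @return A `value_metrics` table of differences (`implementation` holds
#'   the level difference).
#' @export
metric_delta <- function(full, actual) {
  stopifnot(inherits(full, "value_metrics"), inherits(actual, "value_metrics"))
  m <- match(full$intervention_id, actual$intervention_id)
  if (anyNA(m))
    stop("'full' and 'actual' must cover the same interventions", call. = FALSE)
  actual <- actual[m, ]
  out <- full
  for (col in c("implementation", "total_cost", "total_dalys",
                "net_dalys", "financial_value"))
    out[[col]] <- full[[col]] - actual[[col]]
  out
}
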