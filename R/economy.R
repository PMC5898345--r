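#' Health-system economic parameters
#'
#' Bundles the health opportunity cost parameter `k` -- the marginal cost at
#' which the healthcare system averts one DALY, in USD per DALY -- together
#' with an optional set of labelled threshold scenarios used for sensitivity
#' analysis of the package scale.
#'
#' `k` converts money into forgone health: spending `c` dollars displaces
#' `c / k` DALYs averted elsewhere in the system. The default of $61/DALY is
#' an empirical estimate for Malawi; the default scenarios add the widely
#' cited 1x and 3x GDP-per-capita norms ($372 and $1116) for comparison.
#'
#' @param k_usd_per_daly Positive scalar, USD required to avert one DALY at
#'   the margin of current health spending.
#' @param threshold_scenarios Named numeric vector of alternative `k` values,
#'   strictly increasing; names are scenario labels. May be empty.
#' @return An object of class `economy_params`.
#' @examples
#' econ <- economy_params(61)
#' econ$k_usd_per_daly
#' @export
economy_params <- function(k_usd_per_daly = 61,
                           threshold_scenarios = c(A = 61, B = 372, C = 1116)) {
  stopifnot(is.numeric(k_usd_per_daly), length(k_usd_per_daly) == 1L,
            is.finite(k_usd_per_daly))
  if (k_usd_per_daly <= 0)
    stop("'k_usd_per_daly' must be > 0", call. = FALSE)
  scen <- as.numeric(threshold_scenarios)
  names(scen) <- names(threshold_scenarios)
  if (length(scen)) {
    if (is.null(names(scen)) || any(!nzchar(names(scen))))
      stop("all threshold scenarios must be labelled", call. = FALSE)
    if (any(scen <= 0))
      stop("threshold scenario values must be > 0", call. = FALSE)
    if (any(diff(scen) <= 0))
      stop("threshold scenario values must be strictly increasing", call. = FALSE)
  }
  structure(list(k_usd_per_daly = k_usd_per_daly,
                 threshold_scenarios = scen),
            class = "economy_params")
}

#' @export
print.economy_params <- function(x, ...) {
  cat("Health-system economic parameters\n")
  cat(sprintf("  k (health opportunity cost): $%g per DALY averted\n",
              x$k_usd_per_daly))
  if (length(x$threshold_scenarios)) {
    cat("  threshold scenarios:\n")
    for (lab in names(x$threshold_scenarios))
      cat(sprintf("    %s: $%g per DALY\n", lab, x$threshold_scenarios[[lab]]))
  }
  invisible(x)
}

#' Read economic parameters from a YAML or JSON configuration file
#'
#' Expected keys: `k_usd_per_daly` (scalar) and optionally
#' `threshold_scenarios` (a label -> value mapping).
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return An `economy_params` object.
#' @export
read_economy <- function(path) {
  if (!file.exists(path))
    stop("config file not found: ", path, call. = FALSE)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::fromJSON(path)
  else
    yaml::read_yaml(path)
  if (is.null(cfg$k_usd_per_daly))
    stop("config is missing required key 'k_usd_per_daly'", call. = FALSE)
  scen <- cfg$threshold_scenarios
  if (is.null(scen)) {
    economy_params(as.numeric(cfg$k_usd_per_daly), numeric(0))
  } else {
    economy_params(as.numeric(cfg$k_usd_per_daly),
                   unlist(scen))
  }
}

as_economy <- function(econ) {
  if (inherits(econ, "economy_params")) return(econ)
  if (is.numeric(econ) && length(econ) == 1L)
    return(economy_params(econ, numeric(0)))
  stop("'econ' must be an economy_params object or a scalar k", call. = FALSE)
}
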