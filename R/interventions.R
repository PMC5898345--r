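#' Construct a validated intervention table
#'
#' The unit of analysis is a candidate health service ("intervention") for a
#' publicly funded benefits package. Each row carries the quantities the
#' valuation needs at national scale and full implementation:
#' the incremental cost-effectiveness ratio (ICER, USD per DALY averted, or a
#' cost-saving marker), the eligible caseload per year, the total annual cost
#' and total DALYs averted were the whole eligible population served, and the
#' observed implementation level (fraction of the eligible population
#' actually reached).
#'
#' All currency is raw USD and all health raw DALYs; table transcriptions in
#' thousands must be converted on load (see [read_interventions()]).
#'
#' @param df A data.frame with columns `id`, `name`, `icer` (USD/DALY; `NA`
#'   allowed where `cost_saving` is `TRUE`), `cost_saving` (logical),
#'   `cases` (eligible cases per year), `cost_full` (USD at full
#'   implementation; may be negative only for cost-saving rows), `dalys_full`
#'   (DALYs averted at full implementation), `level` (implementation fraction
#'   in \[0,1\]). Optional: `flags` (semicolon-separated policy labels) and
#'   any extra columns, which are preserved.
#' @return The data.frame, validated, with class `interventions`.
#' @examples
#' iv <- interventions(data.frame(
#'   id = "a", name = "A", icer = 30, cost_saving = FALSE,
#'   cases = 1000, cost_full = 3e5, dalys_full = 1e4, level = 0.5))
#' @export
interventions <- function(df) {
  df <- as.data.frame(df)
  req <- c("id", "name", "icer", "cost_saving", "cases",
           "cost_full", "dalys_full", "level")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  df$id <- as.character(df$id)
  df$name <- as.character(df$name)
  df$cost_saving <- as.logical(df$cost_saving)
  for (col in c("icer", "cases", "cost_full", "dalys_full", "level"))
    df[[col]] <- as.numeric(df[[col]])
  if (!"flags" %in% names(df)) df$flags <- rep("", nrow(df))
  df$flags[is.na(df$flags)] <- ""

  if (anyDuplicated(df$id))
    stop("intervention ids must be unique", call. = FALSE)
  if (any(is.na(df$level)))
    stop("implementation level must not be NA (default missing levels on load)",
         call. = FALSE)
  if (any(df$level < 0 | df$level > 1))
    stop("implementation level must lie in [0, 1]", call. = FALSE)
  if (any(df$cases < 0, na.rm = TRUE))
    stop("cases per year must be >= 0", call. = FALSE)
  if (any(!df$cost_saving & is.na(df$icer)))
    stop("icer may be NA only for cost-saving interventions", call. = FALSE)
  if (any(!df$cost_saving & df$icer <= 0, na.rm = TRUE))
    stop("icer must be > 0 for cost-incurring interventions", call. = FALSE)
  if (any(!df$cost_saving & df$cost_full < 0, na.rm = TRUE))
    stop("negative cost_full requires the cost-saving marker", call. = FALSE)

  class(df) <- c("interventions", "data.frame")
  df
}

#' @export
print.interventions <- function(x, ...) {
  cat(sprintf("Intervention set: %d interventions\n", nrow(x)))
  cs <- sum(x$cost_saving)
  if (cs) cat(sprintf("  cost-saving: %d\n", cs))
  cat(sprintf("  total cost at full implementation: $%s\n",
              format(round(sum(x$cost_full)), big.mark = ",")))
  cat(sprintf("  mean implementation level: %.0f%%\n", 100 * mean(x$level)))
  NextMethod()
}

# keep the class when subsetting rows/columns, if all required columns survive
#' @export
`[.interventions` <- function(x, ...) {
  out <- NextMethod()
  req <- c("id", "name", "icer", "cost_saving", "cases",
           "cost_full", "dalys_full", "level")
  if (is.data.frame(out) && all(req %in% names(out)))
    class(out) <- c("interventions", "data.frame")
  else if (is.data.frame(out))
    class(out) <- "data.frame"
  out
}
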