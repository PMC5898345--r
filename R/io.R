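#' Read an intervention table from delimited text
#'
#' Canonical schema (comma-separated, header row):
#' `id,name,icer_usd_per_daly,cost_saving,cases_per_year,cost_full_usd,`
#' `dalys_full,implementation_level,flags`. `cost_saving` is 0/1 or
#' TRUE/FALSE; `icer_usd_per_daly` may be empty/`NA` on cost-saving rows;
#' `flags` is optional. A first line of the form `# units: thousands`
#' declares that the monetary, DALY and caseload columns are in thousands
#' (as published league tables usually are) and triggers conversion to raw
#' units; the same is forced by `units = "thousands"`.
#'
#' Rows with a missing `implementation_level` default to 1 with a warning;
#' duplicated names are dropped (first occurrence kept) with a warning.
#'
#' @param path Path to the file.
#' @param units `"usd"` (raw units, default) or `"thousands"`.
#' @return An [interventions()] table.
#' @export
read_interventions <- function(path, units = c("usd", "thousands")) {
  units <- match.arg(units)
  if (!file.exists(path))
    stop("input file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  if (grepl("^#\\s*units\\s*:\\s*thousands", first, ignore.case = TRUE))
    units <- "thousands"
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  req <- c("id", "name", "icer_usd_per_daly", "cost_saving",
           "cases_per_year", "cost_full_usd", "dalys_full")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("input is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (!"implementation_level" %in% names(df)) {
    warning("no 'implementation_level' column; defaulting all levels to 1",
            call. = FALSE)
    df$implementation_level <- 1
  }
  if (anyNA(df$implementation_level)) {
    warning(sum(is.na(df$implementation_level)),
            " row(s) missing implementation_level; defaulting to 1",
            call. = FALSE)
    df$implementation_level[is.na(df$implementation_level)] <- 1
  }
  if (any(df$implementation_level > 1 | df$implementation_level < 0))
    stop("implementation_level outside [0, 1] in input", call. = FALSE)
  dup <- duplicated(df$name)
  if (any(dup)) {
    warning("dropping ", sum(dup), " duplicated row(s): ",
            paste(unique(df$name[dup]), collapse = "; "), call. = FALSE)
    df <- df[!dup, ]
  }
  mult <- if (units == "thousands") 1000 else 1
  out <- data.frame(id = df$id,
                    name = df$name,
                    icer = as.numeric(df$icer_usd_per_daly),
                    cost_saving = as.logical(df$cost_saving),
                    cases = as.numeric(df$cases_per_year) * mult,
                    cost_full = as.numeric(df$cost_full_usd) * mult,
                    dalys_full = as.numeric(df$dalys_full) * mult,
                    level = as.numeric(df$implementation_level),
                    flags = if ("flags" %in% names(df)) df$flags
                            else rep("", nrow(df)),
                    stringsAsFactors = FALSE)
  interventions(out)
}

#' Write an intervention table in the canonical delimited schema
#'
#' Inverse of [read_interventions()] (raw units); round-trips without loss.
#'
#' @param iv An [interventions()] table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_interventions <- function(iv, path) {
  out <- data.frame(id = iv$id, name = iv$name,
                    icer_usd_per_daly = iv$icer,
                    cost_saving = as.integer(iv$cost_saving),
                    cases_per_year = iv$cases,
                    cost_full_usd = iv$cost_full,
                    dalys_full = iv$dalys_full,
                    implementation_level = iv$level,
                    flags = iv$flags)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Write an analysis report to disk
#'
#' Data frames (league/frontier tables, value metrics) are written as
#' comma-separated text; list-like reports (`hbp_package`,
#' `scaleup_report`, `expansion_report`, conditionality results) as JSON.
#'
#' @param report The object to write.
#' @param path Output path.
#' @param format `"csv"` or `"json"`; default chosen from the object type.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, format = NULL) {
  if (is.null(format))
    format <- if (is.data.frame(report)) "csv" else "json"
  format <- match.arg(format, c("csv", "json"))
  if (format == "csv") {
    if (!is.data.frame(report))
      stop("csv output requires a data.frame report", call. = FALSE)
    utils::write.csv(report, path, row.names = FALSE)
  } else {
    report <- strip_report(report)
    jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, force = TRUE)
  }
  invisible(path)
}

# drop heavyweight embedded objects before serialising
strip_report <- function(x) {
  if (inherits(x, "hbp_package"))
    return(list(label = x$label, k = x$k, included_ids = x$included_ids,
                budget = x$budget, budget_cap = x$budget_cap,
                total_dalys = x$total_dalys,
                total_net_dalys = x$total_net_dalys))
  if (is.list(x) && !is.data.frame(x))
    return(lapply(x, strip_report))
  x
}
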