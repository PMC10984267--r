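#' Growth curves of panicle counts
#'
#' A growth curve is one plot's ordered series of (acquisition date, panicle
#' count). Dates may be integer day offsets or `Date`s (ISO-8601 strings are
#' converted); internally traits are computed on day offsets from the first
#' flight, so the two representations are interchangeable.
#'
#' @param plot_id plot identifier.
#' @param date vector of dates (numeric day offsets, `Date`, or ISO strings),
#'   strictly increasing after sorting; duplicates are an error.
#' @param count non-negative panicle counts.
#' @return object of class `growth_curve` with fields `plot_id`, `date`,
#'   `count`.
#' @export
growth_curve <- function(plot_id, date, count) {
  if (is.character(date)) date <- as.Date(date)
  if (length(date) != length(count)) stop("date/count length mismatch")
  if (anyDuplicated(date))
    stop(sprintf("plot %s: duplicate date(s) %s", plot_id,
                 paste(unique(date[duplicated(date)]), collapse = ", ")))
  ord <- order(date)
  if (any(count < 0)) stop("counts must be non-negative")
  structure(list(plot_id = as.character(plot_id), date = date[ord],
                 count = as.numeric(count)[ord]),
            class = "growth_curve")
}

#' @export
print.growth_curve <- function(x, ...) {
  cat(sprintf("growth_curve %s: %d dates, max count %g\n",
              x$plot_id, length(x$date), if (length(x$count)) max(x$count) else NA))
  invisible(x)
}

#' Assemble growth curves from long-format records
#'
#' @param records data.frame with columns `plot_id`, `date`, `count` (an
#'   alias column `panicle_count` is accepted).
#' @return named list of [growth_curve()]s, one per plot.
#' @export
build_growth_curves <- function(records) {
  records <- as.data.frame(records)
  if ("panicle_count" %in% names(records) && !"count" %in% names(records))
    records$count <- records$panicle_count
  stopifnot(all(c("plot_id", "date", "count") %in% names(records)))
  by_plot <- split(records, as.character(records$plot_id))
  out <- lapply(by_plot, function(d)
    growth_curve(d$plot_id[1], d$date, d$count))
  out[unique(as.character(records$plot_id))]
}

#' Heading date at a fraction of the maximum panicle count
#'
#' The y% heading date is the observed flight date whose panicle count is
#' closest to y% of the curve's maximum:
#' \deqn{\mathrm{hd}_y = \arg\min_x |c(x) - y \cdot \max_t c(t)|.}
#' The argmin runs over observed dates only (no interpolation between
#' flights; resolution is bounded by the flight cadence) and ties break to
#' the earliest date — a stage is "reached" at first attainment.
#'
#' An all-zero curve has no heading signal; the trait is undefined and `NA`
#' is returned.
#'
#' @param curve a [growth_curve()].
#' @param fraction target fraction of the maximum, in `(0, 1]`.
#' @return the heading date (same type as the curve's dates), or `NA`.
#' @export
heading_date <- function(curve, fraction) {
  stopifnot(inherits(curve, "growth_curve"),
            fraction > 0, fraction <= 1, length(curve$count) > 0)
  m <- max(curve$count)
  if (m == 0) return(curve$date[NA_integer_])
  resid <- abs(curve$count - fraction * m)
  curve$date[which.min(resid)]   # first index wins ties -> earliest date
}

#' Extract the six heading-date-related traits from one growth curve
#'
#' Static traits: the maximum panicle count and the heading dates at 10, 30,
#' 50 and 80 percent of it (see [heading_date()]). Dynamic trait: the heading
#' stage, the time from the 10% date to the 80% date in days.
#'
#' `monotonize` optionally replaces the counts by their running maximum
#' before extraction, suppressing transient dips from detection noise; raw
#' counts are the default.
#'
#' @param curve a [growth_curve()] with at least 2 points.
#' @param fractions the fractions defining the static heading dates.
#' @param monotonize apply a cumulative-maximum to the counts first.
#' @return list of class `trait_record`: `plot_id`, `max_count`, one `hd<pct>`
#'   per fraction, and `heading_stage` (days, `NA` when undefined).
#' @export
extract_traits <- function(curve, fractions = c(0.1, 0.3, 0.5, 0.8),
                           monotonize = FALSE) {
  stopifnot(inherits(curve, "growth_curve"))
  if (length(curve$count) < 2L)
    stop(sprintf("plot %s: need >= 2 points for trait extraction",
                 curve$plot_id))
  if (monotonize) curve$count <- cummax(curve$count)
  hds <- lapply(fractions, function(f) heading_date(curve, f))
  names(hds) <- sprintf("hd%d", as.integer(round(100 * fractions)))
  stage <- if ("hd10" %in% names(hds) && "hd80" %in% names(hds) &&
               !is.na(hds$hd10) && !is.na(hds$hd80))
    as.numeric(hds$hd80) - as.numeric(hds$hd10) else NA_real_
  structure(c(list(plot_id = curve$plot_id,
                   max_count = max(curve$count)),
              hds, list(heading_stage = stage)),
            class = "trait_record")
}

#' Tabulate trait records for a set of growth curves
#'
#' One row per plot, CSV-serializable; undefined traits (all-zero curves)
#' come out as `NA` fields.
#'
#' @param curves list of [growth_curve()]s (or output of
#'   [build_growth_curves()]).
#' @param fractions,monotonize passed to [extract_traits()].
#' @return data.frame with columns `plot_id`, `max_count`, `hd10`, `hd30`,
#'   `hd50`, `hd80`, `heading_stage` (for the default fractions).
#' @export
traits_table <- function(curves, fractions = c(0.1, 0.3, 0.5, 0.8),
                         monotonize = FALSE) {
  rows <- lapply(curves, function(cv) {
    tr <- extract_traits(cv, fractions, monotonize)
    as.data.frame(lapply(unclass(tr), function(v)
      if (inherits(v, "Date")) as.character(v) else v),
      stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  df
}
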