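#' Number of arid months in a 12-month climate record
#'
#' A month is arid when the arithmetic mean of its minimum and maximum
#' temperature (degrees C) is larger than half its precipitation (mm) — the
#' Walter/Gaussen drought criterion, with a strict inequality so that
#' equality counts as non-arid.
#'
#' @param tmin,tmax monthly minimum/maximum temperature, length 12, degrees C.
#' @param prec monthly precipitation, length 12, mm.
#' @return integer count in `[0, 12]`.
#' @examples
#' arid_months(rep(20, 12), rep(30, 12), rep(0, 12))    # 12
#' arid_months(rep(20, 12), rep(30, 12), rep(1000, 12)) # 0
#' @export
arid_months <- function(tmin, tmax, prec) {
  if (length(tmin) != 12 || length(tmax) != 12 || length(prec) != 12)
    stop("climate vectors must have 12 monthly values")
  sum((tmin + tmax) / 2 > prec / 2)
}

#' Annual precipitation from monthly values
#'
#' @param prec monthly precipitation, length 12, mm; all values must be
#'   non-negative.
#' @return the 12-month sum, mm.
#' @export
annual_precip <- function(prec) {
  if (length(prec) != 12) stop("precipitation vector must have 12 values")
  if (any(prec < 0)) stop("negative monthly precipitation")
  sum(prec)
}

#' Per-record niche statistics for an occurrence table
#'
#' @param records occurrence data.frame as returned by [read_occurrences()].
#' @return data.frame with `record_id`, `unit`, `annual_precip` (mm) and
#'   `arid_months` (0-12) per record.
#' @export
niche_values <- function(records) {
  mm <- sprintf("%02d", 1:12)
  tmin <- as.matrix(records[paste0("tmin_", mm)])
  tmax <- as.matrix(records[paste0("tmax_", mm)])
  prec <- as.matrix(records[paste0("prec_", mm)])
  data.frame(
    record_id = records$record_id,
    unit = records$unit,
    annual_precip = rowSums(prec),
    arid_months = rowSums((tmin + tmax) / 2 > prec / 2),
    stringsAsFactors = FALSE
  )
}

# five-number summary used for the box-and-whisker tables; quartiles use the
# linear-interpolation convention (stats::quantile type 7) so tables are
# reproducible bit-for-bit
.five_num <- function(x) {
  q <- stats::quantile(x, c(0, 0.25, 0.5, 0.75, 1), names = FALSE, type = 7)
  c(min = q[1], q1 = q[2], median = q[3], q3 = q[4], max = q[5])
}

#' Per-unit niche summaries (box-plot table)
#'
#' Summarizes annual precipitation and arid-month counts across the records
#' of each species/unit: median, quartiles and range — the numbers behind a
#' box-and-whisker figure of precipitation tolerances.
#'
#' @param records occurrence data.frame (see [read_occurrences()]).
#' @param tip_order optional character vector (typically `tree$tip.label`)
#'   fixing the row order so the table follows the phylogeny; units absent
#'   from `tip_order` are dropped with a warning.  Default: first-appearance
#'   order of the input.
#' @return data.frame with one row per unit: `unit`, `n`, then
#'   `annual_precip_{min,q1,median,q3,max}` and
#'   `arid_months_{min,q1,median,q3,max}`.
#' @export
summarize_niche <- function(records, tip_order = NULL) {
  vals <- niche_values(records)
  units <- unique(vals$unit)
  if (!is.null(tip_order)) {
    extra <- setdiff(units, tip_order)
    if (length(extra))
      warning("unit(s) not in tip ordering dropped: ",
              paste(extra, collapse = ", "), call. = FALSE)
    units <- intersect(tip_order, units)
  }
  rows <- lapply(units, function(u) {
    v <- vals[vals$unit == u, ]
    ap <- .five_num(v$annual_precip)
    am <- .five_num(v$arid_months)
    out <- data.frame(unit = u, n = nrow(v), stringsAsFactors = FALSE)
    for (nm in names(ap)) out[[paste0("annual_precip_", nm)]] <- ap[[nm]]
    for (nm in names(am)) out[[paste0("arid_months_", nm)]] <- am[[nm]]
    out
  })
  if (!length(rows)) {
    out <- data.frame(unit = character(0), n = integer(0))
    return(out)
  }
  do.call(rbind, rows)
}

#' Write a niche summary table as TSV
#' @param summary data.frame from [summarize_niche()].
#' @param file output path.
#' @export
write_niche_summary <- function(summary, file) {
  utils::write.table(summary, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}
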