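#' Read a table of geo-referenced occurrence records with monthly climate
#'
#' The expected CSV schema is one row per herbarium collection:
#' `record_id, unit, lat, lon, tmin_01..tmin_12, tmax_01..tmax_12,
#' prec_01..prec_12`, with temperatures in degrees Celsius and monthly
#' precipitation in mm (WorldClim-style values extracted beforehand; raster
#' handling is out of scope here).  Some WorldClim rasters store temperature
#' in tenths of a degree; `temp_scale = 0.1` converts such values on read.
#'
#' Row validation enforces `tmin <= tmax` in every month and `prec >= 0`.
#' By default any invalid row aborts the read (strict mode, so no record is
#' silently dropped); with `strict = FALSE` offending rows are dropped and
#' reported via a warning listing their row numbers.
#'
#' @param path CSV file path.
#' @param strict abort on an invalid row (default) or skip-and-warn.
#' @param temp_scale multiplier applied to `tmin`/`tmax` columns (1 = already
#'   degrees C, 0.1 = tenths of a degree).
#' @return a `data.frame` of validated records with the schema above.
#' @export
read_occurrences <- function(path, strict = TRUE, temp_scale = 1) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  mm <- sprintf("%02d", 1:12)
  needed <- c("record_id", "unit", "lat", "lon",
              paste0("tmin_", mm), paste0("tmax_", mm), paste0("prec_", mm))
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols))
    stop("occurrence file is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  clim_cols <- needed[-(1:4)]
  bad <- logical(nrow(df))
  for (cc in c(clim_cols, "lat", "lon")) {
    v <- suppressWarnings(as.numeric(df[[cc]]))
    bad <- bad | is.na(v)
    df[[cc]] <- v
  }
  tmin <- as.matrix(df[paste0("tmin_", mm)]) * temp_scale
  tmax <- as.matrix(df[paste0("tmax_", mm)]) * temp_scale
  prec <- as.matrix(df[paste0("prec_", mm)])
  bad <- bad | rowSums(tmin > tmax, na.rm = TRUE) > 0 |
    rowSums(prec < 0, na.rm = TRUE) > 0
  if (any(bad)) {
    rows <- which(bad)
    msg <- paste0("invalid occurrence row(s): ",
                  paste(rows, collapse = ", "),
                  " (non-numeric climate, tmin > tmax, or negative precipitation)")
    if (strict) stop(msg) else warning(msg, call. = FALSE)
    df <- df[!bad, , drop = FALSE]
    tmin <- tmin[!bad, , drop = FALSE]
    tmax <- tmax[!bad, , drop = FALSE]
  }
  df[paste0("tmin_", mm)] <- tmin
  df[paste0("tmax_", mm)] <- tmax
  rownames(df) <- NULL
  df[needed]
}

#' Biome state vocabulary
#'
#' The default three habitat categories and their integer codes: semi-arid
#' habitats (0; semi-deserts, bushland, semi-arid savanna), woodland (1;
#' including mountain shrubland, humid grassland, semi-humid savanna), and
#' forest (2; semi-deciduous, lowland rain and mountain forest).
#' @export
biome_states <- c(semi_arid = 0L, woodland = 1L, forest = 2L)

#' Read a tip-to-biome coding table
#'
#' Two columns, `unit` and `biome`, the latter either a state name from the
#' vocabulary (`semi_arid | woodland | forest` by default) or an integer code
#' in `[0, k)`.  Every tip of `tree` must be coded exactly once.  Decisions
#' such as coding a drought-tolerant ruderal species as semi-arid belong in
#' this table, not in code.
#'
#' @param path CSV file path (or a data.frame already in memory).
#' @param tree a `chronogram` whose tips the coding must cover.
#' @param states named integer vector defining the vocabulary
#'   (default [biome_states]).
#' @return a named integer vector, one state per tip label, in tree tip order,
#'   with attribute `k` (number of states).
#' @export
read_biome_coding <- function(path, tree, states = biome_states) {
  df <- if (is.data.frame(path)) path else
    utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("unit", "biome") %in% names(df)))
    stop("biome coding needs columns `unit` and `biome`")
  k <- length(states)
  raw <- as.character(df$biome)
  code <- states[raw]
  num <- suppressWarnings(as.integer(raw))
  code[is.na(code) & !is.na(num)] <- num[is.na(code) & !is.na(num)]
  unknown <- raw[is.na(code)]
  if (length(unknown))
    stop("unknown biome state(s): ", paste(unique(unknown), collapse = ", "))
  if (any(code < 0 | code >= k))
    stop("biome codes must lie in [0, ", k, ")")
  names(code) <- df$unit
  if (anyDuplicated(df$unit))
    stop("unit(s) coded more than once: ",
         paste(unique(df$unit[duplicated(df$unit)]), collapse = ", "))
  tips <- tree$tip.label
  missing <- setdiff(tips, df$unit)
  if (length(missing))
    stop("tip(s) without biome coding: ", paste(missing, collapse = ", "))
  out <- code[tips]
  attr(out, "k") <- k
  out
}
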