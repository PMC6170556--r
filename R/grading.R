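#' @section Grading tables:
#' A grading table holds, for each pollutant and for the AQI index scale,
#' the ordered upper concentration limits of the five grading levels (Good,
#' Moderate, Lightly Polluted, Moderately Polluted, Heavily Polluted). Each
#' level's band runs from the previous level's upper limit (0 for level 1)
#' to its own. The packaged default carries the daily-average bands of the
#' Chinese ambient air quality standards GB 3095-2012 / HJ 633-2012 for
#' PM2.5, PM10, SO2, NO2 and O3 in ug/m3 and CO in mg/m3, with index bands
#' topped at 50, 100, 150, 200 and 300 points.
#' @name grading
NULL

#' The six criteria pollutants, in canonical column order
#' @export
AIR_INDICATORS <- c("PM2.5", "PM10", "SO2", "CO", "NO2", "O3")

#' The five grading-level labels, from least to most severe
#' @export
LEVEL_LABELS <- c("Good", "Moderate", "Lightly Polluted",
                  "Moderately Polluted", "Heavily Polluted")

#' Default regulatory grading table
#'
#' Daily-average grading bands for the six criteria pollutants and the AQI
#' index scale under GB 3095-2012 / HJ 633-2012, five levels per scale.
#' CO is in mg/m3; all other pollutants in ug/m3.
#'
#' @return A `grading_table` object.
#' @export
default_grading_table <- function() {
  new_grading_table(
    labels = LEVEL_LABELS,
    index = c(50, 100, 150, 200, 300),
    indicators = list(
      `PM2.5` = list(unit = "ug/m3", upper = c(35, 75, 115, 150, 250)),
      PM10    = list(unit = "ug/m3", upper = c(50, 150, 250, 350, 420)),
      SO2     = list(unit = "ug/m3", upper = c(50, 150, 475, 800, 1600)),
      CO      = list(unit = "mg/m3", upper = c(2, 4, 14, 24, 36)),
      NO2     = list(unit = "ug/m3", upper = c(40, 80, 180, 280, 565)),
      O3      = list(unit = "ug/m3", upper = c(100, 160, 215, 265, 800))
    )
  )
}

new_grading_table <- function(labels, index, indicators) {
  tb <- structure(list(labels = labels, index = as.numeric(index),
                       indicators = indicators),
                  class = "grading_table")
  validate_grading_table(tb)
}

#' Validate a grading table's structure
#'
#' Checks that every scale carries the same number of levels and strictly
#' increasing positive upper limits; returns the table invisibly on
#' success.
#'
#' @param tb A `grading_table`.
#' @export
validate_grading_table <- function(tb) {
  if (!is.list(tb$indicators) || length(tb$indicators) == 0L)
    stop("grading table has no indicators", call. = FALSE)
  m <- length(tb$labels)
  check_upper <- function(upper, what) {
    if (length(upper) != m)
      stop(sprintf("grading table: %s has %d limits, expected %d",
                   what, length(upper), m), call. = FALSE)
    if (!all(is.finite(upper)) || any(diff(c(0, upper)) <= 0))
      stop(sprintf(
        "grading table: %s limits must be positive and strictly increasing",
        what), call. = FALSE)
  }
  check_upper(tb$index, "index scale")
  for (ind in names(tb$indicators))
    check_upper(tb$indicators[[ind]]$upper, ind)
  tb
}

#' @export
print.grading_table <- function(x, ...) {
  cat(sprintf("<grading table> %d levels (%s)\n", length(x$labels),
              paste(x$labels, collapse = ", ")))
  cat(sprintf("  index scale: %s\n", paste(x$index, collapse = " ")))
  for (ind in names(x$indicators))
    cat(sprintf("  %-6s [%s]: %s\n", ind, x$indicators[[ind]]$unit,
                paste(x$indicators[[ind]]$upper, collapse = " ")))
  invisible(x)
}

#' Level bands of one scale
#'
#' Expands the ordered upper limits of an indicator (or `"AQI"` for the
#' index scale) into explicit bands with lower and upper bounds.
#'
#' @param table A `grading_table`.
#' @param indicator Indicator name or `"AQI"`.
#' @return A `data.frame` with columns `level`, `label`, `cmin`, `cmax`.
#' @export
level_bands <- function(table, indicator) {
  stopifnot(inherits(table, "grading_table"))
  upper <- if (identical(indicator, "AQI")) table$index
  else {
    if (!indicator %in% names(table$indicators))
      stop(sprintf("unknown indicator '%s'", indicator), call. = FALSE)
    table$indicators[[indicator]]$upper
  }
  data.frame(level = seq_along(upper), label = table$labels,
             cmin = c(0, upper[-length(upper)]), cmax = upper)
}

#' Read / write a grading table as JSON
#'
#' The JSON document mirrors the in-memory layout: `labels`, `index`
#' (upper limits of the index bands) and `indicators`, each with `unit` and
#' ordered `upper` limits. The packaged default table round-trips exactly.
#'
#' @param path File path.
#' @return `read_grading_table` returns a validated `grading_table`;
#'   `write_grading_table` invisibly returns `path`.
#' @export
read_grading_table <- function(path) {
  if (!file.exists(path))
    stop(sprintf("grading table file not found: %s", path), call. = FALSE)
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (field in c("labels", "index", "indicators"))
    if (is.null(doc[[field]]))
      stop(sprintf("grading table JSON missing field '%s'", field),
           call. = FALSE)
  inds <- lapply(doc$indicators, function(x)
    list(unit = x$unit, upper = as.numeric(x$upper)))
  new_grading_table(labels = doc$labels, index = doc$index,
                    indicators = inds)
}

#' @rdname read_grading_table
#' @param table A `grading_table` to serialize.
#' @export
write_grading_table <- function(table, path) {
  stopifnot(inherits(table, "grading_table"))
  jsonlite::write_json(
    list(labels = table$labels, index = table$index,
         indicators = table$indicators),
    path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' Standard cloud of one grading band
#'
#' For a concept bounded bilaterally by `[cmin, cmax]`, the standard cloud
#' has `Ex = (cmin + cmax)/2` (band midpoint), `En = (cmax - cmin)/6`
#' (the 3-sigma convention: the band spans six entropies), and
#' `He = k * En`. The ratio `k` tunes how much randomness the membership of
#' the standard concept is allowed; conventionally at most one third, with
#' 0.1 as the working default.
#'
#' @param cmin,cmax Band bounds, `cmin < cmax`.
#' @param k Hyper-entropy ratio in (0, 1/3]; values above 1/3 warn.
#' @return A [cloud_model()].
#' @examples
#' standard_cloud(150, 475) # SO2 Lightly Polluted: (312.5, 54.17, 5.42)
#' @export
standard_cloud <- function(cmin, cmax, k = 0.1) {
  if (!is.numeric(cmin) || !is.numeric(cmax) || cmin >= cmax)
    stop("band requires cmin < cmax", call. = FALSE)
  if (!is.numeric(k) || length(k) != 1L || k <= 0)
    stop("`k` must be a positive ratio", call. = FALSE)
  if (k > 1 / 3)
    warning("hyper-entropy ratio k above 1/3; standard clouds will be thick",
            call. = FALSE)
  en <- (cmax - cmin) / 6
  cloud_model(ex = (cmin + cmax) / 2, en = en, he = k * en)
}

#' Build the full standard cloud set from a grading table
#'
#' Converts every (indicator, level) band of the table, plus the AQI index
#' bands, into standard clouds.
#'
#' @param table A `grading_table`.
#' @param k Hyper-entropy ratio, stored on the result for provenance.
#' @return A `standard_cloud_set`: a `data.frame` with columns `indicator`,
#'   `level`, `label`, `cmin`, `cmax`, `ex`, `en`, `he` and attribute `k`.
#' @examples
#' scs <- build_standard_clouds(default_grading_table())
#' subset(scs, indicator == "AQI")
#' @export
build_standard_clouds <- function(table, k = 0.1) {
  stopifnot(inherits(table, "grading_table"))
  scales <- c("AQI", names(table$indicators))
  rows <- lapply(scales, function(ind) {
    bands <- level_bands(table, ind)
    cl <- lapply(seq_len(nrow(bands)), function(i)
      standard_cloud(bands$cmin[i], bands$cmax[i], k))
    cbind(indicator = ind, bands,
          ex = vapply(cl, `[[`, numeric(1), "ex"),
          en = vapply(cl, `[[`, numeric(1), "en"),
          he = vapply(cl, `[[`, numeric(1), "he"))
  })
  structure(do.call(rbind, rows),
            class = c("standard_cloud_set", "data.frame"), k = k)
}

#' Standard clouds of one indicator as a list of cloud models
#'
#' @param set A `standard_cloud_set` from [build_standard_clouds()].
#' @param indicator Indicator name or `"AQI"`.
#' @return A named list of [cloud_model()] objects ordered by level.
#' @export
standard_clouds_for <- function(set, indicator) {
  stopifnot(inherits(set, "standard_cloud_set"))
  rows <- set[set$indicator == indicator, , drop = FALSE]
  if (nrow(rows) == 0L)
    stop(sprintf("no standard clouds for indicator '%s'", indicator),
         call. = FALSE)
  rows <- rows[order(rows$level), , drop = FALSE]
  out <- lapply(seq_len(nrow(rows)), function(i)
    cloud_model(rows$ex[i], rows$en[i], rows$he[i]))
  names(out) <- rows$label
  out
}

#' Export a standard cloud set to JSON for audit
#'
#' @param set A `standard_cloud_set`.
#' @param path Output file path.
#' @export
write_standard_clouds <- function(set, path) {
  stopifnot(inherits(set, "standard_cloud_set"))
  jsonlite::write_json(
    list(k = attr(set, "k"), clouds = as.data.frame(set)),
    path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' Individual air quality index (IAQI) of one pollutant
#'
#' Linear interpolation of a concentration against the grading table's
#' breakpoints: the band with `BP_Lo < C <= BP_Hi` (band 1 including 0) is
#' located and the concentration mapped linearly onto the corresponding
#' index band. No rounding is applied. Concentrations above the top
#' breakpoint are extrapolated on the last segment and flagged
#' `above_scale`.
#'
#' @param concentration Non-negative concentration in the indicator's unit.
#' @param indicator One of the table's indicator names.
#' @param table A `grading_table`.
#' @return A list with `indicator`, `value` (index points), `segment`
#'   (the `BP_Lo`, `BP_Hi`, `IAQI_Lo`, `IAQI_Hi` used) and `above_scale`.
#' @examples
#' iaqi(75, "PM2.5")$value   # breakpoint -> exactly 100
#' iaqi(220.2, "PM2.5")$value
#' @export
iaqi <- function(concentration, indicator, table = default_grading_table()) {
  stopifnot(inherits(table, "grading_table"))
  if (!indicator %in% names(table$indicators))
    stop(sprintf("unknown indicator '%s'", indicator), call. = FALSE)
  if (!is.numeric(concentration) || length(concentration) != 1L ||
      !is.finite(concentration))
    stop("`concentration` must be a single finite number", call. = FALSE)
  if (concentration < 0)
    stop(sprintf("negative %s concentration: %g", indicator, concentration),
         call. = FALSE)
  bp <- c(0, table$indicators[[indicator]]$upper)
  iq <- c(0, table$index)
  i <- findInterval(concentration, bp, left.open = TRUE)
  i <- max(1L, i)                      # 0 belongs to band 1
  above <- i > length(bp) - 1L
  if (above) i <- length(bp) - 1L      # extrapolate on the top segment
  value <- (iq[i + 1] - iq[i]) / (bp[i + 1] - bp[i]) *
    (concentration - bp[i]) + iq[i]
  list(indicator = indicator, value = value,
       segment = c(BP_Lo = bp[i], BP_Hi = bp[i + 1],
                   IAQI_Lo = iq[i], IAQI_Hi = iq[i + 1]),
       above_scale = above)
}

#' AQI of one daily record
#'
#' The AQI is the maximum of the six individual indices; the pollutant(s)
#' attaining the maximum are reported as dominant.
#'
#' @param record A one-row `data.frame` (or named list/vector) with the six
#'   pollutant concentrations.
#' @param table A `grading_table`.
#' @return A list with `aqi`, `dominant` (character vector; several in case
#'   of ties), `iaqi` (named vector of the six indices) and `above_scale`.
#' @export
aqi_record <- function(record, table = default_grading_table()) {
  inds <- names(table$indicators)
  vals <- vapply(inds, function(ind) {
    v <- record[[ind]]
    if (is.null(v) || length(v) != 1L || is.na(v))
      stop(sprintf("record is missing indicator '%s'", ind), call. = FALSE)
    as.numeric(v)
  }, numeric(1))
  res <- lapply(inds, function(ind) iaqi(vals[[ind]], ind, table))
  iaqis <- vapply(res, `[[`, numeric(1), "value")
  names(iaqis) <- inds
  top <- max(iaqis)
  list(aqi = top,
       dominant = inds[iaqis == top],
       iaqi = iaqis,
       above_scale = any(vapply(res, `[[`, logical(1), "above_scale")))
}

#' Daily AQI series of a month table
#'
#' @param records A month table as returned by [read_daily_csv()].
#' @param table A `grading_table`.
#' @return A `data.frame` with `date`, one IAQI column per pollutant,
#'   `AQI` and `dominant`.
#' @export
daily_aqi <- function(records, table = default_grading_table()) {
  stopifnot(is.data.frame(records), nrow(records) >= 1L)
  rows <- lapply(seq_len(nrow(records)), function(i) {
    r <- aqi_record(records[i, , drop = FALSE], table)
    cbind(data.frame(date = records$date[i]),
          as.data.frame(as.list(r$iaqi), check.names = FALSE),
          data.frame(AQI = r$aqi,
                     dominant = paste(r$dominant, collapse = "+")))
  })
  do.call(rbind, rows)
}
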