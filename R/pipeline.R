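#' Assess one month of daily monitoring data
#'
#' The full monthly pipeline: each pollutant's daily series is summarised
#' into a cloud by the backward generator and classified against that
#' pollutant's standard clouds (quantitative level = maximum similarity;
#' qualitative level = the pair of standard levels whose expectations
#' bracket the assessed expectation). The daily AQI series (per-day maximum
#' of the interpolated individual indices) is summarised and classified the
#' same way on the index scale, and grey relational analysis re-derives the
#' per-indicator levels from the same expectations as an independent
#' cross-check, reported as a concordance count.
#'
#' @param records A month table (see [read_daily_csv()]), at least 2 rows.
#' @param table A `grading_table`; defaults to the regulatory table.
#' @param k Hyper-entropy ratio for the standard clouds.
#' @param rho GRA resolution coefficient.
#' @param month Month identifier (yyyy-mm); inferred from the dates when
#'   omitted.
#' @return A `monthly_assessment` object: a list with `month`,
#'   `indicators` (a `data.frame` of cloud characteristics, levels and peak
#'   similarities), `classifications` (full similarity vectors),
#'   `qualitative` (bracketing level pairs), `aqi` (daily series, cloud,
#'   classification, level), `gra` (the `grey_assessment`) and
#'   `concordance`.
#' @examples
#' res <- assess_month(shenyang_nov2016())
#' res$indicators
#' res$aqi$cloud
#' @export
assess_month <- function(records, table = default_grading_table(),
                         k = 0.1, rho = 0.5, month = NULL) {
  stopifnot(is.data.frame(records))
  if (nrow(records) < 2L)
    stop("monthly assessment needs at least 2 daily records", call. = FALSE)
  missing <- setdiff(AIR_INDICATORS, names(records))
  if (length(missing) > 0L)
    stop(sprintf("missing indicator column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  if (is.null(month) && "date" %in% names(records))
    month <- format(min(as.Date(records$date)), "%Y-%m")

  standards <- build_standard_clouds(table, k)

  clouds <- lapply(AIR_INDICATORS, function(ind)
    backward_cloud(records[[ind]]))
  names(clouds) <- AIR_INDICATORS
  cls <- lapply(AIR_INDICATORS, function(ind)
    classify_cloud(clouds[[ind]], standard_clouds_for(standards, ind)))
  names(cls) <- AIR_INDICATORS
  qual <- lapply(AIR_INDICATORS, function(ind)
    bracket_levels(clouds[[ind]]$ex,
                   standards[standards$indicator == ind, ]))
  names(qual) <- AIR_INDICATORS

  ind_df <- data.frame(
    indicator = AIR_INDICATORS,
    ex = vapply(clouds, `[[`, numeric(1), "ex"),
    en = vapply(clouds, `[[`, numeric(1), "en"),
    he = vapply(clouds, `[[`, numeric(1), "he"),
    level = vapply(cls, `[[`, integer(1), "best_level"),
    label = vapply(cls, function(c) c$labels[c$best_level], character(1)),
    lambda = vapply(cls, function(c) max(c$lambda), numeric(1)),
    row.names = NULL)

  aqi_tab <- daily_aqi(records, table)
  aqi_cloud <- backward_cloud(aqi_tab$AQI)
  aqi_cls <- classify_cloud(aqi_cloud, standard_clouds_for(standards, "AQI"))

  a <- ind_df$ex
  names(a) <- AIR_INDICATORS
  gra <- gra_assess(a, gra_limit_matrix(standards), rho)
  conc <- concordance(ind_df$level, gra$levels)

  structure(list(month = month,
                 indicators = ind_df,
                 clouds = clouds,
                 classifications = cls,
                 qualitative = qual,
                 aqi = list(daily = aqi_tab, cloud = aqi_cloud,
                            classification = aqi_cls,
                            level = aqi_cls$best_level,
                            qualitative = bracket_levels(
                              aqi_cloud$ex,
                              standards[standards$indicator == "AQI", ])),
                 gra = gra,
                 concordance = conc,
                 k = k, rho = rho),
            class = "monthly_assessment")
}

# Levels whose standard-cloud expectations bracket `ex`; a value below the
# first (or above the last) expectation maps to that single extreme level.
bracket_levels <- function(ex, std_rows) {
  std_rows <- std_rows[order(std_rows$level), , drop = FALSE]
  exs <- std_rows$ex
  if (ex <= exs[1]) return(std_rows$level[1])
  if (ex >= exs[length(exs)]) return(std_rows$level[length(exs)])
  i <- findInterval(ex, exs)
  c(std_rows$level[i], std_rows$level[i + 1])
}

#' @export
print.monthly_assessment <- function(x, ...) {
  cat(sprintf("<monthly assessment> %s\n", x$month %||% "(unnamed month)"))
  df <- x$indicators
  df$ex <- round(df$ex, 2); df$en <- round(df$en, 2)
  df$he <- round(df$he, 2); df$lambda <- signif(df$lambda, 3)
  df$gra_level <- x$gra$levels
  print(df, row.names = FALSE)
  cat(sprintf("AQI cloud %s -> %s (lambda = %.4g)\n",
              format(x$aqi$cloud),
              x$aqi$classification$labels[x$aqi$level],
              max(x$aqi$classification$lambda)))
  cat(sprintf("cloud vs GRA concordance: %d/%d indicators\n",
              x$concordance$n_agree, x$concordance$n_total))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Agreement between cloud-model and GRA level assignments
#'
#' @param cloud_levels,gra_levels Equal-length integer level vectors over
#'   the same indicators, in the same order.
#' @return A list with logical `agree`, `n_agree` and `n_total`.
#' @export
concordance <- function(cloud_levels, gra_levels) {
  if (length(cloud_levels) != length(gra_levels))
    stop("level vectors must have equal length", call. = FALSE)
  agree <- as.integer(cloud_levels) == as.integer(gra_levels)
  names(agree) <- names(cloud_levels) %||% names(gra_levels)
  list(agree = agree, n_agree = sum(agree), n_total = length(agree))
}

#' Level trajectories over consecutive months
#'
#' Classifies each month of a multi-month input per indicator and
#' summarises the seasonal contrast as the mean level in meteorological
#' winter (December-February) versus summer (June-August). Months can be
#' supplied either as raw daily tables (a named list of month tables, names
#' yyyy-mm) or as already-estimated cloud characteristics (a `data.frame`
#' with columns `month`, `indicator`, `ex`, `en`, `he`, as returned by
#' [shenyang_monthly_clouds()]). For cloud-characteristic input the AQI and
#' GRA stages need raw daily data and are skipped.
#'
#' @param months Named list of month tables, or a cloud `data.frame`.
#' @param table A `grading_table`.
#' @param k Hyper-entropy ratio for the standard clouds.
#' @return A `seasonal_trajectory`: a list with `levels` (months x
#'   indicators integer matrix) and `season_summary` (per indicator the
#'   mean winter and summer level, when both seasons are present).
#' @examples
#' traj <- assess_series(shenyang_monthly_clouds())
#' traj$levels
#' @export
assess_series <- function(months, table = default_grading_table(),
                          k = 0.1) {
  standards <- build_standard_clouds(table, k)
  if (is.data.frame(months)) {
    need <- c("month", "indicator", "ex", "en", "he")
    if (!all(need %in% names(months)))
      stop(sprintf("cloud input needs columns: %s",
                   paste(need, collapse = ", ")), call. = FALSE)
    ids <- unique(months$month)
    inds <- intersect(AIR_INDICATORS, unique(months$indicator))
    lev <- matrix(NA_integer_, length(ids), length(inds),
                  dimnames = list(ids, inds))
    for (r in seq_len(nrow(months))) {
      ind <- months$indicator[r]
      if (!ind %in% inds) next
      cl <- cloud_model(months$ex[r], months$en[r], months$he[r])
      lev[months$month[r], ind] <-
        classify_cloud(cl, standard_clouds_for(standards, ind))$best_level
    }
  } else if (is.list(months) && length(months) >= 1L) {
    ids <- names(months)
    if (is.null(ids) || any(ids == ""))
      stop("the list of month tables must be named yyyy-mm", call. = FALSE)
    inds <- AIR_INDICATORS
    lev <- matrix(NA_integer_, length(ids), length(inds),
                  dimnames = list(ids, inds))
    for (id in ids) {
      res <- assess_month(months[[id]], table = table, k = k, month = id)
      lev[id, ] <- res$indicators$level
    }
  } else stop("`months` must be a named list or a cloud data.frame",
              call. = FALSE)

  mnum <- as.integer(substr(ids, 6, 7))
  winter <- mnum %in% c(12, 1, 2)
  summer <- mnum %in% c(6, 7, 8)
  season <- NULL
  if (any(winter) && any(summer)) {
    season <- data.frame(
      indicator = colnames(lev),
      winter_mean_level = colMeans(lev[winter, , drop = FALSE]),
      summer_mean_level = colMeans(lev[summer, , drop = FALSE]),
      row.names = NULL)
    season$winter_minus_summer <-
      season$winter_mean_level - season$summer_mean_level
  }
  structure(list(levels = lev, season_summary = season),
            class = "seasonal_trajectory")
}

#' @export
print.seasonal_trajectory <- function(x, ...) {
  cat(sprintf("<seasonal trajectory> %d months x %d indicators\n",
              nrow(x$levels), ncol(x$levels)))
  print(x$levels)
  if (!is.null(x$season_summary)) {
    cat("winter (Dec-Feb) vs summer (Jun-Aug) mean levels:\n")
    print(x$season_summary, row.names = FALSE)
  }
  invisible(x)
}

#' Write a monthly assessment as a JSON report
#'
#' Serializes clouds, similarity vectors, levels, the AQI stage, the GRA
#' cross-check and the run's provenance constants (`k`, `rho`).
#'
#' @param assessment A `monthly_assessment`.
#' @param path Output JSON path.
#' @export
write_assessment_json <- function(assessment, path) {
  stopifnot(inherits(assessment, "monthly_assessment"))
  doc <- list(
    month = assessment$month,
    constants = list(k = assessment$k, rho = assessment$rho),
    indicators = assessment$indicators,
    lambda = lapply(assessment$classifications, `[[`, "lambda"),
    qualitative = assessment$qualitative,
    aqi = list(cloud = unclass(assessment$aqi$cloud),
               level = assessment$aqi$level,
               lambda = assessment$aqi$classification$lambda,
               daily = assessment$aqi$daily),
    gra = list(rho = assessment$gra$rho, d = assessment$gra$d,
               r = assessment$gra$r, levels = assessment$gra$levels),
    concordance = assessment$concordance)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write a level matrix as CSV
#'
#' @param trajectory A `seasonal_trajectory`.
#' @param path Output CSV path.
#' @export
write_level_csv <- function(trajectory, path) {
  stopifnot(inherits(trajectory, "seasonal_trajectory"))
  df <- data.frame(month = rownames(trajectory$levels),
                   trajectory$levels, check.names = FALSE,
                   row.names = NULL)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
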