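#' Read a month of daily pollutant concentrations from CSV
#'
#' The expected dialect is comma-separated with dot decimals and ISO dates,
#' with header columns `date, PM2.5, PM10, SO2, CO, NO2, O3`. CO is in
#' mg/m3, all other pollutants in ug/m3. Every value is validated:
#' missing columns, unparseable numbers, negative concentrations and
#' duplicate dates are reported with row/column context.
#'
#' @param path CSV file path.
#' @return A `data.frame` (class `month_table`) with a `Date` column `date`
#'   and the six numeric pollutant columns.
#' @examples
#' nov <- read_daily_csv(system.file("extdata", "shenyang_nov2016.csv",
#'                                   package = "aircloud"))
#' head(nov)
#' @export
read_daily_csv <- function(path) {
  if (!file.exists(path))
    stop(sprintf("file not found: %s", path), call. = FALSE)
  raw <- utils::read.csv(path, check.names = FALSE,
                         colClasses = "character")
  missing <- setdiff(c("date", AIR_INDICATORS), names(raw))
  if (length(missing) > 0L)
    stop(sprintf("missing column(s): %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  if (nrow(raw) == 0L) stop("no data rows", call. = FALSE)

  date <- as.Date(raw$date, format = "%Y-%m-%d")
  if (anyNA(date))
    stop(sprintf("unparseable date(s): %s",
                 paste(raw$date[is.na(date)], collapse = ", ")),
         call. = FALSE)
  if (anyDuplicated(date))
    stop(sprintf("duplicate date(s): %s",
                 paste(unique(date[duplicated(date)]), collapse = ", ")),
         call. = FALSE)

  out <- data.frame(date = date)
  for (ind in AIR_INDICATORS) {
    v <- suppressWarnings(as.numeric(raw[[ind]]))
    bad <- which(is.na(v) | !is.finite(v))
    if (length(bad) > 0L)
      stop(sprintf("column %s: unparseable value '%s' on %s",
                   ind, raw[[ind]][bad[1]], date[bad[1]]), call. = FALSE)
    neg <- which(v < 0)
    if (length(neg) > 0L)
      stop(sprintf("column %s: negative concentration %g on %s",
                   ind, v[neg[1]], date[neg[1]]), call. = FALSE)
    out[[ind]] <- v
  }
  class(out) <- c("month_table", "data.frame")
  out
}

#' Write a month table back to CSV
#'
#' Inverse of [read_daily_csv()]; the round trip is lossless.
#'
#' @param records A month table.
#' @param path Output CSV path.
#' @export
write_daily_csv <- function(records, path) {
  stopifnot(is.data.frame(records))
  utils::write.csv(as.data.frame(records), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Packaged daily monitoring data: Shenyang, November 2016
#'
#' Thirty days of daily-average concentrations of the six criteria
#' pollutants observed in Shenyang (Liaoning, China) in November 2016, the
#' worked example used throughout the package documentation.
#'
#' @return A month table (see [read_daily_csv()]).
#' @export
shenyang_nov2016 <- function() {
  read_daily_csv(system.file("extdata", "shenyang_nov2016.csv",
                             package = "aircloud", mustWork = TRUE))
}

#' Packaged monthly cloud characteristics: Shenyang, Nov 2016 - Oct 2017
#'
#' Published monthly (Ex, En, He) cloud characteristics and assessed levels
#' for the six pollutants over twelve consecutive months in Shenyang. The
#' raw daily series behind months after November 2016 are not
#' redistributed; these summaries support level-trajectory analysis via
#' [assess_series()] and serve as classification fixtures.
#'
#' @return A `data.frame` with columns `month` (yyyy-mm), `indicator`,
#'   `ex`, `en`, `he`, `level`.
#' @export
shenyang_monthly_clouds <- function() {
  path <- system.file("extdata", "shenyang_monthly_clouds.csv",
                      package = "aircloud", mustWork = TRUE)
  utils::read.csv(path, check.names = FALSE)
}

#' Specification for the synthetic daily-concentration generator
#'
#' Describes, per indicator, a log-normal daily-concentration process with
#' a seasonally modulated median: on day `t` of month `m`,
#' `x ~ Lognormal(log(baseline) + amplitude * cos(2*pi*(m - phase)/12),
#' spread^2)`. `phase` is the peak month (1 = January), so winter-peaking
#' pollutants use phase 1 and the summer-peaking O3 phase 7. The defaults
#' emulate a mid-size northern Chinese industrial city with coal-fired
#' winter heating: elevated PM2.5, SO2 and NO2 in winter, elevated O3 in
#' summer, and roughly season-flat PM10 and CO.
#'
#' @param baseline Named vector of median concentrations (CO in mg/m3,
#'   others ug/m3), all positive.
#' @param spread Named vector of log-scale standard deviations, >= 0.
#' @param amplitude Named vector of seasonal log-amplitudes, >= 0.
#' @param phase Named vector of peak months (1-12).
#' @return A `synthetic_spec` object.
#' @export
synthetic_spec <- function(
    baseline = c(`PM2.5` = 55, PM10 = 95, SO2 = 40, CO = 1.0,
                 NO2 = 42, O3 = 75),
    spread = c(`PM2.5` = 0.50, PM10 = 0.45, SO2 = 0.40, CO = 0.35,
               NO2 = 0.25, O3 = 0.30),
    amplitude = c(`PM2.5` = 0.45, PM10 = 0, SO2 = 0.80, CO = 0,
                  NO2 = 0.30, O3 = 0.55),
    phase = c(`PM2.5` = 1, PM10 = 1, SO2 = 1, CO = 1, NO2 = 1, O3 = 7)) {
  for (v in list(baseline = baseline, spread = spread,
                 amplitude = amplitude, phase = phase)) {
    if (!all(AIR_INDICATORS %in% names(v)))
      stop("synthetic spec fields must name all six indicators",
           call. = FALSE)
    if (!all(is.finite(v[AIR_INDICATORS])))
      stop("synthetic spec fields must be finite", call. = FALSE)
  }
  if (any(baseline[AIR_INDICATORS] <= 0))
    stop("baselines must be positive", call. = FALSE)
  if (any(spread[AIR_INDICATORS] < 0) || any(amplitude[AIR_INDICATORS] < 0))
    stop("spread and amplitude must be >= 0", call. = FALSE)
  structure(list(baseline = baseline[AIR_INDICATORS],
                 spread = spread[AIR_INDICATORS],
                 amplitude = amplitude[AIR_INDICATORS],
                 phase = phase[AIR_INDICATORS]),
            class = "synthetic_spec")
}

#' Generate one synthetic month of daily concentrations
#'
#' @param spec A [synthetic_spec()].
#' @param year,month Calendar year and month (1-12); the number of days is
#'   taken from the calendar.
#' @param seed Integer seed; generation is bit-identical given the seed.
#' @return A month table (see [read_daily_csv()]).
#' @examples
#' jan <- generate_synthetic_month(synthetic_spec(), 2017, 1, seed = 7)
#' backward_cloud(jan$`PM2.5`)
#' @export
generate_synthetic_month <- function(spec = synthetic_spec(), year, month,
                                     seed = 1L) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (!is.numeric(month) || month < 1 || month > 12)
    stop("`month` must be in 1..12", call. = FALSE)
  first <- as.Date(sprintf("%04d-%02d-01", year, month))
  ndays <- as.integer(format(seq(first, by = "month", length.out = 2)[2] - 1,
                             "%d"))
  gen <- function() {
    out <- data.frame(date = seq(first, by = "day", length.out = ndays))
    for (ind in AIR_INDICATORS) {
      mu <- log(spec$baseline[[ind]]) + spec$amplitude[[ind]] *
        cos(2 * pi * (month - spec$phase[[ind]]) / 12)
      out[[ind]] <- stats::rlnorm(ndays, meanlog = mu,
                                  sdlog = spec$spread[[ind]])
    }
    out
  }
  out <- with_seed(seed, gen())
  class(out) <- c("month_table", "data.frame")
  out
}

#' Render an assessed cloud against its standard clouds
#'
#' Draws the forward-generated drops (x, membership) of the five standard
#' clouds of one indicator and overlays the assessed cloud's drops, the
#' visual counterpart of the quantitative classification. Because
#' concentrations are physically non-negative, the horizontal axis starts
#' at 0 even when the assessed cloud's entropy pushes sampled drops below
#' zero.
#'
#' @param assessed A [cloud_model()] estimated from data.
#' @param standards A list of standard [cloud_model()]s ordered by level
#'   (see [standard_clouds_for()]).
#' @param path Output image path (`.png` or `.svg` by extension).
#' @param n_drops Drops per cloud.
#' @param seed Integer seed for the forward generator.
#' @param main Plot title.
#' @param xlab Horizontal axis label.
#' @return Invisibly, `path`.
#' @export
render_cloud_picture <- function(assessed, standards, path,
                                 n_drops = 1000, seed = 1L,
                                 main = "Cloud model assessment",
                                 xlab = "concentration") {
  assert_cloud_model(assessed, "assessed")
  if (n_drops < 1) stop("`n_drops` must be >= 1", call. = FALSE)
  dev <- switch(tolower(tools::file_ext(path)),
                png = function(p) grDevices::png(p, width = 900,
                                                 height = 520),
                svg = function(p) grDevices::svg(p, width = 9, height = 5.2),
                stop("unsupported image format; use .png or .svg",
                     call. = FALSE))
  palette <- c("forestgreen", "gold2", "darkorange", "red2", "hotpink3")
  samples <- lapply(seq_along(standards), function(i)
    forward_cloud(standards[[i]], n_drops, seed = seed + i))
  adrops <- forward_cloud(assessed, n_drops, seed = seed)
  xmax <- max(vapply(samples, function(s) max(s$x), numeric(1)),
              max(adrops$x))
  dev(path)
  on.exit(grDevices::dev.off())
  graphics::plot(NULL, xlim = c(0, xmax), ylim = c(0, 1),
                 xlab = xlab, ylab = "membership degree", main = main)
  for (i in seq_along(samples)) {
    keep <- samples[[i]]$x >= 0
    graphics::points(samples[[i]]$x[keep], samples[[i]]$mu[keep],
                     pch = 16, cex = 0.25, col = palette[i])
  }
  keep <- adrops$x >= 0
  graphics::points(adrops$x[keep], adrops$mu[keep], pch = 16, cex = 0.25,
                   col = "blue")
  labels <- names(standards)
  if (is.null(labels)) labels <- paste("level", seq_along(standards))
  graphics::legend("topright", legend = c(labels, "assessed"),
                   col = c(palette[seq_along(standards)], "blue"),
                   pch = 16, cex = 0.8, bg = "white")
  invisible(path)
}
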