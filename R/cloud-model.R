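#' Normal cloud model
#'
#' A cloud model represents a qualitative concept (such as "Moderate air
#' pollution") by three numerical characteristics: the expectation `Ex`
#' (the most representative value of the concept), the entropy `En` (the
#' spread of values the concept accepts, measuring its fuzziness), and the
#' hyper-entropy `He` (the uncertainty of the entropy itself, which controls
#' the thickness of the rendered cloud). All three are expressed in the unit
#' of the underlying indicator (micrograms or milligrams per cubic metre for
#' pollutant concentrations, index points for the AQI scale).
#'
#' @param ex Expectation, the centre value of the concept.
#' @param en Entropy, must be non-negative.
#' @param he Hyper-entropy, must be non-negative.
#' @return An object of class `cloud_model` with fields `ex`, `en`, `he`.
#' @examples
#' cloud_model(25, 8.33, 0.83)
#' @export
cloud_model <- function(ex, en, he) {
  for (v in list(ex = ex, en = en, he = he)) {
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("cloud model characteristics must be single finite numbers",
           call. = FALSE)
  }
  if (en < 0) stop("entropy `en` must be >= 0", call. = FALSE)
  if (he < 0) stop("hyper-entropy `he` must be >= 0", call. = FALSE)
  structure(list(ex = as.numeric(ex), en = as.numeric(en),
                 he = as.numeric(he)),
            class = "cloud_model")
}

#' @export
print.cloud_model <- function(x, digits = 4, ...) {
  cat(sprintf("<cloud model> (Ex = %s, En = %s, He = %s)\n",
              format(x$ex, digits = digits),
              format(x$en, digits = digits),
              format(x$he, digits = digits)))
  invisible(x)
}

#' @export
format.cloud_model <- function(x, digits = 4, ...) {
  sprintf("(%s, %s, %s)", format(x$ex, digits = digits),
          format(x$en, digits = digits), format(x$he, digits = digits))
}

is_cloud_model <- function(x) inherits(x, "cloud_model")

assert_cloud_model <- function(x, arg = "model") {
  if (!is_cloud_model(x))
    stop(sprintf("`%s` must be a cloud_model object", arg), call. = FALSE)
  invisible(x)
}

#' Gaussian membership of a value in a cloud
#'
#' The membership degree of a quantitative value `x` in the concept
#' described by `model`, evaluated with a specific entropy draw `en_prime`:
#' `mu = exp(-(x - Ex)^2 / (2 * en_prime^2))`. Within the forward cloud
#' generator `en_prime` varies from drop to drop, which is what makes the
#' membership of a fixed `x` a distribution rather than a single number.
#'
#' @param model A [cloud_model()].
#' @param x Quantitative value(s), in the indicator's unit.
#' @param en_prime Entropy draw, strictly positive scalar (or vector
#'   matching `x`).
#' @return Membership degree(s) in (0, 1].
#' @examples
#' cloud_membership(cloud_model(50, 10, 0), x = 70, en_prime = 10) # exp(-2)
#' @export
cloud_membership <- function(model, x, en_prime) {
  assert_cloud_model(model)
  if (!is.numeric(x) || !all(is.finite(x)))
    stop("`x` must be finite numeric", call. = FALSE)
  if (!is.numeric(en_prime) || !all(is.finite(en_prime)) || any(en_prime <= 0))
    stop("`en_prime` must be strictly positive", call. = FALSE)
  exp(-(x - model$ex)^2 / (2 * en_prime^2))
}

#' Forward cloud generator
#'
#' Produces `n` cloud drops from a cloud model by two-stage normal sampling:
#' for each drop an entropy draw `En'` is taken from N(En, He^2), the drop
#' value `x` from N(Ex, En'^2), and the membership from the Gaussian kernel
#' with that drop's own `En'`. Entropy draws that come out non-positive
#' (possible whenever `He > 0`) are rejected and redrawn; the number of
#' rejections is recorded in the `resample_count` attribute so heavy
#' truncation is visible to the caller.
#'
#' A model with `en == 0` describes a crisp constant; it yields a flagged
#' degenerate sample with every drop at `Ex` and membership 1 rather than an
#' error, since constant monitoring data is legal downstream.
#'
#' @param model A [cloud_model()].
#' @param n Number of drops, at least 1.
#' @param seed Integer seed; the sample is reproducible given the seed.
#' @return A `data.frame` of class `cloud_drops` with columns `x`,
#'   `en_prime`, `mu` and attributes `model`, `seed`, `resample_count`,
#'   `degenerate`.
#' @examples
#' drops <- forward_cloud(cloud_model(25, 3, 0.3), n = 1000, seed = 42)
#' mean(drops$x)
#' @export
forward_cloud <- function(model, n, seed = NULL) {
  assert_cloud_model(model)
  if (!is.numeric(n) || length(n) != 1L || !is.finite(n) || n < 1)
    stop("`n` must be a count >= 1", call. = FALSE)
  n <- as.integer(n)

  if (model$en == 0) {
    drops <- data.frame(x = rep(model$ex, n),
                        en_prime = rep(NA_real_, n),
                        mu = rep(1, n))
    return(structure(drops, class = c("cloud_drops", "data.frame"),
                     model = model, seed = seed,
                     resample_count = 0L, degenerate = TRUE))
  }

  run <- function() {
    en_prime <- stats::rnorm(n, mean = model$en, sd = model$he)
    resamples <- 0L
    bad <- which(en_prime <= 0)
    while (length(bad) > 0L) {
      resamples <- resamples + length(bad)
      en_prime[bad] <- stats::rnorm(length(bad), mean = model$en,
                                    sd = model$he)
      bad <- bad[en_prime[bad] <= 0]
    }
    x <- stats::rnorm(n, mean = model$ex, sd = en_prime)
    list(x = x, en_prime = en_prime, resamples = resamples)
  }
  s <- if (is.null(seed)) run() else with_seed(seed, run())

  drops <- data.frame(x = s$x, en_prime = s$en_prime,
                      mu = cloud_membership(model, s$x, s$en_prime))
  structure(drops, class = c("cloud_drops", "data.frame"),
            model = model, seed = seed,
            resample_count = s$resamples, degenerate = FALSE)
}

#' Backward cloud generator (moment estimator)
#'
#' Recovers the three numerical characteristics of a cloud from observed
#' values:
#' \itemize{
#'   \item `Ex` is the sample mean;
#'   \item `En = sqrt(pi/2) * mean(|x - Ex|)`, the first-order absolute
#'     central moment scaled to the normal law;
#'   \item `He = sqrt(|S2 - En^2|)` where `S2` is the sample variance with
#'     divisor `n - 1`.
#' }
#' The absolute value guards against sampling fluctuation making
#' `S2 - En^2` negative; when that clip fires, the returned model carries
#' attribute `variance_clipped = TRUE`.
#'
#' @param values Numeric vector of at least 2 finite observations.
#' @return A [cloud_model()] with attribute `variance_clipped`.
#' @examples
#' backward_cloud(c(0, 2)) # (1, sqrt(pi/2), sqrt(|2 - pi/2|))
#' @export
backward_cloud <- function(values) {
  if (!is.numeric(values) || length(values) < 2L)
    stop("backward cloud estimation needs at least 2 numeric values",
         call. = FALSE)
  if (!all(is.finite(values)))
    stop("backward cloud estimation requires finite values", call. = FALSE)
  ex <- mean(values)
  en <- sqrt(pi / 2) * mean(abs(values - ex))
  s2 <- stats::var(values)
  diff <- s2 - en^2
  he <- sqrt(abs(diff))
  out <- cloud_model(ex, en, he)
  attr(out, "variance_clipped") <- diff < 0
  out
}

#' Similarity between an assessed cloud and a standard cloud
#'
#' The similarity used for level classification compares only the assessed
#' expectation against a standard cloud's expectation and entropy:
#' `lambda = exp(-(Ex - Ex_j)^2 / (2 * En_j^2))`. It equals 1 exactly when
#' the expectations coincide and decays with the squared distance measured
#' in units of the standard cloud's entropy.
#'
#' @param assessed A [cloud_model()] estimated from data.
#' @param standard A standard [cloud_model()] of one grading level; its
#'   entropy must be strictly positive.
#' @return The similarity, a number in (0, 1].
#' @export
cloud_similarity <- function(assessed, standard) {
  assert_cloud_model(assessed, "assessed")
  assert_cloud_model(standard, "standard")
  if (standard$en <= 0)
    stop("standard cloud has zero entropy; similarity is undefined",
         call. = FALSE)
  exp(-(assessed$ex - standard$ex)^2 / (2 * standard$en^2))
}

#' Classify a cloud against ordered standard clouds
#'
#' Applies the maximum membership principle: the similarity of the assessed
#' cloud to each level's standard cloud is computed, and the level attaining
#' the maximum similarity is the quantitative assessment result. Exact ties
#' are broken toward the more severe (higher) level, the protective choice
#' for health-advisory reporting.
#'
#' @param assessed A [cloud_model()] estimated from data.
#' @param standards A list of [cloud_model()] objects ordered by increasing
#'   severity (level 1 first); optionally named with level labels.
#' @return An object of class `cloud_classification`: a list with `lambda`
#'   (the full similarity vector), `best_level` (index of the maximum) and
#'   `labels`.
#' @export
classify_cloud <- function(assessed, standards) {
  assert_cloud_model(assessed, "assessed")
  if (!is.list(standards) || length(standards) == 0L)
    stop("`standards` must be a non-empty list of cloud models",
         call. = FALSE)
  lambda <- vapply(standards, function(s) cloud_similarity(assessed, s),
                   numeric(1))
  best <- max(which(lambda == max(lambda)))  # ties -> more severe level
  structure(list(lambda = lambda,
                 best_level = best,
                 labels = names(standards)),
            class = "cloud_classification")
}

#' @export
print.cloud_classification <- function(x, ...) {
  lab <- if (is.null(x$labels)) paste("level", seq_along(x$lambda)) else x$labels
  cat("<cloud classification>\n")
  for (i in seq_along(x$lambda)) {
    marker <- if (i == x$best_level) " <- assigned" else ""
    cat(sprintf("  %-20s lambda = %.4g%s\n", lab[i], x$lambda[i], marker))
  }
  invisible(x)
}

# Evaluate `code` under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG state afterwards.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("`seed` must be a single integer", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed) %% .Machine$integer.max)
  force(code)
}
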