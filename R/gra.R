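#' Grey relational analysis of pollution levels
#'
#' Grey relational analysis (GRA) serves here as an independent classifier
#' used to cross-check the cloud-model levels. The monitoring vector `a`
#' holds one expectation per indicator (the monthly mean, i.e. the backward
#' cloud's `Ex`); the limiting matrix `b` holds the level expectations of
#' the standard clouds, one row per level and one column per indicator.
#' Both are made dimensionless by dividing each column by its level-1
#' entry, relational coefficients are computed with resolution coefficient
#' `rho`, and each indicator is assigned the level whose coefficient is
#' largest.
#'
#' @param a Numeric monitoring vector, one entry per indicator; names are
#'   carried through to the result.
#' @param b Numeric limiting matrix, levels x indicators; its first row
#'   must be strictly positive (it is the divisor of the dimensionless
#'   transform).
#' @param rho Resolution coefficient in (0, 1]; 0.5 by convention.
#' @return An object of class `grey_assessment`: a list with the
#'   dimensionless `d` and `f`, coefficient matrix `xi`, degrees `r`
#'   (per-indicator maximum of `xi`), `levels` (argmax row per column) and
#'   the `rho` used.
#' @examples
#' scs <- build_standard_clouds(default_grading_table())
#' b <- gra_limit_matrix(scs)
#' gra_assess(c(`PM2.5` = 73.5, PM10 = 108.45, SO2 = 71.33,
#'              CO = 1.01, NO2 = 48.46, O3 = 57.9), b)
#' @export
gra_assess <- function(a, b, rho = 0.5) {
  df <- gra_dimensionless(a, b)
  xi <- gra_coefficients(df$d, df$f, rho)
  dl <- gra_levels(xi)
  structure(list(d = df$d, f = df$f, xi = xi,
                 r = dl$r, levels = dl$levels, rho = rho),
            class = "grey_assessment")
}

#' @export
print.grey_assessment <- function(x, ...) {
  cat(sprintf("<grey relational assessment> rho = %g\n", x$rho))
  print(data.frame(indicator = names(x$levels), d = round(x$d, 3),
                   r = round(x$r, 3), level = x$levels,
                   row.names = NULL))
  invisible(x)
}

#' Dimensionless transform of GRA inputs
#'
#' Divides the monitoring vector and every row of the limiting matrix by
#' the matrix's first row, so that indicators with different units become
#' comparable. The transformed limiting matrix has a first row of ones.
#'
#' @inheritParams gra_assess
#' @return A list with vector `d` and matrix `f`.
#' @export
gra_dimensionless <- function(a, b) {
  b <- as.matrix(b)
  if (!is.numeric(a) || !is.numeric(b))
    stop("GRA inputs must be numeric", call. = FALSE)
  if (length(a) != ncol(b))
    stop(sprintf("monitoring vector has %d entries but limit matrix %d columns",
                 length(a), ncol(b)), call. = FALSE)
  bad <- which(b[1, ] <= 0)
  if (length(bad) > 0L) {
    nm <- colnames(b)[bad]
    if (is.null(nm)) nm <- as.character(bad)
    stop(sprintf("level-1 limits must be positive to normalise (%s)",
                 paste(nm, collapse = ", ")), call. = FALSE)
  }
  d <- a / b[1, ]
  f <- sweep(b, 2, b[1, ], "/")
  list(d = d, f = f)
}

#' Grey relational coefficient matrix
#'
#' `xi_ij = (Dmin + rho * Dmax) / (|d_j - f_ij| + rho * Dmax)` where `Dmin`
#' and `Dmax` are the minimum and maximum of `|d_j - f_ij|` over the whole
#' matrix. The cell attaining the global minimum distance has `xi = 1`
#' exactly. If every distance is zero the matrix is degenerate: all `xi`
#' are set to 1 and the result carries attribute `degenerate = TRUE`.
#'
#' @param d Dimensionless monitoring vector.
#' @param f Dimensionless limiting matrix (levels x indicators).
#' @inheritParams gra_assess
#' @return The coefficient matrix, entries in (0, 1].
#' @export
gra_coefficients <- function(d, f, rho = 0.5) {
  f <- as.matrix(f)
  if (length(d) != ncol(f))
    stop("`d` length must match the number of columns of `f`", call. = FALSE)
  if (!is.numeric(rho) || length(rho) != 1L || rho <= 0 || rho > 1)
    stop("`rho` must lie in (0, 1]", call. = FALSE)
  delta <- abs(sweep(f, 2, d, function(fij, dj) fij - dj))
  dmin <- min(delta)
  dmax <- max(delta)
  if (dmax == 0) {
    xi <- matrix(1, nrow(f), ncol(f), dimnames = dimnames(f))
    attr(xi, "degenerate") <- TRUE
    return(xi)
  }
  xi <- (dmin + rho * dmax) / (delta + rho * dmax)
  dimnames(xi) <- dimnames(f)
  attr(xi, "degenerate") <- FALSE
  xi
}

#' Grey relational degree and level per indicator
#'
#' The degree of indicator `j` is `r_j = max_i xi_ij`; the level attaining
#' it is the indicator's GRA level. Ties go to the more severe level,
#' matching the cloud classifier's rule.
#'
#' @param xi Coefficient matrix from [gra_coefficients()].
#' @return A list with numeric vector `r` and integer vector `levels`.
#' @export
gra_levels <- function(xi) {
  xi <- as.matrix(xi)
  if (nrow(xi) == 0L || ncol(xi) == 0L)
    stop("empty coefficient matrix", call. = FALSE)
  r <- apply(xi, 2, max)
  levels <- apply(xi, 2, function(col) max(which(col == max(col))))
  list(r = r, levels = levels)
}

#' Limiting matrix from a standard cloud set
#'
#' Assembles the GRA limiting matrix `b` from the standard-cloud
#' expectations: entry `(i, j)` is the level-`i` expectation of indicator
#' `j`.
#'
#' @param set A `standard_cloud_set` from [build_standard_clouds()].
#' @param indicators Indicator columns, in order; defaults to the six
#'   pollutants.
#' @return A numeric matrix, levels x indicators, with dimnames.
#' @export
gra_limit_matrix <- function(set, indicators = AIR_INDICATORS) {
  stopifnot(inherits(set, "standard_cloud_set"))
  cols <- lapply(indicators, function(ind) {
    rows <- set[set$indicator == ind, , drop = FALSE]
    rows$ex[order(rows$level)]
  })
  b <- do.call(cbind, cols)
  dimnames(b) <- list(set$label[set$indicator == indicators[1]][
    order(set$level[set$indicator == indicators[1]])], indicators)
  b
}
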