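test_that("the dimensionless transform divides by the level-1 limits", {
  b <- gra_limit_matrix(std_set)
  a <- setNames(as.numeric(b[1, ]), colnames(b))
  df <- gra_dimensionless(a, b)
  expect_equal(unname(df$d), rep(1, 6))
  expect_equal(unname(df$f[1, ]), rep(1, 6))
  bad <- b; bad[1, 2] <- 0
  expect_error(gra_dimensionless(a, bad), "PM10")
  expect_error(gra_dimensionless(a[1:3], b), "3 entries")
})

test_that("relational coefficients match hand evaluation and bounds", {
  # toy: d = 1, limits 1 and 3 -> distances 0 and 2; xi = (0+1)/(0+1), (0+1)/(2+1)
  xi <- gra_coefficients(1, matrix(c(1, 3), ncol = 1), rho = 0.5)
  expect_equal(as.numeric(xi), c(1, 1 / 3))
  expect_equal(gra_levels(xi)$levels, 1)
  # global-argmin cell is exactly 1 for arbitrary random inputs
  set.seed(11)
  for (i in 1:20) {
    d <- runif(4, 0, 5)
    f <- matrix(runif(20, 0, 5), 5, 4)
    xi <- gra_coefficients(d, f, rho = runif(1, 0.1, 1))
    expect_true(all(xi > 0 & xi <= 1))
    delta <- abs(sweep(f, 2, d))
    expect_equal(xi[which.min(delta)], 1)
  }
  # increasing rho weakly increases every coefficient off the argmin cell
  d <- c(1, 2); f <- matrix(c(1, 4, 2.5, 0.5), 2, 2)
  lo <- gra_coefficients(d, f, rho = 0.3)
  hi <- gra_coefficients(d, f, rho = 0.9)
  expect_true(all(hi - lo >= -1e-12))
  # all-zero distances degenerate to xi = 1, flagged
  deg <- gra_coefficients(c(1, 1), matrix(1, 2, 2), 0.5)
  expect_true(all(deg == 1))
  expect_true(attr(deg, "degenerate"))
  expect_error(gra_coefficients(1, matrix(1, 1, 1), rho = 0), "rho")
})

test_that("GRA is invariant to per-indicator rescaling of raw inputs", {
  b <- gra_limit_matrix(std_set)
  a <- setNames(c(73.5, 108.45, 71.33, 1.01, 48.46, 57.9), colnames(b))
  base <- gra_assess(a, b)
  scale <- c(1000, 0.5, 2, 10, 1, 3.7)
  scaled <- gra_assess(a * scale, sweep(b, 2, scale, "*"))
  expect_equal(scaled$xi, base$xi)
  expect_equal(scaled$levels, base$levels)
})

test_that("the November expectations yield the published GRA pattern", {
  res <- assess_month(nov2016)
  # dimensionless monitoring vector, published to two decimals
  expect_equal(unname(round(res$gra$d, 2)),
               c(4.20, 4.34, 2.85, 1.01, 2.42, 1.16))
  # per-indicator argmax rows
  expect_equal(unname(res$gra$levels), c(2, 2, 2, 1, 2, 1))
  expect_equal(unname(res$gra$r), unname(apply(res$gra$xi, 2, max)))
  # degrees sit on the assigned rows
  for (j in seq_along(res$gra$levels))
    expect_equal(unname(res$gra$r[j]), res$gra$xi[res$gra$levels[j], j])
})

test_that("level ties break toward the more severe level", {
  xi <- matrix(c(0.4, 0.9, 0.9, 0.5), 2, 2)
  expect_equal(gra_levels(xi)$levels, c(2, 1))
})
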