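test_that("cloud model construction validates its characteristics", {
  m <- cloud_model(25, 8.33, 0.83)
  expect_s3_class(m, "cloud_model")
  expect_equal(m$ex, 25)
  expect_error(cloud_model(NaN, 1, 0.1), "finite")
  expect_error(cloud_model(Inf, 1, 0.1), "finite")
  expect_error(cloud_model(10, -1, 0.1), "entropy")
  expect_error(cloud_model(10, 1, -0.1), "hyper-entropy")
})

test_that("membership follows the Gaussian kernel", {
  # at the expectation the membership is exactly 1
  expect_equal(cloud_membership(cloud_model(25, 8.33, 0.83), 25, 8.33), 1)
  # a two-entropy offset gives exp(-2) in closed form
  expect_equal(cloud_membership(cloud_model(50, 10, 0), 70, 10), exp(-2))
  # far-tail value, frozen from independent evaluation of the exponential
  expect_equal(cloud_membership(cloud_model(55, 6.67, 0.67), 100, 6.67),
               1.306517e-10, tolerance = 1e-4)
  expect_error(cloud_membership(cloud_model(50, 10, 0), 70, 0), "positive")
  expect_error(cloud_membership(cloud_model(50, 10, 0), 70, -1), "positive")
})

test_that("generated drops are internally consistent and seeded", {
  m <- cloud_model(25, 3, 0.3)
  drops <- forward_cloud(m, n = 1000, seed = 42)
  expect_equal(nrow(drops), 1000)
  expect_equal(drops$mu, exp(-(drops$x - 25)^2 / (2 * drops$en_prime^2)))
  expect_true(all(drops$mu > 0 & drops$mu <= 1))
  expect_true(all(drops$en_prime > 0))
  # sample mean within 3 standard errors of the expectation
  expect_lt(abs(mean(drops$x) - 25), 3 * 3 / sqrt(1000))
  # identical seed, identical sample; different seed, different sample
  expect_identical(drops$x, forward_cloud(m, 1000, seed = 42)$x)
  expect_false(identical(drops$x, forward_cloud(m, 1000, seed = 43)$x))
  # generation does not disturb the caller's RNG stream
  set.seed(99); before <- rnorm(1)
  set.seed(99); invisible(forward_cloud(m, 10, seed = 7))
  expect_identical(rnorm(1), before)
  expect_error(forward_cloud(m, 0), ">= 1")
})

test_that("zero-entropy models yield flagged degenerate samples", {
  drops <- forward_cloud(cloud_model(7, 0, 0), n = 50, seed = 1)
  expect_true(attr(drops, "degenerate"))
  expect_true(all(drops$x == 7))
  expect_true(all(drops$mu == 1))
})

test_that("backward estimation matches hand-computed moments", {
  # {0, 2}: mean 1, MAD 1 -> En = sqrt(pi/2); S2 = 2 -> He = sqrt(2 - pi/2)
  m <- backward_cloud(c(0, 2))
  expect_equal(m$ex, 1)
  expect_equal(m$en, sqrt(pi / 2))
  expect_equal(m$he, sqrt(abs(2 - pi / 2)))
  # constant input collapses to a crisp concept, with the clip flagged
  m0 <- backward_cloud(c(4, 4, 4))
  expect_equal(c(m0$ex, m0$en, m0$he), c(4, 0, 0))
  expect_error(backward_cloud(5), "at least 2")
  expect_error(backward_cloud(c(1, NA)), "finite")
})

test_that("backward estimation is permutation-invariant and translation-equivariant", {
  set.seed(7)
  x <- rlnorm(40, 3, 0.5)
  a <- backward_cloud(x)
  b <- backward_cloud(sample(x))
  expect_equal(unclass(a)[c("ex", "en", "he")],
               unclass(b)[c("ex", "en", "he")])
  shifted <- backward_cloud(x + 100)
  expect_equal(shifted$ex, a$ex + 100)
  expect_equal(shifted$en, a$en)
  expect_equal(shifted$he, a$he)
})

test_that("forward then backward generation recovers the characteristics", {
  m <- cloud_model(50, 10, 1)
  drops <- forward_cloud(m, n = 100000, seed = 20260925)
  est <- backward_cloud(drops$x)
  expect_lt(abs(est$ex - 50) / 50, 0.02)
  expect_lt(abs(est$en - 10) / 10, 0.02)
  expect_lt(abs(est$he - 1) / 1, 0.15)
})

test_that("similarity is 1 iff expectations coincide and decays with distance", {
  std <- cloud_model(75, 8.33, 0.83)
  expect_equal(cloud_similarity(cloud_model(75, 40, 20), std), 1)
  d <- sapply(c(0, 5, 10, 20, 40), function(off)
    cloud_similarity(cloud_model(75 + off, 1, 0), std))
  expect_true(all(diff(d) < 0))
  expect_true(all(d > 0 & d <= 1))
  # symmetric offsets give identical similarity
  expect_equal(cloud_similarity(cloud_model(70, 1, 0), std),
               cloud_similarity(cloud_model(80, 1, 0), std))
  expect_error(cloud_similarity(cloud_model(75, 1, 0),
                                cloud_model(75, 0, 0)), "zero entropy")
})

test_that("classification picks the maximum-similarity level, ties severe", {
  stds <- list(Good = cloud_model(25, 8.33, 0.83),
               Moderate = cloud_model(75, 8.33, 0.83),
               `Lightly Polluted` = cloud_model(125, 8.33, 0.83))
  cls <- classify_cloud(cloud_model(75, 30, 5), stds)
  expect_equal(cls$best_level, 2)
  expect_equal(max(cls$lambda), 1)
  # midpoint between two standards with equal entropy: exact tie -> severe
  tie <- classify_cloud(cloud_model(50, 10, 1), stds)
  expect_equal(unname(tie$lambda[1]), unname(tie$lambda[2]))
  expect_equal(tie$best_level, 2)
  # argmax is stable under rescaling of the lambda vector
  expect_equal(which.max(cls$lambda * 0.123), which.max(cls$lambda))
  expect_error(classify_cloud(cloud_model(1, 1, 0), list()), "non-empty")
})
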