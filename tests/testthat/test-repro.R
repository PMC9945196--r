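test_that("Pearson correlation has its closed forms and a definitional oracle", {
  x <- c(1, 2, 4, 4.5, 7, 9)
  expect_equal(pearsonR(x, 2 * x + 1), 1.0)
  expect_equal(pearsonR(x, -x), -1.0)

  set.seed(19)
  y <- 0.5 * x + rnorm(6)
  num <- sum((x - mean(x)) * (y - mean(y)))
  den <- sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pearsonR(x, y), num / den, tolerance = 1e-12)

  expect_error(pearsonR(c(1, 1, 1), c(1, 2, 3)), "undefined-correlation")
  expect_error(pearsonR(1, 2), "undefined-correlation")
})

test_that("ICC forms match the ANOVA oracle and order as expected under offset", {
  set.seed(23)
  x <- rnorm(12, 10, 2)
  y <- x + rnorm(12, 0, 0.3)
  for (form in c("A1", "C1")) {
    expect_equal(icc(x, y, form)$icc, oracleICC(x, y, form),
                 tolerance = 1e-10)
  }

  expect_equal(icc(x, x)$icc, 1.0)

  yOff <- x + 25
  a1 <- icc(x, yOff, "A1")$icc
  c1 <- icc(x, yOff, "C1")$icc
  expect_lt(a1, 0.2)
  expect_equal(c1, 1.0, tolerance = 1e-12)
  expect_lt(a1, c1)

  expect_warning(r <- icc(rep(2, 5), rep(2, 5)), "degenerate")
  expect_true(is.na(r$icc))
})

test_that("ICC of independent arms is near zero at n = 1000", {
  set.seed(101)
  x <- rnorm(1000)
  y <- rnorm(1000)
  v <- icc(x, y, "A1")$icc
  expect_gte(v, -0.1)
  expect_lte(v, 0.1)
})

test_that("ICC is invariant under a shared affine map; consistency also under shifts", {
  set.seed(29)
  x <- rnorm(15, 5, 1)
  y <- x + rnorm(15, 0, 0.4)
  same <- function(f) expect_equal(f(3 * x - 2, 3 * y - 2), f(x, y),
                                   tolerance = 1e-10)
  same(function(a, b) icc(a, b, "A1")$icc)
  same(function(a, b) icc(a, b, "C1")$icc)
  same(function(a, b) pearsonR(a, b))
  # per-arm shift: consistency unchanged, absolute agreement degraded
  expect_equal(icc(x, y + 7, "C1")$icc, icc(x, y, "C1")$icc,
               tolerance = 1e-10)
  expect_lt(icc(x, y + 7, "A1")$icc, icc(x, y, "A1")$icc)
})

test_that("paired t-test handles identity, shifts and degeneracy", {
  x <- rnorm(20, 3, 1)
  r0 <- pairedTTest(x, x)
  expect_equal(r0$t, 0)
  expect_equal(r0$p, 1)
  expect_true(r0$degenerate)

  set.seed(37)
  y <- x - 0.8 + rnorm(20, 0, 0.3)   # constant positive shift with jitter
  r <- pairedTTest(x, y)
  expect_lt(r$p, 0.05)
  expect_gt(r$t, 0)
  rSwap <- pairedTTest(y, x)
  expect_equal(rSwap$t, -r$t)

  # agrees with stats::t.test
  ref <- t.test(x, y, paired = TRUE)
  expect_equal(r$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(r$p, ref$p.value, tolerance = 1e-12)
})

test_that("reproducibility report behaves on identical arms and edge cases", {
  set.seed(43)
  lr <- data.frame(modulus = rnorm(8, 1600, 300), vbmd = rnorm(8, 1.16, 0.03))
  repSame <- reproReport(lr, lr)
  expect_equal(repSame$icc, c(1, 1))
  expect_equal(repSame$pearson_r, c(1, 1))

  empty <- reproReport(lr, lr, measures = character(0))
  expect_equal(nrow(empty), 0)

  hr <- lr
  hr$modulus[3] <- NA
  expect_warning(repNA <- reproReport(lr, hr), "dropped")
  expect_equal(repNA$n[repNA$measure == "modulus"], 7)
})
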