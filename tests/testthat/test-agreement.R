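test_that("normality test matches an independent reference implementation", {
  # frozen reference values computed with an independent implementation of
  # the same omnibus statistic on these exact samples
  normal50 <- c(0.304717, -1.039984, 0.750451, 0.940565, -1.951035,
                -1.30218, 0.12784, -0.316243, -0.016801, -0.853044,
                0.879398, 0.777792, 0.066031, 1.127241, 0.467509,
                -0.859292, 0.368751, -0.958883, 0.87845, -0.049926,
                -0.184862, -0.68093, 1.222541, -0.154529, -0.428328,
                -0.352134, 0.532309, 0.365444, 0.412733, 0.430821,
                2.141648, -0.406415, -0.512243, -0.813773, 0.615979,
                1.128972, -0.113947, -0.840156, -0.824481, 0.650593,
                0.743254, 0.543154, -0.66551, 0.232161, 0.116686,
                0.218689, 0.871429, 0.223596, 0.678914, 0.067579)
  expo40 <- c(0.167356, 1.315057, 3.995756, 0.563538, 0.28404, 0.397756,
              0.361342, 0.129634, 1.083325, 1.375849, 1.507809, 5.309883,
              2.10666, 1.644866, 1.043491, 0.592524, 0.044454, 0.956603,
              0.621383, 1.507961, 2.028002, 0.332069, 0.049751, 0.924822,
              2.553419, 0.821072, 2.130943, 0.753015, 1.313994, 0.288783,
              0.134417, 0.142481, 0.117682, 0.054673, 1.716593, 0.448615,
              0.386131, 0.934959, 0.187267, 1.918292)
  r1 <- dagostino_pearson(normal50)
  expect_equal(r1$statistic, 0.7077944750, tolerance = 1e-8)
  expect_equal(r1$p.value, 0.7019470975, tolerance = 1e-8)
  r2 <- dagostino_pearson(expo40)
  expect_equal(r2$statistic, 30.1027741600, tolerance = 1e-8)
  expect_equal(r2$p.value, 2.906e-7, tolerance = 1e-3)
  expect_error(dagostino_pearson(1:7), "at least 8")
  expect_error(dagostino_pearson(rep(1, 20)), "zero-variance")
})

test_that("Bland-Altman matches the hand-computed toy case", {
  a <- c(11, 22, 33); b <- c(10, 20, 30)   # differences 1, 2, 3
  r <- bland_altman(a, b)
  expect_equal(r$bias, 2)
  expect_equal(r$sd_diff, 1)
  expect_equal(r$loa_low, 2 - 1.96)
  expect_equal(r$loa_high, 2 + 1.96)
  expect_equal(r$n, 3L)
  expect_equal(r$means, (a + b) / 2)
})

test_that("Bland-Altman identities: antisymmetry, shift, degenerate cases", {
  set.seed(2)
  a <- rnorm(50, 100, 5); b <- a + rnorm(50, 1, 2)
  r_ab <- bland_altman(a, b); r_ba <- bland_altman(b, a)
  expect_equal(r_ab$bias, -r_ba$bias)
  expect_equal(r_ab$loa_low, -r_ba$loa_high)
  r_shift <- bland_altman(a + 7, b)
  expect_equal(r_shift$bias, r_ab$bias + 7)
  expect_equal(r_shift$sd_diff, r_ab$sd_diff)
  r_eq <- bland_altman(a, a)
  expect_equal(r_eq$bias, 0); expect_equal(r_eq$loa_low, 0)
  expect_error(bland_altman(1, 2), "at least 2")
  expect_error(bland_altman(1:3, 1:4), "equal length")
})

test_that("the paired test is gated on normality of the differences", {
  set.seed(31)
  a <- rnorm(200, 24, 2)
  r_norm <- paired_comparison(a, a + rnorm(200, 0, 0.5))
  expect_equal(r_norm$test, "paired t-test")
  # heavy-tailed shifted differences: Wilcoxon branch, clear signal
  d <- 0.8 + 0.1 * rt(247, df = 2)
  r_heavy <- paired_comparison(a[1] + cumsum(rep(0.1, 247)) + d,
                               a[1] + cumsum(rep(0.1, 247)))
  expect_equal(r_heavy$test, "Wilcoxon signed rank")
  expect_lt(r_heavy$p.value, 0.05)
  r_deg <- paired_comparison(a, a)
  expect_true(r_deg$degenerate)
  expect_equal(r_deg$p.value, 1)
})

test_that("the t branch is selected for most normal-difference replicates", {
  picks <- vapply(1:20, function(s) {
    set.seed(1000 + s)
    a <- rnorm(200, 24, 2)
    paired_comparison(a, a + rnorm(200, 0, 0.3))$test
  }, character(1))
  expect_gte(mean(picks == "paired t-test"), 0.9)
})
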