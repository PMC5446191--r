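test_that("the discrete power-law sampler is exact and reproducible", {
  s1 <- sample_discrete_powerlaw(2.0, 1, 100, n = 1000, seed = 5)
  s2 <- sample_discrete_powerlaw(2.0, 1, 100, n = 1000, seed = 5)
  expect_identical(s1, s2)
  expect_true(all(s1 >= 1 & s1 <= 100))
  # empirical mass at x = 1 matches the exact normalized value
  s <- sample_discrete_powerlaw(2.0, 1, 100, n = 2e5, seed = 6)
  exact <- 1 / sum((1:100)^-2)
  expect_equal(mean(s == 1), exact, tolerance = 0.005 / exact)
  # degenerate window
  expect_true(all(sample_discrete_powerlaw(1.5, 7, 7, n = 50, seed = 1) == 7))
})

test_that("the truncated MLE recovers a known exponent", {
  s <- sample_discrete_powerlaw(1.5, 1, 3000, n = 5e4, seed = 11)
  fit <- fit_truncated_powerlaw(s, 1, 3000)
  expect_equal(fit$exponent, 1.5, tolerance = 0.03 / 1.5)
  expect_false(fit$degenerate)
  expect_equal(fit$n_in_window, 5e4)
})

test_that("estimation error shrinks with sample size", {
  errs <- sapply(c(1e3, 1e4, 1e5), function(n) {
    s <- sample_discrete_powerlaw(1.8, 2, 2000, n = n, seed = 21)
    abs(fit_truncated_powerlaw(s, 2, 2000)$exponent - 1.8)
  })
  expect_lt(errs[3], errs[1])
  expect_lt(errs[3], 0.02)
})

test_that("the optimizer matches an exhaustive grid search", {
  grid_mle <- function(x, lo, hi) {
    xs <- x[x >= lo & x <= hi]
    alphas <- seq(1.01, 4, by = 1e-4)
    k <- lo:hi
    logz <- log(colSums(outer(k, alphas, function(k, a) k^(-a))))
    ll <- -alphas * sum(log(xs)) - length(xs) * logz
    alphas[which.max(ll)]
  }
  withr::with_seed(31, {
    for (rep in 1:20) {
      a_true <- runif(1, 1.2, 2.8)
      s <- sample_discrete_powerlaw(a_true, 1, 500, n = 2000, seed = rep)
      opt <- fit_truncated_powerlaw(s, 1, 500)$exponent
      grd <- grid_mle(s, 1, 500)
      expect_lt(abs(opt - grd), 1e-4 + 1e-8)
    }
  })
})

test_that("a pile-up at the lower cutoff is flagged degenerate", {
  fit <- fit_truncated_powerlaw(rep(5L, 100), 5, 50)
  expect_true(fit$degenerate)
})

test_that("too few in-window samples are rejected with the count", {
  expect_error(fit_truncated_powerlaw(c(1:20), 1, 20), "20 samples")
})

test_that("the cutoff likelihood reduces to the pure power law at beta 0", {
  s <- sample_discrete_powerlaw(1.6, 3, 400, n = 500, seed = 2)
  ll_cut <- expcutoff_loglik(s, 1.6, 0, 3, 400)
  ll_pl <- powerlaw_loglik(s, 1.6, 3, 400)
  expect_equal(ll_cut, ll_pl)
})

test_that("the joint cutoff fit recovers both parameters", {
  s <- sample_expcutoff(1.5, 0.01, 1, n = 5e4, seed = 41)
  fit <- fit_powerlaw_expcutoff(s, 1)
  expect_equal(fit$alpha_star, 1.5, tolerance = 0.10)
  expect_equal(fit$beta_star, 0.01, tolerance = 0.10)
  # against a brute-force 2-D grid around the optimum
  grid <- expand.grid(alpha = seq(1.3, 1.7, by = 0.02),
                      beta = seq(0.002, 0.03, by = 0.002))
  ll <- mapply(function(a, b) expcutoff_loglik(s, a, b, 1, fit$k_max),
               grid$alpha, grid$beta)
  best <- grid[which.max(ll), ]
  expect_lt(abs(fit$alpha_star - best$alpha), 0.03)
  expect_lt(abs(fit$beta_star - best$beta), 0.003)
})

test_that("pure power-law samples yield a vanishing cutoff rate", {
  s <- sample_discrete_powerlaw(1.7, 1, NULL, n = 2e4, seed = 51, x_cap = 1e5)
  fit <- fit_powerlaw_expcutoff(s, 1)
  expect_lt(fit$beta_star, 1e-3)
  # likelihood gain over the beta = 0 model is negligible
  ll0 <- expcutoff_loglik(s, fit$alpha_star, 0, 1, fit$k_max)
  expect_lt(fit$loglik - ll0, stats::qchisq(0.99, df = 1) / 2)
})

test_that("log-likelihood ratios carry the documented sign convention", {
  s_pl <- sample_discrete_powerlaw(1.5, 10, 1500, n = 2e4, seed = 61)
  cmp <- powerlaw_vs_exponential(s_pl, 10, 1500)
  expect_gt(cmp$R, 0)
  # exponential samples: the power law loses
  s_ex <- withr::with_seed(62, 10L + stats::rgeom(2e4, prob = 0.05))
  cmp2 <- powerlaw_vs_exponential(s_ex[s_ex <= 1500], 10, 1500)
  expect_lt(cmp2$R, 0)
  # identical models tie
  f <- fit_truncated_powerlaw(s_pl, 10, 1500)
  expect_equal(loglik_ratio(f, f), 0)
  # mismatched sample sets are rejected
  f2 <- fit_truncated_powerlaw(s_pl[1:10000], 10, 1500)
  expect_error(loglik_ratio(f, f2), "different sample counts")
})

test_that("exponential binning integrates to one and keeps slopes", {
  b1 <- exponential_binning(c(7))
  expect_equal(sum(b1$density * b1$width), 1)
  s <- sample_discrete_powerlaw(1.5, 1, 10000, n = 5e4, seed = 71)
  b <- exponential_binning(s, b_s = 0.1)
  expect_equal(sum(b$density * b$width), 1)
  expect_true(all(diff(b$center) > 0))
  slope_of <- function(bs) {
    bb <- exponential_binning(s, b_s = bs)
    bb <- bb[bb$count > 0 & bb$center >= 10 & bb$center <= 3000, ]
    unname(stats::coef(stats::lm(log10(density) ~ log10(center), data = bb))[2])
  }
  expect_equal(slope_of(0.1), slope_of(0.2), tolerance = 0.05)
  expect_error(exponential_binning(c(0.5, 2)), ">= 1")
})

test_that("the crackling prediction is the exponent ratio", {
  expect_equal(crackling_prediction(2, 1.5), 2)
  expect_equal(crackling_prediction(1.45, 1.28), 0.45 / 0.28)
  expect_equal(crackling_prediction(1.45, 1.28), 1.607, tolerance = 1e-3)
  expect_equal(crackling_prediction(1.7, 1.7), 1)
  expect_error(crackling_prediction(1.5, 1), "exceed 1")
})

test_that("mean size versus duration recovers exact scaling", {
  T <- rep(2:40, each = 5)
  S <- round(2 * T^1.5)
  set <- synthetic_avalanche_set(T, S)
  out <- mean_size_vs_duration(set, fit_window = c(2, 40))
  expect_equal(out$gamma, 1.5, tolerance = 0.01)
  expect_error(mean_size_vs_duration(synthetic_avalanche_set(rep(5, 10), 1:10),
                                     fit_window = c(2, 40)),
               "fewer than 2")
})

test_that("pooled fits agree with per-run fits on shared-law data", {
  runs <- lapply(1:4, function(k) {
    sample_discrete_powerlaw(1.4, 10, 1500, n = 1e4, seed = 80 + k)
  })
  per_run <- sapply(runs, function(s) fit_truncated_powerlaw(s, 10, 1500)$exponent)
  pooled <- fit_truncated_powerlaw(unlist(runs), 10, 1500)$exponent
  expect_equal(pooled, mean(per_run), tolerance = 0.02)
  expect_true(pooled >= min(per_run) - 0.01 && pooled <= max(per_run) + 0.01)
})
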