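test_that("two-point rate reproduces the hand-evaluated formula", {
  s <- density_series(c(0, 24), c(1000, 2000))
  expect_equal(two_point_rate(s), log(2) / 24)
  expect_equal(two_point_rate(density_series(c(0, 24), c(1500, 1500))), 0)
  # antisymmetry under swapping D0 and D1
  s_down <- density_series(c(0, 24), c(2000, 1000))
  expect_equal(two_point_rate(s_down), -log(2) / 24)
})

test_that("two-point rate refuses nonpositive densities loudly", {
  s <- density_series(c(0, 19, 26), c(1000, 0, 2000))
  expect_error(two_point_rate(s, 1, 2), "undefined rate")
  expect_error(two_point_rate(s, 3, 2), "i0 < i1")
})

test_that("easylinear is exact on noiseless exponential data", {
  tt <- c(0, 19, 26)
  fit <- easylinear_rate(density_series(tt, 1000 * exp(0.1 * tt)), h = 3)
  expect_equal(fit$mu, 0.1, tolerance = 1e-12)
  expect_equal(fit$window, c(1L, 3L))
  expect_equal(fit$r_squared, 1)
})

test_that("easylinear picks the steepest window, earliest on ties", {
  # slope 0.05 early, 0.12 late
  tt <- c(0, 10, 20, 30, 40, 50)
  y <- c(1000 * exp(0.05 * c(0, 10, 20)),
         1000 * exp(0.05 * 20) * exp(0.12 * c(10, 20, 30)))
  fit <- easylinear_rate(density_series(tt, y), h = 3)
  expect_equal(fit$mu, 0.12, tolerance = 1e-10)
  # windows starting at 3 and 4 tie at slope 0.12; the earlier one wins
  expect_equal(fit$window[1L], 3L)
  # flat series: zero slope, earliest window wins the tie
  flat <- easylinear_rate(density_series(tt, rep(500, 6)), h = 3)
  expect_equal(flat$mu, 0)
  expect_equal(flat$window, c(1L, 3L))
})

test_that("easylinear with h = n is one whole-series log-linear fit", {
  set.seed(1)
  tt <- 0:9
  y <- 800 * exp(0.08 * tt + rnorm(10, 0, 0.05))
  fit <- easylinear_rate(density_series(tt, y), h = 10)
  expect_equal(fit$mu, unname(coef(lm(log(y) ~ tt))[2L]), tolerance = 1e-12)
})

test_that("easylinear agrees with brute-force window enumeration", {
  set.seed(99)
  for (rep in 1:30) {
    n <- sample(4:12, 1)
    tt <- sort(runif(n, 0, 100))
    y <- 1000 * exp(runif(1, -0.05, 0.15) * tt + rnorm(n, 0, 0.3))
    h <- sample(2:min(4, n), 1)
    fit <- easylinear_rate(density_series(tt, y), h = h)
    orc <- oracle_easylinear(tt, y, h)
    expect_equal(fit$window[1L], orc$start)
    expect_equal(fit$mu, orc$mu, tolerance = 1e-10)
  }
})

test_that("two-point rate equals the winning easylinear slope at h = 2", {
  tt <- c(0, 19, 26, 74)
  y <- c(1000, 8000, 9000, 9100)  # steepest two-point segment is 1 -> 2
  fit <- easylinear_rate(density_series(tt, y), h = 2)
  expect_equal(fit$window, c(1L, 2L))
  expect_equal(fit$mu, two_point_rate(density_series(tt, y), 1, 2))
})

test_that("rate estimators are invariant to density rescaling", {
  set.seed(3)
  tt <- seq(0, 96, by = 8)
  y <- logistic_growth(tt, 0.12, 1e6, 1000) * exp(rnorm(length(tt), 0, 0.03))
  for (c_scale in c(0.01, 7)) {
    f1 <- easylinear_rate(density_series(tt, y), h = 3)
    f2 <- easylinear_rate(density_series(tt, c_scale * y), h = 3)
    expect_equal(f1$mu, f2$mu, tolerance = 1e-12)
    g1 <- fit_logistic(density_series(tt, y))
    g2 <- fit_logistic(density_series(tt, c_scale * y))
    expect_equal(g1$mu, g2$mu, tolerance = 1e-6)
    expect_equal(g2$K / g1$K, c_scale, tolerance = 1e-6)
  }
})

test_that("logistic fit recovers noiseless parameters to 1e-6", {
  tt <- seq(0, 120, length.out = 20)
  y <- logistic_growth(tt, 0.15, 1e6, 1e3)
  fit <- fit_logistic(density_series(tt, y))
  expect_true(fit$converged)
  expect_true(fit$k_in_range)
  expect_equal(fit$mu, 0.15, tolerance = 1e-6)
  expect_equal(fit$K, 1e6, tolerance = 1e-6)
})

test_that("pure exponential-phase data flags an unidentifiable K", {
  tt <- seq(0, 30, by = 2)
  y <- 1000 * exp(0.1 * tt)  # max density far below any plateau
  fit <- fit_logistic(density_series(tt, y))
  expect_false(isTRUE(fit$k_in_range))
})

test_that("logistic mu is robust to 5% lognormal noise", {
  set.seed(11)
  tt <- seq(0, 72, length.out = 20)  # samples span the growth phase
  latent <- logistic_growth(tt, 0.15, 1e6, 1e3)
  rel_err <- replicate(200, {
    y <- latent * rlnorm(length(tt), 0, 0.05)
    abs(fit_logistic(density_series(tt, y))$mu - 0.15) / 0.15
  })
  expect_lt(median(rel_err), 0.05)
})

test_that("polynomial order selection finds the true trend order", {
  set.seed(5)
  tt <- seq(0, 96, length.out = 12)
  lin <- 100 + 3 * tt + rnorm(12, 0, 1e-3)
  expect_equal(select_polynomial_order(density_series(tt, lin))$order, 1L)
  hits <- 0L
  for (seed in 1:100) {
    set.seed(seed)
    cubic <- 5e4 + 100 * tt - 30 * tt^2 + 0.9 * tt^3 + rnorm(12, 0, 50)
    cubic <- pmax(cubic, 1)
    if (select_polynomial_order(density_series(tt, cubic))$order == 3L)
      hits <- hits + 1L
  }
  expect_gt(hits, 95)
})

test_that("LR statistic equals n log(RSS ratio) of the nested fits", {
  set.seed(6)
  tt <- seq(0, 50, length.out = 15)
  y <- 200 + 2 * tt + 0.5 * tt^2 + rnorm(15, 0, 5)
  sel <- select_polynomial_order(density_series(tt, pmax(y, 1)),
                                 max_order = 3)
  yv <- pmax(y, 1)
  for (k in seq_len(nrow(sel$trace))) {
    rss_k <- sum(resid(lm(yv ~ poly(tt, sel$trace$order_null[k])))^2)
    rss_k1 <- sum(resid(lm(yv ~ poly(tt, sel$trace$order_alt[k])))^2)
    expect_equal(sel$trace$lr[k], 15 * log(rss_k / rss_k1),
                 tolerance = 1e-10)
  }
})

test_that("effect ratios follow their definition and recover m_K", {
  f <- function(mu, K) structure(list(mu = mu, K = K, converged = TRUE),
                                 class = "growth_fit")
  same <- effect_ratios(list(f(0.1, 1e6)), list(f(0.1, 1e6)))
  expect_equal(same$mu_ratio, 1)
  expect_equal(same$K_ratio, 1)
  r <- effect_ratios(list(f(0.1, 2e6)), list(f(0.1, 1e6)))
  expect_equal(r$K_ratio, 2)
  expect_error(effect_ratios(list(f(0.1, 1e6)), list(f(0, 0))),
               "zero")

  # recovery from a synthetic isolate panel with m_K = 1.5, low noise
  panel <- generate_isolate_panel("H", "iso1", mu = 0.1, K = 1e6,
                                  m_mu = 1, m_K = 1.5, sigma = 0.01,
                                  seed = 4)
  fits <- lapply(split(panel, paste(panel$treatment, panel$replicate)),
                 function(sub) fit_logistic(
                   as_density_series(sub, measurement = "fluorescence")))
  xen <- fits[grep("^iso1", names(fits))]
  axe <- fits[grep("^axenic", names(fits))]
  rr <- effect_ratios(xen, axe)
  expect_gt(rr$K_ratio, 1.4)
  expect_lt(rr$K_ratio, 1.6)
})
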