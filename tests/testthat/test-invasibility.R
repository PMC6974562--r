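test_that("sensitivity follows its definition and sign convention", {
  expect_equal(compute_sensitivity(0.1, 0.1), 0)     # neutral
  expect_equal(compute_sensitivity(0.1, 0), 1)       # full suppression
  expect_equal(compute_sensitivity(0.08, 0.12), -0.5) # facilitation
  expect_error(compute_sensitivity(0, 0.1), "undefined sensitivity")
})

test_that("sensitivity is scale-invariant and monotone in mu_invading", {
  set.seed(8)
  for (i in 1:20) {
    a <- runif(1, 0.01, 0.3); b <- runif(1, -0.1, 0.3); c <- runif(1, 0.1, 9)
    expect_equal(compute_sensitivity(a, b),
                 compute_sensitivity(c * a, c * b), tolerance = 1e-12)
  }
  mu_inv <- seq(-0.1, 0.2, by = 0.01)
  s <- compute_sensitivity(0.1, mu_inv)
  expect_true(all(diff(s) < 0))
})

make_fits <- function(n_mono, n_inv, treatments = "axenic",
                      mu_mono = 0.10, mu_inv = 0.05) {
  do.call(rbind, lapply(treatments, function(tr) rbind(
    data.frame(species = "A", treatment = tr, role = "monoculture",
               replicate = seq_len(n_mono), pair_id = "A",
               mu = mu_mono + 0.001 * seq_len(n_mono),
               measurement = "density"),
    data.frame(species = "A", treatment = tr, role = "invader",
               replicate = seq_len(n_inv), pair_id = "A->B",
               mu = mu_inv + 0.001 * seq_len(n_inv),
               measurement = "density"),
    data.frame(species = "B", treatment = tr, role = "monoculture",
               replicate = seq_len(n_mono), pair_id = "B",
               mu = 0.11, measurement = "density"))))
}

test_that("cross pairing yields n_mono x n_inv records per direction", {
  tab <- sensitivity_table(make_fits(3, 3))
  expect_equal(nrow(tab), 9)
  expect_equal(length(unique(tab$pairing_id)), 9)
  one <- sensitivity_table(make_fits(1, 1))
  expect_equal(nrow(one), 1)
  matched <- sensitivity_table(make_fits(3, 3), pairing = "matched")
  expect_equal(nrow(matched), 3)
  # the stored S_i satisfies the defining identity exactly
  expect_equal(tab$s_i, (tab$mu_alone - tab$mu_invading) / tab$mu_alone)
})

test_that("missing monoculture counterparts are reported by cell", {
  fits <- make_fits(3, 3)
  fits <- fits[!(fits$role == "monoculture" & fits$species == "A"), ]
  expect_error(sensitivity_table(fits), "monoculture.*'A'.*'axenic'")
})

test_that("fluorescence-derived rates are refused by default", {
  fits <- make_fits(2, 2)
  fits$measurement <- "fluorescence"
  expect_error(sensitivity_table(fits), "fluorescence")
  expect_silent(sensitivity_table(fits, allow_fluorescence = TRUE))
})

test_that("noiseless synthetic data recovers alpha K_j / K_i", {
  truth <- two_species_truth(alpha_ab = 0.4, alpha_ba = 0.2,
                             K = c(1e6, 2e6))
  ex <- generate_experiment(truth, experiment_design(replicates = 2),
                            seed = 1, observe = FALSE)
  tab <- sensitivity_table(fit_growth(ex$data))
  for (tr in c("axenic", "xenic")) {
    for (dir in list(c("A", "B"), c("B", "A"))) {
      s <- tab$s_i[tab$invader == dir[1] & tab$resident == dir[2] &
                     tab$treatment == tr]
      s_true <- true_sensitivity(truth, dir[1], dir[2], tr)
      expect_equal(mean(s), s_true, tolerance = 0.01)
    }
  }
})

test_that("treatment contrast: sign, pairing and degenerate df handling", {
  set.seed(21)
  rec <- null_sensitivity_records(9)
  # shift the xenic records down: bacteria reduce sensitivity
  rec$s_i[rec$treatment == "xenic"] <-
    rec$s_i[rec$treatment == "xenic"] - 0.2
  d <- delta_sensitivity(rec)
  expect_equal(d$delta, d$mean_xenic - d$mean_axenic)
  expect_lt(d$delta, 0)
  expect_lt(d$p_value, 0.05)
  expect_equal(d$df, 8)
  # near-identical distributions: difference near zero, test not rejected
  set.seed(22)
  rec0 <- null_sensitivity_records(9, sd_s = 0.05)
  d0 <- delta_sensitivity(rec0)
  expect_lt(abs(d0$delta), 0.1)
  # a single pairing leaves no degrees of freedom: refused, not silent
  one <- null_sensitivity_records(1)
  d1 <- delta_sensitivity(one)
  expect_true(d1$test_refused)
  expect_equal(d1$df, 0)
  expect_true(is.na(d1$p_value))
  expect_true(is.finite(d1$delta))
})

test_that("a missing treatment is a hard error", {
  rec <- null_sensitivity_records(3)
  expect_error(delta_sensitivity(rec[rec$treatment == "axenic", ]),
               "treatment 'xenic' missing")
})

test_that("halving one direction's alpha yields negative contrasts", {
  # xenic modifier cuts A's sensitivity to B by 50%; with counting noise
  # the contrast for A->B must come out significantly negative in nearly
  # every seeded run
  m_alpha <- matrix(c(1, 1, 0.5, 1), 2, 2)
  hits <- 0L
  n_runs <- 40L
  for (seed in seq_len(n_runs)) {
    truth <- two_species_truth(alpha_ab = 0.8, alpha_ba = 0.3,
                               m_alpha = m_alpha)
    ex <- generate_experiment(truth, experiment_design(), seed = seed)
    tab <- sensitivity_table(fit_growth(ex$data))
    d <- delta_sensitivity(tab)
    row <- d[d$invader == "A" & d$resident == "B", ]
    if (row$delta < 0 && row$p_value < 0.05) hits <- hits + 1L
  }
  expect_gt(hits / n_runs, 0.95)
})
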