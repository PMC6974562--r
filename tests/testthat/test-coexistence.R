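test_that("niche difference follows 1 - sqrt(S_A S_B) in its domain", {
  expect_equal(niche_difference(0.5, 0.5), 0.5)
  expect_equal(niche_difference(1, 1), 0)
  expect_equal(niche_difference(0.9, 0.4), 0.4)   # 1 - sqrt(0.36)
  out <- niche_difference(-0.1, 0.5)
  expect_true(is.na(out))
  expect_equal(attr(out, "reason"), "theory-out-of-domain")
  expect_true(is.na(niche_difference(0, 0.5)))
})

test_that("relative fitness difference is ordered and label-invariant", {
  expect_equal(relative_fitness_difference(0.4, 0.4), 1)
  expect_equal(relative_fitness_difference(0.9, 0.4), 1.5)  # sqrt(2.25)
  expect_equal(relative_fitness_difference(0.4, 0.9), 1.5)
  expect_true(is.na(relative_fitness_difference(0.5, -0.2)))
})

test_that("ND/RFD are invariant under swapping species labels", {
  set.seed(13)
  sa <- runif(50, 0.01, 2); sb <- runif(50, 0.01, 2)
  expect_equal(niche_difference(sa, sb), niche_difference(sb, sa))
  expect_equal(relative_fitness_difference(sa, sb),
               relative_fitness_difference(sb, sa))
  # monotonicity: ND decreases in the product, RFD increases in the ratio
  expect_true(all(diff(niche_difference(seq(0.1, 1, 0.1), 0.5)) < 0))
  expect_true(all(diff(relative_fitness_difference(seq(0.6, 2, 0.1),
                                                   0.5)) > 0))
})

test_that("classification matches the printed-threshold arithmetic", {
  expect_equal(classify_coexistence(0.82, 1.98), "coexistence")
  expect_equal(classify_coexistence(0.5, 2), "boundary")  # 1/(1-0.5) = 2
  expect_equal(classify_coexistence(0.5, 2.1), "exclusion")
  expect_equal(classify_coexistence(NA, 1.5), "undefined")
  expect_error(classify_coexistence(1, 1.5), "ND >= 1")
})

test_that("classification reduces to comparing S_A against 1", {
  # sqrt(S_A/S_B) vs 1/sqrt(S_A S_B) is algebraically S_A vs 1 (S_A >= S_B)
  s <- seq(0.05, 2, length.out = 25)
  for (sa in s) for (sb in s) {
    hi <- max(sa, sb); lo <- min(sa, sb)
    got <- classify_coexistence(niche_difference(hi, lo),
                                relative_fitness_difference(hi, lo))
    want <- if (abs(hi - 1) < 1e-12) "boundary"
            else if (hi < 1) "coexistence" else "exclusion"
    expect_equal(got, want)
  }
})

test_that("nd_rfd_table pairs directions and books the ANOVA dfs", {
  set.seed(31)
  rec <- rbind(
    transform(null_sensitivity_records(9, mean_s = 0.5, sd_s = 0.05)),
    transform(null_sensitivity_records(9, mean_s = 0.3, sd_s = 0.05),
              invader = "B", resident = "A"))
  out <- nd_rfd_table(rec, "A", "B")
  expect_equal(nrow(out$pairs), 18)          # 9 pairings x 2 treatments
  expect_equal(out$anova$df_num, c(1, 1))
  expect_equal(out$anova$df_den, c(16, 16))  # the 9 + 9 design
  expect_true(all(out$pairs$s_a >= out$pairs$s_b))
  expect_equal(out$n_excluded, 0)
})

test_that("equal treatment means give an exactly zero F", {
  vals <- c(0.3, 0.4, 0.5)
  rec <- do.call(rbind, lapply(c("axenic", "xenic"), function(tr) rbind(
    data.frame(invader = "A", resident = "B", treatment = tr,
               pairing_id = sprintf("p%d", 1:3), s_i = vals),
    data.frame(invader = "B", resident = "A", treatment = tr,
               pairing_id = sprintf("p%d", 1:3), s_i = rev(vals)))))
  out <- nd_rfd_table(rec, "A", "B")
  expect_equal(out$anova$f, c(0, 0))
})

test_that("nonpositive sensitivities are excluded, never clipped", {
  rec <- rbind(
    data.frame(invader = "A", resident = "B", treatment = "axenic",
               pairing_id = c("p1", "p2"), s_i = c(0.5, -0.1)),
    data.frame(invader = "B", resident = "A", treatment = "axenic",
               pairing_id = c("p1", "p2"), s_i = c(0.4, 0.6)))
  out <- nd_rfd_table(rec, "A", "B")
  expect_equal(nrow(out$pairs), 1)
  expect_equal(out$n_excluded, 1)
})

test_that("a missing invasion direction is named in the error", {
  rec <- data.frame(invader = "A", resident = "B", treatment = "axenic",
                    pairing_id = "p1", s_i = 0.5)
  expect_error(nd_rfd_table(rec, "A", "B"), "B->A missing")
})

test_that("xenic damping of one direction raises the niche difference", {
  m_alpha <- matrix(c(1, 0.4, 1, 1), 2, 2)  # damp B-invading-A (alpha_ba)
  hits <- 0L
  n_runs <- 30L
  for (seed in seq_len(n_runs)) {
    truth <- two_species_truth(alpha_ab = 0.5, alpha_ba = 0.3,
                               m_alpha = m_alpha)
    ex <- generate_experiment(truth, experiment_design(), seed = 100 + seed)
    tab <- sensitivity_table(fit_growth(ex$data))
    out <- nd_rfd_table(tab, "A", "B")
    means <- tapply(out$pairs$nd, out$pairs$treatment, mean)
    if (means[["xenic"]] > means[["axenic"]]) hits <- hits + 1L
  }
  expect_gt(hits / n_runs, 0.9)
})
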