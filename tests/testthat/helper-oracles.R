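# Independent oracles used across tests.  These deliberately take a
# different computational route from the package implementation.

# brute-force easylinear: lm() on log(y) over every all-positive window,
# maximum slope, earliest window on ties (which.max convention)
oracle_easylinear <- function(time, y, h) {
  n <- length(time)
  slopes <- rep(NA_real_, n - h + 1L)
  for (i in seq_len(n - h + 1L)) {
    idx <- i:(i + h - 1L)
    if (any(y[idx] <= 0)) next
    slopes[i] <- unname(coef(lm(log(y[idx]) ~ time[idx]))[2L])
  }
  if (all(is.na(slopes))) return(NULL)
  i <- which.max(slopes)
  list(start = i, mu = slopes[i])
}

# sequential (Type I) sums of squares by explicit least-squares projections
oracle_sequential_anova <- function(y, a, b, interaction = TRUE) {
  rss <- function(X) {
    fit <- qr(X)
    sum((y - X %*% qr.coef(fit, y))^2)
  }
  a <- factor(a); b <- factor(b)
  Xs <- list(
    model.matrix(~1, data.frame(a, b)),
    model.matrix(~a),
    model.matrix(~a + b))
  if (interaction) Xs[[4L]] <- model.matrix(~a * b)
  rs <- vapply(Xs, rss, numeric(1))
  dfs <- diff(vapply(Xs, ncol, integer(1)))
  ss <- -diff(rs)
  full <- Xs[[length(Xs)]]
  df_den <- length(y) - qr(full)$rank
  ms_err <- rs[length(rs)] / df_den
  f <- (ss / dfs) / ms_err
  data.frame(df = dfs, sum_sq = ss, f = f, df_den = df_den,
             p_value = pf(f, dfs, df_den, lower.tail = FALSE))
}

# Welch and pooled two-sample t statistics from the textbook formulas
oracle_t_two_sample <- function(x, y, var_equal = FALSE) {
  nx <- length(x); ny <- length(y)
  vx <- var(x); vy <- var(y)
  if (var_equal) {
    sp2 <- ((nx - 1) * vx + (ny - 1) * vy) / (nx + ny - 2)
    se <- sqrt(sp2 * (1 / nx + 1 / ny))
    df <- nx + ny - 2
  } else {
    se <- sqrt(vx / nx + vy / ny)
    df <- (vx / nx + vy / ny)^2 /
      ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  }
  t <- (mean(x) - mean(y)) / se
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# small two-species truth used by recovery-style tests
two_species_truth <- function(alpha_ab, alpha_ba = alpha_ab,
                              m_alpha = 1, K = c(1e6, 1e6)) {
  sim_truth(
    species = c("A", "B"),
    mu = c(0.10, 0.11), K = K,
    alpha = matrix(c(0, alpha_ba, alpha_ab, 0), 2, 2, byrow = FALSE,
                   dimnames = list(c("A", "B"), c("A", "B"))),
    m_mu = 1.05, m_K = 1.1, m_alpha = m_alpha)
}

# iid-normal sensitivity records for both treatments with matching pairing
# ids: the null model of the treatment contrast
null_sensitivity_records <- function(n_pairings = 9L, mean_s = 0.4,
                                     sd_s = 0.1) {
  ids <- sprintf("p%02d", seq_len(n_pairings))
  do.call(rbind, lapply(c("axenic", "xenic"), function(tr)
    data.frame(invader = "A", resident = "B", treatment = tr,
               pairing_id = ids,
               mono_replicate = 1L, invasion_replicate = 1L,
               mu_alone = 0.1, mu_invading = 0.1 * (1 - mean_s),
               s_i = rnorm(n_pairings, mean_s, sd_s))))
}
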