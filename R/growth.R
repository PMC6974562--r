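#' @title Growth-rate estimation
#' @description Estimators for the per-capita growth rate mu (per hour) and,
#'   where identifiable, the carrying capacity K from a single density time
#'   series: the two-point rate, rolling-window log-linear regression
#'   ("easy linear"), nonlinear logistic fits, and likelihood-ratio
#'   selection of polynomial trend order.
#' @name growth_inference
NULL

growth_fit <- function(method, mu, K = NA_real_, n0 = NA_real_,
                       window = c(NA_integer_, NA_integer_),
                       r_squared = NA_real_, rss = NA_real_,
                       converged = TRUE, k_in_range = NA,
                       measurement = "density", series = NULL) {
  meta <- if (is.null(series)) list() else
    series[c("species", "treatment", "role", "flask_id", "replicate")]
  structure(
    c(list(method = method, mu = unname(mu), K = unname(K), n0 = unname(n0),
           window = window, r_squared = r_squared, rss = rss,
           converged = converged, k_in_range = k_in_range,
           measurement = measurement), meta),
    class = "growth_fit"
  )
}

#' @export
print.growth_fit <- function(x, ...) {
  cat(sprintf("<growth_fit:%s> mu = %.6g /h%s%s%s\n", x$method, x$mu,
              if (is.finite(x$K)) sprintf(", K = %.6g", x$K) else "",
              if (!isTRUE(x$converged)) " [NOT CONVERGED]" else "",
              if (identical(x$measurement, "fluorescence"))
                " [fluorescence]" else ""))
  if (all(is.finite(x$window)))
    cat(sprintf("  window: observations %d..%d\n", x$window[1], x$window[2]))
  invisible(x)
}

#' Two-point per-capita growth rate
#'
#' \deqn{\mu = \frac{1}{T} \ln(D_T / D_0)} between two observations of a
#' density series, where `T` is the elapsed time in hours.
#'
#' @param series a [density_series()] or coercible object.
#' @param i0,i1 indices of the initial and final observation (`i0 < i1`);
#'   defaults to the first two points.
#' @return the rate in per hour (positive for growth, negative for
#'   decline).
#' @examples
#' s <- density_series(c(0, 24), c(1000, 2000))
#' two_point_rate(s)          # log(2)/24
#' @export
two_point_rate <- function(series, i0 = 1L, i1 = 2L) {
  s <- as_density_series(series)
  n <- length(s$time_h)
  if (!(i0 >= 1L && i1 <= n && i0 < i1))
    stop("need 1 <= i0 < i1 <= length(series)", call. = FALSE)
  d0 <- s$value[i0]; d1 <- s$value[i1]
  if (d0 <= 0 || d1 <= 0)
    stop(sprintf(
      "undefined rate: nonpositive density at observation %d (D0 = %g, D1 = %g); zero counts must be resolved, not pseudo-counted",
      if (d0 <= 0) i0 else i1, d0, d1), call. = FALSE)
  log(d1 / d0) / (s$time_h[i1] - s$time_h[i0])
}

# OLS of log(y) on t over indices idx; closed-form slope/intercept/R2
.loglinear_window <- function(t, y, idx) {
  tt <- t[idx]; ly <- log(y[idx])
  tb <- mean(tt); lb <- mean(ly)
  sxx <- sum((tt - tb)^2)
  slope <- sum((tt - tb) * (ly - lb)) / sxx
  fitted <- lb + slope * (tt - tb)
  sse <- sum((ly - fitted)^2)
  sst <- sum((ly - lb)^2)
  r2 <- if (sst > 0) 1 - sse / sst else 1
  list(mu = slope, r_squared = r2, rss = sse)
}

#' Maximum growth rate by rolling log-linear regression
#'
#' Ordinary least-squares regression of `log(density)` on time over every
#' contiguous window of `h` observations; the window with the maximal slope
#' is returned (earliest window on ties), its slope being the maximum
#' per-capita growth rate.  With `h` equal to the series length this is a
#' single whole-series log-linear fit.  The default `h = 3` with the
#' standard five-sample invasion schedule makes the estimate the log-linear
#' slope over the first three samples (0-26 h), i.e. the early-exponential
#' rate before growth decelerates.
#'
#' @param series a [density_series()] or coercible object.
#' @param h window size in observations (>= 2).
#' @return a `growth_fit` with `method = "easylinear"`, the slope `mu`, the
#'   winning window's index range, and its within-window R-squared.
#'   Windows containing nonpositive densities are skipped; if no window of
#'   `h` strictly positive observations exists, an error is thrown.
#' @examples
#' tt <- c(0, 19, 26, 74, 96)
#' s <- density_series(tt, 1000 * exp(0.1 * pmin(tt, 26)))
#' easylinear_rate(s, h = 3)
#' @export
easylinear_rate <- function(series, h = 3L) {
  s <- as_density_series(series)
  n <- length(s$time_h)
  h <- as.integer(h)
  if (h < 2L) stop("'h' must be at least 2", call. = FALSE)
  if (n < h)
    stop(sprintf("insufficient data: %d observations for window size %d",
                 n, h), call. = FALSE)
  best <- NULL
  for (i in seq_len(n - h + 1L)) {
    idx <- i:(i + h - 1L)
    if (any(s$value[idx] <= 0)) next
    w <- .loglinear_window(s$time_h, s$value, idx)
    if (is.null(best) || w$mu > best$mu + 0) {
      best <- w; best$start <- i
    }
  }
  if (is.null(best))
    stop(sprintf(
      "insufficient data: no window of %d strictly positive densities", h),
      call. = FALSE)
  growth_fit("easylinear", mu = best$mu,
             window = c(best$start, best$start + h - 1L),
             r_squared = best$r_squared, rss = best$rss,
             measurement = s$measurement, series = s)
}

#' Fit a logistic growth curve by nonlinear least squares
#'
#' Fits \eqn{N(t) = K / (1 + ((K - N_0)/N_0) e^{-\mu t})} over
#' \eqn{(\mu, K, N_0)} by Levenberg-Marquardt damped least squares
#' ([minpack.lm::nlsLM()]).  Starting values: `K` at 1.05 times the maximum
#' observation, `N0` at the first observation, and `mu` from
#' [easylinear_rate()] (falling back to a whole-series two-point rate).
#'
#' @param series a [density_series()] or coercible object with at least 4
#'   observations.
#' @param start optional named list overriding the starting values
#'   (`mu`, `K`, `n0`).
#' @param maxiter maximum Levenberg-Marquardt iterations.
#' @return a `growth_fit` with `method = "logistic"`, estimates `mu`, `K`,
#'   `n0`, the residual sum of squares, a `converged` flag, and
#'   `k_in_range` indicating whether the fitted `K` lies within
#'   `[max(y)/2, 10 max(y)]` --- outside that range the carrying capacity
#'   is not identified by the data (e.g. a series still in pure exponential
#'   phase).  Non-convergence yields a flagged fit with `NA` estimates,
#'   never silent defaults.
#' @export
fit_logistic <- function(series, start = NULL, maxiter = 200L) {
  s <- as_density_series(series)
  n <- length(s$time_h)
  if (n < 4L)
    stop("logistic fit needs at least 4 observations", call. = FALSE)
  if (any(s$value <= 0))
    stop("logistic fit requires strictly positive values", call. = FALSE)
  t <- s$time_h; y <- s$value
  mu0 <- tryCatch(easylinear_rate(s, h = min(3L, n))$mu,
                  error = function(e) NULL)
  if (is.null(mu0) || !is.finite(mu0) || mu0 == 0)
    mu0 <- log(max(y) / y[1L] + 1e-6) / max(diff(range(t)), 1)
  init <- list(mu = mu0, K = 1.05 * max(y), n0 = y[1L])
  if (!is.null(start)) init[names(start)] <- start
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ K / (1 + ((K - n0) / n0) * exp(-mu * t)),
      data = data.frame(t = t, y = y),
      start = init,
      lower = c(mu = -Inf, K = .Machine$double.eps, n0 = .Machine$double.eps),
      control = minpack.lm::nls.lm.control(
        maxiter = maxiter, ftol = 1e-14, ptol = 1e-14)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(growth_fit("logistic", mu = NA_real_, K = NA_real_,
                      converged = FALSE, k_in_range = NA,
                      measurement = s$measurement, series = s))
  }
  cf <- coef(fit)
  info <- fit$convInfo
  converged <- if (is.null(info)) TRUE else
    isTRUE(info$isConv) || isTRUE(info$stopCode %in% 1:3)
  k_ok <- cf[["K"]] >= max(y) / 2 && cf[["K"]] <= 10 * max(y)
  growth_fit("logistic", mu = cf[["mu"]], K = cf[["K"]], n0 = cf[["n0"]],
             rss = sum(stats::resid(fit)^2),
             converged = converged, k_in_range = k_ok,
             measurement = s$measurement, series = s)
}

#' Select polynomial trend order by nested likelihood-ratio tests
#'
#' Fits polynomial trends of order 1..`max_order` to the series by least
#' squares and compares successive orders with Gaussian likelihood-ratio
#' tests (1 df each), stopping at the first non-significant improvement.
#' The LR statistic for order k vs k+1 equals
#' \eqn{n \log(RSS_k / RSS_{k+1})} under the profile Gaussian likelihood.
#'
#' @param series a [density_series()] or coercible object with at least
#'   `max_order + 2` observations.
#' @param max_order highest order considered (default 3).
#' @param alpha significance level for each step (default 0.05).
#' @return list with `order` (the chosen order) and `trace`, a data frame
#'   of per-step statistics (`order_null`, `order_alt`, `lr`, `df`,
#'   `p_value`, `significant`).
#' @export
select_polynomial_order <- function(series, max_order = 3L, alpha = 0.05) {
  s <- as_density_series(series)
  n <- length(s$time_h)
  max_order <- as.integer(max_order)
  if (n < max_order + 2L)
    stop(sprintf("need at least %d observations for max_order %d",
                 max_order + 2L, max_order), call. = FALSE)
  t <- s$time_h; y <- s$value
  fits <- lapply(seq_len(max_order),
                 function(k) lm(y ~ stats::poly(t, k)))
  chosen <- max_order
  trace <- list()
  for (k in seq_len(max_order - 1L)) {
    lr <- as.numeric(2 * (logLik(fits[[k + 1L]]) - logLik(fits[[k]])))
    p <- pchisq(lr, df = 1, lower.tail = FALSE)
    sig <- p < alpha
    trace[[k]] <- data.frame(order_null = k, order_alt = k + 1L,
                             lr = lr, df = 1L, p_value = p,
                             significant = sig)
    if (!sig) { chosen <- k; break }
  }
  list(order = chosen,
       trace = if (length(trace)) do.call(rbind, trace) else
         data.frame(order_null = integer(), order_alt = integer(),
                    lr = numeric(), df = integer(), p_value = numeric(),
                    significant = logical()))
}

#' Xenic-over-axenic effect ratios of growth parameters
#'
#' Mean carrying capacity and growth rate within each treatment, and their
#' xenic/axenic ratios.  Values above 1 indicate that the bacterial
#' treatment increased the measure.
#'
#' @param xenic_fits,axenic_fits lists of `growth_fit` objects or data
#'   frames with columns `mu`, `K`, `converged` (only converged fits are
#'   used).
#' @return one-row data frame: `mu_xenic`, `mu_axenic`, `mu_ratio`,
#'   `K_xenic`, `K_axenic`, `K_ratio`, `n_xenic`, `n_axenic`.
#' @export
effect_ratios <- function(xenic_fits, axenic_fits) {
  pull <- function(fits, label) {
    if (inherits(fits, "growth_fit")) fits <- list(fits)
    if (is.data.frame(fits)) {
      df <- fits
    } else {
      df <- do.call(rbind, lapply(fits, function(f)
        data.frame(mu = f$mu, K = f$K, converged = isTRUE(f$converged))))
    }
    df <- df[df$converged & is.finite(df$mu), , drop = FALSE]
    if (nrow(df) == 0L)
      stop(sprintf("no converged fits in '%s'", label), call. = FALSE)
    df
  }
  xen <- pull(xenic_fits, "xenic_fits")
  axe <- pull(axenic_fits, "axenic_fits")
  mu_x <- mean(xen$mu); mu_a <- mean(axe$mu)
  K_x <- mean(xen$K, na.rm = TRUE); K_a <- mean(axe$K, na.rm = TRUE)
  if (!is.finite(mu_a) || mu_a == 0 || (is.finite(K_a) && K_a == 0))
    stop("undefined ratio: axenic mean is zero", call. = FALSE)
  data.frame(mu_xenic = mu_x, mu_axenic = mu_a, mu_ratio = mu_x / mu_a,
             K_xenic = K_x, K_axenic = K_a, K_ratio = K_x / K_a,
             n_xenic = nrow(xen), n_axenic = nrow(axe))
}

#' Fit growth rates for every flask-and-species series in a tidy dataset
#'
#' Applies one estimator per (flask, species) series and returns a tidy
#' table of fits annotated with the design cell, ready for
#' [sensitivity_table()].  Monoculture and invader series carry the
#' combination label used by the growth-rate ANOVA (`"<species>_mono"` for
#' monocultures, the directed `pair_id` for invaders).
#'
#' @param data tidy experiment data frame ([generate_experiment()] output
#'   `$data` or [read_tidy_csv()] output).
#' @param method `"easylinear"` (default) or `"logistic"`.
#' @param window easylinear window size `h`.
#' @param roles which roles to fit (default monocultures and invaders: the
#'   series whose rates enter the sensitivity statistic).
#' @param measurement `"density"` or `"fluorescence"`.
#' @return data frame with one row per fitted series: `flask_id`,
#'   `pair_id`, `combination`, `treatment`, `role`, `species`, `replicate`,
#'   `method`, `mu`, `K`, `r_squared`, `converged`, `measurement`.
#' @export
fit_growth <- function(data, method = c("easylinear", "logistic"),
                       window = 3L, roles = c("monoculture", "invader"),
                       measurement = "density") {
  method <- match.arg(method)
  data <- data[data$role %in% roles, , drop = FALSE]
  if (nrow(data) == 0L)
    stop("no rows with the requested roles", call. = FALSE)
  keys <- unique(data[c("flask_id", "species")])
  out <- vector("list", nrow(keys))
  for (i in seq_len(nrow(keys))) {
    sub <- data[data$flask_id == keys$flask_id[i] &
                  data$species == keys$species[i], , drop = FALSE]
    s <- as_density_series(sub, measurement = measurement)
    f <- if (method == "easylinear") easylinear_rate(s, h = window)
         else fit_logistic(s)
    out[[i]] <- data.frame(
      flask_id = s$flask_id, pair_id = sub$pair_id[1L],
      combination = if (sub$role[1L] == "monoculture")
        paste0(s$species, "_mono") else sub$pair_id[1L],
      treatment = s$treatment, role = s$role, species = s$species,
      replicate = s$replicate, method = method,
      mu = f$mu, K = f$K, r_squared = f$r_squared,
      converged = isTRUE(f$converged), measurement = f$measurement)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
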