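#' Ground-truth parameters for a synthetic invasion experiment
#'
#' Defines a Lotka-Volterra competition community
#' \deqn{dN_i/dt = \mu_i N_i (1 - (N_i + \sum_{j \ne i} \alpha_{ij} N_j)/K_i)}
#' under the bacteria-free ("axenic") treatment, together with multiplicative
#' microbiome modifiers applied under the "xenic" treatment:
#' \eqn{\mu^{xen} = m_\mu \mu}, \eqn{K^{xen} = m_K K},
#' \eqn{\alpha^{xen} = m_\alpha \alpha}.  Negative \eqn{\alpha_{ij}} encodes
#' facilitation of invader i by resident j.  The implied true sensitivity of
#' i invading an established j is \eqn{S = \alpha_{ij} K_j / K_i}
#' (treatment-wise), which is what recovery tests check against.
#'
#' @param species character vector of species labels.
#' @param mu intrinsic per-capita growth rates, per hour, one per species
#'   (scalars are recycled), strictly positive.
#' @param K carrying capacities, cells per ml, strictly positive.
#' @param alpha square interaction matrix; `alpha[i, j]` scales the effect
#'   of species j's density on species i's crowding term.  The diagonal is
#'   forced to zero (self-crowding is the `N_i` term itself).
#' @param m_mu,m_K per-species multiplicative modifiers (> 0) applied to
#'   `mu` and `K` under the xenic treatment.
#' @param m_alpha scalar or matrix modifier applied elementwise to `alpha`
#'   under the xenic treatment.
#' @param n0 default initial densities, cells per ml.
#' @param rng_seed optional integer recorded with the truth.
#' @return an object of class `sim_truth`.
#' @seealso [default_truth()] for a ready-made four-species community,
#'   [true_sensitivity()], [generate_experiment()].
#' @export
sim_truth <- function(species, mu, K, alpha, m_mu = 1, m_K = 1, m_alpha = 1,
                      n0 = 1000, rng_seed = NULL) {
  n <- length(species)
  stopifnot(n >= 1L, is.character(species), !anyDuplicated(species))
  rec <- function(x, name) {
    if (length(x) == 1L) x <- rep(x, n)
    if (length(x) != n || !is.numeric(x) || any(!is.finite(x)))
      stop(sprintf("'%s' must be numeric of length 1 or %d, finite", name, n),
           call. = FALSE)
    setNames(as.numeric(x), species)
  }
  mu <- rec(mu, "mu"); K <- rec(K, "K"); n0 <- rec(n0, "n0")
  m_mu <- rec(m_mu, "m_mu"); m_K <- rec(m_K, "m_K")
  if (any(mu <= 0) || any(K <= 0) || any(n0 <= 0))
    stop("'mu', 'K' and 'n0' must be strictly positive", call. = FALSE)
  if (any(m_mu <= 0) || any(m_K <= 0))
    stop("'m_mu' and 'm_K' must be strictly positive", call. = FALSE)
  if (length(alpha) == 1L) alpha <- matrix(alpha, n, n)
  alpha <- as.matrix(alpha)
  if (!all(dim(alpha) == c(n, n)) || any(!is.finite(alpha)))
    stop(sprintf("'alpha' must be a finite %dx%d matrix", n, n), call. = FALSE)
  if (length(m_alpha) == 1L) m_alpha <- matrix(m_alpha, n, n)
  m_alpha <- as.matrix(m_alpha)
  if (!all(dim(m_alpha) == c(n, n)) || any(!is.finite(m_alpha)))
    stop(sprintf("'m_alpha' must be a finite %dx%d matrix", n, n),
         call. = FALSE)
  dimnames(alpha) <- dimnames(m_alpha) <- list(species, species)
  diag(alpha) <- 0
  diag(m_alpha) <- 1
  structure(
    list(species = species, mu = mu, K = K, alpha = alpha,
         m_mu = m_mu, m_K = m_K, m_alpha = m_alpha, n0 = n0,
         rng_seed = rng_seed),
    class = "sim_truth"
  )
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf("<sim_truth> %d species: %s\n", length(x$species),
              paste(x$species, collapse = ", ")))
  print(data.frame(mu = x$mu, K = x$K, m_mu = x$m_mu, m_K = x$m_K,
                   n0 = x$n0))
  cat("alpha (axenic):\n"); print(x$alpha)
  invisible(x)
}

#' Default four-species community
#'
#' A ready-made `sim_truth` emulating a four-species green-algae community
#' with growth rates near 0.1 per hour, carrying capacities of 1.5-3 million
#' cells per ml, a mixture of competitive and facilitative pairwise
#' interactions, and a bacterial (xenic) treatment that mildly raises growth
#' rates and carrying capacities while damping most sensitivities --- with
#' one invasion direction damped strongly, so that exactly one species pair
#' has consistently positive sensitivities and a bacteria-driven increase in
#' its niche difference.
#'
#' @return a `sim_truth` for species `Cmic`, `Scap`, `Mmin`, `Sacu`.
#' @export
default_truth <- function() {
  sp <- c("Cmic", "Scap", "Mmin", "Sacu")
  alpha <- matrix(0, 4, 4, dimnames = list(sp, sp))
  alpha["Cmic", "Scap"] <- 0.35; alpha["Scap", "Cmic"] <- 0.25
  alpha["Cmic", "Mmin"] <- 0.50; alpha["Mmin", "Cmic"] <- 0.90
  alpha["Cmic", "Sacu"] <- 0.60; alpha["Sacu", "Cmic"] <- 0.40
  alpha["Scap", "Mmin"] <- -0.15; alpha["Mmin", "Scap"] <- 0.45
  alpha["Scap", "Sacu"] <- 0.70; alpha["Sacu", "Scap"] <- 0.55
  alpha["Mmin", "Sacu"] <- 0.30; alpha["Sacu", "Mmin"] <- -0.10
  m_alpha <- matrix(0.85, 4, 4, dimnames = list(sp, sp))
  m_alpha["Scap", "Cmic"] <- 0.35  # strong damping of one direction
  sim_truth(
    species = sp,
    mu = c(0.10, 0.11, 0.09, 0.12),
    K = c(2e6, 3e6, 2.5e6, 1.5e6),
    alpha = alpha,
    m_mu = c(1.10, 1.05, 1.15, 1.08),
    m_K = c(1.30, 1.20, 1.40, 1.25),
    m_alpha = m_alpha
  )
}

# parameters of one treatment: axenic = base, xenic = base x modifiers
treatment_params <- function(truth, treatment) {
  stopifnot(inherits(truth, "sim_truth"))
  treatment <- match.arg(treatment, c("axenic", "xenic"))
  if (treatment == "axenic")
    list(mu = truth$mu, K = truth$K, alpha = truth$alpha)
  else
    list(mu = truth$mu * truth$m_mu, K = truth$K * truth$m_K,
         alpha = truth$alpha * truth$m_alpha)
}

#' True sensitivity implied by simulator parameters
#'
#' For invader i entering an established resident j at its carrying
#' capacity, the initial per-capita rate is
#' \eqn{\mu_i (1 - \alpha_{ij} K_j / K_i)}, so the true sensitivity is
#' \eqn{S = \alpha_{ij} K_j / K_i} under the given treatment's parameters.
#'
#' @param truth a [sim_truth()].
#' @param invader,resident species labels.
#' @param treatment `"axenic"` or `"xenic"`.
#' @return the implied sensitivity (dimensionless scalar).
#' @export
true_sensitivity <- function(truth, invader, resident,
                             treatment = "axenic") {
  p <- treatment_params(truth, treatment)
  stopifnot(invader %in% truth$species, resident %in% truth$species)
  unname(p$alpha[invader, resident] * p$K[resident] / p$K[invader])
}

#' Experimental design of a mutual-invasibility experiment
#'
#' Mirrors the standard layout: monocultures and all ordered species pairs,
#' each under both bacterial treatments, in triplicate; residents grown to
#' steady state (about 22 days) before the invader is added at 1,000 cells
#' per ml; densities counted at 0, 19, 26, 74 and 96 h post invasion by
#' hemocytometer, scoring at least 1.8 ul of culture and extending the
#' counted volume until about 200 cells have been scored for low-density
#' samples.
#'
#' @param species optional character vector; defaults at generation time to
#'   the truth's species.
#' @param treatments subset of `c("axenic", "xenic")`.
#' @param replicates flasks per design cell (default 3).
#' @param pre_invasion_h resident monoculture growth period before invasion,
#'   hours (default 528 = 22 days).
#' @param invader_inoculum,monoculture_inoculum starting densities, cells
#'   per ml (default 1000).
#' @param sampling_times post-inoculation sampling times in hours, strictly
#'   increasing and starting at 0.
#' @param volume_ul minimum counted volume, microliters (default 1.8).
#' @param target_count counting continues until about this many cells have
#'   been scored (default 200); the effective counted volume is
#'   `max(volume_ul, 1000 * target_count / density)`, capped at 1 ml.
#' @param fluorescence_days sampling days for isolate-panel (plate reader)
#'   mode.
#' @return an object of class `experiment_design`.
#' @export
experiment_design <- function(species = NULL,
                              treatments = c("axenic", "xenic"),
                              replicates = 3L,
                              pre_invasion_h = 528,
                              invader_inoculum = 1000,
                              monoculture_inoculum = 1000,
                              sampling_times = c(0, 19, 26, 74, 96),
                              volume_ul = 1.8,
                              target_count = 200,
                              fluorescence_days = seq(0, 24, by = 2)) {
  treatments <- match.arg(treatments, c("axenic", "xenic"),
                          several.ok = TRUE)
  assert_scalar_number(replicates, "replicates", positive = TRUE)
  assert_scalar_number(pre_invasion_h, "pre_invasion_h", positive = TRUE)
  assert_scalar_number(invader_inoculum, "invader_inoculum", positive = TRUE)
  assert_scalar_number(monoculture_inoculum, "monoculture_inoculum",
                       positive = TRUE)
  assert_scalar_number(volume_ul, "volume_ul", positive = TRUE)
  assert_scalar_number(target_count, "target_count", positive = TRUE)
  if (length(sampling_times) < 2L || sampling_times[1L] != 0 ||
      any(diff(sampling_times) <= 0))
    stop("'sampling_times' must be strictly increasing and start at 0",
         call. = FALSE)
  structure(
    list(species = species, treatments = treatments,
         replicates = as.integer(replicates),
         pre_invasion_h = pre_invasion_h,
         invader_inoculum = invader_inoculum,
         monoculture_inoculum = monoculture_inoculum,
         sampling_times = as.numeric(sampling_times),
         volume_ul = volume_ul, target_count = target_count,
         fluorescence_days = as.numeric(fluorescence_days)),
    class = "experiment_design"
  )
}

#' Closed-form logistic growth
#'
#' \deqn{N(t) = K / (1 + ((K - N_0)/N_0) e^{-\mu t})}
#'
#' @param t time(s), hours.
#' @param mu per-capita growth rate, per hour.
#' @param K carrying capacity.
#' @param n0 initial density, > 0.
#' @return density at `t`.
#' @export
logistic_growth <- function(t, mu, K, n0) {
  stopifnot(n0 > 0, K > 0)
  K / (1 + ((K - n0) / n0) * exp(-mu * t))
}

# Lotka-Volterra right-hand side for deSolve
lv_rhs <- function(t, y, p) {
  list(p$mu * y * (1 - (y + drop(p$alpha %*% y)) / p$K))
}

#' Simulate latent density trajectories for a species pair or singleton
#'
#' Integrates the two-species (or one-species) Lotka-Volterra competition
#' system with fixed-step fourth-order Runge-Kutta (step at most
#' `step` hours) and returns the latent, noise-free densities at the
#' requested output times.  A singleton reduces to logistic growth.
#'
#' @param truth a [sim_truth()].
#' @param pair character vector of one or two species labels; for an
#'   invasion, order as `c(invader, resident)` (the order only affects
#'   which `n0` default applies to which species).
#' @param treatment `"axenic"` or `"xenic"`.
#' @param n0 named initial densities (cells per ml); defaults to the
#'   truth's `n0` entries for `pair`.
#' @param times output times in hours (default `design$sampling_times`).
#' @param design optional [experiment_design()] supplying default times.
#' @param step maximum integration step, hours (default 0.1).
#' @return data frame with column `time_h` plus one latent-density column
#'   per species.
#' @export
simulate_trajectory <- function(truth, pair, treatment = "axenic",
                                n0 = NULL, times = NULL, design = NULL,
                                step = 0.1) {
  stopifnot(inherits(truth, "sim_truth"),
            all(pair %in% truth$species),
            length(pair) %in% 1:2, !anyDuplicated(pair))
  p <- treatment_params(truth, treatment)
  if (is.null(times)) {
    times <- if (!is.null(design)) design$sampling_times else seq(0, 96, 1)
  }
  times <- sort(unique(as.numeric(times)))
  if (is.null(n0)) n0 <- truth$n0[pair]
  if (is.null(names(n0))) names(n0) <- pair
  stopifnot(all(pair %in% names(n0)), all(n0[pair] >= 0))
  parms <- list(mu = p$mu[pair], K = p$K[pair],
                alpha = p$alpha[pair, pair, drop = FALSE])
  grid <- sort(unique(c(seq(0, max(times), by = step), times)))
  out <- deSolve::ode(y = n0[pair], times = grid, func = lv_rhs,
                      parms = parms, method = "rk4")
  state <- out[match(times, out[, 1L]), -1L, drop = FALSE]
  if (any(!is.finite(state)))
    stop("non-finite state during integration: check parameterization",
         call. = FALSE)
  state[state < 0 & state > -1e-8] <- 0
  if (any(state < 0))
    stop("negative densities during integration: check parameterization",
         call. = FALSE)
  res <- data.frame(time_h = times)
  for (k in seq_along(pair)) res[[pair[k]]] <- unname(state[, k])
  res
}

#' Hemocytometer-style count observation
#'
#' Counts follow a Poisson law with mean `density x volume`:
#' `count ~ Poisson(density * volume_ul / 1000)`, and the implied density
#' estimate is `count / volume`, which is unbiased for the latent density.
#'
#' @param density latent density(ies), cells per ml, nonnegative.
#' @param volume_ul counted volume(s), microliters, positive.
#' @param seed optional integer seed (otherwise the current RNG stream is
#'   used).
#' @return data frame with columns `count`, `volume_ul`,
#'   `density_cells_per_ml` (the count-implied estimate).
#' @export
observe_counts <- function(density, volume_ul, seed = NULL) {
  if (any(density < 0)) stop("'density' must be nonnegative", call. = FALSE)
  if (any(volume_ul <= 0)) stop("'volume_ul' must be positive", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n <- max(length(density), length(volume_ul))
  density <- rep_len(density, n); volume_ul <- rep_len(volume_ul, n)
  count <- rpois(n, density * volume_ul / 1000)
  data.frame(count = count, volume_ul = volume_ul,
             density_cells_per_ml = count / (volume_ul / 1000))
}

# counted volume per the "at least 1.8 ul, until ~200 cells" rule
counting_volume <- function(density, min_volume_ul, target_count,
                            max_volume_ul = 1000) {
  v <- ifelse(density > 0,
              pmax(min_volume_ul, 1000 * target_count / density),
              min_volume_ul)
  pmin(v, max_volume_ul)
}

#' Generate a complete synthetic mutual-invasibility experiment
#'
#' Produces the tidy long-format dataset of a full experiment: for every
#' treatment, monoculture flasks for each species (inoculated at
#' `monoculture_inoculum` and sampled at the design's sampling times) and,
#' for every ordered species pair, invasion flasks in which the resident is
#' first grown alone for `pre_invasion_h` hours (its latent density then
#' follows the closed-form logistic solution of the same model) and the
#' invader is added at `invader_inoculum`; both species are then counted at
#' the sampling times.  Latent dynamics are deterministic; observation noise
#' is Poisson counting in a per-flask RNG sub-stream derived by stable
#' hashing of the flask id, so the full dataset is a pure function of
#' `(truth, design, seed)`.
#'
#' @param truth a [sim_truth()].
#' @param design an [experiment_design()].
#' @param seed integer master seed.
#' @param observe logical; if `FALSE` the reported densities are the latent
#'   (noise-free) values and `count` is `NA`, which is the configuration
#'   used for noiseless parameter-recovery checks.
#' @return object of class `invadyn_experiment`: a list with `data` (tidy
#'   data frame: `flask_id`, `pair_id`, `treatment`, `role`, `species`,
#'   `replicate`, `time_h`, `count`, `volume_ul`, `density_cells_per_ml`,
#'   `fluorescence_rfu`), plus `truth`, `design`, `seed`.
#' @examples
#' ex <- generate_experiment(default_truth(), experiment_design(), seed = 1)
#' head(ex$data)
#' @export
generate_experiment <- function(truth, design = experiment_design(),
                                seed = 1L, observe = TRUE) {
  stopifnot(inherits(truth, "sim_truth"),
            inherits(design, "experiment_design"))
  species <- design$species %||% truth$species
  stopifnot(all(species %in% truth$species), length(species) >= 1L)
  st <- design$sampling_times
  rows <- list()
  add_flask <- function(flask_id, pair_id, treatment, role, species,
                        replicate, latent) {
    if (observe) {
      vol <- counting_volume(latent, design$volume_ul, design$target_count)
      set.seed(substream_seed(seed, paste(flask_id, species, sep = "|")))
      obs <- observe_counts(latent, vol)
    } else {
      obs <- data.frame(count = NA_integer_, volume_ul = NA_real_,
                        density_cells_per_ml = latent)
    }
    rows[[length(rows) + 1L]] <<- data.frame(
      flask_id = flask_id, pair_id = pair_id, treatment = treatment,
      role = role, species = species, replicate = replicate,
      time_h = st, count = obs$count, volume_ul = obs$volume_ul,
      density_cells_per_ml = obs$density_cells_per_ml,
      fluorescence_rfu = NA_real_)
  }

  for (tr in design$treatments) {
    p <- treatment_params(truth, tr)
    # monocultures: logistic growth from the monoculture inoculum
    for (sp in species) {
      latent <- logistic_growth(st, p$mu[sp], p$K[sp],
                                design$monoculture_inoculum)
      for (r in seq_len(design$replicates))
        add_flask(sprintf("%s_mono_%s_r%d", tr, sp, r), sp, tr,
                  "monoculture", sp, r, latent)
    }
    # invasions: resident pre-grown alone, invader added at low density
    for (res in species) {
      res_at_invasion <- logistic_growth(design$pre_invasion_h, p$mu[res],
                                         p$K[res],
                                         design$monoculture_inoculum)
      for (inv in setdiff(species, res)) {
        n0 <- setNames(c(design$invader_inoculum, res_at_invasion),
                       c(inv, res))
        traj <- simulate_trajectory(truth, c(inv, res), treatment = tr,
                                    n0 = n0, times = st)
        pair_id <- paste0(inv, "->", res)
        for (r in seq_len(design$replicates)) {
          fid <- sprintf("%s_%s_into_%s_r%d", tr, inv, res, r)
          add_flask(fid, pair_id, tr, "invader", inv, r, traj[[inv]])
          add_flask(fid, pair_id, tr, "resident", res, r, traj[[res]])
        }
      }
    }
  }
  data <- do.call(rbind, rows)
  rownames(data) <- NULL
  key <- paste(data$flask_id, data$species, data$time_h)
  if (anyDuplicated(key))
    stop("duplicate (flask, species, time) keys generated: design bug",
         call. = FALSE)
  structure(list(data = data, truth = truth, design = design, seed = seed),
            class = "invadyn_experiment")
}

#' @export
print.invadyn_experiment <- function(x, ...) {
  d <- x$data
  cat(sprintf(
    "<invadyn_experiment> %d rows, %d flasks (%d invasion), seed %s\n",
    nrow(d), length(unique(d$flask_id)),
    length(unique(d$flask_id[d$role != "monoculture"])), x$seed))
  invisible(x)
}

#' Generate a synthetic isolate-panel growth assay
#'
#' Emulates plate-reader growth experiments in which axenic hosts are grown
#' alone or with a single bacterial isolate, and population density is
#' tracked by chlorophyll-a fluorescence every couple of days.  Latent
#' growth is logistic; an isolate multiplies the host's rate by `m_mu` and
#' its carrying capacity by `m_K`.  Fluorescence is
#' `density * gain * exp(N(0, sigma^2))` (multiplicative lognormal error,
#' default sigma 0.05), reflecting that fluorescence tracks density only up
#' to cell-condition noise.
#'
#' @param hosts character vector of host species labels.
#' @param isolates character vector of isolate labels.
#' @param mu,K named (per host) or scalar logistic parameters for the
#'   axenic hosts.
#' @param m_mu,m_K matrices (`isolates` x `hosts`) or scalars: the
#'   multiplicative isolate effects.
#' @param n0 inoculum density, cells per ml (default 5000).
#' @param days sampling days (default every 2 days for 24 days).
#' @param replicates wells per treatment (default 3).
#' @param sigma lognormal fluorescence noise (sdlog), default 0.05.
#' @param gain fluorescence per cell per ml (default 0.002 RFU).
#' @param seed integer seed.
#' @return tidy data frame: `host`, `treatment` (`"axenic"` or isolate
#'   label), `replicate`, `day`, `time_h`, `fluorescence_rfu`, with the
#'   latent parameters attached as attribute `"truth"`.
#' @export
generate_isolate_panel <- function(hosts, isolates, mu = 0.1, K = 1e6,
                                   m_mu = 1, m_K = 1, n0 = 5000,
                                   days = seq(0, 24, by = 2),
                                   replicates = 3L, sigma = 0.05,
                                   gain = 0.002, seed = 1L) {
  nh <- length(hosts); ni <- length(isolates)
  if (length(mu) == 1L) mu <- setNames(rep(mu, nh), hosts)
  if (length(K) == 1L) K <- setNames(rep(K, nh), hosts)
  as_mat <- function(x, name) {
    if (length(x) == 1L) x <- matrix(x, ni, nh)
    x <- as.matrix(x)
    if (!all(dim(x) == c(ni, nh)))
      stop(sprintf("'%s' must be scalar or %dx%d", name, ni, nh),
           call. = FALSE)
    dimnames(x) <- list(isolates, hosts)
    x
  }
  m_mu <- as_mat(m_mu, "m_mu"); m_K <- as_mat(m_K, "m_K")
  treatments <- c("axenic", isolates)
  rows <- list()
  for (h in hosts) for (tr in treatments) {
    mu_t <- if (tr == "axenic") mu[h] else mu[h] * m_mu[tr, h]
    K_t <- if (tr == "axenic") K[h] else K[h] * m_K[tr, h]
    latent <- logistic_growth(days * 24, mu_t, K_t, n0)
    for (r in seq_len(replicates)) {
      set.seed(substream_seed(seed, paste("panel", h, tr, r, sep = "|")))
      fl <- latent * gain * rlnorm(length(latent), 0, sigma)
      rows[[length(rows) + 1L]] <- data.frame(
        host = h, treatment = tr, replicate = r, day = days,
        time_h = days * 24, fluorescence_rfu = fl)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "truth") <- list(mu = mu, K = K, m_mu = m_mu, m_K = m_K,
                             n0 = n0, sigma = sigma, gain = gain,
                             seed = seed)
  out
}
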