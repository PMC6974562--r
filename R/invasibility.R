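#' Sensitivity to interspecific interaction
#'
#' \deqn{S_i = (\mu_{i,alone} - \mu_{i,invading}) / \mu_{i,alone}}
#' the proportional change in a species' per-capita growth rate when it
#' invades an established heterospecific population relative to growing
#' alone.  `S_i > 0` indicates competition (growth depressed), `S_i < 0`
#' facilitation, and `S_i = 1` complete suppression of invader growth.
#'
#' @param mu_alone monoculture rate(s), per hour, nonzero.
#' @param mu_invading invasion rate(s), per hour.
#' @return the sensitivity (dimensionless), vectorized over inputs.
#' @examples
#' compute_sensitivity(0.10, 0.05)   # 0.5: competition
#' compute_sensitivity(0.08, 0.12)   # -0.5: facilitation
#' @export
compute_sensitivity <- function(mu_alone, mu_invading) {
  if (any(mu_alone == 0))
    stop("undefined sensitivity: mu_alone is zero", call. = FALSE)
  (mu_alone - mu_invading) / mu_alone
}

#' Build the table of sensitivity records from growth-rate fits
#'
#' Pairs every invasion-rate estimate with monoculture-rate estimates of
#' the same species under the same treatment and evaluates
#' [compute_sensitivity()] for each pairing.  Under the default `"cross"`
#' pairing every monoculture replicate is combined with every invasion
#' replicate (3 x 3 = 9 records per directed pair and treatment at the
#' standard triplicate design); `"matched"` pairs replicates by number
#' (3 records).
#'
#' @param fits fit table from [fit_growth()] (columns `species`,
#'   `treatment`, `role`, `replicate`, `pair_id`, `mu`, `measurement`).
#' @param pairing `"cross"` or `"matched"`.
#' @param allow_fluorescence sensitivities are computed from cell-count
#'   rates only unless this is `TRUE`, since fluorescence responds to cell
#'   properties other than density.
#' @return data frame of sensitivity records: `invader`, `resident`,
#'   `treatment`, `pairing_id`, `mono_replicate`, `invasion_replicate`,
#'   `mu_alone`, `mu_invading`, `s_i`.
#' @export
sensitivity_table <- function(fits, pairing = c("cross", "matched"),
                              allow_fluorescence = FALSE) {
  pairing <- match.arg(pairing)
  need <- c("species", "treatment", "role", "replicate", "pair_id", "mu")
  if (!all(need %in% names(fits)))
    stop("'fits' lacks columns: ",
         paste(setdiff(need, names(fits)), collapse = ", "), call. = FALSE)
  if (!allow_fluorescence && "measurement" %in% names(fits) &&
      any(fits$measurement == "fluorescence"))
    stop(paste("fluorescence-derived rates refused for sensitivity",
               "computation (set allow_fluorescence = TRUE to override)"),
         call. = FALSE)
  inv <- fits[fits$role == "invader", , drop = FALSE]
  mono <- fits[fits$role == "monoculture", , drop = FALSE]
  if (nrow(inv) == 0L) stop("no invader fits", call. = FALSE)
  recs <- list()
  for (i in seq_len(nrow(inv))) {
    sp <- inv$species[i]; tr <- inv$treatment[i]
    resident <- sub("^.*->", "", inv$pair_id[i])
    m <- mono[mono$species == sp & mono$treatment == tr, , drop = FALSE]
    if (nrow(m) == 0L)
      stop(sprintf(
        "no monoculture fit for species '%s' under treatment '%s'", sp, tr),
        call. = FALSE)
    if (pairing == "matched") {
      m <- m[m$replicate == inv$replicate[i], , drop = FALSE]
      if (nrow(m) == 0L)
        stop(sprintf(
          "no matched monoculture replicate %s for species '%s' (%s)",
          inv$replicate[i], sp, tr), call. = FALSE)
    }
    recs[[length(recs) + 1L]] <- data.frame(
      invader = sp, resident = resident, treatment = tr,
      pairing_id = sprintf("m%s_i%s", m$replicate, inv$replicate[i]),
      mono_replicate = m$replicate, invasion_replicate = inv$replicate[i],
      mu_alone = m$mu, mu_invading = inv$mu[i],
      s_i = compute_sensitivity(m$mu, inv$mu[i]))
  }
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out
}

#' Treatment contrast of sensitivity per directed species pair
#'
#' For each directed pair (invader, resident) computes the difference of
#' mean sensitivity between treatments, xenic minus axenic (negative
#' values meaning the bacteria reduced the host's sensitivity to the
#' interaction), and tests it.  The default test forms xenic-minus-axenic
#' differences between records with matching pairing ids (after sorting)
#' and applies a one-sample t test against zero; `"two_sample"` runs a
#' Welch t test of the two treatments' records instead.
#'
#' @param records sensitivity records from [sensitivity_table()].
#' @param method `"one_sample"` (paired differences) or `"two_sample"`
#'   (Welch).
#' @return data frame with one row per directed pair: `invader`,
#'   `resident`, `mean_axenic`, `mean_xenic`, `delta` (xenic - axenic),
#'   `t`, `df`, `p_value`, `method`, `test_refused` (TRUE when a single
#'   difference leaves no degrees of freedom).
#' @export
delta_sensitivity <- function(records,
                              method = c("one_sample", "two_sample")) {
  method <- match.arg(method)
  pairs <- unique(records[c("invader", "resident")])
  out <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    sub <- records[records$invader == pairs$invader[i] &
                     records$resident == pairs$resident[i], , drop = FALSE]
    for (tr in c("axenic", "xenic"))
      if (!any(sub$treatment == tr))
        stop(sprintf("treatment '%s' missing for directed pair %s->%s",
                     tr, pairs$invader[i], pairs$resident[i]),
             call. = FALSE)
    ax <- sub[sub$treatment == "axenic", , drop = FALSE]
    xe <- sub[sub$treatment == "xenic", , drop = FALSE]
    ax <- ax[order(ax$pairing_id), ]; xe <- xe[order(xe$pairing_id), ]
    delta <- mean(xe$s_i) - mean(ax$s_i)
    refused <- FALSE; tt <- list(statistic = NA_real_,
                                 parameter = NA_real_, p.value = NA_real_)
    if (method == "one_sample") {
      if (!identical(ax$pairing_id, xe$pairing_id))
        stop(sprintf("pairing ids differ between treatments for %s->%s",
                     pairs$invader[i], pairs$resident[i]), call. = FALSE)
      d <- xe$s_i - ax$s_i
      if (length(d) < 2L || var(d) == 0) {
        refused <- TRUE
        tt$parameter <- length(d) - 1L
      } else tt <- t.test(d, mu = 0)
    } else {
      if (nrow(ax) < 2L || nrow(xe) < 2L) refused <- TRUE
      else tt <- t.test(xe$s_i, ax$s_i, var.equal = FALSE)
    }
    out[[i]] <- data.frame(
      invader = pairs$invader[i], resident = pairs$resident[i],
      mean_axenic = mean(ax$s_i), mean_xenic = mean(xe$s_i),
      delta = delta,
      t = unname(tt$statistic), df = unname(tt$parameter),
      p_value = unname(tt$p.value),
      method = method, test_refused = refused)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
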