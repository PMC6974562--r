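#' Niche difference of a species pair
#'
#' \deqn{ND = 1 - \sqrt{S_A S_B}} one minus the geometric mean of the two
#' directional sensitivities.  Defined only when both sensitivities are
#' strictly positive (the theory's domain); outside that domain the result
#' is `NA` with attribute `"reason" = "theory-out-of-domain"`, never a
#' number.
#'
#' @param s_a,s_b the two directional sensitivities (vectorized).
#' @return ND, always below 1; positive iff `s_a * s_b < 1`.
#' @export
niche_difference <- function(s_a, s_b) {
  out <- ifelse(s_a > 0 & s_b > 0, 1 - sqrt(s_a * s_b), NA_real_)
  if (anyNA(out)) attr(out, "reason") <- "theory-out-of-domain"
  out
}

#' Relative fitness difference of a species pair
#'
#' \deqn{RFD = \sqrt{S_A / S_B}, \quad S_A \ge S_B} the square root of the
#' ratio of the larger to the smaller sensitivity.  The inputs are ordered
#' internally, so the result is invariant to species labelling and always
#' at least 1.  Defined only for strictly positive sensitivities.
#'
#' @param s_a,s_b the two directional sensitivities (vectorized).
#' @return RFD >= 1, or `NA` with attribute
#'   `"reason" = "theory-out-of-domain"` when a sensitivity is nonpositive.
#' @export
relative_fitness_difference <- function(s_a, s_b) {
  hi <- pmax(s_a, s_b); lo <- pmin(s_a, s_b)
  out <- ifelse(lo > 0, sqrt(hi / lo), NA_real_)
  if (anyNA(out)) attr(out, "reason") <- "theory-out-of-domain"
  out
}

#' Classify coexistence from niche and relative fitness differences
#'
#' The invasion criterion predicts exclusion when
#' \eqn{RFD > 1/(1 - ND)} and coexistence when \eqn{RFD < 1/(1 - ND)}.
#' Values within a relative tolerance `eps` of the threshold are labelled
#' `"boundary"` so that float-exact ties classify deterministically.
#'
#' @param nd niche difference(s), below 1.
#' @param rfd relative fitness difference(s), at least 1.
#' @param eps relative half-width of the boundary band (default 1e-9).
#' @return character vector: `"coexistence"`, `"exclusion"`, `"boundary"`,
#'   or `"undefined"` for `NA` inputs.
#' @examples
#' classify_coexistence(0.82, 1.98)  # "coexistence": 1.98 < 1/(1-0.82)
#' @export
classify_coexistence <- function(nd, rfd, eps = 1e-9) {
  n <- max(length(nd), length(rfd))
  nd <- rep_len(as.numeric(nd), n); rfd <- rep_len(as.numeric(rfd), n)
  out <- rep("undefined", n)
  ok <- !is.na(nd) & !is.na(rfd)
  if (any(nd[ok] >= 1))
    stop("ND >= 1: exclusion threshold 1/(1-ND) undefined", call. = FALSE)
  thr <- 1 / (1 - nd[ok])
  cls <- ifelse(rfd[ok] > thr * (1 + eps), "exclusion",
                ifelse(rfd[ok] < thr * (1 - eps), "coexistence",
                       "boundary"))
  out[ok] <- cls
  out
}

#' Per-pairing ND/RFD table with treatment ANOVA
#'
#' Joins the two invasion directions of a species pair record-by-record
#' (matching replicate pairing ids within treatment), computes ND, RFD and
#' the coexistence classification for every pairing whose two
#' sensitivities are both positive, and runs a one-way ANOVA of treatment
#' on ND and on RFD.  Pairings with a nonpositive sensitivity are excluded
#' from the table (the theory does not apply there) and counted in
#' `n_excluded`.  With the standard triplicate design and cross pairing, 9
#' pairings per treatment give the treatment ANOVA 1 and 16 degrees of
#' freedom.
#'
#' @param records sensitivity records from [sensitivity_table()].
#' @param species_a,species_b the pair's species labels (unordered).
#' @param eps boundary tolerance for [classify_coexistence()].
#' @return list with `pairs` (data frame: `species_a`, `species_b`,
#'   `treatment`, `pairing_id`, `s_a`, `s_b`, `nd`, `rfd`,
#'   `classification`, with `s_a >= s_b`), `anova` (data frame with one
#'   row per response), and `n_excluded`.
#' @export
nd_rfd_table <- function(records, species_a, species_b, eps = 1e-9) {
  species_a <- unname(as.character(species_a))
  species_b <- unname(as.character(species_b))
  ab <- records[records$invader == species_a &
                  records$resident == species_b, , drop = FALSE]
  ba <- records[records$invader == species_b &
                  records$resident == species_a, , drop = FALSE]
  if (nrow(ab) == 0L)
    stop(sprintf("invasion direction %s->%s missing", species_a, species_b),
         call. = FALSE)
  if (nrow(ba) == 0L)
    stop(sprintf("invasion direction %s->%s missing", species_b, species_a),
         call. = FALSE)
  merged <- merge(
    ab[c("treatment", "pairing_id", "s_i")],
    ba[c("treatment", "pairing_id", "s_i")],
    by = c("treatment", "pairing_id"), suffixes = c("_ab", "_ba"))
  if (nrow(merged) == 0L)
    stop("no matching replicate pairings between the two directions",
         call. = FALSE)
  pos <- merged$s_i_ab > 0 & merged$s_i_ba > 0
  n_excluded <- sum(!pos)
  kept <- merged[pos, , drop = FALSE]
  rownames(kept) <- NULL
  if (nrow(kept)) {
    hi <- pmax(kept$s_i_ab, kept$s_i_ba)
    lo <- pmin(kept$s_i_ab, kept$s_i_ba)
    nd <- as.numeric(niche_difference(hi, lo))
    rfd <- as.numeric(relative_fitness_difference(hi, lo))
    pairs <- data.frame(
      species_a = species_a, species_b = species_b,
      treatment = kept$treatment, pairing_id = kept$pairing_id,
      s_a = hi, s_b = lo, nd = nd, rfd = rfd,
      classification = classify_coexistence(nd, rfd, eps))
  } else {
    pairs <- data.frame(species_a = character(), species_b = character(),
                        treatment = character(), pairing_id = character(),
                        s_a = numeric(), s_b = numeric(), nd = numeric(),
                        rfd = numeric(), classification = character())
  }
  anova_tab <- NULL
  if (nrow(pairs) && length(unique(pairs$treatment)) >= 2L) {
    one_way <- function(resp) {
      a <- anova(lm(pairs[[resp]] ~ factor(pairs$treatment)))
      data.frame(response = resp, f = a$`F value`[1L],
                 df_num = a$Df[1L], df_den = a$Df[2L],
                 p_value = a$`Pr(>F)`[1L])
    }
    anova_tab <- rbind(one_way("nd"), one_way("rfd"))
    rownames(anova_tab) <- NULL
  }
  list(pairs = pairs, anova = anova_tab, n_excluded = n_excluded)
}
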