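#' Two-way ANOVA with sequential sums of squares
#'
#' Fits `response ~ factor_a * factor_b` by least squares and returns the
#' sequential (Type I) ANOVA table in the order first factor, second
#' factor, interaction --- the convention for reporting a treatment term
#' first; balanced designs make the ordering immaterial.  If the second
#' factor is absent or has a single level the call degenerates to a
#' one-way ANOVA on the first factor.
#'
#' @param data data frame.
#' @param response name of the numeric response column.
#' @param factor_a,factor_b names of the factor columns (`factor_b`
#'   optional).
#' @param interaction include the interaction term (default `TRUE`).
#' @return data frame with one row per term: `term`, `df`, `sum_sq`,
#'   `mean_sq`, `f`, `df_den`, `p_value`, `ss_type = "sequential"`.
#' @export
two_way_anova <- function(data, response, factor_a, factor_b = NULL,
                          interaction = TRUE) {
  stopifnot(response %in% names(data), factor_a %in% names(data))
  y <- data[[response]]
  a <- factor(data[[factor_a]])
  if (nlevels(a) < 2L)
    stop(sprintf("factor '%s' needs at least 2 levels", factor_a),
         call. = FALSE)
  two_way <- !is.null(factor_b) && factor_b %in% names(data) &&
    nlevels(factor(data[[factor_b]])) >= 2L
  if (two_way) {
    b <- factor(data[[factor_b]])
    cells <- table(a, b)
    if (any(cells == 0L)) {
      empty <- which(cells == 0L, arr.ind = TRUE)
      stop("empty design cells: ",
           paste(sprintf("(%s, %s)", rownames(cells)[empty[, 1L]],
                         colnames(cells)[empty[, 2L]]), collapse = ", "),
           call. = FALSE)
    }
    fml <- if (interaction) y ~ a * b else y ~ a + b
    term_names <- c(factor_a, factor_b,
                    if (interaction) paste(factor_a, factor_b, sep = ":"))
  } else {
    fml <- y ~ a
    term_names <- factor_a
  }
  tab <- anova(lm(fml))
  k <- nrow(tab) - 1L
  df_den <- tab$Df[k + 1L]
  out <- data.frame(
    term = term_names[seq_len(k)],
    df = tab$Df[seq_len(k)],
    sum_sq = tab$`Sum Sq`[seq_len(k)],
    mean_sq = tab$`Mean Sq`[seq_len(k)],
    f = tab$`F value`[seq_len(k)],
    df_den = df_den,
    p_value = tab$`Pr(>F)`[seq_len(k)],
    ss_type = "sequential")
  rownames(out) <- NULL
  out
}

#' Two-sample t test on growth rates
#'
#' Welch's t test by default (unequal variances); the pooled-variance form
#' is available with `var_equal = TRUE`.  Two-sided.
#'
#' @param x,y numeric vectors, each with at least 2 values.
#' @param var_equal pool the variances (default `FALSE`).
#' @return data frame: `t`, `df`, `p_value`, `mean_x`, `mean_y`, `method`.
#' @export
t_two_sample <- function(x, y, var_equal = FALSE) {
  if (length(x) < 2L || length(y) < 2L)
    stop("each group needs at least 2 values", call. = FALSE)
  tt <- t.test(x, y, var.equal = var_equal)
  data.frame(t = unname(tt$statistic), df = unname(tt$parameter),
             p_value = tt$p.value, mean_x = mean(x), mean_y = mean(y),
             method = if (var_equal) "pooled" else "welch")
}

#' Per-isolate ANOVA of an isolate-panel growth assay
#'
#' For every (host, isolate) panel, compares the isolate treatment against
#' the host's axenic control with a two-way fixed-effects ANOVA of
#' fluorescence on sampling day and bacterial treatment (both factors,
#' additive).  Days missing from either treatment are dropped
#' (complete-case) with a warning.  Significance is flagged at p < 0.05
#' and a weak trend at p < 0.10.
#'
#' @param panel tidy data frame from [generate_isolate_panel()] (columns
#'   `host`, `treatment`, `day`, `fluorescence_rfu`).
#' @param alpha significance level (default 0.05).
#' @return data frame with one row per (host, isolate): F, df and p for
#'   the treatment and day terms, plus `significant` and `weak_trend`
#'   flags for the treatment effect.
#' @export
isolate_panel_anova <- function(panel, alpha = 0.05) {
  need <- c("host", "treatment", "day", "fluorescence_rfu")
  if (!all(need %in% names(panel)))
    stop("'panel' lacks columns: ",
         paste(setdiff(need, names(panel)), collapse = ", "), call. = FALSE)
  isolates <- setdiff(unique(panel$treatment), "axenic")
  if (length(isolates) == 0L)
    stop("panel contains no isolate treatment (only axenic)", call. = FALSE)
  out <- list()
  for (h in unique(panel$host)) for (iso in isolates) {
    sub <- panel[panel$host == h &
                   panel$treatment %in% c("axenic", iso), , drop = FALSE]
    if (!all(c("axenic", iso) %in% sub$treatment)) next
    if (length(unique(sub$day)) < 2L)
      stop("need at least 2 sampling days", call. = FALSE)
    days_ok <- Reduce(intersect,
                      tapply(sub$day, sub$treatment, unique, simplify = FALSE))
    if (length(days_ok) < length(unique(sub$day))) {
      warning(sprintf(
        "host %s, isolate %s: dropping days absent from one treatment",
        h, iso), call. = FALSE)
      sub <- sub[sub$day %in% days_ok, , drop = FALSE]
    }
    a <- anova(lm(fluorescence_rfu ~ factor(day) + factor(treatment),
                  data = sub))
    df_den <- a$Df[3L]
    out[[length(out) + 1L]] <- data.frame(
      host = h, isolate = iso,
      f_day = a$`F value`[1L], df_day = a$Df[1L],
      p_day = a$`Pr(>F)`[1L],
      f_treatment = a$`F value`[2L], df_treatment = a$Df[2L],
      df_den = df_den, p_treatment = a$`Pr(>F)`[2L],
      significant = a$`Pr(>F)`[2L] < alpha,
      weak_trend = a$`Pr(>F)`[2L] < 0.10)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
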