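#' Write a synthetic experiment to disk
#'
#' Emits the tidy CSV (`experiment.csv`) and a JSON sidecar
#' (`truth.json`) holding the ground-truth parameters, the design and the
#' master seed, so the dataset can be regenerated or audited.
#'
#' @param experiment an `invadyn_experiment` from [generate_experiment()].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_experiment <- function(experiment, dir) {
  stopifnot(inherits(experiment, "invadyn_experiment"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  csv <- file.path(dir, "experiment.csv")
  json <- file.path(dir, "truth.json")
  write.csv(experiment$data, csv, row.names = FALSE)
  truth <- experiment$truth
  sidecar <- list(
    truth = list(species = truth$species, mu = as.list(truth$mu),
                 K = as.list(truth$K), alpha = truth$alpha,
                 m_mu = as.list(truth$m_mu), m_K = as.list(truth$m_K),
                 m_alpha = truth$m_alpha, n0 = as.list(truth$n0)),
    design = unclass(experiment$design),
    seed = experiment$seed)
  jsonlite::write_json(sidecar, json, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(csv = csv, json = json))
}

required_columns <- c("flask_id", "pair_id", "treatment", "role", "species",
                      "replicate", "time_h", "density_cells_per_ml")

#' Read and validate a tidy density time-series CSV
#'
#' Reads a long-format CSV in the package's dialect (one row per flask,
#' species and time point) or user data mapped onto it, and validates it:
#' required columns present, times in hours and numeric, densities
#' nonnegative, no duplicate (flask, species, time) keys.  Malformed rows
#' are reported with their file line numbers.
#'
#' @param path CSV file path.
#' @param mapping optional named character vector renaming user columns to
#'   the canonical names, e.g. `c(density_cells_per_ml = "dens")` maps the
#'   file's `dens` column onto `density_cells_per_ml`.
#' @return validated data frame with the canonical columns (row order
#'   normalized by flask, species, time).
#' @export
read_tidy_csv <- function(path, mapping = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(mapping)) {
    for (canon in names(mapping)) {
      user <- mapping[[canon]]
      if (!user %in% names(raw))
        stop(sprintf("mapped column '%s' not in file", user), call. = FALSE)
      names(raw)[names(raw) == user] <- canon
    }
  }
  missing <- setdiff(required_columns, names(raw))
  if (length(missing))
    stop("missing required columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (!"fluorescence_rfu" %in% names(raw)) raw$fluorescence_rfu <- NA_real_
  raw$fluorescence_rfu <- as.numeric(raw$fluorescence_rfu)
  line <- seq_len(nrow(raw)) + 1L  # header is line 1
  bad_time <- !is.finite(raw$time_h)
  if (any(bad_time))
    stop("non-numeric time_h on line(s): ",
         paste(line[bad_time], collapse = ", "), call. = FALSE)
  bad_dens <- !is.na(raw$density_cells_per_ml) &
    (!is.finite(raw$density_cells_per_ml) | raw$density_cells_per_ml < 0)
  if (any(bad_dens))
    stop("negative or non-numeric density on line(s): ",
         paste(line[bad_dens], collapse = ", "), call. = FALSE)
  key <- paste(raw$flask_id, raw$species, raw$time_h)
  if (anyDuplicated(key)) {
    dup <- line[duplicated(key)]
    stop("duplicate (flask, species, time) keys on line(s): ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  raw[order(raw$flask_id, raw$species, raw$time_h), , drop = FALSE]
}

#' Pipeline configuration
#'
#' Method choices and bookkeeping for [run_pipeline()].  Round-trips
#' losslessly through JSON ([jsonlite]), and every pipeline run records a
#' manifest with this configuration, its hash, the seed and the package
#' version.
#'
#' @param window easylinear window size `h` (observations; default 3, the
#'   first-three-samples convention).
#' @param pairing replicate pairing for [sensitivity_table()]: `"cross"`
#'   or `"matched"`.
#' @param variance `"welch"` or `"pooled"` for the per-combination
#'   two-sample t tests.
#' @param eps boundary tolerance for [classify_coexistence()].
#' @param alpha significance level for reported flags.
#' @param seed integer seed recorded in the manifest.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(window = 3L, pairing = "cross",
                            variance = "welch", eps = 1e-9, alpha = 0.05,
                            seed = 1L) {
  pairing <- match.arg(pairing, c("cross", "matched"))
  variance <- match.arg(variance, c("welch", "pooled"))
  structure(list(window = as.integer(window), pairing = pairing,
                 variance = variance, eps = eps, alpha = alpha,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

config_to_json <- function(config) {
  jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA)
}

#' @rdname pipeline_config
#' @param json a JSON string or file produced from a `pipeline_config`.
#' @export
config_from_json <- function(json) {
  x <- jsonlite::fromJSON(json)
  do.call(pipeline_config, x)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("%s stage: %s", name, conditionMessage(e)), call. = FALSE))
}

#' Run the full mutual-invasibility analysis pipeline
#'
#' Orchestrates all stages on a tidy dataset: growth-rate fits
#' (easylinear) for monocultures and invaders, the sensitivity table and
#' per-pair treatment contrasts, the growth-rate linear model
#' (status x combination, sequential SS) with per-combination two-sample
#' t tests, the sensitivity linear model over invasion combinations, and
#' ND/RFD coexistence analysis for every unordered species pair whose
#' sensitivities are consistently positive in both directions and
#' treatments.  Deterministic given (data, config).
#'
#' @param data tidy data frame ([generate_experiment()]'s `$data` or
#'   [read_tidy_csv()] output).
#' @param config a [pipeline_config()].
#' @return object of class `invadyn_results`: list with `fits`,
#'   `sensitivities`, `contrasts`, `growth_anova`, `growth_t_tests`,
#'   `sensitivity_anova`, `coexistence` (per-pair list with `pairs`,
#'   `anova`, `n_excluded`), `skipped_pairs`, `manifest`.
#' @export
run_pipeline <- function(data, config = pipeline_config()) {
  stopifnot(is.data.frame(data), inherits(config, "pipeline_config"))
  fits <- stage("growth_inference",
                fit_growth(data, method = "easylinear",
                           window = config$window))
  sens <- stage("invasibility",
                sensitivity_table(fits, pairing = config$pairing))
  contrasts <- stage("invasibility", delta_sensitivity(sens))

  growth_anova <- stage("stats", {
    fits$status <- fits$treatment
    two_way_anova(fits, "mu", "status", "combination")
  })
  growth_t <- stage("stats", {
    combos <- unique(fits$combination)
    res <- lapply(combos, function(cb) {
      sub <- fits[fits$combination == cb, ]
      x <- sub$mu[sub$treatment == "xenic"]
      y <- sub$mu[sub$treatment == "axenic"]
      # zero-variance cells (e.g. noise-free simulations) yield a flagged
      # NA row instead of a hard failure
      tt <- tryCatch(
        t_two_sample(x, y, var_equal = config$variance == "pooled"),
        error = function(e) data.frame(
          t = NA_real_, df = NA_real_, p_value = NA_real_,
          mean_x = mean(x), mean_y = mean(y),
          method = config$variance))
      cbind(data.frame(combination = cb), tt)
    })
    out <- do.call(rbind, res)
    out$significant <- out$p_value < config$alpha
    out$weak_trend <- out$p_value < 0.10
    out
  })
  sens_anova <- stage("stats", {
    sens$status <- sens$treatment
    sens$combination <- paste0(sens$invader, "->", sens$resident)
    two_way_anova(sens, "s_i", "status", "combination")
  })

  coexistence <- list(); skipped <- character()
  pairs <- unique(t(apply(unique(sens[c("invader", "resident")]), 1L, sort)))
  dimnames(pairs) <- NULL
  for (i in seq_len(nrow(pairs))) {
    a <- pairs[i, 1L]; b <- pairs[i, 2L]
    label <- paste(a, b, sep = "~")
    sub <- sens[(sens$invader == a & sens$resident == b) |
                  (sens$invader == b & sens$resident == a), ]
    if (all(sub$s_i > 0)) {
      coexistence[[label]] <- stage(
        "coexistence", nd_rfd_table(sens, a, b, eps = config$eps))
    } else {
      skipped <- c(skipped, label)
    }
  }

  manifest <- list(
    package = "invadyn",
    version = as.character(packageVersion("invadyn")),
    config = unclass(config),
    config_hash = config_hash(as.character(config_to_json(config))),
    seed = config$seed,
    n_input_rows = nrow(data),
    n_fits = nrow(fits),
    n_sensitivity_records = nrow(sens))
  structure(
    list(fits = fits, sensitivities = sens, contrasts = contrasts,
         growth_anova = growth_anova, growth_t_tests = growth_t,
         sensitivity_anova = sens_anova, coexistence = coexistence,
         skipped_pairs = skipped, manifest = manifest),
    class = "invadyn_results")
}

#' @export
print.invadyn_results <- function(x, ...) {
  cat(sprintf(
    "<invadyn_results> %d fits, %d sensitivity records, %d directed pairs\n",
    nrow(x$fits), nrow(x$sensitivities), nrow(x$contrasts)))
  cat(sprintf("coexistence pairs analyzed: %d (skipped: %d)\n",
              length(x$coexistence), length(x$skipped_pairs)))
  invisible(x)
}

#' Write a pipeline result bundle to disk
#'
#' Emits one CSV per stage (`fits.csv`, `sensitivities.csv`,
#' `contrasts.csv`, `growth_anova.csv`, `growth_t_tests.csv`,
#' `sensitivity_anova.csv`, `coexistence.csv`), a `manifest.json` and a
#' short markdown `report.md` summarizing the treatment effects.
#'
#' @param results an `invadyn_results` from [run_pipeline()].
#' @param dir output directory (created if needed).
#' @return invisibly, the directory.
#' @export
write_bundle <- function(results, dir) {
  stopifnot(inherits(results, "invadyn_results"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, name)
    write.csv(df, file.path(dir, name), row.names = FALSE)
  wr(results$fits, "fits.csv")
  wr(results$sensitivities, "sensitivities.csv")
  wr(results$contrasts, "contrasts.csv")
  wr(results$growth_anova, "growth_anova.csv")
  wr(results$growth_t_tests, "growth_t_tests.csv")
  wr(results$sensitivity_anova, "sensitivity_anova.csv")
  co <- do.call(rbind, lapply(results$coexistence, `[[`, "pairs"))
  if (!is.null(co)) wr(co, "coexistence.csv")
  jsonlite::write_json(results$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  rep <- c(
    "# Mutual invasibility analysis report", "",
    sprintf("- growth-rate fits: %d", nrow(results$fits)),
    sprintf("- sensitivity records: %d", nrow(results$sensitivities)),
    sprintf("- directed pairs with significant treatment contrast: %d of %d",
            sum(results$contrasts$p_value < results$manifest$config$alpha,
                na.rm = TRUE), nrow(results$contrasts)),
    sprintf("- coexistence-eligible species pairs: %s",
            if (length(results$coexistence))
              paste(names(results$coexistence), collapse = ", ")
            else "none"),
    "")
  for (label in names(results$coexistence)) {
    cx <- results$coexistence[[label]]
    for (tr in unique(cx$pairs$treatment)) {
      sub <- cx$pairs[cx$pairs$treatment == tr, ]
      rep <- c(rep, sprintf(
        "- %s [%s]: mean ND %.3f, mean RFD %.3f, classification %s",
        label, tr, mean(sub$nd), mean(sub$rfd),
        paste(unique(sub$classification), collapse = "/")))
    }
  }
  writeLines(rep, file.path(dir, "report.md"))
  invisible(dir)
}
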