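#' Cohort run configuration
#'
#' @param threshold Percent-predicted threshold for normal capacity.
#' @param correction Apply the 11% modality correction (`TRUE`) or use
#'   native predictions (`FALSE`, the sensitivity analysis).
#' @param registry Equation registry (default the built-in one).
#' @param precision Decimals used when serializing percent values.
#' @param seed Optional integer echoed into the report for traceability
#'   (the pipeline itself is deterministic).
#' @return List of class `"vo2_config"`.
#' @export
cohort_config <- function(threshold = 80, correction = TRUE,
                          registry = default_registry(), precision = 1,
                          seed = NULL) {
  stopifnot(threshold > 0, threshold < 200, is.logical(correction))
  structure(list(threshold = threshold, correction = correction,
                 registry = registry, precision = precision, seed = seed),
            class = "vo2_config")
}

#' Corrected predictions and percent predicted for a whole cohort
#'
#' @param cohort Validated cohort.
#' @param registry Equation registry.
#' @param correction Apply the modality correction.
#' @return List with `predicted` and `pp`, both n x 6 matrices with equation
#'   ids as column names.
#' @export
cohort_percent_predicted <- function(cohort, registry = default_registry(),
                                     correction = TRUE) {
  cohort <- validate_cohort(as.data.frame(cohort))
  pred <- sapply(EQUATION_IDS, function(id) {
    spec <- registry[[id]]
    native <- predict_vo2(spec, cohort, registry)
    if (!correction) return(native)
    nm <- if (length(spec$native_modes) == 2L) {
      cohort$mode
    } else {
      rep(spec$native_modes, nrow(cohort))
    }
    apply_mode_correction(native, nm, cohort$mode)$corrected_value
  })
  pred <- matrix(pred, nrow = nrow(cohort),
                 dimnames = list(cohort$id, EQUATION_IDS))
  list(predicted = pred, pp = cohort$measured_vo2 / pred * 100)
}

#' Per-equation summary row
#'
#' Median (Q1-Q3) of predicted V̇O2 and percent predicted, plus the count and
#' fraction of subjects with continuous percent predicted below the
#' threshold (reduced capacity).
#'
#' @param pp_vector Continuous percent-predicted values.
#' @param predicted_vector Predicted V̇O2peak values, mL/min.
#' @param threshold Classification threshold.
#' @return One-row data frame.
#' @export
summarize_equation <- function(pp_vector, predicted_vector, threshold = 80) {
  if (length(pp_vector) != length(predicted_vector)) {
    stop("vectors must have equal length")
  }
  if (!length(pp_vector)) stop("empty input")
  qp <- stats::quantile(predicted_vector, c(0.25, 0.5, 0.75), names = FALSE)
  qq <- stats::quantile(pp_vector, c(0.25, 0.5, 0.75), names = FALSE)
  n_red <- sum(pp_vector < threshold)
  data.frame(pred_median = qp[2], pred_q1 = qp[1], pred_q3 = qp[3],
             pp_median = qq[2], pp_q1 = qq[1], pp_q3 = qq[3],
             n_reduced = n_red, frac_reduced = n_red / length(pp_vector))
}

#' Run the full inter-equation comparison over a cohort
#'
#' Orchestrates the whole pipeline: predictions for all six equations with
#' modality handling, percent-predicted classification at the configured
#' threshold, per-equation summaries, all 15 pairwise agreement analyses
#' (kappa with band, bidirectional reclassification, absolute-difference
#' quartiles, post hoc p-value), the Friedman test with Kendall's W, and one
#' difference regression per pair on the scaled covariates. Deterministic
#' given cohort and configuration.
#'
#' @param cohort Cohort data frame (validated on entry; any invalid subject
#'   aborts with a row-numbered report).
#' @param config A [cohort_config()].
#' @return List of class `"vo2_cohort_report"`: `per_equation` (6 rows),
#'   `pairwise` (15 rows), `friedman`, `regression` (long data frame, 15
#'   pairs x 8 terms; terms whose indicator is constant in the cohort — an
#'   absent race level, a single-mode cohort — are reported as NA),
#'   `fraction_reclassified_any` (share of subjects whose
#'   class flips in at least one pair), and `config` (threshold, correction
#'   flag, registry hash, quartile convention, post hoc method, precision,
#'   seed).
#' @export
run_cohort_comparison <- function(cohort, config = cohort_config()) {
  stopifnot(inherits(config, "vo2_config"))
  cohort <- validate_cohort(as.data.frame(cohort))
  if (nrow(cohort) < 2L) stop("cohort comparison needs at least 2 subjects")
  reg <- config$registry
  cp <- cohort_percent_predicted(cohort, reg, config$correction)
  pp <- cp$pp
  thr <- config$threshold

  per_eq <- do.call(rbind, lapply(EQUATION_IDS, function(id) {
    cbind(equation = id,
          summarize_equation(pp[, id], cp$predicted[, id], thr))
  }))

  posthoc <- pairwise_posthoc(pp)
  design <- build_design(cohort)
  pairs <- utils::combn(EQUATION_IDS, 2L)
  any_flip <- rep(FALSE, nrow(cohort))
  pair_rows <- vector("list", ncol(pairs))
  reg_rows <- vector("list", ncol(pairs))
  for (j in seq_len(ncol(pairs))) {
    a <- pairs[1, j]; b <- pairs[2, j]
    ka <- cohens_kappa(classify_capacity(pp[, a], thr),
                       classify_capacity(pp[, b], thr))
    rc <- reclassification(pp[, a], pp[, b], thr)
    ad <- absolute_difference_summary(pp[, a], pp[, b])
    any_flip <- any_flip |
      (classify_capacity(pp[, a], thr) != classify_capacity(pp[, b], thr))
    pair_rows[[j]] <- data.frame(
      from = a, to = b, kappa = ka, band = kappa_band(ka),
      n_to_normal = rc$n_to_normal, frac_to_normal = rc$frac_to_normal,
      n_to_reduced = rc$n_to_reduced, frac_to_reduced = rc$frac_to_reduced,
      ad_median = ad$ad_median, ad_q1 = ad$ad_q1, ad_q3 = ad$ad_q3,
      p_adj = posthoc$p_adj[j], stringsAsFactors = FALSE)
    # indicators constant in this cohort (e.g. no subjects of a race level,
    # single-mode cohorts) cannot be estimated; drop them from the fit but
    # keep the full term layout, reported as NA
    varying <- vapply(design, function(col) length(unique(col)) > 1L,
                      logical(1))
    fit <- fit_difference_model(pp[, a] - pp[, b], design[, varying,
                                                          drop = FALSE])
    co <- fit$coefficients
    all_terms <- c("(Intercept)", names(design))
    co <- co[match(all_terms, co$term), ]
    co$term <- all_terms
    reg_rows[[j]] <- cbind(from = a, to = b, co,
                           sig_05 = co$p_value < 0.05,
                           sig_001 = co$p_value < 0.001)
  }

  structure(list(
    per_equation = per_eq,
    pairwise = do.call(rbind, pair_rows),
    friedman = friedman_test(pp),
    regression = do.call(rbind, reg_rows),
    fraction_reclassified_any = mean(any_flip),
    n = nrow(cohort),
    config = list(threshold = thr, correction = config$correction,
                  registry_hash = registry_hash(reg),
                  quartile_convention = "linear interpolation (type 7)",
                  posthoc_method = posthoc$method[1],
                  precision = config$precision, seed = config$seed)
  ), class = "vo2_cohort_report")
}

#' @export
print.vo2_cohort_report <- function(x, ...) {
  cat("<vo2_cohort_report> n =", x$n, "subjects, threshold",
      x$config$threshold, "%, correction",
      if (x$config$correction) "on" else "off", "\n\n")
  pe <- x$per_equation
  cat("Per-equation (median percent predicted, % reduced):\n")
  for (i in seq_len(nrow(pe))) {
    cat(sprintf("  %-10s pp %5.1f%%  reduced %d (%.0f%%)\n", pe$equation[i],
                pe$pp_median[i], pe$n_reduced[i], 100 * pe$frac_reduced[i]))
  }
  cat(sprintf("\nReclassified in at least one pair: %.0f%%\n",
              100 * x$fraction_reclassified_any))
  print(x$friedman)
  invisible(x)
}

#' Write a cohort report bundle to disk
#'
#' Emits the three delimited tables (per-equation summary, pairwise
#' agreement, difference regressions) plus a structured-text report with the
#' configuration echo and overall statistics. Percent columns are rounded at
#' the configured precision only here, at serialization; the in-memory
#' report keeps full precision.
#'
#' @param report A `vo2_cohort_report`.
#' @param dir Output directory (created if needed).
#' @return Character vector of the files written, invisibly.
#' @export
write_cohort_report <- function(report, dir) {
  stopifnot(inherits(report, "vo2_cohort_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  prec <- report$config$precision %||% 1
  rnd <- function(df) {
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], round, digits = prec)
    df
  }
  f4 <- file.path(dir, "table4.csv")
  f5 <- file.path(dir, "table5.csv")
  f6 <- file.path(dir, "table6.csv")
  fr <- file.path(dir, "report.yaml")
  utils::write.csv(rnd(report$per_equation), f4, row.names = FALSE)
  utils::write.csv(rnd(report$pairwise), f5, row.names = FALSE)
  reg6 <- report$regression
  reg6$estimate <- round(reg6$estimate, 2)
  reg6$se <- round(reg6$se, 3)
  utils::write.csv(reg6, f6, row.names = FALSE)
  writeLines(yaml::as.yaml(list(
    n = report$n,
    config = report$config,
    friedman = unclass(report$friedman),
    fraction_reclassified_any = report$fraction_reclassified_any
  ), precision = 15), fr)
  invisible(c(f4, f5, f6, fr))
}
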