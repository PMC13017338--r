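#' Percent-predicted sweep over body mass
#'
#' Evaluates one equation's percent predicted for a subject over a grid of
#' body masses (default 50-150 kg), holding sex, height, age, test mode and
#' measured V̇O2peak constant — the data behind the comparison app's weight
#' plots. The returned table carries BMI alongside each grid weight
#' (`BMI = weight / (height/100)^2`), since at fixed height a weight sweep
#' and a BMI sweep are the same curve. Markers give the percent predicted at
#' the subject's ideal body weight and actual weight.
#'
#' Grid points outside the equation's weight domain are clipped with a
#' warning rather than failing.
#'
#' @param equation_id One of the six registry ids.
#' @param subject One-row cohort data frame.
#' @param registry Equation registry.
#' @param lo,hi Sweep bounds in kg (`lo < hi`).
#' @param step Grid spacing in kg.
#' @return Data frame of class `"sweep_curve"` with columns `equation`,
#'   `axis`, `grid_value`, `bmi`, `pp`; attribute `markers` holds a two-row
#'   data frame (`type` ideal/actual, `weight`, `pp`).
#' @export
weight_sweep <- function(equation_id, subject, registry = default_registry(),
                         lo = 50, hi = 150, step = 1) {
  subject <- validate_cohort(as.data.frame(subject))
  stopifnot(nrow(subject) == 1L, lo < hi)
  spec <- registry[[equation_id]]
  if (is.null(spec)) stop("unknown equation id '", equation_id, "'")
  wdom <- c(max(spec$domain$weight[1], SUBJECT_BOUNDS$weight[1]),
            min(spec$domain$weight[2], SUBJECT_BOUNDS$weight[2]))
  if (lo < wdom[1] || hi > wdom[2]) {
    warning("weight grid clipped to equation domain [", wdom[1], ", ",
            wdom[2], "] kg")
    lo <- max(lo, wdom[1]); hi <- min(hi, wdom[2])
  }
  grid <- seq(lo, hi, by = step)
  pp_at_weight <- function(w) {
    g <- subject[rep(1L, length(w)), ]
    g$weight <- w
    g$id <- sprintf("%s@%g", subject$id, w)
    suppressWarnings(
      cohort_percent_predicted(g, registry)$pp[, equation_id])
  }
  ibw <- ideal_body_weight(subject$sex, subject$height)
  markers <- data.frame(
    type = c("ideal", "actual"),
    weight = c(ibw, subject$weight),
    pp = unname(pp_at_weight(c(ibw, subject$weight))),
    stringsAsFactors = FALSE
  )
  out <- data.frame(equation = equation_id, axis = "weight",
                    grid_value = grid,
                    bmi = bmi(grid, subject$height),
                    pp = unname(pp_at_weight(grid)),
                    stringsAsFactors = FALSE)
  structure(out, markers = markers,
            class = c("sweep_curve", class(out)))
}

#' Percent-predicted sweep over age
#'
#' Same construction as [weight_sweep()] along the age axis: percent
#' predicted over `[age - delta, age + delta]` (intersected with the valid
#' age domain) with everything else held constant.
#'
#' @inheritParams weight_sweep
#' @param delta Half-width of the age window, years.
#' @param step Grid spacing in years.
#' @return A `"sweep_curve"` data frame (no weight markers on the age axis).
#' @export
age_sweep <- function(equation_id, subject, registry = default_registry(),
                      delta = 15, step = 1) {
  subject <- validate_cohort(as.data.frame(subject))
  stopifnot(nrow(subject) == 1L, delta >= 0)
  spec <- registry[[equation_id]]
  if (is.null(spec)) stop("unknown equation id '", equation_id, "'")
  adom <- c(max(spec$domain$age[1], SUBJECT_BOUNDS$age[1]),
            min(spec$domain$age[2], SUBJECT_BOUNDS$age[2]))
  lo <- subject$age - delta; hi <- subject$age + delta
  if (lo < adom[1] || hi > adom[2]) {
    warning("age window clipped to domain [", adom[1], ", ", adom[2],
            "] years")
    lo <- max(lo, adom[1]); hi <- min(hi, adom[2])
  }
  grid <- if (delta == 0) subject$age else seq(lo, hi, by = step)
  g <- subject[rep(1L, length(grid)), ]
  g$age <- grid
  g$id <- sprintf("%s@%gy", subject$id, grid)
  pp <- suppressWarnings(
    cohort_percent_predicted(g, registry)$pp[, equation_id])
  out <- data.frame(equation = equation_id, axis = "age", grid_value = grid,
                    bmi = bmi(subject$weight, subject$height), pp = unname(pp),
                    stringsAsFactors = FALSE)
  structure(out, markers = NULL, class = c("sweep_curve", class(out)))
}

#' Render sweep curves to static image files
#'
#' One image per curve with the 80% threshold rule and, for weight sweeps,
#' the ideal-weight (red) and actual-weight (blue) markers. Purely
#' presentational; requires ggplot2.
#'
#' @param curves A list of `"sweep_curve"` objects (or a single one).
#' @param path Output directory.
#' @param threshold Threshold rule drawn on each plot.
#' @return Character vector of files written, invisibly.
#' @export
render_static_plots <- function(curves, path, threshold = 80) {
  if (inherits(curves, "sweep_curve")) curves <- list(curves)
  if (!length(curves)) {
    warning("no curves supplied; nothing rendered")
    return(invisible(character(0)))
  }
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plot rendering")
  }
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  files <- vapply(curves, function(cv) {
    stopifnot(inherits(cv, "sweep_curve"))
    mk <- attr(cv, "markers")
    p <- ggplot2::ggplot(cv, ggplot2::aes(x = .data$grid_value,
                                          y = .data$pp)) +
      ggplot2::geom_line() +
      ggplot2::geom_hline(yintercept = threshold, linetype = "dashed") +
      ggplot2::labs(
        x = if (cv$axis[1] == "weight") "Body mass (kg)" else "Age (years)",
        y = "Percent predicted V̇O2peak (%)",
        title = cv$equation[1]) +
      ggplot2::theme_minimal()
    if (!is.null(mk)) {
      p <- p + ggplot2::geom_point(
        data = mk, ggplot2::aes(x = .data$weight, y = .data$pp),
        colour = c(ideal = "red", actual = "blue")[mk$type], size = 3)
    }
    f <- file.path(path, sprintf("sweep_%s_%s.png", cv$equation[1],
                                 cv$axis[1]))
    ggplot2::ggsave(f, p, width = 6, height = 4, dpi = 120)
    f
  }, character(1))
  invisible(files)
}

#' Write sweep curves as delimited text
#'
#' @param curves List of `"sweep_curve"` objects (or one).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_curves <- function(curves, path) {
  if (inherits(curves, "sweep_curve")) curves <- list(curves)
  utils::write.csv(do.call(rbind, lapply(curves, as.data.frame)), path,
                   row.names = FALSE)
  invisible(path)
}
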