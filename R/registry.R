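#' Equation coefficient registry
#'
#' The six prediction equations are driven by an editable registry: a YAML
#' file with one block per equation id holding the coefficient set, native
#' exercise modes, native units and validity domain. The default registry is
#' shipped with the package; [load_equation_registry()] reads a user file and
#' merges it over the default, so a file overriding a single equation leaves
#' the other five untouched.
#'
#' Only `hansen` and `friend` are modality-specific (they declare both
#' `treadmill` and `cycle` as native modes); the other four declare exactly
#' one native mode and rely on the external 11% correction
#' ([apply_mode_correction()]) when evaluated for the other modality.
#'
#' @name equation-registry
NULL

KNOWN_FORMS <- c("friend", "wasserman", "hansen", "per_kg_age",
                 "height_age_sex", "age_weight")
KNOWN_WEIGHT_UNITS <- c("kg", "lb")
KNOWN_HEIGHT_UNITS <- c("cm", "in")
KNOWN_OUTPUTS <- c("ml_min", "ml_kg_min", "l_min")

#' Load an equation registry
#'
#' @param path Path to a YAML registry file, or `NULL` for the built-in
#'   default. A user file may contain any subset of the six equation ids;
#'   blocks present replace the corresponding default blocks wholesale.
#' @param allow_partial If `TRUE`, a registry missing some of the six
#'   canonical ids is accepted (useful for ad hoc exploration); the default
#'   `FALSE` requires all six.
#' @return A validated registry: named list of equation specifications with
#'   class `"vo2_registry"`.
#' @examples
#' reg <- load_equation_registry()
#' names(reg)
#' @export
load_equation_registry <- function(path = NULL, allow_partial = FALSE) {
  default_path <- system.file("extdata", "equations.yaml", package = "vo2compare",
                              mustWork = TRUE)
  reg <- yaml::read_yaml(default_path)
  if (!is.null(path)) {
    if (!file.exists(path)) stop("registry file not found: ", path)
    user <- yaml::read_yaml(path)
    if (!is.list(user) || is.null(names(user)) || any(names(user) == "")) {
      stop("malformed registry file: expected a named block per equation id")
    }
    unknown <- setdiff(names(user), EQUATION_IDS)
    if (length(unknown)) {
      stop("unknown equation id(s) in registry file: ",
           paste(unknown, collapse = ", "))
    }
    if (anyDuplicated(names(user))) {
      stop("duplicate equation id(s) in registry file: ",
           paste(unique(names(user)[duplicated(names(user))]), collapse = ", "))
    }
    if (allow_partial) {
      reg <- user
    } else {
      reg[names(user)] <- user
    }
  }
  validate_registry(reg, allow_partial = allow_partial)
}

#' @rdname equation-registry
#' @export
default_registry <- function() load_equation_registry()

validate_registry <- function(reg, allow_partial = FALSE) {
  if (!is.list(reg) || is.null(names(reg))) stop("registry must be a named list")
  if (anyDuplicated(names(reg))) stop("duplicate equation ids in registry")
  if (!allow_partial) {
    missing <- setdiff(EQUATION_IDS, names(reg))
    if (length(missing)) {
      stop("registry is missing required equation(s): ",
           paste(missing, collapse = ", "))
    }
  }
  for (id in names(reg)) {
    spec <- reg[[id]]
    spec$id <- id
    if (is.null(spec$form) || !spec$form %in% KNOWN_FORMS) {
      stop("equation '", id, "': unknown or missing form '", spec$form, "'")
    }
    if (is.null(spec$native_modes) ||
        !all(spec$native_modes %in% MODES) || !length(spec$native_modes)) {
      stop("equation '", id, "': native_modes must be a subset of {",
           paste(MODES, collapse = ", "), "}")
    }
    if (id %in% c("friend", "hansen")) {
      if (!setequal(spec$native_modes, MODES)) {
        stop("equation '", id, "' is modality-specific and must declare both modes")
      }
    } else if (id %in% EQUATION_IDS && length(spec$native_modes) != 1L) {
      stop("equation '", id, "' must declare exactly one native mode")
    }
    if (!(spec$weight_units %||% "kg") %in% KNOWN_WEIGHT_UNITS) {
      stop("equation '", id, "': unknown weight units '", spec$weight_units, "'")
    }
    if (!(spec$height_units %||% "cm") %in% KNOWN_HEIGHT_UNITS) {
      stop("equation '", id, "': unknown height units '", spec$height_units, "'")
    }
    if (!(spec$output %||% "ml_min") %in% KNOWN_OUTPUTS) {
      stop("equation '", id, "': unknown output units '", spec$output, "'")
    }
    co <- spec$coefficients
    if (is.null(co) || !is.list(co) ||
        !all(rapply(co, is.numeric, how = "unlist"))) {
      stop("equation '", id, "': malformed coefficients (all values must be numeric)")
    }
    dom <- spec$domain %||% SUBJECT_BOUNDS
    for (f in c("age", "height", "weight")) {
      b <- dom[[f]] %||% SUBJECT_BOUNDS[[f]]
      if (length(b) != 2L || !is.numeric(b) || b[1] >= b[2]) {
        stop("equation '", id, "': malformed domain bound for ", f)
      }
      dom[[f]] <- as.numeric(b)
    }
    spec$domain <- dom
    class(spec) <- "equation_spec"
    reg[[id]] <- spec
  }
  structure(reg, class = "vo2_registry")
}

#' Write a registry to a YAML file
#'
#' Round-trips exactly: writing the default registry and reloading it yields
#' bit-identical predictions.
#'
#' @param registry A `vo2_registry`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_equation_registry <- function(registry, path) {
  stopifnot(inherits(registry, "vo2_registry"))
  plain <- lapply(unclass(registry), function(s) {
    s <- unclass(s)
    s$id <- NULL
    s
  })
  writeLines(yaml::as.yaml(plain, precision = 15), path)
  invisible(path)
}

#' Registry fingerprint
#'
#' MD5 hash of the canonical serialized registry, echoed into cohort reports
#' so results are traceable to the coefficient set that produced them.
#'
#' @param registry A `vo2_registry`.
#' @return Character scalar (32 hex digits).
#' @export
registry_hash <- function(registry) {
  tf <- tempfile(fileext = ".yaml")
  on.exit(unlink(tf))
  write_equation_registry(registry, tf)
  unname(tools::md5sum(tf))
}

#' @export
print.vo2_registry <- function(x, ...) {
  cat("<vo2_registry> ", length(x), " equations\n", sep = "")
  for (id in names(x)) {
    s <- x[[id]]
    cat(sprintf("  %-10s form=%-15s native: %s\n", id, s$form,
                paste(s$native_modes, collapse = "+")))
  }
  invisible(x)
}
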