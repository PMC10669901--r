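#' Declare a factorial exposure design
#'
#' A design spec records the factor levels of a crossed
#' temperature x toxicant-density x sampling-day exposure experiment and the
#' number of replicate tanks per treatment. It defines what "balanced" means
#' for a biomarker battery: every (temperature, density, day, biomarker)
#' cell must carry exactly `n_replicates` measurements.
#'
#' @param temperature Ordered numeric vector of water temperatures (degrees C).
#' @param density Ordered numeric vector of toxicant cell densities (cells/mL).
#'   A zero level (control diet) is allowed and typical.
#' @param days Ordered integer vector of sampling days.
#' @param n_replicates Number of replicate tanks per treatment (>= 2, so the
#'   ANOVA error stratum has positive degrees of freedom).
#'
#' @return An object of class `design_spec`: a list with the validated fields.
#' @examples
#' design_spec()  # the default 3 x 3 x 4-day triplicate design
#' @export
design_spec <- function(temperature = c(20, 25, 30),
                        density = c(0, 1e5, 1e6),
                        days = c(1, 3, 5, 7),
                        n_replicates = 3) {
  check_levels <- function(x, name) {
    if (length(x) == 0 || anyNA(x)) {
      rlang::abort(paste0("`", name, "` must be a non-empty vector without NA."),
                   class = "ibrtox_design_error")
    }
    if (is.unsorted(x, strictly = TRUE)) {
      rlang::abort(paste0("`", name, "` must be strictly increasing with no duplicates."),
                   class = "ibrtox_design_error")
    }
    as.numeric(x)
  }
  temperature <- check_levels(temperature, "temperature")
  density <- check_levels(density, "density")
  days <- check_levels(days, "days")
  n_replicates <- as.integer(n_replicates)
  if (length(n_replicates) != 1 || is.na(n_replicates) || n_replicates < 2) {
    rlang::abort("`n_replicates` must be a single integer >= 2.",
                 class = "ibrtox_design_error")
  }
  structure(
    list(temperature = temperature, density = density, days = days,
         n_replicates = n_replicates),
    class = "design_spec"
  )
}

#' @export
print.design_spec <- function(x, ...) {
  cat("<design_spec>\n")
  cat("  temperature (degC): ", paste(x$temperature, collapse = ", "), "\n", sep = "")
  cat("  density (cells/mL): ", paste(format(x$density, scientific = TRUE), collapse = ", "), "\n", sep = "")
  cat("  sampling days:      ", paste(x$days, collapse = ", "), "\n", sep = "")
  cat("  replicates/cell:    ", x$n_replicates, "\n", sep = "")
  invisible(x)
}

# All design cells (treatment x day), one row each.
design_cells <- function(design) {
  tidyr::expand_grid(
    temperature = design$temperature,
    density = design$density,
    day = design$days
  )
}
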