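#' Options for the integrated biomarker response index
#'
#' @param log_base Base of the logarithm used in the log-ratio step
#'   (default 10, the convention of the IBRv2 literature). The choice does
#'   not affect the standardized deviations or the IBR itself, because the
#'   standardization removes any common scale factor.
#' @param aggregation How per-biomarker deviations `A` are combined into
#'   the scalar index: `"absolute_sum"` (IBRv2, sum of |A|, default) or
#'   `"signed_sum"` (plain sum, which lets induced and inhibited biomarkers
#'   cancel).
#' @param scope Scope over which the per-biomarker mean and SD used for
#'   standardization are computed: `"within_day"` (default; one
#'   standardization per sampling day, matching day-wise star plots) or
#'   `"across_days"` (pooled over all days, for sensitivity analysis).
#' @param reference Optional list with elements `temperature` and `density`
#'   naming the reference treatment whose mean is the denominator of the
#'   log-ratio. Default: zero/lowest density at the lowest temperature.
#' @return An object of class `ibr_options`.
#' @export
ibr_options <- function(log_base = 10,
                        aggregation = c("absolute_sum", "signed_sum"),
                        scope = c("within_day", "across_days"),
                        reference = NULL) {
  if (length(log_base) != 1 || !is.finite(log_base) || log_base <= 1) {
    rlang::abort("`log_base` must be a single number > 1.",
                 class = "ibrtox_options_error")
  }
  aggregation <- match.arg(aggregation)
  scope <- match.arg(scope)
  if (!is.null(reference) &&
      !all(c("temperature", "density") %in% names(reference))) {
    rlang::abort("`reference` must have elements `temperature` and `density`.",
                 class = "ibrtox_options_error")
  }
  structure(list(log_base = log_base, aggregation = aggregation,
                 scope = scope, reference = reference),
            class = "ibr_options")
}

#' Log-ratio of a biomarker level to its reference level
#'
#' First step of the IBR index: `Y = log_base(x / x0)`, the (dimensionless)
#' log of each treatment mean relative to the reference-treatment mean.
#'
#' @param x Treatment-level biomarker mean(s); strictly positive.
#' @param x0 Reference-treatment mean(s); strictly positive.
#' @param base Logarithm base (> 1).
#' @return Numeric vector of log-ratios.
#' @export
ibr_log_ratio <- function(x, x0, base = 10) {
  bad <- which(!(x > 0) | !(x0 > 0))
  if (length(bad) > 0) {
    rlang::abort(
      sprintf("Non-positive biomarker value at position %d (x=%g, x0=%g); the log-ratio requires strictly positive means.",
              bad[1], x[bad[1]], x0[bad[1]]),
      class = "ibrtox_domain_error"
    )
  }
  log(x / x0) / log(base)
}

#' Standardize a set of log-ratios
#'
#' Second step of the IBR index: `Z = (Y - mu) / sigma`, with `mu` and
#' `sigma` the mean and sample (n-1) standard deviation of the log-ratios
#' of one biomarker over all treatments in the standardization scope.
#'
#' @param y Numeric vector of log-ratios (length >= 2, not all equal).
#' @return A list with `z` (standardized values), `mu`, and `sigma`.
#' @export
ibr_standardize <- function(y) {
  if (length(y) < 2) {
    rlang::abort("Standardization needs at least 2 values.",
                 class = "ibrtox_domain_error")
  }
  mu <- mean(y)
  sigma <- stats::sd(y)
  if (!is.finite(sigma) || sigma == 0) {
    rlang::abort("Degenerate standardization scope: all log-ratios are identical (sigma = 0).",
                 class = "ibrtox_degenerate_error")
  }
  list(z = (y - mu) / sigma, mu = mu, sigma = sigma)
}

#' Compute the integrated biomarker response index
#'
#' Implements the IBRv2-style index for every treatment and sampling day of
#' a balanced battery. Per biomarker and day: treatment means are divided
#' by the reference-treatment mean and logged (`Y`), standardized over all
#' treatments in the scope (`Z`), and expressed as the deviation from the
#' reference treatment's standardized value (`A = Z - Z0`). The scalar
#' index for a treatment is `sum(|A|)` over biomarkers (or the signed sum,
#' see [ibr_options()]). The reference treatment has `A = 0` for every
#' biomarker and hence IBR exactly 0 under both aggregations. A biomarker
#' whose log-ratios are constant within a standardization scope (zero
#' variance: it did not respond to any treatment) contributes `A = 0` for
#' that scope rather than an undefined standardization.
#'
#' @param battery A battery tibble; every (treatment, day, biomarker) cell
#'   must be present, and the reference treatment must be present at every
#'   day.
#' @param options An [ibr_options()] object.
#' @return An object of class `ibr` with components:
#'   * `scores`: tibble of (temperature, density, day, ibr),
#'   * `components`: tibble of per-biomarker x0, xi, y, z, a per treatment-day,
#'   * `stats`: the mu, sigma, z0 used per (scope, biomarker),
#'   * `options`, `biomarkers` (fixed display order).
#' @examples
#' res <- compute_ibr(generate_battery(clam_preset(seed = 7)))
#' dplyr::filter(tidy(res), day == 7)
#' @export
compute_ibr <- function(battery, options = ibr_options()) {
  battery <- assert_battery(battery)
  stopifnot(inherits(options, "ibr_options"))
  tm <- treatment_means(battery)
  biomarkers <- unique(battery$biomarker)
  ref <- options$reference
  if (is.null(ref)) {
    ref <- list(temperature = min(tm$temperature), density = min(tm$density))
  }
  # every treatment x day must cover every biomarker
  cover <- tm |> dplyr::count(.data$temperature, .data$density, .data$day)
  if (length(unique(cover$n)) != 1 || cover$n[1] != length(biomarkers)) {
    rlang::abort("Battery is incomplete: every (treatment, day) must cover every biomarker.",
                 class = "ibrtox_balance_error")
  }
  ref_tm <- tm |>
    dplyr::filter(.data$temperature == ref$temperature,
                  .data$density == ref$density)
  if (nrow(ref_tm) == 0) {
    rlang::abort(
      sprintf("Reference treatment (temperature=%g, density=%g) not present in battery.",
              ref$temperature, ref$density),
      class = "ibrtox_reference_error"
    )
  }
  days <- sort(unique(tm$day))
  if (!setequal(ref_tm$day, days)) {
    rlang::abort("Reference treatment must be present at every sampling day.",
                 class = "ibrtox_reference_error")
  }

  comp <- tm |>
    dplyr::left_join(
      ref_tm |> dplyr::select("day", "biomarker", x0 = "mean"),
      by = c("day", "biomarker")
    ) |>
    dplyr::mutate(y = ibr_log_ratio(.data$mean, .data$x0, options$log_base)) |>
    dplyr::rename(xi = "mean")

  scope_vars <- if (options$scope == "within_day") c("day", "biomarker") else "biomarker"
  comp <- comp |>
    dplyr::group_by(dplyr::across(dplyr::all_of(scope_vars))) |>
    dplyr::mutate(mu = mean(.data$y), sigma = stats::sd(.data$y)) |>
    dplyr::ungroup()
  # a biomarker whose log-ratios are all identical within scope shows no
  # variation across treatments: it contributes zero deviation (z = 0)
  # rather than an undefined 0/0
  comp <- comp |>
    dplyr::mutate(z = dplyr::if_else(.data$sigma > 0,
                                     (.data$y - .data$mu) / .data$sigma,
                                     0)) |>
    dplyr::group_by(.data$day, .data$biomarker) |>
    dplyr::mutate(z0 = .data$z[.data$temperature == ref$temperature &
                                 .data$density == ref$density]) |>
    dplyr::ungroup() |>
    dplyr::mutate(a = .data$z - .data$z0)

  agg <- if (options$aggregation == "absolute_sum") {
    function(a) sum(abs(a))
  } else {
    sum
  }
  scores <- comp |>
    dplyr::group_by(.data$temperature, .data$density, .data$day) |>
    dplyr::summarise(ibr = agg(.data$a), .groups = "drop") |>
    dplyr::arrange(.data$day, .data$temperature, .data$density)

  structure(
    list(
      scores = scores,
      components = comp |>
        dplyr::select("temperature", "density", "day", "biomarker",
                      "xi", "x0", "y", "mu", "sigma", "z", "z0", "a") |>
        dplyr::arrange(.data$day, .data$temperature, .data$density,
                       match(.data$biomarker, biomarkers)),
      stats = comp |>
        dplyr::distinct(dplyr::across(dplyr::all_of(scope_vars)),
                        .data$mu, .data$sigma),
      options = options,
      reference = ref,
      biomarkers = biomarkers
    ),
    class = "ibr"
  )
}

#' @export
print.ibr <- function(x, ...) {
  cat("<ibr> integrated biomarker response (", x$options$aggregation,
      ", scope ", x$options$scope, ")\n", sep = "")
  cat("  reference: temperature=", x$reference$temperature,
      ", density=", x$reference$density, "\n", sep = "")
  print(x$scores, n = 10)
  invisible(x)
}

#' Tidy an IBR result
#'
#' @param x An `ibr` object.
#' @param type `"scores"` (one row per treatment-day with the scalar IBR)
#'   or `"components"` (per-biomarker Y/Z/A values).
#' @param ... Unused.
#' @return A tibble.
#' @exportS3Method generics::tidy
tidy.ibr <- function(x, type = c("scores", "components"), ...) {
  type <- match.arg(type)
  if (type == "scores") x$scores else x$components
}

#' One-row summary of an IBR result
#'
#' @param x An `ibr` object.
#' @param ... Unused.
#' @return A tibble with the number of treatments, days, biomarkers, and
#'   the range of the index over non-reference treatments.
#' @exportS3Method generics::glance
glance.ibr <- function(x, ...) {
  nonref <- x$scores |>
    dplyr::filter(!(.data$temperature == x$reference$temperature &
                      .data$density == x$reference$density))
  tibble::tibble(
    n_treatments = nrow(dplyr::distinct(x$scores, .data$temperature, .data$density)),
    n_days = length(unique(x$scores$day)),
    n_biomarkers = length(x$biomarkers),
    ibr_min = min(nonref$ibr),
    ibr_max = max(nonref$ibr),
    aggregation = x$options$aggregation,
    scope = x$options$scope
  )
}

#' Star-plot geometry for one treatment and day
#'
#' Places the biomarkers of an IBR result at equally spaced angles
#' `2*pi*k/m` (k = 0..m-1, in the battery's fixed biomarker order) with the
#' signed deviation `A` as radius. The polygon through these vertices is
#' the star plot of the treatment.
#'
#' @param ibr An `ibr` object from [compute_ibr()].
#' @param temperature,density,day Coordinates of the treatment-day to extract.
#' @return A tibble with columns `biomarker`, `angle`, `radius`.
#' @export
star_coordinates <- function(ibr, temperature, density, day) {
  stopifnot(inherits(ibr, "ibr"))
  sel <- ibr$components |>
    dplyr::filter(.data$temperature == !!temperature,
                  .data$density == !!density,
                  .data$day == !!day)
  if (nrow(sel) == 0) {
    rlang::abort(
      sprintf("Treatment (temperature=%g, density=%g) at day %g not found in IBR result.",
              temperature, density, day),
      class = "ibrtox_lookup_error"
    )
  }
  m <- length(ibr$biomarkers)
  sel <- sel[match(ibr$biomarkers, sel$biomarker), ]
  tibble::tibble(
    biomarker = sel$biomarker,
    angle = 2 * pi * (seq_len(m) - 1) / m,
    radius = sel$a
  )
}

#' Star plots of per-biomarker deviations
#'
#' One polar polygon per treatment, faceted by sampling day: the vertex at
#' each biomarker has radius equal to the signed deviation `A` from the
#' reference condition. The reference treatment itself (all radii zero) is
#' omitted.
#'
#' @param object An `ibr` object.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.ibr <- function(object, ...) {
  comp <- object$components |>
    dplyr::filter(!(.data$temperature == object$reference$temperature &
                      .data$density == object$reference$density)) |>
    dplyr::mutate(
      treatment = sprintf("%g°C × %g", .data$temperature, .data$density),
      biomarker = factor(.data$biomarker, levels = object$biomarkers)
    )
  ggplot2::ggplot(comp,
                  ggplot2::aes(x = .data$biomarker, y = .data$a,
                               group = .data$treatment,
                               colour = .data$treatment)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_polygon(fill = NA) +
    ggplot2::geom_point(size = 1) +
    ggplot2::coord_polar() +
    ggplot2::facet_wrap(~day, labeller = ggplot2::label_both) +
    ggplot2::labs(y = "deviation A from reference", x = NULL,
                  colour = "treatment") +
    ggplot2::theme_minimal()
}
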