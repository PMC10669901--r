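#' Condition-level biomarker matrix for ordination
#'
#' Builds the (treatment x day) by biomarker matrix used for principal
#' component analysis: each entry is the replicate mean of one biomarker
#' under one experimental condition, and each column is then z-scored
#' (mean 0, SD 1 with the n-1 denominator), which makes the PCA a
#' correlation-matrix PCA — the right choice when biomarkers carry
#' incommensurable units. Rows are ordered by temperature, then density,
#' then day, and named `T<temp>_D<density>_day<day>`.
#'
#' @param battery A battery tibble.
#' @return A numeric matrix with condition rows and biomarker columns;
#'   attribute `conditions` holds the row-metadata tibble.
#' @export
build_condition_matrix <- function(battery) {
  tm <- treatment_means(battery)
  wide <- tm |>
    dplyr::select("temperature", "density", "day", "biomarker", "mean") |>
    tidyr::pivot_wider(names_from = "biomarker", values_from = "mean") |>
    dplyr::arrange(.data$temperature, .data$density, .data$day)
  conditions <- wide[c("temperature", "density", "day")]
  mat <- as.matrix(wide[setdiff(names(wide), names(conditions))])
  if (anyNA(mat)) {
    rlang::abort("Battery is incomplete: some (treatment, day) lack a biomarker mean.",
                 class = "ibrtox_balance_error")
  }
  sds <- apply(mat, 2, stats::sd)
  if (any(!is.finite(sds) | sds == 0)) {
    rlang::abort(
      paste0("Degenerate (zero-variance) biomarker column(s): ",
             paste(colnames(mat)[!is.finite(sds) | sds == 0], collapse = ", ")),
      class = "ibrtox_degenerate_error"
    )
  }
  scaled <- scale(mat)
  attr(scaled, "scaled:center") <- NULL
  attr(scaled, "scaled:scale") <- NULL
  rownames(scaled) <- sprintf("T%g_D%s_day%g", conditions$temperature,
                              format(conditions$density, scientific = FALSE,
                                     trim = TRUE),
                              conditions$day)
  attr(scaled, "conditions") <- conditions
  scaled
}

#' Principal component analysis of a biomarker battery
#'
#' Correlation-matrix PCA of condition-level biomarker profiles, computed
#' by singular value decomposition of the z-scored condition matrix
#' (equivalent to an eigendecomposition of the biomarker correlation
#' matrix). Loadings columns are orthonormal; scores are the projections
#' of the scaled rows onto the loadings; explained-variance percentages
#' are non-increasing and sum to 100 over all returned components. Sign
#' convention: within each loading column the entry of largest magnitude
#' is made positive, so results are deterministic.
#'
#' @param x A battery tibble, or a pre-built numeric matrix of z-scored
#'   condition rows by biomarker columns (e.g. from
#'   [build_condition_matrix()]).
#' @return An object of class `biomarker_pca` with `loadings`, `scores`,
#'   `explained_variance_pct`, and (when available) the condition metadata.
#' @examples
#' pc <- biomarker_pca(generate_battery(clam_preset(seed = 5)))
#' glance(pc)
#' @export
biomarker_pca <- function(x) {
  conditions <- NULL
  if (is.data.frame(x)) {
    mat <- build_condition_matrix(x)
    conditions <- attr(mat, "conditions")
  } else if (is.matrix(x) && is.numeric(x)) {
    mat <- x
    conditions <- attr(mat, "conditions")
  } else {
    rlang::abort("`x` must be a battery data frame or a numeric matrix.",
                 class = "ibrtox_domain_error")
  }
  if (nrow(mat) < 2) {
    rlang::abort("PCA needs at least 2 rows.", class = "ibrtox_domain_error")
  }
  sv <- svd(mat)
  ncomp <- length(sv$d)
  loadings <- sv$v
  scores <- sv$u %*% diag(sv$d, nrow = ncomp)
  # deterministic orientation: largest-|loading| entry positive per column
  for (j in seq_len(ncomp)) {
    i_star <- which.max(abs(loadings[, j]))
    if (loadings[i_star, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  pct <- 100 * sv$d^2 / sum(sv$d^2)
  dimnames(loadings) <- list(colnames(mat), paste0("PC", seq_len(ncomp)))
  dimnames(scores) <- list(rownames(mat), paste0("PC", seq_len(ncomp)))
  structure(
    list(loadings = loadings, scores = scores,
         explained_variance_pct = pct, conditions = conditions,
         n_conditions = nrow(mat), biomarkers = colnames(mat)),
    class = "biomarker_pca"
  )
}

#' @export
print.biomarker_pca <- function(x, ...) {
  cat("<biomarker_pca>", x$n_conditions, "conditions x",
      length(x$biomarkers), "biomarkers\n")
  cat("  explained variance (%):",
      paste(sprintf("%.2f", x$explained_variance_pct), collapse = ", "), "\n")
  invisible(x)
}

#' @rdname biomarker_pca
#' @param type `"scores"`, `"loadings"`, or `"variance"`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.biomarker_pca <- function(x, type = c("scores", "loadings", "variance"), ...) {
  type <- match.arg(type)
  if (type == "variance") {
    return(tibble::tibble(component = paste0("PC", seq_along(x$explained_variance_pct)),
                          explained_variance_pct = x$explained_variance_pct))
  }
  mat <- if (type == "scores") x$scores else x$loadings
  out <- tibble::as_tibble(mat, rownames = if (type == "scores") "condition" else "biomarker")
  if (type == "scores" && !is.null(x$conditions)) {
    out <- dplyr::bind_cols(x$conditions, out)
  }
  out
}

#' @rdname biomarker_pca
#' @exportS3Method generics::glance
glance.biomarker_pca <- function(x, ...) {
  tibble::tibble(
    n_conditions = x$n_conditions,
    n_biomarkers = length(x$biomarkers),
    pc1_pct = x$explained_variance_pct[1],
    pc2_pct = x$explained_variance_pct[2],
    pc12_pct = sum(x$explained_variance_pct[1:2])
  )
}

#' PCA biplot of biomarker loadings and condition scores
#'
#' @param object A `biomarker_pca` object.
#' @param ... Unused.
#' @return A ggplot showing condition scores (points, coloured by
#'   temperature, shaped by density when metadata are available) and
#'   biomarker loading vectors on the first two components.
#' @exportS3Method ggplot2::autoplot
autoplot.biomarker_pca <- function(object, ...) {
  sc <- tidy(object, "scores")
  ld <- tidy(object, "loadings")
  arrow_scale <- 0.8 * max(abs(c(sc$PC1, sc$PC2))) / max(abs(c(ld$PC1, ld$PC2)))
  p <- ggplot2::ggplot(sc, ggplot2::aes(x = .data$PC1, y = .data$PC2))
  if (!is.null(object$conditions)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(
      colour = factor(.data$temperature), shape = factor(.data$density)), size = 2) +
      ggplot2::labs(colour = "temperature (°C)", shape = "density (cells/mL)")
  } else {
    p <- p + ggplot2::geom_point(size = 2)
  }
  p +
    ggplot2::geom_segment(
      data = ld,
      ggplot2::aes(x = 0, y = 0, xend = .data$PC1 * arrow_scale,
                   yend = .data$PC2 * arrow_scale),
      arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm")),
      colour = "grey30"
    ) +
    ggplot2::geom_text(
      data = ld,
      ggplot2::aes(x = .data$PC1 * arrow_scale * 1.08,
                   y = .data$PC2 * arrow_scale * 1.08,
                   label = .data$biomarker),
      colour = "grey20", size = 3
    ) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", object$explained_variance_pct[1]),
      y = sprintf("PC2 (%.1f%%)", object$explained_variance_pct[2])
    ) +
    ggplot2::theme_minimal()
}
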