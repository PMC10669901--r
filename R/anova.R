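#' Balanced three-way fixed-effects ANOVA for one biomarker
#'
#' Decomposes the variance of one biomarker's measurements over a fully
#' crossed temperature x density x day design into the three main effects,
#' the three two-way interactions, the three-way interaction, and residual
#' (within-cell) error, using the classical balanced-design computation:
#' main-effect sums of squares from marginal means, interaction sums of
#' squares from cell means with lower-order terms removed by
#' inclusion-exclusion, and error from within-cell deviations. With a
#' balanced design, Type I/II/III sums of squares coincide, so no SS-type
#' choice arises; unbalanced input is an error, never a silent fallback.
#'
#' All factors are treated as fixed effects and replicate tanks as the
#' single residual stratum, so each term is tested against the residual
#' mean square with an upper-tail F probability.
#'
#' @param battery A battery tibble.
#' @param biomarker Name of the biomarker to analyse.
#' @param transform Optional function applied to the response before
#'   fitting (e.g. `log` when the data-generating process is
#'   multiplicative). Default: identity.
#' @return An object of class `anova_threeway`; `tidy()` returns the term
#'   table (term, df, sumsq, meansq, statistic, p.value) including
#'   `Residuals` and `Total` rows.
#' @examples
#' fit <- fit_three_way_anova(generate_battery(clam_preset(seed = 1)), "SOD")
#' tidy(fit)
#' @export
fit_three_way_anova <- function(battery, biomarker, transform = NULL) {
  battery <- assert_battery(battery)
  d <- battery[battery$biomarker == biomarker, ]
  if (nrow(d) == 0) {
    rlang::abort(paste0("Biomarker not found: ", biomarker),
                 class = "ibrtox_lookup_error")
  }
  y <- d$value
  if (!is.null(transform)) y <- transform(y)
  A <- factor(d$temperature)  # temperature
  B <- factor(d$density)      # toxicant density
  C <- factor(d$day)          # sampling day
  a <- nlevels(A); b <- nlevels(B); cc <- nlevels(C)

  counts <- table(A, B, C)
  n <- counts[1]
  if (any(counts != n)) {
    deficient <- which(counts != n, arr.ind = TRUE)
    rlang::abort(
      sprintf("Unbalanced design for biomarker %s: cell (temperature=%s, density=%s, day=%s) has %d records, expected %d.",
              biomarker, dimnames(counts)[[1]][deficient[1, 1]],
              dimnames(counts)[[2]][deficient[1, 2]],
              dimnames(counts)[[3]][deficient[1, 3]],
              counts[deficient[1, , drop = FALSE]], n),
      class = "ibrtox_balance_error"
    )
  }
  if (n < 2) {
    rlang::abort("Error stratum needs >= 2 replicates per cell.",
                 class = "ibrtox_balance_error")
  }
  N <- length(y)
  g <- mean(y)

  mA <- tapply(y, A, mean); mB <- tapply(y, B, mean); mC <- tapply(y, C, mean)
  mAB <- tapply(y, list(A, B), mean)
  mAC <- tapply(y, list(A, C), mean)
  mBC <- tapply(y, list(B, C), mean)
  mABC <- tapply(y, list(A, B, C), mean)

  ss_A <- b * cc * n * sum((mA - g)^2)
  ss_B <- a * cc * n * sum((mB - g)^2)
  ss_C <- a * b * n * sum((mC - g)^2)
  ss_AB <- cc * n * sum((mAB - outer(mA, mB, `+`) + g)^2)
  ss_AC <- b * n * sum((mAC - outer(mA, mC, `+`) + g)^2)
  ss_BC <- a * n * sum((mBC - outer(mB, mC, `+`) + g)^2)
  eABC <- mABC
  for (i in seq_len(a)) for (j in seq_len(b)) for (k in seq_len(cc)) {
    eABC[i, j, k] <- mABC[i, j, k] - mAB[i, j] - mAC[i, k] - mBC[j, k] +
      mA[i] + mB[j] + mC[k] - g
  }
  ss_ABC <- n * sum(eABC^2)
  cell_mean <- mABC[cbind(as.integer(A), as.integer(B), as.integer(C))]
  ss_E <- sum((y - cell_mean)^2)
  ss_T <- sum((y - g)^2)

  terms <- c("temperature", "density", "day",
             "temperature:density", "temperature:day", "density:day",
             "temperature:density:day", "Residuals")
  df <- c(a - 1, b - 1, cc - 1,
          (a - 1) * (b - 1), (a - 1) * (cc - 1), (b - 1) * (cc - 1),
          (a - 1) * (b - 1) * (cc - 1), a * b * cc * (n - 1))
  ss <- c(ss_A, ss_B, ss_C, ss_AB, ss_AC, ss_BC, ss_ABC, ss_E)
  ms <- ss / df
  ms_e <- ms[length(ms)]
  if (ms_e > 0) {
    f <- c(ms[-length(ms)] / ms_e, NA_real_)
    p <- c(f_upper_tail(f[-length(f)], df[-length(df)], df[length(df)]),
           NA_real_)
  } else {
    # constant response (or exact cell fit): F undefined, flagged as NA
    f <- rep(NA_real_, length(terms))
    p <- rep(NA_real_, length(terms))
  }
  table <- tibble::tibble(
    term = c(terms, "Total"),
    df = as.integer(c(df, N - 1)),
    sumsq = c(ss, ss_T),
    meansq = c(ms, NA_real_),
    statistic = c(f, NA_real_),
    p.value = c(p, NA_real_)
  )
  structure(
    list(table = table, biomarker = biomarker,
         levels = list(temperature = levels(A), density = levels(B),
                       day = levels(C)),
         n_replicates = n, n_obs = N,
         ms_error = ms_e, df_error = df[length(df)]),
    class = "anova_threeway"
  )
}

#' @export
print.anova_threeway <- function(x, ...) {
  cat("<anova_threeway> biomarker:", x$biomarker, "\n")
  print(x$table)
  invisible(x)
}

#' @rdname fit_three_way_anova
#' @param x An `anova_threeway` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.anova_threeway <- function(x, ...) x$table

#' @rdname fit_three_way_anova
#' @exportS3Method generics::glance
glance.anova_threeway <- function(x, ...) {
  tibble::tibble(
    biomarker = x$biomarker,
    n_obs = x$n_obs,
    df_total = x$n_obs - 1L,
    df_error = x$df_error,
    ms_error = x$ms_error
  )
}

#' Upper tail probability of the F distribution
#'
#' Computes `P(F >= f)` for an F statistic with `df1` and `df2` degrees of
#' freedom through the regularized incomplete beta function identity
#' `P(F >= f) = I_x(df2/2, df1/2)` with `x = df2 / (df2 + df1 f)`.
#'
#' @param f F statistic(s), >= 0.
#' @param df1,df2 Numerator and denominator degrees of freedom (>= 1).
#' @return Upper-tail probability in `[0, 1]`.
#' @export
f_upper_tail <- function(f, df1, df2) {
  if (any(df1 < 1) || any(df2 < 1)) {
    rlang::abort("Degrees of freedom must be >= 1.", class = "ibrtox_domain_error")
  }
  if (any(f < 0)) {
    rlang::abort("F statistic must be >= 0.", class = "ibrtox_domain_error")
  }
  stats::pbeta(df2 / (df2 + df1 * f), df2 / 2, df1 / 2)
}

#' Levene's test for homogeneity of variance
#'
#' Classical mean-centered Levene test: a one-way ANOVA F statistic on the
#' absolute deviations of each observation from its group mean. Returns
#' `W = 0`, `p = 1` when all deviations are identical (e.g. all groups
#' constant).
#'
#' @param data A data frame.
#' @param value Column with the response (tidy-eval).
#' @param group Column identifying the groups (tidy-eval).
#' @return A one-row tibble: `statistic` (W), `df1`, `df2`, `p.value`.
#' @export
levene_test <- function(data, value, group) {
  v <- rlang::eval_tidy(rlang::enquo(value), data)
  grp <- factor(rlang::eval_tidy(rlang::enquo(group), data))
  k <- nlevels(grp)
  if (k < 2) {
    rlang::abort("Levene's test needs >= 2 groups.", class = "ibrtox_domain_error")
  }
  ni <- tabulate(grp)
  if (any(ni < 2)) {
    rlang::abort("Levene's test needs >= 2 observations per group.",
                 class = "ibrtox_domain_error")
  }
  gm <- tapply(v, grp, mean)
  z <- abs(v - gm[as.integer(grp)])
  N <- length(z)
  zbar <- mean(z)
  zi <- tapply(z, grp, mean)
  ss_b <- sum(ni * (zi - zbar)^2)
  ss_w <- sum((z - zi[as.integer(grp)])^2)
  df1 <- k - 1
  df2 <- N - k
  if (ss_w <= 1e-300) {
    if (ss_b <= 1e-300) {
      return(tibble::tibble(statistic = 0, df1 = df1, df2 = df2, p.value = 1))
    }
    return(tibble::tibble(statistic = Inf, df1 = df1, df2 = df2, p.value = 0))
  }
  w <- (ss_b / df1) / (ss_w / df2)
  tibble::tibble(statistic = w, df1 = df1, df2 = df2,
                 p.value = f_upper_tail(w, df1, df2))
}

#' Pearson correlation matrix across biomarkers
#'
#' Pairs observations of different biomarkers by (temperature, density,
#' day, replicate) and returns the Pearson correlation matrix.
#'
#' @param battery A battery tibble.
#' @return A symmetric biomarker x biomarker correlation matrix with unit
#'   diagonal.
#' @export
pearson_matrix <- function(battery) {
  battery <- assert_battery(battery)
  wide <- battery |>
    dplyr::select("temperature", "density", "day", "replicate",
                  "biomarker", "value") |>
    tidyr::pivot_wider(names_from = "biomarker", values_from = "value")
  mat <- as.matrix(wide[setdiff(names(wide),
                                c("temperature", "density", "day", "replicate"))])
  sds <- apply(mat, 2, stats::sd)
  if (any(!is.finite(sds) | sds == 0)) {
    rlang::abort(
      paste0("Zero-variance biomarker(s): ",
             paste(colnames(mat)[!is.finite(sds) | sds == 0], collapse = ", ")),
      class = "ibrtox_degenerate_error"
    )
  }
  stats::cor(mat, use = "all.obs", method = "pearson")
}
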