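# Gauss-Legendre nodes/weights on [lo, hi] (via pracma), cached per order.
gl_nodes <- local({
  cache <- new.env(parent = emptyenv())
  function(n, lo, hi) {
    key <- as.character(n)
    if (is.null(cache[[key]])) cache[[key]] <- pracma::gaussLegendre(n, -1, 1)
    g <- cache[[key]]
    list(x = (hi + lo) / 2 + (hi - lo) / 2 * g$x,
         w = (hi - lo) / 2 * g$w)
  }
})

#' Upper tail of the studentized range distribution
#'
#' Computes `P(Q >= q)` for the range of `k` independent standard normal
#' means divided by an independent scale estimate with `df` degrees of
#' freedom, by direct double numerical integration: the inner integral
#' (over the location of the smallest mean) and the outer integral (over
#' the scale, i.e. the density of `sqrt(chi^2_df / df)`) are both evaluated
#' with composite Gauss-Legendre panels. Node counts are fixed (24-point
#' panels; scale range covering all but 1e-12 of the chi mass; location
#' range of 8.5 normal SDs, beyond which the integrand's normal-density
#' factor vanishes), which keeps the absolute error well below 1e-6 over
#' the (k, df) ranges that arise in biomarker post hoc testing.
#'
#' @param q Studentized range statistic(s), >= 0; vectorized.
#' @param k Number of groups (>= 2).
#' @param df Error degrees of freedom (>= 1).
#' @return Upper-tail probabilities in `[0, 1]`.
#' @export
studentized_range_upper_tail <- function(q, k, df) {
  if (k < 2) rlang::abort("`k` must be >= 2.", class = "ibrtox_domain_error")
  if (df < 1) rlang::abort("`df` must be >= 1.", class = "ibrtox_domain_error")
  if (any(q < 0)) rlang::abort("`q` must be >= 0.", class = "ibrtox_domain_error")
  out <- numeric(length(q))
  pos <- q > 0
  out[!pos] <- 1
  if (!any(pos)) return(out)
  qq <- q[pos]

  # outer nodes: s = sqrt(chi^2_df / df), support trimmed to 1e-12 tail mass
  s_lo <- sqrt(stats::qchisq(1e-12, df) / df)
  s_hi <- sqrt(stats::qchisq(1 - 1e-12, df) / df)
  s_panels <- max(8L, min(30L, ceiling((s_hi - s_lo) * 8)))
  sn <- do.call(rbind, lapply(seq_len(s_panels), function(i) {
    lo <- s_lo + (i - 1) * (s_hi - s_lo) / s_panels
    hi <- s_lo + i * (s_hi - s_lo) / s_panels
    g <- gl_nodes(24L, lo, hi)
    cbind(g$x, g$w)
  }))
  s <- sn[, 1]; ws <- sn[, 2]
  ln_c <- (df / 2) * log(df) - (df / 2 - 1) * log(2) - lgamma(df / 2)
  g_s <- exp(ln_c + (df - 1) * log(s) - df * s^2 / 2)

  # inner nodes: u from -8.5 to 8.5 in unit-width panels; the integrand
  # carries a phi(u) factor, so its effective support does not grow with q
  u_lo <- -8.5
  u_hi <- 8.5
  u_panels <- ceiling(u_hi - u_lo)
  un <- do.call(rbind, lapply(seq_len(u_panels), function(i) {
    g <- gl_nodes(12L, u_lo + (i - 1), min(u_lo + i, u_hi))
    cbind(g$x, g$w)
  }))
  u <- un[, 1]; wu <- un[, 2]
  phi_u <- stats::dnorm(u)
  Phi_u <- stats::pnorm(u)

  cdf <- vapply(qq, function(qi) {
    # inner integral for each scale node: k * int phi(u) (Phi(u)-Phi(u-q s))^(k-1) du
    B <- stats::pnorm(outer(u, qi * s, `-`))
    inner <- as.vector(crossprod(wu * phi_u, (Phi_u - B)^(k - 1))) * k
    sum(ws * g_s * inner)
  }, numeric(1))
  out[pos] <- pmin(pmax(1 - cdf, 0), 1)
  out
}

#' Tukey HSD pairwise comparisons of treatments at one sampling day
#'
#' Compares all treatment groups (temperature x density combinations) of
#' one biomarker at one sampling day. The error mean square and its
#' degrees of freedom come, by default, from a one-way ANOVA on that day's
#' groups (`error_stratum = "within_day"`, matching letters reported "among
#' treatment groups at each sampling time"); alternatively the residual
#' stratum of the full three-way fit can be used
#' (`error_stratum = "three_way"`). For each pair,
#' `q = |mean_i - mean_j| / sqrt(MS_error / n)` and the adjusted p-value is
#' the studentized-range upper tail with `k` groups. Groups then receive
#' compact-letter-display labels: two groups share a letter exactly when
#' their adjusted p-value is >= `alpha`.
#'
#' @param battery A battery tibble.
#' @param biomarker Biomarker name.
#' @param day Sampling day to analyse.
#' @param alpha Family-wise significance level (default 0.05).
#' @param error_stratum `"within_day"` (default) or `"three_way"`.
#' @return An object of class `tukey_cld` with `pairs` (tibble: group1,
#'   group2, estimate, q, adj.p.value) and `letters` (tibble: temperature,
#'   density, mean, letters).
#' @examples
#' battery <- generate_battery(clam_preset(seed = 3))
#' tukey_hsd(battery, "SOD", day = 7)$letters
#' @export
tukey_hsd <- function(battery, biomarker, day, alpha = 0.05,
                      error_stratum = c("within_day", "three_way")) {
  battery <- assert_battery(battery)
  error_stratum <- match.arg(error_stratum)
  d <- battery[battery$biomarker == biomarker & battery$day == day, ]
  if (nrow(d) == 0) {
    rlang::abort(sprintf("No records for biomarker %s at day %g.", biomarker, day),
                 class = "ibrtox_lookup_error")
  }
  d$group <- paste0("T", d$temperature, "_D", format(d$density, scientific = FALSE, trim = TRUE))
  groups <- d |>
    dplyr::group_by(.data$temperature, .data$density, .data$group) |>
    dplyr::summarise(mean = mean(.data$value), n = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(.data$temperature, .data$density)
  k <- nrow(groups)
  if (k < 2) {
    rlang::abort("Tukey HSD needs >= 2 groups.", class = "ibrtox_domain_error")
  }
  if (length(unique(groups$n)) != 1) {
    rlang::abort("Tukey HSD requires equal replicate counts per group.",
                 class = "ibrtox_balance_error")
  }
  n <- groups$n[1]
  if (error_stratum == "within_day") {
    grp <- factor(d$group, levels = groups$group)
    gm <- tapply(d$value, grp, mean)
    ss_e <- sum((d$value - gm[as.integer(grp)])^2)
    df_e <- nrow(d) - k
    ms_e <- ss_e / df_e
  } else {
    fit <- fit_three_way_anova(battery, biomarker)
    ms_e <- fit$ms_error
    df_e <- fit$df_error
  }
  if (df_e < 1 || ms_e <= 0) {
    rlang::abort("Degenerate error stratum (zero error variance or df).",
                 class = "ibrtox_degenerate_error")
  }
  ij <- utils::combn(k, 2)
  est <- groups$mean[ij[2, ]] - groups$mean[ij[1, ]]
  qstat <- abs(est) / sqrt(ms_e / n)
  adj_p <- studentized_range_upper_tail(qstat, k, df_e)
  pairs <- tibble::tibble(
    group1 = groups$group[ij[1, ]],
    group2 = groups$group[ij[2, ]],
    estimate = est,
    q = qstat,
    adj.p.value = adj_p
  )
  letters_tbl <- compact_letter_display(pairs, alpha = alpha,
                                        means = stats::setNames(groups$mean, groups$group))
  letters_out <- groups |>
    dplyr::select("temperature", "density", "group", "mean") |>
    dplyr::left_join(letters_tbl, by = "group")
  structure(
    list(pairs = pairs, letters = letters_out, alpha = alpha,
         biomarker = biomarker, day = day, k = k, df_error = df_e,
         ms_error = ms_e, n_per_group = n),
    class = "tukey_cld"
  )
}

#' @export
print.tukey_cld <- function(x, ...) {
  cat("<tukey_cld>", x$biomarker, "day", x$day,
      sprintf("(k=%d, df_error=%d, alpha=%g)\n", x$k, x$df_error, x$alpha))
  print(x$letters)
  invisible(x)
}

#' @rdname tukey_hsd
#' @param x A `tukey_cld` object.
#' @param type `"pairs"` or `"letters"`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.tukey_cld <- function(x, type = c("pairs", "letters"), ...) {
  type <- match.arg(type)
  if (type == "pairs") x$pairs else x$letters
}

#' Compact letter display from pairwise comparisons
#'
#' Assigns letter labels to groups so that two groups share at least one
#' letter exactly when their pairwise adjusted p-value is >= `alpha`
#' (i.e. they are not significantly different). Uses the insert-and-absorb
#' algorithm: start from one set holding all groups; for each significant
#' pair, split every set containing both members; discard sets that are
#' subsets of others. The letter set is correct but not guaranteed minimal.
#'
#' @param pairs A data frame with columns `group1`, `group2`, and
#'   `adj.p.value` (or `p.value`), covering every unordered pair once.
#' @param alpha Significance level.
#' @param means Optional named numeric vector of group means; letters are
#'   ordered so that `"a"` goes to the set containing the largest mean.
#' @return A tibble with columns `group` and `letters`.
#' @export
compact_letter_display <- function(pairs, alpha = 0.05, means = NULL) {
  pcol <- if ("adj.p.value" %in% names(pairs)) "adj.p.value" else "p.value"
  if (!all(c("group1", "group2") %in% names(pairs)) || !pcol %in% names(pairs)) {
    rlang::abort("`pairs` needs columns group1, group2 and adj.p.value (or p.value).",
                 class = "ibrtox_domain_error")
  }
  groups <- unique(c(pairs$group1, pairs$group2))
  sets <- list(groups)
  sig <- pairs[pairs[[pcol]] < alpha, , drop = FALSE]
  for (r in seq_len(nrow(sig))) {
    g1 <- sig$group1[r]; g2 <- sig$group2[r]
    new_sets <- list()
    for (s in sets) {
      if (g1 %in% s && g2 %in% s) {
        new_sets <- c(new_sets, list(setdiff(s, g1)), list(setdiff(s, g2)))
      } else {
        new_sets <- c(new_sets, list(s))
      }
    }
    # absorb: drop sets contained in another set
    keep <- rep(TRUE, length(new_sets))
    for (i in seq_along(new_sets)) {
      for (j in seq_along(new_sets)) {
        if (i != j && keep[i] &&
            all(new_sets[[i]] %in% new_sets[[j]]) &&
            (length(new_sets[[i]]) < length(new_sets[[j]]) || i > j)) {
          keep[i] <- FALSE
          break
        }
      }
    }
    sets <- new_sets[keep]
  }
  sets <- Filter(length, sets)
  if (!is.null(means)) {
    set_rank <- vapply(sets, function(s) max(means[s]), numeric(1))
    sets <- sets[order(-set_rank)]
  }
  labs <- make_cld_letters(length(sets))
  tibble::tibble(
    group = groups,
    letters = vapply(groups, function(g) {
      paste0(labs[vapply(sets, function(s) g %in% s, logical(1))], collapse = "")
    }, character(1), USE.NAMES = FALSE)
  )
}

# "a", "b", ..., "z", "aa", "ab", ... for arbitrarily many letter sets
make_cld_letters <- function(n) {
  if (n <= 26) return(letters[seq_len(n)])
  c(letters, as.vector(outer(letters, letters, paste0)))[seq_len(n)]
}
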