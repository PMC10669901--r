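# Builders and independent oracles shared across the test files.

# A battery built record-by-record from explicit vectors.
make_battery <- function(temperature, density, day, replicate, biomarker,
                         value, units = "a.u.") {
  tibble::tibble(
    temperature = temperature, density = density, day = day,
    replicate = as.numeric(replicate), biomarker = biomarker,
    value = value, units = units
  )
}

# Two-treatment, one-biomarker worked example: reference mean 10,
# treated mean 100 (constant over replicates so means are exact).
worked_example_battery <- function() {
  make_battery(
    temperature = 20, density = rep(c(0, 1e5), each = 2), day = 1,
    replicate = rep(1:2, 2), biomarker = "GST",
    value = c(10, 10, 100, 100), units = "U/mg prot"
  )
}

# Random small balanced battery: `n_t` temperatures x `n_d` densities x
# `n_day` days x `n_rep` replicates x the given biomarkers, lognormal values.
random_small_battery <- function(seed, n_t = 2, n_d = 2, n_day = 2,
                                 n_rep = 2, biomarkers = c("BM1", "BM2")) {
  set.seed(seed)
  grid <- expand.grid(
    replicate = seq_len(n_rep),
    day = seq_len(n_day),
    density = (seq_len(n_d) - 1) * 1e5,
    temperature = 20 + 5 * (seq_len(n_t) - 1),
    biomarker = biomarkers,
    stringsAsFactors = FALSE
  )
  make_battery(
    temperature = grid$temperature, density = grid$density, day = grid$day,
    replicate = grid$replicate, biomarker = grid$biomarker,
    value = exp(rnorm(nrow(grid), mean = 2, sd = 0.5))
  )
}

# Straight-line spreadsheet-style IBR recomputation, independent of the
# package internals: plain base-R loops over days/biomarkers/treatments.
ibr_oracle <- function(battery, base = 10, absolute = TRUE,
                       ref_temperature = min(battery$temperature),
                       ref_density = min(battery$density)) {
  days <- sort(unique(battery$day))
  bms <- unique(battery$biomarker)
  trts <- unique(battery[c("temperature", "density")])
  trts <- trts[order(trts$temperature, trts$density), ]
  out <- data.frame()
  for (dy in days) {
    a_mat <- matrix(0, nrow(trts), length(bms))
    for (j in seq_along(bms)) {
      xi <- numeric(nrow(trts))
      for (i in seq_len(nrow(trts))) {
        sel <- battery$day == dy & battery$biomarker == bms[j] &
          battery$temperature == trts$temperature[i] &
          battery$density == trts$density[i]
        xi[i] <- mean(battery$value[sel])
      }
      iref <- which(trts$temperature == ref_temperature &
                      trts$density == ref_density)
      yi <- log(xi / xi[iref]) / log(base)
      mu <- mean(yi)
      sigma <- sd(yi)
      zi <- if (sigma > 0) (yi - mu) / sigma else rep(0, length(yi))
      a_mat[, j] <- zi - zi[iref]
    }
    ibr <- if (absolute) rowSums(abs(a_mat)) else rowSums(a_mat)
    out <- rbind(out, data.frame(temperature = trts$temperature,
                                 density = trts$density, day = dy, ibr = ibr))
  }
  out
}

# Reference three-way ANOVA table via stats::aov (oracle only).
aov_oracle <- function(battery, biomarker) {
  d <- battery[battery$biomarker == biomarker, ]
  fit <- stats::aov(value ~ factor(temperature) * factor(density) * factor(day),
                    data = d)
  as.data.frame(stats::anova(fit))
}
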