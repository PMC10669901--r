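test_that("log-ratio handles identities, bases, and domain errors", {
  expect_equal(ibr_log_ratio(7, 7), 0)
  expect_equal(ibr_log_ratio(100, 10, base = 10), 1)
  expect_equal(ibr_log_ratio(2, 8, base = 2), -2)
  expect_error(ibr_log_ratio(0, 1), class = "ibrtox_domain_error")
  expect_error(ibr_log_ratio(1, -2), class = "ibrtox_domain_error")
})

test_that("standardization centres, scales, and is shift-invariant", {
  s <- ibr_standardize(c(-1, 0, 1))
  expect_equal(s$z, c(-1, 0, 1))
  expect_equal(s$mu, 0)
  expect_equal(s$sigma, 1)

  y <- c(1, 2, 3, 4)
  # by hand: mu = 2.5, sigma = sqrt(5/3)
  expect_equal(ibr_standardize(y)$z,
               (y - 2.5) / sqrt(5 / 3), tolerance = 1e-12)
  expect_equal(ibr_standardize(y)$z,
               c(-1.1618950, -0.3872983, 0.3872983, 1.1618950),
               tolerance = 1e-6)
  expect_equal(ibr_standardize(y + 17)$z, ibr_standardize(y)$z)
  expect_error(ibr_standardize(c(3, 3, 3)), class = "ibrtox_degenerate_error")
  expect_error(ibr_standardize(1), class = "ibrtox_domain_error")
})

test_that("the two-treatment worked example gives IBR = sqrt(2) exactly", {
  res <- compute_ibr(worked_example_battery())
  comp <- res$components[res$components$density == 1e5, ]
  expect_equal(comp$y, 1)
  expect_equal(comp$sigma, sqrt(0.5), tolerance = 1e-12)
  expect_equal(comp$a, sqrt(2), tolerance = 1e-12)
  score <- res$scores$ibr[res$scores$density == 1e5]
  expect_equal(score, sqrt(2), tolerance = 1e-12)
})

test_that("the reference treatment scores zero under both aggregations", {
  battery <- generate_battery(clam_preset(seed = 8))
  for (agg in c("absolute_sum", "signed_sum")) {
    res <- compute_ibr(battery, ibr_options(aggregation = agg))
    ref_scores <- res$scores$ibr[res$scores$temperature == 20 &
                                   res$scores$density == 0]
    expect_equal(ref_scores, rep(0, 4))
  }
})

test_that("a battery identical to the reference everywhere gives IBR 0", {
  battery <- make_battery(
    temperature = rep(c(20, 20, 25, 25), each = 2),
    density = rep(c(0, 1e5, 0, 1e5), each = 2),
    day = 1, replicate = rep(1:2, 4), biomarker = "GST", value = 12
  )
  res <- compute_ibr(battery)
  expect_equal(res$scores$ibr, rep(0, 4))
})

test_that("IBR is invariant to units changes and to the log base", {
  battery <- generate_battery(clam_preset(seed = 12))
  base_res <- compute_ibr(battery)

  rescaled <- battery
  sel <- rescaled$biomarker == "SOD"
  rescaled$value[sel] <- rescaled$value[sel] * 1000  # e.g. U -> mU
  expect_equal(compute_ibr(rescaled)$scores, base_res$scores, tolerance = 1e-9)
  expect_equal(compute_ibr(rescaled)$components$a, base_res$components$a,
               tolerance = 1e-9)

  for (base in c(2, exp(1))) {
    alt <- compute_ibr(battery, ibr_options(log_base = base))
    expect_equal(alt$scores$ibr, base_res$scores$ibr, tolerance = 1e-9)
  }
})

test_that("absolute-sum IBR dominates the signed sum on random batteries", {
  for (seed in 1:5) {
    battery <- random_small_battery(seed, n_t = 2, n_d = 2, n_day = 2,
                                    biomarkers = c("BM1", "BM2", "BM3"))
    abs_res <- compute_ibr(battery)$scores
    sgn_res <- compute_ibr(battery, ibr_options(aggregation = "signed_sum"))$scores
    expect_true(all(abs_res$ibr >= abs(sgn_res$ibr) - 1e-12))
  }
})

test_that("compute_ibr matches a straight-line independent recomputation", {
  for (seed in 1:10) {
    battery <- random_small_battery(seed, n_t = 2, n_d = 2, n_day = 2,
                                    n_rep = 3, biomarkers = c("BM1", "BM2", "BM3"))
    for (absolute in c(TRUE, FALSE)) {
      agg <- if (absolute) "absolute_sum" else "signed_sum"
      got <- compute_ibr(battery, ibr_options(aggregation = agg))$scores
      want <- ibr_oracle(battery, absolute = absolute)
      got <- got[order(got$day, got$temperature, got$density), ]
      want <- want[order(want$day, want$temperature, want$density), ]
      expect_equal(got$ibr, want$ibr, tolerance = 1e-12)
    }
  }
})

test_that("IBR increases strictly with dose at low noise (induction pattern)", {
  cfg <- clam_preset(seed = 21, noise_cv = 1e-6)
  res <- compute_ibr(generate_battery(cfg))
  scores <- res$scores
  for (tt in unique(scores$temperature)) {
    for (dy in unique(scores$day)) {
      s <- scores[scores$temperature == tt & scores$day == dy, ]
      s <- s[order(s$density), ]
      expect_true(all(diff(s$ibr) > 0),
                  info = sprintf("temperature %g day %g", tt, dy))
    }
  }
})

test_that("star coordinates mirror the deviations at fixed angles", {
  battery <- generate_battery(clam_preset(seed = 4))
  res <- compute_ibr(battery)

  ref <- star_coordinates(res, 20, 0, 1)
  expect_equal(ref$radius, rep(0, 7))

  st <- star_coordinates(res, 30, 1e6, 5)
  expect_equal(nrow(st), 7)
  expect_equal(st$biomarker, res$biomarkers)
  expect_equal(sum(st$angle), 2 * pi * sum(0:6) / 7)
  comp <- res$components[res$components$temperature == 30 &
                           res$components$density == 1e6 &
                           res$components$day == 5, ]
  expect_identical(st$radius, comp$a[match(st$biomarker, comp$biomarker)])

  expect_error(star_coordinates(res, 99, 0, 1), class = "ibrtox_lookup_error")
})

test_that("a missing reference treatment is a hard error", {
  battery <- generate_battery(clam_preset(seed = 5))
  no_ref <- battery[!(battery$temperature == 20 & battery$density == 0), ]
  expect_error(
    compute_ibr(no_ref, ibr_options(reference = list(temperature = 20, density = 0))),
    class = "ibrtox_reference_error"
  )
})
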