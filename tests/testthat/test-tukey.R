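test_that("studentized range tail has the right limits and monotonicity", {
  expect_equal(studentized_range_upper_tail(0, 3, 10), 1)
  qs <- seq(0.2, 8, by = 0.4)
  p <- studentized_range_upper_tail(qs, 4, 12)
  expect_true(all(diff(p) < 0))
  expect_true(all(p >= 0 & p <= 1))
  expect_error(studentized_range_upper_tail(1, 1, 10), class = "ibrtox_domain_error")
  expect_error(studentized_range_upper_tail(-1, 3, 10), class = "ibrtox_domain_error")
})

test_that("k = 2 reduces to the two-sample t distribution", {
  qs <- c(0.3, 1, 2, 3.2, 4.8, 6)
  for (df in c(2, 5, 18, 72)) {
    expect_equal(
      studentized_range_upper_tail(qs, 2, df),
      2 * pt(qs / sqrt(2), df, lower.tail = FALSE),
      tolerance = 1e-6
    )
  }
})

test_that("the quadrature matches base R's ptukey to 1e-6", {
  grid <- expand.grid(q = c(0.5, 1.5, 2.5, 3.5, 3.88, 5, 7),
                      k = c(2, 3, 5, 9), df = c(10, 18, 72))
  mine <- mapply(function(q, k, df) studentized_range_upper_tail(q, k, df),
                 grid$q, grid$k, grid$df)
  ref <- ptukey(grid$q, grid$k, grid$df, lower.tail = FALSE)
  expect_lt(max(abs(mine - ref)), 1e-6)
  # q = 3.88 with 3 groups and 10 error df sits at the 5% point
  expect_equal(studentized_range_upper_tail(3.88, 3, 10), 0.0498139,
               tolerance = 1e-5)
})

test_that("small error-df tails match a high-precision external oracle", {
  # frozen from an independent studentized-range CDF implementation
  # (ptukey itself is only ~2e-6 accurate at df = 3)
  expect_equal(studentized_range_upper_tail(7, 3, 3), 0.03194716711714318,
               tolerance = 1e-8)
  expect_equal(studentized_range_upper_tail(5, 3, 3), 0.07626939354031004,
               tolerance = 1e-8)
})

test_that("identical group means earn one shared letter with p = 1", {
  battery <- make_battery(
    temperature = rep(c(20, 25, 30), each = 3),
    density = 0, day = 1, replicate = rep(1:3, 3),
    biomarker = "GST", value = rep(c(1, 2, 3), times = 3)
  )
  tk <- tukey_hsd(battery, "GST", day = 1)
  expect_equal(tk$pairs$adj.p.value, rep(1, 3))
  expect_equal(unique(tk$letters$letters), "a")
})

test_that("widely separated groups get distinct letters and tiny p", {
  battery <- make_battery(
    temperature = 20, density = rep(c(0, 1e5), each = 3), day = 1,
    replicate = rep(1:3, 2), biomarker = "GST",
    value = c(10, 10.01, 9.99, 110, 110.01, 109.99)
  )
  tk <- tukey_hsd(battery, "GST", day = 1)
  expect_lt(tk$pairs$adj.p.value, 1e-6)
  expect_setequal(tk$letters$letters, c("a", "b"))
})

test_that("tukey_hsd agrees with stats::TukeyHSD on a full day's groups", {
  battery <- generate_battery(clam_preset(seed = 14))
  tk <- tukey_hsd(battery, "CAT", day = 3)
  d <- battery[battery$biomarker == "CAT" & battery$day == 3, ]
  d$group <- paste0("T", d$temperature, "_D",
                    format(d$density, scientific = FALSE, trim = TRUE))
  ref <- TukeyHSD(aov(value ~ group, data = d))$group
  key_mine <- paste(tk$pairs$group2, tk$pairs$group1, sep = "-")
  ord <- match(rownames(ref), key_mine)
  expect_false(anyNA(ord))
  expect_equal(tk$pairs$adj.p.value[ord], unname(ref[, "p adj"]),
               tolerance = 1e-6)
  expect_equal(abs(tk$pairs$estimate[ord]), abs(unname(ref[, "diff"])),
               tolerance = 1e-10)
})

test_that("letters exactly reproduce the significance matrix they came from", {
  battery <- generate_battery(clam_preset(seed = 14))
  for (dy in c(1, 7)) {
    tk <- tukey_hsd(battery, "SOD", day = dy)
    letters <- setNames(tk$letters$letters, tk$letters$group)
    share <- function(g1, g2) {
      length(intersect(strsplit(letters[[g1]], "")[[1]],
                       strsplit(letters[[g2]], "")[[1]])) > 0
    }
    for (r in seq_len(nrow(tk$pairs))) {
      expect_equal(share(tk$pairs$group1[r], tk$pairs$group2[r]),
                   tk$pairs$adj.p.value[r] >= tk$alpha)
    }
  }
})

test_that("compact letter display covers the canonical cases", {
  pairs_none <- data.frame(group1 = c("A", "A", "B"), group2 = c("B", "C", "C"),
                           adj.p.value = c(0.9, 0.8, 0.7))
  cld <- compact_letter_display(pairs_none)
  expect_equal(unique(cld$letters), "a")

  pairs_all <- data.frame(group1 = c("A", "A", "B"), group2 = c("B", "C", "C"),
                          adj.p.value = c(0.001, 0.001, 0.001))
  cld2 <- compact_letter_display(pairs_all)
  expect_equal(sort(cld2$letters), c("a", "b", "c"))

  # chain: A differs from C; B bridges both
  pairs_chain <- data.frame(group1 = c("A", "A", "B"), group2 = c("B", "C", "C"),
                            adj.p.value = c(0.5, 0.001, 0.5))
  cld3 <- compact_letter_display(pairs_chain,
                                 means = c(A = 3, B = 2, C = 1))
  got <- setNames(cld3$letters, cld3$group)
  expect_equal(got[["A"]], "a")
  expect_equal(got[["B"]], "ab")
  expect_equal(got[["C"]], "b")
})

test_that("letter sharing matches random significance patterns (brute force)", {
  set.seed(77)
  for (case in 1:60) {
    k <- sample(3:6, 1)
    groups <- LETTERS[1:k]
    ij <- combn(k, 2)
    pairs <- data.frame(
      group1 = groups[ij[1, ]], group2 = groups[ij[2, ]],
      adj.p.value = ifelse(runif(ncol(ij)) < 0.4, 0.001, 0.5)
    )
    cld <- compact_letter_display(pairs, alpha = 0.05)
    letters <- setNames(cld$letters, cld$group)
    expect_true(all(nchar(letters) > 0))
    for (r in seq_len(nrow(pairs))) {
      shared <- length(intersect(
        strsplit(letters[[pairs$group1[r]]], "")[[1]],
        strsplit(letters[[pairs$group2[r]]], "")[[1]]
      )) > 0
      expect_equal(shared, pairs$adj.p.value[r] >= 0.05,
                   info = sprintf("case %d pair %s-%s", case,
                                  pairs$group1[r], pairs$group2[r]))
    }
  }
})

test_that("unequal group sizes are rejected", {
  battery <- make_battery(
    temperature = 20, density = c(0, 0, 0, 1e5, 1e5), day = 1,
    replicate = c(1, 2, 3, 1, 2), biomarker = "GST", value = c(1, 2, 3, 4, 5)
  )
  expect_error(tukey_hsd(battery, "GST", day = 1),
               class = "ibrtox_balance_error")
})
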