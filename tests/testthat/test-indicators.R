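catalog <- cascade_indicators()

test_that("indicator values are exact counts and percentages", {
  p <- make_participants(10, seed = 1)
  p$hiv_positive <- rep(c(TRUE, FALSE), c(4, 6))
  p$knows_status <- p$on_art <- p$virally_suppressed <- FALSE
  v <- compute_indicator(catalog$hiv_prevalence, p)
  expect_equal(v$numerator, 4)
  expect_equal(v$denominator, 10)
  expect_equal(v$value, 40.0)

  n <- compute_indicator(catalog$trial_participants, p)
  expect_equal(n$value, 10)
  expect_true(is.na(n$denominator))
})

test_that("a fully treated cascade stage reads exactly 100", {
  p <- make_participants(12, seed = 2)
  p$hiv_positive <- rep(c(TRUE, FALSE), c(7, 5))
  p$knows_status <- p$hiv_positive
  p$on_art <- p$knows_status       # all 7 diagnosed are on ART
  p$virally_suppressed <- FALSE
  v <- compute_indicator(catalog$art_of_diagnosed, p)
  expect_equal(v$denominator, 7)
  expect_equal(v$value, 100.0)
})

test_that("every indicator equals a brute-force row-by-row count", {
  p <- synth_generate(synth_params(n_participants = 700, seed = 13))$participants
  vals <- compute_cascade(catalog, p)
  brute <- list(
    trial_participants = c(nrow(p), NA),
    hiv_prevalence = c(sum(p$hiv_positive), nrow(p)),
    diagnosed_of_positive = c(sum(p$knows_status), sum(p$hiv_positive)),
    art_of_diagnosed = c(sum(p$on_art), sum(p$knows_status)),
    suppressed_of_art = c(sum(p$virally_suppressed), sum(p$on_art))
  )
  for (v in vals) {
    expect_equal(v$numerator, brute[[v$indicator]][1])
    if (!is.na(brute[[v$indicator]][2])) {
      expect_equal(v$denominator, brute[[v$indicator]][2])
      expect_equal(v$value, 100 * v$numerator / v$denominator)
    }
  }
})

test_that("zero denominators yield undefined values, never 0 or 100", {
  p <- make_participants(5, seed = 3)
  p$hiv_positive <- p$knows_status <- p$on_art <- p$virally_suppressed <- FALSE
  vals <- compute_cascade(catalog, p)
  expect_equal(vals$hiv_prevalence$value, 0.0)
  for (nm in c("diagnosed_of_positive", "art_of_diagnosed",
               "suppressed_of_art")) {
    expect_true(is.na(vals[[nm]]$value))
    expect_equal(vals[[nm]]$undefined_reason, "denominator is zero")
  }
})

test_that("cascade linkage holds: each denominator is the prior numerator", {
  for (seed in 1:4) {
    p <- synth_generate(synth_params(n_participants = 400,
                                     seed = seed))$participants
    vals <- compute_cascade(catalog, p)
    ratios <- vals[c("hiv_prevalence", "diagnosed_of_positive",
                     "art_of_diagnosed", "suppressed_of_art")]
    for (k in 2:length(ratios)) {
      expect_equal(ratios[[k]]$denominator, ratios[[k - 1]]$numerator)
    }
  }
})

test_that("cascade counts are monotone non-increasing", {
  for (seed in 5:8) {
    p <- synth_generate(synth_params(n_participants = 300,
                                     seed = seed))$participants
    expect_true(sum(p$virally_suppressed) <= sum(p$on_art))
    expect_true(sum(p$on_art) <= sum(p$knows_status))
    expect_true(sum(p$knows_status) <= sum(p$hiv_positive))
    expect_true(sum(p$hiv_positive) <= nrow(p))
  }
})

test_that("local/global comparison pairs values and differences", {
  p <- make_participants(100, seed = 4)
  g <- compute_cascade(catalog, p)
  cmp0 <- compare_local_global(catalog, g, g)
  expect_true(all(cmp0$difference[!is.na(cmp0$difference)] == 0))

  l <- g
  l$diagnosed_of_positive$value <- 80.0
  g2 <- g
  g2$diagnosed_of_positive$value <- 90.0
  cmp <- compare_local_global(catalog, l, g2)
  row <- cmp[cmp$indicator == "diagnosed_of_positive", ]
  expect_equal(row$difference, -10.0)
  expect_equal(row$target, 90)

  expect_error(compare_local_global(catalog, g[-1], g), "contract error")
})

test_that("breakdown proportions honor the two normalization modes", {
  p <- make_participants(50, seed = 6)
  p$education <- "primary"
  bd <- normalize_breakdown(p, "education", "total_population")
  expect_equal(unname(bd$proportions["primary"]), 1.0)

  # all HIV+ share one label; indicator mode must return it at 1.0
  p2 <- make_participants(60, seed = 7, prevalence = 0.4)
  p2$education <- ifelse(p2$hiv_positive, "secondary",
                         sample(c("none", "primary"), 60, replace = TRUE))
  bi <- normalize_breakdown(p2, "education", "indicator_population",
                            catalog$hiv_prevalence)
  expect_equal(unname(bi$proportions["secondary"]), 1.0)
  expect_equal(bi$base_size, sum(p2$hiv_positive))

  # brute-force tallies on a random bundle
  p3 <- synth_generate(synth_params(n_participants = 500,
                                    seed = 21))$participants
  bt <- normalize_breakdown(p3, "employment", "total_population")
  for (lab in names(bt$counts)) {
    expect_equal(bt$counts[[lab]], sum(p3$employment == lab))
    expect_equal(unname(bt$proportions[lab]),
                 sum(p3$employment == lab) / nrow(p3))
  }
  expect_equal(sum(bt$proportions), 1.0)

  # empty base is flagged, not NaN
  p4 <- make_participants(5, seed = 8)
  p4$hiv_positive[] <- FALSE
  be <- normalize_breakdown(p4, "education", "indicator_population",
                            catalog$hiv_prevalence)
  expect_true(be$undefined)
  expect_equal(be$base_size, 0)
})

test_that("custom indicators parse field expressions and refuse the rest", {
  defn <- custom_indicator("female_art", list(
    kind = "ratio",
    numerator = "on_art & sex == 'female'",
    denominator = "knows_status & sex == 'female'"
  ))
  p <- make_participants(200, seed = 9)
  v <- compute_indicator(defn, p)
  expect_equal(v$numerator, sum(p$on_art & p$sex == "female"))
  expect_equal(v$denominator, sum(p$knows_status & p$sex == "female"))

  expect_error(custom_indicator("bad", list(numerator = "nonexistent_field",
                                            denominator = "TRUE")),
               "unknown field")
  expect_error(custom_indicator("evil", list(numerator = "system('ls')",
                                             denominator = "TRUE")),
               "disallowed")
})
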