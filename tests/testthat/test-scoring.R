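test_that("band mappings reproduce the score table in every band", {
  # alpha bands: [0.75,1] -> 0, [0.50,0.75) -> 1, [0.25,0.50) -> 2, else 3
  alpha_cases <- list(c(1.00, 0), c(0.80, 0), c(0.75, 0), c(0.60, 1),
                      c(0.50, 1), c(0.40, 2), c(0.25, 2), c(0.20, 3),
                      c(0.00, 3))
  for (cs in alpha_cases)
    expect_identical(score_alpha(cs[1]), as.integer(cs[2]))
  # beta bands: [0.90,1] -> 0, [0.80,0.90) -> 1, [0.70,0.80) -> 2, else 3
  beta_cases <- list(c(1.00, 0), c(0.95, 0), c(0.90, 0), c(0.85, 1),
                     c(0.80, 1), c(0.75, 2), c(0.70, 2), c(0.65, 3),
                     c(0.00, 3))
  for (cs in beta_cases)
    expect_identical(score_beta(cs[1]), as.integer(cs[2]))
  expect_error(score_alpha(1.2), class = "cowgait_domain_error")
  expect_error(score_beta(-0.1), class = "cowgait_domain_error")
})

test_that("every coefficient in [0,1] maps to exactly one score", {
  grid <- seq(0, 1, by = 1e-4)
  for (f in list(score_alpha, score_beta)) {
    s <- vapply(grid, f, 1L)
    expect_true(all(s %in% 0:3))
    expect_true(all(diff(s) <= 0))  # monotone non-increasing in C
  }
})

test_that("final score matches the exhaustive hand-computed table", {
  # ceiling((s_alpha + s_beta) / 2) tabulated by hand for all 16 pairs
  oracle <- matrix(c(0, 1, 1, 2,
                     1, 1, 2, 2,
                     1, 2, 2, 3,
                     2, 2, 3, 3), 4, 4, byrow = TRUE)
  for (sa in 0:3) for (sb in 0:3) {
    fs <- final_score(sa, sb)
    expect_identical(fs$s_final, as.integer(oracle[sa + 1, sb + 1]))
    expect_identical(fs$grade_label,
                     c("normal", "mild", "moderate", "severe")[fs$s_final + 1])
  }
  expect_error(final_score(4, 0), class = "cowgait_domain_error")
  expect_error(final_score(1, -1), class = "cowgait_domain_error")
  # monotone in each argument
  for (sa in 0:3) for (sb in 0:2)
    expect_true(final_score(sa, sb + 1)$s_final >=
                final_score(sa, sb)$s_final)
})

test_that("overlap coefficients count frames or intersect intervals", {
  ref <- reference_model()
  # 60 of 100 alpha frames inside the reference
  s <- series_with_fraction(0.60, 1.0, n = 100, seed = 3)
  expect_equal(overlap_coefficient(s, ref$alpha_low, ref$alpha_high,
                                   "alpha"), 0.60)
  expect_equal(overlap_coefficient(s, ref$beta_low, ref$beta_high,
                                   "beta"), 1.0)
  all_out <- series_with_fraction(0, 0, n = 100, seed = 4)
  expect_equal(overlap_coefficient(all_out, ref$alpha_low, ref$alpha_high,
                                   "alpha"), 0)
  # interval overlap: contained -> 1, disjoint -> 0, straddling -> ratio
  inside <- angle_series("i", 25, 0:59, runif(60, 150, 160),
                         runif(60, 176, 179))
  expect_equal(overlap_coefficient(inside, 146.26, 164.87, "alpha",
                                   "interval_overlap"), 1)
  expect_equal(overlap_coefficient(inside, 100, 140, "alpha",
                                   "interval_overlap"), 0)
  straddle <- angle_series("s", 25, 0:1, c(140, 160), c(178, 178))
  expect_equal(overlap_coefficient(straddle, 150, 170, "alpha",
                                   "interval_overlap"), 0.5)
  empty <- angle_series("e", 25, 0:1, c(NA, NA), c(178, 178))
  expect_error(overlap_coefficient(empty, 146.26, 164.87, "alpha"),
               class = "cowgait_insufficient_data")
})

test_that("score_bout composes the pipeline deterministically", {
  cfg <- gait_sim_config(grade = 0, noise_sd = 0, dropout_rate = 0,
                         seed = 5)
  bout <- realize_keypoints(synthesize_angle_series(cfg), cfg)
  r1 <- score_bout(bout)
  r2 <- score_bout(bout)
  expect_identical(score_report(r1), score_report(r2))
  # a normal bout built inside the reference bands scores 0 by construction
  expect_identical(r1$s_final, 0L)
  expect_equal(r1$c_alpha, 1)
  expect_equal(r1$c_beta, 1)
  expect_identical(r1$grade_label, "normal")
  # a severe bout sweeping the full severe intervals scores at least 2
  sev <- gait_sim_config(grade = 3, noise_sd = 0, dropout_rate = 0,
                         alpha_mean = 144.805, alpha_half_range = 11.465,
                         beta_mean = 171.47, beta_half_range = 8.48,
                         seed = 6)
  sb <- realize_keypoints(synthesize_angle_series(sev), sev)
  rs <- score_bout(sb)
  expect_gte(rs$s_final, 2L)
  # too few valid frames propagates as insufficient data with bout context
  short <- make_collinear_bout(10)
  expect_error(score_bout(short), "10 valid",
               class = "cowgait_insufficient_data")
})

test_that("reference model validates intervals and band edges", {
  expect_error(reference_model(alpha_low = 165, alpha_high = 146),
               class = "cowgait_domain_error")
  expect_error(reference_model(alpha_band_edges = c(0.25, 0.5, 0.75)),
               class = "cowgait_domain_error")
  expect_error(reference_model(beta_band_edges = c(0.9, 0.8)),
               class = "cowgait_domain_error")
  # custom band edges shift the mapping
  ref <- reference_model(alpha_band_edges = c(0.9, 0.6, 0.3))
  expect_identical(score_alpha(0.7, ref$alpha_band_edges), 1L)
})

test_that("grade reference table is internally consistent", {
  ref <- cow_grade_reference()
  expect_identical(nrow(ref), 8L)
  expect_true(all(ref$interval_low <= ref$mean &
                  ref$mean <= ref$interval_high))
  expect_equal(ref$amplitude, ref$interval_high - ref$interval_low)
})
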