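test_that("keypoint_distance is Euclidean, symmetric and non-negative", {
  expect_equal(keypoint_distance(c(0, 0), c(3, 4)), 5)
  expect_equal(keypoint_distance(c(7, -2), c(7, -2)), 0)
  expect_equal(keypoint_distance(c(1, 2), c(4, 6)), 5)
  expect_equal(keypoint_distance(c(4, 6), c(1, 2)), 5)
  expect_true(is.na(keypoint_distance(c(NA, 0), c(1, 1))))
})

test_that("vertex_angle handles canonical and degenerate triangles", {
  expect_equal(vertex_angle(c(1, 0), c(0, 0), c(2, 0)), 180)
  expect_equal(vertex_angle(c(0, 1), c(0, 0), c(1, 1)), 90)
  # isoceles: sides 5, 5, base 6 -> acos(14/50)
  expect_equal(vertex_angle(c(3, 4), c(0, 0), c(6, 0)),
               acos(14 / 50) * 180 / pi, tolerance = 1e-12)
  expect_equal(vertex_angle(c(3, 4), c(0, 0), c(6, 0)),
               angle_oracle(c(3, 4), c(0, 0), c(6, 0)), tolerance = 1e-12)
  # vertex coincides with an endpoint -> degenerate, missing
  expect_true(is.na(vertex_angle(c(0, 0), c(0, 0), c(1, 1))))
  expect_true(is.na(vertex_angle(c(1, NA), c(0, 0), c(2, 0))))
})

test_that("vertex_angle matches the dot-product oracle on random triangles", {
  set.seed(101)
  for (i in 1:1000) {
    p <- random_triangle()
    expect_equal(vertex_angle(p[1, ], p[2, ], p[3, ]),
                 angle_oracle(p[1, ], p[2, ], p[3, ]), tolerance = 1e-9)
  }
})

test_that("vertex_angle is invariant under similarity transforms", {
  set.seed(102)
  for (i in 1:200) {
    p <- random_triangle()
    base <- vertex_angle(p[1, ], p[2, ], p[3, ])
    th <- runif(1, 0, 2 * pi)
    sc <- runif(1, 0.1, 10)
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
    if (i %% 2 == 0) R <- R %*% diag(c(1, -1))  # reflection half the time
    q <- sweep(p %*% t(R) * sc, 2, runif(2, -500, 500), "+")
    expect_equal(vertex_angle(q[1, ], q[2, ], q[3, ]), base,
                 tolerance = 1e-9)
  }
})

test_that("the three vertex angles of a triangle sum to 180 degrees", {
  set.seed(103)
  for (i in 1:200) {
    p <- random_triangle()
    total <- vertex_angle(p[1, ], p[2, ], p[3, ]) +
             vertex_angle(p[2, ], p[1, ], p[3, ]) +
             vertex_angle(p[3, ], p[1, ], p[2, ])
    expect_equal(total, 180, tolerance = 1e-6)
  }
})

test_that("cleaning interpolates short gaps and leaves long ones missing", {
  bout <- make_collinear_bout(9)
  # untouched when everything is confident
  expect_equal(clean_trajectory(bout)$frames, bout$frames)
  # single bad frame between x = 10 and x = 12 -> midpoint 11
  b <- make_bout(rbind(c(10, 5), c(99, 99), c(12, 7)),
                 c(0, 0), c(1, 0), c(2, 0))
  b$frames$K1_likelihood[2] <- 0.1
  cl <- clean_trajectory(b, likelihood_threshold = 0.6)
  expect_equal(cl$frames$K1_x[2], 11)
  expect_equal(cl$frames$K1_y[2], 6)
  expect_equal(cl$frames$K1_likelihood[2], 0.6)
  # a gap of max_gap + 1 stays missing; max_gap is bridged
  n <- 12
  b2 <- make_bout(cbind(seq_len(n), 0), c(0, 0), c(1, 0), c(2, 0))
  b2$frames$K1_likelihood[3:6] <- 0   # gap of 4
  b2$frames$K1_likelihood[9:11] <- 0  # gap of 3
  cl2 <- clean_trajectory(b2, max_gap = 3)
  expect_true(all(is.na(cl2$frames$K1_x[3:6])))
  expect_equal(cl2$frames$K1_x[9:11], 9:11 + 0)
  # leading and trailing bad frames are never extrapolated
  b3 <- make_bout(cbind(seq_len(5), 0), c(0, 0), c(1, 0), c(2, 0))
  b3$frames$K1_likelihood[c(1, 5)] <- 0
  cl3 <- clean_trajectory(b3, max_gap = 10)
  expect_true(is.na(cl3$frames$K1_x[1]))
  expect_true(is.na(cl3$frames$K1_x[5]))
})

test_that("angle series computation follows the triangle wiring", {
  bout <- make_collinear_bout(6)
  s <- compute_angle_series(bout)
  expect_equal(s$frames$alpha, rep(180, 6))
  expect_equal(s$frames$beta, rep(180, 6))
  # K1 missing only breaks alpha; K3 missing only breaks beta
  bout$frames$K1_x[2] <- NA
  bout$frames$K3_x[4] <- NA
  s2 <- compute_angle_series(bout)
  expect_true(is.na(s2$frames$alpha[2]) && !is.na(s2$frames$beta[2]))
  expect_true(is.na(s2$frames$beta[4]) && !is.na(s2$frames$alpha[4]))
  # hand-checked geometry: K2 raised over the K1-K4 base
  b <- make_bout(c(1200, 500), c(800, 400), c(400, 500), c(0, 500))
  s3 <- compute_angle_series(b)
  expect_equal(s3$frames$alpha,
               angle_oracle(c(800, 400), c(1200, 500), c(0, 500)),
               tolerance = 1e-9)
  expect_equal(s3$frames$beta,
               angle_oracle(c(400, 500), c(800, 400), c(0, 500)),
               tolerance = 1e-9)
})

test_that("summaries reproduce interval statistics and enforce min frames", {
  vals <- c(146.26, 150.0, 164.87)
  s <- angle_series("t", 25, 0:2, vals, c(173.53, 176, 179.93))
  smry <- summarize_angles(s, min_frames = 3)
  a <- smry[smry$angle == "alpha", ]
  expect_equal(a$interval_low, 146.26)
  expect_equal(a$interval_high, 164.87)
  expect_equal(a$amplitude, 18.61, tolerance = 1e-9)
  expect_equal(a$mean, mean(vals))
  b <- smry[smry$angle == "beta", ]
  expect_equal(b$amplitude, 6.40, tolerance = 1e-9)
  # constant series: zero amplitude, interval collapses onto the mean
  cs <- angle_series("c", 25, 0:59, rep(165, 60), rep(178, 60))
  csm <- summarize_angles(cs)
  expect_equal(csm$amplitude, c(0, 0))
  expect_equal(csm$interval_low, csm$interval_high)
  expect_equal(csm$interval_low, csm$mean)
  # amplitude = width holds exactly in minmax mode
  set.seed(9)
  rs <- angle_series("r", 25, 0:99, runif(100, 140, 170),
                     runif(100, 170, 180))
  rsm <- summarize_angles(rs)
  expect_identical(rsm$amplitude, rsm$interval_high - rsm$interval_low)
  # percentile mode trims the tails
  psm <- summarize_angles(rs, interval_method = "percentile",
                          percentile_tail = 10)
  expect_true(all(psm$amplitude < rsm$amplitude))
  expect_equal(psm$interval_low[1],
               unname(quantile(rs$frames$alpha, 0.10)))
  # too few valid frames is a named insufficient-data error
  short <- angle_series("s", 25, 0:9, rep(160, 10), rep(178, 10))
  expect_error(summarize_angles(short), "alpha",
               class = "cowgait_insufficient_data")
})

test_that("angle series validate their domain and export to CSV", {
  expect_error(angle_series("x", 25, 0:1, c(10, 200), c(170, 170)),
               class = "cowgait_domain_error")
  expect_error(angle_series("x", 25, 0:2, c(10, 20), c(170, 170)),
               class = "cowgait_domain_error")
  s <- angle_series("x", 25, 0:1, c(160, NA), c(178, 177))
  path <- withr::local_tempfile(fileext = ".csv")
  write_angle_series(s, path)
  back <- read.csv(path)
  expect_equal(back$alpha, s$frames$alpha)
  expect_equal(back$beta, s$frames$beta)
})
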