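test_that("signed angle magnitude matches the arccos definition", {
  fr <- frame_convention("+x")
  expect_equal(signed_angle(c(1, 0), c(1, 0), fr), 0)
  expect_equal(abs(signed_angle(c(1, 0), c(0, 1), fr)), 90)
  expect_equal(abs(signed_angle(c(1, 0), c(1, 1), fr)), 45)
})

test_that("signed angle agrees with a rotation-matrix oracle", {
  # oracle: rotate v1 by a known angle with an explicit rotation matrix;
  # the recovered angle must match in magnitude, and flipping the frame
  # orientation must flip the sign
  set.seed(41)
  fr_px <- frame_convention("+x")
  fr_mx <- frame_convention("-x")
  for (i in 1:200) {
    v1 <- rnorm(2)
    while (sum(v1^2) < 1e-6) v1 <- rnorm(2)
    th <- runif(1, -179, 179)
    R <- matrix(c(cos(th * pi / 180), sin(th * pi / 180),
                  -sin(th * pi / 180), cos(th * pi / 180)), 2)
    v2 <- as.numeric(R %*% v1)
    a_px <- signed_angle(v1, v2, fr_px)
    expect_equal(abs(a_px), abs(th), tolerance = 1e-9)
    expect_equal(signed_angle(v1, v2, fr_mx), -a_px, tolerance = 1e-9)
  }
})

test_that("signed angle magnitude matches extended-precision arccos on random pairs", {
  set.seed(7)
  for (i in 1:1000) {
    v1 <- rnorm(2); v2 <- rnorm(2)
    if (sum(v1^2) < 1e-8 || sum(v2^2) < 1e-8) next
    expected <- acos(max(-1, min(1, sum(v1 * v2) /
                                   sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
    expect_equal(abs(signed_angle(v1, v2)), expected, tolerance = 1e-9)
  }
})

test_that("zero-length vectors raise a degenerate-geometry error", {
  expect_error(signed_angle(c(0, 0), c(1, 0), what = "S1 endplate"),
               "zero-length.*S1 endplate")
})

test_that("pt_line is the femoral-midpoint to S1-midpoint vector", {
  lms <- straight_landmarks()
  expect_equal(pt_line(lms), c(0, -10))

  # asymmetric configuration against manual midpoint arithmetic
  pts <- list(
    femoral_head_1 = c(3, 112), femoral_head_2 = c(9, 108),
    sacrum_center = c(1, 104),
    s1_sup_ant = c(14, 99), s1_sup_post = c(-6, 103),
    l1_sup_ant = c(9, 70), l1_sup_post = c(-9, 72),
    t1_sup_ant = c(8, 40), t1_sup_post = c(-8, 41),
    c2_inf_ant = c(5, 20), c2_inf_post = c(-5, 21)
  )
  lms2 <- manual_landmarks(pts)
  expect_equal(pt_line(lms2), c((14 - 6) / 2 - (3 + 9) / 2,
                                (99 + 103) / 2 - (112 + 108) / 2))
})

test_that("degenerate pelvis is rejected", {
  pts <- list(
    femoral_head_1 = c(0, 100), femoral_head_2 = c(0, 100),
    sacrum_center = c(0, 104),
    s1_sup_ant = c(10, 100), s1_sup_post = c(-10, 100),
    l1_sup_ant = c(9, 70), l1_sup_post = c(-9, 70),
    t1_sup_ant = c(8, 40), t1_sup_post = c(-8, 40),
    c2_inf_ant = c(5, 20), c2_inf_post = c(-5, 20)
  )
  expect_error(manual_landmarks(pts), "femoral-head midpoint")
})

test_that("straight vertical configuration has all-zero pelvic parameters", {
  pel <- pelvic_parameters(straight_landmarks())
  expect_equal(pel$PI, 0)
  expect_equal(pel$PT, 0)
  expect_equal(pel$SS, 0)
})

test_that("phantom-built targets are recovered exactly", {
  sp <- phantom_spec(pi_deg = 52.16, pt = 14.99, l1i = 2.46,
                     t1i = 39.77, c2i = 26.87, seed = 2)
  ph <- generate_landmarks(sp)
  pel <- pelvic_parameters(ph$landmarks, ph$frame)
  inc <- incidence_angles(ph$landmarks, ph$frame)
  expect_equal(pel$PI, 52.16, tolerance = 1e-6)
  expect_equal(pel$PT, 14.99, tolerance = 1e-6)
  expect_equal(pel$SS, 52.16 - 14.99, tolerance = 1e-6)
  expect_equal(inc$L1I, 2.46, tolerance = 1e-6)
  expect_equal(inc$T1I, 39.77, tolerance = 1e-6)
  expect_equal(inc$C2I, 26.87, tolerance = 1e-6)
})

test_that("global rotation shifts tilt and slopes but not incidences", {
  set.seed(11)
  ph <- generate_landmarks(random_feasible_spec())
  base <- measure_parameters(ph$landmarks)
  fm <- colMeans(ph$landmarks[ph$landmarks$name %in%
                                c("femoral_head_1", "femoral_head_2"),
                              c("x", "y")])
  rot <- measure_parameters(rotate_landmarks(ph$landmarks, 5, as.numeric(fm)))
  # rotating by +5 with this matrix tips the pelvis anteriorly: PT drops
  # by 5, every slope gains 5, shape parameters are unchanged
  expect_equal(rot$PT, base$PT - 5, tolerance = 1e-9)
  expect_equal(rot$SS, base$SS + 5, tolerance = 1e-9)
  expect_equal(rot$L1S, base$L1S + 5, tolerance = 1e-9)
  expect_equal(rot$T1S, base$T1S + 5, tolerance = 1e-9)
  expect_equal(rot$C2S, base$C2S + 5, tolerance = 1e-9)
  for (p in c("PI", "L1I", "T1I", "C2I", "LL", "TK", "C2_7L")) {
    expect_equal(rot[[p]], base[[p]], tolerance = 1e-9)
  }
})

test_that("all 12 parameters are invariant under translation and scaling", {
  set.seed(12)
  ph <- generate_landmarks(random_feasible_spec())
  base <- measure_parameters(ph$landmarks)
  shifted <- landmark_set(dplyr::mutate(ph$landmarks, x = x + 31.7, y = y - 12.2))
  scaled <- landmark_set(dplyr::mutate(ph$landmarks, x = x * 2.5, y = y * 2.5))
  expect_equal(as.numeric(measure_parameters(shifted)[1, ]),
               as.numeric(base[1, ]), tolerance = 1e-9)
  expect_equal(as.numeric(measure_parameters(scaled)[1, ]),
               as.numeric(base[1, ]), tolerance = 1e-9)
})

test_that("parallel endplates make every incidence equal PI", {
  # all endplates horizontal and parallel to S1: straight configuration
  lms <- straight_landmarks()
  pel <- pelvic_parameters(lms)
  inc <- incidence_angles(lms)
  expect_equal(inc$L1I, pel$PI)
  expect_equal(inc$T1I, pel$PI)
  expect_equal(inc$C2I, pel$PI)

  # tilted but still parallel (wide canvas: steep slopes drift anteriorly)
  sp <- phantom_spec(pi_deg = 50, pt = 12, l1i = 50, t1i = 50, c2i = 50,
                     image_width = 900, seed = 4)
  ph <- generate_landmarks(sp)
  inc2 <- incidence_angles(ph$landmarks)
  pel2 <- pelvic_parameters(ph$landmarks)
  expect_equal(rep(pel2$PI, 3), c(inc2$L1I, inc2$T1I, inc2$C2I),
               tolerance = 1e-9)
})

test_that("direct test parameters vanish for horizontal endplates", {
  d <- direct_parameters(straight_landmarks())
  expect_equal(as.numeric(d[1, ]), rep(0, 6))
})

test_that("parallel endplates give zero regional angles and slope = SS", {
  sp <- phantom_spec(pi_deg = 55, pt = 18, l1i = 55, t1i = 55, c2i = 55,
                     image_width = 900, seed = 5)
  ph <- generate_landmarks(sp)
  d <- direct_parameters(ph$landmarks)
  ss <- pelvic_parameters(ph$landmarks)$SS
  expect_equal(d$LL, 0, tolerance = 1e-9)
  expect_equal(d$TK, 0, tolerance = 1e-9)
  expect_equal(d$C2_7L, 0, tolerance = 1e-9)
  expect_equal(c(d$L1S, d$T1S, d$C2S), rep(ss, 3), tolerance = 1e-9)
})

test_that("derivation equations reproduce the published worked examples", {
  der <- derive_parameters(c(PI = 52.16, PT = 14.99),
                           c(L1I = 2.46, T1I = 39.77, C2I = 26.87))
  expect_equal(der$TK, 37.31)
  expect_equal(der$C2S, 11.88)
  expect_equal(round(der$C2_7L, 2), 12.90)
  expect_equal(round(der$L1S, 2), -12.53)
  expect_equal(round(der$T1S, 2), 24.78)
  expect_equal(as.numeric(derive_parameters(c(PI = 0, PT = 0),
                                            c(L1I = 0, T1I = 0, C2I = 0))[1, ]),
               rep(0, 6))
  expect_error(derive_parameters(c(PI = 1), c(L1I = 1, T1I = 1, C2I = 1)),
               "missing parameter")
})

test_that("angle identities hold on arbitrary valid landmark sets", {
  # angles live in (-180, 180], so on arbitrary (non-anatomical)
  # configurations the additive identities hold modulo 360
  wrap180 <- function(a) ((a + 180) %% 360) - 180
  set.seed(99)
  for (i in 1:250) {
    lms <- random_landmarks()
    m <- measure_parameters(lms)
    expect_lt(abs(wrap180(m$PI - (m$PT + m$SS))), 1e-6)
    expect_lt(abs(wrap180(m$L1I - (m$L1S + m$PT))), 1e-6)
    expect_lt(abs(wrap180(m$T1I - (m$T1S + m$PT))), 1e-6)
    expect_lt(abs(wrap180(m$C2I - (m$C2S + m$PT))), 1e-6)
  }
})

test_that("full report has near-zero derived-vs-direct discrepancy", {
  set.seed(21)
  ph <- generate_landmarks(random_feasible_spec())
  rep_ <- sagittal_report(ph$landmarks)
  expect_s3_class(rep_, "sagittal_report")
  expect_equal(nrow(rep_), 12)
  expect_true(all(rep_$discrepancy[rep_$group == "test"] < 1e-6))
  expect_true(all(rep_$discrepancy[rep_$group == "test"] >= 0))

  # whole-pixel quantization perturbs angles but not the identity
  q <- landmark_set(dplyr::mutate(ph$landmarks, x = round(x), y = round(y)))
  rep_q <- sagittal_report(q)
  expect_true(all(rep_q$discrepancy[rep_q$group == "test"] < 0.05))
})

test_that("degenerate endplates raise errors naming the vertebra", {
  pts <- list(
    femoral_head_1 = c(-2, 110), femoral_head_2 = c(2, 110),
    sacrum_center = c(0, 105),
    s1_sup_ant = c(10, 100), s1_sup_post = c(-10, 100),
    l1_sup_ant = c(9, 70), l1_sup_post = c(9, 70),
    t1_sup_ant = c(8, 40), t1_sup_post = c(-8, 40),
    c2_inf_ant = c(5, 20), c2_inf_post = c(-5, 20)
  )
  expect_error(manual_landmarks(pts), "L1")
})

test_that("frame orientation mirrors every signed parameter", {
  set.seed(31)
  ph <- generate_landmarks(random_feasible_spec())
  w <- 270
  mirrored <- landmark_set(dplyr::mutate(ph$landmarks, x = w - 1 - x))
  m1 <- measure_parameters(ph$landmarks, frame_convention("+x"))
  m2 <- measure_parameters(mirrored, frame_convention("-x"))
  expect_equal(as.numeric(m1[1, ]), as.numeric(m2[1, ]), tolerance = 1e-9)
})

test_that("report tidiers expose routes and summary", {
  ph <- generate_landmarks(phantom_spec(seed = 6))
  rep_ <- sagittal_report(ph$landmarks)
  td <- tidy(rep_)
  expect_true(all(c("parameter", "route", "value") %in% names(td)))
  expect_equal(sum(td$route == "derived"), 6)
  gl <- glance(rep_)
  expect_lt(gl$max_discrepancy, 1e-6)
})
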