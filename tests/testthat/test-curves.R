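test_that("survival function matches the dwell-time convolution integral", {
  r <- reference_rates()
  expect_equal(two_stage_survival(r, 0), 1)
  # independent oracle: double quadrature of the convolution of dwell times
  expect_equal(two_stage_survival(r, 100), survival_quad(r, 100),
               tolerance = 1e-10)
  set.seed(7)
  for (i in 1:5) {
    rr <- random_rates()
    tt <- runif(1, 1, 500)
    expect_equal(two_stage_survival(rr, tt), survival_quad(rr, tt),
                 tolerance = 1e-9)
  }
  # one-stage collapse and basic survival-function shape
  re <- rate_set(0.0109, 0, 0.5)
  tt <- seq(0, 800, 20)
  expect_equal(two_stage_survival(re, tt), exp(-0.0109 * tt))
  s <- two_stage_survival(r, tt)
  expect_true(all(diff(s) < 0))
  expect_lt(two_stage_survival(r, 1e6), 1e-15)
  expect_error(two_stage_survival(r, -1), "non-negative")
})

test_that("lifetime density integrates to one and matches hazard identities", {
  r <- reference_rates()
  expect_equal(integrate(function(t) lifetime_pdf(r, t), 0, Inf,
                         rel.tol = 1e-10)$value, 1, tolerance = 1e-8)
  expect_equal(lifetime_pdf(rate_set(0.01, 0, 0.3), c(0, 50, 200)),
               0.01 * exp(-0.01 * c(0, 50, 200)))
  # f_T(t) = delta(t) exp(-int_0^t delta), reconstructed by quadrature
  set.seed(21)
  for (i in 1:20) {
    rr <- random_rates()
    tt <- runif(1, 1, 300)
    cum_h <- integrate(function(a) hazard_rate(rr, a), 0, tt,
                       rel.tol = 1e-12)$value
    expect_equal(lifetime_pdf(rr, tt),
                 hazard_rate(rr, tt) * exp(-cum_h), tolerance = 1e-8)
  }
  # f = -dS/dt by central differences
  tt <- c(5, 50, 500); h <- 1e-4
  fd <- (two_stage_survival(r, tt - h) - two_stage_survival(r, tt + h)) / (2 * h)
  expect_equal(lifetime_pdf(r, tt), fd, tolerance = 1e-6)
})

test_that("hazard rate runs from kappa10 to the slow eigenvalue", {
  r <- reference_rates()
  expect_equal(hazard_rate(r, 0), 0.0109)
  expect_equal(hazard_rate(r, 10000), 0.0002, tolerance = 1e-6)
  # no 0/0 at extreme ages where the survival underflows
  expect_equal(hazard_rate(r, 1e9), 0.0002)
  # exponential limit: constant hazard
  expect_equal(hazard_rate(rate_set(0.0109, 0, 0.2), c(0, 10, 1e5)),
               rep(0.0109, 3))
  # monotone non-increasing when kappa20 < lambda1 (strict until the hazard
  # saturates at kappa20 below floating resolution)
  a <- seq(0, 2000, 50)
  h <- hazard_rate(r, a)
  expect_true(all(diff(h) <= 1e-15))
  expect_lt(h[2], h[1])
})

test_that("cumulative hazard reconstructs the lifetime distribution", {
  set.seed(31)
  for (i in 1:5) {
    rr <- random_rates()
    tt <- runif(1, 10, 400)
    cum_h <- integrate(function(a) hazard_rate(rr, a), 0, tt,
                       rel.tol = 1e-12)$value
    expect_equal(1 - exp(-cum_h), 1 - two_stage_survival(rr, tt),
                 tolerance = 1e-8)
  }
})

test_that("abundance accumulates the survival and saturates at omega * Tbar", {
  r <- reference_rates()
  expect_identical(abundance(r, 0), 0)
  expect_equal(abundance(r, Inf), mean_lifetime(r))
  expect_equal(abundance(r, Inf, omega = 3.7), 3.7 * mean_lifetime(r))
  quad <- integrate(function(u) two_stage_survival(r, u), 0, 120,
                    rel.tol = 1e-13)$value
  expect_equal(abundance(r, 120), quad, tolerance = 1e-9)
  tt <- seq(0, 5000, 100)
  expect_true(all(diff(abundance(r, tt)) > 0))
  expect_error(abundance(r, -5), "non-negative")
})

test_that("chase mixture weights carry the pulse-length rescaling", {
  r <- reference_rates()
  # infinite pulse: the bracketed factors equal one
  w <- chase_weights(r, Inf)
  expect_equal(w$a, (0.0109 - 0.0002) / 0.0298)
  expect_equal(w$b, 0.0189 / 0.0002)
  expect_equal(w$norm_a + w$norm_b, 1)
  w30 <- chase_weights(r, 30)
  expect_equal(w30$norm_a + w30$norm_b, 1)
  # zero-duration pulse limit: the chase curve tends to the survival
  dt <- c(10, 100, 1000)
  expect_equal(chase_curve(r, 1e-3, dt), two_stage_survival(r, dt),
               tolerance = 1e-4)
  # negative A_c (kappa20 > kappa10) is a valid decreasing curve
  rn <- rate_set(0.002, 0.01, 0.05)
  expect_lt(chase_weights(rn, 30)$a, 0)
  cc <- chase_curve(rn, 30, seq(0, 400, 10))
  expect_true(all(diff(cc) < 0))
})

test_that("closed-form chase curve agrees with the survival-integral ratio", {
  r <- reference_rates()
  dt <- c(0, 40, 160, 480)
  for (tp in c(1, 5, 30, 120, 1200)) {
    expect_identical(chase_curve(r, tp, 0), 1)
    for (d in dt)
      expect_equal(chase_curve(r, tp, d), chase_quad(r, tp, d),
                   tolerance = 1e-9)
  }
  # infinite pulse (synthesis shutoff)
  expect_equal(chase_curve(r, Inf, 160),
               integrate(function(u) two_stage_survival(r, u), 160, Inf,
                         rel.tol = 1e-12)$value / mean_lifetime(r),
               tolerance = 1e-9)
  cc <- chase_curve(r, 30, seq(0, 2000, 50))
  expect_true(all(diff(cc) < 0))
  expect_error(chase_curve(r, 30, -1), "non-negative")
  expect_error(chase_curve(r, -3, 10), "positive")
})

test_that("exponential decay is pulse-independent", {
  re <- rate_set(0.0109, 0, 0.0002)
  dt <- seq(0, 2000, 25)
  expect_identical(chase_curve(re, 1, dt), chase_curve(re, 1200, dt))
  expect_equal(chase_curve(re, 30, dt), exp(-0.0109 * dt))
  # continuity: a vanishingly small kappa12 stays on the exponential curve
  r_eps <- rate_set(0.0109, 1e-12, 0.0002)
  expect_equal(chase_curve(r_eps, 1200, dt), exp(-0.0109 * dt),
               tolerance = 1e-6)
})

test_that("pulse-only curve rises from 0 to 1 and matches the abundance ratio", {
  r <- reference_rates()
  expect_identical(pulse_only_curve(r, 0), 0)
  expect_equal(pulse_only_curve(r, 1e9), 1)
  dt <- c(1, 10, 100, 1000)
  # closed two-term form vs direct abundance-ratio evaluation
  expect_equal(pulse_only_curve(r, dt),
               abundance(r, dt) / abundance(r, Inf), tolerance = 1e-10)
  p <- pulse_only_curve(r, seq(0, 20000, 100))
  expect_true(all(diff(p) > 0))
  # finite-time normalization is an abundance ratio
  expect_equal(pulse_only_curve(r, dt, normalization = "at_time", t_norm = 20),
               abundance(r, dt) / abundance(r, 20))
  expect_error(pulse_only_curve(r, dt, normalization = "at_time", t_norm = 0),
               "strictly positive")
  # near-degenerate eigenvalues stay finite (integral branch)
  rd <- rate_set(0.01, 0.02, 0.03 * (1 + 1e-13))
  expect_equal(pulse_only_curve(rd, 50),
               abundance(rd, 50) / mean_lifetime(rd), tolerance = 1e-12)
})

test_that("half-time solves C = 1/2 and depends on the pulse length", {
  r <- reference_rates()
  th <- half_time(r)                      # infinite pulse by default
  expect_equal(chase_curve(r, Inf, th), 0.5, tolerance = 1e-9)
  th30 <- half_time(r, 30)
  expect_equal(chase_curve(r, 30, th30), 0.5, tolerance = 1e-9)
  # apparent half-time grows with the pulse length when kappa12 > 0
  expect_lt(half_time(r, 1), half_time(r, 1200))
  expect_lt(half_time(r, 1200), th)
  # exponential limit: ln(2)/kappa10 for every pulse
  re <- rate_set(0.0109, 0, 0.0002)
  expect_equal(half_time(re, 1), log(2) / 0.0109)
  expect_identical(half_time(re, 1), half_time(re, 1200))
})

test_that("age density at pulse end is the normalized survival on [0, tp]", {
  r <- reference_rates()
  expect_identical(age_density_at_pulse_end(r, 30, 31), 0)
  set.seed(55)
  for (i in 1:5) {
    rr <- random_rates()
    tp <- runif(1, 5, 500)
    expect_equal(integrate(function(a) age_density_at_pulse_end(rr, tp, a),
                           0, tp, rel.tol = 1e-12)$value, 1,
                 tolerance = 1e-8)
  }
  # kappa12 -> 0, tp -> Inf: exponential age distribution
  re <- rate_set(0.01, 0, 0.3)
  a <- c(0, 50, 200)
  expect_equal(age_density_at_pulse_end(re, Inf, a), 0.01 * exp(-0.01 * a))
})

test_that("closed forms survive near-degenerate and crossing eigenvalues", {
  # lambda2 slightly above, at, and slightly below lambda1
  for (f in c(1 - 1e-9, 1 - 1e-13, 1, 1 + 1e-13, 1 + 1e-9)) {
    rr <- rate_set(0.01, 0.02, 0.03 * f)
    cc <- chase_curve(rr, 30, c(10, 100, 500))
    expect_true(all(is.finite(cc)))
    expect_equal(cc[1], chase_quad(rr, 30, 10), tolerance = 1e-9)
    expect_true(all(is.finite(two_stage_survival(rr, c(1, 100, 1e4)))))
    expect_true(all(is.finite(hazard_rate(rr, c(0, 100, 1e6)))))
  }
})
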