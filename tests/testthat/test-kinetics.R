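# Forward kinetic model: analytic solution, numeric integrator, unit
# conversions, and delivery-rate geometry.

test_that("no activation means no product, in both solution paths", {
  sched <- fig2_schedule()
  tt <- seq(0, 1800, by = 10)
  p <- kinetic_params(k = 0, v_out = 0.01, c_out = 0.002)
  a <- closed_form_concentrations(p, sched, tt)
  b <- simulate_concentrations(p, sched, tt)
  expect_equal(a$C, rep(0, length(tt)))
  expect_equal(b$C, rep(0, length(tt)), tolerance = 1e-10)
  # closed form for V with k = 0 during infusion: (v_in/v_out)(1 - e^-v_out t)
  during <- tt > 300 & tt <= 900
  expect_equal(a$V[during],
               0.107 / 0.01 * (1 - exp(-0.01 * (tt[during] - 300))),
               tolerance = 1e-10)
})

test_that("mass balance holds without efflux: V + C equals the infused dose", {
  tt <- seq(0, 1800, by = 5)
  sched <- infusion_schedule(0, 600, 0.107)
  tr <- closed_form_concentrations(kinetic_params(0.0015), sched, tt)
  expect_equal(tr$V[tt == 600] + tr$C[tt == 600], 0.107 * 600,
               tolerance = 1e-6)
  # property: holds at every time for random parameter draws
  set.seed(42)
  for (i in 1:20) {
    p <- kinetic_params(k = runif(1, 1e-5, 0.1))
    s <- infusion_schedule(runif(1, 0, 200), runif(1, 100, 900),
                           runif(1, 0.001, 0.5))
    tr <- closed_form_concentrations(p, s, tt)
    dose <- s$v_in * pmin(pmax(tt - s$onset, 0), s$duration)
    tot <- tr$V + tr$C
    expect_equal(tot, dose, tolerance = 1e-6)
  }
})

test_that("closed form agrees with the numeric integrator to 1e-8 relative", {
  tt <- seq(0, 2000, by = 20)
  set.seed(7)
  for (i in 1:100) {
    p <- kinetic_params(k = 10^runif(1, -5, -1),
                        v_out = 10^runif(1, -5, -0.3),
                        c_out = 10^runif(1, -6, -2))
    s <- infusion_schedule(runif(1, 0, 300), runif(1, 100, 800),
                           runif(1, 0.005, 0.5))
    a <- closed_form_concentrations(p, s, tt)
    b <- simulate_concentrations(p, s, tt)
    scale_C <- max(b$C); scale_V <- max(b$V)
    expect_lt(max(abs(a$C - b$C)) / max(scale_C, 1e-12), 1e-8)
    expect_lt(max(abs(a$V - b$V)) / max(scale_V, 1e-12), 1e-8)
  }
})

test_that("degenerate rate coincidence k + v_out == c_out uses the limiting form", {
  tt <- seq(0, 1500, by = 5)
  s <- infusion_schedule(0, 600, 0.107)
  p <- kinetic_params(k = 0.01, v_out = 0.01, c_out = 0.02)
  a <- closed_form_concentrations(p, s, tt)
  b <- simulate_concentrations(p, s, tt)
  expect_lt(max(abs(a$C - b$C)) / max(b$C), 1e-8)
  expect_true(all(is.finite(a$C)))
})

test_that("product concentration is monotone without product efflux", {
  tt <- seq(0, 2400, by = 10)
  set.seed(3)
  for (i in 1:10) {
    p <- kinetic_params(k = 10^runif(1, -4, -1), v_out = runif(1, 0, 0.3),
                        c_out = 0)
    s <- infusion_schedule(200, 600, 0.1)
    tr <- closed_form_concentrations(p, s, tt)
    expect_true(all(diff(tr$C) >= -1e-12))
    # intact probe declines after infusion offset
    post <- tt >= 800
    expect_true(all(diff(tr$V[post]) <= 1e-12))
  }
})

test_that("constant infusion drives V to its steady state v_in/(k + v_out)", {
  p <- kinetic_params(k = 0.005, v_out = 0.1, c_out = 0.001)
  rate <- p$k + p$v_out
  s <- infusion_schedule(0, 1e7, 0.107)
  tr <- closed_form_concentrations(p, s, c(1, 20 / rate))
  expect_equal(tr$V[2], 0.107 / rate, tolerance = 1e-6)
})

test_that("enzyme concentration converts to rate and back as exact inverses", {
  enz <- enzyme_constants()  # k_cat 3 /s, K_m 2 uM
  expect_equal(rate_from_fap(1, enz), 0.0015)
  expect_equal(rate_from_fap(10, enz), 0.015)
  expect_equal(rate_from_fap(0, enz), 0)
  expect_equal(fap_from_rate(0.019, enz), 12.6667, tolerance = 1e-4)
  expect_equal(round(fap_from_rate(0.019, enz)), 13)
  expect_equal(fap_from_rate(0, enz), 0)
  # inverse identity and linearity
  x <- c(0.5, 1, 7, 13, 100)
  expect_equal(fap_from_rate(rate_from_fap(x, enz), enz), x)
  expect_equal(rate_from_fap(2 * x, enz), 2 * rate_from_fap(x, enz))
})

test_that("direct infusion delivery rate matches hand arithmetic", {
  expect_equal(point_infusion_rate(0.1, 100, 1.56), 0.107, tolerance = 5e-3)
  expect_equal(round(point_infusion_rate(0.1, 100, 1.56), 3), 0.107)
  expect_equal(point_infusion_rate(1, 100, 1.0), 100 / 60, tolerance = 1e-12)
  expect_equal(point_infusion_rate(0.2, 100, 1.56),
               2 * point_infusion_rate(0.1, 100, 1.56))
  expect_error(point_infusion_rate(0.1, 100, 0), "> 0")
})

test_that("radial delivery rate follows the inverse-square spread model", {
  v <- radial_infusion_rate(1, 100, 0.15, 3.5, 0.15)
  expect_equal(signif(v, 3), 0.0108)
  # hand arithmetic at d = 1 mm
  expect_equal(radial_infusion_rate(1, 100, 0.15, 1, 0.15),
               (1 / 60) * 100 * 0.15 / (4 * pi * 0.15), tolerance = 1e-12)
  expect_equal(radial_infusion_rate(1, 100, 0.15, 7, 0.15), v / 4,
               tolerance = 1e-12)
  expect_error(radial_infusion_rate(1, 100, 0.15, 0, 0.15), "singularity")
})

test_that("signal is proportional to product concentration", {
  tr <- closed_form_concentrations(kinetic_params(0.001), fig2_schedule(),
                                   seq(0, 1200, 10))
  expect_equal(signal_from_concentration(tr, 0)$values,
               rep(0, length(tr$times)))
  s <- signal_from_concentration(tr, 20)
  expect_equal(s$values, 20 * tr$C)
  # rises during infusion and keeps rising toward an asymptote after offset
  # in the zero-efflux regime
  expect_true(all(diff(s$values[tr$times >= 300]) >= -1e-12))
})

test_that("invalid inputs are rejected", {
  expect_error(infusion_schedule(-1, 600, 0.1), "onset")
  expect_error(infusion_schedule(0, 0, 0.1), "duration")
  expect_error(kinetic_params(-0.1), ">= 0")
  expect_error(closed_form_concentrations(kinetic_params(0.1),
                                          fig2_schedule(), c(0, 10, 5)),
               "increasing")
  expect_error(enzyme_constants(k_cat = 0), "k_cat")
})

test_that("trajectories and kinetic configs round-trip through disk", {
  tr <- closed_form_concentrations(kinetic_params(0.002, 0.01, 0.001),
                                   fig2_schedule(), seq(0, 900, 15))
  f <- tempfile(fileext = ".csv")
  write_trajectory_csv(tr, f)
  tr2 <- read_trajectory_csv(f)
  expect_equal(tr2$C, tr$C, tolerance = 1e-12)
  expect_equal(tr2$times, tr$times)

  y <- tempfile(fileext = ".yaml")
  write_kinetic_config(kinetic_params(0.002, 0.01, 0.001, A = 20),
                       fig2_schedule(), y)
  cfg <- read_kinetic_config(y)
  expect_equal(cfg$params$k, 0.002)
  expect_equal(cfg$schedule$v_in, 0.107)
  unlink(c(f, y))
})
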