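test_that("NRH value matches hand arithmetic and its limits", {
  # dark limit
  expect_equal(nrh_value(0, Phi = 0.05, Amax = 20, Theta = 0.7, Rd = 1.2), -1.2)
  # theta = 1 min() identity: Phi*I = 30 caps at Amax = 20
  expect_equal(nrh_value(500, Phi = 0.06, Amax = 20, Theta = 1, Rd = 1), 19)
  # hand-computed general case: (38 - sqrt(436)) / 1.4 - 1
  expect_equal(nrh_value(300, Phi = 0.06, Amax = 20, Theta = 0.7, Rd = 1),
               (38 - sqrt(38^2 - 4 * 0.7 * 18 * 20)) / (2 * 0.7) - 1,
               tolerance = 1e-12)
  expect_equal(nrh_value(300, Phi = 0.06, Amax = 20, Theta = 0.7, Rd = 1),
               11.2283, tolerance = 1e-4)
})

test_that("theta -> 0 limit agrees with the rectangular hyperbola", {
  par <- seq(0, 2000, by = 50)
  rect <- 0.06 * par * 20 / (0.06 * par + 20) - 1
  expect_lt(max(abs(nrh_value(par, 0.06, 20, 1e-7, 1) - rect)), 1e-6)
  # first-order truncation: the theta-expansion error is theta * p^2 / s^3
  p_ <- 0.06 * par * 20; s_ <- 0.06 * par + 20
  expect_lt(max(abs(nrh_value(par, 0.06, 20, 1e-6, 1) - rect) -
                1e-6 * p_^2 / s_^3), 1e-9)
  # theta = 0 handled without division issues
  expect_equal(nrh_value(par, 0.06, 20, 0, 1), rect, tolerance = 1e-12)
})

test_that("NRH fit recovers its own generating parameters", {
  truth <- c(Phi = 0.055, Amax = 18, Theta = 0.72, Rd = 0.9)
  d <- data.frame(par = c(50, 150, 300, 600, 900, 1200, 1500))
  d$A <- nrh_value(d$par, truth["Phi"], truth["Amax"], truth["Theta"], truth["Rd"])
  fit <- fit_nrh(d)
  expect_lt(abs(fit$Phi - truth["Phi"]) / truth["Phi"], 1e-4)
  expect_lt(abs(fit$Amax - truth["Amax"]) / truth["Amax"], 1e-4)
  expect_lt(abs(fit$Theta - truth["Theta"]) / truth["Theta"], 1e-4)
  expect_lt(abs(fit$Rd - truth["Rd"]) / truth["Rd"], 1e-4)
  expect_true(fit$converged)
  # fitted SSE cannot exceed the generating parameters' (zero) SSE
  expect_lt(fit$sse, 1e-10)
})

test_that("NRH fit stays accurate under noise (Monte Carlo)", {
  d0 <- data.frame(par = c(50, 150, 300, 600, 900, 1200, 1500))
  mu <- nrh_value(d0$par, 0.06, 20, 0.7, 1)
  errs <- vapply(1:30, function(seed) {
    set.seed(seed)
    d <- d0
    d$A <- mu + rnorm(nrow(d0), 0, 0.3)
    abs(fit_nrh(d)$Amax - 20) / 20
  }, numeric(1))
  expect_lt(median(errs), 0.10)
})

test_that("degenerate light curves are reported, not fitted silently", {
  flat <- data.frame(par = c(50, 150, 300, 600, 900), A = rep(5, 5))
  fit <- fit_nrh(flat)
  expect_true(fit$boundary)
  expect_false(fit$converged)
  expect_error(fit_nrh(data.frame(par = c(300, 600, 900, 1200, 1500),
                                  A = 1:5)), "150")
  expect_error(fit_nrh(data.frame(par = c(50, 300, 900), A = 1:3)), "5")
})

test_that("photorespiration series is the aligned AG - AN difference", {
  p <- fvcb_params()
  lp <- simulate_light_response_pair(p, fluor_params(), spec_quiet())
  ph <- photorespiration_series(lp$low_O2, lp$photorespiratory)
  expect_identical(ph$par, sort(sim_spec()$par_steps))
  expect_equal(ph$Phresp, ph$AG - ph$AN, tolerance = 1e-12)
  expect_true(all(ph$Phresp > 0)) # photorespiration is a positive flux here
  expect_false(any(ph$flagged))

  # identical oxygen: difference identically zero
  same <- simulate_light_response_pair(p, fluor_params(), spec_quiet(),
                                       O_low = p$O)
  ph0 <- photorespiration_series(same$low_O2, same$photorespiratory)
  expect_equal(ph0$Phresp, rep(0, nrow(ph0)), tolerance = 1e-12)
})

test_that("photorespiration alignment and label checks work", {
  mk <- function(par, A, cond) {
    structure(data.frame(par = par, A = A), condition = cond,
              class = c("light_curve", "data.frame"))
  }
  g <- mk(c(1500, 900, 300), c(20, 18, 10), "low_O2")
  n <- mk(c(1500, 600, 300), c(15, 12, 8), "photorespiratory")
  expect_warning(ph <- photorespiration_series(g, n), "600, 900")
  expect_identical(ph$par, c(300, 1500))

  expect_error(photorespiration_series(n, g), "swapped")
  expect_error(photorespiration_series(g, mk(300, 1, "low_O2")), "same gas")
  expect_error(
    photorespiration_series(mk(100, 1, "low_O2"), mk(200, 1, "photorespiratory")),
    "disjoint")

  # antisymmetry: exchanging the two A series (labels kept valid) negates it
  par3 <- c(300, 900, 1500)
  a1 <- c(20, 24, 25); a2 <- c(15, 18, 18)
  fwd <- photorespiration_series(mk(par3, a1, "low_O2"),
                                 mk(par3, a2, "photorespiratory"))
  rev <- photorespiration_series(mk(par3, a2, "low_O2"),
                                 mk(par3, a1, "photorespiratory"))
  expect_equal(rev$Phresp, -fwd$Phresp)
})

test_that("saturation PAR follows the plateau-fraction rule", {
  s <- saturation_par(c(2, 8, 15, 19, 20, 20), c(50, 150, 300, 600, 900, 1250))
  expect_equal(s$par_sat, 600)
  expect_equal(s$plateau, 20)
  expect_false(s$warning)

  # strictly increasing series saturating only at the last step
  s2 <- saturation_par(1:6, c(50, 150, 300, 600, 900, 1250))
  expect_equal(s2$par_sat, 1250)
  expect_true(s2$warning)

  # fraction 1: first step attaining the maximum
  s3 <- saturation_par(c(1, 5, 9, 9, 9), c(50, 150, 300, 600, 900), fraction = 1)
  expect_equal(s3$par_sat, 300)

  expect_error(saturation_par(1:3, c(300, 100, 200)), "ascending")
})
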