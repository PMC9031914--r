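test_that("simulators are deterministic under a fixed seed", {
  p <- fvcb_params()
  s <- sim_spec(noise_sd_A = 0.5, noise_sd_F = 0.01, seed = 42L)
  expect_identical(simulate_aci(p, s), simulate_aci(p, s))
  expect_identical(simulate_racir_pair(p, s), simulate_racir_pair(p, s))
  expect_identical(simulate_light_response_pair(p, fluor_params(), s),
                   simulate_light_response_pair(p, fluor_params(), s))
  # zero noise: measured values identical regardless of seed
  expect_identical(simulate_aci(p, spec_quiet(seed = 1L))$A,
                   simulate_aci(p, spec_quiet(seed = 99L))$A)
  # different seeds give different noise
  s2 <- sim_spec(noise_sd_A = 0.5, seed = 43L)
  expect_false(identical(simulate_aci(p, s)$A, simulate_aci(p, s2)$A))
})

test_that("simulators do not disturb the caller's RNG stream", {
  set.seed(7)
  before <- .Random.seed
  invisible(simulate_aci(fvcb_params(), sim_spec(noise_sd_A = 0.5, seed = 3L)))
  expect_identical(.Random.seed, before)
})

test_that("A-Ci simulation spans both limitation regimes over the ramp range", {
  curve <- simulate_aci(fvcb_params(), spec_quiet())
  expect_equal(range(curve$Ci), c(20, 1520))
  lim <- attr(curve, "meta")$truth$limitation
  expect_setequal(unique(lim), c("rubisco", "rubp"))
  expect_equal(sum(diff(lim == "rubisco") != 0), 1)
})

test_that("RACiR ramp timing and artifact arithmetic are exact", {
  p <- fvcb_params()
  pair <- simulate_racir_pair(p, spec_quiet(), artifact = c(0.4, -3e-4))
  # 20 -> 1520 ppm at 100 ppm/min is a 900 s ramp, recorded every 2 s
  expect_equal(max(pair$leaf$elapsed), 900)
  expect_equal(nrow(pair$leaf), 451)
  expect_identical(pair$leaf$elapsed, pair$empty$elapsed)
  expect_equal(range(pair$leaf$CO2_r), c(20, 1520))

  # null artifact, zero noise: leaf apparent A equals the embedded truth
  p0 <- simulate_racir_pair(p, spec_quiet(), artifact = 0)
  expect_equal(p0$leaf$A, attr(p0$leaf, "meta")$truth[, "A"],
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(p0$empty$A, rep(0, nrow(p0$empty)))

  # linear artifact recovered from the empty trace by least squares
  lin <- simulate_racir_pair(p, spec_quiet(), artifact = c(0.25, 4e-4))
  cf <- coef(lm(A ~ CO2_r, data = lin$empty))
  expect_equal(unname(cf), c(0.25, 4e-4), tolerance = 1e-6)
})

test_that("light-response pair is fluorescence-consistent and gas-contrasted", {
  p <- fvcb_params(gm = 0.2)
  f <- fluor_params()
  lp <- simulate_light_response_pair(p, f, spec_quiet())
  net <- lp$photorespiratory
  expect_identical(net$par, sim_spec()$par_steps) # protocol steps verbatim
  expect_identical(attr(net, "condition"), "photorespiratory")
  expect_identical(attr(lp$low_O2, "condition"), "low_O2")

  # reconstructed PhiPSII inverts to the model's electron transport exactly
  truth <- attr(net, "meta")$truth
  phi <- (net$Fmp - net$Fs) / net$Fmp
  expect_equal(phi, truth$phiPSII, tolerance = 1e-9)
  expect_equal(compute_etr(phi, net$par, f$absorptance, f$fPSII), truth$J,
               tolerance = 1e-9)

  # low-O2 leaf assimilates more (photorespiration suppressed)
  expect_true(all(lp$low_O2$A >= net$A - 1e-10))

  # no-contrast control: identical oxygen gives identical curves
  same <- simulate_light_response_pair(p, f, spec_quiet(), O_low = p$O)
  expect_equal(same$low_O2$A, same$photorespiratory$A, tolerance = 1e-12)
})

test_that("qPd protocol emits the scripted steps and the photoinhibition onset", {
  f0 <- fluor_params(kinh = 0)
  tr <- simulate_qpd_protocol(f0)
  expect_identical(tr$par, c(60, 100, 250, 400, 600, 850, 1150, 1500))
  # no photoinhibition: dark Fo equals the calculated Fo' everywhere
  expect_equal(tr$Fo_dark, fo_prime_calc(attr(tr, "Fo"), attr(tr, "Fm"), tr$Fmp),
               tolerance = 1e-12)

  f6 <- fluor_params(Icrit = 600, kinh = 1e-3)
  tr6 <- simulate_qpd_protocol(f6)
  above <- tr6$Fo_dark > fo_prime_calc(attr(tr6, "Fo"), attr(tr6, "Fm"), tr6$Fmp) + 1e-12
  expect_equal(tr6$par[which(above)[1]], 850) # first scripted step above Icrit

  expect_error(simulate_qpd_protocol(f0, par_script = c(100, 60)), "increasing")
})

test_that("laisk segment generator carries its ground truth", {
  p <- fvcb_params(gm = 0.25)
  seg <- simulate_laisk_segments(p)
  truth <- attr(seg, "meta")$truth
  expect_equal(truth$ci_star, p$GammaStar - p$Rday / p$gm)
  expect_equal(length(unique(seg$par)), 3)
  # tangent model: every segment passes through (Ci*, -Rday) exactly
  for (pp in unique(seg$par)) {
    s <- seg[seg$par == pp, ]
    cf <- coef(lm(A ~ Ci, data = s))
    expect_equal(unname(cf[1] + cf[2] * truth$ci_star), -p$Rday,
                 tolerance = 1e-10)
  }
})
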