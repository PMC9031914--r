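exact_segments <- function(slopes = c(0.05, 0.03, 0.01), x0 = 40, y0 = -1,
                           ci = c(50, 80, 110, 140), pars = c(421, 210, 63)) {
  df <- do.call(rbind, lapply(seq_along(slopes), function(k) {
    data.frame(Ci = ci, A = slopes[k] * (ci - x0) + y0, par = pars[k])
  }))
  structure(df, class = c("laisk_segments", "data.frame"))
}

test_that("three concurrent lines return their common point exactly", {
  res <- fit_laisk(exact_segments())
  expect_equal(res$GammaStar_app, 40, tolerance = 1e-10)
  expect_equal(res$Rday, 1, tolerance = 1e-10)
  expect_equal(res$triangle_area, 0, tolerance = 1e-16)
  expect_false(res$rday_out_of_range)
  expect_equal(res$barycentre[["x"]], mean(res$triangle[, "x"]))
  expect_equal(res$barycentre[["y"]], mean(res$triangle[, "y"]))
})

test_that("noiseless simulated segments recover Ci* and Rday", {
  for (gm in c(Inf, 0.25)) {
    p <- fvcb_params(gm = gm)
    res <- fit_laisk(simulate_laisk_segments(p))
    truth <- attr(simulate_laisk_segments(p), "meta")$truth
    expect_lt(abs(res$GammaStar_app - truth$ci_star) / truth$ci_star, 0.02)
    expect_lt(abs(res$Rday - p$Rday) / p$Rday, 0.02)
  }
})

test_that("construction is affine-equivariant in Ci", {
  seg <- simulate_laisk_segments(fvcb_params(), noise_sd = 0.1, seed = 3L)
  base <- fit_laisk(seg)
  shifted <- seg
  shifted$Ci <- shifted$Ci + 25
  res <- fit_laisk(shifted)
  expect_equal(res$GammaStar_app, base$GammaStar_app + 25, tolerance = 1e-9)
  expect_equal(res$Rday, base$Rday, tolerance = 1e-9)
})

test_that("parallel segments and bad inputs are rejected", {
  seg <- exact_segments(slopes = c(0.05, 0.05, 0.01))
  expect_error(fit_laisk(seg), "parallel")
  two <- exact_segments()[exact_segments()$par %in% c(421, 210), ]
  expect_error(fit_laisk(two), "three PAR levels")
})

test_that("ETR conversion matches hand arithmetic and unit factors", {
  expect_equal(compute_etr(0.5, 1000), 210)
  expect_equal(compute_etr(0.7, 0), 0)
  expect_equal(compute_etr(0.3, 800, absorptance = 1, fPSII = 1), 240)
  expect_error(compute_etr(1.2, 100), "\\[0, 1\\]")
})

test_that("variable-J gm matches the hand-computed oracle", {
  # independent arithmetic: Cc term = 40 * 188 / 56, gm = 10 / (250 - Cc)
  cc <- 40 * (100 + 8 * (10 + 1)) / (100 - 4 * (10 + 1))
  res <- variable_j_gm(AN = 10, Ci = 250, ETR = 100, GammaStar = 40, Rday = 1)
  expect_equal(res$gm, 10 / (250 - cc), tolerance = 1e-12)
  expect_equal(res$gm, 0.0864198, tolerance = 1e-6)
  expect_false(res$flagged)

  # zero-compensation limit: gm = AN / Ci
  z <- variable_j_gm(10, 250, 100, GammaStar = 0, Rday = 1)
  expect_equal(z$gm, 0.04, tolerance = 1e-12)

  expect_error(variable_j_gm(10, 250, ETR = 44, GammaStar = 40, Rday = 1),
               "singularity")
})

test_that("variable-J inverts the RuBP-limited forward model exactly", {
  p <- fvcb_params(gm = 0.2)
  lp <- simulate_light_response_pair(p, fluor_params(), spec_quiet())
  net <- lp$photorespiratory
  truth <- attr(net, "meta")$truth
  rubp <- truth$limitation == "rubp"
  gm <- gm_from_light_curve(net, GammaStar = p$GammaStar, Rday = p$Rday)
  expect_lt(max(abs(gm$gm[rubp] - 0.2) / 0.2), 1e-6)
  # inverse property: Cc from gm satisfies the Aj equation
  cc <- gm$Cc[rubp]
  J <- truth$J[rubp]
  aj <- J * (cc - p$GammaStar) / (4 * cc + 8 * p$GammaStar)
  expect_equal(aj, net$A[rubp] + p$Rday, tolerance = 1e-9)
})

test_that("non-physical gm values are flagged, not dropped", {
  res <- variable_j_gm(AN = c(10, -2), Ci = c(250, 250), ETR = c(100, 100),
                       GammaStar = 40, Rday = 1)
  expect_equal(nrow(res), 2)
  expect_false(res$flagged[1])
  expect_true(res$flagged[2]) # negative gm
})

test_that("noisy segments keep the compensation point nearly unbiased", {
  p <- fvcb_params()
  est <- vapply(1:60, function(seed) {
    seg <- simulate_laisk_segments(p, noise_sd = 0.2, seed = seed)
    fit_laisk(seg)$GammaStar_app
  }, numeric(1))
  expect_lt(abs(median(est) - p$GammaStar) / p$GammaStar, 0.05)
})
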