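test_that("quenching coefficients match their hand-computed oracles", {
  expect_equal(compute_qp(1200, 600, 400), 0.75, tolerance = 1e-12)
  expect_equal(compute_qp(1200, 400, 400), 1)    # fs = fo': all centres open
  expect_equal(compute_qp(1200, 1200, 400), 0)   # fs = fm': all closed
  expect_error(compute_qp(400, 300, 500), "Fm'")

  expect_equal(compute_qn(2000, 1200, 400), 0.5, tolerance = 1e-12)
  expect_equal(compute_qn(2000, 2000, 400), 0)   # no quenching
  expect_equal(compute_qn(2000, 400, 400), 1)    # maximal under this form
  expect_error(compute_qn(400, 300, 500), "Fm")

  expect_equal(fo_prime_calc(500, 2500, 1250), 500 / (0.8 + 0.4),
               tolerance = 1e-12)
  expect_equal(fo_prime_calc(500, 2500, 2500), 500) # dark-adapted identity
  # monotone: Fo'_calc falls as Fm' falls
  fos <- fo_prime_calc(500, 2500, c(2500, 2000, 1500, 1000, 600))
  expect_true(all(diff(fos) < 0))
})

test_that("qP complement identity holds exactly", {
  fm_prime <- 1100; fo_prime <- 380
  for (x in seq(0, 1, by = 0.125)) {
    fs <- fo_prime + x * (fm_prime - fo_prime)
    expect_equal(compute_qp(fm_prime, fs, fo_prime), 1 - x, tolerance = 1e-12)
  }
})

test_that("qPd series: oracle value, no-photoinhibition identity, flags", {
  # hand-computed qPd on the stated fixture
  tr <- structure(
    data.frame(step = 1, par = 600, Fs = 700, Fmp = 1250,
               Fo_dark = 430, Fmp_dark = 1250),
    Fo = 500, Fm = 2500, class = c("fluor_trace", "data.frame")
  )
  qs <- compute_qpd_series(tr)
  fop <- 500 / (0.8 + 500 / 1250)
  expect_equal(qs$Fo_prime_calc, fop, tolerance = 1e-9)
  expect_equal(qs$qPd, (1250 - 430) / (1250 - fop), tolerance = 1e-9)
  expect_equal(qs$qPd, 0.984, tolerance = 1e-3)
  expect_equal(qs$NPQ, (2500 - 1250) / 1250, tolerance = 1e-12)

  # simulator with kinh = 0: qPd identically 1
  qs0 <- compute_qpd_series(simulate_qpd_protocol(fluor_params(kinh = 0)))
  expect_equal(qs0$qPd, rep(1, 8), tolerance = 1e-9)
  expect_false(any(qs0$flagged))

  # missing dark records are named
  tr_bad <- tr
  tr_bad$Fo_dark <- NA_real_
  expect_error(compute_qpd_series(tr_bad), "step\\(s\\): 1")
})

test_that("measured Fo' is preferred for qP, calculated Fo' always for qPd", {
  tr <- structure(
    data.frame(step = 1:2, par = c(100, 400), Fs = c(500, 600),
               Fmp = c(1400, 1100), Fo_light = c(420, 390),
               Fo_dark = c(400, 420), Fmp_dark = c(1400, 1100)),
    Fo = 500, Fm = 2500, class = c("fluor_trace", "data.frame")
  )
  qs <- compute_qpd_series(tr)
  expect_equal(qs$Fo_prime_used, c(420, 390))
  expect_equal(qs$qP, (tr$Fmp - tr$Fs) / (tr$Fmp - c(420, 390)))
  fop <- fo_prime_calc(500, 2500, tr$Fmp)
  expect_equal(qs$qPd, (tr$Fmp_dark - tr$Fo_dark) / (tr$Fmp_dark - fop))
})

test_that("photoprotection threshold scans the qPd series correctly", {
  s <- data.frame(par = c(60, 100, 250, 400, 600),
                  qPd = c(1.0, 1.0, 0.99, 0.97, 0.92))
  res <- photoprotection_threshold(s, criterion = 0.98)
  expect_equal(res$threshold, 400)
  expect_equal(res$bracket, c(250, 400))

  all_one <- data.frame(par = c(60, 100, 250), qPd = c(1, 1, 1))
  expect_true(is.na(photoprotection_threshold(all_one)$threshold))

  expect_error(photoprotection_threshold(s[c(3, 1, 2), ]), "sorted")
})

test_that("detected threshold tracks Icrit within one scripted step", {
  script <- c(60, 100, 250, 400, 600, 850, 1150, 1500)
  for (icrit in c(300, 600, 1000)) {
    for (kinh in c(5e-4, 1e-3, 2e-3, 5e-3)) {
      f <- fluor_params(Icrit = icrit, kinh = kinh)
      qs <- compute_qpd_series(simulate_qpd_protocol(f))
      thr <- photoprotection_threshold(qs)$threshold
      first_above <- script[script > icrit][1]
      idx_allowed <- which(script == first_above) + c(-1, 0, 1)
      expect_true(thr %in% script[idx_allowed[idx_allowed >= 1]])
    }
  }
})

test_that("raising kinh never raises the detected threshold", {
  thr <- vapply(c(5e-4, 1e-3, 2e-3, 5e-3, 1e-2), function(k) {
    qs <- compute_qpd_series(simulate_qpd_protocol(fluor_params(kinh = k)))
    photoprotection_threshold(qs)$threshold
  }, numeric(1))
  expect_true(all(diff(thr) <= 0))
})
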