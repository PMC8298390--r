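test_that("unmixing an exact linear combination returns the generating coefficients", {
  cs <- make_component_spectra()
  truth <- c(s_d = 0.4, s_fluo = 2.0, s_fura_minus = 0.7,
             s_fura_plus = 1.1, c = 0.05)
  X <- cbind(cs$sc_diode, cs$fl_fluo, cs$fl_fura_minus, cs$fl_fura_plus, 1)
  sp <- spectrum(cs$wavelength_nm, as.numeric(X %*% truth))
  fit <- fit_components(sp, cs)
  expect_equal(coef(fit), truth, tolerance = 1e-10)
  expect_lt(fit$residual_norm, 1e-10)
})

test_that("a single-component spectrum yields that coefficient and zeros elsewhere", {
  cs <- make_component_spectra()
  sp <- spectrum(cs$wavelength_nm, 2 * cs$fl_fluo)
  cf <- coef(fit_components(sp, cs))
  expect_equal(unname(cf["s_fluo"]), 2, tolerance = 1e-10)
  expect_lt(max(abs(cf[c("s_d", "s_fura_minus", "s_fura_plus", "c")])), 1e-10)
  zero <- fit_components(spectrum(cs$wavelength_nm,
                                  numeric(length(cs$wavelength_nm))), cs)
  expect_lt(max(abs(coef(zero))), 1e-12)
})

test_that("duplicate components make the design singular and are reported", {
  cs <- make_component_spectra()
  cs2 <- component_set(cs$wavelength_nm, cs$sc_diode, cs$fl_fluo,
                       cs$fl_fluo, cs$fl_fura_plus)
  sp <- spectrum(cs$wavelength_nm, cs$fl_fluo)
  expect_error(fit_components(sp, cs2), "singular")
})

test_that("coefficient estimates are unbiased under 1% Gaussian noise", {
  cs <- make_component_spectra()
  truth <- c(s_d = 0.3, s_fluo = 1.5, s_fura_minus = 0.8,
             s_fura_plus = 0.6, c = 0.02)
  X <- cbind(cs$sc_diode, cs$fl_fluo, cs$fl_fura_minus, cs$fl_fura_plus, 1)
  clean <- as.numeric(X %*% truth)
  win <- cs$wavelength_nm >= 510 & cs$wavelength_nm <= 750
  sigma <- 0.01 * max(clean[win])
  set.seed(202)
  est <- replicate(200, {
    sp <- spectrum(cs$wavelength_nm, clean + rnorm(length(clean), 0, sigma))
    coef(fit_components(sp, cs))
  })
  m <- rowMeans(est)
  se <- apply(est, 1, sd) / sqrt(ncol(est))
  expect_true(all(abs(m - truth) < 3 * se + 1e-12))
})

test_that("residence-time scaling multiplies by speed over reference and is idempotent", {
  cs <- make_component_spectra()
  sp <- spectrum(cs$wavelength_nm, cs$fl_fluo, tape_speed_mm_s = 200)
  sc <- scale_by_tape_speed(sp, reference_speed = 100)
  expect_equal(sc$intensity, 2 * sp$intensity)
  expect_true(sc$speed_corrected)
  expect_identical(scale_by_tape_speed(sc, 100), sc)   # no double-correction
  same <- scale_by_tape_speed(spectrum(cs$wavelength_nm, cs$fl_fluo,
                                       tape_speed_mm_s = 100), 100)
  expect_equal(same$intensity, cs$fl_fluo)
  expect_error(scale_by_tape_speed(spectrum(1:5, 1:5)), "tape_speed")
})

test_that("scaling commutes with the linear fit", {
  cs <- make_component_spectra()
  X <- cbind(cs$sc_diode, cs$fl_fluo, cs$fl_fura_minus, cs$fl_fura_plus, 1)
  raw <- as.numeric(X %*% c(0.3, 1.5, 0.8, 0.6, 0.02))
  sp <- spectrum(cs$wavelength_nm, raw, tape_speed_mm_s = 300)
  a <- coef(fit_components(scale_by_tape_speed(sp, 100), cs))
  b <- coef(fit_components(sp, cs)) * 3
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("noiseless exponential-rise points are recovered to 1e-6", {
  tp <- c(0.2, 0.3, 0.5, 1, 2)
  pts <- data.frame(t = tp, s = 1 * (1 - exp(-tp / 0.15)))
  fit <- fit_rise(pts)
  expect_equal(unname(coef(fit)["a"]), 1, tolerance = 1e-6)
  expect_equal(unname(coef(fit)["tau"]), 0.15, tolerance = 1e-6)
  expect_true(fit$stable)
  # residual gradient is stationary at the optimum
  expect_lt(sqrt(sum(residuals(fit$fit)^2)), 1e-10)
})

test_that("plateau-only data are flagged unidentifiable, short series rejected", {
  expect_warning(fit <- fit_rise(data.frame(t = c(1, 2, 3, 4), s = rep(2, 4))),
                 "not")
  expect_false(fit$stable)
  expect_true(is.na(coef(fit)["tau"]))
  expect_error(fit_rise(data.frame(t = c(1, 2), s = c(0.1, 0.2))),
               "at least 3")
  expect_error(fit_rise(data.frame(t = c(-1, 1, 2), s = 1:3)), "positive")
})

test_that("averaging the fastest points merges them by mean before fitting", {
  tp <- c(0.2, 0.3, 0.5, 1, 2)
  pts <- data.frame(t = tp, s = 1 - exp(-tp / 0.15))
  fit <- fit_rise(pts, average_fastest = 2L)
  expect_equal(nrow(fit$points), 4L)
  expect_equal(fit$points$t[1], mean(c(0.2, 0.3)))
  expect_equal(fit$points$s[1], mean(pts$s[1:2]))
})

test_that("rise-time estimates are nearly unbiased at 5% noise (500 replicates)", {
  tau <- 0.15; a <- 1
  tp <- 60 / c(600, 300, 200, 100, 60, 30, 10)   # 0.1 to 6 s
  clean <- a * (1 - exp(-tp / tau))
  set.seed(404)
  taus <- replicate(500, {
    pts <- data.frame(t = tp, s = clean + rnorm(length(tp), 0, 0.05 * a))
    out <- tryCatch(coef(fit_rise(pts))["tau"], error = function(e) NA_real_)
    out
  })
  taus <- taus[is.finite(taus)]
  expect_gt(length(taus), 450)
  expect_lt(abs(mean(taus) - tau), 0.1 * tau)
})
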