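test_that("peak regions are detected for isolated peaks and refused when too few", {
  s <- calibration_spectrum(centers = seq(500, 1300, by = 100))
  regions <- detect_peak_regions(s)
  expect_equal(nrow(regions), 9)
  expect_equal(regions$apex_mz, seq(500, 1300, by = 100), tolerance = 1e-3)
  expect_true(all(regions$apex_index > regions$start &
                    regions$apex_index < regions$end))
  # single isolated peak: exactly one region containing the apex
  s1 <- tibble::tibble(mz = seq(499, 501, length.out = 40))
  s1$intensity <- 10 * exp(-(s1$mz - 500)^2 / (2 * 0.15^2))
  r1 <- detect_peak_regions(s1, min_regions = 1)
  expect_equal(nrow(r1), 1)
  expect_equal(r1$apex_mz, 500, tolerance = 0.06)
  expect_error(detect_peak_regions(s1), "well-resolved")
})

test_that("overlapping peaks are discarded as not well resolved", {
  sigma <- 0.05
  mk <- function(delta) {
    mz <- seq(499, 500 + delta + 3, by = 0.005)
    tibble::tibble(
      mz = mz,
      intensity = exp(-(mz - 500)^2 / (2 * sigma^2)) +
        exp(-(mz - 500 - delta)^2 / (2 * sigma^2))
    )
  }
  # far apart (50 sigma): both kept
  far <- detect_peak_regions(mk(50 * sigma), min_regions = 1)
  expect_equal(nrow(far), 2)
  # bimodal but closer than the separation window: both discarded
  expect_error(detect_peak_regions(mk(3 * sigma), min_regions = 1),
               "well-resolved")
  # brute-force valley scan confirms the 3-sigma case is genuinely bimodal
  y <- mk(3 * sigma)$intensity
  expect_equal(sum(diff(sign(diff(y))) < 0 & y[-c(1, length(y))] > 0.5), 2)
})

test_that("region fits recover gaussian and EMG parameters from clean peaks", {
  # gaussian, sigma = 0.05 sampled at 0.005
  mz <- seq(499, 501, by = 0.005)
  s <- tibble::tibble(mz = mz,
                      intensity = 80 * exp(-(mz - 500.013)^2 / (2 * 0.05^2)))
  r <- detect_peak_regions(s, min_regions = 1)
  f <- fit_peak_region(s, r[1, ], "gaussian")
  expect_true(f$converged)
  expect_equal(f$theta$sigma, 0.05, tolerance = 0.01)
  expect_equal(f$apex_mz, 500.013, tolerance = 1e-4)
  expect_equal(f$height, 80, tolerance = 0.01)

  # EMG (alpha 0.03, sigma 0.05, mu 0): alpha, sigma and the combined
  # location center+mu are identifiable; mu alone absorbs the apex offset.
  m0 <- 700.2
  se <- tibble::tibble(mz = seq(699, 702, by = 0.005))
  se$intensity <- 50 * eval_emg(se$mz, m0, 0.03, 0.05, 0)
  re <- detect_peak_regions(se, min_regions = 1)
  fe <- fit_peak_region(se, re[1, ], "emg")
  expect_true(fe$converged)
  expect_equal(fe$theta$alpha, 0.03, tolerance = 0.02)
  expect_equal(fe$theta$sigma, 0.05, tolerance = 0.02)
  expect_equal(fe$center + fe$theta$mu, m0, tolerance = 0.02 * 0.05)

  # pure flat noise region: excluded via non-convergence or large rel_rss
  set.seed(42)
  sn <- tibble::tibble(mz = seq(500, 500.5, by = 0.005),
                       intensity = runif(101, 0.5, 1.5))
  rn <- tibble::tibble(start = 20L, end = 80L, apex_index = 50L,
                       apex_mz = sn$mz[50], apex_intensity = sn$intensity[50])
  fn <- fit_peak_region(sn, rn, "gaussian")
  # a flat-noise region is either rejected outright or fitted as a degenerate
  # near-constant bump far wider than any resolved peak
  expect_true(!fn$converged || fn$rel_rss > 0.2 || fn$theta$sigma >= 0.2)
})

test_that("LAD trend fitting is exact, median-reducing and outlier-immune", {
  mk_fit <- function(x, sigma) {
    structure(list(theta = list(sigma = sigma, alpha = NA_real_, mu = 0),
                   height = 1, apex_mz = x, center = x, rss = 0, rel_rss = 0,
                   converged = TRUE, kind = "gaussian"),
              class = "region_fit")
  }
  # constant basis on {1, 2, 100} -> median 2
  fits <- Map(mk_fit, c(500, 700, 900), c(1, 2, 100))
  m <- fit_param_trend(fits, basis = "constant")
  expect_equal(eval_params(m, 600)$sigma, 2)

  # noiseless linear trend: coefficients recovered to 1e-8
  xs <- seq(400, 1300, by = 100)
  fits <- Map(mk_fit, xs, 0.01 + 2e-5 * xs)
  m <- fit_param_trend(fits, basis = "linear")
  expect_equal(m$components$sigma$coef, c(0.01, 2e-5), tolerance = 1e-8)

  # gross x10 outlier: LAD within 1%, OLS off by > 5% -- checked against the
  # exhaustive interpolation oracle
  truth <- 0.01 + 2e-5 * xs
  th <- truth
  th[4] <- th[4] * 10
  fits <- Map(mk_fit, xs, th)
  m <- fit_param_trend(fits, basis = "linear")
  G <- cbind(1, xs)
  orc <- oracle_lad(G, th)
  lad_pred <- eval_params(m, 800)$sigma
  expect_equal(lad_pred, 0.01 + 2e-5 * 800, tolerance = 0.01)
  expect_equal(sum(abs(th - G %*% m$components$sigma$coef)),
               orc$objective, tolerance = 1e-6)
  ols <- lm.fit(G, th)$coefficients
  expect_gt(abs(sum(ols * c(1, 800)) - (0.01 + 2e-5 * 800)) /
              (0.01 + 2e-5 * 800), 0.05)

  expect_error(fit_param_trend(fits[1], basis = "linear"), "at least")
})

test_that("LAD solution matches the enumeration oracle on random small instances", {
  set.seed(11)
  for (rep in 1:10) {
    n <- sample(6:15, 1)
    x <- sort(runif(n, 400, 1400))
    th <- 0.02 + 1e-5 * x + rnorm(n, 0, 0.003)
    G <- cbind(1, x)
    got <- isopick:::lad_fit(G, th)
    orc <- oracle_lad(G, th)
    expect_equal(sum(abs(th - G %*% got)), orc$objective,
                 tolerance = 1e-6 * max(1, orc$objective))
  }
})

test_that("eval_params clips trends to positive floors", {
  mk_fit <- function(x, sigma) {
    structure(list(theta = list(sigma = sigma, alpha = NA_real_, mu = 0),
                   height = 1, apex_mz = x, center = x, rss = 0, rel_rss = 0,
                   converged = TRUE, kind = "gaussian"),
              class = "region_fit")
  }
  xs <- seq(400, 800, by = 100)
  fits <- Map(mk_fit, xs, 0.1 - 1e-4 * xs)  # goes negative past x = 1000
  m <- fit_param_trend(fits, basis = "linear")
  expect_equal(eval_params(m, 2000)$sigma, 1e-4)
  expect_gt(eval_params(m, 500)$sigma, 1e-3)
})

test_that("detect -> fit -> trend -> eval round trip recovers generating parameters", {
  sigma_fun <- function(x) 0.012 + 1.5e-5 * x
  s <- calibration_spectrum(sigma_fun = sigma_fun)
  model <- calibrate_peak_shape(s, "gaussian")
  for (x in c(500, 800, 1200)) {
    expect_equal(eval_params(model, x)$sigma, sigma_fun(x), tolerance = 0.05)
  }
})

test_that("parameter trends are recovered under noise and outlier regions", {
  sigma_fun <- function(x) 0.012 + 1.5e-5 * x
  set.seed(7)
  rel_err <- replicate(20, {
    s <- calibration_spectrum(sigma_fun = sigma_fun)
    # 5% multiplicative noise, 10% of regions corrupted
    y <- s$intensity * (1 + rnorm(nrow(s), 0, 0.05))
    bad <- sample(seq(450, 1350, by = 100), 1)
    y[abs(s$mz - bad) < 0.2] <- y[abs(s$mz - bad) < 0.2] * runif(1, 2, 3)
    s$intensity <- pmax(y, 0)
    m <- tryCatch(calibrate_peak_shape(s, "gaussian"), error = function(e) NULL)
    if (is.null(m)) return(NA_real_)
    abs(eval_params(m, 900)$sigma - sigma_fun(900)) / sigma_fun(900)
  })
  expect_lt(median(rel_err, na.rm = TRUE), 0.05)
})
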