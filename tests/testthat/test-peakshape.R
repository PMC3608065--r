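test_that("gaussian peak is unit height, symmetric and rejects bad sigma", {
  expect_equal(eval_gaussian(500, 500, 0.05), 1)
  expect_equal(eval_gaussian(c(500.05, 499.95), 500, 0.05),
               rep(exp(-1 / 2), 2))
  d <- runif(20, 0, 0.3)
  expect_equal(eval_gaussian(500 + d, 500, 0.07),
               eval_gaussian(500 - d, 500, 0.07))
  expect_error(eval_gaussian(1, 1, 0), "sigma")
  expect_error(eval_gaussian(1, 1, -1), "sigma")
})

test_that("EMG matches an independent high-precision evaluation", {
  # Direct evaluation of the tailed-peak formula with erfc from pnorm at a
  # point where no overflow occurs.
  alpha <- 0.05; sigma <- 0.1; mu <- 0
  direct <- function(d) {
    (1 / alpha) * exp(sigma^2 / (2 * alpha^2) + (mu - d) / alpha) *
      pnorm(sigma / alpha + (mu - d) / sigma, lower.tail = FALSE)
  }
  d <- c(-0.2, -0.05, 0, 0.04, 0.15, 0.5)
  expect_equal(eval_emg(100 + d, 100, alpha, sigma, mu), direct(d),
               tolerance = 1e-12)
})

test_that("EMG is a density: integrates to 1 and stays finite for extreme sigma/alpha", {
  x <- seq(-3, 5, by = 1e-4)
  for (par in list(c(0.05, 0.1, 0), c(0.3, 0.05, 0.1), c(0.01, 0.2, -0.1))) {
    v <- eval_emg(x, 0, par[1], par[2], par[3])
    expect_true(all(v >= 0))
    expect_equal(sum(v) * 1e-4, 1, tolerance = 1e-3)
  }
  # sigma/alpha = 1e4 must not overflow
  v <- eval_emg(seq(-1, 1, by = 0.01), 0, 1e-5, 0.1, 0)
  expect_true(all(is.finite(v)))
  expect_error(eval_emg(0, 0, -1, 0.1), "alpha")
  expect_error(eval_emg(0, 0, 0.1, 0), "sigma")
})

test_that("EMG converges to the Gaussian as alpha -> 0", {
  sigma <- 0.1
  x <- seq(-6 * sigma, 6 * sigma, length.out = 2001)
  emg <- eval_emg(x, 0, alpha = 1e-4 * sigma, sigma = sigma, mu = 0)
  expect_lt(max(abs(emg / max(emg) - eval_gaussian(x, 0, sigma))), 1e-4)
})

test_that("averagine distribution matches the naive convolution oracle", {
  for (mass in c(500, 1000, 2000, 4000)) {
    got <- averagine_distribution(mass)
    exp_w <- oracle_averagine(mass)
    expect_equal(length(got$weights), length(exp_w))
    expect_equal(got$weights, exp_w, tolerance = 1e-6)
    expect_true(all(got$weights >= 0))
    expect_equal(max(got$weights), 1)
    expect_equal(got$most_intense_index, which.max(exp_w) - 1L)
  }
  # monoisotopic peak dominates below ~1800 Da
  expect_identical(averagine_distribution(700)$most_intense_index, 0L)
  expect_identical(averagine_distribution(1000)$most_intense_index, 0L)
  expect_gt(averagine_distribution(2500)$most_intense_index, 0L)
  expect_error(averagine_distribution(-5), "mass")
})

test_that("templates have kappa/charge spacing and unit maximum", {
  for (chg in 1:3) {
    tpl <- build_template(chg, 351.2 * chg / chg + 300, "gaussian",
                          list(sigma = 0.05), kappa = 1.00235)
    expect_equal(unique(round(diff(tpl$peak_centers), 9)),
                 round(1.00235 / chg, 9))
    grid <- seq(min(tpl$peak_centers) - 0.5, max(tpl$peak_centers) + 0.5,
                by = 0.05 / 50)
    expect_equal(max(eval_template(tpl, grid)), 1, tolerance = 1e-3)
  }
  # charge 2, kappa 1.00235 -> spacing 0.501175
  tpl <- build_template(2, 500, "gaussian", list(sigma = 0.03))
  expect_equal(diff(tpl$peak_centers)[1], 0.501175)
  # ~700 Da neutral mass: monoisotopic is most intense, no centers left of anchor
  tpl <- build_template(2, 351.2, "gaussian", list(sigma = 0.05))
  expect_true(all(tpl$peak_centers >= tpl$anchor_mz - 1e-12))
  expect_error(build_template(0, 500, "gaussian", list(sigma = 0.05)), "charge")
})

test_that("EMG templates also attain unit maximum", {
  tpl <- build_template(2, 800, "emg",
                        list(alpha = 0.04, sigma = 0.06, mu = 0.01))
  grid <- seq(min(tpl$peak_centers) - 1, max(tpl$peak_centers) + 1,
              by = 0.06 / 50)
  expect_equal(max(eval_template(tpl, grid)), 1, tolerance = 1e-3)
})

test_that("template matrix is non-negative, contiguous, permutation-stable and banded", {
  s <- tibble::tibble(mz = seq(698, 720, by = 0.02), intensity = 1)
  pl <- data.frame(charge = c(1, 1, 2, 2),
                   anchor_mz = c(700.1, 700.5, 710.2, 715.8))
  sm <- list(kind = "gaussian", sigma = 0.05)
  tm <- assemble_template_matrix(s, pl, sm)
  expect_true(all(tm$phi@x >= 0))
  expect_equal(unname(apply(as.matrix(tm$phi), 2, max)), rep(1, 4),
               tolerance = 1e-2)
  # contiguous supports
  for (j in 1:4) {
    nz <- which(as.matrix(tm$phi)[, j] > 0)
    expect_equal(nz, seq(min(nz), max(nz)))
  }
  # permuting placements yields the same matrix up to column order
  tm2 <- assemble_template_matrix(s, pl[c(3, 1, 4, 2), ], sm)
  expect_equal(as.matrix(tm$phi), as.matrix(tm2$phi))
  # disjoint supports -> block-diagonal Gram; overlapping anchors -> banded
  G <- as.matrix(Matrix::crossprod(tm$phi))
  expect_equal(G[1, 3], 0)
  expect_equal(G[2, 4], 0)
  expect_gt(G[1, 2], 0)  # 700.1 and 700.5 overlap
  expect_error(assemble_template_matrix(s, pl[0, ], sm), "non-empty")
  expect_error(
    assemble_template_matrix(s, data.frame(charge = 1, anchor_mz = 650), sm),
    "650"
  )
})

test_that("peptide m/z values reproduce the reference mixture table", {
  expect_equal(peptide_monoisotopic_mz("GACLLPK", 2), 351.20437,
               tolerance = 1e-5 / 351)
  expect_equal(peptide_monoisotopic_mz("CCTKPESER", 3), 351.48816,
               tolerance = 1e-5 / 351)
  expect_equal(peptide_monoisotopic_mz("VLASSAR", 2), 352.20850,
               tolerance = 1e-5 / 352)
  expect_error(peptide_monoisotopic_mz("GAXK", 1), "X")
  # carbamidomethyl adds 57.021464 per cysteine
  expect_equal(
    peptide_monoisotopic_mz("GACLLPK", 1, carbamidomethyl = TRUE) -
      peptide_monoisotopic_mz("GACLLPK", 1),
    57.021464
  )
})
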