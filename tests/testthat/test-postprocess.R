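make_fit <- function(beta, blocks) {
  structure(list(beta = beta, blocks = blocks, q = 2L, objective = 0,
                 kkt_residual = 0, stages = 1L, converged = TRUE,
                 method = "nnls_logbarrier", fitted = numeric(0),
                 residuals = numeric(0)),
            class = "nn_fit")
}
make_tm <- function(blocks) {
  structure(list(phi = Matrix::Matrix(0, 1, nrow(blocks), sparse = TRUE),
                 blocks = blocks, mz = numeric(0)),
            class = "template_matrix")
}

test_that("template grouping chains anchors by ppm gaps per charge", {
  blocks <- tibble::tibble(column = 1:4, charge = c(1L, 1L, 1L, 2L),
                           anchor_mz = c(500.000, 500.020, 500.100, 500.010))
  tm <- make_tm(blocks)
  # 40 ppm gap joins at 100 ppm; 160 ppm gap splits
  g <- group_templates(make_fit(c(1, 1, 1, 1), blocks), tm, ppm_tol = 100)
  expect_equal(g$group[g$charge == 1], c(1L, 1L, 2L))
  expect_equal(unique(g$group[g$charge == 2]), 3L)
  # 500.000 / 500.100 alone: 200 ppm apart -> two groups
  g2 <- group_templates(make_fit(c(1, 0, 1, 0), blocks), tm, ppm_tol = 100)
  expect_equal(nrow(g2), 2)
  expect_equal(g2$group, 1:2)
  # no positive coefficients
  expect_equal(nrow(group_templates(make_fit(rep(0, 4), blocks), tm)), 0)
  expect_error(group_templates(make_fit(rep(1, 4), blocks), tm, ppm_tol = 0),
               "ppm_tol")
})

test_that("merging returns singletons unchanged and respects symmetry", {
  sm <- list(kind = "gaussian", sigma = 0.05)
  single <- tibble::tibble(charge = 1L, anchor_mz = 500.123, beta = 42,
                           column = 1L, group = 1L)
  m <- merge_group(single, sm)
  expect_equal(m$anchor_mz, 500.123)
  expect_equal(m$beta, 42)
  # equal weights at m +/- delta, symmetric shape -> merged at m
  delta <- 0.01
  pair <- tibble::tibble(charge = 1L, anchor_mz = 500 + c(-delta, delta),
                         beta = c(5, 5), column = 1:2, group = 1L)
  m2 <- merge_group(pair, sm, data_spacing = 0.02)
  expect_equal(m2$anchor_mz, 500, tolerance = 1e-6)
})

test_that("merge optimum beats the brute-force grid oracle", {
  sigma <- 0.05
  sm <- list(kind = "gaussian", sigma = sigma)
  anchors <- 500 + c(0, 0.3 * sigma)
  betas <- c(0.6, 0.4)
  grp <- tibble::tibble(charge = 1L, anchor_mz = anchors, beta = betas,
                        column = 1:2, group = 1L)
  m <- merge_group(grp, sm, data_spacing = 0.02)
  x_grid <- seq(min(anchors) - 5 * sigma, max(anchors) + 5 * sigma,
                by = sigma / 40)
  orc <- oracle_merge_grid(anchors, betas, sigma,
                           m_grid = seq(min(anchors) - 0.02,
                                        max(anchors) + 0.02,
                                        length.out = 161),
                           b_grid = seq(0.8, 1.2, length.out = 161),
                           x_grid = x_grid)
  expect_equal(m$anchor_mz, orc$m, tolerance = (0.04 + 0.3 * sigma) / 160 * 2)
  expect_equal(m$beta, orc$b, tolerance = 0.4 / 160 * 2)
  # the returned optimum is at least as good as every oracle lattice point
  psi <- function(x, mm) exp(-(x - mm)^2 / (2 * sigma^2))
  target <- betas[1] * psi(x_grid, anchors[1]) + betas[2] * psi(x_grid, anchors[2])
  obj_at <- function(mm, bb) sum((target - bb * psi(x_grid, mm))^2)
  expect_lte(obj_at(m$anchor_mz, m$beta), orc$objective + 1e-10)
})

test_that("feature scoring combines GOF, coefficient and truncated noise level", {
  feats <- tibble::tibble(charge = 1L, anchor_mz = 700.5, beta = 10,
                          n_members = 1L)
  noise <- tibble::tibble(mz = seq(700, 701, by = 0.1), lnl = 2, lnl_plus = 2)
  gof <- tibble::tibble(mz = seq(700, 701, by = 0.1), residual = 0,
                        gof_plus = 0.5)
  sc <- score_features(feats, noise, gof)
  expect_equal(sc$ratio, 2.5)   # 0.5 * 10 / 2
  # ~700 Da: monoisotopic dominant, no shift
  expect_equal(sc$monoisotopic_mz, sc$anchor_mz)
  expect_equal(sc$neutral_mass, 1 * sc$monoisotopic_mz - 1.0072765)
  # heavier feature: monoisotopic below the most intense peak
  f2 <- tibble::tibble(charge = 2L, anchor_mz = 1300.6, beta = 5,
                       n_members = 1L)
  noise2 <- tibble::tibble(mz = seq(1300, 1301, by = 0.1), lnl = 1, lnl_plus = 1)
  gof2 <- tibble::tibble(mz = seq(1300, 1301, by = 0.1), residual = 0,
                         gof_plus = 0.4)
  sc2 <- score_features(f2, noise2, gof2, kappa = 1.00235)
  kmax <- averagine_distribution(2 * 1300.6 - 2 * 1.0072765)$most_intense_index
  expect_gt(kmax, 0)
  expect_equal(sc2$monoisotopic_mz, 1300.6 - kmax * 1.00235 / 2)
})

test_that("thresholding is a monotone filter with trivial endpoints", {
  set.seed(31)
  feats <- tibble::tibble(
    anchor_mz = sort(runif(20, 500, 900)), charge = 1L,
    beta = runif(20, 0.1, 10), ratio = runif(20, 0, 12),
    gof_plus = 0.5, lnl_plus = 1,
    monoisotopic_mz = sort(runif(20, 500, 900)),
    neutral_mass = runif(20, 500, 900), n_members = 1L
  )
  expect_equal(nrow(apply_threshold(feats, 0)), 20)
  expect_equal(nrow(apply_threshold(feats, Inf)), 0)
  sizes <- vapply(c(0, 1, 2, 5, 8, 20),
                  function(t) nrow(apply_threshold(feats, t)), numeric(1))
  expect_true(all(diff(sizes) <= 0))
  expect_error(apply_threshold(feats, -1), "t")
})

test_that("the peptide-mass filter keeps masses near cluster centers only", {
  mk <- function(masses) {
    tibble::tibble(anchor_mz = masses + 1.0072765, charge = 1L, beta = 1,
                   ratio = 10, gof_plus = 0.5, lnl_plus = 1,
                   monoisotopic_mz = masses + 1.0072765,
                   neutral_mass = masses, n_members = 1L)
  }
  # 1.000485 * 700 + 0.029 = 700.3685: exactly on a center
  on_center <- peptide_mass_filter(apply_threshold(mk(700.3685), 0), 200)
  expect_equal(nrow(on_center), 1)
  # 700.85 is > 600 ppm from both neighboring centers
  off <- peptide_mass_filter(apply_threshold(mk(700.85), 0), 200)
  expect_equal(nrow(off), 0)
  # infinite tolerance is the identity
  both <- peptide_mass_filter(apply_threshold(mk(c(700.3685, 700.85)), 0), Inf)
  expect_equal(nrow(both), 2)
})

test_that("split templates are collapsed to the true pattern (sampling repair)", {
  spacing <- 0.04
  sigma <- 0.05
  grid <- seq(994, 1006, by = spacing)
  anchor_true <- grid[150] + spacing / 2     # apex falls between grid points
  tpl <- build_template(1, anchor_true, "gaussian", list(sigma = sigma))
  y <- 100 * eval_template(tpl, grid)
  s <- tibble::tibble(mz = grid, intensity = y)
  tm <- assemble_template_matrix(
    s, data.frame(charge = 1, anchor_mz = grid[150:151]),
    list(kind = "gaussian", sigma = sigma)
  )
  f <- nnls_logbarrier(tm, y)
  expect_true(all(f$beta > 0))               # both flanking templates share the weight
  g <- group_templates(f, tm, ppm_tol = 100)
  expect_equal(length(unique(g$group)), 1)
  m <- merge_group(g, list(kind = "gaussian", sigma = sigma),
                   data_spacing = spacing)
  expect_lt(abs(m$anchor_mz - anchor_true), 0.1 * spacing)
  expect_lt(abs(m$beta - 100) / 100, 0.02)
})

test_that("positions are invariant and coefficients equivariant under rescaling", {
  sim <- noiseless_five_pattern_sim()
  cfg <- pick_config(charges = 1:3, threshold = 1, log_level = "quiet",
                     shape_params = list(kind = "gaussian", sigma = 0.04))
  pl1 <- pick_peaks(sim$spectrum, cfg)
  s2 <- sim$spectrum
  s2$intensity <- s2$intensity * 13
  pl2 <- pick_peaks(s2, cfg)
  expect_equal(pl2$monoisotopic_mz, pl1$monoisotopic_mz, tolerance = 1e-8)
  expect_equal(pl2$beta, 13 * pl1$beta, tolerance = 1e-5 * max(pl1$beta))
  expect_equal(pl2$ratio, pl1$ratio, tolerance = 1e-6 * max(pl1$ratio))
})
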