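# Independent oracles used to verify the implementation.  Each is written
# against the definition, not the package's code path.

# --- isotope distribution oracle -------------------------------------------
# Naive one-element-at-a-time convolution of elemental isotope distributions
# (the package uses binary exponentiation); abundance tables restated here.
oracle_element_isotopes <- list(
  C = c(0.9893, 0.0107),
  H = c(0.999885, 0.000115),
  N = c(0.99636, 0.00364),
  O = c(0.99757, 0.00038, 0.00205),
  S = c(0.9499, 0.0075, 0.0425, 0.0001)
)
oracle_element_mono <- c(C = 12.0, H = 1.0078250319, N = 14.0030740052,
                         O = 15.9949146221, S = 31.97207069)

oracle_convolve <- function(a, b) {
  out <- numeric(length(a) + length(b) - 1L)
  for (i in seq_along(a)) {
    for (j in seq_along(b)) out[i + j - 1L] <- out[i + j - 1L] + a[i] * b[j]
  }
  out
}

# Same composition contract as the package (scaled averagine, H adjusted),
# but the convolution itself is the naive loop above.
oracle_averagine <- function(mass, trim_rel = 0.01) {
  comp <- c(C = 4.9384, N = 1.3577, O = 1.4773, S = 0.0417) * mass / 111.1254
  counts <- round(comp)
  heavy <- sum(counts * oracle_element_mono[names(counts)])
  counts <- c(counts, H = max(0, round((mass - heavy) / oracle_element_mono[["H"]])))
  dist <- 1
  for (el in names(counts)) {
    for (rep in seq_len(counts[[el]])) {
      dist <- oracle_convolve(dist, oracle_element_isotopes[[el]])
      keep <- max(which(dist > 1e-12 * max(dist)))
      dist <- dist[seq_len(keep)]
    }
  }
  dist <- dist / max(dist)
  dist[seq_len(max(which(dist >= trim_rel)))]
}

# --- least absolute deviation oracle ---------------------------------------
# An LAD optimum interpolates M points (generic position): enumerate all
# M-subsets, solve the interpolation system, keep the best objective.
oracle_lad <- function(G, theta) {
  G <- as.matrix(G)
  n <- nrow(G); M <- ncol(G)
  best <- NULL; best_obj <- Inf
  for (idx in utils::combn(n, M, simplify = FALSE)) {
    sub <- G[idx, , drop = FALSE]
    if (abs(det(sub)) < 1e-12) next
    nu <- solve(sub, theta[idx])
    obj <- sum(abs(theta - as.numeric(G %*% nu)))
    if (obj < best_obj) { best_obj <- obj; best <- nu }
  }
  list(coef = best, objective = best_obj)
}

# --- LP oracle for non-negative LAD ----------------------------------------
# scipy.optimize.linprog (HiGHS) on the standard LP reformulation; batch
# interface over instances to amortize interpreter startup.
oracle_nnlad_lp <- function(instances) {
  script <- tempfile(fileext = ".py")
  writeLines(c(
    "import sys, json",
    "import numpy as np",
    "from scipy.optimize import linprog",
    "inst = json.load(open(sys.argv[1]))",
    "out = []",
    "for d in inst:",
    "    phi = np.array(d['phi']); y = np.array(d['y'])",
    "    n, p = phi.shape",
    "    c = np.concatenate([np.zeros(p), np.ones(n)])",
    "    A = np.block([[phi, -np.eye(n)], [-phi, -np.eye(n)]])",
    "    b = np.concatenate([y, -y])",
    "    res = linprog(c, A_ub=A, b_ub=b, bounds=[(0, None)]*(p+n), method='highs')",
    "    out.append(res.fun)",
    "json.dump(out, open(sys.argv[2], 'w'))"
  ), script)
  fin <- tempfile(fileext = ".json")
  fout <- tempfile(fileext = ".json")
  jsonlite::write_json(instances, fin, digits = NA, auto_unbox = FALSE)
  status <- system2("python", c(script, fin, fout))
  stopifnot(status == 0)
  unlist(jsonlite::read_json(fout))
}

# --- brute-force merge oracle ----------------------------------------------
# Exhaustive 2-D lattice search of the merge objective for a group of
# single Gaussian peaks.
oracle_merge_grid <- function(anchors, betas, sigma, m_grid, b_grid,
                              x_grid) {
  target <- numeric(length(x_grid))
  for (j in seq_along(anchors)) {
    target <- target + betas[j] * exp(-(x_grid - anchors[j])^2 / (2 * sigma^2))
  }
  best <- c(NA, NA); best_obj <- Inf
  for (m in m_grid) {
    pm <- exp(-(x_grid - m)^2 / (2 * sigma^2))
    for (b in b_grid) {
      obj <- sum((target - b * pm)^2)
      if (obj < best_obj) { best_obj <- obj; best <- c(m, b) }
    }
  }
  list(m = best[1], b = best[2], objective = best_obj)
}
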