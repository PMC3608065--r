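#' Interior-point solver configuration
#'
#' Controls the log-barrier schedule and Newton iterations shared by
#' [nnls_logbarrier()], [nnlad_logbarrier()] and [weighted_nn_lasso()].
#'
#' @param gamma0 Initial barrier weight (> 0).
#' @param mult Barrier multiplier M > 1 applied between stages.
#' @param gamma_max Final barrier weight; the loop stops once the stage
#'   weight reaches it.
#' @param newton_tol Relative gradient-norm tolerance per Newton solve.
#' @param max_newton Newton iteration cap per barrier stage.
#' @param shrink,armijo Backtracking line-search parameters.
#' @param init_scale Scale of the strictly positive starting point.
#' @param chol `"sparse"` (default; sparse Cholesky with fill-reducing
#'   ordering, symbolic factor reused across Newton steps) or `"dense"`.
#' @return A list of class `"solver_config"`.
#' @export
solver_config <- function(gamma0 = 10, mult = 10, gamma_max = 1e8,
                          newton_tol = 1e-8, max_newton = 100L,
                          shrink = 0.5, armijo = 1e-4, init_scale = 1e-3,
                          chol = c("sparse", "dense")) {
  stopifnot(gamma0 > 0, mult > 1, gamma_max > gamma0, newton_tol > 0)
  structure(
    list(gamma0 = gamma0, mult = mult, gamma_max = gamma_max,
         newton_tol = newton_tol, max_newton = as.integer(max_newton),
         shrink = shrink, armijo = armijo, init_scale = init_scale,
         chol = match.arg(chol)),
    class = "solver_config"
  )
}

# Accept a template_matrix, Matrix, or base matrix; return sparse dgCMatrix.
design_matrix <- function(phi) {
  if (inherits(phi, "template_matrix")) phi <- phi$phi
  if (!inherits(phi, "Matrix")) phi <- Matrix::Matrix(as.matrix(phi), sparse = TRUE)
  as(as(phi, "generalMatrix"), "CsparseMatrix")
}

validate_design <- function(phi, y) {
  if (nrow(phi) != length(y)) abort("`phi` and `y` dimensions disagree.")
  if (anyNA(y) || !all(is.finite(y))) abort("`y` contains non-finite values.")
  if (any(phi@x < 0)) abort("`phi` must be non-negative.")
  colnorm <- sqrt(Matrix::colSums(phi^2))
  if (any(colnorm == 0)) {
    abort(paste0("Design has zero-norm column(s): ",
                 paste(which(colnorm == 0), collapse = ", ")))
  }
}

# Cholesky solve helper: reuses a sparse symbolic factorization across calls
# (only the matrix values change between Newton steps), or falls back to a
# dense factorization when config$chol == "dense".  On numerical failure a
# small diagonal regularization is attempted once.
make_chol_solver <- function(config) {
  factor <- NULL
  function(H, rhs) {
    if (config$chol == "dense") {
      Hd <- as.matrix(H)
      ch <- tryCatch(chol(Hd), error = function(e) {
        chol(Hd + diag(1e-12 * sum(diag(Hd)) / nrow(Hd), nrow(Hd)))
      })
      return(backsolve(ch, backsolve(ch, rhs, transpose = TRUE)))
    }
    H <- as(Matrix::forceSymmetric(H), "CsparseMatrix")
    res <- tryCatch({
      if (is.null(factor)) {
        factor <<- Matrix::Cholesky(H, LDL = FALSE, perm = TRUE)
      } else {
        factor <<- Matrix::update(factor, H)
      }
      as.numeric(Matrix::solve(factor, rhs))
    }, error = function(e) NULL)
    if (is.null(res)) {
      reg <- 1e-12 * sum(Matrix::diag(H)) / nrow(H)
      Hr <- H + Matrix::Diagonal(nrow(H), reg)
      factor <<- Matrix::Cholesky(Hr, LDL = FALSE, perm = TRUE)
      res <- as.numeric(Matrix::solve(factor, rhs))
    }
    res
  }
}

new_nn_fit <- function(beta, objective, q, kkt, stages, converged, method,
                       fitted, residuals, blocks = NULL, lambda = 0) {
  structure(
    list(beta = beta, objective = objective, q = q, kkt_residual = kkt,
         stages = stages, converged = converged, method = method,
         fitted = fitted, residuals = residuals, blocks = blocks,
         lambda = lambda),
    class = "nn_fit"
  )
}

#' Non-negative least squares by the log-barrier method
#'
#' Solves \eqn{\min_{\beta \ge 0} \tfrac12 \|y - \Phi\beta\|_2^2} by solving
#' a sequence of unconstrained problems with barrier term
#' \eqn{-\gamma^{-1}\sum_j \log\beta_j} via damped Newton steps; the Newton
#' system \eqn{(\Phi^\top\Phi + \gamma^{-1}\mathrm{diag}(\beta^{-2}))d =
#' -\nabla} is solved by sparse symmetric positive-definite Cholesky
#' factorization, exploiting the banded structure of the template Gram
#' matrix.  After the final stage, coordinates whose dual gradient is clearly
#' positive are clamped to exact zero (interior-point iterates are never
#' exactly zero; this crossover restores exact complementary slackness).
#'
#' @param phi Design: a `"template_matrix"`, a sparse `Matrix`, or a base
#'   matrix; must be non-negative with no zero columns.
#' @param y Numeric intensity vector.
#' @param config A [solver_config()].
#' @return An object of class `"nn_fit"` with elements `beta` (the
#'   coefficient vector, >= 0), `objective` (\eqn{\|y - \Phi\hat\beta\|_2^2}),
#'   `kkt_residual`, `stages`, `converged`.  Use [tidy()] / [glance()] for
#'   tabular views.
#' @examples
#' phi <- diag(3)
#' nnls_logbarrier(phi, c(1, 0, 2))$beta
#' @export
nnls_logbarrier <- function(phi, y, config = solver_config()) {
  nnls_barrier_impl(phi, y, lambda = 0, weights = NULL, config = config,
                    method = "nnls_logbarrier")
}

#' Weighted non-negative lasso
#'
#' Solves \eqn{\min_{\beta \ge 0} \|y - \Phi\beta\|_2^2 +
#' \lambda\,\mathbf{1}^\top W \beta}, the penalized variant in which the
#' per-column weights (typically the truncated local noise level at each
#' template anchor) rescale the amount of \eqn{\ell_1} regularization.  Uses
#' the same log-barrier machinery as [nnls_logbarrier()] (the linear term
#' only shifts the gradient); `lambda = 0` reduces exactly to NNLS.
#'
#' @inheritParams nnls_logbarrier
#' @param lambda Penalty level (>= 0).
#' @param weights Positive per-column weights (default all 1).
#' @return An `"nn_fit"`; `objective` is the penalized criterion.
#' @export
weighted_nn_lasso <- function(phi, y, lambda, weights = NULL,
                              config = solver_config()) {
  if (lambda < 0) abort("`lambda` must be >= 0.")
  nnls_barrier_impl(phi, y, lambda = lambda, weights = weights,
                    config = config, method = "weighted_nn_lasso")
}

nnls_barrier_impl <- function(phi, y, lambda, weights, config, method) {
  blocks <- if (inherits(phi, "template_matrix")) phi$blocks else NULL
  phi <- design_matrix(phi)
  y <- as.numeric(y)
  validate_design(phi, y)
  p <- ncol(phi)
  w <- if (is.null(weights)) rep(1, p) else as.numeric(weights)
  if (length(w) != p || any(w <= 0)) abort("`weights` must be positive, one per column.")

  yscale <- max(abs(y))
  if (yscale == 0) {
    beta <- rep(0, p)
    fit0 <- rep(0, length(y))
    obj <- if (lambda > 0) 0 else 0
    return(new_nn_fit(beta, obj, 2L, 0, 0L, TRUE, method, fit0, y, blocks, lambda))
  }
  ys <- y / yscale
  lam <- lambda / yscale
  cvec <- lam * w / 2                       # gradient shift of the 1/2-SSQ form

  G <- Matrix::crossprod(phi)
  phity <- as.numeric(Matrix::crossprod(phi, ys))
  gscale <- max(abs(phity), 1)
  solve_chol <- make_chol_solver(config)

  beta <- rep(max(gscale * config$init_scale, 1e-8), p)
  barrier_obj <- function(beta, gamma) {
    r <- ys - as.numeric(phi %*% beta)
    0.5 * sum(r^2) + sum(cvec * beta) - sum(log(beta)) / gamma
  }
  gamma <- config$gamma0
  stages <- 0L
  converged <- TRUE
  repeat {
    for (it in seq_len(config$max_newton)) {
      Gb <- as.numeric(G %*% beta)
      grad <- Gb - phity + cvec - 1 / (gamma * beta)
      if (sqrt(sum(grad^2)) <= config$newton_tol * (1 + gscale)) break
      H <- G + Matrix::Diagonal(p, 1 / (gamma * beta^2))
      d <- solve_chol(H, -grad)
      tmax <- 1
      neg <- d < 0
      if (any(neg)) tmax <- min(1, 0.99 * min(-beta[neg] / d[neg]))
      f0 <- barrier_obj(beta, gamma)
      slope <- sum(grad * d)
      t <- tmax
      while (t > 1e-14 &&
             barrier_obj(beta + t * d, gamma) > f0 + config$armijo * t * slope) {
        t <- t * config$shrink
      }
      if (t <= 1e-14) break
      beta <- beta + t * d
    }
    stages <- stages + 1L
    if (gamma >= config$gamma_max) break
    gamma <- min(gamma * config$mult, config$gamma_max)
  }

  # Crossover: clamp coordinates held at the barrier floor to exact zero,
  # then refine the surviving active set by solving its normal equations
  # exactly (accepted only if still primal and dual feasible).  This removes
  # the O(p / gamma_max) barrier duality gap.
  g <- as.numeric(G %*% beta) - phity + cvec
  zero <- g > 1e-4 * gscale & beta < 1e-5 * max(beta)
  beta[zero] <- 0
  act <- which(beta > 0)
  if (length(act) > 0L) {
    refined <- tryCatch({
      cand <- NULL
      for (iter in 1:30) {
        ba <- as.numeric(Matrix::solve(G[act, act, drop = FALSE],
                                       phity[act] - cvec[act]))
        if (any(ba < 0)) {               # drop the most infeasible column
          act <- act[-which.min(ba)]
          if (length(act) == 0L) { cand <- rep(0, p); break }
          next
        }
        cand <- rep(0, p)
        cand[act] <- ba
        gc_ <- as.numeric(G %*% cand) - phity + cvec
        viol <- which.min(gc_)
        if (gc_[viol] < -1e-9 * gscale && !(viol %in% act)) {
          act <- sort(c(act, viol))      # admit a dual-infeasible column
          cand <- NULL
          next
        }
        break
      }
      cand
    }, error = function(e) NULL)
    if (!is.null(refined)) beta <- refined
  }
  g <- as.numeric(G %*% beta) - phity + cvec
  kkt <- max(c(0, -g / gscale, abs(beta * g) / gscale))
  if (kkt > 1e-3) {
    converged <- FALSE
    warn(sprintf("KKT residual %.2e above tolerance at gamma_max.", kkt))
  }

  beta <- beta * yscale
  fit <- as.numeric(phi %*% beta)
  resid <- y - fit
  obj <- sum(resid^2) + lambda * sum(w * beta)
  new_nn_fit(beta, obj, 2L, kkt, stages, converged, method, fit, resid, blocks, lambda)
}

#' Non-negative least absolute deviation by the log-barrier method
#'
#' Solves \eqn{\min_{\beta \ge 0} \|y - \Phi\beta\|_1} via its linear-program
#' form: minimize \eqn{\mathbf{1}^\top r} subject to
#' \eqn{-r \le y - \Phi\beta \le r}, \eqn{r \ge 0}, \eqn{\beta \ge 0}.  All
#' constraints enter as log-barrier terms; the Newton system over
#' \eqn{(r, \beta)} is reduced by block elimination (the r-block Hessian is
#' diagonal) to a \eqn{p \times p} system with the sparsity pattern of the
#' template Gram matrix, solved by sparse Cholesky.  The \eqn{\ell_1} fit is
#' robust to deviations from the averagine and peak-shape models.
#'
#' @inheritParams nnls_logbarrier
#' @return An `"nn_fit"`; `objective` is \eqn{\|y - \Phi\hat\beta\|_1}.
#' @examples
#' phi <- diag(3)
#' nnlad_logbarrier(phi, c(1, -1, 2))$beta  # max(y, 0) for identity design
#' @export
nnlad_logbarrier <- function(phi, y, config = solver_config()) {
  blocks <- if (inherits(phi, "template_matrix")) phi$blocks else NULL
  phi <- design_matrix(phi)
  y <- as.numeric(y)
  validate_design(phi, y)
  n <- nrow(phi); p <- ncol(phi)

  yscale <- max(abs(y))
  if (yscale == 0) {
    return(new_nn_fit(rep(0, p), 0, 1L, 0, 0L, TRUE, "nnlad_logbarrier",
                      rep(0, n), y, blocks))
  }
  ys <- y / yscale
  phity <- as.numeric(Matrix::crossprod(phi, abs(ys)))
  gscale <- max(abs(phity), 1)
  solve_chol <- make_chol_solver(config)

  beta <- rep(max(gscale * config$init_scale, 1e-8), p)
  e <- as.numeric(phi %*% beta) - ys
  r <- 1.5 * abs(e) + 0.1 * mean(abs(ys)) + 1e-6

  barrier_obj <- function(r, beta, xip, xim, gamma) {
    sum(r) - (sum(log(xip)) + sum(log(xim)) + sum(log(r)) + sum(log(beta))) / gamma
  }
  gamma <- config$gamma0
  stages <- 0L
  converged <- TRUE
  run_barrier <- function(gamma_end) repeat {
    for (it in seq_len(config$max_newton)) {
      e <- as.numeric(phi %*% beta) - ys
      xip <- e + r
      xim <- -e + r
      gr <- 1 - (1 / xip + 1 / xim + 1 / r) / gamma
      gb <- -(as.numeric(Matrix::crossprod(phi, 1 / xip - 1 / xim)) + 1 / beta) / gamma
      if (sqrt(sum(gr^2) + sum(gb^2)) <= config$newton_tol * (1 + sqrt(n))) break
      ap <- 1 / xip^2; am <- 1 / xim^2
      drr <- (ap + am + 1 / r^2) / gamma          # diagonal of the r-block
      d1 <- (ap - am) / gamma                     # coupling diagonal
      # Schur weights (ap+am)/gamma - d1^2/drr, written in a cancellation-free
      # form that is positive by construction:
      ws <- (4 * ap * am + (ap + am) / r^2) / (ap + am + 1 / r^2) / gamma
      A <- Matrix::Diagonal(n, sqrt(ws)) %*% phi
      S <- Matrix::crossprod(A) + Matrix::Diagonal(p, 1 / (gamma * beta^2))
      rhs <- -gb + as.numeric(Matrix::crossprod(phi, d1 * gr / drr))
      dbeta <- solve_chol(S, rhs)
      dr <- -(d1 * as.numeric(phi %*% dbeta) + gr) / drr
      dphi <- as.numeric(phi %*% dbeta)
      dxip <- dphi + dr
      dxim <- -dphi + dr
      tmax <- 1
      for (pair in list(list(beta, dbeta), list(r, dr),
                        list(xip, dxip), list(xim, dxim))) {
        neg <- pair[[2]] < 0
        if (any(neg)) tmax <- min(tmax, 0.99 * min(-pair[[1]][neg] / pair[[2]][neg]))
      }
      f0 <- barrier_obj(r, beta, xip, xim, gamma)
      slope <- sum(gr * dr) + sum(gb * dbeta)
      t <- tmax
      repeat {
        bn <- beta + t * dbeta; rn <- r + t * dr
        en <- as.numeric(phi %*% bn) - ys
        xipn <- en + rn; ximn <- -en + rn
        ok <- all(bn > 0) && all(rn > 0) && all(xipn > 0) && all(ximn > 0) &&
          barrier_obj(rn, bn, xipn, ximn, gamma) <= f0 + config$armijo * t * slope
        if (ok || t <= 1e-14) break
        t <- t * config$shrink
      }
      if (t <= 1e-14) break
      beta <- beta + t * dbeta
      r <- r + t * dr
    }
    beta <<- beta; r <<- r
    stages <<- stages + 1L
    if (gamma >= gamma_end) { gamma <<- gamma; break }
    gamma <<- gamma <- min(gamma * config$mult, gamma_end)
  }
  run_barrier(config$gamma_max)
  beta_ip <- beta; r_ip <- r          # strictly interior terminal iterate

  # Crossover: estimated LP reduced cost of a floored coordinate is
  # 1/(gamma beta_j); clamp clear zeros.
  crossover <- function(beta) {
    red <- 1 / (gamma * beta)
    beta[red > 1e-4 * gscale & beta < 1e-5 * max(beta)] <- 0
    beta
  }
  beta <- crossover(beta)
  # Vertex refinement: at an LAD optimum with k active columns, k residuals
  # vanish (generic position).  Iteratively re-solve the square
  # interpolation system on the k smallest residuals, admitting columns
  # whose L1 reduced cost is violated and dropping infeasible ones; accept
  # only monotone objective improvements, so the step is always safe.
  lad_obj <- function(b) sum(abs(ys - as.numeric(phi %*% b)))
  refine_vertex <- function(beta) {
  cur_obj <- lad_obj(beta)
  for (outer in 1:20) {
    act <- which(beta > 0)
    if (length(act) == 0L) break
    e <- ys - as.numeric(phi %*% beta)
    # Admit a column whose L1 reduced cost is violated.
    sg <- sign(e) * (abs(e) > 1e-7 * max(abs(ys)))
    red <- as.numeric(Matrix::crossprod(phi, sg))
    inactive <- setdiff(seq_len(p), act)
    if (length(inactive) > 0L) {
      jv <- inactive[which.max(red[inactive])]
      if (red[jv] > 1 + 1e-9) act <- sort(c(act, jv))
    }
    # Interpolated data: at the barrier optimum, residuals split into
    # near-zeros (O(1/gamma)) and the rest.  The split can be ambiguous by
    # one at a degenerate vertex, so a few candidate zero-set sizes around
    # the largest multiplicative gap are tried and the best kept.
    ae <- sort(abs(e))
    small <- which(ae < 1e-3 * max(abs(ys)))
    cut <- length(act)
    if (length(small) > 0L && max(small) < length(ae)) {
      ratios <- ae[small + 1L] / pmax(ae[small], 1e-300)
      if (max(ratios) > 50) cut <- small[which.max(ratios)]
    }
    sizes <- unique(pmax(1L, pmin(n, c(cut, cut - 1L, cut + 1L,
                                       length(act), length(act) + 1L))))
    try_size <- function(kz) {
      tryCatch({
        zi <- order(abs(e))[seq_len(kz)]
        a <- if (kz < length(act)) {
          sort(act[order(beta[act], decreasing = TRUE)[seq_len(kz)]])
        } else act
        ba <- NULL
        for (inner in 1:30) {
          if (length(a) == 0L) return(NULL)
          ba <- as.numeric(qr.solve(as.matrix(phi[zi, a, drop = FALSE]), ys[zi]))
          if (any(ba < 0)) {
            a <- a[-which.min(ba)]
            ba <- NULL
            next
          }
          break
        }
        if (is.null(ba)) return(NULL)
        b2 <- rep(0, p)
        b2[a] <- ba
        b2
      }, error = function(err) NULL)
    }
    best <- NULL; best_obj <- cur_obj
    for (kz in sizes) {
      cand <- try_size(kz)
      if (!is.null(cand)) {
        o <- lad_obj(cand)
        if (o < best_obj - 1e-14 * max(1, best_obj)) {
          best <- cand; best_obj <- o
        }
      }
    }
    if (is.null(best)) break
    beta <- best
    cur_obj <- best_obj
  }
  beta
  }
  beta <- refine_vertex(beta)

  # At an optimal vertex at least as many residuals vanish as there are
  # active columns.  If the refinement could not reach one (ambiguous
  # residual split at gamma_max), continue the barrier two stages further
  # and refine again: the sharper split then identifies the vertex.
  at_vertex <- function(beta) {
    e <- ys - as.numeric(phi %*% beta)
    sum(abs(e) <= 1e-9 * max(abs(ys))) >= sum(beta > 0)
  }
  if (!at_vertex(beta) && any(beta > 0)) {
    beta <- beta_ip; r <- r_ip
    run_barrier(config$gamma_max * config$mult^2)
    beta <- refine_vertex(crossover(beta))
  }

  beta <- beta * yscale
  fit <- as.numeric(phi %*% beta)
  resid <- y - fit
  obj <- sum(abs(resid))
  # LP optimality proxy: dual feasibility of the smoothed sign vector.
  s <- resid / (abs(resid) + 1e-12 * yscale)
  g <- as.numeric(Matrix::crossprod(phi, s))
  kkt <- max(c(0, (abs(g[beta > 0]) - 1) / max(1, max(abs(g))),
               (g - 1) / max(1, max(abs(g)))))
  new_nn_fit(beta, obj, 1L, max(0, kkt), stages, converged,
             "nnlad_logbarrier", fit, resid, blocks)
}

#' @export
print.nn_fit <- function(x, ...) {
  cat(sprintf("<nn_fit: %s>\n", x$method))
  cat(sprintf("  n = %d, p = %d, positive coefficients = %d\n",
              length(x$fitted), length(x$beta), sum(x$beta > 0)))
  cat(sprintf("  objective (q = %d): %.6g | KKT residual: %.2e | stages: %d\n",
              x$q, x$objective, x$kkt_residual, x$stages))
  invisible(x)
}
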