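# Sparse REML engine for the saturated band-power mixed model
#
#   delta_p ~ cell(condition x ROI x band) + (1 | channel) + (1 | trial)
#
# with channel nested in ROI (and subject) and trial nested in dataset nested
# in subject. Because the fixed part is a cell-mean indicator matrix and both
# random terms are indicator matrices, the whole fit reduces to sparse
# cross-tabulations plus a small sparse Cholesky of Henderson's mixed-model
# equations. REML profiles the residual variance and optimizes the two
# variance ratios gamma = sigma_u^2 / sigma_e^2 numerically, using
#   -2 l_R = (n - p) (log sigma^2 + 1) + log|D| + log|C|   (+ const),
# where C is the MME coefficient matrix and D the random-effect covariance in
# residual-variance units. This reproduces the usual REML estimates (it is
# cross-checked against lme4 in the test suite) at a fraction of the cost,
# which is what makes 999-resample cluster bootstraps tractable.

# lowest admissible log variance ratio; at the bound the component is
# reported as a boundary (zero) estimate
.lme_log_gamma_bounds <- c(-13, 8)

# sparse indicator design [cells | channels | trials]
mme_design <- function(cell, chan, trial, p, qc, qt) {
  n <- length(cell)
  Matrix::sparseMatrix(
    i = rep(seq_len(n), 3L),
    j = c(cell, p + chan, p + qc + trial),
    x = 1, dims = c(n, p + qc + qt))
}

# solve Henderson's equations for fixed variance ratios; returns the full
# coefficient vector (cell means first) and the residual sum of squares
mme_solve <- function(AtA, Aty, yty, p, qc, qt, gamma_c, gamma_t) {
  dinv <- c(rep(0, p),
            rep(1 / max(gamma_c, 1e-12), qc),
            rep(1 / max(gamma_t, 1e-12), qt))
  C <- AtA + Matrix::Diagonal(x = dinv)
  ch <- Matrix::Cholesky(Matrix::forceSymmetric(C), LDL = FALSE, perm = TRUE)
  b <- Matrix::solve(ch, Aty)
  rss <- max(yty - sum(b * Aty), 0)
  list(b = as.numeric(b), rss = rss, chol = ch)
}

# -2 REML criterion (up to an additive constant) at log variance ratios
reml_criterion <- function(lg, AtA, Aty, yty, n, p, qc, qt) {
  gc <- exp(lg[1]); gt <- exp(lg[2])
  sol <- mme_solve(AtA, Aty, yty, p, qc, qt, gc, gt)
  s2 <- sol$rss / (n - p)
  ldC <- 2 * as.numeric(Matrix::determinant(sol$chol, sqrt = TRUE)$modulus)
  (n - p) * (log(s2) + 1) + qc * log(gc) + qt * log(gt) + ldC
}

# REML fit: optimize the two log variance ratios, then back out coefficients
reml_fit <- function(y, cell, chan, trial, p, qc, qt) {
  n <- length(y)
  if (n <= p) stop("mixed model not estimable: n <= number of cells")
  A <- mme_design(cell, chan, trial, p, qc, qt)
  AtA <- Matrix::crossprod(A)
  Aty <- as.numeric(Matrix::crossprod(A, y))
  yty <- sum(y * y)
  bounds <- .lme_log_gamma_bounds
  obj <- function(lg) reml_criterion(lg, AtA, Aty, yty, n, p, qc, qt)
  opt <- stats::optim(c(-1, -1), obj, method = "L-BFGS-B",
                      lower = bounds[1], upper = bounds[2],
                      control = list(factr = 1e9))
  if (opt$convergence != 0) {
    stop("REML optimization failed to converge: code ", opt$convergence,
         " (", opt$message, ")")
  }
  gamma_c <- exp(opt$par[1]); gamma_t <- exp(opt$par[2])
  boundary_c <- opt$par[1] <= bounds[1] + 1e-6
  boundary_t <- opt$par[2] <= bounds[1] + 1e-6
  sol <- mme_solve(AtA, Aty, yty, p, qc, qt, gamma_c, gamma_t)
  sigma2 <- sol$rss / (n - p)
  list(beta = sol$b[seq_len(p)],
       u_channel = sol$b[p + seq_len(qc)],
       u_trial = sol$b[p + qc + seq_len(qt)],
       sigma = sqrt(sigma2),
       sd_channel = if (boundary_c) 0 else sqrt(gamma_c * sigma2),
       sd_trial = if (boundary_t) 0 else sqrt(gamma_t * sigma2),
       gamma_c = if (boundary_c) 0 else gamma_c,
       gamma_t = if (boundary_t) 0 else gamma_t,
       boundary = c(channel = boundary_c, trial = boundary_t),
       m2reml = opt$value, optim = opt[c("convergence", "counts")],
       n = n, p = p, qc = qc, qt = qt)
}
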