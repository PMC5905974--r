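#' Fourier basis for a two-oscillator phase model
#'
#' The deterministic part of each phase equation is expanded as a constant
#' (the natural-frequency term) plus \eqn{\cos} and \eqn{\sin} of
#' \eqn{k_1\phi_1 + k_2\phi_2} for all integer index pairs with
#' \eqn{\max(|k_1|,|k_2|) \le K}, excluding \eqn{(0,0)} and keeping one
#' representative per \eqn{\pm(k_1,k_2)} pair. At the study order `K = 2`
#' this gives 25 parameters per phase equation (1 + 12 pairs x 2 trig
#' functions).
#'
#' @param K Fourier order (>= 1); default 2.
#' @return An object of class `fourier_basis`: tibble of terms (`k1`, `k2`,
#'   `func`) with `K` and the parameter count `M` as attributes. The first
#'   term is the constant.
#' @export
build_basis <- function(K = 2) {
  if (!is.numeric(K) || K < 1) {
    rlang::abort("`K` must be >= 1.", class = "cacoupling_invalid_parameter")
  }
  K <- as.integer(K)
  grid <- expand.grid(k1 = -K:K, k2 = -K:K)
  grid <- grid[!(grid$k1 == 0 & grid$k2 == 0), ]
  # one representative per +/- pair: k1 > 0, or k1 == 0 and k2 > 0
  grid <- grid[grid$k1 > 0 | (grid$k1 == 0 & grid$k2 > 0), ]
  grid <- grid[order(pmax(abs(grid$k1), abs(grid$k2)), grid$k1, grid$k2), ]
  terms <- tibble::tibble(
    k1 = c(0L, rep(grid$k1, each = 2)),
    k2 = c(0L, rep(grid$k2, each = 2)),
    func = c("const", rep(c("cos", "sin"), nrow(grid)))
  )
  structure(terms,
    class = c("fourier_basis", class(terms)),
    K = K, M = nrow(terms)
  )
}

# evaluate the design matrix and (optionally) its phase derivatives,
# computing each unique argument k1*ph1 + k2*ph2 and its trig pair once
basis_eval <- function(basis, ph1, ph2, derivs = TRUE) {
  L <- length(ph1)
  M <- nrow(basis)
  P <- matrix(1, L, M)
  V1 <- if (derivs) matrix(0, L, M) else NULL
  V2 <- if (derivs) matrix(0, L, M) else NULL
  m <- 2L
  while (m <= M) {
    k1 <- basis$k1[m]
    k2 <- basis$k2[m]
    arg <- k1 * ph1 + k2 * ph2
    ca <- cos(arg)
    sa <- sin(arg)
    P[, m] <- ca       # cos term
    P[, m + 1L] <- sa  # sin term
    if (derivs) {
      V1[, m] <- -k1 * sa
      V1[, m + 1L] <- k1 * ca
      V2[, m] <- -k2 * sa
      V2[, m + 1L] <- k2 * ca
    }
    m <- m + 2L
  }
  list(P = P, V1 = V1, V2 = V2)
}

basis_matrix <- function(basis, ph1, ph2) {
  basis_eval(basis, ph1, ph2, derivs = FALSE)$P
}

# shared per-window sufficient statistics
window_stats <- function(pair, basis) {
  h <- 1 / attr(pair, "fs")
  p1 <- pair$phase1
  p2 <- pair$phase2
  L <- length(p1) - 1L
  phidot <- cbind((p1[-1] - p1[-(L + 1)]) / h, (p2[-1] - p2[-(L + 1)]) / h)
  m1 <- (p1[-1] + p1[-(L + 1)]) / 2
  m2 <- (p2[-1] + p2[-(L + 1)]) / 2
  be <- basis_eval(basis, m1, m2, derivs = TRUE)
  list(
    h = h, L = L, phidot = phidot, P = be$P,
    Q = crossprod(be$P),
    Pd = crossprod(be$P, phidot), # M x 2
    vsum = cbind(colSums(be$V1), colSums(be$V2)) # M x 2
  )
}

#' Infer a two-oscillator phase model on one window
#'
#' Dynamical Bayesian inference of the parameters of the coupled stochastic
#' phase equations from an unwrapped phase pair. The phase derivative is the
#' forward difference \eqn{\dot\phi_l = (\phi_{l+1}-\phi_l)/h} and base
#' functions are evaluated at the midpoint phases. The stationary point of
#' the negative log-likelihood is found by alternating closed-form updates of
#' the noise matrix `D`, the concentration matrix `Xi`, the vector `Gamma`
#' and the parameters `c` until the relative change in `c` falls below `tol`.
#'
#' @param pair A [phase_pair()] (uniform sampling, unwrapped phases).
#' @param basis A [build_basis()] result.
#' @param prior `NULL` for a noninformative prior, or a `coupling_model`
#'   whose posterior becomes the prior (used by [infer_time_evolving()]).
#' @param tol Relative convergence tolerance on `c` (default 1e-6).
#' @param max_iter Iteration cap (default 100); non-convergence raises a
#'   warning and returns the last iterate.
#' @return An object of class `coupling_model`: list with `c` (M x 2 matrix,
#'   one column per phase equation), `Xi` (2M x 2M concentration), `D` (2 x 2
#'   noise), `basis`, `h`, `n_samples`, `iterations`, `converged`,
#'   `window_time` (start/end, s), `labels`.
#' @export
infer_window <- function(pair, basis = build_basis(2), prior = NULL,
                         tol = 1e-6, max_iter = 100) {
  st <- window_stats(pair, basis)
  M <- nrow(basis)
  if (st$L < 2 * M) {
    rlang::abort("Window too short for the basis size.",
      class = "cacoupling_insufficient_data")
  }
  if (is.null(prior)) {
    Xi_prior <- matrix(0, 2 * M, 2 * M)
    rho_prior <- rep(0, 2 * M) # Xi_prior %*% c_prior
  } else {
    Xi_prior <- prior$Xi_next %||% prior$Xi
    cp <- as.vector(prior$c)
    rho_prior <- Xi_prior %*% cp
  }
  fit <- dbi_recursion(st, Xi_prior, rho_prior, tol, max_iter)
  if (!fit$converged) {
    rlang::warn("DBI recursion did not converge; returning last iterate.")
  }
  if (fit$regularized) {
    rlang::inform("Near-singular concentration matrix; ridge regularization applied.")
  }
  structure(
    list(
      c = matrix(fit$c, ncol = 2), Xi = fit$Xi, D = fit$D,
      basis = basis, h = st$h, n_samples = st$L,
      iterations = fit$iterations, converged = fit$converged,
      regularized = fit$regularized,
      window_time = range(pair$time), labels = attr(pair, "labels")
    ),
    class = "coupling_model"
  )
}

# linear solve with a conditioning guard: under-determined windows (slow
# bands, phase-locked pairs) leave near-null directions in the concentration
# matrix; a plain solve then returns numerically huge, meaningless
# components. When the condition number is poor the system is solved by
# truncated SVD, which zeroes the unidentifiable directions (minimum-norm
# solution on the determined subspace).
solve_reg <- function(A, b, rcond_min = 1e-4, sv_cut = 1e-4) {
  rc <- tryCatch(rcond(A), error = function(e) 0)
  if (is.finite(rc) && rc > rcond_min) {
    out <- tryCatch(solve(A, b), error = function(e) NULL)
    if (!is.null(out) && all(is.finite(out))) {
      return(list(x = out, ridge = 0))
    }
  }
  sv <- svd(A)
  keep <- sv$d > sv_cut * sv$d[1]
  x <- sv$v[, keep, drop = FALSE] %*%
    ((t(sv$u[, keep, drop = FALSE]) %*% b) / sv$d[keep])
  list(x = x, ridge = 1)
}

# core alternating recursion on precomputed window statistics
dbi_recursion <- function(st, Xi_prior, rho_prior, tol = 1e-6, max_iter = 100) {
  M <- ncol(st$P)
  h <- st$h
  L <- st$L
  # initial c: per-equation least squares with a tiny ridge
  ridge <- diag(1e-8 * max(diag(st$Q)), M)
  C <- solve_reg(st$Q + ridge, st$Pd)$x
  converged <- FALSE
  iters <- 0L
  Xi <- NULL
  D <- NULL
  regularized <- FALSE
  C_prev <- C
  for (it in seq_len(max_iter)) {
    iters <- it
    r <- st$phidot - st$P %*% C
    D <- (h / L) * crossprod(r)
    if (!all(is.finite(D))) { # numerical blow-up: keep the last sane iterate
      C <- C_prev
      regularized <- TRUE
      break
    }
    # guard against singular D in the noise-free exact-model limit
    eps <- 1e-12 * max(1, max(abs(D)))
    if (min(eigen(D, symmetric = TRUE, only.values = TRUE)$values) < eps) {
      D <- D + diag(eps, 2)
    }
    Dinv <- solve(D)
    Xi <- Xi_prior + h * kronecker(Dinv, st$Q)
    Gam <- as.vector(rho_prior) +
      as.vector(h * st$Pd %*% Dinv) - (h / 2) * as.vector(st$vsum)
    sol <- solve_reg(Xi, Gam)
    c_new <- as.vector(sol$x)
    if (sol$ridge > 0) regularized <- TRUE
    if (!all(is.finite(c_new))) {
      regularized <- TRUE
      break
    }
    dc <- max(abs(c_new - as.vector(C))) / max(1, max(abs(c_new)))
    C_prev <- C
    C <- matrix(c_new, ncol = 2)
    if (dc < tol) {
      converged <- TRUE
      break
    }
  }
  if (is.null(Xi) || !all(is.finite(Xi))) Xi <- diag(1, 2 * M)
  if (is.null(D) || !all(is.finite(D))) D <- diag(1e-6, 2)
  list(c = as.vector(C), Xi = Xi, D = D, converged = converged,
       iterations = iters, regularized = regularized)
}

#' @export
print.coupling_model <- function(x, ...) {
  cat(sprintf(
    "<coupling_model> K=%d (%d params/eq), %d samples, h=%g s, %s in %d iterations\n",
    attr(x$basis, "K"), nrow(x$basis), x$n_samples, x$h,
    if (x$converged) "converged" else "NOT converged", x$iterations
  ))
  cat(sprintf("  noise D: [%.3g %.3g; %.3g %.3g]\n", x$D[1, 1], x$D[1, 2],
              x$D[2, 1], x$D[2, 2]))
  invisible(x)
}

#' Direct minimization of the windowed negative log-likelihood
#'
#' Independent cross-check for [infer_window()]: for fixed parameters `c` the
#' optimal noise matrix is the closed-form residual covariance, and
#' substituting it reduces the quadratic term to a constant, leaving the
#' profiled objective \eqn{S^*(c) = (L/2)\log|D(c)| + L + (h/2)\sum_l c\cdot
#' \partial\Phi/\partial\phi}. That objective is minimized with a
#' general-purpose quasi-Newton optimizer (BFGS, analytic gradient), an
#' entirely different route to the same stationary point as the recursion.
#'
#' @inheritParams infer_window
#' @param reltol Optimizer relative tolerance.
#' @return M x 2 matrix of parameters (columns = phase equations).
#' @export
infer_window_direct <- function(pair, basis = build_basis(2), reltol = 1e-14) {
  st <- window_stats(pair, basis)
  M <- ncol(st$P)
  h <- st$h
  L <- st$L
  obj <- function(cv) {
    C <- matrix(cv, ncol = 2)
    r <- st$phidot - st$P %*% C
    D <- (h / L) * crossprod(r)
    dt <- det(D)
    if (dt <= 0) return(1e12)
    (L / 2) * log(dt) + L + (h / 2) * sum(C * st$vsum)
  }
  grad <- function(cv) {
    C <- matrix(cv, ncol = 2)
    r <- st$phidot - st$P %*% C
    D <- (h / L) * crossprod(r)
    Dinv <- solve(D)
    # d/dC of (L/2) log|D(C)| = -h * P'(r Dinv)
    G <- -h * crossprod(st$P, r %*% Dinv) + (h / 2) * st$vsum
    as.vector(G)
  }
  ridge <- diag(1e-8 * max(diag(st$Q)), M)
  c0 <- as.vector(solve(st$Q + ridge, st$Pd))
  fit <- stats::optim(c0, obj, grad,
    method = "BFGS",
    control = list(maxit = 5000, reltol = reltol)
  )
  # polish
  fit <- stats::optim(fit$par, obj, grad,
    method = "BFGS",
    control = list(maxit = 5000, reltol = reltol)
  )
  matrix(fit$par, ncol = 2)
}

#' Time-evolving inference over sequential windows
#'
#' Splits the record into consecutive windows and runs [infer_window()] on
#' each, propagating each posterior as the next window's prior with its
#' covariance inflated by a diffusion term: the prior covariance diagonal is
#' increased by `propagation^2` times the posterior parameter variances,
#' which lets the parameters drift between windows.
#'
#' @inheritParams infer_window
#' @param window Window length in seconds (default 50).
#' @param propagation Dimensionless diffusion factor (>= 0, default 0.2);
#'   `0` freezes the prior into plain sequential accumulation.
#' @return A list of `coupling_model` objects (class `coupling_models`).
#' @export
infer_time_evolving <- function(pair, basis = build_basis(2), window = 50,
                                propagation = 0.2, tol = 1e-6, max_iter = 100) {
  if (propagation < 0) {
    rlang::abort("`propagation` must be >= 0.", class = "cacoupling_invalid_parameter")
  }
  fs <- attr(pair, "fs")
  wlen <- round(window * fs)
  n <- nrow(pair)
  n_win <- floor(n / wlen)
  if (n_win < 2) {
    rlang::abort("Record must span at least 2 windows.",
      class = "cacoupling_insufficient_data")
  }
  prior <- NULL
  out <- vector("list", n_win)
  for (k in seq_len(n_win)) {
    idx <- ((k - 1) * wlen + 1):(k * wlen)
    sub <- phase_pair(pair$phase1[idx], pair$phase2[idx],
      fs = fs, labels = attr(pair, "labels")
    )
    m <- infer_window(sub, basis, prior = prior, tol = tol, max_iter = max_iter)
    m$window_time <- range(pair$time[idx])
    # diffuse the posterior for the next window: inflate covariance
    # diagonally, Sigma_prior = Sigma_post + (propagation * c)^2 on the diagonal
    Sig <- solve_reg(m$Xi, diag(nrow(m$Xi)))$x
    infl <- diag(Sig) + (propagation * as.vector(m$c))^2
    Sig <- Sig + diag(pmax(infl - diag(Sig), 0), nrow(Sig))
    m$Xi_next <- solve_reg(Sig, diag(nrow(Sig)))$x
    prior <- m
    out[[k]] <- m
  }
  structure(out, class = "coupling_models")
}

#' Evaluate the reconstructed coupling function on a phase grid
#'
#' The coupling function `q` of one phase equation (all non-constant basis
#' terms) is evaluated on an `n` x `n` mesh over `[0, 2pi)^2`. By
#' construction the surface is 2pi-periodic in both arguments.
#'
#' @param model A `coupling_model`, or a `coupling_models` list (parameters
#'   are averaged over windows first).
#' @param direction `"1->2"` (surface of the oscillator-2 equation, e.g.
#'   MAP -> HbO2) or `"2->1"`.
#' @param n Grid size per axis (default 100).
#' @return An object of class `coupling_surface`: list with `q` (n x n matrix,
#'   rows = target phase, columns = source phase), `phi_target`, `phi_source`,
#'   `direction`, `labels`.
#' @export
evaluate_surface <- function(model, direction = "1->2", n = 100) {
  if (inherits(model, "coupling_models")) model <- average_models(model)
  eq <- if (direction == "1->2") 2L else 1L
  basis <- model$basis
  cc <- model$c[, eq]
  grid <- seq(0, 2 * pi, length.out = n + 1)[seq_len(n)]
  # rows: target phase, cols: source phase
  tgt <- if (eq == 2L) "k2" else "k1"
  src <- if (eq == 2L) "k1" else "k2"
  q <- matrix(0, n, n)
  for (m in seq_len(nrow(basis))) {
    if (basis$func[m] == "const") next
    arg <- outer(basis[[tgt]][m] * grid, basis[[src]][m] * grid, `+`)
    q <- q + cc[m] * if (basis$func[m] == "cos") cos(arg) else sin(arg)
  }
  structure(
    list(
      q = q, phi_target = grid, phi_source = grid,
      direction = direction, labels = model$labels
    ),
    class = "coupling_surface"
  )
}

# average parameters over windows (element-wise mean of c; D likewise)
average_models <- function(models) {
  stopifnot(length(models) >= 1)
  out <- models[[1]]
  out$c <- Reduce(`+`, purrr::map(models, "c")) / length(models)
  out$D <- Reduce(`+`, purrr::map(models, "D")) / length(models)
  out$window_time <- range(purrr::map(models, "window_time"))
  out
}

#' Element-wise mean of coupling surfaces
#'
#' Region and group averaging of reconstructed coupling functions.
#'
#' @param surfaces List of `coupling_surface` objects on identical grids.
#' @return A `coupling_surface` whose `q` is the element-wise mean.
#' @export
average_surfaces <- function(surfaces) {
  stopifnot(length(surfaces) >= 1)
  ns <- vapply(surfaces, function(s) nrow(s$q), integer(1))
  if (length(unique(ns)) != 1L) {
    rlang::abort("Surfaces must share one grid size.",
      class = "cacoupling_invalid_parameter")
  }
  out <- surfaces[[1]]
  out$q <- Reduce(`+`, purrr::map(surfaces, "q")) / length(surfaces)
  out
}

#' Directional coupling strength
#'
#' The coupling strength (CS) is the Euclidean norm of the inferred
#' parameters, in the target oscillator's phase equation, whose basis index
#' has nonzero order on the source oscillator (cross terms included; the
#' constant and pure self terms are excluded by default). For a
#' `coupling_models` list the per-window CS values are averaged.
#'
#' @param model A `coupling_model` or `coupling_models`.
#' @param direction `"1->2"` or `"2->1"` (source -> target).
#' @param include_self Include source-independent (self) terms in the norm
#'   (default `FALSE`).
#' @param burn_in Number of leading windows to exclude from the average for
#'   time-evolving models (default 0). The first window is fitted without an
#'   informative prior, so its estimate is a transient; the pipeline treats
#'   it as burn-in. Ignored when too few windows would remain.
#' @return A one-row tibble: `direction`, `sigma`, `n_windows`.
#' @export
coupling_strength <- function(model, direction = "1->2", include_self = FALSE,
                              burn_in = 0) {
  models <- if (inherits(model, "coupling_models")) model else list(model)
  if (burn_in > 0 && length(models) > burn_in + 1) {
    models <- models[-seq_len(burn_in)]
  }
  basis <- models[[1]]$basis
  eq <- if (direction == "1->2") 2L else 1L
  k_src <- if (eq == 2L) basis$k1 else basis$k2
  sel <- if (include_self) basis$func != "const" else k_src != 0L
  sig <- vapply(models, function(m) sqrt(sum(m$c[sel, eq]^2)), numeric(1))
  tibble::tibble(
    direction = direction, sigma = mean(sig), n_windows = length(models)
  )
}
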