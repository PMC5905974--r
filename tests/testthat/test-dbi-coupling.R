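# build a minimal coupling_model by hand for closed-form checks
manual_model <- function(coef_tbl, K = 2) {
  basis <- build_basis(K)
  cc <- matrix(0, nrow(basis), 2)
  for (i in seq_len(nrow(coef_tbl))) {
    m <- which(basis$k1 == coef_tbl$k1[i] & basis$k2 == coef_tbl$k2[i] &
                 basis$func == coef_tbl$func[i])
    cc[m, coef_tbl$eq[i]] <- coef_tbl$value[i]
  }
  structure(
    list(c = cc, Xi = diag(2 * nrow(basis)), D = diag(2) * 1e-4, basis = basis,
         h = 0.1, n_samples = 100, iterations = 1, converged = TRUE,
         regularized = FALSE, window_time = c(0, 10),
         labels = c("map", "hbo2")),
    class = "coupling_model"
  )
}

test_that("the Fourier basis has the right size and evaluation identities", {
  b2 <- build_basis(2)
  expect_equal(nrow(b2), 25)
  b1 <- build_basis(1)
  expect_equal(nrow(b1), 9)
  expect_error(build_basis(0), class = "cacoupling_invalid_parameter")
  # at phi1 = phi2 = 0 all cos terms are 1 and all sin terms 0
  P <- cacoupling:::basis_matrix(b2, 0, 0)
  expect_equal(as.vector(P[, b2$func != "sin"]), rep(1, 13))
  expect_equal(as.vector(P[, b2$func == "sin"]), rep(0, 12))
  # constant present exactly once, (0,0) excluded from trig terms
  expect_equal(sum(b2$func == "const"), 1)
  expect_false(any(b2$k1 == 0 & b2$k2 == 0 & b2$func != "const"))
})

test_that("a noise-free uncoupled pair yields a null model", {
  pp <- simulate_phase_pair(oscillator_spec(0.12), oscillator_spec(0.07),
                            duration = 120, dt = 0.01, seed = 1, fs_out = 10)
  m <- quiet_infer(pp)
  nonconst <- m$basis$func != "const"
  expect_lt(max(abs(m$c[nonconst, ])), 1e-3)
  expect_lt(max(abs(m$D)), 1e-6)
  expect_equal(m$c[1, 1], 2 * pi * 0.12, tolerance = 1e-4)
  expect_equal(m$c[1, 2], 2 * pi * 0.07, tolerance = 1e-4)
})

test_that("the recursion matches direct likelihood minimization", {
  pp <- validation_pair(a = 0.3, seed = 3)
  sub <- phase_pair(pp$phase1[1:200], pp$phase2[1:200], fs = 10)
  m <- quiet_infer(sub)
  direct <- infer_window_direct(sub)
  expect_lt(max(abs(m$c - direct)), 1e-5)
})

test_that("an injected sin coupling coefficient is recovered", {
  est <- sapply(1:5, function(sd) {
    m <- quiet_infer(validation_pair(a = 0.3, seed = sd))
    td <- tidy(m)
    td$estimate[td$equation == 2 & td$k1 == 1 & td$k2 == -1 & td$func == "sin"]
  })
  expect_lt(abs(mean(est) - 0.3), 0.05)
  m1 <- quiet_infer(validation_pair(a = 0.3, seed = 1))
  expect_lt(abs(tidy(m1)$estimate[tidy(m1)$equation == 2 &
                                    tidy(m1)$func == "const"][1] - 2 * pi * 0.1),
            0.02)
})

test_that("time-evolving inference tracks a mid-record coupling step", {
  # piecewise simulation: coupling switched on half-way (constructed fixture)
  set.seed(42)
  fs <- 10; dt <- 0.1; n <- 6000
  w1 <- 2 * pi * 0.25; w2 <- 2 * pi * 0.1
  a_t <- rep(c(0, 0.4), each = n / 2)
  e1 <- stats::rnorm(n - 1, 0, sqrt(2 * 0.01 * dt))
  e2 <- stats::rnorm(n - 1, 0, sqrt(2 * 0.01 * dt))
  p1 <- p2 <- numeric(n)
  for (l in seq_len(n - 1)) {
    p1[l + 1] <- p1[l] + w1 * dt + e1[l]
    p2[l + 1] <- p2[l] + (w2 + a_t[l] * sin(p1[l] - p2[l])) * dt + e2[l]
  }
  pp <- phase_pair(p1, p2, fs = fs)
  models <- suppressMessages(suppressWarnings(
    infer_time_evolving(pp, window = 50, propagation = 0.2)
  ))
  cs_w <- sapply(models, function(m) coupling_strength(m, "1->2")$sigma)
  # coupling switches on at window 7; estimates must cross a = 0.2 by
  # window 9 (within two windows of the step)
  expect_lt(mean(cs_w[1:4]), 0.2)
  crossed <- which(cs_w > 0.2)
  crossed <- crossed[crossed >= 7]
  expect_lte(min(crossed), 9)
  expect_gt(mean(cs_w[10:12]), 0.2)
})

test_that("zero propagation approaches batch inference on stationary data", {
  pp <- validation_pair(a = 0.3, seed = 5, duration = 400)
  batch <- quiet_infer(pp)
  seq0 <- suppressMessages(suppressWarnings(
    infer_time_evolving(pp, window = 100, propagation = 0)
  ))
  final <- seq0[[length(seq0)]]
  expect_lt(max(abs(final$c - batch$c)), 1e-3 * max(1, max(abs(batch$c))))
})

test_that("window-to-window scatter grows with the propagation constant", {
  pp <- validation_pair(a = 0.3, seed = 6)
  sd_of <- function(prop) {
    ms <- suppressMessages(suppressWarnings(
      infer_time_evolving(pp, window = 50, propagation = prop)
    ))
    stats::sd(sapply(ms, function(m) coupling_strength(m, "1->2")$sigma))
  }
  expect_lt(sd_of(0), sd_of(1))
})

test_that("coupling surfaces follow closed forms, periodicity and averaging", {
  m <- manual_model(tibble::tibble(k1 = 1, k2 = -1, func = "sin",
                                   eq = 2, value = 0.3))
  s <- evaluate_surface(m, "1->2", n = 100)
  expect_equal(max(s$q), 0.3, tolerance = 1e-9)
  expect_equal(min(s$q), -0.3, tolerance = 1e-9)
  expect_lt(abs(mean(s$q)), 1e-12)
  # q(phi_t, phi_s) = 0.3 sin(phi_s - phi_t); check a grid point
  expect_equal(s$q[1, 26], 0.3 * sin(s$phi_source[26]), tolerance = 1e-9)
  # periodicity: evaluating the basis at phi and phi + 2*pi is identical
  P0 <- cacoupling:::basis_matrix(m$basis, 0.7, 1.3)
  P1 <- cacoupling:::basis_matrix(m$basis, 0.7 + 2 * pi, 1.3 + 2 * pi)
  expect_equal(P0, P1, tolerance = 1e-12)
  expect_equal(average_surfaces(list(s, s))$q, s$q)
})

test_that("coupling strength is the norm of source-dependent coefficients", {
  m <- manual_model(tibble::tibble(
    k1 = c(1, 2), k2 = c(-1, 0), func = c("sin", "cos"),
    eq = c(2, 2), value = c(3, 4)
  ))
  expect_equal(coupling_strength(m, "1->2")$sigma, 5)
  expect_equal(coupling_strength(m, "2->1")$sigma, 0)
  m0 <- manual_model(tibble::tibble(k1 = integer(), k2 = integer(),
                                    func = character(), eq = integer(),
                                    value = numeric()))
  expect_equal(coupling_strength(m0, "1->2")$sigma, 0)
  # self terms excluded by default, included on request
  ms <- manual_model(tibble::tibble(k1 = c(1, 0), k2 = c(-1, 1),
                                    func = c("sin", "sin"), eq = c(2, 2),
                                    value = c(3, 4)))
  expect_equal(coupling_strength(ms, "1->2")$sigma, 3)
  expect_equal(coupling_strength(ms, "1->2", include_self = TRUE)$sigma, 5)
})

test_that("CS is invariant to 2*pi offsets and monotone in coupling", {
  pp <- validation_pair(a = 0.3, seed = 7, duration = 300)
  base <- coupling_strength(quiet_infer(pp), "1->2")$sigma
  shifted <- phase_pair(pp$phase1 + 2 * pi, pp$phase2 - 4 * pi, fs = 10)
  expect_lt(abs(coupling_strength(quiet_infer(shifted), "1->2")$sigma - base),
            1e-6)
  cs_a <- sapply(c(0.1, 0.2, 0.4), function(a) {
    mean(sapply(1:3, function(sd) {
      coupling_strength(quiet_infer(validation_pair(a = a, seed = sd)),
                        "1->2")$sigma
    }))
  })
  expect_true(all(diff(cs_a) > 0))
  expect_true(all(cs_a >= 0))
})
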