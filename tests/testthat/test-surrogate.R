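# a stable linear discrete-time system in the package's 6-channel state
# layout, with a closed-form step response, as an independent reference
linear_toy <- function() {
  A <- diag(c(0.98, 0.97, 0.96, 0.9, 0.88, 0.86))
  A[1, 4] <- 0.01; A[2, 5] <- 0.01; A[3, 6] <- 0.01
  B <- matrix(0, 6, 6); diag(B) <- c(0.001, 0.001, 0.001, 0.02, 0.02, 0.02)
  list(A = A, B = B,
       run = function(u) {
         x <- matrix(0, nrow(u) + 1, 6)
         for (t in seq_len(nrow(u)))
           x[t + 1, ] <- drop(A %*% x[t, ] + B %*% u[t, ])
         x
       })
}

toy_dataset <- function(n = 4000, seed = 1) {
  toy <- linear_toy()
  set.seed(seed)
  u <- matrix(0, n, 6)
  for (i in 1:6) {
    lev <- runif(1, -1, 1); t <- 0
    while (t < n) {
      hold <- 20 + rgeom(1, 1 / 40)
      u[(t + 1):min(n, t + hold), i] <- lev
      lev <- runif(1, -1, 1)
      t <- t + hold
    }
  }
  structure(list(u = u, x = toy$run(u), train = 1:floor(0.8 * n),
                 validation = (floor(0.8 * n) + 1):n),
            class = "surrogate_dataset")
}

test_that("PRBS signals are binary, hold as configured, and have a flat band", {
  prbs <- generate_prbs(n_ms = 6e5, seed = 3)
  for (i in 1:6) expect_length(unique(prbs[i, ]), 2L)
  x <- prbs[1, ]
  sw <- which(diff(x) != 0)
  expect_gt(length(sw), 9000)           # ~1e4 switches at the 60 ms mean hold
  expect_lt(abs(mean(diff(sw)) - 60) / 60, 0.1)
  # averaged periodogram: flat within +-3 dB of the band mean below half the
  # mean switch rate
  seg <- 4096; nseg <- floor(length(x) / seg)
  ps <- 0
  for (j in seq_len(nseg)) {
    v <- x[((j - 1) * seg + 1):(j * seg)]
    ps <- ps + Mod(fft(v - mean(v)))^2
  }
  f_hz <- (0:(seg - 1)) / seg * 1000
  half_rate_hz <- 1000 / mean(diff(sw)) / 2
  band <- ps[f_hz > 0 & f_hz <= half_rate_hz]
  db <- 10 * log10(band / mean(band))
  expect_lt(max(abs(db)), 3)
})

test_that("PRBS generation is seed-reproducible", {
  expect_identical(unclass(generate_prbs(5000, seed = 9)),
                   unclass(generate_prbs(5000, seed = 9)))
  expect_false(identical(unclass(generate_prbs(5000, seed = 9)),
                         unclass(generate_prbs(5000, seed = 10))))
})

test_that("identification datasets keep exact input/state alignment", {
  p <- default_plant()
  prbs <- generate_prbs(n_ms = 3000, seed = 4)
  ds <- build_dataset(p, prbs)
  expect_equal(dim(ds$u), c(3000, 6))
  expect_equal(dim(ds$x), c(3001, 6))
  expect_equal(max(ds$train) + 1L, min(ds$validation))
  expect_true(all(is.finite(ds$x)))
  # same excitation, same plant -> identical dataset
  ds2 <- build_dataset(p, generate_prbs(n_ms = 3000, seed = 4))
  expect_identical(ds, ds2)
  # the recorded pairs really are the plant's one-step transitions
  tr <- simulate_plant(p, unclass(prbs), eye_state())
  expect_equal(unname(ds$x[100, ]),
               unname(unlist(tr[100, c("rx","ry","rz","wx","wy","wz")])))
})

test_that("the surrogate reproduces a linear toy's step response to <1% NRMSE", {
  ds <- toy_dataset()
  m <- train_surrogate(ds, seed = 1)
  expect_true(all(m$nrmse < 0.01))
  # closed-form step response as the oracle (600 steps: the slowest mode,
  # eigenvalue 0.98, has decayed to ~5e-6 of its initial weight)
  toy <- linear_toy()
  u0 <- c(0.5, -0.3, 0.2, 0, 0, 0)
  u <- matrix(u0, 600, 6, byrow = TRUE)
  x_true <- toy$run(u)
  pred <- surrogate_rollout(m, u)
  x_ss <- drop(solve(diag(6) - toy$A, toy$B %*% u0))
  expect_equal(x_true[601, ], x_ss, tolerance = 1e-3)   # oracle self-check
  span <- apply(x_true, 2, function(z) max(abs(z), 1e-9))
  expect_lt(max(abs(pred[601, ] - x_true[601, ]) / span), 0.01)
})

test_that("the 6-DOF plant surrogate reaches <5% held-out closed-loop NRMSE", {
  p <- default_plant()
  ds <- cached("surr_ds", build_dataset(p, generate_prbs(n_ms = 2e4, seed = 5)))
  m <- cached("surr_model", train_surrogate(ds, subsample = 8000, seed = 2))
  expect_true(all(m$nrmse < 0.05))
  # training is seed-reproducible
  m2 <- train_surrogate(ds, subsample = 8000, seed = 2)
  expect_identical(m$net$coefficients, m2$net$coefficients)
})

test_that("zero-input rollout from equilibrium stays at equilibrium", {
  p <- default_plant()
  ds <- cached("surr_ds", build_dataset(p, generate_prbs(n_ms = 2e4, seed = 5)))
  m <- cached("surr_model", train_surrogate(ds, subsample = 8000, seed = 2))
  pred <- surrogate_rollout(m, matrix(0, 150, 6))
  expect_lt(max(abs(pred[, 1:3])), 5e-3)    # orientation stays within ~0.6 deg
})

test_that("optimizing against the surrogate then replaying on the plant lands close", {
  p <- default_plant()
  ds <- cached("surr_ds", build_dataset(p, generate_prbs(n_ms = 2e4, seed = 5)))
  m <- cached("surr_model", train_surrogate(ds, subsample = 8000, seed = 2))
  g <- saccade_goal(0, -tan(5 * pi / 180))     # 10 deg rightward
  fs <- optimize_for_duration(p, g, eye_state(), D_ms = 70, surrogate = m)
  fp <- optimize_for_duration(p, g, eye_state(), D_ms = 70)
  expect_lt(abs(fs$endpoint_error_deg - fp$endpoint_error_deg), 1)
})
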