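#' Pseudo-random binary step excitation
#'
#' Generates a PRBS command signal for system identification: each muscle
#' independently switches between two command levels at exponentially
#' distributed hold times, giving a broadband (white-at-low-frequency)
#' spectrum that covers a broad workspace. Seeded and reproducible.
#'
#' @param n_ms total length (ms). The identification-scale default is 2e5 ms;
#'   tests use shorter signals.
#' @param levels length-2 command levels (mm, relative to the holding
#'   command), or a 6 x 2 matrix of per-muscle levels.
#' @param hold_mean_ms mean hold time between switches (ms).
#' @param hold_min_ms minimum hold time (ms).
#' @param seed integer seed.
#' @return 6 x `n_ms` command matrix of class `prbs_signal` with the
#'   configuration stored as attributes.
#' @export
generate_prbs <- function(n_ms = 2e5, levels = c(-1.5, 1.5),
                          hold_mean_ms = 60, hold_min_ms = 10, seed = 1) {
  if (!is.matrix(levels)) levels <- matrix(levels, 6, 2, byrow = TRUE)
  stopifnot(nrow(levels) == 6, ncol(levels) == 2, hold_mean_ms > hold_min_ms)
  set.seed(seed)
  u <- matrix(0, 6, n_ms)
  for (i in 1:6) {
    t <- 0L
    lev <- sample(1:2, 1)
    while (t < n_ms) {
      hold <- hold_min_ms + round(rexp(1, 1 / (hold_mean_ms - hold_min_ms)))
      idx <- (t + 1):min(n_ms, t + hold)
      u[i, idx] <- levels[i, lev]
      lev <- 3L - lev
      t <- t + hold
    }
  }
  structure(u, class = c("prbs_signal", "matrix"),
            levels = levels, hold_mean_ms = hold_mean_ms,
            hold_min_ms = hold_min_ms, seed = seed)
}

#' Paired input-state identification data set
#'
#' Passes an excitation signal through the plant and returns aligned
#' `(u(t), x(t)) -> x(t+1)` pairs at 1 ms, split into contiguous training
#' and validation blocks.
#'
#' @param plant an [eye_plant()].
#' @param prbs 6 x T excitation matrix (see [generate_prbs()]).
#' @param val_frac fraction of the record (final contiguous block) held out
#'   for validation.
#' @return list of class `surrogate_dataset` with matrices `u` (T x 6),
#'   `x` (T+1 x 6 state samples: rx ry rz wx wy wz), and the row index
#'   `train`/`validation` split.
#' @export
build_dataset <- function(plant, prbs, val_frac = 0.2) {
  traj <- simulate_plant(plant, unclass(prbs), eye_state())
  x <- as.matrix(traj[, c("rx", "ry", "rz", "wx", "wy", "wz")])
  u <- t(unclass(prbs))
  n <- nrow(u)
  n_train <- floor(n * (1 - val_frac))
  structure(list(u = u, x = x, train = seq_len(n_train),
                 validation = seq.int(n_train + 1L, n)),
            class = "surrogate_dataset")
}

lag_design <- function(u, x, in_taps, out_taps, rows) {
  maxlag <- max(in_taps, out_taps)
  rows <- rows[rows > maxlag & rows < nrow(u)]
  X <- cbind(
    do.call(cbind, lapply(seq_len(out_taps) - 1L, function(l) x[rows - l, , drop = FALSE])),
    do.call(cbind, lapply(seq_len(in_taps) - 1L, function(l) u[rows - l, , drop = FALSE])))
  Y <- x[rows + 1L, , drop = FALSE] - x[rows, , drop = FALSE]
  list(X = X, Y = Y, rows = rows)
}

#' Train a recurrent input-output surrogate of the plant
#'
#' Identifies a NARX-style one-step model: the state increment
#' `x(t+1) - x(t)` is regressed on delay taps of the state and the command
#' (teacher forcing), either linearly in the taps (the default, which is
#' accurate and stable in closed loop on this plant) or through a
#' single-hidden-layer network (`hidden > 0`). Inputs and outputs are
#' z-scored; closed-loop behaviour comes from feeding the model's own
#' predictions back during [surrogate_rollout()]. Accuracy is reported as
#' closed-loop normalized RMSE per state channel on the held-out block;
#' training is considered failed if that rollout diverges.
#'
#' @param dataset a [build_dataset()] result.
#' @param in_taps,out_taps number of input / output delay taps.
#' @param hidden hidden-layer width (0 for a purely linear model).
#' @param maxit optimizer iterations for the network fit.
#' @param subsample cap on the number of training rows (rows are thinned
#'   evenly; keeps the fit tractable on long records).
#' @param seed seed for the weight initialization.
#' @return object of class `eye_surrogate` with the fitted network,
#'   normalization constants and held-out closed-loop `nrmse` (per channel).
#' @export
train_surrogate <- function(dataset, in_taps = 2, out_taps = 2, hidden = 0,
                            maxit = 400, subsample = 20000, seed = 1) {
  d <- lag_design(dataset$u, dataset$x, in_taps, out_taps, dataset$train)
  keep <- if (length(d$rows) > subsample)
    round(seq(1, length(d$rows), length.out = subsample)) else seq_along(d$rows)
  X <- d$X[keep, , drop = FALSE]; Y <- d$Y[keep, , drop = FALSE]
  mu_x <- colMeans(X); sd_x <- pmax(apply(X, 2, sd), 1e-12)
  mu_y <- colMeans(Y); sd_y <- pmax(apply(Y, 2, sd), 1e-12)
  Xs <- sweep(sweep(X, 2, mu_x), 2, sd_x, "/")
  Ys <- sweep(sweep(Y, 2, mu_y), 2, sd_y, "/")
  set.seed(seed)
  if (hidden > 0) {
    net <- nnet::nnet(Xs, Ys, size = hidden, linout = TRUE, trace = FALSE,
                      maxit = maxit, MaxNWts = 100000, decay = 1e-5)
  } else {
    net <- lm.fit(cbind(1, Xs), Ys)
    # exactly collinear taps (e.g. a perfectly linear plant) leave aliased
    # columns NA; zero keeps the fitted map and a finite rollout
    net$coefficients[is.na(net$coefficients)] <- 0
  }
  model <- structure(list(net = net, hidden = hidden,
                          in_taps = in_taps, out_taps = out_taps,
                          mu_x = mu_x, sd_x = sd_x, mu_y = mu_y, sd_y = sd_y),
                     class = "eye_surrogate")
  val <- dataset$validation
  u_val <- dataset$u[val, , drop = FALSE]
  x_val <- dataset$x[c(val, max(val) + 1L), , drop = FALSE]
  m <- max(in_taps, out_taps) + 1L       # rollout start (local state index)
  pred <- surrogate_rollout(model, u_val[m:nrow(u_val), , drop = FALSE],
                            x0_hist = x_val[(m - out_taps + 1L):m, , drop = FALSE],
                            u_hist = u_val[(m - in_taps):(m - 1L), , drop = FALSE])
  if (any(!is.finite(pred)))
    stop("surrogate rollout diverged on held-out data; training failed", call. = FALSE)
  actual <- x_val[m:(m + nrow(pred) - 1L), , drop = FALSE]
  span <- pmax(apply(x_val, 2, function(z) diff(range(z))), 1e-12)
  nr <- sqrt(colMeans((pred - actual)^2)) / span
  model$nrmse <- setNames(nr, c("rx", "ry", "rz", "wx", "wy", "wz"))
  model
}

predict_step <- function(model, feats) {
  fs <- (feats - model$mu_x) / model$sd_x
  ys <- if (model$hidden > 0) as.numeric(predict(model$net, matrix(fs, 1)))
        else as.numeric(c(1, fs) %*% model$net$coefficients)
  ys * model$sd_y + model$mu_y
}

#' Closed-loop rollout of a surrogate model
#'
#' Iterates the one-step model under its own state feedback: from the
#' initial state history, each predicted state is fed back as input for the
#' next step (no access to the true plant).
#'
#' @param model a [train_surrogate()] result.
#' @param controls T x 6 command matrix (or 6 x T, transposed automatically):
#'   the commands applied from the rollout start onwards.
#' @param x0_hist `out_taps` x 6 matrix of initial states, oldest row first;
#'   the last row is the rollout starting state.
#' @param u_hist `in_taps` x 6 matrix of commands preceding the rollout
#'   (oldest first, last row = command one step before the start).
#' @return predicted state matrix, (T+1) x 6; row 1 is the starting state.
#' @export
surrogate_rollout <- function(model, controls,
                              x0_hist = matrix(0, model$out_taps, 6),
                              u_hist = matrix(0, model$in_taps, 6)) {
  if (nrow(controls) == 6 && ncol(controls) != 6) controls <- t(controls)
  n <- nrow(controls)
  ot <- model$out_taps; it <- model$in_taps
  stopifnot(nrow(x0_hist) == ot, nrow(u_hist) == it)
  xh <- x0_hist; uh <- u_hist
  out <- matrix(0, n + 1, 6)
  out[1, ] <- xh[ot, ]
  for (t in seq_len(n)) {
    uh <- rbind(uh[-1, , drop = FALSE], controls[t, ])   # newest command last
    feats <- c(as.vector(t(xh[ot:1, , drop = FALSE])),   # x(t), x(t-1), ...
               as.vector(t(uh[it:1, , drop = FALSE])))   # u(t), u(t-1), ...
    dx <- predict_step(model, feats)
    xn <- xh[ot, ] + dx
    out[t + 1, ] <- xn
    if (!all(is.finite(xn))) {
      if (t < n) out[(t + 2):(n + 1), ] <- NA_real_
      break
    }
    xh <- rbind(xh[-1, , drop = FALSE], xn)
  }
  out
}
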