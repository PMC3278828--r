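# Elman-style recurrent neural network for chlorophyll-a forecasting.
#
# One hidden layer; the hidden state of the previous sampling occasion is
# fed back through its own weight matrix (context units). Activation is
# tanh(alpha * x) with slope alpha = 0.7 at both the hidden and output
# layer, so targets are trained on the normalized [0, 1] chlorophyll scale.
# Learning is backpropagation through time over truncation windows, with
# momentum: delta_w(n) = eta * delta_i(n) * x_j(n) + alpha_m * delta_w(n-1),
# i.e. w(n+1) = w(n) + eta*delta*x + alpha_m*(w(n) - w(n-1)).

#' Recurrent network configuration
#'
#' @param n_inputs Number of input variables.
#' @param n_hidden Hidden (and context) units; 4 in the reference geometry
#'   6-4-1.
#' @param slope_alpha Activation slope: f(x) = tanh(slope_alpha * x).
#' @param learning_rate Gradient step size eta.
#' @param momentum Momentum constant applied to the previous weight
#'   increment.
#' @param epoch_size Truncation window, in time steps, over which the
#'   network is unrolled for backpropagation through time.
#' @param max_epochs Maximum passes over the training sequence.
#' @param patience Early-stopping patience: training stops when validation
#'   RMSE has not improved for this many epochs.
#' @param seed Integer seed for weight initialization.
#' @return A `rann_config` list.
#' @export
rann_config <- function(n_inputs, n_hidden = 4, slope_alpha = 0.7,
                        learning_rate = 0.01, momentum = 0.9,
                        epoch_size = 100, max_epochs = 1000, patience = 50,
                        seed = 1L) {
  stopifnot(n_inputs >= 1, n_hidden >= 1, slope_alpha > 0,
            learning_rate > 0, momentum >= 0, epoch_size >= 1,
            max_epochs >= 1, patience >= 1)
  structure(list(n_inputs = as.integer(n_inputs),
                 n_hidden = as.integer(n_hidden),
                 slope_alpha = slope_alpha, learning_rate = learning_rate,
                 momentum = momentum, epoch_size = as.integer(epoch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), seed = as.integer(seed)),
            class = "rann_config")
}

#' Initialize a recurrent network
#'
#' Weights are drawn uniformly from \[-0.5, 0.5\] with the configured seed;
#' the context state and all previous-increment (momentum) buffers start at
#' zero.
#'
#' @param config A [rann_config()].
#' @param variables Optional input variable names (stored for prediction).
#' @return A `rann_model`.
#' @export
rann_init <- function(config, variables = NULL) {
  stopifnot(inherits(config, "rann_config"))
  if (!is.null(variables) && length(variables) != config$n_inputs) {
    stop("length(variables) must equal n_inputs")
  }
  h <- config$n_hidden
  i <- config$n_inputs
  with_seed(config$seed, {
    model <- list(
      W_ih = matrix(stats::runif(h * i, -0.5, 0.5), h, i),
      W_ch = matrix(stats::runif(h * h, -0.5, 0.5), h, h),
      W_ho = matrix(stats::runif(h, -0.5, 0.5), 1, h),
      b_h = stats::runif(h, -0.5, 0.5),
      b_o = stats::runif(1, -0.5, 0.5),
      context = rep(0, h),
      prev_delta = NULL,
      config = config,
      variables = variables)
    model$prev_delta <- lapply(model[c("W_ih", "W_ch", "W_ho", "b_h", "b_o")],
                               function(w) w * 0)
    structure(model, class = "rann_model")
  })
}

#' @export
print.rann_model <- function(x, ...) {
  cat(sprintf("<rann_model> %d-%d-1 recurrent net (slope %.2f)\n",
              x$config$n_inputs, x$config$n_hidden, x$config$slope_alpha))
  invisible(x)
}

# Forward pass over a T x n_inputs matrix, returning all intermediate
# states needed by BPTT. h0 is the context entering the window.
rann_forward_states <- function(model, X, h0) {
  a <- model$config$slope_alpha
  T_len <- nrow(X)
  h_dim <- model$config$n_hidden
  H <- matrix(0, T_len, h_dim)
  Y <- numeric(T_len)
  h_prev <- h0
  for (t in seq_len(T_len)) {
    h_t <- tanh(a * (model$W_ih %*% X[t, ] + model$W_ch %*% h_prev +
                       model$b_h))
    y_t <- tanh(a * (model$W_ho %*% h_t + model$b_o))
    H[t, ] <- h_t
    Y[t] <- y_t
    h_prev <- as.numeric(h_t)
  }
  list(H = H, Y = Y, h_last = h_prev)
}

#' Run the network forward over a time-ordered sequence
#'
#' The context (hidden state of the previous occasion) is zeroed at the
#' start when `reset = TRUE`, then carried across time steps:
#' `hidden_t = tanh(a (W_ih x_t + W_ch hidden_{t-1} + b_h))`,
#' `output_t = tanh(a (W_ho hidden_t + b_o))`.
#'
#' @param model A `rann_model`.
#' @param X Numeric matrix (time x inputs) of normalized inputs, or a
#'   normalized [limno_series()] when the model stores variable names.
#' @param reset Zero the context before the first step.
#' @return Numeric vector of outputs on the normalized scale, in (-1, 1).
#' @export
rann_forward <- function(model, X, reset = TRUE) {
  X <- rann_input_matrix(model, X)
  h0 <- if (reset) rep(0, model$config$n_hidden) else model$context
  rann_forward_states(model, X, h0)$Y
}

rann_input_matrix <- function(model, X) {
  if (inherits(X, "limno_series") || is.data.frame(X)) {
    if (is.null(model$variables)) {
      stop("model has no stored variable names; pass a numeric matrix")
    }
    X <- as.matrix(as.data.frame(X)[, model$variables, drop = FALSE])
  }
  X <- as.matrix(X)
  if (ncol(X) != model$config$n_inputs) {
    stop("input has ", ncol(X), " columns; network expects ",
         model$config$n_inputs)
  }
  X
}

# Backpropagation through time over one window. Returns the loss gradients
# (of 0.5 * sum (y - t)^2) w.r.t. every parameter, treating the entering
# context h0 as a constant.
rann_bptt_gradients <- function(model, X, targets, h0) {
  a <- model$config$slope_alpha
  fw <- rann_forward_states(model, X, h0)
  H <- fw$H
  Y <- fw$Y
  T_len <- nrow(X)
  h_dim <- model$config$n_hidden
  g <- list(W_ih = model$W_ih * 0, W_ch = model$W_ch * 0,
            W_ho = model$W_ho * 0, b_h = rep(0, h_dim), b_o = 0)
  da_next <- rep(0, h_dim)  # gradient w.r.t. hidden pre-activation at t+1
  for (t in T_len:1) {
    dy <- Y[t] - targets[t]
    do_pre <- dy * a * (1 - Y[t]^2)
    g$W_ho <- g$W_ho + do_pre * matrix(H[t, ], 1, h_dim)
    g$b_o <- g$b_o + do_pre
    dh <- as.numeric(t(model$W_ho) * do_pre) +
      as.numeric(t(model$W_ch) %*% da_next)
    da <- dh * a * (1 - H[t, ]^2)
    x_t <- X[t, ]
    h_prev <- if (t == 1) h0 else H[t - 1, ]
    g$W_ih <- g$W_ih + da %o% x_t
    g$W_ch <- g$W_ch + da %o% h_prev
    g$b_h <- g$b_h + da
    da_next <- da
  }
  list(grads = g, outputs = Y, h_last = fw$h_last)
}

# One momentum update from loss gradients.
rann_apply_update <- function(model, grads) {
  eta <- model$config$learning_rate
  mom <- model$config$momentum
  for (nm in names(grads)) {
    delta <- -eta * grads[[nm]] + mom * model$prev_delta[[nm]]
    model[[nm]] <- model[[nm]] + delta
    model$prev_delta[[nm]] <- delta
  }
  model
}

#' Train a recurrent network by truncated BPTT with momentum
#'
#' The training sequence is cut into consecutive truncation windows of
#' `epoch_size` time steps; within each window the network is unrolled,
#' the quadratic-loss gradient accumulated, and the weights updated with the
#' momentum rule (the context value, not its gradient, flows across window
#' borders). After each pass the validation RMSE (normalized scale) is
#' recorded; training stops at `max_epochs` or once validation RMSE has not
#' improved for `patience` epochs, and the weights from the best validation
#' epoch are returned.
#'
#' @param model A `rann_model` (see [rann_init()]).
#' @param train,validate Normalized [limno_series()] (same normalizer!) with
#'   `chla` targets in \[0, 1\]; `train` must be time-ordered.
#' @param config Optional [rann_config()] overriding the model's.
#' @return The trained model, with a `history` attribute: data frame
#'   `epoch`, `train_rmse`, `val_rmse`.
#' @export
rann_train <- function(model, train, validate, config = model$config) {
  model$config <- config
  if (is.null(model$variables)) {
    stop("model must carry input variable names for series training")
  }
  if (nrow(validate) == 0) {
    stop("early stopping requires a non-empty validation set")
  }
  X <- rann_input_matrix(model, train)
  y <- train$chla
  Xv <- rann_input_matrix(model, validate)
  yv <- validate$chla
  n <- nrow(X)
  starts <- seq(1, n, by = config$epoch_size)
  best <- list(rmse = Inf, model = model, epoch = 0L)
  history <- data.frame(epoch = integer(0), train_rmse = numeric(0),
                        val_rmse = numeric(0))
  for (epoch in seq_len(config$max_epochs)) {
    h0 <- rep(0, config$n_hidden)
    outputs <- numeric(n)
    for (s in starts) {
      e <- min(s + config$epoch_size - 1L, n)
      res <- rann_bptt_gradients(model, X[s:e, , drop = FALSE], y[s:e], h0)
      model <- rann_apply_update(model, res$grads)
      outputs[s:e] <- res$outputs
      h0 <- res$h_last
    }
    train_rmse <- sqrt(mean((outputs - y)^2))
    val_pred <- rann_forward(model, Xv)
    val_rmse <- sqrt(mean((val_pred - yv)^2))
    history <- rbind(history, data.frame(epoch = epoch,
                                         train_rmse = train_rmse,
                                         val_rmse = val_rmse))
    if (val_rmse < best$rmse - 1e-12) {
      best <- list(rmse = val_rmse, model = model, epoch = epoch)
    }
    if (epoch - best$epoch >= config$patience) break
  }
  out <- best$model
  attr(out, "history") <- history
  out
}

#' Predict chlorophyll-a on the original scale
#'
#' Normalizes the input series with the training normalizer, runs the
#' network forward (context reset at the sequence start), and maps the
#' outputs back to ug/l through the normalizer's `chla` range.
#'
#' @param model Trained `rann_model` with stored variable names.
#' @param series [limno_series()] on the original measurement scale.
#' @param spec The training `limno_normalizer` (must cover the model's
#'   variables and `chla`).
#' @return Numeric vector of chlorophyll-a predictions, ug/l.
#' @export
rann_predict <- function(model, series, spec) {
  missing_vars <- setdiff(c(model$variables, "chla"), names(spec$ranges))
  if (length(missing_vars) > 0) {
    stop("normalizer does not cover: ", paste(missing_vars, collapse = ", "))
  }
  X <- sapply(model$variables, function(v)
    normalize_values(spec, v, series[[v]]))
  X <- matrix(X, ncol = length(model$variables))
  out_norm <- rann_forward(model, X, reset = TRUE)
  normalize_values(spec, "chla", out_norm, direction = "inverse")
}

#' Input-sensitivity ranking of a trained network
#'
#' Perturbs one input variable at a time by `perturbation` (on the
#' normalized scale) across the whole training sequence, reruns the forward
#' pass, and scores the variable by the mean absolute output change per unit
#' perturbation. Large scores mark inputs the fitted mapping depends on.
#'
#' @param model Trained `rann_model` with stored variable names.
#' @param train Normalized training [limno_series()].
#' @param perturbation Perturbation size on the normalized \[0, 1\] scale.
#' @return Data frame `variable`, `sensitivity`, sorted descending.
#' @export
sensitivity_analysis <- function(model, train, perturbation = 0.05) {
  stopifnot(perturbation > 0)
  X <- rann_input_matrix(model, train)
  if (all(model$W_ih == 0) && all(model$W_ho == 0)) {
    warning("untrained (all-zero) network: sensitivities are all 0")
  }
  y0 <- rann_forward(model, X)
  scores <- vapply(seq_len(ncol(X)), function(j) {
    Xp <- X
    Xp[, j] <- Xp[, j] + perturbation
    mean(abs(rann_forward(model, Xp) - y0)) / perturbation
  }, numeric(1))
  vars <- if (is.null(model$variables)) paste0("x", seq_len(ncol(X)))
          else model$variables
  out <- data.frame(variable = vars, sensitivity = scores,
                    stringsAsFactors = FALSE)
  out[order(-out$sensitivity), , drop = FALSE]
}

#' Backward elimination of network inputs by sensitivity
#'
#' Trains on the full candidate set, then repeatedly drops the least
#' sensitive variable and retrains; a drop is kept only when validation
#' RMSE does not worsen by more than `tol` (relative). Stops when a drop is
#' rejected or one variable remains. Deterministic for a fixed seed (each
#' retrain derives its initialization seed from `config$seed` and the
#' iteration).
#'
#' @param split A `limno_split` whose sets are already normalized with a
#'   common normalizer; `validate_C` must be non-empty.
#' @param candidates Candidate input variable names (>= 1).
#' @param config A [rann_config()] sized for the *full* candidate set
#'   (`n_inputs` is adjusted internally as variables are dropped).
#' @param tol Accepted relative worsening of validation RMSE.
#' @return List: `selected` variables, trained `model`, `val_rmse`, and a
#'   `trace` data frame of the elimination path.
#' @export
backward_eliminate <- function(split, candidates, config, tol = 0.02) {
  if (length(candidates) < 1) stop("need at least one candidate")
  train_once <- function(vars, step) {
    cfg <- config
    cfg$n_inputs <- length(vars)
    cfg$seed <- derive_seed(config$seed, paste0("beleg", step))
    m <- rann_init(cfg, vars)
    m <- rann_train(m, split$train_A, split$validate_C, cfg)
    val <- rann_forward(m, split$validate_C)
    list(model = m, val_rmse = sqrt(mean((val - split$validate_C$chla)^2)))
  }
  current <- candidates
  fit <- train_once(current, 0)
  trace <- data.frame(step = 0, variables = paste(current, collapse = "+"),
                      val_rmse = fit$val_rmse, stringsAsFactors = FALSE)
  step <- 0
  while (length(current) > 1) {
    step <- step + 1
    sens <- sensitivity_analysis(fit$model, split$train_A)
    drop_var <- sens$variable[nrow(sens)]
    trial_vars <- setdiff(current, drop_var)
    trial <- train_once(trial_vars, step)
    trace <- rbind(trace, data.frame(
      step = step, variables = paste(trial_vars, collapse = "+"),
      val_rmse = trial$val_rmse, stringsAsFactors = FALSE))
    if (trial$val_rmse <= fit$val_rmse * (1 + tol)) {
      current <- trial_vars
      fit <- trial
    } else break
  }
  list(selected = current, model = fit$model, val_rmse = fit$val_rmse,
       trace = trace)
}
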