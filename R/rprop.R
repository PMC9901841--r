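#' Rprop+ training configuration
#'
#' Constants for resilient backpropagation with weight backtracking. The
#' defaults are the canonical Riedmiller-Braun values: step sizes grow by
#' `eta_plus` while the partial derivative keeps its sign, shrink by
#' `eta_minus` on a sign flip (with the previous update reverted), and stay
#' clamped to `[delta_min, delta_max]`. Training stops when the largest
#' absolute partial derivative falls below `threshold` or after `max_steps`
#' full-batch iterations.
#'
#' @param eta_plus Step-growth factor (> 1).
#' @param eta_minus Step-shrink factor (in (0, 1)).
#' @param delta_init Initial per-weight step size.
#' @param delta_min,delta_max Step-size clamp.
#' @param threshold Stopping criterion on `max |dE/dw|`.
#' @param max_steps Iteration cap.
#' @param seed Integer seed used when a caller needs fresh weights.
#' @return An object of class `rprop_config`.
#' @export
rprop_config <- function(eta_plus = 1.2, eta_minus = 0.5,
                         delta_init = 0.1, delta_min = 1e-6, delta_max = 50,
                         threshold = 0.01, max_steps = 1e5, seed = 1) {
  if (!(eta_minus < 1 && 1 < eta_plus)) {
    abort("need eta_minus < 1 < eta_plus", class = "permstack_value_error")
  }
  if (!(delta_min <= delta_init && delta_init <= delta_max)) {
    abort("need delta_min <= delta_init <= delta_max",
          class = "permstack_value_error")
  }
  if (threshold <= 0) {
    abort("threshold must be positive", class = "permstack_value_error")
  }
  structure(list(eta_plus = eta_plus, eta_minus = eta_minus,
                 delta_init = delta_init, delta_min = delta_min,
                 delta_max = delta_max, threshold = threshold,
                 max_steps = as.integer(max_steps), seed = as.integer(seed)),
            class = "rprop_config")
}

#' Initialise a multilayer perceptron
#'
#' Builds a feedforward regression network with logistic hidden units and a
#' single linear output neuron: `o(x) = w0 + sum_j w_j f(w0j + w_j^T x)`
#' with `f` the logistic function, applied layer by layer for deeper nets.
#' Weights and intercepts are drawn from a seeded standard normal.
#'
#' @param layer_sizes Integer vector `c(n_inputs, hidden..., 1)`; an empty
#'   hidden part (`c(n, 1)`) gives a single linear neuron.
#' @param seed Integer seed; the same seed always gives the same weights.
#' @return An object of class `rprop_mlp` with elements `layer_sizes`,
#'   `weights` (list of `n_out x n_in` matrices), `biases` (list of
#'   vectors), activation names and `seed`.
#' @export
mlp_init <- function(layer_sizes, seed = 1) {
  layer_sizes <- as.integer(layer_sizes)
  if (length(layer_sizes) < 2 || layer_sizes[1] < 1 ||
      layer_sizes[length(layer_sizes)] != 1 || any(layer_sizes < 1)) {
    abort("layer_sizes must be c(n_inputs >= 1, hidden sizes >= 1 ..., 1)",
          class = "permstack_value_error")
  }
  n_layers <- length(layer_sizes) - 1
  weights <- vector("list", n_layers)
  biases <- vector("list", n_layers)
  withr::with_seed(seed, {
    for (l in seq_len(n_layers)) {
      n_in <- layer_sizes[l]
      n_out <- layer_sizes[l + 1]
      weights[[l]] <- matrix(stats::rnorm(n_out * n_in), n_out, n_in)
      biases[[l]] <- stats::rnorm(n_out)
    }
  })
  structure(list(layer_sizes = layer_sizes, weights = weights,
                 biases = biases, hidden_activation = "logistic",
                 output_activation = "identity", seed = as.integer(seed)),
            class = "rprop_mlp")
}

#' @export
print.rprop_mlp <- function(x, ...) {
  cat("<rprop_mlp>", paste(x$layer_sizes, collapse = "-"),
      "| logistic hidden, identity output | seed", x$seed, "\n")
  invisible(x)
}

as_input_matrix <- function(model, x) {
  if (is.vector(x) && !is.list(x)) x <- matrix(x, nrow = 1)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (ncol(x) != model$layer_sizes[1]) {
    abort(sprintf("input has %d columns; network expects %d",
                  ncol(x), model$layer_sizes[1]),
          class = "permstack_value_error")
  }
  if (any(!is.finite(x))) {
    abort("non-finite network input", class = "permstack_value_error")
  }
  x
}

# Forward pass keeping all layer activations (for backprop).
forward_pass <- function(model, X) {
  n_layers <- length(model$weights)
  acts <- vector("list", n_layers + 1)
  acts[[1]] <- X
  a <- X
  for (l in seq_len(n_layers)) {
    z <- a %*% t(model$weights[[l]]) +
      matrix(model$biases[[l]], nrow(a), length(model$biases[[l]]),
             byrow = TRUE)
    a <- if (l < n_layers) stats::plogis(z) else z
    acts[[l + 1]] <- a
  }
  acts
}

#' Evaluate the network output
#'
#' @param model An `rprop_mlp`.
#' @param x A numeric vector (one molecule) or matrix (rows = molecules)
#'   with as many columns as network inputs.
#' @return Numeric vector of predictions, one per row.
#' @export
mlp_forward <- function(model, x) {
  X <- as_input_matrix(model, x)
  acts <- forward_pass(model, X)
  as.numeric(acts[[length(acts)]])
}

#' @export
predict.rprop_mlp <- function(object, newdata, ...) {
  mlp_forward(object, newdata)
}

#' Sum-of-squares training error
#'
#' `E = 1/2 * sum((o - y)^2)` over all observations, keeping the 1/2 factor
#' so reported errors match the usual resilient-backpropagation convention.
#'
#' @inheritParams mlp_forward
#' @param y Numeric target vector, one value per row of `x`.
#' @return A single non-negative number.
#' @export
mlp_batch_error <- function(model, x, y) {
  X <- as_input_matrix(model, x)
  if (nrow(X) == 0) {
    abort("empty batch", class = "permstack_value_error")
  }
  if (length(y) != nrow(X)) {
    abort("length(y) must match rows of x", class = "permstack_value_error")
  }
  o <- mlp_forward(model, X)
  0.5 * sum((o - y)^2)
}

#' Analytic gradient of the training error
#'
#' Backpropagates `E = 1/2 sum (o - y)^2` through the logistic hidden layers
#' and linear output.
#'
#' @inheritParams mlp_batch_error
#' @return A list with `weights` and `biases`, shaped like the model's.
#' @export
mlp_gradient <- function(model, x, y) {
  X <- as_input_matrix(model, x)
  if (length(y) != nrow(X)) {
    abort("length(y) must match rows of x", class = "permstack_value_error")
  }
  n_layers <- length(model$weights)
  acts <- forward_pass(model, X)
  gw <- vector("list", n_layers)
  gb <- vector("list", n_layers)
  # output layer is linear: dE/dz_L = o - y
  delta <- acts[[n_layers + 1]] - matrix(y, ncol = 1)
  for (l in rev(seq_len(n_layers))) {
    gw[[l]] <- t(delta) %*% acts[[l]]
    gb[[l]] <- colSums(delta)
    if (l > 1) {
      a <- acts[[l]]
      delta <- (delta %*% model$weights[[l]]) * a * (1 - a)
    }
  }
  list(weights = gw, biases = gb)
}

#' Train a network with Rprop+ (weight backtracking)
#'
#' Full-batch resilient backpropagation: each weight keeps its own step
#' size, adapted from the sign of the partial derivative only. On a
#' consistent sign the step grows by `eta_plus`; on a sign flip the previous
#' update is reverted (backtracking), the step shrinks by `eta_minus`, and
#' the stored gradient is zeroed so the next iteration re-probes the
#' direction. Training stops when `max |dE/dw| < threshold` or at
#' `max_steps`.
#'
#' @inheritParams mlp_batch_error
#' @param config An [rprop_config()].
#' @return A list with `model` (trained `rprop_mlp`) and `trace`, a one-row
#'   tibble with `final_error`, `reached_threshold` (largest absolute
#'   partial derivative at the stop), `steps`, `converged`, and the range of
#'   step sizes seen (`delta_low`, `delta_high`).
#' @export
train_rprop <- function(model, x, y, config = rprop_config()) {
  stopifnot(inherits(model, "rprop_mlp"), inherits(config, "rprop_config"))
  X <- as_input_matrix(model, x)
  if (length(y) != nrow(X) || any(!is.finite(y))) {
    abort("y must be finite and match rows of x",
          class = "permstack_value_error")
  }
  n_layers <- length(model$weights)
  zero_like <- function(src, fill = 0) lapply(src, function(m) {
    m[] <- fill
    m
  })
  delta_w <- zero_like(model$weights, config$delta_init)
  delta_b <- zero_like(model$biases, config$delta_init)
  gprev_w <- zero_like(model$weights)
  gprev_b <- zero_like(model$biases)
  dwprev_w <- zero_like(model$weights)
  dwprev_b <- zero_like(model$biases)
  delta_low <- config$delta_init
  delta_high <- config$delta_init

  rprop_update <- function(w, g, gprev, delta, dwprev) {
    prod_sign <- g * gprev
    pos <- prod_sign > 0
    neg <- prod_sign < 0
    delta[pos] <- pmin(delta[pos] * config$eta_plus, config$delta_max)
    delta[neg] <- pmax(delta[neg] * config$eta_minus, config$delta_min)
    dw <- -sign(g) * delta
    dw[neg] <- -dwprev[neg]    # backtrack the previous update
    w <- w + dw
    gkeep <- g
    gkeep[neg] <- 0            # forget gradient after a flip
    dw[neg] <- 0               # no step to revert twice
    list(w = w, gprev = gkeep, delta = delta, dwprev = dw)
  }

  steps <- 0L
  reached <- Inf
  converged <- FALSE
  while (steps < config$max_steps) {
    g <- mlp_gradient(model, X, y)
    reached <- max(vapply(c(g$weights, g$biases),
                          function(m) max(abs(m)), numeric(1)))
    if (!is.finite(reached)) {
      abort(sprintf("non-finite gradient at training step %d", steps),
            class = "permstack_numeric_error")
    }
    if (reached < config$threshold) {
      converged <- TRUE
      break
    }
    for (l in seq_len(n_layers)) {
      up <- rprop_update(model$weights[[l]], g$weights[[l]], gprev_w[[l]],
                         delta_w[[l]], dwprev_w[[l]])
      model$weights[[l]] <- up$w
      gprev_w[[l]] <- up$gprev
      delta_w[[l]] <- up$delta
      dwprev_w[[l]] <- up$dwprev
      up <- rprop_update(model$biases[[l]], g$biases[[l]], gprev_b[[l]],
                         delta_b[[l]], dwprev_b[[l]])
      model$biases[[l]] <- up$w
      gprev_b[[l]] <- up$gprev
      delta_b[[l]] <- up$delta
      dwprev_b[[l]] <- up$dwprev
    }
    delta_low <- min(delta_low,
                     vapply(c(delta_w, delta_b), min, numeric(1)))
    delta_high <- max(delta_high,
                      vapply(c(delta_w, delta_b), max, numeric(1)))
    steps <- steps + 1L
  }
  err <- mlp_batch_error(model, X, y)
  if (!is.finite(err)) {
    abort(sprintf("non-finite training error after step %d", steps),
          class = "permstack_numeric_error")
  }
  trace <- tibble::tibble(final_error = err, reached_threshold = reached,
                          steps = steps, converged = converged,
                          delta_low = delta_low, delta_high = delta_high)
  list(model = model, trace = trace)
}

#' @export
tidy.rprop_mlp <- function(x, ...) {
  purrr::map_dfr(seq_along(x$weights), function(l) {
    w <- x$weights[[l]]
    dplyr::bind_rows(
      tibble::tibble(layer = l, term = "weight",
                     from = rep(seq_len(ncol(w)), each = nrow(w)),
                     to = rep(seq_len(nrow(w)), ncol(w)),
                     value = as.numeric(w)),
      tibble::tibble(layer = l, term = "intercept",
                     from = NA_integer_, to = seq_along(x$biases[[l]]),
                     value = x$biases[[l]])
    )
  })
}
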