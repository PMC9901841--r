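test_that("initialisation is seeded, shaped, and validated", {
  m <- mlp_init(c(61, 20, 15, 5, 1), seed = 1)
  expect_equal(lapply(m$weights, dim),
               list(c(20L, 61L), c(15L, 20L), c(5L, 15L), c(1L, 5L)))
  expect_equal(lengths(m$biases), c(20L, 15L, 5L, 1L))
  m2 <- mlp_init(c(61, 20, 15, 5, 1), seed = 1)
  expect_identical(m$weights, m2$weights)
  expect_true(all(vapply(m$weights, function(w) all(is.finite(w)), logical(1))))
  # degenerate: a single linear neuron
  lin <- mlp_init(c(2, 1), seed = 3)
  expect_length(lin$weights, 1)
  expect_error(mlp_init(c(3, 0, 1)), class = "permstack_value_error")
  expect_error(mlp_init(c(3, 2, 2)), class = "permstack_value_error")
})

test_that("forward pass matches hand evaluation", {
  # zero network: output equals the output intercept (here forced to 0)
  m <- mlp_init(c(2, 3, 1), seed = 5)
  m$weights <- lapply(m$weights, function(w) { w[] <- 0; w })
  m$biases <- lapply(m$biases, function(b) { b[] <- 0; b })
  expect_equal(mlp_forward(m, c(1.5, -2)), 0)
  # no hidden layer: w = 2, intercept = 1, x = 3 -> 7
  lin <- mlp_init(c(1, 1), seed = 1)
  lin$weights[[1]][] <- 2
  lin$biases[[1]][] <- 1
  expect_equal(mlp_forward(lin, 3), 7)
  # one hidden logistic neuron, hand-set chain
  h <- mlp_init(c(1, 1, 1), seed = 1)
  h$weights[[1]][] <- 0.5
  h$biases[[1]][] <- -0.2
  h$weights[[2]][] <- 3
  h$biases[[2]][] <- 0.1
  x <- 1.4
  expect_equal(mlp_forward(h, x), 0.1 + 3 * plogis(-0.2 + 0.5 * x),
               tolerance = 1e-15)
  expect_error(mlp_forward(h, c(1, 2)), class = "permstack_value_error")
})

test_that("batch error keeps the 1/2 convention and scales quadratically", {
  lin <- mlp_init(c(1, 1), seed = 1)
  lin$weights[[1]][] <- 1
  lin$biases[[1]][] <- 0
  X <- matrix(c(1, 2))
  expect_equal(mlp_batch_error(lin, X, c(1, 2)), 0)
  expect_equal(mlp_batch_error(lin, X, c(0, 3)), 1)    # residuals (1, -1)
  expect_equal(mlp_batch_error(lin, X, c(-1, 4)), 4)   # residuals doubled
  expect_error(mlp_batch_error(lin, X[0, , drop = FALSE], numeric(0)),
               class = "permstack_value_error")
})

test_that("analytic gradient matches central finite differences on random nets", {
  rel_err <- function(a, b) abs(a - b) / pmax(abs(a) + abs(b), 1e-8)
  withr::with_seed(2024, {
    for (s in 1:50) {
      sizes <- c(sample(2:4, 1), sample(2:5, 1), 1)
      if (s %% 3 == 0) sizes <- append(sizes, sample(2:3, 1), after = 2)
      m <- mlp_init(sizes, seed = s)
      n <- 6
      X <- matrix(rnorm(n * sizes[1]), n, sizes[1])
      y <- rnorm(n)
      g <- mlp_gradient(m, X, y)
      eps <- 1e-5
      # probe three random weight coordinates and one bias per net
      for (probe in 1:3) {
        l <- sample(seq_along(m$weights), 1)
        i <- sample(nrow(m$weights[[l]]), 1)
        j <- sample(ncol(m$weights[[l]]), 1)
        mp <- m; mp$weights[[l]][i, j] <- m$weights[[l]][i, j] + eps
        mm <- m; mm$weights[[l]][i, j] <- m$weights[[l]][i, j] - eps
        fd <- (mlp_batch_error(mp, X, y) - mlp_batch_error(mm, X, y)) / (2 * eps)
        expect_lt(rel_err(fd, g$weights[[l]][i, j]), 1e-6)
      }
      l <- sample(seq_along(m$biases), 1)
      i <- sample(length(m$biases[[l]]), 1)
      mp <- m; mp$biases[[l]][i] <- m$biases[[l]][i] + eps
      mm <- m; mm$biases[[l]][i] <- m$biases[[l]][i] - eps
      fd <- (mlp_batch_error(mp, X, y) - mlp_batch_error(mm, X, y)) / (2 * eps)
      expect_lt(rel_err(fd, g$biases[[l]][i]), 1e-6)
    }
  })
})

test_that("gradient is zero at a perfect fit and closed-form for a linear neuron", {
  lin <- mlp_init(c(1, 1), seed = 1)
  lin$weights[[1]][] <- 2
  lin$biases[[1]][] <- 1
  X <- matrix(c(-1, 0, 2))
  y <- 2 * X[, 1] + 1
  g <- mlp_gradient(lin, X, y)
  expect_equal(g$weights[[1]][1, 1], 0)
  expect_equal(g$biases[[1]][1], 0)
  # least-squares gradient: dE/dw = sum((o - y) x), dE/db = sum(o - y)
  y2 <- c(0, 1, 3)
  o <- 2 * X[, 1] + 1
  g2 <- mlp_gradient(lin, X, y2)
  expect_equal(g2$weights[[1]][1, 1], sum((o - y2) * X[, 1]))
  expect_equal(g2$biases[[1]][1], sum(o - y2))
})

test_that("Rprop+ reaches the normal-equations optimum of a linear neuron", {
  X <- matrix(c(-1, 0, 1, 2, 3.5), ncol = 1)
  y <- c(-1.8, 0.4, 2.1, 3.6, 7.4)
  cfg <- rprop_config(threshold = 1e-7, max_steps = 20000, seed = 1)
  fit <- train_rprop(mlp_init(c(1, 1), seed = 4), X, y, cfg)
  ls <- lm(y ~ X)
  expect_equal(fit$model$weights[[1]][1, 1], unname(coef(ls)[2]),
               tolerance = 1e-3)
  expect_equal(fit$model$biases[[1]][1], unname(coef(ls)[1]),
               tolerance = 1e-3)
  e_opt <- 0.5 * sum(residuals(ls)^2)
  expect_lt(fit$trace$final_error - e_opt, 1e-6)
  # step sizes stay clamped throughout training
  expect_gte(fit$trace$delta_low, cfg$delta_min)
  expect_lte(fit$trace$delta_high, cfg$delta_max)
})

test_that("training is reproducible and respects max_steps = 0", {
  d <- small_dataset(seed = 3, n = 40, p = 6)
  X <- as.matrix(d$descriptors[, -1])[, 1:4]
  y <- (d$log_pe - min(d$log_pe)) / diff(range(d$log_pe))
  m0 <- mlp_init(c(4, 3, 1), seed = 9)
  frozen <- train_rprop(m0, X, y, rprop_config(max_steps = 0))
  expect_identical(frozen$model$weights, m0$weights)
  expect_false(frozen$trace$converged)
  cfg <- rprop_config(max_steps = 300, seed = 9)
  f1 <- train_rprop(m0, X, y, cfg)
  f2 <- train_rprop(m0, X, y, cfg)
  expect_identical(f1$model$weights, f2$model$weights)
  expect_identical(f1$trace, f2$trace)
  expect_lt(f1$trace$final_error, mlp_batch_error(m0, X, y))
})

test_that("Rprop+ matches a long-run gradient-descent oracle on a smooth toy problem", {
  withr::with_seed(5, {
    X <- matrix(runif(60, -1, 1), 30, 2)
    y <- 0.6 * sin(2 * X[, 1]) + 0.3 * X[, 2]
  })
  m0 <- mlp_init(c(2, 5, 1), seed = 12)
  rp <- train_rprop(m0, X, y, rprop_config(threshold = 1e-5,
                                           max_steps = 20000, seed = 12))
  # plain gradient descent from the same start, run long
  gd <- m0
  lr <- 0.02
  for (i in 1:20000) {
    g <- mlp_gradient(gd, X, y)
    for (l in seq_along(gd$weights)) {
      gd$weights[[l]] <- gd$weights[[l]] - lr * g$weights[[l]]
      gd$biases[[l]] <- gd$biases[[l]] - lr * g$biases[[l]]
    }
  }
  e_gd <- mlp_batch_error(gd, X, y)
  expect_lte(rp$trace$final_error, e_gd + 1e-3)
})
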