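test_that("ensemble SD matches hand values and a two-pass variance oracle", {
  expect_equal(ensemble_sd(c(-5.5, -5.5, -5.5)), 0)
  expect_equal(ensemble_sd(c(-5, -6)), sqrt(0.5))
  expect_equal(ensemble_sd(c(0, 0, 3)), sqrt(3))
  expect_error(ensemble_sd(1), class = "permstack_value_error")
  # two-pass oracle on random inputs
  withr::with_seed(13, {
    for (i in 1:20) {
      x <- rnorm(sample(2:6, 1))
      mu <- sum(x) / length(x)
      oracle <- sqrt(sum((x - mu)^2) / (length(x) - 1))
      expect_equal(ensemble_sd(x), oracle, tolerance = 1e-12)
    }
    m <- matrix(rnorm(12), 4, 3)
    expect_equal(ensemble_sd(m), apply(m, 1, sd), tolerance = 1e-12)
  })
})

test_that("AD threshold is three times the maximum training spread", {
  expect_equal(compute_ad_threshold(c(0.11, 0.23, 0.05)), 0.69)
  expect_equal(compute_ad_threshold(0.1), 0.3)
  expect_warning(thr <- compute_ad_threshold(c(0, 0)), "degenerate")
  expect_equal(thr, 0)
  expect_error(compute_ad_threshold(numeric(0)),
               class = "permstack_value_error")
})

test_that("fold-error correlation behaves at its boundaries", {
  a <- c(0.2, 0.3, 0.25, 0.4)
  expect_equal(base_prediction_correlation(a, a), 1)
  expect_equal(base_prediction_correlation(a, 1 - a), -1)
  expect_error(base_prediction_correlation(a, a[-1]),
               class = "permstack_value_error")
  withr::with_seed(3, {
    r <- base_prediction_correlation(rnorm(60), rnorm(60))
  })
  expect_lt(abs(r), 0.35)
})

test_that("stacked ensemble trains, predicts consistently, and flags the domain", {
  d <- small_dataset(seed = 2)
  tbl <- drop_zero_variance(d$descriptors)
  ens <- train_stacked_ensemble(tbl, d$log_pe,
                                base_specs = small_base_specs(seed = 4),
                                meta_spec = small_meta_spec())
  expect_s3_class(ens, "stacked_ensemble")
  preds <- predict_with_ad(ens, tbl)
  expect_identical(preds$id, tbl$molecule_id)
  # training molecules all inside the domain by construction of the max
  expect_true(all(preds$sd <= ens$ad_threshold))
  expect_true(all(preds$inside_domain))
  expect_identical(preds$permeability_class,
                   classify_permeability(preds$predicted_log_pe, -6.2))
  # duplicated molecule gives identical records
  dup <- tbl[c(1, 1), ]
  pd <- predict_with_ad(ens, dup)
  expect_equal(pd$predicted_log_pe[1], pd$predicted_log_pe[2])
  expect_equal(pd$sd[1], pd$sd[2])
})

test_that("out-of-distribution probes are flagged outside the domain more often", {
  d <- small_dataset(seed = 8)
  tbl <- drop_zero_variance(d$descriptors)
  ens <- train_stacked_ensemble(tbl, d$log_pe,
                                base_specs = small_base_specs(seed = 2),
                                meta_spec = small_meta_spec())
  p <- ncol(tbl) - 1
  far <- tbl[rep(1, 100), ]
  withr::with_seed(30, {
    far[, -1] <- matrix(rnorm(100 * p, mean = 0, sd = 15), 100, p)
  })
  far$molecule_id <- sprintf("far%03d", 1:100)
  out_far <- predict_with_ad(ens, far)
  in_frac <- mean(!predict_with_ad(ens, tbl)$inside_domain)
  far_frac <- mean(!out_far$inside_domain)
  expect_gt(far_frac, in_frac + 0.2)
})

test_that("two identical base models make the stack behave like one of them", {
  d <- small_dataset(seed = 5, n = 80, p = 10)
  tbl <- drop_zero_variance(d$descriptors)
  spec <- base_learner_spec("A", c(5), rprop_config(seed = 7, max_steps = 600))
  twin <- base_learner_spec("B", c(5), rprop_config(seed = 7, max_steps = 600))
  # identical members leave no spread, so the AD degenerates (warned)
  expect_warning(
    ens <- train_stacked_ensemble(tbl, d$log_pe,
                                  base_specs = list(spec, twin),
                                  meta_spec = small_meta_spec(max_steps = 1500)),
    "degenerate")
  preds <- predict_with_ad(ens, tbl)
  # identical members: zero spread everywhere
  expect_true(all(preds$sd == 0))
  # ensemble tracks the (shared) base model closely on its own training set
  scaled <- apply_minmax_scaler(tbl, ens$scaling)
  base_pred <- mlp_forward(ens$base_models[[1]],
                           as.matrix(scaled[, -1])) * diff(ens$y_range) +
    ens$y_range[1]
  expect_lt(rmse(base_pred, preds$predicted_log_pe), 0.05 * diff(ens$y_range))
})

test_that("meta-feature mode round-trips and out_of_fold trains", {
  d <- small_dataset(seed = 9, n = 60, p = 8)
  tbl <- drop_zero_variance(d$descriptors)
  ens <- train_stacked_ensemble(
    tbl, d$log_pe, base_specs = small_base_specs(seed = 3, max_steps = 300),
    meta_spec = small_meta_spec(max_steps = 300),
    mode = "out_of_fold", k = 4, repeats = 1, seed = 2)
  expect_identical(ens$meta_feature_mode, "out_of_fold")
  path <- tempfile(fileext = ".json")
  save_ensemble(ens, path)
  expect_identical(load_ensemble(path)$meta_feature_mode, "out_of_fold")
})

test_that("save/load round-trips predictions bit-exactly and rejects bad files", {
  d <- small_dataset(seed = 11, n = 50, p = 8)
  tbl <- drop_zero_variance(d$descriptors)
  ens <- train_stacked_ensemble(tbl, d$log_pe,
                                base_specs = small_base_specs(max_steps = 300),
                                meta_spec = small_meta_spec(max_steps = 300))
  path <- tempfile(fileext = ".json")
  save_ensemble(ens, path)
  back <- load_ensemble(path)
  expect_identical(predict_with_ad(back, tbl), predict_with_ad(ens, tbl))
  expect_identical(back$ad_threshold, ens$ad_threshold)
  expect_identical(back$descriptor_manifest, ens$descriptor_manifest)
  # truncated file is an explicit error
  txt <- readLines(path)
  trunc_path <- tempfile(fileext = ".json")
  writeLines(txt[1:(length(txt) %/% 2)], trunc_path)
  expect_error(load_ensemble(trunc_path), class = "permstack_io_error")
  expect_error(load_ensemble(tempfile()), class = "permstack_io_error")
})

test_that("cross-validated evaluation averages folds and flags overfitting nets", {
  d <- small_dataset(seed = 14, n = 60, p = 8)
  tbl <- drop_zero_variance(d$descriptors)
  scaler <- fit_minmax_scaler(tbl)
  scaled <- apply_minmax_scaler(tbl, scaler)
  ys <- (d$log_pe - min(d$log_pe)) / diff(range(d$log_pe))
  spec <- base_learner_spec("A", c(6, 3),
                            rprop_config(seed = 1, max_steps = 400))
  cv <- cv_evaluate_base(spec, scaled, ys, k = 4, repeats = 2, seed = 5)
  expect_identical(cv$context, "cv")
  per_fold <- attr(cv, "per_fold")
  expect_equal(nrow(per_fold), 8)
  expect_equal(cv$rmse, mean(per_fold$rmse))
  # a noiseless linear target with a generous net is learnable in CV
  lin <- generate_descriptor_dataset(synthetic_spec(
    n_molecules = 80, n_descriptors = 6, n_informative = 5, n_constant = 0,
    correlated_block_size = 0, noise_sd = 0, seed = 21))
  # keep only the linear part of the signal for a clean recovery check;
  # inputs scaled to [0,1] as the training contract requires
  lin_scaled <- apply_minmax_scaler(lin$descriptors,
                                    fit_minmax_scaler(lin$descriptors))
  z <- descriptor_matrix(lin$descriptors)[, lin$truth$informative[1]]
  ylin <- (z - min(z)) / diff(range(z))
  cv_lin <- cv_evaluate_base(
    base_learner_spec("lin", c(4), rprop_config(seed = 2, max_steps = 3000)),
    lin_scaled, ylin, k = 4, repeats = 1, seed = 1)
  expect_gte(cv_lin$r2, 0.95)
  # pure-noise target: no generalization
  ynoise <- withr::with_seed(33, runif(80))
  cv_noise <- cv_evaluate_base(
    base_learner_spec("noise", c(4), rprop_config(seed = 3, max_steps = 400)),
    lin_scaled, ynoise, k = 4, repeats = 1, seed = 1)
  expect_lte(cv_noise$r2, 0.1)
})

test_that("leave-one-out degenerate plan executes", {
  d <- small_dataset(seed = 15, n = 12, p = 5)
  tbl <- drop_zero_variance(d$descriptors)
  ys <- (d$log_pe - min(d$log_pe)) / diff(range(d$log_pe))
  spec <- base_learner_spec("A", c(3), rprop_config(seed = 1, max_steps = 150))
  cv <- cv_evaluate_base(spec, tbl, ys, k = 12, repeats = 1, seed = 2)
  expect_true(is.finite(cv$rmse))
  expect_equal(nrow(attr(cv, "per_fold")), 12)
})

test_that("stacking does not lose to the worse base model (median over seeds)", {
  deltas <- vapply(1:20, function(s) {
    d <- generate_descriptor_dataset(synthetic_spec(
      n_molecules = 110, n_descriptors = 8, n_informative = 5,
      n_constant = 0, correlated_block_size = 0, noise_sd = 0.15,
      seed = 400 + s))
    tbl <- d$descriptors
    train <- 1:80
    test <- 81:110
    ens <- train_stacked_ensemble(
      tbl[train, ], d$log_pe[train],
      base_specs = small_base_specs(seed = s, max_steps = 400),
      meta_spec = small_meta_spec(seed = s + 1000, max_steps = 400))
    scaled <- apply_minmax_scaler(tbl[test, ], ens$scaling)
    to_logpe <- function(v) v * diff(ens$y_range) + ens$y_range[1]
    base_rmse <- vapply(ens$base_models, function(m)
      rmse(d$log_pe[test],
           to_logpe(mlp_forward(m, as.matrix(scaled[, -1])))), numeric(1))
    ens_rmse <- rmse(d$log_pe[test],
                     predict_with_ad(ens, tbl[test, ])$predicted_log_pe)
    ens_rmse - max(base_rmse)
  }, numeric(1))
  expect_lte(median(deltas), 0)
})

test_that("linear baseline recovers exact structure and evaluates under CV", {
  # orthogonal design with known coefficients
  X <- cbind(a = rep(c(-1, 1), each = 4), b = rep(c(-1, 1), 4),
             c = rep(c(-1, -1, 1, 1), 2))
  y <- 2 - 1.5 * X[, "a"] + 0.5 * X[, "b"] + 3 * X[, "c"]
  fitted <- fit_linear_baseline(as_dtable(X), y, k = 4, repeats = 1, seed = 1)
  est <- fitted$coefficients$estimate
  names(est) <- fitted$coefficients$term
  expect_equal(unname(est[c("a", "b", "c")]), c(-1.5, 0.5, 3),
               tolerance = 1e-10)
  resub <- fitted$metrics[fitted$metrics$context == "resubstitution", ]
  expect_equal(resub$r2, 1, tolerance = 1e-12)
  # pure noise: cross-validated R^2 near zero or below
  withr::with_seed(44, {
    Xn <- matrix(rnorm(300), 100, 3)
    yn <- rnorm(100)
  })
  noisy <- fit_linear_baseline(as_dtable(Xn), yn, k = 5, repeats = 2, seed = 2)
  expect_lte(noisy$metrics$r2[noisy$metrics$context == "cv"], 0.1)
  # holdout context appears when holdout data are supplied
  hold <- fit_linear_baseline(as_dtable(X), y, k = 4, repeats = 1, seed = 1,
                              holdout = list(table = as_dtable(X), y = y))
  expect_true("holdout" %in% hold$metrics$context)
  expect_error(fit_linear_baseline(as_dtable(X[, 1, drop = FALSE]), y),
               class = "permstack_value_error")
})

test_that("surrogate tree finds a planted threshold and partitions all molecules", {
  withr::with_seed(50, {
    n <- 150
    X <- matrix(rnorm(n * 6), n, 6)
    colnames(X) <- paste0("d", 1:6)
    y <- ifelse(X[, 3] > 0, -5, -7) + rnorm(n, sd = 0.1)
  })
  st <- surrogate_tree(as_dtable(X), y)
  expect_equal(sum(st$leaves$n), n)
  expect_equal(st$class_counts$n_higher + st$class_counts$n_lower, n)
  # the dominant planted descriptor is the root split
  expect_equal(as.character(st$tree$frame$var[1]), "d3")
  # perfectly separable binary descriptor: two pure leaves
  Xb <- cbind(flag = rep(c(0, 1), each = 10), junk = rep(0.5, 20))
  yb <- ifelse(Xb[, "flag"] == 1, -5, -7)
  stb <- surrogate_tree(as_dtable(Xb), yb, minsplit = 2, minbucket = 1,
                        cp = 0.001)
  expect_equal(nrow(stb$leaves), 2)
  expect_setequal(stb$leaves$mean_log_pe, c(-5, -7))
  expect_setequal(stb$leaves$class, c("higher", "lower"))
})
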