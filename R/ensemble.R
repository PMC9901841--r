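#' Base learner specification
#'
#' Architecture and training configuration for one network in the stack.
#' The defaults used by [train_stacked_ensemble()] are two deep perceptrons,
#' `NN1` with hidden layers (20, 15, 5) and `NN2` with (30, 20, 10), stacked
#' by a small meta network with hidden layers (2, 1).
#'
#' @param name Learner label.
#' @param hidden Integer vector of hidden-layer sizes (non-empty for base
#'   learners).
#' @param rprop An [rprop_config()].
#' @return An object of class `base_learner_spec`.
#' @export
base_learner_spec <- function(name, hidden, rprop = rprop_config()) {
  hidden <- as.integer(hidden)
  if (length(hidden) < 1 || any(hidden < 1)) {
    abort("base learners need at least one hidden layer",
          class = "permstack_value_error")
  }
  structure(list(name = name, hidden = hidden, rprop = rprop),
            class = "base_learner_spec")
}

#' Default network specifications
#'
#' The two default base architectures, NN1 with hidden layers (20, 15, 5)
#' and NN2 with (30, 20, 10), and the (2, 1) meta network, each with its own
#' seeded Rprop+ configuration.
#'
#' @param seed Base seed for weight initialisation.
#' @param max_steps Rprop+ iteration cap.
#' @return A list of two [base_learner_spec()] / a single spec.
#' @export
default_base_specs <- function(seed = 1, max_steps = 1e5) {
  list(
    base_learner_spec("NN1", c(20, 15, 5),
                      rprop_config(seed = seed, max_steps = max_steps)),
    base_learner_spec("NN2", c(30, 20, 10),
                      rprop_config(seed = seed + 1, max_steps = max_steps))
  )
}

#' @rdname default_base_specs
#' @export
default_meta_spec <- function(seed = 99, max_steps = 1e5) {
  base_learner_spec("meta", c(2, 1),
                    rprop_config(seed = seed, max_steps = max_steps))
}

# Train one network; on numerical failure retry once with a shifted seed,
# then fail loudly.
train_base_safe <- function(spec, X, y, seed_offset = 0L) {
  seed <- spec$rprop$seed + seed_offset
  model <- mlp_init(c(ncol(X), spec$hidden, 1), seed = seed)
  tryCatch(train_rprop(model, X, y, spec$rprop),
           permstack_numeric_error = function(e) {
             warn(paste0(spec$name, ": training diverged, retrying with a ",
                         "fresh seed"))
             model <- mlp_init(c(ncol(X), spec$hidden, 1), seed = seed + 1L)
             train_rprop(model, X, y, spec$rprop)
           })
}

# Metrics that tolerate tiny validation folds (leave-one-out executes with
# rank statistics unavailable).
fold_metrics <- function(obs, pred) {
  safe <- function(f) tryCatch(f(obs, pred), error = function(e) NA_real_)
  tibble::tibble(
    r2 = safe(r_squared), r2_cov = safe(r_squared_cov),
    rmse = rmse(obs, pred), mae = mae(obs, pred),
    pearson = safe(pearson_r), gini = safe(relative_gini)
  )
}

#' Cross-validated evaluation of one base learner
#'
#' Refits the network in every resample of a repeated k-fold plan, scores it
#' on the held-out fold, and averages each statistic across all folds and
#' repeats (the "cv" reporting convention). The per-fold RMSE vector is kept
#' for pairwise model-correlation analysis.
#'
#' @param spec A [base_learner_spec()].
#' @param table Scaled descriptor table (tibble with `molecule_id`).
#' @param y Numeric response (same scale the networks are trained on).
#' @param k,repeats,seed Cross-validation plan.
#' @return One-row tibble of averaged metrics (context `"cv"`), with the
#'   per-fold results in attribute `"per_fold"`.
#' @export
cv_evaluate_base <- function(spec, table, y, k = 20, repeats = 3, seed = 1) {
  m <- descriptor_matrix(table)
  folds <- make_repeated_folds(nrow(m), k = k, repeats = repeats, seed = seed)
  resamples <- fold_index_list(folds)
  per_fold <- purrr::imap_dfr(resamples, function(val_rows, key) {
    i <- match(key, names(resamples))
    train_rows <- setdiff(seq_len(nrow(m)), val_rows)
    fit <- train_base_safe(spec, m[train_rows, , drop = FALSE], y[train_rows],
                           seed_offset = 104729L * i)
    pred <- mlp_forward(fit$model, m[val_rows, , drop = FALSE])
    dplyr::bind_cols(tibble::tibble(resample = key), fold_metrics(y[val_rows], pred))
  })
  out <- dplyr::summarise(per_fold, dplyr::across(
    c("r2", "r2_cov", "rmse", "mae", "pearson", "gini"),
    ~ mean(.x, na.rm = TRUE)))
  out$n <- length(y)
  out$context <- "cv"
  out$model <- spec$name
  attr(out, "per_fold") <- per_fold
  out
}

#' Correlation between two learners' fold-level errors
#'
#' Pearson correlation of per-fold RMSE vectors obtained under a shared
#' cross-validation plan. Low values indicate the models err on different
#' resamples and are therefore complementary in a stack.
#'
#' @param rmse_a,rmse_b Equal-length numeric vectors of fold RMSEs.
#' @return A single correlation in \[-1, 1\].
#' @export
base_prediction_correlation <- function(rmse_a, rmse_b) {
  if (length(rmse_a) != length(rmse_b)) {
    abort("fold RMSE vectors come from different plans",
          class = "permstack_value_error")
  }
  pearson_r(rmse_a, rmse_b)
}

#' Ensemble-member prediction spread
#'
#' Sample standard deviation of the k base-model predictions for one
#' molecule, `sqrt(sum((y_i - ybar)^2) / (k - 1))` — the reliability score
#' behind the applicability domain.
#'
#' @param predictions Numeric vector (one molecule, k >= 2 members) or a
#'   matrix with one row per molecule and one column per member.
#' @return A number, or a vector with one value per row.
#' @export
ensemble_sd <- function(predictions) {
  if (is.matrix(predictions)) {
    if (ncol(predictions) < 2) {
      abort("need predictions from at least 2 ensemble members",
            class = "permstack_value_error")
    }
    return(apply(predictions, 1, ensemble_sd))
  }
  k <- length(predictions)
  if (k < 2) {
    abort("need predictions from at least 2 ensemble members",
          class = "permstack_value_error")
  }
  sqrt(sum((predictions - mean(predictions))^2) / (k - 1))
}

#' Applicability-domain threshold
#'
#' Three times the largest ensemble standard deviation observed on the
#' training molecules; predictions with a spread above this are flagged
#' unreliable.
#'
#' @param train_sds Numeric vector of training-set ensemble SDs.
#' @return `3 * max(train_sds)`.
#' @export
compute_ad_threshold <- function(train_sds) {
  if (length(train_sds) == 0) {
    abort("empty SD vector", class = "permstack_value_error")
  }
  thr <- 3 * max(train_sds)
  if (thr == 0) {
    warn("all training SDs are zero; applicability domain is degenerate")
  }
  thr
}

#' Train a stacked neural-network ensemble
#'
#' Fits each base network on the full (min-max scaled) training table, then
#' trains a meta network whose inputs are the base-model predictions and
#' whose target is the observed response. With
#' `mode = "resubstitution"` (default) the meta features are the base
#' models' predictions on their own training molecules; with
#' `mode = "out_of_fold"` they are cross-validated predictions from a
#' repeated k-fold plan (averaged over repeats), the statistically safer
#' variant. Descriptors and the response are both scaled to 0-1 from the
#' training data; predictions are reported back in logPe units. The
#' applicability-domain threshold (3x the maximum training-set spread of the
#' base predictions, in logPe units) is computed and stored.
#'
#' @param table Raw (unscaled) descriptor table with `molecule_id`.
#' @param log_pe Observed logPe, one per molecule, in log10(cm/s).
#' @param base_specs List of [base_learner_spec()] (>= 2).
#' @param meta_spec Spec for the meta network (inputs = number of bases).
#' @param mode `"resubstitution"` or `"out_of_fold"`.
#' @param k,repeats,seed Plan for out-of-fold meta features.
#' @param cutoff Permeability class boundary (default -6.2).
#' @return An object of class `stacked_ensemble`.
#' @export
train_stacked_ensemble <- function(table, log_pe,
                                   base_specs = default_base_specs(),
                                   meta_spec = default_meta_spec(),
                                   mode = c("resubstitution", "out_of_fold"),
                                   k = 20, repeats = 3, seed = 1,
                                   cutoff = -6.2) {
  mode <- match.arg(mode)
  if (length(base_specs) < 2) {
    abort("need at least 2 base learners", class = "permstack_value_error")
  }
  if (length(meta_spec$hidden) < 1) {
    abort("meta learner needs a hidden layer", class = "permstack_value_error")
  }
  scaler <- fit_minmax_scaler(table)
  scaled <- apply_minmax_scaler(table, scaler)
  X <- descriptor_matrix(scaled)
  y_range <- range(log_pe)
  if (diff(y_range) == 0) {
    abort("constant response", class = "permstack_value_error")
  }
  ys <- (log_pe - y_range[1]) / diff(y_range)

  base_fits <- purrr::map(base_specs, train_base_safe, X = X, y = ys)
  base_models <- purrr::map(base_fits, "model")
  names(base_models) <- purrr::map_chr(base_specs, "name")
  resub_feats <- vapply(base_models, mlp_forward, numeric(nrow(X)), x = X)

  meta_feats <- if (mode == "resubstitution") {
    resub_feats
  } else {
    oof_meta_features(base_specs, X, ys, k = k, repeats = repeats, seed = seed)
  }
  meta_model <- mlp_init(c(length(base_models), meta_spec$hidden, 1),
                         seed = meta_spec$rprop$seed)
  meta_fit <- train_rprop(meta_model, meta_feats, ys, meta_spec$rprop)

  # spread of the base predictions in logPe units defines the domain
  base_logpe <- resub_feats * diff(y_range) + y_range[1]
  train_sds <- ensemble_sd(base_logpe)
  structure(list(
    base_models = base_models,
    meta_model = meta_fit$model,
    base_specs = base_specs,
    meta_spec = meta_spec,
    scaling = scaler,
    y_range = y_range,
    descriptor_manifest = scaler$stats$descriptor,
    ad_threshold = compute_ad_threshold(train_sds),
    meta_feature_mode = mode,
    cutoff = cutoff,
    traces = c(purrr::map(base_fits, "trace"), list(meta = meta_fit$trace)),
    schema = "permstack-ensemble/1"
  ), class = "stacked_ensemble")
}

oof_meta_features <- function(base_specs, X, ys, k, repeats, seed) {
  folds <- make_repeated_folds(nrow(X), k = k, repeats = repeats, seed = seed)
  feats <- matrix(0, nrow(X), length(base_specs))
  counts <- matrix(0L, nrow(X), length(base_specs))
  resamples <- fold_index_list(folds)
  for (key in names(resamples)) {
    val_rows <- resamples[[key]]
    train_rows <- setdiff(seq_len(nrow(X)), val_rows)
    i <- match(key, names(resamples))
    for (b in seq_along(base_specs)) {
      fit <- train_base_safe(base_specs[[b]], X[train_rows, , drop = FALSE],
                             ys[train_rows], seed_offset = 104729L * i)
      feats[val_rows, b] <- feats[val_rows, b] +
        mlp_forward(fit$model, X[val_rows, , drop = FALSE])
      counts[val_rows, b] <- counts[val_rows, b] + 1L
    }
  }
  feats / counts
}

#' @export
print.stacked_ensemble <- function(x, ...) {
  cat("<stacked_ensemble>", length(x$base_models), "base networks (",
      paste(names(x$base_models), collapse = ", "), ") + meta (",
      paste(x$meta_spec$hidden, collapse = ","), ")\n")
  cat("  descriptors:", length(x$descriptor_manifest),
      "| meta features:", x$meta_feature_mode,
      "| AD threshold:", format(x$ad_threshold, digits = 4), "\n")
  invisible(x)
}

#' Predict with applicability-domain flags
#'
#' Scales new descriptors with the stored training parameters, runs every
#' base network and the meta network, converts back to logPe units, and
#' attaches the ensemble spread (Eq.-style sample SD over the base
#' predictions), the inside/outside-domain flag, and the higher/lower
#' permeability class at the stored cutoff. Out-of-domain molecules are
#' still returned, only flagged.
#'
#' @param ensemble A [train_stacked_ensemble()] result.
#' @param table Raw descriptor table whose columns match the ensemble's
#'   descriptor manifest.
#' @return Tibble with `id`, `predicted_log_pe`, `sd`, `inside_domain`,
#'   `permeability_class`.
#' @export
predict_with_ad <- function(ensemble, table) {
  stopifnot(inherits(ensemble, "stacked_ensemble"))
  missing <- setdiff(ensemble$descriptor_manifest, names(table))
  if (length(missing)) {
    abort(paste0("input lacks manifest descriptors: ",
                 paste(missing, collapse = ", ")),
          class = "permstack_value_error")
  }
  table <- table[, c("molecule_id", ensemble$descriptor_manifest),
                 drop = FALSE]
  scaled <- apply_minmax_scaler(table, ensemble$scaling)
  X <- descriptor_matrix(scaled)[, ensemble$descriptor_manifest, drop = FALSE]
  base_pred <- vapply(ensemble$base_models, mlp_forward, numeric(nrow(X)),
                      x = X)
  if (nrow(X) == 1) base_pred <- matrix(base_pred, nrow = 1)
  meta_pred <- mlp_forward(ensemble$meta_model, base_pred)
  to_logpe <- function(v) v * diff(ensemble$y_range) + ensemble$y_range[1]
  pred_logpe <- to_logpe(meta_pred)
  sds <- ensemble_sd(to_logpe(base_pred))
  tibble::tibble(
    id = table$molecule_id,
    predicted_log_pe = pred_logpe,
    sd = sds,
    inside_domain = sds <= ensemble$ad_threshold,
    permeability_class = classify_permeability(pred_logpe, ensemble$cutoff)
  )
}

#' @export
glance.stacked_ensemble <- function(x, ...) {
  tibble::tibble(
    n_base = length(x$base_models),
    n_descriptors = length(x$descriptor_manifest),
    meta_feature_mode = x$meta_feature_mode,
    ad_threshold = x$ad_threshold,
    meta_error = x$traces$meta$final_error %||% NA_real_,
    meta_steps = x$traces$meta$steps %||% NA_integer_
  )
}

# ---- persistence ----------------------------------------------------------

num_out <- function(x) sprintf("%.17g", as.numeric(x))

model_to_list <- function(model) {
  list(
    layer_sizes = model$layer_sizes,
    weights = purrr::map(model$weights, function(w)
      list(dim = dim(w), values = num_out(t(w)))),  # row-major
    biases = purrr::map(model$biases, num_out),
    hidden_activation = model$hidden_activation,
    output_activation = model$output_activation,
    seed = model$seed
  )
}

model_from_list <- function(lst) {
  weights <- purrr::map(lst$weights, function(w) {
    d <- as.integer(unlist(w$dim))
    matrix(as.numeric(unlist(w$values)), d[1], d[2], byrow = TRUE)
  })
  structure(list(layer_sizes = as.integer(unlist(lst$layer_sizes)),
                 weights = weights,
                 biases = purrr::map(lst$biases,
                                     ~ as.numeric(unlist(.x))),
                 hidden_activation = lst$hidden_activation,
                 output_activation = lst$output_activation,
                 seed = as.integer(lst$seed)),
            class = "rprop_mlp")
}

#' Save / load a stacked ensemble
#'
#' Single JSON document (versioned schema) bundling the base and meta
#' network weights, scaling parameters, descriptor manifest, response range,
#' applicability-domain threshold, meta-feature mode and cutoff. Numbers are
#' written with 17 significant digits so a save/load round trip reproduces
#' predictions bit-exactly.
#'
#' @param ensemble A `stacked_ensemble`.
#' @param path File path for the JSON document.
#' @return `path`, invisibly / the restored `stacked_ensemble`.
#' @export
save_ensemble <- function(ensemble, path) {
  stopifnot(inherits(ensemble, "stacked_ensemble"))
  doc <- list(
    schema = ensemble$schema,
    base_models = purrr::map(ensemble$base_models, model_to_list),
    meta_model = model_to_list(ensemble$meta_model),
    scaling = list(descriptor = ensemble$scaling$stats$descriptor,
                   min = num_out(ensemble$scaling$stats$min),
                   max = num_out(ensemble$scaling$stats$max),
                   fitted_on = ensemble$scaling$fitted_on),
    y_range = num_out(ensemble$y_range),
    descriptor_manifest = ensemble$descriptor_manifest,
    ad_threshold = num_out(ensemble$ad_threshold),
    meta_feature_mode = ensemble$meta_feature_mode,
    cutoff = num_out(ensemble$cutoff)
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname save_ensemble
#' @export
load_ensemble <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("model file not found: ", path),
          class = "permstack_io_error")
  }
  doc <- tryCatch(jsonlite::read_json(path),
                  error = function(e) abort(
                    paste0("corrupt model file: ", conditionMessage(e)),
                    class = "permstack_io_error"))
  if (!identical(doc$schema, "permstack-ensemble/1")) {
    abort(paste0("unsupported model schema: ",
                 doc$schema %||% "<missing>"),
          class = "permstack_io_error")
  }
  stats_tbl <- tibble::tibble(
    descriptor = as.character(unlist(doc$scaling$descriptor)),
    min = as.numeric(unlist(doc$scaling$min)),
    max = as.numeric(unlist(doc$scaling$max))
  )
  stats_tbl$constant <- stats_tbl$min == stats_tbl$max
  scaler <- structure(list(stats = stats_tbl,
                           fitted_on = doc$scaling$fitted_on),
                      class = "minmax_scaler")
  base_models <- purrr::map(doc$base_models, model_from_list)
  structure(list(
    base_models = base_models,
    meta_model = model_from_list(doc$meta_model),
    base_specs = NULL, meta_spec = NULL,
    scaling = scaler,
    y_range = as.numeric(unlist(doc$y_range)),
    descriptor_manifest = as.character(unlist(doc$descriptor_manifest)),
    ad_threshold = as.numeric(unlist(doc$ad_threshold)),
    meta_feature_mode = doc$meta_feature_mode,
    cutoff = as.numeric(unlist(doc$cutoff)),
    traces = NULL,
    schema = doc$schema
  ), class = "stacked_ensemble")
}
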