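#' Run the full model-development and validation protocol
#'
#' End-to-end reproduction of the stacked-ensemble workflow on one dataset:
#' split molecules into train / test / external validation partitions,
#' min-max scale descriptors and response from the training data only,
#' cross-validate each base network on the training set (repeated k-fold,
#' statistics averaged over folds and repeats), train the stacked ensemble
#' on the training set, and evaluate every model by resubstitution and on
#' the held-out test and external sets. The result collects all metrics in
#' one tibble shaped like the classical four-section report (cv /
#' resubstitution / test / external), the fold-level correlation between the
#' base models, and the per-molecule predictions with applicability-domain
#' flags.
#'
#' @param descriptors Raw descriptor table (tibble with `molecule_id`);
#'   screened internally with [drop_nonfinite_columns()] and
#'   [drop_zero_variance()].
#' @param log_pe Observed logPe, aligned with `descriptors` rows.
#' @param manifest Optional character vector of descriptor names pinning the
#'   modelling subset (e.g. from [rfe_random_forest()]).
#' @param n_external,n_test,split_seed Partition sizes and seed (defaults:
#'   16 external, 33 test).
#' @param base_specs,meta_spec Network specifications.
#' @param mode Meta-feature mode for the stack.
#' @param k,repeats,cv_seed Cross-validation plan for the base-model
#'   evaluation.
#' @param run_cv Set `FALSE` to skip the (costly) cross-validated section.
#' @param cutoff Permeability class boundary.
#' @return Object of class `validation_report`.
#' @export
run_validation_protocol <- function(descriptors, log_pe, manifest = NULL,
                                    n_external = 16, n_test = 33,
                                    split_seed = 1,
                                    base_specs = default_base_specs(),
                                    meta_spec = default_meta_spec(),
                                    mode = "resubstitution",
                                    k = 20, repeats = 3, cv_seed = 1,
                                    run_cv = TRUE, cutoff = -6.2) {
  stopifnot(nrow(descriptors) == length(log_pe))
  tbl <- drop_zero_variance(drop_nonfinite_columns(descriptors))
  if (!is.null(manifest)) {
    missing <- setdiff(manifest, descriptor_columns(tbl))
    if (length(missing)) {
      abort(paste0("manifest descriptors not in table: ",
                   paste(missing, collapse = ", ")),
            class = "permstack_value_error")
    }
    tbl <- tbl[, c("molecule_id", manifest), drop = FALSE]
  }

  mol <- tibble::tibble(id = tbl$molecule_id, log_pe = log_pe)
  mol <- split_dataset(mol, n_external = n_external, n_test = n_test,
                       seed = split_seed)
  part <- mol$partition
  rows <- function(p) which(part == p)

  train_tbl <- tbl[rows("train"), , drop = FALSE]
  y_train <- log_pe[rows("train")]

  ensemble <- train_stacked_ensemble(
    train_tbl, y_train, base_specs = base_specs, meta_spec = meta_spec,
    mode = mode, k = k, repeats = repeats, seed = cv_seed, cutoff = cutoff)

  # ---- cross-validated section (base models, scaled units) ----------------
  metrics <- list()
  correlation_bases <- NA_real_
  if (run_cv) {
    scaled_train <- apply_minmax_scaler(train_tbl, ensemble$scaling)
    ys <- (y_train - ensemble$y_range[1]) / diff(ensemble$y_range)
    cv_rows <- purrr::map(base_specs, cv_evaluate_base, table = scaled_train,
                          y = ys, k = k, repeats = repeats, seed = cv_seed)
    per_fold <- purrr::map(cv_rows, ~ attr(.x, "per_fold"))
    if (length(per_fold) >= 2) {
      correlation_bases <- base_prediction_correlation(per_fold[[1]]$rmse,
                                                       per_fold[[2]]$rmse)
    }
    metrics <- c(metrics, cv_rows)
  }

  # ---- resubstitution / holdout sections (logPe units) --------------------
  base_predict <- function(model, tab) {
    scaled <- apply_minmax_scaler(tab, ensemble$scaling)
    mlp_forward(model, descriptor_matrix(scaled)) * diff(ensemble$y_range) +
      ensemble$y_range[1]
  }
  eval_on <- function(p, context) {
    tab <- tbl[rows(p), , drop = FALSE]
    obs <- log_pe[rows(p)]
    rows_out <- purrr::imap(ensemble$base_models, function(mdl, nm) {
      r <- summarize_metrics(obs, base_predict(mdl, tab), context)
      r$model <- nm
      r$partition <- p
      r
    })
    ens_pred <- predict_with_ad(ensemble, tab)
    r <- summarize_metrics(obs, ens_pred$predicted_log_pe, context)
    r$model <- "EnsembleNN"
    r$partition <- p
    c(rows_out, list(r))
  }
  metrics <- c(metrics, eval_on("train", "resubstitution"))
  if (n_test > 0) metrics <- c(metrics, eval_on("test", "holdout"))
  if (n_external > 0) metrics <- c(metrics, eval_on("external", "holdout"))
  metrics <- dplyr::bind_rows(metrics)
  if (!"partition" %in% names(metrics)) metrics$partition <- NA_character_
  metrics$partition[is.na(metrics$partition)] <- "train"

  predictions <- purrr::map_dfr(unique(part), function(p) {
    out <- predict_with_ad(ensemble, tbl[rows(p), , drop = FALSE])
    out$partition <- p
    out$observed_log_pe <- log_pe[rows(p)]
    out
  })

  structure(list(metrics = metrics,
                 base_rmse_correlation = correlation_bases,
                 ensemble = ensemble,
                 predictions = predictions,
                 split = attr(mol, "split"),
                 cutoff = cutoff),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report>\n")
  cols <- intersect(c("model", "context", "partition", "r2", "r2_cov",
                      "rmse", "pearson", "gini"), names(x$metrics))
  print(as.data.frame(x$metrics[, cols]), digits = 3, row.names = FALSE)
  if (is.finite(x$base_rmse_correlation)) {
    cat(sprintf("fold-RMSE correlation between base models: %.2f\n",
                x$base_rmse_correlation))
  }
  cat(sprintf("AD threshold: %.3f | outside domain: %d of %d molecules\n",
              x$ensemble$ad_threshold, sum(!x$predictions$inside_domain),
              nrow(x$predictions)))
  invisible(x)
}

#' @export
tidy.validation_report <- function(x, ...) x$metrics

#' @export
glance.validation_report <- function(x, ...) {
  hold <- x$metrics[x$metrics$model == "EnsembleNN" &
                      x$metrics$context == "holdout", , drop = FALSE]
  tibble::tibble(
    ensemble_test_pearson = hold$pearson[hold$partition == "test"][1],
    ensemble_external_pearson = hold$pearson[hold$partition == "external"][1],
    base_rmse_correlation = x$base_rmse_correlation,
    ad_threshold = x$ensemble$ad_threshold
  )
}

#' @rdname run_validation_protocol
#' @param object A `validation_report`.
#' @param ... Ignored.
#' @export
autoplot.validation_report <- function(object, ...) {
  df <- object$predictions
  ggplot2::ggplot(df, ggplot2::aes(x = .data$observed_log_pe,
                                   y = .data$predicted_log_pe,
                                   colour = .data$partition,
                                   shape = .data$inside_domain)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(x = "observed logPe (log10 cm/s)",
                  y = "ensemble predicted logPe",
                  shape = "inside AD",
                  title = "Stacked-ensemble predictions by partition")
}

#' Gain-curve plot
#'
#' Draws the cumulative gain curve of a prediction-sorted ordering against
#' the ideal outcome-sorted curve and the random-pick diagonal; the relative
#' Gini score is the ratio of the two curve areas above the diagonal.
#'
#' @inheritParams relative_gini
#' @return A ggplot object.
#' @export
plot_gain_curve <- function(observed, predicted) {
  v <- observed - min(observed)
  total <- sum(v)
  curve_pts <- function(scores, label) {
    o <- order(scores, decreasing = TRUE)
    tibble::tibble(frac_items = seq_along(v) / length(v),
                   frac_outcome = cumsum(v[o]) / total,
                   curve = label)
  }
  df <- dplyr::bind_rows(curve_pts(predicted, "model"),
                         curve_pts(v, "ideal"))
  df <- dplyr::bind_rows(tibble::tibble(frac_items = 0, frac_outcome = 0,
                                        curve = c("model", "ideal")), df)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$frac_items,
                                   y = .data$frac_outcome,
                                   colour = .data$curve)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 3) +
    ggplot2::geom_line() +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "fraction of molecules (sorted)",
      y = "fraction of total shifted outcome",
      title = sprintf("Gain curve (relative Gini = %.3f)",
                      relative_gini(observed, predicted)))
}

#' Applicability-domain plot
#'
#' Ensemble spread versus absolute prediction error per molecule, with the
#' 3x-max-training-SD threshold marked.
#'
#' @param report A `validation_report`.
#' @return A ggplot object.
#' @export
plot_ad <- function(report) {
  stopifnot(inherits(report, "validation_report"))
  df <- report$predictions
  df$abs_error <- abs(df$observed_log_pe - df$predicted_log_pe)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sd, y = .data$abs_error,
                                   colour = .data$partition)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_vline(xintercept = report$ensemble$ad_threshold,
                        linetype = 2) +
    ggplot2::labs(x = "ensemble SD (logPe units)",
                  y = "absolute prediction error",
                  title = "Applicability domain: spread vs error")
}
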