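#' Linear baseline on a descriptor subset
#'
#' Ordinary least squares with intercept on a small descriptor subset
#' (classically six structure-carrying descriptors), evaluated under the
#' same repeated cross-validation plan as the networks plus resubstitution,
#' and optionally on held-out data. Serves as the interpretable yardstick
#' the nonlinear stack is compared against.
#'
#' @param table Descriptor table (the subset columns only) with
#'   `molecule_id`.
#' @param y Numeric response.
#' @param k,repeats,seed Cross-validation plan.
#' @param holdout Optional list with elements `table` and `y` for a holdout
#'   evaluation row.
#' @return Object of class `linear_baseline`: list with `fit` (the `lm`),
#'   `coefficients` tibble and `metrics` (tibble with contexts `cv`,
#'   `resubstitution` and optionally `holdout`).
#' @export
fit_linear_baseline <- function(table, y, k = 20, repeats = 3, seed = 1,
                                holdout = NULL) {
  m <- descriptor_matrix(table)
  if (ncol(m) < 2) {
    abort("need at least 2 descriptors", class = "permstack_value_error")
  }
  if (nrow(m) <= ncol(m)) {
    abort("need more molecules than descriptors",
          class = "permstack_value_error")
  }
  df <- as.data.frame(m)
  df$.y <- y
  fit <- stats::lm(.y ~ ., data = df)
  if (any(is.na(stats::coef(fit)))) {
    abort("rank-deficient design", class = "permstack_value_error")
  }

  folds <- make_repeated_folds(nrow(m), k = k, repeats = repeats, seed = seed)
  resamples <- fold_index_list(folds)
  per_fold <- purrr::map_dfr(resamples, function(val_rows) {
    train_rows <- setdiff(seq_len(nrow(m)), val_rows)
    f <- stats::lm(.y ~ ., data = df[train_rows, , drop = FALSE])
    pred <- stats::predict(f, df[val_rows, , drop = FALSE])
    fold_metrics(y[val_rows], pred)
  })
  cv_row <- dplyr::summarise(per_fold, dplyr::across(
    dplyr::everything(), ~ mean(.x, na.rm = TRUE)))
  cv_row$n <- length(y)
  cv_row$context <- "cv"
  resub <- summarize_metrics(y, stats::fitted(fit), "resubstitution")
  metrics <- dplyr::bind_rows(cv_row, resub)
  if (!is.null(holdout)) {
    hm <- as.data.frame(descriptor_matrix(holdout$table))
    pred <- stats::predict(fit, hm)
    metrics <- dplyr::bind_rows(metrics,
                                summarize_metrics(holdout$y, pred, "holdout"))
  }
  structure(list(
    fit = fit,
    coefficients = tibble::tibble(term = names(stats::coef(fit)),
                                  estimate = as.numeric(stats::coef(fit))),
    metrics = metrics
  ), class = "linear_baseline")
}

#' @export
print.linear_baseline <- function(x, ...) {
  cat("<linear_baseline>", nrow(x$coefficients) - 1, "descriptors\n")
  print(x$metrics[, c("context", "r2", "r2_cov", "rmse", "pearson")])
  invisible(x)
}

#' @export
tidy.linear_baseline <- function(x, ...) x$coefficients

#' @export
glance.linear_baseline <- function(x, ...) x$metrics

#' Interpretable surrogate regression tree
#'
#' Fits a single CART regression tree on centred and scaled descriptors so
#' the descriptor thresholds behind high/low permeability are readable. Each
#' leaf reports its mean logPe, molecule count and percentage, and is
#' classified higher/lower by comparing the leaf mean to the cutoff.
#'
#' @param table Descriptor table with `molecule_id`.
#' @param y Observed logPe values.
#' @param cutoff Class boundary (default -6.2).
#' @param ... Passed to [rpart::rpart.control()] (e.g. `maxdepth`,
#'   `minsplit`, `cp`); the defaults give a readable tree of roughly a dozen
#'   leaves on a ~200-molecule table.
#' @return Object of class `surrogate_tree`: list with `tree` (the rpart
#'   fit), `leaves` tibble and `class_counts`.
#' @export
surrogate_tree <- function(table, y, cutoff = -6.2, ...) {
  m <- descriptor_matrix(table)
  if (stats::sd(y) == 0) {
    abort("constant response", class = "permstack_value_error")
  }
  ms <- scale(m)
  ms[, attr(ms, "scaled:scale") == 0] <- 0   # constant columns stay 0
  df <- as.data.frame(ms)
  df$.y <- y
  control <- rpart::rpart.control(...)
  tree <- rpart::rpart(.y ~ ., data = df, method = "anova",
                       control = control)
  leaf_of <- tree$where
  leaves <- tibble::as_tibble(stats::aggregate(
    y, by = list(leaf = leaf_of),
    FUN = function(v) c(n = length(v), mean = mean(v))))
  leaves <- tibble::tibble(
    leaf = leaves$leaf,
    n = as.integer(leaves$x[, "n"]),
    mean_log_pe = leaves$x[, "mean"]
  )
  leaves$pct = 100 * leaves$n / length(y)
  leaves$class <- classify_permeability(leaves$mean_log_pe, cutoff)
  counts <- tibble::tibble(
    n_higher = sum(leaves$n[leaves$class == "higher"]),
    n_lower = sum(leaves$n[leaves$class == "lower"])
  )
  structure(list(tree = tree, leaves = leaves, class_counts = counts,
                 cutoff = cutoff),
            class = "surrogate_tree")
}

#' @export
print.surrogate_tree <- function(x, ...) {
  cat("<surrogate_tree>", nrow(x$leaves), "leaves;",
      x$class_counts$n_higher, "molecules in higher-permeability leaves,",
      x$class_counts$n_lower, "in lower (cutoff", x$cutoff, ")\n")
  invisible(x)
}

#' @export
tidy.surrogate_tree <- function(x, ...) x$leaves
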