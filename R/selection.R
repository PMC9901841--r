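#' Repeated k-fold cross-validation assignments
#'
#' Builds `repeats` independent complete partitions of `1:n` into `k` folds
#' whose sizes differ by at most one, using a single seeded random stream.
#'
#' @param n Number of samples.
#' @param k Folds per repeat (default 20).
#' @param repeats Number of repeats (default 3).
#' @param seed Integer seed.
#' @return Tibble with columns `repeat_id`, `fold`, `row`; within each
#'   repeat every row index appears in exactly one fold.
#' @export
make_repeated_folds <- function(n, k = 20, repeats = 3, seed = 1) {
  if (k < 2 || k > n) {
    abort("need 2 <= k <= n", class = "permstack_value_error")
  }
  withr::with_seed(seed, {
    purrr::map_dfr(seq_len(repeats), function(r) {
      fold <- sample(rep(seq_len(k), length.out = n))
      tibble::tibble(repeat_id = r, fold = fold, row = seq_len(n))
    })
  })
}

fold_index_list <- function(folds) {
  split(folds$row, interaction(folds$repeat_id, folds$fold, drop = TRUE))
}

#' Random-forest descriptor importance
#'
#' Scores every descriptor with a seeded regression random forest. Impurity
#' importance (total decrease in node variance) is the default; permutation
#' importance (out-of-bag MSE increase) is available as well.
#'
#' @param table Descriptor table (tibble with `molecule_id` + numeric
#'   columns).
#' @param y Numeric response, one value per molecule.
#' @param seed Integer seed for the forest.
#' @param type `"impurity"` or `"permutation"`.
#' @param ntree Number of trees (default 500).
#' @return Tibble with `descriptor` and `importance`, sorted decreasing.
#' @export
rf_importance <- function(table, y, seed = 1, type = c("impurity", "permutation"),
                          ntree = 500) {
  type <- match.arg(type)
  m <- descriptor_matrix(table)
  if (length(y) != nrow(m)) {
    abort("length(y) must match the number of molecules",
          class = "permstack_value_error")
  }
  if (stats::sd(y) == 0) {
    abort("constant response; importance undefined",
          class = "permstack_value_error")
  }
  fit <- withr::with_seed(seed, randomForest::randomForest(
    x = m, y = y, ntree = ntree, importance = (type == "permutation")))
  imp <- randomForest::importance(
    fit, type = if (type == "permutation") 1 else 2)
  out <- tibble::tibble(descriptor = rownames(imp),
                        importance = as.numeric(imp[, 1]))
  dplyr::arrange(out, dplyr::desc(.data$importance))
}

#' Recursive feature elimination with random forests
#'
#' Backwards descriptor selection under repeated k-fold cross-validation.
#' Inside every resample a forest is fit on the analysis rows only, the
#' descriptors are ranked by importance, and for each candidate subset size
#' a fresh forest on the top-ranked descriptors is scored by RMSE on the
#' held-out fold. Per-size RMSE is averaged across all folds and repeats;
#' the size with the smallest average wins, with ties broken toward the
#' smaller (more parsimonious) subset. The final ranking is refit on all
#' rows to name the chosen descriptors. Because ranking is recomputed inside
#' each resample, no information from a validation fold ever influences the
#' subset evaluated on it.
#'
#' @inheritParams rf_importance
#' @param sizes Candidate subset sizes; defaults to a doubling grid
#'   `1, 2, 4, ...` capped and completed by the full descriptor count.
#' @param k,repeats,seed Cross-validation plan (see [make_repeated_folds()]).
#' @param ntree Trees per forest fit.
#' @param importance_type Passed to the per-resample ranking forest.
#' @return An object of class `rfe_profile`: list with `profile` (tibble
#'   `size`, `rmse_cv`), `chosen_size`, `chosen_descriptors`,
#'   `final_ranking`, and the plan parameters.
#' @export
rfe_random_forest <- function(table, y, sizes = NULL, k = 20, repeats = 3,
                              seed = 1, ntree = 500,
                              importance_type = c("impurity", "permutation")) {
  importance_type <- match.arg(importance_type)
  m <- descriptor_matrix(table)
  p <- ncol(m)
  n <- nrow(m)
  if (is.null(sizes)) {
    sizes <- unique(c(2^(0:floor(log2(p))), p))
  }
  sizes <- sort(unique(as.integer(sizes)))
  if (length(sizes) == 0 || any(sizes < 1) || any(sizes > p)) {
    abort("candidate sizes must lie in [1, n_descriptors]",
          class = "permstack_value_error")
  }
  folds <- make_repeated_folds(n, k = k, repeats = repeats, seed = seed)
  resamples <- fold_index_list(folds)

  rank_in <- function(rows, seed_i) {
    fit <- withr::with_seed(seed_i, randomForest::randomForest(
      x = m[rows, , drop = FALSE], y = y[rows], ntree = ntree,
      importance = (importance_type == "permutation")))
    imp <- randomForest::importance(
      fit, type = if (importance_type == "permutation") 1 else 2)
    colnames(m)[order(imp[, 1], decreasing = TRUE)]
  }

  per_resample <- purrr::imap(resamples, function(val_rows, key) {
    seed_i <- seed + 7919L * match(key, names(resamples))
    train_rows <- setdiff(seq_len(n), val_rows)
    ranking <- rank_in(train_rows, seed_i)
    vapply(sizes, function(s) {
      keep <- ranking[seq_len(s)]
      fit <- withr::with_seed(seed_i + s, randomForest::randomForest(
        x = m[train_rows, keep, drop = FALSE], y = y[train_rows],
        ntree = ntree))
      pred <- stats::predict(fit, m[val_rows, keep, drop = FALSE])
      rmse(y[val_rows], pred)
    }, numeric(1))
  })

  rmse_by_size <- Reduce(`+`, per_resample) / length(per_resample)
  profile <- tibble::tibble(size = sizes, rmse_cv = rmse_by_size)
  # smallest size among the minima (parsimony tie-break)
  chosen_size <- min(profile$size[profile$rmse_cv == min(profile$rmse_cv)])
  final_ranking <- rank_in(seq_len(n), seed)
  structure(list(profile = profile,
                 chosen_size = chosen_size,
                 chosen_descriptors = final_ranking[seq_len(chosen_size)],
                 final_ranking = final_ranking,
                 k = k, repeats = repeats, seed = seed, ntree = ntree,
                 importance_type = importance_type),
            class = "rfe_profile")
}

#' @export
print.rfe_profile <- function(x, ...) {
  cat("<rfe_profile>", nrow(x$profile), "candidate sizes;",
      "chosen:", x$chosen_size, "descriptors",
      sprintf("(RMSE_cv %.4f)\n",
              x$profile$rmse_cv[x$profile$size == x$chosen_size]))
  invisible(x)
}

#' @export
tidy.rfe_profile <- function(x, ...) {
  dplyr::mutate(x$profile, chosen = .data$size == x$chosen_size)
}

#' @export
glance.rfe_profile <- function(x, ...) {
  tibble::tibble(chosen_size = x$chosen_size,
                 rmse_cv = min(x$profile$rmse_cv),
                 k = x$k, repeats = x$repeats, seed = x$seed)
}

#' @rdname rfe_random_forest
#' @param object An `rfe_profile`.
#' @param ... Ignored.
#' @export
autoplot.rfe_profile <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$size, y = .data$rmse_cv)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$chosen), size = 2) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#D55E00",
                                            `FALSE` = "grey30"),
                                 guide = "none") +
    ggplot2::labs(x = "descriptor subset size",
                  y = "cross-validated RMSE",
                  title = "Recursive feature elimination profile")
}

#' Write / read a descriptor manifest
#'
#' A manifest is a plain-text list of descriptor names (one per line) that
#' pins the modelling subset, bypassing stochastic re-selection.
#'
#' @param descriptors Character vector of descriptor names.
#' @param path File path.
#' @return `path` / the name vector.
#' @export
write_manifest <- function(descriptors, path) {
  writeLines(descriptors, path)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  x <- readLines(path)
  x[nzchar(trimws(x))]
}
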