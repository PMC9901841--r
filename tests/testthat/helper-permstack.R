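# Shared fixture builders: everything is generated in code, no data files.

# Wrap a numeric matrix as a descriptor table.
as_dtable <- function(m, ids = NULL) {
  if (is.null(colnames(m))) colnames(m) <- sprintf("V%02d", seq_len(ncol(m)))
  dplyr::bind_cols(
    tibble::tibble(molecule_id = ids %||% sprintf("M%03d", seq_len(nrow(m)))),
    tibble::as_tibble(m)
  )
}

`%||%` <- rlang::`%||%`

# A compact synthetic dataset for model tests.
small_dataset <- function(seed = 1, n = 120, p = 20) {
  generate_descriptor_dataset(synthetic_spec(
    n_molecules = n, n_descriptors = p, n_informative = min(5, p),
    n_constant = if (p >= 16) 2 else 0,
    correlated_block_size = if (p >= 16) 4 else 0,
    block_correlation = 0.9, noise_sd = 0.1, seed = seed))
}

# Small, fast network specs for ensemble tests.
small_base_specs <- function(seed = 1, max_steps = 800) {
  list(
    base_learner_spec("A", c(6, 3),
                      rprop_config(seed = seed, max_steps = max_steps)),
    base_learner_spec("B", c(10, 4),
                      rprop_config(seed = seed + 50, max_steps = max_steps))
  )
}

small_meta_spec <- function(seed = 99, max_steps = 800) {
  base_learner_spec("meta", c(2, 1),
                    rprop_config(seed = seed, max_steps = max_steps))
}

# Independent brute-force gain-curve area: per-item trapezoids, averaging
# over all orderings of tied prediction groups by explicit enumeration.
oracle_relative_gini <- function(observed, predicted) {
  v <- observed - min(observed)
  total <- sum(v)
  n <- length(v)
  area_for_order <- function(idx) {
    cum <- cumsum(v[idx]) / total
    y_prev <- c(0, cum[-n])
    sum((1 / n) * (y_prev + (cum - y_prev) / 2))
  }
  avg_area <- function(scores) {
    # enumerate all orderings consistent with decreasing scores
    groups <- split(seq_len(n), -rank(scores, ties.method = "min"))
    perms_of <- function(x) {
      if (length(x) <= 1) return(list(x))
      do.call(c, lapply(seq_along(x), function(i)
        lapply(perms_of(x[-i]), function(r) c(x[i], r))))
    }
    orderings <- Reduce(function(acc, g) {
      do.call(c, lapply(acc, function(a)
        lapply(perms_of(g), function(pg) c(a, pg))))
    }, groups, accumulate = FALSE, init = list(integer(0)))
    mean(vapply(orderings, area_for_order, numeric(1)))
  }
  (avg_area(predicted) - 0.5) / (avg_area(v) - 0.5)
}
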