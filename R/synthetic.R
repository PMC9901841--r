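#' Specification for a synthetic descriptor/permeability dataset
#'
#' Describes a descriptor table that emulates the structure of a curated
#' PAMPA QSAR dataset: a handful of informative descriptors driving logPe
#' through a smooth nonlinear signal, one block of highly correlated
#' redundant columns, zero-variance columns, remaining columns pure noise,
#' and Gaussian measurement noise on the response. The defaults mirror the
#' regime the pipeline is designed for: 190 molecules, logPe centred on the
#' -6.2 permeability cutoff and spanning roughly -8.5 to -4.5 so the two
#' permeability classes are roughly balanced, and 0.2 log-unit response
#' noise (the order of PAMPA inter-replicate reproducibility).
#'
#' @param n_molecules,n_descriptors Table dimensions.
#' @param n_informative Number of descriptors carrying signal.
#' @param n_constant Number of zero-variance (all-zero) columns.
#' @param correlated_block_size Columns in the redundant correlated block.
#' @param block_correlation Target pairwise correlation inside the block.
#' @param noise_sd Gaussian SD added to the response (log10 units).
#' @param logpe_center,logpe_spread Centre and scale of the response signal.
#' @param seed Integer seed; generation is bit-reproducible per seed.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_molecules = 190, n_descriptors = 100,
                           n_informative = 5, n_constant = 5,
                           correlated_block_size = 10,
                           block_correlation = 0.9,
                           noise_sd = 0.2,
                           logpe_center = -6.2, logpe_spread = 0.9,
                           seed = 1) {
  if (n_informative + n_constant + correlated_block_size > n_descriptors) {
    abort("informative + constant + block columns exceed n_descriptors",
          class = "permstack_value_error")
  }
  if (block_correlation <= 0 || block_correlation >= 1) {
    abort("block_correlation must be in (0, 1)",
          class = "permstack_value_error")
  }
  if (noise_sd < 0) {
    abort("noise_sd must be non-negative", class = "permstack_value_error")
  }
  structure(list(n_molecules = n_molecules, n_descriptors = n_descriptors,
                 n_informative = n_informative, n_constant = n_constant,
                 correlated_block_size = correlated_block_size,
                 block_correlation = block_correlation, noise_sd = noise_sd,
                 logpe_center = logpe_center, logpe_spread = logpe_spread,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a synthetic descriptor dataset with known ground truth
#'
#' Informative descriptors drive logPe through a sum of linear terms, one
#' pairwise interaction and one saturating nonlinearity — rich enough that a
#' nonlinear stacked model can beat a linear baseline. The signal is
#' standardised, placed at `logpe_center` with scale `logpe_spread`, and
#' Gaussian noise of SD `noise_sd` is added. One block of columns shares a
#' latent factor so its pairwise correlations sit near `block_correlation`,
#' and `n_constant` all-zero columns emulate never-triggered descriptors.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `descriptors` (tibble with `molecule_id`), `log_pe`
#'   (observed, noisy), and `truth`: informative/constant/block column
#'   names, the noise draws, the noise-free signal (`bayes`, the best
#'   possible prediction), and the spec.
#' @export
generate_descriptor_dataset <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n <- spec$n_molecules
  p <- spec$n_descriptors
  withr::with_seed(spec$seed, {
    X <- matrix(stats::rnorm(n * p), n, p)
    colnames(X) <- sprintf("D%03d", seq_len(p))

    cols <- sample(colnames(X))
    informative <- sort(cols[seq_len(spec$n_informative)])
    constant <- sort(cols[spec$n_informative + seq_len(spec$n_constant)])
    block <- sort(cols[spec$n_informative + spec$n_constant +
                         seq_len(spec$correlated_block_size)])

    # redundant block: shared latent factor + independent residual
    u <- stats::rnorm(n)
    rho <- spec$block_correlation
    for (b in block) {
      X[, b] <- sqrt(rho) * u + sqrt(1 - rho) * stats::rnorm(n)
    }
    X[, constant] <- 0

    if (spec$n_informative > 0 && spec$logpe_spread > 0) {
      # recycle informative columns when fewer than the five signal slots
      z <- X[, informative[(0:4) %% spec$n_informative + 1], drop = FALSE]
      raw <- z[, 1] + 0.8 * z[, 2] + 0.8 * z[, 4] * z[, 5] +
        1.2 * tanh(1.5 * z[, 3])
      signal <- spec$logpe_center +
        spec$logpe_spread * (raw - mean(raw)) / stats::sd(raw)
    } else {
      signal <- rep(spec$logpe_center, n)
    }
    noise <- stats::rnorm(n, sd = spec$noise_sd)
  })
  log_pe <- signal + noise
  descriptors <- dplyr::bind_cols(
    tibble::tibble(molecule_id = sprintf("M%03d", seq_len(n))),
    tibble::as_tibble(X)
  )
  attr(descriptors, "backend") <- "synthetic"
  list(descriptors = descriptors,
       log_pe = log_pe,
       truth = list(informative = informative, constant = constant,
                    block = block, noise = noise, bayes = signal,
                    spec = spec))
}

#' Default PAMPA instrument settings
#'
#' A typical 96-well sandwich configuration: 0.3 cm^3 donor and acceptor
#' volumes, 0.3 cm^2 membrane area, 4 h incubation, no lag time, unit
#' porosity, unit initial donor concentration.
#'
#' @return Named list of instrument parameters.
#' @export
pampa_instrument <- function() {
  list(v_d = 0.3, v_a = 0.3, area = 0.3, time_s = 14400,
       tau_ss = 0, epsilon_a = 1, c_d0 = 1)
}

#' Generate raw PAMPA measurements that reproduce given logPe values
#'
#' Inverts the logPe equation: for each requested logPe the acceptor
#' concentration is solved from the inner bracket, and the donor
#' concentration from the requested retention, so that
#' [effective_log_permeability()] on the generated wells recovers the
#' request to machine precision. Requests for which the inner bracket
#' collapses below `min_bracket` (compound essentially equilibrated within
#' the incubation time — too fast for the setup) or is not admissible are
#' rejected.
#'
#' @param log_pe Numeric vector of target logPe values (log10 cm/s).
#' @param instrument Instrument settings, see [pampa_instrument()].
#' @param r_m Requested membrane retention (scalar or per-molecule), < 1.
#' @param min_bracket Smallest admissible inner-bracket value.
#' @return A measurement tibble (one row per logPe) accepted by
#'   [pampa_evaluate()].
#' @export
generate_pampa_measurements <- function(log_pe, instrument = pampa_instrument(),
                                        r_m = 0.1, min_bracket = 1e-9) {
  ins <- utils::modifyList(pampa_instrument(), as.list(instrument))
  r_v <- ins$v_d / ins$v_a
  r_m <- rep_len(r_m, length(log_pe))
  if (any(r_m >= 1)) {
    abort("requested retention must be < 1", class = "permstack_value_error")
  }
  prefactor <- -(2.303 * ins$v_d) /
    (ins$area * (ins$time_s - ins$tau_ss) * ins$epsilon_a) * (1 / (1 + r_v))
  pe <- 10^log_pe
  bracket <- 10^(pe / prefactor)
  bad <- bracket <= min_bracket | bracket >= 1
  if (any(bad)) {
    abort(sprintf(
      "%d logPe value(s) inadmissible for these instrument settings (first: %g)",
      sum(bad), log_pe[which(bad)[1]]), class = "permstack_value_error")
  }
  c_a_t <- (1 - bracket) * (1 - r_m) / (1 + 1 / r_v) * ins$c_d0
  c_d_t <- ins$c_d0 * (1 - r_m + (ins$v_a * c_a_t) / (ins$v_d * ins$c_d0))
  pampa_measurements(
    v_d = ins$v_d, v_a = ins$v_a, area = ins$area, time_s = ins$time_s,
    tau_ss = ins$tau_ss, epsilon_a = ins$epsilon_a, c_d0 = ins$c_d0,
    c_a_t = c_a_t, c_d_t = c_d_t
  )
}

#' Add seeded Gaussian noise to logPe values
#'
#' Emulates rising measurement noise in the training response for
#' robustness analyses; `noise_sd = 0` returns the input unchanged.
#'
#' @param log_pe Numeric vector.
#' @param noise_sd Standard deviation of the perturbation.
#' @param seed Integer seed.
#' @return Perturbed vector of the same length.
#' @export
add_output_noise <- function(log_pe, noise_sd, seed = 1) {
  if (noise_sd < 0) {
    abort("noise_sd must be non-negative", class = "permstack_value_error")
  }
  if (noise_sd == 0) return(log_pe)
  withr::with_seed(seed, log_pe + stats::rnorm(length(log_pe), sd = noise_sd))
}
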