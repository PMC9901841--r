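#' Assemble a PAMPA measurement table
#'
#' Validates and normalises a table of raw PAMPA well measurements. Units
#' are cm, s and cm^3; concentrations enter the equations only as ratios, so
#' any single consistent concentration unit is accepted.
#'
#' @param v_d,v_a Donor and acceptor volumes (cm^3), positive.
#' @param area Membrane area (cm^2), positive.
#' @param time_s Experiment time point (s), must exceed `tau_ss`.
#' @param tau_ss Lag time (s), non-negative.
#' @param epsilon_a Apparent membrane porosity (dimensionless), positive.
#' @param c_d0 Initial donor concentration, positive.
#' @param c_a_t Acceptor concentration at `time_s`, non-negative.
#' @param c_d_t Donor concentration at `time_s`, non-negative.
#' @return Tibble of class-checked measurements, one row per well.
#' @export
pampa_measurements <- function(v_d, v_a, area, time_s, tau_ss = 0,
                               epsilon_a = 1, c_d0 = 1, c_a_t, c_d_t) {
  m <- tibble::tibble(v_d = v_d, v_a = v_a, area = area, time_s = time_s,
                      tau_ss = tau_ss, epsilon_a = epsilon_a, c_d0 = c_d0,
                      c_a_t = c_a_t, c_d_t = c_d_t)
  validate_pampa(m)
  m
}

validate_pampa <- function(m) {
  need <- c("v_d", "v_a", "area", "time_s", "tau_ss", "epsilon_a",
            "c_d0", "c_a_t", "c_d_t")
  missing <- setdiff(need, names(m))
  if (length(missing)) {
    abort(paste0("measurement table lacks columns: ",
                 paste(missing, collapse = ", ")),
          class = "permstack_value_error")
  }
  with(m, {
    if (any(v_d <= 0 | v_a <= 0 | area <= 0 | epsilon_a <= 0 | c_d0 <= 0)) {
      abort("volumes, area, porosity and C_D(0) must be strictly positive",
            class = "permstack_value_error")
    }
    if (any(time_s <= tau_ss)) {
      abort("experiment time must exceed the lag time",
            class = "permstack_value_error")
    }
    if (any(c_a_t < 0 | c_d_t < 0)) {
      abort("concentrations must be non-negative",
            class = "permstack_value_error")
    }
  })
  invisible(m)
}

#' Membrane retention ratio
#'
#' Fraction of compound lost to the membrane, from donor/acceptor mass
#' accounting. The `"printed"` form is
#' `R_M = 1 - (C_D(t)/C_D(0) - V_A C_A(t) / (V_D C_D(0)))`; the
#' `"mass_balance"` form subtracts the acceptor term instead
#' (`1 - C_D(t)/C_D(0) - V_A C_A(t) / (V_D C_D(0))`), the version a strict
#' mass balance gives. The printed form is the default; both are exposed
#' because the two differ only in the sign of the acceptor term and sources
#' disagree.
#'
#' @param m Measurement tibble (see [pampa_measurements()]).
#' @param form `"printed"` (default) or `"mass_balance"`.
#' @return Numeric vector of retention ratios, one per row.
#' @export
membrane_retention <- function(m, form = c("printed", "mass_balance")) {
  form <- match.arg(form)
  validate_pampa(m)
  donor <- m$c_d_t / m$c_d0
  acceptor <- (m$v_a * m$c_a_t) / (m$v_d * m$c_d0)
  if (form == "printed") 1 - (donor - acceptor) else 1 - donor - acceptor
}

#' Effective membrane permeability coefficient (logPe)
#'
#' Converts raw PAMPA well measurements to `log10(Pe)` with Pe in cm/s:
#' \deqn{P_e = -\frac{2.303\,V_D}{A\,(t-\tau_{ss})\,\varepsilon_a}\cdot
#'   \frac{1}{1+r_v}\cdot
#'   \log_{10}\!\left[1-\frac{1+r_v^{-1}}{1-R_M}\cdot
#'   \frac{C_A(t)}{C_D(0)}\right],\quad r_v = V_D/V_A.}
#' Rows where the formula does not apply are returned as `NA` with a status:
#' `"no_permeation"` when `C_A(t) = 0` (Pe would be exactly zero, logPe
#' undefined), `"invalid_retention"` when `R_M >= 1`, and
#' `"out_of_validity"` when the inner bracket falls outside (0, 1) —
#' transport too fast or inconsistent concentrations.
#'
#' @inheritParams membrane_retention
#' @param retention Optional retention values; computed from the
#'   concentrations via `form` when omitted.
#' @return Numeric vector of logPe values (`NA` where inapplicable), with
#'   the per-row status in attribute `"status"`. Use [pampa_evaluate()] for
#'   a tidy table.
#' @export
effective_log_permeability <- function(m, retention = NULL,
                                       form = c("printed", "mass_balance")) {
  form <- match.arg(form)
  validate_pampa(m)
  r_m <- retention %||% membrane_retention(m, form)
  r_v <- m$v_d / m$v_a
  status <- rep("ok", nrow(m))
  status[m$c_a_t == 0] <- "no_permeation"
  status[r_m >= 1] <- "invalid_retention"
  bracket <- 1 - ((1 + 1 / r_v) / (1 - r_m)) * (m$c_a_t / m$c_d0)
  bad <- status == "ok" & (bracket <= 0 | bracket >= 1)
  status[bad] <- "out_of_validity"
  prefactor <- -(2.303 * m$v_d) /
    (m$area * (m$time_s - m$tau_ss) * m$epsilon_a) * (1 / (1 + r_v))
  pe <- prefactor * log10(ifelse(status == "ok", bracket, NA_real_))
  log_pe <- ifelse(status == "ok" & pe > 0, log10(pe), NA_real_)
  status[status == "ok" & is.na(log_pe)] <- "out_of_validity"
  structure(log_pe, status = status)
}

#' Classify permeability at a logPe cutoff
#'
#' `"higher"` when `log_pe >= cutoff` (the boundary itself counts as
#' higher), `"lower"` otherwise.
#'
#' @param log_pe Numeric logPe values (finite).
#' @param cutoff Class boundary, default -6.2.
#' @return Character vector of `"higher"` / `"lower"`.
#' @export
classify_permeability <- function(log_pe, cutoff = -6.2) {
  if (any(!is.finite(log_pe))) {
    abort("non-finite logPe cannot be classified",
          class = "permstack_value_error")
  }
  ifelse(log_pe >= cutoff, "higher", "lower")
}

#' Count molecules in each permeability class
#'
#' @param molecules Tibble with an observed `log_pe` column (no missing
#'   values).
#' @param cutoff Class boundary, default -6.2.
#' @return One-row tibble with `n_higher`, `n_lower`, `n`.
#' @export
count_permeability_classes <- function(molecules, cutoff = -6.2) {
  if (!"log_pe" %in% names(molecules) || anyNA(molecules$log_pe)) {
    abort("all records need an observed log_pe",
          class = "permstack_value_error")
  }
  if (nrow(molecules) == 0) {
    return(tibble::tibble(n_higher = 0L, n_lower = 0L, n = 0L))
  }
  cls <- classify_permeability(molecules$log_pe, cutoff)
  tibble::tibble(n_higher = sum(cls == "higher"),
                 n_lower = sum(cls == "lower"),
                 n = length(cls))
}

#' Evaluate a table of raw PAMPA measurements
#'
#' Tidy wrapper: appends retention, logPe, a per-row status and (where
#' logPe is defined) the permeability class to the measurement table.
#'
#' @inheritParams membrane_retention
#' @param cutoff Class boundary, default -6.2.
#' @return The measurement tibble with columns `r_m`, `log_pe`, `status`,
#'   `permeability_class` appended.
#' @export
pampa_evaluate <- function(m, form = c("printed", "mass_balance"),
                           cutoff = -6.2) {
  form <- match.arg(form)
  r_m <- membrane_retention(m, form)
  log_pe <- effective_log_permeability(m, retention = r_m, form = form)
  status <- attr(log_pe, "status")
  out <- m
  out$r_m <- r_m
  out$log_pe <- as.numeric(log_pe)
  out$status <- status
  out$permeability_class <- ifelse(
    status == "ok", classify_permeability(ifelse(is.na(out$log_pe), cutoff,
                                                 out$log_pe), cutoff),
    status)
  out$permeability_class[status != "ok"] <- status[status != "ok"]
  out
}
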