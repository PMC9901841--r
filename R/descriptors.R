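#' Compute molecular descriptors for a molecule table
#'
#' Calculates a numeric descriptor vector per molecule with the
#' ChemmineR/ChemmineOB (OpenBabel) backend: physicochemical properties
#' (`MW`, `logP`, `MR`, `TPSA`, hydrogen-bond donor/acceptor counts),
#' functional-group counts (including `nAcid`, the carboxylic-acid count),
#' element counts, ring and aromatic-ring counts, and bond counts. Names map
#' onto the usual QSAR vocabulary: `nHBDon` is the donor count, `nHBAcc` the
#' acceptor count, `TopoPSA` the topological polar surface area, `logP` the
#' octanol/water partition coefficient (the XLogP/ALogP family), `nAcid` the
#' acid-group count. Values the backend cannot compute are stored as `NaN`
#' and should be removed with [drop_nonfinite_columns()] before modelling.
#'
#' @param molecules Molecule tibble from [read_molecule_table()] (columns
#'   `id`, `smiles`).
#' @param backend Descriptor engine; only `"chemmine"` is built in.
#' @return A descriptor table: tibble with `molecule_id` plus one numeric
#'   column per descriptor, with the backend recorded in attribute
#'   `"backend"`.
#' @examples
#' \dontrun{
#' mols <- tibble::tibble(id = c("ethanol", "benzene"),
#'                        smiles = c("CCO", "c1ccccc1"))
#' compute_descriptors(mols)
#' }
#' @export
compute_descriptors <- function(molecules, backend = "chemmine") {
  backend <- match.arg(backend, "chemmine")
  if (nrow(molecules) == 0) {
    abort("no molecules to compute descriptors for",
          class = "permstack_value_error")
  }
  require_chem_backend()

  sdfset <- suppressWarnings(ChemmineR::smiles2sdf(
    stats::setNames(molecules$smiles, molecules$id)))
  if (length(sdfset) != nrow(molecules)) {
    abort("SMILES parsing failed for some molecules; validate input first",
          class = "permstack_backend_error")
  }

  prop <- ChemmineR::propOB(sdfset)
  phys <- tibble::tibble(
    MW = as.numeric(prop$MW),
    logP = as.numeric(prop$logP),
    MR = as.numeric(prop$MR),
    TopoPSA = as.numeric(prop$TPSA),
    nHBDon = as.numeric(prop$HBD),
    nHBAcc = as.numeric(prop$HBA1),
    nHBAcc2 = as.numeric(prop$HBA2),
    nF = as.numeric(prop$nF)
  )

  grp <- as.data.frame(ChemmineR::groups(sdfset, groups = "fctgroup",
                                         type = "countMA"))
  names(grp) <- paste0("n", names(grp))
  names(grp)[names(grp) == "nRCOOH"] <- "nAcid"

  atoms <- as.data.frame(ChemmineR::atomcountMA(sdfset, addH = TRUE))
  names(atoms) <- paste0("n_", names(atoms))

  ring <- as.data.frame(ChemmineR::rings(sdfset, type = "count", arom = TRUE))
  names(ring) <- c("nRing", "nAromRing")

  nbonds <- vapply(ChemmineR::bondblock(sdfset), nrow, integer(1))
  natoms <- vapply(ChemmineR::atomblock(sdfset), nrow, integer(1))

  out <- dplyr::bind_cols(
    tibble::tibble(molecule_id = molecules$id),
    phys, tibble::as_tibble(grp), tibble::as_tibble(ring),
    tibble::tibble(nAtomHeavy = as.numeric(natoms),
                   nBond = as.numeric(nbonds),
                   tpsaEfficiency = ifelse(phys$MW > 0,
                                           phys$TopoPSA / phys$MW, NaN)),
    tibble::as_tibble(atoms)
  )
  out <- dplyr::mutate(out, dplyr::across(-"molecule_id", as.numeric))
  attr(out, "backend") <- paste0("ChemmineR/ChemmineOB (OpenBabel ",
                                 "property + structural counts)")
  out
}

#' Descriptor-table accessors
#'
#' `descriptor_columns()` returns the descriptor names (everything except
#' `molecule_id`); `descriptor_matrix()` returns the numeric matrix with
#' molecule ids as row names.
#'
#' @param table Descriptor table (tibble with `molecule_id`).
#' @return Character vector / double matrix.
#' @export
descriptor_columns <- function(table) {
  setdiff(names(table), "molecule_id")
}

#' @rdname descriptor_columns
#' @export
descriptor_matrix <- function(table) {
  m <- as.matrix(table[, descriptor_columns(table), drop = FALSE])
  if ("molecule_id" %in% names(table)) rownames(m) <- table$molecule_id
  storage.mode(m) <- "double"
  m
}

#' Remove zero-variance descriptor columns
#'
#' Drops descriptors whose value is identical across all molecules (the
#' classical screen for non-informative columns). Idempotent.
#'
#' @param table Descriptor table (tibble with `molecule_id` + numeric
#'   columns).
#' @return The table without constant columns; the removed names are in
#'   attribute `"removed"`.
#' @export
drop_zero_variance <- function(table) {
  if (nrow(table) == 0) {
    abort("empty descriptor table", class = "permstack_value_error")
  }
  desc <- descriptor_columns(table)
  constant <- vapply(desc, function(nm) {
    v <- table[[nm]]
    all(v == v[1]) %in% TRUE || all(is.na(v))
  }, logical(1))
  removed <- desc[constant]
  if (length(removed) == length(desc)) {
    abort("all descriptor columns are constant; degenerate table",
          class = "permstack_value_error")
  }
  out <- table[, c("molecule_id", setdiff(desc, removed)), drop = FALSE]
  attr(out, "backend") <- attr(table, "backend")
  attr(out, "removed") <- removed
  out
}

#' Remove descriptor columns containing non-finite values
#'
#' Any column with at least one `NA`, `NaN` or `Inf` entry is removed whole,
#' keeping the matrix dense for modelling.
#'
#' @inheritParams drop_zero_variance
#' @return The table with only fully finite columns; removed names in
#'   attribute `"removed"`.
#' @export
drop_nonfinite_columns <- function(table) {
  desc <- descriptor_columns(table)
  bad <- vapply(desc, function(nm) any(!is.finite(table[[nm]])), logical(1))
  removed <- desc[bad]
  out <- table[, c("molecule_id", setdiff(desc, removed)), drop = FALSE]
  attr(out, "backend") <- attr(table, "backend")
  attr(out, "removed") <- removed
  out
}

#' Report highly correlated descriptor pairs
#'
#' Lists all descriptor pairs whose absolute Pearson correlation exceeds
#' `cutoff`. Diagnostic only: no columns are removed here, since redundancy
#' is resolved downstream by feature elimination.
#'
#' @inheritParams drop_zero_variance
#' @param cutoff Absolute correlation threshold (default 0.8).
#' @return Tibble with columns `name_i`, `name_j`, `r`, ordered by
#'   decreasing `|r|`.
#' @export
correlation_screen <- function(table, cutoff = 0.8) {
  if (nrow(table) < 2) {
    abort("need at least 2 molecules for correlations",
          class = "permstack_value_error")
  }
  m <- descriptor_matrix(table)
  if (any(!is.finite(m))) {
    abort("non-finite values present; run drop_nonfinite_columns() first",
          class = "permstack_value_error")
  }
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0)) {
    abort("zero-variance column present; run drop_zero_variance() first",
          class = "permstack_value_error")
  }
  cm <- stats::cor(m)
  idx <- which(upper.tri(cm) & abs(cm) > cutoff, arr.ind = TRUE)
  out <- tibble::tibble(
    name_i = colnames(cm)[idx[, 1]],
    name_j = colnames(cm)[idx[, 2]],
    r = cm[idx]
  )
  dplyr::arrange(out, dplyr::desc(abs(.data$r)))
}

#' Fit a per-descriptor min-max scaler
#'
#' Records column-wise minima and maxima so that descriptors can be mapped
#' to the 0-1 range, with the same parameters reused for test and external
#' data (no re-fitting on new data).
#'
#' @inheritParams drop_zero_variance
#' @param fitted_on Free-text label of the dataset the scaler was fit on.
#' @return An object of class `minmax_scaler`.
#' @export
fit_minmax_scaler <- function(table, fitted_on = "train") {
  m <- descriptor_matrix(table)
  if (any(!is.finite(m))) {
    abort("non-finite values present; run drop_nonfinite_columns() first",
          class = "permstack_value_error")
  }
  stats_tbl <- tibble::tibble(
    descriptor = colnames(m),
    min = unname(apply(m, 2, min)),
    max = unname(apply(m, 2, max))
  )
  stats_tbl$constant <- stats_tbl$min == stats_tbl$max
  structure(list(stats = stats_tbl, fitted_on = fitted_on),
            class = "minmax_scaler")
}

#' @export
print.minmax_scaler <- function(x, ...) {
  cat("<minmax_scaler> fitted on", x$fitted_on, "-",
      nrow(x$stats), "descriptors,",
      sum(x$stats$constant), "constant\n")
  invisible(x)
}

#' Apply a fitted min-max scaler
#'
#' Maps each descriptor through `(x - min) / (max - min)` using the stored
#' training minima/maxima. Values on new data that fall outside the training
#' range are deliberately not clipped (they land outside 0-1), so that
#' distance from the training domain stays visible to the applicability
#' domain. Constant columns map to 0.
#'
#' @inheritParams drop_zero_variance
#' @param scaler A `minmax_scaler` from [fit_minmax_scaler()].
#' @return The scaled descriptor table.
#' @export
apply_minmax_scaler <- function(table, scaler) {
  stopifnot(inherits(scaler, "minmax_scaler"))
  desc <- descriptor_columns(table)
  if (!setequal(desc, scaler$stats$descriptor)) {
    missing <- setdiff(scaler$stats$descriptor, desc)
    extra <- setdiff(desc, scaler$stats$descriptor)
    abort(paste0("descriptor names do not match the scaler",
                 if (length(missing)) paste0("; missing: ",
                                             paste(missing, collapse = ", ")),
                 if (length(extra)) paste0("; unexpected: ",
                                           paste(extra, collapse = ", "))),
          class = "permstack_value_error")
  }
  out <- table
  for (i in seq_len(nrow(scaler$stats))) {
    nm <- scaler$stats$descriptor[i]
    lo <- scaler$stats$min[i]
    hi <- scaler$stats$max[i]
    out[[nm]] <- if (lo == hi) rep(0, nrow(table)) else (table[[nm]] - lo) / (hi - lo)
  }
  out <- out[, c("molecule_id", scaler$stats$descriptor), drop = FALSE]
  attr(out, "backend") <- attr(table, "backend")
  out
}
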