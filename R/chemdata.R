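#' Read a molecule table from CSV or SDF
#'
#' Loads a table of molecules (identifier, SMILES, optionally an observed
#' effective permeability logPe in log10(cm/s)). Rows whose SMILES cannot be
#' parsed by the cheminformatics backend are dropped with a warning so that
#' downstream descriptor calculation never sees an invalid structure.
#'
#' @param path Path to the input file.
#' @param format `"csv"` (default, comma-separated with a header row) or
#'   `"sdf"` (V2000/V3000; logPe is read from the SD tag named by
#'   `col_map$log_pe` when present).
#' @param col_map Named list mapping the canonical column names `id`,
#'   `smiles`, `log_pe` onto the file's column names (or SD tag names).
#' @param validate_smiles Check each SMILES with the backend parser and
#'   reject rows that fail. Requires the ChemmineR/ChemmineOB backend;
#'   set to `FALSE` to load tables without structural validation.
#'
#' @return A tibble with columns `id`, `smiles`, `log_pe` (double, `NA` when
#'   absent) and `partition` (initialised to `"unassigned"`).
#' @seealso [split_dataset()], [compute_descriptors()]
#' @export
read_molecule_table <- function(path,
                                format = c("csv", "sdf"),
                                col_map = list(id = "id", smiles = "smiles",
                                               log_pe = "log_pe"),
                                validate_smiles = TRUE) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    abort(paste0("input file not found: ", path), class = "permstack_io_error")
  }
  col_map <- utils::modifyList(list(id = "id", smiles = "smiles",
                                    log_pe = "log_pe"), as.list(col_map))

  if (format == "csv") {
    raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                           check.names = FALSE, fileEncoding = "UTF-8")
    for (key in c("id", "smiles")) {
      if (!col_map[[key]] %in% names(raw)) {
        abort(paste0("column '", col_map[[key]], "' (", key,
                     ") not found in ", path),
              class = "permstack_io_error")
      }
    }
    log_pe <- if (col_map$log_pe %in% names(raw)) {
      as.numeric(raw[[col_map$log_pe]])
    } else {
      rep(NA_real_, nrow(raw))
    }
    mol <- tibble::tibble(
      id = as.character(raw[[col_map$id]]),
      smiles = as.character(raw[[col_map$smiles]]),
      log_pe = log_pe
    )
  } else {
    sdf <- read_sdf_molecules(path, col_map$log_pe)
    mol <- sdf
  }

  if (anyDuplicated(mol$id)) {
    dup <- unique(mol$id[duplicated(mol$id)])
    abort(paste0("duplicate molecule ids: ", paste(dup, collapse = ", ")),
          class = "permstack_io_error")
  }
  if (any(!nzchar(mol$id))) {
    abort("empty molecule ids are not allowed", class = "permstack_io_error")
  }

  if (validate_smiles && nrow(mol) > 0) {
    ok <- smiles_is_valid(mol$smiles)
    if (!all(ok)) {
      warn(paste0(sum(!ok), " record(s) with unparsable SMILES excluded: ",
                  paste(mol$id[!ok], collapse = ", ")))
      mol <- mol[ok, , drop = FALSE]
    }
  }
  if (nrow(mol) == 0) {
    abort("no parsable molecule records in input",
          class = "permstack_io_error")
  }
  mol$partition <- "unassigned"
  mol
}

#' Write a molecule table to CSV
#'
#' Inverse of [read_molecule_table()]; logPe values are written at full
#' precision so a load/write/load round trip is lossless.
#'
#' @param molecules Tibble with columns `id`, `smiles`, optionally `log_pe`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_molecule_table <- function(molecules, path) {
  out <- molecules[, intersect(c("id", "smiles", "log_pe", "partition"),
                               names(molecules)), drop = FALSE]
  if ("log_pe" %in% names(out)) {
    out$log_pe <- vapply(out$log_pe, function(v) {
      if (is.na(v)) "" else sprintf("%.17g", v)
    }, character(1))
  }
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

# SDF reader built on ChemmineR; logPe taken from a named SD data tag.
read_sdf_molecules <- function(path, log_pe_tag) {
  require_chem_backend()
  sdfset <- ChemmineR::read.SDFset(path)
  valid <- ChemmineR::validSDF(sdfset)
  if (!all(valid)) {
    warn(paste0(sum(!valid), " invalid SDF entr(ies) excluded"))
    sdfset <- sdfset[valid]
  }
  if (length(sdfset) == 0) {
    abort("no parsable molecule records in input",
          class = "permstack_io_error")
  }
  ids <- ChemmineR::sdfid(sdfset)
  blocks <- ChemmineR::datablock(sdfset)
  log_pe <- vapply(blocks, function(b) {
    if (length(b) && log_pe_tag %in% names(b)) as.numeric(b[[log_pe_tag]])
    else NA_real_
  }, numeric(1))
  smi <- as.character(ChemmineR::sdf2smiles(sdfset))
  tibble::tibble(id = as.character(ids), smiles = smi, log_pe = log_pe)
}

smiles_is_valid <- function(smiles) {
  require_chem_backend()
  vapply(smiles, function(s) {
    if (is.na(s) || !nzchar(s)) return(FALSE)
    ok <- tryCatch({
      sdf <- suppressWarnings(ChemmineR::smiles2sdf(stats::setNames(s, "x")))
      length(sdf) == 1 && ChemmineR::validSDF(sdf)
    }, error = function(e) FALSE)
    isTRUE(ok)
  }, logical(1), USE.NAMES = FALSE)
}

require_chem_backend <- function() {
  for (pkg in c("ChemmineR", "ChemmineOB")) {
    if (!requireNamespace(pkg, quietly = TRUE)) {
      abort(paste0("descriptor backend requires the '", pkg, "' package"),
            class = "permstack_backend_error")
    }
  }
  invisible(TRUE)
}

#' Partition molecules into train / test / external validation sets
#'
#' Draws a seeded, uniformly random three-way split: `n_external` molecules
#' are set aside first as an external validation set, then `n_test` of the
#' remainder form the test set, and everything else is the training set.
#' With the defaults (`n_external = 16`, `n_test = 33`) a 190-molecule table
#' splits 141/33/16.
#'
#' @param molecules Molecule tibble (one row per molecule, unique `id`).
#' @param n_external,n_test Number of molecules for the external and test
#'   partitions.
#' @param seed Integer seed; the same seed always yields the same membership.
#' @return The input tibble with its `partition` column set to
#'   `"train"`, `"test"` or `"external"`. The id lists are attached as
#'   attribute `"split"` (a list with `train_ids`, `test_ids`,
#'   `external_ids`, `seed`).
#' @export
split_dataset <- function(molecules, n_external = 16, n_test = 33, seed = 1) {
  n <- nrow(molecules)
  if (n_external < 0 || n_test < 0) {
    abort("split counts must be non-negative", class = "permstack_value_error")
  }
  if (n_external + n_test >= n) {
    abort(sprintf(
      "n_external + n_test (%d) must be smaller than the number of molecules (%d)",
      n_external + n_test, n), class = "permstack_value_error")
  }
  ids <- molecules$id
  withr::with_seed(seed, {
    external_ids <- sort(sample(ids, n_external))
    rest <- setdiff(ids, external_ids)
    test_ids <- sort(sample(rest, n_test))
  })
  train_ids <- sort(setdiff(ids, c(external_ids, test_ids)))

  out <- molecules
  out$partition <- dplyr::case_when(
    out$id %in% external_ids ~ "external",
    out$id %in% test_ids ~ "test",
    TRUE ~ "train"
  )
  attr(out, "split") <- list(train_ids = train_ids, test_ids = test_ids,
                             external_ids = external_ids, seed = seed)
  out
}
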