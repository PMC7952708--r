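#' Read a protein conformation from a PDB file
#'
#' Parses a PDB-format structure into a tidy atom table representing one
#' conformation of the protein. Only ATOM records of the 20 standard amino
#' acids are kept: HETATM records (ligands, waters, modified residues such
#' as MSE), hydrogens, and non-standard residues are excluded. For atoms
#' with alternate locations the highest-occupancy location is retained
#' (ties broken by file order). Only the first MODEL of a multi-model file
#' is used.
#'
#' @param path Path to a PDB-format file.
#' @param chains Optional character vector of chain identifiers to keep;
#'   `NULL` (default) keeps all chains.
#' @param label Conformation label used downstream (e.g. `"open"`,
#'   `"closed"`). Defaults to the file name without extension.
#' @return A tibble of class `conformation`, one row per heavy atom, with
#'   columns `chain`, `resno`, `icode`, `resname`, `atom`, `element`,
#'   `x`, `y`, `z`, `occupancy`, and a residue identifier `key`
#'   (`"<chain>:<resno><icode>"`). Rows are ordered by (chain, resno,
#'   icode). Attributes `label` and `source` carry the conformation name
#'   and provenance.
#' @seealso [build_correspondence()], [sidechain_com()], [distance_map()]
#' @examples
#' pdb <- fixture_conformer_pair(n_residues = 5)
#' conf <- read_conformation(pdb$path_a, label = "open")
#' dplyr::count(conf, resname)
#' @export
read_conformation <- function(path, chains = NULL, label = NULL) {
  if (!file.exists(path)) {
    stop("PDB file not found: ", path, call. = FALSE)
  }
  if (is.null(label)) {
    label <- sub("\\.[^.]*$", "", basename(path))
  }
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                                     verbose = FALSE)),
    error = function(e) stop("failed to parse PDB file '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  at <- tibble::as_tibble(pdb$atom)
  at <- dplyr::filter(at, .data$type == "ATOM")
  if (nrow(at) == 0L) {
    stop("no ATOM records in '", path, "'", call. = FALSE)
  }

  at <- at |>
    dplyr::mutate(
      atom = trimws(.data$elety),
      resname = toupper(trimws(.data$resid)),
      chain = dplyr::coalesce(.data$chain, " "),
      icode = dplyr::coalesce(.data$insert, ""),
      altloc = dplyr::coalesce(.data$alt, ""),
      occupancy = dplyr::coalesce(.data$o, 1),
      element = dplyr::if_else(
        is.na(.data$elesy) | trimws(.data$elesy) == "",
        element_from_name(.data$elety),
        toupper(trimws(.data$elesy))
      )
    ) |>
    dplyr::filter(
      .data$resname %in% .standard_residues,
      .data$element != "H", .data$element != "D"
    )

  if (!is.null(chains)) {
    at <- dplyr::filter(at, .data$chain %in% chains)
  }
  if (nrow(at) == 0L) {
    stop("no standard amino-acid atoms left after filtering in '", path,
         "'", call. = FALSE)
  }

  # Alternate locations: keep the highest-occupancy copy of each atom;
  # ties resolve to the record that appears first in the file.
  at <- at |>
    dplyr::mutate(.file_order = dplyr::row_number()) |>
    dplyr::group_by(.data$chain, .data$resno, .data$icode, .data$atom) |>
    dplyr::arrange(dplyr::desc(.data$occupancy), .data$.file_order,
                   .by_group = TRUE) |>
    dplyr::slice(1L) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$chain, .data$resno, .data$icode, .data$.file_order)

  out <- at |>
    dplyr::transmute(
      chain = .data$chain,
      resno = as.integer(.data$resno),
      icode = .data$icode,
      resname = .data$resname,
      atom = .data$atom,
      element = .data$element,
      x = .data$x, y = .data$y, z = .data$z,
      occupancy = .data$occupancy,
      key = residue_key(.data$chain, .data$resno, .data$icode)
    )

  if (any(!is.finite(c(out$x, out$y, out$z)))) {
    stop("non-finite coordinates in '", path, "'", call. = FALSE)
  }
  new_conformation(out, label = label, source = path)
}

new_conformation <- function(atoms, label, source) {
  structure(
    tibble::new_tibble(atoms, class = "conformation"),
    label = label, source = source
  )
}

residue_key <- function(chain, resno, icode) {
  paste0(chain, ":", resno, ifelse(icode == "" | is.na(icode), "", icode))
}

#' @export
print.conformation <- function(x, ...) {
  cat("# Conformation '", attr(x, "label"), "' (", attr(x, "source"), ")\n",
      sep = "")
  cat("# ", dplyr::n_distinct(x$key), " residues, ", nrow(x),
      " heavy atoms\n", sep = "")
  NextMethod()
}

#' Conformation label
#' @param conformation A `conformation` tibble from [read_conformation()].
#' @return The conformation's label string.
#' @export
conformation_label <- function(conformation) {
  attr(conformation, "label") %||% "conformation"
}

# One row per residue, keeping identity columns only.
residue_table <- function(conformation) {
  dplyr::distinct(
    tibble::as_tibble(conformation),
    .data$key, .data$chain, .data$resno, .data$icode, .data$resname
  )
}

#' Residue correspondence across conformations
#'
#' Matches residues between two or more conformations of the same protein
#' by author numbering: a residue is in correspondence when the same
#' (chain, residue number, insertion code) exists in every conformation
#' with the same residue type. No sequence alignment is attempted —
#' the method assumes crystal structures of the same construct sharing
#' numbering. Residues that are missing from some conformation or whose
#' type differs are reported in `dropped` with a reason code
#' (`"missing_in:<label>"` or `"type_mismatch"`).
#'
#' @param conformations A list of two or more `conformation` objects.
#' @return A list of class `residue_correspondence` with elements
#'   `keys` (tibble of matched residues: `key`, `chain`, `resno`, `icode`,
#'   `resname`, ordered by chain/number/insertion code) and `dropped`
#'   (tibble `key`, `reason`).
#' @examples
#' pdb <- fixture_conformer_pair(n_residues = 5)
#' confs <- list(read_conformation(pdb$path_a, label = "open"),
#'               read_conformation(pdb$path_b, label = "closed"))
#' build_correspondence(confs)$keys
#' @export
build_correspondence <- function(conformations) {
  stopifnot(is.list(conformations))
  if (length(conformations) < 2L) {
    stop("need at least two conformations", call. = FALSE)
  }
  labels <- vapply(conformations, conformation_label, character(1))
  tabs <- purrr::map2(conformations, labels,
                      ~ dplyr::mutate(residue_table(.x), label = .y))
  all_res <- dplyr::bind_rows(tabs)

  per_key <- all_res |>
    dplyr::group_by(.data$key, .data$chain, .data$resno, .data$icode) |>
    dplyr::summarise(
      n_conf = dplyr::n_distinct(.data$label),
      n_types = dplyr::n_distinct(.data$resname),
      resname = .data$resname[1],
      present_in = list(unique(.data$label)),
      .groups = "drop"
    )

  n <- length(conformations)
  matched <- per_key |>
    dplyr::filter(.data$n_conf == n, .data$n_types == 1L) |>
    dplyr::arrange(.data$chain, .data$resno, .data$icode) |>
    dplyr::select("key", "chain", "resno", "icode", "resname")

  dropped <- per_key |>
    dplyr::filter(.data$n_conf < n | .data$n_types > 1L) |>
    dplyr::mutate(reason = purrr::map2_chr(
      .data$n_types > 1L, .data$present_in,
      function(mismatch, pres) {
        if (mismatch) return("type_mismatch")
        paste0("missing_in:",
               paste(sort(setdiff(labels, pres)), collapse = ","))
      }
    )) |>
    dplyr::arrange(.data$chain, .data$resno, .data$icode) |>
    dplyr::select("key", "reason")

  if (nrow(matched) == 0L) {
    stop("no residues common to all conformations", call. = FALSE)
  }
  structure(list(keys = matched, dropped = dropped, labels = labels),
            class = "residue_correspondence")
}

#' @export
print.residue_correspondence <- function(x, ...) {
  cat("# Residue correspondence across conformations: ",
      paste(x$labels, collapse = ", "), "\n", sep = "")
  cat("# ", nrow(x$keys), " matched residues, ", nrow(x$dropped),
      " dropped\n", sep = "")
  if (nrow(x$dropped) > 0) print(x$dropped)
  invisible(x)
}

#' Fetch a structure from the wwPDB
#'
#' Downloads a PDB entry by accession from RCSB. This helper is strictly
#' opt-in: nothing in the package or its test suite downloads anything
#' unless you call it yourself.
#'
#' @param accession 4-character PDB accession, e.g. `"3L6G"`.
#' @param destdir Directory to save `<accession>.pdb` into.
#' @param quiet Passed to [utils::download.file()].
#' @return Invisibly, the path to the downloaded file.
#' @export
fetch_pdb <- function(accession, destdir = ".", quiet = FALSE) {
  stopifnot(grepl("^[0-9][A-Za-z0-9]{3}$", accession))
  dir.create(destdir, showWarnings = FALSE, recursive = TRUE)
  dest <- file.path(destdir, paste0(toupper(accession), ".pdb"))
  url <- paste0("https://files.rcsb.org/download/", toupper(accession),
                ".pdb")
  status <- utils::download.file(url, dest, quiet = quiet, mode = "wb")
  if (status != 0L) stop("download failed for ", accession, call. = FALSE)
  invisible(dest)
}
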