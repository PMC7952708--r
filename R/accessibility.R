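#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Computes per-residue absolute solvent-accessible surface area with a
#' built-in Shrake-Rupley engine: each heavy atom is covered with a
#' deterministic golden-section-spiral lattice of points on its expanded
#' sphere (van der Waals radius + probe radius); a point is accessible
#' when it lies outside every other atom's expanded sphere, and the atom's
#' area is the accessible fraction of its expanded-sphere area. Residue
#' area sums all heavy atoms of the residue, backbone included, matching
#' the per-residue ACC semantics of the DSSP program. Only the standard
#' amino-acid atoms of the conformation take part, so ligands and waters
#' (HETATM, already excluded at parse time) neither gain area nor occlude.
#'
#' The point lattice contains no randomness, so results are reproducible
#' bit-for-bit across runs and machines.
#'
#' @param conformation A `conformation` from [read_conformation()].
#' @param probe_radius Probe sphere radius in Angstrom; 1.4 approximates a
#'   water molecule and is the universal default.
#' @param n_points Points per atomic sphere; more points, finer area
#'   quadrature. The default 960 keeps per-residue error well under the
#'   tolerances that matter for a percent-scale accessibility filter.
#' @param on_unknown_element `"default"` (use 1.70 Angstrom with a
#'   warning) or `"error"` for atoms whose element has no radius entry.
#' @return A tibble of class `accessibility_tbl`: one row per residue with
#'   `key`, `chain`, `resno`, `icode`, `resname`, `abs_area` (Angstrom^2),
#'   `rsa` (`NA` until [relative_accessibility()]), `ss` (secondary
#'   structure, blank: the internal engine does not assign it), and
#'   `source = "internal"`. Attribute `label` carries the conformation
#'   label.
#' @seealso [relative_accessibility()], [read_dssp()]
#' @examples
#' pdb <- fixture_conformer_pair(n_residues = 4)
#' conf <- read_conformation(pdb$path_a)
#' sasa(conf, n_points = 240)
#' @export
sasa <- function(conformation, probe_radius = 1.4, n_points = 960,
                 on_unknown_element = c("default", "error")) {
  on_unknown_element <- match.arg(on_unknown_element)
  stopifnot(probe_radius > 0, n_points >= 100)
  atoms <- tibble::as_tibble(conformation)
  if (nrow(atoms) == 0L) stop("empty conformation", call. = FALSE)

  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  radii <- atom_radius(atoms$element, on_unknown = on_unknown_element) +
    probe_radius
  sphere <- golden_spiral_points(n_points)

  n <- nrow(xyz)
  atom_area <- numeric(n)
  # neighbor candidates: centers closer than the sum of expanded radii
  d2 <- as.matrix(stats::dist(xyz))^2
  rsum2 <- outer(radii, radii, `+`)^2
  for (i in seq_len(n)) {
    nb <- which(d2[i, ] < rsum2[i, ])
    nb <- nb[nb != i]
    pts <- sweep(sphere * radii[i], 2, xyz[i, ], `+`)
    if (length(nb) > 0) {
      free <- rep(TRUE, n_points)
      for (j in nb) {
        dx <- pts[, 1] - xyz[j, 1]
        dy <- pts[, 2] - xyz[j, 2]
        dz <- pts[, 3] - xyz[j, 3]
        free <- free & (dx * dx + dy * dy + dz * dz > radii[j]^2)
        if (!any(free)) break
      }
      frac <- sum(free) / n_points
    } else {
      frac <- 1
    }
    atom_area[i] <- frac * 4 * pi * radii[i]^2
  }

  out <- atoms |>
    dplyr::mutate(.area = atom_area) |>
    dplyr::group_by(.data$key, .data$chain, .data$resno, .data$icode,
                    .data$resname) |>
    dplyr::summarise(abs_area = sum(.data$.area), .groups = "drop") |>
    dplyr::arrange(.data$chain, .data$resno, .data$icode) |>
    dplyr::mutate(rsa = NA_real_, ss = "", source = "internal")

  structure(tibble::new_tibble(out, class = "accessibility_tbl"),
            label = conformation_label(conformation))
}

# Deterministic, RNG-free near-uniform points on the unit sphere.
golden_spiral_points <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- pi * (3 - sqrt(5)) * (i - 0.5)
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Read a classic DSSP output file
#'
#' Parses the per-residue block of a classic (columnar) DSSP file,
#' extracting the absolute accessible area (ACC column) and the
#' secondary-structure summary letter. DSSP is the route to reproducing
#' published accessibility values exactly; the built-in [sasa()] engine is
#' the self-contained alternative and agrees with DSSP areas to within a
#' few percent (different algorithms).
#'
#' @param path Path to a DSSP-format file.
#' @param label Conformation label to attach; defaults to the file name.
#' @return An `accessibility_tbl` tibble as in [sasa()], with
#'   `source = "dssp-file"` and `ss` filled from the structure column.
#'   Chain-break records (`!`) are skipped. Lowercase amino-acid codes
#'   (disulfide-bridged cysteines) map to CYS.
#' @export
read_dssp <- function(path, label = NULL) {
  if (!file.exists(path)) stop("DSSP file not found: ", path, call. = FALSE)
  if (is.null(label)) label <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^  #  RESIDUE", lines)
  if (length(hdr) != 1L) {
    stop("not a classic DSSP file (missing '  #  RESIDUE' header): ",
         path, call. = FALSE)
  }
  body <- lines[seq.int(hdr + 1L, length(lines))]
  body <- body[nzchar(trimws(body))]

  rows <- purrr::imap(body, function(line, idx) {
    aa <- substr(line, 14, 14)
    if (aa == "!") return(NULL)  # chain break
    resno <- suppressWarnings(as.integer(trimws(substr(line, 6, 10))))
    acc <- suppressWarnings(as.numeric(trimws(substr(line, 35, 38))))
    if (is.na(resno) || is.na(acc)) {
      stop("malformed DSSP record at line ", hdr + idx, " of ", path,
           call. = FALSE)
    }
    # lowercase letters label disulfide-bridged cysteines in DSSP
    resname <- if (grepl("[a-z]", aa)) "CYS" else
      unname(.aa_one_to_three[aa])
    tibble::tibble(
      chain = substr(line, 12, 12),
      resno = resno,
      icode = trimws(substr(line, 11, 11)),
      resname = resname,
      ss = trimws(substr(line, 17, 17)),
      abs_area = acc
    )
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) stop("no residue records in DSSP file: ", path,
                            call. = FALSE)
  out <- out |>
    dplyr::mutate(key = residue_key(.data$chain, .data$resno, .data$icode),
                  rsa = NA_real_, source = "dssp-file") |>
    dplyr::select("key", "chain", "resno", "icode", "resname", "abs_area",
                  "rsa", "ss", "source")
  structure(tibble::new_tibble(out, class = "accessibility_tbl"),
            label = label)
}

#' Relative surface accessibility (RSA)
#'
#' Normalizes absolute accessible areas to percent of the residue type's
#' theoretical maximum — the area of residue X in an extended Gly-X-Gly
#' tripeptide. RSA makes burial comparable across residue types (a lysine
#' and a serine with the same absolute area are very differently exposed).
#' Values above 100% occur for well-exposed residues in real structures
#' and are kept as-is.
#'
#' @param table An `accessibility_tbl` with `abs_area` filled.
#' @param reference Named numeric vector mapping three-letter residue
#'   codes to maximum areas (Angstrom^2); defaults to [reference_areas()].
#' @return The same table with `rsa` filled (percent).
#' @examples
#' pdb <- fixture_conformer_pair(n_residues = 4)
#' conf <- read_conformation(pdb$path_a)
#' relative_accessibility(sasa(conf, n_points = 240))
#' @export
relative_accessibility <- function(table, reference = reference_areas()) {
  stopifnot(inherits(table, "accessibility_tbl") ||
              all(c("resname", "abs_area") %in% names(table)))
  missing <- setdiff(unique(table$resname), names(reference))
  if (length(missing) > 0) {
    stop("no reference area for residue type(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  lab <- attr(table, "label")
  out <- dplyr::mutate(
    table, rsa = 100 * .data$abs_area / unname(reference[.data$resname])
  )
  structure(tibble::new_tibble(out, class = "accessibility_tbl"),
            label = lab)
}

accessibility_label <- function(table) {
  attr(table, "label") %||% "conformation"
}
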