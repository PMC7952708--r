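#' Synthetic conformer-pair fixtures
#'
#' Generates a small polypeptide in two conformations related by a rigid
#' hinge rotation, written as standard PDB files, together with a
#' manifest of ground-truth geometry computed from the construction
#' itself (never by re-measuring the emitted files). Because one domain
#' moves rigidly while the other stays put, every pair's distance change
#' is known analytically, which lets the whole screening pipeline be
#' validated end-to-end without any real structure.
#'
#' The chain mixes residue types (always including glycine, which
#' exercises the C-alpha fallback) built from idealized template
#' geometry. Optional engineered defects mimic the pathologies of real
#' crystal structures: a residue missing from the second conformation, a
#' residue type mismatch, an alternate-location atom, and a truncated
#' side chain.
#'
#' @param n_residues Number of residues (>= 4).
#' @param angle Hinge rotation angle in degrees applied to the second
#'   half of the chain in conformation B; 0 gives two identical
#'   conformations.
#' @param seed Integer seed for the (small) placement jitter; equal seeds
#'   give byte-identical files.
#' @param hinge Index of the hinge residue; residues after it move.
#'   Default: halfway.
#' @param defects Character vector, any of `"missing_residue"`,
#'   `"type_mismatch"`, `"altloc"`, `"incomplete_sidechain"`.
#' @param dir Output directory (created if needed).
#' @return A list: `path_a`, `path_b` (PDB files), `manifest` with
#'   `residues` (keys, types, defect annotations, moving-domain flag),
#'   `coms_a`/`coms_b` (true mass-weighted side-chain COMs), `pairs`
#'   (true `d_a`, `d_b`, `dd` per unordered pair), `hinge_point`,
#'   `hinge_axis`, `angle`; and `manifest_paths` (the same tables as
#'   CSV).
#' @examples
#' fx <- fixture_conformer_pair(n_residues = 6, angle = 45, seed = 7)
#' fx$manifest$pairs
#' @export
fixture_conformer_pair <- function(n_residues = 8, angle = 40, seed = 1,
                                   hinge = NULL, defects = character(0),
                                   dir = tempfile("fixture")) {
  stopifnot(n_residues >= 4, is.numeric(angle), length(angle) == 1)
  bad <- setdiff(defects, c("missing_residue", "type_mismatch", "altloc",
                            "incomplete_sidechain"))
  if (length(bad) > 0) stop("unknown defect(s): ",
                            paste(bad, collapse = ", "), call. = FALSE)
  if (is.null(hinge)) hinge <- floor(n_residues / 2)
  stopifnot(hinge >= 1, hinge < n_residues)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)

  types <- rep(c("ALA", "GLY", "SER", "VAL", "ASP", "LYS", "THR", "LEU"),
               length.out = n_residues)

  rng <- local({ set.seed(as.integer(seed)); list(
    spin = stats::runif(n_residues, 0, 2 * pi),
    jitter = matrix(stats::runif(3 * n_residues, -0.3, 0.3), ncol = 3)
  )})

  # conformation A: residues on a gentle curve, each template spun about z
  spacing <- 6.0
  atoms_a <- vector("list", n_residues)
  for (k in seq_len(n_residues)) {
    tmpl <- .residue_templates[[types[k]]]
    xyz <- as.matrix(tmpl[, c("x", "y", "z")])
    xyz <- xyz %*% t(rot_z(rng$spin[k]))
    shift <- c(spacing * (k - 1), 4 * sin((k - 1) / 2), 0) + rng$jitter[k, ]
    xyz <- sweep(xyz, 2, shift, `+`)
    atoms_a[[k]] <- tibble::tibble(
      resno = k, resname = types[k], atom = tmpl$atom,
      element = tmpl$element,
      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
      altloc = "", occupancy = 1
    )
  }
  atoms_a <- dplyr::bind_rows(atoms_a)

  # hinge motion: residues past the hinge rotate rigidly about the y axis
  # through the hinge residue's CA; the axis is roughly perpendicular to
  # the chain direction, so the moving arm swings out of line and
  # cross-domain distances change strongly (domain-closure-like motion)
  hinge_point <- unlist(atoms_a[atoms_a$resno == hinge &
                                  atoms_a$atom == "CA", c("x", "y", "z")])
  theta <- angle * pi / 180
  moving <- seq_len(n_residues) > hinge
  atoms_b <- atoms_a
  mv <- atoms_b$resno > hinge
  atoms_b[mv, c("x", "y", "z")] <- rotate_about(
    as.matrix(atoms_b[mv, c("x", "y", "z")]), hinge_point, theta,
    axis = c(0, 1, 0)
  )

  res_info <- tibble::tibble(
    key = residue_key("A", seq_len(n_residues), ""),
    resno = seq_len(n_residues), resname = types, moving = moving,
    defect = ""
  )

  # --- engineered defects (applied to conformation B / both, post-motion)
  # candidates are non-glycine, non-hinge residues, assigned in order
  cand <- setdiff(which(types != "GLY"), hinge)
  take_cand <- function() {
    if (length(cand) == 0) stop("too few residues for requested defects",
                                call. = FALSE)
    r <- cand[1]; cand <<- cand[-1]; r
  }
  if ("missing_residue" %in% defects) {
    r <- take_cand()
    atoms_b <- atoms_b[atoms_b$resno != r, , drop = FALSE]
    res_info$defect[r] <- paste0(res_info$defect[r], "missing_residue;")
  }
  if ("type_mismatch" %in% defects) {
    r <- take_cand()
    swap <- if (types[r] == "ALA") "SER" else "ALA"
    tmpl <- .residue_templates[[swap]]
    old <- atoms_b[atoms_b$resno == r, , drop = FALSE]
    ca <- unlist(old[old$atom == "CA", c("x", "y", "z")])
    xyz <- sweep(as.matrix(tmpl[, c("x", "y", "z")]), 2, ca, `+`)
    atoms_b <- dplyr::bind_rows(
      atoms_b[atoms_b$resno != r, , drop = FALSE],
      tibble::tibble(resno = r, resname = swap, atom = tmpl$atom,
                     element = tmpl$element, x = xyz[, 1], y = xyz[, 2],
                     z = xyz[, 3], altloc = "", occupancy = 1)
    ) |> dplyr::arrange(.data$resno)
    res_info$defect[r] <- paste0(res_info$defect[r], "type_mismatch;")
  }
  if ("altloc" %in% defects) {
    r <- take_cand()
    cb <- atoms_b$resno == r & atoms_b$atom == "CB"
    if (any(cb)) {
      dup <- atoms_b[cb, , drop = FALSE][1, ]
      atoms_b$altloc[cb] <- "A"
      atoms_b$occupancy[cb] <- 0.6
      dup$altloc <- "B"; dup$occupancy <- 0.4; dup$x <- dup$x + 0.8
      atoms_b <- dplyr::bind_rows(atoms_b, dup) |>
        dplyr::arrange(.data$resno)
      res_info$defect[r] <- paste0(res_info$defect[r], "altloc;")
    }
  }
  if ("incomplete_sidechain" %in% defects) {
    r <- take_cand()
    sc_rows <- which(atoms_b$resno == r &
                       !(atoms_b$atom %in% .backbone_atoms))
    if (length(sc_rows) > 1) {
      drop_row <- sc_rows[length(sc_rows)]
      # drop from BOTH so truth stays aligned across conformations
      nm <- atoms_b$atom[drop_row]
      atoms_b <- atoms_b[-drop_row, , drop = FALSE]
      atoms_a <- atoms_a[!(atoms_a$resno == r & atoms_a$atom == nm), ,
                         drop = FALSE]
      res_info$defect[r] <- paste0(res_info$defect[r],
                                   "incomplete_sidechain;")
    }
  }

  # ground truth from the construction: mass-weighted side-chain COMs of
  # the coordinates as built (highest-occupancy altloc copies only)
  coms_a <- construction_coms(atoms_a)
  coms_b <- construction_coms(atoms_b)
  pairs <- true_pairs(coms_a, coms_b)

  path_a <- file.path(dir, "conformer_a.pdb")
  path_b <- file.path(dir, "conformer_b.pdb")
  write_fixture_pdb(atoms_a, path_a)
  write_fixture_pdb(atoms_b, path_b)

  manifest_paths <- list(
    residues = file.path(dir, "manifest_residues.csv"),
    pairs = file.path(dir, "manifest_pairs.csv")
  )
  readr::write_csv(res_info, manifest_paths$residues)
  readr::write_csv(pairs, manifest_paths$pairs)

  list(
    path_a = path_a, path_b = path_b,
    manifest = list(residues = res_info, coms_a = coms_a, coms_b = coms_b,
                    pairs = pairs, hinge_point = hinge_point,
                    hinge_axis = c(0, 1, 0), angle = angle, hinge = hinge),
    manifest_paths = manifest_paths
  )
}

construction_coms <- function(atoms) {
  best <- atoms |>
    dplyr::group_by(.data$resno, .data$atom) |>
    dplyr::arrange(dplyr::desc(.data$occupancy), .by_group = TRUE) |>
    dplyr::slice(1L) |>
    dplyr::ungroup()
  best |>
    dplyr::group_by(.data$resno, .data$resname) |>
    dplyr::group_map(function(df, grp) {
      sc <- df[!(df$atom %in% .backbone_atoms), , drop = FALSE]
      if (nrow(sc) == 0L) sc <- df[df$atom == "CA", , drop = FALSE]
      w <- atom_mass(sc$element)
      tibble::tibble(
        key = residue_key("A", grp$resno, ""), resno = grp$resno,
        resname = grp$resname,
        x = sum(w * sc$x) / sum(w), y = sum(w * sc$y) / sum(w),
        z = sum(w * sc$z) / sum(w)
      )
    }) |>
    dplyr::bind_rows() |>
    dplyr::arrange(.data$resno)
}

true_pairs <- function(coms_a, coms_b) {
  shared <- intersect(coms_a$key, coms_b$key)
  ia <- match(shared, coms_a$key)
  ib <- match(shared, coms_b$key)
  n <- length(shared)
  pr <- which(upper.tri(matrix(TRUE, n, n)), arr.ind = TRUE)
  da <- sqrt(rowSums((as.matrix(coms_a[ia[pr[, 1]], c("x", "y", "z")]) -
                        as.matrix(coms_a[ia[pr[, 2]], c("x", "y", "z")]))^2))
  db <- sqrt(rowSums((as.matrix(coms_b[ib[pr[, 1]], c("x", "y", "z")]) -
                        as.matrix(coms_b[ib[pr[, 2]], c("x", "y", "z")]))^2))
  tibble::tibble(
    key_i = shared[pr[, 1]], key_j = shared[pr[, 2]],
    d_a = da, d_b = db, dd = da - db
  )
}

rot_z <- function(theta) {
  c <- cos(theta); s <- sin(theta)
  matrix(c(c, s, 0, -s, c, 0, 0, 0, 1), nrow = 3)
}

# rotation by theta about unit axis u (Rodrigues)
rot_axis <- function(theta, u) {
  u <- u / sqrt(sum(u^2))
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), nrow = 3)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

rotate_about <- function(xyz, point, theta, axis = c(0, 1, 0)) {
  R <- rot_axis(theta, axis)
  sweep(sweep(xyz, 2, point, `-`) %*% t(R), 2, point, `+`)
}

# Fixed-column PDB ATOM records; atom names < 4 chars start in column 14.
write_fixture_pdb <- function(atoms, path, chain = "A") {
  name_field <- ifelse(nchar(atoms$atom) < 4,
                       sprintf(" %-3s", atoms$atom),
                       atoms$atom)
  lines <- sprintf(
    "ATOM  %5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq_len(nrow(atoms)), name_field, atoms$altloc, atoms$resname, chain,
    atoms$resno, atoms$x, atoms$y, atoms$z, atoms$occupancy, 0,
    atoms$element
  )
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Burial-cage fixture
#'
#' Emits a single residue optionally surrounded by a closed spherical
#' shell of occluding atoms, for exercising the accessibility engine:
#' with a full shell the residue's accessible area vanishes; with no
#' shell it equals the isolated-residue value; a half shell lies strictly
#' between.
#'
#' The shell is written as single-atom glycine residues (CA only) on a
#' second chain so the standard-residue parser keeps them; they act as
#' occluders in [sasa()] exactly like protein neighbors would.
#'
#' @param resname Residue type of the target (template-backed types
#'   only).
#' @param shell_radius Shell radius in Angstrom; must exceed the
#'   residue's extent plus probe diameter (default 5).
#' @param coverage `"full"`, `"half"` (z >= 0 hemisphere), or `"none"`.
#' @param point_spacing Approximate shell lattice spacing (Angstrom);
#'   must be small enough that shell spheres overlap (< ~2 vdW radii).
#' @param dir Output directory.
#' @return List with `path` (PDB file) and `target_key` (the target
#'   residue's key, `"A:1"`).
#' @examples
#' cage <- fixture_burial_cage(coverage = "full")
#' conf <- read_conformation(cage$path)
#' @export
fixture_burial_cage <- function(resname = "ALA", shell_radius = 5,
                                coverage = c("full", "half", "none"),
                                point_spacing = 1.1,
                                dir = tempfile("cage")) {
  coverage <- match.arg(coverage)
  stopifnot(resname %in% names(.residue_templates), shell_radius >= 4.5)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)

  tmpl <- .residue_templates[[resname]]
  target <- tibble::tibble(
    resno = 1L, resname = resname, atom = tmpl$atom,
    element = tmpl$element, x = tmpl$x, y = tmpl$y, z = tmpl$z,
    altloc = "", occupancy = 1
  )

  shell <- NULL
  if (coverage != "none") {
    n_pts <- ceiling(4 * pi * shell_radius^2 / point_spacing^2)
    pts <- golden_spiral_points(n_pts) * shell_radius
    if (coverage == "half") pts <- pts[pts[, 3] >= 0, , drop = FALSE]
    shell <- tibble::tibble(
      resno = 100L + seq_len(nrow(pts)), resname = "GLY", atom = "CA",
      element = "C", x = pts[, 1], y = pts[, 2], z = pts[, 3],
      altloc = "", occupancy = 1
    )
  }

  path <- file.path(dir, paste0("cage_", coverage, ".pdb"))
  lines_target <- fixture_atom_lines(target, chain = "A", serial0 = 0L)
  lines_shell <- if (is.null(shell)) character(0) else {
    fixture_atom_lines(shell, chain = "B", serial0 = nrow(target))
  }
  writeLines(c(lines_target, lines_shell, "END"), path)
  list(path = path, target_key = "A:1")
}

fixture_atom_lines <- function(atoms, chain, serial0) {
  name_field <- ifelse(nchar(atoms$atom) < 4,
                       sprintf(" %-3s", atoms$atom),
                       atoms$atom)
  sprintf(
    "ATOM  %5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    serial0 + seq_len(nrow(atoms)), name_field, atoms$altloc,
    atoms$resname, chain, atoms$resno, atoms$x, atoms$y, atoms$z,
    atoms$occupancy, 0, atoms$element
  )
}

# Idealized residue templates: local heavy-atom coordinates with CA at the
# origin. Geometry is plausible, not force-field exact — the pipeline is
# pure geometry, so only self-consistency matters.
.residue_templates <- local({
  bb <- function(extra_atoms, extra_elem, extra_xyz) {
    tibble::tibble(
      atom = c("N", "CA", "C", "O", extra_atoms),
      element = c("N", "C", "C", "O", extra_elem),
      x = c(-1.458, 0, 0.551, 0.320, extra_xyz[, 1]),
      y = c(0, 0, 1.392, 2.517, extra_xyz[, 2]),
      z = c(0, 0, 0, 0.250, extra_xyz[, 3])
    )
  }
  m <- function(...) {
    v <- c(..., numeric(0))
    matrix(v, ncol = 3, byrow = TRUE)
  }
  list(
    GLY = bb(character(0), character(0), m()),
    ALA = bb("CB", "C", m(-0.540, -0.770, 1.210)),
    SER = bb(c("CB", "OG"), c("C", "O"),
             m(-0.540, -0.770, 1.210,
               -0.300, -0.190, 2.480)),
    VAL = bb(c("CB", "CG1", "CG2"), c("C", "C", "C"),
             m(-0.540, -0.770, 1.210,
               -1.660, -1.740, 1.430,
               0.760, -1.500, 1.610)),
    ASP = bb(c("CB", "CG", "OD1", "OD2"), c("C", "C", "O", "O"),
             m(-0.540, -0.770, 1.210,
               -0.310, -0.190, 2.590,
               0.640, 0.600, 2.770,
               -1.060, -0.540, 3.540)),
    LYS = bb(c("CB", "CG", "CD", "CE", "NZ"), c("C", "C", "C", "C", "N"),
             m(-0.540, -0.770, 1.210,
               -0.310, -0.190, 2.590,
               -0.850, -1.080, 3.700,
               -0.620, -0.500, 5.080,
               -1.140, -1.360, 6.180)),
    THR = bb(c("CB", "OG1", "CG2"), c("C", "O", "C"),
             m(-0.540, -0.770, 1.210,
               -1.910, -1.100, 1.020,
               0.270, -2.040, 1.390)),
    LEU = bb(c("CB", "CG", "CD1", "CD2"), c("C", "C", "C", "C"),
             m(-0.540, -0.770, 1.210,
               -0.310, -0.190, 2.590,
               -1.150, -0.940, 3.610,
               1.160, -0.270, 2.980))
  )
})
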