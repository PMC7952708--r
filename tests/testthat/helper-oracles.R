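# Independent oracles and tiny hand-built inputs. Everything here avoids
# the package's own computation paths: PDB text is parsed by raw column
# slicing (not bio3d), centers of mass and distances by naive loops, and
# accessible area by a seeded random-direction sampler (not the package's
# golden-spiral lattice).

# -- minimal fixed-column PDB reader (independent of the package/bio3d) --
oracle_read_pdb <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[startsWith(lines, "ATOM  ")]
  data.frame(
    atom = trimws(substr(lines, 13, 16)),
    altloc = trimws(substr(lines, 17, 17)),
    resname = trimws(substr(lines, 18, 20)),
    chain = substr(lines, 22, 22),
    resno = as.integer(substr(lines, 23, 26)),
    icode = trimws(substr(lines, 27, 27)),
    x = as.numeric(substr(lines, 31, 38)),
    y = as.numeric(substr(lines, 39, 46)),
    z = as.numeric(substr(lines, 47, 54)),
    occ = as.numeric(substr(lines, 55, 60)),
    element = trimws(substr(lines, 77, 78)),
    stringsAsFactors = FALSE
  )
}

.oracle_masses <- c(C = 12.011, N = 14.007, O = 15.999, S = 32.06)
.oracle_backbone <- c("N", "CA", "C", "O", "OXT")

# mass-weighted side-chain COM per residue, naive implementation
oracle_coms <- function(at) {
  at <- at[order(at$chain, at$resno), ]
  keys <- unique(paste0(at$chain, ":", at$resno, at$icode))
  out <- NULL
  for (k in keys) {
    sel <- paste0(at$chain, ":", at$resno, at$icode) == k
    df <- at[sel, ]
    sc <- df[!(df$atom %in% .oracle_backbone), ]
    if (nrow(sc) == 0) sc <- df[df$atom == "CA", ]
    w <- .oracle_masses[sc$element]
    out <- rbind(out, data.frame(
      key = k,
      x = sum(w * sc$x) / sum(w),
      y = sum(w * sc$y) / sum(w),
      z = sum(w * sc$z) / sum(w)
    ))
  }
  out
}

# brute-force double-loop distance matrix over oracle COMs
oracle_distance_matrix <- function(coms) {
  n <- nrow(coms)
  d <- matrix(0, n, n, dimnames = list(coms$key, coms$key))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      d[i, j] <- sqrt((coms$x[i] - coms$x[j])^2 +
                        (coms$y[i] - coms$y[j])^2 +
                        (coms$z[i] - coms$z[j])^2)
    }
  }
  d
}

# random-direction Shrake-Rupley-style sampler; independent of the
# package's deterministic lattice. atoms: data.frame x,y,z,element.
.oracle_vdw <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80)
oracle_sasa <- function(atoms, probe = 1.4, n = 10000, seed = 99) {
  set.seed(seed)
  n_at <- nrow(atoms)
  radii <- unname(.oracle_vdw[atoms$element]) + probe
  area <- numeric(n_at)
  for (i in seq_len(n_at)) {
    dirs <- matrix(stats::rnorm(3 * n), ncol = 3)
    dirs <- dirs / sqrt(rowSums(dirs^2))
    pts <- dirs * radii[i]
    pts <- sweep(pts, 2, c(atoms$x[i], atoms$y[i], atoms$z[i]), `+`)
    exposed <- rep(TRUE, n)
    for (j in seq_len(n_at)[-i]) {
      d2 <- (pts[, 1] - atoms$x[j])^2 + (pts[, 2] - atoms$y[j])^2 +
        (pts[, 3] - atoms$z[j])^2
      exposed <- exposed & (d2 > radii[j]^2)
    }
    area[i] <- mean(exposed) * 4 * pi * radii[i]^2
  }
  sum(area)
}

# hand-rolled toy PDB text (3 ALA residues, chain A, 5 heavy atoms each)
toy_ala3_pdb <- function(path) {
  tpl <- c("N", "CA", "C", "O", "CB")
  ele <- c("N", "C", "C", "O", "C")
  off <- list(c(-1.458, 0, 0), c(0, 0, 0), c(0.551, 1.392, 0),
              c(0.320, 2.517, 0.25), c(-0.540, -0.770, 1.210))
  lines <- character(0)
  serial <- 0
  for (r in 1:3) {
    base <- c(4.0 * (r - 1), 0, 0)
    for (a in 1:5) {
      serial <- serial + 1
      p <- base + off[[a]]
      lines <- c(lines, sprintf(
        "ATOM  %5d  %-3s ALA A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        serial, tpl[a], r, p[1], p[2], p[3], 1, 0, ele[a]))
    }
  }
  writeLines(c(lines, "END"), path)
  path
}

# classic-DSSP-format writer for synthetic accessibility tables
# (fixed columns: resnum 6-10, icode 11, chain 12, aa 14, ss 17, ACC 35-38)
write_synthetic_dssp <- function(path, resno, chain, aa, acc, ss = NULL,
                                 icode = NULL) {
  n <- length(resno)
  if (is.null(ss)) ss <- rep(" ", n)
  if (is.null(icode)) icode <- rep(" ", n)
  ss[ss == ""] <- " "
  icode[icode == ""] <- " "
  hdr <- c(
    "==== Secondary Structure Definition by the program DSSP (synthetic fixture) ====",
    "  #  RESIDUE AA STRUCTURE BP1 BP2  ACC     N-H-->O    O-->H-N    N-H-->O    O-->H-N    TCO  KAPPA ALPHA  PHI   PSI    X-CA   Y-CA   Z-CA"
  )
  body <- sprintf("%5d%5d%1s%1s %1s  %1s%17s%4d",
                  seq_len(n), resno, icode, chain, aa, ss, "", acc)
  writeLines(c(hdr, body), path)
  path
}

# fake map constructors for boundary/threshold unit tests
fake_distance_map <- function(d, keys, label = "conf") {
  dimnames(d) <- list(keys, keys)
  structure(list(label = label, keys = keys, d = d, coms = NULL,
                 mode = "mass"),
            class = "distance_map")
}

fake_difference_map <- function(dd, keys) {
  dimnames(dd) <- list(keys, keys)
  structure(list(label_a = "a", label_b = "b", keys = keys, dd = dd),
            class = "difference_map")
}

# symmetric matrix from upper-triangle pair values
sym_from_pairs <- function(keys, values) {
  n <- length(keys)
  m <- matrix(0, n, n)
  m[upper.tri(m)] <- values
  m <- m + t(m)
  m
}
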