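test_that("isolated residue area matches an independent high-resolution sampler", {
  fx <- fixture_burial_cage(resname = "GLY", coverage = "none")
  conf <- read_conformation(fx$path)
  tab <- sasa(conf, n_points = 960)
  oracle <- oracle_sasa(as.data.frame(conf)[, c("x", "y", "z", "element")],
                        n = 10000)
  expect_lt(abs(tab$abs_area - oracle) / oracle, 0.02)
})

test_that("sphere-sampling converges: doubling the points moves areas < 1%", {
  fx <- fixture_conformer_pair(n_residues = 5, seed = 9)
  conf <- read_conformation(fx$path_a)
  a1 <- sasa(conf, n_points = 960)$abs_area
  a2 <- sasa(conf, n_points = 1920)$abs_area
  expect_lt(max(abs(a1 - a2) / a2), 0.01)
})

test_that("a fully caged residue has zero accessible area; a half shell sits between", {
  full <- fixture_burial_cage(coverage = "full")
  half <- fixture_burial_cage(coverage = "half")
  none <- fixture_burial_cage(coverage = "none")
  area_of <- function(fx) {
    tab <- sasa(read_conformation(fx$path), n_points = 480)
    tab$abs_area[tab$key == fx$target_key]
  }
  a_full <- area_of(full)
  a_half <- area_of(half)
  a_none <- area_of(none)
  expect_equal(a_full, 0, tolerance = 1e-8)
  expect_gt(a_none, 0)
  expect_gt(a_half, a_full)
  expect_lt(a_half, a_none)
})

test_that("adding occluders never increases accessible area", {
  # monotonicity: the same target with progressively more shell coverage
  none <- fixture_burial_cage(coverage = "none")
  conf0 <- read_conformation(none$path)
  base <- sasa(conf0, n_points = 480)$abs_area[1]
  prev <- base
  for (cov in c("half", "full")) {
    fx <- fixture_burial_cage(coverage = cov)
    tab <- sasa(read_conformation(fx$path), n_points = 480)
    now <- tab$abs_area[tab$key == fx$target_key]
    expect_lte(now, prev + 1e-9)
    prev <- now
  }
})

test_that("areas are invariant under rigid motion within sampling noise", {
  fx <- fixture_conformer_pair(n_residues = 5, seed = 10)
  conf <- read_conformation(fx$path_a)
  th <- 0.9
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3)
  xyz <- as.matrix(conf[, c("x", "y", "z")]) %*% t(R)
  moved <- conf
  moved$x <- xyz[, 1] + 5; moved$y <- xyz[, 2] - 3; moved$z <- xyz[, 3] + 1
  # the fixed lattice makes areas weakly orientation-dependent; the noise
  # shrinks with the lattice density (documented in the methods vignette)
  a0 <- sasa(conf, n_points = 960)$abs_area
  a1 <- sasa(moved, n_points = 960)$abs_area
  expect_lt(max(abs(a1 - a0) / a0), 0.015)
  b0 <- sasa(conf, n_points = 1920)$abs_area
  b1 <- sasa(moved, n_points = 1920)$abs_area
  expect_lt(max(abs(b1 - b0) / b0), 0.005)
})

test_that("RSA normalizes by the residue type's reference area, unclamped", {
  tab <- tibble::tibble(
    key = c("A:1", "A:2", "A:3"), chain = "A", resno = 1:3, icode = "",
    resname = c("GLY", "ALA", "LYS"),
    abs_area = c(0, 129.0, 260.0), rsa = NA_real_, ss = "",
    source = "internal"
  )
  tab <- structure(tibble::new_tibble(tab, class = "accessibility_tbl"),
                   label = "x")
  out <- relative_accessibility(tab)
  expect_equal(out$rsa[1], 0)                    # zero area -> 0%
  expect_equal(out$rsa[2], 100)                  # area == reference -> 100%
  expect_gt(out$rsa[3], 100)                     # may exceed 100, not clamped
  expect_equal(out$rsa[3], 100 * 260 / 236)
  bad <- tab
  bad$resname[1] <- "XXX"
  expect_error(relative_accessibility(bad), "XXX")
})

test_that("classic DSSP files parse: ACC, secondary structure, chain breaks", {
  path <- withr::local_tempfile(fileext = ".dssp")
  write_synthetic_dssp(path,
                       resno = c(10, 11, 12), chain = c("A", "A", "A"),
                       aa = c("G", "!", "K"), acc = c(100, 0, 40),
                       ss = c("H", " ", " "))
  tab <- read_dssp(path, label = "toy")
  expect_equal(nrow(tab), 2)                     # '!' break skipped
  expect_equal(tab$abs_area, c(100, 40))
  expect_equal(tab$resname, c("GLY", "LYS"))
  expect_equal(tab$ss, c("H", ""))
  expect_equal(tab$key, c("A:10", "A:12"))
  expect_true(all(tab$source == "dssp-file"))
  # lowercase = half-cystine -> CYS
  path2 <- withr::local_tempfile(fileext = ".dssp")
  write_synthetic_dssp(path2, resno = 1, chain = "A", aa = "a", acc = 55)
  expect_equal(read_dssp(path2)$resname, "CYS")
  # malformed body errors with the line number
  path3 <- withr::local_tempfile(fileext = ".dssp")
  writeLines(c("header", "  #  RESIDUE AA STRUCTURE", "garbage line"), path3)
  expect_error(read_dssp(path3), "line 3")
  # non-DSSP file refused
  expect_error(read_dssp(toy_ala3_pdb(withr::local_tempfile())), "header")
})

test_that("DSSP-derived keys agree with PDB-parser keys on the same fixture", {
  fx <- fixture_conformer_pair(n_residues = 6, seed = 12)
  conf <- read_conformation(fx$path_a)
  res <- dplyr::distinct(tibble::as_tibble(conf), key, chain, resno, resname)
  path <- withr::local_tempfile(fileext = ".dssp")
  write_synthetic_dssp(path, resno = res$resno, chain = res$chain,
                       aa = unname(c(ALA = "A", GLY = "G", SER = "S",
                                     VAL = "V", ASP = "D", LYS = "K",
                                     THR = "T", LEU = "L")[res$resname]),
                       acc = seq(50, by = 10, length.out = nrow(res)))
  tab <- read_dssp(path)
  expect_equal(tab$key, res$key)
  expect_equal(tab$resname, res$resname)
})

test_that("internal engine and DSSP-style areas agree within 5% per residue", {
  # the synthetic DSSP table is built from the independent oracle sampler,
  # standing in for a true DSSP run (different algorithm/point set)
  fx <- fixture_conformer_pair(n_residues = 4, seed = 13)
  conf <- read_conformation(fx$path_a)
  internal <- sasa(conf, n_points = 960)
  atoms <- as.data.frame(conf)
  oracle_areas <- vapply(internal$key, function(k) {
    # oracle computes per-atom areas over the whole structure, we sum the
    # residue's share by recomputing with that residue's atoms flagged
    at <- atoms[, c("x", "y", "z", "element")]
    set.seed(42)
    n <- 4000
    radii <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80)[at$element] + 1.4
    rows <- which(atoms$key == k)
    total <- 0
    for (i in rows) {
      dirs <- matrix(stats::rnorm(3 * n), ncol = 3)
      dirs <- dirs / sqrt(rowSums(dirs^2))
      pts <- sweep(dirs * radii[i], 2,
                   c(at$x[i], at$y[i], at$z[i]), `+`)
      exposed <- rep(TRUE, n)
      for (j in seq_len(nrow(at))[-i]) {
        d2 <- (pts[, 1] - at$x[j])^2 + (pts[, 2] - at$y[j])^2 +
          (pts[, 3] - at$z[j])^2
        exposed <- exposed & (d2 > radii[j]^2)
      }
      total <- total + mean(exposed) * 4 * pi * radii[i]^2
    }
    total
  }, numeric(1))
  expect_lt(max(abs(internal$abs_area - oracle_areas) / oracle_areas), 0.05)
})

test_that("unknown elements fall back to the default radius with a warning", {
  fx <- fixture_conformer_pair(n_residues = 4, seed = 2)
  conf <- read_conformation(fx$path_a)
  conf$element[1] <- "ZZ"
  expect_warning(sasa(conf, n_points = 240), "ZZ")
  expect_error(sasa(conf, n_points = 240, on_unknown_element = "error"),
               "ZZ")
})
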