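keys4 <- c("A:1", "A:2", "A:3", "A:4")

test_that("distance window is strict on both edges and spans all conformations", {
  th <- pair_thresholds(d_min = 40, d_max = 80, d_shift = 0, rsa_min = 0)
  # pair values in column-major upper-tri order:
  # (1,2) (1,3) (2,3) (1,4) (2,4) (3,4)
  d_a <- sym_from_pairs(keys4, c(67.3, 50, 40.0, 79.99, 41, 100))
  d_b <- sym_from_pairs(keys4, c(57.9, 50, 45.0, 80.00, 41, 50))
  maps <- list(fake_distance_map(d_a, keys4, "a"),
               fake_distance_map(d_b, keys4, "b"))
  mask <- filter_distance_range(maps, th)
  expect_true(mask[["A:1|A:2"]])        # inside the window in both
  expect_true(mask[["A:1|A:3"]])
  expect_false(mask[["A:2|A:3"]])       # exactly 40.0 in one -> strict reject
  expect_false(mask[["A:1|A:4"]])       # exactly 80.0 in one -> strict reject
  expect_true(mask[["A:2|A:4"]])
  expect_false(mask[["A:3|A:4"]])       # 100 out of range in one conformation
})

test_that("shift filter uses the absolute value, strictly", {
  th <- pair_thresholds(d_shift = 8)
  dd <- sym_from_pairs(keys4, c(-8.4, 6.4, 9.4, 8.0, -8.0, 0))
  mask <- filter_shift(fake_difference_map(dd, keys4), th)
  expect_true(mask[["A:1|A:2"]])        # -8.4: |dd| > 8 passes
  expect_false(mask[["A:1|A:3"]])       # 6.4 fails
  expect_true(mask[["A:2|A:3"]])        # 9.4 passes
  expect_false(mask[["A:1|A:4"]])       # exactly 8.0 -> strict reject
  expect_false(mask[["A:2|A:4"]])       # exactly -8.0 -> strict reject
  # degenerate threshold 0 keeps every pair with any change
  mask0 <- filter_shift(fake_difference_map(dd, keys4),
                        pair_thresholds(d_shift = 0))
  expect_equal(unname(mask0), c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE))
})

test_that("RSA filter needs both residues exposed in every conformation", {
  fake_tab <- function(rsa, label) {
    structure(
      tibble::new_tibble(tibble::tibble(
        key = keys4, chain = "A", resno = 1:4, icode = "",
        resname = "ALA", abs_area = rsa, rsa = rsa, ss = "",
        source = "internal"
      ), class = "accessibility_tbl"), label = label)
  }
  th <- pair_thresholds(rsa_min = 60)
  tabs <- list(fake_tab(c(91.7, 105.7, 8.8, 60.0), "a"),
               fake_tab(c(90.7, 88.6, 88.1, 61.0), "b"))
  mask <- filter_rsa(tabs, keys4, th)
  expect_true(mask[["A:1|A:2"]])        # 91.7/105.7 and 90.7/88.6
  expect_false(mask[["A:1|A:3"]])       # partner at 8.8 in one conformation
  expect_false(mask[["A:2|A:3"]])
  expect_true(mask[["A:1|A:4"]])        # exactly 60 kept (>= rule)
  # rsa_min 0 keeps everything
  expect_true(all(filter_rsa(tabs, keys4, pair_thresholds(rsa_min = 0))))
  # unfilled rsa errors
  tabs[[1]]$rsa <- NA_real_
  expect_error(filter_rsa(tabs, keys4, th), "relative_accessibility")
})

test_that("selection equals an exhaustive brute-force oracle on a random fixture", {
  fx <- fixture_conformer_pair(n_residues = 8, angle = 80, seed = 21)
  conf_a <- read_conformation(fx$path_a, label = "a")
  conf_b <- read_conformation(fx$path_b, label = "b")
  corr <- build_correspondence(list(conf_a, conf_b))
  dm_a <- distance_map(conf_a, corr)
  dm_b <- distance_map(conf_b, corr)
  diff <- difference_map(dm_a, dm_b)
  tabs <- lapply(list(conf_a, conf_b), function(cf)
    relative_accessibility(sasa(cf, n_points = 480)))
  th <- pair_thresholds(d_min = 10, d_max = 40, d_shift = 3, rsa_min = 60)
  sel <- select_pairs(list(dm_a, dm_b), diff, tabs, th)

  # brute force over all 28 pairs, written independently of the masks
  keys <- corr$keys$key
  rsa_a <- tabs[[1]]$rsa[match(keys, tabs[[1]]$key)]
  rsa_b <- tabs[[2]]$rsa[match(keys, tabs[[2]]$key)]
  expected <- character(0)
  for (i in seq_along(keys)) {
    for (j in seq_along(keys)) {
      if (i >= j) next
      ok <- dm_a$d[i, j] > th$d_min && dm_a$d[i, j] < th$d_max &&
        dm_b$d[i, j] > th$d_min && dm_b$d[i, j] < th$d_max &&
        abs(diff$dd[i, j]) > th$d_shift &&
        rsa_a[i] >= th$rsa_min && rsa_a[j] >= th$rsa_min &&
        rsa_b[i] >= th$rsa_min && rsa_b[j] >= th$rsa_min
      if (ok) expected <- c(expected, paste(keys[i], keys[j], sep = "|"))
    }
  }
  got <- paste(sel$key_i[sel$passed], sel$key_j[sel$passed], sep = "|")
  expect_setequal(got, expected)
  expect_equal(nrow(sel), choose(8, 2))
  # passed <-> failed_filters empty
  expect_equal(sel$passed, sel$failed_filters == "")
})

test_that("an impossible shift threshold yields zero passing pairs", {
  fx <- fixture_conformer_pair(n_residues = 6, angle = 60, seed = 3)
  conf_a <- read_conformation(fx$path_a, label = "a")
  conf_b <- read_conformation(fx$path_b, label = "b")
  corr <- build_correspondence(list(conf_a, conf_b))
  dm_a <- distance_map(conf_a, corr); dm_b <- distance_map(conf_b, corr)
  tabs <- lapply(list(conf_a, conf_b), function(cf)
    relative_accessibility(sasa(cf, n_points = 240)))
  sel <- select_pairs(list(dm_a, dm_b), difference_map(dm_a, dm_b), tabs,
                      pair_thresholds(0.1, 1000, 1e6, 0))
  expect_equal(sum(sel$passed), 0)
})

test_that("tightening any threshold never adds a passing pair", {
  fx <- fixture_conformer_pair(n_residues = 8, angle = 80, seed = 31)
  conf_a <- read_conformation(fx$path_a, label = "a")
  conf_b <- read_conformation(fx$path_b, label = "b")
  corr <- build_correspondence(list(conf_a, conf_b))
  dm_a <- distance_map(conf_a, corr); dm_b <- distance_map(conf_b, corr)
  diff <- difference_map(dm_a, dm_b)
  tabs <- lapply(list(conf_a, conf_b), function(cf)
    relative_accessibility(sasa(cf, n_points = 240)))
  base <- pair_thresholds(d_min = 8, d_max = 45, d_shift = 2, rsa_min = 50)
  passing_set <- function(th) {
    sel <- select_pairs(list(dm_a, dm_b), diff, tabs, th)
    paste(sel$key_i[sel$passed], sel$key_j[sel$passed], sep = "|")
  }
  p0 <- passing_set(base)
  tighter <- list(
    pair_thresholds(12, 45, 2, 50),   # raise d_min
    pair_thresholds(8, 35, 2, 50),    # lower d_max
    pair_thresholds(8, 45, 5, 50),    # raise d_shift
    pair_thresholds(8, 45, 2, 80),    # raise rsa_min
    pair_thresholds(8, 45, 2, 50, min_separation = 3)
  )
  for (th in tighter) {
    expect_true(all(passing_set(th) %in% p0))
  }
})

test_that("filter masks commute: any intersection order gives the same set", {
  fx <- fixture_conformer_pair(n_residues = 7, angle = 70, seed = 17)
  conf_a <- read_conformation(fx$path_a, label = "a")
  conf_b <- read_conformation(fx$path_b, label = "b")
  corr <- build_correspondence(list(conf_a, conf_b))
  dm_a <- distance_map(conf_a, corr); dm_b <- distance_map(conf_b, corr)
  diff <- difference_map(dm_a, dm_b)
  tabs <- lapply(list(conf_a, conf_b), function(cf)
    relative_accessibility(sasa(cf, n_points = 240)))
  th <- pair_thresholds(8, 45, 3, 60)
  m1 <- filter_distance_range(list(dm_a, dm_b), th)
  m2 <- filter_shift(diff, th)
  m3 <- filter_rsa(tabs, corr$keys$key, th)
  expect_equal(m1 & m2 & m3, m3 & m1 & m2)
  expect_equal(m1 & (m2 & m3), (m1 & m2) & m3)
})

test_that("output is canonical: no (j,i) duplicates, sorted by |shift|", {
  fx <- fixture_conformer_pair(n_residues = 8, angle = 80, seed = 5)
  conf_a <- read_conformation(fx$path_a, label = "a")
  conf_b <- read_conformation(fx$path_b, label = "b")
  corr <- build_correspondence(list(conf_a, conf_b))
  dm_a <- distance_map(conf_a, corr); dm_b <- distance_map(conf_b, corr)
  tabs <- lapply(list(conf_a, conf_b), function(cf)
    relative_accessibility(sasa(cf, n_points = 240)))
  sel <- select_pairs(list(dm_a, dm_b), difference_map(dm_a, dm_b), tabs,
                      pair_thresholds(5, 50, 2, 0))
  ids <- paste(sel$key_i, sel$key_j, sep = "|")
  rev_ids <- paste(sel$key_j, sel$key_i, sep = "|")
  expect_equal(anyDuplicated(ids), 0)
  expect_false(any(rev_ids %in% ids))
  shifts <- abs(sel$dd[sel$passed])
  expect_true(all(diff(shifts) <= 1e-12))
  # key order within a pair follows residue order
  ki <- match(sel$key_i, corr$keys$key)
  kj <- match(sel$key_j, corr$keys$key)
  expect_true(all(ki < kj))
})

test_that("thresholds round-trip through the config file", {
  th <- pair_thresholds(35.5, 72, 6.25, 55, ss_allowed = c("H", "E"),
                        min_separation = 4)
  path <- withr::local_tempfile(fileext = ".cfg")
  write_thresholds(th, path)
  back <- read_thresholds(path)
  expect_equal(back, th)
  expect_error(pair_thresholds(d_min = 50, d_max = 40))
})

test_that("glance and tidy summarize the cascade faithfully", {
  fx <- fixture_conformer_pair(n_residues = 7, angle = 80, seed = 7)
  conf_a <- read_conformation(fx$path_a, label = "a")
  conf_b <- read_conformation(fx$path_b, label = "b")
  corr <- build_correspondence(list(conf_a, conf_b))
  dm_a <- distance_map(conf_a, corr); dm_b <- distance_map(conf_b, corr)
  tabs <- lapply(list(conf_a, conf_b), function(cf)
    relative_accessibility(sasa(cf, n_points = 240)))
  sel <- select_pairs(list(dm_a, dm_b), difference_map(dm_a, dm_b), tabs,
                      pair_thresholds(5, 45, 3, 50))
  g <- glance(sel)
  expect_equal(g$n_pairs, choose(7, 2))
  expect_true(g$n_after_distance >= g$n_after_shift)
  expect_true(g$n_after_shift >= g$n_after_rsa)
  expect_equal(g$n_passed, sum(sel$passed))
  expect_equal(nrow(tidy(sel)), sum(sel$passed))
  expect_equal(nrow(tidy(sel, all_pairs = TRUE)), nrow(sel))
})
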