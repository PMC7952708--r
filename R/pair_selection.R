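#' Filter thresholds for residue-pair selection
#'
#' Bundles the tunable cut-offs of the selection cascade. The defaults are
#' the values used for the OpuAC substrate-binding-protein worked example
#' and suit a typical smFRET dye pair with a Forster radius near 5 nm;
#' tighten or relax them to match the distance sensitivity of your label
#' pair.
#'
#' @param d_min,d_max Distance window (Angstrom): a pair is kept only if
#'   `d_min < d < d_max` holds strictly in every conformation.
#' @param d_shift Minimum absolute distance change (Angstrom): a pair is
#'   kept only if `|dd| > d_shift`. The absolute value matters — pairs
#'   moving apart are as informative as pairs approaching; only the sign
#'   of the expected signal differs.
#' @param rsa_min Minimum relative surface accessibility (percent) that
#'   both residues must reach in every conformation (`rsa >= rsa_min`),
#'   ensuring the label can be coupled and can rotate freely.
#' @param ss_allowed Optional character vector of DSSP secondary-structure
#'   codes; when given, both residues must carry one of these codes in
#'   every conformation (e.g. `c("", "S", "T")` to prefer loops and
#'   turns). Requires DSSP-sourced accessibility tables.
#' @param min_separation Minimum |sequence separation| within a chain
#'   (residues); 0 applies no constraint. Cross-chain pairs always pass.
#' @return A list of class `pair_thresholds`.
#' @export
pair_thresholds <- function(d_min = 40, d_max = 80, d_shift = 8,
                            rsa_min = 60, ss_allowed = NULL,
                            min_separation = 0) {
  stopifnot(d_min >= 0, d_min < d_max, d_shift >= 0, rsa_min >= 0,
            min_separation >= 0)
  structure(
    list(d_min = d_min, d_max = d_max, d_shift = d_shift,
         rsa_min = rsa_min, ss_allowed = ss_allowed,
         min_separation = as.integer(min_separation)),
    class = "pair_thresholds"
  )
}

#' @export
print.pair_thresholds <- function(x, ...) {
  cat("# Pair-selection thresholds\n")
  cat(sprintf("#   distance window : %g < d < %g A (all conformations)\n",
              x$d_min, x$d_max))
  cat(sprintf("#   distance shift  : |dd| > %g A\n", x$d_shift))
  cat(sprintf("#   accessibility   : RSA >= %g%% (both residues, all conformations)\n",
              x$rsa_min))
  if (!is.null(x$ss_allowed))
    cat("#   secondary struct: codes {",
        paste(x$ss_allowed, collapse = ","), "}\n", sep = "")
  if (x$min_separation > 0)
    cat(sprintf("#   min separation  : %d residues\n", x$min_separation))
  invisible(x)
}

#' Write / read a thresholds configuration file
#'
#' Round-trips a [pair_thresholds()] object through a flat `key = value`
#' text file.
#'
#' @param thresholds A `pair_thresholds` object.
#' @param path File path.
#' @return `write_thresholds()` returns `path` invisibly;
#'   `read_thresholds()` returns a `pair_thresholds`.
#' @export
write_thresholds <- function(thresholds, path) {
  stopifnot(inherits(thresholds, "pair_thresholds"))
  lines <- c(
    sprintf("d_min = %.15g", thresholds$d_min),
    sprintf("d_max = %.15g", thresholds$d_max),
    sprintf("d_shift = %.15g", thresholds$d_shift),
    sprintf("rsa_min = %.15g", thresholds$rsa_min),
    sprintf("min_separation = %d", thresholds$min_separation)
  )
  if (!is.null(thresholds$ss_allowed)) {
    lines <- c(lines, paste0("ss_allowed = ",
                             paste(thresholds$ss_allowed, collapse = ",")))
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_thresholds
#' @export
read_thresholds <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- trimws(vapply(kv, `[`, "", 1))
  vals <- trimws(vapply(kv, function(p) paste(p[-1], collapse = "="), ""))
  get_num <- function(k, default) {
    if (k %in% keys) as.numeric(vals[match(k, keys)]) else default
  }
  ss <- if ("ss_allowed" %in% keys) {
    strsplit(vals[match("ss_allowed", keys)], ",", fixed = TRUE)[[1]]
  } else NULL
  pair_thresholds(
    d_min = get_num("d_min", 40), d_max = get_num("d_max", 80),
    d_shift = get_num("d_shift", 8), rsa_min = get_num("rsa_min", 60),
    ss_allowed = ss, min_separation = get_num("min_separation", 0)
  )
}

# All unordered residue pairs (i < j in key order) of a key vector,
# as index pairs into `keys`.
pair_index <- function(keys) {
  n <- length(keys)
  idx <- which(upper.tri(matrix(TRUE, n, n)), arr.ind = TRUE)
  tibble::tibble(i = idx[, "row"], j = idx[, "col"])
}

#' Distance-window filter
#'
#' Mask over all unordered residue pairs: `TRUE` where the pair's
#' side-chain COM distance lies strictly inside `(d_min, d_max)` in every
#' conformation.
#'
#' @param dmaps List of `distance_map` objects sharing one key list.
#' @param thresholds A [pair_thresholds()].
#' @return Logical vector over the pairs enumerated by key order
#'   (`i < j`), named `"key_i|key_j"`.
#' @export
filter_distance_range <- function(dmaps, thresholds) {
  keys <- shared_keys(dmaps)
  pr <- pair_index(keys)
  keep <- rep(TRUE, nrow(pr))
  for (m in dmaps) {
    d <- m$d[cbind(pr$i, pr$j)]
    keep <- keep & (d > thresholds$d_min) & (d < thresholds$d_max)
  }
  stats::setNames(keep, paste(keys[pr$i], keys[pr$j], sep = "|"))
}

#' Distance-shift filter
#'
#' Mask over all unordered residue pairs: `TRUE` where the absolute
#' distance change between the two conformations exceeds `d_shift`
#' strictly. The absolute value is deliberate: a pair whose distance
#' grows by 8.4 Angstrom carries as much signal as one that shrinks by
#' 8.4 Angstrom.
#'
#' @param diff A `difference_map`.
#' @param thresholds A [pair_thresholds()].
#' @return Logical pair mask as in [filter_distance_range()].
#' @export
filter_shift <- function(diff, thresholds) {
  pr <- pair_index(diff$keys)
  dd <- diff$dd[cbind(pr$i, pr$j)]
  stats::setNames(abs(dd) > thresholds$d_shift,
                  paste(diff$keys[pr$i], diff$keys[pr$j], sep = "|"))
}

#' Accessibility filter
#'
#' Mask over all unordered residue pairs: `TRUE` where both residues reach
#' `rsa_min` percent relative accessibility in every conformation. If
#' `thresholds$ss_allowed` is set, both residues must additionally carry
#' an allowed secondary-structure code in every table.
#'
#' @param tables List of `accessibility_tbl` with `rsa` filled (one per
#'   conformation).
#' @param keys Ordered residue keys defining the pair enumeration.
#' @param thresholds A [pair_thresholds()].
#' @return Logical pair mask as in [filter_distance_range()].
#' @export
filter_rsa <- function(tables, keys, thresholds) {
  pr <- pair_index(keys)
  keep <- rep(TRUE, nrow(pr))
  for (tab in tables) {
    idx <- match(keys, tab$key)
    if (anyNA(idx)) {
      stop("accessibility table '", accessibility_label(tab),
           "' lacks residue(s): ",
           paste(utils::head(keys[is.na(idx)], 5), collapse = ", "),
           call. = FALSE)
    }
    rsa <- tab$rsa[idx]
    if (anyNA(rsa)) {
      stop("rsa not filled in table '", accessibility_label(tab),
           "'; run relative_accessibility() first", call. = FALSE)
    }
    keep <- keep & (rsa[pr$i] >= thresholds$rsa_min) &
      (rsa[pr$j] >= thresholds$rsa_min)
    if (!is.null(thresholds$ss_allowed)) {
      ss <- tab$ss[idx]
      keep <- keep & (ss[pr$i] %in% thresholds$ss_allowed) &
        (ss[pr$j] %in% thresholds$ss_allowed)
    }
  }
  stats::setNames(keep, paste(keys[pr$i], keys[pr$j], sep = "|"))
}

# sequence-separation mask: TRUE if cross-chain or |resno_i - resno_j| >= k
filter_separation <- function(keys, key_info, thresholds) {
  pr <- pair_index(keys)
  info <- key_info[match(keys, key_info$key), ]
  same_chain <- info$chain[pr$i] == info$chain[pr$j]
  sep <- abs(info$resno[pr$i] - info$resno[pr$j])
  stats::setNames(!same_chain | sep >= thresholds$min_separation,
                  paste(keys[pr$i], keys[pr$j], sep = "|"))
}

shared_keys <- function(dmaps) {
  keys <- dmaps[[1]]$keys
  for (m in dmaps[-1]) {
    if (!identical(m$keys, keys)) {
      stop("distance maps are over different residue sets", call. = FALSE)
    }
  }
  keys
}

#' Select candidate labeling pairs
#'
#' Applies the full filter cascade — distance window in every
#' conformation, minimum absolute distance shift, minimum relative
#' accessibility for both residues in every conformation, plus the
#' optional secondary-structure and sequence-separation constraints — to
#' every unordered residue pair and returns one record per pair.
#'
#' @param dmaps List of `distance_map` objects (one per conformation, at
#'   least two), identical key lists.
#' @param diff `difference_map` between the first two conformations.
#' @param tables List of `accessibility_tbl` with `rsa` filled, same
#'   order as `dmaps`.
#' @param thresholds A [pair_thresholds()].
#' @param correspondence Optional `residue_correspondence` providing
#'   chain/resno for the separation filter; derived from keys if absent.
#' @return A tibble of class `pair_selection` with one row per unordered
#'   pair (`key_i < key_j` in residue order): per-conformation distances
#'   (`d_<label>`), signed shift `dd`, `direction`
#'   (`"decreasing"`/`"increasing"` distance from first to second
#'   conformation), per-residue per-conformation RSA
#'   (`rsa_i_<label>`, `rsa_j_<label>`), `passed`, and `failed_filters`
#'   (comma-separated names, empty when passed). Passing rows sort first,
#'   by decreasing `|dd|` then keys; failing rows follow in key order.
#'   Attributes: `thresholds`, `survivors` (pair counts down the
#'   cascade), `labels`.
#' @examples
#' pdb <- fixture_conformer_pair(n_residues = 8, angle = 60)
#' confs <- list(read_conformation(pdb$path_a, label = "open"),
#'               read_conformation(pdb$path_b, label = "closed"))
#' corr <- build_correspondence(confs)
#' dmaps <- lapply(confs, distance_map, correspondence = corr)
#' diff <- difference_map(dmaps[[1]], dmaps[[2]])
#' tabs <- lapply(confs, function(cf)
#'   relative_accessibility(sasa(cf, n_points = 240)))
#' sel <- select_pairs(dmaps, diff, tabs,
#'                     pair_thresholds(5, 40, 4, 20))
#' dplyr::filter(sel, passed)
#' @export
select_pairs <- function(dmaps, diff, tables, thresholds = pair_thresholds(),
                         correspondence = NULL) {
  stopifnot(length(dmaps) >= 2, length(tables) == length(dmaps),
            inherits(diff, "difference_map"),
            inherits(thresholds, "pair_thresholds"))
  keys <- shared_keys(dmaps)
  if (!identical(diff$keys, keys)) {
    stop("difference map keys differ from distance map keys", call. = FALSE)
  }
  labels <- vapply(dmaps, function(m) m$label, character(1))
  if (anyDuplicated(labels)) {
    labels <- make.unique(labels, sep = "_")
  }

  mask_range <- filter_distance_range(dmaps, thresholds)
  mask_shift <- filter_shift(diff, thresholds)
  mask_rsa <- filter_rsa(tables, keys, thresholds)

  key_info <- if (!is.null(correspondence)) {
    correspondence$keys
  } else {
    parse_keys(keys)
  }
  mask_sep <- filter_separation(keys, key_info, thresholds)

  masks <- list(distance_range = mask_range, distance_shift = mask_shift,
                rsa = mask_rsa, separation = mask_sep)
  pr <- pair_index(keys)

  failed <- vapply(seq_len(nrow(pr)), function(p) {
    paste(names(masks)[!vapply(masks, `[`, NA, p)], collapse = ",")
  }, character(1))

  rec <- tibble::tibble(
    key_i = keys[pr$i], key_j = keys[pr$j],
    dd = diff$dd[cbind(pr$i, pr$j)]
  )
  for (k in seq_along(dmaps)) {
    rec[[paste0("d_", labels[k])]] <- dmaps[[k]]$d[cbind(pr$i, pr$j)]
  }
  for (k in seq_along(tables)) {
    idx <- match(keys, tables[[k]]$key)
    rec[[paste0("rsa_i_", labels[k])]] <- tables[[k]]$rsa[idx][pr$i]
    rec[[paste0("rsa_j_", labels[k])]] <- tables[[k]]$rsa[idx][pr$j]
  }
  rec$direction <- dplyr::case_when(
    rec$dd > 0 ~ "decreasing",
    rec$dd < 0 ~ "increasing",
    TRUE ~ "unchanged"
  )
  rec$passed <- failed == ""
  rec$failed_filters <- failed

  # survivor counts down the cascade, in filter order
  cascade <- c("all", "distance_range", "distance_shift", "rsa")
  surv <- stats::setNames(integer(length(cascade)), cascade)
  running <- rep(TRUE, nrow(pr))
  surv["all"] <- sum(running)
  for (nm in cascade[-1]) {
    running <- running & masks[[nm]]
    surv[nm] <- sum(running)
  }

  ord_pass <- which(rec$passed)
  ord_pass <- ord_pass[order(-abs(rec$dd[ord_pass]), rec$key_i[ord_pass],
                             rec$key_j[ord_pass])]
  ord_fail <- which(!rec$passed)
  rec <- rec[c(ord_pass, ord_fail), , drop = FALSE]

  structure(
    tibble::new_tibble(rec, class = "pair_selection"),
    thresholds = thresholds, survivors = surv, labels = labels
  )
}

parse_keys <- function(keys) {
  m <- regmatches(keys, regexec("^(.*):(-?[0-9]+)([A-Za-z]?)$", keys))
  tibble::tibble(
    key = keys,
    chain = vapply(m, `[`, "", 2),
    resno = as.integer(vapply(m, `[`, "", 3)),
    icode = vapply(m, `[`, "", 4)
  )
}

#' @export
print.pair_selection <- function(x, ...) {
  surv <- attr(x, "survivors")
  cat("# Candidate labeling pairs: ", sum(x$passed), " of ", nrow(x),
      " pairs pass\n", sep = "")
  cat("# cascade: ", paste(sprintf("%s=%d", names(surv), surv),
                           collapse = " -> "), "\n", sep = "")
  NextMethod()
}

#' Tidy the passing pairs of a selection
#'
#' @param x A `pair_selection` from [select_pairs()].
#' @param all_pairs If `TRUE` return every pair with its verdict;
#'   default returns passing pairs only.
#' @param ... Unused.
#' @return A tibble (the selection rows, passed-only by default).
#' @method tidy pair_selection
#' @export
tidy.pair_selection <- function(x, all_pairs = FALSE, ...) {
  out <- tibble::as_tibble(x)
  if (!all_pairs) out <- dplyr::filter(out, .data$passed)
  out
}

#' One-row summary of a selection
#'
#' @param x A `pair_selection`.
#' @param ... Unused.
#' @return A one-row tibble: total pairs, survivors after each filter,
#'   passing count, and the threshold values used.
#' @method glance pair_selection
#' @export
glance.pair_selection <- function(x, ...) {
  surv <- attr(x, "survivors")
  th <- attr(x, "thresholds")
  tibble::tibble(
    n_pairs = unname(surv["all"]),
    n_after_distance = unname(surv["distance_range"]),
    n_after_shift = unname(surv["distance_shift"]),
    n_after_rsa = unname(surv["rsa"]),
    n_passed = sum(x$passed),
    d_min = th$d_min, d_max = th$d_max, d_shift = th$d_shift,
    rsa_min = th$rsa_min
  )
}

#' Plot the distance shifts of candidate pairs
#'
#' Lollipop plot of the signed distance change of every passing pair,
#' colored by direction (distance decreasing vs increasing between the
#' first and second conformation).
#'
#' @param object A `pair_selection`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pair_selection
#' @export
autoplot.pair_selection <- function(object, ...) {
  df <- tidy.pair_selection(object)
  if (nrow(df) == 0) {
    stop("no passing pairs to plot", call. = FALSE)
  }
  df$pair <- paste(df$key_i, df$key_j, sep = " / ")
  df$pair <- factor(df$pair, levels = df$pair[order(abs(df$dd))])
  ggplot2::ggplot(df, ggplot2::aes(.data$dd, .data$pair,
                                   color = .data$direction)) +
    ggplot2::geom_segment(ggplot2::aes(x = 0, xend = .data$dd,
                                       yend = .data$pair)) +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::scale_color_manual(
      values = c(decreasing = "#d95f02", increasing = "#2166ac",
                 unchanged = "grey50")
    ) +
    ggplot2::labs(x = "distance change (Å)", y = NULL,
                  title = "Candidate labeling pairs") +
    ggplot2::theme_minimal()
}
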