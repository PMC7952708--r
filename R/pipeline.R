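#' Screen residue pairs for labeling sites across conformations
#'
#' One-call orchestration of the full screen: parse the structures,
#' establish residue correspondence, build side-chain COM distance maps
#' and the difference map, compute (or ingest) solvent accessibility,
#' normalize to RSA, apply the filter cascade, and return the candidate
#' pairs. This is the tool's main entry point; the individual stages are
#' exported for piecewise use.
#'
#' @param paths Character vector of two or more PDB file paths. The first
#'   is conformation A (e.g. the open/apo state), the second conformation
#'   B; the difference map is `d_A - d_B`, so positive shifts mean the
#'   pair approaches going from A to B.
#' @param labels Conformation labels, same length as `paths` (default:
#'   file names).
#' @param chains Optional chain filter applied to every structure.
#' @param thresholds A [pair_thresholds()].
#' @param com_mode Side-chain anchor: `"mass"`, `"geometric"`, or
#'   `"calpha"` (see [sidechain_com()]).
#' @param dssp Optional character vector of classic DSSP files, same
#'   length/order as `paths`; when given, accessibility comes from their
#'   ACC column instead of the internal engine.
#' @param sasa_n_points Sphere-sampling density for the internal engine.
#' @param pairs_out,matrix_out,pml_out Optional output paths: candidate
#'   CSV, matrix grids (given a path `P`, writes `P_<label>.csv` per
#'   conformation plus `P_diff.csv`), and PyMOL script.
#' @param all_pairs Write failing pairs to `pairs_out` too.
#' @param verbose Log residue counts, dropped residues, and per-filter
#'   survivor counts to stderr.
#' @return The `pair_selection` tibble from [select_pairs()], with
#'   additional attributes `conformations`, `correspondence`, `dmaps`,
#'   `diff`, and `accessibility` for downstream inspection/plotting.
#' @examples
#' fx <- fixture_conformer_pair(n_residues = 8, angle = 60, seed = 2)
#' sel <- screen_pairs(c(fx$path_a, fx$path_b),
#'                     labels = c("open", "closed"),
#'                     thresholds = pair_thresholds(5, 40, 4, 20),
#'                     sasa_n_points = 240)
#' glance(sel)
#' @export
screen_pairs <- function(paths, labels = NULL, chains = NULL,
                         thresholds = pair_thresholds(),
                         com_mode = c("mass", "geometric", "calpha"),
                         dssp = NULL, sasa_n_points = 960,
                         pairs_out = NULL, matrix_out = NULL,
                         pml_out = NULL, all_pairs = FALSE,
                         verbose = FALSE) {
  com_mode <- match.arg(com_mode)
  stopifnot(length(paths) >= 2)
  if (is.null(labels)) {
    labels <- make.unique(sub("\\.[^.]*$", "", basename(paths)), sep = "_")
  }
  stopifnot(length(labels) == length(paths), !anyDuplicated(labels))
  if (!is.null(dssp)) stopifnot(length(dssp) == length(paths))

  say <- function(...) if (verbose) message(...)

  confs <- purrr::map2(paths, labels, function(p, l) {
    cf <- read_conformation(p, chains = chains, label = l)
    say(sprintf("[%s] %d residues, %d heavy atoms (%s)", l,
                dplyr::n_distinct(cf$key), nrow(cf), p))
    cf
  })

  corr <- build_correspondence(confs)
  say(sprintf("correspondence: %d matched residues, %d dropped",
              nrow(corr$keys), nrow(corr$dropped)))
  if (verbose && nrow(corr$dropped) > 0) {
    for (r in seq_len(nrow(corr$dropped))) {
      say(sprintf("  dropped %s (%s)", corr$dropped$key[r],
                  corr$dropped$reason[r]))
    }
  }

  dmaps <- purrr::map(confs, distance_map, correspondence = corr,
                      mode = com_mode)
  diff <- difference_map(dmaps[[1]], dmaps[[2]])

  tables <- if (is.null(dssp)) {
    purrr::map(confs, function(cf) {
      relative_accessibility(sasa(cf, n_points = sasa_n_points))
    })
  } else {
    purrr::map2(dssp, labels, read_dssp) |>
      purrr::map(relative_accessibility)
  }

  sel <- select_pairs(dmaps, diff, tables, thresholds,
                      correspondence = corr)
  surv <- attr(sel, "survivors")
  say(sprintf("filter cascade: %s",
              paste(sprintf("%s=%d", names(surv), surv), collapse = " -> ")))
  if (sum(sel$passed) == 0) {
    warning("no residue pair passes the thresholds; consider relaxing ",
            "them", call. = FALSE)
  }

  if (!is.null(pairs_out)) {
    write_pairs_csv(sel, pairs_out, all_pairs = all_pairs)
    say("wrote pairs: ", pairs_out)
  }
  if (!is.null(matrix_out)) {
    stem <- sub("\\.csv$", "", matrix_out)
    for (k in seq_along(dmaps)) {
      write_matrix(dmaps[[k]], paste0(stem, "_", labels[k], ".csv"))
    }
    write_matrix(diff, paste0(stem, "_diff.csv"))
    say("wrote matrices: ", stem, "_*.csv")
  }
  if (!is.null(pml_out)) {
    write_viewer_script(sel, confs[[1]], pml_out)
    say("wrote viewer script: ", pml_out)
  }

  attr(sel, "conformations") <- confs
  attr(sel, "correspondence") <- corr
  attr(sel, "dmaps") <- dmaps
  attr(sel, "diff") <- diff
  attr(sel, "accessibility") <- tables
  sel
}
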