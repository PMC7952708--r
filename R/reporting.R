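#' Write candidate pairs to CSV
#'
#' Serializes pair records with the field's reporting conventions:
#' distances, shifts and RSA values printed with one decimal. Output is
#' deterministic byte-for-byte for identical input (fixed column order,
#' fixed formatting, no timestamps).
#'
#' @param records A `pair_selection` tibble (or any tibble with its
#'   columns).
#' @param path Output file path.
#' @param all_pairs Write failing pairs too (default: passing only).
#' @return `path`, invisibly.
#' @seealso [read_pairs_csv()]
#' @export
write_pairs_csv <- function(records, path, all_pairs = FALSE) {
  df <- tibble::as_tibble(records)
  if (!all_pairs && "passed" %in% names(df)) {
    df <- dplyr::filter(df, .data$passed)
  }
  num <- vapply(df, is.numeric, NA)
  df[num] <- lapply(df[num], function(v) sprintf("%.1f", v))
  readr::write_csv(df, path, progress = FALSE)
  invisible(path)
}

#' Read back a pairs CSV
#'
#' @param path File written by [write_pairs_csv()].
#' @return A tibble with numeric columns restored.
#' @export
read_pairs_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' Write a distance or difference map as a CSV grid
#'
#' Rectangular grid with residue keys as first row and first column;
#' distances to three decimals (the coordinate precision of the PDB
#' format), signed for difference maps.
#'
#' @param map A `distance_map` or `difference_map`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [read_matrix()]
#' @export
write_matrix <- function(map, path) {
  m <- map_matrix(map)
  keys <- if (inherits(map, "distance_map")) map$keys else map$keys
  header <- paste(c("key", keys), collapse = ",")
  rows <- vapply(seq_along(keys), function(i) {
    paste(c(keys[i], sprintf("%.3f", m[i, ])), collapse = ",")
  }, character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read back a matrix grid written by [write_matrix()]
#'
#' @param path CSV grid file.
#' @return A list with `keys` and numeric matrix `m` (dimnames = keys).
#' @export
read_matrix <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  keys <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  dimnames(m) <- list(keys, keys)
  list(keys = keys, m = m)
}

#' Write a PyMOL viewer script for candidate pairs
#'
#' Emits a plain-text PyMOL command script that loads the structure,
#' shows each candidate pair's residues as spheres, and colors them by
#' the direction of the distance change: red for pairs whose distance
#' decreases from the first to the second conformation, blue for pairs
#' whose distance increases. One command per line; the script loads in
#' PyMOL without edits and supports the manual-inspection step in which
#' pairs clashing with functional or interface regions are weeded out.
#'
#' @param records A `pair_selection` (passing rows are exported).
#' @param conformation The `conformation` the selections refer to (used
#'   to validate that every residue exists and to locate the structure
#'   file to load).
#' @param path Output file path (conventionally `.pml`).
#' @param colors Named vector with `decreasing`/`increasing` colors.
#' @return `path`, invisibly.
#' @export
write_viewer_script <- function(records, conformation, path,
                                colors = c(decreasing = "red",
                                           increasing = "blue")) {
  df <- tibble::as_tibble(records)
  if ("passed" %in% names(df)) df <- dplyr::filter(df, .data$passed)

  res_keys <- unique(tibble::as_tibble(conformation)$key)
  referenced <- unique(c(df$key_i, df$key_j))
  unknown <- setdiff(referenced, res_keys)
  if (length(unknown) > 0) {
    stop("pair record(s) reference residues absent from conformation '",
         conformation_label(conformation), "': ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }

  src <- attr(conformation, "source") %||% "structure.pdb"
  obj <- conformation_label(conformation)
  lines <- c(
    sprintf("load %s, %s", src, obj),
    "hide everything",
    sprintf("show cartoon, %s", obj),
    sprintf("color grey80, %s", obj)
  )
  info <- parse_keys(res_keys)
  sel_expr <- function(key) {
    ki <- info[info$key == key, ]
    sprintf("%s and chain %s and resi %d%s", obj, ki$chain, ki$resno,
            ki$icode)
  }
  for (r in seq_len(nrow(df))) {
    col <- if (df$dd[r] > 0) colors[["decreasing"]] else
      colors[["increasing"]]
    pair_id <- sprintf("pair%02d_%s_%s", r,
                       gsub("[^A-Za-z0-9]", "", df$key_i[r]),
                       gsub("[^A-Za-z0-9]", "", df$key_j[r]))
    lines <- c(
      lines,
      sprintf("select %s_i, %s", pair_id, sel_expr(df$key_i[r])),
      sprintf("select %s_j, %s", pair_id, sel_expr(df$key_j[r])),
      sprintf("show spheres, %s_i", pair_id),
      sprintf("show spheres, %s_j", pair_id),
      sprintf("color %s, %s_i", col, pair_id),
      sprintf("color %s, %s_j", col, pair_id)
    )
  }
  lines <- c(lines, "deselect", "zoom")
  writeLines(lines, path)
  invisible(path)
}
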