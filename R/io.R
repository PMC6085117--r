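.CLONE_COLS <- c("clone_id", "mouse_id", "color", "x_um", "y_um", "z_um",
                 "vol_acinar_um3", "vol_ductal_um3", "vol_islet_um3",
                 "n_branches", "induction", "collection")
.COLORS <- c("CFP", "GFP", "YFP", "RFP")

#' Read a clone table
#'
#' Clone tables are comma-separated UTF-8 text with a header row and the
#' exact columns `clone_id, mouse_id, color, x_um, y_um, z_um,
#' vol_acinar_um3, vol_ductal_um3, vol_islet_um3, n_branches, induction,
#' collection`.  One row describes one traced clone: its confetti colour,
#' 3D position (micrometres), per-compartment volumes (cubic
#' micrometres), and optional branch count.  Validation errors name the
#' offending row and column.
#'
#' @param path file path.
#' @return validated clone data frame.
#' @export
read_clone_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_clone_table(df)
}

#' Validate a clone table held in memory
#'
#' @param df data frame candidate.
#' @return the validated data frame (column order normalized).
#' @export
validate_clone_table <- function(df) {
  missing_cols <- setdiff(.CLONE_COLS, names(df))
  if (length(missing_cols))
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  df <- df[, .CLONE_COLS]
  bad_col <- which(!df$color %in% .COLORS)
  if (length(bad_col))
    stop("unknown color '", df$color[bad_col[1]], "' in row ", bad_col[1],
         ", column 'color' (expected CFP/GFP/YFP/RFP)")
  for (v in .VOL_COLS) {
    bad <- which(!is.finite(df[[v]]) | df[[v]] < 0)
    if (length(bad))
      stop("negative or non-finite volume in row ", bad[1], ", column '", v, "'")
  }
  for (v in c("x_um", "y_um", "z_um")) {
    bad <- which(!is.finite(df[[v]]))
    if (length(bad))
      stop("non-finite coordinate in row ", bad[1], ", column '", v, "'")
  }
  novol <- which(rowSums(as.matrix(df[, .VOL_COLS])) <= 0)
  if (length(novol))
    stop("clone with no positive compartment volume in row ", novol[1])
  df
}

#' Write a clone table
#'
#' @param clones clone data frame (validated before writing).
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_clone_table <- function(clones, path) {
  clones <- validate_clone_table(clones)
  utils::write.csv(clones, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a ductal network as JSON
#'
#' Node-link JSON document with fields `central_duct` (list of \[x, y\]),
#' `segments` (objects with `id`, `parent_id`, `subtree_id`,
#' `generation`, `polyline`, and optional `labels` when the network
#' carries drift pools), and `termini`.  The round trip through
#' [read_network()] is lossless at 15 significant digits.
#'
#' @param network a [ductal_network()].
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_network <- function(network, path) {
  stopifnot(inherits(network, "ductal_network"))
  doc <- list(
    central_duct = unname(network$central_duct),
    segments = lapply(network$segments, function(s) {
      out <- list(id = s$id,
                  parent_id = if (is.null(s$parent_id)) NULL else s$parent_id,
                  subtree_id = s$subtree_id,
                  generation = s$generation,
                  polyline = unname(s$polyline))
      if (!is.null(s$pool)) out$labels <- as.list(s$pool)
      out
    }),
    termini = network$termini)
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, null = "null",
                           dataframe = "columns")
  writeLines(json, path)
  invisible(path)
}

#' Read a ductal network from JSON
#'
#' Parses the schema written by [write_network()] and validates the
#' structural invariants (forest property, generations, polylines) on
#' read; a malformed document raises an error without returning a
#' partial object.
#'
#' @param path file path.
#' @return a [ductal_network()].
#' @export
read_network <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE,
                            simplifyMatrix = TRUE, simplifyVector = TRUE)
  cd <- doc$central_duct
  if (is.list(cd)) cd <- do.call(rbind, cd)
  segs_raw <- doc$segments
  segments <- if (is.data.frame(segs_raw)) {
    lapply(seq_len(nrow(segs_raw)), function(i) {
      s <- list(id = as.integer(segs_raw$id[i]),
                parent_id = if (is.na(segs_raw$parent_id[i])) NULL
                            else as.integer(segs_raw$parent_id[i]),
                subtree_id = as.integer(segs_raw$subtree_id[i]),
                generation = as.integer(segs_raw$generation[i]),
                polyline = segs_raw$polyline[[i]])
      if (!is.null(segs_raw$labels) && !is.null(segs_raw$labels[[i]]) &&
          !all(is.na(segs_raw$labels[[i]])))
        s$pool <- as.character(segs_raw$labels[[i]])
      s
    })
  } else {
    lapply(segs_raw, function(sr) {
      s <- list(id = as.integer(sr$id),
                parent_id = if (is.null(sr$parent_id)) NULL
                            else as.integer(sr$parent_id),
                subtree_id = as.integer(sr$subtree_id),
                generation = as.integer(sr$generation),
                polyline = if (is.matrix(sr$polyline)) sr$polyline
                           else do.call(rbind, sr$polyline))
      if (!is.null(sr$labels)) s$pool <- as.character(unlist(sr$labels))
      s
    })
  }
  tm <- as.data.frame(doc$termini)
  ductal_network(cd, segments, tm)
}
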