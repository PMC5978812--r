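#' Read and write tissue networks as JSON
#'
#' Networks serialize to a small JSON dialect:
#' `{box_length, vertices: [[x, y], ...], cells: [[[j, ox, oy], ...], ...],
#' periodic}` with 0-based vertex ids `j` and integer periodic image
#' offsets `(ox, oy)` per cell-vertex slot; coordinates are dimensionless
#' model units at full double precision. `box_length` is a scalar for a
#' square box or a pair for a rectangle. Reading a written file reproduces
#' the network exactly (vertex order preserved, coordinates round-tripped).
#'
#' @param network A [tissue_network()].
#' @param path File path.
#' @return `read_network` returns a [tissue_network()];
#'   `write_network` returns `path` invisibly.
#' @export
write_network <- function(network, path) {
  stopifnot(inherits(network, "tissue_network"))
  s <- network$slots
  cells <- lapply(seq_along(network$cells), function(a) {
    idx <- which(s$cell == a)
    cbind(s$vert[idx] - 1L, s$off[idx, 1], s$off[idx, 2])
  })
  box <- network$box
  obj <- list(
    box_length = if (isTRUE(all.equal(box[1], box[2]))) box[1] else box,
    vertices = unname(network$vertices),
    cells = cells,
    periodic = network$periodic
  )
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE,
                       always_decimal = TRUE)
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (field in c("box_length", "vertices", "cells", "periodic")) {
    if (is.null(obj[[field]])) {
      stop(sprintf("network JSON is missing required field '%s'", field),
           call. = FALSE)
    }
  }
  vertices <- matrix(as.numeric(as.matrix(obj$vertices)), ncol = 2)
  cells_raw <- obj$cells
  if (is.matrix(cells_raw)) cells_raw <- list(cells_raw)
  cells <- lapply(cells_raw, function(m) {
    m <- matrix(as.numeric(as.matrix(m)), ncol = 3)
    as.integer(m[, 1]) + 1L
  })
  tissue_network(vertices, cells, box = as.numeric(obj$box_length),
                 periodic = isTRUE(obj$periodic))
}

#' Import segmented cell polygons from a table
#'
#' Builds a finite-patch network from a per-vertex polygon table (the
#' quantification-mode input: manually segmented cell outlines). Vertices
#' of adjacent cells that coincide within `merge_tol` times the bounding
#' box diagonal are identified as shared junctions.
#'
#' @param x A data frame (or CSV path) with columns `cell_id`,
#'   `vertex_order`, `x`, `y`. Coordinates may be pixels or micrometres.
#' @param scale Multiplicative conversion from input units to
#'   dimensionless model units (e.g. `1/sqrt(mean cell area)`); default 1.
#' @param merge_tol Relative vertex-merge tolerance (default `1e-6`).
#' @return A finite-patch [tissue_network()].
#' @export
read_polygon_table <- function(x, scale = 1, merge_tol = 1e-6) {
  df <- if (is.character(x)) utils::read.csv(x) else as.data.frame(x)
  need <- c("cell_id", "vertex_order", "x", "y")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("polygon table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df <- df[order(df$cell_id, df$vertex_order), ]
  polys <- lapply(split(df, df$cell_id), function(d) {
    cbind(d$x, d$y) * scale
  })
  span <- sqrt(sum((apply(do.call(rbind, polys), 2, function(v) diff(range(v))))^2))
  merge_polygons_finite(polys, tol = merge_tol * span)
}

# Finite-patch analogue of the periodic merge: union-find over shifted
# quantization grids, no wrapping.
merge_polygons_finite <- function(polys, tol) {
  allv <- do.call(rbind, polys)
  n <- nrow(allv)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (sx in c(0, tol / 2)) {
    for (sy in c(0, tol / 2)) {
      key <- paste(floor((allv[, 1] + sx) / tol),
                   floor((allv[, 2] + sy) / tol))
      rep_idx <- match(key, key)
      for (i in which(rep_idx != seq_len(n))) {
        ri <- find(rep_idx[i]); rj <- find(i)
        if (ri != rj) parent[rj] <- ri
      }
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  ids <- unique(root)
  vid <- match(root, ids)
  counts <- vapply(polys, nrow, integer(1))
  stop_at <- cumsum(counts)
  start_at <- stop_at - counts + 1
  cells <- lapply(seq_along(polys), function(k) {
    cyc <- vid[start_at[k]:stop_at[k]]
    cyc <- cyc[c(TRUE, cyc[-1] != cyc[-length(cyc)])]
    if (length(cyc) > 1 && cyc[1] == cyc[length(cyc)]) cyc <- cyc[-length(cyc)]
    if (polygon_area(polys[[k]]) < 0) cyc <- rev(cyc)
    cyc
  })
  tissue_network(allv[ids, , drop = FALSE], cells, box = NULL,
                 periodic = FALSE)
}

#' Export the per-cell mechanics table to CSV
#'
#' Writes [cell_table()] output with the standard column set.
#'
#' @param network A [tissue_network()].
#' @param params A [model_params()] object.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cell_csv <- function(network, params, path) {
  tab <- cell_table(network, params)
  utils::write.csv(as.data.frame(tab), path, row.names = FALSE)
  invisible(path)
}

#' Serialize run provenance
#'
#' Writes the configuration of a simulation or fit (command, parameters,
#' settings, seed, package version) as JSON next to its outputs, so any
#' run can be reproduced from the provenance file alone.
#'
#' @param config Named list of run parameters.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  config$package_version <- as.character(utils::packageVersion("epivertex"))
  jsonlite::write_json(config, path, digits = NA, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}
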