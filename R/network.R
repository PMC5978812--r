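#' Polygonal cell network of an epithelial monolayer
#'
#' The central container of the package: a planar network of vertices joined
#' into anticlockwise polygonal cell cycles, either on a periodic rectangular
#' domain (a torus, the simulation setting) or as a finite patch (the
#' segmented-image setting). In periodic mode vertex coordinates are stored
#' canonically inside `[0, box)` and each cell is unwrapped into a contiguous
#' polygon by a minimum-image walk around its cycle, which is well defined as
#' long as every edge is shorter than half the box — the regime in which the
#' model operates (cells much smaller than the domain).
#'
#' @param vertices An `n_v` x 2 numeric matrix of vertex coordinates.
#' @param cells A list of integer vectors, each the anticlockwise cycle of
#'   vertex indices (1-based) of one cell. Clockwise cycles are reversed
#'   with a warning.
#' @param box Side of the periodic domain: a scalar (square box) or a
#'   length-2 vector `(Lx, Ly)`. Ignored (may be `NULL`) for finite
#'   patches.
#' @param periodic Logical; `TRUE` for a torus (every vertex must be a
#'   trijunction), `FALSE` for a finite patch with a free boundary.
#' @param meta Optional named list of provenance metadata carried with the
#'   network (parameters, seed, transition counts, ...).
#' @return An object of class `tissue_network`.
#' @seealso [validate_network()], [voronoi_network()], [hexagonal_lattice()]
#' @export
tissue_network <- function(vertices, cells, box = NULL, periodic = TRUE,
                           meta = list()) {
  v <- as.matrix(vertices)
  storage.mode(v) <- "double"
  if (ncol(v) != 2) stop("vertices must be an n x 2 matrix", call. = FALSE)
  cells <- lapply(cells, function(cv) as.integer(cv))
  if (any(lengths(cells) < 3)) {
    stop("every cell cycle must have at least 3 vertices", call. = FALSE)
  }
  if (any(unlist(cells) < 1L) || any(unlist(cells) > nrow(v))) {
    stop("cell cycles reference vertex ids outside 1..n_vertices", call. = FALSE)
  }
  if (periodic) {
    if (is.null(box)) stop("periodic networks need a box size", call. = FALSE)
    box <- as.numeric(box)
    if (length(box) == 1) box <- c(box, box)
    if (any(box <= 0)) stop("box lengths must be positive", call. = FALSE)
    v <- wrap_positions(v, box)
  } else {
    box <- if (is.null(box)) c(NA_real_, NA_real_) else {
      box <- as.numeric(box); if (length(box) == 1) c(box, box) else box
    }
  }
  net <- structure(
    list(vertices = v, cells = cells, box = box, periodic = periodic,
         slots = NULL, meta = meta),
    class = "tissue_network"
  )
  net$slots <- build_slots(net)
  # orientation normalization: reverse clockwise cells
  areas <- cell_areas_slots(net$vertices, net$slots, net$box)
  if (any(areas < 0)) {
    warning(sprintf("%d clockwise cell(s) reversed to anticlockwise orientation",
                    sum(areas < 0)), call. = FALSE)
    net$cells[areas < 0] <- lapply(net$cells[areas < 0], rev)
    net$slots <- build_slots(net)
  }
  net
}

#' @export
print.tissue_network <- function(x, ...) {
  cat(sprintf(
    "<tissue_network> %d cells, %d vertices, %s\n",
    length(x$cells), nrow(x$vertices),
    if (x$periodic) sprintf("periodic box %.4g x %.4g", x$box[1], x$box[2])
    else "finite patch"
  ))
  invisible(x)
}

wrap_positions <- function(v, box) {
  v[, 1] <- v[, 1] %% box[1]
  v[, 2] <- v[, 2] %% box[2]
  v
}

# Flattened cell-vertex incidence ("slots"): one slot per (cell, local
# vertex) pair, with precomputed next/previous slot within each cycle and
# integer periodic image offsets so that pos[vert] + off * box unwraps each
# cell into a contiguous polygon. This is the hot-path representation used
# by the energy/force kernels.
build_slots <- function(net) {
  z <- lengths(net$cells)
  ncell <- length(z)
  cell <- rep.int(seq_len(ncell), z)
  vert <- unlist(net$cells, use.names = FALSE)
  start <- cumsum(c(0L, z[-ncell]))
  local <- sequence(z)
  nxt <- start[cell] + (local %% z[cell]) + 1L
  prv <- start[cell] + ((local - 2L) %% z[cell]) + 1L
  slots <- list(cell = cell, vert = vert, nxt = nxt, prv = prv,
                z = z, ncell = ncell, start = start, local = local)
  slots$off <- if (net$periodic) {
    slot_offsets(net$vertices, slots, net$box)
  } else {
    matrix(0, length(vert), 2)
  }
  slots
}

# Minimum-image walk: offset of the first vertex of each cycle is (0,0);
# each subsequent offset keeps the connecting edge shorter than box/2.
slot_offsets <- function(pos, slots, box) {
  p <- pos[slots$vert, , drop = FALSE]
  d <- pos[slots$vert[slots$nxt], , drop = FALSE] - p
  jump <- cbind(-round(d[, 1] / box[1]), -round(d[, 2] / box[2]))
  # cumulative sum of jumps along each cycle, restarting at each cell start
  first <- slots$local == 1L
  shifted <- rbind(c(0, 0), jump[-nrow(jump), , drop = FALSE])
  shifted[first, ] <- 0
  cum <- apply(shifted, 2, cumsum)
  base <- cum[first, , drop = FALSE][slots$cell, , drop = FALSE]
  cum - base
}

# Unwrapped slot coordinates (one row per slot).
slot_coords <- function(pos, slots, box) {
  x <- pos[slots$vert, , drop = FALSE]
  if (!is.null(box) && is.finite(box[1])) {
    x[, 1] <- x[, 1] + slots$off[, 1] * box[1]
    x[, 2] <- x[, 2] + slots$off[, 2] * box[2]
  }
  x
}

cell_areas_slots <- function(pos, slots, box) {
  x <- slot_coords(pos, slots, box)
  cross <- x[, 1] * x[slots$nxt, 2] - x[slots$nxt, 1] * x[, 2]
  as.numeric(rowsum(cross, slots$cell, reorder = TRUE)) / 2
}

#' Unwrapped polygon of one cell
#'
#' @param network A [tissue_network()].
#' @param cell Cell index.
#' @return A Z x 2 matrix of unwrapped (contiguous) vertex coordinates in
#'   anticlockwise order.
#' @export
cell_polygon <- function(network, cell) {
  stopifnot(inherits(network, "tissue_network"))
  s <- network$slots
  idx <- which(s$cell == cell)
  slot_coords(network$vertices, s, network$box)[idx, , drop = FALSE]
}

#' Cell-vertex incidence map
#'
#' Lists, for every global vertex, the cells it belongs to together with its
#' local index within each cell's cycle — the explicit form of the
#' cell-vertex incidence used to assemble net vertex forces. In the interior
#' of a periodic monolayer every vertex is a trijunction and so appears in
#' exactly three cycles.
#'
#' @param network A [tissue_network()].
#' @return A tibble with columns `vertex`, `cell`, `local_index` (1-based
#'   position within the cell's anticlockwise cycle) and `n_incident` (the
#'   number of cells meeting at that vertex).
#' @export
build_incidence <- function(network) {
  stopifnot(inherits(network, "tissue_network"))
  s <- network$slots
  n_inc <- tabulate(s$vert, nbins = nrow(network$vertices))
  tibble::tibble(
    vertex = s$vert,
    cell = s$cell,
    local_index = s$local,
    n_incident = n_inc[s$vert]
  ) |>
    dplyr::arrange(.data$vertex, .data$cell)
}

peripheral_vertex_ids <- function(network) {
  if (network$periodic) return(integer(0))
  n_inc <- tabulate(network$slots$vert, nbins = nrow(network$vertices))
  which(n_inc < 3L)
}

#' Per-cell geometry table
#'
#' Vectorized geometric summary of every cell: polygonal class, area,
#' perimeter, centroid, circularity and shape major-axis angle.
#'
#' @param network A [tissue_network()].
#' @return A tibble with one row per cell.
#' @export
network_geometry <- function(network) {
  stopifnot(inherits(network, "tissue_network"))
  s <- network$slots
  x <- slot_coords(network$vertices, s, network$box)
  cross <- x[, 1] * x[s$nxt, 2] - x[s$nxt, 1] * x[, 2]
  area <- as.numeric(rowsum(cross, s$cell)) / 2
  tvec <- x[s$nxt, , drop = FALSE] - x
  l <- sqrt(rowSums(tvec^2))
  per <- as.numeric(rowsum(l, s$cell))
  cx <- as.numeric(rowsum(x[, 1], s$cell)) / s$z
  cy <- as.numeric(rowsum(x[, 2], s$cell)) / s$z
  rx <- x[, 1] - cx[s$cell]
  ry <- x[, 2] - cy[s$cell]
  sxx <- as.numeric(rowsum(rx * rx, s$cell)) / s$z
  sxy <- as.numeric(rowsum(rx * ry, s$cell)) / s$z
  syy <- as.numeric(rowsum(ry * ry, s$cell)) / s$z
  half_tr <- (sxx + syy) / 2
  disc <- sqrt(((sxx - syy) / 2)^2 + sxy^2)
  lam1 <- half_tr + disc
  lam2 <- half_tr - disc
  tibble::tibble(
    cell = seq_len(s$ncell),
    z = s$z,
    area = area,
    perimeter = per,
    centroid_x = cx,
    centroid_y = cy,
    circularity = ifelse(lam1 > 0, pmax(lam2, 0) / lam1, 0),
    shape_angle = (0.5 * atan2(2 * sxy, sxx - syy)) %% pi,
    shape_lam1 = lam1,
    shape_lam2 = lam2
  )
}

#' Structural diagnostics of a tissue network
#'
#' Checks the invariants the rest of the package relies on: cycles of length
#' >= 3, anticlockwise orientation, polygon simplicity, the trijunction
#' property (periodic mode), closure of the minimum-image walk around every
#' cycle, unwrapped cell diameter below half the box, and canonical
#' coordinates inside the box. Concave cells are reported but are not a
#' failure — transient mild concavity occurs during relaxation.
#'
#' @param network A [tissue_network()].
#' @return An object of class `network_validation`: list with `ok` (logical,
#'   TRUE when no fatal violation was found), `violations` (tibble with
#'   columns `type`, `where`, `detail`) and `n_concave`.
#' @export
validate_network <- function(network) {
  stopifnot(inherits(network, "tissue_network"))
  s <- network$slots
  viol <- list()
  add <- function(type, where, detail) {
    viol[[length(viol) + 1]] <<- tibble::tibble(
      type = type, where = as.integer(where), detail = detail)
  }
  x <- slot_coords(network$vertices, s, network$box)

  # orientation
  cross <- x[, 1] * x[s$nxt, 2] - x[s$nxt, 1] * x[, 2]
  areas <- as.numeric(rowsum(cross, s$cell)) / 2
  for (a in which(areas <= 0)) {
    add("orientation", a, sprintf("signed area %.3g <= 0", areas[a]))
  }

  # trijunction property (periodic interior)
  n_inc <- tabulate(s$vert, nbins = nrow(network$vertices))
  if (network$periodic) {
    for (j in which(n_inc != 3L)) {
      add("trijunction", j, sprintf("vertex in %d cells (expected 3)", n_inc[j]))
    }
  }

  # periodic closure: the offset walk must return to its start, i.e. the
  # offset difference across the closing edge equals the accumulated jumps
  if (network$periodic) {
    p <- network$vertices[s$vert, , drop = FALSE]
    d <- network$vertices[s$vert[s$nxt], , drop = FALSE] - p
    jump <- cbind(-round(d[, 1] / network$box[1]),
                  -round(d[, 2] / network$box[2]))
    pred_next_off <- s$off + jump
    mismatch <- pred_next_off != s$off[s$nxt, , drop = FALSE]
    bad_cells <- unique(s$cell[rowSums(mismatch) > 0])
    for (a in bad_cells) add("periodic_closure", a, "offset walk does not close")
    # coordinates canonical
    out <- which(network$vertices[, 1] < 0 | network$vertices[, 1] >= network$box[1] |
                 network$vertices[, 2] < 0 | network$vertices[, 2] >= network$box[2])
    for (j in out) add("coordinates", j, "vertex outside [0, box)")
    # minimum-image consistency: unwrapped diameter < box/2
    cx <- as.numeric(rowsum(x[, 1], s$cell)) / s$z
    cy <- as.numeric(rowsum(x[, 2], s$cell)) / s$z
    r2 <- (x[, 1] - cx[s$cell])^2 + (x[, 2] - cy[s$cell])^2
    maxr <- tapply(sqrt(r2), s$cell, max)
    big <- which(2 * maxr >= min(network$box) / 2)
    for (a in big) add("min_image", a, "unwrapped cell diameter >= box/2")
  }

  # simplicity + concavity per cell
  n_concave <- 0L
  for (a in seq_len(s$ncell)) {
    idx <- which(s$cell == a)
    poly <- x[idx, , drop = FALSE]
    if (!is_simple_polygon(poly)) add("simplicity", a, "self-intersecting polygon")
    if (is_concave_polygon(poly)) n_concave <- n_concave + 1L
  }

  violations <- if (length(viol)) dplyr::bind_rows(viol) else {
    tibble::tibble(type = character(), where = integer(), detail = character())
  }
  structure(
    list(ok = nrow(violations) == 0L, violations = violations,
         n_concave = n_concave),
    class = "network_validation"
  )
}

#' @export
print.network_validation <- function(x, ...) {
  if (x$ok) {
    cat(sprintf("<network_validation> PASS (%d concave cells reported)\n",
                x$n_concave))
  } else {
    cat(sprintf("<network_validation> FAIL: %d violation(s)\n",
                nrow(x$violations)))
    print(x$violations, n = 20)
  }
  invisible(x)
}

is_concave_polygon <- function(poly) {
  n <- nrow(poly)
  nxt <- c(2:n, 1)
  t <- poly[nxt, , drop = FALSE] - poly
  cr <- t[, 1] * t[nxt, 2] - t[nxt, 1] * t[, 2]
  any(cr < -1e-12 * max(abs(cr)))
}

# O(Z^2) segment-pair test; Z is small so this is fine for diagnostics.
is_simple_polygon <- function(poly) {
  n <- nrow(poly)
  if (n == 3) return(TRUE)
  nxt <- c(2:n, 1)
  for (i in seq_len(n - 2)) {
    jmax <- if (i == 1) n - 1 else n
    for (j in (i + 2):jmax) {
      if (segments_intersect(poly[i, ], poly[nxt[i], ], poly[j, ], poly[nxt[j], ])) {
        return(FALSE)
      }
    }
  }
  TRUE
}

segments_intersect <- function(p1, p2, p3, p4) {
  d1 <- cross2(p4 - p3, p1 - p3)
  d2 <- cross2(p4 - p3, p2 - p3)
  d3 <- cross2(p2 - p1, p3 - p1)
  d4 <- cross2(p2 - p1, p4 - p1)
  (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
     ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0)))
}

cross2 <- function(a, b) a[1] * b[2] - a[2] * b[1]

# Unique undirected edges of the network. Returns a tibble with the two
# vertex ids, the two incident cells (second NA on a finite boundary) and
# the (minimum-image) length.
network_edges <- function(network) {
  s <- network$slots
  x <- slot_coords(network$vertices, s, network$box)
  tvec <- x[s$nxt, , drop = FALSE] - x
  len <- sqrt(rowSums(tvec^2))
  v1 <- s$vert
  v2 <- s$vert[s$nxt]
  key <- paste(pmin(v1, v2), pmax(v1, v2))
  first <- !duplicated(key)
  twin <- match(key, key)           # index of first slot with the same key
  other_cell <- rep(NA_integer_, length(v1))
  # for the representative slot, find the twin slot (the duplicate occurrence)
  dup_idx <- which(!first)
  other_cell[twin[dup_idx]] <- s$cell[dup_idx]
  tibble::tibble(
    slot = which(first),
    v1 = v1[first], v2 = v2[first],
    cell1 = s$cell[first], cell2 = other_cell[first],
    length = len[first]
  )
}
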