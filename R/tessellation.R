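#' Matern type II hard-core seed points
#'
#' Samples cell-centre seed points on a periodic rectangle by Matern type II
#' dependent thinning: a Poisson proposal is drawn, every point receives an
#' independent uniform mark, and a point is deleted when any proposal point
#' within the hard-core radius (periodic metric) carries a smaller mark. The
#' proposal intensity is doubled until at least `n_target` points survive,
#' then survivors are subsampled to exactly `n_target`. The result is a
#' spatially homogeneous point set with a guaranteed minimum separation —
#' the initial condition that keeps the Voronoi tessellation free of sliver
#' cells.
#'
#' @param box_length Side of the periodic box (scalar, or length 2 for a
#'   rectangle).
#' @param n_target Number of points to return.
#' @param hardcore_radius Minimum periodic separation. Default
#'   `0.6 * sqrt(box_area / (pi * n_target))`, about 60% of the mean
#'   nearest-neighbour spacing: strong enough inhibition to suppress small
#'   Voronoi cells while remaining easily feasible.
#' @param seed Integer RNG seed; the output is fully reproducible.
#' @return An object of class `seed_points`: list with `points`
#'   (`n_target` x 2 matrix in `[0, box)`), `hardcore_radius`, `box`, and
#'   `seed`.
#' @export
matern_ii_points <- function(box_length, n_target, hardcore_radius = NULL,
                             seed = 1L) {
  box <- as.numeric(box_length)
  if (length(box) == 1) box <- c(box, box)
  stopifnot(all(box > 0), n_target >= 3)
  area <- prod(box)
  r <- hardcore_radius %||% (0.6 * sqrt(area / (pi * n_target)))
  if (n_target * pi * r^2 > 0.5 * area) {
    stop("infeasible packing: n_target * pi * r^2 exceeds half the box area",
         call. = FALSE)
  }
  old <- set_local_seed(seed)
  on.exit(restore_seed(old), add = TRUE)
  intensity <- 2 * n_target / area
  for (attempt in 1:25) {
    n_prop <- stats::rpois(1, intensity * area)
    if (n_prop >= n_target) {
      pts <- cbind(stats::runif(n_prop, 0, box[1]), stats::runif(n_prop, 0, box[2]))
      marks <- stats::runif(n_prop)
      keep <- matern_ii_keep(pts, marks, r, box)
      if (sum(keep) >= n_target) {
        surv <- which(keep)
        sel <- sort(sample(surv, n_target))
        return(structure(
          list(points = pts[sel, , drop = FALSE], hardcore_radius = r,
               box = box, seed = seed),
          class = "seed_points"
        ))
      }
    }
    intensity <- intensity * 2
  }
  stop("Matern II sampling failed to reach n_target survivors", call. = FALSE)
}

# Type II thinning: point i survives iff no proposal point within r has a
# smaller mark.
matern_ii_keep <- function(pts, marks, r, box) {
  n <- nrow(pts)
  dx <- abs(outer(pts[, 1], pts[, 1], "-"))
  dx <- pmin(dx, box[1] - dx)
  dy <- abs(outer(pts[, 2], pts[, 2], "-"))
  dy <- pmin(dy, box[2] - dy)
  close <- (dx^2 + dy^2) < r^2
  diag(close) <- FALSE
  smaller <- outer(marks, marks, ">")   # [i, j]: mark_j < mark_i
  !apply(close & smaller, 1, any)
}

#' Periodic Voronoi tessellation as a tissue network
#'
#' Builds the Voronoi diagram of a point set on the periodic rectangle by
#' tessellating a 3 x 3 tiling of the points (via the planar Dirichlet
#' tessellation of \pkg{deldir}), extracting the tiles of the central copy,
#' and re-identifying shared tile vertices across the periodic boundary.
#' For points in general position every Voronoi vertex is a trijunction;
#' cocircular degeneracies are resolved by perturbing the points by
#' `1e-9 * box` and retrying (logged via `message()`).
#'
#' @param points A [matern_ii_points()] result, or an n x 2 matrix of points
#'   in `[0, box)`.
#' @param box_length Periodic box side(s); taken from the `seed_points`
#'   object when omitted.
#' @return A periodic [tissue_network()] with one cell per point; cell `k`
#'   contains point `k`. Cell areas partition the box.
#' @export
voronoi_network <- function(points, box_length = NULL) {
  if (inherits(points, "seed_points")) {
    box <- points$box
    pts <- points$points
  } else {
    box <- as.numeric(box_length)
    if (length(box) == 1) box <- c(box, box)
    pts <- as.matrix(points)
  }
  if (nrow(pts) < 3) stop("need at least 3 points", call. = FALSE)
  for (attempt in 0:5) {
    p <- pts
    if (attempt > 0) {
      # start at the nominal 1e-9 * box jitter; escalate by 100x per retry so
      # that split degenerate vertices eventually clear the merge tolerance
      amp <- 1e-9 * 100^(attempt - 1)
      message("voronoi_network: degenerate vertex detected; ",
              "perturbing points by ", format(amp),
              " * box and retrying (attempt ", attempt, ")")
      set.seed(1000L + attempt)
      p <- p + matrix(stats::runif(length(p), -1, 1), ncol = 2) *
        rep(amp * box, each = nrow(p))
      p[, 1] <- p[, 1] %% box[1]
      p[, 2] <- p[, 2] %% box[2]
    }
    net <- try(voronoi_network_once(p, box), silent = TRUE)
    if (!inherits(net, "try-error")) return(net)
  }
  stop("voronoi_network: could not resolve degeneracies: ",
       attr(net, "condition")$message, call. = FALSE)
}

voronoi_network_once <- function(pts, box) {
  n <- nrow(pts)
  shifts <- as.matrix(expand.grid(ox = -1:1, oy = -1:1))
  shifts <- shifts[order(shifts[, 1] != 0 | shifts[, 2] != 0), , drop = FALSE]
  tiled <- do.call(rbind, lapply(seq_len(nrow(shifts)), function(k) {
    cbind(pts[, 1] + shifts[k, 1] * box[1], pts[, 2] + shifts[k, 2] * box[2])
  }))
  dd <- deldir::deldir(tiled[, 1], tiled[, 2],
                       rw = c(-box[1], 2 * box[1], -box[2], 2 * box[2]),
                       suppressMsge = TRUE)
  tiles <- deldir::tile.list(dd)
  if (length(tiles) != 9 * n) {
    stop("tessellation dropped duplicated points", call. = FALSE)
  }
  polys <- lapply(tiles[seq_len(n)], function(tl) cbind(tl$x, tl$y))
  net <- merge_polygons_to_network(polys, box, tol = 4e-6 * max(box))
  val <- validate_network(net)
  fatal <- val$violations[val$violations$type %in%
                            c("trijunction", "orientation", "periodic_closure"), ]
  if (nrow(fatal) > 0) {
    stop("degenerate tessellation: ", fatal$type[1], call. = FALSE)
  }
  net
}

# Identify shared vertices of a set of unwrapped polygons on the periodic
# rectangle and assemble a tissue_network. Vertices within `tol/2` of each
# other (periodic metric) are identified via union-find over four shifted
# quantization grids of cell size `tol` — any pair closer than tol/2 is
# guaranteed to share a bin in at least one grid, so the match is robust to
# bin-boundary effects.
merge_polygons_to_network <- function(polys, box, tol) {
  allv <- do.call(rbind, polys)
  w <- cbind(allv[, 1] %% box[1], allv[, 2] %% box[2])
  # coordinates within tol of the upper box edge snap below zero so that
  # periodic twins land in neighbouring bins
  w[, 1] <- ((w[, 1] + tol) %% box[1]) - tol
  w[, 2] <- ((w[, 2] + tol) %% box[2]) - tol
  n <- nrow(w)
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
      key <- paste(floor((w[, 1] + sx) / tol), floor((w[, 2] + sy) / tol))
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
  vertices <- w[ids, , drop = FALSE]
  vertices[, 1] <- vertices[, 1] %% box[1]
  vertices[, 2] <- vertices[, 2] %% box[2]
  counts <- vapply(polys, nrow, integer(1))
  stop_at <- cumsum(counts)
  start_at <- stop_at - counts + 1
  cells <- lapply(seq_along(polys), function(k) {
    cyc <- vid[start_at[k]:stop_at[k]]
    cyc <- cyc[c(TRUE, cyc[-1] != cyc[-length(cyc)])]  # drop consecutive dups
    if (length(cyc) > 1 && cyc[1] == cyc[length(cyc)]) cyc <- cyc[-length(cyc)]
    if (polygon_area(polys[[k]]) < 0) cyc <- rev(cyc)
    cyc
  })
  tissue_network(vertices, cells, box = box, periodic = TRUE)
}

#' Periodic lattice of identical regular hexagons
#'
#' A honeycomb of `n_x` x `n_y` regular hexagons of area `a_cell` on a
#' periodic rectangle (`n_y` must be even for the tiling to close). Every
#' cell satisfies \eqn{L/\sqrt{A} = \mu_6} and every vertex is a
#' trijunction — the reference configuration for the closed-form elastic
#' moduli.
#'
#' @param a_cell Area of each hexagon.
#' @param n_x,n_y Number of hexagons per row / number of rows (`n_y` even).
#' @return A periodic [tissue_network()] with `n_x * n_y` cells on a
#'   rectangle of size `n_x * sqrt(3) s` by `n_y * 1.5 s`, where `s` is the
#'   hexagon side.
#' @export
hexagonal_lattice <- function(a_cell = 1, n_x = 4, n_y = 4) {
  stopifnot(a_cell > 0, n_x >= 1, n_y >= 2)
  if (n_y %% 2 != 0) {
    stop("n_y must be even for the periodic honeycomb to close", call. = FALSE)
  }
  s <- sqrt(2 * a_cell / (3 * sqrt(3)))
  w <- sqrt(3) * s
  box <- c(n_x * w, n_y * 1.5 * s)
  theta <- pi / 2 + (0:5) * pi / 3   # pointy-top hexagon, anticlockwise
  hex <- cbind(s * cos(theta), s * sin(theta))
  polys <- list()
  for (j in 0:(n_y - 1)) {
    for (i in 0:(n_x - 1)) {
      cx <- (i + 0.5 * (j %% 2)) * w
      cy <- j * 1.5 * s + s
      polys[[length(polys) + 1]] <- cbind(hex[, 1] + cx, hex[, 2] + cy)
    }
  }
  merge_polygons_to_network(polys, box, tol = 1e-6 * s)
}

#' Vertices of a regular polygon
#'
#' Anticlockwise regular N-gon of prescribed area, centred at the origin
#' with one vertex on the positive x-axis.
#'
#' @param n Number of sides (>= 3).
#' @param area Polygon area.
#' @return An n x 2 matrix of vertex coordinates.
#' @export
regular_ngon <- function(n, area = 1) {
  stopifnot(n >= 3, area > 0)
  r <- sqrt(2 * area / (n * sin(2 * pi / n)))
  th <- 2 * pi * (0:(n - 1)) / n
  cbind(r * cos(th), r * sin(th))
}

#' Noisy hexagonal lattice fixture
#'
#' A periodic honeycomb whose vertices receive independent uniform
#' displacements — a controlled-disorder, off-equilibrium configuration for
#' gradient and stress property checks. Displacements large enough to break
#' polygon simplicity are resampled (bounded retries).
#'
#' @inheritParams hexagonal_lattice
#' @param noise_amplitude Half-width of the uniform displacement per
#'   coordinate, in units of the hexagon side.
#' @param seed Integer RNG seed.
#' @return A periodic [tissue_network()].
#' @export
perturbed_lattice <- function(a_cell = 1, n_x = 4, n_y = 4,
                              noise_amplitude = 0.1, seed = 1L) {
  net <- hexagonal_lattice(a_cell, n_x, n_y)
  if (noise_amplitude == 0) return(net)
  s <- sqrt(2 * a_cell / (3 * sqrt(3)))
  old <- set_local_seed(seed)
  on.exit(restore_seed(old), add = TRUE)
  for (attempt in 1:20) {
    d <- matrix(stats::runif(2 * nrow(net$vertices), -1, 1), ncol = 2) *
      noise_amplitude * s
    cand <- net
    cand$vertices <- wrap_positions(net$vertices + d, net$box)
    cand$slots <- build_slots(cand)
    val <- validate_network(cand)
    if (all(!val$violations$type %in% c("simplicity", "orientation"))) {
      return(cand)
    }
  }
  stop("could not generate a simple perturbed lattice at this noise amplitude",
       call. = FALSE)
}

# Seed handling: run a block under a given seed without clobbering the
# caller's RNG state.
set_local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(as.integer(seed))
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
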