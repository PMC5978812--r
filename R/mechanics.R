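# Vectorized energy/force kernel. One evaluation computes, from vertex
# positions and the fixed slot topology: cell areas A, perimeters L, the
# scalar energy U = sum 1/2 (A-1)^2 + 1/2 Gamma (L-L0)^2, and minus its
# gradient — the net force on every vertex,
#   f^i = -P p^i + T q^i,   p^i = 1/2 (R^{i+1}-R^{i-1}) x z,
#                           q^i = that^i - that^{i-1},
# accumulated over the cells incident on each vertex.
mech_core <- function(pos, slots, box, gam, l0, forces = TRUE) {
  x <- slot_coords(pos, slots, box)
  xn <- x[slots$nxt, , drop = FALSE]
  cross <- x[, 1] * xn[, 2] - xn[, 1] * x[, 2]
  area <- as.numeric(rowsum(cross, slots$cell)) / 2
  tx <- xn[, 1] - x[, 1]
  ty <- xn[, 2] - x[, 2]
  l <- sqrt(tx^2 + ty^2)
  per <- as.numeric(rowsum(l, slots$cell))
  p_cell <- area - 1
  t_cell <- gam * (per - l0)
  u <- sum(0.5 * p_cell^2 + 0.5 * gam * (per - l0)^2)
  out <- list(energy = u, area = area, perimeter = per,
              pressure = p_cell, tension = t_cell)
  if (forces) {
    if (any(l == 0)) {
      stop("zero-length edge: unit tangent undefined", call. = FALSE)
    }
    hx <- tx / l
    hy <- ty / l
    dpx <- x[slots$nxt, 1] - x[slots$prv, 1]
    dpy <- x[slots$nxt, 2] - x[slots$prv, 2]
    pc <- p_cell[slots$cell]
    tc <- t_cell[slots$cell]
    # p^i = 1/2 (dpx, dpy) x z = 1/2 (dpy, -dpx); q^i = that^i - that^{i-1}
    fx <- -pc * (0.5 * dpy) + tc * (hx - hx[slots$prv])
    fy <- -pc * (-0.5 * dpx) + tc * (hy - hy[slots$prv])
    nv <- nrow(pos)
    out$force <- cbind(
      as.numeric(rowsum(fx, slots$vert, reorder = TRUE)),
      as.numeric(rowsum(fy, slots$vert, reorder = TRUE))
    )
    out$slot_force <- cbind(fx, fy)
  }
  out
}

#' Cell pressure and cortical tension
#'
#' The two scalar state variables of one cell under the vertex model:
#' bulk pressure \eqn{P = A - 1} (deviation from the preferred area) and
#' cortical tension \eqn{T = \Gamma (L - L_0)} (perimeter spring force).
#'
#' @param cell A [cell_shape()] object, a vertex matrix, or a list with
#'   `area` and `perimeter`.
#' @param params A [model_params()] object.
#' @return Named numeric vector `c(P = , T = )`.
#' @export
pressure_tension <- function(cell, params) {
  params <- as_model_params(params)
  g <- as_cell_geometry(cell)
  c(P = g$area - 1, T = params$gam * (g$perimeter - params$l0))
}

as_cell_geometry <- function(cell) {
  if (inherits(cell, "cell_geometry")) return(cell)
  if (is.matrix(cell) || is.data.frame(cell)) return(cell_shape(cell))
  if (is.list(cell) && all(c("area", "perimeter") %in% names(cell))) return(cell)
  stop("`cell` must be a cell_geometry, a vertex matrix, or a list with ",
       "area and perimeter", call. = FALSE)
}

#' Restoring forces of a single cell on its vertices
#'
#' The force \eqn{f^i = -P p^i + T q^i} exerted by one cell at each of its
#' vertices, equal to minus the gradient of that cell's energy with respect
#' to the vertex position. The forces of a closed cycle always sum to zero.
#'
#' @param vertices Z x 2 matrix of the cell's vertices (anticlockwise).
#' @param params A [model_params()] object.
#' @return A Z x 2 matrix of force vectors.
#' @export
cell_vertex_forces <- function(vertices, params) {
  params <- as_model_params(params)
  v <- as_vertex_matrix(vertices)
  slots <- list(cell = rep(1L, nrow(v)), vert = seq_len(nrow(v)),
                nxt = c(2:nrow(v), 1L), prv = c(nrow(v), 1:(nrow(v) - 1)),
                z = nrow(v), ncell = 1L, local = seq_len(nrow(v)),
                off = matrix(0, nrow(v), 2))
  mech_core(v, slots, NULL, params$gam, params$l0)$force
}

#' Net force on every vertex of a network
#'
#' Sums the per-cell vertex forces over the cells incident on each vertex
#' via the cell-vertex incidence. At equilibrium the net force on every
#' vertex vanishes. On a finite patch, peripheral vertices additionally
#' receive the imposed isotropic boundary pressure `params$p_ext` acting on
#' the two boundary edges that meet there (the exterior is treated as a
#' tensionless region at pressure `P_ext`).
#'
#' @param network A [tissue_network()].
#' @param params A [model_params()] object.
#' @return An `n_v` x 2 matrix of net force vectors.
#' @export
net_vertex_forces <- function(network, params) {
  stopifnot(inherits(network, "tissue_network"))
  params <- as_model_params(params)
  f <- mech_core(network$vertices, network$slots, network$box,
                 params$gam, params$l0)$force
  if (!network$periodic && params$p_ext != 0) {
    b <- boundary_cycles(network)
    for (cyc in b) {
      nb <- c(cyc[-1], cyc[1])
      pb <- c(cyc[length(cyc)], cyc[-length(cyc)])
      d <- network$vertices[nb, , drop = FALSE] -
        network$vertices[pb, , drop = FALSE]
      # the exterior acts as a tensionless cell at pressure P_ext: positive
      # P_ext pulls the boundary outward (net tension on the patch)
      f[cyc, 1] <- f[cyc, 1] + 0.5 * params$p_ext * d[, 2]
      f[cyc, 2] <- f[cyc, 2] - 0.5 * params$p_ext * d[, 1]
    }
  }
  f
}

# Boundary cycles of a finite patch, each traversed anticlockwise (tissue on
# the left). Boundary edges are the directed cell edges without a twin.
boundary_cycles <- function(network) {
  s <- network$slots
  key <- paste(pmin(s$vert, s$vert[s$nxt]), pmax(s$vert, s$vert[s$nxt]))
  shared <- key %in% key[duplicated(key)]
  from <- s$vert[!shared]
  to <- s$vert[s$nxt][!shared]
  nxt_map <- stats::setNames(to, from)
  cycles <- list()
  remaining <- stats::setNames(rep(TRUE, length(from)), from)
  while (any(remaining)) {
    start <- as.integer(names(remaining)[remaining][1])
    cyc <- start
    remaining[as.character(start)] <- FALSE
    v <- nxt_map[[as.character(start)]]
    while (v != start) {
      cyc <- c(cyc, v)
      remaining[as.character(v)] <- FALSE
      v <- nxt_map[[as.character(v)]]
    }
    cycles[[length(cycles) + 1]] <- cyc
  }
  cycles
}

#' Total mechanical energy of a network
#'
#' \deqn{U = \sum_\alpha \left[ \tfrac12 (A_\alpha - 1)^2 +
#'   \tfrac12 \Gamma (L_\alpha - L_0)^2 \right],}
#' the quadratic area-elasticity plus perimeter-spring energy summed over
#' cells. The additive constant \eqn{\Lambda^2/4\Gamma^2} per cell is
#' dropped; it does not affect forces.
#'
#' @inheritParams net_vertex_forces
#' @return Scalar energy.
#' @export
total_energy <- function(network, params) {
  stopifnot(inherits(network, "tissue_network"))
  params <- as_model_params(params)
  mech_core(network$vertices, network$slots, network$box,
            params$gam, params$l0, forces = FALSE)$energy
}

#' Stress tensor of a single cell
#'
#' The uniform Cauchy stress attributed to one cell,
#' \deqn{\sigma = -P^{eff} I + T J - \tfrac12 \dot S,}
#' with effective pressure \eqn{P^{eff} = P + T L / 2A} (bulk pressure plus
#' a Young-Laplace cortical term), traceless deviator
#' \deqn{J = \frac{1}{A}\left( \tfrac{L}{2} I -
#'   \sum_i l^i\, \hat t^i \otimes \hat t^i \right),}
#' and a dissipative rate-of-shape term \eqn{-\tfrac12\dot S} that is
#' included only when vertex velocities are supplied (it vanishes at
#' equilibrium). At equilibrium \eqn{\mathrm{Tr}\,\sigma = -2 P^{eff}}.
#'
#' @param cell A [cell_shape()] object or vertex matrix.
#' @param params A [model_params()] object.
#' @param velocities Optional Z x 2 matrix of vertex velocities (dynamic
#'   mode); default `NULL` treats the cell as at steady state.
#' @return An object of class `cell_mechanics`: list with `pressure`,
#'   `tension`, `p_eff`, `sigma` (2 x 2), `deviator` (J, 2 x 2),
#'   `eigenvalues` (ordered by decreasing magnitude), `principal_axis`
#'   (unit eigenvector of the larger-magnitude eigenvalue),
#'   `principal_angle`, and `stress_class` (see [classify_cell_stress()]).
#' @examples
#' m <- cell_stress(regular_ngon(6, 1), model_params(-0.1, 0.1))
#' m$p_eff # 0.59976; regular polygons have J = 0
#' @export
cell_stress <- function(cell, params, velocities = NULL) {
  params <- as_model_params(params)
  g <- if (inherits(cell, "cell_geometry")) cell else cell_shape(cell)
  if (g$area <= 0) stop("cell area must be positive", call. = FALSE)
  pt <- pressure_tension(g, params)
  p_eff <- pt[["P"]] + pt[["T"]] * g$perimeter / (2 * g$area)
  j <- cell_deviator(g)
  sig <- -p_eff * diag(2) + pt[["T"]] * j
  if (!is.null(velocities)) {
    vel <- as.matrix(velocities)
    stopifnot(nrow(vel) == g$z)
    rv <- sweep(vel, 2, colMeans(vel))
    # centred vertex vectors of the polygon
    r <- g$centred
    sdot <- (crossprod(r, rv) + crossprod(rv, r)) / g$z
    sig <- sig - 0.5 * sdot
  }
  eig <- stress_eigen(sig)
  out <- structure(
    list(
      pressure = pt[["P"]], tension = pt[["T"]], p_eff = p_eff,
      sigma = sig, deviator = j,
      eigenvalues = eig$values,
      principal_axis = eig$vector1,
      principal_angle = eig$angle
    ),
    class = "cell_mechanics"
  )
  out$stress_class <- classify_cell_stress(out)
  out
}

#' @export
print.cell_mechanics <- function(x, ...) {
  cat(sprintf(
    "<cell_mechanics> P = %.4g, T = %.4g, P_eff = %.4g, class %s\n",
    x$pressure, x$tension, x$p_eff, x$stress_class
  ))
  invisible(x)
}

# J = (1/A) (L/2 I - sum_i l^i that^i x that^i); traceless by construction.
cell_deviator <- function(g) {
  r <- g$centred
  if (is.null(r)) stop("internal: cell geometry lacks centred vertices")
  n <- nrow(r)
  nxt <- c(2:n, 1)
  t <- r[nxt, , drop = FALSE] - r
  l <- sqrt(rowSums(t^2))
  h <- t / l
  dy <- crossprod(h, h * l)     # sum_i l^i that x that
  (diag(2) * g$perimeter / 2 - dy) / g$area
}

# Eigen-decomposition of a symmetric 2x2 stress with magnitude ordering
# (|sigma_1| >= |sigma_2|); returns the eigenvector of the larger-magnitude
# eigenvalue.
stress_eigen <- function(sig) {
  e <- eigen2x2(sig)
  if (abs(e$values[2]) > abs(e$values[1])) {
    ang <- (e$angle + pi / 2) %% pi
    list(values = e$values[2:1], vector1 = c(cos(ang), sin(ang)), angle = ang)
  } else {
    e
  }
}

#' Classify a cell's stress configuration
#'
#' Four qualitative stress states, distinguished by the sign of the
#' effective pressure (net tension when \eqn{P^{eff} > 0}, net compression
#' when \eqn{P^{eff} < 0}) and by whether the two stress eigenvalues share
#' the sign of \eqn{-P^{eff}} ("round": the cell pulls or pushes along both
#' axes) or have mixed signs ("elongated": tension along one axis,
#' compression along the other). The measure-zero boundary
#' \eqn{P^{eff} = 0} (traceless stress) is assigned "tension-elongated"
#' with a `zero_pressure` attribute.
#'
#' @param mech A `cell_mechanics` object from [cell_stress()].
#' @return One of `"tension-round"`, `"tension-elongated"`,
#'   `"compression-round"`, `"compression-elongated"`.
#' @export
classify_cell_stress <- function(mech) {
  stopifnot(inherits(mech, "cell_mechanics"))
  ev <- mech$eigenvalues
  if (mech$p_eff == 0) {
    return(structure("tension-elongated", zero_pressure = TRUE))
  }
  tone <- if (mech$p_eff > 0) "tension" else "compression"
  round_sign <- -sign(mech$p_eff)
  shape <- if (all(sign(ev) == round_sign)) "round" else "elongated"
  paste(tone, shape, sep = "-")
}

#' Tissue-level stress over a region
#'
#' The area-weighted mean of the cell stress tensors,
#' \eqn{(\sum_\alpha A_\alpha)\, \sigma^R = \sum_\alpha A_\alpha \sigma_\alpha},
#' over a subset of cells (default all). For a whole monolayer equilibrated
#' under an isotropic load the tissue stress equals \eqn{-P_{ext} I}; at
#' zero load it vanishes.
#'
#' @inheritParams net_vertex_forces
#' @param cells Optional integer vector of cell indices (default all).
#' @return A 2 x 2 symmetric stress tensor.
#' @export
tissue_stress <- function(network, params, cells = NULL) {
  stopifnot(inherits(network, "tissue_network"))
  params <- as_model_params(params)
  tab <- cell_table(network, params)
  if (!is.null(cells)) {
    if (length(cells) == 0) stop("empty cell subset", call. = FALSE)
    tab <- tab[tab$cell %in% cells, ]
  }
  a <- tab$area
  w <- a / sum(a)
  matrix(c(sum(w * tab$sigma_xx), sum(w * tab$sigma_xy),
           sum(w * tab$sigma_xy), sum(w * tab$sigma_yy)), 2, 2)
}

#' Misalignment between the principal axes of stress and shape
#'
#' Under the vertex model the stress and shape tensors of a cell commute at
#' equilibrium, so their principal axes coincide. This function returns the
#' acute deviation between the shape major axis and the *nearest* stress
#' principal axis (range `[0, pi/4]`): zero when the eigenbases coincide.
#' Note that which stress eigenvalue sits on the shape major axis depends
#' on the cell's state — a cell under net tension carries its
#' larger-magnitude stress eigenvalue along the elongation axis, while a
#' compressed elongated cell carries it along the perpendicular axis — so
#' the deviation of the eigenbasis, not the distance to the
#' larger-magnitude eigenvector, is the meaningful alignment measure.
#' Cells whose shape or stress tensor is isotropic to relative tolerance
#' `1e-6` have no defined axes and return `NA` (flagged degenerate).
#'
#' @param geometry A [cell_shape()] object.
#' @param mechanics A [cell_stress()] object.
#' @return Misalignment angle in radians in `[0, pi/4]`, or `NA_real_` for
#'   isotropic tensors.
#' @export
stress_shape_alignment <- function(geometry, mechanics) {
  stopifnot(inherits(geometry, "cell_geometry"),
            inherits(mechanics, "cell_mechanics"))
  lam <- geometry$eigenvalues
  ev <- mechanics$eigenvalues
  if (geometry$degenerate ||
      (lam[1] - lam[2]) <= 1e-6 * abs(lam[1]) ||
      abs(abs(ev[1]) - abs(ev[2])) <= 1e-6 * max(abs(ev[1]), 1e-300)) {
    return(NA_real_)
  }
  axis_deviation(geometry$major_angle, mechanics$principal_angle)
}

# Acute deviation between an axis and the nearest of the two orthogonal
# axes of an eigenbasis; axes are defined modulo pi.
axis_deviation <- function(a, b) {
  d <- abs(a - b) %% (pi / 2)
  pmin(d, pi / 2 - d)
}

#' Per-cell geometry and mechanics table
#'
#' The package's main tabular output: one row per cell with its polygonal
#' class, geometry (area, perimeter, circularity, shape axis), scalar
#' mechanics (P, T, P_eff), stress tensor components, magnitude-ordered
#' stress eigenvalues, principal stress angle, stress class and the
#' stress-shape alignment angle. Fully vectorized over cells.
#'
#' @inheritParams net_vertex_forces
#' @return A tibble with one row per cell.
#' @export
cell_table <- function(network, params) {
  stopifnot(inherits(network, "tissue_network"))
  params <- as_model_params(params)
  geo <- network_geometry(network)
  s <- network$slots
  x <- slot_coords(network$vertices, s, network$box)
  tx <- x[s$nxt, 1] - x[, 1]
  ty <- x[s$nxt, 2] - x[, 2]
  l <- sqrt(tx^2 + ty^2)
  hx <- tx / l
  hy <- ty / l
  dxx <- as.numeric(rowsum(l * hx * hx, s$cell))
  dxy <- as.numeric(rowsum(l * hx * hy, s$cell))
  dyy <- as.numeric(rowsum(l * hy * hy, s$cell))
  a <- geo$area
  per <- geo$perimeter
  p <- a - 1
  t_c <- params$gam * (per - params$l0)
  p_eff <- p + t_c * per / (2 * a)
  jxx <- (per / 2 - dxx) / a
  jxy <- -dxy / a
  jyy <- (per / 2 - dyy) / a
  sxx <- -p_eff + t_c * jxx
  sxy <- t_c * jxy
  syy <- -p_eff + t_c * jyy
  half_tr <- (sxx + syy) / 2
  disc <- sqrt(((sxx - syy) / 2)^2 + sxy^2)
  e_hi <- half_tr + disc
  e_lo <- half_tr - disc
  swap <- abs(e_lo) > abs(e_hi)
  sig1 <- ifelse(swap, e_lo, e_hi)
  sig2 <- ifelse(swap, e_hi, e_lo)
  ang_hi <- (0.5 * atan2(2 * sxy, sxx - syy)) %% pi
  stress_angle <- ifelse(swap, (ang_hi + pi / 2) %% pi, ang_hi)
  tone <- ifelse(p_eff > 0, "tension", "compression")
  both_round <- sign(sig1) == -sign(p_eff) & sign(sig2) == -sign(p_eff)
  stress_class <- ifelse(p_eff == 0, "tension-elongated",
                         paste(tone, ifelse(both_round, "round", "elongated"),
                               sep = "-"))
  shape_gap <- (geo$shape_lam1 - geo$shape_lam2) > 1e-6 * abs(geo$shape_lam1)
  stress_gap <- abs(abs(sig1) - abs(sig2)) > 1e-6 * pmax(abs(sig1), 1e-300)
  alignment <- ifelse(shape_gap & stress_gap,
                      axis_deviation(geo$shape_angle, stress_angle),
                      NA_real_)
  tibble::tibble(
    cell = geo$cell, z = geo$z,
    area = a, perimeter = per,
    circularity = geo$circularity,
    p = p, t = t_c, p_eff = p_eff,
    sigma_xx = sxx, sigma_xy = sxy, sigma_yy = syy,
    sigma_1 = sig1, sigma_2 = sig2,
    shape_angle = geo$shape_angle,
    stress_angle = stress_angle,
    stress_class = stress_class,
    alignment = alignment
  )
}
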