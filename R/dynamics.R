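#' Relaxation and topology settings
#'
#' Tunable numerical settings of the equilibration pipeline. Lengths and
#' areas in the topological thresholds are measured against the zero-load
#' equilibrium hexagon area \eqn{A_6^*} of the current parameters (the
#' larger root in the bistable region).
#'
#' @param force_tolerance Convergence criterion: maximum residual vertex
#'   force norm at equilibrium (default `1e-6`).
#' @param t1_length_factor An edge shorter than
#'   `t1_length_factor * sqrt(A6*)` triggers a T1 intercalation
#'   (default 0.1).
#' @param t2_area_factor A triangular cell smaller than
#'   `t2_area_factor * A6*` is extruded by a T2 transition (default 0.3).
#' @param t1_post_factor Length of the new edge created by a T1, as a
#'   multiple of the trigger threshold (default 1.5, placing the new edge
#'   safely above the threshold so the transition does not immediately
#'   re-fire; must exceed 1).
#' @param max_outer_iterations Cap on minimize/transition cycles
#'   (default 500).
#' @param load_tolerance Convergence bound on
#'   `|area-weighted mean P_eff - P_ext|` for the isotropic-load iteration
#'   (default `1e-3`).
#' @param optim_maxit Iteration cap handed to the quasi-Newton minimizer
#'   per inner call (default 20000).
#' @return A list of class `relax_settings`.
#' @export
relax_settings <- function(force_tolerance = 1e-6,
                           t1_length_factor = 0.1,
                           t2_area_factor = 0.3,
                           t1_post_factor = 1.5,
                           max_outer_iterations = 500,
                           load_tolerance = 1e-3,
                           optim_maxit = 20000) {
  stopifnot(force_tolerance > 0, t1_length_factor > 0, t2_area_factor > 0,
            t1_post_factor > 1, load_tolerance > 0)
  structure(
    list(force_tolerance = force_tolerance,
         t1_length_factor = t1_length_factor,
         t2_area_factor = t2_area_factor,
         t1_post_factor = t1_post_factor,
         max_outer_iterations = max_outer_iterations,
         load_tolerance = load_tolerance,
         optim_maxit = optim_maxit),
    class = "relax_settings"
  )
}

as_relax_settings <- function(settings) {
  if (is.null(settings)) return(relax_settings())
  if (inherits(settings, "relax_settings")) return(settings)
  do.call(relax_settings, settings)
}

# Quasi-Newton minimization of the network energy over vertex positions at
# fixed topology (offsets frozen during the inner solve, re-canonicalized
# afterwards). Gradient = minus the analytic vertex forces.
minimize_network <- function(net, params, settings) {
  slots <- net$slots
  box <- net$box
  gam <- params$gam
  l0 <- params$l0
  nv <- nrow(net$vertices)
  # finite patch under load: the exterior does work -P_ext * dA_patch
  boundary <- if (!net$periodic && params$p_ext != 0) {
    boundary_cycles(net)
  } else NULL
  cache <- new.env(parent = emptyenv())
  evaluate <- function(par) {
    if (!is.null(cache$par) && identical(par, cache$par)) return(cache$res)
    pos <- matrix(par, ncol = 2)
    res <- mech_core(pos, slots, box, gam, l0)
    if (!is.null(boundary)) {
      # positive P_ext is net tension: the exterior does work +P_ext dA on
      # the patch, so the minimized enthalpy is U - P_ext * A_patch
      res$energy <- res$energy - params$p_ext * sum(res$area)
      for (cyc in boundary) {
        nb <- c(cyc[-1], cyc[1])
        pb <- c(cyc[length(cyc)], cyc[-length(cyc)])
        d <- pos[nb, , drop = FALSE] - pos[pb, , drop = FALSE]
        res$force[cyc, 1] <- res$force[cyc, 1] + 0.5 * params$p_ext * d[, 2]
        res$force[cyc, 2] <- res$force[cyc, 2] - 0.5 * params$p_ext * d[, 1]
      }
    }
    cache$par <- par
    cache$res <- res
    res
  }
  fn <- function(par) evaluate(par)$energy
  gr <- function(par) -as.vector(evaluate(par)$force)
  par <- as.vector(net$vertices)
  for (restart in 1:6) {
    sol <- stats::optim(par, fn, gr, method = "L-BFGS-B",
                        control = list(maxit = settings$optim_maxit,
                                       factr = 10,
                                       pgtol = settings$force_tolerance * 0.2))
    par <- sol$par
    f <- evaluate(par)$force
    if (max(sqrt(rowSums(f^2))) < settings$force_tolerance) break
  }
  pos <- matrix(par, ncol = 2)
  net$vertices <- if (net$periodic) wrap_positions(pos, box) else pos
  net$slots <- build_slots(net)
  net
}

#' Relax a network to mechanical equilibrium
#'
#' Drives the network to a local minimum of the total energy: an outer loop
#' alternates quasi-Newton minimization of the vertex positions (analytic
#' forces as the gradient, convergence on the maximum residual force) with
#' topological checks. A triangular cell below the T2 area threshold is
#' extruded; otherwise the shortest edge below the T1 length threshold is
#' intercalated; one transition fires per outer iteration, followed by
#' re-relaxation, until no transition fires and the force criterion holds.
#' The energy is non-increasing across outer iterations.
#'
#' @param network A periodic [tissue_network()].
#' @param params A [model_params()] object (must admit an equilibrium
#'   hexagon area, used to scale the topological thresholds).
#' @param settings A [relax_settings()] list (or NULL for defaults).
#' @return The equilibrated network. `meta$n_t1` and `meta$n_t2` count the
#'   transitions fired; `meta$max_force` records the final residual. If the
#'   outer iteration cap is hit a warning is issued and the partial result
#'   returned.
#' @export
relax <- function(network, params, settings = NULL) {
  stopifnot(inherits(network, "tissue_network"))
  params <- as_model_params(params)
  settings <- as_relax_settings(settings)
  a6 <- equilibrium_areas(6, params, p_ext = 0)$primary
  if (is.na(a6)) {
    stop("no equilibrium hexagon area exists (region ", params$region,
         "): topological thresholds undefined", call. = FALSE)
  }
  t1_len <- settings$t1_length_factor * sqrt(a6)
  t2_area <- settings$t2_area_factor * a6
  n_t1 <- network$meta$n_t1 %||% 0L
  n_t2 <- network$meta$n_t2 %||% 0L
  skip_edges <- character(0)
  for (outer in seq_len(settings$max_outer_iterations)) {
    network <- minimize_network(network, params, settings)
    # T2 first: extrude any sufficiently small triangle
    geo_area <- cell_areas_slots(network$vertices, network$slots, network$box)
    tri <- which(network$slots$z == 3L & geo_area < t2_area)
    if (length(tri) > 0) {
      victim <- tri[which.min(geo_area[tri])]
      network <- apply_t2(network, victim)
      n_t2 <- n_t2 + 1L
      skip_edges <- character(0)
      next
    }
    # then the shortest sub-threshold edge
    ed <- network_edges(network)
    ed <- ed[ed$length < t1_len & !is.na(ed$cell2), , drop = FALSE]
    ed <- ed[!paste(ed$v1, ed$v2) %in% skip_edges, , drop = FALSE]
    if (nrow(ed) > 0) {
      ed <- ed[order(ed$length), , drop = FALSE]
      res <- apply_t1(network, c(ed$v1[1], ed$v2[1]),
                      new_length = settings$t1_post_factor * t1_len)
      if (res$refused) {
        # adjacent triangle: T2 check; extrusion above threshold is refused,
        # the edge is then left alone
        tri_cell <- res$triangle
        if (!is.null(tri_cell) &&
            cell_areas_slots(network$vertices, network$slots,
                             network$box)[tri_cell] < t2_area) {
          network <- apply_t2(network, tri_cell)
          n_t2 <- n_t2 + 1L
          skip_edges <- character(0)
        } else {
          skip_edges <- c(skip_edges, paste(ed$v1[1], ed$v2[1]))
        }
      } else {
        network <- res$network
        n_t1 <- n_t1 + 1L
        skip_edges <- character(0)
      }
      next
    }
    network$meta$n_t1 <- n_t1
    network$meta$n_t2 <- n_t2
    f <- net_vertex_forces(network, params)
    network$meta$max_force <- max(sqrt(rowSums(f^2)))
    return(network)
  }
  warning("relax: max_outer_iterations reached; returning partial result",
          call. = FALSE)
  network$meta$n_t1 <- n_t1
  network$meta$n_t2 <- n_t2
  f <- net_vertex_forces(network, params)
  network$meta$max_force <- max(sqrt(rowSums(f^2)))
  network
}

#' T1 transition (neighbour intercalation) on one edge
#'
#' If the edge is below the trigger length, it is rotated 90 degrees about
#' its midpoint and reconnected: the two cells that shared it lose one
#' vertex each, the two flanking cells gain one, and the new edge is laid
#' out with length `new_length`. An edge of a triangular cell is refused
#' (the transition would create a 2-gon); the caller should then consider a
#' T2 extrusion of that triangle.
#'
#' @param network A periodic [tissue_network()].
#' @param edge Integer vector `c(v1, v2)` of the edge's vertex ids.
#' @param settings A [relax_settings()] list; together with `params` it
#'   defines the trigger threshold when `threshold` is not given directly.
#' @param params A [model_params()] object (for the `A_6^*` scale).
#' @param threshold Optional trigger length (overrides settings/params).
#' @return The network, modified if the transition fired; `meta$n_t1` is
#'   incremented accordingly.
#' @export
attempt_t1 <- function(network, edge, settings = NULL, params = NULL,
                       threshold = NULL) {
  settings <- as_relax_settings(settings)
  if (is.null(threshold)) {
    params <- as_model_params(params)
    a6 <- equilibrium_areas(6, params, p_ext = 0)$primary
    threshold <- settings$t1_length_factor * sqrt(a6)
  }
  ed <- network_edges(network)
  row <- ed[(ed$v1 == min(edge) & ed$v2 == max(edge)), ]
  if (nrow(row) != 1) stop("edge not found in network", call. = FALSE)
  if (row$length >= threshold) return(network)
  res <- apply_t1(network, edge,
                  new_length = settings$t1_post_factor * threshold)
  if (res$refused) {
    warning("T1 refused: edge belongs to a triangular cell", call. = FALSE)
    return(network)
  }
  res$network$meta$n_t1 <- (network$meta$n_t1 %||% 0L) + 1L
  res$network
}

# Unconditional T1 rewiring; returns list(network, refused, triangle).
apply_t1 <- function(network, edge, new_length) {
  a <- edge[1]; b <- edge[2]
  s <- network$slots
  # directed occurrence a -> b identifies cell X; b -> a identifies cell Y
  sa <- which(s$vert == a & s$vert[s$nxt] == b)
  sb <- which(s$vert == b & s$vert[s$nxt] == a)
  if (length(sa) != 1 || length(sb) != 1) {
    stop("edge is not shared by exactly two cells", call. = FALSE)
  }
  cx <- s$cell[sa]; cy <- s$cell[sb]
  if (s$z[cx] == 3L) return(list(refused = TRUE, triangle = cx))
  if (s$z[cy] == 3L) return(list(refused = TRUE, triangle = cy))
  cells_a <- s$cell[s$vert == a]
  cells_b <- s$cell[s$vert == b]
  cp <- setdiff(cells_a, c(cx, cy))
  cq <- setdiff(cells_b, c(cx, cy))
  if (length(cp) != 1 || length(cq) != 1 || cp == cq) {
    return(list(refused = TRUE, triangle = NULL))
  }
  # geometry in cell X's unwrapped frame
  coords <- slot_coords(network$vertices, s, network$box)
  ra <- coords[sa, ]
  rb <- coords[s$nxt[sa], ]
  m <- (ra + rb) / 2
  u <- rb - ra
  u <- u / sqrt(sum(u^2))
  w <- c(-u[2], u[1])                  # left of a->b: points into cell X
  pa <- m + w * new_length / 2         # X-side endpoint, keeps label a
  pb <- m - w * new_length / 2         # Y-side endpoint, keeps label b
  cells <- network$cells
  cells[[cx]] <- setdiff(cells[[cx]], b)
  cells[[cy]] <- setdiff(cells[[cy]], a)
  ins_before <- function(cyc, at, val) {
    k <- match(at, cyc)
    append(cyc, val, after = k - 1L)
  }
  cells[[cp]] <- ins_before(cells[[cp]], a, b)
  cells[[cq]] <- ins_before(cells[[cq]], b, a)
  vertices <- network$vertices
  if (network$periodic) {
    vertices[a, ] <- c(pa[1] %% network$box[1], pa[2] %% network$box[2])
    vertices[b, ] <- c(pb[1] %% network$box[1], pb[2] %% network$box[2])
  } else {
    vertices[a, ] <- pa
    vertices[b, ] <- pb
  }
  net <- tissue_network(vertices, cells, box = network$box,
                        periodic = network$periodic, meta = network$meta)
  list(network = net, refused = FALSE, triangle = NULL)
}

#' T2 transition (extrusion) of a triangular cell
#'
#' If the triangle's area is below the trigger threshold, its three
#' vertices merge into a single trijunction at their mean position, the
#' cell is removed, and each of its three neighbours loses one vertex.
#'
#' @inheritParams attempt_t1
#' @param cell Index of the cell to extrude (must be a triangle; others are
#'   a no-op with a warning).
#' @return The network, modified if the extrusion fired.
#' @export
attempt_t2 <- function(network, cell, settings = NULL, params = NULL,
                       threshold = NULL) {
  settings <- as_relax_settings(settings)
  if (is.null(threshold)) {
    params <- as_model_params(params)
    a6 <- equilibrium_areas(6, params, p_ext = 0)$primary
    threshold <- settings$t2_area_factor * a6
  }
  if (network$slots$z[cell] != 3L) {
    warning("T2 applies only to triangular cells; no-op", call. = FALSE)
    return(network)
  }
  area <- cell_areas_slots(network$vertices, network$slots, network$box)[cell]
  if (area >= threshold) return(network)
  net <- apply_t2(network, cell)
  net$meta$n_t2 <- (network$meta$n_t2 %||% 0L) + 1L
  net
}

# Unconditional T2 extrusion of triangle `cell`.
apply_t2 <- function(network, cell) {
  tri <- network$cells[[cell]]
  stopifnot(length(tri) == 3L)
  pos_new <- colMeans(cell_polygon(network, cell))
  keep <- tri[1]
  drop_v <- tri[2:3]
  cells <- network$cells[-cell]
  cells <- lapply(cells, function(cyc) {
    cyc[cyc %in% drop_v] <- keep
    cyc <- cyc[c(TRUE, cyc[-1] != cyc[-length(cyc)])]
    if (length(cyc) > 1 && cyc[1] == cyc[length(cyc)]) cyc <- cyc[-length(cyc)]
    cyc
  })
  vertices <- network$vertices
  vertices[keep, ] <- if (network$periodic) {
    c(pos_new[1] %% network$box[1], pos_new[2] %% network$box[2])
  } else pos_new
  live <- setdiff(seq_len(nrow(vertices)), drop_v)
  remap <- integer(nrow(vertices))
  remap[live] <- seq_along(live)
  cells <- lapply(cells, function(cyc) remap[cyc])
  tissue_network(vertices[live, , drop = FALSE], cells, box = network$box,
                 periodic = network$periodic, meta = network$meta)
}

rescale_network <- function(network, factor) {
  network$vertices <- network$vertices * factor
  network$box <- network$box * factor
  # integer offsets are scale-free; slot structure unchanged
  network
}

#' Area-weighted mean effective pressure
#'
#' \eqn{\sum_\alpha A_\alpha P^{eff}_\alpha / \sum_\alpha A_\alpha}: the
#' isotropic load the monolayer currently carries (the tissue stress of an
#' equilibrated monolayer is minus this value times the identity). The
#' zero-load condition sets it to zero.
#'
#' @inheritParams relax
#' @return Scalar mean effective pressure.
#' @export
mean_effective_pressure <- function(network, params) {
  params <- as_model_params(params)
  core <- mech_core(network$vertices, network$slots, network$box,
                    params$gam, params$l0, forces = FALSE)
  p_eff <- core$pressure + core$tension * core$perimeter / (2 * core$area)
  sum(core$area * p_eff) / sum(core$area)
}

#' Equilibrate a monolayer at a prescribed isotropic load
#'
#' Iterates a global isotropic rescaling of the box and all vertex
#' positions, re-relaxing after each rescale, until the area-weighted mean
#' effective pressure matches the imposed external pressure
#' (`params$p_ext`) within `load_tolerance` — the load constraint that
#' fixes the equilibrium cell density. The first step uses the analytic
#' bulk modulus as the slope; subsequent steps are secant updates.
#'
#' @inheritParams relax
#' @return The relaxed network at the prescribed load, with
#'   `meta$box_scale` recording the cumulative rescale factor applied.
#' @export
enforce_isotropic_load <- function(network, params, settings = NULL) {
  params <- as_model_params(params)
  settings <- as_relax_settings(settings)
  target <- params$p_ext
  net <- relax(network, params, settings)
  s_cur <- 1
  g_cur <- mean_effective_pressure(net, params) - target
  if (abs(g_cur) < settings$load_tolerance) {
    net$meta$box_scale <- s_cur
    return(net)
  }
  # initial slope from the analytic bulk modulus: d(load)/d(log s) ~ 2K
  k0 <- tryCatch(bulk_modulus(net, params, force_tol = Inf),
                 error = function(e) NA_real_)
  if (!is.finite(k0) || k0 <= 0) k0 <- 1
  s_prev <- s_cur; g_prev <- g_cur
  s_cur <- s_cur - g_prev / (2 * k0)
  for (iter in 1:40) {
    if (s_cur < 0.5 || s_cur > 2.0) {
      stop("enforce_isotropic_load: no admissible box scale in [0.5, 2] ",
           "(parameters may be near the collapse region)", call. = FALSE)
    }
    net <- rescale_network(net, s_cur / s_prev)
    net <- relax(net, params, settings)
    g_new <- mean_effective_pressure(net, params) - target
    if (abs(g_new) < settings$load_tolerance) {
      net$meta$box_scale <- s_cur
      return(net)
    }
    step <- -g_new * (s_cur - s_prev) / (g_new - g_prev)
    step <- sign(step) * min(abs(step), 0.2 * s_cur)  # damp wild secant steps
    s_prev <- s_cur; g_prev <- g_new
    s_cur <- s_cur + step
  }
  stop("enforce_isotropic_load did not converge in 40 iterations",
       call. = FALSE)
}

#' One explicit overdamped time step
#'
#' Out of equilibrium, each vertex moves down the energy gradient against a
#' substrate drag whose magnitude is the sum of `A/Z` over the (three)
#' incident cells — drag scales with cell area, as for adhesion distributed
#' over the cell base. Setting the net force (elastic + drag) to zero
#' defines the vertex velocities; positions advance by `dt * velocity`. A
#' step that increases the energy is rejected and retried with `dt` halved
#' (logged via `message()`).
#'
#' @inheritParams relax
#' @param dt Time step (dimensionless model units).
#' @return The advanced network; `meta$velocities` holds the vertex
#'   velocity matrix (usable as the rate input of [cell_stress()]) and
#'   `meta$dt_used` the accepted step size.
#' @export
step_overdamped <- function(network, params, dt) {
  stopifnot(inherits(network, "tissue_network"), dt > 0)
  params <- as_model_params(params)
  s <- network$slots
  core <- mech_core(network$vertices, s, network$box, params$gam, params$l0)
  drag_slot <- (core$area / s$z)[s$cell]
  drag <- as.numeric(rowsum(drag_slot, s$vert, reorder = TRUE))
  vel <- core$force / drag
  u0 <- core$energy
  for (halving in 1:30) {
    cand <- network
    pos <- network$vertices + dt * vel
    cand$vertices <- if (network$periodic) wrap_positions(pos, network$box) else pos
    cand$slots <- build_slots(cand)
    u1 <- mech_core(cand$vertices, cand$slots, cand$box, params$gam,
                    params$l0, forces = FALSE)$energy
    if (u1 <= u0 + 1e-12 * abs(u0)) {
      cand$meta$velocities <- vel
      cand$meta$dt_used <- dt
      return(cand)
    }
    message("step_overdamped: energy increased; halving dt to ", dt / 2)
    dt <- dt / 2
  }
  stop("step_overdamped: no admissible step found", call. = FALSE)
}

#' Generate an equilibrated disordered monolayer
#'
#' The full simulation protocol: Matern type II seed points in a periodic
#' square box sized so the mean cell area matches the equilibrium hexagon
#' area at the imposed load, a periodic Voronoi tessellation as the initial
#' network, relaxation with T1/T2 transitions, and finally the isotropic
#' box rescale that enforces the prescribed load `params$p_ext`. Fully
#' reproducible under a fixed seed.
#'
#' @param params A [model_params()] object; parameters in the collapse
#'   region are refused.
#' @param n_cells Number of cells.
#' @param seed Integer RNG seed.
#' @param settings A [relax_settings()] list (or NULL for defaults).
#' @return An equilibrated periodic [tissue_network()]. `meta` records the
#'   parameters, seed, settings, transition counts, final residual force
#'   and box rescale factor.
#' @export
generate_monolayer <- function(params, n_cells, seed = 1L, settings = NULL) {
  params <- as_model_params(params)
  settings <- as_relax_settings(settings)
  if (params$region == "III") {
    stop("parameters lie in the collapse region (III): no equilibrium ",
         "monolayer exists", call. = FALSE)
  }
  a_target <- equilibrium_areas(6, params, p_ext = params$p_ext)$primary
  if (is.na(a_target)) a_target <- equilibrium_areas(6, params, p_ext = 0)$primary
  box <- sqrt(n_cells * a_target)
  pts <- matern_ii_points(box, n_cells, seed = seed)
  net <- voronoi_network(pts)
  net <- enforce_isotropic_load(net, params, settings)
  net$meta$params <- params
  net$meta$seed <- seed
  net$meta$settings <- settings
  net$meta$n_cells_initial <- n_cells
  net
}
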