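# Shared fixtures and oracles for the test suite. Expensive simulated
# monolayers are built once per session and memoized.

fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (is.null(fixture_cache[[key]])) fixture_cache[[key]] <- builder()
  fixture_cache[[key]]
}

# A relaxed, zero-load disordered monolayer (the workhorse fixture).
relaxed_monolayer <- function(n_cells = 100, lam = -0.2, gam = 0.1,
                              seed = 7) {
  key <- paste("mono", n_cells, lam, gam, seed)
  cached(key, function() {
    suppressMessages(
      generate_monolayer(model_params(lam, gam), n_cells, seed = seed)
    )
  })
}

# Central-difference gradient of the total energy with respect to every
# vertex coordinate: the independent oracle for the analytic forces.
fd_net_forces <- function(net, params, h = 1e-6) {
  u_of <- function(pos) {
    n2 <- net
    n2$vertices <- pos
    # keep the slot offsets frozen so the perturbed polygon stays contiguous
    epivertex:::mech_core(pos, net$slots, net$box, params$gam, params$l0,
                          forces = FALSE)$energy
  }
  g <- matrix(0, nrow(net$vertices), 2)
  for (j in seq_len(nrow(net$vertices))) {
    for (k in 1:2) {
      up <- net$vertices; up[j, k] <- up[j, k] + h
      dn <- net$vertices; dn[j, k] <- dn[j, k] - h
      g[j, k] <- (u_of(up) - u_of(dn)) / (2 * h)
    }
  }
  -g
}

# Single-cell energy for the per-cell force oracle.
cell_energy <- function(vertices, params) {
  g <- cell_shape(vertices)
  0.5 * (g$area - 1)^2 + 0.5 * params$gam * (g$perimeter - params$l0)^2
}

# Replace a trijunction by a small triangular cell ("vertex truncation"):
# builds a deterministic fixture containing a triangle for T2 tests. The
# three cells meeting at vertex v each gain one vertex.
truncate_vertex <- function(net, v, eps = 0.15) {
  s <- net$slots
  slots_v <- which(s$vert == v)
  stopifnot(length(slots_v) == 3)
  coords <- epivertex:::slot_coords(net$vertices, s, net$box)
  cells <- net$cells
  nv <- nrow(net$vertices)
  # one new vertex per incident cell edge leaving v, placed a fraction eps
  # along that edge; cell alpha with cycle ... prev -> v -> next ... gets
  # (point on edge prev-v) then (point on edge v-next) in place of v
  new_pts <- matrix(NA_real_, 3, 2)
  in_ids <- integer(3)   # new vertex on the incoming edge of each cell
  out_ids <- integer(3)  # new vertex on the outgoing edge
  # each directed edge v->n appears in exactly one cell; pair them up
  edge_pt <- list()
  for (k in 1:3) {
    sv <- slots_v[k]
    nxt_vert <- s$vert[s$nxt[sv]]
    p_v <- coords[sv, ]
    p_n <- coords[s$nxt[sv], ]
    pt <- p_v + eps * (p_n - p_v)
    edge_pt[[paste(v, nxt_vert)]] <- pt
  }
  keys <- names(edge_pt)
  pts <- do.call(rbind, edge_pt)
  pts_wrapped <- if (net$periodic) epivertex:::wrap_positions(pts, net$box) else pts
  vertices <- rbind(net$vertices, pts_wrapped)
  new_id <- stats::setNames(nv + seq_len(3), keys)
  for (k in 1:3) {
    sv <- slots_v[k]
    a <- s$cell[sv]
    nxt_vert <- s$vert[s$nxt[sv]]
    prv_vert <- s$vert[s$prv[sv]]
    cyc <- cells[[a]]
    i <- match(v, cyc)
    out_v <- new_id[[paste(v, nxt_vert)]]        # on this cell's outgoing edge
    in_v <- new_id[[paste(v, prv_vert)]]         # shared with the cell across
    cells[[a]] <- append(cyc[-i], c(in_v, out_v), after = i - 1L)
  }
  # the triangle cycle: order the three new vertices anticlockwise
  tri_pts <- pts
  ctr <- colMeans(tri_pts)
  ord <- order(atan2(tri_pts[, 2] - ctr[2], tri_pts[, 1] - ctr[1]))
  tri <- (nv + seq_len(3))[ord]
  cells[[length(cells) + 1]] <- tri
  # drop the old vertex v and compact ids
  live <- setdiff(seq_len(nrow(vertices)), v)
  remap <- integer(nrow(vertices))
  remap[live] <- seq_along(live)
  cells <- lapply(cells, function(cyc) remap[cyc])
  tissue_network(vertices[live, , drop = FALSE], cells, box = net$box,
                 periodic = net$periodic)
}

# Small finite honeycomb patch (one central hexagon + its 6 neighbours).
honeycomb_patch <- function(area = 1) {
  s <- sqrt(2 * area / (3 * sqrt(3)))
  w <- sqrt(3) * s
  theta <- pi / 2 + (0:5) * pi / 3
  hex <- cbind(s * cos(theta), s * sin(theta))
  centers <- rbind(
    c(0, 0),
    cbind(w * cos(pi / 6 + (0:5) * pi / 3) * sqrt(3) / sqrt(3),
          w * sin(pi / 6 + (0:5) * pi / 3))
  )
  # neighbour centres sit at distance w
  polys <- lapply(seq_len(nrow(centers)), function(k) {
    cbind(hex[, 1] + centers[k, 1], hex[, 2] + centers[k, 2])
  })
  epivertex:::merge_polygons_finite(polys, tol = 1e-6 * s)
}

expect_equal_tensor <- function(actual, expected, tol = 1e-10) {
  expect_lt(max(abs(actual - expected)), tol)
}
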