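test_that("relaxation converges to a force-free state and is idempotent", {
  p <- model_params(-0.2, 0.1)
  net <- voronoi_network(matern_ii_points(sqrt(40 * 0.538), 40, seed = 15))
  u0 <- total_energy(net, p)
  rel <- relax(net, p)
  expect_lt(rel$meta$max_force, 1e-6)
  expect_lt(total_energy(rel, p), u0)
  expect_true(validate_network(rel)$ok)
  # idempotence: relaxing again changes (almost) nothing
  rel2 <- relax(rel, p)
  expect_equal(rel2$meta$n_t1, rel$meta$n_t1)
  expect_lt(max(abs(rel2$vertices - rel$vertices)), 1e-6)
})

test_that("energy decreases across the outer relaxation loop", {
  p <- model_params(-0.2, 0.1)
  net <- voronoi_network(matern_ii_points(sqrt(40 * 0.538), 40, seed = 19))
  energies <- total_energy(net, p)
  cur <- net
  for (i in 1:6) {
    cur <- epivertex:::minimize_network(cur, p, relax_settings())
    energies <- c(energies, total_energy(cur, p))
  }
  expect_true(all(diff(energies) <= 1e-10))
})

test_that("T1 rewires a short edge with the published class bookkeeping", {
  p <- model_params(-0.1, 0.1)
  net <- hexagonal_lattice(1, 4, 4)
  ed <- epivertex:::network_edges(net)
  e <- ed[1, ]
  x_cells <- sort(c(e$cell1, e$cell2))
  # edge above threshold: untouched
  same <- attempt_t1(net, c(e$v1, e$v2), params = p)
  expect_identical(same$cells, net$cells)
  # force the transition with a threshold just above the edge length
  thr <- e$length * 1.01
  flank <- setdiff(
    unique(net$slots$cell[net$slots$vert %in% c(e$v1, e$v2)]),
    x_cells
  )
  out <- attempt_t1(net, c(e$v1, e$v2), threshold = thr)
  z <- lengths(out$cells)
  expect_equal(sort(z[x_cells]), c(5, 5))      # losers drop to pentagons
  expect_equal(sort(z[flank]), c(7, 7))        # flanks gain to heptagons
  expect_equal(sum(lengths(out$cells)), sum(lengths(net$cells)))
  expect_true(all(tabulate(out$slots$vert) == 3))
  val <- validate_network(out)
  expect_false(any(val$violations$type %in%
                     c("trijunction", "orientation", "periodic_closure")))
  # new edge has the requested post-transition length
  ed2 <- epivertex:::network_edges(out)
  new_e <- ed2[(ed2$v1 == min(e$v1, e$v2) & ed2$v2 == max(e$v1, e$v2)), ]
  expect_equal(new_e$length, 1.5 * thr, tolerance = 1e-9)
})

test_that("T2 extrudes a small triangle and demotes its three neighbours", {
  p <- model_params(-0.1, 0.1)
  net <- hexagonal_lattice(1, 4, 4)
  tri_net <- truncate_vertex(net, v = 10, eps = 0.12)
  tri_cell <- which(lengths(tri_net$cells) == 3)
  expect_length(tri_cell, 1)
  neighbours <- setdiff(
    unique(tri_net$slots$cell[tri_net$slots$vert %in% tri_net$cells[[tri_cell]]]),
    tri_cell
  )
  expect_equal(sort(lengths(tri_net$cells)[neighbours]), c(7, 7, 7))
  area_before <- sum(network_geometry(tri_net)$area)
  # above threshold: no-op
  big <- attempt_t2(tri_net, tri_cell, threshold = 1e-9)
  expect_equal(length(big$cells), length(tri_net$cells))
  # below threshold: extrusion
  out <- attempt_t2(tri_net, tri_cell, threshold = 1)
  expect_equal(length(out$cells), length(tri_net$cells) - 1)
  expect_equal(sort(lengths(out$cells)), rep(6L, 16))
  expect_true(all(tabulate(out$slots$vert) == 3))
  expect_equal(sum(network_geometry(out)$area), area_before, tolerance = 1e-9)
  expect_warning(attempt_t2(out, 1, threshold = 1), "triangular")
})

test_that("torus Euler characteristic and mean class 6 hold through transitions", {
  nets <- list(
    hexagonal_lattice(1, 4, 4),
    relaxed_monolayer(60, seed = 3),
    relaxed_monolayer(100, seed = 7)
  )
  for (net in nets) {
    nv <- nrow(net$vertices)
    nc <- length(net$cells)
    ne <- nrow(epivertex:::network_edges(net))
    expect_equal(sum(lengths(net$cells)), 2 * ne)   # each edge in two cells
    expect_equal(nv - ne + nc, 0)                   # torus Euler formula
    expect_equal(mean(lengths(net$cells)), 6)
  }
})

test_that("isotropic load enforcement recovers the hexagon equilibrium area", {
  p <- model_params(-0.1, 0.1)
  a6 <- equilibrium_areas(6, p)$primary
  net <- hexagonal_lattice(a6 * 1.25, 4, 4)  # start off-density
  out <- enforce_isotropic_load(net, p)
  geo <- network_geometry(out)
  expect_equal(mean(geo$area), a6, tolerance = 5e-3)
  expect_lt(abs(mean_effective_pressure(out, p)), 1e-3)
})

test_that("a loaded monolayer equilibrates at the prescribed pressure", {
  p <- model_params(-0.2, 0.1, p_ext = 0.08)
  net <- suppressMessages(generate_monolayer(p, 48, seed = 4))
  expect_lt(abs(mean_effective_pressure(net, p) - 0.08), 1e-3)
  # the isotropic part of the tissue stress is -P_ext
  ts <- tissue_stress(net, p)
  expect_lt(abs(sum(diag(ts)) / 2 + 0.08), 1e-3)
})

test_that("overdamped steps keep equilibria fixed and dissipate energy otherwise", {
  p <- model_params(-0.2, 0.1)
  eq <- relaxed_monolayer(60, seed = 3)
  stepped <- step_overdamped(eq, p, dt = 0.05)
  expect_lt(max(abs(stepped$meta$velocities)), 1e-4)
  expect_lt(max(abs(stepped$vertices - eq$vertices)), 1e-5)
  # perturb and watch the energy fall
  pert <- eq
  set.seed(8)
  pert$vertices <- epivertex:::wrap_positions(
    eq$vertices + matrix(rnorm(length(eq$vertices), 0, 0.01), ncol = 2),
    eq$box)
  pert$slots <- epivertex:::build_slots(pert)
  u <- total_energy(pert, p)
  cur <- pert
  for (i in 1:5) {
    cur <- suppressMessages(step_overdamped(cur, p, dt = 0.1))
    u2 <- total_energy(cur, p)
    expect_lte(u2, u + 1e-12)
    u <- u2
  }
  # velocities feed a symmetric dissipative stress
  vel_all <- cur$meta$velocities
  a <- 1
  idx <- cur$cells[[a]]
  m <- cell_stress(cell_polygon(cur, a), p, velocities = vel_all[idx, ])
  expect_lt(abs(m$sigma[1, 2] - m$sigma[2, 1]), 1e-12)
})

test_that("monolayer generation is deterministic and refuses the collapse region", {
  p <- model_params(-0.2, 0.1)
  n1 <- suppressMessages(generate_monolayer(p, 30, seed = 12))
  n2 <- suppressMessages(generate_monolayer(p, 30, seed = 12))
  expect_identical(n1$vertices, n2$vertices)
  expect_identical(n1$cells, n2$cells)
  expect_error(generate_monolayer(model_params(0.2, 0.2), 30), "collapse")
})
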