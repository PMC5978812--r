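test_that("pressure and tension vanish at the preferred geometry", {
  p <- model_params(-0.2, 0.1)   # L0 = 1
  g1 <- cell_shape(regular_ngon(6, 1))
  pt <- pressure_tension(g1, p)
  expect_equal(pt[["P"]], 0, tolerance = 1e-12)
  # hexagon of side 1: L = 6, T = 0.1 * (6 - 1) = 0.5
  hex_side1 <- regular_ngon(6, 3 * sqrt(3) / 2)
  pt2 <- pressure_tension(cell_shape(hex_side1), p)
  expect_equal(pt2[["T"]], 0.5, tolerance = 1e-10)
})

test_that("per-cell vertex forces equal minus the energy gradient", {
  set.seed(23)
  p <- model_params(-0.3, 0.12)
  h <- 1e-6
  for (i in 1:8) {
    n <- sample(4:9, 1)
    v <- regular_ngon(n, runif(1, 0.5, 2)) + matrix(rnorm(2 * n, 0, 0.1), ncol = 2)
    f <- cell_vertex_forces(v, p)
    expect_lt(max(abs(colSums(f))), 1e-12)   # closed cycle: forces sum to 0
    fd <- v * 0
    for (j in seq_len(n)) for (k in 1:2) {
      up <- v; up[j, k] <- up[j, k] + h
      dn <- v; dn[j, k] <- dn[j, k] - h
      fd[j, k] <- -(cell_energy(up, p) - cell_energy(dn, p)) / (2 * h)
    }
    expect_lt(max(abs(f - fd)), 1e-8)
  }
  # symmetry: forces on a regular polygon are radial with equal magnitude
  v6 <- regular_ngon(6, 0.7)
  f6 <- cell_vertex_forces(v6, p)
  mags <- sqrt(rowSums(f6^2))
  expect_equal(mags, rep(mags[1], 6), tolerance = 1e-10)
  radial <- f6 / mags
  outward <- v6 / sqrt(rowSums(v6^2))
  expect_equal(abs(rowSums(radial * outward)), rep(1, 6), tolerance = 1e-10)
})

test_that("net vertex forces vanish on the stress-free hexagonal lattice", {
  p <- model_params(-0.1, 0.1)
  a6 <- equilibrium_areas(6, p)$primary
  net <- hexagonal_lattice(a6, 4, 4)
  f <- net_vertex_forces(net, p)
  expect_lt(max(abs(f)), 1e-12)
})

test_that("net vertex forces equal minus the finite-difference energy gradient", {
  p <- model_params(-0.2, 0.1)
  pert <- perturbed_lattice(equilibrium_areas(6, p)$primary, 3, 4,
                            noise_amplitude = 0.08, seed = 2)
  f <- net_vertex_forces(pert, p)
  fd <- fd_net_forces(pert, p)
  expect_lt(max(abs(f - fd)) / max(abs(f)), 1e-6)
  # and on a disordered Voronoi network (off equilibrium)
  vor <- voronoi_network(matern_ii_points(5, 24, seed = 6))
  f2 <- net_vertex_forces(vor, p)
  fd2 <- fd_net_forces(vor, p)
  expect_lt(max(abs(f2 - fd2)) / max(abs(f2)), 1e-6)
})

test_that("total energy vanishes at preferred geometry and ignores the dropped constant", {
  gam <- 0.1
  p <- model_params(-2 * mu_n(6) * gam, gam)  # L0 = mu_6: unit hexagon is preferred
  single <- tissue_network(regular_ngon(6, 1) + 5, list(1:6), periodic = FALSE)
  expect_equal(total_energy(single, p), 0, tolerance = 1e-12)
  # the additive constant affects neither forces nor equilibria: forces are
  # already the gradient of the constant-free energy by construction, so
  # simply check consistency between the two code paths
  f <- net_vertex_forces(single, p)
  expect_lt(max(abs(f)), 1e-10)
})

test_that("geometric identities sum R (x) p = A I and sum R (x) q = -sum that (x) t hold", {
  set.seed(29)
  for (i in 1:20) {
    n <- sample(3:11, 1)
    v <- regular_ngon(n, runif(1, 0.3, 2.5)) + matrix(rnorm(2 * n, 0, 0.15), ncol = 2)
    g <- cell_shape(v)
    r <- g$centred
    nxt <- c(2:n, 1)
    prv <- c(n, 1:(n - 1))
    pvec <- 0.5 * cbind(r[nxt, 2] - r[prv, 2], -(r[nxt, 1] - r[prv, 1]))
    tv <- r[nxt, , drop = FALSE] - r
    th <- tv / sqrt(rowSums(tv^2))
    qvec <- th - th[prv, , drop = FALSE]
    expect_equal_tensor(crossprod(r, pvec), g$area * diag(2), tol = 1e-10)
    expect_equal_tensor(crossprod(r, qvec), -crossprod(th, tv), tol = 1e-10)
  }
})

test_that("cell stress has the exact trace, symmetry and deviator structure", {
  p <- model_params(-0.1, 0.1)
  set.seed(37)
  for (i in 1:15) {
    n <- sample(4:9, 1)
    v <- regular_ngon(n, runif(1, 0.4, 2)) + matrix(rnorm(2 * n, 0, 0.12), ncol = 2)
    m <- cell_stress(v, p)
    expect_lt(abs(sum(diag(m$sigma)) + 2 * m$p_eff), 1e-10)
    expect_lt(abs(m$sigma[1, 2] - m$sigma[2, 1]), 1e-10)
    expect_lt(abs(sum(diag(m$deviator))), 1e-10)
    # virial consistency: A sigma = sum R^i (x) f^i
    g <- cell_shape(v)
    f <- cell_vertex_forces(v, p)
    expect_equal_tensor(m$sigma, crossprod(g$centred, f) / g$area, tol = 1e-10)
  }
  # regular polygons are isotropic: J = 0, sigma = -P_eff I
  m6 <- cell_stress(regular_ngon(6, 1), p)
  expect_equal_tensor(m6$deviator, matrix(0, 2, 2), tol = 1e-12)
  expect_equal_tensor(m6$sigma, -m6$p_eff * diag(2), tol = 1e-12)
  expect_equal(m6$p_eff, 0.59976, tolerance = 1e-5)
  # rectangle (+-1, +-0.5): A = 2, L = 6, J = diag(-1/2, 1/2)
  rect <- rbind(c(1, 0.5), c(-1, 0.5), c(-1, -0.5), c(1, -0.5))
  mr <- cell_stress(rect, p)
  expect_equal_tensor(mr$deviator, diag(c(-0.5, 0.5)), tol = 1e-12)
})

test_that("dissipative stress term is symmetric and responds to vertex velocities", {
  p <- model_params(-0.2, 0.1)
  v <- regular_ngon(5, 1)
  set.seed(5)
  vel <- matrix(rnorm(10, 0, 0.3), ncol = 2)
  m0 <- cell_stress(v, p)
  m1 <- cell_stress(v, p, velocities = vel)
  diss <- m1$sigma - m0$sigma
  expect_lt(abs(diss[1, 2] - diss[2, 1]), 1e-12)
  expect_gt(max(abs(diss)), 0)
  # a rigid translation of the cell produces no dissipative stress
  m2 <- cell_stress(v, p, velocities = matrix(1, 5, 2))
  expect_equal_tensor(m2$sigma, m0$sigma, tol = 1e-12)
})

test_that("tissue stress is the area-weighted cell average with exact subsets", {
  net <- relaxed_monolayer(60, seed = 3)
  p <- model_params(-0.2, 0.1)
  # single-cell subset equals that cell's stress tensor
  m1 <- cell_stress(cell_polygon(net, 5), p)
  expect_equal_tensor(tissue_stress(net, p, cells = 5), m1$sigma, tol = 1e-10)
  expect_error(tissue_stress(net, p, cells = integer(0)), "empty")
  # zero-load equilibrium: the isotropic part vanishes to load tolerance
  ts <- tissue_stress(net, p)
  expect_lt(abs(sum(diag(ts)) / 2), 2e-3)
})

test_that("stress classification distinguishes the four published states", {
  mk <- function(p_eff, e1, e2) {
    structure(list(p_eff = p_eff, eigenvalues = c(e1, e2)),
              class = "cell_mechanics")
  }
  expect_equal(as.character(classify_cell_stress(mk(0.4, -0.5, -0.3))),
               "tension-round")
  expect_equal(as.character(classify_cell_stress(mk(0.1, -0.5, 0.3))),
               "tension-elongated")
  expect_equal(as.character(classify_cell_stress(mk(-0.4, 0.5, 0.3))),
               "compression-round")
  expect_equal(as.character(classify_cell_stress(mk(-0.1, 0.5, -0.3))),
               "compression-elongated")
  zero <- classify_cell_stress(mk(0, 0.3, -0.3))
  expect_true(isTRUE(attr(zero, "zero_pressure")))
})

test_that("stress and shape axes coincide for mirror-symmetric cells and statistically at equilibrium", {
  p <- model_params(-0.1, 0.1)
  # rectangle: both tensors diagonal in the same frame -> exactly 0
  rect <- rbind(c(1, 0.4), c(-1, 0.4), c(-1, -0.4), c(1, -0.4))
  a <- stress_shape_alignment(cell_shape(rect), cell_stress(rect, p))
  expect_equal(a, 0, tolerance = 1e-12)
  # regular polygon: isotropic, flagged degenerate
  reg <- regular_ngon(6, 1)
  expect_true(is.na(stress_shape_alignment(cell_shape(reg),
                                           cell_stress(reg, p))))
  # relaxed monolayer: alignment is strong statistically (median well below
  # a random-axis baseline of pi/8)
  net <- relaxed_monolayer(100, seed = 7)
  tab <- cell_table(net, model_params(-0.2, 0.1))
  expect_lt(median(tab$alignment, na.rm = TRUE), 0.05)
  expect_lt(mean(tab$alignment, na.rm = TRUE), pi / 16)
})

test_that("cell_table matches the single-cell API cell by cell", {
  net <- relaxed_monolayer(60, seed = 3)
  p <- model_params(-0.2, 0.1)
  tab <- cell_table(net, p)
  for (a in c(1, 17, 42)) {
    g <- cell_shape(cell_polygon(net, a))
    m <- cell_stress(g, p)
    expect_equal(tab$area[a], g$area, tolerance = 1e-12)
    expect_equal(tab$p_eff[a], m$p_eff, tolerance = 1e-12)
    expect_equal(tab$sigma_xy[a], m$sigma[1, 2], tolerance = 1e-12)
    expect_equal(tab$stress_class[a], as.character(m$stress_class))
    expect_equal(tab$circularity[a], g$circularity, tolerance = 1e-12)
  }
})
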