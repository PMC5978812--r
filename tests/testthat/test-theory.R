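test_that("shape constants mu_N match closed forms and the circle limit", {
  expect_equal(mu_n(6), 2 * sqrt(2 * sqrt(3)), tolerance = 1e-14)
  expect_equal(round(mu_n(6), 2), 3.72)
  expect_equal(round(mu_n(5), 2), 3.81)
  expect_equal(mu_n(4), 4)
  expect_true(all(diff(mu_n(3:50)) < 0))          # strictly decreasing
  expect_equal(mu_n(10000), 2 * sqrt(pi), tolerance = 1e-6)
  expect_error(mu_n(2))
})

test_that("regular-polygon effective pressure matches arithmetic and limits", {
  p <- model_params(-0.1, 0.1)
  expect_equal(peff_regular(1, 6, p), 0.59976, tolerance = 1e-5)
  # hexagon with L0 = mu_6 is stress-free at unit area
  gam <- 0.1
  p0 <- model_params(-2 * mu_n(6) * gam, gam)
  expect_equal(peff_regular(1, 6, p0), 0, tolerance = 1e-12)
  # Gamma -> 0 reduces to the bulk term alone
  p_small <- model_params(-1e-12, 1e-12)
  expect_equal(peff_regular(2.5, 6, p_small), 1.5, tolerance = 1e-9)
})

test_that("equilibrium areas solve the cubic with correct multiplicity", {
  p <- model_params(-0.1, 0.1)
  eq <- equilibrium_areas(6, p)
  expect_equal(round(eq$primary, 3), 0.446)
  expect_equal(peff_regular(eq$primary, 6, p), 0, tolerance = 1e-10)
  # along the soft boundary the root is exactly 1
  gam <- 0.08
  eq1 <- equilibrium_areas(6, model_params(-2 * mu_n(6) * gam, gam))
  expect_equal(max(eq1$areas), 1, tolerance = 1e-9)
  # on the bistable/collapse boundary the roots coalesce
  gam2 <- 0.05
  lam2 <- 8 / (3^1.5 * mu_n(6)) * (1 - gam2 * mu_n(6)^2 / 2)^1.5
  eq2 <- equilibrium_areas(6, model_params(lam2, gam2))
  expect_true(eq2$repeated)
  # region III: no positive root
  eq3 <- equilibrium_areas(6, model_params(0.2, 0.2))
  expect_length(eq3$areas, 0)
  expect_true(is.na(eq3$primary))
  # every reported root is a root
  for (n in c(5, 6, 7)) {
    eqn <- equilibrium_areas(n, model_params(0.15, 0.04))
    for (a in eqn$areas) {
      expect_lt(abs(peff_regular(a, n, model_params(0.15, 0.04))), 1e-10)
    }
  }
})

test_that("parameter-space classification matches the published boundaries", {
  expect_equal(classify_region(lam = -0.2, gam = 0.1)$region, "IIa")
  expect_equal(classify_region(lam = 0.2, gam = 0.048)$region, "IIb")
  expect_equal(classify_region(lam = -1.2, gam = 0.15)$region, "I")
  expect_equal(classify_region(lam = 0.2, gam = 0.2)$region, "III")
  expect_equal(classify_region(lam = -0.26, gam = 0.17)$region, "IIa")
  # lam = 0 splits on Gamma = 2 / mu6^2
  expect_equal(classify_region(lam = 0, gam = 0.1)$region, "IIa")
  expect_equal(classify_region(lam = 0, gam = 0.15)$region, "III")
  expect_error(classify_region(lam = 0.1, gam = -0.1), "gam > 0")
})

test_that("dagger transform is the identity at zero load and preserves equilibria", {
  p <- model_params(-0.26, 0.17)
  d0 <- dagger_transform(p, p_ext = 0)
  expect_equal(d0$lam_dag, p$lam)
  expect_equal(d0$gam_dag, p$gam)
  d1 <- dagger_transform(p, p_ext = 1)
  expect_equal(d1$lam_dag, p$lam / 2^1.5)
  expect_equal(d1$gam_dag, p$gam / 2)
  expect_error(dagger_transform(p, p_ext = -1), "p_ext > -1")
  # invariance: P_eff(A) = p_ext  <=>  P_eff(A dagger) = 0
  set.seed(31)
  for (i in 1:10) {
    gam <- runif(1, 0.05, 0.25)
    lam <- runif(1, -0.8, -0.05)
    pe <- runif(1, -0.5, 1.5)
    par <- model_params(lam, gam)
    a <- equilibrium_areas(6, par, p_ext = pe)$primary
    if (is.na(a)) next
    expect_equal(peff_regular(a, 6, par), pe, tolerance = 1e-10)
    dg <- dagger_transform(par, p_ext = pe)
    expect_lt(abs(peff_regular(a * dg$area_scale, 6,
                               model_params(dg$lam_dag, dg$gam_dag))), 1e-12)
    # round trip through the inverse
    back <- dagger_invert(dg$lam_dag, dg$gam_dag, pe)
    expect_equal(back$lam, lam, tolerance = 1e-12)
    expect_equal(back$gam, gam, tolerance = 1e-12)
  }
})

test_that("hexagonal moduli closed forms behave at the published special points", {
  expect_equal(bulk_modulus_hex(model_params(-1e-15, 0.1), area = 1), 1,
               tolerance = 1e-10)
  # K(A = 1) = 1 - Lambda mu_6 / 8 vanishes at Lambda = 8 / mu_6
  lam0 <- 8 / mu_n(6)
  expect_equal(bulk_modulus_hex(model_params(lam0, 0.05), area = 1), 0,
               tolerance = 1e-10)
  # shear modulus vanishes when L = L0 (soft boundary) and is positive at
  # the best-fit parameters
  gam <- 0.1
  soft <- model_params(-2 * mu_n(6) * gam, gam)
  expect_equal(shear_modulus_hex(soft, area = 1), 0, tolerance = 1e-10)
  fit <- model_params(-0.26, 0.17)
  expect_gt(shear_modulus_hex(fit), 0)
})

test_that("regular-polygon effective pressure equals -Tr(sigma)/2 of the explicit polygon", {
  set.seed(17)
  for (i in 1:30) {
    n <- sample(3:12, 1)
    a <- runif(1, 0.2, 3)
    par <- model_params(runif(1, -1, 0.3), runif(1, 0.02, 0.3))
    m <- cell_stress(regular_ngon(n, a), par)
    expect_lt(abs(peff_regular(a, n, par) - (-sum(diag(m$sigma)) / 2)), 1e-10)
  }
})
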