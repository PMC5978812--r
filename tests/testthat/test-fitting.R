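test_that("class summaries normalize to the population mean", {
  net <- hexagonal_lattice(0.7, 4, 4)
  cs <- class_summary(net)
  expect_equal(cs$mean_norm_area[cs$class == "6"], 1, tolerance = 1e-12)
  expect_equal(cs$mean_circularity[cs$class == "6"], 1, tolerance = 1e-9)
  expect_equal(cs$n[cs$class == "6"], 16L)
  expect_equal(sum(cs$proportion), 1)
  expect_equal(sum(cs$total_area_fraction), 1, tolerance = 1e-12)
  # empty classes are present with count zero and NA means
  expect_true(all(c("4", "5", "7", "8+") %in% cs$class))
  expect_true(all(is.na(cs$mean_norm_area[cs$class != "6"])))
  # cell-count-weighted mean of normalized areas is 1 for any input
  net2 <- relaxed_monolayer(100, seed = 7)
  cs2 <- class_summary(net2)
  expect_equal(sum(cs2$n * cs2$mean_norm_area, na.rm = TRUE) / sum(cs2$n), 1,
               tolerance = 1e-10)
  expect_error(class_summary(list()), "cell table|tissue_network")
})

test_that("the stage-10 Xenopus preset carries the published summary vectors", {
  tab <- make_experiment_table("xenopus-stage10")
  expect_equal(tab$mean_norm_area, c(0.59, 0.80, 1.03, 1.20, 1.60))
  expect_equal(tab$mean_circularity, c(0.56, 0.58, 0.58, 0.57, 0.53))
  expect_equal(tab$mean_norm_area[tab$class == "6"], 1.03)
  expect_equal(tab$mean_circularity[tab$class == "6"], 0.58)
  # arbitrary vectors are accepted; wrong length is not
  uni <- make_experiment_table(mean_norm_area = rep(1, 5))
  expect_equal(nrow(uni), 5)
  expect_error(make_experiment_table(mean_norm_area = rep(1, 4)), "length 5")
})

test_that("log-likelihood matches hand arithmetic and its invariances", {
  obs <- make_experiment_table(mean_norm_area = rep(1, 5))
  sim <- make_experiment_table(mean_norm_area = rep(1.1, 5))
  # five residuals of 0.1: -ln(0.05)
  expect_equal(log_likelihood(sim, obs), -log(0.05), tolerance = 1e-12)
  # permutation invariance of class order
  sim_perm <- sim[c(3, 1, 5, 2, 4), ]
  expect_equal(log_likelihood(sim_perm, obs), log_likelihood(sim, obs))
  # doubling all residuals lowers the value by ln 4
  sim2 <- make_experiment_table(mean_norm_area = rep(1.2, 5))
  expect_equal(log_likelihood(sim, obs) - log_likelihood(sim2, obs), log(4),
               tolerance = 1e-12)
  # monotone decreasing in each residual
  worse <- make_experiment_table(mean_norm_area = c(1.1, 1.1, 1.1, 1.1, 1.3))
  expect_lt(log_likelihood(worse, obs), log_likelihood(sim, obs))
  # perfect fit capped, missing class takes the maximal penalty
  expect_equal(log_likelihood(obs, obs), -log(1e-12))
  missing <- obs
  missing$mean_norm_area[1] <- NA_real_
  expect_equal(log_likelihood(missing, obs), -log(1), tolerance = 1e-12)
})

test_that("tiny grid fits are deterministic, finite, and region-II only", {
  obs <- make_experiment_table("xenopus-stage10")
  fit <- suppressMessages(grid_fit(obs, lam = c(-0.4, -0.2), gam = 0.12,
                                   n_realizations = 1, n_cells = 30, seed = 3))
  expect_s3_class(fit, "vertex_fit")
  expect_true(all(is.finite(fit$surface$loglik)))
  expect_true(all(fit$surface$region %in% c("IIa", "IIb")))
  fit2 <- suppressMessages(grid_fit(obs, lam = c(-0.4, -0.2), gam = 0.12,
                                    n_realizations = 1, n_cells = 30, seed = 3))
  expect_identical(fit$surface, fit2$surface)
  # grid points outside region II are dropped before simulation
  fit3 <- suppressMessages(grid_fit(obs, lam = c(-0.2, 0.4), gam = 0.2,
                                    n_realizations = 1, n_cells = 30, seed = 3))
  expect_equal(nrow(fit3$surface), 1)
  expect_error(grid_fit(obs, lam = 0.4, gam = 0.2), "region II")
  # tidiers
  expect_identical(generics::tidy(fit), fit$surface)
  gl <- generics::glance(fit)
  expect_equal(gl$lam, fit$argmax$lam)
  expect_equal(gl$l0, -fit$argmax$lam / (2 * fit$argmax$gam))
})

test_that("pressure scan at fixed dagger parameters reduces circularity", {
  sc <- suppressWarnings(
    pext_scan(-0.259, 0.172, pext_values = c(0, 0.6), n_cells = 60, seed = 2)
  )
  ov <- attr(sc, "overview")
  expect_equal(nrow(ov), 2)
  # net tension elongates cells: mean circularity decreases
  expect_lt(ov$mean_circularity[2], ov$mean_circularity[1])
  # p_ext = 0 is the plain generator at the dagger parameters
  direct <- suppressMessages(
    generate_monolayer(model_params(-0.259, 0.172), 60, seed = 3)
  )
  sc0 <- sc[sc$p_ext == 0, ]
  expect_equal(sc0$lam[1], -0.259)
  expect_equal(sc0$gam[1], 0.172)
})
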