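#' Per-polygonal-class summary of one or more monolayers
#'
#' Pools the cells of one or several networks and summarizes them by
#' polygonal class: count, proportion, mean area normalized to the pooled
#' population mean, mean circularity, and the fraction of total tissue area
#' occupied by the class. Classes with 8 or more sides are pooled into
#' `"8+"`; three-sided cells (absent from real epithelia and rare in
#' simulation) are reported as class `"3"` when present but are excluded
#' from likelihood fits. Classes 4 to 8+ always appear; empty ones carry
#' count 0 and `NA` means.
#'
#' @param networks A [tissue_network()], a list of them, or a tibble of
#'   cells with columns `z`, `area` and (optionally) `circularity`.
#' @return A tibble of class `class_summary` with columns `class`, `n`,
#'   `proportion`, `mean_norm_area`, `mean_circularity`,
#'   `total_area_fraction`; the pooled mean cell area is attached as
#'   attribute `norm_const`.
#' @export
class_summary <- function(networks) {
  cells <- pool_cells(networks)
  if (nrow(cells) == 0) stop("no cells to summarize", call. = FALSE)
  norm_const <- mean(cells$area)
  a_tot <- sum(cells$area)
  cells$class <- ifelse(cells$z >= 8, "8+", as.character(cells$z))
  present <- cells |>
    dplyr::group_by(.data$class) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_norm_area = mean(.data$area) / norm_const,
      mean_circularity = if ("circularity" %in% names(cells)) {
        mean(.data$circularity)
      } else NA_real_,
      total_area_fraction = sum(.data$area) / a_tot,
      .groups = "drop"
    )
  classes <- union(c("4", "5", "6", "7", "8+"), sort(unique(cells$class)))
  classes <- classes[order(match(classes, c("3", "4", "5", "6", "7", "8+")))]
  out <- tibble::tibble(class = classes) |>
    dplyr::left_join(present, by = "class") |>
    dplyr::mutate(
      n = dplyr::coalesce(.data$n, 0L),
      proportion = .data$n / sum(.data$n),
      total_area_fraction = dplyr::coalesce(.data$total_area_fraction, 0)
    ) |>
    dplyr::select("class", "n", "proportion", "mean_norm_area",
                  "mean_circularity", "total_area_fraction")
  attr(out, "norm_const") <- norm_const
  class(out) <- c("class_summary", class(out))
  out
}

pool_cells <- function(networks) {
  if (inherits(networks, "tissue_network")) networks <- list(networks)
  if (is.data.frame(networks)) return(networks)
  if (!is.list(networks) || length(networks) == 0) {
    stop("`networks` must be a tissue_network, a list of them, or a ",
         "cell table", call. = FALSE)
  }
  dplyr::bind_rows(lapply(networks, function(x) {
    if (inherits(x, "tissue_network")) {
      network_geometry(x)[, c("z", "area", "circularity")]
    } else {
      as.data.frame(x)
    }
  }))
}

#' Experimental (or synthetic) class-summary table
#'
#' Builds a [class_summary()]-shaped table from per-class mean normalized
#' areas for classes 4, 5, 6, 7 and 8+. The `"xenopus-stage10"` preset
#' carries the published summary statistics of stage-10 *Xenopus laevis*
#' animal-cap epithelium: mean normalized areas
#' \{0.59, 0.80, 1.03, 1.20, 1.60\} and mean circularities
#' \{0.56, 0.58, 0.58, 0.57, 0.53\}. Arbitrary vectors are accepted for
#' synthetic tests.
#'
#' @param profile Preset name (currently `"xenopus-stage10"`) or `NULL`
#'   when vectors are given.
#' @param mean_norm_area Numeric length-5 vector (classes 4..8+).
#' @param mean_circularity Optional numeric length-5 vector.
#' @param n Optional integer length-5 vector of cell counts.
#' @return A `class_summary` tibble.
#' @examples
#' make_experiment_table("xenopus-stage10")
#' @export
make_experiment_table <- function(profile = NULL, mean_norm_area = NULL,
                                  mean_circularity = NULL, n = NULL) {
  if (!is.null(profile)) {
    profile <- match.arg(profile, "xenopus-stage10")
    mean_norm_area <- c(0.59, 0.80, 1.03, 1.20, 1.60)
    mean_circularity <- c(0.56, 0.58, 0.58, 0.57, 0.53)
  }
  if (length(mean_norm_area) != 5) {
    stop("mean_norm_area must have length 5 (classes 4, 5, 6, 7, 8+)",
         call. = FALSE)
  }
  if (!is.null(mean_circularity) && length(mean_circularity) != 5) {
    stop("mean_circularity must have length 5", call. = FALSE)
  }
  out <- tibble::tibble(
    class = c("4", "5", "6", "7", "8+"),
    n = if (is.null(n)) NA_integer_ else as.integer(n),
    proportion = if (is.null(n)) NA_real_ else n / sum(n),
    mean_norm_area = as.numeric(mean_norm_area),
    mean_circularity = if (is.null(mean_circularity)) NA_real_ else
      as.numeric(mean_circularity),
    total_area_fraction = NA_real_
  )
  class(out) <- c("class_summary", class(out))
  out
}

#' Log-likelihood of simulated class areas against observation
#'
#' \deqn{\ell = -\ln \sum_{i \in \{4..8+\}}
#'   |\bar A_i^{obs} - \bar A_i^{sim}|^2,}
#' the negative log of the summed squared residuals of mean normalized
#' areas over polygonal classes 4 to 8+ (the proportionality constant is
#' irrelevant to the argmax and fixed to 1). A residual sum below `1e-12`
#' is capped there (flagged perfect fit). A class absent from the
#' simulation contributes its squared observed mean (maximal penalty).
#'
#' @param sim_table,obs_table `class_summary` tibbles covering classes
#'   4..8+.
#' @return Scalar log-likelihood (larger is better).
#' @export
log_likelihood <- function(sim_table, obs_table) {
  cls <- c("4", "5", "6", "7", "8+")
  sim <- sim_table$mean_norm_area[match(cls, sim_table$class)]
  obs <- obs_table$mean_norm_area[match(cls, obs_table$class)]
  if (anyNA(obs)) stop("observed table must cover classes 4..8+", call. = FALSE)
  resid <- ifelse(is.na(sim), obs, obs - sim)
  -log(max(sum(resid^2), 1e-12))
}

#' Grid likelihood fit of (Lambda, Gamma) to observed class areas
#'
#' Evaluates the class-area log-likelihood on a grid of parameter points:
#' at each region-II point, `n_realizations` monolayers of `n_cells` cells
#' are generated (distinct deterministic seeds derived from `seed`), their
#' cells pooled into one class summary, and [log_likelihood()] evaluated
#' against the observed table. Points outside region II are excluded before
#' simulation.
#'
#' @param obs_table Observed `class_summary` (e.g.
#'   [make_experiment_table()]).
#' @param lam,gam Numeric vectors of grid values (the grid is their outer
#'   product).
#' @param n_realizations Monolayers per grid point.
#' @param n_cells Cells per monolayer.
#' @param seed Base integer seed; realization seeds are
#'   `seed + 1009 * point_index + realization`.
#' @param settings A [relax_settings()] list (or NULL).
#' @param verbose Print progress per grid point.
#' @return An object of class `vertex_fit`: list with `surface` (tibble:
#'   `lam`, `gam`, `region`, `loglik`), `argmax` (one-row tibble),
#'   `obs_table` and the run metadata. Supports [generics::tidy()],
#'   [generics::glance()] and [ggplot2::autoplot()].
#' @export
grid_fit <- function(obs_table, lam, gam, n_realizations = 5, n_cells = 800,
                     seed = 1L, settings = NULL, verbose = FALSE) {
  grid <- tidyr_expand_grid(lam = lam, gam = gam)
  grid$region <- vapply(seq_len(nrow(grid)), function(i) {
    classify_region_label(grid$lam[i], grid$gam[i])
  }, character(1))
  grid <- grid[grid$region %in% c("IIa", "IIb"), , drop = FALSE]
  if (nrow(grid) == 0) stop("no grid point lies in region II", call. = FALSE)
  grid$loglik <- NA_real_
  for (i in seq_len(nrow(grid))) {
    params <- model_params(grid$lam[i], grid$gam[i])
    nets <- lapply(seq_len(n_realizations), function(k) {
      generate_monolayer(params, n_cells,
                         seed = as.integer(seed + 1009 * i + k),
                         settings = settings)
    })
    sim <- class_summary(nets)
    grid$loglik[i] <- log_likelihood(sim, obs_table)
    if (verbose) {
      message(sprintf("grid_fit [%d/%d] (%.3g, %.3g): loglik %.3f",
                      i, nrow(grid), grid$lam[i], grid$gam[i],
                      grid$loglik[i]))
    }
  }
  structure(
    list(
      surface = tibble::as_tibble(grid),
      argmax = tibble::as_tibble(grid[which.max(grid$loglik), , drop = FALSE]),
      obs_table = obs_table,
      n_realizations = n_realizations,
      n_cells = n_cells,
      seed = seed
    ),
    class = "vertex_fit"
  )
}

tidyr_expand_grid <- function(...) {
  out <- expand.grid(..., KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  tibble::as_tibble(out)
}

#' @export
print.vertex_fit <- function(x, ...) {
  cat(sprintf(
    "<vertex_fit> %d grid points (%d x %d cells each); argmax (Lambda, Gamma) = (%g, %g), loglik %.3f\n",
    nrow(x$surface), x$n_realizations, x$n_cells,
    x$argmax$lam, x$argmax$gam, x$argmax$loglik
  ))
  invisible(x)
}

#' Class-summary scan over external pressure at fixed dagger parameters
#'
#' Holds the unloaded-equivalent (dagger) parameters fixed while the
#' imposed isotropic pressure increases: for each `p_ext` the native
#' parameters are recovered by inverting the dagger rescaling, a monolayer
#' is generated and equilibrated at that load, and its class summary
#' recorded. Under increasing net tension cells become more elongated, so
#' the mean circularity decreases while the class-area profile stays close
#' to its unloaded shape.
#'
#' @param lam_dag,gam_dag Dagger parameter values to hold fixed.
#' @param pext_values Numeric vector of external pressures (> -1).
#' @param n_cells Cells per monolayer.
#' @param seed Base integer seed.
#' @param settings A [relax_settings()] list (or NULL).
#' @return A tibble with one row per (p_ext, class): the class-summary
#'   columns plus `p_ext`, `lam`, `gam`. Per-monolayer overall means are
#'   attached as attribute `overview` (tibble: `p_ext`, `mean_circularity`,
#'   `box_width`). Pressures whose native parameters leave region II are
#'   skipped with a warning.
#' @export
pext_scan <- function(lam_dag, gam_dag, pext_values, n_cells = 800,
                      seed = 1L, settings = NULL) {
  rows <- list()
  over <- list()
  for (k in seq_along(pext_values)) {
    pe <- pext_values[k]
    params <- dagger_invert(lam_dag, gam_dag, pe)
    if (!params$region %in% c("IIa", "IIb")) {
      warning(sprintf("p_ext = %g maps to region %s; skipped", pe,
                      params$region), call. = FALSE)
      next
    }
    net <- generate_monolayer(params, n_cells,
                              seed = as.integer(seed + k), settings = settings)
    geo <- network_geometry(net)
    cs <- class_summary(net)
    cs$p_ext <- pe
    cs$lam <- params$lam
    cs$gam <- params$gam
    rows[[length(rows) + 1]] <- cs
    over[[length(over) + 1]] <- tibble::tibble(
      p_ext = pe, mean_circularity = mean(geo$circularity),
      mean_area = mean(geo$area), box_width = net$box[1]
    )
  }
  if (length(rows) == 0) stop("all pressures were skipped", call. = FALSE)
  out <- dplyr::bind_rows(rows)
  attr(out, "overview") <- dplyr::bind_rows(over)
  out
}
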