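#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a grid fit
#'
#' Returns the likelihood surface as a tibble, one row per evaluated grid
#' point.
#'
#' @param x A [grid_fit()] result.
#' @param ... Unused.
#' @return A tibble with columns `lam`, `gam`, `region`, `loglik`.
#' @export
tidy.vertex_fit <- function(x, ...) {
  x$surface
}

#' One-row summary of a grid fit
#'
#' @param x A [grid_fit()] result.
#' @param ... Unused.
#' @return A one-row tibble: argmax `lam`, `gam`, its `loglik`, the derived
#'   preferred perimeter `l0`, grid size and simulation scale.
#' @export
glance.vertex_fit <- function(x, ...) {
  tibble::tibble(
    lam = x$argmax$lam,
    gam = x$argmax$gam,
    l0 = -x$argmax$lam / (2 * x$argmax$gam),
    loglik = x$argmax$loglik,
    n_grid = nrow(x$surface),
    n_realizations = x$n_realizations,
    n_cells = x$n_cells
  )
}

#' Tidy a tissue network
#'
#' Per-cell geometry (and mechanics when parameters are supplied) as a
#' tibble.
#'
#' @param x A [tissue_network()].
#' @param params Optional [model_params()]; adds the mechanics columns.
#' @param ... Unused.
#' @return A tibble with one row per cell.
#' @export
tidy.tissue_network <- function(x, params = NULL, ...) {
  if (is.null(params)) network_geometry(x) else cell_table(x, params)
}

#' One-row summary of a tissue network
#'
#' @param x A [tissue_network()].
#' @param params Optional [model_params()]; adds energy and load columns.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
glance.tissue_network <- function(x, params = NULL, ...) {
  geo <- network_geometry(x)
  out <- tibble::tibble(
    n_cells = length(x$cells),
    n_vertices = nrow(x$vertices),
    box_x = x$box[1], box_y = x$box[2],
    mean_area = mean(geo$area),
    mean_circularity = mean(geo$circularity),
    mean_class = mean(geo$z)
  )
  if (!is.null(params)) {
    params <- as_model_params(params)
    out$energy <- total_energy(x, params)
    out$mean_p_eff <- mean_effective_pressure(x, params)
    f <- net_vertex_forces(x, params)
    out$max_force <- max(sqrt(rowSums(f^2)))
  }
  out
}
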