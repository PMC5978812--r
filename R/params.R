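#' Dimensionless vertex-model parameters
#'
#' Bundles the two dimensionless mechanical parameters of the vertex model —
#' the line tension `lam` (\eqn{\Lambda}, tuning cell-cell adhesion against
#' cortical contraction) and the contractility `gam` (\eqn{\Gamma}, strength
#' of the perimeter spring) — together with an imposed isotropic boundary
#' pressure `p_ext`. Lengths are scaled on the square root of the preferred
#' cell area, so the preferred area is 1 and the derived preferred perimeter
#' is \eqn{L_0 = -\Lambda / 2\Gamma}.
#'
#' @param lam Dimensionless line tension \eqn{\Lambda} (may be negative).
#' @param gam Dimensionless contractility \eqn{\Gamma > 0}.
#' @param p_ext Imposed isotropic external pressure (default 0, an unloaded
#'   monolayer).
#' @return An object of class `model_params`: a list with fields `lam`,
#'   `gam`, `p_ext`, the derived preferred perimeter `l0`, and the parameter
#'   `region` label (see [classify_region()]).
#' @examples
#' p <- model_params(-0.26, 0.17)
#' p$l0 # ~0.76
#' @export
model_params <- function(lam, gam, p_ext = 0) {
  stopifnot(is.numeric(lam), length(lam) == 1L, is.finite(lam))
  stopifnot(is.numeric(gam), length(gam) == 1L, is.finite(gam))
  stopifnot(is.numeric(p_ext), length(p_ext) == 1L, is.finite(p_ext))
  if (gam <= 0) {
    stop("`gam` must be positive: the preferred perimeter L0 = -lam/(2 gam) ",
         "is undefined for gam <= 0.", call. = FALSE)
  }
  structure(
    list(
      lam = lam, gam = gam, p_ext = p_ext,
      l0 = -lam / (2 * gam),
      region = classify_region_label(lam, gam)
    ),
    class = "model_params"
  )
}

#' @export
print.model_params <- function(x, ...) {
  cat(sprintf(
    "<model_params> Lambda = %g, Gamma = %g, P_ext = %g (L0 = %.4g, region %s)\n",
    x$lam, x$gam, x$p_ext, x$l0, x$region
  ))
  invisible(x)
}

as_model_params <- function(params) {
  if (inherits(params, "model_params")) return(params)
  if (is.list(params) && all(c("lam", "gam") %in% names(params))) {
    return(model_params(params$lam, params$gam, params$p_ext %||% 0))
  }
  stop("`params` must be a model_params object (see model_params()).",
       call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
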