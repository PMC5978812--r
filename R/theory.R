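#' Shape constant of a regular polygon
#'
#' The dimensionless perimeter-to-root-area ratio of a regular N-gon,
#' \eqn{\mu_N = 2 (N \tan(\pi/N))^{1/2}}, so that a regular N-gon satisfies
#' \eqn{L = \mu_N \sqrt{A}}. \eqn{\mu_N} decreases strictly with N towards
#' the circle limit \eqn{2\sqrt{\pi}}; \eqn{\mu_6 \approx 3.72} and
#' \eqn{\mu_5 \approx 3.81}.
#'
#' @param n Integer polygonal class (number of sides), `n >= 3`. Vectorized.
#' @return Numeric vector of shape constants.
#' @examples
#' mu_n(6) # 2 * sqrt(2 * sqrt(3))
#' @export
mu_n <- function(n) {
  if (any(n < 3)) stop("polygonal class must be >= 3", call. = FALSE)
  2 * sqrt(n * tan(pi / n))
}

#' Effective pressure of a regular N-gon
#'
#' Closed-form effective pressure of a regular N-gon of area `a`:
#' \deqn{P^{eff}_N(A) = A - 1 + \Gamma \mu_N^2 / 2 + \Lambda \mu_N / (4 \sqrt{A}),}
#' the isotropic part (with sign reversed) of the cell stress tensor. It
#' combines the bulk pressure \eqn{A - 1} with a Young-Laplace cortical
#' contribution of the perimeter tension acting on an effective radius
#' \eqn{2A/L}.
#'
#' @param a Cell area (dimensionless, preferred area = 1). Vectorized.
#' @param n Polygonal class.
#' @param params A [model_params()] object.
#' @return Effective pressure (vectorized over `a`).
#' @examples
#' peff_regular(1, 6, model_params(-0.1, 0.1)) # 0.59976
#' @export
peff_regular <- function(a, n, params) {
  params <- as_model_params(params)
  if (any(a <= 0)) stop("area must be positive", call. = FALSE)
  mu <- mu_n(n)
  a - 1 + params$gam * mu^2 / 2 + params$lam * mu / (4 * sqrt(a))
}

#' Equilibrium areas of a regular N-gon
#'
#' Positive areas at which a regular N-gon has effective pressure equal to
#' `p_ext`. Substituting \eqn{x = \sqrt{A}} turns
#' \eqn{P^{eff}_N(A) = P_{ext}} into the depressed cubic
#' \eqn{x^3 + (\Gamma\mu_N^2/2 - 1 - P_{ext})\,x + \Lambda\mu_N/4 = 0},
#' solved analytically (discriminant-classified Cardano/trigonometric form)
#' so that root multiplicity near the bistable/collapse boundary is detected
#' robustly. Zero, one or two admissible roots may exist; the larger root is
#' labelled primary (it is the stable branch used to set simulation density).
#'
#' @param n Polygonal class.
#' @param params A [model_params()] object.
#' @param p_ext Imposed pressure at which to balance (defaults to
#'   `params$p_ext`).
#' @return A list with `areas` (decreasing numeric vector, possibly empty),
#'   `primary` (largest root or `NA` if none) and `repeated` (logical, TRUE
#'   when the admissible roots coalesce, i.e. the cubic discriminant
#'   vanishes to tolerance).
#' @examples
#' equilibrium_areas(6, model_params(-0.1, 0.1))$primary # 0.446
#' @export
equilibrium_areas <- function(n, params, p_ext = NULL) {
  params <- as_model_params(params)
  p_ext <- p_ext %||% params$p_ext
  mu <- mu_n(n)
  p <- params$gam * mu^2 / 2 - 1 - p_ext
  q <- params$lam * mu / 4
  x <- solve_depressed_cubic(p, q)
  xs <- sort(x$roots[x$roots > 1e-12], decreasing = TRUE)
  list(
    areas = xs^2,
    primary = if (length(xs)) xs[1]^2 else NA_real_,
    repeated = x$repeated
  )
}

# Real roots of x^3 + p x + q = 0 by discriminant classification.
solve_depressed_cubic <- function(p, q, tol = 1e-12) {
  disc <- -4 * p^3 - 27 * q^2
  scale <- max(abs(p), abs(q), 1)^2
  if (abs(disc) < tol * scale) {
    # repeated roots: x1 = 3q/p (simple), x2 = x3 = -3q/(2p); p == 0 -> triple 0
    if (abs(p) < tol) return(list(roots = 0, repeated = TRUE))
    return(list(roots = c(3 * q / p, -3 * q / (2 * p)), repeated = TRUE))
  }
  if (disc > 0) {
    # three distinct real roots (trigonometric form, p < 0 here)
    m <- 2 * sqrt(-p / 3)
    theta <- acos(pmin(1, pmax(-1, 3 * q / (p * m))))
    k <- 0:2
    roots <- m * cos(theta / 3 - 2 * pi * k / 3)
  } else {
    # one real root (Cardano)
    s <- sqrt(q^2 / 4 + p^3 / 27)
    roots <- cbrt(-q / 2 + s) + cbrt(-q / 2 - s)
  }
  list(roots = roots, repeated = FALSE)
}

cbrt <- function(x) sign(x) * abs(x)^(1 / 3)

classify_region_label <- function(lam, gam) {
  if (gam <= 0) return(NA_character_)
  mu6 <- mu_n(6)
  if (lam < -2 * mu6 * gam) return("I")
  if (lam <= 0) {
    # along lam = 0 a positive equilibrium area survives only for gam < 2/mu6^2
    if (lam == 0 && gam >= 2 / mu6^2) return("III")
    return("IIa")
  }
  if (gam >= 2 / mu6^2) return("III")
  bound <- 8 / (3^1.5 * mu6) * (1 - gam * mu6^2 / 2)^1.5
  if (lam < bound) "IIb" else "III"
}

#' Classify a point of (Lambda, Gamma) parameter space
#'
#' Partitions the parameter plane (for \eqn{\Gamma > 0}) into the regions of
#' qualitatively different hexagonal ground states:
#' * `I` — soft network, no shear resistance (\eqn{\Lambda < -2\mu_6\Gamma});
#' * `IIa` — a single stress-free equilibrium (\eqn{-2\mu_6\Gamma < \Lambda \le 0});
#' * `IIb` — two equilibria (bistable), \eqn{\Lambda > 0} below the
#'   repeated-root curve \eqn{\Lambda = 8 (1 - \Gamma\mu_6^2/2)^{3/2} / (3^{3/2}\mu_6)};
#' * `III` — no positive equilibrium area, the network collapses.
#'
#' @param params A [model_params()] object, or `lam` and `gam` given
#'   directly.
#' @param lam,gam Alternative scalar interface.
#' @return A list with `region` (one of `"I"`, `"IIa"`, `"IIb"`, `"III"`)
#'   and `boundaries`, a named numeric vector of signed distances in
#'   \eqn{\Lambda} to each bounding curve at this \eqn{\Gamma} (positive
#'   means the point lies above/right of the curve).
#' @examples
#' classify_region(model_params(-0.2, 0.1))$region # "IIa"
#' @export
classify_region <- function(params = NULL, lam = NULL, gam = NULL) {
  if (!is.null(params)) {
    params <- as_model_params(params)
    lam <- params$lam
    gam <- params$gam
  }
  if (gam <= 0) stop("region classification requires gam > 0", call. = FALSE)
  mu6 <- mu_n(6)
  iib_bound <- if (gam < 2 / mu6^2) {
    8 / (3^1.5 * mu6) * (1 - gam * mu6^2 / 2)^1.5
  } else {
    0
  }
  list(
    region = classify_region_label(lam, gam),
    boundaries = c(
      I_IIa = lam - (-2 * mu6 * gam),  # distance above the soft boundary
      IIa_III = lam,                   # distance from the lam = 0 line
      IIb_III = lam - iib_bound        # distance above the repeated-root curve
    )
  )
}

#' Rescaling of parameters under an isotropic load (dagger transform)
#'
#' For a loaded regular hexagonal packing the substitutions
#' \deqn{A^\dagger = A/(1+P_{ext}),\quad \Gamma^\dagger = \Gamma/(1+P_{ext}),\quad
#'   \Lambda^\dagger = \Lambda/(1+P_{ext})^{3/2}}
#' map a state with \eqn{P^{eff}_6 = P_{ext}} to an equivalent unloaded one
#' with \eqn{P^{eff}_6 = 0}. `dagger_transform` maps native parameters to
#' their unloaded equivalents; `dagger_invert` recovers the native
#' parameters that realize given dagger values at a load `p_ext`.
#'
#' @param params A [model_params()] object.
#' @param p_ext Imposed pressure, must exceed -1.
#' @return For `dagger_transform`: a list with `lam_dag`, `gam_dag` and
#'   `area_scale` (\eqn{1/(1+P_{ext})}). For `dagger_invert`: a
#'   [model_params()] object with `p_ext` set.
#' @examples
#' dagger_transform(model_params(-0.26, 0.17), p_ext = 1)
#' @export
dagger_transform <- function(params, p_ext = NULL) {
  params <- as_model_params(params)
  p_ext <- p_ext %||% params$p_ext
  if (p_ext <= -1) stop("dagger transform requires p_ext > -1", call. = FALSE)
  s <- 1 + p_ext
  list(
    lam_dag = params$lam / s^1.5,
    gam_dag = params$gam / s,
    area_scale = 1 / s
  )
}

#' @rdname dagger_transform
#' @param lam_dag,gam_dag Dagger (unloaded-equivalent) parameter values.
#' @export
dagger_invert <- function(lam_dag, gam_dag, p_ext) {
  if (p_ext <= -1) stop("dagger transform requires p_ext > -1", call. = FALSE)
  s <- 1 + p_ext
  model_params(lam = lam_dag * s^1.5, gam = gam_dag * s, p_ext = p_ext)
}

#' Bulk modulus of a monolayer
#'
#' Linearized resistance of the monolayer to isotropic dilation,
#' \eqn{K = A\, dP_{ext}/dA} evaluated at the zero-load state. For a
#' disordered network at equilibrium this is the area-weighted sum
#' \deqn{K = \sum_\alpha \frac{A_\alpha}{2A}\left[2 A_\alpha +
#'   \frac{\Gamma L_0 L_\alpha}{2 A_\alpha}\right],}
#' which reduces for a uniform hexagonal packing to the closed form
#' \eqn{K = A - \Lambda \mu_6 / (8\sqrt{A})} (see [bulk_modulus_hex()]).
#'
#' @param network A relaxed [tissue_network()]; the force residual is
#'   checked and a non-equilibrated network is refused.
#' @param params A [model_params()] object.
#' @param force_tol Maximum residual vertex force accepted as "equilibrated"
#'   (default `1e-4`).
#' @return Dimensionless bulk modulus (units of the area stiffness times
#'   preferred area).
#' @export
bulk_modulus <- function(network, params, force_tol = 1e-4) {
  params <- as_model_params(params)
  f <- net_vertex_forces(network, params)
  maxf <- max(sqrt(rowSums(f^2)))
  if (maxf > force_tol) {
    stop(sprintf(paste0(
      "bulk_modulus requires an equilibrated network: max residual force ",
      "%.3g exceeds force_tol = %.3g. Relax the network first."),
      maxf, force_tol), call. = FALSE)
  }
  g <- network_geometry(network)
  a_tot <- sum(g$area)
  sum(g$area / (2 * a_tot) * (2 * g$area + params$gam * params$l0 * g$perimeter / (2 * g$area)))
}

#' @rdname bulk_modulus
#' @param area Cell area of the uniform hexagonal packing.
#' @export
bulk_modulus_hex <- function(params, area = 1) {
  params <- as_model_params(params)
  area - params$lam * mu_n(6) / (8 * sqrt(area))
}

#' Shear modulus of a uniform hexagonal packing
#'
#' Closed-form shear modulus of a monolayer of identical regular hexagons,
#' \eqn{G = 3\sqrt{3}\,\Gamma (1 - L_0/L)} with \eqn{L = \mu_6\sqrt{A}}.
#' The monolayer resists shear only when the perimeter exceeds its
#' preferred value (\eqn{L > L_0}, cell walls under tension); along the
#' soft-region boundary \eqn{L = L_0} and G vanishes. No closed form is
#' given for disordered packings; estimate numerically by a small
#' area-preserving shear of the box followed by re-relaxation.
#'
#' @param params A [model_params()] object.
#' @param area Hexagon area (default the zero-load equilibrium area).
#' @return Dimensionless shear modulus.
#' @export
shear_modulus_hex <- function(params, area = NULL) {
  params <- as_model_params(params)
  if (is.null(area)) {
    area <- equilibrium_areas(6, params)$primary
    if (is.na(area)) stop("no equilibrium hexagon area exists for these parameters",
                          call. = FALSE)
  }
  l <- mu_n(6) * sqrt(area)
  3 * sqrt(3) * params$gam * (1 - params$l0 / l)
}
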