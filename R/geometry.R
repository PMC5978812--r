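#' Signed polygon area
#'
#' Shoelace (cross-product) area of a polygon from its ordered vertices,
#' evaluated on centroid-centred coordinates. Positive for anticlockwise
#' traversal — the orientation convention used for all cell cycles — and
#' negative for clockwise input.
#'
#' @param vertices An n x 2 numeric matrix of ordered vertex coordinates
#'   (n >= 3).
#' @return Signed area (scalar).
#' @examples
#' polygon_area(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))) # 1
#' @export
polygon_area <- function(vertices) {
  v <- as_vertex_matrix(vertices)
  r <- sweep(v, 2, colMeans(v))
  nxt <- c(2:nrow(r), 1)
  sum(r[, 1] * r[nxt, 2] - r[nxt, 1] * r[, 2]) / 2
}

#' Edge lengths and perimeter of a polygon
#'
#' Tangents are \eqn{t^i = R^{i+1} - R^i} with cyclic closure; edge `i`
#' joins vertex `i` to vertex `i + 1`.
#'
#' @inheritParams polygon_area
#' @return A list with `edge_lengths` (numeric vector, one per edge) and
#'   `perimeter` (their sum). Coincident consecutive vertices trigger a
#'   zero-length-edge warning.
#' @export
polygon_perimeter <- function(vertices) {
  v <- as_vertex_matrix(vertices)
  nxt <- c(2:nrow(v), 1)
  t <- v[nxt, , drop = FALSE] - v
  l <- sqrt(rowSums(t^2))
  if (any(l == 0)) {
    warning("polygon has zero-length edge(s) (coincident consecutive vertices)",
            call. = FALSE)
  }
  list(edge_lengths = l, perimeter = sum(l))
}

#' Cell shape descriptors from a polygon
#'
#' Computes the full geometric characterization of one cell: area, edge
#' lengths and perimeter, centroid (the arithmetic mean of the vertices, so
#' that centred vertex vectors sum to zero), the vertex-based shape tensor
#' \deqn{S = \frac{1}{Z} \sum_i R^i \otimes R^i}
#' over centred vertices \eqn{R^i}, its eigen-decomposition
#' (\eqn{\lambda_1 \ge \lambda_2}), the circularity
#' \eqn{C = \lambda_2/\lambda_1 \in (0, 1]} and the polygonal class Z.
#' The major principal axis is the eigenvector of \eqn{\lambda_1}.
#'
#' The arithmetic-mean centroid (rather than the area centroid) is the
#' convention under which the shape tensor and the stress/shape identities
#' of the model hold exactly.
#'
#' @inheritParams polygon_area
#' @return An object of class `cell_geometry`: a list with fields `area`,
#'   `edge_lengths`, `perimeter`, `centroid`, `shape_tensor`,
#'   `eigenvalues`, `major_axis` (unit 2-vector), `major_angle` (radians in
#'   `[0, pi)`), `circularity`, `z` and `degenerate` (TRUE for collinear
#'   polygons, which get circularity 0).
#' @examples
#' g <- cell_shape(regular_ngon(6, area = 1))
#' g$circularity # 1 (regular polygons are isotropic)
#' @export
cell_shape <- function(vertices) {
  v <- as_vertex_matrix(vertices)
  centroid <- colMeans(v)
  r <- sweep(v, 2, centroid)
  z <- nrow(r)
  s <- crossprod(r) / z
  eig <- eigen2x2(s)
  per <- suppressWarnings(polygon_perimeter(v))
  degenerate <- eig$values[2] <= 1e-14 * max(eig$values[1], 1)
  structure(
    list(
      area = polygon_area(v),
      edge_lengths = per$edge_lengths,
      perimeter = per$perimeter,
      centroid = centroid,
      shape_tensor = s,
      eigenvalues = eig$values,
      major_axis = eig$vector1,
      major_angle = eig$angle,
      circularity = if (degenerate) 0 else eig$values[2] / eig$values[1],
      z = z,
      degenerate = degenerate,
      centred = r
    ),
    class = "cell_geometry"
  )
}

#' @export
print.cell_geometry <- function(x, ...) {
  cat(sprintf(
    "<cell_geometry> Z = %d, A = %.6g, L = %.6g, C = %.4g\n",
    x$z, x$area, x$perimeter, x$circularity
  ))
  invisible(x)
}

# Eigen-decomposition of a symmetric 2x2 tensor in closed form.
# Returns values (decreasing), the eigenvector of the larger value, and its
# axis angle in [0, pi).
eigen2x2 <- function(s) {
  a <- s[1, 1]; b <- s[1, 2]; c <- s[2, 2]
  half_tr <- (a + c) / 2
  disc <- sqrt(((a - c) / 2)^2 + b^2)
  values <- c(half_tr + disc, half_tr - disc)
  ang <- 0.5 * atan2(2 * b, a - c)  # axis of the larger eigenvalue
  ang <- ang %% pi
  list(values = values, vector1 = c(cos(ang), sin(ang)), angle = ang)
}

as_vertex_matrix <- function(vertices) {
  if (is.data.frame(vertices)) vertices <- as.matrix(vertices[, c("x", "y")])
  v <- as.matrix(vertices)
  if (!is.numeric(v) || ncol(v) != 2) {
    stop("vertices must be an n x 2 numeric matrix", call. = FALSE)
  }
  if (nrow(v) < 3) {
    stop("degenerate polygon: fewer than 3 vertices", call. = FALSE)
  }
  storage.mode(v) <- "double"
  v
}
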