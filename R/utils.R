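# small vector helpers used across the package

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

normalize3 <- function(v, what = "vector") {
  v <- as.numeric(v)
  if (length(v) != 3 || !all(is.finite(v))) {
    abort(sprintf("%s must be a finite 3-vector.", what))
  }
  n <- sqrt(sum(v^2))
  if (n < 1e-12) abort(sprintf("%s has (near-)zero length.", what))
  v / n
}

# Accepts a 3-column numeric matrix or a data frame with x_um/y_um/z_um
# (or x/y/z) columns; returns an n x 3 matrix.
as_xyz_matrix <- function(points) {
  if (is.matrix(points)) {
    if (ncol(points) != 3) abort("point matrix must have 3 columns.")
    return(unname(points))
  }
  if (is.data.frame(points)) {
    nms <- names(points)
    cols <- if (all(c("x_um", "y_um", "z_um") %in% nms)) {
      c("x_um", "y_um", "z_um")
    } else if (all(c("x", "y", "z") %in% nms)) {
      c("x", "y", "z")
    } else {
      abort("data frame must have columns x_um/y_um/z_um (or x/y/z).")
    }
    return(unname(as.matrix(points[cols])))
  }
  if (is.numeric(points) && length(points) == 3) return(matrix(points, 1, 3))
  abort("points must be a 3-column matrix, a data frame, or a 3-vector.")
}

# skew-symmetric matrix such that skew3(w) %*% x == cross3(w, x)
skew3 <- function(w) {
  matrix(c(0, w[3], -w[2],
           -w[3], 0, w[1],
           w[2], -w[1], 0), 3, 3)
}

# wrap angle to (-pi, pi]
wrap_pi <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  y[y <= -pi] <- pi
  y
}
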