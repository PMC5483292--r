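#' Planar affine transform parameters
#'
#' Six-parameter affine transform used for frame registration: translation
#' `tx`, `ty` (pixels), rotation `theta` (degrees), scale factors `sx`, `sy`
#' and `shear`. The identity is `(0, 0, 0, 1, 1, 0)`. The linear part is
#' composed as `R(theta) %*% diag(sx, sy) %*% [[1, shear], [0, 1]]` and acts
#' about the image center (pixel coordinates are 0-based, x = column,
#' y = row).
#'
#' @param tx,ty Translation in pixels.
#' @param theta Rotation in degrees.
#' @param sx,sy Scale factors; must be positive.
#' @param shear Shear coefficient.
#' @return An `affine_params` object.
#' @export
#' @examples
#' affine_matrix(affine_params())          # identity 2 x 3
#' affine_params(tx = 3, ty = -2, theta = 2)
affine_params <- function(tx = 0, ty = 0, theta = 0, sx = 1, sy = 1,
                          shear = 0) {
  stopifnot(sx > 0, sy > 0)
  structure(list(tx = tx, ty = ty, theta = theta, sx = sx, sy = sy,
                 shear = shear),
            class = "affine_params")
}

is_identity_affine <- function(p) {
  p$tx == 0 && p$ty == 0 && p$theta == 0 && p$sx == 1 && p$sy == 1 &&
    p$shear == 0
}

#' @export
print.affine_params <- function(x, ...) {
  cat(sprintf("affine: tx=%.3f ty=%.3f theta=%.3f deg sx=%.4f sy=%.4f shear=%.4f\n",
              x$tx, x$ty, x$theta, x$sx, x$sy, x$shear))
  invisible(x)
}

#' 2 x 3 matrix form of affine parameters
#'
#' @param params An [affine_params()] object.
#' @return Numeric 2 x 3 matrix `(A | t)` acting on centered pixel
#'   coordinates.
#' @export
affine_matrix <- function(params) {
  th <- params$theta * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  A <- R %*% matrix(c(params$sx, 0, params$sx * params$shear, params$sy), 2, 2)
  cbind(A, c(params$tx, params$ty))
}

# Decompose a 2x3 matrix back to (tx, ty, theta, sx, sy, shear).
# Valid when the linear part has positive determinant and positive scales
# (always the case for composed registration transforms).
affine_from_matrix <- function(M) {
  A <- M[, 1:2, drop = FALSE]
  theta <- atan2(A[2, 1], A[1, 1])
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  U <- t(R) %*% A                       # upper-triangular: diag(sx,sy) %*% shear
  sx <- U[1, 1]; sy <- U[2, 2]
  affine_params(tx = M[1, 3], ty = M[2, 3], theta = theta * 180 / pi,
                sx = sx, sy = sy, shear = U[1, 2] / sx)
}

#' Compose and invert affine parameters
#'
#' `affine_compose(p, q)` returns the parameters of the map `p` followed by
#' `q` in pull convention, i.e. applying `q` to a frame already warped by `p`
#' equals applying the composition once. `affine_invert(p)` returns the
#' parameters undoing `p`.
#'
#' @param p,q [affine_params()] objects.
#' @return An `affine_params` object.
#' @export
affine_compose <- function(p, q) {
  P <- rbind(affine_matrix(p), c(0, 0, 1))
  Q <- rbind(affine_matrix(q), c(0, 0, 1))
  affine_from_matrix((P %*% Q)[1:2, , drop = FALSE])
}

#' @rdname affine_compose
#' @export
affine_invert <- function(p) {
  M <- affine_matrix(p)
  A <- M[, 1:2, drop = FALSE]
  Ai <- solve(A)
  affine_from_matrix(cbind(Ai, -Ai %*% M[, 3]))
}

#' Warp a thermal frame by an affine transform
#'
#' Resamples the frame with bilinear interpolation about the image center
#' (pull convention: output pixel `x` takes the input value at `A x + t` in
#' centered coordinates). Out-of-domain pixels are set to `fill`. Identity
#' parameters return the input unchanged, bit for bit.
#'
#' @param frame Numeric matrix of temperatures (rows = y, cols = x).
#' @param params [affine_params()].
#' @param fill Fill temperature for out-of-domain pixels, degrees C.
#' @return Warped matrix of the same shape.
#' @export
apply_affine <- function(frame, params, fill = 27) {
  stopifnot(is.matrix(frame), inherits(params, "affine_params"))
  if (is_identity_affine(params)) return(frame)
  M <- affine_matrix(params)
  warp_affine_cpp(frame, c(M[1, 1], M[1, 2], M[2, 1], M[2, 2],
                           M[1, 3], M[2, 3]), fill)
}
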