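#' Rigid-body transform (6 parameters)
#'
#' A rotation about a centre followed by a translation, in physical (mm)
#' coordinates: `y = R (x - c) + c + t`. The rotation is composed as
#' `Rz(rz) Ry(ry) Rx(rx)` about the RAS axes with angles in degrees.
#'
#' @param rotations numeric length-3, rotation angles about the x, y, z axes
#'   in degrees.
#' @param translations numeric length-3, offsets in mm.
#' @param center numeric length-3, rotation centre in mm.
#' @return An object of class `rigid_transform`.
#' @examples
#' t <- rigid_transform(rotations = c(0, 0, 5), translations = c(2, 0, 0))
#' rt_compose(t, rt_invert(t))  # ~ identity
#' @export
rigid_transform <- function(rotations = c(0, 0, 0), translations = c(0, 0, 0),
                            center = c(0, 0, 0)) {
  rotations <- as.numeric(rotations); translations <- as.numeric(translations)
  center <- as.numeric(center)
  stopifnot(length(rotations) == 3, length(translations) == 3, length(center) == 3)
  if (any(!is.finite(c(rotations, translations, center))))
    stop("transform parameters must be finite", call. = FALSE)
  structure(list(rotations = rotations, translations = translations,
                 center = center), class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("<rigid_transform> rot (deg): %s | trans (mm): %s | centre: %s\n",
              paste(signif(x$rotations, 4), collapse = ", "),
              paste(signif(x$translations, 4), collapse = ", "),
              paste(signif(x$center, 4), collapse = ", ")))
  invisible(x)
}

rot_matrix <- function(deg) {
  r <- deg * pi / 180
  cx <- cos(r[1]); sx <- sin(r[1])
  cy <- cos(r[2]); sy <- sin(r[2])
  cz <- cos(r[3]); sz <- sin(r[3])
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3)
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3)
  Rz %*% Ry %*% Rx
}

#' @rdname rigid_transform
#' @param transform a `rigid_transform`.
#' @return `rt_matrix()` returns the 4x4 homogeneous matrix acting on mm
#'   coordinates.
#' @export
rt_matrix <- function(transform) {
  R <- rot_matrix(transform$rotations)
  d <- as.numeric(-R %*% transform$center + transform$center + transform$translations)
  M <- diag(4)
  M[1:3, 1:3] <- R
  M[1:3, 4] <- d
  M
}

# Recover angle/translation parameters from a rigid 4x4 matrix (ZYX Euler,
# valid away from ry = +/-90 deg, far beyond the rigid-offset regime here).
rigid_from_matrix <- function(M, center = c(0, 0, 0)) {
  R <- M[1:3, 1:3]
  ry <- asin(max(-1, min(1, -R[3, 1])))
  rx <- atan2(R[3, 2], R[3, 3])
  rz <- atan2(R[2, 1], R[1, 1])
  rot <- c(rx, ry, rz) * 180 / pi
  d <- M[1:3, 4]
  t <- as.numeric(d + R %*% center - center)
  rigid_transform(rot, t, center)
}

#' @rdname rigid_transform
#' @export
rt_invert <- function(transform) {
  rigid_from_matrix(solve(rt_matrix(transform)), transform$center)
}

#' @rdname rigid_transform
#' @param a,b `rigid_transform` objects; the composition maps `x` to
#'   `a(b(x))`.
#' @export
rt_compose <- function(a, b) {
  rigid_from_matrix(rt_matrix(a) %*% rt_matrix(b), a$center)
}

#' @rdname rigid_transform
#' @param point numeric length-3 or n-by-3 matrix of mm coordinates.
#' @export
rt_apply <- function(transform, point) {
  M <- rt_matrix(transform)
  p <- rbind(t(matrix(point, ncol = 3)), 1)
  out <- (M %*% p)[1:3, , drop = FALSE]
  if (is.null(dim(point)) || nrow(matrix(point, ncol = 3)) == 1) as.numeric(out) else t(out)
}

#' Serialize a rigid transform to/from JSON
#'
#' Angles are stored in degrees, translations and centre in mm, with a
#' convention string recording the rotation order.
#'
#' @param transform a [rigid_transform()].
#' @param path file path.
#' @export
write_transform <- function(transform, path) {
  jsonlite::write_json(list(rotations_deg = transform$rotations,
                            translations_mm = transform$translations,
                            center_mm = transform$center,
                            convention = "RzRyRx-about-center-then-translate"),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  rigid_transform(x$rotations_deg, x$translations_mm, x$center_mm)
}
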