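#' Scale-plus-translation map between the RGB and thermal frames
#'
#' The two cameras sit side by side in the same plane, so mapping RGB pixel
#' coordinates onto the thermal grid reduces to an axis-aligned affine
#' transform: independent scale factors plus a translation, no rotation or
#' shear. Parameters are rig-specific calibration inputs; [fit_map()]
#' estimates them from point correspondences.
#'
#' @param sx,sy unitless scale factors, > 0.
#' @param tx,ty pixel displacements.
#' @return An object of class `affine_map`.
#' @examples
#' m <- affine_map(0.4, 0.4, 0, 0)  # 640x480 RGB onto a 256x192 grid
#' apply_map(m, c(640, 480))
#' @export
affine_map <- function(sx, sy, tx = 0, ty = 0) {
  stopifnot(is.finite(sx), is.finite(sy), is.finite(tx), is.finite(ty))
  if (sx <= 0 || sy <= 0) stop("scale factors must be positive", call. = FALSE)
  structure(list(sx = as.numeric(sx), sy = as.numeric(sy),
                 tx = as.numeric(tx), ty = as.numeric(ty)),
            class = "affine_map")
}

#' @export
print.affine_map <- function(x, ...) {
  cat(sprintf("<affine_map: scale (%g, %g), shift (%g, %g)>\n",
              x$sx, x$sy, x$tx, x$ty))
  invisible(x)
}

#' Apply an affine map to a point
#' @param m an `affine_map`.
#' @param p numeric `c(x, y)`.
#' @return mapped `c(x, y)`: `(sx * x + tx, sy * y + ty)`.
#' @export
apply_map <- function(m, p) {
  c(m$sx * p[1] + m$tx, m$sy * p[2] + m$ty)
}

#' Invert an affine map
#' @param m an `affine_map`.
#' @return the inverse `affine_map`.
#' @export
invert_map <- function(m) {
  affine_map(1 / m$sx, 1 / m$sy, -m$tx / m$sx, -m$ty / m$sy)
}

#' Map a rectangle onto the thermal frame
#'
#' Both corners are mapped by [apply_map()]; axis alignment is preserved, so
#' parallel edges remain parallel. The result is clipped to the thermal
#' frame bounds.
#'
#' @param m an `affine_map`.
#' @param r numeric `c(x, y, w, h)` in RGB coordinates.
#' @param thermal_dim `c(w, h)` of the thermal frame (default `c(256, 192)`).
#' @return mapped `c(x, y, w, h)` with `attr(, "valid") = FALSE` when the
#'   mapped rectangle falls entirely outside the thermal frame.
#' @export
map_roi <- function(m, r, thermal_dim = c(256, 192)) {
  p0 <- apply_map(m, r[1:2])
  p1 <- apply_map(m, r[1:2] + r[3:4])
  mapped <- c(pmin(p0, p1), abs(p1 - p0))
  out <- clip_rect(mapped, thermal_dim)
  attr(out, "valid") <- out[3] > 0 && out[4] > 0
  out
}

#' Least-squares calibration of the two-camera map
#'
#' Estimates `(sx, sy, tx, ty)` from point correspondences
#' `(rgb_point, thermal_point)`. The x and y axes decouple, giving two
#' simple linear regressions; the fit is exact when the pairs come from a
#' true scale-plus-translation map.
#'
#' @param rgb_points,thermal_points N x 2 matrices (or lists of `c(x, y)`),
#'   N >= 2, matching rows.
#' @return an `affine_map`.
#' @export
fit_map <- function(rgb_points, thermal_points) {
  to_mat <- function(p) if (is.matrix(p)) p else do.call(rbind, p)
  a <- to_mat(rgb_points); b <- to_mat(thermal_points)
  if (nrow(a) < 2 || !all(dim(a) == dim(b)))
    stop("need >= 2 matching point pairs", call. = FALSE)
  fit_axis <- function(x, y) {
    if (stats::var(x) < 1e-12)
      stop("points are collinear along one axis; map is underdetermined",
           call. = FALSE)
    cf <- stats::coef(stats::lm.fit(cbind(1, x), y))
    c(scale = unname(cf[2]), shift = unname(cf[1]))
  }
  fx <- fit_axis(a[, 1], b[, 1])
  fy <- fit_axis(a[, 2], b[, 2])
  affine_map(fx["scale"], fy["scale"], fx["shift"], fy["shift"])
}
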