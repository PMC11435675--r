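#' Pinhole camera intrinsics
#'
#' @param F focal length in pixels.
#' @param cx,cy principal point, pixels.
#' @param width,height image size in pixels (used for in-frame checks;
#'   optional). Defaults emulate a typical smartphone main camera.
#' @return An object of class \code{camera_intrinsics}.
#' @export
camera_intrinsics <- function(F = 3000, cx = 2000, cy = 1500,
                              width = 4000, height = 3000) {
  if (!is.finite(F) || F <= 0) stop("focal length F must be positive")
  stopifnot(is.finite(cx), is.finite(cy))
  structure(list(F = F, cx = cx, cy = cy, width = width, height = height),
            class = "camera_intrinsics")
}

#' Camera pose (extrinsics)
#'
#' World-to-camera rigid transform \eqn{p' = R p + t}. The rotation is
#' parameterized by Euler angles in degrees using the intrinsic Z-Y-X
#' convention: \code{psi} about z, then \code{theta} about the new y,
#' then \code{phi} about the new x, i.e.
#' \code{R = Rz(psi) Ry(theta) Rx(phi)}. The camera looks along its +z
#' axis; pixel u grows rightwards and v downwards.
#'
#' @param phi,theta,psi Euler angles, degrees.
#' @param t translation vector (X, Y, Z) in mm.
#' @return An object of class \code{camera_pose}.
#' @export
camera_pose <- function(phi = 0, theta = 0, psi = 0, t = c(0, 0, 300)) {
  stopifnot(is.finite(phi), is.finite(theta), is.finite(psi),
            length(t) == 3L, all(is.finite(t)))
  structure(list(phi = phi, theta = theta, psi = psi, t = as.numeric(t)),
            class = "camera_pose")
}

#' Rotation matrix from Euler angles
#'
#' Intrinsic Z-Y-X convention, angles in degrees:
#' \code{R = Rz(psi) Ry(theta) Rx(phi)}.
#'
#' @param phi,theta,psi angles in degrees.
#' @return 3x3 orthonormal rotation matrix with determinant +1.
#' @export
rotation_from_euler <- function(phi, theta, psi) {
  a <- phi * pi / 180; b <- theta * pi / 180; c <- psi * pi / 180
  Rx <- rbind(c(1, 0, 0), c(0, cos(a), -sin(a)), c(0, sin(a), cos(a)))
  Ry <- rbind(c(cos(b), 0, sin(b)), c(0, 1, 0), c(-sin(b), 0, cos(b)))
  Rz <- rbind(c(cos(c), -sin(c), 0), c(sin(c), cos(c), 0), c(0, 0, 1))
  Rz %*% Ry %*% Rx
}

#' Project 3D points through a pinhole camera
#'
#' Applies the rigid transform \eqn{p' = R p + t} followed by the pinhole
#' projection \eqn{(F x'/z' + c_x,\ F y'/z' + c_y)}. Input order is
#' preserved.
#'
#' @param intr a [camera_intrinsics].
#' @param pose a [camera_pose].
#' @param pts N x 3 matrix of world points, mm (a length-3 vector is
#'   treated as one point).
#' @return N x 2 matrix of pixel coordinates (columns \code{u}, \code{v}).
#' @export
project_points <- function(intr, pose, pts) {
  stopifnot(inherits(intr, "camera_intrinsics"), inherits(pose, "camera_pose"))
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 3L)
  R <- rotation_from_euler(pose$phi, pose$theta, pose$psi)
  pc <- pts %*% t(R) + matrix(pose$t, nrow(pts), 3L, byrow = TRUE)
  bad <- which(pc[, 3L] <= 0)
  if (length(bad))
    stop(sprintf("point(s) %s behind the camera (z' <= 0)",
                 paste(utils::head(bad, 5L), collapse = ", ")),
         call. = FALSE)
  cbind(u = intr$F * pc[, 1L] / pc[, 3L] + intr$cx,
        v = intr$F * pc[, 2L] / pc[, 3L] + intr$cy)
}

## camera-frame coordinates without projecting (internal)
transform_points <- function(pose, pts) {
  R <- rotation_from_euler(pose$phi, pose$theta, pose$psi)
  pts %*% t(R) + matrix(pose$t, nrow(pts), 3L, byrow = TRUE)
}

## JSON glue -----------------------------------------------------------------

#' Read / write camera intrinsics and poses as JSON
#'
#' Intrinsics: \code{{"F_px","cx_px","cy_px","width","height"}}.
#' Pose: \code{{"phi_deg","theta_deg","psi_deg","t_mm":[X,Y,Z]}}.
#'
#' @param intr a [camera_intrinsics].
#' @param pose a [camera_pose].
#' @param path file path.
#' @export
write_intrinsics_json <- function(intr, path) {
  jsonlite::write_json(list(F_px = intr$F, cx_px = intr$cx, cy_px = intr$cy,
                            width = intr$width, height = intr$height),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_intrinsics_json
#' @export
read_intrinsics_json <- function(path) {
  x <- jsonlite::read_json(path)
  camera_intrinsics(F = x$F_px, cx = x$cx_px, cy = x$cy_px,
                    width = x$width %||% NA_real_,
                    height = x$height %||% NA_real_)
}

#' @rdname write_intrinsics_json
#' @export
write_pose_json <- function(pose, path) {
  jsonlite::write_json(list(phi_deg = pose$phi, theta_deg = pose$theta,
                            psi_deg = pose$psi, t_mm = pose$t),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_intrinsics_json
#' @export
read_pose_json <- function(path) {
  x <- jsonlite::read_json(path)
  camera_pose(phi = x$phi_deg, theta = x$theta_deg, psi = x$psi_deg,
              t = unlist(x$t_mm))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
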