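#' Paper-ruler (tape) specification
#'
#' Describes the adhesive paper ruler laid centrally across the bowl
#' interior. In simulation the tape is 5 mm wide and its length (the
#' bowl's rim-to-rim arc length) is divided into 20 equal segments; the
#' physical tape used for real photographs is 0.94 in (23.876 mm) wide
#' with divisions labeled every 0.5 in (12.7 mm).
#'
#' @param width tape width, mm.
#' @param n_segments number of equal segments the tape length is divided
#'   into (simulation); gives \code{n_segments + 1} division points
#'   including both rim ends.
#' @param division_spacing spacing between labeled divisions, mm (real
#'   tape); \code{NULL} in simulation where the spacing is L/n_segments.
#' @return An object of class \code{tape_spec}.
#' @export
tape_spec <- function(width = 5, n_segments = 20L, division_spacing = NULL) {
  if (!is.finite(width) || width <= 0) stop("tape width must be positive")
  n_segments <- as.integer(n_segments)
  if (n_segments < 2L) stop("n_segments must be at least 2")
  if (!is.null(division_spacing) && division_spacing <= 0)
    stop("division_spacing must be positive")
  structure(list(width = width, n_segments = n_segments,
                 division_spacing = division_spacing),
            class = "tape_spec")
}

#' Division points along the central curve
#'
#' Divides the bowl's meridian arc length L into \code{n_segments} equal
#' segments and returns the \code{n_segments + 1} division points
#' (including both rim ends) by numerical arc-length inversion.
#'
#' @param bowl a [bowl_model].
#' @param n_segments number of segments (>= 2).
#' @param resolution arc-table resolution (see [build_arc_table()]).
#' @return List with \code{s} (arc positions k L / n), \code{points}
#'   (matrix of 3D points on the x = 0 meridian), and \code{L}.
#' @export
division_points <- function(bowl, n_segments = 20L, resolution = 10000L) {
  tab <- build_arc_table(bowl, resolution)
  s <- seq(0, tab$L, length.out = as.integer(n_segments) + 1L)
  list(s = s, points = arc_point(tab, s), L = tab$L)
}

## Offsets a set of division points (on the x = 0 meridian) sideways by half
## the tape width to produce the two tape-edge landmark rows. Points far
## enough from the axis are rotated +-alpha about z along their latitude
## circle, alpha = (w/2)/r, so the arc separation of a pair equals the tape
## width. Near the bottom (alpha > 0.3 rad) latitude circles are tiny and
## nearly coplanar; there the pair is offset +-w/2 along x and re-projected
## onto the surface.
offset_pairs <- function(bowl, div_pts, width, alpha_max = 0.3) {
  y <- div_pts[, "y"]
  r <- abs(y)
  hw <- width / 2
  n <- length(y)
  upper <- matrix(0, n, 3L); lower <- matrix(0, n, 3L)
  alpha <- ifelse(r > 0, hw / r, Inf)
  circ <- alpha <= alpha_max
  if (any(circ)) {
    beta <- ifelse(y[circ] >= 0, pi / 2, -pi / 2)
    rc <- r[circ]; zc <- div_pts[circ, "z"]
    upper[circ, ] <- cbind(rc * cos(beta + alpha[circ]),
                           rc * sin(beta + alpha[circ]), zc)
    lower[circ, ] <- cbind(rc * cos(beta - alpha[circ]),
                           rc * sin(beta - alpha[circ]), zc)
  }
  if (any(!circ)) {
    yb <- y[!circ]
    zb <- (sqrt(yb^2 + hw^2) / bowl$R)^bowl$q * bowl$H
    upper[!circ, ] <- cbind(rep(hw, sum(!circ)), yb, zb)
    lower[!circ, ] <- cbind(rep(-hw, sum(!circ)), yb, zb)
  }
  list(upper = upper, lower = lower, fallback = !circ)
}

#' 3D landmark pairs of the virtual ruler
#'
#' Places the virtual paper ruler centrally across the bowl and computes
#' the paired 3D landmarks where each division meets the tape's two
#' edges. Each pair is centered on a division point of the central curve
#' and separated by the tape width measured as arc length along the
#' latitude circle through that point; near the bottom, where latitude
#' circles degenerate, pairs are offset by half the width in the
#' horizontal normal direction and re-projected onto the surface.
#'
#' @param bowl a [bowl_model].
#' @param tape a [tape_spec].
#' @param resolution arc-table resolution.
#' @return An object of class \code{landmark_set_3d}: list with
#'   \code{points} (N x 3 matrix, first N/2 rows one tape edge, next N/2
#'   the partner edge, row i pairing with row N/2 + i),
#'   \code{arc_positions} (s-value of each division, length N/2),
#'   \code{L}, \code{fallback} (logical per pair) and \code{bowl}.
#' @export
landmark_pairs <- function(bowl, tape = tape_spec(), resolution = 10000L) {
  stopifnot(inherits(bowl, "bowl_model"), inherits(tape, "tape_spec"))
  dv <- division_points(bowl, tape$n_segments, resolution)
  off <- offset_pairs(bowl, dv$points, tape$width)
  structure(list(points = rbind(off$upper, off$lower),
                 arc_positions = dv$s, L = dv$L,
                 fallback = off$fallback, bowl = bowl),
            class = "landmark_set_3d")
}

#' Simulate a 2D landmark observation
#'
#' Projects the virtual ruler's 3D landmark pairs through an ideal
#' pinhole camera, preserving the pairing order, and optionally adds
#' isotropic Gaussian pixel noise.
#'
#' @param bowl a [bowl_model].
#' @param tape a [tape_spec].
#' @param intr a [camera_intrinsics].
#' @param pose a [camera_pose].
#' @param noise_sd pixel noise standard deviation (default 0: exact
#'   projections).
#' @param seed optional integer seed for the noise.
#' @return An object of class \code{landmark_set_2d}: list with
#'   \code{points} (N x 2 pixel matrix, same pairing convention as the 3D
#'   set), \code{arc_positions}, \code{L_gt} (the true tape length) and
#'   \code{provenance = "simulated"}.
#' @export
simulate_observation <- function(bowl, tape, intr, pose,
                                 noise_sd = 0, seed = NULL) {
  lm3 <- landmark_pairs(bowl, tape)
  px <- project_points(intr, pose, lm3$points)
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    px <- px + matrix(stats::rnorm(length(px), sd = noise_sd), nrow(px), 2L)
  }
  structure(list(points = px, arc_positions = lm3$arc_positions,
                 L_gt = lm3$L, provenance = "simulated"),
            class = "landmark_set_2d")
}

#' Parameter ranges for random scenarios
#'
#' Uniform sampling ranges for the bowl parameters and camera extrinsics
#' used in the simulation study. Defaults: R in \[30, 130\] mm, H in
#' \[9, 130\] mm, q in \[2, 10\], X and Y in \[-400, 400\] mm, Z in
#' \[180, 500\] mm, theta in \[30, 90\] deg, phi and psi in
#' \[-60, 60\] deg.
#'
#' @param R,H,q,X,Y,Z,theta,phi,psi length-2 numeric ranges.
#' @return An object of class \code{scenario_ranges}.
#' @export
scenario_ranges <- function(R = c(30, 130), H = c(9, 130), q = c(2, 10),
                            X = c(-400, 400), Y = c(-400, 400),
                            Z = c(180, 500), theta = c(30, 90),
                            phi = c(-60, 60), psi = c(-60, 60)) {
  rng <- list(R = R, H = H, q = q, X = X, Y = Y, Z = Z,
              theta = theta, phi = phi, psi = psi)
  ok <- vapply(rng, function(v) length(v) == 2L && all(is.finite(v)) &&
                 v[1] <= v[2], logical(1))
  if (!all(ok)) stop("each range must be a finite length-2 increasing vector")
  structure(rng, class = "scenario_ranges")
}

runif_range <- function(rng) stats::runif(1, rng[1], rng[2])

## All landmarks projectable and inside the frame plus a relative margin?
scenario_visible <- function(bowl, tape, intr, pose, margin = 0.05) {
  lm3 <- landmark_pairs(bowl, tape, resolution = 2000L)
  pc <- transform_points(pose, lm3$points)
  if (any(pc[, 3L] <= 0)) return(FALSE)
  u <- intr$F * pc[, 1L] / pc[, 3L] + intr$cx
  v <- intr$F * pc[, 2L] / pc[, 3L] + intr$cy
  mw <- margin * intr$width; mh <- margin * intr$height
  all(u >= -mw, u <= intr$width + mw, v >= -mh, v <= intr$height + mh)
}

#' Draw a random bowl-and-camera scenario
#'
#' Draws each bowl parameter and camera extrinsic independently and
#' uniformly from its range, rejecting scenarios in which any ruler
#' landmark falls behind the camera or outside the image frame (plus a
#' 5\% margin) — mirroring that study photographs always contain the
#' whole ruler.
#'
#' @param ranges a [scenario_ranges].
#' @param tape a [tape_spec].
#' @param intr a [camera_intrinsics].
#' @param seed optional integer seed.
#' @param bowl optional fixed [bowl_model]; if supplied only the camera
#'   pose is drawn (the five-bowl study fixes the bowls and randomizes
#'   cameras).
#' @param max_reject maximum consecutive rejections before erroring.
#' @return List with elements \code{bowl} and \code{pose}.
#' @export
random_scenario <- function(ranges = scenario_ranges(), tape = tape_spec(),
                            intr = camera_intrinsics(), seed = NULL,
                            bowl = NULL, max_reject = 1000L) {
  if (!is.null(seed)) set.seed(seed)
  for (i in seq_len(max_reject)) {
    b <- if (is.null(bowl)) {
      bowl_model(R = runif_range(ranges$R), H = runif_range(ranges$H),
                 q = runif_range(ranges$q))
    } else bowl
    pose <- camera_pose(phi = runif_range(ranges$phi),
                        theta = runif_range(ranges$theta),
                        psi = runif_range(ranges$psi),
                        t = c(runif_range(ranges$X), runif_range(ranges$Y),
                              runif_range(ranges$Z)))
    if (scenario_visible(b, tape, intr, pose))
      return(list(bowl = b, pose = pose))
  }
  stop(sprintf(paste("no visible scenario found in %d draws;",
                     "consider widening Z or narrowing X/Y ranges"),
               max_reject))
}

## Landmark CSV I/O ----------------------------------------------------------

#' Read / write a 2D landmark set as CSV
#'
#' Columns: \code{index, edge (u|l), pair_id, x_px, y_px}. Arc positions
#' and tape length travel in a sidecar JSON written next to the CSV when
#' available.
#'
#' @param obs a \code{landmark_set_2d}.
#' @param path CSV file path.
#' @export
write_landmarks_csv <- function(obs, path) {
  stopifnot(inherits(obs, "landmark_set_2d"))
  n2 <- nrow(obs$points) / 2L
  df <- data.frame(index = seq_len(2L * n2),
                   edge = rep(c("u", "l"), each = n2),
                   pair_id = rep(seq_len(n2), 2L),
                   x_px = obs$points[, 1L], y_px = obs$points[, 2L])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  meta <- list(provenance = obs$provenance, L_gt = obs$L_gt,
               arc_positions = obs$arc_positions)
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_landmarks_csv
#' @export
read_landmarks_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("index", "edge", "pair_id", "x_px", "y_px")
  if (!all(need %in% names(df)))
    stop("landmark CSV must have columns ", paste(need, collapse = ", "))
  df <- df[order(match(df$edge, c("u", "l")), df$pair_id), ]
  nu <- sum(df$edge == "u"); nl <- sum(df$edge == "l")
  if (nu != nl) stop("unequal landmark counts on the two tape edges")
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path,
                                                          simplifyVector = TRUE)
          else list(provenance = "labeled", L_gt = NULL, arc_positions = NULL)
  structure(list(points = cbind(u = df$x_px, v = df$y_px),
                 arc_positions = meta$arc_positions,
                 L_gt = meta$L_gt, provenance = meta$provenance),
            class = "landmark_set_2d")
}
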