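#' Hand-labeled ruler landmarks
#'
#' Container for manually clicked landmark points along the two edges of
#' the paper ruler in a real photograph, labeled at every printed
#' division (0.5 in apart on the physical tape). The rim-end pairs must
#' be labeled; no extrapolation is performed downstream.
#'
#' @param upper,lower n x 2 matrices of pixel coordinates, one row per
#'   labeled division, in tape order; row i of \code{upper} pairs with
#'   row i of \code{lower}. Sub-pixel coordinates are allowed.
#' @param division_spacing spacing between labeled divisions on the
#'   physical tape, mm (default 12.7 mm = 0.5 in).
#' @param tape_width physical tape width, mm (default 0.94 in).
#' @param image_size optional (width, height) in pixels.
#' @return An object of class \code{labeled_landmarks}.
#' @export
labeled_landmarks <- function(upper, lower, division_spacing = 12.7,
                              tape_width = 23.876, image_size = NULL) {
  upper <- as.matrix(upper); lower <- as.matrix(lower)
  if (ncol(upper) != 2L || ncol(lower) != 2L)
    stop("edge point matrices must have two columns (pixels)")
  if (nrow(upper) != nrow(lower))
    stop("the two tape edges must have equal landmark counts")
  if (nrow(upper) < 4L) stop("need at least 4 labeled pairs")
  if (any(!is.finite(upper)) || any(!is.finite(lower)))
    stop("landmark coordinates must be finite")
  if (any(rowSums(diff(upper)^2) == 0) || any(rowSums(diff(lower)^2) == 0))
    stop("consecutive landmarks coincide; each edge must be a simple polyline")
  structure(list(upper = upper, lower = lower,
                 division_spacing = division_spacing,
                 tape_width = tape_width, image_size = image_size),
            class = "labeled_landmarks")
}

## Linear interpolation of 2D points along a polyline at arc coordinates s.
polyline_point <- function(pts, cumlen, s) {
  cbind(stats::approx(cumlen, pts[, 1L], xout = s, rule = 2)$y,
        stats::approx(cumlen, pts[, 2L], xout = s, rule = 2)$y)
}

#' Filter and upsample labeled ruler landmarks
#'
#' Turns hand-labeled division marks into a denser, smoother 2D landmark
#' set in three steps:
#' \enumerate{
#'   \item \emph{vertical filter}: each labeled pair is replaced by its
#'     midpoint (plus the half-width offset vector, kept aside);
#'   \item \emph{horizontal filter}: each interior midpoint is
#'     repositioned along the midpoint polyline so that its distances to
#'     the two neighbors become their average
#'     \eqn{h = (\|OA\| + \|OB\|)/2}; bordering points are left alone;
#'   \item \emph{upsampling}: each edge polyline is re-interpolated at
#'     \code{factor} times the original division density through the
#'     filtered points (piecewise cubic by default), keeping the
#'     endpoints.
#' }
#' The published procedure is shown by example rather than stated in
#' full; this three-step decomposition is one faithful reading and each
#' step is configurable.
#'
#' @param labels a [labeled_landmarks].
#' @param factor upsampling factor (default 4).
#' @param passes horizontal-filter passes (default 1).
#' @param interpolation \code{"cubic"} (natural spline) or
#'   \code{"linear"}.
#' @return A \code{landmark_set_2d} whose \code{arc_positions} are the
#'   tape positions of the output pairs (mm) and whose \code{L_gt} is the
#'   labeled tape length \code{(n - 1) * division_spacing}; also carries
#'   a \code{qc} data frame of neighbor spacings before/after filtering.
#' @export
filter_and_upsample <- function(labels, factor = 4L, passes = 1L,
                                interpolation = c("cubic", "linear")) {
  stopifnot(inherits(labels, "labeled_landmarks"))
  interpolation <- match.arg(interpolation)
  factor <- as.integer(factor)
  if (factor < 1L) stop("upsampling factor must be >= 1")
  n <- nrow(labels$upper)

  mid <- (labels$upper + labels$lower) / 2
  off <- (labels$upper - labels$lower) / 2

  seglen <- sqrt(rowSums(diff(mid)^2))
  cum0 <- c(0, cumsum(seglen))
  spacing_before <- seglen

  ## horizontal filter: move interior points to the mean arc position of
  ## their neighbors (equivalent to pairwise-averaging the two adjacent
  ## spacings), re-reading positions and half-width offsets off the
  ## original polylines
  cum <- cum0
  for (p in seq_len(passes)) {
    if (n > 2L)
      cum[2:(n - 1L)] <- (cum[1:(n - 2L)] + cum[3:n]) / 2
  }
  mid_f <- polyline_point(mid, cum0, cum)
  off_f <- polyline_point(off, cum0, cum)
  spacing_after <- sqrt(rowSums(diff(mid_f)^2))

  upper_f <- mid_f + off_f
  lower_f <- mid_f - off_f

  ## upsample each edge through the filtered points; parameterize by the
  ## division index so output pairs sit at regular tape positions
  idx <- seq_len(n)
  m_out <- (n - 1L) * factor + 1L
  idx_out <- seq(1, n, length.out = m_out)
  interp1 <- function(v) {
    if (interpolation == "cubic")
      stats::splinefun(idx, v, method = "natural")(idx_out)
    else stats::approx(idx, v, xout = idx_out)$y
  }
  up_out <- cbind(interp1(upper_f[, 1L]), interp1(upper_f[, 2L]))
  lo_out <- cbind(interp1(lower_f[, 1L]), interp1(lower_f[, 2L]))

  s_out <- (idx_out - 1) * labels$division_spacing
  structure(list(points = rbind(up_out, lo_out),
                 arc_positions = s_out,
                 L_gt = (n - 1) * labels$division_spacing,
                 provenance = "labeled",
                 qc = data.frame(
                   interval = seq_len(n - 1L),
                   spacing_before_px = spacing_before,
                   spacing_after_px = spacing_after)),
            class = "landmark_set_2d")
}

#' Read hand-labeled landmarks from CSV + labeling JSON
#'
#' The CSV uses the simulator's landmark dialect
#' (\code{index, edge (u|l), pair_id, x_px, y_px}); the JSON carries the
#' tape metadata:
#' \code{{"division_spacing_mm", "tape_width_mm", "image_size"}}.
#'
#' @param csv_path landmark CSV path.
#' @param json_path labeling-metadata JSON path.
#' @return A [labeled_landmarks].
#' @export
read_labeled_landmarks <- function(csv_path, json_path) {
  df <- utils::read.csv(csv_path, stringsAsFactors = FALSE)
  meta <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  u <- df[df$edge == "u", ]; l <- df[df$edge == "l", ]
  u <- u[order(u$pair_id), ]; l <- l[order(l$pair_id), ]
  labeled_landmarks(upper = cbind(u$x_px, u$y_px),
                    lower = cbind(l$x_px, l$y_px),
                    division_spacing = meta$division_spacing_mm %||% 12.7,
                    tape_width = meta$tape_width_mm %||% 23.876,
                    image_size = meta$image_size)
}
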