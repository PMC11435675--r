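#' Parametric bowl model
#'
#' A circular dining bowl is modeled as a surface of revolution whose
#' interior profile is the power function
#' \deqn{z = f(y) = (y/R)^q \, H, \qquad 0 \le y \le R,\ q > 1,}
#' where \code{R} is the rim radius (mm), \code{H} the bowl height (mm)
#' and \code{q} a dimensionless shape exponent. The constraint
#' \code{q > 1} makes the profile slope vanish at the bottom, so the bowl
#' rests flat on the tabletop. Larger \code{q} gives a flatter bottom and
#' steeper walls (a "plumper" bowl, closer to a cylinder); as \code{q}
#' approaches 1 the bowl degenerates towards a cone.
#'
#' @param R rim radius in mm, positive.
#' @param H bowl height in mm, positive.
#' @param q shape exponent, strictly greater than 1.
#' @return An object of class \code{bowl_model}: a list with elements
#'   \code{R}, \code{H}, \code{q}.
#' @examples
#' b <- bowl_model(R = 55, H = 44, q = 5.2)
#' bowl_volume(b)   # cm^3
#' @export
bowl_model <- function(R, H, q) {
  stopifnot(is.numeric(R), is.numeric(H), is.numeric(q),
            length(R) == 1L, length(H) == 1L, length(q) == 1L)
  if (!is.finite(R) || R <= 0) stop("bowl radius R must be positive")
  if (!is.finite(H) || H <= 0) stop("bowl height H must be positive")
  if (!is.finite(q) || q <= 1) stop("shape exponent q must be > 1")
  structure(list(R = R, H = H, q = q), class = "bowl_model")
}

#' @export
print.bowl_model <- function(x, ...) {
  cat(sprintf("Bowl model: R = %.3g mm, H = %.3g mm, q = %.3g (V = %.4g cm^3)\n",
              x$R, x$H, x$q, bowl_volume(x)))
  invisible(x)
}

#' Height of the bowl profile at a radial distance
#'
#' Evaluates \eqn{f(y) = (y/R)^q H} on \eqn{0 \le y \le R}.
#'
#' @param bowl a [bowl_model].
#' @param y radial distance(s) from the axis, mm; must lie in \code{[0, R]}.
#' @return Height(s) above the bottom, mm.
#' @export
profile_height <- function(bowl, y) {
  stopifnot(inherits(bowl, "bowl_model"))
  if (any(!is.finite(y)) || any(y < 0) || any(y > bowl$R))
    stop("radial distance y must lie within [0, R]")
  (y / bowl$R)^bowl$q * bowl$H
}

## df/dy = q y^(q-1) H / R^q; finite and 0 at y = 0 for q > 1
profile_slope <- function(bowl, y) {
  bowl$q * y^(bowl$q - 1) * bowl$H / bowl$R^bowl$q
}

#' Plumpness of a power-law bowl
#'
#' Plumpness is the ratio of the bowl's volume to that of the cylinder
#' with the same radius and height. For the power-law profile it has the
#' closed form \eqn{p = q/(q+2)}, bounded in the open interval
#' (1/3, 1): the lower limit corresponds to a cone-like bowl
#' (\eqn{q \to 1}) and the upper to a cylinder (\eqn{q \to \infty}).
#'
#' @param q shape exponent(s), > 1.
#' @return Plumpness value(s) in (1/3, 1).
#' @seealso [q_from_plumpness()] for the inverse.
#' @export
plumpness <- function(q) {
  if (any(!is.finite(q)) || any(q <= 1))
    stop("shape exponent q must be > 1")
  q / (q + 2)
}

#' Shape exponent from plumpness
#'
#' Inverts \eqn{p = q/(q+2)} to \eqn{q = 2p/(1-p)}.
#'
#' @param p plumpness value(s), strictly between 1/3 and 1.
#' @return Shape exponent(s) q > 1.
#' @export
q_from_plumpness <- function(p) {
  if (any(!is.finite(p)) || any(p <= 1 / 3) || any(p >= 1))
    stop("plumpness must lie strictly between 1/3 (cone limit) and 1 (cylinder limit)")
  2 * p / (1 - p)
}

#' Bowl volume
#'
#' Closed-form interior volume of the power-law bowl,
#' \eqn{V = \frac{q}{q+2}\pi H R^2}, reported in cm^3 (geometry is in mm).
#'
#' @param bowl a [bowl_model].
#' @return Volume in cm^3.
#' @export
bowl_volume <- function(bowl) {
  stopifnot(inherits(bowl, "bowl_model"))
  bowl$q / (bowl$q + 2) * pi * bowl$H * bowl$R^2 / 1000
}

#' Shape exponent from hand measurements
#'
#' Given a bowl's measured volume, height and rim radius, computes the
#' plumpness \eqn{p = V / (\pi R^2 H)} (consistent units) and inverts it
#' to the shape exponent \eqn{q = 2p/(1-p)}. This is how ground-truth
#' \code{q} is obtained for a physical bowl whose volume was measured by
#' water filling.
#'
#' @param V measured volume, cm^3.
#' @param H measured height, mm.
#' @param R measured rim radius, mm.
#' @return Shape exponent q.
#' @export
q_from_measurements <- function(V, H, R) {
  stopifnot(is.numeric(V), is.numeric(H), is.numeric(R))
  if (any(V <= 0) || any(H <= 0) || any(R <= 0))
    stop("V, H and R must be positive")
  v_mm3 <- V * 1000
  cyl <- pi * R^2 * H
  if (any(v_mm3 >= cyl))
    stop("measured volume exceeds the cylinder bound pi*R^2*H: ",
         "no power-law bowl is that plump")
  if (any(v_mm3 <= cyl / 3))
    stop("measured volume is below the cone bound pi*R^2*H/3: ",
         "no power-law bowl is that thin")
  q_from_plumpness(v_mm3 / cyl)
}

arc_integrand <- function(bowl, y) sqrt(1 + profile_slope(bowl, y)^2)

#' Length of the central cross-section curve
#'
#' Total arc length of the bowl's interior meridian from rim to rim,
#' \deqn{L = 2\int_0^R \sqrt{1 + f'(y)^2}\, dy,}
#' the length of paper ruler needed to span the bowl through its bottom.
#' The integral has no closed form and is evaluated by adaptive
#' quadrature (relative tolerance 1e-8).
#'
#' @param bowl a [bowl_model].
#' @return Arc length in mm.
#' @export
arc_length <- function(bowl) {
  stopifnot(inherits(bowl, "bowl_model"))
  half <- stats::integrate(function(y) arc_integrand(bowl, y),
                           lower = 0, upper = bowl$R,
                           rel.tol = 1e-8, subdivisions = 500L)
  2 * half$value
}

#' Arc-length table for the central curve
#'
#' Tabulates the meridian of the bowl in the plane x = 0 against the arc
#' coordinate \code{s} measured from one rim end: \code{s = 0} at the rim
#' point (0, -R, H), \code{s = L/2} at the bottom (origin) and
#' \code{s = L} at the opposite rim. Used to invert arc positions (where
#' a ruler division sits along the tape) into 3D points on the surface.
#'
#' @param bowl a [bowl_model].
#' @param resolution number of samples per half-curve (>= 1000).
#' @param method inversion interpolant: \code{"monotone"} (monotone
#'   piecewise-cubic, default) or \code{"linear"} (cheaper; used inside
#'   the estimator's inner loop, where the table is rebuilt for every
#'   candidate bowl and the linear error is far below the table step).
#' @return An object of class \code{arc_table}: list with \code{s}
#'   (strictly increasing arc positions, mm), \code{y} (signed radial
#'   coordinate, -R..R), \code{z} (heights), \code{L} (total length) and
#'   an interpolation function \code{y_of_s}.
#' @export
build_arc_table <- function(bowl, resolution = 10000L,
                            method = c("monotone", "linear")) {
  stopifnot(inherits(bowl, "bowl_model"))
  method <- match.arg(method)
  resolution <- as.integer(resolution)
  if (resolution < 1000L) stop("resolution must be at least 1000 samples")
  yg <- seq(0, bowl$R, length.out = resolution + 1L)
  g <- arc_integrand(bowl, yg)
  ## cumulative trapezoid from the bottom outwards
  ds <- diff(yg) * (g[-1L] + g[-length(g)]) / 2
  s_half <- c(0, cumsum(ds))
  L <- 2 * s_half[length(s_half)]
  ## full curve: y from -R to R, s from 0 to L
  s_full <- c(L / 2 - rev(s_half), L / 2 + s_half[-1L])
  y_full <- c(-rev(yg), yg[-1L])
  z_full <- (abs(y_full) / bowl$R)^bowl$q * bowl$H
  y_of_s <- if (method == "monotone") {
    stats::splinefun(s_full, y_full, method = "monoH.FC")
  } else {
    function(s) stats::approx(s_full, y_full, xout = s, rule = 2)$y
  }
  structure(list(s = s_full, y = y_full, z = z_full, L = L,
                 y_of_s = y_of_s, bowl = bowl),
            class = "arc_table")
}

#' Points on the central curve at given arc positions
#'
#' @param table an [build_arc_table()] result.
#' @param s arc positions in \code{[0, L]}, mm.
#' @return N x 3 matrix of 3D points (x = 0 plane), mm.
#' @export
arc_point <- function(table, s) {
  stopifnot(inherits(table, "arc_table"))
  if (any(s < -1e-9) || any(s > table$L + 1e-9))
    stop("arc position outside [0, L]")
  s <- pmin(pmax(s, 0), table$L)
  y <- table$y_of_s(s)
  y <- pmin(pmax(y, -table$bowl$R), table$bowl$R)
  cbind(x = 0, y = y, z = (abs(y) / table$bowl$R)^table$bowl$q * table$bowl$H)
}

## JSON (de)serialization of bowl parameters ---------------------------------

#' Read / write bowl parameters as JSON
#'
#' The on-disk form is \code{{"R_mm": ..., "H_mm": ..., "q": ...}}.
#'
#' @param bowl a [bowl_model].
#' @param path file path.
#' @return \code{write_bowl_json} returns \code{path} invisibly;
#'   \code{read_bowl_json} returns a [bowl_model].
#' @export
write_bowl_json <- function(bowl, path) {
  stopifnot(inherits(bowl, "bowl_model"))
  jsonlite::write_json(list(R_mm = bowl$R, H_mm = bowl$H, q = bowl$q),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_bowl_json
#' @export
read_bowl_json <- function(path) {
  x <- jsonlite::read_json(path)
  bowl_model(R = x$R_mm, H = x$H_mm, q = x$q)
}
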