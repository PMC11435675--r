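#' Read a 3D point cloud
#'
#' Supports ASCII PLY (header parsed for the vertex element and x/y/z
#' property order), whitespace-separated XYZ, and CSV with x/y/z
#' columns. Binary PLY is not supported; convert to ASCII first.
#'
#' @param path file path (.ply, .xyz, .csv, or .txt).
#' @return N x 3 numeric matrix of coordinates.
#' @export
read_point_cloud <- function(path) {
  first <- readLines(path, n = 1L, warn = FALSE)
  if (identical(trimws(first), "ply")) return(read_ply_ascii(path))
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    df <- utils::read.csv(path)
    cols <- intersect(c("x", "y", "z"), tolower(names(df)))
    if (length(cols) == 3L) {
      names(df) <- tolower(names(df))
      return(unname(as.matrix(df[, c("x", "y", "z")])))
    }
    return(unname(as.matrix(df[, 1:3])))
  }
  m <- as.matrix(utils::read.table(path))
  if (ncol(m) < 3L) stop("point-cloud file must have at least 3 columns")
  unname(m[, 1:3])
}

read_ply_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  end <- match("end_header", trimws(lines))
  if (is.na(end)) stop("malformed PLY: no end_header")
  header <- trimws(lines[seq_len(end)])
  if (!any(grepl("^format\\s+ascii", header)))
    stop("only ASCII PLY is supported; convert binary PLY to ASCII first")
  ## properties of the vertex element, in declaration order
  el <- grep("^element\\s", header)
  vtx <- grep("^element\\s+vertex\\s", header)
  if (!length(vtx)) stop("PLY has no vertex element")
  nv <- as.integer(sub("^element\\s+vertex\\s+", "", header[vtx[1L]]))
  nxt <- el[el > vtx[1L]]
  prop_end <- if (length(nxt)) nxt[1L] else end
  props <- header[(vtx[1L] + 1L):(prop_end - 1L)]
  props <- props[grepl("^property\\s", props)]
  pnames <- vapply(strsplit(props, "\\s+"), function(x) x[length(x)],
                   character(1))
  ixyz <- match(c("x", "y", "z"), pnames)
  if (any(is.na(ixyz))) stop("PLY vertex element lacks x/y/z properties")
  body <- lines[(end + 1L):(end + nv)]
  m <- matrix(scan(text = body, quiet = TRUE), nrow = nv,
              ncol = length(pnames), byrow = TRUE)
  unname(m[, ixyz, drop = FALSE])
}

## Least-squares (Kasa) circle fit in the plane; returns center and radius.
fit_circle <- function(xy) {
  A <- cbind(2 * xy[, 1L], 2 * xy[, 2L], 1)
  b <- rowSums(xy^2)
  sol <- qr.solve(A, b)
  list(center = sol[1:2], radius = sqrt(sol[3] + sum(sol[1:2]^2)))
}

## RANSAC plane fit; returns unit normal and offset (n . p = d).
ransac_plane <- function(pts, n_iter = 200L, tol = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(pts)
  best <- NULL; best_in <- -1L
  for (i in seq_len(n_iter)) {
    tri <- pts[sample.int(n, 3L), ]
    nrm <- crossprod3(tri[2L, ] - tri[1L, ], tri[3L, ] - tri[1L, ])
    len <- sqrt(sum(nrm^2))
    if (len < 1e-9) next
    nrm <- nrm / len
    d <- sum(nrm * tri[1L, ])
    inl <- abs(pts %*% nrm - d) < tol
    if (sum(inl) > best_in) { best_in <- sum(inl); best <- list(n = nrm, d = d, inliers = inl) }
  }
  if (is.null(best)) stop("plane RANSAC failed (degenerate point set)")
  ## least-squares refit on inliers
  P <- pts[best$inliers, , drop = FALSE]
  ctr <- colMeans(P)
  sv <- svd(sweep(P, 2, ctr))
  nrm <- sv$v[, 3L]
  list(n = nrm, d = sum(nrm * ctr))
}

crossprod3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Extract the central cross-section of a scanned bowl
#'
#' Levels the cloud so the rim plane is horizontal (RANSAC plane fit on
#' the top band of points), centers the symmetry axis by a least-squares
#' circle fit to the rim, keeps the points in a thin slab through the
#' axis and folds them about the axis into a (radial distance, height)
#' profile of the interior surface.
#'
#' @param cloud N x 3 point matrix (see [read_point_cloud()]).
#' @param slab_halfwidth half-thickness of the central slab, same units
#'   as the cloud.
#' @param rim_quantile fraction of topmost points treated as the rim
#'   band (default 0.02).
#' @param units \code{"mm"} or \code{"inches"} (propagated to the fit
#'   report).
#' @param seed seed for the RANSAC draws.
#' @return An object of class \code{cross_section_profile}: list with
#'   \code{r}, \code{z} (profile samples, bottom at z = 0),
#'   \code{H_obs} (rim height) and \code{units}.
#' @export
extract_cross_section <- function(cloud, slab_halfwidth, rim_quantile = 0.02,
                                  units = c("mm", "inches"), seed = 1L) {
  units <- match.arg(units)
  cloud <- as.matrix(cloud)
  if (ncol(cloud) != 3L) stop("cloud must be an N x 3 matrix")
  if (slab_halfwidth <= 0) stop("slab_halfwidth must be positive (empty slab)")

  ## level iteratively: the top band selected in a tilted frame covers
  ## only part of the rim ring, so re-select after each leveling pass
  lev <- cloud
  for (it in 1:12) {
    zq <- stats::quantile(lev[, 3L], 1 - rim_quantile)
    top <- lev[lev[, 3L] >= zq, , drop = FALSE]
    if (nrow(top) < 10L) stop("too few rim points for plane fitting")
    if (it == 1L) {
      ## robust pass: the raw orientation may be badly tilted
      pl <- ransac_plane(top, tol = diff(range(lev[, 3L])) * 0.01,
                         seed = seed + it)
    } else {
      ## once roughly level the band covers most of the rim ring, and a
      ## plain LS plane pulls the residual tilt down each pass (RANSAC
      ## inliers are an asymmetric patch and would retain a tilt)
      ctr <- colMeans(top)
      pl <- list(n = svd(sweep(top, 2, ctr))$v[, 3L])
    }
    nrm <- if (pl$n[3L] < 0) -pl$n else pl$n
    lev <- lev %*% t(rotation_to_z(nrm))
    if (it > 1L && acos(min(1, nrm[3L])) < 1e-5) break
  }
  lev[, 3L] <- lev[, 3L] - min(lev[, 3L])
  H_obs <- max(lev[, 3L])

  ## rim circle -> axis center
  rim <- lev[lev[, 3L] >= stats::quantile(lev[, 3L], 1 - rim_quantile), ,
             drop = FALSE]
  if (nrow(rim) < 3L) stop("too few rim points for circle fitting")
  circ <- fit_circle(rim[, 1:2, drop = FALSE])
  lev[, 1L] <- lev[, 1L] - circ$center[1L]
  lev[, 2L] <- lev[, 2L] - circ$center[2L]

  slab <- lev[abs(lev[, 1L]) <= slab_halfwidth, , drop = FALSE]
  if (nrow(slab) == 0L) stop("empty slab: no points within the central slice")
  structure(list(r = abs(slab[, 2L]), z = slab[, 3L], H_obs = H_obs,
                 rim_radius = circ$radius, units = units),
            class = "cross_section_profile")
}

## minimal rotation mapping unit vector n to (0,0,1)
rotation_to_z <- function(n) {
  z <- c(0, 0, 1)
  v <- crossprod3(n, z)
  s <- sqrt(sum(v^2)); cth <- sum(n * z)
  if (s < 1e-12) return(diag(3) * sign(cth))
  vx <- rbind(c(0, -v[3], v[2]), c(v[3], 0, -v[1]), c(-v[2], v[1], 0))
  diag(3) + vx + vx %*% vx * ((1 - cth) / s^2)
}

#' Fit the power-law bowl model to a cross-section profile
#'
#' Least-squares fit of \eqn{z = (r/R)^q H} on vertical residuals.
#' \code{mode = "fixed_RH"} keeps hand-measured R and H and fits only
#' the shape exponent; \code{mode = "free"} fits all three parameters.
#' Errors are summarized as MAE and RMSE in the profile's units plus
#' relative versions normalized by the bowl height (in \%).
#'
#' @param profile a \code{cross_section_profile}.
#' @param mode \code{"free"} or \code{"fixed_RH"}.
#' @param R,H hand-measured radius and height (same units as the
#'   profile); required for \code{fixed_RH}.
#' @return An object of class \code{fit_report}: list with \code{bowl}
#'   (fitted [bowl_model], mm), \code{mae}, \code{rmse} (profile units),
#'   \code{relative_mae}, \code{relative_rmse} (\% of height),
#'   \code{units}, \code{mode}, \code{converged} and \code{q_at_bound}.
#' @export
fit_model_to_profile <- function(profile, mode = c("free", "fixed_RH"),
                                 R = NULL, H = NULL) {
  stopifnot(inherits(profile, "cross_section_profile"))
  mode <- match.arg(mode)
  scale <- if (profile$units == "inches") 25.4 else 1
  r <- profile$r * scale; z <- profile$z * scale
  if (length(r) < 10L) stop("need at least 10 profile samples")
  if (max(r) < 0.5 * max(profile$rim_radius * scale, max(r)))
    stop("profile must span at least half the bowl radius")

  model_z <- function(R, H, q) (pmin(r, R) / R)^q * H
  converged <- TRUE; q_bound <- FALSE
  if (mode == "fixed_RH") {
    if (is.null(R) || is.null(H))
      stop("fixed_RH mode requires hand-measured R and H")
    R_mm <- R * scale; H_mm <- H * scale
    obj <- function(q) sum((z - (pmin(r, R_mm) / R_mm)^q * H_mm)^2)
    op <- stats::optimize(obj, interval = c(1.01, 50))
    fit_bowl <- bowl_model(R = R_mm, H = H_mm, q = op$minimum)
    q_bound <- op$minimum > 49 || op$minimum < 1.02
  } else {
    ## R is capped by the observed radial extent: beyond it the model is
    ## degenerate (only H / R^q would be identified)
    rmax <- max(r); zmax <- max(z)
    resid_fn <- function(p) z - (pmin(r, p[1]) / p[1])^p[3] * p[2]
    fit <- minpack.lm::nls.lm(par = c(0.95 * rmax, zmax, 2),
                              fn = resid_fn,
                              lower = c(0.3 * rmax, 0.05 * zmax, 1.01),
                              upper = c(rmax, 10 * zmax, 50),
                              control = minpack.lm::nls.lm.control(
                                maxiter = 200))
    converged <- fit$info %in% 1:4
    fit_bowl <- bowl_model(R = fit$par[1], H = fit$par[2], q = fit$par[3])
    q_bound <- fit_bowl$q > 49
  }
  res <- z - model_z(fit_bowl$R, fit_bowl$H, fit_bowl$q)
  mae <- mean(abs(res)) / scale
  rmse <- sqrt(mean(res^2)) / scale
  H_rep <- fit_bowl$H / scale
  structure(list(bowl = fit_bowl, mae = mae, rmse = rmse,
                 relative_mae = mae / H_rep * 100,
                 relative_rmse = rmse / H_rep * 100,
                 units = profile$units, mode = mode,
                 converged = converged, q_at_bound = q_bound),
            class = "fit_report")
}

#' @export
print.fit_report <- function(x, ...) {
  cat(sprintf(paste0("Bowl-model fit (%s): R = %.2f mm, H = %.2f mm, ",
                     "q = %.3f\n  MAE = %.4g %s (%.3g%% of height), ",
                     "RMSE = %.4g %s (%.3g%%)\n"),
              x$mode, x$bowl$R, x$bowl$H, x$bowl$q,
              x$mae, x$units, x$relative_mae,
              x$rmse, x$units, x$relative_rmse))
  invisible(x)
}

#' Synthesize a dense bowl point cloud
#'
#' Samples points on a power-law bowl's interior surface (optionally
#' jittered), mainly for validating the slicing/fitting pipeline.
#'
#' @param bowl a [bowl_model].
#' @param n number of points.
#' @param noise_sd isotropic positional jitter sd, mm.
#' @param seed optional integer seed.
#' @return N x 3 matrix.
#' @export
synthesize_bowl_cloud <- function(bowl, n = 20000L, noise_sd = 0,
                                  seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ## area-ish uniform: radius via sqrt, angle uniform
  r <- bowl$R * sqrt(stats::runif(n))
  th <- stats::runif(n, 0, 2 * pi)
  z <- (r / bowl$R)^bowl$q * bowl$H
  pts <- cbind(r * cos(th), r * sin(th), z)
  if (noise_sd > 0) pts <- pts + matrix(stats::rnorm(3 * n, 0, noise_sd), n, 3L)
  pts
}
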