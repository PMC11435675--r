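#' Estimator configuration
#'
#' Tuning knobs of the coarse-to-fine bowl estimator. The coarse grid
#' spans the realistic bowl ranges (H 10..130 mm and R 30..130 mm in
#' 10 mm steps, q 2..10 in steps of 1) so that the refinement
#' neighborhood of one grid step overlaps adjacent cells. Refinement
#' perturbs (H, R, q) around each kept candidate with Gaussian noise
#' whose sd starts at half a grid step and is halved every round.
#'
#' @param H_grid,R_grid,q_grid coarse grid values (mm, mm, unitless).
#' @param m number of candidate bowls kept after the coarse stage.
#' @param n_samples random-search samples per candidate per round.
#' @param sd0 named vector of initial perturbation sds for H, R, q.
#' @param decay multiplicative sd decay per round.
#' @param threshold stop when the best selection score e_n drops below
#'   this value.
#' @param max_rounds maximum refinement rounds.
#' @param init_rotations list of (phi, theta, psi) triples (degrees) used
#'   as pose multi-starts in the coarse stage.
#' @param resolution arc-table resolution used inside the estimator.
#' @param z_min minimum camera-frame depth (mm) below which a landmark is
#'   treated as behind the camera.
#' @param behind_penalty penalty slope (px per mm of depth violation)
#'   keeping the pose objective finite when landmarks fall behind the
#'   camera.
#' @param bounds list of length-2 vectors \code{H}, \code{R}, \code{q}
#'   clamping refinement proposals.
#' @param seed integer seed for the random search.
#' @return An object of class \code{estimation_config}.
#' @export
estimation_config <- function(H_grid = seq(10, 130, by = 10),
                              R_grid = seq(30, 130, by = 10),
                              q_grid = seq(2, 10, by = 1),
                              m = 10L,
                              n_samples = 50L,
                              sd0 = c(H = 5, R = 5, q = 0.5),
                              decay = 0.5,
                              threshold = 0.02,
                              max_rounds = 10L,
                              init_rotations = list(c(0, 30, 0), c(0, 60, 0),
                                                    c(0, 90, 0), c(0, 60, 30),
                                                    c(0, 60, -30)),
                              resolution = 2000L,
                              z_min = 1,
                              behind_penalty = 100,
                              bounds = list(H = c(4, 150), R = c(20, 150),
                                            q = c(1.2, 12)),
                              seed = NULL) {
  stopifnot(m >= 1L, n_samples >= 1L, threshold > 0, max_rounds >= 1L,
            decay > 0, decay <= 1, all(sd0 > 0),
            all(c("H", "R", "q") %in% names(sd0)))
  structure(list(H_grid = H_grid, R_grid = R_grid, q_grid = q_grid,
                 m = as.integer(m), n_samples = as.integer(n_samples),
                 sd0 = sd0, decay = decay, threshold = threshold,
                 max_rounds = as.integer(max_rounds),
                 init_rotations = init_rotations,
                 resolution = as.integer(resolution),
                 z_min = z_min, behind_penalty = behind_penalty,
                 bounds = bounds, seed = seed),
            class = "estimation_config")
}

#' Forward model: 3D landmarks of a candidate bowl
#'
#' Maps the tape's division arc positions (known from the physical
#' ruler) onto a candidate bowl's central curve, anchoring the tape
#' midpoint at the bowl bottom, and offsets each division sideways into
#' its landmark pair. Positions falling outside the candidate's curve
#' (when the candidate is shorter than the tape) are clamped to the rim
#' and counted.
#'
#' @param bowl candidate [bowl_model].
#' @param tape a [tape_spec].
#' @param arc_positions division positions along the tape, mm in
#'   \code{[0, L_gt]}.
#' @param L_gt known physical tape length, mm.
#' @param resolution arc-table resolution.
#' @return A \code{landmark_set_3d} with extra fields \code{n_clamped}
#'   and \code{L_est}.
#' @export
forward_landmarks <- function(bowl, tape, arc_positions, L_gt,
                              resolution = 2000L) {
  tab <- arc_table_fast(bowl, resolution)
  yg <- tab$yg; s_half <- tab$s_half; Lh <- tab$Lh
  L <- 2 * Lh
  s <- arc_positions - L_gt / 2 + Lh
  clamped <- s < 0 | s > L
  s <- pmin(pmax(s, 0), L)
  u <- pmin(abs(s - Lh), Lh)
  i <- pmin(findInterval(u, s_half), resolution)
  w <- (u - s_half[i]) / pmax(s_half[i + 1L] - s_half[i],
                              .Machine$double.xmin)
  y <- (yg[i] + w * (yg[i + 1L] - yg[i])) * sign(s - Lh)
  div <- cbind(x = 0, y = y, z = (abs(y) / bowl$R)^bowl$q * bowl$H)
  off <- offset_pairs(bowl, div, tape$width)
  structure(list(points = rbind(off$upper, off$lower),
                 arc_positions = s, L = L, L_est = L,
                 n_clamped = sum(clamped), fallback = off$fallback,
                 bowl = bowl),
            class = "landmark_set_3d")
}

## lean half-curve arc table: the estimator rebuilds this for every
## candidate bowl, so it is a plain cumulative-trapezoid table
arc_table_fast <- function(bowl, resolution) {
  yg <- seq(0, bowl$R, length.out = resolution + 1L)
  g <- sqrt(1 + profile_slope(bowl, yg)^2)
  s_half <- c(0, cumsum(diff(yg) * (g[-1L] + g[-length(g)]) / 2))
  list(yg = yg, s_half = s_half, Lh = s_half[resolution + 1L])
}

## H making the candidate's rim-to-rim curve length equal the tape length,
## at fixed R and q; NA when no H in `interval` achieves it
solve_H_for_length <- function(R, q, L_gt, resolution = 1000L,
                               interval = c(2, 200)) {
  len <- function(H) 2 * arc_table_fast(bowl_model(R, H, q), resolution)$Lh
  lo <- len(interval[1]) - L_gt
  hi <- len(interval[2]) - L_gt
  if (lo > 0 || hi < 0) return(NA_real_)
  stats::uniroot(function(H) len(H) - L_gt, interval, tol = 1e-6)$root
}

## Pose residuals and analytic Jacobian ---------------------------------------
## Parameter vector: (phi, theta, psi) degrees, (X, Y, Z) mm. Residuals are
## the 2N stacked pixel errors plus N depth-penalty terms (zero when every
## landmark is in front of the camera); depths below z_min are clamped so the
## objective stays finite and LM can escape.

euler_rotation_and_derivs <- function(phi, theta, psi) {
  d <- pi / 180
  a <- phi * d; b <- theta * d; c <- psi * d
  ca <- cos(a); sa <- sin(a); cb <- cos(b); sb <- sin(b)
  cc <- cos(c); sc <- sin(c)
  Rx <- matrix(c(1, 0, 0, 0, ca, sa, 0, -sa, ca), 3L, 3L)
  Ry <- matrix(c(cb, 0, -sb, 0, 1, 0, sb, 0, cb), 3L, 3L)
  Rz <- matrix(c(cc, sc, 0, -sc, cc, 0, 0, 0, 1), 3L, 3L)
  dRx <- matrix(c(0, 0, 0, 0, -sa, ca, 0, -ca, -sa), 3L, 3L) * d
  dRy <- matrix(c(-sb, 0, -cb, 0, 0, 0, cb, 0, -sb), 3L, 3L) * d
  dRz <- matrix(c(-sc, cc, 0, -cc, -sc, 0, 0, 0, 0), 3L, 3L) * d
  list(R = Rz %*% Ry %*% Rx,
       dphi = Rz %*% Ry %*% dRx,
       dtheta = Rz %*% dRy %*% Rx,
       dpsi = dRz %*% Ry %*% Rx)
}

pose_residuals <- function(par, pts3, obs_pts, intr, z_min, pen_k) {
  E <- euler_rotation_and_derivs(par[1], par[2], par[3])
  pc <- pts3 %*% t(E$R)
  x <- pc[, 1L] + par[4]; y <- pc[, 2L] + par[5]; z <- pc[, 3L] + par[6]
  viol <- pmax(0, z_min - z)
  zs <- pmax(z, z_min)
  ru <- intr$F * x / zs + intr$cx - obs_pts[, 1L]
  rv <- intr$F * y / zs + intr$cy - obs_pts[, 2L]
  c(ru, rv, pen_k * viol)
}

pose_jacobian <- function(par, pts3, obs_pts, intr, z_min, pen_k) {
  E <- euler_rotation_and_derivs(par[1], par[2], par[3])
  pc <- pts3 %*% t(E$R)
  x <- pc[, 1L] + par[4]; y <- pc[, 2L] + par[5]; z <- pc[, 3L] + par[6]
  front <- as.numeric(z >= z_min)   # 0 where depth is clamped
  back <- 1 - front
  zs <- pmax(z, z_min)
  n <- length(x)
  Fz <- intr$F / zs
  gx <- intr$F * x / zs^2
  gy <- intr$F * y / zs^2
  ## derivatives of camera-frame coords wrt the three angles
  dA <- pts3 %*% cbind(t(E$dphi), t(E$dtheta), t(E$dpsi))  # n x 9
  Ju <- matrix(0, n, 6L); Jv <- matrix(0, n, 6L); Jp <- matrix(0, n, 6L)
  for (k in 1:3) {
    dx <- dA[, 3L * k - 2L]; dy <- dA[, 3L * k - 1L]; dz <- dA[, 3L * k]
    dzf <- front * dz
    Ju[, k] <- Fz * dx - gx * dzf
    Jv[, k] <- Fz * dy - gy * dzf
    Jp[, k] <- -pen_k * back * dz
  }
  Ju[, 4L] <- Fz
  Jv[, 5L] <- Fz
  Ju[, 6L] <- -gx * front
  Jv[, 6L] <- -gy * front
  Jp[, 6L] <- -pen_k * back
  rbind(Ju, Jv, Jp)
}

#' Summed squared reprojection error
#'
#' \eqn{J = \sum_i \|\tilde c_i - c_i\|^2} between the projections of a
#' candidate bowl's forward-modeled landmarks and the observed pixels.
#' Landmarks that fall behind the camera contribute a large finite
#' penalty rather than an error, so optimizers can recover.
#'
#' @param bowl candidate [bowl_model].
#' @param pose a [camera_pose].
#' @param intr a [camera_intrinsics].
#' @param obs a \code{landmark_set_2d} (with \code{arc_positions} and
#'   \code{L_gt}).
#' @param tape a [tape_spec].
#' @param config an [estimation_config] (depth clamp / penalty settings).
#' @return J in squared pixels.
#' @export
reprojection_cost <- function(bowl, pose, intr, obs, tape,
                              config = estimation_config()) {
  lm3 <- forward_landmarks(bowl, tape, obs$arc_positions, obs$L_gt,
                           config$resolution)
  par <- c(pose$phi, pose$theta, pose$psi, pose$t)
  r <- pose_residuals(par, lm3$points, obs$points, intr,
                      config$z_min, config$behind_penalty)
  sum(r^2)
}

#' Fit the camera pose for a fixed candidate bowl
#'
#' Minimizes the summed squared reprojection error over the six pose
#' parameters (three Euler angles, three translations) by
#' Levenberg-Marquardt, running from each supplied initial pose and
#' returning the best.
#'
#' @param bowl candidate [bowl_model].
#' @param intr a [camera_intrinsics].
#' @param obs a \code{landmark_set_2d}.
#' @param tape a [tape_spec].
#' @param init_poses list of [camera_pose] starting points; if
#'   \code{NULL}, a default multi-start set is built from the
#'   observation's pixel centroid.
#' @param config an [estimation_config].
#' @param maxiter LM iteration cap per start.
#' @return List with \code{pose}, \code{J} (squared-pixel cost) and
#'   \code{diverged} (TRUE when no start converged).
#' @export
fit_pose <- function(bowl, intr, obs, tape, init_poses = NULL,
                     config = estimation_config(), maxiter = 60L) {
  lm3 <- forward_landmarks(bowl, tape, obs$arc_positions, obs$L_gt,
                           config$resolution)
  if (nrow(lm3$points) < 8L)
    stop("pose fitting needs at least 4 landmark pairs")
  if (is.null(init_poses))
    init_poses <- default_pose_inits(bowl, intr, obs, config)
  best <- NULL
  any_conv <- FALSE
  for (p0 in init_poses) {
    par0 <- c(p0$phi, p0$theta, p0$psi, p0$t)
    fit <- tryCatch(
      suppressWarnings(
        minpack.lm::nls.lm(par = par0, fn = pose_residuals,
                           jac = pose_jacobian,
                           pts3 = lm3$points, obs_pts = obs$points,
                           intr = intr, z_min = config$z_min,
                           pen_k = config$behind_penalty,
                           control = minpack.lm::nls.lm.control(
                             maxiter = as.integer(maxiter), ptol = 1e-9,
                             ftol = 1e-11))),
      error = function(e) NULL)
    if (is.null(fit)) next
    any_conv <- any_conv || fit$info %in% 1:4
    J <- fit$deviance
    if (is.null(best) || J < best$J) {
      best <- list(pose = camera_pose(phi = fit$par[1], theta = fit$par[2],
                                      psi = fit$par[3], t = fit$par[4:6]),
                   J = J)
    }
  }
  if (is.null(best))
    stop("all pose starts failed")
  best$diverged <- !any_conv
  best
}

## Canonical multi-start poses: a few tilts combined with a translation
## guess that back-projects the observed pixel centroid to a mid-range depth.
default_pose_inits <- function(bowl, intr, obs, config,
                               Z0 = 300) {
  ubar <- mean(obs$points[, 1L]); vbar <- mean(obs$points[, 2L])
  pbar <- c(0, 0, 0.6 * bowl$H)
  lapply(config$init_rotations, function(ang) {
    R0 <- rotation_from_euler(ang[1], ang[2], ang[3])
    pc_target <- c(Z0 * (ubar - intr$cx) / intr$F,
                   Z0 * (vbar - intr$cy) / intr$F, Z0)
    camera_pose(phi = ang[1], theta = ang[2], psi = ang[3],
                t = pc_target - as.numeric(R0 %*% pbar))
  })
}

#' Candidate selection scores
#'
#' Scores a candidate bowl + fitted pose against the observation:
#' \itemize{
#'   \item \code{e_l}: relative tape-length error
#'     \eqn{|L_{est} - L_{gt}| / L_{gt}} between the candidate's
#'     rim-to-rim arc length and the known tape length;
#'   \item \code{e_c}: mean width-normalized reprojection error,
#'     \eqn{(2/N)\sum_{i=1}^{N/2} (\|\tilde c_i - c_i\| +
#'     \|\tilde c_{N/2+i} - c_{N/2+i}\|) / \|c_i - c_{N/2+i}\|};
#'   \item \code{e_n = e_c + e_l}: the selection score.
#' }
#'
#' @inheritParams reprojection_cost
#' @return List with \code{e_l}, \code{e_c}, \code{e_n}, \code{J},
#'   \code{L_est} and \code{n_clamped}.
#' @export
selection_errors <- function(bowl, pose, intr, obs, tape,
                             config = estimation_config()) {
  lm3 <- forward_landmarks(bowl, tape, obs$arc_positions, obs$L_gt,
                           config$resolution)
  e_l <- abs(lm3$L_est - obs$L_gt) / obs$L_gt
  pc <- transform_points(pose, lm3$points)
  if (any(pc[, 3L] <= 0)) {
    return(list(e_l = e_l, e_c = Inf, e_n = Inf, J = Inf,
                L_est = lm3$L_est, n_clamped = lm3$n_clamped))
  }
  pred <- cbind(intr$F * pc[, 1L] / pc[, 3L] + intr$cx,
                intr$F * pc[, 2L] / pc[, 3L] + intr$cy)
  n2 <- nrow(pred) / 2L
  d <- sqrt(rowSums((pred - obs$points)^2))
  widths <- sqrt(rowSums((obs$points[1:n2, , drop = FALSE] -
                          obs$points[n2 + 1:n2, , drop = FALSE])^2))
  ok <- widths > .Machine$double.eps^0.5
  if (!all(ok))
    warning(sum(!ok), " pair(s) with zero observed width excluded from e_c")
  e_c <- mean((d[1:n2][ok] + d[n2 + 1:n2][ok]) / widths[ok])
  J <- sum(d^2)
  list(e_l = e_l, e_c = e_c, e_n = e_c + e_l, J = J,
       L_est = lm3$L_est, n_clamped = lm3$n_clamped)
}

score_candidate <- function(bowl, intr, obs, tape, config, init_poses = NULL,
                            maxiter = 60L) {
  pf <- fit_pose(bowl, intr, obs, tape, init_poses, config, maxiter)
  sc <- selection_errors(bowl, pf$pose, intr, obs, tape, config)
  list(bowl = bowl, pose = pf$pose, e_l = sc$e_l, e_c = sc$e_c,
       e_n = sc$e_n, J = sc$J, n_clamped = sc$n_clamped)
}

## deterministic ordering: e_n, then J, then volume
better_candidate <- function(a, b) {
  if (is.null(b)) return(TRUE)
  if (a$e_n != b$e_n) return(a$e_n < b$e_n)
  if (a$J != b$J) return(a$J < b$J)
  bowl_volume(a$bowl) < bowl_volume(b$bowl)
}

#' Estimate bowl parameters from a 2D landmark observation
#'
#' The coarse-to-fine estimator. A coarse grid over (H, R, q) is scored
#' by fitting the camera pose per grid bowl (Levenberg-Marquardt on the
#' reprojection residuals) and ranking bowls by the selection score
#' \code{e_n}; the best \code{m} candidates are then refined by rounds of
#' seeded Gaussian random search around each candidate (sd halved every
#' round) with warm-started pose refits, stopping when the best
#' \code{e_n} falls below the threshold or the round budget is spent.
#'
#' For speed the coarse sweep warm-starts each grid bowl's pose fit from
#' its predecessor's solution (the optimal pose varies smoothly with the
#' candidate shape); the sweep is seeded by a full multi-start fit on a
#' mid-grid probe bowl, and the kept candidates are re-polished with the
#' full multi-start set before refinement.
#'
#' @param obs a \code{landmark_set_2d} with \code{arc_positions} and
#'   \code{L_gt}.
#' @param intr a [camera_intrinsics].
#' @param tape a [tape_spec].
#' @param config an [estimation_config].
#' @param L_gt known tape length, mm; defaults to \code{obs$L_gt}.
#' @return An object of class \code{estimation_result}: list with
#'   \code{bowl}, \code{pose}, \code{J}, \code{e_l}, \code{e_c},
#'   \code{e_n}, \code{volume} (cm^3), \code{trace} (best e_n per round,
#'   round 0 = coarse stage) and \code{rounds}.
#' @export
estimate_bowl <- function(obs, intr = camera_intrinsics(),
                          tape = tape_spec(),
                          config = estimation_config(), L_gt = NULL) {
  stopifnot(inherits(obs, "landmark_set_2d"))
  if (!is.null(L_gt)) obs$L_gt <- L_gt
  if (is.null(obs$L_gt))
    stop("the ground-truth tape length L_gt is required (known from the ",
         "physical ruler or the simulator)")
  if (is.null(obs$arc_positions))
    stop("observation lacks tape arc positions for its landmark pairs")
  if (nrow(obs$points) < 8L) stop("need at least 4 landmark pairs")
  if (!is.null(config$seed)) set.seed(config$seed)

  grid <- expand.grid(R = config$R_grid, H = config$H_grid, q = config$q_grid,
                      KEEP.OUT.ATTRS = FALSE)
  if (nrow(grid) == 0L) stop("empty candidate grid")
  ## the known tape length pins the true bowl to the 2D surface
  ## L(R, H, q) = L_gt; add one length-matched candidate per (R, q) so
  ## the coarse ranking always sees bowls with e_l = 0
  lm_grid <- expand.grid(R = config$R_grid, q = config$q_grid,
                         KEEP.OUT.ATTRS = FALSE)
  lm_H <- vapply(seq_len(nrow(lm_grid)), function(i)
    solve_H_for_length(lm_grid$R[i], lm_grid$q[i], obs$L_gt,
                       interval = config$bounds$H), numeric(1))
  ok <- !is.na(lm_H)
  if (any(ok))
    grid <- rbind(grid, data.frame(R = lm_grid$R[ok], H = lm_H[ok],
                                   q = lm_grid$q[ok]))

  ## probe: full multi-start on a mid-grid bowl to anchor the warm chain
  probe <- bowl_model(R = stats::median(config$R_grid),
                      H = stats::median(config$H_grid),
                      q = stats::median(config$q_grid))
  probe_fit <- fit_pose(probe, intr, obs, tape, NULL, config)
  chain_pose <- probe_fit$pose

  cands <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    b <- bowl_model(R = grid$R[i], H = grid$H[i], q = grid$q[i])
    sc <- score_candidate(b, intr, obs, tape, config,
                          init_poses = list(chain_pose), maxiter = 40L)
    chain_pose <- sc$pose
    cands[[i]] <- sc
  }
  en <- vapply(cands, `[[`, numeric(1), "e_n")
  keep <- order(en, vapply(cands, `[[`, numeric(1), "J"))[
    seq_len(min(config$m, length(cands)))]
  cands <- cands[keep]

  ## polish kept candidates with the full multi-start set
  cands <- lapply(cands, function(cd)
    score_candidate(cd$bowl, intr, obs, tape, config,
                    init_poses = c(list(cd$pose),
                                   default_pose_inits(cd$bowl, intr, obs,
                                                      config))))
  best <- NULL
  for (cd in cands) if (better_candidate(cd, best)) best <- cd
  trace <- best$e_n

  round_used <- 0L
  if (best$e_n >= config$threshold) {
    for (r in seq_len(config$max_rounds)) {
      round_used <- r
      sdr <- config$sd0 * config$decay^(r - 1)
      for (k in seq_along(cands)) {
        cd <- cands[[k]]
        for (j in seq_len(config$n_samples)) {
          if (j %% 5L == 0L) {
            ## long-range move on the length-matched surface: sample
            ## (R, q) at grid-step scale (2 sd0) and solve H so the
            ## curve length equals the tape length; escapes deceptive
            ## minima where an oblique view trades bowl height against
            ## camera depth
            Rn <- clamp(cd$bowl$R + stats::rnorm(1, 0, 2 * config$sd0["R"]),
                        config$bounds$R)
            qn <- clamp(cd$bowl$q + stats::rnorm(1, 0, 2 * config$sd0["q"]),
                        config$bounds$q)
            Hn <- solve_H_for_length(Rn, qn, obs$L_gt,
                                     interval = config$bounds$H)
            if (is.na(Hn))
              Hn <- clamp(cd$bowl$H + stats::rnorm(1, 0, config$sd0["H"]),
                          config$bounds$H)
          } else {
            Hn <- clamp(cd$bowl$H + stats::rnorm(1, 0, sdr["H"]),
                        config$bounds$H)
            Rn <- clamp(cd$bowl$R + stats::rnorm(1, 0, sdr["R"]),
                        config$bounds$R)
            qn <- clamp(cd$bowl$q + stats::rnorm(1, 0, sdr["q"]),
                        config$bounds$q)
          }
          bn <- bowl_model(R = Rn, H = Hn, q = qn)
          sc <- score_candidate(bn, intr, obs, tape, config,
                                init_poses = list(cd$pose), maxiter = 40L)
          if (better_candidate(sc, cd)) cd <- sc
        }
        cands[[k]] <- cd
        if (better_candidate(cd, best)) best <- cd
      }
      trace <- c(trace, best$e_n)
      if (best$e_n < config$threshold) break
    }
  }
  structure(list(bowl = best$bowl, pose = best$pose, J = best$J,
                 e_l = best$e_l, e_c = best$e_c, e_n = best$e_n,
                 volume = bowl_volume(best$bowl), trace = trace,
                 rounds = round_used, n_clamped = best$n_clamped),
            class = "estimation_result")
}

clamp <- function(x, b) pmin(pmax(x, b[1]), b[2])

#' @export
print.estimation_result <- function(x, ...) {
  cat(sprintf(paste0("Bowl estimate: R = %.2f mm, H = %.2f mm, q = %.3f ",
                     "(V = %.1f cm^3)\n  e_n = %.4g (e_c = %.4g, e_l = %.4g),",
                     " J = %.4g px^2, %d refinement round(s)\n"),
              x$bowl$R, x$bowl$H, x$bowl$q, x$volume,
              x$e_n, x$e_c, x$e_l, x$J, x$rounds))
  invisible(x)
}

#' Write an estimation result as JSON
#'
#' @param result an \code{estimation_result}.
#' @param path file path.
#' @export
write_result_json <- function(result, path) {
  stopifnot(inherits(result, "estimation_result"))
  jsonlite::write_json(
    list(bowl = list(R_mm = result$bowl$R, H_mm = result$bowl$H,
                     q = result$bowl$q),
         pose = list(phi_deg = result$pose$phi, theta_deg = result$pose$theta,
                     psi_deg = result$pose$psi, t_mm = result$pose$t),
         volume_cm3 = result$volume, J_px2 = result$J,
         e_l = result$e_l, e_c = result$e_c, e_n = result$e_n,
         trace = result$trace, rounds = result$rounds),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
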