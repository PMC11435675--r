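#' The five reference study bowls
#'
#' Fixed bowls spanning the realistic shape/size range (a small deep
#' bowl up to a large serving bowl, plus a plate-like shallow one), used
#' as the representative set in the simulation study.
#'
#' @return Named list of [bowl_model] objects.
#' @export
study_bowls <- function() {
  list(`1` = bowl_model(R = 64, H = 51, q = 6.3),
       `2` = bowl_model(R = 102, H = 71.5, q = 9.0),
       `3` = bowl_model(R = 80, H = 32, q = 3.5),
       `4` = bowl_model(R = 55, H = 44, q = 5.2),
       `5` = bowl_model(R = 130, H = 78, q = 8.5))
}

#' Run the five-bowl simulation study
#'
#' End-to-end evaluation of the estimator: for each (fixed) bowl,
#' generates noiseless landmark observations under random camera
#' extrinsics drawn from the realistic ranges, runs the coarse-to-fine
#' estimator on each image, and summarizes per-bowl estimation accuracy:
#' means and sds of the estimates and of their relative errors, the IQR
#' of the relative volumetric errors, and the experimental versus
#' closed-form volumetric error sd.
#'
#' @param bowls list of [bowl_model]s (default [study_bowls()]).
#' @param images_per_bowl observations per bowl (default 25).
#' @param intr a [camera_intrinsics].
#' @param tape a [tape_spec].
#' @param ranges a [scenario_ranges] for the camera draws.
#' @param config an [estimation_config].
#' @param noise_sd pixel noise added to the projections (default 0).
#' @param seed integer seed governing the whole study.
#' @param verbose print per-image progress.
#' @return An object of class \code{simulation_study}: list with
#'   \code{per_image} (one row per estimate), \code{per_bowl} (summary
#'   rows) and \code{summary} (averaged volumetric-error IQR in \%, the
#'   maximum absolute mean relative error in \%, and the seed).
#' @export
run_simulation_study <- function(bowls = study_bowls(),
                                 images_per_bowl = 25L,
                                 intr = camera_intrinsics(),
                                 tape = tape_spec(),
                                 ranges = scenario_ranges(),
                                 config = estimation_config(),
                                 noise_sd = 0,
                                 seed = 1L,
                                 verbose = FALSE) {
  set.seed(seed)
  config$seed <- NULL  # one RNG stream for the whole study
  rows <- list()
  for (bi in seq_along(bowls)) {
    truth <- bowls[[bi]]
    V0 <- bowl_volume(truth)
    for (img in seq_len(images_per_bowl)) {
      sc <- random_scenario(ranges, tape, intr, bowl = truth)
      obs <- simulate_observation(truth, tape, intr, sc$pose,
                                  noise_sd = noise_sd)
      est <- estimate_bowl(obs, intr, tape, config)
      rows[[length(rows) + 1L]] <- data.frame(
        bowl = names(bowls)[bi] %||% as.character(bi), image = img,
        H_true = truth$H, R_true = truth$R, q_true = truth$q, V_true = V0,
        H_est = est$bowl$H, R_est = est$bowl$R, q_est = est$bowl$q,
        V_est = est$volume, e_n = est$e_n, rounds = est$rounds)
      if (verbose)
        message(sprintf("bowl %s image %d: e_n = %.4g, V err = %.2f%%",
                        names(bowls)[bi] %||% bi, img, est$e_n,
                        100 * (est$volume - V0) / V0))
    }
  }
  per_image <- do.call(rbind, rows)
  per_image$H_err <- (per_image$H_est - per_image$H_true) / per_image$H_true
  per_image$R_err <- (per_image$R_est - per_image$R_true) / per_image$R_true
  per_image$q_err <- (per_image$q_est - per_image$q_true) / per_image$q_true
  per_image$V_err <- (per_image$V_est - per_image$V_true) / per_image$V_true

  per_bowl <- do.call(rbind, lapply(split(per_image, per_image$bowl),
                                    summarize_bowl))
  per_bowl <- per_bowl[order(match(per_bowl$bowl, per_image$bowl)), ]
  rownames(per_bowl) <- NULL

  err_means <- as.matrix(per_bowl[, c("H_err_mean", "R_err_mean",
                                      "q_err_mean", "V_err_mean")])
  structure(list(
    per_image = per_image, per_bowl = per_bowl,
    summary = list(avg_volume_iqr_pct = mean(per_bowl$V_iqr_pct),
                   max_abs_mean_rel_err_pct = max(abs(err_means)),
                   images_per_bowl = images_per_bowl, seed = seed)),
    class = "simulation_study")
}

summarize_bowl <- function(d) {
  rel_sds <- c(H = stats::sd(d$H_err), R = stats::sd(d$R_err),
               q = stats::sd(d$q_err))
  data.frame(
    bowl = d$bowl[1L], n = nrow(d),
    H_true = d$H_true[1L], H_mean = mean(d$H_est), H_sd = stats::sd(d$H_est),
    R_true = d$R_true[1L], R_mean = mean(d$R_est), R_sd = stats::sd(d$R_est),
    q_true = d$q_true[1L], q_mean = mean(d$q_est), q_sd = stats::sd(d$q_est),
    V_true = d$V_true[1L], V_mean = mean(d$V_est), V_sd = stats::sd(d$V_est),
    H_err_mean = 100 * mean(d$H_err), R_err_mean = 100 * mean(d$R_err),
    q_err_mean = 100 * mean(d$q_err), V_err_mean = 100 * mean(d$V_err),
    V_iqr_pct = 100 * stats::IQR(d$V_err),
    sigma_v_exp = stats::sd(d$V_err),
    sigma_v_calc = sigma_v(d$q_true[1L], rel_sds["H"], rel_sds["R"],
                           rel_sds["q"]))
}

#' @export
print.simulation_study <- function(x, ...) {
  cat(sprintf("Simulation study: %d bowls x %d images (seed %s)\n",
              nrow(x$per_bowl), x$summary$images_per_bowl,
              format(x$summary$seed)))
  cols <- c("bowl", "H_err_mean", "R_err_mean", "q_err_mean", "V_err_mean",
            "V_iqr_pct", "sigma_v_exp", "sigma_v_calc")
  print(format(x$per_bowl[, cols], digits = 3), row.names = FALSE)
  cat(sprintf("Averaged volumetric-error IQR: %.2f%%\n",
              x$summary$avg_volume_iqr_pct))
  cat(sprintf("Max |mean relative error| over parameters and volume: %.2f%%\n",
              x$summary$max_abs_mean_rel_err_pct))
  invisible(x)
}
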