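# Synthetic heating trajectories with a programmed two-state melting
# transition, for exercising and validating the Tm estimators.

#' Helical folded reference geometry
#'
#' A Calpha trace on an ideal helix (default rise 1.5 A, twist 100
#' degrees, radius 2.3 A), which gives a rich i/i+4 native-contact set
#' at the 8 A Calpha cutoff.
#'
#' @param n_residues number of residues.
#' @param rise axial rise per residue (A).
#' @param twist twist per residue (degrees).
#' @param radius helix radius (A).
#' @return N x 3 coordinate matrix.
#' @export
helix_reference <- function(n_residues, rise = 1.5, twist = 100, radius = 2.3) {
  i <- seq_len(n_residues) - 1L
  ang <- i * twist * pi / 180
  cbind(radius * cos(ang), radius * sin(ang), i * rise)
}

#' Parameters of the synthetic melting simulation
#'
#' The generator emulates a two-state thermal unfolding transition: below
#' `t_melt` frames fluctuate about the folded reference; at `t_melt` the
#' model expands abruptly (programmed Rg jump) and then drifts further
#' with temperature, so that both the native-contact fraction falls
#' through 0.8 and Rg rises through 14 A at the programmed temperature.
#'
#' @param n_residues residues in the Calpha model (default 30, giving a
#'   folded Rg of about 13.2 A, below the 14 A criterion).
#' @param t_melt programmed melting temperature (K); `NA` for a run with
#'   no transition. Must lie inside the schedule's temperature range.
#' @param noise_sd pre- and post-melt positional noise SD (A).
#' @param rg_jump Rg increase at the transition (A).
#' @param expansion_rate post-melt Rg drift (A/K).
#' @param schedule a [temperature_schedule()].
#' @param frames number of frames.
#' @param t_end last frame time (ns; default the end of the ramp).
#' @param seed mandatory RNG seed; the generator is a pure function of
#'   seed and parameters.
#' @return List of class `melt_sim_params`.
#' @export
melt_sim_params <- function(n_residues = 30L, t_melt = 350, noise_sd = 0.3,
                            rg_jump = 5, expansion_rate = 0.05,
                            schedule = fcmur_heating_schedule(),
                            frames = 2000L, t_end = NULL, seed) {
  if (missing(seed)) stop("seed is mandatory")
  if (is.null(t_end)) t_end <- schedule$segments$t_end[nrow(schedule$segments)]
  stopifnot(noise_sd >= 0, rg_jump >= 0, expansion_rate >= 0, frames >= 2L)
  if (!is.na(t_melt)) {
    T_range <- range(c(schedule$segments$T_start, schedule$segments$T_end))
    if (t_melt < T_range[1] || t_melt > T_range[2]) {
      stop("t_melt outside the schedule's temperature range")
    }
  }
  structure(list(n_residues = as.integer(n_residues), t_melt = t_melt,
                 noise_sd = noise_sd, rg_jump = rg_jump,
                 expansion_rate = expansion_rate, schedule = schedule,
                 frames = as.integer(frames), t_end = t_end,
                 seed = as.integer(seed)),
            class = "melt_sim_params")
}

#' Generate a synthetic heating trajectory
#'
#' @param p a [melt_sim_params()].
#' @return List with `traj` (a [heating_trajectory()]), `reference`
#'   (N x 3 folded coordinates) and `ground_truth` (programmed `t_melt`,
#'   folded Rg, the seed and all parameters) sufficient to re-derive
#'   every expected downstream quantity.
#' @export
gen_heating_trajectory <- function(p) {
  stopifnot(inherits(p, "melt_sim_params"))
  ref <- helix_reference(p$n_residues)
  cen <- colMeans(ref)
  ref_c <- sweep(ref, 2L, cen)
  rg0 <- sqrt(mean(rowSums(ref_c^2)))
  times <- seq(0, p$t_end, length.out = p$frames)
  temps <- frame_temperature(p$schedule, times)
  melted <- if (is.na(p$t_melt)) rep(FALSE, p$frames) else temps >= p$t_melt
  target_rg <- ifelse(melted,
                      rg0 + p$rg_jump + p$expansion_rate * (temps - p$t_melt),
                      rg0)
  scale <- target_rg / rg0
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(p$seed)
  flat_ref <- as.vector(t(ref_c))  # (x1, y1, z1, x2, ...)
  xyz <- outer(scale, flat_ref) +
    matrix(stats::rnorm(p$frames * 3L * p$n_residues, sd = p$noise_sd),
           p$frames, 3L * p$n_residues)
  traj <- heating_trajectory(xyz, times, resno = seq_len(p$n_residues),
                             schedule = p$schedule,
                             atom_names = rep("CA", p$n_residues))
  list(traj = traj, reference = ref_c,
       ground_truth = list(t_melt = p$t_melt, folded_rg = rg0,
                           seed = p$seed, params = p))
}
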