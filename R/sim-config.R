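#' Synthetic-session configuration
#'
#' Builds the parameter set for the synthetic miniscope session generator.
#' The generator emulates the statistical structure the downstream analyses
#' assume: spatially clustered co-activation among nearby cells, event rates
#' coupled to locomotor velocity, alternating rest/movement bouts, and
#' GCaMP-like fluorescence transients with additive noise.
#'
#' Defaults describe a typical 30-min open-field session imaged through a
#' GRIN lens: ~60 cells in a 400 x 400 um field, sparse spontaneous events
#' (~0.01 events/s at rest) whose rate grows with running speed, and a few
#' spatial ensembles whose shared drive is stronger at rest than during
#' movement.
#'
#' @param n_cells number of imaged cells.
#' @param fov_width,fov_height field-of-view extent (um).
#' @param duration session length (s).
#' @param acq_rate miniscope acquisition rate (frames/s).
#' @param track_rate behavioral camera rate (frames/s).
#' @param cm_per_px tracking calibration (cm per pixel).
#' @param arena_cm open-field side length (cm).
#' @param n_ensembles number of spatial ensembles.
#' @param ensemble_radius ensemble radius (um); cells within this distance of
#'   an ensemble center are members.
#' @param p_coactivate probability that a member cell fires at an ensemble
#'   event.
#' @param base_rate baseline per-cell event rate (events/s).
#' @param rate_velocity_slope increase in event rate per unit velocity
#'   ((events/s)/(cm/s)).
#' @param rest_shared_drive,move_shared_drive ensemble event rate (events/s)
#'   while the animal is at rest / moving.
#' @param bout_mean_length,rest_mean_length mean movement-bout and rest-epoch
#'   lengths (s); epochs are drawn exponentially.
#' @param mean_move_speed mean running speed during movement (cm/s).
#' @param kernel_rise,kernel_decay rise and decay time constants (s) of the
#'   difference-of-exponentials transient kernel.  The kernel models the
#'   compound (multi-spike burst) event transient, not a single-AP response,
#'   hence the ~1 s decay default.
#' @param noise_sd additive Gaussian noise SD (trace units; unit-amplitude
#'   transients).
#' @param seed integer RNG seed; a fixed seed gives bit-identical sessions.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_cells = 60,
                       fov_width = 400, fov_height = 400,
                       duration = 1800,
                       acq_rate = 20,
                       track_rate = 30,
                       cm_per_px = 0.1,
                       arena_cm = 40,
                       n_ensembles = 3,
                       ensemble_radius = 100,
                       p_coactivate = 0.5,
                       base_rate = 0.02,
                       rate_velocity_slope = 0.0025,
                       rest_shared_drive = 0.15,
                       move_shared_drive = 0.01,
                       bout_mean_length = 7,
                       rest_mean_length = 12,
                       mean_move_speed = 4,
                       kernel_rise = 0.05,
                       kernel_decay = 1.2,
                       noise_sd = 0.075,
                       seed = 1L) {
  cfg <- list(
    n_cells = as.integer(n_cells), fov_width = fov_width,
    fov_height = fov_height, duration = duration, acq_rate = acq_rate,
    track_rate = track_rate, cm_per_px = cm_per_px, arena_cm = arena_cm,
    n_ensembles = as.integer(n_ensembles),
    ensemble_radius = ensemble_radius, p_coactivate = p_coactivate,
    base_rate = base_rate, rate_velocity_slope = rate_velocity_slope,
    rest_shared_drive = rest_shared_drive,
    move_shared_drive = move_shared_drive,
    bout_mean_length = bout_mean_length, rest_mean_length = rest_mean_length,
    mean_move_speed = mean_move_speed, kernel_rise = kernel_rise,
    kernel_decay = kernel_decay, noise_sd = noise_sd, seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  stopifnot(is.list(cfg))
  pos <- c("fov_width", "fov_height", "duration", "acq_rate", "track_rate",
           "cm_per_px", "arena_cm", "ensemble_radius", "bout_mean_length",
           "rest_mean_length", "mean_move_speed", "kernel_rise",
           "kernel_decay")
  for (f in pos) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("sim_config: `", f, "` must be a single positive finite number",
           call. = FALSE)
  }
  nonneg <- c("base_rate", "rate_velocity_slope", "rest_shared_drive",
              "move_shared_drive", "noise_sd")
  for (f in nonneg) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0)
      stop("sim_config: `", f, "` must be a single non-negative number",
           call. = FALSE)
  }
  if (cfg$n_cells < 0L) stop("sim_config: `n_cells` must be >= 0",
                             call. = FALSE)
  if (cfg$n_ensembles < 0L) stop("sim_config: `n_ensembles` must be >= 0",
                                 call. = FALSE)
  if (cfg$p_coactivate < 0 || cfg$p_coactivate > 1)
    stop("sim_config: `p_coactivate` must lie in [0, 1]", call. = FALSE)
  if (!is.finite(cfg$seed)) stop("sim_config: `seed` must be finite",
                                 call. = FALSE)
  cfg
}
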