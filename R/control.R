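#' Control parameters for a spiking neural network decoder
#'
#' Collects every tunable parameter of the decoding pipeline in one place,
#' grouped by stage. All time constants are in milliseconds; distances are in
#' the coordinate units of the brain template (millimetres for the packaged
#' template).
#'
#' @param codec_factor spike-encoding factor `c` for input channels: the
#'   per-channel threshold is `mean(|diff|) + c * sd(|diff|)` over successive
#'   absolute differences. The default (3) keeps input spike trains sparse
#'   and event-locked at realistic noise levels; the codec primitive itself
#'   defaults to 0.5 when called directly.
#' @param codec_factor_targets encoding factor for target channels; smaller
#'   than the input factor so the desired spike trains resolve the target
#'   waveform more finely.
#' @param template list of brain-template settings: `semi_axes` (ellipsoid
#'   semi-axes, mm), `resolution` (grid spacing, mm), `shell_fraction`
#'   (normalised radius separating the "core" from the "shell" region band).
#' @param reservoir list of reservoir settings: `radius_fraction` (small-world
#'   radius as a fraction of the maximum pairwise distance), `p0` and
#'   `lambda_d` (connection probability `p0 * exp(-d / lambda_d)`; `lambda_d
#'   = NULL` means half the small-world radius), `inhibitory_fraction`,
#'   `w_scale` (weight magnitude scale; `NULL` means five times the grid
#'   resolution), `lif_threshold`, `tau_m` (membrane leak, ms),
#'   `refractory_ticks`, and `w_clip` (weight bounds).
#' @param stdp list of plasticity settings: amplitudes `A_plus`, `A_minus`,
#'   window time constants `tau_plus`, `tau_minus` (ms), and `enabled`.
#' @param span list of SPAN settings: `tau_s` (synaptic kernel time constant,
#'   ms), `lambda` (learning rate), `tau` (learning-kernel time constant, ms),
#'   `th_m` (hidden SPAN firing threshold), `max_epochs`,
#'   `match_tolerance` (spike-match tolerance, ms) and `step_cap`
#'   (trust-region bound on the largest per-epoch weight step).
#' @param readout list of output-layer settings: `th_n` (readout firing
#'   threshold on the normalised population current) and `kappa` (validation
#'   retention factor: members below `kappa` times the population's best
#'   accuracy are silenced).
#' @param evaluation list of scoring settings: `max_lag_ms` (cross-correlation
#'   lag window), `smooth_ms` (moving-average window applied to both sides
#'   before correlation) and `tau_s_pop` (alpha-kernel time constant, ms,
#'   used to convolve member spikes into the continuous population trace
#'   that rectified targets are scored against; matched to the envelope
#'   timescale rather than the model's synaptic constant).
#'
#' @return An object of class `snn_control`: a named list of the groups above
#'   with all defaults filled in.
#' @export
#' @examples
#' ctrl <- snn_control()
#' ctrl$span$tau_s
snn_control <- function(codec_factor = 3,
                        codec_factor_targets = 1,
                        template = list(),
                        reservoir = list(),
                        stdp = list(),
                        span = list(),
                        readout = list(),
                        evaluation = list()) {
  defaults <- list(
    codec_factor = codec_factor,
    codec_factor_targets = codec_factor_targets,
    template = list(
      semi_axes = c(60, 80, 50),
      resolution = 15,
      shell_fraction = 0.7
    ),
    reservoir = list(
      radius_fraction = 0.25,
      p0 = 0.8,
      lambda_d = NULL,
      inhibitory_fraction = 0.2,
      w_scale = NULL,
      lif_threshold = 1,
      tau_m = 20,
      refractory_ticks = 5,
      w_clip = c(-0.6, 0.6)
    ),
    stdp = list(
      A_plus = 0.01,
      A_minus = 0.01,
      tau_plus = 20,
      tau_minus = 20,
      enabled = TRUE
    ),
    span = list(
      tau_s = 100,
      lambda = 1,
      tau = 100,
      th_m = 1,
      max_epochs = 100,
      match_tolerance = 20,
      step_cap = 0.05
    ),
    readout = list(
      th_n = 0.5,
      kappa = 0.8
    ),
    evaluation = list(
      max_lag_ms = 100,
      smooth_ms = 50,
      tau_s_pop = 300
    )
  )
  merge_group <- function(name, user) {
    if (!is.list(user))
      stop("'", name, "' must be a list", call. = FALSE)
    bad <- setdiff(names(user), names(defaults[[name]]))
    if (length(bad))
      stop("unknown ", name, " setting(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    utils::modifyList(defaults[[name]], user)
  }
  ctrl <- defaults
  ctrl$template <- merge_group("template", template)
  ctrl$reservoir <- merge_group("reservoir", reservoir)
  ctrl$stdp <- merge_group("stdp", stdp)
  ctrl$span <- merge_group("span", span)
  ctrl$readout <- merge_group("readout", readout)
  ctrl$evaluation <- merge_group("evaluation", evaluation)

  stopifnot(ctrl$template$resolution > 0,
            ctrl$reservoir$radius_fraction > 0,
            ctrl$reservoir$radius_fraction <= 1,
            ctrl$stdp$A_plus > 0, ctrl$stdp$A_minus > 0,
            ctrl$stdp$tau_plus > 0, ctrl$stdp$tau_minus > 0,
            ctrl$span$tau_s > 0, ctrl$span$tau > 0, ctrl$span$lambda > 0,
            ctrl$span$th_m > 0, ctrl$span$max_epochs >= 1,
            ctrl$readout$th_n > 0,
            ctrl$readout$kappa >= 0, ctrl$readout$kappa <= 1)
  class(ctrl) <- "snn_control"
  ctrl
}
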