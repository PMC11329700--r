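#' Simulate pHluorin traces with known decay kinetics and bleaching
#'
#' Each trace follows the surface-fluorescence model of a pHluorin
#' exo/endocytosis experiment: a flat baseline for `baseline_s` seconds, a
#' step rise of `amplitude` at the stimulus, then a single-exponential
#' decay toward an incomplete-recovery plateau,
#' `F(t) = baseline + amplitude * ((1 - plateau) * exp(-(t - t_stim)/tau)
#' + plateau)`, multiplied by a photobleaching factor `exp(-K * t)` and
#' overlaid with additive Gaussian noise.
#'
#' @param config a [sim_config()] (its `frame_rate` sets the sampling).
#' @param n_traces number of traces (boutons).
#' @param tau decay time constant, s.
#' @param plateau plateau fraction in `[0, 1)`; 0 = complete recovery.
#' @param bleach_K photobleaching rate constant, 1/s.
#' @param noise_sd additive Gaussian noise SD, in intensity units (with
#'   the default `amplitude` of 1, a fraction of the stimulus-evoked
#'   rise).
#' @param duration_s trace length, s.
#' @param baseline_s pre-stimulus baseline duration, s.
#' @param baseline,amplitude baseline level and stimulus-evoked rise;
#'   `amplitude = 0` generates a no-stimulation (bleach-control) trace.
#' @return list with `traces` (list of [fluor_trace()]) and `truth`
#'   (data.frame with tau, plateau, bleach_K, noise_sd per trace).
#' @examples
#' sim <- gen_phluorin_traces(sim_config(1), n_traces = 2, tau = 15,
#'                            plateau = 0.3, bleach_K = 0.005,
#'                            noise_sd = 0.05)
#' sim$traces[[1]]
#' @export
gen_phluorin_traces <- function(config, n_traces, tau = 15, plateau = 0.3,
                                bleach_K = 0.005, noise_sd = 0.05,
                                duration_s = 60, baseline_s = 5,
                                baseline = 1, amplitude = 1) {
  config <- as_sim_config(config)
  stopifnot(n_traces >= 1, tau > 0, plateau >= 0, plateau < 1,
            bleach_K >= 0, duration_s > baseline_s, baseline > 0,
            amplitude >= 0)
  if (noise_sd < 0) stop("noise_sd must be nonnegative", call. = FALSE)

  n_frames <- round(duration_s * config$frame_rate)
  t <- (seq_len(n_frames) - 1) / config$frame_rate
  stimulus_frame <- floor(baseline_s * config$frame_rate) + 1L
  t_stim <- t[stimulus_frame]
  model <- ifelse(
    t < t_stim,
    baseline,
    baseline + amplitude *
      ((1 - plateau) * exp(-(t - t_stim) / tau) + plateau)
  )
  model <- model * exp(-bleach_K * t)

  with_seed(config$seed, {
    traces <- lapply(seq_len(n_traces), function(i) {
      fluor_trace(model + rnorm(n_frames, 0, noise_sd),
                  config$frame_rate, stimulus_frame)
    })
    list(
      traces = traces,
      truth = data.frame(
        trace = seq_len(n_traces), tau = tau, plateau = plateau,
        bleach_K = bleach_K, noise_sd = noise_sd,
        stimulus_frame = stimulus_frame
      )
    )
  })
}
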