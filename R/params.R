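#' Artifact generator parameters
#'
#' Amplitudes are in microvolts. Defaults follow the acquisition the
#' simulator emulates: a multiband EPI sequence with TR = 1.1 s and 64 slices
#' acquired in multiband groups of 4, i.e. 16 slice excitations per volume
#' (slice frequency 16/1.1 = 14.5 Hz, volume frequency 1/1.1 Hz); an imaging
#' artifact reaching tens of mV after acquisition filtering; a heartbeat-locked
#' BCG artifact exceeding 50 uV with its power below 25 Hz; and helium-pump
#' vibration harmonics at and above 30 Hz.
#'
#' @param slice_freq_hz Slice excitation frequency (Hz).
#' @param volume_freq_hz Volume repetition frequency (Hz).
#' @param n_harmonics_slice,n_harmonics_volume Harmonic counts of the imaging
#'   artifact families (slice harmonics k = 1..Ks convolved with volume
#'   sidebands m = 0..Kv).
#' @param imaging_amp Peak imaging-artifact amplitude (uV) on a gain-1 channel.
#' @param bcg_amp Peak BCG template amplitude (uV); > 50 uV by default.
#' @param bcg_components Data frame of Gaussian-windowed oscillations making up
#'   the beat template: columns `freq_hz`, `center_s`, `width_s`, `amp` (rel.).
#'   Support stays within [-0.2, 0.5] s around the delayed beat anchor.
#' @param bcg_delay_s Pulse-arrival delay from the ECG R peak to the BCG
#'   template center of mass (s).
#' @param beat_amp_cv Coefficient of variation of per-beat amplitude jitter.
#' @param beat_latency_sd_ms SD of per-beat latency jitter (ms).
#' @param pump_f0_hz Helium-pump fundamental (Hz, must be >= 30).
#' @param pump_harmonics Number of pump harmonics.
#' @param pump_amp Pump artifact RMS amplitude (uV) on a gain-1 channel.
#' @param pump_am_depth Depth of the slow random amplitude modulation.
#' @param motion_amp Peak amplitude (uV) of band-limited (1-25 Hz) motion
#'   bursts coupled into scalp and loop channels during tapping blocks.
#' @return A list of class `artifact_params`.
#' @export
artifact_params <- function(slice_freq_hz = 16 / 1.1,
                            volume_freq_hz = 1 / 1.1,
                            n_harmonics_slice = 5,
                            n_harmonics_volume = 2,
                            imaging_amp = 20000,
                            bcg_amp = 150,
                            bcg_components = data.frame(
                              freq_hz = c(4.5, 10.5, 3),
                              center_s = c(0.00, 0.17, 0.30),
                              width_s = c(0.10, 0.12, 0.11),
                              amp = c(0.8, 1.3, -0.5)
                            ),
                            bcg_delay_s = 0.21,
                            beat_amp_cv = 0.15,
                            beat_latency_sd_ms = 5,
                            pump_f0_hz = 42,
                            pump_harmonics = 3,
                            pump_amp = 8,
                            pump_am_depth = 0.1,
                            motion_amp = 30) {
  if (pump_f0_hz < 30) {
    abort("pump_f0_hz must be >= 30 Hz (vibration artifacts reside at high frequencies).")
  }
  if (bcg_amp < 0 || imaging_amp < 0) abort("amplitudes must be non-negative.")
  structure(as.list(environment()), class = "artifact_params")
}

#' Neural signal generator parameters
#'
#' Amplitudes are RMS microvolts of the underlying band-limited oscillations
#' (except the VEP peak amplitudes, which are waveform peaks in uV). The
#' defaults encode the response patterns the evaluation tasks elicit:
#' eyes-closed occipital alpha well above eyes-open alpha; finger-tapping
#' desynchronization (amplitude scaled by `1 - depth` during tapping) in the
#' mu-alpha and beta bands with a gamma burst at movement onset; and a
#' biphasic visual evoked response with a positive peak near 120 ms and a
#' negative peak near 175 ms, lateralized to the hemisphere contralateral to
#' the stimulated hemifield.
#'
#' @param alpha_eo,alpha_ec Occipital alpha RMS amplitude (uV) in eyes-open /
#'   eyes-closed blocks. EC must exceed EO.
#' @param mu_amp,beta_amp Pericentral mu-alpha (8-12 Hz) and beta (15-25 Hz)
#'   RMS amplitudes (uV) at rest.
#' @param erd_alpha,erd_beta Desynchronization depths in (0, 1]: oscillation
#'   amplitude is multiplied by `1 - depth` during tapping blocks.
#' @param gamma_amp Baseline gamma (70-80 Hz) RMS amplitude (uV).
#' @param ers_gamma Gamma synchronization gain: amplitude multiplied by
#'   `1 + ers_gamma` during the first second of each tapping block.
#' @param vep_p1,vep_n1 VEP kernel peak amplitudes (uV) at ~120 and ~175 ms.
#' @param pink_level RMS (uV) of per-channel 1/f background activity.
#' @return A list of class `neural_params`.
#' @export
neural_params <- function(alpha_eo = 5, alpha_ec = 15,
                          mu_amp = 6, beta_amp = 4,
                          erd_alpha = 0.7, erd_beta = 0.5,
                          gamma_amp = 0.8, ers_gamma = 1.5,
                          vep_p1 = 5, vep_n1 = -6,
                          pink_level = 2) {
  if (alpha_ec <= alpha_eo) abort("alpha_ec must exceed alpha_eo.")
  if (erd_alpha <= 0 || erd_alpha > 1 || erd_beta <= 0 || erd_beta > 1) {
    abort("ERD depths must lie in (0, 1].")
  }
  structure(as.list(environment()), class = "neural_params")
}

#' Session configuration for the synthetic EEG-fMRI generator
#'
#' Defines one simulated acquisition. The defaults are the acquisition-scale
#' conditions the simulator emulates (5 kHz sampling, TR = 1.1 s); study-level
#' drivers such as [run_study()] override sizes for desk-scale runtime.
#' `seed` fixes all downstream randomness of the session.
#'
#' @param task `"resting"`, `"tapping"` or `"checkerboard"`.
#' @param seed Integer seed controlling every random draw in the session.
#' @param fs_hz Sampling rate (Hz). `fs_hz * tr_s` must be an integer.
#' @param tr_s Volume repetition time (s).
#' @param n_slices_per_tr Slice excitations per volume (after multiband
#'   grouping).
#' @param n_channels Number of scalp channels (layout prefix, default 32).
#' @param n_blocks Resting: number of alternating EO/EC blocks. Tapping:
#'   number of tapping blocks.
#' @param block_s Resting block duration (s).
#' @param n_trials Checkerboard: trials per quadrant condition.
#' @param hr_mean_bpm,hr_sd_bpm Heart-rate mean and between-beat SD (bpm).
#' @param sensor_noise_sd White sensor-noise SD (uV) added to every channel.
#' @param artifact An [artifact_params()] object.
#' @param neural A [neural_params()] object.
#' @param cwl_noise_sd Sensor-noise SD (uV) on the carbon-wire loops.
#' @param lead_in_s Quiet lead-in before the first task event (s).
#' @param volume_marker Label used for volume (TR) markers.
#' @return A list of class `session_config`.
#' @export
session_config <- function(task = c("resting", "tapping", "checkerboard"),
                           seed = 1L,
                           fs_hz = 5000, tr_s = 1.1, n_slices_per_tr = 16,
                           n_channels = 32,
                           n_blocks = if (match.arg(task) == "resting") 22 else 60,
                           block_s = 40,
                           n_trials = 42,
                           hr_mean_bpm = 65, hr_sd_bpm = 3,
                           sensor_noise_sd = 1,
                           artifact = artifact_params(
                             slice_freq_hz = n_slices_per_tr / tr_s,
                             volume_freq_hz = 1 / tr_s
                           ),
                           neural = neural_params(),
                           cwl_noise_sd = 1,
                           lead_in_s = 4,
                           volume_marker = "R128") {
  task <- match.arg(task)
  if (tr_s <= 0) abort("tr_s must be positive.")
  if (fs_hz <= 0) abort("fs_hz must be positive.")
  if (abs(fs_hz * tr_s - round(fs_hz * tr_s)) > 1e-9) {
    abort("fs_hz * tr_s must be an integer number of samples per TR.")
  }
  if (!is_count(seed)) abort("seed must be a non-negative integer.")
  structure(as.list(environment()), class = "session_config")
}
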