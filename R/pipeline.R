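#' Configuration of a synthetic evaluation study
#'
#' Defines a multi-participant simulated comparison of the artifact-reduction
#' variants. Simulated participants differ by seed-controlled draws of heart
#' rate and of neural/artifact amplitude multipliers, populating the second
#' level of the hierarchical models. The defaults are desk-scale: 8
#' participants, 10 alternating 10-s eyes-open/eyes-closed blocks, sessions
#' generated at 500 Hz (the rate the spectral analysis operates at);
#' acquisition-scale sessions remain available through the `session`
#' overrides.
#'
#' @param n_participants Number of simulated participants.
#' @param seed Study master seed; fixes participant seeds and model seeds.
#' @param task Task simulated for every participant.
#' @param fs_hz,tr_s,n_channels,n_blocks,block_s,n_trials Passed to
#'   [session_config()].
#' @param artifact_scale Multiplier on all artifact amplitudes (0 gives an
#'   artifact-free null study).
#' @param hr_sd_between Between-participant SD of mean heart rate (bpm).
#' @param amp_cv Between-participant log-scale SD of the neural and BCG
#'   amplitude multipliers.
#' @param z_threshold Summary-channel selection threshold (SD units).
#' @param chains,warmup,draws MCMC settings for the evaluation models.
#' @return A list of class `study_config`.
#' @export
study_config <- function(n_participants = 8, seed = 1L,
                         task = c("resting", "tapping", "checkerboard"),
                         fs_hz = 500, tr_s = 1.1, n_channels = 32,
                         n_blocks = 10, block_s = 10, n_trials = 8,
                         artifact_scale = 1,
                         hr_sd_between = 6, amp_cv = 0.2,
                         z_threshold = 1,
                         chains = 4, warmup = 1000, draws = 1000) {
  task <- match.arg(task)
  if (n_participants < 2) abort("a study needs at least 2 participants.")
  structure(as.list(environment()), class = "study_config")
}

# participant-specific session config drawn from the study config
participant_session_config <- function(cfg, j) {
  pseed <- child_seed(cfg$seed, 10 + j)
  with_local_seed(child_seed(pseed, 1), {
    hr <- max(45, rnorm(1, 65, cfg$hr_sd_between))
    bcg_mult <- exp(rnorm(1, 0, cfg$amp_cv))
    alpha_mult <- exp(rnorm(1, 0, cfg$amp_cv))
    pump_mult <- exp(rnorm(1, 0, cfg$amp_cv))
  })
  session_config(
    task = cfg$task, seed = pseed, fs_hz = cfg$fs_hz, tr_s = cfg$tr_s,
    n_channels = cfg$n_channels, n_blocks = cfg$n_blocks,
    block_s = cfg$block_s, n_trials = cfg$n_trials,
    hr_mean_bpm = hr, hr_sd_bpm = 3,
    artifact = artifact_params(
      slice_freq_hz = 16 / cfg$tr_s, volume_freq_hz = 1 / cfg$tr_s,
      imaging_amp = 20000 * cfg$artifact_scale,
      bcg_amp = 150 * bcg_mult * cfg$artifact_scale,
      pump_amp = 8 * pump_mult * cfg$artifact_scale,
      motion_amp = 30 * cfg$artifact_scale
    ),
    neural = neural_params(alpha_eo = 5 * alpha_mult,
                           alpha_ec = 15 * alpha_mult)
  )
}

#' Per-block band power features of a resting-state session
#'
#' Computes, for each variant, the mean alpha-band PSD of every block on a
#' summary channel selected from the reference data: the per-channel
#' eyes-closed minus eyes-open alpha power difference is standardized over
#' channels and channels exceeding `z_threshold` SDs form the summary set;
#' per block, per-channel Welch PSDs are averaged bin-wise in dB over that
#' set and the alpha band mean extracted.
#'
#' @param variants Named list of recordings (from [session_variants()]).
#' @param session The [assemble_session()] result the variants came from.
#' @param band A one-row [band_definition()] tibble (default alpha).
#' @param z_threshold Summary-channel selection threshold (default 1).
#' @param nperseg Welch segment length (default 4096).
#' @return List: `features` tibble (`block`, `condition`, `variant`,
#'   `power_db`), `summary_channels`, `delta_topography`.
#' @export
resting_band_features <- function(variants, session,
                                  band = band_definition("alpha"),
                                  z_threshold = 1, nperseg = 4096) {
  fs <- session$recording$fs
  events <- session$ground_truth$events
  block_s <- session$ground_truth$config$block_s
  scalp <- channels_with_role(session$recording, "scalp")
  labels <- session$recording$channel_labels[scalp]

  block_psd <- function(rec, ev_sample) {
    i_scalp <- channels_with_role(rec, "scalp")
    a <- ev_sample + 1L
    b <- min(a + round(block_s * fs) - 1L, n_samples(rec))
    welch_psd(rec$data[i_scalp, a:b, drop = FALSE], fs, nperseg = nperseg,
              channel_labels = rec$channel_labels[i_scalp])
  }

  # summary-channel selection on the reference data topography
  ref <- variants$REF
  ref_band <- vapply(seq_len(nrow(events)), function(i) {
    band_mean_power(block_psd(ref, events$sample[i]), band)
  }, numeric(length(labels)))
  d_topo <- rowMeans(ref_band[, events$condition == "EC", drop = FALSE]) -
    rowMeans(ref_band[, events$condition == "EO", drop = FALSE])
  names(d_topo) <- labels
  sel <- select_summary_channels(d_topo, z_threshold = z_threshold, sign = 1)
  if (length(sel) == 0) sel <- names(sort(d_topo, decreasing = TRUE))[1:3]

  rows <- purrr::map_dfr(names(variants), function(v) {
    rec <- variants[[v]]
    purrr::map_dfr(seq_len(nrow(events)), function(i) {
      psd <- block_psd(rec, events$sample[i])
      val <- band_mean_power(summary_channel_psd(psd, sel), band)
      tibble::tibble(block = i, condition = events$condition[i],
                     variant = v, power_db = unname(val))
    })
  })
  list(features = rows, summary_channels = sel, delta_topography = d_topo)
}

#' Per-trial band power differences of a finger-tapping session
#'
#' For each variant and tapping trial, the difference between the response
#' and baseline mean band PSD (response 0-3 s vs baseline -3-0 s for alpha
#' and beta; 0-1 s vs -1-0 s for gamma) on band-specific summary channels
#' selected from the reference grand-average difference topography
#' (z-threshold 2, negative sign for the desynchronizing bands).
#'
#' @inheritParams resting_band_features
#' @param bands A [band_definition()] tibble of bands to extract.
#' @return List: `features` tibble (`trial`, `band`, `variant`, `dpsd_db`),
#'   `summary_channels` (per band).
#' @export
tapping_band_features <- function(variants, session,
                                  bands = band_definition(),
                                  nperseg = 4096) {
  fs <- session$recording$fs
  events <- session$ground_truth$events
  win <- function(band) if (band == "gamma") 1 else 3
  sgn <- function(band) if (band == "gamma") 1 else -1

  seg_psd <- function(rec, sample0, from_s, to_s) {
    i_scalp <- channels_with_role(rec, "scalp")
    a <- sample0 + round(from_s * fs) + 1L
    b <- sample0 + round(to_s * fs)
    welch_psd(rec$data[i_scalp, a:b, drop = FALSE], fs, nperseg = nperseg,
              channel_labels = rec$channel_labels[i_scalp])
  }
  ok <- events$sample + round(3 * fs) <= n_samples(session$recording) &
    events$sample - round(3 * fs) >= 0
  events <- events[ok, , drop = FALSE]

  out_sel <- list()
  rows <- purrr::map_dfr(seq_len(nrow(bands)), function(bi) {
    band <- bands[bi, ]
    w <- win(band$name)
    # reference topography for the summary channels
    ref_d <- purrr::map(seq_len(nrow(events)), function(i) {
      band_mean_power(seg_psd(variants$REF, events$sample[i], 0, w), band) -
        band_mean_power(seg_psd(variants$REF, events$sample[i], -w, 0), band)
    })
    topo <- Reduce(`+`, ref_d) / length(ref_d)
    sel <- select_summary_channels(topo, z_threshold = 2, sign = sgn(band$name))
    if (length(sel) == 0) {
      sel <- names(sort(sgn(band$name) * topo, decreasing = TRUE))[1:2]
    }
    out_sel[[band$name]] <<- sel
    purrr::map_dfr(names(variants), function(v) {
      purrr::map_dfr(seq_len(nrow(events)), function(i) {
        resp <- band_mean_power(
          summary_channel_psd(seg_psd(variants[[v]], events$sample[i], 0, w), sel), band)
        base <- band_mean_power(
          summary_channel_psd(seg_psd(variants[[v]], events$sample[i], -w, 0), sel), band)
        tibble::tibble(trial = i, band = band$name, variant = v,
                       dpsd_db = unname(resp - base))
      })
    })
  })
  list(features = rows, summary_channels = out_sel)
}

#' Evoked-response features of a checkerboard session
#'
#' Epochs every variant from -200 to 500 ms, forms contralateral/ipsilateral
#' summary signals from the layout hemispheres, and extracts per-trial mean
#' amplitudes in the difference-wave windows (D1 70-100 ms, D2 130-170 ms),
#' trial-level and average-ERP RMS-ratio SNR at the P1 (100-140 ms) and N1
#' (150-200 ms) peaks, and the RMSD between each variant's average response
#' and the reference response.
#'
#' @inheritParams resting_band_features
#' @param n_summary Channels per hemisphere in the summary sets (default 7).
#' @return List of tibbles: `amplitudes` (trial-level, with `side`),
#'   `snr` (per variant/peak/level), `similarity` (per variant/condition
#'   `rmsd_uv`), `difference_waves`.
#' @export
vep_features <- function(variants, session, n_summary = 7) {
  fs <- session$recording$fs
  layout <- session$ground_truth$layout
  ev <- session$ground_truth$events
  hemi <- list(
    left = layout$label[layout$hemisphere == "left" & layout$y < -0.4],
    right = layout$label[layout$hemisphere == "right" & layout$y < -0.4]
  )
  if (length(hemi$left) == 0 || length(hemi$right) == 0) {
    abort("layout lacks posterior channels in one hemisphere; use more channels.")
  }
  # time-domain analyses exclude NC (imaging residuals dominate otherwise)
  vnames <- setdiff(names(variants), "NC")

  scalp_only <- function(rec) {
    i <- channels_with_role(rec, "scalp")
    new_recording(rec$data[i, , drop = FALSE], rec$fs, rec$channel_labels[i],
                  rep("scalp", length(i)), rec$reference)
  }
  ep <- lapply(vnames, function(v) {
    epoch_data(scalp_only(variants[[v]]), ev, -0.2, 0.5)
  })
  names(ep) <- vnames

  # summary channels per hemisphere from the reference difference topography
  waves_ref <- contra_ipsi_waves(ep$REF, hemi)
  pick <- function(window_ms, sign) {
    lf <- ep$REF$events$condition %in% c("LU", "LL")
    erp_l <- apply(ep$REF$data[lf, , , drop = FALSE], c(2, 3), mean)
    erp_r <- apply(ep$REF$data[!lf, , , drop = FALSE], c(2, 3), mean)
    amp <- function(erp) {
      v <- apply(erp, 1, window_mean_amplitude, window_ms = window_ms,
                 fs = fs, t0_s = -0.2)
      names(v) <- ep$REF$channel_labels
      v
    }
    # contralateral topography: right hemisphere for left-field stimuli
    list(
      left_field = utils::head(intersect(
        names(sort(sign * amp(erp_l), decreasing = TRUE)), hemi$right), n_summary),
      right_field = utils::head(intersect(
        names(sort(sign * amp(erp_r), decreasing = TRUE)), hemi$left), n_summary)
    )
  }
  sel_d1 <- pick(c(70, 100), 1)
  sel_d2 <- pick(c(130, 170), -1)

  chan_mean <- function(e, i, labels) {
    idx <- match(labels, e$channel_labels)
    m <- e$data[i, idx, , drop = FALSE]
    dim(m) <- dim(m)[2:3]
    colMeans(m)
  }
  trial_amp <- function(e, window_ms, sel) {
    purrr::map_dfr(seq_len(dim(e$data)[1]), function(i) {
      left_field <- e$events$condition[i] %in% c("LU", "LL")
      # contra set: hemisphere opposite the stimulated field; ipsi: same side
      sets <- if (left_field) {
        list(contra = sel$left_field, ipsi = sel$right_field)
      } else {
        list(contra = sel$right_field, ipsi = sel$left_field)
      }
      sig_c <- chan_mean(e, i, sets$contra)
      sig_i <- chan_mean(e, i, sets$ipsi)
      tibble::tibble(
        trial = i, condition = e$events$condition[i],
        side = c("contra", "ipsi"),
        amplitude_uv = c(window_mean_amplitude(sig_c, window_ms, fs, -0.2),
                         window_mean_amplitude(sig_i, window_ms, fs, -0.2))
      )
    })
  }

  amp_rows <- purrr::map_dfr(vnames, function(v) {
    dplyr::bind_rows(
      dplyr::mutate(trial_amp(ep[[v]], c(70, 100), sel_d1), window = "D1"),
      dplyr::mutate(trial_amp(ep[[v]], c(130, 170), sel_d2), window = "D2")
    ) |> dplyr::mutate(variant = v)
  })

  # SNR on the all-trial summary channel (both hemisphere sets combined)
  sum_set <- unique(c(sel_d1$left_field, sel_d1$right_field,
                      sel_d2$left_field, sel_d2$right_field))
  snr_rows <- purrr::map_dfr(vnames, function(v) {
    e <- ep[[v]]
    idx <- match(sum_set, e$channel_labels)
    trials <- apply(e$data[, idx, , drop = FALSE], c(1, 3), mean)
    erp <- colMeans(trials)
    per_peak <- function(win, peak) {
      snr_t <- mean(apply(trials, 1, function(x) {
        snr_rms(x, win, c(-200, 0), fs, -0.2)
      }))
      tibble::tibble(
        variant = v, peak = peak,
        level = c("trial", "average"),
        snr = c(snr_t, snr_rms(erp, win, c(-200, 0), fs, -0.2))
      )
    }
    dplyr::bind_rows(per_peak(c(100, 140), "P1"), per_peak(c(150, 200), "N1"))
  })

  sim_rows <- purrr::map_dfr(setdiff(vnames, "REF"), function(v) {
    purrr::map_dfr(c("LU", "LL", "RU", "RL"), function(cond) {
      avg <- function(e) {
        sel <- e$events$condition == cond
        idx <- match(sum_set, e$channel_labels)
        colMeans(apply(e$data[sel, idx, , drop = FALSE], c(1, 3), mean))
      }
      a <- avg(ep[[v]]); b <- avg(ep$REF)
      keep <- seq(round(0.2 * fs) + 1, length(a))   # 0-500 ms
      tibble::tibble(variant = v, condition = cond,
                     rmsd_uv = rmsd(a[keep], b[keep]))
    })
  })

  list(amplitudes = amp_rows, snr = snr_rows, similarity = sim_rows,
       difference_waves = waves_ref,
       summary_channels = list(d1 = sel_d1, d2 = sel_d2, snr = sum_set))
}

#' Run the full synthetic evaluation study
#'
#' Simulates every participant's session, derives the reference signal and
#' the five MR variants, extracts the task's evaluation features, fits the
#' hierarchical comparison model and assembles an evaluation report. For the
#' resting task the model is the two-level regression of per-block alpha
#' power on condition, variant and their interaction; the reported
#' eyes-closed minus eyes-open power difference per variant is the condition
#' effect plus the matching interaction.
#'
#' @param cfg A [study_config()].
#' @return A list of class `evaluation_report`: `features`, `fit`,
#'   `delta_psd` (per-variant posterior summaries with `p_positive`),
#'   `ordering` (adjacent pairwise ordering probabilities), `gt_error`
#'   (per-participant RMS error against the clean signal), `diagnostics`,
#'   `summary_channels`, `config`.
#' @export
run_study <- function(cfg) {
  stopifnot(inherits(cfg, "study_config"))
  if (cfg$task != "resting") {
    abort("run_study currently drives the resting-state comparison; use the task feature extractors directly for the other paradigms.")
  }
  all_feats <- list()
  gt_err <- list()
  sel_list <- list()
  for (j in seq_len(cfg$n_participants)) {
    scfg <- participant_session_config(cfg, j)
    session <- assemble_session(scfg)
    variants <- session_variants(session)
    fx <- resting_band_features(variants, session, z_threshold = cfg$z_threshold)
    all_feats[[j]] <- dplyr::mutate(fx$features, participant = j)
    sel_list[[j]] <- fx$summary_channels
    clean <- variants$REF$data
    gt_err[[j]] <- purrr::map_dfr(
      setdiff(names(variants), "REF"), function(v) {
        i_scalp <- channels_with_role(variants[[v]], "scalp")
        tibble::tibble(participant = j, variant = v,
                       rms_error_uv = rms(variants[[v]]$data[i_scalp, ] - clean))
      })
    rm(session, variants); gc(verbose = FALSE)
    log_msg("info", sprintf("participant %d/%d done", j, cfg$n_participants))
  }
  features <- dplyr::bind_rows(all_feats)

  vlev <- c("REF", "CWL", "AAS", "OBS", "IAR", "NC")
  fdat <- dplyr::mutate(features,
                        variant = factor(.data$variant, levels = vlev),
                        ec = as.numeric(.data$condition == "EC"))
  X <- stats::model.matrix(~ ec * variant, data = fdat)
  spec <- model_spec(fdat$power_db, X, fdat$participant,
                     method = as.character(fdat$variant),
                     resid_structure = "per_method")
  fit <- fit_two_level_model(spec, chains = cfg$chains, warmup = cfg$warmup,
                             draws = cfg$draws,
                             seed = child_seed(cfg$seed, 999))
  dm <- draws_matrix(fit)
  cn <- colnames(X)
  ec_col <- match("ec", cn)
  dpsd_draws <- lapply(vlev, function(v) {
    d <- dm[, sprintf("beta[%d]", ec_col)]
    int <- match(sprintf("ec:variant%s", v), cn)
    if (!is.na(int)) d <- d + dm[, sprintf("beta[%d]", int)]
    d
  })
  names(dpsd_draws) <- vlev
  delta_psd <- purrr::map_dfr(vlev, function(v) {
    s <- summarize_posterior(dpsd_draws[[v]])
    dplyr::mutate(s, variant = v,
                  p_positive = mean(dpsd_draws[[v]] > 0), .before = 1)
  })
  ord <- c("NC", "IAR", "OBS", "AAS", "CWL", "REF")
  ordering <- purrr::map_dfr(seq_len(length(ord) - 1), function(i) {
    tibble::tibble(
      left = ord[i], right = ord[i + 1],
      p_right_higher = mean(dpsd_draws[[ord[i + 1]]] > dpsd_draws[[ord[i]]])
    )
  })
  structure(list(
    features = features, fit = fit, delta_psd = delta_psd,
    ordering = ordering, gt_error = dplyr::bind_rows(gt_err),
    diagnostics = fit$diagnostics, summary_channels = sel_list,
    config = cfg
  ), class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> %d participants, task %s\n",
              x$config$n_participants, x$config$task))
  cat("eyes-closed minus eyes-open alpha power (dB), posterior medians:\n")
  print(as.data.frame(x$delta_psd[, c("variant", "median", "l95", "u95",
                                      "p_positive")]), row.names = FALSE)
  invisible(x)
}
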