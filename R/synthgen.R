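#' Synthetic EEG cohort configuration
#'
#' The generator emulates the statistical structure the decoding pipeline
#' assumes: a 1/f background, mu (~10 Hz) and beta (~20 Hz) sensorimotor
#' rhythms over C3/C4 with contralateral event-related desynchronization
#' (ERD) during left/right motor imagery, and frustration-dependent
#' broadband beta/gamma power gains (low < mid, low < high). Frustration
#' additionally degrades the ERD contrast and rotates the sensorimotor
#' source topography, so the optimal MI decoder differs by state. The
#' induction protocol follows the 80/65/50% success-rate design with
#' 7-point Likert self-reports.
#'
#' @param n_subjects Number of simulated subjects.
#' @param channels Channel labels; must include C3 and C4.
#' @param rate Sampling rate, Hz.
#' @param trial_len_s Trial length, seconds.
#' @param trials_per_class_stage1 Stage-1 (calibration) trials per MI class
#'   per subject.
#' @param trials_per_state_class Stage-2 trials per (state x MI class) per
#'   subject.
#' @param mi_erd_depth Fractional mu/beta power reduction contralateral to
#'   the imagined hand, in `[0, 1]`.
#' @param erd_state_scale Multiplier on `mi_erd_depth` per state
#'   (low, mid, high): frustration weakens the ERD contrast.
#' @param state_rotation_deg Rotation (degrees) of the two sensorimotor
#'   sources within the C3/C4 plane per state; makes the MI signature
#'   state-dependent.
#' @param state_gain_beta,state_gain_gamma Multiplicative broadband power
#'   factors per state for the beta and gamma bands. The gains act on the
#'   sensorimotor channels (C3/Cz/C4) while other channels keep the baseline
#'   level, giving the state contrast the spatial structure a CSP-based
#'   decoder relies on (normalized log-variance features are invariant to
#'   spatially uniform gains).
#' @param state_gain_theta Per-state power factors for a 2-8 Hz component
#'   over the lateral sensorimotor channels C3/C4 (strongest under low
#'   frustration, as in the evoked spectra the generator emulates); on Oz
#'   the same component is weighted by `rev(state_gain_theta)` (occipital
#'   low-frequency activity strongest under high frustration). Cz keeps the
#'   baseline broadband level and carries the midline theta oscillation
#'   instead, so the three states differ in spatial pattern, not just
#'   overall power.
#' @param theta_noise_uv Baseline RMS of the 2-8 Hz component, microvolts.
#' @param fm_theta_uv Frontal-midline theta (6 Hz, at Cz) base amplitude;
#'   its per-state scale `fm_theta_state_scale` grows with frustration, the
#'   classic midline-theta correlate of negative affect.
#' @param fm_theta_state_scale Per-state amplitude scale of the midline
#'   theta oscillation.
#' @param alpha_state_scale Per-state amplitude scale of the occipital alpha
#'   rhythm (mildly suppressed under high frustration/arousal).
#' @param noise_exponent 1/f^a background exponent.
#' @param noise_uv Background RMS amplitude, microvolts.
#' @param mu_amp_uv,beta_amp_uv Sensorimotor rhythm amplitudes, microvolts.
#' @param beta_noise_uv,gamma_noise_uv Baseline broadband component RMS,
#'   microvolts.
#' @param alpha_oz_uv Occipital alpha amplitude at Oz, microvolts.
#' @param success_rates Feedback success probability per condition
#'   (low, mid, high frustration).
#' @param likert_means,likert_sds Self-report rating distribution per
#'   condition (7-point scale).
#' @param blocks_per_condition Rated blocks per condition per subject.
#' @param seed Master seed; every draw derives from it.
#' @return A validated `synth_config`.
#' @export
synth_config <- function(n_subjects = 12,
                         channels = c("C3", "Cz", "C4", "Oz"),
                         rate = 1000, trial_len_s = 4,
                         trials_per_class_stage1 = 100,
                         trials_per_state_class = 30,
                         mi_erd_depth = 0.5,
                         erd_state_scale = c(1, 0.85, 0.7),
                         state_rotation_deg = c(0, 60, 120),
                         state_gain_beta = c(1, 1.3, 1.6),
                         state_gain_gamma = c(1, 1.35, 1.65),
                         state_gain_theta = c(1.8, 1.3, 1),
                         noise_exponent = 1, noise_uv = 9,
                         mu_amp_uv = 5, beta_amp_uv = 2.5,
                         beta_noise_uv = 3, gamma_noise_uv = 3.5,
                         theta_noise_uv = 5,
                         fm_theta_uv = 5,
                         fm_theta_state_scale = c(0.5, 1, 1.5),
                         alpha_state_scale = c(1.15, 1, 0.85),
                         alpha_oz_uv = 4,
                         success_rates = c(0.80, 0.65, 0.50),
                         likert_means = c(2.1, 3.5, 4.8),
                         likert_sds = c(0.8, 1.4, 1.2),
                         blocks_per_condition = 1,
                         seed = 1) {
  assert_that(all(c("C3", "C4") %in% norm_channel(channels)),
              "channels must include C3 and C4")
  assert_that(rate > 0 && trial_len_s > 0, "rate and trial length must be positive")
  assert_that(mi_erd_depth >= 0 && mi_erd_depth <= 1,
              "mi_erd_depth must be in [0, 1]")
  assert_that(all(success_rates > 0 & success_rates <= 1),
              "success rates must lie in (0, 1]")
  assert_that(all(state_gain_beta > 0) && all(state_gain_gamma > 0),
              "state gains must be positive")
  assert_that(length(erd_state_scale) == 3 && length(state_rotation_deg) == 3 &&
                length(state_gain_beta) == 3 && length(state_gain_gamma) == 3 &&
                length(state_gain_theta) == 3 &&
                length(fm_theta_state_scale) == 3 && length(alpha_state_scale) == 3,
              "per-state parameters need one value per state")
  structure(as.list(environment()), class = "synth_config")
}

#' Zero-effect configuration
#'
#' Same signal model with every state- and MI-dependent effect switched off;
#' every decoder should fall to chance on such a cohort.
#'
#' @param ... Overrides passed to [synth_config()].
#' @export
null_synth_config <- function(...) {
  args <- list(...)
  args$mi_erd_depth <- 0
  args$erd_state_scale <- c(1, 1, 1)
  args$state_rotation_deg <- c(0, 0, 0)
  args$state_gain_beta <- c(1, 1, 1)
  args$state_gain_gamma <- c(1, 1, 1)
  args$state_gain_theta <- c(1, 1, 1)
  args$fm_theta_state_scale <- c(1, 1, 1)
  args$alpha_state_scale <- c(1, 1, 1)
  do.call(synth_config, args)
}

# 1/f^a noise via spectral shaping of white noise, unit RMS
one_over_f <- function(n, exponent) {
  x <- stats::rnorm(n)
  X <- stats::fft(x)
  f <- c(0, seq_len(n - 1)) ; f <- pmin(f, n - f)      # symmetric bin index
  gain <- ifelse(f < 1, 0, f^(-exponent / 2))
  y <- Re(stats::fft(X * gain, inverse = TRUE)) / n
  y / max(stats::sd(y), .Machine$double.eps)
}

# band-limited unit-RMS noise via FFT masking
band_noise <- function(n, rate, band) {
  x <- stats::rnorm(n)
  X <- stats::fft(x)
  f <- (c(0, seq_len(n - 1))) * rate / n ; f <- pmin(f, rate - f)
  y <- Re(stats::fft(X * (f >= band[1] & f <= band[2]), inverse = TRUE)) / n
  y / max(stats::sd(y), .Machine$double.eps)
}

osc <- function(n, rate, freq, amp) {
  amp * sqrt(2) * sin(2 * pi * freq * seq_len(n) / rate + stats::runif(1, 0, 2 * pi))
}

#' Simulate one EEG trial epoch
#'
#' Draws from the R random stream in effect (seed it, or use
#' [simulate_cohort()] which manages per-subject streams).
#'
#' @param state `"none"` (stage 1), `"low"`, `"mid"` or `"high"`.
#' @param mi_class `"left"` or `"right"`.
#' @param cfg A [synth_config()].
#' @return Channels x samples matrix in microvolts.
#' @export
simulate_trial <- function(state = c("none", "low", "mid", "high"),
                           mi_class = c("left", "right"), cfg = synth_config()) {
  state <- match.arg(state)
  mi_class <- match.arg(mi_class)
  n <- round(cfg$trial_len_s * cfg$rate)
  chn <- norm_channel(cfg$channels)
  C <- length(chn)
  si <- if (state == "none") 0L else match(state, c("low", "mid", "high"))

  x <- matrix(0, C, n)
  for (ch in seq_len(C)) x[ch, ] <- cfg$noise_uv * one_over_f(n, cfg$noise_exponent)

  # sensorimotor sources: s_left -> C3, s_right -> C4; contralateral ERD
  depth <- cfg$mi_erd_depth * (if (si == 0) 1 else cfg$erd_state_scale[si])
  att_l <- if (mi_class == "right") sqrt(1 - depth) else 1   # right hand -> C3 ERD
  att_r <- if (mi_class == "left") sqrt(1 - depth) else 1    # left hand  -> C4 ERD
  s_l <- att_l * (osc(n, cfg$rate, 10, cfg$mu_amp_uv) +
                    osc(n, cfg$rate, 20, cfg$beta_amp_uv))
  s_r <- att_r * (osc(n, cfg$rate, 10, cfg$mu_amp_uv) +
                    osc(n, cfg$rate, 20, cfg$beta_amp_uv))
  theta <- if (si == 0) 0 else cfg$state_rotation_deg[si] * pi / 180
  mixed <- rbind(c(cos(theta), -sin(theta)), c(sin(theta), cos(theta))) %*%
    rbind(s_l, s_r)
  i3 <- match("C3", chn); i4 <- match("C4", chn)
  x[i3, ] <- x[i3, ] + mixed[1, ]
  x[i4, ] <- x[i4, ] + mixed[2, ]
  iz <- match("CZ", chn)
  if (!is.na(iz)) {
    x[iz, ] <- x[iz, ] + 0.25 * (mixed[1, ] + mixed[2, ])
    fm <- if (si == 0) 1 else cfg$fm_theta_state_scale[si]
    x[iz, ] <- x[iz, ] + osc(n, cfg$rate, 6, cfg$fm_theta_uv * fm)
  }
  io <- match("OZ", chn)
  if (!is.na(io)) {
    ga <- if (si == 0) 1 else cfg$alpha_state_scale[si]
    x[io, ] <- x[io, ] + osc(n, cfg$rate, 10, cfg$alpha_oz_uv * ga)
  }

  # state-dependent broadband components: the beta/gamma/theta gains act on
  # the sensorimotor channels, other channels stay at baseline, so the state
  # contrast has spatial structure
  gb <- if (si == 0) 1 else cfg$state_gain_beta[si]
  gg <- if (si == 0) 1 else cfg$state_gain_gamma[si]
  gt <- if (si == 0) 1 else cfg$state_gain_theta[si]
  gt_oz <- if (si == 0) 1 else rev(cfg$state_gain_theta)[si]
  central <- chn %in% c("C3", "CZ", "C4")
  lateral <- chn %in% c("C3", "C4")
  for (ch in seq_len(C)) {
    cb <- if (central[ch]) gb else 1
    cg <- if (central[ch]) gg else 1
    ct <- if (lateral[ch]) gt else if (chn[ch] == "OZ") gt_oz else 1
    x[ch, ] <- x[ch, ] +
      cfg$theta_noise_uv * sqrt(ct) * band_noise(n, cfg$rate, c(2, 8)) +
      cfg$beta_noise_uv * sqrt(cb) * band_noise(n, cfg$rate, c(12, 30)) +
      cfg$gamma_noise_uv * sqrt(cg) * band_noise(n, cfg$rate, c(30, 45))
  }
  rownames(x) <- cfg$channels
  x
}

#' Simulate a full synthetic cohort
#'
#' Per subject: stage-1 calibration trials (no state modulation; both MI
#' classes) followed by stage-2 trials for each frustration state. Fully
#' deterministic under a fixed config seed, with independent per-subject
#' substreams.
#'
#' @param cfg A [synth_config()].
#' @return A `synth_cohort`: list with `epochs` (tibble, one row per trial,
#'   epoch matrices in the `data` list-column), `trial_table` and `config`.
#' @export
simulate_cohort <- function(cfg = synth_config()) {
  gap <- round(cfg$rate)          # inter-trial gap on the virtual timeline
  dur <- round(cfg$trial_len_s * cfg$rate)
  all_rows <- list()
  for (subj in seq_len(cfg$n_subjects)) {
    sid <- sprintf("S%02d", subj)
    plan <- rbind(
      expand.grid(state = "none", mi = mi_levels,
                  rep = seq_len(cfg$trials_per_class_stage1),
                  stringsAsFactors = FALSE),
      expand.grid(state = state_levels, mi = mi_levels,
                  rep = seq_len(cfg$trials_per_state_class),
                  stringsAsFactors = FALSE))
    rows <- with_seed(derive_seed(cfg$seed, "cohort", subj), {
      lapply(seq_len(nrow(plan)), function(i) {
        tibble::tibble(
          subject_id = sid,
          trial_id = sprintf("%s_t%03d", sid, i),
          onset_sample = (i - 1L) * (dur + gap),
          duration_samples = dur,
          mi_label = plan$mi[i],
          state_label = plan$state[i],
          stage = if (plan$state[i] == "none") 1L else 2L,
          data = list(simulate_trial(plan$state[i], plan$mi[i], cfg)),
          rate = cfg$rate)
      })
    })
    all_rows[[subj]] <- dplyr::bind_rows(rows)
  }
  epochs <- dplyr::bind_rows(all_rows)
  structure(list(
    epochs = epochs,
    trial_table = trial_table(epochs[, c("subject_id", "trial_id",
                                         "onset_sample", "duration_samples",
                                         "mi_label", "state_label", "stage")]),
    config = cfg),
    class = "synth_cohort")
}

#' @export
print.synth_cohort <- function(x, ...) {
  cat(sprintf("<synth_cohort> %d subjects, %d trials (%d stage-1, %d stage-2)\n",
              x$config$n_subjects, nrow(x$epochs), sum(x$epochs$stage == 1),
              sum(x$epochs$stage == 2)))
  invisible(x)
}

#' Assemble one subject's epochs into a continuous record
#'
#' Concatenates the subject's trials onto their virtual timeline (gaps are
#' filled with low-amplitude background) and writes `MI/left`, `MI/right`
#' and `STATE/<level>` events at trial onsets — the package's event-code
#' vocabulary for continuous files.
#'
#' @param cohort A `synth_cohort`.
#' @param subject Subject id (e.g. `"S01"`).
#' @return A [signal_record()].
#' @export
as_signal_record <- function(cohort, subject) {
  rows <- cohort$epochs[cohort$epochs$subject_id == subject, ]
  assert_that(nrow(rows) > 0, sprintf("unknown subject '%s'", subject),
              class = "lookup_error")
  total <- max(rows$onset_sample + rows$duration_samples)
  C <- length(cohort$config$channels)
  data <- with_seed(derive_seed(cohort$config$seed, "record", subject), {
    matrix(stats::rnorm(C * total, sd = 1), C, total)
  })
  ev <- list()
  for (i in seq_len(nrow(rows))) {
    sl <- (rows$onset_sample[i] + 1):(rows$onset_sample[i] + rows$duration_samples[i])
    data[, sl] <- rows$data[[i]]
    ev[[length(ev) + 1]] <- tibble::tibble(
      sample = rows$onset_sample[i],
      code = paste0("MI/", rows$mi_label[i]))
    if (rows$stage[i] == 2L) {
      ev[[length(ev) + 1]] <- tibble::tibble(
        sample = rows$onset_sample[i],
        code = paste0("STATE/", rows$state_label[i]))
    }
  }
  signal_record(data, cohort$config$rate, cohort$config$channels,
                dplyr::bind_rows(ev))
}

#' Simulate the frustration-induction protocol log
#'
#' Feedback outcomes are Bernoulli draws at each condition's success rate;
#' block-level Likert ratings are normal draws (condition-specific mean and
#' sd) rounded and clipped to 1..7.
#'
#' @param cfg A [synth_config()].
#' @return A `protocol_log`: list of `trials` (subject, condition,
#'   intended_direction, feedback_outcome) and `ratings` (subject,
#'   condition, block, rating).
#' @export
simulate_protocol <- function(cfg = synth_config()) {
  conds <- state_levels
  trials <- list(); ratings <- list()
  with_seed(derive_seed(cfg$seed, "protocol"), {
    for (subj in seq_len(cfg$n_subjects)) {
      sid <- sprintf("S%02d", subj)
      for (ci in seq_along(conds)) {
        n_tr <- 2 * cfg$trials_per_state_class
        trials[[length(trials) + 1]] <- tibble::tibble(
          subject = sid, condition = conds[ci],
          intended_direction = sample(mi_levels, n_tr, replace = TRUE),
          feedback_outcome = ifelse(
            stats::runif(n_tr) < cfg$success_rates[ci], "success", "failure"))
        ratings[[length(ratings) + 1]] <- tibble::tibble(
          subject = sid, condition = conds[ci],
          block = seq_len(cfg$blocks_per_condition),
          rating = pmin(7, pmax(1, round(stats::rnorm(
            cfg$blocks_per_condition, cfg$likert_means[ci], cfg$likert_sds[ci])))))
      }
    }
  })
  structure(list(trials = dplyr::bind_rows(trials),
                 ratings = dplyr::bind_rows(ratings)),
            class = "protocol_log")
}
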