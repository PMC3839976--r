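#' Effect specification for the synthetic motor-imagery cohort
#'
#' Describes the statistical structure injected into synthetic subjects:
#' a mu-rhythm over sensorimotor channels whose power drops during imagery
#' (event-related desynchronization, ERD), and an imagery-locked rise in
#' inter-channel coherence over frontal channels.
#'
#' @param erd_depth Fraction in \[0, 1\] by which mu-band power is reduced
#'   during imagery trials on `erd_channels`.
#' @param coh_gain Added inter-channel correlation in \[0, 1) on
#'   `coh_channels` during imagery, realized as power- and
#'   spectrum-preserving mixing with a shared background-like component
#'   (so power features are blind to the coupling by construction).
#' @param mu_band Mu-rhythm frequency interval in Hz.
#' @param erd_channels Channels carrying the mu rhythm.
#' @param coh_channels Channels coupled during imagery; every unordered
#'   pair among them is a coupled pair.
#' @param noise_exponent Spectral slope beta of the 1/f^beta background.
#' @param snr Ratio of mu-rhythm RMS to background RMS on `erd_channels`.
#' @param background_rms Background RMS amplitude in microvolts.
#' @param common_frac Variance fraction of the spatially shared background
#'   component (keeps baseline coherence away from 0 and 1).
#' @param rate Sampling rate in Hz.
#' @param n_trials_per_condition Trials generated per condition.
#' @param erd_sd Between-subject SD of `erd_depth` in responsive cohorts
#'   (truncated-normal jitter).
#' @return An object of class `micf_effect_spec`.
#' @export
effect_spec <- function(erd_depth = 0.4, coh_gain = 0.3,
                        mu_band = c(8, 13),
                        erd_channels = c("C3", "C4", "CP1", "CP2"),
                        coh_channels = c("F3", "F4", "Fz", "F7", "F8"),
                        noise_exponent = 1, snr = 0.4,
                        background_rms = 10, common_frac = 0.3,
                        rate = 250, n_trials_per_condition = 24,
                        erd_sd = 0.1) {
  stopifnot(length(erd_depth) == 1L, length(coh_gain) == 1L)
  if (erd_depth < 0 || erd_depth > 1) stop("erd_depth must lie in [0, 1]")
  if (coh_gain < 0 || coh_gain >= 1) stop("coh_gain must lie in [0, 1)")
  if (noise_exponent < 0) stop("noise_exponent must be >= 0")
  if (rate <= 0) stop("rate must be positive")
  if (n_trials_per_condition < 1) stop("need at least one trial per condition")
  if (common_frac < 0 || common_frac >= 1) stop("common_frac in [0, 1)")
  structure(
    list(erd_depth = erd_depth, coh_gain = coh_gain, mu_band = mu_band,
         erd_channels = erd_channels, coh_channels = coh_channels,
         noise_exponent = noise_exponent, snr = snr,
         background_rms = background_rms, common_frac = common_frac,
         rate = rate, n_trials_per_condition = n_trials_per_condition,
         erd_sd = erd_sd),
    class = "micf_effect_spec")
}

# run `expr` under a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  if (is.null(seed)) stop("a seed is required")
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# 1/f^beta noise via spectral shaping of white noise; unit RMS.
# Synthesis runs at a highly composite FFT length and is truncated.
pink_noise <- function(n, beta, rate) {
  m <- stats::nextn(n)
  w <- stats::rnorm(m)
  if (beta == 0) return(w[seq_len(n)] / stats::sd(w))
  f <- c(0, seq_len(m - 1)) * rate / m
  f <- pmin(f, rate - f)                     # fold to two-sided frequencies
  amp <- ifelse(f > 0, pmax(f, 0.5)^(-beta / 2), 0)  # flatten < 0.5 Hz
  x <- Re(stats::fft(stats::fft(w) * amp, inverse = TRUE))[seq_len(n)] / m
  x / sqrt(mean(x^2))
}

# band-limited Gaussian noise (hard spectral mask); unit RMS
band_noise <- function(n, band, rate) {
  m <- stats::nextn(n)
  w <- stats::rnorm(m)
  f <- c(0, seq_len(m - 1)) * rate / m
  f <- pmin(f, rate - f)
  mask <- as.numeric(f >= band[1] & f <= band[2])
  x <- Re(stats::fft(stats::fft(w) * mask, inverse = TRUE))[seq_len(n)] / m
  x / sqrt(mean(x^2))
}

# instruction durations (s) preceding each condition's response window
instruction_seconds <- c(imagery = 9.5, rest = 6)
response_window_seconds <- 5

#' Generate one synthetic subject
#'
#' Produces a continuous recording with pseudo-randomly interleaved
#' imagery/rest events. Each event marks the end of its acoustic
#' instruction and is followed by a 5-s response window. With
#' `erd_depth = 0` and `coh_gain = 0` the two conditions are generated by
#' an identical process (exchangeable null).
#'
#' @param spec An [effect_spec()].
#' @param montage Channel labels to generate (>= 21 channels).
#' @param seed Integer seed; identical inputs give bit-identical output.
#' @param subject_id,group_tag Metadata carried on the recording.
#' @param return_components If `TRUE`, attach the injected mu-rhythm
#'   component as attribute `"components"` for diagnostic use.
#' @return A [recording()].
#' @export
generate_subject <- function(spec, montage = micf_montage(), seed,
                             subject_id = "S01", group_tag = "responsive",
                             return_components = FALSE) {
  stopifnot(inherits(spec, "micf_effect_spec"))
  if (length(montage) < 21)
    stop("montage must contain at least 21 channels")
  missing_ch <- setdiff(c(spec$erd_channels, spec$coh_channels), montage)
  if (length(missing_ch))
    stop("montage error: unknown channel label(s): ",
         paste(missing_ch, collapse = ", "))
  rate <- spec$rate
  with_seed(seed, {
    ntr <- spec$n_trials_per_condition
    cond <- sample(rep(c("imagery", "rest"), each = ntr))
    instr <- instruction_seconds[cond]
    ev_time <- cumsum(instr) + response_window_seconds * (seq_along(cond) - 1)
    ev_samp <- sec_to_samp(ev_time, rate) + 1L
    n <- sec_to_samp(ev_time[length(ev_time)] +
                       response_window_seconds + 1, rate)

    common <- pink_noise(n, spec$noise_exponent, rate)
    nch <- length(montage)
    x <- matrix(0, nch, n, dimnames = list(montage, NULL))
    a_own <- sqrt(1 - spec$common_frac)
    a_com <- sqrt(spec$common_frac)
    for (i in seq_len(nch))
      x[i, ] <- spec$background_rms *
        (a_own * pink_noise(n, spec$noise_exponent, rate) + a_com * common)

    # imagery response windows as a sample mask
    win <- logical(n)
    for (j in which(cond == "imagery")) {
      to <- min(ev_samp[j] + sec_to_samp(response_window_seconds, rate) - 1L, n)
      win[ev_samp[j]:to] <- TRUE
    }

    mu_amp <- spec$snr * spec$background_rms
    mu <- matrix(0, length(spec$erd_channels), n,
                 dimnames = list(spec$erd_channels, NULL))
    for (i in seq_along(spec$erd_channels)) {
      m <- mu_amp * band_noise(n, spec$mu_band, rate)
      m[win] <- m[win] * sqrt(1 - spec$erd_depth)
      mu[i, ] <- m
      x[spec$erd_channels[i], ] <- x[spec$erd_channels[i], ] + m
    }

    if (spec$coh_gain > 0) {
      # spectrum-preserving substitution: the shared component has the
      # same 1/f^beta spectrum and RMS as the background, so power
      # features stay blind to the coupling. coh_gain is the target
      # increase in magnitude-squared coherence over the baseline
      # (whose inter-channel correlation is about common_frac); the
      # mixing weight is derived from that target.
      shared <- spec$background_rms * pink_noise(n, spec$noise_exponent,
                                                 rate)
      r0 <- spec$common_frac
      r1 <- min(sqrt(r0^2 + spec$coh_gain), 0.999)
      w2 <- (r1 - r0) / (1 - r0)
      for (ch in spec$coh_channels)
        x[ch, win] <- sqrt(1 - w2) * x[ch, win] + sqrt(w2) * shared[win]
    }

    rec <- recording(x, rate, montage,
                     events = data.frame(sample = ev_samp, condition = cond,
                                         stringsAsFactors = FALSE),
                     subject_id = subject_id, group_tag = group_tag)
    if (return_components) attr(rec, "components") <- list(mu = mu)
    rec
  })
}

#' Generate a synthetic cohort
#'
#' `n_responsive` subjects carry the specified effect with per-subject
#' truncated-normal jitter on `erd_depth` (SD `spec$erd_sd`);
#' `n_null` subjects are generated with `erd_depth = 0` and
#' `coh_gain = 0`. Per-subject seeds are derived deterministically from
#' the cohort seed, so each subject's data is independent of the order of
#' generation.
#'
#' @param n_responsive,n_null Non-negative cohort sizes (paper-scale
#'   default study: 22 and 14).
#' @param spec An [effect_spec()].
#' @param seed Cohort seed.
#' @return List of [recording()] objects, responsive first.
#' @export
generate_cohort <- function(n_responsive, n_null, spec, seed) {
  stopifnot(n_responsive >= 0, n_null >= 0)
  total <- n_responsive + n_null
  lapply(seq_len(total), function(i) {
    sseed <- subject_seed(seed, i)
    responsive <- i <= n_responsive
    sp <- spec
    if (responsive) {
      sp$erd_depth <- with_seed(sseed, trunc_norm(spec$erd_depth, spec$erd_sd))
    } else {
      sp$erd_depth <- 0
      sp$coh_gain <- 0
    }
    generate_subject(sp, seed = sseed + 1L,
                     subject_id = sprintf("S%02d", i),
                     group_tag = if (responsive) "responsive" else "null")
  })
}

subject_seed <- function(seed, i) {
  as.integer((abs(as.integer(seed)) %% 214000L) * 10000L + 2L * i)
}

trunc_norm <- function(mean, sd, lo = 0, hi = 1) {
  for (k in 1:100) {
    v <- stats::rnorm(1, mean, sd)
    if (v >= lo && v <= hi) return(v)
  }
  min(max(mean, lo), hi)
}

#' Inject artifacts into a recording
#'
#' `step` adds an instantaneous voltage offset over a window; `flat`
#' replaces the window by a constant (range < 0.1 microvolt). Used to
#' exercise the automatic artifact-rejection thresholds.
#'
#' @param rec A [recording()].
#' @param artifacts Data frame with columns `sample` (onset), `kind`
#'   (`"step"` or `"flat"`), `magnitude` (microvolts, used by `step`),
#'   `duration` (seconds) and optionally `channel` (label; defaults to
#'   the first channel).
#' @param seed Unused by the current artifact kinds; kept so stochastic
#'   artifact kinds can be added without interface change.
#' @return The modified [recording()].
#' @export
inject_artifacts <- function(rec, artifacts, seed = NULL) {
  stopifnot(inherits(rec, "micf_recording"))
  artifacts <- as.data.frame(artifacts)
  if (!nrow(artifacts)) return(rec)
  if (is.null(artifacts$channel)) artifacts$channel <- rec$channel_labels[1]
  n <- ncol(rec$samples)
  for (r in seq_len(nrow(artifacts))) {
    a <- artifacts[r, ]
    len <- max(1L, sec_to_samp(a$duration, rec$rate))
    from <- as.integer(a$sample)
    to <- from + len - 1L
    if (from < 1L || to > n)
      stop("index error: artifact window [", from, ", ", to,
           "] outside recording")
    ch <- match(a$channel, rec$channel_labels)
    if (is.na(ch)) stop("unknown artifact channel: ", a$channel)
    w <- from:to
    if (a$kind == "step") {
      rec$samples[ch, w] <- rec$samples[ch, w] + a$magnitude
    } else if (a$kind == "flat") {
      rec$samples[ch, w] <- mean(rec$samples[ch, w])
    } else stop("unknown artifact kind: ", a$kind)
  }
  rec
}
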