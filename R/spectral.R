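# Ricker (Mexican hat) wavelet sampled at integer offsets for width a
ricker_kernel <- function(points, a) {
  t <- seq_len(points) - 1 - (points - 1) / 2
  A <- 2 / (sqrt(3 * a) * pi^0.25)
  A * (1 - (t / a)^2) * exp(-t^2 / (2 * a^2))
}

#' Continuous wavelet transform with the Ricker wavelet
#'
#' Convolves a signal with Ricker (Mexican hat) kernels at integer widths,
#' returning same-length coefficient rows per scale. Kernel support is
#' `min(10 * width + 1, T)` samples (forced odd), centred.
#'
#' @param x numeric signal.
#' @param widths integer scale widths (default 1:9).
#' @return object of class `cwt_coefficients`: list with `coef`
#'   (`length(widths) x length(x)` matrix), `widths`.
#' @export
ricker_cwt <- function(x, widths = 1:9) {
  T_ <- length(x)
  if (T_ < 2L) stop("signal must have length >= 2")
  coef <- matrix(NA_real_, length(widths), T_)
  for (i in seq_along(widths)) {
    a <- widths[i]
    L <- min(10L * a + 1L, T_)
    if (L %% 2L == 0L) L <- L - 1L
    k <- ricker_kernel(L, a)
    full <- stats::convolve(x, rev(k), type = "open")  # length T + L - 1
    half <- (L - 1L) %/% 2L
    coef[i, ] <- full[(half + 1L):(half + T_)]
  }
  structure(list(coef = coef, widths = widths), class = "cwt_coefficients")
}

#' Wavelet entropy of a signal
#'
#' Shannon entropy of the normalised per-scale energy of the Ricker CWT:
#' per-scale energy is the sum of absolute coefficients over time, the
#' energies are normalised to a probability distribution over the scales,
#' and the entropy is `-sum(d * log(d))`. Bounded by `log(number of scales)`
#' (`log(9) ~ 2.197` for the default widths). A zero-energy signal returns 0.
#'
#' @param x numeric signal.
#' @param widths CWT widths (default 1:9).
#' @return nonnegative scalar.
#' @export
wavelet_entropy <- function(x, widths = 1:9) {
  W <- ricker_cwt(x, widths)$coef
  E <- rowSums(abs(W))
  tot <- sum(E)
  if (tot <= 0) {
    warning("zero total wavelet energy; entropy defined as 0")
    return(0)
  }
  d <- E / tot
  d <- d[d > 0]
  -sum(d * log(d))
}

#' Fundamental frequency of a signal
#'
#' Mean-removed DFT; spectral peaks are the frequencies whose magnitude
#' exceeds 30% of the maximum magnitude; the fundamental is the lowest
#' strictly positive peak frequency.
#'
#' @param x numeric signal.
#' @param fs sampling rate, Hz.
#' @return frequency in Hz, or `NA` (with a warning) when no positive
#'   frequency qualifies (e.g. a constant signal).
#' @export
fundamental_frequency <- function(x, fs) {
  T_ <- length(x)
  X <- stats::fft(x - mean(x))
  nf <- T_ %/% 2 + 1L                      # one-sided bins incl. DC
  mag <- Mod(X)[seq_len(nf)]
  freq <- (seq_len(nf) - 1) * fs / T_
  mx <- max(mag)
  if (mx <= 0) {
    warning("flat spectrum; fundamental frequency undefined")
    return(NA_real_)
  }
  peaks <- freq[mag > 0.3 * mx & freq > 0]
  if (!length(peaks)) {
    warning("no positive-frequency peak above threshold")
    return(NA_real_)
  }
  min(peaks)
}

#' Standard deviation of CWT coefficients at one scale
#'
#' Sample standard deviation (denominator T-1) of the Ricker CWT
#' coefficients at the given width, over time.
#'
#' @param x numeric signal.
#' @param width scale width (default 5).
#' @return nonnegative scalar.
#' @export
cwt_scale_std <- function(x, width = 5L) {
  W <- ricker_cwt(x, widths = width)$coef
  stats::sd(W[1, ])
}

# single-segment Welch (Hann window, mean detrend, one-sided density)
welch_psd <- function(x, fs) {
  T_ <- length(x)
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(T_) - 1) / T_)  # periodic Hann
  xd <- (x - mean(x)) * w
  X <- stats::fft(xd)
  nf <- T_ %/% 2 + 1L
  psd <- (Mod(X)[seq_len(nf)])^2 / (fs * sum(w^2))
  scale2 <- rep(2, nf); scale2[1] <- 1
  if (T_ %% 2 == 0) scale2[nf] <- 1
  list(freq = (seq_len(nf) - 1) * fs / T_, psd = psd * scale2)
}

#' Power spectral density bandwidth
#'
#' Width of the frequency interval containing 95% of the signal's spectral
#' power. The signal is normalised by its standard deviation (when nonzero)
#' and a single-segment Welch density (Hann window) is computed; the
#' interval bounds are the forward and reversed cumulative-power 95%
#' crossings and the bandwidth is their absolute difference. A constant
#' signal has bandwidth 0.
#'
#' @param x numeric signal, length >= 8.
#' @param fs sampling rate, Hz.
#' @return bandwidth in Hz, within `[0, fs/2]`.
#' @export
psd_bandwidth <- function(x, fs) {
  if (length(x) < 8L) stop("signal must have length >= 8")
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(0)
  p <- welch_psd(x / s, fs)
  tot <- sum(p$psd)
  if (tot <= 0) return(0)
  cum <- cumsum(p$psd)
  f_lower <- p$freq[which(cum >= 0.95 * tot)[1]]
  cum_rev <- cumsum(rev(p$psd))
  j <- which(cum_rev >= 0.95 * tot)[1]
  f_upper <- p$freq[length(p$psd) - j + 1L]
  abs(f_upper - f_lower)
}

#' Zero-lag autocorrelation (signal energy)
#'
#' The sum of the signal multiplied by itself at zero lag,
#' `sum(x_t * x_t)` - the squared Euclidean norm.
#'
#' @param x numeric signal.
#' @return nonnegative scalar.
#' @export
autocorr_zero_lag <- function(x) {
  if (!length(x)) stop("empty signal")
  sum(x * x)
}

#' Zero-crossing count
#'
#' Number of sign reversals of the signal across zero: transitions where
#' `|sgn(x_t) - sgn(x_{t-1})| = 2`, with `sgn(0) = 0` (so a step through an
#' exact zero sample does not count). Unnormalised by construction.
#'
#' @param x numeric signal.
#' @return nonnegative integer, at most `length(x) - 1`.
#' @export
zero_crossings <- function(x) {
  if (!length(x)) stop("empty signal")
  s <- sign(x)
  sum(abs(diff(s)) == 2)
}

# ---- spectro-temporal feature table -----------------------------------------

#' Core signals for spectro-temporal analysis
#'
#' The pinned per-frame core signals the long-clip spectro-temporal table is
#' built over: chest and neck 3D velocity and acceleration, the tail angle,
#' tip 3D velocity, hands 3D distance and feet 2D distance. Acceleration is
#' the forward difference of speed times the sampling rate.
#'
#' @param seq a [pose_sequence()].
#' @return numeric matrix `n_frames x 8` of named core signals.
#' @export
core_signals <- function(seq) {
  sig <- compute_signals(seq)
  accel <- function(sp) {
    a <- diff(sp) * seq$fs
    c(a[1], a)
  }
  cbind(
    chest_3D_vel = sig[, "chest_3D_speed"],
    chest_3D_acc = accel(sig[, "chest_3D_speed"]),
    neck_3D_vel = sig[, "neck_3D_speed"],
    neck_3D_acc = accel(sig[, "neck_3D_speed"]),
    tail_angle = sig[, "tail_angle"],
    tip_3D_vel = sig[, "tip_3D_speed"],
    hands_3D_dist = sig[, "hands_3D_dist"],
    feet_2D_dist = sig[, "feet_2D_dist"]
  )
}

spectro_ops <- function(fs) {
  list(
    wavelet_entropy = function(x) wavelet_entropy(x),
    fundamental_freq = function(x) {
      suppressWarnings(fundamental_frequency(x, fs))
    },
    cwt_std_w5 = function(x) cwt_scale_std(x, 5L),
    psd_bandwidth = function(x) psd_bandwidth(x, fs),
    autocorr = function(x) autocorr_zero_lag(x),
    zcr = function(x) as.numeric(zero_crossings(x)),
    min = function(x) min(x, na.rm = TRUE),
    max = function(x) max(x, na.rm = TRUE),
    mean = function(x) mean(x, na.rm = TRUE),
    std = function(x) stats::sd(x, na.rm = TRUE)
  )
}

#' Spectro-temporal feature table over long clips
#'
#' Applies the full spectro-temporal operator registry (wavelet entropy,
#' fundamental frequency, wavelet std at width 5, PSD bandwidth, zero-lag
#' autocorrelation, zero-crossing count, plus min/max/mean/std) to every
#' core signal of each 120-frame clip, and appends the 8 episode temporal
#' parameters. Undefined operator results are coded `NA`.
#'
#' @param seq a [pose_sequence()].
#' @param episodes,clips optional precomputed tables; derived from chest 3D
#'   speed with 120-frame clips when `NULL`.
#' @return data frame: metadata columns, then `8 signals x 10 operators + 8`
#'   temporal = 88 feature columns (attribute `feature_cols`).
#' @export
spectro_feature_table <- function(seq, episodes = NULL, clips = NULL) {
  if (is.null(episodes)) {
    episodes <- detect_motion_episodes(node_speed(seq, "chest", "3D"),
                                       fs = seq$fs)
  }
  if (is.null(clips)) clips <- fragment_clips(episodes, 120L)
  core <- core_signals(seq)
  ops <- spectro_ops(seq$fs)
  feat_names <- as.vector(t(outer(colnames(core), names(ops), paste,
                                  sep = "_")))
  ep_names <- c("ep_duration", "ep_interval", "ep_n_clips", "ep_onset",
                "ep_path_length", "ep_mean_speed", "ep_rest_ratio",
                "ep_ordinal")
  if (nrow(clips) == 0L) {
    out <- cbind(
      data.frame(mouse = character(0), group = character(0), week = integer(0),
                 episode = integer(0), clip_index = integer(0),
                 start_frame = integer(0)),
      as.data.frame(matrix(numeric(0), 0, length(feat_names) + 8L,
                           dimnames = list(NULL, c(feat_names, ep_names)))))
    attr(out, "feature_cols") <- c(feat_names, ep_names)
    return(out)
  }
  ep_par <- episode_temporal_params(episodes, seq, 120L)
  rows <- matrix(NA_real_, nrow(clips), length(feat_names),
                 dimnames = list(NULL, feat_names))
  for (i in seq_len(nrow(clips))) {
    idx <- (clips$start_frame[i] + 1L):clips$end_frame[i]
    k <- 0L
    for (sn in colnames(core)) {
      x <- core[idx, sn]
      for (on in names(ops)) {
        k <- k + 1L
        val <- if (anyNA(x) && !on %in% c("min", "max", "mean", "std"))
          NA_real_ else tryCatch(ops[[on]](x), error = function(e) NA_real_)
        rows[i, k] <- val
      }
    }
  }
  ep_idx <- match(clips$episode, ep_par$ep_ordinal)
  out <- cbind(
    data.frame(mouse = seq$mouse_id, group = seq$group, week = seq$week,
               episode = clips$episode, clip_index = clips$clip_index,
               start_frame = clips$start_frame),
    as.data.frame(rows),
    ep_par[ep_idx, , drop = FALSE])
  rownames(out) <- NULL
  attr(out, "feature_cols") <- c(feat_names, ep_names)
  out
}
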