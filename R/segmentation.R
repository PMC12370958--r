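#' Per-frame node speed
#'
#' Speed of one body node in 1D (vertical z), 2D (horizontal xy) or 3D space,
#' as the norm of the coordinate difference over one frame times the sampling
#' rate. The difference over `(t-1, t]` is assigned to frame `t`; frame 0 is
#' padded from frame 1. Speeds are unsigned.
#'
#' @param seq a [pose_sequence()].
#' @param node node name (see [pose_nodes()]).
#' @param space `"1D"`, `"2D"` or `"3D"`.
#' @return numeric vector of length `n_frames`, cm/s.
#' @export
node_speed <- function(seq, node = "chest", space = c("3D", "2D", "1D")) {
  space <- match.arg(space)
  if (seq$n_frames < 2L) stop("need at least 2 frames to compute speed")
  axes <- switch(space, "1D" = "z", "2D" = c("x", "y"),
                 "3D" = c("x", "y", "z"))
  xyz <- seq$coords[, node, axes, drop = FALSE]
  xyz <- matrix(xyz, nrow = seq$n_frames)
  d <- diff(xyz)
  sp <- sqrt(rowSums(d^2)) * seq$fs
  c(sp[1], sp)
}

# speed from a raw coordinate matrix (frames x axes)
coord_speed <- function(xyz, fs) {
  if (is.null(dim(xyz))) xyz <- matrix(xyz, ncol = 1L)
  d <- diff(xyz)
  sp <- sqrt(rowSums(d^2)) * fs
  c(sp[1], sp)
}

#' Detect moving episodes from a speed series
#'
#' A frame is above threshold when its speed exceeds `threshold`. A trailing
#' window of `window` frames starting at frame t is Moving when its count of
#' above-threshold frames exceeds `window * frac`. Episodes are the maximal
#' unions of overlapping Moving windows. The interval of an episode is the
#' time since the previous episode's end (time since session start for the
#' first).
#'
#' @param speed numeric speed series, cm/s.
#' @param fs sampling rate, Hz.
#' @param threshold speed threshold, cm/s (default 1.5).
#' @param window window length in frames (default 100).
#' @param frac qualifying fraction (default 0.8).
#' @return data frame with one row per episode: `start_frame`, `end_frame`
#'   (half-open, 0-based), `duration` (s), `interval` (s), `ordinal`.
#' @export
detect_motion_episodes <- function(speed, fs = 30, threshold = 1.5,
                                   window = 100L, frac = 0.8) {
  n <- length(speed)
  if (n < window) {
    warning("speed series shorter than the detection window; no episodes")
    return(empty_episodes())
  }
  ind <- as.numeric(speed > threshold)
  sums <- cumsum(ind)
  # count in [t, t+window) for t = 1 .. n-window+1 (1-based)
  counts <- sums[window:n] - c(0, sums[seq_len(n - window)])
  starts <- which(counts > window * frac)
  if (!length(starts)) return(empty_episodes())
  covered <- rep(FALSE, n)
  for (t in starts) covered[t:(t + window - 1L)] <- TRUE
  r <- rle(covered)
  ends_r <- cumsum(r$lengths)
  starts_r <- ends_r - r$lengths + 1L
  keep <- which(r$values)
  ep <- data.frame(start_frame = starts_r[keep] - 1L,
                   end_frame = ends_r[keep])
  ep$duration <- (ep$end_frame - ep$start_frame) / fs
  prev_end <- c(0L, ep$end_frame[-nrow(ep)])
  ep$interval <- (ep$start_frame - prev_end) / fs
  ep$ordinal <- seq_len(nrow(ep))
  ep
}

empty_episodes <- function() {
  data.frame(start_frame = integer(0), end_frame = integer(0),
             duration = numeric(0), interval = numeric(0),
             ordinal = integer(0))
}

#' Fragment an episode into fixed-length clips
#'
#' Consecutive non-overlapping windows from the episode start; remainder
#' frames at the episode end are dropped.
#'
#' @param episodes episode table from [detect_motion_episodes()].
#' @param clip_len clip length in frames: 60 (short, 2 s) or 120 (long, 4 s).
#' @return data frame of clips: `episode` (ordinal), `clip_index` (within
#'   episode, 1-based), `start_frame`, `end_frame` (half-open, 0-based).
#' @export
fragment_clips <- function(episodes, clip_len = 60L) {
  stopifnot(clip_len %in% c(60L, 120L))
  out <- vector("list", nrow(episodes))
  for (i in seq_len(nrow(episodes))) {
    len <- episodes$end_frame[i] - episodes$start_frame[i]
    k <- len %/% clip_len
    if (k == 0L) next
    s <- episodes$start_frame[i] + (seq_len(k) - 1L) * clip_len
    out[[i]] <- data.frame(episode = episodes$ordinal[i],
                           clip_index = seq_len(k),
                           start_frame = s, end_frame = s + clip_len)
  }
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(episode = integer(0), clip_index = integer(0),
                      start_frame = integer(0), end_frame = integer(0))
  }
  out
}

#' Episode-level temporal parameters
#'
#' Eight temporal descriptors per episode, later broadcast to every clip of
#' the episode: motion duration (s), motion interval (s), clip count, onset
#' time (s), chest 2D path length (cm), mean chest 2D speed (cm/s), rest
#' ratio `interval / (interval + duration)`, and the episode ordinal.
#'
#' @param episodes episode table from [detect_motion_episodes()].
#' @param seq the [pose_sequence()] the episodes came from.
#' @param clip_len clip length used for the clip count (default 60).
#' @return data frame with one row per episode and the 8 parameters
#'   (`ep_` prefix).
#' @export
episode_temporal_params <- function(episodes, seq, clip_len = 60L) {
  sp2 <- node_speed(seq, "chest", "2D")
  out <- data.frame(ep_duration = episodes$duration,
                    ep_interval = episodes$interval,
                    ep_n_clips = (episodes$end_frame - episodes$start_frame) %/%
                      clip_len,
                    ep_onset = episodes$start_frame / seq$fs,
                    ep_path_length = NA_real_,
                    ep_mean_speed = NA_real_,
                    ep_rest_ratio = episodes$interval /
                      (episodes$interval + episodes$duration),
                    ep_ordinal = episodes$ordinal)
  for (i in seq_len(nrow(episodes))) {
    idx <- (episodes$start_frame[i] + 1L):episodes$end_frame[i]
    out$ep_mean_speed[i] <- mean(sp2[idx])
    out$ep_path_length[i] <- sum(sp2[idx]) / seq$fs
  }
  out
}
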