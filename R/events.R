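wrap_deg <- function(a) {
  # wrap to (-180, 180]
  w <- (a + 180) %% 360 - 180
  ifelse(w == -180, 180, w)
}

#' Detect turning events
#'
#' Quantifies hindbody turning from the horizontal anus-to-chest heading.
#' The heading change over a lag of two frames is wrapped to (-180, 180];
#' abrupt changes (>= 90 degrees) are zeroed as noise; a 5-frame trailing
#' rolling mean smooths the series; frames are categorised as left (+1),
#' right (-1) or no turning by the sign of the smoothed change where its
#' magnitude exceeds `min_rate` deg/frame. Maximal same-category runs of at
#' least `min_len` frames are events; the turning angle is the maximum
#' cumulative heading change from onset, the duration runs from onset to
#' that peak, and the velocity is their ratio.
#'
#' @param seq a [pose_sequence()] (typically one long clip).
#' @param min_rate per-frame category threshold, deg/frame (default 0.5).
#' @param min_len minimum event length in frames (default 5).
#' @return data frame of events: `start_frame`, `end_frame` (half-open),
#'   `direction` (+1 left / -1 right), `turning_angle` (deg, >= 0),
#'   `turning_duration` (s), `turning_velocity` (deg/s).
#' @export
detect_turning <- function(seq, min_rate = 0.5, min_len = 5L) {
  n <- seq$n_frames
  if (n < 7L) stop("need at least 7 frames")
  ch <- node_xyz(seq, "chest", c("x", "y"))
  an <- node_xyz(seq, "anus", c("x", "y"))
  h <- ch - an
  deg_ok <- sqrt(rowSums(h^2)) > 1e-6
  heading <- rep(NA_real_, n)
  heading[deg_ok] <- atan2(h[deg_ok, 2], h[deg_ok, 1]) * 180 / pi
  delta <- rep(NA_real_, n)
  delta[3:n] <- wrap_deg(heading[3:n] - heading[1:(n - 2)])
  delta[!is.na(delta) & abs(delta) >= 90] <- 0
  # trailing 5-frame rolling mean with partial startup windows
  sm <- rep(NA_real_, n)
  for (t in 3:n) {
    win <- delta[max(3, t - 4):t]
    sm[t] <- mean(win, na.rm = TRUE)
  }
  cat_ <- ifelse(is.na(sm) | abs(sm) <= min_rate, 0L, as.integer(sign(sm)))
  r <- rle(cat_)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values != 0L & r$lengths >= min_len)
  out <- data.frame(start_frame = integer(0), end_frame = integer(0),
                    direction = integer(0), turning_angle = numeric(0),
                    turning_duration = numeric(0),
                    turning_velocity = numeric(0))
  for (k in keep) {
    idx <- starts[k]:ends[k]
    dir_ <- r$values[k]
    # the lag-2 difference at onset covers the two preceding frames; each
    # later smoothed difference contributes half (per-frame) change
    step <- sm[idx] / 2
    step[1] <- sm[idx[1]]
    cum <- cumsum(step)
    peak <- which.max(dir_ * cum)
    angle <- dir_ * cum[peak]
    dur <- (peak + 1L) / seq$fs   # onset spans the 2-frame lag
    out <- rbind(out, data.frame(
      start_frame = starts[k] - 1L, end_frame = ends[k],
      direction = dir_, turning_angle = angle,
      turning_duration = dur, turning_velocity = angle / dur))
  }
  out
}

#' Rearing event features
#'
#' Eleven descriptors of one annotated rearing event: upward and downward
#' chest vertical displacement (cm), up/down/total duration (s), and the
#' mean, maximum and standard deviation of the signed chest vertical
#' velocity during the ascending and descending phases.
#'
#' @param seq a [pose_sequence()].
#' @param ann one rearing annotation row (`start_frame`, `peak_frame`,
#'   `end_frame`).
#' @return named numeric vector of length 11.
#' @export
rearing_features <- function(seq, ann) {
  s <- ann$start_frame; p <- ann$peak_frame; e <- ann$end_frame
  if (is.na(p) || p < s || p > e) stop("rearing peak outside [start, end]")
  z <- seq$coords[, "chest", "z"]
  zi <- function(f) z[f + 1L]
  vz_phase <- function(f0, f1) {
    if (f1 <= f0) return(c(mean = 0, max = 0, std = 0))
    v <- diff(z[(f0 + 1L):(f1 + 1L)]) * seq$fs
    c(mean = mean(v), max = max(v), std = if (length(v) > 1) stats::sd(v) else 0)
  }
  up <- vz_phase(s, p); down <- vz_phase(p, e)
  c(up_displacement = zi(p) - zi(s),
    down_displacement = zi(p) - zi(e),
    up_duration = (p - s) / seq$fs,
    down_duration = (e - p) / seq$fs,
    total_duration = (e - s) / seq$fs,
    up_vz_mean = up[["mean"]], up_vz_max = up[["max"]], up_vz_std = up[["std"]],
    down_vz_mean = down[["mean"]], down_vz_max = down[["max"]],
    down_vz_std = down[["std"]])
}

#' Detect strides from swing-phase annotations
#'
#' A foot strike is the end of a swing phase (the shift from swing to
#' stance); a stride spans consecutive strikes of the same foot. Strides
#' overlapping an annotated rearing event are removed.
#'
#' @param annotations annotation data frame with `swing` rows (and
#'   optionally `rearing` rows used for exclusion).
#' @return data frame of strides: `foot`, `start_frame`, `end_frame`
#'   (half-open, strike to strike), `swing_start` (start of the swing that
#'   ends the stride), `stride_index` per foot.
#' @export
detect_strides <- function(annotations) {
  sw <- annotations[annotations$kind == "swing", , drop = FALSE]
  rr <- annotations[annotations$kind == "rearing", , drop = FALSE]
  out <- NULL
  for (ft in unique(sw$foot)) {
    s <- sw[sw$foot == ft, , drop = FALSE]
    s <- s[order(s$start_frame), , drop = FALSE]
    if (nrow(s) < 2L) next
    strikes <- s$end_frame
    st <- data.frame(foot = ft,
                     start_frame = strikes[-length(strikes)],
                     end_frame = strikes[-1],
                     swing_start = s$start_frame[-1],
                     stride_index = seq_len(length(strikes) - 1L))
    out <- rbind(out, st)
  }
  if (is.null(out)) {
    return(data.frame(foot = character(0), start_frame = integer(0),
                      end_frame = integer(0), swing_start = integer(0),
                      stride_index = integer(0)))
  }
  if (nrow(rr)) {
    overlap <- vapply(seq_len(nrow(out)), function(i) {
      any(out$start_frame[i] < rr$end_frame & rr$start_frame < out$end_frame[i])
    }, logical(1))
    out <- out[!overlap, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

# body-frame xy of arbitrary node positions, vectorised over frames
body_xy <- function(seq, node, frames = NULL) {
  idx <- if (is.null(frames)) seq_len(seq$n_frames) else frames + 1L
  an <- node_xyz(seq, "anus", c("x", "y"))[idx, , drop = FALSE]
  ch <- node_xyz(seq, "chest", c("x", "y"))[idx, , drop = FALSE]
  ft <- node_xyz(seq, node, c("x", "y"))[idx, , drop = FALSE]
  h <- ch - an
  nh <- sqrt(rowSums(h^2))
  ok <- nh > 1e-6
  ux <- h[, 1] / nh; uy <- h[, 2] / nh
  dx <- ft[, 1] - an[, 1]; dy <- ft[, 2] - an[, 2]
  xb <- dx * ux + dy * uy
  yb <- -dx * uy + dy * ux
  xb[!ok] <- NA; yb[!ok] <- NA
  cbind(x = xb, y = yb)
}

#' Per-stride gait features
#'
#' Computes the pinned 28-descriptor gait registry for each stride: timing
#' (stride/swing/stance durations, duty factor, cadence), spatial amplitude
#' (stride length, step height, drag duration), foot dynamics (swing peak
#' and mean speed, toe-off and strike speed, vertical speed variability),
#' interlimb coordination (feet distance statistics, stance width,
#' ipsilateral leg angle range and variability, contralateral leg angle
#' correlation, left-right phase lag), posture (body length and angle, foot
#' behind anus fraction) and locomotor context (body speed, straightness,
#' stride regularity).
#'
#' @param strides stride table from [detect_strides()].
#' @param seq the underlying [pose_sequence()].
#' @return data frame: stride metadata columns then the 28 feature columns
#'   (attribute `feature_cols`).
#' @export
gait_features <- function(strides, seq) {
  fs <- seq$fs
  n <- seq$n_frames
  feats <- vector("list", nrow(strides))
  for (i in seq_len(nrow(strides))) {
    st <- strides[i, ]
    ft <- st$foot
    contra <- if (ft == "r_foot") "l_foot" else "r_foot"
    leg <- if (ft == "r_foot") "r_leg_angle" else "l_leg_angle"
    cleg <- if (ft == "r_foot") "l_leg_angle" else "r_leg_angle"
    idx <- (st$start_frame + 1L):min(st$end_frame, n)
    sw_idx <- (st$swing_start + 1L):min(st$end_frame, n)

    foot_xy <- node_xyz(seq, ft, c("x", "y"))
    foot_z <- seq$coords[, ft, "z"]
    foot_sp <- coord_speed(node_xyz(seq, ft), fs)
    chest_sp2 <- coord_speed(node_xyz(seq, "chest", c("x", "y")), fs)

    p0 <- foot_xy[st$start_frame + 1L, ]
    p1 <- foot_xy[min(st$end_frame + 1L, n), ]
    stride_len <- sqrt(sum((p1 - p0)^2))

    d_stride <- (st$end_frame - st$start_frame) / fs
    d_swing <- (st$end_frame - st$swing_start) / fs
    d_stance <- (st$swing_start - st$start_frame) / fs

    ang_u <- kin_angle_defs()[[leg]]
    legang <- vec_angle_deg(
      node_xyz(seq, ang_u$axis[2])[idx, , drop = FALSE] -
        node_xyz(seq, ang_u$axis[1])[idx, , drop = FALSE],
      node_xyz(seq, ang_u$limb[2])[idx, , drop = FALSE] -
        node_xyz(seq, ang_u$limb[1])[idx, , drop = FALSE])
    ang_c <- kin_angle_defs()[[cleg]]
    clegang <- vec_angle_deg(
      node_xyz(seq, ang_c$axis[2])[idx, , drop = FALSE] -
        node_xyz(seq, ang_c$axis[1])[idx, , drop = FALSE],
      node_xyz(seq, ang_c$limb[2])[idx, , drop = FALSE] -
        node_xyz(seq, ang_c$limb[1])[idx, , drop = FALSE])
    corr <- if (sum(stats::complete.cases(legang, clegang)) > 2 &&
                stats::sd(legang, na.rm = TRUE) > 0 &&
                stats::sd(clegang, na.rm = TRUE) > 0) {
      stats::cor(legang, clegang, use = "complete.obs")
    } else 0

    fd <- sqrt(rowSums((node_xyz(seq, "r_foot", c("x", "y")) -
                          node_xyz(seq, "l_foot", c("x", "y")))^2))[idx]
    bxy_own <- body_xy(seq, ft, idx - 1L)
    bxy_con <- body_xy(seq, contra, idx - 1L)
    stance_w <- mean(abs(bxy_own[, "y"] - bxy_con[, "y"]), na.rm = TRUE)

    # first contralateral strike inside the stride, as a stride fraction
    c_sw <- NULL
    if (!is.null(attr(strides, "all_strikes"))) {
      c_sw <- attr(strides, "all_strikes")[[contra]]
    }
    phase <- NA_real_
    if (!is.null(c_sw)) {
      hit <- c_sw[c_sw > st$start_frame & c_sw <= st$end_frame]
      if (length(hit)) phase <- (hit[1] - st$start_frame) /
          (st$end_frame - st$start_frame)
    }

    net <- sqrt(sum((node_xyz(seq, "chest", c("x", "y"))[max(idx), ] -
                       node_xyz(seq, "chest", c("x", "y"))[min(idx), ])^2))
    path <- sum(chest_sp2[idx]) / fs
    bl <- sqrt(rowSums((node_xyz(seq, "neck", c("x", "y")) -
                          node_xyz(seq, "anus", c("x", "y")))^2))[idx]
    bang <- vec_angle_deg(
      node_xyz(seq, "neck")[idx, , drop = FALSE] -
        node_xyz(seq, "chest")[idx, , drop = FALSE],
      node_xyz(seq, "anus")[idx, , drop = FALSE] -
        node_xyz(seq, "chest")[idx, , drop = FALSE])

    feats[[i]] <- c(
      stride_duration = d_stride,
      swing_duration = d_swing,
      stance_duration = d_stance,
      duty_factor = d_stance / d_stride,
      cadence = 1 / d_stride,
      stride_length = stride_len,
      swing_peak_foot_speed = max(foot_sp[sw_idx]),
      swing_mean_foot_speed = mean(foot_sp[sw_idx]),
      step_height = max(foot_z[sw_idx]),
      toe_off_speed = foot_sp[st$swing_start + 1L],
      strike_speed = foot_sp[min(st$end_frame + 1L, n)],
      foot_vz_std = stats::sd(diff(foot_z[idx]) * fs),
      feet_dist_mean = mean(fd), feet_dist_max = max(fd),
      feet_dist_std = stats::sd(fd),
      stance_width_mean = stance_w,
      leg_angle_range = diff(range(legang, na.rm = TRUE)),
      leg_angle_std = stats::sd(legang, na.rm = TRUE),
      contra_leg_corr = corr,
      phase_lag = phase,
      behind_anus_frac = mean(bxy_own[, "x"] < 0, na.rm = TRUE),
      drag_duration = sum(foot_z[sw_idx] < 0.2) / fs,
      body_speed_mean = mean(chest_sp2[idx]),
      body_speed_std = stats::sd(chest_sp2[idx]),
      body_length_mean = mean(bl),
      body_angle_mean = mean(bang, na.rm = TRUE),
      straightness = if (path > 0) net / path else 0,
      regularity = NA_real_
    )
  }
  fm <- do.call(rbind, feats)
  if (is.null(fm)) {
    fm <- matrix(numeric(0), 0, 28)
  } else {
    # regularity: similarity of consecutive stride durations per foot
    for (ft in unique(strides$foot)) {
      j <- which(strides$foot == ft)
      d <- fm[j, "stride_duration"]
      reg <- rep(1, length(j))
      if (length(j) > 1) {
        reg[-1] <- pmin(d[-1], d[-length(d)]) / pmax(d[-1], d[-length(d)])
      }
      fm[j, "regularity"] <- reg
    }
  }
  out <- cbind(strides, as.data.frame(fm))
  attr(out, "feature_cols") <- colnames(fm)
  rownames(out) <- NULL
  out
}

#' Full gait feature table for one session
#'
#' Detects strides from annotations (excluding rearing overlaps) and
#' computes the 28-feature registry per stride, including the left-right
#' phase lag which requires the strikes of both feet.
#'
#' @param seq a [pose_sequence()].
#' @param annotations annotation table with swing (and rearing) rows.
#' @return gait feature table (see [gait_features()]).
#' @export
gait_feature_table <- function(seq, annotations) {
  strides <- detect_strides(annotations)
  sw <- annotations[annotations$kind == "swing", , drop = FALSE]
  strikes <- lapply(split(sw$end_frame, sw$foot), sort)
  attr(strides, "all_strikes") <- strikes
  gait_features(strides, seq)
}

#' Axial bending angle clips
#'
#' Computes per-frame axial bending angles: the interior angle at the
#' hindlimb midpoint (xy) between the vectors to the nose and to the anus.
#' Frames with angle below `thresh` are flagged; a trailing rolling mean of
#' the flags over `window` frames defines bending episodes (mean >=
#' `frac`); each episode is extended `window` frames backward (clipped at
#' 0) and segmented into consecutive `window`-frame clips with their mean
#' bending angle.
#'
#' @param seq a [pose_sequence()].
#' @param thresh flag threshold in degrees (default 75).
#' @param window rolling window and clip length in frames (default 60).
#' @param frac qualifying fraction (default 0.7).
#' @return list with `theta` (per-frame angle, deg, `NA` when degenerate)
#'   and `clips` (data frame `start_frame`, `end_frame`, `mean_theta`).
#' @export
axial_bending_clips <- function(seq, thresh = 75, window = 60L, frac = 0.7) {
  nose <- node_xyz(seq, "nose", c("x", "y"))
  anus <- node_xyz(seq, "anus", c("x", "y"))
  mid <- (node_xyz(seq, "r_foot", c("x", "y")) +
            node_xyz(seq, "l_foot", c("x", "y"))) / 2
  theta <- vec_angle_deg(cbind(nose - mid, 0), cbind(anus - mid, 0))
  flag <- as.numeric(!is.na(theta) & theta < thresh)
  n <- length(flag)
  clips <- data.frame(start_frame = integer(0), end_frame = integer(0),
                      mean_theta = numeric(0))
  if (n >= window) {
    cs <- cumsum(flag)
    rm_ <- (cs[window:n] - c(0, cs[seq_len(n - window)])) / window
    qual <- which(rm_ >= frac) + window - 1L   # 1-based window end frames
    if (length(qual)) {
      # runs of consecutive qualifying end positions
      bounds <- split(qual, cumsum(c(TRUE, diff(qual) != 1L)))
      for (b in bounds) {
        ep_start0 <- max(0L, (b[1] - window) - window)  # 0-based, extended
        ep_end0 <- b[length(b)]                          # exclusive bound
        k <- (ep_end0 - ep_start0) %/% window
        if (k == 0L) next
        s <- ep_start0 + (seq_len(k) - 1L) * window
        mt <- vapply(s, function(ss) {
          mean(theta[(ss + 1L):(ss + window)], na.rm = TRUE)
        }, numeric(1))
        clips <- rbind(clips, data.frame(start_frame = s,
                                         end_frame = s + window,
                                         mean_theta = mt))
      }
    }
  }
  list(theta = theta, clips = clips)
}

#' Hind-foot placement statistics in the body frame
#'
#' Maps hind-foot xy positions into the body frame (origin at the anus, +x
#' toward the chest), bins them on a 2D grid, and reports the percentage of
#' positions behind the anus (body-frame x < 0) - the foot trailing
#' signature.
#'
#' @param seq a [pose_sequence()].
#' @param frames optional 0-based frame subset (default all frames).
#' @param breaks grid edges (cm) for both axes.
#' @return list with `density` (counts matrix, x bins in rows),
#'   `breaks`, and `pct_behind` (percentage, 0-100).
#' @export
feet_placement_stats <- function(seq, frames = NULL,
                                 breaks = seq(-4, 4, by = 0.5)) {
  pts <- rbind(body_xy(seq, "r_foot", frames), body_xy(seq, "l_foot", frames))
  pts <- pts[stats::complete.cases(pts), , drop = FALSE]
  if (!nrow(pts)) stop("no valid frames for foot placement")
  clampv <- function(v) pmin(max(breaks) - 1e-9, pmax(min(breaks) + 1e-9, v))
  xi <- cut(clampv(pts[, "x"]), breaks, labels = FALSE)
  yi <- cut(clampv(pts[, "y"]), breaks, labels = FALSE)
  nb <- length(breaks) - 1L
  dens <- matrix(0L, nb, nb)
  for (k in seq_along(xi)) dens[xi[k], yi[k]] <- dens[xi[k], yi[k]] + 1L
  list(density = dens, breaks = breaks,
       pct_behind = 100 * mean(pts[, "x"] < 0))
}
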