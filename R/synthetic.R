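#' Phenotype parameters for the synthetic pose generator
#'
#' Describes one behavioural phenotype as a set of generative parameters:
#' movement-bout structure, locomotion speed, limb geometry, the chest
#' oscillation band (the tremor-like signature whose dominant frequency
#' separates control from PD-like animals), rearing dynamics, limb phasing
#' and foot trailing. All lengths are cm, rates per minute, durations s.
#'
#' `speed_complexity` is a multiplicative broadband roughness on the bout
#' speed profile; it carries the less-predictable chest dynamics of healthy
#' animals into the wavelet-entropy feature.
#'
#' @param bout_rate movement episodes per minute; 0 disables movement.
#' @param bout_duration_mean,bout_duration_sd bout length draw (s).
#' @param rest_interval_mean,rest_interval_sd rest length draw (s).
#' @param locomotion_speed_mean,locomotion_speed_sd per-bout chest speed
#'   draw (cm/s).
#' @param hand_distance_mean,hand_distance_sd lateral hand separation (cm).
#' @param stance_width_mean,stance_width_sd lateral hind-foot separation (cm).
#' @param body_length_mean,body_length_sd neck-anus body length (cm).
#' @param body_angle_mean,body_angle_sd interior neck-chest-anus angle (deg).
#' @param chest_osc_freq,chest_osc_amp chest oscillation band frequency (Hz)
#'   and vertical amplitude (cm).
#' @param rearing_rate rearing events per minute.
#' @param rearing_peak_vz peak vertical chest velocity during rearing (cm/s).
#' @param limb_phase_jitter sd of the left-right limb phase noise (radians).
#' @param foot_trail_prob probability per stride that the swing is a trailing
#'   (dragging) step with no foot lift.
#' @param tail_persistence lag-1 autocorrelation of the tail wiggle in [0,1).
#' @param speed_complexity broadband roughness of the bout speed profile.
#' @return a `phenotype_params` list.
#' @seealso [preset()] for the pinned control / PD parameterisations.
#' @export
phenotype_params <- function(bout_rate = 3,
                             bout_duration_mean = 8, bout_duration_sd = 3,
                             rest_interval_mean = 12, rest_interval_sd = 5,
                             locomotion_speed_mean = 6, locomotion_speed_sd = 1.5,
                             hand_distance_mean = 2.5, hand_distance_sd = 0.25,
                             stance_width_mean = 2.8, stance_width_sd = 0.3,
                             body_length_mean = 4.2, body_length_sd = 0.3,
                             body_angle_mean = 150, body_angle_sd = 8,
                             chest_osc_freq = 2.8, chest_osc_amp = 0.25,
                             rearing_rate = 2, rearing_peak_vz = 8,
                             limb_phase_jitter = 0.2,
                             foot_trail_prob = 0.02,
                             tail_persistence = 0.8,
                             speed_complexity = 0.25) {
  p <- as.list(environment())
  sds <- grepl("_sd$", names(p))
  if (any(unlist(p[sds]) < 0)) stop("all sds must be >= 0")
  if (bout_rate < 0 || rearing_rate < 0) stop("rates must be >= 0")
  if (foot_trail_prob < 0 || foot_trail_prob > 1) {
    stop("foot_trail_prob must be in [0,1]")
  }
  if (tail_persistence < 0 || tail_persistence >= 1) {
    stop("tail_persistence must be in [0,1)")
  }
  structure(p, class = "phenotype_params")
}

#' Pinned phenotype presets
#'
#' Named parameterisations anchoring the control and PD-like phenotypes:
#' control hands separated 2.5 cm with a 2.8 Hz chest band; severe PD with
#' restricted hands (1.1 cm), wide stance (4.2 cm), elongated rigid body
#' (5.0 cm), a 6.0 Hz chest band, slow prolonged movement bouts and frequent
#' foot trailing. `pd_mild` is the halfway interpolation and `treated` lies a
#' quarter of the way from control to severe.
#'
#' @param name one of `"control"`, `"pd_mild"`, `"pd_severe"`, `"treated"`.
#' @return a `phenotype_params` object.
#' @export
preset <- function(name = c("control", "pd_mild", "pd_severe", "treated")) {
  name <- match.arg(name)
  control <- phenotype_params()
  severe <- phenotype_params(
    bout_rate = 2,
    bout_duration_mean = 15, bout_duration_sd = 4,
    rest_interval_mean = 15, rest_interval_sd = 5,
    locomotion_speed_mean = 3, locomotion_speed_sd = 0.8,
    hand_distance_mean = 1.1, hand_distance_sd = 0.2,
    stance_width_mean = 4.2, stance_width_sd = 0.3,
    body_length_mean = 5.0, body_length_sd = 0.25,
    body_angle_mean = 168, body_angle_sd = 5,
    chest_osc_freq = 6.0, chest_osc_amp = 0.06,
    rearing_rate = 0.5, rearing_peak_vz = 3,
    limb_phase_jitter = 0.8,
    foot_trail_prob = 0.3,
    tail_persistence = 0.9,
    speed_complexity = 0.02
  )
  blend <- function(w) {
    p <- mapply(function(a, b) (1 - w) * a + w * b,
                unclass(control), unclass(severe), SIMPLIFY = FALSE)
    do.call(phenotype_params, p)
  }
  switch(name,
         control = control,
         pd_severe = severe,
         pd_mild = blend(0.5),
         treated = blend(0.25))
}

# stationary AR(1) noise with sd `s` and lag-1 correlation `rho`
ar1_noise <- function(n, s, rho = 0.8) {
  if (n == 0L) return(numeric(0))
  e <- stats::rnorm(n, 0, s * sqrt(1 - rho^2))
  as.numeric(stats::filter(e, rho, method = "recursive"))
}

# alternating rest/bout schedule in frames; returns matrix [start, end) rows
bout_schedule <- function(n, fs, p) {
  if (p$bout_rate <= 0) return(matrix(integer(0), 0, 2))
  bouts <- NULL
  pos <- max(1, stats::rnorm(1, p$rest_interval_mean / 2, p$rest_interval_sd))
  while (TRUE) {
    len <- max(4.5, stats::rnorm(1, p$bout_duration_mean, p$bout_duration_sd))
    s <- round(pos * fs)
    e <- round((pos + len) * fs)
    if (s >= n - 1) break
    bouts <- rbind(bouts, c(s, min(e, n)))
    pos <- pos + len +
      max(2, stats::rnorm(1, p$rest_interval_mean, p$rest_interval_sd))
  }
  if (is.null(bouts)) matrix(integer(0), 0, 2) else bouts
}

#' Generate one synthetic open-field session
#'
#' Simulates a 3D pose recording of a freely moving mouse under a given
#' phenotype: alternating rest and movement bouts, a smoothed random walk of
#' the body centre inside a 40 x 40 cm arena, left-right anti-phase limb
#' oscillators with optional foot trailing, a chest vertical oscillation band
#' at the phenotype frequency, rearing events with vertical chest excursions,
#' and parametric posture geometry. Ground truth (bout intervals, rearing and
#' per-foot swing annotations, realised draws) is returned alongside.
#'
#' @param params a [phenotype_params()] object.
#' @param duration session length in seconds (default 1200 = 20 min).
#' @param fs sampling rate in Hz (default 30).
#' @param seed integer seed; the session is bit-reproducible under it.
#' @param mouse_id,group,week metadata stored on the sequence.
#' @return list with `pose` (a [pose_sequence()]) and `truth` (list of
#'   `bouts`, `annotations`, `params`, `draws`, `seed`).
#' @export
generate_session <- function(params, duration = 1200, fs = 30, seed = 1L,
                             mouse_id = "m1", group = "control", week = 0L) {
  stopifnot(inherits(params, "phenotype_params"), duration > 0)
  if (params$chest_osc_freq >= fs / 2) {
    stop("chest_osc_freq must be below the Nyquist frequency")
  }
  set.seed(as.integer(seed))
  p <- params
  n <- round(duration * fs)
  tt <- (seq_len(n) - 1) / fs

  bouts <- bout_schedule(n, fs, p)
  in_bout <- rep(FALSE, n)
  v <- numeric(n)            # forward speed, cm/s
  f_stride <- numeric(n)     # stride cadence, Hz
  v0s <- numeric(nrow(bouts))
  for (b in seq_len(nrow(bouts))) {
    idx <- (bouts[b, 1] + 1):bouts[b, 2]
    in_bout[idx] <- TRUE
    v0 <- max(2.8, stats::rnorm(1, p$locomotion_speed_mean,
                                p$locomotion_speed_sd))
    v0s[b] <- v0
    surge <- 1 + 0.4 * sin(2 * pi * p$chest_osc_freq * tt[idx] +
                             stats::runif(1, 0, 2 * pi))
    rough <- 1 + p$speed_complexity * ar1_noise(length(idx), 1, 0.6)
    v[idx] <- pmax(1.6, v0 * surge * pmax(0.2, rough))
    f_stride[idx] <- min(5, max(1, v0 / 3))
  }

  # smoothed random walk in a 40 x 40 cm arena: heading wobble plus gentle
  # steering away from the walls; heading frozen while resting
  step <- v / fs
  wob <- ar1_noise(n, 0.012, 0.95)
  psi <- numeric(n); px <- numeric(n); py <- numeric(n)
  x <- 20; y <- 20; ps <- stats::runif(1, 0, 2 * pi); tr <- 0
  for (t in seq_len(n)) {
    if (step[t] > 0) {
      dev <- atan2(20 - y, 20 - x) - ps
      dev <- atan2(sin(dev), cos(dev))
      target <- if (min(x, y, 40 - x, 40 - y) < 6 && abs(dev) > pi / 2) {
        0.06 * sign(dev)
      } else 0
      tr <- tr + 0.2 * (target - tr)
      ps <- ps + wob[t] + tr
      x <- x + step[t] * cos(ps)
      y <- y + step[t] * sin(ps)
      x <- min(39, max(1, x)); y <- min(39, max(1, y))
    }
    psi[t] <- ps; px[t] <- x; py[t] <- y
  }
  ux <- cos(psi); uy <- sin(psi)      # heading unit
  lx <- -uy; ly <- ux                 # left-lateral unit

  # posture draws and per-frame series
  L <- max(2, stats::rnorm(1, p$body_length_mean, p$body_length_sd)) +
    ar1_noise(n, 0.05, 0.95)
  ang <- stats::rnorm(1, p$body_angle_mean, p$body_angle_sd / 2) +
    ar1_noise(n, p$body_angle_sd, 0.95)
  alpha <- pmax(0, (180 - ang)) * pi / 180
  hand_d <- max(0.4, stats::rnorm(1, p$hand_distance_mean, p$hand_distance_sd))
  stance <- max(0.8, stats::rnorm(1, p$stance_width_mean, p$stance_width_sd))

  # chest vertical oscillation band (bouts only)
  z_osc <- p$chest_osc_amp * sin(2 * pi * p$chest_osc_freq * tt +
                                   stats::runif(1, 0, 2 * pi))
  z_osc[!in_bout] <- 0

  # rearing events: half-sine chest elevation, peak vz as parameterised
  rear_T <- 1.5
  rear_len <- round(rear_T * fs)
  n_rear <- stats::rpois(1, p$rearing_rate * duration / 60)
  rear <- NULL
  if (n_rear > 0 && nrow(bouts) > 0) {
    roomy <- bouts[bouts[, 2] - bouts[, 1] > rear_len + 10, , drop = FALSE]
    if (nrow(roomy)) {
      starts <- integer(0)
      for (k in seq_len(n_rear)) {
        b <- roomy[sample.int(nrow(roomy), 1), ]
        s <- b[1] + sample.int(b[2] - b[1] - rear_len, 1)
        if (!any(abs(starts - s) < 2 * rear_len)) starts <- c(starts, s)
      }
      starts <- sort(starts)
      rear <- data.frame(kind = "rearing", foot = NA_character_,
                         start_frame = starts,
                         peak_frame = starts + rear_len %/% 2,
                         end_frame = starts + rear_len)
    }
  }
  z_rear <- numeric(n)
  H <- p$rearing_peak_vz * rear_T / pi
  if (!is.null(rear)) {
    for (k in seq_len(nrow(rear))) {
      idx <- (rear$start_frame[k] + 1):rear$end_frame[k]
      tau <- (idx - idx[1]) / fs
      z_rear[idx] <- H * sin(pi * tau / rear_T)
    }
  }

  # limb oscillators: phase advances during bouts at the bout cadence
  jit_r <- ar1_noise(n, p$limb_phase_jitter, 0.95)
  jit_l <- ar1_noise(n, p$limb_phase_jitter, 0.95)
  theta_r <- cumsum(2 * pi * f_stride / fs) + jit_r
  theta_l <- theta_r + pi + (jit_l - jit_r)
  swing_r <- in_bout & cos(theta_r) > 0
  swing_l <- in_bout & cos(theta_l) > 0

  # per-cycle foot trailing: no lift on trailing strides
  lift_amp <- function(theta) {
    cyc <- floor(theta / (2 * pi))
    ids <- match(cyc, sort(unique(cyc)))
    trail <- stats::runif(length(unique(cyc))) < p$foot_trail_prob
    ifelse(trail[ids], 0, 0.8)
  }
  hr <- lift_amp(theta_r); hl <- lift_amp(theta_l)

  noise <- function(s_rest = 0.01, s_bout = 0.015) {
    e <- ar1_noise(n, 1, 0.9)
    e * ifelse(in_bout, s_bout, s_rest)
  }

  co <- array(0, dim = c(n, 9L, 3L),
              dimnames = list(NULL, pose_nodes(), pose_axes()))
  osc_b <- as.numeric(in_bout)            # gates limb oscillation
  f_amp <- 0.75                           # foot fore-aft amplitude (cm)
  base_x <- 0.5 - 2 * p$foot_trail_prob   # foot base, body frame (cm)

  anus_x <- px; anus_y <- py; anus_z <- 1.5 + noise()
  chest_x <- anus_x + 0.6 * L * ux
  chest_y <- anus_y + 0.6 * L * uy
  chest_z <- 1.5 + z_osc + z_rear + noise()
  neck_x <- chest_x + 0.4 * L * cos(alpha) * ux
  neck_y <- chest_y + 0.4 * L * cos(alpha) * uy
  neck_z <- chest_z + 0.4 * L * sin(alpha) + noise()
  nose_x <- neck_x + 0.8 * cos(alpha) * ux
  nose_y <- neck_y + 0.8 * cos(alpha) * uy
  nose_z <- neck_z + 0.8 * sin(alpha) * 0.5 + noise()

  gamma <- ar1_noise(n, 0.3, p$tail_persistence)
  tip_x <- anus_x + 2.5 * cos(psi + pi + gamma)
  tip_y <- anus_y + 2.5 * sin(psi + pi + gamma)
  tip_z <- 1.0 + noise()

  # hands: lateral from chest, fore-aft anti-phase with ipsilateral feet
  hx_r <- 0.5 * sin(theta_l) * osc_b; hx_l <- 0.5 * sin(theta_r) * osc_b
  rh_x <- chest_x + (hand_d / 2) * (-lx) + hx_r * ux
  rh_y <- chest_y + (hand_d / 2) * (-ly) + hx_r * uy
  rh_z <- 0.8 + 0.3 * pmax(0, cos(theta_l)) * osc_b + 0.4 * z_rear + noise()
  lh_x <- chest_x + (hand_d / 2) * lx + hx_l * ux
  lh_y <- chest_y + (hand_d / 2) * ly + hx_l * uy
  lh_z <- 0.8 + 0.3 * pmax(0, cos(theta_r)) * osc_b + 0.4 * z_rear + noise()

  fx_r <- (base_x + f_amp * sin(theta_r) * osc_b)
  fx_l <- (base_x + f_amp * sin(theta_l) * osc_b)
  rf_x <- anus_x + (stance / 2) * (-lx) + fx_r * ux
  rf_y <- anus_y + (stance / 2) * (-ly) + fx_r * uy
  rf_z <- 0.15 + hr * pmax(0, cos(theta_r)) * osc_b + noise(0.005, 0.01)
  lf_x <- anus_x + (stance / 2) * lx + fx_l * ux
  lf_y <- anus_y + (stance / 2) * ly + fx_l * uy
  lf_z <- 0.15 + hl * pmax(0, cos(theta_l)) * osc_b + noise(0.005, 0.01)

  co[, "nose", ]   <- cbind(nose_x, nose_y, nose_z)
  co[, "neck", ]   <- cbind(neck_x, neck_y, neck_z)
  co[, "chest", ]  <- cbind(chest_x, chest_y, chest_z)
  co[, "r_hand", ] <- cbind(rh_x, rh_y, rh_z)
  co[, "l_hand", ] <- cbind(lh_x, lh_y, lh_z)
  co[, "r_foot", ] <- cbind(rf_x, rf_y, rf_z)
  co[, "l_foot", ] <- cbind(lf_x, lf_y, lf_z)
  co[, "anus", ]   <- cbind(anus_x, anus_y, anus_z)
  co[, "tip", ]    <- cbind(tip_x, tip_y, tip_z)

  pose <- pose_sequence(co, fs = fs, mouse_id = mouse_id, group = group,
                        week = week)
  swing_ann <- rbind(runs_to_ann(swing_r, "r_foot"),
                     runs_to_ann(swing_l, "l_foot"))
  ann <- rbind(rear, swing_ann)
  truth <- list(
    bouts = data.frame(start_frame = bouts[, 1], end_frame = bouts[, 2]),
    annotations = if (is.null(ann)) empty_annotations() else
      validate_annotations(ann, n),
    params = p,
    draws = list(body_length = mean(L), body_angle = mean(ang),
                 hand_distance = hand_d, stance_width = stance,
                 bout_speeds = v0s),
    seed = as.integer(seed)
  )
  list(pose = pose, truth = truth)
}

empty_annotations <- function() {
  data.frame(kind = character(0), foot = character(0),
             start_frame = integer(0), peak_frame = integer(0),
             end_frame = integer(0))
}

# convert a logical flag series into half-open swing annotations
runs_to_ann <- function(flag, foot) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= 2L
  if (!any(keep)) return(NULL)
  data.frame(kind = "swing", foot = foot,
             start_frame = starts[keep] - 1L, peak_frame = NA_integer_,
             end_frame = ends[keep])
}

#' Specify and generate a synthetic cohort
#'
#' A cohort is a set of groups, each with a phenotype, a number of mice and a
#' list of recording weeks. `generate_cohort()` produces one session per
#' mouse per week, bit-reproducibly under the cohort seed. For groups with
#' `drift > 0` the phenotype drifts linearly toward the severe preset with
#' week, emulating disease progression.
#'
#' @param groups list of groups, each a list with `label`,
#'   `params` (a [phenotype_params()]), `n_mice`, and optional `drift`
#'   (fraction of the distance to `preset("pd_severe")` reached at the last
#'   week; default 0).
#' @param weeks integer week indices (default 0).
#' @param seed cohort seed.
#' @param duration,fs session length (s) and sampling rate (Hz).
#' @return for `cohort_spec()` a `cohort_spec` object; for
#'   `generate_cohort()` a list of sessions, each as returned by
#'   [generate_session()], with metadata set.
#' @export
cohort_spec <- function(groups, weeks = 0L, seed = 1L,
                        duration = 1200, fs = 30) {
  for (g in groups) {
    stopifnot(!is.null(g$label), inherits(g$params, "phenotype_params"),
              g$n_mice >= 1)
  }
  structure(list(groups = groups, weeks = as.integer(weeks),
                 seed = as.integer(seed), duration = duration, fs = fs),
            class = "cohort_spec")
}

#' @rdname cohort_spec
#' @param spec a `cohort_spec`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  severe <- preset("pd_severe")
  sessions <- list()
  counter <- 0L
  max_week <- max(spec$weeks, 1L)
  for (g in spec$groups) {
    drift <- if (is.null(g$drift)) 0 else g$drift
    for (m in seq_len(g$n_mice)) {
      mid <- sprintf("%s_%02d", g$label, m)
      for (w in spec$weeks) {
        counter <- counter + 1L
        p <- g$params
        if (drift > 0 && w > 0) {
          frac <- drift * w / max_week
          p <- do.call(phenotype_params, mapply(
            function(a, b) (1 - frac) * a + frac * b,
            unclass(g$params), unclass(severe), SIMPLIFY = FALSE))
        }
        s <- generate_session(
          p, duration = spec$duration, fs = spec$fs,
          seed = (spec$seed * 1000L + counter * 7L) %% .Machine$integer.max,
          mouse_id = mid, group = g$label, week = w)
        sessions[[length(sessions) + 1L]] <- s
      }
    }
  }
  sessions
}
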