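# pinned signal registry ------------------------------------------------------

kin_angle_defs <- function() {
  # interior angle at the middle node, or limb axis vs limb vector
  list(
    head_angle = list(type = "vertex", nodes = c("nose", "neck", "chest")),
    body_angle = list(type = "vertex", nodes = c("neck", "chest", "anus")),
    tail_angle = list(type = "vertex", nodes = c("chest", "anus", "tip")),
    r_arm_angle = list(type = "limb", axis = c("neck", "chest"),
                       limb = c("chest", "r_hand")),
    l_arm_angle = list(type = "limb", axis = c("neck", "chest"),
                       limb = c("chest", "l_hand")),
    r_leg_angle = list(type = "limb", axis = c("chest", "anus"),
                       limb = c("anus", "r_foot")),
    l_leg_angle = list(type = "limb", axis = c("chest", "anus"),
                       limb = c("anus", "l_foot"))
  )
}

kin_dist_defs <- function() {
  list(
    hands_3D_dist = list(nodes = c("r_hand", "l_hand"), space = "3D"),
    hands_2D_dist = list(nodes = c("r_hand", "l_hand"), space = "2D"),
    feet_3D_dist = list(nodes = c("r_foot", "l_foot"), space = "3D"),
    feet_2D_dist = list(nodes = c("r_foot", "l_foot"), space = "2D"),
    body_3D_dist = list(nodes = c("neck", "anus"), space = "3D"),
    body_2D_dist = list(nodes = c("neck", "anus"), space = "2D"),
    upper_body_3D_dist = list(nodes = c("nose", "chest"), space = "3D"),
    upper_body_2D_dist = list(nodes = c("nose", "chest"), space = "2D"),
    nose_tip_3D_dist = list(nodes = c("nose", "tip"), space = "3D"),
    nose_tip_2D_dist = list(nodes = c("nose", "tip"), space = "2D"),
    r_hand_r_foot_3D_dist = list(nodes = c("r_hand", "r_foot"), space = "3D"),
    l_hand_l_foot_3D_dist = list(nodes = c("l_hand", "l_foot"), space = "3D"),
    r_hand_l_foot_3D_dist = list(nodes = c("r_hand", "l_foot"), space = "3D"),
    l_hand_r_foot_3D_dist = list(nodes = c("l_hand", "r_foot"), space = "3D")
  )
}

kin_angdiff_defs <- function() {
  list(c("r_arm_angle", "l_arm_angle"), c("r_leg_angle", "l_leg_angle"),
       c("r_arm_angle", "r_leg_angle"), c("l_arm_angle", "l_leg_angle"),
       c("r_arm_angle", "l_leg_angle"), c("l_arm_angle", "r_leg_angle"),
       c("head_angle", "body_angle"), c("body_angle", "tail_angle"))
}

#' Names of the per-frame kinematic signal registry
#'
#' The registry holds 83 per-frame signals: 27 node speeds (9 nodes x
#' 1D/2D/3D), 7 interior/limb angles (degrees), 14 node-pair distances (cm),
#' 8 absolute angle differences (degrees) and the 27 raw coordinates.
#'
#' @return character vector of the 83 signal names, in registry order.
#' @export
signal_registry <- function() {
  speeds <- as.vector(t(outer(pose_nodes(), c("1D", "2D", "3D"),
                              function(n, s) paste(n, s, "speed", sep = "_"))))
  ad <- vapply(kin_angdiff_defs(), function(p) {
    paste0(sub("_angle$", "", p[1]), "_", sub("_angle$", "", p[2]), "_angdiff")
  }, character(1))
  c(speeds, names(kin_angle_defs()), names(kin_dist_defs()), ad,
    pose_coord_names())
}

vec_angle_deg <- function(u, v) {
  # row-wise interior angle between 3D vectors, degrees; degenerate -> NA
  nu <- sqrt(rowSums(u^2)); nv <- sqrt(rowSums(v^2))
  ok <- nu > 1e-9 & nv > 1e-9
  cosv <- rowSums(u * v) / (nu * nv)
  out <- rep(NA_real_, nrow(u))
  out[ok] <- acos(pmin(1, pmax(-1, cosv[ok]))) * 180 / pi
  out
}

node_xyz <- function(seq, node, axes = c("x", "y", "z")) {
  matrix(seq$coords[, node, axes, drop = FALSE], nrow = seq$n_frames)
}

#' Compute the per-frame signal registry for a session
#'
#' Evaluates all 83 registry signals (see [signal_registry()]) over every
#' frame of a session. Degenerate angle frames (coincident nodes) are `NA`
#' and are excluded from clip statistics downstream.
#'
#' @param seq a [pose_sequence()].
#' @return numeric matrix `n_frames x 83` with signal names as columns.
#' @export
compute_signals <- function(seq) {
  n <- seq$n_frames
  out <- matrix(NA_real_, n, 83L, dimnames = list(NULL, signal_registry()))
  for (node in pose_nodes()) {
    for (sp in c("1D", "2D", "3D")) {
      out[, paste(node, sp, "speed", sep = "_")] <- node_speed(seq, node, sp)
    }
  }
  angs <- kin_angle_defs()
  for (an in names(angs)) {
    d <- angs[[an]]
    if (d$type == "vertex") {
      u <- node_xyz(seq, d$nodes[1]) - node_xyz(seq, d$nodes[2])
      v <- node_xyz(seq, d$nodes[3]) - node_xyz(seq, d$nodes[2])
    } else {
      u <- node_xyz(seq, d$axis[2]) - node_xyz(seq, d$axis[1])
      v <- node_xyz(seq, d$limb[2]) - node_xyz(seq, d$limb[1])
    }
    out[, an] <- vec_angle_deg(u, v)
  }
  dists <- kin_dist_defs()
  for (dn in names(dists)) {
    d <- dists[[dn]]
    axes <- if (d$space == "2D") c("x", "y") else c("x", "y", "z")
    diffm <- node_xyz(seq, d$nodes[1], axes) - node_xyz(seq, d$nodes[2], axes)
    out[, dn] <- sqrt(rowSums(diffm^2))
  }
  for (p in kin_angdiff_defs()) {
    nm <- paste0(sub("_angle$", "", p[1]), "_", sub("_angle$", "", p[2]),
                 "_angdiff")
    out[, nm] <- abs(out[, p[1]] - out[, p[2]])
  }
  out[, pose_coord_names()] <- pose_flat(seq)
  out
}

#' Clip statistics of signal values
#'
#' Minimum, maximum, mean and standard deviation (denominator n-1) of each
#' signal over the frames of one clip, excluding masked (`NA`) frames.
#'
#' @param x numeric matrix (frames x signals) or vector.
#' @return named numeric vector: for each signal, `<signal>_min`, `_max`,
#'   `_mean`, `_std`. A signal with fewer than 2 unmasked frames yields
#'   `NA` statistics.
#' @export
clip_statistics <- function(x) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 1L, dimnames = list(NULL, "x"))
  nok <- colSums(!is.na(x))
  safe <- function(f) {
    v <- suppressWarnings(apply(x, 2L, f, na.rm = TRUE))
    v[nok < 1L] <- NA_real_
    v
  }
  mn <- safe(min); mx <- safe(max); mu <- colMeans(x, na.rm = TRUE)
  sd_ <- apply(x, 2L, stats::sd, na.rm = TRUE)
  mu[nok < 1L] <- NA_real_
  sd_[nok < 2L] <- NA_real_
  sn <- colnames(x)
  stats::setNames(
    as.vector(rbind(mn, mx, mu, sd_)),
    as.vector(rbind(paste0(sn, "_min"), paste0(sn, "_max"),
                    paste0(sn, "_mean"), paste0(sn, "_std"))))
}

kin_metadata_cols <- function() {
  c("mouse", "group", "week", "episode", "clip_index", "start_frame")
}

#' Assemble the 340-column kinematic feature table
#'
#' For each clip: the 4 statistics of the 83 registry signals (332 columns)
#' plus the 8 episode temporal parameters, with session metadata attached.
#' Clips whose signals are entirely masked are dropped with a message.
#'
#' @param seq a [pose_sequence()].
#' @param episodes,clips tables from [detect_motion_episodes()] and
#'   [fragment_clips()]; computed from chest 3D speed when `NULL`.
#' @param clip_len clip length in frames (default 60).
#' @return data frame: 6 metadata columns then exactly 340 feature columns
#'   (attribute `feature_cols` lists them).
#' @export
assemble_feature_table <- function(seq, episodes = NULL, clips = NULL,
                                   clip_len = 60L) {
  if (is.null(episodes)) {
    episodes <- detect_motion_episodes(node_speed(seq, "chest", "3D"),
                                       fs = seq$fs)
  }
  if (is.null(clips)) clips <- fragment_clips(episodes, clip_len)
  sig_names <- signal_registry()
  stat_names <- as.vector(rbind(paste0(sig_names, "_min"),
                                paste0(sig_names, "_max"),
                                paste0(sig_names, "_mean"),
                                paste0(sig_names, "_std")))
  ep_names <- c("ep_duration", "ep_interval", "ep_n_clips", "ep_onset",
                "ep_path_length", "ep_mean_speed", "ep_rest_ratio",
                "ep_ordinal")
  feat_names <- c(stat_names, ep_names)
  meta <- data.frame(mouse = character(0), group = character(0),
                     week = integer(0), episode = integer(0),
                     clip_index = integer(0), start_frame = integer(0))
  if (nrow(clips) == 0L) {
    out <- cbind(meta, as.data.frame(matrix(numeric(0), 0,
                                            length(feat_names),
                                            dimnames = list(NULL, feat_names))))
    attr(out, "feature_cols") <- feat_names
    return(out)
  }
  signals <- compute_signals(seq)
  ep_par <- episode_temporal_params(episodes, seq, clip_len)
  rows <- vector("list", nrow(clips))
  for (i in seq_len(nrow(clips))) {
    idx <- (clips$start_frame[i] + 1L):clips$end_frame[i]
    rows[[i]] <- clip_statistics(signals[idx, , drop = FALSE])
  }
  feats <- do.call(rbind, rows)
  all_masked <- rowSums(!is.na(feats)) == 0L
  if (any(all_masked)) {
    message(sum(all_masked), " clip(s) dropped: all frames masked")
  }
  keep <- !all_masked
  ep_idx <- match(clips$episode, ep_par$ep_ordinal)
  out <- cbind(
    data.frame(mouse = seq$mouse_id, group = seq$group, week = seq$week,
               episode = clips$episode, clip_index = clips$clip_index,
               start_frame = clips$start_frame)[keep, , drop = FALSE],
    as.data.frame(feats[keep, , drop = FALSE]),
    ep_par[ep_idx[keep], , drop = FALSE]
  )
  rownames(out) <- NULL
  attr(out, "feature_cols") <- feat_names
  out
}

#' Kinematic feature table for a set of sessions
#'
#' Convenience wrapper: segments each session from chest 3D speed, fragments
#' into clips and stacks the per-session feature tables.
#'
#' @param sessions list of sessions as returned by [generate_cohort()], or a
#'   list of [pose_sequence()] objects.
#' @param clip_len clip length in frames.
#' @return stacked feature table (see [assemble_feature_table()]).
#' @export
featurize_sessions <- function(sessions, clip_len = 60L) {
  tabs <- lapply(sessions, function(s) {
    seq <- if (inherits(s, "pose_sequence")) s else s$pose
    assemble_feature_table(seq, clip_len = clip_len)
  })
  out <- do.call(rbind, tabs)
  attr(out, "feature_cols") <- attr(tabs[[1]], "feature_cols")
  rownames(out) <- NULL
  out
}

#' Quantile-based trimming of a feature table
#'
#' Per feature and per group, rows with values outside the `[lo, hi]`
#' quantile interval are masked (`NA`) for that feature. The trim bounds are
#' estimated once from the incoming data and stored on the result, so
#' re-applying the same trim is idempotent.
#'
#' @param table a feature table (data frame) with a `group` column.
#' @param lo,hi quantile probabilities (defaults 0.01 and 0.99).
#' @param feature_cols columns to trim; defaults to the table's
#'   `feature_cols` attribute, else all numeric non-metadata columns.
#' @return the table with out-of-bound values masked; attribute
#'   `trim_bounds` records the per-group bounds used.
#' @export
quantile_trim <- function(table, lo = 0.01, hi = 0.99, feature_cols = NULL) {
  if (is.null(feature_cols)) feature_cols <- attr(table, "feature_cols")
  if (is.null(feature_cols)) {
    feature_cols <- setdiff(names(table)[vapply(table, is.numeric, TRUE)],
                            kin_metadata_cols())
  }
  groups <- if ("group" %in% names(table)) table$group else
    rep("all", nrow(table))
  stored <- attr(table, "trim_bounds")
  reuse <- !is.null(stored) && identical(stored$lo, lo) &&
    identical(stored$hi, hi)
  bounds <- if (reuse) stored$bounds else list()
  for (g in unique(groups)) {
    gi <- which(groups == g)
    for (fc in feature_cols) {
      v <- table[[fc]][gi]
      if (reuse) {
        b <- bounds[[g]][[fc]]
      } else {
        b <- stats::quantile(v, c(lo, hi), na.rm = TRUE, names = FALSE)
        bounds[[g]][[fc]] <- b
      }
      if (any(is.na(b))) next
      table[[fc]][gi[!is.na(v) & (v < b[1] | v > b[2])]] <- NA
    }
  }
  attr(table, "trim_bounds") <- list(lo = lo, hi = hi, bounds = bounds)
  table
}
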