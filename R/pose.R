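#' Body node and segment definitions
#'
#' The pose model tracks 9 body nodes of a mouse in 3D and derives 8 body
#' segments (action skeletons) from them. Node order is fixed and is the
#' column order used in pose files.
#'
#' @return `pose_nodes()` returns the 9 node names in their canonical order;
#'   `pose_segments()` returns a named list mapping each of the 8 segment
#'   names to its ordered `c(from, to)` node pair.
#' @examples
#' pose_nodes()
#' pose_segments()$h_body
#' @export
pose_nodes <- function() {
  c("nose", "neck", "chest", "r_hand", "l_hand", "r_foot", "l_foot",
    "anus", "tip")
}

#' @rdname pose_nodes
#' @export
pose_segments <- function() {
  list(
    head   = c("nose", "neck"),
    f_body = c("neck", "chest"),
    h_body = c("chest", "anus"),
    tail   = c("anus", "tip"),
    r_arm  = c("chest", "r_hand"),
    l_arm  = c("chest", "l_hand"),
    r_leg  = c("anus", "r_foot"),
    l_leg  = c("anus", "l_foot")
  )
}

pose_axes <- function() c("x", "y", "z")

# canonical 27 coordinate column names: <node>_<axis>, node-major
pose_coord_names <- function() {
  as.vector(t(outer(pose_nodes(), pose_axes(), paste, sep = "_")))
}

#' Construct a pose sequence
#'
#' A `pose_sequence` holds one recording session: a frames x 9 nodes x 3 axes
#' array of 3D keypoint coordinates (cm) sampled at `fs` Hz, plus session
#' metadata. z is the vertical axis; frames are 0-based and contiguous.
#'
#' @param coords numeric array `n_frames x 9 x 3`, or an `n_frames x 27`
#'   matrix/data frame with columns named `<node>_<axis>`.
#' @param fs sampling rate in Hz (default 30).
#' @param mouse_id,group,week session metadata.
#' @param validate check finiteness and dimensions (default `TRUE`).
#' @return An object of class `pose_sequence` with elements `coords`
#'   (3D array with dimnames), `fs`, `n_frames`, `mouse_id`, `group`, `week`.
#' @export
pose_sequence <- function(coords, fs = 30, mouse_id = NA_character_,
                          group = NA_character_, week = NA_integer_,
                          validate = TRUE) {
  if (is.data.frame(coords)) coords <- as.matrix(coords)
  if (is.matrix(coords)) {
    if (ncol(coords) != 27L) {
      stop("coordinate matrix must have 27 columns, got ", ncol(coords))
    }
    cn <- colnames(coords)
    if (!is.null(cn)) {
      missing <- setdiff(pose_coord_names(), cn)
      if (length(missing)) {
        stop("missing coordinate columns: ", paste(missing, collapse = ", "))
      }
      coords <- coords[, pose_coord_names(), drop = FALSE]
    }
    coords <- array(coords, dim = c(nrow(coords), 3L, 9L))
    # matrix was node-major (x,y,z per node); array fill is column-major so
    # dim 2 is axis, dim 3 is node -> permute to frames x nodes x axes
    coords <- aperm(coords, c(1L, 3L, 2L))
  }
  if (length(dim(coords)) != 3L || dim(coords)[2] != 9L || dim(coords)[3] != 3L) {
    stop("coords must be an n_frames x 9 x 3 array")
  }
  if (validate && length(coords) && !all(is.finite(coords))) {
    stop("non-finite coordinates after validation")
  }
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) stop("fs must be > 0")
  dimnames(coords) <- list(NULL, pose_nodes(), pose_axes())
  structure(
    list(coords = coords, fs = fs, n_frames = dim(coords)[1],
         mouse_id = mouse_id, group = group, week = week),
    class = "pose_sequence"
  )
}

#' @export
print.pose_sequence <- function(x, ...) {
  cat(sprintf("<pose_sequence> %d frames @ %g Hz (%.1f s)\n",
              x$n_frames, x$fs, x$n_frames / x$fs))
  cat(sprintf("  mouse: %s  group: %s  week: %s\n",
              x$mouse_id, x$group, x$week))
  invisible(x)
}

# flatten coords to the canonical n x 27 matrix
pose_flat <- function(seq) {
  m <- matrix(aperm(seq$coords, c(1L, 3L, 2L)), nrow = seq$n_frames,
              ncol = 27L)
  colnames(m) <- pose_coord_names()
  m
}

#' Read and write pose files
#'
#' Pose files are delimited text with a `frame` column followed by the 27
#' coordinate columns `<node>_<axis>` (cm). On read, NA gaps of at most
#' `max_gap` frames per column are linearly interpolated; longer gaps are
#' rejected. The round trip is lossless to 1e-6 cm.
#'
#' @param path file path.
#' @param fs sampling rate in Hz.
#' @param max_gap longest internal NA run (frames) repaired by linear
#'   interpolation; longer runs abort the read.
#' @param ... metadata passed to [pose_sequence()].
#' @return [read_pose()] returns a `pose_sequence`; [write_pose()] invisibly
#'   returns `path`.
#' @export
read_pose <- function(path, fs = 30, max_gap = 5L, ...) {
  tab <- utils::read.csv(path, check.names = FALSE)
  if (!"frame" %in% names(tab)) stop("pose file lacks a 'frame' column")
  want <- pose_coord_names()
  missing <- setdiff(want, names(tab))
  if (length(missing)) {
    stop("missing coordinate columns: ", paste(missing, collapse = ", "))
  }
  extra <- setdiff(names(tab), c("frame", "time", want))
  if (length(extra)) {
    stop("unexpected extra columns: ", paste(extra, collapse = ", "))
  }
  fr <- tab$frame
  if (length(fr) && !all(diff(fr) == 1)) stop("non-monotone frame index")
  m <- as.matrix(tab[, want, drop = FALSE])
  storage.mode(m) <- "double"
  if (anyNA(m)) m <- apply(m, 2L, fill_gaps, max_gap = max_gap)
  if (is.null(dim(m))) m <- matrix(m, ncol = 27L, dimnames = list(NULL, want))
  pose_sequence(m, fs = fs, ...)
}

# linear interpolation of interior NA runs of length <= max_gap
fill_gaps <- function(x, max_gap = 5L) {
  if (!anyNA(x)) return(x)
  na <- is.na(x)
  r <- rle(na)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  bad <- which(r$values)
  for (i in bad) {
    if (starts[i] == 1L || ends[i] == length(x)) {
      stop("NA gap touches the session boundary; cannot interpolate")
    }
    if (r$lengths[i] > max_gap) {
      stop("NA gap of ", r$lengths[i], " frames exceeds the ", max_gap,
           "-frame interpolation limit")
    }
  }
  ok <- which(!na)
  x[na] <- stats::approx(ok, x[ok], xout = which(na))$y
  x
}

#' @rdname read_pose
#' @param seq a `pose_sequence`.
#' @export
write_pose <- function(seq, path) {
  stopifnot(inherits(seq, "pose_sequence"))
  m <- pose_flat(seq)
  df <- data.frame(frame = seq_len(seq$n_frames) - 1L)
  df <- cbind(df, as.data.frame(m))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Per-frame segment vectors
#'
#' For each of the 8 body segments the vector from its start node to its end
#' node, per frame. Invariant to rigid translation of the whole pose.
#'
#' @param seq a `pose_sequence`.
#' @return numeric array `n_frames x 8 segments x 3 axes` with dimnames.
#' @export
segment_vectors <- function(seq) {
  segs <- pose_segments()
  out <- array(NA_real_, dim = c(seq$n_frames, length(segs), 3L),
               dimnames = list(NULL, names(segs), pose_axes()))
  for (i in seq_along(segs)) {
    out[, i, ] <- seq$coords[, segs[[i]][2], , drop = FALSE] -
      seq$coords[, segs[[i]][1], , drop = FALSE]
  }
  out
}

#' Body-aligned reference frame at one frame
#'
#' Maps world xy coordinates into a frame with origin at the anus and +x along
#' the horizontal anus-to-chest direction; z is unchanged. Used for foot
#' placement maps (feet behind the anus have body-frame x < 0).
#'
#' @param seq a `pose_sequence`.
#' @param frame 0-based frame index.
#' @return list with `origin` (anus xy), `rot` (2x2 rotation matrix applied as
#'   `rot %*% (p - origin)`), and `degenerate` (TRUE when anus and chest
#'   coincide in xy within 1e-6 cm, in which case `rot` is NA).
#' @export
body_frame <- function(seq, frame) {
  i <- frame + 1L
  a <- seq$coords[i, "anus", c("x", "y")]
  c2 <- seq$coords[i, "chest", c("x", "y")]
  h <- c2 - a
  nh <- sqrt(sum(h^2))
  if (nh < 1e-6) {
    return(list(origin = a, rot = matrix(NA_real_, 2, 2), degenerate = TRUE))
  }
  u <- h / nh
  # rows: body x axis (heading), body y axis (left of heading)
  rot <- rbind(c(u[1], u[2]), c(-u[2], u[1]))
  list(origin = a, rot = rot, degenerate = FALSE)
}

#' Transform world xy points into a body frame
#'
#' @param bf a frame returned by [body_frame()].
#' @param xy numeric matrix of world xy points (rows) or a length-2 vector.
#' @return matrix of body-frame xy coordinates.
#' @export
to_body_frame <- function(bf, xy) {
  if (is.null(dim(xy))) xy <- matrix(xy, ncol = 2L)
  if (bf$degenerate) {
    return(matrix(NA_real_, nrow(xy), 2L))
  }
  t(bf$rot %*% (t(xy) - bf$origin))
}

#' Read event annotation tables
#'
#' Annotations are CSV with columns `kind` (`rearing` or `swing`), `foot`
#' (required for swing), `start_frame`, `peak_frame` (rearing only),
#' `end_frame`. Intervals are half-open `[start, end)` in 0-based frames.
#'
#' @param path CSV path.
#' @param n_frames optional session length for bounds checking.
#' @return data frame of validated annotations.
#' @export
read_annotations <- function(path, n_frames = NULL) {
  ann <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_annotations(ann, n_frames)
}

validate_annotations <- function(ann, n_frames = NULL) {
  need <- c("kind", "foot", "start_frame", "peak_frame", "end_frame")
  for (col in setdiff(need, names(ann))) ann[[col]] <- NA
  ann <- ann[, need]
  bad_kind <- !ann$kind %in% c("rearing", "swing")
  if (any(bad_kind)) stop("unknown annotation kind: ", ann$kind[bad_kind][1])
  rr <- ann$kind == "rearing"
  if (any(rr & (ann$start_frame > ann$peak_frame |
                ann$peak_frame > ann$end_frame), na.rm = TRUE)) {
    stop("rearing annotation violates start <= peak <= end")
  }
  sw <- ann$kind == "swing"
  if (any(sw & is.na(ann$foot))) stop("swing annotation lacks a foot")
  if (any(sw & !(ann$foot %in% c("r_foot", "l_foot")), na.rm = TRUE)) {
    stop("swing foot must be r_foot or l_foot")
  }
  if (any(ann$start_frame >= ann$end_frame & sw)) {
    stop("swing annotation violates start < end")
  }
  if (!is.null(n_frames) &&
      any(ann$start_frame < 0 | ann$end_frame > n_frames)) {
    stop("annotation outside the session")
  }
  ann
}

#' @rdname read_annotations
#' @param ann annotation data frame.
#' @export
write_annotations <- function(ann, path) {
  utils::write.csv(ann, path, row.names = FALSE)
  invisible(path)
}
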