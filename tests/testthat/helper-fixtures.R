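# in-code fixtures and independent oracles shared across the suite

# a pose array where every node sits at a distinct fixed offset (no
# degenerate geometry), n frames
base_coords <- function(n) {
  offs <- rbind(
    nose = c(3.0, 0.0, 2.4), neck = c(2.4, 0.0, 2.6),
    chest = c(1.8, 0.0, 2.5), r_hand = c(1.8, -1.2, 0.8),
    l_hand = c(1.8, 1.2, 0.8), r_foot = c(0.2, -1.4, 0.2),
    l_foot = c(0.2, 1.4, 0.2), anus = c(0.0, 0.0, 1.5),
    tip = c(-2.5, 0.0, 1.0))
  co <- array(0, dim = c(n, 9, 3),
              dimnames = list(NULL, pose_nodes(), pose_axes()))
  for (nd in pose_nodes()) co[, nd, ] <- matrix(offs[nd, ], n, 3, byrow = TRUE)
  co
}

make_pose <- function(n = 100, fs = 30, ...) {
  pose_sequence(base_coords(n), fs = fs, ...)
}

# random rigid transform: rotation (via QR, det +1) plus translation
rigid_transform <- function(co, rot = NULL, shift = c(0, 0, 0)) {
  if (is.null(rot)) {
    qr_ <- qr(matrix(stats::rnorm(9), 3))
    rot <- qr.Q(qr_)
    if (det(rot) < 0) rot[, 1] <- -rot[, 1]
  }
  out <- co
  for (nd in dimnames(co)[[2]]) {
    out[, nd, ] <- co[, nd, ] %*% t(rot) +
      matrix(shift, nrow(co), 3, byrow = TRUE)
  }
  out
}

# exhaustive window-scan episode oracle (independent of the implementation)
oracle_episodes <- function(speed, threshold = 1.5, window = 100L,
                            frac = 0.8) {
  n <- length(speed)
  covered <- rep(FALSE, n)
  for (t in seq_len(n - window + 1L)) {
    s <- 0
    for (j in t:(t + window - 1L)) s <- s + (speed[j] > threshold)
    if (s > window * frac) covered[t:(t + window - 1L)] <- TRUE
  }
  r <- rle(covered)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  data.frame(start_frame = starts[keep] - 1L, end_frame = ends[keep])
}

# direct-sum convolution oracle for the Ricker CWT (same kernel sampling)
oracle_cwt_row <- function(x, a) {
  T_ <- length(x)
  L <- min(10L * a + 1L, T_)
  if (L %% 2L == 0L) L <- L - 1L
  tt <- seq_len(L) - 1 - (L - 1) / 2
  A <- 2 / (sqrt(3 * a) * pi^0.25)
  k <- A * (1 - (tt / a)^2) * exp(-tt^2 / (2 * a^2))
  h <- (L - 1L) %/% 2L
  out <- numeric(T_)
  for (nn in seq_len(T_)) {
    s <- 0
    for (j in max(1L, nn - h):min(T_, nn + h)) {
      s <- s + x[j] * k[h + 1L + (nn - j)]
    }
    out[nn] <- s
  }
  out
}

# brute-force DFT magnitude spectrum (one-sided) and peak rule
oracle_fundamental <- function(x, fs) {
  T_ <- length(x)
  xc <- x - mean(x)
  nf <- T_ %/% 2 + 1L
  mag <- numeric(nf)
  for (k in seq_len(nf)) {
    re <- sum(xc * cos(-2 * pi * (k - 1) * (seq_len(T_) - 1) / T_))
    im <- sum(xc * sin(-2 * pi * (k - 1) * (seq_len(T_) - 1) / T_))
    mag[k] <- sqrt(re^2 + im^2)
  }
  freq <- (seq_len(nf) - 1) * fs / T_
  peaks <- freq[mag > 0.3 * max(mag) & freq > 0]
  if (!length(peaks)) NA_real_ else min(peaks)
}

# tiny labelled feature set with one informative column, for classifier tests
toy_features <- function(n_per = 120, p_noise = 20, shift = 4, seed = 7) {
  set.seed(seed)
  x <- cbind(
    signal = c(stats::rnorm(n_per), stats::rnorm(n_per, shift)),
    matrix(stats::rnorm(2 * n_per * p_noise), ncol = p_noise,
           dimnames = list(NULL, paste0("noise", seq_len(p_noise)))))
  labels <- factor(rep(c("np", "pd"), each = n_per), levels = c("np", "pd"))
  list(x = x, labels = labels)
}
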