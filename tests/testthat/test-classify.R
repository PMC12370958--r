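test_that("balancing downsamples the majority and splits stratified", {
  set.seed(1)
  x <- matrix(stats::rnorm(1600 * 3), ncol = 3,
              dimnames = list(NULL, c("a", "b", "c")))
  y <- factor(rep(c("np", "pd"), c(1000, 600)))
  sp <- balance_and_split(x, y, ratio = 0.7, seed = 4)
  expect_equal(unname(sp$balance_counts), c(600, 600))
  expect_equal(length(sp$train_y), 840)
  expect_equal(length(sp$valid_y), 360)
  expect_equal(as.integer(table(sp$train_y)), c(420L, 420L))
  sp2 <- balance_and_split(x, y, ratio = 0.7, seed = 4)
  expect_identical(sp$train_idx, sp2$train_idx)
  expect_error(balance_and_split(x, factor(rep("np", 1600))), "two classes")
})

test_that("feature selection drops duplicates and recovers planted signal", {
  tf <- toy_features()
  x <- cbind(tf$x, signal_copy = tf$x[, "signal"])
  sel <- select_features(x, tf$labels, k = 5, seed = 2)
  expect_length(sel, 5)
  expect_false(anyDuplicated(sel) > 0)
  # the collinear twin cannot survive alongside the original
  expect_false(all(c("signal", "signal_copy") %in% sel))
  # the planted feature outranks pure noise
  wins <- 0L
  for (s in 1:20) {
    tf2 <- toy_features(n_per = 60, p_noise = 10, shift = 3, seed = 100 + s)
    sel2 <- select_features(tf2$x, tf2$labels, k = 3, seed = s)
    wins <- wins + ("signal" %in% sel2)
  }
  expect_gte(wins, 19L)
  expect_error(select_features(tf$x[, 1:3], tf$labels, k = 10), "fewer than k")
})

test_that("label-independent features give chance-level validation accuracy", {
  set.seed(12)
  x <- matrix(stats::rnorm(500 * 35), ncol = 35,
              dimnames = list(NULL, paste0("f", 1:35)))
  y <- factor(sample(rep(c("np", "pd"), each = 250)))
  m <- fit_clip_classifier(x, y, k = 30, seed = 3)
  # 99% binomial band around 0.5 at the validation size
  half <- 2.58 * sqrt(0.25 / m$n_valid)
  expect_gt(m$metrics[["accuracy"]], 0.5 - half - 0.05)
  expect_lt(m$metrics[["accuracy"]], 0.5 + half + 0.05)
})

test_that("a separable signal is learnt, reproducibly under one seed", {
  tf <- toy_features()
  m1 <- fit_clip_classifier(tf$x, tf$labels, k = 5, seed = 9)
  m2 <- fit_clip_classifier(tf$x, tf$labels, k = 5, seed = 9)
  expect_gte(m1$metrics[["accuracy"]], 0.95)
  expect_identical(m1$metrics, m2$metrics)
  expect_true(all(m1$metrics[c("accuracy", "precision", "recall", "f1")] >= 0 &
                    m1$metrics[c("accuracy", "precision", "recall", "f1")] <= 1))
  expect_true(all(abs(m1$metrics[c("kappa", "mcc")]) <= 1))
})

test_that("APS is the PD-clip percentage with half-open status bins", {
  tf <- toy_features(n_per = 150, shift = 6)
  m <- fit_clip_classifier(tf$x, tf$labels, k = 5, seed = 5)
  mk <- function(vals) {
    cbind(signal = vals,
          matrix(0, length(vals), 20,
                 dimnames = list(NULL, paste0("noise", 1:20))))
  }
  # predictions pd, np, pd, pd -> APS 75, severe (75 falls in the top bin)
  r <- score_aps(m, mk(c(6, 0, 6, 6)))
  expect_equal(r$aps, 75)
  expect_equal(r$status, "severe")
  r0 <- score_aps(m, mk(rep(0, 4)))
  expect_equal(r0$aps, 0); expect_equal(r0$status, "NP")
  rm_ <- score_aps(m, mk(c(6, 0, 0, 0)))
  expect_equal(rm_$aps, 25); expect_equal(rm_$status, "mild")
  # flipping one np clip to pd strictly increases APS
  expect_gt(score_aps(m, mk(c(6, 6, 0, 0)))$aps, rm_$aps)
  # permutation invariance
  expect_equal(score_aps(m, mk(c(0, 6, 6, 6)))$aps, r$aps)
})

test_that("additive attributions reproduce the model margin exactly", {
  tf <- toy_features()
  m <- fit_clip_classifier(tf$x, tf$labels, k = 5, seed = 6)
  at <- attribute(m, tf$x[1:50, ])
  # the ensemble evaluates in single precision, so the additivity residual
  # is assessed relative to the margin scale
  resid <- (at$base + rowSums(at$contrib) - at$margin) / (1 + abs(at$margin))
  expect_lt(max(abs(resid)), 1e-6)
  # the planted feature dominates the global ranking
  expect_equal(names(at$ranking)[1], "signal")
  # ranking is stable across reruns
  at2 <- attribute(m, tf$x[1:50, ])
  expect_identical(at$ranking, at2$ranking)
  expect_error(attribute(list(), tf$x), "tree-ensemble")
})

test_that("the gait classifier scores steps as a bounded percentage", {
  set.seed(30)
  n <- 180
  x <- cbind(matrix(stats::rnorm(2 * n * 5), ncol = 5,
                    dimnames = list(NULL, paste0("g", 1:5))),
             drag = c(stats::rnorm(n, 0), stats::rnorm(n, 3)),
             matrix(stats::rnorm(2 * n * 20), ncol = 20,
                    dimnames = list(NULL, paste0("h", 1:20))))
  y <- factor(rep(c("np", "pd"), each = n))
  g <- fit_gait_classifier(x, y, k = 20, seed = 8)
  expect_equal(g$task, "gait"); expect_equal(g$engine, "ranger")
  expect_length(g$features, 20)
  expect_gte(g$metrics[["accuracy"]], 0.8)
  sc_np <- score_gait(g, x[1:20, , drop = FALSE])
  sc_pd <- score_gait(g, x[(2 * n - 19):(2 * n), , drop = FALSE])
  expect_gte(sc_np, 0); expect_lte(sc_np, 100)
  expect_gt(sc_pd, sc_np)
  # all-np steps score 0
  far_np <- x[1:20, , drop = FALSE]; far_np[, "drag"] <- -2
  expect_equal(score_gait(g, far_np), 0)
})
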