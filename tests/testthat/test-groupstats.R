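test_that("the KDE approximates known densities on its own grid", {
  set.seed(14)
  x <- stats::rnorm(10000)
  d <- kde(x)
  at0 <- stats::approx(d$x, d$y, xout = 0)$y
  expect_lt(abs(at0 - 1 / sqrt(2 * pi)) / (1 / sqrt(2 * pi)), 0.1)
  expect_true(all(d$y >= 0))
  # change of variables: doubling the values halves the peak density
  d2 <- kde(2 * x)
  at0b <- stats::approx(d2$x, d2$y, xout = 0)$y
  expect_lt(abs(at0b - 0.5 / sqrt(2 * pi)) / (0.5 / sqrt(2 * pi)), 0.1)
  expect_error(kde(1:3), "at least 5")
  expect_warning(kde(rep(1, 10)), "zero-variance")
})

test_that("KL divergence is zero on identity, nonnegative, and near closed form", {
  set.seed(15)
  x <- stats::rnorm(5000)
  p <- kde(x)
  expect_lt(abs(kl_divergence(p, p)), 1e-6)
  # nonnegativity on random pairs (numerical floor -1e-9)
  for (i in 1:40) {
    a <- stats::rnorm(300, 0, stats::runif(1, 0.5, 2))
    b <- stats::rnorm(300, stats::runif(1, -1, 1), stats::runif(1, 0.5, 2))
    v <- kl_divergence(kde(a), kde(b))
    expect_gte(v, -1e-9)
  }
  # N(0,1) vs N(1,1): analytic KL 0.5
  a <- stats::rnorm(20000); b <- stats::rnorm(20000, 1)
  v <- kl_divergence(kde(a), kde(b, grid = kde(a)$x))
  expect_lt(abs(v - 0.5) / 0.5, 0.15)
  # disjoint supports are flagged undefined
  expect_warning(out <- kl_divergence(kde(stats::rnorm(100)),
                                      kde(stats::rnorm(100, 1000))))
  expect_true(is.na(out))
})

test_that("longitudinal divergence is near zero when stationary, six values per week", {
  set.seed(16)
  vals <- lapply(seq(0, 10, 2), function(w) stats::rnorm(1000))
  names(vals) <- seq(0, 10, 2)
  tr <- longitudinal_divergence(vals, seed = 3)
  expect_equal(as.integer(table(tr$week)), rep(6L, 6))
  expect_lt(mean(tr$kl[tr$week > 0]), 0.05)
  expect_error(longitudinal_divergence(list("2" = 1:200)), "baseline")
})

test_that("min-max normalisation matches the printed formulas", {
  expect_equal(normalise(c(2, 4, 6)), c(0, 0.5, 1))
  set.seed(17)
  v <- stats::rnorm(50)
  out <- normalise(v)
  expect_true(all(out >= 0 & out <= 1))
  lg <- normalise(c(1e-6, 1, 1e6), log = TRUE)
  expect_true(all(diff(lg) > 0))
  expect_warning(out0 <- normalise(rep(3, 4)), "constant")
  expect_equal(out0, rep(0, 4))
})

test_that("group differences propagate SEMs in quadrature", {
  expect_equal(unname(group_difference(1.2, 0.3, 1.0, 0.4)),
               c(0.2, 0.5), tolerance = 1e-12)
  expect_equal(group_difference(1, 0.1, 1, 0.2)[["mean_difference"]], 0)
  a <- group_difference(2, 0.3, 1, 0.4)
  b <- group_difference(1, 0.4, 2, 0.3)
  expect_equal(a[["mean_difference"]], -b[["mean_difference"]])
  expect_equal(a[["sem_difference"]], b[["sem_difference"]])
})

test_that("task scores use the two best trials with the 600% exclusion", {
  # baseline best-two mean 10 s, test 25 s
  r <- score_task(baseline = c(10, 10, 30), test = c(20, 30, 40), mode = "BWT")
  expect_equal(r$value, 250)
  expect_false(r$excluded)
  same <- score_task(c(8, 12), c(8, 12), mode = "BWT")
  expect_equal(same$value, 100)
  over <- score_task(c(10, 10), c(70, 70), mode = "BWT")
  expect_equal(over$value, 700)
  expect_true(over$excluded)
  # rotarod takes the longest latencies and is never excluded by the rule
  rr <- score_task(c(100, 50, 20), c(50, 25, 10), mode = "RRT")
  expect_equal(rr$value, 100 * 37.5 / 75)
  expect_false(rr$excluded)
})

test_that("tail suspension scoring weights qualifying classes", {
  rec <- data.frame(class = c(2, 2, 3, 3, 1), duration = c(3, 4, 5, 3, 6))
  expect_equal(score_tss(rec), 5)     # c1 = 0 (one incidence), c2 = c3 = 1
  one <- data.frame(class = 2, duration = 10)
  expect_equal(score_tss(one), 0)
  all3 <- data.frame(class = rep(1:3, each = 2), duration = rep(3, 6))
  expect_equal(score_tss(all3), 6)
  short <- data.frame(class = rep(1, 5), duration = rep(1.5, 5))
  expect_equal(score_tss(short), 0)   # incidences must each exceed 2 s
})

test_that("affected-feature calls control the family-wise error", {
  set.seed(18)
  # identical samples: never affected
  x <- matrix(stats::rnorm(20 * 5), 20, dimnames = list(NULL, paste0("f", 1:5)))
  out <- classify_affected(x, x)
  expect_true(all(!out$affected))
  # planted 3-sd shift is detected almost always
  hits <- 0L
  for (i in 1:100) {
    ct <- matrix(stats::rnorm(20 * 5), 20,
                 dimnames = list(NULL, paste0("f", 1:5)))
    pd <- ct + matrix(rep(c(3, 0, 0, 0, 0), each = 20), 20)
    pd[, 2:5] <- matrix(stats::rnorm(20 * 4), 20)
    hits <- hits + classify_affected(ct, pd)$affected[1]
  }
  expect_gte(hits, 99L)
  # global null: family-wise error at most alpha (with binomial slack)
  fp <- 0L
  for (i in 1:200) {
    ct <- matrix(stats::rnorm(15 * 20), 15,
                 dimnames = list(NULL, paste0("f", 1:20)))
    pd <- matrix(stats::rnorm(15 * 20), 15,
                 dimnames = list(NULL, paste0("f", 1:20)))
    fp <- fp + any(classify_affected(ct, pd)$affected)
  }
  expect_lte(fp / 200, 0.05 + 2.58 * sqrt(0.05 * 0.95 / 200))
})

test_that("TRE categories follow the three-comparison decision rules", {
  set.seed(19)
  n <- 50
  mk <- function(mu) matrix(stats::rnorm(n * 3, rep(mu, each = n), 0.5), n,
                            dimnames = list(NULL, c("f1", "f2", "f3")))
  # constructed midpoint case: all three shifts significant, treated between
  ct <- mk(c(0, 0, 0)); a1 <- mk(c(4, 4, 0)); tr <- mk(c(2, 4, 0))
  led <- classify_tre(ct, a1, tr)
  expect_equal(led$category[1:2], c("partially_treated", "untreated"))
  # exactly identical samples are unaffected (p = 1 throughout)
  same <- mk(c(0, 0, 0))
  expect_true(all(classify_tre(same, same, same)$category == "unaffected"))
  # treated back at control: completely treated
  led2 <- classify_tre(mk(c(0, 0, 0)), mk(c(4, 4, 4)), mk(c(0, 0, 0)))
  expect_true(all(led2$category == "completely_treated"))
  # treated overshoots beyond control: treat associated
  led3 <- classify_tre(mk(0), mk(4), mk(-4))
  expect_true(all(led3$category == "treat_associated"))
  # exhaustive and exclusive on random inputs
  for (i in 1:20) {
    led4 <- classify_tre(mk(stats::rnorm(3, 0, 2)), mk(stats::rnorm(3, 0, 2)),
                         mk(stats::rnorm(3, 0, 2)))
    expect_true(all(led4$category %in%
                      c("unaffected", "completely_treated",
                        "partially_treated", "untreated",
                        "treat_associated")))
  }
})

test_that("Holm-Sidak adjustment is monotone and bounded", {
  p <- c(0.001, 0.04, 0.2, 0.8)
  adj <- holm_sidak(p)
  expect_true(all(adj >= p))
  expect_true(all(adj <= 1))
  expect_equal(adj[1], 1 - (1 - 0.001)^4, tolerance = 1e-12)
  # step-down adjustment is nondecreasing over the sorted p-values
  p2 <- c(0.5, 0.01, 0.3)
  expect_true(all(diff(holm_sidak(sort(p2))) >= 0))
})
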