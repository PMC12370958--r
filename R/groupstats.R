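#' Gaussian kernel density estimate
#'
#' Gaussian kernel with Scott bandwidth (`sd(x) * n^(-1/5)`), evaluated on a
#' 200-point grid over the data range extended by 3 bandwidths (or on a
#' supplied grid).
#'
#' @param values numeric sample, n >= 5.
#' @param grid optional evaluation grid.
#' @param n_grid grid size when `grid` is `NULL` (default 200).
#' @return object of class `density_estimate`: list with `x`, `y`, `bw`, `n`.
#' @export
kde <- function(values, grid = NULL, n_grid = 200L) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 5L) stop("at least 5 values are required")
  s <- stats::sd(values)
  if (s == 0) {
    warning("zero-variance sample; density estimate is degenerate")
    s <- 1e-9
  }
  bw <- s * n^(-1 / 5)
  if (is.null(grid)) {
    grid <- seq(min(values) - 3 * bw, max(values) + 3 * bw,
                length.out = n_grid)
  }
  y <- vapply(grid, function(g) mean(stats::dnorm(g, values, bw)), numeric(1))
  structure(list(x = grid, y = y, bw = bw, n = n),
            class = "density_estimate")
}

#' Kullback-Leibler divergence between two density estimates
#'
#' The second density is interpolated onto the first density's grid; the
#' integrand `p * ln(p / q)` is integrated trapezoidally over the grid
#' points where both densities exceed a 1e-12 floor.
#'
#' @param p,q `density_estimate` objects (see [kde()]).
#' @param floor density floor below which points are excluded.
#' @return scalar divergence (>= 0 up to numerical error), or `NA` with a
#'   warning when the supports do not overlap.
#' @export
kl_divergence <- function(p, q, floor = 1e-12) {
  qy <- stats::approx(q$x, q$y, xout = p$x, yleft = 0, yright = 0)$y
  ok <- p$y > floor & qy > floor
  if (sum(ok) < 2L) {
    warning("densities do not overlap; divergence undefined")
    return(NA_real_)
  }
  x <- p$x[ok]
  f <- p$y[ok] * log(p$y[ok] / qy[ok])
  sum(diff(x) * (f[-1] + f[-length(f)]) / 2)
}

#' Longitudinal distribution divergence from baseline
#'
#' For each of `n_sets` seeded sampling sets, `set_size` clip values are
#' drawn per week (without replacement; with replacement when fewer values
#' are available) and the KL divergence from the baseline (week 0) KDE to
#' each later week's KDE is computed on the baseline grid.
#'
#' @param values_by_week named list of numeric vectors; names are week
#'   indices and must include `"0"`.
#' @param n_sets number of sampling sets (default 6).
#' @param set_size clips per set (default 150).
#' @param seed integer seed.
#' @return data frame with columns `week`, `set`, `kl`.
#' @export
longitudinal_divergence <- function(values_by_week, n_sets = 6L,
                                    set_size = 150L, seed = 1L) {
  weeks <- names(values_by_week)
  if (!"0" %in% weeks) stop("baseline week 0 is missing")
  set.seed(as.integer(seed))
  draw <- function(v) {
    v <- v[!is.na(v)]
    if (length(v) < set_size) {
      message("fewer than ", set_size, " values; sampling with replacement")
      sample(v, set_size, replace = TRUE)
    } else sample(v, set_size)
  }
  out <- NULL
  for (s in seq_len(n_sets)) {
    base <- draw(values_by_week[["0"]])
    p <- kde(base)
    for (w in weeks) {
      q <- kde(draw(values_by_week[[w]]), grid = p$x)
      out <- rbind(out, data.frame(week = as.numeric(w), set = s,
                                   kl = kl_divergence(p, q)))
    }
  }
  out
}

#' Min-max normalisation of raw group means
#'
#' Scales values to the unit interval; with `log = TRUE` a natural log transform
#' `ln(x + 1e-6)` is applied first (for wide-range features such as motion
#' interval and duration).
#'
#' @param x numeric values (typically per-group raw means of one feature).
#' @param log apply the log transform first.
#' @return normalised values in the unit interval; all 0 (with a warning) when the
#'   values are constant.
#' @export
normalise <- function(x, log = FALSE) {
  if (log) x <- base::log(x + 1e-6)
  rng <- range(x, na.rm = TRUE)
  if (rng[2] == rng[1]) {
    warning("constant values; normalisation degenerate, mapped to 0")
    return(rep(0, length(x)))
  }
  (x - rng[1]) / (rng[2] - rng[1])
}

#' Group mean difference with error propagation
#'
#' Difference of experimental and non-disease-control normalised means,
#' with the SEM of the difference propagated as the root sum of squares.
#'
#' @param mean_exp,sem_exp experimental group mean and SEM.
#' @param mean_ndc,sem_ndc control group mean and SEM.
#' @return named vector `c(mean_difference, sem_difference)`.
#' @export
group_difference <- function(mean_exp, sem_exp, mean_ndc, sem_ndc) {
  stopifnot(sem_exp >= 0, sem_ndc >= 0)
  c(mean_difference = mean_exp - mean_ndc,
    sem_difference = sqrt(sem_exp^2 + sem_ndc^2))
}

#' Behavioural task scores (beam walking / rotarod)
#'
#' Score = 100 x mean of the two best test trials over the mean of the two
#' best baseline trials. "Best" is shortest latency for the beam walking
#' test (BWT) and longest latency for the rotarod test (RRT). A BWT score
#' above 600% is excluded (failure type II).
#'
#' @param baseline,test per-trial latencies (s), at least 2 each.
#' @param mode `"BWT"` or `"RRT"`.
#' @return list with `value` (percent), `kind` (`"BWS"`/`"RRS"`),
#'   `excluded`, `reason`.
#' @export
score_task <- function(baseline, test, mode = c("BWT", "RRT")) {
  mode <- match.arg(mode)
  if (length(baseline) < 2L || length(test) < 2L) {
    stop("at least 2 trials per session are required")
  }
  best2 <- function(v) {
    v <- sort(v, decreasing = (mode == "RRT"))
    mean(v[1:2])
  }
  value <- 100 * best2(test) / best2(baseline)
  excluded <- mode == "BWT" && value > 600
  list(value = value, kind = if (mode == "BWT") "BWS" else "RRS",
       excluded = excluded,
       reason = if (excluded) "BWS above 600% (failure type II)" else NA)
}

#' Tail suspension test score
#'
#' Each abnormality class k in 1..3 scores 1 when at least 2 incidences,
#' each lasting over 2 s, were observed; the score is the class-weighted sum
#' `c1 + 2*c2 + 3*c3`, in 0..6.
#'
#' @param records data frame with columns `class` (1, 2 or 3) and
#'   `duration` (s), one row per incidence.
#' @return integer score in 0..6.
#' @export
score_tss <- function(records) {
  ck <- vapply(1:3, function(k) {
    sum(records$class == k & records$duration > 2) >= 2
  }, logical(1))
  sum(ck * 1:3)
}

#' Holm-Sidak correction
#'
#' Step-down Sidak-adjusted p-values across one family of comparisons.
#'
#' @param p raw p-values.
#' @return adjusted p-values, same order.
#' @export
holm_sidak <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- 1 - (1 - p[o])^(m - seq_len(m) + 1)
  adj <- pmin(cummax(adj), 1)
  adj[order(o)]
}

welch_p <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 3L || length(b) < 3L) stop("at least 3 values per group")
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    return(if (mean(a) == mean(b)) 1 else 0)
  }
  stats::t.test(a, b, var.equal = FALSE)$p.value
}

#' Classify PD-affected features
#'
#' Per feature, a two-sided Welch t-test between control and PD values with
#' Holm-Sidak correction across the feature family; features whose
#' corrected p-value falls below `alpha` are affected.
#'
#' @param ct,pd matrices or data frames (rows = mice or clips, columns =
#'   features) with matching columns.
#' @param alpha significance level (default 0.05).
#' @return data frame: `feature`, `p`, `p_adj`, `affected`.
#' @export
classify_affected <- function(ct, pd, alpha = 0.05) {
  ct <- as.matrix(ct); pd <- as.matrix(pd)
  stopifnot(identical(colnames(ct), colnames(pd)))
  p <- vapply(seq_len(ncol(ct)), function(j) welch_p(ct[, j], pd[, j]),
              numeric(1))
  p_adj <- holm_sidak(p)
  data.frame(feature = colnames(ct), p = p, p_adj = p_adj,
             affected = p_adj < alpha, row.names = NULL)
}

#' Treatment-response evaluation (TRE)
#'
#' Per-feature categorisation from three Welch comparisons (each Holm-Sidak
#' corrected across the feature family): untreated PD vs control (A1 vs CT),
#' treated vs control, and treated vs untreated PD. Categories:
#' \describe{
#'   \item{unaffected}{feature not altered by PD and not by treatment.}
#'   \item{completely_treated}{altered in PD but indistinguishable from
#'     control after treatment.}
#'   \item{partially_treated}{still different from control, significantly
#'     shifted from the PD state, and lying between the PD and control
#'     means.}
#'   \item{untreated}{still different from control and indistinguishable
#'     from the PD state.}
#'   \item{treat_associated}{significantly changed by treatment without
#'     aligning toward control.}
#' }
#'
#' @param ct,a1,treated matrices/data frames with matching feature columns:
#'   control, untreated PD, and treated group values.
#' @param alpha significance level (default 0.05).
#' @return object of class `treatment_ledger`: data frame with the three
#'   raw and corrected p-values, group means, and `category`.
#' @export
classify_tre <- function(ct, a1, treated, alpha = 0.05) {
  ct <- as.matrix(ct); a1 <- as.matrix(a1); treated <- as.matrix(treated)
  stopifnot(identical(colnames(ct), colnames(a1)),
            identical(colnames(ct), colnames(treated)))
  nf <- ncol(ct)
  p_a1_ct <- vapply(seq_len(nf), function(j) welch_p(a1[, j], ct[, j]),
                    numeric(1))
  p_tr_ct <- vapply(seq_len(nf), function(j) welch_p(treated[, j], ct[, j]),
                    numeric(1))
  p_tr_a1 <- vapply(seq_len(nf), function(j) welch_p(treated[, j], a1[, j]),
                    numeric(1))
  s_a1_ct <- holm_sidak(p_a1_ct) < alpha
  s_tr_ct <- holm_sidak(p_tr_ct) < alpha
  s_tr_a1 <- holm_sidak(p_tr_a1) < alpha
  m_ct <- colMeans(ct, na.rm = TRUE)
  m_a1 <- colMeans(a1, na.rm = TRUE)
  m_tr <- colMeans(treated, na.rm = TRUE)
  between <- (m_tr > pmin(m_a1, m_ct)) & (m_tr < pmax(m_a1, m_ct))
  category <- character(nf)
  for (j in seq_len(nf)) {
    category[j] <- if (!s_a1_ct[j]) {
      if (!s_tr_ct[j]) "unaffected" else "treat_associated"
    } else if (!s_tr_ct[j]) {
      "completely_treated"
    } else if (!s_tr_a1[j]) {
      "untreated"
    } else if (between[j]) {
      "partially_treated"
    } else {
      "treat_associated"
    }
  }
  out <- data.frame(
    feature = colnames(ct),
    p_a1_ct = p_a1_ct, p_adj_a1_ct = holm_sidak(p_a1_ct),
    p_tr_ct = p_tr_ct, p_adj_tr_ct = holm_sidak(p_tr_ct),
    p_tr_a1 = p_tr_a1, p_adj_tr_a1 = holm_sidak(p_tr_a1),
    mean_ct = m_ct, mean_a1 = m_a1, mean_treated = m_tr,
    category = category, row.names = NULL)
  class(out) <- c("treatment_ledger", "data.frame")
  out
}

#' @export
print.treatment_ledger <- function(x, ...) {
  cat("<treatment_ledger>", nrow(x), "features\n")
  print(table(x$category))
  invisible(x)
}
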