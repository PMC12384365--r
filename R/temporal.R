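# Temporal structure of hypnograms: indicator autocovariance, the
# autocorrelation time of each stage, and the first-order Markov
# transition matrix / transition-vector memory feature.

#' Stage indicator series
#'
#' Binary series I_t = 1 where the hypnogram carries the given stage.
#'
#' @param labels Stage label sequence (one subject's hypnogram).
#' @param stage Stage whose persistence is analyzed.
#' @param delta_t Seconds per epoch (20 or 30 under the usual scoring
#'   conventions).
#' @return Object of class `"stage_indicator"`: list with `values`, `mean`,
#'   `delta_t`, `stage`.
#' @export
indicator_series <- function(labels, stage, delta_t = 30) {
  stopifnot(length(labels) >= 1L, delta_t > 0)
  values <- as.integer(labels == stage)
  structure(list(values = values, mean = mean(values), delta_t = delta_t,
                 stage = stage),
            class = "stage_indicator")
}

#' Biased autocovariance of an indicator series
#'
#' \deqn{\gamma(\tau) = \frac{1}{n} \sum_{t=1}^{n-|\tau|}
#'       (I_{t+|\tau|} - \bar I)(I_t - \bar I)}
#' using the 1/n (biased) normalization at every lag, so \eqn{\gamma(0)}
#' is the population variance of the series.
#'
#' @param series A [indicator_series()] or plain numeric vector.
#' @param max_lag Largest lag (must be `< n`).
#' @return Numeric vector `gamma[tau]` for `tau = 0..max_lag` (R index
#'   `tau + 1`).
#' @export
autocovariance <- function(series, max_lag = 120L) {
  v <- if (inherits(series, "stage_indicator")) series$values else series
  n <- length(v)
  if (n <= 1L) stop("insufficient data: need n > 1")
  if (max_lag >= n) stop("max_lag must be < series length")
  d <- v - mean(v)
  vapply(0:max_lag, function(tau) {
    sum(d[(1L + tau):n] * d[1L:(n - tau)]) / n
  }, numeric(1))
}

#' Normalize an autocovariance to an autocorrelation
#'
#' @param gamma Autocovariance sequence with `gamma[1]` the zero-lag value.
#' @return `rho = gamma / gamma[1]`; errors when the variance is zero.
#' @export
normalize_autocov <- function(gamma) {
  if (gamma[1L] <= 0) stop("degenerate series: gamma(0) must be > 0")
  gamma / gamma[1L]
}

#' Autocorrelation time of a stage
#'
#' \deqn{t_c = \Delta t \sum_{\tau=0}^{\tau_{max}} \rho(\tau)} where
#' `tau_max` is the largest lag before the first non-positive value of
#' `rho` — only positive autocorrelations contribute to the persistence
#' estimate.
#'
#' @param rho Normalized autocovariance, `rho[1] == 1`.
#' @param delta_t Seconds per epoch.
#' @return List with `t_c` (seconds) and `tau_max` (integer lag).
#' @export
autocorrelation_time <- function(rho, delta_t = 30) {
  stopifnot(abs(rho[1L] - 1) < 1e-9)
  nonpos <- which(rho <= 0)
  tau_max <- if (length(nonpos) == 0L) length(rho) - 1L else nonpos[1L] - 2L
  t_c <- delta_t * sum(rho[1:(tau_max + 1L)])
  list(t_c = t_c, tau_max = tau_max)
}

#' Full autocovariance profile of one stage
#'
#' Convenience wrapper: indicator series, biased autocovariance,
#' normalization and autocorrelation time in one call.
#'
#' @inheritParams indicator_series
#' @param max_lag Largest lag analyzed (default 120 epochs).
#' @return Object of class `"autocov_profile"`: `gamma`, `rho`, `tau_max`,
#'   `t_c` (seconds), `delta_t`, `stage`.
#' @export
stage_autocov_profile <- function(labels, stage, delta_t = 30,
                                  max_lag = 120L) {
  ind <- indicator_series(labels, stage, delta_t)
  gamma <- autocovariance(ind, max_lag = min(max_lag, length(labels) - 1L))
  rho <- normalize_autocov(gamma)
  ac <- autocorrelation_time(rho, delta_t)
  structure(
    list(gamma = gamma, rho = rho, tau_max = ac$tau_max, t_c = ac$t_c,
         delta_t = delta_t, stage = stage),
    class = "autocov_profile"
  )
}

#' Group-averaged normalized autocovariance
#'
#' Averages the subjects' autocovariance functions lag by lag, then
#' normalizes the group mean by its own zero-lag value. Subjects with zero
#' variance are skipped with a warning. The per-lag standard error of the
#' mean is reported on the same normalized scale.
#'
#' @param gammas List of per-subject autocovariance vectors (equal length).
#' @return List with `rho` (normalized group mean), `se` (per-lag standard
#'   error of the mean, normalized by the same zero-lag value), and `n`
#'   (number of subjects used).
#' @export
group_average_autocov <- function(gammas) {
  stopifnot(length(gammas) >= 2L)
  keep <- vapply(gammas, function(g) g[1L] > 0, logical(1))
  if (any(!keep)) {
    warning(sum(!keep), " subject(s) with zero variance skipped")
  }
  gammas <- gammas[keep]
  if (length(gammas) < 2L) stop("fewer than 2 usable subjects")
  G <- do.call(rbind, gammas)
  mg <- colMeans(G)
  se <- apply(G, 2L, stats::sd) / sqrt(nrow(G))
  list(rho = mg / mg[1L], se = se / mg[1L], n = nrow(G))
}

# ---- transition machinery --------------------------------------------------

#' Transition matrix constructor
#'
#' @param probs K x K numeric matrix, rows summing to 1.
#' @param stages Ordered stage labels (row/column names).
#' @return Matrix of class `"transition_matrix"` with stage dimnames.
#' @export
transition_matrix <- function(probs, stages = sleep_stages()) {
  probs <- as.matrix(probs)
  K <- length(stages)
  stopifnot(nrow(probs) == K, ncol(probs) == K)
  if (any(probs < 0) || any(probs > 1) ||
      any(abs(rowSums(probs) - 1) > 1e-9)) {
    stop("transition matrix rows must be probabilities summing to 1")
  }
  dimnames(probs) <- list(stages, stages)
  class(probs) <- c("transition_matrix", class(probs))
  probs
}

as_transition_matrix <- function(x) {
  if (inherits(x, "transition_matrix")) return(x)
  stages <- rownames(x)
  if (is.null(stages)) stages <- sleep_stages()
  transition_matrix(as.matrix(unclass(x)), stages)
}

#' @export
print.transition_matrix <- function(x, digits = 3, ...) {
  cat("<transition_matrix> rows = previous stage, cols = next stage\n")
  print(round(unclass(x), digits))
  invisible(x)
}

#' Estimate a first-order transition matrix from hypnograms
#'
#' Counts stage-to-stage transitions within each hypnogram (never across
#' subject boundaries) and row-normalizes:
#' \deqn{T_{ij} = \frac{Count(S_{t-1}=c_i, S_t=c_j) + s}
#'       {\sum_j (Count(S_{t-1}=c_i, S_t=c_j) + s)}}
#' with optional additive smoothing `s`. A stage never observed as a
#' predecessor receives a uniform row so the matrix stays stochastic.
#'
#' @param hypnograms A list of stage-label sequences (or a single
#'   character vector, treated as one hypnogram).
#' @param stages Ordered stage set.
#' @param smoothing Additive smoothing constant (default 0).
#' @return A [transition_matrix()].
#' @export
estimate_transition_matrix <- function(hypnograms, stages = sleep_stages(),
                                       smoothing = 0) {
  if (is.character(hypnograms)) hypnograms <- list(hypnograms)
  K <- length(stages)
  counts <- matrix(0, K, K, dimnames = list(stages, stages))
  total <- 0L
  for (h in hypnograms) {
    h <- check_stage_labels(h, stages)
    n <- length(h)
    if (n < 2L) next
    from <- factor(h[-n], levels = stages)
    to <- factor(h[-1L], levels = stages)
    counts <- counts + table(from, to)
    total <- total + (n - 1L)
  }
  if (total == 0L) stop("need at least one transition")
  counts <- counts + smoothing
  rs <- rowSums(counts)
  probs <- matrix(1 / K, K, K)
  nonzero <- rs > 0
  probs[nonzero, ] <- counts[nonzero, , drop = FALSE] / rs[nonzero]
  transition_matrix(probs, stages)
}

#' Transition vector: memory feature for the next epoch
#'
#' \deqn{v_t = p_{t-1} \cdot T}: the previous epoch's stage probability
#' distribution propagated one step through the transition matrix. A
#' one-hot `p_prev` extracts the corresponding row of `T`.
#'
#' @param p_prev Probability vector over the stages (previous epoch's
#'   softmax output or one-hot label).
#' @param T A [transition_matrix()].
#' @return Numeric probability vector of length K.
#' @export
transition_vector <- function(p_prev, T) {
  T <- as_transition_matrix(T)
  if (length(p_prev) != nrow(T)) stop("dimension mismatch: p_prev vs T")
  check_simplex(p_prev, what = "p_prev")
  as.numeric(p_prev %*% unclass(T))
}

#' Initial stage distribution (wake prior)
#'
#' Recordings are assumed to begin in wakefulness: the initial distribution
#' p0 is one-hot at stage W.
#'
#' @param stages Ordered stage set; must contain `"W"`.
#' @return Numeric one-hot vector over `stages`.
#' @export
initial_distribution <- function(stages = sleep_stages()) {
  i <- match("W", stages)
  if (is.na(i)) stop("stage set must contain W")
  p <- numeric(length(stages))
  p[i] <- 1
  names(p) <- stages
  p
}
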