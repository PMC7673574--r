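#' @include core_io.R
NULL

#' Incidence frequency counts
#'
#' Tallies, from a taxon-by-unit incidence matrix, the number of species
#' `Q_k` detected in exactly `k` sampling units.
#'
#' @param inc An [incidence_matrix()].
#' @return A list with `T` (number of sampling units), `S_obs` (observed
#'   richness) and `Q` (named integer vector over `k = 1..T`; zero entries
#'   included so `Q["1"]`, `Q["2"]` are always present).
#' @export
incidence_frequencies <- function(inc) {
  stopifnot(inherits(inc, "incidence_matrix"))
  tt <- ncol(inc)
  y <- rowSums(inc)
  q <- tabulate(y, nbins = tt)
  names(q) <- as.character(seq_len(tt))
  list(T = tt, S_obs = nrow(inc), Q = q)
}

#' Chao2 asymptotic species richness
#'
#' Bias-corrected incidence-based Chao2 estimator:
#' \deqn{\hat S = S_{obs} + \frac{T-1}{T}\,\frac{Q_1^2}{2 Q_2}} when
#' \eqn{Q_2 > 0}, and \eqn{S_{obs} + \frac{T-1}{T}\, Q_1 (Q_1 - 1)/2} when
#' \eqn{Q_2 = 0}. The estimate is a lower bound on true richness; when there
#' are no uniques (\eqn{Q_1 = 0}) it equals the observed richness.
#'
#' @param T Number of sampling units (at least 2).
#' @param S_obs Observed species richness.
#' @param Q1 Number of species seen in exactly one unit (uniques).
#' @param Q2 Number of species seen in exactly two units (duplicates).
#' @return The asymptotic richness estimate (species), a single number.
#' @export
#' @examples
#' chao2(T = 10, S_obs = 50, Q1 = 10, Q2 = 5) # 59
chao2 <- function(T, S_obs, Q1, Q2) {
  if (T < 2) abort("Chao2 is undefined for fewer than two sampling units.")
  stopifnot(S_obs >= 0, Q1 >= 0, Q2 >= 0)
  k <- (T - 1) / T
  if (Q2 > 0) {
    S_obs + k * Q1^2 / (2 * Q2)
  } else {
    S_obs + k * Q1 * (Q1 - 1) / 2
  }
}

# Chao2 with its undetected-species count, straight from a matrix.
chao2_from_incidence <- function(inc) {
  f <- incidence_frequencies(inc)
  s_hat <- chao2(f$T, f$S_obs, f$Q[["1"]], f$Q[["2"]])
  list(
    T = f$T, S_obs = f$S_obs, Q1 = f$Q[["1"]], Q2 = f$Q[["2"]],
    S_hat = s_hat, Q0_hat = s_hat - f$S_obs
  )
}

#' Interpolated (rarefied) species richness
#'
#' Expected number of species detected in `t` of the `T` sampling units,
#' averaged over all \eqn{\binom{T}{t}} subsets:
#' \deqn{\hat S(t) = S_{obs} - \sum_i \binom{T - Y_i}{t} / \binom{T}{t}}
#' where \eqn{Y_i} is species *i*'s incidence count and binomial coefficients
#' with \eqn{a < b} are zero.
#'
#' @param inc An [incidence_matrix()].
#' @param t Integer vector of unit counts in `[0, T]`.
#' @return Numeric vector of expected richness values, one per `t`.
#' @export
rarefy_incidence <- function(inc, t) {
  stopifnot(inherits(inc, "incidence_matrix"))
  tt <- ncol(inc)
  if (any(t < 0 | t > tt)) {
    abort(paste0("t must lie in [0, ", tt, "]."))
  }
  y <- rowSums(inc)
  s_obs <- nrow(inc)
  vapply(t, function(ti) {
    absent <- exp(lchoose(tt - y, ti) - lchoose(tt, ti))
    absent[tt - y < ti] <- 0
    s_obs - sum(absent)
  }, numeric(1))
}

#' Extrapolated species richness beyond the sample
#'
#' Chao2-based extrapolation to `T + t_star` sampling units:
#' \deqn{\hat S(T + t^*) = S_{obs} + \hat Q_0 \left[1 - \left(1 -
#'   \frac{Q_1}{Q_1 + T \hat Q_0}\right)^{t^*}\right]}
#' with \eqn{\hat Q_0} the Chao2 estimate of undetected species. When there
#' are no uniques the curve is flat at the observed richness.
#'
#' @param inc An [incidence_matrix()].
#' @param t_star Non-negative integer vector of additional units beyond `T`.
#' @return Numeric vector of expected richness at `T + t_star`.
#' @export
extrapolate_incidence <- function(inc, t_star) {
  stopifnot(inherits(inc, "incidence_matrix"))
  if (any(t_star < 0)) abort("t_star must be non-negative.")
  est <- chao2_from_incidence(inc)
  if (est$Q1 == 0 || est$Q0_hat == 0) {
    return(rep(est$S_obs, length(t_star)))
  }
  est$S_obs + est$Q0_hat *
    (1 - (1 - est$Q1 / (est$Q1 + est$T * est$Q0_hat))^t_star)
}

# Point estimate of the full curve on an integer grid of unit counts;
# values at t <= T are interpolated, beyond T extrapolated.
curve_estimate <- function(inc, t_grid) {
  tt <- ncol(inc)
  below <- t_grid[t_grid <= tt]
  above <- t_grid[t_grid > tt]
  c(
    rarefy_incidence(inc, below),
    extrapolate_incidence(inc, above - tt)
  )
}

#' Bootstrap confidence intervals for the accumulation curve
#'
#' Percentile bootstrap obtained by resampling the `T` sampling units
#' (matrix columns) with replacement `B` times and recomputing the whole
#' interpolation/extrapolation curve (and the Chao2 asymptote) on each
#' replicate. Deterministic for a fixed `seed`.
#'
#' @param inc An [incidence_matrix()].
#' @param t_values Integer grid of unit counts (default `1:(2T)`).
#' @param B Number of bootstrap replicates (>= 1).
#' @param level Confidence level in (0, 1).
#' @param seed Optional integer seed; the global RNG state is restored
#'   afterwards.
#' @return Tibble with `t`, `ci_low`, `ci_high`; a final row with
#'   `t = Inf` carries the interval for the Chao2 asymptote.
#' @export
bootstrap_ci <- function(inc, t_values = NULL, B = 1000, level = 0.95,
                         seed = NULL) {
  stopifnot(inherits(inc, "incidence_matrix"), B >= 1, level > 0, level < 1)
  tt <- ncol(inc)
  if (is.null(t_values)) t_values <- seq_len(2 * tt)
  reps <- with_seed(seed, {
    vapply(seq_len(B), function(b) {
      cols <- sample.int(tt, tt, replace = TRUE)
      m <- unclass(inc)[, cols, drop = FALSE]
      m <- m[rowSums(m) > 0, , drop = FALSE]
      if (nrow(m) == 0) {
        # a replicate drawing only empty units detects nothing
        return(rep(0, length(t_values) + 1))
      }
      bm <- incidence_matrix(m)
      c(curve_estimate(bm, t_values), chao2_from_incidence(bm)$S_hat)
    }, numeric(length(t_values) + 1))
  })
  reps <- matrix(reps, nrow = length(t_values) + 1)
  alpha <- (1 - level) / 2
  lo <- apply(reps, 1, quantile, probs = alpha, names = FALSE)
  hi <- apply(reps, 1, quantile, probs = 1 - alpha, names = FALSE)
  tibble(t = c(t_values, Inf), ci_low = lo, ci_high = hi)
}

#' Incidence-based species accumulation curve
#'
#' Full rarefaction/extrapolation analysis of an incidence matrix: observed
#' richness, incidence frequencies, the interpolated and extrapolated curve
#' on an integer grid (default out to twice the observed number of units),
#' the Chao2 asymptote with its undetected-species count, and bootstrap
#' percentile confidence intervals.
#'
#' @param inc An [incidence_matrix()].
#' @param endpoint Last unit count of the curve (default `2 * T`).
#' @param B Bootstrap replicates for the confidence band (default 1000; set
#'   to 0 to skip the bootstrap).
#' @param level Confidence level (default 0.95).
#' @param seed Optional integer seed for the bootstrap.
#' @return A list of class `incidence_accumulation` with fields `T`, `S_obs`,
#'   `Q`, `S_hat`, `Q0_hat`, `curve` (tibble: `t`, `method` one of
#'   `"interpolated"/"observed"/"extrapolated"`, `estimate`, `ci_low`,
#'   `ci_high`) and `asymptote_ci`.
#' @export
accumulation_curve <- function(inc, endpoint = NULL, B = 1000, level = 0.95,
                               seed = NULL) {
  stopifnot(inherits(inc, "incidence_matrix"))
  f <- incidence_frequencies(inc)
  est <- chao2_from_incidence(inc)
  endpoint <- endpoint %||% (2L * f$T)
  if (endpoint < f$T) abort("endpoint must be at least T.")
  t_grid <- seq_len(endpoint)
  curve <- tibble(
    t = t_grid,
    method = dplyr::case_when(
      t_grid < f$T ~ "interpolated",
      t_grid == f$T ~ "observed",
      TRUE ~ "extrapolated"
    ),
    estimate = curve_estimate(inc, t_grid),
    ci_low = NA_real_,
    ci_high = NA_real_
  )
  asymptote_ci <- c(NA_real_, NA_real_)
  if (B >= 1) {
    ci <- bootstrap_ci(inc, t_values = t_grid, B = B, level = level,
      seed = seed)
    curve$ci_low <- ci$ci_low[seq_len(endpoint)]
    curve$ci_high <- ci$ci_high[seq_len(endpoint)]
    asymptote_ci <- c(ci$ci_low[endpoint + 1], ci$ci_high[endpoint + 1])
  }
  structure(
    list(
      T = f$T, S_obs = f$S_obs, Q = f$Q, S_hat = est$S_hat,
      Q0_hat = est$Q0_hat, curve = curve,
      asymptote_ci = setNames(asymptote_ci, c("ci_low", "ci_high")),
      B = B, level = level
    ),
    class = "incidence_accumulation"
  )
}

#' @export
print.incidence_accumulation <- function(x, ...) {
  cat(
    "<incidence_accumulation> T = ", x$T, ", S_obs = ", x$S_obs,
    ", Chao2 = ", round_half_up(x$S_hat, 1),
    if (!is.na(x$asymptote_ci[1])) {
      paste0(
        " (", 100 * x$level, "% CI ",
        round_half_up(x$asymptote_ci[1], 1), "-",
        round_half_up(x$asymptote_ci[2], 1), ")"
      )
    } else {
      ""
    }, "\n",
    sep = ""
  )
  invisible(x)
}

#' @export
tidy.incidence_accumulation <- function(x, ...) x$curve

#' @export
glance.incidence_accumulation <- function(x, ...) {
  tibble(
    T = x$T, S_obs = x$S_obs, Q1 = x$Q[["1"]], Q2 = x$Q[["2"]],
    S_hat = x$S_hat, Q0_hat = x$Q0_hat,
    ci_low = x$asymptote_ci[["ci_low"]],
    ci_high = x$asymptote_ci[["ci_high"]],
    B = x$B, level = x$level
  )
}

#' Write an accumulation curve to TSV and its summary to JSON
#'
#' @param x An `incidence_accumulation` object.
#' @param path Output TSV path for the curve.
#' @param summary_path Optional JSON path for the summary.
#' @return `path`, invisibly.
#' @export
write_accumulation <- function(x, path, summary_path = NULL) {
  stopifnot(inherits(x, "incidence_accumulation"))
  readr::write_tsv(x$curve, path)
  if (!is.null(summary_path)) {
    jsonlite::write_json(
      as.list(glance(x)), summary_path,
      auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
  }
  invisible(path)
}
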