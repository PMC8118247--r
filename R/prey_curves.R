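# Randomized cumulative prey curves and the endpoint-slope sufficiency test.
#
# The curve gives the expected number of distinct prey categories among the
# first k stomachs when stomach order is randomized. Sample size is judged
# sufficient when the OLS slope over the last five points of the mean curve
# is <= 0.05 prey categories per stomach (an asymptote, operationally).

#' Randomized cumulative prey curve
#'
#' For each sample size k = 1..n, the mean (and sd) over random stomach
#' orderings of the number of distinct prey categories observed in the
#' first k stomachs. The exact expectation has a hypergeometric closed form
#' — category i, present in n_i of n stomachs, is missing from a random
#' subset of size k with probability choose(n - n_i, k) / choose(n, k) —
#' available via `method = "exact"` (sd is then the permutation sd of the
#' randomized estimator, omitted).
#'
#' @param dataset a `diet_dataset` of full stomachs.
#' @param permutations number of random orderings (default 999).
#' @param seed RNG seed (required for the randomized method; recorded in the
#'   result).
#' @param method `"random"` (default) or `"exact"`.
#' @return Object of class `prey_curve`: list with `k`, `mean_richness`,
#'   `sd_richness`, `n_points`, `permutations`, `seed`, `method`.
#' @export
accumulation_curve <- function(dataset, permutations = 999, seed = NULL,
                               method = c("random", "exact")) {
  method <- match.arg(method)
  occ <- occurrence_matrix(dataset)
  occ <- occ[rowSums(occ) > 0, , drop = FALSE]
  occ <- occ[, colSums(occ) > 0, drop = FALSE]
  n <- nrow(occ)
  if (n < 2) stopf("need at least 2 full stomachs, got %d", n)
  if (method == "exact") {
    ni <- colSums(occ)
    k <- seq_len(n)
    mean_rich <- vapply(k, function(kk) {
      p_missing <- exp(lchoose(n - ni, kk) - lchoose(n, kk))
      sum(1 - p_missing)
    }, numeric(1))
    sd_rich <- rep(NA_real_, n)
    permutations <- NA_integer_
  } else {
    if (permutations < 1) stopf("permutations must be >= 1")
    if (is.null(seed)) stopf("a seed is required for the randomized curve")
    rich <- with_seed(seed, {
      vapply(seq_len(permutations), function(p) {
        ord <- sample.int(n)
        seen <- apply(occ[ord, , drop = FALSE], 2, cummax)
        rowSums(seen)
      }, numeric(n))
    })
    mean_rich <- unname(rowMeans(rich))
    sd_rich <- unname(apply(rich, 1, stats::sd))
  }
  structure(list(k = seq_len(n), mean_richness = mean_rich,
                 sd_richness = sd_rich, n_points = n,
                 permutations = permutations, seed = seed, method = method),
            class = "prey_curve")
}

#' @export
print.prey_curve <- function(x, ...) {
  cat(sprintf("Cumulative prey curve: %d stomachs, %s\n", x$n_points,
              if (x$method == "exact") "exact expectation"
              else sprintf("%d permutations (seed %s)", x$permutations,
                           format(x$seed))))
  cat(sprintf("  final richness %.0f; endpoint slope (last 5) b = %.3f\n",
              x$mean_richness[x$n_points],
              if (x$n_points >= 5) endpoint_slope(x) else NA_real_))
  invisible(x)
}

#' @export
plot.prey_curve <- function(x, ...) {
  graphics::plot(x$k, x$mean_richness, type = "l",
                 xlab = "Number of stomachs",
                 ylab = "Cumulative prey categories", ...)
  if (!all(is.na(x$sd_richness))) {
    graphics::lines(x$k, x$mean_richness + x$sd_richness, lty = 2)
    graphics::lines(x$k, pmax(x$mean_richness - x$sd_richness, 0), lty = 2)
  }
  invisible(x)
}

#' Endpoint slope of a prey curve
#'
#' OLS slope of mean richness on sample size over the final `k_last` points
#' of the curve, in prey categories per stomach.
#'
#' @param curve a `prey_curve`.
#' @param k_last number of terminal points to regress over (default 5).
#' @return The slope `b`.
#' @export
endpoint_slope <- function(curve, k_last = 5) {
  if (curve$n_points < k_last)
    stopf("curve has %d points; need at least k_last = %d",
          curve$n_points, k_last)
  idx <- seq(curve$n_points - k_last + 1, curve$n_points)
  fit <- stats::lm(y ~ k, data = data.frame(k = curve$k[idx],
                                            y = curve$mean_richness[idx]))
  unname(stats::coef(fit)[2])
}

#' Sample-sufficiency decision
#'
#' A curve is considered to have reached an asymptote — the sample judged
#' sufficient — when its endpoint slope is at or below the threshold
#' (inclusive).
#'
#' @param b endpoint slope from [endpoint_slope()].
#' @param threshold slope threshold (default 0.05 categories per stomach).
#' @return `TRUE` if `b <= threshold`.
#' @export
sufficiency <- function(b, threshold = 0.05) {
  if (!is.finite(b)) stopf("slope must be finite")
  b <= threshold
}

#' Prey-curve sufficiency summary per stratum
#'
#' Runs [accumulation_curve()] and the endpoint-slope test for each
#' location x year stratum.
#'
#' @param dataset a `diet_dataset`.
#' @param permutations,seed passed to [accumulation_curve()].
#' @param k_last,threshold passed to the slope test.
#' @return Data frame with `stratum`, `n`, `richness`, `b`, `sufficient`.
#' @export
prey_curve_summary <- function(dataset, permutations = 999, seed = 1,
                               k_last = 5, threshold = 0.05) {
  full <- apply_exclusions(dataset, drop_other = FALSE)
  key <- paste(full$meta$location, full$meta$year, sep = "_")
  rows <- lapply(unique(key), function(k) {
    d <- subset_stratum(full, sub("_.*$", "", k),
                        as.integer(sub("^.*_", "", k)))
    cur <- accumulation_curve(d, permutations, seed)
    b <- endpoint_slope(cur, k_last)
    data.frame(stratum = k, n = cur$n_points,
               richness = cur$mean_richness[cur$n_points],
               b = b, sufficient = sufficiency(b, threshold),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
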