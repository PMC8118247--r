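# Distance-based multivariate analysis of diet composition.
#
# All tests operate on a symmetric dissimilarity matrix D (Bray-Curtis for
# compositions; Euclidean supported for oracle checks). The machinery is the
# McArdle-Anderson distance-based linear model: with A = -D^2/2 and
# J = I - 11'/n, the Gower-centered matrix G = J A J has tr(G) equal to the
# total sum of squares, and the SS absorbed by a design X is tr(H G) with
# H the hat matrix of X. Sequential (Type I) SS throughout; free permutation
# of observation labels; p = (#{F_perm >= F_obs} + 1) / (permutations + 1).

#' Bray-Curtis dissimilarity matrix
#'
#' `d_ij = sum |x_i - x_j| / sum (x_i + x_j)` over prey categories, for rows
#' of a composition matrix (typically per-stomach %N or %W rows summing to
#' 100).
#'
#' @param x numeric matrix, observations x categories, non-negative.
#' @return A `dist` object with entries in `[0, 1]`.
#' @export
bray_curtis <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stopf("need at least 2 observations")
  if (any(x < 0)) stopf("composition entries must be non-negative")
  s <- rowSums(x)
  if (any(s == 0))
    stopf("all-zero composition row(s): %s",
          paste(utils::head(which(s == 0), 5), collapse = ", "))
  num <- stats::dist(x, method = "manhattan")
  den <- as.dist_outer_sum(s)
  out <- num / den
  attr(out, "method") <- "bray-curtis"
  out
}

# lower-triangle (dist layout) of outer(s, s, `+`)
as.dist_outer_sum <- function(s) {
  stats::as.dist(outer(s, s, `+`))
}

# Gower-centered inner-product matrix from a dissimilarity matrix.
gower_center <- function(d) {
  D <- as.matrix(d)
  A <- -0.5 * D^2
  rm <- rowMeans(A)
  sweep(sweep(A, 1, rm), 2, rm) + mean(A)
}

# Economy hat matrix (rank-revealing) and its rank.
hat_matrix <- function(X) {
  qr_ <- qr(X)
  r <- qr_$rank
  Q <- qr.Q(qr_)[, seq_len(r), drop = FALSE]
  list(H = tcrossprod(Q), rank = r)
}

# All permutations of 1..n (n <= 8), as a list.
all_permutations <- function(n) {
  if (n == 1) return(list(1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n * length(sub))
  k <- 0L
  for (s in sub) for (pos in seq_len(n)) {
    k <- k + 1L
    out[[k]] <- append(s, n, after = pos - 1L)
  }
  out
}

# Sequential designs for an ordered character vector of terms.
# Returns per-term hat matrices of the cumulative designs and per-term df.
sequential_hats <- function(terms, data, n) {
  hats <- vector("list", length(terms))
  dfs <- integer(length(terms))
  prev_rank <- 1L  # intercept
  for (k in seq_along(terms)) {
    X <- stats::model.matrix(stats::reformulate(terms[seq_len(k)]), data)
    if (nrow(X) != n)
      stopf("missing covariate values: design has %d rows for %d observations",
            nrow(X), n)
    hm <- hat_matrix(X)
    dfs[k] <- hm$rank - prev_rank
    if (dfs[k] == 0)
      stopf("term '%s' is aliased with preceding terms", terms[k])
    prev_rank <- hm$rank
    hats[[k]] <- hm$H
  }
  list(hats = hats, dfs = dfs)
}

# F statistics for all sequential terms given centered G (possibly permuted).
seq_f_stats <- function(G, hats, dfs, df_res) {
  trG <- sum(diag(G))
  cum <- vapply(hats, function(H) sum(H * G), numeric(1))
  ss <- diff(c(0, cum))
  ss_res <- trG - cum[length(cum)]
  list(ss = ss, ss_res = ss_res,
       f = (ss / dfs) / (ss_res / df_res))
}

#' Permutational multivariate analysis of variance (PERMANOVA)
#'
#' Distance-based linear model with sequential (Type I) sums of squares and
#' a free-permutation null for the pseudo-F of each term. With Euclidean
#' distances and a single factor the pseudo-F equals the classical one-way
#' ANOVA F summed over coordinates.
#'
#' @param d a `dist` or symmetric dissimilarity matrix.
#' @param data data frame of explanatory variables (rows in the order of
#'   `d`'s observations).
#' @param terms character vector of model terms, in sequential order; may
#'   include interactions (`"Location:Year"`).
#' @param permutations integer number of random permutations (default 999),
#'   or `"exhaustive"` to enumerate all `n!` relabelings (n <= 8).
#' @param seed RNG seed for the permutations.
#' @return Object of class `permanova`: `$table` (term, df, SS, F, r2, p),
#'   `$residual`, `$total_ss`, `$permutations`, `$seed`.
#' @export
permanova <- function(d, data, terms = names(data), permutations = 999,
                      seed = NULL) {
  D <- as.matrix(d)
  n <- nrow(D)
  G <- gower_center(D)
  sq <- sequential_hats(terms, data, n)
  df_res <- n - 1L - sum(sq$dfs)
  if (df_res <= 0) stopf("no residual degrees of freedom")
  obs <- seq_f_stats(G, sq$hats, sq$dfs, df_res)
  exhaustive <- identical(permutations, "exhaustive")
  if (exhaustive) {
    if (n > 8) stopf("exhaustive permutations limited to n <= 8")
    perms <- all_permutations(n)
    count <- rep(0, length(terms))
    for (p in perms) {
      fp <- seq_f_stats(G[p, p], sq$hats, sq$dfs, df_res)$f
      count <- count + (fp >= obs$f - 1e-12)
    }
    pval <- count / length(perms)
    n_perm <- length(perms)
  } else {
    if (!is.numeric(permutations) || permutations < 1)
      stopf("permutations must be a positive integer or \"exhaustive\"")
    if (is.null(seed)) stopf("a seed is required for random permutations")
    count <- with_seed(seed, {
      cnt <- rep(0, length(terms))
      for (i in seq_len(permutations)) {
        p <- sample.int(n)
        fp <- seq_f_stats(G[p, p], sq$hats, sq$dfs, df_res)$f
        cnt <- cnt + (fp >= obs$f - 1e-12)
      }
      cnt
    })
    pval <- (count + 1) / (permutations + 1)
    n_perm <- permutations
  }
  total_ss <- sum(diag(G))
  tab <- data.frame(term = terms, df = sq$dfs, SS = obs$ss, F = obs$f,
                    r2 = obs$ss / total_ss, p = pval,
                    stringsAsFactors = FALSE)
  structure(list(table = tab,
                 residual = data.frame(df = df_res, SS = obs$ss_res,
                                       r2 = obs$ss_res / total_ss),
                 total_ss = total_ss, permutations = n_perm, seed = seed,
                 exhaustive = exhaustive),
            class = "permanova")
}

#' @export
print.permanova <- function(x, ...) {
  cat(sprintf("PERMANOVA (sequential SS, %s permutations%s)\n",
              format(x$permutations),
              if (x$exhaustive) ", exhaustive"
              else sprintf(", seed %s", format(x$seed))))
  tab <- x$table
  tab$SS <- signif(tab$SS, 4); tab$F <- round(tab$F, 2)
  tab$r2 <- round(tab$r2, 3)
  print.data.frame(tab, row.names = FALSE)
  cat(sprintf("Residual: df = %d, r2 = %.3f\n",
              x$residual$df, x$residual$r2))
  invisible(x)
}

#' Screen correlated explanatory variables
#'
#' Pairwise Pearson correlation among numeric candidate covariates; for any
#' pair with `|r| > r_threshold` and two-sided `p < alpha`, the variable
#' appearing later in the priority order is dropped. Constant covariates are
#' dropped with a warning. Every decision is listed in the report.
#'
#' @param data data frame of candidate covariates (numeric columns used).
#' @param candidates candidate names, in priority order (earlier = kept on
#'   conflict); default all numeric columns of `data`.
#' @param r_threshold correlation magnitude threshold (default 0.65).
#' @param alpha significance threshold for the correlation test (0.05).
#' @return List with `retained`, `dropped`, and `report` (data frame of all
#'   pairwise decisions).
#' @export
covariate_screen <- function(data, candidates = NULL, r_threshold = 0.65,
                             alpha = 0.05) {
  if (is.null(candidates))
    candidates <- names(data)[vapply(data, is.numeric, logical(1))]
  bad <- candidates[!vapply(data[candidates], is.numeric, logical(1))]
  if (length(bad))
    stopf("non-numeric candidates: %s", paste(bad, collapse = ", "))
  dropped <- character(0)
  const <- candidates[vapply(data[candidates],
                             function(v) stats::sd(v) == 0, logical(1))]
  if (length(const)) {
    warnf("constant covariate(s) dropped: %s", paste(const, collapse = ", "))
    dropped <- const
  }
  report <- NULL
  for (i in seq_along(candidates)) for (j in seq_along(candidates)) {
    if (j <= i) next
    a <- candidates[i]; b <- candidates[j]
    if (a %in% dropped || b %in% dropped) next
    ct <- stats::cor.test(data[[a]], data[[b]])
    flag <- abs(ct$estimate) > r_threshold && ct$p.value < alpha
    report <- rbind(report, data.frame(
      var1 = a, var2 = b, r = unname(ct$estimate), p = ct$p.value,
      action = if (flag) sprintf("drop %s", b) else "keep both",
      stringsAsFactors = FALSE))
    if (flag) dropped <- c(dropped, b)
  }
  list(retained = setdiff(candidates, dropped), dropped = dropped,
       report = report)
}

#' Forward stepwise PERMANOVA model building
#'
#' At each step, every remaining candidate term is tested sequentially after
#' the terms already included; the candidate with the largest pseudo-F among
#' those with permutation `p <= alpha` enters (alphabetical tie-break).
#' Selection stops when no candidate qualifies. The final table refits the
#' selected model and re-ranks terms by F.
#'
#' @inheritParams permanova
#' @param candidates candidate term names (may include interactions).
#' @param alpha entry threshold on the permutation p-value (default 0.05).
#' @return Object of class `forward_permanova`: `$selected` (in entry
#'   order), `$model` (a [permanova()] fit of the selected terms), `$table`
#'   (the model table re-ranked by descending F), and `$log` of every step.
#' @export
forward_select <- function(d, data, candidates, alpha = 0.05,
                           permutations = 999, seed = NULL) {
  if (!length(candidates)) stopf("no candidate terms")
  if (is.null(seed)) stopf("a seed is required")
  D <- as.matrix(d)
  n <- nrow(D)
  G <- gower_center(D)
  trG <- sum(diag(G))
  included <- character(0)
  log <- NULL
  step <- 0L
  repeat {
    step <- step + 1L
    remaining <- setdiff(candidates, included)
    if (!length(remaining)) break
    # cumulative hats for base + each candidate
    base_H <- if (length(included)) {
      X <- stats::model.matrix(stats::reformulate(included), data)
      hat_matrix(X)
    } else list(H = matrix(1 / n, n, n), rank = 1L)
    cand <- lapply(remaining, function(trm) {
      X <- stats::model.matrix(stats::reformulate(c(included, trm)), data)
      hm <- hat_matrix(X)
      hm$df <- hm$rank - base_H$rank
      hm
    })
    names(cand) <- remaining
    ok <- vapply(cand, function(cm) cm$df > 0, logical(1))
    cand <- cand[ok]
    if (!length(cand)) break
    f_one <- function(Gp) {
      tr_base <- sum(base_H$H * Gp)
      vapply(cand, function(cm) {
        tr_full <- sum(cm$H * Gp)
        df_res <- n - cm$rank
        ((tr_full - tr_base) / cm$df) / ((trG - tr_full) / df_res)
      }, numeric(1))
    }
    f_obs <- f_one(G)
    counts <- with_seed(derive_seed(seed, step), {
      cnt <- rep(0, length(cand))
      for (i in seq_len(permutations)) {
        p <- sample.int(n)
        cnt <- cnt + (f_one(G[p, p]) >= f_obs - 1e-12)
      }
      cnt
    })
    pvals <- (counts + 1) / (permutations + 1)
    log <- rbind(log, data.frame(step = step, term = names(cand),
                                 F = unname(f_obs), p = unname(pvals),
                                 entered = FALSE, stringsAsFactors = FALSE))
    eligible <- names(cand)[pvals <= alpha]
    if (!length(eligible)) break
    fe <- f_obs[eligible]
    best <- eligible[order(-fe, eligible)][1]
    log$entered[log$step == step & log$term == best] <- TRUE
    included <- c(included, best)
  }
  model <- if (length(included))
    permanova(d, data, included, permutations, seed = derive_seed(seed, 0L))
  else NULL
  tab <- if (!is.null(model)) {
    t <- model$table
    t[order(-t$F, t$term), ]
  } else NULL
  structure(list(selected = included, model = model, table = tab, log = log,
                 alpha = alpha, permutations = permutations, seed = seed),
            class = "forward_permanova")
}

#' @export
print.forward_permanova <- function(x, ...) {
  if (!length(x$selected)) {
    cat("Forward PERMANOVA selection: no term qualified at alpha =",
        x$alpha, "\n")
    return(invisible(x))
  }
  cat("Forward PERMANOVA selection, entry order:",
      paste(x$selected, collapse = " -> "), "\n")
  cat("Final model (ranked by F):\n")
  tab <- x$table
  tab$SS <- signif(tab$SS, 4); tab$F <- round(tab$F, 2)
  tab$r2 <- round(tab$r2, 3)
  print.data.frame(tab, row.names = FALSE)
  invisible(x)
}

# Principal-coordinate embedding keeping positive-eigenvalue axes.
pcoa_embed <- function(d) {
  G <- gower_center(d)
  eg <- eigen(G, symmetric = TRUE)
  tol <- max(abs(eg$values)) * 1e-8
  pos <- eg$values > tol
  neg_inertia <- sum(abs(eg$values[eg$values < -tol]))
  if (neg_inertia > 0)
    message(sprintf(
      "discarding %d negative-eigenvalue axes (%.1f%% of absolute inertia)",
      sum(eg$values < -tol),
      100 * neg_inertia / sum(abs(eg$values))))
  Q <- eg$vectors[, pos, drop = FALSE] %*%
    diag(sqrt(eg$values[pos]), sum(pos))
  rownames(Q) <- rownames(as.matrix(d))
  Q
}

#' Permutation test of multivariate group dispersions (PERMDISP)
#'
#' Embeds the dissimilarity matrix by principal coordinates (positive axes),
#' computes each observation's Euclidean distance to its group centroid, and
#' tests group differences in those distances with a one-way ANOVA F whose
#' null distribution is obtained by permuting group labels (centroids and
#' distances recomputed each permutation).
#'
#' @param d a `dist` or symmetric dissimilarity matrix.
#' @param grouping factor of group labels.
#' @param permutations number of label permutations (default 999).
#' @param seed RNG seed.
#' @return Object of class `permdisp`: `$F`, `$p`, `$group_means`,
#'   `$distances`, `$df`.
#' @export
permdisp <- function(d, grouping, permutations = 999, seed = NULL) {
  if (is.null(seed)) stopf("a seed is required")
  grouping <- factor(grouping)
  small <- names(which(table(grouping) < 2))
  if (length(small)) {
    warnf("group(s) of size < 2 excluded: %s", paste(small, collapse = ", "))
    keep <- !(grouping %in% small)
    d <- as.matrix(d)[keep, keep]
    grouping <- droplevels(grouping[keep])
  }
  if (nlevels(grouping) < 2) stopf("need at least 2 groups of size >= 2")
  Q <- pcoa_embed(d)
  disp_f <- function(g) {
    g <- factor(g)
    cent <- apply(Q, 2, function(col) tapply(col, g, mean))
    z <- sqrt(rowSums((Q - cent[as.integer(g), , drop = FALSE])^2))
    grand <- mean(z)
    ssb <- sum(tapply(z, g, function(v) length(v) * (mean(v) - grand)^2))
    ssw <- sum(tapply(z, g, function(v) sum((v - mean(v))^2)))
    dfb <- nlevels(g) - 1L
    dfw <- length(z) - nlevels(g)
    list(F = (ssb / dfb) / (ssw / dfw), z = z, dfb = dfb, dfw = dfw)
  }
  obs <- disp_f(grouping)
  count <- with_seed(seed, {
    cnt <- 0
    for (i in seq_len(permutations)) {
      cnt <- cnt + (disp_f(sample(grouping))$F >= obs$F - 1e-12)
    }
    cnt
  })
  structure(list(F = obs$F, p = (count + 1) / (permutations + 1),
                 group_means = tapply(obs$z, grouping, mean),
                 distances = obs$z, df = c(obs$dfb, obs$dfw),
                 permutations = permutations, seed = seed),
            class = "permdisp")
}

#' @export
print.permdisp <- function(x, ...) {
  cat(sprintf("PERMDISP: F(%d, %d) = %.3f, p = %.4g (%d permutations)\n",
              x$df[1], x$df[2], x$F, x$p, x$permutations))
  cat("mean distance to centroid by group:\n")
  print(round(x$group_means, 3))
  invisible(x)
}

#' Canonical analysis of principal coordinates (CAP / db-RDA)
#'
#' Constrained ordination of a dissimilarity matrix on explanatory
#' variables: the positive-eigenvalue principal-coordinate axes are
#' regressed on the design, and canonical axes are the eigenvectors of the
#' fitted values' cross-product. Per-axis percent variance is the canonical
#' eigenvalue over the total (positive) inertia. Overall and per-axis
#' pseudo-F are tested by free permutation of observations; per-term tests
#' reuse the [permanova()] machinery (sequential or marginal).
#'
#' @inheritParams permanova
#' @param composition optional composition matrix (observations x prey)
#'   used for species biplot scores (correlations with site scores).
#' @param term_test `"sequential"` or `"marginal"` per-variable tests.
#' @return Object of class `cap_result` with eigenvalues, percent variance,
#'   per-axis and overall F and p, site scores, biplot scores and the
#'   per-term table.
#' @export
cap <- function(d, data, terms = names(data), permutations = 999,
                seed = NULL, composition = NULL,
                term_test = c("sequential", "marginal")) {
  term_test <- match.arg(term_test)
  if (is.null(seed)) stopf("a seed is required")
  Q <- pcoa_embed(d)
  n <- nrow(Q)
  X <- stats::model.matrix(stats::reformulate(terms), data)
  if (ncol(X) > n) stopf("more design columns than observations")
  hm <- hat_matrix(X)
  q <- hm$rank - 1L
  if (q < 1) stopf("design has no non-intercept rank")
  df_res <- n - 1L - q
  total_inertia <- sum(Q^2)
  cap_eig <- function(Qm) {
    fit <- hm$H %*% Qm
    ev <- eigen(crossprod(fit), symmetric = TRUE)
    keep <- ev$values > max(ev$values) * 1e-9
    list(values = ev$values[keep], vectors = ev$vectors[, keep, drop = FALSE],
         ss_fit = sum(ev$values[keep]))
  }
  obs <- cap_eig(Q)
  ss_res <- total_inertia - obs$ss_fit
  overall_f <- (obs$ss_fit / q) / (ss_res / df_res)
  axis_f <- obs$values / (ss_res / df_res)
  perm_stats <- with_seed(seed, {
    cnt_overall <- 0
    cnt_axis <- rep(0, length(axis_f))
    for (i in seq_len(permutations)) {
      pe <- cap_eig(Q[sample.int(n), , drop = FALSE])
      ssr_p <- total_inertia - pe$ss_fit
      f_p <- (pe$ss_fit / q) / (ssr_p / df_res)
      cnt_overall <- cnt_overall + (f_p >= overall_f - 1e-12)
      k <- min(length(axis_f), length(pe$values))
      fa <- pe$values[seq_len(k)] / (ssr_p / df_res)
      cnt_axis[seq_len(k)] <- cnt_axis[seq_len(k)] +
        (fa >= axis_f[seq_len(k)] - 1e-12)
    }
    list(overall = cnt_overall, axis = cnt_axis)
  })
  site_scores <- Q %*% obs$vectors          # weighted-average style scores
  lc_scores <- hm$H %*% site_scores         # linear-constraint scores
  colnames(site_scores) <- colnames(lc_scores) <-
    paste0("CAP", seq_len(ncol(site_scores)))
  nonconstant <- function(m) {
    m <- as.matrix(m)
    m[, apply(m, 2, stats::sd) > 0, drop = FALSE]
  }
  species_scores <- if (!is.null(composition))
    stats::cor(nonconstant(composition), site_scores) else NULL
  vars_in_data <- intersect(terms, names(data))
  num_vars <- vars_in_data[vapply(data[vars_in_data], is.numeric, logical(1))]
  env_scores <- if (length(num_vars))
    stats::cor(nonconstant(data[num_vars]), site_scores) else NULL
  fac_vars <- setdiff(vars_in_data, num_vars)
  centroids <- if (length(fac_vars)) {
    do.call(rbind, lapply(fac_vars, function(v) {
      cc <- apply(site_scores, 2, function(col)
        tapply(col, data[[v]], mean))
      rownames(cc) <- paste(v, rownames(cc), sep = ":")
      cc
    }))
  } else NULL
  term_tab <- if (term_test == "sequential") {
    permanova(d, data, terms, permutations,
              seed = derive_seed(seed, 1L))$table
  } else {
    do.call(rbind, lapply(terms, function(trm) {
      ord <- c(setdiff(terms, trm), trm)
      tt <- permanova(d, data, ord, permutations,
                      seed = derive_seed(seed, 1L))$table
      tt[tt$term == trm, ]
    }))
  }
  structure(list(
    eigenvalues = obs$values,
    pct_var = 100 * obs$values / total_inertia,
    pct_explained = 100 * obs$ss_fit / total_inertia,
    overall = data.frame(F = overall_f,
                         p = (perm_stats$overall + 1) / (permutations + 1)),
    axes = data.frame(axis = paste0("CAP", seq_along(axis_f)),
                      eigenvalue = obs$values,
                      pct_var = 100 * obs$values / total_inertia,
                      F = axis_f,
                      p = (perm_stats$axis + 1) / (permutations + 1)),
    site_scores = site_scores, lc_scores = lc_scores,
    species_scores = species_scores, env_scores = env_scores,
    centroids = centroids, terms = term_tab, term_test = term_test,
    permutations = permutations, seed = seed),
    class = "cap_result")
}

#' @export
print.cap_result <- function(x, ...) {
  cat(sprintf("CAP: overall F = %.2f, p = %.4g; model explains %.1f%% of inertia\n",
              x$overall$F, x$overall$p, x$pct_explained))
  ax <- utils::head(x$axes, 4)
  ax$eigenvalue <- signif(ax$eigenvalue, 4)
  ax$pct_var <- round(ax$pct_var, 1); ax$F <- round(ax$F, 2)
  print.data.frame(ax, row.names = FALSE)
  invisible(x)
}

#' Biplot of the first two canonical axes
#'
#' @param x a `cap_result`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.cap_result <- function(x, ...) {
  if (ncol(x$site_scores) < 2) stopf("fewer than 2 canonical axes")
  s <- x$site_scores[, 1:2]
  graphics::plot(s, pch = 16, col = "grey60",
                 xlab = sprintf("CAP1 (%.1f%%)", x$axes$pct_var[1]),
                 ylab = sprintf("CAP2 (%.1f%%)", x$axes$pct_var[2]), ...)
  graphics::abline(h = 0, v = 0, lty = 3)
  scl <- max(abs(s)) * 0.9
  if (!is.null(x$species_scores)) {
    sp <- x$species_scores[, 1:2] * scl
    graphics::arrows(0, 0, sp[, 1], sp[, 2], length = 0.05, col = "red3")
    graphics::text(sp * 1.08, labels = rownames(sp), col = "red3", cex = 0.8)
  }
  if (!is.null(x$env_scores)) {
    en <- x$env_scores[, 1:2] * scl
    graphics::arrows(0, 0, en[, 1], en[, 2], length = 0.05, col = "blue3")
    graphics::text(en * 1.08, labels = rownames(en), col = "blue3", cex = 0.8)
  }
  if (!is.null(x$centroids))
    graphics::text(x$centroids[, 1:2, drop = FALSE],
                   labels = rownames(x$centroids), col = "blue3", cex = 0.8)
  invisible(x)
}
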