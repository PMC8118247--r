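# Prey-specific dietary index family.
#
# For prey category i over the n full stomachs of a stratum:
#   %FO_i  = 100 * (stomachs containing i) / n
#   %PN_i  = mean per-stomach count percentage of i over stomachs containing i
#   %PW_i  = same on the weight basis
#   %N_i   = mean over ALL n stomachs (zeros included) = %PN_i * %FO_i / 100
#   %W_i   = %PW_i * %FO_i / 100
#   %PSIRI = %FO * (%PN + %PW) / 200 = (%N + %W) / 2
# A prey "occurs" in a stomach if its count > 0 OR its weight > 0 (well
# digested items can be weighable but uncountable).

occurrence_matrix <- function(dataset) {
  dataset$counts > 0 | dataset$weights > 0
}

#' Per-stomach prey proportions
#'
#' Converts each record's counts (or weights) into percentages that sum to
#' 100 across prey categories. Records with zero total on the chosen basis
#' are dropped with a warning (possible on the weight basis when all items
#' were too digested to weigh).
#'
#' @param dataset a `diet_dataset`, already passed through
#'   [apply_exclusions()].
#' @param basis `"number"` (counts) or `"weight"` (grams).
#' @return Matrix (record x prey) of percentages; each row sums to 100.
#' @export
per_stomach_proportions <- function(dataset, basis = c("number", "weight")) {
  basis <- match.arg(basis)
  m <- if (basis == "number") dataset$counts else dataset$weights
  tot <- rowSums(m)
  if (any(tot == 0)) {
    warnf("%d records with zero total %s excluded from proportions",
          sum(tot == 0), basis)
    m <- m[tot > 0, , drop = FALSE]
    tot <- tot[tot > 0]
  }
  100 * m / tot
}

#' Frequency of occurrence (%FO)
#'
#' @inheritParams per_stomach_proportions
#' @return Named vector: percentage of full stomachs containing each prey.
#' @export
frequency_of_occurrence <- function(dataset) {
  100 * colMeans(occurrence_matrix(dataset))
}

#' Prey-specific abundance (%PN / %PW)
#'
#' Mean per-stomach percentage of each prey over only the stomachs that
#' contain it; `NaN` for prey absent everywhere.
#'
#' @inheritParams per_stomach_proportions
#' @return Named vector of prey-specific percentages.
#' @export
prey_specific_abundance <- function(dataset, basis = c("number", "weight")) {
  basis <- match.arg(basis)
  prop <- per_stomach_proportions(dataset, basis)
  occ <- occurrence_matrix(dataset)[rownames(prop), , drop = FALSE]
  vapply(colnames(prop), function(j) {
    inset <- occ[, j]
    if (!any(inset)) NaN else mean(prop[inset, j])
  }, numeric(1))
}

#' Mean percent abundance (%N / %W)
#'
#' Mean per-stomach percentage over all full stomachs, zeros included. Both
#' computation routes (direct mean, and %P x %FO / 100) are evaluated and
#' asserted to agree to 1e-9, as an internal consistency check of the
#' prey-specific decomposition.
#'
#' @inheritParams per_stomach_proportions
#' @return Named vector of mean percentages; sums to 100 over prey.
#' @export
mean_percent_abundance <- function(dataset, basis = c("number", "weight")) {
  basis <- match.arg(basis)
  prop <- per_stomach_proportions(dataset, basis)
  direct <- colMeans(prop)
  occ <- occurrence_matrix(dataset)[rownames(prop), , drop = FALSE]
  via_ps <- vapply(colnames(prop), function(j) {
    inset <- occ[, j]
    if (!any(inset)) 0 else mean(prop[inset, j]) * mean(inset)
  }, numeric(1))
  if (max(abs(direct - via_ps)) > 1e-9)
    stopf("internal inconsistency: direct %%%s mean and prey-specific route disagree",
          if (basis == "number") "N" else "W")
  direct
}

#' Reconstruct %N from prey-specific components
#'
#' The decomposition `%N = %PN x %FO / 100` (identically for `%W`), applied
#' to given component values — e.g. to validate published table rows.
#'
#' @param pct_p prey-specific abundance (%PN or %PW).
#' @param pct_fo frequency of occurrence (%FO).
#' @param digits decimals for display rounding (half away from zero); `NULL`
#'   for the unrounded value.
#' @return Reconstructed mean percent abundance.
#' @export
#' @examples
#' pct_mean_from_components(97.3, 70.7)  # 68.8
pct_mean_from_components <- function(pct_p, pct_fo, digits = 1) {
  x <- pct_p * pct_fo / 100
  if (is.null(digits)) x else round_half_up(x, digits)
}

#' Reconstruct %PSIRI from prey-specific components
#'
#' `%PSIRI = (%PN + %PW) x %FO / 200`, applied to given component values.
#'
#' @param pct_pn,pct_pw prey-specific number and weight percentages.
#' @param pct_fo frequency of occurrence (%FO).
#' @inheritParams pct_mean_from_components
#' @return Reconstructed %PSIRI.
#' @export
#' @examples
#' psiri_from_components(97.3, 96.3, 70.7)  # 68.4
psiri_from_components <- function(pct_pn, pct_pw, pct_fo, digits = 1) {
  x <- (pct_pn + pct_pw) * pct_fo / 200
  if (is.null(digits)) x else round_half_up(x, digits)
}

#' Prey-specific index of relative importance table
#'
#' Computes the full index family (%N, %PN, %W, %PW, %FO, %PSIRI) for one
#' stratum of full stomachs. Prey absent from every record are dropped.
#' Rows are sorted by descending %PSIRI (alphabetical tie-break); unrounded
#' values are returned, with a `print` method that displays them rounded
#' half-up to one decimal.
#'
#' @param dataset a `diet_dataset` of full stomachs (see
#'   [apply_exclusions()]).
#' @param stratum optional label attached to the result.
#' @return A data frame of class `diet_metrics` with columns `category`,
#'   `pctN`, `pctPN`, `pctW`, `pctPW`, `pctFO`, `pctPSIRI`; attributes
#'   `n_stomachs` and `stratum`.
#' @export
psiri <- function(dataset, stratum = "pooled") {
  if (all(dataset$counts == 0) || all(dataset$weights == 0))
    stopf("both counts and weights are required for %%PSIRI; use the basis-specific metrics for single-basis data")
  fo <- frequency_of_occurrence(dataset)
  keep <- fo > 0
  pn <- prey_specific_abundance(dataset, "number")
  pw <- prey_specific_abundance(dataset, "weight")
  nn <- mean_percent_abundance(dataset, "number")
  ww <- mean_percent_abundance(dataset, "weight")
  out <- data.frame(
    category = names(fo)[keep],
    pctN = unname(nn[keep]), pctPN = unname(pn[keep]),
    pctW = unname(ww[keep]), pctPW = unname(pw[keep]),
    pctFO = unname(fo[keep]),
    stringsAsFactors = FALSE)
  out$pctPSIRI <- out$pctFO * (out$pctPN + out$pctPW) / 200
  out <- out[order(-out$pctPSIRI, out$category), ]
  rownames(out) <- NULL
  structure(out, class = c("diet_metrics", "data.frame"),
            n_stomachs = nrow(dataset$counts), stratum = stratum)
}

#' @export
print.diet_metrics <- function(x, digits = 1, ...) {
  cat(sprintf("Diet composition, stratum '%s' (n = %d full stomachs)\n",
              attr(x, "stratum"), attr(x, "n_stomachs")))
  disp <- as.data.frame(x)
  num <- vapply(disp, is.numeric, logical(1))
  disp[num] <- lapply(disp[num], round_half_up, digits = digits)
  names(disp) <- sub("^pct", "%", names(disp))
  print.data.frame(disp, row.names = FALSE)
  invisible(x)
}

#' Diet metric tables per stratum
#'
#' Convenience wrapper producing one [psiri()] table per location x year
#' stratum (plus optionally the pooled table).
#'
#' @param dataset a `diet_dataset` (exclusions applied internally with
#'   `drop_other = FALSE`, so the Other bin appears in the tables as
#'   published composition tables do).
#' @param pooled include a pooled all-records table (default `TRUE`).
#' @param drop_other passed to [apply_exclusions()].
#' @return Named list of `diet_metrics` tables.
#' @export
diet_metric_tables <- function(dataset, pooled = TRUE, drop_other = FALSE) {
  full <- apply_exclusions(dataset, drop_other = drop_other)
  key <- paste(full$meta$location, full$meta$year, sep = "_")
  out <- lapply(unique(key), function(k) {
    psiri(subset_stratum(full,
                         location = sub("_.*$", "", k),
                         year = as.integer(sub("^.*_", "", k))),
          stratum = k)
  })
  names(out) <- unique(key)
  if (pooled) out$pooled <- psiri(full, stratum = "pooled")
  out
}

#' Check additivity between lowest-level and generalized metric tables
#'
#' For tables computed from the same records, %N and %W of each generalized
#' category must equal the sum over its member categories (to `tol`), and
#' its %FO must be at least the largest member %FO. Failures are listed, not
#' raised.
#'
#' @param table_lowest,table_generalized `diet_metrics` tables at the two
#'   taxonomic levels.
#' @param taxonomy taxonomy mapping member codes to parents.
#' @param tol tolerance on the %N/%W sums (default 0.1).
#' @return Data frame with one row per generalized category and a logical
#'   `ok` column; attribute `ok` summarises the whole check.
#' @export
additivity_check <- function(table_lowest, table_generalized,
                             taxonomy = lowest_taxonomy(), tol = 0.1) {
  parent <- function(code) {
    lev <- taxonomy$level[match(code, taxonomy$code)]
    ifelse(lev == "generalized", code, taxonomy$parent[match(code, taxonomy$code)])
  }
  grp <- parent(table_lowest$category)
  rows <- lapply(seq_len(nrow(table_generalized)), function(i) {
    g <- table_generalized$category[i]
    mem <- grp == g
    data.frame(
      category = g,
      sumN = sum(table_lowest$pctN[mem]),
      genN = table_generalized$pctN[i],
      sumW = sum(table_lowest$pctW[mem]),
      genW = table_generalized$pctW[i],
      maxMemberFO = if (any(mem)) max(table_lowest$pctFO[mem]) else 0,
      genFO = table_generalized$pctFO[i],
      stringsAsFactors = FALSE)
  })
  rep <- do.call(rbind, rows)
  rep$ok <- abs(rep$sumN - rep$genN) <= tol &
    abs(rep$sumW - rep$genW) <= tol &
    rep$genFO >= rep$maxMemberFO - 1e-9
  structure(rep, ok = all(rep$ok))
}
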