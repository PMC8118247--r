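# Bivariate isotopic niche metrics (Layman-style Eltonian niche
# characteristics) on (d13C, d15N) points, per sampling group:
#   CR    carbon range, max - min d13C (per mil)
#   NR    nitrogen range, max - min d15N (per mil)
#   TA    total convex hull area (per mil squared); 0 for n < 3 or collinear
#   CD    mean Euclidean distance of individuals to the group centroid
#   MNND  mean distance from each individual to its nearest other individual
#   SDNND sample (n-1) standard deviation of those nearest distances

#' Lipid screening by C:N ratio
#'
#' Removes tissue samples whose C:N weight ratio exceeds `cn_max` (high
#' lipid content biases d13C); the threshold itself is retained (only
#' strictly greater ratios are excluded). Records with a missing ratio are
#' retained with a warning unless `strict = TRUE`.
#'
#' @param records an `isotope_table` (or data frame) with a `cn_ratio`
#'   column.
#' @param cn_max exclusion threshold (default 3.5).
#' @param strict reject records with missing `cn_ratio` (default `FALSE`).
#' @return The retained records, with an `exclusions` attribute counting
#'   removals per location x year group.
#' @export
lipid_filter <- function(records, cn_max = 3.5, strict = FALSE) {
  records <- as.data.frame(records)
  if (nrow(records) == 0) return(records)
  cn <- records$cn_ratio
  if (is.null(cn)) stopf("records lack a cn_ratio column")
  miss <- is.na(cn)
  if (any(miss)) {
    if (strict) {
      drop <- miss
    } else {
      warnf("%d records without C:N ratio retained", sum(miss))
      drop <- rep(FALSE, length(cn))
    }
  } else drop <- rep(FALSE, length(cn))
  drop <- drop | (!miss & cn > cn_max)
  key <- paste(records$location %||% "all", records$year %||% "", sep = "_")
  excl <- tapply(drop, key, sum)
  out <- records[!drop, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, exclusions = excl)
}

#' Convex hull area of a planar point set
#'
#' Shoelace area over the hull vertices found by [grDevices::chull()];
#' zero for fewer than three distinct points or collinear sets.
#'
#' @param points two-column matrix or data frame (x, y).
#' @return Hull area (squared input units).
#' @export
convex_hull_area <- function(points) {
  pts <- as.matrix(points)
  pts <- pts[stats::complete.cases(pts), , drop = FALSE]
  if (nrow(unique(pts)) < 3) return(0)
  h <- grDevices::chull(pts)
  v <- pts[h, , drop = FALSE]
  nx <- nrow(v)
  j <- c(2:nx, 1)
  abs(sum(v[, 1] * v[j, 2] - v[j, 1] * v[, 2])) / 2
}

#' Six isotopic niche metrics for one group
#'
#' @param points matrix or data frame with columns (d13C, d15N), one row
#'   per individual; n >= 2 required (TA needs n >= 3 and is `NA` below
#'   that when `ta_na_small = TRUE`, else 0).
#' @param ta_na_small report TA as `NA` rather than 0 when n < 3.
#' @return Named vector `c(n, CR, NR, TA, CD, MNND, SDNND)`.
#' @export
layman_metrics <- function(points, ta_na_small = FALSE) {
  pts <- as.matrix(points)
  pts <- pts[stats::complete.cases(pts), , drop = FALSE]
  n <- nrow(pts)
  if (n < 2) stopf("need at least 2 individuals, got %d", n)
  cr <- diff(range(pts[, 1]))
  nr <- diff(range(pts[, 2]))
  ta <- if (n < 3 && ta_na_small) NA_real_ else convex_hull_area(pts)
  centroid <- colMeans(pts)
  cd <- mean(sqrt(colSums((t(pts) - centroid)^2)))
  dm <- as.matrix(stats::dist(pts))
  diag(dm) <- Inf  # a point is never its own neighbour
  nnd <- apply(dm, 1, min)
  c(n = n, CR = cr, NR = nr, TA = ta, CD = cd,
    MNND = mean(nnd), SDNND = stats::sd(nnd))
}

#' Isotopic niche metrics per group
#'
#' Applies [layman_metrics()] to each location x year group of a
#' lipid-screened isotope table. Groups with n < 3 get `TA = NA` (other
#' metrics still computed); groups with n < 2 are skipped with a warning.
#'
#' @param records isotope records (after [lipid_filter()]).
#' @param grouping character vector of grouping columns
#'   (default `c("location", "year")`).
#' @return Data frame of class `enc_table`: one row per group with columns
#'   `group`, `n`, `CR`, `NR`, `TA`, `CD`, `MNND`, `SDNND`.
#' @export
group_enc_table <- function(records, grouping = c("location", "year")) {
  records <- as.data.frame(records)
  key <- do.call(paste, c(records[grouping], sep = "_"))
  rows <- lapply(unique(key), function(k) {
    sub <- records[key == k, c("d13C", "d15N")]
    if (nrow(sub) < 2) {
      warnf("group '%s' has n < 2; skipped", k)
      return(NULL)
    }
    m <- layman_metrics(sub, ta_na_small = TRUE)
    data.frame(group = k, t(m), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("enc_table", "data.frame"))
}

#' @export
print.enc_table <- function(x, digits = 2, ...) {
  cat("Isotopic niche metrics (per mil; TA per mil squared)\n")
  disp <- as.data.frame(x)
  num <- vapply(disp, is.numeric, logical(1)) & names(disp) != "n"
  disp[num] <- lapply(disp[num], round, digits = digits)
  print.data.frame(disp, row.names = FALSE)
  invisible(x)
}

#' Isotope biplot with group hulls
#'
#' @param records isotope records with `d13C`, `d15N` and grouping columns.
#' @param grouping grouping columns (default location, year).
#' @param ... passed to [graphics::plot()].
#' @export
plot_isotope_niche <- function(records, grouping = c("location", "year"),
                               ...) {
  records <- as.data.frame(records)
  key <- factor(do.call(paste, c(records[grouping], sep = "_")))
  cols <- grDevices::hcl.colors(nlevels(key), "Dark 3")
  graphics::plot(records$d13C, records$d15N, col = cols[key], pch = 16,
                 xlab = expression(delta^13 * C ~ "(‰)"),
                 ylab = expression(delta^15 * N ~ "(‰)"), ...)
  for (g in levels(key)) {
    pts <- as.matrix(records[key == g, c("d13C", "d15N")])
    if (nrow(unique(pts)) >= 3) {
      h <- grDevices::chull(pts)
      graphics::polygon(pts[h, ], border = cols[which(levels(key) == g)])
    }
  }
  graphics::legend("topleft", legend = levels(key), col = cols, pch = 16,
                   bty = "n", cex = 0.8)
  invisible(records)
}
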