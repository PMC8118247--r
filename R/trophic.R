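# Fractional trophic-level estimation from diet proportions:
#   TL_k = 1 + sum_j P_j * TL_j
# where P_j is the proportion of prey category j in the diet of fish k and
# TL_j is the trophic level of that prey category.

#' Default prey trophic levels
#'
#' Package defaults for the generalized prey categories, unitless trophic
#' levels. Euphausiids (2.25) and teleosts/rockfishes (3.24) anchor the
#' endpoints: a euphausiid-exclusive diet gives TL 3.25 and a fish-exclusive
#' diet 4.24. The remaining categories (squids 3.2, amphipods 2.5,
#' unidentified crustaceans 2.4, tunicates 2.1, other 2.5) are typical
#' literature values for pelagic taxa and should be replaced with
#' study-specific assignments where available.
#'
#' @return Named numeric vector of prey trophic levels.
#' @export
default_prey_tl <- function() {
  c(CEPH = 3.2, CRUS = 2.4, AMPH = 2.5, EUPH = 2.25,
    TUNI = 2.1, TELE = 3.24, ROCK = 3.24, OTHR = 2.5)
}

#' Trophic level of a single diet composition
#'
#' @param proportions named vector of diet proportions (any non-negative
#'   weights; normalized internally to sum to 1).
#' @param prey_tl named vector mapping prey codes to trophic levels
#'   (default [default_prey_tl()]).
#' @return `1 + sum(P_j * TL_j)`.
#' @export
#' @examples
#' fish_trophic_level(c(EUPH = 1))            # 3.25
#' fish_trophic_level(c(TELE = 0.5, ROCK = 0.5))  # 4.24
fish_trophic_level <- function(proportions, prey_tl = default_prey_tl()) {
  proportions <- proportions[proportions > 0]
  if (!length(proportions) || sum(proportions) <= 0)
    stopf("diet composition is empty on the chosen basis")
  missing_tl <- setdiff(names(proportions), names(prey_tl))
  if (length(missing_tl))
    stopf("no trophic level configured for prey: %s",
          paste(missing_tl, collapse = ", "))
  p <- proportions / sum(proportions)
  1 + sum(p * prey_tl[names(p)])
}

#' Per-fish trophic levels for a dataset
#'
#' @param dataset a `diet_dataset` of full stomachs.
#' @param prey_tl prey trophic-level map.
#' @param basis `"weight"` (gravimetric, default) or `"number"`.
#' @return Named vector of per-fish trophic levels (fish with zero total on
#'   the chosen basis are dropped with a warning).
#' @export
trophic_levels <- function(dataset, prey_tl = default_prey_tl(),
                           basis = c("weight", "number")) {
  basis <- match.arg(basis)
  m <- if (basis == "weight") dataset$weights else dataset$counts
  tot <- rowSums(m)
  if (any(tot == 0))
    warnf("%d records with zero total %s dropped from trophic levels",
          sum(tot == 0), basis)
  m <- m[tot > 0, , drop = FALSE]
  apply(m, 1, fish_trophic_level, prey_tl = prey_tl)
}

#' Per-stratum trophic-level summary
#'
#' Mean, sample sd and quartiles of per-fish trophic levels by
#' location x year stratum, plus a pooled row.
#'
#' @inheritParams trophic_levels
#' @return Data frame of class `trophic_summary` with columns `stratum`,
#'   `n`, `mean`, `sd`, `q25`, `median`, `q75`, `min`, `max`; per-fish
#'   values in attribute `per_fish`.
#' @export
stratum_trophic_summary <- function(dataset, prey_tl = default_prey_tl(),
                                    basis = c("weight", "number")) {
  basis <- match.arg(basis)
  full <- apply_exclusions(dataset, drop_other = FALSE)
  tl <- trophic_levels(full, prey_tl, basis)
  meta <- full$meta[match(names(tl), full$meta$fish_id), ]
  key <- paste(meta$location, meta$year, sep = "_")
  summarize <- function(v, label) {
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(stratum = label, n = length(v), mean = mean(v),
               sd = if (length(v) > 1) stats::sd(v) else 0,
               q25 = q[1], median = q[2], q75 = q[3],
               min = min(v), max = max(v), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, c(
    lapply(unique(key), function(k) summarize(tl[key == k], k)),
    list(summarize(tl, "pooled"))))
  if (any(out$n == 1))
    warnf("stratum with a single fish: sd reported as 0")
  structure(out, class = c("trophic_summary", "data.frame"), per_fish = tl)
}

#' @export
print.trophic_summary <- function(x, ...) {
  cat("Diet-based trophic levels (TL = 1 + sum P_j TL_j)\n")
  disp <- as.data.frame(x)
  num <- vapply(disp, is.numeric, logical(1))
  disp[num] <- lapply(disp[num], round, digits = 2)
  print.data.frame(disp, row.names = FALSE)
  invisible(x)
}
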