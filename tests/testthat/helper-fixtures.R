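# In-code fixtures and independent oracles shared across test files.

# Small diet dataset from a named list of per-fish count vectors.
make_diet <- function(counts, weights = NULL, location = "COR", year = 2013,
                      taxonomy = generalized_taxonomy(), month = 9) {
  cm <- do.call(rbind, counts)
  if (is.null(rownames(cm)))
    rownames(cm) <- sprintf("f%02d", seq_len(nrow(cm)))
  wm <- if (is.null(weights)) cm * 0.1 else do.call(rbind, weights)
  rownames(wm) <- rownames(cm)
  colnames(wm) <- colnames(cm)
  meta <- data.frame(fish_id = rownames(cm),
                     location = rep_len(location, nrow(cm)),
                     year = rep_len(year, nrow(cm)),
                     month = rep_len(month, nrow(cm)),
                     stringsAsFactors = FALSE)
  diet_dataset(cm, wm, meta, taxonomy)
}

# Random generalized-level dataset (zero-inflated counts).
random_diet <- function(n = 12, seed = 1, p_zero = 0.5) {
  codes <- c("CEPH", "CRUS", "AMPH", "EUPH", "TUNI", "TELE", "ROCK", "OTHR")
  set.seed(seed)
  cm <- matrix(rpois(n * 8, 3) * (runif(n * 8) > p_zero), n, 8,
               dimnames = list(sprintf("f%02d", 1:n), codes))
  cm[rowSums(cm) == 0, "EUPH"] <- 1  # keep every stomach full
  storage.mode(cm) <- "integer"
  wm <- cm * matrix(rlnorm(n * 8, -1, 0.5), n, 8)
  meta <- data.frame(fish_id = rownames(cm), location = "COR", year = 2013,
                     month = 9, stringsAsFactors = FALSE)
  diet_dataset(cm, wm, meta)
}

# --- independent oracles --------------------------------------------------

# Convex-hull area by fan triangulation around the hull-vertex centroid
# (independent of the shoelace formula used by the package).
fan_triangulation_area <- function(pts) {
  pts <- as.matrix(pts)
  if (nrow(unique(pts)) < 3) return(0)
  v <- pts[grDevices::chull(pts), , drop = FALSE]
  ctr <- colMeans(v)
  n <- nrow(v)
  a <- 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1 else i + 1
    a <- a + abs((v[i, 1] - ctr[1]) * (v[j, 2] - ctr[2]) -
                   (v[j, 1] - ctr[1]) * (v[i, 2] - ctr[2])) / 2
  }
  a
}

# O(n^2) brute-force centroid distance and nearest-neighbour statistics.
brute_force_cd <- function(pts) {
  pts <- as.matrix(pts)
  mean(sqrt((pts[, 1] - mean(pts[, 1]))^2 + (pts[, 2] - mean(pts[, 2]))^2))
}
brute_force_nnd <- function(pts) {
  pts <- as.matrix(pts)
  n <- nrow(pts)
  vapply(seq_len(n), function(i) {
    min(sqrt((pts[i, 1] - pts[-i, 1])^2 + (pts[i, 2] - pts[-i, 2])^2))
  }, numeric(1))
}

# Classical one-way ANOVA F, used as the Euclidean pseudo-F oracle.
anova_f <- function(y, g) {
  anova(stats::lm(y ~ g))[["F value"]][1]
}
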