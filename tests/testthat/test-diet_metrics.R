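test_that("per-stomach proportions sum to 100 and match hand values", {
  zero <- stats::setNames(rep(0, 8), colnames(random_diet(2)$counts))
  ab <- zero; ab["EUPH"] <- 1; ab["TUNI"] <- 3
  solo <- zero; solo["TELE"] <- 7
  d <- make_diet(list(a = ab, b = solo))
  p <- per_stomach_proportions(d, "number")
  expect_equal(p["a", "EUPH"], 25)
  expect_equal(p["a", "TUNI"], 75)
  expect_equal(p["b", "TELE"], 100)
  # random matrices: row sums exactly 100
  for (s in 1:4) {
    r <- random_diet(n = 5, seed = s)
    expect_equal(unname(rowSums(per_stomach_proportions(r, "number"))),
                 rep(100, 5), tolerance = 1e-9)
    expect_equal(unname(rowSums(per_stomach_proportions(r, "weight"))),
                 rep(100, 5), tolerance = 1e-9)
  }
})

test_that("frequency of occurrence counts stomachs containing each prey", {
  zero <- stats::setNames(rep(0, 8), colnames(random_diet(2)$counts))
  a <- zero; a["EUPH"] <- 1
  b <- zero; b["EUPH"] <- 2; b["TUNI"] <- 1
  d <- make_diet(list(a = a, b = b))
  fo <- frequency_of_occurrence(d)
  expect_equal(fo[["EUPH"]], 100)
  expect_equal(fo[["TUNI"]], 50)
  expect_equal(fo[["ROCK"]], 0)
  # weight-only occurrence still counts
  d$weights["a", "CEPH"] <- 0.2
  expect_equal(frequency_of_occurrence(d)[["CEPH"]], 50)
})

test_that("prey-specific abundance averages only over occupied stomachs", {
  zero <- stats::setNames(rep(0, 8), colnames(random_diet(2)$counts))
  half <- zero; half["EUPH"] <- 1; half["TUNI"] <- 1
  full <- zero; full["EUPH"] <- 5
  d <- make_diet(list(a = half, b = full))
  pn <- prey_specific_abundance(d, "number")
  expect_equal(pn[["EUPH"]], 75)   # mean of 50% and 100%
  expect_equal(pn[["TUNI"]], 50)
  solo <- make_diet(list(a = full, b = full))
  expect_equal(prey_specific_abundance(solo, "number")[["EUPH"]], 100)
})

test_that("the two %N computation routes agree and the PSIRI table obeys its invariants", {
  for (s in 1:5) {
    d <- random_diet(n = 15, seed = s)
    tab <- psiri(d)
    expect_equal(sum(tab$pctN), 100, tolerance = 1e-9)
    expect_equal(sum(tab$pctW), 100, tolerance = 1e-9)
    expect_equal(sum(tab$pctPSIRI), 100, tolerance = 1e-9)
    expect_true(all(tab$pctPN >= tab$pctN - 1e-12))
    expect_true(all(tab$pctPW >= tab$pctW - 1e-12))
    expect_true(all(tab$pctFO > 0 & tab$pctFO <= 100))
    # identity routes
    expect_equal(tab$pctN, tab$pctPN * tab$pctFO / 100, tolerance = 1e-9)
    expect_equal(tab$pctW, tab$pctPW * tab$pctFO / 100, tolerance = 1e-9)
    expect_equal(tab$pctPSIRI, (tab$pctN + tab$pctW) / 2, tolerance = 1e-9)
    # descending PSIRI order
    expect_true(all(diff(tab$pctPSIRI) <= 1e-12))
  }
})

test_that("metrics are invariant to record order", {
  d <- random_diet(n = 12, seed = 9)
  perm <- c(5, 1, 12, 3, 7, 9, 2, 11, 4, 10, 6, 8)
  d2 <- diet_dataset(d$counts[perm, ], d$weights[perm, ],
                     d$meta[perm, ], d$taxonomy)
  expect_equal(as.data.frame(psiri(d)), as.data.frame(psiri(d2)),
               tolerance = 1e-12)
})

test_that("single-prey dataset gives %PSIRI of 100 and weight-only data errors", {
  zero <- stats::setNames(rep(0, 8), colnames(random_diet(2)$counts))
  solo <- zero; solo["EUPH"] <- 3
  d <- make_diet(list(a = solo, b = solo))
  tab <- psiri(d)
  expect_equal(nrow(tab), 1)
  expect_equal(tab$pctPSIRI, 100)
  d$counts[] <- 0
  expect_error(psiri(d), "basis-specific")
})

test_that("lowest-level metrics are additive into generalized categories", {
  tax <- lowest_taxonomy()
  low <- tax$code[tax$level == "lowest"]
  set.seed(4)
  cm <- matrix(rpois(10 * length(low), 1), 10, length(low),
               dimnames = list(sprintf("f%d", 1:10), low))
  cm[rowSums(cm) == 0, 1] <- 1
  wm <- cm * matrix(rlnorm(length(cm), -1, 0.4), nrow(cm))
  d <- diet_dataset(cm, wm,
                    data.frame(fish_id = rownames(cm), location = "COR",
                               year = 2013), tax)
  t_low <- psiri(d)
  t_gen <- psiri(aggregate_to_generalized(d))
  rep <- additivity_check(t_low, t_gen, tax)
  expect_true(attr(rep, "ok"))
  # brute-force recomputation of one group's sums
  tuni_members <- intersect(c("SALP", "PYRO", "THET"), t_low$category)
  expect_equal(sum(t_low$pctN[t_low$category %in% tuni_members]),
               t_gen$pctN[t_gen$category == "TUNI"], tolerance = 1e-9)
})

test_that("display rounding is half away from zero", {
  expect_equal(round_half_up(c(0.05, 0.15, -0.05, 2.25), 1),
               c(0.1, 0.2, -0.1, 2.3))
  expect_equal(round_half_up(57.97, 1), 58.0)
  expect_equal(round_half_up(100 * 77 / 125, 1), 61.6)
})

test_that("component reconstruction helpers apply the index identities", {
  expect_equal(pct_mean_from_components(50, 50), 25)
  expect_equal(psiri_from_components(100, 100, 100), 100)
  expect_equal(psiri_from_components(40, 60, 50, digits = NULL), 25)
})
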