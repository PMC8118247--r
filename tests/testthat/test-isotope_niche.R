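square <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))

test_that("lipid screen excludes strictly above the C:N threshold", {
  rec <- data.frame(fish_id = 1:4, d13C = -17, d15N = 14,
                    cn_ratio = c(3.1, 3.5, 3.8, 3.51),
                    location = "COR", year = 2013)
  kept <- lipid_filter(rec)
  expect_equal(kept$cn_ratio, c(3.1, 3.5))  # 3.5 retained, > 3.5 removed
  expect_equal(unname(attr(kept, "exclusions")[["COR_2013"]]), 2)
  expect_equal(nrow(lipid_filter(rec[0, ])), 0)
  rec$cn_ratio[1] <- NA
  expect_warning(k2 <- lipid_filter(rec), "without C:N")
  expect_equal(nrow(k2), 2)
  k3 <- lipid_filter(rec, strict = TRUE)
  expect_equal(k3$fish_id, 2)
})

test_that("convex hull area matches analytic shapes and a triangulation oracle", {
  expect_equal(convex_hull_area(square), 1)
  expect_equal(convex_hull_area(rbind(c(0, 0), c(2, 0), c(0, 2))), 2)
  expect_equal(convex_hull_area(square[1:2, ]), 0)          # n < 3
  expect_equal(convex_hull_area(cbind(0:4, 0:4)), 0)        # collinear
  set.seed(40)
  for (i in 1:25) {
    pts <- cbind(rnorm(50), rnorm(50))
    expect_equal(convex_hull_area(pts), fan_triangulation_area(pts),
                 tolerance = 1e-9)
  }
})

test_that("niche metrics on the unit square match hand geometry", {
  m <- layman_metrics(square)
  expect_equal(m[["CR"]], 1)
  expect_equal(m[["NR"]], 1)
  expect_equal(m[["TA"]], 1)
  expect_equal(m[["CD"]], sqrt(0.5))
  expect_equal(m[["MNND"]], 1)
  expect_equal(m[["SDNND"]], 0)
  dup <- rbind(c(2, 3), c(2, 3))
  m2 <- layman_metrics(dup)
  expect_equal(unname(m2[c("CR", "NR", "TA", "CD", "MNND", "SDNND")]),
               rep(0, 6))
  expect_error(layman_metrics(square[1, , drop = FALSE]), "at least 2")
})

test_that("metrics transform correctly under translation and scaling", {
  set.seed(9)
  pts <- cbind(rnorm(20, -17, 0.5), rnorm(20, 14, 0.4))
  m <- layman_metrics(pts)
  mt <- layman_metrics(sweep(pts, 2, c(3, -2), `+`))
  expect_equal(unname(mt), unname(m), tolerance = 1e-9)
  ms <- layman_metrics(pts * 2)
  for (k in c("CR", "NR", "CD", "MNND", "SDNND"))
    expect_equal(ms[[k]], 2 * m[[k]], tolerance = 1e-9)
  expect_equal(ms[["TA"]], 4 * m[["TA"]], tolerance = 1e-9)
  expect_lte(m[["TA"]], m[["CR"]] * m[["NR"]])
})

test_that("CD and nearest-neighbour statistics match brute force", {
  set.seed(18)
  for (i in 1:5) {
    pts <- cbind(rnorm(30), rnorm(30))
    m <- layman_metrics(pts)
    nnd <- brute_force_nnd(pts)
    expect_equal(m[["CD"]], brute_force_cd(pts), tolerance = 1e-12)
    expect_equal(m[["MNND"]], mean(nnd), tolerance = 1e-12)
    expect_equal(m[["SDNND"]], sd(nnd), tolerance = 1e-12)
  }
})

test_that("the group table handles duplicates, small groups and recovers spread ordering", {
  set.seed(7)
  base <- data.frame(d13C = rnorm(20, -17, 0.3), d15N = rnorm(20, 14, 0.3))
  rec <- rbind(data.frame(base, location = "A", year = 2013),
               data.frame(base, location = "B", year = 2013))
  tab <- group_enc_table(rec)
  expect_equal(unlist(tab[1, -1]), unlist(tab[2, -1]), tolerance = 1e-12)
  # n < 3 gives TA = NA but other metrics
  rec2 <- data.frame(d13C = c(0, 1), d15N = c(0, 2), location = "C",
                     year = 2014)
  t2 <- group_enc_table(rec2)
  expect_true(is.na(t2$TA))
  expect_equal(t2$CR, 1)
  # ranges grow with simulated sd (in expectation; large-n single seed)
  tight <- data.frame(d13C = rnorm(200, 0, 0.2), d15N = rnorm(200, 0, 0.2),
                      location = "T", year = 1)
  wide <- data.frame(d13C = rnorm(200, 0, 0.8), d15N = rnorm(200, 0, 0.8),
                     location = "W", year = 1)
  t3 <- group_enc_table(rbind(tight, wide))
  expect_lt(t3$CR[t3$group == "T_1"], t3$CR[t3$group == "W_1"])
  expect_lt(t3$NR[t3$group == "T_1"], t3$NR[t3$group == "W_1"])
})
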