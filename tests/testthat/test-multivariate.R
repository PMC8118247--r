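test_that("Bray-Curtis matches hand values and the vegan implementation", {
  x <- rbind(c(100, 0), c(0, 100), c(75, 25), c(25, 75), c(75, 25))
  d <- as.matrix(bray_curtis(x))
  expect_equal(d[1, 2], 1)
  expect_equal(d[3, 4], 0.5)
  expect_equal(d[3, 5], 0)
  expect_true(all(d >= 0 & d <= 1))
  set.seed(8)
  y <- matrix(rpois(60, 4) + 1, 12, 5)
  expect_equal(as.vector(bray_curtis(y)),
               as.vector(vegan::vegdist(y, "bray")), tolerance = 1e-12)
  y0 <- rbind(y, 0)
  expect_error(bray_curtis(y0), "all-zero")
})

test_that("covariate screen drops duplicates and keeps independent variables", {
  set.seed(21)
  dat <- data.frame(a = rnorm(100))
  dat$b <- dat$a                     # exact copy
  dat$c <- rnorm(100)                # independent
  scr <- covariate_screen(dat, c("a", "b", "c"))
  expect_setequal(scr$retained, c("a", "c"))
  expect_equal(scr$dropped, "b")
  expect_true(any(grepl("drop b", scr$report$action)))
  dat$k <- 1
  expect_warning(scr2 <- covariate_screen(dat, c("a", "k")), "constant")
  expect_equal(scr2$retained, "a")
})

test_that("permanova reproduces adonis2 term statistics exactly", {
  set.seed(3)
  y <- matrix(rpois(26 * 6, 5) + 1, 26, 6)
  comp <- 100 * y / rowSums(y)
  d <- bray_curtis(comp)
  dat <- data.frame(g = factor(rep(1:2, 13)), z = rnorm(26), w = runif(26))
  fit <- permanova(d, dat, c("g", "z", "w"), permutations = 99, seed = 4)
  ref <- vegan::adonis2(d ~ g + z + w, data = dat, permutations = 99,
                        by = "terms")
  expect_equal(fit$table$SS, ref$SumOfSqs[1:3], tolerance = 1e-10)
  expect_equal(fit$table$F, ref$F[1:3], tolerance = 1e-10)
  expect_equal(fit$table$r2, ref$R2[1:3], tolerance = 1e-10)
  expect_equal(fit$table$df, ref$Df[1:3])
  # r2 partition sums to one
  expect_equal(sum(fit$table$r2) + fit$residual$r2, 1, tolerance = 1e-9)
  # reproducible given seed, bounded below by 1/(m+1)
  fit2 <- permanova(d, dat, c("g", "z", "w"), permutations = 99, seed = 4)
  expect_identical(fit$table$p, fit2$table$p)
  expect_true(all(fit$table$p >= 1 / 100))
})

test_that("with Euclidean distance and one factor the pseudo-F is the ANOVA F", {
  set.seed(10)
  y <- rnorm(18)
  g <- factor(rep(letters[1:3], 6))
  fit <- permanova(dist(y), data.frame(g = g), "g", permutations = 49,
                   seed = 1)
  expect_equal(fit$table$F, anova_f(y, g), tolerance = 1e-9)
  # relabeling factor levels changes nothing
  g2 <- factor(g, levels = c("c", "a", "b"), labels = c("Z", "A", "B"))
  fit2 <- permanova(dist(y), data.frame(g = g2), "g", permutations = 49,
                    seed = 1)
  expect_equal(fit2$table$F, fit$table$F, tolerance = 1e-12)
})

test_that("exhaustive permutation p matches brute-force enumeration at n = 6", {
  set.seed(2)
  y <- rnorm(6)
  g <- factor(c("a", "a", "a", "b", "b", "b"))
  fit <- permanova(dist(y), data.frame(g = g), "g",
                   permutations = "exhaustive")
  # oracle: classical ANOVA F over all 720 orderings of the responses
  perms <- as.matrix(expand.grid(rep(list(1:6), 6)))
  perms <- perms[apply(perms, 1, function(r) length(unique(r)) == 6), ]
  f_obs <- anova_f(y, g)
  f_all <- apply(perms, 1, function(p) anova_f(y[p], g))
  expect_equal(nrow(perms), 720)
  expect_equal(fit$table$p, mean(f_all >= f_obs - 1e-12), tolerance = 1e-12)
})

test_that("aliased and rank-deficient designs are rejected with names", {
  set.seed(5)
  y <- rnorm(10)
  dat <- data.frame(g = factor(rep(1:2, 5)))
  dat$h <- dat$g
  expect_error(permanova(dist(y), dat, c("g", "h"), permutations = 9,
                         seed = 1), "aliased")
})

test_that("forward selection plants, skips aliases, and stops without signal", {
  set.seed(31)
  n <- 60
  g <- factor(rep(1:3, each = n / 3))
  comp <- t(sapply(as.integer(g), function(k) {
    alpha <- c(2, 2, 2); alpha[k] <- 10
    p <- rgamma(3, alpha); 100 * p / sum(p)
  }))
  d <- bray_curtis(comp)
  dat <- data.frame(g = g, noise1 = rnorm(n), noise2 = runif(n))
  fs <- forward_select(d, dat, c("g", "noise1", "noise2"),
                       permutations = 99, seed = 7)
  expect_equal(fs$selected[1], "g")
  # an alias of an included term contributes zero marginal SS: never added
  dat$g2 <- dat$g
  fs2 <- forward_select(d, dat, c("g", "g2"), permutations = 99, seed = 7)
  expect_false("g2" %in% fs2$selected)
  # pure noise: usually empty model
  dnull <- bray_curtis(matrix(100 / 3, n, 3) +
                         abs(matrix(rnorm(n * 3, 0, 1), n, 3)))
  fs3 <- forward_select(dnull, dat["noise1"], "noise1",
                        permutations = 99, seed = 8)
  expect_true(length(fs3$selected) <= 1)  # entry is rare under the null
})

test_that("permdisp recovers geometry and flags degenerate groups", {
  # Euclidean 2-D input: distances to centroid match direct computation
  set.seed(12)
  pts <- cbind(rnorm(20), rnorm(20))
  g <- factor(rep(1:2, each = 10))
  pd <- permdisp(dist(pts), g, permutations = 99, seed = 2)
  direct <- sapply(1:20, function(i) {
    ctr <- colMeans(pts[g == g[i], ])
    sqrt(sum((pts[i, ] - ctr)^2))
  })
  expect_equal(unname(pd$distances), direct, tolerance = 1e-9)
  # translation invariance
  pd2 <- permdisp(dist(pts + 5), g, permutations = 99, seed = 2)
  expect_equal(pd2$F, pd$F, tolerance = 1e-9)
  # a collapsed group has dispersion 0 and a large F
  pts2 <- rbind(matrix(rnorm(20, sd = 2), 10, 2),
                matrix(1, 10, 2))
  pd3 <- permdisp(dist(pts2), g, permutations = 99, seed = 3)
  expect_equal(unname(pd3$group_means[["2"]]), 0, tolerance = 1e-9)
  expect_gt(pd3$F, 10)
  # size-one groups are excluded with a warning
  g4 <- factor(c(rep(1, 10), rep(2, 9), 3))
  expect_warning(permdisp(dist(pts2), g4, permutations = 9, seed = 1),
                 "size < 2")
})

test_that("CAP matches capscale on Euclidean data and finds the discriminant axis", {
  set.seed(5)
  Y <- matrix(rnorm(30 * 4), 30, 4)
  dat <- data.frame(g = factor(rep(1:3, each = 10)), z = rnorm(30))
  de <- dist(Y)
  cp <- suppressMessages(cap(de, dat, c("g", "z"), permutations = 49,
                             seed = 1))
  cs <- vegan::capscale(de ~ g + z, data = dat)
  expect_equal(cp$pct_var, unname(100 * cs$CCA$eig / cs$tot.chi),
               tolerance = 1e-8)
  # eigenvalues non-increasing; axis percents sum to the model's share
  expect_true(all(diff(cp$eigenvalues) <= 1e-12))
  expect_equal(sum(cp$axes$pct_var), cp$pct_explained, tolerance = 1e-9)
  # two-group case: CAP1 is the group-mean discriminant direction
  g2 <- factor(rep(1:2, each = 15))
  cp2 <- suppressMessages(cap(dist(Y), data.frame(g = g2), "g",
                              permutations = 49, seed = 1))
  mdiff <- colMeans(Y[g2 == 2, , drop = FALSE]) -
    colMeans(Y[g2 == 1, , drop = FALSE])
  expect_equal(as.numeric(abs(cor(cp2$site_scores[, 1], Y %*% mdiff))), 1,
               tolerance = 1e-9)
  expect_error(cap(dist(Y[1:3, ]), data.frame(z = rnorm(3), w = rnorm(3),
                                              u = rnorm(3), v = rnorm(3)),
                   permutations = 9, seed = 1),
               "design")
})

test_that("a between-year diet shift yields a significant Year term and opposed CAP loadings", {
  cfg <- scenario("heatwave_shift")
  d <- simulate_diet_dataset(cfg, n_per_stratum = c(30, 30, 30, 30, 30),
                             seed = 19)
  mv <- apply_exclusions(d, drop_other = TRUE)
  comp <- per_stomach_proportions(mv, "number")
  dmat <- bray_curtis(comp)
  des <- data.frame(Year = factor(mv$meta$year))
  fit <- permanova(dmat, des, "Year", permutations = 199, seed = 5)
  expect_lt(fit$table$p, 0.05)
  cp <- suppressMessages(cap(dmat, des, "Year", permutations = 49, seed = 5,
                             composition = comp))
  expect_lt(cp$species_scores["TUNI", 1] * cp$species_scores["EUPH", 1], 0)
})
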