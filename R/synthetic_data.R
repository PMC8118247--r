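# Synthetic stomach-content and isotope datasets with the statistical
# structure the analyses assume: multi-site, multi-year sampling with
# empty stomachs, zero-inflated prey counts over the 8 generalized
# categories (per-stomach compositions drawn from low-concentration
# Dirichlets, so individual diets are dominated by one prey group),
# per-item lognormal weights with category-specific medians (so numeric
# and gravimetric metrics can disagree), location-structured covariates,
# and bivariate-normal isotope groups with a C:N lipid-proxy distribution.

prey_codes <- function() c("CEPH", "CRUS", "AMPH", "EUPH",
                           "TUNI", "TELE", "ROCK", "OTHR")

# Per-item weight medians (g) by category; rockfish/teleost items are heavy
# so %PW can greatly exceed %PN for rarely-but-heavily eaten prey.
default_weight_medians <- function() {
  c(CEPH = 4, CRUS = 0.15, AMPH = 0.02, EUPH = 0.1,
    TUNI = 0.5, TELE = 5, ROCK = 8, OTHR = 0.1)
}

study_strata <- function() {
  data.frame(
    stratum = c("COR_2013", "FAR_2013", "COR_2014", "FAR_2014", "HMB_2014"),
    location = c("COR", "FAR", "COR", "FAR", "HMB"),
    year = c(2013L, 2013L, 2014L, 2014L, 2014L),
    n = c(40L, 56L, 104L, 125L, 108L),
    p_empty = c(0.175, 0.268, 0.731, 0.384, 0.333),
    count_mean = c(48, 209, 3, 7, 15),
    count_size = 0.6,
    length_mean = c(40.6, 31.4, 40.7, 30.5, 30.4),
    length_sd = c(3.8, 3.0, 4.4, 2.5, 4.7),
    longitude_mean = c(-123.42, -123.00, -123.42, -123.00, -122.45),
    longitude_sd = 0.03,
    depth_mean = c(95, 75, 95, 75, 55),
    depth_sd = c(25, 18, 25, 18, 12),
    stringsAsFactors = FALSE)
}

study_diet_means <- function() {
  m <- rbind(
    COR_2013 = c(CEPH = 0.02, CRUS = 0.06, AMPH = 0.01, EUPH = 0.33,
                 TUNI = 0.25, TELE = 0.19, ROCK = 0.13, OTHR = 0.01),
    FAR_2013 = c(CEPH = 0.02, CRUS = 0.13, AMPH = 0.005, EUPH = 0.15,
                 TUNI = 0.68, TELE = 0.005, ROCK = 0.005, OTHR = 0.005),
    COR_2014 = c(CEPH = 0.16, CRUS = 0.04, AMPH = 0.15, EUPH = 0.13,
                 TUNI = 0.26, TELE = 0.22, ROCK = 0.005, OTHR = 0.035),
    FAR_2014 = c(CEPH = 0.013, CRUS = 0.44, AMPH = 0.06, EUPH = 0.05,
                 TUNI = 0.26, TELE = 0.04, ROCK = 0.13, OTHR = 0.007),
    HMB_2014 = c(CEPH = 0.06, CRUS = 0.055, AMPH = 0.005, EUPH = 0.05,
                 TUNI = 0.54, TELE = 0.25, ROCK = 0.003, OTHR = 0.042))
  m / rowSums(m)
}

study_isotope_groups <- function() {
  data.frame(
    location = c("COR", "FAR", "COR", "FAR", "HMB"),
    year = c(2013L, 2013L, 2014L, 2014L, 2014L),
    n = c(33L, 33L, 31L, 33L, 31L),
    mu13 = c(-18.4, -18.0, -17.4, -17.2, -16.8),
    mu15 = c(13.6, 13.4, 14.8, 14.9, 14.4),
    sd13 = c(0.40, 0.30, 0.40, 0.38, 0.32),
    sd15 = c(0.30, 0.22, 0.45, 0.46, 0.25),
    rho = 0.2,
    stringsAsFactors = FALSE)
}

#' Simulation configuration scenarios
#'
#' Fully specified configurations for the synthetic-data generator:
#' \describe{
#'   \item{`study`}{Emulates the motivating field study: five location x
#'     year strata with sample sizes 40/56/104/125/108, empty-stomach
#'     probabilities 0.175/0.268/0.731/0.384/0.333, stratum-specific mean
#'     diet compositions, item counts with 2013 >> 2014 means, and five
#'     isotope groups with 2014 signatures less negative than 2013.}
#'   \item{`null`}{All strata share identical diet and isotope parameters
#'     (for type-I-error simulations).}
#'   \item{`planted_location_effect`}{Three locations whose mean diet
#'     compositions differ strongly (euphausiid- / crustacean- /
#'     teleost-dominated), other covariates independent of diet (for power
#'     simulations of the location term).}
#'   \item{`heatwave_shift`}{Identical locations but a between-year shift
#'     from a euphausiid/salp-rich spectrum (2013) to a pyrosome-heavy
#'     tunicate and teleost spectrum (2014).}
#' }
#'
#' @param name scenario name.
#' @return A `sim_config` list: `strata`, `diet_means`, `concentration`,
#'   `weight_medians`, `weight_sdlog`, `isotope`, `cn`.
#' @export
scenario <- function(name = c("study", "null", "planted_location_effect",
                              "heatwave_shift")) {
  name <- match.arg(name)
  cfg <- list(strata = study_strata(), diet_means = study_diet_means(),
              concentration = 1.5,
              weight_medians = default_weight_medians(),
              weight_sdlog = 0.7,
              isotope = study_isotope_groups(),
              cn = list(mean = 3.3, sd = 0.15, min = 3.0, max = 3.9),
              scenario = name)
  flat <- colMeans(study_diet_means())
  flat <- flat / sum(flat)
  if (name == "null") {
    cfg$diet_means[] <- rep(flat, each = nrow(cfg$diet_means))
    cfg$strata$p_empty <- 0.3
    cfg$strata$count_mean <- 25
    cfg$isotope$mu13 <- -17.5; cfg$isotope$mu15 <- 14.2
    cfg$isotope$sd13 <- 0.35; cfg$isotope$sd15 <- 0.35
  } else if (name == "planted_location_effect") {
    base <- flat
    boost <- function(codes, f) {
      v <- base; v[codes] <- v[codes] * f; v / sum(v)
    }
    cfg$diet_means["COR_2013", ] <- boost("EUPH", 6)
    cfg$diet_means["COR_2014", ] <- boost("EUPH", 6)
    cfg$diet_means["FAR_2013", ] <- boost("CRUS", 6)
    cfg$diet_means["FAR_2014", ] <- boost("CRUS", 6)
    cfg$diet_means["HMB_2014", ] <- boost("TELE", 6)
    cfg$strata$p_empty <- 0.2
    cfg$strata$count_mean <- 25
  } else if (name == "heatwave_shift") {
    y13 <- c(CEPH = 0.02, CRUS = 0.08, AMPH = 0.02, EUPH = 0.40,
             TUNI = 0.33, TELE = 0.05, ROCK = 0.09, OTHR = 0.01)
    y14 <- c(CEPH = 0.05, CRUS = 0.08, AMPH = 0.05, EUPH = 0.08,
             TUNI = 0.52, TELE = 0.18, ROCK = 0.03, OTHR = 0.01)
    for (s in rownames(cfg$diet_means)) {
      yr <- cfg$strata$year[cfg$strata$stratum == s]
      cfg$diet_means[s, ] <- if (yr == 2013) y13 / sum(y13) else y14 / sum(y14)
    }
    cfg$strata$p_empty <- 0.3
    cfg$strata$count_mean <- 25
  }
  structure(cfg, class = "sim_config")
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha)
  if (sum(g) == 0) g[which.max(alpha)] <- 1
  g / sum(g)
}

rnbinom_pos <- function(mu, size) {
  repeat {
    x <- stats::rnbinom(1, mu = mu, size = size)
    if (x >= 1) return(x)
  }
}

#' Simulate a multi-stratum diet dataset
#'
#' One record per fish: the stomach is empty with the stratum's probability;
#' otherwise the total item count is negative-binomial (truncated at 1),
#' items are assigned multinomially to categories from a per-stomach
#' Dirichlet-drawn composition, and per-item weights are lognormal with
#' category-specific medians, summed per category and recorded at 0.001 g.
#' Covariates (month, longitude, depth, length, sex) are attached per
#' stratum. Each fish has its own deterministic RNG sub-stream, so adding
#' fish never perturbs existing ones.
#'
#' @param config a `sim_config` from [scenario()].
#' @param n_per_stratum optional named (or positional) override of the
#'   per-stratum sample sizes.
#' @param seed integer base seed.
#' @return A [diet_dataset()] at the generalized taxonomic level.
#' @export
simulate_diet_dataset <- function(config = scenario("study"),
                                  n_per_stratum = NULL, seed = 1) {
  stopifnot(inherits(config, "sim_config"))
  if (any(config$diet_means <= 0)) stopf("diet means must be positive")
  if (any(config$strata$p_empty < 0 | config$strata$p_empty > 1))
    stopf("empty-stomach probabilities must be in [0, 1]")
  codes <- prey_codes()
  strata <- config$strata
  if (!is.null(n_per_stratum)) {
    if (!is.null(names(n_per_stratum)))
      strata$n[match(names(n_per_stratum), strata$stratum)] <- n_per_stratum
    else strata$n <- rep_len(n_per_stratum, nrow(strata))
  }
  total_n <- sum(strata$n)
  counts <- matrix(0L, total_n, length(codes),
                   dimnames = list(NULL, codes))
  weights <- matrix(0, total_n, length(codes),
                    dimnames = list(NULL, codes))
  meta <- vector("list", total_n)
  row <- 0L
  fish_index <- 0L
  for (s in seq_len(nrow(strata))) {
    st <- strata[s, ]
    alpha <- config$concentration * config$diet_means[st$stratum, ]
    for (i in seq_len(st$n)) {
      row <- row + 1L
      fish_index <- fish_index + 1L
      with_seed(derive_seed(seed, fish_index), {
        if (stats::runif(1) >= st$p_empty) {
          p <- rdirichlet1(alpha)
          m <- rnbinom_pos(st$count_mean, st$count_size)
          item_cat <- sample(codes, m, replace = TRUE, prob = p)
          cnt <- table(factor(item_cat, levels = codes))
          counts[row, ] <- as.integer(cnt)
          for (cat in codes[cnt > 0]) {
            w <- sum(stats::rlnorm(cnt[[cat]],
                                   meanlog = log(config$weight_medians[[cat]]),
                                   sdlog = config$weight_sdlog))
            weights[row, cat] <- max(round(w, 3), 0.001)
          }
        }
        meta[[row]] <- data.frame(
          fish_id = sprintf("F%04d", fish_index),
          location = st$location, year = st$year,
          month = sample(8:10, 1),
          longitude = stats::rnorm(1, st$longitude_mean, st$longitude_sd),
          depth_m = min(max(stats::rnorm(1, st$depth_mean, st$depth_sd),
                            37), 168),
          total_length_cm = round(stats::rnorm(1, st$length_mean,
                                               st$length_sd) * 2) / 2,
          sex = sample(c("M", "F", "indeterminate"), 1,
                       prob = c(0.387, 0.418, 0.195)),
          stringsAsFactors = FALSE)
      })
    }
  }
  meta <- do.call(rbind, meta)
  rownames(counts) <- rownames(weights) <- meta$fish_id
  diet_dataset(counts, weights, meta, generalized_taxonomy())
}

#' Simulate a multi-group isotope dataset
#'
#' Per group, (d13C, d15N) are bivariate normal with the configured means,
#' standard deviations and correlation; the C:N weight ratio is drawn from
#' a truncated normal whose upper tail exceeds the 3.5 lipid-screen
#' threshold, so [lipid_filter()] has work to do. `pctN` and `pctC` are
#' back-filled consistently with the ratio.
#'
#' @inheritParams simulate_diet_dataset
#' @param n_per_group optional override of group sample sizes.
#' @return An `isotope_table` data frame.
#' @export
simulate_isotope_dataset <- function(config = scenario("study"),
                                     n_per_group = NULL, seed = 1) {
  stopifnot(inherits(config, "sim_config"))
  groups <- config$isotope
  if (any(groups$sd13 <= 0 | groups$sd15 <= 0 | abs(groups$rho) >= 1))
    stopf("invalid isotope covariance parameters")
  if (!is.null(n_per_group)) groups$n <- rep_len(n_per_group, nrow(groups))
  rows <- vector("list", sum(groups$n))
  idx <- 0L
  for (g in seq_len(nrow(groups))) {
    gr <- groups[g, ]
    for (i in seq_len(gr$n)) {
      idx <- idx + 1L
      rows[[idx]] <- with_seed(derive_seed(seed + 500000L, idx), {
        z <- stats::rnorm(2)
        d13 <- gr$mu13 + gr$sd13 * z[1]
        d15 <- gr$mu15 + gr$sd15 * (gr$rho * z[1] +
                                      sqrt(1 - gr$rho^2) * z[2])
        repeat {
          cn <- stats::rnorm(1, config$cn$mean, config$cn$sd)
          if (cn >= config$cn$min && cn <= config$cn$max) break
        }
        pctN <- stats::runif(1, 13, 16)
        data.frame(fish_id = sprintf("I%04d", idx),
                   d13C = round(d13, 2), d15N = round(d15, 2),
                   pctC = round(pctN * cn, 2), pctN = round(pctN, 2),
                   cn_ratio = round(cn, 2),
                   location = gr$location, year = gr$year,
                   stringsAsFactors = FALSE)
      })
    }
  }
  structure(do.call(rbind, rows),
            class = c("isotope_table", "data.frame"))
}

#' Simulate and write a complete study to CSV files
#'
#' Emits `counts.csv`, `weights.csv`, `meta.csv` and `isotopes.csv` under
#' `out_prefix`, in the layouts read by [read_stomach_tables()] and
#' [read_isotope_table()].
#'
#' @inheritParams simulate_diet_dataset
#' @param out_prefix directory (created if needed) for the four CSVs.
#' @return Invisibly, a named vector of the file paths.
#' @export
simulate_to_csv <- function(config = scenario("study"), out_prefix, seed = 1) {
  dir.create(out_prefix, recursive = TRUE, showWarnings = FALSE)
  diet <- simulate_diet_dataset(config, seed = seed)
  iso <- simulate_isotope_dataset(config, seed = seed)
  paths <- c(counts = file.path(out_prefix, "counts.csv"),
             weights = file.path(out_prefix, "weights.csv"),
             meta = file.path(out_prefix, "meta.csv"),
             isotopes = file.path(out_prefix, "isotopes.csv"))
  write_stomach_tables(diet, paths["counts"], paths["weights"], paths["meta"])
  write_isotope_table(iso, paths["isotopes"])
  invisible(paths)
}
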