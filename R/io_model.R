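# Data model and CSV I/O for stomach-content and isotope tables.
#
# The on-disk layout mirrors the common supplementary-data convention for
# diet studies: one CSV of prey counts (one row per fish, one column per
# prey category), one CSV of prey weights in grams with the same shape, and
# a metadata CSV joined on fish_id. Weights are recorded to 0.001 g.

#' Generalized prey taxonomy for a pelagic mesopredator diet study
#'
#' The eight generalized prey categories used throughout the package:
#' squids (Cephalopoda), unidentified crustaceans, amphipods, euphausiids,
#' tunicates (salps and pyrosomes), unidentified teleosts, rockfishes
#' (*Sebastes* spp.), and a rare-prey "Other" bin (gastropods, polychaetes,
#' isopods). `trophic_level` holds the unitless prey trophic level used by
#' [fish_trophic_level()]; see [default_prey_tl()] for provenance.
#'
#' @return A data frame with columns `code`, `label`, `level`, `parent`,
#'   `trophic_level`.
#' @seealso [lowest_taxonomy()] for an example lowest-level taxonomy.
#' @export
generalized_taxonomy <- function() {
  data.frame(
    code = c("CEPH", "CRUS", "AMPH", "EUPH", "TUNI", "TELE", "ROCK", "OTHR"),
    label = c("Cephalopoda (squids)", "Unidentified crustaceans", "Amphipoda",
              "Euphausiacea", "Tunicata (salps, pyrosomes)",
              "Unidentified teleosts", "Rockfishes (Sebastes spp.)", "Other"),
    level = "generalized",
    parent = NA_character_,
    trophic_level = unname(default_prey_tl()[
      c("CEPH", "CRUS", "AMPH", "EUPH", "TUNI", "TELE", "ROCK", "OTHR")]),
    stringsAsFactors = FALSE
  )
}

#' Example lowest-level prey taxonomy
#'
#' A lowest-taxonomic-level table whose categories roll up into the eight
#' generalized codes of [generalized_taxonomy()]. Used for testing
#' aggregation and for simulating data identified below the generalized
#' level.
#'
#' @return A data frame in the same layout as [generalized_taxonomy()].
#' @export
lowest_taxonomy <- function() {
  gen <- generalized_taxonomy()
  low <- data.frame(
    code = c("SALP", "PYRO", "THET", "EUPH.L", "HYPE", "VIBI", "CRAN",
             "CRUS.U", "SEBA", "SJOR", "TELE.U", "DORY", "POLY", "ISOP"),
    label = c("Salpidae", "Pyrosoma spp.", "Thetys vagina", "Euphausiacea",
              "Hyperiidea", "Vibilia spp.", "Crangon spp.",
              "Unidentified crustaceans", "Sebastes spp.", "Sebastes jordani",
              "Unidentified fishes", "Doryteuthis opalescens", "Polychaeta",
              "Isopoda"),
    level = "lowest",
    parent = c("TUNI", "TUNI", "TUNI", "EUPH", "AMPH", "AMPH", "CRUS",
               "CRUS", "ROCK", "ROCK", "TELE", "CEPH", "OTHR", "OTHR"),
    trophic_level = NA_real_,
    stringsAsFactors = FALSE
  )
  rbind(gen, low)
}

validate_taxonomy <- function(taxonomy) {
  stopifnot(is.data.frame(taxonomy),
            all(c("code", "level", "parent") %in% names(taxonomy)))
  if (anyDuplicated(taxonomy$code))
    stopf("duplicate prey codes in taxonomy: %s",
          paste(unique(taxonomy$code[duplicated(taxonomy$code)]), collapse = ", "))
  low <- taxonomy[taxonomy$level == "lowest", ]
  orphan <- low$code[is.na(low$parent) | !(low$parent %in% taxonomy$code)]
  if (length(orphan))
    stopf("lowest-level categories without a generalized parent: %s",
          paste(orphan, collapse = ", "))
  tl <- taxonomy$trophic_level
  if (any(!is.na(tl) & tl < 1))
    stopf("prey trophic levels must be >= 1")
  invisible(taxonomy)
}

#' Construct a validated diet dataset
#'
#' Bundles per-stomach prey counts and weights with fish metadata and a prey
#' taxonomy, computes exclusion flags, and validates the invariants shared
#' by all downstream analyses: matched dimensions, non-negative cells, and
#' matched count/weight prey keys.
#'
#' @param counts integer matrix, fish x prey category; rownames are fish ids.
#' @param weights numeric matrix of prey weights (g), same shape as `counts`.
#' @param meta data frame with one row per fish: `fish_id`, `location`,
#'   `year`, and optionally `month`, `longitude`, `depth_m`,
#'   `total_length_cm`, `sex`.
#' @param taxonomy prey taxonomy data frame, default [generalized_taxonomy()].
#' @return An object of class `diet_dataset`: a list with elements `counts`,
#'   `weights`, `meta`, `taxonomy` and `flags` (`empty`, `other_only`,
#'   `other_partial` per record).
#' @export
diet_dataset <- function(counts, weights, meta, taxonomy = generalized_taxonomy()) {
  counts <- as.matrix(counts)
  weights <- as.matrix(weights)
  validate_taxonomy(taxonomy)
  if (!identical(dim(counts), dim(weights)))
    stopf("counts (%d x %d) and weights (%d x %d) differ in shape",
          nrow(counts), ncol(counts), nrow(weights), ncol(weights))
  if (!identical(colnames(counts), colnames(weights)))
    stopf("counts and weights must share the same prey columns")
  if (is.null(rownames(counts))) rownames(counts) <- meta$fish_id
  rownames(weights) <- rownames(counts)
  unknown <- setdiff(colnames(counts), taxonomy$code)
  if (length(unknown))
    stopf("prey columns not in taxonomy: %s", paste(unknown, collapse = ", "))
  if (any(counts < 0) || any(weights < 0)) {
    bad <- which(counts < 0 | weights < 0, arr.ind = TRUE)[1, ]
    stopf("negative count/weight for fish '%s', prey '%s'",
          rownames(counts)[bad[1]], colnames(counts)[bad[2]])
  }
  if (!identical(as.character(meta$fish_id), rownames(counts)))
    stopf("meta$fish_id must match count/weight row order")
  if (any(counts != floor(counts)))
    stopf("prey counts must be whole numbers")
  if (!is.null(meta$depth_m) &&
      any(meta$depth_m < 37 | meta$depth_m > 168, na.rm = TRUE))
    warnf("%d records with depth outside the surveyed 37-168 m range (kept)",
          sum(meta$depth_m < 37 | meta$depth_m > 168, na.rm = TRUE))
  x <- structure(
    list(counts = counts, weights = weights, meta = meta,
         taxonomy = taxonomy, flags = NULL),
    class = "diet_dataset")
  x$flags <- compute_flags(x)
  x
}

compute_flags <- function(x) {
  present <- x$counts > 0 | x$weights > 0
  other_codes <- intersect(c("OTHR",
    x$taxonomy$code[!is.na(x$taxonomy$parent) & x$taxonomy$parent == "OTHR"]),
    colnames(present))
  is_other <- colnames(present) %in% other_codes
  any_prey <- rowSums(present) > 0
  n_other <- rowSums(present[, is_other, drop = FALSE])
  n_else <- rowSums(present[, !is_other, drop = FALSE])
  data.frame(
    fish_id = rownames(x$counts),
    empty = !any_prey,
    other_only = any_prey & n_else == 0 & n_other > 0,
    other_partial = n_else > 0 & n_other > 0,
    stringsAsFactors = FALSE)
}

#' @export
print.diet_dataset <- function(x, ...) {
  cat(sprintf("Diet dataset: %d stomachs x %d prey categories (%s level)\n",
              nrow(x$counts), ncol(x$counts),
              if (all(colnames(x$counts) %in%
                      x$taxonomy$code[x$taxonomy$level == "generalized"]))
                "generalized" else "lowest"))
  cat(sprintf("  full: %d, empty: %d, Other-only: %d, mixed Other: %d\n",
              sum(!x$flags$empty), sum(x$flags$empty),
              sum(x$flags$other_only), sum(x$flags$other_partial)))
  if (!is.null(x$meta$location))
    cat("  strata:",
        paste(names(table(paste(x$meta$location, x$meta$year))), collapse = ", "),
        "\n")
  invisible(x)
}

#' Number of stomachs with identifiable prey
#'
#' @param dataset a `diet_dataset`.
#' @return Integer count of records with at least one nonzero prey.
#' @export
n_full <- function(dataset) sum(!dataset$flags$empty)

#' Per-stratum sample summary
#'
#' Tabulates, for each location x year stratum, the total number of stomachs
#' sampled, the number with identifiable prey ("full"), and the full
#' percentage (rounded half-up to one decimal), plus a pooled totals row.
#'
#' @param dataset a `diet_dataset`.
#' @return Data frame with columns `location`, `year`, `total`, `full`,
#'   `pct_full`.
#' @export
sample_summary <- function(dataset) {
  key <- paste(dataset$meta$location, dataset$meta$year, sep = "_")
  full <- !dataset$flags$empty
  tot <- tapply(full, key, length)
  ful <- tapply(full, key, sum)
  out <- data.frame(
    location = sub("_.*$", "", names(tot)),
    year = as.integer(sub("^.*_", "", names(tot))),
    total = as.integer(tot),
    full = as.integer(ful),
    stringsAsFactors = FALSE)
  out <- rbind(out, data.frame(location = "Totals", year = NA_integer_,
                               total = sum(out$total), full = sum(out$full)))
  out$pct_full <- round_half_up(100 * out$full / out$total, 1)
  rownames(out) <- NULL
  out
}

#' Read per-stomach count, weight and metadata CSVs
#'
#' Reads the three-file layout (counts, weights, metadata, joined on
#' `fish_id`) into a validated [diet_dataset()]. Records present in only one
#' of the prey files are an error; records without metadata are reported.
#' All-zero records are flagged `empty` and retained (they count toward
#' sample totals but are excluded from analyses).
#'
#' @param counts_path,weights_path CSVs with a `fish_id` column plus one
#'   integer/numeric column per prey category.
#' @param metadata_path CSV with per-fish covariates, or `NULL` to build a
#'   minimal metadata table (location/year `NA`).
#' @param taxonomy prey taxonomy; defaults to [generalized_taxonomy()].
#' @return A `diet_dataset`.
#' @export
read_stomach_tables <- function(counts_path, weights_path,
                                metadata_path = NULL,
                                taxonomy = generalized_taxonomy()) {
  cn <- utils::read.csv(counts_path, check.names = FALSE,
                        stringsAsFactors = FALSE)
  wt <- utils::read.csv(weights_path, check.names = FALSE,
                        stringsAsFactors = FALSE)
  for (nm in c("counts", "weights")) {
    tab <- if (nm == "counts") cn else wt
    if (!"fish_id" %in% names(tab))
      stopf("%s file '%s' has no fish_id column", nm,
            if (nm == "counts") counts_path else weights_path)
  }
  if (!setequal(cn$fish_id, wt$fish_id)) {
    miss <- c(setdiff(cn$fish_id, wt$fish_id), setdiff(wt$fish_id, cn$fish_id))
    stopf("fish_ids not shared between count and weight files: %s",
          paste(utils::head(miss, 5), collapse = ", "))
  }
  wt <- wt[match(cn$fish_id, wt$fish_id), ]
  prey <- setdiff(names(cn), "fish_id")
  if (!setequal(prey, setdiff(names(wt), "fish_id")))
    stopf("count and weight files list different prey columns")
  counts <- as.matrix(cn[, prey, drop = FALSE])
  weights <- as.matrix(wt[, prey, drop = FALSE])
  for (m in list(counts, weights)) {
    if (any(is.na(m)))
      stopf("non-numeric or missing cell in prey table (row %d)",
            which(rowSums(is.na(m)) > 0)[1])
  }
  if (any(counts < 0) || any(weights < 0))
    stopf("negative count/weight in row %d",
          which(rowSums(counts < 0 | weights < 0) > 0)[1])
  rownames(counts) <- rownames(weights) <- as.character(cn$fish_id)
  if (is.null(metadata_path)) {
    meta <- data.frame(fish_id = as.character(cn$fish_id),
                       location = NA_character_, year = NA_integer_,
                       stringsAsFactors = FALSE)
  } else {
    meta <- utils::read.csv(metadata_path, stringsAsFactors = FALSE)
    if (!"fish_id" %in% names(meta))
      stopf("metadata file '%s' has no fish_id column", metadata_path)
    meta$fish_id <- as.character(meta$fish_id)
    unmatched <- setdiff(rownames(counts), meta$fish_id)
    if (length(unmatched)) {
      message(sprintf("%d fish without metadata rows: %s", length(unmatched),
                      paste(utils::head(unmatched, 5), collapse = ", ")))
      meta <- rbind(meta,
                    data.frame(fish_id = unmatched,
                               meta[rep(NA_integer_, length(unmatched)),
                                    setdiff(names(meta), "fish_id"),
                                    drop = FALSE],
                               row.names = NULL))
    }
    meta <- meta[match(rownames(counts), meta$fish_id), ]
    rownames(meta) <- NULL
  }
  diet_dataset(counts, weights, meta, taxonomy)
}

#' Write a diet dataset back to the three-CSV layout
#'
#' Inverse of [read_stomach_tables()]; weights are written at 0.001 g
#' resolution (the measurement accuracy of the data model).
#'
#' @param dataset a `diet_dataset`.
#' @param counts_path,weights_path,metadata_path output CSV paths;
#'   `metadata_path` may be `NULL` to skip.
#' @return Invisibly, the paths written.
#' @export
write_stomach_tables <- function(dataset, counts_path, weights_path,
                                 metadata_path = NULL) {
  cn <- data.frame(fish_id = rownames(dataset$counts), dataset$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  wt <- data.frame(fish_id = rownames(dataset$weights),
                   round(dataset$weights, 3),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(cn, counts_path, row.names = FALSE)
  utils::write.csv(wt, weights_path, row.names = FALSE)
  if (!is.null(metadata_path))
    utils::write.csv(dataset$meta, metadata_path, row.names = FALSE)
  invisible(c(counts_path, weights_path, metadata_path))
}

#' Aggregate a lowest-level dataset to generalized prey categories
#'
#' Sums counts and weights of lowest-level columns into their generalized
#' parents. Per-record totals are conserved exactly; a dataset already at
#' the generalized level is returned unchanged.
#'
#' @param dataset a `diet_dataset`.
#' @return A `diet_dataset` whose prey columns are generalized codes.
#' @export
aggregate_to_generalized <- function(dataset) {
  tax <- dataset$taxonomy
  lev <- tax$level[match(colnames(dataset$counts), tax$code)]
  if (all(lev == "generalized")) return(dataset)
  parent <- ifelse(lev == "generalized", colnames(dataset$counts),
                   tax$parent[match(colnames(dataset$counts), tax$code)])
  if (any(is.na(parent)))
    stopf("no generalized parent for: %s",
          paste(colnames(dataset$counts)[is.na(parent)], collapse = ", "))
  gen <- tax[tax$level == "generalized", ]
  agg <- function(m) {
    out <- matrix(0, nrow(m), nrow(gen),
                  dimnames = list(rownames(m), gen$code))
    for (j in seq_len(ncol(m))) out[, parent[j]] <- out[, parent[j]] + m[, j]
    out
  }
  diet_dataset(agg(dataset$counts), agg(dataset$weights), dataset$meta, gen)
}

#' Apply analysis exclusions
#'
#' Produces the analysis view of a dataset: empty stomachs are always
#' removed; with `drop_other = TRUE`, records containing exclusively Other
#' prey are removed and mixed records have their Other contributions zeroed
#' before proportions are recalculated downstream. Idempotent.
#'
#' @param dataset a `diet_dataset`.
#' @param drop_other remove/zero the rare-prey "Other" bin (default `TRUE`,
#'   as for multivariate analyses of the generalized categories).
#' @return A filtered `diet_dataset`.
#' @export
apply_exclusions <- function(dataset, drop_other = TRUE) {
  keep <- !dataset$flags$empty
  counts <- dataset$counts
  weights <- dataset$weights
  if (drop_other) {
    other_codes <- intersect(
      c("OTHR", dataset$taxonomy$code[!is.na(dataset$taxonomy$parent) &
                                        dataset$taxonomy$parent == "OTHR"]),
      colnames(counts))
    keep <- keep & !dataset$flags$other_only
    counts[, other_codes] <- 0
    weights[, other_codes] <- 0
  }
  if (!any(keep)) warnf("all records excluded")
  diet_dataset(counts[keep, , drop = FALSE], weights[keep, , drop = FALSE],
               dataset$meta[keep, , drop = FALSE], dataset$taxonomy)
}

#' Subset a diet dataset to one stratum
#'
#' @param dataset a `diet_dataset`.
#' @param location,year stratum key; `NULL` means no restriction.
#' @return A `diet_dataset` restricted to matching records.
#' @export
subset_stratum <- function(dataset, location = NULL, year = NULL) {
  keep <- rep(TRUE, nrow(dataset$counts))
  if (!is.null(location)) keep <- keep & dataset$meta$location %in% location
  if (!is.null(year)) keep <- keep & dataset$meta$year %in% year
  diet_dataset(dataset$counts[keep, , drop = FALSE],
               dataset$weights[keep, , drop = FALSE],
               dataset$meta[keep, , drop = FALSE], dataset$taxonomy)
}

#' Read a per-fish stable isotope CSV
#'
#' Expects columns `fish_id`, `d13C`, `d15N` (per mil), optionally `pctC`,
#' `pctN`, `cn_ratio`, `location`, `year`. When `cn_ratio` is missing but
#' `pctC`/`pctN` are present it is derived as their ratio; when both are
#' present their consistency is checked to 2%.
#'
#' @param path CSV path.
#' @return Data frame of isotope records (class `isotope_table`).
#' @export
read_isotope_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(tab) == 0) {
    warnf("isotope file '%s' has no rows", path)
    return(structure(tab, class = c("isotope_table", "data.frame")))
  }
  for (col in c("d13C", "d15N")) {
    if (!col %in% names(tab)) stopf("isotope file lacks column '%s'", col)
    v <- suppressWarnings(as.numeric(tab[[col]]))
    if (any(is.na(v)))
      stopf("non-numeric %s in isotope row(s) %s", col,
            paste(utils::head(which(is.na(v)), 5), collapse = ", "))
    tab[[col]] <- v
  }
  if (is.null(tab$cn_ratio) && !is.null(tab$pctC) && !is.null(tab$pctN))
    tab$cn_ratio <- tab$pctC / tab$pctN
  if (!is.null(tab$cn_ratio)) {
    if (any(tab$cn_ratio <= 0, na.rm = TRUE)) stopf("C:N ratios must be > 0")
    if (!is.null(tab$pctC) && !is.null(tab$pctN)) {
      rel <- abs(tab$cn_ratio - tab$pctC / tab$pctN) / (tab$pctC / tab$pctN)
      if (any(rel > 0.02, na.rm = TRUE))
        warnf("%d rows where cn_ratio disagrees with pctC/pctN by > 2%%",
              sum(rel > 0.02, na.rm = TRUE))
    }
  }
  structure(tab, class = c("isotope_table", "data.frame"))
}

#' Write a per-fish stable isotope CSV
#' @param table an `isotope_table` (or plain data frame).
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_isotope_table <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}
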