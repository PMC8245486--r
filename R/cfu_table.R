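# CFU tables: the replicate-level substrate of every statistic in the package.
#
# A CFU table is a plain data.frame with one row per
# {environment, host_strain, community, species_id, replicate} and columns
#   environment  "worm" or "media"
#   host_strain  worm strain token (e.g. "AU37"); NA for media
#   community    ";"-joined sorted species list that was fed
#   species_id   one member of `community`
#   replicate    positive integer label within the condition
#   count        CFU per worm (or per mL), non-negative real
#   unit         "cfu_per_worm" or "cfu_per_ml"

CFU_COLUMNS <- c("environment", "host_strain", "community", "species_id",
                 "replicate", "count", "unit")

#' Validate a CFU table
#'
#' Checks the structural invariants every downstream statistic relies on:
#' required columns present, counts non-negative, environments/units from the
#' allowed vocabularies, `host_strain` present iff the environment is a host,
#' and every (condition, replicate) carrying exactly one row per fed species.
#'
#' @param cfu data.frame in CFU-table layout.
#' @return `cfu`, invisibly, if valid; otherwise an error describing the
#'   offending rows.
#' @export
validate_cfu_table <- function(cfu) {
  missing <- setdiff(CFU_COLUMNS, names(cfu))
  assert_that(length(missing) == 0,
              "CFU table is missing column(s): ", paste(missing, collapse = ", "))
  assert_that(is.numeric(cfu$count), "count column must be numeric")
  bad <- which(!is.finite(cfu$count) | cfu$count < 0)
  assert_that(length(bad) == 0,
              "negative or non-finite count in row(s): ",
              paste(utils::head(bad, 5), collapse = ", "))
  assert_that(all(cfu$environment %in% c("worm", "media")),
              "environment must be 'worm' or 'media'")
  assert_that(all(cfu$unit %in% c("cfu_per_worm", "cfu_per_ml")),
              "unit must be 'cfu_per_worm' or 'cfu_per_ml'")
  worm <- cfu$environment == "worm"
  assert_that(all(!is.na(cfu$host_strain[worm])),
              "worm rows must carry a host_strain")
  assert_that(all(is.na(cfu$host_strain[!worm])),
              "media rows must not carry a host_strain")
  assert_that(all(cfu$replicate == as.integer(cfu$replicate) & cfu$replicate >= 1),
              "replicate labels must be positive integers")

  key <- condition_id(cfu)
  grp <- split(cfu, list(key, cfu$replicate), drop = TRUE)
  for (g in grp) {
    fed <- split_community(g$community[1])
    assert_that(length(fed) >= 1 && !anyDuplicated(fed),
                "community must be non-empty and duplicate-free: ", g$community[1])
    if (!setequal(g$species_id, fed) || nrow(g) != length(fed)) {
      stop_ga("replicate ", g$replicate[1], " of condition [",
              condition_id(g[1, ]), "] does not carry exactly one row per fed ",
              "species (has: ", paste(sort(g$species_id), collapse = ","),
              "; fed: ", paste(fed, collapse = ","), ")")
    }
  }
  invisible(cfu)
}

# Condition identity: everything but species/replicate/count.
condition_id <- function(cfu) {
  paste(cfu$environment,
        ifelse(is.na(cfu$host_strain), "-", cfu$host_strain),
        cfu$community, cfu$unit, sep = "|")
}

#' List the conditions present in a CFU table
#'
#' @param cfu validated CFU table.
#' @return data.frame with one row per condition: environment, host_strain,
#'   community, unit, n_species, n_replicates.
#' @export
cfu_conditions <- function(cfu) {
  key <- condition_id(cfu)
  idx <- !duplicated(key)
  out <- cfu[idx, c("environment", "host_strain", "community", "unit")]
  out$n_species <- vapply(out$community,
                          function(k) length(split_community(k)), integer(1))
  nrep <- vapply(split(cfu$replicate, key)[key[idx]],
                 function(r) length(unique(r)), integer(1))
  out$n_replicates <- as.integer(nrep)
  rownames(out) <- NULL
  out[order(out$environment, out$host_strain, out$n_species, out$community), ,
      drop = FALSE]
}

#' Extract one condition from a CFU table
#'
#' @param cfu validated CFU table.
#' @param community species ids fed together (order irrelevant).
#' @param environment "worm" or "media".
#' @param host_strain worm strain; `NULL` selects media conditions or the
#'   single worm strain present.
#' @return the matching rows of `cfu`.
#' @export
cfu_condition <- function(cfu, community, environment = "worm",
                          host_strain = NULL) {
  sel <- cfu$environment == environment &
    cfu$community == community_key(community)
  if (!is.null(host_strain)) sel <- sel & !is.na(cfu$host_strain) &
      cfu$host_strain == host_strain
  out <- cfu[sel, , drop = FALSE]
  assert_that(nrow(out) > 0, "condition not found: ",
              community_key(community), " in ", environment,
              if (!is.null(host_strain)) paste0("/", host_strain) else "")
  out
}

#' Read a CFU table from CSV or TSV
#'
#' The dialect is detected from the file extension (`.tsv`/`.tab` means
#' tab-separated, anything else comma-separated). Non-standard column names
#' can be mapped through `schema`.
#'
#' @param path file path.
#' @param schema optional named character vector mapping standard column names
#'   (see [validate_cfu_table()]) to the names used in the file, e.g.
#'   `c(count = "cfu")`.
#' @return validated CFU-table data.frame.
#' @export
read_cfu_table <- function(path, schema = NULL) {
  assert_that(file.exists(path), "file not found: ", path)
  sep <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, na.strings = c("NA", ""),
                           check.names = FALSE)
  for (std in names(schema %||% character())) {
    assert_that(schema[[std]] %in% names(raw),
                "schema maps '", std, "' to missing column '", schema[[std]], "'")
    names(raw)[names(raw) == schema[[std]]] <- std
  }
  missing <- setdiff(CFU_COLUMNS, names(raw))
  assert_that(length(missing) == 0,
              "input lacks required column(s): ", paste(missing, collapse = ", "))
  cfu <- raw[CFU_COLUMNS]
  # canonicalize community ordering so keys match regardless of input order
  cfu$community <- vapply(cfu$community,
                          function(k) community_key(split_community(k)),
                          character(1))
  cfu$host_strain <- as.character(cfu$host_strain)
  cfu$replicate <- as.integer(cfu$replicate)
  validate_cfu_table(cfu)
}

#' Write a CFU table to CSV or TSV
#'
#' Counts are written at full precision (17 significant digits) so that a
#' write/read round trip reproduces every value bit-for-bit.
#'
#' @param cfu validated CFU table.
#' @param path output path; extension selects the dialect as in
#'   [read_cfu_table()].
#' @return `path`, invisibly.
#' @export
write_cfu_table <- function(cfu, path) {
  validate_cfu_table(cfu)
  sep <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ","
  out <- cfu[CFU_COLUMNS]
  out$count <- sprintf("%.17g", out$count)
  utils::write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a species metadata table
#'
#' @param path CSV with columns species_id, label, origin ("native" or
#'   "non_native"), collection, taxonomy.
#' @return validated data.frame.
#' @export
read_species_metadata <- function(path) {
  assert_that(file.exists(path), "file not found: ", path)
  meta <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("species_id", "label", "origin", "collection", "taxonomy")
  missing <- setdiff(need, names(meta))
  assert_that(length(missing) == 0,
              "metadata lacks column(s): ", paste(missing, collapse = ", "))
  assert_that(!anyDuplicated(meta$species_id), "duplicate species_id in metadata")
  assert_that(all(meta$origin %in% c("native", "non_native")),
              "origin must be 'native' or 'non_native'")
  meta
}

#' Mean and standard error with the least-replicates convention
#'
#' The s.e.m. is the sample standard deviation divided by `sqrt(n)`, where
#' `n` defaults to the number of values but can be overridden — the
#' convention used for monoculture-derived null quantities, where the
#' effective sample size is the least number of monoculture replicates, not
#' the number of enumerated combinations.
#'
#' @param values numeric vector, at least one value.
#' @param n_override optional positive integer replacing `length(values)` in
#'   the s.e.m. denominator.
#' @return named numeric `c(mean, sem)`; `sem` is `NA` for a single value.
#' @export
mean_and_sem <- function(values, n_override = NULL) {
  assert_that(length(values) >= 1, "mean_and_sem needs at least one value")
  if (!is.null(n_override)) {
    assert_that(n_override >= 1 && n_override == as.integer(n_override),
                "n_override must be a positive integer")
  }
  m <- mean(values)
  if (length(values) < 2) return(c(mean = m, sem = NA_real_))
  n <- n_override %||% length(values)
  c(mean = m, sem = stats::sd(values) / sqrt(n))
}
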