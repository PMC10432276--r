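
REQUIRED_COMMUNITY_COLS <- c("site_id", "study_id", "country", "date",
                             "taxon_id", "taxon_level", "abundance")
TAXON_LEVELS <- c("species", "genus", "family", "coarser")

#' Construct a validated community dataset
#'
#' A community dataset is a long-format table with one row per taxon per
#' sampling event (all samples collected at a site within a single day).
#' Abundances are assumed effort-standardized within each site.
#'
#' @param df data.frame with columns `site_id`, `study_id`, `country`,
#'   `date` (ISO-8601 or `Date`), `taxon_id`, `taxon_level`
#'   (species/genus/family/coarser) and `abundance` (non-negative count).
#'   Unknown columns are preserved.
#' @return A `fw_community` data.frame.
#' @export
as_fw_community <- function(df) {
  stopifnot(is.data.frame(df))
  missing_cols <- setdiff(REQUIRED_COMMUNITY_COLS, names(df))
  if (length(missing_cols) > 0L) {
    stop("community table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (!inherits(df$date, "Date")) {
    parsed <- as.Date(as.character(df$date), format = "%Y-%m-%d")
    bad <- which(is.na(parsed) & !is.na(df$date))
    if (length(bad) > 0L) {
      stop("unparseable date(s) in row(s): ",
           paste(utils::head(bad, 10L), collapse = ", "),
           if (length(bad) > 10L) " ..." else "", call. = FALSE)
    }
    df$date <- parsed
  }
  df$abundance <- as.numeric(df$abundance)
  neg <- which(!is.na(df$abundance) & df$abundance < 0)
  if (length(neg) > 0L) {
    stop("negative abundance in row(s): ",
         paste(utils::head(neg, 10L), collapse = ", "),
         if (length(neg) > 10L) " ..." else "", call. = FALSE)
  }
  bad_level <- setdiff(unique(df$taxon_level), TAXON_LEVELS)
  if (length(bad_level) > 0L) {
    stop("unknown taxon_level value(s): ", paste(bad_level, collapse = ", "),
         call. = FALSE)
  }
  for (col in c("site_id", "study_id", "country", "taxon_id", "taxon_level")) {
    df[[col]] <- as.character(df[[col]])
  }
  class(df) <- c("fw_community", "data.frame")
  df
}

#' Read a community table from delimited text
#'
#' @param path file path to a CSV/TSV file (UTF-8), one row per taxon per
#'   sampling event.
#' @param sep field separator, `","` (default) or `"\t"`.
#' @return A `fw_community` data.frame; the number of rows read is reported
#'   via a message.
#' @export
read_community_table <- function(path, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          comment.char = "", quote = "\"",
                          fileEncoding = "UTF-8")
  out <- as_fw_community(df)
  message(sprintf("read %d rows (%d sites) from %s",
                  nrow(out), length(unique(out$site_id)), path))
  out
}

#' Write a community table to delimited text
#' @param x a `fw_community`
#' @param path output path
#' @param sep field separator
#' @export
write_community_table <- function(x, path, sep = ",") {
  utils::write.table(as.data.frame(x), path, sep = sep, row.names = FALSE,
                     quote = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read site metadata
#'
#' Site metadata carry stream characteristics and bookkeeping flags: one
#' row per site with coordinates, elevation (m), slope, stream order,
#' flow accumulation (km2), upstream % urban and % cropland, and the
#' site's taxonomic resolution (`species`, `mixed` or `family`).
#' Percentages are validated to lie in \[0, 100\].
#'
#' @param path CSV keyed by `site_id`
#' @return data.frame
#' @export
read_site_metadata <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"site_id" %in% names(df)) stop("site metadata must have column site_id")
  for (col in intersect(c("pct_urban", "pct_cropland"), names(df))) {
    v <- df[[col]]
    if (any(!is.na(v) & (v < 0 | v > 100))) {
      stop("column ", col, " must lie in [0, 100]")
    }
  }
  df$site_id <- as.character(df$site_id)
  df
}

#' Read a non-native status lookup
#'
#' Non-native status is defined at the country level: a species native in
#' one country may be introduced in another. Status is only meaningful for
#' species-level taxa.
#'
#' @param path CSV with columns `species`, `country`, `status`
#'   (`native`/`non_native`)
#' @return data.frame
#' @export
read_nonnative_lookup <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("species", "country", "status")
  if (!all(need %in% names(df))) {
    stop("non-native lookup must have columns: ", paste(need, collapse = ", "))
  }
  bad <- setdiff(unique(df$status), c("native", "non_native"))
  if (length(bad) > 0L) stop("unknown status value(s): ", paste(bad, collapse = ", "))
  df
}

#' Read a taxonomy map
#'
#' Maps taxon identifiers to higher taxonomy; used for EPT/insect
#' subsetting, small-taxon exclusion, and trait gap-filling.
#'
#' @param path CSV with columns `taxon_id`, `genus`, `family`, `order`,
#'   `class` (empty strings treated as unknown)
#' @return data.frame
#' @export
read_taxonomy_map <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"taxon_id" %in% names(df)) stop("taxonomy map must have column taxon_id")
  df
}

#' Default list of excluded taxonomic groups
#'
#' Taxa that are not consistently recorded freshwater macroinvertebrates —
#' small-bodied groups (mites, copepods, cladocerans), terrestrial and
#' semi-aquatic taxa, and vertebrates — are removed before analysis. The
#' shipped list names example groups and is configurable; it is not an
#' exhaustive nomenclature.
#'
#' @param path optional path to a plain-text file, one group name per
#'   line, `#` comments allowed. Defaults to the file shipped with the
#'   package.
#' @return character vector of group names (matched against taxonomy
#'   `order`, `class` or `group` columns)
#' @export
default_excluded_groups <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "excluded_taxa_groups.txt",
                        package = "freshtrend")
  }
  x <- readLines(path, warn = FALSE)
  x <- trimws(sub("#.*$", "", x))
  x[nzchar(x)]
}

#' Remove taxa belonging to excluded groups
#'
#' @param community a `fw_community`
#' @param taxonomy taxonomy map data.frame
#' @param groups character vector of group names to drop (default:
#'   [default_excluded_groups()])
#' @return filtered `fw_community` with attribute `n_excluded_rows`
#' @export
remove_excluded_taxa <- function(community, taxonomy,
                                 groups = default_excluded_groups()) {
  cols <- intersect(c("order", "class", "group"), names(taxonomy))
  bad_taxa <- character(0)
  for (col in cols) {
    bad_taxa <- union(bad_taxa,
                      taxonomy$taxon_id[taxonomy[[col]] %in% groups])
  }
  keep <- !(community$taxon_id %in% bad_taxa)
  out <- community[keep, , drop = FALSE]
  attr(out, "n_excluded_rows") <- sum(!keep)
  class(out) <- class(community)
  out
}

# ---- seasons -------------------------------------------------------------

#' The 12 rolling three-month season blocks
#'
#' A season is any block of three consecutive calendar months (wrapping
#' over the year boundary), indexed by its starting month.
#' @return integer matrix 12 x 3 of month numbers
#' @export
season_blocks <- function() {
  t(vapply(1:12, function(m) ((m - 1L + 0:2) %% 12L) + 1L, integer(3)))
}

season_label <- function(start_month) {
  months <- ((start_month - 1L + 0:2) %% 12L) + 1L
  paste(month.abb[months], collapse = "-")
}

#' Select one annual series in a single season for a site
#'
#' Applies the inclusion rules for a site's raw sampling events: events are
#' grouped into the 12 rolling three-month season blocks; the block whose
#' events cover the most distinct sampling years is retained (ties broken
#' by the earlier median sampling date); within the chosen block, one event
#' per year is kept (the event closest to the block's median day-of-year,
#' earliest on ties). Series whose best season covers fewer than
#' `min_years` distinct years are excluded with a reason.
#'
#' @param events data.frame of one site's rows from a `fw_community`
#' @param min_years minimum number of distinct sampling years (default 8)
#' @return list with `events` (filtered rows, one sampling event per year),
#'   `season` (starting month of the retained block), `season_label`,
#'   `n_sampling_years`, and `excluded` (logical) with `reason`.
#' @export
select_annual_series <- function(events, min_years = 8L) {
  stopifnot(nrow(events) > 0L)
  dt <- events$date
  mon <- as.integer(format(dt, "%m"))
  yr <- as.integer(format(dt, "%Y"))
  blocks <- season_blocks()
  n_years <- integer(12)
  med_date <- numeric(12)
  for (b in 1:12) {
    inb <- mon %in% blocks[b, ]
    n_years[b] <- length(unique(yr[inb]))
    med_date[b] <- if (any(inb)) median(as.numeric(dt[inb])) else Inf
  }
  best <- which(n_years == max(n_years))
  if (length(best) > 1L) best <- best[which.min(med_date[best])]
  if (n_years[best] < min_years) {
    return(list(events = events[0, , drop = FALSE], season = best[1],
                season_label = season_label(best[1]),
                n_sampling_years = n_years[best],
                excluded = TRUE,
                reason = sprintf("no season reaches %d sampling years (best: %d)",
                                 min_years, n_years[best])))
  }
  inb <- mon %in% blocks[best, ]
  ev <- events[inb, , drop = FALSE]
  doy <- as.integer(format(ev$date, "%j"))
  med_doy <- median(doy)
  keep_dates <- vapply(split(seq_len(nrow(ev)), format(ev$date, "%Y")),
                       function(idx) {
                         d <- abs(doy[idx] - med_doy)
                         cand <- idx[d == min(d)]
                         cand[which.min(as.numeric(ev$date[cand]))]
                       }, integer(1))
  sel_dates <- sort(unique(ev$date[keep_dates]))
  out <- ev[ev$date %in% sel_dates, , drop = FALSE]
  list(events = out, season = best[1], season_label = season_label(best[1]),
       n_sampling_years = length(sel_dates), excluded = FALSE, reason = NA_character_)
}

#' Validate a site's annual time series against the inclusion rules
#'
#' Checks, per rule: at least `min_years` distinct sampling years (not
#' necessarily consecutive); all events within one three-month season
#' block; at most one sampling event per year; consistent sampling effort
#' (metadata flag, asserted by the data provider); consistent taxonomic
#' resolution.
#'
#' @param events data.frame of one site's rows (post-selection)
#' @param min_years minimum sampling years (default 8)
#' @param effort_consistent provider-asserted flag (default TRUE)
#' @param resolution_consistent provider-asserted flag (default TRUE)
#' @return list of class `fw_validation` with logical pass/fail per rule
#'   and overall `pass`, plus `season_selection_required` when events span
#'   more than one season block.
#' @export
validate_time_series <- function(events, min_years = 8L,
                                 effort_consistent = TRUE,
                                 resolution_consistent = TRUE) {
  dt <- unique(events$date)
  yr <- as.integer(format(dt, "%Y"))
  mon <- as.integer(format(dt, "%m"))
  one_per_year <- !anyDuplicated(yr)
  blocks <- season_blocks()
  in_one_season <- any(vapply(1:12, function(b) all(mon %in% blocks[b, ]),
                              logical(1)))
  rules <- list(
    min_years = length(unique(yr)) >= min_years,
    single_season = in_one_season,
    one_event_per_year = one_per_year,
    consistent_effort = isTRUE(effort_consistent),
    consistent_resolution = isTRUE(resolution_consistent)
  )
  structure(list(rules = rules,
                 pass = all(unlist(rules)),
                 season_selection_required = !in_one_season,
                 n_sampling_years = length(unique(yr))),
            class = "fw_validation")
}

#' @export
print.fw_validation <- function(x, ...) {
  cat("time-series validation:", if (x$pass) "PASS" else "FAIL", "\n")
  for (nm in names(x$rules)) {
    cat(sprintf("  %-22s %s\n", nm, if (x$rules[[nm]]) "ok" else "FAIL"))
  }
  invisible(x)
}

#' Assemble annual time series for all sites
#'
#' Runs [select_annual_series()] per site and reports exclusions; the
#' count of retained plus excluded sites always equals the number of input
#' sites.
#'
#' @param community a `fw_community`
#' @param min_years minimum sampling years
#' @return list with `community` (retained rows), `series` (per-site info
#'   data.frame: site_id, season, n_sampling_years) and `exclusions`
#'   (data.frame site_id, reason)
#' @export
assemble_time_series <- function(community, min_years = 8L) {
  sites <- unique(community$site_id)
  kept <- vector("list", length(sites))
  info <- vector("list", length(sites))
  excl <- list()
  for (i in seq_along(sites)) {
    s <- sites[i]
    res <- select_annual_series(community[community$site_id == s, , drop = FALSE],
                                min_years = min_years)
    if (res$excluded) {
      excl[[length(excl) + 1L]] <- data.frame(site_id = s, reason = res$reason,
                                              stringsAsFactors = FALSE)
    } else {
      kept[[i]] <- res$events
      info[[i]] <- data.frame(site_id = s, season = res$season,
                              season_label = res$season_label,
                              n_sampling_years = res$n_sampling_years,
                              stringsAsFactors = FALSE)
    }
  }
  out_comm <- do.call(rbind, kept[!vapply(kept, is.null, logical(1))])
  if (is.null(out_comm)) out_comm <- community[0, , drop = FALSE]
  class(out_comm) <- c("fw_community", "data.frame")
  list(community = out_comm,
       series = do.call(rbind, info[!vapply(info, is.null, logical(1))]),
       exclusions = if (length(excl)) do.call(rbind, excl) else
         data.frame(site_id = character(0), reason = character(0)))
}

# ---- subsetting ----------------------------------------------------------

EPT_ORDERS <- c("Ephemeroptera", "Plecoptera", "Trichoptera")

#' Subset a community dataset
#'
#' Supported subsets: `all` (identity), `EPT` (orders Ephemeroptera,
#' Plecoptera and Trichoptera — a water-quality indicator group),
#' `insects` (class Insecta), `native` and `non_native` (by country-level
#' introduction status). Native/non-native subsets require species-level
#' information: sites whose taxonomic resolution is `family` are skipped
#' with a logged reason. Species not listed in the lookup are treated as
#' native.
#'
#' @param community a `fw_community`
#' @param subset one of `"all"`, `"EPT"`, `"insects"`, `"native"`,
#'   `"non_native"`
#' @param taxonomy taxonomy map (needed for EPT/insects)
#' @param lookup non-native lookup (needed for native/non_native)
#' @param site_resolution named character vector site_id -> taxonomic
#'   resolution (`species`, `mixed`, `family`); needed for
#'   native/non_native
#' @return filtered `fw_community`; attribute `skipped_sites` lists sites
#'   excluded for coarse resolution, attribute `note` flags empty results.
#' @export
subset_community <- function(community,
                             subset = c("all", "EPT", "insects",
                                        "native", "non_native"),
                             taxonomy = NULL, lookup = NULL,
                             site_resolution = NULL) {
  subset <- match.arg(subset)
  out <- community
  skipped <- character(0)
  if (subset %in% c("EPT", "insects")) {
    if (is.null(taxonomy)) stop("taxonomy map required for subset ", subset)
    if (subset == "EPT") {
      keep_taxa <- taxonomy$taxon_id[taxonomy$order %in% EPT_ORDERS]
    } else {
      keep_taxa <- taxonomy$taxon_id[taxonomy$class %in% "Insecta"]
    }
    out <- community[community$taxon_id %in% keep_taxa, , drop = FALSE]
  } else if (subset %in% c("native", "non_native")) {
    if (is.null(lookup)) stop("non-native lookup required for subset ", subset)
    if (is.null(site_resolution)) {
      stop("site_resolution required for subset ", subset)
    }
    res <- site_resolution[community$site_id]
    coarse <- is.na(res) | res == "family"
    skipped <- unique(community$site_id[coarse])
    out <- community[!coarse, , drop = FALSE]
    key <- paste(out$taxon_id, out$country, sep = "\r")
    nn_key <- with(lookup[lookup$status == "non_native", , drop = FALSE],
                   paste(species, country, sep = "\r"))
    is_nn <- (key %in% nn_key) & out$taxon_level == "species"
    out <- if (subset == "non_native") out[is_nn, , drop = FALSE] else
      out[!is_nn, , drop = FALSE]
  }
  class(out) <- c("fw_community", "data.frame")
  attr(out, "skipped_sites") <- skipped
  if (nrow(out) == 0L && subset == "non_native") {
    attr(out, "note") <- "no non-natives detected"
  }
  out
}
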