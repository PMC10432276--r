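# Fuzzy-coded trait tables. A trait table stores, per taxon, graded
# affinities across the modalities of each trait (affinities within a
# trait sum to 1), plus the provenance of every taxon-trait profile:
# direct (observed), genus_data (database entry for the genus),
# genus_median / family_median (gap-filled), or missing.

PROVENANCE_LEVELS <- c("direct", "genus_data", "genus_median",
                       "family_median", "missing")

#' Construct a fuzzy-coded trait table
#'
#' @param affinities numeric matrix, taxa (rows) x modalities (columns);
#'   `NA` marks a missing taxon-trait profile. Column names are modality
#'   identifiers.
#' @param trait_of named character vector mapping each modality (column
#'   name) to its trait.
#' @param provenance optional character matrix taxa x traits.
#' @return object of class `fw_traits`
#' @export
fw_traits <- function(affinities, trait_of, provenance = NULL) {
  stopifnot(is.matrix(affinities), !is.null(colnames(affinities)),
            all(colnames(affinities) %in% names(trait_of)))
  traits <- unique(unname(trait_of[colnames(affinities)]))
  if (is.null(provenance)) {
    provenance <- matrix("missing", nrow(affinities), length(traits),
                         dimnames = list(rownames(affinities), traits))
    for (tr in traits) {
      cols <- colnames(affinities)[trait_of[colnames(affinities)] == tr]
      ok <- rowSums(is.na(affinities[, cols, drop = FALSE])) == 0L
      provenance[ok, tr] <- "direct"
    }
  }
  structure(list(affinities = affinities,
                 trait_of = trait_of[colnames(affinities)],
                 provenance = provenance),
            class = "fw_traits")
}

#' @export
print.fw_traits <- function(x, ...) {
  cat(sprintf("fuzzy trait table: %d taxa, %d traits, %d modalities\n",
              nrow(x$affinities), length(unique(x$trait_of)),
              ncol(x$affinities)))
  cat("coverage:", sprintf("%.1f%%", 100 * trait_coverage(x)$overall), "\n")
  invisible(x)
}

trait_columns <- function(x, trait) {
  colnames(x$affinities)[x$trait_of == trait]
}

#' Normalize raw fuzzy scores to affinities summing to 1 per trait
#'
#' Raw non-negative scores within each trait are divided by their sum.
#' A taxon whose scores are all zero (or all `NA`) for a trait gets a
#' missing profile. Negative scores are an error. Normalization is
#' idempotent.
#'
#' @param raw numeric matrix taxa x modalities of non-negative scores
#' @param trait_of named character vector modality -> trait
#' @return `fw_traits`
#' @export
normalize_fuzzy <- function(raw, trait_of) {
  if (any(raw < 0, na.rm = TRUE)) stop("negative trait scores are not allowed")
  out <- raw
  traits <- unique(unname(trait_of[colnames(raw)]))
  for (tr in traits) {
    cols <- colnames(raw)[trait_of[colnames(raw)] == tr]
    block <- raw[, cols, drop = FALSE]
    block[is.na(block)] <- 0
    s <- rowSums(block)
    miss <- s <= 0
    block <- sweep(block, 1, ifelse(miss, 1, s), "/")
    block[miss, ] <- NA_real_
    out[, cols] <- block
  }
  fw_traits(out, trait_of)
}

#' Read a long-format trait table
#' @param path CSV with columns `taxon`, `trait`, `modality`, `affinity`
#' @param normalize normalize scores to sum 1 per trait (default TRUE)
#' @return `fw_traits`
#' @export
read_trait_table <- function(path, normalize = TRUE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("taxon", "trait", "modality", "affinity")
  if (!all(need %in% names(df))) {
    stop("trait table must have columns: ", paste(need, collapse = ", "))
  }
  taxa <- unique(df$taxon)
  mods <- unique(df[, c("trait", "modality")])
  m <- matrix(NA_real_, length(taxa), nrow(mods),
              dimnames = list(taxa, mods$modality))
  idx <- cbind(match(df$taxon, taxa), match(df$modality, mods$modality))
  m[idx] <- df$affinity
  trait_of <- stats::setNames(mods$trait, mods$modality)
  if (normalize) normalize_fuzzy(m, trait_of) else fw_traits(m, trait_of)
}

#' Write a trait table in long format
#' @param x `fw_traits`
#' @param path output CSV path
#' @export
write_trait_table <- function(x, path) {
  aff <- x$affinities
  df <- data.frame(taxon = rep(rownames(aff), ncol(aff)),
                   trait = rep(unname(x$trait_of), each = nrow(aff)),
                   modality = rep(colnames(aff), each = nrow(aff)),
                   affinity = as.vector(aff), stringsAsFactors = FALSE)
  df <- df[!is.na(df$affinity), , drop = FALSE]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Trait coverage
#' @param x `fw_traits`
#' @return list with `per_trait` (fraction of taxa with a non-missing
#'   profile, per trait) and `overall` (fraction over all taxon-trait
#'   cells)
#' @export
trait_coverage <- function(x) {
  traits <- unique(unname(x$trait_of))
  per <- vapply(traits, function(tr) {
    cols <- trait_columns(x, tr)
    mean(rowSums(is.na(x$affinities[, cols, drop = FALSE])) == 0L)
  }, numeric(1))
  list(per_trait = per, overall = mean(per))
}

median_profile <- function(block) {
  # per-modality median of fuzzy profiles, renormalized to sum 1 (the
  # medians themselves need not preserve the fuzzy-coding invariant)
  med <- apply(block, 2, stats::median)
  s <- sum(med)
  if (!is.finite(s) || s <= 0) return(rep(NA_real_, length(med)))
  med / s
}

#' Fill trait gaps through the taxonomic hierarchy
#'
#' Resolves a trait profile for every analysed taxon through a four-step
#' cascade, recording provenance and coverage after each step:
#' \enumerate{
#'   \item direct database match at the taxon's identification level;
#'   \item the genus-level database entry (for species- or genus-level
#'     taxa whose genus has its own entry);
#'   \item the per-modality median over database profiles of congeneric
#'     species, renormalized to sum 1;
#'   \item the per-modality median over resolved profiles of confamilial
#'     genera, renormalized.
#' }
#' Directly observed values are never modified. Taxa absent from the
#' taxonomy map stay missing and are listed in the report.
#'
#' @param taxa character vector of analysed taxon ids
#' @param trait_db `fw_traits` holding database entries (species and/or
#'   genus names as rows)
#' @param taxonomy data.frame with columns `taxon_id`, `genus`, `family`
#'   covering both analysed taxa and database entries
#' @return list with `traits` (`fw_traits` over `taxa`) and `report`
#'   (data.frame: step, n_resolved_cells, coverage)
#' @export
fill_trait_gaps <- function(taxa, trait_db, taxonomy) {
  trait_of <- trait_db$trait_of
  traits <- unique(unname(trait_of))
  aff <- matrix(NA_real_, length(taxa), ncol(trait_db$affinities),
                dimnames = list(taxa, colnames(trait_db$affinities)))
  prov <- matrix("missing", length(taxa), length(traits),
                 dimnames = list(taxa, traits))
  tax_genus <- stats::setNames(taxonomy$genus, taxonomy$taxon_id)
  tax_family <- stats::setNames(taxonomy$family, taxonomy$taxon_id)
  db_taxa <- rownames(trait_db$affinities)
  db_has <- function(taxon, tr) {
    taxon %in% db_taxa &&
      !anyNA(trait_db$affinities[taxon, trait_columns(trait_db, tr)])
  }
  unresolved_taxa <- setdiff(taxa, taxonomy$taxon_id)

  coverage_now <- function() mean(prov != "missing")
  report <- data.frame(step = character(0), n_resolved_cells = integer(0),
                       coverage = numeric(0))
  log_step <- function(step, n) {
    rbind(report, data.frame(step = step, n_resolved_cells = n,
                             coverage = coverage_now()))
  }

  # step 1: direct match
  n1 <- 0L
  for (tx in intersect(taxa, db_taxa)) {
    for (tr in traits) {
      if (db_has(tx, tr)) {
        cols <- trait_columns(trait_db, tr)
        aff[tx, cols] <- trait_db$affinities[tx, cols]
        prov[tx, tr] <- "direct"
        n1 <- n1 + 1L
      }
    }
  }
  report <- log_step("direct", n1)

  # step 2: genus-level database entry
  n2 <- 0L
  for (tx in taxa) {
    g <- tax_genus[tx]
    if (is.na(g) || !nzchar(g) || !(g %in% db_taxa) || g == tx) next
    for (tr in traits) {
      if (prov[tx, tr] == "missing" && db_has(g, tr)) {
        cols <- trait_columns(trait_db, tr)
        aff[tx, cols] <- trait_db$affinities[g, cols]
        prov[tx, tr] <- "genus_data"
        n2 <- n2 + 1L
      }
    }
  }
  report <- log_step("genus_data", n2)

  # step 3: median over congeneric species in the database
  db_genus <- tax_genus[db_taxa]
  n3 <- 0L
  for (tx in taxa) {
    g <- tax_genus[tx]
    if (is.na(g) || !nzchar(g)) next
    congeners <- db_taxa[!is.na(db_genus) & db_genus == g & db_taxa != g]
    if (length(congeners) == 0L) next
    for (tr in traits) {
      if (prov[tx, tr] != "missing") next
      cols <- trait_columns(trait_db, tr)
      block <- trait_db$affinities[congeners, cols, drop = FALSE]
      block <- block[rowSums(is.na(block)) == 0L, , drop = FALSE]
      if (nrow(block) == 0L) next
      med <- median_profile(block)
      if (!anyNA(med)) {
        aff[tx, cols] <- med
        prov[tx, tr] <- "genus_median"
        n3 <- n3 + 1L
      }
    }
  }
  report <- log_step("genus_median", n3)

  # step 4: median over confamilial genus profiles (resolved so far)
  n4 <- 0L
  fam_of_genus <- unique(taxonomy[, c("genus", "family")])
  for (tx in taxa) {
    f <- tax_family[tx]
    if (is.na(f) || !nzchar(f)) next
    genera <- fam_of_genus$genus[fam_of_genus$family == f]
    genera <- genera[!is.na(genera) & nzchar(genera)]
    if (length(genera) == 0L) next
    for (tr in traits) {
      if (prov[tx, tr] != "missing") next
      cols <- trait_columns(trait_db, tr)
      # one profile per genus: its database entry, else the median of its
      # database species
      gp <- lapply(genera, function(g) {
        if (db_has(g, tr)) return(trait_db$affinities[g, cols])
        members <- db_taxa[!is.na(db_genus) & db_genus == g & db_taxa != g]
        if (length(members) == 0L) return(NULL)
        block <- trait_db$affinities[members, cols, drop = FALSE]
        block <- block[rowSums(is.na(block)) == 0L, , drop = FALSE]
        if (nrow(block) == 0L) return(NULL)
        median_profile(block)
      })
      gp <- gp[!vapply(gp, is.null, logical(1))]
      if (length(gp) == 0L) next
      med <- median_profile(do.call(rbind, gp))
      if (!anyNA(med)) {
        aff[tx, cols] <- med
        prov[tx, tr] <- "family_median"
        n4 <- n4 + 1L
      }
    }
  }
  report <- log_step("family_median", n4)

  out <- fw_traits(aff, trait_of, provenance = prov)
  attr(out, "unresolved_taxa") <- unresolved_taxa
  list(traits = out, report = report)
}

#' Drop traits with insufficient coverage
#'
#' Keeps only traits whose coverage (fraction of taxa with a non-missing
#' profile, after gap-filling) strictly exceeds `threshold`. A trait at
#' exactly the threshold is dropped.
#'
#' @param x `fw_traits`
#' @param threshold coverage threshold (default 0.85)
#' @return filtered `fw_traits`; errors if nothing survives
#' @export
filter_traits_by_coverage <- function(x, threshold = 0.85) {
  cov <- trait_coverage(x)$per_trait
  keep <- names(cov)[cov > threshold]
  if (length(keep) == 0L) {
    stop("all traits fall at or below the coverage threshold ", threshold)
  }
  cols <- colnames(x$affinities)[x$trait_of %in% keep]
  fw_traits(x$affinities[, cols, drop = FALSE], x$trait_of[cols],
            provenance = x$provenance[, keep, drop = FALSE])
}

#' Community-weighted mean trait profile
#'
#' CWM_m = sum_i p_i * affinity_{i,m}, with p_i the relative abundance of
#' taxon i among the taxa that have trait information. Taxa without a
#' profile are excluded; their abundance mass is reported.
#'
#' @param sample named abundance vector
#' @param traits `fw_traits`
#' @return named numeric vector of CWMs per modality (attribute
#'   `excluded_mass` = relative abundance of uncovered taxa), or `NA`
#'   vector if no sampled taxon is covered
#' @export
community_weighted_means <- function(sample, traits) {
  sample <- sample[!is.na(sample) & sample > 0]
  aff <- traits$affinities
  covered <- intersect(names(sample), rownames(aff))
  covered <- covered[rowSums(is.na(aff[covered, , drop = FALSE])) == 0L]
  out <- rep(NA_real_, ncol(aff))
  names(out) <- colnames(aff)
  excluded <- if (sum(sample) > 0)
    1 - sum(sample[covered]) / sum(sample) else NA_real_
  if (length(covered) == 0L) {
    attr(out, "excluded_mass") <- excluded
    return(out)
  }
  p <- sample[covered] / sum(sample[covered])
  out[] <- as.vector(p %*% aff[covered, , drop = FALSE])
  attr(out, "excluded_mass") <- excluded
  out
}
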