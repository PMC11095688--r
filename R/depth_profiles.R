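# Per-sample depth metrics and the depth-group statistical comparisons.

#' Volume-corrected DNA concentration
#'
#' Standardizes a measured concentration to a 1000 mL filtered volume:
#' measured * 1000 / volume. Linear in the measurement and inversely
#' proportional to volume; a 1000 mL sample is unchanged.
#'
#' @param measured Measured DNA concentration (ng/ul). Below-detection
#'   samples must be excluded before calling (they are excluded from
#'   analyses, not zeroed).
#' @param volume Filtered seawater volume (mL), > 0.
#' @return Concentration in ng/ul per 1000 mL.
#' @export
volume_corrected_concentration <- function(measured, volume) {
  if (any(is.na(measured)))
    stop("below-detection/missing concentrations must be excluded, not passed")
  if (any(is.na(volume) | volume <= 0)) stop("volume must be > 0")
  measured * 1000 / volume
}

#' Reads and ASVs per mL of seawater
#'
#' @param table A decontaminated, read-thresholded [asv_table()].
#' @param metadata A [sample_metadata()] table.
#' @return Data frame sample_id, reads_per_ml, asvs_per_ml. Samples with
#'   missing volume are excluded with a warning.
#' @export
per_ml_metrics <- function(table, metadata) {
  ids <- colnames(table$counts)
  vol <- metadata$volume[match(ids, metadata$sample_id)]
  bad <- is.na(vol) | vol <= 0
  if (any(bad)) {
    warning(sprintf("%d sample(s) without usable volume excluded: %s",
                    sum(bad), paste(utils::head(ids[bad], 5L),
                                    collapse = ", ")))
  }
  keep <- !bad
  data.frame(sample_id = ids[keep],
             reads_per_ml = colSums(table$counts)[keep] / vol[keep],
             asvs_per_ml = colSums(table$counts > 0)[keep] / vol[keep],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Proportion of present ASVs assigned to species, per sample
#'
#' Presence-based (not read-weighted): the number of present ASVs whose
#' deepest assigned rank is species, over the number of present ASVs.
#' Samples with zero present ASVs are excluded.
#'
#' @param table An [asv_table()].
#' @param taxonomy A [taxonomy_table()]; ASVs without a record count as
#'   not species-assigned.
#' @return Data frame sample_id, prop_species.
#' @export
proportion_asvs_to_species <- function(table, taxonomy) {
  is_sp <- rownames(table$counts) %in%
    taxonomy$record_id[taxonomy$deepest_rank == "species"]
  pres <- table$counts > 0
  total <- colSums(pres)
  sp <- colSums(pres[is_sp, , drop = FALSE])
  keep <- total > 0
  data.frame(sample_id = colnames(table$counts)[keep],
             prop_species = sp[keep] / total[keep],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' ASV multiplicity per species, summarized by taxonomic group
#'
#' For each species, counts the distinct ASVs assigned to it anywhere in
#' the table; reports the mean and n-1 sample standard deviation of those
#' counts per taxonomic group. Single-species groups get sd 0 with
#' `sd_defined = FALSE`.
#'
#' @param table An [asv_table()].
#' @param taxonomy A [taxonomy_table()].
#' @param group_map Named vector from [assign_groups()].
#' @return List with `per_species` (species, group, n_asvs) and
#'   `per_group` (group, n_species, mean_asvs, sd_asvs, sd_defined).
#' @export
asvs_per_species <- function(table, taxonomy, group_map) {
  tax <- taxonomy[match(rownames(table$counts), taxonomy$record_id), ]
  keep <- !is.na(tax$record_id) & tax$deepest_rank == "species"
  sp <- tax$species[keep]
  ids <- rownames(table$counts)[keep]
  per_species <- data.frame(species = sort(unique(sp)),
                            stringsAsFactors = FALSE)
  per_species$n_asvs <- vapply(per_species$species, function(s)
    length(unique(ids[sp == s])), integer(1))
  grp <- group_map[ids[match(per_species$species, sp)]]
  per_species$group <- ifelse(is.na(grp), "unassigned", grp)
  groups <- sort(unique(per_species$group))
  per_group <- do.call(rbind, lapply(groups, function(g) {
    v <- per_species$n_asvs[per_species$group == g]
    data.frame(group = g, n_species = length(v), mean_asvs = mean(v),
               sd_asvs = if (length(v) > 1) stats::sd(v) else 0,
               sd_defined = length(v) > 1, stringsAsFactors = FALSE)
  }))
  list(per_species = per_species[, c("species", "group", "n_asvs")],
       per_group = per_group)
}

#' Assemble the per-sample depth metrics table
#'
#' @param table A decontaminated [asv_table()].
#' @param metadata A [sample_metadata()] table (below-detection samples
#'   are excluded from the concentration metric).
#' @param taxonomy A [taxonomy_table()].
#' @param scheme A [depth_bin_scheme()] (default the three-group profile
#'   scheme).
#' @return Data frame of class `depth_metrics`: sample_id, depth,
#'   depth_group, conc_per_1000ml, reads_per_ml, asvs_per_ml,
#'   prop_species (NA where a metric is undefined for that sample).
#' @export
depth_metrics <- function(table, metadata, taxonomy,
                          scheme = depth_bin_scheme("profile")) {
  ids <- colnames(table$counts)
  meta <- metadata[match(ids, metadata$sample_id), ]
  out <- data.frame(sample_id = ids, depth = meta$depth,
                    depth_group = bin_depth(meta$depth, scheme),
                    stringsAsFactors = FALSE)
  conc <- rep(NA_real_, nrow(out))
  ok <- !meta$dna_below_detection & !is.na(meta$dna_concentration) &
    !is.na(meta$volume) & meta$volume > 0
  conc[ok] <- volume_corrected_concentration(meta$dna_concentration[ok],
                                             meta$volume[ok])
  out$conc_per_1000ml <- conc
  pm <- per_ml_metrics(table, metadata)
  out$reads_per_ml <- pm$reads_per_ml[match(ids, pm$sample_id)]
  out$asvs_per_ml <- pm$asvs_per_ml[match(ids, pm$sample_id)]
  ps <- proportion_asvs_to_species(table, taxonomy)
  out$prop_species <- ps$prop_species[match(ids, ps$sample_id)]
  class(out) <- c("depth_metrics", "data.frame")
  out
}

#' Depth-group comparison of every eDNA metric
#'
#' Routes each metric (volume-corrected concentration, reads/mL, ASVs/mL,
#' proportion of ASVs to species) through [select_depth_test()] across
#' depth groups, emitting the global statistic and a Games-Howell pairwise
#' block where the Welch route is significant.
#'
#' @param metrics A `depth_metrics` table from [depth_metrics()].
#' @param alpha Significance level (default 0.05).
#' @return List keyed by metric name; each element is the
#'   [select_depth_test()] result plus `group_sizes`. A metric observed in
#'   fewer than 2 depth groups raises an error naming the metric.
#' @export
depth_comparison <- function(metrics, alpha = 0.05) {
  metric_cols <- c("conc_per_1000ml", "reads_per_ml", "asvs_per_ml",
                   "prop_species")
  out <- list()
  for (mc in metric_cols) {
    ok <- !is.na(metrics[[mc]]) & !is.na(metrics$depth_group)
    groups <- split(metrics[[mc]][ok], metrics$depth_group[ok])
    groups <- groups[lengths(groups) > 0]
    if (length(groups) < 2)
      stop(sprintf("metric '%s' observed in fewer than 2 depth groups", mc))
    res <- select_depth_test(groups, alpha = alpha)
    res$group_sizes <- lengths(groups)
    out[[mc]] <- res
  }
  out
}
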