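# Ordered post-denoising sample/ASV filters with per-step bookkeeping.
# Canonical order: read threshold -> non-marine blocklist -> clade removal
# (COI) -> negative-control ASVs -> below-detection samples. Conservation
# (reads_in = reads_out + reads_removed) holds for every step.

totals <- function(tab) {
  c(samples = ncol(tab$counts), asvs = nrow(tab$counts),
    reads = sum(as.numeric(tab$counts)))
}

report_step <- function(label, before, after, note = "") {
  data.frame(step = label,
             samples_removed = unname(before["samples"] - after["samples"]),
             asvs_removed = unname(before["asvs"] - after["asvs"]),
             reads_removed = unname(before["reads"] - after["reads"]),
             samples_out = unname(after["samples"]),
             asvs_out = unname(after["asvs"]),
             reads_out = unname(after["reads"]),
             note = note, stringsAsFactors = FALSE)
}

#' Default non-marine contamination blocklists
#'
#' Taxa that do not occur in marine habitats and so represent contamination
#' or misclassification: for 12S, terrestrial vertebrate clades plus
#' freshwater Cypriniformes; for COI, three non-local bivalve species
#' observed pervasively across samples and controls.
#'
#' @param marker "12S" or "COI".
#' @return A `blocklist`: list with `marker` and `entries`
#'   (data frame rank, name).
#' @export
default_blocklist <- function(marker = c("12S", "COI")) {
  marker <- match.arg(marker)
  entries <- if (marker == "12S") {
    data.frame(
      rank = c("order", "order", "order", "family", "family", "order",
               "order"),
      name = c("Primates", "Galliformes", "Rodentia", "Bovidae", "Suidae",
               "Chiroptera", "Cypriniformes"),
      stringsAsFactors = FALSE)
  } else {
    data.frame(
      rank = rep("species", 3L),
      name = c("Bathymodiolus japonicus", "Saccostrea malabonensis",
               "Abyssogena phaseoliformis"),
      stringsAsFactors = FALSE)
  }
  blocklist(marker, entries)
}

#' Construct a blocklist
#' @param marker Marker label the list applies to.
#' @param entries Data frame with columns `rank`, `name`.
#' @return A `blocklist` object.
#' @export
blocklist <- function(marker, entries) {
  if (nrow(entries) > 0) {
    bad <- !entries$rank %in% taxonomy_ranks()
    if (any(bad))
      stop("blocklist names unrecognized rank(s): ",
           paste(unique(entries$rank[bad]), collapse = ", "))
    if (any(is.na(entries$name) | entries$name == ""))
      stop("blocklist entries must have non-empty names")
  }
  structure(list(marker = marker, entries = entries), class = "blocklist")
}

#' Remove samples with fewer reads than a threshold
#'
#' Samples whose total read count falls strictly below `threshold` are
#' considered unsuccessfully sequenced and dropped. ASV rows are left
#' untouched even if they become all-zero.
#'
#' @param table An [asv_table()].
#' @param threshold Minimum total reads per sample (default 1000;
#'   comparison is strict: a sample with exactly `threshold` reads is kept).
#' @return List with elements `table` and `step` (one-row report).
#' @export
drop_low_read_samples <- function(table, threshold = 1000) {
  stopifnot(threshold >= 0)
  before <- totals(table)
  keep <- colSums(table$counts) >= threshold
  out <- table
  out$counts <- table$counts[, keep, drop = FALSE]
  list(table = out,
       step = report_step("low_read_samples", before, totals(out),
                          sprintf("threshold=%d", as.integer(threshold))))
}

match_blocklist <- function(taxonomy, entries) {
  hit <- rep(FALSE, nrow(taxonomy))
  for (i in seq_len(nrow(entries)))
    hit <- hit | taxonomy[[entries$rank[i]]] == entries$name[i]
  taxonomy$record_id[hit]
}

#' Remove blocklisted (non-marine) taxa
#'
#' Drops every ASV whose lineage matches any (rank, name) entry of the
#' blocklist. ASVs with no taxonomy record cannot be matched and are
#' retained.
#'
#' @param table An [asv_table()].
#' @param taxonomy A [taxonomy_table()].
#' @param blocklist A [blocklist()]; its marker must match the table's.
#' @return List with `table` and `step`.
#' @export
remove_blocklisted_taxa <- function(table, taxonomy, blocklist) {
  if (!identical(blocklist$marker, table$marker))
    stop(sprintf("blocklist marker '%s' does not match table marker '%s'",
                 blocklist$marker, table$marker))
  before <- totals(table)
  bad <- if (nrow(blocklist$entries) > 0)
    match_blocklist(taxonomy, blocklist$entries) else character()
  out <- table
  out$counts <- table$counts[!rownames(table$counts) %in% bad, ,
                             drop = FALSE]
  list(table = out,
       step = report_step("blocklisted_taxa", before, totals(out),
                          sprintf("%d blocklist entries",
                                  nrow(blocklist$entries))))
}

#' Remove all ASVs in a named clade
#'
#' Used to strip vertebrates (subphylum Vertebrata) from the COI dataset,
#' where the 12S marker is the more effective vertebrate detector. Zero
#' matches are allowed.
#'
#' @param table An [asv_table()].
#' @param taxonomy A [taxonomy_table()].
#' @param rank Rank at which the clade is named.
#' @param name Clade name.
#' @return List with `table` and `step`.
#' @export
remove_clade <- function(table, taxonomy, rank, name) {
  if (!rank %in% taxonomy_ranks()) stop("unrecognized rank: ", rank)
  before <- totals(table)
  bad <- taxonomy$record_id[taxonomy[[rank]] == name]
  out <- table
  out$counts <- table$counts[!rownames(table$counts) %in% bad, ,
                             drop = FALSE]
  list(table = out,
       step = report_step("clade_removal", before, totals(out),
                          sprintf("%s=%s", rank, name)))
}

#' Remove negative-control ASVs, per cruise
#'
#' For each cruise, any ASV with at least one read in any of that cruise's
#' negative controls has its counts zeroed in that cruise's environmental
#' samples (the per-cruise rule: an ASV seen in cruise A's controls is not
#' removed from cruise B). Control sample columns are dropped from the
#' output. With `scope = "global"` a control-present ASV is removed from
#' every environmental sample regardless of cruise.
#'
#' @param table An [asv_table()].
#' @param metadata A [sample_metadata()] table identifying controls/cruises.
#' @param scope "cruise" (default) or "global".
#' @return List with `table` and `step`; the step's `asvs_removed` counts
#'   ASV rows that became all-zero and were dropped.
#' @export
remove_control_asvs <- function(table, metadata, scope = c("cruise",
                                                           "global")) {
  scope <- match.arg(scope)
  before <- totals(table)
  samples <- colnames(table$counts)
  meta <- metadata[match(samples, metadata$sample_id), ]
  if (any(is.na(meta$sample_id)))
    stop("samples missing from metadata: ",
         paste(samples[is.na(meta$sample_id)], collapse = ", "))
  counts <- table$counts
  is_ctl <- meta$is_control
  flagged <- rep(FALSE, nrow(counts))
  cruises <- unique(meta$cruise[!is_ctl])
  for (cr in cruises) {
    ctl_cols <- which(is_ctl & meta$cruise == cr)
    if (scope == "global") ctl_cols <- which(is_ctl)
    env_cols <- which(!is_ctl & meta$cruise == cr)
    if (length(ctl_cols) == 0) {
      warning(sprintf("cruise '%s' has environmental samples but no negative controls; no control-ASV removal applied", cr))
      next
    }
    in_ctl <- rowSums(counts[, ctl_cols, drop = FALSE] > 0) > 0
    counts[in_ctl, env_cols] <- 0L
    flagged <- flagged | in_ctl
  }
  counts <- counts[, !is_ctl, drop = FALSE]
  # drop only flagged ASVs that are gone everywhere; incidental all-zero
  # rows from earlier sample filters are left untouched
  counts <- counts[!(flagged & rowSums(counts) == 0), , drop = FALSE]
  out <- table
  out$counts <- counts
  list(table = out,
       step = report_step("control_asvs", before, totals(out),
                          sprintf("scope=%s", scope)))
}

#' Flag below-detection environmental samples as excluded
#'
#' Environmental samples whose measured DNA concentration fell below the
#' assay's detection floor are excluded from all downstream analyses (not
#' zeroed). Controls with below-detection concentrations are retained as
#' controls.
#'
#' @param metadata A [sample_metadata()] table.
#' @return List with `metadata` (gains a logical `excluded_bd` column) and
#'   `step` (data frame with the exclusion count).
#' @export
drop_below_detection_samples <- function(metadata) {
  excl <- metadata$dna_below_detection & !metadata$is_control
  metadata$excluded_bd <- excl
  list(metadata = metadata,
       step = data.frame(step = "below_detection_samples",
                         samples_removed = sum(excl), asvs_removed = 0,
                         reads_removed = 0, samples_out = NA, asvs_out = NA,
                         reads_out = NA, note = "", stringsAsFactors = FALSE))
}

#' Default decontamination configuration
#'
#' @param min_reads Per-sample read threshold (strict `<` removal).
#' @param control_scope "cruise" or "global" control-ASV removal.
#' @param steps Character vector of steps to run, in order. The canonical
#'   order runs the read threshold first; reordering is supported for
#'   sensitivity analysis.
#' @return Named list consumed by [decontaminate()].
#' @export
decontamination_config <- function(min_reads = 1000,
                                   control_scope = "cruise",
                                   steps = c("low_reads", "blocklist",
                                             "clade", "controls",
                                             "below_detection")) {
  list(min_reads = min_reads,
       blocklist_12S = default_blocklist("12S"),
       blocklist_COI = default_blocklist("COI"),
       remove_clade_COI = list(rank = "subphylum", name = "Vertebrata"),
       control_scope = control_scope,
       steps = steps)
}

#' Run the full decontamination pipeline
#'
#' Applies, in order: per-sample read thresholding, non-marine blocklist
#' removal, vertebrate clade removal (COI only), per-cruise negative-control
#' ASV removal, and below-detection sample exclusion, recording removal
#' counts at each step.
#'
#' @param asv An [asv_table()].
#' @param taxonomy A [taxonomy_table()].
#' @param metadata A [sample_metadata()] table.
#' @param config See [decontamination_config()].
#' @return List with `table` (decontaminated [asv_table()], controls and
#'   excluded samples dropped), `metadata` (with `excluded_bd`), and
#'   `report` (class `decontamination_report`).
#' @export
decontaminate <- function(asv, taxonomy, metadata,
                          config = decontamination_config()) {
  tab <- asv
  steps <- list()
  meta <- metadata
  for (s in config$steps) {
    if (s == "low_reads") {
      r <- drop_low_read_samples(tab, config$min_reads)
      tab <- r$table; steps[[length(steps) + 1L]] <- r$step
    } else if (s == "blocklist") {
      bl <- if (tab$marker == "12S") config$blocklist_12S
            else config$blocklist_COI
      r <- remove_blocklisted_taxa(tab, taxonomy, bl)
      tab <- r$table; steps[[length(steps) + 1L]] <- r$step
    } else if (s == "clade") {
      if (tab$marker == "COI" && !is.null(config$remove_clade_COI)) {
        r <- remove_clade(tab, taxonomy, config$remove_clade_COI$rank,
                          config$remove_clade_COI$name)
        tab <- r$table; steps[[length(steps) + 1L]] <- r$step
      }
    } else if (s == "controls") {
      r <- remove_control_asvs(tab, meta, config$control_scope)
      tab <- r$table; steps[[length(steps) + 1L]] <- r$step
    } else if (s == "below_detection") {
      r <- drop_below_detection_samples(meta)
      meta <- r$metadata
      before <- totals(tab)
      keep <- !colnames(tab$counts) %in% meta$sample_id[meta$excluded_bd]
      tab$counts <- tab$counts[, keep, drop = FALSE]
      steps[[length(steps) + 1L]] <-
        report_step("below_detection_samples", before, totals(tab))
    } else stop("unknown decontamination step: ", s)
  }
  report <- if (length(steps) > 0) do.call(rbind, steps) else
    report_step("none", totals(tab), totals(tab))[0, ]
  class(report) <- c("decontamination_report", "data.frame")
  list(table = tab, metadata = meta, report = report)
}

#' @export
print.decontamination_report <- function(x, ...) {
  cat("Decontamination report:\n")
  print.data.frame(x)
  invisible(x)
}
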