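# Mutually exclusive taxonomic grouping, spatial zones, depth bins,
# day/night classification, and presence-based proportional occurrence.

#' Construct a taxonomic group scheme
#'
#' An ordered rule list mapping lineages to mutually exclusive group labels;
#' the first matching rule wins, so mutual exclusivity holds by
#' construction. Each rule is a list with `rank`, optional `name` (character
#' vector; `NULL` matches any non-empty name at that rank), and optional
#' `group` (fixed label; `NULL` uses the lineage's own name at `rank`).
#'
#' @param rules List of rules as described above.
#' @param fallback Label for records no rule matches (default "unassigned").
#' @return A `group_scheme` object.
#' @export
group_scheme <- function(rules, fallback = "unassigned") {
  for (r in rules) {
    if (!r$rank %in% taxonomy_ranks())
      stop("rule names unrecognized rank: ", r$rank)
  }
  structure(list(rules = rules, fallback = fallback),
            class = "group_scheme")
}

#' Vertebrate (12S) group scheme
#'
#' Groups vertebrate identifications at the order level, except lineages
#' only resolvable within the series Ovalentaria or Eupercaria (orders
#' incertae sedis), which are grouped at the series level.
#'
#' @return A [group_scheme()].
#' @export
vertebrate_group_scheme <- function() {
  group_scheme(list(
    list(rank = "series", name = c("Ovalentaria", "Eupercaria")),
    list(rank = "order")))
}

#' Invertebrate (COI) group scheme
#'
#' Bins invertebrate identifications into broad mutually exclusive animal
#' groups: the order where assigned, otherwise the class, otherwise the
#' phylum.
#'
#' @return A [group_scheme()].
#' @export
invertebrate_group_scheme <- function() {
  group_scheme(list(
    list(rank = "order"),
    list(rank = "class"),
    list(rank = "phylum")))
}

#' Assign every taxonomy record to a group
#'
#' @param taxonomy A [taxonomy_table()].
#' @param scheme A [group_scheme()].
#' @return Named character vector: record_id -> group label (or the
#'   scheme's fallback).
#' @export
assign_groups <- function(taxonomy, scheme) {
  stopifnot(inherits(scheme, "group_scheme"))
  out <- rep(scheme$fallback, nrow(taxonomy))
  done <- rep(FALSE, nrow(taxonomy))
  for (r in scheme$rules) {
    vals <- taxonomy[[r$rank]]
    hit <- !done & vals != "" &
      (if (is.null(r$name)) TRUE else vals %in% r$name)
    out[hit] <- if (is.null(r$group)) vals[hit] else r$group
    done <- done | hit
  }
  stats::setNames(out, taxonomy$record_id)
}

#' Assign samples to trawl-centred sampling zones
#'
#' A sample belongs to a zone if it lies within `dlat` degrees latitude and
#' `dlon` degrees longitude of the zone's trawl site. When boxes overlap,
#' the nearer centre wins under the coordinate-normalized Chebyshev
#' distance max(|dlat|/dlat, |dlon|/dlon); remaining ties go to the zone
#' with the lexicographically smallest id, so site order is irrelevant.
#'
#' @param metadata A [sample_metadata()] table.
#' @param sites Data frame with columns `zone`, `latitude`, `longitude`
#'   (one row per trawl sampling site).
#' @param dlat,dlon Half-widths of the zone box in degrees (defaults 1, 2).
#' @return Named character vector sample_id -> zone id; `NA` = unassigned.
#' @export
assign_zones <- function(metadata, sites, dlat = 1.0, dlon = 2.0) {
  if (nrow(sites) == 0) stop("no trawl sites supplied")
  zones <- rep(NA_character_, nrow(metadata))
  for (i in seq_len(nrow(metadata))) {
    ndist <- pmax(abs(metadata$latitude[i] - sites$latitude) / dlat,
                  abs(metadata$longitude[i] - sites$longitude) / dlon)
    inside <- which(ndist <= 1)
    if (length(inside) > 0) {
      cand <- inside[order(ndist[inside], as.character(sites$zone[inside]))]
      zones[i] <- as.character(sites$zone[cand[1L]])
    }
  }
  stats::setNames(zones, metadata$sample_id)
}

#' Depth bin schemes
#'
#' Named presets partitioning (0, Inf) into lower-open/upper-closed bins:
#' \describe{
#'   \item{comparison}{shallow (0-200 m], deep (200 m, Inf) — the two-bin
#'     scheme used when comparing eDNA with trawl catches.}
#'   \item{profile}{0-200, 200-600, >600 m — the three-group scheme for
#'     depth-profile statistics, whose boundaries approximate the daytime
#'     and nighttime deep scattering layers.}
#'   \item{mapping_12S}{shallow (0-120 m], deep (120-565 m], deeper-than-map
#'     (565 m, Inf) — distribution-mapping bins for the vertebrate marker.}
#'   \item{mapping_COI}{shallow (0-120 m], deep (120-900 m], deeper-than-map
#'     (900 m, Inf).}
#' }
#'
#' @param name Preset name.
#' @return A `depth_bin_scheme`: data frame with columns `label`, `lower`,
#'   `upper` (interval (lower, upper]).
#' @export
depth_bin_scheme <- function(name = c("comparison", "profile",
                                      "mapping_12S", "mapping_COI")) {
  name <- match.arg(name)
  df <- switch(name,
    comparison = data.frame(label = c("shallow", "deep"),
                            lower = c(0, 200), upper = c(200, Inf)),
    profile = data.frame(label = c("0-200", "200-600", ">600"),
                         lower = c(0, 200, 600), upper = c(200, 600, Inf)),
    mapping_12S = data.frame(label = c("shallow", "deep", "deeper-than-map"),
                             lower = c(0, 120, 565),
                             upper = c(120, 565, Inf)),
    mapping_COI = data.frame(label = c("shallow", "deep", "deeper-than-map"),
                             lower = c(0, 120, 900),
                             upper = c(120, 900, Inf)))
  df$label <- as.character(df$label)
  structure(df, class = c("depth_bin_scheme", "data.frame"), name = name)
}

#' Bin a depth into a scheme
#'
#' Bins are lower-open/upper-closed, so a 200 m sample falls in the 0-200 m
#' bin and 200.1 m in the next one, consistent with a strictly
#' greater-than ">600 m" deepest group.
#'
#' @param depth Numeric depth(s) in meters, > 0.
#' @param scheme A [depth_bin_scheme()].
#' @return Character vector of bin labels.
#' @export
bin_depth <- function(depth, scheme) {
  stopifnot(all(depth > 0 | is.na(depth)))
  idx <- vapply(depth, function(d) {
    if (is.na(d)) return(NA_integer_)
    which(d > scheme$lower & d <= scheme$upper)[1L]
  }, integer(1L))
  scheme$label[idx]
}

#' Classify a sample time as night, day or transitional
#'
#' Night is the period from `margin_minutes` after sunset to
#' `margin_minutes` before sunrise (default 90 minutes); day is the
#' complementary core of daylight; the crepuscular remainder is
#' transitional. Sunrise and sunset are the absolute datetimes for the
#' sample's date and position, so midnight and date-line wraps are handled
#' by construction and the classification is invariant to shifting all
#' three times by whole days.
#'
#' @param timestamp,sunrise,sunset POSIXct (UTC). `sunrise` is the morning
#'   event nearest the timestamp's date, `sunset` the evening event.
#' @param margin_minutes Twilight margin (default 90).
#' @return Character vector in {"night", "day", "transitional", "unknown"}.
#' @export
classify_diel <- function(timestamp, sunrise, sunset, margin_minutes = 90) {
  m <- margin_minutes * 60
  day <- 86400
  n <- length(timestamp)
  out <- character(n)
  for (i in seq_len(n)) {
    t <- as.numeric(timestamp[i])
    sr <- as.numeric(sunrise[i]); ss <- as.numeric(sunset[i])
    if (is.na(t) || is.na(sr) || is.na(ss)) {
      out[i] <- "unknown"
      next
    }
    # circular time-of-cycle: phase of t past sunrise, daylight length L;
    # representing any of the three times +/- whole days cannot change u
    u <- (t - sr) %% day
    L <- (ss - sr) %% day
    if (u >= L + m && u <= day - m) out[i] <- "night"
    else if (u >= m && u <= L - m) out[i] <- "day"
    else out[i] <- "transitional"
  }
  out
}

po_matrix <- function(pres_counts) {
  tot <- rowSums(pres_counts)
  keep <- tot > 0
  if (any(!keep))
    warning(sprintf("%d unit(s) with zero grouped presences excluded: %s",
                    sum(!keep),
                    paste(utils::head(rownames(pres_counts)[!keep], 5L),
                          collapse = ", ")))
  po <- pres_counts[keep, , drop = FALSE] / tot[keep]
  structure(po, class = c("proportional_occurrence", "matrix"),
            presences = pres_counts[keep, , drop = FALSE],
            excluded = rownames(pres_counts)[!keep])
}

#' Proportional occurrence of taxonomic groups in eDNA samples
#'
#' Presence-based community composition: per sample, the number of present
#' ASVs (count > 0) belonging to each taxonomic group divided by the total
#' number of present ASVs mapped to any group. ASVs with the fallback
#' "unassigned" group are excluded from both numerator and denominator.
#' Read magnitudes are irrelevant: an ASV with 5000 reads and one with a
#' single read each count once.
#'
#' @param table An [asv_table()] (normally decontaminated).
#' @param group_map Named vector from [assign_groups()].
#' @param unassigned Label treated as unassigned (default "unassigned");
#'   ASVs missing from `group_map` are also treated as unassigned.
#' @return Matrix of class `proportional_occurrence` (samples x groups,
#'   rows summing to 1) with attributes `presences` (integer group presence
#'   counts) and `excluded` (units dropped for zero grouped presences).
#' @export
proportional_occurrence_edna <- function(table, group_map,
                                         unassigned = "unassigned") {
  grp <- group_map[rownames(table$counts)]
  grp[is.na(grp)] <- unassigned
  keep <- grp != unassigned
  pres <- table$counts[keep, , drop = FALSE] > 0
  groups <- sort(unique(grp[keep]))
  pc <- t(apply(pres, 2L, function(col) {
    tab <- tapply(col, factor(grp[keep], levels = groups), sum)
    as.integer(ifelse(is.na(tab), 0L, tab))
  }))
  colnames(pc) <- groups
  po_matrix(pc)
}

#' Proportional occurrence of taxonomic groups in trawl samples
#'
#' As [proportional_occurrence_edna()], but the counting unit is the taxon:
#' per net, the number of taxa present in each group divided by the total
#' number of present taxa.
#'
#' @param trawl A [trawl_table()].
#' @param group_map Named vector from [assign_groups()] over trawl taxa.
#' @param unassigned Label treated as unassigned.
#' @return A `proportional_occurrence` matrix (nets x groups).
#' @export
proportional_occurrence_trawl <- function(trawl, group_map,
                                          unassigned = "unassigned") {
  grp <- group_map[trawl$taxon_id]
  grp[is.na(grp)] <- unassigned
  keep <- grp != unassigned & trawl$count > 0
  sub <- trawl[keep, ]
  nets <- unique(trawl$net_id)
  groups <- sort(unique(grp[keep]))
  pc <- matrix(0L, length(nets), length(groups),
               dimnames = list(nets, groups))
  # count distinct present taxa per (net, group); individuals are ignored
  key <- paste(sub$net_id, grp[keep], sep = "\r")
  tab <- tapply(sub$taxon_id, key, function(z) length(unique(z)))
  for (k in names(tab)) {
    parts <- strsplit(k, "\r", fixed = TRUE)[[1L]]
    pc[parts[1L], parts[2L]] <- as.integer(tab[[k]])
  }
  po_matrix(pc)
}

#' Aggregate proportional occurrences into method/zone/depth-bin units
#'
#' @param po A `proportional_occurrence` matrix with sample rows.
#' @param units Named character vector sample_id -> unit label (e.g.
#'   "zone1:shallow"); samples with `NA` unit are dropped with a warning.
#' @param mode "mean" (default) averages sample rows then renormalizes;
#'   "pool" recomputes fractions from pooled group presence counts.
#' @return A `proportional_occurrence` matrix with one row per unit.
#' @export
aggregate_units <- function(po, units, mode = c("mean", "pool")) {
  mode <- match.arg(mode)
  u <- units[rownames(po)]
  if (any(is.na(u)))
    warning(sprintf("%d sample(s) without a unit dropped: %s", sum(is.na(u)),
                    paste(utils::head(rownames(po)[is.na(u)], 5L),
                          collapse = ", ")))
  keep <- !is.na(u)
  po2 <- po[keep, , drop = FALSE]
  u <- u[keep]
  labs <- sort(unique(u))
  if (mode == "mean") {
    agg <- t(vapply(labs, function(l)
      colMeans(po2[u == l, , drop = FALSE]), numeric(ncol(po2))))
  } else {
    pres <- attr(po, "presences")[keep, , drop = FALSE]
    agg <- t(vapply(labs, function(l)
      colSums(pres[u == l, , drop = FALSE]), numeric(ncol(pres))))
  }
  rownames(agg) <- labs
  agg <- agg / rowSums(agg)
  structure(agg, class = c("proportional_occurrence", "matrix"),
            presences = NULL, excluded = character())
}

#' Partition taxonomic groups by detection method
#'
#' @param po_edna,po_trawl `proportional_occurrence` matrices over the same
#'   group scheme.
#' @return List with `shared`, `edna_only`, `trawl_only` group label
#'   vectors (groups with any nonzero occurrence per method).
#' @export
method_group_overlap <- function(po_edna, po_trawl) {
  ge <- colnames(po_edna)[colSums(po_edna) > 0]
  gt <- colnames(po_trawl)[colSums(po_trawl) > 0]
  list(shared = sort(intersect(ge, gt)),
       edna_only = sort(setdiff(ge, gt)),
       trawl_only = sort(setdiff(gt, ge)))
}
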