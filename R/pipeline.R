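# Staged orchestration: simulate/ingest -> decontaminate -> standardize ->
# compare-methods -> depth-profile -> cluster -> report, with per-stage
# artifacts, structured filter logging and a reproducibility manifest.

#' Default pipeline configuration
#'
#' A single nested configuration covering every stage; the same structure
#' can be read from YAML with [read_pipeline_config()]. Either `simulate`
#' (a preset name and seed) or `inputs` (paths to the four on-disk tables)
#' must be provided.
#'
#' @param preset Synthetic preset used when no input paths are given.
#' @param seed Seed propagated to every stochastic stage.
#' @return Nested named list.
#' @export
default_pipeline_config <- function(preset = "separable-3", seed = 1) {
  list(
    seed = seed,
    simulate = list(preset = preset),
    inputs = NULL,
    decontamination = list(min_reads = 1000, control_scope = "cruise"),
    standardize = list(zone_dlat = 1.0, zone_dlon = 2.0,
                       comparison_bins = "comparison",
                       aggregate_mode = "mean"),
    compare = list(n_perm = 999),
    depth = list(scheme = "profile", alpha = 0.05),
    cluster = list(min_samples = 3, diel_filter = "night", k = "auto",
                   k_max = 8,
                   drop_clades_12S = list(
                     list(rank = "class", name = "Mammalia"),
                     list(rank = "class", name = "Aves")),
                   accumulation_permutations = 100))
}

#' Read a pipeline configuration from YAML
#' @param path YAML file path.
#' @return Nested named list merged over [default_pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  merge_cfg(default_pipeline_config(), user)
}

merge_cfg <- function(base, user) {
  for (nm in names(user)) {
    base[[nm]] <- if (is.list(user[[nm]]) && is.list(base[[nm]]) &&
                      !is.null(names(user[[nm]])))
      merge_cfg(base[[nm]], user[[nm]]) else user[[nm]]
  }
  base
}

#' Compare eDNA and trawl communities across zone/depth units
#'
#' Standardizes both methods onto proportional occurrences of one group
#' scheme, aggregates samples into zone x depth-bin units, and runs a
#' Mantel permutation test on Morisita-Horn dissimilarities between the
#' two methods' shared units. Also reports the group detection overlap.
#'
#' @param table A decontaminated [asv_table()].
#' @param metadata A [sample_metadata()] table.
#' @param trawl A [trawl_table()].
#' @param taxonomy A [taxonomy_table()].
#' @param sites Data frame zone, latitude, longitude of trawl sites.
#' @param scheme A [group_scheme()]; default chosen by the table marker.
#' @param bins A [depth_bin_scheme()] (default "comparison").
#' @param mode Aggregation mode, "mean" or "pool".
#' @param n_perm Mantel permutations (default 999).
#' @param seed Seed for the Mantel permutation stream.
#' @return List with `overlap`, `mantel` (NULL when fewer than 3 shared
#'   units exist), `units` (the shared unit ids), and the two aggregated
#'   proportional-occurrence matrices.
#' @export
compare_methods <- function(table, metadata, trawl, taxonomy, sites,
                            scheme = NULL,
                            bins = depth_bin_scheme("comparison"),
                            mode = "mean", n_perm = 999, seed = NULL) {
  if (is.null(scheme))
    scheme <- if (table$marker == "12S") vertebrate_group_scheme()
              else invertebrate_group_scheme()
  gm <- assign_groups(taxonomy, scheme)
  po_e <- suppressWarnings(proportional_occurrence_edna(table, gm))
  po_t <- suppressWarnings(proportional_occurrence_trawl(trawl, gm))
  zones <- assign_zones(metadata, sites)
  meta <- metadata[match(rownames(po_e), metadata$sample_id), ]
  ze <- zones[rownames(po_e)]
  be <- bin_depth(meta$depth, bins)
  unit_e <- stats::setNames(
    ifelse(is.na(ze) | is.na(be), NA, paste(ze, be, sep = ":")),
    rownames(po_e))
  tz <- assign_zones(
    data.frame(sample_id = rownames(po_t),
               latitude = trawl$latitude[match(rownames(po_t),
                                               trawl$net_id)],
               longitude = trawl$longitude[match(rownames(po_t),
                                                 trawl$net_id)]),
    sites)
  tmid <- (trawl$depth_min + trawl$depth_max)[
    match(rownames(po_t), trawl$net_id)] / 2
  zt <- tz[rownames(po_t)]
  bt <- bin_depth(pmax(tmid, 1), bins)
  unit_t <- stats::setNames(
    ifelse(is.na(zt) | is.na(bt), NA, paste(zt, bt, sep = ":")),
    rownames(po_t))
  agg_e <- suppressWarnings(aggregate_units(po_e, unit_e, mode))
  agg_t <- suppressWarnings(aggregate_units(po_t, unit_t, mode))
  shared <- intersect(rownames(agg_e), rownames(agg_t))
  out <- list(overlap = method_group_overlap(po_e, po_t), mantel = NULL,
              units = shared, edna_units = agg_e, trawl_units = agg_t)
  if (length(shared) >= 3) {
    groups <- union(colnames(agg_e), colnames(agg_t))
    pad <- function(m) {
      o <- matrix(0, nrow(m), length(groups),
                  dimnames = list(rownames(m), groups))
      o[, colnames(m)] <- m
      o
    }
    D_e <- pairwise_dissimilarity(pad(agg_e)[shared, , drop = FALSE],
                                  "morisita-horn")
    D_t <- pairwise_dissimilarity(pad(agg_t)[shared, , drop = FALSE],
                                  "morisita-horn")
    out$mantel <- mantel_test(D_e, D_t, n_perm, seed = seed)
  }
  out
}

stage_log <- function(run, stage, msg, ...) {
  line <- sprintf("[%s] %s", stage, sprintf(msg, ...))
  cat(line, "\n", sep = "", file = run$log_con)
  invisible(line)
}

#' Run the full analysis pipeline
#'
#' Executes simulate (or ingest) -> decontaminate -> standardize ->
#' compare-methods -> depth-profile -> cluster, writing each stage's
#' artifacts (CSV/JSON/GeoJSON), a structured log with one line per
#' filter, and a reproducibility manifest of input digests and per-stage
#' dimensions to `out_dir`.
#'
#' @param config A config list (see [default_pipeline_config()]) or the
#'   path to a YAML file.
#' @param out_dir Output directory.
#' @return Invisibly, a list with the in-memory stage results; artifacts
#'   are on disk under `out_dir`. A missing input path raises an error
#'   naming the path.
#' @export
run_pipeline <- function(config = default_pipeline_config(),
                         out_dir = tempfile("edna_run_")) {
  if (is.character(config)) config <- read_pipeline_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  run <- list(log_con = file(log_path, "w"))
  on.exit(close(run$log_con))
  manifest <- list(seed = config$seed, stages = list())

  ## simulate | ingest
  if (!is.null(config$inputs)) {
    for (p in unlist(config$inputs))
      if (!file.exists(p)) stop("input file not found: ", p)
    taxonomy <- read_taxonomy(config$inputs$taxonomy)
    data <- list(
      asv = list("12S" = read_asv_table(config$inputs$asv_12S, "12S"),
                 "COI" = read_asv_table(config$inputs$asv_COI, "COI")),
      taxonomy = taxonomy,
      metadata = read_sample_metadata(config$inputs$metadata),
      trawl = read_trawl_table(config$inputs$trawl, taxonomy),
      truth = NULL)
    manifest$inputs <- as.list(tools::md5sum(unlist(config$inputs)))
    stage_log(run, "ingest", "read %d + %d ASVs, %d metadata rows",
              nrow(data$asv[["12S"]]$counts),
              nrow(data$asv[["COI"]]$counts), nrow(data$metadata))
  } else {
    cfg <- synthetic_preset(config$simulate$preset)
    cfg$seed <- config$seed
    data <- generate_dataset(cfg)
    manifest$simulate <- list(preset = config$simulate$preset,
                              seed = config$seed)
    stage_log(run, "simulate", "preset=%s seed=%d: %d samples",
              config$simulate$preset, config$seed,
              sum(!data$metadata$is_control))
  }
  vr <- validate_dataset(data$asv, data$taxonomy, data$metadata,
                         data$trawl)
  if (nrow(vr$errors) > 0) {
    utils::write.csv(vr$errors, file.path(out_dir, "validation_errors.csv"),
                     row.names = FALSE)
    stop("dataset validation failed with ", nrow(vr$errors), " error(s)")
  }

  ## decontaminate
  dcfg <- decontamination_config(
    min_reads = config$decontamination$min_reads,
    control_scope = config$decontamination$control_scope)
  decon <- list()
  for (mk in names(data$asv)) {
    d <- decontaminate(data$asv[[mk]], data$taxonomy, data$metadata, dcfg)
    decon[[mk]] <- d
    utils::write.csv(d$report,
                     file.path(out_dir,
                               sprintf("decontamination_%s.csv", mk)),
                     row.names = FALSE)
    for (i in seq_len(nrow(d$report)))
      stage_log(run, "decontaminate",
                "%s %s: -%d samples, -%d ASVs, -%.0f reads", mk,
                d$report$step[i], d$report$samples_removed[i],
                d$report$asvs_removed[i], d$report$reads_removed[i])
  }
  metadata <- decon[[1]]$metadata

  ## standardize + compare-methods
  sites <- if (!is.null(data$truth)) data$truth$trawl_sites else {
    u <- unique(data$trawl[, c("latitude", "longitude")])
    data.frame(zone = paste0("Z", seq_len(nrow(u))), u)
  }
  compare <- list()
  for (mk in names(decon)) {
    res <- compare_methods(
      decon[[mk]]$table, metadata, data$trawl, data$taxonomy, sites,
      bins = depth_bin_scheme(config$standardize$comparison_bins),
      mode = config$standardize$aggregate_mode,
      n_perm = config$compare$n_perm, seed = config$seed)
    if (!is.null(res$mantel)) {
      stage_log(run, "compare-methods",
                "%s Mantel r=%.3f p=%.3f (%d units)", mk, res$mantel$r,
                res$mantel$p, length(res$units))
    } else {
      stage_log(run, "compare-methods",
                "%s: only %d shared method units; Mantel skipped", mk,
                length(res$units))
    }
    compare[[mk]] <- res
  }
  jsonlite::write_json(
    lapply(compare, function(z) list(
      overlap = z$overlap,
      mantel = if (!is.null(z$mantel)) unclass(z$mantel))),
    file.path(out_dir, "method_comparison.json"),
    auto_unbox = TRUE, digits = NA, force = TRUE)

  ## depth-profile
  depth <- list()
  for (mk in names(decon)) {
    dm <- depth_metrics(decon[[mk]]$table, metadata, data$taxonomy,
                        depth_bin_scheme(config$depth$scheme))
    utils::write.csv(dm, file.path(out_dir,
                                   sprintf("depth_metrics_%s.csv", mk)),
                     row.names = FALSE)
    cmp <- tryCatch(depth_comparison(dm, alpha = config$depth$alpha),
                    error = function(e) {
                      stage_log(run, "depth-profile", "%s: %s", mk,
                                conditionMessage(e))
                      NULL
                    })
    depth[[mk]] <- list(metrics = dm, tests = cmp)
    if (!is.null(cmp))
      for (m in names(cmp))
        stage_log(run, "depth-profile", "%s %s: %s p=%.3g", mk, m,
                  cmp[[m]]$test, cmp[[m]]$result$p)
  }
  jsonlite::write_json(
    lapply(depth, function(z) lapply(z$tests, function(t) list(
      test = t$test, statistic = t$result$statistic,
      df = t$result$df, p = t$result$p,
      pairwise = lapply(t$posthoc, function(ph) list(
        pair = ph$pair, t = ph$statistic, df = ph$df, p = ph$p))))),
    file.path(out_dir, "depth_tests.json"),
    auto_unbox = TRUE, digits = NA, force = TRUE)

  ## cluster
  clusters <- list()
  for (mk in names(decon)) {
    diel <- stats::setNames(
      classify_diel(metadata$timestamp, metadata$sunrise,
                    metadata$sunset), metadata$sample_id)
    drop_clades <- if (mk == "12S") config$cluster$drop_clades_12S
                   else list()
    cl <- tryCatch({
      pres <- suppressMessages(build_presence_matrix(
        decon[[mk]]$table, data$taxonomy,
        min_samples = config$cluster$min_samples,
        drop_clades = drop_clades, diel = diel,
        diel_filter = config$cluster$diel_filter))
      D <- pairwise_dissimilarity(pres, "jaccard")
      dend <- ward_cluster(D)
      k_max <- min(config$cluster$k_max, nrow(pres) - 1L)
      wss <- wss_curve(D, dend, k_max)
      sil <- silhouette_curve(D, dend, k_max)
      k <- if (identical(config$cluster$k, "auto"))
        choose_k_elbow(wss) else as.integer(config$cluster$k)
      if (k < 2) k <- 2L
      sol <- cluster_solution(D, dend, k)
      summ <- cluster_summary(pres, sol$labels)
      acc <- lapply(split(rownames(pres), sol$labels), function(ids)
        species_accumulation(pres[ids, , drop = FALSE],
                             config$cluster$accumulation_permutations,
                             seed = config$seed))
      pos <- metadata[match(rownames(pres), metadata$sample_id), ]
      regions <- list()
      map_scheme <- depth_bin_scheme(
        if (mk == "12S") "mapping_12S" else "mapping_COI")
      for (ci in which(sol$cluster_stats$cohesive)) {
        members <- names(sol$labels)[sol$labels == ci]
        mpos <- pos[pos$sample_id %in% members, ]
        for (b in c("shallow", "deep")) {
          pts <- mpos[!is.na(mpos$depth) &
                        bin_depth(mpos$depth, map_scheme) == b,
                      c("longitude", "latitude")]
          key <- sprintf("cluster%d_%s", ci, b)
          reg <- tryCatch(density_region_50(pts), error = function(e) NULL)
          if (!is.null(reg)) regions[[key]] <- reg
        }
      }
      stage_log(run, "cluster", "%s: n=%d, k=%d, cohesive=%d", mk,
                nrow(pres), k, sum(sol$cluster_stats$cohesive))
      list(presence = pres, D = D, dendrogram = dend, wss = wss,
           silhouette = sil, k = k, solution = sol, summary = summ,
           accumulation = acc, regions = regions)
    }, error = function(e) {
      stage_log(run, "cluster", "%s failed: %s", mk, conditionMessage(e))
      NULL
    })
    clusters[[mk]] <- cl
    if (is.null(cl)) next
    utils::write.csv(
      data.frame(sample_id = names(cl$solution$labels),
                 cluster = cl$solution$labels,
                 silhouette = cl$solution$widths),
      file.path(out_dir, sprintf("clusters_%s.csv", mk)),
      row.names = FALSE)
    jsonlite::write_json(
      list(k = cl$k, wss = as.list(cl$wss),
           mean_silhouette = as.list(cl$silhouette),
           clusters = lapply(cl$summary, function(s)
             s[c("size", "species_per_sample_mean",
                 "species_per_sample_sd", "richness", "top_species")]),
           cohesion = cl$solution$cluster_stats),
      file.path(out_dir, sprintf("cluster_summary_%s.json", mk)),
      auto_unbox = TRUE, digits = NA, force = TRUE)
    if (length(cl$regions) > 0)
      write_density_geojson(cl$regions,
                            file.path(out_dir,
                                      sprintf("regions_%s.geojson", mk)))
  }

  ## manifest
  for (mk in names(decon))
    manifest$stages[[mk]] <- list(
      decontaminated_dim = dim(decon[[mk]]$table$counts),
      cluster_n = if (!is.null(clusters[[mk]]))
        nrow(clusters[[mk]]$presence),
      cluster_k = clusters[[mk]]$k)
  manifest$config_digest <- digest_obj(config)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)

  invisible(list(data = data, decontaminated = decon, compare = compare,
                 depth = depth, clusters = clusters, out_dir = out_dir,
                 manifest = manifest))
}

digest_obj <- function(x) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(x, tmp, version = 2, compress = FALSE)
  unname(tools::md5sum(tmp))
}

#' Render a human-readable report from a pipeline run
#'
#' Assembles the run's JSON/CSV artifacts into one Markdown report:
#' filter bookkeeping, method comparison, depth statistics and cluster
#' summaries (at most 10 species per cohesive cluster; an explicit note
#' when no cluster is cohesive).
#'
#' @param artifacts_dir Directory written by [run_pipeline()].
#' @return Path to the written `report.md`. Missing stage artifacts are
#'   listed instead of failing.
#' @export
pipeline_report <- function(artifacts_dir) {
  out <- file.path(artifacts_dir, "report.md")
  lines <- c("# eDNA assemblage pipeline report", "")
  missing <- character()
  for (mk in c("12S", "COI")) {
    p <- file.path(artifacts_dir, sprintf("decontamination_%s.csv", mk))
    if (!file.exists(p)) { missing <- c(missing, p); next }
    rep <- utils::read.csv(p)
    lines <- c(lines, sprintf("## Decontamination (%s)", mk), "",
               "| step | samples removed | ASVs removed | reads removed |",
               "|---|---|---|---|",
               sprintf("| %s | %d | %d | %.0f |", rep$step,
                       rep$samples_removed, rep$asvs_removed,
                       rep$reads_removed), "")
  }
  p <- file.path(artifacts_dir, "method_comparison.json")
  if (file.exists(p)) {
    mcj <- jsonlite::read_json(p)
    for (mk in names(mcj)) {
      lines <- c(lines, sprintf("## Method comparison (%s)", mk), "")
      if (!is.null(mcj[[mk]]$mantel))
        lines <- c(lines, sprintf("Mantel: r = %.3f, p = %.3f",
                                  mcj[[mk]]$mantel$r, mcj[[mk]]$mantel$p),
                   "")
      ov <- mcj[[mk]]$overlap
      lines <- c(lines, sprintf(
        "Groups shared: %d; eDNA-only: %d; trawl-only: %d",
        length(ov$shared), length(ov$edna_only), length(ov$trawl_only)),
        "")
    }
  } else missing <- c(missing, p)
  p <- file.path(artifacts_dir, "depth_tests.json")
  if (file.exists(p)) {
    dt <- jsonlite::read_json(p)
    for (mk in names(dt)) {
      lines <- c(lines, sprintf("## Depth-group tests (%s)", mk), "",
                 "| metric | test | statistic | p |", "|---|---|---|---|")
      for (m in names(dt[[mk]]))
        lines <- c(lines, sprintf("| %s | %s | %.4g | %.3g |", m,
                                  dt[[mk]][[m]]$test,
                                  dt[[mk]][[m]]$statistic,
                                  dt[[mk]][[m]]$p))
      lines <- c(lines, "")
    }
  } else missing <- c(missing, p)
  for (mk in c("12S", "COI")) {
    p <- file.path(artifacts_dir, sprintf("cluster_summary_%s.json", mk))
    if (!file.exists(p)) { missing <- c(missing, p); next }
    cs <- jsonlite::read_json(p)
    lines <- c(lines, sprintf("## Clusters (%s), k = %d", mk, cs$k), "")
    coh <- vapply(cs$cohesion, function(z) isTRUE(z$cohesive), logical(1))
    if (!any(coh))
      lines <- c(lines, "No cohesive clusters.", "")
    for (i in seq_along(cs$clusters)) {
      cl <- cs$clusters[[i]]
      flag <- if (coh[i]) "cohesive" else "not cohesive"
      lines <- c(lines, sprintf(
        "### Cluster %s (%s): %d samples, %.2f +/- %.2f species/sample",
        names(cs$clusters)[i], flag, cl$size, cl$species_per_sample_mean,
        cl$species_per_sample_sd))
      if (coh[i]) {
        sp <- vapply(cl$top_species, function(z)
          sprintf("%s (%.2f)", z$species, z$frequency), character(1))
        lines <- c(lines, "", paste("Top species:",
                                    paste(sp, collapse = ", ")), "")
      } else lines <- c(lines, "")
    }
  }
  if (length(missing) > 0)
    lines <- c(lines, "## Missing stage artifacts", "",
               paste("-", missing), "")
  writeLines(lines, out)
  out
}
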