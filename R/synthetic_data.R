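# Ground-truth-annotated synthetic datasets: planted spatial assemblages,
# species -> many-ASV multiplicity, negative-control contamination,
# non-marine bycatch, depth-decaying DNA concentration, and co-located
# trawl catches. Everything a pipeline stage consumes can be generated
# here with known truth.

VERT_ORDERS <- c("Myctophiformes", "Clupeiformes", "Stomiiformes",
                 "Osmeriformes", "Gadiformes", "Argentiniformes",
                 "Scorpaeniformes", "Beloniformes", "Pleuronectiformes",
                 "Stephanoberyciformes")
VERT_SERIES <- c("Ovalentaria", "Eupercaria")
INVERT_POOL <- data.frame(
  order = c("Calanoida", "Cyclopoida", "Euphausiacea", "Decapoda",
            "Amphipoda", "Ostracoda", "Siphonophorae", "Trachymedusae",
            "Leptothecata", "Limnomedusae", "Semaeostomeae", "Salpida",
            "Phyllodocida", "Pteropoda", ""),
  class = c("Copepoda", "Copepoda", "Malacostraca", "Malacostraca",
            "Malacostraca", "Ostracoda", "Hydrozoa", "Hydrozoa",
            "Hydrozoa", "Hydrozoa", "Scyphozoa", "Thaliacea",
            "Polychaeta", "Gastropoda", ""),
  phylum = c(rep("Arthropoda", 6), rep("Cnidaria", 5), "Chordata",
             "Annelida", "Mollusca", "Chaetognatha"),
  subphylum = c(rep("Crustacea", 6), rep("", 5), "Tunicata", "", "", ""),
  stringsAsFactors = FALSE)

#' Synthetic dataset configuration
#'
#' Defaults describe the desk-scale study design; [synthetic_preset()]
#' provides the named designs used throughout the package.
#'
#' @param seed Integer seed fixing the entire dataset.
#' @param n_stations Number of CTD stations.
#' @param depths_per_station Samples per station (recycled over stations).
#' @param n_cruises Number of cruises (stations split evenly).
#' @param controls_per_cruise Negative controls per cruise.
#' @param lat_range,lon_range Study extent (decimal degrees, west
#'   negative).
#' @param K Number of planted assemblages.
#' @param assemblage_centers Optional data frame lon, lat, depth (niche
#'   centre, m); defaults spread across the extent.
#' @param station_placement "assemblage" scatters stations around the
#'   assemblage centres (a survey targeting known features); "uniform"
#'   spreads them over the whole extent.
#' @param night_frac Fraction of stations sampled during night hours
#'   (diel-aware surveys oversample the night).
#' @param depth_profile "skewed" (default; about two thirds of samples
#'   shallower than 200 m, as in depth-stratified CTD surveys) or
#'   "uniform" over 1-1400 m.
#' @param spatial_sd Station scatter around assemblage centres (degrees).
#' @param kernel_softening Spatial kernel sd as a multiple of
#'   `spatial_sd` (default 2): stations scattered one `spatial_sd` from
#'   their centre still sit well inside their assemblage's kernel.
#' @param depth_sd Assemblage depth kernel sd (log-depth units).
#' @param species_vert,species_invert Target marine species per assemblage
#'   (12S / COI).
#' @param overlap Fraction of each assemblage's pool shared with a common
#'   background pool (0 = fully separable).
#' @param p_in,p_out Per-sample species occurrence probability at the
#'   assemblage centre vs outside the assemblage.
#' @param n_noise_samples Samples with unstructured random communities
#'   (truth label "noise").
#' @param p_noise Occurrence probability for species in noise samples.
#' @param vert_asv_mean Mean ASVs per vertebrate species (1 + Poisson).
#' @param invert_asv_meanlog,invert_asv_sdlog Log-normal ASV multiplicity
#'   for invertebrate species (COI-inflated).
#' @param read_mean_12S,read_mean_COI Negative-binomial mean sample totals.
#' @param read_size NB dispersion (size) of sample totals.
#' @param read_fail_prob_12S,read_fail_prob_COI Probability a sample
#'   sequences poorly (total drawn with mean ~300), exercising the
#'   1,000-read filter at roughly the observed failure rates.
#' @param n_control_asvs Contaminant ASVs shared between controls and
#'   environmental samples, per marker.
#' @param contam_prob Probability a contaminant ASV appears in an
#'   environmental sample.
#' @param n_nonmarine Non-marine contaminant ASVs per marker (12S:
#'   terrestrial vertebrates; COI: blocklisted bivalves).
#' @param coi_vert_species Vertebrate bycatch species planted in the COI
#'   dataset (removed by clade filtering).
#' @param species_level_prob_shallow,species_level_prob_deep Probability a
#'   species' reference lineage resolves to species rank, for species of
#'   shallow (niche <= 200 m) vs deep assemblages — emulating poorer deep
#'   library coverage.
#' @param dna_surface,dna_efold,dna_noise_sd,dna_bd DNA concentration
#'   model: surface mean (ng/ul), e-folding depth (m), additive noise sd,
#'   below-detection floor.
#' @param trawl_stations Stations that also host trawl sites.
#' @param trawl_strata Data frame depth_min, depth_max of net strata.
#' @param catchability Named per-group catchability multipliers (defaults
#'   1; gelatinous groups < 1).
#' @param n_trawl_only Trawl-exclusive taxa (groups unseen by eDNA).
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(seed = 1,
                             n_stations = 18, depths_per_station = 4,
                             n_cruises = 2, controls_per_cruise = 2,
                             lat_range = c(29.8, 34.9),
                             lon_range = c(-125.0, -117.3),
                             K = 3, assemblage_centers = NULL,
                             station_placement = c("assemblage",
                                                   "uniform"),
                             night_frac = 0.6,
                             depth_profile = c("skewed", "uniform"),
                             spatial_sd = 0.6, kernel_softening = 2,
                             depth_sd = 1.5,
                             species_vert = 12, species_invert = 20,
                             overlap = 0, p_in = 0.8, p_out = 0.01,
                             n_noise_samples = 0, p_noise = 0.1,
                             vert_asv_mean = 2.1,
                             invert_asv_meanlog = 1.2,
                             invert_asv_sdlog = 1.0,
                             read_mean_12S = 24333,
                             read_mean_COI = 31611,
                             read_size = 2,
                             read_fail_prob_12S = 0.46,
                             read_fail_prob_COI = 0.21,
                             n_control_asvs = 5, contam_prob = 0.3,
                             n_nonmarine = 3, coi_vert_species = 2,
                             species_level_prob_shallow = 0.85,
                             species_level_prob_deep = 0.35,
                             dna_surface = 3.6, dna_efold = 300,
                             dna_noise_sd = 0.25, dna_bd = 0.05,
                             trawl_stations = 3,
                             trawl_strata = NULL,
                             catchability = NULL,
                             n_trawl_only = 4) {
  station_placement <- match.arg(station_placement)
  depth_profile <- match.arg(depth_profile)
  stopifnot(K >= 1, p_in >= 0, p_in <= 1, p_out >= 0, p_out <= 1,
            overlap >= 0, overlap <= 1)
  if (is.null(assemblage_centers)) {
    lon <- seq(lon_range[1] + 0.8, lon_range[2] - 0.8, length.out = K)
    lat <- seq(lat_range[1] + 0.6, lat_range[2] - 0.6, length.out = K)
    depth <- rep(c(60, 60, 500, 120), length.out = K)
    assemblage_centers <- data.frame(lon = lon, lat = rev(lat),
                                     depth = depth)
  }
  if (is.null(trawl_strata))
    trawl_strata <- data.frame(depth_min = c(0, 200, 600),
                               depth_max = c(200, 600, 1000))
  cfg <- as.list(environment())
  class(cfg) <- "synthetic_config"
  cfg
}

#' Named synthetic study designs
#'
#' \describe{
#'   \item{paper-like}{The full study scale: 436 environmental samples
#'     over 40 stations, 11 controls, depth-skewed sampling (about two
#'     thirds shallower than 200 m), heavy COI ASV multiplicity, read
#'     totals averaging ~24k (12S) and ~32k (COI).}
#'   \item{separable-3}{Three well-separated assemblages plus a small
#'     unstructured noise fraction, for end-to-end recovery tests.}
#'   \item{null}{No spatial structure (every species occurs everywhere
#'     with the same probability), for calibration tests.}
#' }
#'
#' @param name Preset name.
#' @return A `synthetic_config`.
#' @export
synthetic_preset <- function(name = c("paper-like", "separable-3",
                                      "null")) {
  name <- tryCatch(match.arg(name), error = function(e)
    stop("unknown preset '", name[1],
         "'; available: paper-like, separable-3, null", call. = FALSE))
  switch(name,
    "paper-like" = synthetic_config(
      n_stations = 40, depths_per_station = c(rep(11, 36), rep(10, 4)),
      controls_per_cruise = c(7, 4), K = 4, spatial_sd = 1.2,
      depth_sd = 1.2, species_vert = 15, species_invert = 26,
      overlap = 0.3, p_in = 0.5, p_out = 0.05, invert_asv_meanlog = 3.5,
      invert_asv_sdlog = 1.3, n_control_asvs = 7, trawl_stations = 3),
    "separable-3" = synthetic_config(
      n_stations = 27, depths_per_station = 6, K = 3,
      assemblage_centers = data.frame(
        lon = c(-123.5, -120.5, -118.5), lat = c(33.8, 30.8, 33.0),
        depth = c(60, 60, 60)),
      spatial_sd = 0.5, depth_sd = 10, species_vert = 20,
      species_invert = 24, overlap = 0, p_in = 0.9, p_out = 0.005,
      n_noise_samples = 12, p_noise = 0.15),
    "null" = synthetic_config(
      n_stations = 12, depths_per_station = 4, K = 1,
      station_placement = "uniform", species_vert = 10,
      species_invert = 16, p_in = 0.2, p_out = 0.2))
}

rdepths <- function(n, profile = "skewed") {
  if (profile == "uniform") return(stats::runif(n, 1, 1400))
  # depth-skewed sampling: about two thirds epipelagic
  u <- stats::runif(n)
  ifelse(u < 0.67, stats::runif(n, 1, 200),
         ifelse(u < 0.90, stats::runif(n, 200, 600),
                stats::runif(n, 600, 1400)))
}

make_species <- function(cfg) {
  # Target marine species for both markers, with assemblage membership,
  # taxonomy, group and planted ASV multiplicity.
  sp <- list()
  add <- function(marker, assemblage, idx, shared) {
    tag <- if (marker == "12S") "V" else "I"
    id <- sprintf("sp%s_%s_%02d", tag,
                  if (shared) "shared" else paste0("a", assemblage), idx)
    list(species_id = id, marker = marker, assemblage = assemblage,
         shared = shared)
  }
  for (k in seq_len(cfg$K)) {
    n_sh_v <- round(cfg$species_vert * cfg$overlap)
    n_sh_i <- round(cfg$species_invert * cfg$overlap)
    for (i in seq_len(cfg$species_vert - n_sh_v))
      sp[[length(sp) + 1L]] <- add("12S", k, i, FALSE)
    for (i in seq_len(cfg$species_invert - n_sh_i))
      sp[[length(sp) + 1L]] <- add("COI", k, i, FALSE)
  }
  # shared background pool: members of every assemblage
  n_sh_v <- round(cfg$species_vert * cfg$overlap)
  n_sh_i <- round(cfg$species_invert * cfg$overlap)
  for (i in seq_len(n_sh_v)) sp[[length(sp) + 1L]] <- add("12S", 0L, i, TRUE)
  for (i in seq_len(n_sh_i)) sp[[length(sp) + 1L]] <- add("COI", 0L, i, TRUE)
  df <- do.call(rbind, lapply(sp, as.data.frame))
  df$species_id <- as.character(df$species_id)
  df$marker <- as.character(df$marker)
  df
}

species_lineage <- function(species_id, marker, order_name, series_name,
                            species_level, binomial) {
  l <- stats::setNames(rep("", length(taxonomy_ranks())), taxonomy_ranks())
  l["kingdom"] <- "Animalia"
  if (marker == "12S") {
    l["phylum"] <- "Chordata"; l["subphylum"] <- "Vertebrata"
    l["class"] <- "Actinopterygii"
    l["order"] <- order_name; l["series"] <- series_name
  } else {
    i <- match(order_name, INVERT_POOL$order)
    l["phylum"] <- INVERT_POOL$phylum[i]
    l["subphylum"] <- INVERT_POOL$subphylum[i]
    l["class"] <- INVERT_POOL$class[i]
    l["order"] <- INVERT_POOL$order[i]
  }
  if (species_level) {
    g <- sub(" .*$", "", binomial)
    l["family"] <- paste0(g, "idae")
    l["genus"] <- g
    l["species"] <- binomial
  }
  l
}

#' Generate a complete synthetic dataset with ground truth
#'
#' Produces ASV count tables for both markers, a taxonomy table, sample
#' metadata (including negative controls), a co-located trawl catch table,
#' and a truth record. Per environmental sample, the latent community is
#' the assemblage species pool weighted by spatial and depth kernels;
#' species occurrences are Bernoulli; occupied species emit reads over
#' their ASVs via a symmetric Dirichlet allocation within a
#' negative-binomial sample total; controls receive reads only from
#' planted contaminant ASVs; DNA concentration decays exponentially with
#' depth and is floored at the below-detection sentinel. The seed fixes
#' the entire dataset.
#'
#' @param config A [synthetic_config()].
#' @return List with elements `asv` (named list of [asv_table()]s),
#'   `taxonomy`, `metadata`, `trawl`, `truth`, `config`.
#' @export
generate_dataset <- function(config = synthetic_config()) {
  cfg <- config
  set.seed(cfg$seed)

  ## --- stations, samples, metadata -------------------------------------
  n_st <- cfg$n_stations
  if (cfg$station_placement == "assemblage") {
    st_k <- rep_len(seq_len(cfg$K), n_st)
    st_lon <- pmin(pmax(cfg$assemblage_centers$lon[st_k] +
                          stats::rnorm(n_st, 0, cfg$spatial_sd),
                        cfg$lon_range[1]), cfg$lon_range[2])
    st_lat <- pmin(pmax(cfg$assemblage_centers$lat[st_k] +
                          stats::rnorm(n_st, 0, cfg$spatial_sd),
                        cfg$lat_range[1]), cfg$lat_range[2])
  } else {
    st_lon <- stats::runif(n_st, cfg$lon_range[1], cfg$lon_range[2])
    st_lat <- stats::runif(n_st, cfg$lat_range[1], cfg$lat_range[2])
  }
  st_cruise <- paste0("CR", rep_len(seq_len(cfg$n_cruises), n_st))
  st_day <- sample.int(30, n_st, replace = TRUE)
  night <- stats::runif(n_st) < cfg$night_frac
  st_hour <- ifelse(night, (20 + stats::runif(n_st, 0, 8)) %% 24,
                    stats::runif(n_st, 0, 24))
  ndep <- rep_len(cfg$depths_per_station, n_st)

  rows <- list()
  for (s in seq_len(n_st)) {
    deps <- sort(rdepths(ndep[s], cfg$depth_profile))
    for (d in deps) {
      rows[[length(rows) + 1L]] <- data.frame(
        station = s, latitude = round(st_lat[s], 4),
        longitude = round(st_lon[s], 4), depth = round(d, 1),
        cruise = st_cruise[s], day = st_day[s], hour = st_hour[s],
        noise = FALSE)
    }
  }
  for (i in seq_len(cfg$n_noise_samples)) {
    rows[[length(rows) + 1L]] <- data.frame(
      station = NA, latitude = round(stats::runif(1, cfg$lat_range[1],
                                                  cfg$lat_range[2]), 4),
      longitude = round(stats::runif(1, cfg$lon_range[1],
                                     cfg$lon_range[2]), 4),
      depth = round(rdepths(1, cfg$depth_profile), 1),
      cruise = paste0("CR", rep_len(seq_len(cfg$n_cruises),
                                    cfg$n_noise_samples)[i]),
      day = sample.int(30, 1), hour = stats::runif(1, 0, 24),
      noise = TRUE)
  }
  env <- do.call(rbind, rows)
  n_env <- nrow(env)
  env$sample_id <- sprintf("S%04d", seq_len(n_env))
  base_date <- as.POSIXct("2021-07-01 00:00:00", tz = "UTC")
  env$timestamp <- base_date + (env$day - 1) * 86400 +
    round(env$hour * 3600)
  env$volume <- round(stats::runif(n_env, 360, 1800), -1)

  conc <- cfg$dna_surface * exp(-env$depth / cfg$dna_efold) +
    stats::rnorm(n_env, 0, cfg$dna_noise_sd)
  bd <- conc < cfg$dna_bd
  conc <- round(pmax(conc, cfg$dna_bd), 3)

  ctl_counts <- rep_len(cfg$controls_per_cruise, cfg$n_cruises)
  ctl <- do.call(rbind, lapply(seq_len(cfg$n_cruises), function(cr)
    if (ctl_counts[cr] > 0)
      data.frame(cruise = paste0("CR", cr), idx = seq_len(ctl_counts[cr]))
    else NULL))
  n_ctl <- nrow(ctl)
  ctl_ids <- sprintf("CTL%02d", seq_len(n_ctl))

  day0 <- function(ts) trunc(ts, "days")
  meta_df <- data.frame(
    sample_id = c(env$sample_id, ctl_ids),
    cruise = c(env$cruise, ctl$cruise),
    latitude = c(env$latitude, rep(mean(cfg$lat_range), n_ctl)),
    longitude = c(env$longitude, rep(mean(cfg$lon_range), n_ctl)),
    depth = c(env$depth, rep(NA_real_, n_ctl)),
    volume = c(env$volume, rep(1000, n_ctl)),
    timestamp = c(env$timestamp,
                  base_date + sample.int(30, n_ctl, TRUE) * 86400 + 43200),
    is_control = c(rep(FALSE, n_env), rep(TRUE, n_ctl)),
    dna_concentration = c(ifelse(bd, BD_TOKEN, as.character(conc)),
                          rep(BD_TOKEN, n_ctl)),
    stringsAsFactors = FALSE)
  meta_df$sunrise <- fmt_utc(day0(as_utc(meta_df$timestamp)) + 6 * 3600)
  meta_df$sunset <- fmt_utc(day0(as_utc(meta_df$timestamp)) + 18 * 3600)
  meta_df$timestamp <- fmt_utc(as_utc(meta_df$timestamp))
  metadata <- sample_metadata(meta_df)

  ## --- species pools, taxonomy, ASV maps -------------------------------
  species <- make_species(cfg)
  n_sp <- nrow(species)
  deep_assemblage <- cfg$assemblage_centers$depth > 200
  sp_deep <- ifelse(species$assemblage == 0, FALSE,
                    deep_assemblage[pmax(species$assemblage, 1)])
  p_sp_level <- ifelse(sp_deep, cfg$species_level_prob_deep,
                       cfg$species_level_prob_shallow)
  species$species_level <- stats::runif(n_sp) < p_sp_level
  # orders: vertebrates drawn from the order pool with an occasional
  # series-only lineage; invertebrates from the invertebrate pool
  is_v <- species$marker == "12S"
  species$order <- NA_character_
  species$series <- ""
  v_idx <- which(is_v)
  ser <- stats::runif(length(v_idx)) < 0.1
  species$order[v_idx] <- ifelse(
    ser, "", sample(VERT_ORDERS, length(v_idx), replace = TRUE))
  species$series[v_idx] <- ifelse(
    ser, sample(VERT_SERIES, length(v_idx), replace = TRUE), "")
  i_idx <- which(!is_v)
  species$order[i_idx] <- sample(INVERT_POOL$order[INVERT_POOL$order != ""],
                                 length(i_idx), replace = TRUE)
  species$binomial <- sprintf("%s %s",
                              paste0("Genus", gsub("[^0-9A-Za-z]", "",
                                                   species$species_id)),
                              "simulatus")
  # COI vertebrate bycatch species (removed later by clade filtering)
  n_by <- cfg$coi_vert_species
  if (n_by > 0) {
    by <- data.frame(
      species_id = sprintf("spB_%02d", seq_len(n_by)), marker = "COI",
      assemblage = sample.int(cfg$K, n_by, replace = TRUE), shared = FALSE,
      species_level = TRUE,
      order = sample(VERT_ORDERS, n_by, replace = TRUE), series = "",
      binomial = sprintf("Genusbycatch%d simulatus", seq_len(n_by)),
      stringsAsFactors = FALSE)
    by$vertebrate_bycatch <- TRUE
    species$vertebrate_bycatch <- FALSE
    species <- rbind(species, by)
  } else species$vertebrate_bycatch <- FALSE
  n_sp <- nrow(species)

  # ASV multiplicity
  n_asvs <- integer(n_sp)
  v <- species$marker == "12S"
  n_asvs[v] <- 1L + stats::rpois(sum(v), cfg$vert_asv_mean - 1)
  n_asvs[!v] <- pmax(1L, round(stats::rlnorm(sum(!v),
                                             cfg$invert_asv_meanlog,
                                             cfg$invert_asv_sdlog)))
  asv_map <- data.frame(
    asv_id = unlist(lapply(seq_len(n_sp), function(i)
      sprintf("ASV_%s_%s_%02d", species$marker[i], species$species_id[i],
              seq_len(n_asvs[i])))),
    species_id = rep(species$species_id, n_asvs),
    marker = rep(species$marker, n_asvs), stringsAsFactors = FALSE)

  # taxonomy records for target species ASVs
  tax_rows <- lapply(seq_len(nrow(asv_map)), function(i) {
    si <- match(asv_map$species_id[i], species$species_id)
    mk <- if (species$vertebrate_bycatch[si]) "12S" else species$marker[si]
    c(record_id = asv_map$asv_id[i],
      species_lineage(species$species_id[si], mk,
                      species$order[si], species$series[si],
                      species$species_level[si], species$binomial[si]))
  })

  # non-marine contaminant ASVs
  nonmarine <- list()
  for (mk in c("12S", "COI")) {
    for (i in seq_len(cfg$n_nonmarine)) {
      id <- sprintf("ASV_%s_NM_%02d", mk, i)
      l <- stats::setNames(rep("", length(taxonomy_ranks())),
                           taxonomy_ranks())
      l["kingdom"] <- "Animalia"
      if (mk == "12S") {
        pick <- (i - 1L) %% 3L + 1L
        l["phylum"] <- "Chordata"; l["subphylum"] <- "Vertebrata"
        l["class"] <- "Mammalia"
        l["order"] <- c("Primates", "Rodentia", "Chiroptera")[pick]
        l["genus"] <- c("Homo", "Mus", "Myotis")[pick]
        l["species"] <- c("Homo sapiens", "Mus musculus",
                          "Myotis simulatus")[pick]
      } else {
        pick <- (i - 1L) %% 3L + 1L
        bl <- c("Bathymodiolus japonicus", "Saccostrea malabonensis",
                "Abyssogena phaseoliformis")[pick]
        l["phylum"] <- "Mollusca"; l["class"] <- "Bivalvia"
        l["order"] <- "Mytilida"
        l["genus"] <- sub(" .*$", "", bl); l["species"] <- bl
      }
      nonmarine[[length(nonmarine) + 1L]] <-
        c(record_id = id, l, marker = mk)
    }
  }
  nonmarine_ids <- vapply(nonmarine, function(z) z[["record_id"]],
                          character(1))
  nonmarine_mk <- vapply(nonmarine, function(z) z[["marker"]],
                         character(1))
  tax_rows <- c(tax_rows, lapply(nonmarine, function(z)
    z[names(z) != "marker"]))

  # control-shared contaminant ASVs (no taxonomic assignment)
  contam <- data.frame(
    asv_id = c(sprintf("ASV_12S_C_%02d", seq_len(cfg$n_control_asvs)),
               sprintf("ASV_COI_C_%02d", seq_len(cfg$n_control_asvs))),
    marker = rep(c("12S", "COI"), each = cfg$n_control_asvs),
    stringsAsFactors = FALSE)
  tax_rows <- c(tax_rows, lapply(contam$asv_id, function(id)
    c(record_id = id,
      stats::setNames(rep("", length(taxonomy_ranks())),
                      taxonomy_ranks()))))

  # series-only and genus-gap lineages are intentional (sparse reference
  # libraries); the reader-level warning is not useful here
  taxonomy <- suppressWarnings(taxonomy_table(
    as.data.frame(do.call(rbind, tax_rows), stringsAsFactors = FALSE)))

  ## --- occupancy and reads ---------------------------------------------
  centers <- cfg$assemblage_centers
  ksd <- cfg$spatial_sd * cfg$kernel_softening
  kern <- function(lat, lon, depth) {
    exp(-((lat - centers$lat)^2 + (lon - centers$lon)^2) / (2 * ksd^2)) *
      exp(-(log(depth) - log(centers$depth))^2 / (2 * cfg$depth_sd^2))
  }
  truth_assemblage <- character(n_env)
  occupancy <- matrix(FALSE, n_sp, n_env,
                      dimnames = list(species$species_id, env$sample_id))
  for (i in seq_len(n_env)) {
    if (env$noise[i]) {
      truth_assemblage[i] <- "noise"
      occupancy[, i] <- stats::runif(n_sp) < cfg$p_noise
      next
    }
    w <- kern(env$latitude[i], env$longitude[i], env$depth[i])
    truth_assemblage[i] <- paste0("A", which.max(w))
    p <- ifelse(species$assemblage == 0 |
                  species$assemblage == which.max(w),
                cfg$p_out + (cfg$p_in - cfg$p_out) * max(w), cfg$p_out)
    occupancy[, i] <- stats::runif(n_sp) < p
  }
  names(truth_assemblage) <- env$sample_id

  build_counts <- function(mk) {
    sp_idx <- which(species$marker == mk)
    amap <- asv_map[asv_map$marker == mk, ]
    asv_by_sp <- split(amap$asv_id, amap$species_id)
    nm_ids <- nonmarine_ids[nonmarine_mk == mk]
    cc <- contam$asv_id[contam$marker == mk]
    all_asvs <- c(amap$asv_id, nm_ids, cc)
    counts <- matrix(0L, length(all_asvs), n_env + n_ctl,
                     dimnames = list(all_asvs,
                                     c(env$sample_id, ctl_ids)))
    read_mean <- if (mk == "12S") cfg$read_mean_12S else cfg$read_mean_COI
    fail_p <- if (mk == "12S") cfg$read_fail_prob_12S
              else cfg$read_fail_prob_COI
    for (i in seq_len(n_env)) {
      occ_sp <- species$species_id[sp_idx][occupancy[sp_idx, i]]
      nm_on <- nm_ids[stats::runif(length(nm_ids)) < 0.25]
      cc_on <- cc[stats::runif(length(cc)) < cfg$contam_prob]
      units <- c(occ_sp, nm_on, cc_on)
      if (length(units) == 0) next
      total <- if (stats::runif(1) < fail_p)
        stats::rnbinom(1, size = 1, mu = 300)
      else stats::rnbinom(1, size = cfg$read_size, mu = read_mean)
      if (total == 0) next
      # symmetric Dirichlet over units, then over each species' ASVs
      wu <- stats::rgamma(length(units), 1)
      wa <- numeric(0); ids <- character(0)
      for (u in seq_along(units)) {
        if (!is.null(asv_by_sp[[units[u]]])) {
          a <- asv_by_sp[[units[u]]]
          va <- stats::rgamma(length(a), 1)
          wa <- c(wa, wu[u] * va / sum(va)); ids <- c(ids, a)
        } else {
          wa <- c(wa, wu[u]); ids <- c(ids, units[u])
        }
      }
      counts[ids, i] <- as.integer(stats::rmultinom(1, total,
                                                    wa / sum(wa)))
    }
    for (j in seq_len(n_ctl)) {
      if (length(cc) == 0) next
      total <- stats::rnbinom(1, size = 1, mu = read_mean / 10)
      if (total == 0) total <- 50L
      wu <- stats::rgamma(length(cc), 1)
      counts[cc, n_env + j] <- as.integer(stats::rmultinom(1, total, wu))
    }
    asv_table(counts, mk)
  }
  asv <- list("12S" = build_counts("12S"), "COI" = build_counts("COI"))

  ## --- trawl -----------------------------------------------------------
  tr_st <- utils::head(order(st_lon), cfg$trawl_stations)
  if (is.null(cfg$catchability)) {
    catch <- stats::setNames(rep(1, nrow(INVERT_POOL)), INVERT_POOL$order)
    catch[c("Siphonophorae", "Trachymedusae", "Leptothecata",
            "Limnomedusae", "Semaeostomeae")] <- 0.4
  } else catch <- cfg$catchability
  trawl_rows <- list()
  trawl_only <- list()
  to_orders <- c("Ctenophora-ord", "Nemertea-ord", "Mysida", "Isopoda")
  for (i in seq_len(cfg$n_trawl_only)) {
    id <- sprintf("trawlTaxon%02d", i)
    l <- stats::setNames(rep("", length(taxonomy_ranks())),
                         taxonomy_ranks())
    l["kingdom"] <- "Animalia"
    l["phylum"] <- c("Ctenophora", "Nemertea", "Arthropoda",
                     "Arthropoda")[(i - 1L) %% 4L + 1L]
    l["order"] <- to_orders[(i - 1L) %% 4L + 1L]
    trawl_only[[i]] <- c(record_id = id, l)
  }
  if (length(trawl_only) > 0)
    taxonomy <- suppressWarnings(taxonomy_table(rbind(
      as.data.frame(taxonomy)[, c("record_id", taxonomy_ranks())],
      as.data.frame(do.call(rbind, trawl_only),
                    stringsAsFactors = FALSE))))
  net_i <- 0L
  for (s in tr_st) {
    for (st_i in seq_len(nrow(cfg$trawl_strata))) {
      net_i <- net_i + 1L
      dmin <- cfg$trawl_strata$depth_min[st_i]
      dmax <- cfg$trawl_strata$depth_max[st_i]
      dmid <- max((dmin + dmax) / 2, 10)
      w <- kern(st_lat[s], st_lon[s], dmid)
      for (si in seq_len(nrow(species))) {
        if (species$marker[si] == "12S" && stats::runif(1) > 0.5) next
        p <- ifelse(species$assemblage[si] %in% c(0, which.max(w)),
                    cfg$p_out + (cfg$p_in - cfg$p_out) * max(w), cfg$p_out)
        co <- species$order[si]
        cmult <- if (nzchar(co) && co %in% names(catch)) catch[[co]] else 1
        cnt <- stats::rpois(1, 8 * p * cmult)
        if (cnt > 0) {
          # trawl identifications are species-level taxa; reuse the first
          # ASV id's record as the taxon when species-assigned
          tid <- asv_map$asv_id[asv_map$species_id ==
                                  species$species_id[si]][1L]
          trawl_rows[[length(trawl_rows) + 1L]] <- data.frame(
            net_id = sprintf("NET%02d", net_i), taxon_id = tid,
            count = cnt, depth_min = dmin, depth_max = dmax,
            latitude = round(st_lat[s], 4),
            longitude = round(st_lon[s], 4),
            timestamp = fmt_utc(base_date + st_day[s] * 86400 + 6 * 3600),
            stringsAsFactors = FALSE)
        }
      }
      for (ti in seq_along(trawl_only)) {
        cnt <- stats::rpois(1, 2)
        if (cnt > 0)
          trawl_rows[[length(trawl_rows) + 1L]] <- data.frame(
            net_id = sprintf("NET%02d", net_i),
            taxon_id = trawl_only[[ti]][["record_id"]], count = cnt,
            depth_min = dmin, depth_max = dmax,
            latitude = round(st_lat[s], 4),
            longitude = round(st_lon[s], 4),
            timestamp = fmt_utc(base_date + st_day[s] * 86400 + 6 * 3600),
            stringsAsFactors = FALSE)
      }
    }
  }
  trawl <- trawl_table(do.call(rbind, trawl_rows), taxonomy)

  truth <- list(
    assemblage = truth_assemblage,
    species = species,
    asv_map = asv_map,
    contaminant_asvs = contam$asv_id,
    nonmarine_asvs = nonmarine_ids,
    coi_vertebrate_species = species$species_id[species$vertebrate_bycatch],
    species_level_prob = c(shallow = cfg$species_level_prob_shallow,
                           deep = cfg$species_level_prob_deep),
    trawl_sites = data.frame(zone = paste0("Z", seq_along(tr_st)),
                             latitude = st_lat[tr_st],
                             longitude = st_lon[tr_st]))
  list(asv = asv, taxonomy = taxonomy, metadata = metadata, trawl = trawl,
       truth = truth, config = cfg)
}

#' Write a synthetic dataset to a directory
#'
#' Writes the marker ASV tables (TSV), taxonomy/metadata/trawl (CSV) and
#' the ground truth (JSON) in the package's on-disk formats.
#'
#' @param data Result of [generate_dataset()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synthetic_dataset <- function(data, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_asv_table(data$asv[["12S"]], file.path(dir, "asv_12S.tsv"))
  write_asv_table(data$asv[["COI"]], file.path(dir, "asv_COI.tsv"))
  write_taxonomy(data$taxonomy, file.path(dir, "taxonomy.csv"))
  write_sample_metadata(data$metadata, file.path(dir, "metadata.csv"))
  write_trawl_table(data$trawl, file.path(dir, "trawl.csv"))
  truth <- data$truth
  truth$assemblage <- as.list(truth$assemblage)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(dir)
}
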