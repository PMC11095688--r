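# Small in-code fixtures shared across test files.

tiny_counts <- function() {
  m <- matrix(c(10L, 0L, 3L,
                0L, 5L, 2L,
                1L, 1L, 0L,
                0L, 0L, 7L), nrow = 4, byrow = TRUE,
              dimnames = list(paste0("ASV", 1:4), paste0("S", 1:3)))
  m
}

tiny_taxonomy <- function() {
  # ASV4's sparse hydrozoan lineage intentionally has rank gaps
  suppressWarnings(taxonomy_table(data.frame(
    record_id = paste0("ASV", 1:4),
    kingdom = "Animalia",
    phylum = c("Chordata", "Chordata", "Arthropoda", "Cnidaria"),
    subphylum = c("Vertebrata", "Vertebrata", "Crustacea", ""),
    class = c("Actinopterygii", "Actinopterygii", "Copepoda", "Hydrozoa"),
    order = c("Myctophiformes", "Clupeiformes", "Calanoida",
              "Siphonophorae"),
    series = "",
    family = c("Myctophidae", "Engraulidae", "Calanidae", ""),
    genus = c("Symbolophorus", "Engraulis", "Calanus", ""),
    species = c("Symbolophorus californiensis", "Engraulis mordax",
                "Calanus pacificus", ""),
    stringsAsFactors = FALSE)))
}

tiny_metadata <- function() {
  sample_metadata(data.frame(
    sample_id = c("S1", "S2", "S3", "C1"),
    cruise = c("CR1", "CR1", "CR2", "CR1"),
    latitude = c(33.0, 32.5, 30.1, 33.0),
    longitude = c(-120.8, -119.0, -124.7, -120.0),
    depth = c(70, 250, 800, NA),
    volume = c(990, 1000, 360, 1000),
    timestamp = c("2021-07-03T20:00:00", "2021-07-03T12:00:00",
                  "2021-07-04T05:00:00", "2021-07-03T12:00:00"),
    is_control = c(FALSE, FALSE, FALSE, TRUE),
    dna_concentration = c("1.5", "0.8", "BD", "BD"),
    sunrise = c("2021-07-03T06:00:00", "2021-07-03T06:00:00",
                "2021-07-04T06:00:00", "2021-07-03T06:00:00"),
    sunset = c("2021-07-03T18:00:00", "2021-07-03T18:00:00",
               "2021-07-04T18:00:00", "2021-07-03T18:00:00"),
    stringsAsFactors = FALSE))
}

# metadata builder for decontamination fixtures: env samples + controls
# with explicit cruises
meta_for <- function(sample_ids, cruises, controls = logical(
                       length(sample_ids))) {
  sample_metadata(data.frame(
    sample_id = sample_ids, cruise = cruises,
    latitude = 32, longitude = -120,
    depth = ifelse(controls, NA, 100), volume = 1000,
    timestamp = "2021-07-03T12:00:00", is_control = controls,
    dna_concentration = "1.0", stringsAsFactors = FALSE))
}

# deterministic random count matrix
random_counts <- function(n_asv, n_samp, seed = 42, lambda = 20) {
  set.seed(seed)
  m <- matrix(rpois(n_asv * n_samp, lambda), n_asv,
              dimnames = list(paste0("ASV", seq_len(n_asv)),
                              paste0("S", seq_len(n_samp))))
  storage.mode(m) <- "integer"
  m
}

# distance matrix from 1-D coordinates
dist1d <- function(x) {
  D <- as.matrix(stats::dist(matrix(x, ncol = 1)))
  dimnames(D) <- list(paste0("u", seq_along(x)), paste0("u", seq_along(x)))
  D
}

# block presence matrix: k blocks of n_per samples sharing a species set,
# within-block species detected with prob p_in, others with p_out
block_presence <- function(k = 3, n_per = 10, sp_per = 15, p_in = 0.95,
                           p_out = 0.02, seed = 11) {
  set.seed(seed)
  n <- k * n_per
  m <- matrix(FALSE, n, k * sp_per,
              dimnames = list(sprintf("s%02d", 1:n),
                              sprintf("sp%02d", 1:(k * sp_per))))
  for (b in seq_len(k)) {
    rows <- (b - 1) * n_per + seq_len(n_per)
    for (i in rows)
      m[i, ] <- runif(k * sp_per) <
        ifelse(rep(seq_len(k * sp_per), 1) %in%
                 ((b - 1) * sp_per + seq_len(sp_per)), p_in, p_out)
  }
  m
}

separable_run <- function(seed = 1, marker = "12S") {
  cfg <- synthetic_preset("separable-3")
  cfg$seed <- seed
  d <- suppressWarnings(generate_dataset(cfg))
  dec <- suppressWarnings(decontaminate(d$asv[[marker]], d$taxonomy,
                                        d$metadata))
  diel <- stats::setNames(
    classify_diel(d$metadata$timestamp, d$metadata$sunrise,
                  d$metadata$sunset), d$metadata$sample_id)
  pres <- suppressMessages(build_presence_matrix(
    dec$table, d$taxonomy, min_samples = 3,
    drop_clades = list(list(rank = "class", name = "Mammalia"),
                       list(rank = "class", name = "Aves")),
    diel = diel, diel_filter = "night"))
  list(data = d, decon = dec, presence = pres)
}
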