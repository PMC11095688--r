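SCHEMA_LINE <- "#schema=edna-assemblage/v1"

#' Recognized taxonomic ranks, highest to lowest
#'
#' The ordered rank ladder used by every taxonomy-aware operation in the
#' package. `series` sits between order and family because some fish orders
#' are incertae sedis and only resolvable at the series level.
#'
#' @return Character vector of rank names, highest first.
#' @export
taxonomy_ranks <- function() {
  c("kingdom", "phylum", "subphylum", "class", "order", "series",
    "family", "genus", "species")
}

#' Construct an ASV count table
#'
#' The central observational unit: a non-negative integer read-count matrix
#' with ASVs as rows and samples as columns, tagged with the marker gene
#' ("12S" for vertebrates, "COI" for invertebrates).
#'
#' @param counts Integer matrix, ASVs x samples, with unique non-empty
#'   dimnames.
#' @param marker One of "12S", "COI".
#' @return An object of class `asv_table`.
#' @export
asv_table <- function(counts, marker = c("12S", "COI")) {
  marker <- match.arg(marker)
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have ASV rownames and sample colnames")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate ASV ids: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]),
               collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]),
               collapse = ", "))
  if (any(is.na(counts)) || any(counts < 0))
    stop("counts must be non-negative and non-missing")
  if (any(counts != round(counts)))
    stop("counts must be integers")
  storage.mode(counts) <- "integer"
  structure(list(marker = marker, counts = counts), class = "asv_table")
}

#' @export
print.asv_table <- function(x, ...) {
  cat(sprintf("ASV count table [%s]: %d ASVs x %d samples, %s reads\n",
              x$marker, nrow(x$counts), ncol(x$counts),
              format(sum(as.numeric(x$counts)), big.mark = ",")))
  invisible(x)
}

#' @export
dim.asv_table <- function(x) dim(x$counts)

# Read non-comment lines of a delimited file, returning the text and any
# "#key=value" header directives.
read_body <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^#", lines, value = TRUE)
  directives <- list()
  for (h in hdr) {
    kv <- sub("^#", "", h)
    if (grepl("=", kv, fixed = TRUE)) {
      k <- sub("=.*$", "", kv)
      directives[[k]] <- sub("^[^=]*=", "", kv)
    }
  }
  list(text = paste(lines[!grepl("^#", lines)], collapse = "\n"),
       directives = directives)
}

#' Read an ASV count table from TSV
#'
#' First column is the ASV id; remaining columns are sample ids; cells are
#' integer read counts. Lines starting with `#` are header directives; a
#' `#orientation=samples_x_asvs` directive makes the reader transpose.
#'
#' @param path Path to a tab-separated file.
#' @param marker Marker label ("12S" or "COI").
#' @return An [asv_table()].
#' @export
read_asv_table <- function(path, marker = c("12S", "COI")) {
  marker <- match.arg(marker)
  if (!file.exists(path)) stop("file not found: ", path)
  body <- read_body(path)
  df <- utils::read.table(text = body$text, sep = "\t", header = TRUE,
                          check.names = FALSE, colClasses = "character",
                          quote = "")
  ids <- df[[1L]]
  m <- as.matrix(df[, -1L, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(m), nrow = nrow(m),
                                 dimnames = list(ids, colnames(m))))
  bad <- which(is.na(num) | num < 0 | num != round(num), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    i <- bad[1, 1]; j <- bad[1, 2]
    stop(sprintf("invalid count at ASV '%s', sample '%s': '%s'",
                 ids[i], colnames(num)[j], m[i, j]))
  }
  if (identical(body$directives$orientation, "samples_x_asvs"))
    num <- t(num)
  asv_table(num, marker)
}

#' Write an ASV count table to TSV
#'
#' @param x An [asv_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_asv_table <- function(x, path) {
  stopifnot(inherits(x, "asv_table"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(SCHEMA_LINE, paste0("#marker=", x$marker)), con)
  df <- data.frame(asv_id = rownames(x$counts), x$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a taxonomy table
#'
#' Maps each record (ASV or trawl taxon) to a ranked lineage. The deepest
#' assigned rank is computed from the lineage. A name below an empty higher
#' rank is accepted with a warning (reference-library lineages are often
#' sparse) and the empty rank treated as unranked.
#'
#' @param df Data frame with a `record_id` column plus one column per rank in
#'   [taxonomy_ranks()] (empty string or NA = unassigned).
#' @return Data frame of class `taxonomy_table` with a `deepest_rank` column.
#' @export
taxonomy_table <- function(df) {
  ranks <- taxonomy_ranks()
  if (!"record_id" %in% names(df)) stop("missing column 'record_id'")
  unknown <- setdiff(names(df), c("record_id", ranks, "deepest_rank"))
  if (length(unknown) > 0)
    stop("unknown rank column(s): ", paste(unknown, collapse = ", "))
  for (r in ranks) {
    if (!r %in% names(df)) df[[r]] <- ""
    df[[r]] <- ifelse(is.na(df[[r]]), "", as.character(df[[r]]))
  }
  if (anyDuplicated(df$record_id))
    stop("duplicate record ids in taxonomy")
  lin <- as.matrix(df[, ranks, drop = FALSE])
  filled <- lin != ""
  deepest <- apply(filled, 1L, function(z) {
    w <- which(z)
    if (length(w) == 0) "" else ranks[max(w)]
  })
  # a gap is an empty rank between the highest and deepest filled ranks;
  # absent top ranks (e.g., no kingdom) are ordinary truncation
  gap <- apply(filled, 1L, function(z) {
    w <- which(z)
    length(w) > 0 && any(!z[seq.int(min(w), max(w))])
  })
  if (any(gap))
    warning(sprintf(
      "%d record(s) have a named rank below an unassigned higher rank (treated as unranked): %s",
      sum(gap), paste(utils::head(df$record_id[gap], 5L), collapse = ", ")))
  df <- df[, c("record_id", ranks)]
  df$deepest_rank <- deepest
  class(df) <- c("taxonomy_table", "data.frame")
  df
}

#' Read a taxonomy table from CSV
#'
#' @param path CSV path with columns `record_id` plus the ranks in
#'   [taxonomy_ranks()]; empty cells mean unassigned.
#' @return A [taxonomy_table()].
#' @export
read_taxonomy <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  body <- read_body(path)
  df <- utils::read.csv(text = body$text, check.names = FALSE,
                        colClasses = "character")
  taxonomy_table(df)
}

#' Write a taxonomy table to CSV
#' @param x A [taxonomy_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_taxonomy <- function(x, path) {
  stopifnot(inherits(x, "taxonomy_table"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(SCHEMA_LINE, con)
  utils::write.csv(x[, c("record_id", taxonomy_ranks())], con,
                   row.names = FALSE, quote = TRUE)
  invisible(path)
}

BD_TOKEN <- "BD"

#' Construct a sample metadata table
#'
#' Per-sample position, depth, filtered volume, UTC timestamp, control flag
#' and measured DNA concentration. A below-detection concentration is carried
#' as the sentinel token `"BD"` on disk and as `NA` concentration with
#' `dna_below_detection = TRUE` in memory; such samples are excluded from
#' analyses rather than zeroed.
#'
#' @param df Data frame with columns `sample_id`, `cruise`, `latitude`,
#'   `longitude`, `depth`, `volume`, `timestamp`, `is_control`,
#'   `dna_concentration`; optional `sunrise`, `sunset`.
#' @return Data frame of class `sample_metadata`.
#' @export
sample_metadata <- function(df) {
  need <- c("sample_id", "cruise", "latitude", "longitude", "depth",
            "volume", "timestamp", "is_control", "dna_concentration")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("missing mandatory column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id)) stop("duplicate sample ids")
  df$is_control <- as.logical(df$is_control)
  for (col in c("latitude", "longitude", "depth", "volume"))
    df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
  conc_raw <- as.character(df$dna_concentration)
  bd <- !is.na(conc_raw) & conc_raw == BD_TOKEN
  df$dna_concentration <- suppressWarnings(as.numeric(ifelse(bd, NA, conc_raw)))
  df$dna_below_detection <- bd
  df$timestamp <- as_utc(df$timestamp)
  for (col in c("sunrise", "sunset")) {
    df[[col]] <- if (col %in% names(df)) as_utc(df[[col]])
                 else as.POSIXct(rep(NA_real_, nrow(df)), tz = "UTC",
                                 origin = "1970-01-01")
  }
  bad_lat <- !is.na(df$latitude) & abs(df$latitude) > 90
  if (any(bad_lat))
    stop("latitude out of [-90, 90] for sample(s): ",
         paste(df$sample_id[bad_lat], collapse = ", "))
  bad_lon <- !is.na(df$longitude) & abs(df$longitude) > 180
  if (any(bad_lon))
    stop("longitude out of [-180, 180] for sample(s): ",
         paste(df$sample_id[bad_lon], collapse = ", "))
  env <- !df$is_control
  bad_vol <- env & (is.na(df$volume) | df$volume <= 0)
  if (any(bad_vol))
    stop("environmental sample(s) with volume <= 0 or missing: ",
         paste(df$sample_id[bad_vol], collapse = ", "))
  class(df) <- c("sample_metadata", "data.frame")
  df
}

as_utc <- function(x) {
  if (inherits(x, "POSIXct")) {
    attr(x, "tzone") <- "UTC"
    return(x)
  }
  as.POSIXct(as.character(x), tz = "UTC",
             tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S",
                            "%Y-%m-%d %H:%M", "%Y-%m-%d"))
}

fmt_utc <- function(x) {
  ifelse(is.na(x), "", format(x, "%Y-%m-%dT%H:%M:%S", tz = "UTC"))
}

#' Read sample metadata from CSV
#' @param path CSV path; timestamps ISO-8601 UTC; below-detection DNA
#'   concentration encoded as `BD`.
#' @return A [sample_metadata()] table.
#' @export
read_sample_metadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  body <- read_body(path)
  df <- utils::read.csv(text = body$text, check.names = FALSE,
                        colClasses = "character")
  sample_metadata(df)
}

#' Write sample metadata to CSV
#' @param x A [sample_metadata()] table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sample_metadata <- function(x, path) {
  stopifnot(inherits(x, "sample_metadata"))
  out <- data.frame(
    sample_id = x$sample_id, cruise = x$cruise,
    latitude = fmt_num(x$latitude), longitude = fmt_num(x$longitude),
    depth = fmt_num(x$depth), volume = fmt_num(x$volume),
    timestamp = fmt_utc(x$timestamp),
    is_control = tolower(as.character(x$is_control)),
    dna_concentration = ifelse(x$dna_below_detection, BD_TOKEN,
                               fmt_num(x$dna_concentration)),
    sunrise = fmt_utc(x$sunrise), sunset = fmt_utc(x$sunset),
    stringsAsFactors = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(SCHEMA_LINE, con)
  utils::write.csv(out, con, row.names = FALSE, quote = TRUE)
  invisible(path)
}

# 10 significant digits keeps float round-trips stable without printing noise
fmt_num <- function(x) ifelse(is.na(x), "", formatC(x, digits = 10,
                                                    format = "g"))

#' Construct a trawl catch table
#'
#' Depth-discrete net samples (e.g., MOCNESS) with per-taxon individual
#' counts, net depth range and position.
#'
#' @param df Data frame with columns `net_id`, `taxon_id`, `count`,
#'   `depth_min`, `depth_max`, `latitude`, `longitude`, `timestamp`.
#' @param taxonomy Optional [taxonomy_table()]; when given, taxon ids absent
#'   from it trigger a warning.
#' @return Data frame of class `trawl_table`.
#' @export
trawl_table <- function(df, taxonomy = NULL) {
  need <- c("net_id", "taxon_id", "count", "depth_min", "depth_max",
            "latitude", "longitude", "timestamp")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("missing mandatory column(s): ", paste(miss, collapse = ", "))
  for (col in c("count", "depth_min", "depth_max", "latitude", "longitude"))
    df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
  df$timestamp <- as_utc(df$timestamp)
  if (any(is.na(df$count) | df$count < 0)) stop("counts must be >= 0")
  bad <- df$depth_min > df$depth_max
  if (any(bad, na.rm = TRUE))
    stop("depth_min > depth_max for net(s): ",
         paste(unique(df$net_id[bad]), collapse = ", "))
  if (!is.null(taxonomy)) {
    unknown <- setdiff(unique(df$taxon_id), taxonomy$record_id)
    if (length(unknown) > 0)
      warning("trawl taxa absent from taxonomy: ",
              paste(utils::head(unknown, 5L), collapse = ", "))
  }
  class(df) <- c("trawl_table", "data.frame")
  df
}

#' Read a trawl catch table from CSV
#' @param path CSV path.
#' @param taxonomy Optional [taxonomy_table()] used to warn on unknown taxa.
#' @return A [trawl_table()].
#' @export
read_trawl_table <- function(path, taxonomy = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  body <- read_body(path)
  df <- utils::read.csv(text = body$text, check.names = FALSE,
                        colClasses = "character")
  trawl_table(df, taxonomy)
}

#' Write a trawl catch table to CSV
#' @param x A [trawl_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trawl_table <- function(x, path) {
  stopifnot(inherits(x, "trawl_table"))
  out <- data.frame(
    net_id = x$net_id, taxon_id = x$taxon_id, count = fmt_num(x$count),
    depth_min = fmt_num(x$depth_min), depth_max = fmt_num(x$depth_max),
    latitude = fmt_num(x$latitude), longitude = fmt_num(x$longitude),
    timestamp = fmt_utc(x$timestamp), stringsAsFactors = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(SCHEMA_LINE, con)
  utils::write.csv(out, con, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Cross-validate a dataset
#'
#' Checks that every sample column of each ASV table resolves in the
#' metadata (missing = error) and that every ASV id resolves in the taxonomy
#' (missing = warning; such ASVs are treated as fully unassigned and the
#' pipeline remains runnable). Pure: repeated calls give identical reports.
#'
#' @param asv An [asv_table()] or a list of them.
#' @param taxonomy A [taxonomy_table()].
#' @param metadata A [sample_metadata()] table.
#' @param trawl Optional [trawl_table()].
#' @return A `validation_report`: list with data frames `errors` and
#'   `warnings` (columns table, id, rule, message).
#' @export
validate_dataset <- function(asv, taxonomy, metadata, trawl = NULL) {
  if (inherits(asv, "asv_table")) asv <- list(asv)
  errs <- list(); warns <- list()
  note <- function(store, table, id, rule, message)
    rbind(store, data.frame(table = table, id = id, rule = rule,
                            message = message, stringsAsFactors = FALSE))
  errors <- data.frame(table = character(), id = character(),
                       rule = character(), message = character(),
                       stringsAsFactors = FALSE)
  warnings <- errors
  for (tab in asv) {
    lab <- paste0("asv_", tab$marker)
    missing_samples <- setdiff(colnames(tab$counts), metadata$sample_id)
    for (s in missing_samples)
      errors <- note(errors, lab, s, "sample_in_metadata",
                     sprintf("sample '%s' absent from metadata", s))
    missing_tax <- setdiff(rownames(tab$counts), taxonomy$record_id)
    for (a in missing_tax)
      warnings <- note(warnings, lab, a, "asv_in_taxonomy",
                       sprintf("ASV '%s' has no taxonomy record; treated as unassigned", a))
  }
  if (!is.null(trawl)) {
    missing_tax <- setdiff(unique(trawl$taxon_id), taxonomy$record_id)
    for (a in missing_tax)
      warnings <- note(warnings, "trawl", a, "taxon_in_taxonomy",
                       sprintf("trawl taxon '%s' has no taxonomy record", a))
  }
  structure(list(errors = errors, warnings = warnings),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("Validation report: %d error(s), %d warning(s)\n",
              nrow(x$errors), nrow(x$warnings)))
  if (nrow(x$errors) > 0) print(x$errors)
  invisible(x)
}

# lineage lookup: named character vector of ranks for one record, or NULL
lineage_of <- function(taxonomy, id) {
  i <- match(id, taxonomy$record_id)
  if (is.na(i)) return(NULL)
  v <- unlist(taxonomy[i, taxonomy_ranks()])
  names(v) <- taxonomy_ranks()
  v
}
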