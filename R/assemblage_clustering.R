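# Species-presence matrices, Ward clustering on Jaccard dissimilarities,
# silhouette-based cluster cohesion, cluster summaries, and 50% KDE
# probability-density regions.

#' Build a species presence matrix for clustering
#'
#' Collapses ASVs to species (a species is present in a sample if any of
#' its ASVs has reads there), keeping only ASVs identified to the species
#' level so assignments are mutually exclusive. Optionally drops named
#' clades (e.g., mammals and birds from the vertebrate marker), restricts
#' to samples of one diel class (night by default, to limit the influence
#' of diel vertical migration), drops species present in fewer than
#' `min_samples` samples, and finally drops samples left with no species.
#'
#' @param table A decontaminated [asv_table()].
#' @param taxonomy A [taxonomy_table()].
#' @param min_samples Minimum number of samples a species must occur in
#'   (strict: a species in exactly `min_samples - 1` samples is dropped).
#' @param drop_clades List of `list(rank =, name =)` clades to remove.
#' @param diel Optional named character vector sample_id -> diel class
#'   (from [classify_diel()]).
#' @param diel_filter Class to retain when `diel` is given (default
#'   "night"; use NULL to keep all samples).
#' @return A `presence_matrix`: logical matrix samples x species with
#'   attributes `marker` and `dropped_samples`.
#' @export
build_presence_matrix <- function(table, taxonomy, min_samples = 3,
                                  drop_clades = list(), diel = NULL,
                                  diel_filter = "night") {
  tax <- taxonomy[match(rownames(table$counts), taxonomy$record_id), ]
  keep_asv <- !is.na(tax$record_id) & tax$deepest_rank == "species"
  for (cl in drop_clades)
    keep_asv <- keep_asv & !(!is.na(tax$record_id) &
                             tax[[cl$rank]] == cl$name)
  counts <- table$counts[keep_asv, , drop = FALSE]
  species <- tax$species[keep_asv]
  if (!is.null(diel) && !is.null(diel_filter)) {
    cls <- diel[colnames(counts)]
    unknown <- is.na(cls) | cls == "unknown"
    if (any(unknown))
      warning(sprintf("%d sample(s) with unknown diel class excluded",
                      sum(unknown)))
    counts <- counts[, !unknown & cls == diel_filter, drop = FALSE]
  }
  sp <- sort(unique(species))
  pres <- matrix(FALSE, ncol(counts), length(sp),
                 dimnames = list(colnames(counts), sp))
  for (s in sp) {
    rows <- which(species == s)
    pres[, s] <- colSums(counts[rows, , drop = FALSE] > 0) > 0
  }
  pres <- pres[, colSums(pres) >= min_samples, drop = FALSE]
  empty <- rowSums(pres) == 0
  if (any(empty))
    message(sprintf("%d sample(s) with no retained species dropped",
                    sum(empty)))
  pres <- pres[!empty, , drop = FALSE]
  if (nrow(pres) == 0 || ncol(pres) == 0)
    stop("no samples/species survive filters")
  structure(pres, class = c("presence_matrix", "matrix"),
            marker = table$marker,
            dropped_samples = names(empty)[empty])
}

#' Agglomerative Ward clustering of a dissimilarity matrix
#'
#' Lance-Williams agglomeration under Ward's minimum variance criterion.
#' The default "ward_d2" variant updates squared distances
#' (d(k, i+j)^2 = ((n_i+n_k) d_ik^2 + (n_j+n_k) d_jk^2 - n_k d_ij^2) /
#' (n_i+n_j+n_k)), producing monotone non-decreasing merge heights; the
#' "ward_d1" compatibility variant applies the same coefficients to
#' unsquared distances. Ties in the minimum inter-cluster distance are
#' broken deterministically by the lexicographically smallest member id,
#' so dendrograms are reproducible across platforms.
#'
#' @param D A symmetric dissimilarity matrix (e.g., from
#'   [pairwise_dissimilarity()]).
#' @param variant "ward_d2" (default) or "ward_d1".
#' @return An `assemblage_dendrogram`: list with `merge` (hclust
#'   convention), `height`, `labels`, `variant`. Coercible with
#'   [as_hclust()].
#' @export
ward_cluster <- function(D, variant = c("ward_d2", "ward_d1")) {
  variant <- match.arg(variant)
  D <- check_dist(D)
  n <- nrow(D)
  if (n < 2) stop("need at least 2 units to cluster")
  labels <- rownames(D)
  if (is.null(labels)) labels <- as.character(seq_len(n))
  work <- if (variant == "ward_d2") D^2 else D
  active <- seq_len(n)
  size <- rep(1L, n)
  minlab <- labels                       # lexicographic tie-break key
  node <- -seq_len(n)                    # hclust convention
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  for (step in seq_len(n - 1L)) {
    best <- NULL
    for (ii in seq_along(active)) {
      for (jj in seq_len(ii - 1L)) {
        i <- active[ii]; j <- active[jj]
        d <- work[i, j]
        key <- sort(c(minlab[i], minlab[j]))
        if (is.null(best) || d < best$d - 1e-15 ||
            (abs(d - best$d) <= 1e-15 &&
             (key[1] < best$key[1] ||
              (key[1] == best$key[1] && key[2] < best$key[2])))) {
          best <- list(i = i, j = j, d = d, key = key)
        }
      }
    }
    i <- best$i; j <- best$j
    height[step] <- if (variant == "ward_d2") sqrt(best$d) else best$d
    merge[step, ] <- sort(c(node[i], node[j]))
    others <- setdiff(active, c(i, j))
    ni <- size[i]; nj <- size[j]
    for (k in others) {
      nk <- size[k]
      work[i, k] <- work[k, i] <-
        ((ni + nk) * work[i, k] + (nj + nk) * work[j, k] -
         nk * work[i, j]) / (ni + nj + nk)
    }
    size[i] <- ni + nj
    minlab[i] <- min(minlab[i], minlab[j])
    node[i] <- step
    active <- setdiff(active, j)
  }
  structure(list(merge = merge, height = height, labels = labels,
                 variant = variant),
            class = "assemblage_dendrogram")
}

#' @export
print.assemblage_dendrogram <- function(x, ...) {
  cat(sprintf("Ward dendrogram (%s): %d leaves, merge heights %.4g-%.4g\n",
              x$variant, length(x$labels), min(x$height), max(x$height)))
  invisible(x)
}

#' Coerce an assemblage dendrogram to a base hclust object
#' @param x An `assemblage_dendrogram`.
#' @return An object of class `hclust`.
#' @export
as_hclust <- function(x) {
  stopifnot(inherits(x, "assemblage_dendrogram"))
  order_leaves <- function(node) {
    if (node < 0) return(-node)
    c(order_leaves(x$merge[node, 1L]), order_leaves(x$merge[node, 2L]))
  }
  structure(list(merge = x$merge, height = x$height,
                 order = order_leaves(nrow(x$merge)),
                 labels = x$labels,
                 method = if (x$variant == "ward_d2") "ward.D2" else
                   "ward.D",
                 call = match.call(), dist.method = NULL),
            class = "hclust")
}

#' Cut a dendrogram into k clusters
#'
#' Removes the k - 1 highest merges. Cluster labels 1..k are assigned by
#' decreasing cluster size, ties broken by the lexicographically smallest
#' member id, so labels are deterministic.
#'
#' @param dendrogram An `assemblage_dendrogram`.
#' @param k Number of clusters, 1 <= k <= n.
#' @return Named integer vector of cluster labels per sample.
#' @export
cut_clusters <- function(dendrogram, k) {
  n <- length(dendrogram$labels)
  stopifnot(k >= 1, k <= n)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  node_rep <- integer(n - 1L)
  n_merges <- n - k
  for (step in seq_len(n - 1L)) {
    if (step > n_merges) break
    members <- dendrogram$merge[step, ]
    reps <- vapply(members, function(m)
      if (m < 0) find(-m) else find(node_rep[m]), integer(1))
    parent[reps[2L]] <- reps[1L]
    node_rep[step] <- reps[1L]
  }
  root <- vapply(seq_len(n), find, integer(1))
  groups <- split(seq_len(n), root)
  ord <- order(-lengths(groups),
               vapply(groups, function(g) min(dendrogram$labels[g]),
                      character(1)))
  labels <- integer(n)
  for (ci in seq_along(ord)) labels[groups[[ord[ci]]]] <- ci
  stats::setNames(labels, dendrogram$labels)
}

#' Silhouette widths for a clustering
#'
#' s(i) = (b - a) / max(a, b), where a is the mean dissimilarity of i to
#' its own cluster (excluding itself) and b the smallest mean
#' dissimilarity to any other cluster. Singletons, and points with
#' a = b = 0, get width 0 by convention.
#'
#' @param D Symmetric dissimilarity matrix.
#' @param labels Integer cluster labels aligned with the rows of `D`.
#' @return Named numeric vector of widths in [-1, 1].
#' @export
silhouette_widths <- function(D, labels) {
  D <- check_dist(D)
  n <- nrow(D)
  stopifnot(length(labels) == n)
  ks <- unique(labels)
  if (length(ks) < 2) stop("silhouette needs k >= 2 clusters")
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(labels == labels[i])
    if (length(own) == 1L) {
      s[i] <- 0
      next
    }
    a <- mean(D[i, setdiff(own, i)])
    b <- min(vapply(setdiff(ks, labels[i]), function(kk)
      mean(D[i, labels == kk]), numeric(1)))
    s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  stats::setNames(s, rownames(D))
}

#' Evaluate a clustering at a given k
#'
#' Bundles the cut, the per-sample silhouette widths, and the per-cluster
#' cohesion verdicts under the retention rule (mean width >= 0.1 and fewer
#' than 15% of members with negative widths).
#'
#' @param D Symmetric dissimilarity matrix.
#' @param dendrogram An `assemblage_dendrogram` over the same units.
#' @param k Number of clusters (>= 2).
#' @param min_mean_width,max_negative_fraction Cohesion rule parameters.
#' @return A `cluster_solution`: list with `k`, `labels`, `widths`,
#'   `cluster_stats` (size, mean width, negative fraction, cohesive flag).
#' @export
cluster_solution <- function(D, dendrogram, k, min_mean_width = 0.1,
                             max_negative_fraction = 0.15) {
  labels <- cut_clusters(dendrogram, k)
  widths <- silhouette_widths(D, labels)
  stats_df <- do.call(rbind, lapply(sort(unique(labels)), function(ci) {
    w <- widths[labels == ci]
    data.frame(cluster = ci, size = length(w), mean_width = mean(w),
               negative_fraction = mean(w < 0))
  }))
  stats_df$cohesive <- stats_df$mean_width >= min_mean_width &
    stats_df$negative_fraction < max_negative_fraction
  structure(list(k = k, labels = labels, widths = widths,
                 cluster_stats = stats_df),
            class = "cluster_solution")
}

#' @export
print.cluster_solution <- function(x, ...) {
  cat(sprintf("Cluster solution: k = %d, %d cohesive cluster(s)\n", x$k,
              sum(x$cluster_stats$cohesive)))
  print.data.frame(x$cluster_stats, row.names = FALSE)
  invisible(x)
}

#' Cohesion verdicts for a cluster solution
#'
#' A cluster is adequately cohesive when its average silhouette width is
#' at least `min_mean_width` and strictly fewer than
#' `max_negative_fraction` of its members have negative widths.
#'
#' @param solution A `cluster_solution` (or anything with `widths` and
#'   `labels`).
#' @param min_mean_width Minimum mean silhouette width (default 0.1).
#' @param max_negative_fraction Maximum tolerated fraction of negative
#'   widths (default 0.15, exclusive).
#' @return Named logical vector, one flag per cluster.
#' @export
cohesive_clusters <- function(solution, min_mean_width = 0.1,
                              max_negative_fraction = 0.15) {
  labels <- solution$labels
  widths <- solution$widths
  vapply(stats::setNames(nm = sort(unique(labels))), function(ci) {
    w <- widths[labels == ci]
    mean(w) >= min_mean_width && mean(w < 0) < max_negative_fraction
  }, logical(1))
}

#' Total within-group sum of squares across cuts
#'
#' WSS(k) = sum over clusters of (sum of squared pairwise dissimilarities
#' within the cluster) / cluster size — the dissimilarity-space analogue
#' of within-cluster variance, non-increasing in k.
#'
#' @param D Symmetric dissimilarity matrix.
#' @param dendrogram An `assemblage_dendrogram`.
#' @param k_max Largest k to evaluate.
#' @return Named numeric vector WSS for k = 1..k_max.
#' @export
wss_curve <- function(D, dendrogram, k_max) {
  D <- check_dist(D)
  stopifnot(k_max <= nrow(D))
  D2 <- D^2
  out <- vapply(seq_len(k_max), function(k) {
    labels <- cut_clusters(dendrogram, k)
    sum(vapply(unique(labels), function(ci) {
      idx <- which(labels == ci)
      sum(D2[idx, idx, drop = FALSE]) / 2 / length(idx)
    }, numeric(1)))
  }, numeric(1))
  stats::setNames(out, seq_len(k_max))
}

#' Mean silhouette width across cuts
#'
#' @param D Symmetric dissimilarity matrix.
#' @param dendrogram An `assemblage_dendrogram`.
#' @param k_max Largest k to evaluate (curve starts at k = 2).
#' @return Named numeric vector of mean widths for k = 2..k_max.
#' @export
silhouette_curve <- function(D, dendrogram, k_max) {
  out <- vapply(2:k_max, function(k)
    mean(silhouette_widths(D, cut_clusters(dendrogram, k))), numeric(1))
  stats::setNames(out, 2:k_max)
}

#' Choose k by the elbow rule
#'
#' Formalizes the visual elbow as the interior k maximizing the discrete
#' second difference (curve(k-1) - curve(k)) - (curve(k) - curve(k+1)) of
#' a decreasing separation curve. A flat or strictly linear curve has no
#' elbow and returns 1 with a warning. The chosen k is a suggestion and
#' can be overridden wherever it is consumed.
#'
#' @param curve Named numeric vector over consecutive k (e.g., from
#'   [wss_curve()]), length >= 3.
#' @return The chosen k (integer).
#' @export
choose_k_elbow <- function(curve) {
  ks <- as.integer(names(curve))
  if (is.null(names(curve))) ks <- seq_along(curve)
  if (length(curve) < 3) stop("elbow rule needs a curve over >= 3 values")
  d2 <- diff(curve, differences = 2)  # curve(k-1) - 2 curve(k) + curve(k+1)
  if (all(abs(d2) < 1e-12)) {
    warning("curve has no elbow (flat or linear); returning k = 1")
    return(1L)
  }
  ks[which.max(d2) + 1L]
}

#' Per-cluster community summary
#'
#' For each cluster: the `top_n` most frequently occurring species (sample
#' fraction within the cluster, ties broken alphabetically), the mean and
#' sd of species per sample, and species richness.
#'
#' @param presence A `presence_matrix` (samples x species).
#' @param labels Cluster labels aligned to the presence rows.
#' @param top_n Maximum species listed per cluster (default 10).
#' @return List, one element per cluster, each with `size`,
#'   `species_per_sample_mean`, `species_per_sample_sd`, `richness`,
#'   `top_species` (data frame species, frequency).
#' @export
cluster_summary <- function(presence, labels, top_n = 10) {
  stopifnot(length(labels) == nrow(presence))
  out <- list()
  for (ci in sort(unique(labels))) {
    sub <- presence[labels == ci, , drop = FALSE]
    freq <- colMeans(sub)
    freq <- freq[freq > 0]
    ord <- order(-freq, names(freq))
    top <- utils::head(ord, top_n)
    per_sample <- rowSums(sub)
    out[[as.character(ci)]] <- list(
      size = nrow(sub),
      species_per_sample_mean = mean(per_sample),
      species_per_sample_sd = if (nrow(sub) > 1) stats::sd(per_sample)
                              else 0,
      richness = length(freq),
      top_species = data.frame(species = names(freq)[top],
                               frequency = unname(freq[top]),
                               stringsAsFactors = FALSE))
  }
  out
}

#' 50% probability-density region of sample positions
#'
#' Gaussian product-kernel density estimate of the sample positions on a
#' padded regular grid (per-dimension Scott bandwidth, 256 x 256 grid,
#' padding of 3 bandwidths), thresholded so the grid cells at or above the
#' threshold capture the requested fraction of total estimated density
#' (the highest-density region), with contour polygons extracted at that
#' threshold. Longitude/latitude are treated as planar coordinates, which
#' is acceptable over a few degrees of extent.
#'
#' @param points Matrix or data frame with columns lon, lat; >= 5 rows
#'   with non-zero spread in both coordinates.
#' @param mass Nominal probability mass (default 0.5).
#' @param grid_size Grid cells per dimension (default 256).
#' @param bandwidth Optional c(hx, hy) kernel standard deviations;
#'   default Scott's rule n^(-1/6) * sd per dimension.
#' @return A `density_region`: list with `mass`, `polygons` (list of
#'   data frames lon/lat), `bandwidth`, `grid_size`, `threshold`,
#'   `enclosed_mass`, `grid_tolerance`.
#' @export
density_region_50 <- function(points, mass = 0.5, grid_size = 256,
                              bandwidth = NULL) {
  pts <- as.matrix(points[, 1:2])
  n <- nrow(pts)
  if (n < 5) stop("need at least 5 points for a density region")
  sds <- apply(pts, 2L, stats::sd)
  if (any(sds == 0)) stop("zero spread in a coordinate")
  h <- if (is.null(bandwidth)) n^(-1 / 6) * sds else bandwidth
  gx <- seq(min(pts[, 1]) - 3 * h[1], max(pts[, 1]) + 3 * h[1],
            length.out = grid_size)
  gy <- seq(min(pts[, 2]) - 3 * h[2], max(pts[, 2]) + 3 * h[2],
            length.out = grid_size)
  Kx <- stats::dnorm(outer(gx, pts[, 1], "-") / h[1]) / h[1]
  Ky <- stats::dnorm(outer(gy, pts[, 2], "-") / h[2]) / h[2]
  dens <- (Kx %*% t(Ky)) / n
  cell <- diff(gx)[1] * diff(gy)[1]
  cm <- dens * cell
  cm <- cm / sum(cm)
  ord <- order(dens, decreasing = TRUE)
  cum <- cumsum(cm[ord])
  idx <- which(cum >= mass)[1L]
  threshold <- dens[ord[idx]]
  enclosed <- cum[idx]
  tol <- max(cm)
  stopifnot(enclosed >= mass, enclosed <= mass + tol + 1e-12)
  polys <- grDevices::contourLines(gx, gy, dens, levels = threshold)
  polygons <- lapply(polys, function(p)
    data.frame(lon = p$x, lat = p$y))
  structure(list(mass = mass, polygons = polygons, bandwidth = h,
                 grid_size = grid_size, threshold = threshold,
                 enclosed_mass = enclosed, grid_tolerance = tol,
                 gx = gx, gy = gy, density = dens),
            class = "density_region")
}

#' @export
print.density_region <- function(x, ...) {
  cat(sprintf(
    "Density region: %.0f%% mass, %d polygon(s), enclosed %.4f (grid tol %.2g)\n",
    100 * x$mass, length(x$polygons), x$enclosed_mass, x$grid_tolerance))
  invisible(x)
}

#' Write density regions as GeoJSON (WGS84 lon/lat)
#'
#' @param regions Named list of `density_region` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_density_geojson <- function(regions, path) {
  features <- list()
  for (nm in names(regions)) {
    reg <- regions[[nm]]
    for (p in reg$polygons) {
      ring <- cbind(p$lon, p$lat)
      if (!all(ring[1, ] == ring[nrow(ring), ]))
        ring <- rbind(ring, ring[1, ])
      features[[length(features) + 1L]] <- list(
        type = "Feature",
        properties = list(region = nm, mass = reg$mass),
        geometry = list(type = "Polygon",
                        coordinates = list(lapply(seq_len(nrow(ring)),
                                                  function(i)
                                                    unname(ring[i, ])))))
    }
  }
  gj <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
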