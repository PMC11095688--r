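test_that("presence matrix collapses ASVs to species with strict filters", {
  counts <- matrix(0L, 4, 5,
                   dimnames = list(paste0("a", 1:4), paste0("s", 1:5)))
  counts["a1", c("s1", "s2", "s3")] <- 5L   # species X, ASV 1
  counts["a2", "s4"] <- 2L                  # species X, ASV 2
  counts["a3", c("s1", "s2")] <- 1L         # species Y: only 2 samples
  counts["a4", c("s3", "s4", "s5")] <- 1L   # genus-level only
  tax <- suppressWarnings(taxonomy_table(data.frame(
    record_id = paste0("a", 1:4),
    phylum = "Arthropoda", class = "Copepoda", order = "Calanoida",
    family = "Calanidae",
    genus = c("Calanus", "Calanus", "Acartia", "Oithona"),
    species = c("Calanus pacificus", "Calanus pacificus",
                "Acartia tonsa", ""),
    stringsAsFactors = FALSE)))
  tab <- asv_table(counts, "COI")
  pres <- suppressMessages(build_presence_matrix(tab, tax,
                                                 min_samples = 3))
  # species X present where any member ASV is; Y dropped (< 3 samples);
  # a4 not species-level; s5 left empty and dropped
  expect_equal(colnames(pres), "Calanus pacificus")
  expect_setequal(rownames(pres), c("s1", "s2", "s3", "s4"))
  expect_true(all(pres[, "Calanus pacificus"]))
  expect_error(build_presence_matrix(tab, tax, min_samples = 10),
               "survive")
})

test_that("presence matrix recovers the planted species map", {
  run <- separable_run(seed = 3)
  d <- run$data
  pres <- run$presence
  amap <- d$truth$asv_map
  sp_names <- stats::setNames(
    d$taxonomy$species[match(amap$asv_id, d$taxonomy$record_id)],
    amap$asv_id)
  counts <- run$decon$table$counts
  for (sname in colnames(pres)) {
    member_asvs <- intersect(names(sp_names)[sp_names == sname],
                             rownames(counts))
    manual <- colSums(counts[member_asvs, rownames(pres),
                             drop = FALSE] > 0) > 0
    expect_equal(unname(pres[, sname]), unname(manual), info = sname)
  }
})

test_that("Ward clustering minimizes within-cluster variance on a known fixture", {
  D <- dist1d(c(0, 0.1, 10, 10.1))
  dend <- ward_cluster(D)
  labels <- cut_clusters(dend, 2)
  expect_equal(unname(labels), c(1, 1, 2, 2))

  # exhaustive oracle: best 2-partition by total within-group D^2/n
  wss_of <- function(assign) {
    sum(vapply(unique(assign), function(c) {
      idx <- which(assign == c)
      sum(D[idx, idx]^2) / 2 / length(idx)
    }, numeric(1)))
  }
  best <- Inf; best_assign <- NULL
  for (code in 1:(2^3)) {
    assign <- c(1, 1 + bitwAnd(code, 1), 1 + bitwAnd(code %/% 2, 1),
                1 + bitwAnd(code %/% 4, 1))
    if (length(unique(assign)) == 2 && wss_of(assign) < best) {
      best <- wss_of(assign); best_assign <- assign
    }
  }
  expect_equal(wss_of(labels), best)
  expect_equal(unname(labels), best_assign)
})

test_that("Ward heights are monotone and match hclust ward.D2", {
  set.seed(31)
  x <- matrix(rnorm(24), 12, 2)
  D <- as.matrix(dist(x))
  dimnames(D) <- list(sprintf("p%02d", 1:12), sprintf("p%02d", 1:12))
  dend <- ward_cluster(D)
  expect_true(all(diff(dend$height) >= -1e-12))
  hc <- stats::hclust(as.dist(D), method = "ward.D2")
  expect_equal(sort(dend$height), sort(hc$height), tolerance = 1e-10)
  # cuts agree up to label renaming
  for (k in 2:5) {
    ours <- cut_clusters(dend, k)
    theirs <- stats::cutree(hc, k)[dend$labels]
    expect_equal(length(unique(paste(ours, theirs))),
                 length(unique(ours)), info = paste("k =", k))
  }

  # ward_d1 compatibility variant matches ward.D
  dend1 <- ward_cluster(D, variant = "ward_d1")
  hc1 <- stats::hclust(as.dist(D), method = "ward.D")
  expect_equal(sort(dend1$height), sort(hc1$height), tolerance = 1e-10)
})

test_that("degenerate Ward inputs behave as documented", {
  D <- matrix(c(0, 0, 1, 0, 0, 1, 1, 1, 0), 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  dend <- ward_cluster(D)
  expect_equal(dend$height[1], 0)  # duplicate leaves merge at 0
  d2 <- ward_cluster(dist1d(c(0, 1)))
  expect_equal(nrow(d2$merge), 1)
  expect_error(ward_cluster(matrix(c(0, 1, 2, 0), 2)), "symmetric")
})

test_that("cluster cuts are labelled deterministically and nest", {
  set.seed(32)
  D <- as.matrix(dist(matrix(rnorm(20), 10)))
  dimnames(D) <- list(paste0("s", 1:10), paste0("s", 1:10))
  dend <- ward_cluster(D)
  expect_equal(unname(cut_clusters(dend, 1)), rep(1, 10))
  expect_equal(sort(unname(cut_clusters(dend, 10))), 1:10)
  for (k in 9:2) {
    fine <- cut_clusters(dend, k + 1)
    coarse <- cut_clusters(dend, k)
    # nesting: every fine cluster maps into exactly one coarse cluster
    expect_true(all(tapply(coarse, fine,
                           function(z) length(unique(z))) == 1))
  }
})

test_that("silhouette widths match the definition and conventions", {
  # two clusters of 3: within-distance 0.1, across 0.9
  D <- matrix(0.9, 6, 6)
  D[1:3, 1:3] <- 0.1; D[4:6, 4:6] <- 0.1
  diag(D) <- 0
  dimnames(D) <- list(paste0("s", 1:6), paste0("s", 1:6))
  labels <- c(1, 1, 1, 2, 2, 2)
  s <- silhouette_widths(D, labels)
  expect_equal(unname(s), rep((0.9 - 0.1) / 0.9, 6), tolerance = 1e-12)

  # equidistant point: width 0
  D2 <- matrix(0.5, 5, 5); diag(D2) <- 0
  expect_equal(unname(silhouette_widths(D2, c(1, 1, 2, 2, 2))),
               rep(0, 5))

  # identical points forced into 2 clusters: 0 by convention
  D3 <- matrix(0, 4, 4)
  expect_equal(unname(silhouette_widths(D3, c(1, 1, 2, 2))), rep(0, 4))

  # singleton cluster: 0 by convention
  s4 <- silhouette_widths(D, c(1, 1, 1, 2, 2, 3))
  expect_equal(unname(s4[6]), 0)
  expect_true(all(s >= -1 & s <= 1))
})

test_that("silhouette widths agree with the cluster package", {
  set.seed(33)
  D <- as.matrix(dist(matrix(rnorm(30), 15)))
  labels <- sample(1:3, 15, replace = TRUE)
  labels[1:3] <- 1:3  # ensure all clusters non-empty
  ours <- silhouette_widths(D, labels)
  ref <- cluster::silhouette(labels, dmatrix = D)[, "sil_width"]
  expect_equal(unname(ours), unname(ref), tolerance = 1e-12)
})

test_that("WSS curve matches brute force and its boundary identities", {
  set.seed(34)
  D <- as.matrix(dist(matrix(rnorm(16), 8)))
  dimnames(D) <- list(paste0("s", 1:8), paste0("s", 1:8))
  dend <- ward_cluster(D)
  curve <- wss_curve(D, dend, 8)
  expect_equal(unname(curve["8"]), 0)
  expect_equal(unname(curve["1"]), sum(D[lower.tri(D)]^2) / 8)
  expect_true(all(diff(curve) <= 1e-12))
  for (k in c(2, 4, 6)) {
    labels <- cut_clusters(dend, k)
    brute <- sum(vapply(unique(labels), function(c) {
      idx <- which(labels == c)
      s <- 0
      for (i in idx) for (j in idx) if (i < j) s <- s + D[i, j]^2
      s / length(idx)
    }, numeric(1)))
    expect_equal(unname(curve[as.character(k)]), brute)
  }
})

test_that("the elbow rule picks the largest second difference", {
  expect_equal(choose_k_elbow(stats::setNames(c(100, 40, 20, 15, 13),
                                              1:5)), 2)
  expect_warning(k <- choose_k_elbow(stats::setNames(c(50, 40, 30, 20),
                                                     1:4)), "no elbow")
  expect_equal(k, 1)
})

test_that("well-separated planted assemblages give a clean elbow and high widths", {
  pres <- block_presence(k = 4, n_per = 8, sp_per = 12)
  D <- pairwise_dissimilarity(pres, "jaccard")
  dend <- ward_cluster(D)
  curve <- wss_curve(D, dend, 8)
  expect_equal(choose_k_elbow(curve), 4)
  sol <- cluster_solution(D, dend, 4)
  expect_gt(mean(sol$widths), 0.5)
  expect_true(all(sol$cluster_stats$cohesive))
})

test_that("the cohesion rule reproduces the stated verdicts", {
  fake <- function(w, labels) list(widths = w, labels = labels)
  v1 <- cohesive_clusters(fake(c(0.3, 0.2, -0.05, 0.4), rep(1, 4)))
  expect_false(unname(v1))   # mean fine but 25% negative
  v2 <- cohesive_clusters(fake(c(0.3, 0.2, 0.1, 0.4), rep(1, 4)))
  expect_true(unname(v2))
  v3 <- cohesive_clusters(fake(c(0.05, 0.05, 0.05), rep(1, 3)))
  expect_false(unname(v3))   # mean below 0.1
})

test_that("cluster summaries rank species by within-cluster frequency", {
  pres <- matrix(FALSE, 4, 3,
                 dimnames = list(paste0("s", 1:4), c("X", "A", "B")))
  pres[, "X"] <- TRUE
  pres[1:2, "A"] <- TRUE
  pres[1, "B"] <- TRUE
  cs <- cluster_summary(pres, rep(1, 4), top_n = 10)
  expect_equal(cs[["1"]]$top_species$species[1], "X")
  expect_equal(cs[["1"]]$top_species$frequency[1], 1.0)
  expect_equal(nrow(cs[["1"]]$top_species), 3)  # top_n > richness
  expect_equal(cs[["1"]]$richness, 3)
  cs2 <- cluster_summary(pres, rep(1, 4), top_n = 2)
  expect_equal(nrow(cs2[["1"]]$top_species), 2)
})

test_that("planted dominant species is recovered as rank one per cluster", {
  run <- separable_run(seed = 5)
  pres <- run$presence
  D <- pairwise_dissimilarity(pres, "jaccard")
  sol <- cluster_solution(D, ward_cluster(D), 4)
  cs <- cluster_summary(pres, sol$labels)
  for (ci in which(sol$cluster_stats$cohesive)) {
    top <- cs[[as.character(ci)]]$top_species
    expect_gte(top$frequency[1], max(top$frequency))
    expect_true(all(diff(top$frequency) <= 1e-12))  # sorted
  }
})

test_that("50% density regions enclose half the estimated and true mass", {
  set.seed(36)
  pts <- cbind(rnorm(2000), rnorm(2000))
  reg <- density_region_50(pts)
  expect_gte(reg$enclosed_mass, 0.5)
  expect_lte(reg$enclosed_mass, 0.5 + reg$grid_tolerance + 1e-12)
  # true standard-normal mass inside the region, integrated on the grid
  cell <- diff(reg$gx)[1] * diff(reg$gy)[1]
  truth <- outer(stats::dnorm(reg$gx), stats::dnorm(reg$gy)) * cell
  true_mass <- sum(truth[reg$density >= reg$threshold])
  expect_lt(abs(true_mass - 0.5), 0.05)
  # HDR of a round normal is a disk of radius ~1.177 sd
  poly <- reg$polygons[[1]]
  radii <- sqrt(poly$lon^2 + poly$lat^2)
  expect_lt(abs(mean(radii) - sqrt(stats::qchisq(0.5, 2))), 0.15)
})

test_that("density regions are translation-equivariant and split for two clouds", {
  set.seed(37)
  pts <- cbind(rnorm(400, 0, 0.3), rnorm(400, 0, 0.3))
  r0 <- density_region_50(pts)
  r1 <- density_region_50(sweep(pts, 2, c(-3, 2), "+"))
  expect_equal(length(r0$polygons), length(r1$polygons))
  for (i in seq_along(r0$polygons)) {
    expect_equal(r1$polygons[[i]]$lon, r0$polygons[[i]]$lon - 3,
                 tolerance = 1e-8)
    expect_equal(r1$polygons[[i]]$lat, r0$polygons[[i]]$lat + 2,
                 tolerance = 1e-8)
  }
  two <- rbind(cbind(rnorm(300, 0, 0.2), rnorm(300, 0, 0.2)),
               cbind(rnorm(300, 5, 0.2), rnorm(300, 5, 0.2)))
  r2 <- density_region_50(two)
  expect_gte(length(r2$polygons), 2)
  expect_error(density_region_50(cbind(1:4, 1:4)), "at least 5")
  expect_error(density_region_50(cbind(rep(1, 9), 1:9)), "spread")
})

test_that("GeoJSON export writes closed polygons with region properties", {
  set.seed(38)
  reg <- density_region_50(cbind(rnorm(200), rnorm(200)))
  path <- withr::local_tempfile(fileext = ".geojson")
  write_density_geojson(list(cluster1_shallow = reg), path)
  gj <- jsonlite::read_json(path)
  expect_equal(gj$type, "FeatureCollection")
  expect_gte(length(gj$features), 1)
  ring <- gj$features[[1]]$geometry$coordinates[[1]]
  expect_equal(unlist(ring[[1]]), unlist(ring[[length(ring)]]))
  expect_equal(gj$features[[1]]$properties$region, "cluster1_shallow")
})
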