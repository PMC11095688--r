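test_that("group assignment follows first-match rules and the series exception", {
  tax <- suppressWarnings(taxonomy_table(data.frame(
    record_id = c("fish", "oval", "bare"),
    order = c("Myctophiformes", "", ""),
    series = c("", "Ovalentaria", ""),
    stringsAsFactors = FALSE)))
  g <- assign_groups(tax, vertebrate_group_scheme())
  expect_equal(unname(g["fish"]), "Myctophiformes")
  expect_equal(unname(g["oval"]), "Ovalentaria")
  expect_equal(unname(g["bare"]), "unassigned")

  inv <- suppressWarnings(taxonomy_table(data.frame(
    record_id = c("cop", "noclass"),
    phylum = c("Arthropoda", "Chaetognatha"),
    class = c("Copepoda", ""),
    order = c("Calanoida", ""), stringsAsFactors = FALSE)))
  gi <- assign_groups(inv, invertebrate_group_scheme())
  expect_equal(unname(gi["cop"]), "Calanoida")   # order beats class
  expect_equal(unname(gi["noclass"]), "Chaetognatha")
})

test_that("zone assignment uses the 1-degree / 2-degree box", {
  sites <- data.frame(zone = "Z1", latitude = 33.7, longitude = -119.5)
  meta <- data.frame(sample_id = c("in", "out"),
                     latitude = c(33.0, 30.0),
                     longitude = c(-120.8, -124.7))
  z <- assign_zones(meta, sites)
  expect_equal(unname(z["in"]), "Z1")   # dlat 0.7 <= 1, dlon 1.3 <= 2
  expect_true(is.na(z["out"]))          # dlat 3.7 > 1
})

test_that("overlapping zones break ties by nearest centre, site-order invariant", {
  sites <- data.frame(zone = c("A", "B"),
                      latitude = c(33.0, 33.5),
                      longitude = c(-120.0, -119.0))
  meta <- data.frame(sample_id = "s", latitude = 33.1,
                     longitude = -119.8)
  z1 <- assign_zones(meta, sites)
  z2 <- assign_zones(meta, sites[2:1, ])
  expect_equal(unname(z1["s"]), "A")
  expect_identical(z1, z2)

  # exactly equidistant: lexicographically smallest zone id wins
  sites_eq <- data.frame(zone = c("B", "A"),
                         latitude = c(33, 33),
                         longitude = c(-121, -119))
  meta_eq <- data.frame(sample_id = "s", latitude = 33, longitude = -120)
  expect_equal(unname(assign_zones(meta_eq, sites_eq)["s"]), "A")
  expect_equal(unname(assign_zones(meta_eq, sites_eq[2:1, ])["s"]), "A")
})

test_that("depth bins are lower-open upper-closed and cover all depths", {
  prof <- depth_bin_scheme("profile")
  expect_equal(bin_depth(100, prof), "0-200")
  expect_equal(bin_depth(200, prof), "0-200")
  expect_equal(bin_depth(200.1, prof), "200-600")
  expect_equal(bin_depth(600, prof), "200-600")
  expect_equal(bin_depth(600.1, prof), ">600")
  cmp <- depth_bin_scheme("comparison")
  expect_equal(bin_depth(1749.1, cmp), "deep")

  # every scheme partitions (0, Inf): boundaries +/- epsilon all bin
  for (nm in c("comparison", "profile", "mapping_12S", "mapping_COI")) {
    sc <- depth_bin_scheme(nm)
    probes <- c(sc$lower[-1] - 1e-9, sc$lower[-1] + 1e-9, sc$upper[
      is.finite(sc$upper)], 0.001, 5000)
    expect_false(any(is.na(bin_depth(probes, sc))), info = nm)
  }
})

test_that("diel classification honors the 90-minute margins and day wraps", {
  sr <- as.POSIXct("2021-07-03 06:00:00", tz = "UTC")
  ss <- as.POSIXct("2021-07-03 18:00:00", tz = "UTC")
  at <- function(h) as.POSIXct(sprintf("2021-07-03 %s:00", h), tz = "UTC")
  expect_equal(classify_diel(at("20:00"), sr, ss), "night")
  expect_equal(classify_diel(at("05:00"), sr, ss), "transitional")
  expect_equal(classify_diel(at("12:00"), sr, ss), "day")
  expect_equal(classify_diel(at("04:30"), sr, ss), "night")
  expect_equal(classify_diel(at("19:30"), sr, ss), "night")
  expect_equal(classify_diel(at("19:29"), sr, ss), "transitional")

  # invariant to representing times +/- 24 h
  for (h in c("02:00", "07:45", "13:00", "19:00", "23:00")) {
    base <- classify_diel(at(h), sr, ss)
    expect_equal(classify_diel(at(h) + 86400, sr, ss), base, info = h)
    expect_equal(classify_diel(at(h) - 86400, sr, ss), base, info = h)
  }
  expect_equal(classify_diel(at("12:00"), as.POSIXct(NA), ss), "unknown")
})

test_that("eDNA proportional occurrence is presence-based over groups", {
  m <- matrix(c(5000L, 1L, 3L, 2L, 0L), nrow = 5,
              dimnames = list(paste0("a", 1:5), "S1"))
  tab <- asv_table(m, "COI")
  gm <- c(a1 = "Copepoda", a2 = "Copepoda", a3 = "Copepoda",
          a4 = "Polychaeta", a5 = "Polychaeta")
  po <- proportional_occurrence_edna(tab, gm)
  expect_equal(po["S1", "Copepoda"], 0.75)   # 3 of 4 present ASVs
  expect_equal(po["S1", "Polychaeta"], 0.25) # read magnitude irrelevant
})

test_that("proportional occurrence matches a brute-force tally and sums to 1", {
  tab <- asv_table(random_counts(30, 8, seed = 5, lambda = 2), "COI")
  gm <- stats::setNames(sample(c("G1", "G2", "G3", "unassigned"), 30,
                               replace = TRUE),
                        rownames(tab$counts))
  po <- suppressWarnings(proportional_occurrence_edna(tab, gm))
  expect_true(all(abs(rowSums(po) - 1) < 1e-9))
  for (s in rownames(po)) {
    pres <- rownames(tab$counts)[tab$counts[, s] > 0]
    pres <- pres[gm[pres] != "unassigned"]
    for (g in colnames(po))
      expect_equal(po[s, g], sum(gm[pres] == g) / length(pres))
  }
})

test_that("trawl proportional occurrence counts taxa, not individuals", {
  tr <- trawl_table(data.frame(
    net_id = c("N1", "N1", "N1", "N1", "N2"),
    taxon_id = c("t1", "t2", "t3", "t4", "t1"),
    count = c(50, 2, 1, 1, 3),
    depth_min = 0, depth_max = 200, latitude = 33, longitude = -120,
    timestamp = "2021-07-03T06:00:00", stringsAsFactors = FALSE))
  gm <- c(t1 = "Malacostraca", t2 = "Malacostraca", t3 = "Siphonophorae",
          t4 = "Myctophiformes")
  po <- proportional_occurrence_trawl(tr, gm)
  expect_equal(po["N1", "Malacostraca"], 0.5)
  expect_equal(po["N1", "Siphonophorae"], 0.25)
  expect_equal(po["N1", "Myctophiformes"], 0.25)
  expect_equal(unname(po["N2", "Malacostraca"]), 1.0)  # single-taxon net
})

test_that("unit aggregation supports mean and pool modes", {
  m <- matrix(c(1, 0,
                0, 1,
                0.9, 0.1), nrow = 3, byrow = TRUE,
              dimnames = list(c("s1", "s2", "s3"), c("G1", "G2")))
  po <- structure(m, class = c("proportional_occurrence", "matrix"),
                  presences = matrix(c(9L, 0L, 0L, 1L, 9L, 1L), 3,
                                     byrow = TRUE,
                                     dimnames = dimnames(m)))
  units <- c(s1 = "u1", s2 = "u1", s3 = "u2")
  agg <- aggregate_units(po, units, "mean")
  expect_equal(unname(agg["u1", ]), c(0.5, 0.5))
  pool <- aggregate_units(po, units, "pool")
  expect_equal(unname(pool["u1", ]), c(0.9, 0.1))  # pooled presences 9:1
  expect_true(all(abs(rowSums(agg) - 1) < 1e-9))
  expect_true(all(abs(rowSums(pool) - 1) < 1e-9))
  # identical rows aggregate to themselves
  agg2 <- aggregate_units(po, c(s1 = "v", s2 = "w", s3 = "w"), "mean")
  expect_equal(unname(agg2["v", ]), c(1, 0))
})

test_that("method group overlap partitions detected groups", {
  a <- matrix(c(0.5, 0.5, 0), 1, dimnames = list("u", c("G1", "G2", "G3")))
  b <- matrix(c(0.7, 0, 0.3), 1, dimnames = list("u", c("G1", "G2", "G3")))
  ov <- method_group_overlap(a, b)
  expect_equal(ov$shared, "G1")
  expect_equal(ov$edna_only, "G2")
  expect_equal(ov$trawl_only, "G3")
  same <- method_group_overlap(a, a)
  expect_equal(same$edna_only, character(0))
  expect_equal(same$trawl_only, character(0))
})
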