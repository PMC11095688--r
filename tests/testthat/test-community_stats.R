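test_that("Morisita-Horn matches hand values and its invariances", {
  expect_equal(morisita_horn(c(3, 1, 2), c(3, 1, 2)), 0)
  expect_equal(morisita_horn(c(1, 0, 2), c(0, 5, 0)), 1)
  expect_equal(morisita_horn(c(1, 1), c(1, 0)), 1 / 3)
  expect_error(morisita_horn(c(0, 0), c(1, 1)), "zero-sum")

  set.seed(3)
  for (i in 1:20) {
    x <- rexp(6); y <- rexp(6)
    expect_equal(morisita_horn(7.3 * x, y), morisita_horn(x, y))
    expect_equal(morisita_horn(x, 0.01 * y), morisita_horn(x, y))
  }
})

test_that("Morisita-Horn agrees with vegan's horn dissimilarity", {
  set.seed(8)
  m <- matrix(rpois(40, 6), 5)
  rownames(m) <- paste0("u", 1:5)
  D <- pairwise_dissimilarity(m, "morisita-horn")
  V <- as.matrix(vegan::vegdist(m, method = "horn"))
  expect_equal(unname(D[lower.tri(D)]), unname(V[lower.tri(V)]),
               tolerance = 1e-12)
})

test_that("binary Jaccard matches set arithmetic", {
  expect_equal(jaccard_binary(c(1, 1, 0), c(1, 1, 0)), 0)
  expect_equal(jaccard_binary(c(1, 0, 0), c(0, 1, 1)), 1)
  # {A,B} vs {B,C}: 1 shared of 3 in the union
  expect_equal(jaccard_binary(c(1, 1, 0), c(0, 1, 1)), 2 / 3)
  expect_error(jaccard_binary(c(0, 0), c(0, 0)), "empty")
  # duplicating a shared species leaves distances to others unchanged
  a <- c(1, 1, 0, 1); b <- c(0, 1, 1, 1)
  expect_equal(jaccard_binary(c(a, 1), c(b, 1)),
               jaccard_binary(c(a, a[2]), c(b, b[2])))
})

test_that("pairwise dissimilarities equal the naive double loop", {
  set.seed(10)
  m <- matrix(rpois(40, 4), 8, 5,
              dimnames = list(paste0("u", 1:8), NULL))
  for (metric in c("morisita-horn", "jaccard")) {
    mm <- if (metric == "jaccard") (m > 0) + 0 else m
    D <- pairwise_dissimilarity(mm, metric)
    f <- if (metric == "jaccard") jaccard_binary else morisita_horn
    for (i in 1:8) for (j in 1:8)
      expect_equal(D[i, j], if (i == j) 0 else f(mm[i, ], mm[j, ]),
                   info = metric)
    expect_equal(D, t(D))
    # permutation equivariance
    p <- sample(8)
    Dp <- pairwise_dissimilarity(mm[p, ], metric)
    expect_equal(matrix(Dp, nrow(Dp)), matrix(D[p, p], nrow(Dp)))
  }
  expect_equal(unname(pairwise_dissimilarity(m[1, , drop = FALSE],
                                             "morisita-horn")[1, 1]), 0)
})

test_that("Mantel test recovers perfect and affine correlation", {
  set.seed(4)
  D1 <- as.matrix(dist(matrix(rnorm(16), 8)))
  expect_equal(mantel_test(D1, D1, 99, seed = 1)$r, 1)
  expect_equal(mantel_test(D1, 0.2 + 3 * D1, 99, seed = 1)$r, 1)
  expect_error(mantel_test(D1[1:2, 1:2], D1[1:2, 1:2]), "3 units")
  expect_error(mantel_test(D1, matrix(0, 8, 8)), "variance")
  r <- mantel_test(D1, as.matrix(dist(matrix(rnorm(16), 8))), 199,
                   seed = 2)
  expect_gte(r$p, 1 / 200)
  # r agrees with vegan's implementation
  D2 <- as.matrix(dist(matrix(rnorm(16), 8)))
  expect_equal(mantel_test(D1, D2, 9, seed = 1)$r,
               unname(vegan::mantel(D1, D2, permutations = 9)$statistic))
})

test_that("Mantel p is stable across seeds at high permutation counts", {
  set.seed(12)
  D1 <- as.matrix(dist(matrix(rnorm(20), 10)))
  D2 <- as.matrix(dist(matrix(rnorm(20), 10) +
                         0.5 * matrix(rnorm(20), 10)))
  p1 <- mantel_test(D1, D2, 9999, seed = 101)$p
  p2 <- mantel_test(D1, D2, 9999, seed = 202)$p
  se <- sqrt(max(p1, 1e-3) * (1 - max(p1, 1e-3)) / 9999)
  expect_lt(abs(p1 - p2), 4 * se + 2e-4)
})

test_that("Kruskal-Wallis reproduces the rank-sum formula value", {
  r <- kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9)))
  expect_equal(unname(r$statistic), 7.2)
  expect_equal(unname(r$df), 2)
  # invariant to within-group order
  r2 <- kruskal_wallis(list(c(3, 1, 2), c(6, 4, 5), c(9, 7, 8)))
  expect_equal(r2$statistic, r$statistic)
  expect_error(kruskal_wallis(list(c(1, 1), c(1, 1))), "identical")
  expect_error(kruskal_wallis(list(1:3)), "2 groups")
})

test_that("Welch ANOVA on ranks reduces to the squared Welch t for k = 2", {
  set.seed(21)
  g <- list(a = rnorm(10), b = rnorm(13, 1, 3))
  w <- welch_anova_ranks(g)
  r <- rank(unlist(g))
  tt <- t.test(r[1:10], r[11:23])
  expect_equal(unname(w$statistic), unname(tt$statistic)^2,
               tolerance = 1e-10)
  expect_equal(unname(w$df[2]), unname(tt$parameter), tolerance = 1e-10)
  expect_equal(w$p, tt$p.value, tolerance = 1e-10)
  expect_error(welch_anova_ranks(list(c(1, 1, 1), c(2, 3, 4))),
               "zero rank variance")
})

test_that("Welch ANOVA on ranks detects strong shifts", {
  set.seed(22)
  g <- list(rnorm(15), rnorm(15, 3), rnorm(15, 6, 3))
  expect_lt(welch_anova_ranks(g)$p, 0.001)
})

test_that("Games-Howell on ranks matches Welch t (k = 2) and handles ties", {
  g0 <- list(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4))
  gh0 <- games_howell_ranks(g0)[[1]]
  expect_equal(gh0$statistic, 0)
  expect_equal(gh0$p, 1)

  set.seed(23)
  g <- list(a = rnorm(12), b = rnorm(15, 0.8, 2))
  gh <- games_howell_ranks(g)[[1]]
  r <- rank(unlist(g))
  tt <- t.test(r[1:12], r[13:27])
  expect_lt(abs(gh$p - tt$p.value), 1e-9)
  expect_error(games_howell_ranks(list(c(2, 2), c(2, 2))),
               "zero pooled")
})

test_that("Games-Howell agrees with an independent reference implementation", {
  set.seed(24)
  g <- list(g1 = rnorm(10), g2 = rnorm(12, 1), g3 = rnorm(9, 2, 3))
  gh <- games_howell_ranks(g)
  r <- rank(unlist(g))
  labs <- rep(names(g), lengths(g))
  payload <- jsonlite::toJSON(list(values = r, groups = labs),
                              auto_unbox = FALSE)
  script <- paste(
    "import sys, json, pandas as pd, pingouin as pg",
    "d = json.load(sys.stdin)",
    "df = pd.DataFrame({'v': d['values'], 'g': d['groups']})",
    "res = pg.pairwise_gameshowell(data=df, dv='v', between='g')",
    "out = {f\"{a} vs {b}\": {'t': abs(float(t)), 'df': float(df_),",
    "       'p': float(p)} for a, b, t, df_, p in",
    "       zip(res['A'], res['B'], res['T'], res['df'], res['pval'])}",
    "print(json.dumps(out))", sep = "\n")
  out <- system2("python", c("-c", shQuote(script)), input = payload,
                 stdout = TRUE, stderr = FALSE)
  ref <- jsonlite::fromJSON(paste(out, collapse = ""))
  for (nm in names(gh)) {
    expect_true(nm %in% names(ref))
    expect_equal(gh[[nm]]$statistic, ref[[nm]]$t, tolerance = 1e-6,
                 info = nm)
    expect_equal(gh[[nm]]$df, ref[[nm]]$df, tolerance = 1e-6, info = nm)
    expect_equal(gh[[nm]]$p, ref[[nm]]$p, tolerance = 1e-6, info = nm)
  }
})

test_that("label permutation permutes pairwise results, not global statistics", {
  set.seed(25)
  g <- list(a = rnorm(8), b = rnorm(8, 1), c = rnorm(8, 2))
  perm <- g[c("c", "a", "b")]
  expect_equal(kruskal_wallis(g)$statistic,
               kruskal_wallis(perm)$statistic)
  expect_equal(welch_anova_ranks(g)$statistic,
               welch_anova_ranks(perm)$statistic)
  gh <- games_howell_ranks(g)
  ghp <- games_howell_ranks(perm)
  expect_equal(ghp[["a vs b"]]$statistic, gh[["a vs b"]]$statistic)
  expect_equal(ghp[["c vs a"]]$p, gh[["a vs c"]]$p)
})

test_that("the depth-test router follows the stated decision rule", {
  set.seed(26)
  het <- list(a = rnorm(20, 0, 1), b = rnorm(20, 0, 10),
              c = rnorm(20, 0, 10))
  rt <- select_depth_test(het)
  expect_equal(rt$test, "welch_anova_ranks")
  expect_false(rt$checks$homoscedastic)

  hom_nonnorm <- list(a = rexp(25), b = rexp(25), c = rexp(25))
  rt2 <- select_depth_test(hom_nonnorm)
  expect_equal(rt2$test, "kruskal_wallis")

  norm_hom <- list(a = rnorm(30), b = rnorm(30), c = rnorm(30))
  rt3 <- select_depth_test(norm_hom)
  expect_equal(rt3$test, "kruskal_wallis")
  expect_match(rt3$note, "rank-based")
})

test_that("species accumulation endpoints and exact mean are correct", {
  set.seed(27)
  pres <- matrix(runif(20) < 0.5, 5, 4,
                 dimnames = list(paste0("s", 1:5), paste0("sp", 1:4)))
  pres[1, ] <- TRUE  # ensure nonzero richness
  acc <- species_accumulation(pres, n_perm = 50, seed = 3)
  expect_equal(acc$richness_mean[5], sum(colSums(pres) > 0))
  expect_equal(acc$richness_mean[1], mean(rowSums(pres)), tolerance = 0.3)
  expect_true(all(diff(acc$richness_mean) >= -1e-12))

  # exact curve equals exhaustive enumeration over all 120 orderings
  exact <- species_accumulation(pres, method = "exact")
  perms <- NULL
  idx <- 1:5
  allperm <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (rest in allperm(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    out
  }
  enum <- sapply(allperm(idx), function(ord) {
    seen <- rep(FALSE, ncol(pres))
    vapply(seq_along(ord), function(i) {
      seen <<- seen | pres[ord[i], ]
      sum(seen)
    }, numeric(1))
  })
  expect_equal(exact$richness_mean, rowMeans(enum), tolerance = 1e-12)
  # the random accumulator's expectation matches the exact curve
  accL <- species_accumulation(pres, n_perm = 2000, seed = 4)
  expect_equal(accL$richness_mean, exact$richness_mean, tolerance = 0.1)
})
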