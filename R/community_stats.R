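# Dissimilarity measures, the Mantel permutation test, rank-based
# depth-group tests, and species accumulation curves.

#' Morisita-Horn dissimilarity between two abundance vectors
#'
#' d = 1 - 2*sum(x_i y_i) / ((lambda_x + lambda_y) * N_x * N_y), where
#' N_x = sum(x) and lambda_x = sum(x^2) / N_x^2. Bounded in [0, 1] and
#' invariant to rescaling either vector by a positive constant, which makes
#' it suitable for proportional-occurrence rows.
#'
#' @param x,y Non-negative numeric vectors of equal length with positive
#'   sums.
#' @return Dissimilarity in [0, 1].
#' @export
morisita_horn <- function(x, y) {
  stopifnot(length(x) == length(y))
  nx <- sum(x); ny <- sum(y)
  if (nx <= 0 || ny <= 0) stop("zero-sum vector in morisita_horn")
  if (any(x < 0) || any(y < 0)) stop("negative abundances")
  lx <- sum(x^2) / nx^2
  ly <- sum(y^2) / ny^2
  d <- 1 - 2 * sum(x * y) / ((lx + ly) * nx * ny)
  min(max(d, 0), 1)
}

#' Binary Jaccard dissimilarity
#'
#' d = 1 - |intersection| / |union| of the two presence sets.
#'
#' @param a,b Logical or 0/1 vectors of equal length; the union must be
#'   non-empty.
#' @return Dissimilarity in [0, 1].
#' @export
jaccard_binary <- function(a, b) {
  stopifnot(length(a) == length(b))
  a <- as.logical(a); b <- as.logical(b)
  uni <- sum(a | b)
  if (uni == 0) stop("both presence vectors empty in jaccard_binary")
  1 - sum(a & b) / uni
}

#' Pairwise dissimilarity matrix
#'
#' @param m Numeric matrix, units as rows (abundances for "morisita-horn",
#'   presences for "jaccard").
#' @param metric "morisita-horn" or "jaccard".
#' @return A `dissimilarity_matrix`: symmetric numeric matrix with zero
#'   diagonal and a `metric` attribute.
#' @export
pairwise_dissimilarity <- function(m, metric = c("morisita-horn",
                                                 "jaccard")) {
  metric <- match.arg(metric)
  f <- if (metric == "morisita-horn") morisita_horn else jaccard_binary
  n <- nrow(m)
  D <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      d <- tryCatch(f(m[i, ], m[j, ]), error = function(e)
        stop(sprintf("undefined %s dissimilarity between '%s' and '%s': %s",
                     metric, rownames(m)[i], rownames(m)[j],
                     conditionMessage(e)), call. = FALSE))
      D[i, j] <- D[j, i] <- d
    }
  }
  structure(D, class = c("dissimilarity_matrix", "matrix"), metric = metric)
}

check_dist <- function(D) {
  D <- as.matrix(D)
  if (nrow(D) != ncol(D) || any(abs(D - t(D)) > 1e-12))
    stop("dissimilarity matrix must be symmetric")
  if (any(D < -1e-12)) stop("negative dissimilarities")
  D
}

lower_tri <- function(D) D[lower.tri(D)]

#' Mantel permutation test
#'
#' Pearson correlation between the strictly-lower triangles of two distance
#' matrices over the same units, with significance from simultaneous
#' row/column permutations of the second matrix. One-sided (upper tail);
#' the observed statistic is included in the null set, so
#' p = (1 + #\{r_perm >= r_obs\}) / (n_perm + 1) > 0.
#'
#' @param D1,D2 Symmetric dissimilarity matrices with matching unit ids.
#' @param n_perm Number of permutations (default 999).
#' @param seed Optional integer seed for the permutation stream.
#' @return A `mantel_result`: list with `r`, `p`, `n_perm`, `seed`, `n`.
#' @export
mantel_test <- function(D1, D2, n_perm = 999, seed = NULL) {
  D1 <- check_dist(D1); D2 <- check_dist(D2)
  n <- nrow(D1)
  if (n < 3) stop("mantel test needs at least 3 units")
  if (!is.null(rownames(D1)) && !is.null(rownames(D2)) &&
      !identical(rownames(D1), rownames(D2)))
    stop("unit ids of the two matrices differ")
  v1 <- lower_tri(D1)
  if (stats::sd(v1) == 0 || stats::sd(lower_tri(D2)) == 0)
    stop("zero variance in a distance triangle")
  r_obs <- stats::cor(v1, lower_tri(D2))
  if (!is.null(seed)) set.seed(seed)
  r_perm <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    p <- sample.int(n)
    r_perm[b] <- stats::cor(v1, lower_tri(D2[p, p]))
  }
  p_val <- (1 + sum(r_perm >= r_obs)) / (n_perm + 1)
  structure(list(r = r_obs, p = p_val, n_perm = n_perm, seed = seed, n = n),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("Mantel test: r = %.4f, p = %.4g (%d permutations, n = %d)\n",
              x$r, x$p, x$n_perm, x$n))
  invisible(x)
}

rank_test_result <- function(test, statistic, stat_name, df, p, groups,
                             note = "") {
  structure(list(test = test, statistic = statistic,
                 stat_name = stat_name, df = df, p = p,
                 groups = groups, note = note),
            class = "rank_test_result")
}

#' @export
print.rank_test_result <- function(x, ...) {
  cat(sprintf("%s: %s = %.4g, df = %s, p = %.4g\n", x$test, x$stat_name,
              x$statistic, paste(signif(x$df, 5), collapse = ", "), x$p))
  invisible(x)
}

as_group_list <- function(groups) {
  if (is.null(names(groups)))
    names(groups) <- paste0("g", seq_along(groups))
  lapply(groups, as.numeric)
}

#' Kruskal-Wallis rank-sum test
#'
#' Mid-ranks with the standard tie correction; the statistic is referred to
#' a chi-squared distribution with k - 1 degrees of freedom.
#'
#' @param groups List of >= 2 numeric vectors.
#' @return A `rank_test_result` (H statistic).
#' @export
kruskal_wallis <- function(groups) {
  groups <- as_group_list(groups)
  if (length(groups) < 2) stop("need at least 2 groups")
  vals <- unlist(groups, use.names = FALSE)
  if (length(vals) < 3) stop("need at least 3 observations")
  if (length(unique(vals)) == 1)
    stop("all values identical: Kruskal-Wallis statistic undefined")
  g <- factor(rep(names(groups), lengths(groups)), levels = names(groups))
  kt <- stats::kruskal.test(vals, g)
  rank_test_result("Kruskal-Wallis", unname(kt$statistic), "X^2",
                   unname(kt$parameter), kt$p.value, names(groups))
}

welch_on_values <- function(vals, g) {
  ow <- stats::oneway.test(vals ~ g, var.equal = FALSE)
  list(F = unname(ow$statistic), df = unname(ow$parameter),
       p = ow$p.value)
}

#' Welch's heteroscedastic ANOVA on ranks
#'
#' Values from all groups are converted to global mid-ranks, then Welch's
#' F (which does not assume equal variances) is computed on the ranks with
#' Welch-Satterthwaite denominator degrees of freedom.
#'
#' @param groups List of >= 2 numeric vectors, each with n >= 2.
#' @return A `rank_test_result` (F statistic; `df` is the (df1, df2) pair).
#' @export
welch_anova_ranks <- function(groups) {
  groups <- as_group_list(groups)
  if (length(groups) < 2) stop("need at least 2 groups")
  if (any(lengths(groups) < 2)) stop("each group needs n >= 2")
  vals <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), lengths(groups)), levels = names(groups))
  r <- rank(vals)
  if (any(tapply(r, g, stats::var) == 0))
    stop("a group has zero rank variance: Welch's ANOVA undefined")
  w <- welch_on_values(r, g)
  rank_test_result("Welch's ANOVA on ranks", w$F, "F", w$df, w$p,
                   levels(g))
}

#' Games-Howell post hoc tests on ranks
#'
#' Pairwise comparisons after a significant Welch's ANOVA, on the global
#' mid-ranks: for groups i, j, t = |m_i - m_j| / sqrt(s_i^2/n_i +
#' s_j^2/n_j) with Welch-Satterthwaite degrees of freedom, and the p-value
#' taken from the studentized range distribution with q = t * sqrt(2) and
#' k = the number of groups (which controls the familywise error).
#'
#' @param groups List of >= 2 numeric vectors, each with n >= 2.
#' @return List of `rank_test_result`s, one per unordered pair, each with
#'   a `pair` element.
#' @export
games_howell_ranks <- function(groups) {
  groups <- as_group_list(groups)
  k <- length(groups)
  if (k < 2) stop("need at least 2 groups")
  if (any(lengths(groups) < 2)) stop("each group needs n >= 2")
  vals <- unlist(groups, use.names = FALSE)
  g <- rep(names(groups), lengths(groups))
  r <- rank(vals)
  rs <- split(r, factor(g, levels = names(groups)))
  m <- vapply(rs, mean, numeric(1))
  v <- vapply(rs, stats::var, numeric(1))
  n <- lengths(rs)
  out <- list()
  for (i in seq_len(k - 1L)) {
    for (j in seq.int(i + 1L, k)) {
      se2 <- v[i] / n[i] + v[j] / n[j]
      if (se2 == 0) stop(sprintf(
        "zero pooled rank variance for pair (%s, %s)",
        names(rs)[i], names(rs)[j]))
      t_stat <- abs(m[i] - m[j]) / sqrt(se2)
      df <- se2^2 / ((v[i] / n[i])^2 / (n[i] - 1) +
                     (v[j] / n[j])^2 / (n[j] - 1))
      p <- stats::ptukey(t_stat * sqrt(2), nmeans = k, df = df,
                         lower.tail = FALSE)
      res <- rank_test_result("Games-Howell on ranks", unname(t_stat), "t",
                              unname(df), unname(p),
                              c(names(rs)[i], names(rs)[j]))
      res$pair <- c(names(rs)[i], names(rs)[j])
      out[[paste(names(rs)[i], names(rs)[j], sep = " vs ")]] <- res
    }
  }
  out
}

#' Route a depth-group comparison to the appropriate rank-based test
#'
#' Per-group normality is assessed with Shapiro-Wilk and homoscedasticity
#' with the Brown-Forsythe (median-centred Levene) test, both at `alpha`.
#' Heteroscedastic data route to Welch's ANOVA on ranks, followed by
#' Games-Howell post hoc tests when the global test is significant;
#' homoscedastic data route to Kruskal-Wallis. Normal homoscedastic data
#' also route to Kruskal-Wallis (with a logged note): staying rank-based
#' keeps the pipeline invariant to monotone transforms.
#'
#' @param groups Named list of numeric vectors, each n >= 3.
#' @param alpha Significance level for the assumption checks and for
#'   triggering the post hoc block (default 0.05).
#' @return List with `test` (label), `result` (`rank_test_result`),
#'   `posthoc` (list or NULL), `checks` (assumption p-values and verdicts).
#' @export
select_depth_test <- function(groups, alpha = 0.05) {
  groups <- as_group_list(groups)
  if (length(groups) < 2) stop("need at least 2 groups")
  if (any(lengths(groups) < 3)) stop("each group needs n >= 3")
  sw <- vapply(groups, function(z) {
    if (stats::sd(z) == 0) return(0)  # degenerate: clearly non-normal
    stats::shapiro.test(z)$p.value
  }, numeric(1))
  vals <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), lengths(groups)), levels = names(groups))
  bf <- car::leveneTest(vals ~ g, center = stats::median)
  bf_p <- bf[["Pr(>F)"]][1L]
  normal <- all(sw >= alpha)
  homoscedastic <- bf_p >= alpha
  checks <- list(shapiro_p = sw, brown_forsythe_p = bf_p,
                 normal = normal, homoscedastic = homoscedastic)
  if (!homoscedastic) {
    res <- welch_anova_ranks(groups)
    posthoc <- if (res$p < alpha) games_howell_ranks(groups) else NULL
    list(test = "welch_anova_ranks", result = res, posthoc = posthoc,
         checks = checks,
         note = if (normal) "data normal but heteroscedastic" else "")
  } else {
    res <- kruskal_wallis(groups)
    list(test = "kruskal_wallis", result = res, posthoc = NULL,
         checks = checks,
         note = if (normal)
           "data normal and homoscedastic; rank-based test retained" else "")
  }
}

#' Species accumulation curve (random accumulator)
#'
#' For each number of samples n, the mean and standard deviation of the
#' cumulative species richness over random orderings of the samples. The
#' "exact" method computes the expectation over all orderings in closed
#' form — E[S(n)] = sum over species of 1 - C(N - f_s, n) / C(N, n),
#' with f_s the species' occupancy — which equals the mean of the random
#' accumulator over every permutation.
#'
#' @param presence Logical/0-1 matrix, samples x species.
#' @param n_perm Number of random orderings (default 100; ignored for
#'   "exact").
#' @param seed Optional integer seed (ignored for "exact").
#' @param method "random" (permutation mean and sd) or "exact"
#'   (closed-form mean; sd reported as NA).
#' @return An `accumulation_curve`: data frame with columns `n_samples`,
#'   `richness_mean`, `richness_sd`, plus attributes `n_perm`, `seed`
#'   and `method`.
#' @export
species_accumulation <- function(presence, n_perm = 100, seed = NULL,
                                 method = c("random", "exact")) {
  method <- match.arg(method)
  presence <- as.matrix(presence) > 0
  n <- nrow(presence)
  if (n < 1) stop("need at least one sample")
  if (method == "exact") {
    f <- colSums(presence)
    mean_rich <- vapply(seq_len(n), function(m)
      sum(1 - exp(lchoose(n - f, m) - lchoose(n, m))), numeric(1))
    out <- data.frame(n_samples = seq_len(n), richness_mean = mean_rich,
                      richness_sd = NA_real_)
    return(structure(out, class = c("accumulation_curve", "data.frame"),
                     n_perm = NA_integer_, seed = NULL, method = "exact"))
  }
  if (!is.null(seed)) set.seed(seed)
  rich <- matrix(0, n_perm, n)
  for (b in seq_len(n_perm)) {
    ord <- sample.int(n)
    seen <- rep(FALSE, ncol(presence))
    for (i in seq_len(n)) {
      seen <- seen | presence[ord[i], ]
      rich[b, i] <- sum(seen)
    }
  }
  out <- data.frame(n_samples = seq_len(n),
                    richness_mean = colMeans(rich),
                    richness_sd = apply(rich, 2L, stats::sd))
  structure(out, class = c("accumulation_curve", "data.frame"),
            n_perm = n_perm, seed = seed, method = "random")
}
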