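test_that("the variance decomposition matches hand-computed and aov values", {
  toy <- data.frame(y = c(1, 2, 3, 4, 5, 6),
                    g = rep(c("a", "b"), each = 3))
  fit <- glance(one_way_anova(toy, "y", "g"))
  expect_equal(fit$statistic, 13.5) # SSB 13.5, SSW 4, df (1, 4)
  expect_equal(c(fit$df_between, fit$df_within), c(1, 4))

  # the emulated survey design: group sizes 5/7/8/10 give df (3, 26)
  set.seed(8)
  df <- data.frame(y = rnorm(30), g = rep(letters[1:4], c(5, 7, 8, 10)))
  fit2 <- glance(one_way_anova(df, "y", "g"))
  expect_equal(c(fit2$df_between, fit2$df_within), c(3, 26))
  oracle <- summary(stats::aov(y ~ g, df))[[1]]
  expect_equal(fit2$statistic, oracle$`F value`[1], tolerance = 1e-12)
  expect_equal(fit2$p_value, oracle$`Pr(>F)`[1], tolerance = 1e-12)

  # invariance under shift and positive rescaling
  df2 <- dplyr::mutate(df, y = 3 * y + 100)
  expect_equal(glance(one_way_anova(df2, "y", "g"))$statistic,
               fit2$statistic, tolerance = 1e-9)

  # degenerate cases are defined, not errors
  same <- data.frame(y = rep(5, 8), g = rep(c("a", "b"), 4))
  expect_equal(glance(one_way_anova(same, "y", "g"))$statistic, 0)
  sep <- data.frame(y = rep(c(1, 2), each = 3),
                    g = rep(c("a", "b"), each = 3))
  expect_equal(glance(one_way_anova(sep, "y", "g"))$p_value, 0)
  expect_error(one_way_anova(data.frame(y = 1:3, g = "a"), "y", "g"),
               "2 groups")
})

test_that("LSD p-values equal pooled-variance pairwise t tests", {
  set.seed(21)
  df <- data.frame(y = rnorm(30, rep(c(0, 1, 3, 5), c(5, 7, 8, 10))),
                   g = rep(letters[1:4], c(5, 7, 8, 10)))
  lsd <- fisher_lsd(one_way_anova(df, "y", "g"), protected = FALSE)
  oracle <- stats::pairwise.t.test(df$y, df$g, p.adjust.method = "none",
                                   pool.sd = TRUE)$p.value
  for (r in seq_len(nrow(lsd$pairwise))) {
    g1 <- lsd$pairwise$group1[r]
    g2 <- lsd$pairwise$group2[r]
    p_oracle <- oracle[max(g1, g2), min(g1, g2)]
    expect_equal(lsd$pairwise$p_value[r], unname(p_oracle),
                 tolerance = 1e-12)
  }
})

test_that("compact letters reflect the significance graph", {
  # two identical groups: one shared letter
  same <- data.frame(y = c(1, 2, 3, 1, 2, 3),
                     g = rep(c("a", "b"), each = 3))
  lsd <- fisher_lsd(one_way_anova(same, "y", "g"))
  expect_identical(unique(lsd$letters$letters), "a")

  # one far-separated group earns its own letter
  df <- data.frame(
    y = c(10.1, 10.2, 9.9, 10.0, 10.2, 9.8, 10.1, 10.0, 0.1, 0.2, 0.0),
    g = rep(c("g1", "g2", "low"), c(4, 4, 3))
  )
  lsd2 <- fisher_lsd(one_way_anova(df, "y", "g"))
  lt <- setNames(lsd2$letters$letters, lsd2$letters$group)
  expect_identical(lt[["g1"]], lt[["g2"]])
  expect_false(lt[["low"]] == lt[["g1"]])
  # alphabet follows descending means: the high pair gets "a"
  expect_identical(unname(lt[["g1"]]), "a")
  expect_identical(unname(lt[["low"]]), "b")

  # letters are stable under relabeling up to the group names themselves
  df_rl <- dplyr::mutate(df, g = chartr("gl", "xq", g))
  lsd3 <- fisher_lsd(one_way_anova(df_rl, "y", "g"))
  expect_identical(sort(lsd3$letters$letters), sort(lsd2$letters$letters))

  # sharing iff non-significant, checked pair by pair
  shared <- function(l1, l2) {
    any(strsplit(l1, "")[[1]] %in% strsplit(l2, "")[[1]])
  }
  pw <- lsd2$pairwise
  for (r in seq_len(nrow(pw))) {
    expect_identical(
      shared(lt[[pw$group1[r]]], lt[[pw$group2[r]]]),
      !pw$significant[r]
    )
  }
})

test_that("box statistics follow the type-7 quartiles and Tukey fences", {
  bs <- box_stats(1:4)
  expect_equal(bs$median, 2.5)
  expect_equal(bs$q1, unname(quantile(1:4, 0.25)))
  one <- box_stats(42)
  expect_equal(one$q1, 42)
  expect_equal(one$max, 42)
  expect_equal(one$mean, 42)
  out <- box_stats(c(1, 2, 3, 4, 100))
  expect_equal(out$outliers, 100)
  expect_equal(box_stats(c(1, 2, 3, 4, 5))$outliers, numeric(0))
})

test_that("Bray-Curtis dissimilarity behaves as a bounded semimetric", {
  expect_equal(bray_curtis(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(bray_curtis(c(5, 0), c(0, 3)), 1)
  expect_equal(bray_curtis(c(2, 1), c(1, 1)), 1 / 5)
  expect_equal(bray_curtis(c(7, 0), c(0, 7)), 1) # disjoint at any scale
  set.seed(4)
  m <- matrix(runif(40), 5, 8)
  d <- bray_curtis_matrix(m)
  expect_equal(d, t(d))
  expect_true(all(d >= 0 & d <= 1))
  # oracle: the standard community-ecology implementation
  expect_equal(d, as.matrix(vegan::vegdist(m, "bray")),
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_error(bray_curtis(c(0, 0), c(0, 0)), "all zero")
})

test_that("agglomerative clustering reproduces the reference dendrogram", {
  # two points merge once at their distance
  d2 <- matrix(c(0, 0.4, 0.4, 0), 2, 2)
  cl2 <- ahc_cluster(d2)
  expect_equal(cl2$height, 0.4)
  expect_equal(nrow(cl2$merge), 1)

  # three equidistant points: the lowest-index pair merges first
  d3 <- matrix(0.5, 3, 3); diag(d3) <- 0
  cl3 <- ahc_cluster(d3)
  expect_equal(cl3$merge[1, ], c(-2, -1))

  # ultrametric input is reproduced exactly by average linkage
  du <- matrix(c(0, 1, 4, 4, 1, 0, 4, 4, 4, 4, 0, 2, 4, 4, 2, 0), 4, 4)
  clu <- ahc_cluster(du, "average")
  expect_equal(sort(clu$height), c(1, 2, 4))

  # all three linkages agree with the classical implementation
  set.seed(10)
  dm <- as.matrix(dist(matrix(rnorm(27), 9, 3)))
  for (lk in c("average", "complete", "single")) {
    mine <- ahc_cluster(dm, lk)
    oracle <- stats::hclust(stats::as.dist(dm), method = lk)
    expect_equal(sort(mine$height), sort(oracle$height),
                 tolerance = 1e-12)
    expect_true(all(diff(mine$height) >= -1e-12)) # monotone heights
    expect_s3_class(stats::as.hclust(mine), "hclust")
  }
  expect_error(ahc_cluster(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("correspondence analysis matches a brute-force decomposition", {
  set.seed(6)
  x <- matrix(rpois(48, 10) + 1, 6, 8)
  ca <- correspondence_analysis(x)
  # oracle: direct eigendecomposition of the standardized cross-product
  p <- x / sum(x); r <- rowSums(p); cc <- colSums(p)
  s <- diag(1 / sqrt(r)) %*% (p - r %o% cc) %*% diag(1 / sqrt(cc))
  ev <- eigen(t(s) %*% s, symmetric = TRUE)$values
  ev <- ev[ev > 1e-12]
  expect_equal(ca$inertia_fractions, ev / sum(s^2), tolerance = 1e-8)
  expect_equal(sum(ca$inertia_fractions), 1, tolerance = 1e-9)
  expect_equal(length(ca$eigenvalues), min(nrow(x), ncol(x)) - 1)
  expect_true(all(diff(ca$inertia_fractions) <= 1e-12))

  # independence (rank-1) table carries no inertia
  indep <- outer(c(1, 2, 3), c(4, 1, 2, 3))
  ca0 <- correspondence_analysis(indep)
  expect_equal(ca0$total_inertia, 0, tolerance = 1e-12)
  expect_equal(length(ca0$eigenvalues), 0)

  # any 2x2 association is one-dimensional
  ca22 <- correspondence_analysis(matrix(c(10, 2, 3, 9), 2, 2))
  expect_equal(ca22$inertia_fractions, 1)

  expect_error(correspondence_analysis(matrix(c(1, -1, 2, 3), 2, 2)),
               ">= 0")
  expect_error(correspondence_analysis(rbind(c(1, 2), c(0, 0))),
               "all-zero")
})

test_that("constrained ordination agrees with the reference CCA", {
  set.seed(12)
  x <- matrix(rpois(60, 12) + 1, 6, 10)
  z <- data.frame(grp = factor(rep(c("a", "b", "c"), 2)), cov = rnorm(6))
  mine <- correspondence_analysis(x, constraints = z)
  oracle <- vegan::cca(x ~ grp + cov, data = z)
  expect_equal(mine$eigenvalues,
               unname(oracle$CCA$eig)[seq_along(mine$eigenvalues)],
               tolerance = 1e-8)
  expect_true(mine$constrained)
  expect_lte(sum(mine$inertia_fractions), 1 + 1e-12)
  dup <- data.frame(a = 1:6, b = 2 * (1:6)) # collinear covariates
  expect_error(correspondence_analysis(x, constraints = dup),
               "rank-deficient")
})
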