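test_that("Bray-Curtis dissimilarity matches hand computations and its bounds", {
  prof <- rbind(a = c(0.6, 0.4, 0), b = c(0.2, 0.3, 0.5))
  expect_equal(as.numeric(bray_curtis(prof)), 0.5)
  ident <- rbind(a = c(0.5, 0.5, 0), b = c(0.5, 0.5, 0))
  expect_equal(as.numeric(bray_curtis(ident)), 0)
  disj <- rbind(a = c(1, 0), b = c(0, 1))
  expect_equal(as.numeric(bray_curtis(disj)), 1)
  # bounds, symmetry, zero diagonal, invariance to joint column permutation
  set.seed(2)
  m <- matrix(rpois(60, 30), nrow = 5,
              dimnames = list(paste0("s", 1:5), paste0("v", 1:12)))
  d <- as.matrix(bray_curtis(m))
  expect_true(all(d >= 0 & d <= 1))
  expect_equal(d, t(d))
  expect_equal(unname(diag(d)), rep(0, 5))
  perm <- sample(12)
  expect_equal(as.matrix(bray_curtis(m[, perm])), d)
})

test_that("NMDS embeds rank-compatible configurations with near-zero stress", {
  set.seed(4)
  pts <- matrix(rnorm(20), ncol = 2)
  rownames(pts) <- paste0("s", 1:10)
  ord <- suppressWarnings(nmds_ordination(dist(pts), k = 2, restarts = 20,
                                          seed = 9))
  expect_lt(ord$stress, 0.01)
  expect_equal(dim(ord$points), c(10, 2))
  # an identical pair of samples lands on (essentially) the same point
  m <- rbind(pts, s11 = pts[1, ] + 1e-9)
  ord2 <- suppressWarnings(nmds_ordination(dist(m), k = 2, restarts = 20,
                                           seed = 9))
  expect_lt(sqrt(sum((ord2$points["s11", ] - ord2$points["s1", ])^2)),
            0.05 * max(dist(ord2$points)))
  expect_error(nmds_ordination(dist(pts[1:3, ]), k = 2), "at least")
})

test_that("PERMANOVA matches the exhaustive enumeration oracle on small n", {
  set.seed(6)
  for (sizes in list(c(3, 3), c(4, 4), c(3, 5))) {
    m <- matrix(rpois(sum(sizes) * 8, 15), nrow = sum(sizes))
    m[seq_len(sizes[1]), 1:3] <- m[seq_len(sizes[1]), 1:3] + 20
    rownames(m) <- paste0("s", seq_len(sum(sizes)))
    grp <- rep(c("g1", "g2"), sizes)
    d <- bray_curtis(m)
    res <- permanova(d, grp, method = "exhaustive")
    expect_equal(res$n_permutations, choose(sum(sizes), sizes[1]))
    expect_equal(res$pseudo_F, oracle_pseudo_f(as.matrix(d), grp),
                 tolerance = 1e-12)
    expect_equal(res$p_value, oracle_exhaustive_p(as.matrix(d), grp),
                 tolerance = 1e-12)
  }
})

test_that("PERMANOVA agrees with the vegan reference implementation", {
  set.seed(10)
  m <- matrix(rpois(12 * 20, 25), nrow = 12,
              dimnames = list(paste0("s", 1:12), NULL))
  grp <- rep(c("a", "b", "c"), each = 4)
  m[grp == "c", 1:5] <- m[grp == "c", 1:5] + 15
  d <- bray_curtis(m)
  res <- permanova(d, grp, n_perm = 999, seed = 1)
  ref <- vegan::adonis2(d ~ grp, permutations = 999)
  expect_equal(res$pseudo_F, ref$F[1], tolerance = 1e-10)
  expect_equal(res$R2, ref$R2[1], tolerance = 1e-10)
  expect_lt(abs(res$p_value - ref$`Pr(>F)`[1]), 0.05)
})

test_that("maximally separated groups reach the smallest attainable p", {
  m <- rbind(matrix(rpois(50, 30), 5, 10), matrix(0L, 5, 10))
  m <- cbind(m, rbind(matrix(0L, 5, 10), matrix(rpois(50, 30), 5, 10)))
  rownames(m) <- paste0("s", 1:10)
  grp <- rep(c("a", "b"), each = 5)
  d <- bray_curtis(m)
  ex <- permanova(d, grp, method = "exhaustive")
  # only the observed split and its label swap tie the observed F
  expect_equal(ex$p_value, 2 / choose(10, 5))
  sam <- permanova(d, grp, n_perm = 999, seed = 3)
  expect_lte(sam$p_value, 0.02)
  expect_error(permanova(d, c("a", rep("b", 9))), "n >= 2")
})

test_that("within-group dispersion pools the right pairs and detects heterogeneity", {
  set.seed(12)
  sim <- simulate_asv_table(sim_config(seed = 12))
  filt <- filter_contaminants(sim$table)$table
  d <- bray_curtis(filt)
  grp <- filt$sample_meta$treatment
  disp <- within_group_dispersion(d, grp)
  expect_equal(as.vector(table(disp$values$group)), rep(choose(5, 2), 3))
  expect_equal(disp$values$similarity, 1 - disp$values$dissimilarity)
  expect_equal(disp$kruskal$df, 2)
  # the aposymbiotic group is planted 10x more dispersed
  med <- tapply(disp$values$dissimilarity, disp$values$group, median)
  expect_gt(med[["ApoL"]], med[["SymL"]])
  expect_gt(med[["ApoL"]], med[["SymD"]])
  expect_lt(disp$kruskal$p_value, 0.001)
  expect_true(all(disp$pairwise$p_holm <= 1))
  # identical group distributions give a near-zero statistic
  dd <- matrix(0.5, 9, 9); diag(dd) <- 0
  rownames(dd) <- colnames(dd) <- paste0("s", 1:9)
  disp0 <- suppressWarnings(within_group_dispersion(dd, rep(c("a", "b", "c"), 3)))
  expect_equal(disp0$kruskal$chi2, 0, tolerance = 1e-12)
  expect_error(within_group_dispersion(dd, c(rep("a", 7), "b", "b")),
               "n >= 3")
})
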