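test_that("the overlap matrix counts pairwise intersections with sizes on the diagonal", {
  sets <- list(a = paste0("g", 1:10), b = paste0("g", 6:15),
               c = paste0("g", 20:24))
  om <- overlap_matrix(sets)
  expect_equal(unname(diag(om)), c(10, 10, 5))
  expect_equal(om["a", "b"], 5L)
  expect_equal(om["a", "c"], 0L)
  expect_equal(unclass(om), t(unclass(om)), ignore_attr = TRUE)

  # brute-force oracle on random sets
  set.seed(12)
  u <- paste0("g", 1:100)
  rs <- setNames(lapply(1:4, function(i) sample(u, sample(5:40, 1))),
                 paste0("s", 1:4))
  om <- overlap_matrix(rs)
  for (i in 1:4) for (j in 1:4) {
    expect_equal(om[i, j], length(intersect(rs[[i]], rs[[j]])))
  }
  expect_error(overlap_matrix(list(a = u[1:3], a = u[4:6])), "duplicate")
})

test_that("the common-gene core is the strict all-set intersection", {
  s <- paste0("g", 1:20)
  expect_setequal(common_genes(list(a = s, b = s)), tolower(s))
  expect_lte(length(common_genes(list(a = s, b = paste0("g", 15:40)))), 20)
  expect_length(common_genes(list(a = s[1:5], b = s[10:15])), 0)

  # planted 87-gene core plus per-set noise is recovered exactly
  set.seed(13)
  core <- sprintf("core%03d", 1:87)
  noise_pool <- sprintf("n%04d", 1:2000)
  sets <- setNames(lapply(1:8, function(i) {
    sample(c(core, sample(noise_pool, 150)))
  }), paste0("cond", 1:8))
  got <- common_genes(sets)
  expect_setequal(got, tolower(core))

  # order-independent and idempotent
  expect_setequal(common_genes(rev(sets)), got)
  expect_setequal(common_genes(c(sets, list(again = got))), got)
})

test_that("mean fold-change ranking averages across conditions and sorts", {
  p1 <- make_profile(c(2, -1, 0.5), genes = c("a", "b", "c"))
  p2 <- make_profile(c(4, -3, 0.5), genes = c("a", "b", "c"))
  tab <- rank_by_mean_fc(c("a", "b", "c"), list(p1, p2))
  expect_equal(tab$mean_log2_fc[tab$gene_id == "a"], 3)
  expect_equal(tab$gene_id, c("a", "c", "b"))  # sorted descending
  expect_equal(tab$rank, 1:3)

  # identical profiles reduce to the single-profile ranking
  tab1 <- rank_by_mean_fc(c("a", "b", "c"), list(p1, p1))
  expect_equal(tab1$mean_log2_fc,
               sort(p1$log2_fc, decreasing = TRUE))

  # genes missing from one profile are dropped with a warning
  p3 <- make_profile(c(1, 2), genes = c("a", "b"))
  expect_warning(tab2 <- rank_by_mean_fc(c("a", "b", "c"), list(p1, p3)),
                 "missing")
  expect_setequal(tab2$gene_id, c("a", "b"))
})

test_that("score-vector correlation matches the Pearson formula and is affine-invariant", {
  v1 <- c(10.45, 9.64, 7.58, 6.70, 3.67, 3.50, 1.50, 0.04)
  v2 <- 2 * v1 + 1
  expect_equal(correlate_scores(v1, v2)$r_squared, 1, tolerance = 1e-12)

  set.seed(14)
  v3 <- v1[sample(8)]
  cs <- correlate_scores(v1, v3)
  expect_equal(cs$pearson_r, pearson_oracle(v1, v3), tolerance = 1e-12)
  expect_equal(cs$r_squared, pearson_oracle(v1, v3)^2, tolerance = 1e-12)

  # positive affine maps leave R^2 unchanged
  expect_equal(correlate_scores(5 * v1 - 2, v3)$r_squared, cs$r_squared,
               tolerance = 1e-12)
  expect_error(correlate_scores(rep(1, 5), v1[1:5]), "zero-variance")
  expect_error(correlate_scores(1:2, 1:2), "length")
})

test_that("the PCA embedding is a centered SVD with a fixed sign convention", {
  # two mirror-image items collapse onto PC1 at +/- the vector norm
  x <- c(3, 4, 0, 0)
  tab <- rbind(i1 = x, i2 = -x)
  emb <- pca_embed(tab)
  expect_equal(unname(abs(emb$points[, 1])), c(5, 5), tolerance = 1e-9)
  expect_equal(sum(emb$points[, 1]), 0, tolerance = 1e-9)
  expect_equal(emb$explained_variance_fraction[1], 1, tolerance = 1e-12)

  set.seed(15)
  tab <- matrix(rnorm(60), 6, 10,
                dimnames = list(paste0("i", 1:6), paste0("f", 1:10)))
  emb <- pca_embed(tab)
  evf <- emb$explained_variance_fraction
  expect_true(all(diff(evf) <= 1e-12))
  expect_lte(sum(evf), 1 + 1e-9)
  # round trip: scores x loadings' reproduces the centered table
  recon <- emb$points %*% t(emb$rotation)
  expect_equal(recon, sweep(tab, 2, emb$center), tolerance = 1e-9,
               ignore_attr = TRUE)
  # sign convention: the largest-|loading| entry of each component is positive
  for (j in seq_len(ncol(emb$rotation))) {
    expect_gt(emb$rotation[which.max(abs(emb$rotation[, j])), j], 0)
  }
  # agreement with prcomp up to the sign convention
  pc <- stats::prcomp(tab, center = TRUE, scale. = FALSE)
  expect_equal(abs(emb$points), abs(pc$x[, 1:ncol(emb$points)]),
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_error(pca_embed(matrix(1, 3, 3)), "constant")
})

test_that("silhouette separation scores match intuition and the cluster package", {
  pts <- rbind(c(0, 0), c(0, 1), c(10, 10), c(10, 11))
  grp <- c("a", "a", "b", "b")
  res <- cluster_separation_check(pts, grp)
  expect_gt(res$score, 0.9)
  if (requireNamespace("cluster", quietly = TRUE)) {
    sil <- cluster::silhouette(as.integer(factor(grp)), stats::dist(pts))
    expect_equal(res$score, mean(sil[, "sil_width"]), tolerance = 1e-12)
  }

  # random labels on a single Gaussian cloud: mean near zero over 100 runs
  set.seed(16)
  cloud <- matrix(rnorm(60), 30, 2)
  scores <- vapply(1:100, function(i) {
    cluster_separation_check(cloud, sample(c("a", "b"), 30, TRUE))$score
  }, numeric(1))
  expect_gt(mean(scores), -0.2)
  expect_lt(mean(scores), 0.2)

  # singleton groups take silhouette 0 by convention, with a flag
  res1 <- cluster_separation_check(rbind(c(0, 0), c(5, 5), c(9, 1)),
                                   c("a", "b", "c"))
  expect_equal(res1$score, 0)
  expect_true(res1$singleton_flag)
  expect_error(cluster_separation_check(pts, rep("a", 4)), "two groups")
})

test_that("embedding module-score vectors separates platforms in a synthetic table", {
  # module x condition z table with a platform effect: PCA of condition
  # vectors splits the two platforms
  set.seed(17)
  base <- rnorm(8, 0, 1)
  z <- cbind(vivo1 = base + rnorm(8, 3, 0.3), vivo2 = base + rnorm(8, 3, 0.3),
             vitro1 = base + rnorm(8, -3, 0.3), vitro2 = base + rnorm(8, -3, 0.3))
  emb <- pca_embed(t(z))
  sep <- cluster_separation_check(emb, c("vivo", "vivo", "vitro", "vitro"))
  expect_gt(sep$score, 0.5)
})
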