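test_that("gene matching is a case-folded intersection", {
  prof <- make_profile(c(1, 2, 3), genes = c("gsta2", "mt2a", "cbr1"))
  mm <- match_genes(c("GSTA2", "MT2A"), prof)
  expect_equal(mm$n_matched, 2)
  expect_setequal(mm$matched, c("gsta2", "mt2a"))
  expect_length(mm$unmatched, 0)

  expect_equal(match_genes(c("x", "y"), prof)$n_matched, 0)

  set.seed(5)
  pool <- sprintf("G%03d", 1:60)
  for (i in 1:100) {
    prof_genes <- sample(pool, 30)
    set_genes <- sample(pool, sample(1:20, 1))
    prof <- make_profile(rnorm(30), genes = prof_genes)
    mm <- match_genes(set_genes, prof)
    expect_setequal(tolower(mm$matched),
                    intersect(tolower(set_genes), tolower(prof_genes)))
  }
})

test_that("AAFC and AFC are the mean absolute and mean signed fold change", {
  prof <- make_profile(c(1, -1, 0), genes = c("a", "b", "c"))
  expect_equal(aafc_score(prof, c("a", "b")), 1)
  expect_equal(afc_score(prof, c("a", "b")), 0)
  expect_equal(aafc_score(prof, "c"), 0)
  expect_equal(afc_score(prof, c("a", "a")), 1)  # duplicates collapse

  set.seed(6)
  fc <- rnorm(30)
  prof <- make_profile(fc, genes = sprintf("g%02d", 1:30))
  picked <- sample(prof$gene_id, 12)
  idx <- match(picked, prof$gene_id)
  expect_equal(aafc_score(prof, picked), sum(abs(fc[idx])) / 12,
               tolerance = 1e-12)
  expect_equal(afc_score(prof, picked), sum(fc[idx]) / 12, tolerance = 1e-12)

  # triangle inequality over random inputs
  for (i in 1:1000) {
    fc <- rnorm(sample(2:15, 1))
    prof <- make_profile(fc, genes = paste0("x", seq_along(fc)))
    expect_lte(abs(afc_score(prof, prof$gene_id)),
               aafc_score(prof, prof$gene_id) + 1e-12)
  }
  expect_error(aafc_score(prof, character()), "empty")
})

test_that("exhaustive null enumerates every subset exactly", {
  prof <- make_profile(c(1, 2, 3, 4), genes = paste0("g", 1:4))
  nul <- permutation_null(prof, 2, "aafc", mode = "exhaustive")
  expect_equal(sort(nul$null_scores), c(1.5, 2.0, 2.5, 2.5, 3.0, 3.5))
  expect_equal(nul$null_mean, 2.5)
  expect_equal(nul$null_sd, sqrt(2.5 / 6), tolerance = 1e-12)
  expect_equal(nul$mode, "exhaustive")

  # constant profile: degenerate null
  prof <- make_profile(rep(3, 6), genes = paste0("g", 1:6))
  nul <- permutation_null(prof, 2, "aafc", mode = "exhaustive")
  expect_equal(nul$null_sd, 0)
  expect_true(all(nul$null_scores == 3))
})

test_that("Monte-Carlo null converges to the exhaustive null", {
  set.seed(7)
  prof <- make_profile(rnorm(12), genes = sprintf("g%02d", 1:12))
  exh <- permutation_null(prof, 4, "aafc", mode = "exhaustive")
  mc <- permutation_null(prof, 4, "aafc", n_resamples = 10000, seed = 99,
                         mode = "monte_carlo")
  expect_lt(abs(mc$null_mean - exh$null_mean),
            3 * exh$null_sd / sqrt(10000))
  # seeded reproducibility
  mc2 <- permutation_null(prof, 4, "aafc", n_resamples = 10000, seed = 99,
                          mode = "monte_carlo")
  expect_identical(mc$null_scores, mc2$null_scores)
  expect_error(permutation_null(prof, 13, "aafc"), "set_size")
  expect_error(permutation_null(prof, 4, "aafc", n_resamples = 10), "100")
})

test_that("module scoring matches the full-enumeration oracle", {
  prof <- make_profile(c(1, 2, 3, 4), genes = paste0("g", 1:4))
  res <- score_module(prof, c("g3", "g4"), "aafc", mode = "exhaustive")
  expect_equal(res$score, 3.5)
  expect_equal(res$null_mean, 2.5)
  expect_equal(res$null_sd, sqrt(2.5 / 6), tolerance = 1e-12)
  expect_equal(res$z_score, (3.5 - 2.5) / sqrt(2.5 / 6), tolerance = 1e-9)
  expect_equal(res$z_score, 1.549, tolerance = 1e-3)
  expect_false(res$activated)
  # exact exhaustive tail: 1 of 6 subsets scores >= 3.5
  expect_equal(res$p_empirical, 1 / 6, tolerance = 1e-12)
})

test_that("activation threshold separates reported strong and weak modules", {
  # magnitudes taken from the shipped activation-score fixture
  t4 <- table4_fixture()
  hd_lt <- t4$invivo_33h_HD
  names(hd_lt) <- t4$module
  expect_gt(hd_lt[["Dilatation"]], 2)   # called activated
  expect_lt(hd_lt[["Hypertrophy"]], 2)  # not activated
  expect_equal(sum(hd_lt > 2), 6)       # bold entries in that column
})

test_that("a whole-universe module has a degenerate null", {
  prof <- make_profile(c(1, 2, 3), genes = paste0("g", 1:3))
  expect_warning(res <- score_module(prof, paste0("g", 1:3), "aafc"),
                 "degenerate")
  expect_true(is.na(res$z_score))
  expect_true(is.na(res$p_empirical))
  expect_false(res$activated)
})

test_that("z is invariant under global scaling and shifts move score and null together", {
  set.seed(8)
  fc <- rnorm(10)
  prof <- make_profile(fc, genes = paste0("g", 1:10))
  mod <- paste0("g", c(2, 5, 8))
  r1 <- score_module(prof, mod, "aafc", mode = "exhaustive")
  prof_scaled <- make_profile(3.7 * fc, genes = paste0("g", 1:10))
  r2 <- score_module(prof_scaled, mod, "aafc", mode = "exhaustive")
  expect_equal(r1$z_score, r2$z_score, tolerance = 1e-9)

  # adding a constant to every |FC| shifts score and null mean equally
  afc <- abs(fc)
  pa <- make_profile(afc, genes = paste0("g", 1:10))
  pb <- make_profile(afc + 2, genes = paste0("g", 1:10))
  ra <- score_module(pa, mod, "aafc", mode = "exhaustive")
  rb <- score_module(pb, mod, "aafc", mode = "exhaustive")
  expect_equal(rb$score - ra$score, 2, tolerance = 1e-12)
  expect_equal(rb$null_mean - ra$null_mean, 2, tolerance = 1e-12)
  expect_equal(ra$z_score, rb$z_score, tolerance = 1e-9)
})

test_that("the AFC empirical p is two-sided and the AAFC p upper-tailed", {
  prof <- make_profile(c(-4, -0.2, 0, 0.2, 4), genes = paste0("g", 1:5))
  up <- score_module(prof, "g5", "afc", mode = "exhaustive")
  dn <- score_module(prof, "g1", "afc", mode = "exhaustive")
  expect_equal(up$p_empirical, dn$p_empirical, tolerance = 1e-12)
  expect_true(dn$z_score < 0 && up$z_score > 0)

  aafc <- score_module(prof, "g5", "aafc", mode = "exhaustive")
  expect_equal(aafc$p_empirical, 2 / 5, tolerance = 1e-12)  # |fc| ties at 4
})

test_that("the module x condition fit is deterministic and order-independent", {
  set.seed(9)
  profs <- list(
    a = make_profile(rnorm(60), genes = sprintf("g%02d", 1:60),
                     condition = list(platform = "p", dose = "low", time = "t1")),
    b = make_profile(rnorm(60), genes = sprintf("g%02d", 1:60),
                     condition = list(platform = "p", dose = "high", time = "t1")))
  mods <- gene_set_collection(list(m1 = sprintf("g%02d", 1:8),
                                   m2 = sprintf("g%02d", 21:30),
                                   m3 = c("zz1", "zz2")))  # unmatched
  f1 <- module_activation(profs, mods, n_resamples = 500, seed = 42,
                          mode = "monte_carlo")
  f2 <- module_activation(profs, mods, n_resamples = 500, seed = 42,
                          mode = "monte_carlo")
  expect_identical(f1$results, f2$results)
  expect_equal(dim(coef(f1)), c(3, 2))

  # unmatched module becomes a flagged cell, not a run failure
  notes <- f1$results$note[f1$results$module == "m3"]
  expect_true(all(grepl("no profiled gene", notes)))
  expect_true(all(is.na(coef(f1)["m3", ])))

  # reversing condition order leaves each cell unchanged (child streams)
  f3 <- module_activation(rev(profs), mods, n_resamples = 500, seed = 42,
                          mode = "monte_carlo")
  expect_equal(coef(f3)[, colnames(coef(f1))], coef(f1))

  # empty collection: empty table, no error
  f0 <- module_activation(profs, gene_set_collection(list()))
  expect_equal(nrow(f0$results), 0)

  # methods surface
  expect_output(print(f1), "module_activation fit")
  expect_output(print(summary(f1)), "activated modules")
  expect_s3_class(as.data.frame(f1), "data.frame")
})
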