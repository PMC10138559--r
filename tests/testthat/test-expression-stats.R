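test_that("log transform matches log2(x + pseudocount) and guards state", {
  m <- matrix(c(0, 3, 7, 1), 2, 2,
              dimnames = list(c("g1", "g2"), c("s1", "s2")))
  em <- log_transform(expression_matrix(m))
  expect_equal(em$values["g1", "s1"], 0)
  expect_equal(em$values["g2", "s1"], 2)
  expect_true(em$is_log2)
  expect_error(log_transform(em), "already log2")

  set.seed(1)
  raw <- matrix(runif(20, 0, 100), 5, 4,
                dimnames = list(paste0("g", 1:5), paste0("s", 1:4)))
  expect_equal(log_transform(expression_matrix(raw))$values,
               log2(raw + 1), tolerance = 1e-15)
  expect_error(expression_matrix(raw - 50), ">= 0")
})

test_that("fold changes equal the difference of cohort means", {
  vals <- rbind(g1 = c(3, 3, 3, 5, 5, 5),
                g2 = c(1, 2, 3, 1, 2, 3))
  colnames(vals) <- c(paste0("c", 1:3), paste0("t", 1:3))
  em <- expression_matrix(vals, is_log2 = TRUE)
  pair <- cohort_pair(list(platform = "p", dose = "d", time = "t"),
                      paste0("c", 1:3), paste0("t", 1:3))
  prof <- fold_changes(em, pair)
  expect_equal(prof$log2_fc, c(2, 0))

  # brute-force oracle on a random 20-gene 3v3 cohort
  set.seed(2)
  vals <- matrix(rnorm(120), 20, 6,
                 dimnames = list(sprintf("g%02d", 1:20),
                                 c(paste0("c", 1:3), paste0("t", 1:3))))
  em <- expression_matrix(vals, is_log2 = TRUE)
  prof <- fold_changes(em, pair)
  oracle <- vapply(1:20, function(i) {
    mean(vals[i, 4:6]) - mean(vals[i, 1:3])
  }, numeric(1))
  expect_equal(prof$log2_fc, oracle, tolerance = 1e-12)

  # antisymmetry: swapping cohort roles negates every fold change
  swapped <- cohort_pair(pair$condition, pair$treated, pair$control)
  expect_equal(fold_changes(em, swapped)$log2_fc, -prof$log2_fc,
               tolerance = 1e-12)
})

test_that("genes with missing values are dropped per cohort with a warning", {
  vals <- matrix(rnorm(24), 4, 6,
                 dimnames = list(paste0("g", 1:4),
                                 c(paste0("c", 1:3), paste0("t", 1:3))))
  vals[1, 1:2] <- NA  # only one usable control value
  em <- expression_matrix(vals, is_log2 = TRUE)
  pair <- cohort_pair(list(platform = "p", dose = "d", time = "t"),
                      paste0("c", 1:3), paste0("t", 1:3))
  expect_warning(prof <- fold_changes(em, pair), "dropped")
  expect_false("g1" %in% prof$gene_id)
  expect_equal(attr(prof, "n_dropped"), 1L)
})

test_that("Welch test agrees with t.test and handles degenerate cohorts", {
  # identical, zero-variance cohorts carry no evidence
  vals <- matrix(5, 3, 6, dimnames = list(paste0("g", 1:3),
                                          c(paste0("c", 1:3), paste0("t", 1:3))))
  em <- expression_matrix(vals, is_log2 = TRUE)
  pair <- cohort_pair(list(platform = "p", dose = "d", time = "t"),
                      paste0("c", 1:3), paste0("t", 1:3))
  prof <- de_test(em, pair)
  expect_equal(prof$p_value, rep(1, 3))
  expect_equal(prof$log2_fc, rep(0, 3))

  # per-gene agreement with stats::t.test (independent route)
  set.seed(3)
  vals <- matrix(rnorm(10 * 9), 10, 9,
                 dimnames = list(sprintf("g%02d", 1:10),
                                 c(paste0("c", 1:4), paste0("t", 1:5))))
  em <- expression_matrix(vals, is_log2 = TRUE)
  pair <- cohort_pair(list(platform = "p", dose = "d", time = "t"),
                      paste0("c", 1:4), paste0("t", 1:5))
  prof <- de_test(em, pair)
  oracle <- vapply(1:10, function(i) {
    stats::t.test(vals[i, 5:9], vals[i, 1:4])$p.value
  }, numeric(1))
  expect_equal(prof$p_value, oracle, tolerance = 1e-12)
})

test_that("planted signals dominate the Welch p-values", {
  genes <- sprintf("g%05d", 1:100)
  d <- small_design(1000, seed = 61, noise_sd = 0.3,
                    n_control = 5, n_treated = 5)
  eff <- planted_effect("m", genes, effect_log2 = 3, direction_mix = 1)
  sim <- simulate_experiment(d, list(eff))
  prof <- de_test(sim$matrix, sim$pairs[[1]])
  expect_gte(sum(prof$p_value[match(genes, prof$gene_id)] < 0.01), 95)
})

test_that("BH adjustment matches the hand-computed step-up", {
  expect_equal(bh_adjust(c(0.002, 0.01, 0.03, 0.04)),
               c(0.008, 0.02, 0.04, 0.04), tolerance = 1e-12)
  expect_equal(bh_adjust(1), 1)
  set.seed(4)
  for (i in 1:25) {
    p <- runif(sample(5:200, 1))
    q <- bh_adjust(p)
    expect_equal(q, bh_oracle(p), tolerance = 1e-12)
    expect_true(all(q >= p))
    expect_true(all(q <= 1))
  }
  expect_error(bh_adjust(c(0.2, 1.3)), "\\[0, 1\\]")
})

test_that("DEG calling applies an inclusive q-value threshold", {
  prof <- make_profile(c(1, -1, 0.5), p = c(0.001, 0.5, 0.9))
  prof$q_value <- c(0.05, 0.10, 0.11)
  degs <- call_degs(prof, 0.1)
  expect_setequal(degs$gene_ids, prof$gene_id[1:2])
  expect_equal(degs$q_threshold, 0.1)

  prof$q_value <- rep(1, 3)
  expect_length(call_degs(prof)$gene_ids, 0)
  expect_error(call_degs(make_profile(c(1, 2))), "q_value")
})
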