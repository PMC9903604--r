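test_that("assign_class_means realises the idealised pattern of every class", {
  # frozen worked examples
  m <- assign_class_means(100, "additive_M_gt_P", 2)
  expect_equal(c(m$mu_M, m$mu_P, m$mu_H), c(200, 50, 125))
  m <- assign_class_means(100, "additive_conserved", 3)
  expect_equal(c(m$mu_M, m$mu_H, m$mu_P), c(100, 100, 100))
  m <- assign_class_means(100, "trans_up_M_eq_P", 1)
  expect_equal(c(m$mu_M, m$mu_P, m$mu_H), c(100, 100, 200))
  expect_error(assign_class_means(100, "no_such_class", 1), "no_such_class")
  expect_error(assign_class_means(-1, "additive_conserved", 1), "positive")

  # defining relations hold exactly for all 13 classes at several baselines
  tab <- triad_class_table()
  for (b in c(0.5, 10, 1234.5)) {
    for (i in seq_len(nrow(tab))) {
      mm <- assign_class_means(b, tab$class_label[i], 1.7)
      dir <- tab$s_mp[i]
      expect_equal(sign(mm$mu_M - mm$mu_P), dir, info = tab$class_label[i])
      switch(tab$category[i],
        additive = expect_equal(mm$mu_H, (mm$mu_M + mm$mu_P) / 2),
        ELD_M = expect_identical(mm$mu_H, mm$mu_M),
        ELD_P = expect_identical(mm$mu_H, mm$mu_P),
        transgressive_up = expect_true(mm$mu_H > max(mm$mu_M, mm$mu_P)),
        transgressive_down = expect_true(mm$mu_H < min(mm$mu_M, mm$mu_P)))
    }
  }
})

test_that("simulate_triad_counts is deterministic and degenerates sensibly", {
  spec <- small_sim_spec(n_genes = 200)
  s1 <- simulate_triad_counts(spec)
  s2 <- simulate_triad_counts(spec)
  expect_identical(s1$counts$values, s2$counts$values)
  expect_identical(s1$truth, s2$truth)

  s3 <- simulate_triad_counts(small_sim_spec(n_genes = 200, seed = 43L))
  expect_false(identical(s1$counts$values, s3$counts$values))

  empty <- simulate_triad_counts(small_sim_spec(n_genes = 0))
  expect_identical(nrow(empty$counts$values), 0L)
  expect_identical(nrow(empty$truth), 0L)

  degen <- simulate_triad_counts(small_sim_spec(n_genes = 100,
                                                effect_log2 = 0,
                                                dispersion = 0))
  expect_true(all(degen$truth$class_label == "additive_conserved"))
  expect_equal(degen$truth$mu_M, degen$truth$mu_H)
  expect_equal(degen$truth$mu_M, degen$truth$mu_P)
})

test_that("simulated truth means satisfy the generating class relations", {
  sim <- simulate_triad_counts(small_sim_spec(n_genes = 2000, seed = 3L))
  tr <- sim$truth
  add <- tr$category == "additive"
  expect_equal(tr$mu_H[add], (tr$mu_M[add] + tr$mu_P[add]) / 2)
  expect_identical(tr$mu_H[tr$category == "ELD_M"],
                   tr$mu_M[tr$category == "ELD_M"])
  expect_identical(tr$mu_H[tr$category == "ELD_P"],
                   tr$mu_P[tr$category == "ELD_P"])
  up <- tr$category == "transgressive_up"
  expect_true(all(tr$mu_H[up] > pmax(tr$mu_M[up], tr$mu_P[up])))
  dn <- tr$category == "transgressive_down"
  expect_true(all(tr$mu_H[dn] < pmin(tr$mu_M[dn], tr$mu_P[dn])))
})

test_that("per-gene sample means track the analytic NB expectation", {
  # oracle: the expected count of gene g in genotype G is
  # mu_gG * len_g * library_size / sum_g(mu_gG * len_g); the mean over
  # replicates is an unbiased estimate, so relative errors centre on 0.
  spec <- small_sim_spec(n_genes = 2000, seed = 1L)
  sim <- simulate_triad_counts(spec)
  tr <- sim$truth
  for (g in c("M", "H", "P")) {
    mu <- tr[[paste0("mu_", g)]]
    expected <- mu * tr$gene_length_bp
    expected <- expected * spec$library_size / sum(expected)
    j <- sim$counts$samples$genotype == g
    obs <- rowMeans(sim$counts$values[, j, drop = FALSE])
    keep <- expected > 50     # relative error is meaningful away from 0
    rel <- (obs[keep] - expected[keep]) / expected[keep]
    expect_lt(abs(mean(rel)), 0.02)
  }
})

test_that("empirical class frequencies match the generating mixture", {
  spec <- triad_sim_spec(n_genes = 20000, daps = 3L, seed = 2024L)
  sim <- simulate_triad_counts(spec)
  p <- spec$class_proportions
  p <- p[p > 0]
  obs <- table(factor(sim$truth$class_label, names(p)))
  gof <- suppressWarnings(stats::chisq.test(obs, p = p / sum(p)))
  expect_gt(gof$p.value, 0.01)
})

test_that("library jitter perturbs totals and spec validation catches misuse", {
  sim <- simulate_triad_counts(small_sim_spec(n_genes = 400,
                                              library_jitter = 0.1,
                                              dispersion = 0))
  totals <- colSums(sim$counts$values)
  expect_gt(diff(range(totals)) / mean(totals), 0.02)
  expect_error(triad_sim_spec(n_reps = 0), "n_reps")
  expect_error(triad_sim_spec(dispersion = -1), "dispersion")
  expect_error(triad_sim_spec(effect_log2 = -0.1), "effect_log2")
  expect_error(triad_sim_spec(class_proportions = c(bad = 1)), "label")
})

test_that("phenotype simulation follows the logistic curve", {
  par1 <- list(K = 80, r = 0.5, t0 = 6)
  s <- simulate_phenotype_series(params = list(M = par1, H = par1, P = par1),
                                 noise_sd = 0, n_reps = 2, seed = 9L)
  curve <- 80 / (1 + exp(-0.5 * (0:15 - 6)))
  for (g in c("M", "H", "P")) {
    v <- s$value[s$genotype == g & s$replicate == 1]
    expect_equal(v, curve)
  }
  # identical parents: the MPV curve equals either parent's curve
  mu <- stats::aggregate(value ~ genotype + dap, s, mean)
  m <- mu$value[mu$genotype == "M"]
  p <- mu$value[mu$genotype == "P"]
  expect_equal(mid_parent_value(m, p), m)
})

test_that("a hybrid raised above the mid-parent is detected at late DAP", {
  # power check: H asymptote 10% above the MPV asymptote, n = 20 replicates
  params <- list(M = list(K = 90, r = 0.55, t0 = 6),
                 P = list(K = 70, r = 0.55, t0 = 6),
                 H = list(K = 88, r = 0.55, t0 = 6))   # MPV K = 80, +10%
  s <- simulate_phenotype_series(params = params, noise_sd = 3, n_reps = 20,
                                 seed = 7L)
  at <- function(g, d) s$value[s$genotype == g & s$dap == d]
  expect_lt(mpv_significance(at("H", 15), at("M", 15), at("P", 15)), 0.01)
})
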