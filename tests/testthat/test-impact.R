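# Independent KL oracle: enumerate both full ensembles, restrict to the
# common structure space, renormalize, sum q_wt log(q_wt/q_mut).
kl_oracle <- function(wt, mut, model) {
  bw <- bruteforce_ensemble(wt, model)
  bm <- bruteforce_ensemble(mut, model)
  keys_w <- vapply(bw$structures, pair_set, "")
  keys_m <- vapply(bm$structures, pair_set, "")
  common <- intersect(keys_w, keys_m)
  wi <- match(common, keys_w)
  mi <- match(common, keys_m)
  zw <- sum(bw$weights[wi])
  zm <- sum(bm$weights[mi])
  qw <- bw$weights[wi] / zw
  qm <- bm$weights[mi] / zm
  list(d = sum(qw * log(qw / qm)),
       coverage_wt = zw / bw$Z, coverage_mut = zm / bm$Z)
}

test_that("relative entropy matches enumeration on worked examples", {
  wt <- seq_gaaac()
  # GC -> GU substitution keeps the pair but reweights it
  mut <- apply_mutations(wt, "C5U")
  m <- mod_pairtype()
  re <- ensemble_relative_entropy(wt, mut, m)
  orc <- kl_oracle(wt, mut, m)
  expect_equal(re$d_common, orc$d, tolerance = 1e-9)
  expect_equal(re$d_common, 0.1698226, tolerance = 1e-6)
  expect_equal(re$d_bits, re$d_common / log(2))
  expect_equal(re$coverage_wt, 1, tolerance = 1e-12)
  expect_equal(re$coverage_mut, 1, tolerance = 1e-12)
  expect_false(re$infinite_flag)

  # G -> A substitution destroys the pair: common space is the open chain
  mut2 <- validate_sequence("AAAAC", "m2")
  mu <- mod_uniform()
  re2 <- ensemble_relative_entropy(wt, mut2, mu)
  orc2 <- kl_oracle(wt, mut2, mu)
  expect_equal(re2$d_common, 0, tolerance = 1e-12)
  expect_equal(re2$coverage_wt, 1 / (1 + exp(1)), tolerance = 1e-9)
  expect_equal(re2$coverage_mut, orc2$coverage_mut, tolerance = 1e-9)
  expect_true(re2$infinite_flag)

  # identical sequences: zero divergence, full coverage
  re3 <- ensemble_relative_entropy(wt, wt, m)
  expect_equal(re3$d_common, 0, tolerance = 1e-12)
  expect_false(re3$infinite_flag)
})

test_that("relative entropy DP equals enumeration on random mutants", {
  set.seed(99)
  for (k in 1:12) {
    wt <- make_fixture_sequences(300 + k, 1, sample(10:14, 1))[[1]]
    chars <- strsplit(wt$residues, "")[[1]]
    pos <- sample(wt$n, 1)
    alt <- sample(setdiff(c("A", "C", "G", "U"), chars[pos]), 1)
    mut <- apply_mutations(wt, sprintf("%s%d%s", chars[pos], pos, alt))
    for (m in all_models()) {
      re <- ensemble_relative_entropy(wt, mut, m)
      orc <- kl_oracle(wt, mut, m)
      expect_lt(abs(re$d_common - orc$d), 1e-9)
      expect_lt(abs(re$coverage_wt - orc$coverage_wt), 1e-9)
      expect_lt(abs(re$coverage_mut - orc$coverage_mut), 1e-9)
      expect_gte(re$d_common, 0)
    }
  }
})

test_that("region scan finds the largest local change", {
  m <- mod_uniform()
  wt <- seq_gaaac()
  mut <- validate_sequence("AAAAC", "m")
  bw <- pair_probabilities_global(wt, m)
  bm <- pair_probabilities_global(mut, m)
  sc <- region_distance_scan(bw, bm, window_lengths = 5, step = 1)
  expect_equal(sc$d_max, P15_UNIFORM, tolerance = 1e-9)
  expect_equal(sc$best_d_interval, c(1, 5))
  # WT vector has variance, mutant vector is all-zero: r falls back to 0
  expect_equal(sc$r_min, 0)

  # identical matrices: zero distance, r = 1, first interval by tie-break
  sc0 <- region_distance_scan(bw, bw, window_lengths = 5, step = 1)
  expect_equal(sc0$d_max, 0)
  expect_equal(sc0$r_min, 1)
  expect_equal(sc0$best_d_interval, c(1, 5))
  expect_equal(sc0$best_r_interval, c(1, 5))

  expect_error(region_distance_scan(bw, bm, window_lengths = 3),
               "below 4")
})

test_that("whole-sequence scan reproduces the global distance", {
  m <- mod_uniform()
  wt <- make_fixture_sequences(21, 1, 18)[[1]]
  chars <- strsplit(wt$residues, "")[[1]]
  alt <- setdiff(c("A", "C", "G", "U"), chars[9])[1]
  mut <- apply_mutations(wt, sprintf("%s9%s", chars[9], alt))
  bw <- pair_probabilities_global(wt, m)
  bm <- pair_probabilities_global(mut, m)
  sc <- region_distance_scan(bw, bm, window_lengths = wt$n, step = 1)
  delta <- bm$P - bw$P
  expect_equal(sc$d_max, sqrt(sum(delta[upper.tri(delta)]^2)),
               tolerance = 1e-12)
  # d_max is monotone non-decreasing as window lengths grow to n
  d_small <- region_distance_scan(bw, bm, window_lengths = 8,
                                  step = 1)$d_max
  d_both <- region_distance_scan(bw, bm, window_lengths = c(8, wt$n),
                                 step = 1)$d_max
  expect_lte(d_small, d_both + 1e-12)
  expect_equal(d_both, sc$d_max, tolerance = 1e-12)
})

test_that("empirical p-values follow the +1 convention", {
  m <- mod_uniform()
  wt <- seq_gaaac()
  bg <- snvfold:::mutation_background(wt, m, folding_params(),
                                      window_lengths = 5, step = 1)
  expect_equal(nrow(bg), 3 * wt$n)  # 15
  # observed above every background score
  p_hi <- empirical_pvalue(max(bg$d) + 1, wt, m, window_lengths = 5,
                           step = 1, mode = "d", background = bg)
  expect_equal(p_hi$p, 1 / (3 * wt$n + 1))
  expect_equal(p_hi$background_size, 15L)
  # for mode r, everything <= max is a hit when observed is the max
  p_r <- empirical_pvalue(max(bg$r), wt, m, window_lengths = 5,
                          step = 1, mode = "r", background = bg)
  expect_equal(p_r$p, 1)
  p_d_min <- empirical_pvalue(min(bg$d), wt, m, window_lengths = 5,
                              step = 1, mode = "d", background = bg)
  expect_equal(p_d_min$p, 1)
})

test_that("leave-one-out calibration is near-uniform on a seeded 20-mer", {
  m <- mod_uniform()
  wt <- make_fixture_sequences(8, 1, 20)[[1]]
  cal <- pvalue_calibration(wt, m, window_lengths = 10, step = 2)
  expect_equal(nrow(cal), 60L)
  expect_true(all(cal$p > 0 & cal$p <= 1))
  frac <- mean(cal$p <= 0.5)
  expect_lt(abs(frac - 0.5), 0.15)
})

test_that("impact reports integrate both scores and serialize losslessly", {
  wt <- seq_gaaac()
  rep <- build_impact_report(wt, "C5U", mod_pairtype(),
                             window_lengths = 5, step = 1)
  expect_equal(rep$relent$d_common, 0.1698226, tolerance = 1e-6)
  expect_equal(rep$scan$background_size, 15L)
  # identity mutation: all-null report
  rep0 <- build_impact_report(wt, "A3A", mod_pairtype(),
                              window_lengths = 5, step = 1)
  expect_equal(rep0$relent$d_common, 0, tolerance = 1e-12)
  expect_equal(rep0$scan$d_max, 0)
  expect_equal(rep0$scan$p_d, 1)
  # JSON round-trip
  f <- withr::local_tempfile(fileext = ".json")
  impact_report_json(rep, f)
  back <- read_impact_report(f)
  expect_equal(back$relent$d_common, rep$relent$d_common, tolerance = 1e-12)
  expect_equal(back$scan$d_max, rep$scan$d_max, tolerance = 1e-12)
  expect_equal(back$mutation, "C5U")
})
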