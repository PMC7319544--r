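test_that("enumeration lists exactly the legal structures", {
  a4 <- enumerate_structures(validate_sequence("AAAA", "a"))
  expect_length(a4, 1L)
  expect_equal(nrow(a4[[1]]), 0L)

  g <- enumerate_structures(seq_gaaac())
  expect_setequal(vapply(g, pair_set, ""), c("open", "1-5"))

  gg <- enumerate_structures(seq_ggaaacc())
  expect_setequal(vapply(gg, pair_set, ""),
                  c("open", "1-7", "2-6", "1-6", "2-7", "1-7;2-6"))
  # crossing pair set {(1,6),(2,7)} must be absent
  expect_false("1-6;2-7" %in% vapply(gg, pair_set, ""))

  long <- validate_sequence(strrep("GC", 13), "too-long")
  expect_error(enumerate_structures(long), "guard")
})

test_that("brute-force ensemble matches closed forms", {
  m <- mod_uniform()
  a <- bruteforce_ensemble(validate_sequence("AAAA", "a"), m)
  expect_equal(a$Z, 1)
  expect_true(all(a$P == 0))

  g <- bruteforce_ensemble(seq_gaaac(), m)
  expect_equal(g$Z, 1 + exp(1), tolerance = 1e-12)
  expect_equal(g$P[1, 5], P15_UNIFORM, tolerance = 1e-12)

  gg <- bruteforce_ensemble(seq_ggaaacc(), m)
  expect_equal(gg$Z, Z_GG, tolerance = 1e-12)
  expect_equal(gg$P[1, 7], P17_UNIFORM, tolerance = 1e-12)
  expect_equal(gg$P[1, 6], exp(1) / Z_GG, tolerance = 1e-12)
})

test_that("McCaskill equals the enumeration oracle on random sequences", {
  # trimmed-down version of the acceptance sweep: 30 sequences, all models
  set.seed(42)
  lens <- sample(8:15, 30, replace = TRUE)
  for (k in seq_along(lens)) {
    s <- make_fixture_sequences(1000 + k, 1, lens[k])[[1]]
    for (m in all_models()) {
      bf <- bruteforce_ensemble(s, m)
      dp <- pair_probabilities_global(s, m)
      expect_lt(max(abs(dp$P - bf$P)), 1e-9)
    }
  }
})

test_that("closed-form pair probabilities are reproduced", {
  g <- seq_gaaac()
  expect_equal(pair_probabilities_global(g, mod_uniform())$P[1, 5],
               P15_UNIFORM, tolerance = 1e-9)
  expect_equal(pair_probabilities_global(g, mod_pairtype())$P[1, 5],
               P15_PAIRTYPE, tolerance = 1e-9)
  expect_equal(pair_probabilities_global(seq_ggaaacc(), mod_uniform())$P[1, 7],
               P17_UNIFORM, tolerance = 1e-9)
  polyA <- validate_sequence(strrep("A", 12), "pa")
  expect_true(all(pair_probabilities_global(polyA, mod_uniform())$P == 0))
})

test_that("pair matrices satisfy symmetry, range and normalization", {
  for (m in all_models()) {
    for (sd in 1:3) {
      s <- make_fixture_sequences(sd, 1, 14)[[1]]
      bp <- pair_probabilities_global(s, m)
      expect_identical(bp$P, t(bp$P))
      expect_true(all(diag(bp$P) == 0))
      expect_true(all(bp$P >= 0 & bp$P <= 1))
      expect_true(all(rowSums(bp$P) <= 1 + 1e-9))
      ap <- accessibility_profile(s, m)
      expect_lt(max(abs(rowSums(bp$P) + ap$pu - 1)), 1e-9)
    }
  }
})

test_that("unpaired region probabilities match constrained closed forms", {
  m <- mod_uniform()
  a <- validate_sequence("AAAA", "a")
  expect_equal(unpaired_region_probability(a, m, 2, 1), 1.0)
  expect_equal(unpaired_region_probability(seq_gaaac(), m, 1, 1),
               1 / (1 + exp(1)), tolerance = 1e-12)
  expect_equal(unpaired_region_probability(seq_ggaaacc(), m, 1, 1),
               PU1_GG, tolerance = 1e-12)
  expect_error(unpaired_region_probability(a, m, 4, 2), "out of range")
})

test_that("accessibility profiles are consistent and monotone in u", {
  m <- mod_uniform()
  g <- seq_gaaac()
  ap <- accessibility_profile(g, m, folding_params(u_lengths = c(1, 2, 3)))
  P <- pair_probabilities_global(g, m)$P
  expect_equal(ap$pu, 1 - rowSums(P), tolerance = 1e-9)
  expect_identical(ap$pu_u[["1"]], ap$pu)
  # monotone: pu_u(u=2)(i) <= min(pu(i), pu(i+1)); non-increasing in u
  pu2 <- ap$pu_u[["2"]]
  for (i in seq_along(pu2)) {
    expect_lte(pu2[i], min(ap$pu[i], ap$pu[i + 1]) + 1e-12)
  }
  pu3 <- ap$pu_u[["3"]]
  for (i in seq_along(pu3)) {
    expect_lte(pu3[i], pu2[i] + 1e-12)
  }
  # u = n on an all-A sequence
  a <- validate_sequence("AAAA", "a")
  apA <- accessibility_profile(a, m, folding_params(u_lengths = 4))
  expect_equal(apA$pu_u[["4"]], 1.0)
  expect_error(
    accessibility_profile(g, m, folding_params(window = 4, u_lengths = 5)),
    "exceeds"
  )
})

test_that("local folding reduces to global at W = L = n", {
  for (m in list(mod_uniform(), mod_stacking())) {
    s <- make_fixture_sequences(7, 1, 14)[[1]]
    glob <- pair_probabilities_global(s, m)
    loc <- pair_probabilities_local(
      s, m, folding_params(window = s$n, max_span = s$n))
    expect_lt(max(abs(glob$P - loc$P)), 1e-12)
  }
})

test_that("span cap zeroes long-range pairs without breaking closer ones", {
  s <- make_fixture_sequences(9, 1, 16)[[1]]
  m <- mod_uniform()
  L <- 8L
  bp <- pair_probabilities_local(
    s, m, folding_params(window = s$n, max_span = L))
  idx <- which(bp$P > 0, arr.ind = TRUE)
  expect_true(all(abs(idx[, 2] - idx[, 1]) + 1 <= L))
  # the capped matrix equals a global fold whose structure space has the cap
  capped <- pair_probabilities_global(s, m, max_span = L)
  expect_lt(max(abs(bp$P - capped$P)), 1e-12)
})

test_that("windowed averaging divides by the number of covering windows", {
  s <- validate_sequence("GAAACGAAAC", "two-hairpins")
  m <- mod_uniform()
  bp <- pair_probabilities_local(
    s, m, folding_params(window = 5, max_span = 5))
  # (1,5) is covered only by window [1..5], where it folds like GAAAC
  expect_equal(bp$P[1, 5], P15_UNIFORM, tolerance = 1e-9)
  expect_equal(bp$P[6, 10], P15_UNIFORM, tolerance = 1e-9)
  # windowed local values agree with the direct mean of window folds
  s2 <- make_fixture_sequences(3, 1, 12)[[1]]
  W <- 8L
  loc <- pair_probabilities_local(
    s2, m, folding_params(window = W, max_span = W))
  chars <- strsplit(s2$residues, "")[[1]]
  n <- s2$n
  manual <- matrix(0, n, n); cnt <- matrix(0, n, n)
  for (a in 1:(n - W + 1)) {
    idx <- a:(a + W - 1)
    sub <- validate_sequence(paste(chars[idx], collapse = ""), "w")
    Pw <- pair_probabilities_global(sub, m)$P
    manual[idx, idx] <- manual[idx, idx] + Pw
    cnt[idx, idx] <- cnt[idx, idx] + 1
  }
  manual[cnt > 0] <- manual[cnt > 0] / cnt[cnt > 0]
  expect_lt(max(abs(loc$P - manual)), 1e-12)
})
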