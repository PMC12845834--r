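test_that("soft_sign is a logistic step approximation", {
  expect_equal(soft_sign(0, 1), 0.5)
  expect_equal(soft_sign(0, 500), 0.5)
  x <- seq(-3, 3, by = 0.37)
  expect_equal(soft_sign(x, 2) + soft_sign(-x, 2), rep(1, length(x)))
  expect_true(all(diff(soft_sign(x, 5)) > 0))
  # sharp kappa: 0.1 above threshold saturates to ~1
  expect_gt(soft_sign(0.1, 100), 1 - 1e-4)
  # extreme inputs saturate without overflow
  expect_equal(soft_sign(1e6, 100), 1)
  expect_equal(soft_sign(-1e6, 100), 0)
})

test_that("threshold_map implements soft-sign gated shrinkage", {
  cfg <- decoding_config(s = 0.5, kappa = 50)
  C <- matrix(c(0, 0.5, 0.9, 0.1), 2, 2)
  Ct <- threshold_map(C, cfg)
  expect_equal(Ct[1, 1], 0)                      # zero stays exactly zero
  expect_equal(Ct[2, 1], 0.25)                   # at s: 0.5 * s
  expect_equal(Ct[1, 2], soft_sign(0.4, 50) * 0.9)
  expect_lt(abs(Ct[1, 2] - 0.9), 1e-8)           # well above s: unchanged
  expect_lt(Ct[2, 2], 1e-9)                      # well below s: ~0
  expect_true(all(Ct <= C + 1e-15))
})

test_that("raising the sparsity threshold never adds pairs", {
  # holds on prediction-like maps whenever s sits above the noise floor;
  # with s below the noise level the multiplier dynamics can suppress true
  # pairs and invert the relationship (see the methods vignette)
  set.seed(31)
  run_grid <- function(Cr, sq, s_grid) {
    n_prev <- Inf
    for (s in s_grid) {
      cfg <- decoding_config(s = s)
      mask <- valid_pair_mask(sq, cfg)
      n <- n_pairs(decode_contact_map(Cr, mask, cfg)$structure)
      expect_lte(n, n_prev)
      n_prev <- n
    }
  }
  for (trial in 1:10) {
    rec <- sample_hairpin(family_spec("hairpin"))
    M <- structure_to_contact_map(rec$structure)
    L <- rec$seq$L
    planted <- matrix(runif(L * L, 0.85, 0.98), L, L)
    # low noise: full threshold grid
    lo <- matrix(runif(L * L, 0, 0.05), L, L)
    Cr <- ifelse(M == 1, planted, (lo + t(lo)) / 2)
    run_grid((Cr + t(Cr)) / 2, rec$seq, seq(0.1, 0.9, by = 0.1))
    # moderate noise: thresholds above the noise ceiling
    hi <- matrix(runif(L * L, 0, 0.4), L, L)
    Cr2 <- ifelse(M == 1, planted, (hi + t(hi)) / 2)
    run_grid((Cr2 + t(Cr2)) / 2, rec$seq, seq(0.5, 0.9, by = 0.1))
  }
})

test_that("valid_pair_mask encodes separation and canonical rules", {
  sq5 <- rna_sequence("x", "GAAAC")
  m <- valid_pair_mask(sq5, decoding_config(min_sep = 4))
  expect_equal(sum(m), 2)                  # only (0,4) and its mirror
  expect_equal(m[1, 5], 1)

  gg <- rna_sequence("g", "GGGGGGGGG")
  mg <- valid_pair_mask(gg, decoding_config(canonical_only = TRUE))
  expect_true(all(mg == 0))                # G-G is never canonical

  sq <- rna_sequence("x", "GCGCAAAGCGC")
  mc <- valid_pair_mask(sq, decoding_config(canonical_only = TRUE))
  # hand-enumerated canonical cells at separation >= 4 (0-based)
  ch <- strsplit(sq$residues, "")[[1]]
  expected <- matrix(0, 11, 11)
  for (i in 1:10) for (j in (i + 1):11)
    if (j - i >= 4 && paste0(ch[i], ch[j]) %in%
        c("AU", "UA", "GC", "CG", "GU", "UG"))
      expected[i, j] <- expected[j, i] <- 1
  expect_equal(mc, expected)

  # N can pair only when canonical_only is off
  sn <- rna_sequence("n", "GNAAAAAANC")
  expect_gt(sum(valid_pair_mask(sn, decoding_config())[2, ]), 0)
  expect_equal(sum(valid_pair_mask(
    sn, decoding_config(canonical_only = TRUE))[2, ]), 0)

  expect_identical(mc, t(mc))
  expect_true(all(diag(mc) == 0))
})

test_that("lagrangian_decode fixed points and confinement", {
  cfg <- decoding_config()
  Z <- matrix(0, 6, 6)
  mask <- matrix(1, 6, 6); diag(mask) <- 0
  A <- lagrangian_decode(Z, mask, cfg)
  expect_true(all(A == 0))
  expect_equal(attr(A, "violation"), rep(0, cfg$iters))

  # single allowed strong entry converges inside (0, 1], others exactly 0
  mask1 <- matrix(0, 6, 6); mask1[2, 6] <- mask1[6, 2] <- 1
  Ct <- matrix(0, 6, 6); Ct[2, 6] <- Ct[6, 2] <- 0.9
  A1 <- lagrangian_decode(Ct, mask1, cfg)
  expect_gt(A1[2, 6], 0.9)
  expect_lte(A1[2, 6], 1)
  expect_equal(sum(A1 != 0), 2)

  asym <- matrix(0, 6, 6); asym[2, 6] <- 1
  expect_error(lagrangian_decode(Ct, asym, decoding_config()), "symmetric")
})

test_that("mean constraint violation is non-increasing late in the run", {
  set.seed(17)
  cfg <- decoding_config(iters = 200)
  worse <- 0
  for (trial in 1:25) {
    L <- sample(10:30, 1)
    Ct <- matrix(runif(L * L, 0, 1), L, L); Ct <- (Ct + t(Ct)) / 2
    mask <- random_mask(L, min_sep = 4)
    A <- lagrangian_decode(Ct, mask, cfg)
    v <- attr(A, "violation")
    tail_v <- v[(3 * cfg$iters / 4):cfg$iters]
    if (tail_v[length(tail_v)] > tail_v[1] + 1e-9) worse <- worse + 1
  }
  expect_equal(worse, 0)
})

test_that("two conflicting candidates resolve to the stronger pair", {
  # nucleotide 2 (0-based) has candidate partners 6 (score 0.9) and 7 (0.6)
  L <- 10
  Cr <- matrix(0.02, L, L)
  Cr[3, 7] <- Cr[7, 3] <- 0.9
  Cr[3, 8] <- Cr[8, 3] <- 0.6
  mask <- matrix(1, L, L) * (abs(row(diag(L)) - col(diag(L))) >= 4)
  dec <- decode_contact_map(Cr, mask, decoding_config())
  expect_equal(unname(dec$structure$pairs), rbind(c(2L, 6L)))
  # matches the exhaustive oracle
  Mo <- brute_force_decode(dec$A, mask, 0.5)
  expect_identical(dec$M, Mo)
})

test_that("binarize guarantees hold on random instances", {
  set.seed(41)
  cfg <- decoding_config()
  for (rep in 1:200) {
    L <- sample(6:40, 1)
    A <- matrix(runif(L * L), L, L); A <- (A + t(A)) / 2
    mask <- random_mask(L, min_sep = sample(1:4, 1))
    M <- binarize(A, mask, cfg)
    expect_identical(M, t(M))
    expect_true(all(rowSums(M) <= 1))
    expect_true(all(M[mask == 0] == 0))
    expect_true(all(diag(M) == 0))
  }
})

test_that("greedy resolves conflicts by score with deterministic ties", {
  cfg <- decoding_config()
  A <- matrix(0, 8, 8)
  A[1, 5] <- A[5, 1] <- 0.9
  A[5, 8] <- A[8, 5] <- 0.8     # shares index 5, must lose
  mask <- matrix(1, 8, 8); diag(mask) <- 0
  M <- binarize(A, mask, cfg)
  expect_equal(M[1, 5], 1L)
  expect_equal(M[5, 8], 0L)
  # exact tie: smaller i, then smaller j wins
  A2 <- matrix(0, 8, 8)
  A2[2, 6] <- A2[6, 2] <- 0.7
  A2[2, 7] <- A2[7, 2] <- 0.7
  M2 <- binarize(A2, mask, cfg)
  expect_equal(M2[2, 6], 1L)
  expect_equal(M2[2, 7], 0L)
})

test_that("brute-force oracle handles trivial cases and dominates greedy", {
  mask <- matrix(1, 8, 8); diag(mask) <- 0
  A <- matrix(0, 8, 8)
  A[1, 6] <- A[6, 1] <- 0.8
  expect_equal(brute_force_decode(A, mask, 0.5)[1, 6], 1L)
  A[2, 7] <- A[7, 2] <- 0.7    # disjoint: both selected
  expect_equal(sum(brute_force_decode(A, mask, 0.5)), 4)
  expect_error(brute_force_decode(matrix(0, 13, 13),
                                  matrix(1, 13, 13), 0.5), "L <= 12")

  set.seed(53)
  cfg <- decoding_config(min_sep = 1)
  for (rep in 1:200) {
    A <- matrix(runif(64), 8, 8); A <- (A + t(A)) / 2
    mask <- random_mask(8, min_sep = 1)
    Mg <- binarize(A, mask, cfg)
    Mo <- brute_force_decode(A, mask, cfg$bin_threshold)
    expect_gte(sum(A * Mo), sum(A * Mg) - 1e-9)
    # equality whenever the greedy choice sequence was conflict-free
    cand <- sum(upper.tri(A) & A > cfg$bin_threshold & mask == 1)
    if (cand == sum(Mg) / 2) expect_identical(Mg, Mo)
  }
})

test_that("decoding_config validates its fields", {
  expect_error(decoding_config(s = 1.2))
  expect_error(decoding_config(kappa = 0))
  expect_error(decoding_config(iters = 0))
  expect_error(decoding_config(bin_threshold = 1))
})
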