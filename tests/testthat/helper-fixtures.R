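# shared fixture builders: everything is generated in code at test time

# a random (possibly pseudoknotted) structure: a random partial matching
# over L positions with pair separation >= min_sep
random_structure <- function(L, min_sep = 4L, density = 0.3) {
  free <- seq_len(L) - 1L
  pairs <- matrix(integer(0), ncol = 2L)
  n_target <- rbinom(1L, floor(L / 2), density)
  for (k in seq_len(n_target)) {
    if (length(free) < 2L) break
    i <- sample(free, 1L)
    partners <- free[abs(free - i) >= min_sep]
    if (!length(partners)) next
    j <- if (length(partners) == 1L) partners else sample(partners, 1L)
    pairs <- rbind(pairs, c(min(i, j), max(i, j)))
    free <- setdiff(free, c(i, j))
  }
  secondary_structure(L, pairs)
}

random_rna <- function(L, id = "rnd") {
  rna_sequence(id, paste(sample(c("A", "C", "G", "U"), L, replace = TRUE),
                         collapse = ""))
}

# symmetric 0/1 mask with zero diagonal and a minimum separation
random_mask <- function(L, min_sep = 1L, keep = 0.7) {
  m <- matrix(rbinom(L * L, 1L, keep), L, L)
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  m <- m * (abs(row(m) - col(m)) >= min_sep)
  m
}

expect_same_pairs <- function(a, b) {
  expect_identical(unname(a$pairs), unname(b$pairs))
}
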