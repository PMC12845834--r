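test_that("FASTA parsing validates, normalises T->U and uppercases", {
  seqs <- parse_fasta(">s1\nGGGAAACCC")
  expect_length(seqs, 1L)
  expect_equal(seqs[[1]]$L, 9L)
  expect_equal(seqs[[1]]$id, "s1")

  expect_equal(parse_fasta(">s1\ngggtttccc")[[1]]$residues, "GGGUUUCCC")

  expect_error(parse_fasta(">s1\nGGGXAACCC"), "position 4")
  expect_error(parse_fasta("GGGAAACCC"), "header")

  multi <- parse_fasta(">a\nGGG\nAAA\n>b\nuuu")
  expect_equal(vapply(multi, `[[`, character(1), "residues"),
               c("GGGAAA", "UUU"))
})

test_that("FASTA round-trips through write_fasta", {
  set.seed(42)
  seqs <- lapply(1:10, function(i) random_rna(sample(20:60, 1),
                                              paste0("seq", i)))
  back <- parse_fasta(write_fasta(seqs))
  expect_equal(back, seqs)
})

test_that("rna_sequence rejects empty and illegal input", {
  expect_error(rna_sequence("x", ""), "empty")
  expect_error(rna_sequence("x", "AC-GU"), "illegal character '-' at position 3")
  expect_equal(rna_sequence("x", "acgtn")$residues, "ACGUN")
})

test_that("CT parsing: 1-based pair column, reciprocity, unpaired rows", {
  ct <- paste(c("9 hp",
                "1 G 0 2 9 1", "2 G 1 3 8 2", "3 G 2 4 7 3",
                "4 A 3 5 0 4", "5 A 4 6 0 5", "6 A 5 7 0 6",
                "7 C 6 8 3 7", "8 C 7 9 2 8", "9 C 8 0 1 9"),
              collapse = "\n")
  parsed <- parse_ct(ct)
  expect_equal(unname(parsed$structure$pairs),
               rbind(c(0L, 8L), c(1L, 7L), c(2L, 6L)))
  expect_equal(parsed$seq$residues, "GGGAAACCC")

  bad <- sub("8 C 7 9 2 8", "8 C 7 9 0 8", ct, fixed = TRUE)
  expect_error(parse_ct(bad), "non-reciprocal")

  none <- paste(c("3 t", "1 A 0 2 0 1", "2 C 1 3 0 2", "3 G 2 0 0 3"),
                collapse = "\n")
  expect_equal(n_pairs(parse_ct(none)$structure), 0L)

  expect_error(parse_ct(paste(c("4 t", "1 A 0 2 0 1"), collapse = "\n")),
               "length mismatch")
  selfp <- paste(c("5 t", "1 A 0 2 0 1", "2 C 1 3 0 2", "3 G 2 4 3 3",
                   "4 U 3 5 0 4", "5 A 4 0 0 5"), collapse = "\n")
  expect_error(parse_ct(selfp), "itself")
})

test_that("CT and BPSEQ round-trip on random synthetic structures", {
  set.seed(7)
  for (rep in 1:100) {
    L <- sample(10:80, 1)
    ss <- random_structure(L)
    sq <- random_rna(L, sprintf("s%03d", rep))
    ct_back <- parse_ct(write_ct(sq, ss))
    expect_same_pairs(ct_back$structure, ss)
    expect_equal(ct_back$seq$residues, sq$residues)
    bp_back <- parse_bpseq(write_bpseq(sq, ss))
    expect_same_pairs(bp_back$structure, ss)
    expect_equal(bp_back$seq$residues, sq$residues)
  }
})

test_that("pseudoknotted structures survive CT (no nesting restriction)", {
  ss <- secondary_structure(12, rbind(c(0, 6), c(1, 7), c(3, 10), c(4, 11)))
  expect_true(is_pseudoknotted(ss))
  sq <- rna_sequence("pk", "GGAGGAUCCUCC")
  expect_same_pairs(parse_ct(write_ct(sq, ss))$structure, ss)
  expect_same_pairs(parse_bpseq(write_bpseq(sq, ss))$structure, ss)
})

test_that("BPSEQ parser enforces format", {
  expect_equal(unname(parse_bpseq(
    "1 G 9\n2 G 8\n3 G 7\n4 A 0\n5 A 0\n6 A 0\n7 C 3\n8 C 2\n9 C 1"
  )$structure$pairs), rbind(c(0L, 8L), c(1L, 7L), c(2L, 6L)))
  expect_error(parse_bpseq("1 A 0\n2 C 0\n3 G 0\n4 U 0\n5 A 5"), "itself")
  expect_error(parse_bpseq("1 A 0\n3 C 0"), "1..L")
})

test_that("dot-bracket: per-layer stacks, crossing pairs, canonical writer", {
  expect_equal(unname(parse_dotbracket("(((...)))")$pairs),
               rbind(c(0L, 8L), c(1L, 7L), c(2L, 6L)))
  expect_equal(unname(parse_dotbracket("([)]")$pairs),
               rbind(c(0L, 2L), c(1L, 3L)))
  # greedy lowest-noncrossing-layer assignment, pairs in ascending i:
  # (0,2) goes to layer 1; (1,3) crosses it, goes to layer 2
  expect_equal(write_dotbracket(
    secondary_structure(4, rbind(c(0, 2), c(1, 3)))), "([)]")
  expect_error(parse_dotbracket("(()"), "unbalanced")
  expect_error(parse_dotbracket("())."), "unbalanced.*position 3")
})

test_that("dot-bracket round-trips preserve the pair set", {
  set.seed(13)
  n_done <- 0L
  for (rep in 1:80) {
    L <- sample(10:60, 1)
    ss <- random_structure(L)
    # random matchings can exceed the 4-layer capacity; those are covered
    # by the rejection test below
    db <- tryCatch(write_dotbracket(ss), error = function(e) NULL)
    if (is.null(db)) next
    expect_same_pairs(parse_dotbracket(db), ss)
    n_done <- n_done + 1L
  }
  expect_gte(n_done, 60L)
  # synthetic families (nested and 2-layer H-type) always round-trip
  recs <- make_dataset(30, c(hairpin = 1, cloverleaf = 1, pseudoknot = 1),
                       seed = 14)
  for (rec in recs)
    expect_same_pairs(parse_dotbracket(write_dotbracket(rec$structure)),
                      rec$structure)
})

test_that("structures needing more than 4 layers are rejected", {
  # 5 mutually crossing pairs: (i, i+5) for i = 0..4
  ss <- secondary_structure(10, cbind(0:4, 5:9))
  expect_error(write_dotbracket(ss), "more than 4")
})

test_that("contact-map conversion is a faithful involution", {
  M <- structure_to_contact_map(secondary_structure(9, rbind(c(0, 8))))
  expect_equal(sum(M), 2)
  expect_equal(M[1, 9], 1L)
  expect_equal(sum(structure_to_contact_map(secondary_structure(5))), 0)

  set.seed(99)
  for (rep in 1:100) {
    ss <- random_structure(sample(8:50, 1))
    M <- structure_to_contact_map(ss)
    expect_identical(M, t(M))
    expect_true(all(diag(M) == 0))
    expect_equal(sum(M), 2 * n_pairs(ss))
    expect_true(all(rowSums(M) <= 1))
    expect_same_pairs(contact_map_to_structure(M), ss)
  }
})

test_that("secondary_structure enforces its invariants", {
  expect_error(secondary_structure(5, rbind(c(2, 2))), "self-pairing")
  expect_error(secondary_structure(5, rbind(c(0, 5))), "out of range")
  expect_error(secondary_structure(8, rbind(c(0, 5), c(5, 7))),
               "exclusivity")
  # order of indices within a pair does not matter
  a <- secondary_structure(9, rbind(c(8, 0), c(1, 7)))
  b <- secondary_structure(9, rbind(c(0, 8), c(1, 7)))
  expect_identical(a$pairs, b$pairs)
})
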