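# Synthetic sequence/structure families: complementary stems (Watson-Crick
# plus wobble), loops, multiloops and H-type pseudoknots. Every generated
# pair respects the decoder's default minimum-loop mask (j - i >= 4), so
# generated truths are always decodable.

#' Specification of a synthetic RNA family
#'
#' @param family one of `"hairpin"`, `"cloverleaf"`, `"pseudoknot"`.
#' @param stem_len integer interval `c(min, max)` for stem lengths (pairs per
#'   stem).
#' @param loop_len integer interval for loop/linker lengths; the minimum must
#'   be at least 3 so the minimum-loop constraint `j - i >= 4` holds.
#' @param gu_fraction probability that a stem position is a G-U/U-G wobble
#'   rather than a Watson-Crick pair.
#' @param mutation_rate per-residue probability of substitution applied to
#'   the sequence after construction; the labelled structure is always the
#'   pre-mutation truth, so mutation emulates an imperfect pairing signal.
#' @return a `family_spec` list.
#' @export
family_spec <- function(family = c("hairpin", "cloverleaf", "pseudoknot"),
                        stem_len = c(3L, 8L), loop_len = c(3L, 8L),
                        gu_fraction = 0.1, mutation_rate = 0) {
  family <- match.arg(family)
  stem_len <- as.integer(stem_len); loop_len <- as.integer(loop_len)
  stopifnot(length(stem_len) == 2L, length(loop_len) == 2L)
  if (stem_len[1L] > stem_len[2L] || stem_len[1L] < 1L)
    stop("empty or invalid stem length range", call. = FALSE)
  if (loop_len[1L] > loop_len[2L])
    stop("empty loop length range", call. = FALSE)
  if (loop_len[1L] < 3L)
    stop("minimum loop length must be >= 3 (decoder mask j - i >= 4)",
         call. = FALSE)
  stopifnot(gu_fraction >= 0, gu_fraction <= 1,
            mutation_rate >= 0, mutation_rate <= 1)
  structure(list(family = family, stem_len = stem_len, loop_len = loop_len,
                 gu_fraction = gu_fraction, mutation_rate = mutation_rate),
            class = "family_spec")
}

.bases <- c("A", "C", "G", "U")

.draw_int <- function(range) {
  range[1L] + sample.int(range[2L] - range[1L] + 1L, 1L) - 1L
}

# one stem of k complementary base pairs: column 1 is the 5' partner,
# column 2 the 3' partner of each pair
.draw_stem <- function(k, gu_fraction) {
  wc <- c("AU", "UA", "GC", "CG")
  gu <- c("GU", "UG")
  pick <- ifelse(runif(k) < gu_fraction, sample(gu, k, replace = TRUE),
                 sample(wc, k, replace = TRUE))
  cbind(substr(pick, 1L, 1L), substr(pick, 2L, 2L))
}

.draw_loop <- function(m) sample(.bases, m, replace = TRUE)

# per-residue substitution: a mutated residue always changes identity
.apply_mutation <- function(chars, rate) {
  if (rate <= 0) return(chars)
  hit <- which(runif(length(chars)) < rate)
  for (p in hit) chars[p] <- sample(setdiff(.bases, chars[p]), 1L)
  chars
}

.finish_sample <- function(id, chars, pairs, spec) {
  chars <- .apply_mutation(chars, spec$mutation_rate)
  list(seq = rna_sequence(id, paste(chars, collapse = "")),
       structure = secondary_structure(length(chars), pairs),
       family = spec$family)
}

#' Sample a hairpin (single stem-loop)
#'
#' A stem of `k` complementary pairs enclosing a loop of `m` unpaired
#' residues, `k` and `m` drawn uniformly from the spec ranges; `L = 2k + m`
#' and the pairs are `(t, L - 1 - t)` for `t = 0..k-1`. Uses the current R
#' random stream (call `set.seed()` for reproducibility).
#'
#' @param spec a [family_spec()].
#' @param id identifier for the generated sequence.
#' @return `list(seq, structure, family)`; `structure` is the pre-mutation
#'   truth.
#' @export
sample_hairpin <- function(spec, id = "hairpin") {
  k <- .draw_int(spec$stem_len)
  m <- .draw_int(spec$loop_len)
  L <- 2L * k + m
  stem <- .draw_stem(k, spec$gu_fraction)
  chars <- character(L)
  t <- seq_len(k)
  chars[t] <- stem[, 1L]
  chars[L + 1L - t] <- stem[, 2L]
  chars[(k + 1L):(k + m)] <- .draw_loop(m)
  pairs <- cbind(t - 1L, L - t)
  .finish_sample(id, chars, pairs, spec)
}

#' Sample a cloverleaf (tRNA-like multiloop)
#'
#' One closing stem plus three inner stem-loops joined by single-stranded
#' linkers of length >= 1; all stems complementary, structure fully nested.
#'
#' @inheritParams sample_hairpin
#' @return `list(seq, structure, family)`.
#' @export
sample_cloverleaf <- function(spec, id = "cloverleaf") {
  k0 <- .draw_int(spec$stem_len)
  karm <- replicate(3L, .draw_int(spec$stem_len))
  marm <- replicate(3L, .draw_int(spec$loop_len))
  link <- replicate(4L, .draw_int(c(1L, 3L)))
  L <- 2L * k0 + sum(2L * karm + marm) + sum(link)
  chars <- character(L)
  pairs <- matrix(integer(0), ncol = 2L)

  close_stem <- .draw_stem(k0, spec$gu_fraction)
  t <- seq_len(k0)
  chars[t] <- close_stem[, 1L]
  chars[L + 1L - t] <- close_stem[, 2L]
  pairs <- rbind(pairs, cbind(t - 1L, L - t))

  pos <- k0  # 0-based offset of the next free position
  for (a in 1:3) {
    chars[pos + seq_len(link[a])] <- .draw_loop(link[a])
    pos <- pos + link[a]
    k <- karm[a]; m <- marm[a]
    stem <- .draw_stem(k, spec$gu_fraction)
    t <- seq_len(k)
    chars[pos + t] <- stem[, 1L]
    chars[pos + 2L * k + m + 1L - t] <- stem[, 2L]
    chars[pos + k + seq_len(m)] <- .draw_loop(m)
    pairs <- rbind(pairs, cbind(pos + t - 1L, pos + 2L * k + m - t))
    pos <- pos + 2L * k + m
  }
  chars[pos + seq_len(link[4L])] <- .draw_loop(link[4L])
  .finish_sample(id, chars, pairs, spec)
}

#' Sample an H-type pseudoknot
#'
#' Two stems over four regions A < B < C < D along the sequence: stem 1
#' pairs A with C, stem 2 pairs B with D, so every stem-1 pair crosses every
#' stem-2 pair (`k1 * k2` crossings).
#'
#' @inheritParams sample_hairpin
#' @return `list(seq, structure, family)`.
#' @export
sample_pseudoknot <- function(spec, id = "pseudoknot") {
  k1 <- .draw_int(spec$stem_len)
  k2 <- .draw_int(spec$stem_len)
  l1 <- .draw_int(spec$loop_len)
  l2 <- .draw_int(spec$loop_len)
  l3 <- .draw_int(spec$loop_len)
  L <- 2L * (k1 + k2) + l1 + l2 + l3
  startB <- k1 + l1
  startC <- startB + k2 + l2
  startD <- startC + k1 + l3
  chars <- character(L)
  stem1 <- .draw_stem(k1, spec$gu_fraction)
  stem2 <- .draw_stem(k2, spec$gu_fraction)
  t1 <- seq_len(k1); t2 <- seq_len(k2)
  chars[t1] <- stem1[, 1L]
  chars[startC + k1 + 1L - t1] <- stem1[, 2L]
  chars[startB + t2] <- stem2[, 1L]
  chars[startD + k2 + 1L - t2] <- stem2[, 2L]
  chars[k1 + seq_len(l1)] <- .draw_loop(l1)
  chars[startB + k2 + seq_len(l2)] <- .draw_loop(l2)
  chars[startC + k1 + seq_len(l3)] <- .draw_loop(l3)
  pairs <- rbind(cbind(t1 - 1L, startC + k1 - t1),
                 cbind(startB + t2 - 1L, startD + k2 - t2))
  .finish_sample(id, chars, pairs, spec)
}

.samplers <- list(hairpin = sample_hairpin, cloverleaf = sample_cloverleaf,
                  pseudoknot = sample_pseudoknot)

#' Generate a synthetic dataset of sequence/structure pairs
#'
#' Families are drawn with the given weights; generation is deterministic
#' under a fixed seed. Optionally writes numbered FASTA + BPSEQ files and a
#' manifest TSV (id, family, L, n_pairs) to `out_dir`.
#'
#' @param n number of records.
#' @param mix named numeric vector of family weights, names among
#'   `"hairpin"`, `"cloverleaf"`, `"pseudoknot"`.
#' @param specs named list of [family_spec()] objects; families missing from
#'   the list get `family_spec(<family>)` defaults.
#' @param seed optional integer seed.
#' @param out_dir optional directory to receive FASTA/BPSEQ fixtures.
#' @return list of records, each `list(seq, structure, family)`.
#' @export
make_dataset <- function(n, mix = c(hairpin = 1), specs = NULL, seed = NULL,
                         out_dir = NULL) {
  stopifnot(n >= 1, length(mix) >= 1, !is.null(names(mix)), sum(mix) > 0)
  if (!all(names(mix) %in% names(.samplers)))
    stop("unknown family in mix: ",
         paste(setdiff(names(mix), names(.samplers)), collapse = ", "),
         call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  fams <- if (length(mix) == 1L) rep(names(mix), n) else
    sample(names(mix), n, replace = TRUE, prob = mix)
  records <- vector("list", n)
  for (r in seq_len(n)) {
    fam <- fams[r]
    spec <- if (!is.null(specs) && !is.null(specs[[fam]])) specs[[fam]] else
      family_spec(fam)
    records[[r]] <- .samplers[[fam]](spec, id = sprintf("%s_%04d", fam, r))
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    manifest <- data.frame(id = character(n), family = fams, L = integer(n),
                           n_pairs = integer(n))
    for (r in seq_len(n)) {
      rec <- records[[r]]
      write_fasta(rec$seq, file.path(out_dir, paste0(rec$seq$id, ".fasta")))
      write_bpseq(rec$seq, rec$structure,
                  file.path(out_dir, paste0(rec$seq$id, ".bpseq")))
      manifest$id[r] <- rec$seq$id
      manifest$L[r] <- rec$seq$L
      manifest$n_pairs[r] <- n_pairs(rec$structure)
    }
    write.table(manifest, file.path(out_dir, "manifest.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  records
}
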