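# Constraint-enforcing decoder: sparsity-aware soft-sign thresholding, an
# iterative Lagrangian relaxation that pushes the map toward the scores
# while penalising rows whose pair mass exceeds one, and a greedy matcher
# that makes the hard guarantees (symmetry, exclusivity, mask compliance)
# unconditional. A brute-force maximum-weight matching oracle is included
# for verification at small L.

#' Decoding configuration
#'
#' @param s sparsity threshold in `[0, 1]` applied to the refined map.
#' @param kappa soft-sign sharpness (> 0).
#' @param eta descent step for the relaxed contact matrix (> 0).
#' @param eta_lambda ascent step for the Lagrange multipliers (> 0).
#' @param iters iteration budget (>= 1).
#' @param min_sep minimum `|j - i|` for a legal pair; the default 4 encodes
#'   a minimum loop of 3 unpaired residues.
#' @param canonical_only restrict pairs to A-U/U-A, G-C/C-G, G-U/U-G. Off by
#'   default so non-canonical interactions (and pairs involving N) survive
#'   when the scores support them.
#' @param bin_threshold final binarisation cut in (0, 1).
#' @return a `decoding_config` list.
#' @export
decoding_config <- function(s = 0.5, kappa = 10, eta = 0.01,
                            eta_lambda = 0.01, iters = 100L, min_sep = 4L,
                            canonical_only = FALSE, bin_threshold = 0.5) {
  stopifnot(s >= 0, s <= 1, kappa > 0, eta > 0, eta_lambda > 0, iters >= 1,
            min_sep >= 1, bin_threshold > 0, bin_threshold < 1)
  structure(list(s = s, kappa = kappa, eta = eta, eta_lambda = eta_lambda,
                 iters = as.integer(iters), min_sep = as.integer(min_sep),
                 canonical_only = isTRUE(canonical_only),
                 bin_threshold = bin_threshold),
            class = "decoding_config")
}

#' Smooth sign approximation
#'
#' `soft_sign(x, kappa) = 1 / (1 + exp(-kappa * x))`: monotone increasing
#' with limits 0 and 1 and value 0.5 at the origin; saturates without
#' overflow.
#'
#' @param x numeric.
#' @param kappa sharpness (> 0); larger values approach a hard step.
#' @return values in (0, 1), same shape as `x`.
#' @export
soft_sign <- function(x, kappa = 10) {
  stopifnot(kappa > 0)
  1 / (1 + exp(-kappa * x))
}

#' Sparsity-aware thresholding of a refined map
#'
#' Elementwise `soft_sign(C - s) * C`: entries well below the threshold `s`
#' shrink toward zero, entries well above pass nearly unchanged, and the
#' result never exceeds the input.
#'
#' @param C numeric matrix with entries in `[0, 1]` (refined map).
#' @param cfg a [decoding_config()].
#' @return matrix of the same shape, entries in `[0, C]`.
#' @export
threshold_map <- function(C, cfg = decoding_config()) {
  soft_sign(C - cfg$s, cfg$kappa) * C
}

#' Mask of structurally legal pairs
#'
#' `mask[i, j] = 1` iff `|i - j| >= min_sep` and, when `canonical_only` is
#' set, the residue pair is Watson-Crick or wobble (so positions holding N
#' can only pair when `canonical_only` is off). Symmetric with zero
#' diagonal.
#'
#' @param seq an [rna_sequence()].
#' @param cfg a [decoding_config()].
#' @return L x L 0/1 matrix.
#' @export
valid_pair_mask <- function(seq, cfg = decoding_config()) {
  L <- seq$L
  idx <- seq_len(L)
  mask <- (abs(outer(idx, idx, "-")) >= cfg$min_sep) * 1
  if (cfg$canonical_only) {
    chars <- strsplit(seq$residues, "", fixed = TRUE)[[1L]]
    canon <- outer(chars, chars, function(a, b)
      paste0(a, b) %in% c("AU", "UA", "GC", "CG", "GU", "UG"))
    mask <- mask * canon
  }
  mask
}

#' Lagrangian constraint relaxation
#'
#' Starting from the masked, symmetrised thresholded map, iterates a
#' min-max scheme: the relaxed matrix `A` moves up where the evidence is
#' strong and down in rows whose total pair mass exceeds one (scaled by a
#' per-row multiplier lambda), with `A` clipped to `[0, 1]`, re-masked and
#' re-symmetrised every step, and lambda ascending on the rectified row-sum
#' violation. The per-iteration mean violation is returned as the
#' `"violation"` attribute.
#'
#' @param Ct nonnegative L x L score matrix (thresholded map).
#' @param mask symmetric L x L 0/1 matrix of legal cells.
#' @param cfg a [decoding_config()].
#' @return L x L relaxed contact matrix in `[0, 1]`, symmetric, with
#'   attribute `violation` (length `cfg$iters`).
#' @export
lagrangian_decode <- function(Ct, mask, cfg = decoding_config()) {
  stopifnot(is.matrix(Ct), is.matrix(mask), all(dim(Ct) == dim(mask)))
  if (!isTRUE(all.equal(mask, t(mask)))) stop("mask must be symmetric")
  if (any(Ct < 0)) stop("thresholded scores must be nonnegative")
  A <- Ct * mask
  A <- (A + t(A)) / 2
  A <- pmin(pmax(A, 0), 1)
  L <- nrow(A)
  lambda <- numeric(L)
  violation <- numeric(cfg$iters)
  for (t in seq_len(cfg$iters)) {
    G <- .decode_gradient(A, lambda, Ct, cfg)
    A <- A - cfg$eta * G
    A <- pmin(pmax(A, 0), 1) * mask
    A <- (A + t(A)) / 2
    viol <- pmax(rowSums(A) - 1, 0)
    lambda <- lambda + cfg$eta_lambda * viol
    violation[t] <- mean(viol)
  }
  attr(A, "violation") <- violation
  A
}

# The descent direction for the relaxed matrix: rows over their pair budget
# are pushed down (multiplier-scaled soft-sign of the row-sum violation,
# broadcast across the row), cells with score evidence are pushed up. Kept
# in one place so an alternative gradient reading can be swapped here.
.decode_gradient <- function(A, lambda, Ct, cfg) {
  press <- lambda * soft_sign(rowSums(A) - 1, cfg$kappa)  # length-L, by row
  A * (press - 0.5 * Ct)
}

#' Greedy constrained binarisation
#'
#' Upper-triangle cells with `A > bin_threshold` and `mask == 1` are sorted
#' by score (descending; ties broken by smaller i, then smaller j) and
#' accepted greedily, skipping any cell whose endpoints are already used.
#' The result is guaranteed symmetric, exclusive (each index in at most one
#' pair) and mask-compliant, regardless of how well the relaxation
#' converged.
#'
#' @param A L x L matrix in `[0, 1]`.
#' @param mask symmetric L x L 0/1 matrix.
#' @param cfg a [decoding_config()].
#' @return L x L binary contact map (integer matrix).
#' @export
binarize <- function(A, mask, cfg = decoding_config()) {
  stopifnot(all(dim(A) == dim(mask)))
  L <- nrow(A)
  M <- matrix(0L, L, L)
  cand <- which(upper.tri(A) & A > cfg$bin_threshold & mask == 1,
                arr.ind = TRUE)
  if (nrow(cand)) {
    vals <- A[cand]
    ord <- order(-vals, cand[, 1L], cand[, 2L])
    used <- logical(L)
    for (r in ord) {
      i <- cand[r, 1L]; j <- cand[r, 2L]
      if (used[i] || used[j]) next
      used[i] <- used[j] <- TRUE
      M[i, j] <- M[j, i] <- 1L
    }
  }
  M
}

#' Exhaustive maximum-weight matching oracle
#'
#' Enumerates every matching over the allowed cells whose weight exceeds
#' `bin_threshold` and returns the one maximising total weight (ties:
#' lexicographically smallest pair list). Exponential; restricted to
#' `L <= 12` and meant for verifying the greedy binariser in tests.
#'
#' @param weights L x L symmetric weight matrix.
#' @param mask symmetric L x L 0/1 matrix.
#' @param bin_threshold candidate cut-off.
#' @return L x L binary contact map (integer matrix).
#' @export
brute_force_decode <- function(weights, mask, bin_threshold = 0.5) {
  L <- nrow(weights)
  if (L > 12L) stop("brute_force_decode is restricted to L <= 12")
  cand <- which(upper.tri(weights) & weights > bin_threshold & mask == 1,
                arr.ind = TRUE)
  # partner lists per vertex (0-based vertices 1..L here)
  adj <- lapply(seq_len(L), function(i)
    sort(cand[cand[, 1L] == i, 2L]))
  best <- list(w = -Inf, pairs = NULL)
  lex_less <- function(a, b) {
    # a, b: matrices of pairs sorted by (i, j); TRUE if a < b
    va <- as.vector(t(a)); vb <- as.vector(t(b))
    n <- min(length(va), length(vb))
    if (n > 0) {
      neq <- which(va[seq_len(n)] != vb[seq_len(n)])
      if (length(neq)) return(va[neq[1L]] < vb[neq[1L]])
    }
    length(va) < length(vb)
  }
  used <- logical(L)
  pairs <- matrix(0L, 0L, 2L)
  recurse <- function(v, w) {
    if (v > L) {
      if (w > best$w + 1e-12 ||
          (abs(w - best$w) <= 1e-12 && lex_less(pairs, best$pairs)))
        best <<- list(w = w, pairs = pairs)
      return(invisible())
    }
    if (!used[v]) {
      for (u in adj[[v]]) {
        if (used[u]) next
        used[v] <<- used[u] <<- TRUE
        pairs <<- rbind(pairs, c(v, u))
        recurse(v + 1L, w + weights[v, u])
        pairs <<- pairs[-nrow(pairs), , drop = FALSE]
        used[v] <<- used[u] <<- FALSE
      }
    }
    recurse(v + 1L, w)  # leave v unmatched (or already used)
  }
  recurse(1L, 0)
  M <- matrix(0L, L, L)
  if (!is.null(best$pairs) && nrow(best$pairs)) {
    M[best$pairs] <- 1L
    M[best$pairs[, 2:1, drop = FALSE]] <- 1L
  }
  M
}

#' Full score-map decoding pipeline
#'
#' Threshold, Lagrangian relaxation, greedy binarisation, and conversion to
#' a pair set.
#'
#' @param Crefined L x L refined score map in `[0, 1]`.
#' @param mask symmetric L x L 0/1 matrix of legal cells (for sequences use
#'   [valid_pair_mask()]).
#' @param cfg a [decoding_config()].
#' @return `list(structure = secondary_structure, A = relaxed matrix,
#'   M = binary contact map)`.
#' @export
decode_contact_map <- function(Crefined, mask, cfg = decoding_config()) {
  Ct <- threshold_map(Crefined, cfg)
  A <- lagrangian_decode(Ct, mask, cfg)
  M <- binarize(A, mask, cfg)
  list(structure = contact_map_to_structure(M), A = A, M = M)
}
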