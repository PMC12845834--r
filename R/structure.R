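#' RNA sequence object
#'
#' A validated RNA sequence: an identifier plus a residue string over the
#' alphabet A, C, G, U, N. `T` is accepted on input and silently normalised
#' to `U`; lowercase is uppercased; any other character is an error.
#'
#' @param id free-text identifier.
#' @param residues character scalar of residues.
#' @return An object of class `rna_sequence` with fields `id`, `residues`
#'   and length `L`.
#' @examples
#' s <- rna_sequence("hp1", "gggtttccc")
#' s$residues # "GGGUUUCCC"
#' @export
rna_sequence <- function(id, residues) {
  stopifnot(is.character(id), length(id) == 1L,
            is.character(residues), length(residues) == 1L)
  res <- chartr("t", "u", toupper(residues))
  res <- chartr("T", "U", res)
  chars <- strsplit(res, "", fixed = TRUE)[[1L]]
  if (length(chars) < 1L)
    stop("sequence '", id, "' is empty", call. = FALSE)
  bad <- which(!chars %in% c("A", "C", "G", "U", "N"))
  if (length(bad))
    stop("sequence '", id, "': illegal character '", chars[bad[1L]],
         "' at position ", bad[1L], call. = FALSE)
  structure(list(id = id, residues = res, L = length(chars)),
            class = "rna_sequence")
}

#' @export
print.rna_sequence <- function(x, ...) {
  cat("<rna_sequence> ", x$id, " (L=", x$L, ")\n", sep = "")
  cat(" ", if (x$L > 60) paste0(substr(x$residues, 1, 60), "...") else
    x$residues, "\n", sep = "")
  invisible(x)
}

#' Secondary structure as a set of base pairs
#'
#' A secondary structure over `L` positions: a set of unordered index pairs,
#' stored 0-based with `i < j`. Crossing pairs (pseudoknots) are permitted;
#' each position may appear in at most one pair.
#'
#' @param L sequence length (positive integer).
#' @param pairs two-column integer matrix of 0-based pairs (one row per
#'   pair), or `NULL`/zero-row matrix for an unpaired structure. Rows may be
#'   given in either order; they are normalised to `i < j` and sorted.
#' @return An object of class `secondary_structure` with fields `L` and
#'   `pairs` (canonical two-column matrix).
#' @examples
#' ss <- secondary_structure(9, rbind(c(0, 8), c(1, 7), c(2, 6)))
#' n_pairs(ss) # 3
#' @export
secondary_structure <- function(L, pairs = NULL) {
  stopifnot(length(L) == 1L, L >= 1)
  L <- as.integer(L)
  if (is.null(pairs) || NROW(pairs) == 0L) {
    pairs <- matrix(integer(0), ncol = 2L)
  } else {
    pairs <- matrix(as.integer(pairs), ncol = 2L)
    i <- pmin(pairs[, 1L], pairs[, 2L])
    j <- pmax(pairs[, 1L], pairs[, 2L])
    if (any(i == j)) stop("self-pairing is not allowed", call. = FALSE)
    if (any(i < 0L) || any(j >= L))
      stop("pair index out of range [0, L)", call. = FALSE)
    idx <- c(i, j)
    if (anyDuplicated(idx))
      stop("pairing exclusivity violated: position ",
           idx[duplicated(idx)][1L], " appears in more than one pair",
           call. = FALSE)
    ord <- order(i, j)
    pairs <- cbind(i = i[ord], j = j[ord])
  }
  colnames(pairs) <- c("i", "j")
  structure(list(L = L, pairs = pairs), class = "secondary_structure")
}

#' @export
print.secondary_structure <- function(x, ...) {
  cat("<secondary_structure> L=", x$L, ", ", nrow(x$pairs), " pairs",
      if (is_pseudoknotted(x)) " (pseudoknotted)" else "", "\n", sep = "")
  invisible(x)
}

#' Number of base pairs in a structure
#' @param ss a `secondary_structure`.
#' @return integer pair count.
#' @export
n_pairs <- function(ss) nrow(ss$pairs)

#' Does a structure contain crossing pairs?
#'
#' Two pairs (i, j) and (k, l) cross when i < k < j < l; a structure with at
#' least one crossing is pseudoknotted and cannot be drawn in a single
#' dot-bracket layer.
#'
#' @param ss a `secondary_structure`.
#' @return logical scalar.
#' @export
is_pseudoknotted <- function(ss) {
  p <- ss$pairs
  n <- nrow(p)
  if (n < 2L) return(FALSE)
  for (a in seq_len(n - 1L)) {
    k <- p[(a + 1L):n, 1L]
    l <- p[(a + 1L):n, 2L]
    if (any(p[a, 1L] < k & k < p[a, 2L] & p[a, 2L] < l)) return(TRUE)
  }
  FALSE
}

#' Convert a structure to its binary contact map
#'
#' The matrix view of a secondary structure: a symmetric L x L 0/1 matrix
#' with ones exactly at paired index pairs (both orientations) and a zero
#' diagonal. The number of ones is twice the number of pairs.
#'
#' @param ss a `secondary_structure`.
#' @return L x L integer matrix.
#' @seealso [contact_map_to_structure()] for the inverse.
#' @export
structure_to_contact_map <- function(ss) {
  M <- matrix(0L, ss$L, ss$L)
  if (nrow(ss$pairs)) {
    M[ss$pairs + 1L] <- 1L
    M[ss$pairs[, 2:1, drop = FALSE] + 1L] <- 1L
  }
  M
}

#' Recover the pair set from a binary contact map
#'
#' @param M symmetric 0/1 matrix with zero diagonal and at most one 1 per
#'   row (pairing exclusivity).
#' @return a `secondary_structure`.
#' @export
contact_map_to_structure <- function(M) {
  stopifnot(is.matrix(M), nrow(M) == ncol(M))
  if (!isTRUE(all.equal(M, t(M)))) stop("contact map must be symmetric")
  idx <- which(M != 0, arr.ind = TRUE)
  idx <- idx[idx[, 1L] < idx[, 2L], , drop = FALSE]
  secondary_structure(nrow(M), idx - 1L)
}

# shared residue complement table (Watson-Crick + wobble)
.complement_pairs <- c(AU = 1, UA = 1, GC = 1, CG = 1, GU = 1, UG = 1)

#' Is a residue pair canonical (Watson-Crick or wobble)?
#' @param a,b single residue characters.
#' @return logical.
#' @keywords internal
is_canonical_pair <- function(a, b) {
  paste0(a, b) %in% names(.complement_pairs)
}
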