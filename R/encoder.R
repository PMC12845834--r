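# Sequence encoder: learned nucleotide embeddings + fixed sinusoidal
# positional encoding, multi-head scaled dot-product self-attention, and the
# head-averaged pairwise correlation map C that feeds the refiner. The
# correlation map is deliberately NOT symmetrised here; symmetry is imposed
# downstream where the structural constraints live.

.alphabet <- c("A", "C", "G", "U", "N")

#' Fixed sinusoidal positional encoding
#'
#' `P[i, 2t+1] = sin(i / 10000^(2t/d))`, `P[i, 2t+2] = cos(i / 10000^(2t/d))`
#' for 0-based position `i` and `t = 0..d/2-1`. Depends only on `(L, d)`;
#' row `i` is the same for every sequence length.
#'
#' @param L number of positions.
#' @param d encoding width; must be even.
#' @return L x d matrix with entries in `[-1, 1]`.
#' @export
positional_encoding <- function(L, d) {
  stopifnot(L >= 1)
  if (d %% 2L != 0L) stop("positional encoding width d must be even")
  pos <- 0:(L - 1L)
  t <- 0:(d %/% 2L - 1L)
  ang <- outer(pos, 10000^(2 * t / d), "/")
  P <- matrix(0, L, d)
  P[, 2L * t + 1L] <- sin(ang)
  P[, 2L * t + 2L] <- cos(ang)
  P
}

#' Initialise encoder parameters
#'
#' Trainable pieces: a |V| x d embedding table over the alphabet
#' A, C, G, U, N (N gets its own learned row) and per-head query/key/value
#' projections of width `d_h = d / H`.
#'
#' @param d embedding width (even, divisible by `H`); default 64.
#' @param H number of attention heads; default 4.
#' @param seed optional seed for the initial draw.
#' @return an `encoder_params` list.
#' @export
init_encoder <- function(d = 64L, H = 4L, seed = NULL) {
  stopifnot(H >= 1, d %% H == 0L, d %% 2L == 0L)
  if (!is.null(seed)) set.seed(seed)
  d_h <- d %/% H
  sd_proj <- sqrt(2 / (d + d_h))
  w <- list(E = matrix(rnorm(5L * d, sd = 0.2), 5L, d,
                       dimnames = list(.alphabet, NULL)))
  for (h in seq_len(H)) {
    w[[paste0("Wq", h)]] <- matrix(rnorm(d * d_h, sd = sd_proj), d, d_h)
    w[[paste0("Wk", h)]] <- matrix(rnorm(d * d_h, sd = sd_proj), d, d_h)
    w[[paste0("Wv", h)]] <- matrix(rnorm(d * d_h, sd = sd_proj), d, d_h)
  }
  structure(list(d = as.integer(d), H = as.integer(H),
                 d_h = as.integer(d_h), pe = "sinusoidal", weights = w),
            class = "encoder_params")
}

#' Embed a sequence
#'
#' Row `i` of the result is the embedding-table row of residue `x_i` plus
#' the positional encoding of position `i`; changing one residue changes
#' exactly one row.
#'
#' @param seq an [rna_sequence()].
#' @param params an [init_encoder()] parameter set.
#' @return L x d matrix `Z`.
#' @export
embed_sequence <- function(seq, params) {
  idx <- match(strsplit(seq$residues, "", fixed = TRUE)[[1L]], .alphabet)
  Z <- params$weights$E[idx, , drop = FALSE] +
    positional_encoding(seq$L, params$d)
  dimnames(Z) <- NULL
  Z
}

.row_softmax <- function(S) {
  S <- S - apply(S, 1L, max)
  E <- exp(S)
  E / rowSums(E)
}

#' One attention head
#'
#' Scaled dot-product attention: `A = row-softmax(Q K' / sqrt(d_h))` with
#' `Q = Z Wq`, `K = Z Wk`, `V = Z Wv`; also returns the context `A V`.
#'
#' @param Z L x d embedding matrix.
#' @param Wq,Wk,Wv d x d_h projection matrices.
#' @return `list(A = L x L attention map, context = L x d_h)`.
#' @export
attention_head <- function(Z, Wq, Wk, Wv) {
  Q <- Z %*% Wq
  K <- Z %*% Wk
  A <- .row_softmax(Q %*% t(K) / sqrt(ncol(Wq)))
  list(A = A, context = A %*% (Z %*% Wv))
}

#' Head-averaged correlation map
#'
#' `C = (1/H) * sum_h A_h`: the average of the per-head attention maps,
#' interpreted as pairwise interaction propensity. Rows sum to 1 (each head
#' is row-stochastic, and averaging preserves that).
#'
#' With `ablate_attention = TRUE` the attention is bypassed and the map is
#' the embedding outer product `sigmoid(z_i . z_j / sqrt(d))` instead
#' (the "no attention" model variant); that map is not row-stochastic.
#'
#' @inheritParams embed_sequence
#' @param ablate_attention replace attention with the embedding
#'   outer-product map.
#' @return L x L matrix.
#' @export
correlation_map <- function(seq, params, ablate_attention = FALSE) {
  .encoder_forward(seq, params, ablate_attention)$C
}

# forward pass retaining everything the backward pass needs
.encoder_forward <- function(seq, params, ablate_attention = FALSE) {
  idx <- match(strsplit(seq$residues, "", fixed = TRUE)[[1L]], .alphabet)
  Z <- params$weights$E[idx, , drop = FALSE] +
    positional_encoding(seq$L, params$d)
  dimnames(Z) <- NULL
  if (ablate_attention) {
    C <- 1 / (1 + exp(-tcrossprod(Z) / sqrt(params$d)))
    return(list(C = C, cache = list(idx = idx, Z = Z, ablated = TRUE)))
  }
  H <- params$H
  heads <- vector("list", H)
  Csum <- 0
  for (h in seq_len(H)) {
    Q <- Z %*% params$weights[[paste0("Wq", h)]]
    K <- Z %*% params$weights[[paste0("Wk", h)]]
    A <- .row_softmax(Q %*% t(K) / sqrt(params$d_h))
    heads[[h]] <- list(Q = Q, K = K, A = A)
    Csum <- Csum + A
  }
  list(C = Csum / H,
       cache = list(idx = idx, Z = Z, heads = heads, ablated = FALSE))
}

# gradients of a scalar loss w.r.t. encoder weights, given dL/dC
.encoder_backward <- function(dC, cache, params) {
  Z <- cache$Z
  grads <- list()
  if (cache$ablated) {
    S <- tcrossprod(Z) / sqrt(params$d)
    Csig <- 1 / (1 + exp(-S))
    dS <- dC * Csig * (1 - Csig)
    dZ <- (dS + t(dS)) %*% Z / sqrt(params$d)
  } else {
    H <- params$H
    sdh <- sqrt(params$d_h)
    dZ <- matrix(0, nrow(Z), ncol(Z))
    for (h in seq_len(H)) {
      hd <- cache$heads[[h]]
      dA <- dC / H
      # softmax backward, row-wise
      dS <- hd$A * (dA - rowSums(dA * hd$A))
      dQ <- dS %*% hd$K / sdh
      dK <- t(dS) %*% hd$Q / sdh
      Wq <- params$weights[[paste0("Wq", h)]]
      Wk <- params$weights[[paste0("Wk", h)]]
      grads[[paste0("Wq", h)]] <- t(Z) %*% dQ
      grads[[paste0("Wk", h)]] <- t(Z) %*% dK
      grads[[paste0("Wv", h)]] <- matrix(0, params$d, params$d_h)
      dZ <- dZ + dQ %*% t(Wq) + dK %*% t(Wk)
    }
  }
  dE <- matrix(0, 5L, params$d)
  for (v in seq_len(5L)) {
    rows <- cache$idx == v
    if (any(rows)) dE[v, ] <- colSums(dZ[rows, , drop = FALSE])
  }
  dimnames(dE) <- dimnames(params$weights$E)
  grads$E <- dE
  grads
}
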