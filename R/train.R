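# End-to-end training of encoder + refiner against true contact maps, with
# hand-written backpropagation and an Adam optimizer. Supervision sits on
# the refined map (the model's structural estimate); the decoder is
# non-trained post-processing.

#' Training configuration
#'
#' @param learning_rate Adam step size.
#' @param epochs number of passes over the dataset.
#' @param batch_size gradients are accumulated over this many sequences per
#'   optimizer step (sequences of different lengths are handled, since each
#'   forward pass is per-sequence).
#' @param pos_weight weight (>= 1) on paired cells in the loss; counters
#'   the ~1/L density of positives among the L^2 cells.
#' @param seed random seed (recorded in the checkpoint).
#' @param no_attention ablation: replace the attention-derived correlation
#'   map with the embedding outer-product map.
#' @param no_refiner ablation: make the refiner inert (symmetrise + squash
#'   only).
#' @param min_sep loss and decoding minimum pair separation.
#' @param max_len maximum accepted sequence length.
#' @param d,H embedding width and head count for the encoder.
#' @param depth,base_channels refiner size.
#' @return a `train_config` list.
#' @export
train_config <- function(learning_rate = 1e-3, epochs = 20L,
                         batch_size = 8L, pos_weight = 6, seed = 1L,
                         no_attention = FALSE, no_refiner = FALSE,
                         min_sep = 4L, max_len = 400L, d = 64L, H = 4L,
                         depth = 2L, base_channels = 16L) {
  stopifnot(learning_rate > 0, epochs >= 1, batch_size >= 1,
            pos_weight >= 1, max_len >= 1)
  structure(list(learning_rate = learning_rate, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 pos_weight = pos_weight, seed = as.integer(seed),
                 no_attention = isTRUE(no_attention),
                 no_refiner = isTRUE(no_refiner),
                 min_sep = as.integer(min_sep),
                 max_len = as.integer(max_len), d = as.integer(d),
                 H = as.integer(H), depth = as.integer(depth),
                 base_channels = as.integer(base_channels)),
            class = "train_config")
}

# ---- Adam over flat named lists of numeric arrays --------------------------

.adam_init <- function(weights) {
  list(m = lapply(weights, function(w) w * 0),
       v = lapply(weights, function(w) w * 0), t = 0L)
}

.adam_step <- function(weights, grads, state, lr, beta1 = 0.9,
                       beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(weights)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    weights[[nm]] <- weights[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(weights = weights, state = state)
}

.add_grads <- function(acc, g) {
  if (is.null(acc)) return(g)
  for (nm in names(g)) acc[[nm]] <-
      if (is.null(acc[[nm]])) g[[nm]] else acc[[nm]] + g[[nm]]
  acc
}

.scale_grads <- function(g, f) lapply(g, function(x) x * f)

# ---- forward/backward through the whole model -------------------------------

# forward returning the symmetrised logits of the refined map plus caches
.model_forward <- function(seq, enc, ref, cfg) {
  ef <- .encoder_forward(seq, enc, ablate_attention = cfg$no_attention)
  rf <- .refiner_forward(ef$C, ref)
  list(prob = rf$prob, logits = rf$logits, enc_cache = ef$cache,
       ref_cache = rf$cache)
}

# backward from the weighted-BCE gradient on the symmetrised logits
.model_backward <- function(fwd, truth_map, enc, ref, cfg) {
  L <- nrow(fwd$prob)
  sel <- upper.tri(fwd$prob) & abs(row(fwd$prob) - col(fwd$prob)) >=
    cfg$min_sep
  n_cells <- sum(sel)
  w <- ifelse(truth_map == 1, cfg$pos_weight, 1)
  dlogits <- matrix(0, L, L)
  dlogits[sel] <- (w * (fwd$prob - truth_map))[sel] / n_cells
  rb <- .refiner_backward(dlogits, fwd$ref_cache, ref)
  eg <- .encoder_backward(rb$dC, fwd$enc_cache, enc)
  list(enc_grads = eg, ref_grads = rb$grads)
}

#' Train the encoder and refiner end to end
#'
#' Gradient-based minimisation of the weighted binary cross-entropy between
#' the refined map and the true contact map, jointly through the refiner
#' and the encoder, with Adam and mini-batch gradient accumulation.
#' Deterministic given `config$seed`.
#'
#' @param dataset list of records as produced by [make_dataset()] (each a
#'   list with `seq` and `structure`).
#' @param config a [train_config()].
#' @param encoder,refiner optional pre-initialised parameter sets; by
#'   default they are freshly initialised from the config (honouring the
#'   ablation flags).
#' @param verbose print per-epoch mean loss.
#' @return an `attnfold_checkpoint`: list with `encoder`, `refiner`,
#'   `config` and `history` (per-epoch mean training loss).
#' @export
train_model <- function(dataset, config = train_config(), encoder = NULL,
                        refiner = NULL, verbose = FALSE) {
  stopifnot(length(dataset) >= 1)
  lens <- vapply(dataset, function(r) r$seq$L, integer(1))
  if (any(lens > config$max_len))
    stop("dataset contains a sequence longer than max_len = ",
         config$max_len)
  set.seed(config$seed)
  if (is.null(encoder)) encoder <- init_encoder(config$d, config$H)
  if (is.null(refiner)) refiner <- init_refiner(
    config$depth, config$base_channels, identity = config$no_refiner)
  truth_maps <- lapply(dataset, function(r)
    structure_to_contact_map(r$structure))

  enc_state <- .adam_init(encoder$weights)
  ref_state <- .adam_init(refiner$weights)
  history <- numeric(config$epochs)
  n <- length(dataset)
  for (epoch in seq_len(config$epochs)) {
    ord <- sample.int(n)
    losses <- numeric(n)
    b_start <- seq(1L, n, by = config$batch_size)
    for (bs in b_start) {
      idx <- ord[bs:min(bs + config$batch_size - 1L, n)]
      enc_acc <- NULL; ref_acc <- NULL
      for (r in idx) {
        rec <- dataset[[r]]
        fwd <- .model_forward(rec$seq, encoder, refiner, config)
        loss <- contact_loss(fwd$prob, truth_maps[[r]], config$pos_weight,
                             config$min_sep)
        if (!is.finite(loss))
          stop("training diverged (non-finite loss) at epoch ", epoch,
               ", sequence ", rec$seq$id)
        losses[r] <- loss
        bk <- .model_backward(fwd, truth_maps[[r]], encoder, refiner,
                              config)
        enc_acc <- .add_grads(enc_acc, bk$enc_grads)
        ref_acc <- .add_grads(ref_acc, bk$ref_grads)
      }
      f <- 1 / length(idx)
      up <- .adam_step(encoder$weights, .scale_grads(enc_acc, f), enc_state,
                       config$learning_rate)
      encoder$weights <- up$weights; enc_state <- up$state
      if (length(refiner$weights)) {
        up <- .adam_step(refiner$weights, .scale_grads(ref_acc, f),
                         ref_state, config$learning_rate)
        refiner$weights <- up$weights; ref_state <- up$state
      }
    }
    history[epoch] <- mean(losses[ord])
    if (verbose)
      message(sprintf("epoch %3d  mean loss %.5f", epoch, history[epoch]))
  }
  structure(list(encoder = encoder, refiner = refiner, config = config,
                 history = history), class = "attnfold_checkpoint")
}

#' @export
print.attnfold_checkpoint <- function(x, ...) {
  cat("<attnfold_checkpoint> d=", x$config$d, " H=", x$config$H,
      " depth=", x$config$depth,
      if (x$config$no_attention) " [no attention]" else "",
      if (x$config$no_refiner) " [no refiner]" else "",
      "\n  epochs trained: ", length(x$history),
      ", final loss: ", signif(x$history[length(x$history)], 4), "\n",
      sep = "")
  invisible(x)
}

#' Predict the secondary structure of a sequence
#'
#' Runs the full pipeline: encoder, refiner, thresholding, Lagrangian
#' relaxation, greedy binarisation, pair-set extraction. The returned
#' structure always satisfies the hard constraints (symmetry, exclusivity,
#' minimum separation and — when configured — canonical pairing),
#' whatever the model weights.
#'
#' @param seq an [rna_sequence()].
#' @param checkpoint a trained (or freshly initialised)
#'   `attnfold_checkpoint`.
#' @param cfg a [decoding_config()].
#' @return `list(structure, A, refined, correlation)`.
#' @export
predict_structure <- function(seq, checkpoint, cfg = decoding_config()) {
  stopifnot(inherits(checkpoint, "attnfold_checkpoint"))
  if (seq$L > checkpoint$config$max_len)
    stop("sequence length ", seq$L, " exceeds the configured maximum ",
         checkpoint$config$max_len)
  C <- correlation_map(seq, checkpoint$encoder,
                       ablate_attention = checkpoint$config$no_attention)
  P <- refine(C, checkpoint$refiner)
  mask <- valid_pair_mask(seq, cfg)
  dec <- decode_contact_map(P, mask, cfg)
  list(structure = dec$structure, A = dec$A, refined = P, correlation = C)
}

# ---- checkpoint serialization: JSON header + raw doubles --------------------

.weight_shapes <- function(w)
  lapply(w, function(x) if (is.null(dim(x))) length(x) else dim(x))

#' Save a checkpoint
#'
#' Single binary container: one JSON header line (format tag, config,
#' weight shapes, loss history) followed by the concatenated weight values
#' as little-endian doubles in header order.
#'
#' @param checkpoint an `attnfold_checkpoint`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(checkpoint, path) {
  stopifnot(inherits(checkpoint, "attnfold_checkpoint"))
  cfg_json <- jsonlite::toJSON(unclass(checkpoint$config),
                               auto_unbox = TRUE, digits = NA)
  tmp <- tempfile(); writeLines(cfg_json, tmp)
  hash <- unname(tools::md5sum(tmp)); unlink(tmp)
  hdr <- list(
    format = "attnfold-checkpoint-v1",
    config = unclass(checkpoint$config),
    config_hash = hash,
    encoder = list(meta = checkpoint$encoder[c("d", "H", "d_h", "pe")],
                   shapes = .weight_shapes(checkpoint$encoder$weights)),
    refiner = list(meta = checkpoint$refiner[c("depth", "base", "in_ch",
                                               "coord_channels",
                                               "identity")],
                   shapes = .weight_shapes(checkpoint$refiner$weights)),
    history = checkpoint$history)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(paste0(jsonlite::toJSON(hdr, auto_unbox = TRUE,
                                             digits = NA), "\n")), con)
  for (w in c(checkpoint$encoder$weights, checkpoint$refiner$weights))
    writeBin(as.numeric(w), con, size = 8L, endian = "little")
  invisible(path)
}

#' Load a checkpoint saved by [save_checkpoint()]
#' @param path checkpoint file.
#' @return an `attnfold_checkpoint`.
#' @export
load_checkpoint <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  nl <- which(raw == as.raw(10L))[1L]
  if (is.na(nl)) stop("not a checkpoint file: no header line")
  hdr <- jsonlite::fromJSON(rawToChar(raw[seq_len(nl - 1L)]),
                            simplifyVector = TRUE)
  if (!identical(hdr$format, "attnfold-checkpoint-v1"))
    stop("unrecognised checkpoint format")
  vals <- readBin(raw[-seq_len(nl)], "double",
                  n = (length(raw) - nl) %/% 8L, size = 8L,
                  endian = "little")
  read_weights <- function(shapes, offset) {
    w <- list()
    for (nm in names(shapes)) {
      dm <- unlist(shapes[[nm]])
      len <- prod(dm)
      x <- vals[offset + seq_len(len)]
      w[[nm]] <- if (length(dm) > 1L) array(x, dim = dm) else x
      offset <- offset + len
    }
    list(w = w, offset = offset)
  }
  enc_r <- read_weights(hdr$encoder$shapes, 0L)
  ref_r <- read_weights(hdr$refiner$shapes, enc_r$offset)
  encoder <- structure(c(hdr$encoder$meta, list(weights = enc_r$w)),
                       class = "encoder_params")
  encoder$d <- as.integer(encoder$d); encoder$H <- as.integer(encoder$H)
  encoder$d_h <- as.integer(encoder$d_h)
  rownames(encoder$weights$E) <- .alphabet
  refiner <- structure(c(hdr$refiner$meta, list(weights = ref_r$w)),
                       class = "refiner_params")
  refiner$depth <- as.integer(refiner$depth)
  cfg <- do.call(train_config, hdr$config)
  structure(list(encoder = encoder, refiner = refiner, config = cfg,
                 history = as.numeric(hdr$history)),
            class = "attnfold_checkpoint")
}
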