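# Structural refinement: a small U-Net style encoder-decoder over the L x L
# correlation map. Shallow levels see local motifs (stems, loops); pooled
# levels see longer-range context. The map is padded to a multiple of
# 2^depth, passed through conv blocks with max-pool down / nearest-neighbour
# up and concatenation skips, cropped back, symmetrised and squashed through
# a logistic so the output is probability-like for the loss and the decoder.

#' Initialise refiner parameters
#'
#' @param depth number of down/up-sampling levels (default 2).
#' @param base_channels channel count at full resolution; doubles per level.
#' @param coord_channels append two normalised coordinate channels (i/L,
#'   j/L) to the input map, letting filters condition on pairing distance
#'   and position.
#' @param identity build an inert refiner: [refine()] becomes
#'   symmetrisation + logistic squashing only (the "no refiner" model
#'   variant).
#' @param seed optional seed for the initial draw.
#' @return a `refiner_params` list.
#' @export
init_refiner <- function(depth = 2L, base_channels = 16L,
                         coord_channels = TRUE, identity = FALSE,
                         seed = NULL) {
  stopifnot(depth >= 1L, base_channels >= 1L)
  if (!is.null(seed)) set.seed(seed)
  in_ch <- if (coord_channels) 3L else 1L
  meta <- list(depth = as.integer(depth),
               base = as.integer(base_channels), in_ch = in_ch,
               coord_channels = coord_channels, identity = identity)
  w <- list()
  if (!identity) {
    ch <- function(k) base_channels * 2L^k
    add_conv <- function(name, cin, cout) {
      w[[paste0(name, "_w")]] <<- array(
        rnorm(9L * cin * cout, sd = sqrt(2 / (9 * cin))),
        dim = c(3L, 3L, cin, cout))
      # small positive bias keeps ReLU units off the kink in regions where
      # the zero-padded input is dead
      w[[paste0(name, "_b")]] <<- rep(0.01, cout)
    }
    add_conv("enc0_1", in_ch, ch(0)); add_conv("enc0_2", ch(0), ch(0))
    for (k in seq_len(depth)) {
      add_conv(paste0("enc", k, "_1"), ch(k - 1L), ch(k))
      add_conv(paste0("enc", k, "_2"), ch(k), ch(k))
    }
    for (k in rev(seq_len(depth)) - 1L) {
      add_conv(paste0("dec", k, "_1"), ch(k + 1L) + ch(k), ch(k))
      add_conv(paste0("dec", k, "_2"), ch(k), ch(k))
    }
    add_conv("out", ch(0), 1L)
  }
  structure(c(meta, list(weights = w)), class = "refiner_params")
}

.conv_fwd <- function(x, w, b) {
  dm <- dim(w)
  cpp_conv3_fwd(x, matrix(w, nrow = 9L * dm[3L], ncol = dm[4L]), b)
}

.conv_bwd <- function(x, w, dy) {
  dm <- dim(w)
  g <- cpp_conv3_bwd(x, matrix(w, nrow = 9L * dm[3L], ncol = dm[4L]), dy)
  g$dw <- array(g$dw, dim = dm)
  g
}

# conv + ReLU with cache
.conv_relu_fwd <- function(x, w, b) {
  pre <- .conv_fwd(x, w, b)
  list(y = pmax(pre, 0), x = x, pre = pre)
}

.conv_relu_bwd <- function(dy, cache, w) {
  .conv_bwd(cache$x, w, dy * (cache$pre > 0))
}

# pad the L x L map to Lp and build the input cube (map + coord channels)
.refiner_input <- function(C, params) {
  L <- nrow(C)
  unit <- 2L^params$depth
  Lp <- max(unit, as.integer(ceiling(L / unit)) * unit)
  x <- array(0, dim = c(Lp, Lp, params$in_ch))
  x[seq_len(L), seq_len(L), 1L] <- C
  if (params$coord_channels) {
    coord <- (seq_len(Lp) - 1L) / L
    x[, , 2L] <- matrix(coord, Lp, Lp)        # row index i / L
    x[, , 3L] <- matrix(coord, Lp, Lp, byrow = TRUE)
  }
  list(x = x, L = L, Lp = Lp)
}

# full forward pass; returns symmetrised logits plus everything backward needs
.refiner_forward <- function(C, params) {
  L <- nrow(C)
  if (L == 0L) stop("refiner input has length 0")
  if (params$identity) {
    logits <- (C + t(C)) / 2
    return(list(prob = 1 / (1 + exp(-logits)), logits = logits,
                cache = list(identity = TRUE, L = L)))
  }
  inp <- .refiner_input(C, params)
  w <- params$weights
  n <- params$depth
  cache <- list(identity = FALSE, L = L, Lp = inp$Lp, conv = list(),
                pool = list())
  run_block <- function(x, name) {
    c1 <- .conv_relu_fwd(x, w[[paste0(name, "_1_w")]],
                         w[[paste0(name, "_1_b")]])
    c2 <- .conv_relu_fwd(c1$y, w[[paste0(name, "_2_w")]],
                         w[[paste0(name, "_2_b")]])
    cache$conv[[paste0(name, "_1")]] <<- c1[c("x", "pre")]
    cache$conv[[paste0(name, "_2")]] <<- c2[c("x", "pre")]
    c2$y
  }
  feats <- vector("list", n + 1L)
  feats[[1L]] <- run_block(inp$x, "enc0")
  for (k in seq_len(n)) {
    pl <- cpp_maxpool2_fwd(feats[[k]])
    cache$pool[[k]] <- pl$idx
    feats[[k + 1L]] <- run_block(pl$y, paste0("enc", k))
  }
  g <- feats[[n + 1L]]
  for (k in rev(seq_len(n)) - 1L) {
    up <- cpp_upsample2_fwd(g)
    skip <- feats[[k + 1L]]
    cat_in <- array(c(up, skip),
                    dim = c(dim(up)[1:2], dim(up)[3L] + dim(skip)[3L]))
    cache$cat_split <- c(cache$cat_split,
                         stats::setNames(dim(up)[3L], paste0("dec", k)))
    g <- run_block(cat_in, paste0("dec", k))
  }
  pre_out <- .conv_fwd(g, w$out_w, w$out_b)
  cache$conv$out <- list(x = g, pre = pre_out)
  logits_raw <- pre_out[seq_len(L), seq_len(L), 1L]
  logits <- (logits_raw + t(logits_raw)) / 2
  list(prob = 1 / (1 + exp(-logits)), logits = logits, cache = cache)
}

# backward from dL/d(symmetrised logits); returns dC and weight gradients
.refiner_backward <- function(dlogits, cache, params) {
  L <- cache$L
  dsym <- (dlogits + t(dlogits)) / 2     # adjoint of the symmetrisation
  if (cache$identity)
    return(list(dC = dsym, grads = list()))
  w <- params$weights
  n <- params$depth
  grads <- list()
  dfull <- array(0, dim = c(cache$Lp, cache$Lp, 1L))
  dfull[seq_len(L), seq_len(L), 1L] <- dsym

  bwd_conv <- function(dy, name, relu) {
    cc <- cache$conv[[name]]
    g <- if (relu) .conv_bwd(cc$x, w[[paste0(name, "_w")]],
                             dy * (cc$pre > 0))
         else .conv_bwd(cc$x, w[[paste0(name, "_w")]], dy)
    grads[[paste0(name, "_w")]] <<- g$dw
    grads[[paste0(name, "_b")]] <<- as.numeric(g$db)
    g$dx
  }
  bwd_block <- function(dy, name) {
    dy <- bwd_conv(dy, paste0(name, "_2"), relu = TRUE)
    bwd_conv(dy, paste0(name, "_1"), relu = TRUE)
  }

  dg <- bwd_conv(dfull, "out", relu = FALSE)
  dskips <- vector("list", n + 1L)
  for (k in seq_len(n) - 1L) {          # decoder levels 0 .. n-1
    dcat <- bwd_block(dg, paste0("dec", k))
    n_up <- cache$cat_split[[paste0("dec", k)]]
    dup <- dcat[, , seq_len(n_up), drop = FALSE]
    dskips[[k + 1L]] <- dcat[, , n_up + seq_len(dim(dcat)[3L] - n_up),
                             drop = FALSE]
    dg <- cpp_upsample2_bwd(dup)
  }
  # dg now reaches the bottleneck (encoder level n)
  dfeat <- bwd_block(dg, paste0("enc", n))
  for (k in rev(seq_len(n))) {          # encoder levels n-1 .. 0
    dpool <- cpp_maxpool2_bwd(cache$pool[[k]], dfeat)
    dlev <- dpool + dskips[[k]]
    dfeat <- bwd_block(dlev, paste0("enc", k - 1L))
  }
  list(dC = dfeat[seq_len(L), seq_len(L), 1L], grads = grads)
}

#' Refine a correlation map
#'
#' Runs the U-Net over the (padded) map and returns an L x L symmetric
#' matrix with entries in (0, 1). With an `identity = TRUE` parameter set
#' the network is skipped and the map is only symmetrised and squashed.
#'
#' @param C square numeric matrix (the correlation map).
#' @param params an [init_refiner()] parameter set.
#' @return L x L symmetric matrix in (0, 1).
#' @export
refine <- function(C, params) {
  stopifnot(is.matrix(C), nrow(C) == ncol(C))
  if (nrow(C) == 0L) stop("cannot refine an empty map")
  .refiner_forward(C, params)$prob
}

#' Sanity checks on a freshly initialised refiner
#'
#' Verifies that an untrained network is alive: output is finite, two
#' different inputs give different outputs, and the gradient of a scalar
#' loss with respect to the weights is nonzero.
#'
#' @param params an [init_refiner()] parameter set.
#' @param L map size used for the probe (default 8).
#' @return `TRUE` invisibly; stops with a message on failure.
#' @export
check_refiner_init <- function(params, L = 8L) {
  if (params$identity) return(invisible(TRUE))
  C1 <- matrix(runif(L * L), L, L)
  C2 <- matrix(runif(L * L), L, L)
  f1 <- .refiner_forward(C1, params)
  f2 <- .refiner_forward(C2, params)
  if (!all(is.finite(f1$prob))) stop("non-finite refiner output at init")
  if (isTRUE(all.equal(f1$prob, f2$prob)))
    stop("refiner output does not depend on its input")
  bk <- .refiner_backward(matrix(1, L, L), f1$cache, params)
  gnorm <- sum(vapply(bk$grads, function(g) sum(g^2), numeric(1)))
  if (gnorm <= 0) stop("zero gradient at init")
  invisible(TRUE)
}
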