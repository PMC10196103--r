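# 2D encoder-decoder segmentation network with deep supervision and a
# feature-swapping layer that exchanges encoder features across resolution
# levels, so that coarse semantic context reaches the fine levels where
# small tissues (pituitary, cistern) live, and fine localization reaches
# the coarse levels. Desk-scale by default (depth 3, width 8, 64x64
# slices) so training runs on a CPU in minutes.

#' Segmentation network configuration
#'
#' @param depth Number of resolution levels (>= 2).
#' @param width Channels at the finest level; doubled per level.
#' @param input_size Training slice size in pixels (square).
#' @param swap_pairs List of level index pairs `c(i, j)` (i < j) whose
#'   encoder features are exchanged; `list()` disables swapping and yields
#'   the plain backbone. `NULL` (default) exchanges every pair of levels.
#' @param supervision_weights Deep-supervision weights for decoder levels
#'   1 (finest) .. depth-1; default halves per coarser level, normalized to
#'   sum 1.
#' @param loss_weights Length-2 weights for the cross-entropy and soft-Dice
#'   terms (renormalized to sum 1).
#' @param lr,epochs,batch_size Adam learning rate and training schedule.
#' @param seed Seed for parameter initialization and batch shuffling.
#' @return List of class `unet_config`.
#' @export
unet_config <- function(depth = 3L, width = 8L, input_size = 64L,
                        swap_pairs = NULL, supervision_weights = NULL,
                        loss_weights = c(0.5, 0.5), lr = 3e-3,
                        epochs = 30L, batch_size = 8L, seed = 1L) {
  stopifnot(depth >= 2, width >= 1, input_size %% 2^(depth - 1) == 0)
  if (is.null(swap_pairs)) {
    swap_pairs <- list()
    for (i in 1:(depth - 1)) for (j in (i + 1):depth)
      swap_pairs <- c(swap_pairs, list(c(i, j)))
  }
  for (p in swap_pairs)
    if (length(p) != 2 || p[1] >= p[2] || p[1] < 1 || p[2] > depth)
      stop("swap pair must be c(i, j) with 1 <= i < j <= depth",
           call. = FALSE)
  if (is.null(supervision_weights))
    supervision_weights <- 0.5^(0:(depth - 2))
  if (length(supervision_weights) != depth - 1 ||
      any(supervision_weights < 0))
    stop("need depth-1 nonnegative supervision weights", call. = FALSE)
  supervision_weights <- supervision_weights / sum(supervision_weights)
  loss_weights <- loss_weights / sum(loss_weights)
  structure(list(depth = as.integer(depth), width = as.integer(width),
                 input_size = as.integer(input_size),
                 swap_pairs = swap_pairs,
                 supervision_weights = supervision_weights,
                 loss_weights = loss_weights, lr = lr,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed)),
            class = "unet_config")
}

unet_channels <- function(cfg) cfg$width * 2^(seq_len(cfg$depth) - 1)

#' Build the segmentation network
#'
#' Initializes all parameters (He-normal, seeded): one 3x3 convolution per
#' encoder and decoder level, bias-free 1x1 projections for each swap pair,
#' and 1x1 heads emitting 7-channel class scores at every supervised level.
#'
#' @param cfg A [unet_config()].
#' @return List of class `swap_unet` with `cfg` and `params`.
#' @export
build_network <- function(cfg) {
  stopifnot(inherits(cfg, "unet_config"))
  ch <- unet_channels(cfg)
  D <- cfg$depth
  params <- with_seed(cfg$seed, {
    p <- list()
    cin <- 1L
    for (l in seq_len(D)) {
      p[[paste0("enc", l, "_W")]] <- he_conv3(cin, ch[l])
      p[[paste0("enc", l, "_b")]] <- numeric(ch[l])
      cin <- ch[l]
    }
    for (sp in cfg$swap_pairs) {
      i <- sp[1]; j <- sp[2]
      p[[sprintf("swap_dn_%d_%d_W", i, j)]] <- he_conv1(ch[i], ch[j])
      p[[sprintf("swap_up_%d_%d_W", j, i)]] <- he_conv1(ch[j], ch[i])
    }
    for (l in seq_len(D - 1)) {
      p[[paste0("dec", l, "_W")]] <- he_conv3(ch[l + 1] + ch[l], ch[l])
      p[[paste0("dec", l, "_b")]] <- numeric(ch[l])
      p[[paste0("head", l, "_W")]] <- he_conv1(ch[l], 7L)
      p[[paste0("head", l, "_b")]] <- numeric(7L)
    }
    p
  })
  structure(list(cfg = cfg, params = params), class = "swap_unet")
}

#' Exchange encoder features across resolution levels
#'
#' For every pair `(i, j)` in the swap specification, level `i`'s features
#' are downsampled (nearest) to level `j`'s grid, projected by a bias-free
#' 1x1 convolution and added to level `j`; symmetrically, level `j`'s
#' features are upsampled (bilinear) to level `i`, projected and added.
#' All exchanges read the input pyramid, so the operation is simultaneous;
#' spatial shapes and channel counts are preserved, and an empty
#' specification is the identity.
#'
#' @param pyramid List of feature arrays `(H_l, W_l, C_l, N)`, finest
#'   first, spatial sizes halving per level.
#' @param swap_pairs List of `c(i, j)` pairs.
#' @param params Parameter list holding the `swap_dn_i_j_W` /
#'   `swap_up_j_i_W` projections (as in a built network).
#' @return The exchanged pyramid, same shapes.
#' @export
feature_swap <- function(pyramid, swap_pairs, params) {
  D <- length(pyramid)
  for (sp in swap_pairs) {
    i <- sp[1]; j <- sp[2]
    di <- dim(pyramid[[i]]); dj <- dim(pyramid[[j]])
    if (any(di[1:2] != dj[1:2] * 2^(j - i)))
      stop("pyramid spatial shapes do not halve between swapped levels",
           call. = FALSE)
  }
  out <- pyramid
  for (sp in swap_pairs) {
    i <- sp[1]; j <- sp[2]
    f <- 2^(j - i)
    Wdn <- params[[sprintf("swap_dn_%d_%d_W", i, j)]]
    Wup <- params[[sprintf("swap_up_%d_%d_W", j, i)]]
    out[[j]] <- out[[j]] + conv1_forward(down_nearest(pyramid[[i]], f), Wdn)
    out[[i]] <- out[[i]] + conv1_forward(up_linear(pyramid[[j]], f), Wup)
  }
  out
}

# full forward pass; returns per-level logits and the cache for backward
unet_forward <- function(net, x, keep_cache = TRUE) {
  cfg <- net$cfg; p <- net$params; D <- cfg$depth
  e <- vector("list", D); pre <- vector("list", D)
  pools <- vector("list", D - 1)
  inp <- vector("list", D)
  cur <- x
  for (l in seq_len(D)) {
    inp[[l]] <- cur
    pre[[l]] <- conv3_forward(cur, p[[paste0("enc", l, "_W")]],
                              p[[paste0("enc", l, "_b")]],
                              keep_cols = keep_cache)
    e[[l]] <- relu_forward(if (keep_cache) pre[[l]]$y else pre[[l]])
    if (l < D) {
      pl <- maxpool2_forward(e[[l]])
      pools[[l]] <- pl$arg
      cur <- pl$y
    }
  }
  s <- feature_swap(e, cfg$swap_pairs, p)
  u <- vector("list", D); z <- vector("list", D)
  outs <- vector("list", D - 1)
  u[[D]] <- s[[D]]
  for (l in seq(D - 1, 1)) {
    upl <- up_nearest2(u[[l + 1]])
    z[[l]] <- conv3_forward(abind4(upl, s[[l]]),
                            p[[paste0("dec", l, "_W")]],
                            p[[paste0("dec", l, "_b")]],
                            keep_cols = keep_cache)
    u[[l]] <- relu_forward(if (keep_cache) z[[l]]$y else z[[l]])
    outs[[l]] <- conv1_forward(u[[l]], p[[paste0("head", l, "_W")]],
                               p[[paste0("head", l, "_b")]])
  }
  cache <- if (keep_cache)
    list(pre = pre, e = e, pools = pools, s = s, z = z, u = u) else NULL
  list(outs = outs, cache = cache)
}

# concatenate two (H,W,C,N) arrays along channels
abind4 <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, dim = c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}

# backward pass given per-level logit gradients; returns parameter grads
unet_backward <- function(net, cache, dout) {
  cfg <- net$cfg; p <- net$params; D <- cfg$depth
  ch <- unet_channels(cfg)
  g <- list()
  ds <- vector("list", D)
  du <- vector("list", D)
  for (l in seq_len(D - 1)) {
    hb <- conv1_backward(cache$u[[l]], p[[paste0("head", l, "_W")]],
                         dout[[l]])
    g[[paste0("head", l, "_W")]] <- hb$dW
    g[[paste0("head", l, "_b")]] <- hb$db
    du[[l]] <- hb$dx
  }
  for (l in seq_len(D - 1)) {
    dz <- relu_backward(cache$z[[l]]$y, du[[l]])
    cb <- conv3_backward(cache$z[[l]], p[[paste0("dec", l, "_W")]], dz)
    g[[paste0("dec", l, "_W")]] <- cb$dW
    g[[paste0("dec", l, "_b")]] <- cb$db
    cup <- ch[l + 1]
    dup <- cb$dx[, , seq_len(cup), , drop = FALSE]
    dskip <- cb$dx[, , cup + seq_len(ch[l]), , drop = FALSE]
    ds[[l]] <- add_maybe(ds[[l]], dskip)
    contrib <- up_nearest2_backward(dup, dim(cache$u[[l + 1]]))
    if (l + 1 <= D - 1) du[[l + 1]] <- du[[l + 1]] + contrib
    else ds[[D]] <- add_maybe(ds[[D]], contrib)
  }
  # swap layer backward: identity path plus projections
  de <- ds
  for (sp in cfg$swap_pairs) {
    i <- sp[1]; j <- sp[2]
    f <- 2^(j - i)
    kdn <- sprintf("swap_dn_%d_%d_W", i, j)
    kup <- sprintf("swap_up_%d_%d_W", j, i)
    ei_dn <- down_nearest(cache$e[[i]], f)
    bdn <- conv1_backward(ei_dn, p[[kdn]], ds[[j]], bias = FALSE)
    g[[kdn]] <- bdn$dW
    de[[i]] <- de[[i]] +
      down_nearest_backward(bdn$dx, dim(cache$e[[i]]), f)
    ej_up <- up_linear(cache$e[[j]], f)
    bup <- conv1_backward(ej_up, p[[kup]], ds[[i]], bias = FALSE)
    g[[kup]] <- bup$dW
    de[[j]] <- de[[j]] +
      up_linear_backward(bup$dx, dim(cache$e[[j]])[1:2], f)
  }
  # encoder backward, coarse to fine
  dnext <- NULL
  for (l in seq(D, 1)) {
    dl <- de[[l]]
    if (!is.null(dnext)) dl <- dl + dnext
    dpre <- relu_backward(cache$pre[[l]]$y, dl)
    eb <- conv3_backward(cache$pre[[l]], p[[paste0("enc", l, "_W")]], dpre)
    g[[paste0("enc", l, "_W")]] <- eb$dW
    g[[paste0("enc", l, "_b")]] <- eb$db
    dnext <- if (l > 1)
      maxpool2_backward(cache$pools[[l - 1]], eb$dx,
                        dim(cache$e[[l - 1]])) else NULL
  }
  g
}

add_maybe <- function(a, b) if (is.null(a)) b else a + b

# one-hot a (H,W,N) integer label array into (H,W,7,N)
onehot_slices <- function(lab) {
  d <- dim(lab)
  oh <- array(0, dim = c(d[1], d[2], 7L, d[3]))
  base <- rep(seq_len(d[1] * d[2]), d[3]) +
    (rep(seq_len(d[3]), each = d[1] * d[2]) - 1) * d[1] * d[2] * 7L
  oh[base + as.vector(lab) * d[1] * d[2]] <- 1
  oh
}

#' Train the segmentation network
#'
#' Minimizes the deep-supervised combination of pixel cross-entropy and
#' soft-Dice loss with Adam. Labels for coarser supervised levels are
#' nearest-downsampled. Reproducible given the config seed.
#'
#' @param data List of training slices, each `list(image = matrix,
#'   labels = integer matrix)` of size `input_size` x `input_size`.
#' @param cfg A [unet_config()].
#' @param net Optionally a pre-built [build_network()] to continue
#'   training.
#' @param verbose Print per-epoch losses.
#' @return List with `net` (trained network) and `loss_history` (per-epoch
#'   mean loss).
#' @export
train_segmentation <- function(data, cfg = unet_config(), net = NULL,
                               verbose = FALSE) {
  stopifnot(length(data) >= 1)
  sz <- cfg$input_size
  for (sl in data)
    if (!all(dim(sl$image) == sz) || !all(dim(sl$labels) == sz))
      stop("all slices must be input_size x input_size", call. = FALSE)
  if (is.null(net)) net <- build_network(cfg)
  D <- cfg$depth
  imgs <- array(unlist(lapply(data, `[[`, "image")),
                dim = c(sz, sz, 1L, length(data)))
  labs <- array(unlist(lapply(data, `[[`, "labels")),
                dim = c(sz, sz, length(data)))
  # per-level one-hot targets
  targets <- lapply(seq_len(D - 1), function(l) {
    f <- 2^(l - 1)
    onehot_slices(labs[seq(1, sz, f), seq(1, sz, f), , drop = FALSE])
  })
  n <- length(data)
  state <- adam_init(net$params)
  history <- numeric(cfg$epochs)
  with_seed(cfg$seed + 1L, {
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample.int(n)
      bl <- split(ord, ceiling(seq_along(ord) / cfg$batch_size))
      eploss <- 0
      for (b in bl) {
        fw <- unet_forward(net, imgs[, , , b, drop = FALSE])
        dout <- vector("list", D - 1)
        loss <- 0
        for (l in seq_len(D - 1)) {
          w <- cfg$supervision_weights[l]
          sl <- seg_loss_weighted(fw$outs[[l]],
                                  targets[[l]][, , , b, drop = FALSE],
                                  cfg$loss_weights)
          loss <- loss + w * sl$loss
          dout[[l]] <- w * sl$grad
        }
        grads <- unet_backward(net, fw$cache, dout)
        upd <- adam_step(net$params, grads, state, lr = cfg$lr)
        net$params <- upd$params
        state <- upd$state
        eploss <- eploss + loss * length(b)
      }
      history[ep] <- eploss / n
      if (verbose)
        message(sprintf("epoch %d/%d loss %.4f", ep, cfg$epochs,
                        history[ep]))
    }
  })
  list(net = net, loss_history = history)
}

# seg_loss with configurable CE/Dice weighting
seg_loss_weighted <- function(z, y, w = c(0.5, 0.5)) {
  sl <- seg_loss(z, y)
  # seg_loss uses equal weights internally; recombine if asked otherwise
  if (isTRUE(all.equal(w, c(0.5, 0.5)))) return(sl)
  p <- sl$prob
  d <- dim(z)
  npix <- prod(d[c(1, 2, 4)])
  ce <- -sum(y * log(pmax(p, 1e-12))) / npix
  dice_term <- (sl$loss - 0.5 * ce) / 0.5
  gce <- (p - y) / npix
  gdice <- (sl$grad - 0.5 * gce) / 0.5
  list(loss = w[1] * ce + w[2] * dice_term,
       grad = w[1] * gce + w[2] * gdice, prob = p)
}

#' Segment an MRI volume slice by slice
#'
#' Each sagittal slice is block-averaged down to the network's input size
#' (the in-plane grid must be an integer multiple), passed through the
#' network, argmaxed over the 7 class scores and nearest-upsampled back, so
#' the returned label map matches the input's shape and spacing.
#'
#' @param net A trained [build_network()] / [train_segmentation()] network.
#' @param vol An [mri_volume()] in canonical orientation.
#' @return A [label_map()].
#' @export
predict_segmentation <- function(net, vol) {
  stopifnot(inherits(net, "swap_unet"), inherits(vol, "mri_volume"))
  d <- dim(vol$voxels)
  sz <- net$cfg$input_size
  if (d[2] %% sz != 0 || d[3] %% sz != 0)
    stop("in-plane size must be an integer multiple of the network input ",
         "size", call. = FALSE)
  f2 <- d[2] %/% sz; f3 <- d[3] %/% sz
  slices <- array(0, dim = c(sz, sz, 1L, d[1]))
  for (i in seq_len(d[1]))
    slices[, , 1L, i] <- block_mean(vol$voxels[i, , ], f2, f3)
  outs <- unet_forward(net, slices, keep_cache = FALSE)$outs[[1]]
  lab_small <- apply(outs, c(1, 2, 4), which.max) - 1L   # sz x sz x d1
  out <- array(0L, dim = d)
  for (i in seq_len(d[1]))
    out[i, , ] <- lab_small[rep(seq_len(sz), each = f2),
                            rep(seq_len(sz), each = f3), i]
  label_map(out, vol$spacing)
}

# block-average a matrix by integer factors
block_mean <- function(m, f1, f2) {
  d <- dim(m)
  if (f1 == 1 && f2 == 1) return(m)
  a <- array(m, dim = c(f1, d[1] %/% f1, f2, d[2] %/% f2))
  colMeans(aperm(a, c(1, 3, 2, 4)), dims = 2)
}

# block-mode (majority) downsample for integer label matrices
block_mode <- function(m, f1, f2) {
  d <- dim(m)
  if (f1 == 1 && f2 == 1) return(m)
  a <- array(m, dim = c(f1, d[1] %/% f1, f2, d[2] %/% f2))
  a <- aperm(a, c(1, 3, 2, 4))
  cnt <- array(0L, dim = c(7L, d[1] %/% f1, d[2] %/% f2))
  for (v in 0:6) cnt[v + 1, , ] <- colSums(a == v, dims = 2)
  apply(cnt, c(2, 3), which.max) - 1L
}

#' Turn phantoms into training slices
#'
#' Extracts the sagittal slices of each phantom that contain at least
#' `min_tumor_px` tumour pixels, block-averaging intensities and
#' majority-downsampling labels to `input_size`.
#'
#' @param samples List of [generate_phantom()] outputs (or a
#'   `phantom_cohort`).
#' @param input_size Target slice size.
#' @param min_tumor_px Minimum tumour pixels (at full resolution) for a
#'   slice to be kept.
#' @return List of `list(image, labels)` slices.
#' @export
phantom_slices <- function(samples, input_size = 64L, min_tumor_px = 1L) {
  if (inherits(samples, "phantom_cohort")) samples <- samples$samples
  out <- list()
  for (s in samples) {
    d <- dim(s$map$voxels)
    f2 <- d[2] %/% input_size; f3 <- d[3] %/% input_size
    stopifnot(f2 * input_size == d[2], f3 * input_size == d[3])
    for (i in seq_len(d[1])) {
      if (sum(s$map$voxels[i, , ] == 1L) < min_tumor_px) next
      out[[length(out) + 1L]] <- list(
        image = block_mean(s$mri$voxels[i, , ], f2, f3),
        labels = block_mode(s$map$voxels[i, , ], f2, f3))
    }
  }
  out
}
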