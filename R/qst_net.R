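# Multimodal QST classification network: a small residual image branch
# consumes the max-tumour sagittal slice stacked with its one-hot
# segmentation (1 + 7 = 8 channels) and emits 32 depth features, which are
# fused with the 34 clinical features into a 66-dimensional vector feeding
# a dense discriminator trained with 3-class cross-entropy.

#' Classifier configuration
#'
#' @param width Channels of the first image-branch convolution.
#' @param depth_features Length of the image-derived feature vector
#'   (default 32; fused dimension is `depth_features + 34`).
#' @param hidden Discriminator hidden width.
#' @param input_size Slice size consumed by the image branch.
#' @param lr,epochs,batch_size Adam settings.
#' @param seed Initialization/shuffling seed.
#' @return List of class `qstnet_config`.
#' @export
qstnet_config <- function(width = 8L, depth_features = 32L, hidden = 32L,
                          input_size = 64L, lr = 3e-3, epochs = 60L,
                          batch_size = 25L, seed = 1L) {
  stopifnot(width >= 1, depth_features >= 1, hidden >= 1,
            input_size %% 8 == 0)
  structure(list(width = as.integer(width),
                 depth_features = as.integer(depth_features),
                 hidden = as.integer(hidden),
                 input_size = as.integer(input_size),
                 n_clinical = 34L, n_classes = 3L,
                 lr = lr, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed)),
            class = "qstnet_config")
}

#' Build the multimodal classifier
#'
#' @param cfg A [qstnet_config()].
#' @return List of class `qst_net` with `cfg` and seeded `params`. The
#'   final discriminator layer starts at zero, so an untrained network
#'   outputs uniform class probabilities.
#' @export
build_classifier <- function(cfg = qstnet_config()) {
  stopifnot(inherits(cfg, "qstnet_config"))
  w <- cfg$width
  fused <- cfg$depth_features + cfg$n_clinical
  params <- with_seed(cfg$seed, list(
    c1_W = he_conv3(8L, w), c1_b = numeric(w),
    c2_W = he_conv3(w, 2L * w), c2_b = numeric(2L * w),
    r1_W = he_conv3(2L * w, 2L * w), r1_b = numeric(2L * w),
    r2_W = he_conv3(2L * w, 2L * w), r2_b = numeric(2L * w),
    proj_W = he_conv1(2L * w, cfg$depth_features),
    proj_b = numeric(cfg$depth_features),
    fc1_W = he_dense(fused, cfg$hidden), fc1_b = numeric(cfg$hidden),
    fc2_W = matrix(0, cfg$n_classes, cfg$hidden),
    fc2_b = numeric(cfg$n_classes)
  ))
  structure(list(cfg = cfg, params = params), class = "qst_net")
}

#' Prepare the three network inputs from one patient volume
#'
#' Selects the sagittal slice with the largest tumour area, block-averages
#' the intensities and majority-downsamples then one-hot encodes the
#' labels to the network's input size, and extracts the 34 clinical
#' features from the full 3D label map.
#'
#' @param mri An [mri_volume()].
#' @param map The co-registered [label_map()] (tumour present).
#' @param input_size Slice size (in-plane dims must be integer multiples).
#' @return List with `slice_index`, `image` (matrix), `onehot`
#'   (`input_size x input_size x 7`) and `features` (`clinical_features`).
#' @export
prepare_inputs <- function(mri, map, input_size = 64L) {
  stopifnot(inherits(mri, "mri_volume"), inherits(map, "label_map"))
  if (!identical(dim(mri$voxels), dim(map$voxels)))
    stop("MRI and label map shapes differ", call. = FALSE)
  idx <- select_max_tumor_slice(map)
  d <- dim(map$voxels)
  f2 <- d[2] %/% input_size; f3 <- d[3] %/% input_size
  if (f2 * input_size != d[2] || f3 * input_size != d[3])
    stop("in-plane size must be an integer multiple of input_size",
         call. = FALSE)
  lab2 <- block_mode(map$voxels[idx, , ], f2, f3)
  oh <- array(0, dim = c(input_size, input_size, 7L))
  oh[seq_len(input_size^2) + as.vector(lab2) * input_size^2] <- 1
  list(slice_index = idx,
       image = block_mean(mri$voxels[idx, , ], f2, f3),
       onehot = oh,
       features = extract_features(map))
}

# image-branch forward for a batch x of dim (sz, sz, 8, N)
image_branch_forward <- function(p, x, keep_cache = TRUE) {
  kc <- keep_cache
  yof <- function(f) if (kc) f$y else f
  a1p <- conv3_forward(x, p$c1_W, p$c1_b, kc); a1 <- relu_forward(yof(a1p))
  pl1 <- maxpool2_forward(a1)
  a2p <- conv3_forward(pl1$y, p$c2_W, p$c2_b, kc)
  a2 <- relu_forward(yof(a2p))
  pl2 <- maxpool2_forward(a2)
  r1p <- conv3_forward(pl2$y, p$r1_W, p$r1_b, kc)
  r1 <- relu_forward(yof(r1p))
  r2p <- conv3_forward(r1, p$r2_W, p$r2_b, kc)
  a3p <- pl2$y + yof(r2p); a3 <- relu_forward(a3p)
  pl3 <- maxpool2_forward(a3)
  prp <- conv1_forward(pl3$y, p$proj_W, p$proj_b); pr <- relu_forward(prp)
  feat <- gap_forward(pr)                    # depth_features x N
  cache <- if (keep_cache)
    list(a1p = a1p, a1 = a1, pl1 = pl1, a2p = a2p, a2 = a2,
         pl2 = pl2, r1p = r1p, r1 = r1, r2p = r2p, a3p = a3p, a3 = a3,
         pl3 = pl3, prp = prp, pr = pr) else NULL
  list(feat = feat, cache = cache)
}

image_branch_backward <- function(p, cache, dfeat) {
  g <- list()
  dpr <- gap_backward(dfeat, dim(cache$pr))
  dprp <- relu_backward(cache$prp, dpr)
  pb <- conv1_backward(cache$pl3$y, p$proj_W, dprp)
  g$proj_W <- pb$dW; g$proj_b <- pb$db
  da3 <- maxpool2_backward(cache$pl3$arg, pb$dx, dim(cache$a3))
  da3p <- relu_backward(cache$a3p, da3)
  rb2 <- conv3_backward(cache$r2p, p$r2_W, da3p)
  g$r2_W <- rb2$dW; g$r2_b <- rb2$db
  dr1p <- relu_backward(cache$r1p$y, rb2$dx)
  rb1 <- conv3_backward(cache$r1p, p$r1_W, dr1p)
  g$r1_W <- rb1$dW; g$r1_b <- rb1$db
  dpl2 <- da3p + rb1$dx                      # residual identity + branch
  da2 <- maxpool2_backward(cache$pl2$arg, dpl2, dim(cache$a2))
  da2p <- relu_backward(cache$a2p$y, da2)
  cb2 <- conv3_backward(cache$a2p, p$c2_W, da2p)
  g$c2_W <- cb2$dW; g$c2_b <- cb2$db
  da1 <- maxpool2_backward(cache$pl1$arg, cb2$dx, dim(cache$a1))
  da1p <- relu_backward(cache$a1p$y, da1)
  cb1 <- conv3_backward(cache$a1p, p$c1_W, da1p)
  g$c1_W <- cb1$dW; g$c1_b <- cb1$db
  g
}

#' Depth features for one prepared sample
#'
#' Runs the image branch on the 8-channel stack (intensity slice + one-hot
#' segmentation) and returns the pooled feature vector.
#'
#' @param net A [build_classifier()] network.
#' @param image `input_size` square intensity matrix.
#' @param onehot `input_size x input_size x 7` one-hot array.
#' @return Numeric vector of length `depth_features` (default 32).
#' @export
extract_depth_features <- function(net, image, onehot) {
  stopifnot(inherits(net, "qst_net"))
  sz <- net$cfg$input_size
  if (!all(dim(image) == sz) || !all(dim(onehot) == c(sz, sz, 7L)))
    stop("image/one-hot shapes do not match the network input size",
         call. = FALSE)
  x <- array(c(image, onehot), dim = c(sz, sz, 8L, 1L))
  as.vector(image_branch_forward(net$params, x, keep_cache = FALSE)$feat)
}

#' Fuse depth and clinical features and classify
#'
#' Concatenates the image-derived vector with the 34 clinical features
#' (fused length 66 at defaults) and applies the dense discriminator,
#' returning Q/S/T probabilities.
#'
#' @param net A [build_classifier()] network.
#' @param depth Numeric vector of length `depth_features`.
#' @param clinical Numeric vector of length 34 (missing values must be
#'   imputed beforehand; training imputes to fold means).
#' @return Named probability vector `c(Q=, S=, T=)` summing to 1.
#' @export
fuse_and_classify <- function(net, depth, clinical) {
  stopifnot(inherits(net, "qst_net"))
  cfg <- net$cfg
  if (length(depth) != cfg$depth_features)
    stop("depth feature vector must have length ", cfg$depth_features,
         call. = FALSE)
  if (length(clinical) != cfg$n_clinical)
    stop("clinical feature vector must have length ", cfg$n_clinical,
         call. = FALSE)
  if (anyNA(clinical))
    stop("clinical features contain NA; impute before fusing",
         call. = FALSE)
  fused <- matrix(c(depth, clinical), ncol = 1)
  p <- net$params
  h <- pmax(p$fc1_W %*% fused + p$fc1_b, 0)
  z <- p$fc2_W %*% h + p$fc2_b
  e <- exp(z - max(z))
  pr <- as.vector(e / sum(e))
  names(pr) <- qst_types()
  pr
}

# full forward/backward over a batch: images (sz,sz,8,N), clin 34 x N
qstnet_forward <- function(p, x, clin, keep_cache = TRUE) {
  ib <- image_branch_forward(p, x, keep_cache)
  fused <- rbind(ib$feat, clin)
  h_pre <- p$fc1_W %*% fused + p$fc1_b
  h <- pmax(h_pre, 0)
  z <- p$fc2_W %*% h + p$fc2_b
  list(z = z, cache = list(ib = ib$cache, feat = ib$feat, fused = fused,
                           h_pre = h_pre, h = h))
}

qstnet_backward <- function(p, cache, dz, nd) {
  g <- list()
  b2 <- dense_backward(cache$h, p$fc2_W, dz)
  g$fc2_W <- b2$dW; g$fc2_b <- b2$db
  dh <- b2$dx * (cache$h_pre > 0)
  b1 <- dense_backward(cache$fused, p$fc1_W, dh)
  g$fc1_W <- b1$dW; g$fc1_b <- b1$db
  dfeat <- b1$dx[seq_len(nd), , drop = FALSE]
  c(g, image_branch_backward(p, cache$ib, dfeat))
}

#' Train the multimodal classifier with cross-validation
#'
#' For each fold, clinical features are imputed (missing to training-fold
#' means) and z-scored on the training fold, the network is trained with
#' 3-class cross-entropy and Adam, and the held-out fold is predicted.
#' Aggregated out-of-fold predictions are scored with
#' [classification_report()].
#'
#' @param prepared List of [prepare_inputs()] outputs.
#' @param labels Character vector of true types (`"Q"/"S"/"T"`).
#' @param cfg A [qstnet_config()].
#' @param folds Fold index list from [make_cv_folds()]; default 5
#'   stratified folds seeded from `cfg$seed`.
#' @param verbose Print fold progress.
#' @return List with `report` (a `classification_report`), `predictions`
#'   (data frame: id, truth, prediction, three probabilities, fold) and
#'   `models` (per-fold trained networks).
#' @export
train_classifier <- function(prepared, labels, cfg = qstnet_config(),
                             folds = NULL, verbose = FALSE) {
  n <- length(prepared)
  stopifnot(n == length(labels))
  labels <- as.character(labels)
  if (is.null(folds))
    folds <- make_cv_folds(n, k = 5L, labels = labels, seed = cfg$seed)
  sz <- cfg$input_size
  x_all <- array(0, dim = c(sz, sz, 8L, n))
  for (i in seq_len(n))
    x_all[, , , i] <- c(prepared[[i]]$image, prepared[[i]]$onehot)
  clin_all <- vapply(prepared, function(s) as.numeric(s$features),
                     numeric(cfg$n_clinical))
  y_all <- match(labels, qst_types())
  if (anyNA(y_all)) stop("labels must be Q, S or T", call. = FALSE)

  pred <- character(n); prob <- matrix(NA_real_, n, 3)
  fold_id <- integer(n)
  models <- vector("list", length(folds))
  for (fi in seq_along(folds)) {
    test <- folds[[fi]]
    train <- setdiff(seq_len(n), test)
    if (length(unique(y_all[train])) < 3)
      stop("a class is absent from a training fold", call. = FALSE)
    cl <- clin_all
    mu <- rowMeans(cl[, train, drop = FALSE], na.rm = TRUE)
    mu[is.na(mu)] <- 0
    for (r in seq_len(nrow(cl))) cl[r, is.na(cl[r, ])] <- mu[r]
    sdv <- apply(cl[, train, drop = FALSE], 1, sd)
    sdv[!is.finite(sdv) | sdv < 1e-8] <- 1
    cl <- (cl - rowMeans(cl[, train, drop = FALSE])) / sdv

    net <- build_classifier(cfg)
    net$cfg$seed <- cfg$seed + fi
    state <- adam_init(net$params)
    with_seed(cfg$seed + 1000L + fi, {
      for (ep in seq_len(cfg$epochs)) {
        ord <- sample(train)
        for (b in split(ord, ceiling(seq_along(ord) / cfg$batch_size))) {
          fw <- qstnet_forward(net$params, x_all[, , , b, drop = FALSE],
                               cl[, b, drop = FALSE])
          ls <- class_loss(fw$z, y_all[b])
          grads <- qstnet_backward(net$params, fw$cache, ls$grad,
                                   cfg$depth_features)
          upd <- adam_step(net$params, grads, state, lr = cfg$lr)
          net$params <- upd$params; state <- upd$state
        }
      }
    })
    fw <- qstnet_forward(net$params, x_all[, , , test, drop = FALSE],
                         cl[, test, drop = FALSE], keep_cache = FALSE)
    zt <- fw$z
    pt <- apply(zt, 2, function(col) { e <- exp(col - max(col)); e / sum(e) })
    pred[test] <- qst_types()[apply(pt, 2, which.max)]
    prob[test, ] <- t(pt)
    fold_id[test] <- fi
    models[[fi]] <- net
    if (verbose)
      message(sprintf("fold %d/%d test accuracy %.3f", fi, length(folds),
                      mean(pred[test] == labels[test])))
  }
  report <- classification_report(labels, pred)
  predictions <- data.frame(id = seq_len(n), truth = labels,
                            prediction = pred, prob_Q = prob[, 1],
                            prob_S = prob[, 2], prob_T = prob[, 3],
                            fold = fold_id)
  list(report = report, predictions = predictions, models = models)
}
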