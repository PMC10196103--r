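test_that("network config validates and echoes its pyramid", {
  cfg <- unet_config(depth = 4, width = 4, input_size = 32)
  expect_equal(sellarqst:::unet_channels(cfg), c(4, 8, 16, 32))
  expect_equal(sum(cfg$supervision_weights), 1)
  expect_error(unet_config(swap_pairs = list(c(2, 1))), "i < j")
  expect_error(unet_config(depth = 3, swap_pairs = list(c(1, 4))), "depth")
  expect_error(unet_config(depth = 3, input_size = 30), "input_size")
})

test_that("initialization is seeded and heads emit 7 channels", {
  cfg <- unet_config(depth = 3, width = 4, input_size = 16, seed = 11)
  n1 <- build_network(cfg)
  n2 <- build_network(cfg)
  expect_identical(n1$params, n2$params)
  n3 <- build_network(unet_config(depth = 3, width = 4, input_size = 16,
                                  seed = 12))
  expect_false(identical(n1$params, n3$params))

  x <- array(rnorm(16 * 16), c(16, 16, 1, 1))
  outs <- sellarqst:::unet_forward(n1, x, keep_cache = FALSE)$outs
  expect_equal(dim(outs[[1]]), c(16, 16, 7, 1))
  expect_equal(dim(outs[[2]]), c(8, 8, 7, 1))
})

test_that("feature swap preserves shapes, is identity on empty spec and linear", {
  cfg <- unet_config(depth = 3, width = 4, input_size = 16, seed = 2)
  net <- build_network(cfg)
  set.seed(1)
  pyr <- list(array(rnorm(16 * 16 * 4 * 2), c(16, 16, 4, 2)),
              array(rnorm(8 * 8 * 8 * 2), c(8, 8, 8, 2)),
              array(rnorm(4 * 4 * 16 * 2), c(4, 4, 16, 2)))
  expect_identical(feature_swap(pyr, list(), net$params), pyr)

  sw <- feature_swap(pyr, cfg$swap_pairs, net$params)
  expect_equal(lapply(sw, dim), lapply(pyr, dim))

  zero <- lapply(pyr, function(p) p * 0)
  swz <- feature_swap(zero, cfg$swap_pairs, net$params)
  expect_equal(swz, zero)

  bad <- pyr; bad[[2]] <- array(0, c(7, 7, 8, 2))
  expect_error(feature_swap(bad, cfg$swap_pairs, net$params), "halve")
})

test_that("an identity swap reproduces the plain backbone bit for bit", {
  cfg_swap <- unet_config(depth = 3, width = 4, input_size = 16, seed = 4)
  cfg_plain <- unet_config(depth = 3, width = 4, input_size = 16, seed = 4,
                           swap_pairs = list())
  swap_net <- build_network(cfg_swap)
  plain_net <- build_network(cfg_plain)
  # same backbone parameters, swap projections forced to zero
  for (nm in names(plain_net$params))
    swap_net$params[[nm]] <- plain_net$params[[nm]]
  for (nm in grep("^swap", names(swap_net$params), value = TRUE))
    swap_net$params[[nm]][] <- 0
  set.seed(9)
  x <- array(rnorm(16 * 16 * 3), c(16, 16, 1, 3))
  o1 <- sellarqst:::unet_forward(swap_net, x, keep_cache = FALSE)$outs
  o2 <- sellarqst:::unet_forward(plain_net, x, keep_cache = FALSE)$outs
  expect_identical(o1, o2)
})

test_that("analytic gradients match finite differences", {
  cfg <- unet_config(depth = 2, width = 2, input_size = 8, seed = 5)
  net <- build_network(cfg)
  set.seed(3)
  x <- array(rnorm(8 * 8 * 2), c(8, 8, 1, 2))
  y <- sellarqst:::onehot_slices(array(sample(0:6, 128, TRUE), c(8, 8, 2)))
  lossfun <- function(net) {
    fw <- sellarqst:::unet_forward(net, x)
    sl <- sellarqst:::seg_loss(fw$outs[[1]], y)
    list(loss = sl$loss, fw = fw, grad = sl$grad)
  }
  L <- lossfun(net)
  grads <- sellarqst:::unet_backward(net, L$fw$cache, list(L$grad))
  eps <- 1e-5
  for (nm in c("enc1_W", "dec1_W", "swap_dn_1_2_W", "swap_up_2_1_W",
               "head1_b")) {
    i <- sample(length(net$params[[nm]]), 1)
    n2 <- net; n2$params[[nm]][i] <- n2$params[[nm]][i] + eps
    lp <- lossfun(n2)$loss
    n2$params[[nm]][i] <- n2$params[[nm]][i] - 2 * eps
    lm <- lossfun(n2)$loss
    fd <- (lp - lm) / (2 * eps)
    expect_lt(abs(fd - grads[[nm]][i]) / max(abs(fd), 1e-8), 1e-4,
              label = paste("gradient of", nm))
  }
})

test_that("training reduces the loss across seeds and is reproducible", {
  set.seed(40)
  mk_slice <- function() {
    lab <- matrix(0L, 16, 16)
    ci <- sample(4:12, 1); cj <- sample(4:12, 1)
    lab[(ci - 2):(ci + 2), (cj - 2):(cj + 2)] <- 1L
    lab[1:3, ] <- 4L
    img <- 0.1 + 0.8 * (lab == 1L) + 0.4 * (lab == 4L) +
      matrix(rnorm(256, 0, 0.05), 16, 16)
    list(image = img, labels = lab)
  }
  data <- replicate(10, mk_slice(), simplify = FALSE)
  finals <- sapply(1:3, function(sd) {
    cfg <- unet_config(depth = 2, width = 4, input_size = 16, epochs = 20,
                       batch_size = 5, seed = sd)
    h <- train_segmentation(data, cfg)$loss_history
    expect_lt(h[20], h[1])
    h[20]
  })
  # identical seed and data give identical final loss
  cfg <- unet_config(depth = 2, width = 4, input_size = 16, epochs = 5,
                     batch_size = 5, seed = 1)
  h1 <- train_segmentation(data, cfg)$loss_history
  h2 <- train_segmentation(data, cfg)$loss_history
  expect_identical(h1, h2)
})

test_that("the network can overfit a single slice to near-perfect Dice", {
  ph <- cached_phantom("S")
  sl <- phantom_slices(list(ph), 64, min_tumor_px = 500)
  slice <- sl[[ceiling(length(sl) / 2)]]
  cfg <- unet_config(epochs = 60, batch_size = 1, seed = 8, lr = 5e-3)
  fit <- train_segmentation(list(slice), cfg)
  x <- array(slice$image, c(64, 64, 1, 1))
  out <- sellarqst:::unet_forward(fit$net, x, keep_cache = FALSE)$outs[[1]]
  pred <- apply(out[, , , 1], c(1, 2), which.max) - 1L
  d <- dice(pred == 1L, slice$labels == 1L)
  expect_gt(d, 0.95)
})

test_that("prediction returns a full-size label map in schema range", {
  ph <- cached_phantom("Q")
  cfg <- unet_config(seed = 2)
  net <- build_network(cfg)                # untrained is fine for contracts
  pred <- predict_segmentation(net, ph$mri)
  expect_s3_class(pred, "label_map")
  expect_equal(dim(pred), dim(ph$map))
  expect_equal(pred$spacing, ph$mri$spacing)
  expect_true(all(pred$voxels %in% 0:6))
})
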