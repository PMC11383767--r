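# Training loop, evaluation, prediction, checkpoint selection, Grad-CAM.

make_tiny_split <- function(dir, n_per_class = 4, img = 32, seed = 21) {
  man <- tiny_dataset(dir, n_per_class, img, seed = seed)
  split_manifest(man, split_spec(ratios = c(0.5, 0.5, 0), seed = 1))
}

test_that("training is deterministic and logs one record per epoch", {
  d <- tempfile()
  man <- make_tiny_split(d)
  cfg <- tiny_config(28)
  run <- function() {
    m <- build_swin_model(cfg, "improved", seed = 5)
    train(m, man, train_config(learning_rate = 1e-4, epochs = 2,
                               batch_size = 4, seed = 9))
  }
  r1 <- run(); r2 <- run()
  expect_equal(nrow(r1$history), 2L)
  expect_identical(r1$history$train_loss[1], r2$history$train_loss[1])
  expect_identical(r1$history, r2$history)
  expect_error(train(build_swin_model(cfg), man[man$split != "val", ],
                     train_config(epochs = 1)), "val")
  unlink(d, recursive = TRUE)
})

test_that("loss decreases over the first Adam steps on a one-sample batch", {
  cfg <- tiny_config(28)
  fwd <- resswin:::resswin_forward
  for (seed in 1:10) {
    m <- build_swin_model(cfg, "improved", seed = seed)
    set.seed(seed + 100)
    img <- array(round(runif(28 * 28 * 3) * 255), c(1, 28, 28, 3))
    y <- sample(3, 1)
    opt <- resswin:::adam_init(m$params)
    losses <- numeric(5)
    for (s in 1:5) {
      fw <- fwd(m, img, training = TRUE)
      m$state <- fw$state
      sm <- resswin:::softmax_ce_fwd(fw$logits, y)
      losses[s] <- sm$loss
      bw <- resswin:::resswin_backward(m, fw, resswin:::softmax_ce_bwd(sm$cache))
      st <- resswin:::adam_step(m$params, bw$grads, opt, lr = 1e-4)
      m$params <- st$params; opt <- st$state
    }
    expect_lt(losses[5], losses[1])
  }
})

test_that("checkpoint selection replays correctly from the logged history", {
  h <- data.frame(epoch = 1:5,
                  val_acc = c(0.3, 0.6, 0.6, 0.5, 0.6),
                  val_loss = c(1.0, 0.7, 0.6, 0.8, 0.6))
  expect_equal(select_best_epoch(h), 3L)        # acc tie -> lower loss -> earlier
  d <- tempfile()
  man <- make_tiny_split(d)
  m <- build_swin_model(tiny_config(28), "baseline", seed = 2)
  r <- train(m, man, train_config(learning_rate = 1e-4, epochs = 3,
                                  batch_size = 4, seed = 3))
  expect_equal(r$best_epoch, select_best_epoch(r$history))
  unlink(d, recursive = TRUE)
})

test_that("evaluation is side-effect free and a constant model scores 1/3", {
  d <- tempfile()
  man <- make_tiny_split(d, n_per_class = 4)
  m <- build_swin_model(tiny_config(28), "baseline", seed = 4)
  # force the head to always pick class 1
  m$params[["head.W"]][] <- 0
  m$params[["head.b"]] <- c(10, 0, 0)
  before <- m$params
  ev <- suppressWarnings(evaluate(m, man, split = "val"))
  expect_identical(m$params, before)
  expect_equal(ev$report$accuracy, 1 / 3)
  expect_true(all(ev$preds == 1L))
  expect_equal(rownames(ev$report$per_class), pest_labels())
  unlink(d, recursive = TRUE)
})

test_that("prediction returns a coherent softmax distribution", {
  d <- tempfile()
  man <- tiny_dataset(d, 1, 32, seed = 31)
  m <- build_swin_model(tiny_config(28), "improved", seed = 6)
  p1 <- predict_image(m, man$path[1])
  p2 <- predict_image(m, man$path[1])
  expect_lt(abs(sum(p1$probabilities) - 1), 1e-6)
  expect_equal(names(which.max(p1$probabilities)), p1$label)
  expect_identical(p1$probabilities, p2$probabilities)
  expect_gte(p1$latency_seconds, 0)
  expect_error(predict_image(m, file.path(d, "absent.png")), "not found")
  unlink(d, recursive = TRUE)
})

test_that("Grad-CAM maps are normalized, guarded, and identical at init", {
  cfg <- tiny_config(28)
  mi <- build_swin_model(cfg, "improved", seed = 7, zero_init_residual = TRUE)
  mb <- build_swin_model(cfg, "baseline", seed = 8)
  for (nm in names(mb$params)) mb$params[[nm]] <- mi$params[[nm]]
  set.seed(32)
  img <- image_array(array(round(runif(28 * 28 * 3) * 255), c(28, 28, 3)))
  ci <- grad_cam(mi, img, target_class = 2)
  cb <- grad_cam(mb, img, target_class = 2)
  expect_true(all(ci$heatmap >= 0 & ci$heatmap <= 1))
  expect_equal(dim(ci$heatmap), c(28L, 28L))
  expect_equal(ci$heatmap, cb$heatmap)          # identity-at-init property
  # zero gradient at the tap -> all-zero map (no 0/0 normalization)
  mz <- mi
  mz$params[["head.W"]][] <- 0
  cz <- grad_cam(mz, img, target_class = 1)
  expect_true(all(cz$heatmap == 0))
  expect_error(grad_cam(mi, img, target_class = 9), "target_class")
})

test_that("the channel-weighting step matches the closed-form mean gradient", {
  # a score defined as the spatial mean of channel 1 has gradient 1/N in
  # every token of that channel: the map must be proportional to the
  # channel-1 activations (ReLU-rectified, max-normalized)
  set.seed(33)
  g <- 4; C <- 5
  act <- matrix(rnorm(g * g * C), g * g, C)
  dtap <- matrix(0, g * g, C); dtap[, 1] <- 1 / (g * g)
  w <- colMeans(dtap)
  cam <- pmax(act %*% w, 0)
  grid <- matrix(cam, g, g, byrow = TRUE)
  grid <- grid / max(grid)
  want <- matrix(pmax(act[, 1], 0), g, g, byrow = TRUE)
  want <- want / max(want)
  expect_equal(grid, want)
})

test_that("overlay rendering stays a valid image", {
  set.seed(34)
  img <- image_array(array(round(runif(16 * 16 * 3) * 255), c(16, 16, 3)))
  hm <- matrix(runif(16 * 16), 16, 16)
  ov <- cam_overlay(img, hm)
  expect_s3_class(ov, "image_array")
  expect_equal(dim(ov), dim(img))
})
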