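# Training, evaluation, prediction, checkpoint selection, Grad-CAM.

#' Training configuration
#'
#' Adam with a constant learning rate of 0.001 and cross-entropy loss is
#' the study protocol (100 epochs at full scale; tests run far fewer).
#' Checkpoints are taken every epoch; the best is the one with maximal
#' validation accuracy, ties broken by lower validation loss, then by the
#' earlier epoch.
#'
#' @param learning_rate Adam learning rate (> 0).
#' @param epochs number of training epochs (>= 1).
#' @param batch_size minibatch size.
#' @param seed RNG seed controlling shuffling (weights are seeded at
#'   [build_swin_model()] time); fixed seed on fixed hardware makes the
#'   run deterministic.
#' @param stop_at_train_acc optional early-stop threshold: training halts
#'   once the epoch training accuracy reaches this value.
#' @return a `train_config` list.
#' @export
train_config <- function(learning_rate = 1e-3, epochs = 100L,
                         batch_size = 32L, seed = 1L,
                         stop_at_train_acc = NULL) {
  stopifnot(learning_rate > 0, epochs >= 1, batch_size >= 1)
  structure(list(learning_rate = learning_rate, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), seed = as.integer(seed),
                 stop_at_train_acc = stop_at_train_acc),
            class = "train_config")
}

# Load every image of one split as a (n, S, S, 3) array, resizing with
# bicubic interpolation when the stored size differs from the model input.
load_split_images <- function(manifest, split, img_size) {
  rows <- manifest[manifest$split == split, , drop = FALSE]
  if (nrow(rows) == 0L) stop("no images in split '", split, "'")
  missing <- !file.exists(rows$path)
  if (any(missing))
    stop("missing image files: ", paste(rows$path[missing], collapse = ", "))
  n <- nrow(rows)
  X <- array(0, c(n, img_size, img_size, 3L))
  for (i in seq_len(n)) {
    im <- read_image(rows$path[i])
    if (dim(im)[1] != img_size || dim(im)[2] != img_size)
      im <- resize_bicubic(im, img_size, img_size)
    X[i, , , ] <- unclass(im)
  }
  y <- match(rows$label, pest_labels())
  if (anyNA(y)) y <- match(rows$label, sort(unique(manifest$label)))
  list(X = X, y = y, rows = rows)
}

model_eval_pass <- function(model, X, y, batch_size = 16L) {
  n <- dim(X)[1]
  preds <- integer(n); loss_sum <- 0
  probs <- matrix(0, n, model$config$num_classes)
  for (b0 in seq(1L, n, by = batch_size)) {
    ix <- b0:min(b0 + batch_size - 1L, n)
    fw <- resswin_forward(model, X[ix, , , , drop = FALSE], training = FALSE)
    sm <- softmax_ce_fwd(fw$logits, y[ix])
    loss_sum <- loss_sum + sm$loss * length(ix)
    probs[ix, ] <- sm$probs
    preds[ix] <- max.col(fw$logits, ties.method = "first")
  }
  list(preds = preds, probs = probs, loss = loss_sum / n,
       acc = mean(preds == y))
}

#' Select the best checkpoint from an epoch history
#'
#' Maximal validation accuracy; ties go to the lower validation loss,
#' then to the earlier epoch.
#'
#' @param history data.frame with columns `epoch`, `val_acc`, `val_loss`.
#' @return the winning epoch number.
#' @export
select_best_epoch <- function(history) {
  ord <- order(-history$val_acc, history$val_loss, history$epoch)
  history$epoch[ord[1]]
}

#' Train a model
#'
#' Minibatch Adam on cross-entropy over the `train` split, with per-epoch
#' evaluation on the `val` split. Checkpoints are taken every epoch and
#' the best is selected by the rule of [select_best_epoch()]. Fully
#' deterministic under a fixed seed.
#'
#' @param model a `resswin_model`.
#' @param manifest dataset manifest with nonempty `train` and `val`
#'   splits.
#' @param cfg a [train_config()].
#' @param log_path optional JSON-lines file receiving one record per
#'   epoch.
#' @param verbose print per-epoch progress.
#' @return list with `model` (weights of the best checkpoint), `history`
#'   (per-epoch data.frame), `best_epoch`, and `final_model` (weights
#'   after the last epoch).
#' @export
train <- function(model, manifest, cfg = train_config(), log_path = NULL,
                  verbose = FALSE) {
  validate_manifest(manifest)
  S <- model$config$img_size
  tr <- load_split_images(manifest, "train", S)
  va <- load_split_images(manifest, "val", S)
  old <- .Random.seed.save(); on.exit(.Random.seed.restore(old))
  set.seed(cfg$seed)
  opt <- adam_init(model$params)
  n <- dim(tr$X)[1]
  hist <- vector("list", cfg$epochs)
  best <- NULL
  for (ep in seq_len(cfg$epochs)) {
    perm <- sample.int(n)
    tr_loss <- 0; tr_correct <- 0L
    for (b0 in seq(1L, n, by = cfg$batch_size)) {
      ix <- perm[b0:min(b0 + cfg$batch_size - 1L, n)]
      fw <- resswin_forward(model, tr$X[ix, , , , drop = FALSE], training = TRUE)
      model$state <- fw$state
      sm <- softmax_ce_fwd(fw$logits, tr$y[ix])
      tr_loss <- tr_loss + sm$loss * length(ix)
      tr_correct <- tr_correct +
        sum(max.col(fw$logits, ties.method = "first") == tr$y[ix])
      bw <- resswin_backward(model, fw, softmax_ce_bwd(sm$cache))
      rm(fw)
      stp <- adam_step(model$params, bw$grads, opt, lr = cfg$learning_rate)
      model$params <- stp$params; opt <- stp$state
      rm(bw, stp); gc(FALSE)
    }
    ev <- model_eval_pass(model, va$X, va$y)
    rec <- data.frame(epoch = ep, train_loss = tr_loss / n,
                      train_acc = tr_correct / n,
                      val_loss = ev$loss, val_acc = ev$acc)
    hist[[ep]] <- rec
    if (verbose)
      message(sprintf("epoch %3d  train loss %.4f acc %.3f | val loss %.4f acc %.3f",
                      ep, rec$train_loss, rec$train_acc, rec$val_loss, rec$val_acc))
    if (!is.null(log_path))
      cat(jsonlite::toJSON(as.list(rec), auto_unbox = TRUE, digits = NA),
          "\n", file = log_path, append = ep > 1)
    if (is.null(best) || ev$acc > best$val_acc ||
        (ev$acc == best$val_acc && ev$loss < best$val_loss)) {
      best <- list(epoch = ep, val_acc = ev$acc, val_loss = ev$loss,
                   params = model$params, state = model$state)
    }
    if (!is.null(cfg$stop_at_train_acc) &&
        rec$train_acc >= cfg$stop_at_train_acc) break
  }
  history <- do.call(rbind, hist[!vapply(hist, is.null, logical(1))])
  best_model <- model
  best_model$params <- best$params; best_model$state <- best$state
  list(model = best_model, history = history,
       best_epoch = best$epoch, final_model = model)
}

#' Evaluate a model on one split
#'
#' Inference without augmentation; builds the confusion matrix and the
#' full metrics report. Side-effect free on the model weights.
#'
#' @param model a `resswin_model`.
#' @param manifest dataset manifest.
#' @param split split name (default `"test"`).
#' @param specificity_denominator see [per_class_metrics()].
#' @return list with `report` ([metrics_report()]), `confusion`, `preds`,
#'   `labels`.
#' @export
evaluate <- function(model, manifest, split = "test",
                     specificity_denominator = "fp") {
  S <- model$config$img_size
  te <- load_split_images(manifest, split, S)
  ev <- model_eval_pass(model, te$X, te$y)
  labs <- pest_labels()[seq_len(model$config$num_classes)]
  cm <- confusion_matrix(te$y, ev$preds, model$config$num_classes, labs)
  list(report = metrics_report(cm, specificity_denominator),
       confusion = cm, preds = ev$preds, labels = te$y)
}

#' Predict the class of one image
#'
#' @param model a `resswin_model`.
#' @param path image file path (resized to the model input if needed).
#' @return list with `label`, `probabilities` (softmax, sums to 1), and
#'   `latency_seconds` (measured, reported only).
#' @export
predict_image <- function(model, path) {
  img <- read_image(path)
  S <- model$config$img_size
  if (dim(img)[1] != S || dim(img)[2] != S) img <- resize_bicubic(img, S, S)
  t0 <- proc.time()[["elapsed"]]
  logits <- forward_classify(model, img)
  lat <- proc.time()[["elapsed"]] - t0
  pr <- drop(softmax_rows(matrix(logits, 1)))
  k <- which.max(pr)
  labs <- pest_labels()[seq_len(model$config$num_classes)]
  list(label = labs[k], probabilities = stats::setNames(pr, labs),
       latency_seconds = lat)
}

#' Grad-CAM class-evidence heatmap
#'
#' Computes the gradient of the target-class logit with respect to the
#' final stage's output token grid (the last spatial feature map, e.g.
#' 7x7x768 at 224 input), averages the gradient over space to get one
#' weight per channel, forms the weighted, ReLU-rectified sum of the
#' activations, min-max normalizes to `[0, 1]`, and bilinearly upsamples
#' to the input size. All-zero gradients return an all-zero map.
#'
#' @param model a `resswin_model`.
#' @param img an [image_array()] of the model's input size.
#' @param target_class class index in `1..num_classes` (default: the
#'   predicted class).
#' @return list with `heatmap` (`img_size` square matrix in `[0, 1]`),
#'   `grid` (the raw low-resolution map), and `target_class`.
#' @export
grad_cam <- function(model, img, target_class = NULL) {
  img <- as_image_array(img)
  fw <- resswin_forward(model, img)
  K <- model$config$num_classes
  if (is.null(target_class))
    target_class <- which.max(drop(fw$logits))
  stopifnot(target_class >= 1, target_class <= K)
  dlogits <- matrix(0, 1, K); dlogits[1, target_class] <- 1

  # head-only backward: logits -> pooled -> layer norm -> final tokens
  hc <- fw$head_cache
  hb <- linear_bwd(dlogits, hc$hd)
  group <- rep(seq_len(hc$B), each = hc$N)
  dhln <- hb$dX[group, , drop = FALSE] / hc$N
  dtap <- layernorm_bwd(dhln, hc$hln)$dX

  g <- fw$tap$g
  act <- fw$tap$act                       # (g^2) x C
  w <- colMeans(dtap)                     # gradient-averaged channel weights
  cam <- pmax(act %*% w, 0)
  grid <- matrix(cam, g, g, byrow = TRUE) # rows ordered column-fastest
  if (max(grid) > 0) grid <- grid / max(grid)
  heat <- bilinear_upsample(grid, model$config$img_size, model$config$img_size)
  list(heatmap = heat, grid = grid, target_class = target_class)
}

# Align-centers bilinear upsampling of a matrix.
bilinear_upsample <- function(m, H, W) {
  h <- nrow(m); w <- ncol(m)
  ry <- pmin(pmax((seq_len(H) - 0.5) * h / H + 0.5, 1), h)
  rx <- pmin(pmax((seq_len(W) - 0.5) * w / W + 0.5, 1), w)
  y0 <- pmin(floor(ry), h - 1L); x0 <- pmin(floor(rx), w - 1L)
  if (h == 1L) y0 <- rep(1L, H)
  if (w == 1L) x0 <- rep(1L, W)
  fy <- ry - y0; fx <- rx - x0
  y1 <- pmin(y0 + 1L, h); x1 <- pmin(x0 + 1L, w)
  m[y0, x0, drop = FALSE] * outer(1 - fy, 1 - fx) +
    m[y1, x0, drop = FALSE] * outer(fy, 1 - fx) +
    m[y0, x1, drop = FALSE] * outer(1 - fy, fx) +
    m[y1, x1, drop = FALSE] * outer(fy, fx)
}

#' Render a Grad-CAM overlay
#'
#' Blends the heatmap (red channel) over the image for visual inspection.
#'
#' @param img an [image_array()].
#' @param heatmap matrix in `[0, 1]` of the same spatial size.
#' @param alpha blend weight of the heatmap.
#' @return an [image_array()].
#' @export
cam_overlay <- function(img, heatmap, alpha = 0.5) {
  img <- as_image_array(img)
  x <- unclass(img)
  hot <- array(0, dim(x))
  hot[, , 1] <- 255 * heatmap
  hot[, , 3] <- 255 * (1 - heatmap)
  image_array(pmin(pmax(round((1 - alpha) * x + alpha * hot), 0), 255))
}
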