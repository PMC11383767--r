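# Model construction, forward pass, and hand-derived backward pass for the
# baseline shifted-window transformer and its residual-augmented variant.
#
# Layout conventions: activations are matrices (B * H * W) x C with rows
# ordered column-fastest within an image, images consecutive. Window
# partition, patch embedding, patch merging and convolution all reduce to
# precomputed integer gather/scatter index vectors (built once per batch
# size and cached on the model), so the compute is pure BLAS.

# ---- parameter construction ------------------------------------------------

make_res_module <- function(C, k, zero_init) {
  fan_in <- k * k * C
  p <- list()
  p[["conv1.W"]] <- matrix(stats::rnorm(fan_in * C, sd = sqrt(2 / fan_in)),
                           fan_in, C)
  p[["conv1.b"]] <- numeric(C)
  p[["bn1.g"]] <- rep(1, C); p[["bn1.b"]] <- numeric(C)
  p[["conv2.W"]] <- matrix(stats::rnorm(fan_in * C, sd = sqrt(2 / fan_in)),
                           fan_in, C)
  p[["conv2.b"]] <- numeric(C)
  p[["bn2.g"]] <- if (zero_init) numeric(C) else rep(1, C)
  p[["bn2.b"]] <- numeric(C)
  p
}

res_module_state <- function(C) {
  list("bn1.mean" = numeric(C), "bn1.var" = rep(1, C),
       "bn2.mean" = numeric(C), "bn2.var" = rep(1, C))
}

#' Build the classifier model
#'
#' `arch = "baseline"` is the plain hierarchical shifted-window
#' transformer. `arch = "improved"` adds the contribution: a convolutional
#' residual module on the raw image (7x7 kernels, 3 channels), and per
#' stage a parameter-free skip fusion of the stage input with the stage
#' output whose sum feeds a second residual module (3x3 kernels at the
#' stage width). Residual branches close with a zero-initialized batch
#' norm by default, so a freshly built improved model computes exactly the
#' baseline function (identity at initialization).
#'
#' @param cfg a [swin_config()].
#' @param arch `"baseline"` or `"improved"`.
#' @param mod1_kernel,mod2_kernel residual module kernel sizes (odd).
#' @param seed RNG seed for weight initialization.
#' @param zero_init_residual zero the closing batch-norm scale of every
#'   residual branch (default TRUE).
#' @return a `resswin_model` object.
#' @export
build_swin_model <- function(cfg = swin_config(), arch = c("baseline", "improved"),
                             mod1_kernel = 7L, mod2_kernel = 3L, seed = 0L,
                             zero_init_residual = TRUE) {
  arch <- match.arg(arch)
  old <- .Random.seed.save(); on.exit(.Random.seed.restore(old))
  set.seed(as.integer(seed))
  P <- list(); S <- list()
  p <- cfg$patch_size; C0 <- cfg$embed_dim
  ns <- length(cfg$depths)
  if (arch == "improved") {
    for (nm in names(mp <- make_res_module(3L, mod1_kernel, zero_init_residual)))
      P[[paste0("mod1.", nm)]] <- mp[[nm]]
    for (nm in names(ms <- res_module_state(3L)))
      S[[paste0("mod1.", nm)]] <- ms[[nm]]
  }
  P[["embed.W"]] <- matrix(trunc_normal(p * p * 3L * C0), p * p * 3L, C0)
  P[["embed.b"]] <- numeric(C0)
  P[["embed.ln.g"]] <- rep(1, C0); P[["embed.ln.b"]] <- numeric(C0)
  for (s in seq_len(ns)) {
    C <- cfg$dims[s]; h <- cfg$heads[s]; M <- cfg$windows[s]
    r <- cfg$mlp_ratio
    for (i in seq_len(cfg$depths[s])) {
      pf <- sprintf("s%d.b%d.", s, i)
      P[[paste0(pf, "ln1.g")]] <- rep(1, C); P[[paste0(pf, "ln1.b")]] <- numeric(C)
      P[[paste0(pf, "qkv.W")]] <- matrix(trunc_normal(C * 3L * C), C, 3L * C)
      if (cfg$qkv_bias) P[[paste0(pf, "qkv.b")]] <- numeric(3L * C)
      P[[paste0(pf, "bias")]] <- matrix(trunc_normal((2L * M - 1L)^2 * h),
                                        (2L * M - 1L)^2, h)
      P[[paste0(pf, "proj.W")]] <- matrix(trunc_normal(C * C), C, C)
      P[[paste0(pf, "proj.b")]] <- numeric(C)
      P[[paste0(pf, "ln2.g")]] <- rep(1, C); P[[paste0(pf, "ln2.b")]] <- numeric(C)
      P[[paste0(pf, "fc1.W")]] <- matrix(trunc_normal(C * r * C), C, r * C)
      P[[paste0(pf, "fc1.b")]] <- numeric(r * C)
      P[[paste0(pf, "fc2.W")]] <- matrix(trunc_normal(r * C * C), r * C, C)
      P[[paste0(pf, "fc2.b")]] <- numeric(C)
    }
    if (arch == "improved") {
      for (nm in names(mp <- make_res_module(C, mod2_kernel, zero_init_residual)))
        P[[sprintf("s%d.mod2.%s", s, nm)]] <- mp[[nm]]
      for (nm in names(ms <- res_module_state(C)))
        S[[sprintf("s%d.mod2.%s", s, nm)]] <- ms[[nm]]
    }
    if (s < ns) {
      P[[sprintf("s%d.merge.ln.g", s)]] <- rep(1, 4L * C)
      P[[sprintf("s%d.merge.ln.b", s)]] <- numeric(4L * C)
      P[[sprintf("s%d.merge.W", s)]] <- matrix(trunc_normal(4L * C * 2L * C),
                                               4L * C, 2L * C)
    }
  }
  Cl <- cfg$dims[ns]
  P[["head.ln.g"]] <- rep(1, Cl); P[["head.ln.b"]] <- numeric(Cl)
  P[["head.W"]] <- matrix(trunc_normal(Cl * cfg$num_classes), Cl, cfg$num_classes)
  P[["head.b"]] <- numeric(cfg$num_classes)
  structure(list(config = cfg, arch = arch, params = P, state = S,
                 mod1_kernel = as.integer(mod1_kernel),
                 mod2_kernel = as.integer(mod2_kernel),
                 geom_env = new.env(parent = emptyenv())),
            class = "resswin_model")
}

#' @export
print.resswin_model <- function(x, ...) {
  cat(sprintf("<resswin_model arch=%s img=%d params=%s (%.2f x 10^4)>\n",
              x$arch, x$config$img_size,
              format(count_parameters(x), big.mark = ","),
              count_parameters(x) / 1e4))
  invisible(x)
}

#' Count trainable parameters
#'
#' Sums the sizes of every trainable tensor (conv/linear weights and
#' biases, norm scale/offset pairs, relative position bias tables). Batch
#' norm running statistics are buffers, not parameters, and are excluded.
#'
#' @param model a `resswin_model`.
#' @return integer parameter count (report `count / 1e4` for the
#'   ten-thousand unit used in ablation tables).
#' @export
count_parameters <- function(model) {
  sum(vapply(model$params, length, numeric(1)))
}

# ---- geometry cache --------------------------------------------------------

patch_embed_geom <- function(H, W, p, B) {
  g_h <- H %/% p; g_w <- W %/% p
  gr <- rep(seq_len(g_h), each = g_w)
  gc <- rep(seq_len(g_w), times = g_h)
  boff <- rep((seq_len(B) - 1L) * H * W, each = g_h * g_w)
  idx <- vector("list", p * p)
  t <- 0L
  for (pr in seq_len(p)) for (pc in seq_len(p)) {
    t <- t + 1L
    src1 <- ((gr - 1L) * p + pr - 1L) * W + (gc - 1L) * p + pc
    idx[[t]] <- as.integer(rep(src1, times = B) + boff)
  }
  idx
}

merge_geom <- function(g, B) {
  gp <- g + g %% 2L          # odd grids are zero-padded before merging
  g2 <- gp %/% 2L
  n <- B * g * g
  r2 <- rep(seq_len(g2), each = g2)
  c2 <- rep(seq_len(g2), times = g2)
  boff <- rep((seq_len(B) - 1L) * g * g, each = g2 * g2)
  grp <- list(c(1L, 1L), c(2L, 1L), c(1L, 2L), c(2L, 2L))
  idx4 <- lapply(grp, function(d) {
    r <- 2L * (r2 - 1L) + d[1]; c0 <- 2L * (c2 - 1L) + d[2]
    ok <- r <= g & c0 <= g
    src1 <- ifelse(ok, (r - 1L) * g + c0, NA_integer_)
    src <- rep(src1, times = B) + boff
    src[is.na(src)] <- n + 1L
    as.integer(src)
  })
  list(idx4 = idx4, g2 = g2, n = n)
}

model_geom <- function(model, B) {
  key <- paste0("B", B)
  if (!is.null(model$geom_env[[key]])) return(model$geom_env[[key]])
  cfg <- model$config
  ns <- length(cfg$depths)
  st <- vector("list", ns)
  for (s in seq_len(ns)) {
    g <- cfg$grids[s]; M <- cfg$windows[s]; sh <- cfg$shifts[s]
    masks <- NULL; perm1 <- NULL
    if (sh > 0) {
      perm1 <- window_perm_batch(g, g, M, sh, B)
      masks <- shifted_window_mask(g, g, M, sh)$masks
      if (all(vapply(masks, function(m) all(m == 0), logical(1)))) masks <- NULL
    }
    st[[s]] <- list(perm0 = window_perm_batch(g, g, M, 0L, B),
                    perm1 = perm1, masks = masks, M = M, g = g,
                    merge = if (s < ns) merge_geom(g, B) else NULL,
                    conv = if (model$arch == "improved")
                      conv_geom(g, g, B, model$mod2_kernel) else NULL)
  }
  gm <- list(stages = st,
             embed = patch_embed_geom(cfg$img_size, cfg$img_size,
                                      cfg$patch_size, B),
             mod1 = if (model$arch == "improved")
               conv_geom(cfg$img_size, cfg$img_size, B, model$mod1_kernel)
             else NULL)
  model$geom_env[[key]] <- gm
  gm
}

# ---- residual module forward/backward (branch form) -----------------------

res_branch_fwd <- function(X, P, S, pfx, geom, training) {
  c1 <- conv2d_fwd(X, P[[paste0(pfx, "conv1.W")]], P[[paste0(pfx, "conv1.b")]], geom)
  b1 <- batchnorm_fwd(c1$out, P[[paste0(pfx, "bn1.g")]], P[[paste0(pfx, "bn1.b")]],
                      S[[paste0(pfx, "bn1.mean")]], S[[paste0(pfx, "bn1.var")]],
                      training)
  r1 <- relu_fwd(b1$out)
  c2 <- conv2d_fwd(r1$out, P[[paste0(pfx, "conv2.W")]], P[[paste0(pfx, "conv2.b")]], geom)
  b2 <- batchnorm_fwd(c2$out, P[[paste0(pfx, "bn2.g")]], P[[paste0(pfx, "bn2.b")]],
                      S[[paste0(pfx, "bn2.mean")]], S[[paste0(pfx, "bn2.var")]],
                      training)
  list(out = b2$out,
       cache = list(c1 = c1$cache, b1 = b1$cache, r1 = r1$cache,
                    c2 = c2$cache, b2 = b2$cache),
       state = stats::setNames(list(b1$run_mean, b1$run_var,
                                    b2$run_mean, b2$run_var),
                               paste0(pfx, c("bn1.mean", "bn1.var",
                                             "bn2.mean", "bn2.var"))))
}

res_branch_bwd <- function(dY, cache, pfx, G) {
  b2 <- batchnorm_bwd(dY, cache$b2)
  G[[paste0(pfx, "bn2.g")]] <- b2$dg; G[[paste0(pfx, "bn2.b")]] <- b2$db
  c2 <- conv2d_bwd(b2$dX, cache$c2)
  G[[paste0(pfx, "conv2.W")]] <- c2$dW; G[[paste0(pfx, "conv2.b")]] <- c2$db
  dr <- relu_bwd(c2$dX, cache$r1)
  b1 <- batchnorm_bwd(dr, cache$b1)
  G[[paste0(pfx, "bn1.g")]] <- b1$dg; G[[paste0(pfx, "bn1.b")]] <- b1$db
  c1 <- conv2d_bwd(b1$dX, cache$c1)
  G[[paste0(pfx, "conv1.W")]] <- c1$dW; G[[paste0(pfx, "conv1.b")]] <- c1$db
  list(dX = c1$dX, G = G)
}

# ---- forward ---------------------------------------------------------------

# imgs: array (B, H, W, 3) of raw 8-bit values, or a single image_array.
# Returns logits (B x K), the tap activation (final stage output tokens),
# head caches (always), full caches + updated BN state when training.
resswin_forward <- function(model, imgs, training = FALSE) {
  cfg <- model$config; P <- model$params
  if (inherits(imgs, "image_array"))
    imgs <- array(unclass(imgs), c(1L, dim(imgs)))
  stopifnot(length(dim(imgs)) == 4L)
  B <- dim(imgs)[1]
  if (dim(imgs)[2] != cfg$img_size || dim(imgs)[3] != cfg$img_size)
    stop("resswin_forward: input must be ", cfg$img_size, "x", cfg$img_size)
  geom <- model_geom(model, B)
  ns <- length(cfg$depths)
  cache <- list(stages = vector("list", ns))
  new_state <- model$state

  M0 <- matrix(aperm(imgs, c(3, 2, 1, 4)), B * cfg$img_size^2, 3L)
  M0 <- scale_cols(add_bias(M0 / 255, -cfg$norm_mean), 1 / cfg$norm_std)

  if (model$arch == "improved") {
    br <- res_branch_fwd(M0, P, model$state, "mod1.", geom$mod1, training)
    Ximg <- M0 + br$out
    if (training) { cache$mod1 <- br$cache
                    new_state[names(br$state)] <- br$state }
  } else Ximg <- M0

  # patch partition + linear embedding + norm
  p2 <- cfg$patch_size^2
  X48 <- matrix(0, B * cfg$grids[1]^2, p2 * 3L)
  for (t in seq_len(p2))
    X48[, ((t - 1L) * 3L + 1L):(t * 3L)] <- Ximg[geom$embed[[t]], , drop = FALSE]
  emb <- linear_fwd(X48, P[["embed.W"]], P[["embed.b"]])
  eln <- layernorm_fwd(emb$out, P[["embed.ln.g"]], P[["embed.ln.b"]])
  X <- eln$out
  if (training) cache$embed <- list(emb = emb$cache, eln = eln$cache)

  for (s in seq_len(ns)) {
    sg <- geom$stages[[s]]
    C <- cfg$dims[s]; h <- cfg$heads[s]; M <- sg$M
    x_in <- X
    scache <- list(blocks = vector("list", cfg$depths[s]))
    for (i in seq_len(cfg$depths[s])) {
      pf <- sprintf("s%d.b%d.", s, i)
      shifted <- (i %% 2L == 0L) && cfg$shifts[s] > 0L
      perm <- if (shifted) sg$perm1 else sg$perm0
      masks <- if (shifted) sg$masks else NULL
      ln1 <- layernorm_fwd(X, P[[paste0(pf, "ln1.g")]], P[[paste0(pf, "ln1.b")]])
      Xw <- ln1$out[perm, , drop = FALSE]
      bm <- relbias_mats(P[[paste0(pf, "bias")]], M)
      qb <- if (cfg$qkv_bias) P[[paste0(pf, "qkv.b")]] else numeric(3L * C)
      at <- attn_core_fwd(Xw, P[[paste0(pf, "qkv.W")]], qb, bm, h, M,
                          masks, keep_cache = training)
      pr <- linear_fwd(at$out, P[[paste0(pf, "proj.W")]], P[[paste0(pf, "proj.b")]])
      Y <- matrix(0, nrow(X), C); Y[perm, ] <- pr$out
      X <- X + Y
      ln2 <- layernorm_fwd(X, P[[paste0(pf, "ln2.g")]], P[[paste0(pf, "ln2.b")]])
      f1 <- linear_fwd(ln2$out, P[[paste0(pf, "fc1.W")]], P[[paste0(pf, "fc1.b")]])
      ge <- gelu_fwd(f1$out)
      f2 <- linear_fwd(ge$out, P[[paste0(pf, "fc2.W")]], P[[paste0(pf, "fc2.b")]])
      X <- X + f2$out
      if (training)
        scache$blocks[[i]] <- list(ln1 = ln1$cache, at = at$cache,
                                   pr = pr$cache, ln2 = ln2$cache,
                                   f1 = f1$cache, ge = ge$cache, f2 = f2$cache,
                                   perm = perm)
    }
    if (model$arch == "improved") {
      f <- x_in + X                        # parameter-free skip fusion
      pf2 <- sprintf("s%d.mod2.", s)
      br <- res_branch_fwd(f, P, model$state, pf2, sg$conv, training)
      X <- X + br$out
      if (training) { scache$mod2 <- br$cache
                      new_state[names(br$state)] <- br$state }
    }
    if (s == ns) tap <- list(act = X, g = sg$g, B = B)
    if (s < ns) {
      mg <- sg$merge
      Xz <- rbind(X, 0)
      Y4 <- cbind(Xz[mg$idx4[[1]], , drop = FALSE], Xz[mg$idx4[[2]], , drop = FALSE],
                  Xz[mg$idx4[[3]], , drop = FALSE], Xz[mg$idx4[[4]], , drop = FALSE])
      mln <- layernorm_fwd(Y4, P[[sprintf("s%d.merge.ln.g", s)]],
                           P[[sprintf("s%d.merge.ln.b", s)]])
      X <- mln$out %*% P[[sprintf("s%d.merge.W", s)]]
      if (training) scache$merge <- list(mln = mln$cache, mln_out = mln$out)
    }
    if (training) cache$stages[[s]] <- scache
  }

  N <- cfg$grids[ns]^2
  group <- rep(seq_len(B), each = N)
  hln <- layernorm_fwd(X, P[["head.ln.g"]], P[["head.ln.b"]])
  pooled <- rowsum(hln$out, group) / N
  hd <- linear_fwd(pooled, P[["head.W"]], P[["head.b"]])
  head_cache <- list(hln = hln$cache, hd = hd$cache, N = N, B = B)
  list(logits = hd$out, tap = tap, head_cache = head_cache,
       cache = if (training) cache else NULL,
       state = if (training) new_state else model$state)
}

# Backward from d(logits); requires a training=TRUE forward result.
# Returns the full gradient list plus the gradient at the tap point.
resswin_backward <- function(model, fwd, dlogits) {
  cfg <- model$config; P <- model$params
  cache <- fwd$cache; hc <- fwd$head_cache
  G <- vector("list", length(P)); names(G) <- names(P)
  ns <- length(cfg$depths)

  hb <- linear_bwd(dlogits, hc$hd)
  G[["head.W"]] <- hb$dW; G[["head.b"]] <- hb$db
  group <- rep(seq_len(hc$B), each = hc$N)
  dhln <- hb$dX[group, , drop = FALSE] / hc$N
  lb <- layernorm_bwd(dhln, hc$hln)
  G[["head.ln.g"]] <- lb$dg; G[["head.ln.b"]] <- lb$db
  dX <- lb$dX
  dtap <- NULL

  for (s in rev(seq_len(ns))) {
    sg <- model_geom(model, nrow(dlogits))$stages[[s]]
    scache <- cache$stages[[s]]
    C <- cfg$dims[s]
    if (s < ns) {
      mg <- sg$merge
      dmln_out <- tcrossprod(dX, P[[sprintf("s%d.merge.W", s)]])
      G[[sprintf("s%d.merge.W", s)]] <- crossprod(scache$merge$mln_out, dX)
      mb <- layernorm_bwd(dmln_out, scache$merge$mln)
      G[[sprintf("s%d.merge.ln.g", s)]] <- mb$dg
      G[[sprintf("s%d.merge.ln.b", s)]] <- mb$db
      dY4 <- mb$dX
      dX <- matrix(0, mg$n, C)
      for (q in 1:4) {
        src <- mg$idx4[[q]]; ok <- src <= mg$n
        dX[src[ok], ] <- dX[src[ok], , drop = FALSE] +
          dY4[ok, ((q - 1L) * C + 1L):(q * C), drop = FALSE]
      }
    }
    if (s == ns) dtap <- dX
    dx_in_extra <- NULL
    if (model$arch == "improved") {
      pf2 <- sprintf("s%d.mod2.", s)
      rb <- res_branch_bwd(dX, scache$mod2, pf2, G)
      G <- rb$G
      dx_in_extra <- rb$dX          # grad through the fused skip input
      dX <- dX + rb$dX              # ... and through the stage-output path
    }
    for (i in rev(seq_len(cfg$depths[s]))) {
      pf <- sprintf("s%d.b%d.", s, i)
      bc <- scache$blocks[[i]]
      f2 <- linear_bwd(dX, bc$f2)
      G[[paste0(pf, "fc2.W")]] <- f2$dW; G[[paste0(pf, "fc2.b")]] <- f2$db
      dge <- gelu_bwd(f2$dX, bc$ge)
      f1 <- linear_bwd(dge, bc$f1)
      G[[paste0(pf, "fc1.W")]] <- f1$dW; G[[paste0(pf, "fc1.b")]] <- f1$db
      l2 <- layernorm_bwd(f1$dX, bc$ln2)
      G[[paste0(pf, "ln2.g")]] <- l2$dg; G[[paste0(pf, "ln2.b")]] <- l2$db
      dX <- dX + l2$dX
      dYw <- dX[bc$perm, , drop = FALSE]
      prb <- linear_bwd(dYw, bc$pr)
      G[[paste0(pf, "proj.W")]] <- prb$dW; G[[paste0(pf, "proj.b")]] <- prb$db
      ab <- attn_core_bwd(prb$dX, bc$at)
      G[[paste0(pf, "qkv.W")]] <- ab$dqkv_W
      if (cfg$qkv_bias) G[[paste0(pf, "qkv.b")]] <- ab$dqkv_b
      G[[paste0(pf, "bias")]] <- relbias_grad(ab$dS_sum, sg$M, cfg$heads[s])
      dln1_out <- matrix(0, nrow(dX), C); dln1_out[bc$perm, ] <- ab$dXw
      l1 <- layernorm_bwd(dln1_out, bc$ln1)
      G[[paste0(pf, "ln1.g")]] <- l1$dg; G[[paste0(pf, "ln1.b")]] <- l1$db
      dX <- dX + l1$dX
    }
    if (!is.null(dx_in_extra)) dX <- dX + dx_in_extra
  }

  eb <- layernorm_bwd(dX, cache$embed$eln)
  G[["embed.ln.g"]] <- eb$dg; G[["embed.ln.b"]] <- eb$db
  el <- linear_bwd(eb$dX, cache$embed$emb)
  G[["embed.W"]] <- el$dW; G[["embed.b"]] <- el$db

  if (model$arch == "improved") {
    geom <- model_geom(model, nrow(dlogits))
    p2 <- cfg$patch_size^2
    dImg <- matrix(0, cfg$img_size^2 * nrow(dlogits), 3L)
    for (t in seq_len(p2))
      dImg[geom$embed[[t]], ] <- el$dX[, ((t - 1L) * 3L + 1L):(t * 3L), drop = FALSE]
    rb <- res_branch_bwd(dImg, cache$mod1, "mod1.", G)
    G <- rb$G
  }
  list(grads = G, dtap = dtap)
}

# ---- public single-image / op wrappers ------------------------------------

#' Patch partition and linear embedding
#'
#' Splits a normalized image into `patch_size`-square patches, projects
#' each flattened patch to an `embed_dim`-channel token, and applies layer
#' normalization, yielding the stage-1 token grid.
#'
#' @param img an [image_array()] of the model's input size.
#' @param model a `resswin_model` (its embedding weights are used).
#' @return a [token_grid()] of size `img_size/patch_size` squared.
#' @export
patch_partition_embed <- function(img, model) {
  cfg <- model$config
  img <- as_image_array(img)
  if (dim(img)[1] != cfg$img_size || dim(img)[2] != cfg$img_size ||
      (cfg$img_size %% cfg$patch_size) != 0)
    stop("patch_partition_embed: input must be ", cfg$img_size, " square")
  geom <- model_geom(model, 1L)
  M0 <- matrix(aperm(array(unclass(img), c(1L, dim(img))), c(3, 2, 1, 4)),
               cfg$img_size^2, 3L)
  M0 <- scale_cols(add_bias(M0 / 255, -cfg$norm_mean), 1 / cfg$norm_std)
  p2 <- cfg$patch_size^2
  X48 <- matrix(0, cfg$grids[1]^2, p2 * 3L)
  for (t in seq_len(p2))
    X48[, ((t - 1L) * 3L + 1L):(t * 3L)] <- M0[geom$embed[[t]], , drop = FALSE]
  X <- layernorm_fwd(add_bias(X48 %*% model$params[["embed.W"]],
                              model$params[["embed.b"]]),
                     model$params[["embed.ln.g"]],
                     model$params[["embed.ln.b"]])$out
  mat_to_grid(X, cfg$grids[1], cfg$grids[1])
}

#' Patch merging downsampling
#'
#' Concatenates each 2x2 token neighborhood (4C channels), layer
#' normalizes, and linearly projects to 2C channels, halving the grid.
#' Odd grids are zero-padded. Parameters per merge at width C: `8C^2`
#' reduction weights plus `8C` norm affine terms.
#'
#' @param grid a [token_grid()].
#' @param params list with `ln.g`, `ln.b` (length 4C) and `W` (4C x 2C);
#'   freshly initialized when omitted.
#' @return a [token_grid()] of halved resolution and doubled width.
#' @export
patch_merging <- function(grid, params = NULL) {
  C <- grid$dim
  if (is.null(params)) {
    old <- .Random.seed.save(); on.exit(.Random.seed.restore(old))
    set.seed(0L)
    params <- list(ln.g = rep(1, 4 * C), ln.b = numeric(4 * C),
                   W = matrix(trunc_normal(8 * C * C), 4 * C, 2 * C))
  }
  if (grid$grid_h %% 2L != 0L || grid$grid_w %% 2L != 0L)
    stop("patch_merging: grid sides must be even")
  mg <- merge_geom(grid$grid_h, 1L)
  X <- grid_to_mat(grid)
  Xz <- rbind(X, 0)
  Y4 <- cbind(Xz[mg$idx4[[1]], , drop = FALSE], Xz[mg$idx4[[2]], , drop = FALSE],
              Xz[mg$idx4[[3]], , drop = FALSE], Xz[mg$idx4[[4]], , drop = FALSE])
  Y <- layernorm_fwd(Y4, params$ln.g, params$ln.b)$out %*% params$W
  mat_to_grid(Y, mg$g2, mg$g2)
}

#' Classify an image (or batch): forward pass to class logits
#'
#' @param model a `resswin_model`.
#' @param imgs an [image_array()] or a `(B, H, W, 3)` array of raw 8-bit
#'   values.
#' @return numeric matrix `B x num_classes` of logits (a vector for a
#'   single image).
#' @export
forward_classify <- function(model, imgs) {
  single <- inherits(imgs, "image_array") ||
    (length(dim(imgs)) == 3L && dim(imgs)[3] == 3L)
  if (single && !inherits(imgs, "image_array")) imgs <- image_array(imgs)
  out <- resswin_forward(model, imgs)$logits
  if (single) drop(out) else out
}

#' Convolutional residual block (functional form)
#'
#' `y = x + BN2(Conv2(ReLU(BN1(Conv1(x)))))` on a channels-first spatial
#' feature map. Two same-padded `k x k` convolution + batch-norm pairs
#' with a ReLU between; `2k^2C^2 + 6C` trainable parameters. With the
#' branch zero-initialized the block is the identity.
#'
#' @param x array `c(C, H, W)`.
#' @param params a [residual_params()] list with matching channel count.
#' @param training use batch statistics in the batch norms.
#' @return array `c(C, H, W)`.
#' @export
residual_block <- function(x, params, training = FALSE) {
  d <- dim(x)
  if (length(d) != 3L) stop("residual_block: x must be C x H x W")
  if (d[1] != params$channels)
    stop("residual_block: channel mismatch (", d[1], " vs ", params$channels, ")")
  X <- matrix(aperm(x, c(3, 2, 1)), d[2] * d[3], d[1])
  geom <- conv_geom(d[2], d[3], 1L, params$kernel)
  br <- res_branch_fwd(X, params$P, params$S, "", geom, training)
  Y <- X + br$out
  aperm(array(Y, c(d[3], d[2], d[1])), c(3, 2, 1))
}

#' Parameters of a convolutional residual block
#'
#' @param channels feature channels C (input == output).
#' @param kernel odd kernel side k.
#' @param seed RNG seed for the convolution weights.
#' @param zero_init zero the closing batch-norm scale so the block is the
#'   identity.
#' @return a `residual_params` list; its trainable size is
#'   `2k^2C^2 + 6C`.
#' @export
residual_params <- function(channels, kernel = 3L, seed = 0L, zero_init = FALSE) {
  old <- .Random.seed.save(); on.exit(.Random.seed.restore(old))
  set.seed(as.integer(seed))
  m <- make_res_module(channels, kernel, zero_init)
  structure(list(channels = as.integer(channels), kernel = as.integer(kernel),
                 P = m, S = res_module_state(channels)),
            class = "residual_params")
}

#' Number of trainable parameters in a residual block
#' @param params a [residual_params()].
#' @return integer count.
#' @export
residual_param_count <- function(params) {
  sum(vapply(params$P, length, numeric(1)))
}

#' Parameter-free skip fusion
#'
#' Element-wise addition of a stage's input and output token grids (or
#' arrays of identical shape). Contributes zero trainable parameters.
#'
#' @param stage_in,stage_out [token_grid()]s or arrays of identical shape.
#' @return object of the same type as the inputs.
#' @export
stage_skip_fuse <- function(stage_in, stage_out) {
  if (inherits(stage_in, "token_grid")) {
    if (!identical(dim(stage_in$values), dim(stage_out$values)))
      stop("stage_skip_fuse: shape mismatch")
    return(token_grid(stage_in$values + stage_out$values))
  }
  if (!identical(dim(stage_in), dim(stage_out)))
    stop("stage_skip_fuse: shape mismatch")
  stage_in + stage_out
}

#' Save / load a model
#'
#' Serializes the model (config, architecture, weights, batch-norm
#' buffers) to an RDS container; geometry caches are rebuilt on load.
#'
#' @param model a `resswin_model`.
#' @param path file path.
#' @export
save_model <- function(model, path) {
  m <- model; m$geom_env <- NULL
  saveRDS(m, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  m <- readRDS(path)
  m$geom_env <- new.env(parent = emptyenv())
  class(m) <- "resswin_model"
  m
}
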