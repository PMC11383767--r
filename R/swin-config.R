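# Backbone configuration, token-grid container, and the window geometry
# machinery: window partition permutations, cyclic-shift masks, relative
# position bias indexing, and the attention complexity formulas.

#' Backbone hyperparameters
#'
#' Defaults pin the base model: patch 4, embedding width 96, stage depths
#' (2,2,6,2), heads (3,6,12,24), window 7, shift 3, MLP ratio 4, 3-class
#' head, qkv bias on, no dropout. Per-stage token grids must be divisible
#' by the (possibly grid-clamped) window; 224, 112 and 56 inputs satisfy
#' this. Input normalization uses fixed per-channel constants recorded
#' here.
#'
#' @param img_size square input side in pixels.
#' @param patch_size patch side in pixels.
#' @param embed_dim token width after patch embedding.
#' @param depths integer vector of transformer blocks per stage.
#' @param heads attention heads per stage.
#' @param window window side in tokens.
#' @param mlp_ratio hidden/width ratio of the block MLP.
#' @param num_classes classifier output size.
#' @param qkv_bias add bias to the qkv projection.
#' @param norm_mean,norm_std per-channel input normalization constants.
#' @return a `swin_config` list; stage grid sizes in `$grids`, per-stage
#'   windows in `$windows`, shifts in `$shifts`, dims in `$dims`.
#' @export
swin_config <- function(img_size = 224L, patch_size = 4L, embed_dim = 96L,
                        depths = c(2L, 2L, 6L, 2L), heads = c(3L, 6L, 12L, 24L),
                        window = 7L, mlp_ratio = 4, num_classes = 3L,
                        qkv_bias = TRUE,
                        norm_mean = c(0.485, 0.456, 0.406),
                        norm_std = c(0.229, 0.224, 0.225)) {
  if (img_size %% patch_size != 0)
    stop("swin_config: img_size must be divisible by patch_size")
  ns <- length(depths)
  stopifnot(length(heads) == ns)
  grids <- integer(ns); g <- img_size %/% patch_size
  dims <- embed_dim * 2^(seq_len(ns) - 1L)
  windows <- integer(ns); shifts <- integer(ns)
  for (s in seq_len(ns)) {
    grids[s] <- g
    windows[s] <- min(window, g)
    shifts[s] <- if (g > windows[s]) windows[s] %/% 2L else 0L
    if (g %% windows[s] != 0)
      stop("swin_config: stage ", s, " grid ", g,
           " not divisible by window ", windows[s])
    if (any(dims[s] %% heads[s] != 0))
      stop("swin_config: dim not divisible by heads at stage ", s)
    g <- (g + g %% 2L) %/% 2L     # patch merging pads odd grids
  }
  structure(list(img_size = as.integer(img_size),
                 patch_size = as.integer(patch_size),
                 embed_dim = as.integer(embed_dim),
                 depths = as.integer(depths), heads = as.integer(heads),
                 window = as.integer(window), mlp_ratio = mlp_ratio,
                 num_classes = as.integer(num_classes), qkv_bias = qkv_bias,
                 norm_mean = norm_mean, norm_std = norm_std,
                 grids = grids, dims = dims, windows = windows,
                 shifts = shifts), class = "swin_config")
}

# ---- TokenGrid -------------------------------------------------------------

#' Token grid container
#'
#' A stage feature map: a `grid_h x grid_w` raster of `dim`-channel
#' tokens, stored as a 3-D array.
#'
#' @param values array of dimension `c(grid_h, grid_w, dim)`.
#' @return a `token_grid` object.
#' @export
token_grid <- function(values) {
  d <- dim(values)
  if (is.null(d) || length(d) != 3L) stop("token_grid: need a 3-D array")
  structure(list(grid_h = d[1], grid_w = d[2], dim = d[3], values = values),
            class = "token_grid")
}

#' @export
print.token_grid <- function(x, ...) {
  cat(sprintf("<token_grid %d x %d x %d>\n", x$grid_h, x$grid_w, x$dim))
  invisible(x)
}

# Internal flat layout: matrix (H*W) x C, rows ordered column-fastest
# (row id = (r-1)*W + c). Lossless relayout in both directions.
grid_to_mat <- function(grid) {
  v <- grid$values
  m <- matrix(aperm(v, c(2, 1, 3)), grid$grid_h * grid$grid_w, grid$dim)
  m
}
mat_to_grid <- function(m, grid_h, grid_w) {
  token_grid(aperm(array(m, c(grid_w, grid_h, ncol(m))), c(2, 1, 3)))
}

#' Relayout tokens to a spatial feature map (and back)
#'
#' `tokens_to_spatial` turns a `grid_h x grid_w x C` token grid into a
#' `C x H x W` spatial feature array (channels first, as convolutions
#' expect); `spatial_to_tokens` inverts it losslessly.
#'
#' @param grid a [token_grid()].
#' @return array `c(C, grid_h, grid_w)`.
#' @export
tokens_to_spatial <- function(grid) {
  aperm(grid$values, c(3, 1, 2))
}

#' @rdname tokens_to_spatial
#' @param x array `c(C, H, W)`.
#' @export
spatial_to_tokens <- function(x) {
  token_grid(aperm(x, c(2, 3, 1)))
}

# ---- window partition ------------------------------------------------------

# Permutation (single image) listing flat row ids in window order:
# windows enumerated row-major over the grid, tokens row-major within
# each window. With shift > 0 the grid is first rolled by (-shift, -shift).
window_perm <- function(grid_h, grid_w, M, shift = 0L) {
  stopifnot(grid_h %% M == 0, grid_w %% M == 0)
  r <- rep(seq_len(grid_h), each = grid_w)
  c0 <- rep(seq_len(grid_w), times = grid_h)
  if (shift > 0) {     # token shown at (r, c) after roll comes from (r+s, c+s)
    r <- ((r - 1L + shift) %% grid_h) + 1L
    c0 <- ((c0 - 1L + shift) %% grid_w) + 1L
  }
  wr <- (rep(seq_len(grid_h), each = grid_w) - 1L) %/% M
  wc <- (rep(seq_len(grid_w), times = grid_h) - 1L) %/% M
  ir <- (rep(seq_len(grid_h), each = grid_w) - 1L) %% M
  ic <- (rep(seq_len(grid_w), times = grid_h) - 1L) %% M
  win <- wr * (grid_w %/% M) + wc
  pos <- ir * M + ic
  ord <- order(win, pos)
  src <- (r - 1L) * grid_w + c0
  as.integer(src[ord])
}

# Batched version: blocks of M^2 rows per window, images consecutive.
window_perm_batch <- function(grid_h, grid_w, M, shift, B) {
  p1 <- window_perm(grid_h, grid_w, M, shift)
  n1 <- grid_h * grid_w
  as.integer(rep(p1, times = B) + rep((seq_len(B) - 1L) * n1, each = n1))
}

#' Partition a token grid into non-overlapping windows
#'
#' @param grid a [token_grid()] whose sides are divisible by `M`.
#' @param M window side in tokens.
#' @return list of `M^2 x dim` matrices, windows row-major over the grid,
#'   tokens row-major within each window.
#' @export
window_partition <- function(grid, M) {
  if (grid$grid_h %% M != 0 || grid$grid_w %% M != 0)
    stop("window_partition: grid not divisible by window")
  X <- grid_to_mat(grid)
  perm <- window_perm(grid$grid_h, grid$grid_w, M)
  nw <- (grid$grid_h %/% M) * (grid$grid_w %/% M)
  lapply(seq_len(nw), function(w)
    X[perm[((w - 1L) * M * M + 1L):(w * M * M)], , drop = FALSE])
}

#' @rdname window_partition
#' @param windows list of windows as returned by [window_partition()].
#' @param grid_h,grid_w grid size to reassemble.
#' @export
window_reverse <- function(windows, grid_h, grid_w) {
  M <- as.integer(sqrt(nrow(windows[[1]])))
  X <- matrix(0, grid_h * grid_w, ncol(windows[[1]]))
  perm <- window_perm(grid_h, grid_w, M)
  for (w in seq_along(windows))
    X[perm[((w - 1L) * M * M + 1L):(w * M * M)], ] <- windows[[w]]
  mat_to_grid(X, grid_h, grid_w)
}

# ---- shifted-window regions and masks --------------------------------------

#' Region map and attention mask for shifted windows
#'
#' Cyclically shifting the grid by `(-shift, -shift)` makes windows
#' straddle former window borders. Tokens are labeled by which of 9
#' contiguous pre-shift regions they come from (3 row-bands x 3
#' column-bands: up to the last full window, the remainder before the
#' shift line, and the shifted tail); within each window, pairs drawn from
#' different regions receive a large negative additive mask so attention
#' stays confined to contiguous content.
#'
#' @param grid_h,grid_w grid size in tokens.
#' @param M window side.
#' @param shift cyclic shift in tokens, `0 <= shift < M`; 0 yields an
#'   all-pass mask.
#' @return list with `region_ids` (`grid_h x grid_w` integer matrix in
#'   rolled-canvas coordinates: entry (r, c) labels the token displayed at
#'   that position after the shift) and `masks` (one `M^2 x M^2` additive
#'   mask per window, in [window_partition()] order; 0 = allowed, -1e9 =
#'   masked).
#' @export
shifted_window_mask <- function(grid_h, grid_w, M, shift) {
  if (shift < 0 || shift >= M) stop("shifted_window_mask: need 0 <= shift < M")
  # Bands are laid out on the rolled canvas: positions up to n-M hold
  # content that stays contiguous under the roll; n-M+1 .. n-shift and the
  # final shift positions hold the two wrapped strips.
  band <- function(x, n) ifelse(x <= n - M, 1L, ifelse(x <= n - shift, 2L, 3L))
  rb <- band(seq_len(grid_h), grid_h)
  cb <- band(seq_len(grid_w), grid_w)
  ids <- outer(rb, cb, function(a, b) (a - 1L) * 3L + b)
  if (shift == 0) ids[, ] <- 1L
  ids_flat <- as.vector(t(ids))            # canvas row id = (r-1)*W + c
  perm <- window_perm(grid_h, grid_w, M, 0L)   # windows over canvas positions
  nw <- (grid_h %/% M) * (grid_w %/% M)
  M2 <- M * M
  masks <- lapply(seq_len(nw), function(w) {
    v <- ids_flat[perm[((w - 1L) * M2 + 1L):(w * M2)]]
    ifelse(outer(v, v, "!="), -1e9, 0)
  })
  list(region_ids = ids, masks = masks)
}

# ---- relative position bias ------------------------------------------------

# M^2 x M^2 matrix of 1-based indices into the (2M-1)^2-row bias table;
# entry (i, j) depends only on the (row, col) offset between tokens i, j.
relpos_index <- function(M) {
  r <- rep(seq_len(M), each = M)
  c0 <- rep(seq_len(M), times = M)
  dr <- outer(r, r, "-") + M - 1L
  dc <- outer(c0, c0, "-") + M - 1L
  dr * (2L * M - 1L) + dc + 1L
}

# ---- attention complexity --------------------------------------------------

#' Multiply-accumulate count of (windowed) multi-head self-attention
#'
#' Closed forms for one attention layer over an `H x W` grid of `C`-dim
#' tokens: global attention costs `4HWC^2 + 2(HW)^2 C`; window attention
#' replaces the quadratic token term with the window area,
#' `4HWC^2 + 2M^2 HWC`. Windowed attention is cheaper whenever
#' `M^2 < HW`.
#'
#' @param H,W token grid size.
#' @param C token width.
#' @param M window side (used when `windowed`).
#' @param windowed compute the window-attention form.
#' @return multiply-accumulate count (numeric, exact integer value).
#' @export
attention_flops <- function(H, W, C, M = 7, windowed = TRUE) {
  stopifnot(H >= 1, W >= 1, C >= 1, M >= 1)
  if (windowed) 4 * H * W * C^2 + 2 * M^2 * H * W * C
  else          4 * H * W * C^2 + 2 * (H * W)^2 * C
}

# ---- fused window attention core (shared by the model and the public op) ---

# Xw: (nblocks * M^2) x C window-ordered activations. masks: list of
# per-window-position additive masks (recycled across the batch) or NULL.
# bias_mats: M^2 x M^2 x heads array from the layer's bias table.
attn_core_fwd <- function(Xw, qkv_W, qkv_b, bias_mats, heads, M,
                          masks = NULL, keep_cache = FALSE) {
  C <- ncol(Xw); d <- C %/% heads; M2 <- M * M
  scale <- 1 / sqrt(d)
  nblocks <- nrow(Xw) %/% M2
  nw <- if (is.null(masks)) 0L else length(masks)
  qkv <- add_bias(Xw %*% qkv_W, qkv_b)
  out <- matrix(0, nrow(Xw), C)
  Pstore <- if (keep_cache) array(0, c(M2, M2, heads, nblocks)) else NULL
  for (blk in seq_len(nblocks)) {
    rows <- ((blk - 1L) * M2 + 1L):(blk * M2)
    mk <- if (nw > 0L) masks[[((blk - 1L) %% nw) + 1L]] else NULL
    for (h in seq_len(heads)) {
      qc <- ((h - 1L) * d + 1L):(h * d)
      Q <- qkv[rows, qc, drop = FALSE]
      K <- qkv[rows, C + qc, drop = FALSE]
      V <- qkv[rows, 2L * C + qc, drop = FALSE]
      S <- tcrossprod(Q, K) * scale + bias_mats[, , h]
      if (!is.null(mk)) S <- S + mk
      P <- softmax_rows(S)
      out[rows, qc] <- P %*% V
      if (keep_cache) Pstore[, , h, blk] <- P
    }
  }
  list(out = out,
       cache = if (keep_cache) list(Xw = Xw, qkv = qkv, P = Pstore,
                                    heads = heads, M = M, qkv_W = qkv_W,
                                    scale = scale) else NULL)
}

attn_core_bwd <- function(dOut, cache) {
  qkv <- cache$qkv; heads <- cache$heads; M2 <- cache$M^2
  C <- ncol(dOut); d <- C %/% heads
  nblocks <- nrow(dOut) %/% M2
  dqkv <- matrix(0, nrow(qkv), 3L * C)
  dS_sum <- array(0, c(M2, M2, heads))
  for (blk in seq_len(nblocks)) {
    rows <- ((blk - 1L) * M2 + 1L):(blk * M2)
    for (h in seq_len(heads)) {
      qc <- ((h - 1L) * d + 1L):(h * d)
      Q <- qkv[rows, qc, drop = FALSE]
      K <- qkv[rows, C + qc, drop = FALSE]
      V <- qkv[rows, 2L * C + qc, drop = FALSE]
      P <- cache$P[, , h, blk]
      dO <- dOut[rows, qc, drop = FALSE]
      dP <- tcrossprod(dO, V)
      dV <- crossprod(P, dO)
      dS <- P * (dP - rowSums(dP * P))
      dS_sum[, , h] <- dS_sum[, , h] + dS
      dqkv[rows, qc] <- dS %*% K * cache$scale
      dqkv[rows, C + qc] <- crossprod(dS, Q) * cache$scale
      dqkv[rows, 2L * C + qc] <- dV
    }
  }
  list(dXw = tcrossprod(dqkv, cache$qkv_W),
       dqkv_W = crossprod(cache$Xw, dqkv),
       dqkv_b = colSums(dqkv),
       dS_sum = dS_sum)     # caller scatters into the bias table
}

# Scatter summed attention-logit grads into the (2M-1)^2 x heads table.
relbias_grad <- function(dS_sum, M, heads) {
  idx <- as.vector(relpos_index(M))
  tbl <- matrix(0, (2L * M - 1L)^2, heads)
  for (h in seq_len(heads)) {
    acc <- rowsum(as.vector(dS_sum[, , h]), idx)
    tbl[as.integer(rownames(acc)), h] <- acc[, 1]
  }
  tbl
}

# Expand a bias table into per-pair M^2 x M^2 x heads matrices.
relbias_mats <- function(table, M) {
  idx <- relpos_index(M)
  heads <- ncol(table)
  out <- array(0, c(M * M, M * M, heads))
  for (h in seq_len(heads)) out[, , h] <- matrix(table[idx, h], M * M, M * M)
  out
}

#' Window-based multi-head self-attention (single layer, functional form)
#'
#' Scaled dot-product attention computed independently inside each window,
#' with a learned relative position bias added to the logits and an
#' optional additive mask (for shifted windows). Exposed functionally for
#' testing and inspection; the model forward uses the same core.
#'
#' @param windows list of `M^2 x C` matrices (see [window_partition()]).
#' @param proj list with `qkv_W` (`C x 3C`), `qkv_b`, `proj_W` (`C x C`),
#'   `proj_b`, `bias_table` (`(2M-1)^2 x heads`), `heads`.
#' @param masks optional list of per-window `M^2 x M^2` additive masks.
#' @return list of output windows (same shapes).
#' @export
window_attention <- function(windows, proj, masks = NULL) {
  M2 <- nrow(windows[[1]]); M <- as.integer(sqrt(M2))
  C <- ncol(windows[[1]])
  if (C %% proj$heads != 0)
    stop("window_attention: dim not divisible by heads")
  if (!is.null(masks)) {
    if (length(masks) != length(windows) ||
        any(vapply(masks, function(m) !all(dim(m) == c(M2, M2)), logical(1))))
      stop("window_attention: mask shape mismatch")
  }
  Xw <- do.call(rbind, windows)
  bias_mats <- relbias_mats(proj$bias_table, M)
  a <- attn_core_fwd(Xw, proj$qkv_W, proj$qkv_b, bias_mats, proj$heads, M, masks)
  Y <- add_bias(a$out %*% proj$proj_W, proj$proj_b)
  lapply(seq_along(windows), function(w)
    Y[((w - 1L) * M2 + 1L):(w * M2), , drop = FALSE])
}
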