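# Window geometry, attention, merging, embedding, and complexity formulas.

test_that("window partition counts and round-trips exactly", {
  set.seed(1)
  g14 <- token_grid(array(rnorm(14 * 14 * 4), c(14, 14, 4)))
  w <- window_partition(g14, 7)
  expect_length(w, 4)
  expect_equal(dim(w[[1]]), c(49L, 4L))
  back <- window_reverse(w, 14, 14)
  expect_identical(back$values, g14$values)

  g7 <- token_grid(array(rnorm(7 * 7 * 2), c(7, 7, 2)))
  expect_length(window_partition(g7, 7), 1)

  for (rep in 1:3) {
    gh <- sample(c(6, 12), 1); gw <- sample(c(6, 9), 1)
    gr <- token_grid(array(rnorm(gh * gw * 3), c(gh, gw, 3)))
    expect_identical(window_reverse(window_partition(gr, 3), gh, gw)$values,
                     gr$values)
  }
  expect_error(window_partition(g14, 4), "divisible")
  # a 56-token grid yields (56/7)^2 = 64 windows
  g56 <- token_grid(array(0, c(56, 56, 1)))
  expect_length(window_partition(g56, 7), 64)
})

test_that("window attention matches a naive per-pair oracle", {
  C <- 8; heads <- 2; M <- 2
  proj <- random_attn_proj(C, heads, M, seed = 2)
  set.seed(3)
  windows <- lapply(1:3, function(i) matrix(rnorm(M * M * C, sd = 0.5), M * M, C))
  got <- window_attention(windows, proj)
  want <- naive_window_attention(windows, proj)
  for (i in seq_along(windows))
    expect_lt(max(abs(got[[i]] - want[[i]])), 1e-5)
})

test_that("attention rows are a softmax and a single token attends to itself", {
  C <- 6; heads <- 3; M <- 1
  proj <- random_attn_proj(C, heads, M, seed = 4)
  x <- matrix(rnorm(C), 1, C)
  out <- window_attention(list(x), proj)[[1]]
  # with one token the attention weight is 1: output is V then projection
  qkv <- x %*% proj$qkv_W + proj$qkv_b
  v <- qkv[, (2 * C + 1):(3 * C), drop = FALSE]
  expect_lt(max(abs(out - (v %*% proj$proj_W + proj$proj_b))), 1e-10)

  # softmax normalization at the core level
  M2 <- 7
  bm <- resswin:::relbias_mats(matrix(0, (2 * 7 - 1)^2, 1), 7)
  Xw <- matrix(rnorm(49 * 4), 49, 4)
  a <- resswin:::attn_core_fwd(Xw, diag(4)[, rep(1:4, 3)] * 0.5, numeric(12),
                               bm, 1, 7, keep_cache = TRUE)
  P <- a$cache$P[, , 1, 1]
  expect_true(all(abs(rowSums(P) - 1) < 1e-6))
})

test_that("mask shape mismatches are rejected", {
  C <- 4; M <- 2
  proj <- random_attn_proj(C, 2, M, seed = 5)
  w <- list(matrix(rnorm(M * M * C), M * M, C))
  expect_error(window_attention(w, proj, masks = list(matrix(0, 3, 3))),
               "mask shape")
})

test_that("the shifted grid carries exactly 9 regions and masks confine them", {
  sm <- shifted_window_mask(14, 14, 7, 3)
  expect_equal(sort(unique(as.vector(sm$region_ids))), 1:9)
  expect_length(sm$masks, 4)
  # the un-shifted corner window holds one region: all-pass mask
  expect_true(all(sm$masks[[1]] == 0))
  # shift 0 degenerates to a single region and all-pass masks
  sm0 <- shifted_window_mask(14, 14, 7, 0)
  expect_equal(unique(as.vector(sm0$region_ids)), 1L)
  expect_true(all(vapply(sm0$masks, function(m) all(m == 0), logical(1))))
  expect_error(shifted_window_mask(14, 14, 7, 7), "shift")
})

test_that("masked shifted attention equals independent per-region attention", {
  # 14x14 grid, M = 7, shift = 3: each of the 9 regions lies inside one
  # window, so masked attention must reproduce plain attention computed on
  # each region's tokens alone (relative position bias included).
  g <- 14; M <- 7; sh <- 3; C <- 6; heads <- 2
  proj <- random_attn_proj(C, heads, M, seed = 6)
  set.seed(7)
  X <- matrix(rnorm(g * g * C, sd = 0.5), g * g, C)   # rows: (r-1)*g + c
  perm1 <- resswin:::window_perm(g, g, M, sh)
  Xw_all <- X[perm1, , drop = FALSE]
  sm <- shifted_window_mask(g, g, M, sh)
  windows <- lapply(1:4, function(w) Xw_all[((w - 1) * 49 + 1):(w * 49), ])
  got_w <- window_attention(windows, proj, masks = sm$masks)
  got <- matrix(0, g * g, C)
  got[perm1, ] <- do.call(rbind, got_w)

  # oracle: plain (unmasked) attention run separately on each region,
  # using each token's in-window coordinates for the position bias
  idx_fun <- function(ri, ci, rj, cj) (ri - rj + M - 1) * (2 * M - 1) + (ci - cj + M - 1) + 1
  canvas_pos <- matrix(perm1, nrow = 49)     # column w: orig rows of window w
  ids_flat <- as.vector(t(sm$region_ids))
  want <- matrix(0, g * g, C)
  for (w in 1:4) {
    slots <- ((w - 1) * 49 + 1):(w * 49)
    canvas_rows <- rep(((w - 1) %/% 2) * 7 + 1:7, each = 7)
    canvas_cols <- rep(((w - 1) %% 2) * 7 + 1:7, times = 7)
    canvas_id <- (canvas_rows - 1) * g + canvas_cols
    regions <- ids_flat[canvas_id]
    for (rg in unique(regions)) {
      pick <- which(regions == rg)
      toks <- X[perm1[slots][pick], , drop = FALSE]
      N <- length(pick)
      d <- C / heads
      out <- matrix(0, N, C)
      qkv <- toks %*% proj$qkv_W + matrix(proj$qkv_b, N, 3 * C, byrow = TRUE)
      for (h in seq_len(heads)) {
        cols <- ((h - 1) * d + 1):(h * d)
        Q <- qkv[, cols, drop = FALSE]; K <- qkv[, C + cols, drop = FALSE]
        V <- qkv[, 2 * C + cols, drop = FALSE]
        for (i in seq_len(N)) {
          s <- numeric(N)
          for (j in seq_len(N)) {
            iw <- pick[i] - 1; jw <- pick[j] - 1
            s[j] <- sum(Q[i, ] * K[j, ]) / sqrt(d) +
              proj$bias_table[idx_fun(iw %/% 7, iw %% 7, jw %/% 7, jw %% 7), h]
          }
          p <- exp(s - max(s)); p <- p / sum(p)
          out[i, cols] <- colSums(p * V)
        }
      }
      out <- out %*% proj$proj_W + matrix(proj$proj_b, N, C, byrow = TRUE)
      want[perm1[slots][pick], ] <- out
    }
  }
  expect_lt(max(abs(got - want)), 1e-8)
})

test_that("relative position bias depends only on the token offset", {
  M <- 7
  idx <- resswin:::relpos_index(M)
  pos <- function(i) c((i - 1) %/% M, (i - 1) %% M)
  set.seed(8)
  for (rep in 1:20) {
    i <- sample(49, 1); j <- sample(49, 1)
    di <- pos(i) - pos(j)
    # find another pair with the same offset
    i2 <- sample(49, 1)
    p2 <- pos(i2) - di
    if (any(p2 < 0) || any(p2 > M - 1)) next
    j2 <- p2[1] * M + p2[2] + 1
    expect_equal(idx[i, j], idx[i2, j2])
  }
})

test_that("patch merging halves the grid and doubles the width", {
  set.seed(9)
  g <- token_grid(array(rnorm(8 * 8 * 4), c(8, 8, 4)))
  out <- patch_merging(g)
  expect_equal(c(out$grid_h, out$grid_w, out$dim), c(4L, 4L, 8L))
  expect_error(patch_merging(token_grid(array(0, c(7, 7, 4)))), "even")
  # one merge at width C carries 4C*2C reduction weights + 2*4C norm terms
  m <- build_swin_model(swin_config(img_size = 56), "baseline")
  C <- 96
  expect_equal(length(m$params[["s1.merge.W"]]), 4 * C * 2 * C)
  expect_equal(length(m$params[["s1.merge.ln.g"]]) +
                 length(m$params[["s1.merge.ln.b"]]), 2 * 4 * C)
})

test_that("patch embedding yields the expected token grid", {
  cfg <- swin_config(img_size = 56)
  m <- build_swin_model(cfg, "baseline", seed = 1)
  set.seed(10)
  img <- image_array(array(round(runif(56 * 56 * 3) * 255), c(56, 56, 3)))
  tg <- patch_partition_embed(img, m)
  expect_equal(c(tg$grid_h, tg$grid_w, tg$dim), c(14L, 14L, 96L))
  expect_error(patch_partition_embed(
    image_array(array(0, c(32, 32, 3))), m), "square")
  # stage chain for the full-size configuration: 56 -> 28 -> 14 -> 7 grids
  cfg224 <- swin_config(img_size = 224)
  expect_equal(cfg224$grids, c(56L, 28L, 14L, 7L))
  expect_equal(cfg224$dims, c(96L, 192L, 384L, 768L))
})

test_that("token/spatial relayout is a lossless inverse pair", {
  set.seed(11)
  g <- token_grid(array(rnorm(4 * 4 * 6), c(4, 4, 6)))
  sp <- tokens_to_spatial(g)
  expect_equal(dim(sp), c(6L, 4L, 4L))
  expect_identical(spatial_to_tokens(sp)$values, g$values)
  # spatial neighbors remain neighbors
  expect_equal(sp[2, 1, 3], g$values[1, 3, 2])
})

test_that("attention complexity follows the printed closed forms", {
  H <- W <- 56; C <- 96; M <- 7
  expect_equal(attention_flops(H, W, C, M, windowed = FALSE),
               4 * 56 * 56 * 96^2 + 2 * 3136^2 * 96)
  expect_equal(attention_flops(H, W, C, M, windowed = TRUE),
               4 * 56 * 56 * 96^2 + 2 * 49 * 3136 * 96)
  # windowed is cheaper whenever M^2 < HW
  for (g in c(14, 28, 56)) {
    expect_lt(attention_flops(g, g, 32, 7, TRUE),
              attention_flops(g, g, 32, 7, FALSE))
  }
  expect_equal(attention_flops(7, 7, 768, 7, TRUE),
               attention_flops(7, 7, 768, 7, FALSE))
})

test_that("the complexity formula matches an instruction-counting oracle", {
  # count multiply-accumulates of the implemented computation explicitly:
  # qkv projection (3 maps), per-window QK^T and PV, output projection
  H <- W <- 14; C <- 8; M <- 7
  macs <- 0
  macs <- macs + H * W * C * (3 * C)            # qkv projection
  nwin <- (H / M) * (W / M)
  heads <- 1; d <- C / heads
  for (w in seq_len(nwin)) {
    for (h in seq_len(heads)) {
      macs <- macs + M^2 * M^2 * d              # logits Q K^T
      macs <- macs + M^2 * M^2 * d              # weighted sum P V
    }
  }
  macs <- macs + H * W * C * C                  # output projection
  expect_equal(macs, attention_flops(H, W, C, M, windowed = TRUE))
})

test_that("classification forward is deterministic with consistent shapes", {
  cfg <- tiny_config(28)
  m <- build_swin_model(cfg, "baseline", seed = 3)
  set.seed(12)
  img <- array(round(runif(2 * 28 * 28 * 3) * 255), c(2, 28, 28, 3))
  img[2, , , ] <- img[1, , , ]
  lg <- forward_classify(m, img)
  expect_equal(dim(lg), c(2L, 3L))
  expect_equal(lg[1, ], lg[2, ])               # identical inputs, identical rows
  lg2 <- forward_classify(m, img)
  expect_identical(lg, lg2)                    # no stochastic layers at inference
  expect_error(forward_classify(m, array(0, c(1, 32, 32, 3))), "must be")
})

test_that("configurations with indivisible grids are rejected", {
  expect_error(swin_config(img_size = 225), "divisible")
  expect_error(swin_config(img_size = 64), "not divisible")
  expect_error(swin_config(img_size = 56, heads = c(5, 6, 12, 24)), "heads")
})
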