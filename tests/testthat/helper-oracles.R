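# Independent oracles, written as literal loop nests so they share no code
# with the implementation they check.

# Naive per-pair scaled dot-product attention over a list of windows.
naive_window_attention <- function(windows, proj, masks = NULL) {
  heads <- proj$heads
  C <- ncol(windows[[1]])
  d <- C / heads
  M <- as.integer(sqrt(nrow(windows[[1]])))
  idx <- outer(seq_len(M * M), seq_len(M * M), function(i, j) {
    ri <- (i - 1) %/% M; ci <- (i - 1) %% M
    rj <- (j - 1) %/% M; cj <- (j - 1) %% M
    (ri - rj + M - 1) * (2 * M - 1) + (ci - cj + M - 1) + 1
  })
  lapply(seq_along(windows), function(w) {
    X <- windows[[w]]
    N <- nrow(X)
    qkv <- X %*% proj$qkv_W
    qkv <- qkv + matrix(proj$qkv_b, N, 3 * C, byrow = TRUE)
    out <- matrix(0, N, C)
    for (h in seq_len(heads)) {
      cols <- ((h - 1) * d + 1):(h * d)
      Q <- qkv[, cols, drop = FALSE]
      K <- qkv[, C + cols, drop = FALSE]
      V <- qkv[, 2 * C + cols, drop = FALSE]
      for (i in seq_len(N)) {
        s <- numeric(N)
        for (j in seq_len(N)) {
          s[j] <- sum(Q[i, ] * K[j, ]) / sqrt(d) + proj$bias_table[idx[i, j], h]
          if (!is.null(masks)) s[j] <- s[j] + masks[[w]][i, j]
        }
        p <- exp(s - max(s)); p <- p / sum(p)
        for (j in seq_len(N)) out[i, cols] <- out[i, cols] + p[j] * V[j, cols - (h - 1) * d]
      }
    }
    out %*% proj$proj_W + matrix(proj$proj_b, N, C, byrow = TRUE)
  })
}

# Random attention projection parameters for a given width / head count.
random_attn_proj <- function(C, heads, M, seed = 1) {
  set.seed(seed)
  list(qkv_W = matrix(rnorm(C * 3 * C, sd = 0.2), C, 3 * C),
       qkv_b = rnorm(3 * C, sd = 0.1),
       proj_W = matrix(rnorm(C * C, sd = 0.2), C, C),
       proj_b = rnorm(C, sd = 0.1),
       bias_table = matrix(rnorm((2 * M - 1)^2 * heads, sd = 0.1),
                           (2 * M - 1)^2, heads),
       heads = heads)
}

# Per-sample counting oracle for one-vs-rest classification metrics.
counting_metrics_oracle <- function(y_true, y_pred, k) {
  TP <- FP <- TN <- FN <- 0
  for (i in seq_along(y_true)) {
    pos_pred <- y_pred[i] == k
    pos_true <- y_true[i] == k
    if (pos_pred && pos_true) TP <- TP + 1
    else if (pos_pred && !pos_true) FP <- FP + 1
    else if (!pos_pred && pos_true) FN <- FN + 1
    else TN <- TN + 1
  }
  P <- if (TP + FP > 0) TP / (TP + FP) else 0
  R <- if (TP + FN > 0) TP / (TP + FN) else 0
  S <- if (TN + FP > 0) TN / (TN + FP) else 0
  F1 <- if (P + R > 0) 2 * P * R / (P + R) else 0
  c(P = P, R = R, S = S, F1 = F1)
}

# Tiny backbone configuration for fast end-to-end harness tests.
tiny_config <- function(img = 28) {
  swin_config(img_size = img, patch_size = 4L, embed_dim = 8L,
              depths = c(1L, 1L), heads = c(2L, 4L), window = 7L)
}

# A manifest of n_per_class synthetic images written under dir.
tiny_dataset <- function(dir, n_per_class, image_size, seed = 11,
                         motif_intensity = 1.0) {
  generate_dataset(synth_config(rep(n_per_class, 3), image_size, seed,
                                motif_intensity = motif_intensity),
                   dir, overwrite = TRUE)
}
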