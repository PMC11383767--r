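# Differentiable layer primitives. Every layer is a pair of functions:
# *_fwd returning list(out, cache) and *_bwd taking (d_out, cache) and
# returning gradients. Activations are plain matrices with rows = tokens
# (or pixels) ordered column-fastest within each image, batch slowest;
# columns = channels. All heavy lifting is BLAS matmuls; the only R-level
# loops are over attention windows and the k^2 taps of a convolution.

# -- broadcast helpers (per-column vector applied to every row) --
add_bias <- function(X, b) X + rep(b, each = nrow(X))
scale_cols <- function(X, s) X * rep(s, each = nrow(X))

# ---- linear ----------------------------------------------------------------

linear_fwd <- function(X, W, b = NULL) {
  Y <- X %*% W
  if (!is.null(b)) Y <- add_bias(Y, b)
  list(out = Y, cache = list(X = X, W = W, has_b = !is.null(b)))
}

linear_bwd <- function(dY, cache) {
  list(dX = tcrossprod(dY, cache$W),
       dW = crossprod(cache$X, dY),
       db = if (cache$has_b) colSums(dY) else NULL)
}

# ---- layer norm (normalize each row over channels) ------------------------

layernorm_fwd <- function(X, g, b, eps = 1e-5) {
  mu <- rowMeans(X)
  xc <- X - mu
  v <- rowMeans(xc * xc)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  Y <- scale_cols(xhat, g)
  Y <- add_bias(Y, b)
  list(out = Y, cache = list(xhat = xhat, inv = inv, g = g))
}

layernorm_bwd <- function(dY, cache) {
  xhat <- cache$xhat; inv <- cache$inv
  dg <- colSums(dY * xhat)
  db <- colSums(dY)
  dxhat <- scale_cols(dY, cache$g)
  C <- ncol(dY)
  dX <- inv * (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
  list(dX = dX, dg = dg, db = db)
}

# ---- batch norm (normalize each column over all rows) ---------------------

batchnorm_fwd <- function(X, g, b, run_mean, run_var, training,
                          momentum = 0.1, eps = 1e-5) {
  n <- nrow(X)
  if (training) {
    mu <- colMeans(X)
    xc <- X - rep(mu, each = n)
    v <- colMeans(xc * xc)
    new_mean <- (1 - momentum) * run_mean + momentum * mu
    new_var <- (1 - momentum) * run_var +
      momentum * v * n / max(n - 1, 1)       # running update uses unbiased var
  } else {
    mu <- run_mean; v <- run_var
    xc <- X - rep(mu, each = n)
    new_mean <- run_mean; new_var <- run_var
  }
  inv <- 1 / sqrt(v + eps)
  xhat <- scale_cols(xc, inv)
  Y <- add_bias(scale_cols(xhat, g), b)
  list(out = Y, cache = list(xhat = xhat, inv = inv, g = g, training = training),
       run_mean = new_mean, run_var = new_var)
}

batchnorm_bwd <- function(dY, cache) {
  n <- nrow(dY)
  xhat <- cache$xhat
  dg <- colSums(dY * xhat)
  db <- colSums(dY)
  if (!cache$training) {
    dX <- scale_cols(dY, cache$g * cache$inv)
  } else {
    m_dy <- colMeans(dY)
    m_dyx <- colMeans(dY * xhat)
    dX <- scale_cols(dY - rep(m_dy, each = n) - xhat * rep(m_dyx, each = n),
                     cache$g * cache$inv)
  }
  list(dX = dX, dg = dg, db = db)
}

# ---- activations -----------------------------------------------------------

gelu_fwd <- function(X) {
  Phi <- stats::pnorm(X)
  list(out = X * Phi, cache = list(X = X, Phi = Phi))
}
gelu_bwd <- function(dY, cache) {
  dY * (cache$Phi + cache$X * stats::dnorm(cache$X))
}

relu_fwd <- function(X) list(out = pmax(X, 0), cache = list(pos = X > 0))
relu_bwd <- function(dY, cache) dY * cache$pos

# ---- softmax cross-entropy -------------------------------------------------

softmax_rows <- function(S) {
  m <- S[cbind(seq_len(nrow(S)), max.col(S, ties.method = "first"))]
  E <- exp(S - m)
  E / rowSums(E)
}

# logits: B x K; y: integer class labels in 1..K
softmax_ce_fwd <- function(logits, y) {
  P <- softmax_rows(logits)
  B <- nrow(logits)
  loss <- -mean(log(pmax(P[cbind(seq_len(B), y)], 1e-12)))
  list(loss = loss, probs = P, cache = list(P = P, y = y, B = B))
}
softmax_ce_bwd <- function(cache) {
  dL <- cache$P
  dL[cbind(seq_len(cache$B), cache$y)] <-
    dL[cbind(seq_len(cache$B), cache$y)] - 1
  dL / cache$B
}

# ---- 2-D convolution on the flat (B*H*W) x C layout -----------------------

# Index maps for a k x k same-padded stride-1 convolution on a B-batch of
# H x W planes stored row-ordered (column fastest, then row, then image).
# For each tap offset, idx[p] is the source row feeding output row p, with
# the sentinel n+1 standing for the zero pad (the engine appends a zero row).
conv_geom <- function(H, W, B, k) {
  stopifnot(k %% 2 == 1)
  half <- (k - 1) / 2
  n1 <- H * W
  r <- rep(seq_len(H), each = W)
  c0 <- rep(seq_len(W), times = H)
  boff <- rep((seq_len(B) - 1L) * n1, each = n1)
  n <- B * n1
  idx <- vector("list", k * k)
  t <- 0L
  for (dy in -half:half) for (dx in -half:half) {
    t <- t + 1L
    rr <- r + dy; cc <- c0 + dx
    ok <- rr >= 1L & rr <= H & cc >= 1L & cc <= W
    src1 <- ifelse(ok, (rr - 1L) * W + cc, NA_integer_)
    src <- rep(src1, times = B) + boff
    src[is.na(src)] <- n + 1L
    idx[[t]] <- as.integer(src)
  }
  list(idx = idx, k = k, n = n, H = H, W = W, B = B)
}

# W_mat: (k^2 * C_in) x C_out, tap-major blocks of C_in rows each. The
# im2col matrix is never materialized: the forward/backward loop over the
# k^2 taps, each tap a gathered matmul, keeping memory at O(n * C).
conv2d_fwd <- function(X, W_mat, b, geom) {
  C <- ncol(X)
  Xz <- rbind(X, 0)
  Y <- matrix(rep(b, each = geom$n), geom$n, length(b))
  for (t in seq_along(geom$idx)) {
    Wt <- W_mat[((t - 1L) * C + 1L):(t * C), , drop = FALSE]
    Y <- Y + Xz[geom$idx[[t]], , drop = FALSE] %*% Wt
  }
  list(out = Y, cache = list(X = X, W_mat = W_mat, C = C, geom = geom))
}

conv2d_bwd <- function(dY, cache) {
  geom <- cache$geom; C <- cache$C
  Xz <- rbind(cache$X, 0)
  dW <- matrix(0, nrow(cache$W_mat), ncol(cache$W_mat))
  db <- colSums(dY)
  dX <- matrix(0, geom$n, C)
  for (t in seq_along(geom$idx)) {
    src <- geom$idx[[t]]
    rows <- ((t - 1L) * C + 1L):(t * C)
    dW[rows, ] <- crossprod(Xz[src, , drop = FALSE], dY)
    Wt <- cache$W_mat[rows, , drop = FALSE]
    ok <- src <= geom$n
    dX[src[ok], ] <- dX[src[ok], , drop = FALSE] +
      tcrossprod(dY[ok, , drop = FALSE], Wt)
  }
  list(dX = dX, dW = dW, db = db)
}

# ---- initializers ----------------------------------------------------------

# Normal(0, sd) truncated at +/- 2 sd (the transformer-standard init).
trunc_normal <- function(n, sd = 0.02) {
  lo <- stats::pnorm(-2); hi <- stats::pnorm(2)
  stats::qnorm(stats::runif(n, lo, hi)) * sd
}

# ---- Adam ------------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, st, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  st$t <- st$t + 1L
  bc1 <- 1 - beta1^st$t
  bc2 <- 1 - beta2^st$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * g
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (st$m[[nm]] / bc1) / (sqrt(st$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = st)
}
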