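# Minimal deterministic neural-network engine.
#
# The super-resolution networks under study (ESPCN, SRGAN, the
# transformer-CNN hybrid GAN) are small, CPU-trainable models, implemented on
# a compact engine written directly in R: convolution via im2col + BLAS
# matmul, manual reverse-mode gradients per layer, and Adam. Forward passes
# are pure (they return a cache consumed by the matching backward call), so a
# module can be run several times inside one training step (as GAN updates
# require) without state corruption. All initialization is seeded; training
# is bit-reproducible for a fixed seed and data order.
#
# Tensor layout: single-sample arrays (H, W, C); token matrices (N, D).

nn_module <- function(.kind, .params = list(), ...) {
  e <- new.env(parent = emptyenv())
  e$kind <- .kind
  e$params <- .params
  e$grads <- lapply(.params, function(p) array(0, dim = dim(p) %||% length(p)))
  e$cfg <- list(...)
  e$memo <- list()
  class(e) <- "nn_module"
  e
}

he_init <- function(dims, fan_in, seed) {
  with_seed(seed, array(stats::rnorm(prod(dims), 0, sqrt(2 / fan_in)), dim = dims))
}

# ---- layer constructors ------------------------------------------------

nn_conv <- function(in_ch, out_ch, k = 3L, seed = 1L, init_scale = 1) {
  stopifnot(k %% 2 == 1)
  W <- he_init(c(k, k, in_ch, out_ch), k * k * in_ch, seed) * init_scale
  nn_module("conv", .params = list(W = W, b = numeric(out_ch)),
            k = as.integer(k), in_ch = in_ch, out_ch = out_ch)
}

nn_act <- function(type = c("relu", "lrelu", "tanh", "sigmoid"), alpha = 0.2) {
  nn_module("act", type = match.arg(type), alpha = alpha)
}

nn_pshuffle <- function(r) nn_module("pshuffle", r = as.integer(r))
nn_pool2 <- function() nn_module("pool2")
nn_up2 <- function() nn_module("up2")

nn_linear <- function(in_d, out_d, seed = 1L) {
  W <- he_init(c(in_d, out_d), in_d, seed)
  nn_module("linear", .params = list(W = W, b = numeric(out_d)))
}

nn_lnorm <- function(d) {
  nn_module("lnorm", .params = list(gamma = rep(1, d), beta = rep(0, d)))
}

nn_attn <- function(d, heads, seed = 1L) {
  stopifnot(d %% heads == 0)
  mk <- function(tag) he_init(c(d, d), d, derive_seed(seed, tag)) / sqrt(2)
  nn_module("attn", .params = list(Wq = mk("q"), Wk = mk("k"),
                                   Wv = mk("v"), Wo = mk("o")),
            heads = as.integer(heads))
}

nn_gap_linear <- function(in_ch, seed = 1L) {
  W <- he_init(c(in_ch, 1), in_ch, seed)
  nn_module("gap_linear", .params = list(W = W, b = 0))
}

nn_patchify <- function(p) nn_module("patchify", p = as.integer(p))
nn_unpatchify <- function(p) nn_module("unpatchify", p = as.integer(p))
nn_posenc <- function() nn_module("posenc")

nn_seq <- function(...) {
  mods <- list(...)
  if (length(mods) == 1 && is.list(mods[[1]]) && !inherits(mods[[1]], "nn_module"))
    mods <- mods[[1]]
  nn_module("seq", children = mods)
}

# residual container: y = x + f(x)
nn_res <- function(...) {
  m <- nn_seq(...)
  nn_module("res", children = m$cfg$children)
}

# transformer block: x + attn(ln1(x)), then + mlp(ln2(.))
nn_tblock <- function(d, heads, seed = 1L) {
  nn_module("tblock",
            ln1 = nn_lnorm(d), at = nn_attn(d, heads, derive_seed(seed, "at")),
            ln2 = nn_lnorm(d),
            mlp = nn_seq(nn_linear(d, 2 * d, derive_seed(seed, "m1")),
                         nn_act("relu"),
                         nn_linear(2 * d, d, derive_seed(seed, "m2"))))
}

# ---- im2col machinery --------------------------------------------------

conv_index <- function(mod, H, W, C, k) {
  key <- paste(H, W, C, k, sep = "x")
  if (!is.null(mod$memo[[key]])) return(mod$memo[[key]])
  pad <- (k - 1L) %/% 2L
  Hp <- H + 2L * pad; Wp <- W + 2L * pad
  tap <- expand.grid(di = 0:(k - 1), dj = 0:(k - 1), c = 0:(C - 1))
  tap_lin <- tap$di + tap$dj * Hp + tap$c * Hp * Wp         # offsets, 0-based
  pos <- expand.grid(pi = seq_len(H), pj = seq_len(W))
  pos_lin <- pos$pi + (pos$pj - 1) * Hp                     # 1-based anchor
  idx <- outer(tap_lin, pos_lin, `+`)                       # (k*k*C, H*W)
  info <- list(idx = idx, Hp = Hp, Wp = Wp, pad = pad)
  mod$memo[[key]] <- info
  info
}

# ---- forward -----------------------------------------------------------

nn_forward <- function(mod, x) {
  switch(mod$kind,
    conv = {
      d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]
      k <- mod$cfg$k
      ci <- conv_index(mod, H, W, C, k)
      xp <- array(0, c(ci$Hp, ci$Wp, C))
      xp[ci$pad + seq_len(H), ci$pad + seq_len(W), ] <- x
      cols <- xp[ci$idx]
      dim(cols) <- dim(ci$idx)
      Wm <- matrix(mod$params$W, nrow = k * k * C)
      y <- crossprod(Wm, cols) + mod$params$b                # (out_ch, H*W)
      ya <- array(t(y), c(H, W, mod$cfg$out_ch))
      list(y = ya, cache = list(cols = cols, ci = ci, H = H, W = W, C = C))
    },
    act = {
      y <- switch(mod$cfg$type,
                  relu = pmax(x, 0),
                  lrelu = ifelse(x > 0, x, mod$cfg$alpha * x),
                  tanh = tanh(x),
                  sigmoid = 1 / (1 + exp(-x)))
      list(y = y, cache = list(x = x, y = y))
    },
    pshuffle = {
      list(y = pixel_shuffle(x, mod$cfg$r), cache = dim(x))
    },
    pool2 = {
      d <- dim(x)
      stopifnot(d[1] %% 2 == 0, d[2] %% 2 == 0)
      y <- (x[seq(1, d[1], 2), seq(1, d[2], 2), , drop = FALSE] +
            x[seq(2, d[1], 2), seq(1, d[2], 2), , drop = FALSE] +
            x[seq(1, d[1], 2), seq(2, d[2], 2), , drop = FALSE] +
            x[seq(2, d[1], 2), seq(2, d[2], 2), , drop = FALSE]) / 4
      list(y = y, cache = d)
    },
    up2 = {
      d <- dim(x)
      y <- x[rep(seq_len(d[1]), each = 2), rep(seq_len(d[2]), each = 2), , drop = FALSE]
      list(y = y, cache = d)
    },
    linear = {
      list(y = x %*% mod$params$W + matrix(mod$params$b, nrow(x),
                                           length(mod$params$b), byrow = TRUE),
           cache = list(x = x))
    },
    lnorm = {
      mu <- rowMeans(x)
      xc <- x - mu
      v <- rowMeans(xc^2)
      istd <- 1 / sqrt(v + 1e-5)
      xhat <- xc * istd
      y <- xhat * matrix(mod$params$gamma, nrow(x), ncol(x), byrow = TRUE) +
        matrix(mod$params$beta, nrow(x), ncol(x), byrow = TRUE)
      list(y = y, cache = list(xhat = xhat, istd = istd))
    },
    attn = {
      h <- mod$cfg$heads; D <- ncol(x); Dh <- D %/% h
      Q <- x %*% mod$params$Wq; K <- x %*% mod$params$Wk; V <- x %*% mod$params$Wv
      heads <- vector("list", h)
      O <- matrix(0, nrow(x), D)
      for (i in seq_len(h)) {
        sl <- ((i - 1) * Dh + 1):(i * Dh)
        S <- (Q[, sl, drop = FALSE] %*% t(K[, sl, drop = FALSE])) / sqrt(Dh)
        S <- S - apply(S, 1, max)
        A <- exp(S); A <- A / rowSums(A)
        O[, sl] <- A %*% V[, sl, drop = FALSE]
        heads[[i]] <- A
      }
      y <- O %*% mod$params$Wo
      list(y = y, cache = list(x = x, Q = Q, K = K, V = V, A = heads, O = O))
    },
    gap_linear = {
      d <- dim(x)
      g <- apply(x, 3, mean)                                 # (C)
      y <- sum(g * mod$params$W) + mod$params$b
      list(y = y, cache = list(g = g, d = d))
    },
    patchify = {
      p <- mod$cfg$p; d <- dim(x)
      stopifnot(d[1] %% p == 0, d[2] %% p == 0, d[3] == 1)
      ni <- d[1] %/% p; nj <- d[2] %/% p
      toks <- matrix(0, ni * nj, p * p)
      t <- 0L
      for (j in seq_len(nj)) for (i in seq_len(ni)) {
        t <- t + 1L
        toks[t, ] <- x[((i - 1) * p + 1):(i * p), ((j - 1) * p + 1):(j * p), 1]
      }
      list(y = toks, cache = list(d = d, ni = ni, nj = nj))
    },
    unpatchify = {
      p <- mod$cfg$p
      n <- nrow(x)
      side_tokens <- as.integer(round(sqrt(n)))
      stopifnot(side_tokens^2 == n, ncol(x) == p * p)
      img <- array(0, c(side_tokens * p, side_tokens * p, 1))
      t <- 0L
      for (j in seq_len(side_tokens)) for (i in seq_len(side_tokens)) {
        t <- t + 1L
        img[((i - 1) * p + 1):(i * p), ((j - 1) * p + 1):(j * p), 1] <- x[t, ]
      }
      list(y = img, cache = list(n = n))
    },
    posenc = {
      # fixed sinusoidal positional encoding added to token embeddings
      N <- nrow(x); D <- ncol(x)
      pos <- matrix(0, N, D)
      for (d2 in seq_len(D)) {
        f <- 1 / (10000^((d2 - 1) %/% 2 * 2 / D))
        pos[, d2] <- if (d2 %% 2 == 1) sin(seq_len(N) * f) else cos(seq_len(N) * f)
      }
      list(y = x + pos, cache = NULL)
    },
    seq = {
      caches <- vector("list", length(mod$cfg$children))
      h <- x
      for (i in seq_along(mod$cfg$children)) {
        fw <- nn_forward(mod$cfg$children[[i]], h)
        h <- fw$y
        caches[[i]] <- fw$cache
      }
      list(y = h, cache = caches)
    },
    res = {
      caches <- vector("list", length(mod$cfg$children))
      h <- x
      for (i in seq_along(mod$cfg$children)) {
        fw <- nn_forward(mod$cfg$children[[i]], h)
        h <- fw$y
        caches[[i]] <- fw$cache
      }
      list(y = x + h, cache = caches)
    },
    tblock = {
      f1 <- nn_forward(mod$cfg$ln1, x)
      fa <- nn_forward(mod$cfg$at, f1$y)
      x2 <- x + fa$y
      f2 <- nn_forward(mod$cfg$ln2, x2)
      fm <- nn_forward(mod$cfg$mlp, f2$y)
      list(y = x2 + fm$y, cache = list(f1 = f1$cache, fa = fa$cache,
                                       f2 = f2$cache, fm = fm$cache))
    },
    stopf("unknown module kind '%s'", mod$kind))
}

# ---- backward ----------------------------------------------------------

nn_backward <- function(mod, cache, dy, acc = TRUE) {
  switch(mod$kind,
    conv = {
      k <- mod$cfg$k; C <- cache$C
      H <- cache$H; W <- cache$W
      dym <- t(matrix(dy, H * W, mod$cfg$out_ch))             # (out, H*W)
      Wm <- matrix(mod$params$W, nrow = k * k * C)
      if (acc) {
        dW <- cache$cols %*% t(dym)
        mod$grads$W <- mod$grads$W + array(dW, dim(mod$params$W))
        mod$grads$b <- mod$grads$b + rowSums(dym)
      }
      dcols <- Wm %*% dym
      ci <- cache$ci
      dxp <- numeric(ci$Hp * ci$Wp * C)
      acc_v <- rowsum(as.vector(dcols), group = as.vector(ci$idx))
      dxp[as.integer(rownames(acc_v))] <- acc_v
      dxp <- array(dxp, c(ci$Hp, ci$Wp, C))
      dxp[ci$pad + seq_len(H), ci$pad + seq_len(W), , drop = FALSE]
    },
    act = {
      switch(mod$cfg$type,
             relu = dy * (cache$x > 0),
             lrelu = dy * ifelse(cache$x > 0, 1, mod$cfg$alpha),
             tanh = dy * (1 - cache$y^2),
             sigmoid = dy * cache$y * (1 - cache$y))
    },
    pshuffle = pixel_unshuffle(dy, mod$cfg$r),
    pool2 = {
      d <- cache
      g <- dy[rep(seq_len(d[1] %/% 2), each = 2),
              rep(seq_len(d[2] %/% 2), each = 2), , drop = FALSE] / 4
      g
    },
    up2 = {
      d <- cache
      (dy[seq(1, 2 * d[1], 2), seq(1, 2 * d[2], 2), , drop = FALSE] +
       dy[seq(2, 2 * d[1], 2), seq(1, 2 * d[2], 2), , drop = FALSE] +
       dy[seq(1, 2 * d[1], 2), seq(2, 2 * d[2], 2), , drop = FALSE] +
       dy[seq(2, 2 * d[1], 2), seq(2, 2 * d[2], 2), , drop = FALSE])
    },
    linear = {
      if (acc) {
        mod$grads$W <- mod$grads$W + crossprod(cache$x, dy)
        mod$grads$b <- mod$grads$b + colSums(dy)
      }
      dy %*% t(mod$params$W)
    },
    lnorm = {
      xhat <- cache$xhat; istd <- cache$istd
      D <- ncol(xhat)
      gam <- matrix(mod$params$gamma, nrow(xhat), D, byrow = TRUE)
      if (acc) {
        mod$grads$gamma <- mod$grads$gamma + colSums(dy * xhat)
        mod$grads$beta <- mod$grads$beta + colSums(dy)
      }
      dxhat <- dy * gam
      (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat)) * istd
    },
    attn = {
      h <- mod$cfg$heads; D <- ncol(cache$x); Dh <- D %/% h
      x <- cache$x
      dO <- dy %*% t(mod$params$Wo)
      if (acc) mod$grads$Wo <- mod$grads$Wo + crossprod(cache$O, dy)
      dQ <- matrix(0, nrow(x), D); dK <- dQ; dV <- dQ
      for (i in seq_len(h)) {
        sl <- ((i - 1) * Dh + 1):(i * Dh)
        A <- cache$A[[i]]
        dOh <- dO[, sl, drop = FALSE]
        dA <- dOh %*% t(cache$V[, sl, drop = FALSE])
        dV[, sl] <- t(A) %*% dOh
        dS <- A * (dA - rowSums(dA * A))
        dS <- dS / sqrt(Dh)
        dQ[, sl] <- dS %*% cache$K[, sl, drop = FALSE]
        dK[, sl] <- t(dS) %*% cache$Q[, sl, drop = FALSE]
      }
      if (acc) {
        mod$grads$Wq <- mod$grads$Wq + crossprod(x, dQ)
        mod$grads$Wk <- mod$grads$Wk + crossprod(x, dK)
        mod$grads$Wv <- mod$grads$Wv + crossprod(x, dV)
      }
      dQ %*% t(mod$params$Wq) + dK %*% t(mod$params$Wk) + dV %*% t(mod$params$Wv)
    },
    gap_linear = {
      d <- cache$d
      if (acc) {
        mod$grads$W <- mod$grads$W + matrix(cache$g * dy, ncol = 1)
        mod$grads$b <- mod$grads$b + dy
      }
      per_ch <- as.numeric(mod$params$W) * dy / (d[1] * d[2])
      array(rep(per_ch, each = d[1] * d[2]), d)
    },
    patchify = {
      p <- mod$cfg$p; d <- cache$d
      g <- array(0, d)
      t <- 0L
      for (j in seq_len(cache$nj)) for (i in seq_len(cache$ni)) {
        t <- t + 1L
        g[((i - 1) * p + 1):(i * p), ((j - 1) * p + 1):(j * p), 1] <- dy[t, ]
      }
      g
    },
    unpatchify = {
      p <- mod$cfg$p
      n <- cache$n
      side <- as.integer(round(sqrt(n)))
      g <- matrix(0, n, p * p)
      t <- 0L
      for (j in seq_len(side)) for (i in seq_len(side)) {
        t <- t + 1L
        g[t, ] <- dy[((i - 1) * p + 1):(i * p), ((j - 1) * p + 1):(j * p), 1]
      }
      g
    },
    posenc = dy,
    seq = {
      g <- dy
      for (i in rev(seq_along(mod$cfg$children)))
        g <- nn_backward(mod$cfg$children[[i]], cache[[i]], g, acc)
      g
    },
    res = {
      g <- dy
      for (i in rev(seq_along(mod$cfg$children)))
        g <- nn_backward(mod$cfg$children[[i]], cache[[i]], g, acc)
      g + dy
    },
    tblock = {
      dx2 <- dy + {
        g <- nn_backward(mod$cfg$mlp, cache$fm, dy, acc)
        nn_backward(mod$cfg$ln2, cache$f2, g, acc)
      }
      dx <- dx2 + {
        g <- nn_backward(mod$cfg$at, cache$fa, dx2, acc)
        nn_backward(mod$cfg$ln1, cache$f1, g, acc)
      }
      dx
    },
    stopf("unknown module kind '%s'", mod$kind))
}

# ---- parameter bookkeeping and Adam ------------------------------------

nn_leaves <- function(mod) {
  out <- list()
  if (length(mod$params)) out <- list(mod)
  kids <- mod$cfg$children
  if (!is.null(kids)) for (k in kids) out <- c(out, nn_leaves(k))
  for (nm in c("ln1", "at", "ln2", "mlp"))
    if (!is.null(mod$cfg[[nm]])) out <- c(out, nn_leaves(mod$cfg[[nm]]))
  out
}

nn_zero_grads <- function(mod) {
  for (m in nn_leaves(mod))
    m$grads <- lapply(m$params, function(p) array(0, dim = dim(p) %||% length(p)))
  invisible(NULL)
}

nn_adam_step <- function(mod, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                         eps = 1e-8, t = 1) {
  for (m in nn_leaves(mod)) {
    if (is.null(m$adam_m)) {
      m$adam_m <- lapply(m$params, function(p) array(0, dim = dim(p) %||% length(p)))
      m$adam_v <- m$adam_m
    }
    for (nm in names(m$params)) {
      g <- m$grads[[nm]]
      m$adam_m[[nm]] <- beta1 * m$adam_m[[nm]] + (1 - beta1) * g
      m$adam_v[[nm]] <- beta2 * m$adam_v[[nm]] + (1 - beta2) * g^2
      mhat <- m$adam_m[[nm]] / (1 - beta1^t)
      vhat <- m$adam_v[[nm]] / (1 - beta2^t)
      upd <- lr * mhat / (sqrt(vhat) + eps)
      p <- m$params[[nm]] - upd
      dim(p) <- dim(m$params[[nm]])
      m$params[[nm]] <- p
    }
  }
  invisible(NULL)
}

# flat numeric vector of all parameters (for determinism checks / serialization)
nn_param_vector <- function(mod) {
  unlist(lapply(nn_leaves(mod), function(m) lapply(m$params, as.numeric)),
         use.names = FALSE)
}

nn_set_param_vector <- function(mod, v) {
  pos <- 1L
  for (m in nn_leaves(mod)) for (nm in names(m$params)) {
    n <- length(m$params[[nm]])
    p <- v[pos:(pos + n - 1)]
    dim(p) <- dim(m$params[[nm]])
    m$params[[nm]] <- p
    pos <- pos + n
  }
  invisible(NULL)
}

#' Pixel shuffle (sub-pixel rearrangement)
#'
#' Rearranges an `(H, W, C*r^2)` feature array into `(r*H, r*W, C)` by the
#' standard sub-pixel layout: channel block `(c-1)*r^2 + (dy-1)*r + dx` fills
#' output position `(r*(i-1)+dy, r*(j-1)+dx, c)`. Bijective; the exact inverse
#' is [pixel_unshuffle()].
#'
#' @param x Numeric array `(H, W, C*r^2)` (a matrix is treated as `C*r^2 = 1`).
#' @param r Positive integer upscaling factor.
#' @return Numeric array `(r*H, r*W, C)`.
#' @export
pixel_shuffle <- function(x, r) {
  r <- as.integer(r)
  if (r < 1) stopf("r must be a positive integer")
  if (is.matrix(x)) x <- array(x, c(dim(x), 1L))
  d <- dim(x)
  if (d[3] %% (r^2) != 0)
    stopf("channel count %d not divisible by r^2 = %d", d[3], r^2)
  if (r == 1) return(x)
  C <- d[3] %/% (r^2)
  out <- array(0, c(d[1] * r, d[2] * r, C))
  for (c0 in seq_len(C)) for (dy2 in seq_len(r)) for (dx2 in seq_len(r)) {
    ch <- (c0 - 1) * r^2 + (dy2 - 1) * r + dx2
    out[seq(dy2, d[1] * r, r), seq(dx2, d[2] * r, r), c0] <- x[, , ch]
  }
  out
}

#' Inverse pixel shuffle
#'
#' Exact inverse of [pixel_shuffle()]: folds an `(r*H, r*W, C)` array back
#' into `(H, W, C*r^2)`.
#'
#' @inheritParams pixel_shuffle
#' @return Numeric array `(H/r, W/r, C*r^2)`.
#' @export
pixel_unshuffle <- function(x, r) {
  r <- as.integer(r)
  if (r < 1) stopf("r must be a positive integer")
  if (is.matrix(x)) x <- array(x, c(dim(x), 1L))
  d <- dim(x)
  if (d[1] %% r != 0 || d[2] %% r != 0)
    stopf("spatial dims must be divisible by r")
  if (r == 1) return(x)
  out <- array(0, c(d[1] %/% r, d[2] %/% r, d[3] * r^2))
  for (c0 in seq_len(d[3])) for (dy2 in seq_len(r)) for (dx2 in seq_len(r)) {
    ch <- (c0 - 1) * r^2 + (dy2 - 1) * r + dx2
    out[, , ch] <- x[seq(dy2, d[1], r), seq(dx2, d[2], r), c0]
  }
  out
}
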