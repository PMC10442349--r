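# Minimal neural-network engine: layers with explicit matrix-based forward
# and backward passes, SGD with momentum and weight decay.  Activations are
# stored as (H, W, C, N) arrays in the convolutional domain and (N, D)
# matrices in the vector domain; vision-transformer blocks use token
# matrices of shape (T*N, D) with tokens ordered fastest.
#
# All layers are environments (mutable parameter/gradient/momentum slots);
# nn_forward() caches what the matching nn_backward() needs.

new_layer <- function(type, ...) {
  e <- new.env(parent = emptyenv())
  e$type <- type
  fields <- list(...)
  for (nm in names(fields)) assign(nm, fields[[nm]], envir = e)
  e$params <- e$params %||% list()
  e$grads <- list()
  e$vel <- list()
  class(e) <- c(paste0("nn_", type), "nn_layer")
  e
}

he_init <- function(n_in, dims) {
  array(rnorm(prod(dims), sd = sqrt(2 / n_in)), dim = dims)
}

# ------------------------------------------------------------------- conv2d

nn_conv2d <- function(in_ch, out_ch, kernel = 3L, stride = 1L, pad = 1L) {
  K <- kernel * kernel * in_ch
  new_layer("conv2d",
    in_ch = in_ch, out_ch = out_ch, kernel = as.integer(kernel),
    stride = as.integer(stride), pad = as.integer(pad),
    params = list(W = he_init(K, c(K, out_ch)), b = numeric(out_ch)),
    idx_cache = NULL
  )
}

conv_geometry <- function(layer, H, W) {
  k <- layer$kernel; s <- layer$stride; p <- layer$pad
  Hp <- H + 2L * p; Wp <- W + 2L * p
  Ho <- (Hp - k) %/% s + 1L
  Wo <- (Wp - k) %/% s + 1L
  list(Hp = Hp, Wp = Wp, Ho = Ho, Wo = Wo)
}

# Index matrix (P x K) into a flattened (Hp, Wp, C) image; row p = output
# position (ho fastest), column k = kernel element (kh fastest, kw, then c).
conv_idxmat <- function(layer, H, W) {
  key <- paste(H, W, sep = "x")
  cached <- layer$idx_cache
  if (!is.null(cached) && identical(cached$key, key)) return(cached)
  g <- conv_geometry(layer, H, W)
  k <- layer$kernel; s <- layer$stride; C <- layer$in_ch
  ho <- rep(seq_len(g$Ho), times = g$Wo)
  wo <- rep(seq_len(g$Wo), each = g$Ho)
  kh <- rep(seq_len(k), times = k * C)
  kw <- rep(rep(seq_len(k), each = k), times = C)
  kc <- rep(seq_len(C), each = k * k)
  h <- outer((ho - 1L) * s, kh, `+`) # P x K
  w <- outer((wo - 1L) * s, kw, `+`)
  cmat <- matrix(kc, nrow = length(ho), ncol = length(kh), byrow = TRUE)
  idx <- h + g$Hp * (w - 1L) + g$Hp * g$Wp * (cmat - 1L)
  out <- list(key = key, idx = idx, geom = g)
  layer$idx_cache <- out
  out
}

pad_input <- function(x, p) {
  if (p == 0L) return(x)
  d <- dim(x)
  out <- array(0, c(d[1] + 2L * p, d[2] + 2L * p, d[3], d[4]))
  out[(p + 1L):(p + d[1]), (p + 1L):(p + d[2]), , ] <- x
  out
}

nn_forward.nn_conv2d <- function(layer, x, train = FALSE) {
  d <- dim(x)
  stopifnot(length(d) == 4L, d[3] == layer$in_ch)
  ic <- conv_idxmat(layer, d[1], d[2])
  g <- ic$geom
  N <- d[4]
  P <- g$Ho * g$Wo
  K <- nrow(layer$params$W)
  xp <- pad_input(x, layer$pad)
  dim(xp) <- c(g$Hp * g$Wp * layer$in_ch, N)
  col <- xp[as.vector(ic$idx), , drop = FALSE] # (P*K) x N
  M <- matrix(aperm(array(col, c(P, K, N)), c(1L, 3L, 2L)), P * N, K)
  out <- M %*% layer$params$W
  out <- sweep(out, 2L, layer$params$b, `+`)
  if (train) layer$cache <- list(M = M, in_dim = d, geom = g, idx = ic$idx, P = P, K = K)
  aperm(array(out, c(g$Ho, g$Wo, N, layer$out_ch)), c(1L, 2L, 4L, 3L))
}

nn_backward.nn_conv2d <- function(layer, gy) {
  cc <- layer$cache
  g <- cc$geom; d <- cc$in_dim
  N <- d[4]; P <- cc$P; K <- cc$K
  G <- matrix(aperm(gy, c(1L, 2L, 4L, 3L)), P * N, layer$out_ch)
  acc_grad(layer, "W", crossprod(cc$M, G))
  acc_grad(layer, "b", colSums(G))
  dM <- G %*% t(layer$params$W) # (P*N) x K
  dM <- array(dM, c(P, N, K))
  dQ <- matrix(0, g$Hp * g$Wp * layer$in_ch, N)
  for (k in seq_len(K)) {
    rows <- cc$idx[, k]
    dQ[rows, ] <- dQ[rows, ] + dM[, , k]
  }
  dxp <- array(dQ, c(g$Hp, g$Wp, layer$in_ch, N))
  p <- layer$pad
  layer$cache <- NULL
  if (p == 0L) dxp else dxp[(p + 1L):(p + d[1]), (p + 1L):(p + d[2]), , , drop = FALSE]
}

# --------------------------------------------------------------- activations

nn_relu <- function() new_layer("relu")

nn_forward.nn_relu <- function(layer, x, train = FALSE) {
  if (train) layer$cache <- x > 0
  x * (x > 0)
}

nn_backward.nn_relu <- function(layer, gy) {
  out <- gy * layer$cache
  layer$cache <- NULL
  out
}

nn_gelu <- function() new_layer("gelu")

gelu_fun <- function(x) x * stats::pnorm(x)
gelu_grad <- function(x) stats::pnorm(x) + x * stats::dnorm(x)

nn_forward.nn_gelu <- function(layer, x, train = FALSE) {
  if (train) layer$cache <- x
  gelu_fun(x)
}

nn_backward.nn_gelu <- function(layer, gy) {
  out <- gy * gelu_grad(layer$cache)
  layer$cache <- NULL
  out
}

# ------------------------------------------------------------------- pooling

nn_avg_pool <- function(factor = 2L) new_layer("avg_pool", factor = as.integer(factor))

nn_forward.nn_avg_pool <- function(layer, x, train = FALSE) {
  f <- layer$factor
  d <- dim(x)
  Ho <- d[1] %/% f; Wo <- d[2] %/% f
  out <- array(0, c(Ho, Wo, d[3], d[4]))
  ri <- seq_len(Ho) * f - f
  ci <- seq_len(Wo) * f - f
  for (i in seq_len(f)) {
    for (j in seq_len(f)) {
      out <- out + x[ri + i, ci + j, , , drop = FALSE]
    }
  }
  if (train) layer$cache <- d
  out / (f * f)
}

nn_backward.nn_avg_pool <- function(layer, gy) {
  f <- layer$factor
  d <- layer$cache
  layer$cache <- NULL
  gx <- array(0, d)
  Ho <- dim(gy)[1]; Wo <- dim(gy)[2]
  ri <- seq_len(Ho) * f - f
  ci <- seq_len(Wo) * f - f
  share <- gy / (f * f)
  for (i in seq_len(f)) {
    for (j in seq_len(f)) {
      gx[ri + i, ci + j, , ] <- share
    }
  }
  gx
}

nn_global_avg_pool <- function() new_layer("global_avg_pool")

nn_forward.nn_global_avg_pool <- function(layer, x, train = FALSE) {
  d <- dim(x)
  if (train) layer$cache <- d
  cm <- colMeans(matrix(x, d[1] * d[2], d[3] * d[4])) # length C*N
  t(matrix(cm, d[3], d[4])) # N x C
}

nn_backward.nn_global_avg_pool <- function(layer, gy) {
  d <- layer$cache
  layer$cache <- NULL
  per_px <- t(gy) / (d[1] * d[2]) # C x N
  array(rep(as.vector(per_px), each = d[1] * d[2]), d)
}

nn_flatten <- function() new_layer("flatten")

nn_forward.nn_flatten <- function(layer, x, train = FALSE) {
  d <- dim(x)
  if (train) layer$cache <- d
  t(matrix(x, prod(d[1:3]), d[4]))
}

nn_backward.nn_flatten <- function(layer, gy) {
  d <- layer$cache
  layer$cache <- NULL
  array(t(gy), d)
}

# --------------------------------------------------------------------- dense

nn_dense <- function(n_in, n_out, init_sd = NULL) {
  W <- if (is.null(init_sd)) {
    he_init(n_in, c(n_in, n_out))
  } else {
    array(rnorm(n_in * n_out, sd = init_sd), c(n_in, n_out))
  }
  new_layer("dense", n_in = n_in, n_out = n_out, params = list(W = W, b = numeric(n_out)))
}

nn_forward.nn_dense <- function(layer, x, train = FALSE) {
  if (train) layer$cache <- x
  sweep(x %*% layer$params$W, 2L, layer$params$b, `+`)
}

nn_backward.nn_dense <- function(layer, gy) {
  acc_grad(layer, "W", crossprod(layer$cache, gy))
  acc_grad(layer, "b", colSums(gy))
  out <- gy %*% t(layer$params$W)
  layer$cache <- NULL
  out
}

# ---------------------------------------------------------------- layer norm

nn_layer_norm <- function(dim, eps = 1e-5) {
  new_layer("layer_norm",
    dim = dim, eps = eps,
    params = list(g = rep(1, dim), b = numeric(dim))
  )
}

nn_forward.nn_layer_norm <- function(layer, x, train = FALSE) {
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc * xc)
  inv <- 1 / sqrt(v + layer$eps)
  xn <- xc * inv
  if (train) layer$cache <- list(xn = xn, inv = inv)
  sweep(xn * rep(layer$params$g, each = nrow(x)), 2L, layer$params$b, `+`)
}

nn_backward.nn_layer_norm <- function(layer, gy) {
  cc <- layer$cache
  layer$cache <- NULL
  D <- layer$dim
  acc_grad(layer, "g", colSums(gy * cc$xn))
  acc_grad(layer, "b", colSums(gy))
  gxn <- gy * rep(layer$params$g, each = nrow(gy))
  # d/dx of (x - mu) * inv with inv = (var + eps)^(-1/2)
  (gxn - rowMeans(gxn) - cc$xn * rowMeans(gxn * cc$xn)) * cc$inv
}

# ---------------------------------------------------- multi-head attention
# Tokens as a (T*N) x D matrix, token index fastest.  Self-attention within
# each image; heads split D into n_heads blocks of d_k columns.

nn_attention <- function(dim, n_heads) {
  stopifnot(dim %% n_heads == 0L)
  new_layer("attention",
    dim = dim, n_heads = n_heads, d_k = dim %/% n_heads,
    params = list(
      Wq = he_init(dim, c(dim, dim)), Wk = he_init(dim, c(dim, dim)),
      Wv = he_init(dim, c(dim, dim)), Wo = he_init(dim, c(dim, dim))
    )
  )
}

nn_forward.nn_attention <- function(layer, x, train = FALSE) {
  n_tok <- attr(x, "n_tokens")
  stopifnot(!is.null(n_tok))
  N <- nrow(x) %/% n_tok
  D <- layer$dim; H <- layer$n_heads; dk <- layer$d_k
  Q <- x %*% layer$params$Wq
  K <- x %*% layer$params$Wk
  V <- x %*% layer$params$Wv
  O <- matrix(0, nrow(x), D)
  A_all <- if (train) vector("list", N * H)
  for (n in seq_len(N)) {
    rows <- ((n - 1L) * n_tok + 1L):(n * n_tok)
    for (h in seq_len(H)) {
      cols <- ((h - 1L) * dk + 1L):(h * dk)
      S <- Q[rows, cols, drop = FALSE] %*% t(K[rows, cols, drop = FALSE]) / sqrt(dk)
      S <- S - apply(S, 1L, max)
      A <- exp(S)
      A <- A / rowSums(A)
      O[rows, cols] <- A %*% V[rows, cols, drop = FALSE]
      if (train) A_all[[(n - 1L) * H + h]] <- A
    }
  }
  out <- O %*% layer$params$Wo
  if (train) layer$cache <- list(x = x, Q = Q, K = K, V = V, O = O, A = A_all, n_tok = n_tok, N = N)
  attr(out, "n_tokens") <- n_tok
  out
}

nn_backward.nn_attention <- function(layer, gy) {
  cc <- layer$cache
  layer$cache <- NULL
  D <- layer$dim; H <- layer$n_heads; dk <- layer$d_k
  n_tok <- cc$n_tok; N <- cc$N
  acc_grad(layer, "Wo", crossprod(cc$O, gy))
  gO <- gy %*% t(layer$params$Wo)
  gQ <- matrix(0, nrow(gy), D)
  gK <- matrix(0, nrow(gy), D)
  gV <- matrix(0, nrow(gy), D)
  for (n in seq_len(N)) {
    rows <- ((n - 1L) * n_tok + 1L):(n * n_tok)
    for (h in seq_len(H)) {
      cols <- ((h - 1L) * dk + 1L):(h * dk)
      A <- cc$A[[(n - 1L) * H + h]]
      gOh <- gO[rows, cols, drop = FALSE]
      Vh <- cc$V[rows, cols, drop = FALSE]
      gA <- gOh %*% t(Vh)
      gV[rows, cols] <- crossprod(A, gOh)
      # softmax backward row-wise: dS = A * (gA - rowSums(gA * A))
      gS <- A * (gA - rowSums(gA * A))
      gS <- gS / sqrt(dk)
      Qh <- cc$Q[rows, cols, drop = FALSE]
      Kh <- cc$K[rows, cols, drop = FALSE]
      gQ[rows, cols] <- gS %*% Kh
      gK[rows, cols] <- crossprod(gS, Qh)
    }
  }
  acc_grad(layer, "Wq", crossprod(cc$x, gQ))
  acc_grad(layer, "Wk", crossprod(cc$x, gK))
  acc_grad(layer, "Wv", crossprod(cc$x, gV))
  out <- gQ %*% t(layer$params$Wq) + gK %*% t(layer$params$Wk) + gV %*% t(layer$params$Wv)
  attr(out, "n_tokens") <- n_tok
  out
}

# ------------------------------------------------------------- patch embed
# Non-overlapping patch projection (conv with kernel = stride = patch) to a
# token matrix, plus a learned positional embedding.

nn_patch_embed <- function(in_ch, dim, patch, img_size) {
  n_tok <- (img_size %/% patch)^2
  new_layer("patch_embed",
    in_ch = in_ch, dim = dim, patch = as.integer(patch),
    conv = nn_conv2d(in_ch, dim, kernel = patch, stride = patch, pad = 0L),
    params = list(pos = array(rnorm(n_tok * dim, sd = 0.02), c(n_tok, dim)))
  )
}

nn_forward.nn_patch_embed <- function(layer, x, train = FALSE) {
  y <- nn_forward(layer$conv, x, train = train) # (Ho, Wo, D, N)
  d <- dim(y)
  n_tok <- d[1] * d[2]
  if (n_tok != nrow(layer$params$pos)) {
    hx_validation_error("patch_embed built for ", nrow(layer$params$pos), " tokens, got ", n_tok)
  }
  tok <- matrix(aperm(y, c(1L, 2L, 4L, 3L)), n_tok * d[4], d[3])
  tok <- tok + kronecker(rep(1, d[4]), layer$params$pos)
  if (train) layer$cache <- list(y_dim = d, n_tok = n_tok)
  attr(tok, "n_tokens") <- n_tok
  tok
}

nn_backward.nn_patch_embed <- function(layer, gy) {
  cc <- layer$cache
  layer$cache <- NULL
  d <- cc$y_dim
  gpos <- matrix(0, cc$n_tok, d[3])
  for (n in seq_len(d[4])) {
    rows <- ((n - 1L) * cc$n_tok + 1L):(n * cc$n_tok)
    gpos <- gpos + gy[rows, , drop = FALSE]
  }
  acc_grad(layer, "pos", gpos)
  gyc <- aperm(array(gy, c(d[1], d[2], d[4], d[3])), c(1L, 2L, 4L, 3L))
  nn_backward(layer$conv, gyc)
}

nn_token_mean <- function() new_layer("token_mean")

nn_forward.nn_token_mean <- function(layer, x, train = FALSE) {
  n_tok <- attr(x, "n_tokens")
  N <- nrow(x) %/% n_tok
  out <- matrix(0, N, ncol(x))
  for (n in seq_len(N)) {
    rows <- ((n - 1L) * n_tok + 1L):(n * n_tok)
    out[n, ] <- colMeans(x[rows, , drop = FALSE])
  }
  if (train) layer$cache <- list(n_tok = n_tok, N = N)
  out
}

nn_backward.nn_token_mean <- function(layer, gy) {
  cc <- layer$cache
  layer$cache <- NULL
  out <- gy[rep(seq_len(cc$N), each = cc$n_tok), , drop = FALSE] / cc$n_tok
  attr(out, "n_tokens") <- cc$n_tok
  out
}

# --------------------------------------------------------------- composites

# Sequential container.
nn_seq <- function(...) new_layer("seq", layers = list(...))

nn_forward.nn_seq <- function(layer, x, train = FALSE) {
  for (l in layer$layers) x <- nn_forward(l, x, train = train)
  x
}

nn_backward.nn_seq <- function(layer, gy) {
  for (l in rev(layer$layers)) gy <- nn_backward(l, gy)
  gy
}

# Residual block: relu(body(x) + shortcut(x)); shortcut defaults to identity.
nn_residual <- function(body, shortcut = NULL) {
  new_layer("residual", body = body, shortcut = shortcut)
}

nn_forward.nn_residual <- function(layer, x, train = FALSE) {
  y <- nn_forward(layer$body, x, train = train)
  s <- if (is.null(layer$shortcut)) x else nn_forward(layer$shortcut, x, train = train)
  z <- y + s
  if (train) layer$cache <- z > 0
  z * (z > 0)
}

nn_backward.nn_residual <- function(layer, gy) {
  gz <- gy * layer$cache
  layer$cache <- NULL
  gx <- nn_backward(layer$body, gz)
  gs <- if (is.null(layer$shortcut)) gz else nn_backward(layer$shortcut, gz)
  gx + gs
}

# Residual sum without the trailing nonlinearity (transformer style).
nn_residual_add <- function(body) new_layer("residual_add", body = body)

nn_forward.nn_residual_add <- function(layer, x, train = FALSE) {
  y <- nn_forward(layer$body, x, train = train)
  out <- x + y
  attr(out, "n_tokens") <- attr(x, "n_tokens") %||% attr(y, "n_tokens")
  out
}

nn_backward.nn_residual_add <- function(layer, gy) {
  gx <- nn_backward(layer$body, gy)
  out <- gx + gy
  attr(out, "n_tokens") <- attr(gy, "n_tokens")
  out
}

# Inception-style block: parallel conv branches concatenated along channels.
nn_inception <- function(branches) new_layer("inception", branches = branches)

nn_forward.nn_inception <- function(layer, x, train = FALSE) {
  outs <- lapply(layer$branches, nn_forward, x = x, train = train)
  chans <- vapply(outs, function(o) dim(o)[3], integer(1))
  d <- dim(outs[[1]])
  out <- array(0, c(d[1], d[2], sum(chans), d[4]))
  at <- 0L
  for (o in outs) {
    nc <- dim(o)[3]
    out[, , (at + 1L):(at + nc), ] <- o
    at <- at + nc
  }
  if (train) layer$cache <- chans
  out
}

nn_backward.nn_inception <- function(layer, gy) {
  chans <- layer$cache
  layer$cache <- NULL
  gx <- NULL
  at <- 0L
  for (i in seq_along(layer$branches)) {
    g <- nn_backward(layer$branches[[i]], gy[, , (at + 1L):(at + chans[i]), , drop = FALSE])
    gx <- if (is.null(gx)) g else gx + g
    at <- at + chans[i]
  }
  gx
}

# Transformer encoder block: x + MHSA(LN(x)); then x + MLP(LN(x)).
nn_transformer_block <- function(dim, n_heads, mlp_ratio = 2) {
  nn_seq(
    nn_residual_add(nn_seq(nn_layer_norm(dim), nn_attention(dim, n_heads))),
    nn_residual_add(nn_seq(
      nn_layer_norm(dim),
      nn_dense(dim, dim * mlp_ratio), nn_gelu(),
      nn_dense(dim * mlp_ratio, dim)
    ))
  )
}

# ------------------------------------------------------------------ generics

nn_forward <- function(layer, x, train = FALSE) UseMethod("nn_forward")
nn_backward <- function(layer, gy) UseMethod("nn_backward")

acc_grad <- function(layer, name, g) {
  cur <- layer$grads[[name]]
  layer$grads[[name]] <- if (is.null(cur)) g else cur + g
  invisible(NULL)
}

# All parameter-bearing layer environments, recursively.
nn_param_layers <- function(layer) {
  out <- list()
  if (length(layer$params)) out <- list(layer)
  for (slot in c("layers", "branches")) {
    if (!is.null(layer[[slot]])) {
      for (l in layer[[slot]]) out <- c(out, nn_param_layers(l))
    }
  }
  for (slot in c("body", "shortcut", "conv")) {
    if (!is.null(layer[[slot]]) && inherits(layer[[slot]], "nn_layer")) {
      out <- c(out, nn_param_layers(layer[[slot]]))
    }
  }
  out
}

nn_zero_grads <- function(net) {
  for (l in nn_param_layers(net)) l$grads <- list()
  invisible(NULL)
}

nn_n_params <- function(net) {
  sum(vapply(
    nn_param_layers(net),
    function(l) sum(vapply(l$params, length, numeric(1))), numeric(1)
  ))
}

# Plain-list snapshot of all parameters (deep copy) and its inverse.
nn_state_dict <- function(net) {
  lapply(nn_param_layers(net), function(l) l$params)
}

nn_load_state <- function(net, state) {
  layers <- nn_param_layers(net)
  stopifnot(length(layers) == length(state))
  for (i in seq_along(layers)) layers[[i]]$params <- state[[i]]
  invisible(net)
}

# One SGD step with momentum and (decoupled-from-loss, L2-coupled) weight
# decay: v <- mu * v + g + wd * p ; p <- p - lr * v.
nn_sgd_step <- function(net, lr, momentum = 0.9, weight_decay = 0) {
  for (l in nn_param_layers(net)) {
    for (nm in names(l$params)) {
      g <- l$grads[[nm]]
      if (is.null(g)) next
      if (weight_decay > 0 && nm != "b") g <- g + weight_decay * l$params[[nm]]
      v <- l$vel[[nm]]
      v <- if (is.null(v)) g else momentum * v + g
      l$vel[[nm]] <- v
      l$params[[nm]] <- l$params[[nm]] - lr * v
    }
  }
  invisible(NULL)
}
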