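#' Configuration of the orchard vision-transformer classifier
#'
#' Houses every architectural hyper-parameter of the classifier: patch
#' geometry, embedding width, encoder depth and attention layout, the MLP
#' head, and the policy for images whose side is not a multiple of the patch
#' size. The reference configuration is 12 layers, hidden size `D = 790`,
#' 12 heads, feed-forward width 3092 and 6 x 6 patches on a 70 x 70 input;
#' tiny test configurations run through the identical code path.
#'
#' @param num_classes Number of output classes `m`.
#' @param image_size `(H, W)` input size in pixels (scalar means square).
#' @param patch_size `(Ph, Pw)` patch size in pixels.
#' @param stride Patch stride; must currently equal `patch_size`
#'   (non-overlapping tiling).
#' @param hidden_size Embedding width `D`.
#' @param num_layers Encoder block count.
#' @param num_heads Attention head count.
#' @param head_dim Per-head projection width; defaults to
#'   `floor(hidden_size / num_heads)`, so `D` need not be divisible by the
#'   head count (the concatenated heads are projected back to `D`).
#' @param mlp_size Encoder feed-forward hidden width.
#' @param head_widths Integer vector of MLP-head hidden widths (may be
#'   empty for a linear head).
#' @param dropout_rate Dropout rate in `[0, 1)` applied after attention and
#'   feed-forward sublayers and after head activations, during training
#'   only.
#' @param boundary_policy `"resize"` (default) rescales the image to the
#'   nearest multiple of the patch size (70 to 72 for 6-pixel patches,
#'   giving `N = 144`); `"crop"` drops the bottom/right remainder
#'   (`N = 121`).
#' @return An object of class `"oaom_config"`.
#' @export
#' @examples
#' oaom_config(num_classes = 85)  # the reference geometry
oaom_config <- function(num_classes,
                        image_size = c(70, 70), patch_size = c(6, 6),
                        stride = patch_size, hidden_size = 790,
                        num_layers = 12, num_heads = 12, head_dim = NULL,
                        mlp_size = 3092, head_widths = 512,
                        dropout_rate = 0.1,
                        boundary_policy = c("resize", "crop")) {
  boundary_policy <- match.arg(boundary_policy)
  image_size <- rep_len(as.integer(image_size), 2)
  patch_size <- rep_len(as.integer(patch_size), 2)
  stride <- rep_len(as.integer(stride), 2)
  if (!identical(stride, patch_size))
    stop("only non-overlapping tiling (stride = patch_size) is supported",
         call. = FALSE)
  if (is.null(head_dim)) head_dim <- max(1L, hidden_size %/% num_heads)
  sizes <- c(image_size, patch_size, hidden_size, num_layers, num_heads,
             head_dim, mlp_size, num_classes)
  if (any(sizes < 1) || any(sizes != floor(sizes)))
    stop("all sizes must be positive integers", call. = FALSE)
  if (dropout_rate < 0 || dropout_rate >= 1)
    stop("`dropout_rate` must lie in [0, 1)", call. = FALSE)
  structure(list(num_classes = as.integer(num_classes),
                 image_size = image_size, patch_size = patch_size,
                 stride = stride, hidden_size = as.integer(hidden_size),
                 num_layers = as.integer(num_layers),
                 num_heads = as.integer(num_heads),
                 head_dim = as.integer(head_dim),
                 mlp_size = as.integer(mlp_size),
                 head_widths = as.integer(head_widths),
                 dropout_rate = dropout_rate,
                 boundary_policy = boundary_policy),
            class = "oaom_config")
}

#' @export
print.oaom_config <- function(x, ...) {
  cat(sprintf(paste0(
    "<oaom_config> %dx%d image, %dx%d patches (%s), D = %d, %d layers, ",
    "%d heads x %d, mlp %d, head [%s] -> %d classes, dropout %g\n"),
    x$image_size[1], x$image_size[2], x$patch_size[1], x$patch_size[2],
    x$boundary_policy, x$hidden_size, x$num_layers, x$num_heads, x$head_dim,
    x$mlp_size, paste(x$head_widths, collapse = ","), x$num_classes,
    x$dropout_rate))
  invisible(x)
}

# Image dimensions after the boundary policy, and the resulting patch grid.
patch_grid <- function(config, image_dims = config$image_size) {
  ph <- config$patch_size[1]; pw <- config$patch_size[2]
  h <- image_dims[1]; w <- image_dims[2]
  if (config$boundary_policy == "resize") {
    h2 <- max(ph, round(h / ph) * ph)
    w2 <- max(pw, round(w / pw) * pw)
  } else {
    h2 <- (h %/% ph) * ph
    w2 <- (w %/% pw) * pw
  }
  list(dims = c(h2, w2), n_rows = h2 %/% ph, n_cols = w2 %/% pw,
       n_patches = (h2 %/% ph) * (w2 %/% pw))
}

#' Extract non-overlapping patches from an image
#'
#' Tiles the image into `Ph x Pw` patches in row-major grid order. When a
#' side is not a multiple of the patch size, the configured boundary policy
#' is applied first: `"resize"` rescales (bilinear) to the nearest multiple;
#' `"crop"` drops the bottom/right remainder. The patch count is
#' `N = (H' / Ph) * (W' / Pw)` for the post-policy dimensions `H', W'`.
#'
#' @param image An H x W x 3 array of intensities in `[0, 1]` (an H x W
#'   matrix is treated as grayscale and replicated across channels).
#' @param config An [oaom_config()].
#' @return An object of class `"patch_sequence"`: a list with `patches`
#'   (N x (Ph*Pw*3) matrix, one flattened patch per row), `positions`
#'   (1..N), `grid`, and `image` (the post-policy image).
#' @export
#' @examples
#' cfg <- oaom_config(num_classes = 3, image_size = 72, patch_size = 6)
#' ps <- extract_patches(array(0.5, c(72, 72, 3)), cfg)
#' nrow(ps$patches)  # 144
extract_patches <- function(image, config) {
  if (length(dim(image)) == 2L)
    image <- array(rep(image, 3), c(dim(image), 3))
  if (dim(image)[1] < config$patch_size[1] ||
      dim(image)[2] < config$patch_size[2])
    stop("image is smaller than one patch", call. = FALSE)
  g <- patch_grid(config, dim(image)[1:2])
  if (config$boundary_policy == "resize") {
    image <- resize_bilinear(image, g$dims[1], g$dims[2])
  } else {
    image <- image[seq_len(g$dims[1]), seq_len(g$dims[2]), , drop = FALSE]
  }
  ph <- config$patch_size[1]; pw <- config$patch_size[2]
  patches <- matrix(0, g$n_patches, ph * pw * 3)
  k <- 0L
  for (r in seq_len(g$n_rows)) for (cc in seq_len(g$n_cols)) {
    k <- k + 1L
    patches[k, ] <- as.vector(
      image[((r - 1) * ph + 1):(r * ph), ((cc - 1) * pw + 1):(cc * pw), ])
  }
  structure(list(patches = patches, positions = seq_len(g$n_patches),
                 grid = g, patch_size = config$patch_size, image = image),
            class = "patch_sequence")
}

#' Reassemble an image from a patch sequence
#'
#' Inverse of [extract_patches()] on the post-policy image: under the crop
#' policy the reassembly reproduces the cropped image exactly.
#'
#' @param seq A [extract_patches()] result.
#' @return An H' x W' x 3 array.
#' @export
patches_to_image <- function(seq) {
  g <- seq$grid
  ph <- seq$patch_size[1]; pw <- seq$patch_size[2]
  img <- array(0, c(g$dims[1], g$dims[2], 3))
  k <- 0L
  for (r in seq_len(g$n_rows)) for (cc in seq_len(g$n_cols)) {
    k <- k + 1L
    img[((r - 1) * ph + 1):(r * ph), ((cc - 1) * pw + 1):(cc * pw), ] <-
      array(seq$patches[k, ], c(ph, pw, 3))
  }
  img
}

# --- parameters ---------------------------------------------------------------

# Gaussian(0, 0.02) init for projections, zeros for biases, ones/zeros for
# layer-norm gain/bias: the conventional transformer initialisation.
init_oaom_params <- function(config, n_patches, init_sd = 0.02) {
  D <- config$hidden_size
  P <- prod(config$patch_size) * 3L
  hd <- config$num_heads * config$head_dim
  rmat <- function(r, c) matrix(stats::rnorm(r * c, sd = init_sd), r, c)
  params <- list(
    embed_W = rmat(P, D), embed_b = numeric(D),
    pos = rmat(n_patches, D), cls = stats::rnorm(D, sd = init_sd))
  for (l in seq_len(config$num_layers)) {
    pre <- sprintf("L%02d_", l)
    params[[paste0(pre, "ln1_g")]] <- rep(1, D)
    params[[paste0(pre, "ln1_b")]] <- numeric(D)
    params[[paste0(pre, "Wq")]] <- rmat(D, hd)
    params[[paste0(pre, "bq")]] <- numeric(hd)
    params[[paste0(pre, "Wk")]] <- rmat(D, hd)
    params[[paste0(pre, "bk")]] <- numeric(hd)
    params[[paste0(pre, "Wv")]] <- rmat(D, hd)
    params[[paste0(pre, "bv")]] <- numeric(hd)
    params[[paste0(pre, "Wo")]] <- rmat(hd, D)
    params[[paste0(pre, "bo")]] <- numeric(D)
    params[[paste0(pre, "ln2_g")]] <- rep(1, D)
    params[[paste0(pre, "ln2_b")]] <- numeric(D)
    params[[paste0(pre, "W1")]] <- rmat(D, config$mlp_size)
    params[[paste0(pre, "b1")]] <- numeric(config$mlp_size)
    params[[paste0(pre, "W2")]] <- rmat(config$mlp_size, D)
    params[[paste0(pre, "b2")]] <- numeric(D)
  }
  params$lnf_g <- rep(1, D)
  params$lnf_b <- numeric(D)
  prev <- D
  for (j in seq_along(config$head_widths)) {
    params[[sprintf("head_W%d", j)]] <- rmat(prev, config$head_widths[j])
    params[[sprintf("head_b%d", j)]] <- numeric(config$head_widths[j])
    prev <- config$head_widths[j]
  }
  params$out_W <- rmat(prev, config$num_classes)
  params$out_b <- numeric(config$num_classes)
  params
}

#' Initialise an untrained classifier
#'
#' Builds the full parameter set for a configuration. All weights are drawn
#' from the current RNG stream (Gaussian, sd 0.02), so results are
#' reproducible under `set.seed()`.
#'
#' @param config An [oaom_config()].
#' @param classes Optional character class labels (length
#'   `config$num_classes`).
#' @return An object of class `"oaom_model"`: a list with `config`,
#'   `params`, `n_patches`, `classes`.
#' @export
oaom_init <- function(config, classes = NULL) {
  n_patches <- patch_grid(config)$n_patches
  if (is.null(classes)) classes <- paste0("class_", seq_len(config$num_classes))
  if (length(classes) != config$num_classes)
    stop("`classes` must have length `num_classes`", call. = FALSE)
  structure(list(config = config, params = init_oaom_params(config, n_patches),
                 n_patches = n_patches, classes = classes),
            class = "oaom_model")
}

#' @export
print.oaom_model <- function(x, ...) {
  n_par <- sum(vapply(x$params, length, integer(1)))
  cat(sprintf("<oaom_model> %d patches + CLS, %s parameters, classes: %s\n",
              x$n_patches, format(n_par, big.mark = ","),
              paste(utils::head(x$classes, 5), collapse = ", ")))
  print(x$config)
  invisible(x)
}

# --- forward primitives -------------------------------------------------------

gelu <- function(x) x * stats::pnorm(x)
gelu_grad <- function(x) stats::pnorm(x) + x * stats::dnorm(x)

add_rowvec <- function(m, v) m + matrix(v, nrow(m), length(v), byrow = TRUE)

layer_norm_fwd <- function(x, g, b, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  inv <- 1 / sqrt(rowMeans(xc^2) + eps)
  xhat <- xc * inv
  list(y = add_rowvec(xhat * matrix(g, nrow(x), ncol(x), byrow = TRUE), b),
       xhat = xhat, inv = inv)
}

layer_norm_bwd <- function(dy, cache, g) {
  xhat <- cache$xhat
  dxhat <- dy * matrix(g, nrow(dy), ncol(dy), byrow = TRUE)
  dx <- cache$inv * (dxhat - rowMeans(dxhat) -
                       xhat * rowMeans(dxhat * xhat))
  list(dx = dx, dg = colSums(dy * xhat), db = colSums(dy))
}

attention_fwd <- function(h, p, pre, config) {
  hd <- config$head_dim
  Q <- add_rowvec(h %*% p[[paste0(pre, "Wq")]], p[[paste0(pre, "bq")]])
  K <- add_rowvec(h %*% p[[paste0(pre, "Wk")]], p[[paste0(pre, "bk")]])
  V <- add_rowvec(h %*% p[[paste0(pre, "Wv")]], p[[paste0(pre, "bv")]])
  O <- matrix(0, nrow(h), config$num_heads * hd)
  A <- vector("list", config$num_heads)
  for (i in seq_len(config$num_heads)) {
    idx <- ((i - 1) * hd + 1):(i * hd)
    S <- Q[, idx, drop = FALSE] %*% t(K[, idx, drop = FALSE]) / sqrt(hd)
    A[[i]] <- softmax_rows(S)
    O[, idx] <- A[[i]] %*% V[, idx, drop = FALSE]
  }
  out <- add_rowvec(O %*% p[[paste0(pre, "Wo")]], p[[paste0(pre, "bo")]])
  list(out = out, h = h, Q = Q, K = K, V = V, A = A, O = O)
}

attention_bwd <- function(dout, cache, p, pre, config) {
  hd <- config$head_dim
  g <- list()
  g[[paste0(pre, "Wo")]] <- t(cache$O) %*% dout
  g[[paste0(pre, "bo")]] <- colSums(dout)
  dO <- dout %*% t(p[[paste0(pre, "Wo")]])
  dQ <- matrix(0, nrow(dout), ncol(cache$Q))
  dK <- dQ; dV <- dQ
  for (i in seq_len(config$num_heads)) {
    idx <- ((i - 1) * hd + 1):(i * hd)
    A <- cache$A[[i]]
    dA <- dO[, idx, drop = FALSE] %*% t(cache$V[, idx, drop = FALSE])
    dV[, idx] <- t(A) %*% dO[, idx, drop = FALSE]
    dS <- A * (dA - rowSums(dA * A))
    dQ[, idx] <- dS %*% cache$K[, idx, drop = FALSE] / sqrt(hd)
    dK[, idx] <- t(dS) %*% cache$Q[, idx, drop = FALSE] / sqrt(hd)
  }
  h <- cache$h
  g[[paste0(pre, "Wq")]] <- t(h) %*% dQ
  g[[paste0(pre, "bq")]] <- colSums(dQ)
  g[[paste0(pre, "Wk")]] <- t(h) %*% dK
  g[[paste0(pre, "bk")]] <- colSums(dK)
  g[[paste0(pre, "Wv")]] <- t(h) %*% dV
  g[[paste0(pre, "bv")]] <- colSums(dV)
  g$dh <- dQ %*% t(p[[paste0(pre, "Wq")]]) +
    dK %*% t(p[[paste0(pre, "Wk")]]) +
    dV %*% t(p[[paste0(pre, "Wv")]])
  g
}

# Inverted dropout: mask scaled by 1/(1-rate) at train time, identity at
# inference. Draws from the current RNG stream.
dropout_mask <- function(dims, rate, training) {
  if (!training || rate == 0) return(NULL)
  array((stats::runif(prod(dims)) >= rate) / (1 - rate), dims)
}

apply_mask <- function(x, mask) if (is.null(mask)) x else x * mask

# Full forward pass over one patch matrix (N x P). Returns logits and, when
# `keep_cache`, every intermediate needed by oaom_backward().
oaom_forward_patches <- function(params, patches, config, training = FALSE,
                                 keep_cache = FALSE) {
  n <- nrow(patches)
  if (n != nrow(params$pos))
    stop("patch count ", n, " does not match the positional table (",
         nrow(params$pos), ")", call. = FALSE)
  emb <- add_rowvec(patches %*% params$embed_W, params$embed_b) + params$pos
  x <- rbind(params$cls, emb)
  cache <- list(patches = patches, layers = vector("list", config$num_layers))
  for (l in seq_len(config$num_layers)) {
    pre <- sprintf("L%02d_", l)
    lc <- list(x_in = x)
    ln1 <- layer_norm_fwd(x, params[[paste0(pre, "ln1_g")]],
                          params[[paste0(pre, "ln1_b")]])
    att <- attention_fwd(ln1$y, params, pre, config)
    m1 <- dropout_mask(dim(att$out), config$dropout_rate, training)
    x <- x + apply_mask(att$out, m1)
    lc$ln1 <- ln1; lc$att <- att; lc$m1 <- m1; lc$x_mid <- x
    ln2 <- layer_norm_fwd(x, params[[paste0(pre, "ln2_g")]],
                          params[[paste0(pre, "ln2_b")]])
    f1 <- add_rowvec(ln2$y %*% params[[paste0(pre, "W1")]],
                     params[[paste0(pre, "b1")]])
    a1 <- gelu(f1)
    f2 <- add_rowvec(a1 %*% params[[paste0(pre, "W2")]],
                     params[[paste0(pre, "b2")]])
    m2 <- dropout_mask(dim(f2), config$dropout_rate, training)
    x <- x + apply_mask(f2, m2)
    lc$ln2 <- ln2; lc$f1 <- f1; lc$a1 <- a1; lc$m2 <- m2
    cache$layers[[l]] <- lc
  }
  lnf <- layer_norm_fwd(x, params$lnf_g, params$lnf_b)
  a <- lnf$y[1, , drop = FALSE]  # CLS token drives the head
  cache$x_final <- x; cache$lnf <- lnf
  cache$head <- vector("list", length(config$head_widths))
  for (j in seq_along(config$head_widths)) {
    z <- add_rowvec(a %*% params[[sprintf("head_W%d", j)]],
                    params[[sprintf("head_b%d", j)]])
    act <- gelu(z)
    mh <- dropout_mask(dim(act), config$dropout_rate, training)
    cache$head[[j]] <- list(a_in = a, z = z, mh = mh)
    a <- apply_mask(act, mh)
  }
  cache$a_last <- a
  logits <- drop(add_rowvec(a %*% params$out_W, params$out_b))
  list(logits = logits, cache = if (keep_cache) cache else NULL)
}

# Backward pass matching oaom_forward_patches(); `dlogits` is the loss
# gradient at the logits. Returns a gradient list with the params layout.
oaom_backward <- function(params, cache, dlogits, config) {
  g <- list()
  dl <- matrix(dlogits, 1)
  g$out_W <- t(cache$a_last) %*% dl
  g$out_b <- drop(dl)
  da <- dl %*% t(params$out_W)
  for (j in rev(seq_along(config$head_widths))) {
    hc <- cache$head[[j]]
    dact <- apply_mask(da, hc$mh)
    dz <- dact * gelu_grad(hc$z)
    g[[sprintf("head_W%d", j)]] <- t(hc$a_in) %*% dz
    g[[sprintf("head_b%d", j)]] <- drop(dz)
    da <- dz %*% t(params[[sprintf("head_W%d", j)]])
  }
  dy_lnf <- matrix(0, nrow(cache$lnf$xhat), ncol(cache$lnf$xhat))
  dy_lnf[1, ] <- da
  lb <- layer_norm_bwd(dy_lnf, cache$lnf, params$lnf_g)
  g$lnf_g <- lb$dg; g$lnf_b <- lb$db
  dx <- lb$dx
  for (l in rev(seq_len(config$num_layers))) {
    pre <- sprintf("L%02d_", l)
    lc <- cache$layers[[l]]
    # FFN sublayer
    df2 <- apply_mask(dx, lc$m2)
    g[[paste0(pre, "W2")]] <- t(lc$a1) %*% df2
    g[[paste0(pre, "b2")]] <- colSums(df2)
    da1 <- df2 %*% t(params[[paste0(pre, "W2")]])
    df1 <- da1 * gelu_grad(lc$f1)
    g[[paste0(pre, "W1")]] <- t(lc$ln2$y) %*% df1
    g[[paste0(pre, "b1")]] <- colSums(df1)
    dln2y <- df1 %*% t(params[[paste0(pre, "W1")]])
    lb2 <- layer_norm_bwd(dln2y, lc$ln2, params[[paste0(pre, "ln2_g")]])
    g[[paste0(pre, "ln2_g")]] <- lb2$dg
    g[[paste0(pre, "ln2_b")]] <- lb2$db
    dx <- dx + lb2$dx
    # attention sublayer
    datt <- apply_mask(dx, lc$m1)
    ab <- attention_bwd(datt, lc$att, params, pre, config)
    for (nm in setdiff(names(ab), "dh")) g[[nm]] <- ab[[nm]]
    lb1 <- layer_norm_bwd(ab$dh, lc$ln1, params[[paste0(pre, "ln1_g")]])
    g[[paste0(pre, "ln1_g")]] <- lb1$dg
    g[[paste0(pre, "ln1_b")]] <- lb1$db
    dx <- dx + lb1$dx
  }
  g$cls <- dx[1, ]
  demb <- dx[-1, , drop = FALSE]
  g$pos <- demb
  g$embed_W <- t(cache$patches) %*% demb
  g$embed_b <- colSums(demb)
  g
}

# --- public forward surface ---------------------------------------------------

#' Embed a patch sequence as transformer tokens
#'
#' Applies the shared affine projection (`Y_i = w A_i + b`, identical `w`
#' and `b` for every patch) to width `D`, adds the learned positional
#' encoding for positions `1..N`, and prepends the learned CLS token at
#' index 0 (which receives no positional encoding).
#'
#' @param seq A [extract_patches()] result.
#' @param model An [oaom_init()] model.
#' @return An (N+1) x D token matrix; row 1 is the CLS token.
#' @export
embed_patches <- function(seq, model) {
  params <- model$params
  if (nrow(seq$patches) != nrow(params$pos))
    stop("patch count does not match the model's positional table",
         call. = FALSE)
  emb <- add_rowvec(seq$patches %*% params$embed_W, params$embed_b) +
    params$pos
  rbind(params$cls, emb)
}

#' Multi-head self-attention of one encoder layer
#'
#' Per head, learned projections map tokens to queries, keys and values of
#' width `head_dim`; scaled dot-product attention (`1/sqrt(head_dim)`) is
#' applied per head and the concatenated heads are projected back to width
#' `D`.
#'
#' @param tokens A T x D token matrix.
#' @param model An [oaom_init()] model.
#' @param layer Encoder layer index whose weights to use.
#' @return A T x D matrix.
#' @export
multi_head_attention <- function(tokens, model, layer = 1) {
  pre <- sprintf("L%02d_", layer)
  attention_fwd(tokens, model$params, pre, model$config)$out
}

#' One pre-norm encoder block
#'
#' `x + MHSA(LN(x))` followed by `y + FFN(LN(y))`, with a two-layer GELU
#' feed-forward of width `mlp_size`; dropout after each sublayer during
#' training.
#'
#' @inheritParams multi_head_attention
#' @param training Apply dropout (draws from the current RNG stream).
#' @return A T x D matrix of the same shape as `tokens`.
#' @export
encoder_block <- function(tokens, model, layer = 1, training = FALSE) {
  p <- model$params; config <- model$config
  pre <- sprintf("L%02d_", layer)
  ln1 <- layer_norm_fwd(tokens, p[[paste0(pre, "ln1_g")]],
                        p[[paste0(pre, "ln1_b")]])
  att <- attention_fwd(ln1$y, p, pre, config)$out
  x <- tokens + apply_mask(att, dropout_mask(dim(att), config$dropout_rate,
                                             training))
  ln2 <- layer_norm_fwd(x, p[[paste0(pre, "ln2_g")]],
                        p[[paste0(pre, "ln2_b")]])
  f2 <- add_rowvec(gelu(add_rowvec(ln2$y %*% p[[paste0(pre, "W1")]],
                                   p[[paste0(pre, "b1")]])) %*%
                     p[[paste0(pre, "W2")]], p[[paste0(pre, "b2")]])
  x + apply_mask(f2, dropout_mask(dim(f2), config$dropout_rate, training))
}

#' Classify one image
#'
#' Runs the full pipeline: patch extraction, embedding, the encoder stack,
#' and the softmax MLP head on the CLS token. Inference mode (no dropout)
#' unless `training = TRUE`.
#'
#' @param model An [oaom_init()] (or trained) model.
#' @param image An H x W x 3 array in `[0, 1]`.
#' @param training Apply dropout.
#' @return A named probability vector over the model's classes (sums to 1).
#' @export
oaom_forward <- function(model, image, training = FALSE) {
  seq <- extract_patches(image, model$config)
  out <- oaom_forward_patches(model$params, seq$patches, model$config,
                              training = training)
  stats::setNames(drop(softmax_rows(matrix(out$logits, 1))), model$classes)
}

#' Predict class probabilities for a list of images
#'
#' @param object An `oaom_model`.
#' @param images A list of H x W x 3 arrays (or a single array).
#' @param ... Unused.
#' @return A matrix of probabilities, one row per image, columns named by
#'   class.
#' @export
predict.oaom_model <- function(object, images, ...) {
  if (!is.list(images)) images <- list(images)
  out <- t(vapply(images, function(im) oaom_forward(object, im),
                  numeric(object$config$num_classes)))
  colnames(out) <- object$classes
  out
}
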