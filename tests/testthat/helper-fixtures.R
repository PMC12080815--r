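# Tiny shared fixtures. Everything is generated in code at test time.

tiny_oaom_config <- function(num_classes = 3, image_size = 16, ...) {
  oaom_config(num_classes = num_classes, image_size = image_size,
              patch_size = 8, hidden_size = 8, num_layers = 2,
              num_heads = 2, head_dim = 4, mlp_size = 12, head_widths = 6,
              dropout_rate = 0, ...)
}

random_image <- function(h = 16, w = h) array(runif(h * w * 3), c(h, w, 3))

# Explicit single-head scaled dot-product attention, written as plain loops:
# the independent oracle for the package's vectorised implementation.
brute_force_attention <- function(tokens, Wq, bq, Wk, bk, Wv, bv, Wo, bo,
                                  head_dim) {
  t_n <- nrow(tokens)
  n_heads <- length(bq) / head_dim
  O <- matrix(0, t_n, length(bq))
  for (h in seq_len(n_heads)) {
    idx <- ((h - 1) * head_dim + 1):(h * head_dim)
    Q <- sweep(tokens %*% Wq[, idx], 2, bq[idx], `+`)
    K <- sweep(tokens %*% Wk[, idx], 2, bk[idx], `+`)
    V <- sweep(tokens %*% Wv[, idx], 2, bv[idx], `+`)
    for (i in seq_len(t_n)) {
      logits <- numeric(t_n)
      for (j in seq_len(t_n)) logits[j] <- sum(Q[i, ] * K[j, ]) / sqrt(head_dim)
      w <- exp(logits - max(logits)); w <- w / sum(w)
      for (j in seq_len(t_n)) O[i, idx] <- O[i, idx] + w[j] * V[j, ]
    }
  }
  sweep(O %*% Wo, 2, bo, `+`)
}
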