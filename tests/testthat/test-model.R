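test_that("patch counts follow the tiling rule under both boundary policies", {
  cfg72 <- oaom_config(3, image_size = 72, patch_size = 6)
  expect_equal(nrow(extract_patches(array(0.2, c(72, 72, 3)), cfg72)$patches),
               144)
  crop <- oaom_config(3, image_size = 70, patch_size = 6,
                      boundary_policy = "crop")
  expect_equal(nrow(extract_patches(array(0.2, c(70, 70, 3)), crop)$patches),
               121)  # floor(70/6)^2
  rs <- oaom_config(3, image_size = 70, patch_size = 6,
                    boundary_policy = "resize")
  ps <- extract_patches(array(0.2, c(70, 70, 3)), rs)
  expect_equal(nrow(ps$patches), 144)  # 70 resized to the nearest multiple, 72
  expect_equal(dim(ps$image), c(72, 72, 3))
  one <- oaom_config(3, image_size = 6, patch_size = 6)
  img <- array(runif(6 * 6 * 3), c(6, 6, 3))
  seq1 <- extract_patches(img, one)
  expect_equal(nrow(seq1$patches), 1)
  expect_equal(array(seq1$patches[1, ], dim(img)), img)
  expect_error(extract_patches(array(0, c(4, 4, 3)), one), "smaller")
})

test_that("patch tiling is lossless under the crop policy", {
  cfg <- oaom_config(3, image_size = 70, patch_size = 6,
                     boundary_policy = "crop")
  img <- array(runif(70 * 70 * 3), c(70, 70, 3))
  seq <- extract_patches(img, cfg)
  expect_identical(patches_to_image(seq), img[1:66, 1:66, , drop = FALSE])
})

test_that("patch embedding shares one projection and adds positions", {
  cfg <- tiny_oaom_config()
  set.seed(3)
  m <- oaom_init(cfg)
  img <- random_image()
  seq <- extract_patches(img, cfg)
  tokens <- embed_patches(seq, m)
  expect_equal(dim(tokens), c(m$n_patches + 1, cfg$hidden_size))
  # zero projection and positional table: every patch token equals the bias
  m0 <- m
  m0$params$embed_W[] <- 0; m0$params$pos[] <- 0
  m0$params$embed_b <- seq_len(cfg$hidden_size) / 10
  tok0 <- embed_patches(seq, m0)
  for (i in 2:nrow(tok0))
    expect_equal(tok0[i, ], m0$params$embed_b)
  # identical patches at two positions differ only by the positional rows
  seq2 <- seq
  seq2$patches[2, ] <- seq2$patches[1, ]
  tok <- embed_patches(seq2, m)
  expect_equal(tok[2, ] - tok[3, ], m$params$pos[1, ] - m$params$pos[2, ],
               tolerance = 1e-12)
})

test_that("multi-head attention matches a brute-force oracle", {
  cfg <- tiny_oaom_config()
  set.seed(9)
  m <- oaom_init(cfg)
  tokens <- matrix(rnorm(3 * cfg$hidden_size), 3)
  p <- m$params
  oracle <- brute_force_attention(tokens, p$L01_Wq, p$L01_bq, p$L01_Wk,
                                  p$L01_bk, p$L01_Wv, p$L01_bv, p$L01_Wo,
                                  p$L01_bo, cfg$head_dim)
  expect_equal(multi_head_attention(tokens, m, layer = 1), oracle,
               tolerance = 1e-10)
})

test_that("attention degenerates correctly for single and constant inputs", {
  cfg <- tiny_oaom_config()
  set.seed(10)
  m <- oaom_init(cfg)
  # a single token attends only to itself: output is its own value projection
  one <- matrix(rnorm(cfg$hidden_size), 1)
  p <- m$params
  v <- sweep(one %*% p$L01_Wv, 2, p$L01_bv, `+`)
  expect_equal(multi_head_attention(one, m),
               sweep(v %*% p$L01_Wo, 2, p$L01_bo, `+`), tolerance = 1e-10)
  # constant value projections make the output independent of the weights
  m2 <- m
  m2$params$L01_Wv[] <- 0
  m2$params$L01_bv <- rnorm(ncol(p$L01_Wv))
  toks <- matrix(rnorm(4 * cfg$hidden_size), 4)
  out <- multi_head_attention(toks, m2)
  for (i in 2:4) expect_equal(out[i, ], out[1, ], tolerance = 1e-10)
  # uniform (zero) query/key projections give uniform attention weights:
  # the output equals attention to the plain token average
  m3 <- m
  m3$params$L01_Wq[] <- 0; m3$params$L01_bq[] <- 0
  m3$params$L01_Wk[] <- 0; m3$params$L01_bk[] <- 0
  avg <- matrix(colMeans(toks), nrow(toks), ncol(toks), byrow = TRUE)
  v_avg <- sweep(avg %*% p$L01_Wv, 2, p$L01_bv, `+`)
  expect_equal(multi_head_attention(toks, m3),
               sweep(v_avg %*% p$L01_Wo, 2, p$L01_bo, `+`),
               tolerance = 1e-10)
})

test_that("encoder blocks conserve shape and pass residuals through zeros", {
  cfg <- tiny_oaom_config()
  set.seed(12)
  m <- oaom_init(cfg)
  toks <- matrix(rnorm(5 * cfg$hidden_size), 5)
  out <- encoder_block(toks, m, layer = 2)
  expect_equal(dim(out), dim(toks))
  mz <- m
  for (nm in grep("^L01_(W|b)", names(mz$params), value = TRUE))
    mz$params[[nm]][] <- 0
  expect_equal(encoder_block(toks, mz, layer = 1), toks, tolerance = 1e-12)
})

test_that("forward output is a probability vector, deterministically", {
  set.seed(20)
  for (i in 1:20) {
    cfg <- tiny_oaom_config(num_classes = sample(2:6, 1))
    m <- oaom_init(cfg)
    img <- random_image()
    probs <- oaom_forward(m, img)
    expect_equal(sum(probs), 1, tolerance = 1e-6)
    expect_true(all(probs > 0 & probs < 1))
    expect_identical(probs, oaom_forward(m, img))
  }
})

test_that("CLS output ignores patch order iff positional encodings are zero", {
  cfg <- tiny_oaom_config(image_size = 32)  # 16 patches
  set.seed(30)
  m <- oaom_init(cfg)
  seq <- extract_patches(random_image(32), cfg)
  perm <- sample(m$n_patches)
  m0 <- m; m0$params$pos[] <- 0
  base <- orchardvit:::oaom_forward_patches(m0$params, seq$patches,
                                            cfg)$logits
  shuf <- orchardvit:::oaom_forward_patches(m0$params,
                                            seq$patches[perm, ], cfg)$logits
  expect_equal(shuf, base, tolerance = 1e-5)
  with_pos <- orchardvit:::oaom_forward_patches(m$params, seq$patches,
                                                cfg)$logits
  with_pos_perm <- orchardvit:::oaom_forward_patches(m$params,
                                                     seq$patches[perm, ],
                                                     cfg)$logits
  expect_gt(max(abs(with_pos - with_pos_perm)), 1e-6)
})

test_that("model gradients match central finite differences", {
  cfg <- tiny_oaom_config()
  set.seed(41)
  m <- oaom_init(cfg)
  seq <- extract_patches(random_image(), cfg)
  pr <- loss_params(gamma = 2, dv = 1, reduction = "none")
  lab <- 2L
  loss_of <- function(params) {
    lg <- orchardvit:::oaom_forward_patches(params, seq$patches, cfg)$logits
    batched_loss("mfce", lab, orchardvit:::softmax_rows(matrix(lg, 1)), pr)
  }
  fw <- orchardvit:::oaom_forward_patches(m$params, seq$patches, cfg,
                                          keep_cache = TRUE)
  dl <- loss_grad_logits("mfce", lab, matrix(fw$logits, 1), pr)
  g <- orchardvit:::oaom_backward(m$params, fw$cache, drop(dl), cfg)
  h <- 1e-5
  for (nm in names(m$params)) {
    n <- length(m$params[[nm]])
    for (j in sample(n, min(3, n))) {
      up <- m$params; up[[nm]][j] <- up[[nm]][j] + h
      dn <- m$params; dn[[nm]][j] <- dn[[nm]][j] - h
      num <- (loss_of(up) - loss_of(dn)) / (2 * h)
      expect_lt(abs(num - g[[nm]][j]) / (abs(num) + 1e-6), 2e-4)
    }
  }
})

test_that("dropout is active in training mode only", {
  cfg <- tiny_oaom_config()
  cfg$dropout_rate <- 0.5
  set.seed(55)
  m <- oaom_init(cfg)
  img <- random_image()
  infer1 <- oaom_forward(m, img)
  infer2 <- oaom_forward(m, img)
  expect_identical(infer1, infer2)
  set.seed(1); tr1 <- oaom_forward(m, img, training = TRUE)
  set.seed(2); tr2 <- oaom_forward(m, img, training = TRUE)
  expect_false(identical(tr1, tr2))
})
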