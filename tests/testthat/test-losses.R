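test_that("cross-entropy matches hand-evaluated values", {
  expect_equal(cross_entropy(c(0, 1), c(0, 1)), 0)
  expect_equal(cross_entropy(c(1, 0), c(0.5, 0.5)), log(2), tolerance = 1e-12)
  for (m in c(2, 5, 85))
    expect_equal(cross_entropy(1, rep(1 / m, m)), log(m), tolerance = 1e-9)
  # integer-index and one-hot labels agree
  expect_equal(cross_entropy(2, c(0.3, 0.7)), cross_entropy(c(0, 1), c(0.3, 0.7)))
})

test_that("loss inputs are validated", {
  expect_error(cross_entropy(c(1, 0, 0), c(0.5, 0.5)), "length")
  expect_error(cross_entropy(c(1, 0), c(0.8, 0.8)), "sum to 1")
  expect_error(cross_entropy(c(1, 1), c(0.5, 0.5)), "one-hot")
  expect_error(loss_params(gamma = -1), "gamma")
  expect_error(loss_params(dv = -0.5), "dv")
  expect_error(batched_loss("ce", integer(0), matrix(numeric(0), 0, 2)),
               "empty batch")
  expect_error(loss_curve("mfce", grid = c(0, 0.5)), "strictly inside")
})

test_that("focal loss reduces to CE at gamma = 0 and matches hand values", {
  set.seed(4)
  for (i in 1:20) {
    p <- as.vector(stats::rmultinom(1, 500, rep(1, 4)) / 500)
    s <- sample(4, 1)
    expect_equal(focal_loss(s, p, loss_params(gamma = 0)),
                 cross_entropy(s, p), tolerance = 1e-12)
  }
  expect_equal(focal_loss(1, c(1, 0), loss_params(gamma = 2)), 0,
               tolerance = 1e-6)
  expect_equal(focal_loss(1, c(0.5, 0.5), loss_params(gamma = 2)),
               0.25 * log(2), tolerance = 1e-9)
})

test_that("gate weights conserve mass, are symmetric, and match the logistic", {
  ps <- seq(0, 1, by = 0.05)
  for (dv in c(0, 0.5, 1, 2, 5, 50)) {
    w <- gate_weights(ps, dv)
    expect_equal(rowSums(w), rep(1, length(ps)))        # exact conservation
    # strictly interior in exact arithmetic; saturates to {0, 1} only once
    # the exponent exceeds double precision
    if (dv <= 5) expect_true(all(w > 0 & w < 1))
    else expect_true(all(w >= 0 & w <= 1))
    rev_w <- gate_weights(1 - ps, dv)
    expect_equal(w[, "w_ce"], rev_w[, "w_f"], tolerance = 1e-12)
  }
  expect_equal(gate_weights(0.5, 3)[1, "w_ce"], c(w_ce = 0.5))
  expect_equal(gate_weights(0.3, 0)[1, "w_ce"], c(w_ce = 0.5))
  expect_equal(gate_weights(0.1, 1)[1, ], c(w_ce = stats::plogis(0.8),
                                            w_f = 1 - stats::plogis(0.8)),
               tolerance = 1e-9)
  # no overflow at extreme sharpness
  expect_true(all(is.finite(gate_weights(c(0, 1), dv = 1e6))))
})

test_that("MFCE matches hand-evaluated values and its CE limit", {
  p <- loss_params(gamma = 2, dv = 1)
  expect_equal(mfce_loss(1, c(0.5, 0.5), p), 0.625 * log(2),
               tolerance = 1e-9)
  expect_equal(mfce_loss(2, c(0.9, 0.1), p), 2.16695, tolerance = 1e-4)
  for (dv in c(0, 0.5, 2, 5))  # symmetry point is dv-independent
    expect_equal(mfce_loss(1, c(0.5, 0.5), loss_params(gamma = 2, dv = dv)),
                 0.625 * log(2), tolerance = 1e-9)
  for (dv in c(0.5, 2)) {
    pr0 <- loss_params(gamma = 0, dv = dv)
    expect_equal(mfce_loss(1, c(0.2, 0.8), pr0),
                 cross_entropy(1, c(0.2, 0.8)), tolerance = 1e-12)
  }
})

test_that("batched losses reduce correctly and agree with the scalar ops", {
  p <- loss_params(gamma = 2, dv = 1)
  probs <- rbind(c(0.5, 0.5), c(0.9, 0.1))
  labs <- c(1L, 2L)
  expect_equal(batched_loss("mfce", 1L, matrix(c(0.5, 0.5), 1), p),
               mfce_loss(1, c(0.5, 0.5), p))
  expect_equal(batched_loss("mfce", labs, probs, p),
               (0.433217 + 2.166952) / 2, tolerance = 1e-5)
  onehot <- rbind(c(1, 0), c(0, 1))
  expect_equal(batched_loss("mfce", onehot, probs, p),
               batched_loss("mfce", labs, probs, p))
  p$reduction <- "sum"
  expect_equal(batched_loss("ce", labs, probs, p),
               cross_entropy(1, probs[1, ]) + cross_entropy(2, probs[2, ]))
  p$reduction <- "none"
  expect_length(batched_loss("focal", labs, probs, p), 2)
  # two identical samples, mean reduction, equals the scalar value
  p$reduction <- "mean"
  expect_equal(batched_loss("mfce", c(1L, 1L), rbind(probs[1, ], probs[1, ]), p),
               mfce_loss(1, probs[1, ], p))
})

test_that("focal <= MFCE <= CE across the probability/gamma/dv lattice", {
  grid <- seq(0.001, 0.999, length.out = 999)
  for (g in c(0, 0.5, 1, 2, 5)) for (dv in c(0, 0.5, 1, 2, 5)) {
    pr <- loss_params(gamma = g, dv = dv, reduction = "none")
    ce <- orchardvit:::loss_core("ce", grid, pr)
    fo <- orchardvit:::loss_core("focal", grid, pr)
    mf <- orchardvit:::loss_core("mfce", grid, pr)
    expect_true(all(fo <= mf + 1e-12))
    expect_true(all(mf <= ce + 1e-12))
    if (g == 0) {
      expect_equal(fo, ce, tolerance = 1e-12)
      expect_equal(mf, ce, tolerance = 1e-12)
    }
  }
})

test_that("MFCE approaches CE near p = 0, faster for larger dv", {
  ratio_at <- function(p, dv) {
    pr <- loss_params(gamma = 2, dv = dv)
    orchardvit:::mfce_core(p, pr) / orchardvit:::ce_core(p, pr)
  }
  for (dv in c(0.5, 1, 2, 5)) {
    r <- vapply(c(0.05, 0.01, 0.001), ratio_at, numeric(1), dv = dv)
    expect_true(all(diff(r) > 0))   # ratio climbs towards 1 as p drops
    expect_lt(abs(ratio_at(1e-4, 5) - 1), 0.01)
  }
  # monotone-improving in dv at fixed small p
  rs <- vapply(c(0.5, 1, 2, 5), ratio_at, numeric(1), p = 0.01)
  expect_true(all(diff(rs) > 0))
})

test_that("gamma barely matters for poorly classified samples", {
  ce <- orchardvit:::ce_core(0.01, loss_params())
  vals <- vapply(c(0.5, 1, 2, 5), function(g)
    orchardvit:::mfce_core(0.01, loss_params(gamma = g, dv = 1)), numeric(1))
  expect_lt(max(abs(vals - vals[1])) / ce, 0.05)
})

test_that("MFCE is non-increasing in gamma for well classified samples", {
  vals <- vapply(c(0, 0.5, 1, 2, 5), function(g)
    orchardvit:::mfce_core(0.9, loss_params(gamma = g, dv = 1)), numeric(1))
  expect_true(all(diff(vals) <= 1e-12))
})

test_that("loss curves tabulate the scalar losses over the grid", {
  tab <- loss_curve("mfce", gamma_values = 2, dv_values = c(0, 1, 5),
                    grid = 0.5)
  expect_equal(tab$loss, rep(0.625 * log(2), 3), tolerance = 1e-9)
  grid <- seq(0.05, 0.95, by = 0.05)
  ce_tab <- loss_curve("ce", gamma_values = 0, dv_values = 1, grid = grid)
  mf_tab <- loss_curve("mfce", gamma_values = 0, dv_values = 1, grid = grid)
  expect_equal(mf_tab$loss, ce_tab$loss, tolerance = 1e-12)
  # near p = 0 with a sharp gate, MFCE is within 2% of CE
  sharp <- loss_curve("mfce", gamma_values = 2, dv_values = 5, grid = 0.01)
  ce01 <- loss_curve("ce", gamma_values = 2, dv_values = 5, grid = 0.01)
  expect_lt(abs(sharp$loss / ce01$loss - 1), 0.02)
  expect_named(tab, c("p", "gamma", "dv", "loss"))
})

test_that("analytic loss gradients match central finite differences", {
  set.seed(11)
  for (kind in c("ce", "focal", "mfce")) {
    for (rep in 1:3) {
      b <- 6; m <- 5
      logits <- matrix(rnorm(b * m, sd = 2), b, m)
      labs <- sample(m, b, replace = TRUE)
      pr <- loss_params(gamma = sample(c(0.5, 1, 2), 1),
                        dv = sample(c(0.5, 1, 2), 1))
      ana <- loss_grad_logits(kind, labs, logits, pr)
      h <- 1e-5
      num <- matrix(0, b, m)
      f <- function(lg) batched_loss(kind, labs,
                                     orchardvit:::softmax_rows(lg), pr)
      for (i in seq_len(b)) for (j in seq_len(m)) {
        up <- logits; up[i, j] <- up[i, j] + h
        dn <- logits; dn[i, j] <- dn[i, j] - h
        num[i, j] <- (f(up) - f(dn)) / (2 * h)
      }
      expect_lt(max(abs(ana - num) / (abs(num) + 1e-8)), 1e-4)
    }
  }
})

test_that("the divisive gate convention moves away from CE as dv grows", {
  # the reason the multiplicative reading of the gate exponent is the default
  ratio <- function(dv) {
    pr <- loss_params(gamma = 2, dv = dv, gate_convention = "divisive")
    orchardvit:::mfce_core(0.01, pr) / orchardvit:::ce_core(0.01, pr)
  }
  expect_gt(ratio(0.5), ratio(5))
})
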