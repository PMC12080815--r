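#' Loss hyper-parameters for the cross-entropy / focal / MFCE family
#'
#' Bundles the tunable parameters shared by [cross_entropy()], [focal_loss()]
#' and [mfce_loss()].
#'
#' @param gamma Focusing exponent of the focal term (unitless, `>= 0`).
#'   `gamma = 0` collapses both the focal and the MFCE loss to plain
#'   cross-entropy.
#' @param dv Gate sharpness of the MFCE softmax gate (unitless, `>= 0`).
#'   Larger values push the gate harder towards cross-entropy for poorly
#'   classified samples and towards the focal term for well classified ones;
#'   `dv = 0` fixes the gate at an even 50/50 blend.
#' @param epsilon Log-clipping floor: predicted probabilities are clipped to
#'   `[epsilon, 1]` before taking logs. Must lie in `(0, 1e-3)`.
#' @param reduction How a batch of per-sample losses is reduced: `"mean"`
#'   (default), `"sum"`, or `"none"` (per-sample vector).
#' @param gate_convention How `dv` enters the gate exponent:
#'   `"multiplicative"` (default) uses `exp((1 - p) * dv)`, `"divisive"` uses
#'   `exp((1 - p) / dv)` (requires `dv > 0`). Only the multiplicative form
#'   makes the loss approach cross-entropy near `p = 0` faster as `dv` grows.
#' @return An object of class `"loss_params"`.
#' @export
#' @examples
#' loss_params(gamma = 2, dv = 1)
loss_params <- function(gamma = 2, dv = 1, epsilon = 1e-7,
                        reduction = c("mean", "sum", "none"),
                        gate_convention = c("multiplicative", "divisive")) {
  reduction <- match.arg(reduction)
  gate_convention <- match.arg(gate_convention)
  if (!is.numeric(gamma) || length(gamma) != 1L || is.na(gamma) || gamma < 0)
    stop("`gamma` must be a single non-negative number", call. = FALSE)
  if (!is.numeric(dv) || length(dv) != 1L || is.na(dv) || dv < 0)
    stop("`dv` must be a single non-negative number", call. = FALSE)
  if (gate_convention == "divisive" && dv == 0)
    stop("the divisive gate convention requires `dv > 0`", call. = FALSE)
  if (!is.numeric(epsilon) || length(epsilon) != 1L ||
      epsilon <= 0 || epsilon >= 1e-3)
    stop("`epsilon` must lie in (0, 1e-3)", call. = FALSE)
  structure(
    list(gamma = gamma, dv = dv, epsilon = epsilon, reduction = reduction,
         gate_convention = gate_convention),
    class = "loss_params"
  )
}

#' @export
print.loss_params <- function(x, ...) {
  cat(sprintf(
    "<loss_params> gamma = %g, dv = %g, epsilon = %g, reduction = %s, gate = %s\n",
    x$gamma, x$dv, x$epsilon, x$reduction, x$gate_convention))
  invisible(x)
}

# --- label / probability validation ------------------------------------------

# Accepts a one-hot vector or a 1-based integer class index; returns the
# true-class index. `m` is the number of classes.
as_class_index <- function(z, m) {
  if (length(z) == 1L && z == as.integer(z)) {
    z <- as.integer(z)
    if (z < 1L || z > m)
      stop("class index out of range [1, ", m, "]", call. = FALSE)
    return(z)
  }
  if (length(z) != m)
    stop("label length (", length(z), ") does not match the number of classes (",
         m, ")", call. = FALSE)
  if (!all(z %in% c(0, 1)) || sum(z) != 1)
    stop("one-hot label must have exactly one entry equal to 1 and the rest 0",
         call. = FALSE)
  which(z == 1)
}

validate_prob_vector <- function(ep, tol = 1e-6) {
  if (!is.numeric(ep) || length(ep) < 2L)
    stop("probability vector must be numeric with at least 2 classes",
         call. = FALSE)
  if (any(ep < -tol) || any(ep > 1 + tol))
    stop("probability entries must lie in [0, 1]", call. = FALSE)
  if (abs(sum(ep) - 1) > tol)
    stop("probability entries must sum to 1 (got ", format(sum(ep)), ")",
         call. = FALSE)
  invisible(ep)
}

# --- scalar per-sample cores --------------------------------------------------

# All three losses are functions of the predicted probability at the true
# class only (one-hot labels). These cores are vectorised over p.
ce_core <- function(p, params) {
  -log(pmin(pmax(p, params$epsilon), 1))
}

focal_core <- function(p, params) {
  (1 - p)^params$gamma * ce_core(p, params)
}

gate_exponent_arg <- function(p, params) {
  if (params$gate_convention == "multiplicative") (1 - 2 * p) * params$dv
  else (1 - 2 * p) / params$dv
}

mfce_core <- function(p, params) {
  w_ce <- stats::plogis(gate_exponent_arg(p, params))
  (w_ce + (1 - w_ce) * (1 - p)^params$gamma) * ce_core(p, params)
}

loss_core <- function(loss_kind, p, params) {
  switch(loss_kind,
         ce = ce_core(p, params),
         focal = focal_core(p, params),
         mfce = mfce_core(p, params),
         stop("unknown loss kind: ", loss_kind, call. = FALSE))
}

# d(loss)/dp, vectorised; p clipped to [epsilon, 1 - epsilon] so the
# (1 - p)^(gamma - 1) factor stays finite for gamma < 1.
loss_core_grad <- function(loss_kind, p, params) {
  eps <- params$epsilon
  p <- pmin(pmax(p, eps), 1 - eps)
  nlp <- -log(p)
  g <- params$gamma
  q <- (1 - p)^g
  dq <- if (g == 0) rep(0, length(p)) else -g * (1 - p)^(g - 1)
  switch(loss_kind,
    ce = -1 / p,
    focal = dq * nlp - q / p,
    mfce = {
      w <- stats::plogis(gate_exponent_arg(p, params))
      du <- if (params$gate_convention == "multiplicative") -2 * params$dv
            else -2 / params$dv
      dw <- w * (1 - w) * du
      blend <- w + (1 - w) * q
      dblend <- dw * (1 - q) + (1 - w) * dq
      dblend * nlp - blend / p
    },
    stop("unknown loss kind: ", loss_kind, call. = FALSE))
}

# --- exported scalar operations ----------------------------------------------

#' Cross-entropy loss for a single sample
#'
#' `-log` of the predicted probability at the true class. Probabilities are
#' clipped to `[epsilon, 1]` before the log.
#'
#' @param z True label: a one-hot vector of length `m` or a 1-based class
#'   index.
#' @param ep Predicted probability vector (length `m >= 2`, entries in
#'   `[0, 1]` summing to 1 within `1e-6`).
#' @param params A [loss_params()] object.
#' @return A single non-negative number; 0 iff the true-class probability
#'   is 1.
#' @export
#' @examples
#' cross_entropy(c(1, 0), c(0.5, 0.5))  # ln 2
cross_entropy <- function(z, ep, params = loss_params()) {
  validate_prob_vector(ep)
  s <- as_class_index(z, length(ep))
  ce_core(ep[s], params)
}

#' Focal loss for a single sample
#'
#' Cross-entropy down-weighted by `(1 - p)^gamma`, so well classified samples
#' contribute less to the total loss. Equals [cross_entropy()] when
#' `gamma = 0`, and never exceeds it.
#'
#' @inheritParams cross_entropy
#' @return A single non-negative number.
#' @export
#' @examples
#' focal_loss(c(1, 0), c(0.5, 0.5), loss_params(gamma = 2))  # 0.25 * ln 2
focal_loss <- function(z, ep, params = loss_params()) {
  validate_prob_vector(ep)
  s <- as_class_index(z, length(ep))
  focal_core(ep[s], params)
}

#' The MFCE softmax gate weights
#'
#' The measured focal cross-entropy loss blends a cross-entropy and a focal
#' term with weights from a two-way softmax over the exponents `p * dv` and
#' `(1 - p) * dv`. The cross-entropy weight is computed in the numerically
#' stable logistic form `plogis((1 - 2p) * dv)`, which cannot overflow at
#' large `dv`.
#'
#' @param p Predicted probability at the true class, in `[0, 1]`
#'   (vectorised).
#' @param dv Gate sharpness, `>= 0`.
#' @param gate_convention `"multiplicative"` (exponent `(1 - p) * dv`,
#'   default) or `"divisive"` (`(1 - p) / dv`).
#' @return A two-column matrix with columns `w_ce` and `w_f`; each row sums
#'   to 1 exactly.
#' @export
#' @examples
#' gate_weights(0.1, dv = 1)  # c(0.6900, 0.3100)
gate_weights <- function(p, dv,
                         gate_convention = c("multiplicative", "divisive")) {
  gate_convention <- match.arg(gate_convention)
  if (any(p < 0 | p > 1)) stop("`p` must lie in [0, 1]", call. = FALSE)
  if (length(dv) != 1L || dv < 0)
    stop("`dv` must be a single non-negative number", call. = FALSE)
  if (gate_convention == "divisive" && dv == 0)
    stop("the divisive gate convention requires `dv > 0`", call. = FALSE)
  u <- if (gate_convention == "multiplicative") (1 - 2 * p) * dv
       else (1 - 2 * p) / dv
  w_ce <- stats::plogis(u)
  cbind(w_ce = w_ce, w_f = 1 - w_ce)
}

#' Measured focal cross-entropy (MFCE) loss for a single sample
#'
#' A probability-dependent softmax gate (sharpness `dv`) blends the
#' cross-entropy and focal terms at the true-class probability `p`:
#' `[w_ce(p) + w_f(p) * (1 - p)^gamma] * (-log p)`. Poorly classified samples
#' (`p` near 0) are penalised at near cross-entropy levels — increasingly so
#' for larger `dv` — while well classified samples receive the focal
#' discount. For every `gamma >= 0` and `dv >= 0` the loss satisfies
#' `focal <= MFCE <= CE` pointwise, with all three equal at `gamma = 0`.
#'
#' @inheritParams cross_entropy
#' @return A single non-negative number.
#' @export
#' @examples
#' mfce_loss(2, c(0.9, 0.1), loss_params(gamma = 2, dv = 1))
mfce_loss <- function(z, ep, params = loss_params()) {
  validate_prob_vector(ep)
  s <- as_class_index(z, length(ep))
  mfce_core(ep[s], params)
}

# --- batched form -------------------------------------------------------------

# Normalises labels to a 1-based index vector of length B for a B x m
# probability matrix.
batch_class_index <- function(labels, m, b) {
  if (is.matrix(labels)) {
    if (nrow(labels) != b || ncol(labels) != m)
      stop("label matrix must be ", b, " x ", m, call. = FALSE)
    apply(labels, 1L, as_class_index, m = m)
  } else {
    if (length(labels) != b)
      stop("label vector length must equal the batch size", call. = FALSE)
    vapply(as.integer(labels), as_class_index, integer(1), m = m)
  }
}

#' Batched loss over samples
#'
#' Applies the selected scalar loss to each row of a probability matrix and
#' reduces per `params$reduction`.
#'
#' @param loss_kind One of `"ce"`, `"focal"`, `"mfce"`.
#' @param labels Integer class indices (length B) or a B x m one-hot matrix.
#' @param probs B x m matrix of predicted probabilities, rows summing to 1.
#' @param params A [loss_params()] object.
#' @return A single number (`mean`/`sum` reduction) or a length-B vector
#'   (`none`).
#' @export
batched_loss <- function(loss_kind = c("ce", "focal", "mfce"), labels, probs,
                         params = loss_params()) {
  loss_kind <- match.arg(loss_kind)
  if (!is.matrix(probs)) probs <- matrix(probs, nrow = 1L)
  b <- nrow(probs)
  if (b == 0L) stop("empty batch", call. = FALSE)
  apply(probs, 1L, validate_prob_vector)
  s <- batch_class_index(labels, ncol(probs), b)
  p_true <- probs[cbind(seq_len(b), s)]
  per_sample <- loss_core(loss_kind, p_true, params)
  switch(params$reduction,
         mean = mean(per_sample),
         sum = sum(per_sample),
         none = per_sample)
}

#' Gradient of the batched loss with respect to the logits
#'
#' For probabilities produced by a row-wise softmax of `logits`, returns the
#' analytic gradient of the mean (or summed) batched loss. With a one-hot
#' label the loss depends on the probabilities only through the true-class
#' entry `p_s`, so the chain rule through the softmax gives
#' `dL/dlogit_k = f'(p_s) * p_s * (1[k = s] - p_k)`.
#'
#' @param loss_kind One of `"ce"`, `"focal"`, `"mfce"`.
#' @param labels Integer class indices (length B) or a B x m one-hot matrix.
#' @param logits B x m matrix of unnormalised scores.
#' @param params A [loss_params()] object; `reduction = "none"` returns the
#'   per-sample (unscaled) gradient rows.
#' @return A B x m gradient matrix.
#' @export
loss_grad_logits <- function(loss_kind = c("ce", "focal", "mfce"), labels,
                             logits, params = loss_params()) {
  loss_kind <- match.arg(loss_kind)
  if (!is.matrix(logits)) logits <- matrix(logits, nrow = 1L)
  b <- nrow(logits)
  probs <- softmax_rows(logits)
  s <- batch_class_index(labels, ncol(logits), b)
  p_true <- probs[cbind(seq_len(b), s)]
  fprime <- loss_core_grad(loss_kind, p_true, params)
  # d p_s / d logit_k = p_s * (delta_ks - p_k)
  grad <- -probs * (fprime * p_true)
  grad[cbind(seq_len(b), s)] <- grad[cbind(seq_len(b), s)] + fprime * p_true
  if (params$reduction == "mean") grad <- grad / b
  grad
}

# Row-wise numerically stable softmax.
softmax_rows <- function(x) {
  x <- x - apply(x, 1L, max)
  e <- exp(x)
  e / rowSums(e)
}

# --- loss curves --------------------------------------------------------------

#' Evaluate loss curves over a probability grid
#'
#' Tabulates the selected scalar loss at every combination of grid
#' probability, `gamma` and `dv`, suitable for plotting and for ordering
#' checks. The cross-entropy curve ignores both hyper-parameters; the focal
#' curve ignores `dv`.
#'
#' @param loss_kind One of `"ce"`, `"focal"`, `"mfce"`.
#' @param gamma_values,dv_values Numeric vectors of hyper-parameter values.
#' @param grid Probabilities strictly inside `(0, 1)`.
#' @param gate_convention Passed to [loss_params()].
#' @return A data frame with columns `p`, `gamma`, `dv`, `loss`.
#' @export
#' @examples
#' head(loss_curve("mfce", gamma_values = 2, dv_values = c(0.5, 2),
#'                 grid = seq(0.01, 0.99, by = 0.01)))
loss_curve <- function(loss_kind = c("ce", "focal", "mfce"),
                       gamma_values = 2, dv_values = 1,
                       grid = seq(0.001, 0.999, length.out = 999),
                       gate_convention = "multiplicative") {
  loss_kind <- match.arg(loss_kind)
  if (any(grid <= 0 | grid >= 1))
    stop("`grid` values must lie strictly inside (0, 1)", call. = FALSE)
  out <- expand.grid(p = grid, gamma = gamma_values, dv = dv_values,
                     KEEP.OUT.ATTRS = FALSE)
  out$loss <- NA_real_
  for (g in gamma_values) for (d in dv_values) {
    sel <- out$gamma == g & out$dv == d
    pr <- loss_params(gamma = g, dv = d, reduction = "none",
                      gate_convention = gate_convention)
    out$loss[sel] <- loss_core(loss_kind, out$p[sel], pr)
  }
  out
}
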