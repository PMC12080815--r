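#' Training configuration
#'
#' @param learning_rate Adam step size (default 0.001, the reference
#'   setting).
#' @param batch_size Mini-batch size.
#' @param epochs Number of passes over the training data (`>= 1`).
#' @param loss_kind `"ce"`, `"focal"`, or `"mfce"`.
#' @param loss_params A [loss_params()] object.
#' @param seed Integer seed driving every source of randomness in a run:
#'   weight init, the validation split, shuffling, and dropout.
#' @param split `(train, validation, test)` fractions summing to 1. The
#'   dataset layout already separates test images, so the validation share
#'   is carved out of the training split as `split[2] / (split[1] +
#'   split[2])` (the default 80/10/10 takes 1/9 of train).
#' @param kfold Optional fold count for [kfold_cv()].
#' @param optimizer Only `"adam"` is implemented.
#' @param verbose Print a line per epoch.
#' @return An object of class `"train_config"`.
#' @export
train_config <- function(learning_rate = 0.001, batch_size = 32, epochs = 10,
                         loss_kind = c("mfce", "ce", "focal"),
                         loss_params = orchardvit::loss_params(),
                         seed = 1, split = c(0.8, 0.1, 0.1), kfold = NULL,
                         optimizer = "adam", verbose = FALSE) {
  loss_kind <- match.arg(loss_kind)
  optimizer <- match.arg(optimizer)
  if (abs(sum(split) - 1) > 1e-8 || length(split) != 3 || any(split < 0))
    stop("`split` must be three non-negative fractions summing to 1",
         call. = FALSE)
  if (epochs < 1) stop("`epochs` must be >= 1", call. = FALSE)
  if (learning_rate <= 0) stop("`learning_rate` must be positive",
                               call. = FALSE)
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), loss_kind = loss_kind,
                 loss_params = loss_params, seed = as.integer(seed),
                 split = split, kfold = kfold, optimizer = optimizer,
                 verbose = isTRUE(verbose)),
            class = "train_config")
}

# --- Adam ---------------------------------------------------------------------

adam_init <- function(params) {
  zero_like <- lapply(params, function(p) p * 0)
  list(m = zero_like, v = zero_like, t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / c1) / (sqrt(state$v[[nm]] / c2) + eps)
  }
  list(params = params, state = state)
}

# --- core training loop -------------------------------------------------------

# Stratified index split: carves `frac` of each class out as validation.
# Every class with at least two training images keeps at least one image on
# each side, so checkpoint selection never scores on a class-free
# validation set.
stratified_val_split <- function(labels, frac) {
  val <- integer(0)
  if (frac > 0) {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      n_val <- if (length(idx) < 2L) 0L
               else min(length(idx) - 1L, max(1L, floor(frac * length(idx))))
      if (n_val > 0) val <- c(val, sample(idx, n_val))
    }
  }
  list(train = setdiff(seq_along(labels), val), val = sort(val))
}

# Trains on in-memory data: `data` has `images` (list of arrays) and
# `labels` (1-based integer indices). Returns an "oaom_run".
train_on_data <- function(model_config, data, train_cfg, classes = NULL) {
  n_cls <- model_config$num_classes
  if (max(data$labels) > n_cls)
    stop("data contains ", max(data$labels),
         " classes but the model is configured for ", n_cls, call. = FALSE)
  set.seed(train_cfg$seed)
  model <- oaom_init(model_config, classes = classes)
  flat_init <- unlist(model$params, use.names = FALSE)
  init_fingerprint <- c(sum(flat_init), sum(flat_init^2),
                        utils::head(flat_init, 5))
  patch_list <- lapply(data$images, function(im)
    extract_patches(im, model_config)$patches)
  val_frac <- train_cfg$split[2] / (train_cfg$split[1] + train_cfg$split[2])
  sp <- stratified_val_split(data$labels, val_frac)
  lp <- train_cfg$loss_params
  lp$reduction <- "none"
  params <- model$params
  state <- adam_init(params)
  history <- data.frame(epoch = seq_len(train_cfg$epochs), train_loss = NA_real_,
                        train_acc = NA_real_, val_loss = NA_real_,
                        val_acc = NA_real_)
  best <- list(acc = -Inf, epoch = NA_integer_, params = params)
  eval_set <- function(idx, p) {
    if (length(idx) == 0) return(c(NA_real_, NA_real_))
    losses <- numeric(length(idx)); hits <- logical(length(idx))
    for (j in seq_along(idx)) {
      k <- idx[j]
      logits <- oaom_forward_patches(p, patch_list[[k]], model_config)$logits
      losses[j] <- batched_loss(train_cfg$loss_kind, data$labels[k],
                                softmax_rows(matrix(logits, 1)), lp)
      hits[j] <- which.max(logits) == data$labels[k]
    }
    c(mean(losses), mean(hits))
  }
  t0 <- proc.time()[["elapsed"]]
  for (ep in seq_len(train_cfg$epochs)) {
    order <- sample(sp$train)
    ep_loss <- 0; ep_hits <- 0
    for (start in seq(1, length(order), by = train_cfg$batch_size)) {
      batch <- order[start:min(start + train_cfg$batch_size - 1L,
                               length(order))]
      acc_grads <- NULL
      for (k in batch) {
        fw <- oaom_forward_patches(params, patch_list[[k]], model_config,
                                   training = TRUE, keep_cache = TRUE)
        dlogits <- loss_grad_logits(train_cfg$loss_kind, data$labels[k],
                                    matrix(fw$logits, 1), lp)
        g <- oaom_backward(params, fw$cache, drop(dlogits), model_config)
        acc_grads <- if (is.null(acc_grads)) g
                     else Map(`+`, acc_grads, g[names(acc_grads)])
        probs <- softmax_rows(matrix(fw$logits, 1))
        ep_loss <- ep_loss + batched_loss(train_cfg$loss_kind,
                                          data$labels[k], probs, lp)
        ep_hits <- ep_hits + (which.max(fw$logits) == data$labels[k])
      }
      acc_grads <- lapply(acc_grads, `/`, length(batch))
      upd <- adam_step(params, acc_grads, state, train_cfg$learning_rate)
      params <- upd$params; state <- upd$state
    }
    history$train_loss[ep] <- ep_loss / length(order)
    history$train_acc[ep] <- ep_hits / length(order)
    vm <- eval_set(sp$val, params)
    history$val_loss[ep] <- vm[1]; history$val_acc[ep] <- vm[2]
    sel_acc <- if (is.na(vm[2])) history$train_acc[ep] else vm[2]
    if (sel_acc > best$acc + 1e-12) {      # ties keep the earliest epoch
      best <- list(acc = sel_acc, epoch = ep, params = params)
    }
    if (train_cfg$verbose)
      message(sprintf(
        "epoch %3d  train_loss %.4f  train_acc %.4f  val_loss %s  val_acc %s",
        ep, history$train_loss[ep], history$train_acc[ep],
        formatC(vm[1], format = "f", digits = 4),
        formatC(vm[2], format = "f", digits = 4)))
  }
  model$params <- best$params
  structure(list(model = model, history = history,
                 best_epoch = best$epoch,
                 final_params = params,
                 init_fingerprint = init_fingerprint,
                 train_config = train_cfg,
                 seed = train_cfg$seed,
                 wall_clock = proc.time()[["elapsed"]] - t0),
            class = "oaom_run")
}

#' @export
print.oaom_run <- function(x, ...) {
  h <- x$history
  cat(sprintf(
    "<oaom_run> %d epochs (%s loss), best epoch %d; final train acc %.4f\n",
    nrow(h), x$train_config$loss_kind, x$best_epoch,
    h$train_acc[nrow(h)]))
  if (!is.null(x$test_report))
    cat(sprintf("test accuracy %.4f\n", x$test_report$accuracy))
  invisible(x)
}

#' Train a classifier on a dataset directory
#'
#' Minimises the configured batched loss with Adam over the `train/` split
#' of a directory-per-class dataset (the [generate_dataset()] layout). A
#' stratified validation subset is carved from the training images per
#' `train_config$split`; the checkpoint kept is the one with the best
#' validation accuracy (ties broken by the earliest epoch). Every source of
#' randomness — weight initialisation, the validation split, shuffling,
#' dropout — derives from `train_config$seed`, so identical configurations
#' reproduce identical runs.
#'
#' @param model_config An [oaom_config()].
#' @param data_dir Dataset root containing `train/` (and optionally
#'   `test/`, which is evaluated with the best checkpoint).
#' @param train_cfg A [train_config()].
#' @param checkpoint Optional path; the best model is saved there with
#'   [save_oaom()].
#' @return An object of class `"oaom_run"`: the best `model`, the per-epoch
#'   `history` (`epoch, train_loss, train_acc, val_loss, val_acc`),
#'   `best_epoch`, the config snapshot, and (when `test/` exists) a
#'   `test_report` [class_report()].
#' @export
oaom_train <- function(model_config, data_dir, train_cfg = train_config(),
                       checkpoint = NULL) {
  data <- load_image_dataset(data_dir, "train")
  if (length(data$classes) != model_config$num_classes)
    stop("dataset has ", length(data$classes),
         " classes but `model_config$num_classes` is ",
         model_config$num_classes, call. = FALSE)
  run <- train_on_data(model_config, data, train_cfg, classes = data$classes)
  if (dir.exists(file.path(data_dir, "test")))
    run$test_report <- evaluate(run$model, data_dir, "test")
  if (!is.null(checkpoint)) save_oaom(run$model, checkpoint)
  run
}

# In-memory evaluation helper shared by evaluate() and kfold_cv().
evaluate_on_data <- function(model, data) {
  probs <- predict(model, data$images)
  pred <- max.col(probs, ties.method = "first")
  class_report(confusion(data$labels, pred, model$config$num_classes,
                         labels = model$classes))
}

#' Evaluate a model (or checkpoint) on a dataset split
#'
#' Inference mode: dropout off. Delegates metric computation to
#' [class_report()].
#'
#' @param model An `oaom_model`, an `oaom_run`, or a checkpoint path.
#' @param data_dir Dataset root in the directory-per-class layout.
#' @param split `"train"` or `"test"`.
#' @return A [class_report()].
#' @export
evaluate <- function(model, data_dir, split = c("test", "train")) {
  split <- match.arg(split)
  if (is.character(model)) model <- load_oaom(model)
  if (inherits(model, "oaom_run")) model <- model$model
  data <- load_image_dataset(data_dir, split)
  if (length(data$classes) != model$config$num_classes)
    stop("class count mismatch between checkpoint and data", call. = FALSE)
  evaluate_on_data(model, data)
}

#' Write a run's per-epoch history as CSV
#'
#' @param run An `oaom_run`.
#' @param path Output file.
#' @export
write_history <- function(run, path) {
  utils::write.csv(run$history, path, row.names = FALSE)
  invisible(path)
}

# --- k-fold cross-validation --------------------------------------------------

# Stratified fold labels: per class, shuffled indices dealt round-robin, so
# per-fold class proportions stay within one sample of the global ones.
stratified_folds <- function(labels, k) {
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    if (length(idx) < k)
      stop("class ", cl, " has fewer than k = ", k, " samples",
           call. = FALSE)
    fold[sample(idx)] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Stratified k-fold cross-validation
#'
#' Pools the dataset's train and test images, partitions them into `k`
#' stratified folds, and trains `k` models, each evaluated on its held-out
#' fold. The summary averages the per-fold reports.
#'
#' @param model_config An [oaom_config()].
#' @param data_dir Dataset root.
#' @param train_cfg A [train_config()] with `kfold = k >= 2`.
#' @return A list with `runs` (per-fold `oaom_run`s), `reports` (per-fold
#'   [class_report()]s), `folds` (fold assignment), and `summary` (a data
#'   frame of per-fold accuracy / macro-F1 / weighted-F1 plus mean and sd
#'   rows).
#' @export
kfold_cv <- function(model_config, data_dir, train_cfg) {
  k <- train_cfg$kfold
  if (is.null(k) || k < 2) stop("`train_cfg$kfold` must be >= 2",
                                call. = FALSE)
  tr <- load_image_dataset(data_dir, "train")
  te <- if (dir.exists(file.path(data_dir, "test")))
    load_image_dataset(data_dir, "test") else NULL
  images <- c(tr$images, if (!is.null(te)) te$images)
  labels <- c(tr$labels, if (!is.null(te)) te$labels)
  set.seed(train_cfg$seed)
  folds <- stratified_folds(labels, k)
  runs <- vector("list", k); reports <- vector("list", k)
  for (i in seq_len(k)) {
    hold <- folds == i
    fold_cfg <- train_cfg
    fold_cfg$seed <- train_cfg$seed + i
    run <- train_on_data(model_config,
                         list(images = images[!hold], labels = labels[!hold]),
                         fold_cfg, classes = tr$classes)
    reports[[i]] <- evaluate_on_data(run$model,
                                     list(images = images[hold],
                                          labels = labels[hold]))
    runs[[i]] <- run
  }
  per_fold <- data.frame(
    fold = as.character(seq_len(k)),
    accuracy = vapply(reports, function(r) r$accuracy, numeric(1)),
    macro_f1 = vapply(reports, function(r) r$macro_avg$f1, numeric(1)),
    weighted_f1 = vapply(reports, function(r) r$weighted_avg$f1, numeric(1)))
  summary <- rbind(per_fold,
                   data.frame(fold = "mean", t(colMeans(per_fold[-1]))),
                   data.frame(fold = "sd",
                              t(apply(per_fold[-1], 2, stats::sd))))
  list(runs = runs, reports = reports, folds = folds, summary = summary)
}

# --- imbalance experiment -----------------------------------------------------

#' Paired loss-comparison experiment on an imbalanced design
#'
#' The evidence surface for the minority-class claim behind the MFCE loss:
#' on a class-imbalanced synthetic design, each loss kind is trained under
#' identical conditions — the same per-seed dataset and the same parameter
#' initialisation (all loss kinds share `train_cfg$seed`, and the loss
#' choice consumes no randomness) — and minority-class recall/F1, macro-F1
#' and accuracy are tabulated per `(loss_kind, seed)` with seed-averaged
#' rows appended. When `include_control = TRUE`, a `ce_control` arm reruns
#' cross-entropy with an independently derived training seed, so the
#' ce-vs-ce_control differences measure pure seed noise (centred at zero).
#'
#' @param design An [imbalance_design()] (must mark at least one minority
#'   class).
#' @param loss_kinds At least two of `"ce"`, `"focal"`, `"mfce"`.
#' @param seeds Integer vector of experiment seeds (datasets and training
#'   are re-drawn per seed).
#' @param model_config An [oaom_config()]; defaults to a tiny 2-layer
#'   transformer suited to the design's image size.
#' @param train_cfg A [train_config()]; its `seed`/`loss_kind` fields are
#'   overridden per run.
#' @param include_control Add the `ce_control` arm.
#' @return A data frame with columns `loss_kind`, `seed`, `accuracy`,
#'   `minority_recall`, `minority_f1`, `macro_f1`; averaged rows have
#'   `seed = NA`.
#' @export
imbalance_experiment <- function(design, loss_kinds = c("ce", "mfce"),
                                 seeds = 1:5, model_config = NULL,
                                 train_cfg = train_config(
                                   epochs = 30, batch_size = 16,
                                   loss_params = loss_params(gamma = 2,
                                                             dv = 1)),
                                 include_control = TRUE) {
  if (is.null(design$minority) || !any(design$minority))
    stop("`design` must mark at least one minority class", call. = FALSE)
  if (length(loss_kinds) < 2)
    stop("need at least two loss kinds to compare", call. = FALSE)
  if (is.null(model_config))
    model_config <- oaom_config(
      num_classes = length(design$classes),
      image_size = design$image_size, patch_size = 8,
      hidden_size = 32, num_layers = 2, num_heads = 2, mlp_size = 64,
      head_widths = 32, dropout_rate = 0)
  arms <- data.frame(kind = loss_kinds, seed_offset = 0L)
  if (include_control)
    arms <- rbind(arms, data.frame(kind = "ce", seed_offset = 104729L))
  arms$label <- ifelse(arms$seed_offset > 0, paste0(arms$kind, "_control"),
                       arms$kind)
  rows <- list()
  minority_idx <- which(design$minority)
  for (s in seeds) {
    data <- synth_data(design, s)
    for (a in seq_len(nrow(arms))) {
      cfg <- train_cfg
      cfg$loss_kind <- arms$kind[a]
      cfg$seed <- as.integer(s + arms$seed_offset[a])
      run <- train_on_data(model_config, data$train, cfg,
                           classes = design$classes)
      rep <- evaluate_on_data(run$model, data$test)
      rows[[length(rows) + 1L]] <- data.frame(
        loss_kind = arms$label[a], seed = s, accuracy = rep$accuracy,
        minority_recall = mean(rep$per_class$recall[minority_idx]),
        minority_f1 = mean(rep$per_class$f1[minority_idx]),
        macro_f1 = rep$macro_avg$f1)
    }
  }
  out <- do.call(rbind, rows)
  means <- do.call(rbind, lapply(split(out, out$loss_kind), function(d)
    data.frame(loss_kind = d$loss_kind[1], seed = NA_integer_,
               accuracy = mean(d$accuracy),
               minority_recall = mean(d$minority_recall),
               minority_f1 = mean(d$minority_f1),
               macro_f1 = mean(d$macro_f1))))
  rownames(means) <- NULL
  rbind(out, means)
}

# --- checkpoints --------------------------------------------------------------

#' Save / load a model checkpoint
#'
#' Checkpoints are a self-describing serialised container holding the
#' configuration, every weight array, and the class labels; loading
#' restores a model that predicts identically.
#'
#' @param model An `oaom_model`.
#' @param path File path (`.rds`).
#' @return `save_oaom()` returns `path` invisibly; `load_oaom()` returns
#'   the restored `oaom_model`.
#' @export
save_oaom <- function(model, path) {
  stopifnot(inherits(model, "oaom_model"))
  saveRDS(list(config = model$config, params = model$params,
               n_patches = model$n_patches, classes = model$classes,
               format = "orchardvit-checkpoint-1"), path)
  invisible(path)
}

#' @rdname save_oaom
#' @export
load_oaom <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "orchardvit-checkpoint-1"))
    stop("not an orchardvit checkpoint: ", path, call. = FALSE)
  structure(obj[c("config", "params", "n_patches", "classes")],
            class = "oaom_model")
}

# --- config files -------------------------------------------------------------

#' Read a run configuration from a YAML file
#'
#' The file has up to four sections: `model` (arguments of
#' [oaom_config()]), `loss` (arguments of [loss_params()]), `train`
#' (arguments of [train_config()]), and `data` (free-form; typically `dir`
#' and/or `preset`). The loss section is attached to the training config as
#' its `loss_params`.
#'
#' @param path YAML file path.
#' @return A list with `model_config`, `train_cfg`, and `data`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  model_config <- do.call(oaom_config, cfg$model)
  lp <- if (is.null(cfg$loss)) loss_params() else do.call(loss_params, cfg$loss)
  train_args <- if (is.null(cfg$train)) list() else cfg$train
  if (!is.null(train_args$split)) train_args$split <- unlist(train_args$split)
  train_args$loss_params <- lp
  list(model_config = model_config,
       train_cfg = do.call(train_config, train_args),
       data = cfg$data)
}
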