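#' Pairwise sequence identity
#'
#' Matched columns divided by the length of the global alignment
#' ([global_align()] scoring).
#'
#' @param a,b Amino-acid strings.
#' @param match,mismatch,gap Alignment scores.
#' @return Fraction in `[0, 1]`.
#' @export
pairwise_identity <- function(a, b, match = 2, mismatch = -1, gap = -2) {
  if (nchar(a) == 0L || nchar(b) == 0L) stop("sequences must be non-empty")
  .nw_identity_cpp(a, b, match, mismatch, gap)
}

#' Split specification
#'
#' Train/validation/test proportions (default 8:1:1) plus the redundancy
#' filter: after splitting, any validation or test sequence with at least
#' `identity_threshold` identity to some training sequence is dropped.
#'
#' @param fractions Numeric length-3 vector summing to 1.
#' @param identity_threshold Identity above which a val/test sequence is
#'   considered redundant with train (default 0.9).
#' @param seed Integer seed.
#' @return A `split_spec` object.
#' @export
split_spec <- function(fractions = c(train = 0.8, val = 0.1, test = 0.1),
                       identity_threshold = 0.9, seed = 1L) {
  if (abs(sum(fractions) - 1) > 1e-9) stop("fractions must sum to 1")
  structure(list(fractions = fractions,
                 identity_threshold = identity_threshold,
                 seed = as.integer(seed)),
            class = "split_spec")
}

#' Split records 8:1:1 with an identity filter
#'
#' Randomly partitions the records into train/val/test at the spec's
#' proportions (sizes within one of the exact proportions), then removes
#' val/test records too similar to any train record. The filter applies
#' between train and (val, test) only, not within train.
#'
#' @param records Data frame with a `sequence` column.
#' @param spec A [split_spec()].
#' @param filter Apply the identity filter (default `TRUE`).
#' @return List `train`, `val`, `test` (data frames) plus `n_filtered`.
#' @export
split_with_identity_filter <- function(records, spec = split_spec(),
                                       filter = TRUE) {
  n <- nrow(records)
  if (n < 10L) stop("need at least 10 records to split")
  withr::local_seed(spec$seed)
  perm <- sample.int(n)
  n_val <- round(n * spec$fractions[2])
  n_test <- round(n * spec$fractions[3])
  val_idx <- perm[seq_len(n_val)]
  test_idx <- perm[n_val + seq_len(n_test)]
  train_idx <- perm[-(seq_len(n_val + n_test))]
  train <- records[train_idx, , drop = FALSE]
  val <- records[val_idx, , drop = FALSE]
  test <- records[test_idx, , drop = FALSE]
  n_filtered <- 0L
  if (filter) {
    keep_v <- .max_identity_cpp(val$sequence, train$sequence, 2, -1, -2) <
      spec$identity_threshold
    keep_t <- .max_identity_cpp(test$sequence, train$sequence, 2, -1, -2) <
      spec$identity_threshold
    n_filtered <- sum(!keep_v) + sum(!keep_t)
    if (n_filtered > 0L)
      message(n_filtered, " val/test record(s) dropped by the ",
              spec$identity_threshold, " identity filter")
    val <- val[keep_v, , drop = FALSE]
    test <- test[keep_t, , drop = FALSE]
    if (nrow(val) == 0L || nrow(test) == 0L)
      stop("identity filter emptied the validation or test split; ",
           "raise identity_threshold or change the seed")
  }
  list(train = train, val = val, test = test, n_filtered = n_filtered)
}

#' Target scaling to [0, 1]
#'
#' Min-max scaler fitted on the training targets only.
#'
#' @param values Numeric training targets.
#' @return A `target_scaler` with `observed_min`, `observed_max`.
#' @export
target_scaler <- function(values) {
  if (diff(range(values)) == 0) stop("targets have zero range")
  structure(list(observed_min = min(values), observed_max = max(values)),
            class = "target_scaler")
}

#' @rdname target_scaler
#' @param scaler A `target_scaler`.
#' @param t Values to (un)scale.
#' @export
scale_targets <- function(scaler, t) {
  (t - scaler$observed_min) / (scaler$observed_max - scaler$observed_min)
}

#' @rdname target_scaler
#' @export
unscale_targets <- function(scaler, t) {
  t * (scaler$observed_max - scaler$observed_min) + scaler$observed_min
}

#' Pearson correlation
#'
#' @param x,y Numeric vectors of equal length (at least 3) with non-zero
#'   variance.
#' @return Product-moment correlation in `[-1, 1]`.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero variance input")
  stats::cor(x, y)
}

#' Dense head configuration
#'
#' A four-layer dense network on the pooled encoder representation:
#' three hidden ReLU layers plus an output layer, with sigmoid output +
#' binary cross-entropy for classification or linear output + mean squared
#' error for regression (the pairing is enforced).
#'
#' @param task `"classify"` (sigmoid/BCE) or `"regress"` (linear/MSE).
#' @param hidden_dims Three hidden sizes; default
#'   `(d, d/2, d/4)` resolved from the encoder at training time.
#' @param seed Integer seed for head initialization.
#' @return A `head_config` object.
#' @export
head_config <- function(task = c("classify", "regress"), hidden_dims = NULL,
                        seed = 1L) {
  task <- match.arg(task)
  if (!is.null(hidden_dims) && length(hidden_dims) != 3L)
    stop("hidden_dims must have length 3 (four dense layers in total)")
  structure(list(task = task,
                 output_activation = if (task == "classify") "sigmoid" else "linear",
                 loss = if (task == "classify") "bce" else "mse",
                 hidden_dims = hidden_dims, seed = as.integer(seed)),
            class = "head_config")
}

.init_head <- function(d, hidden, seed) {
  withr::local_seed(seed)
  dims <- c(d, hidden, 1L)
  p <- list()
  for (l in 1:4) {
    sd <- sqrt(2 / dims[l])
    p[[sprintf("H%d.W", l)]] <- matrix(stats::rnorm(dims[l] * dims[l + 1], sd = sd),
                                       dims[l], dims[l + 1])
    p[[sprintf("H%d.b", l)]] <- rep(0, dims[l + 1])
  }
  p
}

.head_forward <- function(hp, P) {
  A <- P
  cache <- list(A0 = P)
  for (l in 1:3) {
    Z <- .affine(A, hp[[sprintf("H%d.W", l)]], hp[[sprintf("H%d.b", l)]])
    A <- pmax(Z, 0)
    cache[[sprintf("Z%d", l)]] <- Z
    cache[[sprintf("A%d", l)]] <- A
  }
  out <- .affine(A, hp[["H4.W"]], hp[["H4.b"]])
  cache$out <- drop(out)
  cache
}

.head_backward <- function(hp, cache, dout) {
  g <- list()
  dA <- matrix(dout, ncol = 1L)
  g[["H4.W"]] <- crossprod(cache$A3, dA)
  g[["H4.b"]] <- colSums(dA)
  dA <- dA %*% t(hp[["H4.W"]])
  for (l in 3:1) {
    dZ <- dA * (cache[[sprintf("Z%d", l)]] > 0)
    g[[sprintf("H%d.W", l)]] <- crossprod(cache[[sprintf("A%d", l - 1)]] %||%
                                            cache$A0, dZ)
    g[[sprintf("H%d.b", l)]] <- colSums(dZ)
    dA <- dZ %*% t(hp[[sprintf("H%d.W", l)]])
  }
  list(grads = g, dP = dA)
}

.sigmoid <- function(x) 1 / (1 + exp(-x))

# Mean-pool the final hidden states over residue positions (CLS/SEP/PAD
# excluded). ids: B x Lt; h: (B*Lt) x d. Returns B x d.
.pool_mean <- function(h, ids) {
  B <- nrow(ids); Lt <- ncol(ids)
  keep <- t(ids) <= 20L | t(ids) == .special_id("UNK")  # Lt x B, batch-major
  grp <- rep(seq_len(B), each = Lt)
  sel <- as.vector(keep)
  P <- rowsum(h[sel, , drop = FALSE], grp[sel])
  P / colSums(keep)
}

# One fine-tuning run: trains the head (and optionally the encoder) with
# Adam, tracks validation loss per epoch and returns the best-epoch model.
.finetune_run <- function(model, head_cfg, train_seqs, train_y, val_seqs,
                          val_y, epochs = 12L, batch_size = 32L, lr = 1e-3,
                          freeze_encoder = FALSE, encoder_lr_scale = 0.3,
                          head_warmup_epochs = 10L, seed = 1L) {
  cfg <- model$config
  d <- cfg$embedding_dim
  hidden <- head_cfg$hidden_dims %||% c(d, max(2L, d %/% 2L), max(2L, d %/% 4L))
  hp <- .init_head(d, hidden, seed + head_cfg$seed)
  ep_params <- model$params
  st_head <- .adam_new(hp)
  st_enc <- if (!freeze_encoder) .adam_new(ep_params) else NULL
  withr::local_seed(seed)
  classify <- head_cfg$task == "classify"
  # frozen encoder: cache pooled representations once
  pool_cache <- NULL
  pool_of <- function(seqs, params) {
    groups <- .length_batches(seqs, 256L)
    P <- matrix(0, length(seqs), d)
    for (gidx in groups) {
      ids <- .tokenize_matrix(seqs[gidx])
      fw <- .encoder_forward(params, cfg, ids, train = FALSE)
      P[gidx, ] <- .pool_mean(fw$h, ids)
    }
    P
  }
  val_pool_cache <- NULL
  if (freeze_encoder) {
    pool_cache <- pool_of(train_seqs, ep_params)
    val_pool_cache <- pool_of(val_seqs, ep_params)
  }
  eval_loss <- function(params, hp) {
    P <- if (!is.null(val_pool_cache)) val_pool_cache else
      pool_of(val_seqs, params)
    fc <- .head_forward(hp, P)
    if (classify) {
      p <- .sigmoid(fc$out)
      -mean(val_y * log(pmax(p, 1e-12)) + (1 - val_y) * log(pmax(1 - p, 1e-12)))
    } else mean((fc$out - val_y)^2)
  }
  best <- list(loss = Inf, hp = hp, params = ep_params)
  batches <- .length_batches(train_seqs, batch_size)
  # Two-stage protocol: the randomly initialized head is first trained
  # against the frozen encoder (cheap: pooled features cached), so that
  # joint training starts from a sensible head instead of tearing up the
  # pre-trained representation with gradients from random head weights.
  if (!freeze_encoder && head_warmup_epochs > 0L) {
    wtrain <- pool_of(train_seqs, ep_params)
    wval <- pool_of(val_seqs, ep_params)
    for (ep in seq_len(head_warmup_epochs)) {
      for (bi in sample.int(length(batches))) {
        idx <- batches[[bi]]
        fc <- .head_forward(hp, wtrain[idx, , drop = FALSE])
        y <- train_y[idx]
        dout <- if (classify) (.sigmoid(fc$out) - y) / length(y) else
          2 * (fc$out - y) / length(y)
        hb <- .head_backward(hp, fc, dout)
        upd <- .adam_step(hp, hb$grads, st_head, lr)
        hp <- upd$params; st_head <- upd$state
      }
    }
    fcv <- .head_forward(hp, wval)
    vl0 <- if (classify) {
      pv <- .sigmoid(fcv$out)
      -mean(val_y * log(pmax(pv, 1e-12)) +
              (1 - val_y) * log(pmax(1 - pv, 1e-12)))
    } else mean((fcv$out - val_y)^2)
    if (is.finite(vl0)) best <- list(loss = vl0, hp = hp, params = ep_params)
  }
  total_steps <- length(batches) * epochs
  step <- 0L
  for (ep in seq_len(epochs)) {
    for (bi in sample.int(length(batches))) {
      idx <- batches[[bi]]
      y <- train_y[idx]
      if (freeze_encoder) {
        P <- pool_cache[idx, , drop = FALSE]
      } else {
        ids <- .tokenize_matrix(train_seqs[idx])
        fw <- .encoder_forward(ep_params, cfg, ids, train = cfg$dropout > 0)
        P <- .pool_mean(fw$h, ids)
      }
      fc <- .head_forward(hp, P)
      dout <- if (classify) (.sigmoid(fc$out) - y) / length(y) else
        2 * (fc$out - y) / length(y)
      hb <- .head_backward(hp, fc, dout)
      step <- step + 1L
      lr_t <- .lr_at(step, total_steps, lr, warmup_frac = 0.05)
      upd <- .adam_step(hp, hb$grads, st_head, lr_t)
      hp <- upd$params; st_head <- upd$state
      if (!freeze_encoder) {
        # distribute pooled gradient back over residue rows
        B <- nrow(ids); Lt <- ncol(ids)
        keep <- t(ids) <= 20L | t(ids) == .special_id("UNK")
        cnt <- colSums(keep)
        dH <- matrix(0, B * Lt, d)
        sel <- as.vector(keep)
        grp <- rep(seq_len(B), each = Lt)
        dH[sel, ] <- hb$dP[grp[sel], , drop = FALSE] / cnt[grp[sel]]
        genc <- .encoder_backward(ep_params, cfg, fw$cache, dH)
        upd2 <- .adam_step(ep_params, genc, st_enc, lr_t * encoder_lr_scale)
        ep_params <- upd2$params; st_enc <- upd2$state
      }
    }
    vl <- eval_loss(ep_params, hp)
    if (is.finite(vl) && vl < best$loss)
      best <- list(loss = vl, hp = hp, params = ep_params)
  }
  pred_fun <- function(seqs) {
    P <- pool_of(seqs, best$params)
    out <- .head_forward(best$hp, P)$out
    if (classify) .sigmoid(out) else out
  }
  list(predict = pred_fun, val_loss = best$loss)
}

.auc_roc <- function(scores, labels) {
  .rank_auc_lower(scores[labels == 0], scores[labels == 1])
}

.auc_pr <- function(scores, labels) {
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]
  tp <- cumsum(lab)
  prec <- tp / seq_along(lab)
  sum(prec[lab == 1]) / sum(lab)  # average precision
}

#' Fine-tune a binary species classifier
#'
#' Adds the four-layer dense head (sigmoid output, binary cross-entropy) on
#' the mean-pooled encoder representation and trains it — by default
#' updating the encoder too — with the best-validation-epoch model scored
#' on the held-out test split.
#'
#' @param model A (typically pre-trained) [mlm_model()].
#' @param records Data frame with `sequence` and `label` (0/1) columns.
#' @param head A [head_config()] for classification.
#' @param spec A [split_spec()].
#' @param epochs,batch_size,lr Training hyper-parameters.
#' @param freeze_encoder Train the head only.
#' @param encoder_lr_scale Encoder learning rate as a fraction of the head
#'   rate; small values protect the pre-trained representation.
#' @param seed Integer seed.
#' @return List with `roc_auc`, `pr_auc`, `test_scores`, `test_labels`,
#'   `splits`.
#' @export
finetune_classifier <- function(model, records, head = head_config("classify"),
                                spec = split_spec(), epochs = 8L,
                                batch_size = 32L, lr = 1e-3,
                                freeze_encoder = FALSE,
                                encoder_lr_scale = 0.1, seed = 1L) {
  if (head$task != "classify") stop("head must be a classification head")
  sp <- split_with_identity_filter(records, spec, filter = FALSE)
  for (part in sp[c("train", "val", "test")])
    if (length(unique(part$label)) < 2L)
      stop("both classes must be present in every split")
  run <- .finetune_run(model, head, sp$train$sequence, sp$train$label,
                       sp$val$sequence, sp$val$label, epochs = epochs,
                       batch_size = batch_size, lr = lr,
                       freeze_encoder = freeze_encoder,
                       encoder_lr_scale = encoder_lr_scale, seed = seed)
  sc <- run$predict(sp$test$sequence)
  list(roc_auc = .auc_roc(sc, sp$test$label),
       pr_auc = .auc_pr(sc, sp$test$label),
       test_scores = sc, test_labels = sp$test$label, splits = sp)
}

#' Fine-tune a thermostability regressor
#'
#' Targets are min-max scaled to `[0, 1]` on the training split; the
#' four-layer head (linear output, MSE) is trained `repeats` times with
#' distinct seeds on a fixed split, and the test Pearson correlation is
#' reported per repeat with its mean and SD.
#'
#' @param model A (typically pre-trained) [mlm_model()].
#' @param records Data frame with `sequence` and `value` columns.
#' @param head A [head_config()] for regression.
#' @param spec A [split_spec()] (identity filter applied).
#' @param repeats Number of fine-tuning repetitions.
#' @param epochs,batch_size,lr Training hyper-parameters.
#' @param freeze_encoder Train the head only.
#' @param encoder_lr_scale Encoder learning rate as a fraction of the head
#'   rate; small values protect the pre-trained representation.
#' @param seed Integer seed.
#' @return List with `per_repeat_r`, `mean_r`, `sd_r`, `splits`.
#' @export
finetune_regressor <- function(model, records, head = head_config("regress"),
                               spec = split_spec(), repeats = 5L,
                               epochs = 12L, batch_size = 32L, lr = 1e-3,
                               freeze_encoder = FALSE,
                               encoder_lr_scale = 0.1, seed = 1L) {
  if (head$task != "regress") stop("head must be a regression head")
  if (nrow(records) < 50L) stop("need at least 50 labelled records")
  if (stats::sd(records$value) == 0) stop("targets have zero variance")
  sp <- split_with_identity_filter(records, spec, filter = TRUE)
  scaler <- target_scaler(sp$train$value)
  rs <- numeric(repeats)
  for (k in seq_len(repeats)) {
    run <- .finetune_run(model, head, sp$train$sequence,
                         scale_targets(scaler, sp$train$value),
                         sp$val$sequence, scale_targets(scaler, sp$val$value),
                         epochs = epochs, batch_size = batch_size, lr = lr,
                         freeze_encoder = freeze_encoder,
                         encoder_lr_scale = encoder_lr_scale, seed = seed + k)
    pred <- run$predict(sp$test$sequence)
    rs[k] <- pearson(pred, sp$test$value)
  }
  list(per_repeat_r = rs, mean_r = mean(rs), sd_r = stats::sd(rs),
       splits = sp, scaler = scaler)
}

#' Uniform-random prediction baseline
#'
#' Predictions drawn i.i.d. from Uniform(0, 1), correlated against the
#' targets; repeated to produce the mean/SD format of the fine-tuning
#' reports.
#'
#' @param targets Numeric test targets.
#' @param repeats Number of repetitions.
#' @param seed Integer seed.
#' @return List with `per_repeat_r`, `mean_r`, `sd_r`, `scores` (last
#'   repeat's predictions).
#' @export
random_baseline <- function(targets, repeats = 5L, seed = 1L) {
  withr::local_seed(seed)
  rs <- numeric(repeats)
  sc <- NULL
  for (k in seq_len(repeats)) {
    sc <- stats::runif(length(targets))
    rs[k] <- pearson(sc, targets)
  }
  list(per_repeat_r = rs, mean_r = mean(rs), sd_r = stats::sd(rs),
       scores = sc)
}
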