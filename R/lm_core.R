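#' Encoder configuration
#'
#' Architecture hyper-parameters for the bidirectional encoder. Three named
#' presets are provided: `"tiny"` (2 layers, embedding 32) is the desk-scale
#' default used throughout the test suite; `"small"` (10 layers, embedding
#' 320, ~12.4M parameters) and `"big"` (12 layers, embedding 768, ~85M
#' parameters) match the published model scales and exist for users with the
#' compute to train them.
#'
#' @param preset One of `"tiny"`, `"small"`, `"big"`, or `NULL` to set all
#'   fields explicitly.
#' @param n_layers,n_heads,embedding_dim,feedforward_dim Integers; the usual
#'   transformer shape parameters. `embedding_dim` must be divisible by
#'   `n_heads`.
#' @param max_positions Maximum tokenized length (sequence + CLS/SEP).
#' @param dropout Dropout probability applied during training only.
#' @param seed Integer seed controlling parameter initialization.
#' @return An `encoder_config` list.
#' @export
encoder_config <- function(preset = "tiny", n_layers = NULL, n_heads = NULL,
                           embedding_dim = NULL, feedforward_dim = NULL,
                           max_positions = 160L, dropout = 0, seed = 1L) {
  base <- switch(
    preset %||% "custom",
    tiny  = list(n_layers = 2L, n_heads = 2L, embedding_dim = 32L,
                 feedforward_dim = 64L),
    small = list(n_layers = 10L, n_heads = 8L, embedding_dim = 320L,
                 feedforward_dim = 1280L),
    big   = list(n_layers = 12L, n_heads = 12L, embedding_dim = 768L,
                 feedforward_dim = 3072L),
    custom = list(n_layers = n_layers, n_heads = n_heads,
                  embedding_dim = embedding_dim,
                  feedforward_dim = feedforward_dim),
    stop("unknown preset: ", preset)
  )
  cfg <- list(
    n_layers = as.integer(n_layers %||% base$n_layers),
    n_heads = as.integer(n_heads %||% base$n_heads),
    embedding_dim = as.integer(embedding_dim %||% base$embedding_dim),
    feedforward_dim = as.integer(feedforward_dim %||% base$feedforward_dim),
    max_positions = as.integer(max_positions),
    dropout = dropout,
    seed = as.integer(seed)
  )
  if (cfg$embedding_dim %% cfg$n_heads != 0L)
    stop("embedding_dim must be divisible by n_heads")
  if (cfg$max_positions < 160L)
    stop("max_positions must be at least 160")
  if (dropout < 0 || dropout >= 1) stop("dropout must be in [0, 1)")
  structure(cfg, class = "encoder_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Masking policy for masked-language-model training
#'
#' Per training example, `ceiling(mask_fraction * n_residues)` residue
#' positions (never CLS/SEP/PAD, at least one) are selected without
#' replacement; each selected position is replaced by `[MASK]` with
#' probability `replace_with_mask`, by a random residue with
#' `replace_with_random`, or left unchanged with `keep_original`. The
#' defaults are the standard BERT corruption scheme (15%, 80/10/10).
#'
#' @param mask_fraction Fraction of residue positions to label.
#' @param replace_with_mask,replace_with_random,keep_original Corruption
#'   fractions; must sum to 1.
#' @param seed Integer seed.
#' @return A `mask_policy` list.
#' @export
mask_policy <- function(mask_fraction = 0.15, replace_with_mask = 0.8,
                        replace_with_random = 0.1, keep_original = 0.1,
                        seed = 1L) {
  s <- replace_with_mask + replace_with_random + keep_original
  if (abs(s - 1) > 1e-9) stop("corruption fractions must sum to 1")
  if (mask_fraction < 0 || mask_fraction > 1)
    stop("mask_fraction must be in [0, 1]")
  structure(list(mask_fraction = mask_fraction,
                 replace_with_mask = replace_with_mask,
                 replace_with_random = replace_with_random,
                 keep_original = keep_original,
                 seed = as.integer(seed)),
            class = "mask_policy")
}

#' Apply MLM corruption to a token batch
#'
#' @param batch Integer matrix (sequences x tokens) from the tokenizer.
#' @param policy A [mask_policy()].
#' @param seed Optional seed overriding `policy$seed`.
#' @return List with `corrupted` (matrix like `batch`), `rows` (indices of
#'   labelled positions in batch-major (B*L) layout) and `targets` (original
#'   token ids at those positions).
#' @export
apply_mask <- function(batch, policy, seed = NULL) {
  withr::local_seed(seed %||% policy$seed)
  B <- nrow(batch); L <- ncol(batch)
  corrupted <- batch
  rows <- integer(0); targets <- integer(0)
  for (b in seq_len(B)) {
    maskable <- which(batch[b, ] <= 20L)
    k <- max(1L, ceiling(policy$mask_fraction * length(maskable)))
    sel <- if (length(maskable) == 1L) maskable else
      sample(maskable, min(k, length(maskable)))
    u <- stats::runif(length(sel))
    new <- batch[b, sel]
    is_mask <- u < policy$replace_with_mask
    is_rand <- !is_mask & u < policy$replace_with_mask + policy$replace_with_random
    new[is_mask] <- .special_id("MASK")
    if (any(is_rand)) new[is_rand] <- sample.int(20L, sum(is_rand), replace = TRUE)
    corrupted[b, sel] <- new
    rows <- c(rows, (b - 1L) * L + sel)
    targets <- c(targets, batch[b, sel])
  }
  list(corrupted = corrupted, rows = rows, targets = targets)
}

#' Instantiate an untrained masked language model
#'
#' @param config An [encoder_config()].
#' @return An `mlm_model` with fields `config`, `params`, `vocab`.
#' @export
mlm_model <- function(config = encoder_config("tiny")) {
  withr::local_seed(config$seed)
  structure(list(config = config, params = .init_params(config),
                 vocab = aa_vocabulary()),
            class = "mlm_model")
}

#' @export
print.mlm_model <- function(x, ...) {
  cat(sprintf("<mlm_model> %d layers, %d heads, embedding %d, %s parameters\n",
              x$config$n_layers, x$config$n_heads, x$config$embedding_dim,
              format(.param_count(x$params), big.mark = ",")))
  invisible(x)
}

# Group sequence indices into equal-length batches (attention needs no
# padding this way; PAD handling exists but is never exercised in training).
.length_batches <- function(seqs, batch_size) {
  by_len <- split(seq_along(seqs), nchar(seqs))
  out <- list()
  for (idx in by_len) {
    nb <- ceiling(length(idx) / batch_size)
    grp <- rep(seq_len(nb), length.out = length(idx))
    out <- c(out, split(idx, grp))
  }
  out
}

#' Train a masked language model
#'
#' Standard MLM training: cross-entropy over corrupted positions only, AdamW
#' with linear warmup/decay, dynamic re-masking each epoch, and a held-out
#' validation fraction scored per epoch.
#'
#' @param model An [mlm_model()].
#' @param corpus Character vector of amino-acid sequences, or a repertoire
#'   data frame with a `sequence` column.
#' @param policy A [mask_policy()].
#' @param epochs,batch_size,lr Training hyper-parameters.
#' @param val_fraction Fraction of the corpus held out for validation
#'   (default 1%, at least one sequence when the corpus has two or more).
#' @param seed Integer seed for shuffling, masking and dropout.
#' @param verbose Print one line per epoch.
#' @return The trained `mlm_model`, with a `history` data frame attached
#'   (`epoch`, `train_loss`, `val_loss` in nats per masked position).
#' @export
train_mlm <- function(model, corpus, policy = mask_policy(), epochs = 3L,
                      batch_size = 64L, lr = 3e-3, val_fraction = 0.01,
                      seed = 1L, verbose = FALSE) {
  seqs <- if (is.data.frame(corpus)) corpus$sequence else corpus
  if (length(seqs) == 0L) stop("corpus is empty")
  if (epochs == 0L) {
    model$history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                                val_loss = numeric(0))
    return(model)
  }
  withr::local_seed(seed)
  n_val <- if (length(seqs) >= 2L) max(1L, floor(val_fraction * length(seqs)))
           else 0L
  perm <- sample.int(length(seqs))
  val_idx <- perm[seq_len(n_val)]
  tr_idx <- setdiff(perm, val_idx)
  tr <- seqs[tr_idx]
  val <- seqs[val_idx]
  params <- model$params
  cfg <- model$config
  st <- .adam_new(params)
  batches <- .length_batches(tr, batch_size)
  total_steps <- length(batches) * epochs
  hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                     val_loss = numeric(0))
  step <- 0L
  for (ep in seq_len(epochs)) {
    ord <- sample.int(length(batches))
    ep_losses <- numeric(0)
    for (bi in ord) {
      idx <- batches[[bi]]
      toks <- .tokenize_matrix(tr[idx])
      mk <- apply_mask(toks, policy, seed = sample.int(.Machine$integer.max, 1L))
      fw <- .encoder_forward(params, cfg, mk$corrupted, train = cfg$dropout > 0)
      ls <- .mlm_loss_backward(params, fw$h, mk$rows, mk$targets)
      if (!is.finite(ls$loss))
        stop("training diverged: non-finite loss at epoch ", ep)
      grads <- .encoder_backward(params, cfg, fw$cache, ls$dH)
      grads$W_out <- ls$dW_out
      grads$b_out <- ls$db_out
      step <- step + 1L
      upd <- .adam_step(params, grads, st, .lr_at(step, total_steps, lr))
      params <- upd$params
      st <- upd$state
      ep_losses <- c(ep_losses, ls$loss)
    }
    vl <- NA_real_
    if (length(val) > 0L) {
      vls <- numeric(0)
      for (vb in .length_batches(val, batch_size)) {
        toks <- .tokenize_matrix(val[vb])
        mk <- apply_mask(toks, policy, seed = 7L)
        fw <- .encoder_forward(params, cfg, mk$corrupted, train = FALSE)
        vls <- c(vls, .mlm_loss_only(params, fw$h, mk$rows, mk$targets))
      }
      vl <- mean(vls)
    }
    hist <- rbind(hist, data.frame(epoch = ep, train_loss = mean(ep_losses),
                                   val_loss = vl))
    if (verbose)
      message(sprintf("epoch %d: train %.4f val %.4f", ep, mean(ep_losses), vl))
  }
  model$params <- params
  model$history <- hist
  model
}

# Final-layer logits at every residue position of `seq`, each computed with
# that single position masked (one batched forward pass: L masked copies).
# Returns an L x 25 matrix of raw logits.
.masked_logits <- function(model, seq) {
  ids <- tokenize(seq, model$vocab)
  L <- length(ids) - 2L
  batch <- matrix(rep(ids, each = L), nrow = L)
  for (l in seq_len(L)) batch[l, l + 1L] <- .special_id("MASK")
  fw <- .encoder_forward(model$params, model$config, batch, train = FALSE)
  Lt <- ncol(batch)
  rows <- (seq_len(L) - 1L) * Lt + seq_len(L) + 1L
  .affine(fw$h[rows, , drop = FALSE], model$params$W_out, model$params$b_out)
}

#' Predict the residue distribution at one position
#'
#' Replaces the residue at `position` by `[MASK]`, runs one forward pass,
#' and returns the softmax over the 20 canonical residues (special-token
#' mass is excluded and the distribution renormalized).
#'
#' @param model A trained [mlm_model()].
#' @param seq Amino-acid sequence.
#' @param position 1-based residue index.
#' @return Named numeric vector of 20 probabilities summing to 1.
#' @export
predict_position <- function(model, seq, position) {
  n <- nchar(seq)
  if (position < 1L || position > n)
    stop("position ", position, " out of range for sequence of length ", n)
  ids <- tokenize(seq, model$vocab)
  ids[position + 1L] <- .special_id("MASK")
  fw <- .encoder_forward(model$params, model$config,
                         matrix(ids, nrow = 1L), train = FALSE)
  logits <- .affine(fw$h[position + 1L, , drop = FALSE],
                    model$params$W_out, model$params$b_out)
  .residue_softmax(logits[1, ])
}

# Softmax restricted to the 20 residue logits.
.residue_softmax <- function(logits) {
  z <- logits[1:20]
  z <- z - max(z)
  p <- exp(z) / sum(exp(z))
  names(p) <- .AA
  p
}

# All-position residue distributions for one sequence: L x 20 matrix.
.predict_all_positions <- function(model, seq) {
  lg <- .masked_logits(model, seq)[, 1:20, drop = FALSE]
  lg <- lg - apply(lg, 1L, max)
  p <- exp(lg)
  p <- p / rowSums(p)
  colnames(p) <- .AA
  p
}

#' Save / load a model checkpoint
#'
#' A checkpoint directory holds `config.yaml` (architecture + class) and
#' `params.rds` (parameter values).
#'
#' @param model An `mlm_model`.
#' @param dir Directory path (created if missing).
#' @return `save_model` returns `dir` invisibly; `load_model` the model.
#' @export
save_model <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(unclass(model$config), file.path(dir, "config.yaml"))
  saveRDS(model$params, file.path(dir, "params.rds"))
  invisible(dir)
}

#' @rdname save_model
#' @export
load_model <- function(dir) {
  cfg <- yaml::read_yaml(file.path(dir, "config.yaml"))
  cfg <- structure(lapply(cfg, function(x)
    if (is.numeric(x) && x == as.integer(x)) as.integer(x) else x),
    class = "encoder_config")
  structure(list(config = cfg,
                 params = readRDS(file.path(dir, "params.rds")),
                 vocab = aa_vocabulary()),
            class = "mlm_model")
}
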