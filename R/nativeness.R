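#' Nativeness score of a sequence under a masked language model
#'
#' Zero-shot statistic of how closely a sequence matches the distribution
#' the model was trained on. Each position is masked in turn; with `z_i`
#' the final-layer logit of the observed residue at position `i`, the
#' default score is the sum of inverse exponents `sum_i exp(-z_i)`. Lower
#' scores indicate sequences closer to the training distribution. The
#' alternative pseudo-log-likelihood reading (`sum_i -log p_i` over the
#' renormalized residue distribution) is available as `method = "pll"`;
#' both are monotone decreasing in the observed residue's logit.
#'
#' @param model A trained [mlm_model()].
#' @param seq Amino-acid string or one-row repertoire record.
#' @param method `"invexp"` (default) or `"pll"`.
#' @param normalize Divide the score by sequence length (default `FALSE`;
#'   the raw sum confounds length with nativeness, so the normalized
#'   variant is offered for cross-length comparisons).
#' @return A `nativeness_score`: list with `score`, `per_position`
#'   (contributions summing to the raw score), `length`, `method`.
#' @export
nativeness_score <- function(model, seq, method = c("invexp", "pll"),
                             normalize = FALSE) {
  method <- match.arg(method)
  if (is.data.frame(seq)) seq <- seq$sequence[1]
  chars <- strsplit(seq, "")[[1]]
  canonical <- chars %in% .AA
  if (!all(canonical))
    warning(sum(!canonical),
            " non-canonical position(s) excluded from the nativeness sum")
  logits <- .masked_logits(model, seq)
  contrib <- rep(NA_real_, length(chars))
  for (i in which(canonical)) {
    zi <- logits[i, match(chars[i], .AA)]
    contrib[i] <- if (method == "invexp") exp(-zi) else {
      z <- logits[i, 1:20]
      -(zi - max(z) - log(sum(exp(z - max(z)))))
    }
  }
  raw <- sum(contrib, na.rm = TRUE)
  structure(list(score = if (normalize) raw / sum(canonical) else raw,
                 per_position = contrib,
                 length = length(chars),
                 method = method),
            class = "nativeness_score")
}

#' Nativeness scores for a set of sequences
#'
#' @param model A trained [mlm_model()].
#' @param records Repertoire data frame or character vector.
#' @inheritParams nativeness_score
#' @return Data frame `id`, `score`, `length`, `score_per_position`.
#' @export
nativeness_scores <- function(model, records, method = "invexp",
                              normalize = FALSE) {
  if (is.character(records))
    records <- data.frame(id = sprintf("seq%04d", seq_along(records)),
                          sequence = records, stringsAsFactors = FALSE)
  sc <- vapply(records$sequence, function(s)
    nativeness_score(model, s, method = method, normalize = normalize)$score,
    numeric(1), USE.NAMES = FALSE)
  data.frame(id = records$id, score = sc, length = nchar(records$sequence),
             score_per_position = sc / ifelse(normalize, 1, nchar(records$sequence)),
             stringsAsFactors = FALSE)
}

# Probability that a random native score is lower than a random foreign
# one, with ties counted half (rank-based, equivalent to the Wilcoxon
# statistic).
.rank_auc_lower <- function(native, foreign) {
  r <- rank(c(native, foreign))
  n1 <- length(native)
  n2 <- length(foreign)
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  1 - u / (n1 * n2)
}

#' Species-separation experiment
#'
#' Scores a native set and one or more foreign sets under the model and
#' reports, per foreign set, the probability that a random native sequence
#' scores lower (more native) than a random foreign one.
#'
#' @param model A trained [mlm_model()].
#' @param native_set Character vector or repertoire data frame.
#' @param foreign_sets Named list of character vectors / data frames.
#' @inheritParams nativeness_score
#' @return List with `native_scores`, `foreign_scores` (named list) and
#'   `auc` (named vector, one entry per foreign set).
#' @export
separation_experiment <- function(model, native_set, foreign_sets,
                                  method = "invexp", normalize = FALSE) {
  if (!is.list(foreign_sets) || is.data.frame(foreign_sets))
    foreign_sets <- list(foreign = foreign_sets)
  if (length(native_set) == 0L || any(lengths(foreign_sets) == 0L))
    stop("all sets must be non-empty")
  nat <- nativeness_scores(model, native_set, method, normalize)$score
  fs <- lapply(foreign_sets, function(x)
    nativeness_scores(model, x, method, normalize)$score)
  auc <- vapply(fs, function(f) .rank_auc_lower(nat, f), numeric(1))
  list(native_scores = nat, foreign_scores = fs, auc = auc)
}
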