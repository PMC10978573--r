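#' Infilling predictors
#'
#' A predictor is a function of `(seq, position)` returning a named
#' 20-vector of residue probabilities; the constructors below add an
#' optional fast path (`predict_all` attribute) that scores every position
#' of a sequence at once.
#'
#' `mlm_predictor` wraps a trained masked language model: each position is
#' obscured in turn and reconstructed from the full bidirectional context.
#'
#' @param model A trained [mlm_model()].
#' @return A predictor function.
#' @export
mlm_predictor <- function(model) {
  f <- function(seq, position) predict_position(model, seq, position)
  attr(f, "predict_all") <- function(seq) .predict_all_positions(model, seq)
  attr(f, "label") <- "mlm"
  f
}

#' @rdname mlm_predictor
#'
#' @details `pssm_predictor` is the context-free baseline: the prediction
#' at a position is the PSSM row for that position regardless of sequence
#' context. With `scaffolds` supplied, the query is IMGT-numbered and
#' positions map to PSSM rows by IMGT label; without, rows are indexed by
#' raw position (for fixed-length corpora). Positions absent from the PSSM
#' fall back to the uniform distribution.
#'
#' @param pssm A [build_pssm()] result or plain positions-x-20 matrix.
#' @param scaffolds Optional numbering references.
#' @export
pssm_predictor <- function(pssm, scaffolds = NULL) {
  rows <- .as_pssm_matrix(pssm)
  uniform <- stats::setNames(rep(1 / 20, 20), .AA)
  if (is.null(scaffolds)) {
    f <- function(seq, position) {
      if (position <= nrow(rows)) rows[position, ] else uniform
    }
    attr(f, "predict_all") <- function(seq) {
      L <- nchar(seq)
      out <- matrix(1 / 20, L, 20, dimnames = list(NULL, .AA))
      k <- min(L, nrow(rows))
      out[seq_len(k), ] <- rows[seq_len(k), ]
      out
    }
  } else {
    lookup <- function(seq) {
      ns <- number_sequence(seq, scaffolds)
      idx <- match(ns$imgt, rownames(rows))
      out <- matrix(1 / 20, length(idx), 20, dimnames = list(NULL, .AA))
      hit <- !is.na(idx)
      out[hit, ] <- rows[idx[hit], ]
      out
    }
    f <- function(seq, position) lookup(seq)[position, ]
    attr(f, "predict_all") <- lookup
  }
  attr(f, "label") <- "pssm"
  f
}

#' Infill every position of a sequence
#'
#' Obscures one position at a time and records the predictor's residue
#' distribution, ranking and match against the true residue. Ranking ties
#' are broken alphabetically.
#'
#' @param predictor A predictor function (see [mlm_predictor()]).
#' @param seq Amino-acid string or one-row repertoire record.
#' @return Data frame with one row per position: `index`, `true_residue`,
#'   `top_prediction`, `match`, `tie`, plus a `probabilities` matrix
#'   attribute (positions x 20).
#' @export
infill_sequence <- function(predictor, seq) {
  if (is.data.frame(seq)) seq <- seq$sequence[1]
  L <- nchar(seq)
  pa <- attr(predictor, "predict_all")
  probs <- if (!is.null(pa)) pa(seq) else
    t(vapply(seq_len(L), function(i) predictor(seq, i), numeric(20)))
  colnames(probs) <- .AA
  truth <- strsplit(seq, "")[[1]]
  # alphabetical tie-break: which.max returns the first (alphabetical) max
  top <- .AA[apply(probs, 1L, which.max)]
  tie <- apply(probs, 1L, function(p) sum(p == max(p)) > 1L)
  out <- data.frame(index = seq_len(L), true_residue = truth,
                    top_prediction = top, match = top == truth, tie = tie,
                    stringsAsFactors = FALSE)
  attr(out, "probabilities") <- probs
  out
}

.AGGREGATES <- list(V = .REGIONS,
                    FW = c("FW1", "FW2", "FW3", "FW4"),
                    CDRs = c("CDR1", "CDR2", "CDR3"))

#' Per-region infilling accuracy of one sequence
#'
#' Accuracy of a region is the number of matched positions divided by the
#' number of positions the sequence has in that region. Aggregates `V`
#' (all positions), `FW` (FW1-4) and `CDRs` (CDR1-3) are reported alongside
#' the seven individual regions; regions with zero positions are omitted.
#'
#' @param preds [infill_sequence()] output covering all residues.
#' @param ns Matching [number_sequence()] result.
#' @return Named numeric vector of accuracies in `[0, 1]`.
#' @export
region_accuracy <- function(preds, ns) {
  if (nrow(preds) != length(ns$residues))
    stop("predictions (", nrow(preds), ") do not cover the numbered sequence (",
         length(ns$residues), ")")
  acc <- c()
  for (r in .REGIONS) {
    idx <- ns$region_spans[[r]]
    if (length(idx) > 0L)
      acc[r] <- sum(preds$match[idx]) / length(idx)
  }
  for (a in names(.AGGREGATES)) {
    idx <- unlist(ns$region_spans[.AGGREGATES[[a]]], use.names = FALSE)
    if (length(idx) > 0L)
      acc[a] <- sum(preds$match[idx]) / length(idx)
  }
  acc
}

#' Positional infilling benchmark
#'
#' For each test sequence: number it, obscure every position in turn,
#' count top-prediction matches, and aggregate accuracy per IMGT region.
#' Region means are unweighted averages over the sequences that have the
#' region; unnumberable sequences are skipped and counted.
#'
#' @param predictor A predictor function.
#' @param dataset Repertoire data frame (`id`, `sequence`).
#' @param scaffolds Numbering references.
#' @return An `infill_report`: list with `per_sequence` (data frame of
#'   per-sequence region accuracies), `mean_per_region` (named vector),
#'   `n_sequences`, `n_skipped`.
#' @export
benchmark_infilling <- function(predictor, dataset, scaffolds) {
  if (nrow(dataset) == 0L) stop("dataset is empty")
  rows <- list()
  n_skipped <- 0L
  for (i in seq_len(nrow(dataset))) {
    ns <- tryCatch(number_sequence(dataset$sequence[i], scaffolds),
                   nanomlm_unnumberable = function(e) NULL)
    if (is.null(ns)) { n_skipped <- n_skipped + 1L; next }
    preds <- infill_sequence(predictor, dataset$sequence[i])
    acc <- region_accuracy(preds, ns)
    row <- as.data.frame(as.list(acc), optional = TRUE)
    row$id <- dataset$id[i]
    rows[[length(rows) + 1L]] <- row
  }
  if (length(rows) == 0L) stop("all sequences were unnumberable")
  all_cols <- unique(unlist(lapply(rows, names)))
  per_seq <- do.call(rbind, lapply(rows, function(r) {
    miss <- setdiff(all_cols, names(r))
    for (m in miss) r[[m]] <- NA_real_
    r[all_cols]
  }))
  region_cols <- setdiff(all_cols, "id")
  means <- vapply(region_cols, function(cn) {
    v <- per_seq[[cn]]
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }, numeric(1))
  means <- means[!is.na(means)]
  structure(list(per_sequence = per_seq[c("id", region_cols)],
                 mean_per_region = means,
                 n_sequences = nrow(per_seq),
                 n_skipped = n_skipped),
            class = "infill_report")
}

#' @export
print.infill_report <- function(x, ...) {
  cat(sprintf("<infill_report> %d sequences (%d skipped)\n",
              x$n_sequences, x$n_skipped))
  df <- data.frame(region = names(x$mean_per_region),
                   mean_accuracy = round(unname(x$mean_per_region), 4))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Write an infilling report to CSV
#'
#' Columns `region`, `mean_accuracy`, `n_sequences`.
#'
#' @param report An `infill_report`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_infill_report <- function(report, path) {
  n_per <- vapply(names(report$mean_per_region), function(cn)
    sum(!is.na(report$per_sequence[[cn]])), integer(1))
  utils::write.csv(data.frame(region = names(report$mean_per_region),
                              mean_accuracy = unname(report$mean_per_region),
                              n_sequences = n_per),
                   path, row.names = FALSE)
  invisible(path)
}
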