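#' Levenshtein edit distance
#'
#' Standard unit-cost edit distance (substitution, insertion, deletion).
#'
#' @param a,b Strings.
#' @return Non-negative integer.
#' @export
levenshtein <- function(a, b) .lev_cpp(a, b)

#' Assign the closest germline gene
#'
#' The gene whose scaffold has the highest framework identity with the
#' numbered query, computed over the IMGT framework positions the two share.
#' Ties are broken by `gene_id` sort order and flagged. Sequences without
#' FW2 or FW3 residues raise a condition of class `nanomlm_excluded`
#' (callers count these rather than fail).
#'
#' @param ns A [number_sequence()] result.
#' @param germlines List of [germline_scaffold()] objects.
#' @return List `id`-less assignment: `gene_id`, `framework_identity`,
#'   `tie` (logical).
#' @export
assign_gene <- function(ns, germlines) {
  if (length(ns$region_spans$FW2) == 0L || length(ns$region_spans$FW3) == 0L) {
    cond <- structure(
      class = c("nanomlm_excluded", "error", "condition"),
      list(message = "sequence lacks FW2/FW3 data; excluded from assignment",
           call = sys.call()))
    stop(cond)
  }
  q_res <- stats::setNames(ns$residues, ns$imgt)
  fw_labels <- ns$imgt[startsWith(ns$region, "FW")]
  ids <- numeric(length(germlines))
  gene_ids <- vapply(germlines, `[[`, "", "gene_id")
  for (k in seq_along(germlines)) {
    g <- germlines[[k]]
    g_res <- stats::setNames(strsplit(g$sequence, "")[[1]], g$imgt_numbers)
    shared <- intersect(fw_labels, g$imgt_numbers)
    ids[k] <- if (length(shared) == 0L) 0 else
      mean(q_res[shared] == g_res[shared])
  }
  ord <- order(-ids, gene_ids)
  best <- ord[1]
  tie <- sum(abs(ids - ids[best]) < 1e-12) > 1L
  list(gene_id = gene_ids[best], framework_identity = ids[best], tie = tie)
}

#' Assign genes to a repertoire
#'
#' Numbers each record and assigns the closest germline; unnumberable or
#' FW2/FW3-less records are excluded and counted.
#'
#' @param records Repertoire data frame with `id`, `sequence`.
#' @param germlines Germline scaffolds (also used as numbering references).
#' @return List with `assignments` (data frame `id`, `gene_id`,
#'   `framework_identity`, `tie`) and `n_excluded`.
#' @export
assign_genes <- function(records, germlines) {
  rows <- vector("list", nrow(records))
  n_excluded <- 0L
  for (i in seq_len(nrow(records))) {
    res <- tryCatch({
      ns <- number_sequence(records$sequence[i], germlines)
      a <- assign_gene(ns, germlines)
      data.frame(id = records$id[i], gene_id = a$gene_id,
                 framework_identity = a$framework_identity, tie = a$tie,
                 stringsAsFactors = FALSE)
    },
    nanomlm_unnumberable = function(e) NULL,
    nanomlm_excluded = function(e) NULL)
    if (is.null(res)) n_excluded <- n_excluded + 1L else rows[[i]] <- res
  }
  list(assignments = do.call(rbind, rows[!vapply(rows, is.null, TRUE)]),
       n_excluded = n_excluded)
}

#' Gene frequency table
#'
#' @param assignments Data frame with a `gene_id` column (from
#'   [assign_genes()]).
#' @return Data frame `gene_id`, `percent`, sorted by decreasing percent;
#'   percents sum to 100.
#' @export
gene_frequency_table <- function(assignments) {
  if (is.null(assignments) || nrow(assignments) == 0L)
    stop("no assignments (all sequences excluded?)")
  tab <- table(assignments$gene_id)
  out <- data.frame(gene_id = names(tab),
                    percent = 100 * as.numeric(tab) / sum(tab),
                    stringsAsFactors = FALSE)
  out[order(-out$percent, out$gene_id), , drop = FALSE]
}

#' Edit-distance curve of FW2+FW3 clones
#'
#' For a set of records assigned to one gene: extract the concatenated
#' FW2+FW3 of each chain, identify the most frequent such clone (the
#' empirical germline proxy; lexicographic tie-break, flagged), and report,
#' for each edit distance `d` from that modal clone, the total frequency of
#' all chains at `d` and the frequency of the single most frequent unique
#' clone at `d`.
#'
#' @param records Repertoire data frame.
#' @param scaffolds Numbering references.
#' @return A `distance_curve`: list with `modal_fw23`, `modal_tie`,
#'   `n_used`, `n_excluded`, and `points` (data frame `distance`,
#'   `total_frequency`, `top_clone_frequency`, `n_unique_clones`).
#' @export
distance_curve <- function(records, scaffolds) {
  clones <- character(0)
  n_excluded <- 0L
  for (i in seq_len(nrow(records))) {
    fw23 <- tryCatch({
      ns <- number_sequence(records$sequence[i], scaffolds)
      f2 <- extract_region(ns, "FW2")
      f3 <- extract_region(ns, "FW3")
      if (nchar(f2) == 0L || nchar(f3) == 0L) NULL else paste0(f2, f3)
    }, nanomlm_unnumberable = function(e) NULL)
    if (is.null(fw23)) n_excluded <- n_excluded + 1L
    else clones <- c(clones, fw23)
  }
  if (length(clones) == 0L) stop("no records with FW2 and FW3 data")
  tab <- sort(table(clones), decreasing = TRUE)
  top_count <- tab[1]
  modal_candidates <- names(tab)[tab == top_count]
  modal <- sort(modal_candidates)[1]
  uniq <- names(tab)
  d <- vapply(uniq, function(s) .lev_cpp(s, modal), integer(1))
  counts <- as.numeric(tab)
  N <- sum(counts)
  pts <- do.call(rbind, lapply(sort(unique(d)), function(dd) {
    at <- d == dd
    data.frame(distance = dd,
               total_frequency = sum(counts[at]) / N,
               top_clone_frequency = max(counts[at]) / N,
               n_unique_clones = sum(at))
  }))
  structure(list(modal_fw23 = modal,
                 modal_tie = length(modal_candidates) > 1L,
                 n_used = N, n_excluded = n_excluded, points = pts),
            class = "distance_curve")
}

#' @export
print.distance_curve <- function(x, ...) {
  cat(sprintf("<distance_curve> modal FW2+3 of %d chains (%d excluded)\n",
              x$n_used, x$n_excluded))
  print(x$points, row.names = FALSE)
  invisible(x)
}

#' Build a PSSM from numbered records
#'
#' Per-IMGT-position residue frequencies. Positions never observed emit no
#' row; smoothing is off by default.
#'
#' @param numbered List of [number_sequence()] results.
#' @param pseudocount Added to every cell before normalization (default 0).
#' @return List of class `pssm`: `rows` (positions x 20 matrix, rows
#'   summing to 1, rownames = IMGT labels in numbering order) and
#'   `support` (observation count per position).
#' @export
build_pssm <- function(numbered, pseudocount = 0) {
  if (length(numbered) == 0L) stop("need at least one numbered record")
  counts <- list()
  for (ns in numbered) {
    for (k in seq_along(ns$residues)) {
      lab <- ns$imgt[k]
      if (is.null(counts[[lab]]))
        counts[[lab]] <- stats::setNames(rep(0, 20), .AA)
      counts[[lab]][ns$residues[k]] <- counts[[lab]][ns$residues[k]] + 1
    }
  }
  labs <- names(counts)[order(.imgt_numeric(names(counts)))]
  rows <- t(vapply(labs, function(l) {
    v <- counts[[l]] + pseudocount
    v / sum(v)
  }, numeric(20)))
  support <- vapply(labs, function(l) sum(counts[[l]]), numeric(1))
  structure(list(rows = rows, support = support), class = "pssm")
}

#' Framework mismatches against the closest reference germline
#'
#' Identifies the closest germline in `germlines` (by framework identity)
#' and lists every framework position where the query differs from it.
#' CDR positions are treated as grafted and never reported.
#'
#' @param ns A [number_sequence()] result.
#' @param germlines Reference germline set (e.g. the human scaffolds).
#' @return List with `gene_id` and `mismatches` (data frame `imgt`,
#'   `query`, `germline`).
#' @export
closest_human_mismatches <- function(ns, germlines) {
  a <- assign_gene(ns, germlines)
  g <- germlines[[match(a$gene_id, vapply(germlines, `[[`, "", "gene_id"))]]
  g_res <- stats::setNames(strsplit(g$sequence, "")[[1]], g$imgt_numbers)
  fw <- startsWith(ns$region, "FW")
  rows <- list()
  for (k in which(fw)) {
    lab <- ns$imgt[k]
    gr <- g_res[lab]
    if (!is.na(gr) && gr != ns$residues[k])
      rows[[length(rows) + 1L]] <- data.frame(
        imgt = lab, query = ns$residues[k], germline = unname(gr),
        stringsAsFactors = FALSE)
  }
  list(gene_id = a$gene_id,
       mismatches = if (length(rows)) do.call(rbind, rows) else
         data.frame(imgt = character(0), query = character(0),
                    germline = character(0)))
}
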