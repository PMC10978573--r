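#' IMGT region boundary table
#'
#' The standard IMGT unique-numbering region boundaries for a variable
#' domain: FW1 1-26, CDR1 27-38, FW2 39-55, CDR2 56-65, FW3 66-104,
#' CDR3 105-117, FW4 118-128.
#'
#' @return Data frame with columns `region`, `first`, `last`.
#' @export
imgt_region_table <- function() {
  data.frame(
    region = c("FW1", "CDR1", "FW2", "CDR2", "FW3", "CDR3", "FW4"),
    first = c(1, 27, 39, 56, 66, 105, 118),
    last = c(26, 38, 55, 65, 104, 117, 128),
    stringsAsFactors = FALSE
  )
}

.REGIONS <- c("FW1", "CDR1", "FW2", "CDR2", "FW3", "CDR3", "FW4")
.REGION_FIRST <- c(1, 27, 39, 56, 66, 105, 118)
.REGION_LAST <- c(26, 38, 55, 65, 104, 117, 128)

# Region name for numeric IMGT values (insertions carry fractional parts
# and fall inside their enclosing region's range).
.region_of_imgt <- function(num) {
  .REGIONS[findInterval(num, .REGION_FIRST)]
}

.check_canonical <- function(seq, what = "sequence") {
  bad <- setdiff(unique(strsplit(seq, "")[[1]]), .AA)
  if (length(bad) > 0L)
    stop("non-canonical characters in ", what, ": ",
         paste(bad, collapse = ", "))
}

#' Global pairwise alignment
#'
#' Needleman-Wunsch with a linear gap penalty and deterministic traceback
#' tie-breaking (diagonal, then up, then left).
#'
#' @param query,reference Amino-acid strings.
#' @param match,mismatch,gap Scoring parameters.
#' @return List with `aligned_query`, `aligned_reference` (gap character
#'   `-`) and `score`.
#' @export
global_align <- function(query, reference, match = 2, mismatch = -1,
                         gap = -2) {
  if (nchar(query) == 0L || nchar(reference) == 0L)
    stop("both sequences must be non-empty")
  .check_canonical(query, "query")
  .check_canonical(reference, "reference")
  al <- .nw_cpp(query, reference, match, mismatch, gap)
  list(aligned_query = al$aligned_a, aligned_reference = al$aligned_b,
       score = al$score)
}

#' Assign IMGT numbers to a query sequence
#'
#' Aligns the query to every scaffold, picks the best-scoring one, and
#' transfers its IMGT labels through the aligned columns. Query residues
#' inserted relative to the scaffold receive lettered sub-positions
#' (`"111A"`) attached to the preceding numbered position and belong to the
#' enclosing region. If the framework identity of the best alignment is
#' below `min_fw_identity` the sequence is rejected with an error of class
#' `nanomlm_unnumberable` (mirroring the exclusion of chains without usable
#' framework data).
#'
#' @param query Amino-acid string (length 80-160) or a one-row repertoire
#'   record.
#' @param scaffolds List of [germline_scaffold()] objects.
#' @param match,mismatch,gap Alignment scores.
#' @param min_fw_identity Rejection threshold on framework identity.
#' @return A `numbered_sequence`: list with `sequence`, `residues`,
#'   `imgt` (labels), `region` (per residue), `region_spans` (list of
#'   index vectors), `scaffold` (gene_id of the numbering reference),
#'   `fw_identity`.
#' @export
number_sequence <- function(query, scaffolds, match = 2, mismatch = -1,
                            gap = -2, min_fw_identity = 0.5) {
  if (is.data.frame(query)) query <- query$sequence[1]
  n <- nchar(query)
  if (n < 80L || n > 160L)
    stop("query length must be in [80, 160], got ", n)
  .check_canonical(query)
  best <- NULL
  for (sc in scaffolds) {
    al <- .nw_cpp(query, sc$sequence, match, mismatch, gap)
    if (is.null(best) || al$score > best$al$score)
      best <- list(al = al, sc = sc)
  }
  qa <- strsplit(best$al$aligned_a, "")[[1]]
  ra <- strsplit(best$al$aligned_b, "")[[1]]
  # Right-normalize query insertions: when the leading inserted residue
  # equals the query residue of the next aligned column the two alignments
  # score identically, and the canonical numbering puts loop surplus after
  # the last matched framework position (cf. indel right-alignment).
  k <- 1L
  K <- length(qa)
  while (k <= K) {
    if (ra[k] == "-" && qa[k] != "-") {
      e <- k
      while (e < K && ra[e + 1L] == "-") e <- e + 1L
      while (e < K && ra[e + 1L] != "-" && qa[e + 1L] != "-" &&
             qa[k] == qa[e + 1L]) {
        ra[k] <- ra[e + 1L]
        ra[e + 1L] <- "-"
        k <- k + 1L
        e <- e + 1L
      }
      k <- e + 1L
    } else k <- k + 1L
  }
  sc_labels <- best$sc$imgt_numbers
  labels <- character(n)
  qi <- 0L; ri <- 0L
  last_label <- "0"
  ins_count <- 0L
  for (k in seq_along(qa)) {
    if (ra[k] != "-" && qa[k] != "-") {
      ri <- ri + 1L; qi <- qi + 1L
      labels[qi] <- sc_labels[ri]
      last_label <- sc_labels[ri]
      ins_count <- 0L
    } else if (ra[k] == "-") {        # insertion in query
      qi <- qi + 1L
      ins_count <- ins_count + 1L
      base <- sub("[A-Z]+$", "", last_label)
      labels[qi] <- paste0(base, LETTERS[ins_count])
    } else {                          # deletion: scaffold position skipped
      ri <- ri + 1L
      last_label <- sc_labels[ri]
      ins_count <- 0L
    }
  }
  # Canonical CDR3 renumbering: alignment against a scaffold with a
  # different CDR3 length places the surplus residues ambiguously around
  # the FW3/CDR3/FW4 boundaries. Everything between the last aligned
  # framework-1..3 position (numeric label <= 104) and the first aligned
  # FW4 position (>= 118) is the CDR3 loop and is renumbered contiguously.
  plain <- !grepl("[A-Z]$", labels) & labels != ""
  numv <- .imgt_numeric(ifelse(labels == "", "0", labels))
  fw_pre <- which(plain & numv <= 104)
  fw_post <- which(plain & numv >= 118)
  if (length(fw_pre) > 0L) {
    lo <- max(fw_pre)
    hi <- if (length(fw_post) > 0L) min(fw_post) else n + 1L
    if (hi - lo > 1L)
      labels[(lo + 1L):(hi - 1L)] <- .cdr3_labels(hi - lo - 1L)
  }
  num <- .imgt_numeric(labels)
  region <- .region_of_imgt(num)
  # framework identity of the chosen alignment
  fw_cols <- ra != "-" &
    startsWith(.region_of_imgt(.imgt_numeric(sc_labels))[cumsum(ra != "-")], "FW")
  fw_id <- if (any(fw_cols)) mean(qa[fw_cols] == ra[fw_cols]) else 0
  if (fw_id < min_fw_identity) {
    cond <- structure(
      class = c("nanomlm_unnumberable", "error", "condition"),
      list(message = sprintf(
        "framework identity %.2f below %.2f; sequence not numberable",
        fw_id, min_fw_identity), call = sys.call()))
    stop(cond)
  }
  spans <- lapply(stats::setNames(.REGIONS, .REGIONS),
                  function(r) which(region == r))
  structure(list(sequence = query,
                 residues = strsplit(query, "")[[1]],
                 imgt = labels,
                 region = region,
                 region_spans = spans,
                 scaffold = best$sc$gene_id,
                 fw_identity = fw_id),
            class = "numbered_sequence")
}

#' @export
print.numbered_sequence <- function(x, ...) {
  cat(sprintf("<numbered_sequence> %d residues, scaffold %s, FW identity %.2f\n",
              length(x$residues), x$scaffold, x$fw_identity))
  invisible(x)
}

#' Extract the residues of one IMGT region
#'
#' @param ns A [number_sequence()] result.
#' @param region Region name (`"FW1"` ... `"FW4"`, `"CDR1"` ... `"CDR3"`).
#' @return Amino-acid string; `""` if the region has no numbered residues.
#' @export
extract_region <- function(ns, region) {
  if (!region %in% .REGIONS)
    stop("unknown region: ", region, " (expected one of ",
         paste(.REGIONS, collapse = ", "), ")")
  idx <- ns$region_spans[[region]]
  if (length(idx) == 0L) return("")
  paste(ns$residues[idx], collapse = "")
}

#' FW2 hallmark motif
#'
#' The residues at IMGT positions 42, 49, 50 and 52, which distinguish
#' nanobody-like chains (typically `FERF`) from conventional human heavy
#' chains (`VGLW`). Absent positions are reported as `-`.
#'
#' @param ns A [number_sequence()] result.
#' @return 4-character string.
#' @export
hallmark_motif <- function(ns) {
  pos <- c("42", "49", "50", "52")
  res <- ns$residues[match(pos, ns$imgt)]
  paste(ifelse(is.na(res), "-", res), collapse = "")
}
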