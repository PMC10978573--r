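#' Read sequences from FASTA
#'
#' Sequences are upper-cased, gap characters (`-`, `.`) stripped with a
#' warning, and duplicate ids suffixed with a counter.
#'
#' @param path FASTA file path.
#' @return Data frame with `id`, `sequence`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("cannot read FASTA: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("FASTA file is empty: ", path)
  seqs <- toupper(as.character(set))
  if (any(grepl("[-.]", seqs))) {
    warning("gap characters stripped from sequences")
    seqs <- gsub("[-.]", "", seqs)
  }
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    warning("duplicate FASTA ids suffixed with a counter")
    ids <- make.unique(ids, sep = "_")
  }
  data.frame(id = ids, sequence = unname(seqs), stringsAsFactors = FALSE)
}

#' Write sequences to FASTA
#'
#' @param records Data frame with `id`, `sequence`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  set <- Biostrings::BStringSet(stats::setNames(records$sequence, records$id))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read a metadata sidecar CSV
#'
#' Comma-separated, UTF-8, header required, `id` column mandatory. Numeric
#' columns are typed by `utils::read.csv`; ids not present in `known_ids`
#' (when given) are flagged with a warning but retained.
#'
#' @param path CSV path.
#' @param known_ids Optional character vector of expected ids.
#' @return Data frame keyed by `id`.
#' @export
read_metadata_csv <- function(path, known_ids = NULL) {
  if (!file.exists(path)) stop("cannot read metadata: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"id" %in% names(df)) stop("metadata CSV must have an `id` column")
  if (!is.null(known_ids)) {
    unknown <- setdiff(df$id, known_ids)
    if (length(unknown) > 0L)
      warning(length(unknown), " metadata row(s) with ids not in the ",
              "sequence set (retained)")
  }
  df
}

#' Write a repertoire with its sidecar
#'
#' FASTA plus a CSV with the simulation metadata columns.
#'
#' @param records Repertoire data frame from [simulate_repertoire()],
#'   optionally carrying a `property_value` column.
#' @param prefix Output path prefix; writes `<prefix>.fasta` and
#'   `<prefix>.csv`.
#' @return Named character vector of the two paths, invisibly.
#' @export
write_repertoire <- function(records, prefix) {
  fa <- paste0(prefix, ".fasta")
  csv <- paste0(prefix, ".csv")
  write_fasta(records, fa)
  meta <- records[setdiff(names(records), "sequence")]
  utils::write.csv(meta, csv, row.names = FALSE)
  invisible(c(fasta = fa, csv = csv))
}

#' Dataset manifest
#'
#' Bookkeeping record for a sequence file: name, sequence count, source and
#' content checksum.
#'
#' @param path FASTA path.
#' @param name Dataset name (default the file name).
#' @param source `"simulated"` or `"user-supplied"`.
#' @return List with `name`, `n_sequences`, `source`, `checksum`.
#' @export
dataset_manifest <- function(path, name = basename(path),
                             source = c("simulated", "user-supplied")) {
  source <- match.arg(source)
  recs <- read_fasta(path)
  list(name = name, n_sequences = nrow(recs), source = source,
       checksum = unname(tools::md5sum(path)))
}

#' Read a run configuration
#'
#' A single YAML file with a documented key-value schema; see the package
#' vignette for the keys each subcommand reads.
#'
#' @param path YAML path.
#' @return Named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  yaml::read_yaml(path)
}

#' Snapshot a run configuration next to its outputs
#'
#' @param config Named list.
#' @param dir Output directory.
#' @return Path of the snapshot, invisibly.
#' @export
write_config_snapshot <- function(config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- file.path(dir, "run_config.yaml")
  yaml::write_yaml(config, p)
  invisible(p)
}
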