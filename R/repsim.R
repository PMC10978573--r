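#' Germline scaffold
#'
#' A hand-built, IMGT-numbered variable-domain scaffold used both as the
#' germline of the repertoire simulator and as the numbering reference for
#' query sequences. These are synthetic scaffolds, not real IGHV alleles.
#'
#' @param gene_id Gene label, e.g. `"VHH1"`.
#' @param sequence Amino-acid string (length 95-128, canonical alphabet).
#' @param imgt_numbers Character vector of IMGT position labels, one per
#'   residue, strictly increasing.
#' @return A `germline_scaffold` object.
#' @export
germline_scaffold <- function(gene_id, sequence, imgt_numbers) {
  chars <- strsplit(sequence, "")[[1]]
  if (!all(chars %in% .AA))
    stop("non-canonical residues in scaffold ", gene_id, ": ",
         paste(unique(setdiff(chars, .AA)), collapse = ","))
  if (length(imgt_numbers) != length(chars))
    stop("imgt_numbers length must equal sequence length")
  num <- .imgt_numeric(imgt_numbers)
  if (any(diff(num) <= 0)) stop("imgt_numbers must be strictly increasing")
  if (min(num) > 26 || max(num) < 118)
    stop("scaffold must span FW1 through FW4")
  structure(list(gene_id = gene_id, sequence = sequence,
                 imgt_numbers = as.character(imgt_numbers)),
            class = "germline_scaffold")
}

# Numeric ordering value of an IMGT label ("88", "111A" -> 111.01, ...).
.imgt_numeric <- function(labels) {
  base <- as.numeric(sub("[A-Z]+$", "", labels))
  suf <- sub("^[0-9]+", "", labels)
  off <- ifelse(suf == "", 0, match(suf, LETTERS) / 100)
  base + off
}

# Shared scaffold geometry: IMGT labels of the 117-residue base layout.
.base_imgt_numbers <- function(cdr3_len = 10L) {
  c(1:9, 11:26,                 # FW1  (25)
    27:30, 35:38,               # CDR1 (8)
    39:55,                      # FW2  (17)
    56:63,                      # CDR2 (8)
    66:72, 74:104,              # FW3  (38)
    .cdr3_labels(cdr3_len),     # CDR3
    118:128)                    # FW4  (11)
}

# Simplified CDR3 numbering: consecutive positions from 105; lengths beyond
# 13 receive lettered insertions after position 111.
.cdr3_labels <- function(len) {
  if (len <= 13L) return(as.character(104L + seq_len(len)))
  extra <- len - 13L
  c(as.character(105:111), paste0("111", LETTERS[seq_len(extra)]),
    as.character(112:117))
}

.SPECIES_A_PARTS <- list(
  fw1 = "EVQLVESGGGLVQPGGSLRLSCAAS", cdr1 = "GFTFSSYA",
  fw2 = "MSWFRQAPGKEREFVSA", cdr2 = "ISGSGGST",
  fw3 = "YYADSVKGRFTISRDNAKNTVYLQMNSLKPEDTAVYYC",
  cdr3 = "ARDGYSSGWY", fw4 = "WGQGTQVTVSS")

.SPECIES_B_PARTS <- list(
  fw1 = "EVQLVESGGGLVQPGGSLRLSCAAS", cdr1 = "GFTFSSYA",
  fw2 = "MSWVRQAPGKGLEWVSA", cdr2 = "ISGSGGST",
  fw3 = "YYADSVKGRFTISRDNSKNTLYLQMNSLRAEDTAVYYC",
  cdr3 = "ARDGYSSGWY", fw4 = "WGQGTLVTVSS")

# Allelic variants: per-gene substitutions at (residue index, new residue),
# indices into the 117-residue base layout. Three framework substitutions
# per gene (hallmarks untouched, new residue distinct from both species'
# base residues) so any two genes differ at >= 6 framework positions and
# closest-germline assignment is robust to a stray hypermutation.
.GENE_VARIANTS <- list(
  list(),                                      # gene 1 = base
  list(c(3L, "K"), c(64L, "I"), c(114L, "S")), # FW1, FW3, FW4
  list(c(8L, "A"), c(70L, "V"), c(85L, "T")),  # FW1, FW3, FW3
  list(c(14L, "A"), c(75L, "T"), c(91L, "S")), # FW1, FW3, FW3
  list(c(18L, "V"), c(79L, "I"), c(112L, "M")) # FW1, FW3, FW4
)

.species_scaffolds <- function(parts, prefix) {
  base <- paste0(parts$fw1, parts$cdr1, parts$fw2, parts$cdr2, parts$fw3,
                 parts$cdr3, parts$fw4)
  labs <- .base_imgt_numbers(nchar(parts$cdr3))
  lapply(seq_along(.GENE_VARIANTS), function(k) {
    s <- strsplit(base, "")[[1]]
    for (sub in .GENE_VARIANTS[[k]]) s[as.integer(sub[1])] <- sub[2]
    germline_scaffold(sprintf("%s%d", prefix, k), paste(s, collapse = ""), labs)
  })
}

#' Built-in scaffold sets
#'
#' Five synthetic nanobody-like (`"vhh"`) or five human-like (`"human"`)
#' scaffolds. The two sets share most of the framework but differ at the
#' FW2 hallmark positions (IMGT 42/49/50/52: F/E/R/F vs V/G/L/W), at a few
#' FW3/FW4 positions, and by small per-gene allelic substitutions.
#'
#' @param species `"vhh"` or `"human"`.
#' @return List of five [germline_scaffold()] objects.
#' @export
builtin_scaffolds <- function(species = c("vhh", "human")) {
  species <- match.arg(species)
  if (species == "vhh") .species_scaffolds(.SPECIES_A_PARTS, "VHH")
  else .species_scaffolds(.SPECIES_B_PARTS, "VH")
}

#' Somatic-hypermutation configuration
#'
#' Point-substitution model applied to the germline-derived part of each
#' simulated sequence (FW1-FW3 plus CDR1/2; CDR3 is resampled separately).
#' Each position mutates independently with probability
#' `base_rate * hotspot_multipliers[region]`; the substituted residue is
#' drawn from the row of `substitution_matrix` for the current residue
#' (zero diagonal — a mutation always changes the residue).
#'
#' @param base_rate Per-residue substitution probability.
#' @param hotspot_multipliers Named multipliers per region (defaults model
#'   elevated CDR mutation rates).
#' @param substitution_matrix 20x20 row-stochastic matrix with zero
#'   diagonal; default uniform over the 19 alternatives.
#' @param seed Integer seed.
#' @return An `shm_config` object.
#' @export
shm_config <- function(base_rate = 0.02,
                       hotspot_multipliers = c(FW1 = 1, CDR1 = 3, FW2 = 1,
                                               CDR2 = 3, FW3 = 1, FW4 = 1),
                       substitution_matrix = NULL, seed = 1L) {
  if (base_rate < 0 || base_rate > 1) stop("base_rate must be in [0,1]")
  if (any(hotspot_multipliers < 0)) stop("multipliers must be >= 0")
  if (is.null(substitution_matrix)) {
    substitution_matrix <- matrix(1 / 19, 20, 20,
                                  dimnames = list(.AA, .AA))
    diag(substitution_matrix) <- 0
  }
  if (any(abs(rowSums(substitution_matrix) - 1) > 1e-9))
    stop("substitution_matrix rows must sum to 1")
  if (any(diag(substitution_matrix) != 0))
    stop("substitution_matrix diagonal must be 0")
  structure(list(base_rate = base_rate,
                 hotspot_multipliers = hotspot_multipliers,
                 substitution_matrix = substitution_matrix,
                 seed = as.integer(seed)),
            class = "shm_config")
}

#' CDR3 sampling configuration
#'
#' Junctional diversity is modelled as i.i.d. per-position sampling at a
#' sampled length, replacing the scaffold CDR3 entirely.
#'
#' @param length_distribution Named numeric vector, probability per CDR3
#'   length (lengths 3-30, summing to 1). Default: a discretized unimodal
#'   distribution over 8-16 peaking at 12, a realistic VHH-like range.
#' @param composition Named 20-vector of residue probabilities (shared
#'   across positions), or a matrix with one row per position.
#' @param seed Integer seed.
#' @return A `cdr3_config` object.
#' @export
cdr3_config <- function(length_distribution = NULL, composition = NULL,
                        seed = 1L) {
  if (is.null(length_distribution)) {
    lens <- 8:16
    w <- stats::dnorm(lens, 12, 2)
    length_distribution <- stats::setNames(w / sum(w), lens)
  }
  lens <- as.integer(names(length_distribution))
  if (any(lens < 3L | lens > 30L)) stop("CDR3 lengths must be in [3, 30]")
  if (abs(sum(length_distribution) - 1) > 1e-9)
    stop("length_distribution must sum to 1")
  if (is.null(composition)) {
    composition <- stats::setNames(rep(1, 20), .AA)
    composition[c("G", "S", "Y", "D", "R", "A")] <- 3
    composition <- composition / sum(composition)
  }
  if (is.null(dim(composition)) && abs(sum(composition) - 1) > 1e-9)
    stop("composition must sum to 1")
  structure(list(length_distribution = length_distribution,
                 composition = composition, seed = as.integer(seed)),
            class = "cdr3_config")
}

# Region of each scaffold residue, from its IMGT label.
.scaffold_regions <- function(scaffold) {
  .region_of_imgt(.imgt_numeric(scaffold$imgt_numbers))
}

#' Simulate a repertoire
#'
#' Draws `n` sequences: pick a germline (by `gene_weights`), apply
#' independent per-position somatic hypermutation to the germline-derived
#' segment, and replace CDR3 with a freshly sampled loop. Framework
#' residues differ from the germline only where the SHM process mutated
#' them.
#'
#' @param germlines List of [germline_scaffold()] objects.
#' @param shm An [shm_config()].
#' @param cdr3 A [cdr3_config()].
#' @param n Number of sequences.
#' @param seed Integer seed; the output is reproducible given
#'   `(germlines, shm, cdr3, n, seed)`.
#' @param gene_weights Germline mixing weights (default uniform).
#' @param species Species label stored on each record.
#' @return Data frame with columns `id`, `sequence`, `species`,
#'   `germline_gene`, `n_mutations` (all mutated germline-segment
#'   positions), `n_fw_mutations` (framework only).
#' @export
simulate_repertoire <- function(germlines, shm = shm_config(),
                                cdr3 = cdr3_config(), n, seed = 1L,
                                gene_weights = NULL, species = "simulated") {
  if (length(germlines) == 0L) stop("at least one germline is required")
  if (n < 1L) stop("n must be >= 1")
  gene_weights <- gene_weights %||% rep(1 / length(germlines), length(germlines))
  if (length(gene_weights) != length(germlines) ||
      abs(sum(gene_weights) - 1) > 1e-6)
    stop("gene_weights must match germlines and sum to 1")
  withr::local_seed(seed)
  pre <- lapply(germlines, function(g) {
    regs <- .scaffold_regions(g)
    keep <- regs != "CDR3"
    list(gene = g$gene_id,
         res = strsplit(g$sequence, "")[[1]][keep],
         regs = regs[keep],
         rate = pmin(1, shm$base_rate *
                       unname(shm$hotspot_multipliers[regs[keep]])))
  })
  lens <- as.integer(names(cdr3$length_distribution))
  gidx <- sample.int(length(germlines), n, replace = TRUE, prob = gene_weights)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    g <- pre[[gidx[i]]]
    res <- g$res
    mut <- which(stats::runif(length(res)) < g$rate)
    for (m in mut) {
      res[m] <- sample(.AA, 1L, prob = shm$substitution_matrix[res[m], ])
    }
    cl <- if (length(lens) == 1L) lens else
      sample(lens, 1L, prob = cdr3$length_distribution)
    loop <- .sample_cdr3(cdr3$composition, cl)
    n_fw <- sum(startsWith(g$regs[mut], "FW"))
    out[[i]] <- list(seq = paste(c(res[g$regs %in% c("FW1", "CDR1", "FW2", "CDR2", "FW3")],
                                   loop,
                                   res[g$regs == "FW4"]), collapse = ""),
                     gene = g$gene, nm = length(mut), nfw = n_fw)
  }
  data.frame(id = sprintf("seq%05d", seq_len(n)),
             sequence = vapply(out, `[[`, "", "seq"),
             species = species,
             germline_gene = vapply(out, `[[`, "", "gene"),
             n_mutations = vapply(out, `[[`, 0L, "nm"),
             n_fw_mutations = vapply(out, `[[`, 0L, "nfw"),
             stringsAsFactors = FALSE)
}

.sample_cdr3 <- function(composition, len) {
  if (is.matrix(composition)) {
    idx <- pmin(seq_len(len), nrow(composition))
    paste(vapply(idx, function(j)
      sample(.AA, 1L, prob = composition[j, ]), ""), collapse = "")
  } else {
    paste(sample(.AA, len, replace = TRUE, prob = composition), collapse = "")
  }
}

#' Sample sequences from a PSSM
#'
#' Independent per-position sampling; the ground-truth generator for the
#' distribution-recovery experiments.
#'
#' @param pssm Matrix, positions x 20 residues (rows sum to 1), as built by
#'   [build_pssm()] or [random_pssm()].
#' @param n Number of sequences (0 allowed).
#' @param seed Integer seed.
#' @return Character vector of `n` sequences.
#' @export
sample_from_pssm <- function(pssm, n, seed = 1L) {
  pssm <- .as_pssm_matrix(pssm)
  if (any(abs(rowSums(pssm) - 1) > 1e-6)) stop("PSSM rows must sum to 1")
  if (n == 0L) return(character(0))
  withr::local_seed(seed)
  cols <- vapply(seq_len(nrow(pssm)), function(j)
    sample(.AA, n, replace = TRUE, prob = pssm[j, ]), character(n))
  if (n == 1L) cols <- matrix(cols, nrow = 1L)
  apply(cols, 1L, paste, collapse = "")
}

#' Random PSSM
#'
#' Rows drawn from a symmetric Dirichlet; low `concentration` gives the
#' sparse, peaked per-position profiles typical of protein families.
#'
#' @param n_positions Number of positions.
#' @param seed Integer seed.
#' @param concentration Dirichlet concentration parameter.
#' @return Matrix `n_positions` x 20 with rows summing to 1.
#' @export
random_pssm <- function(n_positions, seed = 1L, concentration = 0.3) {
  withr::local_seed(seed)
  g <- matrix(stats::rgamma(n_positions * 20L, concentration),
              n_positions, 20L)
  g <- pmax(g, 1e-12)
  g <- g / rowSums(g)
  colnames(g) <- .AA
  rownames(g) <- as.character(seq_len(n_positions))
  g
}

.as_pssm_matrix <- function(pssm) {
  if (is.list(pssm) && !is.null(pssm$rows)) pssm$rows else pssm
}

#' Corpus with a planted position-pair dependency
#'
#' Samples from `pssm`, then overwrites position `i` with one of two
#' residues (50/50) and position `j` with a residue that is a deterministic
#' function of the residue at `i`. A PSSM sees 50/50 marginals at `j`; only
#' a context-aware model can predict it.
#'
#' @param pssm Background PSSM.
#' @param n Number of sequences.
#' @param i,j Driver and dependent positions.
#' @param states Two residues for position `i`.
#' @param outcomes Two residues for position `j`, matched to `states`.
#' @param seed Integer seed.
#' @return Character vector of sequences.
#' @export
sample_paired_dependency <- function(pssm, n, i = 10L, j = 30L,
                                     states = c("A", "G"),
                                     outcomes = c("W", "Y"), seed = 1L) {
  s <- sample_from_pssm(pssm, n, seed = seed)
  withr::local_seed(seed + 1L)
  pick <- sample(c(TRUE, FALSE), n, replace = TRUE)
  substr(s, i, i) <- ifelse(pick, states[1], states[2])
  substr(s, j, j) <- ifelse(pick, outcomes[1], outcomes[2])
  s
}

#' Sequence-dependent property model
#'
#' Linear model of a melting-temperature-like property: the expected value
#' of a sequence is `intercept` plus the sum of `effect_weights` whose
#' (IMGT position, residue) pair the sequence matches, plus Gaussian noise.
#'
#' @param effect_weights Data frame with columns `imgt` (character label),
#'   `residue`, `effect` (degrees C).
#' @param intercept Baseline value (degrees C).
#' @param noise_sd Gaussian noise SD (degrees C).
#' @param seed Integer seed.
#' @return A `property_model` object.
#' @export
property_model <- function(effect_weights, intercept = 65, noise_sd = 1.5,
                           seed = 1L) {
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  stopifnot(all(c("imgt", "residue", "effect") %in% names(effect_weights)))
  effect_weights$imgt <- as.character(effect_weights$imgt)
  structure(list(effect_weights = effect_weights, intercept = intercept,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "property_model")
}

#' Default thermostability fixture model
#'
#' Effects sit on positions that actually vary in the simulated
#' repertoires: the allelic framework substitutions that distinguish the
#' built-in genes (IMGT 3, 78, 83, 87) and the arginine content of the
#' CDR3 loop, so the signal is recoverable from sequence.
#'
#' @return A [property_model()].
#' @export
default_property_model <- function() {
  ew <- data.frame(
    imgt = c("3", "78", "83", "87",
             "106", "107", "108", "109", "111"),
    residue = c("K", "V", "T", "I", "R", "R", "R", "R", "R"),
    effect = c(4, 3, -3, 2.5, 2, 2, 2, 2, 2),
    stringsAsFactors = FALSE
  )
  property_model(ew, intercept = 65, noise_sd = 1, seed = 1L)
}

#' Simulate a property value per sequence
#'
#' Sequences are IMGT-numbered against `scaffolds`; unnumberable sequences
#' are skipped with a warning.
#'
#' @param records Repertoire data frame (columns `id`, `sequence`).
#' @param model A [property_model()].
#' @param scaffolds Numbering references, default the built-in VHH set.
#' @return Data frame `id`, `value` for the numberable records.
#' @export
simulate_property <- function(records, model,
                              scaffolds = builtin_scaffolds("vhh")) {
  if (nrow(records) == 0L) stop("records must be non-empty")
  withr::local_seed(model$seed)
  noise <- stats::rnorm(nrow(records), 0, model$noise_sd)
  vals <- rep(NA_real_, nrow(records))
  for (i in seq_len(nrow(records))) {
    ns <- tryCatch(number_sequence(records$sequence[i], scaffolds),
                   nanomlm_unnumberable = function(e) NULL)
    if (is.null(ns)) next
    res <- stats::setNames(ns$residues, ns$imgt)
    hit <- res[model$effect_weights$imgt] == model$effect_weights$residue
    vals[i] <- model$intercept +
      sum(model$effect_weights$effect[which(hit)]) + noise[i]
  }
  drop <- is.na(vals)
  if (any(drop))
    warning(sum(drop), " unnumberable sequence(s) skipped")
  data.frame(id = records$id[!drop], value = vals[!drop],
             stringsAsFactors = FALSE)
}

#' Paired species study conditions
#'
#' Returns the simulation setup for the two-species contrast: species A
#' (nanobody-like, FW2 hallmarks F/E/R/F at IMGT 42/49/50/52) and species B
#' (human-like, V/G/L/W), each with its own SHM and CDR3 configuration.
#' The CDR3 compositions differ between species (A favours the longer,
#' R/Y-rich loops typical of VHH) so the species differ in both framework
#' and loop statistics.
#'
#' @param seed_a,seed_b Seeds wired into the two species' configs.
#' @return List with elements `A` and `B`, each holding `germlines`,
#'   `shm`, `cdr3`, `species`.
#' @export
make_species_pair <- function(seed_a = 1L, seed_b = 2L) {
  comp_a <- stats::setNames(rep(1, 20), .AA)
  comp_a[c("Y", "R", "G", "D", "S", "W")] <- 3.5
  comp_a <- comp_a / sum(comp_a)
  comp_b <- stats::setNames(rep(1, 20), .AA)
  comp_b[c("G", "S", "A", "F", "D", "Y")] <- 3.5
  comp_b <- comp_b / sum(comp_b)
  lens_a <- 10:18; wa <- stats::dnorm(lens_a, 14, 2)
  lens_b <- 6:14; wb <- stats::dnorm(lens_b, 10, 2)
  list(
    A = list(germlines = builtin_scaffolds("vhh"),
             shm = shm_config(seed = seed_a),
             cdr3 = cdr3_config(stats::setNames(wa / sum(wa), lens_a),
                                comp_a, seed = seed_a),
             species = "A"),
    B = list(germlines = builtin_scaffolds("human"),
             shm = shm_config(seed = seed_b),
             cdr3 = cdr3_config(stats::setNames(wb / sum(wb), lens_b),
                                comp_b, seed = seed_b),
             species = "B")
  )
}
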