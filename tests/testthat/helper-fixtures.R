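# Shared fixtures. Heavy objects (trained models, large corpora) are built
# once per test run and cached in this environment; every fixture is fully
# reproducible from the seeds below.

.fx <- new.env(parent = emptyenv())

fx_get <- function(name, build) {
  if (!exists(name, envir = .fx)) assign(name, build(), envir = .fx)
  get(name, envir = .fx)
}

fx_pair <- function() fx_get("pair", function() make_species_pair(1L, 2L))

# Fixed background PSSM for the distribution-recovery experiments.
fx_pssm <- function() fx_get("pssm", function() random_pssm(40L, seed = 101L))

# Tiny model trained on sequences drawn from fx_pssm().
fx_pssm_model <- function() fx_get("pssm_model", function() {
  corpus <- sample_from_pssm(fx_pssm(), 20000L, seed = 202L)
  train_mlm(mlm_model(encoder_config("tiny", seed = 1L)), corpus,
            epochs = 3L, batch_size = 128L, lr = 3e-3, seed = 11L)
})

# Corpus with the planted position-pair dependency and the model trained on
# it (higher masking rate: more learning signal per pass on a small corpus).
fx_context <- function() fx_get("context", function() {
  corpus <- sample_paired_dependency(fx_pssm(), 6000L, i = 10L, j = 30L,
                                     seed = 303L)
  model <- train_mlm(mlm_model(encoder_config("tiny", seed = 2L)), corpus,
                     policy = mask_policy(mask_fraction = 0.25),
                     epochs = 6L, batch_size = 128L, lr = 3e-3, seed = 12L)
  list(corpus = corpus, model = model,
       test = sample_paired_dependency(fx_pssm(), 150L, i = 10L, j = 30L,
                                       seed = 304L))
})

fx_species_data <- function() fx_get("species_data", function() {
  pair <- fx_pair()
  list(
    train_a = simulate_repertoire(pair$A$germlines, pair$A$shm, pair$A$cdr3,
                                  n = 3000L, seed = 21L, species = "A"),
    train_b = simulate_repertoire(pair$B$germlines, pair$B$shm, pair$B$cdr3,
                                  n = 3000L, seed = 22L, species = "B"),
    test_a = simulate_repertoire(pair$A$germlines, pair$A$shm, pair$A$cdr3,
                                 n = 60L, seed = 23L, species = "A"),
    test_b = simulate_repertoire(pair$B$germlines, pair$B$shm, pair$B$cdr3,
                                 n = 60L, seed = 24L, species = "B")
  )
})

fx_model_A <- function() fx_get("model_A", function() {
  train_mlm(mlm_model(encoder_config("tiny", seed = 1L)),
            fx_species_data()$train_a, epochs = 4L, batch_size = 64L,
            lr = 3e-3, seed = 31L)
})

fx_model_B <- function() fx_get("model_B", function() {
  train_mlm(mlm_model(encoder_config("tiny", seed = 2L)),
            fx_species_data()$train_b, epochs = 3L, batch_size = 64L,
            lr = 3e-3, seed = 32L)
})

# Thermostability fixture: 400 species-A records with simulated melting
# temperatures from the default property model.
fx_thermo <- function() fx_get("thermo", function() {
  pair <- fx_pair()
  rec <- simulate_repertoire(pair$A$germlines, pair$A$shm, pair$A$cdr3,
                             n = 400L, seed = 41L, species = "A")
  prop <- simulate_property(rec, default_property_model(),
                            scaffolds = pair$A$germlines)
  rec$value <- prop$value[match(rec$id, prop$id)]
  rec[!is.na(rec$value), ]
})

# A sixth, unmapped germline: species-A gene 1 with six extra FW3
# substitutions, used to plant a secondary mode in the distance curve.
fx_hidden_germline <- function() {
  g <- fx_pair()$A$germlines[[1]]
  res <- strsplit(g$sequence, "")[[1]]
  subs <- list(c(63L, "T"), c(67L, "K"), c(72L, "Q"),
               c(78L, "S"), c(81L, "I"), c(92L, "G"))
  for (s in subs) res[as.integer(s[1])] <- s[2]
  germline_scaffold("VHH_HIDDEN", paste(res, collapse = ""), g$imgt_numbers)
}

# Brute-force global alignment score over all alignments of two short
# strings (independent oracle for the Needleman-Wunsch implementation).
brute_force_align_score <- function(a, b, match = 2, mismatch = -1,
                                    gap = -2) {
  rec <- function(i, j) {
    if (i == 0L && j == 0L) return(0)
    best <- -Inf
    if (i > 0L && j > 0L) {
      s <- if (substr(a, i, i) == substr(b, j, j)) match else mismatch
      best <- max(best, rec(i - 1L, j - 1L) + s)
    }
    if (i > 0L) best <- max(best, rec(i - 1L, j) + gap)
    if (j > 0L) best <- max(best, rec(i, j - 1L) + gap)
    best
  }
  rec(nchar(a), nchar(b))
}

random_aa_string <- function(len) paste(sample(nanomlm:::.AA, len, TRUE),
                                        collapse = "")

# Frozen mock predictor: deterministic hand-specifiable distributions. The
# returned distribution at position i puts `p_true` on `answers[i]` and the
# remainder uniformly on the other residues.
mock_predictor <- function(answers, p_true = 0.6) {
  f <- function(seq, position) {
    p <- rep((1 - p_true) / 19, 20)
    names(p) <- nanomlm:::.AA
    p[answers[position]] <- p_true
    p
  }
  f
}

# Independent brute-force recomputation of an infilling report: explicit
# position-by-position loops and counting, no shared code with the package
# aggregation path.
brute_force_infill_report <- function(predictor, dataset, scaffolds) {
  agg <- list(V = c("FW1", "CDR1", "FW2", "CDR2", "FW3", "CDR3", "FW4"),
              FW = c("FW1", "FW2", "FW3", "FW4"),
              CDRs = c("CDR1", "CDR2", "CDR3"))
  per_seq <- list()
  for (i in seq_len(nrow(dataset))) {
    s <- dataset$sequence[i]
    ns <- tryCatch(number_sequence(s, scaffolds),
                   nanomlm_unnumberable = function(e) NULL)
    if (is.null(ns)) next
    match_at <- logical(nchar(s))
    for (pos in seq_len(nchar(s))) {
      pr <- predictor(s, pos)
      top <- names(pr)[which.max(pr)]
      match_at[pos] <- top == substr(s, pos, pos)
    }
    accs <- c()
    for (r in unique(c(names(agg), ns$region))) {
      members <- if (r %in% names(agg)) agg[[r]] else r
      idx <- which(ns$region %in% members)
      if (length(idx) > 0) accs[r] <- sum(match_at[idx]) / length(idx)
    }
    accs["id"] <- dataset$id[i]
    per_seq[[length(per_seq) + 1]] <- accs
  }
  regions <- setdiff(unique(unlist(lapply(per_seq, names))), "id")
  means <- c()
  for (r in regions) {
    vals <- unlist(lapply(per_seq, function(x) x[r]))
    vals <- as.numeric(vals[!is.na(vals)])
    if (length(vals) > 0) means[r] <- mean(vals)
  }
  list(means = means, n = length(per_seq))
}
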