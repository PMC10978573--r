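test_that("scaffold sets are valid and carry the species hallmarks", {
  for (sp in c("vhh", "human")) {
    scafs <- builtin_scaffolds(sp)
    expect_length(scafs, 5L)
    for (g in scafs) {
      n <- nchar(g$sequence)
      expect_true(n >= 95 && n <= 128)
      ns <- number_sequence(g$sequence, list(g))
      expect_identical(ns$imgt, g$imgt_numbers)
      expect_equal(hallmark_motif(ns), if (sp == "vhh") "FERF" else "VGLW")
    }
  }
  a_seqs <- vapply(builtin_scaffolds("vhh"), `[[`, "", "sequence")
  b_seqs <- vapply(builtin_scaffolds("human"), `[[`, "", "sequence")
  expect_length(intersect(a_seqs, b_seqs), 0L)
})

test_that("zero mutation rate reproduces the germline framework exactly", {
  pair <- fx_pair()
  g <- pair$A$germlines[[1]]
  rec <- simulate_repertoire(list(g), shm_config(base_rate = 0),
                             cdr3_config(stats::setNames(1, 10L)),
                             n = 5L, seed = 9L)
  germ_regions <- nanomlm:::.scaffold_regions(g)
  germ_fw <- strsplit(g$sequence, "")[[1]]
  pre_cdr3 <- paste(germ_fw[germ_regions %in%
                              c("FW1", "CDR1", "FW2", "CDR2", "FW3")],
                    collapse = "")
  fw4 <- paste(germ_fw[germ_regions == "FW4"], collapse = "")
  for (s in rec$sequence) {
    expect_identical(substr(s, 1, nchar(pre_cdr3)), pre_cdr3)
    expect_identical(substr(s, nchar(s) - nchar(fw4) + 1L, nchar(s)), fw4)
  }
  expect_true(all(rec$n_mutations == 0L))
})

test_that("simulation is reproducible and mutation counts are binomial", {
  pair <- fx_pair()
  shm <- shm_config(base_rate = 0.02,
                    hotspot_multipliers = c(FW1 = 1, CDR1 = 1, FW2 = 1,
                                            CDR2 = 1, FW3 = 1, FW4 = 1))
  r1 <- simulate_repertoire(pair$A$germlines, shm, pair$A$cdr3,
                            n = 1000L, seed = 77L)
  r2 <- simulate_repertoire(pair$A$germlines, shm, pair$A$cdr3,
                            n = 1000L, seed = 77L)
  expect_identical(r1, r2)
  # framework length 91 in the base layout; Binomial(91, 0.02)
  fw_len <- 91
  expected <- fw_len * 0.02
  se <- sqrt(fw_len * 0.02 * 0.98 / 1000)
  expect_lt(abs(mean(r1$n_fw_mutations) - expected), 3 * se)
})

test_that("hotspot multipliers scale the per-region mutation rate", {
  pair <- fx_pair()
  g <- pair$A$germlines[[1]]
  shm <- shm_config(base_rate = 0.01,
                    hotspot_multipliers = c(FW1 = 1, CDR1 = 4, FW2 = 1,
                                            CDR2 = 4, FW3 = 1, FW4 = 1))
  rec <- simulate_repertoire(list(g), shm, cdr3_config(), n = 5000L,
                             seed = 55L)
  regions <- nanomlm:::.scaffold_regions(g)
  keep <- regions != "CDR3"
  germ <- strsplit(g$sequence, "")[[1]][keep]
  regs <- regions[keep]
  pre_len <- sum(regs %in% c("FW1", "CDR1", "FW2", "CDR2", "FW3"))
  mat <- matrix(unlist(strsplit(substr(rec$sequence, 1, pre_len), "")),
                nrow = nrow(rec), byrow = TRUE)
  mut <- t(mat) != germ[seq_len(pre_len)]
  rate_by_region <- tapply(rowMeans(mut), regs[seq_len(pre_len)], mean)
  ratio <- rate_by_region[["CDR1"]] / rate_by_region[["FW3"]]
  expect_gt(ratio, 4 * 0.8)
  expect_lt(ratio, 4 * 1.2)
})

test_that("PSSM sampling matches the generating distribution", {
  p <- matrix(0, 3, 20, dimnames = list(NULL, nanomlm:::.AA))
  p[1, "A"] <- 0.5; p[1, "G"] <- 0.5
  p[2, "W"] <- 1
  p[3, "C"] <- 0.25; p[3, "Y"] <- 0.75
  s <- sample_from_pssm(p, 5000L, seed = 3L)
  expect_true(all(nchar(s) == 3L))
  fA <- mean(substr(s, 1, 1) == "A")
  expect_gt(fA, 0.46); expect_lt(fA, 0.54)
  expect_true(all(substr(s, 2, 2) == "W"))
  expect_identical(sample_from_pssm(p, 4L, seed = 5L),
                   sample_from_pssm(p, 4L, seed = 5L))
  expect_identical(sample_from_pssm(p, 0L, seed = 1L), character(0))
  bad <- p; bad[1, "A"] <- 0.9
  expect_error(sample_from_pssm(bad, 2L), "sum to 1")
})

test_that("degenerate one-hot PSSM always emits its consensus", {
  p <- diag(20)[rep(5, 6), ]   # one-hot on residue F at every position
  colnames(p) <- nanomlm:::.AA
  expect_true(all(sample_from_pssm(p, 20L, seed = 1L) == "FFFFFF"))
})

test_that("property model is linear in the matched effects", {
  pair <- fx_pair()
  rec <- simulate_repertoire(pair$A$germlines[1], shm_config(base_rate = 0),
                             cdr3_config(), n = 10L, seed = 2L)
  flat <- property_model(data.frame(imgt = character(0),
                                    residue = character(0),
                                    effect = numeric(0)),
                         intercept = 70, noise_sd = 0)
  v <- simulate_property(rec, flat, pair$A$germlines)
  expect_true(all(v$value == 70))
  # +5 for R at IMGT 50: every species-A framework carries R at 50
  m50 <- property_model(data.frame(imgt = "50", residue = "R", effect = 5),
                        intercept = 70, noise_sd = 0)
  v50 <- simulate_property(rec, m50, pair$A$germlines)
  expect_true(all(v50$value == 75))
})

test_that("property noise SD is recovered from residuals", {
  pair <- fx_pair()
  rec <- simulate_repertoire(pair$A$germlines, pair$A$shm, pair$A$cdr3,
                             n = 200L, seed = 6L)
  base <- property_model(data.frame(imgt = "50", residue = "R", effect = 5),
                         intercept = 65, noise_sd = 0, seed = 8L)
  noisy <- property_model(base$effect_weights, intercept = 65, noise_sd = 2,
                          seed = 8L)
  v0 <- simulate_property(rec, base, pair$A$germlines)
  v2 <- simulate_property(rec, noisy, pair$A$germlines)
  resid <- v2$value - v0$value
  expect_gt(stats::sd(resid), 1.6)
  expect_lt(stats::sd(resid), 2.4)
})

test_that("regression on the true effect features recovers the weights", {
  pair <- fx_pair()
  rec <- simulate_repertoire(pair$A$germlines, pair$A$shm, pair$A$cdr3,
                             n = 300L, seed = 14L)
  pm <- default_property_model()
  pm$noise_sd <- 0.3
  prop <- simulate_property(rec, pm, pair$A$germlines)
  rec <- rec[match(prop$id, rec$id), ]
  X <- matrix(0, nrow(rec), nrow(pm$effect_weights))
  for (i in seq_len(nrow(rec))) {
    ns <- number_sequence(rec$sequence[i], pair$A$germlines)
    res <- stats::setNames(ns$residues, ns$imgt)
    X[i, ] <- as.numeric(res[pm$effect_weights$imgt] ==
                           pm$effect_weights$residue)
    X[i, is.na(X[i, ])] <- 0
  }
  keep <- apply(X, 2, stats::sd) > 0
  fit <- stats::lm(prop$value ~ X[, keep])
  est <- stats::coef(summary(fit))
  # simultaneous bound over all coefficients: 3 SE per weight
  for (k in seq_len(sum(keep))) {
    true_w <- pm$effect_weights$effect[which(keep)[k]]
    expect_lt(abs(est[k + 1, "Estimate"] - true_w),
              3 * est[k + 1, "Std. Error"] + 1e-9)
  }
})

test_that("species pair carries FERF vs VGLW hallmarks and invalid configs fail", {
  pair <- make_species_pair(3L, 4L)
  for (g in pair$A$germlines)
    expect_equal(hallmark_motif(number_sequence(g$sequence, list(g))), "FERF")
  for (g in pair$B$germlines)
    expect_equal(hallmark_motif(number_sequence(g$sequence, list(g))), "VGLW")
  expect_error(simulate_repertoire(list(), shm_config(), cdr3_config(), 5L),
               "at least one germline")
  expect_error(shm_config(base_rate = 1.5), "base_rate")
  expect_error(cdr3_config(stats::setNames(c(0.5, 0.4), c(10, 11))), "sum to 1")
  expect_error(cdr3_config(stats::setNames(1, 31)), "\\[3, 30\\]")
})
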