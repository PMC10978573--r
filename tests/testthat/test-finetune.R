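test_that("pairwise identity matches hand-computable cases", {
  expect_equal(pairwise_identity("ACDEFGHIKL", "ACDEFGHIKL"), 1)
  expect_equal(pairwise_identity("A", "G"), 0)
  expect_equal(pairwise_identity("ACDEFGHIKL", "ACDEFGHIKV"), 0.9)
  expect_error(pairwise_identity("", "A"), "non-empty")
})

test_that("splits hit the 8:1:1 proportions and are deterministic", {
  rec <- data.frame(id = sprintf("s%03d", 1:100),
                    sequence = vapply(1:100, function(i)
                      withr::with_seed(i, random_aa_string(90)), ""),
                    stringsAsFactors = FALSE)
  sp <- split_with_identity_filter(rec, split_spec(seed = 3L))
  expect_equal(nrow(sp$train), 80L)
  expect_equal(nrow(sp$val), 10L)
  expect_equal(nrow(sp$test), 10L)
  expect_length(intersect(sp$train$id, c(sp$val$id, sp$test$id)), 0L)
  sp2 <- split_with_identity_filter(rec, split_spec(seed = 3L))
  expect_identical(sp, sp2)
  expect_error(split_with_identity_filter(rec[1:5, ], split_spec()),
               "at least 10")
})

test_that("a fully duplicated dataset empties val/test and errors", {
  rec <- data.frame(id = sprintf("s%03d", 1:60),
                    sequence = rep(withr::with_seed(1, random_aa_string(90)),
                                   60),
                    stringsAsFactors = FALSE)
  expect_error(
    suppressMessages(split_with_identity_filter(rec, split_spec(seed = 2L))),
    "emptied")
})

test_that("identity filter leaves no val/test record near train", {
  # brute-force soundness check over every emitted pair
  withr::with_seed(7L, {
    base <- random_aa_string(90)
    seqs <- vapply(1:60, function(i) {
      s <- strsplit(base, "")[[1]]
      k <- sample(5:40, 1)     # 5 to 40 substitutions
      pos <- sample(90, k)
      s[pos] <- sample(nanomlm:::.AA, k, TRUE)
      paste(s, collapse = "")
    }, "")
  })
  rec <- data.frame(id = sprintf("s%03d", 1:60), sequence = seqs,
                    stringsAsFactors = FALSE)
  sp <- suppressMessages(
    split_with_identity_filter(rec, split_spec(identity_threshold = 0.8,
                                               seed = 5L)))
  for (s in c(sp$val$sequence, sp$test$sequence))
    for (t in sp$train$sequence)
      expect_lt(pairwise_identity(s, t), 0.8)
})

test_that("threshold 1.0 removes only exact duplicates", {
  withr::with_seed(9L, seqs <- vapply(1:40, function(i) random_aa_string(60), ""))
  rec <- data.frame(id = sprintf("s%03d", 1:40), sequence = seqs,
                    stringsAsFactors = FALSE)
  sp <- split_with_identity_filter(rec, split_spec(identity_threshold = 1.0,
                                                   seed = 1L))
  expect_equal(sp$n_filtered, 0L)
})

test_that("target scaling round-trips and rejects degenerate input", {
  sc <- target_scaler(c(40, 60, 80))
  t <- c(40, 47.3, 62.001, 80)
  expect_equal(unscale_targets(sc, scale_targets(sc, t)), t,
               tolerance = 1e-9)
  expect_true(all(scale_targets(sc, t) >= 0 & scale_targets(sc, t) <= 1))
  expect_error(target_scaler(rep(5, 3)), "zero range")
})

test_that("pearson matches hand computations and validates input", {
  expect_equal(pearson(1:10, 2 * (1:10) + 1), 1)
  expect_equal(pearson(1:10, -(1:10)), -1)
  expect_equal(pearson(c(1, 2, 3), c(1, 3, 2)), 0.5)
  expect_error(pearson(1:3, 1:4), "equal length")
  expect_error(pearson(1:2, 1:2), "at least 3")
  expect_error(pearson(c(1, 1, 1), 1:3), "zero variance")
})

test_that("random baseline is reproducible and near-null", {
  withr::with_seed(11L, targets <- stats::rnorm(200))
  rb <- random_baseline(targets, repeats = 5L, seed = 3L)
  rb2 <- random_baseline(targets, repeats = 5L, seed = 3L)
  expect_identical(rb, rb2)
  expect_lt(abs(rb$mean_r), 3 / sqrt(200))
  expect_length(rb$per_repeat_r, 5L)
})

test_that("head config enforces the four-layer pairing", {
  hc <- head_config("classify")
  expect_equal(hc$output_activation, "sigmoid")
  expect_equal(hc$loss, "bce")
  hr <- head_config("regress")
  expect_equal(hr$output_activation, "linear")
  expect_equal(hr$loss, "mse")
  expect_error(head_config("classify", hidden_dims = c(8, 4)), "length 3")
})

test_that("head forward/backward gradients match finite differences", {
  withr::with_seed(13L, {
    hp <- nanomlm:::.init_head(6L, c(5L, 4L, 3L), seed = 1L)
    P <- matrix(stats::rnorm(4 * 6), 4, 6)
    y <- c(0.2, 0.8, 0.5, 0.1)
    lossfun <- function(hp) {
      out <- nanomlm:::.head_forward(hp, P)$out
      mean((out - y)^2)
    }
    fc <- nanomlm:::.head_forward(hp, P)
    hb <- nanomlm:::.head_backward(hp, fc, 2 * (fc$out - y) / length(y))
    for (nm in names(hp)) {
      for (k in sample(length(hp[[nm]]), min(3, length(hp[[nm]])))) {
        eps <- 1e-6
        p1 <- hp; p1[[nm]][k] <- p1[[nm]][k] + eps
        p2 <- hp; p2[[nm]][k] <- p2[[nm]][k] - eps
        num <- (lossfun(p1) - lossfun(p2)) / (2 * eps)
        expect_equal(hb$grads[[nm]][k], num, tolerance = 1e-4,
                     label = paste("head grad", nm, k))
      }
    }
  })
})

test_that("classifier separates the hallmark species even on a frozen encoder", {
  pair <- fx_pair()
  rec_a <- simulate_repertoire(pair$A$germlines, pair$A$shm, pair$A$cdr3,
                               n = 75L, seed = 61L, species = "A")
  rec_b <- simulate_repertoire(pair$B$germlines, pair$B$shm, pair$B$cdr3,
                               n = 75L, seed = 62L, species = "B")
  rec <- rbind(rec_a, rec_b)
  rec$id <- sprintf("s%03d", seq_len(nrow(rec)))
  rec$label <- as.integer(rec$species == "A")
  m <- mlm_model(encoder_config("tiny", seed = 3L))
  res <- finetune_classifier(m, rec, spec = split_spec(seed = 7L),
                             epochs = 20L, lr = 3e-3,
                             freeze_encoder = TRUE, seed = 5L)
  # this task is trivially separable; it does not isolate pre-training value
  expect_gte(res$roc_auc, 0.9)
  expect_gte(res$pr_auc, 0.8)
})

test_that("shuffled labels give chance-level classification", {
  pair <- fx_pair()
  rec_a <- simulate_repertoire(pair$A$germlines, pair$A$shm, pair$A$cdr3,
                               n = 100L, seed = 63L, species = "A")
  rec_b <- simulate_repertoire(pair$B$germlines, pair$B$shm, pair$B$cdr3,
                               n = 100L, seed = 64L, species = "B")
  rec <- rbind(rec_a, rec_b)
  rec$id <- sprintf("s%03d", seq_len(nrow(rec)))
  withr::with_seed(17L,
    rec$label <- sample(as.integer(rec$species == "A")))
  m <- mlm_model(encoder_config("tiny", seed = 3L))
  res <- finetune_classifier(m, rec, spec = split_spec(seed = 7L),
                             epochs = 4L, freeze_encoder = TRUE, seed = 5L)
  # permutation null band (3 sigma) at a 20-sequence test split
  expect_gt(res$roc_auc, 0.15)
  expect_lt(res$roc_auc, 0.85)
})

test_that("single-class splits are rejected", {
  pair <- fx_pair()
  rec <- simulate_repertoire(pair$A$germlines, pair$A$shm, pair$A$cdr3,
                             n = 40L, seed = 65L)
  rec$label <- 1L
  m <- mlm_model(encoder_config("tiny", seed = 3L))
  expect_error(finetune_classifier(m, rec), "both classes")
})
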