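test_that("candidate enumeration covers every 21-nt window with correct strands", {
  set.seed(10)
  tx <- toy_transcript(100, 20, 80)
  cand <- enumerate_candidates(tx)
  expect_equal(nrow(cand), 80L)
  expect_equal(cand$start, 1:80)
  expect_equal(cand$sense[5], substr(tx$sequence, 5, 25))
  expect_equal(cand$guide, reverse_complement(cand$sense))
  expect_equal(cand$location,
               vapply(cand$start, function(s) region_of(tx, s, 21), ""))

  tx21 <- transcript("t", "T", random_dna(21), 2, 20)
  expect_equal(nrow(enumerate_candidates(tx21)), 1L)
  short <- transcript("s", "S", random_dna(20), 2, 19)
  expect_message(none <- enumerate_candidates(short), "shorter than 21")
  expect_equal(nrow(none), 0L)
})

test_that("feature encoding has the documented structure and counts", {
  set.seed(11)
  guides <- replicate(10, random_dna(21))
  X <- encode_features(guides)
  expect_equal(dim(X), c(10L, 168L))
  pos_block <- X[, 1:84, drop = FALSE]
  expect_true(all(rowSums(pos_block) == 21))
  k1 <- X[, grep("^kmer_.$", colnames(X)), drop = FALSE]
  k2 <- X[, grep("^kmer_..$", colnames(X)), drop = FALSE]
  k3 <- X[, grep("^kmer_...$", colnames(X)), drop = FALSE]
  expect_equal(ncol(k1), 4L); expect_equal(ncol(k2), 16L)
  expect_equal(ncol(k3), 64L)
  expect_true(all(rowSums(k1) == 21))
  expect_true(all(rowSums(k2) == 20))
  expect_true(all(rowSums(k3) == 19))

  allA <- encode_features(strrep("A", 21))
  expect_true(all(allA[1, paste0("pos", 1:21, "_A")] == 1))
  expect_equal(unname(allA[1, "kmer_AAA"]), 19)
  expect_error(encode_features("ACGT"), "21-mer")
})

test_that("training recovers a planted linear model and is deterministic", {
  set.seed(12)
  guides <- unique(replicate(300, random_dna(21)))
  X <- encode_features(guides)
  planted <- numeric(168)
  planted[c(3, 40, 90, 120, 150)] <- c(2.0, -1.5, 0.8, 1.2, -0.7)
  y <- 60 + drop(X %*% planted)
  expect_true(all(y >= 0 & y <= 100))

  m <- train_model(guides, y, regularization = 1e-8)
  expect_equal(predict_efficacy(m, guides), unname(y), tolerance = 1e-6)

  m2 <- train_model(guides, y, regularization = 1e-8)
  expect_identical(m$weights, m2$weights)

  # GCV path is deterministic too, and predicts well on noise-free data
  mg <- train_model(guides, y)
  expect_lt(mean(abs(predict_efficacy(mg, guides) - y)), 0.5)

  expect_error(train_model(rep(guides[1], 5), rep(50, 5)), "degenerate")
  expect_error(train_model(guides[1:3], c(50, 120, 30)), "\\[0, 100\\]")
})

test_that("prediction is affine in feature space and clipped to [0, 100]", {
  set.seed(13)
  guides <- unique(replicate(60, random_dna(21)))
  m <- train_model(guides, runif(length(guides), 20, 90),
                   regularization = 1)
  # affine: prediction differences equal weight-vector contrasts
  g1 <- guides[1]; g2 <- guides[2]
  d <- encode_features(g1) - encode_features(g2)
  expect_equal(predict_efficacy(m, g1) - predict_efficacy(m, g2),
               unname(drop(d %*% m$weights)), tolerance = 1e-10)

  hi <- m; hi$weights[] <- 0; hi$intercept <- 120
  expect_equal(predict_efficacy(hi, g1), 100)
  lo <- m; lo$weights[] <- 0; lo$intercept <- 85
  expect_equal(predict_efficacy(lo, g1), 85)

  untrained <- structure(list(trained = FALSE), class = "sirna_scoring_model")
  expect_error(predict_efficacy(untrained, g1), "not a trained")

  # 3-feature toy model checked by hand: intercept 10, w(pos1_A)=5,
  # w(kmer_A)=2 -> all-A guide: 10 + 5 + 2*21 = 57
  toy <- m
  toy$weights[] <- 0
  toy$intercept <- 10
  toy$weights["pos1_A"] <- 5
  toy$weights["kmer_A"] <- 2
  expect_equal(predict_efficacy(toy, strrep("A", 21)), 57)
})

test_that("positional correction reproduces the location and distance effects", {
  expect_equal(apply_positional_correction(90, "CDS", 1), 90)
  # 1% per 100 bp over 1000 bp
  expect_equal(apply_positional_correction(90, "CDS", 1001), 80)
  # 39-point CDS-vs-5'UTR contrast
  expect_equal(apply_positional_correction(90, "FIVE_UTR", 1), 51)
  # 3'UTR sits 26 below CDS (13 above 5'UTR)
  expect_equal(apply_positional_correction(90, "THREE_UTR", 1), 64)
  expect_error(apply_positional_correction(90, "INTRON", 1), "unknown location")
  expect_error(apply_positional_correction(90, "CDS", 0), "start")

  # monotone non-increasing in start for slope <= 0, and clipped
  starts <- seq(1, 9001, by = 500)
  sc <- apply_positional_correction(50, "CDS", starts)
  expect_true(all(diff(sc) <= 0))
  expect_true(all(sc >= 0 & sc <= 100))
})

test_that("polynucleotide tracts are detected at the >= 4 run threshold", {
  expect_true(has_polyn_tract("GAAAAC"))
  expect_false(has_polyn_tract("AGAGAGAG"))
  expect_true(has_polyn_tract("UUUU"))
  expect_false(has_polyn_tract("AAACCCGGG"))
  expect_true(has_polyn_tract("AAACCCGGG", min_run = 3))
})

test_that("filtering applies strict score threshold and complete flags", {
  cand <- data.frame(
    target_id = "t", gene = "G",
    start = c(1, 30, 60, 90, 120),
    sense = c(paste0(strrep("AC", 10), "G"),      # clean
              paste0(strrep("CA", 10), "G"),      # clean
              paste0("GAAAAC", strrep("TG", 7), "C"),  # poly-A tract
              paste0(strrep("GT", 10), "A"),      # clean
              paste0(strrep("TC", 10), "A")),     # clean
    location = c("CDS", "FIVE_UTR", "CDS", "CDS", "CDS"),
    base_score = c(92, 85, 90, 80, 79),
    n_offtargets = c(0L, 0L, 0L, 0L, 2L),
    stringsAsFactors = FALSE
  )
  rules <- list(min_score = 80, cds_only = TRUE, no_polyn = TRUE,
                max_offtargets = 0)
  res <- filter_candidates(cand, rules)
  expect_equal(res$retained$start, 1)
  expect_equal(nrow(res$retained) + nrow(res$rejected), nrow(cand))

  # score exactly 80 fails the strict > threshold
  expect_true("LOW_SCORE" %in%
                strsplit(res$rejected$flags[res$rejected$start == 90], ",")[[1]])
  expect_equal(res$rejected$flags[res$rejected$start == 30], "NOT_CDS")
  expect_equal(res$rejected$flags[res$rejected$start == 60], "POLYN_TRACT")
  # flags are complete: the last row fails both score and off-targets
  expect_setequal(strsplit(res$rejected$flags[res$rejected$start == 120], ",")[[1]],
                  c("LOW_SCORE", "OFFTARGETS"))

  # empty rule set is the identity
  none <- filter_candidates(cand, list())
  expect_equal(none$retained, cand)
  expect_equal(nrow(none$rejected), 0L)

  # off-target rule without counts is an error
  expect_error(filter_candidates(cand[, setdiff(names(cand), "n_offtargets")],
                                 list(max_offtargets = 0)),
               "n_offtargets")
})

test_that("spaced selection is greedy by score with small-start tie-break", {
  cand <- data.frame(
    target_id = "t", start = c(10, 15, 40, 100),
    corrected_score = c(95, 90, 95, 70),
    stringsAsFactors = FALSE
  )
  # overlapping 95 and 90: only the 95 survives at min_gap = 21
  sel <- select_spaced(cand, k = 4, min_gap = 21)
  expect_false(15 %in% sel$start)
  expect_true(all(c(10, 40, 100) %in% sel$start))

  # min_gap = 0 is plain top-k by score
  topk <- select_spaced(cand, k = 2, min_gap = 0)
  expect_setequal(topk$start, c(10, 40))

  # equal scores: smaller start wins the single slot
  one <- select_spaced(cand[c(1, 3), ], k = 1, min_gap = 21)
  expect_equal(one$start, 10)

  # spacing is per transcript
  two_tx <- data.frame(target_id = c("a", "b"), start = c(10, 12),
                       corrected_score = c(90, 89))
  expect_equal(nrow(select_spaced(two_tx, k = 2, min_gap = 21)), 2L)
})

test_that("efficacy grading uses the 70/50 boundaries", {
  expect_equal(grade_efficacy(c(70, 55, 49.9, 100, 50, 69.99, 0, -10)),
               c("HIGH", "MODERATE", "INEFFICIENT", "HIGH", "MODERATE",
                 "MODERATE", "INEFFICIENT", "INEFFICIENT"))
})
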