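test_that("covariate table assembly joins all feature blocks by sirna_id", {
  set.seed(40)
  tab0 <- simulate_study(seed = 40)
  cand <- data.frame(sirna_id = tab0$sirna_id, gene = tab0$gene,
                     start = tab0$start, location = tab0$location,
                     sense = replicate(nrow(tab0), random_dna(21)),
                     base_score = runif(nrow(tab0), 81, 98),
                     stringsAsFactors = FALSE)
  cand$guide <- reverse_complement(cand$sense)
  ot <- data.frame(sirna_id = cand$sirna_id,
                   n_offtargets = rpois(nrow(cand), 0.5))
  sp <- data.frame(sirna_id = cand$sirna_id, n_seqs = 10L, hit1 = 8L,
                   hit2 = 1L, hit3plus = 1L)
  ec <- data.frame(sirna_id = cand$sirna_id, target_exon_length = 150L,
                   spans_junction = 0L)
  eff <- data.frame(sirna_id = cand$sirna_id,
                    efficacy_pct = tab0$efficacy_pct)

  expect_message(
    tab <- build_covariate_table(cand, ot, sp, ec, NULL, eff),
    "no accessibility")
  expect_equal(nrow(tab), 88L)
  expect_false("accessibility" %in% names(tab))
  expect_true(all(c("dsir_score", "gene", "position_bp", "location",
                    "n_offtargets", "polyn", "seed_hit3plus",
                    "target_exon_length", "efficacy_pct") %in% names(tab)))

  # a guide with a poly-A tract gets polyn = 1
  cand2 <- cand
  cand2$guide[1] <- paste0("AAAA", substr(cand2$guide[1], 5, 21))
  tab2 <- suppressMessages(build_covariate_table(cand2, ot, sp, ec, NULL, eff))
  expect_equal(tab2$polyn[tab2$sirna_id == cand2$sirna_id[1]], 1L)

  # efficacy for an unknown siRNA is a hard error
  eff_bad <- rbind(eff, data.frame(sirna_id = "si_999", efficacy_pct = 50))
  expect_error(build_covariate_table(cand, ot, sp, ec, NULL, eff_bad),
               "si_999")
})

test_that("full model ANOVA conserves sums of squares and is row-order invariant", {
  tab <- simulate_study(seed = 41, full_covariates = TRUE)
  res <- fit_full_model(tab)
  a <- res$anova
  expect_equal(sum(a$sum_sq),
               sum((tab$efficacy_pct - mean(tab$efficacy_pct))^2),
               tolerance = 1e-8)
  expect_true("Residuals" %in% a$term)
  expect_true(all(a$p[!is.na(a$p)] >= 0 & a$p[!is.na(a$p)] <= 1))

  perm <- tab[sample(nrow(tab)), ]
  res2 <- fit_full_model(perm)
  expect_equal(res$anova$sum_sq, res2$anova$sum_sq, tolerance = 1e-8)
  expect_equal(sort(res$coefficients), sort(res2$coefficients),
               tolerance = 1e-8)

  # duplicated covariate column -> rank-deficiency error naming the alias
  dup <- tab
  dup$n_transcriptome_hits <- dup$n_offtargets
  expect_error(fit_full_model(dup), "aliased")

  # marginal tests run and cover the same terms
  resm <- fit_full_model(tab, anova = "marginal")
  expect_setequal(setdiff(resm$anova$term, "Residuals"), res$terms_used)
})

test_that("only the planted covariates come out significant in the full model", {
  hits <- c(gene = 0, location = 0, position = 0, other = 0)
  n_sim <- 60
  for (s in 1:n_sim) {
    tab <- simulate_study(seed = 500 + s, full_covariates = TRUE)
    a <- fit_full_model(tab)$anova
    p <- setNames(a$p, a$term)
    hits["gene"] <- hits["gene"] + (p[["gene"]] < 0.05)
    hits["location"] <- hits["location"] + (p[["location"]] < 0.05)
    hits["position"] <- hits["position"] + (p[["position_bp"]] < 0.05)
    null_terms <- setdiff(a$term, c("gene", "location", "position_bp",
                                    "Residuals"))
    hits["other"] <- hits["other"] + mean(p[null_terms] < 0.05)
  }
  expect_gt(hits[["gene"]] / n_sim, 0.9)
  expect_gt(hits[["location"]] / n_sim, 0.9)
  expect_gt(hits[["position"]] / n_sim, 0.9)
  # null covariates reject near the nominal 5% rate
  expect_lt(hits[["other"]] / n_sim, 0.2)
})

test_that("reduced model recovers planted gene, location and position effects", {
  params <- efficacy_gen_params()
  n_sim <- 60
  slopes <- numeric(n_sim); cds <- numeric(n_sim); utr3 <- numeric(n_sim)
  hdac6 <- numeric(n_sim)
  for (s in 1:n_sim) {
    r <- refit_reduced(simulate_study(params, seed = 600 + s))
    slopes[s] <- r$slope_per_100bp
    cds[s] <- r$location_offsets[["CDS"]]
    utr3[s] <- r$location_offsets[["THREE_UTR"]]
    hdac6[s] <- r$gene_offsets[["HDAC6"]]
  }
  mc_se <- function(x) sd(x) / sqrt(length(x))
  expect_lt(abs(mean(slopes) - params$slope_per_100bp), 3 * mc_se(slopes))
  expect_lt(abs(mean(cds) - params$location_offsets[["CDS"]]), 3 * mc_se(cds))
  expect_lt(abs(mean(utr3) - params$location_offsets[["THREE_UTR"]]),
            3 * mc_se(utr3))
  expect_lt(abs(mean(hdac6) - params$gene_offsets[["HDAC6"]]),
            3 * mc_se(hdac6))

  # zero planted effects: slope estimate centered at 0
  null_slopes <- vapply(1:40, function(s) {
    refit_reduced(simulate_study(seed = 700 + s,
                                 null_response = TRUE))$slope_per_100bp
  }, 0)
  expect_lt(abs(mean(null_slopes)), 3 * mc_se(null_slopes))
})

test_that("reduced-model reporting uses the documented reference levels", {
  tab <- simulate_study(seed = 42)
  r <- refit_reduced(tab)
  expect_false("BCL2L1" %in% names(r$gene_offsets))
  expect_setequal(names(r$location_offsets), c("CDS", "THREE_UTR"))
  expect_named(r$p_values, c("gene", "location", "position"))
  expect_equal(nrow(r$fitted_values), nrow(tab))
  expect_equal(r$fitted_values$measured, tab$efficacy_pct)
})

test_that("per-gene positional test detects strong decay and stays calibrated", {
  # strong planted decay at a realistic per-gene design (HDAC6-like:
  # long CDS, ~13 CDS sites) is detected at p < 0.0005 most of the time
  params <- efficacy_gen_params(slope_per_100bp = -2.2)
  detected <- vapply(1:40, function(s) {
    tab <- simulate_study(params, seed = 800 + s)
    per_gene_position_test(tab, "HDAC6")$p
  }, 0)
  expect_gt(mean(detected < 0.0005, na.rm = TRUE), 0.5)
  expect_lt(median(detected, na.rm = TRUE), 0.0005)

  # planted zero slope: p roughly uniform (mean near 0.5)
  null_p <- vapply(1:60, function(s) {
    tab <- simulate_study(seed = 900 + s, null_response = TRUE)
    per_gene_position_test(tab, "HDAC6")$p
  }, 0)
  expect_gt(mean(null_p), 0.3)
  expect_lt(mean(null_p), 0.7)

  # too few CDS records: declared not testable, not p = 1
  small <- simulate_study(seed = 43)
  small <- small[small$gene != "HDAC6" | small$location != "CDS" |
                   seq_len(nrow(small)) %in%
                     head(which(small$gene == "HDAC6" &
                                  small$location == "CDS"), 3), ]
  res <- per_gene_position_test(small, "HDAC6")
  expect_false(res$testable)
  expect_true(is.na(res$p))
})
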