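#' Default first-round study design
#'
#' The transcript-level design of the default synthetic knockdown study:
#' eight cancer-relevant target genes with their transcript lengths, CDS
#' lengths, exon counts and number of siRNA tested in the first screening
#' round (88 siRNA in total). Used by [simulate_study()] as the default
#' template so that simulated panels have the size and structure of a
#' realistic validation screen.
#'
#' @return A data.frame with columns `symbol`, `total_length`,
#'   `cds_length`, `n_exons`, `n_sirna`.
#' @export
default_study_design <- function() {
  data.frame(
    symbol = c("BCL2L1", "CSNK2A1", "CSNK2A2", "CSNK2B",
               "ERCC1", "ERCC2", "HIF1A", "HDAC6"),
    total_length = c(2575L, 2732L, 1674L, 1128L, 3400L, 2568L, 4082L, 4099L),
    cds_length = c(702L, 1176L, 1053L, 648L, 894L, 2283L, 2481L, 3648L),
    n_exons = c(3L, 13L, 12L, 7L, 10L, 23L, 15L, 29L),
    n_sirna = c(12L, 10L, 10L, 10L, 9L, 15L, 9L, 13L),
    stringsAsFactors = FALSE
  )
}

# 35% of the untranslated length sits 5' of the CDS — a typical mRNA
# architecture; the design table records only total and CDS lengths.
utr5_length <- function(total_length, cds_length, utr5_share = 0.35) {
  pmax(1L, as.integer(round(utr5_share * (total_length - cds_length))))
}

#' Generating-model parameters for synthetic siRNA efficacies
#'
#' Defaults mirror the fitted effects of the reduced three-covariate
#' knockdown model: gene offsets relative to the BCL2L1 reference, location
#' offsets relative to the 5'UTR reference (CDS +39, 3'UTR +13), a
#' positional decay of 1 percentage point per 100 bp, and Gaussian
#' replicate-level noise. HIF1A, with no individually resolvable offset,
#' sits at the reference level.
#'
#' @param gene_offsets Named numeric, percent, relative to `BCL2L1 = 0`.
#' @param location_offsets Named numeric, percent, relative to
#'   `FIVE_UTR = 0`.
#' @param slope_per_100bp Percent change per 100 bp of target-site distance
#'   from the transcript 5' end (default -1.0).
#' @param noise_sd Gaussian noise standard deviation, percent (default 10).
#' @param baseline Mean efficacy of a 5'UTR site at position 1 in the
#'   reference gene, percent (default 45).
#' @return A list of class `"efficacy_gen_params"`.
#' @export
efficacy_gen_params <- function(gene_offsets = c(BCL2L1 = 0, CSNK2A1 = 9,
                                                 CSNK2A2 = 10, CSNK2B = 8,
                                                 ERCC1 = 7, ERCC2 = -11,
                                                 HIF1A = 0, HDAC6 = -22),
                                location_offsets = c(FIVE_UTR = 0, CDS = 39,
                                                     THREE_UTR = 13),
                                slope_per_100bp = -1.0,
                                noise_sd = 10,
                                baseline = 45) {
  stopifnot(all(is.finite(gene_offsets)), all(is.finite(location_offsets)),
            is.finite(slope_per_100bp), noise_sd >= 0, is.finite(baseline),
            setequal(names(location_offsets), REGION_LEVELS))
  structure(list(gene_offsets = gene_offsets,
                 location_offsets = location_offsets,
                 slope_per_100bp = slope_per_100bp,
                 noise_sd = noise_sd, baseline = baseline),
            class = "efficacy_gen_params")
}

#' Generate a random annotated transcriptome
#'
#' Uniform-random sequences with CDS boundaries placed by the UTR
#' fractions and a random exon partition. Deterministic for a fixed seed.
#'
#' @param n_genes Number of transcripts.
#' @param length_range Integer range of transcript lengths (default
#'   1128-4099 nt, the span of a typical validation panel).
#' @param utr_fractions Length-2 numeric: fractions of the transcript
#'   assigned to the 5'UTR and 3'UTR (their sum must be < 1).
#' @param seed Integer seed.
#' @param symbols Optional gene symbols (default `GENE1..n`).
#' @return A named list of [transcript()] objects.
#' @export
make_transcriptome <- function(n_genes, length_range = c(1128L, 4099L),
                               utr_fractions = c(0.1, 0.3), seed,
                               symbols = NULL) {
  stopifnot(n_genes >= 1L, length_range[1L] >= 200L,
            sum(utr_fractions) < 1, all(utr_fractions > 0))
  if (is.null(symbols)) symbols <- paste0("GENE", seq_len(n_genes))
  set.seed(as.integer(seed))
  out <- vector("list", n_genes)
  for (i in seq_len(n_genes)) {
    n <- sample(length_range[1L]:length_range[2L], 1L)
    seq <- paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                 collapse = "")
    cds_start <- max(2L, as.integer(round(utr_fractions[1L] * n)) + 1L)
    cds_end <- min(n - 1L, n - as.integer(round(utr_fractions[2L] * n)))
    n_exons <- sample(2:20, 1L)
    cuts <- sort(sample(seq_len(n - 1L), n_exons - 1L))
    exon_lengths <- diff(c(0L, cuts, n))
    out[[i]] <- transcript(paste0("SYN_", sprintf("%03d", i)), symbols[i],
                           seq, cds_start, cds_end, exon_lengths)
  }
  names(out) <- vapply(out, `[[`, "", "id")
  out
}

#' Plant near-match off-target sites into a transcriptome
#'
#' Overwrites randomly chosen 21-nt windows with copies of `sense_21mer`
#' carrying exactly `n_mismatches` random substitutions, and returns both
#' the modified transcriptome and a ground-truth manifest for oracle
#' testing. Planting replaces bases in place, so transcript lengths and
#' annotations stay valid. Planted windows do not overlap one another.
#'
#' @param transcriptome Named list of [transcript()] objects.
#' @param sense_21mer The 21-nt sense sequence to plant.
#' @param n_sites Number of sites to plant.
#' @param n_mismatches Substitutions per planted copy (0-3).
#' @param seed Integer seed.
#' @return A list: `transcriptome` (modified) and `manifest` (data.frame
#'   `subject_id`, `subject_start`, `n_mismatches`, `mismatch_positions`
#'   — comma-joined 1-based positions on the pattern).
#' @export
plant_offtarget <- function(transcriptome, sense_21mer, n_sites,
                            n_mismatches, seed) {
  sense_21mer <- normalize_sequence(sense_21mer)
  stopifnot(nchar(sense_21mer) == 21L, n_mismatches >= 0L, n_mismatches <= 3L,
            n_sites >= 1L)
  if (any(vapply(transcriptome, function(tx) nchar(tx$sequence), 0L) < 21L)) {
    stop("plant_offtarget: site longer than some host transcript")
  }
  set.seed(as.integer(seed))
  bases <- c("A", "C", "G", "T")
  taken <- lapply(transcriptome, function(tx) integer(0))
  manifest <- vector("list", n_sites)
  for (s in seq_len(n_sites)) {
    repeat {
      ti <- sample(seq_along(transcriptome), 1L)
      tx <- transcriptome[[ti]]
      pos <- sample.int(nchar(tx$sequence) - 20L, 1L)
      if (!length(taken[[ti]]) || all(abs(taken[[ti]] - pos) >= 21L)) break
    }
    taken[[ti]] <- c(taken[[ti]], pos)
    copy <- strsplit(sense_21mer, "")[[1]]
    mm <- sort(sample.int(21L, n_mismatches))
    for (p in mm) copy[p] <- sample(setdiff(bases, copy[p]), 1L)
    seq <- transcriptome[[ti]]$sequence
    substr(seq, pos, pos + 20L) <- paste(copy, collapse = "")
    transcriptome[[ti]]$sequence <- seq
    manifest[[s]] <- data.frame(
      subject_id = tx$id, subject_start = pos,
      n_mismatches = n_mismatches,
      mismatch_positions = paste(mm, collapse = ","),
      stringsAsFactors = FALSE)
  }
  list(transcriptome = transcriptome, manifest = do.call(rbind, manifest))
}

#' Draw siRNA efficacies from the generating model
#'
#' `efficacy = baseline + gene_offset + location_offset +
#' slope_per_100bp * (start - 1) / 100 + N(0, noise_sd)`, clipped to
#' `[-50, 100]` (noise can produce apparent up-regulation, as in real
#' screens).
#'
#' @param candidates data.frame with columns `gene`, `location`, `start`
#'   and ideally `sirna_id` (used to name the result).
#' @param params An [efficacy_gen_params()] object.
#' @param seed Integer seed.
#' @return Named numeric vector of efficacies (percent knockdown).
#' @export
simulate_efficacies <- function(candidates, params = efficacy_gen_params(),
                                seed) {
  stopifnot(inherits(params, "efficacy_gen_params"),
            all(c("gene", "location", "start") %in% names(candidates)))
  unknown <- setdiff(unique(candidates$gene), names(params$gene_offsets))
  if (length(unknown)) {
    stop("simulate_efficacies: no gene offset for: ",
         paste(unknown, collapse = ", "))
  }
  set.seed(as.integer(seed))
  mu <- params$baseline +
    params$gene_offsets[candidates$gene] +
    params$location_offsets[candidates$location] +
    params$slope_per_100bp * (candidates$start - 1) / 100
  eff <- mu + stats::rnorm(nrow(candidates), sd = params$noise_sd)
  eff <- pmin(100, pmax(-50, eff))
  names(eff) <- if (!is.null(candidates$sirna_id)) candidates$sirna_id else
    paste0("si_", sprintf("%03d", seq_len(nrow(candidates))))
  eff
}

#' Simulate a complete synthetic knockdown study
#'
#' Draws one screening panel under the generating model: target sites are
#' placed uniformly along each design transcript, labelled with their
#' region, and assigned efficacies by [simulate_efficacies()]. With
#' `full_covariates = TRUE` the remaining covariates of the full model
#' (predicted score, off-target and seed-match counts, polynucleotide
#' flag, exon context, accessibility) are drawn from plausible null
#' distributions — by construction none of them carries signal, which is
#' exactly what per-term calibration tests need.
#'
#' @param params An [efficacy_gen_params()] object.
#' @param seed Integer seed.
#' @param design Study-design data.frame (default [default_study_design()]).
#' @param full_covariates Add the non-signal covariates (default FALSE).
#' @param null_response When TRUE the response is pure noise around the
#'   baseline: all gene/location/position effects are zeroed.
#' @return A covariate table (one row per siRNA) with `sirna_id`, `gene`,
#'   `position_bp`, `location`, `efficacy_pct` and, optionally, the full
#'   covariate set.
#' @export
simulate_study <- function(params = efficacy_gen_params(), seed,
                           design = default_study_design(),
                           full_covariates = FALSE,
                           null_response = FALSE) {
  stopifnot(inherits(params, "efficacy_gen_params"))
  if (null_response) {
    params <- efficacy_gen_params(
      gene_offsets = params$gene_offsets * 0,
      location_offsets = params$location_offsets * 0,
      slope_per_100bp = 0, noise_sd = params$noise_sd,
      baseline = params$baseline)
  }
  set.seed(as.integer(seed))
  utr5 <- utr5_length(design$total_length, design$cds_length)
  rows <- lapply(seq_len(nrow(design)), function(i) {
    starts <- sample.int(design$total_length[i] - 20L, design$n_sirna[i],
                         replace = FALSE)
    cds_start <- utr5[i] + 1L
    cds_end <- utr5[i] + design$cds_length[i]
    loc <- vapply(starts, function(s) {
      window_region(s, 21L, cds_start, cds_end, design$total_length[i])
    }, "")
    data.frame(gene = design$symbol[i], start = starts, location = loc,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab$sirna_id <- paste0("si_", sprintf("%03d", seq_len(nrow(tab))))
  eff_seed <- sample.int(.Machine$integer.max - 1L, 1L)
  eff <- simulate_efficacies(tab, params, seed = eff_seed)
  tab$position_bp <- tab$start
  tab$efficacy_pct <- unname(eff)
  if (full_covariates) {
    n <- nrow(tab)
    tab$dsir_score <- stats::runif(n, 80.5, 98)
    tab$n_offtargets <- stats::rpois(n, 0.5)
    tab$polyn <- stats::rbinom(n, 1L, 0.15)
    tab$n_transcriptome_hits <- tab$n_offtargets + stats::rpois(n, 0.3)
    n_seqs <- stats::rpois(n, 60)
    h1 <- stats::rbinom(n, n_seqs, 0.8)
    h2 <- stats::rbinom(n, n_seqs - h1, 0.7)
    tab$seed_n_seqs <- n_seqs
    tab$seed_hit1 <- h1
    tab$seed_hit2 <- h2
    tab$seed_hit3plus <- n_seqs - h1 - h2
    tab$target_exon_length <- as.integer(round(stats::rlnorm(n, log(170), 0.6)))
    tab$spans_junction <- stats::rbinom(n, 1L, 0.3)
    tab$accessibility <- stats::runif(n)
  }
  keep <- c("sirna_id", intersect(covariate_order, names(tab)),
            "gene", "start", "efficacy_pct")
  tab[, unique(keep), drop = FALSE]
}

# majority-overlap region call on raw boundary numbers (same rule as
# region_of, without needing a transcript object)
window_region <- function(start, site_len, cds_start, cds_end, total) {
  end <- start + site_len - 1L
  ov <- c(
    FIVE_UTR = max(0L, min(end, cds_start - 1L) - start + 1L),
    CDS = max(0L, min(end, cds_end) - max(start, cds_start) + 1L),
    THREE_UTR = max(0L, end - max(start, cds_end + 1L) + 1L)
  )
  REGION_LEVELS[4L - which.max(rev(ov))]
}

#' Simulate qPCR cycle-threshold records
#'
#' Generates Ct tables consistent with the comparative-quantification
#' model: for each siRNA sample the target Ct is shifted by
#' `-log(q) / log(e)` cycles relative to the mock calibrator, reference
#' genes are unshifted, and independent Gaussian noise of `replicate_sd`
#' cycles is added to every measurement. Reactions are generated in
#' triplicate by default.
#'
#' @param true_q Named positive vector: true relative expression per siRNA
#'   sample.
#' @param target_gene Target gene name.
#' @param efficiencies Named amplification rates per gene; genes absent
#'   default to 2.0.
#' @param replicate_sd Ct noise standard deviation in cycles.
#' @param n_replicates Replicates per reaction (default 3).
#' @param seed Integer seed.
#' @param normalizers Reference gene names (default `c("36B4", "HPRT")`).
#' @param calibrator Calibrator sample label (default `"mock"`).
#' @param base_ct Baseline Ct of every assay in the calibrator (default 20).
#' @return A Ct record data.frame (see [read_ct_table()] for columns).
#' @export
simulate_ct <- function(true_q, target_gene, efficiencies = NULL,
                        replicate_sd = 0.15, n_replicates = 3L, seed,
                        normalizers = c("36B4", "HPRT"),
                        calibrator = "mock", base_ct = 20) {
  stopifnot(all(true_q > 0), !is.null(names(true_q)), n_replicates >= 1L)
  set.seed(as.integer(seed))
  eff_of <- function(gene) {
    if (!is.null(efficiencies) && gene %in% names(efficiencies))
      efficiencies[[gene]] else 2.0
  }
  samples <- c(names(true_q), calibrator)
  genes <- c(target_gene, normalizers)
  grid <- expand.grid(sample = samples, gene = genes,
                      replicate = seq_len(n_replicates),
                      stringsAsFactors = FALSE)
  shift <- ifelse(grid$gene == target_gene & grid$sample != calibrator,
                  -log(true_q[grid$sample]) / log(vapply(grid$gene, eff_of, 0)),
                  0)
  data.frame(
    run_id = "run1",
    sample = grid$sample,
    gene = grid$gene,
    role = ifelse(grid$gene == target_gene, "TARGET", "NORMALIZER"),
    replicate = grid$replicate,
    ct = base_ct + shift + stats::rnorm(nrow(grid), sd = replicate_sd),
    efficiency = vapply(grid$gene, eff_of, 0),
    stringsAsFactors = FALSE
  )
}
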