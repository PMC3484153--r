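#' Build a pipeline run configuration
#'
#' Collects paths, thresholds and seeds for [run_pipeline()]. Every output
#' table carries the package version, a hash of the resolved configuration
#' and the seed in commented header lines, so a report bundle is fully
#' reproducible from its own headers.
#'
#' @param fasta,annot Target transcript FASTA and annotation TSV
#'   (see [read_transcripts()]).
#' @param out_dir Output directory (created if missing).
#' @param databank_fasta,databank_annot Optional off-target databank; when
#'   `NULL` the target transcriptome itself is the databank.
#' @param utr3_fasta Optional 3'UTR FASTA for seed-match profiling; when
#'   `NULL`, annotated 3'UTRs of the databank are used.
#' @param training_tsv Optional TSV with columns `guide`, `efficacy` used
#'   to train the scoring model; without it candidates carry no predicted
#'   score and the score filter is skipped (logged).
#' @param ct_tsv Optional Ct table for the quantify stage.
#' @param efficacy_tsv Optional TSV `sirna_id`, `efficacy_pct` for the
#'   analyze stage (the quantify stage output can be reused here).
#' @param min_score,cds_only,no_polyn,max_offtargets Candidate filter rules
#'   (see [filter_candidates()]).
#' @param mismatches Off-target scan mismatch tolerance.
#' @param top_k,min_gap Spaced-selection parameters (see [select_spaced()]).
#' @param target_gene,normalizers,calibrator,control_id,control_threshold
#'   Quantify-stage settings (see [estimate_extinction()], [validate_run()]).
#' @param alpha ANOVA significance threshold for reporting.
#' @param seed Integer seed recorded in outputs.
#' @param dry_run Print the resolved plan without writing anything.
#' @return A list of class `"run_config"`.
#' @export
run_config <- function(fasta, annot, out_dir,
                       databank_fasta = NULL, databank_annot = NULL,
                       utr3_fasta = NULL, training_tsv = NULL,
                       ct_tsv = NULL, efficacy_tsv = NULL,
                       min_score = 80, cds_only = TRUE, no_polyn = TRUE,
                       max_offtargets = 0L, mismatches = 3L,
                       top_k = 5L, min_gap = 21L,
                       target_gene = NULL, normalizers = c("36B4", "HPRT"),
                       calibrator = "mock", control_id = NULL,
                       control_threshold = 80, alpha = 0.05,
                       seed = 1L, dry_run = FALSE) {
  stopifnot(min_score >= 0, min_score <= 100, mismatches >= 0L,
            control_threshold > 0, control_threshold <= 100,
            alpha > 0, alpha < 1, min_gap >= 0L, top_k >= 1L)
  cfg <- as.list(environment())
  class(cfg) <- "run_config"
  cfg
}

config_hash <- function(config) {
  # the hash captures the analysis settings; where outputs land (or a dry
  # run) does not change what is computed
  config <- config[setdiff(names(config), c("out_dir", "dry_run"))]
  dump <- paste(names(config),
                vapply(config, function(x) paste(format(x), collapse = ","), ""),
                sep = "=", collapse = ";")
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(dump, tmp)
  unname(tools::md5sum(tmp))
}

write_report_tsv <- function(df, path, config, flatten = TRUE) {
  if (flatten) {
    is_list <- vapply(df, is.list, TRUE)
    for (j in which(is_list)) {
      df[[j]] <- vapply(df[[j]], paste, "", collapse = ",")
    }
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# sirnadesign ",
           as.character(utils::packageVersion("sirnadesign"))),
    paste0("# config_hash: ", config_hash(config)),
    paste0("# seed: ", config$seed)
  ), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

pipeline_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full design-screen-quantify-analyze pipeline
#'
#' Executes the stages in order on one configuration: candidate design and
#' scoring, off-target and seed-match screening, filtering and spaced
#' selection; optionally knockdown quantification from a Ct table; and,
#' when measured efficacies are available, the covariate linear-model
#' analysis. Each output TSV carries the tool version, configuration hash
#' and seed; re-running an identical configuration reproduces the bundle
#' byte for byte.
#'
#' @param config A [run_config()] object.
#' @return Invisibly, a named list of written file paths (or, for
#'   `dry_run`, the printed plan).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  plan <- c("design", "offtarget",
            if (!is.null(config$ct_tsv)) "quantify",
            if (!is.null(config$efficacy_tsv)) "analyze")
  if (isTRUE(config$dry_run)) {
    cat("plan:", paste(plan, collapse = " -> "), "\n")
    cat("config_hash:", config_hash(config), "\n")
    return(invisible(plan))
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  outputs <- list()

  transcripts <- pipeline_stage("design", {
    read_transcripts(config$fasta, config$annot)
  })
  candidates <- pipeline_stage("design", {
    cand <- do.call(rbind, lapply(transcripts, enumerate_candidates))
    rownames(cand) <- NULL
    if (!is.null(config$training_tsv)) {
      train <- utils::read.delim(config$training_tsv, comment.char = "#",
                                 stringsAsFactors = FALSE)
      model <- train_model(train$guide, train$efficacy)
      cand$base_score <- predict_efficacy(model, cand$guide)
    } else {
      message("design: no training set; candidates carry no predicted score")
      cand$base_score <- NA_real_
    }
    cand$corrected_score <- ifelse(
      is.na(cand$base_score), NA_real_,
      apply_positional_correction(cand$base_score, cand$location, cand$start))
    cand$sirna_id <- paste0(cand$target_id, ":", cand$start)
    cand
  })

  candidates <- pipeline_stage("offtarget", {
    databank <- if (is.null(config$databank_fasta)) transcripts else
      read_transcripts(config$databank_fasta, config$databank_annot)
    utr3 <- if (is.null(config$utr3_fasta)) databank else {
      s <- Biostrings::readBStringSet(config$utr3_fasta)
      stats::setNames(as.character(s), sub("\\s.*$", "", names(s)))
    }
    n_ot <- integer(nrow(candidates))
    seed_prof <- vector("list", nrow(candidates))
    for (i in seq_len(nrow(candidates))) {
      scan <- scan_offtargets(candidates[i, ], databank,
                              k = config$mismatches)
      n_ot[i] <- scan$n_offtarget_transcripts
      seed_prof[[i]] <- seed_match_profile(candidates$guide[i], utr3)
    }
    candidates$n_offtargets <- n_ot
    cbind(candidates, do.call(rbind, seed_prof))
  })

  rules <- list(cds_only = config$cds_only, no_polyn = config$no_polyn,
                max_offtargets = config$max_offtargets)
  if (!all(is.na(candidates$base_score))) rules$min_score <- config$min_score
  filtered <- filter_candidates(candidates, rules)
  selected <- select_spaced(filtered$retained, config$top_k, config$min_gap)

  report <- selected
  report$sense <- as_rna(report$sense)
  report$guide <- as_rna(report$guide)
  outputs$candidates <- write_report_tsv(
    report, file.path(config$out_dir, "selected_candidates.tsv"), config)
  rej <- filtered$rejected
  rej$sense <- as_rna(rej$sense)
  rej$guide <- as_rna(rej$guide)
  outputs$rejected <- write_report_tsv(
    rej, file.path(config$out_dir, "rejected_candidates.tsv"), config)

  if (!is.null(config$ct_tsv)) {
    outputs$extinction <- pipeline_stage("qpcr", {
      records <- read_ct_table(config$ct_tsv)
      if (!is.null(config$control_id)) {
        v <- validate_run(records, config$control_id,
                          config$control_threshold,
                          calibrator = config$calibrator)
        if (!v$pass) stop("run failed validation: ", v$reason)
      }
      target <- config$target_gene
      if (is.null(target)) {
        target <- unique(records$gene[records$role == "TARGET"])[1L]
      }
      ids <- setdiff(unique(records$sample),
                     c(config$calibrator, config$control_id))
      est <- do.call(rbind, lapply(ids, function(id) {
        estimate_extinction(records, id, target, config$normalizers,
                            config$calibrator)
      }))
      est$grade <- grade_efficacy(est$knockdown_pct)
      write_report_tsv(est, file.path(config$out_dir, "extinction.tsv"),
                       config)
    })
  }

  if (!is.null(config$efficacy_tsv)) {
    outputs$analysis <- pipeline_stage("analyze", {
      eff <- utils::read.delim(config$efficacy_tsv, comment.char = "#",
                               stringsAsFactors = FALSE)
      exon_ctx <- do.call(rbind, lapply(seq_len(nrow(candidates)), function(i) {
        tx <- transcripts[[candidates$target_id[i]]]
        ec <- suppressMessages(exon_context(tx, candidates$start[i], 21L))
        data.frame(sirna_id = candidates$sirna_id[i],
                   target_exon_length = ec$target_exon_length,
                   spans_junction = ec$spans_junction)
      }))
      tab <- build_covariate_table(
        candidates,
        candidates[, c("sirna_id", "n_offtargets")],
        candidates[, c("sirna_id", "n_seqs", "hit1", "hit2", "hit3plus")],
        exon_ctx, accessibility = NULL, efficacies = eff)
      red <- refit_reduced(tab)
      res <- data.frame(
        term = c(names(red$gene_offsets), names(red$location_offsets),
                 "slope_per_100bp"),
        estimate = c(red$gene_offsets, red$location_offsets,
                     red$slope_per_100bp))
      write_report_tsv(res, file.path(config$out_dir, "reduced_model.tsv"),
                       config)
    })
  }
  invisible(outputs)
}
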