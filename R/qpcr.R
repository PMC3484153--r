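#' Relative expression ratio from cycle thresholds
#'
#' Efficiency-corrected comparative threshold-cycle quantification: the
#' expression of the target in a treated sample relative to a calibrator
#' sample, normalized by a reference gene, is
#' `q = e_target^(Ct_target_calibrator - Ct_target_sample) /
#' e_ref^(Ct_ref_calibrator - Ct_ref_sample)`, where each `e` is the
#' per-cycle amplification rate of the assay (2 for perfect doubling).
#' With `e = 2` on both assays this reduces exactly to the familiar
#' `2^-ddCt` formula. Knockdown percent is `100 * (1 - q)`; `q = 1/4` with
#' perfect efficiency corresponds to 75% knockdown.
#'
#' @param ct_target_sample,ct_target_calibrator Target-gene Ct values in
#'   the treated and calibrator samples.
#' @param e_target,e_ref Amplification rates per cycle, in `(1, 2]`.
#' @param ct_ref_sample,ct_ref_calibrator Reference-gene Ct values.
#' @return The relative quantity `q` (positive). Vectorized.
#' @examples
#' relative_quantity(22, 20, 2, 18, 18, 2)  # 0.25 -> 75% knockdown
#' @export
relative_quantity <- function(ct_target_sample, ct_target_calibrator,
                              e_target, ct_ref_sample, ct_ref_calibrator,
                              e_ref) {
  if (any(e_target <= 1 | e_target > 2) || any(e_ref <= 1 | e_ref > 2)) {
    stop("relative_quantity: amplification rates must lie in (1, 2]")
  }
  e_target^(ct_target_calibrator - ct_target_sample) /
    e_ref^(ct_ref_calibrator - ct_ref_sample)
}

#' Read a cycle-threshold table
#'
#' @param path TSV with columns `run_id`, `sample`, `gene`, `role`
#'   (`TARGET`/`NORMALIZER`), `replicate`, `ct` and optionally `efficiency`
#'   (default 2.0 when absent).
#' @return A validated data.frame of Ct records.
#' @export
read_ct_table <- function(path) {
  if (!file.exists(path)) stop("Ct table not found: ", path)
  rec <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  validate_ct_records(rec)
}

validate_ct_records <- function(records) {
  required <- c("run_id", "sample", "gene", "role", "replicate", "ct")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols)) {
    stop("Ct records lack column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (is.null(records$efficiency)) records$efficiency <- 2.0
  if (any(records$ct <= 0)) stop("Ct records: ct must be positive")
  if (any(records$efficiency <= 1 | records$efficiency > 2)) {
    stop("Ct records: efficiency must lie in (1, 2]")
  }
  if (!all(records$role %in% c("TARGET", "NORMALIZER"))) {
    stop("Ct records: role must be TARGET or NORMALIZER")
  }
  records
}

#' Estimate knockdown (extinction) for one siRNA from Ct records
#'
#' For each reference gene, the relative quantity `q` is computed per
#' replicate (pairing sample and calibrator replicates by index within each
#' run) and averaged on the log2 scale; the combined estimate across
#' reference genes is their geometric mean. Replicate dispersion is the
#' standard deviation of the per-replicate log2 ratios.
#'
#' @param records Ct record data.frame (see [read_ct_table()]).
#' @param sirna_id Sample label of the siRNA treatment.
#' @param target_gene Target gene name.
#' @param normalizer_genes Character vector of reference genes (e.g.
#'   `c("36B4", "HPRT")`).
#' @param calibrator Sample label of the untreated calibrator
#'   (default `"mock"`).
#' @return A one-row data.frame: `sirna_id`, `q`, `knockdown_pct`
#'   (`= 100 * (1 - q)`), `log2_sd` (NA with a single replicate pair),
#'   `n_reps`, `normalizers` (comma-joined).
#' @export
estimate_extinction <- function(records, sirna_id, target_gene,
                                normalizer_genes, calibrator = "mock") {
  records <- validate_ct_records(records)
  if (!any(records$sample == calibrator)) {
    stop("estimate_extinction: no records for calibrator '", calibrator, "'")
  }
  if (!any(records$sample == sirna_id)) {
    stop("estimate_extinction: no records for sample '", sirna_id, "'")
  }
  per_norm_log2q <- numeric(0)
  all_rep_log2q <- numeric(0)
  for (norm_gene in normalizer_genes) {
    rep_log2q <- numeric(0)
    for (run in unique(records$run_id)) {
      r <- records[records$run_id == run, , drop = FALSE]
      ts <- r[r$sample == sirna_id & r$gene == target_gene, , drop = FALSE]
      tc <- r[r$sample == calibrator & r$gene == target_gene, , drop = FALSE]
      ns <- r[r$sample == sirna_id & r$gene == norm_gene, , drop = FALSE]
      nc <- r[r$sample == calibrator & r$gene == norm_gene, , drop = FALSE]
      if (!nrow(ts) || !nrow(tc) || !nrow(ns) || !nrow(nc)) next
      reps <- Reduce(intersect, list(ts$replicate, tc$replicate,
                                     ns$replicate, nc$replicate))
      for (rep_i in reps) {
        q <- relative_quantity(
          ts$ct[ts$replicate == rep_i][1L], tc$ct[tc$replicate == rep_i][1L],
          ts$efficiency[1L],
          ns$ct[ns$replicate == rep_i][1L], nc$ct[nc$replicate == rep_i][1L],
          ns$efficiency[1L])
        rep_log2q <- c(rep_log2q, log2(q))
      }
    }
    if (length(rep_log2q)) {
      per_norm_log2q <- c(per_norm_log2q, mean(rep_log2q))
      all_rep_log2q <- c(all_rep_log2q, rep_log2q)
    }
  }
  if (!length(per_norm_log2q)) {
    stop("estimate_extinction: no complete replicate sets for '",
         sirna_id, "' vs '", calibrator, "' on ", target_gene)
  }
  q <- 2^mean(per_norm_log2q)  # geometric mean across reference genes
  n_reps <- length(all_rep_log2q)
  log2_sd <- if (n_reps > 1L) stats::sd(all_rep_log2q) else NA_real_
  if (n_reps == 1L) {
    message("estimate_extinction: single replicate pair; dispersion undefined")
  }
  data.frame(sirna_id = sirna_id, q = q, knockdown_pct = 100 * (1 - q),
             log2_sd = log2_sd, n_reps = n_reps,
             normalizers = paste(normalizer_genes, collapse = ","),
             stringsAsFactors = FALSE)
}

#' Validate a qPCR run with a positive-control siRNA
#'
#' A run passes when the positive-control siRNA knocks down its own target
#' by at least `threshold_pct` percent. The control's target gene is taken
#' from its TARGET-role records unless given explicitly. Failing runs
#' should be excluded from downstream efficacy tables.
#'
#' @param records Ct record data.frame.
#' @param positive_control_id Sample label of the positive-control siRNA.
#' @param threshold_pct Minimum control knockdown in percent (default 80;
#'   some protocols use 70).
#' @param normalizer_genes Reference genes; default: all NORMALIZER-role
#'   genes present.
#' @param calibrator Calibrator sample label.
#' @return A list: `pass` (logical), `knockdown_pct` (NA when the control
#'   is absent), `reason`.
#' @export
validate_run <- function(records, positive_control_id, threshold_pct = 80,
                         normalizer_genes = NULL, calibrator = "mock") {
  records <- validate_ct_records(records)
  ctrl <- records[records$sample == positive_control_id &
                    records$role == "TARGET", , drop = FALSE]
  if (!nrow(ctrl)) {
    return(list(pass = FALSE, knockdown_pct = NA_real_,
                reason = paste0("positive control '", positive_control_id,
                                "' absent from records")))
  }
  if (is.null(normalizer_genes)) {
    normalizer_genes <- unique(records$gene[records$role == "NORMALIZER"])
  }
  est <- estimate_extinction(records, positive_control_id,
                             target_gene = unique(ctrl$gene)[1L],
                             normalizer_genes = normalizer_genes,
                             calibrator = calibrator)
  pass <- est$knockdown_pct >= threshold_pct
  list(pass = pass, knockdown_pct = est$knockdown_pct,
       reason = if (pass) "control knockdown meets threshold" else
         sprintf("control knockdown %.1f%% below threshold %.1f%%",
                 est$knockdown_pct, threshold_pct))
}
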