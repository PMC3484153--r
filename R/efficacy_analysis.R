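# Covariate inventory, in the documented model order. Covariates 8-10
# (3'UTR seed-match classes) are carried as four fields per the seed-match
# profile; accessibility is optional and never imputed.
covariate_order <- c("dsir_score", "gene", "position_bp", "location",
                     "n_offtargets", "polyn", "n_transcriptome_hits",
                     "seed_n_seqs", "seed_hit1", "seed_hit2", "seed_hit3plus",
                     "target_exon_length", "spans_junction", "accessibility")

# seed_n_seqs is the sum of the three hit-class counts, so it can never
# enter a model next to them; the hit classes carry the information.
model_covariates <- setdiff(covariate_order, "seed_n_seqs")

#' Assemble the per-siRNA covariate table
#'
#' Joins the candidate descriptions with off-target counts, seed-match
#' profiles, exon context, optional accessibility values and measured
#' efficacies into one analysis-ready record per siRNA. All inputs are
#' keyed by `sirna_id`.
#'
#' @param candidates Candidate data.frame with columns `sirna_id`, `gene`,
#'   `start`, `location`, `sense`, `guide` and (optionally) `base_score`.
#' @param offtarget_results data.frame `sirna_id`, `n_offtargets` and
#'   optionally `n_transcriptome_hits` (total hit positions).
#' @param seed_profiles data.frame `sirna_id`, `n_seqs`, `hit1`, `hit2`,
#'   `hit3plus`.
#' @param exon_contexts data.frame `sirna_id`, `target_exon_length`,
#'   `spans_junction`.
#' @param accessibility Optional data.frame `sirna_id`, `accessibility`
#'   (in `[0, 1]`); when `NULL` the covariate is absent (a note is logged).
#' @param efficacies data.frame `sirna_id`, `efficacy_pct`. Every id here
#'   must exist in `candidates`.
#' @return A data.frame with one row per entry of `efficacies`, columns in
#'   the documented covariate order plus `sirna_id` and `efficacy_pct`.
#' @export
build_covariate_table <- function(candidates, offtarget_results,
                                  seed_profiles, exon_contexts,
                                  accessibility = NULL, efficacies) {
  stopifnot("sirna_id" %in% names(candidates),
            "sirna_id" %in% names(efficacies),
            "efficacy_pct" %in% names(efficacies))
  unknown <- setdiff(efficacies$sirna_id, candidates$sirna_id)
  if (length(unknown)) {
    stop("build_covariate_table: efficacy id(s) absent from candidates: ",
         paste(unknown, collapse = ", "))
  }
  tab <- merge(efficacies, candidates, by = "sirna_id", sort = FALSE)
  tab$position_bp <- tab$start
  if (is.null(tab$base_score)) tab$dsir_score <- NA_real_ else
    tab$dsir_score <- tab$base_score
  tab$polyn <- as.integer(has_polyn_tract(tab$guide))
  names(offtarget_results)[names(offtarget_results) == "n_offtarget_transcripts"] <-
    "n_offtargets"
  tab <- merge(tab, offtarget_results, by = "sirna_id", all.x = TRUE, sort = FALSE)
  if (is.null(tab$n_transcriptome_hits)) tab$n_transcriptome_hits <- tab$n_offtargets
  sp <- seed_profiles
  names(sp)[match(c("n_seqs", "hit1", "hit2", "hit3plus"), names(sp))] <-
    c("seed_n_seqs", "seed_hit1", "seed_hit2", "seed_hit3plus")
  tab <- merge(tab, sp, by = "sirna_id", all.x = TRUE, sort = FALSE)
  tab <- merge(tab, exon_contexts, by = "sirna_id", all.x = TRUE, sort = FALSE)
  if (is.null(accessibility)) {
    message("build_covariate_table: no accessibility values; ",
            "covariate omitted from models")
  } else {
    tab <- merge(tab, accessibility, by = "sirna_id", all.x = TRUE, sort = FALSE)
  }
  keep <- c("sirna_id", intersect(covariate_order, names(tab)), "efficacy_pct")
  tab[, keep, drop = FALSE]
}

#' Fit the full covariate linear model with per-term ANOVA
#'
#' Least-squares fit of measured efficacy on every available covariate of
#' the documented inventory (gene and location enter as factors against a
#' reference level; `seed_n_seqs`, being the exact sum of the three seed
#' hit classes, is reported in tables but never fitted alongside them),
#' followed by per-term significance tests: sequential
#' (type-I) sums of squares in the documented covariate order by default,
#' or marginal (drop-one) F tests.
#'
#' @param table Covariate table from [build_covariate_table()] (>= 20 rows).
#' @param anova Either `"sequential"` (default) or `"marginal"`.
#' @return A list: `fit` (the `lm` object), `coefficients`, `anova`
#'   (data.frame `term`, `df`, `sum_sq`, `F`, `p` with a `Residuals` row),
#'   `terms_used`.
#' @export
fit_full_model <- function(table, anova = c("sequential", "marginal")) {
  anova <- match.arg(anova)
  stopifnot(nrow(table) >= 20L, "efficacy_pct" %in% names(table))
  terms_used <- intersect(model_covariates, names(table))
  terms_used <- terms_used[vapply(terms_used, function(v) {
    !all(is.na(table[[v]]))
  }, TRUE)]
  dropped <- setdiff(intersect(model_covariates, names(table)), terms_used)
  if (length(dropped)) {
    message("fit_full_model: dropping all-missing covariate(s): ",
            paste(dropped, collapse = ", "))
  }
  tab <- prepare_factors(table)
  fml <- stats::reformulate(terms_used, response = "efficacy_pct")
  fit <- stats::lm(fml, data = tab)
  if (anyNA(stats::coef(fit))) {
    aliased <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("fit_full_model: rank-deficient design; aliased term(s): ",
         paste(aliased, collapse = ", "))
  }
  at <- if (anova == "sequential") {
    a <- stats::anova(fit)
    data.frame(term = rownames(a), df = a$Df, sum_sq = a$`Sum Sq`,
               F = a$`F value`, p = a$`Pr(>F)`, stringsAsFactors = FALSE)
  } else {
    a <- stats::drop1(fit, test = "F")
    a <- a[-1L, , drop = FALSE]
    rbind(
      data.frame(term = rownames(a), df = a$Df, sum_sq = a$`Sum of Sq`,
                 F = a$`F value`, p = a$`Pr(>F)`, stringsAsFactors = FALSE),
      data.frame(term = "Residuals", df = fit$df.residual,
                 sum_sq = sum(stats::resid(fit)^2), F = NA, p = NA)
    )
  }
  list(fit = fit, coefficients = stats::coef(fit), anova = at,
       terms_used = terms_used)
}

prepare_factors <- function(table) {
  tab <- table
  if ("gene" %in% names(tab)) {
    levels <- unique(as.character(tab$gene))
    ref <- if ("BCL2L1" %in% levels) "BCL2L1" else levels[1L]
    tab$gene <- stats::relevel(factor(tab$gene), ref = ref)
  }
  if ("location" %in% names(tab)) {
    tab$location <- factor(tab$location,
                           levels = intersect(REGION_LEVELS,
                                              unique(tab$location)))
  }
  tab
}

#' Refit the reduced three-covariate efficacy model
#'
#' Fits measured efficacy on target gene, target-site location and
#' target-site position only — the covariates that carry the signal in
#' this kind of knockdown screen. The location factor uses the 5'UTR as
#' reference, so its coefficients are the CDS-vs-5'UTR and 3'UTR-vs-5'UTR
#' contrasts; the gene factor is coded against BCL2L1 when present. The
#' position slope is reported per 100 bp.
#'
#' @param table Covariate table with `gene`, `location`, `position_bp`,
#'   `efficacy_pct`.
#' @param position_col Position covariate column (default `"position_bp"`,
#'   distance from the transcript 5' end; supply a CDS-relative column to
#'   measure from the start codon instead).
#' @return A list of class `"reduced_efficacy_fit"`: `gene_offsets`,
#'   `location_offsets`, `slope_per_100bp`, `p_values` (sequential ANOVA
#'   p per term), `fitted_values` (data.frame `sirna_id`, `measured`,
#'   `fitted`), `fit`.
#' @export
refit_reduced <- function(table, position_col = "position_bp") {
  stopifnot(all(c("gene", "location", position_col, "efficacy_pct") %in%
                  names(table)))
  tab <- prepare_factors(table)
  tab$.position <- tab[[position_col]]
  small <- table(tab$gene)
  if (any(small < 2L)) {
    warning("refit_reduced: gene(s) with < 2 records retained: ",
            paste(names(small)[small < 2L], collapse = ", "))
  }
  fit <- stats::lm(efficacy_pct ~ gene + location + .position, data = tab)
  a <- stats::anova(fit)
  cf <- stats::coef(fit)
  gene_offsets <- cf[grep("^gene", names(cf))]
  names(gene_offsets) <- sub("^gene", "", names(gene_offsets))
  location_offsets <- cf[grep("^location", names(cf))]
  names(location_offsets) <- sub("^location", "", names(location_offsets))
  p <- a$`Pr(>F)`[seq_len(3L)]
  names(p) <- c("gene", "location", "position")
  structure(list(
    gene_offsets = gene_offsets,
    location_offsets = location_offsets,
    slope_per_100bp = unname(cf[".position"] * 100),
    p_values = p,
    fitted_values = data.frame(
      sirna_id = if (!is.null(tab$sirna_id)) tab$sirna_id else
        seq_len(nrow(tab)),
      measured = tab$efficacy_pct,
      fitted = stats::fitted(fit)),
    fit = fit
  ), class = "reduced_efficacy_fit")
}

#' @export
print.reduced_efficacy_fit <- function(x, ...) {
  cat("<reduced_efficacy_fit> efficacy ~ gene + location + position\n")
  cat("  slope per 100 bp:", format(x$slope_per_100bp, digits = 3), "\n")
  cat("  location offsets (vs 5'UTR):",
      paste(names(x$location_offsets),
            format(x$location_offsets, digits = 3), collapse = ", "), "\n")
  invisible(x)
}

#' Per-gene positional test
#'
#' Within one target gene (optionally restricted to CDS-targeting siRNA),
#' regresses measured efficacy on target-site position and reports the
#' two-sided p-value and slope (per 100 bp). At least 4 records are needed
#' for the test to be meaningful; with fewer, the result is declared
#' not testable rather than returning an uninformative p-value.
#'
#' @param table Covariate table.
#' @param gene Gene symbol to test.
#' @param cds_only Restrict to CDS-located records (default TRUE).
#' @param position_col As in [refit_reduced()].
#' @return A list: `gene`, `testable`, `n`, `slope_per_100bp`, `p`.
#' @export
per_gene_position_test <- function(table, gene, cds_only = TRUE,
                                   position_col = "position_bp") {
  rows <- table[table$gene == gene, , drop = FALSE]
  if (cds_only) rows <- rows[rows$location == "CDS", , drop = FALSE]
  if (nrow(rows) < 4L) {
    return(list(gene = gene, testable = FALSE, n = nrow(rows),
                slope_per_100bp = NA_real_, p = NA_real_))
  }
  fit <- stats::lm(rows$efficacy_pct ~ rows[[position_col]])
  sm <- summary(fit)$coefficients
  list(gene = gene, testable = TRUE, n = nrow(rows),
       slope_per_100bp = unname(sm[2L, 1L] * 100),
       p = unname(sm[2L, 4L]))
}
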