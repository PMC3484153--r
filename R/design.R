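#' Enumerate 21-nt siRNA candidates along a transcript
#'
#' One candidate is produced per possible 21-nt target window, in order of
#' start position. The sense strand equals the target window; the guide
#' (antisense) strand is its reverse complement, written 5' to 3'. Both are
#' kept in the DNA alphabet internally; use [as_rna()] when reporting.
#'
#' @param transcript A [transcript()] object of length >= 21.
#' @return A data.frame with columns `target_id`, `gene`, `start` (1-based
#'   first base of the window), `sense`, `guide`, `location`. Empty (with a
#'   message) when the transcript is shorter than 21 nt.
#' @export
enumerate_candidates <- function(transcript) {
  stopifnot(inherits(transcript, "transcript"))
  n <- nchar(transcript$sequence)
  if (n < 21L) {
    message("transcript '", transcript$id,
            "' is shorter than 21 nt; no candidates")
    return(empty_candidates())
  }
  starts <- seq_len(n - 20L)
  sense <- substring(transcript$sequence, starts, starts + 20L)
  # guide windows read off the reverse complement of the whole sequence:
  # window [s, s+20] maps to [n-s-19, n-s+1] on the rc strand
  rc <- reverse_complement(transcript$sequence)
  guide <- substring(rc, n - starts - 19L, n - starts + 1L)
  location <- vapply(starts, function(s) region_of(transcript, s, 21L), "")
  data.frame(
    target_id = transcript$id,
    gene = transcript$symbol,
    start = starts,
    sense = sense,
    guide = guide,
    location = location,
    stringsAsFactors = FALSE
  )
}

empty_candidates <- function() {
  data.frame(target_id = character(), gene = character(), start = integer(),
             sense = character(), guide = character(), location = character(),
             stringsAsFactors = FALSE)
}

# Fixed feature inventory: 21 x 4 positional indicators, then 1/2/3-mer
# counts, each block in lexicographic k-mer order.
feature_names <- function() {
  bases <- c("A", "C", "G", "T")
  pos <- as.vector(t(outer(seq_len(21L), bases,
                           function(p, b) paste0("pos", p, "_", b))))
  kmers <- unlist(lapply(1:3, function(k) {
    apply(expand.grid(rep(list(bases), k))[, k:1, drop = FALSE], 1L,
          paste0, collapse = "")
  }))
  c(pos, paste0("kmer_", kmers))
}

#' Encode a guide strand as a numeric feature vector
#'
#' The DSIR-style efficacy model is linear in a fixed encoding of the 21-nt
#' guide strand (including the 2-nt 3' overhang positions): 84 binary
#' indicators for "nucleotide b at guide position p" (positions numbered
#' 5' to 3') followed by 84 counts of all 1-, 2- and 3-mers over the guide.
#' Feature order is fixed and exposed through the column names.
#'
#' @param guide Character vector of 21-mers over `{A,C,G,T,U}`.
#' @return A numeric matrix with one row per guide and 168 named columns.
#' @export
encode_features <- function(guide) {
  guide <- normalize_sequence(guide)
  if (any(nchar(guide) != 21L) || any(grepl("[^ACGT]", guide))) {
    stop("encode_features: every guide must be a 21-mer over {A,C,G,T,U}")
  }
  bases <- c("A", "C", "G", "T")
  nm <- feature_names()
  X <- matrix(0, nrow = length(guide), ncol = length(nm),
              dimnames = list(guide, nm))
  chars <- strsplit(guide, "", fixed = TRUE)
  for (i in seq_along(guide)) {
    cc <- chars[[i]]
    X[i, (seq_len(21L) - 1L) * 4L + match(cc, bases)] <- 1
    for (k in 1:3) {
      words <- substring(guide[i], seq_len(22L - k), seq_len(22L - k) + k - 1L)
      tab <- table(words)
      X[i, paste0("kmer_", names(tab))] <- as.numeric(tab)
    }
  }
  X
}

#' Train the linear efficacy-scoring model
#'
#' Fits predicted extinction activity (percent) on the [encode_features()]
#' encoding of the guide strand by ridge-regularized least squares with an
#' unpenalized intercept. When `regularization` is `NULL` the penalty is
#' chosen by generalized cross-validation (GCV) over a log-spaced grid. The
#' fit is closed-form (SVD) and fully deterministic.
#'
#' @param guides Character vector of 21-mer guide strands (>= 2 distinct).
#' @param efficacy Numeric vector of measured/assigned efficacies in
#'   `[0, 100]`, same length as `guides`.
#' @param regularization Non-negative ridge penalty, or `NULL` for GCV.
#' @param seed Stored for provenance; the fit itself is deterministic.
#' @return An object of class `"sirna_scoring_model"` with elements
#'   `intercept`, `weights` (named length-168 vector), `regularization`,
#'   `gcv` (grid, when used) and `trained = TRUE`.
#' @export
train_model <- function(guides, efficacy, regularization = NULL, seed = NULL) {
  stopifnot(length(guides) == length(efficacy), length(guides) >= 2L)
  if (length(unique(guides)) < 2L) {
    stop("train_model: degenerate design, all guides identical")
  }
  efficacy <- as.numeric(efficacy)
  if (anyNA(efficacy) || any(efficacy < 0 | efficacy > 100)) {
    stop("train_model: efficacies must lie in [0, 100]")
  }
  X <- encode_features(guides)
  xbar <- colMeans(X)
  ybar <- mean(efficacy)
  Xc <- sweep(X, 2L, xbar)
  yc <- efficacy - ybar
  sv <- svd(Xc)
  pos <- sv$d > max(sv$d) * 1e-12
  d <- sv$d[pos]
  U <- sv$u[, pos, drop = FALSE]
  V <- sv$v[, pos, drop = FALSE]
  uty <- crossprod(U, yc)

  coef_for <- function(lambda) {
    drop(V %*% (d / (d^2 + lambda) * uty))
  }
  gcv_tab <- NULL
  if (is.null(regularization)) {
    grid <- 10^seq(-8, 4, length.out = 61)
    n <- length(yc)
    gcv <- vapply(grid, function(lambda) {
      f <- d^2 / (d^2 + lambda)
      fit <- drop(U %*% (f * uty))
      df <- sum(f) + 1  # + intercept
      n * sum((yc - fit)^2) / (n - df)^2
    }, 0)
    regularization <- grid[which.min(gcv)]
    gcv_tab <- data.frame(lambda = grid, gcv = gcv)
  }
  if (regularization < 0) stop("train_model: regularization must be >= 0")
  beta <- coef_for(regularization)
  names(beta) <- colnames(X)
  structure(
    list(intercept = ybar - sum(beta * xbar),
         weights = beta,
         regularization = regularization,
         gcv = gcv_tab,
         seed = seed,
         trained = TRUE),
    class = "sirna_scoring_model"
  )
}

#' @export
print.sirna_scoring_model <- function(x, ...) {
  cat("<sirna_scoring_model> 168-feature ridge fit\n")
  cat("  intercept:", format(x$intercept, digits = 4),
      " lambda:", format(x$regularization, digits = 4), "\n")
  invisible(x)
}

#' Predict extinction activity for guide strands
#'
#' Affine prediction from a trained [train_model()] fit, clipped to
#' `[0, 100]` percent.
#'
#' @param model A trained `"sirna_scoring_model"`.
#' @param guide Character vector of 21-mer guide strands.
#' @return Numeric vector of predicted extinction percentages.
#' @export
predict_efficacy <- function(model, guide) {
  if (!inherits(model, "sirna_scoring_model") || !isTRUE(model$trained)) {
    stop("predict_efficacy: model is not a trained scoring model")
  }
  X <- encode_features(guide)
  unname(pmin(100, pmax(0, drop(X %*% model$weights) + model$intercept)))
}

#' Positional/location correction parameters
#'
#' Measured knockdown declines with the distance of the target site from
#' the transcript 5' end (about 1 percentage point per 100 bp) and differs
#' by region: relative to the CDS reference, 5'UTR sites are about 39 points
#' weaker and 3'UTR sites about 26 points weaker (equivalently, CDS and
#' 3'UTR sites are about 39 and 13 points stronger than 5'UTR sites).
#'
#' @param slope_per_100bp Efficacy change per 100 bp of distance from the
#'   reference position (default -1.0).
#' @param location_offset Named numeric offsets per region with `CDS = 0`
#'   as the reference level.
#' @return A list of class `"correction_params"`.
#' @export
correction_params <- function(slope_per_100bp = -1.0,
                              location_offset = c(FIVE_UTR = -39, CDS = 0,
                                                  THREE_UTR = -26)) {
  stopifnot(setequal(names(location_offset), REGION_LEVELS))
  if (location_offset[["CDS"]] != 0) {
    stop("correction_params: CDS is the reference level; its offset must be 0")
  }
  structure(list(slope_per_100bp = slope_per_100bp,
                 location_offset = location_offset),
            class = "correction_params")
}

#' Apply the positional/location correction to a predicted score
#'
#' `corrected = clip(base_score + location_offset[location] +
#' slope_per_100bp * (start - 1) / 100, 0, 100)`. With the defaults, a CDS
#' site at `start = 1` is the reference point (no change).
#'
#' @param base_score Numeric predicted extinction percent.
#' @param location Region label(s), one of `FIVE_UTR`, `CDS`, `THREE_UTR`.
#' @param start 1-based target-site start position(s).
#' @param params A [correction_params()] object.
#' @return Corrected scores, clipped to `[0, 100]`. Vectorized.
#' @export
apply_positional_correction <- function(base_score, location, start,
                                        params = correction_params()) {
  stopifnot(inherits(params, "correction_params"))
  if (any(!location %in% REGION_LEVELS)) {
    stop("apply_positional_correction: unknown location label(s): ",
         paste(setdiff(unique(location), REGION_LEVELS), collapse = ", "))
  }
  if (any(start < 1L)) stop("apply_positional_correction: start must be >= 1")
  corrected <- base_score + params$location_offset[location] +
    params$slope_per_100bp * (start - 1) / 100
  unname(pmin(100, pmax(0, corrected)))
}

#' Detect a polynucleotide tract
#'
#' True when some nucleotide occurs at least `min_run` times consecutively,
#' a known negative design feature for siRNA.
#'
#' @param seq Character vector of sequences (RNA `U` normalized to `T`).
#' @param min_run Minimum run length (default 4).
#' @return Logical vector.
#' @examples
#' has_polyn_tract(c("GAAAAC", "AGAGAGAG"))  # TRUE FALSE
#' @export
has_polyn_tract <- function(seq, min_run = 4L) {
  seq <- normalize_sequence(seq)
  stopifnot(all(nzchar(seq)), min_run >= 2L)
  grepl(sprintf("([ACGT])\\1{%d,}", min_run - 1L), seq)
}

#' Filter scored candidates by design rules
#'
#' Applies any subset of the selection rules: `min_score` (strict `>` on the
#' predicted score, default threshold 80), `cds_only` (target site in the
#' CDS), `no_polyn` (no polynucleotide tract in the sense window) and
#' `max_offtargets` (at most this many off-target transcripts, default 0).
#' Every rejected candidate carries the complete set of failed-rule flags.
#'
#' @param candidates Candidate data.frame (from [enumerate_candidates()]),
#'   with a `base_score` column when `min_score` is active and an
#'   `n_offtargets` column when `max_offtargets` is active.
#' @param rules Named list; recognized entries `min_score`, `cds_only`
#'   (logical), `no_polyn` (logical), `max_offtargets`. An empty list
#'   retains everything.
#' @return A list with data.frames `retained` and `rejected`; `rejected`
#'   gains a `flags` column (comma-joined tags from `LOW_SCORE`, `NOT_CDS`,
#'   `POLYN_TRACT`, `OFFTARGETS`).
#' @export
filter_candidates <- function(candidates, rules = list()) {
  known <- c("min_score", "cds_only", "no_polyn", "max_offtargets")
  if (length(setdiff(names(rules), known))) {
    stop("filter_candidates: unknown rule(s): ",
         paste(setdiff(names(rules), known), collapse = ", "))
  }
  n <- nrow(candidates)
  fail <- matrix(FALSE, nrow = n, ncol = 4L,
                 dimnames = list(NULL, c("LOW_SCORE", "NOT_CDS",
                                         "POLYN_TRACT", "OFFTARGETS")))
  if (!is.null(rules$min_score)) {
    if (is.null(candidates$base_score)) {
      stop("filter_candidates: min_score rule needs a base_score column")
    }
    fail[, "LOW_SCORE"] <- !(candidates$base_score > rules$min_score)
  }
  if (isTRUE(rules$cds_only)) {
    fail[, "NOT_CDS"] <- candidates$location != "CDS"
  }
  if (isTRUE(rules$no_polyn)) {
    fail[, "POLYN_TRACT"] <- has_polyn_tract(candidates$sense)
  }
  if (!is.null(rules$max_offtargets)) {
    if (is.null(candidates$n_offtargets)) {
      stop("filter_candidates: max_offtargets rule needs an n_offtargets ",
           "column; run the off-target scan first")
    }
    fail[, "OFFTARGETS"] <- candidates$n_offtargets > rules$max_offtargets
  }
  bad <- rowSums(fail) > 0
  rejected <- candidates[bad, , drop = FALSE]
  rejected$flags <- apply(fail[bad, , drop = FALSE], 1L, function(f) {
    paste(colnames(fail)[f], collapse = ",")
  })
  list(retained = candidates[!bad, , drop = FALSE], rejected = rejected)
}

#' Select top candidates with spacing along the target
#'
#' Greedy selection by descending `corrected_score` (falling back to
#' `base_score` if no corrected score is present), skipping any candidate
#' whose start lies within `min_gap` of an already selected candidate on the
#' same transcript. Score ties are broken toward the smaller start.
#'
#' @param candidates Scored candidate data.frame.
#' @param k Maximum number of candidates to return.
#' @param min_gap Minimum start-to-start distance (default 21, i.e.
#'   non-overlapping windows).
#' @return At most `k` rows of `candidates`, in selection order.
#' @export
select_spaced <- function(candidates, k, min_gap = 21L) {
  stopifnot(k >= 0L, min_gap >= 0L)
  score <- candidates$corrected_score
  if (is.null(score)) score <- candidates$base_score
  if (is.null(score)) stop("select_spaced: candidates carry no score")
  ord <- order(-score, candidates$start)
  chosen <- integer(0)
  for (i in ord) {
    if (length(chosen) >= k) break
    same <- chosen[candidates$target_id[chosen] == candidates$target_id[i]]
    if (!length(same) ||
        all(abs(candidates$start[same] - candidates$start[i]) >= min_gap)) {
      chosen <- c(chosen, i)
    }
  }
  candidates[chosen, , drop = FALSE]
}

#' Grade a measured knockdown percentage
#'
#' Knockdown of at least 70% is graded `HIGH`, 50% up to (but excluding)
#' 70% is `MODERATE`, and anything below 50% — including apparent
#' up-regulation (negative knockdown) — is `INEFFICIENT`.
#'
#' @param knockdown_pct Numeric vector of knockdown percentages (<= 100).
#' @return Character vector over `{HIGH, MODERATE, INEFFICIENT}`.
#' @examples
#' grade_efficacy(c(70, 55, 49.9))  # "HIGH" "MODERATE" "INEFFICIENT"
#' @export
grade_efficacy <- function(knockdown_pct) {
  stopifnot(all(knockdown_pct <= 100))
  ifelse(knockdown_pct >= 70, "HIGH",
         ifelse(knockdown_pct >= 50, "MODERATE", "INEFFICIENT"))
}
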