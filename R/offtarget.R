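#' Approximate pattern search with a bit-parallel shift-add matcher
#'
#' Finds every alignment of `pattern` against `text` with Hamming distance
#' at most `k`, using per-position saturating counters packed in a 64-bit
#' machine word (the shift-add counting method, as in Wu-Manber style
#' approximate matching). The required state is `length(pattern)` counters
#' of `ceiling(log2(k+1)) + 1` bits; patterns needing more than 64 state
#' bits raise an error suggesting chunking. A 21-nt siRNA at the default
#' `k = 3` fits comfortably.
#'
#' @param pattern DNA pattern, length 1..32, over `{A,C,G,T,U}`.
#' @param text Subject sequence; characters outside `{A,C,G,T}` never match.
#' @param k Maximum number of mismatches (>= 0).
#' @return A data.frame sorted by `subject_start` (1-based) with columns
#'   `subject_start`, `mismatch_count` and the list-column
#'   `mismatch_positions` (sorted 1-based positions on the pattern).
#' @examples
#' shift_add_search("ACGT", "ACGAACGT", k = 1)
#' @export
shift_add_search <- function(pattern, text, k) {
  pattern <- normalize_sequence(pattern)
  text <- normalize_sequence(text)
  if (nchar(pattern) < 1L || nchar(pattern) > 32L) {
    stop("shift_add_search: pattern length must be in [1, 32]")
  }
  res <- .shift_add_core(pattern, text, as.integer(k))
  out <- data.frame(subject_start = res$subject_start,
                    mismatch_count = res$mismatch_count)
  out$mismatch_positions <- res$mismatch_positions
  out
}

#' Scan a candidate against a transcript databank for off-targets
#'
#' The candidate's 21-nt sense sequence (or its 19-nt core, positions
#' 1-19) is searched against every transcript in the databank except the
#' intended target(s), allowing up to `k` mismatches. A transcript that
#' nearly matches the sense sequence is a potential cleavage target of the
#' guide strand. The headline count is the number of distinct off-target
#' transcripts, not the number of hit positions.
#'
#' @param candidate A single-row candidate data.frame (needs `sense` and
#'   `target_id`), or a plain sense sequence string.
#' @param databank List of [transcript()] objects.
#' @param k Maximum mismatches (default 3, the recommended tolerance).
#' @param exclude_ids Transcript ids to skip (defaults to the candidate's
#'   own `target_id`).
#' @param core Either `"21nt"` (default, the full sense window) or `"19nt"`
#'   (drop the 2-nt 3' overhang positions of the window).
#' @return A list with `n_offtarget_transcripts` and a `hits` data.frame
#'   (`pattern_id`, `subject_id`, `subject_start`, `mismatch_count`,
#'   `mismatch_positions`).
#' @export
scan_offtargets <- function(candidate, databank, k = 3L, exclude_ids = NULL,
                            core = c("21nt", "19nt")) {
  core <- match.arg(core)
  if (is.data.frame(candidate)) {
    stopifnot(nrow(candidate) == 1L)
    sense <- candidate$sense
    pattern_id <- if (!is.null(candidate$sirna_id)) candidate$sirna_id else
      paste0(candidate$target_id, ":", candidate$start)
    if (is.null(exclude_ids)) exclude_ids <- candidate$target_id
  } else {
    sense <- candidate
    pattern_id <- "query"
    if (is.null(exclude_ids)) exclude_ids <- character()
  }
  if (core == "19nt") sense <- substr(sense, 1L, 19L)
  hits <- list()
  for (tx in databank) {
    if (tx$id %in% exclude_ids) next
    h <- shift_add_search(sense, tx$sequence, k)
    if (nrow(h)) {
      h <- cbind(pattern_id = pattern_id, subject_id = tx$id, h,
                 stringsAsFactors = FALSE)
      hits[[length(hits) + 1L]] <- h
    }
  }
  hits <- if (length(hits)) do.call(rbind, hits) else
    data.frame(pattern_id = character(), subject_id = character(),
               subject_start = integer(), mismatch_count = integer(),
               mismatch_positions = I(list()), stringsAsFactors = FALSE)
  list(n_offtarget_transcripts = length(unique(hits$subject_id)), hits = hits)
}

#' Seed-match site of a guide strand
#'
#' The seed region of the guide (antisense) strand is positions 2-8,
#' numbered 5' to 3'. Its miRNA-style match site on an mRNA is the reverse
#' complement of that heptamer; 3'UTRs containing this site are candidate
#' seed-mediated off-targets.
#'
#' @param guide A 21-mer guide strand (DNA or RNA alphabet).
#' @param mode `"complement"` (default; reverse complement of guide 2-8,
#'   the mRNA-side site) or `"identity"` (the guide heptamer itself).
#' @return A 7-mer DNA string.
#' @export
seed_site <- function(guide, mode = c("complement", "identity")) {
  mode <- match.arg(mode)
  guide <- normalize_sequence(guide)
  if (nchar(guide) != 21L) stop("seed_site: guide must be a 21-mer")
  heptamer <- substr(guide, 2L, 8L)
  if (mode == "identity") heptamer else reverse_complement(heptamer)
}

#' Profile seed matches of a guide against a 3'UTR databank
#'
#' Counts exact (k = 0) occurrences of the guide's [seed_site()] in every
#' 3'UTR, overlapping occurrences included, and bins the matched UTRs by
#' occurrence count: exactly once (`hit1`), exactly twice (`hit2`), three
#' or more times (`hit3plus`). `n_seqs` is the total number of matched
#' UTRs, so `n_seqs == hit1 + hit2 + hit3plus`.
#'
#' @param guide A 21-mer guide strand.
#' @param utr3_databank Named character vector (or list) of 3'UTR
#'   sequences, or a list of [transcript()] objects (their annotated 3'UTR
#'   regions are extracted).
#' @param mode Passed to [seed_site()].
#' @return A one-row data.frame: `n_seqs`, `hit1`, `hit2`, `hit3plus`.
#' @export
seed_match_profile <- function(guide, utr3_databank,
                               mode = c("complement", "identity")) {
  site <- seed_site(guide, match.arg(mode))
  seqs <- utr3_sequences(utr3_databank)
  counts <- vapply(seqs, function(s) {
    if (nchar(s) < 7L) return(0L)
    nrow(shift_add_search(site, s, k = 0L))
  }, 0L)
  data.frame(n_seqs = sum(counts >= 1L),
             hit1 = sum(counts == 1L),
             hit2 = sum(counts == 2L),
             hit3plus = sum(counts >= 3L))
}

utr3_sequences <- function(databank) {
  if (is.character(databank)) return(databank)
  vapply(databank, function(x) {
    if (inherits(x, "transcript")) {
      n <- nchar(x$sequence)
      if (x$cds_end >= n) "" else substr(x$sequence, x$cds_end + 1L, n)
    } else {
      as.character(x)
    }
  }, "")
}

#' Mismatch positions of a guide against an mRNA window
#'
#' Positions are numbered on the guide, 5' to 3'. Guide position `p` pairs
#' with window position `22 - p` (the guide is antiparallel to the mRNA);
#' position `p` is a mismatch when `guide[p]` is not the Watson-Crick
#' complement of the base it pairs with — equivalently, when the guide
#' differs from the reverse complement of the window at `p`.
#'
#' @param guide,mrna_window 21-mers.
#' @return Sorted integer vector of mismatching guide positions (1-based).
#' @export
mismatch_positions <- function(guide, mrna_window) {
  guide <- normalize_sequence(guide)
  mrna_window <- normalize_sequence(mrna_window)
  if (nchar(guide) != 21L || nchar(mrna_window) != 21L) {
    stop("mismatch_positions: guide and window must both be 21-mers")
  }
  g <- strsplit(guide, "")[[1]]
  w <- strsplit(reverse_complement(mrna_window), "")[[1]]
  which(g != w)
}
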