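#' Construct an annotated transcript
#'
#' A transcript couples an mRNA sequence with the coordinates of its coding
#' sequence (CDS) and, optionally, its exon structure in transcript
#' coordinates. All coordinates are 1-based and inclusive: `cds_start` is the
#' first base of the start codon and `cds_end` the last base of the stop
#' codon. RNA input (`U`) is normalized to DNA (`T`) and case-folded to
#' uppercase on construction.
#'
#' @param id Transcript identifier (e.g. a RefSeq accession).
#' @param symbol Gene symbol.
#' @param sequence Nucleotide sequence over `{A,C,G,T,U}` (any case).
#' @param cds_start,cds_end 1-based inclusive CDS boundaries with
#'   `1 <= cds_start < cds_end <= nchar(sequence)`.
#' @param exon_lengths Optional integer vector of exon lengths in transcript
#'   order; must sum to the sequence length when given.
#' @return An object of class `"transcript"`: a list with fields `id`,
#'   `symbol`, `sequence`, `cds_start`, `cds_end`, `exon_lengths`.
#' @examples
#' tx <- transcript("tx1", "GENE1", paste(rep("ACGT", 30), collapse = ""),
#'                  cds_start = 13, cds_end = 96)
#' transcript_length(tx)
#' @export
transcript <- function(id, symbol, sequence, cds_start, cds_end,
                       exon_lengths = NULL) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id),
            is.character(symbol), length(symbol) == 1L,
            is.character(sequence), length(sequence) == 1L)
  sequence <- normalize_sequence(sequence)
  n <- nchar(sequence)
  if (grepl("[^ACGT]", sequence)) {
    stop("transcript '", id, "': sequence contains characters outside {A,C,G,T,U}")
  }
  cds_start <- as.integer(cds_start)
  cds_end <- as.integer(cds_end)
  if (is.na(cds_start) || is.na(cds_end) ||
      cds_start < 1L || cds_start >= cds_end || cds_end > n) {
    stop("transcript '", id, "': invalid CDS coordinates [", cds_start, ", ",
         cds_end, "] for sequence of length ", n)
  }
  if (!is.null(exon_lengths)) {
    exon_lengths <- as.integer(exon_lengths)
    if (anyNA(exon_lengths) || any(exon_lengths <= 0L)) {
      stop("transcript '", id, "': exon lengths must be positive integers")
    }
    if (sum(exon_lengths) != n) {
      stop("transcript '", id, "': exon lengths sum to ", sum(exon_lengths),
           " but sequence length is ", n)
    }
  }
  structure(
    list(id = id, symbol = symbol, sequence = sequence,
         cds_start = cds_start, cds_end = cds_end,
         exon_lengths = exon_lengths),
    class = "transcript"
  )
}

#' @export
print.transcript <- function(x, ...) {
  cat("<transcript>", x$id, " (", x$symbol, ")\n", sep = "")
  cat("  length: ", nchar(x$sequence),
      " nt; CDS: [", x$cds_start, ", ", x$cds_end, "]",
      if (!is.null(x$exon_lengths))
        paste0("; exons: ", length(x$exon_lengths)),
      "\n", sep = "")
  invisible(x)
}

#' Transcript length in nucleotides
#' @param transcript A [transcript()] object.
#' @return Integer length.
#' @export
transcript_length <- function(transcript) {
  stopifnot(inherits(transcript, "transcript"))
  nchar(transcript$sequence)
}

normalize_sequence <- function(seq) {
  chartr("U", "T", toupper(seq))
}

#' Read transcripts from FASTA plus an annotation table
#'
#' The FASTA file holds the mRNA sequences; the tab-separated annotation
#' table supplies the CDS coordinates and (optionally) exon lengths. FASTA
#' record ids (the first whitespace-delimited token of each header) must each
#' have a matching `id` row in the annotation table.
#'
#' @param fasta_path Path to a (multi-record) FASTA file.
#' @param annotation_path Path to a TSV with columns `id`, `symbol`,
#'   `cds_start`, `cds_end` and optionally `exon_lengths` (comma-separated).
#' @return A named list of [transcript()] objects, in FASTA order.
#' @export
read_transcripts <- function(fasta_path, annotation_path) {
  seqs <- Biostrings::readBStringSet(fasta_path)
  ids <- sub("\\s.*$", "", names(seqs))
  annot <- utils::read.delim(annotation_path, stringsAsFactors = FALSE,
                             comment.char = "#")
  required <- c("id", "symbol", "cds_start", "cds_end")
  missing_cols <- setdiff(required, names(annot))
  if (length(missing_cols)) {
    stop("annotation table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  out <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    row <- annot[annot$id == ids[i], , drop = FALSE]
    if (nrow(row) == 0L) {
      stop("no annotation row for FASTA record '", ids[i], "'")
    }
    if (nrow(row) > 1L) {
      stop("duplicated annotation rows for id '", ids[i], "'")
    }
    exons <- NULL
    if ("exon_lengths" %in% names(row) && !is.na(row$exon_lengths) &&
        nzchar(row$exon_lengths)) {
      exons <- as.integer(strsplit(as.character(row$exon_lengths), ",")[[1]])
    }
    out[[i]] <- transcript(ids[i], row$symbol, as.character(seqs[[i]]),
                           row$cds_start, row$cds_end, exons)
  }
  names(out) <- ids
  out
}

#' Write transcripts to FASTA and annotation TSV
#'
#' Inverse of [read_transcripts()]; used mainly by the synthetic-data module.
#'
#' @param transcripts Named list of [transcript()] objects.
#' @param fasta_path,annotation_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_transcripts <- function(transcripts, fasta_path, annotation_path) {
  seqs <- Biostrings::DNAStringSet(vapply(transcripts, `[[`, "", "sequence"))
  names(seqs) <- vapply(transcripts, `[[`, "", "id")
  Biostrings::writeXStringSet(seqs, fasta_path, width = 70L)
  annot <- data.frame(
    id = vapply(transcripts, `[[`, "", "id"),
    symbol = vapply(transcripts, `[[`, "", "symbol"),
    cds_start = vapply(transcripts, `[[`, 0L, "cds_start"),
    cds_end = vapply(transcripts, `[[`, 0L, "cds_end"),
    exon_lengths = vapply(transcripts, function(tx) {
      if (is.null(tx$exon_lengths)) "" else paste(tx$exon_lengths, collapse = ",")
    }, ""),
    stringsAsFactors = FALSE
  )
  utils::write.table(annot, annotation_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(fasta_path, annotation_path))
}

#' Region labels
#'
#' The three transcript regions, ordered 5' to 3'. Used as factor levels
#' throughout the package.
#' @export
REGION_LEVELS <- c("FIVE_UTR", "CDS", "THREE_UTR")

#' Region of a target site
#'
#' Assigns a single region label (`FIVE_UTR`, `CDS` or `THREE_UTR`) to a
#' site of `site_len` bases starting at `start`. The site gets the region
#' containing the majority of its bases; an exact tie goes to the more 3'
#' region. Region boundaries: 5'UTR is `[1, cds_start-1]`, CDS is
#' `[cds_start, cds_end]`, 3'UTR is `[cds_end+1, length]`.
#'
#' @param transcript A [transcript()] object.
#' @param start 1-based start of the site.
#' @param site_len Site length in bases (default 21, one siRNA target window).
#' @return One of `"FIVE_UTR"`, `"CDS"`, `"THREE_UTR"`.
#' @export
region_of <- function(transcript, start, site_len = 21L) {
  stopifnot(inherits(transcript, "transcript"))
  n <- nchar(transcript$sequence)
  start <- as.integer(start)
  site_len <- as.integer(site_len)
  if (start < 1L || site_len < 1L || start + site_len - 1L > n) {
    stop("site [", start, ", ", start + site_len - 1L,
         "] out of bounds for transcript '", transcript$id,
         "' of length ", n)
  }
  end <- start + site_len - 1L
  bounds <- rbind(
    FIVE_UTR  = c(1L, transcript$cds_start - 1L),
    CDS       = c(transcript$cds_start, transcript$cds_end),
    THREE_UTR = c(transcript$cds_end + 1L, n)
  )
  overlap <- pmax(0L, pmin(end, bounds[, 2L]) - pmax(start, bounds[, 1L]) + 1L)
  # which.max on the reversed vector implements the 3' tie-break
  REGION_LEVELS[4L - which.max(rev(overlap))]
}

#' Exon context of a target site
#'
#' Reports the length of the exon containing the site's first base, and
#' whether the site crosses any exon-exon junction.
#'
#' @inheritParams region_of
#' @return A list with `target_exon_length` and `spans_junction` (0/1).
#'   When the transcript has no exon annotation both are `NA` and a message
#'   is emitted.
#' @export
exon_context <- function(transcript, start, site_len = 21L) {
  stopifnot(inherits(transcript, "transcript"))
  if (is.null(transcript$exon_lengths)) {
    message("transcript '", transcript$id,
            "': no exon annotation; exon context is NA")
    return(list(target_exon_length = NA_integer_, spans_junction = NA_integer_))
  }
  n <- nchar(transcript$sequence)
  start <- as.integer(start)
  site_len <- as.integer(site_len)
  if (start < 1L || start + site_len - 1L > n) {
    stop("site out of bounds for transcript '", transcript$id, "'")
  }
  ends <- cumsum(transcript$exon_lengths)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  exon_idx <- findInterval(start, starts)
  site_end <- start + site_len - 1L
  list(
    target_exon_length = transcript$exon_lengths[exon_idx],
    spans_junction = as.integer(site_end > ends[exon_idx])
  )
}

#' Watson-Crick reverse complement
#'
#' @param seq Character vector of DNA sequences over `{A,C,G,T}` (RNA `U` is
#'   normalized to `T` first).
#' @return Character vector of reverse complements (DNA alphabet).
#' @examples
#' reverse_complement("AAAC")  # "GTTT"
#' @export
reverse_complement <- function(seq) {
  seq <- normalize_sequence(seq)
  if (any(grepl("[^ACGT]", seq))) {
    stop("reverse_complement: sequence contains characters outside {A,C,G,T,U}")
  }
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq)))
}

#' Render a DNA-alphabet sequence as RNA
#'
#' Used at the report layer: internal sequences are DNA (`T`), while guide
#' and sense strands are conventionally written as RNA (`U`).
#' @param seq Character vector over `{A,C,G,T}`.
#' @return The same sequences with `T` replaced by `U`.
#' @export
as_rna <- function(seq) {
  chartr("T", "U", toupper(seq))
}
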