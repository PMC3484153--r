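# Independent oracles and fixture builders shared across tests.

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# naive sliding-window Hamming scanner, the reference for shift_add_search
naive_hamming_search <- function(pattern, text, k) {
  pc <- strsplit(pattern, "")[[1]]
  tc <- strsplit(text, "")[[1]]
  m <- length(pc)
  starts <- integer(0); counts <- integer(0); positions <- list()
  if (length(tc) >= m) {
    for (s in seq_len(length(tc) - m + 1L)) {
      mm <- which(tc[s:(s + m - 1L)] != pc)
      if (length(mm) <= k) {
        starts <- c(starts, s)
        counts <- c(counts, length(mm))
        positions[[length(positions) + 1L]] <- as.integer(mm)
      }
    }
  }
  list(subject_start = starts, mismatch_count = counts,
       mismatch_positions = positions)
}

# character-by-character overlapping occurrence count (no regex)
naive_count_occurrences <- function(site, seq) {
  m <- nchar(site)
  n <- nchar(seq)
  if (n < m) return(0L)
  sum(vapply(seq_len(n - m + 1L),
             function(s) substr(seq, s, s + m - 1L) == site, TRUE))
}

# simple two-exon transcript used in several coordinate tests
toy_transcript <- function(len = 900L, cds_start = 100L, cds_end = 800L,
                           exon_lengths = NULL, seed = 42L) {
  set.seed(seed)
  transcript("toy1", "TOY", random_dna(len), cds_start, cds_end, exon_lengths)
}

expect_same_hits <- function(got, oracle) {
  expect_identical(got$subject_start, as.integer(oracle$subject_start))
  expect_identical(got$mismatch_count, as.integer(oracle$mismatch_count))
  expect_identical(lapply(got$mismatch_positions, as.integer),
                   oracle$mismatch_positions)
}
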