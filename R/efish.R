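#' IUPAC-aware exact probe match against one read
#'
#' TRUE iff the probe, or its reverse complement, occurs as a contiguous
#' exact substring of the read under IUPAC compatibility: degenerate
#' positions in the probe match any base of their expansion, while the
#' read is taken literally (an `N` in a read matches nothing).
#'
#' @param probe IUPAC nucleotide string.
#' @param read Concrete nucleotide string (A/C/G/T/N).
#' @param max_mismatch Number of tolerated mismatches; the default 0 is
#'   exact matching.
#' @return Logical scalar.
#' @export
#' @examples
#' iupac_match("GCWTTC", "AAGCATTCAA")  # W matches A
#' iupac_match("GCCTTC", "TTGAAGGCTT")  # reverse-complement hit
iupac_match <- function(probe, read, max_mismatch = 0L) {
  probe <- toupper(probe); read <- toupper(read)
  if (!grepl("^[ACGTRYSWKMBDHVN]+$", probe)) stop_validation("probe contains non-IUPAC characters")
  if (!grepl("^[ACGTN]+$", read)) stop_validation("read must be over A/C/G/T/N")
  if (nchar(probe) > nchar(read)) return(FALSE)
  subj <- Biostrings::DNAString(read)
  pat <- Biostrings::DNAString(probe)
  fwd <- Biostrings::countPattern(pat, subj, max.mismatch = max_mismatch, fixed = "subject")
  rev <- Biostrings::countPattern(Biostrings::reverseComplement(pat), subj,
                                  max.mismatch = max_mismatch, fixed = "subject")
  (fwd + rev) > 0
}

#' Count probe target hits in a read collection
#'
#' For every probe (and probe mix), the number of distinct reads
#' containing at least one exact IUPAC-compatible occurrence of the probe
#' or its reverse complement.  A read matching two different probes
#' increments both; a read matching one probe twice increments once; a
#' mix counts distinct reads matching any of its members.
#'
#' @param reads A tibble with a `sequence` column (and optionally
#'   `sample`), e.g. from [sim_probe_reads()], or a character vector of
#'   read sequences.
#' @param probes An `ebpr_probes` tibble (see [read_probes()]).
#' @param max_mismatch Tolerated mismatches per occurrence (default 0 =
#'   exact matching; nonzero is a sensitivity mode, not the standard
#'   analysis).
#' @return A tibble of class `ebpr_efish`: `sample`, `probe`, `role`,
#'   `raw_hits`, `total_reads`.  Mixes appear under their mix label; the
#'   universal aggregate under `"universal"`.
#' @export
count_probe_hits <- function(reads, probes, max_mismatch = 0L) {
  stopifnot(inherits(probes, "ebpr_probes"))
  if (is.character(reads)) reads <- tibble(sequence = reads)
  if (!"sample" %in% names(reads)) reads$sample <- "sample_1"
  out <- lapply(split(reads, reads$sample), function(chunk) {
    set <- Biostrings::DNAStringSet(chunk$sequence)
    hit_read <- sapply(seq_len(nrow(probes)), function(i) {
      pat <- Biostrings::DNAString(probes$sequence[i])
      f <- Biostrings::vcountPattern(pat, set, max.mismatch = max_mismatch,
                                     fixed = "subject")
      r <- Biostrings::vcountPattern(Biostrings::reverseComplement(pat), set,
                                     max.mismatch = max_mismatch, fixed = "subject")
      (f + r) > 0
    })
    hit_read <- matrix(hit_read, nrow = length(set))
    per_probe <- tibble(sample = chunk$sample[1],
                        probe = probes$probe_id,
                        role = probes$role,
                        raw_hits = colSums(hit_read),
                        total_reads = length(set))
    # aggregates: distinct reads matching any member of a mix
    agg <- lapply(unique(probes$mix), function(mx) {
      members <- which(probes$mix == mx)
      if (length(members) == 1 && probes$probe_id[members] == mx) return(NULL)
      tibble(sample = chunk$sample[1], probe = mx,
             role = if (mx == "universal") "universal" else "mix",
             raw_hits = sum(rowSums(hit_read[, members, drop = FALSE]) > 0),
             total_reads = length(set))
    })
    bind_rows(per_probe, bind_rows(agg))
  })
  out <- bind_rows(out)
  class(out) <- c("ebpr_efish", class(out))
  out
}

#' Normalise probe hit counts to the universal probe
#'
#' Divides each probe's raw hit count by the universal aggregate's hit
#' count in the same sample, the in-silico analogue of expressing FISH
#' signal relative to a universal bacterial probe.  The universal
#' aggregate itself normalises to 1 by construction.  Samples with zero
#' universal hits are flagged undefined, never silently zero.
#'
#' @param counts An `ebpr_efish` tibble from [count_probe_hits()].
#' @return The same tibble with `universal_hits`, `normalized` and
#'   `flag` columns added.
#' @export
normalize_probe_counts <- function(counts) {
  stopifnot(inherits(counts, "ebpr_efish"))
  uni <- counts %>%
    filter(.data$probe == "universal" |
             (.data$role == "universal" & !"universal" %in% counts$probe)) %>%
    group_by(.data$sample) %>%
    summarise(universal_hits = max(.data$raw_hits), .groups = "drop")
  out <- counts %>%
    left_join(uni, by = "sample") %>%
    mutate(normalized = ifelse(.data$universal_hits > 0,
                               .data$raw_hits / .data$universal_hits, NA_real_),
           flag = ifelse(.data$universal_hits > 0, NA_character_, "undefined_normalization"))
  class(out) <- c("ebpr_efish", class(out))
  out
}

#' In-silico FISH quantification of probe targets in shotgun reads
#'
#' Convenience wrapper: [count_probe_hits()] then
#' [normalize_probe_counts()].
#'
#' @inheritParams count_probe_hits
#' @return A normalised `ebpr_efish` tibble.
#' @export
#' @examples
#' probes <- as_probe_set(
#'   data.frame(probe_id = c("UNIV", "GRP"),
#'              sequence = c("ACGTACGTACGTACGTAC", "GGATCCGGATCCGGATCC")),
#'   universal = "UNIV")
#' reads <- sim_probe_reads(read_sim_spec(
#'   c(carrier = 0.2, other = 0.8), list(carrier = "GRP"), probes,
#'   n_reads = 500, rng_seed = 7))
#' efish(reads, probes)
efish <- function(reads, probes, max_mismatch = 0L) {
  normalize_probe_counts(count_probe_hits(reads, probes, max_mismatch))
}
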