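#' Read a batch-cycle concentration time series
#'
#' Loads one anaerobic/aerobic batch-test cycle from a comma-separated file.
#' The file must carry a header with at least `time_min`, `phase` and one
#' analyte column.  Recognised analyte columns are `acetate` (C-mmol/L),
#' `phosphate` (P-mmol/L), `phb`, `phv`, `glycogen` (C-mmol per g VSS) and
#' `vss` (g/L); a `replicate_id` column is carried through untouched so
#' duplicate reactors can be averaged at whichever level the analysis
#' chooses.
#'
#' @param path Path to a CSV file.
#' @return A tibble of class `ebpr_batch`, sorted by `time_min`, with
#'   `phase` as a factor with levels `anaerobic`, `aerobic`.
#' @seealso [write_batch_timeseries()], [sim_batch_timeseries()]
#' @export
#' @examples
#' ts <- sim_batch_timeseries(batch_sim_spec(noise_sd = 0, rng_seed = 1))
#' f <- tempfile(fileext = ".csv")
#' write_batch_timeseries(ts, f)
#' read_batch_timeseries(f)
read_batch_timeseries <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("time_min", "phase")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop_format("batch time-series file is missing required column(s): %s",
                paste(missing, collapse = ", "))
  }
  analytes <- intersect(batch_analytes(), names(df))
  if (length(analytes) == 0) {
    stop_format("batch time-series file has no analyte column (expected one of: %s)",
                paste(batch_analytes(), collapse = ", "))
  }
  as_batch_timeseries(df)
}

batch_analytes <- function() c("acetate", "phosphate", "phb", "phv", "glycogen", "vss")

#' Validate and classify a batch time-series data frame
#'
#' @param df A data frame with columns `time_min`, `phase` and analyte
#'   columns as described in [read_batch_timeseries()].
#' @return A validated `ebpr_batch` tibble sorted by time.
#' @export
as_batch_timeseries <- function(df) {
  df <- as_tibble(df)
  bad <- setdiff(unique(as.character(df$phase)), c("anaerobic", "aerobic"))
  if (length(bad) > 0) {
    stop_validation("unknown phase label(s): %s (expected 'anaerobic' or 'aerobic')",
                    paste(shQuote(bad), collapse = ", "))
  }
  if (!is.numeric(df$time_min)) stop_validation("`time_min` must be numeric")
  df <- arrange(df, .data$time_min)
  if (any(duplicated(df$time_min))) {
    stop_validation("`time_min` contains duplicated time points")
  }
  # phases must form contiguous blocks, anaerobic first when both present
  ph <- as.character(df$phase)
  blocks <- rle(ph)$values
  if (any(duplicated(blocks))) {
    stop_validation("phase labels do not form contiguous blocks over time")
  }
  for (a in intersect(batch_analytes(), names(df))) {
    if (!is.numeric(df[[a]])) stop_validation("analyte column `%s` must be numeric", a)
    if (any(df[[a]] < 0, na.rm = TRUE)) {
      stop_validation("analyte column `%s` contains negative concentrations", a)
    }
  }
  df$phase <- factor(ph, levels = c("anaerobic", "aerobic"))
  class(df) <- c("ebpr_batch", class(df))
  df
}

#' Write a batch time series to CSV
#'
#' Inverse of [read_batch_timeseries()]: a written file re-read with the
#' loader is value-identical.
#'
#' @param ts An `ebpr_batch` tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_batch_timeseries <- function(ts, path) {
  out <- as_tibble(ts)
  out$phase <- as.character(out$phase)
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Read an OTU count table
#'
#' Loads a tab-separated OTU table: first column the OTU identifier, a
#' final `taxonomy` column holding the semicolon-delimited ranked lineage
#' string, and one column of integer read counts per dated sample.  Sample
#' column headers must be ISO-8601 dates; columns are re-ordered
#' chronologically on load.
#'
#' @param path Path to a TSV file.
#' @return A tibble of class `ebpr_otu` with columns `otu_id`, one count
#'   column per sample date (ascending), and `taxonomy`.
#' @seealso [write_otu_table()], [sim_otu_counts()]
#' @export
read_otu_table <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (ncol(df) < 3) stop_format("OTU table needs an id column, sample columns and a taxonomy column")
  names(df)[1] <- "otu_id"
  if (!"taxonomy" %in% names(df)) {
    stop_format("OTU table is missing the `taxonomy` column")
  }
  as_otu_table(df)
}

#' Validate an OTU count data frame
#'
#' @param df Data frame with `otu_id`, date-named count columns, `taxonomy`.
#' @return A validated `ebpr_otu` tibble with sample columns sorted by date.
#' @export
as_otu_table <- function(df) {
  df <- as_tibble(df)
  if (any(duplicated(df$otu_id))) {
    stop_validation("duplicated OTU id(s): %s",
                    paste(unique(df$otu_id[duplicated(df$otu_id)]), collapse = ", "))
  }
  samples <- setdiff(names(df), c("otu_id", "taxonomy"))
  dates <- as.Date(samples, format = "%Y-%m-%d")
  if (any(is.na(dates))) {
    stop_format("sample column header(s) are not ISO-8601 dates: %s",
                paste(samples[is.na(dates)], collapse = ", "))
  }
  for (s in samples) {
    x <- df[[s]]
    if (!is.numeric(x) || any(is.na(x)) || any(x < 0) || any(x != as.integer(x))) {
      stop_validation("sample column `%s` must contain non-negative integer counts", s)
    }
    df[[s]] <- as.integer(x)
  }
  df <- df[, c("otu_id", samples[order(dates)], "taxonomy")]
  class(df) <- c("ebpr_otu", class(df))
  df
}

#' Write an OTU table to TSV
#'
#' @param table An `ebpr_otu` tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_otu_table <- function(table, path) {
  readr::write_tsv(as_tibble(table), path, progress = FALSE)
  invisible(path)
}

#' Sample dates of an OTU table
#' @param table An `ebpr_otu` tibble.
#' @return A `Date` vector, ascending.
#' @export
otu_sample_dates <- function(table) {
  as.Date(setdiff(names(table), c("otu_id", "taxonomy")))
}

#' Count matrix of an OTU table
#' @param table An `ebpr_otu` tibble.
#' @return Integer matrix, OTUs x samples, rownames `otu_id`.
#' @export
otu_counts <- function(table) {
  samples <- setdiff(names(table), c("otu_id", "taxonomy"))
  m <- as.matrix(table[, samples])
  rownames(m) <- table$otu_id
  storage.mode(m) <- "integer"
  m
}

#' Epoch membership of samples
#'
#' Assigns each sample date to the high- or low-aeration epoch by
#' comparison with the boundary date: samples strictly before the boundary
#' are `high`, all later ones `low`.
#'
#' @param dates A `Date` vector (or object coercible with `as.Date()`).
#' @param boundary The first date of the low-aeration epoch.
#' @return A factor with levels `high`, `low`.
#' @export
epoch_of <- function(dates, boundary) {
  dates <- as.Date(dates)
  boundary <- as.Date(boundary)
  factor(ifelse(dates < boundary, "high", "low"), levels = c("high", "low"))
}

#' Extract the most resolved named rank from a lineage string
#'
#' Lineage strings use the greengenes-style `k__...; p__...; ...; g__...;
#' s__...` convention.  The value of the requested rank prefix is
#' returned; empty ranks (`g__` with no name) yield `NA`.
#'
#' @param taxonomy Character vector of lineage strings.
#' @param rank Single rank letter, e.g. `"g"` for genus.
#' @return Character vector of rank names (`NA` where unclassified).
#' @export
#' @examples
#' taxonomy_rank(
#'   "k__Bacteria; p__Proteobacteria; g__Candidatus Accumulibacter; s__", "g")
taxonomy_rank <- function(taxonomy, rank = "g") {
  pat <- paste0("(?:^|;)\\s*", rank, "__([^;]*)")
  m <- stringr::str_match(taxonomy, pat)[, 2]
  m <- stringr::str_trim(m)
  m[is.na(m) | m == ""] <- NA_character_
  m
}

#' Read a FISH probe / primer set from FASTA
#'
#' Sequences may use the full IUPAC nucleotide alphabet (degenerate
#' positions included).  One or more records must be designated as the
#' universal reference aggregate (e.g. the EUB338 mix) used by
#' [normalize_probe_counts()].
#'
#' @param path FASTA file of probe/primer sequences.
#' @param universal Character vector of record ids forming the universal
#'   aggregate.
#' @param mixes Optional named list mapping a mix label to the member
#'   record ids (FISH mix semantics: a mix counts distinct reads matching
#'   any member).
#' @return A tibble of class `ebpr_probes` with columns `probe_id`,
#'   `sequence`, `role` and `mix`.
#' @export
read_probes <- function(path, universal, mixes = NULL) {
  set <- tryCatch(
    Biostrings::readDNAStringSet(path),
    error = function(e) stop_validation("probe FASTA could not be parsed as IUPAC nucleotide sequences: %s",
                                        conditionMessage(e))
  )
  ids <- sub("\\s.*$", "", names(set))
  as_probe_set(tibble(probe_id = ids, sequence = as.character(set)),
               universal = universal, mixes = mixes)
}

#' Build a validated probe set from a data frame
#'
#' @param df Data frame with columns `probe_id` and `sequence`.
#' @inheritParams read_probes
#' @return A tibble of class `ebpr_probes`.
#' @export
as_probe_set <- function(df, universal, mixes = NULL) {
  df <- as_tibble(df)
  if (any(duplicated(df$probe_id))) stop_validation("probe ids must be unique")
  df$sequence <- toupper(df$sequence)
  ok <- grepl("^[ACGTRYSWKMBDHVN]+$", df$sequence)
  if (!all(ok)) {
    stop_validation("probe(s) contain non-IUPAC characters: %s",
                    paste(df$probe_id[!ok], collapse = ", "))
  }
  if (missing(universal) || length(universal) == 0) {
    stop_config("a universal reference probe must be designated")
  }
  if (!all(universal %in% df$probe_id)) {
    stop_config("universal probe id(s) not present in the set: %s",
                paste(setdiff(universal, df$probe_id), collapse = ", "))
  }
  df$role <- ifelse(df$probe_id %in% universal, "universal", "group_probe")
  df$mix <- df$probe_id
  df$mix[df$role == "universal"] <- "universal"
  if (!is.null(mixes)) {
    for (mx in names(mixes)) {
      miss <- setdiff(mixes[[mx]], df$probe_id)
      if (length(miss) > 0) stop_config("mix `%s` references unknown probe id(s): %s",
                                        mx, paste(miss, collapse = ", "))
      df$mix[df$probe_id %in% mixes[[mx]] & df$role != "universal"] <- mx
    }
  }
  class(df) <- c("ebpr_probes", class(df))
  df
}

#' Analysis configuration
#'
#' A single declarative object holding every tunable of the pipeline so a
#' run is reproducible from its configuration alone.
#'
#' @param rarefaction_depth Even depth for [rarefy_counts()] (reads per
#'   sample).
#' @param rng_seed Integer seed applied to every stochastic step.
#' @param changepoint_split Integer pair `(n1, n2)`: samples in the first
#'   (high-aeration) and second (low-aeration) segment.
#' @param alpha_fdr Target false discovery rate in (0, 1).
#' @param epoch_boundary_date First date of the low-aeration epoch.
#' @param balance_coefficients Named stoichiometric coefficients for the
#'   flux-balance model; see [balance_coefficients()].
#' @return A list of class `ebpr_config`.
#' @export
analysis_config <- function(rarefaction_depth,
                            rng_seed = 1L,
                            changepoint_split = c(4L, 6L),
                            alpha_fdr = 0.1,
                            epoch_boundary_date = NULL,
                            balance_coefficients = ebprtools::balance_coefficients()) {
  check_count(rarefaction_depth, "rarefaction_depth", lower = 1)
  check_count(rng_seed, "rng_seed", lower = -.Machine$integer.max)
  if (length(changepoint_split) != 2 || any(changepoint_split < 2)) {
    stop_validation("`changepoint_split` must be two integers, both >= 2")
  }
  check_number(alpha_fdr, "alpha_fdr", lower = 1e-12, upper = 1 - 1e-12)
  structure(
    list(rarefaction_depth = as.integer(rarefaction_depth),
         rng_seed = as.integer(rng_seed),
         changepoint_split = as.integer(changepoint_split),
         alpha_fdr = alpha_fdr,
         epoch_boundary_date = if (!is.null(epoch_boundary_date)) as.Date(epoch_boundary_date),
         balance_coefficients = balance_coefficients),
    class = "ebpr_config"
  )
}
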