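# Exhaustive variable-gap motif scanning ---------------------------------
#
# Matching strategy: every variable-length gap is enumerated, so a motif
# expands into a finite set of fixed-length layouts (the product of the gap
# ranges; the published motifs expand to at most a few dozen). For each
# layout, class membership is tested with vectorized logical masks over the
# sequence, so scanning a record costs O(layouts * elements * length)
# vector operations rather than per-position backtracking. All distinct
# (start, end) spans are reported — overlapping matches and multiple gap
# resolutions of the same start included — which is what an exhaustive
# PROSITE-style query over a proteome requires.

MAX_MOTIF_EXPANSIONS <- 100000L

# Enumerate the fixed gap-length layouts of a motif. Returns an integer
# matrix with one row per layout and one column per element (the chosen
# repeat count), rows in lexicographic order, first element varying slowest.
gap_layouts <- function(m) {
  ranges <- lapply(m$elements, function(e) seq.int(e$min_repeat, e$max_repeat))
  n_comb <- prod(vapply(ranges, length, numeric(1)))
  if (n_comb > MAX_MOTIF_EXPANSIONS)
    stop("motif expands to ", n_comb, " gap layouts (limit ",
         MAX_MOTIF_EXPANSIONS, "); narrow the gap ranges", call. = FALSE)
  grid <- do.call(expand.grid, c(rev(ranges), KEEP.OUT.ATTRS = FALSE))
  as.matrix(grid[, rev(seq_along(ranges)), drop = FALSE])
}

# Per-element membership masks over a character vector of residues.
# Named classes match exactly their allowed letters; the wildcard matches
# any letter A-Z (ambiguity codes included) but never '*' or other symbols.
element_masks <- function(m, chars) {
  lapply(m$elements, function(e) {
    if (is_gap_element(e)) chars %in% LETTERS else chars %in% e$residue_class$allowed
  })
}

#' Find all motif occurrences in one protein sequence
#'
#' Reports every distinct (start, end) span of `sequence` that admits at
#' least one assignment of motif elements, including overlapping spans and
#' spans sharing a start but differing in gap-length choices. For each span
#' a single witness assignment is stored: the lexicographically smallest
#' gap-length vector (earlier gaps as short as possible).
#'
#' @param m A motif.
#' @param sequence Protein sequence as a single string (or an
#'   `AAString`). Matching is case-insensitive; `*` never matches.
#' @param record_id Identifier copied into the result.
#' @return A data frame of class `acscan_matches` with columns `record_id`,
#'   `start`, `end` (1-based, inclusive), `matched` (the spanned substring)
#'   and `gap_choices` (semicolon-separated repeat count per element), plus
#'   a list column `element_spans` of per-element `(start, end)` matrices.
#'   Rows are ordered by `(start, end)`.
#' @examples
#' find_matches(motif_preset("ac_core"), "RYDVAAAAAAAAAKAD")
#' @export
find_matches <- function(m, sequence, record_id = "seq") {
  stopifnot(is_motif(m))
  seq_str <- toupper(as.character(sequence))
  stopifnot(length(seq_str) == 1L)
  n <- nchar(seq_str)
  if (n < m$min_span) return(empty_matches())
  chars <- strsplit(seq_str, "")[[1]]
  masks <- element_masks(m, chars)
  csum  <- lapply(masks, function(mk) cumsum(c(0L, mk)))
  layouts <- gap_layouts(m)

  starts_all <- integer(0); ends_all <- integer(0); layout_all <- integer(0)
  for (li in seq_len(nrow(layouts))) {
    reps <- layouts[li, ]
    len <- sum(reps)
    if (len > n) next
    n_starts <- n - len + 1L
    ok <- rep(TRUE, n_starts)
    offset <- 0L
    for (k in seq_along(reps)) {
      r <- reps[k]
      if (r > 0L) {
        cs <- csum[[k]]
        # run of r consecutive TRUEs starting at position p + offset
        ok <- ok & (cs[seq_len(n_starts) + offset + r] -
                      cs[seq_len(n_starts) + offset] == r)
      }
      offset <- offset + r
      if (!any(ok)) break
    }
    hit <- which(ok)
    if (length(hit) > 0L) {
      starts_all <- c(starts_all, hit)
      ends_all   <- c(ends_all, hit + len - 1L)
      layout_all <- c(layout_all, rep.int(li, length(hit)))
    }
  }
  if (length(starts_all) == 0L) return(empty_matches())

  # one row per distinct span; layouts were generated with earlier gaps
  # varying slowest and ascending, so the first layout index per span is the
  # lexicographically smallest witness
  ord <- order(starts_all, ends_all, layout_all)
  starts_all <- starts_all[ord]; ends_all <- ends_all[ord]
  layout_all <- layout_all[ord]
  keep <- !duplicated(cbind(starts_all, ends_all))
  starts <- starts_all[keep]; ends <- ends_all[keep]
  lays <- layout_all[keep]

  spans <- lapply(seq_along(starts), function(i) {
    reps <- layouts[lays[i], ]
    el_end <- starts[i] - 1L + cumsum(reps)
    el_start <- c(starts[i], utils::head(el_end, -1L) + 1L)
    el_start[reps == 0L] <- NA_integer_
    el_end[reps == 0L] <- NA_integer_
    cbind(start = el_start, end = el_end)
  })
  out <- data.frame(
    record_id = rep.int(record_id, length(starts)),
    start = starts, end = ends,
    matched = substring(seq_str, starts, ends),
    gap_choices = vapply(seq_along(starts), function(i)
      paste(layouts[lays[i], ], collapse = ";"), character(1)),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out$element_spans <- spans
  class(out) <- c("acscan_matches", class(out))
  out
}

empty_matches <- function() {
  out <- data.frame(record_id = character(), start = integer(),
                    end = integer(), matched = character(),
                    gap_choices = character(), stringsAsFactors = FALSE)
  out$element_spans <- list()
  class(out) <- c("acscan_matches", class(out))
  out
}

# FASTA loading -----------------------------------------------------------

#' Read a protein FASTA file for scanning
#'
#' Loads records with `Biostrings`, upper-cases residues, strips one
#' trailing stop `*`, skips zero-length records with a warning, and
#' suffix-deduplicates duplicate ids (`id`, `id.dup2`, ...) with a warning.
#' The id is the header token up to the first whitespace; the full header is
#' kept as the description.
#'
#' @param fasta_path Path to a FASTA file.
#' @return Data frame with columns `id`, `description`, `residues`.
#' @export
read_protein_fasta <- function(fasta_path) {
  if (!file.exists(fasta_path))
    stop("cannot read FASTA file: ", fasta_path, call. = FALSE)
  aa <- Biostrings::readBStringSet(fasta_path)
  headers <- names(aa)
  if (is.null(headers)) headers <- rep("", length(aa))
  ids <- sub("\\s.*$", "", headers)
  seqs <- toupper(as.character(aa))
  seqs <- sub("\\*$", "", seqs)
  keep <- nchar(seqs) > 0L
  if (any(!keep)) {
    warning("skipping ", sum(!keep), " zero-length record(s): ",
            paste(utils::head(ids[!keep], 5), collapse = ", "), call. = FALSE)
    ids <- ids[keep]; headers <- headers[keep]; seqs <- seqs[keep]
  }
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    warning("duplicate record id(s) deduplicated by suffix: ",
            paste(utils::head(dup, 5), collapse = ", "), call. = FALSE)
    ids <- make.unique(ids, sep = ".dup")
  }
  data.frame(id = ids, description = headers, residues = seqs,
             stringsAsFactors = FALSE)
}

# Scanning over record sets ----------------------------------------------

#' Scan a set of protein records with a motif
#'
#' @param m A motif.
#' @param records Data frame as returned by [read_protein_fasta()].
#' @param collapse_isoforms If `TRUE`, distinct-protein counting truncates
#'   record ids at the first `.` (the `AT#G#####.#` isoform convention) and
#'   counts distinct loci instead of distinct records.
#' @return An `acscan_scan_summary`: list with `motif_name`,
#'   `n_records_scanned`, `n_records_hit`, `n_matches` and the `hits` match
#'   table.
#' @export
scan_records <- function(m, records, collapse_isoforms = FALSE) {
  stopifnot(is_motif(m), is.data.frame(records))
  hit_list <- vector("list", nrow(records))
  for (i in seq_len(nrow(records))) {
    hit_list[[i]] <- find_matches(m, records$residues[i],
                                  record_id = records$id[i])
  }
  hits <- if (nrow(records) > 0L) do.call(rbind, hit_list) else empty_matches()
  key <- unique(hits$record_id)
  if (collapse_isoforms) key <- unique(sub("\\..*$", "", key))
  out <- list(
    motif_name = m$name,
    n_records_scanned = nrow(records),
    n_records_hit = length(key),
    n_matches = nrow(hits),
    hits = hits
  )
  class(out) <- "acscan_scan_summary"
  out
}

#' @export
print.acscan_scan_summary <- function(x, ...) {
  cat("<scan summary> motif ", x$motif_name, ": ", x$n_matches,
      " match(es) in ", x$n_records_hit, " of ", x$n_records_scanned,
      " record(s)\n", sep = "")
  invisible(x)
}

#' Scan a protein FASTA file with a motif
#'
#' Convenience wrapper: [read_protein_fasta()] followed by
#' [scan_records()].
#'
#' @inheritParams scan_records
#' @param fasta_path Path to a protein FASTA file.
#' @return An `acscan_scan_summary`.
#' @export
scan_fasta <- function(m, fasta_path, collapse_isoforms = FALSE) {
  scan_records(m, read_protein_fasta(fasta_path),
               collapse_isoforms = collapse_isoforms)
}

#' Compare hit counts of several motif variants over one protein set
#'
#' Scans the same records once per motif and tabulates distinct-protein and
#' total match counts, the four-way comparison used to choose among motif
#' variants of differing stringency. When a background model is supplied,
#' expected chance-hit columns are appended (see [expected_hits()]).
#'
#' @param motifs List of motifs (or a single motif).
#' @param fasta_path Path to the FASTA file to scan.
#' @param collapse_isoforms Passed to [scan_records()].
#' @param background Optional [background_model()] for expected-hit columns;
#'   `"empirical"` estimates composition from the scanned records.
#' @return Data frame with one row per motif: `motif_name`, `pattern`,
#'   `n_records_hit`, `n_matches` (and `expected_sites`,
#'   `expected_records` when a background is given), in input order.
#' @export
compare_variants <- function(motifs, fasta_path, collapse_isoforms = FALSE,
                             background = NULL) {
  if (is_motif(motifs)) motifs <- list(motifs)
  stopifnot(length(motifs) >= 1L)
  records <- read_protein_fasta(fasta_path)
  if (identical(background, "empirical"))
    background <- background_from_records(records)
  rows <- lapply(motifs, function(m) {
    s <- scan_records(m, records, collapse_isoforms = collapse_isoforms)
    row <- data.frame(motif_name = m$name, pattern = motif_to_string(m),
                      n_records_hit = s$n_records_hit,
                      n_matches = s$n_matches, stringsAsFactors = FALSE)
    if (!is.null(background)) {
      total <- sum(nchar(records$residues))
      mean_len <- if (nrow(records) > 0L) total / nrow(records) else 0
      eh <- expected_hits(m, background, total_residues = max(total, 1),
                          n_records = max(nrow(records), 1L),
                          mean_length = max(mean_len, 1))
      row$expected_sites <- eh$expected_sites
      row$expected_records <- eh$expected_records
    }
    row
  })
  do.call(rbind, rows)
}
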