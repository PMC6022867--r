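# Report writers ----------------------------------------------------------

#' Write a match table to TSV
#'
#' Columns: `record_id`, `motif`, `start`, `end`, `matched`, `gap_choices`.
#'
#' @param hits Match table (from [find_matches()] or a scan summary's
#'   `hits`).
#' @param motif_name Motif name column value.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hits_tsv <- function(hits, motif_name, path) {
  df <- data.frame(record_id = hits$record_id, motif = motif_name,
                   start = hits$start, end = hits$end,
                   matched = hits$matched, gap_choices = hits$gap_choices,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write matches as GFF3 polypeptide-motif features
#'
#' Protein-coordinate GFF3 (1-based, inclusive) with feature type
#' `polypeptide_motif`; the seqid is the protein record id and strand is
#' `.` (protein coordinates have no strand).
#'
#' @inheritParams write_hits_tsv
#' @return `path`, invisibly.
#' @export
write_hits_gff3 <- function(hits, motif_name, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(hits) > 0L) {
    attrs <- sprintf("ID=%s.%s.%d;Name=%s;gap_choices=%s",
                     hits$record_id, motif_name, seq_len(nrow(hits)),
                     motif_name, hits$gap_choices)
    writeLines(paste(hits$record_id, "acscan", "polypeptide_motif",
                     hits$start, hits$end, ".", ".", ".", attrs,
                     sep = "\t"), con)
  }
  invisible(path)
}
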