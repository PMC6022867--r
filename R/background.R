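# Background expected-hit model ------------------------------------------
#
# A scan of a whole proteome with a permissive pattern returns some hits by
# chance alone. Under an i.i.d. residue background, the probability that a
# match starts at a fixed position has a closed form: each residue-class
# position contributes the class's total frequency, wildcard positions
# contribute 1, and the alternatives arising from variable gap lengths are
# combined by a union bound (summed). The union bound slightly over-counts
# sequences matched by several gap layouts, so all quantities here are
# documented upper bounds; at the probabilities involved (~1e-5) the
# difference is negligible.

#' Construct an i.i.d. residue background model
#'
#' @param composition Named numeric vector or list mapping one-letter
#'   residue codes to frequencies; must be non-negative and sum to 1 within
#'   1e-9. Residues of [STANDARD_AA] absent from the map get frequency 0.
#' @return An `acscan_background` with field `composition` (named numeric
#'   over the 20 standard residues).
#' @examples
#' background_uniform()
#' background_model(c(A = 0.5, G = 0.5))
#' @export
background_model <- function(composition) {
  comp <- unlist(composition)
  if (is.null(names(comp)) || any(!nzchar(names(comp))))
    stop("composition must be a named residue -> frequency map", call. = FALSE)
  names(comp) <- toupper(names(comp))
  bad <- setdiff(names(comp), STANDARD_AA)
  if (length(bad) > 0L)
    stop("non-standard residue(s) in composition: ",
         paste(bad, collapse = ", "), call. = FALSE)
  if (any(comp < 0))
    stop("frequencies must be non-negative", call. = FALSE)
  if (abs(sum(comp) - 1) > 1e-9)
    stop("frequencies must sum to 1 (got ", format(sum(comp)), ")",
         call. = FALSE)
  full <- stats::setNames(numeric(length(STANDARD_AA)), STANDARD_AA)
  full[names(comp)] <- comp
  bg <- list(composition = full)
  class(bg) <- "acscan_background"
  bg
}

#' @rdname background_model
#' @export
background_uniform <- function() {
  background_model(stats::setNames(rep(1 / 20, 20), STANDARD_AA))
}

#' Estimate a background model from protein sequences
#'
#' Empirical frequencies over the 20 standard residues; ambiguity codes and
#' stops are ignored.
#'
#' @param fasta_path Path to a protein FASTA file.
#' @param records Alternatively, a record table from
#'   [read_protein_fasta()].
#' @return An `acscan_background`.
#' @export
background_from_fasta <- function(fasta_path) {
  background_from_records(read_protein_fasta(fasta_path))
}

#' @rdname background_from_fasta
#' @export
background_from_records <- function(records) {
  counts <- stats::setNames(numeric(length(STANDARD_AA)), STANDARD_AA)
  for (s in records$residues) {
    tab <- table(strsplit(s, "")[[1]])
    keep <- intersect(names(tab), STANDARD_AA)
    counts[keep] <- counts[keep] + as.numeric(tab[keep])
  }
  if (sum(counts) == 0)
    stop("no standard residues found; cannot estimate composition",
         call. = FALSE)
  background_model(counts / sum(counts))
}

#' Probability that a motif match starts at a fixed position
#'
#' Union-bound probability, under an i.i.d. background, that at least one
#' gap layout of the motif matches starting at a given position of an
#' infinitely long background sequence: the sum over gap layouts of the
#' product over residue-class positions of the class frequency (wildcard
#' positions contribute 1). An upper bound on the exact probability; exact
#' for motifs with a single layout.
#'
#' @param m A motif.
#' @param bg A [background_model()].
#' @return Numeric probability (may exceed the exact value, never the
#'   number of layouts).
#' @examples
#' start_probability(motif_preset("ac_core"), background_uniform())
#' @export
start_probability <- function(m, bg) {
  stopifnot(is_motif(m), inherits(bg, "acscan_background"))
  class_prob <- vapply(m$elements, function(e) {
    if (is_gap_element(e)) 1.0 else sum(bg$composition[e$residue_class$allowed])
  }, numeric(1))
  n_layouts <- prod(vapply(m$elements, function(e)
    e$max_repeat - e$min_repeat + 1, numeric(1)))
  n_layouts * prod(class_prob)
}

#' Expected chance hits of a motif in a background proteome
#'
#' Converts the per-position start probability into expected counts for a
#' proteome of given size. Each record of length L offers
#' `max(L - max_span + 1, 0)` start positions (edge correction), so expected
#' sites are `p * (total_residues - n_records * (max_span - 1))` clamped at
#' zero, and the expected number of records with at least one hit treats
#' positions as independent: `n_records * (1 - (1 - p)^eff)` with `eff` the
#' effective positions per record of mean length.
#'
#' @param m A motif.
#' @param bg A [background_model()].
#' @param total_residues Total residue count of the proteome.
#' @param n_records Number of protein records.
#' @param mean_length Mean record length (aa).
#' @return List with `start_probability`, `expected_sites`,
#'   `expected_records`.
#' @export
expected_hits <- function(m, bg, total_residues, n_records, mean_length) {
  stopifnot(is_motif(m))
  if (total_residues <= 0 || n_records <= 0 || mean_length <= 0)
    stop("proteome sizes must be positive", call. = FALSE)
  p <- start_probability(m, bg)
  eff_total <- max(total_residues - n_records * (m$max_span - 1), 0)
  eff_per_record <- max(mean_length - m$max_span + 1, 0)
  list(
    start_probability = p,
    expected_sites = p * eff_total,
    expected_records = n_records * (1 - (1 - min(p, 1))^eff_per_record)
  )
}
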