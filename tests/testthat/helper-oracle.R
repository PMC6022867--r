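# Independent match oracle: recursive element-by-element backtracking,
# structurally unrelated to the vectorized layout-enumeration scanner in
# R/scan.R. Returns all distinct (start, end) spans as a two-column matrix.

oracle_find_spans <- function(m, seq_str) {
  chars <- strsplit(toupper(seq_str), "")[[1]]
  n <- length(chars)
  elements <- m$elements
  ends_from <- function(pos, k) {
    # set of positions just past a complete match of elements k..K
    # beginning at pos
    if (k > length(elements)) return(pos)
    el <- elements[[k]]
    out <- integer(0)
    if (el$residue_class$is_wildcard) {
      for (r in el$min_repeat:el$max_repeat) {
        if (pos + r - 1L > n) break
        run <- if (r == 0L) character(0) else chars[pos:(pos + r - 1L)]
        if (all(run %in% LETTERS))
          out <- c(out, ends_from(pos + r, k + 1L))
        else break  # a bad residue blocks all longer runs too
      }
    } else {
      if (pos <= n && chars[pos] %in% el$residue_class$allowed)
        out <- ends_from(pos + 1L, k + 1L)
    }
    unique(out)
  }
  spans <- list()
  for (s in seq_len(max(n - m$min_span + 1L, 0L))) {
    for (e in ends_from(s, 1L))
      spans[[length(spans) + 1L]] <- c(s, e - 1L)
  }
  if (length(spans) == 0L)
    return(matrix(integer(0), ncol = 2,
                  dimnames = list(NULL, c("start", "end"))))
  mat <- unique(do.call(rbind, spans))
  mat <- mat[order(mat[, 1], mat[, 2]), , drop = FALSE]
  colnames(mat) <- c("start", "end")
  mat
}

spans_of <- function(matches) {
  if (nrow(matches) == 0L)
    return(matrix(integer(0), ncol = 2,
                  dimnames = list(NULL, c("start", "end"))))
  cbind(start = matches$start, end = matches$end)
}

random_protein <- function(len, alphabet = acscan::STANDARD_AA) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# Random motif generator for property tests: 2-8 elements mixing classes
# and bounded gaps.
random_motif <- function() {
  n_el <- sample(2:8, 1)
  elements <- lapply(seq_len(n_el), function(i) {
    if (stats::runif(1) < 0.45) {
      lo <- sample(0:4, 1)
      hi <- lo + sample(0:3, 1)
      if (hi == 0L) hi <- 1L
      motif_element(residue_class(wildcard = TRUE), lo, hi)
    } else {
      motif_element(residue_class(sample(acscan::STANDARD_AA,
                                         sample(1:4, 1))))
    }
  })
  is_class <- vapply(elements, function(e) !e$residue_class$is_wildcard,
                     logical(1))
  if (!any(is_class))  # avoid degenerate all-gap motifs (zero-length spans)
    elements[[length(elements) + 1L]] <-
      motif_element(residue_class(sample(acscan::STANDARD_AA, 2)))
  motif(elements, name = "random")
}
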