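# Residue alphabet ------------------------------------------------------

#' The twenty standard amino-acid one-letter codes
#'
#' Upper-case one-letter codes of the twenty proteinogenic amino acids, in
#' alphabetical order. Ambiguity codes (B, J, Z), the rare residues U and O,
#' and the wildcard letter X are deliberately excluded: a named residue class
#' may only contain standard codes, and named classes never match ambiguity
#' codes in a scanned sequence.
#'
#' @format Character vector of length 20.
#' @export
STANDARD_AA <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Construct a residue class
#'
#' A residue class is either a named alternation such as `[RKS]` (matches
#' exactly the listed residues) or the wildcard `X` (matches any residue
#' letter, including ambiguity codes, but never the stop symbol `*`).
#'
#' @param allowed Character vector of one-letter codes (ignored for
#'   wildcards). Must be non-empty, unique after upper-casing, and a subset
#'   of [STANDARD_AA].
#' @param wildcard Logical flag; `TRUE` builds the wildcard class.
#' @return An object of class `acscan_residue_class` with fields `allowed`
#'   (sorted character vector, empty for wildcards) and `is_wildcard`.
#' @examples
#' residue_class(c("D", "E"))
#' residue_class(wildcard = TRUE)
#' @export
residue_class <- function(allowed = character(), wildcard = FALSE) {
  if (wildcard) {
    rc <- list(allowed = character(), is_wildcard = TRUE)
    class(rc) <- "acscan_residue_class"
    return(rc)
  }
  allowed <- unique(toupper(as.character(allowed)))
  if (length(allowed) == 0L)
    stop("residue class must allow at least one residue (or be a wildcard)",
         call. = FALSE)
  bad <- setdiff(allowed, STANDARD_AA)
  if (length(bad) > 0L)
    stop("non-standard residue code(s) in class: ",
         paste(bad, collapse = ", "), call. = FALSE)
  rc <- list(allowed = sort(allowed), is_wildcard = FALSE)
  class(rc) <- "acscan_residue_class"
  rc
}

is_residue_class <- function(x) inherits(x, "acscan_residue_class")

#' @export
format.acscan_residue_class <- function(x, ...) {
  if (x$is_wildcard) return("X")
  if (length(x$allowed) == 1L) return(x$allowed)
  paste0("[", paste(x$allowed, collapse = ""), "]")
}

#' @export
print.acscan_residue_class <- function(x, ...) {
  cat("<residue class> ", format(x), "\n", sep = "")
  invisible(x)
}

# Internal: coerce strings like "[DE]", "DE" or "X" to a residue class.
as_residue_class <- function(x) {
  if (is_residue_class(x)) return(x)
  if (is.character(x) && length(x) == 1L) {
    s <- gsub("^\\[|\\]$", "", x)
    if (identical(toupper(s), "X")) return(residue_class(wildcard = TRUE))
    return(residue_class(strsplit(s, "")[[1]]))
  }
  if (is.character(x)) return(residue_class(x))
  stop("cannot interpret object as a residue class", call. = FALSE)
}
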