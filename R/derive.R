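# Derivation operators ---------------------------------------------------
#
# The search motifs form a small family derived from a guanylate-cyclase
# parent: swapping the substrate-specificity class turns the GC motif into
# the AC motif; fixing a wildcard position narrows the hit list; prepending
# an upstream arginine anchor filters for pyrophosphate binding.

#' Substitute the residue class of one motif element
#'
#' Replaces the class of a non-gap element, keeping its functional role.
#' This is the operator that converts a guanylate-cyclase search motif into
#' an adenylate-cyclase one: the substrate-specificity class at motif
#' position 3 changes from `[CTGH]` (GTP preference) to `[DE]` (ATP
#' preference).
#'
#' @param m A motif.
#' @param element_index Index into the element list; must address a
#'   residue-class element, not a wildcard gap.
#' @param new_class New [residue_class()] (or string form such as `"[DE]"`).
#' @return A new motif differing from `m` only at that element.
#' @examples
#' gc <- motif_preset("gc_core")
#' ac <- substitute_position(gc, 3, "[DE]")
#' motif_to_string(ac)
#' @export
substitute_position <- function(m, element_index, new_class) {
  stopifnot(is_motif(m))
  element_index <- as.integer(element_index)
  if (element_index < 1L || element_index > length(m$elements))
    stop("element index out of range", call. = FALSE)
  el <- m$elements[[element_index]]
  if (is_gap_element(el))
    stop("element ", element_index, " is a wildcard gap; ",
         "only residue-class elements can be substituted", call. = FALSE)
  rc <- as_residue_class(new_class)
  if (rc$is_wildcard)
    stop("cannot substitute a class with the wildcard; widen the gap instead",
         call. = FALSE)
  elements <- m$elements
  elements[[element_index]] <- motif_element(rc, role = el$role)
  motif(elements, name = m$name)
}

#' Constrain one wildcard position of a fixed-length gap to a residue class
#'
#' Splits a fixed-length gap so that the named expanded motif position
#' becomes a one-residue class element; the surrounding gap shrinks by one
#' position, so total motif spans are unchanged. This is how the `[FV]`
#' constraint at motif position 5 is added to the core AC motif to obtain a
#' narrower candidate list.
#'
#' Positions are counted over the minimal instantiation of the motif
#' (see [expanded_position()]). Constraining a position of a
#' variable-length gap is rejected: the split would be ambiguous.
#' Constraining a position to the wildcard `X` is the identity (after
#' canonical gap merging).
#'
#' @param m A motif.
#' @param motif_position 1-based expanded motif position inside a
#'   fixed-length gap.
#' @param new_class Residue class for that position.
#' @param role Optional functional role for the new element.
#' @return A new motif with the same min/max spans.
#' @examples
#' ac <- motif_preset("ac_core")
#' motif_to_string(constrain_wildcard(ac, 5, "[FV]"))
#' @export
constrain_wildcard <- function(m, motif_position, new_class, role = "none") {
  stopifnot(is_motif(m))
  motif_position <- as.integer(motif_position)
  rc <- as_residue_class(new_class)
  starts <- element_expanded_starts(m)
  mins <- vapply(m$elements, function(e) e$min_repeat, integer(1))
  ends <- starts + mins - 1L
  k <- which(starts <= motif_position & motif_position <= ends)
  if (length(k) != 1L)
    stop("motif position ", motif_position,
         " does not fall inside the motif's minimal span", call. = FALSE)
  el <- m$elements[[k]]
  if (!is_gap_element(el))
    stop("motif position ", motif_position,
         " addresses a residue-class element, not a gap", call. = FALSE)
  if (el$min_repeat != el$max_repeat)
    stop("motif position ", motif_position, " lies in a variable-length gap ",
         "X{", el$min_repeat, ",", el$max_repeat,
         "}; the split would be ambiguous", call. = FALSE)
  if (rc$is_wildcard) return(motif(m$elements, name = m$name))
  before <- motif_position - starts[k]
  after  <- ends[k] - motif_position
  repl <- list()
  if (before > 0L)
    repl <- c(repl, list(motif_element(residue_class(wildcard = TRUE),
                                       before, before)))
  repl <- c(repl, list(motif_element(rc, role = role)))
  if (after > 0L)
    repl <- c(repl, list(motif_element(residue_class(wildcard = TRUE),
                                       after, after)))
  elements <- append(m$elements[-k], repl, after = k - 1L)
  motif(elements, name = m$name)
}

#' Prepend an upstream anchor residue with a bounded gap
#'
#' Adds an anchor class (by default carrying the `anchor` role) followed by
#' a variable gap `X{min_gap,max_gap}` before the motif's first element.
#' Used to require an upstream arginine — implicated in pyrophosphate
#' binding — within a bounded distance of motif position 1, which shrinks
#' the hit list.
#'
#' @param m A motif.
#' @param anchor_class Residue class of the anchor (e.g. `"[R]"`).
#' @param min_gap,max_gap Bounds (in residues) of the wildcard gap between
#'   the anchor and the old first element; both must be non-negative.
#' @param role Functional role recorded on the anchor element.
#' @return A new motif whose hit set is a subset of `m`'s.
#' @examples
#' motif_to_string(add_upstream_anchor(motif_preset("ac_core"), "R", 5, 20))
#' @export
add_upstream_anchor <- function(m, anchor_class, min_gap, max_gap,
                                role = "anchor") {
  stopifnot(is_motif(m))
  min_gap <- as.integer(min_gap); max_gap <- as.integer(max_gap)
  if (is.na(min_gap) || is.na(max_gap) || min_gap < 0L || max_gap < 0L)
    stop("anchor gap bounds must be non-negative", call. = FALSE)
  if (min_gap > max_gap)
    stop("min_gap exceeds max_gap", call. = FALSE)
  rc <- as_residue_class(anchor_class)
  pre <- list(motif_element(rc, role = role))
  if (max_gap > 0L)
    pre <- c(pre, list(motif_element(residue_class(wildcard = TRUE),
                                     min_gap, max_gap)))
  motif(c(pre, m$elements), name = m$name)
}
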