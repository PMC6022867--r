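# Motif model: elements, motifs, parsing and canonical serialization ----

MOTIF_ROLES <- c("purine_binding", "substrate_specificity",
                 "hydrophobic_pocket", "transition_state",
                 "metal_binding", "anchor", "none")

#' Construct a motif element
#'
#' One position-group of a motif: either a residue-class element (exactly one
#' residue drawn from the class) or a bounded wildcard gap `X{min,max}`.
#' Functional roles record what the residue does at the catalytic centre
#' (hydrogen bonding with the purine moiety, substrate specificity,
#' transition-state stabilization, metal-ion binding, the upstream
#' pyrophosphate-binding anchor) and are preserved by all derivation
#' operators.
#'
#' @param residue_class A [residue_class()] object (or a string such as
#'   `"[DE]"` or `"X"`).
#' @param min_repeat,max_repeat Repeat bounds. Non-wildcard elements must
#'   have `min_repeat = max_repeat = 1`.
#' @param role One of `"purine_binding"`, `"substrate_specificity"`,
#'   `"hydrophobic_pocket"`, `"transition_state"`, `"metal_binding"`,
#'   `"anchor"`, `"none"`.
#' @return An `acscan_motif_element`.
#' @export
motif_element <- function(residue_class, min_repeat = 1L, max_repeat = 1L,
                          role = "none") {
  rc <- as_residue_class(residue_class)
  min_repeat <- as.integer(min_repeat)
  max_repeat <- as.integer(max_repeat)
  role <- match.arg(role, MOTIF_ROLES)
  if (is.na(min_repeat) || is.na(max_repeat) || min_repeat < 0L)
    stop("repeat bounds must be non-negative integers", call. = FALSE)
  if (max_repeat < 1L)
    stop("max_repeat must be positive", call. = FALSE)
  if (min_repeat > max_repeat)
    stop("min_repeat exceeds max_repeat", call. = FALSE)
  if (!rc$is_wildcard && (min_repeat != 1L || max_repeat != 1L))
    stop("non-wildcard elements must have min_repeat = max_repeat = 1",
         call. = FALSE)
  el <- list(residue_class = rc, min_repeat = min_repeat,
             max_repeat = max_repeat, role = role)
  class(el) <- "acscan_motif_element"
  el
}

is_gap_element <- function(el) el$residue_class$is_wildcard

#' Construct a motif
#'
#' An ordered list of [motif_element()]s. The element list is canonicalized
#' on construction: adjacent wildcard gaps merge (their repeat bounds add),
#' so two motifs describing the same pattern compare equal. Spans are
#' derived, never stored independently: `min_span`/`max_span` are the sums
#' of element repeat bounds.
#'
#' @param elements List of motif elements.
#' @param name Motif name (used in reports).
#' @return An `acscan_motif` with fields `name`, `elements`, `min_span`,
#'   `max_span`.
#' @seealso [parse_motif()], [motif_to_string()]
#' @export
motif <- function(elements, name = "motif") {
  stopifnot(is.list(elements), length(elements) > 0L)
  ok <- vapply(elements, inherits, logical(1), "acscan_motif_element")
  if (!all(ok)) stop("all elements must be motif elements", call. = FALSE)
  elements <- merge_adjacent_gaps(elements)
  roles <- vapply(elements, function(e) e$role, character(1))
  dup <- roles[roles != "none"][duplicated(roles[roles != "none"])]
  if (length(dup) > 0L)
    stop("duplicate functional role(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  m <- list(
    name     = as.character(name),
    elements = elements,
    min_span = sum(vapply(elements, function(e) e$min_repeat, integer(1))),
    max_span = sum(vapply(elements, function(e) e$max_repeat, integer(1)))
  )
  class(m) <- "acscan_motif"
  m
}

is_motif <- function(x) inherits(x, "acscan_motif")

merge_adjacent_gaps <- function(elements) {
  out <- list()
  for (el in elements) {
    n <- length(out)
    if (n > 0L && is_gap_element(el) && is_gap_element(out[[n]]) &&
        el$role == "none" && out[[n]]$role == "none") {
      out[[n]] <- motif_element(residue_class(wildcard = TRUE),
                                out[[n]]$min_repeat + el$min_repeat,
                                out[[n]]$max_repeat + el$max_repeat)
    } else {
      out[[n + 1L]] <- el
    }
  }
  out
}

#' @export
print.acscan_motif <- function(x, ...) {
  cat("<motif> ", x$name, ": ", motif_to_string(x),
      "  (span ", x$min_span,
      if (x$max_span != x$min_span) paste0("-", x$max_span), " aa, ",
      length(x$elements), " elements)\n", sep = "")
  roles <- vapply(x$elements, function(e) e$role, character(1))
  if (any(roles != "none")) {
    ann <- paste0(which(roles != "none"), ":", roles[roles != "none"])
    cat("  roles (element index): ", paste(ann, collapse = ", "), "\n",
        sep = "")
  }
  invisible(x)
}

# Parsing ---------------------------------------------------------------

#' Parse a bracket-syntax motif pattern
#'
#' Accepts the PROSITE-like syntax used for cyclase catalytic-centre motifs:
#' bracket alternations `[RKS]`, bare upper-case residues (`R`), the
#' wildcard `X`, fixed gaps `X{9}` and bounded variable gaps `X{1,3}`.
#'
#' @param pattern Pattern string, e.g.
#'   `"[RKS][YFW][DE][VIL]X{9}[KR]X{1,3}[DE]"`.
#' @param name Name for the resulting motif.
#' @return An [motif()] object.
#' @examples
#' m <- parse_motif("[RKS][YFW][DE][VIL]X{9}[KR]X{1,3}[DE]", name = "ac_core")
#' m$min_span  # 16
#' m$max_span  # 18
#' @export
parse_motif <- function(pattern, name = "motif") {
  stopifnot(is.character(pattern), length(pattern) == 1L)
  chars <- strsplit(pattern, "")[[1]]
  n <- length(chars)
  if (n == 0L) stop("empty motif pattern", call. = FALSE)
  elements <- list()
  i <- 1L
  perr <- function(msg, at) {
    stop(sprintf("motif parse error at offset %d ('%s'): %s",
                 at, substr(pattern, at, min(at + 9L, n)), msg),
         call. = FALSE)
  }
  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i + 1L
      while (j <= n && chars[j] != "]") j <- j + 1L
      if (j > n) perr("unterminated '['", i)
      body <- chars[seq.int(i + 1L, length.out = j - i - 1L)]
      if (length(body) == 0L) perr("empty residue class", i)
      bad <- setdiff(body, STANDARD_AA)
      if (length(bad) > 0L)
        perr(paste0("invalid residue code(s): ", paste(bad, collapse = ",")), i)
      elements[[length(elements) + 1L]] <- motif_element(residue_class(body))
      i <- j + 1L
    } else if (ch == "X") {
      if (i < n && chars[i + 1L] == "{") {
        j <- i + 2L
        while (j <= n && chars[j] != "}") j <- j + 1L
        if (j > n) perr("unterminated '{'", i)
        body <- paste(chars[seq.int(i + 2L, length.out = j - i - 2L)],
                      collapse = "")
        if (grepl("^[0-9]+$", body)) {
          lo <- hi <- as.integer(body)
        } else if (grepl("^[0-9]+,[0-9]+$", body)) {
          parts <- as.integer(strsplit(body, ",")[[1]])
          lo <- parts[1]; hi <- parts[2]
        } else perr("malformed repeat specifier", i)
        if (hi < 1L) perr("gap maximum must be >= 1", i)
        if (lo > hi) perr("gap minimum exceeds maximum", i)
        elements[[length(elements) + 1L]] <-
          motif_element(residue_class(wildcard = TRUE), lo, hi)
        i <- j + 1L
      } else {
        elements[[length(elements) + 1L]] <-
          motif_element(residue_class(wildcard = TRUE), 1L, 1L)
        i <- i + 1L
      }
    } else if (ch %in% STANDARD_AA) {
      elements[[length(elements) + 1L]] <- motif_element(residue_class(ch))
      i <- i + 1L
    } else {
      perr("unexpected character", i)
    }
  }
  motif(elements, name = name)
}

#' Serialize a motif to its canonical bracket-syntax string
#'
#' Canonical form: residues inside brackets in alphabetical order,
#' single-residue classes written bare, `X` for a single wildcard position,
#' `X{n}` for fixed gaps with `n > 1`, `X{m,n}` for variable gaps.
#' `parse_motif(motif_to_string(m))` reproduces `m` up to roles and name.
#'
#' @param m A motif.
#' @return Pattern string.
#' @export
motif_to_string <- function(m) {
  stopifnot(is_motif(m))
  paste(vapply(m$elements, format_element, character(1)), collapse = "")
}

format_element <- function(el) {
  cls <- format(el$residue_class)
  if (!is_gap_element(el)) return(cls)
  if (el$min_repeat == el$max_repeat) {
    if (el$min_repeat == 1L) "X" else sprintf("X{%d}", el$min_repeat)
  } else {
    sprintf("X{%d,%d}", el$min_repeat, el$max_repeat)
  }
}

#' Test two motifs for structural equality
#'
#' Compares canonicalized element lists (classes, repeat bounds and roles);
#' names are ignored.
#'
#' @param a,b Motifs.
#' @return Logical.
#' @export
motif_equal <- function(a, b) {
  stopifnot(is_motif(a), is_motif(b))
  if (length(a$elements) != length(b$elements)) return(FALSE)
  for (k in seq_along(a$elements)) {
    ea <- a$elements[[k]]; eb <- b$elements[[k]]
    if (ea$residue_class$is_wildcard != eb$residue_class$is_wildcard)
      return(FALSE)
    if (!identical(ea$residue_class$allowed, eb$residue_class$allowed))
      return(FALSE)
    if (ea$min_repeat != eb$min_repeat || ea$max_repeat != eb$max_repeat)
      return(FALSE)
    if (!identical(ea$role, eb$role)) return(FALSE)
  }
  TRUE
}

# Expanded-position bookkeeping ------------------------------------------
#
# "Motif positions" count residues over the minimal instantiation of the
# motif: element k occupies expanded positions
# [1 + sum(min_repeat of earlier elements), ... + min_repeat(k)].
# Class elements occupy exactly one expanded position.

element_expanded_starts <- function(m) {
  mins <- vapply(m$elements, function(e) e$min_repeat, integer(1))
  cumsum(c(1L, mins))[seq_along(mins)]
}

#' Expanded motif position of an element
#'
#' Returns the 1-based position of element `element_index` when the motif is
#' written out at minimal gap lengths (the numbering used to say, e.g., that
#' the transition-state residue of the core cyclase motif sits at
#' position 14).
#'
#' @param m A motif.
#' @param element_index Index into the element list.
#' @return Integer expanded position (start position for gaps).
#' @export
expanded_position <- function(m, element_index) {
  stopifnot(is_motif(m))
  element_index <- as.integer(element_index)
  if (element_index < 1L || element_index > length(m$elements))
    stop("element index out of range", call. = FALSE)
  element_expanded_starts(m)[element_index]
}

#' Expanded position of the element carrying a given functional role
#'
#' @param m A motif.
#' @param role Role name, e.g. `"transition_state"`.
#' @return Integer expanded position, or `NA` if no element has the role.
#' @export
role_position <- function(m, role) {
  role <- match.arg(role, MOTIF_ROLES)
  roles <- vapply(m$elements, function(e) e$role, character(1))
  k <- which(roles == role)
  if (length(k) == 0L) return(NA_integer_)
  expanded_position(m, k[1])
}
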