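# Preset catalogue --------------------------------------------------------
#
# The published search patterns for plant nucleotide-cyclase catalytic
# centres. gc_core is the guanylate-cyclase parent; the others derive from
# it (substrate-specificity substitution, position-5 constraint, upstream
# arginine anchor), except ac_kr15 which is stored verbatim: its printed
# pattern places an X{8} gap after [VIL] and doubles the [KR], and is not
# reachable from ac_core by a single well-defined insertion.

PRESET_PATTERNS <- c(
  gc_core         = "[RKS][YFW][CTGH][VIL]X{9}[KR]X{1,3}[DE]",
  ac_core         = "[RKS][YFW][DE][VIL]X{9}[KR]X{1,3}[DE]",
  ac_anchored     = "[R]X{5,20}[RKS][YFW][DE][VIL]X{9}[KR]X{1,3}[DE]",
  ac_fv5          = "[RKS][YFW][DE][VIL][FV]X{8}[KR]X{1,3}[DE]",
  ac_kr15         = "[R]X{5,20}[RKS][YFW][DE][VIL]X{8}[KR][KR]X{0,2}[DE]",
  functional_core = "[RKS]X[DE]X{10}[KR]X{1,3}[DE]"
)

# Functional roles keyed by expanded motif position of the 14-aa core:
# 1 purine binding, 3 substrate specificity, 4 hydrophobic pocket,
# 14 transition state, terminal [DE] metal binding. Anchored presets carry
# the upstream [R] with the anchor role.
assign_core_roles <- function(m) {
  roles <- vapply(m$elements, function(e) e$role, character(1))
  cls   <- !vapply(m$elements, is_gap_element, logical(1))
  starts <- element_expanded_starts(m)
  offset <- 0L
  if (cls[1] && identical(m$elements[[1]]$residue_class$allowed, "R")) {
    roles[1] <- "anchor"
    # core numbering restarts after the anchor and its gap
    offset <- starts[3] - 1L
  }
  pos <- starts - offset
  n <- length(roles)
  for (k in seq_len(n)) {
    if (!cls[k] || roles[k] != "none") next
    if (pos[k] == 1L) roles[k] <- "purine_binding"
    else if (pos[k] == 3L) roles[k] <- "substrate_specificity"
    else if (pos[k] == 4L) roles[k] <- "hydrophobic_pocket"
    else if (pos[k] == 14L && roles[k] == "none" &&
             !"transition_state" %in% roles) roles[k] <- "transition_state"
    else if (k == n) roles[k] <- "metal_binding"
  }
  elements <- m$elements
  for (k in seq_len(n)) {
    el <- elements[[k]]
    elements[[k]] <- motif_element(el$residue_class, el$min_repeat,
                                   el$max_repeat, role = roles[k])
  }
  motif(elements, name = m$name)
}

#' Retrieve a named preset motif
#'
#' The preset catalogue covers the published cyclase-centre search family:
#' \describe{
#'   \item{`gc_core`}{`[RKS][YFW][CTGH][VIL]X{9}[KR]X{1,3}[DE]` — the
#'     guanylate-cyclase parent motif.}
#'   \item{`ac_core`}{`[RKS][YFW][DE][VIL]X{9}[KR]X{1,3}[DE]` — the
#'     14-position adenylate-cyclase motif (substrate-specificity class
#'     swapped to `[DE]`).}
#'   \item{`ac_anchored`}{`ac_core` with an upstream `[R]X{5,20}`
#'     pyrophosphate-binding anchor.}
#'   \item{`ac_fv5`}{`ac_core` with position 5 constrained to `[FV]`.}
#'   \item{`ac_kr15`}{`[R]X{5,20}[RKS][YFW][DE][VIL]X{8}[KR][KR]X{0,2}[DE]`,
#'     the doubled transition-state variant, stored verbatim as printed.}
#'   \item{`functional_core`}{`[RKS]X[DE]X{10}[KR]X{1,3}[DE]` — only the
#'     functionally assigned residues, the most permissive of the family.}
#' }
#'
#' @param name Preset name.
#' @return A motif with functional-role annotations.
#' @examples
#' motif_preset("ac_core")
#' @export
motif_preset <- function(name) {
  if (length(name) != 1L || !name %in% names(PRESET_PATTERNS))
    stop("unknown preset '", paste(name, collapse = ","),
         "'; valid presets: ", paste(names(PRESET_PATTERNS), collapse = ", "),
         call. = FALSE)
  assign_core_roles(parse_motif(PRESET_PATTERNS[[name]], name = name))
}

#' List all preset motifs
#'
#' @return Data frame with columns `name`, `pattern` (canonical form),
#'   `min_span`, `max_span`, `n_elements`, `roles` (semicolon-separated
#'   `position:role` annotations), in stable catalogue order.
#' @export
preset_catalogue <- function() {
  rows <- lapply(names(PRESET_PATTERNS), function(nm) {
    m <- motif_preset(nm)
    roles <- vapply(m$elements, function(e) e$role, character(1))
    ann <- which(roles != "none")
    data.frame(
      name = nm,
      pattern = motif_to_string(m),
      min_span = m$min_span,
      max_span = m$max_span,
      n_elements = length(m$elements),
      roles = paste(sprintf("%d:%s", element_expanded_starts(m)[ann],
                            roles[ann]), collapse = ";"),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Export or re-import the preset catalogue as JSON
#'
#' The catalogue (name, pattern, role map and a provenance note) round-trips
#' through JSON so that external pipelines can consume the motif family
#' without parsing R objects.
#'
#' @param path File path for the JSON catalogue.
#' @return `export_presets_json` returns `path` invisibly;
#'   `import_presets_json` returns a named list of motifs.
#' @export
export_presets_json <- function(path) {
  cat_df <- preset_catalogue()
  entries <- lapply(seq_len(nrow(cat_df)), function(i) {
    list(name = cat_df$name[i],
         pattern = cat_df$pattern[i],
         roles = cat_df$roles[i],
         provenance = "cyclase catalytic-centre search family")
  })
  jsonlite::write_json(entries, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname export_presets_json
#' @export
import_presets_json <- function(path) {
  entries <- jsonlite::read_json(path, simplifyVector = FALSE)
  out <- lapply(entries, function(e) {
    m <- parse_motif(e$pattern, name = e$name)
    if (!is.null(e$roles) && nzchar(e$roles)) {
      for (tok in strsplit(e$roles, ";")[[1]]) {
        kv <- strsplit(tok, ":")[[1]]
        pos <- as.integer(kv[1])
        starts <- element_expanded_starts(m)
        k <- which(starts == pos &
                   !vapply(m$elements, is_gap_element, logical(1)))
        if (length(k) == 1L) {
          el <- m$elements[[k]]
          m$elements[[k]] <- motif_element(el$residue_class, role = kv[2])
        }
      }
      m <- motif(m$elements, name = e$name)
    }
    m
  })
  names(out) <- vapply(out, function(m) m$name, character(1))
  out
}
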