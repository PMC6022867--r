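# Synthetic proteomes and expression matrices ----------------------------
#
# Ground-truth generators for validating the scanner and the co-expression
# ranker: i.i.d. background proteomes with motif instantiations planted at
# known positions, and expression matrices in which target genes carry
# designed Pearson correlations with a query gene and designed fold
# inductions between conditions.

# Run expr with a private RNG state; the caller's RNG is untouched.
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Generate a synthetic background proteome
#'
#' Residues are drawn i.i.d. from `composition`; record lengths follow a
#' shifted geometric distribution with minimum 50 aa and the requested mean
#' (any positive-support length model would do; the geometric is simply
#' stated and easy to reason about). Output is bit-reproducible given
#' `seed`.
#'
#' @param n_records Number of records (0 allowed).
#' @param mean_length Target mean record length in aa; means below the
#'   50-aa floor produce constant length 50.
#' @param composition A [background_model()] (or a named frequency vector).
#' @param seed Integer seed.
#' @return Record data frame (`id`, `description`, `residues`) in the
#'   layout of [read_protein_fasta()]; ids are `SYN0001`, `SYN0002`, ...
#' @export
generate_proteome <- function(n_records, mean_length = 400,
                              composition = background_uniform(),
                              seed = 1L) {
  n_records <- as.integer(n_records)
  if (is.na(n_records) || n_records < 0L)
    stop("n_records must be a non-negative integer", call. = FALSE)
  if (!inherits(composition, "acscan_background"))
    composition <- background_model(composition)
  if (n_records == 0L)
    return(data.frame(id = character(), description = character(),
                      residues = character(), stringsAsFactors = FALSE))
  freqs <- composition$composition
  alphabet <- names(freqs)[freqs > 0]
  probs <- freqs[freqs > 0]
  with_local_seed(seed, {
    extra_mean <- max(mean_length - 50, 0)
    lens <- if (extra_mean == 0) rep(50L, n_records)
            else 50L + stats::rgeom(n_records, prob = 1 / (extra_mean + 1))
    residues <- vapply(lens, function(L)
      paste(sample(alphabet, L, replace = TRUE, prob = probs), collapse = ""),
      character(1))
    ids <- sprintf("SYN%04d", seq_len(n_records))
    data.frame(id = ids,
               description = paste(ids, "synthetic background protein"),
               residues = residues, stringsAsFactors = FALSE)
  })
}

#' Write protein records to FASTA
#'
#' Deterministic writer (60-column wrap) so fixed-seed simulations produce
#' byte-identical files.
#'
#' @param records Record data frame (`id`, `description`, `residues`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_protein_fasta <- function(records, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    desc <- records$description[i]
    header <- if (nzchar(desc) && !identical(desc, records$id[i]))
      desc else records$id[i]
    writeLines(paste0(">", header), con)
    s <- records$residues[i]
    starts <- seq(1L, nchar(s), by = 60L)
    writeLines(substring(s, starts, pmin(starts + 59L, nchar(s))), con)
  }
  invisible(path)
}

#' Sample one concrete instantiation of a motif
#'
#' Residue-class elements draw uniformly from their allowed set; gaps draw
#' a uniform length within their bounds and uniform standard residues. The
#' result is always matched by the motif at position 1.
#'
#' @param m A motif.
#' @param seed Integer seed.
#' @return A single string of length in `[min_span, max_span]`.
#' @export
sample_instantiation <- function(m, seed = 1L) {
  stopifnot(is_motif(m))
  with_local_seed(seed, sample_instantiation_impl(m))
}

sample_instantiation_impl <- function(m) {
  parts <- vapply(m$elements, function(e) {
    if (is_gap_element(e)) {
      len <- if (e$min_repeat == e$max_repeat) e$min_repeat
             else sample(seq.int(e$min_repeat, e$max_repeat), 1L)
      if (len == 0L) "" else
        paste(sample(STANDARD_AA, len, replace = TRUE), collapse = "")
    } else {
      allowed <- e$residue_class$allowed
      if (length(allowed) == 1L) allowed else sample(allowed, 1L)
    }
  }, character(1))
  paste(parts, collapse = "")
}

#' Plant motif instantiations into background records
#'
#' Inserts freshly sampled instantiations by substitution (overwriting the
#' background residues, so record lengths and downstream coordinates are
#' unchanged) at uniformly chosen non-overlapping positions. Placement
#' draws a record uniformly among those with remaining capacity, then a
#' start uniformly among its non-overlapping offsets.
#'
#' @param records Record data frame (modified copy is returned).
#' @param m A motif.
#' @param n_insertions Number of instances to plant.
#' @param seed Integer seed.
#' @param max_per_record Cap on instances per record (default unlimited;
#'   set to 1 to force distinct records).
#' @return List with `records` (modified) and `truth`, a data frame
#'   `record_id`, `start`, `end`, `motif_name`, `instantiation`.
#' @export
plant_motifs <- function(records, m, n_insertions, seed = 1L,
                         max_per_record = Inf) {
  stopifnot(is_motif(m), is.data.frame(records))
  n_insertions <- as.integer(n_insertions)
  if (n_insertions == 0L)
    return(list(records = records,
                truth = data.frame(record_id = character(), start = integer(),
                                   end = integer(), motif_name = character(),
                                   instantiation = character(),
                                   stringsAsFactors = FALSE)))
  with_local_seed(seed, {
    occupied <- vector("list", nrow(records))  # list of (start,end) matrices
    counts <- integer(nrow(records))
    truth <- vector("list", n_insertions)
    for (ins in seq_len(n_insertions)) {
      inst <- sample_instantiation_impl(m)
      L <- nchar(inst)
      lens <- nchar(records$residues)
      candidates <- which(lens >= L & counts < max_per_record)
      placed <- FALSE
      # uniform record then uniform free offset; records that turn out to be
      # fully occupied are removed and redrawn
      while (length(candidates) > 0L) {
        ri <- if (length(candidates) == 1L) candidates else
          sample(candidates, 1L)
        free <- free_offsets(lens[ri], L, occupied[[ri]])
        if (length(free) == 0L) {
          candidates <- setdiff(candidates, ri)
          next
        }
        start <- if (length(free) == 1L) free else sample(free, 1L)
        substr(records$residues[ri], start, start + L - 1L) <- inst
        occupied[[ri]] <- rbind(occupied[[ri]], c(start, start + L - 1L))
        counts[ri] <- counts[ri] + 1L
        truth[[ins]] <- data.frame(record_id = records$id[ri], start = start,
                                   end = start + L - 1L, motif_name = m$name,
                                   instantiation = inst,
                                   stringsAsFactors = FALSE)
        placed <- TRUE
        break
      }
      if (!placed)
        stop("cannot place insertion ", ins,
             ": no record has free capacity", call. = FALSE)
    }
    list(records = records, truth = do.call(rbind, truth))
  })
}

free_offsets <- function(record_len, inst_len, occupied) {
  starts <- seq_len(record_len - inst_len + 1L)
  if (is.null(occupied)) return(starts)
  ok <- rep(TRUE, length(starts))
  for (r in seq_len(nrow(occupied))) {
    # overlap iff start <= occ_end and start + inst_len - 1 >= occ_start
    ok <- ok & !(starts <= occupied[r, 2] &
                   starts + inst_len - 1L >= occupied[r, 1])
  }
  starts[ok]
}

#' Write a planted-truth table to TSV
#'
#' @param truth Truth data frame from [plant_motifs()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth_tsv <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Generate an expression matrix with designed correlation structure
#'
#' A latent standard-normal signal per sample plays the role of the query
#' gene's profile. Each target gene with designed correlation `r` is
#' `r * signal + sqrt(1 - r^2) * noise`, where the noise vector is
#' orthogonalized against the realized signal (empirical-covariance
#' construction), so the sample correlation with the query equals `r`
#' exactly at any sample size; remaining genes are independent noise. All latent values are mapped affinely to positive
#' microarray-style intensities (`base_mean + noise_sd * value`) — an
#' affine map preserves Pearson correlations exactly. Designed fold
#' inductions then multiply a gene's intensities in the samples of one
#' condition.
#'
#' @param n_genes Number of genes beside the query gene.
#' @param n_samples Number of samples.
#' @param query_r_targets Numeric vector of designed correlations in
#'   (-1, 1); names are gene ids (unnamed values are assigned to
#'   `gene_0001`, `gene_0002`, ...).
#' @param inductions Optional data frame (`gene`, `condition`, `fold`) of
#'   multiplicative inductions, `fold > 0`.
#' @param groups Character vector of length `n_samples` of condition
#'   labels (default: all `"control"`).
#' @param noise_sd Intensity scale: standard deviation of each gene's
#'   intensities around `base_mean`.
#' @param base_mean Baseline intensity; must be comfortably larger than
#'   `noise_sd` so intensities stay positive.
#' @param seed Integer seed.
#' @param query_gene Id of the query gene row.
#' @return List with `matrix` (an [expression_matrix()] including the
#'   query gene row) and `truth` (`query_gene`, `r_targets`,
#'   `inductions`).
#' @export
generate_expression <- function(n_genes, n_samples, query_r_targets = NULL,
                                inductions = NULL, groups = NULL,
                                noise_sd = 10, base_mean = 100, seed = 1L,
                                query_gene = "gene_query") {
  n_genes <- as.integer(n_genes); n_samples <- as.integer(n_samples)
  stopifnot(n_genes >= 1L, n_samples >= 3L)
  if (!is.null(query_r_targets)) {
    if (any(abs(query_r_targets) >= 1))
      stop("designed correlations must lie strictly inside (-1, 1)",
           call. = FALSE)
    if (length(query_r_targets) > n_genes)
      stop("more correlation targets than genes", call. = FALSE)
  }
  if (!is.null(inductions) && any(inductions$fold <= 0))
    stop("induction folds must be positive", call. = FALSE)
  gene_ids <- sprintf("gene_%04d", seq_len(n_genes))
  if (!is.null(query_r_targets)) {
    if (is.null(names(query_r_targets)))
      names(query_r_targets) <- gene_ids[seq_along(query_r_targets)]
    # custom target names take over successive default gene ids
    novel <- setdiff(names(query_r_targets), gene_ids)
    free <- setdiff(gene_ids, names(query_r_targets))
    if (length(novel) > length(free))
      stop("more correlation targets than genes", call. = FALSE)
    gene_ids[match(free[seq_along(novel)], gene_ids)] <- novel
  }
  if (is.null(groups)) groups <- rep("control", n_samples)
  stopifnot(length(groups) == n_samples)
  sample_ids <- sprintf("S%03d", seq_len(n_samples))

  with_local_seed(seed, {
    signal <- stats::rnorm(n_samples)
    signal <- as.numeric(scale(signal))  # standardized latent
    latent <- matrix(stats::rnorm(n_genes * n_samples), nrow = n_genes)
    for (g in names(query_r_targets)) {
      r <- query_r_targets[[g]]
      i <- match(g, gene_ids)
      if (is.na(i)) stop("correlation target for unknown gene '", g, "'",
                         call. = FALSE)
      eps <- latent[i, ]
      # orthogonalize the noise against the signal (empirical-covariance
      # construction) so the designed r is exact at any sample size
      eps <- eps - signal * sum(eps * signal) / sum(signal^2)
      eps <- as.numeric(scale(eps))
      latent[i, ] <- r * signal + sqrt(1 - r^2) * eps
    }
    vals <- rbind(signal, latent)
    rownames(vals) <- c(query_gene, gene_ids)
    intens <- base_mean + noise_sd * vals
    intens <- pmax(intens, base_mean * 1e-3)  # guard; ~10 sd event
    colnames(intens) <- sample_ids
    if (!is.null(inductions)) {
      for (j in seq_len(nrow(inductions))) {
        g <- as.character(inductions$gene[j])
        cond <- as.character(inductions$condition[j])
        if (!g %in% rownames(intens))
          stop("induction for unknown gene '", g, "'", call. = FALSE)
        cols <- which(groups == cond)
        if (length(cols) == 0L)
          stop("induction condition '", cond, "' has no samples",
               call. = FALSE)
        intens[g, cols] <- intens[g, cols] * inductions$fold[j]
      }
    }
    em <- expression_matrix(intens,
                            group_labels = stats::setNames(groups, sample_ids))
    list(matrix = em,
         truth = list(query_gene = query_gene,
                      r_targets = query_r_targets,
                      inductions = inductions))
  })
}
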