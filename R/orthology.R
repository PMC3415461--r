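# all-vs-all global protein alignment stats for one query against a proteome;
# vectorised through the alignment engine (one call per query protein)
ortho_stats_one <- function(seq_a, set_b, len_b, scoring) {
  aln <- Biostrings::pairwiseAlignment(
    pattern = set_b, subject = Biostrings::AAString(seq_a), type = "global",
    substitutionMatrix = scoring$substitution_matrix,
    gapOpening = -scoring$gap_open, gapExtension = -scoring$gap_extend
  )
  n_cols <- Biostrings::nchar(aln)
  n_ident <- Biostrings::nmatch(aln)
  len_a <- nchar(seq_a)
  n_m <- len_a + len_b - n_cols  # gap-free columns of a global alignment
  tibble(pct_identity = 100 * n_ident / n_cols,
         pct_aligned = 100 * n_m / pmax(len_a, len_b))
}

shared_kmer_matrix <- function(seqs_a, seqs_b, k) {
  kmers <- function(s) {
    n <- nchar(s)
    if (n < k) return(character(0))
    unique(substring(s, 1:(n - k + 1), k:n))
  }
  ka <- purrr::map(seqs_a, kmers)
  kb <- purrr::map(seqs_b, kmers)
  outer(seq_along(ka), seq_along(kb),
        Vectorize(function(i, j) length(intersect(ka[[i]], kb[[j]])) > 0))
}

#' Find orthologous gene pairs by reciprocal protein alignment
#'
#' Performs all-vs-all global protein alignments between the two proteomes,
#' keeps pairs passing both the percent-identity and percent-aligned cutoffs
#' (50/50 by default) as homolog candidates, and derives a one-to-one
#' reciprocal-best-hit set from them (best hit by percent identity; ties by
#' higher percent aligned, then lexicographic partner id). Non-best passing
#' pairs are reported with `reciprocal_best = FALSE`.
#'
#' @param proteome_a,proteome_b tibbles with `gene_id` and `protein` columns;
#'   ids must be unique within each proteome.
#' @param params a [pipeline_params()] list (uses `ortholog_min_identity`,
#'   `ortholog_min_aligned`).
#' @param scoring protein scoring scheme; default [aa_scoring()].
#' @param prefilter when `TRUE`, only pairs sharing at least one exact
#'   `prefilter_k`-mer are aligned (a speed device; at the default thresholds
#'   passing pairs always share k-mers at desk scale).
#' @param prefilter_k k-mer length for the prefilter.
#' @return A tibble `gene_a`, `gene_b`, `pct_identity`, `pct_aligned`,
#'   `reciprocal_best`, sorted by `gene_a`, `gene_b`.
#' @export
find_orthologs <- function(proteome_a, proteome_b, params = pipeline_params(),
                           scoring = aa_scoring(), prefilter = FALSE,
                           prefilter_k = 4L) {
  if (nrow(proteome_a) == 0 || nrow(proteome_b) == 0) abort("empty proteome")
  if (anyDuplicated(proteome_a$gene_id) || anyDuplicated(proteome_b$gene_id)) {
    abort("duplicate gene ids in proteome")
  }
  if (any(nchar(c(proteome_a$protein, proteome_b$protein)) == 0)) {
    abort("empty protein sequence(s)")
  }
  keep <- if (prefilter) {
    shared_kmer_matrix(proteome_a$protein, proteome_b$protein, prefilter_k)
  } else {
    matrix(TRUE, nrow(proteome_a), nrow(proteome_b))
  }
  len_b <- nchar(proteome_b$protein)
  rows <- purrr::map(seq_len(nrow(proteome_a)), function(i) {
    j <- which(keep[i, ])
    if (length(j) == 0) return(NULL)
    st <- ortho_stats_one(proteome_a$protein[i],
                          Biostrings::AAStringSet(proteome_b$protein[j]),
                          len_b[j], scoring)
    st |> mutate(gene_a = proteome_a$gene_id[i], gene_b = proteome_b$gene_id[j])
  })
  all_pairs <- bind_rows(rows)
  cand <- all_pairs |>
    filter(.data$pct_identity >= params$ortholog_min_identity,
           .data$pct_aligned >= params$ortholog_min_aligned)
  if (nrow(cand) == 0) {
    return(tibble(gene_a = character(), gene_b = character(),
                  pct_identity = numeric(), pct_aligned = numeric(),
                  reciprocal_best = logical()))
  }
  best_a <- cand |>
    group_by(.data$gene_a) |>
    arrange(desc(.data$pct_identity), desc(.data$pct_aligned), .data$gene_b,
            .by_group = TRUE) |>
    slice(1) |>
    ungroup()
  best_b <- cand |>
    group_by(.data$gene_b) |>
    arrange(desc(.data$pct_identity), desc(.data$pct_aligned), .data$gene_a,
            .by_group = TRUE) |>
    slice(1) |>
    ungroup()
  rbh <- inner_join(best_a |> select("gene_a", "gene_b"),
                    best_b |> select("gene_a", "gene_b"),
                    by = c("gene_a", "gene_b"))
  cand |>
    left_join(rbh |> mutate(reciprocal_best = TRUE), by = c("gene_a", "gene_b")) |>
    mutate(reciprocal_best = !is.na(.data$reciprocal_best)) |>
    select("gene_a", "gene_b", "pct_identity", "pct_aligned", "reciprocal_best") |>
    arrange(.data$gene_a, .data$gene_b)
}

#' Nearest ortholog-bearing genes flanking a genomic interval
#'
#' Scans outward from the interval on its contig (strand-agnostic) and
#' returns the closest gene on each side that has an ortholog; a side may be
#' absent near contig ends.
#'
#' @param genes gene tibble for the species containing the interval.
#' @param contig_id contig of the interval.
#' @param start,end 1-based inclusive interval (a point if `end == start`).
#' @param ortholog_ids character vector of gene ids that have orthologs.
#' @param genome optional genome tibble for bounds checking.
#' @return A one-row tibble `left_gene`, `right_gene` (NA when absent).
#' @export
ortholog_neighbors <- function(genes, contig_id, start, end = start,
                               ortholog_ids, genome = NULL) {
  if (!is.null(genome)) {
    len <- contig_length(genome, contig_id)
    if (start < 1 || end > len) {
      abort(sprintf("interval %d..%d outside contig '%s'", start, end, contig_id))
    }
  }
  g <- genes |>
    filter(.data$contig_id == !!contig_id, .data$gene_id %in% ortholog_ids)
  left <- g |> filter(.data$end < !!start) |> arrange(desc(.data$end)) |> slice(1)
  right <- g |> filter(.data$start > !!end) |> arrange(.data$start) |> slice(1)
  tibble(left_gene = if (nrow(left)) left$gene_id else NA_character_,
         right_gene = if (nrow(right)) right$gene_id else NA_character_)
}

#' Write an ortholog table as TSV
#'
#' @param orthologs tibble from [find_orthologs()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ortholog_table <- function(orthologs, path) {
  readr::write_tsv(orthologs, path)
  invisible(path)
}
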