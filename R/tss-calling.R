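#' Reconcile two replicate 5'-end count tracks
#'
#' A position is a TSS candidate only when it carries at least
#' `min_read_count` reads in *both* biological replicates; replicate counts
#' are then combined (sum by default).
#'
#' @param track1,track2 count-track tibbles (one replicate each).
#' @param params a [pipeline_params()] list.
#' @return A tibble of candidates: `contig_id`, `position`, `strand`,
#'   `count_rep1`, `count_rep2`, `combined_count`.
#' @export
reconcile_replicates <- function(track1, track2, params = pipeline_params()) {
  c1 <- unique(track1$contig_id); c2 <- unique(track2$contig_id)
  if (length(c1) > 0 && length(c2) > 0 && length(intersect(c1, c2)) == 0) {
    abort("replicate tracks share no contig: are these from different genomes?")
  }
  out <- inner_join(
    track1 |> select("contig_id", "position", "strand", count_rep1 = "count"),
    track2 |> select("contig_id", "position", "strand", count_rep2 = "count"),
    by = c("contig_id", "position", "strand")
  ) |>
    filter(.data$count_rep1 >= params$min_read_count,
           .data$count_rep2 >= params$min_read_count)
  comb <- if (params$combine_replicates == "sum") {
    out$count_rep1 + out$count_rep2
  } else {
    (out$count_rep1 + out$count_rep2) / 2
  }
  out |>
    mutate(combined_count = comb) |>
    arrange(.data$contig_id, .data$strand, .data$position)
}

#' Suppress local noise around strong TSS candidates
#'
#' Greedy non-maximum suppression per contig and strand: candidates are
#' visited in decreasing `combined_count` (ties: lower coordinate first) and
#' retained only if no already-retained candidate lies closer than
#' `noise_window` nt. Two retained TSSs are therefore always >=
#' `noise_window` apart (a spacing of exactly `noise_window` is allowed).
#'
#' @param candidates candidate tibble from [reconcile_replicates()].
#' @param params a [pipeline_params()] list.
#' @return The retained candidates, sorted by contig, strand, position.
#' @export
suppress_local_noise <- function(candidates, params = pipeline_params()) {
  if (nrow(candidates) == 0) return(candidates)
  w <- params$noise_window
  one_group <- function(g) {
    g <- g |> arrange(desc(.data$combined_count), .data$position)
    kept <- numeric(0)
    keep_row <- logical(nrow(g))
    for (i in seq_len(nrow(g))) {
      p <- g$position[i]
      if (length(kept) == 0 || all(abs(p - kept) >= w)) {
        kept <- c(kept, p)
        keep_row[i] <- TRUE
      }
    }
    g[keep_row, ]
  }
  candidates |>
    group_by(.data$contig_id, .data$strand) |>
    dplyr::group_modify(~ one_group(.x)) |>
    ungroup() |>
    arrange(.data$contig_id, .data$strand, .data$position)
}

#' Assign TSSs to the nearest downstream gene
#'
#' A TSS is assigned to the same-contig, same-strand feature (ORF or sRNA)
#' whose translation start lies at or downstream of the TSS, at the minimum
#' distance, provided that distance does not exceed `max_tss_gene_dist`.
#' Intervening features are ignored, so a TSS may legitimately sit inside an
#' upstream gene's coding region. Distance 0 marks a leaderless transcript.
#' TSSs downstream of a gene's translation start are never assigned to it.
#'
#' @param tss tibble of retained TSSs (needs `contig_id`, `position`,
#'   `strand`, `combined_count`).
#' @param genes gene tibble.
#' @param params a [pipeline_params()] list.
#' @return `tss` with `gene_id`, `dist_to_start`, `leaderless` columns added
#'   (`NA` gene for unassigned TSSs).
#' @export
assign_to_genes <- function(tss, genes, params = pipeline_params()) {
  if (nrow(genes) == 0) abort("empty gene table")
  tst <- translation_start(genes)
  if (any(is.na(tst))) abort("gene(s) without resolvable translation start")
  gene_tbl <- genes |>
    mutate(tstart = tst) |>
    select("gene_id", "contig_id", "strand", "tstart") |>
    arrange(.data$gene_id)
  hits <- tss |>
    mutate(.tss_row = row_number()) |>
    inner_join(gene_tbl, by = c("contig_id", "strand"),
               relationship = "many-to-many") |>
    mutate(dist = ifelse(.data$strand == "+",
                         .data$tstart - .data$position,
                         .data$position - .data$tstart)) |>
    filter(.data$dist >= 0, .data$dist <= params$max_tss_gene_dist) |>
    group_by(.data$.tss_row) |>
    arrange(.data$dist, .data$gene_id, .by_group = TRUE) |>
    slice(1) |>
    ungroup() |>
    select(".tss_row", "gene_id", "dist")
  tss |>
    mutate(.tss_row = row_number()) |>
    left_join(hits, by = ".tss_row") |>
    mutate(dist_to_start = .data$dist,
           leaderless = !is.na(.data$dist) & .data$dist == 0) |>
    select(-".tss_row", -"dist")
}

#' Apply the multiple-TSS rule within each gene
#'
#' Within each gene's assigned TSS group, TSSs with `combined_count` at or
#' above `multi_tss_frac` of the group's strongest signal are retained in the
#' gene's TSS list (`retained_in_gene = TRUE`); weaker TSSs are flagged
#' sub-threshold but stay in the genome-wide table. The strongest retained
#' TSS per gene (ties: lower coordinate) is marked `is_primary`.
#'
#' @param tss assigned TSS tibble from [assign_to_genes()].
#' @param params a [pipeline_params()] list.
#' @return `tss` with `retained_in_gene` and `is_primary` columns
#'   (`NA`/`FALSE` for unassigned TSSs).
#' @export
call_multiple_tss <- function(tss, params = pipeline_params()) {
  tss |>
    group_by(.data$gene_id) |>
    mutate(
      retained_in_gene = if_else(
        is.na(.data$gene_id), NA,
        .data$combined_count >= params$multi_tss_frac * max(.data$combined_count)),
      .max_ret = if (any(.data$retained_in_gene %in% TRUE)) {
        max(.data$combined_count[.data$retained_in_gene %in% TRUE])
      } else NA_real_,
      .primary_pos = if (any(.data$retained_in_gene %in% TRUE)) {
        min(.data$position[.data$retained_in_gene %in% TRUE &
                             .data$combined_count == .data$.max_ret])
      } else NA_integer_,
      is_primary = !is.na(.data$gene_id) & .data$retained_in_gene %in% TRUE &
        .data$combined_count == .data$.max_ret &
        .data$position == .data$.primary_pos
    ) |>
    ungroup() |>
    select(-".max_ret", -".primary_pos")
}

#' Full TSS calling pipeline for one species
#'
#' Composes [reconcile_replicates()], [suppress_local_noise()],
#' [assign_to_genes()] and [call_multiple_tss()].
#'
#' @param track1,track2 replicate count-track tibbles.
#' @param genes gene tibble.
#' @param params a [pipeline_params()] list.
#' @return The annotated TSS tibble.
#' @export
call_tss <- function(track1, track2, genes, params = pipeline_params()) {
  reconcile_replicates(track1, track2, params) |>
    suppress_local_noise(params) |>
    assign_to_genes(genes, params) |>
    call_multiple_tss(params)
}

#' Number of retained TSSs per gene
#'
#' @param tss annotated TSS tibble from [call_tss()].
#' @return A tibble `gene_id`, `n_tss` for genes with at least one retained
#'   TSS.
#' @export
tss_per_gene <- function(tss) {
  tss |>
    filter(!is.na(.data$gene_id), .data$retained_in_gene %in% TRUE) |>
    dplyr::count(.data$gene_id, name = "n_tss")
}

#' Compare two TSS datasets with positional tolerance
#'
#' Each reference TSS is scored *exact* when some query TSS shares its contig,
#' strand, and position, else *within tolerance* when a strand-matched query
#' TSS lies within `tol` nt. Matching is not one-to-one.
#'
#' @param reference,query tibbles with `contig_id`, `position`, `strand`.
#' @param tol non-negative tolerance in nt.
#' @return A one-row tibble: `n_reference`, `n_exact`, `n_within_tol`,
#'   `frac_exact`, `frac_within_tol` (percent of the reference set).
#' @export
compare_tss_sets <- function(reference, query, tol = 3) {
  if (tol < 0) abort("tolerance must be >= 0")
  n_ref <- nrow(reference)
  if (n_ref == 0) {
    return(tibble(n_reference = 0L, n_exact = 0L, n_within_tol = 0L,
                  frac_exact = NA_real_, frac_within_tol = NA_real_))
  }
  qkey <- paste(query$contig_id, query$strand)
  status <- purrr::map_chr(seq_len(n_ref), function(i) {
    qs <- query$position[qkey == paste(reference$contig_id[i], reference$strand[i])]
    if (length(qs) == 0) return("none")
    d <- abs(qs - reference$position[i])
    if (any(d == 0)) "exact" else if (any(d <= tol)) "tol" else "none"
  })
  tibble(
    n_reference = n_ref,
    n_exact = sum(status == "exact"),
    n_within_tol = sum(status == "tol"),
    frac_exact = 100 * sum(status == "exact") / n_ref,
    frac_within_tol = 100 * sum(status == "tol") / n_ref
  )
}

#' Write a TSS table as TSV
#'
#' @param tss annotated TSS tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tss_table <- function(tss, path) {
  readr::write_tsv(tss, path)
  invisible(path)
}

#' Write TSSs as a BED6 track
#'
#' Score is the combined count capped at 1000; the name is the assigned gene
#' or `.` for unassigned TSSs.
#'
#' @param tss annotated TSS tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tss_bed <- function(tss, path) {
  bed <- tibble(
    chrom = tss$contig_id,
    start = tss$position - 1L,
    end = tss$position,
    name = dplyr::coalesce(tss$gene_id, "."),
    score = pmin(tss$combined_count, 1000),
    strand = tss$strand
  )
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}
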