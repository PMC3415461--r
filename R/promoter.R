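# strand-aware upstream window of length <= len ending just before tstart;
# seq is oriented 5'->3' toward the translation start. Returns the sequence,
# the number of available bases, and what is needed to map window coordinates
# back to genomic positions.
upstream_window <- function(genome, contig_id, tstart, strand, len) {
  clen <- contig_length(genome, contig_id)
  if (strand == "+") {
    ws <- max(1, tstart - len); we <- tstart - 1
    if (we < ws) return(list(seq = "", n = 0L))
    list(seq = extract_region(genome, contig_id, ws, we, "+"),
         n = we - ws + 1L, strand = "+", anchor = ws)
  } else {
    ws <- tstart + 1; we <- min(clen, tstart + len)
    if (we < ws) return(list(seq = "", n = 0L))
    list(seq = extract_region(genome, contig_id, ws, we, "-"),
         n = we - ws + 1L, strand = "-", anchor = we)
  }
}

# genomic coordinate one base downstream (in gene direction) of window index e
implied_position <- function(win, e) {
  if (win$strand == "+") win$anchor + e else win$anchor - e
}

#' Extract 50-bp promoter regions upstream of TSSs
#'
#' The promoter is the `promoter_len` bases immediately upstream of the TSS on
#' its strand, so the last base of the returned sequence abuts the TSS. TSSs
#' with insufficient upstream sequence on their contig are flagged and get an
#' `NA` sequence.
#'
#' @param tss tibble with `contig_id`, `position`, `strand`.
#' @param genome genome tibble.
#' @param params a [pipeline_params()] list.
#' @return `tss` with `promoter_seq` and `insufficient_upstream` columns.
#' @export
extract_promoter <- function(tss, genome, params = pipeline_params()) {
  L <- params$promoter_len
  seqs <- purrr::pmap(tss[c("contig_id", "position", "strand")],
    function(contig_id, position, strand) {
      clen <- contig_length(genome, contig_id)
      if (strand == "+") {
        if (position - L < 1) return(NA_character_)
        extract_region(genome, contig_id, position - L, position - 1, "+")
      } else {
        if (position + L > clen) return(NA_character_)
        extract_region(genome, contig_id, position + 1, position + L, "-")
      }
    })
  out <- tss |>
    mutate(promoter_seq = unlist(seqs),
           insufficient_upstream = is.na(.data$promoter_seq))
  if (any(out$insufficient_upstream)) {
    warn(sprintf("%d TSS(s) lack %d nt of upstream sequence and are flagged",
                 sum(out$insufficient_upstream), L))
  }
  out
}

cons_test <- function(aln, params) {
  !is.null(aln) &&
    aln$n_columns >= params$promoter_conserved_min_cols * params$promoter_len &&
    pw_identity(aln) >= params$promoter_conserved_min_identity
}

#' Categorize promoter regions by cross-species conservation
#'
#' Classifies every gene-assigned, retained TSS of species A against species B
#' following the reciprocal promoter-to-upstream alignment procedure:
#'
#' * **SSP** — the TSS is not assigned to a gene with an ortholog.
#' * The A promoter (50 bp upstream of the TSS) is locally aligned onto the
#'   800-bp window upstream of the B ortholog's translation start. A failed
#'   conservation test (identity and span thresholds) gives **OP**.
#' * The implied B position is one base downstream (gene direction) of the
#'   alignment's 3' end. When a B TSS of the ortholog matches it within
#'   `tss_match_tol` and the reciprocal alignment of that TSS's promoter back
#'   onto A's upstream window implies the original TSS, the pair is **CPT**.
#' * Otherwise the matched B segment is aligned back onto A's upstream
#'   window; implying the original TSS gives **CPNT**, else **OP**.
#'
#' TSSs without `promoter_len` of upstream sequence, or whose partner upstream
#' window is clipped below `promoter_len`, are excluded with category `NA` and
#' an explanatory flag.
#'
#' @param tss_a annotated TSS tibble for species A (from [call_tss()]).
#' @param tss_b annotated TSS tibble for species B.
#' @param genes_a,genes_b gene tibbles.
#' @param genome_a,genome_b genome tibbles.
#' @param orthologs ortholog tibble from [find_orthologs()]; only
#'   `reciprocal_best` pairs are used as gene partners, with `gene_a` ids from
#'   species A.
#' @param params a [pipeline_params()] list.
#' @param species label stored in the `species` column.
#' @return A tibble with one row per categorized TSS: coordinates, gene,
#'   `category` (`CPT`/`CPNT`/`OP`/`SSP`), partner gene and TSS position (CPT
#'   only), implied partner position, forward alignment identity, and `flag`.
#' @export
categorize_promoters <- function(tss_a, tss_b, genes_a, genes_b,
                                 genome_a, genome_b, orthologs,
                                 params = pipeline_params(), species = "A") {
  ortho_map <- orthologs |> filter(.data$reciprocal_best)
  gene_b_tbl <- genes_b |> mutate(tstart = translation_start(genes_b))
  gene_a_tbl <- genes_a |> mutate(tstart = translation_start(genes_a))
  # per-gene retained TSS lists of B, keyed by gene
  tss_b_gene <- tss_b |>
    filter(!is.na(.data$gene_id), .data$retained_in_gene %in% TRUE)
  # TSSs of A to categorize: assigned+retained, or unassigned (-> SSP)
  work <- tss_a |>
    filter(is.na(.data$gene_id) | .data$retained_in_gene %in% TRUE) |>
    extract_promoter(genome_a, params)
  L <- params$promoter_len
  U <- params$upstream_search_len
  tol <- params$tss_match_tol
  rows <- purrr::map(seq_len(nrow(work)), function(i) {
    w <- work[i, ]
    res <- tibble(
      species = species, contig_id = w$contig_id, position = w$position,
      strand = w$strand, gene_id = w$gene_id, category = NA_character_,
      partner_gene = NA_character_, partner_position = NA_integer_,
      implied_partner_position = NA_integer_, fwd_identity = NA_real_,
      flag = NA_character_
    )
    if (w$insufficient_upstream) {
      res$flag <- "insufficient_upstream"
      return(res)
    }
    # SSP: no gene, or gene without a one-to-one ortholog
    j <- if (is.na(w$gene_id)) integer(0) else which(ortho_map$gene_a == w$gene_id)
    if (length(j) == 0) {
      res$category <- "SSP"
      return(res)
    }
    gb_id <- ortho_map$gene_b[j[1]]
    res$partner_gene <- gb_id
    gb <- gene_b_tbl |> filter(.data$gene_id == gb_id)
    ga <- gene_a_tbl |> filter(.data$gene_id == w$gene_id)
    win_b <- upstream_window(genome_b, gb$contig_id, gb$tstart, gb$strand, U)
    win_a <- upstream_window(genome_a, ga$contig_id, ga$tstart, ga$strand, U)
    if (win_b$n < L || win_a$n < L) {
      res$flag <- "clipped_window"
      return(res)
    }
    aln1 <- align_local(w$promoter_seq, win_b$seq, nt_scoring())
    if (!cons_test(aln1, params)) {
      res$category <- "OP"
      return(res)
    }
    res$fwd_identity <- pw_identity(aln1)
    implied_b <- implied_position(win_b, aln1$target_span[2])
    res$implied_partner_position <- implied_b
    # candidate partner TSSs of the ortholog, nearest to the implied position
    # first; equal distance broken by stronger signal
    cand <- tss_b_gene |>
      filter(.data$gene_id == gb_id, abs(.data$position - implied_b) <= tol) |>
      arrange(abs(.data$position - implied_b), desc(.data$combined_count))
    for (k in seq_len(nrow(cand))) {
      t_b <- cand[k, ]
      p_b <- extract_promoter(t_b, genome_b, params)
      if (p_b$insufficient_upstream) next
      aln2 <- align_local(p_b$promoter_seq, win_a$seq, nt_scoring())
      if (!cons_test(aln2, params)) next
      implied_a <- implied_position(win_a, aln2$target_span[2])
      if (abs(implied_a - w$position) <= tol) {
        res$category <- "CPT"
        res$partner_position <- t_b$position
        return(res)
      }
    }
    # no partner TSS (or reciprocity failed): conserved sequence test via the
    # matched B segment aligned back onto A's upstream window
    seg <- substr(win_b$seq, aln1$target_span[1], aln1$target_span[2])
    aln3 <- align_local(seg, win_a$seq, nt_scoring())
    if (cons_test(aln3, params)) {
      implied_a <- implied_position(win_a, aln3$target_span[2])
      if (abs(implied_a - w$position) <= tol) {
        res$category <- "CPNT"
        return(res)
      }
    }
    res$category <- "OP"
    res
  })
  bind_rows(rows)
}

#' Summarize promoter categories per species
#'
#' @param results categorization tibble, possibly row-bound over species.
#' @return A tibble `species`, `category`, `n`, `frac_pct` (percent of that
#'   species' categorized TSSs). Flagged TSSs (`NA` category) are excluded.
#' @export
summarize_categories <- function(results) {
  cats <- c("CPT", "CPNT", "OP", "SSP")
  done <- results |> filter(!is.na(.data$category))
  if (nrow(done) == 0) {
    return(tidyr::crossing(species = unique(results$species), category = cats) |>
             mutate(n = 0L, frac_pct = NA_real_))
  }
  done |>
    mutate(category = factor(.data$category, levels = cats)) |>
    group_by(.data$species) |>
    dplyr::count(.data$category, .drop = FALSE) |>
    mutate(frac_pct = 100 * .data$n / sum(.data$n)) |>
    ungroup() |>
    mutate(category = as.character(.data$category))
}

#' Cross-species CPT promoter pairs
#'
#' @param results_a categorization tibble for one species direction.
#' @return A tibble of distinct CPT pairs: `gene_id`, `position`,
#'   `partner_gene`, `partner_position`.
#' @export
cpt_pairs <- function(results_a) {
  results_a |>
    filter(.data$category == "CPT") |>
    distinct(.data$gene_id, .data$position, .data$strand,
             .data$partner_gene, .data$partner_position)
}
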