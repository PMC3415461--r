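#' Synteny-bounded search interval for an sRNA homolog
#'
#' Finds the nearest ortholog-bearing genes flanking the sRNA locus in
#' species A and returns the interval in species B between the facing (inner)
#' boundaries of their orthologs, regardless of the B genes' order or strand.
#' When one flank is missing (contig end), the interval extends `flank_cap`
#' nt from the present ortholog, clipped to the contig.
#'
#' @param srna one-row gene tibble for the sRNA locus in species A.
#' @param genes_a,genes_b gene tibbles.
#' @param orthologs ortholog tibble (reciprocal-best rows used).
#' @param genome_b genome tibble of species B (for clipping).
#' @param flank_cap nt cap applied on a missing flank; default 10000.
#' @return A one-row tibble `contig_id`, `start`, `end`, `left_gene_b`,
#'   `right_gene_b`.
#' @export
synteny_interval <- function(srna, genes_a, genes_b, orthologs, genome_b,
                             flank_cap = 10000) {
  rbh <- orthologs |> filter(.data$reciprocal_best)
  nb <- ortholog_neighbors(genes_a, srna$contig_id, srna$start, srna$end,
                           ortholog_ids = rbh$gene_a)
  if (is.na(nb$left_gene) && is.na(nb$right_gene)) {
    abort(sprintf("sRNA '%s' has no ortholog-bearing flanking gene", srna$gene_id))
  }
  b_of <- function(a_id) {
    if (is.na(a_id)) return(NULL)
    genes_b |> filter(.data$gene_id == rbh$gene_b[match(a_id, rbh$gene_a)])
  }
  gl <- b_of(nb$left_gene)
  gr <- b_of(nb$right_gene)
  if (!is.null(gl) && !is.null(gr)) {
    if (gl$contig_id != gr$contig_id) {
      abort("flanking orthologs lie on different contigs in the target species")
    }
    contig <- gl$contig_id
    lo <- min(gl$end, gr$end) + 1
    hi <- max(gl$start, gr$start) - 1
    if (lo > hi) abort("flanking orthologs leave no intergenic interval")
  } else {
    g <- if (is.null(gl)) gr else gl
    contig <- g$contig_id
    if (is.null(gl)) {  # only the right flank present: search upstream of it
      lo <- max(1, g$start - flank_cap)
      hi <- g$start - 1
    } else {
      lo <- g$end + 1
      hi <- min(contig_length(genome_b, contig), g$end + flank_cap)
    }
    if (lo > hi) abort("capped synteny interval is empty")
  }
  tibble(contig_id = contig, start = as.integer(lo), end = as.integer(hi),
         left_gene_b = if (is.null(gl)) NA_character_ else gl$gene_id,
         right_gene_b = if (is.null(gr)) NA_character_ else gr$gene_id)
}

#' Search a synteny interval for an sRNA homolog
#'
#' Locally aligns the source sRNA sequence against both strands of the
#' interval and keeps the better hit if it reaches `srna_min_identity`
#' identity and covers at least `srna_min_coverage` of the source length.
#' The candidate 5' end is the interval position corresponding to the source
#' sRNA's 5' terminus (extrapolated when the alignment does not reach it).
#'
#' @param srna_seq source sRNA sequence, 5' to 3'.
#' @param genome_b genome tibble of species B.
#' @param interval one-row tibble from [synteny_interval()].
#' @param params a [pipeline_params()] list.
#' @param name candidate name.
#' @param scoring nucleotide scoring; default [nt_scoring()].
#' @return A one-row candidate tibble (`name`, `contig_id`, `hit_start`,
#'   `hit_end`, `strand`, `five_prime`, `pct_identity`, `coverage`), or a
#'   zero-row tibble when no acceptable hit exists.
#' @export
find_srna_homolog <- function(srna_seq, genome_b, interval,
                              params = pipeline_params(), name = "srna",
                              scoring = nt_scoring()) {
  empty <- tibble(name = character(), contig_id = character(),
                  hit_start = integer(), hit_end = integer(),
                  strand = character(), five_prime = integer(),
                  pct_identity = numeric(), coverage = numeric())
  iseq <- extract_region(genome_b, interval$contig_id, interval$start,
                         interval$end, "+")
  if (nchar(iseq) == 0) return(empty)
  best <- NULL; best_strand <- NULL
  for (st in c("+", "-")) {
    target <- if (st == "+") iseq else revcomp(iseq)
    aln <- align_local(srna_seq, target, scoring)
    if (!is.null(aln) && (is.null(best) || aln$score > best$score)) {
      best <- aln; best_strand <- st
    }
  }
  if (is.null(best)) return(empty)
  coverage <- (best$query_span[2] - best$query_span[1] + 1) / nchar(srna_seq)
  if (pw_identity(best) < params$srna_min_identity ||
      coverage < params$srna_min_coverage) {
    return(empty)
  }
  ts <- best$target_span
  qs <- best$query_span[1]
  if (best_strand == "+") {
    hit_start <- interval$start + ts[1] - 1
    hit_end <- interval$start + ts[2] - 1
    five_prime <- hit_start - (qs - 1)
  } else {
    hit_start <- interval$end - ts[2] + 1
    hit_end <- interval$end - ts[1] + 1
    five_prime <- hit_end + (qs - 1)
  }
  tibble(name = name, contig_id = interval$contig_id,
         hit_start = as.integer(hit_start), hit_end = as.integer(hit_end),
         strand = best_strand, five_prime = as.integer(five_prime),
         pct_identity = 100 * pw_identity(best), coverage = coverage)
}

#' Confirm candidate sRNA expression by TSS support
#'
#' A candidate is expressed when a TSS on its contig and strand lies within
#' `srna_tss_tol` nt of the candidate 5' end; the nearest such TSS is
#' recorded.
#'
#' @param candidates candidate tibble from [find_srna_homolog()].
#' @param tss tibble of TSSs in species B.
#' @param params a [pipeline_params()] list.
#' @return `candidates` with `expressed` and `tss_support` columns.
#' @export
confirm_expression <- function(candidates, tss, params = pipeline_params()) {
  if (nrow(candidates) == 0) {
    return(candidates |> mutate(expressed = logical(0), tss_support = integer(0)))
  }
  sup <- purrr::map(seq_len(nrow(candidates)), function(i) {
    x <- candidates[i, ]
    near <- tss |>
      filter(.data$contig_id == x$contig_id, .data$strand == x$strand,
             abs(.data$position - x$five_prime) <= params$srna_tss_tol) |>
      arrange(abs(.data$position - x$five_prime))
    tibble(expressed = nrow(near) > 0,
           tss_support = if (nrow(near)) near$position[1] else NA_integer_)
  })
  bind_cols(candidates, bind_rows(sup))
}

#' Scan all annotated sRNAs of species A for homologs in species B
#'
#' For each sRNA feature: build the synteny interval, search it on both
#' strands, and confirm expression against the B TSS set. Also accepts an
#' external hit table (e.g. covariance-model hits) via `extra_hits`, which is
#' passed straight to expression confirmation.
#'
#' @param genes_a,genes_b gene tibbles (sRNAs are `feature_type == "sRNA"`
#'   rows of `genes_a`).
#' @param orthologs ortholog tibble.
#' @param genome_a,genome_b genome tibbles.
#' @param tss_b TSS tibble for species B.
#' @param params a [pipeline_params()] list.
#' @param extra_hits optional tibble with `name`, `contig_id`, `hit_start`,
#'   `hit_end`, `strand`, `five_prime`, `pct_identity`, `coverage`.
#' @return A candidate tibble with expression flags; sRNAs without an
#'   acceptable hit are absent.
#' @export
scan_srna_homologs <- function(genes_a, genes_b, orthologs, genome_a, genome_b,
                               tss_b, params = pipeline_params(),
                               extra_hits = NULL) {
  srnas <- genes_a |> filter(.data$feature_type == "sRNA")
  found <- purrr::map(seq_len(nrow(srnas)), function(i) {
    s <- srnas[i, ]
    seq <- extract_region(genome_a, s$contig_id, s$start, s$end, s$strand)
    iv <- synteny_interval(s, genes_a, genes_b, orthologs, genome_b)
    find_srna_homolog(seq, genome_b, iv, params, name = s$gene_id)
  }) |> bind_rows()
  if (!is.null(extra_hits)) found <- bind_rows(found, extra_hits)
  confirm_expression(found, tss_b, params)
}

# identity over the M columns of an alignment restricted to a query interval;
# needs the gapped row strings
region_identity <- function(aln, qstart, qend) {
  if (is.null(aln$q_aln) || is.null(aln$t_aln)) return(NA_real_)
  ops <- expand_ops(aln$op_string)
  ac <- strsplit(aln$q_aln, "")[[1]]
  bc <- strsplit(aln$t_aln, "")[[1]]
  qpos <- aln$query_span[1] - 1L
  n_m <- 0L; n_id <- 0L
  for (k in seq_along(ops)) {
    if (ops[k] != "D") qpos <- qpos + 1L
    if (ops[k] == "M" && qpos >= qstart && qpos <= qend) {
      n_m <- n_m + 1L
      if (ac[k] == bc[k] && ac[k] != "N") n_id <- n_id + 1L
    }
    if (qpos > qend) break
  }
  if (n_m == 0) NA_real_ else n_id / n_m
}

#' Project known sRNA target sites across species
#'
#' Each target site on the species-A mRNA region is projected through the
#' mRNA-pair alignment onto species B, reporting the projected interval and
#' the percent identity over the site's aligned columns; when the site's
#' pairing region on the sRNA is given, the identity of that region under the
#' sRNA-pair alignment is reported too. Sites outside the aligned span or
#' opposite gaps are flagged, never dropped.
#'
#' @param srna_aln `pw_alignment` of the two sRNA homologs (A as query), or
#'   `NULL`.
#' @param mrna_aln `pw_alignment` of the two target mRNA regions (A as
#'   query).
#' @param sites tibble with `site_name`, `mrna_start`, `mrna_end` and
#'   optionally `srna_start`, `srna_end` (coordinates on the A sequences).
#' @return A tibble per site: projected interval in B, `mapped_fraction`,
#'   `site_pct_identity`, `srna_binding_region_pct_identity`, `projected`.
#' @export
map_target_sites <- function(srna_aln, mrna_aln, sites) {
  rows <- purrr::map(seq_len(nrow(sites)), function(i) {
    s <- sites[i, ]
    proj <- tryCatch(map_region(mrna_aln, s$mrna_start, s$mrna_end),
                     error = function(e) tibble(target_start = NA_integer_,
                                                target_end = NA_integer_,
                                                mapped_fraction = 0,
                                                projected = FALSE))
    site_id <- if (proj$projected) {
      100 * region_identity(mrna_aln, s$mrna_start, s$mrna_end)
    } else NA_real_
    srna_id <- if (!is.null(srna_aln) && !is.null(s$srna_start) &&
                   !is.na(s$srna_start %||% NA)) {
      100 * region_identity(srna_aln, s$srna_start, s$srna_end)
    } else NA_real_
    tibble(site_name = s$site_name,
           site_b_start = proj$target_start, site_b_end = proj$target_end,
           mapped_fraction = proj$mapped_fraction,
           site_pct_identity = site_id,
           srna_binding_region_pct_identity = srna_id,
           projected = proj$projected)
  })
  bind_rows(rows)
}
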