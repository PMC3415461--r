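#' 5' UTR length of an assigned TSS
#'
#' The number of transcribed nucleotides strictly upstream of the start
#' codon's first base — identical to the TSS's distance to the translation
#' start; 0 for leaderless transcripts.
#'
#' @param tss annotated TSS tibble (needs `gene_id`, `dist_to_start`).
#' @return Integer vector of UTR lengths.
#' @export
utr_length <- function(tss) {
  if (any(is.na(tss$gene_id))) abort("utr_length: TSS(s) not assigned to a gene")
  tss$dist_to_start
}

# transcribed sequence from the TSS up to (not including) the start codon
utr_sequence <- function(genome, contig_id, position, strand, tstart) {
  d <- if (strand == "+") tstart - position else position - tstart
  if (d == 0) return("")
  if (strand == "+") {
    extract_region(genome, contig_id, position, tstart - 1, "+")
  } else {
    extract_region(genome, contig_id, tstart + 1, position, "-")
  }
}

#' Build comparable 5' UTR pairs from CPT promoters
#'
#' Each conserved promoter with TSSs in both species (CPT) defines one
#' comparable 5' UTR pair: the sequences between the two TSSs and their
#' respective start codons. Percent identity comes from a global alignment of
#' the two UTRs; a pair with a leaderless member keeps its lengths but has
#' `NA` identity (flagged).
#'
#' @param cpt_results categorization tibble rows with `category == "CPT"`
#'   from [categorize_promoters()] (species A perspective).
#' @param genes_a,genes_b gene tibbles.
#' @param genome_a,genome_b genome tibbles.
#' @param scoring nucleotide scoring; default [nt_scoring()].
#' @return A tibble `gene_a`, `gene_b`, `len_a`, `len_b`, `seq_a`, `seq_b`,
#'   `pct_identity`, `leaderless_member`.
#' @export
build_utr_pairs <- function(cpt_results, genes_a, genes_b, genome_a, genome_b,
                            scoring = nt_scoring()) {
  cpt <- cpt_results |> filter(.data$category == "CPT")
  ga <- genes_a |> mutate(tstart = translation_start(genes_a))
  gb <- genes_b |> mutate(tstart = translation_start(genes_b))
  rows <- purrr::map(seq_len(nrow(cpt)), function(i) {
    x <- cpt[i, ]
    a <- ga |> filter(.data$gene_id == x$gene_id)
    b <- gb |> filter(.data$gene_id == x$partner_gene)
    seq_a <- utr_sequence(genome_a, a$contig_id, x$position, a$strand, a$tstart)
    seq_b <- utr_sequence(genome_b, b$contig_id, x$partner_position, b$strand,
                          b$tstart)
    leaderless <- nchar(seq_a) == 0 || nchar(seq_b) == 0
    pid <- if (leaderless) NA_real_ else {
      100 * pw_identity(align_global(seq_a, seq_b, scoring))
    }
    tibble(gene_a = x$gene_id, gene_b = x$partner_gene,
           len_a = nchar(seq_a), len_b = nchar(seq_b),
           seq_a = seq_a, seq_b = seq_b, pct_identity = pid,
           leaderless_member = leaderless)
  })
  bind_rows(rows)
}

#' Summary statistics of 5' UTR pairs
#'
#' @param pairs tibble from [build_utr_pairs()].
#' @return A one-row tibble: `n_pairs`, `r_squared` (squared Pearson
#'   correlation of the two length vectors; `NA` with fewer than two pairs or
#'   zero length variance), `n_equal_length`, `frac_equal_pct`, `mean_len_a`,
#'   `mean_len_b`, `mean_identity`.
#' @export
utr_length_stats <- function(pairs) {
  n <- nrow(pairs)
  r2 <- if (n < 2 || stats::sd(pairs$len_a) == 0 || stats::sd(pairs$len_b) == 0) {
    warn("r_squared undefined: need >= 2 pairs with length variance")
    NA_real_
  } else {
    cor(pairs$len_a, pairs$len_b)^2
  }
  tibble(
    n_pairs = n,
    r_squared = r2,
    n_equal_length = sum(pairs$len_a == pairs$len_b),
    frac_equal_pct = if (n > 0) 100 * sum(pairs$len_a == pairs$len_b) / n else NA_real_,
    mean_len_a = mean(pairs$len_a),
    mean_len_b = mean(pairs$len_b),
    mean_identity = mean(pairs$pct_identity, na.rm = TRUE)
  )
}

#' Extract CDS sequence pairs for orthologous genes
#'
#' @param orthologs ortholog tibble (reciprocal-best rows are used).
#' @param genes_a,genes_b gene tibbles.
#' @param genome_a,genome_b genome tibbles.
#' @return A tibble `gene_a`, `gene_b`, `cds_a`, `cds_b`.
#' @export
ortholog_cds_pairs <- function(orthologs, genes_a, genes_b, genome_a, genome_b) {
  pairs <- orthologs |> filter(.data$reciprocal_best)
  rows <- purrr::map(seq_len(nrow(pairs)), function(i) {
    a <- genes_a |> filter(.data$gene_id == pairs$gene_a[i])
    b <- genes_b |> filter(.data$gene_id == pairs$gene_b[i])
    tibble(gene_a = a$gene_id, gene_b = b$gene_id,
           cds_a = extract_region(genome_a, a$contig_id, a$start, a$end, a$strand),
           cds_b = extract_region(genome_b, b$contig_id, b$start, b$end, b$strand))
  })
  bind_rows(rows)
}

# does the global CDS alignment have a clean (gap-free) start: no indels in
# the first n_codons codons
clean_start <- function(aln, n_codons = 3) {
  ops <- expand_ops(aln$op_string)
  all(ops[seq_len(min(3 * n_codons, length(ops)))] == "M")
}

#' Per-position conservation profile around translation starts
#'
#' For every reciprocal-best ortholog pair whose global CDS alignment starts
#' cleanly (no gaps within the first three codons — "clearly aligned"
#' translation starts), the two `2 * window`-nt regions centred on the start
#' codon are compared ungapped, anchored at the translation start (offset 0 =
#' first base of the start codon; offsets run `-window .. window - 1`).
#'
#' @param orthologs ortholog tibble.
#' @param genes_a,genes_b gene tibbles.
#' @param genome_a,genome_b genome tibbles.
#' @param window nt on each side of the translation start; default 100.
#' @param scoring nucleotide scoring for the eligibility alignment.
#' @return A tibble `offset`, `frac_identical`, `n_pairs`.
#' @export
conservation_profile <- function(orthologs, genes_a, genes_b,
                                 genome_a, genome_b, window = 100,
                                 scoring = nt_scoring()) {
  cds <- ortholog_cds_pairs(orthologs, genes_a, genes_b, genome_a, genome_b)
  ga <- genes_a |> mutate(tstart = translation_start(genes_a))
  gb <- genes_b |> mutate(tstart = translation_start(genes_b))
  region <- function(genes, genome, id, w) {
    g <- genes |> filter(.data$gene_id == id)
    clen <- contig_length(genome, g$contig_id)
    if (g$strand == "+") {
      s <- g$tstart - w; e <- g$tstart + w - 1
      if (s < 1 || e > clen) return(NULL)
      extract_region(genome, g$contig_id, s, e, "+")
    } else {
      s <- g$tstart - w + 1; e <- g$tstart + w
      if (s < 1 || e > clen) return(NULL)
      extract_region(genome, g$contig_id, s, e, "-")
    }
  }
  ident <- matrix(0L, nrow = 0, ncol = 2 * window)
  n_skipped <- 0L
  for (i in seq_len(nrow(cds))) {
    aln <- align_global(cds$cds_a[i], cds$cds_b[i], scoring)
    if (!clean_start(aln)) next
    ra <- region(ga, genome_a, cds$gene_a[i], window)
    rb <- region(gb, genome_b, cds$gene_b[i], window)
    if (is.null(ra) || is.null(rb)) {
      n_skipped <- n_skipped + 1L
      next
    }
    ident <- rbind(ident,
                   as.integer(strsplit(ra, "")[[1]] == strsplit(rb, "")[[1]]))
  }
  if (n_skipped > 0) {
    warn(sprintf("%d ortholog pair(s) skipped: %d-nt window exceeds contig bounds",
                 n_skipped, window))
  }
  tibble(offset = c(-window:-1, 0:(window - 1)),
         frac_identical = if (nrow(ident)) colMeans(ident) else NA_real_,
         n_pairs = nrow(ident))
}

#' Conservation by codon position in orthologous CDS pairs
#'
#' Globally aligns each CDS pair and, over aligned gap-free columns where both
#' sequences are in the same codon phase, computes the fraction of identical
#' bases at codon positions 1, 2, and 3. Trailing bases of a CDS whose length
#' is not a multiple of three are ignored with a warning.
#'
#' @param cds_pairs tibble with `cds_a`, `cds_b` columns (see
#'   [ortholog_cds_pairs()]).
#' @param scoring nucleotide scoring; default [nt_scoring()].
#' @return A tibble `codon_pos` (1..3), `frac_identical`, `n_columns`.
#' @export
codon_position_conservation <- function(cds_pairs, scoring = nt_scoring()) {
  if (any(nchar(c(cds_pairs$cds_a, cds_pairs$cds_b)) %% 3 != 0)) {
    warn("CDS length(s) not divisible by 3: trailing bases ignored")
  }
  n_ident <- c(0L, 0L, 0L)
  n_total <- c(0L, 0L, 0L)
  for (i in seq_len(nrow(cds_pairs))) {
    a <- cds_pairs$cds_a[i]; b <- cds_pairs$cds_b[i]
    lim_a <- 3L * (nchar(a) %/% 3L)
    lim_b <- 3L * (nchar(b) %/% 3L)
    aln <- align_global(a, b, scoring)
    ops <- expand_ops(aln$op_string)
    ac <- strsplit(aln$q_aln, "")[[1]]
    bc <- strsplit(aln$t_aln, "")[[1]]
    pa <- 0L; pb <- 0L
    for (k in seq_along(ops)) {
      op <- ops[k]
      if (op == "M") { pa <- pa + 1L; pb <- pb + 1L } else
      if (op == "I") { pa <- pa + 1L; next } else { pb <- pb + 1L; next }
      if (pa > lim_a || pb > lim_b) next
      if ((pa - 1L) %% 3L != (pb - 1L) %% 3L) next  # out-of-frame column
      cp <- (pa - 1L) %% 3L + 1L
      n_total[cp] <- n_total[cp] + 1L
      if (ac[k] == bc[k] && ac[k] != "N") n_ident[cp] <- n_ident[cp] + 1L
    }
  }
  tibble(codon_pos = 1:3,
         frac_identical = ifelse(n_total > 0, n_ident / n_total, NA_real_),
         n_columns = n_total)
}

#' Dinucleotide (base) preference around TSSs
#'
#' Strand-aware base composition at offsets -5..+5 around each TSS, where +1
#' is the TSS base itself and -1 the base immediately upstream (there is no
#' offset 0). Also reports the purine (A+G) fraction at +1 and the pyrimidine
#' (C+T) fraction at -1. TSSs whose flanks leave the contig are skipped.
#'
#' @param tss tibble with `contig_id`, `position`, `strand`; must be
#'   non-empty.
#' @param genome genome tibble.
#' @param flank offsets span `-flank..+flank`; default 5.
#' @return An object of class `dinuc_pref` with elements `freqs` (tibble
#'   `offset`, `base`, `fraction`, `n`), `purine_frac_plus1`,
#'   `pyrimidine_frac_minus1`, `n_tss`. `tidy()` returns the frequency table,
#'   `glance()` the headline fractions.
#' @export
dinucleotide_preference <- function(tss, genome, flank = 5) {
  if (nrow(tss) == 0) abort("empty TSS list")
  offsets <- c(-flank:-1, 1:flank)
  base_at <- function(contig_id, position, strand, k) {
    g <- if (strand == "+") {
      if (k > 0) position + k - 1 else position + k
    } else {
      if (k > 0) position - k + 1 else position - k
    }
    clen <- contig_length(genome, contig_id)
    if (g < 1 || g > clen) return(NA_character_)
    extract_region(genome, contig_id, g, g, strand)
  }
  freqs <- purrr::map(offsets, function(k) {
    b <- purrr::pmap_chr(tss[c("contig_id", "position", "strand")],
                         function(contig_id, position, strand)
                           base_at(contig_id, position, strand, k))
    b <- b[!is.na(b) & b != "N"]
    counts <- table(factor(b, levels = c("A", "C", "G", "T")))
    tibble(offset = k, base = names(counts),
           fraction = as.numeric(counts) / length(b), n = length(b))
  }) |> bind_rows()
  at <- function(k, bases) {
    f <- freqs |> filter(.data$offset == k, .data$base %in% bases)
    100 * sum(f$fraction)
  }
  structure(list(freqs = freqs,
                 purine_frac_plus1 = at(1, c("A", "G")),
                 pyrimidine_frac_minus1 = at(-1, c("C", "T")),
                 n_tss = nrow(tss)),
            class = "dinuc_pref")
}

#' @export
print.dinuc_pref <- function(x, ...) {
  cat(sprintf("<dinuc_pref> %d TSSs: purine at +1 = %.1f%%, pyrimidine at -1 = %.1f%%\n",
              x$n_tss, x$purine_frac_plus1, x$pyrimidine_frac_minus1))
  invisible(x)
}

#' @rdname dinucleotide_preference
#' @param x a `dinuc_pref` object.
#' @param ... unused.
#' @method tidy dinuc_pref
#' @export
tidy.dinuc_pref <- function(x, ...) x$freqs

#' @rdname dinucleotide_preference
#' @method glance dinuc_pref
#' @export
glance.dinuc_pref <- function(x, ...) {
  tibble(purine_frac_plus1 = x$purine_frac_plus1,
         pyrimidine_frac_minus1 = x$pyrimidine_frac_minus1,
         n_tss = x$n_tss)
}

#' Extract sequence sets for external motif discovery
#'
#' Writes (or returns) one record per eligible TSS: either the 50-bp promoter
#' region (`region = "promoter50"`) or the 5' UTR (`region = "utr"`;
#' leaderless and unassigned TSSs are skipped with a warning). Record ids
#' encode species, gene, position, and strand.
#'
#' @param tss annotated TSS tibble.
#' @param genome genome tibble.
#' @param genes gene tibble (required for `region = "utr"`).
#' @param region `"promoter50"` or `"utr"`.
#' @param params a [pipeline_params()] list.
#' @param species label used in record ids.
#' @param path optional FASTA output path.
#' @return A tibble `id`, `seq` (invisibly when `path` is given).
#' @export
extract_motif_inputs <- function(tss, genome, genes = NULL,
                                 region = c("promoter50", "utr"),
                                 params = pipeline_params(), species = "A",
                                 path = NULL) {
  region <- match.arg(region)
  mk_id <- function(x) sprintf("%s|%s|%d|%s", species,
                               dplyr::coalesce(x$gene_id, "unassigned"),
                               x$position, x$strand)
  if (region == "promoter50") {
    p <- extract_promoter(tss, genome, params) |>
      filter(!.data$insufficient_upstream)
    out <- tibble(id = mk_id(p), seq = p$promoter_seq)
  } else {
    if (is.null(genes)) abort("region = 'utr' requires the gene table")
    eligible <- tss |> filter(!is.na(.data$gene_id))
    skipped <- sum(eligible$dist_to_start == 0)
    if (skipped > 0) {
      warn(sprintf("%d leaderless transcript(s) skipped in UTR extraction", skipped))
    }
    eligible <- eligible |> filter(.data$dist_to_start > 0)
    gt <- genes |> mutate(tstart = translation_start(genes))
    seqs <- purrr::map_chr(seq_len(nrow(eligible)), function(i) {
      x <- eligible[i, ]
      g <- gt |> filter(.data$gene_id == x$gene_id)
      utr_sequence(genome, x$contig_id, x$position, x$strand, g$tstart)
    })
    out <- tibble(id = mk_id(eligible), seq = seqs)
  }
  if (!is.null(path)) {
    write_fasta(out$id, out$seq, path, alphabet = "dna")
    return(invisible(out))
  }
  out
}
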