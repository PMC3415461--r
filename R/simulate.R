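#' Configuration for the synthetic genome-pair simulator
#'
#' Defines the study conditions the simulator emulates: two related bacterial
#' genomes sharing a tunable fraction of orthologous genes, promoters planted
#' in the four conservation categories, negative-binomial TSS read counts in
#' two replicates over sparse background noise, and sRNAs flanked by
#' orthologous genes.
#'
#' @param rng_seed integer seed; the whole simulation is deterministic given
#'   it.
#' @param n_contigs contigs per species (each of length `contig_len`).
#' @param contig_len nt per contig.
#' @param n_genes protein-coding genes per species.
#' @param frac_orthologous fraction of genes with a one-to-one ortholog.
#' @param protein_divergence per-residue substitution probability between
#'   orthologous proteins.
#' @param decoy_divergence per-residue substitution probability between
#'   paired species-specific ("decoy") proteins.
#' @param category_mix named integer vector of planted promoter categories
#'   per species: `CPT` (cross-species pairs), `CPNT`, `OP`, `SSP`.
#' @param promoter_divergence per-base substitution probability applied when
#'   a conserved promoter is copied into the partner genome.
#' @param tss_count_mean,tss_count_dispersion negative-binomial mean and size
#'   for planted TSS read counts (per replicate, truncated at 1).
#' @param noise_rate background noise positions per kb per replicate
#'   (independent across replicates).
#' @param noise_count_mean mean of the geometric noise read counts.
#' @param n_srnas sRNAs planted between ortholog-bearing genes.
#' @param srna_divergence per-base substitution probability of the sRNA copy.
#' @param srna_len sRNA length in nt.
#' @param frac_multi_tss probability that a planted gene TSS gets a secondary
#'   TSS 15-40 nt further upstream.
#' @param frac_leaderless probability that a planted TSS is leaderless
#'   (distance 0).
#' @param utr_range inclusive range UTR lengths are drawn from (non-leaderless).
#' @param syn_rate probability of a synonymous third-position swap per codon
#'   between orthologous CDSs.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(rng_seed = 1L, n_contigs = 1L, contig_len = 300000L,
                       n_genes = 200L, frac_orthologous = 0.8,
                       protein_divergence = 0.05, decoy_divergence = 0.7,
                       category_mix = c(CPT = 40L, CPNT = 20L, OP = 20L, SSP = 20L),
                       promoter_divergence = 0.1,
                       tss_count_mean = 20, tss_count_dispersion = 5,
                       noise_rate = 0.5, noise_count_mean = 2,
                       n_srnas = 8L, srna_divergence = 0.1, srna_len = 120L,
                       frac_multi_tss = 0.1, frac_leaderless = 0.05,
                       utr_range = c(20L, 120L), syn_rate = 0.3) {
  probs <- c(frac_orthologous, protein_divergence, decoy_divergence,
             promoter_divergence, srna_divergence, frac_multi_tss,
             frac_leaderless, syn_rate)
  if (any(probs < 0 | probs > 1)) abort("probabilities must lie in [0,1]")
  if (!all(c("CPT", "CPNT", "OP", "SSP") %in% names(category_mix))) {
    abort("category_mix must name CPT, CPNT, OP, SSP")
  }
  n_orth <- round(frac_orthologous * n_genes)
  n_spec <- n_genes - n_orth
  need_orth <- category_mix[["CPT"]] + 2 * category_mix[["CPNT"]] +
    2 * category_mix[["OP"]]
  if (need_orth > n_orth) {
    abort(sprintf("category_mix needs %d orthologous genes but only %d exist",
                  need_orth, n_orth))
  }
  if (category_mix[["SSP"]] > n_spec) {
    abort(sprintf("category_mix needs %d species-specific genes but only %d exist",
                  category_mix[["SSP"]], n_spec))
  }
  structure(list(
    rng_seed = as.integer(rng_seed), n_contigs = as.integer(n_contigs),
    contig_len = as.integer(contig_len), n_genes = as.integer(n_genes),
    frac_orthologous = frac_orthologous,
    protein_divergence = protein_divergence,
    decoy_divergence = decoy_divergence,
    category_mix = category_mix, promoter_divergence = promoter_divergence,
    tss_count_mean = tss_count_mean,
    tss_count_dispersion = tss_count_dispersion,
    noise_rate = noise_rate, noise_count_mean = noise_count_mean,
    n_srnas = as.integer(n_srnas), srna_divergence = srna_divergence,
    srna_len = as.integer(srna_len), frac_multi_tss = frac_multi_tss,
    frac_leaderless = frac_leaderless, utr_range = as.integer(utr_range),
    syn_rate = syn_rate
  ), class = "sim_config")
}

# codon machinery --------------------------------------------------------

genetic_code_tbls <- function() {
  gc <- Biostrings::GENETIC_CODE
  sense <- names(gc)[gc != "*"]
  list(code = gc, sense = sense, by_aa = split(names(gc), unname(gc)))
}

translate_cds <- function(cds, gc) {
  codons <- substring(cds, seq(1, nchar(cds) - 2, 3), seq(3, nchar(cds), 3))
  aa <- unname(gc$code[codons])
  paste0(aa[aa != "*"], collapse = "")
}

random_cds <- function(n_codons, gc) {
  paste0(c("ATG", sample(gc$sense, n_codons - 2, replace = TRUE), "TAA"),
         collapse = "")
}

# derive a diverged CDS: non-synonymous codon replacement at `nonsyn`, plus
# synonymous codon swaps at `syn`; start and stop codons untouched
derive_cds <- function(cds, nonsyn, syn, gc) {
  codons <- substring(cds, seq(1, nchar(cds) - 2, 3), seq(3, nchar(cds), 3))
  n <- length(codons)
  for (i in seq(2, n - 1)) {
    aa <- unname(gc$code[codons[i]])
    if (runif(1) < nonsyn) {
      new_aa <- sample(setdiff(names(gc$by_aa), c(aa, "*")), 1)
      codons[i] <- sample(gc$by_aa[[new_aa]], 1)
    } else if (runif(1) < syn && length(gc$by_aa[[aa]]) > 1) {
      codons[i] <- sample(setdiff(gc$by_aa[[aa]], codons[i]), 1)
    }
  }
  paste0(codons, collapse = "")
}

mutate_seq <- function(seq, rate) {
  if (rate == 0 || nchar(seq) == 0) return(seq)
  ch <- strsplit(seq, "")[[1]]
  hit <- which(runif(length(ch)) < rate)
  for (i in hit) ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1)
  paste0(ch, collapse = "")
}

# genomes are built as per-base character vectors and pasted once at the end;
# string surgery on multi-hundred-kb strings is far slower
random_dna_vec <- function(n) {
  sample(c("A", "C", "G", "T"), n, replace = TRUE)
}

random_dna <- function(n) paste0(random_dna_vec(n), collapse = "")

put_seq_vec <- function(vec, start, seq) {
  ch <- strsplit(seq, "")[[1]]
  vec[start + seq_along(ch) - 1L] <- ch
  vec
}

read_seq_vec <- function(vec, start, end) {
  paste0(vec[start:end], collapse = "")
}

# place a promoter copy so that its 3' end (gene direction) abuts position q
put_promoter <- function(vec, q, strand, promoter) {
  L <- nchar(promoter)
  if (strand == "+") put_seq_vec(vec, q - L, promoter)
  else put_seq_vec(vec, q + 1, revcomp(promoter))
}

#' Simulate a pair of related genomes with planted truth
#'
#' Builds two genomes gene by gene on a fixed slot grid (one gene or sRNA per
#' slot, so features never overlap and every gene keeps a free 800-nt
#' upstream window), derives orthologous CDS pairs from common ancestors at
#' the configured protein divergence, plants promoters and TSSs in the four
#' conservation categories, and plants sRNAs (annotated in species A only)
#' between ortholog-bearing genes. Fully deterministic given
#' `config$rng_seed`.
#'
#' @param config a [sim_config()] list.
#' @return A list of class `synthetic_truth`: `genome_a`, `genome_b`,
#'   `genes_a`, `genes_b`, `proteome_a`, `proteome_b`, `orthologs` (planted
#'   pairs, with `decoy` pairs flagged), `tss_truth`, `srna_truth`, `config`.
#' @export
simulate_genome_pair <- function(config = sim_config()) {
  set.seed(config$rng_seed)
  gc <- genetic_code_tbls()
  n_orth <- round(config$frac_orthologous * config$n_genes)
  n_spec <- config$n_genes - n_orth
  n_slots <- config$n_genes + config$n_srnas
  # slots -> contigs, evenly
  cuts <- round(seq(0, n_slots, length.out = config$n_contigs + 1))
  slot_contig <- rep(seq_len(config$n_contigs), times = diff(cuts))
  slots_in_contig <- table(slot_contig)
  slot_len <- as.integer(floor(config$contig_len / max(slots_in_contig)))
  min_slot <- 800 + 600 + 10
  if (slot_len < min_slot) {
    abort(sprintf(
      "infeasible packing: %d features on %d x %d nt leave %d nt per slot (< %d)",
      n_slots, config$n_contigs, config$contig_len, slot_len, min_slot))
  }
  slot_rank <- stats::ave(seq_len(n_slots), slot_contig, FUN = seq_along)
  slot_start <- (slot_rank - 1L) * slot_len + 1L
  contig_ids <- sprintf("c%d", seq_len(config$n_contigs))

  # sRNA slots: interior positions of the ortholog block, never adjacent to a
  # contig boundary or to each other
  block <- n_orth + config$n_srnas
  srna_slots <- integer(0)
  if (config$n_srnas > 0) {
    cand <- setdiff(2:(block - 1), c(which(diff(slot_contig) != 0),
                                     which(diff(slot_contig) != 0) + 1L))
    pick <- unique(round(seq(min(cand), max(cand),
                             length.out = config$n_srnas)))
    if (length(pick) < config$n_srnas || any(diff(sort(pick)) < 2)) {
      abort("cannot place sRNA slots with ortholog-bearing neighbors; reduce n_srnas")
    }
    srna_slots <- sort(pick)
  }
  gene_slots <- setdiff(seq_len(n_slots), srna_slots)
  orth_slots <- gene_slots[seq_len(n_orth)]
  spec_slots <- gene_slots[seq(n_orth + 1, length.out = n_spec)]

  # per-gene geometry, shared between species for ortholog pairs
  gene_plan <- tibble(
    slot = gene_slots,
    is_orth = gene_slots %in% orth_slots,
    len = 3L * sample(100:200, length(gene_slots), replace = TRUE),
    strand = sample(c("+", "-"), length(gene_slots), replace = TRUE)
  ) |>
    mutate(contig = contig_ids[slot_contig[.data$slot]],
           sstart = slot_start[.data$slot],
           gstart = if_else(.data$strand == "+",
                            .data$sstart + slot_len - .data$len - 5L,
                            .data$sstart + 5L),
           gend = .data$gstart + .data$len - 1L,
           tstart = if_else(.data$strand == "+", .data$gstart, .data$gend))

  # CDS per species
  make_genes <- function(sp) {
    gene_plan |>
      mutate(gene_id = sprintf("%s_g%03d", sp, row_number()))
  }
  genes_a <- make_genes("A")
  genes_b <- make_genes("B")
  cds_a <- character(nrow(gene_plan))
  cds_b <- character(nrow(gene_plan))
  for (i in seq_len(nrow(gene_plan))) {
    anc <- random_cds(gene_plan$len[i] / 3L, gc)
    div <- if (gene_plan$is_orth[i]) config$protein_divergence else config$decoy_divergence
    cds_a[i] <- anc
    cds_b[i] <- derive_cds(anc, div, config$syn_rate, gc)
  }

  # genome backgrounds, then write CDSs
  build_genome <- function(cds) {
    seqs <- purrr::map(seq_len(config$n_contigs), ~ random_dna_vec(config$contig_len))
    for (i in seq_len(nrow(gene_plan))) {
      ci <- match(gene_plan$contig[i], contig_ids)
      s <- if (gene_plan$strand[i] == "+") cds[i] else revcomp(cds[i])
      seqs[[ci]] <- put_seq_vec(seqs[[ci]], gene_plan$gstart[i], s)
    }
    seqs
  }
  seq_a <- build_genome(cds_a)
  seq_b <- build_genome(cds_b)

  # sRNAs: annotated locus in A, diverged unannotated copy in B
  srna_truth <- tibble()
  srna_genes_a <- tibble()
  if (config$n_srnas > 0) {
    rows <- list()
    for (k in seq_along(srna_slots)) {
      sl <- srna_slots[k]
      ci <- slot_contig[sl]
      start <- slot_start[sl] + 400L
      end <- start + config$srna_len - 1L
      strand <- sample(c("+", "-"), 1)
      seq_fwd <- random_dna(config$srna_len)
      copy_fwd <- mutate_seq(seq_fwd, config$srna_divergence)
      seq_a[[ci]] <- put_seq_vec(seq_a[[ci]], start, seq_fwd)
      seq_b[[ci]] <- put_seq_vec(seq_b[[ci]], start, copy_fwd)
      five_a <- if (strand == "+") start else end
      rows[[k]] <- tibble(name = sprintf("A_s%02d", k),
                          contig_id = contig_ids[ci],
                          start = start, end = end, strand = strand,
                          five_prime_a = five_a, five_prime_b = five_a)
    }
    srna_truth <- bind_rows(rows)
    srna_genes_a <- tibble(
      gene_id = srna_truth$name, contig_id = srna_truth$contig_id,
      start = srna_truth$start, end = srna_truth$end,
      strand = srna_truth$strand, feature_type = "sRNA",
      protein = NA_character_
    )
  }

  # category assignment over ortholog genes (indices into gene_plan rows)
  orth_rows <- which(gene_plan$is_orth)
  spec_rows <- which(!gene_plan$is_orth)
  mix <- config$category_mix
  take <- function(pool, n) pool[seq_len(n)]
  i_cpt <- take(orth_rows, mix[["CPT"]])
  rest <- setdiff(orth_rows, i_cpt)
  i_cpnt_a <- take(rest, mix[["CPNT"]]); rest <- setdiff(rest, i_cpnt_a)
  i_cpnt_b <- take(rest, mix[["CPNT"]]); rest <- setdiff(rest, i_cpnt_b)
  i_op_a <- take(rest, mix[["OP"]]); rest <- setdiff(rest, i_op_a)
  i_op_b <- take(rest, mix[["OP"]])
  i_ssp_a <- take(spec_rows, mix[["SSP"]])
  i_ssp_b <- take(spec_rows, mix[["SSP"]])

  draw_d <- function() {
    if (runif(1) < config$frac_leaderless) 0L
    else sample(config$utr_range[1]:config$utr_range[2], 1)
  }
  tss_pos <- function(row, d) {
    if (gene_plan$strand[row] == "+") gene_plan$tstart[row] - d
    else gene_plan$tstart[row] + d
  }
  promoter_of <- function(seqs, row, p) {
    ci <- match(gene_plan$contig[row], contig_ids)
    if (gene_plan$strand[row] == "+") read_seq_vec(seqs[[ci]], p - 50, p - 1)
    else revcomp(read_seq_vec(seqs[[ci]], p + 1, p + 50))
  }

  tss_rows <- list()
  add_tss <- function(species, row, pos, category, role, d, gene_id) {
    tss_rows[[length(tss_rows) + 1]] <<- tibble(
      species = species, contig_id = gene_plan$contig[row],
      gene_id = gene_id, position = as.integer(pos),
      strand = gene_plan$strand[row], category = category, role = role,
      leaderless = d == 0
    )
  }
  maybe_secondary <- function(species, row, pos, d, gene_id) {
    if (runif(1) < config$frac_multi_tss && d < 700) {
      off <- sample(15:40, 1)
      p2 <- if (gene_plan$strand[row] == "+") pos - off else pos + off
      add_tss(species, row, p2, NA_character_, "secondary", d + off, gene_id)
    }
  }

  # CPT: TSS in both species; A promoter copied (diverged) upstream of the B
  # TSS, and the start-codon-proximal part of the 5' UTR copied too, so
  # comparable UTR pairs are conserved with possible 5' length extensions
  for (row in i_cpt) {
    d_a <- draw_d()
    d_b <- if (d_a == 0) 0L else max(0L, d_a + as.integer(round(stats::rnorm(1, 3, 6))))
    p_a <- tss_pos(row, d_a)
    p_b <- tss_pos(row, d_b)
    prom <- promoter_of(seq_a, row, p_a)
    ci <- match(gene_plan$contig[row], contig_ids)
    seq_b[[ci]] <- put_promoter(seq_b[[ci]], p_b, gene_plan$strand[row],
                                mutate_seq(prom, config$promoter_divergence))
    m <- min(d_a, d_b)
    if (m > 0) {
      tstart <- gene_plan$tstart[row]
      utr_tail <- if (gene_plan$strand[row] == "+") {
        read_seq_vec(seq_a[[ci]], tstart - m, tstart - 1)
      } else {
        revcomp(read_seq_vec(seq_a[[ci]], tstart + 1, tstart + m))
      }
      seq_b[[ci]] <- put_promoter(seq_b[[ci]], tstart, gene_plan$strand[row],
                                  mutate_seq(utr_tail, config$promoter_divergence))
    }
    add_tss("A", row, p_a, "CPT", "primary", d_a, genes_a$gene_id[row])
    add_tss("B", row, p_b, "CPT", "primary", d_b, genes_b$gene_id[row])
    maybe_secondary("A", row, p_a, d_a, genes_a$gene_id[row])
    maybe_secondary("B", row, p_b, d_b, genes_b$gene_id[row])
  }
  # CPNT: TSS in one species; conserved promoter copy in the other at a
  # phantom position with no TSS
  plant_cpnt <- function(rows_idx, src) {
    for (row in rows_idx) {
      d <- draw_d()
      p <- tss_pos(row, d)
      d_imp <- sample(150:400, 1)
      p_imp <- tss_pos(row, d_imp)
      ci <- match(gene_plan$contig[row], contig_ids)
      if (src == "A") {
        prom <- promoter_of(seq_a, row, p)
        seq_b[[ci]] <<- put_promoter(seq_b[[ci]], p_imp, gene_plan$strand[row],
                                     mutate_seq(prom, config$promoter_divergence))
        add_tss("A", row, p, "CPNT", "primary", d, genes_a$gene_id[row])
        maybe_secondary("A", row, p, d, genes_a$gene_id[row])
      } else {
        prom <- promoter_of(seq_b, row, p)
        seq_a[[ci]] <<- put_promoter(seq_a[[ci]], p_imp, gene_plan$strand[row],
                                     mutate_seq(prom, config$promoter_divergence))
        add_tss("B", row, p, "CPNT", "primary", d, genes_b$gene_id[row])
        maybe_secondary("B", row, p, d, genes_b$gene_id[row])
      }
    }
  }
  plant_cpnt(i_cpnt_a, "A")
  plant_cpnt(i_cpnt_b, "B")
  # OP: TSS in one species, partner upstream left random
  for (row in i_op_a) {
    d <- draw_d(); p <- tss_pos(row, d)
    add_tss("A", row, p, "OP", "primary", d, genes_a$gene_id[row])
    maybe_secondary("A", row, p, d, genes_a$gene_id[row])
  }
  for (row in i_op_b) {
    d <- draw_d(); p <- tss_pos(row, d)
    add_tss("B", row, p, "OP", "primary", d, genes_b$gene_id[row])
    maybe_secondary("B", row, p, d, genes_b$gene_id[row])
  }
  # SSP: TSS on species-specific genes
  for (row in i_ssp_a) {
    d <- draw_d(); p <- tss_pos(row, d)
    add_tss("A", row, p, "SSP", "primary", d, genes_a$gene_id[row])
  }
  for (row in i_ssp_b) {
    d <- draw_d(); p <- tss_pos(row, d)
    add_tss("B", row, p, "SSP", "primary", d, genes_b$gene_id[row])
  }
  # sRNA TSSs at the 5' ends in both species
  if (nrow(srna_truth) > 0) {
    for (k in seq_len(nrow(srna_truth))) {
      s <- srna_truth[k, ]
      tss_rows[[length(tss_rows) + 1]] <- tibble(
        species = c("A", "B"), contig_id = s$contig_id,
        gene_id = c(s$name, NA_character_),
        position = c(s$five_prime_a, s$five_prime_b),
        strand = s$strand, category = NA_character_, role = "srna",
        leaderless = TRUE
      )
    }
  }
  tss_truth <- bind_rows(tss_rows)

  genome_tbl <- function(seqs) {
    str <- purrr::map_chr(seqs, paste0, collapse = "")
    tibble(contig_id = contig_ids, seq = str, length = nchar(str))
  }
  finish_genes <- function(genes, cds) {
    g <- genes |>
      mutate(feature_type = "CDS",
             protein = purrr::map_chr(cds, translate_cds, gc = gc)) |>
      select("gene_id", contig_id = "contig", start = "gstart", end = "gend",
             "strand", "feature_type", "protein")
    g
  }
  genes_a_out <- bind_rows(finish_genes(genes_a, cds_a), srna_genes_a) |>
    arrange(.data$contig_id, .data$start)
  genes_b_out <- finish_genes(genes_b, cds_b) |>
    arrange(.data$contig_id, .data$start)

  orth_truth <- tibble(
    gene_a = genes_a$gene_id, gene_b = genes_b$gene_id,
    decoy = !gene_plan$is_orth
  )
  structure(list(
    genome_a = genome_tbl(seq_a), genome_b = genome_tbl(seq_b),
    genes_a = genes_a_out, genes_b = genes_b_out,
    proteome_a = genes_a_out |> filter(.data$feature_type == "CDS") |>
      select("gene_id", "protein"),
    proteome_b = genes_b_out |> filter(.data$feature_type == "CDS") |>
      select("gene_id", "protein"),
    orthologs = orth_truth, tss_truth = tss_truth, srna_truth = srna_truth,
    config = config
  ), class = "synthetic_truth")
}

#' Simulate replicate 5'-end count tracks from planted truth
#'
#' Every planted TSS receives, in each of two replicates, a negative-binomial
#' read count truncated at 1; background noise positions are placed
#' independently per replicate (Poisson per kb) with geometric counts, so
#' noise rarely survives replicate reconciliation while planted TSSs always
#' appear in both replicates. Deterministic given `config$rng_seed`.
#'
#' @param truth a `synthetic_truth` from [simulate_genome_pair()].
#' @param config the [sim_config()] used (defaults to `truth$config`).
#' @return A list with `a` and `b`, each a list of two replicate count-track
#'   tibbles.
#' @export
simulate_count_tracks <- function(truth, config = truth$config) {
  set.seed(config$rng_seed + 1L)
  genome_len <- sum(truth$genome_a$length)
  one_species <- function(sp, genome) {
    planted <- truth$tss_truth |> filter(.data$species == sp)
    one_rep <- function(r) {
      signal <- planted |>
        mutate(count = pmax(1L, rnbinom(n(), size = config$tss_count_dispersion,
                                        mu = config$tss_count_mean))) |>
        select("contig_id", "position", "strand", "count")
      n_noise <- rpois(1, config$noise_rate * genome_len / 1000)
      noise <- if (n_noise > 0) {
        ci <- sample(genome$contig_id, n_noise, replace = TRUE)
        tibble(
          contig_id = ci,
          position = purrr::map_int(ci, ~ sample.int(contig_length(genome, .x), 1)),
          strand = sample(c("+", "-"), n_noise, replace = TRUE),
          count = rgeom(n_noise, prob = 1 / config$noise_count_mean) + 1L
        )
      } else {
        tibble(contig_id = character(), position = integer(),
               strand = character(), count = integer())
      }
      bind_rows(signal, noise) |>
        group_by(.data$contig_id, .data$strand, .data$position) |>
        summarise(count = as.integer(sum(.data$count)), .groups = "drop") |>
        mutate(replicate = sprintf("rep%d", r)) |>
        arrange(.data$contig_id, .data$strand, .data$position) |>
        select("contig_id", "position", "strand", "count", "replicate")
    }
    list(one_rep(1), one_rep(2))
  }
  list(a = one_species("A", truth$genome_a),
       b = one_species("B", truth$genome_b))
}
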