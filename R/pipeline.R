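#' Full two-species comparison
#'
#' Composes the comparative stages on already-called TSS sets: reciprocal
#' protein orthology, promoter categorization in both directions, comparable
#' 5' UTR pairs and their length/identity statistics, the conservation
#' profile around translation starts, codon-position conservation, and
#' per-species dinucleotide preference at the TSS.
#'
#' @param tss_a,tss_b annotated TSS tibbles from [call_tss()].
#' @param genes_a,genes_b gene tibbles.
#' @param genome_a,genome_b genome tibbles.
#' @param proteome_a,proteome_b tibbles with `gene_id`, `protein`; default:
#'   CDS rows of the gene tables.
#' @param params a [pipeline_params()] list.
#' @param profile_window nt on each side of the start codon for the
#'   conservation profile.
#' @return A list of class `species_comparison`: `orthologs`, `categories`
#'   (both species, row-bound), `category_summary`, `utr_pairs`, `utr_stats`,
#'   `conservation_profile`, `codon_conservation`, `dinuc_a`, `dinuc_b`.
#' @export
compare_species <- function(tss_a, tss_b, genes_a, genes_b, genome_a, genome_b,
                            proteome_a = NULL, proteome_b = NULL,
                            params = pipeline_params(), profile_window = 100) {
  proteome_a <- proteome_a %||%
    (genes_a |> filter(.data$feature_type == "CDS") |> select("gene_id", protein = "protein"))
  proteome_b <- proteome_b %||%
    (genes_b |> filter(.data$feature_type == "CDS") |> select("gene_id", protein = "protein"))
  orthologs <- find_orthologs(proteome_a, proteome_b, params)
  if (sum(orthologs$reciprocal_best) == 0) {
    warn("no reciprocal-best orthologs found: every categorizable promoter will be SSP")
  }
  cat_a <- categorize_promoters(tss_a, tss_b, genes_a, genes_b, genome_a,
                                genome_b, orthologs, params, species = "A")
  orthologs_rev <- orthologs |>
    rename(gene_a = "gene_b", gene_b = "gene_a") |>
    select("gene_a", "gene_b", "pct_identity", "pct_aligned", "reciprocal_best")
  cat_b <- categorize_promoters(tss_b, tss_a, genes_b, genes_a, genome_b,
                                genome_a, orthologs_rev, params, species = "B")
  categories <- bind_rows(cat_a, cat_b)
  utr_pairs <- build_utr_pairs(cat_a, genes_a, genes_b, genome_a, genome_b)
  cons <- conservation_profile(orthologs, genes_a, genes_b, genome_a, genome_b,
                               window = profile_window)
  cds_pairs <- ortholog_cds_pairs(orthologs, genes_a, genes_b, genome_a, genome_b)
  structure(list(
    orthologs = orthologs,
    categories = categories,
    category_summary = summarize_categories(categories),
    utr_pairs = utr_pairs,
    utr_stats = utr_length_stats(utr_pairs),
    conservation_profile = cons,
    codon_conservation = codon_position_conservation(cds_pairs),
    dinuc_a = dinucleotide_preference(tss_a, genome_a),
    dinuc_b = dinucleotide_preference(tss_b, genome_b)
  ), class = "species_comparison")
}

#' @export
print.species_comparison <- function(x, ...) {
  cat("<species_comparison>\n")
  cat(sprintf("  orthologs: %d candidate pairs, %d reciprocal-best\n",
              nrow(x$orthologs), sum(x$orthologs$reciprocal_best)))
  cat(sprintf("  categorized TSSs: %d\n",
              sum(!is.na(x$categories$category))))
  cat(sprintf("  comparable UTR pairs: %d (R^2 = %s)\n", nrow(x$utr_pairs),
              format(x$utr_stats$r_squared, digits = 3)))
  invisible(x)
}

#' One-row summary of a species comparison
#'
#' @param x a `species_comparison`.
#' @param ... unused.
#' @return A one-row tibble of headline quantities.
#' @method glance species_comparison
#' @export
glance.species_comparison <- function(x, ...) {
  cs <- x$category_summary
  n_cpt_a <- cs$n[cs$species == "A" & cs$category == "CPT"]
  tibble(
    n_orthologs = sum(x$orthologs$reciprocal_best),
    n_cpt_pairs = nrow(cpt_pairs(x$categories |> filter(.data$species == "A"))),
    n_cpt_a = n_cpt_a,
    n_utr_pairs = x$utr_stats$n_pairs,
    utr_r_squared = x$utr_stats$r_squared,
    mean_utr_identity = x$utr_stats$mean_identity,
    purine_plus1_a = x$dinuc_a$purine_frac_plus1,
    purine_plus1_b = x$dinuc_b$purine_frac_plus1
  )
}

# run manifest ---------------------------------------------------------------

write_run_manifest <- function(out_dir, command, inputs, params, seed = NULL) {
  inputs <- inputs[!purrr::map_lgl(inputs, is.null)]
  manifest <- list(
    command = command,
    tool = "tsscompare",
    version = as.character(utils::packageVersion("tsscompare")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    rng_seed = seed,
    params = if (inherits(params, "tss_params")) unclass(params) else params,
    inputs = purrr::imap(inputs, function(p, nm) {
      list(path = p, md5 = unname(tools::md5sum(p)))
    })
  )
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(manifest)
}

#' Simulate a genome pair and write the bundle to disk
#'
#' Writes, per species: genome FASTA, annotation GFF3, two replicate count
#' tracks (TSV), plus the planted truth tables and a run manifest.
#'
#' @param config a [sim_config()] list.
#' @param out_dir output directory (created if needed).
#' @return The `synthetic_truth`, invisibly.
#' @export
run_simulate <- function(config = sim_config(), out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  truth <- simulate_genome_pair(config)
  tracks <- simulate_count_tracks(truth, config)
  for (sp in c("a", "b")) {
    write_genome_fasta(truth[[paste0("genome_", sp)]],
                       file.path(out_dir, sprintf("genome_%s.fasta", sp)))
    write_gene_annotation(truth[[paste0("genes_", sp)]],
                          file.path(out_dir, sprintf("genes_%s.gff3", sp)))
    prot <- truth[[paste0("proteome_", sp)]]
    write_fasta(prot$gene_id, prot$protein,
                file.path(out_dir, sprintf("proteins_%s.fasta", sp)),
                alphabet = "aa")
    for (r in 1:2) {
      write_count_track_tsv(tracks[[sp]][[r]],
                            file.path(out_dir, sprintf("track_%s_rep%d.tsv", sp, r)))
    }
  }
  readr::write_tsv(truth$tss_truth, file.path(out_dir, "truth_tss.tsv"))
  readr::write_tsv(truth$orthologs, file.path(out_dir, "truth_orthologs.tsv"))
  if (nrow(truth$srna_truth) > 0) {
    readr::write_tsv(truth$srna_truth, file.path(out_dir, "truth_srna.tsv"))
  }
  write_run_manifest(out_dir, "simulate", list(), unclass(config),
                     seed = config$rng_seed)
  invisible(truth)
}

#' Call TSSs from files and write the result tables
#'
#' File-level wrapper over [call_tss()]: reads a genome FASTA, a GFF3
#' annotation and two replicate count tracks (TSV), and writes the TSS table
#' (TSV), a BED6 track and a run manifest into `out_dir`.
#'
#' @param genome_path,gff_path,track1_path,track2_path input files.
#' @param out_dir output directory.
#' @param params a [pipeline_params()] list.
#' @return The annotated TSS tibble, invisibly.
#' @export
run_call_tss <- function(genome_path, gff_path, track1_path, track2_path,
                         out_dir, params = pipeline_params()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  genome <- read_genome_fasta(genome_path)
  genes <- read_gene_annotation(gff_path, genome)
  t1 <- read_count_track_tsv(track1_path, "rep1", genome)
  t2 <- read_count_track_tsv(track2_path, "rep2", genome)
  tss <- call_tss(t1, t2, genes, params)
  write_tss_table(tss, file.path(out_dir, "tss.tsv"))
  write_tss_bed(tss, file.path(out_dir, "tss.bed"))
  write_run_manifest(out_dir, "call-tss",
                     list(genome = genome_path, gff = gff_path,
                          track1 = track1_path, track2 = track2_path),
                     params, seed = params$rng_seed)
  invisible(tss)
}

#' Compare two species from simulated or on-disk bundles
#'
#' File-level wrapper over [compare_species()] for bundles laid out as
#' written by [run_simulate()]: calls TSSs for both species, runs the
#' comparison, and writes the ortholog table, categorization table, category
#' summary, UTR pair table and stats, conservation profile and dinucleotide
#' tables, plus a manifest.
#'
#' @param bundle_dir directory holding `genome_[ab].fasta`,
#'   `genes_[ab].gff3`, `track_[ab]_rep[12].tsv`.
#' @param out_dir output directory.
#' @param params a [pipeline_params()] list.
#' @return The `species_comparison`, invisibly.
#' @export
run_compare_species <- function(bundle_dir, out_dir, params = pipeline_params()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  load_sp <- function(sp) {
    genome <- read_genome_fasta(file.path(bundle_dir, sprintf("genome_%s.fasta", sp)))
    genes <- read_gene_annotation(file.path(bundle_dir, sprintf("genes_%s.gff3", sp)), genome)
    t1 <- read_count_track_tsv(file.path(bundle_dir, sprintf("track_%s_rep1.tsv", sp)), "rep1", genome)
    t2 <- read_count_track_tsv(file.path(bundle_dir, sprintf("track_%s_rep2.tsv", sp)), "rep2", genome)
    prot <- read_protein_fasta(file.path(bundle_dir, sprintf("proteins_%s.fasta", sp)))
    list(genome = genome, genes = genes, proteome = prot,
         tss = call_tss(t1, t2, genes, params))
  }
  a <- load_sp("a"); b <- load_sp("b")
  cmp <- compare_species(a$tss, b$tss, a$genes, b$genes, a$genome, b$genome,
                         proteome_a = a$proteome, proteome_b = b$proteome,
                         params = params)
  write_ortholog_table(cmp$orthologs, file.path(out_dir, "orthologs.tsv"))
  readr::write_tsv(cmp$categories, file.path(out_dir, "categories.tsv"))
  readr::write_tsv(cmp$category_summary, file.path(out_dir, "category_summary.tsv"))
  readr::write_tsv(cmp$utr_pairs |> select(-"seq_a", -"seq_b"),
                   file.path(out_dir, "utr_pairs.tsv"))
  readr::write_tsv(cmp$utr_stats, file.path(out_dir, "utr_stats.tsv"))
  readr::write_tsv(cmp$conservation_profile,
                   file.path(out_dir, "conservation_profile.tsv"))
  readr::write_tsv(tidy(cmp$dinuc_a), file.path(out_dir, "dinuc_a.tsv"))
  readr::write_tsv(tidy(cmp$dinuc_b), file.path(out_dir, "dinuc_b.tsv"))
  write_run_manifest(out_dir, "compare", list(bundle = bundle_dir), params,
                     seed = params$rng_seed)
  invisible(cmp)
}

#' Scan for sRNA homologs from an on-disk bundle
#'
#' @param bundle_dir bundle directory as for [run_compare_species()]; species
#'   A must carry sRNA annotations.
#' @param out_dir output directory.
#' @param params a [pipeline_params()] list.
#' @return The candidate tibble, invisibly.
#' @export
run_srna_scan <- function(bundle_dir, out_dir, params = pipeline_params()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  genome_a <- read_genome_fasta(file.path(bundle_dir, "genome_a.fasta"))
  genome_b <- read_genome_fasta(file.path(bundle_dir, "genome_b.fasta"))
  genes_a <- read_gene_annotation(file.path(bundle_dir, "genes_a.gff3"), genome_a)
  genes_b <- read_gene_annotation(file.path(bundle_dir, "genes_b.gff3"), genome_b)
  tss_b <- call_tss(
    read_count_track_tsv(file.path(bundle_dir, "track_b_rep1.tsv"), "rep1", genome_b),
    read_count_track_tsv(file.path(bundle_dir, "track_b_rep2.tsv"), "rep2", genome_b),
    genes_b, params)
  orthologs <- find_orthologs(
    read_protein_fasta(file.path(bundle_dir, "proteins_a.fasta")),
    read_protein_fasta(file.path(bundle_dir, "proteins_b.fasta")), params)
  cands <- scan_srna_homologs(genes_a, genes_b, orthologs, genome_a, genome_b,
                              tss_b, params)
  readr::write_tsv(cands, file.path(out_dir, "srna_candidates.tsv"))
  write_run_manifest(out_dir, "srna-scan", list(bundle = bundle_dir), params,
                     seed = params$rng_seed)
  invisible(cands)
}
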