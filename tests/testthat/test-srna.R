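srna_genes <- function() {
  tibble::tibble(
    gene_id = c("g1", "g2", "s1"), contig_id = "c1",
    start = c(500L, 2000L, 1500L), end = c(1000L, 2500L, 1560L),
    strand = c("+", "-", "+"),
    feature_type = c("CDS", "CDS", "sRNA"), protein = NA_character_
  )
}

orth_fix <- function(b_names = c("o1", "o2")) {
  tibble::tibble(gene_a = c("g1", "g2"), gene_b = b_names,
                 pct_identity = 90, pct_aligned = 95, reciprocal_best = TRUE)
}

b_genes <- function(o1 = c(4000L, 5000L), o2 = c(7000L, 7500L)) {
  tibble::tibble(gene_id = c("o1", "o2"), contig_id = "c1",
                 start = c(o1[1], o2[1]), end = c(o1[2], o2[2]),
                 strand = c("+", "+"), feature_type = "CDS",
                 protein = NA_character_)
}

test_that("synteny intervals span the gap between flanking orthologs", {
  set.seed(90)
  gb <- tiny_genome(random_seq(20000))
  srna <- srna_genes()[3, ]
  iv <- synteny_interval(srna, srna_genes(), b_genes(), orth_fix(), gb)
  expect_equal(c(iv$start, iv$end), c(5001L, 6999L))
  expect_equal(iv$left_gene_b, "o1")

  # inverted order in B: min/max keeps the interval well-formed
  iv2 <- synteny_interval(srna, srna_genes(),
                          b_genes(o1 = c(7000L, 8000L), o2 = c(1000L, 2000L)),
                          orth_fix(), gb)
  expect_equal(c(iv2$start, iv2$end), c(2001L, 6999L))

  # interval does not depend on the strands of the flanking genes
  flipped <- b_genes()
  flipped$strand <- c("-", "-")
  iv3 <- synteny_interval(srna, srna_genes(), flipped, orth_fix(), gb)
  expect_equal(c(iv3$start, iv3$end), c(5001L, 6999L))
})

test_that("a missing flank caps the interval at 10 kb, clipped to the contig", {
  set.seed(91)
  gb <- tiny_genome(random_seq(12000))
  genes_a <- srna_genes()
  genes_a$start[2] <- 200L; genes_a$end[2] <- 400L  # g2 now left of the sRNA
  # only g1 has an ortholog: right flank missing in B
  orth <- orth_fix()[1, ]
  iv <- synteny_interval(genes_a[3, ], genes_a, b_genes()[1, ], orth, gb)
  expect_equal(c(iv$start, iv$end), c(5001L, 12000L))  # clipped at contig end
  expect_true(is.na(iv$right_gene_b))

  expect_error(
    synteny_interval(genes_a[3, ], genes_a, b_genes(), orth_fix()[0, ], gb),
    "no ortholog-bearing")
})

test_that("planted homologs are found on either strand with exact 5' ends", {
  set.seed(92)
  srna_seq <- random_seq(80)
  gb_seq <- random_seq(3000)
  substr(gb_seq, 1200, 1279) <- srna_seq
  gb <- tiny_genome(gb_seq)
  iv <- tibble::tibble(contig_id = "c1", start = 1000L, end = 2000L)
  hit <- find_srna_homolog(srna_seq, gb, iv, name = "sx")
  expect_equal(hit$strand, "+")
  expect_equal(c(hit$hit_start, hit$hit_end), c(1200L, 1279L))
  expect_equal(hit$five_prime, 1200L)
  expect_equal(hit$pct_identity, 100)
  expect_equal(hit$coverage, 1.0)

  # reverse-complement copy: hit on the minus strand, 5' end at the right edge
  gb2_seq <- random_seq(3000)
  substr(gb2_seq, 1200, 1279) <- revcomp(srna_seq)
  hit2 <- find_srna_homolog(srna_seq, tiny_genome(gb2_seq), iv)
  expect_equal(hit2$strand, "-")
  expect_equal(hit2$five_prime, 1279L)

  # random interval: nothing acceptable
  none <- find_srna_homolog(srna_seq, tiny_genome(random_seq(3000)), iv)
  expect_equal(nrow(none), 0L)
})

test_that("diverged homologs pass thresholds and extrapolate the 5' end", {
  set.seed(93)
  srna_seq <- random_seq(100)
  ch <- strsplit(srna_seq, "")[[1]]
  for (i in sample(5:96, 10)) ch[i] <- sample(setdiff(c("A","C","G","T"), ch[i]), 1)
  gb_seq <- random_seq(3000)
  substr(gb_seq, 1500, 1599) <- paste0(ch, collapse = "")
  hit <- find_srna_homolog(srna_seq, tiny_genome(gb_seq),
                           tibble::tibble(contig_id = "c1", start = 1000L,
                                          end = 2200L))
  expect_equal(nrow(hit), 1L)
  expect_lte(abs(hit$five_prime - 1500L), 2L)
  expect_gte(hit$coverage, 0.6)
})

test_that("expression confirmation respects the 5'-end tolerance", {
  cand <- tibble::tibble(name = "s", contig_id = "c1", hit_start = 1200L,
                         hit_end = 1279L, strand = "+", five_prime = 1200L,
                         pct_identity = 100, coverage = 1)
  tss_at <- function(p) mk_tss(p)
  expect_true(confirm_expression(cand, tss_at(1200))$expressed)
  expect_true(confirm_expression(cand, tss_at(1202))$expressed)  # boundary
  out <- confirm_expression(cand, tss_at(1210))
  expect_false(out$expressed)
  expect_true(is.na(out$tss_support))
  # monotone in tolerance
  wide <- pipeline_params(srna_tss_tol = 12)
  expect_true(confirm_expression(cand, tss_at(1210), wide)$expressed)
  # strand mismatch never supports
  expect_false(confirm_expression(cand, mk_tss(1200, strand = "-"))$expressed)
})

test_that("target sites project through alignments with identities", {
  set.seed(94)
  s <- random_seq(60)
  m_aln <- align_global(s, s)
  s_aln <- align_global(random_seq(40), random_seq(40))
  sites <- tibble::tibble(site_name = "site1", mrna_start = 10L, mrna_end = 20L,
                          srna_start = 5L, srna_end = 15L)
  out <- map_target_sites(s_aln, m_aln, sites)
  expect_equal(c(out$site_b_start, out$site_b_end), c(10L, 20L))
  expect_equal(out$site_pct_identity, 100)
  expect_true(out$projected)

  # a 3-nt insertion in B upstream of the site shifts the projection
  ins <- new_pw_alignment("5M3D55M", c(1, 60), c(1, 63), 60,
                          q_aln = paste0(substr(s, 1, 5), "---", substr(s, 6, 60)),
                          t_aln = paste0(substr(s, 1, 5), "NNN", substr(s, 6, 60)))
  out2 <- map_target_sites(NULL, ins, sites)
  expect_equal(c(out2$site_b_start, out2$site_b_end), c(13L, 23L))

  # site opposite a gap in B: flagged unprojectable
  gap <- new_pw_alignment("8M15I37M", c(1, 60), c(1, 45), 45,
                          q_aln = s,
                          t_aln = paste0(substr(s, 1, 8), strrep("-", 15),
                                         substr(s, 24, 60)))
  out3 <- map_target_sites(NULL, gap, sites)
  expect_false(out3$projected)
  expect_equal(out3$mapped_fraction, 0)

  # site outside the aligned span: flagged, not dropped
  part <- new_pw_alignment("10M", c(30, 39), c(1, 10), 10)
  out4 <- map_target_sites(NULL, part, sites)
  expect_false(out4$projected)
})

test_that("scanning annotated sRNAs composes intervals, hits and expression", {
  truth <- small_truth()
  tracks <- simulate_count_tracks(truth)
  tss_b <- call_tss(tracks$b[[1]], tracks$b[[2]], truth$genes_b)
  orthologs <- truth$orthologs |>
    dplyr::filter(!decoy) |>
    dplyr::mutate(pct_identity = 95, pct_aligned = 100, reciprocal_best = TRUE)
  cands <- scan_srna_homologs(truth$genes_a, truth$genes_b, orthologs,
                              truth$genome_a, truth$genome_b, tss_b)
  ev <- evaluate_srna_recovery(cands, truth$srna_truth)
  expect_equal(ev$recall, 1)
  expect_equal(ev$frac_expressed, 1)

  # an external hit table merges into expression confirmation
  extra <- cands[1, ]
  extra$name <- "external_hit"
  with_extra <- scan_srna_homologs(truth$genes_a, truth$genes_b, orthologs,
                                   truth$genome_a, truth$genome_b, tss_b,
                                   extra_hits = extra[, 1:8])
  expect_true("external_hit" %in% with_extra$name)

  # no sRNA annotations: empty result, no error
  none <- scan_srna_homologs(truth$genes_b, truth$genes_a,
                             dplyr::rename(orthologs, gene_a = gene_b,
                                           gene_b = gene_a),
                             truth$genome_b, truth$genome_a, tss_b)
  expect_equal(nrow(none), 0L)
})
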