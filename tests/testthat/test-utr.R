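test_that("UTR length equals the TSS distance to the translation start", {
  expect_equal(utr_length(mk_tss(100, gene = "g", dist = 30L)), 30L)
  expect_equal(utr_length(mk_tss(2866139, "-", gene = "rpoS", dist = 566L)),
               566L)
  expect_equal(utr_length(mk_tss(130, gene = "g", dist = 0L)), 0L)
  expect_error(utr_length(mk_tss(100)), "not assigned")
})

# build a CPT pair context where the two UTR sequences are fully controlled:
# genes on +, translation starts at 3000, TSS at 3000 - len
utr_ctx <- function(seq_utr_a, seq_utr_b, seed = 80) {
  set.seed(seed)
  sa <- random_seq(4000); sb <- random_seq(4000)
  la <- nchar(seq_utr_a); lb <- nchar(seq_utr_b)
  if (la > 0) substr(sa, 3000 - la, 2999) <- seq_utr_a
  if (lb > 0) substr(sb, 3000 - lb, 2999) <- seq_utr_b
  gene <- function(id) tibble::tibble(
    gene_id = id, contig_id = "c1", start = 3000L, end = 3599L, strand = "+",
    feature_type = "CDS", protein = NA_character_)
  cpt <- tibble::tibble(
    species = "A", contig_id = "c1", position = 3000L - la, strand = "+",
    gene_id = "gA", category = "CPT", partner_gene = "gB",
    partner_position = 3000L - lb, implied_partner_position = 3000L - lb,
    fwd_identity = 1, flag = NA_character_)
  list(cpt = cpt, genes_a = gene("gA"), genes_b = gene("gB"),
       genome_a = tiny_genome(sa), genome_b = tiny_genome(sb))
}

test_that("UTR pairs carry lengths, sequences and global identity", {
  u <- utr_ctx(strrep("ACGTAC", 5), strrep("ACGTAC", 5))
  p <- build_utr_pairs(u$cpt, u$genes_a, u$genes_b, u$genome_a, u$genome_b)
  expect_equal(p$len_a, 30L)
  expect_equal(p$pct_identity, 100)

  u2 <- utr_ctx("ACGTACGTAC", "ACGTACGTTC")
  p2 <- build_utr_pairs(u2$cpt, u2$genes_a, u2$genes_b, u2$genome_a, u2$genome_b)
  expect_equal(p2$pct_identity, 90)

  # leaderless member: lengths kept, identity flagged undefined
  u3 <- utr_ctx("ACGTACGTAC", "")
  p3 <- build_utr_pairs(u3$cpt, u3$genes_a, u3$genes_b, u3$genome_a, u3$genome_b)
  expect_true(p3$leaderless_member)
  expect_true(is.na(p3$pct_identity))
  expect_equal(p3$len_b, 0L)
})

test_that("planted 20% UTR divergence is recovered within 5 points", {
  set.seed(81)
  ids <- numeric(20)
  for (k in 1:20) {
    a <- random_seq(60)
    ch <- strsplit(a, "")[[1]]
    idx <- sample(60, 12)  # exactly 20% of sites substituted
    for (i in idx) ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1)
    u <- utr_ctx(a, paste0(ch, collapse = ""), seed = 500 + k)
    ids[k] <- build_utr_pairs(u$cpt, u$genes_a, u$genes_b,
                              u$genome_a, u$genome_b)$pct_identity
  }
  expect_lt(abs(mean(ids) - 80), 5)
})

test_that("UTR length statistics match direct computation", {
  pairs <- tibble::tibble(len_a = c(10, 20, 30), len_b = c(20, 35, 55),
                          pct_identity = c(90, 80, 70))
  st <- utr_length_stats(pairs)
  expect_equal(st$r_squared, 0.9932432432, tolerance = 1e-9)
  expect_equal(st$n_equal_length, 0L)
  expect_equal(st$mean_identity, 80)

  same <- tibble::tibble(len_a = c(5, 10, 30), len_b = c(5, 10, 30),
                         pct_identity = 100)
  st2 <- utr_length_stats(same)
  expect_equal(st2$r_squared, 1.0)
  expect_equal(st2$n_equal_length, 3L)

  # swapping species leaves R^2 unchanged
  swapped <- dplyr::rename(pairs, len_a = len_b, len_b = len_a)
  expect_equal(utr_length_stats(swapped)$r_squared, st$r_squared)

  expect_warning(one <- utr_length_stats(pairs[1, ]), "undefined")
  expect_true(is.na(one$r_squared))
  expect_warning(flat <- utr_length_stats(
    tibble::tibble(len_a = c(7, 7), len_b = c(9, 12), pct_identity = 100)),
    "undefined")
  expect_true(is.na(flat$r_squared))
})

# one-gene-per-contig genome pairs with controlled 200-nt start regions
profile_ctx <- function(n_pairs, mutate_offsets = NULL, rate = 0, seed = 82) {
  set.seed(seed)
  contigs <- sprintf("k%d", seq_len(n_pairs))
  mk <- function() {
    purrr::map_chr(contigs, ~ random_seq(1000))
  }
  sa <- mk()
  sb <- sa  # start from identical, then mutate B
  muts <- list()
  for (i in seq_len(n_pairs)) {
    ch <- strsplit(sb[i], "")[[1]]
    # CDS occupies [500, 799]; ensure a shared ATG start for realism
    idx <- integer(0)
    if (!is.null(mutate_offsets)) idx <- 500 + mutate_offsets
    if (rate > 0) idx <- which(runif(1000) < rate)
    for (p in idx) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
    muts[[i]] <- idx
    sb[i] <- paste0(ch, collapse = "")
  }
  gene <- function(ids) tibble::tibble(
    gene_id = ids, contig_id = contigs, start = 500L, end = 799L,
    strand = "+", feature_type = "CDS", protein = NA_character_)
  list(
    genome_a = tibble::tibble(contig_id = contigs, seq = sa, length = 1000L),
    genome_b = tibble::tibble(contig_id = contigs, seq = sb, length = 1000L),
    genes_a = gene(sprintf("a%d", seq_len(n_pairs))),
    genes_b = gene(sprintf("b%d", seq_len(n_pairs))),
    orthologs = tibble::tibble(gene_a = sprintf("a%d", seq_len(n_pairs)),
                               gene_b = sprintf("b%d", seq_len(n_pairs)),
                               pct_identity = 100, pct_aligned = 100,
                               reciprocal_best = TRUE),
    muts = muts
  )
}

test_that("conservation profile is 1 for identical genomes and local to a change", {
  ctx <- profile_ctx(2)
  prof <- conservation_profile(ctx$orthologs, ctx$genes_a, ctx$genes_b,
                               ctx$genome_a, ctx$genome_b, window = 100)
  expect_equal(nrow(prof), 200L)
  expect_equal(prof$offset, c(-100:-1, 0:99))
  expect_true(all(prof$frac_identical == 1))
  expect_true(all(prof$n_pairs == 2))

  # a single change at offset +5 in one of two pairs
  ctx2 <- profile_ctx(1, mutate_offsets = 5)
  prof2 <- conservation_profile(ctx2$orthologs, ctx2$genes_a, ctx2$genes_b,
                                ctx2$genome_a, ctx2$genome_b, window = 100)
  expect_equal(prof2$frac_identical[prof2$offset == 5], 0)
  expect_true(all(prof2$frac_identical[prof2$offset != 5] == 1))
})

test_that("conservation profile equals a direct per-column count", {
  ctx <- profile_ctx(10, rate = 0.08, seed = 83)
  prof <- conservation_profile(ctx$orthologs, ctx$genes_a, ctx$genes_b,
                               ctx$genome_a, ctx$genome_b, window = 100)
  # independent count straight from the genome strings
  direct <- purrr::map(1:10, function(i) {
    a <- strsplit(substr(ctx$genome_a$seq[i], 400, 599), "")[[1]]
    b <- strsplit(substr(ctx$genome_b$seq[i], 400, 599), "")[[1]]
    as.integer(a == b)
  })
  expected <- colMeans(do.call(rbind, direct))
  expect_equal(prof$frac_identical, expected)
})

test_that("codon-position conservation recovers planted substitution rates", {
  cds_pair <- function(n_codons, rates, seed) {
    set.seed(seed)
    gc <- Biostrings::GENETIC_CODE
    sense <- names(gc)[gc != "*"]
    a <- c("ATG", sample(sense, n_codons - 2, replace = TRUE), "TAA")
    a_str <- paste0(a, collapse = "")
    ch <- strsplit(a_str, "")[[1]]
    for (p in seq(4, length(ch) - 3)) {
      cp <- (p - 1) %% 3 + 1
      if (runif(1) < rates[cp]) ch[p] <- sample(setdiff(c("A","C","G","T"), ch[p]), 1)
    }
    tibble::tibble(cds_a = a_str, cds_b = paste0(ch, collapse = ""))
  }
  ident <- codon_position_conservation(cds_pair(200, c(0, 0, 0), 1))
  expect_equal(ident$frac_identical, c(1, 1, 1))

  syn <- codon_position_conservation(cds_pair(200, c(0, 0, 0.5), 2))
  expect_equal(syn$frac_identical[1:2], c(1, 1))
  expect_lt(syn$frac_identical[3], 1)

  rates <- c(0.1, 0.05, 0.3)
  cc <- codon_position_conservation(cds_pair(700, rates, 3))
  for (cp in 1:3) {
    se <- sqrt(rates[cp] * (1 - rates[cp]) / cc$n_columns[cp])
    expect_lt(abs(cc$frac_identical[cp] - (1 - rates[cp])), 3 * se + 1e-9)
  }

  expect_warning(
    codon_position_conservation(tibble::tibble(cds_a = "ATGAA", cds_b = "ATGAA")),
    "divisible")
})

test_that("dinucleotide preference reads strand-aware offsets", {
  # genome engineered so every TSS has A at +1 and C at -1
  seq <- strrep("G", 400)
  for (p in c(100, 200)) {
    substr(seq, p, p) <- "A"; substr(seq, p - 1, p - 1) <- "C"
  }
  # minus-strand TSS at 300: +1 base is complement of position 300 => place T;
  # -1 is complement of 301 => place G
  substr(seq, 300, 300) <- "T"; substr(seq, 301, 301) <- "G"
  g <- tiny_genome(seq)
  tss <- dplyr::bind_rows(mk_tss(100), mk_tss(200), mk_tss(300, strand = "-"))
  d <- dinucleotide_preference(tss, g)
  expect_equal(d$purine_frac_plus1, 100)
  expect_equal(d$pyrimidine_frac_minus1, 100)
  # per-offset fractions always sum to 1
  sums <- tidy(d) |> dplyr::group_by(offset) |>
    dplyr::summarise(s = sum(fraction))
  expect_equal(sums$s, rep(1, 10))
  expect_equal(glance(d)$n_tss, 3L)
  expect_error(dinucleotide_preference(mk_tss(integer(0)), g), "empty")
})

test_that("dinucleotide estimates recover a planted purine rate", {
  set.seed(85)
  n <- 1000
  seq <- random_seq(15000)
  pos <- seq(20, by = 14, length.out = n)
  purine <- runif(n) < 0.8
  for (i in seq_len(n)) {
    b <- if (purine[i]) sample(c("A", "G"), 1) else sample(c("C", "T"), 1)
    substr(seq, pos[i], pos[i]) <- b
  }
  d <- dinucleotide_preference(mk_tss(pos), tiny_genome(seq))
  se <- sqrt(0.8 * 0.2 / n) * 100
  expect_lt(abs(d$purine_frac_plus1 - 80), 3 * se)
})

test_that("motif input extraction writes one record per eligible region", {
  set.seed(86)
  g <- tiny_genome(random_seq(2000))
  genes <- tibble::tibble(gene_id = "g1", contig_id = "c1", start = 1000L,
                          end = 1500L, strand = "+", feature_type = "CDS",
                          protein = NA_character_)
  tss <- dplyr::bind_rows(mk_tss(950, gene = "g1", dist = 50L),
                          mk_tss(1000, gene = "g1", dist = 0L))
  pr <- extract_motif_inputs(tss, g, region = "promoter50")
  expect_equal(nrow(pr), 2L)
  expect_equal(nchar(pr$seq), c(50L, 50L))

  expect_warning(
    ut <- extract_motif_inputs(tss, g, genes = genes, region = "utr"),
    "leaderless")
  expect_equal(nrow(ut), 1L)  # the leaderless TSS is skipped
  expect_equal(ut$seq, extract_region(g, "c1", 950, 999, "+"))

  fa <- withr::local_tempfile(fileext = ".fa")
  extract_motif_inputs(tss, g, region = "promoter50", path = fa)
  expect_equal(length(Biostrings::readDNAStringSet(fa)), 2L)
})
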