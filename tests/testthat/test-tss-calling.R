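test_that("replicate reconciliation keeps only positions present in both", {
  r1 <- make_track(data.frame(pos = c(100, 200), count = c(5, 3), strand = "+"))
  r2 <- make_track(data.frame(pos = 100, count = 2, strand = "+"), "rep2")
  out <- reconcile_replicates(r1, r2)
  expect_equal(nrow(out), 1L)
  expect_equal(out$position, 100L)
  expect_equal(out$combined_count, 7L)

  m1 <- make_track(data.frame(pos = 50, count = 4, strand = "-"))
  m2 <- make_track(data.frame(pos = 50, count = 1, strand = "-"), "rep2")
  expect_equal(reconcile_replicates(m1, m2)$combined_count, 5L)

  empty <- make_track(data.frame(pos = integer(0), count = integer(0),
                                 strand = character(0)))
  expect_equal(nrow(reconcile_replicates(r1, empty)), 0L)

  other <- make_track(data.frame(pos = 100, count = 5, strand = "+",
                                 contig = "c9"))
  expect_error(reconcile_replicates(r1, other), "no contig")
})

test_that("replicate counts can be averaged instead of summed", {
  r1 <- make_track(data.frame(pos = 100, count = 6, strand = "+"))
  r2 <- make_track(data.frame(pos = 100, count = 2, strand = "+"), "rep2")
  p <- pipeline_params(combine_replicates = "mean")
  expect_equal(reconcile_replicates(r1, r2, p)$combined_count, 4)
})

cand <- function(pos, count, strand = "+") {
  tibble::tibble(contig_id = "c1", position = as.integer(pos), strand = strand,
                 count_rep1 = 1L, count_rep2 = 1L,
                 combined_count = as.numeric(count))
}

test_that("local-noise suppression enforces the window with fixed ties", {
  # Delta = 5 < 10: weaker candidate suppressed
  out <- suppress_local_noise(cand(c(100, 105), c(50, 10)))
  expect_equal(out$position, 100L)
  # boundary Delta = 10 allowed
  out2 <- suppress_local_noise(cand(c(100, 110), c(50, 10)))
  expect_equal(out2$position, c(100L, 110L))
  # equal counts: lower coordinate wins
  out3 <- suppress_local_noise(cand(c(100, 104), c(10, 10)))
  expect_equal(out3$position, 100L)
  # empty input passes through
  expect_equal(nrow(suppress_local_noise(cand(integer(0), numeric(0)))), 0L)
})

test_that("suppression matches the priority-order oracle on random inputs", {
  set.seed(21)
  for (k in 1:20) {
    n <- 50
    pos <- sample(1:300, n)
    count <- sample(1:40, n, replace = TRUE)
    got <- suppress_local_noise(cand(pos, count))
    expect_equal(sort(got$position), suppress_oracle(pos, count, 10))
    # invariant: retained TSSs on one strand are >= window apart
    expect_true(all(diff(sort(got$position)) >= 10))
  }
})

test_that("suppression treats strands and contigs independently", {
  x <- dplyr::bind_rows(cand(c(100, 105), c(50, 10), "+"),
                        cand(c(103, 111), c(40, 39), "-"))
  out <- suppress_local_noise(x)
  # each strand independently loses its weaker close candidate
  expect_equal(nrow(out), 2L)
  expect_equal(out$position[out$strand == "+"], 100L)
  expect_equal(out$position[out$strand == "-"], 103L)
})

genes_fix <- tibble::tibble(
  gene_id = c("g1", "g2"), contig_id = "c1", start = c(1000L, 3000L),
  end = c(1900L, 3900L), strand = "+", feature_type = "CDS",
  protein = NA_character_
)

test_that("TSSs are assigned to the nearest downstream start within 700 bp", {
  tss <- cand(c(950, 250, 1000, 1100), c(10, 10, 10, 10))
  out <- assign_to_genes(tss, genes_fix)
  expect_equal(out$gene_id, c("g1", NA, "g1", NA))  # 250 is 750 away: cutoff
  expect_equal(out$dist_to_start, c(50L, NA, 0L, NA))
  expect_equal(out$leaderless, c(FALSE, FALSE, TRUE, FALSE))
  # 1100 is internal to g1 (downstream of its start) and > 700 from g2
})

test_that("a TSS inside an upstream gene still reaches the downstream start", {
  # TSS at 1800 sits inside g1's span but belongs to g2 (distance 1200 > 700
  # fails; use a closer gene to show the intervening ORF is ignored)
  genes <- dplyr::bind_rows(genes_fix,
                            tibble::tibble(gene_id = "g3", contig_id = "c1",
                                           start = 2100L, end = 2600L,
                                           strand = "+", feature_type = "CDS",
                                           protein = NA_character_))
  out <- assign_to_genes(cand(1800, 10), genes)
  expect_equal(out$gene_id, "g3")
  expect_equal(out$dist_to_start, 300L)
})

test_that("minus-strand assignment reproduces the rpoS distance", {
  genes <- tibble::tibble(gene_id = "rpoS", contig_id = "c1",
                          start = 2864581L, end = 2865573L, strand = "-",
                          feature_type = "CDS", protein = NA_character_)
  out <- assign_to_genes(cand(2866139, 30, strand = "-"), genes)
  expect_equal(out$gene_id, "rpoS")
  expect_equal(out$dist_to_start, 566L)
})

test_that("the >= 50% multiple-TSS rule retains and flags correctly", {
  tss3 <- assign_to_genes(cand(c(950, 960, 980), c(100, 60, 40)), genes_fix)
  out <- call_multiple_tss(tss3)
  expect_equal(out$retained_in_gene, c(TRUE, TRUE, FALSE))  # 40 < 50
  expect_equal(out$is_primary, c(TRUE, FALSE, FALSE))

  one <- call_multiple_tss(assign_to_genes(cand(950, 100), genes_fix))
  expect_true(one$retained_in_gene)

  # boundary: 10 >= 0.5 * 20
  two <- call_multiple_tss(assign_to_genes(cand(c(950, 960), c(20, 10)),
                                           genes_fix))
  expect_equal(two$retained_in_gene, c(TRUE, TRUE))
})

test_that("per-gene TSS counts summarize retained TSSs only", {
  tss <- call_multiple_tss(
    assign_to_genes(cand(c(950, 960, 980, 2950), c(100, 60, 40, 30)),
                    genes_fix))
  pg <- tss_per_gene(tss)
  expect_equal(pg$n_tss[pg$gene_id == "g1"], 2L)
  expect_equal(pg$n_tss[pg$gene_id == "g2"], 1L)
})

test_that("TSS set comparison applies the positional tolerance", {
  ref <- tibble::tibble(contig_id = "c1", position = 100L, strand = "+")
  q <- function(p, s = "+") tibble::tibble(contig_id = "c1",
                                           position = as.integer(p), strand = s)
  expect_equal(compare_tss_sets(ref, q(100), 3)$n_exact, 1L)
  r2 <- compare_tss_sets(ref, q(103), 3)
  expect_equal(c(r2$n_exact, r2$n_within_tol), c(0L, 1L))
  expect_equal(compare_tss_sets(ref, q(104), 3)$n_within_tol, 0L)
  # strand must agree
  expect_equal(compare_tss_sets(ref, q(100, "-"), 3)$n_exact, 0L)
  expect_error(compare_tss_sets(ref, q(100), -1), ">= 0")
  # fractions are percentages of the reference set
  ref2 <- dplyr::bind_rows(ref, q(500))
  r3 <- compare_tss_sets(ref2, q(c(100, 502)), 3)
  expect_equal(r3$frac_exact, 50)
  expect_equal(r3$frac_within_tol, 50)
})

test_that("calling is symmetric under genome mirroring", {
  # mirror: position p -> L - p + 1, strands flipped
  L <- 5000L
  genes <- tibble::tibble(gene_id = "g", contig_id = "c1", start = 2000L,
                          end = 2900L, strand = "+", feature_type = "CDS",
                          protein = NA_character_)
  r1 <- make_track(data.frame(pos = c(1950, 1956, 300), count = c(30, 10, 5),
                              strand = "+"))
  r2 <- make_track(data.frame(pos = c(1950, 1956), count = c(28, 12),
                              strand = "+"), "rep2")
  fwd <- call_tss(r1, r2, genes)

  mirror_track <- function(t) dplyr::mutate(t, position = L - position + 1L,
                                            strand = "-")
  mgenes <- tibble::tibble(gene_id = "g", contig_id = "c1",
                           start = L - 2900L + 1L, end = L - 2000L + 1L,
                           strand = "-", feature_type = "CDS",
                           protein = NA_character_)
  rev <- call_tss(mirror_track(r1), mirror_track(r2), mgenes)
  expect_equal(sort(L - rev$position + 1L), sort(fwd$position))
  expect_equal(rev$gene_id[order(L - rev$position + 1L)],
               fwd$gene_id[order(fwd$position)])
  expect_equal(sort(rev$combined_count), sort(fwd$combined_count))
})

test_that("TSS tables export to TSV and BED6 with capped scores", {
  tss <- call_multiple_tss(assign_to_genes(cand(950, 800), genes_fix))
  bed <- withr::local_tempfile(fileext = ".bed")
  write_tss_bed(tss, bed)
  b <- readr::read_tsv(bed, col_names = c("chrom", "start", "end", "name",
                                          "score", "strand"),
                       col_types = "ciicic", progress = FALSE)
  expect_equal(b$start, 949)   # BED is 0-based
  expect_equal(b$end, 950)
  expect_equal(b$score, 800L)
  expect_equal(b$name, "g1")
})
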