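# Independent oracles and fixture builders shared across the test files.
# Everything here is deliberately naive: correctness over speed, and no reuse
# of the package's own computational paths.

# exhaustive global alignment score by recursive enumeration of all monotone
# edit paths, with affine gaps (a gap of length L costs gap_open + L * extend;
# terminal gaps count). State is the previous move so extensions are scored
# correctly. With memo = FALSE every path is visited (complexity ~ number of
# alignments; keep lengths <= 6); memo = TRUE caches the identical recursion
# on (i, j, previous-move) so longer pairs stay feasible. The two modes are
# cross-checked against each other in the alignment unit tests.
enum_global_score <- function(a, b, match = 2, mismatch = -3,
                              gap_open = -5, gap_extend = -2, memo = FALSE) {
  ac <- strsplit(a, "")[[1]]
  bc <- strsplit(b, "")[[1]]
  la <- length(ac); lb <- length(bc)
  # precomputed substitution scores; prev coded 0 = none/M, 1 = gap-in-b run,
  # 2 = gap-in-a run
  open_ext <- gap_open + gap_extend
  cache <- if (memo) array(NA_real_, dim = c(la + 1L, lb + 1L, 3L)) else NULL
  rec <- function(i, j, prev) {
    if (i == la) {
      if (j == lb) return(0)
      return((lb - j) * gap_extend + if (prev == 2L) 0 else gap_open)
    }
    if (j == lb) {
      return((la - i) * gap_extend + if (prev == 1L) 0 else gap_open)
    }
    if (memo && !is.na(cache[i + 1L, j + 1L, prev + 1L])) {
      return(cache[i + 1L, j + 1L, prev + 1L])
    }
    best <- (if (ac[i + 1L] == bc[j + 1L]) match else mismatch) +
      rec(i + 1L, j + 1L, 0L)
    s <- (if (prev == 1L) gap_extend else open_ext) + rec(i + 1L, j, 1L)
    if (s > best) best <- s
    s <- (if (prev == 2L) gap_extend else open_ext) + rec(i, j + 1L, 2L)
    if (s > best) best <- s
    if (memo) cache[i + 1L, j + 1L, prev + 1L] <<- best
    best
  }
  rec(0L, 0L, 0L)
}

# exhaustive best local alignment score: enumerate every substring pair and
# take the best gapless-or-gapped global score over them via enum_global_score
enum_local_score <- function(a, b, ...) {
  la <- nchar(a); lb <- nchar(b)
  best <- 0
  for (i1 in 1:la) for (i2 in i1:la) for (j1 in 1:lb) for (j2 in j1:lb) {
    s <- enum_global_score(substr(a, i1, i2), substr(b, j1, j2), ...)
    if (s > best) best <- s
  }
  best
}

random_seq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste0(sample(alphabet, n, replace = TRUE), collapse = "")
}

# reference (priority-order) implementation of local-noise suppression used
# as a cross-check: repeatedly take the strongest remaining candidate (ties:
# lowest coordinate) and discard everything closer than the window
suppress_oracle <- function(pos, count, window) {
  keep <- integer(0)
  remaining <- order(-count, pos)
  while (length(remaining) > 0) {
    i <- remaining[1]
    keep <- c(keep, i)
    remaining <- remaining[abs(pos[remaining] - pos[i]) >= window]
  }
  sort(pos[keep])
}

# tiny genome fixture: one contig with a known sequence
tiny_genome <- function(seq = "ACGTACGTACGTACGTACGT", contig = "c1") {
  tibble::tibble(contig_id = contig, seq = seq, length = nchar(seq))
}

make_track <- function(df, replicate = "rep1") {
  tibble::tibble(contig_id = df$contig %||% "c1", position = as.integer(df$pos),
                 strand = df$strand, count = as.integer(df$count),
                 replicate = replicate)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# annotated TSS tibble row(s) in the shape call_tss() produces
mk_tss <- function(pos, strand = "+", gene = NA_character_, dist = NA_integer_,
                   count = 20L, contig = "c1", retained = TRUE) {
  tibble::tibble(
    contig_id = contig, position = as.integer(pos), strand = strand,
    count_rep1 = count, count_rep2 = count, combined_count = 2L * count,
    gene_id = gene, dist_to_start = as.integer(dist),
    leaderless = !is.na(dist) & dist == 0,
    retained_in_gene = ifelse(is.na(gene), NA, retained), is_primary = retained
  )
}

# a small diverged genome pair used by several comparison tests
small_truth <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- tsscompare::sim_config(
        rng_seed = 7, n_genes = 40, contig_len = 70000,
        category_mix = c(CPT = 8, CPNT = 4, OP = 4, SSP = 4),
        frac_orthologous = 0.8, n_srnas = 2)
      cache <<- tsscompare::simulate_genome_pair(cfg)
    }
    cache
  }
})
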