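#' Pipeline parameters
#'
#' Bundles every tunable threshold of the comparative TSS pipeline with its
#' default. Defaults follow the analysis conventions for replicated bacterial
#' 5'-end tag data: a 10-bp local-noise suppression window, retention of
#' per-gene TSSs at >= 50% of the strongest signal, a 700-bp cap on the
#' TSS-to-translation-start distance, 50-bp promoter regions, an 800-bp
#' upstream search window in the partner species, a 2-bp tolerance when
#' matching an implied position to a TSS, a 3-bp tolerance when comparing
#' whole TSS datasets, and 50%/50% identity/aligned cutoffs for reciprocal
#' protein orthology.
#'
#' @param noise_window nt; minimum spacing enforced between retained TSSs on
#'   one strand (suppression radius). Default 10.
#' @param multi_tss_frac fraction of a gene's strongest TSS signal a secondary
#'   TSS must reach to be kept in the gene's TSS list. Default 0.5.
#' @param max_tss_gene_dist nt; maximum distance from a TSS to the translation
#'   start of the gene it is assigned to. Default 700.
#' @param promoter_len nt; promoter region length immediately upstream of a
#'   TSS. Default 50.
#' @param upstream_search_len nt; length of the upstream window of the
#'   orthologous gene searched for a conserved promoter. Default 800.
#' @param tss_match_tol nt; tolerance when matching an alignment-implied
#'   position to a TSS during promoter categorization. Default 2.
#' @param dataset_match_tol nt; tolerance when comparing two TSS datasets.
#'   Default 3.
#' @param ortholog_min_identity %; minimum protein percent identity for an
#'   ortholog candidate. Default 50.
#' @param ortholog_min_aligned %; minimum percent-aligned score for an
#'   ortholog candidate. Default 50.
#' @param promoter_conserved_min_identity fraction; minimum local-alignment
#'   identity for a promoter to count as conserved. Default 0.60.
#' @param promoter_conserved_min_cols fraction of `promoter_len` the
#'   conserved local alignment must span. Default 0.5.
#' @param min_read_count minimum per-replicate read count for a position to be
#'   a TSS candidate. Default 1.
#' @param srna_min_identity fraction; minimum identity of an sRNA homolog hit.
#'   Default 0.60.
#' @param srna_min_coverage fraction of the source sRNA length that must be
#'   aligned. Default 0.60.
#' @param srna_tss_tol nt; tolerance between an sRNA hit 5' end and a
#'   supporting TSS. Default 2.
#' @param combine_replicates `"sum"` (default) or `"mean"`: how replicate
#'   counts are combined into `combined_count`.
#' @param rng_seed integer seed recorded in run manifests.
#' @return A named list of class `tss_params`.
#' @export
#' @examples
#' p <- pipeline_params(noise_window = 5)
#' p$noise_window
pipeline_params <- function(noise_window = 10,
                            multi_tss_frac = 0.5,
                            max_tss_gene_dist = 700,
                            promoter_len = 50,
                            upstream_search_len = 800,
                            tss_match_tol = 2,
                            dataset_match_tol = 3,
                            ortholog_min_identity = 50,
                            ortholog_min_aligned = 50,
                            promoter_conserved_min_identity = 0.60,
                            promoter_conserved_min_cols = 0.5,
                            min_read_count = 1,
                            srna_min_identity = 0.60,
                            srna_min_coverage = 0.60,
                            srna_tss_tol = 2,
                            combine_replicates = c("sum", "mean"),
                            rng_seed = 1L) {
  combine_replicates <- match.arg(combine_replicates)
  p <- list(
    noise_window = noise_window, multi_tss_frac = multi_tss_frac,
    max_tss_gene_dist = max_tss_gene_dist, promoter_len = promoter_len,
    upstream_search_len = upstream_search_len, tss_match_tol = tss_match_tol,
    dataset_match_tol = dataset_match_tol,
    ortholog_min_identity = ortholog_min_identity,
    ortholog_min_aligned = ortholog_min_aligned,
    promoter_conserved_min_identity = promoter_conserved_min_identity,
    promoter_conserved_min_cols = promoter_conserved_min_cols,
    min_read_count = min_read_count,
    srna_min_identity = srna_min_identity,
    srna_min_coverage = srna_min_coverage,
    srna_tss_tol = srna_tss_tol,
    combine_replicates = combine_replicates,
    rng_seed = as.integer(rng_seed)
  )
  lens <- c("noise_window", "max_tss_gene_dist", "promoter_len",
            "upstream_search_len", "tss_match_tol", "dataset_match_tol",
            "srna_tss_tol")
  for (nm in lens) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1 || p[[nm]] < 0) {
      abort(sprintf("parameter '%s' must be a single length >= 0", nm))
    }
  }
  fracs <- c("multi_tss_frac", "promoter_conserved_min_identity",
             "promoter_conserved_min_cols", "srna_min_identity",
             "srna_min_coverage")
  for (nm in fracs) {
    if (!is.numeric(p[[nm]]) || p[[nm]] < 0 || p[[nm]] > 1) {
      abort(sprintf("parameter '%s' must be a fraction in [0,1]", nm))
    }
  }
  structure(p, class = "tss_params")
}

#' @export
print.tss_params <- function(x, ...) {
  cat("<tss_params>\n")
  for (nm in names(x)) cat(sprintf("  %-32s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

#' Read pipeline parameters from a YAML config file
#'
#' The file holds a flat mapping whose keys are `pipeline_params()` argument
#' names; unknown keys are an error, absent keys keep their defaults.
#'
#' @param path path to a YAML file.
#' @return A `tss_params` list.
#' @export
read_params_yaml <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  known <- names(formals(pipeline_params))
  unknown <- setdiff(names(cfg), known)
  if (length(unknown) > 0) {
    abort(sprintf("unknown parameter(s) in %s: %s", path,
                  paste(unknown, collapse = ", ")))
  }
  do.call(pipeline_params, cfg)
}

#' Write pipeline parameters to a YAML config file
#'
#' @param params a `tss_params` list.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_params_yaml <- function(params, path) {
  yaml::write_yaml(unclass(params), path)
  invisible(path)
}
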