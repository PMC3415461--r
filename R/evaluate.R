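#' Score called TSSs against planted truth
#'
#' A called TSS matches a planted one when contig, strand and position agree
#' exactly. Recall is the fraction of planted TSSs recovered; precision the
#' fraction of called TSSs that were planted.
#'
#' @param called TSS tibble (post noise suppression) for one species.
#' @param truth_tss planted TSS rows for that species (from
#'   `synthetic_truth$tss_truth`).
#' @return A one-row tibble `n_planted`, `n_called`, `recall`, `precision`.
#' @export
evaluate_tss_recovery <- function(called, truth_tss) {
  key <- function(x) paste(x$contig_id, x$strand, x$position)
  planted <- unique(key(truth_tss))
  got <- key(called)
  tibble(
    n_planted = length(planted),
    n_called = nrow(called),
    recall = mean(planted %in% got),
    precision = mean(got %in% planted)
  )
}

#' Score promoter categorization against planted truth
#'
#' Joins the categorization results onto the planted primary TSSs of both
#' species by contig, strand and position, and reports the fraction whose
#' predicted category equals the planted one. Planted TSSs missing from the
#' results (e.g. lost during TSS calling) count as errors.
#'
#' @param results categorization tibble (both species row-bound, `species`
#'   column `"A"`/`"B"`).
#' @param truth_tss planted TSS table (`species`, `contig_id`, `position`,
#'   `strand`, `category`, `role`).
#' @return A one-row tibble `n_truth`, `n_scored`, `accuracy`.
#' @export
evaluate_category_calls <- function(results, truth_tss) {
  truth <- truth_tss |>
    filter(.data$role == "primary") |>
    select("species", "contig_id", "position", "strand",
           truth_category = "category")
  joined <- truth |>
    left_join(results |> select("species", "contig_id", "position", "strand",
                                "category"),
              by = c("species", "contig_id", "position", "strand"))
  tibble(
    n_truth = nrow(truth),
    n_scored = sum(!is.na(joined$category)),
    accuracy = mean(!is.na(joined$category) &
                      joined$category == joined$truth_category)
  )
}

#' Score reciprocal-best ortholog calls against planted truth
#'
#' @param orthologs ortholog tibble from [find_orthologs()].
#' @param truth_orthologs planted pair table with `gene_a`, `gene_b` and a
#'   logical `decoy` column (decoy pairs are not true orthologs).
#' @return A one-row tibble `n_true`, `n_called`, `precision`, `recall`.
#' @export
evaluate_ortholog_calls <- function(orthologs, truth_orthologs) {
  truth <- truth_orthologs |> filter(!.data$decoy)
  tkey <- paste(truth$gene_a, truth$gene_b)
  called <- orthologs |> filter(.data$reciprocal_best)
  ckey <- paste(called$gene_a, called$gene_b)
  tibble(
    n_true = length(tkey),
    n_called = length(ckey),
    precision = if (length(ckey)) mean(ckey %in% tkey) else NA_real_,
    recall = mean(tkey %in% ckey)
  )
}

#' Score sRNA homolog discovery against planted truth
#'
#' A planted sRNA is recovered when a candidate with its name is found on the
#' planted strand with a 5'-end error of at most `tol` nt; it is confirmed
#' when that candidate is also flagged expressed.
#'
#' @param candidates candidate tibble from [scan_srna_homologs()].
#' @param truth_srna planted sRNA table (`name`, `strand`, `five_prime_b`).
#' @param tol nt tolerance on the recovered 5' end.
#' @return A one-row tibble `n_planted`, `recall`, `frac_expressed`.
#' @export
evaluate_srna_recovery <- function(candidates, truth_srna, tol = 2) {
  hit <- truth_srna |>
    left_join(candidates, by = "name", suffix = c("_truth", "")) |>
    mutate(recovered = !is.na(.data$five_prime) &
             .data$strand == .data$strand_truth &
             abs(.data$five_prime - .data$five_prime_b) <= tol)
  tibble(
    n_planted = nrow(truth_srna),
    recall = mean(hit$recovered),
    frac_expressed = mean(hit$recovered & hit$expressed %in% TRUE)
  )
}
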