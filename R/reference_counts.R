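#' Published per-subject component rejection summary
#'
#' Loads the bundled per-subject ICA component counts from a published
#' 14-subject EEG-fMRI cohort (shipped as a plain TSV in `extdata`) and
#' recomputes the per-subject rejected-component percentages from the raw
#' counts.  Percentages are rounded to whole percent, matching the printed
#' summary convention.
#'
#' @param path TSV with columns `subject`, `n_components`, `n_artifact`,
#'   `n_unlikely_artifact`; defaults to the bundled table.
#' @return list with the counts `table` (including a `rejected_pct` column),
#'   and the `min`, `max` and `mean` rejected percentage.
#' @export
rejected_ic_summary <- function(path = system.file("extdata",
                                                   "ica_sock_counts.tsv",
                                                   package = "sockeica")) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t")
  stopifnot(all(c("n_components", "n_artifact") %in% names(tab)))
  if (any(tab$n_artifact + tab$n_unlikely_artifact != tab$n_components)) {
    warning("artifact + unlikely-artifact counts do not sum to totals")
  }
  tab$rejected_pct <- round(100 * tab$n_artifact / tab$n_components)
  list(table = tab,
       min = min(tab$rejected_pct),
       max = max(tab$rejected_pct),
       mean = round(mean(100 * tab$n_artifact / tab$n_components)))
}
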