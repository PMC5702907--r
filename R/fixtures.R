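#' Packaged fixture tables
#'
#' The package ships four small TSVs under `extdata`, hand-transcribed from
#' the published study of the dry mature rice seed:
#' * `table1` - tissue-specific and differentially accumulated metabolites
#'   (`compound`, `class`, `log2_ratio`, `fdr`, `specific_tissue`); the
#'   seven tissue-specific compounds carry `NA` ratios.
#' * `table2` - the 64 z-score differential proteins (`protein_id`,
#'   `description`, `log2_ratio`, `p_value`).
#' * `table3` - folding/chaperone proteins with their tissue specificity.
#' * `results_counts` - the printed per-layer detected/common set sizes and
#'   favored counts (`quantity`, `value`).
#'
#' @param name One of `"table1"`, `"table2"`, `"table3"`,
#'   `"results_counts"`.
#' @return A data frame.
#' @export
load_fixture <- function(name = c("table1", "table2", "table3",
                                  "results_counts")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, ".tsv"),
                      package = "seedcontrast", mustWork = TRUE)
  read_tsv(path)
}

#' Printed set sizes as a named vector
#'
#' @return Named numeric vector of the `results_counts` fixture.
#' @export
fixture_counts <- function() {
  tab <- load_fixture("results_counts")
  setNames(tab$value, tab$quantity)
}
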