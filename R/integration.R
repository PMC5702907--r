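#' Strip the isoform suffix from a rice locus identifier
#'
#' Protein identifiers follow the `OsNNgNNNNN.K` locus.isoform convention
#' (e.g. `Os02g06410.1`); probe-to-gene maps use the bare locus
#' (`Os02g06410`). Stripping the suffix bridges the two; the operation is
#' idempotent.
#'
#' @param protein_id Character vector of `locus` or `locus.isoform`
#'   identifiers.
#' @return Character vector of locus identifiers.
#' @examples
#' normalize_locus(c("Os02g06410.1", "Os08g38086.3", "Os02g06410"))
#' @export
normalize_locus <- function(protein_id) {
  ok <- grepl("^Os[0-9]{2}g[0-9]{5,}(\\.[0-9]+)?$", protein_id)
  if (any(!ok)) {
    stop_param("malformed locus identifier(s): %s",
               paste(utils::head(protein_id[!ok], 5), collapse = ", "))
  }
  sub("\\.[0-9]+$", "", protein_id)
}

#' Build unique probe-set/protein pairs across omics layers
#'
#' Joins the common-protein ratio table to the common-probe ratio table
#' through a probe-to-locus map, enforcing a bijection: protein isoforms of
#' the same locus are collapsed to the most abundant one, candidate probes
#' are restricted to those detected in both tissues, and loci matched by
#' zero or by more than one candidate probe are removed (probe sets
#' corresponding to the same gene are dropped, not arbitrated). Probes left
#' mapping to more than one retained locus are also removed so each probe
#' appears at most once.
#'
#' @param protein_ratios Data frame with `feature_id` (protein id),
#'   `log2_ratio`, and optionally `abundance` used to resolve isoform
#'   collisions (defaults to keeping the first).
#' @param probe_map Data frame with columns `probe_id`, `locus`
#'   (many-to-many allowed).
#' @param probe_ratios Data frame with `feature_id` (probe id, restricted to
#'   common probes) and `log2_ratio`.
#' @return A list: `pairs` (data frame `locus`, `probe_id`, `protein_id`,
#'   `mrna_log2_ratio`, `protein_log2_ratio`) and `report` (counts at each
#'   exclusion step).
#' @export
pair_probe_protein <- function(protein_ratios, probe_map, probe_ratios) {
  prot <- data.frame(
    protein_id = protein_ratios$feature_id,
    locus = normalize_locus(protein_ratios$feature_id),
    protein_log2_ratio = protein_ratios$log2_ratio,
    abundance = if ("abundance" %in% names(protein_ratios)) {
      protein_ratios$abundance
    } else {
      rep(1, nrow(protein_ratios))
    },
    stringsAsFactors = FALSE
  )
  n_prot <- nrow(prot)
  # collapse isoforms: keep the most abundant protein per locus
  prot <- prot[order(prot$locus, -prot$abundance), ]
  prot <- prot[!duplicated(prot$locus), ]
  n_loci <- nrow(prot)

  map <- unique(probe_map[c("probe_id", "locus")])
  map <- map[map$locus %in% prot$locus &
               map$probe_id %in% probe_ratios$feature_id, , drop = FALSE]
  probes_per_locus <- table(map$locus)
  multi <- names(probes_per_locus)[probes_per_locus > 1]
  map <- map[!map$locus %in% multi, , drop = FALSE]
  loci_per_probe <- table(map$probe_id)
  shared_probe <- names(loci_per_probe)[loci_per_probe > 1]
  map <- map[!map$probe_id %in% shared_probe, , drop = FALSE]

  pairs <- merge(map, prot, by = "locus")
  pairs <- merge(pairs,
                 data.frame(probe_id = probe_ratios$feature_id,
                            mrna_log2_ratio = probe_ratios$log2_ratio,
                            stringsAsFactors = FALSE),
                 by = "probe_id")
  pairs <- pairs[order(pairs$locus),
                 c("locus", "probe_id", "protein_id",
                   "mrna_log2_ratio", "protein_log2_ratio")]
  rownames(pairs) <- NULL
  stopifnot(!anyDuplicated(pairs$locus), !anyDuplicated(pairs$probe_id))
  list(
    pairs = pairs,
    report = c(
      input_proteins = n_prot,
      loci_after_isoform_collapse = n_loci,
      loci_removed_multi_probe = length(multi),
      probes_removed_multi_locus = length(shared_probe),
      loci_without_common_probe = n_loci - length(multi) - nrow(pairs),
      pairs = nrow(pairs)
    )
  )
}

#' mRNA-protein log2-ratio concordance
#'
#' Compares the endosperm-to-embryo log2 ratios of the two layers over the
#' unique probe-set/protein pairs: Pearson correlation (via
#' [pearson_correlation()]) and the quadrant decomposition by ratio signs
#' (both positive, both negative, discordant, or on an axis when a ratio is
#' exactly zero).
#'
#' @param pairs Pair table from [pair_probe_protein()] (or its `pairs`
#'   element).
#' @return A list: `r`, `p`, `n`, and `quadrants` (named counts
#'   `both_positive`, `both_negative`, `mrna_only_positive`,
#'   `protein_only_positive`, `on_axis`). When either ratio vector has zero
#'   variance, `r` and `p` are `NA` with a warning and the quadrants are
#'   still reported.
#' @export
concordance <- function(pairs) {
  if (!is.data.frame(pairs)) pairs <- pairs$pairs
  if (nrow(pairs) < 3) stop_param("need at least 3 pairs")
  m <- pairs$mrna_log2_ratio
  p <- pairs$protein_log2_ratio
  quadrants <- c(
    both_positive = sum(m > 0 & p > 0),
    both_negative = sum(m < 0 & p < 0),
    mrna_only_positive = sum(m > 0 & p < 0),
    protein_only_positive = sum(m < 0 & p > 0),
    on_axis = sum(m == 0 | p == 0)
  )
  cor_res <- tryCatch(pearson_correlation(m, p),
                      error = function(e) {
                        warning(conditionMessage(e), call. = FALSE)
                        list(r = NA_real_, p = NA_real_, n = length(m))
                      })
  list(r = cor_res$r, p = cor_res$p, n = cor_res$n, quadrants = quadrants)
}
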