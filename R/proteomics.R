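#' Filter peptide ions for protein specificity and replicate reproducibility
#'
#' Applies the two quantification filters of label-free XIC proteomics:
#' ions matching more than one protein are discarded (non-specific), and,
#' per tissue, ions detected in fewer than `min_detections` of the
#' `n_replicates` biological replicates are discarded (not reliably
#' detectable). The reproducibility filter is applied per tissue
#' independently, so an ion can survive in one tissue only.
#'
#' @param ions Data frame with columns `ion_id`, `protein_ids`
#'   (`;`-separated when ambiguous), `tissue`, `replicate`, `area` (`NA` =
#'   undetected).
#' @param min_detections Minimum detected replicates per tissue (default 2).
#' @param n_replicates Number of biological replicates per tissue.
#' @return A list: `ions` (retained rows, with a plain `protein_id` column),
#'   and `report` (named counts of rows removed by reason).
#' @export
filter_peptide_ions <- function(ions, min_detections = 2L, n_replicates = 3L) {
  min_detections <- check_count(min_detections, "min_detections", min = 1L)
  n_replicates <- check_count(n_replicates, "n_replicates", min = 1L)
  if (min_detections > n_replicates) {
    stop_param("min_detections (%d) exceeds n_replicates (%d)",
               min_detections, n_replicates)
  }
  check_tissue(ions$tissue)
  if (any(ions$replicate < 1 | ions$replicate > n_replicates)) {
    stop_param("replicate indices must lie in 1..%d", n_replicates)
  }

  n0 <- nrow(ions)
  specific <- !grepl(";", ions$protein_ids, fixed = TRUE)
  ions1 <- ions[specific, , drop = FALSE]

  # detections per (ion, tissue)
  key <- paste(ions1$ion_id, ions1$tissue, sep = "\r")
  detected <- tapply(!is.na(ions1$area), key, sum)
  keep_key <- names(detected)[detected >= min_detections]
  ions2 <- ions1[key %in% keep_key, , drop = FALSE]

  ions2$protein_id <- ions2$protein_ids
  rownames(ions2) <- NULL
  list(
    ions = ions2,
    report = c(
      input_rows = n0,
      removed_nonspecific = n0 - nrow(ions1),
      removed_low_reproducibility = nrow(ions1) - nrow(ions2),
      retained_rows = nrow(ions2)
    )
  )
}

#' Collapse repeated detections of an ion within one biological sample
#'
#' When a peptide ion is observed several times in the same
#' (tissue, replicate) sample, the extracted-ion-current areas are summed
#' into a single row. Missing areas are ignored unless all detections of the
#' ion in that sample are missing, in which case the summed area is `NA`.
#' The result is independent of input row order.
#'
#' @param ions Peptide-ion data frame (see [filter_peptide_ions()]).
#' @return A data frame with one row per (ion, tissue, replicate).
#' @export
sum_within_sample <- function(ions) {
  key_cols <- intersect(c("ion_id", "protein_ids", "protein_id",
                          "tissue", "replicate"), names(ions))
  agg <- aggregate(
    list(area = ions$area),
    by = ions[key_cols],
    FUN = function(a) if (all(is.na(a))) NA_real_ else sum(a, na.rm = TRUE),
    drop = TRUE
  )
  ord <- do.call(order, agg[key_cols])
  agg <- agg[ord, c(key_cols, "area"), drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Roll peptide-ion areas up to protein abundances
#'
#' Sums, per (protein, tissue, replicate), the areas of all the protein's
#' retained peptide ions to obtain the protein abundance on the raw
#' (exp) scale, log2-transforms it, and averages the detected replicate
#' abundances into a per-tissue mean. Replicates where none of a protein's
#' ions were detected are treated as missing, not zero. Proteins with no
#' detected replicate in either tissue are dropped with a warning.
#'
#' @param ions Filtered, sample-summed peptide-ion data frame with a
#'   `protein_id` column.
#' @return A list: `replicates` (protein_id, tissue, replicate, abundance,
#'   log2_abundance) and `means` (protein_id, tissue, n_detected,
#'   tissue_mean on the raw scale, log2_tissue_mean, mean_log2 = mean of the
#'   per-replicate log2 abundances).
#' @export
rollup_protein_abundance <- function(ions) {
  if (!"protein_id" %in% names(ions)) {
    stop_param("ions must carry a 'protein_id' column (run filter_peptide_ions first)")
  }
  det <- ions[!is.na(ions$area), , drop = FALSE]
  if (!nrow(det)) stop_param("no detected peptide-ion areas to roll up")
  reps <- aggregate(list(abundance = det$area),
                    by = det[c("protein_id", "tissue", "replicate")],
                    FUN = sum)
  reps$log2_abundance <- log2(reps$abundance)
  ord <- order(reps$protein_id, reps$tissue, reps$replicate)
  reps <- reps[ord, ]
  rownames(reps) <- NULL

  means <- aggregate(list(tissue_mean = reps$abundance),
                     by = reps[c("protein_id", "tissue")], FUN = mean)
  means$n_detected <- aggregate(list(n = reps$abundance),
                                by = reps[c("protein_id", "tissue")],
                                FUN = length)$n
  means$log2_tissue_mean <- log2(means$tissue_mean)
  means$mean_log2 <- aggregate(list(m = reps$log2_abundance),
                               by = reps[c("protein_id", "tissue")],
                               FUN = mean)$m
  means <- means[order(means$protein_id, means$tissue),
                 c("protein_id", "tissue", "n_detected", "tissue_mean",
                   "log2_tissue_mean", "mean_log2")]
  rownames(means) <- NULL

  all_prot <- unique(ions$protein_id)
  lost <- setdiff(all_prot, means$protein_id)
  if (length(lost)) {
    warning(sprintf("%d protein(s) had no detected replicate in either tissue and were excluded",
                    length(lost)), call. = FALSE)
  }
  list(replicates = reps, means = means)
}

#' Endosperm-to-embryo log2 ratios for common features
#'
#' For every feature quantified in both tissues, computes
#' `log2(mean_endosperm) - log2(mean_embryo)`. Positive values are
#' endosperm-favored, negative embryo-favored. The default averages the
#' raw-scale replicate abundances before logging; `ratio_mode =
#' "mean-of-log"` instead differences the mean per-replicate log2
#' abundances.
#'
#' @param rollup Result of [rollup_protein_abundance()], or any data frame
#'   shaped like its `means` element.
#' @param ratio_mode `"mean-of-raw"` (default) or `"mean-of-log"`.
#' @return Data frame `feature_id`, `log2_ratio`, plus the two tissue means,
#'   ordered by decreasing ratio. Features with a non-positive tissue mean
#'   are excluded with a warning.
#' @export
tissue_log2_ratio <- function(rollup, ratio_mode = c("mean-of-raw", "mean-of-log")) {
  ratio_mode <- match.arg(ratio_mode)
  means <- if (is.data.frame(rollup)) rollup else rollup$means
  id_col <- intersect(c("protein_id", "feature_id", "name"), names(means))[1]
  val_col <- if (ratio_mode == "mean-of-raw") "log2_tissue_mean" else "mean_log2"

  emb <- means[means$tissue == "embryo", c(id_col, val_col, "tissue_mean")]
  end <- means[means$tissue == "endosperm", c(id_col, val_col, "tissue_mean")]
  merged <- merge(emb, end, by = id_col, suffixes = c("_embryo", "_endosperm"))
  bad <- merged$tissue_mean_embryo <= 0 | merged$tissue_mean_endosperm <= 0
  if (any(bad)) {
    warning(sprintf("%d feature(s) with non-positive tissue mean excluded",
                    sum(bad)), call. = FALSE)
    merged <- merged[!bad, , drop = FALSE]
  }
  out <- data.frame(
    feature_id = merged[[id_col]],
    mean_embryo = merged$tissue_mean_embryo,
    mean_endosperm = merged$tissue_mean_endosperm,
    log2_ratio = merged[[paste0(val_col, "_endosperm")]] -
      merged[[paste0(val_col, "_embryo")]],
    stringsAsFactors = FALSE
  )
  out <- out[order(-out$log2_ratio), ]
  rownames(out) <- NULL
  out
}

#' Classify tissue-favored features by the sign-class median rule
#'
#' Within the positive-ratio features, those strictly above the median of
#' the positive ratios are endosperm-favored; within the negative-ratio
#' features, those strictly below the median of the negative ratios are
#' embryo-favored; everything else (including exact zeros and features at
#' the medians) is unclassified. Strict inequality implements "superior to
#' the median".
#'
#' @param ratios Data frame with `feature_id` and `log2_ratio` columns.
#' @return A list: `ratios` (input plus `favored_class` in
#'   `{endosperm-favored, embryo-favored, none}`), `median_positive`,
#'   `median_negative` (NA when the sign class is empty), and `counts`.
#' @export
favored_by_median <- function(ratios) {
  r <- ratios$log2_ratio
  pos <- r[r > 0]
  neg <- r[r < 0]
  med_pos <- if (length(pos)) median(pos) else NA_real_
  med_neg <- if (length(neg)) median(neg) else NA_real_
  cls <- rep("none", length(r))
  if (!is.na(med_pos)) cls[r > 0 & r > med_pos] <- "endosperm-favored"
  if (!is.na(med_neg)) cls[r < 0 & r < med_neg] <- "embryo-favored"
  ratios$favored_class <- cls
  list(
    ratios = ratios,
    median_positive = med_pos,
    median_negative = med_neg,
    counts = c(endosperm_favored = sum(cls == "endosperm-favored"),
               embryo_favored = sum(cls == "embryo-favored"),
               none = sum(cls == "none"))
  )
}

#' z-score differential test on a vector of log2 ratios
#'
#' Standardizes each feature's log2 ratio against the mean and sample
#' standard deviation of the whole ratio set and converts it to a two-sided
#' standard-normal tail probability. Appropriate when the ratio distribution
#' is approximately normal (check with [shapiro_normality()]).
#'
#' @param ratios Data frame with `feature_id` and `log2_ratio`.
#' @param alpha Significance level (default 0.05).
#' @return The input with `z`, `p` and `significant` columns appended,
#'   ordered by increasing `p`.
#' @export
zscore_differential <- function(ratios, alpha = 0.05) {
  check_prob(alpha, "alpha")
  r <- ratios$log2_ratio
  if (length(r) < 3) stop_param("need at least 3 ratios for a z-score analysis")
  s <- sd(r)
  if (!is.finite(s) || s == 0) {
    stop_param("degenerate input: ratio standard deviation is zero")
  }
  ratios$z <- (r - mean(r)) / s
  ratios$p <- 2 * pnorm(-abs(ratios$z))
  ratios$significant <- ratios$p < alpha
  ratios <- ratios[order(ratios$p), ]
  rownames(ratios) <- NULL
  ratios
}

#' Shapiro-Wilk normality diagnostic for log2 ratios
#'
#' Thin wrapper around the Royston approximation in
#' [stats::shapiro.test()], reported as a diagnostic of whether the z-score
#' analysis's normality assumption is tenable; it is never used as a gate.
#'
#' @param ratios Numeric vector or a data frame with a `log2_ratio` column;
#'   3 to 5000 values.
#' @return A list with elements `W` and `p`.
#' @export
shapiro_normality <- function(ratios) {
  r <- if (is.data.frame(ratios)) ratios$log2_ratio else ratios
  n <- length(r)
  if (n < 3 || n > 5000) {
    stop_param("Shapiro-Wilk requires 3 <= n <= 5000 (got %d)", n)
  }
  st <- shapiro.test(r)
  list(W = unname(st$statistic), p = st$p.value)
}
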