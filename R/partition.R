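#' Partition two detected feature sets into specific and common sets
#'
#' Decomposes the features detected in tissue A and tissue B into the
#' A-specific, B-specific and common (shared) sets, the basic Venn
#' decomposition applied to proteins, probe sets and metabolites alike.
#' A feature is "specific" when it is detected in exactly one tissue and
#' "common" when detected in both.
#'
#' @param detected_a Character vector of features detected in tissue A
#'   (conventionally the embryo).
#' @param detected_b Character vector of features detected in tissue B
#'   (conventionally the endosperm).
#' @param tissue_a,tissue_b Labels used in summaries.
#' @return An object of class `feature_partition`: a list with character
#'   vectors `specific_a`, `specific_b`, `common`, the `counts` (including
#'   `union` and `shared_fraction`, the percentage of the union that is
#'   common), and the tissue labels.
#' @examples
#' p <- partition_features(c("f1", "f2", "f3"), c("f3", "f4"))
#' p$counts
#' @export
partition_features <- function(detected_a, detected_b,
                               tissue_a = "embryo", tissue_b = "endosperm") {
  a <- unique(as.character(detected_a))
  b <- unique(as.character(detected_b))
  common <- intersect(a, b)
  specific_a <- setdiff(a, b)
  specific_b <- setdiff(b, a)
  n_union <- length(a) + length(b) - length(common)
  stopifnot(n_union == length(union(a, b)))  # inclusion-exclusion
  out <- list(
    specific_a = specific_a,
    specific_b = specific_b,
    common = common,
    tissue_a = tissue_a,
    tissue_b = tissue_b,
    counts = c(
      detected_a = length(a),
      detected_b = length(b),
      specific_a = length(specific_a),
      specific_b = length(specific_b),
      common = length(common),
      union = n_union,
      shared_fraction = if (n_union > 0) 100 * length(common) / n_union else NA_real_
    )
  )
  class(out) <- "feature_partition"
  out
}

#' @export
print.feature_partition <- function(x, ...) {
  cat(sprintf(
    "feature partition: %d %s-specific, %d %s-specific, %d common (union %d, %.1f%% shared)\n",
    x$counts[["specific_a"]], x$tissue_a,
    x$counts[["specific_b"]], x$tissue_b,
    x$counts[["common"]], x$counts[["union"]],
    x$counts[["shared_fraction"]]))
  invisible(x)
}

#' Reconstruct a partition from printed set sizes
#'
#' Builds placeholder feature identifiers with the given detected-set sizes
#' and overlap, then delegates to [partition_features()]. Used to check the
#' set arithmetic of published Venn counts without the underlying data.
#'
#' @param n_a,n_b Number of features detected in tissues A and B.
#' @param n_common Size of the intersection.
#' @inheritParams partition_features
#' @return A `feature_partition`.
#' @examples
#' partition_from_counts(2099, 786, 673)$counts
#' @export
partition_from_counts <- function(n_a, n_b, n_common,
                                  tissue_a = "embryo", tissue_b = "endosperm") {
  n_a <- check_count(n_a, "n_a")
  n_b <- check_count(n_b, "n_b")
  n_common <- check_count(n_common, "n_common")
  if (n_common > min(n_a, n_b)) {
    stop_param("n_common (%d) exceeds min(n_a, n_b)", n_common)
  }
  ids_common <- if (n_common > 0) sprintf("shared_%d", seq_len(n_common)) else character()
  ids_a <- c(ids_common, if (n_a > n_common) sprintf("a_only_%d", seq_len(n_a - n_common)) else character())
  ids_b <- c(ids_common, if (n_b > n_common) sprintf("b_only_%d", seq_len(n_b - n_common)) else character())
  partition_features(ids_a, ids_b, tissue_a = tissue_a, tissue_b = tissue_b)
}
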