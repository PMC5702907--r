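#' Bundle probe intensities, presence calls and the sample design
#'
#' Container for a normalized two-tissue microarray experiment: a
#' probes-by-samples matrix of log2-scale intensities (as delivered by array
#' normalization; no re-normalization is performed), a same-shaped matrix of
#' per-sample P/M/A detection calls, and the design mapping each sample to a
#' (tissue, replicate).
#'
#' @param intensity Numeric matrix, probes x samples, log2 scale.
#' @param calls Character matrix of `"P"`, `"M"`, `"A"` with the same
#'   dimnames.
#' @param design Data frame with columns `sample`, `tissue`, `replicate`;
#'   tissues must have equal replicate counts.
#' @return An object of class `probe_matrix`.
#' @export
probe_matrix <- function(intensity, calls, design) {
  stopifnot(is.matrix(intensity), is.matrix(calls),
            identical(dim(intensity), dim(calls)))
  if (!identical(colnames(intensity), design$sample)) {
    stop_param("design samples must match intensity column names, in order")
  }
  bad <- setdiff(unique(as.vector(calls)), c("P", "M", "A"))
  if (length(bad)) {
    stop_param("unknown presence call symbol(s): %s", paste(bad, collapse = ", "))
  }
  check_tissue(design$tissue)
  if (length(unique(table(design$tissue))) != 1L) {
    stop_param("tissues must have equal replicate counts")
  }
  structure(list(intensity = intensity, calls = calls, design = design),
            class = "probe_matrix")
}

#' @export
print.probe_matrix <- function(x, ...) {
  cat(sprintf("probe matrix: %d probes x %d samples (%s)\n",
              nrow(x$intensity), ncol(x$intensity),
              paste(sprintf("%s n=%d", names(table(x$design$tissue)),
                            table(x$design$tissue)), collapse = ", ")))
  invisible(x)
}

#' Read a probe matrix from TSV files
#'
#' The matrix file has a `probe_id` column followed by one intensity and one
#' call column per sample (`<sample>` and `<sample>_call`); the design file
#' has columns `sample`, `tissue`, `replicate`.
#'
#' @param matrix_path,design_path Paths to the two TSV files.
#' @return A [probe_matrix()].
#' @export
read_probe_matrix <- function(matrix_path, design_path) {
  tab <- read_tsv(matrix_path)
  design <- read_tsv(design_path)
  intensity <- as.matrix(tab[design$sample])
  calls <- as.matrix(tab[paste0(design$sample, "_call")])
  rownames(intensity) <- rownames(calls) <- tab$probe_id
  colnames(calls) <- design$sample
  probe_matrix(intensity, calls, design)
}

#' Write a probe matrix to TSV files
#'
#' Inverse of [read_probe_matrix()].
#'
#' @param pm A [probe_matrix()].
#' @param matrix_path,design_path Output paths.
#' @return `matrix_path`, invisibly.
#' @export
write_probe_matrix <- function(pm, matrix_path, design_path) {
  calls <- pm$calls
  colnames(calls) <- paste0(colnames(calls), "_call")
  tab <- data.frame(probe_id = rownames(pm$intensity), pm$intensity, calls,
                    check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(pm$design, design_path)
  write_tsv(tab, matrix_path)
}

#' Per-tissue detected probe sets from presence-call consensus
#'
#' A probe is detected in a tissue when enough of its replicate calls are
#' `"P"`: at least 2 under the default `"two-of-n"` rule, all replicates
#' under `"all"`, or any single replicate under `"any"`. Marginal (`"M"`)
#' calls count as not present (ambiguous probes are removed). Probes
#' detected in neither tissue are dropped from the universe.
#'
#' @param pm A [probe_matrix()].
#' @param rule Consensus rule, one of `"two-of-n"`, `"all"`, `"any"`.
#' @return A list of character vectors of detected probe ids, one per
#'   tissue, plus `universe` (probes detected in at least one tissue).
#' @export
consensus_detection <- function(pm, rule = c("two-of-n", "all", "any")) {
  rule <- match.arg(rule)
  stopifnot(inherits(pm, "probe_matrix"))
  detected <- lapply(TISSUES, function(tis) {
    cols <- pm$design$sample[pm$design$tissue == tis]
    n_p <- rowSums(pm$calls[, cols, drop = FALSE] == "P")
    need <- switch(rule, "two-of-n" = 2L, all = length(cols), any = 1L)
    rownames(pm$calls)[n_p >= need]
  })
  names(detected) <- TISSUES
  detected$universe <- union(detected$embryo, detected$endosperm)
  detected
}

#' Equal-variance t-tests with Bonferroni control
#'
#' Performs, for every probe in `probes`, the two-group Student t-test
#' assuming equal variance (pooled variance, `df = n1 + n2 - 2`) between the
#' embryo and endosperm samples, and adjusts the two-sided p-values by the
#' Bonferroni method (`min(1, m * p)`), with `m` the number of testable
#' probes. Probes with zero pooled variance are flagged untestable and do
#' not count toward `m`.
#'
#' @param pm A [probe_matrix()].
#' @param probes Probe ids to test; defaults to the detection universe under
#'   the default consensus rule.
#' @param alpha Significance level on the adjusted p-value (default 0.01).
#' @return Data frame with per-probe `t`, `p`, `p_adj`, tissue means,
#'   `direction` (sign of endosperm minus embryo), `de` flag and
#'   `untestable` flag; attribute `"m"` records the Bonferroni family size.
#' @export
ttest_bonferroni <- function(pm, probes = NULL, alpha = 0.01) {
  stopifnot(inherits(pm, "probe_matrix"))
  check_prob(alpha, "alpha")
  if (is.null(probes)) probes <- consensus_detection(pm)$universe
  x <- pm$intensity[probes, pm$design$sample[pm$design$tissue == "embryo"],
                    drop = FALSE]
  y <- pm$intensity[probes, pm$design$sample[pm$design$tissue == "endosperm"],
                    drop = FALSE]
  n1 <- ncol(x); n2 <- ncol(y)
  if (n1 < 2 || n2 < 2) stop_param("need >= 2 replicates per tissue")
  m1 <- rowMeans(x); m2 <- rowMeans(y)
  v1 <- apply(x, 1, var); v2 <- apply(y, 1, var)
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  untestable <- sp2 == 0
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  tstat <- ifelse(untestable, NA_real_, (m2 - m1) / se)
  p <- 2 * pt(-abs(tstat), df = n1 + n2 - 2)
  m <- sum(!untestable)
  p_adj <- pmin(1, m * p)
  out <- data.frame(
    probe_id = probes,
    mean_embryo = m1,
    mean_endosperm = m2,
    t = tstat,
    p = p,
    p_adj = p_adj,
    direction = ifelse(m2 > m1, "endosperm", "embryo"),
    de = !untestable & p_adj < alpha,
    untestable = untestable,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "m") <- m
  out
}

#' Keep only strongly expressed differential probes
#'
#' Restricts a set of differentially expressed probes to those whose mean
#' intensity in the favored (higher) tissue strictly exceeds the median
#' expression of the detected universe, i.e. "strongly (superior to median)
#' and differentially regulated". The reference median is taken over the
#' per-(probe, tissue) mean intensities of all probes in `universe`.
#'
#' @param de Result of [ttest_bonferroni()].
#' @param pm The [probe_matrix()] the tests were run on.
#' @param universe Probe ids defining the reference median; defaults to the
#'   probes in `de`.
#' @return The DE rows passing the filter, with attribute
#'   `"median_intensity"`.
#' @export
strong_de_filter <- function(de, pm, universe = NULL) {
  stopifnot(inherits(pm, "probe_matrix"))
  if (is.null(universe)) universe <- de$probe_id
  means <- vapply(TISSUES, function(tis) {
    cols <- pm$design$sample[pm$design$tissue == tis]
    rowMeans(pm$intensity[universe, cols, drop = FALSE])
  }, numeric(length(universe)))
  med <- median(as.vector(means))
  top_mean <- pmax(de$mean_embryo, de$mean_endosperm)
  out <- de[de$de & top_mean > med, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "median_intensity") <- med
  out
}

#' Pearson correlation with a t-based two-sided p-value
#'
#' Product-moment correlation computed from the covariance formula, with
#' significance from `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees
#' of freedom (p = 1 when |r| = 1 cannot be beaten, p -> 0).
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return A list with `r`, `p` and `n`.
#' @export
pearson_correlation <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop_param("x and y must have equal length")
  if (n < 3) stop_param("need at least 3 observations")
  sx <- sd(x); sy <- sd(y)
  if (sx == 0 || sy == 0) {
    stop_param("correlation undefined: zero variance input")
  }
  r <- sum((x - mean(x)) * (y - mean(y))) / ((n - 1) * sx * sy)
  r <- max(-1, min(1, r))
  p <- if (abs(r) == 1) 0 else 2 * pt(-abs(r * sqrt((n - 2) / (1 - r^2))),
                                      df = n - 2)
  list(r = r, p = p, n = n)
}
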