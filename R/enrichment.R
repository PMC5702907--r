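#' Read a term-annotation table
#'
#' Annotation TSVs have columns `term`, `label`, `locus` (one row per
#' term-locus association). Returned as a list of locus sets keyed by term
#' id, with term labels as an attribute.
#'
#' @param path Path to the annotation TSV.
#' @return Named list of character vectors; attribute `"labels"` maps term
#'   ids to descriptions.
#' @export
read_annotation <- function(path) {
  tab <- read_tsv(path)
  ann <- split(tab$locus, tab$term)
  ann <- lapply(ann, unique)
  labels <- tab$label[!duplicated(tab$term)]
  names(labels) <- tab$term[!duplicated(tab$term)]
  attr(ann, "labels") <- labels[names(ann)]
  ann
}

# Upper-tail hypergeometric probability P(X >= k) computed as an explicit
# sum of log-space binomial coefficients (stable for genome-scale N).
hypergeom_upper_tail <- function(k, K, n, N) {
  if (k <= 0) return(1)
  hi <- min(n, K)
  if (k > hi) return(0)
  i <- k:hi
  min(1, sum(exp(lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n))))
}

#' Hypergeometric over-representation test with Benjamini-Yekutieli control
#'
#' For each annotation term with at least one study hit, computes the exact
#' upper-tail hypergeometric probability of drawing `k` or more annotated
#' loci in a study set of size `n` from a background of size `N` containing
#' `K` annotated loci, then adjusts across terms by the Benjamini-Yekutieli
#' FDR ([by_adjust()]), which is valid under the arbitrary dependence
#' created by overlapping terms. Annotations are treated as flat sets (no
#' ontology propagation), and annotated loci outside the background are
#' ignored.
#'
#' @param study Character vector of study loci; must be a subset of
#'   `background`.
#' @param background Character vector of background loci.
#' @param ann Named list of character vectors (term id -> annotated loci),
#'   e.g. from [read_annotation()].
#' @param alpha Significance level on the adjusted p-value (default 0.05).
#' @param test_zero_hit Test (and count toward the family) terms with zero
#'   study hits; default `FALSE`, the standard over-representation practice.
#' @return Data frame `term`, `label`, `k`, `n`, `K`, `N`, `p`, `p_adj`,
#'   `enriched`, ordered by `p`.
#' @export
hypergeom_enrich <- function(study, background, ann, alpha = 0.05,
                             test_zero_hit = FALSE) {
  check_prob(alpha, "alpha")
  study <- unique(study)
  background <- unique(background)
  if (!length(background)) stop_param("background is empty")
  stray <- setdiff(study, background)
  if (length(stray)) {
    stop_param("study loci missing from background: %s%s",
               paste(utils::head(stray, 5), collapse = ", "),
               if (length(stray) > 5) sprintf(" (and %d more)", length(stray) - 5) else "")
  }
  N <- length(background)
  n <- length(study)
  labels <- attr(ann, "labels")
  rows <- lapply(names(ann), function(term) {
    hits_bg <- intersect(ann[[term]], background)
    K <- length(hits_bg)
    k <- length(intersect(hits_bg, study))
    if (k == 0 && !test_zero_hit) return(NULL)
    if (K == 0) return(NULL)
    data.frame(term = term,
               label = if (!is.null(labels)) unname(labels[term]) else NA_character_,
               k = k, n = n, K = K, N = N,
               p = hypergeom_upper_tail(k, K, n, N),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(term = character(), label = character(), k = integer(),
                      n = integer(), K = integer(), N = integer(),
                      p = numeric(), p_adj = numeric(), enriched = logical())
    return(out)
  }
  out$p_adj <- by_adjust(out$p)
  out$enriched <- out$p_adj < alpha
  out <- out[order(out$p, out$term), ]
  rownames(out) <- NULL
  out
}
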