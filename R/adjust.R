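#' Multiple-testing adjustments
#'
#' Hand-rolled implementations of the three corrections the pipeline uses,
#' kept separate from [stats::p.adjust()] so the test suite can compare the
#' two routes. `bonferroni_adjust` returns `min(1, m * p)`;
#' `bh_adjust` is the Benjamini-Hochberg step-up
#' `q_(i) = min_{j >= i} min(1, m * p_(j) / j)`; `by_adjust` is the
#' Benjamini-Yekutieli variant that multiplies by the harmonic sum
#' `c(m) = sum_{k=1}^m 1/k`, valid under arbitrary dependence. All return
#' values in the original order and satisfy
#' `by >= bh >= raw` and `bonferroni >= bh` elementwise.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @param m Family size; defaults to `length(p)`.
#' @return Adjusted p-values, same length and order as `p`.
#' @export
bonferroni_adjust <- function(p, m = length(p)) {
  check_pvec(p)
  pmin(1, m * p)
}

step_up <- function(p, factor) {
  m <- length(p)
  o <- order(p)
  q <- pmin(1, factor * p[o] / seq_len(m))
  q <- rev(cummin(rev(q)))
  out <- numeric(m)
  out[o] <- q
  out
}

#' @rdname bonferroni_adjust
#' @export
bh_adjust <- function(p) {
  check_pvec(p)
  if (!length(p)) return(p)
  step_up(p, length(p))
}

#' @rdname bonferroni_adjust
#' @export
by_adjust <- function(p) {
  check_pvec(p)
  if (!length(p)) return(p)
  m <- length(p)
  cm <- sum(1 / seq_len(m))
  step_up(p, m * cm)
}

check_pvec <- function(p) {
  if (length(p) && (!is.numeric(p) || any(is.na(p)) || any(p < 0 | p > 1))) {
    stop_param("p-values must be numeric in [0, 1] with no NA")
  }
  invisible(p)
}
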