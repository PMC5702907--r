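#' @keywords internal
"_PACKAGE"

#' @importFrom stats aggregate median pnorm pt qnorm rbinom rnorm rpois runif
#'   sd shapiro.test setNames var
#' @importFrom utils read.delim write.table
NULL

TISSUES <- c("embryo", "endosperm")

# Evaluate `code` with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards so generators are deterministic without clobbering the
# session stream.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

stop_param <- function(fmt, ...) {
  stop(sprintf(fmt, ...), call. = FALSE)
}

check_tissue <- function(tissue) {
  bad <- setdiff(unique(tissue), TISSUES)
  if (length(bad)) {
    stop_param("unknown tissue label(s): %s (expected %s)",
               paste(bad, collapse = ", "), paste(TISSUES, collapse = "/"))
  }
  invisible(tissue)
}

check_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop_param("'%s' must be a single probability in [0, 1]", name)
  }
  invisible(x)
}

check_nonneg <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0) {
    stop_param("'%s' must be a single non-negative number", name)
  }
  invisible(x)
}

check_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != round(x)) {
    stop_param("'%s' must be a single integer >= %d", name, min)
  }
  invisible(as.integer(x))
}

#' Read a tab-separated file with a header row
#'
#' Thin wrapper around [utils::read.delim()] with the conventions used for
#' every table the pipeline reads and writes (no factors, no name mangling,
#' `NA` for empty and literal `NA` fields).
#'
#' @param path Path to a TSV file.
#' @return A data frame.
#' @export
read_tsv <- function(path) {
  read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
             check.names = FALSE, na.strings = c("NA", ""), quote = "")
}

#' Write a data frame as TSV
#'
#' @param x A data frame.
#' @param path Output path; parent directories are created.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}
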