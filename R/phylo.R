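#' Read a gapped protein alignment from FASTA
#'
#' @param path Path to an aligned FASTA file (equal-length sequences, `-`
#'   for gaps).
#' @return Named character vector of upper-case sequences.
#' @export
read_alignment <- function(path) {
  aas <- Biostrings::readAAStringSet(path)
  seqs <- toupper(as.character(aas))
  names(seqs) <- names(aas)
  validate_alignment(seqs)
  seqs
}

validate_alignment <- function(seqs) {
  if (length(seqs) < 2) stop_param("alignment needs at least 2 sequences")
  if (length(unique(nchar(seqs))) != 1L) {
    stop_param("aligned sequences must have equal length")
  }
  invisible(seqs)
}

blosum62_matrix <- function() {
  env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = env)
  env$BLOSUM62
}

#' BLOSUM62 similarity-derived distances from a protein alignment
#'
#' For every pair of sequences, sums the BLOSUM62 substitution score over
#' the alignment columns where both sequences carry a residue (columns with
#' a gap in either sequence are ignored) and converts the similarity to a
#' distance by `d_ij = 1 - 2 * S_ij / (S_ii + S_jj)`, clamped below at zero.
#' Identical sequences get distance 0; the matrix is symmetric by
#' construction.
#'
#' @param aln Named character vector of equal-length gapped sequences (see
#'   [read_alignment()]), or anything coercible to one.
#' @param gap Gap character (default `"-"`).
#' @return Symmetric numeric distance matrix with zero diagonal, dimnames =
#'   sequence names.
#' @export
blosum62_distance <- function(aln, gap = "-") {
  aln <- unlist(aln)
  validate_alignment(aln)
  B <- blosum62_matrix()
  chars <- lapply(aln, function(s) strsplit(s, "")[[1]])
  n <- length(aln)
  ids <- names(aln)
  score <- function(a, b) {
    keep <- a != gap & b != gap
    if (!any(keep)) return(NA_real_)
    sum(B[cbind(a[keep], b[keep])])
  }
  self <- vapply(chars, function(a) score(a, a), numeric(1))
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      s <- score(chars[[i]], chars[[j]])
      if (is.na(s)) {
        stop_param("distance undefined: sequences %s and %s share no gap-free column",
                   ids[i], ids[j])
      }
      D[i, j] <- D[j, i] <- max(0, 1 - 2 * s / (self[i] + self[j]))
    }
  }
  D
}

#' Neighbor-joining tree from a distance matrix
#'
#' Classical neighbor joining: at each step the pair minimizing
#' `Q_ij = (r - 2) d_ij - R_i - R_j` (row sums `R`, current taxon count `r`)
#' is joined; branch lengths come from the standard NJ formulas and
#' distances to the new node are `(d_ik + d_jk - d_ij) / 2`. Ties are broken
#' toward the lowest-index pair for determinism; negative branch lengths are
#' clamped to zero and the total clamped deficit is recorded in attribute
#' `"negative_branch_deficit"`. On distances that are exactly additive on a
#' binary tree, the input topology and path lengths are recovered.
#'
#' @param D Symmetric non-negative distance matrix with zero diagonal and at
#'   least 3 taxa.
#' @return An unrooted `phylo` object (internal nodes of degree 3).
#' @export
neighbor_joining <- function(D) {
  if (!is.matrix(D) || nrow(D) != ncol(D)) stop_param("D must be a square matrix")
  if (nrow(D) < 3) stop_param("neighbor joining needs at least 3 taxa")
  if (max(abs(D - t(D))) > 1e-8 || any(D < 0) || any(abs(diag(D)) > 1e-12)) {
    stop_param("D must be symmetric and non-negative with a zero diagonal")
  }
  n_tip <- nrow(D)
  labels <- rownames(D)
  if (is.null(labels)) labels <- paste0("t", seq_len(n_tip))

  active <- seq_len(n_tip)          # node ids of active clusters
  next_node <- n_tip + 1L           # provisional ids for internal nodes
  edges <- matrix(0L, 0, 2)
  lens <- numeric(0)
  deficit <- 0
  clamp <- function(x) {
    if (x < 0) deficit <<- deficit - x
    max(0, x)
  }

  while (length(active) > 3) {
    r <- length(active)
    R <- rowSums(D)
    Q <- (r - 2) * D - outer(R, R, "+")
    diag(Q) <- Inf
    # lowest-index pair among the minima, column-major scan
    idx <- which(Q == min(Q), arr.ind = TRUE)
    idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
    i <- idx[1, 1]; j <- idx[1, 2]
    li <- clamp(D[i, j] / 2 + (R[i] - R[j]) / (2 * (r - 2)))
    lj <- clamp(D[i, j] - (D[i, j] / 2 + (R[i] - R[j]) / (2 * (r - 2))))
    edges <- rbind(edges, c(next_node, active[i]), c(next_node, active[j]))
    lens <- c(lens, li, lj)
    d_new <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(r), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], d_new[keep]),
               c(d_new[keep], 0))
    active <- c(active[keep], next_node)
    rownames(D) <- colnames(D) <- NULL
    next_node <- next_node + 1L
  }

  # final trifurcation joining the last three clusters
  la <- clamp((D[1, 2] + D[1, 3] - D[2, 3]) / 2)
  lb <- clamp((D[1, 2] + D[2, 3] - D[1, 3]) / 2)
  lc <- clamp((D[1, 3] + D[2, 3] - D[1, 2]) / 2)
  edges <- rbind(edges, c(next_node, active[1]), c(next_node, active[2]),
                 c(next_node, active[3]))
  lens <- c(lens, la, lb, lc)

  # renumber internal nodes so the final node is the ape root (n_tip + 1)
  # and edges point away from it
  n_internal <- next_node - n_tip
  old_ids <- (n_tip + 1L):next_node
  # root (last created) becomes n_tip+1; earlier internals shift up by one
  new_ids <- setNames(c(seq.int(n_tip + 2L, length.out = n_internal - 1L),
                        n_tip + 1L), old_ids)
  relabel <- function(v) ifelse(v > n_tip, new_ids[as.character(v)], v)
  edge <- cbind(relabel(edges[, 1]), relabel(edges[, 2]))
  storage.mode(edge) <- "integer"

  tree <- structure(list(edge = edge, edge.length = lens,
                         tip.label = labels, Nnode = n_internal),
                    class = "phylo")
  tree <- ape::reorder.phylo(tree, "cladewise")
  attr(tree, "negative_branch_deficit") <- deficit
  if (deficit > 0) {
    message(sprintf("neighbor_joining: clamped negative branch lengths (total deficit %.4g)",
                    deficit))
  }
  tree
}

#' Serialize a tree as a Newick string
#'
#' Writes `tree` in Newick format with branch lengths, children in the order
#' stored in the tree. Re-parsing yields a tree isomorphic to the input.
#'
#' @param tree A `phylo` object.
#' @param file Optional path; when given the string is also written there.
#' @param digits Significant digits for branch lengths.
#' @return The Newick string, invisibly when `file` is given.
#' @export
write_newick <- function(tree, file = NULL, digits = 10) {
  stopifnot(inherits(tree, "phylo"))
  n_tip <- length(tree$tip.label)
  children <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  fmt <- function(x) sprintf("%.*g", digits, x)
  render <- function(node) {
    if (node <= n_tip) return(tree$tip.label[node])
    kid_edges <- children[[as.character(node)]]
    parts <- vapply(kid_edges, function(e) {
      paste0(render(tree$edge[e, 2]), ":", fmt(tree$edge.length[e]))
    }, character(1))
    paste0("(", paste(parts, collapse = ","), ")")
  }
  nwk <- paste0(render(n_tip + 1L), ";")
  if (!is.null(file)) {
    dir.create(dirname(file), recursive = TRUE, showWarnings = FALSE)
    writeLines(nwk, file)
    return(invisible(nwk))
  }
  nwk
}

#' Locate asparagine-glycine (NG) cleavage motifs in a protein sequence
#'
#' Glutelin precursors are cleaved into acidic and basic subunits at a
#' conserved NG site. Reports the 1-based position of every `N` immediately
#' followed by `G` (overlapping occurrences included) with a flanking
#' context window.
#'
#' @param sequence Ungapped amino-acid string.
#' @param context Residues of flanking context to report on each side.
#' @return Data frame with columns `position` and `context`; zero rows when
#'   the motif is absent.
#' @export
find_ng_cleavage <- function(sequence, context = 5L) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  hits <- gregexpr("N(?=G)", sequence, perl = TRUE)[[1]]
  if (hits[1] == -1) {
    return(data.frame(position = integer(), context = character(),
                      stringsAsFactors = FALSE))
  }
  pos <- as.integer(hits)
  ctx <- vapply(pos, function(p) {
    substr(sequence, max(1, p - context), min(nchar(sequence), p + 1 + context))
  }, character(1))
  data.frame(position = pos, context = ctx, stringsAsFactors = FALSE)
}
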