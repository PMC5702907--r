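test_that("blosum62_distance reproduces the hand-computed example", {
  # AAA vs AAR: S12 = 4+4-1 = 7, S11 = 12, S22 = 4+4+5 = 13
  d <- blosum62_distance(c(s1 = "AAA", s2 = "AAR"))
  expect_equal(d["s1", "s2"], 1 - 14 / 25)
  expect_equal(d["s1", "s2"], 0.44)
  expect_equal(diag(d), c(s1 = 0, s2 = 0))
})

test_that("identical sequences give the zero matrix; gaps are ignored", {
  d <- blosum62_distance(c(a = "MKV-LW", b = "MKV-LW", c = "MKVQLW"))
  expect_equal(d["a", "b"], 0)
  expect_true(all(d >= 0))
  expect_equal(d, t(d))
  # gap column drops out of S_xy but self-similarities keep their own
  # non-gap columns: S_xy = 10, S_xx = 10, S_yy = 5 + 5 + 11 = 21
  d2 <- blosum62_distance(c(x = "MK-", y = "MKW"))
  expect_equal(d2["x", "y"], 1 - 2 * 10 / (10 + 21))
  expect_error(blosum62_distance(c(x = "--A", y = "AA-")), "no gap-free")
  expect_error(blosum62_distance(c(x = "AA", y = "AAA")), "equal length")
})

test_that("distance matrix is symmetric for random sequence sets", {
  set.seed(61)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  seqs <- vapply(1:5, function(i) {
    paste(sample(c(aa, "-"), 40, replace = TRUE, prob = c(rep(1, 20), 3)),
          collapse = "")
  }, character(1))
  names(seqs) <- paste0("s", 1:5)
  d <- blosum62_distance(seqs)
  expect_equal(d, t(d))
  expect_true(all(diag(d) == 0))
})

test_that("3-taxon NJ uses the closed-form branch lengths", {
  D <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tree <- neighbor_joining(D)
  expect_equal(ape::Ntip(tree), 3)
  expect_equal(tree$Nnode, 1)
  bl <- setNames(tree$edge.length, tree$tip.label[tree$edge[, 2]])
  expect_equal(bl[["A"]], (3 + 4 - 5) / 2)
  expect_equal(bl[["B"]], (3 + 5 - 4) / 2)
  expect_equal(bl[["C"]], (4 + 5 - 3) / 2)
})

test_that("NJ recovers topology and path lengths from additive distances", {
  set.seed(71)
  for (n in 4:8) {
    ref <- ape::rtree(n, rooted = FALSE)
    D <- ape::cophenetic.phylo(ref)
    D <- D[ref$tip.label, ref$tip.label]
    tree <- neighbor_joining(D)
    # additivity: path lengths on the reconstructed tree reproduce the input
    back <- ape::cophenetic.phylo(tree)[ref$tip.label, ref$tip.label]
    expect_lt(max(abs(back - D)), 1e-9)
    # topology identical (RF distance 0)
    expect_equal(ape::dist.topo(ape::unroot(ref), ape::unroot(tree)), 0,
                 ignore_attr = TRUE)
  }
})

test_that("NJ validates its input and agrees with the reference implementation", {
  expect_error(neighbor_joining(matrix(0, 2, 2)), "at least 3")
  bad <- matrix(c(0, 1, 2, 5, 0, 1, 2, 1, 0), 3)
  expect_error(neighbor_joining(bad), "symmetric")
  set.seed(81)
  # noisy (non-additive) matrix: same topology as ape::nj
  D <- as.matrix(dist(matrix(rnorm(7 * 4), 7)))
  dimnames(D) <- list(paste0("t", 1:7), paste0("t", 1:7))
  expect_equal(ape::dist.topo(ape::unroot(ape::nj(D)),
                              ape::unroot(neighbor_joining(D))), 0,
               ignore_attr = TRUE)
})

test_that("write_newick round-trips through a reference parser", {
  D <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tree <- neighbor_joining(D)
  nwk <- write_newick(tree)
  expect_match(nwk, "^\\(.*A:1.*\\);$")
  reparsed <- ape::read.tree(text = nwk)
  expect_setequal(reparsed$tip.label, tree$tip.label)
  expect_equal(sum(reparsed$edge.length), sum(tree$edge.length))

  set.seed(91)
  for (i in 1:5) {
    ref <- ape::rtree(sample(4:10, 1), rooted = FALSE)
    rt <- ape::read.tree(text = write_newick(ref))
    expect_equal(ape::dist.topo(ref, rt), 0, ignore_attr = TRUE)
    expect_equal(ape::cophenetic.phylo(rt)[ref$tip.label, ref$tip.label],
                 ape::cophenetic.phylo(ref)[ref$tip.label, ref$tip.label],
                 tolerance = 1e-8)
    # writing the reparsed tree is a fixed point
    expect_equal(write_newick(rt), write_newick(ape::read.tree(
      text = write_newick(rt))))
  }
})

test_that("simulated families yield trees resembling the generating topology", {
  gen <- ape::read.tree(text = "((A:0.3,B:0.3):0.4,(C:0.3,D:0.3):0.4,E:0.6);")
  seqs <- gen_protein_family(gen, 600, 0.5, rng_seed = 17)
  tree <- neighbor_joining(blosum62_distance(seqs))
  expect_equal(ape::dist.topo(ape::unroot(gen), ape::unroot(tree)), 0,
               ignore_attr = TRUE)
})

test_that("find_ng_cleavage reports 1-based overlapping motif positions", {
  expect_equal(find_ng_cleavage("AANGAA")$position, 3)
  expect_equal(nrow(find_ng_cleavage("AAAAAA")), 0)   # GluC-1-like negative
  expect_equal(find_ng_cleavage("NGNG")$position, c(1, 3))
  hit <- find_ng_cleavage("MMMMMNGKKKKK", context = 3)
  expect_equal(hit$context, "MMMNGKKK")
})
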