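test_that("normalize_locus strips isoform suffixes and is idempotent", {
  expect_equal(normalize_locus("Os02g06410.1"), "Os02g06410")
  expect_equal(normalize_locus("Os08g38086.3"), "Os08g38086")
  expect_equal(normalize_locus("Os02g06410"), "Os02g06410")
  expect_equal(normalize_locus(normalize_locus("Os02g06410.12")), "Os02g06410")
  expect_error(normalize_locus("AT1G01010.1"), "malformed")
})

test_that("pair_probe_protein builds a bijection and reports exclusions", {
  prot <- data.frame(
    feature_id = c("Os01g10000.1", "Os01g10000.2", "Os01g20000.1",
                   "Os01g30000.1", "Os01g40000.1"),
    log2_ratio = c(1, 2, 3, 4, 5),
    abundance = c(10, 50, 1, 1, 1))
  map <- data.frame(
    probe_id = c("pA", "pB1", "pB2", "pC", "pD"),
    locus = c("Os01g10000", "Os01g20000", "Os01g20000", "Os01g30000",
              "Os01g40000"))
  probes <- data.frame(feature_id = c("pA", "pB1", "pB2", "pC"),
                       log2_ratio = c(0.5, 1, 1.5, -2))
  res <- pair_probe_protein(prot, map, probes)
  # Os01g20000 excluded (two common probes); Os01g40000 excluded (probe pD
  # not common); isoform collision resolved toward the more abundant .2
  expect_equal(res$pairs$locus, c("Os01g10000", "Os01g30000"))
  expect_equal(res$pairs$protein_id[1], "Os01g10000.2")
  expect_equal(res$pairs$protein_log2_ratio, c(2, 4))
  expect_equal(res$pairs$mrna_log2_ratio, c(0.5, -2))
  expect_equal(unname(res$report[["loci_removed_multi_probe"]]), 1)
  expect_equal(unname(res$report[["input_proteins"]]), 5)
  expect_equal(unname(res$report[["loci_after_isoform_collapse"]]), 4)
})

test_that("pairing matches brute force and is a fixed point", {
  set.seed(23)
  loci <- sprintf("Os05g%05d", sample(10000:99999, 60))
  prot <- data.frame(feature_id = paste0(loci, ".1"),
                     log2_ratio = rnorm(60), abundance = runif(60))
  # random many-to-many map over those loci
  map <- data.frame(
    probe_id = sprintf("probe_%03d", 1:90),
    locus = sample(loci, 90, replace = TRUE))
  probes <- data.frame(feature_id = sample(map$probe_id, 70),
                       log2_ratio = rnorm(70))
  res <- pair_probe_protein(prot, map, probes)

  # oracle: enumerate candidate probes per locus
  cand <- map[map$probe_id %in% probes$feature_id, ]
  per_locus <- table(unique(cand)[["locus"]])
  expected_loci <- names(per_locus)[per_locus == 1]
  # drop probes shared across retained loci
  cand1 <- unique(cand[cand$locus %in% expected_loci, ])
  shared <- names(table(cand1$probe_id))[table(cand1$probe_id) > 1]
  expected_loci <- sort(cand1$locus[!cand1$probe_id %in% shared])
  expect_equal(res$pairs$locus, expected_loci)
  expect_lte(nrow(res$pairs), min(60, length(unique(probes$feature_id))))
  expect_false(any(duplicated(res$pairs$probe_id)))

  # re-running on its own output changes nothing
  again <- pair_probe_protein(
    data.frame(feature_id = res$pairs$protein_id,
               log2_ratio = res$pairs$protein_log2_ratio),
    map,
    data.frame(feature_id = res$pairs$probe_id,
               log2_ratio = res$pairs$mrna_log2_ratio))
  expect_equal(again$pairs, res$pairs)
})

test_that("concordance reports r and quadrant counts", {
  pairs <- data.frame(locus = paste0("L", 1:6), probe_id = paste0("p", 1:6),
                      protein_id = paste0("P", 1:6),
                      mrna_log2_ratio = c(-3, -2, -1, 1, 2, 3),
                      protein_log2_ratio = c(-3, -2, -1, 1, 2, 3))
  res <- concordance(pairs)
  expect_equal(res$r, 1)
  expect_equal(unname(res$quadrants[["both_positive"]]), 3)
  expect_equal(unname(res$quadrants[["both_negative"]]), 3)
  expect_equal(unname(res$quadrants[["mrna_only_positive"]]), 0)

  anti <- pairs
  anti$protein_log2_ratio <- -anti$mrna_log2_ratio
  expect_equal(concordance(anti)$r, -1)
  expect_equal(unname(concordance(anti)$quadrants[["both_positive"]]), 0)

  flat <- pairs
  flat$protein_log2_ratio <- 1
  expect_warning(res3 <- concordance(flat), "zero variance")
  expect_true(is.na(res3$r))
  expect_equal(unname(res3$quadrants[["both_positive"]]), 3)
})

test_that("decoupled layers give small |r|, coupled layers recover rho", {
  set.seed(31)
  r_null <- replicate(50, {
    m <- rnorm(200); p <- rnorm(200)
    concordance(data.frame(locus = 1:200, probe_id = 1:200, protein_id = 1:200,
                           mrna_log2_ratio = m, protein_log2_ratio = p))$r
  })
  expect_lt(abs(mean(r_null)), 0.03)
  expect_lt(max(abs(r_null)), 0.3)

  # parameter recovery through the full simulator at rho = 0.7
  cfg <- run_config(
    scenario = omics_scenario(n_features_common = 400, n_specific_a = 20,
                              n_specific_b = 20, ion_multiplicity = 2,
                              noise_sd = 0.2, dropout_rate = 0,
                              shared_ion_rate = 0),
    coupling_rho = 0.7, rng_seed = 99)
  rep <- run_pipeline(cfg)
  expect_equal(rep$integration$concordance$r, 0.7, tolerance = 0.12)
})
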