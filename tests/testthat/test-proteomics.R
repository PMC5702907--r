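test_that("filter_peptide_ions drops non-specific and poorly reproducible ions", {
  ions <- rbind(
    ion_row("i1", "Os01g00001.1;Os01g00002.1", "embryo", 1:3, c(1, 2, 3)),
    ion_row("i2", "Os01g00001.1", "embryo", 1:3, c(5, NA, NA)),   # 1/3 detected
    ion_row("i3", "Os01g00001.1", "embryo", 1:3, c(5, NA, 7)),    # 2/3 detected
    ion_row("i4", "Os01g00003.1", "endosperm", 1:3, c(1, 1, 1))
  )
  res <- filter_peptide_ions(ions)
  expect_setequal(unique(res$ions$ion_id), c("i3", "i4"))
  expect_equal(unname(res$report[["removed_nonspecific"]]), 3)
  expect_equal(unname(res$report[["removed_low_reproducibility"]]), 3)
  expect_error(filter_peptide_ions(ions, min_detections = 4), "exceeds")
})

test_that("the reproducibility filter is applied per tissue independently", {
  ions <- rbind(
    ion_row("i1", "P1", "embryo", 1:3, c(1, 2, 3)),
    ion_row("i1", "P1", "endosperm", 1:3, c(1, NA, NA))
  )
  res <- filter_peptide_ions(ions)$ions
  expect_setequal(unique(res$tissue), "embryo")
})

test_that("filtering matches a brute-force recount on synthetic tables", {
  g <- gen_peptide_ion_table(tiny_scenario(rng_seed = 31))
  res <- filter_peptide_ions(g$ions)

  # oracle: loop over every (ion, tissue) group independently
  keep <- logical(nrow(g$ions))
  for (grp in split(seq_len(nrow(g$ions)),
                    paste(g$ions$ion_id, g$ions$tissue))) {
    specific <- !any(grepl(";", g$ions$protein_ids[grp]))
    reproducible <- sum(!is.na(g$ions$area[grp])) >= 2
    keep[grp] <- specific && reproducible
  }
  expect_equal(nrow(res$ions), sum(keep))
  expect_setequal(paste(res$ions$ion_id, res$ions$tissue, res$ions$replicate),
                  paste(g$ions$ion_id, g$ions$tissue, g$ions$replicate)[keep])
})

test_that("sum_within_sample collapses duplicates and ignores row order", {
  ions <- rbind(
    ion_row("i1", "P1", "embryo", c(1, 1), c(10, 15)),
    ion_row("i2", "P1", "embryo", 1, 7)
  )
  out <- sum_within_sample(ions)
  expect_equal(nrow(out), 2)
  expect_equal(out$area[out$ion_id == "i1"], 25)
  expect_equal(out$area[out$ion_id == "i2"], 7)

  shuffled <- ions[c(3, 1, 2), ]
  expect_equal(sum_within_sample(shuffled), out)

  # all-NA group stays NA, partial NA is dropped from the sum
  nas <- rbind(ion_row("i3", "P2", "embryo", c(1, 1), c(NA, NA)),
               ion_row("i4", "P2", "embryo", c(2, 2), c(NA, 4)))
  out2 <- sum_within_sample(nas)
  expect_true(is.na(out2$area[out2$ion_id == "i3"]))
  expect_equal(out2$area[out2$ion_id == "i4"], 4)
})

test_that("rollup sums ion areas per protein and log2-transforms", {
  ions <- ion_row("i1", "P1", "embryo", 1:3, c(4, 8, 16))
  ions$protein_id <- ions$protein_ids
  roll <- rollup_protein_abundance(ions)
  expect_equal(roll$replicates$log2_abundance, c(2, 3, 4))
  expect_equal(roll$means$tissue_mean, mean(c(4, 8, 16)))

  two <- rbind(ion_row("a", "P1", "embryo", 1, 8),
               ion_row("b", "P1", "embryo", 1, 8))
  two$protein_id <- two$protein_ids
  expect_equal(rollup_protein_abundance(two)$replicates$abundance, 16)
})

test_that("rollup is additive and matches a brute-force re-sum", {
  g <- gen_peptide_ion_table(tiny_scenario(rng_seed = 12, shared_ion_rate = 0))
  filt <- filter_peptide_ions(g$ions)$ions
  roll <- rollup_protein_abundance(filt)

  oracle <- c()
  for (i in seq_len(nrow(roll$replicates))) {
    row <- roll$replicates[i, ]
    sel <- filt$protein_id == row$protein_id & filt$tissue == row$tissue &
      filt$replicate == row$replicate
    oracle[i] <- sum(filt$area[sel], na.rm = TRUE)
  }
  expect_equal(roll$replicates$abundance, oracle)

  # splitting one ion's area across two ions leaves the protein unchanged
  split_ions <- filt
  first <- which(!is.na(split_ions$area))[1]
  extra <- split_ions[first, ]
  extra$ion_id <- "split_twin"
  extra$area <- split_ions$area[first] / 2
  split_ions$area[first] <- split_ions$area[first] / 2
  roll2 <- rollup_protein_abundance(rbind(split_ions, extra))
  expect_equal(roll2$means, roll$means)
})

test_that("tissue_log2_ratio has the documented sign and symmetry", {
  means <- data.frame(
    protein_id = rep(c("P1", "P2", "P3"), each = 2),
    tissue = rep(c("embryo", "endosperm"), 3),
    tissue_mean = c(2, 8, 5, 5, 8, 2),
    stringsAsFactors = FALSE)
  means$log2_tissue_mean <- log2(means$tissue_mean)
  means$mean_log2 <- means$log2_tissue_mean
  r <- tissue_log2_ratio(means)
  expect_equal(r$log2_ratio[r$feature_id == "P1"], 2)
  expect_equal(r$log2_ratio[r$feature_id == "P2"], 0)
  expect_equal(r$log2_ratio[r$feature_id == "P3"], -2)

  # swapping tissue labels negates every ratio
  swapped <- means
  swapped$tissue <- ifelse(means$tissue == "embryo", "endosperm", "embryo")
  r2 <- tissue_log2_ratio(swapped)
  expect_equal(r2$log2_ratio[match(r$feature_id, r2$feature_id)], -r$log2_ratio)
})

test_that("favored_by_median applies the strict per-sign median rule", {
  ratios <- data.frame(feature_id = paste0("f", 1:6),
                       log2_ratio = c(1, 2, 3, -1, -2, -3))
  fav <- favored_by_median(ratios)
  expect_equal(fav$median_positive, 2)
  expect_equal(fav$median_negative, -2)
  expect_equal(fav$ratios$favored_class,
               c("none", "none", "endosperm-favored",
                 "none", "none", "embryo-favored"))

  tied <- favored_by_median(data.frame(feature_id = c("a", "b"),
                                       log2_ratio = c(1, 1)))
  expect_equal(unname(tied$counts[["endosperm_favored"]]), 0)
  expect_true(is.na(tied$median_negative))

  # brute-force oracle on random vectors
  set.seed(9)
  for (i in 1:20) {
    r <- round(rnorm(sample(5:50, 1), 0, 3), 2)
    res <- favored_by_median(data.frame(feature_id = seq_along(r),
                                        log2_ratio = r))
    pos <- r[r > 0]; neg <- r[r < 0]
    oracle <- rep("none", length(r))
    for (j in seq_along(r)) {
      if (length(pos) && r[j] > 0 && r[j] > median(pos)) oracle[j] <- "endosperm-favored"
      if (length(neg) && r[j] < 0 && r[j] < median(neg)) oracle[j] <- "embryo-favored"
    }
    expect_equal(res$ratios$favored_class, oracle)
  }
})

test_that("zscore_differential matches the direct formula", {
  r <- c(-2, -1, 0, 1, 2)
  res <- zscore_differential(data.frame(feature_id = letters[1:5],
                                        log2_ratio = r))
  res <- res[order(res$feature_id), ]
  s <- sqrt(sum((r - mean(r))^2) / 4)           # sample sd, computed directly
  expect_equal(res$z, r / s)
  expect_equal(res$p, 2 * pnorm(-abs(r / s)))

  # a ratio equal to the mean gets z = 0, p = 1
  res2 <- zscore_differential(data.frame(feature_id = 1:3,
                                         log2_ratio = c(-1, 0, 1)))
  expect_equal(res2$p[res2$feature_id == 2], 1)
  expect_equal(res2$z[res2$feature_id == 2], 0)

  expect_error(zscore_differential(data.frame(feature_id = 1:3,
                                              log2_ratio = c(1, 1, 1))),
               "degenerate")
  expect_error(zscore_differential(data.frame(feature_id = 1:2,
                                              log2_ratio = c(1, 2))),
               "at least 3")
})

test_that("shapiro_normality distinguishes normal from bimodal samples", {
  expect_error(shapiro_normality(c(1, 2)), "3 <= n <= 5000")
  set.seed(77)
  normal_p <- replicate(100, shapiro_normality(rnorm(200))$p)
  expect_gt(mean(normal_p > 0.05), 0.8)
  bimodal_p <- replicate(100,
    shapiro_normality(c(rnorm(100, -4, 0.5), rnorm(100, 4, 0.5)))$p)
  expect_gt(mean(bimodal_p < 0.05), 0.95)
})

test_that("planted high-effect proteome is recovered exactly end to end", {
  sc <- tiny_scenario(tissue_effect_sd = 8, noise_sd = 0.1, dropout_rate = 0,
                      shared_ion_rate = 0, rng_seed = 21)
  g <- gen_peptide_ion_table(sc)
  roll <- rollup_protein_abundance(sum_within_sample(
    filter_peptide_ions(g$ions)$ions))
  part <- partition_features(
    roll$means$protein_id[roll$means$tissue == "embryo"],
    roll$means$protein_id[roll$means$tissue == "endosperm"])
  expect_setequal(part$specific_a,
                  g$truth$protein_id[g$truth$membership == "specific_a"])
  expect_setequal(part$specific_b,
                  g$truth$protein_id[g$truth$membership == "specific_b"])
  expect_setequal(part$common,
                  g$truth$protein_id[g$truth$membership == "common"])
  # recovered ratios track the planted effects tightly
  ratios <- tissue_log2_ratio(roll)
  truth <- g$truth[match(ratios$feature_id, g$truth$protein_id), ]
  expect_gt(cor(ratios$log2_ratio, truth$log2_effect), 0.999)
})
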