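#' Describe a synthetic two-tissue omics scenario
#'
#' A scenario fixes the statistical world the generators draw from: a core of
#' features shared by both tissues with log2-scale tissue effects, plus
#' tissue-specific features (complete dropout in the other tissue), measured
#' in a fixed number of biological replicates per tissue. Defaults mirror the
#' dry rice seed proteome design: 673 common, 1426 embryo-specific and 113
#' endosperm-specific features in three biological replicates, with a mean of
#' 15 peptide ions per protein (the study's ~34k embryo ions over ~2.1k
#' proteins).
#'
#' @param n_features_common Number of features detected in both tissues.
#' @param n_specific_a Number of tissue-A (embryo) specific features.
#' @param n_specific_b Number of tissue-B (endosperm) specific features.
#' @param n_replicates Biological replicates per tissue.
#' @param tissue_effect_sd Standard deviation (log2 scale) of the planted
#'   tissue effect for common features.
#' @param noise_sd Standard deviation (log2 scale) of replicate-level
#'   multiplicative noise.
#' @param ion_multiplicity Mean number of peptide ions per protein
#'   (zero-truncated Poisson).
#' @param dropout_rate Probability that an ion (or probe call) is undetected
#'   in any one replicate where its parent feature is present.
#' @param shared_ion_rate Probability a peptide ion maps to more than one
#'   protein (and is therefore discarded by the specificity filter).
#' @param rng_seed Integer seed; identical seeds give identical tables.
#' @return An object of class `omics_scenario` (a validated list).
#' @export
omics_scenario <- function(n_features_common = 673,
                           n_specific_a = 1426,
                           n_specific_b = 113,
                           n_replicates = 3,
                           tissue_effect_sd = 2.5,
                           noise_sd = 0.5,
                           ion_multiplicity = 15,
                           dropout_rate = 0.1,
                           shared_ion_rate = 0.05,
                           rng_seed = 1L) {
  sc <- list(
    n_features_common = check_count(n_features_common, "n_features_common"),
    n_specific_a = check_count(n_specific_a, "n_specific_a"),
    n_specific_b = check_count(n_specific_b, "n_specific_b"),
    n_replicates = check_count(n_replicates, "n_replicates", min = 1L),
    tissue_effect_sd = check_nonneg(tissue_effect_sd, "tissue_effect_sd"),
    noise_sd = check_nonneg(noise_sd, "noise_sd"),
    ion_multiplicity = check_nonneg(ion_multiplicity, "ion_multiplicity"),
    dropout_rate = check_prob(dropout_rate, "dropout_rate"),
    shared_ion_rate = check_prob(shared_ion_rate, "shared_ion_rate"),
    rng_seed = check_count(rng_seed, "rng_seed")
  )
  class(sc) <- "omics_scenario"
  sc
}

#' @export
print.omics_scenario <- function(x, ...) {
  cat(sprintf(
    "omics scenario: %d common + %d/%d specific features, %d replicates/tissue, effect sd %.2f, noise sd %.2f (seed %d)\n",
    x$n_features_common, x$n_specific_a, x$n_specific_b, x$n_replicates,
    x$tissue_effect_sd, x$noise_sd, x$rng_seed))
  invisible(x)
}

# Shared ground-truth feature frame: id, membership, planted log2 effect
# (endosperm minus embryo) and per-tissue true mean log2 abundance.
scenario_truth <- function(scenario, base_mean, base_sd, prefix) {
  n_c <- scenario$n_features_common
  n_a <- scenario$n_specific_a
  n_b <- scenario$n_specific_b
  n <- n_c + n_a + n_b
  membership <- rep(c("common", "specific_a", "specific_b"), c(n_c, n_a, n_b))
  id <- sprintf("%s%05d", prefix, seq_len(n))
  base <- rnorm(n, base_mean, base_sd)
  effect <- ifelse(membership == "common",
                   rnorm(n, 0, scenario$tissue_effect_sd), 0)
  data.frame(
    feature_id = id,
    membership = membership,
    log2_effect = effect,
    log2_mean_embryo = ifelse(membership == "specific_b", NA_real_,
                              base - effect / 2),
    log2_mean_endosperm = ifelse(membership == "specific_a", NA_real_,
                                 base + effect / 2),
    stringsAsFactors = FALSE
  )
}

#' Generate a synthetic peptide-ion quantification table
#'
#' Emulates a label-free XIC quantification export: one row per
#' (ion, tissue, replicate) with a summed chromatographic peak area.
#' Proteins carry a zero-truncated Poisson number of ions; each ion takes a
#' share of the protein's exp-scale abundance and is observed with
#' multiplicative log-normal noise. Per-replicate dropout leaves `NA` areas
#' (undetected), and a fraction of ions is assigned to a second protein so
#' the downstream specificity filter has work to do. Proteins specific to
#' one tissue produce no signal in the other.
#'
#' @param scenario An [omics_scenario()].
#' @return A list with `ions` (data frame: `ion_id`, `protein_ids`
#'   (`;`-separated), `tissue`, `replicate`, `area`) and `truth` (per-protein
#'   ground truth: membership, planted log2 effect, true tissue means).
#' @export
gen_peptide_ion_table <- function(scenario) {
  stopifnot(inherits(scenario, "omics_scenario"))
  with_seed(scenario$rng_seed, {
    # log2 XIC areas of seed proteins typically span ~15-30
    truth <- scenario_truth(scenario, base_mean = 22, base_sd = 2, prefix = "Os01g")
    truth$feature_id <- paste0(truth$feature_id, ".1")
    n_prot <- nrow(truth)
    n_ions <- pmax(1L, rpois(n_prot, scenario$ion_multiplicity))
    rows <- vector("list", n_prot)
    ion_counter <- 0L
    for (i in seq_len(n_prot)) {
      k <- n_ions[i]
      w <- runif(k)
      w <- w / sum(w)
      shared <- runif(k) < scenario$shared_ion_rate
      second <- sample(truth$feature_id[-i], k, replace = TRUE)
      prot_ids <- ifelse(shared, paste(truth$feature_id[i], second, sep = ";"),
                         truth$feature_id[i])
      ion_id <- sprintf("pep%06d_z2", ion_counter + seq_len(k))
      ion_counter <- ion_counter + k
      per_tissue <- lapply(TISSUES, function(tis) {
        mu <- truth[[paste0("log2_mean_", tis)]][i]
        if (is.na(mu)) return(NULL)
        reps <- seq_len(scenario$n_replicates)
        grid <- expand.grid(ion = seq_len(k), replicate = reps)
        area <- 2^(mu + rnorm(nrow(grid), 0, scenario$noise_sd)) * w[grid$ion]
        area[runif(nrow(grid)) < scenario$dropout_rate] <- NA_real_
        data.frame(ion_id = ion_id[grid$ion],
                   protein_ids = prot_ids[grid$ion],
                   tissue = tis, replicate = grid$replicate,
                   area = area, stringsAsFactors = FALSE)
      })
      rows[[i]] <- do.call(rbind, per_tissue)
    }
    ions <- do.call(rbind, rows)
    rownames(ions) <- NULL
    names(truth)[names(truth) == "feature_id"] <- "protein_id"
    list(ions = ions, truth = truth)
  })
}

#' Generate a synthetic probe intensity matrix with presence calls
#'
#' Emulates a normalized two-tissue microarray experiment: log2-scale
#' intensities (Gaussian noise around a per-probe mean shifted by the
#' planted tissue effect) and per-sample P/M/A detection calls. Probes
#' specific to one tissue are called `A` in the other tissue and carry only
#' background-level intensity there; `dropout_rate` degrades calls of
#' genuinely present probes to `M` or `A` to exercise consensus rules.
#'
#' @param scenario An [omics_scenario()].
#' @param feature_ids Optional probe identifiers overriding the generated
#'   ones (used to couple layers in the full pipeline).
#' @param effects Optional vector of planted log2 effects for common
#'   features, overriding the scenario's random draw.
#' @return A list with `matrix` (a [probe_matrix()]) and `truth`.
#' @export
gen_probe_matrix <- function(scenario, feature_ids = NULL, effects = NULL) {
  stopifnot(inherits(scenario, "omics_scenario"))
  with_seed(scenario$rng_seed + 1L, {
    # GC-RMA-like log2 intensities: expressed ~N(8,2), background ~N(3,0.5)
    truth <- scenario_truth(scenario, base_mean = 8, base_sd = 2,
                            prefix = "probe_")
    if (!is.null(feature_ids)) {
      stopifnot(length(feature_ids) == nrow(truth))
      truth$feature_id <- feature_ids
    }
    if (!is.null(effects)) {
      stopifnot(length(effects) == sum(truth$membership == "common"))
      common <- truth$membership == "common"
      base <- (truth$log2_mean_embryo[common] + truth$log2_mean_endosperm[common]) / 2
      truth$log2_effect[common] <- effects
      truth$log2_mean_embryo[common] <- base - effects / 2
      truth$log2_mean_endosperm[common] <- base + effects / 2
    }
    n <- nrow(truth)
    reps <- scenario$n_replicates
    samples <- paste(rep(TISSUES, each = reps), rep(seq_len(reps), 2), sep = "_")
    design <- data.frame(sample = samples,
                         tissue = rep(TISSUES, each = reps),
                         replicate = rep(seq_len(reps), 2),
                         stringsAsFactors = FALSE)
    intensity <- matrix(NA_real_, n, length(samples),
                        dimnames = list(truth$feature_id, samples))
    calls <- matrix("A", n, length(samples),
                    dimnames = list(truth$feature_id, samples))
    for (j in seq_along(samples)) {
      tis <- design$tissue[j]
      mu <- truth[[paste0("log2_mean_", tis)]]
      present <- !is.na(mu)
      intensity[, j] <- rnorm(n, ifelse(present, mu, 3),
                              ifelse(present, scenario$noise_sd, 0.5))
      call_j <- ifelse(present, "P", "A")
      degrade <- present & runif(n) < scenario$dropout_rate
      call_j[degrade] <- sample(c("M", "A"), sum(degrade), replace = TRUE)
      calls[, j] <- call_j
    }
    names(truth)[names(truth) == "feature_id"] <- "probe_id"
    list(matrix = probe_matrix(intensity, calls, design), truth = truth)
  })
}

#' Generate a synthetic per-dry-weight metabolite table
#'
#' Emulates a GC-MS peak-area table: one row per (metabolite, tissue,
#' replicate) with a peak area per mg dry weight, drawn log-normally around
#' the planted per-mg tissue means. Tissue-specific metabolites are missing
#' (`NA`) in the other tissue; per-replicate dropout adds sporadic missing
#' values.
#'
#' @param scenario An [omics_scenario()].
#' @param mass A [seed_mass_model()]; recorded with the truth so per-seed
#'   expectations can be derived, the per-mg areas themselves do not depend
#'   on it.
#' @return A list with `metabolites` (data frame: `name`, `class`, `tissue`,
#'   `replicate`, `peak_area_per_mg`) and `truth`.
#' @export
gen_metabolite_table <- function(scenario, mass = seed_mass_model()) {
  stopifnot(inherits(scenario, "omics_scenario"))
  stopifnot(inherits(mass, "seed_mass_model"))
  with_seed(scenario$rng_seed + 2L, {
    # per-mg log2 peak areas around 2^10 arbitrary units
    truth <- scenario_truth(scenario, base_mean = 10, base_sd = 1.5,
                            prefix = "met_")
    classes <- c("Amino acids", "Carbohydrate", "Organic acids",
                 "Sugar alcohol", "Apolar", "Fatty acids")
    truth$class <- sample(classes, nrow(truth), replace = TRUE)
    reps <- seq_len(scenario$n_replicates)
    grid <- expand.grid(i = seq_len(nrow(truth)), tissue = TISSUES,
                        replicate = reps, stringsAsFactors = FALSE)
    mu <- ifelse(grid$tissue == "embryo",
                 truth$log2_mean_embryo[grid$i],
                 truth$log2_mean_endosperm[grid$i])
    area <- 2^(mu + rnorm(nrow(grid), 0, scenario$noise_sd))
    area[!is.na(area) & runif(nrow(grid)) < scenario$dropout_rate] <- NA_real_
    metabolites <- data.frame(
      name = truth$feature_id[grid$i],
      class = truth$class[grid$i],
      tissue = grid$tissue,
      replicate = grid$replicate,
      peak_area_per_mg = area,
      stringsAsFactors = FALSE
    )
    ord <- order(metabolites$name, metabolites$tissue, metabolites$replicate)
    metabolites <- metabolites[ord, ]
    rownames(metabolites) <- NULL
    names(truth)[names(truth) == "feature_id"] <- "name"
    list(metabolites = metabolites, truth = truth, mass = mass)
  })
}

AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Evolve an aligned protein family along a tree
#'
#' Simulates ungapped, equal-length protein sequences along a phylogeny
#' under a uniform (Jukes-Cantor-like, 20-state) substitution model: on a
#' branch of length `t`, each site experiences at least one substitution
#' event with probability `1 - exp(-rate * t)`, and an affected site is
#' redrawn uniformly from the 20 amino acids (so it may revert). With
#' `subst_rate = 0` all tips equal the root sequence.
#'
#' @param tree A rooted or unrooted `phylo` tree with branch lengths.
#' @param seq_length Number of alignment columns.
#' @param subst_rate Per-site substitution rate per unit branch length.
#' @param rng_seed Integer seed.
#' @return Named character vector of tip sequences (names = tip labels),
#'   with the root sequence in attribute `"root"`.
#' @export
gen_protein_family <- function(tree, seq_length, subst_rate, rng_seed = 1L) {
  stopifnot(inherits(tree, "phylo"))
  seq_length <- check_count(seq_length, "seq_length", min = 1L)
  check_nonneg(subst_rate, "subst_rate")
  if (is.null(tree$edge.length)) {
    stop_param("tree must have branch lengths")
  }
  with_seed(rng_seed, {
    n_tip <- length(tree$tip.label)
    root <- n_tip + 1L
    seqs <- vector("list", n_tip + tree$Nnode)
    seqs[[root]] <- sample(AA_ALPHABET, seq_length, replace = TRUE)
    # parents precede children in a preorder edge walk
    ord <- order(tree$edge[, 1])
    edge <- tree$edge[ord, , drop = FALSE]
    len <- tree$edge.length[ord]
    # walk edges until every child is filled (handles arbitrary edge order)
    remaining <- seq_len(nrow(edge))
    while (length(remaining)) {
      ready <- remaining[vapply(edge[remaining, 1],
                                function(p) !is.null(seqs[[p]]), logical(1))]
      if (!length(ready)) stop_param("tree edges are not connected to the root")
      for (e in ready) {
        parent_seq <- seqs[[edge[e, 1]]]
        hit <- runif(seq_length) < 1 - exp(-subst_rate * len[e])
        child_seq <- parent_seq
        if (any(hit)) {
          child_seq[hit] <- sample(AA_ALPHABET, sum(hit), replace = TRUE)
        }
        seqs[[edge[e, 2]]] <- child_seq
      }
      remaining <- setdiff(remaining, ready)
    }
    out <- vapply(seq_len(n_tip), function(i) paste(seqs[[i]], collapse = ""),
                  character(1))
    names(out) <- tree$tip.label
    attr(out, "root") <- paste(seqs[[root]], collapse = "")
    out
  })
}
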