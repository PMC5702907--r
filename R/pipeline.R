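#' Pipeline run configuration
#'
#' Collects every tunable the end-to-end analysis uses: per-layer
#' significance levels (0.05 for proteins and metabolites, 0.01 for
#' transcripts), the >=2-of-3 detection rule, the presence-call consensus
#' rule, the ratio-mode switch, the metabolite FDR procedure, the seed mass
#' model, the synthetic scenarios used when no input files are given, the
#' mRNA-protein coupling used by the simulator, and the RNG seed. Configs
#' round-trip through JSON ([write_run_config()] / [read_run_config()]).
#'
#' @param alpha_proteins,alpha_transcripts,alpha_metabolites,alpha_enrichment
#'   Per-layer significance levels.
#' @param min_detections Replicate-detection threshold shared by the
#'   peptide-ion and metabolite filters.
#' @param call_rule Presence-call consensus rule (see
#'   [consensus_detection()]).
#' @param ratio_mode Protein ratio mode (see [tissue_log2_ratio()]).
#' @param metabolite_fdr `"BH"` or `"BY"`.
#' @param mass A [seed_mass_model()].
#' @param scenario [omics_scenario()] for the proteome/transcriptome layers.
#' @param metabolite_scenario [omics_scenario()] for the metabolome layer;
#'   defaults to the study's 117 common / 6 embryo-specific / 1
#'   endosperm-specific structure.
#' @param coupling_rho Correlation between planted mRNA and protein tissue
#'   effects in the simulator.
#' @param rng_seed Master seed; layer seeds are derived from it.
#' @return An object of class `run_config`.
#' @export
run_config <- function(alpha_proteins = 0.05,
                       alpha_transcripts = 0.01,
                       alpha_metabolites = 0.05,
                       alpha_enrichment = 0.05,
                       min_detections = 2L,
                       call_rule = "two-of-n",
                       ratio_mode = "mean-of-raw",
                       metabolite_fdr = "BH",
                       mass = seed_mass_model(),
                       scenario = omics_scenario(),
                       metabolite_scenario = omics_scenario(
                         n_features_common = 117, n_specific_a = 6,
                         n_specific_b = 1, ion_multiplicity = 1,
                         tissue_effect_sd = 2, noise_sd = 0.4),
                       coupling_rho = 0.3,
                       rng_seed = 1L) {
  cfg <- list(
    alpha_proteins = check_prob(alpha_proteins, "alpha_proteins"),
    alpha_transcripts = check_prob(alpha_transcripts, "alpha_transcripts"),
    alpha_metabolites = check_prob(alpha_metabolites, "alpha_metabolites"),
    alpha_enrichment = check_prob(alpha_enrichment, "alpha_enrichment"),
    min_detections = check_count(min_detections, "min_detections", min = 1L),
    call_rule = match.arg(call_rule, c("two-of-n", "all", "any")),
    ratio_mode = match.arg(ratio_mode, c("mean-of-raw", "mean-of-log")),
    metabolite_fdr = match.arg(metabolite_fdr, c("BH", "BY")),
    mass = mass,
    scenario = scenario,
    metabolite_scenario = metabolite_scenario,
    coupling_rho = coupling_rho,
    rng_seed = check_count(rng_seed, "rng_seed")
  )
  stopifnot(inherits(mass, "seed_mass_model"),
            inherits(scenario, "omics_scenario"),
            inherits(metabolite_scenario, "omics_scenario"),
            is.numeric(coupling_rho), abs(coupling_rho) <= 1)
  class(cfg) <- "run_config"
  cfg
}

#' @rdname run_config
#' @param config A `run_config`.
#' @param path JSON file path.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  plain <- lapply(config, function(x) if (is.list(x)) unclass(x) else x)
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(plain, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$mass <- do.call(seed_mass_model, raw$mass)
  raw$scenario <- do.call(omics_scenario, raw$scenario)
  raw$metabolite_scenario <- do.call(omics_scenario, raw$metabolite_scenario)
  do.call(run_config, raw)
}

# Derive a reproducible 31-bit sub-seed from the master seed.
derive_seed <- function(seed, offset) {
  (seed * 7919 + offset * 104729) %% 2147483647
}

#' Simulate a complete set of coupled pipeline inputs
#'
#' Draws the three omics layers from the configured scenarios, with the
#' transcriptome planted effects correlated to the proteome effects at
#' `coupling_rho`, locus-named proteins (`OsNNgNNNNN.1`), probes named after
#' the same loci, and a bijective probe-to-locus map; plus a random protein
#' family evolved along a random tree for the phylogeny stage and a flat
#' synthetic annotation map over the protein loci.
#'
#' @param config A [run_config()].
#' @return A list with `proteome`, `transcriptome`, `metabolome`,
#'   `probe_map`, `annotation`, `family` (sequences + generating tree).
#' @export
simulate_pipeline_inputs <- function(config) {
  stopifnot(inherits(config, "run_config"))
  sc <- config$scenario
  sc$rng_seed <- derive_seed(config$rng_seed, 1L)
  proteome <- gen_peptide_ion_table(sc)

  loci <- normalize_locus(proteome$truth$protein_id)
  probe_ids <- paste0(loci, "_at")
  sc_t <- sc
  sc_t$rng_seed <- derive_seed(config$rng_seed, 2L)
  common <- proteome$truth$membership == "common"
  prot_eff <- proteome$truth$log2_effect[common]
  rho <- config$coupling_rho
  coupled <- with_seed(derive_seed(config$rng_seed, 3L), {
    z <- rnorm(sum(common), 0, sc_t$tissue_effect_sd)
    if (sd(prot_eff) > 0) {
      rho * prot_eff / sd(prot_eff) * sc_t$tissue_effect_sd +
        sqrt(1 - rho^2) * z
    } else {
      z
    }
  })
  transcriptome <- gen_probe_matrix(sc_t, feature_ids = probe_ids,
                                    effects = coupled)
  probe_map <- data.frame(probe_id = probe_ids, locus = loci,
                          stringsAsFactors = FALSE)

  sc_m <- config$metabolite_scenario
  sc_m$rng_seed <- derive_seed(config$rng_seed, 4L)
  metabolome <- gen_metabolite_table(sc_m, config$mass)

  annotation <- with_seed(derive_seed(config$rng_seed, 5L), {
    terms <- sprintf("GO:%07d", seq_len(12))
    ann <- lapply(terms, function(t) {
      sample(loci, max(5L, rbinom(1, length(loci), 0.05)))
    })
    names(ann) <- terms
    attr(ann, "labels") <- setNames(paste("synthetic term", seq_along(terms)),
                                    terms)
    ann
  })

  fam_seed <- derive_seed(config$rng_seed, 6L)
  family_tree <- with_seed(fam_seed, ape::rtree(13, rooted = FALSE))
  family_tree$tip.label <- c(sprintf("GluSyn%02d", 1:12), "GluX_syn")
  family <- gen_protein_family(family_tree, seq_length = 400,
                               subst_rate = 0.4, rng_seed = fam_seed + 1L)

  list(proteome = proteome, transcriptome = transcriptome,
       metabolome = metabolome, probe_map = probe_map,
       annotation = annotation,
       family = list(tree = family_tree, sequences = family))
}

#' Run the full tissue-contrast pipeline
#'
#' Executes every stage in order on the supplied inputs (simulated from the
#' config when `inputs` is `NULL`): peptide-ion filtering, within-sample
#' summation and protein rollup; per-layer specific/common partitions with
#' the inclusion-exclusion check; protein log2 ratios, median-favored
#' classes, Shapiro diagnostic and z-score differential; probe consensus
#' detection, Bonferroni t-tests and the strong-expression filter;
#' metabolite per-seed normalization and Student-t/FDR contrasts;
#' probe/protein pairing and mRNA-protein concordance; hypergeometric
#' enrichment of the embryo-favored protein loci; BLOSUM62/NJ phylogeny of
#' the simulated protein family. Deterministic given config + inputs.
#'
#' @param config A [run_config()].
#' @param inputs Optional result of [simulate_pipeline_inputs()] (or
#'   equivalently shaped real data).
#' @param out_dir Optional directory; when given, all tables, the Newick
#'   tree and a summary are persisted there via [write_report()].
#' @return An object of class `seedcontrast_report` (a nested list).
#' @export
run_pipeline <- function(config = run_config(), inputs = NULL,
                         out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(inputs)) inputs <- simulate_pipeline_inputs(config)
  log <- character()
  note <- function(fmt, ...) log <<- c(log, sprintf(fmt, ...))

  ## --- proteomics ---------------------------------------------------------
  filt <- filter_peptide_ions(inputs$proteome$ions,
                              min_detections = config$min_detections,
                              n_replicates = config$scenario$n_replicates)
  note("proteomics filter: %d rows in, %d removed non-specific, %d removed low-reproducibility",
       filt$report[["input_rows"]], filt$report[["removed_nonspecific"]],
       filt$report[["removed_low_reproducibility"]])
  summed <- sum_within_sample(filt$ions)
  roll <- rollup_protein_abundance(summed)
  prot_part <- partition_features(
    roll$means$protein_id[roll$means$tissue == "embryo"],
    roll$means$protein_id[roll$means$tissue == "endosperm"])
  ratios <- tissue_log2_ratio(roll, ratio_mode = config$ratio_mode)
  fav <- favored_by_median(ratios)
  shap <- if (nrow(ratios) >= 3 && nrow(ratios) <= 5000) {
    shapiro_normality(ratios)
  } else {
    list(W = NA_real_, p = NA_real_)
  }
  zres <- zscore_differential(ratios, alpha = config$alpha_proteins)
  note("proteomics: %d common proteins, %d endosperm-favored, %d embryo-favored, %d z-significant",
       nrow(ratios), fav$counts[["endosperm_favored"]],
       fav$counts[["embryo_favored"]], sum(zres$significant))

  ## --- transcriptome ------------------------------------------------------
  det <- consensus_detection(inputs$transcriptome$matrix,
                             rule = config$call_rule)
  probe_part <- partition_features(det$embryo, det$endosperm)
  de <- ttest_bonferroni(inputs$transcriptome$matrix, probes = det$universe,
                         alpha = config$alpha_transcripts)
  strong <- strong_de_filter(de, inputs$transcriptome$matrix,
                             universe = det$universe)
  common_probes <- probe_part$common
  pm <- inputs$transcriptome$matrix
  emb_mean <- rowMeans(pm$intensity[common_probes,
                                    pm$design$sample[pm$design$tissue == "embryo"],
                                    drop = FALSE])
  end_mean <- rowMeans(pm$intensity[common_probes,
                                    pm$design$sample[pm$design$tissue == "endosperm"],
                                    drop = FALSE])
  tcor <- if (length(common_probes) >= 3) {
    pearson_correlation(emb_mean, end_mean)
  } else {
    list(r = NA_real_, p = NA_real_, n = length(common_probes))
  }
  note("transcriptome: %d/%d detected, %d common, %d DE (Bonferroni %g), %d strong",
       probe_part$counts[["detected_a"]], probe_part$counts[["detected_b"]],
       probe_part$counts[["common"]], sum(de$de), config$alpha_transcripts,
       nrow(strong))

  ## --- metabolome ---------------------------------------------------------
  per_seed <- per_seed_normalize(inputs$metabolome$metabolites, config$mass)
  met_part <- call_tissue_specific(per_seed,
                                   min_detections = config$min_detections)
  met_diff <- differential_metabolites(per_seed,
                                       alpha = config$alpha_metabolites,
                                       min_detections = config$min_detections,
                                       fdr_method = config$metabolite_fdr)
  note("metabolome: %d common, %d specific, %d differential at FDR %g",
       met_part$counts[["common"]],
       met_part$counts[["specific_a"]] + met_part$counts[["specific_b"]],
       sum(met_diff$significant), config$alpha_metabolites)

  ## --- integration --------------------------------------------------------
  prot_for_pairs <- ratios
  prot_for_pairs$abundance <- (ratios$mean_embryo + ratios$mean_endosperm) / 2
  probe_ratios <- data.frame(feature_id = common_probes,
                             log2_ratio = end_mean - emb_mean,
                             stringsAsFactors = FALSE)
  pairing <- pair_probe_protein(prot_for_pairs, inputs$probe_map,
                                probe_ratios)
  conc <- if (nrow(pairing$pairs) >= 3) concordance(pairing$pairs) else NULL
  note("integration: %d unique probe-set/protein pairs, r = %s",
       nrow(pairing$pairs),
       if (is.null(conc)) "NA" else sprintf("%.3f", conc$r))

  ## --- enrichment ---------------------------------------------------------
  embryo_loci <- normalize_locus(prot_part$specific_a)
  fav_embryo <- fav$ratios$feature_id[fav$ratios$favored_class == "embryo-favored"]
  study <- unique(c(embryo_loci, normalize_locus(fav_embryo)))
  background <- unique(normalize_locus(
    roll$means$protein_id[roll$means$tissue == "embryo"]))
  study <- intersect(study, background)
  enr <- hypergeom_enrich(study, background, inputs$annotation,
                          alpha = config$alpha_enrichment)
  note("enrichment: %d terms tested, %d enriched at BY-FDR %g",
       nrow(enr), sum(enr$enriched), config$alpha_enrichment)

  ## --- phylogeny ----------------------------------------------------------
  dist <- blosum62_distance(inputs$family$sequences)
  nj <- neighbor_joining(dist)
  newick <- write_newick(nj)
  ng <- lapply(inputs$family$sequences, find_ng_cleavage)
  note("phylogeny: %d taxa, NJ tree with %d internal nodes",
       length(inputs$family$sequences), nj$Nnode)

  report <- list(
    config = config,
    proteomics = list(filter_report = filt$report, rollup = roll,
                      partition = prot_part, ratios = ratios, favored = fav,
                      shapiro = shap, zscore = zres),
    transcriptome = list(partition = probe_part, de = de, strong = strong,
                         correlation = tcor,
                         median_intensity = attr(strong, "median_intensity")),
    metabolome = list(partition = met_part, differential = met_diff),
    integration = list(pairing = pairing, concordance = conc),
    enrichment = enr,
    phylogeny = list(distances = dist, tree = nj, newick = newick,
                     ng_sites = ng),
    log = log
  )
  class(report) <- "seedcontrast_report"
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.seedcontrast_report <- function(x, ...) {
  cat("seedcontrast pipeline report\n")
  cat(paste0("  ", x$log, collapse = "\n"), "\n")
  invisible(x)
}

#' Persist a pipeline report as plain-text artifacts
#'
#' Writes every intermediate table as TSV, the tree as Newick and the stage
#' log as `summary.txt`, so that each stage can be re-run and checked
#' independently.
#'
#' @param report A `seedcontrast_report`.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(out_dir, ...)
  write_tsv(report$proteomics$rollup$means, p("protein_abundance.tsv"))
  write_tsv(report$proteomics$favored$ratios, p("protein_ratios.tsv"))
  write_tsv(report$proteomics$zscore, p("protein_zscore.tsv"))
  write_tsv(report$transcriptome$de, p("probe_de.tsv"))
  write_tsv(report$transcriptome$strong, p("probe_de_strong.tsv"))
  write_tsv(report$metabolome$differential, p("metabolite_differential.tsv"))
  write_tsv(report$integration$pairing$pairs, p("probe_protein_pairs.tsv"))
  write_tsv(report$enrichment, p("enrichment.tsv"))
  writeLines(report$phylogeny$newick, p("family_tree.nwk"))
  counts <- function(part) {
    data.frame(quantity = names(part$counts), value = unname(part$counts))
  }
  write_tsv(rbind(
    cbind(layer = "proteome", counts(report$proteomics$partition)),
    cbind(layer = "transcriptome", counts(report$transcriptome$partition)),
    cbind(layer = "metabolome", counts(report$metabolome$partition))
  ), p("partitions.tsv"))
  writeLines(report$log, p("summary.txt"))
  invisible(out_dir)
}
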