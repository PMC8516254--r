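#' @include io.R
#' @include popsim.R
#' @include permtest.R
NULL

#' Run the full HARE workflow from a configuration
#'
#' Chains the stages simulate -> variance partition -> HARE estimation ->
#' imputation -> prediction -> permutation baseline, writing every artifact
#' under `outDir` together with a JSON run manifest (configuration
#' snapshot, master seed, file digests, package version, timestamps). Two
#' runs with the same configuration and seed produce bit-identical
#' artifacts.
#'
#' @param config a named list or the path of a YAML file. Recognized
#'   entries (all optional, defaults in parentheses): `seed` (1),
#'   `n_founders` (26), `n_ranges` (60), `panel` (`"diverse"` or `"nam"`),
#'   `n_lines` (300), `n_families` (25), `rils_per_family` (12),
#'   `mosaic_block_mean` (10), `scenario` (a sublist passed to
#'   [simScenario()]), `model` (3), `n_causal_genes` (10),
#'   `trait_noise` (scenario default), `n_repeats` (20),
#'   `permutations` (0 = skip the permutation stage).
#' @param outDir output directory (created if needed).
#' @return invisibly, a list with the main in-memory artifacts (`panel`,
#'   `expression`, `varcomp`, `hare`, `imputed`, `prediction`,
#'   `permutation`) and the `manifest`.
#' @export
runPipeline <- function(config = list(), outDir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  dflt <- list(seed = 1L, n_founders = 26L, n_ranges = 60L,
               panel = "diverse", n_lines = 300L, n_families = 25L,
               rils_per_family = 12L, mosaic_block_mean = 10,
               scenario = list(), model = 3L, n_causal_genes = 10L,
               trait_noise = NULL, n_repeats = 20L, permutations = 0L)
  cfg <- utils::modifyList(dflt, config)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  seeds <- expandSeed(cfg$seed, 6L)

  scen <- do.call(simScenario, utils::modifyList(
    list(nGenes = min(40L, cfg$n_ranges), seed = seeds[2L]), cfg$scenario))
  founders <- makeFounders(cfg$n_founders, cfg$n_ranges)
  panel <- if (cfg$panel == "nam")
    simulateNamPanel(founders, cfg$n_families, cfg$rils_per_family,
                     seed = seeds[1L])
  else simulateDiversePanel(founders, cfg$n_lines,
                            cfg$mosaic_block_mean, seed = seeds[1L])
  writeHaplotypePanel(panel, file.path(outDir, "haplotypes.tsv"))

  se <- simulateExpression(panel, scen)
  writeExpression(se, file.path(outDir, "expression"))

  vc <- partitionExpression(se, panel, model = cfg$model)
  utils::write.table(vc, file.path(outDir, "varcomp.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  hm <- hareFromExpression(se, panel, model = cfg$model)
  writeHareMatrix(hm, file.path(outDir, "hare.tsv"))

  imp <- imputeExpression(hm, panel)
  utils::write.table(
    data.frame(line_id = rownames(imp), imp, check.names = FALSE),
    file.path(outDir, "imputed_expression.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)

  ph <- simulatePhenotype(se, nCausalGenes = cfg$n_causal_genes,
                          traitNoise = cfg$trait_noise, seed = seeds[3L])
  writePhenotype(ph$trait, file.path(outDir, "phenotype.tsv"))

  pred <- evaluateWithinPanel(imp, ph$trait, nRepeats = cfg$n_repeats,
                              seed = seeds[4L])
  utils::write.table(
    data.frame(repeat_id = seq_along(accuracies(pred)),
               accuracy = accuracies(pred), lambda = pred@lambdas),
    file.path(outDir, "prediction.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)

  perm <- NULL
  if (cfg$permutations > 0L) {
    perm <- runPermutationStudy(hm, panel, ph$trait, k = cfg$permutations,
                                seed = seeds[5L],
                                nRepeats = cfg$n_repeats)
    jsonlite::write_json(
      list(observed_mean = perm$observedMean,
           permuted_means = perm$permutedMeans, p_high = perm$pHigh,
           p_low = perm$pLow, k = perm$k),
      file.path(outDir, "permutation.json"), auto_unbox = TRUE, digits = NA)
  }

  arte <- list.files(outDir, full.names = TRUE)
  arte <- arte[!grepl("manifest\\.json$", arte)]
  manifest <- list(
    package = as.character(utils::packageVersion("hare")),
    seed = cfg$seed,
    config = cfg[setdiff(names(cfg), "trait_noise")],
    digests = as.list(tools::md5sum(sort(arte))),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(panel = panel, expression = se, varcomp = vc, hare = hm,
                 imputed = imp, prediction = pred, permutation = perm,
                 manifest = manifest))
}
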