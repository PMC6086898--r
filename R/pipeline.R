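## Pipeline orchestration: a single declarative configuration drives the
## four analysis stages (stats -> divergence -> ltr -> synteny) over either
## simulated or on-disk inputs, producing a consolidated RunReport.

#' Build and validate a pipeline configuration
#'
#' Either `simulate = TRUE` (inputs come from [simulateGenomePair()] with
#' `simParams`) or paths to on-disk inputs are given. Thresholds default to
#' the package's standard values; validation fails early on missing files
#' or inconsistent thresholds.
#'
#' @param simulate logical; generate inputs with the simulator.
#' @param simParams a [simulationParams()] list (when `simulate`).
#' @param paths named list of input paths (`genomeA`, `genomeB`, `genesA`,
#'   `genesB`, `cdsA`, `cdsB`, `orthologs`, `coverage`, `selfAlignments`,
#'   `teCandidates`, `teDomains`) for file-driven runs.
#' @param divergence a [DivergenceConfig-class].
#' @param maxRankGap,minAnchors chaining parameters.
#' @param ltrEMax,ltrMinSimilarity LTR classification thresholds.
#' @param regionBoundaries optional arm/centre boundary `data.frame`
#'   (see [assignRegions()]).
#' @param stages character subset of
#'   `c("stats", "divergence", "ltr", "synteny")`.
#' @param outDir optional output directory for stage TSV/JSON files.
#' @param seed integer seed.
#' @return a validated configuration list of class `nemadiv_config`.
#' @export
pipelineConfig <- function(simulate = TRUE, simParams = simulationParams(),
                           paths = list(),
                           divergence = divergenceConfig(),
                           maxRankGap = 10, minAnchors = 3,
                           ltrEMax = 1e-20, ltrMinSimilarity = 95,
                           regionBoundaries = NULL,
                           stages = c("stats", "divergence", "ltr",
                                      "synteny"),
                           outDir = NULL, seed = 1) {
  stopifnot(methods::is(divergence, "DivergenceConfig"))
  methods::validObject(divergence)
  bad <- setdiff(stages, c("stats", "divergence", "ltr", "synteny"))
  if (length(bad)) stop("unknown stage: ", bad[1])
  if (maxRankGap < 1 || minAnchors < 1) {
    stop("maxRankGap and minAnchors must be >= 1")
  }
  if (ltrEMax <= 0) stop("ltrEMax must be > 0")
  if (!simulate) {
    need <- c("genomeA", "cdsA", "cdsB", "orthologs")
    missing_keys <- setdiff(need, names(paths))
    if (length(missing_keys)) {
      stop("file-driven run needs path: ", missing_keys[1])
    }
    for (p in unlist(paths)) {
      if (!file.exists(p)) stop("input file not found: ", p)
    }
  }
  structure(list(simulate = simulate, simParams = simParams, paths = paths,
                 divergence = divergence, maxRankGap = maxRankGap,
                 minAnchors = minAnchors, ltrEMax = ltrEMax,
                 ltrMinSimilarity = ltrMinSimilarity,
                 regionBoundaries = regionBoundaries, stages = stages,
                 outDir = outDir, seed = seed),
            class = "nemadiv_config")
}

#' Load a pipeline configuration from YAML
#'
#' Reads a declarative key-value file whose keys mirror the
#' [pipelineConfig()] arguments (with `divergence` given as a mapping of
#' `mu`, `generation_days`, `dn_max`, `ds_max`, `ds_min`, `nc_reference`).
#'
#' @param path path to a YAML file.
#' @return a validated configuration list.
#' @export
readPipelineConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  y <- yaml::read_yaml(path)
  div <- y$divergence %||% list()
  cfg <- divergenceConfig(
    mu = div$mu %||% 9.0e-9,
    generationDays = div$generation_days %||% 30,
    dnMax = div$dn_max %||% 0.5,
    dsMax = div$ds_max %||% 5,
    dsMin = div$ds_min %||% 0.0005,
    ncReference = div$nc_reference %||% 61)
  sp <- y$sim_params %||% list()
  simParams <- do.call(simulationParams,
                       sp[names(sp) %in% names(formals(simulationParams))])
  pipelineConfig(
    simulate = y$simulate %||% TRUE,
    simParams = simParams,
    paths = y$paths %||% list(),
    divergence = cfg,
    maxRankGap = y$max_rank_gap %||% 10,
    minAnchors = y$min_anchors %||% 3,
    ltrEMax = y$ltr_e_max %||% 1e-20,
    ltrMinSimilarity = y$ltr_min_similarity %||% 95,
    stages = y$stages %||% c("stats", "divergence", "ltr", "synteny"),
    outDir = y$out_dir %||% NULL,
    seed = y$seed %||% 1)
}

#' Run the analysis pipeline
#'
#' Executes the selected stages in dependency order over simulated or
#' on-disk inputs and returns a [RunReport-class] with per-stage headline
#' numbers; unselected stages are marked `"skipped"`.
#'
#' @param config a [pipelineConfig()] (or YAML path).
#' @return a [RunReport-class].
#' @export
runPipeline <- function(config = pipelineConfig()) {
  if (is.character(config)) config <- readPipelineConfig(config)
  stopifnot(inherits(config, "nemadiv_config"))
  if (config$simulate) {
    config$simParams$seed <- config$seed
    sim <- simulateGenomePair(config$simParams)
  } else {
    p <- config$paths
    sim <- list(
      assemblyA = readAssembly(p$genomeA),
      assemblyB = if (!is.null(p$genomeB)) readAssembly(p$genomeB),
      genesA = if (!is.null(p$genesA)) readGeneModels(p$genesA),
      genesB = if (!is.null(p$genesB)) readGeneModels(p$genesB),
      cdsA = Biostrings::readDNAStringSet(p$cdsA),
      cdsB = Biostrings::readDNAStringSet(p$cdsB),
      orthologs = readOrthologTable(p$orthologs),
      coverage = if (!is.null(p$coverage)) readCoverageTrack(p$coverage),
      selfAlignments = if (!is.null(p$selfAlignments))
        utils::read.delim(p$selfAlignments),
      teCandidates = if (!is.null(p$teCandidates))
        utils::read.delim(p$teCandidates),
      teDomains = if (!is.null(p$teDomains)) utils::read.delim(p$teDomains))
  }
  stages <- list(stats = "skipped", divergence = "skipped",
                 ltr = "skipped", synteny = "skipped")

  if ("stats" %in% config$stages) {
    st <- assemblyStats(sim$assemblyA)
    hap <- if (!is.null(sim$coverage) && !is.null(sim$selfAlignments)) {
      filterResidualHaplotypes(sim$assemblyA, sim$selfAlignments,
                               sim$coverage)
    }
    stages$stats <- list(assembly = as.data.frame(st),
                         gap_runs = nrow(gapRuns(sim$assemblyA)),
                         haplotigs_removed =
                           if (is.null(hap)) character(0) else hap$removed)
  }

  if ("divergence" %in% config$stages) {
    m <- match(sim$orthologs$gene_a, names(sim$cdsA))
    m2 <- match(sim$orthologs$gene_b, names(sim$cdsB))
    ok <- !is.na(m) & !is.na(m2)
    div <- divergencePipeline(sim$orthologs$gene_a[ok],
                              sim$cdsA[m[ok]], sim$cdsB[m2[ok]],
                              config$divergence)
    stages$divergence <- list(
      n_input = div$result@nInput, n_retained = div$result@nRetained,
      median_adjusted_ds = medianAdjustedDs(div$result),
      t_generations = tGenerations(div$result),
      t_years = tYears(div$result),
      filter_counts = as.list(div$filterCounts),
      estimates = div$estimates)
  }

  if ("ltr" %in% config$stages &&
      !is.null(sim$teCandidates) && nrow(sim$teCandidates)) {
    cls <- classifyCandidates(sim$teCandidates, sim$teDomains,
                              eMax = config$ltrEMax,
                              minSimilarity = config$ltrMinSimilarity)
    stages$ltr <- list(counts = as.list(summarizeLtr(cls)),
                       classified = cls)
  }

  if ("synteny" %in% config$stages &&
      !is.null(sim$genesA) && !is.null(sim$genesB)) {
    anchors <- makeAnchors(sim$genesA, sim$genesB, sim$orthologs)
    ch <- chainAnchors(anchors, config$maxRankGap, config$minAnchors)
    cov <- syntenyCoverage(ch$blocks, sim$assemblyA)
    regions <- assignRegions(
      stats::setNames(Biostrings::width(sim$assemblyA),
                      names(sim$assemblyA))[
                        as.character(unique(GenomeInfoDb::seqnames(
                          sim$genesA)))],
      config$regionBoundaries)
    cmp <- if (!identical(stages$divergence, "skipped")) {
      est <- stages$divergence$estimates
      tryCatch(compareRegionDs(est, sim$genesA, regions,
                               "arm_vs_centre"),
               error = function(e) NULL)
    }
    stages$synteny <- list(n_blocks = nrow(ch$blocks),
                           coverage_percent = cov,
                           blocks = ch$blocks,
                           arm_vs_centre = cmp)
  }

  report <- methods::new("RunReport", stages = stages, seed = config$seed,
                         version = as.character(
                           utils::packageVersion("nemadiv")),
                         config = list(
                           stages = config$stages, seed = config$seed,
                           simulate = config$simulate))
  if (!is.null(config$outDir)) writeRunReport(report, config$outDir)
  report
}

#' Write a RunReport to disk
#'
#' Headline numbers go to `report.json`; per-gene estimates, classified
#' candidates and block tables to TSV alongside.
#'
#' @param report a [RunReport-class].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
writeRunReport <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  slim <- report@stages
  if (is.list(slim$divergence)) {
    writeEstimates(slim$divergence$estimates,
                   file.path(dir, "estimates.tsv"))
    slim$divergence$estimates <- NULL
  }
  if (is.list(slim$ltr)) {
    utils::write.table(slim$ltr$classified, file.path(dir, "ltr_classes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    slim$ltr$classified <- NULL
  }
  if (is.list(slim$synteny)) {
    utils::write.table(slim$synteny$blocks, file.path(dir, "blocks.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    slim$synteny$blocks <- NULL
    slim$synteny$arm_vs_centre <-
      if (!is.null(slim$synteny$arm_vs_centre)) {
        slim$synteny$arm_vs_centre[c("u_statistic", "p_value", "medians",
                                     "n")]
      }
  }
  jsonlite::write_json(
    list(version = report@version, seed = report@seed,
         config = report@config, stages = slim),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE, force = TRUE)
  invisible(dir)
}
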