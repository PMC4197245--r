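## End-to-end orchestration with config validation, provenance headers and
## checksummed outputs. The R functions are the entry points; every stage is
## also callable on its own.

#' Pipeline configuration
#'
#' Collects the survey thresholds (all at their published defaults), the
#' stage list and either a simulation configuration or paths to real inputs.
#' The validated configuration is serialized into the run directory so each
#' run carries its own reproducibility record.
#'
#' @param seed run seed (drives simulation and bootstrap stages).
#' @param sim a [simConfig()] to generate the inputs, or `NULL` to read
#'   `genome_paths`/`pspm_path`/`tree_path`.
#' @param genome_paths,pspm_path,tree_path input files when `sim` is `NULL`.
#' @param min_orf_len,p_cutoff,signal_cutoff,decay,min_group_size survey
#'   thresholds: minimum ORF length (50 aa), scan P-value cutoff (6e-11),
#'   signal-score cutoff (0.400), lineage decay per internal node (0.8),
#'   minimum orthologous group size (4).
#' @param stages stages to run, in order, from
#'   `c("discover", "pspm", "iopd", "ortho", "dnds", "gc")`.
#' @param bootstrap_reps bootstrap replicates for the dN/dS stage.
#' @return validated configuration list of class `pipelineConfig`.
#' @export
pipelineConfig <- function(seed, sim = NULL, genome_paths = NULL,
                           pspm_path = NULL, tree_path = NULL,
                           min_orf_len = 50, p_cutoff = 6e-11,
                           signal_cutoff = 0.400, decay = 0.8,
                           min_group_size = 4,
                           stages = c("discover", "pspm", "iopd", "ortho",
                                      "dnds", "gc"),
                           bootstrap_reps = 200) {
  if (missing(seed)) stop("a seed is mandatory")
  if (!(p_cutoff > 0 && p_cutoff < 1))
    stop("p_cutoff must lie strictly within (0, 1)")
  if (!(signal_cutoff >= 0 && signal_cutoff < 1))
    stop("signal_cutoff must lie within [0, 1)")
  if (!(decay > 0 && decay <= 1)) stop("decay must lie in (0, 1]")
  if (min_orf_len < 1 || min_group_size < 1)
    stop("min_orf_len and min_group_size must be positive")
  bad <- setdiff(stages, c("discover", "pspm", "iopd", "ortho", "dnds", "gc"))
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  if (is.null(sim) && is.null(genome_paths))
    stop("either a simulation config or genome paths are required")
  structure(list(seed = seed, sim = sim, genome_paths = genome_paths,
                 pspm_path = pspm_path, tree_path = tree_path,
                 min_orf_len = min_orf_len, p_cutoff = p_cutoff,
                 signal_cutoff = signal_cutoff, decay = decay,
                 min_group_size = min_group_size, stages = stages,
                 bootstrap_reps = bootstrap_reps),
            class = "pipelineConfig")
}

## Serialize the config to YAML (S4/phylo-free representation).
configRecord <- function(config) {
  rec <- config
  class(rec) <- NULL
  if (!is.null(rec$sim)) {
    sim <- rec$sim
    class(sim) <- NULL
    sim$pspm <- if (is.null(sim$pspm)) "default" else motifId(sim$pspm)
    rec$sim <- sim
  }
  rec
}

#' Write a result table with a provenance header
#'
#' Writes a TSV preceded by comment lines carrying the tool version, config
#' hash and seed, so every output is traceable to its run. Coordinates in all
#' tables are 0-based, half-open; strand is `{+,-}`.
#'
#' @param df data.frame to write.
#' @param path output path.
#' @param provenance named list with `version`, `config_hash`, `seed`.
#' @return `path`, invisibly.
#' @export
writeResultTable <- function(df, path, provenance) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# cepkit %s | config=%s | seed=%s",
                     provenance$version, provenance$config_hash,
                     provenance$seed), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the pipeline end to end
#'
#' Executes the configured stages in order (discover, pspm, iopd, ortho,
#' dnds, gc) and writes one TSV per stage into `out_dir`, each with a
#' provenance header; the run manifest records an MD5 checksum per output.
#' A stage failure halts the run with the stage name and the list of
#' completed stages. Reruns with identical configuration and inputs produce
#' identical checksums.
#'
#' @param config a [pipelineConfig()].
#' @param out_dir run directory (created if absent).
#' @return invisibly, a list with `genes`, `groups`, `iopds`, `outputs`
#'   (paths) and the `provenance` record.
#' @export
runPipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipelineConfig"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_path <- file.path(out_dir, "run_config.yaml")
  yaml::write_yaml(configRecord(config), cfg_path)
  prov <- list(version = as.character(packageVersion("cepkit")),
               config_hash = unname(tools::md5sum(cfg_path)),
               seed = config$seed)
  completed <- character(0)
  outputs <- character(0)
  stageFail <- function(stage, e)
    stop("stage '", stage, "' failed: ", conditionMessage(e),
         " (completed: ",
         if (length(completed)) paste(completed, collapse = ", ") else "none",
         ")", call. = FALSE)

  ## inputs
  if (!is.null(config$sim)) {
    ds <- simulateDataset(config$sim)
    assemblies <- ds$assemblies; tree <- ds$tree; pspm <- ds$pspm
  } else {
    assemblies <- lapply(config$genome_paths, readGenomeFasta)
    names(assemblies) <- vapply(assemblies, assemblyId, character(1))
    pspm <- if (!is.null(config$pspm_path)) readMemeMotif(config$pspm_path)
      else defaultDomainPSPM()
    tree <- if (!is.null(config$tree_path)) readSpeciesTree(config$tree_path)
      else NULL
  }

  genes <- NULL; groups <- NULL; iopds <- NULL
  emit <- function(df, name) {
    p <- file.path(out_dir, name)
    writeResultTable(df, p, prov)
    outputs[[length(outputs) + 1L]] <<- p
  }
  for (stage in config$stages) {
    tryCatch({
      if (stage == "discover") {
        dcfg <- discoveryConfig(config$min_orf_len, config$p_cutoff,
                                config$signal_cutoff)
        genes <- do.call(rbind, lapply(assemblies, discoverGenes,
                                       pspm = pspm, config = dcfg))
        rownames(genes) <- NULL
        emit(genes, "genes.tsv")
      } else if (stage == "pspm") {
        if (is.null(genes)) stop("requires the discover stage")
        doms <- do.call(rbind, lapply(seq_len(nrow(genes)), function(i) {
          offs <- as.integer(strsplit(genes$domain_offsets[i], ",")[[1]])
          data.frame(sequence = substring(genes$prepropeptide[i], offs + 1L,
                                          offs + 15L),
                     orf_id = genes$orf_id[i],
                     assembly_id = genes$assembly_id[i],
                     organism = genes$organism[i])
        }))
        doms <- assignWeights(doms, tree, config$decay)
        wpspm <- buildPSPM(doms, motifId = "weighted-domain-pspm")
        writeMemeMotif(wpspm, file.path(out_dir, "motif.meme"))
        outputs[[length(outputs) + 1L]] <- file.path(out_dir, "motif.meme")
        emit(doms, "domains.tsv")
      } else if (stage == "iopd") {
        if (is.null(genes)) stop("requires the discover stage")
        iopds <- computeIopds(genes, level = "gene")
        emit(iopds, "iopd.tsv")
        fam_n <- table(iopds$family)
        if (length(fam_n) >= 2 && all(fam_n >= 2)) {
          M <- rankTukey(iopds$distance, iopds$family)
          emit(data.frame(family_a = rownames(M)[row(M)[upper.tri(M)]],
                          family_b = colnames(M)[col(M)[upper.tri(M)]],
                          p_adj = M[upper.tri(M)]), "iopd_tukey.tsv")
        }
      } else if (stage == "ortho") {
        if (is.null(genes)) stop("requires the discover stage")
        sim_sc <- similarityScores(setNames(genes$prepropeptide,
                                            genes$gene_id), genes$organism)
        groups <- pruneToCliques(buildRbhGraph(sim_sc),
                                 config$min_group_size)
        emit(groups, "groups.tsv")
      } else if (stage == "dnds") {
        if (is.null(groups)) stop("requires the ortho stage")
        prof <- list()
        for (gid in unique(groups$group_id)) {
          ids <- groups$gene_id[groups$group_id == gid]
          cds <- genes$cds[match(ids, genes$gene_id)]
          if (length(unique(nchar(cds))) != 1L || length(cds) < 4L) next
          p <- sitewiseDnds(cds, bootstrap_reps = config$bootstrap_reps,
                            seed = config$seed + gid)
          p$group_id <- gid
          prof[[length(prof) + 1L]] <- p
        }
        if (length(prof)) emit(do.call(rbind, prof), "dnds.tsv")
      } else if (stage == "gc") {
        if (is.null(genes)) stop("requires the discover stage")
        gc <- data.frame(gene_id = genes$gene_id, family = genes$family,
                         gc = gcContent(genes$cds))
        emit(gc, "gc.tsv")
        fam_n <- table(gc$family)
        if (length(fam_n) >= 2 && all(fam_n >= 2)) {
          M <- logitTukey(gc$gc, gc$family)
          emit(data.frame(family_a = rownames(M)[row(M)[upper.tri(M)]],
                          family_b = colnames(M)[col(M)[upper.tri(M)]],
                          p_adj = M[upper.tri(M)]), "gc_tukey.tsv")
        }
      }
      completed <- c(completed, stage)
    }, error = function(e) stageFail(stage, e))
  }
  manifest <- data.frame(file = basename(unlist(outputs)),
                         md5 = unname(tools::md5sum(unlist(outputs))))
  writeResultTable(manifest, file.path(out_dir, "run_manifest.tsv"), prov)
  invisible(list(genes = genes, groups = groups, iopds = iopds,
                 outputs = unlist(outputs), provenance = prov))
}
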