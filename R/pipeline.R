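#' Default pipeline configuration
#'
#' One flat list exposing every analysis knob with its package default:
#' DEG FDR level `alpha`, permutation count, log pseudocount, fuzzy
#' c-means fuzzifier and candidate `k_range`, restarts, network threshold
#' `r_threshold`, kappa grouping threshold, enrichment `q_threshold`, and
#' the MDS dimension. By default the pipeline simulates its input
#' (`simulate$enabled = TRUE`); set `counts`, `samples` (and optionally
#' `gene_sets`) to file paths and `simulate$enabled = FALSE` to analyse
#' real data. `seed` drives every stochastic stage.
#'
#' @param seed integer master seed.
#' @return a named list; serializable to/from YAML with [yaml::write_yaml()].
#' @export
defaultPipelineConfig <- function(seed = 1) {
  list(seed = as.integer(seed),
       alpha = 0.05, n_perm = 10000, pseudocount = 1,
       k_range = c(2, 10), fuzzifier = 2, n_starts = 20,
       r_threshold = 0.95, kappa_threshold = 0.4, q_threshold = 0.05,
       mds_dims = 2,
       simulate = list(enabled = TRUE, n_random_sets = 10,
                       genes_per_archetype = NULL),
       counts = NULL, samples = NULL, gene_sets = NULL)
}

#' Run the full temporal-transcriptome pipeline
#'
#' Executes, in dependency order: input acquisition (simulation or file
#' reading), RPKM/log normalization, three-test DEG calling over all
#' pairwise age comparisons, fuzzy c-means clustering of DEG profiles with
#' the validity-index vote, quadratic U/bell shape analysis, per-cluster
#' hypergeometric enrichment with kappa term grouping, correlation-network
#' construction (overall and age-stratified) with hub and component
#' reports, and classical MDS of the samples. Every stage writes a TSV
#' whose first line is a comment carrying the configuration hash, and a
#' `manifest.json` records the hash, seed, and the row count of every
#' output — re-running with an identical configuration reproduces
#' byte-identical outputs.
#'
#' @param config configuration list (see [defaultPipelineConfig()]) or the
#'   path of a YAML file containing one.
#' @param outDir output directory, created if needed.
#' @return invisibly, the manifest list.
#' @export
runPipeline <- function(config = defaultPipelineConfig(), outDir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(defaultPipelineConfig(), config)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  hash <- .configHash(cfg)
  note <- paste0("config_hash: ", hash)
  files <- list()
  emit <- function(df, name) {
    path <- file.path(outDir, name)
    .writeTsv(df, path, comments = note)
    files[[name]] <<- nrow(df)
    path
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  ## 1. input
  truth <- NULL
  ae <- stage("input", {
    if (isTRUE(cfg$simulate$enabled)) {
      gpa <- cfg$simulate$genes_per_archetype
      sc <- if (is.null(gpa)) simConfig()
            else simConfig(genesPerArchetype = unlist(gpa))
      sim <- simulateAgingCounts(sc, seed = cfg$seed)
      truth <- sim$truth
      emit(truth, "truth.tsv")
      sim$experiment
    } else {
      for (key in c("counts", "samples"))
        if (is.null(cfg[[key]]))
          stop("config key '", key, "' is required when simulation is off")
      readAgingExperiment(cfg$counts, cfg$samples)
    }
  })
  writeAgingExperiment(ae, file.path(outDir, "counts.tsv"),
                       file.path(outDir, "samples.tsv"))
  files[["counts.tsv"]] <- nrow(ae); files[["samples.tsv"]] <- ncol(ae)

  ## 2. normalization
  ae <- stage("normalize", logTransform(rpkm(ae),
                                        pseudocount = cfg$pseudocount))
  norm <- SummarizedExperiment::assay(ae, "logrpkm")
  emit(data.frame(gene_id = rownames(norm), norm, check.names = FALSE),
       "normalized.tsv")

  ## 3. DEG calling
  deg <- stage("deg", callDegs(ae, alpha = cfg$alpha, nPerm = cfg$n_perm,
                               seed = cfg$seed,
                               pseudocount = cfg$pseudocount))
  emit(deg$results, "deg_tests.tsv")
  emit(deg$calls, "degs.tsv")
  degGenes <- deg$calls$gene[deg$calls$is_deg]

  ## 4. clustering
  clusterLabels <- NULL
  if (length(degGenes) >= 4L) {
    fit <- stage("cluster", {
      prof <- standardizeProfiles(ae, degGenes)
      kr <- seq(cfg$k_range[1L], min(cfg$k_range[2L], nrow(prof) - 1L))
      validityVote(prof, kRange = kr, m = cfg$fuzzifier,
                   nStarts = cfg$n_starts, seed = cfg$seed)
    })
    prof <- standardizeProfiles(ae, degGenes)
    emit(data.frame(gene = rownames(prof), membership(fit),
                    cluster = hardLabels(fit), check.names = FALSE),
         "memberships.tsv")
    emit(data.frame(cluster = seq_len(fit@k), centroids(fit),
                    check.names = FALSE), "centroids.tsv")
    emit(validityTable(fit), "validity.tsv")
    emit(summarizeClusters(fit, prof)$summary, "cluster_summary.tsv")
    clusterLabels <- stats::setNames(hardLabels(fit), rownames(prof))
  }

  ## 5. shape analysis
  shapes <- stage("shapes", fitShapes(ae, genes = if (length(degGenes))
    degGenes else rownames(ae), alpha = cfg$alpha))
  emit(shapes, "shapes.tsv")

  ## 6. enrichment
  sets <- stage("gene_sets", {
    if (!is.null(cfg$gene_sets)) readGmt(cfg$gene_sets)
    else if (!is.null(truth))
      simulateGeneSets(truth, nRandomSets = cfg$simulate$n_random_sets,
                       seed = cfg$seed)
    else NULL
  })
  if (!is.null(sets) && !is.null(clusterLabels)) {
    enr <- stage("enrich", {
      background <- deg$calls$gene
      do.call(rbind, lapply(sort(unique(clusterLabels)), function(cl) {
        res <- hypergeomEnrich(names(clusterLabels)[clusterLabels == cl],
                               sets, background)
        if (nrow(res)) cbind(cluster = cl, res) else NULL
      }))
    })
    emit(enr, "enrichment.tsv")
    sig <- enr[enr$q < cfg$q_threshold, , drop = FALSE]
    if (nrow(sig)) {
      grp <- stage("kappa_group", {
        do.call(rbind, lapply(unique(sig$cluster), function(cl) {
          sub <- sig[sig$cluster == cl, , drop = FALSE]
          cbind(cluster = cl,
                kappaGroup(sub, sets, deg$calls$gene,
                           kappaThreshold = cfg$kappa_threshold))
        }))
      })
      emit(grp, "term_groups.tsv")
    }
  }

  ## 7. networks
  net <- stage("network", buildNetwork(ae, rThreshold = cfg$r_threshold))
  emit(networkEdges(net), "network_edges.tsv")
  if (igraph::gorder(networkGraph(net)) > 0L) {
    hub <- hubReport(net)
    emit(data.frame(hub = hub$hub, degree = hub$degree,
                    ties = paste(hub$ties, collapse = ";"),
                    neighborhood_nodes = hub$neighborhoodNodes,
                    neighborhood_edges = hub$neighborhoodEdges),
         "hub.tsv")
    comps <- networkComponents(net)
    emit(data.frame(component = rep(seq_along(comps), lengths(comps)),
                    gene = unlist(comps, use.names = FALSE)),
         "components.tsv")
  }
  if (length(degGenes) >= 2L) {
    strat <- stage("stratified_network",
                   ageStratifiedNetworks(ae, rThreshold = cfg$r_threshold,
                                         genes = degGenes,
                                         clusterLabels = clusterLabels))
    jac <- strat$jaccard
    emit(data.frame(age = rownames(jac), jac, check.names = FALSE),
         "jaccard.tsv")
  }

  ## 8. ordination
  mds <- stage("mds", mdsSamples(ae, dims = cfg$mds_dims))
  pts <- data.frame(sample = rownames(mds$points), mds$points,
                    age_weeks = unname(ageWeeks(ae)), type = "sample",
                    check.names = FALSE)
  cents <- data.frame(sample = paste0("centroid_", rownames(mds$centroids)),
                      mds$centroids,
                      age_weeks = as.numeric(rownames(mds$centroids)),
                      type = "centroid", check.names = FALSE)
  emit(rbind(pts, cents), "mds.tsv")

  manifest <- list(config_hash = hash, seed = cfg$seed,
                   n_stages = 8L, outputs = files)
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

# md5 of the canonical YAML rendering of the configuration
.configHash <- function(cfg) {
  cfg <- cfg[order(names(cfg))]
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(cfg), tmp)
  unname(tools::md5sum(tmp))
}
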