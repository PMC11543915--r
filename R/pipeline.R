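#' Assemble a pipeline run configuration
#'
#' A \code{RunConfig} holds the synthetic-cohort spec (or an input dataset
#' manifest), all module parameters and seeds, and the output directory; it
#' round-trips losslessly through YAML/JSON via
#' \code{\link{readRunConfig}} / \code{\link{writeRunConfig}}.
#'
#' @param cohort a \code{\link{cohortSpec}} (simulated input), or
#'   \code{NULL} when a manifest of on-disk datasets is given.
#' @param manifest optional data.frame with columns path, format, platform,
#'   dataset_id for reading real datasets.
#' @param source_map named character vector dataset id -> source label.
#' @param reference_dataset id of the dataset used as annotation reference
#'   (its truth labels are the reference labels).
#' @param out_dir artifact directory.
#' @param seed master seed for all stochastic stages.
#' @param params named list overriding module parameters (n_bins, n_ctrl,
#'   resolution, k_neighbors, n_pcs, margin_cutoff, delta_cutoff,
#'   ks_iterations, ks_modules, sensitivity_sizes, run_sensitivity,
#'   top_fraction, subtype2_clusters, min_cells_per_gene,
#'   min_features_per_cell, mito_threshold).
#' @return a \code{RunConfig} list.
#' @export
runConfig <- function(cohort = NULL, manifest = NULL, source_map = NULL,
                      reference_dataset = NULL, out_dir = tempfile("run"),
                      seed = 1, params = list(), gene_sets = NULL) {
  defaults <- list(n_bins = 25, n_ctrl = 100, resolution = 2.0,
                   k_neighbors = 20, n_pcs = 12, margin_cutoff = 0.25,
                   delta_cutoff = 0.05, ks_iterations = 200,
                   ks_modules = c("EPI_ICM", "PE", "TE", "AMN"),
                   sensitivity_sizes = c(100, 400, 800, 1000, 1500),
                   run_sensitivity = FALSE, top_fraction = 0.05,
                   subtype2_clusters = integer(),
                   min_cells_per_gene = 10, min_features_per_cell = 100,
                   mito_threshold = 0.20)
  defaults[names(params)] <- params
  structure(list(cohort = cohort, manifest = manifest,
                 source_map = source_map,
                 reference_dataset = reference_dataset,
                 out_dir = out_dir, seed = as.integer(seed),
                 params = defaults, gene_sets = gene_sets),
            class = "RunConfig")
}

#' @rdname runConfig
#' @param path YAML config path.
#' @export
writeRunConfig <- function(config, path) {
  lst <- unclass(config)
  if (!is.null(lst$cohort)) {
    tmp <- tempfile()
    writeCohortSpec(lst$cohort, tmp)
    lst$cohort <- yaml::read_yaml(tmp)
    unlink(tmp)
  }
  if (!is.null(lst$source_map)) lst$source_map <- as.list(lst$source_map)
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname readRunConfig
#' @name readRunConfig
#' @title Read a pipeline configuration from YAML
#' @param path YAML config path.
#' @return a \code{RunConfig}.
#' @export
readRunConfig <- function(path) {
  lst <- yaml::read_yaml(path)
  cohort <- NULL
  if (!is.null(lst$cohort)) {
    tmp <- tempfile()
    yaml::write_yaml(lst$cohort, tmp)
    cohort <- readCohortSpec(tmp)
    unlink(tmp)
  }
  runConfig(cohort = cohort,
            manifest = if (!is.null(lst$manifest))
              as.data.frame(lst$manifest),
            source_map = unlist(lst$source_map),
            reference_dataset = lst$reference_dataset,
            out_dir = lst$out_dir, seed = lst$seed,
            params = lapply(lst$params, function(p)
              if (is.list(p)) unlist(p) else p))
}

.STAGES <- c("simulate", "qc", "score", "annotate", "compose", "landscape",
             "ks", "pathways", "report")

.needStage <- function(state, what, stage_needed) {
  if (is.null(state[[what]]))
    stop("missing upstream artifact '", what, "': run stage '",
         stage_needed, "' first")
  state[[what]]
}

.writeProvenance <- function(path, stage, config) {
  jsonlite::write_json(list(stage = stage, seed = config$seed,
                            config_hash = .hashObject(unclass(config))),
                       paste0(path, ".provenance.json"),
                       auto_unbox = TRUE, digits = NA)
}

#' Run the comparison pipeline
#'
#' Executes the requested stages in dependency order
#' (simulate -> qc -> score -> annotate -> compose -> landscape -> ks ->
#' pathways -> report), writing each stage's artifacts plus a JSON
#' provenance record (stage, seed, config hash) into
#' \code{config$out_dir}. Reruns with an identical config produce
#' byte-identical numeric artifacts. Requesting a stage whose upstream
#' artifacts are absent raises an error naming the stage to run first.
#'
#' @param config a \code{\link{runConfig}}.
#' @param stages subset of stage names, or \code{"all"}.
#' @param state optional environment carrying artifacts from a previous
#'   partial run.
#' @return the state environment (artifacts: cohort, filtered, normalized,
#'   scores, scores_z, annotation, composition, association, embedding,
#'   assignment, distributions, jsd, pcd, ks, activity).
#' @export
runPipeline <- function(config, stages = "all", state = new.env()) {
  stopifnot(inherits(config, "RunConfig"))
  if (identical(stages, "all")) stages <- .STAGES
  bad <- setdiff(stages, .STAGES)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  stages <- .STAGES[.STAGES %in% stages]
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- config$params
  for (stage in stages) {
    switch(stage,
      simulate = {
        if (is.null(config$cohort) && is.null(config$manifest))
          stop("config has neither a cohort spec nor a manifest")
        state$cohort <- if (!is.null(config$cohort))
          generateCohort(config$cohort)
        else {
          mf <- config$manifest
          setNames(lapply(seq_len(nrow(mf)), function(i)
            readDataset(mf$path[i], mf$format[i], mf$platform[i],
                        mf$dataset_id[i])), mf$dataset_id)
        }
      },
      qc = {
        cohort <- .needStage(state, "cohort", "simulate")
        res <- lapply(cohort, qcFilter,
                      min_cells_per_gene = p$min_cells_per_gene,
                      min_features_per_cell = p$min_features_per_cell,
                      mito_threshold = p$mito_threshold)
        state$filtered <- lapply(res, `[[`, "dataset")
        state$qc_reports <- lapply(res, `[[`, "report")
        for (d in names(state$qc_reports))
          writeQCReport(state$qc_reports[[d]],
                        file.path(config$out_dir,
                                  paste0("qc_", d, ".json")))
      },
      score = {
        filtered <- .needStage(state, "filtered", "qc")
        state$normalized <- lapply(filtered, logNormalize)
        mats <- lapply(state$normalized, .logcounts)
        shared <- Reduce(intersect, lapply(mats, rownames))
        joint <- do.call(cbind, lapply(mats, function(m)
          m[shared, , drop = FALSE]))
        ds_ids <- unlist(lapply(state$normalized, function(d)
          as.character(colData(d)$dataset_id)), use.names = FALSE)
        state$scores <- scoreModules(joint, dataset = ds_ids,
                                     n_bins = p$n_bins, n_ctrl = p$n_ctrl,
                                     seed = config$seed)
        state$scores_minmax <- minmaxModuleScores(state$scores)
        state$scores_z <- suppressWarnings(zscaleByDataset(state$scores))
        f <- file.path(config$out_dir, "module_scores.tsv")
        writeModuleScores(state$scores, f)
        .writeProvenance(f, "score", config)
      },
      annotate = {
        normalized <- .needStage(state, "normalized", "score")
        if (is.null(state$assignment)) .computeLandscape(state, config)
        ref_id <- config$reference_dataset %||% names(normalized)[1]
        ref <- normalized[[ref_id]]
        if (is.null(trueType(ref)))
          stop("reference dataset '", ref_id, "' carries no labels")
        ref_labels <- .primaryLabel(trueType(ref))
        keep <- ref_labels != "unknown"
        mats <- lapply(normalized, .logcounts)
        shared <- Reduce(intersect, lapply(mats, rownames))
        joint <- do.call(cbind, lapply(mats, function(m)
          m[shared, , drop = FALSE]))
        ds_ids <- unlist(lapply(normalized, function(d)
          as.character(colData(d)$dataset_id)), use.names = FALSE)
        clusters <- state$assignment$cluster[
          match(colnames(joint), state$assignment$cell_id)]
        state$annotation <- consensusAnnotation(
          joint, clusters,
          reference = .logcounts(normalized[[ref_id]])[, keep, drop = FALSE],
          ref_labels = ref_labels[keep],
          margin_cutoff = p$margin_cutoff, delta_cutoff = p$delta_cutoff,
          cell_ids = colnames(joint), dataset_ids = ds_ids)
        if (length(p$subtype2_clusters)) {
          lab <- annotationLabels(state$annotation)
          lab$consensus <- refinePESubtypes(lab$consensus, clusters,
                                            p$subtype2_clusters)
          state$annotation <- AnnotationTable(lab)
        }
        f <- file.path(config$out_dir, "annotation.tsv")
        writeAnnotationTable(state$annotation, f)
        .writeProvenance(f, "annotate", config)
      },
      compose = {
        ann <- .needStage(state, "annotation", "annotate")
        if (is.null(config$source_map))
          stop("config$source_map is required for the compose stage")
        state$composition <- compositionTable(ann, config$source_map,
                                              include_unknown = FALSE)
        state$composition_unknown <- compositionTable(
          ann, config$source_map, include_unknown = TRUE)
        state$association <- tryCatch(
          chiSquaredAssociation(state$composition),
          error = function(e) structure(list(error = conditionMessage(e)),
                                        class = "AssociationResult"))
        ndat <- nrow(state$composition$counts)
        state$composition_clustering <- if (ndat >= 3)
          clusterCompositions(state$composition) else NULL
        f <- file.path(config$out_dir, "composition.tsv")
        writeCompositionTable(state$composition, f)
        if (is.null(state$association$error))
          writeAssociationResult(state$association,
                                 file.path(config$out_dir,
                                           "association.json"))
        .writeProvenance(f, "compose", config)
      },
      landscape = {
        .needStage(state, "normalized", "score")
        if (is.null(state$assignment)) .computeLandscape(state, config)
        state$distributions <- clusterDistributions(state$assignment)
        state$jsd <- jsdMatrix(state$distributions)
        state$pcd <- suppressWarnings(pcdMatrix(state$distributions))
        state$dist_pca <- if (nrow(state$distributions) >= 3)
          pcaOfDistributions(state$distributions) else NULL
        f <- file.path(config$out_dir, "jsd.tsv")
        writeDistanceMatrix(state$jsd, f)
        writeDistanceMatrix(state$pcd, file.path(config$out_dir, "pcd.tsv"))
        writeClusterAssignment(state$assignment,
                               file.path(config$out_dir, "clusters.tsv"))
        .writeProvenance(f, "landscape", config)
      },
      ks = {
        scores_z <- .needStage(state, "scores_z", "score")
        mods <- intersect(p$ks_modules,
                          colnames(moduleScores(scores_z)))
        state$ks <- lapply(setNames(mods, mods), function(mod)
          bootstrapKSMatrix(scores_z, mod,
                            n_iterations = p$ks_iterations,
                            seed = config$seed))
        for (mod in mods) {
          f <- file.path(config$out_dir, paste0("ks_", mod, ".tsv"))
          writeDistanceMatrix(state$ks[[mod]]$matrix, f)
          .writeProvenance(f, "ks", config)
        }
        if (isTRUE(p$run_sensitivity)) {
          state$ks_sensitivity <- ksSensitivity(
            scores_z, mods[1], sizes = p$sensitivity_sizes,
            n_iterations = p$ks_iterations, seed = config$seed)
          writeSensitivityReport(state$ks_sensitivity,
                                 file.path(config$out_dir,
                                           "ks_sensitivity.json"))
        }
      },
      pathways = {
        normalized <- .needStage(state, "normalized", "score")
        sets <- config$gene_sets %||% markerSets(defaultMarkerPanel())
        mats <- lapply(normalized, .logcounts)
        shared <- Reduce(intersect, lapply(mats, rownames))
        joint <- do.call(cbind, lapply(mats, function(m)
          m[shared, , drop = FALSE]))
        state$activity <- pathwayActivity(joint, sets,
                                          top_fraction = p$top_fraction,
                                          seed = config$seed)
        grouping <- data.frame(
          dataset = unlist(lapply(normalized, function(d)
            as.character(colData(d)$dataset_id)), use.names = FALSE))
        if (!is.null(state$annotation))
          grouping$cell_type <- annotationLabels(state$annotation)$consensus
        state$activity_by_group <- aggregateActivity(state$activity,
                                                     grouping)
        f <- file.path(config$out_dir, "pathway_activity.tsv")
        writeActivityTable(state$activity_by_group, f,
                           id_column = "group")
        .writeProvenance(f, "pathways", config)
      },
      report = {
        summary <- list(
          datasets = if (!is.null(state$cohort)) names(state$cohort),
          n_cells_post_qc = if (!is.null(state$filtered))
            vapply(state$filtered, ncol, 1L),
          association = if (!is.null(state$association) &&
                            is.null(state$association$error))
            list(statistic = state$association$statistic,
                 df = state$association$df,
                 p_value = state$association$p_value),
          ks_modules = names(state$ks))
        jsonlite::write_json(summary,
                             file.path(config$out_dir, "report.json"),
                             auto_unbox = TRUE, digits = NA)
      })
  }
  invisible(state)
}

# joint embedding + graph clustering shared by annotate and landscape
.computeLandscape <- function(state, config) {
  normalized <- .needStage(state, "normalized", "score")
  p <- config$params
  state$embedding <- jointEmbed(normalized, n_pcs = p$n_pcs)
  state$assignment <- graphCluster(state$embedding,
                                   resolution = p$resolution,
                                   k_neighbors = p$k_neighbors,
                                   seed = config$seed)
  invisible(state)
}

# map simulated truth labels onto the annotation label domain
.primaryLabel <- function(types) {
  out <- types
  out[out %in% c("PE_I", "PE_II")] <- "PE"
  out[out == "intermediate_EPI_TE"] <- "unknown"
  out
}
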