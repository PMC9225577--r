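#' Correlate predicted and measured interaction strengths
#'
#' Pairs every defined (recipient, influencer) entry of a predicted
#' interaction matrix with the corresponding measured entry and computes
#' the Pearson correlation. By default only measured interactions
#' significant at the MIS matrix's alpha are included (insignificant
#' growth differences say nothing about direction); pairs with undefined
#' predictions are excluded and counted.
#'
#' @param pis \linkS4class{InteractionMatrix} of type \code{"PIS"}.
#' @param mis \linkS4class{InteractionMatrix} of type \code{"MIS"} over
#'   the same isolates.
#' @param significantOnly restrict to significant measured entries.
#' @return list with \code{r}, \code{p}, \code{n}, \code{pairs} (the
#'   paired data.frame), \code{nExcludedUndefined} and
#'   \code{perRecipient} (per-recipient correlations where >= 3 pairs).
#' @export
correlatePredictedMeasured <- function(pis, mis, significantOnly = TRUE) {
  stopifnot(is(pis, "InteractionMatrix"), interactionType(pis) == "PIS",
            is(mis, "InteractionMatrix"), interactionType(mis) == "MIS")
  sp <- interactionStrengths(pis)
  sm <- interactionStrengths(mis)
  iso <- intersect(rownames(sp), rownames(sm))
  if (length(iso) < 2) stop("no shared isolates between matrices")
  sp <- sp[iso, iso]; sm <- sm[iso, iso]
  sig <- isSignificant(mis)[iso, iso]
  grid <- expand.grid(recipient = iso, influencer = iso,
                      stringsAsFactors = FALSE)
  grid <- grid[grid$recipient != grid$influencer, ]
  grid$predicted <- sp[cbind(grid$recipient, grid$influencer)]
  grid$measured <- sm[cbind(grid$recipient, grid$influencer)]
  grid$significant <- sig[cbind(grid$recipient, grid$influencer)]
  nUndef <- sum(is.na(grid$predicted) & !is.na(grid$measured))
  keep <- complete.cases(grid[, c("predicted", "measured")])
  if (significantOnly) keep <- keep & grid$significant
  pairs <- grid[keep, , drop = FALSE]
  if (nrow(pairs) < 3) stop("fewer than 3 paired interaction values")
  if (sd(pairs$measured) == 0 || sd(pairs$predicted) == 0)
    stop("zero-variance vector: correlation undefined")
  ct <- cor.test(pairs$predicted, pairs$measured, method = "pearson")
  perRec <- do.call(rbind, lapply(split(pairs, pairs$recipient),
    function(d) {
      if (nrow(d) < 3 || sd(d$measured) == 0 || sd(d$predicted) == 0)
        return(NULL)
      cr <- cor.test(d$predicted, d$measured)
      data.frame(recipient = d$recipient[1], n = nrow(d),
                 r = unname(cr$estimate), p = cr$p.value,
                 stringsAsFactors = FALSE)
    }))
  rownames(perRec) <- NULL
  list(r = unname(ct$estimate), p = ct$p.value, n = nrow(pairs),
       pairs = pairs, nExcludedUndefined = nUndef,
       perRecipient = perRec)
}

#' Export a directed interaction network
#'
#' Writes the measured (or predicted) interaction matrix as a directed
#' graph -- source = influencer, target = recipient, edge weight = mean
#' interaction strength, boolean attribute \code{significant} -- in
#' GraphML or SIF (Cytoscape) dialects. Repeated exports of the same
#' object are byte-identical.
#'
#' @param mis an \linkS4class{InteractionMatrix}.
#' @param path output file path.
#' @param format \code{"graphml"} or \code{"sif"}.
#' @return \code{path}, invisibly.
#' @export
exportNetwork <- function(mis, path, format = c("graphml", "sif")) {
  format <- match.arg(format)
  stopifnot(is(mis, "InteractionMatrix"))
  s <- interactionStrengths(mis)
  sig <- isSignificant(mis)
  off <- !is.na(s)
  if (!any(off)) stop("interaction matrix has no defined entries")
  idx <- which(off, arr.ind = TRUE)
  edges <- data.frame(
    from = colnames(s)[idx[, "col"]],      # influencer (source)
    to = rownames(s)[idx[, "row"]],        # recipient (target)
    weight = s[idx],
    significant = sig[idx],
    stringsAsFactors = FALSE)
  edges <- edges[order(edges$from, edges$to), ]
  if (format == "sif") {
    writeLines(sprintf("%s\taffects\t%s", edges$from, edges$to), path)
  } else {
    g <- graph_from_data_frame(edges, directed = TRUE,
                               vertices = sort(rownames(s)))
    write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Run the full interaction-inference pipeline
#'
#' Executes the stages in order -- gated fold changes, utilization
#' profiles, substrate metrics, predicted interactions and ranks,
#' growth-based measured interactions (final OD and respiration),
#' background filtering and cross-feeding classification, and the
#' predicted-vs-measured comparison -- and writes every result table into
#' an output directory together with the resolved configuration.
#'
#' The configuration is a named list or a YAML file with either a
#' \code{simulate} block (\code{seed}, \code{isolates},
#' \code{metabolites}, \code{cv}, \code{replicates},
#' \code{cross_feeding}) or a \code{paths} block naming input CSVs
#' (\code{targeted}, \code{targeted_metadata}, \code{growth},
#' \code{respiration}, \code{untargeted}, \code{untargeted_metadata}),
#' plus optional \code{alpha}.
#'
#' @param config named list or path to a YAML config file.
#' @param outDir output directory (created if missing).
#' @return invisibly, a list with all intermediate objects
#'   (\code{foldChanges}, \code{profiles}, \code{metrics}, \code{pis},
#'   \code{ranks}, \code{misOD}, \code{misResp}, \code{crossFeeding},
#'   \code{comparison}).
#' @export
runPipeline <- function(config, outDir) {
  if (is.character(config)) config <- read_yaml(config)
  stopifnot(is.list(config))
  alpha <- if (!is.null(config$alpha)) config$alpha else 0.05
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  if (!is.null(config$simulate)) {
    sc <- config$simulate
    seed <- if (!is.null(sc$seed)) sc$seed else 1
    truth <- stage("simulate", simulateTruth(
      nIsolates = if (!is.null(sc$isolates)) sc$isolates else 8,
      nMetabolites = if (!is.null(sc$metabolites)) sc$metabolites else 89,
      seed = seed,
      crossFeeding = if (!is.null(sc$cross_feeding)) sc$cross_feeding
                     else TRUE))
    cv <- if (!is.null(sc$cv)) sc$cv else 0.1
    nrep <- if (!is.null(sc$replicates)) sc$replicates else 3
    mono <- stage("simulate",
                  simulateMonocultures(truth, cv = cv,
                                       nReplicates = nrep, seed = seed))
    seq_ <- stage("simulate",
                  simulateSequential(truth, cv = cv, nReplicates = nrep,
                                     seed = seed))
    targeted <- mono$peaks
    growth <- seq_$growth
    untargeted <- seq_$peaks
  } else if (!is.null(config$paths)) {
    pth <- config$paths
    targeted <- stage("read", readPeakTable(pth$targeted,
                                            pth$targeted_metadata,
                                            tableKind = "targeted"))
    growth <- if (!is.null(pth$growth))
      stage("read", readGrowthTable(pth$growth, pth$respiration))
    else NULL
    untargeted <- if (!is.null(pth$untargeted))
      stage("read", readPeakTable(pth$untargeted,
                                  pth$untargeted_metadata,
                                  tableKind = "untargeted"))
    else NULL
  } else stop("config needs a 'simulate' or 'paths' block")

  fc <- stage("foldchange", gatedFoldChanges(targeted, alpha = alpha))
  profiles <- stage("profiles", utilizationProfiles(fc))
  metrics <- stage("metrics", substrateMetrics(profiles))
  pis <- stage("predict", predictedInteractions(profiles))
  ranks <- stage("predict", competitiveRank(pis))
  writeMatrix(fc, file.path(outDir, "fold_changes.csv"))
  writeMatrix(pValues(fc), file.path(outDir, "fold_change_pvalues.csv"))
  writeMatrix(profiles, file.path(outDir, "utilization_profiles.csv"))
  write.csv(metrics, file.path(outDir, "substrate_metrics.csv"),
            row.names = FALSE)
  writeMatrix(pis, file.path(outDir, "predicted_interactions.csv"))
  write.csv(ranks, file.path(outDir, "competitive_ranks.csv"),
            row.names = FALSE)

  misOD <- misResp <- comparison <- NULL
  if (!is.null(growth)) {
    params <- stage("growth", fitGrowthCurves(growth))
    write.csv(params, file.path(outDir, "growth_parameters.csv"),
              row.names = FALSE)
    misOD <- stage("growth", misMatrix(finalGrowth(growth), alpha = alpha,
                                       metric = "final_od"))
    writeMatrix(misOD, file.path(outDir, "mis_final_od.csv"))
    writeMatrix(pValues(misOD),
                file.path(outDir, "mis_final_od_pvalues.csv"))
    exportNetwork(misOD, file.path(outDir, "network_final_od.graphml"))
    exportNetwork(misOD, file.path(outDir, "network_final_od.sif"),
                  format = "sif")
    if (!is.null(growth$respiration)) {
      misResp <- stage("growth",
                       misMatrix(respirationGrowth(growth), alpha = alpha,
                                 metric = "respiration"))
      writeMatrix(misResp, file.path(outDir, "mis_respiration.csv"))
      exportNetwork(misResp,
                    file.path(outDir, "network_respiration.graphml"))
    }
    comparison <- stage("report", tryCatch(
      correlatePredictedMeasured(pis, misOD), error = function(e) NULL))
    if (!is.null(comparison))
      write.csv(comparison$pairs,
                file.path(outDir, "predicted_vs_measured.csv"),
                row.names = FALSE)
  }

  crossFeeding <- NULL
  if (!is.null(untargeted)) {
    kept <- stage("crossfeed", filterBackground(untargeted, alpha = alpha))
    production <- stage("crossfeed", callProduction(kept, alpha = alpha))
    write.csv(production$summary,
              file.path(outDir, "production_summary.csv"),
              row.names = FALSE)
    crossFeeding <- stage("crossfeed",
                          classifyCrossFeeding(kept, alpha = alpha))
    write.csv(crossFeeding$calls,
              file.path(outDir, "crossfeed_calls.csv"), row.names = FALSE)
    write.csv(crossFeeding$summary,
              file.path(outDir, "crossfeed_summary.csv"),
              row.names = FALSE)
  }
  write_yaml(config, file.path(outDir, "config_resolved.yaml"))
  invisible(list(foldChanges = fc, profiles = profiles, metrics = metrics,
                 pis = pis, ranks = ranks, misOD = misOD,
                 misResp = misResp, crossFeeding = crossFeeding,
                 comparison = comparison))
}
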