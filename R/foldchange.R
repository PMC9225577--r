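#' Significance-gated relative fold changes of medium metabolites
#'
#' For every (metabolite, isolate) cell, compares the isolate's spent-medium
#' replicates against its matched uninoculated-medium control replicates and
#' computes the relative fold change
#' \code{FC = mean(spent) / mean(control) - 1}. Comparisons are one-way
#' ANOVA with a Dunnett-style many-to-one post hoc test: within each
#' control group, all isolates sharing that control form one family per
#' metabolite, so the familywise error rate is controlled across isolates
#' compared against the same control. Cells with adjusted p > alpha are set
#' to exactly 0 ("no significant change"), the gating that downstream niche
#' overlap relies on.
#'
#' Negative FC is depletion (bounded below by -1), positive FC is
#' production. Cells with a control mean of zero but non-zero spent signal
#' have no defined ratio; they are returned as \code{NA} and flagged.
#'
#' @param phe a targeted \linkS4class{PeakHeightExperiment} with
#'   \code{spent} samples and matched \code{medium_control_*} samples.
#' @param alpha significance level for gating (default 0.05).
#' @param transform \code{"none"} tests raw peak heights;
#'   \code{"log10"} tests \code{log10(height + 1)}. Fold changes are always
#'   computed from raw means.
#' @param naPolicy what to do with metabolites carrying missing heights:
#'   \code{"drop"} removes the metabolite (NA row in the result, flagged);
#'   \code{"halfmin"} imputes half the metabolite's minimum observed height.
#' @return a \linkS4class{FoldChangeMatrix} (metabolites x isolates).
#' @examples
#' sim <- simulateMonocultures(simulateTruth(nIsolates = 3,
#'                                           nMetabolites = 12, seed = 1),
#'                             cv = 0.05, seed = 2)
#' fc <- gatedFoldChanges(sim$peaks)
#' fc
#' @export
gatedFoldChanges <- function(phe, alpha = 0.05,
                             transform = c("none", "log10"),
                             naPolicy = c("drop", "halfmin")) {
  transform <- match.arg(transform)
  naPolicy <- match.arg(naPolicy)
  stopifnot(is(phe, "PeakHeightExperiment"))
  cd <- as.data.frame(colData(phe))
  spent <- cd$role == "spent"
  if (!any(spent)) stop("no spent samples in table")
  isolates <- sort(unique(as.character(cd$isolate_id[spent])))
  mets <- rownames(phe)
  h <- peakHeights(phe)

  fc <- p <- matrix(NA_real_, length(mets), length(isolates),
                    dimnames = list(mets, isolates))
  nrep <- matrix(NA_integer_, length(mets), length(isolates),
                 dimnames = list(mets, isolates))
  flag <- matrix(FALSE, length(mets), length(isolates),
                 dimnames = list(mets, isolates))

  ## an isolate belongs to exactly one control group
  iso_group <- tapply(as.character(cd$control_group[spent]),
                      as.character(cd$isolate_id[spent]),
                      function(g) unique(g))
  if (any(lengths(iso_group) != 1))
    stop("isolate(s) mapped to more than one control_group: ",
         paste(names(iso_group)[lengths(iso_group) != 1], collapse = ", "))

  ctrl_roles <- c("medium_control_early", "medium_control_late",
                  "sdm_culture_control")
  for (g in unique(unlist(iso_group))) {
    iso_g <- names(iso_group)[unlist(iso_group) == g]
    ctrl_cols <- which(cd$role %in% ctrl_roles & cd$control_group == g)
    if (length(ctrl_cols) < 2)
      stop("control_group '", g, "' has fewer than 2 control samples")
    spent_cols <- lapply(iso_g, function(i)
      which(spent & cd$isolate_id == i))
    if (any(lengths(spent_cols) < 2))
      stop("fewer than 2 spent replicates for isolate(s): ",
           paste(iso_g[lengths(spent_cols) < 2], collapse = ", "))
    cols <- c(ctrl_cols, unlist(spent_cols))
    grp <- factor(rep(c(".control", iso_g),
                      c(length(ctrl_cols), lengths(spent_cols))),
                  levels = c(".control", iso_g))
    sub <- h[, cols, drop = FALSE]

    for (m in seq_along(mets)) {
      v <- sub[m, ]
      if (anyNA(v)) {
        if (naPolicy == "drop") {
          flag[m, iso_g] <- TRUE
          next
        }
        obs <- v[!is.na(v)]
        v[is.na(v)] <- if (length(obs)) min(obs) / 2 else 0
      }
      tv <- if (transform == "log10") log10(v + 1) else v
      res <- .dunnettTest(tv, grp, ".control")
      mu <- tapply(v, grp, mean)   # raw means regardless of transform
      for (i in iso_g) {
        p[m, i] <- res$p[[i]]
        nrep[m, i] <- sum(grp == i)
        if (mu[[".control"]] == 0) {
          if (mu[[i]] > 0) {       # ratio undefined
            flag[m, i] <- TRUE
          } else {
            fc[m, i] <- 0
          }
          next
        }
        fc[m, i] <- if (res$p[[i]] <= alpha)
          mu[[i]] / mu[[".control"]] - 1 else 0
      }
    }
  }
  new("FoldChangeMatrix", fc = fc, pvalues = p, alpha = alpha,
      nReplicates = nrep, flagged = flag)
}

#' Substrate-utilization profiles from gated fold changes
#'
#' The utilization profile of isolate r is the vector of depletion
#' fractions p[m, r] = max(0, -FC[m, r]): the fraction of metabolite m the
#' isolate significantly depleted from the medium. Produced (FC > 0),
#' unchanged (FC = 0) and undefined (NA) metabolites contribute 0. The
#' support of a profile is the set of metabolites with p > 0.
#'
#' @param fc a \linkS4class{FoldChangeMatrix}.
#' @return numeric matrix (metabolites x isolates) of depletion fractions
#'   in [0, 1].
#' @export
utilizationProfiles <- function(fc) {
  stopifnot(is(fc, "FoldChangeMatrix"))
  m <- foldChanges(fc)
  p <- m
  p[] <- pmax(0, -m)
  p[is.na(p)] <- 0
  p
}
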