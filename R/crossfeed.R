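## Untargeted-feature analysis: background filtering against extraction
## blanks, production calls, and classification of feature trajectories
## across spent -> double-spent media.

## group label for each sample, used as the ANOVA factor in untargeted
## families: biological samples of the same role/isolate/pair pool their
## replicates.
.sampleGroups <- function(cd) {
  lab <- as.character(cd$role)
  hasIso <- !is.na(cd$isolate_id)
  lab[hasIso] <- paste(lab[hasIso], cd$isolate_id[hasIso], sep = ":")
  ds <- cd$role == "double_spent"
  lab[ds] <- paste("double_spent", cd$influencer_id[ds],
                   cd$recipient_id[ds], sep = ":")
  us <- cd$role == "uninoculated_spent_control"
  lab[us] <- paste("uninoculated_spent_control", cd$influencer_id[us],
                   sep = ":")
  lab
}

#' Filter untargeted features against extraction blanks
#'
#' Keeps the features whose peak height is significantly higher in at
#' least one sample group than in the extraction controls (one-way ANOVA
#' with Dunnett-style many-to-one comparison of every sample group against
#' the blanks; a feature is retained when any group with a positive mean
#' difference reaches adjusted p <= alpha). Everything downstream
#' (production calls, cross-feeding classification) operates on retained
#' features only.
#'
#' @param phe an untargeted \linkS4class{PeakHeightExperiment} containing
#'   \code{extraction_control} samples.
#' @param alpha significance level.
#' @return the \code{PeakHeightExperiment} subset to retained features;
#'   per-mode retention counts are stored in
#'   \code{metadata(.)$backgroundFilter}.
#' @export
filterBackground <- function(phe, alpha = 0.05) {
  stopifnot(is(phe, "PeakHeightExperiment"))
  cd <- as.data.frame(colData(phe))
  if (!any(cd$role == "extraction_control"))
    stop("no extraction_control samples in metadata")
  grp <- .sampleGroups(cd)
  blank <- "extraction_control"
  grp[cd$role == "extraction_control"] <- blank
  h <- peakHeights(phe)
  keep <- vapply(seq_len(nrow(h)), function(m) {
    v <- h[m, ]
    ok <- !is.na(v)
    g <- factor(grp[ok])
    fam <- .dunnettFamilyStats(v[ok], g, blank)
    if (is.null(fam)) return(FALSE)
    up <- which(fam$diff > 0)
    if (!length(up)) return(FALSE)
    if (fam$degenerate) return(any(fam$p[up] == 0))
    tmax <- max(fam$tstat[up])
    .dunnettAdjP(tmax, fam$lam, fam$df) <= alpha
  }, logical(1))
  out <- phe[keep, ]
  mode <- unique(as.character(cd$ionization_mode))
  metadata(out)$backgroundFilter <- data.frame(
    mode = paste(mode[!is.na(mode)], collapse = "+"),
    n_features = nrow(phe), n_retained = sum(keep),
    alpha = alpha, stringsAsFactors = FALSE)
  out
}

## per-feature Dunnett comparisons of spent_i groups vs their matched
## medium control, within each control group. Returns p, direction and
## fold change matrices (features x isolates).
.spentVsControl <- function(phe, alpha) {
  cd <- as.data.frame(colData(phe))
  h <- peakHeights(phe)
  spent <- cd$role == "spent"
  if (!any(spent)) stop("no spent samples in table")
  isolates <- sort(unique(as.character(cd$isolate_id[spent])))
  p <- fc <- matrix(NA_real_, nrow(h), length(isolates),
                    dimnames = list(rownames(h), isolates))
  ctrl_roles <- c("medium_control_early", "medium_control_late",
                  "sdm_culture_control")
  iso_group <- tapply(as.character(cd$control_group[spent]),
                      as.character(cd$isolate_id[spent]), unique)
  for (g in unique(unlist(iso_group))) {
    iso_g <- names(iso_group)[unlist(iso_group) == g]
    ctrl_cols <- which(cd$role %in% ctrl_roles & cd$control_group == g)
    if (length(ctrl_cols) < 2)
      stop("control_group '", g, "' has fewer than 2 control samples")
    spent_cols <- lapply(iso_g, function(i)
      which(spent & cd$isolate_id == i))
    cols <- c(ctrl_cols, unlist(spent_cols))
    grp <- factor(rep(c(".control", iso_g),
                      c(length(ctrl_cols), lengths(spent_cols))),
                  levels = c(".control", iso_g))
    for (m in seq_len(nrow(h))) {
      v <- h[m, cols]
      ok <- !is.na(v)
      res <- .dunnettTest(v[ok], grp[ok], ".control")
      mu <- tapply(v[ok], grp[ok], mean)
      for (i in iso_g) {
        p[m, i] <- res$p[[i]]
        fc[m, i] <- if (mu[[".control"]] > 0)
          mu[[i]] / mu[[".control"]] - 1
        else if (mu[[i]] > 0) Inf else 0
      }
    }
  }
  list(p = p, fc = fc)
}

#' Call metabolite production by each isolate
#'
#' A retained feature is "produced" by an isolate when its abundance is
#' significantly higher in the isolate's spent medium than in the matched
#' uninoculated-medium control (Dunnett-adjusted p <= alpha and positive
#' fold change). Reports per-isolate produced percentages relative to the
#' retained feature count.
#'
#' @param phe a background-filtered untargeted
#'   \linkS4class{PeakHeightExperiment}.
#' @param alpha significance level.
#' @return list with \code{produced} (logical features x isolates matrix),
#'   \code{summary} (per-isolate counts and percentages) and
#'   \code{meanPercent} / \code{sdPercent} across isolates.
#' @export
callProduction <- function(phe, alpha = 0.05) {
  sv <- .spentVsControl(phe, alpha)
  produced <- !is.na(sv$p) & sv$p <= alpha & sv$fc > 0
  nRet <- nrow(produced)
  mode <- unique(as.character(colData(phe)$ionization_mode))
  mode <- paste(mode[!is.na(mode)], collapse = "+")
  summary <- data.frame(
    isolate = colnames(produced), mode = mode,
    n_produced = colSums(produced), n_retained = nRet,
    percent = 100 * colSums(produced) / nRet,
    row.names = NULL, stringsAsFactors = FALSE)
  list(produced = produced, summary = summary,
       meanPercent = mean(summary$percent),
       sdPercent = sd(summary$percent))
}

## direction calls at alpha: "up", "down" or "unchanged"
.direction <- function(p, fc, alpha) {
  d <- rep("unchanged", length(p))
  sig <- !is.na(p) & p <= alpha & !is.na(fc)
  d[sig & fc > 0] <- "up"
  d[sig & fc < 0] <- "down"
  d
}

#' Classify feature trajectories across spent and double-spent media
#'
#' For every (influencer i, recipient r) pair with double-spent samples,
#' every retained feature is classified from two comparisons: leg 1,
#' spent_i vs. the uninoculated defined-medium control; leg 2,
#' double_spent_ri vs. the spent_i reference (the uninoculated, incubated
#' spent-medium control for i when present, otherwise the spent_i samples
#' themselves). Classes, mutually exclusive and exhaustive:
#' \itemize{
#'   \item \code{cross_fed}: up on leg 1 and down on leg 2 -- the
#'     influencer secreted it, the recipient consumed it;
#'   \item \code{sequentially_depleted}: down on both legs -- both
#'     isolates drew the same medium component down, evidence of resource
#'     competition;
#'   \item \code{recipient_produced}: up on leg 2 (and not cross-fed);
#'   \item \code{produced_not_consumed}: up on leg 1, unchanged on leg 2;
#'   \item \code{unchanged}: everything else.
#' }
#' Leg-2 significance uses a per-influencer Dunnett family (all recipients
#' grown on i's spent medium against the shared reference). Tests are
#' two-sided with direction read from the sign of the mean difference.
#'
#' @param phe a background-filtered untargeted
#'   \linkS4class{PeakHeightExperiment} containing \code{spent},
#'   \code{double_spent}, medium-control and (optionally)
#'   \code{uninoculated_spent_control} samples.
#' @param alpha significance level.
#' @return list with \code{calls} (long data.frame: influencer, recipient,
#'   feature, mode, class, p1, p2, fc1, fc2), \code{summary} (per (r, i):
#'   percentage of retained features per class) and \code{perRecipient}
#'   (mean and sd of the cross-fed percentage across influencers).
#' @export
classifyCrossFeeding <- function(phe, alpha = 0.05) {
  stopifnot(is(phe, "PeakHeightExperiment"))
  cd <- as.data.frame(colData(phe))
  h <- peakHeights(phe)
  ds <- cd$role == "double_spent"
  if (!any(ds)) stop("no double_spent samples in metadata")
  pairs <- unique(data.frame(influencer = as.character(cd$influencer_id[ds]),
                             recipient = as.character(cd$recipient_id[ds]),
                             stringsAsFactors = FALSE))
  mode <- unique(as.character(cd$ionization_mode))
  mode <- paste(mode[!is.na(mode)], collapse = "+")

  leg1 <- .spentVsControl(phe, alpha)    # features x influencer isolates

  calls <- vector("list", nrow(pairs) * nrow(h))
  idx <- 0L
  for (i in unique(pairs$influencer)) {
    recips <- pairs$recipient[pairs$influencer == i]
    ## leg-2 reference: abiotic incubated spent control, else spent itself
    ref_cols <- which(cd$role == "uninoculated_spent_control" &
                      cd$influencer_id == i)
    if (length(ref_cols) < 2)
      ref_cols <- which(cd$role == "spent" & cd$isolate_id == i)
    if (length(ref_cols) < 2)
      stop("missing spent-medium reference for influencer '", i, "'")
    dcols <- lapply(recips, function(r)
      which(ds & cd$influencer_id == i & cd$recipient_id == r))
    if (any(lengths(dcols) < 2))
      stop("missing double-spent replicates for influencer '", i, "'")
    cols <- c(ref_cols, unlist(dcols))
    grp <- factor(rep(c(".ref", recips), c(length(ref_cols),
                                           lengths(dcols))),
                  levels = c(".ref", recips))
    for (m in seq_len(nrow(h))) {
      v <- h[m, cols]
      ok <- !is.na(v)
      res <- .dunnettTest(v[ok], grp[ok], ".ref")
      mu <- tapply(v[ok], grp[ok], mean)
      d1 <- .direction(leg1$p[m, i], leg1$fc[m, i], alpha)
      for (r in recips) {
        p2 <- res$p[[r]]
        fc2 <- if (mu[[".ref"]] > 0) mu[[r]] / mu[[".ref"]] - 1
               else if (mu[[r]] > 0) Inf else 0
        d2 <- .direction(p2, fc2, alpha)
        cls <- if (d1 == "up" && d2 == "down") "cross_fed"
          else if (d1 == "down" && d2 == "down") "sequentially_depleted"
          else if (d2 == "up") "recipient_produced"
          else if (d1 == "up") "produced_not_consumed"
          else "unchanged"
        idx <- idx + 1L
        calls[[idx]] <- data.frame(
          influencer = i, recipient = r, feature = rownames(h)[m],
          mode = mode, class = cls, p1 = leg1$p[m, i], p2 = p2,
          fc1 = leg1$fc[m, i], fc2 = fc2, stringsAsFactors = FALSE)
      }
    }
  }
  calls <- do.call(rbind, calls[seq_len(idx)])
  ## per-(recipient, influencer) class percentages over retained features
  tab <- as.data.frame(table(recipient = calls$recipient,
                             influencer = calls$influencer,
                             class = factor(calls$class,
                                            levels = .CROSSFEED_CLASSES)),
                       stringsAsFactors = FALSE)
  tested <- unique(calls[, c("recipient", "influencer")])
  tab <- merge(tested, tab, by = c("recipient", "influencer"))
  nFeat <- nrow(h)
  tab$percent <- 100 * tab$Freq / nFeat
  names(tab)[names(tab) == "Freq"] <- "n"
  tab$mode <- mode
  cf <- tab[tab$class == "cross_fed", ]
  perRecipient <- do.call(rbind, lapply(split(cf, cf$recipient),
    function(d) data.frame(recipient = d$recipient[1], mode = mode,
                           n_influencers = nrow(d),
                           mean_percent = mean(d$percent),
                           sd_percent = sd(d$percent),
                           stringsAsFactors = FALSE)))
  rownames(perRecipient) <- NULL
  list(calls = calls, summary = tab, perRecipient = perRecipient)
}
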