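#' PeakHeightExperiment: LC-MS peak heights with sample roles
#'
#' A \linkS4class{SummarizedExperiment} holding one peak-height matrix
#' (analytes x samples) together with the sample annotation the downstream
#' statistics need: which isolate a sample belongs to, its experimental role
#' (spent medium, double-spent medium, uninoculated medium control,
#' extraction blank, ...), the influencer/recipient pair for sequential
#' samples, the replicate index, the ionization mode, and the
#' \code{control_group} label linking biological samples to their matched
#' control samples.
#'
#' Missing peak heights are encoded as \code{NA}, never as zero; zero is a
#' real measurement (analyte absent). Heights must be non-negative.
#'
#' @slot tableKind \code{"targeted"} (defined-medium metabolites) or
#'   \code{"untargeted"} (LC-MS features as m/z\@retention-time ids).
#'
#' @param heights numeric matrix, analytes in rows, samples in columns;
#'   column names must match \code{sampleData$sample_id}.
#' @param sampleData data.frame (or DataFrame) of sample metadata with
#'   columns \code{sample_id}, \code{isolate_id}, \code{role},
#'   \code{influencer_id}, \code{recipient_id}, \code{replicate},
#'   \code{ionization_mode}, \code{control_group}. Missing optional columns
#'   are filled with \code{NA}.
#' @param tableKind \code{"targeted"} or \code{"untargeted"}.
#' @param object a \code{PeakHeightExperiment}.
#'
#' @return \code{PeakHeightExperiment()} returns a validated object.
#'   \code{peakHeights()} returns the height matrix, \code{analyteIds()} the
#'   row labels, \code{sampleRoles()} the role of each sample, and
#'   \code{tableKind()} the table kind.
#'
#' @examples
#' h <- matrix(c(100, 200, 50, 210, 110, 190), nrow = 2,
#'             dimnames = list(c("alanine", "glucose"),
#'                             c("s1", "s2", "s3")))
#' md <- data.frame(sample_id = c("s1", "s2", "s3"),
#'                  isolate_id = c("iso1", NA, NA),
#'                  role = c("spent", "medium_control_early",
#'                           "medium_control_early"),
#'                  replicate = c(1, 1, 2),
#'                  control_group = "early")
#' phe <- PeakHeightExperiment(h, md, tableKind = "targeted")
#' tableKind(phe)
#' @export PeakHeightExperiment
#' @exportClass PeakHeightExperiment
#' @aliases PeakHeightExperiment-class peakHeights
#' @name PeakHeightExperiment-class
setClass("PeakHeightExperiment",
         contains = "SummarizedExperiment",
         slots = c(tableKind = "character"))

.PHE_META_COLS <- c("sample_id", "isolate_id", "role", "influencer_id",
                    "recipient_id", "replicate", "ionization_mode",
                    "control_group")

setValidity("PeakHeightExperiment", function(object) {
  msg <- character(0)
  if (!length(object@tableKind) == 1L ||
      !object@tableKind %in% c("targeted", "untargeted"))
    msg <- c(msg, "tableKind must be 'targeted' or 'untargeted'")
  if (!"peaks" %in% names(assays(object)))
    return(c(msg, "assay 'peaks' is required"))
  h <- assay(object, "peaks")
  if (!is.numeric(h))
    msg <- c(msg, "peak heights must be numeric")
  if (any(h < 0, na.rm = TRUE))
    msg <- c(msg, "negative peak heights are not allowed")
  if (anyDuplicated(rownames(h)))
    msg <- c(msg, "duplicate analyte ids")
  cd <- colData(object)
  missing_cols <- setdiff(.PHE_META_COLS, colnames(cd))
  if (length(missing_cols))
    return(c(msg, paste("missing sample metadata columns:",
                        paste(missing_cols, collapse = ", "))))
  if (anyDuplicated(cd$sample_id))
    msg <- c(msg, "duplicate sample ids")
  if (!identical(colnames(object), as.character(cd$sample_id)))
    msg <- c(msg, "column names must equal sample_id, in order")
  bad_role <- setdiff(unique(as.character(cd$role)), .PHE_ROLES)
  if (length(bad_role))
    msg <- c(msg, paste("unknown role value(s):",
                        paste(bad_role, collapse = ", ")))
  rep_ok <- is.na(cd$replicate) |
    (cd$replicate == round(cd$replicate) & cd$replicate >= 1)
  if (!all(rep_ok))
    msg <- c(msg, "replicate must be a positive integer")
  ds <- cd$role == "double_spent"
  if (any(ds) &&
      (any(is.na(cd$influencer_id[ds])) || any(is.na(cd$recipient_id[ds]))))
    msg <- c(msg, "double_spent samples need influencer_id and recipient_id")
  ## every spent sample's control_group must resolve to >=2 medium controls
  sp <- cd$role == "spent"
  if (any(sp)) {
    ctrl <- cd$role %in% c("medium_control_early", "medium_control_late",
                           "sdm_culture_control")
    for (g in unique(as.character(cd$control_group[sp]))) {
      if (is.na(g)) {
        msg <- c(msg, "spent samples must carry a control_group")
        break
      }
      n_ctrl <- sum(ctrl & cd$control_group == g, na.rm = TRUE)
      if (n_ctrl < 2) {
        msg <- c(msg, sprintf(
          "control_group '%s' resolves to %d control sample(s); >=2 required",
          g, n_ctrl))
      }
    }
  }
  if (length(msg)) msg else TRUE
})

PeakHeightExperiment <- function(heights, sampleData,
                                 tableKind = c("targeted", "untargeted")) {
  tableKind <- match.arg(tableKind)
  heights <- as.matrix(heights)
  sampleData <- as.data.frame(sampleData)
  for (col in .PHE_META_COLS)
    if (!col %in% colnames(sampleData)) sampleData[[col]] <- NA
  sampleData$sample_id <- as.character(sampleData$sample_id)
  if (is.null(colnames(heights)))
    colnames(heights) <- sampleData$sample_id
  ## align metadata rows to matrix columns
  idx <- match(colnames(heights), sampleData$sample_id)
  if (anyNA(idx)) {
    stop("sample(s) in table absent from metadata: ",
         paste(colnames(heights)[is.na(idx)], collapse = ", "))
  }
  sampleData <- sampleData[idx, , drop = FALSE]
  cd <- DataFrame(sampleData, row.names = sampleData$sample_id)
  se <- SummarizedExperiment(assays = list(peaks = heights), colData = cd)
  new("PeakHeightExperiment", se, tableKind = tableKind)
}

#' @rdname PeakHeightExperiment-class
#' @export
peakHeights <- function(object) assay(object, "peaks")

#' @rdname PeakHeightExperiment-class
#' @export
setMethod("tableKind", "PeakHeightExperiment",
          function(object) object@tableKind)

#' @rdname PeakHeightExperiment-class
#' @export
setMethod("analyteIds", "PeakHeightExperiment",
          function(object) rownames(object))

#' @rdname PeakHeightExperiment-class
#' @export
setMethod("sampleRoles", "PeakHeightExperiment",
          function(object) setNames(as.character(colData(object)$role),
                                    colnames(object)))

setMethod("show", "PeakHeightExperiment", function(object) {
  cat(sprintf("PeakHeightExperiment (%s): %d analytes x %d samples\n",
              object@tableKind, nrow(object), ncol(object)))
  tab <- table(colData(object)$role)
  cat("samples per role:\n")
  for (r in names(tab)) cat(sprintf("  %-28s %d\n", r, tab[[r]]))
  invisible(NULL)
})


#' FoldChangeMatrix: significance-gated relative fold changes
#'
#' Relative fold changes \code{FC = mean(spent)/mean(control) - 1} for each
#' (metabolite, isolate) cell, gated by a many-to-one Dunnett-style test:
#' cells whose peak heights do not differ significantly from the matched
#' uninoculated-medium control (adjusted p > alpha) are set to exactly 0.
#' Negative values are depletion (bounded below by -1 because heights are
#' non-negative); positive values are production.
#'
#' Cells where the test or ratio is undefined (control mean of zero with
#' non-zero spent signal, or missing data under the chosen policy) carry
#' \code{NA} in both matrices and are flagged in \code{flagged()}.
#'
#' @slot fc numeric matrix, metabolites x isolates.
#' @slot pvalues Dunnett-adjusted p-values, same shape.
#' @slot alpha significance level used for gating.
#' @slot nReplicates integer matrix of spent-replicate counts per cell.
#' @slot flagged logical matrix marking undefined cells.
#'
#' @param object a \code{FoldChangeMatrix}.
#' @aliases FoldChangeMatrix-class flagged
#' @name FoldChangeMatrix-class
#' @exportClass FoldChangeMatrix
setClass("FoldChangeMatrix",
         slots = c(fc = "matrix", pvalues = "matrix", alpha = "numeric",
                   nReplicates = "matrix", flagged = "matrix"))

setValidity("FoldChangeMatrix", function(object) {
  msg <- character(0)
  d <- dim(object@fc)
  if (!identical(d, dim(object@pvalues)) ||
      !identical(d, dim(object@flagged)))
    msg <- c(msg, "fc, pvalues and flagged must share dimensions")
  if (length(object@alpha) != 1L || object@alpha <= 0 || object@alpha >= 1)
    msg <- c(msg, "alpha must be a single value in (0, 1)")
  p <- object@pvalues
  if (any(p < 0 | p > 1, na.rm = TRUE))
    msg <- c(msg, "p-values must lie in [0, 1]")
  if (any(object@fc < -1, na.rm = TRUE))
    msg <- c(msg, "fold changes below -1 are impossible for non-negative heights")
  gate <- !is.na(p) & !is.na(object@fc) & p > object@alpha & object@fc != 0
  if (any(gate))
    msg <- c(msg, "non-significant cells must have fold change exactly 0")
  if (length(msg)) msg else TRUE
})

#' @rdname FoldChangeMatrix-class
#' @export
setMethod("foldChanges", "FoldChangeMatrix", function(object) object@fc)

#' @rdname FoldChangeMatrix-class
#' @export
setMethod("pValues", "FoldChangeMatrix", function(object) object@pvalues)

#' @rdname FoldChangeMatrix-class
#' @export
setMethod("alphaLevel", "FoldChangeMatrix", function(object) object@alpha)

#' @rdname FoldChangeMatrix-class
#' @export
flagged <- function(object) object@flagged

setMethod("show", "FoldChangeMatrix", function(object) {
  fc <- object@fc
  cat(sprintf("FoldChangeMatrix: %d metabolites x %d isolates (alpha = %g)\n",
              nrow(fc), ncol(fc), object@alpha))
  cat(sprintf("  depleted cells: %d, produced: %d, gated to 0: %d, undefined: %d\n",
              sum(fc < 0, na.rm = TRUE), sum(fc > 0, na.rm = TRUE),
              sum(fc == 0, na.rm = TRUE), sum(is.na(fc))))
  invisible(NULL)
})


#' InteractionMatrix: directional isolate-by-isolate interaction strengths
#'
#' Square matrix of directional interaction strengths, rows = recipients,
#' columns = influencers. Entry \code{[r, i]} is the effect of influencer
#' \code{i} on recipient \code{r}. Two types exist:
#' \itemize{
#'   \item \code{"PIS"} (predicted): niche-overlap scores in [-1*, 0]
#'     (unbounded below only through asymmetric preference weighting, but
#'     always <= 0); no p-values.
#'   \item \code{"MIS"} (measured): relative change of recipient growth in
#'     the influencer's spent medium versus fresh defined medium; bounded
#'     below by -1; carries Dunnett-adjusted p-values and a significance
#'     flag at \code{alphaLevel()}.
#' }
#' The diagonal is undefined (\code{NA}). Recipients for which the quantity
#' is undefined (empty utilization support for PIS, no reference growth for
#' MIS) have all-\code{NA} rows and are listed in
#' \code{undefinedRecipients()}.
#'
#' @slot strength numeric square matrix (recipients x influencers).
#' @slot pvalues numeric matrix of the same shape (all NA for PIS).
#' @slot type \code{"PIS"} or \code{"MIS"}.
#' @slot metric growth metric for MIS (\code{"final_od"},
#'   \code{"respiration"}) or \code{"niche_overlap"} for PIS.
#' @slot alpha significance level for \code{isSignificant()}.
#' @slot undefinedRecipients character vector of all-NA rows.
#'
#' @param object an \code{InteractionMatrix}.
#' @aliases InteractionMatrix-class undefinedRecipients interactionMetric
#' @name InteractionMatrix-class
#' @exportClass InteractionMatrix
setClass("InteractionMatrix",
         slots = c(strength = "matrix", pvalues = "matrix",
                   type = "character", metric = "character",
                   alpha = "numeric", undefinedRecipients = "character"))

setValidity("InteractionMatrix", function(object) {
  msg <- character(0)
  s <- object@strength
  if (nrow(s) != ncol(s))
    msg <- c(msg, "strength matrix must be square")
  if (is.null(rownames(s)) || !identical(rownames(s), colnames(s)))
    msg <- c(msg, "row and column names must be identical isolate ids")
  if (!identical(dim(s), dim(object@pvalues)))
    msg <- c(msg, "pvalues must match strength dimensions")
  if (!object@type %in% c("PIS", "MIS"))
    msg <- c(msg, "type must be 'PIS' or 'MIS'")
  if (nrow(s) && any(!is.na(diag(s))))
    msg <- c(msg, "diagonal (self-interaction) must be NA")
  if (object@type == "PIS" && any(s > 1e-12, na.rm = TRUE))
    msg <- c(msg, "predicted interaction strengths must be <= 0")
  if (object@type == "MIS" && any(s < -1 - 1e-9, na.rm = TRUE))
    msg <- c(msg, "measured interaction strengths must be >= -1")
  if (length(msg)) msg else TRUE
})

#' @rdname InteractionMatrix-class
#' @export
setMethod("interactionStrengths", "InteractionMatrix",
          function(object) object@strength)

#' @rdname InteractionMatrix-class
#' @export
setMethod("interactionType", "InteractionMatrix",
          function(object) object@type)

#' @rdname InteractionMatrix-class
#' @export
setMethod("pValues", "InteractionMatrix", function(object) object@pvalues)

#' @rdname InteractionMatrix-class
#' @export
setMethod("alphaLevel", "InteractionMatrix", function(object) object@alpha)

#' @rdname InteractionMatrix-class
#' @export
setMethod("isSignificant", "InteractionMatrix", function(object) {
  p <- object@pvalues
  !is.na(p) & p <= object@alpha
})

#' @rdname InteractionMatrix-class
#' @export
undefinedRecipients <- function(object) object@undefinedRecipients

#' @rdname InteractionMatrix-class
#' @export
interactionMetric <- function(object) object@metric

setMethod("show", "InteractionMatrix", function(object) {
  s <- object@strength
  off <- s[row(s) != col(s)]
  cat(sprintf("InteractionMatrix [%s, %s]: %d x %d isolates\n",
              object@type, object@metric, nrow(s), ncol(s)))
  cat(sprintf("  defined pairs: %d (negative: %d, positive: %d)\n",
              sum(!is.na(off)), sum(off < 0, na.rm = TRUE),
              sum(off > 0, na.rm = TRUE)))
  if (object@type == "MIS")
    cat(sprintf("  significant at alpha = %g: %d\n", object@alpha,
                sum(isSignificant(object))))
  if (length(object@undefinedRecipients))
    cat("  undefined recipients:",
        paste(object@undefinedRecipients, collapse = ", "), "\n")
  invisible(NULL)
})


#' SyntheticTruth: ground truth for a simulated isolate community
#'
#' Parameters of a simulated community of bacterial isolates growing in a
#' defined medium of equimolar metabolites: which fraction of each medium
#' metabolite each isolate consumes, what it secretes, which secreted
#' features other isolates can consume, and the growth/respiration
#' coefficients that couple substrate consumption to optical density and
#' CO2 readouts. All downstream recovery tests compare pipeline estimates
#' against these slots.
#'
#' @slot consumption numeric matrix isolates x metabolites, entries in
#'   [0, 1]: fraction of the metabolite's medium concentration the isolate
#'   depletes in monoculture.
#' @slot secretion numeric matrix isolates x secreted features (>= 0):
#'   peak-height amount added above background by the secreting isolate.
#' @slot consumable logical matrix isolates x secreted features: whether an
#'   isolate can consume the feature when grown in spent medium.
#' @slot secretionNutrition numeric per secreted feature: growth value in
#'   medium-metabolite substrate equivalents when fully consumed.
#' @slot yield numeric per isolate: OD600 gained per substrate equivalent.
#' @slot respirationFraction numeric per isolate: A570 drop per substrate
#'   equivalent consumed.
#' @slot growthRate numeric per isolate: logistic maximum growth rate (1/h).
#' @slot archetype character per isolate: "generalist" or "specialist".
#' @slot seed integer seed the truth was generated from.
#'
#' @param object a \code{SyntheticTruth}.
#' @aliases SyntheticTruth-class
#' @name SyntheticTruth-class
#' @exportClass SyntheticTruth
setClass("SyntheticTruth",
         slots = c(consumption = "matrix", secretion = "matrix",
                   consumable = "matrix", secretionNutrition = "numeric",
                   yield = "numeric", respirationFraction = "numeric",
                   growthRate = "numeric", archetype = "character",
                   seed = "integer"))

setValidity("SyntheticTruth", function(object) {
  msg <- character(0)
  C <- object@consumption
  if (any(C < 0 | C > 1))
    msg <- c(msg, "consumption fractions must lie in [0, 1]")
  if (any(object@secretion < 0))
    msg <- c(msg, "secretion amounts must be >= 0")
  if (!identical(dim(object@secretion), dim(object@consumable)))
    msg <- c(msg, "secretion and consumable must share dimensions")
  if (ncol(object@secretion) != length(object@secretionNutrition))
    msg <- c(msg, "secretionNutrition must have one entry per feature")
  nI <- nrow(C)
  if (length(object@yield) != nI || length(object@growthRate) != nI ||
      length(object@respirationFraction) != nI ||
      length(object@archetype) != nI)
    msg <- c(msg, "per-isolate slots must have one entry per isolate")
  if (any(object@yield <= 0) || any(object@growthRate <= 0))
    msg <- c(msg, "yield and growthRate must be positive")
  if (length(msg)) msg else TRUE
})

#' @rdname SyntheticTruth-class
#' @export
setMethod("consumptionMatrix", "SyntheticTruth",
          function(object) object@consumption)

#' @rdname SyntheticTruth-class
#' @export
setMethod("secretionMatrix", "SyntheticTruth",
          function(object) object@secretion)

setMethod("show", "SyntheticTruth", function(object) {
  cat(sprintf("SyntheticTruth: %d isolates x %d metabolites, %d secreted features (seed %d)\n",
              nrow(object@consumption), ncol(object@consumption),
              ncol(object@secretion), object@seed))
  cat(sprintf("  archetypes: %s\n",
              paste(sprintf("%s=%d", names(table(object@archetype)),
                            table(object@archetype)), collapse = ", ")))
  invisible(NULL)
})
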