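#' Read a peak-height table with its sample metadata
#'
#' Reads an analyte x sample CSV (first column = analyte id, remaining
#' columns = samples) together with a sample-metadata CSV and returns a
#' validated \linkS4class{PeakHeightExperiment}. Empty cells become
#' \code{NA} (missing measurement); zeros are kept as true zeros.
#'
#' @param path CSV of peak heights; header row required, UTF-8, "." decimal.
#' @param metadataPath CSV with columns \code{sample_id}, \code{isolate_id},
#'   \code{role}, \code{influencer_id}, \code{recipient_id},
#'   \code{replicate}, \code{ionization_mode}, \code{control_group}.
#' @param tableKind \code{"targeted"} or \code{"untargeted"}.
#' @param verbose print analyte/sample counts per role.
#' @return a \code{PeakHeightExperiment}.
#' @export
readPeakTable <- function(path, metadataPath,
                          tableKind = c("targeted", "untargeted"),
                          verbose = FALSE) {
  tableKind <- match.arg(tableKind)
  raw <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(raw) < 2) stop("peak table needs an analyte column plus samples")
  ids <- as.character(raw[[1]])
  if (anyDuplicated(ids))
    stop("duplicate analyte id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  h <- as.matrix(raw[, -1, drop = FALSE])
  storage.mode(h) <- "double"
  rownames(h) <- ids
  meta <- read.csv(metadataPath, stringsAsFactors = FALSE)
  phe <- PeakHeightExperiment(h, meta, tableKind = tableKind)
  if (verbose) {
    message(sprintf("%d analytes, %d samples", nrow(phe), ncol(phe)))
    tab <- table(colData(phe)$role)
    for (r in names(tab)) message(sprintf("  %-28s %d", r, tab[[r]]))
  }
  phe
}

#' Write a peak-height table (and optionally its metadata) to CSV
#'
#' Inverse of \code{\link{readPeakTable}}: writing then re-reading
#' reproduces the object, including label order. \code{NA} heights are
#' written as empty cells.
#'
#' @param phe a \code{PeakHeightExperiment}.
#' @param path output CSV for the height matrix.
#' @param metadataPath optional output CSV for the sample metadata.
#' @return \code{path}, invisibly.
#' @export
writePeakTable <- function(phe, path, metadataPath = NULL) {
  h <- peakHeights(phe)
  df <- data.frame(analyte_id = rownames(h), h, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.csv(df, path, row.names = FALSE, na = "", quote = TRUE)
  if (!is.null(metadataPath)) {
    md <- as.data.frame(colData(phe))[, .PHE_META_COLS]
    write.csv(md, metadataPath, row.names = FALSE, na = "", quote = TRUE)
  }
  invisible(path)
}

#' Read growth (and optional respiration) tables
#'
#' Growth CSV is long format with columns \code{isolate}, \code{medium},
#' \code{replicate}, \code{time_h}, \code{od600}; uninoculated-medium
#' control wells use isolate id \code{"none"}. Series are returned sorted
#' by time; duplicate time points within a series or negative OD are
#' errors. The optional respiration CSV has columns \code{isolate},
#' \code{medium}, \code{replicate}, \code{a570_initial}, \code{a570_final}.
#'
#' @param path growth CSV.
#' @param respirationPath optional respiration CSV.
#' @return a list of class \code{GrowthTable} with elements \code{od}
#'   (data.frame) and \code{respiration} (data.frame or NULL).
#' @export
readGrowthTable <- function(path, respirationPath = NULL) {
  od <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("isolate", "medium", "replicate", "time_h", "od600")
  miss <- setdiff(need, colnames(od))
  if (length(miss))
    stop("growth table missing column(s): ", paste(miss, collapse = ", "))
  if (any(od$od600 < 0, na.rm = TRUE))
    stop("negative od600 value(s) in growth table")
  key <- interaction(od$isolate, od$medium, od$replicate, drop = TRUE)
  for (k in levels(key)) {
    tt <- od$time_h[key == k]
    if (anyDuplicated(tt))
      stop("duplicate time points within series ", k)
  }
  od <- od[order(od$isolate, od$medium, od$replicate, od$time_h), ,
           drop = FALSE]
  rownames(od) <- NULL
  resp <- NULL
  if (!is.null(respirationPath)) {
    resp <- read.csv(respirationPath, stringsAsFactors = FALSE)
    needr <- c("isolate", "medium", "replicate", "a570_initial",
               "a570_final")
    missr <- setdiff(needr, colnames(resp))
    if (length(missr))
      stop("respiration table missing column(s): ",
           paste(missr, collapse = ", "))
    if (any(resp$a570_initial < 0 | resp$a570_final < 0, na.rm = TRUE))
      stop("negative A570 reading(s)")
  }
  structure(list(od = od, respiration = resp), class = "GrowthTable")
}

#' @export
print.GrowthTable <- function(x, ...) {
  key <- interaction(x$od$isolate, x$od$medium, x$od$replicate, drop = TRUE)
  cat(sprintf("GrowthTable: %d OD series (%d readings)",
              nlevels(key), nrow(x$od)))
  if (!is.null(x$respiration))
    cat(sprintf(", %d respiration wells", nrow(x$respiration)))
  cat("\n")
  invisible(x)
}

#' Write a growth table to CSV
#'
#' @param growth a \code{GrowthTable} (from \code{\link{readGrowthTable}}
#'   or \code{\link{simulateSequential}}).
#' @param path output CSV for the OD series.
#' @param respirationPath optional output CSV for respiration readings.
#' @return \code{path}, invisibly.
#' @export
writeGrowthTable <- function(growth, path, respirationPath = NULL) {
  write.csv(growth$od, path, row.names = FALSE, na = "", quote = TRUE)
  if (!is.null(respirationPath) && !is.null(growth$respiration))
    write.csv(growth$respiration, respirationPath, row.names = FALSE,
              na = "", quote = TRUE)
  invisible(path)
}

#' Write a labelled result matrix to CSV
#'
#' Writes any isolate x isolate or analyte x isolate result matrix with row
#' and column labels. Missing entries become empty cells. Output is
#' byte-identical across repeated writes of the same object.
#'
#' @param m a matrix with dimnames (or an \code{InteractionMatrix} /
#'   \code{FoldChangeMatrix}, whose strength / fold-change matrix is used).
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeMatrix <- function(m, path) {
  if (is(m, "InteractionMatrix")) m <- interactionStrengths(m)
  if (is(m, "FoldChangeMatrix")) m <- foldChanges(m)
  stopifnot(is.matrix(m))
  if (any(is.infinite(m)))
    stop("matrix contains non-finite entries that are not flagged missing")
  df <- data.frame(id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.csv(df, path, row.names = FALSE, na = "", quote = TRUE)
  invisible(path)
}

#' Read a labelled matrix written by \code{writeMatrix}
#' @param path CSV path.
#' @return a numeric matrix with dimnames.
#' @export
readMatrix <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df[[1]]
  m
}
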