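#' Fit a logistic growth model to an OD time series
#'
#' Least-squares fit of
#' \deqn{N(t) = K / (1 + ((K - N_0)/N_0) e^{-rt})}
#' returning the maximum growth rate r (1/h), carrying capacity K (OD),
#' initial size N0 (OD) and doubling time t_dd = ln(2)/r (h).
#' Initialisation: N0 from the first observation, K from the maximum, r
#' from a log-linear regression on the early (sub-half-K) phase; the fit
#' itself is bounded Levenberg-Marquardt. Flat or monotone-decreasing
#' series are flagged as no-growth rather than fitted; non-convergence is
#' reported, never silently defaulted.
#'
#' @param time time points in hours, strictly increasing; >= 8 points.
#' @param od non-negative OD600 readings.
#' @param minGrowth minimum rise above the initial reading (OD units) to
#'   attempt a fit; below it the series is flagged no-growth.
#' @return list with \code{r}, \code{K}, \code{N0}, \code{t_dd},
#'   \code{rss}, \code{converged}, \code{noGrowth}.
#' @examples
#' t <- seq(0, 48, by = 1/3)
#' od <- 1.2 / (1 + ((1.2 - 0.02) / 0.02) * exp(-0.6 * t))
#' fitLogistic(t, od)[c("r", "K", "t_dd")]
#' @export
fitLogistic <- function(time, od, minGrowth = 0.02) {
  stopifnot(length(time) == length(od))
  if (length(time) < 8) stop("need >= 8 time points spanning growth")
  if (is.unsorted(time, strictly = TRUE)) stop("time must be strictly increasing")
  if (any(od < 0)) stop("negative OD600 values")
  none <- list(r = NA_real_, K = NA_real_, N0 = NA_real_, t_dd = NA_real_,
               rss = NA_real_, converged = FALSE, noGrowth = TRUE)
  rise <- max(od) - od[1]
  if (rise < minGrowth || which.max(od) == 1L) return(none)
  N0s <- max(od[1], 1e-4)
  Ks <- max(od)
  ## early exponential phase: positive readings below half the plateau
  early <- od > 0 & od < (N0s + (Ks - N0s) / 2)
  rs <- if (sum(early) >= 3) {
    sl <- unname(coef(lm(log(od[early]) ~ time[early]))[2])
    if (is.finite(sl) && sl > 0) sl else 0.2
  } else 0.2
  fit <- tryCatch(
    nlsLM(od ~ K / (1 + ((K - N0) / N0) * exp(-r * time)),
          start = list(K = Ks, r = rs, N0 = N0s),
          lower = c(K = 1e-6, r = 1e-6, N0 = 1e-9),
          control = nls.control(maxiter = 200, warnOnly = TRUE)),
    error = function(e) NULL)
  if (is.null(fit)) return(modifyList(none, list(noGrowth = FALSE)))
  cf <- coef(fit)
  conv <- isTRUE(fit$convInfo$isConv)
  list(r = unname(cf["r"]), K = unname(cf["K"]), N0 = unname(cf["N0"]),
       t_dd = log(2) / unname(cf["r"]),
       rss = sum(residuals(fit)^2), converged = conv, noGrowth = FALSE)
}

#' Fit logistic parameters for every series in a growth table
#'
#' @param growth a \code{GrowthTable} (see \code{\link{readGrowthTable}})
#'   or its \code{od} data.frame. Uninoculated control series
#'   (isolate \code{"none"}) are skipped.
#' @param minGrowth passed to \code{\link{fitLogistic}}.
#' @return data.frame with one row per (isolate, medium, replicate):
#'   \code{r}, \code{K}, \code{N0}, \code{t_dd}, \code{rss},
#'   \code{converged}, \code{no_growth}.
#' @export
fitGrowthCurves <- function(growth, minGrowth = 0.02) {
  od <- if (inherits(growth, "GrowthTable")) growth$od else growth
  od <- od[od$isolate != "none", , drop = FALSE]
  key <- unique(od[, c("isolate", "medium", "replicate")])
  rows <- lapply(seq_len(nrow(key)), function(j) {
    sel <- od$isolate == key$isolate[j] & od$medium == key$medium[j] &
      od$replicate == key$replicate[j]
    f <- fitLogistic(od$time_h[sel], od$od600[sel], minGrowth = minGrowth)
    data.frame(key[j, ], r = f$r, K = f$K, N0 = f$N0, t_dd = f$t_dd,
               rss = f$rss, converged = f$converged, no_growth = f$noGrowth,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Baseline-corrected cumulative respiration
#'
#' MicroResp cumulative CO2 respiration is the drop in indicator-gel
#' absorbance at 570 nm, baseline-corrected with uninoculated medium
#' controls:
#' \code{(A_initial - A_final)_sample - mean((A_initial - A_final)_controls)}.
#'
#' @param a570Initial,a570Final sample readings (vectors of equal length).
#' @param controlInitial,controlFinal matched uninoculated-control
#'   readings; at least one pair.
#' @return corrected delta-A570 per sample (can be negative; clamp for
#'   growth ratios downstream).
#' @examples
#' cumulativeRespiration(1.00, 0.60, c(1.00, 1.00), c(0.95, 0.93))
#' @export
cumulativeRespiration <- function(a570Initial, a570Final,
                                  controlInitial, controlFinal) {
  stopifnot(length(a570Initial) == length(a570Final),
            length(controlInitial) == length(controlFinal),
            length(controlInitial) >= 1)
  if (anyNA(c(a570Initial, a570Final, controlInitial, controlFinal)))
    stop("missing paired A570 reading")
  (a570Initial - a570Final) - mean(controlInitial - controlFinal)
}

#' Measured interaction strength from a growth pair
#'
#' Relative change of recipient growth in the influencer's spent medium
#' versus fresh defined medium:
#' \deqn{MIS_{ri} = Growth_{r,i} / Growth_{r,SDM} - 1.}
#' Growth values are non-negative after blank correction, so MIS >= -1,
#' with -1 exactly when the recipient did not grow at all in the spent
#' medium.
#'
#' @param growthSpent recipient growth in spent medium (>= 0).
#' @param growthSdm recipient growth in fresh defined medium (> 0).
#' @return the interaction strength (scalar or vector).
#' @examples
#' measuredInteraction(0, 0.2)     # no growth at all: -1
#' measuredInteraction(0.3, 0.2)   # facilitation: +0.5
#' @export
measuredInteraction <- function(growthSpent, growthSdm) {
  if (any(growthSdm <= 0))
    stop("growth in the defined-medium reference must be positive")
  if (any(growthSpent < 0))
    stop("spent-medium growth must be clamped at 0 before use")
  growthSpent / growthSdm - 1
}

#' Blank-corrected final growth per culture well
#'
#' The growth metric "final OD" for each (recipient, medium, replicate)
#' series: the last OD reading minus the mean last reading of the matched
#' uninoculated control series for the same medium (isolate \code{"none"}),
#' clamped at 0.
#'
#' @param growth a \code{GrowthTable} or its \code{od} data.frame.
#' @param blankCorrect subtract the uninoculated-control baseline
#'   (default TRUE; without control series the raw final OD is used).
#' @return data.frame (\code{isolate}, \code{medium}, \code{replicate},
#'   \code{value}).
#' @export
finalGrowth <- function(growth, blankCorrect = TRUE) {
  od <- if (inherits(growth, "GrowthTable")) growth$od else growth
  lastOf <- function(d) d$od600[which.max(d$time_h)]
  key <- unique(od[, c("isolate", "medium", "replicate")])
  finals <- vapply(seq_len(nrow(key)), function(j) {
    sel <- od$isolate == key$isolate[j] & od$medium == key$medium[j] &
      od$replicate == key$replicate[j]
    lastOf(od[sel, ])
  }, numeric(1))
  res <- data.frame(key, value = finals, stringsAsFactors = FALSE)
  blanks <- res[res$isolate == "none", , drop = FALSE]
  res <- res[res$isolate != "none", , drop = FALSE]
  if (blankCorrect && nrow(blanks)) {
    bl <- tapply(blanks$value, blanks$medium, mean)
    corr <- bl[res$medium]
    corr[is.na(corr)] <- 0
    res$value <- pmax(0, res$value - corr)
  }
  rownames(res) <- NULL
  res
}

#' Blank-corrected cumulative respiration per culture well
#'
#' Applies \code{\link{cumulativeRespiration}} to a respiration table,
#' using the uninoculated control wells (isolate \code{"none"}) of the
#' same medium as the baseline; negative corrected values are clamped at 0
#' so that growth ratios stay within the MIS bound.
#'
#' @param respiration data.frame (\code{isolate}, \code{medium},
#'   \code{replicate}, \code{a570_initial}, \code{a570_final}), or a
#'   \code{GrowthTable} carrying one.
#' @return data.frame (\code{isolate}, \code{medium}, \code{replicate},
#'   \code{value}).
#' @export
respirationGrowth <- function(respiration) {
  rp <- if (inherits(respiration, "GrowthTable")) respiration$respiration
        else respiration
  if (is.null(rp)) stop("no respiration readings available")
  blanks <- rp[rp$isolate == "none", , drop = FALSE]
  res <- rp[rp$isolate != "none", , drop = FALSE]
  corr <- if (nrow(blanks))
    tapply(blanks$a570_initial - blanks$a570_final, blanks$medium, mean)
  else setNames(numeric(0), character(0))
  base <- corr[res$medium]
  base[is.na(base)] <- 0
  out <- data.frame(res[, c("isolate", "medium", "replicate")],
                    value = pmax(0, (res$a570_initial - res$a570_final) - base),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Measured interaction-strength matrix from sequential growth
#'
#' Builds the recipient x influencer matrix of measured interaction
#' strengths from per-well growth values (final OD or cumulative
#' respiration). MIS uses replicate-mean growths,
#' \code{mean(spent) / mean(SDM) - 1}. Significance comes from a
#' per-recipient Dunnett family comparing each spent medium against the
#' recipient's SDM reference; insignificant entries are retained but
#' flagged via their p-values (mirroring dashed network edges).
#'
#' @param growthValues data.frame (\code{isolate} = recipient,
#'   \code{medium} = influencer id or \code{reference}, \code{replicate},
#'   \code{value}) from \code{\link{finalGrowth}} or
#'   \code{\link{respirationGrowth}}.
#' @param alpha significance level.
#' @param metric label stored in the result (\code{"final_od"} or
#'   \code{"respiration"}).
#' @param reference medium id of the fresh-medium reference
#'   (default \code{"SDM"}).
#' @return an \linkS4class{InteractionMatrix} of type \code{"MIS"}.
#' @export
misMatrix <- function(growthValues, alpha = 0.05, metric = "final_od",
                      reference = "SDM") {
  gv <- growthValues
  stopifnot(all(c("isolate", "medium", "replicate", "value") %in%
                colnames(gv)))
  recipients <- sort(unique(gv$isolate))
  influencers <- sort(setdiff(unique(gv$medium), reference))
  iso <- sort(union(recipients, influencers))
  mis <- pv <- matrix(NA_real_, length(iso), length(iso),
                      dimnames = list(iso, iso))
  undef <- character(0)
  for (r in recipients) {
    sub <- gv[gv$isolate == r, ]
    if (!reference %in% sub$medium) {
      stop("recipient '", r, "' has no growth in the reference medium '",
           reference, "'")
    }
    refMean <- mean(sub$value[sub$medium == reference])
    if (refMean <= 0) {
      undef <- c(undef, r)
      next
    }
    media <- setdiff(unique(sub$medium), c(reference, r))
    keep <- sub$medium %in% c(reference, media)
    grp <- factor(sub$medium[keep], levels = c(reference, media))
    res <- .dunnettTest(sub$value[keep], grp, reference)
    for (i in media) {
      mis[r, i] <- max(-1, mean(sub$value[sub$medium == i]) / refMean - 1)
      pv[r, i] <- res$p[[i]]
    }
  }
  new("InteractionMatrix", strength = mis, pvalues = pv, type = "MIS",
      metric = metric, alpha = alpha, undefinedRecipients = undef)
}
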