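#' Predicted competitive interaction strengths from niche overlap
#'
#' The predicted interaction strength of influencer i on recipient r is the
#' directional overlap of their substrate-utilization profiles,
#' \deqn{PIS_{ri} = - \frac{\sum_m p_{m,r} \, p_{m,i}}{\sum_m p_{m,r}^2},}
#' where \eqn{p_{m,r}} is the fraction of metabolite m significantly
#' depleted by isolate r in monoculture. PIS is always <= 0 (competition or
#' nothing): it is 0 exactly when the two supports are disjoint, -1 when
#' the profiles are identical, and invariant under common positive
#' rescaling of all profiles (so fractions vs. percentages give identical
#' results). Recipients with empty support leave the denominator 0; their
#' rows are undefined (\code{NA}) and reported via
#' \code{undefinedRecipients()}.
#'
#' @param profiles metabolite x isolate matrix of depletion fractions
#'   (from \code{\link{utilizationProfiles}}); >= 2 isolates over a shared
#'   metabolite index.
#' @return an \linkS4class{InteractionMatrix} of type \code{"PIS"}
#'   (rows = recipients, columns = influencers, diagonal NA).
#' @examples
#' p <- cbind(r = c(0.8, 0.4, 0), i = c(0.5, 1.0, 0.9))
#' interactionStrengths(predictedInteractions(p))
#' @export
predictedInteractions <- function(profiles) {
  stopifnot(is.matrix(profiles), ncol(profiles) >= 2,
            all(profiles >= 0))
  iso <- colnames(profiles)
  if (is.null(iso)) iso <- paste0("isolate", seq_len(ncol(profiles)))
  N <- crossprod(profiles)            # N[r, i] = sum_m p_mr p_mi
  denom <- diag(N)
  if (all(denom == 0)) stop("all profiles have empty support")
  pis <- -sweep(N, 1, denom, "/")     # rows = recipients
  diag(pis) <- NA_real_
  undef <- iso[denom == 0]
  pis[denom == 0, ] <- NA_real_
  dimnames(pis) <- list(iso, iso)
  new("InteractionMatrix", strength = pis,
      pvalues = matrix(NA_real_, nrow(pis), ncol(pis), dimnames = dimnames(pis)),
      type = "PIS", metric = "niche_overlap", alpha = NA_real_,
      undefinedRecipients = undef)
}

#' Competitive rank of each isolate
#'
#' Sums, for each focal isolate r, the predicted negative effects of all
#' other isolates on r minus the negative effects of r on all others:
#' \deqn{R_r = \sum_i (PIS_{ri} - PIS_{ir}).}
#' Because the summand is antisymmetric, the scores sum to zero over
#' isolates. The larger R_r, the greater the isolate's potential for
#' competitive interactions (it suppresses others more than it is
#' suppressed). Isolates with undefined PIS rows are excluded (with a
#' warning) before ranking.
#'
#' @param pis an \linkS4class{InteractionMatrix} of type \code{"PIS"}.
#' @return data.frame with columns \code{isolate}, \code{score} (R_r) and
#'   \code{rank} (1 = largest score).
#' @export
competitiveRank <- function(pis) {
  stopifnot(is(pis, "InteractionMatrix"), interactionType(pis) == "PIS")
  s <- interactionStrengths(pis)
  undef <- undefinedRecipients(pis)
  if (length(undef)) {
    warning("excluding isolate(s) with undefined profiles: ",
            paste(undef, collapse = ", "))
    keep <- setdiff(rownames(s), undef)
    s <- s[keep, keep, drop = FALSE]
  }
  if (nrow(s) < 2) stop("fewer than 2 isolates with defined profiles")
  s0 <- s
  s0[is.na(s0)] <- 0                   # diagonal; Eq. sums run over i != r
  score <- rowSums(s0) - colSums(s0)
  data.frame(isolate = rownames(s), score = score,
             rank = as.integer(rank(-score, ties.method = "min")),
             row.names = NULL, stringsAsFactors = FALSE)
}
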