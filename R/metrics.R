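#' Per-isolate substrate-utilization metrics
#'
#' Summarises each isolate's utilization profile with three numbers:
#' \itemize{
#'   \item richness: the number of substrates significantly depleted
#'     (profile support size);
#'   \item abundance: the sum of the percentages of depletion,
#'     \code{100 * sum(p)} (one fully depleted substrate contributes 100);
#'   \item diversity: the inverse Simpson index
#'     \code{D = 1 / sum(pi^2)} with proportions
#'     \code{pi = p / sum(p)} over the support. D is the evenness-weighted
#'     effective number of substrates used: D = richness for perfectly even
#'     utilization, D = 1 for a single substrate, and D is undefined
#'     (\code{NA}) on an empty support.
#' }
#'
#' @param profiles metabolite x isolate matrix of depletion fractions from
#'   \code{\link{utilizationProfiles}} (or a single profile vector).
#' @return data.frame with columns \code{isolate}, \code{richness},
#'   \code{abundance}, \code{diversity}.
#' @examples
#' p <- cbind(even = c(0.5, 0.5, 0), single = c(1, 0, 0))
#' substrateMetrics(p)
#' @export
substrateMetrics <- function(profiles) {
  if (is.null(dim(profiles)))
    profiles <- matrix(profiles, ncol = 1,
                       dimnames = list(names(profiles), "isolate"))
  stopifnot(all(profiles >= 0), all(profiles <= 1))
  iso <- colnames(profiles)
  if (is.null(iso)) iso <- paste0("isolate", seq_len(ncol(profiles)))
  rich <- colSums(profiles > 0)
  abun <- 100 * colSums(profiles)
  div <- vapply(seq_len(ncol(profiles)), function(j) {
    pj <- profiles[, j]
    pj <- pj[pj > 0]
    if (!length(pj)) return(NA_real_)
    pi <- pj / sum(pj)
    1 / sum(pi^2)
  }, numeric(1))
  data.frame(isolate = iso, richness = as.integer(rich), abundance = abun,
             diversity = div, row.names = NULL,
             stringsAsFactors = FALSE)
}
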