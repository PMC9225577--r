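## Seeded synthetic spent-medium experiments with known ground truth.
##
## The generator emulates the design of an exometabolomic interaction
## study: a defined medium of equimolar metabolites, isolates with
## generalist/specialist consumption structure grown in monoculture
## (triplicates, early/late uninoculated medium controls), sequential
## re-culture of every recipient in every influencer's spent medium with
## OD and MicroResp readouts, and untargeted LC-MS tables including
## extraction blanks and double-spent media. Replicate noise is
## multiplicative log-normal with a chosen coefficient of variation.

## mean-one log-normal noise factors; exactly 1 when cv = 0
.noiseFactor <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  s2 <- log(1 + cv^2)
  rlnorm(n, meanlog = -s2 / 2, sdlog = sqrt(s2))
}

#' Generate the ground truth of a synthetic isolate community
#'
#' Draws a reproducible community: a consumption-fraction matrix with
#' generalist/specialist archetypes (generalists deplete many substrates,
#' specialists few; every isolate depletes at least one substrate almost
#' completely), logistic growth rates (generalists faster), yield and
#' respiration coefficients coupling consumed substrate to OD600 and A570,
#' and -- unless \code{crossFeeding = FALSE} -- secreted features with a
#' consumability map stating which other isolates can use them.
#'
#' Secretion amounts are expressed in units of the feature's background
#' peak height, so an amount of 2 plants a 3-fold abundance increase in
#' the secreting isolate's spent medium.
#'
#' @param nIsolates number of isolates (>= 2).
#' @param nMetabolites number of defined-medium metabolites (>= 2); the
#'   emulated medium has 89 equimolar compounds, smaller communities are
#'   used for fast tests.
#' @param seed integer seed; identical seeds give identical truths.
#' @param crossFeeding plant secreted, cross-consumable features; set
#'   FALSE for a pure-competition community (all true interactions <= 0).
#' @param nSecretedPer secreted features per isolate.
#' @param consumableProb probability a secreted feature is consumable by
#'   any given non-producer isolate.
#' @return a \linkS4class{SyntheticTruth}.
#' @examples
#' truth <- simulateTruth(nIsolates = 4, nMetabolites = 20, seed = 7)
#' truth
#' @export
simulateTruth <- function(nIsolates = 8, nMetabolites = 89, seed = 1,
                          crossFeeding = TRUE, nSecretedPer = 3,
                          consumableProb = 0.4) {
  stopifnot(nIsolates >= 2, nMetabolites >= 2)
  set.seed(seed)
  iso <- sprintf("iso%d", seq_len(nIsolates))
  met <- sprintf("met%03d", seq_len(nMetabolites))
  archetype <- rep(c("generalist", "specialist"), length.out = nIsolates)
  supLo <- c(generalist = 0.45, specialist = 0.10)
  supHi <- c(generalist = 0.70, specialist = 0.25)
  C <- matrix(0, nIsolates, nMetabolites, dimnames = list(iso, met))
  for (j in seq_len(nIsolates)) {
    a <- archetype[j]
    size <- max(2L, round(runif(1, supLo[a], supHi[a]) * nMetabolites))
    if (size > nMetabolites)
      stop("support size exceeds the number of metabolites")
    sup <- sample.int(nMetabolites, size)
    C[j, sup] <- runif(size, 0.15, 0.95)
    ## every isolate depletes at least one substrate nearly completely
    C[j, sup[which.max(C[j, sup])]] <- runif(1, 0.97, 1)
  }
  growthRate <- ifelse(archetype == "generalist",
                       runif(nIsolates, 0.4, 0.8),
                       runif(nIsolates, 0.15, 0.4))
  yield <- runif(nIsolates, 0.015, 0.03)
  respirationFraction <- runif(nIsolates, 0.010, 0.020)
  nF <- if (crossFeeding) nIsolates * nSecretedPer else 0L
  feat <- if (nF) sprintf("secr_%s_f%d", rep(iso, each = nSecretedPer),
                          rep(seq_len(nSecretedPer), nIsolates))
          else character(0)
  S <- matrix(0, nIsolates, nF, dimnames = list(iso, feat))
  consumable <- matrix(FALSE, nIsolates, nF, dimnames = list(iso, feat))
  nutrition <- numeric(nF)
  if (nF) {
    producer <- rep(seq_len(nIsolates), each = nSecretedPer)
    for (f in seq_len(nF)) {
      S[producer[f], f] <- runif(1, 1.5, 4)
      others <- setdiff(seq_len(nIsolates), producer[f])
      consumable[others, f] <- runif(length(others)) < consumableProb
    }
    nutrition <- runif(nF, 0.3, 1.0)
    names(nutrition) <- feat
  }
  new("SyntheticTruth", consumption = C, secretion = S,
      consumable = consumable, secretionNutrition = nutrition,
      yield = setNames(yield, iso),
      respirationFraction = setNames(respirationFraction, iso),
      growthRate = setNames(growthRate, iso),
      archetype = setNames(archetype, iso), seed = as.integer(seed))
}

#' Planted cross-feeding events of a synthetic truth
#'
#' @param truth a \linkS4class{SyntheticTruth}.
#' @return data.frame (\code{influencer}, \code{recipient},
#'   \code{feature}) of every (producer, consumer, feature) triple the
#'   generator planted; the cross-feeding classifier should recover these.
#' @export
trueCrossFeeding <- function(truth) {
  S <- secretionMatrix(truth)
  if (!ncol(S))
    return(data.frame(influencer = character(0), recipient = character(0),
                      feature = character(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, lapply(colnames(S), function(f) {
    prod <- rownames(S)[S[, f] > 0]
    cons <- rownames(S)[truth@consumable[, f]]
    if (!length(cons)) return(NULL)
    expand.grid(influencer = prod, recipient = cons, feature = f,
                stringsAsFactors = FALSE)
  }))
  if (is.null(out))
    out <- data.frame(influencer = character(0), recipient = character(0),
                      feature = character(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

## logistic curve through the generator's parameters
.logisticOD <- function(t, K, r, N0)
  K / (1 + ((K - N0) / N0) * exp(-r * t))

#' Simulate monoculture spent-medium profiling and growth
#'
#' Produces the targeted peak-height table of a monoculture experiment:
#' each isolate grown in triplicate in the defined medium, spent media
#' sampled at early stationary phase, plus triplicate early and late
#' uninoculated medium controls (fast growers are matched to the early
#' control, slow growers to the late one, which carries a small abiotic
#' degradation drift). Spent peak heights are
#' \code{baseline * (1 - C[i, m]) * noise}; secreted features are appended
#' as extra rows with backgrounds at blank level. Also returns triplicate
#' logistic OD600 growth curves with carrying capacity coupled linearly to
#' total consumed substrate.
#'
#' @param truth a \linkS4class{SyntheticTruth}.
#' @param cv coefficient of variation of multiplicative replicate noise.
#' @param nReplicates replicates per isolate and control (default 3).
#' @param seed integer seed for the measurement-level randomness.
#' @param baselineMeanLog,baselineSdLog log-normal parameters of the
#'   baseline peak-height distribution across metabolites (defaults span
#'   roughly two orders of magnitude).
#' @param controlDrift maximum fractional abiotic degradation of the late
#'   control relative to the early one.
#' @param timeStepH,durationH OD sampling grid (defaults: every 20 min
#'   for 48 h).
#' @return list with \code{peaks} (targeted
#'   \linkS4class{PeakHeightExperiment}), \code{growth}
#'   (\code{GrowthTable}) and \code{baseline} (named numeric).
#' @export
simulateMonocultures <- function(truth, cv = 0.1, nReplicates = 3,
                                 seed = 1,
                                 baselineMeanLog = log(2e4),
                                 baselineSdLog = 1.15,
                                 controlDrift = 0.03,
                                 timeStepH = 1 / 3, durationH = 48) {
  stopifnot(is(truth, "SyntheticTruth"), nReplicates >= 2)
  set.seed(seed)
  C <- consumptionMatrix(truth)
  iso <- rownames(C)
  met <- colnames(C)
  S <- secretionMatrix(truth)
  feat <- colnames(S)
  bm <- setNames(rlnorm(length(met), baselineMeanLog, baselineSdLog), met)
  bf <- setNames(rlnorm(length(feat), log(150), 0.3), feat)
  drift <- runif(length(met), 0, controlDrift)
  fast <- truth@growthRate >= median(truth@growthRate)
  ctrlGroup <- ifelse(fast, "early", "late")

  rows <- c(met, feat)
  cols <- list()
  md <- list()
  addSample <- function(id, values, isolate, role, group, rep,
                        influencer = NA, recipient = NA) {
    cols[[length(cols) + 1L]] <<- values
    md[[length(md) + 1L]] <<- data.frame(
      sample_id = id, isolate_id = isolate, role = role,
      influencer_id = influencer, recipient_id = recipient,
      replicate = rep, ionization_mode = "not_applicable",
      control_group = group, stringsAsFactors = FALSE)
  }
  expected <- function(i) {
    base <- if (ctrlGroup[i] == "late") bm * (1 - drift) else bm
    c(base * (1 - C[i, ]),
      if (length(feat)) bf * (1 + S[i, ]) else numeric(0))
  }
  for (rep in seq_len(nReplicates)) {
    addSample(sprintf("ctrl_early_r%d", rep),
              c(bm, bf) * .noiseFactor(length(rows), cv),
              NA, "medium_control_early", "early", rep)
    addSample(sprintf("ctrl_late_r%d", rep),
              c(bm * (1 - drift), bf) * .noiseFactor(length(rows), cv),
              NA, "medium_control_late", "late", rep)
  }
  for (i in iso)
    for (rep in seq_len(nReplicates))
      addSample(sprintf("%s_spent_r%d", i, rep),
                expected(i) * .noiseFactor(length(rows), cv),
                i, "spent", ctrlGroup[i], rep)
  h <- do.call(cbind, cols)
  rownames(h) <- rows
  meta <- do.call(rbind, md)
  colnames(h) <- meta$sample_id
  peaks <- PeakHeightExperiment(h, meta, tableKind = "targeted")

  ## triplicate logistic growth in the defined medium
  tg <- seq(0, durationH, by = timeStepH)
  N0 <- 0.02
  odr <- list()
  for (i in iso) {
    K <- N0 + truth@yield[i] * sum(C[i, ])
    for (rep in seq_len(nReplicates)) {
      od <- .logisticOD(tg, K, truth@growthRate[i], N0) *
        .noiseFactor(length(tg), cv)
      odr[[length(odr) + 1L]] <- data.frame(
        isolate = i, medium = "SDM", replicate = rep, time_h = tg,
        od600 = od, stringsAsFactors = FALSE)
    }
  }
  for (rep in seq_len(nReplicates))
    odr[[length(odr) + 1L]] <- data.frame(
      isolate = "none", medium = "SDM", replicate = rep, time_h = tg,
      od600 = 0.001 * .noiseFactor(length(tg), cv),
      stringsAsFactors = FALSE)
  growth <- structure(list(od = do.call(rbind, odr), respiration = NULL),
                      class = "GrowthTable")
  list(peaks = peaks, growth = growth, baseline = c(bm, bf))
}

#' Simulate the sequential (spent-medium re-culture) experiment
#'
#' For every ordered (recipient, influencer) pair, grows the recipient in
#' the influencer's spent medium. Recipient growth is proportional to the
#' substrate left over for it, \code{sum_m C[r, m] (1 - C[i, m])}, plus
#' the nutritional value of consumable secreted features, which yields the
#' ground-truth measured interaction strength
#' \code{trueMIS[r, i] = available(r in spent_i) / available(r in SDM) - 1}.
#' Returns triplicate OD600 curves and MicroResp A570 readings (with
#' uninoculated controls) and, unless \code{withPeaks = FALSE}, the
#' untargeted feature table: extraction blanks, the defined-medium
#' control, spent and abiotic incubated-spent controls per influencer, and
#' all double-spent media. Medium metabolites appear at
#' \code{baseline * (1 - C[i, m]) * (1 - C[r, m])} in double-spent medium;
#' consumable secreted features drop to 15 percent of their secreted
#' amount, planting a cross-feeding pattern (up in spent, down in
#' double-spent).
#'
#' @param truth a \linkS4class{SyntheticTruth}.
#' @param cv coefficient of variation of replicate noise.
#' @param nReplicates replicates per condition.
#' @param seed integer seed.
#' @param withPeaks build the untargeted peak table (set FALSE to
#'   simulate growth only, e.g. for interaction-recovery runs).
#' @param mode ionization-mode tag for the untargeted table.
#' @param baselineMeanLog,baselineSdLog baseline peak-height distribution.
#' @param blankFraction extraction-blank carryover as a fraction of the
#'   medium baseline.
#' @param residualConsumption fraction of a consumable secreted feature
#'   removed by the recipient.
#' @param timeStepH,durationH OD sampling grid (defaults: every 30 min
#'   for 48 h).
#' @return list with \code{peaks} (untargeted
#'   \linkS4class{PeakHeightExperiment} or NULL), \code{growth}
#'   (\code{GrowthTable} with OD and respiration), and \code{trueMIS}
#'   (recipient x influencer matrix).
#' @export
simulateSequential <- function(truth, cv = 0.1, nReplicates = 3, seed = 1,
                               withPeaks = TRUE, mode = "positive",
                               baselineMeanLog = log(2e4),
                               baselineSdLog = 1.15,
                               blankFraction = 0.02,
                               residualConsumption = 0.85,
                               timeStepH = 0.5, durationH = 48) {
  stopifnot(is(truth, "SyntheticTruth"), nReplicates >= 2)
  set.seed(seed)
  C <- consumptionMatrix(truth)
  iso <- rownames(C)
  met <- colnames(C)
  S <- secretionMatrix(truth)
  feat <- colnames(S)
  nutr <- truth@secretionNutrition

  ## substrate available to r in each medium, and the true MIS
  availSDM <- rowSums(C)
  trueMIS <- matrix(NA_real_, length(iso), length(iso),
                    dimnames = list(iso, iso))
  avail <- matrix(NA_real_, length(iso), length(iso),
                  dimnames = list(iso, iso))
  for (r in iso) for (i in iso) {
    if (r == i) next
    a <- sum(C[r, ] * (1 - C[i, ]))
    if (length(feat)) {
      use <- truth@consumable[r, ] & S[i, ] > 0
      a <- a + sum(nutr[use])
    }
    avail[r, i] <- a
    trueMIS[r, i] <- a / availSDM[r] - 1
  }

  peaks <- NULL
  if (withPeaks) {
    bm <- setNames(rlnorm(length(met), baselineMeanLog, baselineSdLog), met)
    bf <- setNames(rlnorm(length(feat), log(150), 0.3), feat)
    rows <- c(met, feat)
    cols <- list(); md <- list()
    addSample <- function(id, values, isolate, role, group, rep,
                          influencer = NA, recipient = NA) {
      cols[[length(cols) + 1L]] <<- values * .noiseFactor(length(values), cv)
      md[[length(md) + 1L]] <<- data.frame(
        sample_id = id, isolate_id = isolate, role = role,
        influencer_id = influencer, recipient_id = recipient,
        replicate = rep, ionization_mode = mode,
        control_group = group, stringsAsFactors = FALSE)
    }
    spentLevel <- function(i)
      c(bm * (1 - C[i, ]),
        if (length(feat)) bf * (1 + S[i, ]) else numeric(0))
    for (rep in seq_len(nReplicates)) {
      addSample(sprintf("blank_r%d", rep),
                c(bm * blankFraction, bf), NA, "extraction_control",
                NA, rep)
      addSample(sprintf("sdm_r%d", rep), c(bm, bf), NA,
                "medium_control_late", "seq", rep)
    }
    for (i in iso) for (rep in seq_len(nReplicates)) {
      addSample(sprintf("%s_spent_r%d", i, rep), spentLevel(i),
                i, "spent", "seq", rep)
      addSample(sprintf("%s_uspent_r%d", i, rep), spentLevel(i),
                NA, "uninoculated_spent_control", NA, rep,
                influencer = i)
    }
    for (i in iso) for (r in setdiff(iso, i)) {
      lev <- bm * (1 - C[i, ]) * (1 - C[r, ])
      if (length(feat)) {
        sf <- S[i, ]                       # influencer's secretion
        sf <- sf * ifelse(truth@consumable[r, ] & sf > 0,
                          1 - residualConsumption, 1)
        lev <- c(lev, bf * (1 + sf + S[r, ]))  # plus recipient's own
      }
      for (rep in seq_len(nReplicates))
        addSample(sprintf("%s_on_%s_r%d", r, i, rep), lev,
                  r, "double_spent", NA, rep,
                  influencer = i, recipient = r)
    }
    h <- do.call(cbind, cols)
    rownames(h) <- rows
    meta <- do.call(rbind, md)
    colnames(h) <- meta$sample_id
    peaks <- PeakHeightExperiment(h, meta, tableKind = "untargeted")
  }

  ## sequential growth curves + respiration
  tg <- seq(0, durationH, by = timeStepH)
  N0 <- 0.01
  odr <- list(); resp <- list()
  media <- c("SDM", iso)
  for (r in iso) for (mmed in media) {
    if (identical(r, mmed)) next
    a <- if (mmed == "SDM") availSDM[r] else avail[r, mmed]
    K <- N0 + truth@yield[r] * a
    for (rep in seq_len(nReplicates)) {
      od <- .logisticOD(tg, max(K, N0 + 1e-6), truth@growthRate[r], N0) *
        .noiseFactor(length(tg), cv)
      odr[[length(odr) + 1L]] <- data.frame(
        isolate = r, medium = mmed, replicate = rep, time_h = tg,
        od600 = od, stringsAsFactors = FALSE)
      dA <- (0.02 + truth@respirationFraction[r] * a) *
        .noiseFactor(1, cv)
      resp[[length(resp) + 1L]] <- data.frame(
        isolate = r, medium = mmed, replicate = rep,
        a570_initial = 1.2, a570_final = 1.2 - dA,
        stringsAsFactors = FALSE)
    }
  }
  for (mmed in media) for (rep in seq_len(nReplicates)) {
    odr[[length(odr) + 1L]] <- data.frame(
      isolate = "none", medium = mmed, replicate = rep, time_h = tg,
      od600 = 0.001 * .noiseFactor(length(tg), cv),
      stringsAsFactors = FALSE)
    resp[[length(resp) + 1L]] <- data.frame(
      isolate = "none", medium = mmed, replicate = rep,
      a570_initial = 1.2,
      a570_final = 1.2 - 0.02 * .noiseFactor(1, cv),
      stringsAsFactors = FALSE)
  }
  growth <- structure(list(od = do.call(rbind, odr),
                           respiration = do.call(rbind, resp)),
                      class = "GrowthTable")
  list(peaks = peaks, growth = growth, trueMIS = trueMIS)
}

#' Standard small synthetic community bundle
#'
#' Convenience wrapper generating the reference fixture used throughout
#' the examples and tests: an 8-isolate, 60-metabolite community
#' (seed 42) with its monoculture and sequential simulations at the
#' default replicate noise.
#'
#' @param cv replicate coefficient of variation.
#' @param crossFeeding plant secreted consumable features.
#' @param seed integer seed.
#' @return list with \code{truth}, \code{mono} and \code{sequential}.
#' @export
fixtureCommunity <- function(cv = 0.1, crossFeeding = TRUE, seed = 42) {
  truth <- simulateTruth(nIsolates = 8, nMetabolites = 60, seed = seed,
                         crossFeeding = crossFeeding)
  list(truth = truth,
       mono = simulateMonocultures(truth, cv = cv, seed = seed),
       sequential = simulateSequential(truth, cv = cv, seed = seed))
}
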