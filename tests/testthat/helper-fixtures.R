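## Small fixtures built in code.

## 5 metabolites x 9 samples: one isolate's triplicate spent medium plus
## triplicate early and late uninoculated medium controls.
makeToyTargeted <- function() {
  h <- rbind(
    ala = c(45, 50, 55,   100, 110, 90,   100, 100, 100),
    glc = c(95, 105, 100, 100, 110, 90,   100, 100, 100),
    suc = c(300, 310, 290, 100, 110, 90,  100, 100, 100),
    trp = c(1, 2, 3,      100, 110, 90,   100, 100, 100),
    urea = c(100, 110, 90, 100, 110, 90,  100, 100, 100))
  colnames(h) <- c(paste0("iso1_r", 1:3), paste0("ce_r", 1:3),
                   paste0("cl_r", 1:3))
  md <- data.frame(
    sample_id = colnames(h),
    isolate_id = c(rep("iso1", 3), rep(NA, 6)),
    role = c(rep("spent", 3), rep("medium_control_early", 3),
             rep("medium_control_late", 3)),
    replicate = rep(1:3, 3),
    control_group = c(rep("early", 6), rep("late", 3)),
    stringsAsFactors = FALSE)
  PeakHeightExperiment(h, md, tableKind = "targeted")
}

## untargeted toy with blanks, SDM control, spent, abiotic spent control
## and double-spent samples for one (influencer, recipient) pair; feature
## means chosen per trajectory pattern.
makeToyUntargeted <- function() {
  tri <- function(m, cv = 0.03) m * c(0.97, 1, 1.03)
  blocks <- list(
    blank = c(crossfed = 100, seqdep = 100, flat = 100, background = 100),
    sdm   = c(crossfed = 100, seqdep = 1000, flat = 500, background = 103),
    spent = c(crossfed = 400, seqdep = 400, flat = 500, background = 101),
    uspent = c(crossfed = 400, seqdep = 400, flat = 500, background = 101),
    double = c(crossfed = 150, seqdep = 40, flat = 500, background = 102))
  h <- do.call(cbind, lapply(names(blocks), function(b)
    vapply(1:3, function(r) blocks[[b]] * (0.96 + 0.02 * r), numeric(4))))
  colnames(h) <- paste0(rep(names(blocks), each = 3), "_r", 1:3)
  md <- data.frame(
    sample_id = colnames(h),
    isolate_id = c(rep(NA, 6), rep("isoA", 3), rep(NA, 3), rep("isoB", 3)),
    role = rep(c("extraction_control", "medium_control_late", "spent",
                 "uninoculated_spent_control", "double_spent"), each = 3),
    influencer_id = c(rep(NA, 9), rep("isoA", 6)),
    recipient_id = c(rep(NA, 12), rep("isoB", 3)),
    replicate = rep(1:3, 5),
    ionization_mode = "positive",
    control_group = c(rep(NA, 3), rep("g", 6), rep(NA, 6)),
    stringsAsFactors = FALSE)
  PeakHeightExperiment(h, md, tableKind = "untargeted")
}

## noiseless logistic series
logisticSeries <- function(K = 1.2, r = 0.6, N0 = 0.02,
                           by = 1 / 3, to = 48) {
  t <- seq(0, to, by = by)
  list(time = t, od = K / (1 + ((K - N0) / N0) * exp(-r * t)))
}
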