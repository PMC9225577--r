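## Many-to-one (Dunnett-style) comparisons against a shared control.
##
## For a one-way layout with groups j = 1..k compared against a common
## control 0, the statistics T_j = (Ybar_j - Ybar_0) / (S sqrt(1/n_j + 1/n_0))
## follow a multivariate t with one-factor correlation R_jl = lambda_j
## lambda_l, lambda_j = sqrt(n_j / (n_j + n_0)). That structure factorises
## the joint CDF into a double integral over the shared control variate and
## the studentising chi variable, evaluated here with fixed Gauss-Hermite x
## Gauss-Legendre quadrature. Deterministic (unlike quasi-Monte-Carlo
## multivariate-t integration) and fast enough to run per analyte.

.gaussHermiteCache <- new.env(parent = emptyenv())

.gaussHermite <- function(n) {
  key <- as.character(n)
  if (!is.null(.gaussHermiteCache[[key]])) return(.gaussHermiteCache[[key]])
  ## Golub-Welsch: eigen-decomposition of the Jacobi matrix for Hermite
  i <- seq_len(n - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- J[cbind(i + 1, i)] <- sqrt(i / 2)
  e <- eigen(J, symmetric = TRUE)
  w <- sqrt(pi) * e$vectors[1, ]^2
  out <- list(x = rev(e$values), w = rev(w))
  .gaussHermiteCache[[key]] <- out
  out
}

.gaussLegendre <- function(n, a, b) {
  i <- seq_len(n - 1)
  b_ <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- J[cbind(i + 1, i)] <- b_
  e <- eigen(J, symmetric = TRUE)
  x <- e$values
  w <- 2 * e$vectors[1, ]^2
  list(x = (b - a) / 2 * x + (a + b) / 2, w = (b - a) / 2 * w)
}

## P(max_j |T_j| >= q) for each q, the two-sided single-step adjusted
## p-value. lam: per-comparison lambda; df: error degrees of freedom.
.dunnettAdjP <- function(q, lam, df, nz = 32L, nu = 48L) {
  k <- length(lam)
  q <- abs(q)
  if (k == 1L)            # single comparison: plain two-sided t
    return(2 * pt(-q, df))
  gh <- .gaussHermite(nz)
  z0 <- gh$x * sqrt(2)
  wz <- gh$w / sqrt(pi)
  ## u = S/sigma: u^2 * df ~ chi^2_df
  lo <- sqrt(qchisq(1e-12, df) / df)
  hi <- sqrt(qchisq(1 - 1e-12, df) / df)
  gl <- .gaussLegendre(nu, lo, hi)
  u <- gl$x
  wu <- gl$w * (2 * df * u) * dchisq(df * u^2, df)
  sq <- sqrt(pmax(1 - lam^2, .Machine$double.eps))
  vapply(q, function(qq) {
    if (!is.finite(qq)) return(0)
    P <- matrix(1, nu, nz)
    for (j in seq_len(k)) {
      shift <- lam[j] * z0
      A <- outer(qq * u, shift, "+") / sq[j]
      B <- outer(-qq * u, shift, "+") / sq[j]
      P <- P * (pnorm(A) - pnorm(B))
    }
    min(max(1 - sum(wu * (P %*% wz)), 0), 1)
  }, numeric(1))
}

## One family: numeric values, grouping factor, name of the control level.
## Returns per non-control group: mean, difference from control, t, and
## Dunnett-adjusted two-sided p. Degenerate families (zero pooled variance)
## fall back to an exact-equality rule: p = 1 if the group mean equals the
## control mean, p = 0 otherwise.
.dunnettTest <- function(values, group, control) {
  group <- factor(group)
  stopifnot(control %in% levels(group))
  ns <- tapply(values, group, length)
  if (any(ns < 2))
    stop("fewer than 2 replicates in group(s): ",
         paste(names(ns)[ns < 2], collapse = ", "))
  means <- c(tapply(values, group, mean))
  ss <- tapply(values, group, function(x) sum((x - mean(x))^2))
  df <- length(values) - nlevels(group)
  mse <- sum(ss) / df
  trt <- setdiff(levels(group), control)
  diffs <- means[trt] - means[control]
  scale2 <- mean(values^2)
  if (mse <= .Machine$double.eps * max(scale2, 1)) {
    ## all replicates (numerically) identical within groups
    p <- ifelse(abs(diffs) <= sqrt(.Machine$double.eps * max(scale2, 1)),
                1, 0)
    tstat <- ifelse(p == 1, 0, Inf) * sign(diffs)
    return(list(means = means, control = control, diff = diffs,
                tstat = tstat, p = p, df = df, degenerate = TRUE))
  }
  se <- sqrt(mse * (1 / ns[trt] + 1 / ns[control]))
  tstat <- diffs / se
  lam <- sqrt(ns[trt] / (ns[trt] + ns[control]))
  p <- .dunnettAdjP(abs(tstat), lam, df)
  names(p) <- trt
  list(means = means, control = control, diff = diffs, tstat = tstat,
       p = p, df = df, degenerate = FALSE)
}

## Fast screen used for background filtering: adjusted p of the *largest*
## statistic among a subset of comparisons (adjusted p is monotone in |t|,
## so "any comparison in the subset significant" reduces to this one value).
.dunnettMaxP <- function(values, group, control, subset = NULL) {
  fam <- .dunnettFamilyStats(values, group, control)
  if (is.null(fam)) return(list(p = 1, degenerate = TRUE, diff = NULL))
  keep <- if (is.null(subset)) seq_along(fam$tstat) else subset
  if (!length(keep) || !any(is.finite(fam$tstat[keep]) | fam$tstat[keep] == Inf))
    return(list(p = 1, degenerate = fam$degenerate, diff = fam$diff))
  if (fam$degenerate) {
    p <- if (any(fam$p[keep] == 0)) 0 else 1
    return(list(p = p, degenerate = TRUE, diff = fam$diff))
  }
  tmax <- max(abs(fam$tstat[keep]))
  list(p = .dunnettAdjP(tmax, fam$lam, fam$df), degenerate = FALSE,
       diff = fam$diff)
}

## shared family statistics without adjusting every comparison
.dunnettFamilyStats <- function(values, group, control) {
  group <- factor(group)
  if (!control %in% levels(group)) return(NULL)
  ns <- tapply(values, group, length)
  if (any(ns < 2))
    stop("fewer than 2 replicates in group(s): ",
         paste(names(ns)[ns < 2], collapse = ", "))
  means <- tapply(values, group, mean)
  ss <- tapply(values, group, function(x) sum((x - mean(x))^2))
  df <- length(values) - nlevels(group)
  mse <- sum(ss) / df
  trt <- setdiff(levels(group), control)
  diffs <- means[trt] - means[control]
  scale2 <- mean(values^2)
  if (mse <= .Machine$double.eps * max(scale2, 1)) {
    eq <- abs(diffs) <= sqrt(.Machine$double.eps * max(scale2, 1))
    return(list(tstat = ifelse(eq, 0, Inf) * sign(diffs),
                p = ifelse(eq, 1, 0), diff = diffs, df = df,
                lam = sqrt(ns[trt] / (ns[trt] + ns[control])),
                degenerate = TRUE))
  }
  se <- sqrt(mse * (1 / ns[trt] + 1 / ns[control]))
  tstat <- diffs / se
  list(tstat = tstat, p = NULL, diff = diffs, df = df,
       lam = sqrt(ns[trt] / (ns[trt] + ns[control])), degenerate = FALSE)
}
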