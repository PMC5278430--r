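## Repeated-measures statistical battery on long-format absorption tables:
## subject-by-treatment model, between-subjects ANOVA on marginal means,
## Mauchly sphericity test, Greenhouse-Geisser-corrected within-subject
## ANOVA, and Tukey-Kramer pairwise comparisons (overall and per band).
## Subjects are wing sets; the between factor is preparation or preparation
## group; the within factor is frequency band.

#' Validate a long-format repeated-measures absorption table
#'
#' Checks the balanced design: columns `preparation, group, set_id, fc_hz,
#' alpha`, every subject (`preparation` x `set_id`) measured exactly once
#' per band.
#'
#' @param dataset data.frame in long format
#' @return the dataset, invisibly; errors identify the offending cell
#' @export
validateRMDataset <- function(dataset) {
  need <- c("preparation", "group", "set_id", "fc_hz", "alpha")
  miss <- setdiff(need, names(dataset))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  tab <- table(dataset$set_id, dataset$fc_hz)
  if (any(tab != 1)) {
    bad <- which(tab != 1, arr.ind = TRUE)[1, ]
    stop("unbalanced design: subject '", rownames(tab)[bad[1]],
         "' has ", tab[bad[1], bad[2]], " records at ",
         colnames(tab)[bad[2]], " Hz")
  }
  invisible(dataset)
}

#' Fit the subject-by-treatment repeated-measures model
#'
#' Computes cell means per (between-level, band), subject marginal means
#' (mean over bands), and the pooled within-level covariance of the
#' within-subject measures, for a balanced long-format absorption table.
#'
#' @param dataset long-format data.frame (see [validateRMDataset()])
#' @param between `"preparation"` or `"group"`: the between-subjects factor
#' @return an object of class `RMFit`: list with `wide` (subjects x bands
#'   response matrix), `level` (between factor per subject), `cellMeans`,
#'   `marginalMeans`, `cov` (pooled within-level covariance), `k` bands,
#'   `nSubjects`, `nLevels`, `between`
#' @export
fitRM <- function(dataset, between = c("preparation", "group")) {
  between <- match.arg(between)
  validateRMDataset(dataset)
  bands <- sort(unique(dataset$fc_hz))
  dataset <- dataset[order(dataset$set_id, dataset$fc_hz), ]
  subjects <- unique(dataset$set_id)
  wide <- matrix(dataset$alpha, nrow = length(subjects),
                 ncol = length(bands), byrow = TRUE,
                 dimnames = list(subjects, bands))
  lvl <- dataset[[between]][match(subjects, dataset$set_id)]
  lvl <- factor(lvl)
  if (any(table(lvl) < 2))
    stop("each level of '", between, "' needs at least 2 subjects")
  cellMeans <- apply(wide, 2, function(col) tapply(col, lvl, mean))
  pooled <- Reduce(`+`, lapply(levels(lvl), function(g) {
    w <- wide[lvl == g, , drop = FALSE]
    crossprod(scale(w, center = TRUE, scale = FALSE))
  })) / (length(subjects) - nlevels(lvl))
  structure(list(wide = wide, level = lvl,
                 cellMeans = cellMeans,
                 marginalMeans = rowMeans(wide),
                 cov = pooled,
                 k = length(bands), bands = bands,
                 nSubjects = length(subjects), nLevels = nlevels(lvl),
                 between = between),
            class = "RMFit")
}

#' @export
print.RMFit <- function(x, ...) {
  cat(sprintf("RMFit: %d subjects x %d bands, between factor '%s' (%d levels)\n",
              x$nSubjects, x$k, x$between, x$nLevels))
  invisible(x)
}

#' Between-subjects ANOVA on marginal means
#'
#' Classical one-way ANOVA of the subjects' marginal mean absorption
#' (averaged across the analysed bands) on the between factor, with
#' `df1 = levels - 1` and `df2 = subjects - levels`.
#'
#' @param fit an `RMFit` from [fitRM()]
#' @return data.frame with columns `effect, F, df1, df2, p, epsilon`
#' @export
betweenAnova <- function(fit) {
  stopifnot(inherits(fit, "RMFit"))
  y <- fit$marginalMeans
  g <- fit$level
  gm <- mean(y)
  ssb <- sum(tapply(y, g, length) * (tapply(y, g, mean) - gm)^2)
  ssw <- sum((y - ave(y, g))^2)
  df1 <- nlevels(g) - 1L
  df2 <- length(y) - nlevels(g)
  Fv <- (ssb / df1) / (ssw / df2)
  data.frame(effect = fit$between, F = Fv, df1 = df1, df2 = df2,
             p = stats::pf(Fv, df1, df2, lower.tail = FALSE), epsilon = 1)
}

#' Mauchly sphericity test and Greenhouse-Geisser epsilon
#'
#' Both statistics are computed from the pooled within-level covariance
#' of the within-subject measures projected onto orthonormal contrasts.
#' Mauchly's W is the ratio of the determinant to the sphericity-ideal
#' determinant, with the usual chi-square approximation; the
#' Greenhouse-Geisser epsilon is the eigenvalue-dispersion measure,
#' bounded in `[1/(k-1), 1]`.
#'
#' @param fit an `RMFit` from [fitRM()]
#' @return list with `mauchlyW`, `mauchlyChi2`, `mauchlyDf`, `mauchlyP`,
#'   `ggEpsilon`
#' @export
sphericity <- function(fit) {
  stopifnot(inherits(fit, "RMFit"))
  k <- fit$k
  if (k < 2) stop("need at least 2 within-subject levels")
  C <- stats::contr.helmert(k)
  C <- sweep(C, 2, sqrt(colSums(C^2)), "/")   # orthonormal contrasts
  S <- crossprod(C, fit$cov %*% C)
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0))
    stop("singular within-subject covariance; need more subjects than bands")
  d <- k - 1
  W <- prod(ev) / (mean(ev))^d
  nE <- fit$nSubjects - fit$nLevels          # error df of the covariance
  rho <- 1 - (2 * d^2 + d + 2) / (6 * d * nE)
  chi2 <- -nE * rho * log(W)
  dfM <- d * (d + 1) / 2 - 1
  ## second-order term of the chi-square approximation
  w2 <- (d + 2) * (d - 1) * (d - 2) * (2 * d^3 + 6 * d^2 + 3 * d + 2) /
    (288 * d^2 * nE^2 * rho^2)
  p <- stats::pchisq(chi2, dfM, lower.tail = FALSE) +
    w2 * (stats::pchisq(chi2, dfM + 4, lower.tail = FALSE) -
            stats::pchisq(chi2, dfM, lower.tail = FALSE))
  eps <- sum(ev)^2 / (d * sum(ev^2))
  list(mauchlyW = W, mauchlyChi2 = chi2, mauchlyDf = dfM,
       mauchlyP = p, ggEpsilon = eps)
}

#' Within-subject (repeated-measures) ANOVA
#'
#' Split-plot F tests for the within-subject main effect of frequency and
#' the between-by-frequency interaction, from the balanced-design sums of
#' squares.  Under `correction = "greenhouse_geisser"` the degrees of
#' freedom are multiplied by the Greenhouse-Geisser epsilon and the
#' p-values use the corrected (non-integer) dfs directly in the F
#' distribution; the F statistics themselves are unchanged.
#'
#' @param fit an `RMFit` from [fitRM()]
#' @param correction `"none"` or `"greenhouse_geisser"`
#' @return data.frame with one row per effect (`frequency`,
#'   `between:frequency`): `effect, F, df1, df2, p, epsilon`
#' @export
withinAnova <- function(fit, correction = c("greenhouse_geisser", "none")) {
  correction <- match.arg(correction)
  stopifnot(inherits(fit, "RMFit"))
  Y <- fit$wide
  g <- fit$level
  n <- fit$nSubjects; k <- fit$k; a <- fit$nLevels
  grand <- mean(Y)
  bandMeans <- colMeans(Y)
  subjMeans <- rowMeans(Y)
  cellMeans <- fit$cellMeans                  # a x k
  groupMeans <- rowMeans(cellMeans)
  ssTime <- n * sum((bandMeans - grand)^2)
  ns <- as.numeric(table(g))
  ssInter <- sum(vapply(seq_len(k), function(j) {
    sum(ns * (cellMeans[, j] - groupMeans - bandMeans[j] + grand)^2)
  }, numeric(1)))
  ## within-subject error: band-by-subject-within-group residual
  gi <- as.integer(g)
  resid <- Y - cellMeans[gi, , drop = FALSE] - subjMeans + groupMeans[gi]
  ssErr <- sum(resid^2)
  df1t <- k - 1; df1i <- (a - 1) * (k - 1); dfe <- (n - a) * (k - 1)
  Ft <- (ssTime / df1t) / (ssErr / dfe)
  Fi <- (ssInter / df1i) / (ssErr / dfe)
  eps <- if (correction == "greenhouse_geisser") sphericity(fit)$ggEpsilon else 1
  data.frame(
    effect = c("frequency", paste0(fit$between, ":frequency")),
    F = c(Ft, Fi),
    df1 = c(df1t, df1i), df2 = c(dfe, dfe),
    p = c(stats::pf(Ft, eps * df1t, eps * dfe, lower.tail = FALSE),
          stats::pf(Fi, eps * df1i, eps * dfe, lower.tail = FALSE)),
    epsilon = eps)
}

#' Tukey-Kramer pairwise comparisons
#'
#' Studentized-range pairwise comparisons between the levels of the between
#' factor, on the subjects' marginal means (`atBand = NULL`, the overall
#' comparison) or on the subjects' values at one band (per-frequency
#' comparison, each band using its own one-way error term).  The Kramer
#' form of the standard error accommodates unequal group sizes.
#'
#' @param dataset long-format data.frame (see [validateRMDataset()])
#' @param between `"preparation"` or `"group"`
#' @param atBand `NULL` for the overall comparison, or a band centre
#'   frequency (Hz, matched to `fc_hz`) or a [Band-class]
#' @return data.frame with columns `pair, diff, se, q, p`
#' @export
tukeyKramer <- function(dataset, between = c("preparation", "group"),
                        atBand = NULL) {
  between <- match.arg(between)
  validateRMDataset(dataset)
  if (is.null(atBand)) {
    agg <- stats::aggregate(dataset$alpha,
                            by = list(set_id = dataset$set_id,
                                      lvl = dataset[[between]]),
                            FUN = mean)
    y <- agg$x; g <- factor(agg$lvl)
  } else {
    fc <- if (is(atBand, "Band")) bandCentre(atBand) else as.numeric(atBand)
    sub <- dataset[abs(dataset$fc_hz - fc) < 1e-6 * fc, ]
    if (!nrow(sub)) stop("no records at band ", fc, " Hz")
    y <- sub$alpha; g <- factor(sub[[between]])
  }
  if (nlevels(g) < 2) stop("need at least 2 levels")
  ns <- table(g)
  if (any(ns < 2)) stop("every level needs at least 2 subjects")
  means <- tapply(y, g, mean)
  dfe <- length(y) - nlevels(g)
  mse <- sum((y - ave(y, g))^2) / dfe
  pairs <- utils::combn(levels(g), 2)
  out <- apply(pairs, 2, function(pr) {
    d <- means[pr[2]] - means[pr[1]]
    se <- sqrt(mse / 2 * (1 / ns[pr[1]] + 1 / ns[pr[2]]))
    q <- abs(d) / se
    data.frame(pair = paste(pr[1], pr[2], sep = "-"),
               diff = unname(d), se = unname(se), q = unname(q),
               p = stats::ptukey(q, nlevels(g), dfe, lower.tail = FALSE))
  })
  do.call(rbind, out)
}

#' Per-band Tukey-Kramer significance markers
#'
#' Convenience wrapper running [tukeyKramer()] at every band and attaching
#' the three-tier significance markers used in the figures: one, two or
#' three symbols for `0.01 < p < 0.05`, `0.001 < p < 0.01` and `p < 0.001`.
#'
#' @param dataset long-format data.frame
#' @param between `"preparation"` or `"group"`
#' @return data.frame with columns `fc_hz, pair, diff, q, p, tier`
#' @export
tukeyKramerPerBand <- function(dataset, between = c("preparation", "group")) {
  between <- match.arg(between)
  bands <- sort(unique(dataset$fc_hz))
  out <- lapply(bands, function(fc) {
    tk <- tukeyKramer(dataset, between, atBand = fc)
    tk$fc_hz <- fc
    tk
  })
  res <- do.call(rbind, out)
  res$tier <- cut(res$p, c(-Inf, 0.001, 0.01, 0.05, Inf),
                  labels = c("***", "**", "*", ""))
  res[, c("fc_hz", "pair", "diff", "q", "p", "tier")]
}
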