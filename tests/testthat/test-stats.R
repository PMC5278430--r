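test_that("fitRM produces the design's marginal means and rejects imbalance", {
  ds <- genRMDataset(defaultPreparationMeans(), seed = 2)
  fit <- fitRM(ds, "preparation")
  expect_length(fit$marginalMeans, 54)              # 9 preparations x 6 sets
  expect_equal(fit$k, 8)
  expect_equal(dim(fit$cellMeans), c(9, 8))
  ## zero-noise dataset reproduces the generating means exactly
  ds0 <- genRMDataset(defaultPreparationMeans(), sd = 1e-12,
                      sdSubject = 1e-12, seed = 1)
  fit0 <- fitRM(ds0, "preparation")
  means <- defaultPreparationMeans()
  m1 <- means$mean[means$preparation == "A_io_f"][order(
    means$fc_hz[means$preparation == "A_io_f"])]
  expect_equal(unname(fit0$cellMeans["A_io_f", ]), m1, tolerance = 1e-9)
  ## independent groupby oracle for cell means
  agg <- aggregate(alpha ~ preparation + fc_hz, data = ds, FUN = mean)
  for (p in rownames(fit$cellMeans))
    expect_equal(unname(fit$cellMeans[p, ]),
                 agg$alpha[agg$preparation == p][order(
                   agg$fc_hz[agg$preparation == p])],
                 tolerance = 1e-12)
  ## unbalanced data identified by cell
  bad <- ds[-5, ]
  expect_error(fitRM(bad, "preparation"), "unbalanced")
})

test_that("ANOVA degrees of freedom reproduce the study design structure", {
  ds <- genRMDataset(defaultPreparationMeans(), seed = 3)
  fitP <- fitRM(ds, "preparation")
  bP <- betweenAnova(fitP)
  expect_equal(c(bP$df1, bP$df2), c(8, 45))
  fitG <- fitRM(ds, "group")
  bG <- betweenAnova(fitG)
  expect_equal(c(bG$df1, bG$df2), c(2, 51))
  wP <- withinAnova(fitP, "none")
  expect_equal(wP$df1, c(7, 56))
  expect_equal(wP$df2, c(315, 315))
  wG <- withinAnova(fitG, "none")
  expect_equal(wG$df1, c(7, 14))
  expect_equal(wG$df2, c(357, 357))
})

test_that("split-plot F statistics agree with the aov Error-term oracle", {
  ds <- genRMDataset(defaultPreparationMeans(), seed = 17)
  fit <- fitRM(ds, "preparation")
  w <- withinAnova(fit, "none")
  b <- betweenAnova(fit)
  ds$band <- factor(ds$fc_hz)
  ds$prep <- factor(ds$preparation)
  a <- summary(aov(alpha ~ prep * band + Error(factor(set_id) / band),
                   data = ds))
  withinTab <- a[["Error: factor(set_id):band"]][[1]]
  expect_equal(w$F[1], withinTab["band", "F value"], tolerance = 1e-8)
  expect_equal(w$F[2], withinTab["prep:band", "F value"], tolerance = 1e-8)
  betweenTab <- a[["Error: factor(set_id)"]][[1]]
  ## aov partitions subject SS; its between F equals the marginal-means F
  expect_equal(b$F, betweenTab["prep", "F value"], tolerance = 1e-8)
})

test_that("sphericity statistics match the multivariate-model oracle", {
  skip_if_not_installed("car")
  ds <- genRMDataset(defaultPreparationMeans(), seed = 7)
  fit <- fitRM(ds, "preparation")
  sph <- sphericity(fit)
  wide <- fit$wide
  mlmfit <- lm(wide ~ fit$level)
  av <- car::Anova(mlmfit, idata = data.frame(band = factor(1:8)),
                   idesign = ~band, type = 3)
  s <- suppressWarnings(summary(av, multivariate = FALSE))
  expect_equal(sph$mauchlyW,
               unname(s$sphericity.tests[1, "Test statistic"]),
               tolerance = 1e-8)
  expect_equal(sph$ggEpsilon, unname(s$pval.adjustments[1, "GG eps"]),
               tolerance = 1e-8)
  expect_equal(sph$mauchlyP, unname(s$sphericity.tests[1, "p-value"]),
               tolerance = 1e-4)
  ## GG-corrected p-values agree with the oracle's adjusted p-values
  w <- withinAnova(fit, "greenhouse_geisser")
  expect_equal(w$p[1], unname(s$pval.adjustments[1, "Pr(>F[GG])"]),
               tolerance = 1e-6)
  expect_equal(w$p[2], unname(s$pval.adjustments[2, "Pr(>F[GG])"]),
               tolerance = 1e-6)
})

test_that("epsilon respects its bounds and sphericity holds for CS data", {
  ## compound-symmetric generative covariance: epsilon estimate near 1,
  ## Mauchly rarely significant; epsilon never leaves [1/(k-1), 1]
  epsvals <- c()
  for (s in 1:25) {
    ds <- nullRMData(seed = 400 + s)
    sph <- sphericity(fitRM(ds, "preparation"))
    expect_gte(sph$ggEpsilon, 1 / 7)
    expect_lte(sph$ggEpsilon, 1)
    epsvals <- c(epsvals, sph$ggEpsilon)
  }
  expect_gt(mean(epsvals), 0.8)
})

test_that("Tukey-Kramer agrees with TukeyHSD and the pooled t special case", {
  ds <- genRMDataset(defaultPreparationMeans(), seed = 7)
  tk <- tukeyKramer(ds, "group")
  agg <- aggregate(alpha ~ set_id + group, data = ds, FUN = mean)
  th <- TukeyHSD(aov(alpha ~ group, data = agg))$group
  expect_equal(tk$p, unname(th[, "p adj"]), tolerance = 1e-6)
  expect_equal(tk$diff, unname(th[, "diff"]), tolerance = 1e-10)
  ## two balanced levels: Tukey p equals the two-sided pooled-t p
  ds2 <- ds[ds$group != "chalcosiine", ]
  tk2 <- tukeyKramer(ds2, "group", atBand = 25000)
  sub <- ds2[ds2$fc_hz == 25000, ]
  tt <- t.test(alpha ~ group, data = sub, var.equal = TRUE)
  expect_equal(tk2$p, tt$p.value, tolerance = 1e-6)
  ## two identical levels: q = 0, p = 1
  dup <- ds[ds$group == "chalcosiine", ]
  dup2 <- dup
  dup2$group <- "clone"
  dup2$set_id <- paste0(dup2$set_id, "_c")
  both <- rbind(dup, dup2)
  tkDup <- tukeyKramer(both, "group")
  expect_equal(tkDup$q, 0, tolerance = 1e-12)
  expect_equal(tkDup$p, 1, tolerance = 1e-12)
})

test_that("per-band markers use the three-tier significance convention", {
  ds <- genRMDataset(defaultPreparationMeans(), seed = 9)
  pb <- tukeyKramerPerBand(ds, "group")
  expect_setequal(unique(pb$fc_hz), unique(ds$fc_hz))
  expect_true(all(pb$tier[pb$p < 0.001] == "***"))
  expect_true(all(pb$tier[pb$p > 0.05] == ""))
})
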