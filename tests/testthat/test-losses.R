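# The IPLF: value, analytic gradient, baselines and curve tabulation.

test_that("IPLF values match independent scalar evaluation", {
  # ln(1 + (0.5 + 1/0.5)^2 * ln 2), written out by hand
  expect_equal(iplfValue(1, 0.5), log(1 + 6.25 * log(2)), tolerance = 1e-12)
  # -(0.95 * 0.5)^2 * ln(1 - 0.475)
  expect_equal(iplfValue(0, 0.5), -0.475^2 * log(0.525), tolerance = 1e-12)
  # frozen decimals of the two reference points
  expect_equal(iplfValue(1, 0.5), 1.673758, tolerance = 1e-6)
  expect_equal(iplfValue(0, 0.5), 0.145383, tolerance = 1e-6)
})

test_that("IPLF vanishes at the correct extremes", {
  p <- lossParams(eps = 1e-12)
  # perfect positive prediction: log(1) = 0
  expect_equal(iplfValue(1, 1, p), 0, tolerance = 1e-9)
  # perfect negative prediction: (beta * 0)^2 = 0
  expect_equal(iplfValue(0, 0, p), 0, tolerance = 1e-20)
  expect_equal(iplfGradient(0, 0, p), 0, tolerance = 1e-9)
  # gradient at a perfect positive prediction is -(alpha + 1)^2
  expect_equal(iplfGradient(1, 1, p), -2.25, tolerance = 1e-6)
})

test_that("analytic IPLF gradient matches central finite differences", {
  grid <- seq(0.01, 0.99, by = 0.01)
  for (a in c(0.5, 0.95)) for (b in c(0.5, 0.95)) {
    prm <- lossParams(alpha = a, beta = b)
    for (y in c(0, 1)) {
      num <- vapply(grid, function(p)
        centralDiff(function(q) iplfValue(y, q, prm), p), numeric(1))
      ana <- iplfGradient(y, grid, prm)
      expect_lt(max(abs(ana - num) / pmax(abs(num), 1e-8)), 1e-6)
    }
  }
})

test_that("IPLF is monotone in the prediction and bounded for background", {
  grid <- seq(0.01, 0.99, by = 0.01)
  vPos <- iplfValue(1, grid)
  vNeg <- iplfValue(0, grid)
  expect_true(all(diff(vPos) < 0))   # decreasing for lesion pixels
  expect_true(all(diff(vNeg) > 0))   # increasing for background pixels
  # worst-case background penalty is finite: -beta^2 * log(1 - beta)
  bound <- -0.95^2 * log(1 - 0.95)
  expect_true(all(iplfValue(0, seq(0, 1, by = 0.001)) <= bound + 1e-12))
  # whereas bce and focal diverge as the background prediction approaches 1
  expect_gt(baselineLoss("bce", 0, 1 - 1e-7), bound)
  expect_gt(baselineLoss("focal", 0, 1 - 1e-7), bound)
})

test_that("all loss outputs are finite on [0, 1] under clipping", {
  edge <- c(0, 1e-12, 0.5, 1 - 1e-12, 1)
  for (y in c(0, 1)) {
    expect_true(all(is.finite(iplfValue(y, edge))))
    expect_true(all(is.finite(iplfGradient(y, edge))))
    for (nm in c("bce", "focal"))
      expect_true(is.finite(baselineLoss(nm, y, edge)))
  }
})

test_that("invalid loss inputs raise domain errors", {
  expect_error(iplfValue(0.5, 0.5), "binary")
  expect_error(iplfValue(1, 1.2), "0, 1")
  expect_error(iplfGradient(1, -0.1), "0, 1")
  expect_error(baselineLoss("nope", 1, 0.5), "unknown loss")
  expect_error(baselineLoss("f1", numeric(0), numeric(0)), "non-empty")
  expect_error(lossParams(beta = 1), "beta")
  expect_error(lossParams(alpha = -1), "alpha")
  expect_error(lossParams(eps = 0.7), "eps")
})

test_that("baseline losses reproduce closed-form reference points", {
  expect_equal(baselineLoss("bce", 1, 0.5), log(2), tolerance = 1e-12)
  # focal with gamma = 2 at (y = 1, p = 0.5): 0.25 * ln 2
  expect_equal(baselineLoss("focal", 1, 0.5), 0.25 * log(2),
               tolerance = 1e-12)
  expect_equal(0.25 * log(2), 0.1733, tolerance = 1e-4)
  # soft-Dice complement: perfect overlap scores zero
  y <- c(1, 0, 1, 1, 0)
  expect_equal(baselineLoss("f1", y, y), 0)
  # and a hand-computed partial overlap: 1 - 2*1.0/(2 + 1.5)
  expect_equal(baselineLoss("f1", c(1, 1, 0), c(0.5, 0.5, 0.5)),
               1 - 2 * 1 / (2 + 1.5), tolerance = 1e-12)
})

test_that("baseline gradients match finite differences", {
  grid <- seq(0.05, 0.95, by = 0.05)
  prm <- lossParams()
  for (nm in c("bce", "focal")) for (y in c(0, 1)) {
    num <- vapply(grid, function(p)
      centralDiff(function(q)
        iplfseg:::pointwiseLossValue(nm, y, q, prm), p), numeric(1))
    ana <- iplfseg:::pointwiseLossGradient(nm, y, grid, prm)
    expect_lt(max(abs(ana - num) / pmax(abs(num), 1e-6)), 1e-5)
  }
})

test_that("loss dominance over the probability grid mirrors the design", {
  grid <- seq(0.01, 0.99, length.out = 99)
  cv0 <- tabulateCurves(0, grid, c("iplf", "focal"))
  v0 <- split(cv0, cv0$loss_name)
  # background: IPLF sits below focal in value and |gradient|
  expect_true(all(v0$iplf$value <= v0$focal$value + 1e-12))
  expect_true(all(abs(v0$iplf$gradient) <= abs(v0$focal$gradient) + 1e-12))
  cv1 <- tabulateCurves(1, grid, c("iplf", "focal", "bce"))
  v1 <- split(cv1, cv1$loss_name)
  # lesion: IPLF dominates both baselines
  expect_true(all(v1$iplf$value >= v1$focal$value - 1e-12))
  expect_true(all(v1$iplf$value >= v1$bce$value - 1e-12))
  expect_true(all(abs(v1$iplf$gradient) >= abs(v1$focal$gradient) - 1e-12))
  expect_true(all(abs(v1$iplf$gradient) >= abs(v1$bce$gradient) - 1e-12))
})

test_that("tabulateCurves validates inputs and is CSV-exportable", {
  expect_error(tabulateCurves(1, numeric(0)), "non-empty")
  expect_error(tabulateCurves(1, c(0.5, 0.4)), "increasing")
  expect_error(tabulateCurves(1, c(0.5), "f1"), "batch statistic")
  tab <- tabulateCurves(1, 0.5, "iplf")
  expect_equal(tab$value, log(1 + 6.25 * log(2)), tolerance = 1e-9)
  f <- withr::local_tempfile(fileext = ".csv")
  writeLossCurves(tab, f)
  back <- read.csv(f)
  expect_identical(names(back),
                   c("ground_truth", "probability", "loss_name", "value",
                     "gradient"))
  expect_equal(back$value, tab$value, tolerance = 1e-12)
})

test_that("gradient surface is invariant to the inactive hyperparameter", {
  probs <- seq(0.1, 0.9, by = 0.1)
  # the background branch of the loss contains no alpha
  g0 <- gradientSurface(0, alphaGrid = c(0.5, 0.7, 0.95), betaGrid = 0.9,
                        probGrid = probs)
  byAlpha <- split(g0$gradient, g0$alpha)
  expect_equal(byAlpha[[1]], byAlpha[[2]], tolerance = 1e-12)
  expect_equal(byAlpha[[1]], byAlpha[[3]], tolerance = 1e-12)
  # the lesion branch contains no beta
  g1 <- gradientSurface(1, alphaGrid = 0.6, betaGrid = c(0.5, 0.95),
                        probGrid = probs)
  byBeta <- split(g1$gradient, g1$beta)
  expect_equal(byBeta[[1]], byBeta[[2]], tolerance = 1e-12)
  # each surface point matches the finite-difference oracle
  for (a in c(0.5, 0.95)) {
    g <- gradientSurface(1, a, 0.9, 0.5)$gradient
    num <- centralDiff(function(q)
      iplfValue(1, q, lossParams(alpha = a)), 0.5)
    expect_equal(g, num, tolerance = 1e-6)
  }
  expect_error(gradientSurface(1, numeric(0), 0.5, 0.5), "non-empty")
  expect_error(gradientSurface(1, -1, 0.5, 0.5), "positive")
  expect_error(gradientSurface(1, 0.5, 1.5, 0.5), "beta")
})
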