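mkWells <- function(fireflyFun, constructs = c("ctrl", "utrA"),
                    nBio = 3, nTech = 4) {
  grid <- expand.grid(construct_id = constructs,
                      condition = c("effector", "control_effector"),
                      bio_rep = seq_len(nBio), tech_rep = seq_len(nTech),
                      stringsAsFactors = FALSE)
  grid$renilla <- 1000
  grid$firefly <- fireflyFun(grid)
  grid
}

test_that("the normalization chain cancels completely on identical wells", {
  wells <- mkWells(function(g) 2000)
  act <- normalizeLuciferase(wells, "ctrl")
  expect_equal(act$log2_activity, rep(0, 6))
})

test_that("a doubled effector firefly shows up as +1 log2 on that construct only", {
  wells <- mkWells(function(g)
    ifelse(g$construct_id == "utrA" & g$condition == "effector",
           4000, 2000))
  act <- normalizeLuciferase(wells, "ctrl")
  expect_equal(act$log2_activity[act$construct_id == "utrA"], rep(1, 3))
  expect_equal(act$log2_activity[act$construct_id == "ctrl"], rep(0, 3))
  ## without the effector-condition normalization the ratio chain stops
  ## at the control-construct division; the planted doubling remains
  act2 <- normalizeLuciferase(wells, "ctrl", withEffectorNorm = FALSE)
  expect_equal(act2$log2_activity[act2$construct_id == "utrA"], rep(1, 3))
})

test_that("per-replicate firefly rescaling cancels exactly", {
  set.seed(30)
  wells <- simulateLuciferaseWells(c(ctrl = 0, utrA = -0.5, utrB = 0.3),
                                  seed = 44)
  act <- normalizeLuciferase(wells, "ctrl")
  scaled <- wells
  for (b in unique(wells$bio_rep)) {
    f <- runif(1, 0.5, 3)
    scaled$firefly[scaled$bio_rep == b] <-
      scaled$firefly[scaled$bio_rep == b] * f
  }
  actScaled <- normalizeLuciferase(scaled, "ctrl")
  expect_equal(actScaled$log2_activity, act$log2_activity,
               tolerance = 1e-12)
})

test_that("a planted repression effect is recovered within tolerance", {
  wells <- simulateLuciferaseWells(c(ctrl = 0, utrA = -0.5),
                                  nBioReps = 6, sigma = 0.05, seed = 1)
  act <- normalizeLuciferase(wells, "ctrl")
  est <- mean(act$log2_activity[act$construct_id == "utrA"])
  expect_lt(abs(est - (-0.5)), 0.05)
})

test_that("normalization validates its pairings and inputs", {
  wells <- mkWells(function(g) 2000)
  expect_error(normalizeLuciferase(wells, "nope"), "control construct")
  expect_error(normalizeLuciferase(transform(wells, renilla = 0), "ctrl"),
               "renilla")
  broken <- wells[!(wells$construct_id == "ctrl" & wells$bio_rep == 2), ]
  expect_error(normalizeLuciferase(broken, "ctrl"), "control-construct")
  expect_error(normalizeLuciferase(wells[, -1], "ctrl"), "columns")
})

test_that("one-sample tests BH-adjust across constructs and flag degeneracies", {
  set.seed(9)
  act <- data.frame(
    construct_id = rep(c("a", "b", "c"), each = 5),
    bio_rep = rep(1:5, 3),
    log2_activity = c(rnorm(5, -1, 0.1), rnorm(5, 0, 0.1), rep(0.3, 5)))
  res <- suppressWarnings(oneSampleTests(act))
  expect_equal(res$padj, oracleBH(res$p), tolerance = 1e-12)
  expect_true(all(res$padj >= res$p - 1e-15))
  expect_equal(res$flag[res$construct_id == "c"], "zero_variance")
  expect_equal(res$p[res$construct_id == "c"], 1)

  ## single construct: padj = p
  one <- suppressWarnings(oneSampleTests(act[act$construct_id == "a", ]))
  expect_equal(one$padj, one$p)

  ## n < 2 excluded with a warning
  act2 <- rbind(act, data.frame(construct_id = "d", bio_rep = 1,
                                log2_activity = 5))
  expect_warning(r2 <- suppressWarnings(oneSampleTests(act2)), regexp = NA)
  expect_false("d" %in%
                 suppressWarnings(oneSampleTests(act2))$construct_id)
})

test_that("one-sample tests hold their nominal type-I error under the null", {
  set.seed(77)
  rej <- mean(vapply(1:1000, function(i) {
    t.test(rnorm(6, 0, 0.2))$p.value < 0.05
  }, logical(1)))
  ## the package path uses the same t test; check it agrees on one batch
  act <- data.frame(construct_id = "a", bio_rep = 1:6,
                    log2_activity = rnorm(6, 0, 0.2))
  expect_equal(oneSampleTests(act)$p,
               t.test(act$log2_activity)$p.value)
  expect_lt(abs(rej - 0.05), 3 * sqrt(0.05 * 0.95 / 1000))
})

test_that("defect-proportion chi-square matches the closed form", {
  expect_equal(proportionTest(rbind(c(30, 70), c(30, 70)))$statistic, 0)
  r <- proportionTest(rbind(c(70, 30), c(5, 95)))
  o <- oracleChi2(r$observed)
  expect_equal(r$statistic, o$statistic, tolerance = 1e-10)
  expect_equal(r$p.value, o$p.value, tolerance = 1e-10)
  expect_error(proportionTest(rbind(c(0, 30), c(0, 95))), "degenerate")
  expect_error(proportionTest(matrix(1, 3, 2)), "2x2")
})

test_that("morphometry computes diameter-product areas and paired tests", {
  m <- simulateEyeMeasurements(nLarvae = 8, seed = 2)
  res <- pairedMorphometry(m)
  ## area = minor x major for every record
  expect_equal(res$areas$area, m$minor_diameter * m$major_diameter)
  tests <- res$tests
  expect_setequal(tests$endpoint, c("eye_area", "lens_area",
                                    "lens_eye_ratio", "cornea_thickness"))
  expect_true(all(tests$n == 8))
  ## the planted 30% lens reduction dominates the 10% eye reduction
  lens <- tests[tests$endpoint == "lens_area", ]
  expect_lt(lens$mean_injected, lens$mean_control)
  ratio <- tests[tests$endpoint == "lens_eye_ratio", ]
  expect_lt(ratio$mean_injected, ratio$mean_control)

  ## invariance: larva order and diameter units
  perm <- m[sample(nrow(m)), ]
  expect_equal(pairedMorphometry(perm)$tests$p, tests$p)
  scaled <- m
  scaled$minor_diameter <- scaled$minor_diameter * 1000
  scaled$major_diameter <- scaled$major_diameter * 1000
  s <- pairedMorphometry(scaled)$tests
  expect_equal(s[s$endpoint != "cornea_thickness", ]$p,
               tests[tests$endpoint != "cornea_thickness", ]$p,
               tolerance = 1e-9)
})

test_that("identical sides give the zero-variance path and unpaired larvae drop", {
  m <- simulateEyeMeasurements(nLarvae = 4, lensAreaReduction = 0,
                               eyeAreaReduction = 0, corneaThickening = 1,
                               noise = 0, seed = 3)
  res <- suppressWarnings(pairedMorphometry(m))
  expect_true(all(res$tests$p == 1))
  expect_true(all(res$tests$flag == "zero_variance"))

  m2 <- simulateEyeMeasurements(nLarvae = 4, seed = 4)
  m2 <- m2[!(m2$larva_id == "larva01" & m2$side == "injected"), ]
  suppressWarnings(expect_warning(res2 <- pairedMorphometry(m2),
                                  "unpaired"))
  expect_true(all(res2$tests$n == 3))

  expect_error(pairedMorphometry(transform(m, minor_diameter = 0)),
               "positive")
})

test_that("a planted paired lens reduction is detected across seeds", {
  hits <- vapply(1:20, function(s) {
    m <- simulateEyeMeasurements(nLarvae = 8, lensAreaReduction = 0.3,
                                 seed = s)
    res <- pairedMorphometry(m)
    res$tests$p[res$tests$endpoint == "lens_area"] < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})
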