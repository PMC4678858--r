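test_that("co-migration rules merge T/C on the lesion strand and resolve N=A/N=G", {
  tc <- data.frame(sequence = c("GGCGTGCTAT", "GGCGCGCTAT"),
                   labeled = TRUE, intensity = c(30, 20))
  b <- assignBands(tc, "BbsI-first")
  expect_equal(nrow(b), 1L)
  expect_equal(b$band, "10mer-T/C")
  expect_equal(b$intensity, 50)
  expect_equal(b$species, "GGCGCGCTAT,GGCGTGCTAT")

  ag <- data.frame(sequence = c("AATTATAGCA", "AATTATAGCG"),
                   labeled = TRUE, intensity = c(1, 1))
  b2 <- assignBands(ag, "MluCI-first")
  expect_equal(nrow(b2), 2L)

  # the competitor 13-mer never co-migrates with the 10-mers
  mix <- data.frame(sequence = c("GGCGTGCTAT", "GGCGATAAGCTAT"),
                    labeled = TRUE, intensity = c(1, 1),
                    channel = c("lesion", "competitor"))
  b3 <- assignBands(mix, "BbsI-first")
  expect_equal(nrow(b3), 2L)
  expect_setequal(b3$band, c("10mer-T/C", "13mer"))

  # species without a rule: length fallback, or an error in strict mode
  odd <- data.frame(sequence = "ACGTACGTACG", labeled = TRUE, intensity = 1)
  expect_equal(assignBands(odd, "BbsI-first")$band, "11nt")
  expect_error(assignBands(odd, "BbsI-first", strict = TRUE),
               "no mobility class")
})

test_that("bypass efficiency reproduces the defining formula", {
  run <- assayRun(1, workedRunBands())
  expect_equal(bypassEfficiency(run)$mean, 50)

  # identical lesion and control lanes give 100% at equal ratios
  ident <- assayRun(1, workedRunBands(80, 20, 80, 20))
  expect_equal(bypassEfficiency(ident)$mean, 100)
  ident2 <- assayRun(1, workedRunBands(80, 55, 80, 55))
  expect_equal(bypassEfficiency(ident2)$mean, 100)

  # the mixing-ratio correction divides by r_lesion / r_control
  corr <- assayRun(1, workedRunBands(), rLesion = 2, rControl = 1)
  expect_equal(bypassEfficiency(corr)$mean, 25)

  # invariant under uniform rescaling of a lane
  b <- workedRunBands()
  b$intensity[b$lane == "lesion"] <- b$intensity[b$lane == "lesion"] * 17.3
  expect_equal(bypassEfficiency(assayRun(1, b))$mean, 50)

  # zero competitor signal is an error, not zero
  bad <- workedRunBands(comp = 0)
  expect_error(suppressWarnings(bypassEfficiency(assayRun(1, bad))),
               "undefined")
  expect_error(assayRun(1, workedRunBands()[-2, ]), "no competitor band")
})

test_that("replicate aggregation reports mean and sample SD", {
  runs <- list(assayRun(1, workedRunBands(40, 20, 80, 20)),
               assayRun(2, workedRunBands(48, 20, 80, 20)),
               assayRun(3, workedRunBands(44, 20, 80, 20)))
  be <- bypassEfficiency(runs)
  expect_equal(be$nReplicates, 3L)
  expect_equal(be$mean, mean(c(50, 60, 55)))
  expect_equal(be$sd, sd(c(50, 60, 55)))
})

test_that("mutation spectrum combines the two schemes correctly", {
  mkBands <- function(nA, nG, bA = 0, bG = 0, tTC = NULL) {
    # complementary-strand bands N=A / N=G; lesion-strand bands A / G and
    # the merged T/C band (defaults to the consistent value)
    if (is.null(tTC)) tTC <- nA + nG
    rbind(
      data.frame(lane = "lesion", scheme = "MluCI-first",
                 band = c("10mer-N.A", "10mer-N.G", "13mer"),
                 species = c("AATTATAGCA", "AATTATAGCG", "AATTATAGCTTAT"),
                 channel = c("lesion", "lesion", "competitor"),
                 intensity = c(nA, nG, 100)),
      data.frame(lane = "lesion", scheme = "BbsI-first",
                 band = c("10mer-T/C", "10mer-A", "10mer-G", "13mer"),
                 species = c("GGCGCGCTAT,GGCGTGCTAT", "GGCGAGCTAT",
                             "GGCGGGCTAT", "GGCGATAAGCTAT"),
                 channel = c("lesion", "lesion", "lesion", "competitor"),
                 intensity = c(tTC, bA, bG, 100)),
      data.frame(lane = "control", scheme = c("MluCI-first", "BbsI-first"),
                 band = "13mer",
                 species = c("AATTATAGCTTAT", "GGCGATAAGCTAT"),
                 channel = "competitor", intensity = 100))
  }

  # direct proportion: N=A 20, N=G 80, no A/G products
  ms <- mutationSpectrum(assayRun(1, mkBands(20, 80)))
  expect_equal(unname(ms$spectrum),
               c(0.2, 0.8, 0, 0), tolerance = 1e-9)
  expect_equal(ms$mutationFrequency$mean, 0.8, tolerance = 1e-9)

  # all four products equal
  b4 <- mkBands(25, 25, bA = 25, bG = 25, tTC = 50)
  b4$intensity[b4$band == "10mer-N.A" & b4$lane == "lesion"] <- 25
  run4 <- assayRun(1, rbind(
    b4,
    data.frame(lane = "lesion", scheme = "MluCI-first",
               band = c("10mer-N.T", "10mer-N.C"),
               species = c("AATTATAGCT", "AATTATAGCC"),
               channel = "lesion", intensity = c(25, 25))))
  ms4 <- mutationSpectrum(run4)
  expect_equal(unname(ms4$spectrum), rep(0.25, 4), tolerance = 1e-9)

  # the spectrum always lies on the simplex
  expect_equal(sum(ms4$spectrum), 1, tolerance = 1e-9)
  expect_true(all(ms4$spectrum >= 0))

  # both schemes are required
  oneScheme <- mkBands(20, 80)
  oneScheme <- oneScheme[oneScheme$scheme == "MluCI-first", ]
  expect_error(mutationSpectrum(assayRun(1, oneScheme)), "both digestion")

  # all-zero product bands are an error
  expect_error(mutationSpectrum(assayRun(1, mkBands(0, 0, tTC = 0))),
               "undefined|zero")
})

test_that("spectrum recovery is exact on consistent two-scheme tables", {
  set.seed(11)
  for (i in 1:20) {
    p <- as.vector(stats::rgamma(4, 1))
    p <- p / sum(p)
    gt <- groundTruth("Me", theta = 0.7,
                      spectrum = setNames(p, c("f_T", "f_C", "f_A", "f_G")),
                      rLesion = 2, rControl = 1, n = 1L, sigma = 0,
                      seed = i)
    run <- generateRun(gt)[[1]]
    ms <- mutationSpectrum(run)
    expect_equal(unname(ms$spectrum), p, tolerance = 1e-9)
  }
})

test_that("the T/C split comes from the complementary strand alone", {
  # corrupt the lesion-strand merged band: the split must still follow
  # the complementary-strand N=A / N=G proportions
  gt <- groundTruth("Me", theta = 1,
                    spectrum = c(f_T = 0.3, f_C = 0.7, f_A = 0, f_G = 0),
                    rLesion = 1, rControl = 1, n = 1L, sigma = 0, seed = 1)
  run <- generateRun(gt)[[1]]
  ms <- mutationSpectrum(run)
  expect_equal(unname(ms$spectrum[c("f_T", "f_C")]), c(0.3, 0.7),
               tolerance = 1e-9)
})

test_that("frameshift bands are flagged against the detection threshold", {
  clean <- data.frame(scheme = "BbsI-first",
                      band = c("10mer-T/C", "13mer"),
                      species = c("GGCGTGCTAT", "GGCGATAAGCTAT"),
                      channel = c("lesion", "competitor"),
                      intensity = c(50, 50))
  expect_equal(nrow(detectFrameshifts(clean)), 0L)

  with9 <- rbind(clean, data.frame(
    scheme = "BbsI-first", band = "9mer", species = "GGCGGCTAT",
    channel = "lesion", intensity = 100 / 19))  # 5% of the lane
  fs <- detectFrameshifts(with9)
  expect_equal(fs$shift, -1L)
  expect_equal(fs$fraction, 0.05, tolerance = 1e-9)
  expect_true(fs$detected)

  faint <- rbind(clean, data.frame(
    scheme = "BbsI-first", band = "9mer", species = "GGCGGCTAT",
    channel = "lesion", intensity = 0.1))
  fs2 <- detectFrameshifts(faint, threshold = 0.005)
  expect_false(fs2$detected)
})
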