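test_that("the default acquisition grid has 30 points per degree over 70 degrees", {
  grid <- temperatureGrid(instrumentProfile())
  expect_length(grid, 2101L)
  expect_equal(diff(range(grid)), 70)
  expect_equal(unique(round(diff(grid), 10)), 1 / 30)
})

test_that("a noiseless curve is steepest at the reference midpoint", {
  p <- thermoParams(postPeakDecay = 0)
  cv <- renderCurve(p, profile = quietProfile())
  i <- 2:(length(cv$temperature) - 1)
  d <- (cv$fluorescence[i + 1] - cv$fluorescence[i - 1]) /
       (cv$temperature[i + 1] - cv$temperature[i - 1])
  steepest <- cv$temperature[i][which.max(d)]
  expect_lt(abs(steepest - 55), 1 / 30 + 1e-9)
  # and it agrees with a fine-grid brute-force oracle of the model curve
  expect_lt(abs(steepest - steepestAscentOracle(55, 450)), 1 / 30 + 1e-3)
})

test_that("near-flat baselines give a curve without a transition", {
  p <- thermoParams(nativeBaseline = c(200, -0.5),
                    unfoldedBaseline = c(201, -0.5), postPeakDecay = 0)
  cv <- renderCurve(p, profile = instrumentProfile(), seed = 4, wellKey = "f")
  res <- callTm(cv$temperature, cv$fluorescence)
  expect_identical(res$flag, "no_clear_melt")
  expect_true(is.na(res$tm))
})

test_that("fatty-acid background raises the trace above the protein-only signal", {
  p <- thermoParams()
  plain <- renderCurve(p, profile = quietProfile())
  fat <- renderCurve(p, ligandConc = 40, fattyAcid = TRUE,
                     profile = quietProfile())
  expect_true(all(fat$fluorescence > plain$fluorescence))
  # at standard (100x) concentrations the background rivals the signal
  fat1000 <- renderCurve(p, ligandConc = 1000, fattyAcid = TRUE,
                         profile = quietProfile())
  expect_gt(min(fat1000$fluorescence - plain$fluorescence),
            max(plain$fluorescence))
})

test_that("fixed seed gives bit-identical plates; wells have independent noise", {
  setup <- exampleScreenSetup(2, 1)
  pools <- buildPools(setup$ligandLibrary)
  plan <- planPooledStage(setup$proteins, pools, proteinConc = 10)
  a <- simulatePlate(plan, setup$truths, setup$params,
                     ligandLibrary = setup$ligandLibrary, pools = pools,
                     seed = 11)
  b <- simulatePlate(plan, setup$truths, setup$params,
                     ligandLibrary = setup$ligandLibrary, pools = pools,
                     seed = 11)
  expect_identical(fluorescence(a), fluorescence(b))
  c2 <- simulatePlate(plan, setup$truths, setup$params,
                      ligandLibrary = setup$ligandLibrary, pools = pools,
                      seed = 12)
  expect_false(identical(fluorescence(a), fluorescence(c2)))
  fl <- fluorescence(a)
  expect_false(identical(fl[, 1], fl[, 2]))
})

test_that("empty and invalid plans are handled", {
  empty <- new("ScreenPlan", stage = "pooled",
               wells = data.frame(plate = character(0), well = character(0),
                                  protein = character(0),
                                  contentType = character(0),
                                  content = character(0),
                                  proteinConc = numeric(0),
                                  ligandConc = numeric(0),
                                  solvent = character(0),
                                  replicate = integer(0),
                                  role = character(0)))
  mcs <- simulatePlate(empty, NULL, list(), seed = 1)
  expect_identical(ncol(mcs), 0L)
  setup <- exampleScreenSetup(1, 1)
  pools <- buildPools(setup$ligandLibrary)
  plan <- planPooledStage("UNKNOWN", pools, proteinConc = 10)
  expect_error(simulatePlate(plan, setup$truths, setup$params,
                             ligandLibrary = setup$ligandLibrary,
                             pools = pools, seed = 1),
               "unknown protein")
})

test_that("a protein-only control plan yields one curve melting at tm0", {
  wells <- data.frame(plate = "P1", well = "A1", protein = "SBP001",
                      contentType = "none", content = NA_character_,
                      proteinConc = 10, ligandConc = NA_real_,
                      solvent = "aqueous", replicate = 1L,
                      role = "protein_only", stringsAsFactors = FALSE)
  plan <- new("ScreenPlan", stage = "pooled", wells = wells)
  mcs <- simulatePlate(plan, NULL, list(SBP001 = thermoParams(tm0 = 58)),
                       seed = 2)
  expect_identical(ncol(mcs), 1L)
  gt <- metadata(mcs)$groundTruth
  expect_equal(gt$tmTrue, 58)
})

test_that("pooled wells carry the member ligand with the largest shift", {
  lib <- data.frame(ligandId = c("lg1", "lg2"), name = c("weak", "strong"),
                    category = "amino_acid", solvent = "hepes_ph7.5",
                    stringsAsFactors = FALSE)
  p <- thermoParams()
  truths <- data.frame(protein = "SBP001", ligand = c("lg1", "lg2"),
                       kd = c(kdForShift(p, 3, 1000), kdForShift(p, 8, 1000)),
                       bindsNative = TRUE, stringsAsFactors = FALSE)
  pools <- buildPools(lib)
  expect_identical(unique(pools$poolId), "pool001")
  plan <- planPooledStage("SBP001", pools, proteinConc = 10)
  mcs <- simulatePlate(plan, truths, list(SBP001 = p), quietProfile(),
                       ligandLibrary = lib, pools = pools, seed = 1)
  gt <- metadata(mcs)$groundTruth
  poolRow <- gt[!is.na(gt$content) & gt$content == "pool001", ]
  expect_identical(poolRow$dominantLigand, "lg2")
  expect_equal(poolRow$tmTrue, 63, tolerance = 1e-6)
})

test_that("an instrument midpoint offset moves Tm but cancels in delta-Tm", {
  p <- thermoParams()
  kd <- kdForShift(p, 8, 1000)
  tmOf <- function(cv) callTm(cv$temperature, cv$fluorescence)$tm
  ctrl0 <- tmOf(renderCurve(p, profile = quietProfile()))
  ctrl3 <- tmOf(renderCurve(p, profile = quietProfile(tmOffset = 3)))
  expect_equal(ctrl3 - ctrl0, 3, tolerance = 1 / 30 + 1e-9)
  d0 <- tmOf(renderCurve(p, kd, 1000, quietProfile())) - ctrl0
  d3 <- tmOf(renderCurve(p, kd, 1000, quietProfile(tmOffset = 3))) - ctrl3
  expect_lt(abs(d3 - d0), 1)
})

test_that("duplicate wells at default noise stay within typical assay variability", {
  p <- thermoParams()
  prof <- instrumentProfile()
  spreads <- vapply(1:20, function(s) {
    r1 <- renderCurve(p, profile = prof, seed = s, wellKey = "rep1")
    r2 <- renderCurve(p, profile = prof, seed = s, wellKey = "rep2")
    abs(callTm(r1$temperature, r1$fluorescence)$tm -
        callTm(r2$temperature, r2$fluorescence)$tm)
  }, numeric(1))
  expect_lt(max(spreads), 2)
})
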