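test_that("pool building partitions the library with balanced id-ordered splits", {
  big <- data.frame(
    ligandId = sprintf("aa%02d", 1:25), name = sprintf("aa%02d", 1:25),
    category = "amino_acid", solvent = "hepes_ph7.5",
    stringsAsFactors = FALSE)
  pools <- buildPools(big, maxSize = 10L)
  sizes <- as.integer(table(pools$poolId))
  expect_identical(sort(sizes, decreasing = TRUE), c(9L, 8L, 8L))
  expect_setequal(pools$ligandId, big$ligandId)
  expect_false(anyDuplicated(pools$ligandId) > 0)
  # members stay in ligand-id order within pools
  first <- pools$ligandId[pools$poolId == pools$poolId[1]]
  expect_identical(first, sort(first))
})

test_that("pool construction respects size, solvent and category boundaries", {
  lib <- miniLibrary()
  pools <- buildPools(lib)
  expect_true(all(table(pools$poolId) <= 10))
  byPool <- split(pools, pools$poolId)
  for (g in byPool) {
    expect_identical(length(unique(g$category)), 1L)
    expect_identical(length(unique(g$solvent)), 1L)
  }
  # nonstandard pH stocks are singleton pools
  pur <- pools[pools$ligandId == "pur01", ]
  expect_identical(sum(pools$poolId == pur$poolId), 1L)
  single <- buildPools(lib[1, , drop = FALSE])
  expect_identical(nrow(single), 1L)
  badSolvent <- transform(lib, solvent = "ethanol")
  expect_error(buildPools(badSolvent), "solvent")
})

test_that("concentration planning enforces the 100x and 10x ratios", {
  expect_identical(planConcentrations(10, "amino_acid"), 1000)
  expect_identical(planConcentrations(5, "sugar"), 500)
  expect_identical(planConcentrations(4, "fatty_acid"), 40)
  for (pc in c(4, 5, 10)) {
    expect_identical(planConcentrations(pc, "metal") / pc, 100)
    expect_identical(planConcentrations(pc, "fatty_acid") / pc, 10)
  }
  expect_error(planConcentrations(-1, "metal"), "positive")
  expect_error(planConcentrations(7, "metal"), "one of")
})

test_that("the pooled plan carries per-plate controls and DMSO matching", {
  lib <- miniLibrary()
  pools <- buildPools(lib)
  plan <- planPooledStage("sbpA", pools, proteinConc = 10)
  w <- planWells(plan)
  nPools <- length(unique(pools$poolId))
  expect_identical(sum(w$role == "sample"), nPools)
  expect_identical(sum(w$role == "buffer_only"), 1L)
  expect_identical(sum(w$role == "dye_only"), 1L)
  # aromatic pools stock in DMSO -> DMSO-matched protein-only controls
  expect_true(any(w$role == "protein_only" & w$solvent == "dmso2pct"))
  expect_true(any(w$role == "protein_only" & w$solvent == "aqueous"))
  expect_error(planPooledStage("sbpA", pools[0, ], proteinConc = 10),
               "rejected")
})

test_that("large campaigns span multiple plates, each with its own controls", {
  lib <- exampleLigandLibrary(3)           # 99 ligands
  pools <- buildPools(lib)
  proteins <- sprintf("sbp%02d", 1:12)
  plan <- planPooledStage(proteins, pools, proteinConc = 10)
  w <- planWells(plan)
  expect_identical(sum(w$role == "sample"),
                   12L * length(unique(pools$poolId)))
  expect_gte(length(unique(w$plate)), 4L)
  for (pl in unique(w$plate)) {
    pw <- w[w$plate == pl, ]
    expect_lte(nrow(pw), 96L)
    expect_true(any(pw$role == "buffer_only"))
    expect_true(any(pw$role == "dye_only"))
    expect_true(all(unique(pw$protein[pw$role == "sample"]) %in%
                    pw$protein[pw$role == "protein_only"]))
  }
})

test_that("deconvolution schedules the pool re-test plus each member, hits only", {
  lib <- data.frame(
    ligandId = sprintf("aa%02d", 1:8), name = sprintf("aa%02d", 1:8),
    category = "amino_acid", solvent = "hepes_ph7.5",
    stringsAsFactors = FALSE)
  pools <- buildPools(lib)
  calls <- data.frame(protein = c("sbpA", "sbpB"),
                      content = c("pool001", "pool001"),
                      contentType = "pool",
                      meanDeltaTm = c(8, 1), spread = 0.2, n = 1L,
                      verdict = c("binding", "no_binding"),
                      stringsAsFactors = FALSE)
  plan <- deconvolute(calls, pools, lib)
  w <- planWells(plan)
  expect_identical(sum(w$role == "sample"), 9L)   # pool + 8 singles
  expect_identical(unique(w$protein[w$role == "sample"]), "sbpA")
  # no pooled hits -> nothing scheduled
  expect_null(deconvolute(transform(calls, verdict = "no_binding"),
                          pools, lib))
  bad <- transform(calls, content = "pool999")
  expect_error(deconvolute(bad, pools, lib), "absent")
})

test_that("hits on two pools deconvolute together without duplicated controls", {
  lib <- rbind(
    data.frame(ligandId = c("aa01", "aa02"), name = c("a", "b"),
               category = "amino_acid", solvent = "hepes_ph7.5",
               stringsAsFactors = FALSE),
    data.frame(ligandId = c("mt01", "mt02"), name = c("c", "d"),
               category = "metal", solvent = "hepes_ph7.5",
               stringsAsFactors = FALSE))
  pools <- buildPools(lib)
  expect_identical(length(unique(pools$poolId)), 2L)
  calls <- data.frame(protein = "sbpA", content = unique(pools$poolId),
                      contentType = "pool", meanDeltaTm = 6, spread = 0.1,
                      n = 1L, verdict = "binding", stringsAsFactors = FALSE)
  w <- planWells(deconvolute(calls, pools, lib))
  expect_identical(sum(w$role == "sample"), 6L)   # 2 pools + 4 singles
  for (pl in unique(w$plate)) {
    ctrl <- w[w$plate == pl & w$role == "protein_only" &
              w$solvent == "aqueous", ]
    expect_identical(nrow(ctrl), 2L)              # duplicate, not repeated
  }
})

test_that("the two-step screen recovers exactly the planted binders", {
  prof <- quietProfile()
  setup <- exampleScreenSetup(3, 2)
  res <- runScreen(setup$proteins, setup$ligandLibrary, setup$truths,
                   setup$params, prof, seed = 5)
  got <- res$final[res$final$verdict == "binding", ]
  expect_identical(sort(paste(got$protein, got$content)),
                   sort(paste(setup$truths$protein, setup$truths$ligand)))
})

test_that("the pooled screen equals the exhaustive screen on noise-free data", {
  prof <- quietProfile()
  p1 <- thermoParams(tm0 = 52)
  p2 <- thermoParams(tm0 = 58)
  lib <- miniLibrary()
  truths <- data.frame(
    protein = c("sbpA", "sbpA", "sbpB"),
    ligand = c("amp01", "amp02", "aro02"),
    kd = c(kdForShift(p1, 5, 1000), kdForShift(p1, 9, 1000),
           kdForShift(p2, 4, 1000)),
    bindsNative = TRUE, stringsAsFactors = FALSE)
  params <- list(sbpA = p1, sbpB = p2)
  two <- runScreen(c("sbpA", "sbpB"), lib, truths, params, prof, seed = 7)
  exh <- exhaustiveScreen(c("sbpA", "sbpB"), lib, truths, params, prof,
                          seed = 7)
  key <- function(calls) sort(paste(calls$protein, calls$content)[
    calls$verdict == "binding"])
  expect_identical(key(two$final), key(exh$calls))
  # two binders sharing a pool are both recovered at deconvolution
  expect_setequal(key(two$final),
                  paste(truths$protein, truths$ligand))
})

test_that("no planted binders means no binding calls and no deconvolution", {
  prof <- quietProfile()
  setup <- exampleScreenSetup(2, 1)
  res <- runScreen(setup$proteins, setup$ligandLibrary,
                   setup$truths[0, ], setup$params, prof, seed = 2)
  expect_null(res$deconvPlan)
  expect_identical(nrow(res$final), 0L)
})

test_that("a missing curve fails that well's call without stopping the stage", {
  prof <- quietProfile()
  setup <- exampleScreenSetup(1, 1)
  pools <- buildPools(setup$ligandLibrary)
  plan <- planPooledStage(setup$proteins, pools, proteinConc = 10)
  mcs <- simulatePlate(plan, setup$truths, setup$params, prof,
                       ligandLibrary = setup$ligandLibrary, pools = pools,
                       seed = 1)
  keep <- setdiff(colnames(fluorescence(mcs)), "P1:A1")
  st <- screenStage(mcs[, keep], plan)
  missingRow <- st$tmTable[paste(st$tmTable$plate, st$tmTable$well,
                                 sep = ":") == "P1:A1", ]
  expect_identical(missingRow$flag, "missing_curve")
  expect_gt(nrow(st$calls), 0L)
})
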