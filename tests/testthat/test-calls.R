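test_that("control matching prefers same plate and solvent, then degrades with notes", {
  tmTab <- rbind(
    tmRow("sbpA", NA, 55.0, role = "protein_only", solvent = "aqueous"),
    tmRow("sbpA", NA, 53.5, role = "protein_only", solvent = "dmso2pct"),
    tmRow("sbpA", "lig1", 60.0, solvent = "dmso2pct"))
  got <- matchControl(tmTab[3, ], tmTab)
  expect_equal(got$tm, 53.5)           # the DMSO-matched control wins
  expect_identical(got$solvent, "dmso2pct")
  expect_identical(got$note, "")

  onlyAq <- tmTab[c(1, 3), ]
  got <- matchControl(onlyAq[2, ], onlyAq)
  expect_equal(got$tm, 55.0)
  expect_identical(got$note, "solvent_mismatch")

  offPlate <- rbind(tmRow("sbpA", NA, 54.2, role = "protein_only",
                          plate = "P2", solvent = "dmso2pct"),
                    tmTab[3, ])
  got <- matchControl(offPlate[2, ], offPlate)
  expect_equal(got$tm, 54.2)
  expect_identical(got$note, "off_plate")

  none <- matchControl(tmTab[3, ], tmTab[3, , drop = FALSE])
  expect_true(is.na(none$tm))
  expect_identical(none$note, "no_control")
})

test_that("protein-only replicates are averaged into the control midpoint", {
  tmTab <- rbind(
    tmRow("sbpA", NA, 54.8, role = "protein_only", replicate = 1L),
    tmRow("sbpA", NA, 55.2, role = "protein_only", replicate = 2L),
    tmRow("sbpA", "lig1", 72.0))
  got <- matchControl(tmTab[3, ], tmTab)
  expect_equal(got$tm, 55.0)
})

test_that("delta-Tm is signed and propagates undefined inputs", {
  expect_identical(deltaTm(72.0, 55.0), 17.0)
  expect_identical(deltaTm(55.0, 55.0), 0)
  expect_identical(deltaTm(50.0, 55.0), -5.0)
  expect_identical(deltaTm(60, 55), -deltaTm(55, 60))
  expect_true(is.na(deltaTm(NA_real_, 55)))
  expect_error(deltaTm("a", 55), "numeric")
})

test_that("replicate averaging reports mean, spread and variability flag", {
  got <- averageReplicates(c(16.8, 17.2))
  expect_equal(got$mean, 17.0)
  expect_equal(got$spread, 0.4)
  expect_false(got$highVariability)
  one <- averageReplicates(3.0)
  expect_equal(one$mean, 3.0)
  expect_identical(one$spread, 0)
  wide <- averageReplicates(c(1, 3.5))
  expect_true(wide$highVariability)
  expect_error(averageReplicates(NA_real_), "no replicate")
})

test_that("the binding threshold is inclusive at exactly 2 degrees", {
  expect_identical(classifyBinding(2.0), "binding")
  expect_identical(classifyBinding(1.99), "no_binding")
  expect_identical(classifyBinding(17.0), "binding")
  expect_identical(classifyBinding(-5), "no_binding")
  expect_identical(classifyBinding(NA_real_), "qc_fail")
  # monotone in the shift
  grid <- seq(-3, 6, by = 0.25)
  v <- classifyBinding(grid)
  expect_true(all(diff(v == "binding") >= 0))
})

test_that("bindingCalls averages duplicates against matched controls", {
  tmTab <- rbind(
    tmRow("sbpA", NA, 55.1, role = "protein_only", replicate = 1L),
    tmRow("sbpA", NA, 54.9, role = "protein_only", replicate = 2L),
    tmRow("sbpA", "lig1", 71.9, replicate = 1L),
    tmRow("sbpA", "lig1", 72.1, replicate = 2L),
    tmRow("sbpA", "lig2", 55.4, replicate = 1L),
    tmRow("sbpA", "lig3", 60.0, flag = "no_clear_melt"))
  calls <- bindingCalls(tmTab)
  l1 <- calls[calls$content == "lig1", ]
  expect_equal(l1$meanDeltaTm, 17.0)
  expect_identical(l1$verdict, "binding")
  expect_identical(l1$n, 2L)
  l2 <- calls[calls$content == "lig2", ]
  expect_identical(l2$verdict, "no_binding")
  l3 <- calls[calls$content == "lig3", ]
  expect_identical(l3$verdict, "qc_fail")
})

test_that("top ligands are ranked by shift with deterministic tie-breaking", {
  calls <- data.frame(
    protein = "sbpA",
    content = c("lg1", "lg2", "lg3", "lg4", "lg5", "lg6"),
    contentType = "ligand",
    meanDeltaTm = c(5, 9, 3, 3, 12, 2.5),
    verdict = "binding", stringsAsFactors = FALSE)
  top <- topLigands(calls, 4)
  expect_identical(top$content, c("lg5", "lg2", "lg1", "lg3"))
  two <- topLigands(calls[1:2, ], 4)
  expect_identical(nrow(two), 2L)
  none <- topLigands(transform(calls, verdict = "no_binding"), 4)
  expect_identical(nrow(none), 0L)
})

test_that("funnel summary reproduces hand-counted stage percentages", {
  status <- data.frame(
    target = paste0("t", 1:10),
    cloned = rep(TRUE, 10),
    expressed = c(rep(TRUE, 9), FALSE),
    soluble_small = c(rep(TRUE, 8), FALSE, FALSE),
    soluble_scaled = c(rep(TRUE, 7), rep(FALSE, 3)),
    purified = c(rep(TRUE, 6), rep(FALSE, 4)),
    screened = c(rep(TRUE, 6), rep(FALSE, 4)),
    ligand_assigned = c(rep(TRUE, 3), rep(FALSE, 7)))
  got <- funnelSummary(status)
  expect_equal(got$stages$count,
               c(10L, 9L, 8L, 7L, 6L, 6L, 3L))
  expect_equal(got$stages$percent[2], 90)
  expect_equal(got$assignedOfScreened, 50)
  # row order must not matter
  perm <- funnelSummary(status[sample.int(10), ])
  expect_equal(perm$stages, got$stages)
  # monotonicity violations are rejected by id
  bad <- status
  bad$purified[9] <- TRUE
  expect_error(funnelSummary(bad), "t9")
})

test_that("all-false outcomes give zero counts", {
  status <- data.frame(target = "t1", cloned = FALSE, expressed = FALSE,
                       soluble_small = FALSE, soluble_scaled = FALSE,
                       purified = FALSE, screened = FALSE,
                       ligand_assigned = FALSE)
  got <- funnelSummary(status)
  expect_true(all(got$stages$count == 0L))
  expect_identical(got$assignedOfScreened, 0)
})

test_that("simulated end-to-end calls separate real binders from non-binders", {
  p <- thermoParams()
  prof <- instrumentProfile()
  lib <- miniLibrary()[1:2, ]
  truths <- data.frame(protein = "sbpA", ligand = "amp01",
                       kd = kdForShift(p, 3, 1000), bindsNative = TRUE,
                       stringsAsFactors = FALSE)
  hits <- 0L; misses <- 0L
  for (s in 1:25) {
    res <- exhaustiveScreen("sbpA", lib, truths, list(sbpA = p), prof,
                            seed = s, replicates = 2L)
    v <- setNames(res$calls$verdict, res$calls$content)
    hits <- hits + (v[["amp01"]] == "binding")
    misses <- misses + (v[["amp02"]] == "no_binding")
  }
  expect_identical(hits, 25L)
  expect_identical(misses, 25L)
})
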