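# Shared fixtures and independent oracles. Oracles are written from the
# model definitions directly (plain arithmetic, bisection, brute force) and
# never call the code paths they check.

RGAS <- 8.314

quietProfile <- function(noiseSD = 0, ...)
  instrumentProfile("lightcycler480", noiseSD = noiseSD, ...)

# bisection oracle for the ligand-shifted midpoint (degC)
bisectShiftedTm <- function(tm0C, dhKJ, kd, L, hi = 150, iters = 200) {
  tm0K <- tm0C + 273.15
  g <- function(tC) {
    tK <- tC + 273.15
    dhKJ * 1000 * (1 - tK / tm0K) + RGAS * tK * log1p(L / kd)
  }
  lo <- tm0C
  for (i in seq_len(iters)) {
    mid <- (lo + hi) / 2
    if (g(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# direct evaluation of the two-state unfolded fraction (independent of the
# package's implementation)
directFraction <- function(tC, tm0C, dhKJ) {
  tK <- tC + 273.15
  dG <- dhKJ * 1000 * (1 - tK / (tm0C + 273.15))
  1 / (1 + exp(dG / (RGAS * tK)))
}

# steepest-ascent temperature of the noiseless model curve on a fine grid;
# brute-force oracle for derivative-based calling (no post-peak decay)
steepestAscentOracle <- function(tm0C, dhKJ, natB = c(200, -0.5),
                                 unfB = c(2600, -0.5), lo = 25, hi = 95) {
  tt <- seq(lo, hi, by = 0.001)
  f <- directFraction(tt, tm0C, dhKJ)
  F <- (1 - f) * (natB[1] + natB[2] * tt) + f * (unfB[1] + unfB[2] * tt)
  i <- 2:(length(tt) - 1)
  d <- (F[i + 1] - F[i - 1]) / (tt[i + 1] - tt[i - 1])
  tt[i][which.max(d)]
}

# tiny ligand library for screen-construction tests
miniLibrary <- function() {
  data.frame(
    ligandId = c("amp01", "amp02", "aro01", "aro02", "fat01", "pur01"),
    name = c("alanine", "glycine", "benzoate", "coumarate", "octanoate",
             "guanine"),
    category = c("amino_acid", "amino_acid", "aromatic_acid", "aromatic_acid",
                 "fatty_acid", "purine"),
    solvent = c("hepes_ph7.5", "hepes_ph7.5", "dmso", "dmso", "hepes_ph7.5",
                "hepes_ph10"),
    stockNote = "synthetic",
    stringsAsFactors = FALSE)
}

# Tm table row builder for calls-module tests
tmRow <- function(protein, content, tm, role = "sample", plate = "P1",
                  solvent = "aqueous", replicate = 1L, flag = "ok",
                  contentType = if (role == "sample") "ligand" else "none") {
  data.frame(plate = plate, well = "A1", protein = protein,
             contentType = contentType,
             content = if (role == "sample") content else NA_character_,
             solvent = solvent, replicate = replicate, role = role,
             tm = tm, extremum = -100, amplitude = 50, flag = flag,
             secondary = 0L, stringsAsFactors = FALSE)
}
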