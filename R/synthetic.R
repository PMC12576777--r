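## Synthetic data: energy tables with the statistical structure the ratio
## analysis assumes, synthetic benchmark sets with analytic MAD, and toy
## flexible-molecule polymorph pairs for the end-to-end pipeline.

#' Sample a triangular distribution
#'
#' Inverse-CDF sampling of the triangular density on [a, b] with mode c. The
#' default (0, 0.1, 0.4) is the package's model of the intra-to-inter ratio
#' density: peaked near 10% of |E_inter| and declining linearly to zero at the
#' 40% truncation.
#'
#' @param n number of draws.
#' @param a,c,b lower limit, mode, upper limit.
#' @return numeric vector of draws.
#' @export
rtriangular <- function(n, a = 0, c = 0.1, b = 0.4) {
  if (!(a <= c && c <= b && a < b)) stop("need a <= c <= b with a < b")
  u <- stats::runif(n)
  fc <- (c - a) / (b - a)
  ifelse(u < fc,
         a + sqrt(u * (b - a) * (c - a)),
         b - sqrt((1 - u) * (b - a) * (b - c)))
}

## closed-form CDF of the same triangular density (used by tests and docs)
ptriangular <- function(q, a = 0, c = 0.1, b = 0.4) {
  ifelse(q <= a, 0,
         ifelse(q < c, (q - a)^2 / ((b - a) * (c - a)),
                ifelse(q < b, 1 - (b - q)^2 / ((b - a) * (b - c)), 1)))
}

#' Generate a synthetic partition energy table
#'
#' Draws |E_inter| from a lognormal magnitude distribution, the
#' intra-to-inter ratio r from a truncated triangular density (mode
#' \code{ratioMode}, upper truncation \code{ratioMax}) and the adjustment share
#' of the intramolecular penalty from a Beta distribution (default mean 0.8:
#' conformational distortion is predominantly adjustment-driven). Every emitted
#' row is an internally consistent partition ledger row; the draw is
#' deterministic per seed.
#'
#' @param n number of structures.
#' @param seed RNG seed.
#' @param interMedianKJ median of |E_inter| in kJ/mol.
#' @param interSigmaLog lognormal log-scale spread of |E_inter|.
#' @param ratioMin,ratioMode,ratioMax triangular ratio density parameters.
#' @param adjShape1,adjShape2 Beta parameters of the adjustment share.
#' @param dataset dataset label written to the rows.
#' @return a ledger data.frame (see \code{\link{partitionLedger}}) with an
#'   extra \code{dataset} column; the generating parameters are attached as
#'   attribute \code{spec}.
#' @export
genEnergyTable <- function(n = 1000L, seed = 1L, interMedianKJ = 120,
                           interSigmaLog = 0.5, ratioMin = 0, ratioMode = 0.1,
                           ratioMax = 0.4, adjShape1 = 4, adjShape2 = 1,
                           dataset = "synthetic") {
  if (ratioMax <= ratioMin || ratioMax >= 1 || ratioMin < 0)
    stop("ratio truncation must satisfy 0 <= ratioMin < ratioMax < 1")
  if (adjShape1 <= 0 || adjShape2 <= 0)
    stop("Beta shape parameters must be positive")
  out <- withSeed(seed, {
    absInter <- stats::rlnorm(n, meanlog = log(interMedianKJ),
                              sdlog = interSigmaLog)
    r <- rtriangular(n, ratioMin, ratioMode, ratioMax)
    share <- stats::rbeta(n, adjShape1, adjShape2)
    eInter <- -absInter
    eIntra <- r * absInter
    eAdj <- share * eIntra
    dChg <- eIntra - eAdj
    data.frame(structure_id = sprintf("SYN%05d", seq_len(n)),
               compound_id = sprintf("SYNC%05d", seq_len(n)),
               inter_model = "synthetic-inter", intra_model = "synthetic-intra",
               E_inter = eInter, E_adjustment = eAdj, dE_change_global = dChg,
               E_intra_global = eIntra, E_latt_global = eInter + eIntra,
               dataset = dataset, stringsAsFactors = FALSE)
  })
  attr(out, "spec") <- list(n = n, seed = seed, interMedianKJ = interMedianKJ,
                            interSigmaLog = interSigmaLog, ratioMin = ratioMin,
                            ratioMode = ratioMode, ratioMax = ratioMax,
                            adjShape1 = adjShape1, adjShape2 = adjShape2)
  out
}

#' Generate a synthetic polymorph benchmark set
#'
#' Draws one polymorph pair per compound with computed relative stability
#' dE_latt and an "experimental" enthalpy difference
#' dH_exp = dE_latt + Normal(0, sigma). The expected MAD is the half-normal
#' mean sigma * sqrt(2/pi), which makes the benchmark machinery's calibration
#' analytically checkable.
#'
#' @param nCompounds number of pairs.
#' @param sigma Gaussian noise s.d. in kJ/mol.
#' @param seed RNG seed.
#' @return list with \code{pairs} (pairing table incl. dH_exp and dE_latt) and
#'   \code{ledger} (a consistent partition ledger for both forms of each pair).
#' @export
genBenchmarkSet <- function(nCompounds = 100L, sigma = 1, seed = 1L) {
  if (sigma < 0) stop("'sigma' must be >= 0")
  withSeed(seed, {
    ## dE_latt is kept well away from zero so the dH_exp >= 0 convention
    ## truncates a negligible fraction of the noise
    dE <- stats::runif(nCompounds, 4 * sigma, 4 * sigma + 10)
    dH <- pmax(dE + stats::rnorm(nCompounds, 0, sigma), 0)
    refc <- sprintf("SYNP%04dA", seq_len(nCompounds))
    altc <- sprintf("SYNP%04dB", seq_len(nCompounds))
    eLattRef <- -stats::rlnorm(nCompounds, log(120), 0.4)
    pairs <- data.frame(compound = sprintf("SYNPC%04d", seq_len(nCompounds)),
                        refcode_ref = refc, refcode_alt = altc,
                        dH_exp = dH, dE_latt = dE, subset = "synthetic",
                        source_note = "synthetic benchmark generator",
                        stringsAsFactors = FALSE)
    ledger <- data.frame(
      structure_id = c(refc, altc),
      compound_id = rep(pairs$compound, 2L),
      inter_model = "synthetic-inter", intra_model = "synthetic-intra",
      E_inter = c(eLattRef, eLattRef + dE),
      E_adjustment = 0, dE_change_global = 0, E_intra_global = 0,
      E_latt_global = c(eLattRef, eLattRef + dE),
      stringsAsFactors = FALSE)
    list(pairs = pairs, ledger = ledger)
  })
}

#' Toy flexible-compound specification
#'
#' Parameters of the acyclic chain compound used by the toy polymorph
#' generator: an n-atom united-atom chain with harmonic bonds/angles, a cosine
#' torsion series whose 1-fold term splits the anti and gauche rotamers, and
#' Lennard-Jones sites.
#'
#' @param chainLength number of chain atoms (>= 2; torsions exist from 4).
#' @param torsionPars cosine series shared by all backbone torsions. The
#'   default V1 = 4, V3 = 12 kJ/mol gives a global anti minimum and strained
#'   gauche rotamers about 3 kJ/mol higher.
#' @param bondPars,anglePars harmonic parameters (kb, r0) and (ka, theta0).
#' @param charges,sigma,epsilon nonbonded parameters, recycled over atoms.
#' @param looseness extra cell padding (A) applied to the relaxed-conformer
#'   polymorph so its packing is looser than the strained-conformer one.
#' @param margin required intermolecular-energy separation between the two
#'   forms (kJ/mol).
#' @param seed RNG seed (jitter retries only).
#' @return a specification list for \code{\link{genToyPolymorphPair}}.
#' @export
toyCompoundSpec <- function(chainLength = 4L,
                            torsionPars = data.frame(V = c(4, 12), n = c(1, 3),
                                                     gamma = c(0, 0)),
                            bondPars = c(1000, 1.54),
                            anglePars = c(300, 109.47 * pi / 180),
                            charges = 0, sigma = 3.4, epsilon = 0.5,
                            looseness = 1.0, margin = 0.5, seed = 1L) {
  if (chainLength < 2L) stop("'chainLength' must be >= 2")
  list(chainLength = as.integer(chainLength), torsionPars = torsionPars,
       bondPars = bondPars, anglePars = anglePars, charges = charges,
       sigma = sigma, epsilon = epsilon, looseness = looseness,
       margin = margin, seed = as.integer(seed))
}

#' Build the toy chain molecule of a specification
#'
#' Constructs an all-anti zig-zag chain geometry and the matching
#' \linkS4class{Molecule} with every backbone torsion rotatable.
#'
#' @param spec a \code{\link{toyCompoundSpec}}.
#' @return a \linkS4class{Molecule}.
#' @export
buildChainMolecule <- function(spec = toyCompoundSpec()) {
  n <- spec$chainLength
  r0 <- spec$bondPars[2L]
  th0 <- spec$anglePars[2L]
  coords <- matrix(0, n, 3L)
  if (n >= 2L) coords[2L, ] <- c(r0, 0, 0)
  if (n >= 3L)
    coords[3L, ] <- coords[2L, ] + r0 * c(-cos(th0), sin(th0), 0)
  if (n >= 4L) for (i in 4L:n)
    coords[i, ] <- placeAtom(coords[i - 3L, ], coords[i - 2L, ],
                             coords[i - 1L, ], r0, th0, pi)
  bonds <- cbind(seq_len(n - 1L), 2L:n)
  nt <- max(0L, n - 3L)
  mol <- Molecule(elements = rep("C", n), coords = coords, bonds = bonds,
                  bondPars = spec$bondPars, anglePars = spec$anglePars,
                  torsionPars = spec$torsionPars,
                  charges = spec$charges, sigma = spec$sigma,
                  epsilon = spec$epsilon,
                  rotatable = seq_len(nt),
                  compoundId = sprintf("TOYCHN%d", n))
  mol
}

## NERF atom placement: given A, B, C put D at bond length r from C, valence
## angle theta (B-C-D) and dihedral phi (A-B-C-D).
placeAtom <- function(a, b, c0, r, theta, phi) {
  bc <- (c0 - b) / vnorm(c0 - b)
  nrm <- cross3(b - a, bc)
  nrm <- nrm / vnorm(nrm)
  m <- cross3(nrm, bc)
  d2 <- c(-r * cos(theta), r * sin(theta) * cos(phi), r * sin(theta) * sin(phi))
  c0 + d2[1L] * bc + d2[2L] * m + d2[3L] * nrm
}

#' Generate a toy conformational-polymorph pair
#'
#' Builds two crystal forms of one flexible chain compound: form A packs the
#' near-global-minimum (anti) conformer in a deliberately loose cell; form B
#' packs a strained (gauche) conformer in the tightest stable cell found by a
#' padding scan. By construction, after the partition pipeline form B has the
#' larger intramolecular penalty AND the more negative intermolecular energy -
#' the strained conformer buys better packing.
#'
#' @param spec a \code{\link{toyCompoundSpec}}.
#' @param cfg a \linkS4class{ForceFieldConfig}; a shorter cutoff than the
#'   global default keeps the toy lattice sums small.
#' @return list with \code{formA}, \code{formB}
#'   (\linkS4class{CrystalStructure}), \code{molecule}, and the scan record
#'   \code{details}.
#' @export
genToyPolymorphPair <- function(spec = toyCompoundSpec(),
                                cfg = ForceFieldConfig(cutoff = 8)) {
  mol <- buildChainMolecule(spec)
  optAnti <- optimizeMolecule(mol, coordinates(mol), cfg)
  nrot <- nRotatableBonds(mol)
  if (nrot > 0L) {
    gauche0 <- setTorsionValues(mol, optAnti$coords,
                                c(60, rep(180, nrot - 1L)))
    optGauche <- optimizeMolecule(mol, gauche0, cfg)
  } else {
    optGauche <- optAnti
  }
  packOne <- function(coords, pad) {
    ctr <- colMeans(coords)
    xc <- sweep(coords, 2L, ctr)
    ext <- apply(xc, 2L, function(v) diff(range(v)))
    CrystalStructure(diag(ext + pad), mol, list(xc),
                     structureId = "TMP", compoundId = compoundId(mol))
  }
  eInterAt <- function(coords, pad) {
    xt <- packOne(coords, pad)
    crystalEnergyPerMolecule(xt, cfg) - moleculeEnergy(mol, coordinates(xt, molecule = 1L), cfg)
  }
  scanPads <- seq(2.8, 9, by = 0.1)
  jitters <- withSeed(spec$seed, stats::runif(6L, -0.05, 0.05))
  buildForms <- function(coordsA, coordsB) {
    eB <- vapply(scanPads, function(p) eInterAt(coordsB, p), numeric(1L))
    eA <- vapply(scanPads, function(p) eInterAt(coordsA, p), numeric(1L))
    if (!any(is.finite(eB)) || min(eB, na.rm = TRUE) >= 0)
      stop("packing generator failure: no bound cell found for the strained form")
    padB <- scanPads[which.min(eB)]
    eInterB <- min(eB)
    padA <- scanPads[which.min(eA)] + spec$looseness
    ## loosen form A until its packing is less stabilizing than form B's
    repeat {
      eInterA <- eInterAt(coordsA, padA)
      if (is.finite(eInterA) && eInterA < 0 &&
          eInterA > eInterB + spec$margin) break
      padA <- padA + 0.25
      if (padA > 25)
        stop("packing generator failure: could not separate the two forms")
    }
    list(padA = padA, padB = padB, eInterA = eInterA, eInterB = eInterB)
  }
  res <- tryCatch(buildForms(optAnti$coords, optGauche$coords),
                  error = function(e) e)
  if (inherits(res, "error")) {
    ## retry with a small deterministic jitter before giving up
    jA <- optAnti$coords + matrix(jitters[1:3], nAtoms(mol), 3L, byrow = TRUE)
    jB <- optGauche$coords + matrix(jitters[4:6], nAtoms(mol), 3L, byrow = TRUE)
    res <- buildForms(jA, jB)
    optAnti$coords <- jA
    optGauche$coords <- jB
  }
  cid <- compoundId(mol)
  formA <- packOne(optAnti$coords, res$padA)
  formA@structureId <- paste0(cid, "-A")
  formB <- packOne(optGauche$coords, res$padB)
  formB@structureId <- paste0(cid, "-B")
  list(formA = formA, formB = formB, molecule = mol,
       details = list(padA = res$padA, padB = res$padB,
                      eInterA = res$eInterA, eInterB = res$eInterB,
                      gasAnti = optAnti$energy, gasGauche = optGauche$energy))
}
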