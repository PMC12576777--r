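## Toy classical force field: bonded intramolecular terms plus periodic
## intermolecular Lennard-Jones/Coulomb with a shifted-potential cutoff.
## Energies are kJ/mol, lengths Angstrom, charges e.

torsionSeriesEnergy <- function(pars, phi) {
  ## phi in radians; pars: data.frame(V, n, gamma)
  sum(pars$V / 2 * (1 + cos(pars$n * phi - pars$gamma)))
}

#' Intramolecular (gas-phase) energy of a molecule
#'
#' Bonded terms (harmonic bonds and angles, cosine torsion series) plus
#' intramolecular nonbonded Lennard-Jones and Coulomb over non-excluded pairs
#' (1-2 and 1-3 excluded, 1-4 scaled). Smooth and deterministic in the
#' coordinates; no cutoff is applied intramolecularly.
#'
#' @param mol a \linkS4class{Molecule}.
#' @param coords N x 3 coordinates (defaults to the stored geometry).
#' @param cfg a \linkS4class{ForceFieldConfig} (only the Coulomb constant is
#'   used here).
#' @return energy in kJ/mol.
#' @export
moleculeEnergy <- function(mol, coords = coordinates(mol),
                           cfg = ForceFieldConfig()) {
  coords <- as.matrix(coords)
  if (!all(dim(coords) == c(nAtoms(mol), 3L)))
    stop(sprintf("coordinate matrix must be %d x 3", nAtoms(mol)))
  assertFinite(coords, "coordinates")
  e <- 0
  b <- mol@bonds
  if (nrow(b)) {
    d <- bondLengths(mol, coords)
    e <- e + sum(mol@bondPars[, 1L] * (d - mol@bondPars[, 2L])^2)
  }
  a <- mol@angles
  for (i in seq_len(nrow(a))) {
    th <- angleValue(coords[a[i, 1L], ], coords[a[i, 2L], ], coords[a[i, 3L], ])
    e <- e + mol@anglePars[i, 1L] * (th - mol@anglePars[i, 2L])^2
  }
  tq <- mol@torsions
  for (i in seq_len(nrow(tq))) {
    phi <- dihedralValue(coords[tq[i, 1L], ], coords[tq[i, 2L], ],
                         coords[tq[i, 3L], ], coords[tq[i, 4L], ])
    e <- e + torsionSeriesEnergy(mol@torsionPars[[i]], phi)
  }
  e + intraNonbondedEnergy(mol, coords, cfg)
}

intraNonbondedEnergy <- function(mol, coords, cfg) {
  n <- nAtoms(mol)
  if (n < 2L) return(0)
  S <- mol@pairScale
  idx <- which(upper.tri(S) & S > 0, arr.ind = TRUE)
  if (!nrow(idx)) return(0)
  dx <- coords[idx[, 1L], , drop = FALSE] - coords[idx[, 2L], , drop = FALSE]
  r <- sqrt(rowSums(dx^2))
  sig <- (mol@sigma[idx[, 1L]] + mol@sigma[idx[, 2L]]) / 2
  eps <- sqrt(mol@epsilon[idx[, 1L]] * mol@epsilon[idx[, 2L]])
  s6 <- (sig / r)^6
  elj <- 4 * eps * (s6^2 - s6)
  ec <- cfg@coulombK * mol@charges[idx[, 1L]] * mol@charges[idx[, 2L]] / r
  sum(S[idx] * (elj + ec))
}

## Analytic + per-term finite-difference gradient of moleculeEnergy.
## Bonds and nonbonded pairs are analytic (radial); angle and torsion terms use
## central differences restricted to the atoms in the term, which is cheap and
## accurate to O(h^2).
moleculeGradient <- function(mol, coords = coordinates(mol),
                             cfg = ForceFieldConfig(), h = 1e-5) {
  n <- nAtoms(mol)
  g <- matrix(0, n, 3L)
  b <- mol@bonds
  if (nrow(b)) {
    dx <- coords[b[, 1L], , drop = FALSE] - coords[b[, 2L], , drop = FALSE]
    d <- sqrt(rowSums(dx^2))
    f <- 2 * mol@bondPars[, 1L] * (d - mol@bondPars[, 2L]) / d
    for (k in seq_len(nrow(b))) {
      gi <- f[k] * dx[k, ]
      g[b[k, 1L], ] <- g[b[k, 1L], ] + gi
      g[b[k, 2L], ] <- g[b[k, 2L], ] - gi
    }
  }
  S <- mol@pairScale
  idx <- which(upper.tri(S) & S > 0, arr.ind = TRUE)
  if (nrow(idx)) {
    dx <- coords[idx[, 1L], , drop = FALSE] - coords[idx[, 2L], , drop = FALSE]
    r2 <- rowSums(dx^2)
    r <- sqrt(r2)
    sig <- (mol@sigma[idx[, 1L]] + mol@sigma[idx[, 2L]]) / 2
    eps <- sqrt(mol@epsilon[idx[, 1L]] * mol@epsilon[idx[, 2L]])
    s6 <- (sig^2 / r2)^3
    dljdr <- 24 * eps * (s6 - 2 * s6^2) / r
    qq <- cfg@coulombK * mol@charges[idx[, 1L]] * mol@charges[idx[, 2L]]
    dcdr <- -qq / r2
    dphidr <- S[idx] * (dljdr + dcdr)
    for (k in seq_len(nrow(idx))) {
      gi <- dphidr[k] * dx[k, ] / r[k]
      g[idx[k, 1L], ] <- g[idx[k, 1L], ] + gi
      g[idx[k, 2L], ] <- g[idx[k, 2L], ] - gi
    }
  }
  a <- mol@angles
  for (i in seq_len(nrow(a))) {
    ka <- mol@anglePars[i, 1L]; th0 <- mol@anglePars[i, 2L]
    at <- a[i, ]
    for (p in seq_len(3L)) for (d0 in seq_len(3L)) {
      xp <- coords; xp[at[p], d0] <- xp[at[p], d0] + h
      xm <- coords; xm[at[p], d0] <- xm[at[p], d0] - h
      ep <- ka * (angleValue(xp[at[1L], ], xp[at[2L], ], xp[at[3L], ]) - th0)^2
      em <- ka * (angleValue(xm[at[1L], ], xm[at[2L], ], xm[at[3L], ]) - th0)^2
      g[at[p], d0] <- g[at[p], d0] + (ep - em) / (2 * h)
    }
  }
  tq <- mol@torsions
  for (i in seq_len(nrow(tq))) {
    pars <- mol@torsionPars[[i]]
    if (all(pars$V == 0)) next
    at <- tq[i, ]
    for (p in seq_len(4L)) for (d0 in seq_len(3L)) {
      xp <- coords; xp[at[p], d0] <- xp[at[p], d0] + h
      xm <- coords; xm[at[p], d0] <- xm[at[p], d0] - h
      ep <- torsionSeriesEnergy(pars, dihedralValue(xp[at[1L], ], xp[at[2L], ],
                                                    xp[at[3L], ], xp[at[4L], ]))
      em <- torsionSeriesEnergy(pars, dihedralValue(xm[at[1L], ], xm[at[2L], ],
                                                    xm[at[3L], ], xm[at[4L], ]))
      g[at[p], d0] <- g[at[p], d0] + (ep - em) / (2 * h)
    }
  }
  g
}

## Perpendicular heights of the cell (distance between opposite faces).
cellHeights <- function(L) {
  v <- abs(det(L))
  areas <- c(vnorm(cross3(L[2L, ], L[3L, ])),
             vnorm(cross3(L[3L, ], L[1L, ])),
             vnorm(cross3(L[1L, ], L[2L, ])))
  v / areas
}

## Enumerate lattice translation vectors t = n %*% L potentially contributing
## pairs within the cutoff, given the maximal intra-cell atom spread.
imageVectors <- function(L, cutoff, spread) {
  h <- cellHeights(L)
  kmax <- pmax(0L, ceiling((cutoff + spread) / h))
  grid <- as.matrix(expand.grid(n1 = -kmax[1L]:kmax[1L],
                                n2 = -kmax[2L]:kmax[2L],
                                n3 = -kmax[3L]:kmax[3L]))
  list(trans = grid %*% L, zero = which(rowSums(abs(grid)) == 0L))
}

## Flatten a crystal into atom arrays shared by the energy and gradient code.
crystalAtoms <- function(xtal) {
  mol <- xtal@molecule
  n <- nAtoms(mol)
  Z <- zMolecules(xtal)
  X <- do.call(rbind, xtal@coordsList)
  list(X = X, molIdx = rep(seq_len(Z), each = n),
       sigma = rep(mol@sigma, Z), epsilon = rep(mol@epsilon, Z),
       charges = rep(mol@charges, Z), n = n, Z = Z)
}

#' Crystal energy per molecule
#'
#' Intramolecular energy of every molecule in the cell plus the periodic
#' intermolecular Lennard-Jones/Coulomb lattice sum over all periodic images
#' within the cutoff (shifted potentials, so the energy is continuous at the
#' cutoff), normalized by the number of molecules Z in the cell. Interactions
#' between a molecule and its own periodic images count as intermolecular; the
#' intramolecular exclusions apply only within the central (untranslated)
#' molecule.
#'
#' @param xtal a \linkS4class{CrystalStructure}.
#' @param cfg a \linkS4class{ForceFieldConfig}.
#' @return energy per molecule in kJ/mol.
#' @export
crystalEnergyPerMolecule <- function(xtal, cfg = ForceFieldConfig()) {
  at <- crystalAtoms(xtal)
  mol <- xtal@molecule
  eIntra <- sum(vapply(xtal@coordsList, function(xm)
    moleculeEnergy(mol, xm, cfg), numeric(1L)))
  (eIntra + interLatticeSum(at, xtal@lattice, cfg)$energy) / at$Z
}

## Core periodic pair sum. Returns energy and (optionally) per-atom gradient.
interLatticeSum <- function(at, L, cfg, gradient = FALSE) {
  X <- at$X
  Na <- nrow(X)
  rc <- cfg@cutoff
  rc2 <- rc^2
  ctr <- colMeans(X)
  spread <- 2 * sqrt(max(rowSums(sweep(X, 2L, ctr)^2)))
  iv <- imageVectors(L, rc, spread)
  SIG <- outer(at$sigma, at$sigma, `+`) / 2
  EPS <- sqrt(outer(at$epsilon, at$epsilon))
  QQ <- cfg@coulombK * outer(at$charges, at$charges)
  sc6 <- (SIG^2 / rc2)^3
  LJSHIFT <- 4 * EPS * (sc6^2 - sc6)
  CSHIFT <- QQ / rc
  sameMol <- outer(at$molIdx, at$molIdx, `==`)
  dx1 <- outer(X[, 1L], X[, 1L], `-`)
  dx2 <- outer(X[, 2L], X[, 2L], `-`)
  dx3 <- outer(X[, 3L], X[, 3L], `-`)
  e <- 0
  g <- if (gradient) matrix(0, Na, 3L) else NULL
  for (im in seq_len(nrow(iv$trans))) {
    t0 <- iv$trans[im, ]
    r2 <- (dx1 + t0[1L])^2 + (dx2 + t0[2L])^2 + (dx3 + t0[3L])^2
    mask <- r2 < rc2
    if (im == iv$zero) mask <- mask & !sameMol
    if (!any(mask)) next
    r2m <- r2[mask]
    s6 <- (SIG[mask]^2 / r2m)^3
    elj <- 4 * EPS[mask] * (s6^2 - s6) - LJSHIFT[mask]
    rm <- sqrt(r2m)
    ec <- QQ[mask] * (1 / rm) - CSHIFT[mask]
    e <- e + sum(elj + ec)
    if (gradient) {
      dphidr <- 24 * EPS[mask] * (s6 - 2 * s6^2) / rm - QQ[mask] / r2m
      w <- dphidr / rm
      gx <- matrix(0, Na, Na); gy <- gx; gz <- gx
      gx[mask] <- w * (dx1[mask] + t0[1L])
      gy[mask] <- w * (dx2[mask] + t0[2L])
      gz[mask] <- w * (dx3[mask] + t0[3L])
      ## ordered pairs appear twice across images (i,j,t)/(j,i,-t); row sums
      ## give the full derivative for atom i without the 1/2 factor
      g[, 1L] <- g[, 1L] + rowSums(gx)
      g[, 2L] <- g[, 2L] + rowSums(gy)
      g[, 3L] <- g[, 3L] + rowSums(gz)
    }
  }
  list(energy = e / 2, gradient = g)
}

## Gradient of Z * crystalEnergyPerMolecule w.r.t. all atomic coordinates.
crystalGradient <- function(xtal, cfg = ForceFieldConfig()) {
  at <- crystalAtoms(xtal)
  mol <- xtal@molecule
  gIntra <- do.call(rbind, lapply(xtal@coordsList, function(xm)
    moleculeGradient(mol, xm, cfg)))
  gInter <- interLatticeSum(at, xtal@lattice, cfg, gradient = TRUE)$gradient
  gIntra + gInter
}
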