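## Internal geometry: distances, valence angles, dihedrals, torsion driving,
## periodic re-wrapping.

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

vnorm <- function(v) sqrt(sum(v * v))

bondLengths <- function(mol, coords) {
  b <- mol@bonds
  sqrt(rowSums((coords[b[, 1L], , drop = FALSE] -
                  coords[b[, 2L], , drop = FALSE])^2))
}

## valence angle i-j-k in radians
angleValue <- function(a, b, c) {
  u <- a - b; v <- c - b
  cosv <- sum(u * v) / (vnorm(u) * vnorm(v))
  acos(pmin(1, pmax(-1, cosv)))
}

## signed dihedral i-j-k-l in radians, IUPAC convention
dihedralValue <- function(a, b, c, d) {
  b1 <- b - a; b2 <- c - b; b3 <- d - c
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  atan2(vnorm(b2) * sum(b1 * n2), sum(n1 * n2))
}

#' Measure rotatable-torsion angles
#'
#' @param mol a \linkS4class{Molecule}.
#' @param coords optional N x 3 coordinates (defaults to the stored geometry).
#' @param which torsion row indices (default: the rotatable subset).
#' @return torsion angles in degrees, wrapped to [0, 360).
#' @export
torsionValues <- function(mol, coords = coordinates(mol), which = mol@rotatable) {
  vapply(which, function(t) {
    q <- mol@torsions[t, ]
    wrapDeg(dihedralValue(coords[q[1L], ], coords[q[2L], ],
                          coords[q[3L], ], coords[q[4L], ]) * 180 / pi)
  }, numeric(1L))
}

rotationMatrix <- function(axis, theta) {
  u <- axis / vnorm(axis)
  ct <- cos(theta); st <- sin(theta)
  ux <- u[1L]; uy <- u[2L]; uz <- u[3L]
  matrix(c(
    ct + ux^2 * (1 - ct), ux * uy * (1 - ct) - uz * st, ux * uz * (1 - ct) + uy * st,
    uy * ux * (1 - ct) + uz * st, ct + uy^2 * (1 - ct), uy * uz * (1 - ct) - ux * st,
    uz * ux * (1 - ct) - uy * st, uz * uy * (1 - ct) + ux * st, ct + uz^2 * (1 - ct)),
    nrow = 3L, byrow = TRUE)
}

## Atoms on the 'l side' of the central bond j-k of a torsion (reachable from k
## without crossing the j-k bond). These move when the torsion is driven.
movingSide <- function(mol, j, k) {
  n <- nAtoms(mol)
  adj <- vector("list", n)
  for (b in seq_len(nrow(mol@bonds))) {
    p <- mol@bonds[b, 1L]; q <- mol@bonds[b, 2L]
    if ((p == j && q == k) || (p == k && q == j)) next
    adj[[p]] <- c(adj[[p]], q); adj[[q]] <- c(adj[[q]], p)
  }
  seen <- rep(FALSE, n)
  seen[k] <- TRUE
  frontier <- k
  while (length(frontier)) {
    nxt <- setdiff(unique(unlist(adj[frontier])), which(seen))
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  setdiff(which(seen), k)
}

#' Drive rotatable torsions to target angles
#'
#' Rotates the distal side of each rotatable bond rigidly about the bond axis
#' so the measured dihedral equals the target. Torsions are applied in order;
#' for acyclic molecules the operations commute.
#'
#' @param mol a \linkS4class{Molecule}.
#' @param coords starting N x 3 coordinates.
#' @param values target angles in degrees, one per rotatable torsion.
#' @return the modified coordinate matrix.
#' @export
setTorsionValues <- function(mol, coords, values) {
  rot <- mol@rotatable
  if (length(values) != length(rot))
    stop("need one target angle per rotatable torsion")
  for (s in seq_along(rot)) {
    q <- mol@torsions[rot[s], ]
    cur <- dihedralValue(coords[q[1L], ], coords[q[2L], ],
                         coords[q[3L], ], coords[q[4L], ]) * 180 / pi
    delta <- (values[s] - cur) * pi / 180
    axis <- coords[q[3L], ] - coords[q[2L], ]
    R <- rotationMatrix(axis, delta)
    mv <- movingSide(mol, q[2L], q[3L])
    pivot <- coords[q[3L], ]
    coords[mv, ] <- sweep(sweep(coords[mv, , drop = FALSE], 2L, pivot) %*% t(R),
                          2L, pivot, `+`)
    ## the rotation sign depends on the dihedral convention; correct if needed
    new <- dihedralValue(coords[q[1L], ], coords[q[2L], ],
                         coords[q[3L], ], coords[q[4L], ]) * 180 / pi
    if (circDiffDeg(new, values[s]) > 1e-6) {
      R2 <- rotationMatrix(axis, -2 * delta)
      coords[mv, ] <- sweep(sweep(coords[mv, , drop = FALSE], 2L, pivot) %*% t(R2),
                            2L, pivot, `+`)
    }
  }
  coords
}

#' Re-wrap a molecule split across periodic boundaries
#'
#' Walks the bond graph from atom 1 and shifts every atom by the lattice
#' translation that minimizes its distance to the bonded parent, recovering a
#' whole molecular geometry from coordinates wrapped into the cell.
#'
#' @param coords N x 3 coordinates (possibly wrapped).
#' @param mol the \linkS4class{Molecule} topology.
#' @param lattice 3 x 3 lattice vector matrix (rows).
#' @return re-wrapped N x 3 coordinates.
#' @export
reWrapMolecule <- function(coords, mol, lattice) {
  n <- nAtoms(mol)
  if (n == 1L) return(coords)
  Linv <- solve(lattice)
  adj <- vector("list", n)
  for (b in seq_len(nrow(mol@bonds))) {
    i <- mol@bonds[b, 1L]; j <- mol@bonds[b, 2L]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  seen <- rep(FALSE, n)
  seen[1L] <- TRUE
  frontier <- 1L
  while (length(frontier)) {
    nxt <- integer()
    for (p in frontier) for (c0 in adj[[p]]) {
      if (seen[c0]) next
      dfrac <- (coords[c0, ] - coords[p, ]) %*% Linv
      shift <- -round(dfrac)
      coords[c0, ] <- coords[c0, ] + as.numeric(shift %*% lattice)
      seen[c0] <- TRUE
      nxt <- c(nxt, c0)
    }
    frontier <- nxt
  }
  coords
}
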