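## Local geometry optimization: BFGS with Armijo backtracking. Hand-rolled so
## the optimizer can guarantee a monotone energy trace and terminate on the
## maximum force component, both of which the partition contracts rely on.

bfgsMinimize <- function(x0, fn, gr, forceTol = 1e-3, maxIter = 500L) {
  x <- as.numeric(x0)
  d <- length(x)
  f <- fn(x)
  g <- gr(x)
  H <- diag(d)
  trace <- f
  converged <- max(abs(g)) <= forceTol
  iter <- 0L
  while (!converged && iter < maxIter) {
    iter <- iter + 1L
    p <- -as.numeric(H %*% g)
    if (sum(p * g) >= 0) {            # not a descent direction: reset
      H <- diag(d)
      p <- -g
    }
    ## Armijo backtracking line search; cap the first trial displacement so a
    ## stiff-bond gradient cannot fling atoms apart
    alpha <- min(1, 0.5 / max(1e-12, max(abs(p))))
    fnew <- Inf
    ok <- FALSE
    for (ls in seq_len(60L)) {
      xnew <- x + alpha * p
      fnew <- fn(xnew)
      if (is.finite(fnew) && fnew <= f + 1e-4 * alpha * sum(g * p)) {
        ok <- TRUE
        break
      }
      alpha <- alpha / 2
    }
    if (!ok) {                         # stall: try plain steepest descent once
      H <- diag(d)
      p <- -g
      alpha <- 1e-4 / max(1, max(abs(g)))
      xnew <- x + alpha * p
      fnew <- fn(xnew)
      if (!is.finite(fnew) || fnew > f) break
    }
    gnew <- gr(xnew)
    s <- xnew - x
    y <- gnew - g
    sy <- sum(s * y)
    if (sy > 1e-12) {                  # standard inverse-Hessian BFGS update
      rho <- 1 / sy
      Hy <- H %*% y
      yHy <- sum(y * Hy)
      H <- H - rho * (Hy %*% t(s) + s %*% t(Hy)) +
        rho * (1 + rho * yHy) * (s %*% t(s))
    }
    x <- xnew; f <- fnew; g <- gnew
    trace <- c(trace, f)
    converged <- max(abs(g)) <= forceTol
  }
  list(par = x, value = f, grad = g, maxForce = max(abs(g)),
       trace = trace, converged = converged, iterations = iter)
}

#' Optimize a molecular geometry to the nearest local minimum
#'
#' Gas-phase local geometry optimization (no basin hopping, no torsion jumps):
#' descends from the starting geometry until the maximum force component is
#' below \code{cfg@forceTol}. The energy trace is non-increasing by
#' construction of the line search. Non-convergence within
#' \code{cfg@maxIter} iterations is flagged, never silent.
#'
#' @param mol a \linkS4class{Molecule}.
#' @param coords starting N x 3 coordinates (default: stored geometry).
#' @param cfg a \linkS4class{ForceFieldConfig}.
#' @return list with \code{coords}, \code{energy}, \code{trace} (energies of
#'   accepted iterates), \code{converged}, \code{maxForce}.
#' @export
optimizeMolecule <- function(mol, coords = coordinates(mol),
                             cfg = ForceFieldConfig()) {
  coords <- as.matrix(coords)
  if (!all(dim(coords) == c(nAtoms(mol), 3L)))
    stop(sprintf("coordinate matrix must be %d x 3", nAtoms(mol)))
  assertFinite(coords, "coordinates")
  n <- nAtoms(mol)
  fn <- function(x) moleculeEnergy(mol, matrix(x, n, 3L), cfg)
  gr <- function(x) as.numeric(moleculeGradient(mol, matrix(x, n, 3L), cfg))
  res <- bfgsMinimize(as.numeric(coords), fn, gr,
                      forceTol = cfg@forceTol, maxIter = cfg@maxIter)
  if (!res$converged)
    warning(sprintf(
      "geometry optimization did not converge (max force %.3g kJ/mol/A after %d iterations)",
      res$maxForce, res$iterations))
  list(coords = matrix(res$par, n, 3L), energy = res$value, trace = res$trace,
       converged = res$converged, maxForce = res$maxForce)
}

#' Relax a crystal structure
#'
#' Optimizes all atomic positions at fixed lattice vectors; with
#' \code{cfg@cellMode == "isotropic"} an outer golden-section search over a
#' uniform cell scale factor is wrapped around the coordinate relaxation.
#' The per-molecule energy never increases along the optimization.
#'
#' @param xtal a \linkS4class{CrystalStructure}.
#' @param cfg a \linkS4class{ForceFieldConfig}.
#' @return list with \code{crystal} (relaxed \linkS4class{CrystalStructure}),
#'   \code{energyPerMolecule}, \code{trace}, \code{converged}.
#' @export
optimizeCrystal <- function(xtal, cfg = ForceFieldConfig()) {
  relaxAtoms <- function(xt) {
    at <- crystalAtoms(xt)
    Na <- nrow(at$X)
    Z <- at$Z
    n <- at$n
    rebuild <- function(x) {
      ## trial line-search geometries may transiently violate the bond-length
      ## sanity check, so bypass validity here
      X <- matrix(x, Na, 3L)
      xt2 <- xt
      xt2@coordsList <- lapply(seq_len(Z), function(m)
        X[((m - 1L) * n + 1L):(m * n), , drop = FALSE])
      xt2
    }
    fn <- function(x) crystalEnergyPerMolecule(rebuild(x), cfg) * Z
    gr <- function(x) as.numeric(crystalGradient(rebuild(x), cfg))
    res <- bfgsMinimize(as.numeric(at$X), fn, gr,
                        forceTol = cfg@forceTol, maxIter = cfg@maxIter)
    list(crystal = rebuild(res$par), energyPerMolecule = res$value / Z,
         trace = res$trace / Z, converged = res$converged,
         maxForce = res$maxForce)
  }
  if (cfg@cellMode == "fixed") {
    out <- relaxAtoms(xtal)
  } else {
    L0 <- latticeVectors(xtal)
    scaled <- function(s) {
      ## scale the lattice and the molecular centroids; internal geometry rigid
      cl <- lapply(xtal@coordsList, function(xm) {
        ctr <- colMeans(xm)
        sweep(xm, 2L, ctr) + matrix(ctr * s, nrow(xm), 3L, byrow = TRUE)
      })
      xt2 <- xtal
      xt2@lattice <- L0 * s
      xt2@coordsList <- cl
      xt2
    }
    obj <- function(s) relaxAtoms(scaled(s))$energyPerMolecule
    sopt <- stats::optimize(obj, interval = c(0.85, 1.25), tol = 1e-3)$minimum
    out <- relaxAtoms(scaled(sopt))
  }
  if (!out$converged)
    warning(sprintf(
      "crystal relaxation did not converge (max force %.3g kJ/mol/A)",
      out$maxForce))
  out
}
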