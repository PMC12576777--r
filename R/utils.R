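#' @import methods
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

## Run an expression under a fixed RNG state, restoring the caller's state.
withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' must be a single integer")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## Wrap an angle in degrees into [0, 360).
wrapDeg <- function(x) ((x %% 360) + 360) %% 360

## Smallest absolute circular difference between two angles in degrees.
circDiffDeg <- function(a, b) {
  d <- abs(wrapDeg(a) - wrapDeg(b))
  pmin(d, 360 - d)
}

assertFinite <- function(x, what) {
  if (!all(is.finite(x)))
    stop(sprintf("non-finite values in %s", what), call. = FALSE)
  invisible(x)
}

## Shortest-path graph distances up to 'maxd' bonds (BFS from every atom).
## Used for the 1-2/1-3/1-4 nonbonded exclusion scheme.
graphDistances <- function(nAtoms, bonds, maxd = 3L) {
  adj <- vector("list", nAtoms)
  for (b in seq_len(nrow(bonds))) {
    i <- bonds[b, 1L]; j <- bonds[b, 2L]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  D <- matrix(Inf, nAtoms, nAtoms)
  for (s in seq_len(nAtoms)) {
    D[s, s] <- 0
    frontier <- s
    d <- 0L
    while (length(frontier) && d < maxd) {
      d <- d + 1L
      nxt <- unique(unlist(adj[frontier]))
      nxt <- nxt[D[s, nxt] > d]
      D[s, nxt] <- d
      frontier <- nxt
    }
  }
  D
}

isConnectedGraph <- function(nAtoms, bonds) {
  if (nAtoms == 1L) return(TRUE)
  if (nrow(bonds) == 0L) return(FALSE)
  seen <- rep(FALSE, nAtoms)
  seen[1L] <- TRUE
  frontier <- 1L
  adj <- vector("list", nAtoms)
  for (b in seq_len(nrow(bonds))) {
    i <- bonds[b, 1L]; j <- bonds[b, 2L]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  while (length(frontier)) {
    nxt <- setdiff(unique(unlist(adj[frontier])), which(seen))
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  all(seen)
}
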