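## Polymorph-pair relative stabilities and MAD-vs-experiment model selection.

#' Relative lattice energies for polymorph pairs
#'
#' For every pair in the pairing table, computes
#' dE_latt = E_latt_global(alternative form) - E_latt_global(reference form)
#' from a partition ledger. The reference form is the experimentally stable
#' one, so dH_exp >= 0 by convention; a negative dE_latt means the model
#' inverts the experimental stability order.
#'
#' @param ledger partition ledger data.frame (see \code{\link{partitionLedger}}).
#' @param pairs pairing table with columns compound, refcode_ref, refcode_alt,
#'   dH_exp and optionally subset.
#' @param interModel,intraModel optional model labels used to filter the ledger
#'   (required when the ledger holds a model grid).
#' @return the pairing table with a dE_latt column and a model label attribute.
#' @export
pairRelativeEnergies <- function(ledger, pairs, interModel = NULL,
                                 intraModel = NULL) {
  led <- ledger
  if (!is.null(interModel)) led <- led[led$inter_model == interModel, ]
  if (!is.null(intraModel)) led <- led[led$intra_model == intraModel, ]
  lookup <- function(refcode) {
    hit <- which(led$structure_id == refcode)
    if (!length(hit))
      stop(sprintf("no ledger entry for refcode '%s' (model %s/%s)", refcode,
                   interModel %||% "any", intraModel %||% "any"))
    led$E_latt_global[hit[1L]]
  }
  pairs$dE_latt <- vapply(seq_len(nrow(pairs)), function(i)
    lookup(pairs$refcode_alt[i]) - lookup(pairs$refcode_ref[i]), numeric(1L))
  attr(pairs, "model") <- paste(interModel %||% "toy-ff",
                                intraModel %||% "toy-ff", sep = "/")
  pairs
}

#' Mean absolute deviation between computed and experimental stabilities
#'
#' MAD = mean |dH_exp - dE_latt| over polymorph pairs, computed per subset and
#' overall. Full precision is retained; round to 0.1 kJ/mol for display only.
#'
#' @param pairs pairing table with dH_exp and dE_latt columns (and optionally a
#'   subset column).
#' @param model model label for the result.
#' @return a data.frame with columns model, subset, n_pairs, mad and an
#'   attribute \code{deviations} (per-pair absolute deviations by subset).
#' @export
madBenchmark <- function(pairs, model = attr(pairs, "model") %||% "model") {
  if (!nrow(pairs)) stop("empty pairing table")
  if (!all(c("dH_exp", "dE_latt") %in% names(pairs)))
    stop("pairs must have dH_exp and dE_latt columns")
  dev <- abs(pairs$dH_exp - pairs$dE_latt)
  subsets <- if ("subset" %in% names(pairs)) unique(pairs$subset) else character()
  rows <- lapply(subsets, function(s) {
    sel <- pairs$subset == s
    data.frame(model = model, subset = s, n_pairs = sum(sel),
               mad = mean(dev[sel]), stringsAsFactors = FALSE)
  })
  rows[[length(rows) + 1L]] <- data.frame(model = model, subset = "all",
                                          n_pairs = nrow(pairs),
                                          mad = mean(dev),
                                          stringsAsFactors = FALSE)
  out <- do.call(rbind, rows)
  devs <- lapply(c(subsets, "all"), function(s)
    if (s == "all") dev else dev[pairs$subset == s])
  names(devs) <- c(subsets, "all")
  attr(out, "deviations") <- devs
  out
}

#' MAD over a grid of inter x intra energy models
#'
#' Computes one MAD per (inter, intra) model combination present in the ledger
#' and returns them sorted ascending, identifying the best lattice energy model
#' (the combination minimizing the MAD on the chosen subset).
#'
#' @param ledger partition ledger with inter_model/intra_model columns covering
#'   every refcode in \code{pairs} for every model combination.
#' @param pairs pairing table (see \code{\link{pairRelativeEnergies}}).
#' @param subset subset used for ranking ("validation", "test" or "all").
#' @return a data.frame (inter_model, intra_model, n_pairs, mad) sorted by MAD
#'   ascending; the first row is the best model.
#' @export
modelGrid <- function(ledger, pairs, subset = "all") {
  combos <- unique(ledger[, c("inter_model", "intra_model")])
  need <- unique(c(pairs$refcode_ref, pairs$refcode_alt))
  missing <- list()
  for (i in seq_len(nrow(combos))) {
    led <- ledger[ledger$inter_model == combos$inter_model[i] &
                    ledger$intra_model == combos$intra_model[i], ]
    gap <- setdiff(need, led$structure_id)
    if (length(gap))
      missing[[paste(combos$inter_model[i], combos$intra_model[i], sep = "/")]] <- gap
  }
  if (length(missing))
    stop("incomplete model grid; missing ledger cells: ",
         paste(vapply(names(missing), function(m)
           sprintf("%s [%s]", m, paste(missing[[m]], collapse = ",")),
           character(1L)), collapse = "; "))
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    pr <- pairRelativeEnergies(ledger, pairs,
                               interModel = combos$inter_model[i],
                               intraModel = combos$intra_model[i])
    if (subset != "all") pr <- pr[pr$subset == subset, ]
    data.frame(inter_model = combos$inter_model[i],
               intra_model = combos$intra_model[i],
               n_pairs = nrow(pr),
               mad = mean(abs(pr$dH_exp - pr$dE_latt)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$mad, out$inter_model, out$intra_model), , drop = FALSE]
}

#' Flag pairs where the model inverts the experimental stability order
#'
#' @param pairs pairing table with dE_latt.
#' @return the subset of rows with dE_latt < 0 (the alternative form predicted
#'   more stable than the experimental reference).
#' @export
signInversions <- function(pairs) pairs[pairs$dE_latt < 0, , drop = FALSE]
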