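## The 40% limit machinery: intra-to-inter ratio records, upper-envelope
## estimation, cumulative distribution, component linear fits, the kink-site
## stabilization score and the crystallizability report.

ratioRow <- function(structure_id, dataset, eInter, eAdj, dChg) {
  if (eInter >= 0)
    stop(sprintf("E_inter must be negative (bound crystal); got %.4g for '%s'",
                 eInter, structure_id))
  data.frame(structure_id = structure_id, dataset = dataset,
             r = abs((eAdj + dChg) / eInter), r_adj = abs(eAdj / eInter),
             r_chg = abs(dChg / eInter), stringsAsFactors = FALSE)
}

#' @describeIn ratio ratio record of a single partition.
#' @param dataset dataset label for the record.
#' @export
setMethod("ratio", "EnergyPartition", function(x, dataset = "CP", ...) {
  ratioRow(structureId(x), dataset, eInter(x), eAdjustment(x), dEChangeGlobal(x))
})

#' @describeIn ratio vectorized over the rows of a partition ledger.
#' @export
setMethod("ratio", "data.frame", function(x, dataset = "CP", ...) {
  validateLedger(x, addTol = 1e-6)
  bad <- x$E_inter >= 0
  if (any(bad))
    stop("E_inter must be negative (bound crystal); offending: ",
         paste(x$structure_id[bad], collapse = ", "))
  data.frame(structure_id = x$structure_id, dataset = dataset,
             r = abs(x$E_intra_global / x$E_inter),
             r_adj = abs(x$E_adjustment / x$E_inter),
             r_chg = abs(x$dE_change_global / x$E_inter),
             stringsAsFactors = FALSE)
})

#' Upper-envelope fit of the intra-to-inter ratio
#'
#' Estimates the slope s of the empirical upper bound
#' |E_intra-global| <= s * |E_inter| over a set of ratio records. The
#' "max-ratio" estimator returns the maximum observed ratio (the bound covering
#' all data); the "upper-quantile" estimator returns the given quantile of the
#' ratios, which is robust to single outliers.
#'
#' @param records a ratio data.frame (from \code{\link{ratio}}) or a numeric
#'   vector of ratios.
#' @param estimator "max-ratio" or "upper-quantile".
#' @param level quantile level for the upper-quantile estimator.
#' @return an \linkS4class{EnvelopeFit}.
#' @export
envelopeFit <- function(records, estimator = c("max-ratio", "upper-quantile"),
                        level = 0.99) {
  estimator <- match.arg(estimator)
  r <- if (is.data.frame(records)) records$r else as.numeric(records)
  if (!length(r)) stop("no ratio records to fit")
  slope <- if (estimator == "max-ratio") max(r)
  else as.numeric(stats::quantile(r, level, names = FALSE, type = 7))
  new("EnvelopeFit", estimator = estimator, slope = slope,
      n = length(r), level = if (estimator == "max-ratio") NA_real_ else level)
}

#' @describeIn envelopeFit slope accessor.
#' @param fit an EnvelopeFit.
#' @export
envelopeSlope <- function(fit) fit@slope

#' Cumulative fraction of crystals below ratio thresholds
#'
#' Evaluates the empirical CDF of the intra-to-inter ratio at the given
#' thresholds: the fraction of structures whose intramolecular penalty is
#' within threshold * |E_inter|.
#'
#' @param records ratio data.frame or numeric vector of ratios.
#' @param thresholds ratio thresholds, sorted ascending.
#' @return named numeric vector of fractions, monotone non-decreasing in the
#'   thresholds.
#' @export
cumulativeFractions <- function(records, thresholds = c(0.10, 0.15, 0.40)) {
  if (is.unsorted(thresholds))
    stop("'thresholds' must be sorted ascending")
  r <- if (is.data.frame(records)) records$r else as.numeric(records)
  out <- vapply(thresholds, function(t0) mean(r <= t0), numeric(1L))
  names(out) <- format(thresholds)
  out
}

#' Linear fits of intramolecular components against E_inter
#'
#' Ordinary least-squares fits of E_intra_global, E_adjustment and
#' dE_change_global against E_inter across a partition ledger, mirroring the
#' component-correlation analysis: a more negative intermolecular energy
#' affords a larger intramolecular penalty, and the decomposition shows which
#' component drives it.
#'
#' @param ledger partition ledger data.frame with at least 3 rows.
#' @return data.frame with columns component, slope, intercept, r_squared.
#' @export
intraLinearFit <- function(ledger) {
  validateLedger(ledger, addTol = 1e-6)
  if (nrow(ledger) < 3L) stop("need at least 3 partitions for a linear fit")
  if (stats::var(ledger$E_inter) <= 0)
    stop("degenerate fit: E_inter has no variance")
  comps <- c(intra_global = "E_intra_global", adjustment = "E_adjustment",
             change_global = "dE_change_global")
  do.call(rbind, lapply(names(comps), function(nm) {
    y <- ledger[[comps[[nm]]]]
    fit <- stats::lm(y ~ ledger$E_inter)
    tss <- sum((y - mean(y))^2)
    r2 <- if (tss > 0) 1 - sum(stats::resid(fit)^2) / tss else NA_real_
    data.frame(component = nm,
               slope = unname(stats::coef(fit)[2L]),
               intercept = unname(stats::coef(fit)[1L]),
               r_squared = r2,
               stringsAsFactors = FALSE)
  }))
}

kinkScoreCore <- function(eInter, eIntraGlobal, f = 0.5) {
  if (!is.finite(f) || f <= 0 || f > 1)
    stop("'f' must be in (0, 1]")
  if (eInter >= 0) stop("E_inter must be negative (bound crystal)")
  score <- f * abs(eInter) - eIntraGlobal
  attr(score, "favorable") <- score > 0
  score
}

#' @describeIn kinkScore for an EnergyPartition.
#' @param f fraction of lattice interactions engaged at the site (default 0.5).
#' @export
setMethod("kinkScore", "EnergyPartition", function(x, f = 0.5, ...) {
  kinkScoreCore(eInter(x), eIntraGlobal(x), f)
})

#' @describeIn kinkScore for raw component energies: \code{x} is E_inter
#'   (negative, kJ/mol).
#' @param eIntraGlobal intramolecular penalty (kJ/mol).
#' @export
setMethod("kinkScore", "numeric", function(x, eIntraGlobal, f = 0.5, ...) {
  kinkScoreCore(x, eIntraGlobal, f)
})

#' Crystallizability report
#'
#' Per-structure table of the intra-to-inter ratio, its adjustment/change
#' decomposition, the kink-site stabilization score and the percentile of the
#' ratio within a reference distribution (by default a synthetic calibration
#' table drawn from the package's paper-calibrated ratio density). High ratios
#' flag structures expected to be difficult to crystallize.
#'
#' @param ledger partition ledger data.frame.
#' @param f kink-site interaction fraction (default 0.5).
#' @param reference numeric vector of reference ratios; default: ratios of a
#'   fixed-seed synthetic energy table.
#' @param dataset dataset label for the records.
#' @return a data.frame, one row per input row, in input order.
#' @export
crystallizabilityReport <- function(ledger, f = 0.5, reference = NULL,
                                    dataset = "CP") {
  rr <- ratio(ledger, dataset = dataset)
  if (is.null(reference))
    reference <- genEnergyTable(n = 5000L, seed = 990913L)
  refR <- if (is.data.frame(reference)) ratio(reference, dataset = "synthetic")$r
  else as.numeric(reference)
  pct <- 100 * stats::ecdf(refR)(rr$r)
  score <- vapply(seq_len(nrow(ledger)), function(i)
    as.numeric(kinkScoreCore(ledger$E_inter[i], ledger$E_intra_global[i], f)),
    numeric(1L))
  data.frame(structure_id = rr$structure_id, r = rr$r, r_adj = rr$r_adj,
             r_chg = rr$r_chg, kink_score = score,
             kink_favorable = score > 0, high_ratio = rr$r > f,
             percentile = pct, stringsAsFactors = FALSE)
}
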