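#' @title Cutoff-scaling calibration scans
#' @name calibration
#' @description Count residue-pair contacts (or triad cliques) as a
#'   function of the cutoff over a structure set, fit the upper log-log
#'   scaling region, and locate the boundary where the curve departs from
#'   pure size scaling. The cutoff of interest for the network model sits
#'   at that boundary.
NULL

as_chain_list <- function(chains) {
  if (inherits(chains, "calpha_chain")) return(list(chains))
  stopifnot(is.list(chains), length(chains) >= 1L,
            all(vapply(chains, inherits, TRUE, "calpha_chain")))
  chains
}

# Shared tail: counts per cutoff from a vector of "activation distances"
# (the distance at which each counted object first appears), plus the
# log-log fit and boundary detection.
scan_from_distances <- function(act_dist, cutoffs, fit_fraction, dev_tol,
                                kind) {
  stopifnot(all(diff(cutoffs) > 0))
  counts <- findInterval(cutoffs + 1e-9, sort(act_dist))
  fit_from <- cutoffs[min(ceiling(length(cutoffs) * (1 - fit_fraction)) + 1L,
                          length(cutoffs))]
  in_fit <- cutoffs >= fit_from & counts > 0
  slope <- NA_real_; intercept <- NA_real_
  fit_range <- if (any(in_fit)) range(cutoffs[in_fit]) else c(NA_real_, NA_real_)
  boundary <- cutoffs[1L]
  if (sum(in_fit) >= 2L) {
    fit <- stats::lm(log(counts[in_fit]) ~ log(cutoffs[in_fit]))
    intercept <- unname(stats::coef(fit)[1L])
    slope <- unname(stats::coef(fit)[2L])
    pred <- intercept + slope * log(cutoffs)
    ok <- counts > 0 & abs(pred) > .Machine$double.eps
    rel_dev <- ifelse(ok, abs(log(pmax(counts, 1)) - pred) / abs(pred), Inf)
    dev_idx <- which(rel_dev > dev_tol)
    if (length(dev_idx) > 0L) boundary <- cutoffs[max(dev_idx)]
  }
  structure(list(cutoffs = cutoffs, counts = counts,
                 log_slope_fit = list(slope = slope, intercept = intercept,
                                      fit_range = fit_range),
                 boundary_cutoff = boundary, kind = kind),
            class = "scan_result")
}

#' Residue-contact frequency versus cutoff
#'
#' Counts, at each cutoff of the grid, the unordered residue pairs in
#' contact, summed over the supplied chains. A straight line is fitted to
#' the upper portion of the log-log curve (the size-scaling region); the
#' boundary cutoff is the largest grid value whose log-count deviates from
#' the fit by more than \code{dev_tol} relative.
#'
#' @param chains A \code{calpha_chain} or list of them.
#' @param cutoff_min,cutoff_max,step Cutoff grid in Angstrom
#'   (defaults 5, 15, 0.1).
#' @param fit_fraction Upper fraction of the grid used for the line fit
#'   (default 0.5).
#' @param dev_tol Relative deviation in log space flagging departure from
#'   scaling (default 0.02).
#' @return An object of class \code{scan_result}: \code{cutoffs},
#'   \code{counts}, \code{log_slope_fit} (slope, intercept, fit_range),
#'   \code{boundary_cutoff}, \code{kind}.
#' @export
contact_scan <- function(chains, cutoff_min = 5, cutoff_max = 15, step = 0.1,
                         fit_fraction = 0.5, dev_tol = 0.02) {
  chains <- as_chain_list(chains)
  cutoffs <- seq(cutoff_min, cutoff_max, by = step)
  pair_d <- unlist(lapply(chains, function(ch) as.numeric(stats::dist(ch$xyz))))
  scan_from_distances(pair_d, cutoffs, fit_fraction, dev_tol, "contacts")
}

#' Triad-clique count versus cutoff
#'
#' Same scan as \code{\link{contact_scan}} but counting residue triads in
#' mutual contact with pairwise sequence separation at least
#' \code{min_separation} (see \code{\link{find_triad_cliques}}). Each
#' triad's activation distance is the largest of its three pair distances,
#' so per-cutoff counts follow from a single enumeration at the top cutoff.
#'
#' @inheritParams contact_scan
#' @param min_separation Minimum pairwise sequence separation (default 4).
#' @return A \code{scan_result} with \code{kind = "cliques"}.
#' @export
clique_scan <- function(chains, cutoff_min = 5, cutoff_max = 15, step = 0.1,
                        min_separation = 4, fit_fraction = 0.5,
                        dev_tol = 0.02) {
  chains <- as_chain_list(chains)
  cutoffs <- seq(cutoff_min, cutoff_max, by = step)
  act <- unlist(lapply(chains, function(ch) {
    cs <- find_triad_cliques(ch, cutoff = cutoff_max,
                             min_separation = min_separation)
    if (nrow(cs$triads) == 0L) return(numeric())
    d <- as.matrix(stats::dist(ch$xyz))
    rownames(d) <- colnames(d) <- ch$resno
    apply(cs$triads, 1L, function(tr) {
      key <- as.character(tr)
      max(d[key[1L], key[2L]], d[key[1L], key[3L]], d[key[2L], key[3L]])
    })
  }))
  scan_from_distances(act, cutoffs, fit_fraction, dev_tol, "cliques")
}

#' @export
print.scan_result <- function(x, ...) {
  cat("Cutoff scan (", x$kind, "): grid ", x$cutoffs[1L], "-",
      x$cutoffs[length(x$cutoffs)], " A, counts ", x$counts[1L], "-",
      x$counts[length(x$counts)], "\n  log-log slope ",
      format(x$log_slope_fit$slope, digits = 4), ", boundary cutoff ",
      x$boundary_cutoff, " A\n", sep = "")
  invisible(x)
}

#' Write a scan result as CSV
#'
#' @param scan A \code{scan_result}.
#' @param path Output file path.
#' @return Invisibly, the data frame written.
#' @export
write_scan_csv <- function(scan, path) {
  df <- data.frame(cutoff = scan$cutoffs, count = scan$counts)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(df)
}
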