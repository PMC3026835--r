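#' @title Fastest-mode total coupling
#' @name coupling
#' @description Per-residue total coupling of the maximum-eigenvalue
#'   (fastest) GNM mode, the quantity whose support defines the interaction
#'   pathway and whose global maximum is the hub residue. Profiles are
#'   computed at several cutoff stations and averaged so that the result
#'   does not hinge on a single cutoff value.
NULL

#' Total coupling of each residue in one fastest mode
#'
#' With u the unit eigenvector of the \code{mode_rank}-th largest eigenvalue
#' lambda, the total coupling of residue i is the row sum of that mode's
#' squared distance-fluctuation contributions,
#' \code{C_T(i) = w * sum_j (u_i - u_j)^2}, evaluated through the algebraic
#' identity \code{n u_i^2 + 1 - 2 u_i sum_j u_j}. The mode weight w is
#' lambda by default (energy exchange is carried by fast modes); since only
#' one mode enters, the weight rescales but never reorders the profile —
#' \code{"inv-lambda"} and \code{"none"} are provided to make that explicit.
#' The minimum over residues is subtracted (default) so that the baseline of
#' the localized fast mode is exactly zero and "non-zero coupling" is well
#' defined.
#'
#' @param model A \code{gnm_model} with at least one nonzero eigenvalue.
#' @param mode_rank Which fastest mode: 1 = largest eigenvalue (default),
#'   2 = second largest, and so on. Counts within nonzero modes.
#' @param mode_weight One of \code{"lambda"}, \code{"inv-lambda"},
#'   \code{"none"}.
#' @param baseline Subtract the per-profile minimum (default TRUE).
#' @return Nonnegative numeric vector, one entry per residue, named by
#'   author residue number when available.
#' @export
total_coupling <- function(model, mode_rank = 1,
                           mode_weight = c("lambda", "inv-lambda", "none"),
                           baseline = TRUE) {
  stopifnot(inherits(model, "gnm_model"), mode_rank >= 1L)
  mode_weight <- match.arg(mode_weight)
  nz <- nonzero_modes(model)
  if (mode_rank > length(nz)) {
    stop("mode_rank ", mode_rank, " exceeds the ", length(nz),
         " nonzero mode(s)")
  }
  k <- length(model$values) - mode_rank + 1L
  u <- model$vectors[, k]
  lam <- model$values[k]
  n <- length(u)
  ct <- n * u^2 + sum(u^2) - 2 * u * sum(u)
  ct <- pmax(ct, 0) # guard tiny negative round-off
  w <- switch(mode_weight, lambda = lam, `inv-lambda` = 1 / lam, none = 1)
  ct <- w * ct
  if (baseline) ct <- ct - min(ct)
  if (!is.null(model$resno)) names(ct) <- model$resno
  ct
}

#' Station-averaged fastest-mode coupling profile
#'
#' Computes the fastest-mode total coupling at \code{n_stations} equally
#' spaced cutoff stations spanning \code{[station_min, station_max]}
#' (defaults 6.9, 6.975, 7.05, 7.125, 7.2 Angstrom), max-normalizes each
#' station's profile, averages across stations and re-normalizes so the
#' maximum is exactly 1. The residue attaining 1 is the hub (ties broken by
#' lowest author residue number, with a warning). A station whose contact
#' graph is disconnected is used as-is after a warning reporting the
#' zero-mode multiplicity.
#'
#' @param chain A \code{calpha_chain}.
#' @param station_min,station_max Cutoff band in Angstrom.
#' @param n_stations Number of equally spaced stations, endpoints included.
#' @param mode_rank,mode_weight Passed to \code{\link{total_coupling}}.
#' @param gamma Spring-constant scale.
#' @param peak_min_height Minimum averaged height for a reported peak,
#'   as a fraction of the maximum.
#' @return An object of class \code{coupling_profile}: \code{residue_ids},
#'   \code{residue_names}, \code{stations}, \code{per_station_ct}
#'   (stations x residues, each row max-normalized), \code{averaged_ct}
#'   (in [0, 1], max exactly 1), \code{mode_rank}, \code{hub} (author
#'   residue number) and \code{peaks} (data frame from
#'   \code{\link{find_peaks}}).
#' @examples
#' ch <- toy_chain("clustered", 40, seed = 7)
#' prof <- coupling_profile(ch)
#' prof$hub
#' @export
coupling_profile <- function(chain, station_min = 6.9, station_max = 7.2,
                             n_stations = 5, mode_rank = 1,
                             mode_weight = "lambda", gamma = 1,
                             peak_min_height = 0.02) {
  stopifnot(inherits(chain, "calpha_chain"), n_stations >= 1L)
  if (n_stations > 1L) stopifnot(station_min < station_max)
  stations <- if (n_stations == 1L) station_min else
    seq(station_min, station_max, length.out = n_stations)

  per_station <- matrix(0, nrow = length(stations), ncol = chain$n,
                        dimnames = list(format(stations), chain$resno))
  for (s in seq_along(stations)) {
    model <- gnm(chain, stations[s], gamma = gamma)
    if (!model$connected) {
      warning("contact graph disconnected at station ", stations[s],
              " A (", model$n_zero_modes, " zero modes); proceeding")
    }
    ct <- total_coupling(model, mode_rank = mode_rank,
                         mode_weight = mode_weight)
    m <- max(ct)
    per_station[s, ] <- if (m > 0) ct / m else ct
  }
  avg <- colMeans(per_station)
  m <- max(avg)
  if (m > 0) avg <- avg / m

  top <- which(avg == max(avg))
  if (length(top) > 1L) {
    warning("hub tie among residues ", paste(chain$resno[top], collapse = ", "),
            "; reporting the lowest residue number")
    top <- top[which.min(chain$resno[top])]
  }
  prof <- structure(list(
    residue_ids = chain$resno,
    residue_names = chain$resid,
    stations = stations,
    per_station_ct = per_station,
    averaged_ct = stats::setNames(avg, chain$resno),
    mode_rank = mode_rank,
    hub = chain$resno[top],
    peaks = NULL
  ), class = "coupling_profile")
  prof$peaks <- find_peaks(prof, min_height_fraction = peak_min_height)
  prof
}

#' @export
print.coupling_profile <- function(x, ...) {
  cat("Fastest-mode coupling profile (mode rank ", x$mode_rank, "): ",
      length(x$residue_ids), " residues, ", length(x$stations),
      " station(s) ", format(min(x$stations)), "-", format(max(x$stations)),
      " A\n  hub residue: ", x$hub, "; peaks: ",
      if (nrow(x$peaks) > 0) paste(utils::head(x$peaks$residue, 5L),
                                   collapse = ", ") else "none", "\n",
      sep = "")
  invisible(x)
}

#' Locate peaks of a coupling profile
#'
#' A peak is a residue whose averaged coupling is strictly higher than both
#' sequence neighbours; chain termini and residues flanking a numbering gap
#' (chain break) are compared to their single neighbour. Peaks below
#' \code{min_height_fraction} of the profile maximum are dropped. Results
#' are sorted by descending height.
#'
#' @param profile A \code{coupling_profile}.
#' @param min_height_fraction Minimum height retained, default 0.02.
#' @return data.frame with columns \code{residue}, \code{height},
#'   \code{rank}.
#' @export
find_peaks <- function(profile, min_height_fraction = 0.02) {
  stopifnot(inherits(profile, "coupling_profile"))
  v <- unname(profile$averaged_ct)
  ids <- profile$residue_ids
  n <- length(v)
  # segment break after position i when author numbering jumps
  brk <- c(diff(ids) != 1L, TRUE)
  is_peak <- logical(n)
  for (i in seq_len(n)) {
    left_ok <- i == 1L || brk[i - 1L] || v[i] > v[i - 1L]
    right_ok <- i == n || brk[i] || v[i] > v[i + 1L]
    lone <- (i == 1L || brk[i - 1L]) && (i == n || brk[i])
    is_peak[i] <- left_ok && right_ok && !lone
  }
  keep <- which(is_peak & v >= min_height_fraction)
  keep <- keep[order(-v[keep], ids[keep])]
  data.frame(residue = ids[keep], height = v[keep],
             rank = seq_along(keep), row.names = NULL)
}

#' Write a coupling profile as TSV
#'
#' One row per residue: residue number, residue name, averaged coupling,
#' whether the residue is on the interaction path at \code{ct_threshold},
#' and whether it is the hub.
#'
#' @param profile A \code{coupling_profile}.
#' @param path Output file path.
#' @param ct_threshold Path-membership threshold on the averaged coupling.
#' @return Invisibly, the data frame written.
#' @export
write_profile_tsv <- function(profile, path, ct_threshold = 0.02) {
  df <- data.frame(
    residue_number = profile$residue_ids,
    residue_name = profile$residue_names,
    averaged_ct = round(unname(profile$averaged_ct), 6),
    is_path_residue = as.integer(profile$averaged_ct >= ct_threshold),
    is_hub = as.integer(profile$residue_ids == profile$hub)
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
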