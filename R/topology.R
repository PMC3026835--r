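#' @title Interaction paths, gates and stiff residue triads
#' @name topology
#' @description Turn a coupling profile into an interaction-path report
#'   (path residues, connected components, gate residues, close residue
#'   pairs) and enumerate contact-map cliques of size three: residue triads
#'   mutually in contact at a tight cutoff while far apart in sequence.
NULL

#' Extract interaction pathways from a coupling profile
#'
#' Path residues are those with averaged coupling at or above
#' \code{ct_threshold}. The path-residue contact graph (C-alpha distance at
#' most \code{pair_cutoff}) is split into connected components; within each
#' component the gate residues are the extremities — members of subgraph
#' degree at most 1 — plus the member with the fewest contacts in the whole
#' chain (a surface-exposure proxy). The pair table lists every unordered
#' path-residue pair closer than \code{pair_cutoff} whose author residue
#' numbers differ by at least \code{min_pair_separation}.
#'
#' @param chain A \code{calpha_chain}.
#' @param profile A \code{coupling_profile} computed on the same chain.
#' @param ct_threshold Path membership threshold on averaged coupling
#'   (default 0.02).
#' @param pair_cutoff Contact distance for components and the pair table,
#'   Angstrom (default 7.2).
#' @param min_pair_separation Minimum author-number separation for pair
#'   table entries (default 10).
#' @return An object of class \code{pathway_report}: \code{path_residues}
#'   (author numbers), \code{components} (list of author-number vectors),
#'   \code{gates} (list parallel to components), \code{pair_table}
#'   (data.frame i, j, dist), \code{hub}, and the thresholds used.
#' @export
extract_pathways <- function(chain, profile, ct_threshold = 0.02,
                             pair_cutoff = 7.2, min_pair_separation = 10) {
  stopifnot(inherits(chain, "calpha_chain"),
            inherits(profile, "coupling_profile"),
            identical(chain$resno, profile$residue_ids))
  on_path <- which(profile$averaged_ct >= ct_threshold)
  empty_pairs <- data.frame(i = integer(), j = integer(), dist = numeric())
  if (length(on_path) == 0L) {
    warning("no residues reach the coupling threshold ", ct_threshold,
            "; empty pathway report")
    return(structure(list(path_residues = integer(), components = list(),
                          gates = list(), pair_table = empty_pairs,
                          hub = profile$hub, ct_threshold = ct_threshold,
                          pair_cutoff = pair_cutoff,
                          min_pair_separation = min_pair_separation),
                     class = "pathway_report"))
  }
  d <- as.matrix(stats::dist(chain$xyz))
  full_degree <- rowSums(d <= pair_cutoff) - 1

  ids <- chain$resno[on_path]
  dsub <- d[on_path, on_path, drop = FALSE]
  adj <- dsub <= pair_cutoff
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)
  components <- lapply(seq_len(comp$no), function(ci) ids[comp$membership == ci])
  gates <- lapply(seq_len(comp$no), function(ci) {
    members <- which(comp$membership == ci)
    deg <- rowSums(adj[members, members, drop = FALSE])
    ext <- members[deg <= 1]
    lowcoord <- members[which.min(full_degree[on_path][members])]
    sort(unique(ids[c(ext, lowcoord)]))
  })

  pr <- which(upper.tri(dsub) & dsub <= pair_cutoff &
                abs(outer(ids, ids, "-")) >= min_pair_separation,
              arr.ind = TRUE)
  pair_table <- data.frame(i = ids[pr[, 1L]], j = ids[pr[, 2L]],
                           dist = dsub[pr])
  # report each unordered pair once with i < j, sorted like the tables
  flip <- pair_table$i > pair_table$j
  tmp <- pair_table$i[flip]
  pair_table$i[flip] <- pair_table$j[flip]
  pair_table$j[flip] <- tmp
  pair_table <- pair_table[order(pair_table$i, pair_table$j), , drop = FALSE]
  rownames(pair_table) <- NULL

  structure(list(path_residues = ids, components = components, gates = gates,
                 pair_table = pair_table, hub = profile$hub,
                 ct_threshold = ct_threshold, pair_cutoff = pair_cutoff,
                 min_pair_separation = min_pair_separation),
            class = "pathway_report")
}

#' @export
print.pathway_report <- function(x, ...) {
  cat("Interaction pathway report: ", length(x$path_residues),
      " path residue(s) in ", length(x$components), " component(s); hub ",
      x$hub, "\n  pair table: ", nrow(x$pair_table), " pair(s) within ",
      x$pair_cutoff, " A, separation >= ", x$min_pair_separation, "\n",
      sep = "")
  invisible(x)
}

#' Enumerate residue triads in mutual contact (cliques of size three)
#'
#' All unordered triples whose three C-alpha distances are at most
#' \code{cutoff} and whose three pairwise author-number separations are at
#' least \code{min_separation}. Such triads are stiff structural motifs:
#' residues far apart along the sequence yet mutually packed.
#'
#' @param chain A \code{calpha_chain} with at least 3 residues.
#' @param cutoff Contact cutoff in Angstrom (default 6.2).
#' @param min_separation Minimum sequence separation between every pair of
#'   the triad (default 4).
#' @return An object of class \code{clique_set}: \code{cutoff},
#'   \code{min_separation}, and \code{triads}, an m x 3 matrix of author
#'   residue numbers, each row sorted ascending, rows ordered
#'   lexicographically.
#' @examples
#' ch <- toy_chain("clustered", 30, seed = 3)
#' find_triad_cliques(ch, cutoff = 6.2)
#' @export
find_triad_cliques <- function(chain, cutoff = 6.2, min_separation = 4) {
  stopifnot(inherits(chain, "calpha_chain"), chain$n >= 3L)
  d <- as.matrix(stats::dist(chain$xyz))
  sep <- abs(outer(chain$resno, chain$resno, "-"))
  adj <- d <= cutoff & sep >= min_separation
  diag(adj) <- FALSE

  triads <- matrix(integer(), ncol = 3L)
  edges <- which(upper.tri(adj) & adj, arr.ind = TRUE)
  if (nrow(edges) > 0L) {
    rows <- vector("list", nrow(edges))
    for (e in seq_len(nrow(edges))) {
      i <- edges[e, 1L]; j <- edges[e, 2L]
      k <- which(adj[i, ] & adj[j, ])
      k <- k[k > j]
      if (length(k) > 0L) rows[[e]] <- cbind(i, j, k, deparse.level = 0)
    }
    idx <- do.call(rbind, rows)
    if (!is.null(idx) && nrow(idx) > 0L) {
      triads <- matrix(chain$resno[idx], ncol = 3L)
      triads <- t(apply(triads, 1L, sort))
      triads <- unique(triads)
      triads <- triads[order(triads[, 1L], triads[, 2L], triads[, 3L]), ,
                       drop = FALSE]
    }
  }
  colnames(triads) <- c("res_i", "res_j", "res_k")
  structure(list(cutoff = cutoff, min_separation = min_separation,
                 triads = triads),
            class = "clique_set")
}

#' @export
print.clique_set <- function(x, ...) {
  cat("Clique set at cutoff ", x$cutoff, " A (separation >= ",
      x$min_separation, "): ", nrow(x$triads), " triad(s)\n", sep = "")
  if (nrow(x$triads) > 0L) {
    apply(utils::head(x$triads, 10L), 1L, function(r)
      cat("  {", paste(r, collapse = ", "), "}\n", sep = ""))
  }
  invisible(x)
}

#' Triad cliques across a cutoff sweep
#'
#' One clique set per cutoff. Because the contact condition is a closed
#' ball, the triad set at a smaller cutoff is always a subset of the set at
#' a larger one.
#'
#' @param chain A \code{calpha_chain}.
#' @param cutoffs Numeric vector of cutoffs in Angstrom
#'   (default 6.0-6.4 in steps of 0.1).
#' @param min_separation Minimum pairwise sequence separation (default 4).
#' @return Named list of \code{clique_set} objects, names the cutoff values.
#' @export
clique_cutoff_sweep <- function(chain, cutoffs = c(6.0, 6.1, 6.2, 6.3, 6.4),
                                min_separation = 4) {
  stopifnot(length(cutoffs) >= 1L)
  out <- lapply(cutoffs, function(rc)
    find_triad_cliques(chain, cutoff = rc, min_separation = min_separation))
  names(out) <- format(cutoffs)
  out
}

#' Query whether a clique set contains a given triad
#'
#' @param cliques A \code{clique_set}.
#' @param triad Integer vector of three author residue numbers, any order.
#' @return TRUE if the (sorted) triad is present.
#' @export
has_triad <- function(cliques, triad) {
  stopifnot(inherits(cliques, "clique_set"), length(triad) == 3L)
  tr <- sort(as.integer(triad))
  any(cliques$triads[, 1L] == tr[1L] & cliques$triads[, 2L] == tr[2L] &
        cliques$triads[, 3L] == tr[3L])
}
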