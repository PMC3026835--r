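#' @title Synthetic C-alpha chains and complexes
#' @name synthetic
#' @description Deterministic toy structures with known properties — rings
#'   (full symmetry), ideal helices, random coils and coils carrying one
#'   compact cluster of elevated coordination — plus a synthetic bound
#'   complex whose ground-truth ligand contacts are returned alongside.
#'   Every other module is testable offline against these.
NULL

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate a toy C-alpha chain
#'
#' Geometries:
#' \describe{
#'   \item{ring}{Regular polygon in the xy-plane; every residue is
#'     symmetry-equivalent, so the baseline-subtracted fastest-mode
#'     coupling is identically zero. Radius defaults to the value giving
#'     3.8 Angstrom between neighbours.}
#'   \item{helix}{Ideal alpha-helix: radius 2.3 Angstrom, rise 1.5 per
#'     residue, 100 degrees per turn — about 3.8 Angstrom C-alpha spacing.}
#'   \item{random_coil}{Self-avoiding random walk with 3.8 Angstrom steps
#'     (new points rejected within 3.0 Angstrom of previous ones).}
#'   \item{clustered}{Extended coil (clash radius 6.5 Angstrom) followed by
#'     a compact blob of \code{cluster_size} residues with mutual distances
#'     of a few Angstrom attached near the coil end: a locally dense region
#'     of elevated coordination on which the fastest mode localizes.}
#' }
#'
#' @param kind One of \code{"ring"}, \code{"helix"}, \code{"random_coil"},
#'   \code{"clustered"}.
#' @param n Residue count (>= 3).
#' @param seed Integer seed; identical (kind, n, seed, geometry) gives
#'   bit-identical coordinates.
#' @param radius Ring radius override, Angstrom.
#' @param spacing Neighbour spacing for rings/coils (default 3.8).
#' @param cluster_size,cluster_spread Clustered-kind parameters: residues
#'   in the dense blob (default 8) and the scale of their mutual distances
#'   (default 2.5 Angstrom; blob diameter about 1.4x this).
#' @param first_resno Author number of the first residue (default 1).
#' @return A \code{calpha_chain} with pdb_id \code{"toy-<kind>"}.
#' @examples
#' ring <- toy_chain("ring", 12)
#' range(total_coupling(gnm(ring, 7)))
#' @export
toy_chain <- function(kind = c("ring", "helix", "random_coil", "clustered"),
                      n, seed = 1, radius = NULL, spacing = 3.8,
                      cluster_size = 8, cluster_spread = 2.5,
                      first_resno = 1L) {
  kind <- match.arg(kind)
  stopifnot(n >= 3L)
  xyz <- switch(kind,
    ring = {
      r <- if (is.null(radius)) spacing / (2 * sin(pi / n)) else radius
      th <- 2 * pi * (seq_len(n) - 1L) / n
      cbind(r * cos(th), r * sin(th), 0)
    },
    helix = {
      th <- (seq_len(n) - 1L) * 100 * pi / 180
      cbind(2.3 * cos(th), 2.3 * sin(th), 1.5 * (seq_len(n) - 1L))
    },
    random_coil = with_seed(seed, coil_walk(n, spacing)),
    clustered = with_seed(seed, {
      stopifnot(cluster_size >= 3L, n > cluster_size)
      # extended coil (clash radius 6.5) so that the appended blob is
      # unambiguously the region of highest coordination at ~7 A cutoffs:
      # non-consecutive coil residues sit >= 6.5 A apart, capping coil
      # degree well below the blob's cluster_size - 1 mutual contacts
      coil <- coil_walk(n - cluster_size, spacing, min_clash = 6.5)
      last <- coil[nrow(coil), ]
      dir <- last - coil[nrow(coil) - 1L, ]
      dir <- dir / sqrt(sum(dir^2))
      # far enough that the attachment residue touches only the blob's near
      # face (keeping its coordination below the blob's), close enough that
      # the contact graph stays connected at ~7 A cutoffs
      center <- last + dir * (spacing + 1.6 * cluster_spread)
      rbind(coil, blob_points(cluster_size, cluster_spread) +
                    rep(center, each = cluster_size))
    })
  )
  if (min(stats::dist(xyz)) < 0.5) {
    stop("degenerate geometry: self-coincident points")
  }
  structure(list(
    pdb_id = paste0("toy-", kind),
    chain_id = "A",
    resno = seq.int(first_resno, length.out = n),
    icode = rep("", n),
    resid = rep("ALA", n),
    xyz = unname(xyz),
    n = n
  ), class = "calpha_chain")
}

# Self-avoiding-ish random walk, fixed step length.
coil_walk <- function(n, spacing, min_clash = 3.0, max_try = 200L) {
  xyz <- matrix(0, n, 3L)
  for (i in seq_len(n)[-1L]) {
    for (try in seq_len(max_try)) {
      v <- stats::rnorm(3L)
      cand <- xyz[i - 1L, ] + spacing * v / sqrt(sum(v^2))
      prev <- xyz[seq_len(i - 2L), , drop = FALSE]
      if (i == 2L || nrow(prev) == 0L ||
          min(sqrt(rowSums((prev - rep(cand, each = nrow(prev)))^2))) >=
            min_clash) {
        xyz[i, ] <- cand
        break
      }
      if (try == max_try) stop("coil walk failed to avoid clashes")
    }
  }
  xyz
}

# Compact quasi-spherical blob: jittered Fibonacci-sphere points scaled so
# the blob diameter is about 1.4 * spread — every pair mutually in contact
# at the cutoffs of interest, none self-coincident.
blob_points <- function(m, spread) {
  i <- seq_len(m) - 0.5
  phi <- pi * (3 - sqrt(5)) * (seq_len(m) - 1L)
  z <- 1 - 2 * i / m
  r <- sqrt(pmax(1 - z^2, 0))
  pts <- cbind(r * cos(phi), r * sin(phi), z) * (0.7 * spread)
  pts + matrix(stats::rnorm(3 * m, sd = 0.1), m, 3L)
}

#' Emit a synthetic bound complex as PDB text
#'
#' Writes the chain's ATOM records (optionally with ideal N/C/O backbone
#' stubs so residues have non-C-alpha heavy atoms) plus one HETATM ligand
#' group centred at \code{ligand_offset} (absolute coordinates). Ligand
#' atoms beyond the first are placed on a 0.8 Angstrom grid around the
#' centre. The ground-truth contact set — residues with any heavy atom
#' strictly within 3.5 Angstrom of any ligand atom — is returned alongside
#' for assertions.
#'
#' @param chain A \code{calpha_chain}.
#' @param ligand_offset Numeric 3-vector: ligand centre position, Angstrom.
#' @param n_ligand_atoms Number of ligand atoms (default 1).
#' @param het_code HET code for the ligand (default "LIG").
#' @param full_atoms Add N/C/O stubs at fixed ideal offsets from each
#'   C-alpha (default FALSE).
#' @param contact_cutoff Ground-truth rule, strict upper bound
#'   (default 3.5).
#' @return List with \code{pdb_text} (single string), \code{ligand_xyz},
#'   and \code{true_contacts} (author residue numbers).
#' @export
toy_complex <- function(chain, ligand_offset, n_ligand_atoms = 1L,
                        het_code = "LIG", full_atoms = FALSE,
                        contact_cutoff = 3.5) {
  stopifnot(inherits(chain, "calpha_chain"), length(ligand_offset) == 3L)
  stub <- rbind(CA = c(0, 0, 0), N = c(-1.2, 0.8, 0), C = c(1.3, 0.6, 0),
                O = c(1.5, -0.6, 0.6))
  atom_names <- if (full_atoms) rownames(stub) else "CA"

  lines <- character()
  serial <- 0L
  prot_xyz <- NULL
  prot_res <- integer()
  for (i in seq_len(chain$n)) {
    for (an in atom_names) {
      serial <- serial + 1L
      pos <- chain$xyz[i, ] + stub[an, ]
      lines <- c(lines, pdb_atom_line(serial, an, chain$resid[i],
                                      chain$chain_id, chain$resno[i], pos))
      prot_xyz <- rbind(prot_xyz, pos)
      prot_res <- c(prot_res, chain$resno[i])
    }
  }
  lines <- c(lines, "TER")

  grid <- as.matrix(expand.grid(x = 0:2, y = 0:2, z = 0:2)) * 0.8
  lig_xyz <- grid[seq_len(n_ligand_atoms), , drop = FALSE]
  lig_xyz <- lig_xyz - rep(colMeans(lig_xyz), each = n_ligand_atoms)
  lig_xyz <- lig_xyz + rep(as.numeric(ligand_offset), each = n_ligand_atoms)
  for (a in seq_len(n_ligand_atoms)) {
    serial <- serial + 1L
    lines <- c(lines, pdb_atom_line(serial, paste0("C", a), het_code,
                                    chain$chain_id, 900L, lig_xyz[a, ],
                                    record = "HETATM"))
  }
  lines <- c(lines, "END")

  mind <- min_dist_to(prot_xyz, lig_xyz)
  true_contacts <- sort(unique(prot_res[mind < contact_cutoff]))
  list(pdb_text = paste(lines, collapse = "\n"), ligand_xyz = lig_xyz,
       true_contacts = true_contacts)
}
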