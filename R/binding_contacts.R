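#' @title Bound-complex contact annotation
#' @name binding_contacts
#' @description Validate apo-structure predictions on a holo complex: a
#'   residue is a contacting residue when any of its heavy atoms lies
#'   strictly within 3.5 Angstrom of any ligand atom AND the residue
#'   carries non-zero total coupling in the profile computed from the
#'   unbound structure.
NULL

# Heavy atoms of one chain's ATOM records, altloc-collapsed.
holo_heavy_atoms <- function(pdb_source, chain_id) {
  atoms <- parse_pdb_atoms(pdb_source)
  atoms <- atoms[atoms$record == "ATOM" & atoms$chain == chain_id, ,
                 drop = FALSE]
  if (nrow(atoms) == 0L) stop("chain not found: '", chain_id, "'")
  atoms <- atoms[!is_hydrogen(atoms) & atoms$occ > 0, , drop = FALSE]
  collapse_altloc(atoms)
}

min_dist_to <- function(xyz, lig_xyz) {
  # smallest Euclidean distance from each row of xyz to any row of lig_xyz
  cross <- xyz %*% t(lig_xyz)
  d2 <- outer(rowSums(xyz^2), rowSums(lig_xyz^2), "+") - 2 * cross
  sqrt(pmax(apply(d2, 1L, min), 0))
}

#' Annotate ligand-contacting residues with apo coupling
#'
#' All heavy atoms of every residue of the holo chain are tested against all
#' atoms of the ligand; residues with minimum atom-atom distance strictly
#' below \code{contact_cutoff} and apo averaged coupling at or above
#' \code{ct_threshold} are reported. Apo and holo chains must share author
#' residue numbering (checked by residue-name agreement on common numbers).
#' Holo residues absent from the apo profile are logged in
#' \code{mapping_notes}, never silently dropped. When \code{ligand} selects
#' several copies (for example two ions of the same HET code), one
#' sub-report per copy is produced together with the pooled set.
#'
#' @param holo_source Path to (or text of) the bound-complex PDB.
#' @param holo_chain Chain identifier in the holo structure.
#' @param ligand A \code{ligand_group}, a list of them, or a HET code
#'   (character) to look up in the holo file.
#' @param apo_profile A \code{coupling_profile} computed from the unbound
#'   structure.
#' @param ct_threshold Non-zero-coupling threshold (default 0.02).
#' @param contact_cutoff Atom-atom contact distance, strict upper bound
#'   (default 3.5 Angstrom).
#' @return An object of class \code{contact_report}: \code{holo_id},
#'   \code{ligands} (the groups used), \code{per_ligand} (list of data
#'   frames residue_number, residue_name, min_atom_distance, averaged_ct),
#'   \code{contacts} (pooled data frame, one row per residue with its
#'   smallest distance over copies), \code{mapping_notes}.
#' @export
annotate_contacts <- function(holo_source, holo_chain, ligand, apo_profile,
                              ct_threshold = 0.02, contact_cutoff = 3.5) {
  stopifnot(inherits(apo_profile, "coupling_profile"))
  if (is.character(ligand)) {
    ligand <- load_ligands(holo_source, het_codes = ligand)
    if (length(ligand) == 0L) stop("ligand HET code not found in holo file")
  }
  if (inherits(ligand, "ligand_group")) ligand <- list(ligand)
  stopifnot(length(ligand) >= 1L,
            all(vapply(ligand, inherits, TRUE, "ligand_group")))

  atoms <- holo_heavy_atoms(holo_source, holo_chain)
  res_key <- paste(atoms$resno, atoms$icode, sep = "\r")
  res_order <- unique(res_key)
  res_split <- split(seq_len(nrow(atoms)), factor(res_key, levels = res_order))
  res_no <- as.integer(vapply(strsplit(res_order, "\r"), `[`, "", 1L))
  res_name <- vapply(res_split, function(i) atoms$resid[i[1L]], "")

  apo_ids <- apo_profile$residue_ids
  shared <- intersect(res_no, apo_ids)
  if (length(shared) == 0L) {
    stop("numbering mismatch: apo and holo chains share no residue numbers")
  }
  apo_names <- apo_profile$residue_names[match(shared, apo_ids)]
  holo_names <- res_name[match(shared, res_no)]
  agree <- mean(apo_names == holo_names)
  notes <- character()
  if (agree < 1) {
    notes <- c(notes, sprintf(
      "residue-name agreement on %d shared numbers: %.0f%%",
      length(shared), 100 * agree))
    if (agree < 0.5) {
      stop("numbering mismatch: residue names disagree on ",
           round(100 * (1 - agree)), "% of shared residue numbers")
    }
  }
  unmatched <- setdiff(res_no, apo_ids)
  if (length(unmatched) > 0L) {
    notes <- c(notes, paste0("holo residues absent from apo profile: ",
                             paste(unmatched, collapse = ", ")))
  }

  ct <- unname(apo_profile$averaged_ct)[match(res_no, apo_ids)]
  per_ligand <- lapply(ligand, function(lg) {
    mind <- vapply(res_split, function(i)
      min(min_dist_to(as.matrix(atoms[i, c("x", "y", "z")]), lg$xyz)),
      numeric(1))
    keep <- which(mind < contact_cutoff & !is.na(ct) & ct >= ct_threshold)
    keep <- keep[order(res_no[keep])]
    data.frame(residue_number = res_no[keep], residue_name = res_name[keep],
               min_atom_distance = unname(mind[keep]),
               averaged_ct = ct[keep], row.names = NULL)
  })
  names(per_ligand) <- vapply(ligand, function(lg)
    paste0(lg$het_code, "/", lg$chain_id, "/", lg$resno), "")

  pooled <- do.call(rbind, per_ligand)
  if (!is.null(pooled) && nrow(pooled) > 0L) {
    pooled <- pooled[order(pooled$residue_number, pooled$min_atom_distance), ,
                     drop = FALSE]
    pooled <- pooled[!duplicated(pooled$residue_number), , drop = FALSE]
    rownames(pooled) <- NULL
  } else {
    pooled <- per_ligand[[1L]][0L, , drop = FALSE]
  }

  structure(list(holo_id = pdb_source_id(holo_source),
                 holo_chain = holo_chain, ligands = ligand,
                 per_ligand = per_ligand, contacts = pooled,
                 ct_threshold = ct_threshold,
                 contact_cutoff = contact_cutoff,
                 mapping_notes = notes),
            class = "contact_report")
}

#' @export
print.contact_report <- function(x, ...) {
  cat("Contact report for ", x$holo_id, "/", x$holo_chain, " (",
      length(x$ligands), " ligand group(s), atom rule < ",
      x$contact_cutoff, " A):\n", sep = "")
  if (nrow(x$contacts) == 0L) {
    cat("  no contacting residues with non-zero coupling\n")
  } else {
    cat(" ", paste0(x$contacts$residue_name, x$contacts$residue_number,
                    collapse = " "), "\n")
  }
  for (note in x$mapping_notes) cat("  note: ", note, "\n", sep = "")
  invisible(x)
}

#' Write a contact report as TSV
#'
#' One row per pooled contacting residue, residues rendered as
#' NAME+number strings alongside the numeric columns.
#'
#' @param report A \code{contact_report}.
#' @param path Output file path.
#' @return Invisibly, the data frame written.
#' @export
write_contacts_tsv <- function(report, path) {
  df <- report$contacts
  df$residue <- paste0(df$residue_name, df$residue_number)
  df <- df[, c("residue", "residue_number", "residue_name",
               "min_atom_distance", "averaged_ct")]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
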