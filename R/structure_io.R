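#' @title Minimal PDB input for coarse-grained network analysis
#' @name structure_io
#' @description Read a single-chain C-alpha trace or the HETATM ligand groups
#'   from a PDB file. Only the fixed-width ATOM/HETATM/MODEL/ENDMDL/TER
#'   records are interpreted; everything else is ignored.
NULL

# Parse the ATOM/HETATM records of a PDB source into a data.frame.
# `source` is a file path, a single string of PDB text, or a character
# vector of lines. Only MODEL 1 is kept for multi-model files.
parse_pdb_atoms <- function(source) {
  lines <- pdb_source_lines(source)
  rec <- substr(lines, 1L, 6L)
  is_atom <- rec == "ATOM  " | rec == "HETATM"
  if (!any(is_atom)) stop("format error: no ATOM/HETATM records found")

  # restrict to the first model when MODEL/ENDMDL records are present
  model_starts <- which(rec == "MODEL ")
  if (length(model_starts) > 0L) {
    endmdl <- which(rec == "ENDMDL")
    last <- if (length(endmdl) > 0L) endmdl[1L] else length(lines)
    keep_range <- seq(model_starts[1L], last)
    is_atom <- is_atom & seq_along(lines) %in% keep_range
  }
  lines <- lines[is_atom]
  rec <- rec[is_atom]

  fw <- function(a, b) trimws(substr(lines, a, b))
  x <- suppressWarnings(as.numeric(substr(lines, 31L, 38L)))
  y <- suppressWarnings(as.numeric(substr(lines, 39L, 46L)))
  z <- suppressWarnings(as.numeric(substr(lines, 47L, 54L)))
  if (anyNA(x) || anyNA(y) || anyNA(z)) {
    stop("format error: malformed coordinate fields")
  }
  occ <- suppressWarnings(as.numeric(substr(lines, 55L, 60L)))
  occ[is.na(occ)] <- 1
  resno <- suppressWarnings(as.integer(fw(23L, 26L)))
  if (anyNA(resno)) stop("format error: malformed residue numbers")

  data.frame(
    record = trimws(rec),
    name = fw(13L, 16L),
    altloc = substr(lines, 17L, 17L),
    resid = fw(18L, 20L),
    chain = substr(lines, 22L, 22L),
    resno = resno,
    icode = trimws(substr(lines, 27L, 27L)),
    x = x, y = y, z = z,
    occ = occ,
    element = fw(77L, 78L),
    stringsAsFactors = FALSE
  )
}

pdb_source_lines <- function(source) {
  if (length(source) == 1L && !grepl("\n", source) && file.exists(source)) {
    return(readLines(source, warn = FALSE))
  }
  if (length(source) == 1L && grepl("\n", source)) {
    return(strsplit(source, "\n", fixed = TRUE)[[1L]])
  }
  if (is.character(source) && length(source) > 1L) return(source)
  stop("format error: source is neither an existing file nor PDB text")
}

pdb_source_id <- function(source) {
  if (length(source) == 1L && !grepl("\n", source) && file.exists(source)) {
    return(sub("\\.(pdb|ent)$", "", basename(source), ignore.case = TRUE))
  }
  "pdb"
}

is_hydrogen <- function(atoms) {
  el <- atoms$element
  byel <- el %in% c("H", "D")
  # fall back on the atom-name convention when the element column is absent
  noel <- el == ""
  byname <- grepl("^[0-9]*[HD]", atoms$name)
  byel | (noel & byname)
}

# Collapse alternate locations: keep the highest-occupancy conformer of each
# (resno, icode, atom name) triple; ties go to altloc "A", then file order.
collapse_altloc <- function(atoms) {
  if (all(atoms$altloc %in% c(" ", ""))) return(atoms)
  key <- paste(atoms$resno, atoms$icode, atoms$name, sep = "\r")
  pref <- order(key, -atoms$occ, atoms$altloc != "A", seq_len(nrow(atoms)))
  atoms <- atoms[pref, , drop = FALSE]
  atoms <- atoms[!duplicated(key[pref]), , drop = FALSE]
  atoms[order(as.integer(rownames(atoms))), , drop = FALSE]
}

#' Load the C-alpha trace of one chain from a PDB file
#'
#' Extracts an ordered C-alpha record per residue from the ATOM records of
#' one chain. Alternate locations keep the highest-occupancy conformer
#' (altloc \code{"A"} on ties), hydrogens and zero-occupancy atoms are
#' ignored, residues lacking a C-alpha are skipped with a warning, and only
#' the first MODEL of a multi-model file is read. Missing residues (chain
#' breaks) are accepted silently: the network model operates on the observed
#' residue set.
#'
#' @param pdb_source Path to a PDB file, or PDB text (single string or
#'   character vector of lines).
#' @param chain_id Single chain identifier character.
#' @return An object of class \code{calpha_chain}: a list with elements
#'   \code{pdb_id}, \code{chain_id}, \code{resno} (author residue numbers),
#'   \code{icode} (insertion codes), \code{resid} (3-letter residue names),
#'   \code{xyz} (n x 3 coordinate matrix, Angstrom) and \code{n}.
#' @examples
#' pdb <- toy_complex(toy_chain("helix", 12), ligand_offset = c(50, 0, 0))
#' ch <- load_calpha_chain(pdb$pdb_text, "A")
#' ch$n
#' @export
load_calpha_chain <- function(pdb_source, chain_id) {
  stopifnot(is.character(chain_id), length(chain_id) == 1L, nchar(chain_id) == 1L)
  atoms <- parse_pdb_atoms(pdb_source)
  atoms <- atoms[atoms$record == "ATOM", , drop = FALSE]
  if (!any(atoms$chain == chain_id)) {
    stop("chain not found: '", chain_id, "'")
  }
  atoms <- atoms[atoms$chain == chain_id, , drop = FALSE]
  atoms <- atoms[!is_hydrogen(atoms) & atoms$occ > 0, , drop = FALSE]
  rownames(atoms) <- seq_len(nrow(atoms))

  res_key <- paste(atoms$resno, atoms$icode, sep = "\r")
  all_res <- unique(res_key)
  ca <- atoms[atoms$name == "CA", , drop = FALSE]
  ca <- collapse_altloc(ca)
  ca_key <- paste(ca$resno, ca$icode, sep = "\r")
  missing_ca <- setdiff(all_res, ca_key)
  if (length(missing_ca) > 0L) {
    nums <- vapply(strsplit(missing_ca, "\r"), `[`, "", 1L)
    warning("skipping ", length(missing_ca), " residue(s) without a C-alpha ",
            "in chain ", chain_id, ": ", paste(nums, collapse = ", "))
  }
  if (nrow(ca) < 2L) stop("chain too short: fewer than 2 C-alpha records")
  if (anyDuplicated(ca_key)) stop("format error: duplicate residue identifiers")

  structure(list(
    pdb_id = pdb_source_id(pdb_source),
    chain_id = chain_id,
    resno = ca$resno,
    icode = ca$icode,
    resid = ca$resid,
    xyz = unname(as.matrix(ca[, c("x", "y", "z")])),
    n = nrow(ca)
  ), class = "calpha_chain")
}

#' @export
print.calpha_chain <- function(x, ...) {
  cat("C-alpha chain ", x$pdb_id, "/", x$chain_id, ": ", x$n, " residues (",
      x$resno[1L], "-", x$resno[x$n], ")\n", sep = "")
  invisible(x)
}

#' Load HETATM ligand groups from a PDB file
#'
#' Returns one group per distinct (HET code, chain, residue number,
#' insertion code) HETATM record set, excluding water. Single-atom groups
#' (metal ions such as ZN or CA) are valid ligands. Hydrogens are dropped.
#'
#' @param pdb_source Path to a PDB file or PDB text.
#' @param het_codes Optional character vector restricting the HET codes
#'   returned.
#' @return A list of \code{ligand_group} objects, each with \code{het_code},
#'   \code{chain_id}, \code{resno}, \code{atom_names} and \code{xyz}.
#'   Empty list when the file has no qualifying HETATM records.
#' @export
load_ligands <- function(pdb_source, het_codes = NULL) {
  atoms <- tryCatch(parse_pdb_atoms(pdb_source), error = function(e) NULL)
  if (is.null(atoms)) return(list())
  atoms <- atoms[atoms$record == "HETATM", , drop = FALSE]
  atoms <- atoms[!(atoms$resid %in% c("HOH", "WAT", "DOD")), , drop = FALSE]
  atoms <- atoms[!is_hydrogen(atoms) & atoms$occ > 0, , drop = FALSE]
  if (!is.null(het_codes)) atoms <- atoms[atoms$resid %in% het_codes, , drop = FALSE]
  if (nrow(atoms) == 0L) return(list())
  atoms <- collapse_altloc(atoms)
  key <- paste(atoms$resid, atoms$chain, atoms$resno, atoms$icode, sep = "\r")
  lapply(split(seq_len(nrow(atoms)), factor(key, levels = unique(key))), function(i) {
    g <- atoms[i, , drop = FALSE]
    structure(list(
      het_code = g$resid[1L],
      chain_id = g$chain[1L],
      resno = g$resno[1L],
      atom_names = g$name,
      xyz = unname(as.matrix(g[, c("x", "y", "z")]))
    ), class = "ligand_group")
  })
}

#' @export
print.ligand_group <- function(x, ...) {
  cat("Ligand ", x$het_code, " (chain ", x$chain_id, ", residue ", x$resno,
      "): ", nrow(x$xyz), " heavy atom(s)\n", sep = "")
  invisible(x)
}

pdb_atom_line <- function(serial, name, resid, chain, resno, xyz,
                          record = "ATOM") {
  # PDB convention: atom names of <4 characters start in column 14
  nm <- if (nchar(name) < 4L) paste0(" ", name) else name
  sprintf("%-6s%5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
          record, serial, nm, resid, chain, resno,
          xyz[1L], xyz[2L], xyz[3L], 1, 0)
}

#' Write a C-alpha chain as minimal PDB text
#'
#' Emits one ATOM record per residue (C-alpha only). Intended for fixtures
#' and round-trip testing, not for deposition-grade output.
#'
#' @param chain A \code{calpha_chain}.
#' @param path Optional file path; when \code{NULL} the text is returned.
#' @return Invisibly (or visibly, when \code{path} is \code{NULL}) a
#'   character vector of PDB lines.
#' @export
write_calpha_pdb <- function(chain, path = NULL) {
  stopifnot(inherits(chain, "calpha_chain"))
  lines <- vapply(seq_len(chain$n), function(i) {
    pdb_atom_line(i, "CA", chain$resid[i], chain$chain_id, chain$resno[i],
                  chain$xyz[i, ])
  }, "")
  lines <- c(lines, "TER", "END")
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}
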