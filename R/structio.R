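# Structure parsing: protein chains, chlorophyll cofactors with named ring
# atom groups, and alignment-column-to-residue mapping.

# default chemical-component ids treated as chlorophyll. Chl f is deposited
# as component CLA in the FRL-PSI structures, so CLA covers both.
CHL_COMPONENTS <- c("CLA", "CHL", "CL0", "CL7", "F6C", "G9R", "BCL")

#' Ring definitions for the chlorophyll tetrapyrrole
#'
#' Atom-name groups for the four pyrrole rings A-D (each containing its
#' nitrogen NA-ND) and the isocyclic ring E, in chemical-component
#' dictionary style naming. The 13\eqn{^1}-keto oxygen of ring E is `OBD`.
#' Ring membership is configuration: structures deposited with different
#' naming can supply their own list.
#'
#' @return Named list of character vectors, one per ring label A-E.
#' @export
ring_definitions <- function() {
  list(A = c("NA", "C1A", "C2A", "C3A", "C4A"),
       B = c("NB", "C1B", "C2B", "C3B", "C4B"),
       C = c("NC", "C1C", "C2C", "C3C", "C4C"),
       D = c("ND", "C1D", "C2D", "C3D", "C4D"),
       E = c("CAD", "CBD", "OBD", "CGD"))
}

PYRROLE_NITROGENS <- c("NA", "NB", "NC", "ND")

#' Read a macromolecular structure (PDB or mmCIF)
#'
#' Wraps the bio3d readers into a light container: an atom table split into
#' protein chains and recognized cofactors. The first model is used; the
#' highest-occupancy altloc wins (ties: altloc `A`). Chlorophyll cofactors
#' lacking any of the four pyrrole nitrogens are kept but flagged, and
#' excluded from ring geometry.
#'
#' @param path PDB (`.pdb`) or mmCIF (`.cif`) file.
#' @param structure_id Identifier stored with the model (default: file base
#'   name).
#' @param chl_components Component ids recognized as chlorophyll.
#' @return Object of class `structure_model`: `structure_id`, `atoms` (data
#'   frame with chain, resno, insert, resid, elety, elesy, x, y, z, het),
#'   and `cofactors` (data frame: resid, chain, resno, complete).
#' @export
read_structure <- function(path, structure_id = NULL,
                           chl_components = CHL_COMPONENTS) {
  if (is.null(structure_id))
    structure_id <- sub("\\.(pdb|cif|ent)$", "", basename(path),
                        ignore.case = TRUE)
  is_cif <- grepl("\\.cif$", path, ignore.case = TRUE)
  pdb <- tryCatch(
    if (is_cif) bio3d::read.cif(path) else bio3d::read.pdb(path),
    error = function(e) stop("cannot parse structure file '", path,
                             "': ", conditionMessage(e)))
  at <- pdb$atom
  # altloc resolution: keep highest occupancy per (chain, resno, insert,
  # resid, elety); ties resolved towards the alphabetically first altloc
  alt <- at$alt; alt[is.na(alt)] <- ""
  occ <- at$o; occ[is.na(occ)] <- 1
  key <- paste(at$chain, at$resno, at$insert, at$resid, at$elety, sep = "|")
  ord <- order(key, -occ, alt)
  at <- at[ord, , drop = FALSE]
  at <- at[!duplicated(paste(at$chain, at$resno, at$insert, at$resid,
                             at$elety, sep = "|")), , drop = FALSE]
  at <- at[order(at$chain, at$resno, at$eleno), , drop = FALSE]
  if (any(!is.finite(at$x) | !is.finite(at$y) | !is.finite(at$z)))
    stop("non-finite coordinates in ", path)
  atoms <- data.frame(chain = at$chain, resno = at$resno,
                      insert = ifelse(is.na(at$insert), "", at$insert),
                      resid = at$resid, elety = at$elety,
                      elesy = at$elesy, x = at$x, y = at$y, z = at$z,
                      het = at$type == "HETATM",
                      stringsAsFactors = FALSE)
  cof_rows <- atoms$resid %in% chl_components
  cof <- unique(atoms[cof_rows, c("resid", "chain", "resno")])
  if (nrow(cof)) {
    cof$complete <- vapply(seq_len(nrow(cof)), function(i) {
      sub <- atoms[atoms$resid == cof$resid[i] & atoms$chain == cof$chain[i] &
                     atoms$resno == cof$resno[i], ]
      all(PYRROLE_NITROGENS %in% sub$elety)
    }, logical(1L))
    if (any(!cof$complete))
      warning(structure_id, ": chlorophyll cofactor(s) missing pyrrole ",
              "nitrogens excluded from geometry: ",
              paste(cof$chain[!cof$complete], cof$resno[!cof$complete],
                    sep = ":", collapse = ", "))
  } else {
    cof$complete <- logical(0)
  }
  rownames(cof) <- NULL
  structure(list(structure_id = structure_id, atoms = atoms,
                 cofactors = cof),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  prot <- x$atoms[!x$atoms$het, ]
  cat("Structure", x$structure_id, "-",
      length(unique(prot$chain)), "protein chain(s),",
      nrow(x$atoms), "atoms,", nrow(x$cofactors), "chlorophyll cofactor(s)\n")
  invisible(x)
}

#' Write a structure model as a PDB file
#'
#' @param struct A `structure_model`.
#' @param path Output path.
#' @export
write_structure <- function(struct, path) {
  a <- struct$atoms
  bio3d::write.pdb(file = path,
                   type = ifelse(a$het, "HETATM", "ATOM"),
                   resno = a$resno, resid = a$resid, chain = a$chain,
                   elety = a$elety, elesy = a$elesy,
                   xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))))
  invisible(path)
}

# atoms of one cofactor
.cofactor_atoms <- function(struct, chain, resno, resid = NULL) {
  a <- struct$atoms
  sel <- a$chain == chain & a$resno == resno & a$het
  if (!is.null(resid)) sel <- sel & a$resid == resid
  out <- a[sel, , drop = FALSE]
  if (nrow(out) == 0L)
    stop("structure ", struct$structure_id, ": no cofactor at ",
         chain, ":", resno)
  out
}

#' One-letter sequence of the observed residues of a protein chain
#'
#' @param struct A `structure_model`.
#' @param chain Chain id.
#' @return List with `sequence` (character scalar) and `resno` (author
#'   residue numbers, one per residue, in order).
#' @export
chain_sequence <- function(struct, chain) {
  a <- struct$atoms
  a <- a[a$chain == chain & !a$het, , drop = FALSE]
  if (nrow(a) == 0L) stop("no protein chain '", chain, "' in structure ",
                          struct$structure_id)
  res <- unique(a[, c("resno", "insert", "resid")])
  res <- res[order(res$resno, res$insert), , drop = FALSE]
  one <- bio3d::aa321(res$resid)
  one[is.na(one)] <- "X"
  list(sequence = paste(one, collapse = ""), resno = res$resno)
}

#' Map alignment columns of one row to residues of a structure chain
#'
#' Globally aligns the ungapped alignment row to the chain's observed
#' sequence and returns the column-to-author-residue-number map. Residues
#' not modeled in the structure (e.g. flexible loops) are simply absent
#' from the map. The mapped span must agree at `min_identity` or better.
#'
#' @param id Sequence id (a row of `aln`).
#' @param aln A [grouped_alignment()].
#' @param struct A `structure_model`.
#' @param chain Chain id.
#' @param min_identity Minimum identity over aligned (mapped) positions,
#'   default 0.95.
#' @return Data frame of class `structure_residue_map`: `column`, `chain`,
#'   `resno`; attribute `identity` records the observed identity.
#' @export
map_alignment_to_chain <- function(id, aln, struct, chain,
                                   min_identity = 0.95) {
  cm <- column_map(aln, id)
  row_seq <- gsub("-", "", aln$seq[[id]], fixed = TRUE)
  cs <- chain_sequence(struct, chain)
  if (nchar(cs$sequence) < 20L)
    stop("chain ", chain, " has fewer than 20 observed residues")
  al <- .align_global(row_seq, cs$sequence)
  ca <- strsplit(al$a, "")[[1L]]; cb <- strsplit(al$b, "")[[1L]]
  ia <- cumsum(ca != "-"); ib <- cumsum(cb != "-")
  both <- ca != "-" & cb != "-"
  n_id <- sum(ca[both] == cb[both] & ca[both] != "X")
  identity <- n_id / sum(both)
  if (identity < min_identity)
    stop("chain does not match alignment row: identity ",
         sprintf("%.1f%%", 100 * identity), " < ",
         sprintf("%.0f%%", 100 * min_identity), " for ", id, " vs chain ",
         chain)
  map <- data.frame(column = cm$column[ia[both]], chain = chain,
                    resno = cs$resno[ib[both]])
  attr(map, "identity") <- identity
  class(map) <- c("structure_residue_map", class(map))
  map
}

#' Read a chlorophyll-site definition table
#'
#' Tab-separated columns: `structure_id`, `site_name`, `chain`, `resnum`,
#' `component_id` — naming each candidate chlorophyll site's cofactor in
#' each structure.
#'
#' @param path TSV path.
#' @return Data frame.
#' @export
read_site_table <- function(path) {
  read.table(path, sep = "\t", header = TRUE, comment.char = "#",
             stringsAsFactors = FALSE, quote = "")
}
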