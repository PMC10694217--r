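# Integration of specificity, ancestral conservation and structural
# evidence into per-chlorophyll-site ancestral yes/no calls.

#' Read a chlorophyll-site support configuration
#'
#' Tab-separated columns: `site` (site name, e.g. `B7`), `subunit` (name of
#' the alignment the residue lives in), `column` (1-based alignment
#' column), `role` (one of `hbond_donor`, `cavity`, `stabilizer`). Lines
#' starting with `#` are comments.
#'
#' @param path TSV path.
#' @return Data frame.
#' @export
read_site_config <- function(path) {
  cfg <- read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE, quote = "")
  need <- c("site", "subunit", "column", "role")
  if (!all(need %in% names(cfg)))
    stop("site config must have columns: ", paste(need, collapse = ", "))
  bad <- setdiff(cfg$role, c("hbond_donor", "cavity", "stabilizer"))
  if (length(bad)) stop("unknown role(s): ", paste(bad, collapse = ", "))
  cfg
}

#' Read a structure-evidence table
#'
#' Tab-separated matrix of extant structural evidence: one row per
#' structure, one column per site, entries `Y`/`N` recording whether the
#' site shows the FRL-specific feature (chlorophyll-f occupancy or cofactor
#' rotation) in that structure.
#'
#' @param path TSV path with a `structure` id column.
#' @return Data frame with structure ids as rownames.
#' @export
read_site_evidence <- function(path) {
  ev <- read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                   stringsAsFactors = FALSE, quote = "",
                   check.names = FALSE)
  rownames(ev) <- ev$structure
  ev$structure <- NULL
  ev
}

#' Ancestral chlorophyll-site calls from residue-level evidence
#'
#' Integrates column classifications and ancestral conservation into a
#' per-site ancestral `Y`/`N` call. A site is called ancestral (`Y`) iff
#' every supporting residue with role `hbond_donor` or `cavity` is
#' `GROUP_SPECIFIC` *and* ancestral-conserved, and at least
#' `required_fraction` of its `stabilizer` residues are ancestral-conserved
#' (vacuously satisfied for sites without stabilizers). A site configured
#' with no supporting residues is called `N` with rationale "no evidence".
#'
#' @param site_config Data frame as from [read_site_config()].
#' @param classifications Named list of scored `column_classification`
#'   objects (as returned in `$classifications` by
#'   [score_ancestral_conservation()]), one per subunit.
#' @param required_fraction Minimum conserved fraction of stabilizers
#'   (default 0.5).
#' @param evidence Optional extant-evidence data frame (see
#'   [read_site_evidence()]) carried through to the output.
#' @param sites Optional character vector fixing the site order; default:
#'   order of first appearance in `site_config`.
#' @return Object of class `chl_site_assignment`: data frame with `site`,
#'   `ancestral_call`, support counts and a `rationale`; the evidence table
#'   (if given) is attached as attribute `evidence`.
#' @export
assign_ancestral_sites <- function(site_config, classifications,
                                   required_fraction = 0.5,
                                   evidence = NULL, sites = NULL) {
  if (is.null(sites)) sites <- unique(site_config$site)
  rows <- lapply(sites, function(s) {
    sub <- site_config[site_config$site == s, , drop = FALSE]
    if (nrow(sub) == 0L)
      return(data.frame(site = s, ancestral_call = "N",
                        n_required = 0L, n_required_conserved = 0L,
                        n_stabilizers = 0L, n_stabilizers_conserved = 0L,
                        rationale = "no evidence"))
    conserved <- vapply(seq_len(nrow(sub)), function(i) {
      su <- sub$subunit[i]
      if (!su %in% names(classifications))
        stop("site ", s, ": subunit '", su, "' has no classification")
      cl <- classifications[[su]]
      j <- sub$column[i]
      if (is.na(j) || j < 1L || j > nrow(cl))
        stop("site ", s, ": residue at ", su, " column ", j,
             " cannot be resolved to a classified column")
      cl$status[j] == "GROUP_SPECIFIC" &&
        isTRUE(cl$ancestral_conserved[j])
    }, logical(1L))
    req <- sub$role %in% c("hbond_donor", "cavity")
    stab <- sub$role == "stabilizer"
    req_ok <- all(conserved[req])
    stab_ok <- if (any(stab))
      mean(conserved[stab]) >= required_fraction else TRUE
    call <- if (sum(req) + sum(stab) == 0L) "N"
      else if (req_ok && stab_ok) "Y" else "N"
    rationale <- if (call == "Y")
      sprintf("all %d required residue(s) and %d/%d stabilizer(s) ancestral-conserved",
              sum(req), sum(conserved[stab]), sum(stab))
    else if (!req_ok)
      sprintf("%d/%d required residue(s) not ancestral-conserved",
              sum(!conserved[req]), sum(req))
    else
      sprintf("only %d/%d stabilizer(s) ancestral-conserved (need >= %.0f%%)",
              sum(conserved[stab]), sum(stab), 100 * required_fraction)
    data.frame(site = s, ancestral_call = call,
               n_required = sum(req), n_required_conserved = sum(conserved[req]),
               n_stabilizers = sum(stab),
               n_stabilizers_conserved = sum(conserved[stab]),
               rationale = rationale)
  })
  out <- do.call(rbind, rows)
  attr(out, "evidence") <- evidence
  class(out) <- c("chl_site_assignment", class(out))
  out
}

#' Site matrix: structures x sites plus the ancestral row
#'
#' Produces the summary matrix of chlorophyll-site evidence: one `Y`/`N`
#' row per extant structure (from the evidence table) and a final
#' `Ancestral` row from the residue-conservation calls.
#'
#' @param assignments A `chl_site_assignment`.
#' @param evidence Extant-evidence data frame; defaults to the one attached
#'   to `assignments`.
#' @return Character matrix with structures + `Ancestral` as rows and sites
#'   as columns.
#' @export
site_matrix <- function(assignments, evidence = attr(assignments, "evidence")) {
  sites <- assignments$site
  anc <- setNames(assignments$ancestral_call, sites)
  if (is.null(evidence)) {
    m <- matrix(anc, nrow = 1, dimnames = list("Ancestral", sites))
    return(m)
  }
  common <- intersect(sites, colnames(evidence))
  m <- rbind(as.matrix(evidence[, sites[sites %in% common], drop = FALSE]),
             Ancestral = anc[common])
  missing <- setdiff(sites, common)
  if (length(missing)) {
    extra <- matrix(NA_character_, nrow(m), length(missing),
                    dimnames = list(rownames(m), missing))
    extra["Ancestral", ] <- anc[missing]
    m <- cbind(m, extra)[, sites, drop = FALSE]
  }
  m
}

#' Write a site matrix as TSV
#'
#' @param m Matrix from [site_matrix()].
#' @param path Output path.
#' @export
write_site_matrix <- function(m, path) {
  df <- data.frame(structure = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
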