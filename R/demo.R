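# Synthetic chlorophyll-site demonstration: per-subunit alignments whose
# planted column patterns follow the residue-level evidence described for
# the eight candidate sites, so that the ancestral site calls are computed,
# not asserted.

# plant one column pattern into a residue matrix and the ancestor vector.
# types:
#   specific          FRL all one residue, VL another; ancestor retains it
#   specific_derived  as above but the ancestor keeps the VL residue
#   class             FRL a two-residue similarity-class mix, VL outside it
#   half_split        FRL half new residue, half the VL residue (no call)
.plant <- function(mat, anc, col, type, frl_rows, vl_rows,
                   frl_res, vl_res, frl_res2 = NULL) {
  switch(type,
    specific = {
      mat[frl_rows, col] <- frl_res
      mat[vl_rows, col] <- vl_res
      anc[col] <- frl_res
    },
    specific_derived = {
      mat[frl_rows, col] <- frl_res
      mat[vl_rows, col] <- vl_res
      anc[col] <- vl_res
    },
    class = {
      mat[frl_rows, col] <- sample(c(frl_res, frl_res2),
                                   length(frl_rows), replace = TRUE)
      mat[vl_rows, col] <- vl_res
      anc[col] <- sort(c(frl_res, frl_res2))[1L]
    },
    half_split = {
      half <- seq_len(floor(length(frl_rows) / 2))
      mat[frl_rows, col] <- vl_res
      mat[frl_rows[half], col] <- frl_res
      mat[vl_rows, col] <- vl_res
      anc[col] <- vl_res
    },
    stop("unknown pattern type: ", type))
  list(mat = mat, anc = anc)
}

#' Synthetic chlorophyll-site demonstration dataset
#'
#' Generates one small grouped alignment per FRL-specific subunit (PsaA2,
#' PsaB2, PsaF2, PsaI2, PsaJ2, PsaL2) together with a true ancestral
#' sequence and a site-support configuration for the eight candidate
#' chlorophyll sites (A0B_rotation, B7, B37, B38, B30, A21, A23, B19). The
#' planted column patterns emulate the kinds of residue evidence seen at
#' each site in FRL photosystem I:
#'
#' * B7, B37, B30 and the A0B rotation are supported by group-specific
#'   residues that the ancestor retains (including a Val/Ile
#'   similarity-class column and a Ser-for-Gly substitution at the A0B
#'   supports);
#' * B38's cavity position is a Trp-to-Phe replacement present in only
#'   half of the FRL sequences, with the ancestor keeping Trp;
#' * A21's backbone donor is conserved, but only a third of its
#'   surrounding loop stabilizers are ancestral;
#' * A23 and B19 are supported by columns with no group signal.
#'
#' Feeding this dataset through [classify_columns()],
#' [score_ancestral_conservation()] and [assign_ancestral_sites()] yields
#' an ancestral call per site that emerges from the residue-level rules.
#'
#' @param seed RNG seed.
#' @param n_frl,n_vl Sequences per group in every subunit alignment.
#' @param n_columns Columns per subunit alignment (default 60).
#' @return List: `alignments` (named list of [grouped_alignment()]),
#'   `ancestors` (named character vector of true ancestral sequences),
#'   `site_config` (data frame for [assign_ancestral_sites()]), `sites`
#'   (site order), `patterns` (the planted-pattern table).
#' @export
generate_site_demo <- function(seed = 1L, n_frl = 30L, n_vl = 30L,
                               n_columns = 60L) {
  set.seed(seed)
  subunits <- c("PsaA2", "PsaB2", "PsaF2", "PsaI2", "PsaJ2", "PsaL2")
  bg <- substitution_model("LG")$pi
  frl_rows <- seq_len(n_frl)
  vl_rows <- n_frl + seq_len(n_vl)

  # planted patterns: subunit, column, type, residues, and the site/role
  # each column supports
  pat <- rbind(
    # A0B rotation: Val/Ile-for-Thr, Ser-for-Gly, Thr-for-Ser, all ancestral
    data.frame(subunit = "PsaB2", column = 20, type = "class",
               frl = "V", frl2 = "I", vl = "T",
               site = "A0B_rotation", role = "cavity"),
    data.frame(subunit = "PsaB2", column = 21, type = "specific",
               frl = "S", frl2 = NA, vl = "G",
               site = "A0B_rotation", role = "hbond_donor"),
    data.frame(subunit = "PsaB2", column = 25, type = "specific",
               frl = "T", frl2 = NA, vl = "S",
               site = "A0B_rotation", role = "hbond_donor"),
    # B7: two Tyr donors plus seven stabilizers, all ancestral
    data.frame(subunit = "PsaI2", column = 27, type = "specific",
               frl = "Y", frl2 = NA, vl = "F",
               site = "B7", role = "hbond_donor"),
    data.frame(subunit = "PsaL2", column = 50, type = "specific",
               frl = "Y", frl2 = NA, vl = "L",
               site = "B7", role = "hbond_donor"),
    data.frame(subunit = rep(c("PsaI2", "PsaL2"), c(4, 3)),
               column = c(10, 12, 14, 16, 10, 12, 14), type = "specific",
               frl = c("A", "G", "S", "T", "L", "V", "F"), frl2 = NA,
               vl = c("S", "A", "G", "A", "F", "A", "Y"),
               site = "B7", role = "stabilizer"),
    # B37: backbone Gly donor and the flipped Gln donor, Ala cavity,
    # five loop stabilizers, all ancestral
    data.frame(subunit = "PsaB2", column = 40, type = "specific",
               frl = "G", frl2 = NA, vl = "A",
               site = "B37", role = "hbond_donor"),
    data.frame(subunit = "PsaB2", column = 45, type = "specific",
               frl = "Q", frl2 = NA, vl = "I",
               site = "B37", role = "hbond_donor"),
    data.frame(subunit = "PsaB2", column = 41, type = "specific",
               frl = "A", frl2 = NA, vl = "N",
               site = "B37", role = "cavity"),
    data.frame(subunit = "PsaL2", column = c(30, 32, 34, 36, 38),
               type = "specific", frl = c("P", "D", "G", "N", "S"),
               frl2 = NA, vl = c("A", "G", "D", "S", "T"),
               site = "B37", role = "stabilizer"),
    # B38: Trp-to-Phe cavity in only half the FRL sequences; ancestor Trp
    data.frame(subunit = "PsaB2", column = 22, type = "half_split",
               frl = "F", frl2 = NA, vl = "W",
               site = "B38", role = "cavity"),
    # B30: Tyr donor with Glu and Leu stabilizers, all ancestral
    data.frame(subunit = "PsaF2", column = 49, type = "specific",
               frl = "Y", frl2 = NA, vl = "G",
               site = "B30", role = "hbond_donor"),
    data.frame(subunit = "PsaB2", column = 47, type = "specific",
               frl = "E", frl2 = NA, vl = "Q",
               site = "B30", role = "stabilizer"),
    data.frame(subunit = "PsaJ2", column = 31, type = "specific",
               frl = "L", frl2 = NA, vl = "N",
               site = "B30", role = "stabilizer"),
    # A21: conserved backbone donor but only 2 of 6 loop stabilizers
    # ancestral
    data.frame(subunit = "PsaA2", column = 10, type = "specific",
               frl = "L", frl2 = NA, vl = "M",
               site = "A21", role = "hbond_donor"),
    data.frame(subunit = "PsaA2", column = c(11, 12),
               type = "specific", frl = c("G", "P"), frl2 = NA,
               vl = c("D", "E"), site = "A21", role = "stabilizer"),
    data.frame(subunit = "PsaA2", column = c(13, 14, 15, 16),
               type = "specific_derived", frl = c("S", "T", "N", "D"),
               frl2 = NA, vl = c("A", "G", "K", "R"),
               site = "A21", role = "stabilizer"))
  # A23 and B19: supported only by columns left as background (no group
  # signal), so their calls must come out N
  extra <- rbind(
    data.frame(subunit = "PsaA2", column = 30, type = "background",
               frl = NA, frl2 = NA, vl = NA, site = "A23",
               role = "hbond_donor"),
    data.frame(subunit = "PsaB2", column = 55, type = "background",
               frl = NA, frl2 = NA, vl = NA, site = "B19",
               role = "hbond_donor"))
  pat <- rbind(pat, extra)

  alignments <- list()
  ancestors <- character(0)
  for (su in subunits) {
    mat <- matrix(AA20[sample.int(20, (n_frl + n_vl) * n_columns,
                                  replace = TRUE, prob = bg)],
                  nrow = n_frl + n_vl)
    anc <- AA20[sample.int(20, n_columns, replace = TRUE, prob = bg)]
    for (i in which(pat$subunit == su & pat$type != "background")) {
      pl <- .plant(mat, anc, pat$column[i], pat$type[i], frl_rows, vl_rows,
                   pat$frl[i], pat$vl[i], pat$frl2[i])
      mat <- pl$mat; anc <- pl$anc
    }
    ids <- c(sprintf("%s_frl%02d", su, frl_rows),
             sprintf("%s_vl%02d", su, seq_len(n_vl)))
    seqs <- setNames(apply(mat, 1, paste, collapse = ""), ids)
    groups <- setNames(rep(c("FRL", "VL"), c(n_frl, n_vl)), ids)
    alignments[[su]] <- grouped_alignment(seqs, groups)
    ancestors[su] <- paste(anc, collapse = "")
  }
  sites <- c("A0B_rotation", "B7", "B37", "B38", "B30", "A21", "A23", "B19")
  list(alignments = alignments, ancestors = ancestors,
       site_config = pat[, c("site", "subunit", "column", "role")],
       sites = sites, patterns = pat)
}

#' Run the site demonstration end to end
#'
#' Classifies every subunit alignment of [generate_site_demo()], scores
#' ancestral conservation against the demo's true ancestors, and derives
#' the ancestral chlorophyll-site calls.
#'
#' @param demo Output of [generate_site_demo()].
#' @param rule A [specificity_rule()].
#' @param required_fraction Stabilizer threshold for
#'   [assign_ancestral_sites()].
#' @return List: `assignments` (a `chl_site_assignment`), `matrix` (the
#'   structures-by-sites evidence matrix with the computed `Ancestral`
#'   row), `classified` (per-subunit scored classifications),
#'   `conservation` (pooled n_specific / n_conserved / fraction).
#' @export
run_site_demo <- function(demo, rule = specificity_rule(),
                          required_fraction = 0.5) {
  classified <- list()
  n_spec <- 0L; n_cons <- 0L
  for (su in names(demo$alignments)) {
    cols <- classify_columns(demo$alignments[[su]], rule)
    sc <- score_ancestral_conservation(cols, demo$ancestors[[su]])
    classified[[su]] <- sc$classifications
    n_spec <- n_spec + sc$n_specific
    n_cons <- n_cons + sc$n_conserved
  }
  evidence_path <- system.file("extdata", "frl_psi_site_evidence.tsv",
                               package = "frlpsi")
  evidence <- if (nzchar(evidence_path)) read_site_evidence(evidence_path)
    else NULL
  asg <- assign_ancestral_sites(demo$site_config, classified,
                                required_fraction = required_fraction,
                                evidence = evidence, sites = demo$sites)
  list(assignments = asg, matrix = site_matrix(asg),
       classified = classified,
       conservation = list(n_specific = n_spec, n_conserved = n_cons,
                           fraction = if (n_spec) n_cons / n_spec else NA))
}
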