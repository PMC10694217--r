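# Synthetic-data generators: every pipeline stage can be exercised against
# known ground truth without any external download.

#' Generate a grouped alignment with planted group-specific columns
#'
#' Background columns are i.i.d. draws from `background_freqs` shared
#' across groups (so they carry no group signal). Planted columns are
#' group-disjoint by construction: every FRL sequence receives the planted
#' FRL residue (or a member of the planted similarity class) and every VL
#' sequence a different residue, so each planted column satisfies the
#' default [specificity_rule()]. A true ancestral sequence is emitted
#' alongside: at a planted column it carries the FRL residue when the
#' column is marked retained and the VL residue otherwise, emulating
#' residues that became group-specific only after the ancestor.
#'
#' @param n_frl,n_vl Sequences per group (defaults 30/30).
#' @param n_columns Alignment length (default 200).
#' @param n_specific Number of planted group-specific columns (default 10).
#' @param retained_fraction Fraction of planted columns whose FRL residue
#'   the emitted ancestor retains (default 0.7).
#' @param n_class_planted How many planted columns are conserved as a
#'   two-residue similarity class (e.g. Val/Ile) instead of a single
#'   residue (default 0).
#' @param background_freqs Length-20 equilibrium frequencies (PAML order);
#'   default: LG frequencies.
#' @param seed RNG seed; identical seed and parameters give identical
#'   output.
#' @return List: `aln` (a [grouped_alignment()]), `truth` (data frame:
#'   `column`, `frl_residues`, `vl_residue`, `class_planted`,
#'   `ancestral_retained`), `ancestral_sequence`.
#' @export
generate_grouped_alignment <- function(n_frl = 30L, n_vl = 30L,
                                       n_columns = 200L, n_specific = 10L,
                                       retained_fraction = 0.7,
                                       n_class_planted = 0L,
                                       background_freqs = NULL,
                                       seed = 1L) {
  if (n_specific > n_columns)
    stop("cannot plant ", n_specific, " specific columns in ", n_columns)
  if (n_class_planted > n_specific)
    stop("n_class_planted cannot exceed n_specific")
  set.seed(seed)
  if (is.null(background_freqs))
    background_freqs <- substitution_model("LG")$pi
  stopifnot(length(background_freqs) == 20)

  n_seq <- n_frl + n_vl
  mat <- matrix(AA20[replicate(n_columns,
                               sample.int(20, n_seq, replace = TRUE,
                                          prob = background_freqs))],
                nrow = n_seq)
  planted <- sort(sample.int(n_columns, n_specific))
  class_cols <- if (n_class_planted > 0)
    planted[sample.int(n_specific, n_class_planted)] else integer(0)
  frl_rows <- seq_len(n_frl)
  vl_rows <- n_frl + seq_len(n_vl)
  anc <- AA20[sample.int(20, n_columns, replace = TRUE,
                         prob = background_freqs)]
  retained <- rep(FALSE, n_specific)
  if (n_specific > 0)
    retained[sample.int(n_specific, round(retained_fraction * n_specific))] <-
      TRUE
  truth_frl <- truth_vl <- character(n_specific)
  for (i in seq_along(planted)) {
    j <- planted[i]
    if (j %in% class_cols) {
      cls <- SIMILARITY_CLASSES[[sample.int(length(SIMILARITY_CLASSES), 1L)]]
      pair <- sample(cls, 2L)
      vl_res <- sample(setdiff(AA20, cls), 1L)
      mat[frl_rows, j] <- sample(pair, n_frl, replace = TRUE)
      truth_frl[i] <- paste(sort(pair), collapse = ",")
      anc[j] <- if (retained[i]) sort(pair)[1L] else vl_res
    } else {
      frl_res <- sample(AA20, 1L)
      vl_res <- sample(setdiff(AA20, frl_res), 1L)
      mat[frl_rows, j] <- frl_res
      truth_frl[i] <- frl_res
      anc[j] <- if (retained[i]) frl_res else vl_res
    }
    mat[vl_rows, j] <- vl_res
    truth_vl[i] <- vl_res
  }
  ids <- c(sprintf("frl%03d", seq_len(n_frl)), sprintf("vl%03d", seq_len(n_vl)))
  seqs <- setNames(apply(mat, 1, paste, collapse = ""), ids)
  groups <- setNames(rep(c("FRL", "VL"), c(n_frl, n_vl)), ids)
  list(aln = grouped_alignment(seqs, groups),
       truth = data.frame(column = planted, frl_residues = truth_frl,
                          vl_residue = truth_vl,
                          class_planted = planted %in% class_cols,
                          ancestral_retained = retained),
       ancestral_sequence = paste(anc, collapse = ""))
}

#' Generate a random tree and sequences simulated down it
#'
#' Topology from a uniform random rooted tree (or a fully balanced one),
#' branch lengths uniform in `branch_range`; sequences by
#' [simulate_evolution()]. All internal-node sequences — in particular the
#' true root — are returned as ground truth for testing ancestral
#' reconstruction.
#'
#' @param n_leaves Number of leaves (default 12).
#' @param n_sites Sites (default 300).
#' @param model A [substitution_model()] (default LG).
#' @param branch_range Branch-length range in substitutions/site (default
#'   0.05-0.3).
#' @param topology `"random"` or `"balanced"` (n_leaves a power of 2).
#' @param seed RNG seed.
#' @return List: `tree` (rooted `phylo`), `aln` (leaf
#'   [grouped_alignment()], all labelled FRL), `node_seqs`,
#'   `root_sequence`.
#' @export
generate_tree_and_sequences <- function(n_leaves = 12L, n_sites = 300L,
                                        model = substitution_model("LG"),
                                        branch_range = c(0.05, 0.3),
                                        topology = c("random", "balanced"),
                                        seed = 1L) {
  topology <- match.arg(topology)
  set.seed(seed)
  tree <- if (topology == "balanced")
    ape::stree(n_leaves, type = "balanced") else ape::rtree(n_leaves, br = NULL)
  tree$edge.length <- runif(nrow(tree$edge), branch_range[1L], branch_range[2L])
  tree$tip.label <- sprintf("t%02d", seq_len(n_leaves))
  sim <- simulate_evolution(tree, model, n_sites)
  groups <- setNames(rep("FRL", n_leaves), tree$tip.label)
  list(tree = tree, aln = grouped_alignment(sim$leaf_seqs, groups),
       node_seqs = sim$node_seqs, root_sequence = sim$root_sequence)
}

# element symbol from a CCD-style atom name
.elesy_of <- function(elety) {
  ifelse(elety == "MG", "MG", substr(gsub("[0-9']", "", elety), 1L, 1L))
}

.make_structure <- function(atoms, structure_id) {
  atoms$elesy <- .elesy_of(atoms$elety)
  cof <- unique(atoms[atoms$het, c("resid", "chain", "resno")])
  if (nrow(cof)) {
    cof$complete <- vapply(seq_len(nrow(cof)), function(i) {
      sub <- atoms[atoms$chain == cof$chain[i] & atoms$resno == cof$resno[i], ]
      all(PYRROLE_NITROGENS %in% sub$elety)
    }, logical(1L))
  } else cof$complete <- logical(0)
  rownames(cof) <- NULL
  structure(list(structure_id = structure_id, atoms = atoms, cofactors = cof),
            class = "structure_model")
}

#' Idealized planar chlorin template
#'
#' A hand-built synthetic chlorophyll head group lying in the z = 0 plane,
#' with chemical-component-dictionary style atom names: four pyrrole rings
#' A-D (nitrogens `NA`-`ND` facing a central `MG`), and the isocyclic ring
#' E (atoms `CAD`, `CBD`, `CGD` with the 13-1 keto oxygen `OBD`) fused
#' beyond ring C. It mimics only local tetrapyrrole geometry, not real
#' chlorophyll coordinates, and is the basis of all synthetic rotation
#' fixtures.
#'
#' @param chain Chain id (default `"X"`).
#' @param resno Residue number (default 501).
#' @return Data frame of atoms (chain, resno, insert, resid, elety, x, y,
#'   z, het).
#' @export
chlorin_template <- function(chain = "X", resno = 501L) {
  rows <- list(data.frame(elety = "MG", x = 0, y = 0, z = 0))
  # pyrrole rings A-D at 90 degree intervals; one pentagon vertex (the
  # nitrogen) points at the ring center
  dirs <- c(A = 90, B = 0, C = 270, D = 180) * pi / 180
  for (r in names(dirs)) {
    th <- dirs[[r]]
    ctr <- 3.2 * c(cos(th), sin(th))
    vang <- th + pi + (0:4) * 2 * pi / 5
    vx <- ctr[1] + 1.19 * cos(vang)
    vy <- ctr[2] + 1.19 * sin(vang)
    nm <- c(paste0("N", r), paste0("C", c(1, 2, 3, 4), r))
    rows[[length(rows) + 1L]] <- data.frame(elety = nm, x = vx, y = vy, z = 0)
  }
  # isocyclic ring E fused beyond ring C, with the keto oxygen OBD
  thC <- dirs[["C"]]
  ectr <- 5.6 * c(cos(thC), sin(thC))
  eang <- thC + pi + (0:2) * 2 * pi / 3
  rows[[length(rows) + 1L]] <- data.frame(
    elety = c("CAD", "CBD", "CGD"),
    x = ectr[1] + 1.1 * cos(eang), y = ectr[2] + 1.1 * sin(eang), z = 0)
  cad <- c(ectr[1] + 1.1 * cos(eang[1]), ectr[2] + 1.1 * sin(eang[1]))
  ob <- cad + 1.23 * c(cos(thC), sin(thC))
  rows[[length(rows) + 1L]] <- data.frame(elety = "OBD",
                                          x = ob[1], y = ob[2], z = 0)
  at <- do.call(rbind, rows)
  data.frame(chain = chain, resno = resno, insert = "", resid = "CLA",
             elety = at$elety, x = at$x, y = at$y, z = at$z, het = TRUE,
             stringsAsFactors = FALSE)
}

# shell of pseudo glycine backbone residues surrounding the template, used
# as the matched atoms for local superposition
.decoy_backbone <- function(n_res = 24L, radius = 13, chain = "A") {
  rows <- list()
  for (i in seq_len(n_res)) {
    th <- 2 * pi * (i - 1) / n_res
    z0 <- 3 * sin(5 * th)              # break coplanarity
    base <- c(radius * cos(th), radius * sin(th), z0)
    offs <- rbind(N = c(0, 0, 0), CA = c(1.0, 0.6, 0.4),
                  C = c(2.1, 0.1, 0.1), O = c(2.6, -0.9, 0.6))
    rows[[i]] <- data.frame(chain = chain, resno = i, insert = "",
                            resid = "GLY", elety = rownames(offs),
                            x = base[1] + offs[, 1], y = base[2] + offs[, 2],
                            z = base[3] + offs[, 3], het = FALSE,
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

# rotate points about an axis (unit vector) through a pivot point
.rotate_about_axis <- function(xyz, axis, pivot, angle_deg) {
  th <- angle_deg * pi / 180
  k <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -k[3], k[2], k[3], 0, -k[1], -k[2], k[1], 0), 3, 3,
              byrow = TRUE)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  sweep(sweep(xyz, 2, pivot) %*% t(R), 2, pivot, "+")
}

#' Generate a reference/rotated pair of synthetic cofactor structures
#'
#' Builds two structures each holding the [chlorin_template()] cofactor
#' plus a surrounding backbone shell. In the mobile copy the cofactor is
#' rotated `rotation_deg` about the macrocycle-plane normal through the
#' pivot ring's centroid, then optionally perturbed with isotropic Gaussian
#' noise. The backbone shell is left in place, so a local superposition of
#' the pair isolates the cofactor motion — the synthetic analogue of
#' comparing the A0B chlorophyll between FRL and VL photosystem I
#' structures.
#'
#' @param rotation_deg True rotation in degrees (default 5).
#' @param pivot_ring Ring label A-E about whose centroid the rotation
#'   pivots (default "E").
#' @param noise_sd Gaussian coordinate noise (angstroms) added to the
#'   mobile cofactor atoms (default 0).
#' @param seed RNG seed (only relevant when `noise_sd > 0`).
#' @return List: `ref` and `mobile` (`structure_model`s), `site` (locator
#'   usable with [measure_cofactor_rotation()]), and `truth`
#'   (`angle_deg`, `pivot_ring`).
#' @export
generate_rotated_cofactor_pair <- function(rotation_deg = 5,
                                           pivot_ring = "E",
                                           noise_sd = 0, seed = 1L) {
  set.seed(seed)
  cof <- chlorin_template()
  bb <- .decoy_backbone()
  ref <- .make_structure(rbind(bb, cof), "synthetic_ref")
  rings <- ring_definitions()
  ring_atoms <- cof[cof$elety %in% rings[[pivot_ring]], c("x", "y", "z")]
  pivot <- colMeans(as.matrix(ring_atoms))
  xyz <- as.matrix(cof[, c("x", "y", "z")])
  # the template lies in z = 0, so the plane normal is the z axis
  rot <- .rotate_about_axis(xyz, c(0, 0, 1), pivot, rotation_deg)
  if (noise_sd > 0)
    rot <- rot + matrix(rnorm(length(rot), sd = noise_sd), ncol = 3)
  cof_m <- cof
  cof_m[, c("x", "y", "z")] <- rot
  mobile <- .make_structure(rbind(bb, cof_m), "synthetic_mobile")
  list(ref = ref, mobile = mobile,
       site = list(chain = "X", resno = 501L),
       truth = list(angle_deg = rotation_deg, pivot_ring = pivot_ring))
}

#' Generate synthetic residue positions in spatial blobs
#'
#' Draws `n_per_blob` points around each of `n_blobs` well-separated
#' centres — the synthetic analogue of spatial clusters of group-specific
#' residues on a structure.
#'
#' @param n_blobs Number of blobs (default 2).
#' @param n_per_blob Points per blob (default 10).
#' @param separation Distance between blob centres (default 60).
#' @param spread Within-blob standard deviation (default 4).
#' @param seed RNG seed.
#' @return List: `positions` (matrix with rownames `r1`, `r2`, ...) and
#'   `truth` (integer blob assignment per point).
#' @export
generate_cluster_positions <- function(n_blobs = 2L, n_per_blob = 10L,
                                       separation = 60, spread = 4,
                                       seed = 1L) {
  set.seed(seed)
  centers <- cbind(separation * (seq_len(n_blobs) - 1L), 0, 0)
  pos <- do.call(rbind, lapply(seq_len(n_blobs), function(b) {
    sweep(matrix(rnorm(3L * n_per_blob, sd = spread), ncol = 3), 2,
          centers[b, ], "+")
  }))
  rownames(pos) <- sprintf("r%02d", seq_len(nrow(pos)))
  list(positions = pos, truth = rep(seq_len(n_blobs), each = n_per_blob))
}
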