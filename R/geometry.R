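# Rigid superposition, ring-plane fitting, cofactor rotation measurement
# and hydrogen-bond geometry.

.vnorm <- function(v) sqrt(sum(v^2))
.unit <- function(v) v / .vnorm(v)
.deg <- function(rad) rad * 180 / pi
.clamp1 <- function(x) pmin(1, pmax(-1, x))

#' Least-squares rigid superposition (Kabsch algorithm)
#'
#' Finds the proper rotation and translation minimizing the RMSD between
#' matched point sets, via singular value decomposition of the covariance;
#' reflections are excluded by construction (`det(R) = +1`).
#'
#' @param ref,mobile n x 3 coordinate matrices of matched points (row i of
#'   `mobile` pairs with row i of `ref`). At least 3 non-collinear pairs.
#' @return Object of class `superposition`: `rotation` (3 x 3), and
#'   centroids such that the fitted mobile coordinates are
#'   `(x - center_mobile) %*% t(rotation) + center_ref`; plus `translation`,
#'   `rmsd` and `n_atoms_used`.
#' @examples
#' p <- matrix(rnorm(30), 10, 3)
#' superpose(p, p)$rmsd
#' @export
superpose <- function(ref, mobile) {
  ref <- as.matrix(ref); mobile <- as.matrix(mobile)
  stopifnot(ncol(ref) == 3, ncol(mobile) == 3)
  if (nrow(ref) != nrow(mobile)) stop("point sets must be matched 1:1")
  n <- nrow(ref)
  if (n < 3L) stop("need at least 3 matched pairs")
  cr <- colMeans(ref); cm <- colMeans(mobile)
  A <- sweep(ref, 2, cr); B <- sweep(mobile, 2, cm)
  if (svd(B)$d[2] < 1e-8 * max(1, svd(B)$d[1]))
    stop("matched points are collinear; superposition is underdetermined")
  H <- t(B) %*% A
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  fitted <- B %*% t(R)
  rmsd <- sqrt(mean(rowSums((fitted - A)^2)))
  structure(list(rotation = R, center_ref = cr, center_mobile = cm,
                 translation = cr - as.numeric(R %*% cm),
                 rmsd = rmsd, n_atoms_used = n),
            class = "superposition")
}

#' Apply a superposition to coordinates
#'
#' @param sp A `superposition` from [superpose()].
#' @param xyz n x 3 matrix of mobile-frame coordinates.
#' @return Transformed n x 3 matrix.
#' @export
apply_superposition <- function(sp, xyz) {
  xyz <- as.matrix(xyz)
  sweep(sweep(xyz, 2, sp$center_mobile) %*% t(sp$rotation), 2,
        sp$center_ref, "+")
}

#' Rotation angle (degrees) of a superposition or rotation matrix
#'
#' @param x A `superposition` or a 3 x 3 rotation matrix.
#' @return Angle in degrees in \[0, 180\].
#' @export
rotation_angle <- function(x) {
  R <- if (inherits(x, "superposition")) x$rotation else x
  .deg(acos(.clamp1((sum(diag(R)) - 1) / 2)))
}

#' Fit a least-squares plane through atoms
#'
#' The plane through the centroid whose normal is the smallest-singular-
#' value direction of the centered coordinates (total least squares). When
#' the three pyrrole-nitrogen positions `NA`, `NB`, `NC` are supplied the
#' normal's sign is fixed along `(NB-NA) x (NC-NA)`.
#'
#' @param xyz n x 3 coordinates (n >= 3, non-collinear).
#' @param orient Optional 3 x 3 matrix of the NA, NB, NC positions fixing
#'   the normal orientation.
#' @return Object of class `ring_plane`: `centroid`, `normal` (unit),
#'   `rms_residual`.
#' @export
fit_ring_plane <- function(xyz, orient = NULL) {
  xyz <- as.matrix(xyz)
  if (nrow(xyz) < 3L) stop("need at least 3 atoms to fit a plane")
  ctr <- colMeans(xyz)
  X <- sweep(xyz, 2, ctr)
  sv <- svd(X)
  if (sv$d[2] < 1e-8 * max(1, sv$d[1]))
    stop("atoms are collinear; plane is underdetermined")
  normal <- sv$v[, 3L]
  if (!is.null(orient)) {
    ref <- pracma::cross(orient[2L, ] - orient[1L, ],
                         orient[3L, ] - orient[1L, ])
    if (sum(normal * ref) < 0) normal <- -normal
  }
  rms <- sqrt(mean((X %*% normal)^2))
  structure(list(centroid = ctr, normal = .unit(normal), rms_residual = rms),
            class = "ring_plane")
}

# geometry summary of one chlorophyll: ring centroids, macrocycle plane,
# in-plane NA->NC axis
.tetrapyrrole_frame <- function(cof_atoms, rings = ring_definitions()) {
  get_xyz <- function(names) {
    sub <- cof_atoms[match(names, cof_atoms$elety), , drop = FALSE]
    if (anyNA(sub$x)) {
      miss <- names[is.na(sub$x)]
      stop("cofactor lacks ring atoms: ", paste(miss, collapse = ", "))
    }
    as.matrix(sub[, c("x", "y", "z")])
  }
  ring_centroids <- lapply(rings, function(at) colMeans(get_xyz(at)))
  macro_atoms <- get_xyz(unique(unlist(rings[c("A", "B", "C", "D")])))
  nloc <- get_xyz(PYRROLE_NITROGENS)
  plane <- fit_ring_plane(macro_atoms, orient = nloc[1:3, ])
  ax <- nloc[3L, ] - nloc[1L, ]                 # NA -> NC
  ax <- ax - sum(ax * plane$normal) * plane$normal
  list(ring_centroids = ring_centroids, plane = plane,
       in_plane_axis = .unit(ax))
}

#' Measure the rotation of a cofactor between two structures
#'
#' The two structures are first superposed locally: backbone atoms (N, CA,
#' C, O) of residues within `radius` angstroms of the reference cofactor
#' are matched between the structures (by chain, residue number and atom
#' name, or through an explicit residue `pairing`) and fitted by
#' [superpose()]. The mobile cofactor is then transformed into the
#' reference frame and the two tetrapyrroles compared: the reported angle
#' is the angle between the two in-plane NA-to-NC axes after projecting
#' both into the plane bisecting the two macrocycle planes; the pivot ring
#' is the ring whose centroid moves least.
#'
#' @param ref,mobile `structure_model` objects.
#' @param site List locating the cofactor: `chain`, `resno` (and optional
#'   `resid`), either shared or as `ref`/`mobile` sublists with those
#'   fields.
#' @param radius Local superposition radius in angstroms (default 12).
#' @param rings Ring definitions, see [ring_definitions()].
#' @param pairing Optional data frame with columns `ref_chain, ref_resno,
#'   mob_chain, mob_resno` pairing backbone residues explicitly (for
#'   structures with different numbering).
#' @return Object of class `rotation_measurement`: `angle_deg`,
#'   `pivot_ring`, `per_ring_centroid_shift` (named, angstroms),
#'   `axis_angle_deg` (angle between plane normals), `superposition`.
#' @export
measure_cofactor_rotation <- function(ref, mobile, site, radius = 12,
                                      rings = ring_definitions(),
                                      pairing = NULL) {
  locate <- function(s, which) {
    loc <- if (!is.null(s[[which]])) s[[which]] else s
    loc
  }
  rloc <- locate(site, "ref"); mloc <- locate(site, "mobile")
  ref_cof <- .cofactor_atoms(ref, rloc$chain, rloc$resno, rloc$resid)
  mob_cof <- .cofactor_atoms(mobile, mloc$chain, mloc$resno, mloc$resid)

  bb_names <- c("N", "CA", "C", "O")
  ref_bb <- ref$atoms[!ref$atoms$het & ref$atoms$elety %in% bb_names, ]
  cof_xyz <- as.matrix(ref_cof[, c("x", "y", "z")])
  near <- vapply(seq_len(nrow(ref_bb)), function(i) {
    d2 <- (cof_xyz[, 1] - ref_bb$x[i])^2 + (cof_xyz[, 2] - ref_bb$y[i])^2 +
      (cof_xyz[, 3] - ref_bb$z[i])^2
    min(d2) <= radius^2
  }, logical(1L))
  ref_bb <- ref_bb[near, , drop = FALSE]
  mob_bb <- mobile$atoms[!mobile$atoms$het &
                           mobile$atoms$elety %in% bb_names, ]
  if (is.null(pairing)) {
    key_r <- paste(ref_bb$chain, ref_bb$resno, ref_bb$elety)
    key_m <- paste(mob_bb$chain, mob_bb$resno, mob_bb$elety)
  } else {
    pk_r <- paste(pairing$ref_chain, pairing$ref_resno)
    pk_m <- paste(pairing$mob_chain, pairing$mob_resno)
    idx <- match(paste(ref_bb$chain, ref_bb$resno), pk_r)
    key_r <- ifelse(is.na(idx), NA,
                    paste(pk_m[idx], ref_bb$elety))
    key_m <- paste(paste(mob_bb$chain, mob_bb$resno), mob_bb$elety)
  }
  hit <- match(key_r, key_m)
  ok <- !is.na(key_r) & !is.na(hit)
  if (sum(ok) < 3L)
    stop("fewer than 3 matched backbone atoms within ", radius,
         " angstroms of the cofactor")
  sp <- superpose(as.matrix(ref_bb[ok, c("x", "y", "z")]),
                  as.matrix(mob_bb[hit[ok], c("x", "y", "z")]))
  mob_cof_fit <- mob_cof
  mob_cof_fit[, c("x", "y", "z")] <-
    apply_superposition(sp, as.matrix(mob_cof[, c("x", "y", "z")]))

  fr <- .tetrapyrrole_frame(ref_cof, rings)
  fm <- .tetrapyrrole_frame(mob_cof_fit, rings)
  shifts <- vapply(names(rings), function(r)
    .vnorm(fr$ring_centroids[[r]] - fm$ring_centroids[[r]]), numeric(1L))
  pivot <- names(rings)[which.min(shifts)]
  n1 <- fr$plane$normal; n2 <- fm$plane$normal
  if (sum(n1 * n2) < 0) n2 <- -n2
  axis_angle <- .deg(acos(.clamp1(sum(n1 * n2))))
  nb <- .unit(n1 + n2)                      # bisecting-plane normal
  proj <- function(v) .unit(v - sum(v * nb) * nb)
  u1 <- proj(fr$in_plane_axis); u2 <- proj(fm$in_plane_axis)
  angle <- .deg(acos(.clamp1(sum(u1 * u2))))
  structure(list(angle_deg = angle, pivot_ring = pivot,
                 per_ring_centroid_shift = shifts,
                 axis_angle_deg = axis_angle, superposition = sp),
            class = "rotation_measurement")
}

#' @export
print.rotation_measurement <- function(x, ...) {
  cat(sprintf("Cofactor rotation: %.2f deg (plane normals %.2f deg), pivot ring %s\n",
              x$angle_deg, x$axis_angle_deg, x$pivot_ring))
  cat("Per-ring centroid shifts (A):",
      paste(sprintf("%s=%.2f", names(x$per_ring_centroid_shift),
                    x$per_ring_centroid_shift), collapse = " "), "\n")
  invisible(x)
}

#' Significance threshold for a rotation from baseline coordinate variation
#'
#' The angle separating genuine rearrangement from ordinary coordinate
#' variation is estimated as mean + 2 SD of the angles measured between
#' baseline (e.g. all visible-light) structures at the same site.
#'
#' @param angles Numeric vector of baseline angles (degrees).
#' @return The threshold in degrees.
#' @export
rotation_threshold <- function(angles) {
  mean(angles) + 2 * stats::sd(angles)
}

# antecedent: nearest heavy atom covalently bonded to `atom` (< 2.0 A),
# preferring atoms of the same residue
.antecedent <- function(atoms, idx) {
  a <- atoms[idx, ]
  d <- sqrt((atoms$x - a$x)^2 + (atoms$y - a$y)^2 + (atoms$z - a$z)^2)
  cand <- which(d > 0.1 & d < 2.0 & seq_len(nrow(atoms)) != idx)
  if (length(cand) == 0L) return(NA_integer_)
  same <- cand[atoms$chain[cand] == a$chain & atoms$resno[cand] == a$resno]
  if (length(same)) cand <- same
  cand[which.min(d[cand])]
}

#' Detect hydrogen bonds from heavy-atom geometry
#'
#' Hydrogens are absent from the deposited models, so candidate bonds are
#' inferred from heavy atoms only: donor/acceptor pairs of N, O or S atoms
#' within `distance_cutoff`, excluding covalently bonded (< 2.2 A) and 1-3
#' pairs (sharing a covalent neighbour). The acceptor-side geometry is the
#' angle antecedent-acceptor...donor, where the antecedent is the
#' acceptor's nearest covalently bonded heavy atom; an orientation is
#' reported only when this angle lies in `angle_range`. The bond `quality`
#' is `|acceptor_angle - 120|`, the deviation from the near-optimal
#' sp2-acceptor angle.
#'
#' @param struct A `structure_model`.
#' @param selection Optional logical or integer index into `struct$atoms`
#'   restricting the search; a bond is reported when at least one partner
#'   is in the selection. Default: all atoms.
#' @param distance_cutoff Donor-acceptor distance cutoff in angstroms
#'   (default 3.5).
#' @param angle_range Acceptable acceptor-angle window in degrees (default
#'   c(90, 180)).
#' @return Data frame sorted by distance: donor/acceptor chain, resno,
#'   atom, `distance`, `acceptor_angle_deg`, `quality`. Zero rows when no
#'   bond is found.
#' @export
detect_hbonds <- function(struct, selection = NULL, distance_cutoff = 3.5,
                          angle_range = c(90, 180)) {
  atoms <- struct$atoms
  polar <- which(atoms$elesy %in% c("N", "O", "S"))
  if (length(polar) < 2L) return(.empty_hbonds())
  sel <- if (is.null(selection)) rep(TRUE, nrow(atoms)) else {
    s <- rep(FALSE, nrow(atoms)); s[selection] <- TRUE; s
  }
  xyz <- as.matrix(atoms[polar, c("x", "y", "z")])
  dmat <- as.matrix(dist(xyz))
  all_xyz <- as.matrix(atoms[, c("x", "y", "z")])
  rows <- list()
  np <- length(polar)
  for (i in seq_len(np - 1L)) for (j in (i + 1L):np) {
    d <- dmat[i, j]
    if (d > distance_cutoff || d < 2.2) next
    ai <- polar[i]; aj <- polar[j]
    if (!sel[ai] && !sel[aj]) next
    # 1-3 exclusion: a shared covalent neighbour
    di <- sqrt(colSums((t(all_xyz) - all_xyz[ai, ])^2))
    dj <- sqrt(colSums((t(all_xyz) - all_xyz[aj, ])^2))
    if (any(di < 2.0 & dj < 2.0 & di > 0.1 & dj > 0.1)) next
    for (acc_don in list(c(ai, aj), c(aj, ai))) {
      acc <- acc_don[1L]; don <- acc_don[2L]
      ant <- .antecedent(atoms, acc)
      if (is.na(ant)) next
      v1 <- all_xyz[ant, ] - all_xyz[acc, ]
      v2 <- all_xyz[don, ] - all_xyz[acc, ]
      ang <- .deg(acos(.clamp1(sum(v1 * v2) / (.vnorm(v1) * .vnorm(v2)))))
      if (ang < angle_range[1L] || ang > angle_range[2L]) next
      rows[[length(rows) + 1L]] <- data.frame(
        donor_chain = atoms$chain[don], donor_resno = atoms$resno[don],
        donor_atom = atoms$elety[don],
        acceptor_chain = atoms$chain[acc], acceptor_resno = atoms$resno[acc],
        acceptor_atom = atoms$elety[acc],
        distance = d, acceptor_angle_deg = ang,
        quality = abs(ang - 120))
    }
  }
  if (length(rows) == 0L) return(.empty_hbonds())
  out <- do.call(rbind, rows)
  out[order(out$distance), , drop = FALSE]
}

.empty_hbonds <- function() {
  data.frame(donor_chain = character(0), donor_resno = integer(0),
             donor_atom = character(0), acceptor_chain = character(0),
             acceptor_resno = integer(0), acceptor_atom = character(0),
             distance = numeric(0), acceptor_angle_deg = numeric(0),
             quality = numeric(0))
}

#' Compare hydrogen-bond angle quality between two structures
#'
#' Bonds are paired by a shared `role` label and judged by which angle lies
#' closer to the near-optimal acceptor angle (~120 degrees for an sp2
#' carbonyl acceptor such as the 13-1 keto oxygen of chlorophyll).
#'
#' @param bonds_a,bonds_b Data frames as returned by [detect_hbonds()],
#'   each with an additional `role` column naming the structural role of
#'   each bond.
#' @param target_angle Optimal angle in degrees (default 120).
#' @param tie_tolerance Angular difference treated as a tie (default 0.5).
#' @return Data frame: `role`, `angle_a`, `angle_b`, `closer` (`"a"`,
#'   `"b"`, `"tie"`, or `"unpaired"`).
#' @export
compare_hbond_quality <- function(bonds_a, bonds_b, target_angle = 120,
                                  tie_tolerance = 0.5) {
  stopifnot("role" %in% names(bonds_a), "role" %in% names(bonds_b))
  roles <- union(bonds_a$role, bonds_b$role)
  rows <- lapply(roles, function(r) {
    aa <- bonds_a$acceptor_angle_deg[bonds_a$role == r]
    bb <- bonds_b$acceptor_angle_deg[bonds_b$role == r]
    if (length(aa) == 0L || length(bb) == 0L)
      return(data.frame(role = r, angle_a = if (length(aa)) aa[1L] else NA,
                        angle_b = if (length(bb)) bb[1L] else NA,
                        closer = "unpaired"))
    qa <- abs(aa[1L] - target_angle); qb <- abs(bb[1L] - target_angle)
    verdict <- if (abs(qa - qb) <= tie_tolerance) "tie"
      else if (qa < qb) "a" else "b"
    data.frame(role = r, angle_a = aa[1L], angle_b = bb[1L],
               closer = verdict)
  })
  do.call(rbind, rows)
}
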