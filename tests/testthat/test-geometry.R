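test_that("superposition recovers exact rigid transforms", {
  set.seed(1)
  p <- matrix(rnorm(30), 10, 3)
  sp <- superpose(p, p)
  expect_equal(sp$rmsd, 0, tolerance = 1e-12)
  expect_equal(sp$rotation, diag(3), tolerance = 1e-9)

  # known 17 degree rotation about z plus a translation
  th <- 17 * pi / 180
  Rz <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
               3, 3, byrow = TRUE)
  q <- sweep(p %*% t(Rz), 2, c(4, -2, 7), "+")
  sp2 <- superpose(q, p)
  expect_equal(sp2$rmsd, 0, tolerance = 1e-9)
  expect_equal(rotation_angle(sp2), 17, tolerance = 1e-6)
  expect_equal(apply_superposition(sp2, p), q, tolerance = 1e-9)
  expect_equal(det(sp2$rotation), 1, tolerance = 1e-10)

  expect_error(superpose(p[1:2, ], p[1:2, ]), "at least 3")
  line <- cbind(1:5, 2 * (1:5), 3 * (1:5))
  expect_error(superpose(line, line), "collinear")
})

test_that("Kabsch agrees with the quaternion-method oracle", {
  set.seed(2)
  for (i in 1:100) {
    ref <- matrix(rnorm(3 * 50), ncol = 3)
    mob <- sweep(ref %*% t(random_rotation()), 2, rnorm(3), "+") +
      matrix(rnorm(3 * 50, sd = 0.2), ncol = 3)
    sp <- superpose(ref, mob)
    qo <- quaternion_superpose(ref, mob)
    expect_equal(sp$rmsd, qo$rmsd, tolerance = 1e-8)
    expect_equal(sp$rotation, qo$rotation, tolerance = 1e-6)
  }
})

test_that("plane fitting is exact on constructions and matches eigen oracle", {
  xy <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1), 0)
  pl <- fit_ring_plane(xy)
  expect_equal(abs(pl$normal[3]), 1, tolerance = 1e-12)
  expect_equal(pl$rms_residual, 0, tolerance = 1e-12)

  # plane tilted 30 degrees from xy
  th <- 30 * pi / 180
  Rx <- matrix(c(1, 0, 0, 0, cos(th), -sin(th), 0, sin(th), cos(th)),
               3, 3, byrow = TRUE)
  tilted <- xy %*% t(Rx)
  pl2 <- fit_ring_plane(tilted)
  ang <- acos(abs(pl2$normal[3])) * 180 / pi
  expect_equal(ang, 30, tolerance = 1e-9)

  # noisy points: same normal as the covariance eigen-decomposition
  set.seed(3)
  pts <- cbind(rnorm(40), rnorm(40), rnorm(40, sd = 0.05))
  pl3 <- fit_ring_plane(pts)
  ev <- eigen(cov(pts))$vectors[, 3]
  expect_equal(abs(sum(pl3$normal * ev)), 1, tolerance = 1e-9)

  expect_error(fit_ring_plane(cbind(1:4, 1:4, 1:4)), "collinear")
})

test_that("self-comparison measures zero rotation", {
  pair <- generate_rotated_cofactor_pair(rotation_deg = 0, noise_sd = 0)
  rot <- measure_cofactor_rotation(pair$ref, pair$ref, pair$site)
  expect_equal(rot$angle_deg, 0, tolerance = 1e-9)
  expect_true(all(rot$per_ring_centroid_shift < 1e-9))
})

test_that("known ring rotations are recovered with the correct pivot", {
  n_correct <- 0L; n_total <- 0L
  for (ring in c("A", "B", "C", "D", "E")) {
    for (theta in c(1, 2, 5, 10, 20)) {
      pair <- generate_rotated_cofactor_pair(rotation_deg = theta,
                                             pivot_ring = ring,
                                             noise_sd = 0)
      rot <- measure_cofactor_rotation(pair$ref, pair$mobile, pair$site)
      expect_equal(rot$angle_deg, theta, tolerance = 0.1)
      n_total <- n_total + 1L
      if (rot$pivot_ring == ring) n_correct <- n_correct + 1L
    }
  }
  expect_gte(n_correct / n_total, 0.95)
})

test_that("rotation measurement is symmetric and rigid-motion invariant", {
  pair <- generate_rotated_cofactor_pair(rotation_deg = 5, noise_sd = 0)
  fwd <- measure_cofactor_rotation(pair$ref, pair$mobile, pair$site)
  rev <- measure_cofactor_rotation(pair$mobile, pair$ref, pair$site)
  expect_lt(abs(fwd$angle_deg - rev$angle_deg), 1e-6)

  set.seed(5)
  R <- random_rotation(); tv <- rnorm(3, sd = 20)
  moved <- measure_cofactor_rotation(transform_structure(pair$ref, R, tv),
                                     transform_structure(pair$mobile, R, tv),
                                     pair$site)
  expect_lt(abs(moved$angle_deg - fwd$angle_deg), 1e-6)
  expect_equal(moved$per_ring_centroid_shift, fwd$per_ring_centroid_shift,
               tolerance = 1e-6)
  expect_identical(moved$pivot_ring, fwd$pivot_ring)
})

test_that("the rotation-significance threshold is mean + 2 sd", {
  expect_equal(rotation_threshold(c(1, 2, 3)), 2 + 2 * sd(c(1, 2, 3)))
})

test_that("hydrogen bonds require distance and acceptor-angle geometry", {
  mk <- function(donor_xy) {
    at <- data.frame(chain = "A", resno = c(1, 1, 2), insert = "",
                     resid = "GLY", elety = c("C", "O", "N"),
                     x = c(-1.23, 0, donor_xy[1]),
                     y = c(0, 0, donor_xy[2]), z = 0, het = FALSE,
                     stringsAsFactors = FALSE)
    frlpsi:::.make_structure(at, "hb")
  }
  # beyond the cutoff: nothing
  expect_equal(nrow(detect_hbonds(mk(c(5, 0)))), 0L)
  # 2.9 A at a 120 degree acceptor angle: one bond of quality ~0
  hb <- detect_hbonds(mk(2.9 * c(cos(pi / 3), sin(pi / 3))))
  expect_equal(nrow(hb), 1L)
  expect_equal(hb$distance, 2.9, tolerance = 1e-9)
  expect_equal(hb$acceptor_angle_deg, 120, tolerance = 1e-9)
  expect_equal(hb$quality, 0, tolerance = 1e-9)
  expect_equal(hb$donor_atom, "N")
  expect_equal(hb$acceptor_atom, "O")
  # acceptor angle outside the window: rejected
  expect_equal(nrow(detect_hbonds(mk(c(-1.45, 2.511)))), 0L)
  # covalent-range pair excluded
  at2 <- data.frame(chain = "A", resno = 1, insert = "", resid = "GLY",
                    elety = c("O", "N"), x = c(0, 1.4), y = 0, z = 0,
                    het = FALSE)
  expect_equal(nrow(detect_hbonds(frlpsi:::.make_structure(at2, "cov"))), 0L)
})

test_that("bond-quality comparison pairs by role and flags the closer angle", {
  mkb <- function(role, ang) data.frame(role = role,
                                        acceptor_angle_deg = ang)
  out <- compare_hbond_quality(mkb("keto", 118), mkb("keto", 95))
  expect_equal(out$closer, "a")
  expect_equal(compare_hbond_quality(mkb("keto", 117),
                                     mkb("keto", 117.2))$closer, "tie")
  out2 <- compare_hbond_quality(rbind(mkb("keto", 118), mkb("extra", 130)),
                                mkb("keto", 95))
  expect_setequal(out2$closer, c("a", "unpaired"))
})
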