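test_that("dihedral reproduces cis, trans and the signed -90 case", {
  expect_equal(dihedral(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, 1, 0)), 0)
  expect_equal(dihedral(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, -1, 0)), 180)
  expect_equal(dihedral(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, 0, 1)), -90)
  expect_error(dihedral(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0), c(1, 1, 0)),
               class = "degenerate_geometry")
  expect_error(dihedral(c(2, 0, 0), c(0, 0, 0), c(1, 0, 0), c(1, 1, 0)),
               class = "degenerate_geometry")
})

test_that("dihedral obeys reversal, mirror and rigid-invariance properties", {
  set.seed(42)
  for (k in 1:25) {
    p <- lapply(1:4, function(i) stats::rnorm(3) * 5)
    d0 <- tryCatch(dihedral(p[[1]], p[[2]], p[[3]], p[[4]]),
                   arpgeom_error = function(e) NULL)
    if (is.null(d0)) next
    expect_equal(dihedral(p[[4]], p[[3]], p[[2]], p[[1]]), d0, tolerance = 1e-9)
    mirrored <- dihedral(-p[[1]], -p[[2]], -p[[3]], -p[[4]])
    expect_equal(abs(mirrored), abs(d0), tolerance = 1e-9)
    if (abs(abs(d0) - 180) > 1e-6 && abs(d0) > 1e-6) {
      expect_equal(mirrored, -d0, tolerance = 1e-9)
    }
    tr <- random_rigid()
    q <- lapply(p, function(x) apply_transform(tr, x))
    expect_equal(dihedral(q[[1]], q[[2]], q[[3]], q[[4]]), d0,
                 tolerance = 1e-9)
    a0 <- oracle_angle(p[[1]], p[[2]], p[[3]])
    expect_equal(angle3(apply_transform(tr, p[[1]]), apply_transform(tr, p[[2]]),
                        apply_transform(tr, p[[3]])), a0, tolerance = 1e-9)
  }
})

test_that("angle3 reproduces right, straight and 45-degree cases", {
  expect_equal(angle3(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0)), 90)
  expect_equal(angle3(c(1, 0, 0), c(0, 0, 0), c(-1, 0, 0)), 180)
  expect_equal(angle3(c(1, 0, 0), c(0, 0, 0), c(1, 1, 0)), 45)
  expect_error(angle3(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0)),
               class = "degenerate_geometry")
})

test_that("center_of_mass weights by average atomic mass over heavy atoms", {
  at <- function(el, x) data.frame(chain = "A", resno = 1, insert = "",
                                   resid = "UNK", elety = el, element = el,
                                   x = x, y = 0, z = 0, o = 1, alt = "",
                                   hetero = FALSE, stringsAsFactors = FALSE)
  two_c <- rbind(at("C", 0), at("C", 2))
  expect_equal(center_of_mass(two_c), c(1, 0, 0))
  expect_equal(center_of_mass(at("C", 5)), c(5, 0, 0))
  co <- rbind(at("C", 0), at("O", 1))
  expect_equal(center_of_mass(co)[1], 15.999 / (12.011 + 15.999),
               tolerance = 1e-12)
  # hydrogens dropped in mass mode but kept in geometric mode
  ch <- rbind(at("C", 0), at("H", 10))
  expect_equal(center_of_mass(ch, "mass")[1], 0)
  expect_equal(center_of_mass(ch, "geometric")[1], 5)
  expect_error(center_of_mass(two_c[0, ]), class = "empty_selection")
  expect_error(center_of_mass(at("XX", 0)), class = "mass_table_error")
})

test_that("superpose recovers identity, translation, and refuses reflection fits", {
  set.seed(7)
  P <- matrix(stats::rnorm(15), 5, 3)
  id <- superpose(P, P)
  expect_equal(id$rmsd, 0, tolerance = 1e-9)
  expect_equal(id$rotation, diag(3), tolerance = 1e-9)
  tr <- superpose(P, sweep(P, 2, c(-10, 0, 0)))
  expect_equal(tr$translation, c(-10, 0, 0), tolerance = 1e-9)
  expect_equal(tr$rmsd, 0, tolerance = 1e-9)
  # a chiral set mirrored cannot be superposed by a proper rotation
  chiral <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 2))
  mir <- chiral %*% diag(c(-1, 1, 1))
  fit <- superpose(chiral, mir)
  expect_gt(fit$rmsd, 0.1)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
  expect_error(superpose(P, P[1:4, ]), class = "pairing_error")
  expect_error(superpose(P[1:2, ], P[1:2, ]), class = "degenerate_geometry")
  line <- cbind(1:4, 0, 0)
  expect_error(superpose(line, line), class = "degenerate_geometry")
})

test_that("superpose rmsd equals the brute-force global minimum on small instances", {
  set.seed(13)
  for (k in 1:4) {
    n <- sample(4:6, 1)
    ref <- matrix(stats::rnorm(3 * n, sd = 4), n, 3)
    mob <- matrix(stats::rnorm(3 * n, sd = 4), n, 3)
    expect_equal(superpose(ref, mob)$rmsd, oracle_min_rmsd(ref, mob),
                 tolerance = 1e-3)
  }
})

test_that("superpose agrees with an established reference implementation", {
  set.seed(99)
  ref <- matrix(stats::rnorm(30, sd = 5), 10, 3)
  mob <- apply_transform(random_rigid(), ref) + matrix(stats::rnorm(30, sd = 0.3), 10, 3)
  fit <- superpose(ref, mob)
  b3d <- bio3d::fit.xyz(as.numeric(t(ref)), as.numeric(t(mob)),
                        fixed.inds = 1:30, mobile.inds = 1:30)
  rms_b3d <- sqrt(mean(colSums(matrix(as.numeric(b3d) - as.numeric(t(ref)), 3)^2)))
  expect_equal(fit$rmsd, rms_b3d, tolerance = 1e-6)
})

test_that("sequence_mass is additive and matches hand-derived values", {
  expect_equal(sequence_mass("G"), 0.07506718, tolerance = 1e-7)
  expect_error(sequence_mass(""), class = "sequence_error")
  expect_error(sequence_mass("GXZ"), class = "sequence_error")
  set.seed(3)
  aa <- residue_masses()$letter
  for (k in 1:5) {
    s1 <- paste(sample(aa, 8, TRUE), collapse = "")
    s2 <- paste(sample(aa, 5, TRUE), collapse = "")
    expect_equal(sequence_mass(paste0(s1, s2)),
                 sequence_mass(s1) + sequence_mass(s2) - 18.01528 / 1000,
                 tolerance = 1e-12)
  }
})
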