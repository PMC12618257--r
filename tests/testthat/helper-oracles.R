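# Independent geometric oracles, deliberately using different algebra
# than the package implementation.

# torsion by projecting the outer bonds onto the plane perpendicular
# to the central bond (the package uses the two-normal construction)
oracle_dihedral <- function(p1, p2, p3, p4) {
  b <- (p3 - p2) / sqrt(sum((p3 - p2)^2))
  v1 <- (p1 - p2) - sum((p1 - p2) * b) * b
  v2 <- (p4 - p3) - sum((p4 - p3) * b) * b
  cr <- c(v1[2] * v2[3] - v1[3] * v2[2],
          v1[3] * v2[1] - v1[1] * v2[3],
          v1[1] * v2[2] - v1[2] * v2[1])
  ang <- -atan2(sum(cr * b), sum(v1 * v2)) * 180 / pi
  if (ang <= -180) ang + 360 else ang
}

oracle_angle <- function(p1, p2, p3) {
  u <- p1 - p2; v <- p3 - p2
  acos(min(1, max(-1, sum(u * v) / sqrt(sum(u^2) * sum(v^2))))) * 180 / pi
}

rotation_from_axis_angle <- function(w) {
  th <- sqrt(sum(w^2))
  if (th < 1e-12) return(diag(3))
  k <- w / th
  K <- matrix(c(0, -k[3], k[2], k[3], 0, -k[1], -k[2], k[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
}

# global minimum RMSD over proper rotations by coarse grid search plus
# local refinement (optimal translation folded in by centering)
oracle_min_rmsd <- function(ref, mob) {
  rc <- sweep(ref, 2, colMeans(ref))
  mc <- sweep(mob, 2, colMeans(mob))
  rmsd_of <- function(w) {
    R <- rotation_from_axis_angle(w)
    sqrt(mean(rowSums((mc %*% t(R) - rc)^2)))
  }
  i <- seq_len(60) - 0.5
  dirs <- cbind(sqrt(1 - (1 - 2 * i / 60)^2) * cos(pi * (3 - sqrt(5)) * (i - 0.5)),
                sqrt(1 - (1 - 2 * i / 60)^2) * sin(pi * (3 - sqrt(5)) * (i - 0.5)),
                1 - 2 * i / 60)
  best <- c(0, 0, 0); best_val <- rmsd_of(best)
  for (a in seq(0.1, pi, length.out = 36)) {
    for (d in seq_len(nrow(dirs))) {
      w <- dirs[d, ] * a
      v <- rmsd_of(w)
      if (v < best_val) { best <- w; best_val <- v }
    }
  }
  opt <- stats::optim(best, rmsd_of, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 5000))
  min(best_val, opt$value)
}

# closed-form accessible area of two expanded spheres (lens geometry),
# written independently of the generator's formula
oracle_two_sphere_union <- function(R1, R2, d) {
  if (d >= R1 + R2) return(4 * pi * (R1^2 + R2^2))
  if (d < 1e-12 && abs(R1 - R2) < 1e-12) return(4 * pi * R1^2)
  if (d + R1 <= R2) return(4 * pi * R2^2)
  if (d + R2 <= R1) return(4 * pi * R1^2)
  cap1 <- 2 * pi * R1 * (R1 - (d^2 + R1^2 - R2^2) / (2 * d))
  cap2 <- 2 * pi * R2 * (R2 - (d^2 + R2^2 - R1^2) / (2 * d))
  4 * pi * (R1^2 + R2^2) - cap1 - cap2
}

random_rigid <- function() {
  rigid_transform(rotation_from_axis_angle(stats::rnorm(3)),
                  stats::runif(3, -30, 30))
}

# minimal hand-built models for unit tests
tiny_chain_model <- function(chain = "F", resnos = 1:150, resid = "ALA") {
  rows <- lapply(resnos, function(r)
    data.frame(chain = chain, resno = r, insert = "", resid = resid,
               elety = "CA", element = "C", x = r * 3.8, y = sin(r) * 2,
               z = cos(r) * 2, o = 1, alt = "", hetero = FALSE,
               stringsAsFactors = FALSE))
  arpgeom:::new_structure_model(do.call(rbind, rows), "tiny", "synthetic")
}
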