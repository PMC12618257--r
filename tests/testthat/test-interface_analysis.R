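single_atom_df <- function(el = "C", pos = c(0, 0, 0), chain = "A",
                           resno = 1, resid = "UNK", elety = el) {
  data.frame(chain = chain, resno = resno, insert = "", resid = resid,
             elety = elety, element = el, x = pos[1], y = pos[2], z = pos[3],
             o = 1, alt = "", hetero = FALSE, stringsAsFactors = FALSE)
}

test_that("SASA of isolated, duplicated and caged atoms matches geometry", {
  s1 <- sasa(single_atom_df())
  expect_equal(s1$total, 4 * pi * (1.88 + 1.4)^2, tolerance = 0.02)
  # two identical atoms far apart: exactly twice the single-atom area
  far <- rbind(single_atom_df(), single_atom_df(pos = c(100, 0, 0), chain = "B"))
  expect_equal(sasa(far)$total, 2 * s1$total, tolerance = 1e-9)
  # a caged atom has zero accessible area
  cg <- make_cage()
  expect_equal(sasa(cg$model$atoms)$per_atom[cg$center_index], 0)
  # per-atom areas sum to the total
  set.seed(8)
  cl <- do.call(rbind, lapply(1:30, function(i)
    single_atom_df(pos = stats::runif(3, 0, 8), resno = i)))
  s <- sasa(cl)
  expect_equal(sum(s$per_atom), s$total, tolerance = 1e-9)
  expect_error(sasa(cl[0, ]), class = "empty_selection")
  expect_error(sasa(single_atom_df(el = "XX")), class = "radii_error")
})

test_that("SASA tracks the closed-form two-sphere oracle within 2% across separations", {
  radii <- vdw_radii()
  p <- sasa_params()
  R1 <- radii[["C"]] + p$probe_radius
  R2 <- radii[["O"]] + p$probe_radius
  for (d in seq(0, R1 + R2 + 0.5, by = 0.4)) {
    fix <- make_sphere_fixture(d = d, elements = c("C", "O"))
    got <- sasa(fix$model$atoms, p)$total
    want <- oracle_two_sphere_union(R1, R2, d)
    expect_equal(fix$truth$sasa_union, want, tolerance = 1e-9)
    expect_lt(abs(got - want) / want, 0.02)
  }
  # exact tangency of the expanded spheres buries nothing
  tang <- make_sphere_fixture(d = R1 + R2, elements = c("C", "O"))
  expect_equal(tang$truth$buried, 0)
})

test_that("SASA converges: doubling the point count moves a 100-atom total by <0.5%", {
  set.seed(4)
  atoms <- do.call(rbind, lapply(1:100, function(i)
    single_atom_df(el = sample(c("C", "N", "O", "S"), 1),
                   pos = stats::runif(3, 0, 12), resno = i)))
  a960 <- sasa(atoms, sasa_params(points_per_atom = 960))$total
  a1920 <- sasa(atoms, sasa_params(points_per_atom = 1920))$total
  expect_lt(abs(a960 - a1920) / a1920, 0.005)
})

test_that("buried area is symmetric, zero for distant chains and additive", {
  fix <- make_sphere_fixture(d = 100)
  expect_equal(as.numeric(buried_area(fix$model, fix$map, "Ac1", "Ac2")), 0)
  fix2 <- make_sphere_fixture(d = 2.5)
  ab <- buried_area(fix2$model, fix2$map, "Ac1", "Ac2")
  ba <- buried_area(fix2$model, fix2$map, "Ac2", "Ac1")
  expect_equal(as.numeric(ab), as.numeric(ba), tolerance = 1e-9)
  expect_gte(as.numeric(ab), 0)
  expect_equal(attr(ab, "full_loss"), 2 * as.numeric(ab), tolerance = 1e-9)
  # coincident identical atoms: half the single-sphere area
  fix0 <- make_sphere_fixture(d = 0)
  b0 <- buried_area(fix0$model, fix0$map, "Ac1", "Ac2")
  expect_equal(as.numeric(b0), 4 * pi * (1.88 + 1.4)^2 / 2,
               tolerance = 1e-9)
  expect_equal(fix0$truth$buried, as.numeric(b0), tolerance = 1e-9)
  # additivity over mutually distant chains
  rows <- rbind(single_atom_df(pos = c(0, 0, 0), chain = "A"),
                single_atom_df(pos = c(2.5, 0, 0), chain = "B"),
                single_atom_df(pos = c(-2.5, 0, 0), chain = "C"))
  m3 <- arpgeom:::new_structure_model(rows, "tri", "synthetic")
  map3 <- subunit_map(c(Ac1 = "A", Ac2 = "B", Ac3 = "C"))
  lhs <- as.numeric(buried_area(m3, map3, "Ac1", c("Ac2", "Ac3")))
  rhs <- as.numeric(buried_area(m3, map3, "Ac1", "Ac2")) +
    as.numeric(buried_area(m3, map3, "Ac1", "Ac3"))
  expect_equal(lhs, rhs, tolerance = 0.5)
  expect_error(buried_area(m3, map3, c("Ac1", "Ac2"), "Ac2"),
               class = "disjointness_error")
})

test_that("interface residues obey the distance cutoff exactly and monotonically", {
  # one cross pair at 4.9 A
  rows <- rbind(single_atom_df(pos = c(0, 0, 0), chain = "A", resid = "GLY"),
                single_atom_df(pos = c(4.9, 0, 0), chain = "B", resid = "GLY"),
                single_atom_df(pos = c(30, 0, 0), chain = "B", resno = 2,
                               resid = "GLY"))
  m <- arpgeom:::new_structure_model(rows, "iface", "synthetic")
  map <- subunit_map(c(Ac1 = "A", Ac2 = "B"))
  ir <- interface_residues(m, map, "Ac1", "Ac2")
  expect_equal(nrow(ir$a), 1)
  expect_equal(nrow(ir$b), 1)
  expect_equal(ir$a$min_dist, 4.9, tolerance = 1e-9)
  ir48 <- interface_residues(m, map, "Ac1", "Ac2",
                             rules = contact_rules(interface_cutoff = 4.8))
  expect_equal(nrow(ir48$a), 0)
  expect_equal(nrow(ir48$b), 0)
  # monotone: 4 A list is a subset of the 5 A list
  toy <- make_toy_complex(seed = 9)
  r5 <- interface_residues(toy$model, toy$maps$copy1, "ArpC2", "ArpC4",
                           rules = contact_rules(interface_cutoff = 5))
  r4 <- interface_residues(toy$model, toy$maps$copy1, "ArpC2", "ArpC4",
                           rules = contact_rules(interface_cutoff = 4))
  expect_true(all(paste(r4$a$resno) %in% paste(r5$a$resno)))
})

test_that("contacts are classified by priority salt bridge > hbond > hydrophobic", {
  rows <- rbind(
    single_atom_df(el = "N", pos = c(0, 0, 0), chain = "A", resno = 1,
                   resid = "LYS", elety = "NZ"),
    single_atom_df(el = "O", pos = c(3.2, 0, 0), chain = "B", resno = 1,
                   resid = "GLU", elety = "OE1"),
    single_atom_df(el = "O", pos = c(0, 20, 0), chain = "A", resno = 2,
                   resid = "SER", elety = "OG"),
    single_atom_df(el = "O", pos = c(3.0, 20, 0), chain = "B", resno = 2,
                   resid = "ALA", elety = "O"),
    single_atom_df(el = "C", pos = c(0, 40, 0), chain = "A", resno = 3,
                   resid = "LEU", elety = "CD1"),
    single_atom_df(el = "C", pos = c(4.0, 40, 0), chain = "B", resno = 3,
                   resid = "ILE", elety = "CD1"))
  m <- arpgeom:::new_structure_model(rows, "contacts", "synthetic")
  map <- subunit_map(c(Ac1 = "A", Ac2 = "B"))
  cc <- classify_contacts(m, map, "Ac1", "Ac2")
  expect_equal(cc$class[cc$resid_a == "LYS"], "salt_bridge")
  expect_equal(cc$class[cc$resid_a == "SER"], "hbond")
  expect_equal(cc$class[cc$resid_a == "LEU"], "hydrophobic")
  counts <- attr(cc, "counts")
  expect_equal(as.integer(counts[c("salt_bridge", "hbond", "hydrophobic")]),
               c(1L, 1L, 1L))
})

test_that("interface_table keeps computing past a failing pair", {
  toy <- make_toy_complex(seed = 6)
  pairs <- list(
    ok = list(a = "ArpC2", b = "ArpC4"),
    bad = list(a = c("ArpC2", "ArpC4"), b = "ArpC4")
  )
  tab <- interface_table(toy$model, toy$maps$copy1, pairs,
                         params = sasa_params(points_per_atom = 92))
  expect_equal(nrow(tab), 2)
  expect_true(is.na(tab$buried_area[tab$pair == "bad"]))
  expect_match(tab$error[tab$pair == "bad"], "overlap")
  expect_false(is.na(tab$buried_area[tab$pair == "ok"]))
})
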