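write_mini_pdb <- function(path) {
  writeLines(c(
    "ATOM      1  N   ALA A   1      11.104   6.134  -6.504  1.00  0.00           N",
    "ATOM      2  CA AALA A   1      11.639   6.071  -5.147  0.60  0.00           C",
    "ATOM      3  CA BALA A   1      11.700   6.100  -5.200  0.40  0.00           C",
    "ATOM      4  CB AALA A   1      12.000   7.000  -4.000  0.50  0.00           C",
    "ATOM      5  CB BALA A   1      12.100   7.100  -4.100  0.50  0.00           C",
    "ATOM      6  H   ALA A   1      10.000   6.000  -6.000  1.00  0.00           H",
    "ATOM      7  CA  GLY B   2       1.000   2.000   3.000  1.00  0.00           C",
    "HETATM    8 MG    MG B 201       5.000   5.000   5.000  1.00  0.00          MG",
    "TER",
    "END"), path)
  path
}

test_that("PDB parsing resolves altlocs by occupancy with alphabetical ties and flags hetero", {
  path <- write_mini_pdb(tempfile(fileext = ".pdb"))
  m <- read_structure(path)
  a <- m$atoms
  # one CA survives: the 0.60-occupancy A copy
  ca <- a[a$chain == "A" & a$elety == "CA", ]
  expect_equal(nrow(ca), 1)
  expect_equal(ca$alt, "A")
  expect_equal(ca$x, 11.639)
  # CB occupancy tie broken alphabetically
  cb <- a[a$chain == "A" & a$elety == "CB", ]
  expect_equal(nrow(cb), 1)
  expect_equal(cb$alt, "A")
  # hydrogens retained but flagged by element; hetero flagged
  expect_true(any(a$element == "H"))
  expect_equal(a$hetero, a$resid == "MG")
  expect_equal(sum(a$hetero), 1)
})

test_that("a one-atom PDB parses to one chain, one residue, one atom", {
  path <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  GLY A   1       1.000   2.000   3.000  1.00  0.00           C",
    "END"), path)
  m <- read_structure(path)
  expect_equal(nrow(m$atoms), 1)
  expect_equal(m$atoms$chain, "A")
  expect_equal(c(m$atoms$x, m$atoms$y, m$atoms$z), c(1, 2, 3))
  expect_error(read_structure(tempfile(fileext = ".pdb")), class = "parse_error")
  expect_error(read_structure(path, "auto") -> ok, NA)
  expect_error(read_structure(write_mini_pdb(tempfile(fileext = ".xyz"))),
               class = "format_error")
})

test_that("write/read round trip preserves atoms, names and coordinates to 1e-3 A", {
  toy <- make_toy_complex(seed = 11)
  path <- tempfile(fileext = ".pdb")
  write_structure(toy$model, path)
  back <- read_structure(path)
  expect_equal(nrow(back$atoms), nrow(toy$model$atoms))
  expect_equal(back$atoms$elety, toy$model$atoms$elety)
  expect_equal(back$atoms$chain, toy$model$atoms$chain)
  expect_equal(back$atoms$resno, toy$model$atoms$resno)
  expect_lt(max(abs(back$atoms$x - toy$model$atoms$x),
                abs(back$atoms$y - toy$model$atoms$y),
                abs(back$atoms$z - toy$model$atoms$z)), 1e-3 + 1e-9)
})

test_that("select_atoms does range arithmetic, filters and deterministic ordering", {
  m <- tiny_chain_model(chain = "F", resnos = 1:150)
  map1 <- subunit_map(c(ArpC4 = "F"))
  sel <- select_atoms(m, residue_range("ArpC4", 2, 141), map1, "calpha")
  expect_equal(nrow(sel), 140)
  # order invariant to map key order
  map2 <- subunit_map(c(ArpC2 = "Z", ArpC4 = "F"))
  map3 <- subunit_map(c(ArpC4 = "F", ArpC2 = "Z"))
  s2 <- select_atoms(m, "ArpC4", map2)
  s3 <- select_atoms(m, "ArpC4", map3)
  expect_identical(s2, s3)
  # unmapped subunit errors; empty selection is not an error
  expect_error(select_atoms(m, "Arp3", map1), class = "mapping_error")
  expect_equal(nrow(select_atoms(m, residue_range("ArpC4", 500, 600), map1)), 0)
  # heavy filter drops hydrogens
  path <- write_mini_pdb(tempfile(fileext = ".pdb"))
  mm <- read_structure(path)
  heavy <- select_atoms(mm, "Ac1", subunit_map(c(Ac1 = "A")), "heavy")
  expect_false(any(heavy$element == "H"))
})

test_that("resolve_anchor checks residue identity and reports missing anchors", {
  rows <- data.frame(chain = "D", resno = 130, insert = "", resid = "LYS",
                     elety = "CA", element = "C", x = 1, y = 2, z = 3,
                     o = 1, alt = "", hetero = FALSE, stringsAsFactors = FALSE)
  m <- arpgeom:::new_structure_model(rows, "t", "synthetic")
  map <- subunit_map(c(ArpC4 = "D"))
  expect_equal(as.numeric(resolve_anchor(m, map, "ArpC4", 130, "LYS")),
               c(1, 2, 3))
  expect_error(resolve_anchor(m, map, "ArpC4", 130, "GLU"),
               class = "anchor_identity")
  expect_warning(
    p <- resolve_anchor(m, map, "ArpC4", 130, "GLU", permissive = TRUE),
    "mismatch")
  expect_equal(as.numeric(p), c(1, 2, 3))
  expect_error(resolve_anchor(m, map, "ArpC4", 131, "LYS"),
               class = "anchor_missing")
})

test_that("subunit maps enforce the logical vocabulary and verify against structures", {
  expect_error(subunit_map(c(Bogus = "A")), class = "mapping_error")
  expect_silent(subunit_map(c(Ac7 = "A", MA3 = "B", `SPIN90*` = "C")))
  toy <- make_toy_complex(seed = 2)
  d <- tempfile()
  paths <- write_fixture_set(d, seed = 2)
  model <- read_structure(paths$pdb)
  maps <- load_map(paths$map, model = model)
  expect_named(maps, c("copy1", "copy2"))
  # inference recovers the anchored chains
  inf <- infer_subunit_map(model)
  arpc4 <- inf[inf$subunit == "ArpC4" & inf$n_matched == inf$n_anchors, ]
  expect_setequal(arpc4$chain, c("D", "c"))
})
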