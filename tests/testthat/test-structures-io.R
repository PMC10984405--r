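test_that("PDB read converts units, keeps file order, and flags glycans", {
  pdb <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  N   ALA A   1      10.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1      11.500   0.500   0.000  1.00  0.00           C",
    "HETATM    3  C1  NAG A   2      15.000   2.000   1.000  1.00  0.00           C",
    "END"), pdb)
  m <- read_pdb(pdb)
  expect_equal(n_atoms(m), 3)
  expect_equal(m$atoms$atom_name, c("N", "CA", "C1"))
  expect_equal(coords(m)[1, ], c(1, 0, 0))          # Angstrom -> nm
  expect_equal(m$atoms$is_glycan, c(FALSE, FALSE, TRUE))
  expect_equal(m$atoms$residue_number, c(1L, 1L, 2L))
})

test_that("PDB read errors name the problem", {
  expect_error(read_pdb(tempfile()), "No such file")
  bad <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  QQ  ALA A   1      10.000   0.000   0.000  1.00  0.00          Qq",
    "END"), bad)
  expect_error(read_pdb(bad), "Unknown element")
})

test_that("write/read round trip preserves coordinates to PDB precision, order, and bonds", {
  m <- asn_protein_stub()
  m2 <- attach_glycan(m, list(segment_id = "A", residue_number = 297))
  tf <- tempfile(fileext = ".pdb")
  write_pdb(m2, tf)
  m3 <- read_pdb(tf)
  expect_equal(n_atoms(m3), n_atoms(m2))
  expect_lte(max(abs(coords(m3) - coords(m2))), 1e-4 + 1e-12)
  expect_equal(m3$atoms$atom_name, m2$atoms$atom_name)
  expect_equal(m3$atoms$is_glycan, m2$atoms$is_glycan)
  # glycan atoms written as HETATM, glycosidic bond as CONECT
  lines <- readLines(tf)
  expect_true(any(grepl("^HETATM", lines)))
  expect_true(any(grepl("^CONECT", lines)))
  expect_equal(nrow(m3$bonds), nrow(m2$bonds))
})

test_that("writing an empty/invalid model is refused", {
  expect_error(write_pdb(list(), tempfile()), "empty or invalid")
})

test_that("glycan attachment places C1 near the Asn sidechain N and conserves atoms", {
  m <- asn_protein_stub()
  g <- make_glycan_template()
  m2 <- attach_glycan(m, list(segment_id = "A", residue_number = 297),
                      glycan_template = g)
  expect_equal(n_atoms(m2), n_atoms(m) + n_atoms(g))
  nd2 <- which(m2$atoms$atom_name == "ND2")
  c1 <- which(m2$atoms$is_glycan)[1]
  d <- sqrt(sum((coords(m2)[nd2, ] - coords(m2)[c1, ])^2))
  expect_lte(d, 0.14)
  # no clash between placed glycan and protein heavy atoms
  gl <- coords(m2)[m2$atoms$is_glycan, ]
  pr <- coords(m2)[!m2$atoms$is_glycan & m2$atoms$residue_number != 297, ]
  expect_gte(flexsas:::.min_cross_dist(gl, pr), 0.20)
})

test_that("glycan attachment to a non-Asn residue errors", {
  m <- asn_protein_stub()
  expect_error(attach_glycan(m, list(segment_id = "A", residue_number = 1)),
               "not ASN")
})

test_that("strip_glycans removes exactly the glycan atoms and is idempotent", {
  m <- asn_protein_stub()
  m2 <- attach_glycan(m, list(segment_id = "A", residue_number = 297))
  n_gly <- sum(m2$atoms$is_glycan)
  s1 <- strip_glycans(m2)
  expect_equal(n_atoms(s1), n_atoms(m2) - n_gly)
  expect_equal(coords(s1), coords(m))
  expect_equal(s1$atoms$atom_name, m$atoms$atom_name)
  s2 <- strip_glycans(s1)
  expect_identical(s1, s2)
})

test_that("scattering-length assignment follows the element tables and H/D exchange", {
  at <- tibble::tibble(
    element = c("C", "N", "O", "H", "H"),
    atom_name = c("CA", "N", "O", "H", "HG"),
    residue_name = "CYS", residue_number = 1L, segment_id = "A",
    x = c(0, 0.15, 0.3, 0.45, 0.6), y = 0, z = 0,
    is_hydrogen = c(FALSE, FALSE, FALSE, TRUE, TRUE),
    is_exchangeable = c(FALSE, FALSE, FALSE, FALSE, TRUE))
  m <- atomic_model(at)
  bH <- flexsas_constants$b_H_fm
  bD <- flexsas_constants$b_D_fm
  m0 <- assign_scattering_lengths(m, d2o_fraction = 0)
  expect_equal(m0$atoms$xray_b, c(6, 7, 8, 1, 1))     # atomic numbers
  expect_equal(m0$atoms$neutron_b[5], bH)              # no-exchange limit
  m1 <- assign_scattering_lengths(m, d2o_fraction = 1,
                                  exchange_fraction = 1)
  expect_equal(m1$atoms$neutron_b[5], bD)              # full exchange
  expect_equal(m1$atoms$neutron_b[4], bH)              # non-labile H keeps b_H
  mh <- assign_scattering_lengths(m, d2o_fraction = 0.5,
                                  exchange_fraction = 0.8)
  expect_equal(mh$atoms$neutron_b[5], 0.6 * bH + 0.4 * bD)
  expect_error(
    assign_scattering_lengths(atomic_model(dplyr::mutate(at, element = "ZZ"))),
    "Unknown element")
})

test_that("total X-ray scattering length equals the sum of atomic numbers", {
  m <- assign_scattering_lengths(asn_protein_stub())
  z <- c(C = 6, N = 7, O = 8)[m$atoms$element]
  # stub has no explicit H: implicit-H electrons are folded in per residue
  n_impl <- sum(m$atoms$xray_b) - sum(z)
  expect_gte(n_impl, 0)
  at <- tibble::tibble(
    element = c("C", "S", "O"), atom_name = c("A", "B", "C"),
    residue_name = "XXX", residue_number = 1L, segment_id = "A",
    x = c(0, 1, 2), y = 0, z = 0)
  m2 <- assign_scattering_lengths(atomic_model(at))
  expect_equal(sum(m2$atoms$xray_b), 6 + 16 + 8)
})

test_that("model construction validates inputs", {
  at <- tibble::tibble(element = "C", atom_name = "A", residue_name = "ALA",
                       residue_number = 1L, segment_id = "A",
                       x = NA_real_, y = 0, z = 0)
  expect_error(atomic_model(at), "finite")
  at$x <- 0
  expect_error(atomic_model(at, bonds = rbind(c(1, 5))), "out of range")
})
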