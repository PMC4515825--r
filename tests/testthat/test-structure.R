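# A hand-built three-residue fixture with one ligand at a known distance:
# residue CA atoms on the x axis, ligand 3.5 A from the nearest CA.
make_toy_pdb <- function(path, lig_dist = 3.5, altloc_lines = NULL) {
  fmt <- thiamintargets:::format_pdb_line
  lines <- character(0)
  serial <- 0L
  for (r in 1:3) {
    for (atom in list(
      c("N", -0.5), c("CA", 0), c("C", 0.5)
    )) {
      serial <- serial + 1L
      lines <- c(lines, fmt(
        "ATOM", serial, atom[1], "GLY", "A", r,
        c(4 * (r - 1) + as.numeric(atom[2]), 0, 0),
        element = substr(atom[1], 1, 1)
      ))
    }
  }
  if (!is.null(altloc_lines)) lines <- c(lines, altloc_lines)
  lines <- c(
    lines,
    fmt("HETATM", 90L, "C1", "LIG", "A", 10L, c(0, lig_dist, 0), element = "C"),
    fmt("HETATM", 91L, "O1", "HOH", "A", 11L, c(50, 50, 50), element = "O"),
    "END"
  )
  writeLines(lines, path)
  path
}

test_that("PDB reading keeps protein/ligand split, drops waters, resolves altlocs", {
  tf <- withr::local_tempfile(fileext = ".pdb")
  make_toy_pdb(tf)
  m <- read_structure(tf)
  expect_s3_class(m, "structure_model")
  expect_equal(sum(m$atoms$record == "ATOM"), 9L)
  het <- hetero_groups(m)
  expect_equal(het$resid, "LIG") # the water was dropped
  expect_false(any(m$atoms$resid == "HOH"))

  # altloc: keep the higher-occupancy copy
  fmt <- thiamintargets:::format_pdb_line
  alt_a <- fmt("ATOM", 50L, "O", "GLY", "A", 2L, c(10, 0, 0), occ = 0.6, element = "O")
  alt_b <- fmt("ATOM", 51L, "O", "GLY", "A", 2L, c(20, 0, 0), occ = 0.4, element = "O")
  substr(alt_a, 17, 17) <- "A"
  substr(alt_b, 17, 17) <- "B"
  alt <- c(alt_a, alt_b)
  tf2 <- withr::local_tempfile(fileext = ".pdb")
  make_toy_pdb(tf2, altloc_lines = alt)
  m2 <- read_structure(tf2)
  o_atoms <- dplyr::filter(m2$atoms, elety == "O", resno == 2)
  expect_equal(nrow(o_atoms), 1L)
  expect_equal(o_atoms$x, 10)
  expect_equal(o_atoms$alt, "A")

  empty <- withr::local_tempfile(fileext = ".pdb")
  writeLines("END", empty)
  expect_error(read_structure(empty), class = "tt_structure_parse")
})

test_that("ligand contacts respect the cutoff and report minimum distances", {
  tf <- withr::local_tempfile(fileext = ".pdb")
  make_toy_pdb(tf, lig_dist = 3.5)
  m <- read_structure(tf)
  ct <- find_ligand_contacts(m, "LIG", cutoff = 4.0)
  expect_equal(ct$resno, 1L) # residues 2 and 3 are beyond 4 A
  expect_equal(ct$min_distance, 3.5, tolerance = 1e-9)
  # residue 2's closest atom is its N at (3.5, 0, 0): distance sqrt(3.5^2+3.5^2)
  expect_equal(
    nrow(find_ligand_contacts(m, "LIG", cutoff = sqrt(2) * 3.5 - 0.01)), 1L
  )
  expect_equal(
    nrow(find_ligand_contacts(m, "LIG", cutoff = sqrt(2) * 3.5 + 0.01)), 2L
  )
  expect_equal(nrow(find_ligand_contacts(m, "LIG", cutoff = 0.5)), 0L)
  expect_error(find_ligand_contacts(m, "XYZ"), class = "tt_ligand_not_found")
})

test_that("contact sets equal the all-pairs oracle and are monotone in cutoff", {
  withr::with_seed(303, {
    for (case in 1:8) {
      segs <- tibble::tibble(
        class = sample(c("helix", "strand", "loop"), 3, replace = TRUE),
        length = sample(4:8, 3, replace = TRUE)
      )
      g <- gen_backbone(
        segs,
        ligand_target = sample(sum(segs$length), 1),
        ligand_distance = runif(1, 2.5, 4),
        seed = case
      )
      tf <- withr::local_tempfile(fileext = ".pdb")
      writeLines(g$pdb, tf)
      m <- read_structure(tf)
      for (cutoff in c(3.5, 4.5, 6)) {
        got <- find_ligand_contacts(m, "LIG", cutoff)
        want <- oracle_contacts(m, "LIG", cutoff)
        expect_equal(as.data.frame(got), as.data.frame(want), tolerance = 1e-12)
      }
      inner <- find_ligand_contacts(m, "LIG", 3.5)
      outer <- find_ligand_contacts(m, "LIG", 4.5)
      expect_true(all(inner$resno %in% outer$resno))
    }
  })
})

test_that("torsion angles agree with an independent implementation", {
  withr::with_seed(17, {
    for (case in 1:200) {
      pts <- matrix(rnorm(12, sd = 3), nrow = 4)
      ours <- torsion_angle(pts[1, ], pts[2, ], pts[3, ], pts[4, ])
      ref <- bio3d::torsion.xyz(as.vector(t(pts)))
      # both live in (-180, 180]; compare modulo the wrap point
      delta <- (ours - ref) %% 360
      delta <- min(delta, 360 - delta)
      expect_lt(delta, 1e-6)
    }
  })
})

test_that("phi/psi of generated backbones match bio3d and classify exactly", {
  segs <- tibble::tibble(class = c("helix", "strand"), length = c(10, 10))
  g <- gen_backbone(segs, seed = 9)
  tf <- withr::local_tempfile(fileext = ".pdb")
  writeLines(g$pdb, tf)
  m <- read_structure(tf)

  a <- assess_conformation(m, "A", 1, 20)
  # interior residues carry the planned dihedrals, up to the 0.001 A
  # coordinate rounding of the PDB text format (~0.1 degree)
  expect_equal(a$residues$phi[2:20], g$truth$residues$phi[2:20], tolerance = 5e-3)
  expect_equal(a$residues$psi[1:19], g$truth$residues$psi[1:19], tolerance = 5e-3)
  # and bio3d's torsions agree with ours on the same file
  ref <- bio3d::torsion.pdb(bio3d::read.pdb(tf))
  expect_equal(a$residues$phi[2:20], unname(ref$phi[2:20]), tolerance = 1e-4)
  expect_equal(a$residues$psi[1:19], unname(ref$psi[1:19]), tolerance = 1e-4)

  helix <- assess_conformation(m, "A", 2, 9)
  expect_equal(helix$majority_class, "helix")
  expect_equal(unname(helix$class_fractions["helix"]), 1)
  strand <- assess_conformation(m, "A", 12, 19)
  expect_equal(strand$majority_class, "strand")
  expect_equal(unname(strand$class_fractions["strand"]), 1)
})

test_that("majority class counts fractions over classified residues, ties to loop", {
  segs <- tibble::tibble(class = c("helix", "strand"), length = c(5, 3))
  g <- gen_backbone(segs, seed = 21)
  tf <- withr::local_tempfile(fileext = ".pdb")
  writeLines(g$pdb, tf)
  m <- read_structure(tf)
  # interior window with 4 helix + 2 strand residues
  a <- assess_conformation(m, "A", 2, 7)
  expect_equal(a$majority_class, "helix")
  expect_equal(
    unname(a$class_fractions[c("helix", "strand")]),
    c(4 / 6, 2 / 6),
    tolerance = 1e-12
  )
  expect_equal(sum(a$class_fractions), 1)

  # 2 helix + 2 strand: tie resolves to loop
  tie <- assess_conformation(m, "A", 4, 7)
  expect_equal(tie$majority_class, "loop")

  expect_error(
    assess_conformation(m, "A", 100, 110),
    class = "tt_empty_selection"
  )
})

test_that("terminal residues without a dihedral are undefined", {
  segs <- tibble::tibble(class = "helix", length = 6)
  g <- gen_backbone(segs, seed = 2)
  tf <- withr::local_tempfile(fileext = ".pdb")
  writeLines(g$pdb, tf)
  m <- read_structure(tf)
  a <- assess_conformation(m, "A", 1, 6)
  expect_true(is.na(a$residues$phi[1]))
  expect_true(is.na(a$residues$psi[6]))
  expect_equal(a$residues$class[c(1, 6)], c("undefined", "undefined"))
  # fractions are taken over classified residues only
  expect_equal(sum(a$class_fractions), 1)
  expect_equal(unname(a$class_fractions["helix"]), 1)
})

test_that("min_site_distance returns the constructed separation and flags overlap", {
  tf <- withr::local_tempfile(fileext = ".pdb")
  make_toy_pdb(tf, lig_dist = 3.0)
  m <- read_structure(tf)
  res1 <- tibble::tibble(chain = "A", resno = 1L)
  expect_equal(min_site_distance(m, res1, ligand_selection("LIG")), 3.0)
  # residue-to-residue: closest atoms are C of 1 (x=0.5) and N of 2 (x=3.5)
  expect_equal(
    min_site_distance(m, res1, tibble::tibble(chain = "A", resno = 2L)),
    3.0
  )
  expect_error(
    min_site_distance(m, res1, res1),
    class = "tt_empty_selection"
  )
  expect_equal(min_site_distance(m, res1, res1, strict = FALSE), 0)
})

test_that("matches map onto structures through numbering maps and offsets", {
  tf <- withr::local_tempfile(fileext = ".pdb")
  make_toy_pdb(tf)
  m <- read_structure(tf)
  match <- list(start = 1L, end = 3L)
  ident <- map_match_to_structure(match, m, 0L, chain = "A")
  expect_equal(ident$resno, 1:3)
  expect_true(all(ident$resolved))

  # offset convention (e.g. expression tag): seq position + offset = resno
  shifted <- map_match_to_structure(list(start = 1L, end = 2L), m, 1L, chain = "A")
  expect_equal(shifted$resno, 2:3)

  # a position mapping to a missing residue is reported unresolved
  gap <- map_match_to_structure(list(start = 1L, end = 4L), m, 0L, chain = "A")
  expect_equal(sum(!gap$resolved), 1L)
  expect_error(
    map_match_to_structure(list(start = 1L, end = 4L), m, 0L, chain = "A", strict = TRUE),
    class = "tt_mapping_gap"
  )
})

test_that("contacts generalize to patterns that rediscover their source", {
  seqc <- "MKTAYIADSSTNQRWEKLVHGF"
  contacts <- tibble::tibble(
    chain = "A", resno = c(8L, 9L, 12L), resid = c("ASP", "SER", "ASN")
  )
  tpl <- contacts_to_pattern(contacts, seqc)
  expect_equal(pattern_to_string(tpl$pattern), "DSx(2)N")
  hit <- scan_sequence(tpl$pattern, seqc)
  expect_true(any(hit$start == 8L & hit$end == 12L))

  # alignment widens positions to observed residue sets and gap ranges
  aln <- c(
    ref = "MKTAYIADSSTNQRWEKLVHGF",
    hom1 = "MKTAYIAESS-NQRWEKLVHGF",
    hom2 = "MKTAYIADTSTNQRWEKLVHGF"
  )
  tpl2 <- contacts_to_pattern(contacts, seqc, alignment = aln)
  expect_equal(pattern_to_string(tpl2$pattern), "[DE][ST]x(1,2)N")
  expect_true(nrow(scan_sequence(tpl2$pattern, seqc)) >= 1L)

  expect_error(
    contacts_to_pattern(contacts[0, ], seqc),
    class = "tt_empty_contacts"
  )
  expect_error(
    contacts_to_pattern(contacts, seqc, alignment = c(x = "AAAA")),
    class = "tt_alignment_mismatch"
  )
})

test_that("multi-chain contacts emit one pattern per chain with a note", {
  seqc <- "ADSSTN"
  contacts <- tibble::tibble(
    chain = c("A", "A", "B"), resno = c(2L, 3L, 5L),
    resid = c("ASP", "SER", "THR")
  )
  expect_warning(
    out <- contacts_to_pattern(contacts, seqc),
    "span chains"
  )
  expect_named(out, c("A", "B"))
  expect_equal(pattern_to_string(out$A$pattern), "DS")
  expect_match(attr(out, "cross_chain_note"), "per chain")
})
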