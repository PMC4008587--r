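# Structure parsing, writing and interface geometry.

test_that("minimal PDB text parses into one residue and one nucleotide", {
  cx <- read_structure(minimal_pdb(), id = "mini")
  expect_s3_class(cx, "complex_structure")
  expect_equal(nrow(protein_residues(cx)), 1L)
  expect_equal(unique(cx$dna$resno), 1L)
  expect_equal(cx$resolution, 1.8)
  ## base/backbone partition: N9/N1 are base atoms, P/C1' are not
  expect_setequal(cx$dna$elety[cx$dna$base_atom], c("N9", "N1"))
  expect_setequal(cx$dna$elety[!cx$dna$base_atom], c("P", "C1'"))
})

test_that("waters, hydrogens and later altlocs are dropped", {
  txt <- append(minimal_pdb(),
    c("HETATM   90  O   HOH A  99       9.000   9.000   9.000  1.00  0.00           O",
      "ATOM     91  H   ALA A   1       0.500   0.500   0.000  1.00  0.00           H",
      "ATOM     92  CB AALA A   1       2.000  -1.000   0.000  1.00  0.00           C",
      "ATOM     93  CB BALA A   1       2.200  -1.000   0.000  1.00  0.00           C"),
    after = 5)
  cx <- read_structure(txt, id = "mini2")
  expect_equal(sum(cx$protein$elety == "CB"), 1L)
  expect_equal(cx$protein$x[cx$protein$elety == "CB"], 2.0)
  expect_false(any(cx$protein$elesy == "H"))
  base <- read_structure(minimal_pdb(), id = "mini")
  expect_equal(nrow(cx$protein), nrow(base$protein) + 1L)  # only CB added
  expect_equal(nrow(cx$dna), nrow(base$dna))
})

test_that("malformed coordinate records and proteinless input error", {
  bad <- minimal_pdb()
  bad[3] <- "ATOM      2  CA  ALA A   1       xxx"
  expect_error(read_structure(bad, "bad"), "line 3")
  dna_only <- minimal_pdb()[c(1, 6:8, 10:11)]
  expect_error(read_structure(dna_only, "apo"), "no protein content")
})

test_that("read/write round-trip preserves atoms and coordinates", {
  cx <- make_complex(30, n_bp = 6, seed = 11)
  txt <- write_structure(cx)
  back <- read_structure(txt, id = cx$id)
  expect_equal(nrow(back$protein), nrow(cx$protein))
  expect_equal(nrow(back$dna), nrow(cx$dna))
  expect_equal(back$protein$elety, cx$protein$elety)
  expect_equal(back$dna$elety, cx$dna$elety)
  expect_equal(back$dna$base_atom, cx$dna$base_atom)
  expect_lt(max(abs(back$protein$x - cx$protein$x),
                abs(back$protein$y - cx$protein$y),
                abs(back$protein$z - cx$protein$z),
                abs(back$dna$x - cx$dna$x)), 1e-3)
  expect_equal(back$resolution, cx$resolution)
  ## determinism of the writer
  expect_identical(txt, write_structure(cx))
})

test_that("a protein-only structure writes protein records only", {
  cx <- make_complex(5, n_bp = 0, seed = 3)
  txt <- write_structure(cx)
  expect_false(any(grepl(" D[ACGT] ", txt)))
  ## 1-residue complex: 5 atoms (incl CB) or 4 for glycine, + TER + END
  one <- make_complex(1, n_bp = 0, seed = 4, sequence = "A",
                      resolution = NA)
  txt1 <- write_structure(one)
  expect_equal(sum(grepl("^ATOM", txt1)), 5L)
  expect_equal(txt1[length(txt1)], "END")
})

test_that("interface rule uses strict inequality and base atoms only", {
  ## one CA exactly at 4.5 A from the only base atom, backbone P nearer
  prot <- data.frame(chain = "A", resno = 1L, icode = "", resid = "ALA",
                     aa = "A", elety = "CA", elesy = "C",
                     x = 0, y = 0, z = 0, stringsAsFactors = FALSE)
  dna <- data.frame(chain = "D", resno = 1L, icode = "", base = "A",
                    elety = c("N1", "P"), elesy = c("N", "P"),
                    base_atom = c(TRUE, FALSE),
                    x = c(4.5, 1.0), y = 0, z = 0, stringsAsFactors = FALSE)
  cx <- complex_structure("edge", prot, dna)
  expect_equal(nrow(interface_residues(cx, 4.5)), 0L)
  expect_equal(nrow(interface_residues(cx, 4.5 + 1e-9)), 1L)
  ## the 1.0-A-away backbone P counts only under contact_atoms = "all_dna"
  expect_equal(nrow(interface_residues(cx, 4.5, contact_atoms = "all_dna")),
               1L)
  ## no DNA -> empty set
  apo <- make_complex(5, n_bp = 0, seed = 9)
  expect_equal(nrow(interface_residues(apo)), 0L)
})

test_that("interface_residues matches the brute-force oracle", {
  for (seed in 1:50) {
    cx <- random_toy_complex(seed)
    got <- interface_residues(cx, 4.5)$key
    expect_identical(sort(got), sort(oracle_interface(cx, 4.5)),
                     label = sprintf("seed %d", seed))
  }
})

test_that("base-pair counting: duplex, single strand, deletion", {
  cx <- make_complex(40, n_bp = 8, seed = 21)
  expect_equal(count_base_pairs(cx), 8L)
  ## single-stranded: drop the complementary strand
  ss <- cx
  ss$dna <- ss$dna[ss$dna$chain == "D", , drop = FALSE]
  expect_equal(count_base_pairs(ss), 0L)
  ## delete one nucleotide from the complementary strand
  del <- cx
  del$dna <- del$dna[!(del$dna$chain == "E" & del$dna$resno == 5L), ,
                     drop = FALSE]
  expect_equal(count_base_pairs(del), 7L)
})

test_that("RNA chains are rejected with a warning", {
  txt <- append(minimal_pdb(), c(
    "ATOM     60  C1'   A R   1       6.000   5.000   9.000  1.00  0.00           C",
    "ATOM     61  O2'   A R   1       6.500   5.500   9.000  1.00  0.00           O"),
    after = 8)
  expect_warning(cx <- read_structure(txt, "rna"), "RNA")
  expect_false("R" %in% cx$dna$chain)
})
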