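test_that("parse_smiles builds valid hydrogen-depleted graphs", {
  carvacrol <- parse_smiles("CC(C)c1ccc(C)cc1O")
  expect_equal(n_atoms(carvacrol), 11)
  expect_equal(nrow(carvacrol$bonds), 11)
  expect_equal(cyclomatic_number(carvacrol), 1)
  expect_equal(sum(carvacrol$aromatic), 6)

  myrcene <- parse_smiles("CC(=CCCC(=C)C=C)C")
  expect_equal(n_atoms(myrcene), 10)
  expect_equal(cyclomatic_number(myrcene), 0)
  expect_equal(sum(myrcene$bonds$order == 2), 3)

  # carbon valence invariant: bond orders + implicit H = 4 everywhere
  for (smi in c("CC(C)c1ccc(C)cc1O", "CC(=CCCC(=C)C=C)C",
                "CC12CCC(CC1)C(C)(C)O2")) {
    g <- parse_smiles(smi)
    for (i in which(g$element == "C")) {
      sel <- g$bonds$i == i | g$bonds$j == i
      expect_equal(sum(g$bonds$order[sel]) + g$hcount[i], 4)
    }
  }
})

test_that("parse_smiles rejects malformed and disconnected input", {
  expect_error(parse_smiles("garbage(("), "parse error")
  expect_error(parse_smiles("C1CC"), "unclosed ring")
  expect_error(parse_smiles("CC.CC"), "disconnected")
  expect_error(parse_smiles(""), "non-empty")
  expect_error(parse_smiles("C)C"), "unmatched")
})

test_that("Kekule-written benzene is perceived aromatic (Hueckel rule)", {
  a <- parse_smiles("C1=CC=CC=C1C")   # toluene, Kekule form
  b <- parse_smiles("c1ccccc1C")
  expect_equal(sum(a$aromatic), 6)
  expect_equal(sort(table(hybridization(a))), sort(table(hybridization(b))))
  # cyclohexene must not be aromatic
  expect_equal(sum(parse_smiles("C1=CCCCC1")$aromatic), 0)
})

test_that("distance matrix matches hand counts and the Floyd-Warshall oracle", {
  p3 <- path_graph(3)
  D <- mol_distance_matrix(p3)
  expect_equal(attr(D, "s"), c(3, 2, 3))
  expect_equal(attr(D, "W2"), 8)

  pcym <- parse_smiles("CC(C)c1ccc(C)cc1")
  expect_equal(min(attr(mol_distance_matrix(pcym), "s")), 18)

  lib <- compound_library(validate = FALSE)
  for (smi in lib$smiles[c(2, 9, 18, 34, 41)]) {
    g <- parse_smiles(smi)
    D <- mol_distance_matrix(g)
    expect_equal(unname(D[, ]), unname(floyd_warshall_oracle(g)))
    # metric space invariants
    expect_true(all(D == t(D)))
    expect_true(all(diag(D) == 0))
  }
})

test_that("canonical SMILES round-trips to an isomorphic graph", {
  lib <- compound_library(validate = FALSE)
  for (smi in lib$smiles[c(1, 4, 9, 18, 30, 41, 42, 50)]) {
    g <- parse_smiles(smi)
    g2 <- parse_smiles(write_smiles(g))
    expect_true(graphs_isomorphic(g, g2), info = smi)
    # canonical emission is stable
    expect_identical(write_smiles(g), write_smiles(g2))
  }
})

test_that("compound library carries the printed activity fixtures", {
  w <- capture_warnings(lib <- compound_library(validate = TRUE))
  expect_true(any(grepl("confidence interval inconsistent", w)))
  expect_equal(nrow(lib), 50)
  expect_equal(lib$id, 1:50)

  carvacrol <- lib[lib$id == 4, ]
  expect_equal(carvacrol$name, "Carvacrol")
  expect_equal(carvacrol$lc50_iii, 5.5)
  expect_equal(c(carvacrol$lc50_iii_lo, carvacrol$lc50_iii_hi), c(5.28, 5.72))

  thymol <- lib[lib$id == 50, ]
  expect_equal(thymol$name, "Thymol")
  expect_equal(thymol$lc50_iv, 12.2)
  expect_equal(c(thymol$lc50_iv_lo, thymol$lc50_iv_hi), c(11.7, 12.7))

  myrcene <- lib[lib$id == 34, ]
  expect_equal(myrcene$name, "Myrcene")
  expect_equal(myrcene$lc50_pupae, 31.8)
  expect_equal(c(myrcene$lc50_pupae_lo, myrcene$lc50_pupae_hi), c(30.2, 33.2))

  # censored pupae entries
  expect_true(all(lib$lc50_pupae_censored[lib$id %in% c(23, 24)]))
  expect_true(all(is.na(lib$lc50_pupae[lib$id %in% c(23, 24)])))

  # every SMILES parses into a connected graph of plausible size
  for (k in seq_len(50)) {
    g <- parse_smiles(lib$smiles[k])
    expect_gte(n_atoms(g), 8)
    expect_lte(n_atoms(g), 15)
  }
})

test_that("SMILES file reader/writer round-trips", {
  lib <- compound_library(validate = FALSE)
  f <- withr::local_tempfile(fileext = ".smi")
  gs <- lapply(lib$smiles[1:5], parse_smiles)
  write_smiles_file(gs, f, names = lib$name[1:5])
  back <- read_smiles_file(f)
  expect_equal(nrow(back), 5)
  expect_equal(back$name, lib$name[1:5])
  for (k in 1:5)
    expect_true(graphs_isomorphic(gs[[k]], parse_smiles(back$smiles[k])))
  suppressWarnings(
    expect_error(read_smiles_file(withr::local_tempfile(fileext = ".smi")),
                 "cannot open|empty"))
})
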