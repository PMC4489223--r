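# PDB reading, validation, normalization, peptide checks, model writing.

test_that("read_pdb parses a synthetic structure and normalizes chain IDs", {
  s <- read_pdb(tiny_pdb_text(3))
  expect_s3_class(s, "receptor_structure")
  expect_equal(nrow(s$residues), 3L)
  expect_equal(unique(s$residues$chain), "A")
  expect_equal(nrow(s$atoms), 12L)
  expect_equal(dim(s$ca), c(3L, 3L))
  # blank chain ID normalized to A
  txt <- tiny_pdb_text(2)
  txt <- sub("(.{21})A", "\\1 ", txt)  # blank out the chain column
  s2 <- read_pdb(txt)
  expect_equal(unique(s2$residues$chain), "A")
})

test_that("read_pdb keeps only the first altloc of each atom", {
  txt <- c(
    "ATOM      1  N   ALA A   1      -0.700   1.000   0.200  1.00  0.00           N",
    "ATOM      2  CA AALA A   1       0.000   0.000   0.000  0.50  0.00           C",
    "ATOM      3  CA BALA A   1       9.000   9.000   9.000  0.50  0.00           C",
    "ATOM      4  C   ALA A   1       0.800   1.000  -0.200  1.00  0.00           C",
    "ATOM      5  O   ALA A   1       0.800   2.200  -0.200  1.00  0.00           O",
    "END")
  s <- read_pdb(txt)
  ca <- s$atoms[s$atoms$atom_name == "CA", ]
  expect_equal(nrow(ca), 1L)
  expect_equal(ca$x, 0)  # altloc A kept
})

test_that("read_pdb rejects non-protein and malformed input", {
  hoh <- "HETATM    1  O   HOH A   1       0.000   0.000   0.000  1.00  0.00           O"
  expect_error(read_pdb(c(hoh, "END")), "no protein residues")
  expect_error(read_pdb(c("REMARK nothing", "END")), "no ATOM records")
  bad <- tiny_pdb_text(2)
  bad[2] <- sub("   0.000", "  xx.000", bad[2])
  expect_error(read_pdb(bad), "line 2")
})

test_that("validate_receptor enforces backbone completeness and chain length", {
  s <- read_pdb(tiny_pdb_text(3))
  expect_invisible(validate_receptor(s))

  # drop the O atom of residue 2 -> violation naming that residue
  txt <- tiny_pdb_text(3)
  is_o2 <- trimws(substr(txt, 13, 16)) == "O" &
    suppressWarnings(as.integer(substr(txt, 23, 26))) == 2L
  txt <- txt[!(is_o2 %in% TRUE)]
  s2 <- read_pdb(txt)
  v <- receptor_violations(s2)
  expect_equal(nrow(v), 1L)
  expect_equal(v$res_seq, 2L)
  expect_match(v$detail, "O")
  expect_error(validate_receptor(s2), "residue 2")

  # chain longer than the cap (validated with a reduced cap: the rule is
  # the same comparison, and building 501 real residues is wasteful)
  s3 <- read_pdb(tiny_pdb_text(6))
  expect_error(validate_receptor(s3, max_chain_length = 5L), "chain_too_long")
  v3 <- receptor_violations(s3, max_chain_length = 5L)
  expect_equal(v3$type, "chain_too_long")
  # default cap is 500
  expect_identical(formals(receptor_violations)$max_chain_length, 500L)
})

test_that("validate_receptor matches brute-force backbone-set check", {
  set.seed(42)
  for (rep in 1:5) {
    txt <- tiny_pdb_text(4)
    drop <- sample(c(TRUE, FALSE), 1)
    if (drop) {
      cand <- which(trimws(substr(txt, 13, 16)) %in% c("N", "C", "O") &
                      startsWith(txt, "ATOM"))
      txt <- txt[-sample(cand, 1)]
    }
    s <- read_pdb(txt)
    # oracle: per residue, set equality with {N, CA, C, O}
    ok <- all(vapply(split(s$atoms$atom_name, s$atoms$global_index),
                     function(a) all(c("N", "CA", "C", "O") %in% a),
                     logical(1)))
    expect_equal(nrow(receptor_violations(s)) == 0L, ok)
  }
})

test_that("normalize_nonstandard maps known names, errors on unknown, idempotent", {
  s <- read_pdb(tiny_pdb_text(3, res_names = c("MSE", "ALA", "SEC")))
  s2 <- normalize_nonstandard(s)
  expect_equal(s2$residues$res_name, c("MET", "ALA", "CYS"))
  # idempotent
  expect_identical(normalize_nonstandard(s2), s2)
  # all-standard input returned unchanged
  s3 <- read_pdb(tiny_pdb_text(2))
  expect_identical(normalize_nonstandard(s3)$residues, s3$residues)
  # unmappable name errors (XYZ-like names are dropped at parse time, so
  # inject a fake mapping entry to carry it through, then normalize without)
  s4 <- read_pdb(tiny_pdb_text(2, res_names = c("XYZ", "ALA")),
                 mapping = c(XYZ = "ALA"))
  expect_error(normalize_nonstandard(s4, mapping = c(MSE = "MET")), "XYZ")
})

test_that("validate_peptide enforces length, alphabet and ss contract", {
  sp <- validate_peptide("acdefg")
  expect_equal(sp$sequence, "ACDEFG")
  expect_equal(sp$ss, "CCCCCC")
  sp2 <- validate_peptide("ACD", "HEC")
  expect_equal(sp2$ss, "HEC")
  expect_error(validate_peptide(strrep("A", 31)), "1-30")
  expect_error(validate_peptide("ACB"), "non-standard")
  expect_error(validate_peptide("ACD", "HH"), "length")
  expect_error(validate_peptide("ACD", "HXC"), "H, E or C")
})

test_that("write_models_pdb writes Calpha models that round-trip", {
  rec <- toy_receptor_chain(10)
  pep <- toy_peptide_chain("FKWDE")
  cx <- cg_complex(rec, pep)
  f <- withr::local_tempfile(fileext = ".pdb")
  lines <- write_models_pdb(list(cx), f)
  expect_equal(sum(grepl("^ATOM", lines)), 15L)  # 10 receptor + 5 peptide
  expect_equal(sum(startsWith(lines, "MODEL")), 1L)
  # peptide chain distinct from receptor chains
  pep_lines <- lines[startsWith(lines, "ATOM") & substr(lines, 22, 22) == "P"]
  expect_equal(length(pep_lines), 5L)
  # round trip to 1e-3 A
  models <- read_ca_models(f)
  expect_equal(length(models), 1L)
  got <- models[[1]]$ca
  expect_lt(max(abs(got - rbind(rec$ca, pep$ca))), 1e-3 + 1e-9)
  expect_error(write_models_pdb(list(), f), "empty")
})

test_that("receptor PDB writer round-trips coordinates and ordering", {
  set.seed(7)
  s <- globule_receptor(20)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_receptor_pdb(s, f)
  s2 <- read_pdb(f)
  expect_equal(s2$residues$res_name, s$residues$res_name)
  expect_equal(s2$residues$res_seq, s$residues$res_seq)
  expect_lt(max(abs(s2$ca - s$ca)), 1e-3 + 1e-9)
  # second round trip is exact (formatting precision already applied)
  f2 <- withr::local_tempfile(fileext = ".pdb")
  write_receptor_pdb(s2, f2)
  expect_identical(readLines(f)[grepl("^ATOM.{7} CA", readLines(f))],
                   readLines(f2)[grepl("^ATOM.{7} CA", readLines(f2))])
})
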