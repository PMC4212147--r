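test_that("SMILES parsing perceives the heavy-atom graph and implicit hydrogens", {
  m <- mol_ethanol()
  expect_equal(nrow(m$atoms), 3L)
  expect_equal(sort(m$atoms$element), c("C", "C", "O"))
  expect_equal(nrow(m$bonds), 2L)
  expect_true(all(m$bonds$order == 1L))
  expect_equal(sum(m$atoms$nH), 6L)

  b <- mol_benzene()
  expect_equal(nrow(b$atoms), 6L)
  expect_true(all(b$atoms$aromatic))
  expect_equal(sum(b$bonds$aromatic), 6L)
})

test_that("malformed SMILES raise structured errors instead of silently skipping", {
  expect_error(parse_structure("C1CC"), "unparseable")
  expect_error(parse_smiles(c("CCO", "C1CC"), ids = c("a", "b")), "b")
  res <- suppressWarnings(parse_smiles(c("CCO", "C1CC"), ids = c("a", "b"),
                                       on_error = "skip"))
  expect_named(res, "a")
  expect_equal(attr(res, "failed_ids"), "b")
})

test_that("parsing is deterministic", {
  m1 <- parse_structure("Oc1ccc(Cl)cc1", id = "x")
  m2 <- parse_structure("Oc1ccc(Cl)cc1", id = "x")
  expect_identical(m1$atoms, m2$atoms)
  expect_identical(m1$bonds, m2$bonds)
})

test_that("molecule invariants hold across the fixture library", {
  for (m in library_molecules()) {
    expect_gte(nrow(m$atoms), 1L)
    if (nrow(m$bonds)) {
      expect_true(all(m$bonds$i >= 1L & m$bonds$j <= nrow(m$atoms)))
      expect_true(all(m$bonds$i != m$bonds$j))
      expect_false(anyDuplicated(m$bonds[, c("i", "j")]) > 0)
      # aromatic bonds join aromatic atoms
      ar <- m$bonds$aromatic
      expect_true(all(m$atoms$aromatic[m$bonds$i[ar]]))
      expect_true(all(m$atoms$aromatic[m$bonds$j[ar]]))
    }
  }
})

test_that("canonical SMILES round-trip preserves the heavy-atom graph", {
  mols <- library_molecules()
  for (m in mols[seq(1, length(mols), by = 7)]) {
    back <- parse_structure(write_smiles(m), id = m$id)
    expect_equal(nrow(back$atoms), nrow(m$atoms), info = m$id)
    expect_equal(sort(back$atoms$element), sort(m$atoms$element), info = m$id)
    expect_equal(sum(back$atoms$nH), sum(m$atoms$nH), info = m$id)
    # bond multiset with aromatic bonds treated uniformly
    bond_sig <- function(x) sort(paste0(ifelse(x$bonds$aromatic, "ar", x$bonds$order)))
    expect_equal(bond_sig(back), bond_sig(m), info = m$id)
  }
})

test_that("dot-disconnected SMILES keep the largest fragment with a warning", {
  expect_warning(m <- parse_structure("[Na+].CC(=O)[O-]", id = "salt"),
                 "largest fragment")
  expect_equal(sort(m$atoms$element), c("C", "C", "O", "O"))
  expect_equal(sum(m$atoms$charge), -1L)
})

test_that("single SDF blocks parse through the same pipeline", {
  src <- parse_structure("CC(=O)O", id = "acetic")
  block <- paste(c(src$sdf, "$$$$"), collapse = "\n")
  m <- parse_structure(block)
  expect_equal(nrow(m$atoms), 4L)
  expect_equal(m$source_smiles, "CC(=O)O")
})

test_that("read_dataset parses valid files and reports problems by row", {
  ok <- data.frame(id = paste0("m", 1:5),
                   smiles = c("CCO", "c1ccccc1", "CCN", "CC(=O)O", "CCCC"),
                   value = c(1.2, -0.5, 0.3, 2.2, 0.9))
  d <- read_dataset(write_temp_dataset(ok))
  expect_s3_class(d, "property_dataset")
  expect_equal(nrow(d), 5L)
  expect_true(all(vapply(d$mol, inherits, logical(1), "molecule")))

  bad <- ok
  bad$smiles[3] <- "C1CC"
  path <- write_temp_dataset(bad)
  expect_error(read_dataset(path), "row 3")
  expect_warning(d2 <- read_dataset(path, on_error = "skip"), "row 3")
  expect_equal(nrow(d2), 4L)

  dup <- ok; dup$id[2] <- "m1"
  expect_error(read_dataset(write_temp_dataset(dup)), "duplicate id")

  nonnum <- ok; nonnum$value <- as.character(nonnum$value); nonnum$value[4] <- "high"
  expect_error(read_dataset(write_temp_dataset(nonnum)), "row 4")

  expect_error(read_dataset(write_temp_dataset(ok[, 1:2])), "missing column")
})

test_that("tab-separated dataset files are accepted", {
  df <- data.frame(id = c("a", "b", "c", "d"), smiles = c("C", "CC", "CCC", "CO"),
                   value = 1:4)
  tf <- tempfile(fileext = ".tsv")
  readr::write_tsv(df, tf)
  d <- read_dataset(tf)
  expect_equal(d$id, df$id)
})
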