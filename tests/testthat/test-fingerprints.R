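test_that("single-atom molecules hash exactly one path per hashed family", {
  m <- parse_structure("C", id = "methane")
  expect_identical(enumerate_paths(m), "C")
  for (ty in c("default", "graph_only", "hybridization")) {
    fp <- compute_fingerprint(m, ty)
    expect_length(fp$set_bits, 1L)
    expect_true(all(fp$set_bits >= 0 & fp$set_bits < fp$length))
  }
  # methane has no rings: extended adds nothing beyond the hashed segment
  expect_identical(compute_fingerprint(m, "extended")$set_bits,
                   compute_fingerprint(m, "default")$set_bits)
})

test_that("fingerprints are deterministic for every family", {
  m1 <- parse_structure("Oc1ccc(Cl)cc1", id = "x")
  m2 <- parse_structure("Oc1ccc(Cl)cc1", id = "x")
  for (ty in list_fingerprint_types()$name) {
    expect_identical(compute_fingerprint(m1, ty)$set_bits,
                     compute_fingerprint(m2, ty)$set_bits, info = ty)
  }
})

test_that("graph-only paths ignore bond orders: benzene equals cyclohexane", {
  b <- mol_benzene(); chx <- mol_cyclohexane()
  # brute-force path enumeration confirms equal path-string sets
  expect_setequal(enumerate_paths(b, 7, FALSE, FALSE),
                  enumerate_paths(chx, 7, FALSE, FALSE))
  expect_identical(compute_fingerprint(b, "graph_only")$set_bits,
                   compute_fingerprint(chx, "graph_only")$set_bits)
  # but not for the aromaticity-aware default family
  expect_false(identical(compute_fingerprint(b, "default")$set_bits,
                         compute_fingerprint(chx, "default")$set_bits))
})

test_that("hybridization family uses Kekule orders without aromaticity", {
  b <- mol_benzene()
  paths <- enumerate_paths(b, 7, TRUE, FALSE)
  expect_true(any(grepl("=", paths, fixed = TRUE)))
  expect_false(any(grepl(":", paths, fixed = TRUE)))
  expect_false(any(grepl("c", paths, fixed = TRUE)))
})

test_that("extended is a superset of default on the shared hashed segment", {
  for (m in probe_molecules()) {
    d <- compute_fingerprint(m, "default")
    e <- compute_fingerprint(m, "extended")
    expect_true(all(d$set_bits %in% e$set_bits), info = m$id)
    expect_equal(e$length, d$length + 16L)
  }
  # ring-feature block fires for ring systems
  b <- compute_fingerprint(mol_benzene(), "extended")
  expect_true(any(b$set_bits >= 1024L))
})

test_that("the registry lists the nine shipped families and accepts plugins", {
  tb <- list_fingerprint_types()
  expect_setequal(tb$name, c("default", "extended", "graph_only",
                             "hybridization", "estate", "maccs", "pubchem",
                             "substructure", "klekota_roth"))
  expect_equal(tb$length[tb$name == "estate"], 79L)
  expect_equal(tb$length[tb$name == "maccs"], 166L)
  expect_equal(tb$length[tb$name == "substructure"], 307L)
  expect_equal(tb$length[tb$name == "pubchem"], 881L)
  expect_equal(tb$length[tb$name == "klekota_roth"], 4860L)

  register_fingerprint("plugin_test", 16L,
                       function(mol, len, trace) integer(0))
  expect_equal(nrow(list_fingerprint_types()), 10L)
  expect_error(register_fingerprint("plugin_test", 16L, function(...) NULL),
               "already registered")
  simdex:::reset_fingerprint_registry()
  expect_equal(nrow(list_fingerprint_types()), 9L)

  expect_error(compute_fingerprint(mol_ethanol(), "no_such_type"),
               "unknown fingerprint type")
})

test_that("key-family catalogs have the published lengths and valid entries", {
  expect_equal(nrow(catalog_estate()), 79L)
  expect_equal(nrow(catalog_maccs()), 166L)
  expect_equal(nrow(catalog_substructure()), 307L)
  expect_equal(nrow(catalog_pubchem()), 881L)
  expect_equal(nrow(catalog_klekota_roth()), 4860L)
  for (cat_tb in list(catalog_estate(), catalog_maccs(), catalog_pubchem())) {
    expect_false(any(duplicated(stats::na.omit(cat_tb$key))))
    expect_true(all(nzchar(cat_tb$smarts)))
  }
})

test_that("each key bit equals its own pattern's match against an independent SMARTS engine", {
  # sampled per-pattern oracle: Open Babel SMARTS search vs the native matcher
  mols <- probe_molecules()
  set.seed(11)
  fams <- list(estate = catalog_estate(), maccs = catalog_maccs(),
               substructure = catalog_substructure(),
               pubchem = catalog_pubchem(),
               klekota_roth = catalog_klekota_roth())
  for (fam in names(fams)) {
    cat_tb <- fams[[fam]]
    idx <- sample(nrow(cat_tb), 10L)
    for (m in mols[c(1, 4, 6)]) {
      bits <- simdex:::key_catalog_bits(m, cat_tb)
      sdf <- simdex:::molecules_to_sdfset(list(m))
      for (i in idx) {
        ob <- suppressWarnings(
          ChemmineR::smartsSearchOB(sdf, cat_tb$smarts[i], uniqueMatches = TRUE)
        )[1L] > 0
        expect_equal((i - 1L) %in% bits, unname(ob),
                     info = paste(fam, cat_tb$smarts[i], m$id))
      }
    }
  }
})

test_that("every hashed set bit is traceable to an enumerated path", {
  for (m in probe_molecules()[c(2, 5, 9)]) {
    fp <- compute_fingerprint(m, "default", trace = TRUE)
    tr <- attr(fp, "trace")
    expect_setequal(as.integer(names(tr)), fp$set_bits)
    # re-hashing each traced path reproduces its bit
    for (bit in names(tr)) {
      expect_true(all(simdex:::fnv1a32(tr[[bit]]) %% 1024 == as.integer(bit)))
    }
  }
})

test_that("the stable hash is fixed across calls and distinct on a probe set", {
  h1 <- simdex:::fnv1a32(c("C", "C-C", "c:c"))
  h2 <- simdex:::fnv1a32(c("C", "C-C", "c:c"))
  expect_identical(h1, h2)
  expect_equal(length(unique(h1)), 3L)
  expect_true(all(h1 >= 0 & h1 < 2^32))
})

test_that("fingerprint CSV dumps round-trip the set bits", {
  tf <- tempfile(fileext = ".csv")
  out <- write_fingerprints(probe_molecules()[1:3], tf,
                            types = c("default", "maccs"))
  expect_equal(nrow(out), 6L)
  back <- readr::read_csv(tf, show_col_types = FALSE)
  fp <- compute_fingerprint(probe_molecules()[[1]], "default")
  bits <- as.integer(strsplit(back$set_bits[back$id == "p1" &
                                            back$type == "default"], ";")[[1]])
  expect_identical(bits, fp$set_bits)
})

test_that("hashed families accept a custom length, key families do not", {
  m <- mol_ethanol()
  fp <- compute_fingerprint(m, "default", length = 256L)
  expect_equal(fp$length, 256L)
  expect_true(all(fp$set_bits < 256L))
  expect_error(compute_fingerprint(m, "maccs", length = 256L), "fixed length")
})
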