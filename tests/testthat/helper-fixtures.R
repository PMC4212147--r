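# Shared, lazily-built test objects. Everything is generated in code; the
# expensive ones (functional-group keys, fingerprint sets) are memoised so
# multiple test files reuse them within one session.

.test_cache <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (is.null(.test_cache[[key]])) .test_cache[[key]] <- builder()
  .test_cache[[key]]
}

mol_ethanol <- function() memo("ethanol", function() parse_structure("CCO", id = "ethanol"))
mol_benzene <- function() memo("benzene", function() parse_structure("c1ccccc1", id = "benzene"))
mol_cyclohexane <- function() memo("chx", function() parse_structure("C1CCCCC1", id = "chx"))

# a small structurally varied set for oracle/property checks
probe_molecules <- function() {
  memo("probe", function() {
    parse_smiles(
      c("CCO", "c1ccccc1", "CC(=O)NC", "Oc1ccc(Cl)cc1", "CC(C)=CC",
        "c1ccsc1", "CCBr", "C[N+](=O)[O-]", "COP(=O)(OC)OC", "CB(O)O"),
      ids = paste0("p", 1:10)
    )
  })
}

library_molecules <- function() {
  memo("libmols", function() {
    lib <- fixture_library()
    parse_smiles(lib$smiles, ids = lib$id)
  })
}

fixture30 <- function(which = "a") {
  memo(paste0("fx30", which), function() {
    if (which == "a") {
      build_fixture(n = 30L, beta = c(MW = 0.01, nHet = -0.5), sigma = 0.1,
                    seed = 42L, endpoint_name = "bcf_like")
    } else {
      build_fixture(n = 30L, beta = c(nC = 0.25, nHet = -0.3), sigma = 0.1,
                    seed = 43L, endpoint_name = "logp_like")
    }
  })
}

fixture50 <- function(sigma = 0.1) {
  memo(paste0("fx50_", sigma), function() {
    build_fixture(n = 50L, beta = c(MW = 0.01, nHet = -0.5), sigma = sigma,
                  seed = 42L)
  })
}

# descriptor keys for the 50-molecule fixture (molecule set is identical
# for every sigma: only the endpoint changes)
keys50 <- function(config = similarity_config()) {
  memo(paste0("keys50_", config$fingerprint), function() {
    molecule_keys(fixture50(0.1), config = config)
  })
}

keys30 <- function(which = "a") {
  memo(paste0("keys30", which), function() {
    molecule_keys(fixture30(which), config = similarity_config())
  })
}

# fingerprint lists for the 30-molecule fixture, one entry per family
fps30 <- function(type) {
  memo(paste0("fps30_", type), function() {
    lapply(fixture30("a")$mol, compute_fingerprint, type = type)
  })
}

make_fp <- function(bits, length = 8L, type = "test") {
  structure(list(type = type, length = as.integer(length),
                 set_bits = as.integer(sort(bits))),
            class = "bit_fingerprint")
}

write_temp_dataset <- function(df, ext = ".csv") {
  tf <- tempfile(fileext = ext)
  readr::write_csv(df, tf)
  tf
}

# independent brute-force oracle for the weight lattice: triple loop over
# multiples of 0.05, with the fp range on its own 0.1 grid
weight_oracle <- function() {
  out <- list()
  for (fp in seq(0.30, 1.00, by = 0.10)) {
    for (cd in seq(0.00, 0.40, by = 0.05)) {
      for (hd in seq(0.00, 1.00, by = 0.05)) {
        fg <- 1 - fp - cd - hd
        if (fg < -1e-9 || fg > 1 + 1e-9) next
        fg <- round(fg / 0.05) * 0.05
        if (abs(fp + cd + hd + fg - 1) > 1e-9) next
        out[[length(out) + 1L]] <- c(fp, cd, hd, fg)
      }
    }
  }
  m <- do.call(rbind, out)
  m[!duplicated(round(m * 20)), , drop = FALSE]
}

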