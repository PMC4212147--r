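# Packaged test chemistry: a curated SMILES library spanning all the
# hetero-atom types of the HD key, plus a seeded synthetic-property
# generator so every module (and both evaluation stages) can run
# end-to-end without external datasets.

#' Curated fixture molecule library
#'
#' A hand-written library of small organic molecules covering every
#' hetero-atom counted by the HD key (N, O, P, S, F, Cl, Br, I, B),
#' aromatic and aliphatic ring systems, and several homologous pairs that
#' differ only in the multiplicity of one functional group (e.g. ethanol /
#' ethylene glycol) - the case where occurrence counts outperform boolean
#' keys. The library is organised as dense homologous series (alkanes,
#' alcohols, acids, amines, halides, ... each in several chain lengths) so
#' that read-across always has close structural neighbours: by design,
#' every compound class appears in at least three members.
#'
#' @return A tibble with columns `id` and `smiles`.
#' @export
fixture_library <- function() {
  tibble::tribble(
    ~id, ~smiles,
    # n-alkanes
    "methane",            "C",
    "ethane",             "CC",
    "propane",            "CCC",
    "butane",             "CCCC",
    "pentane",            "CCCCC",
    "hexane",             "CCCCCC",
    "heptane",            "CCCCCCC",
    "octane",             "CCCCCCCC",
    # alkylbenzenes
    "benzene",            "c1ccccc1",
    "toluene",            "Cc1ccccc1",
    "ethylbenzene",       "CCc1ccccc1",
    "propylbenzene",      "CCCc1ccccc1",
    # 1-alcohols
    "methanol",           "CO",
    "ethanol",            "CCO",
    "propanol",           "CCCO",
    "butanol",            "CCCCO",
    "pentanol",           "CCCCCO",
    # diols (repeated hydroxyl vs ethanol)
    "ethylene_glycol",    "OCCO",
    "propanediol_13",     "OCCCO",
    "butanediol_14",      "OCCCCO",
    # phenols (catechol: repeated phenolic hydroxyl)
    "phenol",             "Oc1ccccc1",
    "cresol_p",           "Cc1ccc(O)cc1",
    "catechol",           "Oc1ccccc1O",
    "methylcatechol_4",   "Cc1ccc(O)c(O)c1",
    # ethers
    "dimethyl_ether",     "COC",
    "methyl_ethyl_ether", "CCOC",
    "diethyl_ether",      "CCOCC",
    # aldehydes
    "acetaldehyde",       "CC=O",
    "propanal",           "CCC=O",
    "butanal",            "CCCC=O",
    # monoacids
    "acetic_acid",        "CC(=O)O",
    "propanoic_acid",     "CCC(=O)O",
    "butanoic_acid",      "CCCC(=O)O",
    # diacids (repeated carboxyl)
    "malonic_acid",       "OC(=O)CC(=O)O",
    "succinic_acid",      "OC(=O)CCC(=O)O",
    "glutaric_acid",      "OC(=O)CCCC(=O)O",
    # amines
    "methylamine",        "CN",
    "ethylamine",         "CCN",
    "propylamine",        "CCCN",
    # diamines (repeated amino)
    "ethylenediamine",    "NCCN",
    "diaminopropane_13",  "NCCCN",
    # nitriles (succinonitrile: repeated cyano)
    "acetonitrile",       "CC#N",
    "propionitrile",      "CCC#N",
    "succinonitrile",     "N#CCCC#N",
    "glutaronitrile",     "N#CCCCC#N",
    # nitroalkanes
    "nitromethane",       "C[N+](=O)[O-]",
    "nitroethane",        "CC[N+](=O)[O-]",
    "nitropropane_1",     "CCC[N+](=O)[O-]",
    # fluoro
    "fluoroethane",       "CCF",
    "fluoropropane_1",    "CCCF",
    # chloro (dichloroethane: repeated chloride)
    "chloroethane",       "CCCl",
    "chloropropane_1",    "CCCCl",
    "chlorobutane_1",     "CCCCCl",
    "dichloroethane_12",  "ClCCCl",
    # bromo
    "bromoethane",        "CCBr",
    "bromopropane_1",     "CCCBr",
    "bromobutane_1",      "CCCCBr",
    "bromopentane_1",     "CCCCCBr",
    # iodo
    "iodomethane",        "CI",
    "iodoethane",         "CCI",
    "iodopropane_1",      "CCCI",
    "iodobutane_1",       "CCCCI",
    "iodopentane_1",      "CCCCCI",
    # sulfur
    "ethanethiol",        "CCS",
    "propanethiol_1",     "CCCS",
    "dimethyl_sulfide",   "CSC",
    # phosphate ester ladder
    "dimethyl_phosphate", "OP(=O)(OC)OC",
    "trimethyl_phosphate", "COP(=O)(OC)OC",
    "dimethyl_ethyl_phosphate", "CCOP(=O)(OC)OC",
    "diethyl_methyl_phosphate", "CCOP(=O)(OCC)OC",
    "triethyl_phosphate", "CCOP(=O)(OCC)OCC",
    # borate ester ladder
    "trimethyl_borate",   "COB(OC)OC",
    "dimethyl_ethyl_borate", "CCOB(OC)OC",
    "diethyl_methyl_borate", "CCOB(OCC)OC"
  )
}

#' Build a seeded synthetic property dataset
#'
#' Samples `n` molecules from the curated library and attaches a synthetic
#' endpoint: a stated linear combination of constitutional descriptors
#' plus Gaussian noise,
#' `y = sum(beta[d] * CD[d]) + N(0, sigma^2)`.
#' The same specification and seed always produce the identical dataset.
#' Because the property is generated from descriptors the similarity index
#' itself uses, read-across recovery on these fixtures is a meaningful
#' end-to-end check of the machinery (high LOO R^2 expected), not a claim
#' about real endpoints.
#'
#' @param n Number of molecules (must not exceed the library size).
#' @param beta Named numeric vector of coefficients over CD descriptor
#'   names (default `c(MW = 0.01, nHet = -0.5)`).
#' @param sigma Gaussian noise standard deviation (endpoint units).
#' @param seed Integer seed.
#' @param library A tibble with `id`, `smiles` columns (default
#'   [fixture_library()]).
#' @param endpoint_name Endpoint label.
#' @return A `property_dataset` tibble with the generator specification in
#'   attribute `fixture_spec` (list: `beta`, `sigma`, `seed`, `n`).
#' @export
build_fixture <- function(n = 50L, beta = c(MW = 0.01, nHet = -0.5),
                          sigma = 0.1, seed = 42L,
                          library = fixture_library(),
                          endpoint_name = "synthetic") {
  if (n > nrow(library)) {
    stop("n = ", n, " exceeds library size ", nrow(library), call. = FALSE)
  }
  if (is.null(names(beta)) || !all(names(beta) %in% cd_names)) {
    stop("beta must be named with CD descriptor names", call. = FALSE)
  }
  set.seed(seed)
  # stratified along the curated series ordering: the library lists each
  # homologous series consecutively, so drawing one member per stratum of
  # consecutive entries keeps every series represented in every sample
  bounds <- as.integer(round(seq(0L, nrow(library), length.out = n + 1L)))
  idx <- vapply(seq_len(n), function(i) {
    lo <- bounds[i] + 1L; hi <- bounds[i + 1L]
    if (lo > hi) lo <- hi
    if (lo == hi) lo else sample(lo:hi, 1L)
  }, integer(1))
  lib <- library[sort(unique(idx)), ]
  n <- nrow(lib)
  mols <- parse_smiles(lib$smiles, ids = lib$id)
  cd <- compute_cd(mols)
  signal <- as.matrix(cd[, names(beta), drop = FALSE]) %*% unname(beta)
  y <- as.numeric(signal) + stats::rnorm(n, 0, sigma)
  out <- as_property_dataset(
    tibble::tibble(id = lib$id, smiles = lib$smiles, value = y,
                   mol = unname(mols[lib$id])),
    endpoint_name = endpoint_name
  )
  attr(out, "fixture_spec") <- list(beta = beta, sigma = sigma,
                                    seed = seed, n = n)
  out
}

#' Write a fixture dataset to CSV plus a metadata sidecar
#'
#' Emits the standard `id,smiles,value` dataset CSV and, when the dataset
#' was built by [build_fixture()], a JSON sidecar (`<path>.meta.json`)
#' recording the generator coefficients, noise level and seed.
#'
#' @param data A property dataset.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_fixture <- function(data, path) {
  readr::write_csv(data[, c("id", "smiles", "value")], path)
  spec <- attr(data, "fixture_spec")
  if (!is.null(spec)) {
    jsonlite::write_json(
      list(beta = as.list(spec$beta), sigma = spec$sigma, seed = spec$seed,
           n = spec$n),
      paste0(path, ".meta.json"),
      auto_unbox = TRUE, digits = NA
    )
  }
  invisible(path)
}
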