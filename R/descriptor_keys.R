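# The three non-binary structural keys: constitutional descriptors (CD, 35),
# hetero-atom counters (HD, 11) and functional-group occurrence counts (FG).

cd_names <- c(
  "MW", "AMW", "Sv", "Mv", "Sp", "Mp", "Se", "Me", "nAt", "nSk", "nBt",
  "nBo", "nBm", "nDblBo", "nTrpBo", "nArBo", "SCBO", "nH", "nC", "nN",
  "nO", "nP", "nS", "nF", "nCl", "nBr", "nI", "nB", "HPerc", "CPerc",
  "NPerc", "OPerc", "XPerc", "nHet", "nX"
)
hd_names <- c("nN", "nO", "nP", "nS", "nF", "nCl", "nBr", "nI", "nB", "nHet", "nX")

#' Atomic constants table
#'
#' Per-element constants used by the constitutional key: standard atomic
#' mass (u), van der Waals volume, Sanderson electronegativity and atomic
#' polarizability, the last three scaled so carbon = 1 (volumes derived from
#' Bondi radii, electronegativities from Sanderson's 1983 scale,
#' polarizabilities from Miller's 1990 compilation). The shipped table is a
#' plain TSV under `extdata`; pass your own file to substitute values.
#'
#' @param path Path to a TSV with columns `element`, `mass`, `vdw_volume`,
#'   `sanderson_en`, `polarizability` (default: the shipped table).
#' @return A tibble with one row per element.
#' @export
atom_constants <- function(path = system.file("extdata", "atom_constants.tsv",
                                              package = "simdex")) {
  tb <- readr::read_tsv(path, col_types = "cdddd", progress = FALSE)
  need <- c("element", "mass", "vdw_volume", "sanderson_en", "polarizability")
  if (!all(need %in% names(tb))) {
    stop("atom constants file must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  carbon <- tb[tb$element == "C", ]
  if (nrow(carbon) != 1L ||
      any(abs(unlist(carbon[, c("vdw_volume", "sanderson_en", "polarizability")]) - 1) > 1e-6)) {
    stop("atom constants must be carbon-scaled (C row = 1)", call. = FALSE)
  }
  tb
}

as_molecule_list <- function(mol) {
  if (inherits(mol, "molecule")) return(list(mol))
  if (is.list(mol) && all(vapply(mol, inherits, logical(1), "molecule"))) return(mol)
  if (is.data.frame(mol) && "mol" %in% names(mol)) return(mol$mol)
  stop("expected a molecule, a list of molecules, or a dataset with a `mol` column",
       call. = FALSE)
}

#' Constitutional descriptors key (CD)
#'
#' Computes the 35-descriptor constitutional key for one or more molecules:
#' molecular weight, carbon-scaled sums/means of atomic van der Waals
#' volume, polarizability and Sanderson electronegativity, atom/bond/element
#' counts, bond-order sums and composition percentages. Hydrogens are
#' implicit: `nH` comes from perceived implicit-H counts, and `SCBO` sums
#' conventional bond orders over the H-depleted graph with aromatic bonds
#' counted as 1.5. `Sv`/`Sp`/`Se` sum over heavy atoms; `Mv`/`Mp`/`Me` are
#' their heavy-atom means.
#'
#' @param mol A `molecule`, list of molecules, or dataset with a `mol` column.
#' @param constants Atomic constants table, see [atom_constants()].
#' @return A tibble with one row per molecule and 35 named columns (plus a
#'   leading `id` column).
#' @export
compute_cd <- function(mol, constants = atom_constants()) {
  mols <- as_molecule_list(mol)
  rows <- lapply(mols, compute_cd_one, constants = constants)
  out <- dplyr::bind_rows(rows)
  tibble::add_column(out, id = vapply(mols, `[[`, character(1), "id"), .before = 1L)
}

compute_cd_one <- function(m, constants) {
  el <- m$atoms$element
  missing_el <- setdiff(unique(el), constants$element)
  if (length(missing_el)) {
    stop("molecule '", m$id, "': no atomic constants for element(s): ",
         paste(missing_el, collapse = ", "), call. = FALSE)
  }
  idx <- match(el, constants$element)
  h <- constants[constants$element == "H", ]
  if (nrow(h) != 1L) stop("atomic constants must include H", call. = FALSE)

  nSk <- length(el)
  nH <- sum(m$atoms$nH)
  nAt <- nSk + nH
  MW <- sum(constants$mass[idx]) + nH * h$mass
  Sv <- sum(constants$vdw_volume[idx])
  Sp <- sum(constants$polarizability[idx])
  Se <- sum(constants$sanderson_en[idx])

  b <- m$bonds
  nBo <- nrow(b)
  nDblBo <- sum(b$order == 2L & !b$aromatic)
  nTrpBo <- sum(b$order == 3L & !b$aromatic)
  nArBo <- sum(b$aromatic)
  SCBO <- sum(ifelse(b$aromatic, 1.5, b$order))

  cnt <- function(e) sum(el == e)
  nC <- cnt("C"); nN <- cnt("N"); nO <- cnt("O"); nP <- cnt("P"); nS <- cnt("S")
  nF <- cnt("F"); nCl <- cnt("Cl"); nBr <- cnt("Br"); nI <- cnt("I"); nB <- cnt("B")
  nX <- nF + nCl + nBr + nI
  tibble::tibble(
    MW = MW, AMW = MW / nAt, Sv = Sv, Mv = Sv / nSk, Sp = Sp, Mp = Sp / nSk,
    Se = Se, Me = Se / nSk, nAt = nAt, nSk = nSk, nBt = nBo + nH, nBo = nBo,
    nBm = nDblBo + nTrpBo + nArBo, nDblBo = nDblBo, nTrpBo = nTrpBo,
    nArBo = nArBo, SCBO = SCBO, nH = nH, nC = nC, nN = nN, nO = nO, nP = nP,
    nS = nS, nF = nF, nCl = nCl, nBr = nBr, nI = nI, nB = nB,
    HPerc = 100 * nH / nAt, CPerc = 100 * nC / nAt, NPerc = 100 * nN / nAt,
    OPerc = 100 * nO / nAt, XPerc = 100 * nX / nAt,
    nHet = nSk - nC, nX = nX
  )
}

#' Hetero-atom descriptors key (HD)
#'
#' The 11 hetero-atom counters (N, O, P, S, the four halogens, B, plus total
#' heteroatom and halogen counts). By construction a subset of the
#' constitutional key.
#'
#' @inheritParams compute_cd
#' @return A tibble with one row per molecule, columns `id` + the 11 counters.
#' @export
compute_hd <- function(mol) {
  mols <- as_molecule_list(mol)
  rows <- lapply(mols, function(m) {
    el <- m$atoms$element
    cnt <- function(e) sum(el == e)
    nX <- cnt("F") + cnt("Cl") + cnt("Br") + cnt("I")
    tibble::tibble(
      nN = cnt("N"), nO = cnt("O"), nP = cnt("P"), nS = cnt("S"),
      nF = cnt("F"), nCl = cnt("Cl"), nBr = cnt("Br"), nI = cnt("I"),
      nB = cnt("B"), nHet = length(el) - cnt("C"), nX = nX
    )
  })
  out <- dplyr::bind_rows(rows)
  tibble::add_column(out, id = vapply(mols, `[[`, character(1), "id"), .before = 1L)
}

#' Functional-group occurrence key (FG)
#'
#' Counts the occurrences of each functional-group SMARTS pattern in the
#' catalog (default: the shipped 154-entry curated catalog), using Open
#' Babel substructure matching with symmetry-equivalent duplicate matches
#' deduplicated by matched-atom set. Occurrence counts, not booleans, are
#' returned: two hydroxyls yield 2 on the hydroxyl entry.
#'
#' @inheritParams compute_cd
#' @param catalog A functional-group catalog, see [fg_catalog()].
#' @return A tibble with one row per molecule: `id` + one integer column per
#'   catalog entry (named `fg_<index>`).
#' @export
compute_fg <- function(mol, catalog = fg_catalog()) {
  mols <- as_molecule_list(mol)
  sdfset <- molecules_to_sdfset(mols)
  counts <- matrix(0L, nrow = length(mols), ncol = nrow(catalog))
  for (p in seq_len(nrow(catalog))) {
    res <- tryCatch(
      suppressWarnings(
        ChemmineR::smartsSearchOB(sdfset, catalog$smarts[p], uniqueMatches = TRUE)
      ),
      error = function(e) {
        stop("invalid SMARTS in FG catalog at index ", catalog$index[p], ": ",
             catalog$smarts[p], call. = FALSE)
      }
    )
    counts[, p] <- as.integer(res)
  }
  colnames(counts) <- paste0("fg_", catalog$index)
  out <- tibble::as_tibble(counts)
  tibble::add_column(out, id = vapply(mols, `[[`, character(1), "id"), .before = 1L)
}

#' Functional-group SMARTS catalog
#'
#' Loads a functional-group catalog: a TSV with columns `index`, `smarts`,
#' `name`. The shipped default is the package's own curated, openly
#' redistributable set of 154 common organic functional groups (the
#' proprietary Dragon definitions are not reproduced); any same-format file
#' can be substituted.
#'
#' @param path Path to a catalog TSV (default: shipped catalog).
#' @return A tibble with columns `index`, `smarts`, `name`.
#' @export
fg_catalog <- function(path = system.file("extdata", "fg_catalog.tsv",
                                          package = "simdex")) {
  tb <- readr::read_tsv(path, col_types = "icc", progress = FALSE)
  if (!all(c("index", "smarts", "name") %in% names(tb))) {
    stop("FG catalog must have columns index, smarts, name", call. = FALSE)
  }
  tb
}

# One SDFset for a list of molecules (explicit-H molblocks kept at parse time).
molecules_to_sdfset <- function(mols) {
  lines <- unlist(lapply(mols, function(m) c(m$sdf, "$$$$")), use.names = FALSE)
  tf <- tempfile(fileext = ".sdf")
  on.exit(unlink(tf))
  writeLines(lines, tf)
  ChemmineR::read.SDFset(ChemmineR::read.SDFstr(tf))
}

#' All four similarity keys for a set of molecules
#'
#' Convenience wrapper computing, for each molecule, the fingerprint named
#' in `config` plus the CD, HD and FG keys, returned in the internal layout
#' the similarity and read-across engines consume.
#'
#' @param mol A `molecule`, list of molecules, or dataset with `mol` column.
#' @param config A [similarity_config()].
#' @param constants,catalog Passed to [compute_cd()] / [compute_fg()].
#' @return A list with elements `ids`, `fp` (list of bit fingerprints),
#'   `cd`, `hd`, `fg` (numeric matrices, one row per molecule).
#' @export
molecule_keys <- function(mol, config = similarity_config(),
                          constants = atom_constants(), catalog = fg_catalog()) {
  mols <- as_molecule_list(mol)
  ids <- vapply(mols, `[[`, character(1), "id")
  fp <- lapply(mols, compute_fingerprint, type = config$fingerprint)
  cd <- as.matrix(compute_cd(mols, constants = constants)[, -1L])
  hd <- as.matrix(compute_hd(mols)[, -1L])
  fg <- as.matrix(compute_fg(mols, catalog = catalog)[, -1L])
  rownames(cd) <- rownames(hd) <- rownames(fg) <- ids
  list(ids = ids, fp = fp, cd = cd, hd = hd, fg = fg)
}
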