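# Molecule input: SMILES / SDF -> heavy-atom graph with implicit hydrogens.
# All structure perception (parsing, hydrogen addition, ring/aromaticity
# detection) is delegated to Open Babel via ChemmineOB/ChemmineR; this file
# only reshapes the result into the light-weight graph the rest of the
# package consumes.

#' Parse a molecular structure
#'
#' Parses a SMILES string or a single SDF/MOL (V2000) block into the package's
#' molecule representation: a heavy-atom graph with perceived aromaticity and
#' per-atom implicit hydrogen counts. Dot-disconnected inputs (salts,
#' mixtures) are reduced to the largest fragment by heavy-atom count with a
#' warning, the common QSAR convention. Stereochemistry is accepted on input
#' but not represented: none of the descriptors or fingerprints downstream
#' are stereo-aware.
#'
#' @param text A single SMILES string, or the text of one SDF/MOL block
#'   (recognised by its `V2000` counts line).
#' @param id Identifier to attach to the molecule (defaults to the input
#'   string for SMILES, the title line for SDF).
#' @return An object of class `molecule`: a list with elements `id`,
#'   `atoms` (tibble: `element`, `charge`, `aromatic`, `nH`), `bonds`
#'   (tibble: `i`, `j`, `order`, `aromatic`), `source_smiles`, and `sdf`
#'   (the hydrogen-explicit molblock lines used for SMARTS matching).
#' @examples
#' \donttest{
#' m <- parse_structure("CCO")
#' nrow(m$atoms)  # 3 heavy atoms
#' sum(m$atoms$nH)  # 6 implicit hydrogens
#' }
#' @export
parse_structure <- function(text, id = NULL) {
  stopifnot(is.character(text), length(text) == 1L)
  if (is_sdf_block(text)) {
    mols <- parse_sdf_blocks(text, ids = id)
  } else {
    mols <- parse_smiles(text, ids = id)
  }
  if (length(mols) != 1L) {
    stop("expected exactly one structure, got ", length(mols), call. = FALSE)
  }
  mols[[1L]]
}

#' Parse a batch of SMILES strings
#'
#' Vectorised SMILES parsing through a single Open Babel conversion.
#' Unparseable records either abort with an error naming the offending
#' records (`on_error = "stop"`) or are dropped with a warning
#' (`on_error = "skip"`); they are never silently lost.
#'
#' @param smiles Character vector of SMILES strings.
#' @param ids Unique identifiers, same length as `smiles` (default
#'   `"M1"`, `"M2"`, ...).
#' @param on_error `"stop"` (default) or `"skip"`.
#' @return A named list of `molecule` objects (names = ids); in skip mode
#'   failed records are absent and listed in the `failed_ids` attribute.
#' @export
parse_smiles <- function(smiles, ids = NULL, on_error = c("stop", "skip")) {
  on_error <- match.arg(on_error)
  stopifnot(is.character(smiles), length(smiles) >= 1L)
  if (is.null(ids)) ids <- paste0("M", seq_along(smiles))
  ids <- as.character(ids)
  if (anyDuplicated(ids)) stop("molecule ids must be unique", call. = FALSE)
  if (length(ids) != length(smiles)) stop("`ids` and `smiles` lengths differ", call. = FALSE)

  smiles_in <- smiles
  # Largest-fragment selection for dot-disconnected SMILES.
  multi <- grepl(".", smiles, fixed = TRUE)
  if (any(multi)) {
    for (k in which(multi)) smiles_in[k] <- largest_fragment_smiles(smiles[k], ids[k])
  }

  sdf_text <- tryCatch(
    ob_convert_quiet("SMI", "SDF",
                     paste0(smiles_in, "\t", ids, collapse = "\n"),
                     add_h = TRUE),
    error = function(e) ""
  )
  blocks <- split_sdf_text(sdf_text)
  got <- vapply(blocks, function(b) b[1L], character(1))
  # Open Babel may abort a batch at an invalid record; retry the missing
  # ones individually so one bad row never swallows its successors
  missing <- setdiff(ids, got)
  for (id_m in missing) {
    blk <- tryCatch({
      txt <- ob_convert_quiet("SMI", "SDF",
                              paste0(smiles_in[match(id_m, ids)], "\t", id_m),
                              add_h = TRUE)
      split_sdf_text(txt)
    }, error = function(e) list())
    if (length(blk) == 1L) {
      blocks <- c(blocks, blk)
      got <- c(got, blk[[1L]][1L])
    }
  }
  failed <- setdiff(ids, got)
  if (length(failed)) {
    msg <- paste0(
      "unparseable SMILES for record(s): ",
      paste0(failed, " (", smiles[match(failed, ids)], ")", collapse = ", ")
    )
    if (on_error == "stop") stop(msg, call. = FALSE)
    warning(msg, call. = FALSE)
  }
  keep <- match(setdiff(ids, failed), got)
  out <- lapply(keep, function(k) {
    build_molecule(blocks[[k]], id = got[k], source_smiles = smiles[match(got[k], ids)])
  })
  names(out) <- got[keep]
  attr(out, "failed_ids") <- failed
  out
}

#' @keywords internal
parse_sdf_blocks <- function(text, ids = NULL, on_error = "stop") {
  lines <- strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE)[[1L]]
  if (!any(grepl("\\$\\$\\$\\$", lines))) lines <- c(lines, "$$$$")
  # normalise through Open Babel: adds explicit H, rewrites V2000
  sdf_text <- ob_convert_quiet("SDF", "SDF", paste(lines, collapse = "\n"), add_h = TRUE)
  blocks <- split_sdf_text(sdf_text)
  if (!length(blocks)) stop("SDF input could not be parsed", call. = FALSE)
  can <- ob_convert_quiet("SDF", "CAN", paste(lines, collapse = "\n"))
  can_smiles <- vapply(
    strsplit(strsplit(can, "\n", fixed = TRUE)[[1L]], "\t", fixed = TRUE),
    `[`, character(1), 1L
  )
  if (is.null(ids)) {
    ids <- vapply(blocks, function(b) b[1L], character(1))
    ids[!nzchar(ids)] <- paste0("SDF", which(!nzchar(ids)))
  }
  out <- lapply(seq_along(blocks), function(k) {
    build_molecule(blocks[[k]], id = ids[k],
                   source_smiles = if (k <= length(can_smiles)) can_smiles[k] else NA_character_)
  })
  names(out) <- ids
  out
}

is_sdf_block <- function(text) {
  grepl("V2000", text, fixed = TRUE) || grepl("\n", text, fixed = TRUE)
}

# Pick the largest dot-separated fragment by heavy-atom count.
largest_fragment_smiles <- function(smi, id) {
  frags <- strsplit(smi, ".", fixed = TRUE)[[1L]]
  frags <- frags[nzchar(frags)]
  if (length(frags) == 1L) return(frags)
  counts <- vapply(frags, function(f) {
    sdf <- tryCatch(
      ob_convert_quiet("SMI", "SDF", paste0(f, "\tx")),
      error = function(e) NULL
    )
    if (is.null(sdf)) return(-1L)
    b <- split_sdf_text(sdf)
    if (!length(b)) return(-1L)
    sum(molblock_atoms(b[[1L]])$element != "H")
  }, integer(1))
  if (all(counts < 0L)) return(smi) # let downstream parsing raise the error
  warning("record '", id, "': dot-disconnected SMILES; keeping largest fragment",
          call. = FALSE)
  frags[which.max(counts)]
}

# One quiet Open Babel conversion; errors if conversion produced no output.
ob_convert_quiet <- function(from, to, source, add_h = FALSE) {
  out <- if (add_h) {
    suppressWarnings(ChemmineOB::convertFormat(
      from, to, source, options = data.frame(names = "h", args = "")
    ))
  } else {
    suppressWarnings(ChemmineOB::convertFormat(from, to, source))
  }
  if (!nzchar(out)) stop("Open Babel produced no output for ", from, " input", call. = FALSE)
  out
}

split_sdf_text <- function(sdf_text) {
  lines <- strsplit(sdf_text, "\n", fixed = TRUE)[[1L]]
  ends <- grep("^\\$\\$\\$\\$", lines)
  if (!length(ends)) return(list())
  starts <- c(1L, head(ends, -1L) + 1L)
  mapply(function(s, e) lines[s:(e - 1L)], starts, ends, SIMPLIFY = FALSE)
}

# Minimal V2000 molblock field extraction (the block itself always comes from
# Open Babel, so the layout is regular).
molblock_atoms <- function(block) {
  counts <- block[4L]
  na <- as.integer(substr(counts, 1L, 3L))
  nb <- as.integer(substr(counts, 4L, 6L))
  at <- block[5L:(4L + na)]
  element <- trimws(substr(at, 32L, 34L))
  charge <- integer(na)
  chg_lines <- grep("^M  CHG", block, value = TRUE)
  for (cl in chg_lines) {
    toks <- as.integer(strsplit(trimws(substr(cl, 7L, nchar(cl))), "\\s+")[[1L]])
    npair <- toks[1L]
    for (p in seq_len(npair)) {
      charge[toks[2L * p]] <- toks[2L * p + 1L]
    }
  }
  list(element = element, charge = charge, n_atoms = na, n_bonds = nb)
}

molblock_bonds <- function(block, na, nb) {
  if (nb == 0L) {
    return(data.frame(i = integer(), j = integer(), order = integer()))
  }
  bl <- block[(5L + na):(4L + na + nb)]
  data.frame(
    i = as.integer(substr(bl, 1L, 3L)),
    j = as.integer(substr(bl, 4L, 6L)),
    order = as.integer(substr(bl, 7L, 9L))
  )
}

#' @keywords internal
build_molecule <- function(block, id, source_smiles = NA_character_) {
  at <- molblock_atoms(block)
  bd <- molblock_bonds(block, at$n_atoms, at$n_bonds)
  if (any(bd$i == bd$j)) stop("molecule '", id, "': bond with identical endpoints", call. = FALSE)

  heavy <- which(at$element != "H")
  if (!length(heavy)) stop("molecule '", id, "': no heavy atoms", call. = FALSE)
  idx_map <- integer(at$n_atoms)
  idx_map[heavy] <- seq_along(heavy)

  is_h <- at$element == "H"
  nH <- integer(length(heavy))
  keep_bond <- logical(nrow(bd))
  for (r in seq_len(nrow(bd))) {
    hi <- is_h[bd$i[r]]; hj <- is_h[bd$j[r]]
    if (hi && hj) next
    if (hi) { nH[idx_map[bd$j[r]]] <- nH[idx_map[bd$j[r]]] + 1L; next }
    if (hj) { nH[idx_map[bd$i[r]]] <- nH[idx_map[bd$i[r]]] + 1L; next }
    keep_bond[r] <- TRUE
  }
  bonds <- bd[keep_bond, , drop = FALSE]
  bonds$i <- idx_map[bonds$i]
  bonds$j <- idx_map[bonds$j]
  swap <- bonds$i > bonds$j
  tmp <- bonds$i[swap]; bonds$i[swap] <- bonds$j[swap]; bonds$j[swap] <- tmp
  if (anyDuplicated(bonds[, c("i", "j")])) {
    stop("molecule '", id, "': duplicate bond", call. = FALSE)
  }

  # order 4 = pre-kekulised aromatic bond in user-supplied SDF input
  arom_from_order4 <- bonds$order == 4L
  bonds$order[arom_from_order4] <- 1L

  arom <- perceive_aromaticity(block, at$n_atoms, idx_map, bonds)
  atoms <- tibble::tibble(
    element = at$element[heavy],
    charge = at$charge[heavy],
    aromatic = arom$atoms,
    nH = nH
  )
  bonds_tb <- tibble::tibble(
    i = bonds$i, j = bonds$j,
    order = as.integer(bonds$order),
    aromatic = arom$bonds | arom_from_order4
  )
  structure(
    list(id = id, atoms = atoms, bonds = bonds_tb,
         ring_sizes = arom$ring_sizes,
         source_smiles = source_smiles, sdf = block),
    class = "molecule"
  )
}

# Aromatic atoms/bonds from ring perception (ChemmineR, which applies a
# Hueckel-style test per ring). Returns flags on the heavy-atom indexing.
perceive_aromaticity <- function(block, n_atoms, idx_map, bonds) {
  n_heavy <- sum(idx_map > 0L)
  atoms_flag <- logical(n_heavy)
  bonds_flag <- logical(nrow(bonds))
  none <- list(atoms = atoms_flag, bonds = bonds_flag, ring_sizes = integer(0))
  sdfset <- tryCatch(
    ChemmineR::read.SDFset(ChemmineR::read.SDFstr(tempfile_with(c(block, "$$$$"))))[[1L]],
    error = function(e) NULL
  )
  if (is.null(sdfset)) return(none)
  rg <- tryCatch(
    suppressWarnings(ChemmineR::rings(sdfset, type = "all", arom = TRUE)),
    error = function(e) NULL
  )
  if (is.null(rg) || !length(rg$RINGS)) return(none)
  key <- paste0
  bond_key <- key(pmin(bonds$i, bonds$j), "_", pmax(bonds$i, bonds$j))
  for (r in seq_along(rg$RINGS)) {
    if (!isTRUE(rg$AROMATIC[[r]])) next
    members <- as.integer(sub("^.*_", "", rg$RINGS[[r]]))
    hm <- idx_map[members]
    if (any(hm == 0L)) next
    atoms_flag[hm] <- TRUE
    ring_pairs <- cbind(hm, c(hm[-1L], hm[1L]))
    rk <- key(pmin(ring_pairs[, 1L], ring_pairs[, 2L]), "_",
              pmax(ring_pairs[, 1L], ring_pairs[, 2L]))
    bonds_flag[bond_key %in% rk] <- TRUE
  }
  list(atoms = atoms_flag, bonds = bonds_flag,
       ring_sizes = vapply(rg$RINGS, length, integer(1)))
}

tempfile_with <- function(lines) {
  tf <- tempfile(fileext = ".sdf")
  writeLines(lines, tf)
  tf
}

#' Canonical SMILES for a molecule
#'
#' @param mol A `molecule` object.
#' @return A single canonical SMILES string (Open Babel canonicalisation).
#' @export
write_smiles <- function(mol) {
  stopifnot(inherits(mol, "molecule"))
  out <- ob_convert_quiet("SDF", "CAN", paste(c(mol$sdf, "$$$$"), collapse = "\n"))
  strsplit(strsplit(out, "\n", fixed = TRUE)[[1L]][1L], "\t", fixed = TRUE)[[1L]][1L]
}

#' @export
print.molecule <- function(x, ...) {
  cat("<molecule> ", x$id, ": ", nrow(x$atoms), " heavy atoms, ",
      nrow(x$bonds), " bonds, formula H count ", sum(x$atoms$nH), "\n", sep = "")
  invisible(x)
}

#' Read a property dataset (id, smiles, value)
#'
#' Reads a delimited text file with header columns `id`, `smiles`, `value`
#' (any order, case-insensitive; comma- or tab-separated), parses every
#' structure, and returns a tidy dataset ready for similarity and
#' read-across computations. All row-level problems (missing columns,
#' duplicate ids, non-numeric values, unparseable SMILES) are collected and
#' reported with row numbers; in strict mode any problem aborts, in skip
#' mode offending rows are dropped with a warning.
#'
#' @param path Path to a CSV/TSV file.
#' @param endpoint_name Name of the measured endpoint (stored as an
#'   attribute; defaults to `"value"`).
#' @param on_error `"stop"` (default) or `"skip"`.
#' @return A tibble of class `property_dataset` with columns `id`, `smiles`,
#'   `value`, `mol` (list-column of `molecule` objects).
#' @export
read_dataset <- function(path, endpoint_name = "value", on_error = c("stop", "skip")) {
  on_error <- match.arg(on_error)
  if (!file.exists(path)) stop("dataset file not found: ", path, call. = FALSE)
  header <- readLines(path, n = 1L)
  delim <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(.default = "c"),
                           progress = FALSE)
  names(raw) <- tolower(names(raw))
  missing_cols <- setdiff(c("id", "smiles", "value"), names(raw))
  if (length(missing_cols)) {
    stop("dataset is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  problems <- character()
  row_no <- seq_len(nrow(raw))
  value <- suppressWarnings(as.numeric(raw$value))
  bad_value <- which(!is.finite(value))
  if (length(bad_value)) {
    problems <- c(problems, paste0("row ", bad_value, ": non-numeric value '",
                                   raw$value[bad_value], "'"))
  }
  dup <- which(duplicated(raw$id))
  if (length(dup)) {
    problems <- c(problems, paste0("row ", dup, ": duplicate id '", raw$id[dup], "'"))
  }
  keep <- setdiff(row_no, union(bad_value, dup))
  mols <- withCallingHandlers(
    parse_smiles(raw$smiles[keep], ids = raw$id[keep], on_error = "skip"),
    warning = function(w) invokeRestart("muffleWarning")
  )
  failed_ids <- attr(mols, "failed_ids")
  if (length(failed_ids)) {
    bad_rows <- keep[match(failed_ids, raw$id[keep])]
    problems <- c(problems, paste0("row ", bad_rows, ": unparseable SMILES '",
                                   raw$smiles[bad_rows], "'"))
    keep <- setdiff(keep, bad_rows)
  }
  if (length(problems)) {
    msg <- paste0("dataset '", basename(path), "': ", length(problems),
                  " problem row(s):\n  ", paste(problems, collapse = "\n  "))
    if (on_error == "stop") stop(msg, call. = FALSE)
    warning(msg, call. = FALSE)
  }
  out <- tibble::tibble(
    id = raw$id[keep],
    smiles = raw$smiles[keep],
    value = value[keep],
    mol = unname(mols[raw$id[keep]])
  )
  as_property_dataset(out, endpoint_name = endpoint_name)
}

#' Construct a property dataset from parsed parts
#'
#' @param data A data frame with columns `id`, `smiles`, `value`, `mol`.
#' @param endpoint_name Endpoint label stored as attribute.
#' @return The input as a `property_dataset` tibble.
#' @export
as_property_dataset <- function(data, endpoint_name = "value") {
  stopifnot(all(c("id", "smiles", "value", "mol") %in% names(data)))
  if (anyDuplicated(data$id)) stop("ids must be unique", call. = FALSE)
  if (!all(is.finite(data$value))) stop("all values must be finite", call. = FALSE)
  out <- tibble::as_tibble(data)
  class(out) <- c("property_dataset", class(out))
  attr(out, "endpoint_name") <- endpoint_name
  out
}
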