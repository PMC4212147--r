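# Fingerprint engine: simple linear-path enumeration over the heavy-atom
# graph, a fixed 32-bit FNV-1a hash for the hashed families, and a provider
# registry so fingerprint backends can be swapped or extended.
#
# The four hashed families follow the classic Daylight-style contract:
# enumerate all simple linear paths of 0..7 bonds, build a canonical path
# string from element and bond-order symbols, and hash each path into the
# bit vector. The five structural-key families evaluate an ordered pattern
# catalog (see catalogs.R); they are synthetic, openly redistributable
# stand-ins for the proprietary or oversized published key sets, at the
# published lengths. Bit-exact reproduction of the CDK implementations is
# deliberately not attempted: the contract is family semantics.

#' Enumerate simple linear paths of a molecule
#'
#' Enumerates all simple (non-repeating) linear atom paths of 0 to
#' `max_bonds` bonds in the heavy-atom graph and returns their canonical
#' path strings. Atom symbols are element symbols, lower-cased for aromatic
#' atoms when `use_aromaticity`; bond symbols are `-`, `=`, `#`, `:` when
#' `use_bond_orders`. A path reads the same from either end: the canonical
#' string is the lexicographic minimum of the two directions.
#'
#' @param mol A `molecule`.
#' @param max_bonds Maximum number of bonds per path (default 7).
#' @param use_bond_orders Include bond symbols (FALSE for the graph-only
#'   family).
#' @param use_aromaticity Use perceived aromaticity (lowercase atoms, `:`
#'   bonds); FALSE gives Kekule orders and uppercase symbols (the
#'   hybridization family).
#' @return Character vector of unique canonical path strings.
#' @export
enumerate_paths <- function(mol, max_bonds = 7L, use_bond_orders = TRUE,
                            use_aromaticity = TRUE) {
  stopifnot(inherits(mol, "molecule"))
  n <- nrow(mol$atoms)
  asym <- mol$atoms$element
  if (use_aromaticity) {
    asym <- ifelse(mol$atoms$aromatic, tolower(asym), asym)
  }
  if (use_bond_orders) {
    bsym <- c("-", "=", "#")[mol$bonds$order]
    if (use_aromaticity) bsym[mol$bonds$aromatic] <- ":"
  } else {
    bsym <- rep("", nrow(mol$bonds))
  }
  # adjacency: list of (neighbour, bond symbol)
  adj <- vector("list", n)
  for (r in seq_len(nrow(mol$bonds))) {
    i <- mol$bonds$i[r]; j <- mol$bonds$j[r]
    adj[[i]] <- rbind(adj[[i]], c(j, r))
    adj[[j]] <- rbind(adj[[j]], c(i, r))
  }
  out <- new.env(parent = emptyenv())
  out$paths <- character(0)
  emit <- function(atom_seq, bond_seq) {
    fwd <- paste0(asym[atom_seq], c(if (length(bond_seq)) bsym[bond_seq], ""),
                  collapse = "")
    rev_ <- paste0(asym[rev(atom_seq)],
                   c(if (length(bond_seq)) bsym[rev(bond_seq)], ""),
                   collapse = "")
    out$paths <- c(out$paths, if (fwd <= rev_) fwd else rev_)
  }
  walk <- function(atom_seq, bond_seq, visited) {
    last <- atom_seq[length(atom_seq)]
    if (length(bond_seq) >= max_bonds) return()
    nb <- adj[[last]]
    if (is.null(nb)) return()
    for (r in seq_len(nrow(nb))) {
      nxt <- nb[r, 1L]
      if (visited[nxt]) next
      a2 <- c(atom_seq, nxt); b2 <- c(bond_seq, nb[r, 2L])
      # each multi-atom path is enumerated from both of its ends; keep one
      if (nxt > atom_seq[1L]) emit(a2, b2)
      visited[nxt] <- TRUE
      walk(a2, b2, visited)
      visited[nxt] <- FALSE
    }
  }
  for (s in seq_len(n)) {
    emit(s, integer(0))
    v <- logical(n); v[s] <- TRUE
    walk(s, integer(0), v)
  }
  unique(out$paths)
}

# 32-bit FNV-1a over the UTF-8 bytes of each string; returned as doubles in
# [0, 2^32). Fixed, platform-independent: arithmetic is done on 16-bit
# halves so every intermediate stays exactly representable in a double.
fnv1a32 <- function(strings) {
  prime <- 16777619
  vapply(strings, function(s) {
    bytes <- utf8ToInt(s)
    hi <- 33165; lo <- 9381 # 2166136261 = 33165*65536 + 9381
    for (b in bytes) {
      lo <- bitwXor(lo, b)
      ph <- (hi * prime) %% 65536
      pl <- lo * prime
      h <- (ph * 65536 + pl) %% 4294967296
      hi <- h %/% 65536
      lo <- h %% 65536
    }
    hi * 65536 + lo
  }, numeric(1), USE.NAMES = FALSE)
}

# --- provider registry ----------------------------------------------------

.fp_registry <- new.env(parent = emptyenv())

#' Register a fingerprint provider
#'
#' Adds a fingerprint family to the registry. The provider function receives
#' `(mol, length, trace)` and must return a sorted integer vector of set bit
#' positions in `[0, length)`; with `trace = TRUE` it may attach a `trace`
#' attribute mapping bits to the features that set them.
#'
#' @param name Family name (string).
#' @param length Default bit length.
#' @param fn Provider function.
#' @param fixed_length If TRUE the length cannot be overridden per call
#'   (structural-key families); hashed families accept a custom length.
#' @param overwrite Replace an existing provider of the same name.
#' @return `name`, invisibly.
#' @export
register_fingerprint <- function(name, length, fn, fixed_length = TRUE,
                                 overwrite = FALSE) {
  stopifnot(is.character(name), length(name) == 1L, is.function(fn),
            is.numeric(length), length >= 1)
  ensure_fp_registry()
  if (!overwrite && !is.null(.fp_registry[[name]])) {
    stop("fingerprint type '", name, "' is already registered", call. = FALSE)
  }
  .fp_registry[[name]] <- list(name = name, length = as.integer(length),
                               fn = fn, fixed_length = fixed_length)
  invisible(name)
}

#' List registered fingerprint types
#'
#' @return A tibble with columns `name` and `length` (default bit length),
#'   one row per registered provider. The default build registers the nine
#'   shipped families.
#' @export
list_fingerprint_types <- function() {
  ensure_fp_registry()
  nm <- sort(ls(.fp_registry))
  tibble::tibble(
    name = nm,
    length = vapply(nm, function(x) .fp_registry[[x]]$length, integer(1),
                    USE.NAMES = FALSE)
  )
}

#' @keywords internal
reset_fingerprint_registry <- function() {
  rm(list = ls(.fp_registry), envir = .fp_registry)
  ensure_fp_registry()
  invisible(NULL)
}

#' Compute a fingerprint
#'
#' @param mol A `molecule`.
#' @param type Registered fingerprint family name (see
#'   [list_fingerprint_types()]).
#' @param length Optional bit length override (hashed families only).
#' @param trace If TRUE, attach a `trace` attribute mapping each set bit to
#'   the enumerated features that produced it (hashed families).
#' @return A `bit_fingerprint`: list with `type`, `length`, `set_bits`
#'   (sorted 0-based positions).
#' @export
compute_fingerprint <- function(mol, type = "extended", length = NULL,
                                trace = FALSE) {
  stopifnot(inherits(mol, "molecule"))
  ensure_fp_registry()
  prov <- .fp_registry[[type]]
  if (is.null(prov)) {
    stop("unknown fingerprint type '", type, "'; registered types: ",
         paste(list_fingerprint_types()$name, collapse = ", "), call. = FALSE)
  }
  len <- prov$length
  if (!is.null(length)) {
    if (prov$fixed_length) {
      stop("fingerprint type '", type, "' has a fixed length of ", prov$length,
           call. = FALSE)
    }
    len <- as.integer(length)
  }
  bits <- prov$fn(mol, len, trace)
  tr <- attr(bits, "trace")
  bits <- sort(unique(as.integer(bits)))
  if (any(bits < 0L | bits >= fp_total_length(type, len))) {
    stop("provider '", type, "' produced out-of-range bits", call. = FALSE)
  }
  structure(list(type = type, length = fp_total_length(type, len),
                 set_bits = bits),
            class = "bit_fingerprint", trace = tr)
}

# extended appends a fixed 16-bit ring-feature block after the hashed segment
fp_total_length <- function(type, hashed_len) {
  if (type == "extended") hashed_len + 16L else hashed_len
}

#' Dump fingerprints to CSV
#'
#' Writes one row per (molecule, type): `id`, `type`, `length`,
#' `set_bits` (semicolon-joined 0-based positions).
#'
#' @param mols A `molecule`, list of molecules, or dataset with a `mol`
#'   column.
#' @param path Output CSV path.
#' @param types Fingerprint families to compute (default: the configured
#'   default family).
#' @return The written tibble, invisibly.
#' @export
write_fingerprints <- function(mols, path, types = "extended") {
  mols <- as_molecule_list(mols)
  rows <- list()
  for (ty in types) {
    for (m in mols) {
      fp <- compute_fingerprint(m, ty)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        id = m$id, type = ty, length = fp$length,
        set_bits = paste(fp$set_bits, collapse = ";")
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  readr::write_csv(out, path)
  invisible(out)
}

#' @export
print.bit_fingerprint <- function(x, ...) {
  cat("<bit_fingerprint> ", x$type, ": ", length(x$set_bits), "/", x$length,
      " bits set\n", sep = "")
  invisible(x)
}

hashed_bits <- function(paths, len, trace = FALSE) {
  if (!length(paths)) return(integer(0))
  bits <- as.integer(fnv1a32(paths) %% len)
  if (trace) {
    tr <- split(paths, bits)
    bits <- structure(bits, trace = tr)
  }
  bits
}

fp_default <- function(mol, len, trace = FALSE) {
  hashed_bits(enumerate_paths(mol, 7L, TRUE, TRUE), len, trace)
}

fp_graph_only <- function(mol, len, trace = FALSE) {
  # neither bond orders nor aromaticity: pure element skeleton paths
  hashed_bits(enumerate_paths(mol, 7L, FALSE, FALSE), len, trace)
}

fp_hybridization <- function(mol, len, trace = FALSE) {
  hashed_bits(enumerate_paths(mol, 7L, TRUE, FALSE), len, trace)
}

# ring features: any ring of size 3..8 (6 bits), cyclomatic ring count
# thermometer >=1..>=8 (8 bits), any aromatic ring, any ring (2 bits)
fp_extended <- function(mol, len, trace = FALSE) {
  base <- fp_default(mol, len, trace)
  sizes <- mol$ring_sizes
  n_rings <- nrow(mol$bonds) - nrow(mol$atoms) + count_components(mol)
  ring_bits <- integer(0)
  for (s in 3:8) if (any(sizes == s)) ring_bits <- c(ring_bits, len + (s - 3L))
  if (n_rings > 0L) {
    ring_bits <- c(ring_bits, len + 6L + seq_len(min(n_rings, 8L)) - 1L)
  }
  if (any(mol$atoms$aromatic)) ring_bits <- c(ring_bits, len + 14L)
  if (n_rings > 0L) ring_bits <- c(ring_bits, len + 15L)
  out <- c(as.integer(base), ring_bits)
  attr(out, "trace") <- attr(base, "trace")
  out
}

count_components <- function(mol) {
  n <- nrow(mol$atoms)
  if (n == 0L) return(0L)
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  for (r in seq_len(nrow(mol$bonds))) {
    ri <- find(mol$bonds$i[r]); rj <- find(mol$bonds$j[r])
    if (ri != rj) parent[ri] <- rj
  }
  length(unique(vapply(seq_len(n), find, integer(1))))
}

# structural-key family provider built from a pattern catalog (catalogs.R)
fp_key_family <- function(catalog_fn) {
  force(catalog_fn)
  function(mol, len, trace = FALSE) {
    cat_tb <- catalog_fn()
    bits <- key_catalog_bits(mol, cat_tb)
    if (trace) {
      attr(bits, "trace") <- split(cat_tb$smarts[bits + 1L], bits)
    }
    bits
  }
}

ensure_fp_registry <- function() {
  if (!is.null(.fp_registry[["default"]])) return(invisible(NULL))
  reg <- function(name, length, fn, fixed = TRUE) {
    .fp_registry[[name]] <- list(name = name, length = as.integer(length),
                                 fn = fn, fixed_length = fixed)
  }
  reg("default", 1024L, fp_default, fixed = FALSE)
  reg("extended", 1024L, fp_extended, fixed = FALSE) # +16 ring-feature bits
  reg("graph_only", 1024L, fp_graph_only, fixed = FALSE)
  reg("hybridization", 1024L, fp_hybridization, fixed = FALSE)
  reg("estate", 79L, fp_key_family(catalog_estate))
  reg("maccs", 166L, fp_key_family(catalog_maccs))
  reg("substructure", 307L, fp_key_family(catalog_substructure))
  reg("pubchem", 881L, fp_key_family(catalog_pubchem))
  reg("klekota_roth", 4860L, fp_key_family(catalog_klekota_roth))
  invisible(NULL)
}
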