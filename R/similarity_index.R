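# The combined similarity index: one binary fingerprint similarity and
# three non-binary key similarities (CD, HD, FG) blended under weights
# summing to one. The default combination is a weighted geometric mean
# (exponents = weights), with an arithmetic mode available for sensitivity
# analysis.

#' Similarity index configuration
#'
#' Bundles the four choices that define a similarity index: the fingerprint
#' family, the binary coefficient applied to it, the non-binary coefficient
#' applied to the three descriptor keys, and the weights of the four
#' contributions (fingerprint, constitutional, hetero-atom, functional
#' group), which must sum to 1. The shipped default is the best-performing
#' configuration of the index's original calibration: Extended fingerprint,
#' Maxwell-Pilliner binary coefficient (id 37), Bray/Curtis non-binary
#' coefficient (id 3), weights (0.4, 0.35, 0.1, 0.15).
#'
#' @param fingerprint Registered fingerprint family name.
#' @param binary_id Binary coefficient id (1-44).
#' @param nonbinary_id Non-binary coefficient id (1-6).
#' @param weights Numeric length-4 vector of weights for (fp, cd, hd, fg);
#'   names optional but checked when present. Must sum to 1 (tolerance
#'   1e-9), each in \[0,1\].
#' @param mode `"geometric"` (default; weighted geometric mean with the
#'   convention that a zero-weight factor contributes 1) or
#'   `"arithmetic"`.
#' @return An object of class `similarity_config`.
#' @export
similarity_config <- function(fingerprint = "extended", binary_id = 37L,
                              nonbinary_id = 3L,
                              weights = c(fp = 0.4, cd = 0.35, hd = 0.1, fg = 0.15),
                              mode = c("geometric", "arithmetic")) {
  mode <- match.arg(mode)
  if (!fingerprint %in% list_fingerprint_types()$name) {
    stop("unknown fingerprint type '", fingerprint, "'", call. = FALSE)
  }
  if (!binary_id %in% binary_coefficients()$id) {
    stop("unknown binary coefficient id: ", binary_id, call. = FALSE)
  }
  if (!nonbinary_id %in% nonbinary_coefficients()$id) {
    stop("unknown non-binary coefficient id: ", nonbinary_id, call. = FALSE)
  }
  w <- validate_weights(weights)
  structure(
    list(fingerprint = fingerprint, binary_id = as.integer(binary_id),
         nonbinary_id = as.integer(nonbinary_id), weights = w, mode = mode),
    class = "similarity_config"
  )
}

validate_weights <- function(weights) {
  if (length(weights) != 4L || !is.numeric(weights)) {
    stop("weights must be a numeric vector of length 4 (fp, cd, hd, fg)",
         call. = FALSE)
  }
  nm <- c("fp", "cd", "hd", "fg")
  if (!is.null(names(weights)) && any(nzchar(names(weights)))) {
    if (!setequal(names(weights), nm)) {
      stop("weight names must be fp, cd, hd, fg", call. = FALSE)
    }
    weights <- weights[nm]
  } else {
    names(weights) <- nm
  }
  if (any(weights < 0 | weights > 1)) {
    stop("weights must lie in [0, 1]", call. = FALSE)
  }
  if (abs(sum(weights) - 1) > 1e-9) {
    stop("weights must sum to 1 (got ", format(sum(weights), digits = 12), ")",
         call. = FALSE)
  }
  weights
}

#' @export
print.similarity_config <- function(x, ...) {
  bc <- binary_coefficients()
  nb <- nonbinary_coefficients()
  cat("<similarity_config>\n",
      "  fingerprint:  ", x$fingerprint, "\n",
      "  binary:       ", x$binary_id, " (",
      bc$name[match(x$binary_id, bc$id)], ")\n",
      "  non-binary:   ", x$nonbinary_id, " (",
      nb$code[match(x$nonbinary_id, nb$id)], ")\n",
      "  weights:      fp=", x$weights[["fp"]], " cd=", x$weights[["cd"]],
      " hd=", x$weights[["hd"]], " fg=", x$weights[["fg"]], "\n",
      "  mode:         ", x$mode, "\n", sep = "")
  invisible(x)
}

#' Read a similarity configuration from a YAML file
#'
#' Expected keys: `fingerprint`, `binary_coefficient`,
#' `nonbinary_coefficient`, `weights` (mapping with `fp`, `cd`, `hd`,
#' `fg`), and optional `mode`. Missing keys fall back to the shipped
#' default configuration.
#'
#' @param path YAML file path.
#' @return A [similarity_config()].
#' @export
read_similarity_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  y <- yaml::read_yaml(path)
  default <- similarity_config()
  w <- default$weights
  if (!is.null(y$weights)) w <- unlist(y$weights)[c("fp", "cd", "hd", "fg")]
  similarity_config(
    fingerprint = y$fingerprint %||% default$fingerprint,
    binary_id = y$binary_coefficient %||% default$binary_id,
    nonbinary_id = y$nonbinary_coefficient %||% default$nonbinary_id,
    weights = w,
    mode = y$mode %||% default$mode
  )
}

# combine the four component similarities under a config
combine_components <- function(s_fp, s_cd, s_hd, s_fg, config) {
  w <- config$weights
  if (config$mode == "geometric") {
    # 0^0 = 1 in R, which is exactly the required zero-weight convention
    s_fp^w[["fp"]] * s_cd^w[["cd"]] * s_hd^w[["hd"]] * s_fg^w[["fg"]]
  } else {
    w[["fp"]] * s_fp + w[["cd"]] * s_cd + w[["hd"]] * s_hd + w[["fg"]] * s_fg
  }
}

#' Combined similarity index of two molecules
#'
#' Computes the four component similarities (binary coefficient on the
#' fingerprints; non-binary coefficient on the CD, HD and FG keys) and
#' blends them under the configuration's weights. In geometric mode the
#' index is the product of component similarities raised to their weights
#' (a factor with weight 0 contributes 1); in arithmetic mode it is the
#' weighted sum. Both are symmetric and lie in \[0,1\].
#'
#' @param keys_a,keys_b Per-molecule key sets: lists with elements `fp`
#'   (a `bit_fingerprint`), `cd`, `hd`, `fg` (numeric vectors), e.g. one
#'   molecule's slice of [molecule_keys()].
#' @param config A [similarity_config()].
#' @return The similarity index, a number in \[0,1\], with the four
#'   component similarities attached as attribute `components`.
#' @export
combined_similarity <- function(keys_a, keys_b, config = similarity_config()) {
  stopifnot(inherits(config, "similarity_config"))
  s_fp <- binary_similarity(config$binary_id,
                            confusion_counts(keys_a$fp, keys_b$fp))
  s_cd <- nonbinary_similarity(config$nonbinary_id, keys_a$cd, keys_b$cd)
  s_hd <- nonbinary_similarity(config$nonbinary_id, keys_a$hd, keys_b$hd)
  s_fg <- nonbinary_similarity(config$nonbinary_id, keys_a$fg, keys_b$fg)
  si <- combine_components(s_fp, s_cd, s_hd, s_fg, config)
  structure(si, components = c(fp = s_fp, cd = s_cd, hd = s_hd, fg = s_fg))
}

# slice one molecule out of a molecule_keys() list
keys_slice <- function(keys, i) {
  list(fp = keys$fp[[i]], cd = keys$cd[i, ], hd = keys$hd[i, ],
       fg = keys$fg[i, ])
}

# pairwise binary-coefficient similarity matrix from a list of fingerprints
binary_sim_matrix <- function(id, fps) {
  n <- length(fps)
  len <- fps[[1L]]$length
  M <- matrix(0, n, len)
  for (i in seq_len(n)) M[i, fps[[i]]$set_bits + 1L] <- 1
  A <- tcrossprod(M)              # common set bits
  r <- rowSums(M)
  B <- outer(r, rep(1, n)) - A    # set in row molecule only
  C <- outer(rep(1, n), r) - A    # set in column molecule only
  D <- len - A - B - C
  S <- matrix(binary_sim_vec(id, as.vector(A), as.vector(B), as.vector(C),
                             as.vector(D)), n, n)
  S
}

# full pairwise SI matrix for a key set under a config; component matrices
# can be precomputed and passed to avoid repeated work in grid sweeps
si_matrix <- function(keys, config, components = NULL) {
  comp <- components %||% si_components(keys, config)
  combine_components(comp$fp, comp$cd, comp$hd, comp$fg, config)
}

si_components <- function(keys, config) {
  list(
    fp = binary_sim_matrix(config$binary_id, keys$fp),
    cd = nonbinary_sim_matrix(config$nonbinary_id, keys$cd),
    hd = nonbinary_sim_matrix(config$nonbinary_id, keys$hd),
    fg = nonbinary_sim_matrix(config$nonbinary_id, keys$fg)
  )
}

#' Pairwise similarity table of a dataset
#'
#' Computes the similarity index and its four components for every
#' unordered pair of molecules in a dataset.
#'
#' @param data A dataset with a `mol` list-column (see [read_dataset()]),
#'   or a list of `molecule` objects.
#' @param config A [similarity_config()].
#' @param keys Optional precomputed [molecule_keys()] for `data`.
#' @return A tibble with columns `id_a`, `id_b`, `s_fp`, `s_cd`, `s_hd`,
#'   `s_fg`, `si`.
#' @export
pairwise_similarity <- function(data, config = similarity_config(), keys = NULL) {
  keys <- keys %||% molecule_keys(data, config)
  comp <- si_components(keys, config)
  S <- combine_components(comp$fp, comp$cd, comp$hd, comp$fg, config)
  n <- length(keys$ids)
  pr <- which(upper.tri(S), arr.ind = TRUE)
  tibble::tibble(
    id_a = keys$ids[pr[, 1L]],
    id_b = keys$ids[pr[, 2L]],
    s_fp = comp$fp[pr], s_cd = comp$cd[pr], s_hd = comp$hd[pr],
    s_fg = comp$fg[pr], si = S[pr]
  )
}
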