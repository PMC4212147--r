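# Similarity coefficient registries: 44 binary coefficients over confusion
# counts (a, b, c, d) and 6 non-binary coefficients over nonnegative
# descriptor vectors.
#
# Binary formulas follow the standard literature forms of the coefficients
# in the Todeschini et al. (2012, J Chem Inf Model 52:2884) roster, under
# that paper's numbering; the CT1-CT5 and Austin-Colwell entries are the
# Consonni-Todeschini log-forms. Non-binary forms follow Holliday, Hu &
# Willett (2002, Comb Chem HTS 5:155). Every coefficient is mapped into
# [0,1]: identity for naturally unit-range forms, (s+1)/2 for
# correlation-type [-1,1] forms, and documented fixed transforms for the
# few forms with count-dependent ranges (`rescale` column). Degenerate
# denominators follow a tabulated policy: identical fingerprints score 1
# for reflexive coefficients, undefined correlation forms fall back to the
# rescaled raw 0 (0.5), and other undefined forms score 0.

div0 <- function(num, den, default) {
  out <- num / den
  out[den == 0] <- default
  out
}

# raw formula, rescale rule, reflexivity (s(x,x)=1 for non-degenerate x)
binary_coeff_defs <- function() {
  L <- list(
    list(1L, "Simple matching", "sm", "unit", TRUE,
         function(a, b, c, d, n) (a + d) / n),
    list(2L, "Rogers/Tanimoto", "rt", "unit", TRUE,
         function(a, b, c, d, n) (a + d) / (n + b + c)),
    list(3L, "Jaccard/Tanimoto", "jt", "unit", TRUE,
         function(a, b, c, d, n) a / (a + b + c)),
    list(4L, "Gleason/Dice/Sorensen/Nei-Li", "gle", "unit", TRUE,
         function(a, b, c, d, n) 2 * a / (2 * a + b + c)),
    list(5L, "Russel-Rao", "rr", "unit", FALSE,
         function(a, b, c, d, n) a / n),
    list(6L, "Forbes", "for", "over1", FALSE,
         function(a, b, c, d, n) n * a / ((a + b) * (a + c))),
    list(7L, "Simpson", "sim", "unit", TRUE,
         function(a, b, c, d, n) a / pmin(a + b, a + c)),
    list(8L, "Braun-Blanquet", "bb", "unit", TRUE,
         function(a, b, c, d, n) a / pmax(a + b, a + c)),
    list(9L, "Driver-Kroeber/Ochiai", "dk", "unit", TRUE,
         function(a, b, c, d, n) a / sqrt((a + b) * (a + c))),
    list(10L, "Baroni-Urbani 1", "bub", "unit", TRUE,
         function(a, b, c, d, n) (sqrt(a * d) + a) / (sqrt(a * d) + a + b + c)),
    list(11L, "Kulczynski 1", "kul", "unit", TRUE,
         function(a, b, c, d, n) 0.5 * (div0(a, a + b, 0) + div0(a, a + c, 0))),
    list(12L, "Sokal-Sneath 1", "ss1", "unit", TRUE,
         function(a, b, c, d, n) a / (a + 2 * (b + c))),
    list(13L, "Sokal-Sneath 2", "ss2", "unit", TRUE,
         function(a, b, c, d, n) 2 * (a + d) / (n + a + d)),
    list(14L, "Jaccard 2", "ja2", "unit", TRUE,
         function(a, b, c, d, n) 3 * a / (3 * a + b + c)),
    list(15L, "Faith", "fai", "unit", FALSE,
         function(a, b, c, d, n) (a + 0.5 * d) / n),
    list(16L, "Mountford", "mou", "over1", TRUE,
         function(a, b, c, d, n) 2 * a / (a * b + a * c + 2 * b * c)),
    list(17L, "Michael", "mic", "pm1", FALSE,
         function(a, b, c, d, n) 4 * (a * d - b * c) / ((a + d)^2 + (b + c)^2)),
    list(18L, "Rogot-Goldberg", "rg", "unit", TRUE,
         function(a, b, c, d, n) div0(a, 2 * a + b + c, 0.5) + div0(d, 2 * d + b + c, 0.5)),
    list(19L, "Hawkins-Dotson", "hd", "unit", TRUE,
         function(a, b, c, d, n) 0.5 * (div0(a, a + b + c, 1) + div0(d, d + b + c, 1))),
    list(20L, "Yule 1", "yu1", "pm1", TRUE,
         function(a, b, c, d, n) (a * d - b * c) / (a * d + b * c)),
    list(21L, "Yule 2", "yu2", "pm1", TRUE,
         function(a, b, c, d, n) (sqrt(a * d) - sqrt(b * c)) / (sqrt(a * d) + sqrt(b * c))),
    list(22L, "Fossum", "fos", "div_n", FALSE,
         function(a, b, c, d, n) n * (a - 0.5)^2 / ((a + b) * (a + c))),
    list(23L, "Dennis", "den", "dennis", FALSE,
         function(a, b, c, d, n) (a * d - b * c) / sqrt(n * (a + b) * (a + c))),
    list(24L, "Cole 1", "co1", "pm1", TRUE,
         function(a, b, c, d, n) (a * d - b * c) / ((a + b) * (b + d))),
    list(25L, "Cole 2", "co2", "pm1", TRUE,
         function(a, b, c, d, n) (a * d - b * c) / ((a + c) * (c + d))),
    list(26L, "Dispersion", "dis", "disp", FALSE,
         function(a, b, c, d, n) (a * d - b * c) / n^2),
    list(27L, "Goodman-Kruskal", "gk", "unit", TRUE,
         function(a, b, c, d, n) {
           sig <- pmax(a, b) + pmax(c, d) + pmax(a, c) + pmax(b, d)
           sig2 <- pmax(a + c, b + d) + pmax(a + b, c + d)
           (sig - sig2) / (2 * n - sig2)
         }),
    list(28L, "Sokal-Sneath 3", "ss3", "over1", TRUE,
         function(a, b, c, d, n) (a + d) / (b + c)),
    list(29L, "Sokal-Sneath 4", "ss4", "unit", TRUE,
         function(a, b, c, d, n) {
           0.25 * (div0(a, a + b, 1) + div0(a, a + c, 1) +
                   div0(d, b + d, 1) + div0(d, c + d, 1))
         }),
    list(30L, "Phi", "phi", "pm1", TRUE,
         function(a, b, c, d, n) {
           (a * d - b * c) / sqrt((a + b) * (a + c) * (b + d) * (c + d))
         }),
    list(31L, "Dice 1", "di1", "unit", TRUE,
         function(a, b, c, d, n) a / (a + b)),
    list(32L, "Dice 2", "di2", "unit", TRUE,
         function(a, b, c, d, n) a / (a + c)),
    list(33L, "Sorgenfrei", "sor", "unit", TRUE,
         function(a, b, c, d, n) a^2 / ((a + b) * (a + c))),
    list(34L, "Cohen", "coh", "pm1", TRUE,
         function(a, b, c, d, n) {
           2 * (a * d - b * c) / ((a + b) * (b + d) + (a + c) * (c + d))
         }),
    list(35L, "Peirce 1", "pe1", "pm1", TRUE,
         function(a, b, c, d, n) (a * d - b * c) / ((a + b) * (c + d))),
    list(36L, "Peirce 2", "pe2", "pm1", TRUE,
         function(a, b, c, d, n) (a * d - b * c) / ((a + c) * (b + d))),
    list(37L, "Maxwell-Pilliner", "mp", "pm1", TRUE,
         function(a, b, c, d, n) {
           2 * (a * d - b * c) / ((a + b) * (c + d) + (a + c) * (b + d))
         }),
    list(38L, "Harris-Lahey", "hl", "div_n", TRUE,
         function(a, b, c, d, n) {
           div0(a * (2 * d + b + c), 2 * (a + b + c), 0) +
             div0(d * (2 * a + b + c), 2 * (b + c + d), 0)
         }),
    list(39L, "CT1", "ct1", "unit", TRUE,
         function(a, b, c, d, n) log1p(a + d) / log1p(n)),
    list(40L, "CT2", "ct2", "unit", TRUE,
         function(a, b, c, d, n) (log1p(n) - log1p(b + c)) / log1p(n)),
    list(41L, "CT3", "ct3", "unit", FALSE,
         function(a, b, c, d, n) log1p(a) / log1p(n)),
    list(42L, "CT4", "ct4", "unit", TRUE,
         function(a, b, c, d, n) log1p(a) / log1p(a + b + c)),
    list(43L, "CT5", "ct5", "pm1", FALSE,
         function(a, b, c, d, n) (log1p(a * d) - log1p(b * c)) / log1p(n^2 / 4)),
    list(44L, "Austin-Colwell angular coeff.", "ac", "unit", TRUE,
         function(a, b, c, d, n) (2 / pi) * asin(sqrt((a + d) / n)))
  )
  L
}

.similarity_registry <- new.env(parent = emptyenv())

binary_registry <- function() {
  if (is.null(.similarity_registry$binary)) {
    .similarity_registry$binary <- binary_coeff_defs()
  }
  .similarity_registry$binary
}

#' Binary similarity coefficient roster
#'
#' The 44 binary similarity coefficients over fingerprint confusion counts,
#' with their registry metadata: id, name, short code, the [0,1] rescaling
#' rule applied to the raw form (`unit` = already in \[0,1\], `pm1` =
#' correlation-type rescaled by (s+1)/2, `over1` = unbounded ratio mapped by
#' s/(1+s), `div_n`, `dennis`, `disp` = fixed linear maps of count-dependent
#' ranges), and whether the coefficient is reflexive (self-similarity of a
#' non-degenerate fingerprint equals 1; e.g. Russel-Rao a/n is not).
#'
#' @details Six coefficients of the roster are directionally asymmetric and
#' come in transpose pairs (Cole 1/2, Dice 1/2, Peirce 1/2): exchanging the
#' two fingerprints maps each onto its partner. The `symmetric` column
#' records this; the combined index is symmetric whenever a symmetric
#' binary coefficient is configured.
#'
#' @return A tibble with columns `id`, `name`, `code`, `rescale`,
#'   `reflexive`, `symmetric`.
#' @export
binary_coefficients <- function() {
  defs <- binary_registry()
  ids <- vapply(defs, `[[`, integer(1), 1L)
  tibble::tibble(
    id = ids,
    name = vapply(defs, `[[`, character(1), 2L),
    code = vapply(defs, `[[`, character(1), 3L),
    rescale = vapply(defs, `[[`, character(1), 4L),
    reflexive = vapply(defs, `[[`, logical(1), 5L),
    symmetric = !ids %in% c(24L, 25L, 31L, 32L, 35L, 36L)
  )
}

rescale_binary <- function(raw, rule, n) {
  switch(rule,
    unit = raw,
    pm1 = (pmin(pmax(raw, -1), 1) + 1) / 2,
    over1 = raw / (1 + raw),
    div_n = raw / n,
    dennis = (raw / sqrt(n) + 0.5) / 1.5,
    disp = 2 * raw + 0.5,
    stop("unknown rescale rule: ", rule, call. = FALSE)
  )
}

# vectorised evaluation of one binary coefficient over count vectors
binary_sim_vec <- function(id, a, b, c, d) {
  defs <- binary_registry()
  if (!is.numeric(id) || length(id) != 1L || is.na(id) || id < 1L ||
      id > length(defs)) {
    stop("unknown binary coefficient id: ", id, call. = FALSE)
  }
  ent <- defs[[as.integer(id)]]
  n <- a + b + c + d
  raw <- ent[[6L]](a, b, c, d, n)
  s <- rescale_binary(raw, ent[[4L]], n)
  identical_in <- (b == 0 & c == 0)
  bad <- !is.finite(s)
  s[bad & identical_in] <- 1
  s[bad & !identical_in] <- if (ent[[4L]] == "pm1") 0.5 else 0
  if (ent[[5L]]) s[identical_in] <- 1 # reflexive: exact identity scores 1
  pmin(pmax(s, 0), 1)
}

#' Confusion counts of two fingerprints
#'
#' For two bit fingerprints of the same type, counts positions set in both
#' (`a`), in the first only (`b`), in the second only (`c`) and in neither
#' (`d`); the arguments of every binary similarity coefficient.
#'
#' @param x,y `bit_fingerprint` objects of identical type and length.
#' @return A tibble with columns `a`, `b`, `c`, `d`, `n`.
#' @export
confusion_counts <- function(x, y) {
  stopifnot(inherits(x, "bit_fingerprint"), inherits(y, "bit_fingerprint"))
  if (x$type != y$type || x$length != y$length) {
    stop("fingerprints must have the same type and length", call. = FALSE)
  }
  a <- length(intersect(x$set_bits, y$set_bits))
  b <- length(x$set_bits) - a
  c_ <- length(y$set_bits) - a
  tibble::tibble(a = a, b = b, c = c_, d = x$length - a - b - c_,
                 n = x$length)
}

#' Evaluate a binary similarity coefficient
#'
#' @param id Coefficient id (1-44, see [binary_coefficients()]).
#' @param counts Confusion counts: a data frame with columns `a`, `b`, `c`,
#'   `d` (one row per pair, e.g. from [confusion_counts()]), or a numeric
#'   vector `c(a, b, c, d)`.
#' @return Numeric vector of similarities in \[0,1\], one per row of
#'   `counts`.
#' @export
binary_similarity <- function(id, counts) {
  if (is.numeric(counts) && length(counts) == 4L) {
    counts <- tibble::tibble(a = counts[1L], b = counts[2L], c = counts[3L],
                             d = counts[4L])
  }
  stopifnot(all(c("a", "b", "c", "d") %in% names(counts)))
  if (any(counts$a < 0 | counts$b < 0 | counts$c < 0 | counts$d < 0)) {
    stop("confusion counts must be nonnegative", call. = FALSE)
  }
  binary_sim_vec(id, counts$a, counts$b, counts$c, counts$d)
}

# --- non-binary coefficients ---------------------------------------------

nonbinary_defs <- function() {
  list(
    list(1L, "Mean Camberra", "MC", function(x, y) {
      1 - mean(div0(abs(x - y), x + y, 0))
    }),
    list(2L, "Divergence", "Div", function(x, y) {
      1 - mean(div0((x - y)^2, (x + y)^2, 0))
    }),
    list(3L, "Bray/Curtis", "BC", function(x, y) {
      1 - div0(sum(abs(x - y)), sum(x + y), 0)
    }),
    list(4L, "Dice", "Dice", function(x, y) {
      den <- sum(x^2) + sum(y^2)
      if (den == 0) 1 else 2 * sum(x * y) / den
    }),
    list(5L, "Sokal/Sneath", "SS1", function(x, y) {
      A <- sum(x^2); B <- sum(y^2); C <- sum(x * y)
      den <- 2 * A + 2 * B - 3 * C
      if (den == 0) 1 else C / den
    }),
    list(6L, "Cosine/Ochiai", "Cos", function(x, y) {
      A <- sum(x^2); B <- sum(y^2)
      if (A == 0 && B == 0) return(1)
      if (A == 0 || B == 0) return(0)
      sum(x * y) / sqrt(A * B)
    })
  )
}

#' Non-binary similarity coefficient roster
#'
#' The six non-binary coefficients applied to the descriptor-based keys,
#' under the Holliday et al. coding: Mean Camberra (MC), Divergence (Div),
#' Bray/Curtis (BC), Dice, Sokal/Sneath (SS1), Cosine/Ochiai (Cos).
#' Distance-type forms (MC, Div, BC) are returned as similarity
#' complements of the normalised distance; all outputs are in \[0,1\] for
#' nonnegative input vectors.
#'
#' @return A tibble with columns `id`, `name`, `code`.
#' @export
nonbinary_coefficients <- function() {
  defs <- nonbinary_defs()
  tibble::tibble(
    id = vapply(defs, `[[`, integer(1), 1L),
    name = vapply(defs, `[[`, character(1), 2L),
    code = vapply(defs, `[[`, character(1), 3L)
  )
}

#' Evaluate a non-binary similarity coefficient
#'
#' @param id Coefficient id (1-6, see [nonbinary_coefficients()]).
#' @param x,y Equal-length nonnegative numeric vectors (descriptor keys).
#' @return Similarity in \[0,1\].
#' @export
nonbinary_similarity <- function(id, x, y) {
  defs <- nonbinary_defs()
  if (!is.numeric(id) || length(id) != 1L || is.na(id) || id < 1L ||
      id > length(defs)) {
    stop("unknown non-binary coefficient id: ", id, call. = FALSE)
  }
  if (length(x) != length(y)) stop("vectors must have equal length", call. = FALSE)
  if (any(x < 0) || any(y < 0)) {
    stop("non-binary coefficients require nonnegative components", call. = FALSE)
  }
  s <- defs[[as.integer(id)]][[4L]](as.numeric(x), as.numeric(y))
  min(max(s, 0), 1)
}

# full pairwise non-binary similarity matrix over the rows of M
nonbinary_sim_matrix <- function(id, M) {
  n <- nrow(M)
  S <- diag(1, n)
  if (n < 2L) return(S)
  for (i in seq_len(n - 1L)) {
    xi <- M[i, ]
    for (j in (i + 1L):n) {
      S[i, j] <- S[j, i] <- nonbinary_similarity(id, xi, M[j, ])
    }
  }
  S
}
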