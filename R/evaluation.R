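# Two-stage combinatorial evaluation of similarity-index settings.
#
# Stage 1 benchmarks every fingerprint family x binary coefficient pair
# with a fingerprint-only index (weights 1,0,0,0). Stage 2 fixes the
# winning pair and sweeps weight schemes x non-binary coefficients. Each
# run is scored by leave-one-out read-across on every supplied dataset;
# batches are ranked by desirability (geometric) and utility (arithmetic)
# functions of the min-max-scaled quality parameters.

#' Enumerate weight schemes on a step lattice
#'
#' Exhaustively enumerates weight tuples (fp, cd, hd, fg) on the given
#' ranges and step lattice, keeping those summing to 1 (tolerance 1e-9).
#' Defaults reproduce the evaluation grid of the index's original
#' calibration: fp in \[0.3, 1\] step 0.1, cd in \[0, 0.4\] step 0.05,
#' hd and fg in \[0, 1\] step 0.05. Enumeration is performed in exact
#' integer arithmetic on a common lattice, in deterministic lexicographic
#' order (fp, then cd, then hd).
#'
#' @param fp_range,cd_range,hd_range,fg_range Length-2 numeric ranges.
#' @param fp_step,cd_step,hd_step,fg_step Step sizes.
#' @return A tibble with columns `w_fp`, `w_cd`, `w_hd`, `w_fg`.
#' @export
enumerate_weights <- function(fp_range = c(0.3, 1), fp_step = 0.1,
                              cd_range = c(0, 0.4), cd_step = 0.05,
                              hd_range = c(0, 1), hd_step = 0.05,
                              fg_range = c(0, 1), fg_step = 0.05) {
  for (rs in list(list(fp_range, fp_step), list(cd_range, cd_step),
                  list(hd_range, hd_step), list(fg_range, fg_step))) {
    k <- (rs[[1]][2L] - rs[[1]][1L]) / rs[[2]]
    if (abs(k - round(k)) > 1e-9) {
      stop("steps must divide ranges exactly", call. = FALSE)
    }
  }
  # common integer lattice: scale so every step and bound is integral
  denom <- 1 / Reduce(gcd_frac, c(fp_step, cd_step, hd_step, fg_step,
                                  fp_range, cd_range, hd_range, fg_range, 1))
  to_int <- function(x) {
    xi <- round(x * denom)
    if (any(abs(xi - x * denom) > 1e-6)) {
      stop("steps must divide ranges exactly", call. = FALSE)
    }
    as.integer(xi)
  }
  seq_int <- function(range, step) seq(to_int(range[1L]), to_int(range[2L]),
                                       by = to_int(step))
  total <- to_int(1)
  fp <- seq_int(fp_range, fp_step)
  cd <- seq_int(cd_range, cd_step)
  hd <- seq_int(hd_range, hd_step)
  fg_min <- to_int(fg_range[1L]); fg_max <- to_int(fg_range[2L])
  fg_step_i <- to_int(fg_step)
  rows <- list()
  for (a in fp) for (b in cd) for (h in hd) {
    g <- total - a - b - h
    if (g < fg_min || g > fg_max || g %% fg_step_i != 0L) next
    rows[[length(rows) + 1L]] <- c(a, b, h, g)
  }
  m <- do.call(rbind, rows) / denom
  tibble::tibble(w_fp = m[, 1L], w_cd = m[, 2L], w_hd = m[, 3L],
                 w_fg = m[, 4L])
}

gcd_frac <- function(x, y) {
  # gcd for small rationals via integer gcd on a 1e4 grid
  xi <- round(x * 1e4); yi <- round(y * 1e4)
  g <- function(p, q) if (q == 0) p else g(q, p %% q)
  g(xi, yi) / 1e4
}

dataset_label <- function(datasets, i) {
  nm <- names(datasets)
  lab <- if (!is.null(nm) && nzchar(nm[i])) {
    nm[i]
  } else {
    attr(datasets[[i]], "endpoint_name") %||% paste0("dataset", i)
  }
  make.names(lab)
}

#' Stage-1 grid: fingerprint families x binary coefficients
#'
#' Runs leave-one-out read-across on every supplied dataset for every
#' (fingerprint type, binary coefficient) combination, using a
#' fingerprint-only similarity index (weights (1, 0, 0, 0)), and ranks the
#' batch with [rank_results()]. Fingerprints and confusion-count matrices
#' are computed once per type and reused across coefficients. Failed runs
#' are excluded from ranking with a warning.
#'
#' @param datasets A property dataset or (optionally named) list of them.
#' @param fp_types Fingerprint family names (default: all registered).
#' @param binary_ids Binary coefficient ids (default 1-44).
#' @param k Neighbours per prediction (default 3).
#' @return A `grid_result` tibble: one row per combination with columns
#'   `fingerprint`, `binary_id`, per-dataset `r2_*` / `rmse_*`, scaled
#'   parameters `p1`..`p4` (or `p1`..`p2m`), `des`, `uti`, `rank_des`,
#'   `rank_uti`.
#' @export
stage1_grid <- function(datasets, fp_types = list_fingerprint_types()$name,
                        binary_ids = binary_coefficients()$id, k = 3L) {
  datasets <- as_dataset_list(datasets)
  stopifnot(length(fp_types) >= 1L, length(binary_ids) >= 1L)
  labels <- vapply(seq_along(datasets), function(i) dataset_label(datasets, i),
                   character(1))
  cfg0 <- function(type, id) {
    similarity_config(fingerprint = type, binary_id = id,
                      weights = c(fp = 1, cd = 0, hd = 0, fg = 0))
  }
  # cache fingerprints per (dataset, type): heavy; coefficients are cheap
  rows <- list()
  for (type in fp_types) {
    fp_mats <- lapply(datasets, function(ds) {
      fps <- lapply(ds$mol, compute_fingerprint, type = type)
      fps
    })
    for (id in binary_ids) {
      run <- tibble::tibble(fingerprint = type, binary_id = as.integer(id))
      ok <- TRUE
      for (di in seq_along(datasets)) {
        ds <- datasets[[di]]
        res <- tryCatch({
          S <- binary_sim_matrix(id, fp_mats[[di]])
          preds <- loo_from_si_matrix(S, ds$value, ds$id, k)
          loo_metrics(preds$observed, preds$predicted)
        }, error = function(e) {
          warning("stage 1 run (", type, ", ", id, ") failed on ",
                  labels[di], ": ", conditionMessage(e), call. = FALSE)
          NULL
        })
        if (is.null(res)) { ok <- FALSE; break }
        run[[paste0("r2_", labels[di])]] <- res$r2
        run[[paste0("rmse_", labels[di])]] <- res$rmse
      }
      if (ok) rows[[length(rows) + 1L]] <- run
    }
  }
  out <- dplyr::bind_rows(rows)
  rank_results(out, metric_labels = labels)
}

#' Stage-2 grid: weight schemes x non-binary coefficients
#'
#' Fixes the fingerprint family and binary coefficient (by default the
#' shipped stage-1 winner: Extended / Maxwell-Pilliner) and evaluates every
#' supplied weight scheme with every non-binary coefficient, ranking the
#' batch with [rank_results()]. The four component similarity matrices are
#' computed once per (dataset, non-binary coefficient) and recombined per
#' weight scheme, so the sweep is dominated by key computation, not by the
#' number of weight tuples.
#'
#' @param datasets A property dataset or (optionally named) list of them.
#' @param fp_type Fingerprint family (default `"extended"`).
#' @param binary_id Binary coefficient id (default 37, Maxwell-Pilliner).
#' @param weights A tibble from [enumerate_weights()] (default: the full
#'   calibration grid).
#' @param nonbinary_ids Non-binary coefficient ids (default 1-6).
#' @param k Neighbours per prediction (default 3).
#' @param mode Combination mode, `"geometric"` or `"arithmetic"`.
#' @return A `grid_result` tibble: one row per (weight scheme, coefficient)
#'   with config columns `w_fp`, `w_cd`, `w_hd`, `w_fg`, `nonbinary_id`,
#'   per-dataset metrics and ranking columns as in [stage1_grid()].
#' @export
stage2_grid <- function(datasets, fp_type = "extended", binary_id = 37L,
                        weights = enumerate_weights(),
                        nonbinary_ids = nonbinary_coefficients()$id,
                        k = 3L, mode = "geometric") {
  datasets <- as_dataset_list(datasets)
  stopifnot(nrow(weights) >= 1L, length(nonbinary_ids) >= 1L)
  labels <- vapply(seq_along(datasets), function(i) dataset_label(datasets, i),
                   character(1))
  base_cfg <- similarity_config(fingerprint = fp_type, binary_id = binary_id,
                                weights = c(fp = 1, cd = 0, hd = 0, fg = 0),
                                mode = mode)
  keys <- lapply(datasets, molecule_keys, config = base_cfg)
  fp_mat <- lapply(seq_along(datasets), function(di) {
    binary_sim_matrix(binary_id, keys[[di]]$fp)
  })
  rows <- list()
  for (nb in nonbinary_ids) {
    nb_mats <- lapply(seq_along(datasets), function(di) {
      list(cd = nonbinary_sim_matrix(nb, keys[[di]]$cd),
           hd = nonbinary_sim_matrix(nb, keys[[di]]$hd),
           fg = nonbinary_sim_matrix(nb, keys[[di]]$fg))
    })
    for (wi in seq_len(nrow(weights))) {
      w <- c(fp = weights$w_fp[wi], cd = weights$w_cd[wi],
             hd = weights$w_hd[wi], fg = weights$w_fg[wi])
      cfg <- similarity_config(fingerprint = fp_type, binary_id = binary_id,
                               nonbinary_id = nb, weights = w, mode = mode)
      run <- tibble::tibble(w_fp = w[["fp"]], w_cd = w[["cd"]],
                            w_hd = w[["hd"]], w_fg = w[["fg"]],
                            nonbinary_id = as.integer(nb))
      ok <- TRUE
      for (di in seq_along(datasets)) {
        ds <- datasets[[di]]
        res <- tryCatch({
          S <- combine_components(fp_mat[[di]], nb_mats[[di]]$cd,
                                  nb_mats[[di]]$hd, nb_mats[[di]]$fg, cfg)
          preds <- loo_from_si_matrix(S, ds$value, ds$id, k)
          loo_metrics(preds$observed, preds$predicted)
        }, error = function(e) {
          warning("stage 2 run (w = ", paste(w, collapse = "/"), ", nb = ",
                  nb, ") failed on ", labels[di], ": ", conditionMessage(e),
                  call. = FALSE)
          NULL
        })
        if (is.null(res)) { ok <- FALSE; break }
        run[[paste0("r2_", labels[di])]] <- res$r2
        run[[paste0("rmse_", labels[di])]] <- res$rmse
      }
      if (ok) rows[[length(rows) + 1L]] <- run
    }
  }
  out <- dplyr::bind_rows(rows)
  rank_results(out, metric_labels = labels)
}

as_dataset_list <- function(datasets) {
  if (is.data.frame(datasets)) datasets <- list(datasets)
  stopifnot(length(datasets) >= 1L)
  lapply(datasets, function(d) {
    stopifnot(all(c("id", "value", "mol") %in% names(d)))
    d
  })
}

#' Rank a batch of evaluation runs by desirability and utility
#'
#' Min-max scales each quality metric across the batch into \[0,1\] (R^2
#' ascending; RMSE scaled then complemented, so 1 is always best), then
#' scores every run with the desirability function DES (geometric mean of
#' the scaled parameters, with 0^w = 0: a run worst on any parameter gets
#' DES 0) and the utility function UTI (arithmetic mean), and appends dense
#' rank columns for both. With two datasets this is the four-parameter
#' scheme with exponents/weights 1/4; with m datasets the 2m parameters
#' get exponents/weights 1/(2m). A metric with zero spread across the
#' batch is set to 1 for all runs, with a warning.
#'
#' @param results A tibble with `r2_*` and `rmse_*` metric columns (one
#'   pair per dataset), e.g. from [stage1_grid()].
#' @param metric_labels Optional dataset labels; default: inferred from the
#'   `r2_*` column names.
#' @return The input with appended scaled-parameter columns `p1`, `p2`,
#'   ... (R^2 parameters first, then RMSE complements, in dataset order),
#'   `des`, `uti`, `rank_des`, `rank_uti`; class `grid_result`.
#' @export
rank_results <- function(results, metric_labels = NULL) {
  if (nrow(results) == 0L) stop("no runs to rank", call. = FALSE)
  labels <- metric_labels %||%
    sub("^r2_", "", grep("^r2_", names(results), value = TRUE))
  if (!length(labels)) stop("no r2_*/rmse_* metric columns found", call. = FALSE)
  scale01 <- function(x, what) {
    rng <- range(x)
    if (diff(rng) == 0) {
      warning("metric '", what, "' has zero spread across the batch; ",
              "scaled parameter set to 1 for all runs", call. = FALSE)
      return(rep(1, length(x)))
    }
    (x - rng[1L]) / diff(rng)
  }
  params <- list()
  for (i in seq_along(labels)) {
    params[[i]] <- scale01(results[[paste0("r2_", labels[i])]],
                           paste0("r2_", labels[i]))
  }
  for (i in seq_along(labels)) {
    params[[length(labels) + i]] <-
      1 - scale01(results[[paste0("rmse_", labels[i])]],
                  paste0("rmse_", labels[i]))
  }
  P <- do.call(cbind, params)
  m <- ncol(P)
  ex <- 1 / m
  des <- apply(P, 1L, function(p) prod(p^ex))
  uti <- rowMeans(P)
  out <- results
  for (j in seq_len(m)) out[[paste0("p", j)]] <- P[, j]
  out$des <- des
  out$uti <- uti
  # deterministic ranks: score descending, then original row order
  out$rank_des <- rank_desc_first(des)
  out$rank_uti <- rank_desc_first(uti)
  class(out) <- unique(c("grid_result", class(out)))
  attr(out, "metric_labels") <- labels
  out
}

rank_desc_first <- function(score) {
  ord <- order(-score, seq_along(score))
  rk <- integer(length(score))
  rk[ord] <- seq_along(score)
  rk
}

#' Length of the agreeing top prefix of the two rankings
#'
#' Reports how many leading positions of the desirability and utility
#' rankings of a batch coincide (the original calibration observed
#' agreement over the full top ten).
#'
#' @param results A ranked `grid_result`.
#' @return Integer prefix length.
#' @export
ranking_agreement_prefix <- function(results) {
  a <- order(results$rank_des)
  b <- order(results$rank_uti)
  agree <- a == b
  if (all(agree)) return(length(a))
  sum(cumprod(agree))
}

#' Write a grid-result batch to CSV
#'
#' Emits the configuration columns, per-dataset raw metrics, scaled
#' parameters (RMSE parameters already complement-scaled), DES/UTI scores
#' and both rank columns, in rank_des order. Numbers are written with full
#' precision so rewriting the same batch is byte-identical.
#'
#' @param results A `grid_result`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_grid_csv <- function(results, path) {
  out <- results[order(results$rank_des), ]
  readr::write_csv(out, path)
  invisible(path)
}

#' Plot a ranked evaluation batch
#'
#' Desirability versus utility for every run in a batch, highlighting the
#' agreeing top of the two rankings.
#'
#' @param object A `grid_result`.
#' @param top Number of top-ranked runs to highlight (default 10).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot grid_result
#' @export
autoplot.grid_result <- function(object, top = 10L, ...) {
  df <- tibble::as_tibble(object)
  df$top <- df$rank_des <= top
  ggplot2::ggplot(df, ggplot2::aes(x = .data$uti, y = .data$des)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$top), alpha = 0.7) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "#D55E00")) +
    ggplot2::labs(title = "Evaluation batch: desirability vs utility",
                  x = "utility (UTI)", y = "desirability (DES)",
                  colour = paste0("top ", top, " (DES)")) +
    ggplot2::theme_minimal()
}
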