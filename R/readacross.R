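# Read-across prediction: the endpoint of a query compound is estimated as
# the similarity-weighted mean of the experimental values of its k most
# similar training compounds (k = 3 by default), with leave-one-out
# cross-validation and R^2 / RMSE quality metrics.

#' Read-across prediction for one query molecule
#'
#' Finds the `k` training compounds most similar to the query under the
#' configured similarity index and predicts the endpoint as the SI-weighted
#' mean of their experimental values. Ties in SI are broken by ascending
#' compound id, making predictions fully deterministic. If all `k`
#' similarities are zero the unweighted mean is used and the prediction is
#' flagged low-confidence.
#'
#' @param query A `molecule` (must not be part of `training`).
#' @param training A property dataset (see [read_dataset()]).
#' @param config A [similarity_config()].
#' @param k Number of neighbours (default 3).
#' @param training_keys Optional precomputed [molecule_keys()] for the
#'   training set.
#' @return A one-row tibble: `id`, `predicted`, `low_confidence`, and a
#'   nested `neighbors` tibble (`id`, `si`, `value`, sorted by descending
#'   SI).
#' @export
ra_predict <- function(query, training, config = similarity_config(), k = 3L,
                       training_keys = NULL) {
  stopifnot(inherits(query, "molecule"))
  if (nrow(training) < k) {
    stop("training set smaller than k = ", k, call. = FALSE)
  }
  if (query$id %in% training$id) {
    stop("query id '", query$id, "' is present in the training set", call. = FALSE)
  }
  tk <- training_keys %||% molecule_keys(training, config)
  qk <- molecule_keys(list(query), config)
  sims <- vapply(seq_along(tk$ids), function(i) {
    as.numeric(combined_similarity(keys_slice(qk, 1L), keys_slice(tk, i), config))
  }, numeric(1))
  sel <- pick_neighbours(sims, training$id, k)
  nb <- tibble::tibble(id = training$id[sel], si = sims[sel],
                       value = training$value[sel])
  pred <- si_weighted_mean(nb$si, nb$value)
  tibble::tibble(id = query$id, predicted = pred$value,
                 low_confidence = pred$low_confidence,
                 neighbors = list(nb))
}

# top-k by similarity, ties broken by ascending id
pick_neighbours <- function(sims, ids, k) {
  ord <- order(-sims, ids)
  ord[seq_len(k)]
}

si_weighted_mean <- function(si, values) {
  tot <- sum(si)
  if (tot == 0) {
    list(value = mean(values), low_confidence = TRUE)
  } else {
    list(value = sum(si * values) / tot, low_confidence = FALSE)
  }
}

#' Leave-one-out validation of the read-across model
#'
#' Predicts every compound of the dataset from all others under the given
#' similarity configuration and summarises prediction quality as the
#' coefficient of determination R^2 = 1 - SS_res/SS_tot and the root mean
#' square error. All fingerprints and descriptor keys are computed once and
#' reused across folds. A dataset with zero variance in the observed values
#' (SS_tot = 0) is reported with `r2 = 1` and flagged `degenerate_variance`.
#'
#' @param data A property dataset of at least `k + 1` compounds.
#' @param config A [similarity_config()].
#' @param k Number of neighbours (default 3).
#' @param keys Optional precomputed [molecule_keys()].
#' @return An object of class `readacross_loo`: list with `predictions`
#'   (tibble: `id`, `observed`, `predicted`, `low_confidence`, neighbour
#'   ids/similarities `n1_id`..`n3_si`), `metrics` (tibble: `r2`, `rmse`,
#'   `n`, `r2_pearson`, `degenerate_variance`), `config`, `k`.
#' @export
loo_validate <- function(data, config = similarity_config(), k = 3L,
                         keys = NULL) {
  if (nrow(data) < k + 1L) {
    stop("leave-one-out needs at least k + 1 = ", k + 1L, " compounds",
         call. = FALSE)
  }
  keys <- keys %||% molecule_keys(data, config)
  S <- si_matrix(keys, config)
  preds <- loo_from_si_matrix(S, data$value, data$id, k)
  metrics <- loo_metrics(preds$observed, preds$predicted)
  structure(
    list(predictions = preds, metrics = metrics, config = config, k = k),
    class = "readacross_loo"
  )
}

# LOO predictions given a full SI matrix (the grid engine's fast path)
loo_from_si_matrix <- function(S, values, ids, k) {
  n <- length(values)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    cand <- setdiff(seq_len(n), i)
    sims <- S[i, cand]
    sel <- cand[pick_neighbours(sims, ids[cand], k)]
    pred <- si_weighted_mean(S[i, sel], values[sel])
    row <- list(id = ids[i], observed = values[i], predicted = pred$value,
                low_confidence = pred$low_confidence)
    for (j in seq_len(k)) {
      row[[paste0("n", j, "_id")]] <- ids[sel[j]]
      row[[paste0("n", j, "_si")]] <- S[i, sel[j]]
    }
    rows[[i]] <- tibble::as_tibble(row)
  }
  dplyr::bind_rows(rows)
}

#' LOO quality metrics from observed/predicted values
#'
#' @param observed,predicted Numeric vectors of equal length.
#' @return A one-row tibble: `r2` (1 - SS_res/SS_tot), `rmse`, `n`,
#'   `r2_pearson` (squared Pearson correlation, reported alongside because
#'   the two R-squared conventions differ for biased predictors), and
#'   `degenerate_variance`.
#' @export
loo_metrics <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted))
  n <- length(observed)
  ss_res <- sum((observed - predicted)^2)
  ss_tot <- sum((observed - mean(observed))^2)
  degenerate <- ss_tot == 0
  r2 <- if (degenerate) 1 else 1 - ss_res / ss_tot
  r2p <- if (degenerate || stats::sd(predicted) == 0) {
    NA_real_
  } else {
    stats::cor(observed, predicted)^2
  }
  tibble::tibble(r2 = r2, rmse = sqrt(ss_res / n), n = n, r2_pearson = r2p,
                 degenerate_variance = degenerate)
}

#' @export
print.readacross_loo <- function(x, ...) {
  m <- x$metrics
  cat("<readacross_loo> ", m$n, " LOO predictions (k = ", x$k, ", ",
      x$config$fingerprint, "/", x$config$binary_id, "/", x$config$nonbinary_id,
      ")\n  R2 = ", round(m$r2, 4), ", RMSE = ", round(m$rmse, 4),
      if (m$degenerate_variance) "  [degenerate variance]", "\n", sep = "")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname loo_validate
#' @param x A `readacross_loo` object.
#' @param ... Unused.
#' @method tidy readacross_loo
#' @export
tidy.readacross_loo <- function(x, ...) {
  x$predictions
}

#' @rdname loo_validate
#' @method glance readacross_loo
#' @export
glance.readacross_loo <- function(x, ...) {
  x$metrics
}

#' Observed-versus-predicted plot for a LOO run
#'
#' @param object A `readacross_loo` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot readacross_loo
#' @export
autoplot.readacross_loo <- function(object, ...) {
  df <- object$predictions
  m <- object$metrics
  ggplot2::ggplot(df, ggplot2::aes(x = .data$observed, y = .data$predicted)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$low_confidence),
                        show.legend = any(df$low_confidence)) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      title = "Read-across leave-one-out predictions",
      subtitle = sprintf("R² = %.3f, RMSE = %.3f, n = %d", m$r2, m$rmse, m$n),
      x = "observed", y = "predicted", colour = "low confidence"
    ) +
    ggplot2::theme_minimal()
}

#' Recompute LOO metrics from a dumped prediction table
#'
#' Reproduces the `metrics` tibble of [loo_validate()] from its
#' `predictions` table (e.g. after a round-trip through CSV), so that
#' reported metrics are always recomputable from the per-compound output.
#'
#' @param predictions A data frame with columns `observed`, `predicted`.
#' @return Same as [loo_metrics()].
#' @export
metrics_from_predictions <- function(predictions) {
  loo_metrics(predictions$observed, predictions$predicted)
}
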