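#' Rank features by coefficient magnitude
#'
#' Fits a single logistic model on all standardized baseline rows (follow-up
#' rows, lacking a ground-truth label, are excluded) and ranks the feature
#' columns by the absolute value of their fitted coefficients. On
#' standardized inputs coefficient magnitudes are directly comparable, so a
#' larger magnitude means a larger influence on the decision boundary. Ties
#' are broken by column order.
#'
#' The input must already be standardized over the baseline rows (column
#' means 0, variances 1); anything else is rejected, since magnitudes of
#' coefficients on unstandardized columns are not comparable.
#'
#' @param x standardized feature matrix tibble (baseline rows).
#' @param ridge ridge penalty passed to [fit_logistic()].
#' @return a `jae_ranking` tibble with columns `rank`, `feature`,
#'   `coefficient`, `magnitude`.
#' @export
rank_features <- function(x, ridge = 1e-4) {
  base <- dplyr::filter(x, .data$visit == "baseline", !is.na(.data$label))
  cols <- feature_columns(base)
  m <- vapply(base[cols], mean, numeric(1))
  v <- vapply(base[cols], var, numeric(1))
  ok <- abs(m) < 1e-6 & (abs(v - 1) < 1e-6 | v < 1e-12)
  if (!all(ok)) {
    stop_invalid(paste0(
      "feature matrix must be standardized over the baseline rows before ranking ",
      "(offending columns: ", paste(head(cols[!ok], 3), collapse = ", "), ", ...)"
    ))
  }
  model <- fit_logistic(base, base$label, ridge = ridge)
  mag <- abs(model$coefficients)
  ord <- order(-mag, seq_along(mag))
  out <- tibble::tibble(
    rank = seq_along(ord),
    feature = names(model$coefficients)[ord],
    coefficient = unname(model$coefficients[ord]),
    magnitude = unname(mag[ord])
  )
  class(out) <- c("jae_ranking", class(out))
  out
}

# deterministic unique m-subsets of 1..n (exhaustive when feasible)
draw_subsets <- function(n, m, cap, seed) {
  if (m >= n) return(list(seq_len(n)))
  n_comb <- choose(n, m)
  if (n_comb <= cap) {
    return(unname(as.list(as.data.frame(combn(n, m)))))
  }
  with_seed(seed, {
    seen <- new.env(parent = emptyenv())
    out <- vector("list", cap)
    got <- 0L
    while (got < cap) {
      s <- sort(sample.int(n, m))
      key <- paste(s, collapse = ",")
      if (is.null(seen[[key]])) {
        seen[[key]] <- TRUE
        got <- got + 1L
        out[[got]] <- s
      }
    }
    out
  })
}

#' Accuracy as a function of top-k features and cycles used
#'
#' Quantifies how classification accuracy depends jointly on how many
#' top-ranked features the model is trained on and how many movement cycles
#' are available from the tested subject. For each `k` in `1..max_features`
#' a full leave-one-subject-out pass is run with only the top-`k` ranked
#' feature columns (fold models are fitted once per `k` and reused across
#' cycle counts). For each held-out subject and each cycle count `m`, up to
#' `perm_cap` unique `m`-subsets of the subject's rows (pooled across all of
#' its channels) are drawn with a deterministic per-(subject, k, m) sub-seed
#' -- exhaustively when there are at most `perm_cap` subsets -- the subject
#' is classified from the mean probability of each subset, and the cell value
#' is the subject-level accuracy averaged over subsets and subjects. A
#' subject with fewer than `m` rows contributes its full row set.
#'
#' @param x unstandardized feature matrix tibble (baseline rows used).
#' @param ranking a `jae_ranking` from [rank_features()].
#' @param max_features number of top features to sweep (rows of the grid).
#' @param perm_cap maximum unique cycle subsets per cell (the study protocol
#'   used up to 1000).
#' @param ridge,threshold model penalty and decision threshold.
#' @param seed integer seed for subset sampling.
#' @return a `jae_heatmap` object: `grid` tibble (`n_features`, `n_cycles`,
#'   `accuracy`, `n_subsets`), the accuracy `matrix`, and the call settings.
#' @export
accuracy_heatmap <- function(x, ranking, max_features = 20, perm_cap = 1000,
                             ridge = 1e-4, threshold = 0.5, seed = 1L) {
  stopifnot(inherits(ranking, "jae_ranking"))
  check_scalar_number(perm_cap, "perm_cap", min = 1)
  base <- dplyr::filter(x, .data$visit == "baseline", !is.na(.data$label))
  if (max_features > nrow(ranking)) {
    stop_invalid("`max_features` exceeds the number of ranked feature columns")
  }
  sids <- unique(base$subject_id)
  max_cycles <- max(table(base$subject_id))

  cells <- purrr::map(seq_len(max_features), function(k) {
    cols <- ranking$feature[seq_len(k)]
    kept <- base[c(jae_meta_cols, cols)]
    # one LOSO pass: per-subject probabilities under the top-k model
    probs <- purrr::map(sids, function(sid) {
      train <- dplyr::filter(kept, .data$subject_id != sid)
      test <- dplyr::filter(kept, .data$subject_id == sid)
      st <- standardize_fit(train)
      model <- fit_logistic(standardize_apply(st, train), train$label, ridge = ridge)
      list(p = predict(model, standardize_apply(st, test)), label = test$label[1])
    })
    purrr::map_dfr(seq_len(max_cycles), function(m) {
      per_subject <- purrr::imap_dbl(probs, function(pr, i) {
        subs <- draw_subsets(length(pr$p), m, perm_cap,
                             seed = jae_seed(seed, sids[i], k, m))
        correct <- vapply(subs, function(s) {
          subject_label(mean(pr$p[s]), threshold) == pr$label
        }, logical(1))
        mean(correct)
      })
      n_subsets <- mean(purrr::map_dbl(probs, function(pr) {
        min(perm_cap, choose(length(pr$p), min(m, length(pr$p))))
      }))
      tibble::tibble(n_features = k, n_cycles = m,
                     accuracy = mean(per_subject), n_subsets = n_subsets)
    })
  })
  grid <- dplyr::bind_rows(cells)
  mat <- matrix(grid$accuracy, nrow = max_features, ncol = max_cycles,
                byrow = TRUE,
                dimnames = list(paste0("k", seq_len(max_features)),
                                paste0("m", seq_len(max_cycles))))
  structure(
    list(grid = grid, matrix = mat, perm_cap = perm_cap, seed = seed,
         threshold = threshold, ridge = ridge),
    class = "jae_heatmap"
  )
}

#' @export
print.jae_heatmap <- function(x, ...) {
  cat("<jae_heatmap>", nrow(x$matrix), "feature counts x", ncol(x$matrix),
      "cycle counts; accuracy range",
      sprintf("%.3f-%.3f\n", min(x$matrix), max(x$matrix)))
  invisible(x)
}
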