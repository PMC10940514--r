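# Label rules, cross-validation, grid search over (M, P1, P2),
# confusion-matrix metrics.

#' Binarize affective ratings into task labels
#'
#' Valence and arousal tasks: high iff the rating is strictly above 5, low
#' otherwise. Stress/calm task: stress iff `valence <= 3` and
#' `arousal >= 5`; calm iff `4 <= valence <= 6` and `arousal < 4`; records
#' matching neither rule are excluded (`NA`).
#'
#' @param ratings Data frame with numeric columns `valence` and `arousal`
#'   on the 1-9 rating scale.
#' @param task `"valence"`, `"arousal"`, or `"stress_calm"`.
#' @return Factor of the same length as `nrow(ratings)` with levels
#'   `c("low", "high")` or `c("calm", "stress")`; excluded records are
#'   `NA`. The positive class (second level) is high / stress.
#' @export
binarize_labels <- function(ratings, task = c("valence", "arousal", "stress_calm")) {
  task <- match.arg(task)
  stopifnot(all(c("valence", "arousal") %in% names(ratings)))
  v <- ratings$valence
  a <- ratings$arousal
  if (any(v < 1 | v > 9 | a < 1 | a > 9, na.rm = TRUE)) {
    stop("ratings out of the 1-9 scale")
  }
  if (task == "valence") {
    return(factor(ifelse(v > 5, "high", "low"), levels = c("low", "high")))
  }
  if (task == "arousal") {
    return(factor(ifelse(a > 5, "high", "low"), levels = c("low", "high")))
  }
  lab <- rep(NA_character_, length(v))
  lab[v <= 3 & a >= 5] <- "stress"
  lab[v >= 4 & v <= 6 & a < 4] <- "calm"
  factor(lab, levels = c("calm", "stress"))
}

#' Random k-fold partition
#'
#' Assigns `n` samples to `folds` folds of size differing by at most one;
#' every sample lands in exactly one test fold.
#'
#' @param n Sample count, `n >= folds`.
#' @param folds Number of folds (default 5).
#' @param seed Optional integer seed.
#' @return Integer vector of fold ids in `1:folds`.
#' @export
kfold_indices <- function(n, folds = 5L, seed = NULL) {
  if (n < folds) stop("invalid split: fewer samples than folds")
  if (!is.null(seed)) set.seed(seed)
  sample(rep_len(seq_len(folds), n))
}

#' Confusion-matrix metric suite for a binary task
#'
#' Precision, sensitivity (recall), specificity, accuracy and F1 computed
#' from the 2x2 confusion table. The positive class defaults to the second
#' factor level (high / stress). Ratios with a zero denominator are
#' returned as `NaN` and flagged.
#'
#' @param y_true,y_pred Equal-length label vectors (factors or coercible).
#' @param positive Positive class; default the second level of `y_true`.
#' @return Object of class `"mesn_metrics"`: list with the five metrics,
#'   the `confusion` table (rows = truth, cols = prediction), and
#'   `undefined`, the names of metrics with zero denominators.
#' @export
confusion_metrics <- function(y_true, y_pred, positive = NULL) {
  y_true <- as.factor(y_true)
  lev <- levels(y_true)
  y_pred <- factor(as.character(y_pred), levels = lev)
  if (length(y_true) != length(y_pred) || length(y_true) == 0L) {
    stop("y_true and y_pred must be nonempty and of equal length")
  }
  if (is.null(positive)) positive <- lev[length(lev)]
  stopifnot(positive %in% lev)
  pos_t <- y_true == positive
  pos_p <- y_pred == positive
  tp <- sum(pos_t & pos_p)
  fp <- sum(!pos_t & pos_p)
  fn <- sum(pos_t & !pos_p)
  tn <- sum(!pos_t & !pos_p)
  safe_div <- function(num, den) if (den == 0) NaN else num / den
  precision <- safe_div(tp, tp + fp)
  sensitivity <- safe_div(tp, tp + fn)
  specificity <- safe_div(tn, tn + fp)
  accuracy <- (tp + tn) / length(y_true)
  f1 <- if (is.nan(precision) || is.nan(sensitivity) ||
            precision + sensitivity == 0) {
    NaN
  } else {
    2 * precision * sensitivity / (precision + sensitivity)
  }
  confusion <- matrix(c(tn, fp, fn, tp), 2L, 2L, byrow = TRUE,
                      dimnames = list(
                        truth = c(setdiff(lev, positive)[1L], positive),
                        predicted = c(setdiff(lev, positive)[1L], positive)))
  metrics <- c(precision = precision, sensitivity = sensitivity,
               specificity = specificity, accuracy = accuracy, f1 = f1)
  structure(
    list(precision = precision, sensitivity = sensitivity,
         specificity = specificity, accuracy = accuracy, f1 = f1,
         confusion = confusion, positive = positive,
         undefined = names(metrics)[is.nan(metrics)]),
    class = "mesn_metrics"
  )
}

#' @export
print.mesn_metrics <- function(x, ...) {
  cat(sprintf(
    "precision %.4f  sensitivity %.4f  specificity %.4f  accuracy %.4f  F1 %.4f\n",
    x$precision, x$sensitivity, x$specificity, x$accuracy, x$f1))
  print(x$confusion)
  invisible(x)
}

#' Repeated k-fold evaluation of one modularity configuration
#'
#' For each repeat, draws a fresh seeded reservoir realization
#' `(n, modules, p1, p2)`, encodes all feature vectors once (per-sample
#' mode), and runs k-fold cross-validation of the ridge readout on the
#' encoded states; accuracies are averaged over folds and repeats. A new
#' reservoir per repeat averages out the sensitivity of ESNs to random
#' initialization.
#'
#' @param features `S x d` numeric feature matrix (rows are segments).
#' @param labels Length-S label factor/vector; `NA` rows are dropped.
#' @param modules,p1,p2 Modularity parameters of the reservoir.
#' @param n Reservoir size (default 600).
#' @param esn An [esn_config()].
#' @param folds Folds per repeat (default 5).
#' @param repeats Reservoir/CV repeats (default 3).
#' @param seed Master seed: expands into per-repeat reservoir and fold
#'   seeds.
#' @return List with `mean_accuracy`, `per_repeat` accuracies, `sd`, and
#'   the configuration.
#' @export
evaluate_config <- function(features, labels, modules, p1, p2, n = 600L,
                            esn = esn_config(), folds = 5L, repeats = 3L,
                            seed = 1L) {
  stopifnot(is.matrix(features))
  labels <- as.factor(labels)
  keep <- !is.na(labels)
  features <- features[keep, , drop = FALSE]
  labels <- droplevels(labels[keep])
  s_count <- nrow(features)
  if (s_count == 0L) stop("empty labeled dataset")
  set.seed(seed)
  repeat_seeds <- matrix(sample.int(.Machine$integer.max - 1L, 2L * repeats),
                         nrow = repeats)
  per_repeat <- vapply(seq_len(repeats), function(r) {
    res <- generate_reservoir(n = n, modules = modules, p1 = p1, p2 = p2,
                              rho = esn$rho, d = ncol(features),
                              seed = repeat_seeds[r, 1L])
    states <- encode_sequence(features, res, esn)
    fold_id <- kfold_indices(s_count, folds, seed = repeat_seeds[r, 2L])
    accs <- vapply(seq_len(folds), function(f) {
      test <- fold_id == f
      y_train <- labels[!test]
      if (nlevels(droplevels(y_train)) < 2L) {
        stop("degenerate fold: training split contains a single class")
      }
      ro <- fit_readout(states[, !test, drop = FALSE], y_train,
                        esn$ridge_lambda)
      pred <- predict(ro, states[, test, drop = FALSE])$labels
      mean(pred == labels[test])
    }, numeric(1L))
    mean(accs)
  }, numeric(1L))
  list(mean_accuracy = mean(per_repeat), per_repeat = per_repeat,
       sd = if (repeats > 1L) stats::sd(per_repeat) else NA_real_,
       modules = modules, p1 = p1, p2 = p2, n = n,
       folds = folds, repeats = repeats, seed = seed)
}

#' Grid specification for modularity optimization
#'
#' Default grid of the optimization protocol: `P1` over
#' `{0.05, 0.1, 0.15, 0.2, 0.25, 0.3}`, `M` over `{1..6, 8, 10}`, and for
#' each `P1` the inter-module probability `P2` over
#' `{P1/5, 2*P1/5, 3*P1/5, 4*P1/5, P1}` -- 240 triples in all, with
#' `P2 <= P1` by construction.
#'
#' @param p1_values Intra-module probabilities.
#' @param m_values Module counts.
#' @param p2_fractions Fractions of `P1` defining the `P2` sweep.
#' @param folds,repeats Cross-validation shape per triple.
#' @return List of class `"mesn_grid_spec"`.
#' @export
grid_spec <- function(p1_values = c(0.05, 0.1, 0.15, 0.2, 0.25, 0.3),
                      m_values = c(1, 2, 3, 4, 5, 6, 8, 10),
                      p2_fractions = c(1, 2, 3, 4, 5) / 5,
                      folds = 5L, repeats = 3L) {
  if (length(p1_values) == 0L || length(m_values) == 0L ||
      length(p2_fractions) == 0L) {
    stop("invalid grid: empty dimension")
  }
  if (any(p2_fractions <= 0 | p2_fractions > 1)) {
    stop("invalid grid: p2 fractions must lie in (0, 1] so that P2 <= P1")
  }
  structure(list(p1_values = p1_values, m_values = m_values,
                 p2_fractions = p2_fractions,
                 folds = as.integer(folds), repeats = as.integer(repeats)),
            class = "mesn_grid_spec")
}

#' Exhaustive grid search over (M, P1, P2)
#'
#' Evaluates every triple in the loop order P1 (outer), M, then P2 as a
#' fraction of P1, keeping the first triple that strictly improves the
#' best accuracy so far (ties keep the earlier triple). By default each
#' triple is scored by [evaluate_config()]; an `eval_fn(modules, p1, p2)`
#' can be injected to replace the scorer (used for testing the search
#' logic in isolation).
#'
#' @param features,labels Dataset passed to [evaluate_config()]; ignored
#'   when `eval_fn` is given.
#' @param grid A [grid_spec()].
#' @param n Reservoir size.
#' @param esn An [esn_config()].
#' @param seed Master seed; each triple gets a derived seed.
#' @param eval_fn Optional `function(modules, p1, p2) -> accuracy`.
#' @return List with `best` (list `modules`, `p1`, `p2`, `accuracy`) and
#'   `results`, a data frame of all evaluated triples in visit order.
#' @export
grid_search <- function(features = NULL, labels = NULL, grid = grid_spec(),
                        n = 600L, esn = esn_config(), seed = 1L,
                        eval_fn = NULL) {
  set.seed(seed)
  n_triples <- length(grid$p1_values) * length(grid$m_values) *
    length(grid$p2_fractions)
  triple_seeds <- sample.int(.Machine$integer.max - 1L, n_triples)
  rows <- vector("list", n_triples)
  best <- list(modules = NA, p1 = NA, p2 = NA, accuracy = -Inf)
  i <- 0L
  for (p1 in grid$p1_values) {
    for (m in grid$m_values) {
      for (frac in grid$p2_fractions) {
        i <- i + 1L
        p2 <- p1 * frac
        acc <- if (is.null(eval_fn)) {
          evaluate_config(features, labels, modules = m, p1 = p1, p2 = p2,
                          n = n, esn = esn, folds = grid$folds,
                          repeats = grid$repeats,
                          seed = triple_seeds[i])$mean_accuracy
        } else {
          eval_fn(m, p1, p2)
        }
        rows[[i]] <- data.frame(p1 = p1, m = m, p2 = p2, accuracy = acc)
        if (best$accuracy < acc) {
          best <- list(modules = m, p1 = p1, p2 = p2, accuracy = acc)
        }
      }
    }
  }
  list(best = best, results = do.call(rbind, rows))
}
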