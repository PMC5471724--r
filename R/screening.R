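# Two-step predictor screening for highly collinear covariate sets:
# (1) rank predictors by out-of-bag permutation importance from a bagged
# regression-tree ensemble; (2) greedily keep, in importance order, only
# predictors whose pairwise |Pearson r| with every already-kept predictor is
# below 0.5; (3) optionally stop adding predictors once the out-of-bag R^2
# stops improving by at least epsilon.

#' Rank predictors by permutation importance
#'
#' Out-of-bag permutation importance (mean OOB error increase) from a random
#' forest regression; deterministic under the seed.
#'
#' @param response Numeric response vector.
#' @param predictors Data frame of candidate predictors (numeric or factor).
#' @param weights Optional case weights.
#' @param n_trees Number of trees.
#' @param seed Integer seed.
#' @return Data frame (predictor, importance) sorted by decreasing
#'   importance, with attribute \code{"constant_response"} when the response
#'   has no variance (all importances 0).
#' @export
rank_importance <- function(response, predictors, weights = NULL,
                            n_trees = 500, seed = 1) {
  stopifnot(nrow(predictors) == length(response))
  if (nrow(predictors) < 30) {
    stop("importance ranking requires at least 30 records")
  }
  df <- data.frame(.y = response, predictors, check.names = FALSE)
  df <- df[stats::complete.cases(df), , drop = FALSE]
  constant <- stats::sd(df$.y) == 0
  if (constant) {
    out <- data.frame(predictor = names(predictors),
                      importance = 0, stringsAsFactors = FALSE)
    attr(out, "constant_response") <- TRUE
    return(out)
  }
  for (nm in names(df)) if (is.character(df[[nm]])) df[[nm]] <- factor(df[[nm]])
  fit <- ranger::ranger(
    dependent.variable.name = ".y", data = df,
    num.trees = n_trees, importance = "permutation",
    case.weights = if (is.null(weights)) NULL else weights,
    seed = seed, num.threads = 1)
  imp <- fit$variable.importance
  out <- data.frame(predictor = names(imp), importance = as.numeric(imp),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$importance), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "constant_response") <- FALSE
  attr(out, "oob_r2") <- fit$r.squared
  out
}

#' Greedy de-correlation filter
#'
#' Scans predictors in importance order and keeps each one iff its absolute
#' Pearson correlation with every already-kept numeric predictor is below
#' the threshold. Categorical predictors are exempt from r and always
#' eligible. Dropped predictors record the kept predictor that blocked them.
#'
#' @param ranked Data frame from \code{\link{rank_importance}} (or any
#'   data frame with a \code{predictor} column in priority order).
#' @param data Data frame holding the predictor columns.
#' @param threshold Absolute correlation threshold (default 0.5, strict:
#'   |r| must be < threshold).
#' @param method Correlation method (\code{"pearson"} default).
#' @return List: \code{kept} (character, importance order), \code{dropped}
#'   (data frame predictor/blocked_by/r).
#' @export
decorrelate <- function(ranked, data, threshold = 0.5, method = "pearson") {
  kept <- character(0)
  dropped <- data.frame(predictor = character(), blocked_by = character(),
                        r = numeric(), stringsAsFactors = FALSE)
  for (p in ranked$predictor) {
    if (!is.numeric(data[[p]])) { kept <- c(kept, p); next }
    blocked <- NULL
    for (q in kept) {
      if (!is.numeric(data[[q]])) next
      r <- suppressWarnings(stats::cor(data[[p]], data[[q]], method = method,
                                       use = "pairwise.complete.obs"))
      if (!is.na(r) && abs(r) >= threshold) { blocked <- c(q, r); break }
    }
    if (is.null(blocked)) {
      kept <- c(kept, p)
    } else {
      dropped <- rbind(dropped, data.frame(predictor = p,
                                           blocked_by = blocked[1],
                                           r = as.numeric(blocked[2]),
                                           stringsAsFactors = FALSE))
    }
  }
  list(kept = kept, dropped = dropped)
}

#' Predictive-accuracy stopping rule
#'
#' Adds predictors in priority order and stops the first time the model's
#' out-of-bag R^2 improves by less than \code{epsilon}; returns the set
#' accumulated before the plateau. With \code{epsilon = Inf} only the top
#' predictor is returned.
#'
#' @param candidates Character vector in priority (importance) order.
#' @param response Numeric response.
#' @param data Data frame holding the candidate columns.
#' @param epsilon Minimum R^2 improvement to continue (default 0.01).
#' @param n_trees,seed Forest parameters.
#' @return List: \code{kept}, \code{r2_trace} (R^2 after each addition).
#' @export
accuracy_stop <- function(candidates, response, data, epsilon = 0.01,
                          n_trees = 300, seed = 1) {
  stopifnot(length(candidates) >= 1)
  oob_r2 <- function(vars) {
    df <- data.frame(.y = response, data[vars], check.names = FALSE)
    df <- df[stats::complete.cases(df), , drop = FALSE]
    for (nm in names(df)) if (is.character(df[[nm]])) df[[nm]] <- factor(df[[nm]])
    fit <- ranger::ranger(dependent.variable.name = ".y", data = df,
                          num.trees = n_trees, seed = seed, num.threads = 1)
    fit$r.squared
  }
  kept <- candidates[1]
  trace <- oob_r2(kept)
  for (p in candidates[-1]) {
    r2 <- oob_r2(c(kept, p))
    if (r2 - trace[length(trace)] < epsilon) break
    kept <- c(kept, p)
    trace <- c(trace, r2)
  }
  list(kept = kept, r2_trace = trace)
}

#' Substitute an interpretable representative for a near-duplicate blocker
#'
#' When predictors are near-duplicates (|r| above \code{r_min}), which member
#' the greedy filter keeps is arbitrary. For interpretation one often wants a
#' specific representative (e.g. mean temperature rather than growing degree
#' days, which is a shifted copy of it). If none of \code{prefer} was kept
#' but one was blocked by a near-duplicate, the blocker is swapped for the
#' preferred predictor; otherwise the kept set is returned unchanged.
#'
#' @param screening A \code{\link{screen_predictors}} result.
#' @param prefer Character vector of preferred predictors (priority order).
#' @param r_min Minimum |r| with the blocker for the swap to be admissible.
#' @return The (possibly modified) kept set.
#' @export
swap_representative <- function(screening, prefer, r_min = 0.9) {
  kept <- screening$kept
  if (any(prefer %in% kept)) return(kept)
  dr <- screening$dropped
  cand <- dr[dr$predictor %in% prefer & !is.na(dr$r) & abs(dr$r) > r_min, ,
             drop = FALSE]
  if (nrow(cand) == 0) return(kept)
  cand <- cand[order(match(cand$predictor, prefer)), , drop = FALSE]
  kept[kept == cand$blocked_by[1]] <- cand$predictor[1]
  kept
}

#' Full two-step screen of a predictor category
#'
#' Importance ranking, then the |r| < threshold filter, then (optionally)
#' the accuracy stopping rule.
#'
#' @inheritParams rank_importance
#' @param threshold Correlation threshold.
#' @param epsilon Accuracy-rule epsilon; NULL skips the stopping rule.
#' @return List of class \code{screening_result}: \code{ranking},
#'   \code{kept}, \code{dropped}, \code{r2_trace}.
#' @export
screen_predictors <- function(response, predictors, weights = NULL,
                              threshold = 0.5, epsilon = NULL,
                              n_trees = 500, seed = 1) {
  ranked <- rank_importance(response, predictors, weights, n_trees, seed)
  dec <- decorrelate(ranked, predictors, threshold)
  kept <- dec$kept
  trace <- NULL
  if (!is.null(epsilon) && length(kept) >= 2) {
    acc <- accuracy_stop(kept, response, predictors, epsilon,
                         n_trees = max(200, n_trees %/% 2), seed = seed)
    for (p in setdiff(kept, acc$kept)) {
      dec$dropped <- rbind(dec$dropped,
                           data.frame(predictor = p, blocked_by = "accuracy-plateau",
                                      r = NA_real_, stringsAsFactors = FALSE))
    }
    kept <- acc$kept
    trace <- acc$r2_trace
  }
  structure(list(ranking = ranked, kept = kept, dropped = dec$dropped,
                 r2_trace = trace), class = "screening_result")
}
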