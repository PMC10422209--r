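# Evaluation battery for a continuous severity score against ordinal
# disease stages: correlation, pairwise t-tests, threshold-based two- and
# three-class classification metrics, dispersion statistics, Pareto bins.

#' Ordinal coding of disease stages
#'
#' NC = 0, MCI = 1, AD = 2: strictly increasing with clinical severity.
#' Spearman correlation is invariant to any monotone recoding.
#'
#' @return named integer vector.
#' @export
stage_coding <- function() c(NC = 0L, MCI = 1L, AD = 2L)

#' Correlation between score and ordinal disease stage
#'
#' @param scores numeric vector.
#' @param stages stage labels (NC/MCI/AD).
#' @param coding named stage -> integer map, default [stage_coding()].
#' @return list with signed `pearson` and `spearman` (rank correlation with
#'   midranks for ties) plus `pearson_pct`/`spearman_pct`, the absolute
#'   values as percentages for table-style display.
#' @export
correlation_with_stage <- function(scores, stages, coding = stage_coding()) {
  stages <- as_stage(stages)
  if (length(scores) != length(stages)) {
    stop("scores and stages differ in length", call. = FALSE)
  }
  if (length(scores) < 3L) stop("need at least 3 observations", call. = FALSE)
  if (length(unique(stages)) < 2L) {
    stop("need at least 2 distinct stages", call. = FALSE)
  }
  code <- unname(coding[as.character(stages)])
  if (stats::sd(scores) == 0) {
    stop("correlation undefined: scores are constant", call. = FALSE)
  }
  pearson <- stats::cor(scores, code, method = "pearson")
  spearman <- stats::cor(scores, code, method = "spearman")
  list(pearson = pearson, spearman = spearman,
       pearson_pct = 100 * abs(pearson), spearman_pct = 100 * abs(spearman))
}

#' Pairwise two-sample t-tests between stages
#'
#' Two-sided tests for NC/MCI, MCI/AD and NC/AD. The default is the
#' unequal-variance (Welch) variant; `var_equal = TRUE` gives the
#' pooled-variance Student form.
#'
#' @param scores numeric vector.
#' @param stages stage labels.
#' @param var_equal logical; pooled-variance test if `TRUE`.
#' @return named numeric vector of p-values
#'   (`"NC/MCI"`, `"MCI/AD"`, `"NC/AD"`).
#' @export
pairwise_ttests <- function(scores, stages, var_equal = FALSE) {
  stages <- as_stage(stages)
  pairs <- list(c("NC", "MCI"), c("MCI", "AD"), c("NC", "AD"))
  out <- stats::setNames(rep(NA_real_, 3L),
                         vapply(pairs, paste, "", collapse = "/"))
  for (i in seq_along(pairs)) {
    a <- scores[stages == pairs[[i]][1]]
    b <- scores[stages == pairs[[i]][2]]
    if (length(a) < 2L || length(b) < 2L) {
      small <- pairs[[i]][c(length(a) < 2L, length(b) < 2L)]
      stop("group(s) with fewer than 2 members: ",
           paste(small, collapse = ", "), call. = FALSE)
    }
    if (stats::var(a) == 0 && stats::var(b) == 0) {
      # degenerate: no within-group variability; p is 1 or 0 by mean equality
      out[i] <- if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0
    } else {
      out[i] <- stats::t.test(a, b, var.equal = var_equal)$p.value
    }
  }
  out
}

# Midpoints between consecutive sorted unique values, padded one step
# beyond each end so all-one-class assignments are reachable.
threshold_candidates <- function(scores) {
  u <- sort(unique(scores))
  if (length(u) == 1L) return(c(u - 1, u + 1))
  c(u[1] - 1, (u[-length(u)] + u[-1]) / 2, u[length(u)] + 1)
}

#' Two-class threshold metrics for an ordered stage pair
#'
#' The more severe stage of the task is the positive class. A single
#' cut-point is chosen by maximizing accuracy over all midpoints between
#' sorted unique selection scores (ties broken toward higher sensitivity,
#' then toward the lower threshold); the direction (whether low scores
#' predict positive) is inferred from group means. Metrics are then
#' computed on the evaluation data.
#'
#' @param scores,stages evaluation data.
#' @param task character pair, e.g. `c("NC", "MCI")`.
#' @param selection_scores,selection_stages optional separate selection set
#'   for the cut-point; defaults to the evaluation data (both modes exist
#'   because published work rarely states which was used).
#' @return list: `sensitivity`, `specificity`, `accuracy`, `threshold`,
#'   `direction` (`"low_is_positive"` or `"high_is_positive"`), and the 2x2
#'   `confusion` matrix (truth in rows, prediction in columns).
#' @export
binary_threshold_metrics <- function(scores, stages, task,
                                     selection_scores = NULL,
                                     selection_stages = NULL) {
  stages <- as_stage(stages)
  task <- as.character(as_stage(task))
  if (length(task) != 2L || task[1] == task[2]) {
    stop("task must be two distinct stages", call. = FALSE)
  }
  code <- stage_coding()
  task <- task[order(code[task])]       # (less severe, more severe)
  pos <- task[2]; neg <- task[1]
  keep <- stages %in% task
  scores <- scores[keep]; stages <- droplevels(stages[keep])
  if (!all(task %in% stages)) stop("both task stages must be present",
                                   call. = FALSE)
  if (is.null(selection_scores)) {
    selection_scores <- scores
    selection_stages <- stages
  } else {
    selection_stages <- as_stage(selection_stages)
    keep_s <- selection_stages %in% task
    selection_scores <- selection_scores[keep_s]
    selection_stages <- droplevels(selection_stages[keep_s])
  }
  low_pos <- mean(selection_scores[selection_stages == pos]) <=
    mean(selection_scores[selection_stages == neg])
  classify <- function(x, thr) {
    if (low_pos) x <= thr else x >= thr
  }
  best <- NULL
  for (thr in threshold_candidates(selection_scores)) {
    pred_pos <- classify(selection_scores, thr)
    is_pos <- selection_stages == pos
    tp <- sum(pred_pos & is_pos); fn <- sum(!pred_pos & is_pos)
    tn <- sum(!pred_pos & !is_pos); fp <- sum(pred_pos & !is_pos)
    acc <- (tp + tn) / length(selection_scores)
    sens <- tp / (tp + fn)
    cand <- list(thr = thr, acc = acc, sens = sens)
    if (is.null(best) || acc > best$acc + 1e-12 ||
        (abs(acc - best$acc) <= 1e-12 && sens > best$sens + 1e-12)) {
      best <- cand
    }
  }
  pred_pos <- classify(scores, best$thr)
  is_pos <- stages == pos
  tp <- sum(pred_pos & is_pos); fn <- sum(!pred_pos & is_pos)
  tn <- sum(!pred_pos & !is_pos); fp <- sum(pred_pos & !is_pos)
  confusion <- matrix(c(tp, fp, fn, tn), 2L, 2L,
                      dimnames = list(truth = c(pos, neg),
                                      predicted = c(pos, neg)))
  list(sensitivity = tp / (tp + fn),
       specificity = tn / (tn + fp),
       accuracy = (tp + tn) / length(scores),
       threshold = best$thr,
       direction = if (low_pos) "low_is_positive" else "high_is_positive",
       confusion = confusion)
}

#' Three-class threshold metrics
#'
#' Two ordered cut-points partition the score axis into three intervals;
#' intervals are mapped to stages by the order of the stage mean scores.
#' Cut-points maximize overall accuracy by exhaustive scan over all pairs
#' of midpoint candidates (ties broken toward the lexicographically
#' smallest pair). Per-stage one-vs-rest sensitivity, specificity and
#' accuracy are reported together with the 3x3 confusion matrix.
#'
#' @param scores,stages evaluation data containing all three stages.
#' @param selection_scores,selection_stages optional separate selection set.
#' @return list: `per_stage` (data.frame stage/sensitivity/specificity/
#'   accuracy), `cutpoints`, `stage_order` (stage of each interval, low to
#'   high score), `confusion`, `accuracy` (overall).
#' @export
threeclass_threshold_metrics <- function(scores, stages,
                                         selection_scores = NULL,
                                         selection_stages = NULL) {
  stages <- as_stage(stages)
  if (nlevels(droplevels(stages)) < 3L) {
    stop("all three stages must be present", call. = FALSE)
  }
  if (is.null(selection_scores)) {
    selection_scores <- scores
    selection_stages <- stages
  } else {
    selection_stages <- as_stage(selection_stages)
  }
  grp_mean <- tapply(selection_scores, selection_stages, mean)
  stage_order <- names(sort(grp_mean))   # stage of interval, low to high
  cand <- threshold_candidates(selection_scores)
  m <- length(cand)
  # prefix counts per interval-stage: n_c(t) = #selection obs of stage c <= t
  pref <- sapply(stage_order, function(st)
    vapply(cand, function(t) sum(selection_scores[selection_stages == st] <= t),
           numeric(1)))
  n_sel <- length(selection_scores)
  n3 <- sum(selection_stages == stage_order[3])
  best <- list(acc = -1, i = NA, j = NA)
  for (i in seq_len(m - 1L)) {
    j <- (i + 1L):m
    correct <- pref[i, 1] + (pref[j, 2] - pref[i, 2]) + (n3 - pref[j, 3])
    acc <- correct / n_sel
    k <- which.max(acc)               # first max: smallest j
    if (acc[k] > best$acc + 1e-12) {
      best <- list(acc = acc[k], i = i, j = j[k])
    }
  }
  cutpoints <- c(cand[best$i], cand[best$j])
  pred <- stage_order[findInterval(scores, cutpoints, left.open = TRUE) + 1L]
  pred <- factor(pred, levels = levels(stages))
  confusion <- table(truth = stages, predicted = pred)
  n <- length(scores)
  per <- do.call(rbind, lapply(levels(stages), function(st) {
    tp <- confusion[st, st]
    fn <- sum(confusion[st, ]) - tp
    fp <- sum(confusion[, st]) - tp
    tn <- n - tp - fn - fp
    data.frame(stage = st, sensitivity = tp / (tp + fn),
               specificity = tn / (tn + fp), accuracy = (tp + tn) / n)
  }))
  list(per_stage = per, cutpoints = cutpoints, stage_order = stage_order,
       confusion = confusion, accuracy = sum(diag(confusion)) / n)
}

#' Dispersion statistics of min-max-normalized scores
#'
#' Scores are first min-max normalized to `[0, 1]`. Variance and standard
#' deviation are the population forms; quartile deviation is
#' `(Q3 - Q1) / 2` under the linear-interpolation quantile rule (R type 7);
#' the variation ratio is `1 - modal frequency / n` after rounding the
#' normalized values to 2 decimals (a documented discretization -- a mode
#' needs one for continuous scores).
#'
#' @param scores numeric vector, length >= 2.
#' @return list: `variance`, `std`, `quartile_deviation`, `variation_ratio`.
#' @export
dispersion_table <- function(scores) {
  if (length(scores) < 2L) stop("need at least 2 observations", call. = FALSE)
  if (max(scores) == min(scores)) {
    return(list(variance = 0, std = 0, quartile_deviation = 0,
                variation_ratio = 0))
  }
  x <- (scores - min(scores)) / (max(scores) - min(scores))
  v <- mean((x - mean(x))^2)
  q <- stats::quantile(x, c(0.25, 0.75), type = 7, names = FALSE)
  tab <- table(round(x, 2))
  list(variance = v, std = sqrt(v),
       quartile_deviation = (q[2] - q[1]) / 2,
       variation_ratio = 1 - max(tab) / length(x))
}

#' Pareto bins of a score distribution
#'
#' Equal-width bins over `[min, max]`; frequencies sum to `n` and the
#' cumulative percentage curve is nondecreasing and ends at exactly 100.
#'
#' @param scores numeric vector.
#' @param n_bins number of bins (>= 2, default 10).
#' @return list: `bin_edges` (length `n_bins + 1`), `frequencies`,
#'   `cumulative_percent`.
#' @export
pareto_bins <- function(scores, n_bins = 10L) {
  if (length(scores) < 1L) stop("need at least 1 observation", call. = FALSE)
  stopifnot_scalar_number(n_bins, "n_bins", TRUE)
  if (n_bins < 2L) stop("n_bins must be >= 2", call. = FALSE)
  lo <- min(scores); hi <- max(scores)
  if (lo == hi) {
    edges <- seq(lo - 0.5, hi + 0.5, length.out = n_bins + 1L)
  } else {
    edges <- seq(lo, hi, length.out = n_bins + 1L)
  }
  bin <- findInterval(scores, edges, rightmost.closed = TRUE,
                      all.inside = TRUE)
  freq <- tabulate(bin, nbins = n_bins)
  list(bin_edges = edges, frequencies = freq,
       cumulative_percent = 100 * cumsum(freq) / length(scores))
}

#' Run the full evaluation battery on a scores table
#'
#' @param scores data.frame with columns `score` and `stage` (e.g. from
#'   [score_dataset()]), or a numeric vector if `stages` is given.
#' @param stages stage labels when `scores` is a vector.
#' @param var_equal passed to [pairwise_ttests()].
#' @param n_bins passed to [pareto_bins()].
#' @return an object of class `odss_eval` collecting every component;
#'   confusion matrices are carried so each rate is recomputable.
#' @export
evaluate_scores <- function(scores, stages = NULL, var_equal = FALSE,
                            n_bins = 10L) {
  if (is.data.frame(scores)) {
    if (!all(c("score", "stage") %in% names(scores))) {
      stop("scores data.frame needs columns `score` and `stage`",
           call. = FALSE)
    }
    stages <- scores$stage
    scores <- scores$score
  }
  stages <- as_stage(stages)
  tasks <- list(c("NC", "MCI"), c("MCI", "AD"), c("NC", "AD"))
  binary <- lapply(tasks, function(tk)
    binary_threshold_metrics(scores, stages, tk))
  names(binary) <- vapply(tasks, paste, "", collapse = "/")
  structure(list(
    n = length(scores),
    correlation = correlation_with_stage(scores, stages),
    ttests = pairwise_ttests(scores, stages, var_equal = var_equal),
    binary = binary,
    threeclass = threeclass_threshold_metrics(scores, stages),
    dispersion = dispersion_table(scores),
    pareto = pareto_bins(scores, n_bins = n_bins)
  ), class = "odss_eval")
}

#' @export
print.odss_eval <- function(x, ...) {
  cat("Severity-score evaluation (n =", x$n, "images)\n")
  cat(sprintf("  Pearson r = %.4f (|r| = %.2f%%), Spearman rho = %.4f (|rho| = %.2f%%)\n",
              x$correlation$pearson, x$correlation$pearson_pct,
              x$correlation$spearman, x$correlation$spearman_pct))
  cat("  pairwise t-test p-values:\n")
  for (nm in names(x$ttests)) {
    cat(sprintf("    %-7s %.3g\n", nm, x$ttests[[nm]]))
  }
  cat("  two-class tasks (sens / spec / acc):\n")
  for (nm in names(x$binary)) {
    b <- x$binary[[nm]]
    cat(sprintf("    %-7s %.3f / %.3f / %.3f\n", nm,
                b$sensitivity, b$specificity, b$accuracy))
  }
  cat(sprintf("  three-class overall accuracy: %.3f\n", x$threeclass$accuracy))
  d <- x$dispersion
  cat(sprintf("  dispersion (normalized): var %.4f, sd %.4f, QD %.4f, VR %.4f\n",
              d$variance, d$std, d$quartile_deviation, d$variation_ratio))
  invisible(x)
}

# Plain-list view of a report for JSON serialization.
eval_report_as_list <- function(report) {
  stopifnot(inherits(report, "odss_eval"))
  list(
    n = report$n,
    correlation = report$correlation,
    ttests = as.list(report$ttests),
    binary = lapply(report$binary, function(b) {
      list(sensitivity = b$sensitivity, specificity = b$specificity,
           accuracy = b$accuracy, threshold = b$threshold,
           direction = b$direction,
           confusion = unclass(b$confusion))
    }),
    threeclass = list(
      per_stage = report$threeclass$per_stage,
      cutpoints = report$threeclass$cutpoints,
      stage_order = report$threeclass$stage_order,
      confusion = unclass(as.matrix(report$threeclass$confusion)),
      accuracy = report$threeclass$accuracy
    ),
    dispersion = report$dispersion,
    pareto = report$pareto
  )
}

#' Serialize an evaluation report to JSON
#'
#' Deterministic for identical reports (fixed digits, stable field order),
#' so a seeded rerun of the pipeline is byte-identical.
#'
#' @param report an `odss_eval`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_eval_report <- function(report, path) {
  json <- jsonlite::toJSON(eval_report_as_list(report), auto_unbox = TRUE,
                           digits = 10, pretty = TRUE)
  writeLines(json, path)
  invisible(path)
}
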