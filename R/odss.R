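# The user-facing model: fit, predict, print, summary, plot.

#' Fit a severity-scoring model to a labeled slice dataset
#'
#' Trains the weight-sharing residual encoder with the supervised
#' contrastive loss on the training split, draws the five-subject healthy
#' baseline panel, scores the held-out test split (100 x mean cosine
#' similarity to the panel), and runs the evaluation battery on those
#' scores.
#'
#' @param data an [odss_dataset()] with a subject-wise split (see
#'   [split_by_subject()]) and at least 2 stages in the training split.
#' @param encoder an [encoder_config()] (or a prebuilt `odss_encoder` to
#'   start from).
#' @param training a [train_config()].
#' @param panel_seed seed for the baseline-panel draw.
#' @param evaluate logical; run [evaluate_scores()] on the test-split
#'   scores (requires all 3 stages there).
#' @return an object of class `odss` with elements `encoder`, `history`,
#'   `panel`, `scores` (test split), `evaluation`, `call`.
#' @export
odss_fit <- function(data, encoder = encoder_config(),
                     training = train_config(), panel_seed = 1L,
                     evaluate = TRUE) {
  stopifnot(inherits(data, "odss_dataset"))
  if (is.null(data$meta$split)) {
    stop("dataset has no train/test split; call split_by_subject() first",
         call. = FALSE)
  }
  enc <- if (inherits(encoder, "odss_encoder")) encoder else
    build_encoder(encoder)
  fit <- train_encoder(enc, data, training)
  panel <- build_baseline_panel(data, fit$encoder, seed = panel_seed)
  test <- dataset_split(data, "test")
  scores <- score_dataset(test, fit$encoder, panel, per_subject = TRUE)
  evaluation <- if (evaluate && nlevels(droplevels(scores$stage)) == 3L) {
    evaluate_scores(scores)
  } else {
    NULL
  }
  structure(list(encoder = fit$encoder, history = fit$history,
                 panel = panel, scores = scores, evaluation = evaluation,
                 training = training, call = match.call()),
            class = "odss")
}

#' @export
print.odss <- function(x, ...) {
  cat("Severity-scoring model (supervised contrastive encoder)\n")
  cat("  trained", nrow(x$history), "epochs;")
  if (nrow(x$history) > 0) {
    cat(" mean per-anchor loss", format(x$history$loss_mean[1], digits = 4),
        "->", format(x$history$loss_mean[nrow(x$history)], digits = 4))
  }
  cat("\n  baseline panel:", paste(x$panel$subject_ids, collapse = ", "), "\n")
  cat("  test images scored:", nrow(x$scores), "\n")
  invisible(x)
}

#' @export
summary.odss <- function(object, ...) {
  print(object)
  grp <- tapply(object$scores$score, object$scores$stage, mean)
  cat("  mean test score by stage:",
      paste(sprintf("%s %.2f", names(grp), grp), collapse = ", "), "\n")
  if (!is.null(object$evaluation)) {
    cat("\n")
    print(object$evaluation)
  }
  invisible(object)
}

#' Score new images with a fitted model
#'
#' @param object an `odss` fit.
#' @param newdata an `odss_dataset` or list of `[0, 1]` image matrices;
#'   defaults to the stored test-split scores.
#' @param ... unused.
#' @return data.frame of score records (one row per image).
#' @export
predict.odss <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$scores)
  score_dataset(newdata, object$encoder, object$panel)
}

#' Plot a fitted model: training loss curve and test scores by stage
#'
#' @param x an `odss` fit.
#' @param ... passed to the underlying plot calls.
#' @export
plot.odss <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  if (nrow(x$history) > 0) {
    plot(x$history$epoch, x$history$loss_mean, type = "b",
         xlab = "epoch", ylab = "mean per-anchor loss",
         main = "Contrastive training loss", ...)
  }
  graphics::boxplot(score ~ stage, data = x$scores,
                    xlab = "stage", ylab = "severity score",
                    main = "Held-out scores by stage", ...)
  invisible(x)
}
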