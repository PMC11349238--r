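#' Build the internal-control training set
#'
#' Training labels come from the screen's internal controls: premature stop
#' (nonsense) outcomes in codons 1..boundary are presumed damaging and
#' synonymous outcomes in the same span presumed tolerated. Stops beyond the
#' boundary are excluded because late truncation does not impair
#' complementation; unscorable outcomes are excluded.
#'
#' @param outcome_scores Outcome-level scores ([aggregate_outcomes()]).
#' @param boundary Last codon included for both control classes.
#' @return Data.frame `outcome_id`, `codon_index`, `kind`, `rcs`, `label`
#'   (factor with levels `tolerated`, `damaging`).
#' @export
build_training_set <- function(outcome_scores, boundary = 500L) {
  sc <- outcome_scores[outcome_scores$scorable & is.finite(outcome_scores$rcs), ]
  keep <- sc$codon_index <= boundary & sc$kind %in% c("stop_gain", "synonymous")
  tr <- sc[keep, c("outcome_id", "codon_index", "kind", "rcs")]
  tr$label <- factor(ifelse(tr$kind == "stop_gain", "damaging", "tolerated"),
                     levels = c("tolerated", "damaging"))
  n_dam <- sum(tr$label == "damaging")
  n_tol <- sum(tr$label == "tolerated")
  if (n_dam == 0L) stop("damaging control class empty (no scored stop-gain ",
                        "outcomes in codons 1..", boundary, ")", call. = FALSE)
  if (n_tol == 0L) stop("tolerated control class empty (no scored synonymous ",
                        "outcomes in codons 1..", boundary, ")", call. = FALSE)
  rownames(tr) <- NULL
  tr
}

# Ridge-penalized one-feature logistic regression fitted by BFGS on the
# penalized negative log-likelihood. The (small) ridge keeps coefficients
# finite under complete separation, where the unpenalized MLE diverges.
fit_logistic_ridge <- function(x, y, ridge = 1e-6) {
  stopifnot(length(x) == length(y), all(y %in% c(0, 1)))
  if (length(unique(y)) < 2L) stop("single-class input", call. = FALSE)
  if (isTRUE(all.equal(stats::var(x), 0))) {
    stop("degenerate training data: score is constant", call. = FALSE)
  }
  nll <- function(b) {
    eta <- b[1] + b[2] * x
    # log(1 + exp(eta)) computed stably
    sum(pmax(eta, 0) + log1p(exp(-abs(eta))) - y * eta) +
      ridge / 2 * sum(b^2)
  }
  grad <- function(b) {
    p <- stats::plogis(b[1] + b[2] * x)
    c(sum(p - y), sum((p - y) * x)) + ridge * b
  }
  fit <- optim(c(0, 0), nll, grad, method = "BFGS",
               control = list(maxit = 1000, reltol = 1e-12))
  list(coefficients = c(intercept = fit$par[1], slope = fit$par[2]),
       converged = fit$convergence == 0)
}

#' Fit the damaging/tolerated classifier to screen scores
#'
#' The core model: a one-feature logistic regression of damaging status on
#' the complementation score, trained on the internal nonsense/synonymous
#' controls. The implied decision threshold is the score at which the
#' damaging probability crosses 0.5 (`t* = -intercept/slope`); missense
#' outcomes with scores below it are called damaging. A small ridge penalty
#' (default `1e-6`) keeps the fit finite when the control classes are
#' completely separated.
#'
#' @param outcome_scores Outcome-level scores ([aggregate_outcomes()] or the
#'   `outcome` element of [score_screen()]); a `screen_scores` object is
#'   also accepted.
#' @param boundary Training-control codon boundary (see
#'   [build_training_set()]).
#' @param ridge Ridge penalty scale.
#' @param level `"outcome"` (default) trains on outcome-level scores;
#'   `"snv"` trains on per-SNV scores (requires `snv_scores`).
#' @param snv_scores Optional [score_snvs()] table for `level = "snv"`.
#' @return Object of class `rcs_fit`: list with `coefficients` (intercept,
#'   slope), `threshold`, `training` (with fitted probabilities), `calls`
#'   (effect calls for scorable missense outcomes), `boundary`, `ridge`,
#'   `outcome_scores`.
#' @seealso [predict.rcs_fit()], [summary.rcs_fit()], [plot.rcs_fit()]
#' @export
rcs_fit <- function(outcome_scores, boundary = 500L, ridge = 1e-6,
                    level = c("outcome", "snv"), snv_scores = NULL) {
  level <- match.arg(level)
  if (inherits(outcome_scores, "screen_scores")) {
    if (is.null(snv_scores)) snv_scores <- outcome_scores$snv
    outcome_scores <- outcome_scores$outcome
  }
  if (level == "snv") {
    if (is.null(snv_scores)) stop("level = 'snv' requires snv_scores", call. = FALSE)
    base <- snv_scores[snv_scores$scorable, ]
    base$outcome_id <- base$outcome_id
    tr_src <- data.frame(outcome_id = base$outcome_id,
                         codon_index = base$codon_index, kind = base$kind,
                         rcs = base$rcs, scorable = TRUE,
                         stringsAsFactors = FALSE)
    training <- build_training_set(tr_src, boundary)
  } else {
    training <- build_training_set(outcome_scores, boundary)
  }
  if (nrow(training) < 4L || min(table(training$label)) < 2L) {
    stop("need at least 2 scored outcomes in each control class", call. = FALSE)
  }
  y <- as.integer(training$label == "damaging")
  fit <- fit_logistic_ridge(training$rcs, y, ridge)
  b <- fit$coefficients
  threshold <- unname(-b["intercept"] / b["slope"])
  training$probability <- stats::plogis(b["intercept"] + b["slope"] * training$rcs)

  obj <- structure(list(
    coefficients = b, threshold = threshold, converged = fit$converged,
    training = training, boundary = boundary, ridge = ridge, level = level,
    outcome_scores = outcome_scores, call = match.call()
  ), class = "rcs_fit")
  obj$calls <- predict_effects(obj, outcome_scores)
  obj
}

#' Effect calls for scorable missense outcomes
#'
#' Applies a fitted classifier to outcome-level scores and emits one call
#' per scorable non-synonymous (missense) outcome: probability of being
#' damaging and the binary label (damaging iff probability >= 0.5, i.e.
#' score below the decision threshold).
#'
#' @param model An [rcs_fit()] object.
#' @param outcome_scores Outcome-level scores.
#' @param kinds Consequence kinds to call (default missense only).
#' @return Data.frame `outcome_id`, `hgvs_p`, `codon_index`, `kind`, `rcs`,
#'   `probability`, `label`.
#' @export
predict_effects <- function(model, outcome_scores,
                            kinds = "missense") {
  stopifnot(inherits(model, "rcs_fit"))
  sub <- outcome_scores[outcome_scores$kind %in% kinds &
                          outcome_scores$scorable &
                          is.finite(outcome_scores$rcs), ]
  p <- predict(model, sub$rcs, type = "response")
  data.frame(outcome_id = sub$outcome_id, hgvs_p = sub$hgvs_p,
             codon_index = sub$codon_index, kind = sub$kind, rcs = sub$rcs,
             probability = p,
             label = ifelse(p >= 0.5, "damaging", "tolerated"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' @export
print.rcs_fit <- function(x, ...) {
  cat("Complementation-score classifier (one-feature logistic regression)\n")
  cat(sprintf("  intercept %.4f, slope %.4f; decision threshold t* = %.3f\n",
              x$coefficients["intercept"], x$coefficients["slope"], x$threshold))
  cat(sprintf("  trained on %d damaging (stop <= codon %d) and %d tolerated (synonymous) controls\n",
              sum(x$training$label == "damaging"), x$boundary,
              sum(x$training$label == "tolerated")))
  if (!is.null(x$calls)) {
    cat(sprintf("  calls: %d damaging / %d tolerated missense outcomes\n",
                sum(x$calls$label == "damaging"),
                sum(x$calls$label == "tolerated")))
  }
  invisible(x)
}

#' @export
coef.rcs_fit <- function(object, ...) object$coefficients

#' Predict damaging probability or label from a fitted classifier
#'
#' @param object An [rcs_fit()].
#' @param newdata Numeric vector of complementation scores, or a data.frame
#'   with an `rcs` column; omitted = training scores.
#' @param type `"response"` (probability damaging), `"class"`
#'   (`damaging`/`tolerated`), or `"link"` (logit).
#' @param ... Unused.
#' @export
predict.rcs_fit <- function(object, newdata = NULL,
                            type = c("response", "class", "link"), ...) {
  type <- match.arg(type)
  rcs <- if (is.null(newdata)) object$training$rcs
         else if (is.data.frame(newdata)) newdata$rcs
         else as.numeric(newdata)
  eta <- object$coefficients["intercept"] + object$coefficients["slope"] * rcs
  switch(type,
         link = unname(eta),
         response = unname(stats::plogis(eta)),
         class = unname(ifelse(stats::plogis(eta) >= 0.5, "damaging", "tolerated")))
}

#' @export
fitted.rcs_fit <- function(object, ...) object$training$probability

#' @export
residuals.rcs_fit <- function(object, type = c("deviance", "response"), ...) {
  type <- match.arg(type)
  y <- as.integer(object$training$label == "damaging")
  p <- object$training$probability
  if (type == "response") return(y - p)
  sign(y - p) * sqrt(-2 * (y * log(pmax(p, 1e-300)) +
                             (1 - y) * log(pmax(1 - p, 1e-300))))
}

#' Classifier performance report
#'
#' Confusion matrix, accuracy, ROC curve and AUC on labeled scores.
#'
#' @param model An [rcs_fit()].
#' @param labeled Data.frame with `rcs` and `label` columns (default: the
#'   model's training set).
#' @return List of class `classifier_eval`: `confusion` (2x2 table, truth in
#'   rows), `accuracy`, `n_correct`, `n_total`, `roc` (data.frame `fpr`,
#'   `tpr`, `threshold`), `auc`.
#' @export
evaluate_classifier <- function(model, labeled = model$training) {
  stopifnot(all(c("rcs", "label") %in% names(labeled)))
  lab <- as.character(labeled$label)
  if (length(unique(lab)) < 2L) stop("single-class input", call. = FALSE)
  p <- predict(model, labeled$rcs, type = "response")
  pred <- ifelse(p >= 0.5, "damaging", "tolerated")
  lev <- c("damaging", "tolerated")
  confusion <- table(truth = factor(lab, lev), predicted = factor(pred, lev))
  n_correct <- sum(diag(confusion))
  n_total <- sum(confusion)

  # ROC by sweeping the probability threshold over all observed values;
  # tied probabilities move along one diagonal segment
  y <- as.integer(lab == "damaging")
  thr <- c(Inf, sort(unique(p), decreasing = TRUE))
  tpr <- vapply(thr, function(t) sum(y == 1 & p >= t) / sum(y == 1), numeric(1))
  fpr <- vapply(thr, function(t) sum(y == 0 & p >= t) / sum(y == 0), numeric(1))
  roc <- data.frame(fpr = fpr, tpr = tpr, threshold = thr)
  auc <- sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) + utils::tail(roc$tpr, -1)) / 2)

  structure(list(confusion = confusion, accuracy = n_correct / n_total,
                 n_correct = n_correct, n_total = n_total,
                 roc = roc, auc = auc),
            class = "classifier_eval")
}

#' @export
print.classifier_eval <- function(x, ...) {
  cat(sprintf("Accuracy %.1f%% (%d/%d), AUC %.3f\n", 100 * x$accuracy,
              x$n_correct, x$n_total, x$auc))
  print(x$confusion)
  invisible(x)
}

#' @export
summary.rcs_fit <- function(object, ...) {
  ev <- evaluate_classifier(object)
  structure(list(fit = object, eval = ev), class = "summary.rcs_fit")
}

#' @export
print.summary.rcs_fit <- function(x, ...) {
  print(x$fit)
  cat("\nTraining performance:\n")
  print(x$eval)
  invisible(x)
}

#' Diagnostic plots for a fitted classifier
#'
#' `which = 1`: training scores by class with the fitted logistic curve and
#' decision threshold; `which = 2`: ROC curve on the training set.
#'
#' @param x An [rcs_fit()].
#' @param which Plots to draw.
#' @param ... Passed to plotting functions.
#' @export
plot.rcs_fit <- function(x, which = 1:2, ...) {
  if (1 %in% which) {
    tr <- x$training
    plot(tr$rcs, as.integer(tr$label == "damaging"),
         pch = ifelse(tr$label == "damaging", 4, 1),
         col = ifelse(tr$label == "damaging", "firebrick", "steelblue"),
         xlab = "complementation score (RCS)", ylab = "P(damaging)",
         main = "Control classes and fitted logistic model", ...)
    grid_x <- seq(min(tr$rcs), max(tr$rcs), length.out = 200)
    graphics::lines(grid_x, predict(x, grid_x, type = "response"), lwd = 2)
    graphics::abline(v = x$threshold, lty = 2, col = "grey40")
  }
  if (2 %in% which) {
    ev <- evaluate_classifier(x)
    plot(ev$roc$fpr, ev$roc$tpr, type = "l", lwd = 2,
         xlab = "false positive rate", ylab = "true positive rate",
         main = sprintf("ROC (AUC = %.3f)", ev$auc), ...)
    graphics::abline(0, 1, lty = 3, col = "grey60")
  }
  invisible(x)
}

#' Variant effect map matrix
#'
#' Residues-by-alternate-amino-acid matrix of damaging probabilities for all
#' SNV-reachable missense outcomes (cells for unreachable or unscorable
#' changes are `NA`), the tabular form of a variant-effect-map figure.
#'
#' @param model An [rcs_fit()].
#' @param outcome_scores Outcome-level scores (default: those stored in the
#'   model).
#' @return Numeric matrix, rows = alternate amino acids (one-letter),
#'   columns = residue positions.
#' @export
effect_map <- function(model, outcome_scores = model$outcome_scores) {
  calls <- predict_effects(model, outcome_scores)
  aas <- setdiff(names(AA3), "*")
  n_codons <- max(outcome_scores$codon_index)
  m <- matrix(NA_real_, nrow = length(aas), ncol = n_codons,
              dimnames = list(aas, seq_len(n_codons)))
  sub <- merge(calls, outcome_scores[, c("outcome_id", "alt_aa")], by = "outcome_id")
  m[cbind(match(sub$alt_aa, aas), sub$codon_index)] <- sub$probability
  m
}
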