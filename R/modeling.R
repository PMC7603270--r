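#' Per-subset logistic models
#'
#' Each immune subset gets a logistic regression of its binary
#' enrichment level on the selected radiomic features, fitted by
#' iteratively reweighted least squares with a tiny L2 ridge
#' (`1e-6` on the non-intercept coefficients) so separable leave-one-out
#' folds stay finite. Evaluation is leave-one-out cross-validation with
#' accuracy and rank-based AUC.
#'
#' @name modeling
NULL

#' Fit a ridge-stabilized logistic model
#'
#' @param features samples x features numeric matrix.
#' @param labels binary labels; `"high"` (or 1 / TRUE / the second factor
#'   level) is the positive class.
#' @param subset optional subset name stored in the model.
#' @param ridge L2 penalty on non-intercept coefficients (default 1e-6).
#' @param max_iter,tol IRLS iteration controls.
#' @return a `subset_model` with coefficients, intercept and metadata.
#' @export
fit_subset_model <- function(features, labels, subset = NA_character_,
                             ridge = 1e-6, max_iter = 100, tol = 1e-10) {
  X <- as.matrix(features)
  y <- as_binary(labels)
  if (length(unique(y)) < 2) stop("labels contain a single class")
  if (nrow(X) <= ncol(X))
    warning("n <= p: coefficients rely on the ridge for identifiability")
  # fit on standardized columns so the ridge acts on a common scale;
  # constant columns get coefficient 0
  ctr <- colMeans(X)
  scl <- apply(X, 2, sd)
  ok <- is.finite(scl) & scl > 0
  Xs <- sweep(sweep(X[, ok, drop = FALSE], 2, ctr[ok]), 2, scl[ok], "/")
  Xd <- cbind(`(Intercept)` = 1, Xs)
  p <- ncol(Xd)
  # negligible jitter on the intercept keeps fully separated fits solvable
  pen_diag <- c(1e-10, rep(ridge, p - 1))
  pen <- diag(pen_diag, p)
  # penalized negative log-likelihood, overflow-safe
  pnll <- function(b) {
    eta <- drop(Xd %*% b)
    -sum(y * eta - (pmax(eta, 0) + log1p(exp(-abs(eta))))) +
      0.5 * sum(pen_diag * b^2)
  }
  beta <- rep(0, p)
  obj <- pnll(beta)
  for (it in seq_len(max_iter)) {
    eta <- drop(Xd %*% beta)
    mu <- plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-12)
    z <- eta + (y - mu) / w
    XtW <- t(Xd * w)
    cand <- drop(solve(XtW %*% Xd + pen, XtW %*% z))
    # step-halving keeps the penalized deviance monotone on separable or
    # ill-conditioned folds where plain IRLS oscillates
    step <- cand - beta
    new_obj <- pnll(cand)
    h <- 0
    while (new_obj > obj + 1e-12 && h < 30) {
      step <- step / 2
      cand <- beta + step
      new_obj <- pnll(cand)
      h <- h + 1
    }
    done <- max(abs(cand - beta)) < tol || abs(obj - new_obj) < 1e-12
    beta <- cand
    obj <- new_obj
    if (done) break
  }
  coefs <- setNames(rep(0, ncol(X)), colnames(X))
  coefs[ok] <- beta[-1] / scl[ok]
  intercept <- beta[1] - sum(beta[-1] * ctr[ok] / scl[ok])
  structure(list(subset = subset, features = colnames(X),
                 intercept = unname(intercept), coefficients = coefs,
                 feature_sd = scl,
                 n = nrow(X), ridge = ridge),
            class = "subset_model")
}

as_binary <- function(labels) {
  if (is.character(labels) || is.factor(labels)) {
    l <- as.character(labels)
    if (all(l %in% c("low", "high"))) return(as.integer(l == "high"))
    f <- factor(l)
    return(as.integer(f) - 1L)
  }
  as.integer(as.logical(labels))
}

#' @export
print.subset_model <- function(x, ...) {
  cat(sprintf("<subset_model %s> %d features, n = %d\n",
              x$subset, length(x$features), x$n))
  invisible(x)
}

#' Predicted probability of the high-enrichment class
#'
#' @param object a `subset_model`.
#' @param newdata samples x features matrix containing the model's
#'   features (by name).
#' @param ... unused.
#' @return probabilities in (0, 1).
#' @export
predict.subset_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata)[, object$features, drop = FALSE]
  plogis(drop(object$intercept + X %*% object$coefficients))
}

#' Leave-one-out cross-validation of a subset model
#'
#' Refits the model `n` times, each excluding one sample, and scores the
#' held-out probabilities: accuracy at threshold 0.5 and rank-based
#' (Mann-Whitney) AUC with 0.5 credit for ties. Folds whose training
#' labels collapse to a single class are skipped with a warning.
#'
#' @inheritParams fit_subset_model
#' @return a `loocv_result`: accuracy, auc and per-sample predictions.
#' @export
loocv <- function(features, labels, subset = NA_character_, ridge = 1e-6) {
  X <- as.matrix(features)
  y <- as_binary(labels)
  n <- nrow(X)
  if (n < 3) stop("LOOCV needs at least 3 samples")
  prob <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    ytr <- y[-i]
    if (length(unique(ytr)) < 2) {
      warning("fold ", i, " skipped: single-class training labels")
      next
    }
    fit <- fit_subset_model(X[-i, , drop = FALSE], ytr, subset, ridge)
    prob[i] <- predict(fit, X[i, , drop = FALSE])
  }
  ok <- !is.na(prob)
  acc <- mean((prob[ok] > 0.5) == (y[ok] == 1))
  auc <- rank_auc(prob[ok], y[ok])
  structure(list(subset = subset, accuracy = acc, auc = auc,
                 predictions = data.frame(sample = rownames(X) %||% seq_len(n),
                                          label = y, probability = prob),
                 n = n, n_scored = sum(ok)),
            class = "loocv_result")
}

# Rank-based AUC (probability a positive outranks a negative; ties 0.5).
rank_auc <- function(scores, y) {
  pos <- scores[y == 1]
  neg <- scores[y == 0]
  if (!length(pos) || !length(neg)) return(NA_real_)
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

#' Per-feature chi-squared significance and importance ratios
#'
#' For each feature, a likelihood-ratio chi-squared statistic (1 df)
#' compares the full model with a refit dropping that feature. The
#' importance ratio is the feature's absolute standardized coefficient
#' divided by the model total (ratios sum to 1).
#'
#' @param model a fitted `subset_model`.
#' @param features,labels the training data.
#' @return data frame: feature, chisq, p_value, importance_ratio.
#' @export
feature_significance <- function(model, features, labels) {
  X <- as.matrix(features)[, model$features, drop = FALSE]
  y <- as_binary(labels)
  ll <- function(fit, Xs) {
    p <- predict(fit, Xs)
    sum(y * log(p) + (1 - y) * log(1 - p))
  }
  ll_full <- ll(model, X)
  std <- abs(model$coefficients) * model$feature_sd
  ratio <- if (sum(std) > 0) std / sum(std) else rep(1 / length(std), length(std))
  res <- lapply(seq_along(model$features), function(j) {
    Xr <- X[, -j, drop = FALSE]
    fit_r <- if (ncol(Xr) == 0) {
      fit_subset_model(matrix(0, nrow(X), 0, dimnames = list(NULL, NULL)), y,
                       model$subset, model$ridge)
    } else fit_subset_model(Xr, y, model$subset, model$ridge)
    stat <- max(0, 2 * (ll_full - ll(fit_r, Xr)))
    data.frame(feature = model$features[j], chisq = stat,
               p_value = pchisq(stat, df = 1, lower.tail = FALSE),
               importance_ratio = ratio[j], stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Predict phenotype groups from the four subset models
#'
#' Each subset probability is thresholded at 0.5 into a high/low level;
#' the level quadruple maps to a group with [map_levels_to_group()].
#' Samples with missing feature values are skipped with a logged reason.
#'
#' @param models named list of four `subset_model`s (CTL, aDC, Treg,
#'   MDSC).
#' @param features samples x features matrix covering all model features.
#' @return data frame: sample_id, per-subset probability and level,
#'   group, source = `"rule_mapped"`, rule_fired; skipped samples carry
#'   NA group and the reason.
#' @export
predict_groups <- function(models, features) {
  stopifnot(all(SUBSETS %in% names(models)))
  X <- as.matrix(features)
  need <- unique(unlist(lapply(models[SUBSETS], `[[`, "features")))
  miss_col <- setdiff(need, colnames(X))
  if (length(miss_col)) stop("missing feature columns: ",
                             paste(head(miss_col, 5), collapse = ", "))
  out <- data.frame(sample_id = rownames(X) %||% seq_len(nrow(X)),
                    stringsAsFactors = FALSE)
  probs <- sapply(SUBSETS, function(s) predict(models[[s]], X))
  probs <- matrix(probs, nrow = nrow(X),
                  dimnames = list(out$sample_id, SUBSETS))
  lv <- ifelse(probs > 0.5, "high", "low")
  incomplete <- apply(X[, need, drop = FALSE], 1, anyNA)
  for (s in SUBSETS) {
    out[[paste0(tolower(s), "_prob")]] <- probs[, s]
    out[[paste0(tolower(s), "_level")]] <- lv[, s]
  }
  lv_filled <- lv
  lv_filled[is.na(lv_filled)] <- "low"  # placeholder; skipped rows get NA group
  mp <- map_levels_to_group(lv_filled)
  out$group <- ifelse(incomplete, NA_character_, mp$group)
  out$source <- "rule_mapped"
  out$rule_fired <- ifelse(incomplete, "skipped:missing_feature_value",
                           mp$rule_fired)
  out
}

#' Serialize / restore subset models as JSON
#'
#' @param models named list of `subset_model`s.
#' @param path JSON file.
#' @export
write_models_json <- function(models, path) {
  payload <- lapply(models, function(m)
    list(subset = m$subset, features = as.list(m$features),
         intercept = m$intercept,
         coefficients = as.list(m$coefficients),
         feature_sd = as.list(m$feature_sd), n = m$n, ridge = m$ridge))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_models_json
#' @export
read_models_json <- function(path) {
  payload <- jsonlite::read_json(path)
  lapply(payload, function(m) {
    structure(list(subset = m$subset,
                   features = unlist(m$features),
                   intercept = m$intercept,
                   coefficients = setNames(unlist(m$coefficients),
                                           unlist(m$features)),
                   feature_sd = setNames(unlist(m$feature_sd),
                                         unlist(m$features)),
                   n = m$n, ridge = m$ridge),
              class = "subset_model")
  })
}
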