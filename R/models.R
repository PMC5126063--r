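#' Shapiro-Wilk normality check
#'
#' Thin wrapper used for reporting only (never as a gate in the modelling
#' chain).
#'
#' @param values numeric vector, 3 <= n <= 5000, non-constant.
#' @return list with `statistic` and `p_value`.
#' @export
normality_check <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 3) stop("need at least 3 observations")
  if (stats::sd(values) == 0) stop("constant input: normality undefined")
  sw <- stats::shapiro.test(values)
  list(statistic = unname(sw$statistic), p_value = sw$p.value)
}

#' Univariate predictor screen
#'
#' One ordinary least-squares fit of the outcome on each predictor;
#' predictors with slope p-value at or below `alpha` form the selected set
#' carried into the multivariate model. Constant predictors are skipped with
#' a warning.
#'
#' @param outcome numeric outcome vector (CI-OCS).
#' @param X data.frame of candidate predictors.
#' @param alpha selection threshold (default 0.05).
#' @return list with `table` (predictor, beta, p) and `selected`.
#' @export
univariate_screen <- function(outcome, X, alpha = 0.05) {
  if (length(outcome) <= 2) stop("need n > 2")
  if (stats::sd(outcome) == 0) {
    warning("degenerate fit: constant outcome; no predictor selected")
    return(list(table = data.frame(predictor = names(X), beta = NA_real_,
                                   p = NA_real_), selected = character(0)))
  }
  rows <- lapply(names(X), function(nm) {
    x <- X[[nm]]
    if (stats::sd(x) == 0) {
      warning("skipping constant predictor: ", nm)
      return(data.frame(predictor = nm, beta = NA_real_, p = NA_real_))
    }
    co <- summary(stats::lm(outcome ~ x))$coefficients
    data.frame(predictor = nm, beta = co[2, 1], p = co[2, 4])
  })
  tab <- do.call(rbind, rows)
  list(table = tab,
       selected = tab$predictor[!is.na(tab$p) & tab$p <= alpha])
}

# Columns involved in an (almost) linearly dependent set, for error messages.
collinear_members <- function(X) {
  M <- cbind(`(Intercept)` = 1, as.matrix(X))
  q <- qr(M)
  if (q$rank == ncol(M)) return(character(0))
  setdiff(colnames(M)[q$pivot[(q$rank + 1):ncol(M)]], "(Intercept)")
}

#' Multivariate linear regression with backward elimination
#'
#' Starting from the selected predictor set, iteratively refits the model
#' and removes the predictor with the largest partial-t p-value while any
#' exceeds `alpha`. Exact p ties are broken by removing the alphabetically
#' later column name, making the procedure independent of input column
#' order. Errors if the predictor matrix is numerically collinear
#' (condition number above 1e10), naming the offending columns.
#'
#' @param outcome numeric outcome vector.
#' @param X data.frame of selected predictors (nonempty).
#' @param alpha retention threshold (default 0.05).
#' @return list of class `backward_fit`: `model` (the final `lm`),
#'   `coefficients` (beta, p per retained predictor), `adjusted_r2`,
#'   `r_squared`, `retained`, `removed` (in removal order).
#' @export
backward_eliminate <- function(outcome, X, alpha = 0.05) {
  if (!ncol(X)) stop("selected predictor set is empty")
  if (length(outcome) <= ncol(X) + 2) stop("need n > predictors + 2")
  Z <- scale(as.matrix(X))
  kap <- kappa(cbind(1, Z[, apply(Z, 2, function(c) all(is.finite(c))),
                          drop = FALSE]), exact = TRUE)
  if (kap > 1e10)
    stop("collinear predictor columns: ",
         paste(collinear_members(X), collapse = ", "))
  sel <- names(X)
  removed <- character(0)
  repeat {
    dat <- X[sel]
    dat$.outcome <- outcome
    fit <- stats::lm(.outcome ~ ., data = dat)
    co <- summary(fit)$coefficients
    rn <- setdiff(rownames(co), "(Intercept)")
    pv <- co[rn, 4]
    names(pv) <- sub("^`(.*)`$", "\\1", rn)
    if (all(pv <= alpha) || length(sel) == 0) break
    worst <- max(pv)
    cand <- sort(names(pv)[abs(pv - worst) < 1e-15])
    drop_nm <- cand[length(cand)]           # later alphabetically on ties
    sel <- setdiff(sel, drop_nm)
    removed <- c(removed, drop_nm)
    if (!length(sel)) {
      fit <- stats::lm(outcome ~ 1)
      pv <- numeric(0)
      break
    }
  }
  sm <- summary(fit)
  coefs <- if (length(sel)) {
    co <- summary(fit)$coefficients
    rn <- setdiff(rownames(co), "(Intercept)")
    data.frame(predictor = sub("^`(.*)`$", "\\1", rn),
               beta = co[rn, 1], p = co[rn, 4], row.names = NULL)
  } else data.frame(predictor = character(0), beta = numeric(0), p = numeric(0))
  structure(list(model = fit, coefficients = coefs,
                 adjusted_r2 = sm$adj.r.squared, r_squared = sm$r.squared,
                 retained = sel, removed = removed, alpha = alpha),
            class = "backward_fit")
}

# R^2 of outcome on a subset of (centred) predictor columns, by direct solve.
subset_r2 <- function(xty, xtx, yty, cols) {
  if (!length(cols)) return(0)
  b <- solve(xtx[cols, cols, drop = FALSE], xty[cols])
  drop(crossprod(xty[cols], b)) / yty
}

#' LMG relative-importance decomposition (exact)
#'
#' Decomposes the model R-squared over predictors by the LMG method: each
#' predictor's share is the average, over all orderings of the predictors,
#' of the increase in R-squared when it enters. Computed exactly by
#' enumeration over all subsets with the combinatorial weights
#' `|S|! (p - |S| - 1)! / p!`. Shares are reported on the outcome-variance
#' percentage scale (non-normalised), so they sum to 100 times the model
#' R-squared — not to 100.
#'
#' @param outcome numeric outcome vector.
#' @param X data.frame of the final model's predictors (at most 12).
#' @return named numeric vector of shares (percent of outcome variance);
#'   attribute `r_squared` carries the full-model R-squared.
#' @export
lmg_decomposition <- function(outcome, X) {
  p <- ncol(X)
  if (p > 12)
    stop("more than 12 predictors: exact enumeration not attempted ",
         "(a sampling approximation is out of scope)")
  y <- outcome - mean(outcome)
  M <- scale(as.matrix(X), scale = FALSE)
  if (p > 1 && kappa(scale(M), exact = TRUE) > 1e10)
    stop("collinear predictor columns in LMG decomposition: ",
         paste(collinear_members(X), collapse = ", "))
  xtx <- crossprod(M)
  xty <- drop(crossprod(M, y))
  yty <- drop(crossprod(y))
  subsets <- expand.grid(rep(list(c(FALSE, TRUE)), p))
  r2 <- apply(subsets, 1, function(s) subset_r2(xty, xtx, yty, which(s)))
  lf <- lfactorial(0:p)
  shares <- numeric(p)
  for (j in seq_len(p)) {
    without_j <- !subsets[[j]]
    for (i in which(without_j)) {
      s <- which(unlist(subsets[i, ]))
      k <- length(s)
      w <- exp(lf[k + 1] + lf[p - k] - lf[p + 1])
      i_with <- i + 2^(j - 1)
      shares[j] <- shares[j] + w * (r2[i_with] - r2[i])
    }
  }
  names(shares) <- names(X)
  out <- 100 * shares
  attr(out, "r_squared") <- r2[length(r2)]
  out
}

#' Confounder check by explained-variance comparison
#'
#' For each key predictor, compares its explained-variance share in a
#' predictor-only model (its R-squared) with its LMG share in a model adding
#' the confounders, and reports the difference. The predictor is flagged
#' "not confounded" when the absolute change is below `tolerance` times the
#' unadjusted share.
#'
#' @param outcome numeric outcome vector.
#' @param X data.frame containing the predictors and confounders.
#' @param predictors character vector of key predictor names.
#' @param confounders character vector of confounder names (default age,
#'   sex, education).
#' @param tolerance relative change below which "no confounding" is declared
#'   (default 0.2).
#' @return data.frame with `predictor`, `share_unadjusted`,
#'   `share_adjusted` (both percent of outcome variance), `delta`, and
#'   `confounded`.
#' @export
confound_check <- function(outcome, X, predictors,
                           confounders = c("age", "sex", "education_years"),
                           tolerance = 0.2) {
  confounders <- intersect(confounders, names(X))
  rows <- lapply(predictors, function(nm) {
    conf <- setdiff(confounders, nm)   # a predictor cannot confound itself
    share0 <- 100 * summary(stats::lm(outcome ~ X[[nm]]))$r.squared
    lmg <- lmg_decomposition(outcome, X[c(nm, conf)])
    share1 <- unname(lmg[nm])
    data.frame(predictor = nm, share_unadjusted = share0,
               share_adjusted = share1, delta = share1 - share0,
               confounded = abs(share1 - share0) >= tolerance * share0)
  })
  do.call(rbind, rows)
}

#' ROC analysis of a prognostic marker
#'
#' Empirical ROC curve of a continuous marker against a dichotomous outcome
#' (higher marker values indicate the positive class), with trapezoidal AUC
#' and the Youden-optimal operating point; exact ties in Youden's J are
#' resolved toward higher specificity. Computed with the pROC package with
#' the marker direction held fixed, so AUC is invariant under strictly
#' monotone marker transforms and `AUC(marker) + AUC(-marker) = 1`.
#'
#' @param marker numeric marker values.
#' @param outcome logical or 0/1 vector; `TRUE`/1 is the positive
#'   (impaired) class.
#' @return list of class `roc_summary`: `auc`, `sensitivity`, `specificity`,
#'   `threshold`, and the underlying `pROC::roc` object in `roc`.
#' @export
roc_analysis <- function(marker, outcome) {
  outcome <- as.integer(outcome)
  if (length(unique(outcome)) < 2) stop("both outcome classes must be present")
  r <- pROC::roc(response = outcome, predictor = marker,
                 levels = c(0, 1), direction = "<", quiet = TRUE)
  cc <- pROC::coords(r, "all", ret = c("threshold", "sensitivity",
                                       "specificity"), transpose = FALSE)
  j <- cc$sensitivity + cc$specificity - 1
  best <- which(abs(j - max(j)) < 1e-12)
  best <- best[which.max(cc$specificity[best])]
  structure(list(auc = as.numeric(pROC::auc(r)),
                 sensitivity = cc$sensitivity[best],
                 specificity = cc$specificity[best],
                 threshold = cc$threshold[best],
                 roc = r),
            class = "roc_summary")
}

#' @export
print.roc_summary <- function(x, ...) {
  cat(sprintf("<roc_summary> AUC = %.3f; Youden point: sens = %.3f, spec = %.3f at %.4g\n",
              x$auc, x$sensitivity, x$specificity, x$threshold))
  invisible(x)
}

#' Random-forest importances (regression)
#'
#' Fits a regression random forest and reports the two standard importance
#' measures: MDA, the mean increase in out-of-bag prediction error when a
#' predictor is permuted (the `%IncMSE` score, normalised by its standard
#' error as conventionally printed), and MDGC, the total node-impurity
#' (residual sum of squares) decrease attributed to the predictor summed
#' over all splits and trees — the regression analogue of the Gini
#' importance.
#'
#' @param outcome numeric outcome vector (n >= 20, non-constant).
#' @param X data.frame of predictors.
#' @param n_trees number of trees (default 500).
#' @param seed integer seed; results are seed-deterministic.
#' @param scale_mda normalise the permutation importance by its standard
#'   error (default TRUE, as conventionally reported).
#' @return data.frame with `predictor`, `mda`, `mdgc`.
#' @export
rf_importance <- function(outcome, X, n_trees = 500, seed = 1,
                          scale_mda = TRUE) {
  if (length(outcome) < 20) stop("need n >= 20")
  if (stats::sd(outcome) == 0) stop("constant outcome")
  set.seed(as.integer(seed))
  rf <- randomForest::randomForest(x = X, y = outcome, ntree = n_trees,
                                   importance = TRUE)
  imp <- randomForest::importance(rf, scale = scale_mda)
  data.frame(predictor = rownames(imp),
             mda = unname(imp[, "%IncMSE"]),
             mdgc = unname(imp[, "IncNodePurity"]),
             row.names = NULL)
}

#' Assemble the baseline predictor matrix
#'
#' Binds the qEEG features, cognitive domain scores and clinical covariates
#' into the candidate predictor matrix of the prognostic chain, keeping
#' complete cases only (dropped rows are reported in a message). Column
#' provenance (qEEG / cognitive / clinical) is stored in the
#' `"provenance"` attribute.
#'
#' @param features per-subject qEEG features (`grmp_*`, `occipital_mf_hz`).
#' @param domains per-subject baseline domain scores (six columns).
#' @param clinical per-subject clinical covariates (age, sex,
#'   education_years, disease_duration_years, observation_years, ledd,
#'   updrs3 — whichever are present are used).
#' @return data.frame of predictors with attribute `provenance`.
#' @export
build_predictors <- function(features, domains, clinical) {
  fcols <- intersect(c("grmp_delta", "grmp_theta", "grmp_alpha1",
                       "grmp_alpha2", "grmp_beta", "occipital_mf_hz"),
                     names(features))
  dcols <- intersect(c("attention", "executive", "fluency",
                       "long_term_memory", "working_memory", "visuospatial"),
                     names(domains))
  ccols <- intersect(c("age", "sex", "education_years",
                       "disease_duration_years", "observation_years",
                       "ledd", "updrs3"), names(clinical))
  X <- cbind(features[fcols], domains[dcols], clinical[ccols])
  keep <- stats::complete.cases(X)
  if (!all(keep)) message(sum(!keep), " row(s) dropped (incomplete cases)")
  X <- X[keep, , drop = FALSE]
  attr(X, "provenance") <- c(stats::setNames(rep("qEEG", length(fcols)), fcols),
                             stats::setNames(rep("cognitive", length(dcols)), dcols),
                             stats::setNames(rep("clinical", length(ccols)), ccols))
  attr(X, "kept") <- which(keep)
  X
}

#' Fit the full prognostic model chain
#'
#' The package's central fit: given baseline predictors and the CI-OCS
#' outcome, runs (1) a Shapiro-Wilk report on the outcome, (2) the
#' univariate screen at `alpha`, (3) multivariate backward elimination on
#' the screened set (pre-dropping the weakest members of any numerically
#' collinear screened subset, as happens when all five compositional band
#' fractions are screened in together), (4) the exact LMG explained-variance
#' decomposition of the final model, (5) a confounder check of every
#' retained predictor against age, sex and education, (6) ROC analysis of
#' each retained predictor against a dichotomised follow-up MMSE (< 24)
#' when supplied, and (7) random-forest importances over the full candidate
#' set.
#'
#' @param X candidate predictor data.frame (see [build_predictors()]).
#' @param ci_ocs numeric outcome vector (change index of the overall
#'   cognitive score).
#' @param mmse_followup optional integer vector of follow-up MMSE scores for
#'   the ROC stage (dichotomised at `mmse_cutoff`).
#' @param alpha screening/elimination threshold (default 0.05).
#' @param mmse_cutoff MMSE dichotomisation cut-off (default 24: scores
#'   below 24 form the impaired class).
#' @param n_trees random-forest size (default 500).
#' @param seed seed for the random-forest stage.
#' @param confounders confounder names for the confounding check.
#' @return object of class `prognosis_fit`.
#' @export
fit_prognosis <- function(X, ci_ocs, mmse_followup = NULL, alpha = 0.05,
                          mmse_cutoff = 24, n_trees = 500, seed = 1,
                          confounders = c("age", "sex", "education_years")) {
  stopifnot(nrow(X) == length(ci_ocs))
  normality <- tryCatch(normality_check(ci_ocs), error = function(e) NULL)
  screen <- univariate_screen(ci_ocs, X, alpha = alpha)
  sel <- screen$selected
  dropped_collinear <- character(0)
  if (length(sel) > 1) {
    ptab <- stats::setNames(screen$table$p, screen$table$predictor)
    while (length(sel) > 1 &&
           kappa(cbind(1, scale(as.matrix(X[sel]))), exact = TRUE) > 1e10) {
      weakest <- sel[which.max(ptab[sel])]
      sel <- setdiff(sel, weakest)
      dropped_collinear <- c(dropped_collinear, weakest)
    }
  }
  final <- if (length(sel)) backward_eliminate(ci_ocs, X[sel], alpha = alpha)
           else NULL
  lmg <- if (!is.null(final) && length(final$retained))
    lmg_decomposition(ci_ocs, X[final$retained]) else NULL
  confounds <- if (!is.null(final) && length(final$retained))
    confound_check(ci_ocs, X, final$retained, confounders = confounders)
    else NULL
  roc <- NULL
  if (!is.null(mmse_followup) && !is.null(final) && length(final$retained)) {
    impaired <- mmse_followup < mmse_cutoff
    if (length(unique(impaired)) == 2) {
      roc <- lapply(final$retained, function(nm) {
        prov <- attr(X, "provenance")[nm]
        mk <- X[[nm]]
        # impairment direction: more theta / slower EEG is worse, better
        # cognition is protective -> orient marker so higher = impaired
        if (!is.na(prov) && prov == "cognitive") mk <- -mk
        if (nm %in% c("occipital_mf_hz", "grmp_alpha1", "grmp_alpha2",
                      "grmp_beta")) mk <- -mk
        roc_analysis(mk, impaired)
      })
      names(roc) <- final$retained
    }
  }
  rf <- tryCatch(rf_importance(ci_ocs, X, n_trees = n_trees, seed = seed),
                 error = function(e) NULL)
  structure(list(normality = normality, univariate = screen$table,
                 screened = screen$selected,
                 dropped_collinear = dropped_collinear,
                 final = final, lmg = lmg, confounds = confounds,
                 roc = roc, rf = rf, alpha = alpha, n = nrow(X),
                 outcome = ci_ocs, X = X),
            class = "prognosis_fit")
}

#' @export
print.prognosis_fit <- function(x, ...) {
  cat(sprintf("<prognosis_fit> n = %d, alpha = %g\n", x$n, x$alpha))
  if (is.null(x$final) || !length(x$final$retained)) {
    cat("  no predictor survived the univariate screen\n")
    return(invisible(x))
  }
  cat(sprintf("  final model (adj R^2 = %.3f, explained variance = %.1f%%):\n",
              x$final$adjusted_r2, 100 * x$final$r_squared))
  co <- x$final$coefficients
  for (i in seq_len(nrow(co)))
    cat(sprintf("    %-22s beta = %8.3f  p = %.4g  LMG = %5.1f%%\n",
                co$predictor[i], co$beta[i], co$p[i],
                unname(x$lmg[co$predictor[i]])))
  if (!is.null(x$roc)) {
    best <- which.max(vapply(x$roc, function(r) r$auc, 0))
    r <- x$roc[[best]]
    cat(sprintf("  best ROC marker: %s (AUC = %.1f%%, sens = %.0f%%, spec = %.0f%%)\n",
                names(x$roc)[best], 100 * r$auc, 100 * r$sensitivity,
                100 * r$specificity))
  }
  invisible(x)
}

#' @export
summary.prognosis_fit <- function(object, ...) {
  print(object)
  cat("\nUnivariate screen:\n")
  tab <- object$univariate
  tab$selected <- tab$predictor %in% object$screened
  print(tab, digits = 3)
  if (!is.null(object$confounds)) {
    cat("\nConfounder check (explained variance, % of outcome variance):\n")
    print(object$confounds, digits = 3)
  }
  if (!is.null(object$rf)) {
    cat("\nRandom-forest importances (top 5 by MDA):\n")
    print(utils::head(object$rf[order(-object$rf$mda), ], 5), digits = 3)
  }
  invisible(object)
}

#' @export
coef.prognosis_fit <- function(object, ...) {
  if (is.null(object$final)) return(numeric(0))
  stats::coef(object$final$model)
}

#' @export
predict.prognosis_fit <- function(object, newdata = NULL, ...) {
  if (is.null(object$final)) stop("no final model to predict from")
  if (is.null(newdata)) return(stats::fitted(object$final$model))
  stats::predict(object$final$model, newdata = newdata, ...)
}

#' @export
residuals.prognosis_fit <- function(object, ...) {
  if (is.null(object$final)) stop("no final model")
  stats::residuals(object$final$model)
}

#' Plot a prognostic fit
#'
#' Bar chart of the non-normalised LMG explained-variance shares and, when
#' available, the ROC curve of the best marker.
#'
#' @param x a `prognosis_fit`.
#' @param which `"lmg"`, `"roc"` or `"both"`.
#' @param ... ignored.
#' @export
plot.prognosis_fit <- function(x, which = "both", ...) {
  if (is.null(x$final) || !length(x$final$retained)) {
    warning("nothing to plot: empty final model")
    return(invisible(x))
  }
  do_lmg <- which %in% c("lmg", "both")
  do_roc <- which %in% c("roc", "both") && !is.null(x$roc)
  if (do_lmg && do_roc) {
    op <- graphics::par(mfrow = c(1, 2))
    on.exit(graphics::par(op))
  }
  if (do_lmg)
    graphics::barplot(sort(x$lmg, decreasing = TRUE),
                      ylab = "explained variance (% of outcome variance)",
                      main = sprintf("LMG shares (sum = %.1f%%)", sum(x$lmg)),
                      las = 2)
  if (do_roc) {
    best <- which.max(vapply(x$roc, function(r) r$auc, 0))
    plot(x$roc[[best]]$roc, main = sprintf("ROC: %s (AUC = %.1f%%)",
                                           names(x$roc)[best],
                                           100 * x$roc[[best]]$auc))
  }
  invisible(x)
}
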