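#' Normative z-scoring of raw test scores
#'
#' Converts raw scores to z-scores against a normative table:
#' `z = (raw - mean) / sd` for higher-is-better tests and
#' `z = -(raw - mean) / sd` for lower-is-better tests (times, errors,
#' omissions, ratio scores), so that higher z always means better
#' performance.
#'
#' @param raw data.frame of raw scores; test columns are matched by name
#'   against `norms$test` (non-test columns are ignored).
#' @param norms normative table from [generate_norms()] (columns `test`,
#'   `norm_mean`, `norm_sd`, `direction`).
#' @param tests which tests to score (default: all tests in `norms`).
#' @return data.frame of z-scores, one column per test.
#' @export
normalize_to_norms <- function(raw, norms, tests = norms$test) {
  missing_norm <- setdiff(tests, norms$test)
  if (length(missing_norm))
    stop("no normative row for test(s): ", paste(missing_norm, collapse = ", "))
  missing_col <- setdiff(tests, names(raw))
  if (length(missing_col))
    stop("raw table is missing test column(s): ",
         paste(missing_col, collapse = ", "))
  if (any(norms$norm_sd[norms$test %in% tests] <= 0))
    stop("normative SD must be > 0")
  z <- sapply(tests, function(tn) {
    i <- match(tn, norms$test)
    sgn <- if (norms$direction[i] == "lower") -1 else 1
    sgn * (raw[[tn]] - norms$norm_mean[i]) / norms$norm_sd[i]
  })
  as.data.frame(z, optional = TRUE)
}

#' Domain scores and the overall cognitive score
#'
#' Each of the six domain scores is the arithmetic mean of its member tests'
#' z-scores; the overall cognitive score (OCS) is the unweighted mean of all
#' 14 test z-scores (not the mean of the six domain means). Subjects with
#' any missing test are dropped with a message.
#'
#' @param z data.frame of z-scores (columns named as in
#'   [cognitive_battery()]).
#' @param battery test-to-domain mapping (default [cognitive_battery()]).
#' @return data.frame with the six domain scores, `ocs`, and a `kept`
#'   attribute of retained row indices.
#' @export
domain_and_overall_scores <- function(z, battery = cognitive_battery()) {
  missing_col <- setdiff(battery$test, names(z))
  if (length(missing_col))
    stop("missing test column(s): ", paste(missing_col, collapse = ", "))
  zm <- as.matrix(z[, battery$test, drop = FALSE])
  keep <- stats::complete.cases(zm)
  if (!all(keep))
    message(sum(!keep), " subject(s) dropped for missing test scores")
  zm <- zm[keep, , drop = FALSE]
  doms <- unique(battery$domain)
  out <- as.data.frame(
    matrix(vapply(doms, function(d) {
      rowMeans(zm[, battery$test[battery$domain == d], drop = FALSE])
    }, numeric(nrow(zm))), nrow = nrow(zm), dimnames = list(NULL, doms)))
  out$ocs <- rowMeans(zm)
  attr(out, "kept") <- which(keep)
  out
}

#' Change index of the overall cognitive score (CI-OCS)
#'
#' The paired OCS change between follow-up and baseline divided by the
#' standard error of the difference, estimated as the cohort SD of the
#' paired differences (default). Alternatively, the Jacobson-Truax
#' `sqrt(2) * SEM` variant is available when a test-retest reliability is
#' supplied.
#'
#' @param ocs_baseline,ocs_followup numeric vectors of per-subject overall
#'   cognitive scores at the two visits (>= 4 subjects).
#' @param reliability optional test-retest correlation; when given, the
#'   standard error of the difference is
#'   `sqrt(2) * sd(ocs_baseline) * sqrt(1 - reliability)`.
#' @return list of class `change_index`: `ci_ocs` (per subject) and
#'   `se_diff`.
#' @export
change_index <- function(ocs_baseline, ocs_followup, reliability = NULL) {
  if (length(ocs_baseline) != length(ocs_followup))
    stop("both visits must cover the same subjects")
  if (length(ocs_baseline) < 4) stop("need at least 4 subjects")
  d <- ocs_followup - ocs_baseline
  se <- if (is.null(reliability)) {
    stats::sd(d)
  } else {
    sqrt(2) * stats::sd(ocs_baseline) * sqrt(1 - reliability)
  }
  if (!is.finite(se) || se <= 0)
    stop("zero variance of paired differences; change index undefined")
  structure(list(ci_ocs = d / se, se_diff = se), class = "change_index")
}

#' @export
print.change_index <- function(x, ...) {
  cat(sprintf("<change_index> n = %d, se_diff = %.4f\n",
              length(x$ci_ocs), x$se_diff))
  print(summary(x$ci_ocs))
  invisible(x)
}

#' Cognitive profiles and outcome for a two-visit cohort
#'
#' Normative z-scoring, domain/overall scores at both visits, and the
#' change index, in one call.
#'
#' @param baseline,followup raw tables carrying the 14 test columns.
#' @param norms normative table (default [generate_norms()]).
#' @return list with `baseline`, `followup` (domain scores + `ocs`) and
#'   `change` (a [change_index()]).
#' @export
cognitive_profiles <- function(baseline, followup, norms = generate_norms()) {
  zb <- normalize_to_norms(baseline, norms)
  zf <- normalize_to_norms(followup, norms)
  pb <- domain_and_overall_scores(zb)
  pf <- domain_and_overall_scores(zf)
  keep <- intersect(attr(pb, "kept"), attr(pf, "kept"))
  pb2 <- pb[match(keep, attr(pb, "kept")), , drop = FALSE]
  pf2 <- pf[match(keep, attr(pf, "kept")), , drop = FALSE]
  list(baseline = pb2, followup = pf2, kept = keep,
       change = change_index(pb2$ocs, pf2$ocs))
}
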