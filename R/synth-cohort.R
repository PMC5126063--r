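#' The 14-test neuropsychological battery and its six cognitive domains
#'
#' Built-in test-to-domain mapping with a direction flag per test:
#' `higher` means larger raw scores are better; `lower` marks time, error,
#' omission and ratio scores where smaller raw values are better (their sign
#' is flipped during z-scoring so that every aggregate is higher-is-better).
#' Domains: attention (3 tests), executive functions (3), fluency (2),
#' long-term memory (2), working memory (2), visuospatial functions (2).
#' "Divided attention: omissions" belongs to working memory in this battery.
#'
#' @return data.frame with columns `test`, `domain`, `direction`.
#' @export
cognitive_battery <- function() {
  data.frame(
    test = c("stroop_color_time", "tmt_a_time", "digit_span_backward",
             "tmt_ratio", "stroop_ratio", "wcst_errors",
             "phonemic_fluency", "semantic_fluency",
             "vl_delayed_recall", "vl_discrimination",
             "corsi_forward", "divided_attention_omissions",
             "block_design", "rey_figure_copy"),
    domain = c(rep("attention", 3), rep("executive", 3), rep("fluency", 2),
               rep("long_term_memory", 2), rep("working_memory", 2),
               rep("visuospatial", 2)),
    direction = c("lower", "lower", "higher",
                  "lower", "lower", "lower",
                  "higher", "higher",
                  "higher", "higher",
                  "higher", "lower",
                  "higher", "higher"),
    stringsAsFactors = FALSE
  )
}

# Built-in synthetic normative parameters (means/SDs on plausible raw scales).
# These emulate a healthy-control normative database; they are synthetic, not
# estimated from any real control sample.
norm_parameters <- function() {
  data.frame(
    test = cognitive_battery()$test,
    norm_mean = c(32, 38, 7, 2.3, 1.8, 15, 14, 22, 9, 13, 8.5, 2, 32, 33),
    norm_sd   = c(6, 12, 2, 0.7, 0.45, 8, 4.5, 5.5, 3, 2.5, 1.8, 1.5, 9, 3),
    stringsAsFactors = FALSE
  )
}

#' Generate a synthetic normative table for the cognitive battery
#'
#' Returns mean, SD and direction flag per requested test, emulating a
#' normative database of healthy controls. The table is deterministic; an
#' optional seed adds small jitter to the parameters for sensitivity studies.
#'
#' @param tests character vector of test names (default: the full battery).
#' @param jitter_seed optional integer; when given, means are jittered by 2%
#'   and SDs by 5% (log-normal), seed-deterministically.
#' @return data.frame with columns `test`, `norm_mean`, `norm_sd`, `direction`.
#' @export
generate_norms <- function(tests = cognitive_battery()$test, jitter_seed = NULL) {
  if (!length(tests)) stop("empty test list")
  base <- merge(norm_parameters(), cognitive_battery(), by = "test", sort = FALSE)
  unknown <- setdiff(tests, base$test)
  if (length(unknown)) stop("unknown test(s): ", paste(unknown, collapse = ", "))
  out <- base[match(tests, base$test), c("test", "norm_mean", "norm_sd", "direction")]
  if (!is.null(jitter_seed)) {
    set.seed(as.integer(jitter_seed))
    out$norm_mean <- out$norm_mean * exp(stats::rnorm(nrow(out), 0, 0.02))
    out$norm_sd <- out$norm_sd * exp(stats::rnorm(nrow(out), 0, 0.05))
  }
  rownames(out) <- NULL
  out
}

#' Specification for a synthetic two-visit cohort
#'
#' Declares the planted linear model of the cognitive outcome: the change
#' index of the overall cognitive score (CI-OCS) at follow-up is
#' `intercept + beta_theta * GRMP_theta + beta_exec * executive +
#' beta_wm * working_memory + e`, with `e ~ N(0, noise_sd^2)`. Default
#' coefficients are -3.16 (GRMP theta, fraction scale), 0.54 (executive
#' domain) and 0.19 (working memory), the planted effects the downstream
#' regression chain must recover. The default `noise_sd` (0.76) makes the
#' planted change index approximately unit-variance under the default
#' covariate distributions, consistent with its definition as a standardised
#' change score.
#'
#' @param n_subjects cohort size (>= 4).
#' @param beta_theta,beta_exec,beta_wm,intercept planted coefficients.
#' @param noise_sd SD of the outcome residual (> 0).
#' @param seed integer seed.
#' @return list of class `cohort_gen_spec`.
#' @export
cohort_gen_spec <- function(n_subjects = 37,
                            beta_theta = -3.16, beta_exec = 0.54,
                            beta_wm = 0.19, intercept = 0.3,
                            noise_sd = 0.76, seed = 1) {
  if (n_subjects < 4) stop("n_subjects must be >= 4")
  if (noise_sd <= 0) stop("noise_sd must be > 0")
  structure(list(n_subjects = as.integer(n_subjects), beta_theta = beta_theta,
                 beta_exec = beta_exec, beta_wm = beta_wm,
                 intercept = intercept, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "cohort_gen_spec")
}

#' Draw per-subject spectral features directly (without simulating EEG)
#'
#' Samples global relative median power fractions and occipital median
#' frequency from a logistic-normal model around typical PD-cohort medians
#' (delta/theta/alpha1/alpha2/beta near 24/20/20/14/22 percent of 1-30 Hz
#' power, MF near 8.7 Hz), with a latent "EEG slowing" factor that raises
#' delta/theta, lowers alpha/beta and lowers MF. Used by large-n
#' parameter-recovery studies where simulating full recordings per subject
#' would be pointless; the EEG-to-feature path is validated separately by the
#' spectral round-trip tests.
#'
#' @param n number of subjects.
#' @param seed integer seed.
#' @return data.frame with `grmp_delta` ... `grmp_beta` (fractions summing to
#'   1), `occipital_mf_hz`, and the latent `slowing` factor.
#' @export
simulate_spectral_features <- function(n, seed = 1) {
  set.seed(derive_seed(seed, 11L))
  s <- stats::rnorm(n)
  mu <- log(c(delta = 0.242, theta = 0.198, alpha1 = 0.198,
              alpha2 = 0.143, beta = 0.219))
  load <- c(0.30, 0.35, -0.20, -0.25, -0.15)
  U <- matrix(stats::rnorm(n * 5, 0, 0.22), n, 5) + outer(s, load)
  E <- exp(sweep(U, 2, mu, "+"))
  B <- E / rowSums(E)
  colnames(B) <- paste0("grmp_", names(mu))
  mf <- pmin(10.5, pmax(6.8, 8.7 - 0.45 * s + stats::rnorm(n, 0, 0.45)))
  out <- as.data.frame(B)
  out$occipital_mf_hz <- mf
  out$slowing <- s
  out
}

#' Generate a synthetic two-visit cohort with a planted outcome model
#'
#' Builds baseline and follow-up cognitive/clinical tables around the
#' supplied per-subject spectral features. Six domain scores are drawn with a
#' shared latent cognition factor (inter-domain correlation about 0.35)
#' mildly coupled to EEG slowing; per-test z-scores scatter around their
#' domain score with zero within-domain mean, so recomputed domain means
#' equal the planted ground truth. The follow-up overall cognitive score is
#' constructed so that the change index (paired change divided by the
#' cohort SD of changes) recovers the planted linear model. Clinical
#' covariates (age, sex, education, disease duration, LEDD, UPDRS-III, mood
#' scales, MMSE) are drawn within plausible ranges for a PD cohort.
#'
#' @param spec a [cohort_gen_spec()].
#' @param eeg_features data.frame with one row per subject containing at
#'   least `grmp_theta` (fraction scale); typically from
#'   [simulate_spectral_features()] or measured via [spectral_features()].
#' @return list with `baseline` and `followup` data.frames and a `truth` list
#'   (planted change index, domain ground truth, coefficients).
#' @export
generate_cohort <- function(spec, eeg_features) {
  stopifnot(inherits(spec, "cohort_gen_spec"))
  n <- spec$n_subjects
  if (nrow(eeg_features) != n)
    stop("alignment error: eeg_features must have one row per subject (",
         nrow(eeg_features), " rows for ", n, " subjects)")
  theta <- eeg_features$grmp_theta
  set.seed(derive_seed(spec$seed, 21L))

  # latent cognition, mildly (negatively) tied to EEG slowing via theta
  th_c <- if (stats::sd(theta) > 0) (theta - mean(theta)) / stats::sd(theta) else theta * 0
  g <- stats::rnorm(n, 0, 0.5) - 0.2 * th_c
  domains <- c("attention", "executive", "fluency", "long_term_memory",
               "working_memory", "visuospatial")
  D <- sapply(domains, function(d) g + stats::rnorm(n, -0.1, 0.68))

  battery <- cognitive_battery()
  norms <- generate_norms()

  # per-test baseline z: domain value + zero-mean within-domain scatter
  zb <- matrix(NA_real_, n, nrow(battery), dimnames = list(NULL, battery$test))
  for (d in domains) {
    member <- battery$test[battery$domain == d]
    k <- length(member)
    eps <- matrix(stats::rnorm(n * k, 0, 0.4), n, k)
    eps <- eps - rowMeans(eps)
    zb[, member] <- D[, d] + eps
  }
  ocs_bl <- rowMeans(zb)

  # planted outcome
  ci <- spec$intercept + spec$beta_theta * theta +
    spec$beta_exec * D[, "executive"] + spec$beta_wm * D[, "working_memory"] +
    stats::rnorm(n, 0, spec$noise_sd)
  se_target <- 0.15  # OCS-units scale of a paired change
  ocs_fu <- ocs_bl + ci * se_target

  zf <- zb + (ocs_fu - ocs_bl)
  for (d in domains) {
    member <- battery$test[battery$domain == d]
    k <- length(member)
    eps <- matrix(stats::rnorm(n * k, 0, 0.15), n, k)
    eps <- eps - rowMeans(eps)
    zf[, member] <- zf[, member] + eps
  }

  z_to_raw <- function(z) {
    raw <- z
    for (j in seq_len(ncol(z))) {
      i <- match(colnames(z)[j], norms$test)
      sgn <- if (norms$direction[i] == "lower") -1 else 1
      raw[, j] <- norms$norm_mean[i] + sgn * z[, j] * norms$norm_sd[i]
    }
    raw
  }

  clamp <- function(x, lo, hi) pmin(hi, pmax(lo, x))
  age <- clamp(stats::rnorm(n, 67, 9), 31, 84)
  sex <- stats::rbinom(n, 1, 25 / 37)  # 1 = male
  education <- clamp(round(stats::rnorm(n, 14, 3)), 9, 20)
  disease_duration <- clamp(stats::rnorm(n, 8, 4.5), 1, 20)
  obs_months <- clamp(round(stats::rnorm(n, 37, 3)), 30, 44)
  ledd <- clamp(exp(stats::rnorm(n, log(691), 0.5)), 150, 2129)
  updrs3 <- clamp(round(stats::rnorm(n, 14, 8)), 0, 50)
  bdi2 <- clamp(round(exp(stats::rnorm(n, log(6), 0.6))), 0, 15)
  oci <- clamp(round(exp(stats::rnorm(n, log(6), 0.7))), 0, 25)
  pdq39_ewb <- clamp(round(stats::rnorm(n, 17, 9)), 0, 50)
  mmse_bl <- clamp(round(30 - abs(stats::rnorm(n, 0, 1.6))), 24, 30)
  mmse_fu <- clamp(round(mmse_bl + 2.5 * ci - 1 + stats::rnorm(n, 0, 1)), 0, 30)

  subject_id <- sprintf("S%03d", seq_len(n))
  baseline <- data.frame(subject_id, age, sex, education_years = education,
                         disease_duration_years = disease_duration,
                         ledd, updrs3, bdi2, oci, pdq39_ewb, mmse = mmse_bl,
                         z_to_raw(zb), stringsAsFactors = FALSE)
  followup <- data.frame(subject_id, observation_months = obs_months,
                         mmse = mmse_fu, z_to_raw(zf), stringsAsFactors = FALSE)
  list(baseline = baseline, followup = followup,
       truth = list(ci_ocs = ci, domains = D, ocs_baseline = ocs_bl,
                    ocs_followup = ocs_fu,
                    betas = c(grmp_theta = spec$beta_theta,
                              executive = spec$beta_exec,
                              working_memory = spec$beta_wm),
                    intercept = spec$intercept))
}
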