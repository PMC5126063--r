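# Shared fixtures, built once per test run and cached.
.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixture_cache[[name]])) .fixture_cache[[name]] <- build()
  .fixture_cache[[name]]
}

# small artifact-free recording (24 ch, 60 s) used across spectral tests
clean_rec <- function(seed = 11) {
  fixture(paste0("clean_", seed), function() {
    generate_eeg(eeg_gen_spec(n_channels = 24, duration = 60,
                              blink_rate = 0, n_bad_channels = 0, seed = seed))
  })
}

# band power of a channel subset from the multitaper PSD
band_power <- function(rec, channels, lo, hi) {
  psd <- fixture(paste0("psd_", substr(digest_rec(rec), 1, 12)), function() {
    multitaper_psd(rec)
  })
  i <- match(channels, rec$channel_labels)
  sp <- colMeans(psd$power[i, , drop = FALSE])
  sum(sp[psd$freqs >= lo & psd$freqs < hi])
}

digest_rec <- function(rec) {
  paste0(nrow(rec$data), "x", ncol(rec$data), "_",
         format(sum(rec$data[1, seq_len(min(100, ncol(rec$data)))]), digits = 12))
}

# a synthetic psd_matrix with given per-channel spectra (uniform grid)
toy_psd <- function(power, freqs, roles = NULL) {
  if (is.null(roles)) roles <- rep("active", nrow(power))
  structure(list(power = power, freqs = freqs, epoch_count = 1L,
                 taper_count = 1L,
                 channel_labels = sprintf("E%03d", seq_len(nrow(power))),
                 roles = roles),
            class = "psd_matrix")
}

# feature + cohort pair at a given n, used by modelling tests
toy_cohort <- function(n = 200, seed = 1, ...) {
  feats <- simulate_spectral_features(n, seed = seed)
  co <- generate_cohort(cohort_gen_spec(n_subjects = n, seed = seed, ...), feats)
  list(features = feats, cohort = co)
}

# run screen + backward on a generated cohort, as the pipeline does
chain_fit <- function(n, seed, alpha = 0.05) {
  tc <- toy_cohort(n, seed)
  prof <- cognitive_profiles(tc$cohort$baseline, tc$cohort$followup)
  clin <- tc$cohort$baseline
  clin$observation_years <- tc$cohort$followup$observation_months / 12
  X <- build_predictors(tc$features, prof$baseline, clin)
  scr <- univariate_screen(prof$change$ci_ocs, X, alpha = alpha)
  sel <- scr$selected
  ptab <- stats::setNames(scr$table$p, scr$table$predictor)
  while (length(sel) > 1 &&
         kappa(cbind(1, scale(as.matrix(X[sel]))), exact = TRUE) > 1e10) {
    sel <- setdiff(sel, sel[which.max(ptab[sel])])
  }
  fin <- if (length(sel)) backward_eliminate(prof$change$ci_ocs, X[sel],
                                             alpha = alpha) else NULL
  list(X = X, ci = prof$change$ci_ocs, screen = scr, final = fin,
       truth = tc$cohort$truth)
}

# independent LMG oracle: average sequential R^2 gain over all orderings
lmg_bruteforce <- function(y, X) {
  p <- ncol(X)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) out <- c(out, lapply(perms(v[-i]), function(r) c(v[i], r)))
    out
  }
  r2 <- function(cols) if (!length(cols)) 0 else
    summary(lm(y ~ ., data = X[, cols, drop = FALSE]))$r.squared
  shares <- setNames(numeric(p), names(X))
  allp <- perms(names(X))
  for (ord in allp) {
    sofar <- character(0)
    for (nm in ord) {
      shares[nm] <- shares[nm] + r2(c(sofar, nm)) - r2(sofar)
      sofar <- c(sofar, nm)
    }
  }
  shares / length(allp)
}

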