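# Scaled-down speech-recognition-threshold evaluation harness:
# recognition result maps over a training-SNR x test-SNR grid with a
# diagonal-Gaussian per-word template classifier, interpolated SRTs,
# Plomp curves and psychometric segments.

# time-pooled feature statistics of a log-Mel matrix: per-channel mean and
# mean absolute frame-to-frame difference (delta statistics)
.pool_features <- function(lms) {
  v <- lms$values_db
  if (nrow(v) < 2) return(c(colMeans(v), rep(0, ncol(v))))
  c(colMeans(v), colMeans(abs(diff(v))))
}

# derive a per-utterance sub-seed (< 2^31) from a master seed
.sub_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 7919 + i * 104729) %% 2147000000)
}

#' Simulate a recognition result map
#'
#' Scaled-down analogue of an ASR-based speech-test simulation: for each
#' training SNR, noisy (optionally PLATT-processed) tokens of the training
#' split are turned into profile-degraded, time-pooled log-Mel feature
#' statistics and summarized into per-word diagonal-Gaussian templates;
#' tokens of the disjoint test split are then classified by maximum
#' likelihood at each test SNR. The result is the percentage of correctly
#' recognized words over the training-SNR x test-SNR grid. Everything
#' (masker realization, fragment choice, level-uncertainty draws) is
#' seeded and therefore reproducible.
#'
#' @param corpus A [synthetic_word_corpus()].
#' @param masker `"stationary"`, `"fluctuating"` or `"none"` (quiet).
#' @param masker_level_db_spl Masker presentation level in dB SPL.
#' @param profile A [listener_profile()], or a list of profiles to
#'   evaluate on the shared audio/feature pipeline (returns one map per
#'   profile).
#' @param processing `NULL` (unaided) or a [platt_config()]: every mixture
#'   is processed with [platt_process()] before feature extraction.
#' @param train_snrs_db,test_snrs_db SNR grids in dB (3 dB steps by
#'   default).
#' @param seed Master integer seed.
#' @param n_uncertainty_draws Independent level-uncertainty draws per test
#'   token (each classified separately), to raise the number of
#'   Monte-Carlo decisions per grid point without more audio.
#' @param var_floor Variance floor for degenerate template dimensions.
#' @return An object of class `recognition_map` (or a list of them, one
#'   per profile): list with `correct_pct` (matrix train x test),
#'   `train_snrs_db`, `test_snrs_db` and condition metadata.
#' @export
simulate_recognition_map <- function(corpus, masker = c("stationary",
                                                        "fluctuating",
                                                        "none"),
                                     masker_level_db_spl = 70,
                                     profile = listener_profile("P-8000-1"),
                                     processing = NULL,
                                     train_snrs_db = seq(-18, 0, 3),
                                     test_snrs_db = seq(-24, 3, 3),
                                     seed = 1, n_uncertainty_draws = 1,
                                     var_floor = 1e-3) {
  stopifnot(inherits(corpus, "platt_corpus"), corpus$n_words >= 2)
  masker <- match.arg(masker)
  profiles <- if (inherits(profile, "listener_profile")) list(profile)
              else profile
  stopifnot(all(vapply(profiles, inherits, logical(1),
                       "listener_profile")))
  fs <- corpus$sample_rate_hz
  fb <- if (!is.null(processing)) design_filterbank(fs) else NULL
  if (masker == "none") {
    train_snrs_db <- 0
    test_snrs_db <- 0
  }

  # disjoint train/test token split per word (alternating tokens)
  words <- vapply(corpus$tokens, `[[`, numeric(1), "word")
  is_train <- logical(length(words))
  for (w in unique(words)) {
    ix <- which(words == w)
    is_train[ix[seq_along(ix) %% 2 == 1]] <- TRUE
  }

  masker_sig <- switch(masker,
    stationary = speech_shaped_noise(masker_level_db_spl, 10,
                                     .sub_seed(seed, 1), fs),
    fluctuating = fluctuating_noise(masker_level_db_spl, 10,
                                    .sub_seed(seed, 2), fs),
    none = NULL)

  # log-Mel of one token at one SNR (shared across profiles)
  lms_of <- function(tok_idx, snr, tag) {
    sp <- corpus$tokens[[tok_idx]]$audio
    mix <- if (is.null(masker_sig)) sp else
      mix_at_snr(sp, masker_sig, snr, masker_level_db_spl,
                 seed = .sub_seed(seed, 1000 + tok_idx * 131 + tag))
    if (!is.null(processing)) {
      mix <- platt_process(mix, fs, processing, fb)
    }
    log_mel_spectrogram(mix, fs)
  }

  train_idx <- which(is_train)
  test_idx <- which(!is_train)
  train_words <- words[train_idx]
  test_words <- words[test_idx]
  uw <- sort(unique(words))

  # cache degraded pooled features: [[profile]][[snr]] -> matrix
  pooled <- function(lms_list, prof, seeds, draws) {
    out <- list()
    for (d in seq_len(draws)) {
      m <- t(vapply(seq_along(lms_list), function(i) {
        .pool_features(apply_listener_profile(lms_list[[i]], prof,
                                              seeds[i] + d))
      }, numeric(2 * sum(lms_list[[1]]$channel_freqs_hz <=
                           prof$limit_freq_hz))))
      out[[d]] <- m
    }
    out
  }

  train_lms <- lapply(seq_along(train_snrs_db), function(si) {
    lapply(train_idx, function(ti) lms_of(ti, train_snrs_db[si], si))
  })
  test_lms <- lapply(seq_along(test_snrs_db), function(si) {
    lapply(test_idx, function(ti) lms_of(ti, test_snrs_db[si], 100 + si))
  })

  results <- lapply(profiles, function(prof) {
    correct <- matrix(NA_real_, length(train_snrs_db),
                      length(test_snrs_db),
                      dimnames = list(train_snrs_db, test_snrs_db))
    for (si in seq_along(train_snrs_db)) {
      seeds_tr <- vapply(seq_along(train_idx), function(i) {
        .sub_seed(seed, 5e5 + si * 1000 + i)
      }, integer(1))
      feat_tr <- pooled(train_lms[[si]], prof, seeds_tr, 1)[[1]]
      mu <- t(vapply(uw, function(w) colMeans(feat_tr[train_words == w, ,
                                                      drop = FALSE]),
                     numeric(ncol(feat_tr))))
      s2 <- t(vapply(uw, function(w) {
        apply(feat_tr[train_words == w, , drop = FALSE], 2,
              function(x) max(stats::var(x), var_floor))
      }, numeric(ncol(feat_tr))))
      log_det <- 0.5 * rowSums(log(s2))
      for (ti in seq_along(test_snrs_db)) {
        seeds_te <- vapply(seq_along(test_idx), function(i) {
          .sub_seed(seed, 7e5 + ti * 1000 + i)
        }, integer(1))
        draws <- pooled(test_lms[[ti]], prof, seeds_te,
                        n_uncertainty_draws)
        n_ok <- 0; n_tot <- 0
        for (feat_te in draws) {
          for (i in seq_len(nrow(feat_te))) {
            ll <- -0.5 * rowSums(sweep(mu, 2, feat_te[i, ])^2 / s2) -
              log_det
            n_ok <- n_ok + (uw[which.max(ll)] == test_words[i])
            n_tot <- n_tot + 1
          }
        }
        correct[si, ti] <- 100 * n_ok / n_tot
      }
    }
    structure(list(correct_pct = correct,
                   train_snrs_db = train_snrs_db,
                   test_snrs_db = test_snrs_db,
                   masker = masker,
                   masker_level_db_spl = masker_level_db_spl,
                   profile = prof$name,
                   processing = if (is.null(processing)) "none" else
                     paste0("PLATT-", processing$expansion_factor),
                   seed = seed),
              class = "recognition_map")
  })
  if (inherits(profile, "listener_profile")) results[[1]] else results
}

#' @export
print.recognition_map <- function(x, ...) {
  cat("recognition result map (", x$masker, " masker at ",
      x$masker_level_db_spl, " dB SPL, profile ", x$profile,
      ", processing ", x$processing, ")\n", sep = "")
  print(round(x$correct_pct, 1))
  invisible(x)
}

#' Interpolate an SRT from a recognition result map
#'
#' For each training SNR the lowest test SNR at which the target word
#' recognition rate is reached is linearly interpolated along the test
#' axis; the reported SRT is the minimum across training SNRs. A row whose
#' first grid point already exceeds the target is left-censored at the
#' grid minimum; a map that never reaches the target yields an explicit
#' "no SRT" result (`reached = FALSE`).
#'
#' @param map A `recognition_map`.
#' @param target_pct Target recognition rate in percent (default 50).
#' @return An object of class `srt_result`: list with `srt_db`,
#'   `target_pct`, `train_snr_at_min`, `censored`, `reached`.
#' @export
srt_from_map <- function(map, target_pct = 50) {
  stopifnot(inherits(map, "recognition_map"))
  snrs <- map$test_snrs_db
  row_srt <- apply(map$correct_pct, 1, function(p) {
    if (p[1] >= target_pct) return(c(snrs[1], TRUE))
    for (i in seq_len(length(p) - 1)) {
      if (p[i] < target_pct && p[i + 1] >= target_pct) {
        s <- snrs[i] + (target_pct - p[i]) / (p[i + 1] - p[i]) *
          (snrs[i + 1] - snrs[i])
        return(c(s, FALSE))
      }
    }
    c(NA_real_, FALSE)
  })
  srts <- row_srt[1, ]
  if (all(is.na(srts))) {
    return(structure(list(srt_db = NA_real_, target_pct = target_pct,
                          train_snr_at_min = NA_real_, censored = FALSE,
                          reached = FALSE), class = "srt_result"))
  }
  k <- which.min(srts)
  structure(list(srt_db = srts[k], target_pct = target_pct,
                 train_snr_at_min = map$train_snrs_db[k],
                 censored = as.logical(row_srt[2, k]), reached = TRUE),
            class = "srt_result")
}

#' @export
print.srt_result <- function(x, ...) {
  if (!x$reached) {
    cat("SRT-", x$target_pct, ": target never reached\n", sep = "")
  } else {
    cat("SRT-", x$target_pct, ": ", round(x$srt_db, 2), " dB SNR",
        if (x$censored) " (left-censored at grid minimum)" else "",
        " [best training SNR ", x$train_snr_at_min, " dB]\n", sep = "")
  }
  invisible(x)
}

#' Plomp curve and benefit of a compensation
#'
#' Summarizes SRTs as a function of masker presentation level (the Plomp
#' curve) for an unaided and an aided condition, and computes the benefit
#' as the mean improvement (unaided SRT minus aided SRT, positive =
#' improvement) at noise presentation levels of 70, 80 and 90 dB SPL --
#' levels at which linear amplification cannot improve the SRT, so any
#' benefit is attributable to the compensation.
#'
#' @param unaided,aided Numeric vectors of SRTs (dB) named by masker
#'   presentation level (dB SPL), e.g. `c("70" = -7, ...)`.
#' @param benefit_levels Levels averaged for the benefit (default 70, 80,
#'   90 dB SPL); each must be present in both arms.
#' @return A list with `benefit_db` and `curve` (data frame with columns
#'   `level_db_spl`, `unaided_srt_db`, `aided_srt_db`, `benefit_db`).
#' @export
#' @examples
#' plomp_benefit(c("70" = 0, "80" = 1, "90" = -1),
#'               c("70" = -3, "80" = -2, "90" = -4))$benefit_db   # 3
plomp_benefit <- function(unaided, aided,
                          benefit_levels = c(70, 80, 90)) {
  lev_u <- as.numeric(names(unaided))
  lev_a <- as.numeric(names(aided))
  for (l in benefit_levels) {
    if (!(l %in% lev_u) || !(l %in% lev_a)) {
      stop("missing SRT at masker level ", l, " dB SPL")
    }
  }
  lev <- sort(union(lev_u, lev_a))
  curve <- data.frame(
    level_db_spl = lev,
    unaided_srt_db = unaided[match(lev, lev_u)],
    aided_srt_db = aided[match(lev, lev_a)])
  curve$benefit_db <- curve$unaided_srt_db - curve$aided_srt_db
  b <- curve$benefit_db[curve$level_db_spl %in% benefit_levels]
  list(benefit_db = mean(b), curve = curve)
}

#' Psychometric-function segment from a recognition map
#'
#' Evaluates [srt_from_map()] for a range of target recognition rates
#' (default SRT-20 to SRT-90 in 5 % steps), giving a segment of the
#' psychometric function. Unreached targets are flagged, not dropped.
#'
#' @param map A `recognition_map`.
#' @param targets_pct Target rates in percent (default `seq(20, 90, 5)`).
#' @return Data frame with columns `target_pct`, `srt_db`,
#'   `train_snr_at_min`, `censored`, `reached`.
#' @export
psychometric_segment <- function(map, targets_pct = seq(20, 90, 5)) {
  rows <- lapply(targets_pct, function(t) {
    r <- srt_from_map(map, t)
    data.frame(target_pct = t, srt_db = r$srt_db,
               train_snr_at_min = r$train_snr_at_min,
               censored = r$censored, reached = r$reached)
  })
  do.call(rbind, rows)
}

#' Write a recognition map (and optional SRT table) as CSV
#'
#' @param map A `recognition_map`.
#' @param path Output CSV path for the map matrix (rows = training SNRs).
#' @export
write_map_csv <- function(map, path) {
  stopifnot(inherits(map, "recognition_map"))
  m <- map$correct_pct
  df <- data.frame(train_snr_db = map$train_snrs_db, m, check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
}
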