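#' Synthetic head model bundle
#'
#' Convenience constructor bundling the mesh, sensor array, lead field,
#' graph Laplacian and Green's function with the package defaults
#' (D = 642 dipoles, 32 channels, sigma = 0.6).
#'
#' @param n_subdivisions,radius_mm Passed to [make_cortical_mesh()].
#' @param n_channels Passed to [make_sensor_array()].
#' @param sigma Smoothness constant for [greens_function()].
#' @param montage Sensor montage, see [make_sensor_array()].
#' @return List of class `head_model`: `mesh`, `sensors`, `M`, `G`, `Q_G`.
#' @export
make_head_model <- function(n_subdivisions = 3, radius_mm = 80,
                            n_channels = 32, sigma = 0.6,
                            montage = "full") {
  mesh <- make_cortical_mesh(n_subdivisions, radius_mm)
  sensors <- make_sensor_array(n_channels, radius_mm * 1.2, montage)
  M <- make_lead_field(mesh, sensors)
  G <- graph_laplacian(mesh)
  Q_G <- greens_function(G, sigma)
  structure(list(mesh = mesh, sensors = sensors, M = M, G = G, Q_G = Q_G,
                 sigma = sigma),
            class = "head_model")
}

#' Two-class synthetic emotion EEG dataset
#'
#' Generates a subject-equivalent recording session in which the `high`
#' class of one affective dimension carries extra alpha-band source power in
#' a fixed cortical patch - the discriminative structure the pipeline is
#' meant to recover. Every trial contains a common distractor patch
#' oscillating in the beta band at a second fixed location, plus
#' `n_background` background patches at random locations and frequencies
#' (4-30 Hz). The target patch oscillates in the alpha band with a
#' log-normal per-trial amplitude whose median is `alpha_high` for
#' `high`-class trials and `alpha_low` for `low`-class trials
#' (`amp_log_sd` on the log scale), reflecting the log-normal
#' trial-to-trial variability of cortical oscillatory power. Sensor noise
#' is added at `snr_db`. Ratings consistent with the class are drawn
#' uniformly from 6..9 (`high`) or 1..5 (`low`).
#'
#' @param head A `head_model`; built with defaults when `NULL`.
#' @param n_trials Number of trials (default 40, one affect-protocol session).
#' @param duration_s Trial length in seconds (default 4).
#' @param fs Sampling rate (default 128 Hz).
#' @param prop_high Proportion of `high` trials (default 0.5).
#' @param alpha_high,alpha_low Median target-patch amplitudes for the two
#'   classes (defaults 1 and 0: the high class adds the patch, the low
#'   class lacks it).
#' @param amp_log_sd Standard deviation of the per-trial log-amplitude
#'   (default 0.4).
#' @param distractor_amp Common beta-patch amplitude (default 0.6).
#' @param n_background Background patches per trial (default 2).
#' @param background_amp Background patch amplitude (default 0.3).
#' @param snr_db Sensor signal-to-noise ratio in dB (default 5).
#' @param dimension Affective dimension the labels describe.
#' @param seed Integer RNG seed; reproduces the dataset exactly.
#' @return List of class `emotion_dataset`: `trials` (list of C x T
#'   matrices), `ratings` (data frame), `labels` (`label_set`), `fs`,
#'   `head`, `truth` (target/distractor centers and per-trial class).
#' @export
simulate_emotion_dataset <- function(head = NULL, n_trials = 40,
                                     duration_s = 4, fs = 128,
                                     prop_high = 0.5, alpha_high = 1,
                                     alpha_low = 0, amp_log_sd = 0.4,
                                     distractor_amp = 0.6,
                                     n_background = 2, background_amp = 0.3,
                                     snr_db = 5,
                                     dimension = "valence", seed = 1) {
  if (is.null(head)) head <- make_head_model()
  D <- nrow(head$mesh$vertices)
  T_len <- round(duration_s * fs)
  t_s <- (seq_len(T_len) - 1) / fs

  set.seed(seed)
  # fixed, well-separated patch centers for this session
  adj <- adjacency_list(head$mesh)
  target <- sample.int(D, 1)
  far <- which(graph_distance_from(adj, target, D) >= 6)
  distractor <- far[sample.int(length(far), 1)]

  n_high <- round(prop_high * n_trials)
  cls <- sample(rep(c("high", "low"), c(n_high, n_trials - n_high)))
  prof_t <- head$Q_G[, target] / max(head$Q_G[, target])
  prof_d <- head$Q_G[, distractor] / max(head$Q_G[, distractor])

  # draw all per-trial parameters up front so the inner noise seeds cannot
  # perturb the parameter stream
  f_a <- stats::runif(n_trials, 8, 13)
  f_b <- stats::runif(n_trials, 13, 30)
  ph_a <- stats::runif(n_trials, 0, 2 * pi)
  ph_b <- stats::runif(n_trials, 0, 2 * pi)
  amp_a <- ifelse(cls == "high", alpha_high, alpha_low) *
    exp(stats::rnorm(n_trials, 0, amp_log_sd))
  bg_v <- matrix(sample.int(D, n_background * n_trials, replace = TRUE),
                 nrow = max(n_background, 1))
  bg_f <- matrix(stats::runif(n_background * n_trials, 4, 30),
                 nrow = max(n_background, 1))
  bg_ph <- matrix(stats::runif(n_background * n_trials, 0, 2 * pi),
                  nrow = max(n_background, 1))

  trials <- vector("list", n_trials)
  for (i in seq_len(n_trials)) {
    J <- outer(prof_t, amp_a[i] * sin(2 * pi * f_a[i] * t_s + ph_a[i])) +
         outer(prof_d, distractor_amp * sin(2 * pi * f_b[i] * t_s + ph_b[i]))
    if (n_background > 0) {
      for (b in seq_len(n_background)) {
        prof_b <- head$Q_G[, bg_v[b, i]] / max(head$Q_G[, bg_v[b, i]])
        J <- J + outer(prof_b, background_amp *
                         sin(2 * pi * bg_f[b, i] * t_s + bg_ph[b, i]))
      }
    }
    rec <- simulate_eeg(head$M, J, snr_db,
                        seed = (seed * 10007 + i) %% 2147483647)
    X <- rec$X
    rownames(X) <- head$sensors$labels
    trials[[i]] <- X
  }
  set.seed(seed + 5000L)
  ratings <- ifelse(cls == "high", sample(6:9, n_trials, replace = TRUE),
                    sample(1:5, n_trials, replace = TRUE))
  labels <- make_labels(ratings, dimension)
  structure(
    list(trials = trials,
         ratings = stats::setNames(data.frame(ratings), dimension),
         labels = labels, fs = fs, head = head,
         truth = list(target = target, distractor = distractor,
                      class = cls),
         seed = seed),
    class = "emotion_dataset"
  )
}

#' Run one experiment arm of the discrimination pipeline
#'
#' Executes the full chain for a dataset: (optional) inverse solution per
#' trial, region-of-interest selection on the trial-averaged source energy
#' map, ROI time-course extraction, 45-feature extraction per signal, and
#' leave-one-out SVM evaluation. Three arms are available: `"eeg"` extracts
#' features directly from the sensor channels with no source mapping;
#' `"loreta-roi"` and `"msp-roi"` extract them from ROI time courses of the
#' respective inverse solution.
#'
#' The ROI labeling is computed once per dataset from the mean energy map
#' across trials, so every trial yields the same number of ROI signals; the
#' hyperparameters of the sparse solver are optimized per trial.
#'
#' @param dataset An `emotion_dataset` (or compatible list with `trials`,
#'   `labels`, `fs`, `head`).
#' @param arm `"eeg"`, `"loreta-roi"` or `"msp-roi"`.
#' @param lam LORETA regularization parameter (default 1).
#' @param n_basis MSP dictionary size (default 512).
#' @param rho ROI radius in mm (default 20).
#' @param threshold_frac ROI peak threshold (default 0.10).
#' @param var_explained,mass,cost Passed to [loo_evaluate()].
#' @param max_iter MSP optimizer iteration cap.
#' @return List of class `pipeline_result`: `evaluation`
#'   (`evaluation_result`), `arm`, `features` (the trial-by-feature
#'   matrix), and for ROI arms `labeling` and `energy` (mean map).
#' @export
run_pipeline_arm <- function(dataset, arm = c("eeg", "loreta-roi", "msp-roi"),
                             lam = 1, n_basis = 512, rho = 20,
                             threshold_frac = 0.10, var_explained = 0.9,
                             mass = 0.9, cost = 1, max_iter = 256) {
  arm <- match.arg(arm)
  fs <- dataset$fs
  head <- dataset$head
  labeling <- NULL
  e_mean <- NULL

  if (arm == "eeg") {
    signals <- dataset$trials
  } else {
    J_list <- vector("list", length(dataset$trials))
    if (arm == "msp-roi") {
      dict <- build_patch_dictionary(head$Q_G, head$mesh, n_basis)
      for (i in seq_along(dataset$trials)) {
        J_list[[i]] <- msp_solve(dataset$trials[[i]], head$M, dict,
                                 max_iter = max_iter)$J_hat
      }
    } else {
      # the smoothness-prior inverse operator is trial-independent: factor
      # the sensor-space system once and apply it to every trial
      M <- unclass(head$M)
      QJMt <- unclass(head$Q_G) %*% t(M)
      S <- lam * diag(nrow(M)) + M %*% QJMt
      K <- QJMt %*% solve((S + t(S)) / 2)
      for (i in seq_along(dataset$trials)) {
        J_list[[i]] <- K %*% dataset$trials[[i]]
      }
    }
    maps <- vapply(J_list, function(J) as.numeric(source_energy(J)),
                   numeric(nrow(head$mesh$vertices)))
    e_mean <- rowMeans(maps)
    labeling <- select_rois(e_mean, head$mesh, rho = rho,
                            threshold_frac = threshold_frac)
    signals <- lapply(J_list, roi_timecourses, labeling = labeling)
  }

  Xi <- build_feature_matrix(signals, fs = fs)
  eval_res <- loo_evaluate(Xi, dataset$labels, var_explained = var_explained,
                           mass = mass, cost = cost, method = arm)
  structure(
    list(evaluation = eval_res, arm = arm, features = Xi,
         labeling = labeling, energy = e_mean),
    class = "pipeline_result"
  )
}

#' Compare experiment arms on one dataset
#'
#' Convenience wrapper running several arms on the same dataset and
#' returning their evaluations side by side.
#'
#' @param dataset An `emotion_dataset`.
#' @param arms Character vector of arms to run.
#' @param ... Passed to [run_pipeline_arm()].
#' @return Named list of `pipeline_result`s with a `summary` data frame
#'   attribute (arm, accuracy, F1).
#' @export
run_pipeline <- function(dataset,
                         arms = c("eeg", "loreta-roi", "msp-roi"), ...) {
  res <- lapply(arms, function(a) run_pipeline_arm(dataset, arm = a, ...))
  names(res) <- arms
  attr(res, "summary") <- data.frame(
    arm = arms,
    accuracy = vapply(res, function(r) r$evaluation$accuracy, numeric(1)),
    f1 = vapply(res, function(r) r$evaluation$f1, numeric(1))
  )
  res
}

#' Write trials to delimited text
#'
#' Stores a list of channel-by-time trials plus the sampling rate as a
#' directory of CSV files (`trial001.csv`, ... with one row per channel)
#' and a `meta.json` with `fs` and channel labels.
#'
#' @param trials List of C x T matrices.
#' @param fs Sampling rate.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_trials <- function(trials, fs, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  labels <- rownames(trials[[1]])
  for (i in seq_along(trials)) {
    utils::write.table(trials[[i]],
                       file.path(dir, sprintf("trial%03d.csv", i)),
                       sep = ",", row.names = FALSE, col.names = FALSE)
  }
  jsonlite::write_json(list(fs = fs, n_trials = length(trials),
                            channels = labels),
                       file.path(dir, "meta.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Read trials written by [write_trials()]
#'
#' @param dir Directory containing `trial*.csv` and `meta.json`.
#' @return List with `trials`, `fs`, `channels`.
#' @export
read_trials <- function(dir) {
  meta_path <- file.path(dir, "meta.json")
  if (!file.exists(meta_path)) stop("missing meta.json in ", dir)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  files <- sort(list.files(dir, pattern = "^trial[0-9]+\\.csv$",
                           full.names = TRUE))
  trials <- lapply(files, function(f) {
    m <- as.matrix(utils::read.table(f, sep = ",", header = FALSE))
    if (!all(is.finite(m))) stop("non-finite values in ", f)
    if (length(meta$channels) == nrow(m)) {
      dimnames(m) <- list(meta$channels, NULL)
    } else {
      dimnames(m) <- NULL
    }
    m
  })
  ch <- unique(vapply(trials, nrow, integer(1)))
  if (length(ch) != 1) {
    stop("mismatched channel counts across trials: ",
         paste(ch, collapse = ", "))
  }
  list(trials = trials, fs = meta$fs, channels = meta$channels)
}
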