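# internal: deterministic 31-bit seed from a master seed and a tag string
derive_seed <- function(master, tag) {
  m <- 2147483647
  h <- as.numeric(master) %% m
  for (ch in utf8ToInt(as.character(tag))) h <- (h * 31 + ch) %% m
  as.integer(h %% (m - 1)) + 1L
}

#' Cohort configuration for the synthetic generator
#'
#' Defaults reflect the emulated study: 15 participants per group,
#' first-contact pain ratings 41.6 +/- 14.2 (FM) and 24.6 +/- 14.4 (HC)
#' on the 0-100 numerical pain scale, moderate innovation noise.
#'
#' @param n_per_group participants per group (>= 2).
#' @param noise_sd SD of per-region innovations (signal units; latent
#'   drives have unit variance).
#' @param seed master seed.
#' @param rating_mean_sd list with per-group `c(mean, sd)` of the
#'   first-contact pain rating.
#' @param rating_connection optional connection label whose
#'   participant-level DB value is correlated with the rating.
#' @param rating_correlation target correlation for `rating_connection`.
#' @param conditions run conditions to generate.
#' @return list of class `sapm_cohort_config`.
#' @export
cohort_config <- function(n_per_group = 15L, noise_sd = 0.2, seed = 1L,
                          rating_mean_sd = list(FM = c(41.6, 14.2),
                                                HC = c(24.6, 14.4)),
                          rating_connection = NULL, rating_correlation = 0,
                          conditions = c("Pain", "No-Pain")) {
  if (n_per_group < 2) stop("n_per_group must be >= 2", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  structure(list(n_per_group = as.integer(n_per_group), noise_sd = noise_sd,
                 seed = as.integer(seed), rating_mean_sd = rating_mean_sd,
                 rating_connection = rating_connection,
                 rating_correlation = rating_correlation,
                 conditions = conditions),
            class = "sapm_cohort_config")
}

# internal: draw a stable participant-level weight vector
.draw_db <- function(gt, max_tries = 200L, radius_max = 0.95, net) {
  for (i in seq_len(max_tries)) {
    db <- stats::rnorm(length(gt$db_mean), gt$db_mean, gt$db_sd_between)
    names(db) <- names(gt$db_mean)
    A <- .net_matrices(net, c(db, gt$latent_gain))$A
    rad <- max(Mod(eigen(A, only.values = TRUE)$values))
    if (rad < radius_max) return(db)
  }
  stop("could not draw stable connection weights (spectral radius >= ",
       radius_max, " after ", max_tries, " tries)", call. = FALSE)
}

#' Generate one synthetic participant run-average dataset
#'
#' Participant-level connection weights are drawn once per connection
#' from `Normal(db_mean, db_sd_between)` (redrawn deterministically if
#' the draw is unstable, spectral radius >= 0.95).  Latent drives are the
#' HRF-convolved neural design components of the paradigm (stimulation,
#' cue, tonic drift, assigned to latents in declaration order).  Noise is
#' modeled as per-region innovations that propagate through the network:
#' `X = (I - A)^-1 (M L + E)`, the structural-equation convention, so at
#' `noise_sd = 0` the observed series equal the [forward_model()] output
#' exactly.  Within each region, one sub-region carries the region
#' signal; the others carry an attenuated copy plus independent noise,
#' to exercise sub-region selection.
#'
#' @param net a `sapm_network`.
#' @param gt a `sapm_ground_truth` (see [ground_truth()]).
#' @param paradigm a `sapm_paradigm`.
#' @param noise_sd innovation SD (default 0.2).
#' @param seed integer seed (dataset is deterministic given the seed).
#' @param signal_subregion optional integer vector (one index per region)
#'   naming the signal-bearing sub-region; sampled uniformly if `NULL`.
#' @param attenuation signal attenuation in non-signal sub-regions.
#' @param noise_model `"innovations"` (default, propagated) or
#'   `"additive"` (pure observation noise).
#' @param id,group participant metadata.
#' @return object of class `sapm_participant` with `timecourses`
#'   (array regions x subregions x volumes), `region_series` (the
#'   signal-bearing series), `db_true`, `latents`, `signal_subregion`.
#' @export
generate_participant <- function(net, gt, paradigm, noise_sd = 0.2, seed = 1L,
                                 signal_subregion = NULL, attenuation = 0.3,
                                 noise_model = c("innovations", "additive"),
                                 id = "P01", group = "FM") {
  noise_model <- match.arg(noise_model)
  set.seed(seed)
  ab <- net$regions$abbrev
  R <- length(ab)
  db <- .draw_db(gt, net = net)
  full_db <- c(db, gt$latent_gain)
  mats <- .net_matrices(net, full_db)
  rad <- max(Mod(eigen(mats$A, only.values = TRUE)$values))
  if (rad >= 1)
    stop(sprintf("unstable weights: spectral radius %.4f >= 1", rad),
         call. = FALSE)

  nd <- neural_design(paradigm)
  comp <- bold_from_neural(nd, paradigm$tr_s)
  lnames <- vapply(net$latents, `[[`, character(1), "name")
  Lmat <- comp[((seq_along(lnames) - 1L) %% nrow(comp)) + 1L, , drop = FALSE]
  rownames(Lmat) <- lnames
  V <- ncol(Lmat)

  E <- matrix(stats::rnorm(R * V, 0, noise_sd), R, V)
  I_A <- diag(R) - mats$A
  drive <- mats$M %*% Lmat
  X <- if (noise_model == "innovations") solve(I_A, drive + E)
       else solve(I_A, drive) + E
  rownames(X) <- ab
  X <- X - rowMeans(X)

  S <- max(net$regions$n_subregions)
  if (is.null(signal_subregion))
    signal_subregion <- sample.int(S, R, replace = TRUE)
  signal_subregion <- stats::setNames(as.integer(signal_subregion), ab)
  tc <- array(NA_real_, c(R, S, V), dimnames = list(ab, NULL, NULL))
  for (r in seq_len(R)) for (s in seq_len(S)) {
    tc[r, s, ] <- if (s == signal_subregion[r]) X[r, ]
      else attenuation * X[r, ] + stats::rnorm(V, 0, noise_sd)
  }
  structure(list(id = id, group = group, condition = paradigm$condition,
                 timecourses = tc, region_series = X, db_true = full_db,
                 signal_subregion = signal_subregion, latents = Lmat,
                 paradigm = paradigm, noise_sd = noise_sd),
            class = "sapm_participant")
}

#' Generate a synthetic two-group cohort
#'
#' `n_per_group` participants per group, each with run-averaged datasets
#' for every requested condition, plus a covariate table: first- and
#' last-contact pain ratings (group-specific Normal draws truncated to
#' the 0-100 pain scale; the last-contact rating adds a group-specific
#' temporal-summation increment) and the normalized pain score
#' (mean rating / mean stimulus temperature).  If `rating_connection`
#' is set, the first-contact rating is drawn with the configured
#' correlation to that connection's participant-level Pain-condition DB
#' value via a Gaussian copula.
#'
#' @param net a `sapm_network`.
#' @param gt_fm,gt_hc `sapm_ground_truth` per group; `gt_hc` may be a
#'   per-condition list `list(Pain=, "No-Pain"=)`, as may `gt_fm`.
#' @param cfg a [cohort_config()].
#' @return object of class `sapm_cohort`: `participants` (list with
#'   `$conditions` per participant) and `covariates` (data.frame).
#' @export
generate_cohort <- function(net, gt_fm, gt_hc, cfg = cohort_config()) {
  per_cond <- function(gt, cond)
    if (inherits(gt, "sapm_ground_truth")) gt else gt[[cond]]
  temps <- stimulus_protocol()$temperatures_C
  ts_gain <- c(FM = 4.5, HC = 12.2)     # mean last-minus-first increment
  participants <- list()
  cov_rows <- list()
  for (grp in c("FM", "HC")) {
    gt_g <- if (grp == "FM") gt_fm else gt_hc
    for (i in seq_len(cfg$n_per_group)) {
      pid <- sprintf("%s%02d", grp, i)
      conds <- list()
      for (cond in cfg$conditions) {
        p <- build_paradigm(cond)
        conds[[cond]] <- generate_participant(
          net, per_cond(gt_g, cond), p, noise_sd = cfg$noise_sd,
          seed = derive_seed(cfg$seed, paste(pid, cond)),
          id = pid, group = grp)
      }
      set.seed(derive_seed(cfg$seed, paste(pid, "covariates")))
      ms <- cfg$rating_mean_sd[[grp]]
      z <- stats::rnorm(1)
      if (!is.null(cfg$rating_connection) && "Pain" %in% names(conds)) {
        gtp <- per_cond(gt_g, "Pain")
        dsd <- gtp$db_sd_between[cfg$rating_connection]
        if (is.na(dsd) || dsd <= 0)
          stop("rating_connection has no between-participant variability",
               call. = FALSE)
        zdb <- (conds[["Pain"]]$db_true[cfg$rating_connection] -
                gtp$db_mean[cfg$rating_connection]) / dsd
        rho <- cfg$rating_correlation
        z <- rho * zdb + sqrt(max(0, 1 - rho^2)) * z
      }
      first <- min(100, max(0, ms[1] + ms[2] * z))
      last <- min(100, max(0, first + stats::rnorm(1, ts_gain[grp], 8)))
      participants[[pid]] <- list(id = pid, group = grp, conditions = conds)
      cov_rows[[pid]] <- data.frame(
        participant = pid, group = grp, first_pain = first, last_pain = last,
        normalized_pain = normalized_pain_score(c(first, last), temps),
        stringsAsFactors = FALSE)
    }
  }
  covariates <- do.call(rbind, cov_rows)
  rownames(covariates) <- NULL
  structure(list(participants = participants, covariates = covariates,
                 config = cfg), class = "sapm_cohort")
}

#' Render a participant dataset as a small 4-D image plus label map
#'
#' Lays regions out along the third image axis, sub-regions along the
#' second, with `voxels_per_subregion` voxels along the first; each
#' voxel carries its sub-region time-course plus independent voxel
#' noise.  The integer label map assigns consecutive region codes
#' (1, 2, ...) in region declaration order.  With `dir` set, the pair is
#' written as NIfTI-1 files (`bold.nii.gz`, `labels.nii.gz`).
#'
#' @param participant a `sapm_participant`.
#' @param voxels_per_subregion voxels per sub-region (>= 1).
#' @param voxel_noise_sd SD of additional per-voxel noise.
#' @param seed seed for the voxel noise.
#' @param dir optional output directory for NIfTI files.
#' @return list with `image` (4-D array), `labels` (3-D integer array),
#'   `region_codes` (named vector), and `paths` when written.
#' @export
render_nifti <- function(participant, voxels_per_subregion = 2L,
                         voxel_noise_sd = 0, seed = 1L, dir = NULL) {
  tc <- participant$timecourses
  R <- dim(tc)[1]; S <- dim(tc)[2]; V <- dim(tc)[3]
  g <- as.integer(voxels_per_subregion)
  if (g < 1) stop("voxels_per_subregion must be >= 1", call. = FALSE)
  set.seed(seed)
  img <- array(0, c(g, S, R, V))
  lab <- array(0L, c(g, S, R))
  for (r in seq_len(R)) {
    lab[, , r] <- r
    for (s in seq_len(S)) for (x in seq_len(g))
      img[x, s, r, ] <- tc[r, s, ] + stats::rnorm(V, 0, voxel_noise_sd)
  }
  codes <- stats::setNames(seq_len(R), dimnames(tc)[[1]])
  out <- list(image = img, labels = lab, region_codes = codes)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    ipath <- file.path(dir, "bold.nii.gz")
    lpath <- file.path(dir, "labels.nii.gz")
    write_nifti(img, ipath)
    write_nifti(lab, lpath)
    out$paths <- c(image = ipath, labels = lpath)
  }
  out
}
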