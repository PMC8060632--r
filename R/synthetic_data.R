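#' Configuration for a synthetic canopy scene
#'
#' Describes a nadir view of a wheat canopy over bare soil: a target cover
#' fraction, mean leaf and soil colours, Gaussian colour noise, and the
#' number of elliptical leaf blobs used to build the canopy mask. Leaf
#' colour must satisfy G\eqn{-}R > 0 and soil colour G\eqn{-}R \eqn{\le} 0, so
#' that noiseless scenes segment exactly at threshold 0.
#'
#' @param width,height Image size in pixels.
#' @param target_cover Ground-truth canopy fraction in \code{[0, 1]}.
#' @param leaf_color_mean,soil_color_mean RGB triples (0-255).
#' @param color_noise_sd Per-channel Gaussian noise SD in intensity units.
#' @param n_leaf_blobs Number of elliptical blobs drawn before the exact
#'   cover adjustment.
#' @param seed Integer seed; every random draw in the generator flows from it.
#' @return A list of class \code{"scene_config"}.
#' @export
scene_config <- function(width = 120, height = 80, target_cover = 0.5,
                         leaf_color_mean = c(60, 130, 45),
                         soil_color_mean = c(115, 85, 65),
                         color_noise_sd = 8, n_leaf_blobs = 25,
                         seed = 1L) {
  if (target_cover < 0 || target_cover > 1)
    stop("'target_cover' must be in [0, 1]", call. = FALSE)
  if (leaf_color_mean[2] - leaf_color_mean[1] <= 0)
    stop("leaf colour must have G - R > 0", call. = FALSE)
  if (soil_color_mean[2] - soil_color_mean[1] > 0)
    stop("soil colour must have G - R <= 0", call. = FALSE)
  if (color_noise_sd < 0) stop("'color_noise_sd' must be >= 0", call. = FALSE)
  if (width < 1 || height < 1) stop("image must be at least 1 x 1", call. = FALSE)
  structure(list(width = as.integer(width), height = as.integer(height),
                 target_cover = target_cover,
                 leaf_color_mean = leaf_color_mean,
                 soil_color_mean = soil_color_mean,
                 color_noise_sd = color_noise_sd,
                 n_leaf_blobs = as.integer(n_leaf_blobs),
                 seed = as.integer(seed)),
            class = "scene_config")
}

#' Generate a synthetic canopy image with a known ground-truth mask
#'
#' Draws random elliptical leaf blobs over a soil background, then adjusts
#' the mask pixel-by-pixel so its cover fraction equals
#' \code{round(target_cover * n_pixels) / n_pixels} exactly. Leaf and soil
#' pixels get their mean colours plus optional Gaussian noise (clipped to
#' \code{[0, 255]}). Reproducible under a fixed seed.
#'
#' @param config A [scene_config()].
#' @return A list with \code{image} (integer array
#'   \code{height x width x 3}), \code{mask} (logical matrix, \code{TRUE} =
#'   canopy) and \code{true_cover} (the exact mask fraction).
#' @examples
#' scn <- simulate_canopy_image(scene_config(target_cover = 0.42, seed = 7))
#' mean(scn$mask)       # 0.42 to within one pixel
#' @export
simulate_canopy_image <- function(config = scene_config()) {
  stopifnot(inherits(config, "scene_config"))
  w <- config$width; h <- config$height
  n <- w * h
  n_target <- round(config$target_cover * n)
  rng <- local_rng(config$seed)

  mask <- matrix(FALSE, h, w)
  if (n_target == n) {
    mask[] <- TRUE
  } else if (n_target > 0) {
    # blobs sized so the expected union roughly reaches the target
    area_per <- max(4, ceiling(1.6 * n_target / config$n_leaf_blobs))
    xs <- matrix(rep(seq_len(w), each = h), h, w)
    ys <- matrix(rep(seq_len(h), times = w), h, w)
    i <- 0L
    while (sum(mask) < n_target && i < 200L * config$n_leaf_blobs) {
      i <- i + 1L
      cx <- rng$runif(1, 1, w); cy <- rng$runif(1, 1, h)
      ar <- exp(rng$rnorm(1, 0, 0.4))             # aspect ratio of the ellipse
      rx <- sqrt(area_per / pi * ar); ry <- sqrt(area_per / pi / ar)
      th <- rng$runif(1, 0, pi)
      dx <- xs - cx; dy <- ys - cy
      u <- dx * cos(th) + dy * sin(th)
      v <- -dx * sin(th) + dy * cos(th)
      d2 <- (u / rx)^2 + (v / ry)^2
      new_px <- which(d2 <= 1 & !mask)
      remaining <- n_target - sum(mask)
      if (length(new_px) > remaining) {
        # the blob that crosses the target is grown from its centre only
        # until the cover is exact, keeping the mask contiguous (no speckle)
        new_px <- new_px[order(d2[new_px])][seq_len(remaining)]
      }
      mask[new_px] <- TRUE
    }
    deficit <- n_target - sum(mask)   # unreachable in practice
    if (deficit > 0) mask[rng$sample(which(!mask), deficit)] <- TRUE
  }

  img <- array(0, c(h, w, 3))
  for (ch in 1:3)
    img[, , ch] <- ifelse(mask, config$leaf_color_mean[ch],
                          config$soil_color_mean[ch])
  if (config$color_noise_sd > 0)
    img <- img + rng$rnorm(length(img), 0, config$color_noise_sd)
  img <- round(pmin(pmax(img, 0), 255))
  storage.mode(img) <- "integer"
  list(image = img, mask = mask, true_cover = sum(mask) / n)
}

#' Write a batch of synthetic canopy images to disk
#'
#' Generates \code{n} scenes with covers spaced across \code{cover_range},
#' writes them as PNG files, and returns (and writes) a ground-truth table.
#'
#' @param dir Output directory (created if needed).
#' @param n Number of images.
#' @param cover_range Length-2 numeric: range of target covers.
#' @param seed Integer seed.
#' @param ... Further arguments to [scene_config()] (e.g. width, height,
#'   color_noise_sd).
#' @return Data frame with columns \code{image_path}, \code{target_cover},
#'   \code{true_cover}; also written to \code{dir/ground_truth.csv}.
#' @export
simulate_image_batch <- function(dir, n = 10, cover_range = c(0.1, 0.9),
                                 seed = 1L, ...) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  covers <- seq(cover_range[1], cover_range[2], length.out = n)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    cfg <- scene_config(target_cover = covers[i], seed = seed + i, ...)
    scn <- simulate_canopy_image(cfg)
    path <- file.path(dir, sprintf("canopy_%03d.png", i))
    png::writePNG(scn$image / 255, path)
    rows[[i]] <- data.frame(image_path = path, target_cover = covers[i],
                            true_cover = scn$true_cover,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  utils::write.csv(out, file.path(dir, "ground_truth.csv"), row.names = FALSE)
  out
}

# Default per-cultivar allometric parameters for the trial generator:
# SDM = a_d CC^b_d (t/ha), LAI = a_l CC^b_l, SNA = a_n CC^b_n (kg N/ha).
default_cultivar_params <- function() {
  data.frame(
    cultivar = c("AK58", "YM58", "BN207", "WM28"),
    a_d = c(4.87, 5.05, 5.79, 6.72),
    b_d = c(1.92, 1.76, 1.79, 1.54),
    a_l = c(3.66, 3.68, 4.27, 4.95),
    b_l = c(1.63, 1.46, 1.52, 1.36),
    a_n = c(134.37, 134.77, 176.77, 185.24),
    b_n = c(1.73, 1.56, 1.67, 1.50),
    stringsAsFactors = FALSE)
}

# Default per-stage SNC power laws SNC = a_s CC^b_s (% of dry matter),
# kept as reference metadata for composing indirect NNI models.
default_snc_stage_params <- function() {
  data.frame(stage = c("Feekes 3", "Feekes 5", "Feekes 6"),
             a_s = c(11.97, 3.81, 3.46),
             b_s = c(1.03, 0.50, 0.86),
             stringsAsFactors = FALSE)
}

#' Configuration for a synthetic factorial field trial
#'
#' Describes a multi-site, multi-season winter-wheat trial: sites x seasons
#' x cultivars x N rates x replicates x growth stages. Canopy cover for
#' each N rate is interpolated between per-rate (min, max) endpoints across
#' the ordered stages; growth indices follow per-cultivar allometric power
#' laws of CC with multiplicative lognormal noise.
#'
#' Default CC endpoints run from 0.18-0.61 under 0 kg N/ha to 0.30-0.88
#' under 300 kg N/ha (intermediate rates linearly interpolated), the ranges
#' typical of winter wheat between tillering (Feekes 3) and first node
#' (Feekes 6) under those N supplies.
#'
#' @param sites,seasons Character vectors of site and season labels.
#' @param cultivars Data frame with columns \code{cultivar, a_d, b_d, a_l,
#'   b_l, a_n, b_n}; defaults cover four cultivars with realistic
#'   parameter spreads.
#' @param n_rates Numeric vector of N application rates, kg N/ha.
#' @param replicates Number of replicate plots per treatment.
#' @param stages Ordered character vector of growth-stage labels.
#' @param cc_range_per_n_rate Matrix/data frame with one \code{(min, max)}
#'   CC row per N rate, or \code{NULL} to interpolate the defaults.
#' @param cc_jitter_sd SD of additive Gaussian jitter on CC (truncated to
#'   keep CC in (0, 1)).
#' @param noise_cv Coefficient of variation of the multiplicative lognormal
#'   noise applied independently to SDM, LAI and SNA.
#' @param snc_stage_params Per-stage SNC power-law parameters (reference
#'   metadata; columns \code{stage, a_s, b_s}).
#' @param seed Integer seed.
#' @return A list of class \code{"trial_config"}.
#' @export
trial_config <- function(sites = c("Xinxiang", "Qinyang"),
                         seasons = c("2016-2017", "2017-2018"),
                         cultivars = default_cultivar_params(),
                         n_rates = c(0, 75, 150, 225, 300),
                         replicates = 3,
                         stages = c("Feekes 3", "Feekes 5", "Feekes 6"),
                         cc_range_per_n_rate = NULL,
                         cc_jitter_sd = 0.05,
                         noise_cv = 0.1,
                         snc_stage_params = default_snc_stage_params(),
                         seed = 1L) {
  if (replicates < 1) stop("'replicates' must be >= 1", call. = FALSE)
  if (noise_cv < 0) stop("'noise_cv' must be >= 0", call. = FALSE)
  needed <- c("cultivar", "a_d", "b_d", "a_l", "b_l", "a_n", "b_n")
  if (!all(needed %in% names(cultivars)))
    stop("'cultivars' must have columns ", paste(needed, collapse = ", "),
         call. = FALSE)
  if (is.null(cc_range_per_n_rate)) {
    # endpoints at 0 and 300 kg N/ha, linear in the rate between them
    f <- (n_rates - 0) / 300
    cc_range_per_n_rate <- cbind(min = 0.18 + f * (0.30 - 0.18),
                                 max = 0.61 + f * (0.88 - 0.61))
  }
  cc_range_per_n_rate <- as.matrix(cc_range_per_n_rate)
  if (nrow(cc_range_per_n_rate) != length(n_rates))
    stop("'cc_range_per_n_rate' needs one (min, max) row per N rate",
         call. = FALSE)
  if (any(cc_range_per_n_rate <= 0) || any(cc_range_per_n_rate >= 1))
    stop("CC endpoints must lie in (0, 1)", call. = FALSE)
  structure(list(sites = sites, seasons = seasons, cultivars = cultivars,
                 n_rates = n_rates, replicates = as.integer(replicates),
                 stages = stages, cc_range_per_n_rate = cc_range_per_n_rate,
                 cc_jitter_sd = cc_jitter_sd, noise_cv = noise_cv,
                 snc_stage_params = snc_stage_params,
                 seed = as.integer(seed)),
            class = "trial_config")
}

#' Generate a synthetic factorial trial table
#'
#' For every site x season x cultivar x N rate x replicate x stage cell,
#' draws canopy cover by interpolating the N rate's (min, max) CC range
#' across stages plus Gaussian jitter, then sets
#' \deqn{SDM = a_d CC^{b_d} \epsilon,\quad LAI = a_l CC^{b_l} \epsilon,\quad
#'       SNA = a_n CC^{b_n} \epsilon,}
#' with independent lognormal \eqn{\epsilon} of coefficient of variation
#' \code{noise_cv}, and derives shoot N concentration from the accounting
#' identity \eqn{SNC = SNA / (10\, SDM)} (t/ha x % to kg/ha). All values are
#' strictly positive; the draw is reproducible under the config seed.
#'
#' @param config A [trial_config()].
#' @return A data frame with columns \code{site, season, cultivar,
#'   n_rate_kg_ha, replicate, stage, cc, sdm_t_ha, lai, snc_pct, sna_kg_ha}.
#' @examples
#' trial <- simulate_trial(trial_config(noise_cv = 0, seed = 3))
#' nrow(trial)  # 2 sites x 2 seasons x 4 cultivars x 5 N x 3 reps x 3 stages
#' @export
simulate_trial <- function(config = trial_config()) {
  stopifnot(inherits(config, "trial_config"))
  rng <- local_rng(config$seed)
  grid <- expand.grid(stage = config$stages,
                      replicate = seq_len(config$replicates),
                      n_rate_kg_ha = config$n_rates,
                      cultivar = config$cultivars$cultivar,
                      season = config$seasons,
                      site = config$sites,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[, c("site", "season", "cultivar", "n_rate_kg_ha",
                   "replicate", "stage")]
  n <- nrow(grid)

  stage_pos <- match(grid$stage, config$stages)
  stage_frac <- (stage_pos - 1) / max(1, length(config$stages) - 1)
  rate_idx <- match(grid$n_rate_kg_ha, config$n_rates)
  cc_lo <- config$cc_range_per_n_rate[rate_idx, 1]
  cc_hi <- config$cc_range_per_n_rate[rate_idx, 2]
  cc <- cc_lo + stage_frac * (cc_hi - cc_lo)
  if (config$cc_jitter_sd > 0) {
    cc <- cc + rng$rnorm(n, 0, config$cc_jitter_sd)
    cc <- pmin(pmax(cc, 0.01), 0.99)
  }

  cp <- config$cultivars[match(grid$cultivar, config$cultivars$cultivar), ]
  # median-1 lognormal with CV = noise_cv: in log space the noise is
  # mean-zero Gaussian, exactly the error model the log-linear fit assumes
  sdlog <- sqrt(log(1 + config$noise_cv^2))
  eps <- function() {
    if (config$noise_cv == 0) rep(1, n)
    else rng$rlnorm(n, 0, sdlog)
  }
  sdm <- cp$a_d * cc^cp$b_d * eps()
  lai <- cp$a_l * cc^cp$b_l * eps()
  sna <- cp$a_n * cc^cp$b_n * eps()
  snc <- sna / (10 * sdm)

  cbind(grid, data.frame(cc = cc, sdm_t_ha = sdm, lai = lai,
                         snc_pct = snc, sna_kg_ha = sna))
}

# Seed-scoped RNG: draws come from an isolated stream so the generator
# never disturbs (or depends on) the caller's global RNG state.
local_rng <- function(seed) {
  env <- new.env(parent = emptyenv())
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  set.seed(seed)
  env$state <- get(".Random.seed", globalenv())
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  with_state <- function(f) {
    function(...) {
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
      assign(".Random.seed", env$state, globalenv())
      out <- f(...)
      env$state <- get(".Random.seed", globalenv())
      if (!is.null(old)) assign(".Random.seed", old, globalenv())
      out
    }
  }
  list(runif = with_state(stats::runif),
       rnorm = with_state(stats::rnorm),
       rlnorm = with_state(stats::rlnorm),
       sample = with_state(function(x, size) sample(x, size)))
}
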