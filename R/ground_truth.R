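#' One-sided area of the 60 sampling discs
#'
#' Leaf discs are punched with a 0.8 cm diameter punch; the disc-weighing
#' protocol uses the total one-sided area of all 60 discs, in m^2.
#' @return total disc area in m^2 (about 3.016e-3).
#' @export
disc_area_m2 <- function() 60 * pi * 0.004^2

#' Leaf area index from the disc-weighing protocol
#'
#' Destructive ground truth: 60 leaf discs are punched from the leaves of 3
#' sampled plants and weighed wet (`W1`); the remaining leaves of the 3 plants
#' are weighed wet (`W2`). Assuming constant specific fresh weight per leaf
#' area, total leaf area of one plant is (W1 + W2)/(3 W1) * S and
#'
#'   LAI = (W1 + W2) / (3 * W1) * S * M
#'
#' where `S` is the total one-sided area of the 60 discs (m^2) and `M` the
#' number of plants per m^2 of ground.
#'
#' @param W1 wet weight of the 60 discs, grams (> 0).
#' @param W2 wet weight of the remaining leaves of the 3 plants, grams (>= 0).
#' @param S total one-sided disc area, m^2 (> 0).
#' @param M plants per m^2 (> 0).
#' @return dimensionless LAI (vectorized over its arguments).
#' @export
compute_lai_eq1 <- function(W1, W2, S = disc_area_m2(), M) {
  if (any(!is.finite(W1)) || any(W1 <= 0)) stop("W1 must be positive", call. = FALSE)
  if (any(!is.finite(W2)) || any(W2 < 0)) stop("W2 must be non-negative", call. = FALSE)
  if (any(!is.finite(S)) || any(S <= 0)) stop("S must be positive", call. = FALSE)
  if (any(!is.finite(M)) || any(M <= 0)) stop("M must be positive", call. = FALSE)
  (W1 + W2) / (3 * W1) * S * M
}

lai_stages <- c("BBCH41", "BBCH44", "BBCH47")

# Per-stage canopy mean LAI the generator is calibrated to: tuber formation,
# tuber growth, starch accumulation.
stage_mean_lai <- c(BBCH41 = 1.50, BBCH44 = 1.32, BBCH47 = 1.28)

# Multiplicative treatment response, relative scale. LAI increases with
# planting density, increases with N up to the N2 rate and drops slightly at
# the luxury N3 rate, responds weakly to potash, and differs mildly between
# varieties.
treatment_response <- function(layout) {
  d_eff <- c(`60000` = 0.80, `72000` = 1.00, `84000` = 1.18)
  n_eff <- c(`0` = 0.50, `112.5` = 0.82, `225` = 1.12, `337.5` = 1.02)
  k_eff <- c(`0` = 0.93, `495` = 1.00, `990` = 1.04)
  v_eff <- c(Z3 = 0.95, Z5 = 1.05)
  d_eff[as.character(layout$density_level)] *
    n_eff[as.character(layout$n_level)] *
    k_eff[as.character(layout$k_level)] *
    v_eff[layout$variety]
}

#' Simulate disc-weighing ground truth for one growth stage
#'
#' The plot LAI is a deterministic multiplicative treatment response
#' (increasing in density; increasing in N up to the third rate; weak potash
#' and variety effects), scaled so the design mean at each stage equals the
#' calibrated stage mean (1.50, 1.32, 1.28 at BBCH41/44/47), times lognormal
#' plot noise with unit mean, truncated to the observed LAI range
#' [0.29, 3.75]. Disc weights `W1`, `W2` are then back-computed so that
#' [compute_lai_eq1()] reproduces the stored LAI exactly, with `S` the total
#' disc area and `M` the planting density converted to plants per m^2.
#'
#' @param layout a `plot_layout` from [make_layout()].
#' @param stage one of "BBCH41", "BBCH44", "BBCH47".
#' @param seed integer master seed.
#' @param noise_sd lognormal sigma (log scale) of the plot noise; 0 gives the
#'   deterministic treatment response.
#' @return a data.frame with one row per plot: `plot_id`, `stage`,
#'   `replicate`, `W1`, `W2`, `S`, `M`, `lai`.
#' @export
simulate_lai <- function(layout, stage, seed = 0L, noise_sd = 0.35) {
  if (!stage %in% lai_stages) {
    stop(sprintf("unknown stage '%s' (expected one of %s)", stage,
                 paste(lai_stages, collapse = ", ")), call. = FALSE)
  }
  stage_idx <- match(stage, lai_stages)
  rel <- treatment_response(layout)
  rel <- rel / mean(rel)                 # design mean of the response = 1
  lai_det <- stage_mean_lai[[stage]] * rel
  set.seed(derive_seed(seed, 23L, stage_idx))
  noise <- exp(rnorm(nrow(layout), mean = -noise_sd^2 / 2, sd = noise_sd))
  lai <- pmin(pmax(lai_det * noise, 0.29), 3.75)
  S <- disc_area_m2()
  M <- layout$density_level / 1e4        # tubers/ha -> plants per m^2
  W1 <- runif(nrow(layout), 1.0, 2.5)    # grams; 60 fresh discs
  W2 <- W1 * (3 * lai / (S * M) - 1)
  data.frame(plot_id = layout$plot_id, stage = stage,
             replicate = layout$replicate,
             W1 = W1, W2 = W2, S = S, M = M, lai = lai,
             stringsAsFactors = FALSE)
}

#' Simulate ground truth for all three growth stages
#'
#' @inheritParams simulate_lai
#' @return row-bound data.frame of [simulate_lai()] results (144 rows on the
#'   default design).
#' @export
simulate_lai_all_stages <- function(layout, seed = 0L, noise_sd = 0.35) {
  do.call(rbind, lapply(lai_stages, simulate_lai,
                        layout = layout, seed = seed, noise_sd = noise_sd))
}
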