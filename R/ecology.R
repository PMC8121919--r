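#' Bin particle observations into depth-resolved concentrations
#'
#' Counts objects per half-open depth bin `[z, z + h)` for every
#' (cast, time, morphotype) combination and divides by the water volume
#' sampled in that bin, giving concentrations in individuals per litre.
#' Bins that were sampled (volume known) but hold no particles get
#' concentration 0; bins with no sampled volume are absent from the
#' output.
#'
#' @param objects Data frame with one row per particle: `cast`, `time`,
#'   `depth` (m), `morphotype`.
#' @param volumes Data frame with `cast`, `depth_bin` (lower bin edge, m)
#'   and `volume_L` (> 0).
#' @param bin_height Bin height in metres (default 5).
#' @return Long tibble: `cast`, `time`, `depth_bin`, `morphotype`,
#'   `count`, `volume_L`, `concentration_per_L`.
#' @export
bin_concentrations <- function(objects, volumes, bin_height = 5) {
  stopifnot(bin_height > 0)
  if (any(volumes$volume_L <= 0)) abort("sampled volumes must be positive.")
  if (any(objects$depth < 0)) abort("depths must be non-negative.")
  obj <- objects %>%
    mutate(depth_bin = floor(.data$depth / bin_height) * bin_height)
  # every object must fall into a sampled bin of its cast
  sampled <- volumes %>% select("cast", "depth_bin") %>% mutate(.ok = TRUE)
  chk <- obj %>% left_join(sampled, by = c("cast", "depth_bin"))
  if (any(is.na(chk$.ok))) {
    bad <- chk$object_id[is.na(chk$.ok)] %||%
      which(is.na(chk$.ok))
    abort(paste0(
      "object(s) outside the sampled depth range: ",
      paste(head(bad, 10), collapse = ", "),
      if (length(bad) > 10) ", ..." else ""
    ))
  }
  counts <- obj %>%
    count(.data$cast, .data$time, .data$depth_bin, .data$morphotype,
          name = "count")
  grid <- volumes %>%
    select("cast", "depth_bin", "volume_L") %>%
    tidyr::crossing(
      obj %>% distinct(.data$time),
      obj %>% distinct(.data$morphotype)
    )
  grid %>%
    left_join(counts, by = c("cast", "time", "depth_bin", "morphotype")) %>%
    mutate(
      count = tidyr::replace_na(.data$count, 0L),
      concentration_per_L = .data$count / .data$volume_L
    ) %>%
    select("cast", "time", "depth_bin", "morphotype", "count",
           "volume_L", "concentration_per_L") %>%
    arrange(.data$cast, .data$time, .data$depth_bin, .data$morphotype)
}

#' Log-spaced size bins
#'
#' @param range_mm Diameter range to cover (mm).
#' @param per_octave Bins per factor-2 of diameter (default 5).
#' @return Numeric vector of bin edges.
#' @export
size_bins <- function(range_mm = c(0.5, 20), per_octave = 5) {
  stopifnot(range_mm[1] > 0, range_mm[2] > range_mm[1], per_octave > 0)
  n_oct <- log2(range_mm[2] / range_mm[1])
  n_bins <- ceiling(n_oct * per_octave)
  range_mm[1] * 2^(seq(0, n_bins) / per_octave)
}

#' Slope of the normalized particle size spectrum
#'
#' Particles are counted into diameter bins; the normalized abundance
#' `n = count / (volume × bin width)` is regressed in log–log space on the
#' bin-centre diameter (geometric mean of the edges):
#' `ln n = ln a + b ln d`. The slope `b` is the size-spectrum exponent
#' (more negative = smaller particles dominate). Only non-empty bins enter
#' the fit.
#'
#' @param esd_mm Vector of equivalent spherical diameters (mm).
#' @param volume_L Total water volume sampled (L); scales the intercept
#'   only, not the slope.
#' @param bins Bin edges from [size_bins()] (or custom). Diameters outside
#'   the bin range are ignored.
#' @return One-row tibble: `slope`, `intercept`, `n_bins_used`, `n_particles`.
#' @examples
#' set.seed(1)
#' d <- 0.5 * (1 - runif(1e4))^(-1 / 2)  # power-law sample, exponent -3
#' size_spectrum_slope(d[d < 20], volume_L = 100)
#' @export
size_spectrum_slope <- function(esd_mm, volume_L = 1,
                                bins = size_bins()) {
  stopifnot(volume_L > 0)
  inside <- esd_mm >= bins[1] & esd_mm < bins[length(bins)]
  cuts <- cut(esd_mm[inside], bins, right = FALSE, labels = FALSE)
  counts <- tabulate(cuts, nbins = length(bins) - 1L)
  widths <- diff(bins)
  centres <- sqrt(bins[-length(bins)] * bins[-1])
  keep <- counts > 0
  if (sum(keep) < 3L) {
    abort("spectrum undefined: fewer than 3 non-empty size bins.")
  }
  nn <- counts[keep] / (volume_L * widths[keep])
  fit <- lm(log(nn) ~ log(centres[keep]))
  tibble(
    slope = unname(coef(fit)[2]),
    intercept = unname(coef(fit)[1]),
    n_bins_used = sum(keep),
    n_particles = sum(counts)
  )
}

#' Martin-type vertical attenuation exponent
#'
#' Fits the power law `n(z) = n_100 * (z / z_ref)^b` to a concentration
#' profile by ordinary least squares in log–log space:
#' `ln n = ln n_100 + b ln(z / z_ref)`. A negative `b` means concentration
#' decreases with depth; `n_100` is the concentration at the reference
#' depth (100 m by convention).
#'
#' @param profile Data frame with `depth` (m, bin centres) and
#'   `concentration` columns, one morphotype/time at a time.
#' @param z_ref Reference depth (m, default 100).
#' @param z_max Fit restricted to depths in `(0, z_max]` (default 500).
#' @return One-row tibble: `n_100`, `b`, `n_bins_used`.
#' @examples
#' prof <- data.frame(depth = seq(52.5, 497.5, 5))
#' prof$concentration <- 2 * (prof$depth / 100)^-0.8
#' attenuation_exponent(prof)  # recovers n_100 = 2, b = -0.8
#' @export
attenuation_exponent <- function(profile, z_ref = 100, z_max = 500) {
  use <- profile$depth > 0 & profile$depth <= z_max &
    profile$concentration > 0
  if (sum(use) < 3L) {
    abort("attenuation undefined: fewer than 3 positive bins in range.")
  }
  z <- profile$depth[use]
  n <- profile$concentration[use]
  fit <- lm(log(n) ~ log(z / z_ref))
  tibble(
    n_100 = exp(unname(coef(fit)[1])),
    b = unname(coef(fit)[2]),
    n_bins_used = sum(use)
  )
}

#' Shannon–Wiener diversity of morphotype concentrations
#'
#' Morphotype clusters are treated as "species":
#' `H = -sum(p_i log(p_i))` with `p_i = n_i / sum(n)`, natural log.
#' Zero-concentration types contribute nothing.
#'
#' @param concentrations Non-negative vector, at least one positive entry.
#' @return `H` (numeric scalar), bounded by `[0, log(k)]`.
#' @examples
#' shannon_diversity(rep(1, 5))  # log(5)
#' @export
shannon_diversity <- function(concentrations) {
  if (any(concentrations < 0)) abort("concentrations must be >= 0.")
  tot <- sum(concentrations)
  if (tot <= 0) abort("diversity undefined: all concentrations are zero.")
  p <- concentrations[concentrations > 0] / tot
  -sum(p * log(p))
}

#' Sensitivity of diversity patterns to the number of clusters
#'
#' Refits k-means on the morphospace coordinates at each `k` and
#' recomputes the Shannon diversity of cluster composition within each
#' stratum (e.g. bloom phase or depth layer). The Spearman rank
#' correlation of the stratum diversity ordering against the `k = 5`
#' baseline quantifies whether conclusions depend on the choice of five
#' morphotypes.
#'
#' @param scores Morphospace coordinates (see [fit_morphotypes()]).
#' @param strata Stratum label per row of `scores`.
#' @param ks Cluster numbers to test (default 25, 50, 100).
#' @param seed Integer seed.
#' @param n_restarts Random restarts per fit (default 5; these are large,
#'   well-populated fits).
#' @return List with `diversity` (tibble `k`, `stratum`, `H`) and
#'   `rank_correlation` (tibble `k`, `spearman` vs the `k = 5` baseline).
#' @export
diversity_sensitivity <- function(scores, strata, ks = c(25, 50, 100),
                                  seed, n_restarts = 5) {
  x <- score_matrix(scores)
  if (length(strata) != nrow(x)) {
    abort("`strata` must label every row of `scores`.")
  }
  all_k <- c(5, setdiff(ks, 5))
  res <- purrr::map_dfr(seq_along(all_k), function(i) {
    k <- all_k[i]
    model <- fit_morphotypes(x, k = k, seed = seed + i - 1,
                             n_restarts = n_restarts)
    tibble(k = k, stratum = strata, cluster = model$cluster) %>%
      count(.data$k, .data$stratum, .data$cluster) %>%
      group_by(.data$k, .data$stratum) %>%
      summarise(H = shannon_diversity(.data$n), .groups = "drop")
  })
  base <- res %>% filter(.data$k == 5) %>% arrange(.data$stratum)
  rc <- res %>%
    filter(.data$k != 5) %>%
    group_by(.data$k) %>%
    arrange(.data$stratum, .by_group = TRUE) %>%
    summarise(
      spearman = cor(.data$H, base$H, method = "spearman"),
      .groups = "drop"
    )
  list(diversity = res, rank_correlation = rc)
}

#' Track the depth of the concentration maximum through time
#'
#' For each time point, returns the (bin-centre) depth of the
#' maximum-concentration bin; exact ties go to the shallowest bin. Time
#' points whose profile is entirely zero are omitted (with a message).
#'
#' @param profiles Long data frame with `time`, `depth_bin` (lower edge),
#'   `concentration_per_L`, typically one morphotype (filter first).
#' @param bin_height Bin height (m, default 5) used to place bin centres.
#' @param smooth If `TRUE`, profiles are smoothed with a centred 3-bin
#'   running mean before locating the maximum.
#' @return Tibble with `time` and `peak_depth` (m).
#' @export
peak_depth_series <- function(profiles, bin_height = 5, smooth = FALSE) {
  out <- profiles %>%
    group_by(.data$time) %>%
    arrange(.data$depth_bin, .by_group = TRUE) %>%
    summarise(
      peak_depth = {
        conc <- .data$concentration_per_L
        if (smooth && length(conc) >= 3) {
          conc <- stats::filter(conc, rep(1 / 3, 3), sides = 2)
          conc[is.na(conc)] <- 0
        }
        if (max(conc) <= 0) NA_real_
        else .data$depth_bin[which.max(conc)] + bin_height / 2
      },
      .groups = "drop"
    )
  n_empty <- sum(is.na(out$peak_depth))
  if (n_empty > 0) {
    inform(paste0(n_empty, " time point(s) with all-zero profiles omitted."))
    out <- out %>% filter(!is.na(.data$peak_depth))
  }
  if (nrow(out) < 2L) {
    abort("need at least 2 time points with non-empty profiles.")
  }
  out
}

#' Bulk sinking rate from the deepening of the concentration peak
#'
#' Type I (ordinary least squares) regression of time of the maximum
#' concentration signal (dependent variable) against its depth
#' (independent variable). The slope is in days per metre; its reciprocal
#' is the bulk sinking speed in m per day. A non-positive slope means the
#' peak is not deepening and is flagged as non-sinking instead of being
#' converted to a speed.
#'
#' @param series Data frame with `time` (days) and `peak_depth` (m), e.g.
#'   from [peak_depth_series()].
#' @return One-row tibble: `speed_m_per_d` (`NA` when non-sinking),
#'   `slope_d_per_m`, `sinking` (logical), `n`, `r_squared`.
#' @examples
#' s <- data.frame(peak_depth = seq(100, 500, 100))
#' s$time <- s$peak_depth / 38
#' sinking_rate_regression(s)  # 38 m per day
#' @export
sinking_rate_regression <- function(series) {
  if (nrow(series) < 3L) abort("need at least 3 points.")
  if (diff(range(series$peak_depth)) <= 0) {
    abort("zero depth spread: regression undefined.")
  }
  fit <- lm(time ~ peak_depth, data = series)
  s <- unname(coef(fit)[2])
  sinking <- s > 0
  tss <- sum((series$time - mean(series$time))^2)
  tibble(
    speed_m_per_d = if (sinking) 1 / s else NA_real_,
    slope_d_per_m = s,
    sinking = sinking,
    n = nrow(series),
    r_squared = if (tss > 0) 1 - sum(stats::residuals(fit)^2) / tss else NA_real_
  )
}

#' Maximum sinking speed from a single depth/time displacement
#'
#' The back-of-envelope bound: particles produced at the surface and
#' observed `depth_m` deeper after `elapsed_d` days must have sunk at
#' least `depth_m / elapsed_d` metres per day.
#'
#' @param depth_m Depth travelled (m, >= 0).
#' @param elapsed_d Elapsed time (days, > 0).
#' @return Speed in m per day.
#' @examples
#' max_sinking_speed(900, 10)  # 90
#' @export
max_sinking_speed <- function(depth_m, elapsed_d) {
  if (any(elapsed_d <= 0)) abort("`elapsed_d` must be positive.")
  if (any(depth_m < 0)) abort("`depth_m` must be non-negative.")
  depth_m / elapsed_d
}
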