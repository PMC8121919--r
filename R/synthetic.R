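#' Default archetype specifications
#'
#' Parameters of the five synthetic particle archetypes. They are frozen
#' defaults chosen so that the generated classes reproduce the qualitative
#' ordering of the field morphotype signatures: *dark* is darkest, small
#' and compact; *elongated* has the highest aspect ratio; *flake* is
#' small, bright and smooth; *fluffy* is medium-sized, bright and
#' grey-heterogeneous with a rough boundary; *agglomerated* is a
#' multi-element union of blobs with by far the largest perimeter.
#'
#' Size parameters are lognormal on the characteristic radius (pixels);
#' `grey_mean`/`grey_sd` give the between-object base grey distribution
#' and `texture_sd` the within-object pixel noise.
#'
#' @return Named list of per-archetype parameter lists.
#' @export
archetype_specs <- function() {
  list(
    dark = list(
      r_meanlog = log(6.5), r_sdlog = 0.15,
      grey_mean = 45, grey_sd = 10, texture_sd = 4
    ),
    elongated = list(
      a_meanlog = log(15), a_sdlog = 0.15,
      aspect_min = 4, aspect_max = 7,
      grey_mean = 120, grey_sd = 20, texture_sd = 12
    ),
    flake = list(
      r_meanlog = log(5.4), r_sdlog = 0.12,
      grey_mean = 195, grey_sd = 8, texture_sd = 4
    ),
    fluffy = list(
      r_meanlog = log(7.5), r_sdlog = 0.15, roughness = 0.35,
      grey_mean = 175, grey_sd = 8, texture_sd = 25
    ),
    agglomerated = list(
      n_blobs_min = 5, n_blobs_max = 9,
      r_meanlog = log(6), r_sdlog = 0.2, anchor = 0.95,
      grey_mean = 165, grey_sd = 10, texture_sd = 18
    )
  )
}

# Paint a foreground mask with base grey + texture onto a white canvas.
paint_mask <- function(mask, base_grey, texture_sd) {
  px <- matrix(255, nrow(mask), ncol(mask))
  nfg <- sum(mask)
  px[mask] <- pmin(pmax(base_grey + rnorm(nfg, 0, texture_sd), 5), 235)
  round(px)
}

#' Generate one synthetic particle vignette
#'
#' Draws a single particle of the given archetype on a white canvas:
#' *dark* and *flake* are filled discs (dark vs bright), *elongated* a
#' rotated high-aspect ellipse, *fluffy* a radially perturbed blob with a
#' rough boundary and strong grey texture, *agglomerated* a chained union
#' of overlapping discs. Deterministic given the RNG state (seed it or use
#' [generate_population()]).
#'
#' @param archetype One of `"dark"`, `"elongated"`, `"flake"`, `"fluffy"`,
#'   `"agglomerated"`.
#' @param object_id Identifier for the vignette.
#' @param canvas Canvas side length in pixels; defaults to 64, or 96 for
#'   the spatially extended agglomerated archetype.
#' @param pixel_size_mm Emulated pixel size (default 0.08 mm, a
#'   UVP-like optical scale).
#' @param specs Archetype parameter list, see [archetype_specs()].
#' @return A [snow_vignette()] with attribute `truth` = archetype name.
#' @export
generate_vignette <- function(archetype, object_id = archetype,
                              canvas = NULL, pixel_size_mm = 0.08,
                              specs = archetype_specs()) {
  archetype <- match.arg(archetype, names(specs))
  p <- specs[[archetype]]
  if (is.null(canvas)) {
    canvas <- if (archetype == "agglomerated") 96 else 64
  }
  ctr <- (canvas + 1) / 2
  rr <- matrix(seq_len(canvas), canvas, canvas) - ctr
  cc <- t(rr)

  mask <- switch(archetype,
    dark = ,
    flake = {
      r <- rlnorm(1, p$r_meanlog, p$r_sdlog)
      rr^2 + cc^2 < r^2
    },
    elongated = {
      a <- rlnorm(1, p$a_meanlog, p$a_sdlog)
      aspect <- runif(1, p$aspect_min, p$aspect_max)
      b <- max(a / aspect, 1.2)
      th <- runif(1, 0, pi)
      u <- cc * cos(th) + rr * sin(th)
      w <- -cc * sin(th) + rr * cos(th)
      (u / a)^2 + (w / b)^2 < 1
    },
    fluffy = {
      r0 <- rlnorm(1, p$r_meanlog, p$r_sdlog)
      amp <- rnorm(5, 0, 1) / seq(2, 6)
      phs <- runif(5, 0, 2 * pi)
      theta <- atan2(rr, cc)
      pert <- Reduce(`+`, lapply(seq_along(amp), function(h) {
        amp[h] * cos((h + 1) * theta + phs[h])
      }))
      rtheta <- pmax(r0 * (1 + p$roughness * pert), 2)
      sqrt(rr^2 + cc^2) < rtheta
    },
    agglomerated = {
      nb <- sample(p$n_blobs_min:p$n_blobs_max, 1)
      radii <- rlnorm(nb, p$r_meanlog, p$r_sdlog)
      cx <- numeric(nb)
      cy <- numeric(nb)
      m <- matrix(FALSE, canvas, canvas)
      for (i in seq_len(nb)) {
        if (i == 1) {
          cx[i] <- 0
          cy[i] <- 0
        } else {
          # anchor to a random earlier blob, close enough to overlap
          j <- sample(i - 1, 1)
          ang <- runif(1, 0, 2 * pi)
          d <- p$anchor * (radii[i] + radii[j])
          cx[i] <- cx[j] + d * cos(ang)
          cy[i] <- cy[j] + d * sin(ang)
        }
        m <- m | ((cc - cx[i])^2 + (rr - cy[i])^2 < radii[i]^2)
      }
      m
    }
  )
  if (!any(mask)) {
    # radii are bounded away from zero, but guard the degenerate draw
    mask[round(ctr), round(ctr)] <- TRUE
  }
  base_grey <- min(max(rnorm(1, p$grey_mean, p$grey_sd), 10), 225)
  px <- paint_mask(mask, base_grey, p$texture_sd)
  v <- snow_vignette(px, object_id, pixel_size_mm)
  attr(v, "truth") <- archetype
  v
}

#' Generate a mixed population of synthetic vignettes
#'
#' Draws `n` archetype labels from a multinomial with the given mixture
#' weights and generates one vignette per draw. Deterministic given
#' `seed`.
#'
#' @param n Number of vignettes.
#' @param weights Mixture weights over the five archetypes (summing to 1);
#'   named or in [archetype_specs()] order.
#' @param seed Integer seed.
#' @param id_prefix Prefix for the generated object ids (default
#'   `"syn"`); use distinct prefixes when pooling several populations.
#' @param ... Passed to [generate_vignette()].
#' @return List with `vignettes` (list of [snow_vignette()]) and `truth`
#'   (tibble `object_id`, `truth`).
#' @export
generate_population <- function(n, weights = rep(1 / 5, 5), seed,
                                id_prefix = "syn", ...) {
  if (n < 1) abort("`n` must be at least 1.")
  types <- names(archetype_specs())
  if (!is.null(names(weights))) {
    weights <- weights[types]
  }
  if (length(weights) != 5 || any(is.na(weights)) || any(weights < 0) ||
      abs(sum(weights) - 1) > 1e-8) {
    abort("`weights` must be 5 non-negative values summing to 1.")
  }
  withr::with_seed(seed, {
    draws <- sample(types, n, replace = TRUE, prob = weights)
    ids <- sprintf("%s_%06d", id_prefix, seq_len(n))
    vigs <- lapply(seq_len(n), function(i) {
      generate_vignette(draws[i], object_id = ids[i], ...)
    })
    list(vignettes = vigs, truth = tibble(object_id = ids, truth = draws))
  })
}

#' Specification of a synthetic depth-time concentration field
#'
#' Each morphotype gets a Gaussian concentration peak that starts at the
#' surface at `t0` and deepens at its sinking speed `v`, superposed on a
#' Martin-type background `bg * (z/100)^b` (held constant above
#' `bg_plateau_m` to avoid the unphysical surface blow-up of the power
#' law). Defaults use the two field-estimated sinking speeds (38 m/d for
#' dark, 7.2 m/d for elongated) and plausible mid-range values for the
#' three types whose field speeds could not be estimated; dark gets the
#' weakest attenuation and elongated the strongest, matching their
#' observed vertical behaviour.
#'
#' @param morphotypes Tibble with columns `morphotype`, `v_m_per_d`, `b`,
#'   `peak_width_m`, `peak_amp_per_L`, `bg_per_L`.
#' @param times Sampling times (days).
#' @param depth_max_m,bin_height_m Depth grid (default 0-1000 m in 5 m
#'   bins).
#' @param volume_L Sampled volume per bin per cast (default 112 L, the
#'   campaign-average bin volume).
#' @param n_casts Casts pooled per time point (counts scale with
#'   `n_casts * volume_L`; default 10, emulating the several profiles
#'   available per phase in a field campaign).
#' @param bg_plateau_m Depth above which the background is held constant
#'   (default 50 m).
#' @param t0 Time at which peaks leave the surface (default 0).
#' @return A list of class `snow_field_spec`.
#' @export
field_spec <- function(morphotypes = NULL,
                       times = 1:20,
                       depth_max_m = 1000,
                       bin_height_m = 5,
                       volume_L = 112,
                       n_casts = 10,
                       bg_plateau_m = 50,
                       t0 = 0) {
  if (is.null(morphotypes)) {
    morphotypes <- tibble(
      morphotype = c("dark", "elongated", "flake", "fluffy", "agglomerated"),
      v_m_per_d = c(38, 7.2, 15, 20, 25),
      b = c(-0.4, -1.5, -0.9, -0.8, -1.0),
      peak_width_m = c(30, 25, 30, 30, 35),
      peak_amp_per_L = c(0.6, 0.8, 0.5, 0.5, 0.4),
      bg_per_L = c(0.08, 0.05, 0.05, 0.05, 0.03)
    )
  }
  stopifnot(
    all(morphotypes$v_m_per_d >= 0),
    volume_L > 0, n_casts >= 1, bin_height_m > 0
  )
  structure(
    list(
      morphotypes = morphotypes, times = times,
      depth_max_m = depth_max_m, bin_height_m = bin_height_m,
      volume_L = volume_L, n_casts = n_casts,
      bg_plateau_m = bg_plateau_m, t0 = t0
    ),
    class = "snow_field_spec"
  )
}

# Expected concentration n(z, t) for one morphotype row of the spec.
field_concentration <- function(z, t, row, spec) {
  peak_z <- row$v_m_per_d * (t - spec$t0)
  row$peak_amp_per_L * exp(-(z - peak_z)^2 / (2 * row$peak_width_m^2)) +
    row$bg_per_L * (pmax(z, spec$bg_plateau_m) / 100)^row$b
}

#' Generate a synthetic depth-time concentration field
#'
#' Counts per (time, depth bin, morphotype) are drawn Poisson with mean
#' `n_casts * volume_L * n(z, t)` around the expected field of the spec
#' (or set to the exact expectation with `noiseless = TRUE`). The spec's
#' sinking speeds and attenuation exponents are the recorded ground truth
#' for recovery tests.
#'
#' @param spec A [field_spec()].
#' @param seed Integer seed (ignored when `noiseless = TRUE`).
#' @param noiseless If `TRUE`, counts equal their (non-integer)
#'   expectation exactly.
#' @return List with `profiles` (long tibble: `time`, `depth_bin`,
#'   `morphotype`, `count`, `volume_L`, `concentration_per_L`) and `truth`
#'   (the spec's morphotype table).
#' @export
generate_field <- function(spec = field_spec(), seed = NULL,
                           noiseless = FALSE) {
  stopifnot(inherits(spec, "snow_field_spec"))
  edges <- seq(0, spec$depth_max_m - spec$bin_height_m, spec$bin_height_m)
  centres <- edges + spec$bin_height_m / 2
  vol <- spec$n_casts * spec$volume_L
  grid <- tidyr::crossing(
    time = spec$times,
    depth_bin = edges,
    morphotype = spec$morphotypes$morphotype
  )
  make <- function() {
    grid %>%
      left_join(spec$morphotypes, by = "morphotype") %>%
      mutate(
        .z = .data$depth_bin + spec$bin_height_m / 2,
        .mu = vol * field_concentration(
          .data$.z, .data$time,
          dplyr::pick("v_m_per_d", "peak_width_m", "peak_amp_per_L",
                      "bg_per_L", "b"),
          spec
        ),
        count = if (noiseless) .data$.mu else rpois(n(), .data$.mu),
        volume_L = vol,
        concentration_per_L = .data$count / vol
      ) %>%
      select("time", "depth_bin", "morphotype", "count", "volume_L",
             "concentration_per_L")
  }
  profiles <- if (noiseless || is.null(seed)) {
    make()
  } else {
    withr::with_seed(seed, make())
  }
  list(profiles = profiles, truth = spec$morphotypes)
}
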