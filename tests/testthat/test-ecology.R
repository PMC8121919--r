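test_that("depth binning divides counts by sampled volume and conserves counts", {
  objects <- tibble::tibble(
    object_id = sprintf("o%03d", 1:60),
    cast = "c1", time = 0,
    depth = c(runif(56, 10, 14.9), runif(4, 20, 24.9)),
    morphotype = rep(c("dark", "flake"), c(56, 4))
  )
  volumes <- tibble::tibble(cast = "c1", depth_bin = c(10, 20),
                            volume_L = c(112, 100))
  prof <- bin_concentrations(objects, volumes)
  # 56 particles in a 112 L bin -> 0.5 ind per litre
  expect_equal(
    prof$concentration_per_L[prof$depth_bin == 10 &
                               prof$morphotype == "dark"], 0.5)
  # sampled-but-empty bins are zero
  expect_equal(
    prof$concentration_per_L[prof$depth_bin == 20 &
                               prof$morphotype == "dark"], 0)
  # conservation: concentrations times volumes sum back to the count
  expect_equal(sum(prof$concentration_per_L * prof$volume_L), 60)
  expect_equal(sum(prof$count), 60)

  # an object below the sampled bins is reported by id
  objects$depth[1] <- 999
  expect_error(bin_concentrations(objects, volumes), "o001")
})

test_that("size-spectrum slope matches hand computation and Monte Carlo", {
  # all particles one size: degenerate
  expect_error(size_spectrum_slope(rep(1, 100), bins = size_bins()),
               "undefined")

  # three bins engineered for an exact -3 line: with centres in geometric
  # progression r, counts proportional to centre^-3 give slope exactly -3
  bins <- c(1, 2, 4, 8)
  centres <- sqrt(bins[-4] * bins[-1])
  widths <- diff(bins)
  target <- centres^-3
  counts <- round(target / min(target) * 64 * widths)
  d <- rep(centres, counts)
  res <- size_spectrum_slope(d, volume_L = 1, bins = bins)
  expect_equal(res$slope, -3, tolerance = 1e-9)

  # 1e5 diameters from an exponent -3 power law over [0.5, 20] mm
  withr::with_seed(99, {
    u <- runif(1e5)
    d <- 0.5 / sqrt(1 - u * (1 - (0.5 / 20)^2))
  })
  res2 <- size_spectrum_slope(d, volume_L = 100)
  expect_equal(res2$slope, -3, tolerance = 0.1 / 3)
})

test_that("slope estimator is unbiased across exponents", {
  for (expo in c(-2, -3, -4)) {
    est <- withr::with_seed(1000 - expo, {
      sapply(1:5, function(i) {
        u <- runif(3e4)
        a <- expo + 1
        d <- (0.5^a * (1 - u * (1 - (20 / 0.5)^a)))^(1 / a)
        size_spectrum_slope(d, volume_L = 1)$slope
      })
    })
    expect_equal(mean(est), expo, tolerance = 0.05 * abs(expo))
  }
})

test_that("attenuation fit round-trips exact and noisy power laws", {
  # constant profile: b = 0 and n_100 equals the constant
  prof <- tibble::tibble(depth = seq(52.5, 497.5, 5), concentration = 0.7)
  r <- attenuation_exponent(prof)
  expect_equal(r$b, 0, tolerance = 1e-12)
  expect_equal(r$n_100, 0.7, tolerance = 1e-12)

  # exact synthetic law n(z) = 2 (z/100)^-0.8
  prof2 <- tibble::tibble(depth = seq(52.5, 497.5, 5))
  prof2$concentration <- 2 * (prof2$depth / 100)^-0.8
  r2 <- attenuation_exponent(prof2)
  expect_equal(r2$b, -0.8, tolerance = 1e-9)
  expect_equal(r2$n_100, 2, tolerance = 1e-9)

  # Poisson-noised counts at 112 L bins around the same law
  mt <- tibble::tibble(morphotype = "bg", v_m_per_d = 0, b = -0.8,
                       peak_width_m = 30, peak_amp_per_L = 0,
                       bg_per_L = 0.05)
  fld <- generate_field(field_spec(morphotypes = mt, times = 1), seed = 12)
  prof3 <- dplyr::filter(fld$profiles, depth_bin >= 50, depth_bin < 500)
  prof3$depth <- prof3$depth_bin + 2.5
  prof3$concentration <- prof3$concentration_per_L
  r3 <- attenuation_exponent(prof3)
  expect_equal(r3$b, -0.8, tolerance = 0.1 / 0.8)

  expect_error(
    attenuation_exponent(tibble::tibble(depth = c(100, 200),
                                        concentration = c(1, 0.5))),
    "undefined")
})

test_that("Shannon diversity follows the usual formula and bounds", {
  expect_equal(shannon_diversity(c(0, 0, 3, 0, 0)), 0)
  expect_equal(shannon_diversity(rep(2.5, 5)), log(5))
  expect_equal(shannon_diversity(c(0.5, 0.5, 0, 0, 0)), log(2))
  expect_error(shannon_diversity(rep(0, 5)), "undefined")
  expect_error(shannon_diversity(c(-1, 2)), ">= 0")

  withr::with_seed(4, {
    for (i in 1:200) {
      k <- sample(2:8, 1)
      x <- runif(k)
      h <- shannon_diversity(x)
      expect_true(h >= 0 && h <= log(k) + 1e-12)
    }
  })

  # evenness transfer (rich-to-poor) never decreases H
  x <- c(5, 3, 1, 0.5, 0.2)
  for (eps in c(0.05, 0.1, 0.2)) {
    y <- x
    y[1] <- y[1] - eps
    y[5] <- y[5] + eps
    expect_gte(shannon_diversity(y), shannon_diversity(x))
  }

  # cross-check against vegan on random vectors
  withr::with_seed(9, {
    x <- runif(5)
    expect_equal(shannon_diversity(x),
                 unname(vegan::diversity(matrix(x, 1), index = "shannon")),
                 tolerance = 1e-12)
  })
})

test_that("peak tracking finds maxima, honours ties, skips empty profiles", {
  prof <- tidyr::crossing(time = 1:3, depth_bin = seq(0, 95, 5))
  prof$concentration_per_L <- ifelse(prof$depth_bin == 50, 1, 0.1)
  pk <- peak_depth_series(prof)
  expect_equal(pk$peak_depth, rep(52.5, 3))

  # tie at two equal maxima: shallower bin reported
  prof2 <- tibble::tibble(time = rep(1:2, each = 3),
                          depth_bin = rep(c(10, 20, 30), 2),
                          concentration_per_L = c(1, 0.2, 1, 1, 1, 0.2))
  pk2 <- peak_depth_series(prof2)
  expect_equal(pk2$peak_depth, c(12.5, 12.5))

  # all-zero time point omitted with a message
  prof3 <- tibble::tibble(time = rep(1:3, each = 2),
                          depth_bin = rep(c(10, 20), 3),
                          concentration_per_L = c(1, 0, 0, 0, 0, 1))
  expect_message(pk3 <- peak_depth_series(prof3), "omitted")
  expect_equal(pk3$time, c(1, 3))
})

test_that("sinking regression inverts time-on-depth OLS", {
  # points exactly on t = z/38
  s <- tibble::tibble(peak_depth = seq(100, 500, 100))
  s$time <- s$peak_depth / 38
  r <- sinking_rate_regression(s)
  expect_equal(r$speed_m_per_d, 38, tolerance = 1e-9)
  expect_true(r$sinking)

  # rising peak: flagged non-sinking, no speed
  s2 <- tibble::tibble(time = 1:5, peak_depth = c(500, 400, 300, 200, 100))
  r2 <- sinking_rate_regression(s2)
  expect_false(r2$sinking)
  expect_true(is.na(r2$speed_m_per_d))

  expect_error(sinking_rate_regression(
    tibble::tibble(time = 1:2, peak_depth = c(1, 2))), "3 points")
  expect_error(sinking_rate_regression(
    tibble::tibble(time = 1:3, peak_depth = rep(5, 3))), "spread")
})

test_that("worked displacement example and speed ratio hold", {
  expect_equal(max_sinking_speed(900, 10), 90)
  expect_equal(max_sinking_speed(0, 3), 0)
  expect_error(max_sinking_speed(100, 0), "positive")
  expect_equal(round(38 / 7.2), 5)
})

test_that("the morphotype-poor phase stays least diverse at any k", {
  # phases differ in how many morphotypes are present: a dark-dominated
  # two-type under-ice phase against two rich open-water phases; the
  # designed qualitative contrast (poor phase least diverse) must survive
  # refitting at much larger k
  withr::with_seed(55, {
    w <- list(under_ice = c(0.7, 0.3, 0, 0, 0),
              break_up = c(0.3, 0.25, 0.2, 0.15, 0.1),
              ice_free = rep(0.2, 5))
    pops <- lapply(seq_along(w), function(i) {
      generate_population(350, weights = w[[i]], seed = 550 + i,
                          id_prefix = names(w)[i])
    })
    ft <- feature_table(unlist(lapply(pops, `[[`, "vignettes"),
                               recursive = FALSE))
    phase <- rep(names(w), each = 350)
    ms <- fit_morphospace(ft)
    keep <- ft$object_id %in% ms$scores$object_id
    sens <- diversity_sensitivity(ms$scores, phase[keep],
                                  ks = c(25, 50), seed = 56)
    # k = 5 baseline equals shannon_diversity on morphotype proportions
    km5 <- fit_morphotypes(ms$scores, k = 5, seed = 56, n_restarts = 5)
    h5 <- tapply(km5$cluster, phase[keep], function(cl) {
      shannon_diversity(as.vector(table(cl)))
    })
    base <- dplyr::filter(sens$diversity, k == 5)
    expect_equal(base$H[match(names(h5), base$stratum)],
                 as.vector(h5), tolerance = 1e-12)
    # the under-ice phase is strictly least diverse at the baseline and
    # at every larger k
    for (kk in c(5, 25, 50)) {
      dk <- dplyr::filter(sens$diversity, k == kk)
      expect_lt(dk$H[dk$stratum == "under_ice"],
                min(dk$H[dk$stratum != "under_ice"]))
    }
  })
})
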