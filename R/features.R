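#' Names of the 24 morphological descriptors
#'
#' The descriptor set spans four groups, following standard
#' particle-imaging conventions:
#'
#' * **size** (pixels): `area`, `perimeter`, `esd` (equivalent spherical
#'   diameter), `major_axis`, `minor_axis`, `convex_area`;
#' * **grey intensity** (0 = black): `mean_grey`, `median_grey`,
#'   `min_grey`, `max_grey`, `integrated_grey`, `darkness`
#'   (255 − mean grey, so dark particles score high);
#' * **shape**: `elongation` (major/minor), `circularity`
#'   (4·pi·area/perimeter²), `eccentricity`, `symmetry_major`,
#'   `symmetry_minor` (reflection overlap about the principal axes),
#'   `solidity` (area/convex area);
#' * **structure** (grey-level heterogeneity and boundary complexity):
#'   `grey_sd`, `grey_skew`, `grey_kurt`, `grey_range`,
#'   `perim_area_ratio`, `boundary_index` (log perimeter / log area).
#'
#' @return Character vector of length 24.
#' @export
descriptor_names <- function() {
  c(
    "area", "perimeter", "esd", "major_axis", "minor_axis", "convex_area",
    "mean_grey", "median_grey", "min_grey", "max_grey", "integrated_grey",
    "darkness",
    "elongation", "circularity", "eccentricity", "symmetry_major",
    "symmetry_minor", "solidity",
    "grey_sd", "grey_skew", "grey_kurt", "grey_range",
    "perim_area_ratio", "boundary_index"
  )
}

#' Segment a vignette into its object mask
#'
#' Foreground pixels are those strictly darker than `threshold` (particles
#' are dark on a light background). If several 8-connected components
#' survive thresholding, only the largest is kept, so the mask always holds
#' exactly one object.
#'
#' @param vignette A [snow_vignette()].
#' @param threshold Grey level in `(0, 255)`; pixels with grey `< threshold`
#'   are foreground.
#' @return A logical matrix congruent with the vignette.
#' @examples
#' px <- matrix(255, 9, 9); px[4:6, 4:6] <- 50
#' v <- snow_vignette(px, "blk", 0.08)
#' sum(binarize(v))  # 9
#' @export
binarize <- function(vignette, threshold = 240) {
  stopifnot(inherits(vignette, "snow_vignette"))
  if (threshold <= 0 || threshold >= 255) {
    abort("`threshold` must lie strictly between 0 and 255.")
  }
  fg <- vignette$pixels < threshold
  if (!any(fg)) {
    abort(
      paste0("empty object: no pixel below threshold in '",
             vignette$object_id, "'"),
      class = "snowmorph_empty_object"
    )
  }
  largest_component(fg)
}

#' Extract the 24 morphological descriptors of one particle
#'
#' Grey statistics are computed over foreground pixels only, so the
#' background never influences any descriptor. The perimeter is the exact
#' count of foreground pixel edges exposed to background. Degenerate cases
#' are defined rather than undefined: a zero-variance grey distribution has
#' skewness and kurtosis 0, and a single-pixel object has
#' elongation 1 and perimeter 4.
#'
#' @param vignette A [snow_vignette()].
#' @param mask Logical matrix from [binarize()]; defaults to
#'   `binarize(vignette, threshold)`.
#' @param threshold Passed to [binarize()] when `mask` is missing.
#' @return A one-row tibble: `object_id`, then the 24 descriptors in the
#'   order of [descriptor_names()].
#' @examples
#' px <- matrix(255, 9, 9); px[4:6, 4:6] <- 50
#' extract_features(snow_vignette(px, "blk", 0.08))
#' @export
extract_features <- function(vignette, mask = NULL, threshold = 240) {
  stopifnot(inherits(vignette, "snow_vignette"))
  if (is.null(mask)) {
    mask <- binarize(vignette, threshold)
  }
  if (!is.logical(mask) || !identical(dim(mask), dim(vignette$pixels))) {
    abort("`mask` must be a logical matrix congruent with the vignette.")
  }
  if (!any(mask)) {
    abort(
      paste0("empty object: mask has no foreground pixel for '",
             vignette$object_id, "'"),
      class = "snowmorph_empty_object"
    )
  }

  g <- vignette$pixels[mask]
  area <- sum(mask)
  perimeter <- mask_perimeter(mask)
  ax <- mask_axes(mask)

  mean_grey <- mean(g)
  m2 <- mean((g - mean_grey)^2)
  if (m2 > 0) {
    grey_sd <- sd(g)
    grey_skew <- mean((g - mean_grey)^3) / m2^1.5
    grey_kurt <- mean((g - mean_grey)^4) / m2^2 - 3
  } else {
    grey_sd <- 0
    grey_skew <- 0
    grey_kurt <- 0
  }

  convex_area <- mask_convex_area(mask)
  # hull of pixel squares always contains the pixel squares themselves
  solidity <- min(area / convex_area, 1)

  tibble(
    object_id = vignette$object_id,
    area = area,
    perimeter = perimeter,
    esd = 2 * sqrt(area / pi),
    major_axis = ax$major,
    minor_axis = ax$minor,
    convex_area = convex_area,
    mean_grey = mean_grey,
    median_grey = median(g),
    min_grey = min(g),
    max_grey = max(g),
    integrated_grey = sum(g),
    darkness = 255 - mean_grey,
    elongation = ax$major / ax$minor,
    circularity = 4 * pi * area / perimeter^2,
    eccentricity = ax$eccentricity,
    symmetry_major = mask_symmetry(mask, ax$dir_major),
    symmetry_minor = mask_symmetry(mask, ax$dir_minor),
    solidity = solidity,
    grey_sd = grey_sd,
    grey_skew = grey_skew,
    grey_kurt = grey_kurt,
    grey_range = max(g) - min(g),
    perim_area_ratio = perimeter / area,
    # log perimeter / log area; area 1 makes the denominator 0, in which
    # case the index is defined as 1
    boundary_index = if (area > 1) log(perimeter) / log(area) else 1
  )
}

#' Build the feature table for a batch of vignettes
#'
#' Applies [extract_features()] to every vignette. Vignettes whose
#' segmentation yields no foreground ("empty object") are skipped and their
#' ids reported via a message and the `"failed_ids"` attribute; all other
#' errors propagate.
#'
#' @param vignettes List of [snow_vignette()] objects.
#' @param threshold Segmentation threshold, see [binarize()].
#' @return Tibble with one row per successfully processed vignette,
#'   columns as in [extract_features()]. Attribute `failed_ids` holds the
#'   ids of skipped vignettes (possibly empty).
#' @export
feature_table <- function(vignettes, threshold = 240) {
  if (length(vignettes) == 0L) {
    abort("`vignettes` must contain at least one vignette.")
  }
  ids <- vapply(vignettes, function(v) v$object_id, character(1))
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    abort(paste0(
      "duplicate object_id: ", paste(head(dup, 10), collapse = ", "),
      if (length(dup) > 10) ", ..." else ""
    ))
  }
  failed <- character(0)
  rows <- vector("list", length(vignettes))
  for (i in seq_along(vignettes)) {
    rows[[i]] <- tryCatch(
      extract_features(vignettes[[i]], threshold = threshold),
      snowmorph_empty_object = function(e) {
        failed <<- c(failed, ids[i])
        NULL
      }
    )
  }
  if (length(failed) > 0L) {
    inform(paste0(
      length(failed), " vignette(s) skipped as empty objects: ",
      paste(head(failed, 10), collapse = ", "),
      if (length(failed) > 10) ", ..." else ""
    ))
  }
  out <- bind_rows(rows)
  attr(out, "failed_ids") <- failed
  out
}
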