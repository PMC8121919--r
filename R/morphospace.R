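#' Default set of log-transformed descriptors
#'
#' The strongly right-skewed size and structure descriptors are mapped
#' through `log10(1 + x)` before standardisation. All are non-negative by
#' construction.
#'
#' @return Character vector of descriptor names.
#' @export
default_log_vars <- function() {
  c("area", "perimeter", "esd", "convex_area", "integrated_grey",
    "perim_area_ratio")
}

#' Trim rows with extreme descriptor values
#'
#' For each variable, rows outside the `[f/2, 1 - f/2]` empirical quantile
#' interval are dropped; a row extreme in any variable is removed once
#' (union over variables). The bounds are returned so that objects
#' projected later can be flagged against the same limits.
#'
#' @param data Data frame of descriptors.
#' @param vars Variables to trim on; defaults to all of
#'   [descriptor_names()] present in `data`.
#' @param trim_fraction Total tail mass `f` removed per variable, in
#'   `[0, 0.05]`. Default 0.001, i.e. the 0.1% most extreme values.
#' @return List with `data` (trimmed tibble) and `bounds` (tibble with
#'   `variable`, `lower`, `upper`).
#' @export
trim_extremes <- function(data, vars = NULL, trim_fraction = 0.001) {
  if (trim_fraction < 0 || trim_fraction > 0.05) {
    abort("`trim_fraction` must lie in [0, 0.05].")
  }
  if (is.null(vars)) {
    vars <- intersect(descriptor_names(), names(data))
  }
  missing_vars <- setdiff(vars, names(data))
  if (length(missing_vars) > 0L) {
    abort(paste0("missing variable(s): ", paste(missing_vars, collapse = ", ")))
  }
  bounds <- purrr::map_dfr(vars, function(v) {
    q <- quantile(data[[v]], c(trim_fraction / 2, 1 - trim_fraction / 2),
                  names = FALSE, na.rm = FALSE)
    tibble(variable = v, lower = q[1], upper = q[2])
  })
  keep <- rep(TRUE, nrow(data))
  for (i in seq_len(nrow(bounds))) {
    x <- data[[bounds$variable[i]]]
    keep <- keep & x >= bounds$lower[i] & x <= bounds$upper[i]
  }
  dropped <- sum(!keep)
  if (dropped > 0.2 * nrow(data)) {
    abort(paste0(
      "trimming would drop ", dropped, " of ", nrow(data),
      " rows (> 20%); the table looks pathological"
    ))
  }
  list(data = as_tibble(data[keep, , drop = FALSE]), bounds = bounds)
}

# Apply the fitted log + standardisation transform. `constants` is a tibble
# with variable/log_transform/center/scale columns.
apply_transform <- function(data, constants, ids = NULL) {
  out <- matrix(NA_real_, nrow(data), nrow(constants),
                dimnames = list(NULL, constants$variable))
  for (i in seq_len(nrow(constants))) {
    v <- constants$variable[i]
    x <- data[[v]]
    if (constants$log_transform[i]) {
      if (any(x < 0)) {
        bad <- which(x < 0)[1]
        id <- if (!is.null(ids)) ids[bad] else paste0("row ", bad)
        abort(paste0(
          "negative value in log-transformed variable '", v,
          "' for object '", id, "'"
        ))
      }
      x <- log10(1 + x)
    }
    out[, i] <- (x - constants$center[i]) / constants$scale[i]
  }
  out
}

#' Fit the PCA morphospace
#'
#' Fits the full preprocessing + ordination chain on a descriptor table:
#' trim the most extreme values per variable ([trim_extremes()]),
#' `log10(1 + x)`-transform the skewed variables, standardise every
#' variable to mean 0 / sd 1, and run a principal component analysis on the
#' standardised table (correlation PCA — the descriptors have
#' incommensurate units). Component signs are fixed so that each
#' component's largest-magnitude loading is positive, making fits
#' reproducible across platforms.
#'
#' The descriptor set contains exact linear redundancies (e.g. `darkness`
#' is 255 − `mean_grey`), so the correlation matrix is singular by design;
#' this is harmless as long as `n_components` does not exceed the
#' effective rank, and an error listing the aliased variables is raised if
#' it does.
#'
#' @param data Descriptor table (one row per object); needs all `vars`.
#' @param vars Descriptor columns to use; default [descriptor_names()].
#' @param log_vars Variables to log-transform; default
#'   [default_log_vars()].
#' @param n_components Number of components retained (default 4).
#' @param trim_fraction See [trim_extremes()].
#' @param training_id Free-text identifier of the training set.
#' @param id_col Column holding object ids, used in error messages.
#' @return An object of class `snow_morphospace`: preprocessing constants,
#'   loadings, explained-variance fractions, and the scores of the
#'   (trimmed) training data in `$scores`.
#' @seealso [project_morphospace()], [tidy.snow_morphospace()]
#' @export
fit_morphospace <- function(data,
                            vars = descriptor_names(),
                            log_vars = default_log_vars(),
                            n_components = 4,
                            trim_fraction = 0.001,
                            training_id = "training",
                            id_col = "object_id") {
  missing_vars <- setdiff(vars, names(data))
  if (length(missing_vars) > 0L) {
    abort(paste0("missing variable(s): ", paste(missing_vars, collapse = ", ")))
  }
  if (n_components > length(vars)) {
    abort("`n_components` cannot exceed the number of variables.")
  }
  trimmed <- trim_extremes(data, vars, trim_fraction)
  dat <- trimmed$data
  if (nrow(dat) <= length(vars)) {
    abort("need more rows than variables to fit a morphospace.")
  }

  constants <- tibble(
    variable = vars,
    log_transform = vars %in% log_vars,
    center = NA_real_,
    scale = NA_real_
  )
  ids <- if (id_col %in% names(dat)) dat[[id_col]] else NULL
  raw <- matrix(NA_real_, nrow(dat), length(vars),
                dimnames = list(NULL, vars))
  for (i in seq_along(vars)) {
    x <- dat[[vars[i]]]
    if (constants$log_transform[i]) {
      if (any(x < 0)) {
        abort(paste0("negative value in log-transformed variable '",
                     vars[i], "'"))
      }
      x <- log10(1 + x)
    }
    raw[, i] <- x
  }
  constants$center <- colMeans(raw)
  constants$scale <- apply(raw, 2, sd)
  if (any(constants$scale <= 0)) {
    abort(paste0(
      "zero-variance variable(s) after transformation: ",
      paste(constants$variable[constants$scale <= 0], collapse = ", ")
    ))
  }
  z <- sweep(sweep(raw, 2, constants$center), 2, constants$scale, `/`)

  pca <- prcomp(z, center = FALSE, scale. = FALSE)
  eig <- pca$sdev^2
  rank_tol <- max(eig) * 1e-9
  eff_rank <- sum(eig > rank_tol)
  if (n_components > eff_rank) {
    qrz <- qr(z)
    aliased <- colnames(z)[qrz$pivot[seq(qrz$rank + 1L, ncol(z))]]
    abort(paste0(
      "table is rank-deficient (effective rank ", eff_rank,
      " < ", n_components, " components); collinear variable(s): ",
      paste(aliased, collapse = ", ")
    ))
  }

  rotation <- pca$rotation[, seq_len(n_components), drop = FALSE]
  # sign convention: largest-magnitude loading of each component positive
  for (j in seq_len(n_components)) {
    peak <- which.max(abs(rotation[, j]))
    if (rotation[peak, j] < 0) rotation[, j] <- -rotation[, j]
  }
  colnames(rotation) <- paste0("PC", seq_len(n_components))

  scores <- z %*% rotation
  scores_tbl <- as_tibble(scores)
  if (!is.null(ids)) {
    scores_tbl <- dplyr::bind_cols(tibble(object_id = ids), scores_tbl)
  }

  structure(
    list(
      constants = constants,
      bounds = trimmed$bounds,
      rotation = rotation,
      explained = eig[seq_len(n_components)] / sum(eig),
      eigenvalues = eig,
      n_components = n_components,
      n_train = nrow(dat),
      training_id = training_id,
      scores = scores_tbl
    ),
    class = "snow_morphospace"
  )
}

#' Project objects into a fitted morphospace
#'
#' Applies the stored transform (log set, centring, scaling constants —
#' unchanged from fit time) and the stored loadings to new descriptor
#' rows. Objects outside the stored trim bounds are still projected but
#' flagged in the `out_of_bounds` column.
#'
#' @param data Descriptor table with all fitted variables.
#' @param morphospace A `snow_morphospace` from [fit_morphospace()].
#' @param id_col Column holding object ids (kept in the output when
#'   present).
#' @return Tibble of PC coordinates, one row per input row, plus
#'   `out_of_bounds`.
#' @export
project_morphospace <- function(data, morphospace, id_col = "object_id") {
  stopifnot(inherits(morphospace, "snow_morphospace"))
  vars <- morphospace$constants$variable
  missing_vars <- setdiff(vars, names(data))
  if (length(missing_vars) > 0L) {
    abort(paste0("missing variable(s): ", paste(missing_vars, collapse = ", ")))
  }
  ids <- if (id_col %in% names(data)) data[[id_col]] else NULL
  z <- apply_transform(data, morphospace$constants, ids)
  scores <- z %*% morphospace$rotation
  oob <- rep(FALSE, nrow(data))
  for (i in seq_len(nrow(morphospace$bounds))) {
    v <- morphospace$bounds$variable[i]
    x <- data[[v]]
    oob <- oob | x < morphospace$bounds$lower[i] |
      x > morphospace$bounds$upper[i]
  }
  out <- as_tibble(scores)
  if (!is.null(ids)) {
    out <- dplyr::bind_cols(tibble(object_id = ids), out)
  }
  out$out_of_bounds <- oob
  out
}

#' @export
print.snow_morphospace <- function(x, ...) {
  cat("<snow_morphospace> ", x$n_components, " components over ",
      nrow(x$rotation), " descriptors; trained on ", x$n_train,
      " objects ('", x$training_id, "')\n", sep = "")
  cat("explained variance: ",
      paste0(sprintf("%.1f%%", 100 * x$explained), collapse = ", "),
      " (cumulative ", sprintf("%.1f%%", 100 * sum(x$explained)), ")\n",
      sep = "")
  invisible(x)
}

#' Tidy and summarise a fitted morphospace
#'
#' `tidy()` returns the loadings in long form (one row per descriptor per
#' component); `glance()` returns a one-row summary.
#'
#' @param x A `snow_morphospace`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy snow_morphospace
#' @export
tidy.snow_morphospace <- function(x, ...) {
  as_tibble(x$rotation) %>%
    mutate(variable = rownames(x$rotation), .before = 1) %>%
    tidyr::pivot_longer(-"variable",
                        names_to = "component", values_to = "loading")
}

#' @rdname tidy.snow_morphospace
#' @method glance snow_morphospace
#' @export
glance.snow_morphospace <- function(x, ...) {
  tibble(
    n_components = x$n_components,
    n_descriptors = nrow(x$rotation),
    n_train = x$n_train,
    var_explained = sum(x$explained),
    training_id = x$training_id
  )
}
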