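#' Read an EcoTaxa-style object export
#'
#' Reads a tab-separated per-object table. Exports in the wild come with
#' either a single header row or a second row of type codes such as `[f]`
#' or `[t]`; both dialects are accepted (the type row is detected and
#' dropped). Required columns: `object_id`, `depth` (m) and `cast`;
#' recognised optional columns: `annotation` (category), `time` (days),
#' `esd_mm`, plus any descriptor columns, which are preserved.
#'
#' Rows whose annotation marks a living organism are separated into a
#' zooplankton stream; everything else (non-living) is treated as marine
#' snow. A category is deemed living when it contains "living" or "zoo"
#' but not "not-living"/"non-living".
#'
#' @param path Path to the delimited text file.
#' @return List with `snow` (tibble), `zooplankton` (tibble) and
#'   `n_skipped` (rows dropped as unparseable, with a message).
#' @export
read_objects <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  header <- strsplit(readLines(path, n = 2L), "\t")
  if (length(header) < 1L || length(header[[1]]) < 2L) {
    abort("invalid header: expected a tab-separated header row.")
  }
  type_row <- length(header) == 2L &&
    all(grepl("^\\[.\\]$", trimws(header[[2]])))
  dat <- read.delim(path, sep = "\t", skip = if (type_row) 1L else 0L,
                    header = !type_row, stringsAsFactors = FALSE,
                    check.names = FALSE)
  if (type_row) names(dat) <- trimws(header[[1]])
  dat <- as_tibble(dat)

  required <- c("object_id", "depth", "cast")
  for (col in required) {
    if (!col %in% names(dat)) {
      abort(paste0("missing required column: ", col))
    }
  }
  dat$depth <- suppressWarnings(as.numeric(dat$depth))
  bad <- is.na(dat$depth) | is.na(dat$object_id) | dat$object_id == ""
  n_skipped <- sum(bad)
  if (n_skipped > 0) {
    inform(paste0(n_skipped, " unparseable row(s) skipped."))
    dat <- dat[!bad, , drop = FALSE]
  }
  if ("annotation" %in% names(dat)) {
    ann <- tolower(dat$annotation)
    living <- (grepl("living", ann) | grepl("zoo", ann)) &
      !grepl("no[nt][-_ ]?living", ann)
  } else {
    living <- rep(FALSE, nrow(dat))
  }
  list(
    snow = dat[!living, , drop = FALSE],
    zooplankton = dat[living, , drop = FALSE],
    n_skipped = n_skipped
  )
}

#' Write a tibble as tab-separated text
#'
#' @param data Data frame.
#' @param path Target path.
#' @return `path`, invisibly.
#' @export
write_tsv_table <- function(data, path) {
  write.table(data, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Serialize a fitted morphospace (and optional morphotype model)
#'
#' The morphospace — trim bounds, log set, standardisation constants,
#' loadings, explained variances, training-set id — and, when given, the
#' k-means morphotype model (centroids, names, seed) are written to one
#' portable JSON file.
#'
#' @param morphospace A `snow_morphospace`.
#' @param path Target path.
#' @param model Optional `snow_morphotypes` to append.
#' @return `path`, invisibly.
#' @export
write_morphospace <- function(morphospace, path, model = NULL) {
  stopifnot(inherits(morphospace, "snow_morphospace"))
  out <- list(
    constants = morphospace$constants,
    bounds = morphospace$bounds,
    rotation = morphospace$rotation,
    rotation_rows = rownames(morphospace$rotation),
    explained = morphospace$explained,
    eigenvalues = morphospace$eigenvalues,
    n_components = morphospace$n_components,
    n_train = morphospace$n_train,
    training_id = morphospace$training_id
  )
  if (!is.null(model)) {
    stopifnot(inherits(model, "snow_morphotypes"))
    out$model <- list(
      centroids = model$centroids,
      dim_names = model$dim_names,
      names = model$names,
      k = model$k,
      withinss = model$withinss,
      seed = model$seed,
      n_restarts = model$n_restarts,
      training_id = model$training_id
    )
  }
  jsonlite::write_json(out, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_morphospace
#' @return `read_morphospace()` returns a list with `morphospace` and
#'   `model` (`NULL` when absent).
#' @export
read_morphospace <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  rotation <- as.matrix(raw$rotation)
  rownames(rotation) <- raw$rotation_rows
  colnames(rotation) <- paste0("PC", seq_len(ncol(rotation)))
  ms <- structure(
    list(
      constants = as_tibble(raw$constants),
      bounds = as_tibble(raw$bounds),
      rotation = rotation,
      explained = raw$explained,
      eigenvalues = raw$eigenvalues,
      n_components = raw$n_components,
      n_train = raw$n_train,
      training_id = raw$training_id,
      scores = NULL
    ),
    class = "snow_morphospace"
  )
  model <- NULL
  if (!is.null(raw$model)) {
    model <- structure(
      list(
        centroids = as.matrix(raw$model$centroids),
        dim_names = raw$model$dim_names,
        names = raw$model$names,
        k = raw$model$k,
        cluster = NULL,
        withinss = raw$model$withinss,
        seed = raw$model$seed,
        n_restarts = raw$model$n_restarts,
        training_id = raw$model$training_id
      ),
      class = "snow_morphotypes"
    )
  }
  list(morphospace = ms, model = model)
}
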