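# Optimal assignment (Hungarian algorithm, O(n^3) shortest augmenting
# path) on a square cost matrix; returns for each row the column assigned.
# Used to align arbitrary cluster indices between two classifications.
solve_assignment <- function(cost) {
  n <- nrow(cost)
  stopifnot(ncol(cost) == n)
  # index helpers: virtual row/column 0 stored at position 1
  uu <- numeric(n + 1)
  vv <- numeric(n + 1)
  pp <- integer(n + 1)
  wy <- integer(n + 1)
  for (i in seq_len(n)) {
    pp[1] <- i
    j0 <- 0L
    mv <- rep(Inf, n + 1)
    us <- rep(FALSE, n + 1)
    repeat {
      us[j0 + 1L] <- TRUE
      i0 <- pp[j0 + 1L]
      delta <- Inf
      j1 <- 0L
      for (j in seq_len(n)) {
        if (!us[j + 1L]) {
          cur <- cost[i0, j] - uu[i0 + 1L] - vv[j + 1L]
          if (cur < mv[j + 1L]) {
            mv[j + 1L] <- cur
            wy[j + 1L] <- j0
          }
          if (mv[j + 1L] < delta) {
            delta <- mv[j + 1L]
            j1 <- j
          }
        }
      }
      for (j in 0:n) {
        if (us[j + 1L]) {
          uu[pp[j + 1L] + 1L] <- uu[pp[j + 1L] + 1L] + delta
          vv[j + 1L] <- vv[j + 1L] - delta
        } else {
          mv[j + 1L] <- mv[j + 1L] - delta
        }
      }
      j0 <- j1
      if (pp[j0 + 1L] == 0L) break
    }
    repeat {
      j1 <- wy[j0 + 1L]
      pp[j0 + 1L] <- pp[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  ans <- integer(n)
  for (j in seq_len(n)) {
    if (pp[j + 1L] > 0L) ans[pp[j + 1L]] <- j
  }
  ans
}

#' Fit k-means morphotypes on morphospace coordinates
#'
#' Partitions PC coordinates into `k` clusters with `stats::kmeans`
#' (Hartigan–Wong), taking the best of `n_restarts` random starts; the
#' whole fit is deterministic given `seed`. Clusters are initially named
#' `type_1 ... type_k`; use [name_morphotypes()] to attach the semantic
#' names at `k = 5`.
#'
#' @param scores Data frame or matrix of coordinates; columns matching
#'   `^PC` are used (all columns if none match).
#' @param k Number of clusters (default 5).
#' @param seed Integer seed (required, for reproducibility).
#' @param n_restarts Number of random starts (default 10).
#' @param training_id Free-text identifier of the training set.
#' @return An object of class `snow_morphotypes` with centroids, names,
#'   per-row cluster assignment of the training data, and fit metadata.
#' @export
fit_morphotypes <- function(scores, k = 5, seed, n_restarts = 10,
                            training_id = "training") {
  x <- score_matrix(scores)
  if (k < 1) abort("`k` must be at least 1.")
  if (nrow(x) < k) abort("need at least `k` rows.")
  if (nrow(unique(x)) < k) {
    abort("fewer distinct points than clusters requested.")
  }
  fit <- withr::with_seed(
    seed,
    kmeans(x, centers = k, nstart = n_restarts, iter.max = 100)
  )
  structure(
    list(
      centroids = unname(fit$centers),
      dim_names = colnames(x),
      names = paste0("type_", seq_len(k)),
      k = k,
      cluster = fit$cluster,
      withinss = fit$tot.withinss,
      seed = seed,
      n_restarts = n_restarts,
      training_id = training_id
    ),
    class = "snow_morphotypes"
  )
}

# Extract the coordinate matrix from scores (tibble or matrix).
score_matrix <- function(scores) {
  if (is.matrix(scores)) {
    return(scores)
  }
  pc_cols <- grep("^PC", names(scores), value = TRUE)
  if (length(pc_cols) == 0L) {
    pc_cols <- names(scores)[vapply(scores, is.numeric, logical(1))]
  }
  as.matrix(scores[, pc_cols, drop = FALSE])
}

#' Assign objects to the nearest morphotype centroid
#'
#' Each row is labelled by its nearest centroid (Euclidean distance);
#' exact ties are broken toward the lowest centroid index.
#'
#' @param scores Data frame or matrix of coordinates (see
#'   [fit_morphotypes()]).
#' @param model A `snow_morphotypes` object.
#' @return The input as a tibble with `cluster` (integer) and `morphotype`
#'   (name) columns appended; a bare matrix input returns a tibble of the
#'   two label columns.
#' @export
assign_morphotypes <- function(scores, model) {
  stopifnot(inherits(model, "snow_morphotypes"))
  x <- score_matrix(scores)
  if (ncol(x) != ncol(model$centroids)) {
    abort(paste0(
      "dimensionality mismatch: coordinates have ", ncol(x),
      " columns, centroids ", ncol(model$centroids)
    ))
  }
  d2 <- vapply(
    seq_len(model$k),
    function(j) rowSums(sweep(x, 2, model$centroids[j, ])^2),
    numeric(nrow(x))
  )
  d2 <- matrix(d2, nrow = nrow(x))
  cl <- apply(d2, 1, which.min)  # which.min ties -> lowest index
  lab <- tibble(cluster = as.integer(cl), morphotype = model$names[cl])
  if (is.data.frame(scores)) {
    dplyr::bind_cols(as_tibble(scores), lab)
  } else {
    lab
  }
}

#' Align two cluster labelings
#'
#' Cluster indices are arbitrary, so before two classifications of the
#' same objects can be compared their labels must be matched. The
#' bijection of `labels_b`-levels onto `labels_a`-levels that maximises
#' the confusion-matrix diagonal is found by optimal assignment
#' (Hungarian algorithm).
#'
#' @param labels_a,labels_b Label vectors over the same objects.
#' @return Named character vector: names are `labels_b` levels, values the
#'   matched `labels_a` levels.
#' @export
align_labels <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) {
    abort("`labels_a` and `labels_b` must label the same objects.")
  }
  if (length(labels_a) == 0L) abort("empty labelings.")
  la <- sort(unique(as.character(labels_a)))
  lb <- sort(unique(as.character(labels_b)))
  m <- max(length(la), length(lb))
  cm <- matrix(0, m, m)
  tab <- table(factor(labels_a, la), factor(labels_b, lb))
  cm[seq_along(la), seq_along(lb)] <- tab
  # maximize diagonal == minimize negated counts; rows = b-levels so the
  # result maps each b-level to an a-level
  assign_idx <- solve_assignment(-t(cm))
  mapping <- setNames(rep(NA_character_, length(lb)), lb)
  for (j in seq_along(lb)) {
    if (assign_idx[j] <= length(la)) {
      mapping[j] <- la[assign_idx[j]]
    }
  }
  mapping
}

#' Agreement and Cohen's kappa between two classifications
#'
#' Labels are first aligned with [align_labels()], then percent agreement
#' (100 × diagonal / n) and unweighted Cohen's kappa
#' (`(p_o - p_e) / (1 - p_e)`, chance term from the marginal products) are
#' computed on the aligned confusion matrix.
#'
#' @inheritParams align_labels
#' @return An object of class `snow_agreement` with the aligned confusion
#'   matrix, `agreement_pct`, `kappa`, the label `mapping` used, and a
#'   `degenerate` flag (`TRUE` when both labelings are constant and equal,
#'   where chance agreement is 1 and kappa is reported as 1).
#' @examples
#' agreement_kappa(c(1, 1, 2), c(2, 2, 1))  # perfect after alignment
#' @export
agreement_kappa <- function(labels_a, labels_b) {
  n <- length(labels_a)
  if (n == 0L) abort("empty labelings.")
  mapping <- align_labels(labels_a, labels_b)
  b_aligned <- unname(mapping[as.character(labels_b)])
  lev <- sort(unique(c(as.character(labels_a), b_aligned)))
  cm <- table(
    a = factor(labels_a, lev),
    b = factor(b_aligned, lev)
  )
  p_o <- sum(diag(cm)) / n
  p_e <- sum(rowSums(cm) * colSums(cm)) / n^2
  degenerate <- (1 - p_e) < .Machine$double.eps
  kappa <- if (degenerate) 1 else (p_o - p_e) / (1 - p_e)
  structure(
    list(
      confusion = unclass(cm),
      agreement_pct = 100 * p_o,
      kappa = kappa,
      mapping = mapping,
      n = n,
      degenerate = degenerate
    ),
    class = "snow_agreement"
  )
}

#' @export
print.snow_agreement <- function(x, ...) {
  cat("<snow_agreement> n = ", x$n, ": agreement ",
      sprintf("%.1f%%", x$agreement_pct), ", kappa ",
      sprintf("%.3f", x$kappa),
      if (x$degenerate) " (degenerate: both labelings constant)" else "",
      "\n", sep = "")
  invisible(x)
}

#' @rdname tidy.snow_morphospace
#' @method glance snow_agreement
#' @export
glance.snow_agreement <- function(x, ...) {
  tibble(
    n = x$n,
    agreement_pct = x$agreement_pct,
    kappa = x$kappa,
    degenerate = x$degenerate
  )
}

#' @rdname tidy.snow_morphospace
#' @method tidy snow_agreement
#' @export
tidy.snow_agreement <- function(x, ...) {
  as_tibble(as.data.frame(as.table(x$confusion))) %>%
    rename(label_a = "a", label_b = "b", count = "Freq")
}

#' Name the five morphotypes from cluster medians
#'
#' Deterministic codification of the field-observed cluster signatures:
#' the rules are applied in order and each consumes its cluster, so the
#' naming is always a bijection. 1) largest median perimeter →
#' *agglomerated*; 2) highest median darkness → *dark*; 3) highest median
#' elongation → *elongated*; 4) of the remaining two, higher median grey
#' heterogeneity (`grey_sd`) → *fluffy*, the other → *flake*.
#'
#' @param model A `snow_morphotypes` fit with `k = 5` (other `k` fall back
#'   to `type_1 ... type_k` with a warning).
#' @param features Descriptor table for the labelled objects (needs
#'   `perimeter`, `darkness`, `elongation`, `grey_sd`).
#' @param cluster Integer cluster label per row of `features`; defaults to
#'   the model's training assignment.
#' @return The model with `$names` replaced by the semantic names.
#' @export
name_morphotypes <- function(model, features, cluster = model$cluster) {
  stopifnot(inherits(model, "snow_morphotypes"))
  if (model$k != 5) {
    warn("naming rules are defined for k = 5; keeping generic names.")
    model$names <- paste0("type_", seq_len(model$k))
    return(model)
  }
  if (length(cluster) != nrow(features)) {
    abort("`cluster` must label every row of `features`.")
  }
  med <- features %>%
    mutate(.cluster = cluster) %>%
    group_by(.data$.cluster) %>%
    summarise(
      perimeter = median(.data$perimeter),
      darkness = median(.data$darkness),
      elongation = median(.data$elongation),
      grey_sd = median(.data$grey_sd),
      .groups = "drop"
    ) %>%
    arrange(.data$.cluster)
  if (nrow(med) != 5) {
    abort("`cluster` must cover all five clusters.")
  }
  nm <- rep(NA_character_, 5)
  remaining <- seq_len(5)
  take <- function(stat) {
    i <- remaining[which.max(med[[stat]][remaining])]
    remaining <<- setdiff(remaining, i)
    i
  }
  nm[take("perimeter")] <- "agglomerated"
  nm[take("darkness")] <- "dark"
  nm[take("elongation")] <- "elongated"
  nm[take("grey_sd")] <- "fluffy"
  nm[remaining] <- "flake"
  model$names <- nm
  model
}

#' @export
print.snow_morphotypes <- function(x, ...) {
  cat("<snow_morphotypes> k = ", x$k, " in ",
      ncol(x$centroids), "-D morphospace (seed ", x$seed, ", ",
      x$n_restarts, " restarts)\n", sep = "")
  cat("clusters:", paste(x$names, collapse = ", "), "\n")
  invisible(x)
}

#' @rdname tidy.snow_morphospace
#' @method tidy snow_morphotypes
#' @export
tidy.snow_morphotypes <- function(x, ...) {
  cent <- x$centroids
  colnames(cent) <- x$dim_names %||% paste0("PC", seq_len(ncol(cent)))
  as_tibble(cent) %>%
    mutate(cluster = seq_len(x$k), morphotype = x$names, .before = 1)
}

#' @rdname tidy.snow_morphospace
#' @method glance snow_morphotypes
#' @export
glance.snow_morphotypes <- function(x, ...) {
  tibble(
    k = x$k,
    tot_withinss = x$withinss,
    n_restarts = x$n_restarts,
    seed = x$seed,
    training_id = x$training_id
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
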