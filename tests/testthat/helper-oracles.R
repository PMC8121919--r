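# Brute-force oracles, deliberately naive and independent of the package
# internals.

# Exposed-edge perimeter by looping over every pixel and direction.
oracle_perimeter <- function(mask) {
  nr <- nrow(mask)
  nc <- ncol(mask)
  p <- 0L
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      if (!mask[r, c]) next
      for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        rr <- r + d[1]
        cc <- c + d[2]
        if (rr < 1 || rr > nr || cc < 1 || cc > nc || !mask[rr, cc]) {
          p <- p + 1L
        }
      }
    }
  }
  p
}

# 8-connected component labelling by repeated flood fill from a stack.
oracle_label <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  cur <- 0L
  for (start in which(mask)) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    stack <- start
    while (length(stack) > 0L) {
      s <- stack[1]
      stack <- stack[-1]
      if (lab[s] != 0L) next
      lab[s] <- cur
      r <- (s - 1L) %% nrow(mask) + 1L
      c <- (s - 1L) %/% nrow(mask) + 1L
      for (dr in -1:1) {
        for (dc in -1:1) {
          rr <- r + dr
          cc <- c + dc
          if (rr >= 1 && rr <= nrow(mask) && cc >= 1 && cc <= ncol(mask) &&
              mask[rr, cc] && lab[rr, cc] == 0L) {
            stack <- c(stack, (cc - 1L) * nrow(mask) + rr)
          }
        }
      }
    }
  }
  lab
}

# Cohen's kappa straight from the definition on two label vectors that are
# already in the same label space (no alignment).
oracle_kappa <- function(a, b) {
  lev <- sort(unique(c(a, b)))
  cm <- table(factor(a, lev), factor(b, lev))
  n <- length(a)
  po <- sum(diag(cm)) / n
  pe <- sum(rowSums(cm) * colSums(cm)) / n^2
  (po - pe) / (1 - pe)
}

# All permutations of 1..n (for exhaustive assignment checks).
oracle_perms <- function(n) {
  if (n == 1) {
    return(matrix(1L))
  }
  p <- oracle_perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, ifelse(p >= k, p + 1L, p))
  }))
}

# A random connected-ish small mask plus a matching grey vignette.
random_mask_vignette <- function(nr = 15, nc = 15, p_fg = 0.4) {
  mask <- matrix(runif(nr * nc) < p_fg, nr, nc)
  if (!any(mask)) mask[sample(nr * nc, 1)] <- TRUE
  px <- matrix(255, nr, nc)
  px[mask] <- sample(0:239, sum(mask), replace = TRUE)
  list(mask = mask, vignette = snow_vignette(px, "rand", 1))
}
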