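# Independent brute-force oracles used to cross-check the package's
# implementations. Deliberately naive: no shared code with R/.

# Piecewise-linear interpolation by explicit interval search.
oracle_interp <- function(x, y, xout) {
  vapply(xout, function(q) {
    if (q <= x[1]) return(y[1])
    n <- length(x)
    if (q >= x[n]) return(y[n])
    i <- max(which(x <= q))
    if (x[i] == q) return(y[i])
    y[i] + (y[i + 1] - y[i]) * (q - x[i]) / (x[i + 1] - x[i])
  }, numeric(1))
}

# Circular run-finding by unrolling three copies of the sample vector
# and keeping runs that cover the middle copy.
oracle_circular_runs <- function(above) {
  n <- length(above)
  trip <- rep(above, 3)
  r <- rle(trip)
  ends <- cumsum(r$lengths)
  starts <- c(1L, ends[-length(ends)] + 1L)
  runs <- list()
  for (j in which(r$values)) {
    # keep a run if it contains at least one index of the middle copy
    idx <- starts[j]:ends[j]
    mid <- idx[idx > n & idx <= 2 * n]
    if (length(mid) == 0) next
    # report middle-copy sample indices (1-based, circular)
    runs[[length(runs) + 1L]] <- ((idx - 1L) %% n) + 1L
  }
  # de-duplicate runs that appear in more than one copy
  unique(lapply(runs, function(ix) sort(unique(ix))))
}

# All-pairs maximum distance over boundary-pixel centers (no hull).
oracle_feret <- function(mask, pixel_size = 1) {
  mask <- mask != 0
  px <- which(mask, arr.ind = TRUE)
  nr <- nrow(mask); nc <- ncol(mask)
  at <- function(r, c) {
    ok <- r >= 1 & r <= nr & c >= 1 & c <= nc
    out <- logical(length(r)); out[ok] <- mask[cbind(r[ok], c[ok])]
    out
  }
  interior <- at(px[, 1] - 1, px[, 2]) & at(px[, 1] + 1, px[, 2]) &
    at(px[, 1], px[, 2] - 1) & at(px[, 1], px[, 2] + 1)
  bnd <- px[!interior, , drop = FALSE]
  if (nrow(bnd) < 2) return(0)
  best <- 0
  for (i in seq_len(nrow(bnd) - 1)) {
    d2 <- (bnd[(i + 1):nrow(bnd), 1] - bnd[i, 1])^2 +
      (bnd[(i + 1):nrow(bnd), 2] - bnd[i, 2])^2
    best <- max(best, max(d2))
  }
  sqrt(best) * pixel_size
}

# Exhaustive least-squares window search with lm(): all window lengths
# from min_len to min(max_len, n), longest r2 >= r2_accept wins, else
# max r2.
oracle_rate_window <- function(t, y, min_len = 4, max_len = 8,
                               r2_accept = 0.98) {
  lens <- min_len:min(max_len, length(t))
  fits <- lapply(lens, function(L) {
    m <- stats::lm(y[1:L] ~ t[1:L])
    r2 <- if (stats::var(y[1:L]) == 0) 0
          else suppressWarnings(summary(m)$r.squared)
    list(len = L, slope = unname(stats::coef(m)[2]), r2 = r2)
  })
  r2s <- vapply(fits, `[[`, 0, "r2")
  ok <- which(r2s >= r2_accept)
  fits[[if (length(ok)) ok[length(ok)] else which.max(r2s)]]
}

# Dense evaluation of a falling logistic to locate its half-max.
oracle_sigmoid_halfmax <- function(edge, softness, plateau, background,
                                   lo, hi) {
  xs <- seq(lo, hi, length.out = 200001)
  ys <- background + (plateau - background) / (1 + exp((xs - edge) / softness))
  level <- background + 0.5 * (plateau - background)
  xs[which.min(abs(ys - level))]
}
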