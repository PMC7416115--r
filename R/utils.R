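#' @keywords internal
"_PACKAGE"

## Internal helpers shared across modules.

# Run `code` under a fixed RNG seed without disturbing the caller's RNG
# state. All generators route their randomness through this, so there is
# no dependence on global random state.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

abort_param <- function(...) {
  stop(errorCondition(paste0(...), class = c("engulfquant_param_error",
                                             "engulfquant_error")))
}

abort_geometry <- function(...) {
  stop(errorCondition(paste0(...), class = c("engulfquant_geometry_error",
                                             "engulfquant_error")))
}

abort_detection <- function(...) {
  stop(errorCondition(paste0(...), class = c("engulfquant_detection_error",
                                             "engulfquant_error")))
}

abort_validation <- function(...) {
  stop(errorCondition(paste0(...), class = c("engulfquant_validation_error",
                                             "engulfquant_error")))
}

check_that <- function(cond, ..., abort = abort_param) {
  if (!isTRUE(cond)) abort(...)
  invisible(TRUE)
}

# Unit 2-vector check used by track code.
check_unit_vector <- function(v, name = "gradient_axis", tol = 1e-9) {
  check_that(is.numeric(v) && length(v) == 2L && all(is.finite(v)),
             name, " must be a finite numeric 2-vector")
  check_that(abs(sqrt(sum(v^2)) - 1) <= tol,
             name, " must have unit length (|", name, "| = 1 within ", tol, ")")
  invisible(v)
}

# Bilinear interpolation of a matrix `img` at continuous (x, y) coordinates
# in pixel units, with pixel centers at (i - 0.5, j - 0.5) for column i,
# row j (origin top-left, y increasing downward). Out-of-image queries
# clamp to the border pixel.
bilinear_sample <- function(img, x, y) {
  nr <- nrow(img)
  nc <- ncol(img)
  cx <- pmin(pmax(x - 0.5, 0), nc - 1)   # 0-based continuous column index
  cy <- pmin(pmax(y - 0.5, 0), nr - 1)
  c0 <- pmin(floor(cx), nc - 2)
  r0 <- pmin(floor(cy), nr - 2)
  fx <- cx - c0
  fy <- cy - r0
  i00 <- cbind(r0 + 1, c0 + 1)
  i01 <- cbind(r0 + 1, c0 + 2)
  i10 <- cbind(r0 + 2, c0 + 1)
  i11 <- cbind(r0 + 2, c0 + 2)
  img[i00] * (1 - fx) * (1 - fy) + img[i01] * fx * (1 - fy) +
    img[i10] * (1 - fx) * fy + img[i11] * fx * fy
}

# Centered moving average with window of `k` samples (k odd); edges use
# the available samples only (shrinking window).
moving_average <- function(y, k) {
  k <- as.integer(k)
  if (k <= 1L) return(y)
  n <- length(y)
  half <- (k - 1L) %/% 2L
  cs <- cumsum(c(0, y))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Position of a falling crossing of `level` in sampled signal (pos, y):
# linear interpolation between the bracketing samples. `which` selects
# the first (innermost) or last (outermost) crossing.
falling_crossing <- function(pos, y, level, which = c("last", "first")) {
  which <- match.arg(which)
  n <- length(y)
  idx <- which(y[-n] >= level & y[-1] < level)
  if (length(idx) == 0L) {
    abort_detection("no falling crossing of level ", signif(level, 6),
                    " found in profile")
  }
  i <- if (which == "last") idx[length(idx)] else idx[1]
  if (y[i] == level) return(pos[i])
  frac <- (y[i] - level) / (y[i] - y[i + 1])
  pos[i] + frac * (pos[i + 1] - pos[i])
}

fmt_num <- function(x) {
  # Fixed decimal format used for every numeric CSV column so written
  # files are byte-stable across runs.
  ifelse(is.na(x), "NA", sprintf("%.6f", x))
}
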