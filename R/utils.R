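#' @keywords internal
"_PACKAGE"

## Internal helpers shared across modules. All stochastic code goes through
## with_seed() so no function touches the caller's RNG state.

# Evaluate `code` under a local RNG seeded with `seed`; the global
# .Random.seed is restored afterwards.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

# Robust scale estimate: MAD scaled to the normal; falls back to sd, then 0.
robust_sd <- function(x) {
  x <- x[is.finite(x)]
  if (!length(x)) return(0)
  s <- stats::mad(x)
  if (s == 0) s <- stats::sd(x)
  if (!is.finite(s)) s <- 0
  s
}

stop_param <- function(msg) {
  stop(structure(class = c("rad51kit_param_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

check_scalar <- function(x, name, min = -Inf, strict_min = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_param(sprintf("'%s' must be a single finite number", name))
  if (strict_min && x <= min)
    stop_param(sprintf("'%s' must be > %g", name, min))
  if (!strict_min && x < min)
    stop_param(sprintf("'%s' must be >= %g", name, min))
  invisible(x)
}

# 8-connected component labelling of a logical matrix. Returns an integer
# matrix of labels (0 = background). BFS over a pixel queue; masks here are
# sparse (skeletons, event blobs) so plain R is adequate.
label_components8 <- function(mask) {
  stopifnot(is.matrix(mask))
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  idx <- which(mask)
  if (!length(idx)) return(lab)
  cur <- 0L
  doff <- as.integer(c(-1, 0, 1))
  for (start in idx) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      p <- queue[[1L]]; queue <- queue[-1L]
      r <- ((p - 1L) %% nr) + 1L
      cl <- ((p - 1L) %/% nr) + 1L
      for (dr in doff) for (dc in doff) {
        if (dr == 0L && dc == 0L) next
        rr <- r + dr; cc <- cl + dc
        if (rr < 1L || rr > nr || cc < 1L || cc > nc) next
        q <- (cc - 1L) * nr + rr
        if (mask[q] && lab[q] == 0L) {
          lab[q] <- cur
          queue <- c(queue, q)
        }
      }
    }
  }
  lab
}

# Count of 8-neighbours that are TRUE, for every pixel of a logical matrix.
neighbour_count8 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  m <- matrix(0L, nr + 2L, nc + 2L)
  m[2:(nr + 1L), 2:(nc + 1L)] <- as.integer(mask)
  out <- matrix(0L, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    out <- out + m[(2:(nr + 1L)) + dr, (2:(nc + 1L)) + dc]
  }
  out
}

# Centred moving average with window w (odd); edges use the available
# (shrinking) window so the output has the same length as the input.
running_mean <- function(x, w = 3L) {
  n <- length(x)
  if (w <= 1L || n < 2L) return(x)
  h <- (w - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
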