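## Negative-stain EM filament detection: difference-of-Gaussians contrast
## enhancement, ridge-mask skeletonization, branch tracing and length
## measurement, and the condition comparison statistics.

# Separable Gaussian blur with reflective boundary handling.
gaussian_blur_reflect <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(1L, ceiling(3.5 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma); k <- k / sum(k)
  blur1 <- function(mm) {  # along rows (down columns)
    nr <- nrow(mm)
    ridx <- c(pmin(r:1 + 1L, nr), seq_len(nr), nr - pmin(1:r, nr - 1L))
    pad <- mm[ridx, , drop = FALSE]
    out <- matrix(0, nr, ncol(mm))
    for (o in seq_along(k))
      out <- out + k[o] * pad[(o - 1L) + seq_len(nr), , drop = FALSE]
    out
  }
  t(blur1(t(blur1(m))))
}

#' Difference-of-Gaussians filter
#'
#' Band-pass contrast enhancement used before filament detection: the image
#' blurred at `sigma1_px` minus the image blurred at `sigma2_px`
#' (`sigma1 < sigma2`), with reflective boundary handling. Constants map to
#' zero and the operator is linear.
#'
#' @param img a [micrograph] or numeric matrix.
#' @param sigma1_px,sigma2_px Gaussian widths in pixels; defaults 2 and 6
#'   (about one filament width vs the background scale at ~6 A/px).
#' @return object of the same kind as the input, with filtered intensities.
#' @export
dog_filter <- function(img, sigma1_px = 2, sigma2_px = 6) {
  check_scalar(sigma1_px, "sigma1_px", 0, strict_min = TRUE)
  check_scalar(sigma2_px, "sigma2_px", 0, strict_min = TRUE)
  if (sigma1_px >= sigma2_px)
    stop_param("'sigma1_px' must be smaller than 'sigma2_px'")
  m <- if (inherits(img, "micrograph")) img$data else img
  if (!is.matrix(m)) stop_param("'img' must be a matrix or micrograph")
  out <- gaussian_blur_reflect(m, sigma1_px) -
    gaussian_blur_reflect(m, sigma2_px)
  if (inherits(img, "micrograph")) micrograph(out, img$pixel_size_A) else out
}

# Thin a logical mask to a 1-px-wide 8-connected skeleton by subfield
# simple-point thinning. A pixel is 8-simple iff its Yokoi connectivity
# number is 1 (removal preserves topology); non-endpoint simple pixels are
# deleted in four subfields (r mod 2, c mod 2) so no two 8-adjacent pixels
# are deleted in the same parallel sweep. Unlike plain Zhang-Suen this keeps
# 2-px-wide diagonal structures connected and leaves no redundant staircase
# corners.
skeletonize <- function(mask) {
  stopifnot(is.matrix(mask))
  img <- mask
  nr <- nrow(img); nc <- ncol(img)
  shift <- function(m, dr, dc) {
    out <- matrix(FALSE, nr, nc)
    rs <- max(1, 1 + dr):min(nr, nr + dr)
    cs <- max(1, 1 + dc):min(nc, nc + dc)
    out[rs, cs] <- m[rs - dr, cs - dc]
    out
  }
  ring <- list(c(0, 1), c(-1, 1), c(-1, 0), c(-1, -1),
               c(0, -1), c(1, -1), c(1, 0), c(1, 1))
  rpar <- row(img) %% 2L
  cpar <- col(img) %% 2L
  repeat {
    changed <- FALSE
    for (rp in 0:1) for (cp in 0:1) {
      x <- lapply(ring, function(d) shift(img, d[1L], d[2L]))
      b <- Reduce(`+`, x)
      # Yokoi connectivity number for 8-connectivity, computed on the
      # complement: C8 = sum over the 4-neighbours k in {1,3,5,7} of
      # (!x_k) - (!x_k)(!x_{k+1})(!x_{k+2})
      c8 <- matrix(0L, nr, nc)
      for (k in c(1L, 3L, 5L, 7L)) {
        xk <- x[[k]]
        xk1 <- x[[(k %% 8L) + 1L]]
        xk2 <- x[[((k + 1L) %% 8L) + 1L]]
        c8 <- c8 + (!xk) - ((!xk) & (!xk1) & (!xk2))
      }
      cond <- img & c8 == 1L & b >= 2 & rpar == rp & cpar == cp
      if (any(cond)) {
        img[cond] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  img
}

# Remove short terminal spurs from a skeleton: walk inward from every
# endpoint; when a junction is met within max_spur_px steps, delete the
# walked pixels. Repeated until stable so staircase artifacts do not split
# filaments at spurious junctions.
prune_spurs <- function(skel, max_spur_px = 5L) {
  nr <- nrow(skel); nc <- ncol(skel)
  repeat {
    nb <- neighbour_count8(skel)
    endpoints <- which(skel & nb == 1L)
    if (!length(endpoints)) break
    removed <- FALSE
    for (e in endpoints) {
      if (!skel[e]) next
      path <- integer(); cur <- e; prev <- 0L
      hit_junction <- FALSE
      for (step in seq_len(max_spur_px)) {
        path <- c(path, cur)
        r <- ((cur - 1L) %% nr) + 1L
        cl <- ((cur - 1L) %/% nr) + 1L
        nbrs <- integer()
        for (dr in -1:1) for (dc in -1:1) {
          if (dr == 0L && dc == 0L) next
          rr <- r + dr; cc <- cl + dc
          if (rr < 1L || rr > nr || cc < 1L || cc > nc) next
          q <- (cc - 1L) * nr + rr
          if (skel[q] && q != prev && !(q %in% path)) nbrs <- c(nbrs, q)
        }
        if (!length(nbrs)) break           # isolated stub: leave it alone
        if (length(nbrs) > 1L) {
          # the current pixel is itself a junction: keep it, drop the rest
          path <- path[path != cur]
          hit_junction <- TRUE
          break
        }
        if (nb[nbrs[1L]] > 2L) {
          hit_junction <- TRUE             # next pixel is a junction
          break
        }
        prev <- cur; cur <- nbrs[1L]
      }
      if (hit_junction && length(path)) {
        skel[path] <- FALSE
        removed <- TRUE
      }
    }
    if (!removed) break
  }
  skel
}

# Order the pixels of one branch (degree <= 2 within the branch) into a path.
# `coords` is a 2-column matrix (row, col).
order_branch <- function(coords) {
  n <- nrow(coords)
  if (n <= 2L) return(coords)
  d <- as.matrix(stats::dist(coords, method = "maximum"))
  adj <- d <= 1 & d > 0
  deg <- rowSums(adj)
  start <- which(deg <= 1L)[1L]
  if (is.na(start)) start <- 1L  # loop: start anywhere
  path <- integer(n)
  visited <- logical(n)
  path[1L] <- start; visited[start] <- TRUE
  for (i in 2:n) {
    nb <- which(adj[path[i - 1L], ] & !visited)
    if (!length(nb)) { path <- path[1:(i - 1L)]; break }
    # prefer axial moves for a stable ordering
    if (length(nb) > 1L) {
      dd <- abs(coords[nb, 1L] - coords[path[i - 1L], 1L]) +
            abs(coords[nb, 2L] - coords[path[i - 1L], 2L])
      nb <- nb[order(dd)]
    }
    path[i] <- nb[1L]; visited[nb[1L]] <- TRUE
  }
  coords[path, , drop = FALSE]
}

arc_length_px <- function(path, smooth_px = 1L) {
  if (nrow(path) < 2L) return(0)
  r <- path[, 1L]; c <- path[, 2L]
  if (smooth_px > 1L && nrow(path) > smooth_px) {
    # smooth the polyline before measuring: the 1-px medial axis zigzags
    # laterally inside a noisy ridge band, which inflates raw arc length.
    # Endpoints stay pinned so smoothing does not shorten the trace.
    n <- length(r)
    rs <- running_mean(r, smooth_px); cs <- running_mean(c, smooth_px)
    rs[c(1L, n)] <- r[c(1L, n)]; cs[c(1L, n)] <- c[c(1L, n)]
    r <- rs; c <- cs
  }
  sum(sqrt(diff(r)^2 + diff(c)^2))
}

#' Measure filament traces from a skeleton mask
#'
#' Splits a 1-px-wide binary skeleton at junction pixels (more than two
#' 8-neighbours) and turns each remaining branch of at least `min_length_px`
#' pixels into a trace; arc length counts 1 per axial and `sqrt(2)` per
#' diagonal step, scaled by the pixel size.
#'
#' @param mask logical matrix (a skeleton, or any thin binary mask).
#' @param pixel_size_A Angstrom per pixel.
#' @param min_length_px minimum branch size in pixels.
#' @param intensity optional matrix from which `mean_ridge_intensity` is read.
#' @param prune_spur_px terminal spurs up to this many pixels are removed
#'   before branches are split at junctions (skeletonization artifacts would
#'   otherwise fragment filaments).
#' @param path_smooth_px window (path points) of the moving-average polyline
#'   smoothing applied before arc length is computed; 1 disables smoothing
#'   and gives the raw 1-per-axial, sqrt(2)-per-diagonal step metric.
#' @return a `filament_traces` list; each element has `path` (n x 2 matrix of
#'   row, col), `length_nm`, `n_points`, `mean_ridge_intensity`.
#' @export
traces_from_mask <- function(mask, pixel_size_A, min_length_px = 5L,
                             intensity = NULL, prune_spur_px = 8L,
                             path_smooth_px = 1L) {
  stopifnot(is.matrix(mask))
  check_scalar(pixel_size_A, "pixel_size_A", 0, strict_min = TRUE)
  mask <- mask & TRUE
  if (prune_spur_px > 0L) mask <- prune_spurs(mask, prune_spur_px)
  nb <- neighbour_count8(mask)
  branches <- mask & nb <= 2L
  lab <- label_components8(branches)
  ids <- setdiff(unique(as.vector(lab)), 0L)
  traces <- list()
  for (id in ids) {
    coords <- which(lab == id, arr.ind = TRUE)
    if (nrow(coords) < min_length_px) next
    path <- order_branch(coords)
    if (!is.null(intensity)) {
      # trim the tip overhang of the threshold mask: keep the stretch where
      # the ridge intensity is at least half its plateau (FWHM convention)
      prof <- intensity[path[, 1:2, drop = FALSE]]
      keep <- prof >= 0.5 * stats::median(prof)
      first <- which(keep)[1L]
      last <- utils::tail(which(keep), 1L)
      if (!is.na(first) && last - first + 1L >= min_length_px)
        path <- path[first:last, , drop = FALSE]
    }
    len_nm <- arc_length_px(path, path_smooth_px) * pixel_size_A / 10
    if (len_nm <= 0) next
    traces[[length(traces) + 1L]] <- list(
      path = unname(path[, 1:2, drop = FALSE]),
      length_nm = len_nm,
      n_points = nrow(path),
      mean_ridge_intensity = if (is.null(intensity)) NA_real_
        else mean(intensity[path[, 1:2, drop = FALSE]]))
  }
  structure(traces, class = "filament_traces", pixel_size_A = pixel_size_A)
}

#' Trace filaments in a filtered micrograph
#'
#' Detects curvilinear filaments in a (difference-of-Gaussians filtered)
#' micrograph: pixels at least `threshold_sigmas` robust SDs above the median
#' form the ridge mask, the mask is thinned to a 1-px skeleton, the skeleton
#' is split at junctions, and every branch of at least `min_length_px` pixels
#' becomes a measured trace.
#'
#' @param filtered a [micrograph] or matrix, typically from [dog_filter()].
#' @param pixel_size_A Angstrom per pixel (taken from the micrograph when
#'   omitted).
#' @param threshold_sigmas ridge threshold in robust SDs (default 3).
#' @param min_length_px minimum branch size (default 5).
#' @param path_smooth_px polyline smoothing window for the length metric
#'   (default 7; see [traces_from_mask()]).
#' @return a `filament_traces` list (possibly empty); see
#'   [traces_from_mask()].
#' @examples
#' sim <- simulate_micrograph(sim_micrograph_params(n_filaments = 2, seed = 5))
#' tr <- trace_filaments(dog_filter(sim$image))
#' filament_lengths(tr)
#' @export
trace_filaments <- function(filtered, pixel_size_A = NULL,
                            threshold_sigmas = 3, min_length_px = 5L,
                            path_smooth_px = 7L) {
  m <- if (inherits(filtered, "micrograph")) filtered$data else filtered
  pixel_size_A <- pixel_size_A %||%
    (if (inherits(filtered, "micrograph")) filtered$pixel_size_A else
       stop_param("'pixel_size_A' required for a bare matrix"))
  if (!is.matrix(m)) stop_param("'filtered' must be a matrix or micrograph")
  sigma <- robust_sd(as.vector(m))
  thr <- stats::median(m) + threshold_sigmas * max(sigma,
                                                   .Machine$double.eps)
  mask <- m >= thr
  if (!any(mask))
    return(structure(list(), class = "filament_traces",
                     pixel_size_A = pixel_size_A))
  # alternating thinning and spur pruning dissolves the junction clumps that
  # boundary noise leaves in a single thinning pass
  skel <- skeletonize(mask)
  for (i in 1:2) skel <- skeletonize(prune_spurs(skel, 8L))
  traces_from_mask(skel, pixel_size_A, min_length_px, intensity = m,
                   path_smooth_px = path_smooth_px)
}

#' Lengths of a set of filament traces
#' @param traces a `filament_traces` list.
#' @return numeric vector of lengths in nm.
#' @export
filament_lengths <- function(traces)
  vapply(traces, function(tr) tr$length_nm, numeric(1))

#' @export
print.filament_traces <- function(x, ...) {
  l <- filament_lengths(x)
  cat(sprintf("<filament_traces> %d filaments, median length %.1f nm\n",
              length(x), if (length(l)) stats::median(l) else NA))
  invisible(x)
}

#' Mann-Whitney U test with exact small-sample enumeration
#'
#' Two-sided Mann-Whitney U test. When both samples have at most
#' `exact_max` observations the null distribution is obtained by exact
#' enumeration of all group assignments (a full permutation test on U, valid
#' with ties); otherwise the normal approximation with tie correction and
#' continuity correction is used.
#'
#' @param x,y numeric samples.
#' @param exact_max exact-enumeration size limit per group (default 8).
#' @return list with `u` (U statistic of `x`), `p_value`, `method`.
#' @export
mann_whitney_test <- function(x, y, exact_max = 8L) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 < 1L || n2 < 1L) stop_param("both samples must be non-empty")
  u_stat <- function(a, b) {
    sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  }
  u <- u_stat(x, y)
  mu <- n1 * n2 / 2
  if (n1 <= exact_max && n2 <= exact_max) {
    pool <- c(x, y)
    idx <- utils::combn(n1 + n2, n1)
    us <- apply(idx, 2L, function(i) u_stat(pool[i], pool[-i]))
    p <- mean(abs(us - mu) >= abs(u - mu) - 1e-12)
    return(list(u = u, p_value = p, method = "exact enumeration"))
  }
  nn <- n1 + n2
  ties <- table(c(x, y))
  tie_term <- sum(ties^3 - ties) / (nn * (nn - 1))
  sigma2 <- n1 * n2 / 12 * ((nn + 1) - tie_term)
  if (sigma2 <= 0) return(list(u = u, p_value = 1,
                               method = "degenerate (all tied)"))
  z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sigma2)
  list(u = u, p_value = min(1, 2 * stats::pnorm(-abs(z))),
       method = "normal approximation, tie-corrected")
}

#' Compare two filament detection conditions
#'
#' Pools filament lengths per condition and compares them with a two-sided
#' Mann-Whitney test (lengths are typically non-normal); compares
#' per-micrograph filament counts with a two-sided Welch t-test (as used for
#' count data). Medians and interquartile ranges are reported per condition.
#'
#' @param setA,setB one condition each: a list with one element per
#'   micrograph, each element either a `filament_traces` object or a numeric
#'   vector of lengths (nm).
#' @return a `filament_stats` list: `counts_A`, `counts_B`,
#'   `lengths_A`, `lengths_B`, `median_A/B`, `iqr_A/B`, `count_test`
#'   (t statistic, p), `length_test` (U, p).
#' @export
compare_conditions <- function(setA, setB) {
  get_lengths <- function(set) lapply(set, function(el)
    if (inherits(el, "filament_traces")) filament_lengths(el)
    else as.numeric(el))
  la <- get_lengths(setA); lb <- get_lengths(setB)
  if (!length(la) || !length(lb)) stop_param("both sets must be non-empty")
  counts_a <- vapply(la, length, integer(1))
  counts_b <- vapply(lb, length, integer(1))
  pool_a <- unlist(la); pool_b <- unlist(lb)
  lt <- mann_whitney_test(pool_a, pool_b)
  ct <- if (length(counts_a) >= 2L && length(counts_b) >= 2L &&
            (stats::var(counts_a) + stats::var(counts_b)) > 0) {
    tt <- stats::t.test(counts_a, counts_b)
    list(t = unname(tt$statistic), p_value = tt$p.value)
  } else if (length(counts_a) >= 2L && length(counts_b) >= 2L) {
    list(t = 0, p_value = 1)  # identical constant counts
  } else {
    warning("fewer than 2 micrographs in a set; count t-test disabled")
    list(t = NA_real_, p_value = NA_real_)
  }
  structure(list(counts_A = counts_a, counts_B = counts_b,
                 lengths_A = pool_a, lengths_B = pool_b,
                 median_A = stats::median(pool_a),
                 median_B = stats::median(pool_b),
                 iqr_A = stats::IQR(pool_a), iqr_B = stats::IQR(pool_b),
                 count_test = ct, length_test = lt),
            class = "filament_stats")
}

#' @export
print.filament_stats <- function(x, ...) {
  cat("<filament_stats>\n")
  cat(sprintf("  lengths: median A %.1f nm (IQR %.1f), B %.1f nm (IQR %.1f)\n",
              x$median_A, x$iqr_A, x$median_B, x$iqr_B))
  cat(sprintf("  Mann-Whitney U = %.1f, p = %.4g (%s)\n",
              x$length_test$u, x$length_test$p_value, x$length_test$method))
  cat(sprintf("  counts: Welch t = %.3g, p = %.4g\n",
              x$count_test$t, x$count_test$p_value))
  invisible(x)
}

#' Write a binary overlay mask of traced filaments
#'
#' Renders the traced paths into a binary mask and writes it as a PNG next to
#' the analysed micrograph, for visual confirmation of detection.
#'
#' @param img a [micrograph] (defines the mask size).
#' @param traces a `filament_traces` list.
#' @param path output file path (`.png`).
#' @return the mask matrix, invisibly.
#' @export
write_overlay <- function(img, traces, path) {
  stopifnot(inherits(img, "micrograph"))
  mask <- matrix(0, nrow(img$data), ncol(img$data))
  for (tr in traces) {
    if (any(tr$path[, 1L] < 1 | tr$path[, 1L] > nrow(mask) |
            tr$path[, 2L] < 1 | tr$path[, 2L] > ncol(mask)))
      stop_param("trace outside image bounds")
    mask[tr$path] <- 1
  }
  ok <- tryCatch({ png::writePNG(mask, path); TRUE },
                 error = function(e) FALSE)
  if (!ok) stop(sprintf("cannot write overlay to '%s'", path))
  invisible(mask)
}
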