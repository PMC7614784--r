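## Synthetic negative-stain micrographs containing curvilinear filaments of
## known contour length over a particulate background.

#' Parameters for micrograph simulation
#'
#' @param image_size_px `c(height, width)` in pixels.
#' @param pixel_size_A calibration, Angstrom per pixel (default 5.85, a
#'   30,000x negative-stain magnification).
#' @param n_filaments filament count; drawn as Poisson when
#'   `poisson_count = TRUE`.
#' @param length_meanlog,length_sdlog log-normal parameters of contour length
#'   in nm.
#' @param persistence_px directional persistence of the traced curve: the
#'   per-pixel heading change is Gaussian with sd `1/sqrt(persistence_px)`
#'   radians. Large values give straight filaments.
#' @param filament_width_px Gaussian cross-section sd, pixels.
#' @param filament_amplitude peak intensity of a filament above background.
#' @param background_particles_per_um2 density of disc-shaped background
#'   particles.
#' @param particle_radius_px,particle_amplitude background particle geometry.
#' @param noise_sd additive Gaussian noise.
#' @param poisson_count logical, see `n_filaments`.
#' @param seed RNG seed.
#' @return list of class `sim_micrograph_params`.
#' @export
sim_micrograph_params <- function(image_size_px = c(512, 512),
                                  pixel_size_A = 5.85, n_filaments = 20,
                                  length_meanlog = log(120),
                                  length_sdlog = 0.35,
                                  persistence_px = 400,
                                  filament_width_px = 1.5,
                                  filament_amplitude = 1,
                                  background_particles_per_um2 = 30,
                                  particle_radius_px = 2,
                                  particle_amplitude = 0.5,
                                  noise_sd = 0.05, poisson_count = FALSE,
                                  seed = 1L) {
  if (length(image_size_px) != 2L || any(image_size_px < 16))
    stop_param("'image_size_px' must be c(height, width), both >= 16")
  check_scalar(pixel_size_A, "pixel_size_A", 0, strict_min = TRUE)
  check_scalar(n_filaments, "n_filaments", 0)
  check_scalar(persistence_px, "persistence_px", 0, strict_min = TRUE)
  check_scalar(filament_width_px, "filament_width_px", 0, strict_min = TRUE)
  for (nm in c("filament_amplitude", "background_particles_per_um2",
               "particle_radius_px", "particle_amplitude", "noise_sd"))
    check_scalar(get(nm), nm, 0)
  structure(list(image_size_px = as.integer(image_size_px),
                 pixel_size_A = pixel_size_A, n_filaments = n_filaments,
                 length_meanlog = length_meanlog, length_sdlog = length_sdlog,
                 persistence_px = persistence_px,
                 filament_width_px = filament_width_px,
                 filament_amplitude = filament_amplitude,
                 background_particles_per_um2 = background_particles_per_um2,
                 particle_radius_px = particle_radius_px,
                 particle_amplitude = particle_amplitude,
                 noise_sd = noise_sd, poisson_count = isTRUE(poisson_count),
                 seed = as.integer(seed)),
            class = "sim_micrograph_params")
}

#' Micrograph container
#' @param data numeric matrix (rows = y, cols = x).
#' @param pixel_size_A Angstrom per pixel.
#' @return object of class `micrograph`.
#' @export
micrograph <- function(data, pixel_size_A) {
  if (!is.matrix(data) || !is.numeric(data))
    stop_param("'data' must be a numeric matrix")
  check_scalar(pixel_size_A, "pixel_size_A", 0, strict_min = TRUE)
  structure(list(data = data, pixel_size_A = pixel_size_A),
            class = "micrograph")
}

#' @export
print.micrograph <- function(x, ...) {
  cat(sprintf("<micrograph> %d x %d px, %.3g A/px\n",
              nrow(x$data), ncol(x$data), x$pixel_size_A))
  invisible(x)
}

# Stamp a Gaussian cross-section of sd `w` centred at (r, c) onto `img`.
stamp_gaussian <- function(img, r, c, w, amp) {
  rad <- max(1L, ceiling(3 * w))
  rr <- max(1L, floor(r - rad)):min(nrow(img), ceiling(r + rad))
  cc <- max(1L, floor(c - rad)):min(ncol(img), ceiling(c + rad))
  if (!length(rr) || !length(cc)) return(img)
  g <- outer(exp(-((rr - r)^2) / (2 * w^2)), exp(-((cc - c)^2) / (2 * w^2)))
  img[rr, cc] <- pmax(img[rr, cc], amp * g)
  img
}

# Sample a persistence-random-walk polyline of `len_px` unit steps starting
# at (r0, c0) with heading theta0. Stops at the image margin; returns the
# points and the realized (possibly clipped) step count.
sample_curve <- function(len_px, r0, c0, theta0, persistence_px, nr, nc,
                         margin = 3) {
  n <- max(1L, round(len_px))
  r <- numeric(n + 1L); c <- numeric(n + 1L)
  r[1L] <- r0; c[1L] <- c0
  th <- theta0
  sd_th <- 1 / sqrt(persistence_px)
  k <- 1L
  for (i in seq_len(n)) {
    th <- th + stats::rnorm(1L, 0, sd_th)
    nrp <- r[k] + sin(th); ncp <- c[k] + cos(th)
    if (nrp < margin || nrp > nr - margin || ncp < margin ||
        ncp > nc - margin) break
    k <- k + 1L
    r[k] <- nrp; c[k] <- ncp
  }
  list(r = r[seq_len(k)], c = c[seq_len(k)], steps = k - 1L)
}

#' Simulate a negative-stain micrograph of filaments
#'
#' Renders curvilinear filaments (persistence-sampled smooth curves with a
#' Gaussian cross-section) over disc-shaped background particles and Gaussian
#' noise. Ground truth records each filament's realized contour length; a
#' filament clipped at the image margin is recorded with its clipped length
#' and flagged, with a warning.
#'
#' @param params a [sim_micrograph_params()] object.
#' @param filaments optional explicit placement: data.frame with columns
#'   `row`, `col`, `theta` (radians) and `length_px`; overrides the random
#'   count and length distribution (used for controlled test images).
#' @return list of `image` ([micrograph]) and `truth` (`sim_truth` with
#'   `lengths_nm`, `clipped`, per-filament start points).
#' @examples
#' sim <- simulate_micrograph(sim_micrograph_params(n_filaments = 3, seed = 2))
#' sim$truth$lengths_nm
#' @export
simulate_micrograph <- function(params, filaments = NULL) {
  stopifnot(inherits(params, "sim_micrograph_params"))
  p <- params
  nr <- p$image_size_px[1L]; nc <- p$image_size_px[2L]
  with_seed(p$seed, {
    img <- matrix(0, nr, nc)
    if (is.null(filaments)) {
      nf <- if (p$poisson_count) stats::rpois(1L, p$n_filaments)
            else round(p$n_filaments)
      if (nf > 0) {
        len_nm <- stats::rlnorm(nf, p$length_meanlog, p$length_sdlog)
        len_px <- len_nm * 10 / p$pixel_size_A
        filaments <- data.frame(
          row = stats::runif(nf, 0.15 * nr, 0.85 * nr),
          col = stats::runif(nf, 0.15 * nc, 0.85 * nc),
          theta = stats::runif(nf, 0, 2 * pi),
          length_px = len_px)
      } else {
        filaments <- data.frame(row = numeric(), col = numeric(),
                                theta = numeric(), length_px = numeric())
      }
    }
    n <- nrow(filaments)
    real_len_px <- numeric(n)
    clipped <- logical(n)
    if (n > 0) for (i in seq_len(n)) {
      cv <- sample_curve(filaments$length_px[i], filaments$row[i],
                         filaments$col[i], filaments$theta[i],
                         p$persistence_px, nr, nc)
      real_len_px[i] <- cv$steps
      clipped[i] <- cv$steps < round(filaments$length_px[i])
      for (j in seq_along(cv$r))
        img <- stamp_gaussian(img, cv$r[j], cv$c[j], p$filament_width_px,
                              p$filament_amplitude)
    }
    if (any(clipped))
      warning(sprintf("%d filament(s) clipped at the image margin",
                      sum(clipped)))
    area_um2 <- nr * nc * (p$pixel_size_A / 1e4)^2
    n_part <- stats::rpois(1L, p$background_particles_per_um2 * area_um2)
    if (n_part > 0) {
      pr <- stats::runif(n_part, 1, nr)
      pc <- stats::runif(n_part, 1, nc)
      for (i in seq_len(n_part))
        img <- stamp_gaussian(img, pr[i], pc[i], p$particle_radius_px / 2,
                              p$particle_amplitude)
    }
    if (p$noise_sd > 0)
      img <- img + matrix(stats::rnorm(nr * nc, 0, p$noise_sd), nr, nc)
    list(image = micrograph(img, p$pixel_size_A),
         truth = structure(list(
           lengths_nm = real_len_px * p$pixel_size_A / 10,
           clipped = clipped,
           filaments = filaments,
           n_filaments = n,
           params = p), class = "sim_truth"))
  })
}
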