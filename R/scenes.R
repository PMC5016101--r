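## Ground-truthed synthetic scenes.
##
## A scene emulates the statistical structure the analysis assumes: punctate
## organelles (130-650 nm), a confocal matrix channel that fills organelle
## interiors, STED membrane-protein channels that concentrate into angular
## domains on the organelle rim (with a controllable angular offset between
## the two protein channels), optional unrelated filaments, Gaussian PSF
## blur and Poisson photon noise over a uniform background.

#' Specify a synthetic scene
#'
#' Defaults are the package's standing simulation conditions; see the methods
#' vignette for the rationale behind each value.
#'
#' @param image_size_px integer pair `(rows, cols)`.
#' @param pixel_size_nm pixel size in nm (20 nm, the acquisition raster).
#' @param n_organelles number of organelles; 0 gives a background-only scene.
#' @param diameter_range_nm organelle diameter range, drawn uniformly
#'   (130-650 nm, the observed size range of the organelles).
#' @param morphology_mix named proportions for classes `dot`, `ring`,
#'   `ellipse`; must sum to 1.
#' @param domain_offset_deg angular separation in `[0, 180]` between the
#'   channel-A and channel-B membrane domains of each organelle.
#' @param n_domains_per_organelle number of rim domains per organelle (>= 1).
#' @param n_protein_channels 1 or 2 STED membrane-protein channels.
#' @param psf_fwhm_nm per-channel PSF FWHM in nm (confocal ~250, STED <60);
#'   recycled if scalar.
#' @param photon_budget expected photons per organelle and channel
#'   (defaults 20000 confocal / 8000 STED, giving realistic peak counts of
#'   order 100 per pixel); `Inf`
#'   renders the noiseless unit-amplitude image. Recycled if scalar.
#' @param background_rate background photons per pixel; recycled if scalar.
#' @param filament_channel add an unrelated random-walk filament channel
#'   (mimicking a mitochondrial outer-membrane stain).
#' @param n_filaments number of filaments when `filament_channel` is TRUE.
#' @param brightness_range per-organelle brightness factors are drawn
#'   uniformly from this range and normalized to mean 1, so channel totals
#'   stay exactly `photon_budget * n_organelles` in noiseless renders.
#' @param min_separation_nm minimum center-to-center distance between
#'   organelles (rejection sampling).
#' @param ring_thickness_px rim thickness before PSF blur (2 px = 40 nm; the
#'   membrane itself is far below resolution, so appearance is PSF-dominated).
#' @param domain_sigma_deg angular width (s.d.) of a rim domain.
#' @param ring_base uniform rim intensity relative to a unit domain peak
#'   for `ring`/`ellipse` organelles; the default 0.1 keeps most membrane
#'   signal in domains, as expected for compartmentalized proteins.
#' @param poisson_noise sample Poisson counts from the blurred mean.
#' @param seed integer seed; scenes are bit-reproducible for a fixed
#'   specification object.
#' @return an object of class `scene_spec`.
#' @export
scene_spec <- function(image_size_px = c(512, 512),
                       pixel_size_nm = 20,
                       n_organelles = 40,
                       diameter_range_nm = c(130, 650),
                       morphology_mix = c(dot = 0.35, ring = 0.45, ellipse = 0.20),
                       domain_offset_deg = 0,
                       n_domains_per_organelle = 2,
                       n_protein_channels = 2,
                       psf_fwhm_nm = NULL,
                       photon_budget = NULL,
                       background_rate = NULL,
                       filament_channel = FALSE,
                       n_filaments = 3,
                       brightness_range = c(0.5, 1.5),
                       min_separation_nm = 800,
                       ring_thickness_px = 2,
                       domain_sigma_deg = 25,
                       ring_base = 0.1,
                       poisson_noise = TRUE,
                       seed = 1) {
  n_ch <- 1L + as.integer(n_protein_channels) + as.integer(filament_channel)
  if (is.null(psf_fwhm_nm))
    psf_fwhm_nm <- c(250, rep(60, n_ch - 1L))
  if (is.null(photon_budget))
    photon_budget <- c(20000, rep(8000, n_ch - 1L))
  if (is.null(background_rate))
    background_rate <- c(0.5, rep(0.3, n_ch - 1L))
  spec <- structure(list(
    image_size_px = as.integer(image_size_px),
    pixel_size_nm = pixel_size_nm,
    n_organelles = as.integer(n_organelles),
    diameter_range_nm = as.numeric(diameter_range_nm),
    morphology_mix = morphology_mix,
    domain_offset_deg = domain_offset_deg,
    n_domains_per_organelle = as.integer(n_domains_per_organelle),
    n_protein_channels = as.integer(n_protein_channels),
    psf_fwhm_nm = rep_len(psf_fwhm_nm, n_ch),
    photon_budget = rep_len(photon_budget, n_ch),
    background_rate = rep_len(background_rate, n_ch),
    filament_channel = isTRUE(filament_channel),
    n_filaments = as.integer(n_filaments),
    brightness_range = as.numeric(brightness_range),
    min_separation_nm = min_separation_nm,
    ring_thickness_px = ring_thickness_px,
    domain_sigma_deg = domain_sigma_deg,
    ring_base = ring_base,
    poisson_noise = isTRUE(poisson_noise),
    seed = as.integer(seed)
  ), class = "scene_spec")
  validate_scene_spec(spec)
  spec
}

validate_scene_spec <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  with(spec, {
    stopifnot(length(image_size_px) == 2, all(image_size_px >= 8),
              pixel_size_nm > 0, n_organelles >= 0,
              length(diameter_range_nm) == 2,
              diameter_range_nm[1] < diameter_range_nm[2],
              all(setdiff(names(morphology_mix), c("dot", "ring", "ellipse")) ==
                    character(0)),
              abs(sum(morphology_mix) - 1) < 1e-9, all(morphology_mix >= 0),
              domain_offset_deg >= 0, domain_offset_deg <= 180,
              n_domains_per_organelle >= 1,
              n_protein_channels %in% c(1L, 2L),
              all(psf_fwhm_nm > 0), all(photon_budget > 0),
              all(background_rate >= 0),
              brightness_range[1] > 0,
              brightness_range[1] <= brightness_range[2])
    if (diameter_range_nm[1] / pixel_size_nm < 2)
      stop("organelle diameter below 2 pixels; reject spec")
  })
  invisible(spec)
}

n_channels <- function(spec) {
  1L + spec$n_protein_channels + as.integer(spec$filament_channel)
}

## Angle at pixel offsets (dr, dc) from a center, CCW from the +col axis.
pixel_angles_deg <- function(dr, dc) atan2(-dr, dc) * 180 / pi

wrap_angle_deg <- function(a) {
  a <- (a + 180) %% 360 - 180
  a
}

#' Generate a synthetic scene
#'
#' Renders matrix, membrane-protein and optional filament channels from a
#' [scene_spec()], blurs each with its Gaussian PSF and (optionally) samples
#' Poisson counts. Deterministic for a fixed spec (the seed lives in the
#' spec). Noiseless, background-free channels integrate exactly to
#' `photon_budget * n_organelles`.
#'
#' @param spec a `scene_spec`.
#' @return list of class `perox_scene` with elements `stack` (an
#'   [image_stack()]) and `truth` (organelle table, per-organelle domain
#'   angles, applied drift/chromatic shifts).
#' @export
generate_scene <- function(spec) {
  validate_scene_spec(spec)
  with_seed(spec$seed, generate_scene_impl(spec))
}

generate_scene_impl <- function(spec) {
  nr <- spec$image_size_px[1]; nc <- spec$image_size_px[2]
  px <- spec$pixel_size_nm
  n <- spec$n_organelles
  n_ch <- n_channels(spec)
  sigmas_px <- spec$psf_fwhm_nm / FWHM_FACTOR / px
  r_max <- spec$diameter_range_nm[2] / px / 2
  margin <- ceiling(r_max + 3 * max(sigmas_px) + 2)
  if (n > 0 && (nr - 2 * margin < 1 || nc - 2 * margin < 1))
    stop("image too small for the requested organelles and PSF margins")

  ## --- sample ground truth ---------------------------------------------
  centers <- matrix(numeric(0), 0, 2)
  if (n > 0) {
    min_sep <- spec$min_separation_nm / px
    tries <- 0L
    while (nrow(centers) < n) {
      tries <- tries + 1L
      if (tries > 20000L)
        stop("could not place organelles at the requested density")
      cand <- c(stats::runif(1, margin + 1, nr - margin),
                stats::runif(1, margin + 1, nc - margin))
      if (nrow(centers) == 0 ||
          all((centers[, 1] - cand[1])^2 + (centers[, 2] - cand[2])^2 >=
                min_sep^2))
        centers <- rbind(centers, cand)
    }
  }
  diam_nm <- if (n > 0) stats::runif(n, spec$diameter_range_nm[1],
                                     spec$diameter_range_nm[2]) else numeric(0)
  mix <- spec$morphology_mix[spec$morphology_mix > 0]
  cls <- if (n > 0) sample(names(mix), n, replace = TRUE, prob = mix)
         else character(0)
  bright <- if (n > 0) stats::runif(n, spec$brightness_range[1],
                                    spec$brightness_range[2]) else numeric(0)
  if (n > 0) bright <- bright / mean(bright)
  axis_ratio <- ifelse(cls == "ellipse", stats::runif(n, 1.4, 2.2), 1)
  orient <- stats::runif(max(n, 0), 0, 180)
  nd <- spec$n_domains_per_organelle
  dom_angle <- if (n > 0) matrix(stats::runif(n * nd, 0, 360), n, nd)
               else matrix(numeric(0), 0, nd)

  organelles <- data.frame(
    id = seq_len(n), row = centers[, 1], col = centers[, 2],
    diameter_nm = diam_nm, diameter_px = diam_nm / px,
    class = cls, brightness = bright,
    axis_ratio = axis_ratio, orientation_deg = orient
  )[seq_len(n), , drop = FALSE]
  domains <- if (n > 0)
    data.frame(organelle = rep(seq_len(n), each = nd),
               domain = rep(seq_len(nd), n),
               angle_deg = as.vector(t(dom_angle)))
  else data.frame(organelle = integer(0), domain = integer(0),
                  angle_deg = numeric(0))

  ## --- render structure images -----------------------------------------
  structs <- replicate(n_ch, matrix(0, nr, nc), simplify = FALSE)
  for (i in seq_len(n)) {
    R <- organelles$diameter_px[i] / 2
    w <- as.integer(ceiling(R) + 2L)
    r0 <- round_half_up(organelles$row[i]); c0 <- round_half_up(organelles$col[i])
    rows <- (r0 - w):(r0 + w); cols <- (c0 - w):(c0 + w)
    dr <- matrix(rows - organelles$row[i], length(rows), length(cols))
    dc <- matrix(rep(cols - organelles$col[i], each = length(rows)),
                 length(rows), length(cols))
    ## normalized elliptical radius (u = 1 on the rim)
    phi <- orient[i] * pi / 180
    a <- R * sqrt(axis_ratio[i]); b <- R / sqrt(axis_ratio[i])
    xr <- dc * cos(phi) - (-dr) * sin(phi)
    yr <- dc * sin(phi) + (-dr) * cos(phi)
    u <- sqrt((xr / a)^2 + (yr / b)^2)
    interior <- u <= 1
    stamp_add <- function(ch, stamp) {
      s <- sum(stamp)
      if (s <= 0) return()
      structs[[ch]][rows, cols] <<- structs[[ch]][rows, cols] +
        stamp / s * bright[i]
    }
    stamp_add(1L, interior * 1)
    ## membrane-protein channels
    band <- interior & u > max(0, 1 - spec$ring_thickness_px / R)
    if (!any(band)) band <- interior
    ang <- pixel_angles_deg(dr, dc)
    for (p in seq_len(spec$n_protein_channels)) {
      ch <- 1L + p
      offs <- if (p == 1) 0 else spec$domain_offset_deg
      if (cls[i] == "dot") {
        core <- u <= max(1 / R, 1 / 3)
        if (!any(core)) core <- interior
        stamp_add(ch, core * 1)
      } else {
        wgt <- matrix(spec$ring_base, nrow(band), ncol(band))
        for (d in seq_len(nd)) {
          dth <- wrap_angle_deg(ang - (dom_angle[i, d] + offs))
          wgt <- wgt + exp(-dth^2 / (2 * spec$domain_sigma_deg^2))
        }
        stamp_add(ch, band * wgt)
      }
    }
  }
  if (spec$filament_channel) {
    structs[[n_ch]] <- render_filaments(nr, nc, margin, spec$n_filaments)
  }

  ## --- PSF blur, photon budget, noise ----------------------------------
  budgets <- spec$photon_budget
  noiseless <- !spec$poisson_noise | is.infinite(budgets)
  budgets[is.infinite(budgets)] <- 1
  channels <- vector("list", n_ch)
  for (ch in seq_len(n_ch)) {
    mu <- gaussian_blur(structs[[ch]], sigmas_px[ch]) * budgets[ch] +
      spec$background_rate[ch]
    mu <- pmax(mu, 0) # FFT convolution can leave -1e-17 residues
    channels[[ch]] <- if (noiseless[ch]) mu else
      matrix(stats::rpois(length(mu), mu), nr, nc)
  }

  labels <- c("matrix",
              c("protein_a", "protein_b")[seq_len(spec$n_protein_channels)],
              if (spec$filament_channel) "filament")
  modality <- c("confocal", rep("sted", n_ch - 1L))
  stack <- image_stack(channels, pixel_size_nm = px,
                       labels = labels, modality = modality)
  truth <- structure(list(
    organelles = organelles, domains = domains,
    domain_offset_deg = spec$domain_offset_deg,
    drift_shift_px = c(0L, 0L), chromatic_shift_px = c(0, 0),
    seed = spec$seed
  ), class = "scene_truth")
  structure(list(stack = stack, truth = truth, spec = spec),
            class = "perox_scene")
}

## Unrelated filamentous structure: persistent random walks, one unit of
## total intensity per filament (deposited before PSF blur).
render_filaments <- function(nr, nc, margin, n_filaments, n_steps = 200) {
  img <- matrix(0, nr, nc)
  for (f in seq_len(n_filaments)) {
    p <- c(stats::runif(1, margin + 1, nr - margin),
           stats::runif(1, margin + 1, nc - margin))
    th <- stats::runif(1, 0, 2 * pi)
    pts <- matrix(0, n_steps, 2)
    for (s in seq_len(n_steps)) {
      th <- th + stats::rnorm(1, 0, 0.15)
      p <- p + c(sin(th), cos(th))
      p <- pmin(pmax(p, margin + 1), c(nr, nc) - margin) # reflect at margins
      pts[s, ] <- p
    }
    idx <- cbind(round_half_up(pts[, 1]), round_half_up(pts[, 2]))
    for (s in seq_len(n_steps)) {
      img[idx[s, 1], idx[s, 2]] <- img[idx[s, 1], idx[s, 2]] + 1 / n_steps
    }
  }
  img
}

#' Apply a known integer shift to one channel (drift fixture)
#'
#' Translates the named channel with zero fill and records the shift in the
#' ground truth, so registration can be tested against a known displacement.
#'
#' @param x a `perox_scene` or an `image_stack`.
#' @param shift_px integer `(dr, dc)`; each component must be within the
#'   drift search window (|shift| <= 18), otherwise the fixture would be
#'   outside the testable regime and an error is raised.
#' @param channel channel index to translate.
#' @return object of the same class as `x` with the channel translated.
#' @export
apply_known_shift <- function(x, shift_px, channel) {
  shift_px <- as.integer(round(shift_px))
  if (any(abs(shift_px) > 18))
    stop("shift outside the 18-pixel search window")
  if (inherits(x, "perox_scene")) {
    x$stack <- apply_known_shift(x$stack, shift_px, channel)
    x$truth$drift_shift_px <- shift_px
    return(x)
  }
  stopifnot(inherits(x, "image_stack"),
            channel >= 1, channel <= length(x$channels))
  x$channels[[channel]] <- translate_zero(x$channels[[channel]], shift_px)
  x
}

#' Simulate a two-channel fluorescent bead field
#'
#' Point emitters rendered as Gaussian spots of the per-channel PSF width;
#' the second channel is displaced by `shift_px` (sub-pixel allowed). Used
#' as the fixture for chromatic-shift estimation.
#'
#' @param n_beads number of beads (>= 3 for downstream registration).
#' @param image_size_px integer pair.
#' @param shift_px numeric `(dr, dc)` displacement of channel 2.
#' @param psf_fwhm_nm FWHM pair for (channel 1, channel 2).
#' @param pixel_size_nm pixel size in nm.
#' @param amplitude peak intensity per bead.
#' @param background constant background level.
#' @param poisson_noise sample Poisson counts.
#' @param seed integer seed.
#' @return list with matrices `a`, `b` and the true `positions` (n x 2).
#' @export
simulate_beads <- function(n_beads = 12, image_size_px = c(256, 256),
                           shift_px = c(0, 0), psf_fwhm_nm = c(250, 60),
                           pixel_size_nm = 20, amplitude = 1000,
                           background = 0, poisson_noise = FALSE, seed = 1) {
  stopifnot(n_beads >= 1, all(abs(shift_px) < 20))
  with_seed(seed, {
    nr <- image_size_px[1]; nc <- image_size_px[2]
    sig <- psf_fwhm_nm / FWHM_FACTOR / pixel_size_nm
    margin <- ceiling(4 * max(sig)) + 22
    pos <- matrix(numeric(0), 0, 2)
    tries <- 0L
    while (nrow(pos) < n_beads) {
      tries <- tries + 1L
      if (tries > 10000L) stop("could not place beads")
      cand <- c(stats::runif(1, margin, nr - margin),
                stats::runif(1, margin, nc - margin))
      if (nrow(pos) == 0 ||
          all((pos[, 1] - cand[1])^2 + (pos[, 2] - cand[2])^2 >= 20^2))
        pos <- rbind(pos, cand)
    }
    render <- function(centers, sigma) {
      img <- matrix(0, nr, nc)
      w <- ceiling(4 * sigma) + 1
      for (i in seq_len(nrow(centers))) {
        r0 <- round_half_up(centers[i, 1]); c0 <- round_half_up(centers[i, 2])
        rows <- max(1, r0 - w):min(nr, r0 + w)
        cols <- max(1, c0 - w):min(nc, c0 + w)
        dr <- outer(rows - centers[i, 1], rep(1, length(cols)))
        dc <- outer(rep(1, length(rows)), cols - centers[i, 2])
        img[rows, cols] <- img[rows, cols] +
          amplitude * exp(-(dr^2 + dc^2) / (2 * sigma^2))
      }
      img + background
    }
    a <- render(pos, sig[1])
    b <- render(sweep(pos, 2, shift_px, "+"), sig[2])
    if (poisson_noise) {
      a <- matrix(stats::rpois(length(a), a), nr, nc)
      b <- matrix(stats::rpois(length(b), b), nr, nc)
    }
    list(a = a, b = b, positions = pos)
  })
}
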