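#' Phantom specification
#'
#' Describes one synthetic PET volume: grid, spacing, background SUV noise,
#' and a list of ellipsoidal lesions. Each lesion carries a target SUVmax, a
#' texture correlation length (mm) and a texture amplitude (SUV units) that
#' together control the spatial heterogeneity the co-occurrence features
#' respond to.
#'
#' @param grid_shape integer length-3 `(slices, rows, cols)`.
#' @param spacing `(dx, dy, dz)` mm.
#' @param background_suv_mean,background_suv_sd background normal parameters
#'   (clipped at 0); defaults 1.0 and 0.1, the typical mediastinal blood-pool
#'   level.
#' @param lesions list of lesions, each a list with `center` (mm, x/y/z),
#'   `radii` (mm, ellipsoid semi-axes), `target_suv_max` (> 2.5 for lesions
#'   meant to survive segmentation), `texture_corr_length` (mm) and
#'   `texture_sd` (SUV).
#' @param seed integer seed; the phantom is a pure function of this object.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(32L, 32L, 32L),
                         spacing = c(4, 4, 4),
                         background_suv_mean = 1.0,
                         background_suv_sd = 0.1,
                         lesions = list(),
                         seed = 1L) {
  stopifnot(length(grid_shape) == 3, all(grid_shape >= 1),
            length(spacing) == 3, all(spacing > 0),
            background_suv_mean >= 0, background_suv_sd >= 0)
  structure(list(grid_shape = as.integer(grid_shape),
                 spacing = as.numeric(spacing),
                 background_suv_mean = background_suv_mean,
                 background_suv_sd = background_suv_sd,
                 lesions = lesions,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Convenience single-lesion spec
#'
#' Builds a [phantom_spec] with one centered ellipsoid of a given volume.
#'
#' @param volume_cc lesion volume in cc (sets the ellipsoid radii).
#' @param target_suv_max lesion SUVmax (pinned exactly by rescaling).
#' @param texture_corr_length correlation length of the lesion texture, mm.
#' @param texture_sd texture amplitude, SUV units (0 gives a uniform lesion).
#' @param anisotropy length-3 multipliers on the semi-axes (product ~ 1).
#' @inheritParams phantom_spec
#' @return A [phantom_spec].
#' @export
single_lesion_spec <- function(volume_cc = 20, target_suv_max = 8,
                               texture_corr_length = 6, texture_sd = 1,
                               anisotropy = c(1, 1, 1),
                               grid_shape = c(32L, 32L, 32L),
                               spacing = c(4, 4, 4),
                               seed = 1L) {
  r0 <- (3 * volume_cc * 1000 / (4 * pi))^(1 / 3)
  radii <- r0 * anisotropy / prod(anisotropy)^(1 / 3)
  extent <- rev(grid_shape) * spacing  # (x, y, z) mm
  phantom_spec(grid_shape = grid_shape, spacing = spacing,
               lesions = list(list(center = extent / 2, radii = radii,
                                   target_suv_max = target_suv_max,
                                   texture_corr_length = texture_corr_length,
                                   texture_sd = texture_sd)),
               seed = seed)
}

# Separable Gaussian smoothing of a 3-D array, replicate-padded edges.
.gauss_smooth_3d <- function(a, sigma_vox) {
  for (ax in 1:3) {
    s <- sigma_vox[ax]
    if (s <= 0) next
    h <- max(1L, ceiling(3 * s))
    k <- stats::dnorm(seq(-h, h), sd = s)
    k <- k / sum(k)
    perm <- c(ax, setdiff(1:3, ax))
    a <- aperm(a, perm)
    dd <- dim(a)
    m <- matrix(a, dd[1], dd[2] * dd[3])
    mp <- rbind(m[rep(1, h), , drop = FALSE], m,
                m[rep(nrow(m), h), , drop = FALSE])
    f <- stats::filter(mp, k, sides = 2)
    a <- array(f[(h + 1):(h + dd[1]), , drop = FALSE], dd)
    a <- aperm(a, order(perm))
  }
  a
}

#' Generate one synthetic phantom
#'
#' Background voxels are drawn from a normal distribution (floored at 0).
#' Inside each ellipsoidal lesion the SUV is a smooth Gaussian random field
#' — white noise filtered with a Gaussian kernel of width
#' `texture_corr_length / spacing` voxels — affinely rescaled so that the
#' lesion maximum equals `target_suv_max` exactly and the minimum stays
#' above 2.6 (every lesion voxel therefore survives the 2.5 threshold). The
#' intensity spread is `min(target_suv_max - 2.65, 4 * texture_sd)`, so
#' `texture_sd = 0` produces a uniform lesion at `target_suv_max`. The
#' phantom is deterministic in the `phantom_spec` (including its seed).
#'
#' @param spec a [phantom_spec].
#' @return `list(vol = suv_volume, mask = site_mask)`; the mask is the union
#'   of the lesion ellipsoids.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$grid_shape
  sp <- spec$spacing
  extent <- rev(d) * sp  # (x, y, z)

  set.seed(spec$seed)
  vox <- array(pmax(0, stats::rnorm(prod(d), spec$background_suv_mean,
                                    spec$background_suv_sd)), d)
  mask <- array(FALSE, d)

  # voxel-center coordinates, broadcast per axis
  zc <- (seq_len(d[1]) - 0.5) * sp[3]  # slice axis
  yc <- (seq_len(d[2]) - 0.5) * sp[2]
  xc <- (seq_len(d[3]) - 0.5) * sp[1]

  for (les in spec$lesions) {
    ctr <- les$center; rad <- les$radii
    if (any(ctr - rad < 0) || any(ctr + rad > extent))
      stop("lesion extends outside the grid (center ",
           paste(signif(ctr, 4), collapse = ","), " mm, radii ",
           paste(signif(rad, 4), collapse = ","), " mm)")
    q <- outer(outer((zc - ctr[3])^2 / rad[3]^2,
                     (yc - ctr[2])^2 / rad[2]^2, `+`),
               (xc - ctr[1])^2 / rad[1]^2, `+`)
    inside <- q <= 1
    if (!any(inside)) next
    target <- les$target_suv_max
    tsd <- les$texture_sd
    if (tsd <= 0) {
      vox[inside] <- target
    } else {
      noise <- array(stats::rnorm(prod(d)), d)
      sigma_vox <- les$texture_corr_length / c(sp[3], sp[2], sp[1])
      field <- .gauss_smooth_3d(noise, sigma_vox)[inside]
      rng <- range(field)
      if (rng[1] == rng[2]) {
        vox[inside] <- target
      } else {
        spread <- min(target - 2.65, 4 * tsd)
        u <- (field - rng[1]) / (rng[2] - rng[1])
        vox[inside] <- (target - spread) + spread * u
      }
    }
    mask <- mask | inside
  }
  list(vol = suv_volume(vox, sp), mask = site_mask(mask))
}

#' Class-conditional cohort model
#'
#' Distributions of the lesion parameters for the refractory and
#' non-refractory classes. Each parameter is drawn log-normally around a
#' class median with log-sd `sigma`, then clamped to its plausible range.
#' The defaults emulate an early-stage mediastinal Hodgkin cohort:
#' prevalence 12/169; refractory lesions hotter (higher SUVmax), bulkier and
#' more heterogeneous (shorter texture correlation length, larger texture
#' amplitude) than non-refractory ones. Secondary outcomes: relapse among
#' the non-refractory at rate 7/157, death from lymphoma among the
#' refractory at rate 4/12.
#'
#' @param prevalence refractory prevalence in (0,1).
#' @param refractory,nonrefractory named lists with elements `suv_max`,
#'   `volume_cc`, `corr_length`, `texture_sd`, each `c(median, sigma)`.
#' @param relapse_rate P(relapse | not refractory).
#' @param death_rate P(death from HL | refractory).
#' @return An object of class `class_model`.
#' @export
class_model <- function(prevalence = 12 / 169,
                        refractory = list(suv_max = c(10, 0.30),
                                          volume_cc = c(35, 0.40),
                                          corr_length = c(4, 0.20),
                                          texture_sd = c(1.2, 0.30)),
                        nonrefractory = list(suv_max = c(6, 0.35),
                                             volume_cc = c(15, 0.50),
                                             corr_length = c(8, 0.20),
                                             texture_sd = c(0.6, 0.30)),
                        relapse_rate = 7 / 157,
                        death_rate = 4 / 12) {
  stopifnot(prevalence > 0, prevalence < 1)
  for (cls in list(refractory, nonrefractory))
    for (nm in c("suv_max", "volume_cc", "corr_length", "texture_sd"))
      stopifnot(length(cls[[nm]]) == 2, cls[[nm]][1] > 0, cls[[nm]][2] >= 0)
  structure(list(prevalence = prevalence, refractory = refractory,
                 nonrefractory = nonrefractory,
                 relapse_rate = relapse_rate, death_rate = death_rate),
            class = "class_model")
}

.draw_lognormal <- function(par, n = 1) par[1] * exp(stats::rnorm(n, 0, par[2]))

#' Generate a synthetic patient cohort
#'
#' Draws refractory labels by prevalence (redrawing, with a message, until
#' both classes have at least 2 members), then one mediastinal phantom per
#' patient with lesion parameters from the class-conditional distributions.
#' Lesion volumes are clamped to `[7, 90]` cc so every lesion passes the
#' 5 cc exclusion after voxelization; SUVmax is clamped to `[3.2, 25]`, the
#' correlation length to `[1.5, 16]` mm. Deterministic under `seed`.
#'
#' @param model a [class_model].
#' @param n_patients cohort size (>= 4).
#' @param seed integer seed.
#' @param grid_shape,spacing phantom grid (per patient).
#' @return `list(patients = list of patient_record, truth = data.frame)`;
#'   `truth` records the designed per-patient parameters.
#' @export
generate_cohort <- function(model, n_patients, seed = 1L,
                            grid_shape = c(32L, 32L, 32L),
                            spacing = c(4, 4, 4)) {
  stopifnot(inherits(model, "class_model"), n_patients >= 4)
  set.seed(seed)
  repeat {
    refr <- stats::runif(n_patients) < model$prevalence
    if (sum(refr) >= 2 && sum(!refr) >= 2) break
    message("redrawing labels: a class had fewer than 2 members")
  }
  relapsed <- !refr & stats::runif(n_patients) < model$relapse_rate
  death <- refr & stats::runif(n_patients) < model$death_rate

  max_r <- min(rev(grid_shape) * spacing) / 2 - max(spacing)
  patients <- vector("list", n_patients)
  truth <- vector("list", n_patients)
  for (p in seq_len(n_patients)) {
    cls <- if (refr[p]) model$refractory else model$nonrefractory
    suvmax <- min(25, max(3.2, .draw_lognormal(cls$suv_max)))
    vol_cc <- min(90, max(7, .draw_lognormal(cls$volume_cc)))
    corr_len <- min(16, max(1.5, .draw_lognormal(cls$corr_length)))
    tsd <- .draw_lognormal(cls$texture_sd)
    aniso <- exp(stats::rnorm(3, 0, 0.15))
    r0 <- (3 * vol_cc * 1000 / (4 * pi))^(1 / 3)
    radii <- pmin(max_r, r0 * aniso / prod(aniso)^(1 / 3))
    pseed <- sample.int(.Machine$integer.max, 1)

    extent <- rev(grid_shape) * spacing
    spec <- phantom_spec(grid_shape = grid_shape, spacing = spacing,
                         lesions = list(list(center = extent / 2,
                                             radii = radii,
                                             target_suv_max = suvmax,
                                             texture_corr_length = corr_len,
                                             texture_sd = tsd)),
                         seed = pseed)
    ph <- generate_phantom(spec)
    pid <- sprintf("P%03d", p)
    patients[[p]] <- patient_record(pid,
                                    sites = list(list(vol = ph$vol, mask = ph$mask)),
                                    refractory = refr[p], relapsed = relapsed[p],
                                    death_from_hl = death[p])
    truth[[p]] <- data.frame(patient_id = pid, refractory = refr[p],
                             relapsed = relapsed[p], death_from_hl = death[p],
                             target_suv_max = suvmax, volume_cc = vol_cc,
                             corr_length = corr_len, texture_sd = tsd,
                             phantom_seed = pseed)
  }
  list(patients = patients, truth = do.call(rbind, truth))
}
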