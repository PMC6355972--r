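# Synthetic phantoms with exact analytic ground truth.
#
# Every generator seeds its own RNG scope (withr::with_seed), so a fixed
# seed regenerates byte-identical output and nothing leaks into the
# caller's RNG stream.

.defaultSpacing <- function() c(y = 0.2, x = 0.2, z = 0.4)

# voxel-centre coordinate vectors, origin at the array corner
.centers <- function(n, sp) (seq_len(n) - 0.5) * sp

.noisify <- function(arr, noiseSd, noiseModel = "gaussian") {
  if (noiseModel == "poisson") {
    arr[] <- stats::rpois(length(arr), lambda = pmax(arr, 0))
  } else if (noiseSd > 0) {
    arr <- arr + stats::rnorm(length(arr), sd = noiseSd)
  }
  pmax(arr, 0)
}

.checkIntensities <- function(fg, bg) {
  if (!(fg > bg) || bg < 0)
    stop("need foreground > background >= 0 (got fg=", fg, ", bg=", bg, ")")
}

# squared-distance field from a centre, anisotropic spacing
.radialSq <- function(dims, spacing, center) {
  dy2 <- (.centers(dims[1], spacing["y"]) - center[1])^2
  dx2 <- (.centers(dims[2], spacing["x"]) - center[2])^2
  dz2 <- (.centers(dims[3], spacing["z"]) - center[3])^2
  outer(outer(dy2, dx2, "+"), dz2, "+")
}

#' Digitized sphere phantom
#'
#' Voxelizes a solid sphere of known radius (the in-silico analog of the
#' fluorescent calibration microbeads, nominal diameters 1 um and
#' 15 um): a voxel is foreground when its centre lies inside the sphere.
#' Ground truth is the analytic volume \eqn{4/3 \pi r^3} and area
#' \eqn{4 \pi r^2}.
#'
#' @param radiusUm sphere radius, micrometres. Must be at least twice
#'   the largest voxel pitch to be resolvable.
#' @param spacingUm voxel pitch `(y, x, z)` in micrometres. The default
#'   `0.2 x 0.2 x 0.4` reproduces a typical high-NA confocal acquisition
#'   with a 0.4-um z interval, so anisotropy is exercised by default.
#' @param intensityFg,intensityBg foreground / background intensity.
#' @param noiseSd additive Gaussian noise SD (clipped at zero).
#' @param noiseModel `"gaussian"` (default) or `"poisson"`.
#' @param padUm padding between sphere and stack border, micrometres.
#' @param centerUm optional sphere centre `(y, x, z)` in micrometres
#'   from the array corner; default centred. Stack extent is unchanged,
#'   so off-centre spheres can be pushed against the border on purpose.
#' @param seed integer RNG seed.
#' @return `list(stack = ImageStack, truth = PhantomTruth)`.
#' @examples
#' ph <- makeSphereStack(5, spacingUm = c(0.4, 0.4, 0.4))
#' truthValues(ph$truth)$volume_um3  # 4/3 pi 5^3
#' @export
makeSphereStack <- function(radiusUm, spacingUm = .defaultSpacing(),
                            intensityFg = 100, intensityBg = 10,
                            noiseSd = 0, noiseModel = c("gaussian", "poisson"),
                            padUm = 2, centerUm = NULL, seed = 1) {
  noiseModel <- match.arg(noiseModel)
  spacingUm <- stats::setNames(as.numeric(spacingUm), c("y", "x", "z"))
  if (radiusUm < 2 * max(spacingUm))
    stop("radius ", radiusUm, " um is below the resolvable size (need >= 2 x max spacing = ",
         2 * max(spacingUm), " um)")
  .checkIntensities(intensityFg, intensityBg)
  ext <- 2 * (radiusUm + padUm)
  dims <- pmax(4L, as.integer(ceiling(ext / spacingUm)))
  if (is.null(centerUm)) centerUm <- dims * spacingUm / 2

  inside <- .radialSq(dims, spacingUm, centerUm) <= radiusUm^2
  img <- array(intensityBg, dim = dims)
  img[inside] <- intensityFg
  img <- withr::with_seed(seed, .noisify(img, noiseSd, noiseModel))

  stack <- ImageStack(img, spacingUm, channelNames = "membrane",
                      meta = list(phantom = "sphere"))
  truth <- PhantomTruth("sphere",
    params = list(radius_um = radiusUm, spacing_um = spacingUm,
                  intensity_fg = intensityFg, intensity_bg = intensityBg,
                  noise_sd = noiseSd, center_um = centerUm),
    seed = seed,
    truth = list(volume_um3 = 4 / 3 * pi * radiusUm^3,
                 area_um2 = 4 * pi * radiusUm^2,
                 sphericity = 1))
  list(stack = stack, truth = truth)
}

#' Digitized ellipsoid phantom
#'
#' Axis-aligned solid ellipsoid. Truth volume is \eqn{4/3 \pi abc};
#' truth area uses the exact spheroid formula when two semi-axes are
#' equal and the Thomsen approximation (flagged in the truth as
#' `area_approximate`) otherwise.
#'
#' @param semiAxesUm semi-axes `(y, x, z)` in micrometres.
#' @inheritParams makeSphereStack
#' @return `list(stack, truth)` as for [makeSphereStack()].
#' @export
makeEllipsoidStack <- function(semiAxesUm, spacingUm = .defaultSpacing(),
                               intensityFg = 100, intensityBg = 10,
                               noiseSd = 0, padUm = 2, seed = 1) {
  spacingUm <- stats::setNames(as.numeric(spacingUm), c("y", "x", "z"))
  if (min(semiAxesUm) < 2 * max(spacingUm))
    stop("smallest semi-axis is below the resolvable size")
  .checkIntensities(intensityFg, intensityBg)
  dims <- as.integer(ceiling(2 * (semiAxesUm + padUm) / spacingUm))
  ctr <- dims * spacingUm / 2
  ny <- .centers(dims[1], spacingUm["y"]); nx <- .centers(dims[2], spacingUm["x"])
  nz <- .centers(dims[3], spacingUm["z"])
  q <- outer(outer(((ny - ctr[1]) / semiAxesUm[1])^2,
                   ((nx - ctr[2]) / semiAxesUm[2])^2, "+"),
             ((nz - ctr[3]) / semiAxesUm[3])^2, "+")
  img <- array(intensityBg, dim = dims)
  img[q <= 1] <- intensityFg
  img <- withr::with_seed(seed, .noisify(img, noiseSd))

  a <- sort(as.numeric(semiAxesUm))
  area <- .ellipsoidArea(a[1], a[2], a[3])
  vol <- 4 / 3 * pi * prod(semiAxesUm)
  truth <- PhantomTruth("ellipsoid",
    params = list(semi_axes_um = semiAxesUm, spacing_um = spacingUm,
                  noise_sd = noiseSd),
    seed = seed,
    truth = list(volume_um3 = vol, area_um2 = area$area,
                 area_approximate = area$approximate,
                 sphericity = pi^(1 / 3) * (6 * vol)^(2 / 3) / area$area))
  list(stack = ImageStack(img, spacingUm, "membrane",
                          meta = list(phantom = "ellipsoid")),
       truth = truth)
}

# exact for spheroids, Thomsen (p = 1.6075) otherwise
.ellipsoidArea <- function(a, b, c) {
  tol <- 1e-9
  if (abs(a - c) < tol * c)           # sphere
    return(list(area = 4 * pi * a^2, approximate = FALSE))
  if (abs(a - b) < tol * b) {         # prolate: a = b < c
    e <- sqrt(1 - a^2 / c^2)
    return(list(area = 2 * pi * a^2 * (1 + c / (a * e) * asin(e)),
                approximate = FALSE))
  }
  if (abs(b - c) < tol * c) {         # oblate: a < b = c
    e <- sqrt(1 - a^2 / c^2)
    return(list(area = 2 * pi * c^2 + pi * a^2 / e * log((1 + e) / (1 - e)),
                approximate = FALSE))
  }
  p <- 1.6075
  list(area = 4 * pi * ((a^p * b^p + a^p * c^p + b^p * c^p) / 3)^(1 / p),
       approximate = TRUE)
}

#' Sphere-with-protrusion phantom
#'
#' A spherical cell body with a single capsule-shaped protrusion along
#' +x, emulating a cell extending a protrusion into a fast-relaxing
#' hydrogel. The arm is a cylinder of radius `r` spanning the interval
#' `[R, R + L]` from the body centre, closed by a hemispherical cap at
#' each end; the inner cap fills the neck where the cylinder meets the
#' body so the shape has no pinch point. The union volume is exact:
#' \deqn{V = \tfrac{4}{3}\pi R^3 + \pi r^2 L + \tfrac{2}{3}\pi r^3 +
#'   \frac{\pi r^4}{4R},}
#' the last term being the sliver of the inner cap outside the body.
#'
#' @param bodyRadiusUm body radius `R`, micrometres.
#' @param armLengthUm cylinder length `L`; `0` means no arm (pure
#'   sphere). Positive values must be at least `armRadiusUm` so the end
#'   caps stay inside the cylinder's span.
#' @param armRadiusUm arm radius `r`; must be smaller than the body.
#' @inheritParams makeSphereStack
#' @return `list(stack, truth)`; `truth$sphericity` is `NA` (no closed
#'   form for the joined surface) but is guaranteed below the sphere's.
#' @export
makeProtrusionStack <- function(bodyRadiusUm = 5, armLengthUm = 10,
                                armRadiusUm = 1,
                                spacingUm = .defaultSpacing(),
                                intensityFg = 100, intensityBg = 10,
                                noiseSd = 0, padUm = 2, seed = 1) {
  spacingUm <- stats::setNames(as.numeric(spacingUm), c("y", "x", "z"))
  R <- bodyRadiusUm; L <- armLengthUm; r <- armRadiusUm
  if (r >= R) stop("arm radius must be smaller than the body radius")
  if (L == 0)
    return(.relabel(makeSphereStack(R, spacingUm, intensityFg, intensityBg,
                                    noiseSd, padUm = padUm, seed = seed)))
  if (L < r) stop("armLengthUm must be 0 or >= armRadiusUm")
  if (r < 2 * max(spacingUm))
    stop("arm radius is below the resolvable size")

  extY <- 2 * (R + padUm)
  extX <- 2 * padUm + 2 * R + L + r
  dims <- as.integer(ceiling(c(extY, extX, extY) / spacingUm))
  ctr <- c(extY / 2, padUm + R, extY / 2)   # body centre

  cy <- .centers(dims[1], spacingUm["y"]) - ctr[1]
  cx <- .centers(dims[2], spacingUm["x"]) - ctr[2]
  cz <- .centers(dims[3], spacingUm["z"]) - ctr[3]
  rho2 <- outer(outer(cy^2, rep(0, dims[2]), "+"), cz^2, "+") # y^2 + z^2
  xf <- outer(outer(rep(0, dims[1]), cx, "+"), rep(0, dims[3]), "+")

  inside <- (rho2 + xf^2 <= R^2) |
    (xf >= R & xf <= R + L & rho2 <= r^2) |
    (rho2 + (xf - R)^2 <= r^2) |
    (rho2 + (xf - R - L)^2 <= r^2)

  img <- array(intensityBg, dim = dims)
  img[inside] <- intensityFg
  img <- withr::with_seed(seed, .noisify(img, noiseSd))

  vol <- 4 / 3 * pi * R^3 + pi * r^2 * L + 2 / 3 * pi * r^3 + pi * r^4 / (4 * R)
  truth <- PhantomTruth("protrusion",
    params = list(body_radius_um = R, arm_length_um = L, arm_radius_um = r,
                  spacing_um = spacingUm, noise_sd = noiseSd),
    seed = seed,
    truth = list(volume_um3 = vol, sphericity = NA_real_,
                 sphericity_below = 1))
  list(stack = ImageStack(img, spacingUm, "membrane",
                          meta = list(phantom = "protrusion")),
       truth = truth)
}

# L = 0 degenerates to a sphere; keep the protrusion kind label honest
.relabel <- function(ph) {
  ph$truth@kind <- "protrusion"
  ph
}

#' Two-sphere phantom (contact and separation cases)
#'
#' Two equal spheres with centres `2 radius + gapUm` apart along x.
#' Negative `gapUm` overlaps them; `gapUm = 0` is the tangent contact
#' case that digitization merges into a single component with a thin
#' neck.
#'
#' @param gapUm surface-to-surface gap, micrometres (may be negative).
#' @inheritParams makeSphereStack
#' @return `list(stack, truth)`; truth records the centre distance and
#'   whether the spheres touch (`gapUm <= 0`).
#' @export
makeTwoSphereStack <- function(radiusUm = 5, gapUm = 4,
                               spacingUm = .defaultSpacing(),
                               intensityFg = 100, intensityBg = 10,
                               noiseSd = 0, padUm = 2, seed = 1) {
  spacingUm <- stats::setNames(as.numeric(spacingUm), c("y", "x", "z"))
  if (radiusUm < 2 * max(spacingUm))
    stop("radius is below the resolvable size")
  d <- 2 * radiusUm + gapUm
  extY <- 2 * (radiusUm + padUm)
  extX <- 2 * (radiusUm + padUm) + d
  dims <- as.integer(ceiling(c(extY, extX, extY) / spacingUm))
  c1 <- c(extY / 2, padUm + radiusUm, extY / 2)
  c2 <- c1 + c(0, d, 0)
  inside <- (.radialSq(dims, spacingUm, c1) <= radiusUm^2) |
            (.radialSq(dims, spacingUm, c2) <= radiusUm^2)
  img <- array(intensityBg, dim = dims)
  img[inside] <- intensityFg
  img <- withr::with_seed(seed, .noisify(img, noiseSd))
  truth <- PhantomTruth("sphere",
    params = list(radius_um = radiusUm, gap_um = gapUm,
                  center_distance_um = d, spacing_um = spacingUm),
    seed = seed,
    truth = list(touching = gapUm <= 0,
                 volume_each_um3 = 4 / 3 * pi * radiusUm^3))
  list(stack = ImageStack(img, spacingUm, "membrane",
                          meta = list(phantom = "two_sphere")),
       truth = truth)
}

#' Nucleus-in-cell phantom for N:C ratio recovery
#'
#' Concentric nucleus and cell (disks in 2D mode, spheres in 3D) with a
#' target-protein channel whose nuclear and cytoplasmic plateau
#' intensities are prescribed, so the true nuclear:cytoplasmic ratio is
#' `nucIntensity / cytoIntensity` by construction. DAPI marks the
#' nucleus and phalloidin the whole cell, as in the imaging protocol the
#' measurement emulates.
#'
#' @param cellRadiusUm,nucleusRadiusUm cell and nucleus radii; the
#'   nucleus must be strictly inside the cell.
#' @param cytoIntensity,nucIntensity protein-channel plateau levels.
#' @param mode `"2D"` (single plane) or `"3D"` (volumetric).
#' @param bgIntensity protein intensity outside the cell.
#' @inheritParams makeSphereStack
#' @return `list(stack, truth)` with channels
#'   `dapi`, `phalloidin`, `protein` and `truth$nc_ratio`.
#' @export
makeNCCell <- function(cellRadiusUm = 10, nucleusRadiusUm = 5,
                       cytoIntensity = 100, nucIntensity = 200,
                       mode = c("2D", "3D"),
                       spacingUm = .defaultSpacing(),
                       noiseSd = 5, bgIntensity = 5, padUm = 2, seed = 1) {
  mode <- match.arg(mode)
  spacingUm <- stats::setNames(as.numeric(spacingUm), c("y", "x", "z"))
  if (nucleusRadiusUm >= cellRadiusUm)
    stop("nucleus radius must be strictly smaller than the cell radius")
  ext <- 2 * (cellRadiusUm + padUm)
  dims <- as.integer(ceiling(c(ext, ext, if (mode == "3D") ext else spacingUm["z"]) /
                               spacingUm))
  dims[3] <- max(dims[3], 1L)
  ctr <- dims * spacingUm / 2
  r2 <- .radialSq(dims, spacingUm, ctr)
  if (mode == "2D") {
    # distance in the single plane only
    dy2 <- (.centers(dims[1], spacingUm["y"]) - ctr[1])^2
    dx2 <- (.centers(dims[2], spacingUm["x"]) - ctr[2])^2
    r2 <- array(outer(dy2, dx2, "+"), dim = dims)
  }
  inCell <- r2 <= cellRadiusUm^2
  inNuc <- r2 <= nucleusRadiusUm^2

  dapi <- array(5, dim = dims); dapi[inNuc] <- 200
  phall <- array(5, dim = dims); phall[inCell] <- 150
  prot <- array(bgIntensity, dim = dims)
  prot[inCell] <- cytoIntensity
  prot[inNuc] <- nucIntensity

  arr <- withr::with_seed(seed, {
    a <- array(0, dim = c(dims, 3L))
    a[, , , 1] <- .noisify(dapi, noiseSd)
    a[, , , 2] <- .noisify(phall, noiseSd)
    a[, , , 3] <- .noisify(prot, noiseSd)
    a
  })
  truth <- PhantomTruth("nc_cell",
    params = list(cell_radius_um = cellRadiusUm,
                  nucleus_radius_um = nucleusRadiusUm,
                  cyto_intensity = cytoIntensity,
                  nuc_intensity = nucIntensity, mode = mode,
                  noise_sd = noiseSd, spacing_um = spacingUm),
    seed = seed,
    truth = list(nc_ratio = nucIntensity / cytoIntensity))
  list(stack = ImageStack(arr, spacingUm, c("dapi", "phalloidin", "protein"),
                          meta = list(phantom = "nc_cell", mode = mode)),
       truth = truth)
}

#' Peri-cellular matrix accumulation phantom
#'
#' Single-plane two-channel image of a cell in fluorescently tagged
#' hydrogel: the alginate channel sits at a uniform background level
#' everywhere in the gel and is multiplied by `bandFold` in the shell
#' 0--3 um outside the cell border (a fold of 1 is featureless, below 1
#' is depletion). The image extends far enough that the 28--32 um
#' background shell fits.
#'
#' @param cellRadiusUm cell radius, micrometres.
#' @param bandFold enrichment fold in the 0--3 um band; ground truth of
#'   the accumulation ratio.
#' @param marginUm gel margin beyond the cell border; at least 32 um so
#'   the background shell is present.
#' @param baseIntensity gel background intensity level.
#' @inheritParams makeSphereStack
#' @return `list(stack, truth)` with channels `membrane`, `alginate`.
#' @export
makeAccumulationPhantom <- function(cellRadiusUm = 5, bandFold = 3,
                                    spacingUm = c(y = 0.2, x = 0.2, z = 0.4),
                                    marginUm = 34, baseIntensity = 50,
                                    noiseSd = 0, seed = 1) {
  spacingUm <- stats::setNames(as.numeric(spacingUm), c("y", "x", "z"))
  if (marginUm < 32)
    stop("image too small to contain the 30 um background shell ",
         "(marginUm must be >= 32)")
  ext <- 2 * (cellRadiusUm + marginUm)
  dims <- c(as.integer(ceiling(ext / spacingUm[1:2])), 1L)
  ctr <- dims * spacingUm / 2
  dy2 <- (.centers(dims[1], spacingUm["y"]) - ctr[1])^2
  dx2 <- (.centers(dims[2], spacingUm["x"]) - ctr[2])^2
  rad <- array(sqrt(outer(dy2, dx2, "+")), dim = dims)

  inCell <- rad <= cellRadiusUm
  band <- rad > cellRadiusUm & rad <= cellRadiusUm + 3

  memb <- array(5, dim = dims); memb[inCell] <- 100
  alg <- array(baseIntensity, dim = dims)
  alg[band] <- baseIntensity * bandFold
  alg[inCell] <- baseIntensity * 0.1     # gel excluded from the cell body

  arr <- withr::with_seed(seed, {
    a <- array(0, dim = c(dims, 2L))
    a[, , , 1] <- .noisify(memb, noiseSd)
    a[, , , 2] <- .noisify(alg, noiseSd)
    a
  })
  truth <- PhantomTruth("accumulation",
    params = list(cell_radius_um = cellRadiusUm, band_fold = bandFold,
                  margin_um = marginUm, base_intensity = baseIntensity,
                  noise_sd = noiseSd, spacing_um = spacingUm),
    seed = seed,
    truth = list(accumulation_ratio = bandFold))
  list(stack = ImageStack(arr, spacingUm, c("membrane", "alginate"),
                          meta = list(phantom = "accumulation")),
       truth = truth)
}

#' Ratiometric calcium phantom
#'
#' Two-channel (Fluo-3 / Fura-red) single-plane image of one cell. Both
#' dyes are uniform over the cell, with the Fluo-3 level set to
#' `ratioFieldMean` times the Fura-red level, so the true per-cell
#' intensity ratio equals `ratioFieldMean`. Setting `furaredLevel = 0`
#' produces the degenerate zero-denominator case, flagged invalid in the
#' truth.
#'
#' @param ratioFieldMean true Fluo-3 : Fura-red ratio over the cell.
#' @param cellRadiusUm cell radius, micrometres.
#' @param furaredLevel Fura-red plateau intensity inside the cell.
#' @param bgIntensity intensity outside the cell (both channels).
#' @inheritParams makeSphereStack
#' @return `list(stack, truth)` with channels `fluo3`, `furared`.
#' @export
makeCalciumPhantom <- function(ratioFieldMean = 2.5, cellRadiusUm = 10,
                               spacingUm = c(y = 0.2, x = 0.2, z = 0.4),
                               furaredLevel = 100, bgIntensity = 2,
                               noiseSd = 2, padUm = 3, seed = 1) {
  spacingUm <- stats::setNames(as.numeric(spacingUm), c("y", "x", "z"))
  ext <- 2 * (cellRadiusUm + padUm)
  dims <- c(as.integer(ceiling(ext / spacingUm[1:2])), 1L)
  ctr <- dims * spacingUm / 2
  dy2 <- (.centers(dims[1], spacingUm["y"]) - ctr[1])^2
  dx2 <- (.centers(dims[2], spacingUm["x"]) - ctr[2])^2
  inCell <- array(outer(dy2, dx2, "+"), dim = dims) <= cellRadiusUm^2

  fluo <- array(bgIntensity, dim = dims)
  fura <- array(bgIntensity, dim = dims)
  # in the degenerate dark-Fura-red case the Fluo-3 channel stays visible
  fluo[inCell] <- ratioFieldMean * (if (furaredLevel > 0) furaredLevel else 100)
  fura[inCell] <- furaredLevel
  arr <- withr::with_seed(seed, {
    a <- array(0, dim = c(dims, 2L))
    a[, , , 1] <- .noisify(fluo, noiseSd)
    a[, , , 2] <- .noisify(fura, noiseSd)
    a
  })
  valid <- furaredLevel > 0
  truth <- PhantomTruth("calcium",
    params = list(ratio_field_mean = ratioFieldMean,
                  cell_radius_um = cellRadiusUm,
                  furared_level = furaredLevel, noise_sd = noiseSd,
                  spacing_um = spacingUm),
    seed = seed,
    truth = list(calcium_ratio = if (valid) ratioFieldMean else NA_real_,
                 valid = valid))
  list(stack = ImageStack(arr, spacingUm, c("fluo3", "furared"),
                          meta = list(phantom = "calcium")),
       truth = truth)
}

#' Synthetic stress-relaxation trace
#'
#' Emulates an unconfined-compression test: a linear-elastic ramp to the
#' hold strain at a constant strain rate (1 mm/min on a 2-mm sample
#' gives 0.00833/s), then a hold phase whose stress follows the chosen
#' viscoelastic model:
#' \describe{
#'   \item{maxwell}{\eqn{\sigma(t) = \sigma_0 e^{-t/\tau}};
#'     \eqn{\tau_{1/2} = \tau \ln 2}.}
#'   \item{sls}{standard linear solid,
#'     \eqn{\sigma(t) = \sigma_0 (p + (1-p) e^{-t/\tau})};
#'     \eqn{\tau_{1/2} = \tau \ln\frac{1-p}{0.5-p}} when the plateau
#'     fraction \eqn{p < 0.5}, otherwise stress never halves.}
#'   \item{elastic}{constant stress; never halves.}
#' }
#' \eqn{\sigma_0} is the stress at the start of the hold,
#' `E0KPa * holdStrain`.
#'
#' @param model `"maxwell"`, `"sls"` or `"elastic"`.
#' @param E0KPa initial elastic modulus, kPa (ramp slope).
#' @param tauS relaxation time constant, seconds.
#' @param plateauFraction SLS plateau fraction `p` in `[0, 1)`.
#' @param durationS hold duration, seconds (the experiment the trace
#'   emulates held for 1e4 s; tests use shorter records).
#' @param dtS sampling interval, seconds.
#' @param noiseSd additive stress noise SD, kPa (clipped at zero).
#' @param holdStrain strain held, fraction (default 0.15).
#' @param strainRatePerS ramp strain rate, 1/s.
#' @param seed integer RNG seed.
#' @return `list(trace = TraceRecord, truth = PhantomTruth)`;
#'   `truth$tau_half_s` is `NA` when the stress never halves.
#' @export
makeRelaxationTrace <- function(model = c("maxwell", "sls", "elastic"),
                                E0KPa = 20, tauS = 100,
                                plateauFraction = 0.1, durationS = 1000,
                                dtS = 1, noiseSd = 0, holdStrain = 0.15,
                                strainRatePerS = 0.15 / 18, seed = 1) {
  model <- match.arg(model)
  if (model == "sls" && (plateauFraction < 0 || plateauFraction >= 1))
    stop("plateauFraction must be in [0, 1)")
  sigma0 <- E0KPa * holdStrain
  rampT <- seq(0, holdStrain / strainRatePerS, by = dtS)
  rampStrain <- strainRatePerS * rampT
  rampStress <- E0KPa * rampStrain
  holdT <- seq(dtS, durationS, by = dtS)
  holdStress <- switch(model,
    maxwell = sigma0 * exp(-holdT / tauS),
    sls = sigma0 * (plateauFraction + (1 - plateauFraction) * exp(-holdT / tauS)),
    elastic = rep(sigma0, length(holdT)))
  time <- c(rampT, max(rampT) + holdT)
  stress <- c(rampStress, holdStress)
  strain <- c(rampStrain, rep(holdStrain, length(holdT)))
  phase <- c(rep("ramp", length(rampT)), rep("hold", length(holdT)))
  stress <- withr::with_seed(seed, .noisify(stress, noiseSd))

  tauHalf <- switch(model,
    maxwell = tauS * log(2),
    sls = if (plateauFraction < 0.5)
      tauS * log((1 - plateauFraction) / (0.5 - plateauFraction))
    else NA_real_,
    elastic = NA_real_)
  truth <- PhantomTruth("relaxation",
    params = list(model = model, E0_kPa = E0KPa, tau_s = tauS,
                  plateau_fraction = plateauFraction,
                  duration_s = durationS, dt_s = dtS, noise_sd = noiseSd,
                  hold_strain = holdStrain),
    seed = seed,
    truth = list(tau_half_s = tauHalf, E0_kPa = E0KPa,
                 sigma0_kPa = sigma0))
  list(trace = TraceRecord(time, stress, strain, phase, holdStrain),
       truth = truth)
}

#' Synthetic per-cell population table
#'
#' Seeded stand-in for the study population behind the volume vs
#' ALP-positivity relationship: per-cell volumes are lognormal within
#' each condition and ALP positivity is Bernoulli with probability given
#' by a saturating monotone link of volume,
#' \eqn{g(V) = (a/100) \, V / (k + V)} (with `linkK = 0` the link is
#' flat at `linkA` percent, useful as a null case).
#'
#' @param nCellsPerCondition cells per condition (default 75, giving a
#'   300-cell population over the default conditions).
#' @param conditionSpecs data.frame with columns `condition`,
#'   `volume_mean_um3`, `volume_sd_um3` (natural-scale lognormal mean
#'   and SD). The default emulates four study arms -- fast, mid and slow
#'   stress relaxation plus a hyperosmotically confined group -- with
#'   condition-mean volumes from about 4500 down to 700 cubic
#'   micrometres, the volume span over which the ALP response curve is
#'   observed.
#' @param linkA saturating-link amplitude, percent (asymptotic ALP
#'   positivity).
#' @param linkK half-saturation volume, cubic micrometres.
#' @param seed integer RNG seed.
#' @return `list(table, truth)`; `table` has columns `cell_id`,
#'   `condition`, `volume_um3`, `alp_positive`.
#' @export
makePopulationTable <- function(nCellsPerCondition = 75,
                                conditionSpecs = NULL,
                                linkA = 60, linkK = 2000, seed = 1) {
  if (is.null(conditionSpecs))
    conditionSpecs <- data.frame(
      condition = c("fast", "mid", "slow", "hyper"),
      volume_mean_um3 = c(4500, 2200, 1100, 700),
      volume_sd_um3 = c(1400, 700, 350, 220))
  stopifnot(all(c("condition", "volume_mean_um3", "volume_sd_um3") %in%
                  names(conditionSpecs)))
  tab <- withr::with_seed(seed, {
    rows <- lapply(seq_len(nrow(conditionSpecs)), function(i) {
      m <- conditionSpecs$volume_mean_um3[i]
      s <- conditionSpecs$volume_sd_um3[i]
      sdlog <- sqrt(log(1 + (s / m)^2))
      meanlog <- log(m) - sdlog^2 / 2
      v <- stats::rlnorm(nCellsPerCondition, meanlog, sdlog)
      p <- if (linkK == 0) rep(linkA / 100, length(v))
           else pmin(1, (linkA / 100) * v / (linkK + v))
      data.frame(condition = conditionSpecs$condition[i], volume_um3 = v,
                 alp_positive = stats::rbinom(length(v), 1L, p))
    })
    out <- do.call(rbind, rows)
    out$cell_id <- sprintf("cell%04d", seq_len(nrow(out)))
    out[, c("cell_id", "condition", "volume_um3", "alp_positive")]
  })
  truth <- PhantomTruth("population",
    params = list(n_cells_per_condition = nCellsPerCondition,
                  condition_specs = conditionSpecs),
    seed = seed,
    truth = list(link = "saturating", link_a = linkA, link_k = linkK))
  list(table = tab, truth = truth)
}
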