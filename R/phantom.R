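# Synthetic striatal slab phantom ---------------------------------------
#
# The phantom is a 2D stand-in for a 12 mm transversal slab through the
# striatum: a smooth brain-shaped background plus, per hemisphere, a
# caudate blob and an elongated putamen blob whose plateau intensity is
# `striatalContrast` times the background.  Disease severity scales the
# two blobs down, putamen before caudate, which mimics the typical
# posterior-to-anterior reduction pattern of nigrostriatal degeneration.
# It is a feature-faithful toy, not an anatomical or physical model.

# mm-space geometry of the four striatal components (per side: caudate
# head, putamen) and the brain outline.  Values chosen once to give a
# plausible slab at 3 mm/pixel on a 64x64 grid.
.geom <- list(
  brain = c(a = 78, b = 92),          # ellipse semi-axes [mm]
  caudate = list(cx = 13, cy = 22, sx = 6, sy = 10, rot = 15),
  putamen = list(cx = 25, cy = -2, sx = 14, sy = 6, rot = -55),
  amp = 1.6                           # blob gain; >1 creates a plateau
)

# severity response of the two components (strictly decreasing in s)
.putamenFactor <- function(s) (1 - s)^1.7
.caudateFactor <- function(s) 1 - 0.75 * s

#' Phantom parameters
#'
#' @param severity disease severity in `[0, 1]` (0 = normal striatal
#'   signal, 1 = maximal reduction).
#' @param asymmetry left/right imbalance in `[0, 1]`; the left striatum
#'   is affected more.
#' @param backgroundLevel background intensity (a.u.).
#' @param striatalContrast striatum-to-background plateau ratio at
#'   severity 0; must exceed 1.
#' @param noiseSd additive Gaussian noise standard deviation (a.u.).
#' @param pixelSizeMm pixel size in mm.
#' @param psfFwhmMm intrinsic resolution of the emulated scanner
#'   (Gaussian point-spread FWHM, mm) applied before noise.
#' @return a validated list of class `PhantomParams`.
#' @export
phantomParams <- function(severity = 0, asymmetry = 0.3,
                          backgroundLevel = 50, striatalContrast = 4,
                          noiseSd = 2.5, pixelSizeMm = 3,
                          psfFwhmMm = 10) {
  stopIfNot01(severity, "severity")
  stopIfNot01(asymmetry, "asymmetry")
  if (striatalContrast <= 1) stop("striatalContrast must exceed 1")
  if (noiseSd < 0) stop("noiseSd must be non-negative")
  if (pixelSizeMm <= 0 || backgroundLevel <= 0 || psfFwhmMm < 0)
    stop("backgroundLevel, pixelSizeMm must be positive; psfFwhmMm non-negative")
  structure(list(severity = severity, asymmetry = asymmetry,
                 backgroundLevel = backgroundLevel,
                 striatalContrast = striatalContrast,
                 noiseSd = noiseSd, pixelSizeMm = pixelSizeMm,
                 psfFwhmMm = psfFwhmMm),
            class = "PhantomParams")
}

# mm coordinate grids for a size x size image centred on the brain
.mmGrid <- function(size, pixelSizeMm) {
  ax <- (seq_len(size) - (size + 1) / 2) * pixelSizeMm
  list(x = matrix(ax, size, size, byrow = TRUE),   # columns: left-right
       y = matrix(-ax, size, size))                # rows: anterior at top
}

.blobShape <- function(g, cx, cy, sx, sy, rot) {
  th <- rot * pi / 180
  u <- cos(th) * (g$x - cx) + sin(th) * (g$y - cy)
  v <- -sin(th) * (g$x - cx) + cos(th) * (g$y - cy)
  q <- (u / sx)^2 + (v / sy)^2
  pmin(1, .geom$amp * exp(-q / 2))
}

# Striatal shape field in [0, 1]: per side the max of the severity-scaled
# caudate and putamen components.  side = -1 is the patient's left
# (displayed right); severity hits the left side harder via `asymmetry`.
.striatalShape <- function(g, severity, asymmetry) {
  sev <- c(left = min(1, severity * (1 + 0.5 * asymmetry)),
           right = max(0, severity * (1 - 0.5 * asymmetry)))
  out <- 0
  for (side in c(-1, 1)) {
    s <- if (side < 0) sev["left"] else sev["right"]
    ca <- .geom$caudate
    pu <- .geom$putamen
    caud <- .blobShape(g, side * ca$cx, ca$cy, ca$sx, ca$sy, side * ca$rot)
    put <- .blobShape(g, side * pu$cx, pu$cy, pu$sx, pu$sy, side * pu$rot)
    out <- pmax(out, pmax(.caudateFactor(s) * caud, .putamenFactor(s) * put))
  }
  out
}

.brainMask <- function(g) {
  r <- sqrt((g$x / .geom$brain["a"])^2 + (g$y / .geom$brain["b"])^2)
  1 / (1 + exp((r - 1) / 0.03))
}

#' Noise-free slab template
#'
#' Renders the analytic phantom template (no point-spread, no noise, no
#' smoothing): background times `1 + (C - 1) * shape` inside the brain
#' outline, where `C` is the striatal contrast and `shape` the striatal
#' shape field.  The `NOASC` reconstruction variant raises the
#' background by 25\% and rescales the striatal excess contrast by 0.8.
#'
#' @param params a [phantomParams()] object.
#' @param size image side length in pixels.
#' @param variant `"ASC"` (attenuation/scatter corrected) or `"NOASC"`.
#' @return a `size x size` intensity matrix.
#' @export
slabTemplate <- function(params, size = 64, variant = c("ASC", "NOASC")) {
  variant <- match.arg(variant)
  g <- .mmGrid(size, params$pixelSizeMm)
  shape <- .striatalShape(g, params$severity, params$asymmetry)
  bg <- params$backgroundLevel
  excess <- params$striatalContrast - 1
  if (variant == "NOASC") {
    bg <- bg * 1.25
    excess <- excess * 0.8
  }
  bg * .brainMask(g) * (1 + excess * shape)
}

.smoothingLevels <- c(0, 10, 12, 14, 16, 18)

.gaussianBlur <- function(img, fwhmMm, pixelSizeMm) {
  if (fwhmMm <= 0) return(img)
  sigma <- fwhmMm / (2 * sqrt(2 * log(2))) / pixelSizeMm
  as.matrix(EBImage::gblur(img, sigma = sigma, boundary = "replicate"))
}

#' Generate one synthetic slab image
#'
#' Pipeline: analytic template (per reconstruction variant) -> scanner
#' point-spread blur -> additive Gaussian noise (seeded) -> optional
#' post-reconstruction Gaussian smoothing with the stated FWHM
#' (`sigma = FWHM / (2 sqrt(2 ln 2))`) -> clamping at zero.
#'
#' @inheritParams slabTemplate
#' @param smoothingFwhmMm one of 0, 10, 12, 14, 16, 18 (mm); 0 denotes
#'   the unsmoothed instance.
#' @param seed integer seed for the noise realization; the same seed
#'   reproduces the image bit-identically.
#' @return a `size x size` matrix with attributes `variant` and
#'   `smoothing_fwhm_mm`.
#' @examples
#' img <- generatePhantom(phantomParams(severity = 0.8), seed = 1)
#' dim(img)
#' @export
generatePhantom <- function(params, variant = c("ASC", "NOASC"),
                            smoothingFwhmMm = 0, seed = 1, size = 64) {
  variant <- match.arg(variant)
  if (!smoothingFwhmMm %in% .smoothingLevels)
    stop("smoothingFwhmMm must be one of ",
         paste(.smoothingLevels, collapse = ", "))
  img <- slabTemplate(params, size, variant)
  img <- .gaussianBlur(img, params$psfFwhmMm, params$pixelSizeMm)
  if (params$noiseSd > 0) {
    noise <- withSeed(seed, rnorm(length(img), sd = params$noiseSd))
    img <- img + matrix(noise, nrow(img))
  }
  img <- pmax(img, 0)
  img <- .gaussianBlur(img, smoothingFwhmMm, params$pixelSizeMm)
  img <- pmax(img, 0)
  attr(img, "variant") <- variant
  attr(img, "smoothing_fwhm_mm") <- smoothingFwhmMm
  img
}

#' Region-of-interest masks for the phantom geometry
#'
#' `striatalROI` marks the plateau core of the severity-0 striatal
#' shape; `backgroundROI` marks brain tissue well away from the striatum
#' and from the brain edge.  Both are purely geometric, hence identical
#' for every scan of a cohort with the same grid.
#'
#' @param size image side length in pixels.
#' @param pixelSizeMm pixel size in mm.
#' @return a logical matrix.
#' @export
striatalROI <- function(size = 64, pixelSizeMm = 3) {
  g <- .mmGrid(size, pixelSizeMm)
  .striatalShape(g, 0, 0) >= 0.999
}

#' @rdname striatalROI
#' @export
backgroundROI <- function(size = 64, pixelSizeMm = 3) {
  g <- .mmGrid(size, pixelSizeMm)
  r <- sqrt((g$x / .geom$brain["a"])^2 + (g$y / .geom$brain["b"])^2)
  shape <- .striatalShape(g, 0, 0)
  r < 0.82 & shape < 0.02
}
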