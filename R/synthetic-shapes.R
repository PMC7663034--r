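#' Construct a synthetic shape specification
#'
#' @param classLabel 0 (benign-like) or 1 (malignant-like).
#' @param baseSemiAxes `(a, b)` semi-axes in px, `a` along x before
#'   rotation.
#' @param rotationDeg ellipse rotation, degrees counterclockwise (y-up).
#' @param spiculeAmplitude radial spicule amplitude, fraction of the local
#'   radius in `[0, 0.5)`.
#' @param spiculeCount dominant number of spicule lobes.
#' @param lobulationAmplitude smooth lobulation amplitude fraction.
#' @param canvas `(width, height)` px of the output mask.
#' @param seed integer seed.
#' @return a [ShapeSpec-class].
#' @export
ShapeSpec <- function(classLabel = 0L, baseSemiAxes = c(50, 50),
                      rotationDeg = 0, spiculeAmplitude = 0,
                      spiculeCount = 8L, lobulationAmplitude = 0,
                      canvas = c(224L, 224L), seed = 1L) {
  new("ShapeSpec", classLabel = as.integer(classLabel),
      baseSemiAxes = as.numeric(baseSemiAxes),
      rotationDeg = as.numeric(rotationDeg),
      spiculeAmplitude = as.numeric(spiculeAmplitude),
      spiculeCount = as.integer(spiculeCount),
      lobulationAmplitude = as.numeric(lobulationAmplitude),
      canvas = as.integer(canvas), seed = as.integer(seed))
}

#' Generate one synthetic nodule shape
#'
#' Builds a closed contour from the polar model
#' \deqn{r(\theta) = r_e(\theta)\,(1 + \lambda \sin(3\theta + \phi) +
#'   \alpha\, s(\theta))}
#' where \eqn{r_e} is the radius of the base ellipse, \eqn{\lambda} the
#' lobulation amplitude, \eqn{\alpha} the spicule amplitude and
#' \eqn{s(\theta)} seeded band-limited noise whose dominant angular
#' frequency equals the requested spicule count, normalized to unit peak.
#' The polar form is star-shaped about the center, so the contour can never
#' self-intersect; if the combined amplitudes would drive the radius to
#' zero they are rescaled with a warning. The mask is the contour's
#' rasterization. Fully deterministic for a given spec.
#'
#' @param spec a [ShapeSpec-class].
#' @param nPoints number of boundary samples (default 360).
#' @return list with elements `mask` (integer matrix, rows = y) and
#'   `contour` ([NoduleContour-class]).
#' @examples
#' sh <- generateShape(ShapeSpec(baseSemiAxes = c(60, 30), seed = 4))
#' featureValues(extractFeatures(sh$contour))$eccentricity  # ~ 0.5
#' @export
generateShape <- function(spec, nPoints = 360L) {
  w <- spec@canvas[1]; h <- spec@canvas[2]
  theta <- seq(0, 2 * pi, length.out = nPoints + 1L)[-(nPoints + 1L)]
  a <- spec@baseSemiAxes[1]; b <- spec@baseSemiAxes[2]
  re <- a * b / sqrt((b * cos(theta))^2 + (a * sin(theta))^2)
  mod <- withr::with_seed(spec@seed, {
    lob <- if (spec@lobulationAmplitude > 0)
      spec@lobulationAmplitude * sin(3 * theta + stats::runif(1, 0, 2 * pi))
    else 0
    spic <- if (spec@spiculeAmplitude > 0) {
      harm <- pmax(1L, spec@spiculeCount + (-1L:1L))
      s <- rowSums(vapply(seq_along(harm), function(i)
        c(1, 2, 1)[i] * sin(harm[i] * theta + stats::runif(1, 0, 2 * pi)),
        numeric(length(theta))))
      spec@spiculeAmplitude * s / max(abs(s))
    } else 0
    1 + lob + spic
  })
  if (min(mod) <= 0.05) {
    warning("amplitudes too large; rescaling to keep the radius positive")
    mod <- 1 + (mod - 1) * (0.95 / max(abs(mod - 1)))
  }
  r <- re * mod
  phi <- spec@rotationDeg * pi / 180
  xu <- r * cos(theta + phi)
  yu <- r * sin(theta + phi)
  ct <- NoduleContour(cbind(w / 2 + xu, h / 2 - yu),
                      imageSize = c(w, h))
  list(mask = contourToMask(ct, c(w, h)), contour = ct)
}

#' Generate a labeled synthetic cohort
#'
#' Draws `nPerClass` benign-like and `nPerClass` malignant-like shapes with
#' class-conditional parameter distributions encoding the clinical shape
#' attributes: benign nodules are smooth, wider-than-tall ovals
#' (vertical-to-horizontal semi-axis ratio uniform on (0.55, 0.9), spicule
#' amplitude uniform on (0, 0.03)); malignant nodules are taller-than-wide
#' (depth/width uniform on (1.05, 1.5)), spiculated (amplitude uniform on
#' (0.08, 0.2)) and lobulated. All draws come from one stream seeded with
#' `seed`.
#'
#' @param nPerClass cases per class.
#' @param benignParams,malignantParams named lists overriding the class
#'   defaults: `axisRatioRange`, `sizeRange` (horizontal semi-axis, px),
#'   `rotationRange` (deg), `spiculeAmpRange`, `spiculeCountRange`,
#'   `lobulationAmpRange`.
#' @param seed integer seed.
#' @param canvas mask canvas `(width, height)`, px.
#' @return list of `2 * nPerClass` labeled [CaseRecord-class] with embedded
#'   masks, benign cases first.
#' @export
generateCohort <- function(nPerClass, benignParams = list(),
                           malignantParams = list(), seed = 1L,
                           canvas = c(224L, 224L)) {
  stopifnot(nPerClass >= 1)
  ben <- utils::modifyList(list(
    axisRatioRange = c(0.55, 0.9), sizeRange = c(35, 60),
    rotationRange = c(-15, 15), spiculeAmpRange = c(0, 0.03),
    spiculeCountRange = c(6L, 12L), lobulationAmpRange = c(0, 0.02)),
    benignParams)
  mal <- utils::modifyList(list(
    axisRatioRange = c(1.05, 1.5), sizeRange = c(30, 50),
    rotationRange = c(-10, 10), spiculeAmpRange = c(0.08, 0.2),
    spiculeCountRange = c(7L, 13L), lobulationAmpRange = c(0.03, 0.08)),
    malignantParams)
  tiradsPool <- list(`0` = c("2", "3"), `1` = c("4a", "4b", "4c", "5"))
  withr::with_seed(as.integer(seed), {
    cases <- vector("list", 2L * nPerClass)
    k <- 0L
    for (cls in c(0L, 1L)) {
      par <- if (cls == 0L) ben else mal
      for (i in seq_len(nPerClass)) {
        k <- k + 1L
        ax <- stats::runif(1, par$sizeRange[1], par$sizeRange[2])
        ratio <- stats::runif(1, par$axisRatioRange[1],
                              par$axisRatioRange[2])
        spec <- ShapeSpec(
          classLabel = cls,
          baseSemiAxes = c(ax, ax * ratio),
          rotationDeg = stats::runif(1, par$rotationRange[1],
                                     par$rotationRange[2]),
          spiculeAmplitude = stats::runif(1, par$spiculeAmpRange[1],
                                          par$spiculeAmpRange[2]),
          spiculeCount = sample(par$spiculeCountRange[1]:
                                  par$spiculeCountRange[2], 1L),
          lobulationAmplitude = stats::runif(1, par$lobulationAmpRange[1],
                                            par$lobulationAmpRange[2]),
          canvas = canvas,
          seed = sample.int(.Machine$integer.max, 1L))
        sh <- generateShape(spec)
        cases[[k]] <- CaseRecord(
          caseId = sprintf("syn%s%04d", cls, i),
          contours = sh$contour, label = cls,
          tirads = sample(tiradsPool[[as.character(cls)]], 1L),
          image = sh$mask + 0)
      }
    }
    cases
  })
}
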