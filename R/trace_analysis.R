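## Single-cell quantification rules: Mad2 localization index (LoG),
## kinetochore-signal quantification, Clb2 degradation detection and
## classification, adaptation scoring, and the missegregation predictor.

.LOG_KERNEL <- matrix(c(-0.0085, 0.0038, -0.0085,
                         0.0038, 0.0187,  0.0038,
                        -0.0085, 0.0038, -0.0085),
                      nrow = 3, byrow = TRUE)

#' Analysis configuration constructor
#'
#' Defaults follow the single-cell image-analysis protocol: the fixed 3x3
#' Laplacian-of-Gaussian kernel, a localization threshold at 110% of the
#' G1 (first 20 min) index maximum, a 5x5-pixel kinetochore mask, a
#' 4-point exponential fit for the Clb2 degradation rate, and the
#' partial-degradation rule (rate < 0.01/min, or < 50% degraded within
#' 90 min). The Savitzky-Golay window (7 frames) and order (2) and the
#' "starts decreasing and falls" criterion (a local maximum followed by
#' `fallK = 2` lower smoothed frames) are configurable operational
#' choices.
#'
#' @param thresholdFactor,g1Window,kinetochoreWindow,sgWindow,sgOrder
#'   see [AnalysisConfig-class].
#' @param ratePoints,partialRateCutoff,partialFraction,partialHorizon,fallK
#'   see [AnalysisConfig-class].
#' @return an [AnalysisConfig-class].
#' @export
analysisConfig <- function(thresholdFactor = 1.10, g1Window = 20,
                           kinetochoreWindow = 5L, sgWindow = 7L,
                           sgOrder = 2L, ratePoints = 4L,
                           partialRateCutoff = 0.01, partialFraction = 0.5,
                           partialHorizon = 90, fallK = 2L) {
  new("AnalysisConfig", logKernel = .LOG_KERNEL,
      thresholdFactor = thresholdFactor, g1Window = g1Window,
      kinetochoreWindow = as.integer(kinetochoreWindow),
      sgWindow = as.integer(sgWindow), sgOrder = as.integer(sgOrder),
      ratePoints = as.integer(ratePoints),
      partialRateCutoff = partialRateCutoff,
      partialFraction = partialFraction, partialHorizon = partialHorizon,
      fallK = as.integer(fallK))
}

#' Cell-trace constructor
#'
#' @param time frame times (min).
#' @param clb2 mean Clb2 fluorescence.
#' @param mad2Index Mad2 localization index.
#' @param buddingTime first budding time (min).
#' @param label optional ground-truth label.
#' @param meta metadata list.
#' @return a [CellTrace-class].
#' @export
cellTrace <- function(time, clb2, mad2Index, buddingTime = 0,
                      label = NA_character_, meta = list()) {
  new("CellTrace", time = as.numeric(time), clb2 = as.numeric(clb2),
      mad2Index = as.numeric(mad2Index), buddingTime = buddingTime,
      label = label, meta = meta)
}

#' @describeIn cellTrace ground-truth label accessor.
#' @param trace a `CellTrace`.
#' @export
traceLabel <- function(trace) trace@label

#' Mad2 localization index of an image
#'
#' Convolves the image with the fixed 3x3 LoG kernel (replicated-edge
#' borders) and returns the maximum of the filtered image over the
#' segmented-cell mask. The kernel's near-zero sum makes the index
#' insensitive to uniform background while a point source contributes its
#' intensity times the 0.0187 center weight.
#'
#' @param image numeric matrix of pixel intensities (at least 3x3).
#' @param mask logical matrix of the segmented cell (default: all pixels).
#' @param config an [AnalysisConfig-class].
#' @return the localization index (scalar).
#' @export
logLocalizationIndex <- function(image, mask = NULL,
                                 config = analysisConfig()) {
  stopifnot(nrow(image) >= 3, ncol(image) >= 3)
  if (is.null(mask)) mask <- matrix(TRUE, nrow(image), ncol(image))
  if (!any(mask)) stop("empty mask")
  k <- config@logKernel
  nr <- nrow(image); nc <- ncol(image)
  padded <- image[c(1, seq_len(nr), nr), c(1, seq_len(nc), nc)]
  filt <- matrix(0, nrow(image), ncol(image))
  for (di in -1:1) for (dj in -1:1) {
    filt <- filt + k[di + 2, dj + 2] *
      padded[(2 + di):(nrow(image) + 1 + di),
             (2 + dj):(ncol(image) + 1 + dj)]
  }
  max(filt[mask])
}

#' Frame-wise Mad2 localization call
#'
#' Mad2 counts as localized when the raw localization index strictly
#' exceeds a threshold calibrated per cell: `thresholdFactor` (110%)
#' times the maximal index over the G1 window (first 20 minutes).
#'
#' @param trace a [CellTrace-class].
#' @param config an [AnalysisConfig-class].
#' @return logical vector, one entry per frame.
#' @export
mad2Localized <- function(trace, config = analysisConfig()) {
  trace@mad2Index > mad2Threshold(trace, config)
}

#' @describeIn mad2Localized the calibrated localization threshold.
#' @export
mad2Threshold <- function(trace, config = analysisConfig()) {
  ## G1 window in absolute experiment time: the first 20 minutes
  g1 <- trace@time <= config@g1Window
  if (!any(g1)) stop("trace does not cover the G1 calibration window")
  config@thresholdFactor * max(trace@mad2Index[g1])
}

#' Total kinetochore fluorescence around a peak
#'
#' Sums the (non-deconvolved) average-projection intensities over the
#' square kinetochore mask centered on the detected peak. Deconvolution
#' does not scale linearly with total signal, so the sum is taken on the
#' raw projection. Windows clipped at the image border are renormalized
#' to the full mask area and flagged.
#'
#' @param avgProjection numeric intensity matrix.
#' @param peak integer `c(row, col)` of the spot peak.
#' @param config an [AnalysisConfig-class].
#' @return summed intensity, with attribute `clipped` (logical).
#' @export
kinetochoreSignal <- function(avgProjection, peak,
                              config = analysisConfig()) {
  w <- config@kinetochoreWindow %/% 2L
  if (peak[1] < 1 || peak[1] > nrow(avgProjection) ||
      peak[2] < 1 || peak[2] > ncol(avgProjection))
    stop("peak outside image")
  ri <- max(1, peak[1] - w):min(nrow(avgProjection), peak[1] + w)
  ci <- max(1, peak[2] - w):min(ncol(avgProjection), peak[2] + w)
  covered <- length(ri) * length(ci)
  full <- config@kinetochoreWindow^2
  s <- sum(avgProjection[ri, ci])
  if (covered < full) s <- s * full / covered
  attr(s, "clipped") <- covered < full
  s
}

.smooth_clb2 <- function(trace, config) {
  if (length(trace@clb2) < config@sgWindow)
    stop("trace shorter than the smoothing window")
  signal::sgolayfilt(trace@clb2, p = config@sgOrder, n = config@sgWindow)
}

#' Onset time of Clb2 degradation
#'
#' Smooths the Clb2 signal (Savitzky-Golay) and operationalizes "starts
#' decreasing and falls" as follows: estimate the mitotic plateau as the
#' median of the smoothed signal near its post-budding maximum, require a
#' sustained fall — the smoothed signal dropping below
#' `(1 - minDrop)` of the plateau and staying there for `fallK`
#' consecutive frames — and report the last frame before that fall at
#' which the raw signal was still at plateau level (97%). The raw-signal
#' refinement avoids the early bias a least-squares smoother introduces
#' at a sharp falling edge. `NA` if the signal never falls.
#'
#' @param trace a [CellTrace-class] with budding time set.
#' @param config an [AnalysisConfig-class].
#' @param minDrop minimal sustained drop, as a fraction of the plateau,
#'   for a fall to count (guards against calling noise on a flat arrest).
#' @return onset time (min) or `NA`.
#' @export
clb2DegradationTime <- function(trace, config = analysisConfig(),
                                minDrop = 0.1) {
  sm <- .smooth_clb2(trace, config)
  post <- which(trace@time >= trace@buddingTime)
  if (!length(post)) return(NA_real_)
  smp <- sm[post]
  raw <- trace@clb2[post]
  n <- length(smp)
  ipk <- which.max(smp)
  ## cap by the raw maximum: on a short plateau the smoother overshoots
  plateau <- min(stats::median(smp[smp >= 0.95 * smp[ipk]]), max(raw))
  lowFor <- function(i) {
    idx <- i:min(i + config@fallK - 1L, n)
    all(smp[idx] < (1 - minDrop) * plateau)
  }
  d <- NA_integer_
  for (i in seq(ipk + 1L, length.out = max(n - ipk, 0)))
    if (lowFor(i)) { d <- i; break }
  if (is.na(d)) return(NA_real_)
  atPlateau <- which(raw[seq_len(d)] >= 0.97 * plateau)
  onset <- if (length(atPlateau)) max(atPlateau) else ipk
  trace@time[post[onset]]
}

#' Clb2 degradation rate
#'
#' Log-linear least-squares exponential fit over `ratePoints` frames
#' starting at the degradation onset; the sign is flipped so decay gives
#' a positive rate (1/min). Nonpositive signal values are shifted to a
#' small positive floor before taking logs and the result is flagged.
#'
#' @param trace a [CellTrace-class].
#' @param tDeg degradation onset time (min), e.g. from
#'   [clb2DegradationTime()].
#' @param config an [AnalysisConfig-class].
#' @return rate (1/min), with attribute `shifted` if the signal needed a
#'   positivity shift.
#' @export
clb2DegradationRate <- function(trace, tDeg, config = analysisConfig()) {
  i0 <- which(trace@time >= tDeg)[1]
  idx <- i0:(i0 + config@ratePoints - 1L)
  if (max(idx) > length(trace@time))
    stop("fewer than ", config@ratePoints, " frames from the onset")
  y <- trace@clb2[idx]
  shifted <- any(y <= 0)
  if (shifted) y <- y - min(y) + 1e-6 * max(abs(y), 1)
  fit <- stats::lm(log(y) ~ trace@time[idx])
  r <- -unname(stats::coef(fit)[2])
  attr(r, "shifted") <- shifted
  r
}

#' Classify Clb2 degradation behavior
#'
#' `"arrested"` if the smoothed signal never falls; `"partial"` if the
#' fitted degradation rate is below the cutoff (0.01/min) or less than
#' half of the Clb2 present at onset is degraded within the 90 minutes
#' that follow; `"full"` otherwise.
#'
#' @param trace a [CellTrace-class].
#' @param config an [AnalysisConfig-class].
#' @return `"full"`, `"partial"` or `"arrested"`, with attributes `tDeg`
#'   and `rate` when degradation starts.
#' @export
classifyClb2Behavior <- function(trace, config = analysisConfig()) {
  tDeg <- clb2DegradationTime(trace, config)
  if (is.na(tDeg)) return(structure("arrested", tDeg = NA_real_,
                                    rate = NA_real_))
  rate <- clb2DegradationRate(trace, tDeg, config)
  sm <- .smooth_clb2(trace, config)
  s0 <- sm[which(trace@time >= tDeg)[1]]
  horizon <- trace@time >= tDeg &
    trace@time <= tDeg + config@partialHorizon
  degraded <- (s0 - min(sm[horizon])) / s0
  cls <- if (rate < config@partialRateCutoff ||
             degraded < config@partialFraction) "partial" else "full"
  structure(cls, tDeg = tDeg, rate = as.numeric(rate))
}

#' Score adaptation versus checkpoint satisfaction for one cell
#'
#' Only cells that fully degrade Clb2 are scored. A cell adapted if Mad2
#' was still localized (index above its per-cell threshold) at the frame
#' of the Clb2 degradation onset; it exited (satisfied the checkpoint) if
#' Mad2 had already delocalized.
#'
#' @param trace a [CellTrace-class].
#' @param config an [AnalysisConfig-class].
#' @return `"adapted"`, `"exited"` or `"not-applicable"`.
#' @export
classifyAdaptation <- function(trace, config = analysisConfig()) {
  beh <- classifyClb2Behavior(trace, config)
  if (beh != "full") return("not-applicable")
  tDeg <- attr(beh, "tDeg")
  loc <- mad2Localized(trace, config)
  frame <- which(trace@time >= tDeg)[1]
  if (loc[frame]) "adapted" else "exited"
}

#' Classify a whole cohort of traces
#'
#' @param traces list of [CellTrace-class] objects.
#' @param config an [AnalysisConfig-class].
#' @return data.frame: cell, behavior, adaptation, tDeg, rate, and the
#'   stored ground-truth label (if any).
#' @export
classifyCohort <- function(traces, config = analysisConfig()) {
  rows <- lapply(seq_along(traces), function(i) {
    tr <- traces[[i]]
    beh <- classifyClb2Behavior(tr, config)
    ad <- if (beh == "full") classifyAdaptation(tr, config)
          else "not-applicable"
    call <- if (beh != "full") as.character(beh) else ad
    data.frame(cell = i, behavior = as.character(beh), adaptation = ad,
               call = call, tDeg = attr(beh, "tDeg"),
               rate = attr(beh, "rate"), label = tr@label)
  })
  do.call(rbind, rows)
}

#' Probability of missegregating at least one chromosome
#'
#' With each of `n` chromosomes missegregating independently with
#' probability `p`, the chance that at least one does is 1 - (1 - p)^n.
#' With the measured per-chromosome rate p = 0.075 and the n = 16
#' chromosomes of haploid budding yeast this predicts the observed
#' adaptation rate.
#'
#' @param p per-chromosome missegregation probability in \[0, 1\].
#' @param n number of chromosomes (>= 1).
#' @return probability of at least one missegregation.
#' @examples
#' missegregationProbability(0.075, 16)
#' @export
missegregationProbability <- function(p, n) {
  if (any(p < 0 | p > 1)) stop("p must lie in [0, 1]")
  if (any(n < 1)) stop("n must be >= 1")
  1 - (1 - p)^n
}
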