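# Edge-depth profiles: aggregation over the rectified band, robust
# normalization, and trend-template classification (flat / linear / abrupt /
# smooth).

EPS_FLAT <- 1e-6

#' Aggregate a rectified depth band into one edge profile
#'
#' Takes the per-column median over valid band rows, yielding a single
#' outside-to-inside depth trace per wound. The median is robust to local
#' contour noise and to short invalid (out-of-frame) stretches. At least
#' half of the rows must be fully valid.
#'
#' @param band a depth-channel [RectifiedBand-class].
#' @return An unnormalized [EdgeProfile-class].
#' @export
aggregateProfile <- function(band) {
  stopifnot(is(band, "RectifiedBand"))
  if (band@channel != "depth")
    stop("aggregateProfile expects a depth-channel band")
  rowValid <- rowSums(!band@valid) == 0L
  if (mean(rowValid) < 0.5)
    stop(sprintf("only %.0f%% of band rows are valid (need >= 50%%)",
                 100 * mean(rowValid)))
  vals <- band@values[rowValid, , drop = FALSE]
  prof <- apply(vals, 2L, stats::median)
  new("EdgeProfile", values = prof, delta = bandOffsets(band),
      offset = 0, scale = 1, degenerate = FALSE, normalized = FALSE,
      validCount = as.integer(sum(rowValid)))
}

#' Construct an EdgeProfile directly from values
#'
#' Convenience constructor used when profiles are built analytically (e.g.
#' template-recovery simulations) rather than from a rectified band.
#'
#' @param values numeric vector, ordered outside -> inside.
#' @param dIn,dOut half-widths; `length(values)` must equal
#'   `dIn + dOut + 1`.
#' @return An [EdgeProfile-class].
#' @export
edgeProfile <- function(values, dIn, dOut) {
  stopifnot(length(values) == dIn + dOut + 1)
  new("EdgeProfile", values = values, delta = seq(dOut, -dIn),
      offset = 0, scale = 1, degenerate = FALSE, normalized = FALSE,
      validCount = length(values))
}

setMethod("show", "EdgeProfile", function(object) {
  cat(sprintf(
    "EdgeProfile: %d samples, delta in [%g, %g]%s%s\n",
    length(object@values), min(object@delta), max(object@delta),
    if (object@normalized) ", normalized" else "",
    if (object@degenerate) ", degenerate-flat" else ""))
})

#' Normalize an edge profile to a common offset and amplitude
#'
#' Subtracts the outermost (peri-wound) value and divides by the robust
#' amplitude, the 90th minus 10th percentile of the profile. Profiles whose
#' amplitude is below `epsFlat` are flagged degenerate-flat and only
#' offset-corrected, so noise is not blown up to unit scale. Normalization
#' makes template selection invariant to depth offset and positive scaling.
#'
#' @param p an [EdgeProfile-class].
#' @param epsFlat amplitude threshold (depth units) below which the profile
#'   counts as flat.
#' @return The normalized [EdgeProfile-class] (normalization recorded in
#'   `offset`/`scale`).
#' @export
normalizeProfile <- function(p, epsFlat = EPS_FLAT) {
  stopifnot(is(p, "EdgeProfile"), all(is.finite(p@values)))
  offset <- p@values[1L]
  v <- p@values - offset
  amp <- unname(diff(stats::quantile(v, c(0.1, 0.9))))
  if (amp < epsFlat) {
    new("EdgeProfile", values = v, delta = p@delta, offset = offset,
        scale = 1, degenerate = TRUE, normalized = TRUE,
        validCount = p@validCount)
  } else {
    new("EdgeProfile", values = v / amp, delta = p@delta, offset = offset,
        scale = amp, degenerate = FALSE, normalized = TRUE,
        validCount = p@validCount)
  }
}

# One bounded logistic fit A / (1 + exp(-(delta - d0)/w)) + c with a fixed
# multi-start grid; returns the best (RSS) converged fit or NULL.
fitLogistic <- function(delta, y, wLower, wUpper, dIn, dOut, wStarts) {
  best <- NULL
  d0Starts <- c(-dIn / 2, 0, dOut / 2)
  amp <- max(y) - min(y)
  for (d0 in d0Starts) for (w0 in wStarts) {
    fit <- tryCatch(
      suppressWarnings(minpack.lm::nlsLM(
        y ~ A / (1 + exp(-(delta - d0) / w)) + c0,
        start = list(A = if (amp > 0) amp else 1, c0 = min(y),
                     d0 = d0, w = w0),
        lower = c(A = 0, c0 = -Inf, d0 = -dIn, w = wLower),
        upper = c(A = Inf, c0 = Inf, d0 = dOut, w = wUpper),
        control = minpack.lm::nls.lm.control(maxiter = 100))),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::resid(fit)^2)
    if (is.null(best) || rss < best$rss - 1e-12)
      best <- list(par = as.list(stats::coef(fit)), rss = rss, ok = TRUE)
  }
  best
}

#' Fit the four trend templates to a normalized edge profile
#'
#' Fits flat (constant), linear, abrupt and smooth templates to the profile
#' as a function of the signed offset `delta` and selects the winner by BIC,
#' `n log(RSS/n) + p log(n)` with `p` the parameter count (1, 2, 4, 4).
#' Abrupt and smooth are both logistic steps
#' `A / (1 + exp(-(delta - delta0)/w)) + c`; abrupt is constrained to
#' transition width `w <= wAbrupt`, smooth to `w > wAbrupt`. All templates
#' describe a descent from peri-wound skin into the wound bed, so the linear
#' slope and the logistic amplitude are constrained non-ascending inward
#' (`beta >= 0`, `A >= 0` in the `delta` parametrisation); this halves the
#' rate at which pure noise is mistaken for a trend. Logistics use
#' bounded Levenberg-Marquardt least squares from a fixed multi-start grid
#' (`delta0` in three positions x three widths), so repeated fits are
#' bit-reproducible. If no logistic start converges that template is marked
#' unavailable and the winner is chosen among the rest.
#'
#' @param p a normalized [EdgeProfile-class] (see [normalizeProfile()]).
#' @param wAbrupt width threshold (px) separating abrupt from smooth.
#' @return A [TemplateFit-class].
#' @export
fitTemplates <- function(p, wAbrupt = 3) {
  stopifnot(is(p, "EdgeProfile"))
  if (!p@normalized)
    stop("profile must be normalized before template fitting")
  y <- p@values; delta <- p@delta
  n <- length(y)
  dIn <- -min(delta); dOut <- max(delta)

  fits <- list(
    flat = list(par = list(c0 = mean(y)),
                rss = sum((y - mean(y))^2), ok = TRUE),
    linear = local({
      # trends describe a descent from skin into the bed, so the slope is
      # constrained non-negative in delta (non-ascending inward)
      cf <- stats::lm.fit(cbind(1, delta), y)$coefficients
      if (cf[2L] < 0) cf <- c(mean(y), 0)
      list(par = list(alpha = unname(cf[1L]), beta = unname(cf[2L])),
           rss = sum((y - cf[1L] - cf[2L] * delta)^2), ok = TRUE)
    }),
    abrupt = fitLogistic(delta, y, wLower = 0.2, wUpper = wAbrupt,
                         dIn, dOut, wStarts = c(0.5, 1, 2)),
    smooth = fitLogistic(delta, y, wLower = wAbrupt + 1e-6, wUpper = 100,
                         dIn, dOut, wStarts = c(5, 15, 40)))

  pCount <- c(flat = 1, linear = 2, abrupt = 4, smooth = 4)
  for (nm in names(fits)) {
    if (is.null(fits[[nm]])) {
      fits[[nm]] <- list(par = NULL, rss = Inf, bic = Inf, ok = FALSE)
    } else {
      rss <- max(fits[[nm]]$rss, 1e-12)
      fits[[nm]]$bic <- n * log(rss / n) + pCount[[nm]] * log(n)
    }
  }
  bics <- vapply(fits, function(f) f$bic, 0)
  winner <- names(fits)[which.min(bics)]   # ties: first = simplest
  new("TemplateFit", fits = fits, winner = winner, wAbrupt = wAbrupt)
}

setMethod("show", "TemplateFit", function(object) {
  cat(sprintf("TemplateFit: winner '%s'\n", object@winner))
  for (nm in names(object@fits)) {
    f <- object@fits[[nm]]
    cat(sprintf("  %-7s RSS %.4g  BIC %.4g%s\n", nm,
                f$rss, f$bic, if (!f$ok) " (unavailable)" else ""))
  }
})

#' @describeIn fitTemplates name of the selected template.
#' @param fit a [TemplateFit-class].
#' @export
selectedTemplate <- function(fit) fit@winner

#' Scalar descriptors of an edge profile and its template decomposition
#'
#' Emits the winning template as a one-hot block, the winning logistic
#' parameters (step location, width, amplitude), the residual of each
#' template, gradient statistics (maximum magnitude and its offset
#' location), the inside-minus-outside mean difference, and the rim
#' prominence: the maximum of the profile over the outer half
#' (`delta` in `[0, dOut]`) above the outer baseline (median of the
#' outermost quarter). All belong to the geometry descriptor group.
#'
#' @param fit a [TemplateFit-class].
#' @param p the (normalized) [EdgeProfile-class] the fit was computed on.
#' @return Named numeric vector (prefix `profile_`).
#' @export
profileFeatures <- function(fit, p) {
  stopifnot(is(fit, "TemplateFit"), is(p, "EdgeProfile"))
  y <- p@values; delta <- p@delta
  templates <- c("flat", "linear", "abrupt", "smooth")
  oneHot <- as.numeric(templates == fit@winner)
  names(oneHot) <- paste0("profile_is_", templates)
  rss <- vapply(fit@fits, function(f)
    if (is.finite(f$rss)) f$rss else sum((y - mean(y))^2), 0)
  names(rss) <- paste0("profile_rss_", templates)

  logi <- fit@fits[[if (fit@winner %in% c("abrupt", "smooth")) fit@winner
                    else if (fit@fits$abrupt$ok) "abrupt"
                    else "smooth"]]
  lp <- if (!is.null(logi$par))
    c(delta0 = logi$par$d0, width = logi$par$w, amplitude = logi$par$A)
  else c(delta0 = 0, width = 0, amplitude = 0)
  names(lp) <- paste0("profile_logistic_", c("delta0", "width", "amplitude"))

  grad <- diff(y) / diff(delta)            # d value / d delta
  gmax <- which.max(abs(grad))
  gradLoc <- (delta[gmax] + delta[gmax + 1L]) / 2
  insideMean <- mean(y[delta < 0])
  outsideMean <- mean(y[delta > 0])
  outerQuarter <- y[delta >= 0.75 * max(delta)]
  rim <- max(y[delta >= 0 & delta <= max(delta)]) -
    stats::median(outerQuarter)

  c(oneHot, lp, rss,
    profile_grad_max = max(abs(grad)),
    profile_grad_location = gradLoc,
    profile_inside_minus_outside = insideMean - outsideMean,
    profile_rim_prominence = rim,
    profile_amplitude = p@scale,
    profile_degenerate = as.numeric(p@degenerate))
}
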