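#' Per-channel transform specification
#'
#' Describes how each channel is mapped from the linear instrument scale to
#' the analysis scale.  Supported types: `"logicle"` (biexponential, linear
#' near zero, logarithmic at the top of scale), `"asinh"` (inverse
#' hyperbolic sine with a cofactor), and `"identity"` (scatter and time
#' channels).
#'
#' @param channels Character vector of channel names.
#' @param type One of `"logicle"`, `"asinh"`, `"identity"` (recycled).
#' @param T Top of scale for logicle (default 262144).
#' @param m Logicle decades (default 4.5).
#' @param w Logicle linearization width in decades (default 0.5); ignored
#'   when estimated from data via [estimate_logicle_width()].
#' @param cofactor asinh cofactor (default 150).
#' @return A data.frame with one row per channel (class `TransformSpec`).
#' @export
transform_spec <- function(channels, type = "asinh", T = 262144, m = 4.5,
                           w = 0.5, cofactor = 150) {
  type <- rep_len(type, length(channels))
  bad <- setdiff(unique(type), c("logicle", "asinh", "identity"))
  if (length(bad)) stop("unknown transform type(s): ", paste(bad, collapse = ", "))
  if (any(T <= 0)) stop("logicle top of scale T must be positive")
  if (any(m <= 0) || any(cofactor <= 0) || any(w < 0)) {
    stop("transform parameters must be positive (w may be zero)")
  }
  out <- data.frame(channel = channels, type = type,
                    T = rep_len(T, length(channels)),
                    m = rep_len(m, length(channels)),
                    w = rep_len(w, length(channels)),
                    cofactor = rep_len(cofactor, length(channels)),
                    stringsAsFactors = FALSE)
  class(out) <- c("TransformSpec", "data.frame")
  out
}

#' Default transform for an EventTable
#'
#' Marker, viability and bead channels get the given type; scatter and time
#' stay identity.
#'
#' @param x An `EventTable`.
#' @param type Transform for non-scatter channels.
#' @param ... Passed to [transform_spec()].
#' @return A `TransformSpec`.
#' @export
default_transform_spec <- function(x, type = "asinh", ...) {
  tr <- ifelse(x$roles %in% c("scatter", "time"), "identity", type)
  transform_spec(x$channels, type = tr, ...)
}

# ---- logicle (biexponential) -------------------------------------------
# Standard parameterization: the inverse (scale -> data) is
#   S(y) = a e^{b y} - c e^{-d y} + f    on the normalized scale y in [0, 1],
# with parameters chosen so that S(1) = T, S(x1) = 0 and the function is
# linear through zero over a width of w decades.  The forward transform is
# computed by Newton iteration seeded from a monotone spline of the inverse,
# and reported in decade units (y * m) so one "scale unit" is one decade.

logicle_params <- function(T, m, w) {
  if (T <= 0) stop("logicle parameter error: T must be positive")
  if (w < 0 || w > m / 2) stop("logicle parameter error: need 0 <= w <= m/2")
  wn <- w / m                      # normalized width
  x2 <- 0                          # no additional negative decades
  x1 <- x2 + wn
  x0 <- x2 + 2 * wn
  b <- m * log(10)
  d <- if (wn == 0) b else {
    g <- function(d) 2 * (log(d) - log(b)) + wn * (b + d)
    stats::uniroot(g, c(1e-12 * b, b), tol = 1e-14)$root
  }
  c_a <- exp(x0 * (b + d))
  mf_a <- exp(b * x1) - c_a * exp(-d * x1)
  a <- T / ((exp(b) - mf_a) - c_a * exp(-d))
  list(T = T, m = m, w = w, a = a, b = b, c = c_a * a, d = d, f = -mf_a * a)
}

logicle_inverse_core <- function(y, p) {
  # y in normalized [0, 1] units
  p$a * exp(p$b * y) - p$c * exp(-p$d * y) + p$f
}

logicle_forward_core <- function(x, p) {
  # seed with a monotone spline over a grid of the closed-form inverse,
  # then polish with Newton steps (the derivative is closed form)
  grid_y <- seq(-2, 1.2, length.out = 2048)
  grid_x <- logicle_inverse_core(grid_y, p)
  fit <- stats::splinefun(grid_x, grid_y, method = "hyman")
  y <- fit(pmin(pmax(x, min(grid_x)), max(grid_x)))
  for (i in 1:8) {
    fx <- logicle_inverse_core(y, p) - x
    dfx <- p$a * p$b * exp(p$b * y) + p$c * p$d * exp(-p$d * y)
    y <- y - fx / dfx
  }
  y
}

#' Logicle transform of a numeric vector
#'
#' @param x Values on the linear scale.
#' @param T Top of scale.
#' @param m Number of decades.
#' @param w Linearization width in decades.
#' @return Values in decade units (0 at the linear anchor, `m` at `T`).
#' @export
logicle <- function(x, T = 262144, m = 4.5, w = 0.5) {
  p <- logicle_params(T, m, w)
  logicle_forward_core(x, p) * m
}

#' Inverse logicle transform
#' @inheritParams logicle
#' @param y Values in decade units.
#' @return Values on the linear scale.
#' @export
logicle_inverse <- function(y, T = 262144, m = 4.5, w = 0.5) {
  p <- logicle_params(T, m, w)
  logicle_inverse_core(y / m, p)
}

#' Estimate the logicle linearization width from negative events
#'
#' `w = (m - log10(T / |r|)) / 2` with `r` the 5th percentile of the
#' negative values of the channel, clamped to `[0, m/2]`.  Channels without
#' negative values get `w = 0` (a plain log-like scale).
#'
#' @param x Channel values on the linear scale.
#' @param T Top of scale.
#' @param m Decades.
#' @return The estimated width in decades.
#' @export
estimate_logicle_width <- function(x, T = 262144, m = 4.5) {
  neg <- x[x < 0]
  if (!length(neg)) return(0)
  r <- stats::quantile(neg, 0.05, names = FALSE)
  w <- (m - log10(T / abs(r))) / 2
  min(max(w, 0), m / 2)
}

apply_channel_transform <- function(x, row, inverse = FALSE) {
  switch(row$type,
         identity = x,
         asinh = if (inverse) sinh(x) * row$cofactor else asinh(x / row$cofactor),
         logicle = if (inverse) logicle_inverse(x, row$T, row$m, row$w)
                   else logicle(x, row$T, row$m, row$w))
}

#' Transform an EventTable to the analysis scale
#'
#' Applies the per-channel transforms of `spec`; channels absent from the
#' spec are left unchanged.  Event count and order are preserved.
#'
#' @param events An `EventTable`.
#' @param spec A [transform_spec()].
#' @param estimate_w If `TRUE`, logicle widths are re-estimated per channel
#'   from the data via [estimate_logicle_width()].
#' @return The transformed `EventTable`.
#' @export
transform_events <- function(events, spec, estimate_w = FALSE) {
  for (i in seq_len(nrow(spec))) {
    row <- spec[i, ]
    if (!row$channel %in% events$channels) next
    if (estimate_w && row$type == "logicle") {
      row$w <- estimate_logicle_width(events$exprs[, row$channel], row$T, row$m)
    }
    events$exprs[, row$channel] <- apply_channel_transform(
      events$exprs[, row$channel], row)
  }
  events
}

#' Invert [transform_events()]
#' @inheritParams transform_events
#' @return The `EventTable` back on the linear scale.
#' @export
inverse_transform_events <- function(events, spec) {
  for (i in seq_len(nrow(spec))) {
    row <- spec[i, ]
    if (!row$channel %in% events$channels) next
    events$exprs[, row$channel] <- apply_channel_transform(
      events$exprs[, row$channel], row, inverse = TRUE)
  }
  events
}
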