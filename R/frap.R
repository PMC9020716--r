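# FRAP quantification: concentric-region integrated intensity,
# pre-bleach normalization and single-exponential recovery fitting.
#
# Images are numeric matrices indexed [row = y, col = x]; rectangles are
# given as c(x0, y0, x1, y1) in 0-based, half-open pixel coordinates.

#' Concentric region pair around a structure of interest
#'
#' The inner rectangle encloses the structure (e.g. a centrosome); the
#' ring between inner and outer rectangles samples the local cytoplasmic
#' background.
#'
#' @param inner,outer Rectangles `c(x0, y0, x1, y1)` in 0-based,
#'   half-open pixel coordinates; `inner` must lie strictly inside
#'   `outer` so the background ring is non-empty.
#' @return A `region_pair` list.
#' @export
region_pair <- function(inner, outer) {
  check_rect <- function(r, nm) {
    if (length(r) != 4 || any(r < 0) || r[3] <= r[1] || r[4] <= r[2])
      stop("invalid ", nm, " rectangle: need c(x0, y0, x1, y1) with ",
           "x1 > x0, y1 > y0")
    as.integer(r)
  }
  inner <- check_rect(inner, "inner")
  outer <- check_rect(outer, "outer")
  if (inner[1] < outer[1] || inner[2] < outer[2] ||
      inner[3] > outer[3] || inner[4] > outer[4])
    stop("inner region must be contained in outer region")
  if (all(inner == outer)) stop("background ring is empty")
  structure(list(inner = inner, outer = outer), class = "region_pair")
}

rect_mask <- function(dim, rect) {
  # dim = c(ny, nx); rect = c(x0, y0, x1, y1), 0-based half-open
  m <- matrix(FALSE, dim[1], dim[2])
  if (rect[4] > dim[1] || rect[3] > dim[2])
    stop("region out of image bounds")
  m[(rect[2] + 1):rect[4], (rect[1] + 1):rect[3]] <- TRUE
  m
}

#' Background-corrected integrated intensity of a region pair
#'
#' Computes (mean intensity in the inner region minus mean intensity in
#' the ring between inner and outer regions) multiplied by the inner
#' region's pixel area.  The ring mean estimates the local background.
#'
#' @param frame Numeric matrix (a single image plane).
#' @param regions A [region_pair()].
#' @return Background-corrected integrated intensity (scalar).
#' @export
integrated_intensity <- function(frame, regions) {
  stopifnot(is.matrix(frame), inherits(regions, "region_pair"))
  inner <- rect_mask(dim(frame), regions$inner)
  outer <- rect_mask(dim(frame), regions$outer)
  ring <- outer & !inner
  if (!any(ring)) stop("background ring is empty")
  (mean(frame[inner]) - mean(frame[ring])) * sum(inner)
}

#' Construct a FRAP trace
#'
#' @param times Acquisition times in seconds, strictly increasing.
#' @param raw Integrated intensities, one per time point.
#' @param bleach_index 1-based index of the first post-bleach time point;
#'   points before it are pre-bleach.
#' @param normalized Optional normalized intensities (filled by
#'   [normalize_trace()]).
#' @return A `frap_trace` list.
#' @export
frap_trace <- function(times, raw, bleach_index, normalized = NULL) {
  stopifnot(length(times) == length(raw))
  if (is.unsorted(times, strictly = TRUE))
    stop("times must be strictly increasing")
  bleach_index <- as.integer(bleach_index)
  if (bleach_index < 1 || bleach_index > length(times))
    stop("bleach_index out of range")
  if (!is.null(normalized) && length(normalized) != length(raw))
    stop("normalized must match raw in length")
  structure(list(times = as.numeric(times), raw = as.numeric(raw),
                 bleach_index = bleach_index, normalized = normalized),
            class = "frap_trace")
}

#' @export
print.frap_trace <- function(x, ...) {
  cat("frap_trace:", length(x$times), "time points,",
      x$bleach_index - 1, "pre-bleach;",
      if (is.null(x$normalized)) "raw" else "normalized", "\n")
  invisible(x)
}

#' Extract a FRAP trace from an image stack
#'
#' Applies [integrated_intensity()] to every frame of a time series.
#'
#' @param stack 3-D numeric array `[y, x, t]` or list of matrices, one
#'   frame per time point.
#' @param regions A single [region_pair()] used for all frames, or a list
#'   with one pair per frame (for a drifting structure).
#' @param times Acquisition times in seconds.
#' @param bleach_index 1-based index of the first post-bleach frame.
#' @return A raw `frap_trace`.
#' @export
extract_trace <- function(stack, regions, times, bleach_index) {
  frames <- if (is.array(stack) && length(dim(stack)) == 3)
    lapply(seq_len(dim(stack)[3]), function(i) stack[, , i])
  else if (is.list(stack)) stack
  else stop("stack must be a 3-D array or a list of matrices")
  if (length(frames) != length(times))
    stop("number of frames (", length(frames),
         ") does not match number of times (", length(times), ")")
  per_frame <- if (inherits(regions, "region_pair"))
    rep(list(regions), length(frames)) else regions
  if (length(per_frame) != length(frames))
    stop("need one region pair per frame")
  raw <- mapply(integrated_intensity, frames, per_frame)
  frap_trace(times, raw, bleach_index)
}

#' Normalize a FRAP trace to its pre-bleach intensity
#'
#' Divides the whole trace by the mean of the pre-bleach measurements, so
#' 1.0 corresponds to the unbleached steady state.
#'
#' @param trace A `frap_trace`.
#' @param n_prebleach Number of pre-bleach frames (counted backwards from
#'   the bleach) to average; default all available.
#' @return The trace with its `normalized` field filled.
#' @export
normalize_trace <- function(trace, n_prebleach = NULL) {
  stopifnot(inherits(trace, "frap_trace"))
  if (trace$bleach_index < 2)
    stop("no pre-bleach points to normalize to")
  pre <- seq_len(trace$bleach_index - 1)
  if (!is.null(n_prebleach))
    pre <- utils::tail(pre, n_prebleach)
  base <- mean(trace$raw[pre])
  if (base <= 0) stop("pre-bleach mean must be positive")
  trace$normalized <- trace$raw / base
  trace
}

#' Fit the single-exponential recovery model to a FRAP trace
#'
#' Fits `Y = A * (1 - exp(-k * X)) + B` by nonlinear least squares to the
#' post-bleach points of a normalized trace, with `X` measured from the
#' first post-bleach time point.  `A` is the mobile fraction, `B` the
#' background remaining right after the bleach, and the recovery
#' half-time is `t_half = ln(2) / k`.  Starting values are derived from
#' the data (plateau span for `A`, first post-bleach value for `B`, time
#' to half-plateau for `k`), with up to 5 jittered restarts on failure.
#'
#' @param trace A normalized `frap_trace` with at least 4 post-bleach
#'   points (run [normalize_trace()] first).
#' @return A `recovery_fit` list with elements `A`, `k`, `B`, `t_half`,
#'   `r_squared`, plus `fitted` values and the post-bleach `x`/`y` used.
#' @export
#' @examples
#' tr <- generate_frap_trace(A = 0.8, k = 0.2, B = 0.05,
#'                           times = 0:35, bleach_index = 6,
#'                           noise_sd = 0, seed = 1)
#' fit_recovery(normalize_trace(tr))
fit_recovery <- function(trace) {
  stopifnot(inherits(trace, "frap_trace"))
  if (is.null(trace$normalized))
    stop("trace is not normalized; run normalize_trace() first")
  post <- trace$bleach_index:length(trace$times)
  if (length(post) < 4)
    stop("need at least 4 post-bleach points to fit 3 parameters")
  x <- trace$times[post] - trace$times[trace$bleach_index]
  y <- trace$normalized[post]

  b0 <- y[1]
  a0 <- max(max(y) - b0, 0.1)
  half_level <- b0 + a0 / 2
  i_half <- which(y >= half_level)[1]
  k0 <- if (!is.na(i_half) && x[i_half] > 0) log(2) / x[i_half]
        else 1 / max(x[length(x)] / 4, .Machine$double.eps)

  try_fit <- function(st) tryCatch(
    minpack.lm::nlsLM(y ~ A * (1 - exp(-k * x)) + B,
                      start = as.list(st),
                      control = minpack.lm::nls.lm.control(
                        maxiter = 200, ftol = 1e-12, ptol = 1e-12)),
    error = function(e) NULL)

  fit <- NULL
  start <- c(A = a0, k = k0, B = b0)
  for (attempt in 0:5) {
    st <- if (attempt == 0) start else {
      jit <- with_seed(attempt, stats::runif(3, 0.3, 3))
      start * jit
    }
    fit <- try_fit(st)
    if (!is.null(fit)) break
  }
  # the k > 0 basin can shadow a better k < 0 optimum when the trace
  # grows instead of recovering; try the reflected start and keep the
  # lower-deviance optimum so such traces are flagged, not mis-fit
  refl <- try_fit(c(A = -a0, k = -k0, B = b0))
  if (!is.null(refl) &&
      (is.null(fit) || stats::deviance(refl) < stats::deviance(fit)))
    fit <- refl
  if (is.null(fit))
    stop("recovery fit did not converge after restarts; best residual ",
         "unavailable for starting values A=", signif(a0, 3),
         " k=", signif(k0, 3), " B=", signif(b0, 3))
  est <- stats::coef(fit)
  if (est[["k"]] <= 0) stop("no recovery detected (fitted rate k <= 0)")
  fitted_y <- stats::fitted(fit)
  ss_res <- sum((y - fitted_y)^2)
  ss_tot <- sum((y - mean(y))^2)
  structure(list(
    A = unname(est[["A"]]), k = unname(est[["k"]]),
    B = unname(est[["B"]]),
    t_half = log(2) / est[["k"]],
    r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else 1,
    fitted = as.numeric(fitted_y), x = x, y = y
  ), class = "recovery_fit")
}

#' @export
print.recovery_fit <- function(x, ...) {
  cat(sprintf(
    "recovery_fit: A = %.3f, k = %.4f /s, B = %.3f, t1/2 = %.2f s, R2 = %.4f\n",
    x$A, x$k, x$B, x$t_half, x$r_squared))
  invisible(x)
}

#' Fit an ensemble of FRAP traces and summarize
#'
#' @param traces List of normalized `frap_trace` objects.
#' @return List with `fits` (data frame of per-trace A, k, B, t_half,
#'   r_squared) and `summary` (one-row data frame of ensemble means and
#'   SDs of A and t_half).
#' @export
fit_recovery_ensemble <- function(traces) {
  fits <- lapply(traces, fit_recovery)
  tab <- data.frame(
    trace = seq_along(fits),
    A = vapply(fits, `[[`, numeric(1), "A"),
    k = vapply(fits, `[[`, numeric(1), "k"),
    B = vapply(fits, `[[`, numeric(1), "B"),
    t_half = vapply(fits, `[[`, numeric(1), "t_half"),
    r_squared = vapply(fits, `[[`, numeric(1), "r_squared"))
  list(fits = tab,
       summary = data.frame(n = nrow(tab),
                            mean_A = mean(tab$A), sd_A = stats::sd(tab$A),
                            mean_t_half = mean(tab$t_half),
                            sd_t_half = stats::sd(tab$t_half)))
}
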