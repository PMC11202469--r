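#' The q sweep grid
#'
#' @param start,stop Endpoints of the sweep, `start >= 0`.
#' @param step Grid spacing, > 0.  The defaults (0 to 100 by 0.001) give
#'   the 100001-point grid used throughout.
#' @return Numeric vector of q values, closed at both ends.
#' @export
q_grid <- function(start = 0, stop = 100, step = 0.001) {
  if (start < 0) stop("`start` must be >= 0")
  if (step <= 0) stop("`step` must be > 0")
  if (stop < start) stop("`stop` must be >= `start`")
  seq(start, stop, by = step)
}

#' Coarse-grain a series
#'
#' Non-overlapping window averages at scale `s`: element `j` of the
#' output is the mean of samples `(j-1)s + 1` through `js`; trailing
#' samples that do not fill a window are dropped.  `s = 1` returns the
#' series unchanged.
#'
#' @param x Numeric vector.
#' @param s Scale factor, integer >= 1 and <= `length(x)`.
#' @return Numeric vector of length `floor(length(x) / s)`.
#' @export
coarse_grain <- function(x, s) {
  s <- as.integer(s)
  if (s < 1L) stop("scale `s` must be >= 1")
  if (s > length(x)) stop(sprintf("scale s = %d exceeds the series length %d", s, length(x)))
  if (s == 1L) return(x)
  n_win <- length(x) %/% s
  colMeans(matrix(x[seq_len(n_win * s)], nrow = s))
}

#' Entropy-complexity curve over a q grid
#'
#' Coarse-grains the series at scale `s`, normalizes and symbolizes it
#' once, then sweeps `q` to produce the normalized Tsallis entropy `Hq`
#' and statistical complexity `Cq` at every grid point.  Plotting `Hq`
#' against `Cq` traces the causality-plane signature of the series.
#'
#' @param x Numeric vector, the raw series.
#' @param m Embedding dimension (default 4).
#' @param tau Time delay (default 1).
#' @param L Quantization levels (default 4).
#' @param q Numeric vector of q values, typically [q_grid()].
#' @param s Coarse-graining scale (default 1, the raw series).
#' @return A `plane_curve`: a data frame with columns `q`, `Hq`, `Cq`,
#'   `delta_q`, and attributes `m`, `tau`, `L`, `scale`, `n` (length of
#'   the coarse-grained series) and `n_states`.
#' @export
causality_curve <- function(x, m = 4L, tau = 1L, L = 4L, q = q_grid(), s = 1L) {
  xc <- coarse_grain(x, s)
  d <- ipe_distribution(xc, m = m, tau = tau, L = L)
  out <- curve_from_distribution(d, q, s = s, n = length(xc))
  attr(out, "m") <- as.integer(m)
  attr(out, "tau") <- as.integer(tau)
  attr(out, "L") <- as.integer(L)
  out
}

#' Entropy-complexity curve of an explicit distribution
#'
#' The q sweep of [causality_curve()] starting from an already-computed
#' pattern distribution (or dense probability vector), useful for
#' synthetic injections and ensemble work.
#'
#' @param d A `pattern_distribution` or dense probability vector.
#' @param q Numeric vector of q values.
#' @param s Scale recorded in the result (metadata only).
#' @param n Series length recorded in the result (metadata only).
#' @return A `plane_curve` data frame.
#' @export
curve_from_distribution <- function(d, q = q_grid(), s = 1L, n = NA_integer_) {
  parts <- .dist_parts(d)
  Hq <- .tsallis_parts(parts, q) / .max_entropy(parts$n, q)
  dq <- .q_jsd_uniform(parts, q) / max_q_jsd(parts$n, q)
  out <- data.frame(q = q, Hq = Hq, Cq = dq * Hq, delta_q = dq)
  attr(out, "m") <- if (inherits(d, "pattern_distribution")) d$m else NA
  attr(out, "tau") <- NA
  attr(out, "L") <- if (inherits(d, "pattern_distribution")) d$L else NA
  attr(out, "scale") <- as.integer(s)
  attr(out, "n") <- n
  attr(out, "n_states") <- parts$n
  class(out) <- c("plane_curve", "data.frame")
  out
}

#' Characteristic points of a plane curve
#'
#' `q_H_star` is the grid q at which `Hq` attains its minimum and
#' `q_C_star` the grid q at which `Cq` attains its maximum; ties are
#' broken toward the smallest q.  A curve that is constant in both
#' coordinates is flagged as degenerate (both features then sit at the
#' smallest grid q).
#'
#' @param curve A `plane_curve`.
#' @return A `plane_features` one-row data frame with columns `scale`,
#'   `q_H_star`, `H_min`, `q_C_star`, `C_max`, `degenerate`.
#' @export
extract_features <- function(curve) {
  if (!inherits(curve, "plane_curve") || nrow(curve) < 1L)
    stop("`curve` must be a nonempty plane_curve")
  ord <- order(curve$q)
  qv <- curve$q[ord]; H <- curve$Hq[ord]; C <- curve$Cq[ord]
  iH <- which.min(H)   # first index at ties: smallest q
  iC <- which.max(C)
  out <- data.frame(
    scale = attr(curve, "scale") %||% NA_integer_,
    q_H_star = qv[iH], H_min = H[iH],
    q_C_star = qv[iC], C_max = C[iC],
    degenerate = (max(H) - min(H) == 0) && (max(C) - min(C) == 0))
  class(out) <- c("plane_features", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Multiscale plane features
#'
#' Computes one causality-plane curve and its characteristic points per
#' coarse-graining scale.  The concatenated `(q_H_star, q_C_star)` pairs
#' across scales form a classifier-ready feature vector.
#'
#' @inheritParams causality_curve
#' @param scales Integer vector of scales (default `1:20`).  Every scale
#'   must leave at least `(m - 1) * tau + 1` coarse-grained samples.
#' @return A list of class `multiscale_features` with elements
#'   `features` (one `plane_features` row per scale) and `curves` (named
#'   list of `plane_curve`s).
#' @export
multiscale_features <- function(x, m = 4L, tau = 1L, L = 4L, q = q_grid(),
                                scales = 1:20) {
  scales <- as.integer(scales)
  need <- (as.integer(m) - 1L) * as.integer(tau) + 1L
  bad <- scales[length(x) %/% scales < need]
  if (length(bad))
    stop(sprintf("scale %d leaves fewer than %d coarse-grained samples",
                 bad[1L], need))
  curves <- lapply(scales, function(s) causality_curve(x, m, tau, L, q, s))
  names(curves) <- paste0("scale_", scales)
  features <- do.call(rbind, lapply(curves, extract_features))
  rownames(features) <- NULL
  structure(list(features = features, curves = curves),
            class = "multiscale_features")
}

#' Pointwise ensemble mean of plane curves
#'
#' Averages `Hq` and `Cq` across realizations at each grid q.  Feature
#' extraction can then run on the mean curve; per-realization features
#' are available by mapping [extract_features()] over the input list.
#'
#' @param curves List of `plane_curve`s computed on identical q grids.
#' @return A `plane_curve` with the averaged coordinates.
#' @export
average_curves <- function(curves) {
  if (!length(curves)) stop("`curves` must be a nonempty list")
  q0 <- curves[[1L]]$q
  for (cv in curves)
    if (!isTRUE(all.equal(cv$q, q0)))
      stop("all curves must share the same q grid")
  out <- data.frame(
    q = q0,
    Hq = rowMeans(sapply(curves, `[[`, "Hq")),
    Cq = rowMeans(sapply(curves, `[[`, "Cq")),
    delta_q = rowMeans(sapply(curves, `[[`, "delta_q")))
  for (a in c("m", "tau", "L", "scale", "n", "n_states"))
    attr(out, a) <- attr(curves[[1L]], a)
  class(out) <- c("plane_curve", "data.frame")
  out
}

#' @export
print.multiscale_features <- function(x, ...) {
  cat(sprintf("<multiscale_features> %d scales\n", nrow(x$features)))
  print(x$features)
  invisible(x)
}
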