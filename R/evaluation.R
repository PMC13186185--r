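# Per-site missingness signals and dynamic time warping, used to compare the
# spatial pattern of missingness an empirical segment carries with the
# pattern a masked replicate of a different length reproduces.

#' Extract the per-site missingness signal
#'
#' The signal is the ordered vector of per-site proportions of samples whose
#' genotype is fully missing, in genomic order.
#'
#' @param x A non-empty [geno_matrix].
#' @return A numeric vector of length `n_sites(x)`, each entry in `[0, 1]`.
#' @export
extract_signal <- function(x) {
  if (n_sites(x) < 1L) stop("matrix has no sites")
  site_missing_prop(x)
}

#' Average equal-length signals element-wise
#'
#' @param signals List of numeric vectors of identical length (e.g. signals
#'   from repeated masking runs under different seeds).
#' @return The element-wise mean signal.
#' @export
average_signals <- function(signals) {
  stopifnot(length(signals) >= 1L)
  len <- lengths(signals)
  if (any(len != len[1])) stop("signals differ in length")
  Reduce(`+`, signals) / length(signals)
}

# cumulative-cost matrix for classic DTW with local cost |a_i - b_k|
dtw_matrix <- function(a, b) {
  n <- length(a)
  m <- length(b)
  cost <- abs(outer(a, b, `-`))
  D <- matrix(Inf, n + 1L, m + 1L)
  D[1L, 1L] <- 0
  for (i in seq_len(n)) {
    prev <- D[i, ]
    cur <- D[i + 1L, ]
    ci <- cost[i, ]
    for (k in seq_len(m)) {
      cur[k + 1L] <- ci[k] + min(prev[k + 1L], cur[k], prev[k])
    }
    D[i + 1L, ] <- cur
  }
  D
}

#' Dynamic time warping distance between two signals
#'
#' Classic unconstrained, unnormalized DTW: with local cost
#' `|a[i] - b[k]|`, the cumulative cost follows
#' `D(i,k) = |a[i]-b[k]| + min(D(i-1,k), D(i,k-1), D(i-1,k-1))`, the warping
#' path starts at `(1,1)` and ends at `(length(a), length(b))`, and the
#' returned value is the total cost of the optimal path. Lower means the two
#' signals are more similar; identical signals give 0.
#'
#' @param a,b Non-empty numeric vectors (typically missingness signals of
#'   different lengths).
#' @return A single non-negative number.
#' @examples
#' dtw_distance(c(0, 0, 1), c(0, 1))   # 0: b is a compressed a
#' @export
dtw_distance <- function(a, b) {
  if (length(a) < 1L || length(b) < 1L) stop("signals must be non-empty")
  D <- dtw_matrix(a, b)
  D[length(a) + 1L, length(b) + 1L]
}

#' DTW distance with the optimal warping path
#'
#' Same recurrence as [dtw_distance()], plus a backtrace of one optimal
#' monotone warping path (ties broken diagonal, then up, then left).
#'
#' @inheritParams dtw_distance
#' @return A list with `distance` and `path`, a tibble with columns
#'   `index_a`, `index_b` and the local `cost` at each aligned pair.
#' @export
dtw_alignment <- function(a, b) {
  if (length(a) < 1L || length(b) < 1L) stop("signals must be non-empty")
  D <- dtw_matrix(a, b)
  i <- length(a)
  k <- length(b)
  ii <- i
  kk <- k
  while (i > 1L || k > 1L) {
    step <- which.min(c(D[i, k], D[i, k + 1L], D[i + 1L, k]))
    if (step == 1L) {
      i <- i - 1L
      k <- k - 1L
    } else if (step == 2L) {
      i <- i - 1L
    } else {
      k <- k - 1L
    }
    ii <- c(i, ii)
    kk <- c(k, kk)
  }
  path <- tibble::tibble(index_a = ii, index_b = kk,
                         cost = abs(a[ii] - b[kk]))
  list(distance = D[length(a) + 1L, length(b) + 1L], path = path)
}

#' Plot missingness signals along their segments
#'
#' Overlays signals of possibly different lengths on a common relative
#' coordinate (position along the segment in `[0, 1]`).
#'
#' @param signals Named list of numeric signals.
#' @return A ggplot.
#' @export
plot_missingness_signals <- function(signals) {
  stopifnot(length(signals) >= 1L, !is.null(names(signals)))
  d <- dplyr::bind_rows(lapply(names(signals), function(nm) {
    v <- signals[[nm]]
    tibble::tibble(signal = nm,
                   rel_pos = seq(0, 1, length.out = length(v)),
                   f_miss = v)
  }))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$rel_pos, y = .data$f_miss,
                                  colour = .data$signal)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "relative position", y = "proportion of samples missing")
}
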