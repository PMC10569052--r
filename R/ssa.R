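#' Singular spectrum analysis of a daily series
#'
#' Embeds the series in a Hankel trajectory matrix of window length `L`,
#' takes its singular value decomposition, and reconstructs each elementary
#' component by diagonal (anti-diagonal) averaging. Components are grouped
#' by the standard frequency criterion: the leading component, plus any
#' further component whose reconstruction carries most of its power at
#' periods longer than the window, form the trend (a linear trend spreads
#' over two components, so grouping by frequency rather than by rank
#' recovers it whole); among the rest, consecutive pairs with near-equal
#' singular values (the signature of a sine/cosine pair) are grouped as
#' oscillatory, everything else as the remainder. The three grouped series
#' sum back to the input exactly (to numerical precision) because the
#' elementary decomposition is complete.
#'
#' @param x Numeric vector, e.g. daily nightly-bias values. Missing values
#'   are not allowed; interpolate or split runs beforehand.
#' @param L Window length, `2 <= L <= length(x)/2`. Default
#'   `min(30, floor(length(x)/3))`, separating longer-than-monthly trend
#'   from shorter oscillations.
#' @param pair_tol Relative tolerance on singular-value equality used to
#'   pair oscillatory components (default 0.05).
#' @return An object of class `aq_ssa`: a list with `series` (the input),
#'   `L`, `trend`, `oscillatory`, `remainder` (numeric vectors of the input
#'   length), `shares` (eigenvalue shares, sum to 1) and `groups`
#'   (component-to-group assignment).
#' @examples
#' s <- ssa_decompose(sin(2 * pi * (1:120) / 30) + (1:120) / 60)
#' max(abs(s$trend + s$oscillatory + s$remainder - s$series))
#' @export
ssa_decompose <- function(x, L = NULL, pair_tol = 0.05) {
  x <- as.numeric(x)
  n <- length(x)
  if (anyNA(x)) stop("ssa_decompose requires a gap-free series", call. = FALSE)
  if (is.null(L)) L <- max(2L, min(30L, floor(n / 3)))
  L <- as.integer(L)
  if (n < 2 * L || L < 2) {
    stop(sprintf("series length %d too short for window L = %d (need N >= 2L, L >= 2)", n, L),
      call. = FALSE
    )
  }
  K <- n - L + 1L
  traj <- sapply(seq_len(K), function(j) x[j:(j + L - 1L)]) # L x K Hankel
  sv <- svd(traj)
  d <- sv$d
  nc <- sum(d > max(d[1], 1) * 1e-12)
  nc <- max(nc, 1L)

  # reconstruct elementary component i by diagonal averaging of d_i u_i v_i^T
  diag_avg <- function(u, vvec, dval) {
    comp <- numeric(n)
    cnt <- numeric(n)
    m <- dval * tcrossprod(u, vvec)
    for (j in seq_len(K)) {
      idx <- j:(j + L - 1L)
      comp[idx] <- comp[idx] + m[, j]
      cnt[idx] <- cnt[idx] + 1
    }
    comp / cnt
  }
  comps <- sapply(seq_len(nc), function(i) diag_avg(sv$u[, i], sv$v[, i], d[i]))
  comps <- matrix(comps, nrow = n)
  resid_comp <- x - rowSums(comps) # rank beyond nc (numerically zero)

  total <- sum(d^2)
  shares <- if (total > 0) d^2 / total else rep(1 / length(d), length(d))

  # share of a component's power at periods longer than the window
  low_freq_share <- function(v) {
    p <- Mod(stats::fft(v))^2
    freq <- (seq_along(v) - 1) / length(v)
    low <- freq <= 1 / L | freq >= 1 - 1 / L # fft is symmetric about n/2
    if (sum(p) == 0) 1 else sum(p[low]) / sum(p)
  }
  groups <- rep("remainder", nc)
  groups[1] <- "trend"
  i <- 2L
  while (i <= nc) {
    if (low_freq_share(comps[, i]) >= 0.5) {
      groups[i] <- "trend"
      i <- i + 1L
    } else if (i < nc && d[i] > 0 && abs(d[i] - d[i + 1L]) / d[i] < pair_tol &&
      low_freq_share(comps[, i + 1L]) < 0.5) {
      groups[c(i, i + 1L)] <- "oscillatory"
      i <- i + 2L
    } else {
      i <- i + 1L
    }
  }
  sum_group <- function(g) {
    sel <- which(groups == g)
    if (length(sel)) rowSums(comps[, sel, drop = FALSE]) else numeric(n)
  }
  structure(
    list(
      series = x, L = L,
      trend = sum_group("trend"),
      oscillatory = sum_group("oscillatory"),
      remainder = sum_group("remainder") + resid_comp,
      shares = shares[seq_len(nc)] / sum(shares[seq_len(nc)]),
      groups = groups
    ),
    class = "aq_ssa"
  )
}

#' @export
print.aq_ssa <- function(x, ...) {
  cat(sprintf(
    "<aq_ssa> N = %d, L = %d; trend share %.1f%%, oscillatory %.1f%%, remainder %.1f%%\n",
    length(x$series), x$L,
    100 * sum(x$shares[x$groups == "trend"]),
    100 * sum(x$shares[x$groups == "oscillatory"]),
    100 * sum(x$shares[x$groups == "remainder"])
  ))
  invisible(x)
}

#' Tidy an SSA decomposition into long format
#' @param x An `aq_ssa` object.
#' @param ... Unused.
#' @return A tibble with columns `index`, `component`
#'   (series/trend/oscillatory/remainder) and `value`.
#' @export
tidy.aq_ssa <- function(x, ...) {
  n <- length(x$series)
  tibble::tibble(
    index = rep(seq_len(n), 4),
    component = rep(c("series", "trend", "oscillatory", "remainder"), each = n),
    value = c(x$series, x$trend, x$oscillatory, x$remainder)
  )
}

#' @export
autoplot.aq_ssa <- function(object, ...) {
  ggplot2::ggplot(tidy.aq_ssa(object), ggplot2::aes(.data$index, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~component, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "Day", y = "Value")
}
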