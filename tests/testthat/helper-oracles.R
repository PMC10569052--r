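# independent dense-matrix construction of the optimal-interpolation
# analysis: builds the full grid covariance B, a dense observation
# operator H and the gain K = B H' (H B H' + R)^-1 explicitly, with its
# own distance and kernel code. Used only as an oracle in tests.
oi_dense_oracle <- function(x_b, obs, cfg) {
  ny <- x_b$ny
  nx <- x_b$nx
  G <- nx * ny
  cx <- x_b$origin[1] + (rep(seq_len(nx), each = ny) - 0.5) * x_b$cell_size
  cy <- x_b$origin[2] + (rep(seq_len(ny), times = nx) - 0.5) * x_b$cell_size
  dmat <- sqrt(outer(cx, cx, "-")^2 + outer(cy, cy, "-")^2)
  rho <- if (cfg$kernel == "gaussian") {
    exp(-dmat^2 / (2 * cfg$correlation_length^2))
  } else {
    exp(-dmat / cfg$correlation_length)
  }
  if (!is.null(cfg$localization_radius)) rho[dmat > cfg$localization_radius] <- 0
  B <- cfg$sigma_b^2 * rho

  p <- nrow(obs)
  H <- matrix(0, p, G)
  for (i in seq_len(p)) {
    if (cfg$operator == "nearest") {
      col <- min(max(floor((obs$easting[i] - x_b$origin[1]) / x_b$cell_size) + 1, 1), nx)
      row <- min(max(floor((obs$northing[i] - x_b$origin[2]) / x_b$cell_size) + 1, 1), ny)
      H[i, (col - 1) * ny + row] <- 1
    } else {
      fx <- (obs$easting[i] - x_b$origin[1]) / x_b$cell_size - 0.5
      fy <- (obs$northing[i] - x_b$origin[2]) / x_b$cell_size - 0.5
      c0 <- min(max(floor(fx) + 1, 1), nx - 1)
      r0 <- min(max(floor(fy) + 1, 1), ny - 1)
      tx <- min(max(fx - (c0 - 1), 0), 1)
      ty <- min(max(fy - (r0 - 1), 0), 1)
      H[i, (c0 - 1) * ny + r0] <- (1 - tx) * (1 - ty)
      H[i, c0 * ny + r0] <- tx * (1 - ty)
      H[i, (c0 - 1) * ny + r0 + 1] <- (1 - tx) * ty
      H[i, c0 * ny + r0 + 1] <- tx * ty
    }
  }
  xb_vec <- as.vector(x_b$values)
  R <- diag(obs$var, p)
  K <- B %*% t(H) %*% solve(H %*% B %*% t(H) + R)
  xa_vec <- xb_vec + drop(K %*% (obs$value - drop(H %*% xb_vec)))
  list(
    analysis = matrix(xa_vec, ny, nx),
    analysis_at_sites = drop(H %*% xa_vec),
    background_at_sites = drop(H %*% xb_vec)
  )
}

random_obs <- function(g, p, sd_range = c(0.5, 4)) {
  tibble::tibble(
    site_id = sprintf("s%d", seq_len(p)),
    easting = stats::runif(p, 0, g$nx * g$cell_size),
    northing = stats::runif(p, 0, g$ny * g$cell_size),
    value = stats::runif(p, 4, 20),
    var = stats::runif(p, sd_range[1], sd_range[2])^2,
    source = "lcs"
  )
}
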