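#' Thin-plate-spline warp grid at a principal component extreme
#'
#' Visualizes the shape deformation from the mean shape to a position along
#' a principal component (by default the most extreme observed score), as
#' the classic bent Cartesian grid.
#'
#' @param pca A [pca_shapes()] result.
#' @param pc Component number (default 1).
#' @param extreme `"max"`, `"min"`, or a numeric score.
#' @param grid_n Grid lines per axis (default 24).
#' @return A ggplot object.
#' @export
plot_warpgrid <- function(pca, pc = 1, extreme = c("max", "min"),
                          grid_n = 24) {
  score <- if (is.numeric(extreme)) extreme else {
    extreme <- match.arg(extreme)
    s <- pca$scores[[paste0("PC", pc)]]
    if (extreme == "max") max(s) else min(s)
  }
  k <- length(pca$center) / 2
  ref <- matrix(pca$center, k, 2)
  target <- matrix(pca$center + score * pca$loadings[, pc], k, 2)
  rng_x <- range(ref[, 1]); rng_y <- range(ref[, 2])
  pad_x <- 0.1 * diff(rng_x); pad_y <- 0.1 * diff(rng_y)
  gx <- seq(rng_x[1] - pad_x, rng_x[2] + pad_x, length.out = grid_n)
  gy <- seq(rng_y[1] - pad_y, rng_y[2] + pad_y, length.out = grid_n)
  grid_pts <- as.matrix(expand.grid(x = gx, y = gy))
  warped <- tps_warp(ref, target, grid_pts)
  d <- tibble(x = warped[, 1], y = warped[, 2],
              row = rep(seq_len(grid_n), each = grid_n),
              col = rep(seq_len(grid_n), grid_n))
  lm_d <- tibble(x = target[, 1], y = target[, 2])
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_path(ggplot2::aes(group = .data$row), linewidth = 0.2,
                       colour = "grey55") +
    ggplot2::geom_path(ggplot2::aes(group = .data$col), linewidth = 0.2,
                       colour = "grey55") +
    ggplot2::geom_point(data = lm_d, colour = "firebrick", size = 1) +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("PC%d warp at score %.3g", pc, score),
                  x = NULL, y = NULL) +
    ggplot2::theme_void()
}

# thin-plate-spline interpolation mapping ref -> target, applied to pts
tps_warp <- function(ref, target, pts) {
  k <- nrow(ref)
  d2 <- as.matrix(stats::dist(ref))^2
  K <- ifelse(d2 > 0, d2 * log(d2), 0)
  Q <- cbind(1, ref)
  L <- rbind(cbind(K, Q), cbind(t(Q), matrix(0, 3, 3)))
  rhs <- rbind(target, matrix(0, 3, 2))
  coefs <- solve(L, rhs)
  W <- coefs[seq_len(k), , drop = FALSE]
  A <- coefs[k + 1:3, , drop = FALSE]
  d2p <- outer(rowSums(pts^2), rowSums(ref^2), "+") - 2 * pts %*% t(ref)
  d2p[d2p < 1e-300] <- 1e-300
  U <- d2p * log(d2p)
  cbind(1, pts) %*% A + U %*% W
}
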