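#' Centroid size of landmark configurations
#'
#' The standard geometric-morphometric size measure: the square root of the
#' summed squared distances of the landmarks to their centroid. Invariant to
#' rotation and translation, and linear under uniform scaling.
#'
#' @param shapes Landmark tibble (`id`, `landmark`, `x`, `y`) with one or
#'   more configurations, or a single k x 2 coordinate matrix.
#' @return A tibble with columns `id` and `csize` (original units), or a
#'   single number for a matrix input.
#' @export
#' @examples
#' sq <- tibble::tibble(id = "sq", landmark = 1:4,
#'                      x = c(-.5, .5, .5, -.5), y = c(-.5, -.5, .5, .5))
#' centroid_size(sq)  # sqrt(2)
centroid_size <- function(shapes) {
  cs_one <- function(m) {
    if (nrow(m) < 2) abort("centroid size needs at least 2 landmarks")
    cen <- colMeans(m)
    cs <- sqrt(sum((m[, 1] - cen[1])^2 + (m[, 2] - cen[2])^2))
    if (cs <= 0) abort("all landmarks coincide: zero centroid size")
    cs
  }
  if (is.matrix(shapes)) return(cs_one(shapes))
  out <- lapply(split(shapes, factor(shapes$id, unique(shapes$id))),
                function(d) cs_one(config_matrix(d)))
  tibble(id = names(out), csize = unlist(out, use.names = FALSE))
}

# centre a k x 2 matrix and return it with its centroid size
center_config <- function(m) {
  cen <- colMeans(m)
  m[, 1] <- m[, 1] - cen[1]; m[, 2] <- m[, 2] - cen[2]
  m
}

# optimal rotation (no reflection) of b onto a, both centred
procrustes_rotation <- function(a, b) {
  s <- svd(crossprod(b, a))
  d <- sign(det(s$u %*% t(s$v)))
  s$u %*% diag(c(1, d)) %*% t(s$v)
}

#' Procrustes distance between two configurations
#'
#' The root-sum-of-squares difference after both configurations are centred,
#' scaled to unit centroid size and optimally rotated (partial Procrustes
#' distance; reflections are not allowed). Symmetric, and zero exactly when
#' the two configurations are similar. On unit-size centred pairs this
#' equals `sqrt(2 - 2 * sum(sigma))`, the singular-value closed form.
#'
#' @param a,b Landmark tibbles of a single configuration each, or k x 2
#'   matrices with matching landmark count.
#' @return Non-negative number.
#' @export
procrustes_distance <- function(a, b) {
  ma <- config_matrix(a); mb <- config_matrix(b)
  if (nrow(ma) != nrow(mb)) abort("configurations differ in landmark count")
  ma <- center_config(ma); mb <- center_config(mb)
  ca <- sqrt(sum(ma^2)); cb <- sqrt(sum(mb^2))
  if (ca <= 0 || cb <= 0) abort("degenerate configuration (zero size)")
  ma <- ma / ca; mb <- mb / cb
  r <- procrustes_rotation(ma, mb)
  sqrt(sum((ma - mb %*% r)^2))
}

#' Generalized Procrustes superimposition with sliding semilandmarks
#'
#' Iteratively translates every configuration to zero centroid, scales it to
#' unit centroid size, rotates it onto the running consensus by orthogonal
#' Procrustes (reflections disallowed), and recomputes the consensus, until
#' the consensus changes by less than `tol` (root-sum-of-squares). When a
#' curve-slide table is supplied, semilandmarks are slid once per outer
#' iteration (see [slide_semilandmarks()]). The procedure is deterministic.
#'
#' @param shapes Landmark tibble with at least 2 configurations of at least
#'   3 landmarks.
#' @param curves Optional [read_curveslide()] table; `NULL` for fixed
#'   landmarks only.
#' @param slide_mode `"bending"` (thin-plate-spline bending energy, default)
#'   or `"procrustes"` (Procrustes distance to the consensus).
#' @param tol Convergence tolerance on the consensus within a
#'   superimposition pass (default 1e-10).
#' @param max_iter Maximum iterations of a superimposition pass (default
#'   100).
#' @param slide_iter Maximum sliding passes (default 10). Sliding moves
#'   semilandmarks along a direction the superimposition itself cannot pin
#'   down, so convergence of the sliding phase is judged on its objective:
#'   the phase stops when the summed sliding objective changes by less than
#'   `slide_tol` relative to its value.
#' @param slide_tol Relative tolerance for the sliding objective (default
#'   1e-7).
#' @param scale Scale configurations to unit centroid size (default TRUE).
#' @return An object of class `gpa_fit` with elements `coords` (aligned
#'   coordinates, long tibble), `consensus`, `csize` (per-specimen centroid
#'   sizes in original units), `n_iter`, `slid`, `mode`, `converged`.
#' @export
align_gpa <- function(shapes, curves = NULL,
                      slide_mode = c("bending", "procrustes"),
                      tol = 1e-10, max_iter = 100, slide_iter = 10,
                      slide_tol = 1e-7, scale = TRUE) {
  slide_mode <- match.arg(slide_mode)
  arr <- shapes_to_array(shapes)
  k <- dim(arr)[1]; n <- dim(arr)[3]
  if (n < 2) abort("need at least 2 configurations")
  if (k < 3) abort("need at least 3 landmarks")
  if (!is.null(curves)) curves <- validate_curveslide(curves, k = k)
  ids <- dimnames(arr)[[3]]
  cs <- numeric(n)
  for (j in seq_len(n)) {
    m <- center_config(arr[, , j])
    cs[j] <- sqrt(sum(m^2))
    if (cs[j] <= 0) abort(paste0("zero-size configuration: ", ids[j]))
    sv <- svd(m)$d
    if (sv[2] / sv[1] < 1e-12)
      abort(paste0("degenerate (collinear) configuration: ", ids[j]))
    arr[, , j] <- if (scale) m / cs[j] else m
  }
  consensus <- arr[, , 1]
  consensus <- consensus / sqrt(sum(consensus^2))
  iter <- 0L
  superimpose <- function(arr, consensus) {
    delta <- Inf; it <- 0L
    while (it < max_iter && delta > tol) {
      it <- it + 1L
      for (j in seq_len(n)) {
        m <- center_config(arr[, , j])
        if (scale) m <- m / sqrt(sum(m^2))
        arr[, , j] <- m %*% procrustes_rotation(consensus, m)
      }
      new_consensus <- apply(arr, c(1, 2), mean)
      new_consensus <- center_config(new_consensus)
      if (scale) new_consensus <- new_consensus / sqrt(sum(new_consensus^2))
      delta <- sqrt(sum((new_consensus - consensus)^2))
      consensus <- new_consensus
    }
    if (delta > tol)
      abort(sprintf("GPA did not converge in %d iterations (last delta %.3g)",
                    max_iter, delta))
    list(arr = arr, consensus = consensus, it = it)
  }
  fit <- superimpose(arr, consensus)
  arr <- fit$arr; consensus <- fit$consensus; iter <- fit$it
  if (!is.null(curves) && nrow(curves) > 0) {
    obj <- sum(vapply(seq_len(n), function(j)
      slide_objective(arr[, , j], consensus, slide_mode), numeric(1)))
    for (pass in seq_len(slide_iter)) {
      arr <- slide_array(arr, consensus, curves, slide_mode)
      fit <- superimpose(arr, consensus)
      arr <- fit$arr; consensus <- fit$consensus; iter <- iter + fit$it
      obj_new <- sum(vapply(seq_len(n), function(j)
        slide_objective(arr[, , j], consensus, slide_mode), numeric(1)))
      done <- abs(obj - obj_new) <= slide_tol * max(obj, .Machine$double.eps)
      obj <- obj_new
      if (done) break
    }
  }
  # orientation standardization: principal axes of the consensus, with a
  # deterministic 180-degree tie-break, so the fit is invariant to a common
  # rotation of all input configurations
  rot <- svd(consensus)$v
  if (det(rot) < 0) rot[, 2] <- -rot[, 2]
  consensus_r <- consensus %*% rot
  skew <- sum(consensus_r[, 1]^3)
  if (skew < 0 || (abs(skew) < 1e-12 && sum(consensus_r[, 2]^3) < 0))
    rot <- -rot
  consensus <- consensus %*% rot
  for (j in seq_len(n)) arr[, , j] <- arr[, , j] %*% rot
  structure(list(
    coords = array_to_shapes(arr),
    consensus = tibble(landmark = seq_len(k),
                       x = consensus[, 1], y = consensus[, 2]),
    csize = tibble(id = ids, csize = cs),
    n_iter = iter, slid = !is.null(curves) && nrow(curves) > 0,
    mode = if (is.null(curves)) NA_character_ else slide_mode,
    converged = TRUE
  ), class = "gpa_fit")
}

#' Slide semilandmarks along their curve tangents
#'
#' Each sliding semilandmark moves along the tangent direction defined by
#' its `before`/`after` neighbours. Per specimen, the tangent displacements
#' jointly minimize either the thin-plate-spline bending energy of the
#' deformation from the consensus (`"bending"`) or the squared Procrustes
#' distance to the consensus (`"procrustes"`). Fixed landmarks never move,
#' and every displacement is bounded by half the distance to the nearer
#' neighbour (a fold-over guard): when the unconstrained optimum violates
#' the bound, the whole displacement vector is shrunk towards zero, which
#' preserves the guarantee that the objective does not increase.
#'
#' @param shapes Aligned landmark tibble.
#' @param consensus Consensus configuration (tibble with `landmark`, `x`,
#'   `y`).
#' @param curves Curve-slide table.
#' @param mode `"bending"` or `"procrustes"`.
#' @return The shapes tibble with semilandmarks adjusted.
#' @export
slide_semilandmarks <- function(shapes, consensus, curves,
                                mode = c("bending", "procrustes")) {
  mode <- match.arg(mode)
  arr <- shapes_to_array(shapes)
  curves <- validate_curveslide(curves, k = dim(arr)[1])
  cons <- config_matrix(consensus)
  array_to_shapes(slide_array(arr, cons, curves, mode))
}

slide_array <- function(arr, cons, curves, mode) {
  k <- dim(arr)[1]
  B <- if (mode == "bending") {
    L <- bending_energy_matrix(cons)
    rbind(cbind(L, matrix(0, k, k)), cbind(matrix(0, k, k), L))
  } else diag(2 * k)
  for (j in seq_len(dim(arr)[3]))
    arr[, , j] <- slide_one(arr[, , j], cons, curves, B)
  arr
}

slide_one <- function(X, cons, curves, B) {
  k <- nrow(X); m <- nrow(curves)
  tangents <- X[curves$after, , drop = FALSE] - X[curves$before, , drop = FALSE]
  len <- sqrt(rowSums(tangents^2))
  if (any(len <= 0)) abort("degenerate tangent: before and after coincide")
  tangents <- tangents / len
  U <- matrix(0, 2 * k, m)
  for (q in seq_len(m)) {
    s <- curves$slide[q]
    U[s, q] <- tangents[q, 1]; U[k + s, q] <- tangents[q, 2]
  }
  z0 <- c(X[, 1] - cons[, 1], X[, 2] - cons[, 2])
  BU <- B %*% U
  H <- crossprod(U, BU)
  H <- H + diag(1e-12 * max(diag(H)), m)
  tt <- -solve(H, crossprod(BU, z0))
  # fold-over guard: half the distance to each neighbour
  lim <- 0.5 * pmin(
    sqrt(rowSums((X[curves$slide, , drop = FALSE] -
                  X[curves$before, , drop = FALSE])^2)),
    sqrt(rowSums((X[curves$slide, , drop = FALSE] -
                  X[curves$after, , drop = FALSE])^2)))
  over <- abs(tt) > lim
  alpha <- if (any(over)) min(lim[over] / abs(tt)[over]) else 1
  disp <- U %*% (alpha * tt)
  X + cbind(disp[seq_len(k)], disp[k + seq_len(k)])
}

# thin-plate-spline bending energy matrix of a reference configuration
bending_energy_matrix <- function(P) {
  k <- nrow(P)
  d2 <- as.matrix(stats::dist(P))^2
  K <- ifelse(d2 > 0, d2 * log(d2), 0)
  Q <- cbind(1, P)
  L <- rbind(cbind(K, Q), cbind(t(Q), matrix(0, 3, 3)))
  Li <- solve(L)
  Lbe <- Li[seq_len(k), seq_len(k)]
  (Lbe + t(Lbe)) / 2
}

# bending-energy / squared-distance objective used in tests and sliding
slide_objective <- function(X, cons, mode) {
  if (mode == "procrustes") return(sum((X - cons)^2))
  L <- bending_energy_matrix(cons)
  dx <- X[, 1] - cons[, 1]; dy <- X[, 2] - cons[, 2]
  drop(t(dx) %*% L %*% dx + t(dy) %*% L %*% dy)
}

#' @export
print.gpa_fit <- function(x, ...) {
  cat("<gpa_fit>", nrow(x$csize), "configurations,",
      max(x$coords$landmark), "landmarks;",
      x$n_iter, "iterations;",
      if (x$slid) paste0("semilandmarks slid (", x$mode, ")") else "no sliding",
      "\n")
  invisible(x)
}

#' @describeIn align_gpa Aligned coordinates joined with centroid sizes.
#' @param x A `gpa_fit`.
#' @param ... Unused.
#' @export
tidy.gpa_fit <- function(x, ...) {
  left_join(x$coords, x$csize, by = "id")
}

#' @describeIn align_gpa One-row fit summary.
#' @export
glance.gpa_fit <- function(x, ...) {
  tibble(n = nrow(x$csize), k = max(x$coords$landmark),
         n_iter_gpa = x$n_iter, slid = x$slid, mode = x$mode,
         converged = x$converged, mean_csize = mean(x$csize$csize))
}

#' Export a GPA consensus as a TPS record
#' @param x A `gpa_fit`.
#' @param path Output TPS path.
#' @export
write_consensus_tps <- function(x, path) {
  write_tps(mutate(x$consensus, id = "consensus", scale = 1), path)
}

#' @describeIn align_gpa Aligned shapes overplotted with the consensus.
#' @param object A `gpa_fit`.
#' @export
autoplot.gpa_fit <- function(object, ...) {
  ggplot2::ggplot(object$coords, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(ggplot2::aes(group = .data$id), alpha = 0.25, size = 0.7) +
    ggplot2::geom_point(data = object$consensus, colour = "firebrick", size = 1.6) +
    ggplot2::coord_equal() +
    ggplot2::labs(title = "Procrustes-aligned shapes", x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}
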