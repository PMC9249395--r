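test_that("centroid size matches hand geometry and the direct formula", {
  sq <- tibble::tibble(id = "sq", landmark = 1:4,
                       x = c(-.5, .5, .5, -.5), y = c(-.5, -.5, .5, .5))
  expect_equal(centroid_size(sq)$csize, sqrt(2), tolerance = 1e-12)
  cfg <- random_config(38, 11)
  m <- cbind(cfg$x, cfg$y)
  # brute-force loop over the defining formula
  cen <- c(mean(m[, 1]), mean(m[, 2]))
  acc <- 0
  for (j in 1:38) acc <- acc + (m[j, 1] - cen[1])^2 + (m[j, 2] - cen[2])^2
  expect_equal(centroid_size(cfg)$csize, sqrt(acc), tolerance = 1e-12)
  # rotation invariance
  rotated <- dplyr::mutate(cfg, x0 = x, x = -y, y = x0)[c("id", "landmark", "x", "y")]
  expect_equal(centroid_size(rotated)$csize, centroid_size(cfg)$csize,
               tolerance = 1e-12)
  # linear under uniform scaling
  expect_equal(centroid_size(dplyr::mutate(cfg, x = 3 * x, y = 3 * y))$csize,
               3 * centroid_size(cfg)$csize, tolerance = 1e-12)
  coincident <- tibble::tibble(id = "pt", landmark = 1:3, x = 1, y = 2)
  expect_error(centroid_size(coincident), "zero centroid size")
})

test_that("procrustes distance is a similarity-invariant metric with the SVD closed form", {
  a <- random_config(12, 21); b <- random_config(12, 22)
  expect_equal(procrustes_distance(a, a), 0, tolerance = 1e-12)
  expect_equal(procrustes_distance(a, b), procrustes_distance(b, a),
               tolerance = 1e-12)
  # closed form sqrt(2 - 2 sum(sigma)) on centred unit-size pairs
  ma <- scale(cbind(a$x, a$y), scale = FALSE); ma <- ma / sqrt(sum(ma^2))
  mb <- scale(cbind(b$x, b$y), scale = FALSE); mb <- mb / sqrt(sum(mb^2))
  sv <- svd(t(mb) %*% ma)$d
  if (det(t(mb) %*% ma) < 0) sv[2] <- -sv[2]   # no reflections allowed
  expect_equal(procrustes_distance(a, b), sqrt(2 - 2 * sum(sv)),
               tolerance = 1e-10)
  # a similarity transform of a is at distance zero
  m2 <- (2.3 * cbind(a$x, a$y) %*% t(rot2(0.646))) + 5
  b2 <- tibble::tibble(id = "t", landmark = 1:12, x = m2[, 1], y = m2[, 2])
  expect_lt(procrustes_distance(a, b2), 1e-12)
})

test_that("GPA removes similarity transforms exactly", {
  a <- random_config(10, 31)
  m <- cbind(a$x, a$y)
  m2 <- 2.3 * m %*% t(rot2(37 * pi / 180)) + matrix(c(4, -7), 10, 2, byrow = TRUE)
  shapes <- dplyr::bind_rows(a, tibble::tibble(id = "copy", landmark = 1:10,
                                               x = m2[, 1], y = m2[, 2]))
  fit <- align_gpa(shapes)
  arr <- cuspkit:::shapes_to_array(fit$coords)
  expect_lt(sqrt(sum((arr[, , 1] - arr[, , 2])^2)), 1e-10)
  # identical configurations coincide with the consensus
  cons <- cbind(fit$consensus$x, fit$consensus$y)
  expect_lt(sqrt(sum((arr[, , 1] - cons)^2)), 1e-10)
})

test_that("GPA agrees with an independent alternating-minimization oracle", {
  set.seed(99)
  arr <- array(rnorm(3 * 2 * 5), c(3, 2, 5),
               dimnames = list(NULL, NULL, paste0("t", 1:5)))
  shapes <- cuspkit:::array_to_shapes(arr)
  fit <- align_gpa(shapes)
  oracle <- brute_gpa(arr)
  # consensus shapes agree up to a rotation
  d_cons <- procrustes_distance(
    tibble::tibble(id = "a", landmark = 1:3, x = fit$consensus$x,
                   y = fit$consensus$y),
    tibble::tibble(id = "b", landmark = 1:3, x = oracle$consensus[, 1],
                   y = oracle$consensus[, 2]))
  expect_lt(d_cons, 1e-8)
  # rotation-invariant residual structure agrees specimen by specimen
  got <- cuspkit:::shapes_to_array(fit$coords)
  for (j in 1:5) {
    d1 <- sqrt(sum((got[, , j] - cbind(fit$consensus$x, fit$consensus$y))^2))
    d2 <- sqrt(sum((oracle$arr[, , j] - oracle$consensus)^2))
    expect_equal(d1, d2, tolerance = 1e-6)
  }
})

test_that("GPA output is invariant to a common similarity transform of all inputs", {
  set.seed(7)
  shapes <- dplyr::bind_rows(lapply(1:6, function(j) random_config(9, 40 + j)))
  fit1 <- align_gpa(shapes)
  R <- rot2(1.1)
  moved <- shapes
  pts <- 0.37 * cbind(shapes$x, shapes$y) %*% t(R)
  moved$x <- pts[, 1] + 11; moved$y <- pts[, 2] - 3
  fit2 <- align_gpa(moved)
  expect_equal(fit1$coords$x, fit2$coords$x, tolerance = 1e-9)
  expect_equal(fit1$coords$y, fit2$coords$y, tolerance = 1e-9)
})

test_that("aligned configurations satisfy the unit-size and consensus-optimality invariants", {
  set.seed(12)
  shapes <- dplyr::bind_rows(lapply(1:5, function(j) random_config(7, 50 + j)))
  fit <- align_gpa(shapes)
  arr <- cuspkit:::shapes_to_array(fit$coords)
  for (j in 1:5) {
    expect_lt(max(abs(colMeans(arr[, , j]))), 1e-9)        # centred
    expect_equal(sqrt(sum(arr[, , j]^2)), 1, tolerance = 1e-9)  # unit CS
  }
  # consensus equals the mean of the aligned configurations up to norm
  mean_shape <- apply(arr, c(1, 2), mean)
  mean_shape <- mean_shape / sqrt(sum(mean_shape^2))
  expect_equal(mean_shape[, 1], fit$consensus$x, tolerance = 1e-8,
               ignore_attr = TRUE)
  # degenerate collinear specimen is named
  line <- tibble::tibble(id = "flatline", landmark = 1:7,
                         x = as.numeric(1:7), y = 2 * (1:7) + 1)
  expect_error(align_gpa(dplyr::bind_rows(shapes, line)), "flatline")
})

make_arc_shapes <- function(n = 4, k = 8, jitter = 0.05) {
  th <- seq(0.2, pi - 0.2, length.out = k)
  dplyr::bind_rows(lapply(seq_len(n), function(j) {
    set.seed(700 + j)
    tibble::tibble(id = paste0("arc", j), landmark = seq_len(k),
                   x = cos(th) + jitter * rnorm(k),
                   y = sin(th) + jitter * rnorm(k))
  }))
}

arc_curves <- tibble::tibble(before = c(2, 3, 4), slide = c(3, 4, 5),
                             after = c(4, 5, 6))

test_that("sliding is a no-op at its optimum and recovers a tangent perturbation", {
  cons <- align_gpa(make_arc_shapes())$consensus
  cons_cfg <- tibble::tibble(id = "c", landmark = cons$landmark,
                             x = cons$x, y = cons$y)
  for (mode in c("bending", "procrustes")) {
    slid <- slide_semilandmarks(cons_cfg, cons, arc_curves, mode = mode)
    expect_equal(slid$x, cons_cfg$x, tolerance = 1e-9)
    expect_equal(slid$y, cons_cfg$y, tolerance = 1e-9)
  }
  # perturb one semilandmark along its own tangent: procrustes-mode sliding
  # pulls it back to the consensus position (1D quadratic minimum)
  pert <- cons_cfg
  tang <- c(cons$x[5] - cons$x[3], cons$y[5] - cons$y[3])
  tang <- tang / sqrt(sum(tang^2))
  eps <- 0.02
  pert$x[4] <- pert$x[4] + eps * tang[1]
  pert$y[4] <- pert$y[4] + eps * tang[2]
  slid <- slide_semilandmarks(pert, cons, arc_curves, mode = "procrustes")
  expect_equal(slid$x[4], cons_cfg$x[4], tolerance = 1e-3)
  expect_equal(slid$y[4], cons_cfg$y[4], tolerance = 1e-3)
})

test_that("sliding matches a dense grid-search minimizer on a toy arc", {
  shapes <- make_arc_shapes(n = 3)
  fit <- align_gpa(shapes)          # no sliding: defines the consensus
  cons <- cbind(fit$consensus$x, fit$consensus$y)
  one <- cuspkit:::shapes_to_array(fit$coords)[, , 2]
  for (mode in c("bending", "procrustes")) {
    slid <- cuspkit:::slide_one(
      one, cons, arc_curves,
      if (mode == "bending") {
        L <- cuspkit:::bending_energy_matrix(cons)
        rbind(cbind(L, matrix(0, 8, 8)), cbind(matrix(0, 8, 8), L))
      } else diag(16))
    # independent oracle: coarse-to-fine grid search over tangent offsets
    tangents <- (one[arc_curves$after, ] - one[arc_curves$before, ])
    tangents <- tangents / sqrt(rowSums(tangents^2))
    apply_t <- function(tv) {
      X <- one
      for (q in 1:3) {
        s <- arc_curves$slide[q]
        X[s, ] <- X[s, ] + tv[q] * tangents[q, ]
      }
      X
    }
    objective <- function(tv) cuspkit:::slide_objective(apply_t(tv), cons, mode)
    best <- c(0, 0, 0)
    span <- 0.2
    for (level in 1:6) {
      grid <- expand.grid(t1 = best[1] + seq(-span, span, length.out = 11),
                          t2 = best[2] + seq(-span, span, length.out = 11),
                          t3 = best[3] + seq(-span, span, length.out = 11))
      vals <- apply(grid, 1, objective)
      best <- as.numeric(grid[which.min(vals), ])
      span <- span / 4
    }
    oracle <- apply_t(best)
    expect_equal(slid, oracle, tolerance = 1e-4)
  }
})

test_that("sliding never increases its objective and GPA+sliding keeps invariants", {
  shapes <- make_arc_shapes(n = 5, jitter = 0.08)
  for (mode in c("bending", "procrustes")) {
    fit0 <- align_gpa(shapes)
    cons <- cbind(fit0$consensus$x, fit0$consensus$y)
    arr <- cuspkit:::shapes_to_array(fit0$coords)
    before <- sum(sapply(1:5, function(j)
      cuspkit:::slide_objective(arr[, , j], cons, mode)))
    slid <- cuspkit:::slide_array(arr, cons, arc_curves, mode)
    after <- sum(sapply(1:5, function(j)
      cuspkit:::slide_objective(slid[, , j], cons, mode)))
    expect_lte(after, before + 1e-12)
    fit <- align_gpa(shapes, curves = arc_curves, slide_mode = mode)
    expect_true(fit$slid)
    arr2 <- cuspkit:::shapes_to_array(fit$coords)
    for (j in 1:5)
      expect_equal(sqrt(sum(arr2[, , j]^2)), 1, tolerance = 1e-9)
  }
})

test_that("degenerate tangents are rejected", {
  bad <- tibble::tibble(before = 2, slide = 3, after = 2)
  expect_error(validate_curveslide(bad), "distinct")
  shapes <- make_arc_shapes(n = 2)
  dup <- shapes
  dup$x[dup$landmark == 4] <- dup$x[dup$landmark == 2][1]
  # coincident before/after points produce a zero-length tangent
  one <- cuspkit:::shapes_to_array(align_gpa(shapes)$coords)[, , 1]
  one[2, ] <- one[4, ]
  expect_error(cuspkit:::slide_one(one, one, arc_curves, diag(16)),
               "degenerate tangent")
})
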