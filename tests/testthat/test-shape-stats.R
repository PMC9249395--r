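toy_meta <- function(n_groups = 3, per_group = 4, teeth = 1) {
  grid <- expand.grid(g = seq_len(n_groups), s = seq_len(per_group),
                      t = seq_len(teeth))
  tibble::tibble(
    id = sprintf("g%d_s%d_t%d", grid$g, grid$s, grid$t),
    sample_id = sprintf("g%d_s%d", grid$g, grid$s),
    treatment = c("DMSO", "IWR", "CHIR")[grid$g])
}

toy_shapes <- function(meta, k = 5, effect = 1, seed = 3) {
  set.seed(seed)
  offs <- setNames(effect * c(0, 1, -1), c("DMSO", "IWR", "CHIR"))
  dplyr::bind_rows(lapply(seq_len(nrow(meta)), function(i)
    tibble::tibble(id = meta$id[i], landmark = seq_len(k),
                   x = rnorm(k) + offs[[meta$treatment[i]]],
                   y = rnorm(k))))
}

test_that("identical specimens give zero sums of squares everywhere", {
  meta <- toy_meta(3, 4, 2)
  one <- random_config(5, 1)
  shapes <- dplyr::bind_rows(lapply(meta$id, function(i)
    dplyr::mutate(one, id = i)))
  an <- procrustes_anova(shapes, meta, n_perm = 9, seed = 1)
  expect_lt(abs(an$SS[an$term == "treatment"]), 1e-10)
  expect_lt(abs(an$SS[an$term == "Total"]), 1e-10)
})

test_that("sequential SS, R2 and F match an explicit hat-matrix oracle", {
  meta <- toy_meta(3, 2, 2)   # 12 shapes, 3 groups, nested samples
  shapes <- toy_shapes(meta, k = 4, effect = 0.8)
  an <- procrustes_anova(shapes, meta, n_perm = 9, seed = 1)
  # oracle: explicit projection matrices H = X (X'X)^- X'
  Y <- do.call(rbind, lapply(meta$id, function(i) {
    d <- shapes[shapes$id == i, ]
    c(d$x, d$y)
  }))
  hat <- function(X) X %*% MASS::ginv(crossprod(X)) %*% t(X)
  n <- nrow(Y)
  X0 <- matrix(1, n, 1)
  X1 <- stats::model.matrix(~ treatment, data = meta)
  X2 <- stats::model.matrix(~ treatment + sample_id, data = meta)
  H0 <- hat(X0); H1 <- hat(X1); H2 <- hat(X2)
  ss <- function(M) sum(diag(t(Y) %*% M %*% Y))
  ss_tr <- ss(H1 - H0); ss_sm <- ss(H2 - H1); ss_res <- ss(diag(n) - H2)
  ss_tot <- ss(diag(n) - H0)
  df_tr <- qr(X1)$rank - 1; df_sm <- qr(X2)$rank - qr(X1)$rank
  df_res <- n - qr(X2)$rank
  expect_equal(an$SS[1:2], c(ss_tr, ss_sm), tolerance = 1e-9)
  expect_equal(an$SS[an$term == "Residuals"], ss_res, tolerance = 1e-9)
  expect_equal(an$df[1:3], c(df_tr, df_sm, df_res))
  expect_equal(an$R2[1], ss_tr / ss_tot, tolerance = 1e-12)
  expect_equal(an$F[1], (ss_tr / df_tr) / (ss_res / df_res), tolerance = 1e-12)
  # bookkeeping invariant: term SS + residual = total
  expect_equal(sum(an$SS[1:2]) + an$SS[an$term == "Residuals"],
               an$SS[an$term == "Total"], tolerance = 1e-9)
  expect_true(all(an$R2[1:2] >= 0 & an$R2[1:2] <= 1))
})

test_that("the shape machinery reduces to univariate sequential ANOVA on scalars", {
  meta <- toy_meta(3, 3, 2)
  set.seed(8)
  cs <- tibble::tibble(id = meta$id,
                       csize = rnorm(nrow(meta)) +
                         2 * (meta$treatment == "IWR"))
  an <- procrustes_anova(cs, meta, n_perm = 49, seed = 2)
  ref <- anova(stats::lm(cs$csize ~ treatment + sample_id,
                         data = dplyr::mutate(meta,
                                              treatment = factor(treatment),
                                              sample_id = factor(sample_id))))
  expect_equal(an$SS[1:2], ref$`Sum Sq`[1:2], tolerance = 1e-10)
  expect_equal(an$F[1:2], ref$`F value`[1:2], tolerance = 1e-10)
  expect_equal(an$df[1:2], ref$Df[1:2])
})

test_that("RRPP p-values are seed-reproducible and SS/F independent of n_perm", {
  meta <- toy_meta(3, 2, 2)
  shapes <- toy_shapes(meta, effect = 0.5)
  a1 <- procrustes_anova(shapes, meta, n_perm = 99, seed = 42)
  a2 <- procrustes_anova(shapes, meta, n_perm = 99, seed = 42)
  a3 <- procrustes_anova(shapes, meta, n_perm = 299, seed = 42)
  expect_identical(a1$p_perm, a2$p_perm)
  expect_equal(a1$F, a3$F, tolerance = 1e-14)
  expect_equal(a1$SS, a3$SS, tolerance = 1e-14)
})

test_that("PCA variance proportions behave like an eigen-decomposition", {
  # rank-1 data: a single axis explains everything
  meta1 <- toy_meta(3, 2, 1)
  base <- random_config(4, 5)
  shapes1 <- dplyr::bind_rows(lapply(seq_len(nrow(meta1)), function(i)
    dplyr::mutate(base, id = meta1$id[i], x = x + 0.1 * i)))
  p1 <- pca_shapes(shapes1, meta1, level = "tooth")
  expect_equal(p1$var_prop[1], 100, tolerance = 1e-9)
  # toy matrix against a direct eigen oracle
  meta2 <- toy_meta(3, 2, 1)
  shapes2 <- toy_shapes(meta2, k = 2, effect = 0.4, seed = 10)
  p2 <- pca_shapes(shapes2, meta2, level = "tooth")
  Y <- do.call(rbind, lapply(meta2$id, function(i) {
    d <- shapes2[shapes2$id == i, ]; c(d$x, d$y)
  }))
  ev <- eigen(stats::cov(Y))$values
  expect_equal(p2$var_prop, 100 * ev / sum(ev), tolerance = 1e-9)
  expect_equal(sum(p2$var_prop), 100, tolerance = 1e-9)
  # invariance to specimen order
  perm <- sample(nrow(meta2))
  p3 <- pca_shapes(shapes2[order(match(shapes2$id, meta2$id[perm])), ],
                   meta2[perm, ], level = "tooth")
  expect_equal(sort(p3$var_prop), sort(p2$var_prop), tolerance = 1e-9)
  expect_error(pca_shapes(shapes2[shapes2$id %in% meta2$id[1:2], ],
                          meta2[1:2, ], level = "tooth"), "at least 3")
})

test_that("sample-mean PCA averages the teeth of each sample first", {
  meta <- toy_meta(3, 3, 2)
  shapes <- toy_shapes(meta, k = 3, effect = 1, seed = 12)
  psm <- pca_shapes(shapes, meta, level = "sample_mean")
  expect_equal(nrow(psm$scores), 9)   # 3 groups x 3 samples
  expect_true(all(c("sample_id", "treatment") %in% names(psm$scores)))
})

test_that("size model recovers group structure, Tukey pairs and percent change", {
  meta <- toy_meta(3, 4, 3)
  set.seed(20)
  mult <- c(DMSO = 1, IWR = 0.6, CHIR = 1.2)
  cs <- tibble::tibble(id = meta$id,
                       csize = 10 * mult[meta$treatment] *
                         exp(rnorm(nrow(meta), 0, 0.01)))
  sm <- size_model(cs, meta)
  expect_equal(nrow(sm$tukey), 3)      # one row per unordered pair
  pc <- sm$group_means$pct_change
  names(pc) <- as.character(sm$group_means$treatment)
  expect_equal(pc[["DMSO"]], 0)
  expect_equal(pc[["IWR"]], -40, tolerance = 1)
  expect_equal(pc[["CHIR"]], 20, tolerance = 1)
  # scale equivariance: percent changes unchanged under common rescaling
  sm2 <- size_model(dplyr::mutate(cs, csize = 7.3 * csize), meta)
  expect_equal(sm2$group_means$pct_change, sm$group_means$pct_change,
               tolerance = 1e-10)
  # equal group means give zero change and F near zero
  cs0 <- tibble::tibble(id = meta$id, csize = 5 + rnorm(nrow(meta), 0, 1e-3))
  sm0 <- size_model(cs0, meta)
  expect_lt(max(abs(sm0$group_means$pct_change)), 0.1)
  expect_error(size_model(cs, dplyr::mutate(meta, treatment = "IWR")),
               "control")
})

test_that("variance F-test matches construction and var.test", {
  meta <- toy_meta(2, 4, 2)[, c("id", "treatment")]
  set.seed(30)
  scores <- tibble::tibble(id = meta$id,
                           PC1 = ifelse(meta$treatment == "IWR",
                                        rnorm(nrow(meta), 0, 2),
                                        rnorm(nrow(meta), 0, 1)))
  scores <- dplyr::left_join(scores, meta, by = "id")
  same <- dplyr::mutate(scores, PC1 = rep(c(1, 2, 3, 4), length.out = dplyr::n()))
  f_same <- variance_ftest(same, pair = c("DMSO", "IWR"))
  expect_equal(f_same$F, 1, tolerance = 1e-12)
  # construct exact variance ratio 4 -> F = 0.25
  g1 <- scores$treatment == "DMSO"
  constructed <- scores
  constructed$PC1[g1] <- scale(constructed$PC1[g1]) * 1
  constructed$PC1[!g1] <- scale(constructed$PC1[!g1]) * 2
  f_c <- variance_ftest(constructed, pair = c("DMSO", "IWR"))
  expect_equal(f_c$F, 0.25, tolerance = 1e-12)
  ref <- stats::var.test(constructed$PC1[g1], constructed$PC1[!g1])
  expect_equal(f_c$F, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(f_c$p_value, ref$p.value, tolerance = 1e-12)
  expect_equal(c(f_c$df1, f_c$df2), unname(ref$parameter))
})

test_that("chi-square of proportions matches the hand Pearson formula", {
  tab <- matrix(c(10, 90, 30, 70), 2, 2, byrow = TRUE)
  got <- chisq_proportions(tab)
  # direct Pearson computation
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(got$chi2, sum((tab - E)^2 / E), tolerance = 1e-12)
  expect_equal(got$df, 1)
  equal <- matrix(c(20, 80, 20, 80), 2, 2, byrow = TRUE)
  expect_equal(chisq_proportions(equal)$chi2, 0, tolerance = 1e-12)
  expect_error(chisq_proportions(matrix(c(0, 0, 5, 5), 2, 2, byrow = TRUE)),
               "marginal")
  expect_error(chisq_proportions(matrix(c(1.5, 2, 3, 4), 2, 2)), "integers")
  # continuity correction is a switch
  got_c <- chisq_proportions(tab, correct = TRUE)
  expect_lt(got_c$chi2, got$chi2)
})
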