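#' Procrustes ANOVA with residual randomization (RRPP)
#'
#' Sequential (type-I) decomposition of shape or size variation over an
#' ordered series of factors, with treatment first and sample nested within
#' treatment, matching the standard design for repeatedly measured teeth.
#' Sums of squares are computed on the flattened Procrustes-aligned
#' coordinates (or on scalar centroid sizes, to which the machinery reduces
#' exactly). Significance comes from residual randomization: for each term,
#' residuals of its reduced model are permuted, added back to the reduced
#' fit, and the term's F statistic recomputed; the p-value is the
#' proportion of permuted statistics at or above the observed one
#' (including the observed permutation). `df`, `SS`, `R2` and `F` are
#' deterministic regardless of `n_perm`.
#'
#' @param data A [align_gpa()] fit (shape response), a long coordinate
#'   tibble, or a centroid-size tibble (`id`, `csize`) for a univariate
#'   analysis.
#' @param meta Specimen metadata with `id` and the factor columns.
#' @param terms Ordered factor columns of `meta`; nested terms arise
#'   naturally when level codes are unique (default
#'   `c("treatment", "sample_id")`).
#' @param n_perm Number of random permutations (default 999; the observed
#'   arrangement is added).
#' @param seed Integer seed for the permutations.
#' @return A tibble of class `shape_anova` with columns `term`, `df`, `SS`,
#'   `MS`, `R2`, `F`, `p_perm` (rows for each term, plus `Residuals` and
#'   `Total`), and attributes `n_perm`, `seed`.
#' @export
procrustes_anova <- function(data, meta, terms = c("treatment", "sample_id"),
                             n_perm = 999, seed = 1L) {
  Y <- response_matrix(data, meta)
  n <- nrow(Y)
  if (!all(terms %in% names(meta)))
    abort(paste0("metadata lacks factor column(s): ",
                 paste(setdiff(terms, names(meta)), collapse = ", ")))
  if (length(unique(meta[[terms[1]]])) < 2)
    abort("first factor needs at least 2 groups")
  # orthonormal bases of the cumulative model matrices
  bases <- list(qr_basis(matrix(1, n, 1)))
  for (c_i in seq_along(terms)) {
    f <- lapply(terms[seq_len(c_i)], function(t) factor(meta[[t]]))
    X <- stats::model.matrix(~ ., data = as.data.frame(setNames(f, terms[seq_len(c_i)])))
    bases[[c_i + 1]] <- qr_basis(X)
  }
  ranks <- vapply(bases, ncol, integer(1))
  df <- diff(ranks)
  df_res <- n - ranks[length(ranks)]
  if (df_res <= 0) abort("singular design: no residual degrees of freedom")
  fit_ss <- vapply(bases, function(G) sum(crossprod(G, Y)^2), numeric(1))
  ss_total <- sum(Y^2) - fit_ss[1]
  ss_terms <- diff(fit_ss)
  ss_res <- sum(Y^2) - fit_ss[length(fit_ss)]
  ms <- ss_terms / df
  f_obs <- ms / (ss_res / df_res)
  # residual randomization, same permutation schedule for every term
  set.seed(seed)
  perms <- replicate(n_perm, sample.int(n))
  p_perm <- vapply(seq_along(terms), function(c_i) {
    G_red <- bases[[c_i]]; G_cum <- bases[[c_i + 1]]; G_full <- bases[[length(bases)]]
    fitted_red <- G_red %*% crossprod(G_red, Y)
    resid_red <- Y - fitted_red
    count <- 1L
    for (b in seq_len(n_perm)) {
      Yb <- fitted_red + resid_red[perms[, b], , drop = FALSE]
      tot <- sum(Yb^2)
      ss_b <- sum(crossprod(G_cum, Yb)^2) - sum(crossprod(G_red, Yb)^2)
      res_b <- tot - sum(crossprod(G_full, Yb)^2)
      f_b <- (ss_b / df[c_i]) / (res_b / df_res)
      if (f_b >= f_obs[c_i] - 1e-12) count <- count + 1L
    }
    count / (n_perm + 1)
  }, numeric(1))
  out <- tibble(
    term = c(terms, "Residuals", "Total"),
    df = c(df, df_res, n - 1L),
    SS = c(ss_terms, ss_res, ss_total),
    MS = c(ms, ss_res / df_res, NA_real_),
    R2 = c(ss_terms / ss_total, ss_res / ss_total, 1),
    F = c(f_obs, NA_real_, NA_real_),
    p_perm = c(p_perm, NA_real_, NA_real_)
  )
  structure(out, class = c("shape_anova", class(out)),
            n_perm = n_perm, seed = seed)
}

qr_basis <- function(X) {
  q <- qr(X)
  qr.Q(q)[, seq_len(q$rank), drop = FALSE]
}

# response matrix with rows ordered as meta$id
response_matrix <- function(data, meta) {
  if (inherits(data, "gpa_fit")) data <- data$coords
  if (!is.data.frame(data)) abort("unsupported response object")
  if ("csize" %in% names(data) && !"landmark" %in% names(data)) {
    y <- data$csize[match(meta$id, data$id)]
    if (anyNA(y)) abort("centroid sizes missing for some metadata ids")
    return(matrix(y, ncol = 1))
  }
  arr <- shapes_to_array(data)
  ids <- dimnames(arr)[[3]]
  j <- match(meta$id, ids)
  if (anyNA(j)) abort("coordinates missing for some metadata ids")
  t(apply(arr[, , j, drop = FALSE], 3, as.numeric))
}

#' @export
print.shape_anova <- function(x, ...) {
  cat("Procrustes ANOVA (sequential SS, RRPP with", attr(x, "n_perm"),
      "permutations)\n")
  NextMethod()
}

#' Principal component analysis of aligned shapes
#'
#' Eigen-decomposition of the covariance of the flattened Procrustes
#' coordinates. At the `"sample_mean"` level the teeth of each sample are
#' averaged before the decomposition, which is the level used to ordinate
#' treated samples in shape space; the `"tooth"` level keeps every tooth
#' and feeds the variance F-test. Score signs are fixed by making each
#' component's largest-magnitude loading positive.
#'
#' @param gpa A [align_gpa()] fit (or long coordinate tibble).
#' @param meta Metadata with `id` (and `sample_id`, `treatment` when
#'   averaging or annotating).
#' @param level `"tooth"` or `"sample_mean"`.
#' @return Object of class `shape_pca`: list with `scores` (tibble),
#'   `var_prop` (percent variance per component), `loadings`, `center`,
#'   `level`.
#' @export
pca_shapes <- function(gpa, meta = NULL, level = c("tooth", "sample_mean")) {
  level <- match.arg(level)
  coords <- if (inherits(gpa, "gpa_fit")) gpa$coords else gpa
  arr <- shapes_to_array(coords)
  Y <- t(apply(arr, 3, as.numeric))
  ids <- dimnames(arr)[[3]]
  unit <- ids
  if (level == "sample_mean") {
    if (is.null(meta) || !"sample_id" %in% names(meta))
      abort("sample-mean PCA needs metadata with sample_id")
    samp <- as.character(meta$sample_id[match(ids, meta$id)])
    Y <- rowsum(Y, samp, reorder = FALSE) /
      as.vector(table(factor(samp, unique(samp))))
    unit <- rownames(Y)
  }
  if (nrow(Y) < 3) abort("PCA needs at least 3 observations")
  pc <- prcomp(Y, center = TRUE, scale. = FALSE)
  # sign convention: largest-magnitude loading positive
  for (c_i in seq_len(ncol(pc$rotation))) {
    jmax <- which.max(abs(pc$rotation[, c_i]))
    if (pc$rotation[jmax, c_i] < 0) {
      pc$rotation[, c_i] <- -pc$rotation[, c_i]
      pc$x[, c_i] <- -pc$x[, c_i]
    }
  }
  var_prop <- 100 * pc$sdev^2 / sum(pc$sdev^2)
  scores <- as_tibble(pc$x, .name_repair = "minimal")
  names(scores) <- paste0("PC", seq_len(ncol(scores)))
  id_col <- if (level == "sample_mean") "sample_id" else "id"
  scores <- dplyr::bind_cols(tibble(!!id_col := unit), scores)
  if (!is.null(meta)) {
    ann <- if (level == "sample_mean")
      distinct(meta, .data$sample_id, .data$treatment)
    else meta
    scores <- left_join(scores, ann, by = id_col)
  }
  structure(list(scores = scores, var_prop = var_prop,
                 loadings = pc$rotation, center = pc$center, level = level),
            class = "shape_pca")
}

#' @export
print.shape_pca <- function(x, ...) {
  cat("<shape_pca> level:", x$level, "\n")
  cat("  PC1", sprintf("%.1f%%", x$var_prop[1]),
      " PC2", sprintf("%.1f%%", x$var_prop[2]), "\n")
  invisible(x)
}

#' @describeIn pca_shapes Scores as a tibble.
#' @param x A `shape_pca`.
#' @param ... Unused.
#' @export
tidy.shape_pca <- function(x, ...) x$scores

#' @describeIn pca_shapes Variance proportions.
#' @export
glance.shape_pca <- function(x, ...) {
  tibble(level = x$level, pc1_var = x$var_prop[1], pc2_var = x$var_prop[2],
         n = nrow(x$scores))
}

#' @describeIn pca_shapes PC1-PC2 ordination coloured by treatment.
#' @param object A `shape_pca`.
#' @export
autoplot.shape_pca <- function(object, ...) {
  d <- object$scores
  aes <- if ("treatment" %in% names(d))
    ggplot2::aes(x = .data$PC1, y = .data$PC2, colour = .data$treatment)
  else ggplot2::aes(x = .data$PC1, y = .data$PC2)
  ggplot2::ggplot(d, aes) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", object$var_prop[1]),
      y = sprintf("PC2 (%.1f%%)", object$var_prop[2]),
      title = paste0("Shape space (", object$level, " level)")) +
    ggplot2::theme_minimal()
}

#' Centroid-size model with Tukey contrasts
#'
#' Sequential linear model of centroid size on treatment with sample nested
#' within treatment, followed by Tukey honest significant differences on the
#' treatment means and percent change of each treatment relative to the
#' control group.
#'
#' @param cs Centroid-size tibble (`id`, `csize`), e.g. from
#'   [centroid_size()] or a [align_gpa()] fit's `csize` element.
#' @param meta Metadata with `id`, `treatment`, `sample_id`.
#' @param control Control treatment level (default `"DMSO"`).
#' @return Object of class `size_stats`: list with `group_means` (mean CS,
#'   n, `pct_change` vs control), `anova` (sequential table), `tukey`
#'   (pairwise differences with adjusted p-values).
#' @export
size_model <- function(cs, meta, control = "DMSO") {
  if (inherits(cs, "gpa_fit")) cs <- cs$csize
  d <- left_join(meta, cs, by = "id")
  if (anyNA(d$csize)) abort("centroid sizes missing for some metadata ids")
  if (!control %in% d$treatment)
    abort(paste0("control group '", control, "' absent from the data"))
  d$treatment <- factor(d$treatment)
  d$treatment <- stats::relevel(d$treatment, control)
  d$sample_id <- factor(d$sample_id)
  fit <- aov(csize ~ treatment + sample_id, data = d)
  an <- as_tibble(anova(fit), rownames = "term")
  names(an) <- c("term", "df", "SS", "MS", "F", "p_value")
  tk <- TukeyHSD(fit, which = "treatment")$treatment
  tukey <- as_tibble(tk, rownames = "pair")
  names(tukey) <- c("pair", "diff", "lwr", "upr", "p_adj")
  gm <- d %>%
    group_by(.data$treatment) %>%
    summarise(mean_csize = mean(.data$csize), n = dplyr::n(), .groups = "drop")
  ctrl_mean <- gm$mean_csize[gm$treatment == control]
  gm <- mutate(gm, pct_change = 100 * (.data$mean_csize - ctrl_mean) / ctrl_mean)
  structure(list(group_means = gm, anova = an, tukey = tukey,
                 control = control), class = "size_stats")
}

#' @export
print.size_stats <- function(x, ...) {
  cat("Centroid size ~ treatment + sample (sequential SS)\n")
  print(x$group_means)
  print(x$anova)
  invisible(x)
}

#' @describeIn size_model The Tukey pairwise table.
#' @param x A `size_stats`.
#' @param ... Unused.
#' @export
tidy.size_stats <- function(x, ...) x$tukey

#' @describeIn size_model Treatment F test and percent changes in one row.
#' @export
glance.size_stats <- function(x, ...) {
  tr <- x$anova[x$anova$term == "treatment", ]
  pc <- setNames(x$group_means$pct_change, x$group_means$treatment)
  out <- tibble(F_treatment = tr$F, df_treatment = tr$df,
                p_treatment = tr$p_value)
  for (g in names(pc)) out[[paste0("pct_change_", g)]] <- pc[[g]]
  out
}

#' @describeIn size_model Centroid size by treatment.
#' @param object A `size_stats`.
#' @export
autoplot.size_stats <- function(object, ...) {
  ggplot2::ggplot(object$group_means,
                  ggplot2::aes(x = .data$treatment, y = .data$mean_csize)) +
    ggplot2::geom_col(fill = "grey70") +
    ggplot2::labs(x = NULL, y = "mean centroid size") +
    ggplot2::theme_minimal()
}

#' Pairwise variance F-test on PC scores
#'
#' Compares within-group variance of a principal component between two
#' treatments, with the group order fixed as (control, treatment) so that
#' F below 1 means inflated variance in the treated group.
#'
#' @param scores Tooth-level score tibble (from [pca_shapes()] `tidy()` or
#'   `$scores`) containing the `pc` column and `treatment` (joined from
#'   metadata if absent).
#' @param meta Optional metadata with `id`, `treatment`.
#' @param pair Character vector `(control, treatment)`.
#' @param pc Score column (default `"PC1"`).
#' @return One-row tibble with `F`, `df1`, `df2`, `p_value` (two-sided),
#'   `var_control`, `var_treatment`.
#' @export
variance_ftest <- function(scores, meta = NULL, pair = c("DMSO", "IWR"),
                           pc = "PC1") {
  if (inherits(scores, "shape_pca")) scores <- scores$scores
  if (!"treatment" %in% names(scores)) {
    if (is.null(meta)) abort("need treatment labels (supply meta)")
    scores <- left_join(scores, meta[c("id", "treatment")], by = "id")
  }
  g1 <- scores[[pc]][scores$treatment == pair[1]]
  g2 <- scores[[pc]][scores$treatment == pair[2]]
  if (length(g1) < 2 || length(g2) < 2) abort("need at least 2 teeth per group")
  v1 <- var(g1); v2 <- var(g2)
  if (v2 <= 0) abort("zero variance in denominator group")
  f <- v1 / v2
  df1 <- length(g1) - 1L; df2 <- length(g2) - 1L
  p <- 2 * min(pf(f, df1, df2), pf(f, df1, df2, lower.tail = FALSE))
  tibble(F = f, df1 = df1, df2 = df2, p_value = min(p, 1),
         var_control = v1, var_treatment = v2)
}

#' Chi-square test of two proportions
#'
#' Pearson chi-square on a 2 x 2 count table (presence/absence of a fourth
#' cusp by treatment, in the motivating design), without continuity
#' correction by default.
#'
#' @param counts 2 x 2 matrix or data frame of non-negative integer counts
#'   (rows = groups, columns = outcome present/absent).
#' @param correct Apply Yates continuity correction (default FALSE).
#' @return One-row tibble with `chi2`, `df`, `p_value`.
#' @export
chisq_proportions <- function(counts, correct = FALSE) {
  m <- as.matrix(counts)
  if (!all(m >= 0) || any(m != round(m))) abort("counts must be non-negative integers")
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    abort("zero marginal total")
  exp_counts <- outer(rowSums(m), colSums(m)) / sum(m)
  if (any(exp_counts <= 0)) abort("all expected counts must be positive")
  ht <- suppressWarnings(stats::chisq.test(m, correct = correct))
  tibble(chi2 = unname(ht$statistic), df = unname(ht$parameter),
         p_value = ht$p.value)
}
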