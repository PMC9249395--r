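#' Configuration for the synthetic landmark-data generator
#'
#' Encodes the structure of a three-arm small-molecule perturbation study:
#' a DMSO control (7 animals), a Wnt-downregulated arm (IWR, 8 animals) and
#' a Wnt-upregulated arm (CHIR, 8 animals), each contributing the three
#' most lateral teeth from both jaw sides (6 teeth per animal). Treatment
#' effects are expressed as centroid-size multipliers (default 0.641 and
#' 1.128, i.e. -35.9% and +12.8% against control), a mean-shape
#' displacement along a cusp-reduction axis, an inflated tooth-level shape
#' variance in the IWR arm (SD multiplier ~1.9, a variance ratio of ~3.6),
#' and per-treatment probabilities of a fourth cusp.
#'
#' @param n_samples Named per-treatment animal counts.
#' @param teeth_per_sample Teeth measured per animal (default 6: positions
#'   1-3 on each side).
#' @param size_mult Named per-treatment centroid-size multipliers.
#' @param shape_effect Named per-treatment displacement magnitudes along the
#'   cusp-reduction axis (positive shrinks secondary cusps).
#' @param var_inflation Named per-treatment tooth-level shape-noise SD
#'   multipliers.
#' @param sigma_sample Between-animal isotropic landmark noise SD.
#' @param sigma_tooth Within-animal (tooth-level) landmark noise SD.
#' @param size_sd_sample,size_sd_tooth Log-scale SDs of the animal- and
#'   tooth-level size factors.
#' @param fourth_cusp_prob Named per-treatment fourth-cusp probabilities.
#' @param seed Integer RNG seed.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_samples = c(DMSO = 7, IWR = 8, CHIR = 8),
                             teeth_per_sample = 6,
                             size_mult = c(DMSO = 1, IWR = 0.641, CHIR = 1.128),
                             shape_effect = c(DMSO = 0, IWR = 0.20, CHIR = -0.10),
                             var_inflation = c(DMSO = 1, IWR = 1.9, CHIR = 1),
                             sigma_sample = 0.012, sigma_tooth = 0.02,
                             size_sd_sample = 0.11, size_sd_tooth = 0.11,
                             fourth_cusp_prob = c(DMSO = 0.01, IWR = 0, CHIR = 0.12),
                             seed = 1L) {
  cfg <- list(n_samples = n_samples, teeth_per_sample = teeth_per_sample,
              size_mult = size_mult, shape_effect = shape_effect,
              var_inflation = var_inflation, sigma_sample = sigma_sample,
              sigma_tooth = sigma_tooth, size_sd_sample = size_sd_sample,
              size_sd_tooth = size_sd_tooth,
              fourth_cusp_prob = fourth_cusp_prob, seed = as.integer(seed))
  trs <- names(cfg$n_samples)
  for (nm in c("size_mult", "shape_effect", "var_inflation", "fourth_cusp_prob"))
    if (!setequal(names(cfg[[nm]]), trs))
      abort(paste0("`", nm, "` must be named for treatments ",
                   paste(trs, collapse = ", ")))
  if (any(cfg$fourth_cusp_prob < 0 | cfg$fourth_cusp_prob > 1))
    abort("fourth-cusp probabilities must lie in [0, 1]")
  if (any(cfg$size_mult <= 0) || any(cfg$var_inflation <= 0))
    abort("multipliers must be positive")
  if (any(cfg$n_samples < 1) || teeth_per_sample < 1)
    abort("counts must be at least 1")
  structure(cfg, class = "generator_config")
}

# analytic tricuspid crown profile; `secondary` scales the flanking cusps,
# `fourth` adds a small extra cusp on the posterior shoulder
tricuspid_profile <- function(x, secondary = 0.45, fourth = 0) {
  0.9 * (exp(-(x / 0.18)^2) +
         secondary * exp(-((x - 0.55) / 0.15)^2) +
         secondary * exp(-((x + 0.55) / 0.15)^2) +
         fourth * exp(-((x - 0.85) / 0.09)^2))
}

template_outline <- function(secondary = 0.45, fourth = 0, m = 161) {
  x <- seq(-1, 1, length.out = m)
  y <- tricuspid_profile(x, secondary, fourth)
  tibble(x = c(x, 1, 0, -1), y = c(y + 0.02, 0, 0, 0))
}

#' Deterministic tricuspid template configuration
#'
#' The mean shape of the generator: a bilaterally symmetric tricuspid tooth
#' (one tall primary cusp flanked by two equal secondary cusps), landmarked
#' into the 38-point scheme by [landmark_outline()].
#'
#' @param secondary Relative height of the secondary cusps (default 0.45).
#' @param fourth Relative height of an extra posterior cusp (default 0).
#' @param id Identifier for the returned configuration.
#' @return A 38-row landmark tibble.
#' @export
make_template <- function(secondary = 0.45, fourth = 0, id = "template") {
  landmark_outline(template_outline(secondary, fourth), id = id,
                   check_simple = FALSE)
}

# unit-norm displacement fields stored as k x 2 matrices
template_axes <- function() {
  t0 <- config_matrix(make_template())
  red <- config_matrix(make_template(secondary = 0.10)) - t0
  red <- red / sqrt(sum(red^2))
  fth <- config_matrix(make_template(fourth = 0.30)) - t0
  fth <- fth / sqrt(sum(fth^2))
  list(template = t0, reduction = red, fourth = fth)
}

#' Generate a synthetic landmark dataset with known truth
#'
#' Hierarchical model: each animal draws an isotropic normal shape offset
#' (`sigma_sample`) and a lognormal size factor; each tooth adds isotropic
#' landmark noise (`sigma_tooth`, SD-inflated per treatment), a treatment
#' mean-shape displacement along the cusp-reduction axis, an optional
#' fourth-cusp displacement, and a lognormal tooth-level size factor on top
#' of the treatment size multiplier. Reproducible from the seed.
#'
#' @param cfg A [generator_config()].
#' @param out_dir Optional directory; when given, writes `shapes.tps`,
#'   `metadata.csv`, `curveslide.csv` and `truth.json`.
#' @return A list of class `synthetic_dataset` with elements `data` (a
#'   [landmark_dataset()]), `truth` (configured and realized effects).
#' @export
generate_dataset <- function(cfg = generator_config(), out_dir = NULL) {
  set.seed(cfg$seed)
  axes <- template_axes()
  k <- nrow(axes$template)
  sides <- c("left", "right")
  shapes <- list(); meta <- list()
  fourth_draws <- list()
  for (tr in names(cfg$n_samples)) {
    for (s in seq_len(cfg$n_samples[[tr]])) {
      sample_id <- sprintf("%s_%02d", tr, s)
      d_sample <- matrix(rnorm(2 * k, sd = cfg$sigma_sample), k, 2)
      f_sample <- rlnorm(1, 0, cfg$size_sd_sample)
      for (tooth in seq_len(cfg$teeth_per_sample)) {
        side <- sides[(tooth - 1) %/% 3 + 1]
        pos <- (tooth - 1) %% 3 + 1
        id <- sprintf("%s_%s%d", sample_id, substr(side, 1, 1), pos)
        noise <- matrix(rnorm(2 * k, sd = cfg$sigma_tooth *
                                cfg$var_inflation[[tr]]), k, 2)
        has4 <- rbinom(1, 1, cfg$fourth_cusp_prob[[tr]]) == 1
        xy <- axes$template +
          cfg$shape_effect[[tr]] * axes$reduction +
          d_sample + noise +
          if (has4) 0.20 * axes$fourth else 0
        f_tooth <- rlnorm(1, 0, cfg$size_sd_tooth)
        xy <- xy * cfg$size_mult[[tr]] * f_sample * f_tooth
        shapes[[id]] <- tibble(id = id, landmark = seq_len(k),
                               x = xy[, 1], y = xy[, 2], scale = 1)
        meta[[id]] <- tibble(id = id, sample_id = sample_id, treatment = tr,
                             side = side, tooth_position = pos)
        fourth_draws[[id]] <- tibble(id = id, treatment = tr, fourth = has4)
      }
    }
  }
  shapes <- bind_rows(shapes); meta <- bind_rows(meta)
  fourth_draws <- bind_rows(fourth_draws)
  ds <- landmark_dataset(shapes, meta, curveslide_scheme())
  truth <- list(
    size_mult = as.list(cfg$size_mult),
    pct_change = as.list(100 * (cfg$size_mult / cfg$size_mult[["DMSO"]] - 1)),
    shape_effect = as.list(cfg$shape_effect),
    var_inflation = as.list(cfg$var_inflation),
    expected_var_ratio_dmso_iwr =
      (cfg$sigma_sample^2 + cfg$sigma_tooth^2) /
      (cfg$sigma_sample^2 + (cfg$sigma_tooth * cfg$var_inflation[["IWR"]])^2),
    fourth_cusp_counts = as.list(tapply(fourth_draws$fourth,
                                        fourth_draws$treatment, sum)),
    template_csize = centroid_size(make_template())$csize,
    seed = cfg$seed
  )
  out <- structure(list(data = ds, truth = truth, config = cfg),
                   class = "synthetic_dataset")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_tps(shapes, file.path(out_dir, "shapes.tps"))
    utils::write.csv(meta, file.path(out_dir, "metadata.csv"),
                     row.names = FALSE, quote = FALSE)
    write_curveslide(ds$curves, file.path(out_dir, "curveslide.csv"))
    jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("<synthetic_dataset> seed", x$truth$seed, "\n")
  print(x$data)
  invisible(x)
}

#' Simulate fourth-cusp count tables
#'
#' Binomial draws of fourth-cusp presence per tooth for a pair of treatment
#' arms, in the form expected by [chisq_proportions()].
#'
#' @param cfg A [generator_config()].
#' @param pair Two treatment names (default control vs Wnt-upregulated).
#' @param n_teeth Teeth scored per arm (default 200).
#' @param seed Seed (defaults to the config's).
#' @return A 2 x 2 integer matrix with rows = treatments and columns
#'   `present`/`absent`.
#' @export
generate_cusp_counts <- function(cfg = generator_config(),
                                 pair = c("DMSO", "CHIR"), n_teeth = 200,
                                 seed = cfg$seed) {
  set.seed(seed)
  pres <- vapply(pair, function(tr)
    rbinom(1, n_teeth, cfg$fourth_cusp_prob[[tr]]), numeric(1))
  m <- cbind(present = pres, absent = n_teeth - pres)
  rownames(m) <- pair
  storage.mode(m) <- "integer"
  m
}
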