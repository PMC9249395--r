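#' End-to-end geometric-morphometric analysis
#'
#' Runs the full landmark pipeline on a dataset: optional reflection of
#' right-side teeth into the left shape space, generalized Procrustes
#' superimposition with semilandmark sliding, centroid-size statistics with
#' Tukey contrasts, Procrustes ANOVA of shape with RRPP, principal
#' component analyses at the sample-mean and tooth level, and the pairwise
#' variance F-test on tooth-level PC1. All seeds and switches are recorded
#' in the result so every number is reproducible from the configuration.
#'
#' @param data A [landmark_dataset()], a [generate_dataset()] result, or a
#'   named list of paths `list(tps = , meta = , curves = )`.
#' @param reflect Reflect right-side configurations about their apex-base
#'   axis before superimposition (default TRUE).
#' @param slide_mode Semilandmark sliding objective (`"bending"` or
#'   `"procrustes"`).
#' @param n_perm RRPP permutations (default 999).
#' @param seed Seed for the permutations (default 1).
#' @param variance_pair Treatments compared by the variance F-test
#'   (control first; default `c("DMSO", "IWR")`).
#' @param out_dir Optional directory for `report.json` and tidy CSV tables.
#' @return A list of class `morpho_report` with elements `gpa`,
#'   `shape_anova`, `size_stats`, `pca_sample_mean`, `pca_tooth`,
#'   `variance_ftest`, `settings`.
#' @export
run_morphometrics <- function(data, reflect = TRUE,
                              slide_mode = c("bending", "procrustes"),
                              n_perm = 999, seed = 1L,
                              variance_pair = c("DMSO", "IWR"),
                              out_dir = NULL) {
  slide_mode <- match.arg(slide_mode)
  if (inherits(data, "synthetic_dataset")) data <- data$data
  if (is.list(data) && !inherits(data, "landmark_dataset")) {
    if (!all(c("tps", "meta") %in% names(data)))
      abort("path input needs elements `tps` and `meta`")
    shapes <- read_tps(data$tps)
    meta <- read_specimen_meta(data$meta)
    curves <- if (!is.null(data$curves)) read_curveslide(data$curves)
    data <- landmark_dataset(shapes, meta, curves)
  }
  shapes <- data$shapes; meta <- data$meta
  if (reflect) shapes <- reflect_side(shapes, meta)
  gpa <- align_gpa(shapes, curves = data$curves, slide_mode = slide_mode)
  shape_an <- procrustes_anova(gpa, meta, n_perm = n_perm, seed = seed)
  size_st <- size_model(gpa$csize, meta)
  pca_sm <- pca_shapes(gpa, meta, level = "sample_mean")
  pca_t <- pca_shapes(gpa, meta, level = "tooth")
  var_f <- variance_ftest(pca_t$scores, meta, pair = variance_pair)
  report <- structure(list(
    gpa = gpa, shape_anova = shape_an, size_stats = size_st,
    pca_sample_mean = pca_sm, pca_tooth = pca_t, variance_ftest = var_f,
    settings = list(reflect = reflect, slide_mode = slide_mode,
                    n_perm = n_perm, seed = seed,
                    variance_pair = variance_pair)
  ), class = "morpho_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.morpho_report <- function(x, ...) {
  cat("<morpho_report>\n")
  print(glance(x))
  invisible(x)
}

#' @describeIn run_morphometrics Headline statistics in one row.
#' @param x A `morpho_report`.
#' @param ... Unused.
#' @export
glance.morpho_report <- function(x, ...) {
  an <- x$shape_anova
  tibble(
    treatment_R2 = an$R2[1], treatment_F = an$F[1], treatment_p = an$p_perm[1],
    sample_R2 = an$R2[2],
    df_treatment = an$df[1], df_sample = an$df[2],
    df_residual = an$df[an$term == "Residuals"],
    csize_F = glance(x$size_stats)$F_treatment,
    pct_change_IWR = x$size_stats$group_means$pct_change[
      x$size_stats$group_means$treatment == "IWR"],
    pct_change_CHIR = x$size_stats$group_means$pct_change[
      x$size_stats$group_means$treatment == "CHIR"],
    pc1_var = x$pca_sample_mean$var_prop[1],
    pc2_var = x$pca_sample_mean$var_prop[2],
    variance_F = x$variance_ftest$F
  )
}

report_list <- function(x) {
  list(
    settings = x$settings,
    gpa = as.list(glance(x$gpa)),
    shape_anova = as.data.frame(x$shape_anova),
    size_stats = list(group_means = as.data.frame(x$size_stats$group_means),
                      anova = as.data.frame(x$size_stats$anova),
                      tukey = as.data.frame(x$size_stats$tukey)),
    pca_sample_mean = list(var_prop = x$pca_sample_mean$var_prop,
                           scores = as.data.frame(x$pca_sample_mean$scores)),
    pca_tooth = list(var_prop = x$pca_tooth$var_prop),
    variance_ftest = as.list(x$variance_ftest)
  )
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(report_list(report), file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.csv(as.data.frame(report$shape_anova),
                   file.path(out_dir, "shape_anova.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(report$size_stats$tukey),
                   file.path(out_dir, "tukey.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(report$pca_sample_mean$scores),
                   file.path(out_dir, "pca_sample_scores.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(tidy(report$gpa)),
                   file.path(out_dir, "aligned_coords.csv"), row.names = FALSE)
  invisible(out_dir)
}

#' In silico perturbation experiment
#'
#' Simulates the baseline preset, searches both Wnt-mimicking directions
#' with [mimic_treatment()], optionally runs one-at-a-time sweeps, and
#' collects a phenotype table plus the baseline outline as a TPS-ready
#' landmark configuration.
#'
#' @param params A [sim_params()] object or preset name.
#' @param sweeps Optional character vector of parameters to sweep.
#' @param step,range Sweep resolution (see [sweep_params()]).
#' @param out_dir Optional directory for `phenotypes.csv`, `baseline.tps`
#'   and `insilico.json`.
#' @return A list of class `insilico_report` with `baseline` (a
#'   [simulate_tooth()] fit), `mimicry` (both directions), `sweep` (or
#'   NULL), `outline_landmarks`.
#' @export
run_insilico <- function(params = "shark", sweeps = NULL, step = 0.1,
                         range = c(0.5, 1.5), out_dir = NULL) {
  if (is.character(params)) params <- tooth_preset(params)
  baseline <- simulate_tooth(params)
  mim <- bind_rows(mimic_treatment(params, "wnt-down", step = step),
                   mimic_treatment(params, "wnt-up", step = step))
  sw <- if (!is.null(sweeps)) sweep_params(params, sweeps, step = step,
                                           range = range)
  lmk <- landmark_outline(outline_of(baseline), id = params$label,
                          check_simple = FALSE)
  report <- structure(list(baseline = baseline, mimicry = mim, sweep = sw,
                           outline_landmarks = lmk),
                      class = "insilico_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    phen <- bind_rows(
      mutate(glance(baseline), role = "baseline", param = NA, multiple = NA),
      mutate(mim, role = "mimicry"))
    utils::write.csv(as.data.frame(phen), file.path(out_dir, "phenotypes.csv"),
                     row.names = FALSE)
    write_tps(lmk, file.path(out_dir, "baseline.tps"))
    jsonlite::write_json(
      list(baseline = as.list(glance(baseline)),
           mimicry = as.data.frame(mim),
           sweep = if (!is.null(sw)) as.data.frame(sw)),
      file.path(out_dir, "insilico.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

#' @export
print.insilico_report <- function(x, ...) {
  print(x$baseline)
  print(x$mimicry)
  invisible(x)
}
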