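#' One-at-a-time parameter sweep
#'
#' Scans each named parameter over multiples of its baseline value at a
#' fixed relative step (default 10%), holding every other parameter at the
#' baseline, and records the simulated phenotype for every grid point. Rows
#' appear in deterministic scan order; a simulation failure is recorded in
#' the row (`ok = FALSE`) rather than aborting the sweep.
#'
#' @param base A [sim_params()] baseline.
#' @param params Character vector of parameter names to sweep.
#' @param step Relative increment between multiples (default 0.10).
#' @param range Multiples spanned, `c(lower, upper)` (default 0.5-1.5).
#' @param min_prominence Cusp detection threshold passed to
#'   [simulate_tooth()].
#' @return A tibble of class `sweep_result` with columns `param`,
#'   `multiple`, `value`, `n_cusps`, `category`, `width`, `height`, `ok`,
#'   `accepted` (all TRUE initially; see [eliminate()]).
#' @export
sweep_params <- function(base, params, step = 0.1, range = c(0.5, 1.5),
                         min_prominence = 0.1) {
  if (length(params) == 0) abort("`params` must name at least one parameter")
  if (step <= 0) abort("`step` must be positive")
  multiples <- seq(range[1], range[2], by = step)
  rows <- list()
  for (pn in params) {
    v0 <- param_get(base, pn)
    for (m in multiples) {
      rows[[length(rows) + 1L]] <- sweep_row(base, pn, m, v0 * m,
                                             min_prominence)
    }
  }
  out <- bind_rows(rows)
  out$accepted <- TRUE
  structure(out, class = c("sweep_result", class(out)),
            base = base, step = step, range = range)
}

sweep_row <- function(base, pn, m, value, min_prominence, extra_cols = NULL) {
  res <- tryCatch({
    fit <- simulate_tooth(param_set(base, pn, value), min_prominence)
    ph <- fit$phenotype
    tibble(param = pn, multiple = m, value = value,
           n_cusps = ph$n_cusps, category = ph$category,
           width = ph$width, height = ph$height, ok = TRUE)
  }, error = function(e) {
    tibble(param = pn, multiple = m, value = value,
           n_cusps = NA_integer_, category = paste0("error: ", conditionMessage(e)),
           width = NA_real_, height = NA_real_, ok = FALSE)
  })
  if (!is.null(extra_cols)) res <- dplyr::bind_cols(extra_cols, res)
  res
}

#' Two-parameter factorial sweep
#'
#' Full cross of multiples of two parameters, for interaction questions such
#' as activator auto-activation against protein degradation, or initial
#' border width against activation.
#'
#' @param base A [sim_params()] baseline.
#' @param params Character vector of exactly two parameter names.
#' @param multiples1,multiples2 Multiples for the first and second parameter.
#' @inheritParams sweep_params
#' @return A `sweep_result` tibble with additional columns `param2`,
#'   `multiple2`, `value2`.
#' @export
sweep_factorial <- function(base, params, multiples1 = seq(0.9, 1.2, 0.1),
                            multiples2 = seq(1, 2, 0.25),
                            min_prominence = 0.1) {
  if (length(params) != 2) abort("factorial sweep needs exactly two parameters")
  v1 <- param_get(base, params[1]); v2 <- param_get(base, params[2])
  rows <- list()
  for (m1 in multiples1) for (m2 in multiples2) {
    b2 <- param_set(base, params[2], v2 * m2)
    rows[[length(rows) + 1L]] <- sweep_row(
      b2, params[1], m1, v1 * m1, min_prominence,
      extra_cols = tibble(param2 = params[2], multiple2 = m2, value2 = v2 * m2))
  }
  out <- bind_rows(rows)
  out$accepted <- TRUE
  structure(out, class = c("sweep_result", class(out)), base = base)
}

#' Filter a sweep by a phenotype predicate
#'
#' Formalizes the process of elimination: each call narrows the accepted
#' subset by a predicate on the grid columns; calls compose, and the grid
#' itself is never dropped (an unsatisfiable predicate leaves an empty
#' accepted set, with a message).
#'
#' @param result A [sweep_params()] result.
#' @param ... Logical filter expressions on the grid columns, e.g.
#'   `n_cusps == 3`.
#' @return The `sweep_result` with its `accepted` column narrowed.
#' @export
eliminate <- function(result, ...) {
  if (nrow(result) == 0) abort("empty sweep grid")
  keep <- Reduce(`&`, lapply(rlang::quos(...), rlang::eval_tidy,
                             data = result))
  keep[is.na(keep)] <- FALSE
  result$accepted <- result$accepted & keep
  if (!any(result$accepted))
    message("process of elimination: no grid rows remain accepted")
  result
}

#' @export
print.sweep_result <- function(x, ...) {
  cat("<sweep_result>", nrow(x), "grid rows,", sum(x$accepted), "accepted\n")
  NextMethod()
}

#' Search for the minimal perturbation mimicking a Wnt treatment
#'
#' The canonical Wnt manipulations map onto the gene network as activation
#' strength changes: downregulation corresponds to decreasing activator
#' auto-activation (`act`) or increasing inhibition (`inh`), and
#' upregulation to the opposite. Starting from a tricuspid baseline, the
#' search walks each direction at the sweep resolution until the target
#' phenotype appears: unicuspid for `"wnt-down"`, more than 3 cusps or a
#' widened tooth for `"wnt-up"`. The first multiple reaching the target is
#' minimal at that resolution.
#'
#' @param base A [sim_params()] producing a tricuspid tooth.
#' @param direction `"wnt-down"` or `"wnt-up"`.
#' @param step Relative step (default 0.10).
#' @param max_change Largest relative change explored, as a multiple
#'   distance from 1 (default 2, i.e. multiples down to 1/(1+2) ~ or up to 3).
#' @param min_prominence Cusp detection threshold.
#' @return Tibble with one row per searched parameter: `param`, `direction`,
#'   `multiple`, `value`, `n_cusps`, `category`, `achieved` (FALSE rows
#'   document a no-transition result within the range).
#' @export
mimic_treatment <- function(base, direction = c("wnt-down", "wnt-up"),
                            step = 0.1, max_change = 2,
                            min_prominence = 0.1) {
  direction <- match.arg(direction)
  base_fit <- simulate_tooth(base, min_prominence)
  if (base_fit$phenotype$category != "tricuspid")
    abort(paste0("baseline must be tricuspid, got ",
                 base_fit$phenotype$category))
  ref_width <- base_fit$phenotype$width
  down <- seq(1 - step, 1 / (1 + max_change), by = -step)
  up <- seq(1 + step, 1 + max_change, by = step)
  plan <- if (direction == "wnt-down")
    list(act = down, inh = up) else list(act = up, inh = down)
  target <- if (direction == "wnt-down") {
    function(ph) ph$category == "unicuspid"
  } else {
    function(ph) ph$n_cusps > 3 || ph$category == "widened"
  }
  rows <- lapply(names(plan), function(pn) {
    v0 <- param_get(base, pn)
    for (m in plan[[pn]]) {
      fit <- tryCatch(simulate_tooth(param_set(base, pn, v0 * m),
                                     min_prominence),
                      error = function(e) NULL)
      if (is.null(fit)) next
      ph <- classify_phenotype(fit$cusps, fit$sheet, params = fit$params,
                               ref_width = ref_width)
      if (target(ph))
        return(tibble(param = pn, direction = direction, multiple = m,
                      value = v0 * m, n_cusps = ph$n_cusps,
                      category = ph$category, achieved = TRUE))
    }
    tibble(param = pn, direction = direction, multiple = NA_real_,
           value = NA_real_, n_cusps = NA_integer_,
           category = "no-transition", achieved = FALSE)
  })
  bind_rows(rows)
}
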