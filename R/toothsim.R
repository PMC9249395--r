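#' Create an epithelial sheet in its initial state
#'
#' The modelled epithelium is a one-dimensional anterior-posterior strip of
#' cells carrying activator and inhibitor concentrations and an accumulated
#' height (the occlusal profile). The active tooth site starts `bwi` cells
#' wide and its borders advance every iteration. The initial condition is a
#' small activator peak at the central cell; if the `noise` constant is
#' positive, seeded Gaussian noise of that amplitude is added on top of the
#' basal level across the initial site.
#'
#' @param p A [sim_params()] object.
#' @return An object of class `epithelial_sheet`.
#' @export
new_sheet <- function(p) {
  validate_sim_params(p)
  ex <- p$gene$extra
  n0 <- max(32L, as.integer(ceiling(p$tissue$bwi)) + 16L)
  cen <- (n0 + 1) / 2
  sheet <- structure(list(
    n = n0,
    a = numeric(n0), i = numeric(n0),
    height = numeric(n0),
    knot = logical(n0),
    le = cen - p$tissue$bwi / 2, re = cen + p$tissue$bwi / 2,
    origin = 0,          # grid-unit offset accumulated by reallocation
    iter = 0L
  ), class = "epithelial_sheet")
  lo <- active_lo(sheet); hi <- active_hi(sheet)
  sheet$a[round(cen)] <- ex$a0
  if (ex$noise > 0) {
    set.seed(p$seed)
    bg <- if (p$gene$deg > 0) ex$ba / p$gene$deg else 0
    sheet$a[lo:hi] <- pmax(0, bg + ex$noise * rnorm(hi - lo + 1))
  }
  sheet
}

active_lo <- function(sheet) max(1L, as.integer(ceiling(sheet$le)))
active_hi <- function(sheet) min(sheet$n, as.integer(floor(sheet$re)))

# pad the strip when the active borders approach the allocated ends
grow_alloc <- function(sheet, pad = 64L) {
  z <- numeric(pad); f <- logical(pad)
  sheet$a <- c(z, sheet$a, z); sheet$i <- c(z, sheet$i, z)
  sheet$height <- c(z, sheet$height, z); sheet$knot <- c(f, sheet$knot, f)
  sheet$n <- sheet$n + 2L * pad
  sheet$le <- sheet$le + pad; sheet$re <- sheet$re + pad
  sheet$origin <- sheet$origin - pad
  sheet
}

#' Advance the epithelial sheet by one iteration
#'
#' Applies one synchronous update: (1) reaction - the activator grows by
#' saturating auto-activation scaled by `act`, is suppressed by the inhibitor
#' scaled by `inh`, and both species decay with `deg` (the inhibitor turnover
#' is `idr` times faster); the inhibitor is produced from the activator at
#' rate `aip`; (2) diffusion with coefficients `da` and `di` under zero-flux
#' boundaries at the active borders; (3) cells whose activator exceeds the
#' differentiation threshold join the knot (irreversibly); (4) non-knot cells
#' grow in height by `pro` times their activator level (knot cells are
#' non-proliferative and frozen); (5) the active border widens at rate
#' `bgr * min(1, sec * mean(a))`, split between the anterior and posterior
#' side according to the bias `bia`. Concentrations are clamped at zero.
#'
#' @param sheet An `epithelial_sheet`.
#' @param p A [sim_params()] object.
#' @return The updated sheet.
#' @export
step_sheet <- function(sheet, p) {
  g <- p$gene; tis <- p$tissue; ex <- g$extra
  lo <- active_lo(sheet); hi <- active_hi(sheet)
  av <- sheet$a[lo:hi]; iv <- sheet$i[lo:hi]
  if (!all(is.finite(av)) || !all(is.finite(iv)))
    abort(paste0("numerical instability at iteration ", sheet$iter))
  m <- length(av)
  # zero-flux discrete laplacians
  lap_a <- c(av[-1], av[m]) + c(av[1], av[-m]) - 2 * av
  lap_i <- c(iv[-1], iv[m]) + c(iv[1], iv[-m]) - 2 * iv
  react <- ex$ba + g$act * av^2 / ((1 + g$inh * iv) * (1 + ex$sat * av^2))
  a_new <- pmax(av + react - g$deg * av + g$da * lap_a, 0)
  i_new <- pmax(iv + ex$aip * av^2 - ex$idr * g$deg * iv + g$di * lap_i, 0)
  if (!all(is.finite(a_new)) || !all(is.finite(i_new)))
    abort(paste0("numerical instability at iteration ", sheet$iter + 1L))
  idx <- lo:hi
  sheet$a[idx] <- a_new; sheet$i[idx] <- i_new
  # knot differentiation is irreversible
  sheet$knot[idx] <- sheet$knot[idx] | (a_new > ex$knot_thr)
  grow_cells <- idx[!sheet$knot[idx]]
  sheet$height[grow_cells] <- sheet$height[grow_cells] +
    tis$pro * sheet$a[grow_cells]
  # border growth, modulated by growth-signal secretion, skewed by bias
  rate <- tis$bgr * min(1, g$sec * mean(a_new))
  sheet$le <- sheet$le - rate / (1 + tis$bia)
  sheet$re <- sheet$re + rate * tis$bia / (1 + tis$bia)
  sheet$iter <- sheet$iter + 1L
  if (sheet$le < 3 || sheet$re > sheet$n - 2) sheet <- grow_alloc(sheet)
  sheet
}

#' Run a full tooth morphogenesis simulation
#'
#' Runs [step_sheet()] for `n_iter` iterations from the seeded initial
#' condition, then detects cusps on the resulting height profile and
#' classifies the phenotype. Fully deterministic for fixed parameters
#' (including the seed when initial noise is enabled).
#'
#' @param p A [sim_params()] object.
#' @param min_prominence Cusp detection threshold, as a fraction of the
#'   maximum height (default 0.10).
#' @return An object of class `tooth_sim`: a list with elements `sheet`,
#'   `cusps` (a [detect_cusps()] tibble), `phenotype` (a
#'   [classify_phenotype()] row) and `params`.
#' @export
#' @examples
#' \donttest{
#' fit <- simulate_tooth(tooth_preset("shark"))
#' glance(fit)
#' }
simulate_tooth <- function(p, min_prominence = 0.1) {
  sheet <- new_sheet(p)
  for (t in seq_len(p$n_iter)) sheet <- step_sheet(sheet, p)
  cusps <- detect_cusps(sheet, min_prominence)
  phen <- classify_phenotype(cusps, sheet, params = p)
  structure(list(sheet = sheet, cusps = cusps, phenotype = phen, params = p),
            class = "tooth_sim")
}

#' Detect cusps on a height profile
#'
#' Finds local maxima of the height field along the anterior-posterior axis
#' whose topographic prominence is at least `min_prominence` times the
#' maximum height. Prominence of a peak is its height minus the highest of
#' the two key saddles: on each side, descend until terrain higher than the
#' peak is met (or the profile ends) and record the lowest point passed; the
#' peak's drop is taken as the smaller of the two side drops. Plateaus count
#' once, at their first cell (first-encountered tie-break).
#'
#' @param sheet An `epithelial_sheet`, a `tooth_sim`, or a bare numeric
#'   height profile.
#' @param min_prominence Fraction of the maximum height (strictly between 0
#'   and 1).
#' @return A tibble of class `cusp_set` with columns `position` (grid units,
#'   along the active domain), `height` and `prominence`, ordered by
#'   position, with attributes `n` (cusp count) and `primary_index` (row of
#'   the tallest cusp, first encountered on ties).
#' @export
detect_cusps <- function(sheet, min_prominence = 0.1) {
  if (min_prominence <= 0 || min_prominence >= 1)
    abort("`min_prominence` must be strictly between 0 and 1")
  if (inherits(sheet, "tooth_sim")) sheet <- sheet$sheet
  if (inherits(sheet, "epithelial_sheet")) {
    lo <- active_lo(sheet); hi <- active_hi(sheet)
    h <- sheet$height[lo:hi]
    pos <- (lo:hi) + sheet$origin
  } else {
    h <- as.numeric(sheet)
    pos <- seq_along(h)
  }
  if (any(h < 0)) abort("height profile must be non-negative")
  res <- tibble(position = numeric(0), height = numeric(0),
                prominence = numeric(0))
  hmax <- if (length(h)) max(h) else 0
  if (length(h) >= 2 && hmax > 0 && any(h != h[1])) {
    m <- length(h)
    left  <- c(-Inf, h[-m]); right <- c(h[-1], -Inf)
    cand <- which(h > left & h >= right)
    prom <- vapply(cand, function(j) peak_prominence(h, j), numeric(1))
    keep <- prom >= min_prominence * hmax
    res <- tibble(position = pos[cand[keep]], height = h[cand[keep]],
                  prominence = prom[keep])
  }
  structure(res, class = c("cusp_set", class(res)),
            n = nrow(res),
            primary_index = if (nrow(res)) which.max(res$height) else NA_integer_)
}

# topographic prominence of the local maximum at index j
peak_prominence <- function(h, j) {
  side_drop <- function(dir) {
    low <- h[j]; k <- j + dir
    while (k >= 1 && k <= length(h)) {
      if (h[k] > h[j]) return(h[j] - low)
      low <- min(low, h[k])
      k <- k + dir
    }
    h[j] - low
  }
  min(side_drop(-1L), side_drop(1L))
}

#' Number of cusps in a cusp set
#' @param x A `cusp_set`.
#' @return Integer cusp count.
#' @export
n_cusps <- function(x) attr(x, "n")

#' Classify the simulated tooth phenotype
#'
#' Maps a cusp count and width/height summaries onto a phenotype category:
#' `no-tooth` (no cusps, or a crown no taller than twice the basal
#' patternless expectation), `unicuspid`, `tricuspid`, `serrated-like`
#' (five or more cusps whose largest secondary prominence is below 25% of
#' the primary's), `widened` (when a reference width is supplied and the
#' basal width is at least 1.25 times it, for cusp counts other than 0, 1
#' and 3), otherwise `multicuspid` with the count recorded.
#'
#' @param cusps A [detect_cusps()] result.
#' @param sheet The `epithelial_sheet` the cusps came from.
#' @param params The [sim_params()] used (for the basal-height floor);
#'   optional.
#' @param ref_width Optional reference basal width (grid units) against
#'   which `widened` is judged.
#' @return A one-row tibble of class `phenotype_label` with columns
#'   `category`, `n_cusps`, `width`, `height`.
#' @export
classify_phenotype <- function(cusps, sheet, params = NULL, ref_width = NULL) {
  width <- active_hi(sheet) - active_lo(sheet) + 1
  hmax <- max(sheet$height)
  n <- n_cusps(cusps)
  basal <- 0
  if (!is.null(params)) {
    ex <- params$gene$extra
    if (params$gene$deg > 0)
      basal <- 2 * (ex$ba / params$gene$deg) * params$tissue$pro * sheet$iter
  }
  category <- if (n == 0 || hmax <= basal) {
    "no-tooth"
  } else if (n == 1) {
    "unicuspid"
  } else if (n == 3) {
    "tricuspid"
  } else if (n >= 5 &&
             max(cusps$prominence[-attr(cusps, "primary_index")]) <
               0.25 * cusps$prominence[attr(cusps, "primary_index")]) {
    "serrated-like"
  } else if (!is.null(ref_width) && width >= 1.25 * ref_width) {
    "widened"
  } else {
    "multicuspid"
  }
  out <- tibble(category = category,
                n_cusps = if (category == "no-tooth") 0L else n,
                width = width, height = hmax)
  class(out) <- c("phenotype_label", class(out))
  out
}

#' Extract the occlusal outline of a simulated tooth
#'
#' Builds a closed two-dimensional outline from the height profile, apex up:
#' the crown curve runs anterior to posterior over the active domain, and
#' the base closes the polygon through a basal midpoint, so that landmarking
#' can anchor one fixed point at the primary cusp tip and one at the tooth
#' base. Points carry a cumulative arc-length coordinate `s`.
#'
#' @param sheet An `epithelial_sheet` or `tooth_sim`.
#' @return A tibble with columns `x`, `y`, `s` tracing the closed outline
#'   counter-clockwise starting at the anterior basal corner; the first
#'   point is not repeated at the end.
#' @export
outline_of <- function(sheet) {
  if (inherits(sheet, "tooth_sim")) sheet <- sheet$sheet
  cusps <- detect_cusps(sheet)
  if (n_cusps(cusps) == 0)
    abort("no-tooth phenotype: cannot extract an outline without cusps")
  lo <- active_lo(sheet); hi <- active_hi(sheet)
  x <- (lo:hi) + sheet$origin
  y <- sheet$height[lo:hi]
  # crown: anterior -> posterior; base: posterior corner -> base midpoint ->
  # anterior corner (polygon closes implicitly)
  xs <- c(x, x[length(x)], mean(range(x)), x[1])
  ys <- c(y, 0, 0, 0)
  keep <- !duplicated(cbind(xs, ys))
  xs <- xs[keep]; ys <- ys[keep]
  seg <- sqrt(diff(xs)^2 + diff(ys)^2)
  tibble(x = xs, y = ys, s = c(0, cumsum(seg)))
}

#' @export
print.tooth_sim <- function(x, ...) {
  ph <- x$phenotype
  cat("<tooth_sim>", x$params$label, "-", ph$category,
      sprintf("(%d cusps, width %g, height %.2f) after %d iterations\n",
              ph$n_cusps, ph$width, ph$height, x$sheet$iter))
  invisible(x)
}

#' @describeIn simulate_tooth Per-cell state of the final sheet as a tibble.
#' @param x A `tooth_sim` object.
#' @param ... Unused.
#' @export
tidy.tooth_sim <- function(x, ...) {
  sheet <- x$sheet
  lo <- active_lo(sheet); hi <- active_hi(sheet)
  tibble(cell = (lo:hi) + sheet$origin,
         activator = sheet$a[lo:hi],
         inhibitor = sheet$i[lo:hi],
         height = sheet$height[lo:hi],
         knot = sheet$knot[lo:hi])
}

#' @describeIn simulate_tooth One-row phenotype summary.
#' @export
glance.tooth_sim <- function(x, ...) {
  dplyr::bind_cols(tibble(label = x$params$label), x$phenotype,
                   tibble(n_iter = x$sheet$iter))
}

#' @describeIn simulate_tooth Height profile with detected cusps marked.
#' @param object A `tooth_sim` object.
#' @export
autoplot.tooth_sim <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$cell, y = .data$height)) +
    ggplot2::geom_area(fill = "grey85") +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = as_tibble(object$cusps),
                        ggplot2::aes(x = .data$position, y = .data$height),
                        colour = "firebrick", size = 2) +
    ggplot2::labs(x = "anterior-posterior position (grid cells)",
                  y = "height",
                  title = paste0(object$params$label, ": ",
                                 object$phenotype$category)) +
    ggplot2::theme_minimal()
}
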