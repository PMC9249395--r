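#' Simulation parameters for the tooth morphogenesis model
#'
#' Bundles the gene-network and tissue-level parameters that drive one
#' simulation of tooth cusp patterning. The gene network is a saturating
#' activator-inhibitor (Gierer-Meinhardt-type) system; the tissue block
#' controls the growing epithelial strip on which it runs.
#'
#' Gene-network parameters:
#' * `act` - activator auto-activation rate (per iteration).
#' * `inh` - inhibition strength of the activator by the inhibitor.
#' * `deg` - protein degradation rate shared by both species (per iteration).
#' * `da`, `di` - activator and inhibitor diffusion coefficients
#'   (grid units^2 / iteration). Explicit-Euler stability requires both
#'   at or below 0.5; values above 0.45 trigger a warning because the
#'   inhibitor decay term pushes the true bound slightly under 0.5.
#' * `sec` - growth-signal secretion: couples the border growth rate to the
#'   mean activator level, so strongly activated teeth widen faster.
#'
#' Tissue parameters:
#' * `bwi` - initial border width of the tooth site (grid cells, minimum 3).
#' * `bgr` - baseline border growth rate (grid cells / iteration).
#' * `bia` - anterior-posterior bias of border growth (1 = symmetric).
#' * `pro` - proliferation rate scaling for non-knot cells
#'   (height units / iteration per unit activator).
#'
#' Additional network constants (`sat` activator saturation, `ba` basal
#' activator production, `aip` inhibitor production rate, `idr` inhibitor
#' turnover ratio, `a0` seed amplitude, `noise` seeded initial noise
#' amplitude) and any unknown keys are routed to the `extra` maps.
#'
#' @param act,inh,deg,da,di,sec Gene-network rates, see Details.
#' @param bwi,bgr,bia,pro Tissue parameters, see Details.
#' @param n_iter Number of iterations to run (default 11000).
#' @param seed Integer RNG seed; only used when the seeded initial noise
#'   amplitude (`noise`) is positive.
#' @param label Free-text preset name.
#' @param ... Additional named constants routed to the extra maps.
#' @return An object of class `sim_params`: a list with elements `gene`,
#'   `tissue`, `n_iter`, `seed`, `label`.
#' @seealso [tooth_preset()], [read_params()], [simulate_tooth()]
#' @export
#' @examples
#' p <- sim_params(act = 0.25, inh = 52)
#' p$gene$act
sim_params <- function(act = 0.25, inh = 52, deg = 0.005, da = 0.01, di = 0.45,
                       sec = 1.1, bwi = 10, bgr = 0.01, bia = 1, pro = 0.001,
                       n_iter = 11000, seed = 1L, label = "custom", ...) {
  extra <- list(...)
  defaults <- list(sat = 0.05, ba = 5e-4, aip = 0.02, idr = 3, a0 = 0.05,
                   noise = 0, knot_thr = 3)
  gene_extra <- modifyList(defaults, extra)
  p <- structure(list(
    gene = list(act = act, inh = inh, deg = deg, da = da, di = di, sec = sec,
                extra = gene_extra),
    tissue = list(bwi = bwi, bgr = bgr, bia = bia, pro = pro, extra = list()),
    n_iter = as.integer(n_iter), seed = as.integer(seed), label = label
  ), class = "sim_params")
  validate_sim_params(p)
  p
}

validate_sim_params <- function(p) {
  g <- p$gene; tis <- p$tissue
  if (!all(is.finite(c(g$act, g$inh, g$deg, g$da, g$di, g$sec))))
    abort("gene-network parameters must be finite")
  if (any(c(g$act, g$inh, g$deg, g$da, g$sec) < 0))
    abort("gene-network rates must be non-negative")
  if (g$di <= 0) abort("inhibitor diffusion `di` must be positive")
  if (g$da > 0.5 || g$di > 0.5)
    abort("diffusion coefficients must not exceed 0.5 (explicit-Euler stability)")
  if (g$di > 0.45 || g$da > 0.45)
    warn("diffusion above 0.45 can be marginally unstable once decay is included")
  if (tis$bwi < 3) abort("initial border width `bwi` must be at least 3 grid cells")
  if (tis$bgr < 0) abort("border growth rate `bgr` must be non-negative")
  if (tis$bia <= 0) abort("anterior-posterior bias `bia` must be positive")
  if (p$n_iter < 1) abort("`n_iter` must be at least 1")
  invisible(p)
}

#' Built-in simulation presets
#'
#' `"shark"` is calibrated to produce the characteristic embryonic tricuspid
#' tooth after 11,000 iterations; lowering its activator auto-activation or
#' raising inhibition gives unicuspid teeth, while the opposite perturbations
#' add cusps and widen the tooth. `"seal"` is the low-activation baseline:
#' unicuspid at default, shifting to tricuspid and quadricuspid as `act`
#' increases.
#'
#' @param name `"shark"` or `"seal"`.
#' @return A [sim_params()] object.
#' @export
#' @examples
#' tooth_preset("shark")$gene$act
tooth_preset <- function(name = c("shark", "seal")) {
  name <- match.arg(name)
  switch(name,
    shark = sim_params(label = "shark"),
    seal  = sim_params(act = 0.10, label = "seal")
  )
}

#' @export
print.sim_params <- function(x, ...) {
  cat("<sim_params>", x$label, "\n")
  g <- x$gene; tis <- x$tissue
  cat(sprintf("  gene:   act=%g inh=%g deg=%g da=%g di=%g sec=%g\n",
              g$act, g$inh, g$deg, g$da, g$di, g$sec))
  cat(sprintf("  tissue: bwi=%g bgr=%g bia=%g pro=%g\n",
              tis$bwi, tis$bgr, tis$bia, tis$pro))
  cat(sprintf("  n_iter=%d seed=%d extra: %s\n", x$n_iter, x$seed,
              paste(names(g$extra), unlist(g$extra), sep = "=", collapse = " ")))
  invisible(x)
}

gene_names   <- c("act", "inh", "deg", "da", "di", "sec")
tissue_names <- c("bwi", "bgr", "bia", "pro")

#' Get or set a named simulation parameter
#'
#' Resolves a parameter name in the gene block, tissue block, top level
#' (`n_iter`, `seed`) or the extra maps, in that order.
#'
#' @param p A [sim_params()] object.
#' @param name Parameter name, e.g. `"act"` or `"bwi"`.
#' @param value Replacement value (for `param_set`).
#' @return `param_get` returns the numeric value; `param_set` returns a new
#'   validated `sim_params` object.
#' @export
param_get <- function(p, name) {
  if (name %in% gene_names) return(p$gene[[name]])
  if (name %in% tissue_names) return(p$tissue[[name]])
  if (name %in% c("n_iter", "seed")) return(p[[name]])
  if (name %in% names(p$gene$extra)) return(p$gene$extra[[name]])
  if (name %in% names(p$tissue$extra)) return(p$tissue$extra[[name]])
  abort(paste0("unknown parameter: ", name))
}

#' @rdname param_get
#' @export
param_set <- function(p, name, value) {
  if (name %in% gene_names) p$gene[[name]] <- value
  else if (name %in% tissue_names) p$tissue[[name]] <- value
  else if (name %in% c("n_iter", "seed")) p[[name]] <- as.integer(value)
  else p$gene$extra[[name]] <- value
  validate_sim_params(p)
  p
}

#' Read and write simulation parameter files
#'
#' Flat `key=value` text, one parameter per line, `#` starts a comment.
#' Unknown keys are routed to the extra map.
#'
#' @param path File path.
#' @param base Parameter set supplying defaults for keys absent from the file.
#' @return `read_params` returns a [sim_params()] object.
#' @export
read_params <- function(path, base = sim_params()) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  p <- base
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2)
      abort(paste0("malformed parameter line: '", ln, "'"))
    key <- trimws(kv[1]); val <- suppressWarnings(as.numeric(trimws(kv[2])))
    if (key == "label") { p$label <- trimws(kv[2]); next }
    if (is.na(val)) abort(paste0("non-numeric value for '", key, "'"))
    p <- param_set(p, key, val)
  }
  p
}

#' @rdname read_params
#' @param p A [sim_params()] object to write.
#' @export
write_params <- function(p, path) {
  g <- p$gene; tis <- p$tissue
  kv <- c(setNames(unlist(g[gene_names]), gene_names),
          setNames(unlist(tis[tissue_names]), tissue_names),
          n_iter = p$n_iter, seed = p$seed,
          unlist(g$extra))
  lines <- c(paste0("# preset: ", p$label),
             paste0("label=", p$label),
             sprintf("%s=%.17g", names(kv), kv))
  writeLines(lines, path)
  invisible(path)
}
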