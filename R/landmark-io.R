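#' Read landmark configurations from a TPS file
#'
#' Parses the tpsUtil/tpsDig dialect: records begin with `LM=<n>`, followed
#' by `n` whitespace-separated coordinate lines and optional `IMAGE=`, `ID=`
#' and `SCALE=` keys. Coordinates are stored in the file in image convention
#' (y growing downwards) and are converted to mathematical convention (y up)
#' on load; the scale factor, when present, is applied multiplicatively.
#' A record without `SCALE=` gets scale 1 with a warning.
#'
#' @param path Path to a TPS file.
#' @return A tibble with columns `id`, `landmark` (1-based), `x`, `y`,
#'   `scale`; empty (zero rows) for an empty file.
#' @seealso [write_tps()], [read_curveslide()]
#' @export
read_tps <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  out <- list(); rec <- 0L; i <- 1L
  while (i <= length(lines)) {
    if (!grepl("^LM\\s*=", lines[i], ignore.case = TRUE))
      abort(paste0("expected LM= at line ", i, " of ", path))
    rec <- rec + 1L
    k <- suppressWarnings(as.integer(sub("^LM\\s*=\\s*", "", lines[i],
                                         ignore.case = TRUE)))
    if (is.na(k)) abort(paste0("record ", rec, ": malformed LM= count"))
    if (i + k > length(lines))
      abort(paste0("record ", rec, ": fewer coordinate lines than LM=", k))
    coord_lines <- lines[(i + 1):(i + k)]
    if (k > 0 && any(grepl("^(LM|IMAGE|ID|SCALE)\\s*=", coord_lines,
                           ignore.case = TRUE)))
      abort(paste0("record ", rec, ": LM= count does not match coordinate lines"))
    xy <- lapply(coord_lines, function(ln) {
      v <- suppressWarnings(as.numeric(strsplit(ln, "\\s+")[[1]]))
      if (length(v) != 2 || any(is.na(v)))
        abort(paste0("record ", rec, ": non-numeric coordinate line '", ln, "'"))
      v
    })
    i <- i + k + 1L
    id <- NULL; scale <- NA_real_
    while (i <= length(lines) &&
           grepl("^(IMAGE|ID|SCALE)\\s*=", lines[i], ignore.case = TRUE)) {
      key <- toupper(sub("\\s*=.*$", "", lines[i]))
      val <- sub("^[^=]*=\\s*", "", lines[i])
      if (key == "ID") id <- val
      if (key == "IMAGE" && is.null(id)) id <- sub("\\.[^.]*$", "", basename(val))
      if (key == "SCALE") scale <- suppressWarnings(as.numeric(val))
      i <- i + 1L
    }
    if (is.na(scale)) {
      warn(paste0("record ", rec, ": no SCALE=, assuming 1"))
      scale <- 1
    }
    if (is.null(id)) id <- paste0("specimen_", rec)
    m <- do.call(rbind, xy)
    out[[rec]] <- tibble(id = id, landmark = seq_len(k),
                         x = m[, 1] * scale, y = -m[, 2] * scale,
                         scale = scale)
  }
  if (!length(out))
    return(tibble(id = character(0), landmark = integer(0),
                  x = numeric(0), y = numeric(0), scale = numeric(0)))
  bind_rows(out)
}

#' Write landmark configurations to a TPS file
#'
#' Emits the dialect [read_tps()] accepts; reading the file back restores
#' coordinates and scales exactly (the y axis is converted back to image
#' convention and the scale divided out on write).
#'
#' @param shapes Tibble with columns `id`, `landmark`, `x`, `y` and
#'   optionally `scale` (default 1).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tps <- function(shapes, path) {
  stopifnot(all(c("id", "landmark", "x", "y") %in% names(shapes)))
  if (!"scale" %in% names(shapes)) shapes$scale <- 1
  ks <- tapply(shapes$landmark, shapes$id, length)
  if (any(ks < 2)) abort("degenerate configuration: fewer than 2 landmarks")
  if (length(unique(ks)) > 1)
    abort("all configurations must share one landmark count")
  con <- file(path, "w"); on.exit(close(con))
  for (one_id in unique(shapes$id)) {
    d <- shapes[shapes$id == one_id, ]
    d <- d[order(d$landmark), ]
    sc <- d$scale[1]
    writeLines(paste0("LM=", nrow(d)), con)
    writeLines(sprintf("%.17g %.17g", d$x / sc, -d$y / sc), con)
    writeLines(paste0("ID=", one_id), con)
    writeLines(sprintf("SCALE=%.17g", sc), con)
  }
  invisible(path)
}

#' Read a curve-slide definition table
#'
#' A curve-slide table names, for every sliding semilandmark, the two
#' neighbours (`before`, `after`) that define the tangent of its curve.
#' Indices are 1-based landmark numbers, as in the files produced by
#' tpsUtil.
#'
#' @param path CSV file with header `before,slide,after`.
#' @param k Total number of landmarks the indices must fit in (optional).
#' @return A validated tibble of class `curveslide` with integer columns
#'   `before`, `slide`, `after`; zero rows mean a pure fixed-landmark
#'   analysis.
#' @export
read_curveslide <- function(path, k = NULL) {
  d <- utils::read.csv(path)
  names(d) <- tolower(names(d))
  if (!all(c("before", "slide", "after") %in% names(d)))
    abort("curveslide file needs columns before, slide, after")
  validate_curveslide(as_tibble(d[c("before", "slide", "after")]), k = k)
}

#' @rdname read_curveslide
#' @param curves A curveslide tibble to validate or write.
#' @export
validate_curveslide <- function(curves, k = NULL) {
  curves <- dplyr::mutate(curves, across(all_of(c("before", "slide", "after")),
                                         as.integer))
  if (anyDuplicated(curves$slide))
    abort("each slide index may appear only once")
  if (any(curves$before == curves$slide) || any(curves$after == curves$slide) ||
      any(curves$before == curves$after))
    abort("before, slide and after must be three distinct landmarks")
  if (!is.null(k)) {
    idx <- c(curves$before, curves$slide, curves$after)
    if (any(idx < 1 | idx > k))
      abort(paste0("landmark index out of range 1..", k))
  }
  # every before/after chain must terminate at a non-sliding landmark
  nxt <- function(col) setNames(curves[[col]], curves$slide)
  for (col in c("before", "after")) {
    step_to <- nxt(col)
    for (s0 in curves$slide) {
      seen <- integer(0); s <- s0
      while (s %in% curves$slide) {
        if (s %in% seen) abort("cyclic curve definition (no fixed anchor)")
        seen <- c(seen, s)
        s <- step_to[[as.character(s)]]
      }
    }
  }
  structure(curves, class = c("curveslide", class(curves)))
}

#' @rdname read_curveslide
#' @export
write_curveslide <- function(curves, path) {
  utils::write.csv(as.data.frame(curves)[c("before", "slide", "after")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' The packaged 38-landmark tooth scheme
#'
#' Two fixed landmarks (1 = primary cusp tip, 20 = tooth base) and 18
#' sliding semilandmarks on either side of the tooth: landmarks 2-19 run
#' from apex to base along one side, 21-38 from base back to apex along the
#' other. `curveslide_scheme()` returns the matching 36-row curve-slide
#' table.
#'
#' @param n_semi Semilandmarks per side (default 18).
#' @return A `curveslide` tibble with `2 * n_semi` rows.
#' @export
curveslide_scheme <- function(n_semi = 18) {
  k <- 2 * n_semi + 2
  base_idx <- n_semi + 2          # 20 in the default scheme
  side_a <- tibble(before = 1:n_semi, slide = 2:(n_semi + 1),
                   after = 3:(n_semi + 2))
  side_b <- tibble(before = base_idx:(k - 1), slide = (base_idx + 1):k,
                   after = c((base_idx + 2):k, 1))
  validate_curveslide(bind_rows(side_a, side_b), k = k)
}

#' Read specimen metadata
#'
#' @param path CSV with columns `id`, `sample_id`, `treatment`
#'   (DMSO/IWR/CHIR), `side` (left/right), `tooth_position` (1-3,
#'   lateral-most = 1).
#' @return A validated tibble.
#' @export
read_specimen_meta <- function(path) {
  d <- as_tibble(utils::read.csv(path))
  validate_specimen_meta(d)
}

validate_specimen_meta <- function(meta) {
  need <- c("id", "sample_id", "treatment", "side", "tooth_position")
  if (!all(need %in% names(meta)))
    abort(paste0("metadata needs columns ", paste(need, collapse = ", ")))
  if (!all(meta$treatment %in% c("DMSO", "IWR", "CHIR")))
    abort("treatment must be one of DMSO, IWR, CHIR")
  if (!all(meta$side %in% c("left", "right")))
    abort("side must be left or right")
  if (!all(meta$tooth_position %in% 1:3))
    abort("tooth_position must be 1, 2 or 3")
  meta
}

#' Place the 38-landmark scheme on a tooth outline
#'
#' Anchors fixed landmark 1 at the apex (primary cusp tip) and fixed
#' landmark 20 at the tooth base, then distributes 18 sliding semilandmarks
#' at equal arc-length spacing along each of the two outline arcs between
#' them (so each side is divided into 19 equal arcs).
#'
#' @param outline Tibble or data frame with ordered columns `x`, `y` tracing
#'   a closed, non-self-intersecting polygon (first point not repeated).
#' @param apex,base Points on the outline (length-2 numeric or 1-row data
#'   frames); defaults are the highest vertex and the basal midpoint (lowest
#'   vertex closest to the apex's x). Supplied points are snapped to the
#'   nearest outline vertex.
#' @param n_semi Semilandmarks per side (default 18).
#' @param id Identifier carried into the result.
#' @param check_simple Check for outline self-intersection (default TRUE).
#' @return Tibble with columns `id`, `landmark`, `x`, `y`, `scale` following
#'   the scheme of [curveslide_scheme()].
#' @export
landmark_outline <- function(outline, apex = NULL, base = NULL, n_semi = 18,
                             id = "tooth", check_simple = TRUE) {
  pts <- cbind(outline$x, outline$y)
  n <- nrow(pts)
  if (n < 4) abort("outline needs at least 4 points")
  if (check_simple && outline_self_intersects(pts))
    abort("outline is self-intersecting")
  snap <- function(p) which.min((pts[, 1] - p[1])^2 + (pts[, 2] - p[2])^2)
  i_apex <- if (is.null(apex)) which.max(pts[, 2]) else snap(as.numeric(apex))
  i_base <- if (is.null(base)) {
    low <- which(pts[, 2] <= min(pts[, 2]) + 1e-12)
    low[which.min(abs(pts[low, 1] - pts[i_apex, 1]))]
  } else snap(as.numeric(base))
  if (i_apex == i_base) abort("apex and base coincide")
  # the two arcs of the closed polygon between apex and base
  idx_fwd <- if (i_apex < i_base) i_apex:i_base else c(i_apex:n, 1:i_base)
  idx_bwd <- if (i_base < i_apex) i_base:i_apex else c(i_base:n, 1:i_apex)
  side_a <- resample_arc(pts[idx_fwd, , drop = FALSE], n_semi)  # apex -> base
  side_b <- resample_arc(pts[idx_bwd, , drop = FALSE], n_semi)  # base -> apex
  coords <- rbind(pts[i_apex, ], side_a, pts[i_base, ], side_b)
  tibble(id = id, landmark = seq_len(2 * n_semi + 2),
         x = coords[, 1], y = coords[, 2], scale = 1)
}

# n points at equal arc-length spacing strictly inside a polyline
resample_arc <- function(arc, n) {
  seg <- sqrt(diff(arc[, 1])^2 + diff(arc[, 2])^2)
  s <- c(0, cumsum(seg))
  L <- s[length(s)]
  if (L <= 0) abort("degenerate (zero-length) outline arc")
  target <- L * seq_len(n) / (n + 1)
  xi <- stats::approx(s, arc[, 1], xout = target)$y
  yi <- stats::approx(s, arc[, 2], xout = target)$y
  cbind(xi, yi)
}

outline_self_intersects <- function(pts) {
  n <- nrow(pts)
  seg_from <- pts
  seg_to <- pts[c(2:n, 1), , drop = FALSE]
  cross2 <- function(ox, oy, ax, ay, bx, by) (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  for (i in seq_len(n - 2)) {
    js <- (i + 2):n
    js <- js[!(i == 1 & js == n)]   # skip segments sharing an endpoint
    for (j in js) {
      d1 <- cross2(seg_from[i, 1], seg_from[i, 2], seg_to[i, 1], seg_to[i, 2],
                   seg_from[j, 1], seg_from[j, 2])
      d2 <- cross2(seg_from[i, 1], seg_from[i, 2], seg_to[i, 1], seg_to[i, 2],
                   seg_to[j, 1], seg_to[j, 2])
      d3 <- cross2(seg_from[j, 1], seg_from[j, 2], seg_to[j, 1], seg_to[j, 2],
                   seg_from[i, 1], seg_from[i, 2])
      d4 <- cross2(seg_from[j, 1], seg_from[j, 2], seg_to[j, 1], seg_to[j, 2],
                   seg_to[i, 1], seg_to[i, 2])
      if (((d1 > 0) != (d2 > 0)) && ((d3 > 0) != (d4 > 0))) return(TRUE)
    }
  }
  FALSE
}

#' Reflect one side's configurations into the other side's shape space
#'
#' Teeth from the right jaw margin are mirror images of left-side teeth.
#' Reflecting them about their own apex-base axis (the line through fixed
#' landmarks 1 and 20) and relabelling the two semilandmark curves puts both
#' sides into a single shape space. Whether the original analysis did this
#' is not recorded, so it is a switch (default on in [run_morphometrics()]).
#'
#' @param shapes Landmark tibble (`id`, `landmark`, `x`, `y`, ...).
#' @param meta Specimen metadata with `id` and `side`.
#' @param side Which side to reflect (default `"right"`).
#' @param apex_lm,base_lm Indices of the axis landmarks (defaults 1 and 20).
#' @return The shapes tibble with the chosen side reflected and relabelled.
#' @export
reflect_side <- function(shapes, meta, side = "right", apex_lm = 1,
                         base_lm = NULL) {
  k <- max(shapes$landmark)
  if (is.null(base_lm)) base_lm <- k / 2 + 1
  flip_ids <- meta$id[meta$side == side]
  n_semi <- (k - 2) / 2
  # after mirroring, the two semilandmark curves swap and reverse
  perm <- c(apex_lm, k:(base_lm + 1), base_lm, (base_lm - 1):2)
  labels <- integer(k); labels[perm] <- seq_len(k)
  done <- lapply(split(shapes, factor(shapes$id, unique(shapes$id))),
                 function(d) {
    if (!d$id[1] %in% flip_ids) return(d)
    d <- d[order(d$landmark), ]
    p1 <- c(d$x[apex_lm], d$y[apex_lm]); p2 <- c(d$x[base_lm], d$y[base_lm])
    u <- (p2 - p1) / sqrt(sum((p2 - p1)^2))
    rel <- cbind(d$x - p1[1], d$y - p1[2])
    along <- rel %*% u
    refl <- 2 * along %*% t(u) - rel    # householder reflection about the axis
    d$x <- refl[, 1] + p1[1]; d$y <- refl[, 2] + p1[2]
    d$landmark <- labels                # relabel the two curves
    d[order(d$landmark), ]
  })
  bind_rows(done)
}

#' Bundle landmark shapes, metadata and curve definitions
#'
#' @param shapes Landmark tibble.
#' @param meta Specimen metadata (one row per configuration id).
#' @param curves Optional `curveslide` table.
#' @return A list of class `landmark_dataset`.
#' @export
landmark_dataset <- function(shapes, meta, curves = NULL) {
  ids <- unique(shapes$id)
  if (!setequal(ids, meta$id))
    abort("metadata ids do not match landmark configuration ids")
  ks <- tapply(shapes$landmark, shapes$id, length)
  if (length(unique(ks)) != 1)
    abort("all configurations must share one landmark count")
  if (!is.null(curves)) curves <- validate_curveslide(curves, k = ks[[1]])
  structure(list(shapes = as_tibble(shapes), meta = as_tibble(meta),
                 curves = curves), class = "landmark_dataset")
}

#' @export
print.landmark_dataset <- function(x, ...) {
  cat("<landmark_dataset>", length(unique(x$shapes$id)), "configurations x",
      max(x$shapes$landmark), "landmarks;",
      if (is.null(x$curves)) "no sliding curves" else
        paste(nrow(x$curves), "sliding semilandmarks"), "\n")
  invisible(x)
}
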