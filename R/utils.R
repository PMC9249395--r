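# long landmark tibble <-> k x 2 x n array
shapes_to_array <- function(shapes) {
  ids <- unique(shapes$id)
  k <- max(shapes$landmark)
  arr <- array(NA_real_, c(k, 2, length(ids)), dimnames = list(NULL, c("x", "y"), ids))
  for (j in seq_along(ids)) {
    d <- shapes[shapes$id == ids[j], ]
    d <- d[order(d$landmark), ]
    if (nrow(d) != k) abort(paste0("configuration ", ids[j], " is incomplete"))
    arr[, 1, j] <- d$x; arr[, 2, j] <- d$y
  }
  if (!all(is.finite(arr))) abort("non-finite landmark coordinates")
  arr
}

array_to_shapes <- function(arr) {
  ids <- dimnames(arr)[[3]]
  k <- dim(arr)[1]
  bind_rows(lapply(seq_along(ids), function(j)
    tibble(id = ids[j], landmark = seq_len(k), x = arr[, 1, j], y = arr[, 2, j])))
}

config_matrix <- function(config) {
  if (is.matrix(config)) return(config)
  d <- config[order(config$landmark), ]
  cbind(d$x, d$y)
}
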