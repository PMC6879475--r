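# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

clamp01 <- function(x) pmin(pmax(x, 0), 1)

#' Disk-shaped region of interest
#'
#' Builds a boolean raster that is `TRUE` inside a disk. Coordinates follow
#' the package convention: row-major, origin at the top-left pixel, 0-based,
#' with `x` running along columns and `y` along rows.
#'
#' @param height,width Canvas size in pixels.
#' @param center Numeric `(x, y)` center in pixels (0-based). Defaults to the
#'   canvas center.
#' @param radius Disk radius in pixels.
#' @return A `height x width` logical matrix.
#' @export
disk_mask <- function(height, width, center = c((width - 1) / 2, (height - 1) / 2),
                      radius) {
  stopifnot(height >= 1, width >= 1, radius > 0)
  xs <- matrix(rep(seq_len(width) - 1, each = height), nrow = height)
  ys <- matrix(rep(seq_len(height) - 1, times = width), nrow = height)
  (xs - center[1])^2 + (ys - center[2])^2 <= radius^2
}

# Robust z-score: (x - median) / (1.4826 * MAD); MAD floor avoids division
# by zero on constant vectors.
robust_z <- function(x) {
  med <- stats::median(x)
  s <- stats::mad(x, center = med)
  if (s < .Machine$double.eps) s <- .Machine$double.eps
  (x - med) / s
}

# 8-connected component labelling of a logical matrix. EBImage::bwlabel is
# 4-connected, so thin diagonal vessels would fragment; we build the
# 8-neighbour adjacency graph over foreground pixels instead.
label_components_8 <- function(mask) {
  stopifnot(is.logical(mask), is.matrix(mask))
  lab <- matrix(0L, nrow(mask), ncol(mask))
  idx <- which(mask)
  if (length(idx) == 0L) return(lab)
  nr <- nrow(mask); nc <- ncol(mask)
  row <- ((idx - 1L) %% nr) + 1L
  col <- ((idx - 1L) %/% nr) + 1L
  pos <- integer(nr * nc)
  pos[idx] <- seq_along(idx)          # pixel linear index -> vertex id
  edges <- integer(0)
  for (d in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))) {
    r2 <- row + d[1]; c2 <- col + d[2]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    if (!any(ok)) next
    nb <- (c2[ok] - 1L) * nr + r2[ok]
    hit <- mask[nb]
    if (!any(hit)) next
    from <- pos[idx[ok][hit]]
    to <- pos[nb[hit]]
    edges <- c(edges, rbind(from, to))
  }
  g <- igraph::make_graph(edges = edges, n = length(idx), directed = FALSE)
  comp <- igraph::components(g)$membership
  lab[idx] <- as.integer(comp)
  lab
}

# Remove 8-connected components smaller than min_area pixels.
drop_small_components <- function(mask, min_area) {
  if (min_area <= 0L || !any(mask)) return(mask)
  lab <- label_components_8(mask)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= min_area)
  lab > 0L & matrix(lab %in% keep, nrow(mask), ncol(mask)) & mask
}


# Coerce an EBImage result back to a plain numeric matrix.
ebi_matrix <- function(img) {
  d <- EBImage::imageData(img)
  matrix(d, dim(d)[1], dim(d)[2])
}

stop_validation <- function(msg, class) {
  stop(rlang::error_cnd(c(class, "vasctrack_error"), message = msg))
}
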