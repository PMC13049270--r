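#' Label connected components of a 3D binary mask
#'
#' True 3D connected-component labeling under 6- (face) or 26- (face, edge,
#' corner) neighborhood connectivity, built on the voxel adjacency graph.
#' Labels are assigned deterministically in order of each component's first
#' voxel in linear (column-major) order.
#'
#' @param mask Logical 3D array.
#' @param connectivity 6 or 26 (default 26).
#' @return Integer 3D array; 0 is background, components are 1..k.
#' @export
label_components <- function(mask, connectivity = 26) {
  stopifnot(length(dim(mask)) == 3, connectivity %in% c(6, 26))
  dims <- dim(mask)
  idx <- which(mask)
  out <- array(0L, dims)
  if (length(idx) == 0) return(out)

  # forward neighbor offsets only (each undirected edge counted once)
  all_offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  all_offs <- all_offs[rowSums(abs(all_offs)) > 0, , drop = FALSE]
  if (connectivity == 6) {
    all_offs <- all_offs[rowSums(abs(all_offs)) == 1, , drop = FALSE]
  }
  fwd <- all_offs[all_offs[, 3] > 0 |
                  (all_offs[, 3] == 0 & (all_offs[, 2] > 0 |
                   (all_offs[, 2] == 0 & all_offs[, 1] > 0))), , drop = FALSE]

  pos <- integer(prod(dims))
  pos[idx] <- seq_along(idx)
  co <- arrayInd(idx, dims)
  edges_from <- integer(0); edges_to <- integer(0)
  for (i in seq_len(nrow(fwd))) {
    nc <- sweep(co, 2, fwd[i, ], "+")
    ok <- nc[, 1] >= 1 & nc[, 1] <= dims[1] &
          nc[, 2] >= 1 & nc[, 2] <= dims[2] &
          nc[, 3] >= 1 & nc[, 3] <= dims[3]
    if (!any(ok)) next
    lin <- (nc[ok, 3] - 1L) * dims[1] * dims[2] + (nc[ok, 2] - 1L) * dims[1] + nc[ok, 1]
    nb <- pos[lin]
    hit <- nb > 0
    edges_from <- c(edges_from, which(ok)[hit])
    edges_to <- c(edges_to, nb[hit])
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (length(edges_from) > 0) {
    g <- igraph::add_edges(g, rbind(edges_from, edges_to))
  }
  memb <- igraph::components(g)$membership
  # relabel by first occurrence in linear order for determinism
  relab <- integer(max(memb))
  nxt <- 0L
  lab <- integer(length(memb))
  for (i in seq_along(memb)) {
    m <- memb[i]
    if (relab[m] == 0L) { nxt <- nxt + 1L; relab[m] <- nxt }
    lab[i] <- relab[m]
  }
  out[idx] <- lab
  out
}
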