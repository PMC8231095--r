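# Cell adjacency graph: cells sharing a face-adjacent pixel pair are
# neighbours. Edges carry the interface pixel set (pixels of either cell lying
# on the shared boundary) and a class derived from the clone flags of the two
# cells: clone-clone, clone-normal or normal-normal.

EDGE_CLASSES <- c("normal-normal", "clone-clone", "clone-normal")

# per-axis shifted index pairs of a 2D/3D array, as linear indices
face_adjacent_pairs <- function(x) {
  d <- dim(x)
  nd <- length(d)
  idx <- array(seq_along(x), d)
  pairs <- list()
  for (ax in seq_len(nd)) {
    n <- d[ax]
    if (n < 2L) next
    take <- function(arr, from, to) {
      args <- rep(list(quote(expr = )), nd)
      args[[ax]] <- from:to
      do.call(`[`, c(list(arr), args, list(drop = FALSE)))
    }
    a <- take(idx, 1L, n - 1L)
    b <- take(idx, 2L, n)
    pairs[[ax]] <- cbind(as.vector(a), as.vector(b))
  }
  do.call(rbind, pairs)
}

#' Build the cell adjacency graph of a labelled cell image
#'
#' Nodes are cells (labels > 0) with their nucleus centroids in physical
#' coordinates; an undirected edge joins every pair of cells sharing at least
#' one face-adjacent pixel pair. Per edge, the set of interface pixels (linear
#' indices into the image, both sides of the boundary) is recorded, and the
#' edge is classed by the clone flags of its two cells.
#'
#' @param cells a [label_image()] whose labels partition the tissue (0 =
#'   outside tissue).
#' @param nuclei_centroids data frame with columns `label`, `row_um`, `col_um`
#'   (and `plane_um` for 3D): one nucleus centre per label, 0-based physical
#'   coordinates. An optional logical `clone` column flags clone-labelled
#'   cells (default all normal).
#' @return object of class `cell_graph`: `nodes` (data frame), `edges` (data
#'   frame with `a`, `b`, `class`, `n_interface_px`), `interface` (list of
#'   linear pixel index vectors per edge), `pixel_class` (integer array: 0 =
#'   not an interface pixel, else index into the class levels with precedence
#'   clone-normal > clone-clone > normal-normal), plus image `dim`/`spacing`.
#' @export
build_cell_graph <- function(cells, nuclei_centroids) {
  stopifnot(inherits(cells, "label_image"))
  x <- cells$data
  labs <- setdiff(sort(unique(as.vector(x))), 0L)
  nodes <- as.data.frame(nuclei_centroids)
  if (!"label" %in% names(nodes)) stop("`nuclei_centroids` needs a `label` column")
  if (!all(nodes$label %in% labs))
    stop("centroid given for a label absent from the image")
  if (!all(labs %in% nodes$label))
    stop("every image label needs a nucleus centroid")
  if (!"clone" %in% names(nodes)) nodes$clone <- FALSE
  nodes <- nodes[order(nodes$label), , drop = FALSE]
  rownames(nodes) <- NULL

  prs <- face_adjacent_pairs(x)
  la <- x[prs[, 1L]]; lb <- x[prs[, 2L]]
  sel <- la != lb & la > 0L & lb > 0L
  ea <- pmin(la[sel], lb[sel]); eb <- pmax(la[sel], lb[sel])
  pa <- prs[sel, 1L]; pb <- prs[sel, 2L]
  key <- paste(ea, eb)

  clone_of <- setNames(nodes$clone, nodes$label)
  edge_keys <- unique(key)
  interface <- vector("list", length(edge_keys))
  edges <- data.frame(a = integer(length(edge_keys)),
                      b = integer(length(edge_keys)),
                      class = character(length(edge_keys)),
                      n_interface_px = integer(length(edge_keys)))
  grp <- split(seq_along(key), key)
  pixel_class <- array(0L, dim(x))
  for (e in seq_along(edge_keys)) {
    k <- edge_keys[e]
    rows <- grp[[k]]
    a <- ea[rows[1L]]; b <- eb[rows[1L]]
    px <- unique(c(pa[rows], pb[rows]))
    interface[[e]] <- px
    nclone <- clone_of[as.character(a)] + clone_of[as.character(b)]
    # class codes double as pixel precedence:
    # 1 = normal-normal < 2 = clone-clone < 3 = clone-normal
    code <- c(1L, 3L, 2L)[nclone + 1L]
    edges$a[e] <- a; edges$b[e] <- b
    edges$class[e] <- EDGE_CLASSES[code]
    edges$n_interface_px[e] <- length(px)
    pixel_class[px] <- pmax(pixel_class[px], code)
  }
  structure(list(nodes = nodes, edges = edges, interface = interface,
                 pixel_class = pixel_class, dim = dim(x),
                 spacing = cells$spacing),
            class = "cell_graph")
}

#' @export
print.cell_graph <- function(x, ...) {
  cat(sprintf("<cell_graph> %d cells, %d edges (%s)\n", nrow(x$nodes),
              nrow(x$edges),
              paste(names(table(x$edges$class)), table(x$edges$class),
                    sep = ": ", collapse = ", ")))
  invisible(x)
}

#' Internuclear distances between neighbouring cells
#'
#' Euclidean distance between nucleus centroids, in micrometres, for every
#' edge of the cell graph (optionally only edges whose two cells both belong
#' to `restrict_to`, e.g. clone cells in direct contact).
#'
#' @param graph a [build_cell_graph()] result.
#' @param restrict_to optional vector of cell labels.
#' @return numeric vector of distances (one per qualifying edge).
#' @export
internuclear_distances <- function(graph, restrict_to = NULL) {
  stopifnot(inherits(graph, "cell_graph"))
  ed <- graph$edges
  if (!is.null(restrict_to))
    ed <- ed[ed$a %in% restrict_to & ed$b %in% restrict_to, , drop = FALSE]
  if (nrow(ed) == 0L) return(numeric(0))
  cc <- c("row_um", "col_um", if ("plane_um" %in% names(graph$nodes)) "plane_um")
  pos <- as.matrix(graph$nodes[match(ed$a, graph$nodes$label), cc, drop = FALSE]) -
    as.matrix(graph$nodes[match(ed$b, graph$nodes$label), cc, drop = FALSE])
  unname(sqrt(rowSums(pos^2)))
}

# chebyshev dilation of linear pixel indices by `band` pixels
dilate_indices <- function(px, dims, band) {
  if (band <= 0L) return(px)
  nd <- length(dims)
  coords <- arrayInd(px, dims)
  offs <- as.matrix(expand.grid(rep(list(-band:band), nd)))
  out <- matrix(rep(t(coords), each = nrow(offs)), ncol = nd, byrow = TRUE) +
    offs[rep(seq_len(nrow(offs)), times = nrow(coords)), , drop = FALSE]
  keep <- rep(TRUE, nrow(out))
  for (ax in seq_len(nd))
    keep <- keep & out[, ax] >= 1L & out[, ax] <= dims[ax]
  out <- out[keep, , drop = FALSE]
  unique(c(px, out %*% cumprod(c(1, dims[-nd])) - sum(cumprod(c(1, dims[-nd]))) + 1))
}

#' Mean signal intensity at cell--cell interfaces
#'
#' For every edge of the requested class, the mean of the intensity image over
#' the edge's interface pixels (optionally dilated by `band_width_px` pixels,
#' Chebyshev metric). Interface pixels that also touch a higher-precedence
#' interface class (e.g. a normal-normal pixel at a junction with a clone
#' cell) are excluded, so each pixel is quantified under exactly one class.
#'
#' @param intensity numeric array aligned with the cell label image.
#' @param graph a [build_cell_graph()] result.
#' @param pair_class one of `"clone-clone"`, `"clone-normal"`,
#'   `"normal-normal"`.
#' @param band_width_px dilation of the interface pixel set, in pixels.
#' @return data frame with `a`, `b`, `class`, `mean_intensity` (one row per
#'   edge of the class; `NaN` if all its pixels were reclassified).
#' @export
interface_intensity <- function(intensity, graph,
                                pair_class = c("clone-normal", "clone-clone",
                                               "normal-normal"),
                                band_width_px = 0L) {
  pair_class <- match.arg(pair_class)
  stopifnot(inherits(graph, "cell_graph"))
  if (!identical(dim(intensity), graph$dim))
    stop("intensity image shape does not match the cell graph")
  cls_code <- match(pair_class, EDGE_CLASSES)
  sel <- which(graph$edges$class == pair_class)
  out <- graph$edges[sel, c("a", "b", "class"), drop = FALSE]
  out$mean_intensity <- vapply(sel, function(e) {
    px <- graph$interface[[e]]
    px <- px[graph$pixel_class[px] == cls_code]
    px <- dilate_indices(px, graph$dim, as.integer(band_width_px))
    mean(intensity[px])
  }, numeric(1))
  rownames(out) <- NULL
  out
}

#' Count clone-labelled cells per cluster
#'
#' Assigns each clone cell to the cluster its pixels overlap and counts cells
#' per cluster. A clone cell whose pixels overlap two different clusters is a
#' contract violation (the generator never produces one) and raises an error.
#'
#' @param cells a [label_image()] of cell ids.
#' @param cluster_labels a [label_image()] of cluster ids (same shape).
#' @param clone_labels vector of cell labels that are clone cells.
#' @return data frame `cluster_id`, `cell_count`, one row per cluster with at
#'   least one clone cell.
#' @export
cells_per_cluster <- function(cells, cluster_labels, clone_labels) {
  stopifnot(inherits(cells, "label_image"), inherits(cluster_labels, "label_image"))
  if (!identical(dim(cells$data), dim(cluster_labels$data)))
    stop("cell and cluster images must have the same shape")
  if (length(clone_labels) == 0L)
    return(data.frame(cluster_id = integer(), cell_count = integer()))
  assign <- vapply(clone_labels, function(lb) {
    cl <- cluster_labels$data[cells$data == lb]
    cl <- cl[cl > 0L]
    u <- unique(cl)
    if (length(u) > 1L)
      stop(sprintf("cell %d spans clusters %s", lb,
                   paste(sort(u), collapse = ", ")))
    if (length(u) == 0L) NA_integer_ else u
  }, integer(1))
  tb <- table(assign[!is.na(assign)])
  data.frame(cluster_id = as.integer(names(tb)), cell_count = as.integer(tb))
}
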