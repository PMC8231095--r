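# Morphometry of labelled tissue images: cluster segmentation, density by
# size, and boundary-shape scores. Coordinates are 0-based (row, col[, plane]);
# all outputs are in physical units via the per-axis pixel spacing.

#' Labelled image container
#'
#' @param data 2D or 3D integer array; 0 = background, k > 0 = object id
#'   (logical arrays are accepted for binary masks).
#' @param spacing per-axis physical pixel size in micrometres
#'   (length 2 for 2D, 3 for 3D).
#' @return object of class `label_image`.
#' @export
label_image <- function(data, spacing = rep(1, length(dim(data)))) {
  if (is.null(dim(data))) stop("`data` must be a 2D or 3D array")
  nd <- length(dim(data))
  if (!nd %in% c(2L, 3L)) stop("`data` must be 2D or 3D")
  if (is.logical(data)) storage.mode(data) <- "integer"
  if (anyNA(data) || any(data < 0)) stop("labels must be non-negative integers")
  storage.mode(data) <- "integer"
  spacing <- as.numeric(spacing)
  if (length(spacing) != nd || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must give one positive size per axis")
  structure(list(data = data, spacing = spacing), class = "label_image")
}

#' @export
print.label_image <- function(x, ...) {
  cat(sprintf("<label_image> %s px, spacing %s um, %d labels\n",
              paste(dim(x$data), collapse = " x "),
              paste(x$spacing, collapse = " x "),
              length(setdiff(unique(as.vector(x$data)), 0L))))
  invisible(x)
}

as_label_image <- function(x, spacing = NULL) {
  if (inherits(x, "label_image")) return(x)
  if (is.null(spacing)) spacing <- rep(1, length(dim(x)))
  label_image(x, spacing)
}

#' Crofton (4-direction) perimeter of a binary mask
#'
#' Estimates the boundary length from intercept counts along horizontal,
#' vertical and both diagonal line families (Cauchy--Crofton):
#' \eqn{\hat P = (\pi/8)\,(I_h h + I_v h + (I_{d1} + I_{d2})\, h/\sqrt 2)}.
#' Unlike pixel-edge counting (`method = "edge"`, which returns 4nh for an
#' n x n square and overestimates smooth shapes), the Crofton estimate
#' converges to the true perimeter for digital discs.
#'
#' @param mask logical/0-1 matrix.
#' @param h isotropic pixel size, micrometres.
#' @param method `"crofton"` (default) or `"edge"` (count of exposed 4-neighbour
#'   pixel edges times `h`).
#' @return perimeter in micrometres.
#' @export
perimeter2d <- function(mask, h = 1, method = c("crofton", "edge")) {
  method <- match.arg(method)
  m <- matrix(0L, nrow(mask) + 2L, ncol(mask) + 2L)
  m[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L)] <- (mask != 0) * 1L
  nr <- nrow(m); nc <- ncol(m)
  if (method == "edge") {
    exposed <- sum(m[-1, ] != m[-nr, ]) + sum(m[, -1] != m[, -nc])
    return(exposed * h)
  }
  I_h <- sum(m[, -1] != m[, -nc])                       # along rows
  I_v <- sum(m[-1, ] != m[-nr, ])                       # along columns
  I_d1 <- sum(m[-1, -1] != m[-nr, -nc])                 # 45 degrees
  I_d2 <- sum(m[-1, -nc] != m[-nr, -1])                 # 135 degrees
  (pi / 8) * (I_h * h + I_v * h + (I_d1 + I_d2) * h / sqrt(2))
}

#' Circularity score 4*pi*A / P^2
#'
#' 1 for a perfect disc, smaller for elongated or rough shapes. The perimeter
#' is estimated by the Crofton method by default; because discretisation can
#' push the raw score slightly above 1, the returned value is clamped to
#' <= 1 (the raw value is kept in attribute `"raw"`).
#'
#' @param mask binary matrix (one object).
#' @param spacing per-axis pixel size, micrometres (must be isotropic).
#' @param method perimeter estimator, see [perimeter2d()].
#' @return clamped circularity score in (0, 1], with attribute `raw`.
#' @export
circularity <- function(mask, spacing = c(1, 1), method = c("crofton", "edge")) {
  if (length(dim(mask)) != 2L)
    stop("circularity is a 2D metric; use volume/3D measures for 3D objects")
  if (length(spacing) != 2L || abs(spacing[1] - spacing[2]) > 1e-12)
    stop("circularity requires isotropic 2D spacing")
  method <- match.arg(method)
  A <- sum(mask != 0) * spacing[1]^2
  if (A == 0) stop("empty mask")
  P <- perimeter2d(mask, h = spacing[1], method = method)
  if (P == 0) stop("zero perimeter")
  raw <- 4 * pi * A / P^2
  structure(min(raw, 1), raw = raw)
}

#' Index of sphericity: boundary smoothness of a 2D object
#'
#' Convention used throughout this package: the ratio of the convex-hull
#' perimeter of the object's pixel centres to the object's (Crofton) boundary
#' perimeter, clamped to (0, 1]. A convex object with a smooth boundary scores
#' about 1; lobed or invaginated boundaries score lower. A single-pixel object
#' scores 1 by definition.
#'
#' @param mask binary matrix (one object).
#' @param spacing per-axis pixel size, micrometres (isotropic).
#' @return sphericity index in (0, 1].
#' @export
sphericity_index <- function(mask, spacing = c(1, 1)) {
  if (length(dim(mask)) != 2L) stop("sphericity index is a 2D metric")
  if (length(spacing) != 2L || abs(spacing[1] - spacing[2]) > 1e-12)
    stop("sphericity index requires isotropic 2D spacing")
  px <- which(mask != 0, arr.ind = TRUE)
  if (nrow(px) == 0L) stop("empty mask")
  if (nrow(px) == 1L) return(1)
  pts <- (px - 1) * spacing[1]  # 0-based physical coordinates
  hull <- chull(pts[, 2L], pts[, 1L])
  hp <- pts[hull, , drop = FALSE]
  hp <- rbind(hp, hp[1L, , drop = FALSE])
  hull_perim <- sum(sqrt(rowSums(diff(hp)^2)))
  if (hull_perim == 0) return(1)  # collinear degenerate
  obj_perim <- perimeter2d(mask, h = spacing[1])
  min(1, hull_perim / obj_perim)
}

#' Segment labelled clusters from a binary mask
#'
#' Connected components of the foreground under 4- or 8-connectivity (2D) or
#' face connectivity (3D); components smaller than `min_area` are dropped.
#' Areas are pixel count times pixel area. For 2D isotropic images each record
#' also carries the Crofton perimeter, circularity and sphericity index.
#'
#' @param mask a [label_image()] (binary) or logical/0-1 matrix/array.
#' @param connectivity 4 (default, von Neumann) or 8 for 2D; 6 for 3D.
#' @param min_area drop components below this area (um^2; um^3 in 3D).
#' @param spacing pixel spacing if `mask` is a bare array.
#' @param shape_metrics compute circularity/sphericity per cluster (2D only)?
#' @return data frame of cluster records: `id`, `n_pixels`, `area_um2` (or
#'   `volume_um3` in 3D), `perimeter_um`, `circularity`, `sphericity`,
#'   `cell_count` (0 until [cells_per_cluster()] fills it), centroid columns in
#'   physical units. Attribute `"labels"` holds the `label_image` of cluster ids.
#' @export
segment_clusters <- function(mask, connectivity = 4L, min_area = 0,
                             spacing = NULL, shape_metrics = TRUE) {
  img <- as_label_image(mask, spacing)
  nd <- length(dim(img$data))
  if (nd == 3L && !connectivity %in% c(6L, 26L)) connectivity <- 6L
  lab <- .label_components(as.integer(img$data != 0L), dim(img$data),
                           as.integer(connectivity))
  labels_img <- label_image(lab, img$spacing)
  n <- max(lab)
  px_size <- prod(img$spacing)
  empty <- data.frame(id = integer(), n_pixels = integer(),
                      area_um2 = numeric(), perimeter_um = numeric(),
                      circularity = numeric(), sphericity = numeric(),
                      cell_count = integer(),
                      centroid_row_um = numeric(), centroid_col_um = numeric())
  if (n == 0L) {
    attr(empty, "labels") <- labels_img
    return(empty)
  }
  is2d <- nd == 2L
  isotropic <- is2d && abs(img$spacing[1] - img$spacing[2]) < 1e-12
  recs <- vector("list", n)
  for (id in seq_len(n)) {
    idx <- which(lab == id, arr.ind = TRUE)
    npx <- nrow(idx)
    area <- npx * px_size
    if (area < min_area) next
    cent <- (colMeans(idx) - 1) * img$spacing  # 0-based physical coordinates
    if (is2d && shape_metrics && isotropic) {
      sub <- submask(lab, idx, id)
      perim <- perimeter2d(sub, h = img$spacing[1])
      circ <- as.numeric(circularity(sub, spacing = img$spacing))
      sph <- sphericity_index(sub, spacing = img$spacing)
    } else {
      perim <- NA_real_; circ <- NA_real_; sph <- NA_real_
    }
    rec <- data.frame(id = id, n_pixels = npx, area_um2 = area,
                      perimeter_um = perim, circularity = circ,
                      sphericity = sph, cell_count = 0L,
                      centroid_row_um = cent[1], centroid_col_um = cent[2])
    if (!is2d) {
      names(rec)[names(rec) == "area_um2"] <- "volume_um3"
      rec$centroid_plane_um <- cent[3]
    }
    recs[[id]] <- rec
  }
  recs <- recs[!vapply(recs, is.null, logical(1))]
  out <- if (length(recs)) do.call(rbind, recs) else empty
  rownames(out) <- NULL
  attr(out, "labels") <- labels_img
  out
}

# crop the bounding box of one label as a binary matrix
submask <- function(lab, idx, id) {
  r <- range(idx[, 1L]); cc <- range(idx[, 2L])
  (lab[r[1]:r[2], cc[1]:cc[2], drop = FALSE] == id) * 1L
}

#' Cluster density by size bin
#'
#' Bins cluster areas and normalises the counts to total tissue area, giving
#' clusters per mm^2 tissue per size bin.
#'
#' @param records cluster records from [segment_clusters()] (or any data frame
#'   with an `area_um2` column).
#' @param tissue_area_mm2 total tissue area, mm^2 (> 0).
#' @param bin_edges area bin edges, um^2 (default includes the 2,000 um^2 edge).
#' @return a [size_distribution()].
#' @export
density_by_size <- function(records, tissue_area_mm2,
                            bin_edges = default_bin_edges()) {
  if (!is.numeric(tissue_area_mm2) || tissue_area_mm2 <= 0)
    stop("`tissue_area_mm2` must be > 0")
  nb <- length(bin_edges) - 1L
  counts <- rep(0L, nb)
  if (nrow(records) > 0L) {
    b <- findInterval(records$area_um2, bin_edges, rightmost.closed = FALSE)
    b <- pmin(pmax(b, 1L), nb)
    tb <- table(factor(b, levels = seq_len(nb)))
    counts <- as.integer(tb)
  }
  size_distribution(bin_edges, counts / tissue_area_mm2,
                    tissue_area_mm2 = tissue_area_mm2)
}

#' Labelled-area fraction of a tissue
#'
#' Percentage of the tissue mask covered by the label mask, the whole-tissue
#' readout of clone abundance.
#'
#' @param label_mask,tissue_mask binary arrays (or `label_image`s) of the same
#'   shape.
#' @return percent of tissue area labelled.
#' @export
label_area_fraction <- function(label_mask, tissue_mask) {
  lm <- if (inherits(label_mask, "label_image")) label_mask$data else label_mask
  tm <- if (inherits(tissue_mask, "label_image")) tissue_mask$data else tissue_mask
  if (!identical(dim(lm), dim(tm))) stop("masks must have the same shape")
  tt <- sum(tm != 0)
  if (tt == 0) stop("empty tissue mask")
  100 * sum(lm != 0 & tm != 0) / tt
}

#' Volume of one labelled cell in a 3D image
#'
#' @param cells a 3D [label_image()].
#' @param label cell id present in the image.
#' @return volume in cubic micrometres (voxel count times voxel volume).
#' @export
cell_volume <- function(cells, label) {
  stopifnot(inherits(cells, "label_image"))
  if (length(dim(cells$data)) != 3L) stop("`cells` must be a 3D label image")
  n <- sum(cells$data == label)
  if (n == 0L) stop(sprintf("label %s not present in image", label))
  n * prod(cells$spacing)
}
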