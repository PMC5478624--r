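# Otsu threshold of the valid cells of a height field (values in mm).
otsu_threshold <- function(residual) {
  v <- residual$valid
  rng <- range(residual$z[v])
  if (diff(rng) < .Machine$double.eps) return(rng[1])
  u <- (residual$z - rng[1]) / diff(rng)
  u[!v] <- 0
  t01 <- EBImage::otsu(EBImage::Image(t(u)), range = c(0, 1), levels = 256)
  rng[1] + t01 * diff(rng)
}

#' Threshold the block residual into a clod mask
#'
#' Marks cells whose block residual protrudes above the basal surface as clod
#' (1) and the rest as basal (0). With `method = "otsu"` (default, since the
#' field threshold is data-dependent) the mask is grown by hysteresis: seed
#' cells above the Otsu threshold of the residual histogram anchor clods, and
#' each clod extends through 8-connected cells down to the ground-noise floor
#' (median + 3 MAD of the sub-threshold residual), so the gently sloping
#' skirts of a clod are kept while isolated noise stays out. With
#' `method = "fixed"` a single threshold in mm is applied directly.
#'
#' @param residual The `block` component of a [decompose_surface()] result
#'   (a [height_field()]).
#' @param method `"otsu"` or `"fixed"`.
#' @param value Threshold in mm when `method = "fixed"` (must be >= 0).
#' @return Logical matrix mask (TRUE = clod), with the seed threshold in
#'   attribute `"threshold"` (and the floor in `"threshold_low"` for Otsu);
#'   invalid cells are FALSE.
#' @export
binarize_blocks <- function(residual, method = c("otsu", "fixed"),
                            value = NULL) {
  stopifnot(inherits(residual, "height_field"))
  method <- match.arg(method)
  v <- residual$valid
  if (!any(v)) stop("empty input: residual has no valid cells")
  if (method == "fixed") {
    if (is.null(value) || value < 0)
      stop("fixed thresholding needs a threshold value >= 0 (mm)")
    thr <- value
    mask <- residual$z > thr & v
    mask[is.na(mask)] <- FALSE
    attr(mask, "threshold") <- thr
    return(mask)
  }
  thr <- otsu_threshold(residual)
  seeds <- residual$z > thr & v
  seeds[is.na(seeds)] <- FALSE
  ground <- residual$z[v & !seeds]
  low <- if (length(ground) > 1)
    stats::median(ground) + 3 * stats::mad(ground) else thr
  low <- min(low, thr)
  cand <- residual$z > low & v
  cand[is.na(cand)] <- FALSE
  if (any(seeds) && any(cand & !seeds)) {
    lab <- label8(cand)
    keep <- unique(lab[seeds])
    mask <- matrix(lab %in% keep[keep > 0L], nrow(lab), ncol(lab))
  } else {
    mask <- seeds
  }
  attr(mask, "threshold") <- thr
  attr(mask, "threshold_low") <- low
  mask
}

# 8-connected labeling (EBImage 4-connected labeling + diagonal merge).
label8 <- function(mask) {
  lab <- t(EBImage::imageData(EBImage::bwlabel(EBImage::Image(t(mask * 1)))))
  lab <- matrix(as.integer(round(lab)), nrow(mask), ncol(mask))
  nlab <- max(lab)
  if (nlab == 0L) return(lab)
  parent <- seq_len(nlab)
  uf_find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  merge_pairs <- function(a, b) {
    keep <- a > 0L & b > 0L & a != b
    if (!any(keep)) return(invisible())
    pr <- unique(cbind(a[keep], b[keep]))
    for (r in seq_len(nrow(pr))) {
      ra <- uf_find(pr[r, 1]); rb <- uf_find(pr[r, 2])
      if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb)
    }
  }
  nr <- nrow(lab); nc <- ncol(lab)
  if (nr > 1 && nc > 1) {
    merge_pairs(lab[-nr, -nc], lab[-1, -1])   # down-right diagonal
    merge_pairs(lab[-nr, -1], lab[-1, -nc])   # down-left diagonal
  }
  root <- vapply(seq_len(nlab), uf_find, integer(1))
  lab[lab > 0L] <- root[lab[lab > 0L]]
  lab
}

#' Label connected clods in a binary mask
#'
#' 8-connected component labeling (diagonal contact joins clods), with
#' components below a minimum cell count removed to suppress single-pixel
#' depth-noise speckles.
#'
#' @param mask Logical (or 0/1) matrix from [binarize_blocks()].
#' @param min_area_cells Minimum component size in cells (default 4);
#'   set to 1 to disable.
#' @return Integer matrix of labels (0 = background, 1..n = clods) with the
#'   count in attribute `"n"`.
#' @export
label_blocks <- function(mask, min_area_cells = 4L) {
  mask <- as.matrix(mask) > 0
  if (!any(mask)) {
    lab <- matrix(0L, nrow(mask), ncol(mask))
    attr(lab, "n") <- 0L
    return(lab)
  }
  lab <- label8(mask)
  nlab <- max(lab)
  # min-area filter, then compact labels to 1..n
  sizes <- tabulate(lab[lab > 0L], nbins = nlab)
  keep <- which(sizes >= max(1L, as.integer(min_area_cells)))
  remap <- integer(nlab)
  remap[keep] <- seq_along(keep)
  lab[lab > 0L] <- remap[lab[lab > 0L]]
  attr(lab, "n") <- length(keep)
  lab
}

#' Measure every labeled clod
#'
#' Per-clod geometry from the labeled mask and the block residual: planimetric
#' area (cell count x cell area), maximum residual height, major/minor-axis
#' extents (ranges of the cell centres projected on the principal axes, plus
#' one cell pitch), area-equivalent diameter 2*sqrt(area/pi), and centroid.
#'
#' @param labels Label matrix from [label_blocks()].
#' @param residual The block-residual [height_field()] the labels were
#'   derived from (same dimensions).
#' @return A `data.frame` (class `block_records`) with one row per clod:
#'   `label`, `area_mm2`, `length_mm`, `width_mm`, `height_mm`,
#'   `equiv_diameter_mm`, `centroid_x_mm`, `centroid_y_mm`.
#' @export
measure_blocks <- function(labels, residual) {
  stopifnot(inherits(residual, "height_field"))
  if (!all(dim(labels) == dim(residual$z)))
    stop("input error: label matrix and residual field dimensions differ")
  n <- attr(labels, "n")
  if (is.null(n)) n <- max(labels)
  cell_area <- residual$pitch_x * residual$pitch_y
  co <- field_coords(residual)
  out <- data.frame(label = integer(0), area_mm2 = numeric(0),
                    length_mm = numeric(0), width_mm = numeric(0),
                    height_mm = numeric(0), equiv_diameter_mm = numeric(0),
                    centroid_x_mm = numeric(0), centroid_y_mm = numeric(0))
  if (n > 0) {
    idx <- which(labels > 0L)
    lb <- labels[idx]
    xs <- split(co$x[idx], lb)
    ys <- split(co$y[idx], lb)
    zs <- split(residual$z[idx], lb)
    pitch <- sqrt(cell_area)
    rows <- lapply(seq_len(n), function(k) {
      x <- xs[[k]]; y <- ys[[k]]
      area <- length(x) * cell_area
      if (length(x) > 1) {
        cc <- cbind(x - mean(x), y - mean(y))
        ev <- eigen(stats::cov(cc), symmetric = TRUE)$vectors
        pr <- cc %*% ev
        ext <- apply(pr, 2, function(u) diff(range(u))) + pitch
        len <- max(ext); wid <- min(ext)
      } else {
        len <- pitch; wid <- pitch
      }
      data.frame(label = k, area_mm2 = area, length_mm = len, width_mm = wid,
                 height_mm = max(zs[[k]], na.rm = TRUE),
                 equiv_diameter_mm = 2 * sqrt(area / pi),
                 centroid_x_mm = mean(x), centroid_y_mm = mean(y))
    })
    out <- do.call(rbind, rows)
  }
  class(out) <- c("block_records", "data.frame")
  out
}

#' Clod size-class edges (mm)
#'
#' The fixed grain-size classes used for seedbed grading:
#' <5, 5-15, 15-50, 50-80, 80-120 and >120 mm.
#' @return Numeric vector of bin edges, `c(0, 5, 15, 50, 80, 120, Inf)`.
#' @export
size_class_edges <- function() c(0, 5, 15, 50, 80, 120, Inf)

size_class_labels <- function() c("<5", "5-15", "15-50", "50-80", "80-120", ">120")

#' Clod size distribution over the standard grain-size classes
#'
#' Bins clods by area-equivalent diameter into the half-open classes
#' `[0,5) [5,15) [15,50) [50,80) [80,120) [120,Inf)` mm and reports count
#' fractions.
#'
#' @param blocks A `block_records` data frame from [measure_blocks()], or a
#'   numeric vector of equivalent diameters in mm.
#' @return An object of class `size_distribution`: list with `bin_edges`,
#'   `labels`, `counts`, `fractions` (sum 1 when any clod exists), `n`, and
#'   `empty` flag.
#' @examples
#' size_distribution(c(3, 10, 60))
#' @export
size_distribution <- function(blocks) {
  d <- if (is.data.frame(blocks)) blocks$equiv_diameter_mm else as.numeric(blocks)
  edges <- size_class_edges()
  if (length(d) == 0) {
    out <- list(bin_edges = edges, labels = size_class_labels(),
                counts = rep(0L, 6), fractions = rep(NA_real_, 6),
                n = 0L, empty = TRUE)
  } else {
    bin <- findInterval(d, edges, left.open = FALSE)  # [lo, hi)
    counts <- tabulate(bin, nbins = 6)
    out <- list(bin_edges = edges, labels = size_class_labels(),
                counts = counts, fractions = counts / sum(counts),
                n = length(d), empty = FALSE)
  }
  structure(out, class = "size_distribution")
}

#' @export
print.size_distribution <- function(x, ...) {
  if (x$empty) {
    cat("<size_distribution> empty (no clods)\n")
  } else {
    cat("<size_distribution>", x$n, "clods\n")
    print(stats::setNames(round(100 * x$fractions, 1), x$labels))
  }
  invisible(x)
}

#' Full clod inventory of a block residual
#'
#' Convenience wrapper: binarize, label, measure and bin in one call.
#'
#' @inheritParams binarize_blocks
#' @inheritParams label_blocks
#' @return List with `mask`, `labels`, `blocks` (records), `distribution`,
#'   and the `threshold` used (mm).
#' @export
extract_blocks <- function(residual, method = c("otsu", "fixed"),
                           value = NULL, min_area_cells = 4L) {
  mask <- binarize_blocks(residual, method, value)
  labels <- label_blocks(mask, min_area_cells)
  blocks <- measure_blocks(labels, residual)
  list(mask = mask, labels = labels, blocks = blocks,
       distribution = size_distribution(blocks),
       threshold = attr(mask, "threshold"))
}
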