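#' Maximum intensity projection
#'
#' Collapses a z-stack to one plane per channel by per-pixel maximum over z,
#' the projection applied to the acquired stacks before spot counting.
#'
#' @param stack an `nl_image_stack`, a 4D array (y, x, z, channel), or a 3D
#'   array (y, x, z).
#' @return For a 3D array, a matrix; otherwise a named list of matrices, one
#'   per channel.
#' @export
max_intensity_projection <- function(stack) {
  if (inherits(stack, "nl_image_stack")) stack <- stack$stack
  d <- dim(stack)
  if (is.null(d) || length(d) < 3L || any(d == 0L)) {
    stop("need a non-empty stack with at least one z-slice", call. = FALSE)
  }
  project <- function(a3) Reduce(pmax, lapply(seq_len(dim(a3)[3]),
                                              function(z) a3[, , z]))
  if (length(d) == 3L) return(project(stack))
  chans <- dimnames(stack)[[4]] %||% as.character(seq_len(d[4]))
  stats::setNames(lapply(seq_len(d[4]), function(ci) project(stack[, , , ci])),
                  chans)
}

# Laplacian-of-Gaussian kernel (positive response at bright blobs after
# negation).
log_kernel <- function(sigma) {
  half <- max(2L, ceiling(3 * sigma))
  x <- seq.int(-half, half)
  g <- outer(x, x, function(i, j) exp(-(i^2 + j^2) / (2 * sigma^2)))
  g <- g / sum(g)
  lap <- outer(x, x, function(i, j) (i^2 + j^2 - 2 * sigma^2) / sigma^4)
  k <- -lap * g
  k - mean(k)
}

#' Detect spots in a projected plane
#'
#' Band-pass (Laplacian of Gaussian at `blob_scale_px`), threshold in robust
#' MAD units of the filtered plane, 3x3 local maxima, greedy non-maximum
#' suppression at `min_separation` (of two detections closer than the
#' separation, only the stronger is kept), and subpixel centroids by local
#' center of mass of the positive band-pass response. Deterministic.
#'
#' @param plane numeric matrix (projected image).
#' @param blob_scale_px expected spot sigma in pixels (default 2).
#' @param threshold_k detection threshold in MAD units above the median of
#'   the band-passed plane (default 5).
#' @param min_separation minimum center distance between detections (px).
#' @return tibble of spots: `x`, `y` (subpixel, column/row pixel centers),
#'   `peak` (plane value at the maximum), `response` (band-pass quality
#'   score).
#' @export
detect_spots <- function(plane, blob_scale_px = 2, threshold_k = 5,
                         min_separation = 3) {
  stopifnot(is.matrix(plane))
  bp <- EBImage::filter2(plane, log_kernel(blob_scale_px))
  thr <- stats::median(bp) + threshold_k * stats::mad(bp)
  ny <- nrow(plane); nx <- ncol(plane)
  empty <- tibble::tibble(x = numeric(0), y = numeric(0), peak = numeric(0),
                          response = numeric(0))
  if (ny < 3L || nx < 3L) return(empty)

  inner <- bp[2:(ny - 1L), 2:(nx - 1L)]
  is_max <- inner > thr
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0L && dx == 0L) next
    is_max <- is_max & (inner >= bp[2:(ny - 1L) + dy, 2:(nx - 1L) + dx])
  }
  idx <- which(is_max, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(empty)
  cand <- tibble::tibble(row = idx[, 1] + 1L, col = idx[, 2] + 1L,
                         response = bp[cbind(idx[, 1] + 1L, idx[, 2] + 1L)])
  cand <- dplyr::arrange(cand, dplyr::desc(.data$response),
                         .data$row, .data$col)

  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!any(keep)) { keep[i] <- TRUE; next }
    d2 <- (cand$row[keep] - cand$row[i])^2 + (cand$col[keep] - cand$col[i])^2
    keep[i] <- all(d2 >= min_separation^2)
  }
  cand <- cand[keep, ]

  # subpixel center of mass on the positive band-pass response
  w <- max(1L, round(blob_scale_px))
  pos <- pmax(bp, 0)
  res <- purrr::pmap_dfr(cand, function(row, col, response) {
    rs <- max(1L, row - w):min(ny, row + w)
    cs <- max(1L, col - w):min(nx, col + w)
    patch <- pos[rs, cs, drop = FALSE]
    s <- sum(patch)
    if (s <= 0) {
      cy <- row; cx <- col
    } else {
      cy <- sum(rowSums(patch) * rs) / s
      cx <- sum(colSums(patch) * cs) / s
    }
    tibble::tibble(x = cx, y = cy, peak = plane[row, col], response = response)
  })
  dplyr::arrange(res, .data$y, .data$x)
}

circle_offsets <- function(radius) {
  r <- ceiling(radius)
  off <- expand.grid(dy = -r:r, dx = -r:r)
  off[off$dy^2 + off$dx^2 <= radius^2, ]
}

annulus_offsets <- function(inner, outer) {
  r <- ceiling(outer)
  off <- expand.grid(dy = -r:r, dx = -r:r)
  d2 <- off$dy^2 + off$dx^2
  off[d2 > inner^2 & d2 <= outer^2, ]
}

#' Aperture photometry of called spots
#'
#' Integrated intensity in a circular aperture around each spot minus the
#' median of an annulus times the aperture area (local background
#' subtraction), clamped at zero. Spots whose aperture is clipped by the
#' image border are flagged.
#'
#' @param plane numeric matrix.
#' @param spots tibble with `x`, `y` columns (e.g. from [detect_spots()]).
#' @param aperture_px aperture radius (px).
#' @param annulus_px length-2 inner/outer annulus radii (px).
#' @return `spots` with `intensity` and `border_clipped` columns added.
#' @export
measure_spots <- function(plane, spots, aperture_px = 3,
                          annulus_px = c(4, 6)) {
  stopifnot(is.matrix(plane), all(c("x", "y") %in% names(spots)))
  ap <- circle_offsets(aperture_px)
  an <- annulus_offsets(annulus_px[1], annulus_px[2])
  ny <- nrow(plane); nx <- ncol(plane)
  n_ap <- nrow(ap)
  out <- spots
  vals <- purrr::map2_dfr(spots$x, spots$y, function(x, y) {
    xi <- round(x); yi <- round(y)
    ay <- yi + ap$dy; ax <- xi + ap$dx
    clipped <- any(ay < 1 | ay > ny | ax < 1 | ax > nx)
    ok <- ay >= 1 & ay <= ny & ax >= 1 & ax <= nx
    ap_sum <- sum(plane[cbind(ay[ok], ax[ok])])
    by <- yi + an$dy; bx <- xi + an$dx
    okb <- by >= 1 & by <= ny & bx >= 1 & bx <= nx
    bg <- if (any(okb)) stats::median(plane[cbind(by[okb], bx[okb])]) else 0
    clipped <- clipped || !all(okb)
    tibble::tibble(intensity = max(0, ap_sum - bg * n_ap),
                   border_clipped = clipped)
  })
  out$intensity <- vals$intensity
  out$border_clipped <- vals$border_clipped
  out
}

#' Colocalize detection spots to reference anchors
#'
#' Mutual-nearest-neighbor pairing within `radius_px`, one matched record per
#' reference spot (the reference channel anchors the amplicon). Detection
#' channels without a mutual match within the radius contribute intensity 0.
#' Distance ties are broken by lower spot index.
#'
#' @param ref_spots tibble with `x`, `y`, `intensity` (reference channel).
#' @param det_spots named list of detection-channel spot tibbles (same
#'   columns).
#' @param radius_px matching radius in pixels (default 2).
#' @return tibble: `spot_id`, `x`, `y`, `I_Re`, and `I_<channel>` per
#'   detection channel.
#' @export
match_across_channels <- function(ref_spots, det_spots, radius_px = 2) {
  stopifnot(is.list(det_spots), !is.null(names(det_spots)))
  n_ref <- nrow(ref_spots)
  out <- tibble::tibble(spot_id = seq_len(n_ref),
                        x = ref_spots$x, y = ref_spots$y,
                        I_Re = ref_spots$intensity)
  for (ch in names(det_spots)) {
    ds <- det_spots[[ch]]
    inten <- numeric(n_ref)
    if (!is.null(ds) && nrow(ds) > 0L && n_ref > 0L) {
      dmat <- outer(ref_spots$x, ds$x, "-")^2 + outer(ref_spots$y, ds$y, "-")^2
      # nearest det for each ref and vice versa; ties -> lower index
      nn_det <- apply(dmat, 1L, which.min)
      nn_ref <- apply(dmat, 2L, which.min)
      for (i in seq_len(n_ref)) {
        j <- nn_det[i]
        if (dmat[i, j] <= radius_px^2 && nn_ref[j] == i) {
          inten[i] <- ds$intensity[j]
        }
      }
    }
    out[[paste0("I_", ch)]] <- inten
  }
  out
}

#' Assign matched spots to cells via a label mask
#'
#' Cell identity is the mask label at the rounded centroid; label 0 leaves
#' the spot unassigned (`NA`). Spot counts are conserved: assigned plus
#' unassigned equals input.
#'
#' @param matched tibble from [match_across_channels()].
#' @param cell_mask integer label matrix (same field geometry as the images).
#' @return `matched` with a `cell_id` column.
#' @export
assign_spots_to_cells <- function(matched, cell_mask) {
  stopifnot(is.matrix(cell_mask))
  ny <- nrow(cell_mask); nx <- ncol(cell_mask)
  if (nrow(matched) > 0L &&
      (any(matched$x < 0.5 | matched$x > nx + 0.5) ||
       any(matched$y < 0.5 | matched$y > ny + 0.5))) {
    stop("spot coordinates fall outside the mask geometry", call. = FALSE)
  }
  ids <- integer(nrow(matched))
  if (nrow(matched) > 0L) {
    yi <- pmin(pmax(round(matched$y), 1L), ny)
    xi <- pmin(pmax(round(matched$x), 1L), nx)
    ids <- cell_mask[cbind(yi, xi)]
  }
  matched$cell_id <- ifelse(ids == 0L, NA_integer_, as.integer(ids))
  matched
}

#' Call, measure, match and cell-assign spots in a rendered field
#'
#' Convenience pipeline over one `nl_image_stack`: MIP per channel, spot
#' detection on every fluorescence channel, aperture photometry, reference-
#' anchored channel matching, and cell assignment from the field's mask.
#'
#' @param field `nl_image_stack`.
#' @param codebook the codebook (names the reference/detection channels).
#' @param blob_scale_px,threshold_k,min_separation see [detect_spots()].
#' @param aperture_px,annulus_px see [measure_spots()].
#' @param radius_px see [match_across_channels()].
#' @return matched-spot tibble with `cell_id`.
#' @export
call_spots <- function(field, codebook, blob_scale_px = 2, threshold_k = 5,
                       min_separation = 3, aperture_px = 3,
                       annulus_px = c(4, 6), radius_px = 2) {
  cfg <- codebook_config(codebook)
  mip <- max_intensity_projection(field)
  detect_measure <- function(ch) {
    sp <- detect_spots(mip[[ch]], blob_scale_px, threshold_k, min_separation)
    measure_spots(mip[[ch]], sp, aperture_px, annulus_px)
  }
  ref <- detect_measure(cfg$reference_channel)
  dets <- stats::setNames(lapply(cfg$channel_names, detect_measure),
                          cfg$channel_names)
  matched <- match_across_channels(ref, dets, radius_px)
  assign_spots_to_cells(matched, field$cell_mask)
}
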