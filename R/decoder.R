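#' Detection/reference ratio vectors
#'
#' Elementwise `r_c = I_De_c / I_Re` per detection channel. Spots with
#' non-positive reference intensity are flagged for rejection (ratios `NA`);
#' zero detection intensity gives ratio 0. Division is never by zero.
#'
#' @param matched matched-spot tibble with `I_Re` and `I_<channel>` columns
#'   (from [match_across_channels()] or [simulate_spot_intensities()]).
#' @param codebook the codebook (names the channels).
#' @return `matched` with `r_<channel>` columns and a logical `ref_invalid`.
#' @export
compute_ratio_vector <- function(matched, codebook) {
  cfg <- codebook_config(codebook)
  out <- matched
  out$ref_invalid <- !(matched$I_Re > 0)
  for (ch in cfg$channel_names) {
    out[[paste0("r_", ch)]] <-
      ifelse(out$ref_invalid, NA_real_, matched[[paste0("I_", ch)]] / matched$I_Re)
  }
  out
}

#' Robust per-channel ratio calibration
#'
#' Estimates the scale factor mapping observed ratios onto integer repeat
#' levels. Candidate scales `median(r_c) / l` for each level l are scored by
#' the mean level-relative distance of the rescaled ratios to their nearest
#' level; the best candidate (ties resolved toward the smallest
#' correction) is refined once as `median(r_c / nearest level)` over
#' confident spots (ratio at least half the lowest level). The medians make
#' the estimate robust to a minority of outlier spots. With fewer than
#' `min_spots` usable ratios in a channel the identity scale is returned
#' with a warning.
#'
#' @param ratios tibble from [compute_ratio_vector()].
#' @param codebook the codebook.
#' @param min_spots minimum usable spots per channel.
#' @return named numeric vector of per-channel scale factors.
#' @export
calibrate_ratio_scale <- function(ratios, codebook, min_spots = 10L) {
  cfg <- codebook_config(codebook)
  R <- cfg$levels
  vapply(cfg$channel_names, function(ch) {
    r <- ratios[[paste0("r_", ch)]]
    r <- r[!is.na(r) & r >= 0.5]
    if (length(r) < min_spots) {
      warning("too few spots to calibrate channel ", ch,
              "; using identity scale", call. = FALSE)
      return(1)
    }
    cand <- unique(c(1, stats::median(r) / seq_len(R)))
    score <- vapply(cand, function(s) {
      rs <- r / s
      mean(vapply(rs, function(x) min(abs(x - seq_len(R)) / seq_len(R)),
                  numeric(1)))
    }, numeric(1))
    # best score; ties broken toward the smallest correction (s nearest 1)
    best <- which(score <= min(score) + 1e-12)
    s0 <- cand[best][which.min(abs(log(cand[best])))]
    lev <- pmin(pmax(round(r / s0), 1L), R)
    stats::median(r / lev)
  }, numeric(1))
}

#' Classify spots into virtual codes
#'
#' Nearest-code assignment under the level-relative distance
#' `d(code) = sum_c |r_c / s_c - level_c| / level_c` (dividing by the level
#' because ratio dispersion grows with level). A spot is `REJECT`ed when its
#' reference intensity was invalid, when any scaled ratio falls below 0.5
#' (beneath the lowest level - where degenerate and nonspecific spots land),
#' when the minimum distance exceeds `reject_margin`, or when the top two
#' codes tie exactly.
#'
#' @param ratios tibble from [compute_ratio_vector()].
#' @param codebook the codebook.
#' @param scale per-channel scale from [calibrate_ratio_scale()] (default
#'   identity).
#' @param reject_margin maximum accepted level-relative distance (default
#'   0.35).
#' @return `ratios` with `gene_id` (`NA` for rejected spots), `decoded_label`
#'   (`"REJECT"` or the code label), and `code_distance` columns.
#' @export
classify_spots <- function(ratios, codebook, scale = NULL,
                           reject_margin = 0.35) {
  cfg <- codebook_config(codebook)
  chn <- cfg$channel_names
  if (is.null(scale)) scale <- stats::setNames(rep(1, cfg$channels), chn)
  lv <- as.matrix(tibble::as_tibble(codebook)[, level_cols(cfg), drop = FALSE])
  n <- nrow(ratios)
  out <- ratios
  if ("gene_id" %in% names(out)) {
    # input carries ground truth (simulated photometry): keep it aside
    names(out)[names(out) == "gene_id"] <- "gene_id_true"
  }
  gene <- rep(NA_character_, n)
  label <- rep("REJECT", n)
  dist_min <- rep(NA_real_, n)
  if (n > 0L) {
    rmat <- sapply(chn, function(ch) ratios[[paste0("r_", ch)]] / scale[[ch]])
    rmat <- matrix(rmat, nrow = n)
    valid <- !ratios$ref_invalid & apply(rmat >= 0.5, 1L, all)
    valid[is.na(valid)] <- FALSE
    if (any(valid)) {
      d <- sapply(seq_len(nrow(lv)), function(k) {
        rowSums(abs(sweep(rmat[valid, , drop = FALSE], 2L, lv[k, ], "-")) %*%
                  diag(1 / lv[k, ], nrow = length(chn)))
      })
      d <- matrix(d, nrow = sum(valid))
      best <- apply(d, 1L, which.min)
      dmin <- d[cbind(seq_len(nrow(d)), best)]
      d2 <- apply(d, 1L, function(row) sort(row)[min(2L, length(row))])
      tie <- ncol(d) > 1L & abs(d2 - dmin) < 1e-9
      ok <- dmin <= reject_margin & !tie
      vi <- which(valid)
      gene[vi[ok]] <- codebook$transcript_id[best[ok]]
      label[vi[ok]] <- codebook$code_label[best[ok]]
      dist_min[vi] <- dmin
    }
  }
  out$gene_id <- gene
  out$decoded_label <- label
  out$code_distance <- dist_min
  out
}

#' Decode matched spots to per-cell transcript counts
#'
#' The field-level decoding pipeline: ratio computation, robust per-channel
#' calibration (fields, not cells, are the calibration unit - per-cell spot
#' counts are far too small), nearest-code classification with rejection,
#' and per-cell aggregation. Decoded plus rejected always equals the input
#' spot count.
#'
#' @param matched matched-spot tibble with `cell_id`, `I_Re`, `I_<channel>`.
#' @param codebook the codebook.
#' @param reject_margin see [classify_spots()].
#' @param calibrate logical; apply [calibrate_ratio_scale()] (default TRUE).
#' @return list of class `nl_decoded`: `spots` (classified spot table),
#'   `counts` (per cell x gene decoded counts plus per-cell rejects),
#'   `calibration`, `codebook`.
#' @export
decode_cells <- function(matched, codebook, reject_margin = 0.35,
                         calibrate = TRUE) {
  cfg <- codebook_config(codebook)
  if (nrow(matched) == 0L) {
    res <- list(spots = tibble::tibble(), counts = tibble::tibble(),
                calibration = stats::setNames(rep(1, cfg$channels),
                                              cfg$channel_names),
                codebook = codebook)
    class(res) <- "nl_decoded"
    return(res)
  }
  ratios <- compute_ratio_vector(matched, codebook)
  s <- if (calibrate) calibrate_ratio_scale(ratios, codebook)
       else stats::setNames(rep(1, cfg$channels), cfg$channel_names)
  spots <- classify_spots(ratios, codebook, scale = s,
                          reject_margin = reject_margin)
  counts <- spots |>
    dplyr::filter(!is.na(.data$cell_id)) |>
    dplyr::count(.data$cell_id, decoded = dplyr::coalesce(.data$gene_id, "REJECT")) |>
    tidyr::pivot_wider(names_from = "decoded", values_from = "n",
                       values_fill = 0L)
  for (g in c(codebook$transcript_id, "REJECT")) {
    if (!g %in% names(counts)) counts[[g]] <- 0L
  }
  counts <- counts[, c("cell_id", codebook$transcript_id, "REJECT")]
  res <- list(spots = spots, counts = counts, calibration = s,
              codebook = codebook)
  class(res) <- "nl_decoded"
  res
}

#' @export
print.nl_decoded <- function(x, ...) {
  n <- nrow(x$spots)
  nr <- if (n > 0L) sum(x$spots$decoded_label == "REJECT") else 0L
  cat("<decoded spots> ", n, " spots, ", n - nr, " decoded, ", nr,
      " rejected (", if (n > 0) round(100 * nr / n, 1) else 0, "%)\n", sep = "")
  cat("calibration: ",
      paste(names(x$calibration), round(x$calibration, 3), sep = "=",
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a decoding result
#'
#' @param x `nl_decoded` object.
#' @param ... unused.
#' @return the classified spot tibble.
#' @method tidy nl_decoded
#' @export
tidy.nl_decoded <- function(x, ...) tibble::as_tibble(x$spots)

#' One-row decoding summary
#'
#' @param x `nl_decoded` object.
#' @param ... unused.
#' @return tibble: spot totals, reject count and rate, genes decoded.
#' @method glance nl_decoded
#' @export
glance.nl_decoded <- function(x, ...) {
  n <- nrow(x$spots)
  nr <- if (n > 0L) sum(x$spots$decoded_label == "REJECT") else 0L
  tibble::tibble(n_spots = n, n_decoded = n - nr, n_rejected = nr,
                 reject_rate = if (n > 0L) nr / n else NA_real_,
                 n_genes = length(unique(stats::na.omit(x$spots$gene_id))))
}
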