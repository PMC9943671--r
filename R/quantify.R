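#' Build the genes x cells expression matrix
#'
#' Aggregates decoded spots into integer per-cell transcript counts.
#' Rejected spots are excluded from the counts but reported in the
#' `"rejected"` attribute; column sums equal per-cell decoded totals.
#'
#' @param decoded an `nl_decoded` object or a decoded spot tibble with
#'   `cell_id` and `gene_id` columns.
#' @return tibble of class `nl_expression`: one row per gene, one column per
#'   cell (named `cell_<id>`), first column `gene_id`.
#' @export
build_expression_matrix <- function(decoded) {
  if (inherits(decoded, "nl_decoded")) {
    genes <- decoded$codebook$transcript_id
    spots <- decoded$spots
  } else {
    spots <- decoded
    genes <- sort(unique(stats::na.omit(spots$gene_id)))
  }
  if (is.null(spots) || nrow(spots) == 0L) {
    out <- tibble::tibble(gene_id = character(0))
    attr(out, "rejected") <- tibble::tibble(cell_id = integer(0), n = integer(0))
    class(out) <- c("nl_expression", class(out))
    return(out)
  }
  assigned <- dplyr::filter(spots, !is.na(.data$cell_id))
  cells <- sort(unique(assigned$cell_id))
  counted <- assigned |>
    dplyr::filter(!is.na(.data$gene_id)) |>
    dplyr::count(.data$gene_id, .data$cell_id)
  mat <- matrix(0L, nrow = length(genes), ncol = length(cells),
                dimnames = list(genes, paste0("cell_", cells)))
  if (nrow(counted) > 0L) {
    mat[cbind(match(counted$gene_id, genes),
              match(counted$cell_id, cells))] <- counted$n
  }
  out <- tibble::tibble(gene_id = genes, tibble::as_tibble(mat))
  rejected <- assigned |>
    dplyr::filter(is.na(.data$gene_id)) |>
    dplyr::count(.data$cell_id)
  attr(out, "rejected") <- rejected
  attr(out, "cells") <- cells
  class(out) <- c("nl_expression", class(out))
  out
}

#' Expression matrix as a base matrix
#'
#' @param x `nl_expression` tibble.
#' @return integer matrix, genes in rows, cells in columns.
#' @export
as_count_matrix <- function(x) {
  m <- as.matrix(tibble::as_tibble(x)[, -1, drop = FALSE])
  rownames(m) <- x$gene_id
  m
}

# Wilson score interval for a binomial proportion.
wilson_interval <- function(x, n, conf = 0.95) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- x / n
  denom <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(lower = max(0, center - half), upper = min(1, center + half))
}

#' Estimate in situ detection efficiency
#'
#' Ratio of mean observed per-cell counts to the reference mean copy number
#' (e.g. from qPCR), with a Wilson confidence interval treating the pooled
#' observed count as binomial out of the pooled reference copies.
#'
#' @param observed numeric vector of per-cell observed counts for one gene.
#' @param reference_mean reference mean copies per cell (> 0).
#' @param conf confidence level.
#' @return one-row tibble: `efficiency`, `conf_low`, `conf_high`, `n_cells`.
#' @export
estimate_detection_efficiency <- function(observed, reference_mean,
                                          conf = 0.95) {
  if (!is.numeric(reference_mean) || length(reference_mean) != 1L ||
      reference_mean <= 0) {
    stop("reference_mean must be a single positive number", call. = FALSE)
  }
  n_cells <- length(observed)
  stopifnot(n_cells >= 1L)
  eff <- mean(observed) / reference_mean
  n_trials <- max(1L, round(reference_mean * n_cells))
  x <- min(sum(observed), n_trials)
  ci <- wilson_interval(x, n_trials, conf)
  tibble::tibble(efficiency = eff, conf_low = unname(ci["lower"]),
                 conf_high = unname(ci["upper"]), n_cells = n_cells)
}

#' Relative quantification by the 2^-ddCt method
#'
#' `ddCt = (Ct_target,test - Ct_ref,test) - (Ct_target,cal - Ct_ref,cal)`,
#' fold change `2^-ddCt`. Replicates are averaged per sample/gene first.
#'
#' @param ct tibble of Ct records: `sample_id`, `gene_id`, `ct` (replicate
#'   column optional).
#' @param target_gene,reference_gene gene labels.
#' @param test_sample,calibrator_sample sample labels.
#' @return one-row tibble: `target_gene`, `test_sample`,
#'   `calibrator_sample`, `delta_delta_ct`, `fold_change`.
#' @export
fold_change_ddct <- function(ct, target_gene, reference_gene,
                             test_sample, calibrator_sample) {
  stopifnot(all(c("sample_id", "gene_id", "ct") %in% names(ct)))
  mean_ct <- function(s, g) {
    v <- ct$ct[ct$sample_id == s & ct$gene_id == g]
    if (length(v) == 0L) {
      stop("no Ct records for sample '", s, "', gene '", g, "'", call. = FALSE)
    }
    mean(v)
  }
  ddct <- (mean_ct(test_sample, target_gene) -
             mean_ct(test_sample, reference_gene)) -
          (mean_ct(calibrator_sample, target_gene) -
             mean_ct(calibrator_sample, reference_gene))
  tibble::tibble(target_gene = target_gene, test_sample = test_sample,
                 calibrator_sample = calibrator_sample,
                 delta_delta_ct = ddct, fold_change = 2^(-ddct))
}

#' Nearest-centroid cell-type discrimination
#'
#' Fits a nearest-centroid classifier on log1p-transformed counts (counts
#' per gene are small, 0-30, so the transform stabilizes variance without
#' hyperparameters) and reports leave-one-out predictions, the confusion
#' table, and accuracy.
#'
#' @param cells tibble with one row per cell: a `cell_type` label column plus
#'   one numeric count column per gene.
#' @param label_col name of the label column.
#' @return object of class `nl_centroid_fit`: `centroids`, `predictions`
#'   (LOO), `confusion`, `accuracy`, `genes`.
#' @export
discriminate_cell_types <- function(cells, label_col = "cell_type") {
  stopifnot(is.data.frame(cells), label_col %in% names(cells))
  labels <- as.character(cells[[label_col]])
  classes <- sort(unique(labels))
  if (length(classes) < 2L) stop("need at least 2 classes", call. = FALSE)
  if (any(table(labels) < 2L)) {
    stop("need at least 2 cells per class", call. = FALSE)
  }
  genes <- setdiff(names(cells)[vapply(cells, is.numeric, logical(1))],
                   label_col)
  x <- log1p(as.matrix(cells[, genes, drop = FALSE]))
  n <- nrow(x)

  sums <- rowsum(x, labels)
  cnt <- as.integer(table(labels)[rownames(sums)])
  centroids <- sums / cnt

  # leave-one-out: recompute the held-out cell's own class centroid without it
  loo_pred <- character(n)
  for (i in seq_len(n)) {
    cen <- centroids
    k <- match(labels[i], rownames(cen))
    cen[k, ] <- (sums[k, ] - x[i, ]) / (cnt[k] - 1L)
    d2 <- rowSums(sweep(cen, 2L, x[i, ], "-")^2)
    loo_pred[i] <- rownames(cen)[which.min(d2)]
  }
  confusion <- table(truth = factor(labels, classes),
                     predicted = factor(loo_pred, classes))
  structure(list(centroids = centroids,
                 predictions = tibble::tibble(truth = labels,
                                              predicted = loo_pred),
                 confusion = confusion,
                 accuracy = mean(loo_pred == labels),
                 genes = genes),
            class = "nl_centroid_fit")
}

#' Predict cell types for new profiles
#'
#' @param object `nl_centroid_fit`.
#' @param newdata tibble with the fit's gene count columns.
#' @param ... unused.
#' @return character vector of predicted labels.
#' @export
predict.nl_centroid_fit <- function(object, newdata, ...) {
  x <- log1p(as.matrix(newdata[, object$genes, drop = FALSE]))
  apply(x, 1L, function(row) {
    d2 <- rowSums(sweep(object$centroids, 2L, row, "-")^2)
    rownames(object$centroids)[which.min(d2)]
  })
}

#' @export
print.nl_centroid_fit <- function(x, ...) {
  cat("<nearest-centroid cell-type model> ", nrow(x$centroids), " classes, ",
      length(x$genes), " genes; LOO accuracy ",
      round(100 * x$accuracy, 1), "%\n", sep = "")
  invisible(x)
}

#' Tidy a cell-type model: centroids in long form
#'
#' @param x `nl_centroid_fit`.
#' @param ... unused.
#' @return tibble: `cell_type`, `gene_id`, `centroid` (log1p scale).
#' @method tidy nl_centroid_fit
#' @export
tidy.nl_centroid_fit <- function(x, ...) {
  tibble::as_tibble(as.table(x$centroids), .name_repair = "minimal") |>
    stats::setNames(c("cell_type", "gene_id", "centroid"))
}

#' One-row cell-type model summary
#'
#' @param x `nl_centroid_fit`.
#' @param ... unused.
#' @return tibble: `n_cells`, `n_classes`, `n_genes`, `accuracy`.
#' @method glance nl_centroid_fit
#' @export
glance.nl_centroid_fit <- function(x, ...) {
  tibble::tibble(n_cells = nrow(x$predictions),
                 n_classes = nrow(x$centroids),
                 n_genes = length(x$genes),
                 accuracy = x$accuracy)
}
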