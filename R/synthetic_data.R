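#' Default nine-gene panel
#'
#' The transcript panel used throughout the examples (GAPDH, THBS1, HER2, PR,
#' ER, PFN1, EGFR, KI67, PRKCA) with per-gene negative-binomial copy-number
#' parameters. PFN1 (mean 24) and ER (mean 4) follow the printed single-cell
#' ranges 18-30 and 1-9; the remaining means are plausible defaults for the
#' panel, documented in the vignette.
#'
#' @param cell_type optional cell-type name to modulate the means (see
#'   [cell_type_profiles()]).
#' @return tibble: `gene_id`, `nb_mean`, `nb_size`.
#' @export
default_gene_panel <- function(cell_type = NULL) {
  panel <- tibble::tibble(
    gene_id = c("GAPDH", "THBS1", "HER2", "PR", "ER",
                "PFN1", "EGFR", "KI67", "PRKCA"),
    nb_mean = c(100, 40, 15, 10, 4, 24, 20, 12, 8),
    nb_size = 5
  )
  if (!is.null(cell_type)) {
    prof <- cell_type_profiles()
    fac <- prof[prof$cell_type == cell_type, ]
    if (nrow(fac) == 0L) stop("unknown cell type: ", cell_type, call. = FALSE)
    mult <- unlist(fac[1, panel$gene_id])
    panel$nb_mean <- panel$nb_mean * mult
  }
  panel
}

#' Expression multipliers per cell line
#'
#' Qualitative orderings used for cell-type simulations: PR, EGFR and KI67
#' elevated in MDA-MB-231; PRKCA elevated in MCF-10A; ER flat across lines.
#'
#' @return tibble with one row per cell type and one multiplier column per
#'   panel gene.
#' @export
cell_type_profiles <- function() {
  tibble::tribble(
    ~cell_type,   ~GAPDH, ~THBS1, ~HER2, ~PR, ~ER, ~PFN1, ~EGFR, ~KI67, ~PRKCA,
    "MCF-10A",       1,      1,     1,    1,   1,    1,     1,     1,     3,
    "MCF-7",         1,      1,     2,    1,   1,    1,     1,     1,     1,
    "MDA-MB-231",    1,      1.5,   1,    3,   1,    1.2,   3,     3,     1,
    "HeLa",          1,      1,     1,    1,   1,    1,     1,     1,     1
  )
}

#' Simulation configuration
#'
#' All the knobs of the synthetic single-cell experiment: copy-number law,
#' in situ detection efficiency, rolling-circle amplicon repeat-count law,
#' hybridization efficiencies, photometric noise, nonspecific-spot rate, and
#' imaging geometry.
#'
#' @param n_cells number of cells.
#' @param genes gene panel tibble (`gene_id`, `nb_mean`, `nb_size`).
#' @param p_det in situ detection efficiency: fraction of true copies that
#'   become amplicons (default 0.30, the regime the method operates in).
#' @param k_meanlog,k_sdlog lognormal parameters of the amplicon tandem
#'   repeat count K (discretized, min 1); defaults `log(60)` and 0.5 give the
#'   right-skewed heterogeneity of rolling-circle amplification.
#' @param h_dfp,h_rfp hybridization efficiency of detection / reference
#'   fluorescent probes (per binding site).
#' @param brightness_dfp,brightness_rfp expected camera counts per bound
#'   fluorophore.
#' @param shot_noise Poisson shot noise on intensities (logical).
#' @param read_noise_sd Gaussian camera read noise (counts), applied at
#'   rendering.
#' @param background constant image background (counts).
#' @param ns_mode nonspecific-amplification mode: `"rna_primed"` (default,
#'   mean 0.2 nonspecific spots per cell) or `"primer_assisted"` (mean 16).
#' @param lambda_ns override for the Poisson nonspecific rate per cell.
#' @param fov_px minimum field-of-view side (pixels); grown as needed to fit
#'   all cells.
#' @param n_z number of z-slices; `z_spacing_nm` defaults to 500 nm.
#' @param z_spacing_nm z-slice spacing in nm.
#' @param pixel_size_nm lateral pixel size in nm.
#' @param psf_sigma_px,psf_sigma_z Gaussian PSF sigma laterally (px) and
#'   axially (slices).
#' @param cell_radius_px,nucleus_radius_px cell and nucleus disk radii (px).
#' @param qpcr_intercept,qpcr_slope,qpcr_noise_sd standard-curve parameters
#'   for the simulated qPCR (Ct = intercept - slope * log10(copies)); the
#'   default slope log2(10) = 3.32 is the ideal-efficiency (doubling per
#'   cycle) slope.
#' @return list of class `nl_sim_config`.
#' @export
simulation_config <- function(n_cells = 50L,
                              genes = default_gene_panel(),
                              p_det = 0.30,
                              k_meanlog = log(60), k_sdlog = 0.5,
                              h_dfp = 0.9, h_rfp = 0.9,
                              brightness_dfp = 20, brightness_rfp = 20,
                              shot_noise = TRUE, read_noise_sd = 2,
                              background = 100,
                              ns_mode = c("rna_primed", "primer_assisted"),
                              lambda_ns = NULL,
                              fov_px = 128L, n_z = 7L, z_spacing_nm = 500,
                              pixel_size_nm = 160,
                              psf_sigma_px = 1.2, psf_sigma_z = 1.0,
                              cell_radius_px = 14L, nucleus_radius_px = 6L,
                              qpcr_intercept = 38, qpcr_slope = log2(10),
                              qpcr_noise_sd = 0.1) {
  ns_mode <- match.arg(ns_mode)
  if (is.null(lambda_ns)) {
    lambda_ns <- c(rna_primed = 0.2, primer_assisted = 16)[[ns_mode]]
  }
  stopifnot(p_det >= 0, p_det <= 1, h_dfp >= 0, h_dfp <= 1,
            h_rfp >= 0, h_rfp <= 1, lambda_ns >= 0, n_cells >= 0)
  structure(list(n_cells = as.integer(n_cells), genes = genes, p_det = p_det,
                 k_meanlog = k_meanlog, k_sdlog = k_sdlog,
                 h_dfp = h_dfp, h_rfp = h_rfp,
                 brightness_dfp = brightness_dfp,
                 brightness_rfp = brightness_rfp,
                 shot_noise = shot_noise, read_noise_sd = read_noise_sd,
                 background = background,
                 ns_mode = ns_mode, lambda_ns = lambda_ns,
                 fov_px = as.integer(fov_px), n_z = as.integer(n_z),
                 z_spacing_nm = z_spacing_nm, pixel_size_nm = pixel_size_nm,
                 psf_sigma_px = psf_sigma_px, psf_sigma_z = psf_sigma_z,
                 cell_radius_px = as.integer(cell_radius_px),
                 nucleus_radius_px = as.integer(nucleus_radius_px),
                 qpcr_intercept = qpcr_intercept, qpcr_slope = qpcr_slope,
                 qpcr_noise_sd = qpcr_noise_sd),
            class = "nl_sim_config")
}

empty_truth <- function(config, codebook) {
  lvl <- level_cols(codebook_config(codebook))
  amp <- tibble::tibble(amplicon_id = integer(0), cell_id = integer(0),
                        gene_id = character(0))
  for (l in lvl) amp[[l]] <- integer(0)
  amp$x <- numeric(0); amp$y <- numeric(0); amp$z <- numeric(0)
  amp$K <- integer(0); amp$is_nonspecific <- logical(0)
  list(cells = tibble::tibble(cell_id = integer(0), cx = numeric(0),
                              cy = numeric(0), radius = numeric(0)),
       copies = tibble::tibble(cell_id = integer(0), gene_id = character(0),
                               true_copies = integer(0),
                               detected_copies = integer(0)),
       amplicons = amp, fov_px = config$fov_px)
}

#' Simulate single-cell ground truth
#'
#' Per cell and gene, true copy numbers are drawn from a negative binomial;
#' each copy becomes a visible amplicon with probability `p_det` (binomial
#' thinning, the in situ detection efficiency); each amplicon receives a
#' lognormal tandem repeat count K and a position inside its cell; and a
#' Poisson number of nonspecific amplicons per cell is added with
#' `gene_id = NA` and a single random-channel code signature.
#'
#' @param codebook [assign_codebook()] result; its transcripts must be a
#'   subset of `config$genes$gene_id` (extra panel genes are ignored).
#' @param config [simulation_config()].
#' @param seed RNG seed; the whole simulation is deterministic given it.
#' @return list with elements `cells` (cell geometry), `copies` (per
#'   cell/gene true and detected copy counts), `amplicons` (one row per
#'   amplicon with code levels, position, K, `is_nonspecific`), and `fov_px`.
#' @export
simulate_ground_truth <- function(codebook, config = simulation_config(),
                                  seed = NULL) {
  cfg <- codebook_config(codebook)
  lvl <- level_cols(cfg)
  genes <- dplyr::semi_join(config$genes,
                            tibble::tibble(gene_id = codebook$transcript_id),
                            by = "gene_id")
  missing <- setdiff(codebook$transcript_id, genes$gene_id)
  if (length(missing) > 0L) {
    stop("codebook transcripts missing from the gene panel: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (config$n_cells == 0L) return(empty_truth(config, codebook))

  with_seed(seed, {
    # cells on a square grid, grown to fit the requested fov if needed
    pitch <- 2L * config$cell_radius_px + 4L
    ncol_g <- max(1L, ceiling(sqrt(config$n_cells)))
    nrow_g <- ceiling(config$n_cells / ncol_g)
    fov <- max(config$fov_px, pitch * max(ncol_g, nrow_g) + 2L)
    idx <- seq_len(config$n_cells) - 1L
    cells <- tibble::tibble(
      cell_id = seq_len(config$n_cells),
      cx = (idx %% ncol_g) * pitch + pitch / 2 + 1,
      cy = (idx %/% ncol_g) * pitch + pitch / 2 + 1,
      radius = config$cell_radius_px
    )

    copies <- tidyr::expand_grid(cell_id = cells$cell_id,
                                 gene_id = genes$gene_id) |>
      dplyr::left_join(genes, by = "gene_id") |>
      dplyr::mutate(
        true_copies = stats::rnbinom(dplyr::n(), mu = .data$nb_mean,
                                     size = .data$nb_size),
        detected_copies = stats::rbinom(dplyr::n(), .data$true_copies,
                                        config$p_det)
      ) |>
      dplyr::select("cell_id", "gene_id", "true_copies", "detected_copies")

    spec <- copies |>
      dplyr::filter(.data$detected_copies > 0L) |>
      tidyr::uncount(.data$detected_copies, .remove = FALSE) |>
      dplyr::left_join(tibble::as_tibble(codebook)[, c("transcript_id", lvl)],
                       by = c(gene_id = "transcript_id")) |>
      dplyr::mutate(is_nonspecific = FALSE) |>
      dplyr::select("cell_id", "gene_id", dplyr::all_of(lvl), "is_nonspecific")

    n_ns <- stats::rpois(config$n_cells, config$lambda_ns)
    if (sum(n_ns) > 0L) {
      ns <- tibble::tibble(cell_id = rep(cells$cell_id, n_ns),
                           gene_id = NA_character_)
      for (l in lvl) ns[[l]] <- 0L
      ch_pick <- sample.int(cfg$channels, nrow(ns), replace = TRUE)
      lv_pick <- sample.int(cfg$levels, nrow(ns), replace = TRUE)
      for (j in seq_len(cfg$channels)) {
        sel <- ch_pick == j
        ns[[lvl[j]]][sel] <- lv_pick[sel]
      }
      ns$is_nonspecific <- TRUE
      amp <- dplyr::bind_rows(spec, ns)
    } else {
      amp <- spec
    }

    n_amp <- nrow(amp)
    amp <- amp |>
      dplyr::left_join(cells, by = "cell_id") |>
      dplyr::mutate(
        r = .data$radius * sqrt(stats::runif(n_amp)),
        theta = stats::runif(n_amp, 0, 2 * pi),
        x = .data$cx + .data$r * cos(.data$theta),
        y = .data$cy + .data$r * sin(.data$theta),
        z = stats::runif(n_amp, 1, config$n_z),
        K = pmax(1L, as.integer(round(stats::rlnorm(n_amp, config$k_meanlog,
                                                    config$k_sdlog))))
      ) |>
      dplyr::arrange(.data$cell_id, .data$gene_id) |>
      dplyr::mutate(amplicon_id = dplyr::row_number()) |>
      dplyr::select("amplicon_id", "cell_id", "gene_id", dplyr::all_of(lvl),
                    "x", "y", "z", "K", "is_nonspecific")

    list(cells = cells, copies = copies, amplicons = amp, fov_px = fov)
  })
}

#' Simulate per-amplicon spot photometry
#'
#' Each amplicon binds `Binomial(K * level_c, h_dfp)` detection fluorophores
#' in channel c and `Binomial(K, h_rfp)` reference fluorophores; intensities
#' are brightness-scaled counts with optional Poisson shot noise. With noise
#' off and unit hybridization efficiency the detection/reference ratio is
#' exactly the repeat level for every K - the normalization rationale of the
#' reference channel.
#'
#' @param amplicons amplicon tibble from [simulate_ground_truth()].
#' @param codebook the codebook (supplies channel names).
#' @param config [simulation_config()].
#' @param seed RNG seed.
#' @return photometry tibble: amplicon columns plus `I_Re` and one
#'   `I_<channel>` column per detection channel.
#' @export
simulate_spot_intensities <- function(amplicons, codebook,
                                      config = simulation_config(),
                                      seed = NULL) {
  cfg <- codebook_config(codebook)
  lvl <- level_cols(cfg)
  n <- nrow(amplicons)
  out <- amplicons
  with_seed(seed, {
    bound_ref <- if (config$h_rfp == 1) amplicons$K
                 else stats::rbinom(n, amplicons$K, config$h_rfp)
    i_ref <- config$brightness_rfp * bound_ref
    if (config$shot_noise && n > 0L) i_ref <- stats::rpois(n, i_ref)
    out$I_Re <- as.numeric(i_ref)
    for (j in seq_len(cfg$channels)) {
      sites <- amplicons$K * amplicons[[lvl[j]]]
      bound <- if (config$h_dfp == 1) sites
               else stats::rbinom(n, sites, config$h_dfp)
      i_de <- config$brightness_dfp * bound
      if (config$shot_noise && n > 0L) i_de <- stats::rpois(n, i_de)
      out[[paste0("I_", cfg$channel_names[j])]] <- as.numeric(i_de)
    }
    out
  })
}

gaussian_kernel_1d <- function(sigma, half) {
  x <- seq.int(-half, half)
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

#' Render a multi-channel z-stack and cell masks
#'
#' Places each spot as a separable 3D Gaussian (sigma from the config) whose
#' voxel sum equals its channel intensity, over a constant background with
#' optional Gaussian read noise, quantized to 16-bit with saturation
#' clipping. A nuclear-stain channel and 16-bit label masks (cells, nuclei)
#' are rendered from the cell geometry. Spots outside the field are clipped
#' with a warning.
#'
#' @param photometry tibble from [simulate_spot_intensities()].
#' @param cells cell tibble from [simulate_ground_truth()].
#' @param codebook the codebook.
#' @param config [simulation_config()].
#' @param fov_px field side length (pixels), e.g. the `fov_px` returned by
#'   [simulate_ground_truth()].
#' @param seed RNG seed for the read noise.
#' @return list of class `nl_image_stack`: `stack` (array y, x, z, channel),
#'   `channels`, `cell_mask`, `nucleus_mask`, `meta` (pixel size, z spacing
#'   in nm, channel labels).
#' @export
render_image_stack <- function(photometry, cells, codebook,
                               config = simulation_config(),
                               fov_px = config$fov_px, seed = NULL) {
  cfg <- codebook_config(codebook)
  channels <- c(cfg$reference_channel, cfg$channel_names, "DAPI")
  ny <- nx <- as.integer(fov_px)
  nz <- config$n_z
  stack <- array(config$background, dim = c(ny, nx, nz, length(channels)),
                 dimnames = list(NULL, NULL, NULL, channels))

  half_xy <- max(1L, ceiling(4 * config$psf_sigma_px))
  half_z <- max(1L, ceiling(3 * config$psf_sigma_z))
  kx <- gaussian_kernel_1d(config$psf_sigma_px, half_xy)
  kz <- gaussian_kernel_1d(config$psf_sigma_z, half_z)

  intensity_cols <- paste0("I_", c(cfg$reference_channel, cfg$channel_names))
  n_clip <- 0L
  if (nrow(photometry) > 0L) {
    for (i in seq_len(nrow(photometry))) {
      x0 <- photometry$x[i]; y0 <- photometry$y[i]; z0 <- photometry$z[i]
      if (x0 < 1 || x0 > nx || y0 < 1 || y0 > ny) n_clip <- n_clip + 1L
      xi <- round(x0); yi <- round(y0); zi <- round(z0)
      if (xi + half_xy < 1 || xi - half_xy > nx ||
          yi + half_xy < 1 || yi - half_xy > ny ||
          zi + half_z < 1 || zi - half_z > nz) next
      xs <- max(1L, xi - half_xy):min(nx, xi + half_xy)
      ys <- max(1L, yi - half_xy):min(ny, yi + half_xy)
      zs <- max(1L, zi - half_z):min(nz, zi + half_z)
      wx <- exp(-(xs - x0)^2 / (2 * config$psf_sigma_px^2))
      wy <- exp(-(ys - y0)^2 / (2 * config$psf_sigma_px^2))
      wz <- exp(-(zs - z0)^2 / (2 * config$psf_sigma_z^2))
      blob <- outer(wy, wx) %o% wz
      blob <- blob / sum(blob)
      for (ci in seq_along(intensity_cols)) {
        inten <- photometry[[intensity_cols[ci]]][i]
        if (inten > 0) {
          stack[ys, xs, zs, ci] <- stack[ys, xs, zs, ci] + inten * blob
        }
      }
    }
  }
  if (n_clip > 0L) {
    warning(n_clip, " spot(s) outside the field were clipped", call. = FALSE)
  }

  # cell + nucleus masks and the nuclear-stain channel
  cell_mask <- matrix(0L, ny, nx)
  nuc_mask <- matrix(0L, ny, nx)
  xg <- matrix(rep(seq_len(nx), each = ny), ny, nx)
  yg <- matrix(rep(seq_len(ny), nx), ny, nx)
  for (i in seq_len(nrow(cells))) {
    d2 <- (xg - cells$cx[i])^2 + (yg - cells$cy[i])^2
    cell_mask[d2 <= cells$radius[i]^2] <- cells$cell_id[i]
    nuc_mask[d2 <= config$nucleus_radius_px^2] <- cells$cell_id[i]
  }
  dapi_level <- 2000
  for (z in seq_len(nz)) {
    stack[, , z, "DAPI"] <- stack[, , z, "DAPI"] + dapi_level * (nuc_mask > 0L)
  }

  with_seed(seed, {
    if (config$read_noise_sd > 0) {
      stack <- stack + stats::rnorm(length(stack), 0, config$read_noise_sd)
    }
    stack <- round(pmin(pmax(stack, 0), 65535))
    structure(list(stack = stack, channels = channels,
                   cell_mask = cell_mask, nucleus_mask = nuc_mask,
                   meta = list(pixel_size_nm = config$pixel_size_nm,
                               z_spacing_nm = config$z_spacing_nm,
                               channels = channels, fov_px = ny, n_z = nz)),
              class = "nl_image_stack")
  })
}

#' Write / read a rendered field of view
#'
#' One multi-page 16-bit TIFF per channel plus 16-bit label-mask TIFFs and a
#' JSON sidecar carrying the calibration metadata; metadata round-trips
#' exactly.
#'
#' @param field [render_image_stack()] result.
#' @param dir output directory (created if needed).
#' @return `write_image_stack()`: `dir` invisibly; `read_image_stack()`: an
#'   `nl_image_stack` list.
#' @export
write_image_stack <- function(field, dir) {
  stopifnot(inherits(field, "nl_image_stack"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (ch in field$channels) {
    pages <- lapply(seq_len(dim(field$stack)[3]),
                    function(z) field$stack[, , z, ch] / 65535)
    tiff::writeTIFF(pages, file.path(dir, paste0(ch, ".tiff")),
                    bits.per.sample = 16L)
  }
  tiff::writeTIFF(field$cell_mask / 65535, file.path(dir, "cell_mask.tiff"),
                  bits.per.sample = 16L)
  tiff::writeTIFF(field$nucleus_mask / 65535,
                  file.path(dir, "nucleus_mask.tiff"), bits.per.sample = 16L)
  jsonlite::write_json(field$meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_image_stack
#' @export
read_image_stack <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  for (f in c("pixel_size_nm", "z_spacing_nm")) meta[[f]] <- as.numeric(meta[[f]])
  for (f in c("fov_px", "n_z")) meta[[f]] <- as.integer(meta[[f]])
  channels <- meta$channels
  read_pages <- function(path) {
    pg <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pg)) pg <- list(pg)
    lapply(pg, function(m) round(m * 65535))
  }
  first <- read_pages(file.path(dir, paste0(channels[1], ".tiff")))
  ny <- nrow(first[[1]]); nx <- ncol(first[[1]]); nz <- length(first)
  stack <- array(0, dim = c(ny, nx, nz, length(channels)),
                 dimnames = list(NULL, NULL, NULL, channels))
  for (ch in channels) {
    pages <- read_pages(file.path(dir, paste0(ch, ".tiff")))
    for (z in seq_along(pages)) stack[, , z, ch] <- pages[[z]]
  }
  cm <- round(tiff::readTIFF(file.path(dir, "cell_mask.tiff")) * 65535)
  nm <- round(tiff::readTIFF(file.path(dir, "nucleus_mask.tiff")) * 65535)
  structure(list(stack = stack, channels = channels,
                 cell_mask = matrix(as.integer(cm), nrow(cm), ncol(cm)),
                 nucleus_mask = matrix(as.integer(nm), nrow(nm), ncol(nm)),
                 meta = meta),
            class = "nl_image_stack")
}

#' Simulate qPCR Ct values from mean expression
#'
#' Standard-curve model: `Ct = intercept - slope * log10(mean copies)` plus
#' Gaussian replicate noise. Feeds [fold_change_ddct()].
#'
#' @param expression tibble with `sample_id`, `gene_id`, `mean_copies`.
#' @param config [simulation_config()] (supplies curve and noise parameters).
#' @param n_replicates technical replicates per sample/gene.
#' @param seed RNG seed.
#' @return Ct tibble: `sample_id`, `gene_id`, `replicate`, `ct`.
#' @export
simulate_qpcr <- function(expression, config = simulation_config(),
                          n_replicates = 3L, seed = NULL) {
  stopifnot(all(c("sample_id", "gene_id", "mean_copies") %in% names(expression)),
            all(expression$mean_copies > 0))
  with_seed(seed, {
    expression |>
      tidyr::expand_grid(replicate = seq_len(n_replicates)) |>
      dplyr::mutate(
        ct = config$qpcr_intercept -
          config$qpcr_slope * log10(.data$mean_copies) +
          stats::rnorm(dplyr::n(), 0, config$qpcr_noise_sd)
      ) |>
      dplyr::select("sample_id", "gene_id", "replicate", "ct")
  })
}
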