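# Shared fixtures: everything is generated in code at test time.

rand_rna <- function(len, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "U"), len, replace = TRUE), collapse = "")
}

rand_targets <- function(n, len, seed = 1) {
  set.seed(seed)
  target_transcripts(paste0("tx", seq_len(n)),
                     vapply(seq_len(n), function(i) rand_rna(len), ""))
}

# Independent nested-loop oracle for R-Y cleavage junctions.
brute_cleavage_positions <- function(sequence) {
  ch <- strsplit(sequence, "", fixed = TRUE)[[1]]
  out <- integer(0)
  if (length(ch) >= 2) {
    for (i in seq_len(length(ch) - 1)) {
      if (ch[i] %in% c("A", "G") && ch[i + 1] %in% c("U", "C")) {
        out <- c(out, i - 1L)  # 0-based purine index
      }
    }
  }
  out
}

hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# A small nine-plex experiment used by several decoder/quantify tests.
nine_plex <- function(n_cells, seed, config = NULL) {
  cfg <- channel_config(2, 3)
  cb <- assign_codebook(default_gene_panel()$gene_id, cfg)
  sc <- config %||% simulation_config(n_cells = n_cells)
  tr <- simulate_ground_truth(cb, sc, seed = seed)
  ph <- simulate_spot_intensities(tr$amplicons, cb, sc, seed = seed + 1000L)
  list(codebook = cb, config = sc, truth = tr, photometry = ph)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

noiseless_config <- function(n_cells = 20) {
  simulation_config(n_cells = n_cells, h_dfp = 1, h_rfp = 1,
                    shot_noise = FALSE, read_noise_sd = 0, lambda_ns = 0)
}

# Plant well-separated Gaussian blobs on a plane; returns plane + truth.
plant_blobs <- function(n_side = 5, spacing = 12, sigma = 2, amp = 500,
                        size = 64, offset = 8) {
  plane <- matrix(0, size, size)
  xs <- ys <- numeric(0)
  grid <- seq(offset, by = spacing, length.out = n_side)
  for (gy in grid) for (gx in grid) {
    xs <- c(xs, gx); ys <- c(ys, gy)
  }
  for (k in seq_along(xs)) {
    rr <- max(1, round(ys[k]) - 6):min(size, round(ys[k]) + 6)
    cc <- max(1, round(xs[k]) - 6):min(size, round(xs[k]) + 6)
    for (r in rr) for (c in cc) {
      plane[r, c] <- plane[r, c] +
        amp * exp(-((r - ys[k])^2 + (c - xs[k])^2) / (2 * sigma^2))
    }
  }
  list(plane = plane, x = xs, y = ys)
}
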