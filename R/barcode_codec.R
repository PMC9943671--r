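#' Virtual-channel configuration
#'
#' Describes the encoding space of the fluorescent nanoladders: `channels`
#' detection spectral channels, each carrying 1..`levels` tandem repeats of
#' its detection fluorescent probe (DFP) binding site per amplicon unit, plus
#' one reference channel. Levels start at 1 so every spot is detectable in
#' every channel; capacity per imaging round is `levels ^ channels`.
#'
#' @param channels number of detection spectral channels (C >= 1).
#' @param levels maximum repeat count of the DFP sequence per channel
#'   (R >= 1).
#' @param channel_names labels for the detection channels; default
#'   `De1..DeC`.
#' @param reference_channel label of the reference channel (default `"Re"`).
#' @param brightness relative brightness factor per detection channel
#'   (all > 0).
#' @param ref_brightness relative brightness of the reference fluorophore.
#' @param norm_level level used to normalize theoretical ratios; defaults to
#'   the design maximum `levels` (set to 10 for the 1..10 single-channel
#'   ladder).
#' @param dfp_length DFP length in nt (default 20).
#' @return A list of class `nl_channel_config`.
#' @examples
#' channel_config(channels = 2, levels = 3)   # the nine-plex design
#' @export
channel_config <- function(channels = 2L, levels = 3L,
                           channel_names = paste0("De", seq_len(channels)),
                           reference_channel = "Re",
                           brightness = rep(1, channels), ref_brightness = 1,
                           norm_level = levels, dfp_length = 20L) {
  channels <- as.integer(channels); levels <- as.integer(levels)
  stopifnot(channels >= 1L, levels >= 1L, length(channel_names) == channels,
            length(brightness) == channels, all(brightness > 0),
            ref_brightness > 0, norm_level >= 1)
  structure(list(channels = channels, levels = levels,
                 channel_names = channel_names,
                 reference_channel = reference_channel,
                 brightness = stats::setNames(as.numeric(brightness), channel_names),
                 ref_brightness = as.numeric(ref_brightness),
                 norm_level = as.numeric(norm_level),
                 dfp_length = as.integer(dfp_length)),
            class = "nl_channel_config")
}

#' @export
print.nl_channel_config <- function(x, ...) {
  cat("<virtual-channel config> ", x$channels, " detection channel(s) x ",
      x$levels, " repeat level(s) = ", capacity(x, 1L),
      " codes/round (reference: ", x$reference_channel, ")\n", sep = "")
  invisible(x)
}

level_cols <- function(config) paste0("level_", config$channel_names)

#' Enumerate all virtual codes of a design
#'
#' @param config [channel_config()].
#' @return A tibble of `levels ^ channels` rows, lexicographically ordered,
#'   with `code_id`, one `level_<channel>` column per detection channel, and
#'   a `code_label` like `"2-3"`.
#' @export
enumerate_codes <- function(config) {
  stopifnot(inherits(config, "nl_channel_config"))
  grid <- do.call(expand.grid,
                  c(rev(stats::setNames(rep(list(seq_len(config$levels)),
                                            config$channels),
                                        level_cols(config))),
                    KEEP.OUT.ATTRS = FALSE))
  grid <- tibble::as_tibble(grid)[, level_cols(config), drop = FALSE]
  grid <- dplyr::mutate(grid, dplyr::across(dplyr::everything(), as.integer))
  tibble::tibble(code_id = seq_len(nrow(grid)),
                 grid,
                 code_label = apply(grid, 1L, paste, collapse = "-"))
}

#' Theoretical detection/reference intensity ratios of codes
#'
#' The expected ratio in channel c is
#' `level_c * brightness_c / (norm_level * ref_brightness)`: the amplicon
#' repeat count cancels between numerator and denominator, which is the point
#' of the reference channel. For the single-channel 1..10 ladder normalized
#' to its largest barcode, the 1-DFP barcode has ratio 0.1.
#'
#' @param codes tibble from [enumerate_codes()] (or any tibble with the
#'   design's `level_*` columns).
#' @param config [channel_config()].
#' @return `codes` with one `ratio_<channel>` column added per detection
#'   channel.
#' @export
theoretical_ratio <- function(codes, config) {
  stopifnot(inherits(config, "nl_channel_config"))
  for (ch in config$channel_names) {
    codes[[paste0("ratio_", ch)]] <-
      codes[[paste0("level_", ch)]] * config$brightness[[ch]] /
      (config$norm_level * config$ref_brightness)
  }
  codes
}

#' Multiplexing capacity
#'
#' Number of transcripts addressable with `n_rounds` sequential imaging
#' rounds of the design: `n_rounds * levels ^ channels`.
#'
#' @param config [channel_config()].
#' @param n_rounds number of hybridize/image/strip rounds (>= 1).
#' @return integer capacity.
#' @examples
#' capacity(channel_config(2, 3), n_rounds = 2)  # 18
#' @export
capacity <- function(config, n_rounds = 1L) {
  stopifnot(inherits(config, "nl_channel_config"), n_rounds >= 1L)
  as.integer(n_rounds) * config$levels^config$channels
}

#' Assign virtual codes to transcripts
#'
#' Deterministic injective assignment: transcripts in input order receive
#' codes in lexicographic order. Errors if the design's single-round capacity
#' is exceeded, stating the required increase.
#'
#' @param transcript_ids character vector of transcript labels.
#' @param config [channel_config()].
#' @return A tibble of class `nl_codebook`: `transcript_id`, `code_id`,
#'   `level_*` columns, `code_label`, `round_index` (0). The config is kept
#'   in the `"config"` attribute.
#' @export
assign_codebook <- function(transcript_ids, config = channel_config()) {
  stopifnot(!anyDuplicated(transcript_ids))
  cap <- capacity(config, 1L)
  n <- length(transcript_ids)
  if (n > cap) {
    need_r <- ceiling(n^(1 / config$channels))
    need_c <- ceiling(log(n) / log(max(config$levels, 2L)))
    stop(sprintf(paste0("%d transcripts exceed the single-round capacity %d; ",
                        "increase levels to >= %d or channels to >= %d"),
                 n, cap, need_r, need_c), call. = FALSE)
  }
  codes <- enumerate_codes(config)[seq_len(n), ]
  out <- tibble::tibble(transcript_id = as.character(transcript_ids),
                        codes, round_index = 0L)
  attr(out, "config") <- config
  class(out) <- c("nl_codebook", class(out))
  out
}

#' Branched-barcode build sheet for a codebook
#'
#' Per transcript and detection channel, the DFP repeat count the branched
#' barcode must carry (equal to the code level), the DFP length, and the
#' presence of the reference fluorescent probe site.
#'
#' @param codebook [assign_codebook()] result.
#' @return long tibble: `transcript_id`, `channel`, `dfp_repeats`,
#'   `dfp_length_nt`, `rfp_present`.
#' @export
barcode_spec <- function(codebook) {
  config <- codebook_config(codebook)
  codebook |>
    tibble::as_tibble() |>
    dplyr::select("transcript_id", dplyr::starts_with("level_")) |>
    tidyr::pivot_longer(dplyr::starts_with("level_"),
                        names_to = "channel", values_to = "dfp_repeats",
                        names_prefix = "level_") |>
    dplyr::mutate(dfp_length_nt = config$dfp_length, rfp_present = TRUE)
}

codebook_config <- function(codebook) {
  config <- attr(codebook, "config")
  if (is.null(config)) stop("codebook carries no channel config", call. = FALSE)
  config
}

#' Write / read a codebook as versioned JSON
#'
#' The on-disk schema (version 1) stores the channel config and the
#' transcript -> level-vector map; reading it back reproduces the codebook
#' exactly.
#'
#' @param codebook [assign_codebook()] result.
#' @param path JSON file path.
#' @return `write_codebook()`: `path` invisibly; `read_codebook()`: the
#'   codebook tibble.
#' @export
write_codebook <- function(codebook, path) {
  config <- codebook_config(codebook)
  lv <- as.matrix(tibble::as_tibble(codebook)[, level_cols(config), drop = FALSE])
  obj <- list(
    schema_version = 1L,
    channels = config$channels, levels = config$levels,
    channel_names = config$channel_names,
    reference_channel = config$reference_channel,
    brightness = unname(config$brightness),
    ref_brightness = config$ref_brightness,
    norm_level = config$norm_level, dfp_length = config$dfp_length,
    transcripts = purrr::map2(codebook$transcript_id,
                              seq_len(nrow(codebook)),
                              function(id, i) list(id = id,
                                                   levels = unname(lv[i, ]),
                                                   round_index = codebook$round_index[i]))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_codebook
#' @export
read_codebook <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(as.integer(obj$schema_version), 1L)) {
    stop("unsupported codebook schema version", call. = FALSE)
  }
  config <- channel_config(channels = obj$channels, levels = obj$levels,
                           channel_names = unlist(obj$channel_names),
                           reference_channel = obj$reference_channel,
                           brightness = unlist(obj$brightness),
                           ref_brightness = obj$ref_brightness,
                           norm_level = obj$norm_level,
                           dfp_length = obj$dfp_length)
  ids <- vapply(obj$transcripts, `[[`, character(1), "id")
  cb <- assign_codebook(ids, config)
  # restore stored levels/rounds verbatim (robust to future non-sequential maps)
  lv <- t(vapply(obj$transcripts, function(t) as.integer(unlist(t$levels)),
                 integer(config$channels)))
  for (j in seq_len(config$channels)) cb[[level_cols(config)[j]]] <- lv[, j]
  cb$code_label <- apply(lv, 1L, paste, collapse = "-")
  cb$round_index <- vapply(obj$transcripts, function(t) as.integer(t$round_index),
                           integer(1))
  cb
}
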