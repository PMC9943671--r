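#' Assemble a table of target transcripts
#'
#' Builds the tibble of target RNAs every design function consumes. Sequences
#' are uppercased and restricted to the RNA alphabet; `T` is converted to `U`
#' with a warning so DNA-style input is accepted.
#'
#' @param id character vector of transcript labels.
#' @param sequence character vector of RNA sequences (5'->3').
#' @return A tibble with columns `id` and `sequence`.
#' @examples
#' target_transcripts("GAPDH-frag", "AUGGGGAAGGUGAAGGUCGGAGUCAACGGAUUUGGUCGU")
#' @export
target_transcripts <- function(id, sequence) {
  stopifnot(length(id) == length(sequence), !anyDuplicated(id))
  sequence <- toupper(sequence)
  if (any(nchar(sequence) == 0L)) {
    stop("empty target sequence", call. = FALSE)
  }
  if (any(grepl("T", sequence, fixed = TRUE))) {
    warning("'T' found in target sequence(s); converting to 'U'", call. = FALSE)
    sequence <- chartr("T", "U", sequence)
  }
  bad <- grepl("[^ACGU]", sequence)
  if (any(bad)) {
    stop("invalid characters in target sequence(s): ",
         paste(id[bad], collapse = ", "), call. = FALSE)
  }
  tibble::tibble(id = as.character(id), sequence = sequence)
}

#' Read target transcripts from a FASTA file
#'
#' @param path path to a FASTA file of target RNA (or DNA-alphabet) sequences.
#' @return A tibble as produced by [target_transcripts()].
#' @export
read_targets <- function(path) {
  set <- Biostrings::readBStringSet(path)
  target_transcripts(names(set), as.character(set))
}

#' Probe design configuration
#'
#' Collects the tunables of circular DNAzyme probe design. The default
#' catalytic core is the canonical 10-23 DNAzyme core; any core sequence can
#' be supplied. Junction preference follows the usual 10-23 ranking
#' AU > GU > AC > GC.
#'
#' @param arm_len recognition arm length in nt (each arm; default 20).
#' @param ref_len reference-region length in nt (default 20).
#' @param anchor_len barcode-anchor length in nt (default 20).
#' @param catalytic_core DNA sequence of the catalytic core.
#' @param spacer inert spacer placed between circle segments.
#' @param junction_rank preferred cleavable dinucleotides, best first.
#' @param critical_window half-width (nt) of the junction window in which a
#'   mismatch is assumed to abolish cleavage.
#' @param gc_range,max_homopolymer,ortho_k orthogonal-pool rejection-sampling
#'   constraints: GC fraction bounds, longest allowed homopolymer, and the
#'   k-mer size that must not be shared with any target.
#' @param seed seed for the orthogonal-sequence pool.
#' @return A list of class `nl_probe_config`.
#' @export
probe_config <- function(arm_len = 20L, ref_len = 20L, anchor_len = 20L,
                         catalytic_core = "GGCTAGCTACAACGA",
                         spacer = "TT",
                         junction_rank = c("AU", "GU", "AC", "GC"),
                         critical_window = 8L,
                         gc_range = c(0.4, 0.6), max_homopolymer = 4L,
                         ortho_k = 10L, seed = 1L) {
  stopifnot(arm_len >= 1L, ref_len >= 1L, anchor_len >= 1L,
            nchar(catalytic_core) >= 1L,
            all(junction_rank %in% c("AU", "GU", "AC", "GC")))
  structure(list(
    arm_len = as.integer(arm_len), ref_len = as.integer(ref_len),
    anchor_len = as.integer(anchor_len),
    catalytic_core = toupper(catalytic_core), spacer = toupper(spacer),
    junction_rank = junction_rank,
    critical_window = as.integer(critical_window),
    gc_range = gc_range, max_homopolymer = as.integer(max_homopolymer),
    ortho_k = as.integer(ortho_k), seed = seed
  ), class = "nl_probe_config")
}

#' Find candidate DNAzyme cleavage sites
#'
#' Scans each target for purine-pyrimidine (R-Y) dinucleotide junctions, the
#' sites a 10-23-style DNAzyme can cleave. `position` is the 0-based index of
#' the purine; `flank_ok` records whether at least `arm_len` nt exist on each
#' side of the junction (the upstream window ends at the purine, the
#' downstream window starts at the pyrimidine).
#'
#' @param targets tibble from [target_transcripts()].
#' @param arm_len recognition arm length used for the flank check.
#' @return A tibble with columns `target_id`, `position`, `dinucleotide`,
#'   `flank_ok`, and `rank` (preference order AU > GU > AC > GC), sorted by
#'   target then position.
#' @export
find_cleavage_sites <- function(targets, arm_len = 20L) {
  stopifnot(is.data.frame(targets), arm_len >= 1L)
  if (!all(c("id", "sequence") %in% names(targets))) {
    targets <- target_transcripts(targets[[1]], targets[[2]])
  }
  rank_map <- c(AU = 1L, GU = 2L, AC = 3L, GC = 4L)
  purrr::pmap_dfr(targets, function(id, sequence, ...) {
    n <- nchar(sequence)
    if (n < 2L) {
      return(tibble::tibble(target_id = character(0), position = integer(0),
                            dinucleotide = character(0), flank_ok = logical(0),
                            rank = integer(0)))
    }
    ch <- strsplit(sequence, "", fixed = TRUE)[[1]]
    pos <- which(is_purine(ch[-n]) & is_pyrimidine(ch[-1])) - 1L  # 0-based
    dinuc <- paste0(ch[pos + 1L], ch[pos + 2L])
    tibble::tibble(
      target_id = id,
      position = pos,
      dinucleotide = dinuc,
      flank_ok = (pos + 1L >= arm_len) & (n - pos - 1L >= arm_len),
      rank = unname(rank_map[dinuc])
    )
  })
}

# 0-based half-open windows flanking the junction of a site.
# upstream: [position - arm_len + 1, position + 1); downstream:
# [position + 1, position + 1 + arm_len). Returned 1-based for substr().
site_windows <- function(position, arm_len) {
  list(up_start = position - arm_len + 2L, up_end = position + 1L,
       dn_start = position + 2L, dn_end = position + 1L + arm_len)
}

# RNA window covered by both arms (2 * arm_len nt centred on the junction).
recognition_window <- function(sequence, position, arm_len) {
  w <- site_windows(position, arm_len)
  substr(sequence, w$up_start, w$dn_end)
}

#' Generate a pool of orthogonal DNA sequences
#'
#' Rejection sampling of sequences with constrained GC content, no long
#' homopolymer, and no shared k-mer with any target (either strand) or with a
#' previously accepted pool member. Used for reference regions and barcode
#' anchors.
#'
#' @param n number of sequences.
#' @param len sequence length (nt).
#' @param targets tibble of target transcripts to stay orthogonal to.
#' @param config [probe_config()].
#' @param seed RNG seed (default taken from `config`).
#' @return character vector of DNA sequences.
#' @export
orthogonal_pool <- function(n, len, targets, config = probe_config(),
                            seed = config$seed) {
  forbidden <- character(0)
  if (!is.null(targets) && nrow(targets) > 0L) {
    tdna <- rna_to_dna(targets$sequence)
    forbidden <- unlist(lapply(c(tdna, rc_dna(tdna)), kmers, k = config$ortho_k))
  }
  forbidden <- unique(forbidden)
  with_seed(seed, {
    out <- character(0)
    tries <- 0L
    while (length(out) < n) {
      tries <- tries + 1L
      if (tries > 50000L) stop("orthogonal pool sampling failed to converge")
      cand <- random_seq(1L, len)
      gc <- gc_fraction(cand)
      if (gc < config$gc_range[1] || gc > config$gc_range[2]) next
      if (max_homopolymer(cand) > config$max_homopolymer) next
      km <- c(kmers(cand, config$ortho_k), kmers(rc_dna(cand), config$ortho_k))
      if (any(km %in% forbidden)) next
      forbidden <- c(forbidden, km)
      out <- c(out, cand)
    }
    out
  })
}

#' Design circular DNAzyme probes
#'
#' Builds one circular DNAzyme probe per cleavage site: two recognition arms
#' (reverse complements of the target windows flanking the junction), the
#' catalytic core between them, and a reference region plus barcode anchor
#' drawn from an orthogonal sequence pool. The circle is stored linearized at
#' an arbitrary origin; positions are to be read modulo its length.
#'
#' @param targets tibble from [target_transcripts()].
#' @param sites tibble of cleavage sites (subset of [find_cleavage_sites()]
#'   rows with `flank_ok = TRUE`), one row per probe to design.
#' @param config [probe_config()].
#' @return A tibble with one row per probe: ids, site, component sequences,
#'   `circle_sequence`, and `kind = "matched"`.
#' @export
design_circular_dnazyme <- function(targets, sites, config = probe_config()) {
  stopifnot(is.data.frame(sites), nrow(sites) >= 1L)
  if (!all(sites$flank_ok)) stop("flank too short for arm length", call. = FALSE)
  a <- config$arm_len
  pool <- orthogonal_pool(2L * nrow(sites), max(config$ref_len, config$anchor_len),
                          targets, config)
  refs <- substr(pool[seq_len(nrow(sites))], 1L, config$ref_len)
  anchors <- substr(pool[nrow(sites) + seq_len(nrow(sites))], 1L, config$anchor_len)

  rows <- purrr::pmap(list(sites$target_id, sites$position, seq_len(nrow(sites))),
                      function(tid, pos, i) {
    seq <- targets$sequence[match(tid, targets$id)]
    if (is.na(seq)) stop("site refers to unknown target: ", tid, call. = FALSE)
    w <- site_windows(pos, a)
    up <- substr(seq, w$up_start, w$up_end)
    dn <- substr(seq, w$dn_start, w$dn_end)
    # probe 5' arm pairs with the downstream (3') target flank, 3' arm with
    # the upstream flank (antiparallel duplex)
    arm_5p <- arm_for_rna(dn)
    arm_3p <- arm_for_rna(up)
    circle <- paste0(arm_5p, config$catalytic_core, arm_3p, config$spacer,
                     refs[i], config$spacer, anchors[i], config$spacer)
    tibble::tibble(
      target_id = tid, site_position = pos,
      dinucleotide = paste0(substr(seq, pos + 1L, pos + 1L),
                            substr(seq, pos + 2L, pos + 2L)),
      arm_5p = arm_5p, arm_3p = arm_3p,
      catalytic_core = config$catalytic_core,
      reference_region = refs[i], barcode_anchor = anchors[i],
      spacer = config$spacer,
      recognition_target = paste0(up, dn),
      circle_sequence = circle,
      kind = "matched"
    )
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "config") <- config
  out
}

#' Design probes end-to-end, one per target
#'
#' Convenience wrapper: finds cleavage sites, keeps those with sufficient
#' flanks, ranks them by junction preference (AU > GU > AC > GC, then
#' centrality), and designs one probe per target at the best site.
#'
#' @inheritParams design_circular_dnazyme
#' @return probe tibble as from [design_circular_dnazyme()].
#' @export
design_probes <- function(targets, config = probe_config()) {
  sites <- find_cleavage_sites(targets, config$arm_len)
  sites <- dplyr::filter(sites, .data$flank_ok)
  if (nrow(sites) == 0L) stop("no usable cleavage site in any target", call. = FALSE)
  lens <- stats::setNames(nchar(targets$sequence), targets$id)
  best <- sites |>
    dplyr::mutate(centrality = abs(.data$position - lens[.data$target_id] / 2)) |>
    dplyr::group_by(.data$target_id) |>
    dplyr::arrange(.data$rank, .data$centrality, .by_group = TRUE) |>
    dplyr::slice(1L) |>
    dplyr::ungroup()
  missing <- setdiff(targets$id, best$target_id)
  if (length(missing) > 0L) {
    stop("no flank-compatible cleavage site for: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  design_circular_dnazyme(targets, best[match(targets$id, best$target_id), ],
                          config)
}

# Deterministic mismatch substitution (swap within chemical class so the
# result is never the original base): A<->C, G<->U (RNA) / G<->T (DNA).
mismatch_base <- function(base, rna = TRUE) {
  map <- if (rna) c(A = "C", C = "A", G = "U", U = "G")
         else c(A = "C", C = "A", G = "T", T = "G")
  unname(map[base])
}

mutate_positions <- function(seq, pos0, rna = TRUE) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  ch[pos0 + 1L] <- mismatch_base(ch[pos0 + 1L], rna = rna)
  paste(ch, collapse = "")
}

# Evenly spread 0-based mismatch positions over a region of length len.
spread_positions <- function(n_mm, len) {
  unique(as.integer(floor((seq_len(n_mm) - 0.5) / n_mm * len)))
}

#' Make a control variant of a target or probe
#'
#' Emits the negative-control constructs used to demonstrate specificity:
#' `SNV` substitutes the single central base of the recognition region,
#' `MM12` substitutes 12 bases spread evenly across it, `random` replaces it
#' with a GC-matched sequence sharing no 10-mer with the original, and
#' `core_deleted` (probes only) replaces the catalytic core by an inert
#' spacer of equal length. Substitutions are deterministic; only `random`
#' uses the seed.
#'
#' @param x a target tibble ([target_transcripts()]) or a probe tibble
#'   ([design_circular_dnazyme()]). One row.
#' @param kind one of `"SNV"`, `"MM12"`, `"random"`, `"core_deleted"`.
#' @param seed RNG seed for `kind = "random"`.
#' @param site 0-based cleavage position (required for target input, ignored
#'   for probes which carry their site).
#' @param arm_len arm length framing the recognition region for target input.
#' @return A tibble of the same type as `x` with a `kind` column.
#' @export
make_control_variant <- function(x, kind = c("SNV", "MM12", "random", "core_deleted"),
                                 seed = NULL, site = NULL, arm_len = 20L) {
  kind <- match.arg(kind)
  stopifnot(is.data.frame(x), nrow(x) == 1L)
  is_probe <- "circle_sequence" %in% names(x)
  if (!is_probe && kind == "core_deleted") {
    stop("core_deleted applies to probes only", call. = FALSE)
  }

  if (is_probe) {
    if (kind == "core_deleted") {
      out <- x
      inert <- paste(rep("T", nchar(x$catalytic_core)), collapse = "")
      out$circle_sequence <- sub(x$catalytic_core, inert, x$circle_sequence,
                                 fixed = TRUE)
      out$catalytic_core <- inert
      out$kind <- "core_deleted"
      return(out)
    }
    region <- x$recognition_target  # RNA window the arms pair with
    new_region <- variant_region(region, kind, seed, rna = TRUE)
    a <- nchar(region) %/% 2L
    up <- substr(new_region, 1L, a)
    dn <- substr(new_region, a + 1L, nchar(new_region))
    out <- x
    new_5p <- arm_for_rna(dn)
    new_3p <- arm_for_rna(up)
    out$circle_sequence <- sub(x$arm_5p, new_5p, out$circle_sequence, fixed = TRUE)
    out$circle_sequence <- sub(x$arm_3p, new_3p, out$circle_sequence, fixed = TRUE)
    out$arm_5p <- new_5p
    out$arm_3p <- new_3p
    out$recognition_target <- new_region
    out$kind <- kind
    return(out)
  }

  if (is.null(site)) stop("'site' is required for target variants", call. = FALSE)
  seq <- x$sequence
  w <- site_windows(site, arm_len)
  region <- substr(seq, w$up_start, w$dn_end)
  new_region <- variant_region(region, kind, seed, rna = TRUE)
  out <- x
  out$sequence <- paste0(substr(seq, 1L, w$up_start - 1L), new_region,
                         substr(seq, w$dn_end + 1L, nchar(seq)))
  out$id <- paste0(x$id, "_", kind)
  out$kind <- kind
  out
}

variant_region <- function(region, kind, seed, rna = TRUE) {
  len <- nchar(region)
  if (kind == "SNV") {
    return(mutate_positions(region, len %/% 2L, rna = rna))
  }
  if (kind == "MM12") {
    if (len < 12L) stop("recognition region shorter than 12 nt", call. = FALSE)
    return(mutate_positions(region, spread_positions(12L, len), rna = rna))
  }
  # random: same length, GC within 5%, no shared 10-mer with the original
  alphabet <- if (rna) c("A", "C", "G", "U") else c("A", "C", "G", "T")
  orig_km <- unique(kmers(region, 10L))
  gc0 <- gc_fraction(region)
  with_seed(seed, {
    for (i in seq_len(20000L)) {
      cand <- paste(sample(alphabet, len, replace = TRUE), collapse = "")
      if (abs(gc_fraction(cand) - gc0) > 0.05) next
      if (any(kmers(cand, 10L) %in% orig_km)) next
      return(cand)
    }
    stop("random variant sampling failed to converge", call. = FALSE)
  })
}

#' Screen probe specificity against background sequences
#'
#' Slides the probe's intended recognition window along each background
#' sequence and reports, per background record, the longest contiguous
#' complementarity of each arm, the total matched nt at the best full-window
#' alignment, and whether any alignment is predicted cleavage-competent: an
#' R-Y junction with no mismatch within `critical_window` nt on either side.
#'
#' @param probe one-row probe tibble.
#' @param background tibble of background transcripts ([target_transcripts()]).
#' @param critical_window half-width (nt) of the junction-critical window.
#' @return A tibble with one row per background sequence:
#'   `off_target_id`, `max_contig_arm5`, `max_contig_arm3`, `total_matched`,
#'   `predicted_cleavage_competent`. Empty background gives an empty report.
#' @export
screen_specificity <- function(probe, background, critical_window = 8L) {
  stopifnot(is.data.frame(probe), nrow(probe) == 1L)
  if (is.null(background) || nrow(background) == 0L) {
    return(tibble::tibble(off_target_id = character(0),
                          max_contig_arm5 = integer(0),
                          max_contig_arm3 = integer(0),
                          total_matched = integer(0),
                          predicted_cleavage_competent = logical(0)))
  }
  w <- probe$recognition_target             # RNA window the probe pairs with
  a <- nchar(w) %/% 2L
  wch <- strsplit(w, "", fixed = TRUE)[[1]]

  purrr::pmap_dfr(background, function(id, sequence, ...) {
    sch <- strsplit(sequence, "", fixed = TRUE)[[1]]
    n <- length(sch)
    best_total <- 0L; best5 <- 0L; best3 <- 0L; competent <- FALSE
    if (n >= 2L * a) {
      for (j in 0:(n - 2L * a)) {
        m <- sch[j + seq_len(2L * a)] == wch
        runs <- rle(m)
        run3 <- rle(m[seq_len(a)])          # upstream half (3' arm)
        run5 <- rle(m[a + seq_len(a)])      # downstream half (5' arm)
        c3 <- max(c(0L, run3$lengths[run3$values]))
        c5 <- max(c(0L, run5$lengths[run5$values]))
        best3 <- max(best3, c3)
        best5 <- max(best5, c5)
        best_total <- max(best_total, sum(m))
        junction_ry <- is_purine(sch[j + a]) && is_pyrimidine(sch[j + a + 1L])
        crit <- seq.int(a - critical_window + 1L, a + critical_window)
        crit <- crit[crit >= 1L & crit <= 2L * a]
        if (junction_ry && all(m[crit])) competent <- TRUE
      }
    } else {
      # background shorter than the recognition window: per-arm scan only
      for (arm_idx in list(seq_len(a), a + seq_len(a))) {
        alen <- length(arm_idx)
        if (n >= 1L) {
          for (j in 0:max(0L, n - alen)) {
            k <- min(alen, n - j)
            m <- sch[j + seq_len(k)] == wch[arm_idx[seq_len(k)]]
            r <- rle(m)
            cc <- max(c(0L, r$lengths[r$values]))
            if (identical(arm_idx[1], 1L)) best3 <- max(best3, cc)
            else best5 <- max(best5, cc)
          }
        }
      }
    }
    tibble::tibble(off_target_id = id,
                   max_contig_arm5 = best5, max_contig_arm3 = best3,
                   total_matched = best_total,
                   predicted_cleavage_competent = competent)
  })
}

#' Linearize a circular probe into a padlock + ligation linker
#'
#' Rotates the circle so the nick falls inside the catalytic core (the probe
#' is later re-circularized by hybridization to the linker and ligation).
#' The linker is the reverse complement of the 10 nt on each side of the
#' nick, so the padlock's 3' and 5' termini abut on it.
#'
#' @param probes probe tibble.
#' @return The probe tibble with added `padlock` and `linker` columns.
#' @export
emit_padlock_linker <- function(probes) {
  stopifnot(is.data.frame(probes), "circle_sequence" %in% names(probes))
  out <- probes
  res <- purrr::pmap(probes, function(arm_5p, catalytic_core, circle_sequence, ...) {
    nick <- nchar(arm_5p) + nchar(catalytic_core) %/% 2L  # 0-based, inside core
    L <- nchar(circle_sequence)
    padlock <- paste0(substr(circle_sequence, nick + 1L, L),
                      substr(circle_sequence, 1L, nick))
    junction <- paste0(substr(padlock, L - 9L, L), substr(padlock, 1L, 10L))
    list(padlock = padlock, linker = rc_dna(junction))
  })
  out$padlock <- vapply(res, `[[`, character(1), "padlock")
  out$linker <- vapply(res, `[[`, character(1), "linker")
  out
}

#' Write the probe sheet as TSV
#'
#' One row per probe component, 5'->3' sequences, ready for ordering review.
#' @param probes probe tibble (optionally after [emit_padlock_linker()]).
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_probe_sheet <- function(probes, path) {
  long <- probes |>
    dplyr::select(dplyr::any_of(c("target_id", "kind", "arm_5p", "catalytic_core",
                                  "arm_3p", "reference_region", "barcode_anchor",
                                  "padlock", "linker"))) |>
    tidyr::pivot_longer(-dplyr::all_of(c("target_id", "kind")),
                        names_to = "component", values_to = "sequence_5to3")
  readr::write_tsv(long, path)
  invisible(path)
}

#' Write padlock and linker oligos as FASTA
#'
#' @param probes probe tibble after [emit_padlock_linker()].
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_probe_fasta <- function(probes, path) {
  stopifnot(all(c("padlock", "linker") %in% names(probes)))
  seqs <- c(probes$padlock, probes$linker)
  names(seqs) <- c(paste0(probes$target_id, "_padlock"),
                   paste0(probes$target_id, "_linker"))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}
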