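test_that("target validation restricts the alphabet and converts T to U", {
  expect_warning(tg <- target_transcripts("a", "ACGT"), "converting")
  expect_equal(tg$sequence, "ACGU")
  expect_error(target_transcripts("a", ""), "empty")
  expect_error(target_transcripts("a", "ACGX"), "invalid")
})

test_that("cleavage-site finding obeys the purine-pyrimidine rule", {
  # no R-Y junction exists in a pyrimidine-only sequence
  py <- target_transcripts("py", strrep("UUUUCCCC", 6))
  expect_equal(nrow(find_cleavage_sites(py)), 0L)

  # a single G followed by U between A-free flanks gives exactly one site
  one <- target_transcripts("one", paste0(strrep("C", 20), "GU", strrep("C", 20)))
  sites <- find_cleavage_sites(one, arm_len = 20)
  expect_equal(nrow(sites), 1L)
  expect_equal(sites$position, 20L)
  expect_equal(sites$dinucleotide, "GU")
  expect_true(sites$flank_ok)
})

test_that("site scan matches the brute-force oracle on random sequences", {
  set.seed(42)
  for (i in 1:25) {
    seq <- rand_rna(200)
    got <- find_cleavage_sites(target_transcripts("t", seq), arm_len = 20)
    expect_equal(got$position, brute_cleavage_positions(seq))
    # every reported dinucleotide satisfies R-Y
    expect_true(all(substr(got$dinucleotide, 1, 1) %in% c("A", "G")))
    expect_true(all(substr(got$dinucleotide, 2, 2) %in% c("U", "C")))
    # flank rule
    expect_equal(got$flank_ok,
                 got$position + 1L >= 20L & 200L - got$position - 1L >= 20L)
    # sorted by position
    expect_false(is.unsorted(got$position))
  }
})

test_that("site counts equal the brute-force scan across many seeded sequences", {
  set.seed(7)
  n_match <- 0L
  for (i in 1:1000) {
    seq <- rand_rna(60)
    got <- find_cleavage_sites(target_transcripts("t", seq), arm_len = 5)
    if (identical(got$position, brute_cleavage_positions(seq))) {
      n_match <- n_match + 1L
    }
  }
  expect_equal(n_match, 1000L)
})

test_that("probe architecture matches the design: 20-nt arms and reference region", {
  tg <- rand_targets(2, 150, seed = 5)
  probes <- design_probes(tg)
  expect_equal(nchar(probes$arm_5p), c(20L, 20L))
  expect_equal(nchar(probes$arm_3p), c(20L, 20L))
  expect_equal(nchar(probes$reference_region), c(20L, 20L))
  expect_equal(probes$kind, c("matched", "matched"))

  # arms reverse-complement the flanking target windows (involution check)
  p <- probes[1, ]
  seq <- tg$sequence[tg$id == p$target_id]
  up <- substr(seq, p$site_position - 18, p$site_position + 1)  # 1-based
  dn <- substr(seq, p$site_position + 2, p$site_position + 21)
  expect_equal(chartr("ACGT", "UGCA", nanoladder:::str_rev(p$arm_3p)), up)
  expect_equal(chartr("ACGT", "UGCA", nanoladder:::str_rev(p$arm_5p)), dn)
})

test_that("circle length is the sum of its components", {
  tg <- rand_targets(1, 120, seed = 9)
  cfg <- probe_config(arm_len = 20, ref_len = 20, anchor_len = 20,
                      spacer = "TT")
  p <- design_probes(tg, cfg)
  expect_equal(nchar(p$circle_sequence),
               20L + nchar(cfg$catalytic_core) + 20L +  # arms + core
                 20L + 20L + 3L * 2L)                    # ref + anchor + spacers
})

test_that("design is deterministic and errors on short flanks", {
  tg <- rand_targets(1, 120, seed = 3)
  expect_identical(design_probes(tg), design_probes(tg))
  sites <- find_cleavage_sites(tg, arm_len = 20)
  bad <- sites[!sites$flank_ok, ][1, ]
  expect_error(design_circular_dnazyme(tg, bad), "flank")
})

test_that("orthogonal pool respects GC, homopolymer and k-mer constraints", {
  tg <- rand_targets(2, 200, seed = 4)
  pool <- orthogonal_pool(4, 20, tg, probe_config(), seed = 2)
  gc <- vapply(pool, nanoladder:::gc_fraction, numeric(1))
  expect_true(all(gc >= 0.4 & gc <= 0.6))
  tdna <- chartr("U", "T", tg$sequence)
  forb <- unique(unlist(lapply(c(tdna, nanoladder:::rc_dna(tdna)),
                               nanoladder:::kmers, k = 10)))
  for (s in pool) {
    expect_false(any(nanoladder:::kmers(s, 10) %in% forb))
    expect_lte(nanoladder:::max_homopolymer(s), 4)
  }
})

test_that("control variants carry the documented mismatch structure", {
  tg <- rand_targets(1, 150, seed = 6)
  p <- design_probes(tg)

  mm12 <- make_control_variant(p, "MM12")
  expect_equal(hamming(mm12$recognition_target, p$recognition_target), 12L)
  expect_equal(mm12$kind, "MM12")

  snv <- make_control_variant(p, "SNV")
  diff_at <- which(strsplit(snv$recognition_target, "")[[1]] !=
                     strsplit(p$recognition_target, "")[[1]])
  expect_equal(diff_at, 21L)  # 0-based index 20: centre of the 40-nt region
  expect_equal(hamming(snv$recognition_target, p$recognition_target), 1L)

  # SNV on an odd-length (41 nt) recognition region also mutates index 20
  reg <- rand_rna(41, seed = 8)
  v <- nanoladder:::variant_region(reg, "SNV", NULL)
  expect_equal(which(strsplit(v, "")[[1]] != strsplit(reg, "")[[1]]), 21L)

  cd <- make_control_variant(p, "core_deleted")
  expect_equal(nchar(cd$catalytic_core), nchar(p$catalytic_core))
  expect_false(cd$catalytic_core == p$catalytic_core)
  expect_equal(nchar(cd$circle_sequence), nchar(p$circle_sequence))

  expect_error(make_control_variant(tg[1, ], "MM12", site = 4, arm_len = 4),
               "12 nt")
})

test_that("random variants share no 10-mer with the recognition region", {
  tg <- rand_targets(1, 150, seed = 11)
  p <- design_probes(tg)
  rv <- make_control_variant(p, "random", seed = 7)
  orig_km <- nanoladder:::kmers(p$recognition_target, 10)
  # brute-force 10-mer set intersection
  expect_length(intersect(nanoladder:::kmers(rv$recognition_target, 10),
                          orig_km), 0)
  expect_equal(nchar(rv$recognition_target), nchar(p$recognition_target))
  expect_lte(abs(nanoladder:::gc_fraction(rv$recognition_target) -
                   nanoladder:::gc_fraction(p$recognition_target)), 0.05)
})

test_that("specificity screen: self-match is competent, SNV is not", {
  tg <- rand_targets(1, 150, seed = 12)
  p <- design_probes(tg)
  self <- screen_specificity(p, tg)
  expect_equal(self$max_contig_arm5, 20L)
  expect_equal(self$max_contig_arm3, 20L)
  expect_true(self$predicted_cleavage_competent)

  snv <- make_control_variant(p, "SNV")
  expect_false(screen_specificity(snv, tg)$predicted_cleavage_competent)

  expect_equal(nrow(screen_specificity(p, tg[0, ])), 0L)
})

test_that("design -> SNV -> screen round-trip always flags incompetence", {
  for (seed in 1:5) {
    tg <- rand_targets(1, 120, seed = 100 + seed)
    p <- design_probes(tg)
    snv <- make_control_variant(p, "SNV")
    expect_false(screen_specificity(snv, tg)$predicted_cleavage_competent)
  }
})

test_that("arm complementarity against shuffled background matches an exhaustive scan", {
  set.seed(13)
  tg <- rand_targets(1, 120, seed = 13)
  p <- design_probes(tg)
  # dinucleotide-ish shuffle: permute the target's characters
  shuf <- paste(sample(strsplit(tg$sequence, "")[[1]]), collapse = "")
  bg <- target_transcripts("shuffled", shuf)
  rep <- screen_specificity(p, bg)

  # independent oracle: manual run-length scan of each arm window
  w <- p$recognition_target
  wch <- strsplit(w, "")[[1]]
  sch <- strsplit(shuf, "")[[1]]
  oracle_arm <- function(idx) {
    alen <- length(idx)
    best <- 0L
    for (j in 0:(length(sch) - alen)) {
      run <- 0L
      for (k in seq_len(alen)) {
        if (sch[j + k] == wch[idx[k]]) {
          run <- run + 1L
          if (run > best) best <- run
        } else run <- 0L
      }
    }
    best
  }
  expect_equal(rep$max_contig_arm3, oracle_arm(1:20))
  expect_equal(rep$max_contig_arm5, oracle_arm(21:40))
})

test_that("padlock linearization is a pure rotation with a bridging linker", {
  tg <- rand_targets(2, 140, seed = 14)
  p <- emit_padlock_linker(design_probes(tg))
  for (i in 1:2) {
    circ <- p$circle_sequence[i]
    pad <- p$padlock[i]
    expect_equal(nchar(pad), nchar(circ))
    # rotation: circ is a substring of pad+pad
    expect_true(grepl(circ, paste0(pad, pad), fixed = TRUE))
    # linker reverse-complements the two padlock termini, 10 nt each
    L <- nchar(pad)
    junction <- paste0(substr(pad, L - 9, L), substr(pad, 1, 10))
    expect_equal(p$linker[i], nanoladder:::rc_dna(junction))
    expect_equal(nchar(p$linker[i]), 20L)
  }
})

test_that("probe sheet and oligo FASTA are written and readable", {
  tg <- rand_targets(1, 130, seed = 15)
  p <- emit_padlock_linker(design_probes(tg))
  tsv <- tempfile(fileext = ".tsv"); fa <- tempfile(fileext = ".fasta")
  write_probe_sheet(p, tsv)
  sheet <- readr::read_tsv(tsv, show_col_types = FALSE)
  expect_true(all(c("target_id", "component", "sequence_5to3") %in% names(sheet)))
  write_probe_fasta(p, fa)
  oligos <- Biostrings::readDNAStringSet(fa)
  expect_length(oligos, 2L)
  expect_equal(as.character(oligos[[paste0(p$target_id, "_padlock")]]),
               p$padlock)
})
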