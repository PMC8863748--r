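test_that("primer sites are located on both strands in forward coordinates", {
  set.seed(31)
  kp_f078 <- "GTGCCAGCMGCCGCGGTAA"
  genome <- paste0(random_dna(9), "GTGCCAGCAGCCGCGGTAA", random_dna(40))
  hits <- find_primer_sites(genome, kp_f078, "KP_F078")
  expect_identical(hits$strand, "+")
  expect_identical(hits$start, 10L)
  expect_identical(hits$end, 28L)

  # reverse primer binding site = occurrence of its reverse complement
  op_r010 <- "GGACTACHVGGGTWTCTAAT"
  site <- reverse_complement(sample(expand_degenerate(op_r010), 1L))
  genome <- paste0(random_dna(20), site, random_dna(20))
  hits <- find_primer_sites(genome, op_r010, "OP_R010")
  expect_identical(hits$strand, "-")
  expect_identical(hits$start, 21L)

  # duplicated locus gives two hits
  genome <- paste0(random_dna(10), site, random_dna(30), site, random_dna(10))
  expect_identical(nrow(find_primer_sites(genome, op_r010)), 2L)
})

test_that("amplicons respect the strict length window", {
  pair <- catalog_pair("OP_F053-KP_R020")
  set.seed(37)
  f <- sample(expand_degenerate(pair$f_seq), 1L)
  rsite <- reverse_complement(sample(expand_degenerate(pair$r_seq), 1L))

  build <- function(core_len, at = 9L) {
    seg <- paste0(f, random_dna(core_len), rsite)
    make_genomes(paste0(random_dna(at), seg, random_dna(25)))
  }
  # forward site starts at 10, reverse site ends at 10 + seg_len - 1;
  # core 347 - 19 - 15 + 1 = 314 gives the cataloged reported length 347
  g <- build(314L)
  amp <- extract_amplicons(g, pair)
  expect_identical(nrow(amp), 1L)
  expect_identical(amp$start, 10L)
  expect_identical(amp$reported_length, 347L)
  expect_identical(nchar(amp$sequence), 348L)
  expect_true(startsWith(amp$sequence, f))
  expect_true(endsWith(amp$sequence, rsite))

  # distances at or below 100 and at or above 2300 are excluded (strict)
  span_for <- function(core) core + nchar(f) + nchar(rsite) - 1L
  expect_identical(nrow(extract_amplicons(build(100L - span_for(0L)), pair)),
                   0L)
  expect_identical(nrow(extract_amplicons(build(101L - span_for(0L)), pair)),
                   1L)
  expect_identical(nrow(extract_amplicons(build(2300L - span_for(0L)), pair)),
                   0L)
  expect_identical(nrow(extract_amplicons(build(2299L - span_for(0L)), pair)),
                   1L)
})

test_that("extraction is invariant under reverse-complementing the genome", {
  pair <- catalog_pair("KP_F078-OP_R010")
  set.seed(41)
  for (i in 1:8) {
    n_sites <- sample(1:2, 1L)
    genome <- random_dna(60)
    for (k in seq_len(n_sites)) {
      p <- plant_amplicon(pair, random_dna(sample(120:200, 1L)), at = 0L,
                          tail = 60L)
      genome <- paste0(genome, p$genome)
    }
    g_fwd <- make_genomes(genome)
    g_rev <- make_genomes(reverse_complement(genome))
    a_fwd <- extract_amplicons(g_fwd, pair)
    a_rev <- extract_amplicons(g_rev, pair)
    expect_identical(sort(a_fwd$sequence), sort(a_rev$sequence))
    expect_true(all(a_fwd$reported_length > 100 &
                      a_fwd$reported_length < 2300))
  }
})

test_that("extraction equals brute force over expansions on small genomes", {
  pair <- catalog_pair("OP_F066-OP_R073")  # 13 + 15 nt, cores fit easily
  set.seed(43)
  for (i in 1:5) {
    p1 <- plant_amplicon(pair, random_dna(100), at = 15L, tail = 5L)
    p2 <- plant_amplicon(pair, random_dna(130), at = 0L, tail = 30L)
    genome <- paste0(p1$genome, p2$genome)
    # oracle: scan expansions of F and rc(R) (plus strand), and of R and
    # rc(F) (minus strand), pair sites by the distance rule
    f_starts <- oracle_find_sites(genome, pair$f_seq)
    r_rc_starts <- oracle_find_sites(genome, reverse_complement(pair$r_seq))
    nf <- nchar(pair$f_seq); nr <- nchar(pair$r_seq)
    expected <- character()
    for (fs in f_starts) for (rs in r_rc_starts) {
      len <- (rs + nr - 1L) - fs
      if (len > 100 && len < 2300) {
        expected <- c(expected, substr(genome, fs, rs + nr - 1L))
      }
    }
    rc_genome <- reverse_complement(genome)
    f_starts <- oracle_find_sites(rc_genome, pair$f_seq)
    r_rc_starts <- oracle_find_sites(rc_genome, reverse_complement(pair$r_seq))
    for (fs in f_starts) for (rs in r_rc_starts) {
      len <- (rs + nr - 1L) - fs
      if (len > 100 && len < 2300) {
        expected <- c(expected, substr(rc_genome, fs, rs + nr - 1L))
      }
    }
    got <- extract_amplicons(make_genomes(genome), pair)
    expect_identical(sort(got$sequence), sort(expected))
  }
})

test_that("variant collapse pools strains and numbers distinct sequences", {
  pair <- catalog_pair("KP_F078-OP_R010")
  set.seed(47)
  core <- random_dna(160)
  # one fixed concrete realization, so identical cores mean identical amplicons
  f <- sample(expand_degenerate(pair$f_seq), 1L)
  rsite <- reverse_complement(sample(expand_degenerate(pair$r_seq), 1L))
  mk <- function(core, at) {
    paste0(random_dna(at), f, core, rsite, random_dna(30))
  }

  # three identical amplicons from three strains of one species -> V1 only
  g <- make_genomes(c(mk(core, 10L), mk(core, 50L), mk(core, 25L)),
                    species = c(1L, 1L, 1L))
  amp <- extract_all(g, pair)
  expect_identical(nrow(amp), 1L)
  expect_identical(amp$variant_id, 1L)

  # a genome carrying the segment twice also emits the nested
  # forward-1 x reverse-2 combination, which is a distinct variant
  g2 <- g[1, , drop = FALSE]
  g2$sequence <- paste0(g2$sequence, mk(core, 5L))
  amp <- extract_all(g2, pair)
  expect_identical(nrow(amp), 2L)
  expect_identical(sum(amp$sequence == paste0(f, core, rsite)), 1L)

  # one-substitution difference makes a second variant, ordered by
  # first appearance (accession, then coordinate)
  core2 <- mutate_positions(core, 80L)
  g <- make_genomes(c(mk(core, 10L), mk(core2, 10L)), species = c(1L, 1L))
  amp <- extract_all(g, pair)
  expect_identical(amp$variant_id, 1:2)
  expect_identical(amp$accession, c("ACC001", "ACC002"))

  # identical sequences in different species stay separate
  g <- make_genomes(c(mk(core, 10L), mk(core, 10L)), species = c(1L, 2L))
  amp <- extract_all(g, pair)
  expect_identical(amp$species_id, c(1L, 2L))
  expect_identical(amp$variant_id, c(1L, 1L))
  expect_identical(amp$sequence[1], amp$sequence[2])
})

test_that("detected species shrink (weakly) as the length window narrows", {
  pair <- catalog_pair("KP_F078-OP_R010")
  set.seed(53)
  genomes <- make_genomes(vapply(1:6, function(s) {
    plant_amplicon(pair, random_dna(sample(c(80, 150, 400), 1L)), at = 20L)$genome
  }, character(1L)))
  windows <- list(c(100L, 2300L), c(110L, 500L), c(150L, 300L))
  detected <- vapply(windows, function(w) {
    length(unique(extract_all(genomes, pair, w[1], w[2])$species_id))
  }, integer(1L))
  expect_true(all(diff(detected) <= 0L))
})
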