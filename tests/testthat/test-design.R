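# Design fixtures use two 20-mers whose Tm under the default model
# (200 mM monovalent equivalent, 250 nM oligo) sits inside the 57-63 C
# window; the windows are planted in introns exactly one primer long so the
# search space is fully enumerable by hand.
GOODF <- "CGAGTCGGTTATCTTCGGAT"       # forward primer window
GOODR <- "ACTGTATAGTCCCACCTGGT"       # reverse-primer template window

one_window_fixture <- function() {
  set.seed(303)
  genome <- genome_sequence("chr", paste0(
    rand_dna(30), GOODF, rand_dna(100), GOODR, rand_dna(30)))
  site <- list(exon_index = 2L,
               upstream_intron = c(30L, 50L),
               exon = c(50L, 150L),
               downstream_intron = c(150L, 170L))
  params <- design_params(primer_len_min = 20L, primer_len_max = 20L,
                          min_intron_len = 20L)
  list(genome = genome, site = site, params = params)
}

test_that("enumerate_candidate_sites keeps short exons with long flanking introns", {
  # exon lengths 50, 90, 400, 100, 50 separated by 400 nt introns
  lens <- c(50L, 90L, 400L, 100L, 50L)
  starts <- cumsum(c(0L, head(lens, -1) + 400L))
  m <- make_gene_model(starts, starts + lens)
  sites <- enumerate_candidate_sites(m, design_params())
  expect_length(sites, 2L)
  expect_equal(vapply(sites, `[[`, integer(1), "exon_index"), c(2L, 4L))
  expect_equal(sites[[1]]$exon, c(m$exons$start[2], m$exons$end[2]))

  expect_length(enumerate_candidate_sites(make_gene_model(0L, 100L)), 0L)

  # 10 nt intron cannot host an 18-25 nt primer
  short <- make_gene_model(c(0L, 110L, 620L), c(100L, 120L, 720L))
  expect_length(enumerate_candidate_sites(short, design_params()), 0L)
})

test_that("design finds the single surviving pair in a one-window-per-intron site", {
  fx <- one_window_fixture()
  pairs <- design_primer_pairs(fx$site, fx$genome, fx$params, top_k = 5L,
                               species_tag = "human")
  expect_length(pairs, 1L)
  p <- pairs[[1]]
  expect_equal(p$forward_seq, GOODF)
  expect_equal(p$reverse_seq, naive_revcomp(GOODR))
  expect_equal(p$forward_interval, c(30L, 50L))
  expect_equal(p$reverse_interval, c(150L, 170L))
  expect_equal(p$amplicon, c(30L, 170L))
  expect_equal(p$amplicon_len, 140L)
  expect_equal(p$species_tag, "human")
  # amplicon spans the bracketed exon
  expect_true(p$amplicon[1] <= fx$site$exon[1] && fx$site$exon[2] <= p$amplicon[2])

  # brute-force enumeration oracle: only one window per intron passes filters
  pass <- function(intron) {
    hits <- 0L
    for (s in intron[1]:(intron[2] - 20L)) {
      w <- substr(fx$genome$seq, s + 1L, s + 20L)
      gc <- 100 * sum(strsplit(w, "")[[1]] %in% c("G", "C")) / 20
      tm <- oracle_tm(w, 200, 250)
      if (gc >= 40 && gc <= 60 && tm >= 57 && tm <= 63 &&
          max(rle(strsplit(w, "")[[1]])$lengths) <= 4) hits <- hits + 1L
    }
    hits
  }
  expect_equal(pass(fx$site$upstream_intron), 1L)
  expect_equal(pass(fx$site$downstream_intron), 1L)

  # penalty recomputation
  mid <- (fx$params$amplicon_len_min + fx$params$amplicon_len_max) / 2
  expect_equal(p$penalty,
               abs(p$tm_f - 60) + abs(p$tm_r - 60) + abs(p$tm_f - p$tm_r) +
                 abs(140 - mid) / 100 + (abs(p$gc_f - 50) + abs(p$gc_r - 50)) / 10)
})

test_that("infeasible constraints yield an empty list and a rejection tally", {
  fx <- one_window_fixture()
  tight <- design_params(primer_len_min = 20L, primer_len_max = 20L,
                         min_intron_len = 20L,
                         tm_min = 75, tm_opt = 77, tm_max = 80)
  pairs <- design_primer_pairs(fx$site, fx$genome, tight)
  expect_length(pairs, 0L)
  tally <- attr(pairs, "rejections")
  expect_gt(tally[["tm"]], 0L)
})

test_that("design output is deterministic and ranking is enumeration-order independent", {
  pair <- synthetic_genome_pair(synthetic_genome_spec(seed = 17))
  sites <- enumerate_candidate_sites(pair$model_a, design_params())
  expect_gt(length(sites), 0L)
  a <- design_primer_pairs(sites[[1]], pair$genome_a, design_params(), top_k = 3L)
  b <- design_primer_pairs(sites[[1]], pair$genome_a, design_params(), top_k = 3L)
  expect_identical(a, b)
  if (length(a) >= 2L) {
    pens <- vapply(a, `[[`, numeric(1), "penalty")
    expect_true(all(diff(pens) >= 0))
  }
})

test_that("verify_genomic_only enforces intron containment and a spanned exon", {
  model <- make_gene_model(c(10L, 50L, 170L), c(30L, 150L, 190L))
  fx <- one_window_fixture()
  good <- design_primer_pairs(fx$site, fx$genome, fx$params)[[1]]
  v <- verify_genomic_only(good, model)
  expect_true(v$ok)

  bad_f <- good
  bad_f$forward_interval <- c(49L, 69L)   # 1 nt into intron, rest on exon 2
  v2 <- verify_genomic_only(bad_f, model)
  expect_false(v2$ok)
  expect_match(v2$explanation, "overlaps exon 2")

  same <- good
  same$forward_interval <- c(150L, 160L)
  same$reverse_interval <- c(158L, 168L)
  same$amplicon <- c(150L, 168L)
  v3 <- verify_genomic_only(same, model)
  expect_false(v3$ok)
  expect_match(v3$explanation, "no exon spanned")
})

test_that("designed pairs on simulated genomes always verify as genomic-only (property)", {
  for (seed in c(1, 2, 3)) {
    pair <- synthetic_genome_pair(synthetic_genome_spec(seed = seed))
    sites <- enumerate_candidate_sites(pair$model_a, design_params())
    found <- FALSE
    for (site in sites) {
      for (p in design_primer_pairs(site, pair$genome_a, design_params(), top_k = 3L)) {
        expect_true(verify_genomic_only(p, pair$model_a)$ok)
        found <- TRUE
      }
    }
    expect_true(found, label = sprintf("seed %d yields at least one pair", seed))
  }
})

test_that("place_probe picks the hottest qualifying internal window", {
  w <- "CCGCTAGCGCATCGCAGC"  # 18-mer, GC-rich, no 5' G
  middle <- paste0("ATATATATAT", w, "ATATAT", w, "ATATATAT")
  g <- genome_sequence("chr", paste0(rand_dna(20), middle, rand_dna(20)))
  pair <- structure(list(forward_seq = "X", reverse_seq = "X",
                         forward_interval = c(0L, 20L),
                         reverse_interval = c(20L + nchar(middle), 40L + nchar(middle)),
                         tm_f = 50, tm_r = 50,
                         amplicon = c(0L, 40L + nchar(middle)),
                         amplicon_len = 40L + nchar(middle)),
                    class = "primer_pair")
  params <- design_params(probe_len_min = 18L, probe_len_max = 18L)
  probe <- place_probe(pair, g, params)
  expect_false(is.null(probe))
  expect_equal(probe$seq, w)
  expect_equal(probe$interval, c(30L, 48L))   # leftmost of the two equal-Tm copies
  expect_false(startsWith(probe$seq, "G"))
  expect_gte(probe$tm, 55)
  expect_equal(probe$reporter, "FAM")

  cramped <- pair
  cramped$reverse_interval <- c(25L, 45L)
  expect_null(place_probe(cramped, g, params))
})

test_that("assay table and oligo FASTA round-trip", {
  assays <- gapdh_assays()
  expect_equal(assays$expected_amplicon_len, c(189L, 260L))
  expect_true(all(grepl("^[ACGT]+$", c(assays$primer_f, assays$primer_r, assays$probe))))

  full <- cbind(assays[, c("species_tag", "gene_id", "primer_f", "primer_r", "probe")],
                tm_f = 60, tm_r = 60, gc_f = 50, gc_r = 50,
                amplicon_len = assays$expected_amplicon_len, penalty = 0,
                on_target_products = 1L, off_target_products = 0L)
  tsv <- tempfile(fileext = ".tsv")
  write_assay_tsv(full, tsv)
  back <- read.delim(tsv, stringsAsFactors = FALSE)
  expect_equal(back$primer_f, assays$primer_f)
  expect_equal(names(back)[1:3], c("species_tag", "gene_id", "primer_f"))

  fa <- tempfile(fileext = ".fa")
  write_oligo_fasta(full, fa)
  oligos <- parse_fasta(fa)
  expect_length(oligos, 6L)
  expect_equal(oligos[["human_hGapdh_F"]]$seq, assays$primer_f[1])
})
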