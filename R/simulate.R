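# Seeded simulator: Ct values from known template copy numbers, whole
# mixture/dilution plates, and a designable two-species synthetic genome
# pair, so the design and quantification modules can be validated
# end-to-end with no external data.
#
# Ct model: ct = ct_single_copy - log_{1+E}(copies) + N(0, noise_sd),
# censored at the final cycle; with E = 1 (exact doubling) each doubling of
# input lowers Ct by one cycle. Ct depends on target copies only, matching
# the one-locus-per-haploid-genome premise of the assay.

# Evaluate `code` under a temporary RNG seed, restoring the caller's state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv())
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

#' Simulator configuration
#'
#' @param efficiency Per-cycle amplification efficiency `E` in `(0, 1]`;
#'   `E = 1` is exact doubling.
#' @param ct_single_copy Intercept: expected Ct for a single template copy
#'   (default 38, a typical single-copy crossing point on a 40-cycle run).
#' @param noise_sd Gaussian Ct noise SD in cycles (default 0.15, keeping
#'   triplicate SEMs at the near-invisible level typical of clean genomic
#'   qPCR).
#' @param censor_cycle Final cycle; draws beyond it are censored
#'   (default 40).
#' @param seed Integer seed; all randomness in plate-level simulators flows
#'   from it.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(efficiency = 1.0, ct_single_copy = 38.0,
                              noise_sd = 0.15, censor_cycle = 40L,
                              seed = 1L) {
  stopifnot(efficiency > 0, efficiency <= 1, noise_sd >= 0,
            ct_single_copy <= censor_cycle)
  structure(list(efficiency = efficiency, ct_single_copy = ct_single_copy,
                 noise_sd = noise_sd, censor_cycle = censor_cycle,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Simulate one well's Ct from a template copy number
#'
#' Zero copies yield a censored well. Otherwise
#' `ct = ct_single_copy - log_{1+E}(copies) + N(0, noise_sd)`, censored at
#' `censor_cycle`. Draws from the current RNG state; seed management is the
#' caller's (or [simulate_plate()]'s) job.
#'
#' @param copies Non-negative integer template copy number.
#' @param config A [simulation_config()].
#' @return Numeric Ct, or `NA` for a censored well.
#' @export
simulate_ct <- function(copies, config = simulation_config()) {
  if (length(copies) != 1L || is.na(copies) || copies < 0 ||
      copies != round(copies)) {
    stop("copies must be a single non-negative integer")
  }
  if (copies == 0) return(NA_real_)
  ct <- config$ct_single_copy - log(copies, base = 1 + config$efficiency)
  if (config$noise_sd > 0) ct <- ct + stats::rnorm(1L, 0, config$noise_sd)
  if (ct >= config$censor_cycle) NA_real_ else ct
}

#' Simulate a two-assay qPCR plate for one mixed sample
#'
#' Generates `n_replicates` independent noisy wells for each assay, seeded
#' from `config$seed` (identical seed, identical table; the caller's RNG
#' state is untouched).
#'
#' @param h_copies,m_copies Human and murine template copies per well.
#' @param n_replicates Replicate wells per assay (default 3).
#' @param config A [simulation_config()].
#' @param sample_id Sample label for the table.
#' @return Data.frame in the quantifier's input schema: `sample_id`,
#'   `assay`, `replicate`, `ct` (`NA` = censored).
#' @export
simulate_plate <- function(h_copies, m_copies, n_replicates = 3L,
                           config = simulation_config(), sample_id = "sample") {
  stopifnot(n_replicates >= 1L)
  inner <- config
  inner$seed <- NULL
  with_seed(config$seed, {
    wells <- expand.grid(replicate = seq_len(n_replicates),
                         assay = c("human", "mouse"),
                         stringsAsFactors = FALSE)
    copies <- ifelse(wells$assay == "human", h_copies, m_copies)
    ct <- vapply(copies, simulate_ct, numeric(1), config = inner)
    data.frame(sample_id = sample_id, assay = wells$assay,
               replicate = wells$replicate, ct = ct,
               stringsAsFactors = FALSE)
  })
}

#' Fraction presets for mixture and sensitivity plate series
#'
#' `"mixture"` is the efficiency-test design — pure endpoints plus
#' 75/25, 50/50 and 25/75 mixtures of 5000 total copies. `"sensitivity"`
#' spans 99%..1% so that at 5000 total copies the smallest component is 50
#' copies at both extremes.
#'
#' @param preset `"mixture"` or `"sensitivity"`.
#' @return Numeric vector of human fractions.
#' @export
fraction_presets <- function(preset = c("mixture", "sensitivity")) {
  preset <- match.arg(preset)
  switch(preset,
         mixture = c(1, 0.75, 0.5, 0.25, 0),
         sensitivity = c(0.99, 0.9, 0.75, 0.5, 0.25, 0.1, 0.01))
}

#' Simulate a series of mixture plates at given human fractions
#'
#' Each fraction becomes one plate with
#' `h_copies = round(f * total_copies)` and the remainder murine. Plate `i`
#' is seeded with `config$seed + i - 1` so the whole series is reproducible
#' from one seed.
#'
#' @param total_copies Total genome copies per well (default 5000).
#' @param fractions Human fractions in `[0, 1]`; default the `"mixture"`
#'   preset.
#' @param config A [simulation_config()].
#' @param n_replicates Replicates per assay per plate (default 3).
#' @return List with `wells` (row-bound plate tables; sample ids
#'   `mix_<pct>pct`) and `manifest` (data.frame: `sample_id`, `fraction`,
#'   `h_copies`, `m_copies`, `seed`).
#' @export
mixture_series <- function(total_copies = 5000L,
                           fractions = fraction_presets("mixture"),
                           config = simulation_config(),
                           n_replicates = 3L) {
  if (any(fractions < 0 | fractions > 1)) stop("fractions must lie in [0, 1]")
  plates <- list()
  manifest <- list()
  for (i in seq_along(fractions)) {
    f <- fractions[[i]]
    h <- as.integer(round(f * total_copies))
    m <- as.integer(total_copies) - h
    id <- sprintf("mix_%gpct", 100 * f)
    cfg <- config
    cfg$seed <- config$seed + i - 1L
    plates[[i]] <- simulate_plate(h, m, n_replicates, cfg, sample_id = id)
    manifest[[i]] <- data.frame(sample_id = id, fraction = f,
                                h_copies = h, m_copies = m, seed = cfg$seed,
                                stringsAsFactors = FALSE)
  }
  list(wells = do.call(rbind, plates), manifest = do.call(rbind, manifest))
}

#' Specification for a synthetic two-species genome pair
#'
#' Defaults emulate the design substrate of a conserved housekeeping gene:
#' short (100 nt) exons that are highly conserved between the species, long
#' (400 nt) introns that have diverged, and flanking sequence on both
#' sides. Identity is the expected per-base match fraction when deriving
#' species B's sequence from species A's.
#'
#' @param n_exons Exon count (>= 3 so internal exons have two flanking
#'   introns).
#' @param exon_len,intron_len,flank_len Segment lengths in nt.
#' @param exon_identity Cross-species exon identity (default 0.9,
#'   conserved coding sequence).
#' @param intron_identity Cross-species intron identity (default 0.25, the
#'   floor for unrelated sequence over a 4-letter alphabet).
#' @param seed Integer seed.
#' @param min_primer_len Used to validate that introns can host a primer.
#' @return A `synthetic_genome_spec` list.
#' @export
synthetic_genome_spec <- function(n_exons = 5L, exon_len = 100L,
                                  intron_len = 400L, flank_len = 300L,
                                  exon_identity = 0.9,
                                  intron_identity = 0.25,
                                  seed = 1L, min_primer_len = 18L) {
  if (n_exons < 3L) stop("need at least 3 exons for an internal bracketed site")
  if (intron_len < min_primer_len + 10L) {
    stop(sprintf("infeasible spec: introns (%d nt) too short to host a %d nt primer",
                 intron_len, min_primer_len))
  }
  stopifnot(exon_identity >= 0, exon_identity <= 1,
            intron_identity >= 0, intron_identity <= 1)
  structure(list(n_exons = as.integer(n_exons), exon_len = as.integer(exon_len),
                 intron_len = as.integer(intron_len),
                 flank_len = as.integer(flank_len),
                 exon_identity = exon_identity,
                 intron_identity = intron_identity,
                 seed = as.integer(seed)),
            class = "synthetic_genome_spec")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Derive a diverged copy: each base is replaced by a uniform draw from the
# other three bases with probability 1 - identity (identity 1 => identical).
mutate_dna <- function(seq, identity) {
  if (identity >= 1) return(seq)
  bases <- strsplit(seq, "", fixed = TRUE)[[1L]]
  hit <- stats::runif(length(bases)) > identity
  if (any(hit)) {
    alt <- vapply(bases[hit], function(b) {
      sample(setdiff(c("A", "C", "G", "T"), b), 1L)
    }, character(1))
    bases[hit] <- alt
  }
  paste(bases, collapse = "")
}

#' Generate a designable synthetic two-species genome pair
#'
#' Builds species A as flank + alternating exons/introns + flank, then
#' derives species B segment-by-segment: exons at `exon_identity`
#' (conserved), introns at `intron_identity` (diverged), flanks
#' independently random. Every internal exon is a qualifying primer site
#' under default [design_params()] (exons 100 nt, introns 400 nt). Fully
#' seeded and reproducible.
#'
#' @param spec A [synthetic_genome_spec()].
#' @return List with `genome_a`, `genome_b` ([genome_sequence()]s, ids
#'   `chrA`/`chrB`), `model_a`, `model_b` (`gene_model`s, gene ids
#'   `geneA`/`geneB`), and `spec`.
#' @export
synthetic_genome_pair <- function(spec = synthetic_genome_spec()) {
  with_seed(spec$seed, {
    segs_a <- list(flank5 = random_dna(spec$flank_len))
    kinds <- character()
    for (i in seq_len(spec$n_exons)) {
      segs_a[[paste0("exon", i)]] <- random_dna(spec$exon_len)
      if (i < spec$n_exons) segs_a[[paste0("intron", i)]] <- random_dna(spec$intron_len)
    }
    segs_a$flank3 <- random_dna(spec$flank_len)
    segs_b <- lapply(names(segs_a), function(nm) {
      if (grepl("^exon", nm)) mutate_dna(segs_a[[nm]], spec$exon_identity)
      else if (grepl("^intron", nm)) mutate_dna(segs_a[[nm]], spec$intron_identity)
      else random_dna(nchar(segs_a[[nm]]))
    })
    names(segs_b) <- names(segs_a)
    build <- function(segs, chrom, gene) {
      seq <- paste(unlist(segs), collapse = "")
      pos <- spec$flank_len
      exons <- data.frame(start = integer(), end = integer())
      for (i in seq_len(spec$n_exons)) {
        exons <- rbind(exons, data.frame(start = pos, end = pos + spec$exon_len))
        pos <- pos + spec$exon_len + if (i < spec$n_exons) spec$intron_len else 0L
      }
      introns <- data.frame(start = exons$end[-spec$n_exons],
                            end = exons$start[-1L])
      model <- structure(list(gene_id = gene, chrom = chrom, strand = "+",
                              exons = exons, introns = introns),
                         class = "gene_model")
      list(genome = genome_sequence(chrom, seq), model = model)
    }
    a <- build(segs_a, "chrA", "geneA")
    b <- build(segs_b, "chrB", "geneB")
    list(genome_a = a$genome, genome_b = b$genome,
         model_a = a$model, model_b = b$model, spec = spec)
  })
}

#' Write a genome pair as FASTA + GFF3 fixture files
#'
#' Emits `<prefix>_a.fa`, `<prefix>_a.gff3`, `<prefix>_b.fa`,
#' `<prefix>_b.gff3` consumable by the design workflow without edits.
#'
#' @param pair Output of [synthetic_genome_pair()].
#' @param prefix Output path prefix.
#' @return Character vector of the four paths, invisibly.
#' @export
write_genome_pair <- function(pair, prefix) {
  write_one <- function(genome, model, fa_path, gff_path) {
    set <- Biostrings::DNAStringSet(stats::setNames(genome$seq, genome$id))
    Biostrings::writeXStringSet(set, fa_path)
    tx <- paste0(model$gene_id, ".t1")
    lines <- c("##gff-version 3",
               sprintf("%s\tsynthetic\tgene\t%d\t%d\t.\t%s\t.\tID=%s;gene_id=%s",
                       model$chrom, model$exons$start[1L] + 1L,
                       model$exons$end[nrow(model$exons)], model$strand,
                       model$gene_id, model$gene_id),
               sprintf("%s\tsynthetic\texon\t%d\t%d\t.\t%s\t.\tParent=%s;gene_id=%s",
                       model$chrom, model$exons$start + 1L, model$exons$end,
                       model$strand, tx, model$gene_id))
    writeLines(lines, gff_path)
  }
  paths <- c(paste0(prefix, "_a.fa"), paste0(prefix, "_a.gff3"),
             paste0(prefix, "_b.fa"), paste0(prefix, "_b.gff3"))
  write_one(pair$genome_a, pair$model_a, paths[1L], paths[2L])
  write_one(pair$genome_b, pair$model_b, paths[3L], paths[4L])
  invisible(paths)
}
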