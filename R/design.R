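# Assay design: enumerate exons short enough to be bracketed by intronic
# primers, exhaustively scan primer windows in the two flanking introns,
# filter on length/Tm/GC/homopolymer/amplicon-length, and rank by a
# deterministic penalty. Both primers lie wholly inside introns so the pair
# amplifies genomic DNA but never spliced cDNA.

#' Primer design parameters
#'
#' Defaults target standard qPCR oligos: 18-25 nt primers, 80-300 nt
#' amplicons (covering typical intron-anchored products), Tm 57-63 C with a
#' 60 C optimum, 40-60% GC, homopolymer runs capped at 4. A candidate site
#' is an exon of at most `max_exon_len` nt whose two flanking introns each
#' have at least `min_intron_len` nt to host a primer.
#'
#' @param primer_len_min,primer_len_max Primer length bounds (nt).
#' @param amplicon_len_min,amplicon_len_max Product length bounds (nt).
#' @param tm_min,tm_opt,tm_max Primer melting temperature bounds and optimum
#'   (degrees C), `tm_min <= tm_opt <= tm_max`.
#' @param gc_min,gc_max Primer GC bounds (%).
#' @param max_homopolymer Longest allowed single-base run.
#' @param max_exon_len Longest exon that still qualifies as a bracketed site
#'   (nt).
#' @param min_intron_len Shortest intron that can host a primer; default
#'   `primer_len_max + 10`.
#' @param salt_mM,oligo_nM Tm model conditions (see
#'   [melting_temperature()]). The 200 mM default is the monovalent
#'   equivalent of a typical PCR master mix (50 mM K+ with ~3 mM Mg2+),
#'   under which standard qPCR oligos fall in the 57-63 C window.
#' @param probe_len_min,probe_len_max Hydrolysis-probe length bounds (nt).
#' @return A `design_params` list.
#' @export
design_params <- function(primer_len_min = 18L, primer_len_max = 25L,
                          amplicon_len_min = 80L, amplicon_len_max = 300L,
                          tm_min = 57, tm_opt = 60, tm_max = 63,
                          gc_min = 40, gc_max = 60,
                          max_homopolymer = 4L,
                          max_exon_len = 150L,
                          min_intron_len = primer_len_max + 10L,
                          salt_mM = 200, oligo_nM = 250,
                          probe_len_min = 18L, probe_len_max = 30L) {
  stopifnot(primer_len_min <= primer_len_max,
            amplicon_len_min <= amplicon_len_max,
            tm_min <= tm_opt, tm_opt <= tm_max,
            gc_min <= gc_max,
            probe_len_min <= probe_len_max)
  structure(list(primer_len_min = as.integer(primer_len_min),
                 primer_len_max = as.integer(primer_len_max),
                 amplicon_len_min = as.integer(amplicon_len_min),
                 amplicon_len_max = as.integer(amplicon_len_max),
                 tm_min = tm_min, tm_opt = tm_opt, tm_max = tm_max,
                 gc_min = gc_min, gc_max = gc_max,
                 max_homopolymer = as.integer(max_homopolymer),
                 max_exon_len = as.integer(max_exon_len),
                 min_intron_len = as.integer(min_intron_len),
                 salt_mM = salt_mM, oligo_nM = oligo_nM,
                 probe_len_min = as.integer(probe_len_min),
                 probe_len_max = as.integer(probe_len_max)),
            class = "design_params")
}

#' Enumerate exons that can be bracketed by intronic primers
#'
#' A qualifying site is an exon no longer than `max_exon_len` whose two
#' flanking introns are each at least `min_intron_len` long. First and last
#' exons never qualify (only one flanking intron).
#'
#' @param gene_model A `gene_model` from [build_gene_models()].
#' @param params A [design_params()].
#' @return List of sites ordered by exon position; each site has
#'   `exon_index`, `upstream_intron`, `exon`, `downstream_intron` (each a
#'   `c(start, end)` pair, 0-based half-open).
#' @export
enumerate_candidate_sites <- function(gene_model, params = design_params()) {
  ex <- gene_model$exons
  int <- gene_model$introns
  sites <- list()
  if (nrow(ex) < 3L) return(sites)
  for (i in 2L:(nrow(ex) - 1L)) {
    exon_len <- ex$end[i] - ex$start[i]
    up <- c(int$start[i - 1L], int$end[i - 1L])
    down <- c(int$start[i], int$end[i])
    if (exon_len <= params$max_exon_len &&
        (up[2L] - up[1L]) >= params$min_intron_len &&
        (down[2L] - down[1L]) >= params$min_intron_len) {
      sites[[length(sites) + 1L]] <- list(
        exon_index = i,
        upstream_intron = up,
        exon = c(ex$start[i], ex$end[i]),
        downstream_intron = down)
    }
  }
  sites
}

# Scan all primer-length windows of one intron; returns a data.frame of
# windows passing the per-oligo filters plus a tally of rejections.
# Windowed GC counts, homopolymer runs and nearest-neighbor dH/dS sums are
# computed with cumulative sums so the scan is linear in intron length.
# Filter priority for the tally: N > GC > homopolymer > Tm.
scan_primer_windows <- function(genome, intron, params) {
  tally <- c(n = 0L, tm = 0L, gc = 0L, homopolymer = 0L)
  lo <- intron[1L]
  iseq <- extract_interval_sequence(genome, intron[1L], intron[2L])
  chars <- strsplit(iseq, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  cs_gc <- c(0, cumsum(chars %in% c("G", "C")))
  cs_n <- c(0, cumsum(chars == "N"))
  # run length ending at each position; a window fails the homopolymer
  # filter iff it fully contains a run of max_homopolymer + 1 bases, i.e.
  # some position i with runend >= max+1 and [i-max, i] inside the window
  runs <- rle(chars)
  runend <- sequence(runs$lengths)
  cs_bad <- c(0, cumsum(runend >= params$max_homopolymer + 1L))
  stacks <- if (n >= 2L) paste0(chars[-n], chars[-1L]) else character()
  dh_s <- unname(.NN_DH[stacks]); dh_s[is.na(dh_s)] <- 0
  ds_s <- unname(.NN_DS[stacks]); ds_s[is.na(ds_s)] <- 0
  cs_dh <- c(0, cumsum(dh_s))
  cs_ds <- c(0, cumsum(ds_s))
  conc <- params$oligo_nM * 1e-9 / 4
  rows <- list()
  for (len in params$primer_len_min:params$primer_len_max) {
    if (n < len) next
    starts <- seq_len(n - len + 1L)           # 1-based within the intron
    ends <- starts + len - 1L
    has_n <- (cs_n[ends + 1L] - cs_n[starts]) > 0
    gc <- 100 * (cs_gc[ends + 1L] - cs_gc[starts]) / len
    gc_bad <- gc < params$gc_min | gc > params$gc_max
    homo_bad <- if (len > params$max_homopolymer) {
      (cs_bad[ends + 1L] - cs_bad[starts + params$max_homopolymer]) > 0
    } else rep(FALSE, length(starts))
    dh <- cs_dh[ends] - cs_dh[starts] +
      ifelse(chars[starts] %in% c("A", "T"), 2.3, 0.1) +
      ifelse(chars[ends] %in% c("A", "T"), 2.3, 0.1)
    ds <- cs_ds[ends] - cs_ds[starts] +
      ifelse(chars[starts] %in% c("A", "T"), 4.1, -2.8) +
      ifelse(chars[ends] %in% c("A", "T"), 4.1, -2.8) +
      0.368 * (len - 1L) * log(params$salt_mM * 1e-3)
    tm <- dh * 1000 / (ds + .GAS_CONSTANT * log(conc)) - 273.15
    tm_bad <- has_n | tm < params$tm_min | tm > params$tm_max
    tally[["n"]] <- tally[["n"]] + sum(has_n)
    tally[["gc"]] <- tally[["gc"]] + sum(gc_bad & !has_n)
    tally[["homopolymer"]] <- tally[["homopolymer"]] + sum(homo_bad & !gc_bad & !has_n)
    tally[["tm"]] <- tally[["tm"]] + sum(tm_bad & !homo_bad & !gc_bad & !has_n)
    keep <- which(!has_n & !gc_bad & !homo_bad & !tm_bad)
    if (length(keep)) {
      seqs <- substring(iseq, starts[keep], ends[keep])
      # the windowed sums omit the self-complementarity correction; fix the
      # (rare) symmetric oligos with the exact scalar computation
      sc <- if (len %% 2L == 0L) seqs == revcomp_chr(seqs) else rep(FALSE, length(seqs))
      tmk <- tm[keep]
      if (any(sc)) {
        tmk[sc] <- vapply(seqs[sc], melting_temperature, numeric(1),
                          salt_mM = params$salt_mM, oligo_nM = params$oligo_nM)
        ok <- tmk >= params$tm_min & tmk <= params$tm_max
        tally[["tm"]] <- tally[["tm"]] + sum(!ok)
        keep <- keep[ok]; seqs <- seqs[ok]; tmk <- tmk[ok]
      }
      if (length(keep)) {
        rows[[length(rows) + 1L]] <- data.frame(
          start = lo + starts[keep] - 1L, end = lo + ends[keep],
          seq = seqs, tm = tmk, gc = gc[keep], stringsAsFactors = FALSE)
      }
    }
  }
  windows <- if (length(rows)) do.call(rbind, rows) else
    data.frame(start = integer(), end = integer(), seq = character(),
               tm = numeric(), gc = numeric(), stringsAsFactors = FALSE)
  list(windows = windows, tally = tally)
}

#' Design ranked intronic primer pairs for one candidate site
#'
#' Exhaustively scans every primer window in the upstream intron (forward
#' primer, template strand) and the downstream intron (reverse primer,
#' reported 5'->3' as synthesized, i.e. the reverse complement of the
#' template window), filters each oligo on length, N-content, GC,
#' homopolymer run and Tm, pairs them under the amplicon-length bounds, and
#' ranks pairs by the penalty
#' `|Tm_f - opt| + |Tm_r - opt| + |Tm_f - Tm_r| +
#'  |amplicon_len - midpoint| / 100 + (|GC_f - 50| + |GC_r - 50|) / 10`.
#' Ties break deterministically on leftmost forward start, then leftmost
#' reverse start.
#'
#' @param site One element of [enumerate_candidate_sites()].
#' @param genome The [genome_sequence()] the site lives on.
#' @param params A [design_params()].
#' @param top_k Number of pairs to return.
#' @param species_tag Label stored on each pair (e.g. `"human"`).
#' @return List of `primer_pair` objects, best first, with attribute
#'   `rejections` (named per-filter rejection tally).
#' @export
design_primer_pairs <- function(site, genome, params = design_params(),
                                top_k = 5L, species_tag = "") {
  fw <- scan_primer_windows(genome, site$upstream_intron, params)
  rv <- scan_primer_windows(genome, site$downstream_intron, params)
  tally <- fw$tally + rv$tally
  tally <- c(tally, amplicon_len = 0L)
  pairs <- list()
  f <- fw$windows; r <- rv$windows
  amp_mid <- (params$amplicon_len_min + params$amplicon_len_max) / 2
  if (nrow(f) && nrow(r)) {
    fi <- rep(seq_len(nrow(f)), each = nrow(r))
    ri <- rep(seq_len(nrow(r)), times = nrow(f))
    amp_len <- r$end[ri] - f$start[fi]
    ok <- amp_len >= params$amplicon_len_min & amp_len <= params$amplicon_len_max
    tally[["amplicon_len"]] <- tally[["amplicon_len"]] + sum(!ok)
    fi <- fi[ok]; ri <- ri[ok]; amp_len <- amp_len[ok]
    if (length(fi)) {
      penalty <- abs(f$tm[fi] - params$tm_opt) + abs(r$tm[ri] - params$tm_opt) +
        abs(f$tm[fi] - r$tm[ri]) +
        abs(amp_len - amp_mid) / 100 +
        (abs(f$gc[fi] - 50) + abs(r$gc[ri] - 50)) / 10
      ord <- order(penalty, f$start[fi], r$start[ri])
      best <- ord[seq_len(min(top_k, length(ord)))]
      pairs <- lapply(best, function(k) {
        i <- fi[k]; j <- ri[k]
        structure(list(
          forward_seq = f$seq[i],
          reverse_seq = reverse_complement(r$seq[j]),
          forward_interval = c(f$start[i], f$end[i]),
          reverse_interval = c(r$start[j], r$end[j]),
          species_tag = species_tag,
          tm_f = f$tm[i], tm_r = r$tm[j],
          gc_f = f$gc[i], gc_r = r$gc[j],
          amplicon = c(f$start[i], r$end[j]),
          amplicon_len = amp_len[k],
          penalty = penalty[k]), class = "primer_pair")
      })
    }
  }
  structure(pairs, rejections = tally)
}

#' @export
print.primer_pair <- function(x, ...) {
  cat(sprintf("<primer_pair> %s F:%s R:%s amplicon %d nt (Tm %.1f/%.1f C, penalty %.2f)\n",
              x$species_tag, x$forward_seq, x$reverse_seq, x$amplicon_len,
              x$tm_f, x$tm_r, x$penalty))
  invisible(x)
}

#' Check that a primer pair can only amplify genomic DNA
#'
#' True iff both primers sit wholly inside (distinct) introns — so neither
#' binding site survives splicing — and the amplicon contains at least one
#' complete exon. Pairs failing either condition could amplify cDNA or
#' nothing diagnostic.
#'
#' @param pair A `primer_pair`.
#' @param gene_model The `gene_model` the pair was designed on.
#' @return List with `ok` (logical) and `explanation` (character).
#' @export
verify_genomic_only <- function(pair, gene_model) {
  within_intron <- function(iv) {
    which(gene_model$introns$start <= iv[1L] & iv[2L] <= gene_model$introns$end)
  }
  f_in <- within_intron(pair$forward_interval)
  r_in <- within_intron(pair$reverse_interval)
  if (length(f_in) == 0L) {
    ex <- which(gene_model$exons$start < pair$forward_interval[2L] &
                pair$forward_interval[1L] < gene_model$exons$end)
    msg <- if (length(ex)) sprintf("forward primer overlaps exon %d", ex[[1L]])
           else "forward primer not inside an intron"
    return(list(ok = FALSE, explanation = msg))
  }
  if (length(r_in) == 0L) {
    ex <- which(gene_model$exons$start < pair$reverse_interval[2L] &
                pair$reverse_interval[1L] < gene_model$exons$end)
    msg <- if (length(ex)) sprintf("reverse primer overlaps exon %d", ex[[1L]])
           else "reverse primer not inside an intron"
    return(list(ok = FALSE, explanation = msg))
  }
  if (f_in[[1L]] == r_in[[1L]]) {
    return(list(ok = FALSE, explanation = "no exon spanned: both primers inside the same intron"))
  }
  amp <- pair$amplicon
  spanned <- any(gene_model$exons$start >= amp[1L] & gene_model$exons$end <= amp[2L])
  if (!spanned) {
    return(list(ok = FALSE, explanation = "no complete exon inside the amplicon"))
  }
  list(ok = TRUE, explanation = sprintf(
    "both primers intronic (introns %d and %d), amplicon spans a complete exon",
    f_in[[1L]], r_in[[1L]]))
}

#' Place a hydrolysis probe inside an amplicon
#'
#' Scans windows strictly between the two primer binding sites, requires
#' probe Tm at least 5 C above the hotter primer (standard hydrolysis-probe
#' practice, so the probe is bound before the primers extend), no
#' 5'-terminal G (which quenches the reporter), and fully specified bases.
#' The highest-Tm window wins; ties break on leftmost position.
#'
#' @param pair A `primer_pair`.
#' @param genome The template [genome_sequence()].
#' @param params A [design_params()].
#' @param reporter,quencher Dye labels recorded on the probe.
#' @return A `probe` list (`seq`, `interval`, `tm`, `reporter`, `quencher`)
#'   or `NULL` when no window qualifies.
#' @export
place_probe <- function(pair, genome, params = design_params(),
                        reporter = "FAM", quencher = "TAMRA") {
  lo <- pair$forward_interval[2L]
  hi <- pair$reverse_interval[1L]
  tm_floor <- max(pair$tm_f, pair$tm_r) + 5
  best <- NULL
  for (len in params$probe_len_min:params$probe_len_max) {
    if (hi - lo < len) next
    for (start in lo:(hi - len)) {
      s <- extract_interval_sequence(genome, start, start + len)
      if (grepl("N", s, fixed = TRUE)) next
      if (startsWith(s, "G")) next
      tm <- melting_temperature(s, params$salt_mM, params$oligo_nM)
      if (tm < tm_floor) next
      if (is.null(best) || tm > best$tm + 1e-9 ||
          (abs(tm - best$tm) <= 1e-9 && start < best$interval[1L])) {
        best <- list(seq = s, interval = c(start, start + len), tm = tm,
                     reporter = reporter, quencher = quencher)
      }
    }
  }
  if (!is.null(best)) class(best) <- "probe"
  best
}

#' Bundled human/mouse Gapdh intronic assay definitions
#'
#' The published intron-anchored Gapdh oligo set: the human pair anchors on
#' introns 3 and 4 around exon 4 (189 bp product on the reference genome),
#' the murine pair on introns 1 and 2 around exon 2 (260 bp product), each
#' with its hydrolysis probe. Useful as ready-made queries for
#' [insilico_pcr()] against user-supplied genomic sequence.
#'
#' @return Data.frame with one row per assay: `species_tag`, `gene_id`,
#'   `primer_f`, `primer_r`, `probe`, `reporter`, `quencher`,
#'   `expected_amplicon_len`.
#' @export
gapdh_assays <- function() {
  data.frame(
    species_tag = c("human", "mouse"),
    gene_id = c("hGapdh", "mGapdh"),
    primer_f = c("CTGACTCAGCCCTGCAAAG", "GGCCACGCTAATCTCATTTT"),
    primer_r = c("CCTGCCTTCCTCACCTGAT", "AAGGCGGAGTTACCAGAGGT"),
    probe = c("ACTGTCTGCTTCTCTGCTGTAGGCTCA", "CGAGCCATCGCCAGGTCCGAGC"),
    reporter = c("FAM", "FAM"),
    quencher = c("TAMRA", "TAMRA"),
    expected_amplicon_len = c(189L, 260L),
    stringsAsFactors = FALSE)
}

#' Write an assay table as TSV
#'
#' Fixed column set and order: `species_tag`, `gene_id`, `primer_f`,
#' `primer_r`, `probe`, `tm_f`, `tm_r`, `gc_f`, `gc_r`, `amplicon_len`,
#' `penalty`, `on_target_products`, `off_target_products`.
#'
#' @param assays Data.frame with the columns above.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_assay_tsv <- function(assays, path) {
  cols <- c("species_tag", "gene_id", "primer_f", "primer_r", "probe",
            "tm_f", "tm_r", "gc_f", "gc_r", "amplicon_len", "penalty",
            "on_target_products", "off_target_products")
  missing <- setdiff(cols, names(assays))
  if (length(missing)) stop(sprintf("assay table missing columns: %s",
                                    paste(missing, collapse = ", ")))
  utils::write.table(assays[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write designed oligos as FASTA
#'
#' @param assays Data.frame with `species_tag`, `gene_id`, `primer_f`,
#'   `primer_r` and optionally `probe` columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_oligo_fasta <- function(assays, path) {
  seqs <- character()
  for (i in seq_len(nrow(assays))) {
    base <- sprintf("%s_%s", assays$species_tag[i], assays$gene_id[i])
    seqs[[paste0(base, "_F")]] <- assays$primer_f[i]
    seqs[[paste0(base, "_R")]] <- assays$primer_r[i]
    if (!is.null(assays$probe) && !is.na(assays$probe[i]) && nzchar(assays$probe[i])) {
      seqs[[paste0(base, "_probe")]] <- assays$probe[i]
    }
  }
  set <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}
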