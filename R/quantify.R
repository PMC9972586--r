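# Ct-based quantification of two-species genomic mixtures.
#
# Core model: the two intronic assays each see one locus copy per haploid
# genome and amplify with equal (two-fold per cycle) efficiency, so a Ct
# difference of dCt between the human and murine assays corresponds to a
# 2^dCt fold ratio of genomic copies, and the human percentage is
# hP = F / (F + 1) * 100 with F = 2^(mCt - hCt); mP = 100 - hP exactly.
# Undetermined wells are censored at the final cycle and enter means at
# that value, with an explicit detection-floor bound reported because a
# censored reading only lower-bounds the true Ct.

#' Physical constants for mass/copy-number conversion
#'
#' @param avogadro Avogadro's number, 1/mol.
#' @param bp_mass Mean molar mass of a base pair, g/mol.
#' @param human_genome_len Haploid human genome length, nt.
#' @param mouse_genome_len Haploid mouse genome length, nt.
#' @param censor_cycle Final qPCR cycle; undetermined wells are recorded at
#'   this Ct.
#' @return A `quant_constants` list.
#' @export
quant_constants <- function(avogadro = 6.022e23, bp_mass = 650,
                            human_genome_len = 3.2e9,
                            mouse_genome_len = 2.5e9,
                            censor_cycle = 40) {
  stopifnot(avogadro > 0, bp_mass > 0, human_genome_len > 0,
            mouse_genome_len > 0, censor_cycle > 0)
  structure(list(avogadro = avogadro, bp_mass = bp_mass,
                 human_genome_len = human_genome_len,
                 mouse_genome_len = mouse_genome_len,
                 censor_cycle = censor_cycle),
            class = "quant_constants")
}

#' Aggregate replicate wells into mean Ct and SEM
#'
#' Censored (undetermined) wells enter the mean at `censor_cycle`, the
#' plate-reader convention for readings that never crossed threshold; the
#' count of censored wells is reported so downstream code can flag the
#' estimate.
#'
#' @param ct Numeric Ct values; `NA` marks a censored well.
#' @param censor_cycle Cycle substituted for censored wells (default 40).
#' @return A `ct_summary`: `mean_ct`, `sem`, `n`, `n_censored`.
#' @export
aggregate_replicates <- function(ct, censor_cycle = 40) {
  if (length(ct) == 0L) stop("no replicate wells to aggregate")
  censored <- is.na(ct)
  vals <- ifelse(censored, censor_cycle, ct)
  if (any(vals <= 0 | vals > censor_cycle)) {
    stop(sprintf("Ct values must lie in (0, %g]", censor_cycle))
  }
  n <- length(vals)
  sem <- if (n > 1L) stats::sd(vals) / sqrt(n) else 0
  structure(list(mean_ct = mean(vals), sem = sem, n = n,
                 n_censored = sum(censored)),
            class = "ct_summary")
}

#' Fold ratio implied by a Ct difference
#'
#' Under exact doubling per cycle, a Ct gap of `delta_ct` cycles between two
#' assays means a `2^|delta_ct|` fold copy-number ratio in favor of the
#' lower-Ct assay (e.g. 2^6.64386 = 100-fold).
#'
#' @param delta_ct Ct difference (cycles), any sign.
#' @return Fold ratio `>= 1`.
#' @export
fold_from_delta_ct <- function(delta_ct) {
  if (!all(is.finite(delta_ct))) stop("delta_ct must be finite")
  2^abs(delta_ct)
}

#' Detection sensitivity implied by a Ct difference
#'
#' The dynamic-range interpretation of a Ct gap: a 100-fold ratio
#' (`delta_ct` = 6.64386) corresponds to 1% sensitivity, 1000-fold to 0.1%,
#' 10000-fold to 0.01% — i.e. `100 / 2^delta_ct` percent.
#'
#' @param delta_ct Non-negative Ct difference (orientation resolved by the
#'   caller).
#' @return Sensitivity in percent.
#' @export
sensitivity_from_delta_ct <- function(delta_ct) {
  if (any(delta_ct < 0)) stop("delta_ct must be non-negative")
  100 / 2^delta_ct
}

#' Estimate human/murine composition from paired Ct summaries
#'
#' With `F = 2^(mCt - hCt)`, the human percentage is
#' `hP = F / (F + 1) * 100` and `mP = 100 - hP` (the identity
#' `hP + mP = 100` holds bit-exactly by construction). When one assay is
#' fully censored the point estimate uses `Ct = censor_cycle` and a
#' detection floor `100 / 2^(censor_cycle - other mean Ct)` percent is
#' reported as an upper bound on the undetected species' fraction.
#'
#' @param h A `ct_summary` for the human assay (or a single Ct value).
#' @param m A `ct_summary` for the murine assay (or a single Ct value).
#' @param censor_cycle Final cycle (default 40).
#' @return A `composition_estimate`: `delta_ct` (hCt - mCt), `fold`, `hP`,
#'   `mP`, `dominant`, `detection_flag`, `detection_floor`.
#' @export
composition_from_ct <- function(h, m, censor_cycle = 40) {
  as_summary <- function(x) {
    if (inherits(x, "ct_summary")) x else aggregate_replicates(x, censor_cycle)
  }
  h <- as_summary(h); m <- as_summary(m)
  h_out <- h$n_censored == h$n
  m_out <- m$n_censored == m$n
  if (h_out && m_out) stop("no template detected: both assays fully censored")
  delta_ct <- h$mean_ct - m$mean_ct
  f <- 2^(-delta_ct)                 # folds of human per one fold of mouse
  hP <- f / (f + 1) * 100
  mP <- 100 - hP
  flag <- "none"
  floor <- NA_real_
  if (h_out) {
    flag <- "human_not_detected"
    floor <- 100 / 2^(censor_cycle - m$mean_ct)
  } else if (m_out) {
    flag <- "mouse_not_detected"
    floor <- 100 / 2^(censor_cycle - h$mean_ct)
  }
  dominant <- if (delta_ct < 0) "human" else if (delta_ct > 0) "mouse" else "balanced"
  structure(list(delta_ct = delta_ct, fold = fold_from_delta_ct(delta_ct),
                 hP = hP, mP = mP, dominant = dominant,
                 detection_flag = flag, detection_floor = floor,
                 h_summary = h, m_summary = m),
            class = "composition_estimate")
}

#' @export
print.composition_estimate <- function(x, ...) {
  cat(sprintf("<composition_estimate> human %.4f%% / murine %.4f%% (dCt %.3f, %.4g-fold, %s)\n",
              x$hP, x$mP, x$delta_ct, x$fold, x$dominant))
  if (x$detection_flag != "none") {
    cat(sprintf("  %s; detection floor %.4g%%\n", x$detection_flag, x$detection_floor))
  }
  invisible(x)
}

#' Convert a genomic DNA mass to genome copy number
#'
#' `copies = amount_ng * avogadro / (genome_len * 1e9 * bp_mass)` — the mass
#' of one haploid genome equivalent being `genome_len * bp_mass / avogadro`
#' grams, with the `1e9` factor converting ng to g.
#'
#' @param amount_ng DNA mass in ng.
#' @param genome_len_nt Haploid genome length in nt (e.g. 3.2e9 human,
#'   2.5e9 mouse).
#' @param constants A [quant_constants()].
#' @return Genome copy number.
#' @export
mass_to_copies <- function(amount_ng, genome_len_nt,
                           constants = quant_constants()) {
  if (any(genome_len_nt <= 0)) stop("genome length must be positive")
  if (any(amount_ng < 0)) stop("DNA amount must be non-negative")
  amount_ng * constants$avogadro / (genome_len_nt * 1e9 * constants$bp_mass)
}

#' Convert a genome copy number to DNA mass in ng
#'
#' Exact algebraic inverse of [mass_to_copies()].
#'
#' @param copies Genome copy number.
#' @param genome_len_nt Haploid genome length in nt.
#' @param constants A [quant_constants()].
#' @return DNA mass in ng.
#' @export
copies_to_mass <- function(copies, genome_len_nt,
                           constants = quant_constants()) {
  if (any(genome_len_nt <= 0)) stop("genome length must be positive")
  if (any(copies < 0)) stop("copy number must be non-negative")
  copies * genome_len_nt * 1e9 * constants$bp_mass / constants$avogadro
}

#' Relative quantification by the delta-delta-Ct method
#'
#' `RQ = 2^(-ddCt)` with
#' `ddCt = (ct_target_sample - ct_ref_sample) - (ct_target_control - ct_ref_control)`.
#'
#' @param ct_target_sample,ct_ref_sample Target and reference-gene Cts in
#'   the sample of interest.
#' @param ct_target_control,ct_ref_control The same pair in the calibrator.
#' @return Relative quantity (fold change vs the calibrator).
#' @export
relative_quantification <- function(ct_target_sample, ct_ref_sample,
                                    ct_target_control, ct_ref_control) {
  cts <- c(ct_target_sample, ct_ref_sample, ct_target_control, ct_ref_control)
  if (!all(is.finite(cts))) stop("all four Ct values must be finite")
  ddct <- (ct_target_sample - ct_ref_sample) -
    (ct_target_control - ct_ref_control)
  2^(-ddct)
}

#' Cell-culture doubling time
#'
#' `dt = T * ln(2) / ln(Xe / Xb)` for a culture growing from `Xb` to `Xe`
#' cells over elapsed time `T`.
#'
#' @param T_elapsed Elapsed time (any unit; the result is in the same unit).
#' @param Xb Starting cell count, `> 0`.
#' @param Xe Ending cell count, `> Xb`.
#' @return Doubling time in the unit of `T_elapsed`.
#' @export
doubling_time <- function(T_elapsed, Xb, Xe) {
  if (T_elapsed <= 0) stop("elapsed time must be positive")
  if (Xb <= 0 || Xe <= 0) stop("cell counts must be positive")
  if (Xe <= Xb) stop("no net growth: Xe must exceed Xb")
  T_elapsed * log(2) / log(Xe / Xb)
}

#' Caliper tumor volume
#'
#' `TV = width^2 * length / 2` (mm^3), the standard ellipsoid approximation
#' for subcutaneous xenografts.
#'
#' @param width_mm,length_mm Caliper measurements in mm, `>= 0`.
#' @return Tumor volume in mm^3.
#' @export
tumor_volume <- function(width_mm, length_mm) {
  if (any(width_mm < 0) || any(length_mm < 0)) {
    stop("caliper measurements must be non-negative")
  }
  width_mm^2 * length_mm / 2
}

#' Read a qPCR well table (CSV/TSV)
#'
#' Expected columns: `sample_id`, `assay`, `replicate`, `ct`. Ct values
#' `"Undetermined"`, `"N/A"`, `"NA"` or empty are parsed as censored
#' (`NA`). The delimiter is sniffed from the header line (tab wins over
#' comma).
#'
#' @param path Input path.
#' @return Data.frame with columns `sample_id`, `assay`, `replicate`
#'   (integer), `ct` (numeric, `NA` = censored).
#' @export
read_ct_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("Ct table not found: %s", path))
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, colClasses = "character")
  need <- c("sample_id", "assay", "replicate", "ct")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop(sprintf("Ct table missing columns: %s", paste(missing, collapse = ", ")))
  }
  ct_raw <- trimws(df$ct)
  censored <- ct_raw %in% c("", "Undetermined", "N/A", "NA")
  ct <- suppressWarnings(as.numeric(ct_raw))
  bad <- which(!censored & is.na(ct))
  if (length(bad)) {
    stop(sprintf("unparseable Ct value '%s' at data row %d", ct_raw[bad[1L]], bad[1L]))
  }
  ct[censored] <- NA_real_
  data.frame(sample_id = df$sample_id, assay = df$assay,
             replicate = as.integer(df$replicate), ct = ct,
             stringsAsFactors = FALSE)
}

#' Write a qPCR well table as CSV
#'
#' Censored wells (`NA` Ct) are written as `"Undetermined"`, so the file
#' round-trips through [read_ct_table()].
#'
#' @param wells Data.frame with `sample_id`, `assay`, `replicate`, `ct`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ct_table <- function(wells, path) {
  out <- wells[, c("sample_id", "assay", "replicate", "ct")]
  out$ct <- ifelse(is.na(out$ct), "Undetermined", format(out$ct, digits = 15))
  utils::write.table(out, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Quantify species composition for every sample in a well table
#'
#' @param wells Data.frame as from [read_ct_table()] with assay labels
#'   `human_assay` / `mouse_assay`.
#' @param censor_cycle Final cycle (default 40).
#' @param human_assay,mouse_assay Assay labels in the table (defaults
#'   `"human"`, `"mouse"`).
#' @return Data.frame, one row per sample ordered by `sample_id`, columns:
#'   `sample_id`, `n`, `hCt_mean`, `hCt_sem`, `mCt_mean`, `mCt_sem`,
#'   `delta_ct`, `fold`, `human_pct`, `murine_pct`, `detection_flag`,
#'   `detection_floor_pct`.
#' @export
quantify_samples <- function(wells, censor_cycle = 40,
                             human_assay = "human", mouse_assay = "mouse") {
  known <- c(human_assay, mouse_assay)
  unknown <- setdiff(unique(wells$assay), known)
  if (length(unknown)) {
    stop(sprintf("unknown assay label(s): %s (expected %s)",
                 paste(unknown, collapse = ", "), paste(known, collapse = "/")))
  }
  samples <- sort(unique(wells$sample_id))
  if (length(samples) == 0L) stop("empty well table")
  rows <- lapply(samples, function(s) {
    w <- wells[wells$sample_id == s, , drop = FALSE]
    hct <- w$ct[w$assay == human_assay]
    mct <- w$ct[w$assay == mouse_assay]
    if (length(hct) == 0L || length(mct) == 0L) {
      miss <- if (length(hct) == 0L) "human" else "mouse"
      warning(sprintf("sample '%s': no %s-assay wells; treating as fully censored",
                      s, miss), call. = FALSE)
      if (length(hct) == 0L) hct <- NA_real_
      if (length(mct) == 0L) mct <- NA_real_
    }
    est <- composition_from_ct(aggregate_replicates(hct, censor_cycle),
                               aggregate_replicates(mct, censor_cycle),
                               censor_cycle)
    data.frame(sample_id = s, n = est$h_summary$n + est$m_summary$n,
               hCt_mean = est$h_summary$mean_ct, hCt_sem = est$h_summary$sem,
               mCt_mean = est$m_summary$mean_ct, mCt_sem = est$m_summary$sem,
               delta_ct = est$delta_ct, fold = est$fold,
               human_pct = est$hP, murine_pct = est$mP,
               detection_flag = est$detection_flag,
               detection_floor_pct = est$detection_floor,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write a composition report as TSV
#'
#' Percentages are formatted to 4 decimal places; other numeric columns keep
#' full precision.
#'
#' @param report Data.frame from [quantify_samples()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_composition_report <- function(report, path) {
  out <- report
  for (col in c("human_pct", "murine_pct", "detection_floor_pct")) {
    out[[col]] <- ifelse(is.na(out[[col]]), "NA", sprintf("%.4f", out[[col]]))
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
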