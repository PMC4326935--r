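#' Configuration for the synthetic TLDA panel simulator
#'
#' Defaults emulate the structure of a 365-assay TaqMan Low Density Array
#' screen of peripheral-blood miRNA across the lifespan: 30 preterm
#' infants, 66 children, 32 young and 28 middle-aged adults; roughly a
#' third of the panel undetectable in both comparison groups, a third
#' age-constant, and a third differentially expressed, with class
#' fractions 137/104/1/22/20/81 out of 365 (nonexpressed, age-constant,
#' preterm-only, adult-only, down-, up-regulated in adults).
#'
#' @param panel_size Number of target assays (default 365; the endogenous
#'   control is added on top).
#' @param n_preterm,n_children,n_young,n_middle Group sizes (defaults
#'   30 / 66 / 32 / 28).
#' @param class_fractions Named fractions over the six classes; must sum
#'   to 1.
#' @param effect_cycles Planted between-group effect for the up/down
#'   classes, in delta-Ct cycles (default 1.5).
#' @param sigma Within-group delta-Ct standard deviation in cycles
#'   (default 1.0).
#' @param aging_frac Fraction of adult-detectable miRNAs given an
#'   aging-diminution slope (default 0.03).
#' @param aging_slope Delta-Ct increase per year of adult age for
#'   aging-diminished miRNAs (default +0.03 cycles/year, i.e. expression
#'   decline).
#' @param control_mean,control_sd Endogenous-control Ct distribution
#'   (defaults 24 and 0.5 cycles).
#' @param ct_max Detection limit in cycles (default 40).
#' @param baseline_range Range of per-miRNA baseline delta-Ct for
#'   expressed classes (default 2 to 10 cycles).
#' @param offscale_dct Delta-Ct planted for nondetectable states
#'   (default 19 cycles: mean Ct ~3 cycles past the detection limit).
#' @param extra_dropout Extra per-cell dropout probability on top of
#'   limit censoring (default 0).
#' @param seed Integer seed fixing the full output bit-exactly.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(panel_size = 365L, n_preterm = 30L,
                              n_children = 66L, n_young = 32L, n_middle = 28L,
                              class_fractions = c(nonexpressed = 137 / 365,
                                                  age_constant = 104 / 365,
                                                  preterm_only = 1 / 365,
                                                  adult_only = 22 / 365,
                                                  down_in_adult = 20 / 365,
                                                  up_in_adult = 81 / 365),
                              effect_cycles = 1.5, sigma = 1.0,
                              aging_frac = 0.03, aging_slope = 0.03,
                              control_mean = 24, control_sd = 0.5,
                              ct_max = 40, baseline_range = c(2, 10),
                              offscale_dct = 19, extra_dropout = 0,
                              seed = 1L) {
  want <- c("nonexpressed", "age_constant", "preterm_only", "adult_only",
            "down_in_adult", "up_in_adult")
  if (!setequal(names(class_fractions), want))
    stop("class_fractions must be named: ", paste(want, collapse = ", "))
  class_fractions <- class_fractions[want]
  if (abs(sum(class_fractions) - 1) > 1e-9)
    stop("class fractions must sum to 1 (got ",
         format(sum(class_fractions)), ")")
  if (any(class_fractions < 0)) stop("class fractions must be non-negative")
  stopifnot(panel_size >= 1, n_preterm >= 1, n_children >= 0,
            n_young >= 1, n_middle >= 1, effect_cycles >= 0, sigma >= 0,
            aging_frac >= 0, aging_frac < 1, control_sd >= 0, ct_max > 0,
            length(baseline_range) == 2, baseline_range[1] <= baseline_range[2],
            extra_dropout >= 0, extra_dropout < 1)
  structure(list(panel_size = as.integer(panel_size),
                 n_preterm = as.integer(n_preterm),
                 n_children = as.integer(n_children),
                 n_young = as.integer(n_young),
                 n_middle = as.integer(n_middle),
                 class_fractions = class_fractions,
                 effect_cycles = effect_cycles, sigma = sigma,
                 aging_frac = aging_frac, aging_slope = aging_slope,
                 control_mean = control_mean, control_sd = control_sd,
                 ct_max = ct_max, baseline_range = baseline_range,
                 offscale_dct = offscale_dct, extra_dropout = extra_dropout,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

# Apportion panel_size among classes, largest fractional remainder last.
largest_remainder <- function(frac, total) {
  raw <- frac * total
  base <- floor(raw)
  rem <- total - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  stats::setNames(as.integer(base), names(frac))
}

#' Generate a synthetic Ct matrix with planted ground truth
#'
#' Draws a control Ct per sample, plants per-stratum delta-Ct means per
#' miRNA according to its class, adds Gaussian noise, and censors any Ct
#' at or beyond the detection limit. Expressed classes get a per-miRNA
#' baseline delta-Ct; the preterm-only miRNA sits at the detection margin
#' so that roughly two thirds of preterm samples detect it; nondetectable
#' states sit past the limit so detection is sporadic. Aging-diminished
#' miRNAs additionally gain `aging_slope` delta-Ct per year of adult age
#' (centered at the 35-year cutoff). Deterministic under the config seed.
#'
#' @param config A [simulation_config()].
#' @return A list with `ct` (a [ct_matrix()] including the `RNU48`
#'   control column), `meta` (sample metadata), and `truth` (class
#'   `synthetic_truth`: planted class per miRNA, per-stratum delta-Ct
#'   means, aging flags/slopes, and the config).
#' @export
generate_dataset <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  p <- config$panel_size
  n_class <- largest_remainder(config$class_fractions, p)
  classes <- stats::setNames(rep(names(n_class), n_class),
                             sprintf("sim-miR-%03d", seq_len(p)))
  mirna <- names(classes)
  strata <- c("preterm", "child", "young_adult", "middle_adult")

  base <- stats::runif(p, config$baseline_range[1], config$baseline_range[2])
  # detection margin: per-cell preterm detectability ~2/3 for the
  # preterm-only class (qnorm(2/3) ~ 0.43); floored at half a cycle so the
  # plant stays detectable in the noiseless limit
  margin <- config$ct_max - config$control_mean -
    max(stats::qnorm(2 / 3) * sqrt(config$control_sd^2 + config$sigma^2), 0.5)
  off <- config$offscale_dct
  mu <- matrix(off, nrow = p, ncol = 4L, dimnames = list(mirna, strata))
  for (j in seq_len(p)) {
    mu[j, ] <- switch(classes[j],
      nonexpressed  = rep(off, 4L),
      age_constant  = rep(base[j], 4L),
      preterm_only  = c(margin, off, off, off),
      adult_only    = c(off, off, base[j], base[j]),
      down_in_adult = c(base[j], base[j],
                        base[j] + config$effect_cycles,
                        base[j] + config$effect_cycles),
      up_in_adult   = c(base[j], base[j],
                        base[j] - config$effect_cycles,
                        base[j] - config$effect_cycles))
  }
  adult_detectable <- classes %in% c("age_constant", "adult_only",
                                     "down_in_adult", "up_in_adult")
  n_aging <- round(config$aging_frac * sum(adult_detectable))
  slope <- stats::setNames(numeric(p), mirna)
  if (n_aging > 0L)
    slope[sample(mirna[adult_detectable], n_aging)] <- config$aging_slope

  n_pt <- config$n_preterm; n_ch <- config$n_children
  n_yg <- config$n_young; n_md <- config$n_middle
  n <- n_pt + n_ch + n_yg + n_md
  meta <- data.frame(
    sample_id = c(sprintf("PT%03d", seq_len(n_pt)),
                  if (n_ch > 0L) sprintf("CH%03d", seq_len(n_ch)),
                  sprintf("AD%03d", seq_len(n_yg + n_md))),
    group = c(rep("preterm", n_pt), rep("child", n_ch),
              rep("adult", n_yg + n_md)),
    age = c(rep(0, n_pt), if (n_ch > 0L) stats::runif(n_ch, 9, 10),
            stats::runif(n_yg, 21, 35), stats::runif(n_md, 35.5, 61)),
    gender = sample(c("F", "M"), n, replace = TRUE),
    gest_weeks = c(stats::runif(n_pt, 24, 33), rep(NA_real_, n_ch + n_yg + n_md)),
    stringsAsFactors = FALSE)
  stratum_idx <- c(rep(1L, n_pt), rep(2L, n_ch), rep(3L, n_yg), rep(4L, n_md))

  control_ct <- stats::rnorm(n, config$control_mean, config$control_sd)
  age_adj <- ifelse(meta$group == "adult", meta$age - 35, 0)
  expected <- t(mu)[stratum_idx, , drop = FALSE] + outer(age_adj, slope)
  ct <- expected + control_ct +
    matrix(stats::rnorm(n * p, 0, config$sigma), n, p)
  ct[ct >= config$ct_max] <- NA_real_
  if (config$extra_dropout > 0)
    ct[matrix(stats::runif(n * p) < config$extra_dropout, n, p)] <- NA_real_
  ct <- pmax(ct, 0.01)
  dimnames(ct) <- list(meta$sample_id, mirna)
  full <- cbind(ct, RNU48 = pmin(pmax(control_ct, 0.01), config$ct_max))
  truth <- structure(list(class = classes, strata_means = mu,
                          aging = slope != 0, slope = slope,
                          config = config),
                     class = "synthetic_truth")
  list(ct = ct_matrix(full, ct_max = config$ct_max), meta = meta,
       truth = truth)
}

# Fixed pool of plausible cytoband names used to scatter non-cluster loci.
scatter_band_pool <- function() {
  c("1p36.33", "1q21.1", "1p34.2", "2p23.3", "2q13", "2q31.1", "3p21.31",
    "3p24.1", "3q26.2", "4q25", "5p15.33", "5q31.1", "6p21.31", "6q13",
    "6q25.1", "7p15.2", "7q32.2", "8p21.3", "8q12.3", "8q24.21", "9p21.3",
    "10q23.31", "10q24.32", "11p15.5", "11q13.1", "12p13.31", "12q24.11",
    "13q14.2", "13q31.3", "15q26.1", "16p13.3", "16q22.1", "17p13.1",
    "17q21.31", "18q21.2", "19p13.3", "19q13.42", "20p13", "20q13.33",
    "21q22.3", "22q11.21", "22q13.31", "Xp11.23", "Xq26.2")
}

band_chromosome <- function(band) sub("^([0-9XY]+)[pq].*$", "\\1", band)

#' Generate a synthetic genomic annotation with planted hot spots
#'
#' Places the requested same-class clusters on named cytobands and
#' scatters every remaining panel miRNA across a fixed pool of other
#' bands, cycling each class round-robin so no accidental same-class
#' cluster of more than five arises outside the planted ones. Extra loci
#' are duplicated onto additional bands for a random subset of detectable
#' miRNAs, so the total placement count exceeds the panel size (multi-locus
#' miRNAs, as in real miRBase annotations). Coordinates are 1-based
#' inclusive, laid out on synthetic 2-Mb band windows; the matching
#' cytoband intervals are attached as attribute `cytoband_map`.
#'
#' @param truth A `synthetic_truth` from [generate_dataset()].
#' @param hotspot_spec List of planted clusters, each a list with `band`,
#'   `class`, `n` (member count). Defaults to a 16-member age-constant
#'   cluster on 14q32.31 and a 6-member up-in-adult cluster on 9q22.32.
#' @param n_extra_loci Number of additional placements for multi-locus
#'   miRNAs (default 36, mirroring a 264-placements-for-228-miRNAs
#'   accounting when applied to the detectable set).
#' @param seed Seed for the placement randomness (default: config seed
#'   plus one).
#' @return A `mirna_loci` data.frame with attribute `cytoband_map`.
#' @export
generate_annotation <- function(truth,
                                hotspot_spec = list(
                                  list(band = "14q32.31",
                                       class = "age_constant", n = 16L),
                                  list(band = "9q22.32",
                                       class = "up_in_adult", n = 6L)),
                                n_extra_loci = 36L, seed = NULL) {
  stopifnot(inherits(truth, "synthetic_truth"))
  set.seed(if (is.null(seed)) truth$config$seed + 1L else as.integer(seed))
  classes <- truth$class
  hot_bands <- vapply(hotspot_spec, `[[`, character(1L), "band")
  pool <- setdiff(scatter_band_pool(), hot_bands)

  assign_band <- character(0)
  assign_mirna <- character(0)
  used <- character(0)
  for (spec in hotspot_spec) {
    members <- setdiff(names(classes)[classes == spec$class], used)
    if (length(members) < spec$n)
      stop(sprintf("cannot place %d '%s' miRNAs on %s: only %d available",
                   spec$n, spec$class, spec$band, length(members)))
    take <- members[seq_len(spec$n)]
    used <- c(used, take)
    assign_mirna <- c(assign_mirna, take)
    assign_band <- c(assign_band, rep(spec$band, spec$n))
  }
  for (cl in unique(classes)) {
    rem <- setdiff(names(classes)[classes == cl], used)
    if (length(rem) == 0L) next
    bands <- rep(sample(pool), length.out = length(rem))
    assign_mirna <- c(assign_mirna, rem)
    assign_band <- c(assign_band, bands)
  }
  # extra loci: duplicate detectable miRNAs onto further bands, keeping
  # every (band, class) scatter count at or below the cluster threshold
  placement_count <- function(band, cl) {
    sum(assign_band == band & classes[assign_mirna] == cl)
  }
  cand <- names(classes)[classes != "nonexpressed"]
  n_extra <- min(n_extra_loci, length(cand))
  if (n_extra > 0L) {
    for (m in sample(cand, n_extra)) {
      cl <- classes[[m]]
      open <- setdiff(pool, assign_band[assign_mirna == m])
      counts <- vapply(open, placement_count, numeric(1L), cl = cl)
      b <- open[which.min(counts)]
      assign_mirna <- c(assign_mirna, m)
      assign_band <- c(assign_band, b)
    }
  }
  all_bands <- sort(unique(c(pool, hot_bands)))
  registry <- data.frame(band = all_bands,
                         chromosome = band_chromosome(all_bands),
                         stringsAsFactors = FALSE)
  registry <- registry[order(registry$chromosome, registry$band), ]
  idx_in_chrom <- stats::ave(seq_len(nrow(registry)), registry$chromosome,
                             FUN = seq_along)
  registry$start0 <- (idx_in_chrom - 1) * 2e6
  registry$end <- idx_in_chrom * 2e6

  slot <- integer(nrow(registry)); names(slot) <- registry$band
  n_loci <- length(assign_mirna)
  start <- numeric(n_loci)
  for (i in seq_len(n_loci)) {
    b <- assign_band[i]
    slot[b] <- slot[b] + 1L
    start[i] <- registry$start0[registry$band == b] + (slot[b] - 1L) * 1e4 + 1
  }
  loci <- data.frame(mirna_id = assign_mirna,
                     chromosome = band_chromosome(assign_band),
                     start = start, end = start + 79,
                     strand = sample(c("+", "-"), n_loci, replace = TRUE),
                     cytoband = assign_band, stringsAsFactors = FALSE)
  loci <- loci[order(loci$chromosome, loci$start, loci$mirna_id), ]
  rownames(loci) <- NULL
  attr(loci, "cytoband_map") <- registry
  as_mirna_loci(loci)
}

#' Write an annotation as flat TSV
#'
#' @param loci A `mirna_loci` data.frame.
#' @param path Output path.
#' @export
write_annotation <- function(loci, path) {
  stopifnot(inherits(loci, "mirna_loci"))
  utils::write.table(as.data.frame(loci), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write an annotation as miRBase-style GFF3
#'
#' Emits one `miRNA_primary_transcript` record per locus, 1-based
#' inclusive coordinates, `chr`-prefixed seqnames, and `ID`/`Name`
#' attributes (the `Name` is the miRNA id; `ID`s are unique per locus).
#'
#' @param loci A `mirna_loci` data.frame.
#' @param path Output path.
#' @export
write_mirna_gff3 <- function(loci, path) {
  stopifnot(inherits(loci, "mirna_loci"))
  lines <- c("##gff-version 3",
             sprintf("chr%s\t.\tmiRNA_primary_transcript\t%d\t%d\t.\t%s\t.\tID=MI%05d;Name=%s",
                     loci$chromosome, as.integer(loci$start),
                     as.integer(loci$end), loci$strand,
                     seq_len(nrow(loci)), loci$mirna_id))
  writeLines(lines, path)
  invisible(path)
}

#' Write a UCSC-format cytoband map
#'
#' Takes either a `mirna_loci` object carrying a `cytoband_map` attribute
#' (as produced by [generate_annotation()]) or a registry data.frame with
#' columns `band`, `chromosome`, `start0`, `end`. Writes the 0-based
#' half-open five-column `cytoBand.txt` dialect.
#'
#' @param x Loci or registry.
#' @param path Output path.
#' @export
write_cytoband_map <- function(x, path) {
  reg <- if (inherits(x, "mirna_loci")) attr(x, "cytoband_map") else x
  if (is.null(reg)) stop("no cytoband map available")
  lines <- sprintf("chr%s\t%d\t%d\t%s\tgneg",
                   reg$chromosome, as.integer(reg$start0),
                   as.integer(reg$end),
                   sub("^[0-9XY]+", "", reg$band))
  writeLines(lines, path)
  invisible(path)
}

#' Plant a clinical outcome associated with a miRNA's detection state
#'
#' Draws a binary outcome per sample of the named group with probability
#' `p_detected` when the miRNA amplified in that sample and
#' `p_undetected` otherwise, emulating a detection-state/outcome
#' association (e.g. periventricular leukomalacia being rarer among
#' preterm infants expressing a given miRNA). Samples outside the group
#' get `NA`.
#'
#' @param ct A [ct_matrix()].
#' @param meta Sample metadata.
#' @param mirna miRNA id whose detection state drives the outcome.
#' @param group Group in which the outcome is defined
#'   (default `"preterm"`).
#' @param flag Name of the outcome column to add (default `"PVL"`).
#' @param p_detected,p_undetected Outcome probabilities by detection
#'   state (defaults 0.10 and 0.50).
#' @param seed Optional seed.
#' @return `meta` with the logical outcome column added.
#' @export
generate_clinical_flags <- function(ct, meta, mirna, group = "preterm",
                                    flag = "PVL", p_detected = 0.10,
                                    p_undetected = 0.50, seed = NULL) {
  stopifnot(inherits(ct, "ct_matrix"))
  if (!mirna %in% colnames(ct$ct)) stop("miRNA '", mirna, "' not on the panel")
  if (p_detected < 0 || p_detected > 1 || p_undetected < 0 || p_undetected > 1)
    stop("probabilities must lie in [0, 1]")
  ids <- meta$sample_id[meta$group == group]
  if (length(ids) == 0L) stop("no samples in group '", group, "'")
  if (!is.null(seed)) set.seed(seed)
  det <- is.finite(ct$ct[ids, mirna])
  pr <- ifelse(det, p_detected, p_undetected)
  meta[[flag]] <- NA
  meta[[flag]][match(ids, meta$sample_id)] <- stats::runif(length(ids)) < pr
  meta
}
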