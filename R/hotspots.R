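#' Load miRNA genomic annotation
#'
#' Accepts either a miRBase-style GFF3 (1-based inclusive coordinates;
#' `miRNA_primary_transcript` records are used for placement by default)
#' or a flat TSV with columns `mirna_id`, `chromosome`, `start`, `end`,
#' `strand` and optionally `cytoband`. A miRNA may own several loci (one
#' row per genomic placement).
#'
#' Cytobands come from an explicit `cytoband` column or, when
#' `cytoband_map` is given, by interval lookup in a UCSC `cytoBand.txt`
#' file (0-based half-open; converted internally to 1-based inclusive). A
#' locus overlapping several bands is assigned the band of maximal
#' overlap; loci with no resolvable band get `NA` with a warning and are
#' excluded from band-level analyses.
#'
#' @param path Annotation file (`.gff`/`.gff3` or delimited text).
#' @param cytoband_map Optional path to a UCSC-format cytoband file.
#' @param feature GFF3 feature type used for placement
#'   (default `"miRNA_primary_transcript"`; falls back to all records if
#'   absent).
#' @return A data.frame (class `mirna_loci`) with columns `mirna_id`,
#'   `chromosome` (without `chr` prefix), `start`, `end`, `strand`,
#'   `cytoband`.
#' @export
load_annotation <- function(path, cytoband_map = NULL,
                            feature = "miRNA_primary_transcript") {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  if (grepl("\\.gff3?$", path, ignore.case = TRUE)) {
    gr <- rtracklayer::import(path)
    md <- S4Vectors::mcols(gr)
    if ("type" %in% names(md) && any(md$type == feature))
      gr <- gr[md$type == feature]
    md <- S4Vectors::mcols(gr)
    nm <- if ("Name" %in% names(md)) as.character(md$Name)
          else if ("ID" %in% names(md)) as.character(md$ID)
          else stop("GFF3 records carry neither Name nor ID attributes")
    loci <- data.frame(
      mirna_id = nm,
      chromosome = sub("^chr", "", as.character(GenomicRanges::seqnames(gr))),
      start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
      strand = as.character(GenomicRanges::strand(gr)),
      cytoband = NA_character_, stringsAsFactors = FALSE)
  } else {
    tab <- read_delim_auto(path)
    need <- c("mirna_id", "chromosome", "start", "end", "strand")
    miss <- setdiff(need, names(tab))
    if (length(miss) > 0L)
      stop("annotation is missing column(s): ", paste(miss, collapse = ", "))
    loci <- data.frame(
      mirna_id = tab$mirna_id,
      chromosome = sub("^chr", "", tab$chromosome),
      start = as.numeric(tab$start), end = as.numeric(tab$end),
      strand = tab$strand,
      cytoband = if ("cytoband" %in% names(tab)) tab$cytoband else NA_character_,
      stringsAsFactors = FALSE)
  }
  if (nrow(loci) == 0L) return(as_mirna_loci(loci))
  if (any(!is.finite(loci$start)) || any(!is.finite(loci$end)) ||
      any(loci$start > loci$end))
    stop("malformed coordinate(s): start must be a number <= end")
  if (any(!loci$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  if (!is.null(cytoband_map))
    loci$cytoband <- assign_cytobands(loci, read_cytoband_map(cytoband_map))
  n_unbanded <- sum(is.na(loci$cytoband))
  if (n_unbanded > 0L && (!is.null(cytoband_map) || any(!is.na(loci$cytoband))))
    warning(n_unbanded,
            " locus/loci without a resolvable cytoband; excluded from",
            " band-level analyses")
  as_mirna_loci(loci)
}

as_mirna_loci <- function(df) {
  class(df) <- c("mirna_loci", "data.frame")
  df
}

#' Read a UCSC-format cytoband map
#'
#' Five unnamed columns: chrom, chromStart (0-based), chromEnd, band name
#' (e.g. `q32.31`), Giemsa stain. Coordinates are converted to 1-based
#' inclusive and the chromosome prefix is joined onto the band name
#' (`14q32.31`).
#'
#' @param path Path to a `cytoBand.txt`-style file.
#' @return A data.frame with `chromosome`, `start`, `end` (1-based
#'   inclusive), `band`.
#' @export
read_cytoband_map <- function(path) {
  tab <- utils::read.table(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE,
                           col.names = c("chrom", "start0", "end", "name", "stain"))
  chrom <- sub("^chr", "", tab$chrom)
  data.frame(chromosome = chrom, start = tab$start0 + 1L, end = tab$end,
             band = paste0(chrom, tab$name), stringsAsFactors = FALSE)
}

assign_cytobands <- function(loci, map) {
  lgr <- GenomicRanges::GRanges(loci$chromosome,
                                IRanges::IRanges(loci$start, loci$end))
  bgr <- GenomicRanges::GRanges(map$chromosome,
                                IRanges::IRanges(map$start, map$end))
  ov <- GenomicRanges::findOverlaps(lgr, bgr)
  band <- rep(NA_character_, nrow(loci))
  if (length(ov) > 0L) {
    q <- S4Vectors::queryHits(ov); s <- S4Vectors::subjectHits(ov)
    w <- GenomicRanges::width(GenomicRanges::pintersect(lgr[q], bgr[s]))
    o <- order(q, -w)
    keep <- !duplicated(q[o])
    band[q[o][keep]] <- map$band[s[o][keep]]
  }
  band
}

#' Per-band class composition of classified miRNAs
#'
#' Joins expression classes onto genomic placements and counts distinct
#' miRNAs per (chromosome, cytoband, class). A multi-locus miRNA
#' contributes its class once to every band it maps to, so the total
#' placement count can exceed the panel size. The `nonexpressed` and
#' `untestable` classes are excluded (hot-spot scanning concerns the
#' detectable panel); classified miRNAs without a banded locus are
#' tallied in an `unplaced` attribute.
#'
#' @param assignments A `class_assignment` (see
#'   [assign_expression_classes()]).
#' @param loci A `mirna_loci` annotation (see [load_annotation()]).
#' @return A data.frame (class `band_class_table`) with `chromosome`,
#'   `cytoband`, `class`, `n_mirna`, `mirna_ids`. Attributes:
#'   `band_sizes` (distinct detectable miRNAs per band),
#'   `genome_class_counts` (panel-wide class counts over the detectable
#'   set), `genome_total`, `unplaced`.
#' @export
chromosome_class_table <- function(assignments, loci) {
  stopifnot(inherits(loci, "mirna_loci"))
  cls <- stats::setNames(assignments$class, assignments$mirna_id)
  unknown <- setdiff(unique(loci$mirna_id), names(cls))
  if (length(unknown) > 0L) {
    warning(length(unknown), " annotated miRNA(s) absent from the ",
            "classification; their loci are ignored")
    loci <- loci[!loci$mirna_id %in% unknown, , drop = FALSE]
  }
  nondetect <- c("nonexpressed", "untestable")
  genome_counts <- table(assignments$class[!assignments$class %in% nondetect])
  genome_counts <- stats::setNames(as.integer(genome_counts), names(genome_counts))
  placed <- loci[!is.na(loci$cytoband), , drop = FALSE]
  placed <- unique(placed[, c("mirna_id", "chromosome", "cytoband")])
  placed$class <- unname(cls[placed$mirna_id])
  placed <- placed[!placed$class %in% nondetect, , drop = FALSE]
  if (nrow(placed) > 0L) {
    key <- interaction(placed$chromosome, placed$cytoband, placed$class,
                       drop = TRUE, sep = "\r")
    agg <- lapply(split(placed, key), function(d) {
      data.frame(chromosome = d$chromosome[1L], cytoband = d$cytoband[1L],
                 class = d$class[1L], n_mirna = nrow(d),
                 mirna_ids = paste(sort(d$mirna_id), collapse = ","),
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, agg)
    out <- out[order(out$chromosome, out$cytoband, out$class), , drop = FALSE]
    rownames(out) <- NULL
    band_sizes <- tapply(placed$mirna_id, placed$cytoband,
                         function(x) length(unique(x)))
    band_sizes <- stats::setNames(as.integer(band_sizes), names(band_sizes))
  } else {
    out <- data.frame(chromosome = character(), cytoband = character(),
                      class = character(), n_mirna = integer(),
                      mirna_ids = character(), stringsAsFactors = FALSE)
    band_sizes <- integer()
  }
  detectable_ids <- assignments$mirna_id[!assignments$class %in% nondetect]
  attr(out, "band_sizes") <- band_sizes
  attr(out, "genome_class_counts") <- genome_counts
  attr(out, "genome_total") <- length(detectable_ids)
  attr(out, "unplaced") <- setdiff(detectable_ids, placed$mirna_id)
  class(out) <- c("band_class_table", "data.frame")
  out
}

#' Detect cytoband hot spots of same-class miRNAs
#'
#' A hot spot is a cytoband carrying *more than* `cluster_threshold`
#' distinct miRNAs of the same expression class (strictly greater, so the
#' default threshold 5 flags clusters of 6 or more). Each hot spot
#' reports the within-band class proportion, the genome-wide (panel)
#' class proportion for comparison, and a right-tail hypergeometric
#' enrichment p-value.
#'
#' @param band_table A `band_class_table` from
#'   [chromosome_class_table()].
#' @param cluster_threshold Member count that must be exceeded
#'   (default 5).
#' @return A data.frame (class `hotspot_set`) with `cytoband`,
#'   `chromosome`, `class`, `n_members`, `band_total`, `prop_band`,
#'   `genome_class_total`, `genome_total`, `prop_genome`, `p_enrich`,
#'   `mirna_ids`; ordered by band then class (invariant to input row
#'   order).
#' @export
find_hotspots <- function(band_table, cluster_threshold = 5L) {
  stopifnot(inherits(band_table, "band_class_table"))
  band_sizes <- attr(band_table, "band_sizes")
  gcc <- attr(band_table, "genome_class_counts")
  g_total <- attr(band_table, "genome_total")
  hs <- band_table[band_table$n_mirna > cluster_threshold, , drop = FALSE]
  hs <- hs[order(hs$cytoband, hs$class), , drop = FALSE]
  out <- data.frame(
    cytoband = hs$cytoband, chromosome = hs$chromosome, class = hs$class,
    n_members = hs$n_mirna,
    band_total = unname(band_sizes[hs$cytoband]),
    prop_band = hs$n_mirna / unname(band_sizes[hs$cytoband]),
    genome_class_total = unname(gcc[hs$class]),
    genome_total = g_total,
    prop_genome = unname(gcc[hs$class]) / g_total,
    mirna_ids = hs$mirna_ids, stringsAsFactors = FALSE)
  out$p_enrich <- if (nrow(out) > 0L)
    hotspot_enrichment(out$n_members, out$band_total,
                       out$genome_class_total, out$genome_total)
  else numeric()
  rownames(out) <- NULL
  class(out) <- c("hotspot_set", "data.frame")
  out
}

#' Hypergeometric enrichment of a class within a band
#'
#' Right-tail probability of drawing at least `n_same_class` members of a
#' class in a band of `band_size` distinct miRNAs, when `class_total` of
#' the `genome_total` panel miRNAs carry that class. A formal complement
#' to the descriptive proportion comparison.
#'
#' @param n_same_class Observed same-class members in the band.
#' @param band_size Distinct miRNAs in the band.
#' @param class_total Panel-wide class count.
#' @param genome_total Panel-wide detectable count.
#' @return Right-tail hypergeometric p-value(s); vectorized.
#' @export
hotspot_enrichment <- function(n_same_class, band_size, class_total,
                               genome_total) {
  if (any(n_same_class > band_size) || any(n_same_class > class_total) ||
      any(band_size > genome_total) || any(class_total > genome_total))
    stop("inconsistent totals: band/class counts exceed the genome totals")
  stats::phyper(n_same_class - 1, class_total, genome_total - class_total,
                band_size, lower.tail = FALSE)
}
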