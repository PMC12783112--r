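#' Summary statistics of predicted gene models
#'
#' Computes the standard gene-model report: gene/exon/CDS counts and
#' total lengths (1-based inclusive, so a feature spans `end - start +
#' 1` bp), mean gene length, mean exons per gene, and the intron
#' identities for single-transcript models: `n_introns = n_exons -
#' n_genes` and `total_intron_length = total_gene_length -
#' total_exon_length`.
#'
#' @param genes Tibble of gene spans: `gene_id`, `chrom`, `start`,
#'   `end` (and optionally `strand`).
#' @param exons Tibble of exon intervals: `gene_id`, `start`, `end`.
#' @param cds Optional tibble of CDS intervals: `gene_id`, `start`,
#'   `end`.
#' @return One-row tibble: `n_genes`, `total_gene_length`,
#'   `mean_gene_length`, `n_exons`, `total_exon_length`,
#'   `mean_exons_per_gene`, `total_cds_length` (`NA` without `cds`),
#'   `n_introns`, `total_intron_length`, `mean_introns_per_gene`. All
#'   means at full precision; round on report.
#' @export
summarize_annotation <- function(genes, exons, cds = NULL) {
  check_columns(genes, c("gene_id", "chrom", "start", "end"),
                "gene table")
  check_columns(exons, c("gene_id", "start", "end"), "exon table")
  if (any(genes$end < genes$start) || any(exons$end < exons$start))
    abort("feature end must be >= start")
  missing_exons <- setdiff(genes$gene_id, exons$gene_id)
  if (length(missing_exons))
    abort(paste0(length(missing_exons),
                 " gene(s) have no exons (e.g. ", missing_exons[1], ")"))
  n_genes <- nrow(genes)
  n_exons <- nrow(exons)
  total_gene_length <- sum(genes$end - genes$start + 1)
  total_exon_length <- sum(exons$end - exons$start + 1)
  tibble(n_genes = n_genes,
         total_gene_length = total_gene_length,
         mean_gene_length = total_gene_length / n_genes,
         n_exons = n_exons,
         total_exon_length = total_exon_length,
         mean_exons_per_gene = n_exons / n_genes,
         total_cds_length = if (is.null(cds)) NA_real_ else
           sum(cds$end - cds$start + 1),
         n_introns = n_exons - n_genes,
         total_intron_length = total_gene_length - total_exon_length,
         mean_introns_per_gene = (n_exons - n_genes) / n_genes)
}

#' Feature density in fixed genomic windows
#'
#' Tiles each chromosome with half-open windows of `window_size` bp
#' (0-based starts, BED convention; the trailing partial window is
#' included) and counts features by their start coordinate: a 1-based
#' position `pos` falls in window `floor((pos - 1) / window_size)`.
#'
#' @param features Tibble with columns `chrom` and `pos` (1-based).
#' @param chrom_lengths Tibble with columns `chrom` and `length` (bp).
#' @param window_size Window width in bp (default 50,000).
#' @return Tibble `chrom`, `window_start`, `window_end`, `count`,
#'   covering every window of every chromosome in `chrom_lengths`.
#' @export
windowed_density <- function(features, chrom_lengths, window_size = 50000) {
  check_columns(features, c("chrom", "pos"), "feature table")
  check_columns(chrom_lengths, c("chrom", "length"), "chromosome lengths")
  stopifnot(window_size >= 1)
  bad_chrom <- setdiff(features$chrom, chrom_lengths$chrom)
  if (length(bad_chrom))
    abort(paste0("features on unknown chromosome(s): ",
                 paste(bad_chrom, collapse = ", ")))
  lens <- setNames(chrom_lengths$length, chrom_lengths$chrom)
  if (nrow(features) > 0 &&
      (any(features$pos < 1) || any(features$pos > lens[features$chrom])))
    abort("feature positions must lie within [1, chromosome length]")
  windows <- list_rbind(map(seq_len(nrow(chrom_lengths)), function(i) {
    tibble(chrom = chrom_lengths$chrom[i],
           window_start = seq(0, chrom_lengths$length[i] - 1,
                              by = window_size))
  })) |>
    mutate(window_end = pmin(.data$window_start + window_size,
                             lens[.data$chrom]))
  hits <- features |>
    mutate(window_start = floor((.data$pos - 1) / window_size) * window_size) |>
    count(.data$chrom, .data$window_start, name = "count")
  windows |>
    left_join(hits, by = c("chrom", "window_start")) |>
    mutate(count = ifelse(is.na(.data$count), 0L, .data$count)) |>
    arrange(.data$chrom, .data$window_start)
}

#' Span of a genomic interval under the end-minus-start convention
#'
#' Returns `end - start`. Note this is the exclusive-style span, not the
#' 1-based inclusive length (`end - start + 1`) used elsewhere for gene
#' models: it is the convention under which the reported
#' resistance-locus coordinates (598,337..602,501 on chromosome 3)
#' reproduce the quoted 4,164 bp alignment span.
#'
#' @param start,end Coordinates in bp, `end >= start`.
#' @return `end - start` in bp.
#' @export
#' @examples
#' interval_length(598337, 602501)  # 4164
interval_length <- function(start, end) {
  if (any(end < start)) abort("end must be >= start")
  end - start
}
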