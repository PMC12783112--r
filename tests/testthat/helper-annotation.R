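# vectorised synthetic annotation: n genes on one chromosome with given
# per-gene exon counts; exons of fixed length separated by fixed gaps
synth_annotation <- function(exons_per_gene, exon_len = 120,
                             intron_len = 80, spacer = 1000) {
  n <- length(exons_per_gene)
  gene_span <- exons_per_gene * exon_len +
    pmax(exons_per_gene - 1, 0) * intron_len
  gene_start <- cumsum(c(1, head(gene_span + spacer, -1)))
  gene_id <- sprintf("g%06d", seq_len(n))
  genes <- tibble::tibble(gene_id = gene_id, chrom = "Chr01",
                          start = gene_start,
                          end = gene_start + gene_span - 1,
                          strand = "+")
  idx <- rep.int(seq_len(n), exons_per_gene)
  within <- sequence(exons_per_gene) - 1
  exon_start <- gene_start[idx] + within * (exon_len + intron_len)
  exons <- tibble::tibble(gene_id = gene_id[idx], start = exon_start,
                          end = exon_start + exon_len - 1)
  list(genes = genes, exons = exons)
}
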