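# schema check shared by every table-consuming function
check_columns <- function(x, required, what) {
  if (!is.data.frame(x)) abort(paste0(what, " must be a data frame"))
  missing <- setdiff(required, names(x))
  if (length(missing))
    abort(paste0(what, " is missing required column(s): ",
                 paste(missing, collapse = ", ")))
  invisible(x)
}

#' Write genotype calls as a GT-only VCF v4.2
#'
#' One row per site, unphased genotypes. The REF allele is the
#' susceptible parent's allele where that parent is called homozygous,
#' otherwise the lexicographically smallest allele at the site; the
#' remaining alleles become ALT. Missing calls are written `./.`. Sites
#' where no sample is called are dropped. Output is deterministic, with
#' samples in the order parents first (as given), then remaining sample
#' ids sorted.
#'
#' @param calls Genotype-call tibble from [call_genotypes()].
#' @param path Output file path.
#' @param susceptible_parent Optional sample id anchoring the REF
#'   convention.
#' @param parents Parent sample ids, recorded in a `##parents=` header
#'   line.
#' @return Invisibly, `path`.
#' @export
write_vcf <- function(calls, path, susceptible_parent = NULL,
                      parents = character()) {
  check_columns(calls, c("sample_id", "chrom", "pos", "state",
                         "allele1", "allele2"), "genotype-call table")
  samples <- c(parents, sort(setdiff(unique(calls$sample_id), parents)))
  site_alleles <- calls |>
    filter(.data$state != "MISSING") |>
    pivot_longer(c("allele1", "allele2"), values_to = "allele") |>
    distinct(.data$chrom, .data$pos, .data$allele)
  ref_tbl <- if (!is.null(susceptible_parent)) {
    calls |>
      filter(.data$sample_id == susceptible_parent, .data$state == "HOM") |>
      select("chrom", "pos", ref = "allele1")
  } else {
    tibble(chrom = character(), pos = integer(), ref = character())
  }
  sites <- site_alleles |>
    group_by(.data$chrom, .data$pos) |>
    summarise(alleles = list(sort(.data$allele)), .groups = "drop") |>
    left_join(ref_tbl, by = c("chrom", "pos")) |>
    mutate(ref = ifelse(is.na(.data$ref), map_chr(.data$alleles, 1),
                        .data$ref)) |>
    arrange(.data$chrom, .data$pos)
  if (nrow(sites) == 0) {
    lines <- c("##fileformat=VCFv4.2", "##source=gbsmap",
               paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
                      paste(samples, collapse = "\t")))
    writeLines(lines, path)
    return(invisible(path))
  }
  sites$alt <- map2_chr(sites$alleles, sites$ref, function(a, r) {
    alt <- setdiff(a, r)
    if (length(alt) == 0) "." else paste(alt, collapse = ",")
  })
  # genotype index lookup per site
  ord <- map2(sites$alleles, sites$ref,
              function(a, r) c(r, setdiff(a, r)))
  key <- paste(sites$chrom, sites$pos, sep = "\r")
  ord <- setNames(ord, key)
  gt_of <- function(chrom, pos, state, a1, a2) {
    alle <- ord[[paste(chrom, pos, sep = "\r")]]
    if (is.na(state) || state == "MISSING") return("./.")
    i <- match(a1, alle) - 1L
    j <- match(a2, alle) - 1L
    paste(min(i, j), max(i, j), sep = "/")
  }
  wide <- calls |>
    mutate(gt = pmap(list(.data$chrom, .data$pos, .data$state,
                          .data$allele1, .data$allele2), gt_of)) |>
    mutate(gt = unlist(.data$gt)) |>
    select("sample_id", "chrom", "pos", "gt") |>
    pivot_wider(names_from = "sample_id", values_from = "gt")
  miss <- setdiff(samples, names(wide))
  for (s in miss) wide[[s]] <- "./."
  wide <- left_join(sites, wide, by = c("chrom", "pos"))
  for (s in samples) wide[[s]][is.na(wide[[s]])] <- "./."
  body <- paste(wide$chrom, wide$pos, ".", wide$ref, wide$alt, ".", ".",
                ".", "GT",
                do.call(paste, c(wide[samples], sep = "\t")),
                sep = "\t")
  header <- c("##fileformat=VCFv4.2", "##source=gbsmap",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">")
  if (length(parents))
    header <- c(header,
                paste0("##parents=", paste(parents, collapse = ",")))
  header <- c(header,
              paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
                     paste(samples, collapse = "\t")))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a GT-only VCF back into a genotype-call tibble
#'
#' Parses with vcfR and decodes unphased GT fields against REF/ALT.
#' Phased separators (`|`) are accepted and treated as unphased.
#'
#' @param path VCF file path.
#' @return Genotype-call tibble (`sample_id`, `chrom`, `pos`, `state`,
#'   `allele1`, `allele2`) with attribute `parents` when the file
#'   carries a `##parents=` header line.
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) abort(paste0("no such VCF file: ", path))
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  alleles <- map(seq_len(nrow(fix)), function(i) {
    alt <- fix$ALT[i]
    c(fix$REF[i], if (is.na(alt) || alt == ".") character() else
      strsplit(alt, ",", fixed = TRUE)[[1]])
  })
  long <- expand_grid(site = seq_len(nrow(fix)),
                      sample_id = colnames(gt))
  gts <- gt[cbind(long$site, match(long$sample_id, colnames(gt)))]
  idx <- str_split_fixed(gsub("|", "/", gts, fixed = TRUE), "/", 2)
  a1 <- suppressWarnings(as.integer(idx[, 1]))
  a2 <- suppressWarnings(as.integer(idx[, 2]))
  decode <- function(site, k) {
    out <- rep(NA_character_, length(site))
    ok <- !is.na(k)
    out[ok] <- map2_chr(site[ok], k[ok], function(s, kk) alleles[[s]][kk + 1])
    out
  }
  al1 <- decode(long$site, a1)
  al2 <- decode(long$site, a2)
  tibble(sample_id = long$sample_id,
         chrom = fix$CHROM[long$site],
         pos = as.integer(fix$POS[long$site]),
         allele1 = pmin(al1, al2),
         allele2 = pmax(al1, al2)) |>
    mutate(state = case_when(is.na(.data$allele1) ~ "MISSING",
                             .data$allele1 == .data$allele2 ~ "HOM",
                             .default = "HET")) |>
    select("sample_id", "chrom", "pos", "state", "allele1", "allele2") |>
    arrange(.data$chrom, .data$pos, .data$sample_id) -> out
  pl <- grep("^##parents=", v@meta, value = TRUE)
  if (length(pl))
    attr(out, "parents") <- strsplit(sub("^##parents=", "", pl[1]), ",")[[1]]
  out
}

#' Read gene models from a GFF3 file
#'
#' Imports with rtracklayer and flattens to the tables
#' [summarize_annotation()] consumes. When genes carry multiple mRNAs,
#' the longest transcript represents the gene. Files where a feature's
#' end precedes its start are rejected with the offending line number.
#'
#' @param path GFF3 file path.
#' @return List of tibbles `genes` (`gene_id`, `chrom`, `start`, `end`,
#'   `strand`), `exons` and `cds` (`gene_id`, `start`, `end`).
#' @export
read_gff3_genes <- function(path) {
  if (!file.exists(path)) abort(paste0("no such GFF3 file: ", path))
  raw <- readLines(path)
  dat_lines <- which(!startsWith(raw, "#") & nzchar(raw))
  for (i in dat_lines) {
    f <- strsplit(raw[i], "\t", fixed = TRUE)[[1]]
    if (length(f) >= 5) {
      s <- suppressWarnings(as.numeric(f[4]))
      e <- suppressWarnings(as.numeric(f[5]))
      if (!is.na(s) && !is.na(e) && e < s)
        abort(paste0("GFF3 line ", i, ": end (", f[5],
                     ") is before start (", f[4], ")"))
    }
  }
  gr <- rtracklayer::import(path, format = "gff3")
  n <- length(gr)
  ids <- if (is.null(gr$ID)) rep(NA_character_, n) else as.character(gr$ID)
  parent <- if (is.null(gr$Parent)) {
    rep(NA_character_, n)
  } else {
    vapply(as.list(gr$Parent),
           function(p) if (length(p)) as.character(p)[1] else NA_character_,
           character(1))
  }
  d <- tibble(chrom = as.character(GenomicRanges::seqnames(gr)),
              start = GenomicRanges::start(gr),
              end = GenomicRanges::end(gr),
              strand = as.character(GenomicRanges::strand(gr)),
              type = as.character(gr$type),
              id = ids,
              parent = parent)
  genes <- d |>
    filter(.data$type == "gene") |>
    transmute(gene_id = .data$id, chrom = .data$chrom,
              start = .data$start, end = .data$end, strand = .data$strand)
  mrna <- d |>
    filter(.data$type %in% c("mRNA", "transcript")) |>
    transmute(tx_id = .data$id, gene_id = .data$parent,
              tx_len = .data$end - .data$start + 1)
  # longest transcript per gene when several are annotated
  keep_tx <- mrna |>
    group_by(.data$gene_id) |>
    slice_max(.data$tx_len, n = 1, with_ties = FALSE) |>
    ungroup()
  tx_to_gene <- setNames(keep_tx$gene_id, keep_tx$tx_id)
  child <- function(ty) {
    d |>
      filter(.data$type == ty) |>
      mutate(gene_id = ifelse(.data$parent %in% genes$gene_id,
                              .data$parent,
                              tx_to_gene[.data$parent])) |>
      filter(!is.na(.data$gene_id)) |>
      select("gene_id", "start", "end")
  }
  list(genes = genes, exons = child("exon"), cds = child("CDS"))
}

#' Read the plain-text interchange tables
#'
#' Readers for the pipeline's tabular formats, with schema validation
#' that names any missing column.
#'
#' @param path File path.
#' @return A tibble with the table's required columns.
#' @name read_tables
NULL

#' @rdname read_tables
#' @export
read_observations <- function(path) {
  x <- read_tsv(path, show_col_types = FALSE, progress = FALSE)
  check_columns(x, c("sample_id", "chrom", "pos", "allele",
                     "offset_start", "offset_end", "phred"),
                paste0("base-observation file '", path, "'"))
  x
}

#' @rdname read_tables
#' @export
read_phenotypes <- function(path) {
  x <- read_csv(path, show_col_types = FALSE, progress = FALSE)
  check_columns(x, c("genotype_id", "year", "replicate",
                     "shoot_length_mm", "necrosis_length_mm"),
                paste0("phenotype file '", path, "'"))
  x
}

#' @rdname read_tables
#' @export
read_marker_map <- function(path) {
  x <- read_tsv(path, show_col_types = FALSE, progress = FALSE)
  check_columns(x, c("marker_id", "chrom", "pos_bp", "pos_cM",
                     "parent1_gt", "parent2_gt"),
                paste0("marker map file '", path, "'"))
  x
}

#' Write a window track as BED
#'
#' BED is 0-based half-open, matching [windowed_density()] output
#' directly; the count goes in the score column.
#'
#' @param track Tibble from [windowed_density()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_window_bed <- function(track, path) {
  check_columns(track, c("chrom", "window_start", "window_end", "count"),
                "window track")
  readr::write_tsv(track[c("chrom", "window_start", "window_end", "count")],
                   path, col_names = FALSE)
  invisible(path)
}
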