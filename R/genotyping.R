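#' Thresholds for step-1 polymorphic-site discovery
#'
#' A provisional per-sample call is homozygous when the unique top allele
#' is supported by at least `hom_min_reads` reads making up at least
#' `hom_min_fraction` of all reads at the site, and heterozygous when the
#' two most frequent alleles are each supported by at least
#' `het_min_reads_each` reads and at least `het_min_fraction_each` of all
#' reads.
#'
#' @param hom_min_reads,hom_min_fraction Homozygous support thresholds
#'   (defaults 5 reads, 80%).
#' @param het_min_reads_each,het_min_fraction_each Heterozygous per-allele
#'   thresholds (defaults 5 reads, 30%).
#' @return A list of class `discovery_config`.
#' @export
discovery_config <- function(hom_min_reads = 5, hom_min_fraction = 0.80,
                             het_min_reads_each = 5,
                             het_min_fraction_each = 0.30) {
  fr <- c(hom_min_fraction, het_min_fraction_each)
  if (any(fr <= 0 | fr > 1)) abort("fractions must lie in (0, 1]")
  structure(list(hom_min_reads = hom_min_reads,
                 hom_min_fraction = hom_min_fraction,
                 het_min_reads_each = het_min_reads_each,
                 het_min_fraction_each = het_min_fraction_each),
            class = "discovery_config")
}

#' Thresholds for step-2 genotype classification
#'
#' A site in a sample is called homozygous when at least `hom_min_reads`
#' reads support the major allele and they make up at least
#' `hom_min_fraction` of all reads at the site; otherwise heterozygous
#' when at least `het_min_reads_each` reads support each of the two most
#' frequent alleles, each allele individually makes up strictly more than
#' `het_min_fraction_each_exclusive` of all reads, and their combined
#' reads number at least `het_min_combined_reads` while covering at least
#' `het_min_combined_fraction` of all reads; otherwise missing.
#'
#' @param hom_min_reads,hom_min_fraction Homozygous thresholds (5, 90%).
#' @param het_min_reads_each Minimum reads per heterozygous allele (2).
#' @param het_min_fraction_each_exclusive Strict per-allele fraction
#'   bound (20%).
#' @param het_min_combined_reads,het_min_combined_fraction Combined
#'   support thresholds for the allele pair (5 reads, 90%).
#' @return A list of class `caller_config`.
#' @export
caller_config <- function(hom_min_reads = 5, hom_min_fraction = 0.90,
                          het_min_reads_each = 2,
                          het_min_fraction_each_exclusive = 0.20,
                          het_min_combined_reads = 5,
                          het_min_combined_fraction = 0.90) {
  fr <- c(hom_min_fraction, het_min_fraction_each_exclusive,
          het_min_combined_fraction)
  if (any(fr <= 0 | fr > 1)) abort("fractions must lie in (0, 1]")
  structure(list(hom_min_reads = hom_min_reads,
                 hom_min_fraction = hom_min_fraction,
                 het_min_reads_each = het_min_reads_each,
                 het_min_fraction_each_exclusive = het_min_fraction_each_exclusive,
                 het_min_combined_reads = het_min_combined_reads,
                 het_min_combined_fraction = het_min_combined_fraction),
            class = "caller_config")
}

#' Filter base observations and tally allele support
#'
#' Applies the per-base evidence filters: observations whose variant
#' position lies within the first or last `edge_mask_bp` bases of the
#' read are ignored, as are base calls with PHRED quality below
#' `min_phred`. Records with a non-ACGT allele are rejected with a
#' warning. Remaining observations are tallied into per-sample, per-site
#' allele read counts.
#'
#' @param obs Base-observation table with columns `sample_id`, `chrom`,
#'   `pos`, `allele`, `offset_start`, `offset_end`, `phred`.
#' @param edge_mask_bp Read-edge mask width in bp (default 3).
#' @param min_phred Minimum base quality retained (default 20).
#' @return Site-count tibble: `sample_id`, `chrom`, `pos`, `allele`, `n`.
#' @export
#' @examples
#' obs <- tibble::tibble(sample_id = "s1", chrom = "Chr01", pos = 100L,
#'   allele = c("A", "A", "G"), offset_start = c(4L, 3L, 10L),
#'   offset_end = c(70L, 71L, 64L), phred = c(30L, 30L, 19L))
#' filter_observations(obs)  # only the first observation survives
filter_observations <- function(obs, edge_mask_bp = 3, min_phred = 20) {
  required <- c("sample_id", "chrom", "pos", "allele",
                "offset_start", "offset_end", "phred")
  check_columns(obs, required, "base-observation table")
  stopifnot(edge_mask_bp >= 0)
  bad <- !obs$allele %in% .bases
  if (any(bad)) {
    warn(paste0("rejected ", sum(bad),
                " observation(s) with non-ACGT allele"))
    obs <- obs[!bad, ]
  }
  obs |>
    filter(.data$offset_start > edge_mask_bp,
           .data$offset_end > edge_mask_bp,
           .data$phred >= min_phred) |>
    count(.data$sample_id, .data$chrom, .data$pos, .data$allele,
          name = "n") |>
    ungroup()
}

# rank allele counts within each sample x site: top three counts/alleles,
# total depth and allele number. Ties are broken by allele for
# determinism; tie *semantics* (ambiguous major / ambiguous pair) are
# resolved from the count values themselves, so results never depend on
# input order.
rank_site_counts <- function(counts) {
  counts |>
    arrange(.data$sample_id, .data$chrom, .data$pos,
            desc(.data$n), .data$allele) |>
    group_by(.data$sample_id, .data$chrom, .data$pos) |>
    mutate(.rk = row_number(), total = sum(.data$n),
           n_alleles = n()) |>
    ungroup() |>
    filter(.data$.rk <= 3) |>
    pivot_wider(id_cols = c("sample_id", "chrom", "pos", "total",
                            "n_alleles"),
                names_from = ".rk", values_from = c("n", "allele")) |>
    rename(n1 = "n_1", a1 = "allele_1")
}

# make sure the rank columns exist even when no group has 2 or 3 alleles
pad_rank_cols <- function(ranked) {
  for (col in c("n_2", "n_3")) if (!col %in% names(ranked)) ranked[[col]] <- NA_real_
  for (col in c("allele_2", "allele_3")) if (!col %in% names(ranked)) ranked[[col]] <- NA_character_
  ranked |>
    mutate(n2 = ifelse(is.na(.data$n_2), 0, .data$n_2),
           n3 = ifelse(is.na(.data$n_3), 0, .data$n_3),
           a2 = .data$allele_2)
}

# vectorised two-step classification on a ranked count frame
classify_ranked <- function(ranked, cfg) {
  r <- pad_rank_cols(ranked)
  unique_major <- r$n1 > r$n2
  hom <- unique_major &
    r$n1 >= cfg$hom_min_reads &
    ge_frac(r$n1, cfg$hom_min_fraction, r$total)
  # the het candidate pair is the top two alleles; a tie extending to a
  # third allele makes the pair ambiguous -> cannot call het
  pair_ok <- r$n2 > 0 & r$n2 > r$n3
  het <- pair_ok &
    r$n2 >= cfg$het_min_reads_each &
    gt_frac(r$n1, cfg$het_min_fraction_each_exclusive, r$total) &
    gt_frac(r$n2, cfg$het_min_fraction_each_exclusive, r$total) &
    (r$n1 + r$n2) >= cfg$het_min_combined_reads &
    ge_frac(r$n1 + r$n2, cfg$het_min_combined_fraction, r$total)
  r |>
    mutate(state = case_when(hom ~ "HOM", het ~ "HET",
                             .default = "MISSING"),
           allele1 = case_when(hom ~ .data$a1,
                               het ~ pmin(.data$a1, .data$a2),
                               .default = NA_character_),
           allele2 = case_when(hom ~ .data$a1,
                               het ~ pmax(.data$a1, .data$a2),
                               .default = NA_character_)) |>
    select("sample_id", "chrom", "pos", "state", "allele1", "allele2")
}

# provisional discovery calls: allele set supported by each sample under
# the step-1 thresholds (character(0) when the sample is uninformative)
classify_discovery <- function(ranked, cfg) {
  r <- pad_rank_cols(ranked)
  unique_major <- r$n1 > r$n2
  hom <- unique_major &
    r$n1 >= cfg$hom_min_reads &
    ge_frac(r$n1, cfg$hom_min_fraction, r$total)
  pair_ok <- r$n2 > 0 & r$n2 > r$n3
  het <- pair_ok &
    r$n1 >= cfg$het_min_reads_each & r$n2 >= cfg$het_min_reads_each &
    ge_frac(r$n1, cfg$het_min_fraction_each, r$total) &
    ge_frac(r$n2, cfg$het_min_fraction_each, r$total)
  r |>
    mutate(state = case_when(hom ~ "HOM", het ~ "HET",
                             .default = "NONE"),
           allele1 = ifelse(hom | het, .data$a1, NA_character_),
           allele2 = case_when(het ~ .data$a2, hom ~ .data$a1,
                               .default = NA_character_)) |>
    select("sample_id", "chrom", "pos", "state", "allele1", "allele2")
}

#' Identify polymorphic sites (discovery step)
#'
#' Makes a provisional call per sample under [discovery_config()]
#' thresholds and declares a site polymorphic when at least two distinct
#' alleles occur across all provisional calls -- either different
#' homozygous calls in different samples or a single heterozygous call.
#'
#' @param counts Site-count tibble from [filter_observations()].
#' @param cfg A [discovery_config()].
#' @return Tibble of polymorphic sites (`chrom`, `pos`).
#' @export
discover_polymorphic_sites <- function(counts, cfg = discovery_config()) {
  check_columns(counts, c("sample_id", "chrom", "pos", "allele", "n"),
                "site-count table")
  prov <- classify_discovery(rank_site_counts(counts), cfg)
  prov |>
    filter(.data$state != "NONE") |>
    pivot_longer(c("allele1", "allele2"), values_to = "allele") |>
    distinct(.data$chrom, .data$pos, .data$allele) |>
    count(.data$chrom, .data$pos, name = "n_alleles") |>
    filter(.data$n_alleles >= 2) |>
    select("chrom", "pos") |>
    arrange(.data$chrom, .data$pos)
}

#' Classify one sample's allele counts at a site
#'
#' Scalar form of the step-2 caller, convenient for inspection and for
#' oracle checks: homozygous calls require a unique major allele with at
#' least 5 supporting reads covering at least 90% of the site's reads;
#' heterozygous calls require the two top alleles to each have at least 2
#' reads and strictly more than 20% of reads, with combined support of at
#' least 5 reads covering at least 90%; anything else is missing. The two
#' conditions are mutually exclusive for every count vector.
#'
#' @param counts Named integer vector of read counts per allele, e.g.
#'   `c(A = 9, G = 1)`. May be empty.
#' @param cfg A [caller_config()].
#' @return List with elements `state` (`"HOM"`, `"HET"` or `"MISSING"`)
#'   and `alleles` (character vector of length 1, 2 or 0).
#' @export
#' @examples
#' call_genotype(c(A = 9, G = 1))  # HOM A: 9/10 = 90%
#' call_genotype(c(A = 3, G = 3))  # HET A/G
#' call_genotype(c(A = 5, G = 2, C = 1))  # MISSING
call_genotype <- function(counts, cfg = caller_config()) {
  counts <- counts[counts > 0]
  if (length(counts) == 0) return(list(state = "MISSING", alleles = character()))
  if (is.null(names(counts)) || !all(names(counts) %in% .bases))
    abort("counts must be named by alleles A/C/G/T")
  ranked <- tibble(sample_id = "s", chrom = "c", pos = 1L,
                   allele = names(counts), n = as.numeric(counts)) |>
    rank_site_counts()
  out <- classify_ranked(ranked, cfg)
  alleles <- switch(out$state,
                    HOM = out$allele1,
                    HET = c(out$allele1, out$allele2),
                    character())
  list(state = out$state, alleles = alleles)
}

#' Call the genotype matrix over polymorphic sites
#'
#' Runs discovery (step 1) to fix the polymorphic site set, then
#' classifies every sample at every retained site with the step-2 caller.
#' Samples without filtered reads at a retained site are called missing.
#'
#' @param counts Site-count tibble from [filter_observations()].
#' @param caller A [caller_config()].
#' @param discovery A [discovery_config()], or `NULL` to skip discovery
#'   and call every site present in `counts`.
#' @param samples Sample ids to include; defaults to every sample in
#'   `counts` (pass explicitly to include samples with no reads at all).
#' @return Genotype-call tibble ordered by (`chrom`, `pos`, `sample_id`):
#'   `sample_id`, `chrom`, `pos`, `state`, `allele1`, `allele2`. Alleles
#'   are `NA` for missing calls and equal for homozygous calls.
#' @export
call_genotypes <- function(counts, caller = caller_config(),
                           discovery = discovery_config(),
                           samples = NULL) {
  check_columns(counts, c("sample_id", "chrom", "pos", "allele", "n"),
                "site-count table")
  if (anyDuplicated(counts[c("sample_id", "chrom", "pos", "allele")]))
    abort("duplicate (sample, site, allele) rows in count table")
  samples <- samples %||% sort(unique(counts$sample_id))
  sites <- if (is.null(discovery)) {
    distinct(counts, .data$chrom, .data$pos)
  } else {
    discover_polymorphic_sites(counts, discovery)
  }
  if (nrow(sites) == 0) {
    return(tibble(sample_id = character(), chrom = character(),
                  pos = integer(), state = character(),
                  allele1 = character(), allele2 = character()))
  }
  calls <- counts |>
    semi_join(sites, by = c("chrom", "pos")) |>
    rank_site_counts() |>
    classify_ranked(caller)
  sites |>
    cross_join(tibble(sample_id = samples)) |>
    left_join(calls, by = c("sample_id", "chrom", "pos")) |>
    mutate(state = ifelse(is.na(.data$state), "MISSING", .data$state)) |>
    select("sample_id", "chrom", "pos", "state", "allele1", "allele2") |>
    arrange(.data$chrom, .data$pos, .data$sample_id)
}
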