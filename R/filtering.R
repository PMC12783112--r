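#' Per-site summaries of a genotype-call matrix
#'
#' Computes, per site, the quantities the post-calling filters consume:
#' call rate, observed alleles, allele frequencies from called genotypes
#' (two allele draws per called sample), number of distinct genotype
#' classes, minor allele frequency and heterozygosity rate. Flagged
#' parent samples are excluded by default, since segregation-based
#' filters describe the progeny.
#'
#' @param calls Genotype-call tibble from [call_genotypes()].
#' @param parents Sample ids to exclude from the summary (default none).
#' @return One row per site: `chrom`, `pos`, `n_samples`, `n_called`,
#'   `call_rate`, `n_alleles`, `allele_a`, `allele_b` (major and minor
#'   allele; `NA` beyond the observed alleles), `p` and `q` (their
#'   frequencies), `maf`, `het_rate`, `n_genotype_classes`, `degenerate`
#'   (`TRUE` when no sample is called).
#' @export
#' @examples
#' calls <- tibble::tibble(
#'   sample_id = paste0("s", 1:4), chrom = "Chr01", pos = 10L,
#'   state = c("HOM", "HOM", "HET", "MISSING"),
#'   allele1 = c("A", "A", "A", NA), allele2 = c("A", "A", "G", NA))
#' summarize_sites(calls)
summarize_sites <- function(calls, parents = character()) {
  check_columns(calls, c("sample_id", "chrom", "pos", "state",
                         "allele1", "allele2"), "genotype-call table")
  x <- filter(calls, !.data$sample_id %in% parents)
  if (nrow(x) == 0) abort("no samples left after excluding parents")
  base <- x |>
    group_by(.data$chrom, .data$pos) |>
    summarise(n_samples = n(),
              n_called = sum(.data$state != "MISSING"),
              call_rate = .data$n_called / .data$n_samples,
              het_rate = ifelse(.data$n_called > 0,
                                sum(.data$state == "HET") / .data$n_called,
                                NA_real_),
              n_genotype_classes = n_distinct(
                paste(.data$allele1, .data$allele2)[.data$state != "MISSING"]),
              .groups = "drop")
  freqs <- x |>
    filter(.data$state != "MISSING") |>
    pivot_longer(c("allele1", "allele2"), values_to = "allele") |>
    count(.data$chrom, .data$pos, .data$allele, name = "n_draws") |>
    group_by(.data$chrom, .data$pos) |>
    arrange(desc(.data$n_draws), .data$allele, .by_group = TRUE) |>
    summarise(n_alleles = n(),
              allele_a = .data$allele[1],
              allele_b = .data$allele[2],
              p = .data$n_draws[1] / sum(.data$n_draws),
              q = ifelse(n() >= 2, .data$n_draws[2] / sum(.data$n_draws),
                         0),
              .groups = "drop")
  base |>
    left_join(freqs, by = c("chrom", "pos")) |>
    mutate(degenerate = .data$n_called == 0,
           n_alleles = ifelse(.data$degenerate, 0L, .data$n_alleles),
           maf = ifelse(.data$n_alleles == 2, pmin(.data$p, .data$q),
                        NA_real_)) |>
    select("chrom", "pos", "n_samples", "n_called", "call_rate",
           "n_alleles", "allele_a", "allele_b", "p", "q", "maf",
           "het_rate", "n_genotype_classes", "degenerate") |>
    arrange(.data$chrom, .data$pos)
}

#' Upper bound for the per-site heterozygosity rate
#'
#' The filter accepts observed heterozygosity only up to the
#' Hardy-Weinberg expectation plus a slack: `2 * p * q + slack`, capped
#' at 1.
#'
#' @param p,q Allele frequencies; must sum to 1.
#' @param slack Additive slack (default 0.20).
#' @return The bound as a fraction in \[0, 1\].
#' @export
#' @examples
#' het_upper_bound(0.5, 0.5)  # 0.7
#' het_upper_bound(0.3, 0.7)  # 0.62
het_upper_bound <- function(p, q, slack = 0.20) {
  if (any(p < 0) || any(q < 0)) abort("allele frequencies must be >= 0")
  if (any(abs(p + q - 1) > 1e-8)) abort("allele frequencies must sum to 1")
  pmin(2 * p * q + slack, 1)
}

#' Apply the post-calling site filters
#'
#' Keeps a site when all of the following hold: call rate at least
#' `min_call_rate`, exactly `required_allele_number` observed alleles, at
#' least `min_genotype_classes` distinct genotype classes, minor allele
#' frequency at least `min_maf`, and heterozygosity rate between 0 and
#' `2pq + het_bound_slack`. The filters are conjunctive; the reported
#' `reason` for a dropped site is the first failing check in the fixed
#' order call_rate, allele_number, genotype_classes, maf, het_range.
#'
#' @param summaries Site summaries from [summarize_sites()].
#' @param min_call_rate Minimum fraction of samples called (default 0.50).
#' @param required_allele_number Exact observed allele count (default 2).
#' @param min_genotype_classes Minimum distinct genotype classes (2).
#' @param min_maf Minimum minor allele frequency (default 0.10).
#' @param het_bound_slack Slack passed to [het_upper_bound()] (0.20).
#' @return `summaries` with added columns `het_bound`, `kept` and
#'   `reason` (`NA` for kept sites).
#' @export
apply_site_filters <- function(summaries, min_call_rate = 0.50,
                               required_allele_number = 2,
                               min_genotype_classes = 2,
                               min_maf = 0.10,
                               het_bound_slack = 0.20) {
  check_columns(summaries, c("chrom", "pos", "call_rate", "n_alleles",
                             "n_genotype_classes", "maf", "het_rate",
                             "p", "q"), "site-summary table")
  summaries |>
    mutate(
      het_bound = ifelse(.data$n_alleles == 2,
                         pmin(2 * .data$p * .data$q + het_bound_slack, 1),
                         NA_real_),
      .f_call_rate = .data$call_rate < min_call_rate,
      .f_allele_number = .data$n_alleles != required_allele_number,
      .f_genotype_classes = .data$n_genotype_classes < min_genotype_classes,
      .f_maf = is.na(.data$maf) | .data$maf < min_maf - .frac_eps,
      .f_het_range = is.na(.data$het_rate) | .data$het_rate < 0 |
        .data$het_rate > .data$het_bound + .frac_eps,
      kept = !(.data$.f_call_rate | .data$.f_allele_number |
                 .data$.f_genotype_classes | .data$.f_maf |
                 .data$.f_het_range),
      reason = case_when(.data$.f_call_rate ~ "call_rate",
                         .data$.f_allele_number ~ "allele_number",
                         .data$.f_genotype_classes ~ "genotype_classes",
                         .data$.f_maf ~ "maf",
                         .data$.f_het_range ~ "het_range",
                         .default = NA_character_)) |>
    select(-starts_with(".f_"))
}

#' Imputation pass-through
#'
#' The study pipeline imputes residual missing genotypes with an external
#' phasing-based imputer before downstream use. That step is outside this
#' package's scope; this stub marks where such an imputer would slot into
#' [run_pipeline()] and returns the calls unchanged, preserving missing
#' values.
#'
#' @param calls Genotype-call tibble.
#' @param method Only `"none"` is implemented.
#' @return `calls`, unchanged.
#' @export
impute_genotypes <- function(calls, method = "none") {
  method <- match.arg(method)
  calls
}
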