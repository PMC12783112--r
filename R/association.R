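#' Split progeny into allele groups using the susceptible parent
#'
#' At a biallelic SNP the non-reference allele is the allele not carried
#' homozygously by the susceptible reference parent; group 1 contains
#' the called progeny carrying at least one non-reference allele,
#' group 2 the remaining called progeny. Sites where the reference
#' parent is heterozygous or missing, sites that are not biallelic among
#' the calls, and sites where a group would be empty are skipped with a
#' reason code.
#'
#' @param site_calls Genotype calls for a single site (one `chrom`/`pos`
#'   combination), including the parent row(s).
#' @param susceptible_parent Sample id of the susceptible reference
#'   parent.
#' @param parents All parent sample ids to exclude from the progeny
#'   groups (defaults to just the susceptible parent).
#' @return A list: `ok` (logical), `reason` (`NA` when grouped, else one
#'   of `no_reference_call`, `ambiguous_reference`, `monomorphic`,
#'   `multiallelic`, `reference_allele_absent`, `degenerate_grouping`),
#'   `ref_allele`, `alt_allele`, `group1`, `group2` (sample-id vectors).
#' @export
group_by_allele <- function(site_calls, susceptible_parent,
                            parents = susceptible_parent) {
  if (nrow(site_calls) == 0 ||
      nrow(unique(site_calls[c("chrom", "pos")])) != 1)
    abort("site_calls must contain calls for exactly one site")
  skip <- function(reason) list(ok = FALSE, reason = reason,
                                ref_allele = NA_character_,
                                alt_allele = NA_character_,
                                group1 = character(), group2 = character())
  pr <- site_calls[site_calls$sample_id == susceptible_parent, ]
  if (nrow(pr) != 1 || pr$state == "MISSING")
    return(skip("no_reference_call"))
  if (pr$state == "HET") return(skip("ambiguous_reference"))
  prog <- site_calls[!site_calls$sample_id %in% parents &
                       site_calls$state != "MISSING", ]
  alleles <- unique(c(prog$allele1, prog$allele2, pr$allele1))
  if (length(alleles) < 2) return(skip("monomorphic"))
  if (length(alleles) > 2) return(skip("multiallelic"))
  ref <- pr$allele1
  if (!ref %in% alleles) return(skip("reference_allele_absent"))
  alt <- setdiff(alleles, ref)
  carrier <- prog$allele1 == alt | prog$allele2 == alt
  out <- list(ok = TRUE, reason = NA_character_, ref_allele = ref,
              alt_allele = alt,
              group1 = prog$sample_id[carrier],
              group2 = prog$sample_id[!carrier])
  if (length(out$group1) == 0 || length(out$group2) == 0)
    return(skip("degenerate_grouping"))
  out
}

# exact two-sided rank-sum p by dynamic programming over the number of
# size-n1 subsets of ranks 1..N attaining each rank sum (equivalent to
# full enumeration of the C(N, n1) equally likely assignments)
exact_ranksum_p <- function(W, n1, n2) {
  N <- n1 + n2
  smax <- sum((n2 + 1):N)
  f <- matrix(0, n1 + 1, smax + 1)
  f[1, 1] <- 1
  for (i in seq_len(N)) {
    for (k in min(i, n1):1) {
      f[k + 1, (i + 1):(smax + 1)] <-
        f[k + 1, (i + 1):(smax + 1)] + f[k, 1:(smax + 1 - i)]
    }
  }
  counts <- f[n1 + 1, ]
  total <- sum(counts)
  p_le <- sum(counts[1:(W + 1)]) / total
  p_ge <- sum(counts[(W + 1):(smax + 1)]) / total
  min(1, 2 * min(p_le, p_ge))
}

#' Wilcoxon rank-sum test with an exact/approximate switch
#'
#' Ranks use midranks for ties. When both groups are no larger than
#' `exact_max_n` and there are no ties, the two-sided p-value is exact,
#' computed from the full null distribution of the rank sum over all
#' equally likely rank assignments (two-sided p = min(1, 2 x smaller
#' tail)). Otherwise a normal approximation with tie-corrected variance
#' and continuity correction is used. A fully tied comparison has zero
#' rank-sum variance and returns p = 1.
#'
#' @param x,y Numeric response values for the two groups (non-empty).
#' @param exact_max_n Largest per-group size for the exact path (25).
#' @return List with `W` (rank sum of `x`), `p` (two-sided), and
#'   `method` (`"exact"` or `"normal"`).
#' @export
#' @examples
#' wilcoxon_rank_sum(c(10, 20, 30), c(40, 50, 60))$p  # 0.1, exact
wilcoxon_rank_sum <- function(x, y, exact_max_n = 25) {
  n1 <- length(x)
  n2 <- length(y)
  if (n1 == 0 || n2 == 0) abort("both groups must be non-empty")
  pooled <- c(x, y)
  r <- rank(pooled)
  W <- sum(r[seq_len(n1)])
  ties <- anyDuplicated(pooled) > 0
  if (!ties && n1 <= exact_max_n && n2 <= exact_max_n) {
    return(list(W = W, p = exact_ranksum_p(W, n1, n2), method = "exact"))
  }
  N <- n1 + n2
  mu <- n1 * (N + 1) / 2
  tie_sizes <- table(r)
  v <- n1 * n2 / 12 * ((N + 1) - sum(tie_sizes^3 - tie_sizes) / (N * (N - 1)))
  if (v <= 0) return(list(W = W, p = 1, method = "normal"))
  z <- (W - mu - sign(W - mu) * 0.5) / sqrt(v)
  list(W = W, p = min(1, 2 * pnorm(-abs(z))), method = "normal")
}

#' Bonferroni genome-wide significance threshold
#'
#' The threshold on the -log10(p) scale for family-wise error rate
#' `alpha` over `n_tests` tests: `-log10(alpha / n_tests)`.
#'
#' @param n_tests Number of SNPs tested (>= 1).
#' @param alpha Family-wise error rate (default 0.01).
#' @return Threshold on the -log10 scale.
#' @export
#' @examples
#' bonferroni_threshold(100)     # 4
#' bonferroni_threshold(319620)  # ~7.50
bonferroni_threshold <- function(n_tests, alpha = 0.01) {
  if (length(n_tests) != 1 || is.na(n_tests) || n_tests < 1)
    abort("n_tests must be a single value >= 1")
  if (alpha <= 0 || alpha >= 1) abort("alpha must lie in (0, 1)")
  -log10(alpha / n_tests)
}

#' Genome-wide allele-group Wilcoxon scan of mean PLL
#'
#' For every SNP with minor allele frequency at least `min_maf` among
#' the tested progeny, progeny are split into carrier/non-carrier groups
#' of the non-reference allele (the allele not carried homozygously by
#' the susceptible parent; see [group_by_allele()]) and their mean PLL
#' values are compared with the Wilcoxon rank-sum test. The genome-wide
#' threshold is `-log10(alpha / N)` with `N` the number of SNPs actually
#' tested.
#'
#' @param calls Genotype-call tibble (progeny and parents).
#' @param pll_table Per-genotype mean PLL from [aggregate_pll()] (uses
#'   the `pll_mean` column).
#' @param susceptible_parent Sample id of the susceptible parent.
#' @param parents All parent sample ids (excluded from the groups).
#' @param min_maf Scan MAF filter on tested progeny (default 0.05).
#' @param alpha Family-wise error rate for the threshold (default 0.01).
#' @param exact_max_n Passed to [wilcoxon_rank_sum()].
#' @return A `gbs_scan` object: list with `results` (tibble `snp_id`,
#'   `chrom`, `pos`, `n_group1`, `n_group2`, `W`, `p`, `neg_log10_p`,
#'   `significant`), `skipped` (tibble `chrom`, `pos`, `reason`),
#'   `n_tested`, `threshold`, `alpha`, `min_maf`. Use [tidy()],
#'   [glance()] and [autoplot()] on it.
#' @export
run_scan <- function(calls, pll_table, susceptible_parent,
                     parents = susceptible_parent, min_maf = 0.05,
                     alpha = 0.01, exact_max_n = 25) {
  check_columns(calls, c("sample_id", "chrom", "pos", "state",
                         "allele1", "allele2"), "genotype-call table")
  check_columns(pll_table, c("genotype_id", "pll_mean"), "PLL table")
  pheno <- pll_table |>
    filter(!is.na(.data$pll_mean), !.data$genotype_id %in% parents)
  phen <- setNames(pheno$pll_mean, pheno$genotype_id)
  keep <- calls$sample_id == susceptible_parent |
    (!calls$sample_id %in% parents & calls$sample_id %in% names(phen))
  x <- calls[keep, ]
  if (!any(x$sample_id %in% names(phen)))
    abort("no phenotyped progeny overlap the genotype calls")
  site_key <- paste(x$chrom, x$pos, sep = "\r")
  sites <- split(seq_len(nrow(x)), site_key)
  res <- vector("list", length(sites))
  skipped <- vector("list", length(sites))
  for (i in seq_along(sites)) {
    sc <- x[sites[[i]], ]
    grp <- group_by_allele(sc, susceptible_parent, parents)
    chrom <- sc$chrom[1]
    pos <- sc$pos[1]
    if (grp$ok) {
      # MAF among the tested (called, phenotyped) progeny, from the two
      # allele draws per called sample
      called <- sc[!sc$sample_id %in% parents & sc$state != "MISSING", ]
      draws <- c(called$allele1, called$allele2)
      f_alt <- mean(draws == grp$alt_allele)
      if (min(f_alt, 1 - f_alt) < min_maf - .frac_eps) {
        grp <- list(ok = FALSE, reason = "maf")
      }
    }
    if (!grp$ok) {
      skipped[[i]] <- tibble(chrom = chrom, pos = pos, reason = grp$reason)
      next
    }
    wt <- wilcoxon_rank_sum(phen[grp$group1], phen[grp$group2],
                            exact_max_n = exact_max_n)
    res[[i]] <- tibble(snp_id = paste(chrom, pos, sep = "_"),
                       chrom = chrom, pos = pos,
                       n_group1 = length(grp$group1),
                       n_group2 = length(grp$group2),
                       W = wt$W, p = wt$p,
                       neg_log10_p = -log10(wt$p))
  }
  results <- list_rbind(res[!vapply(res, is.null, logical(1))])
  skipped <- list_rbind(skipped[!vapply(skipped, is.null, logical(1))])
  if (is.null(results) || nrow(results) == 0) {
    results <- tibble(snp_id = character(), chrom = character(),
                      pos = integer(), n_group1 = integer(),
                      n_group2 = integer(), W = numeric(), p = numeric(),
                      neg_log10_p = numeric(), significant = logical())
    threshold <- NA_real_
    n_tested <- 0L
  } else {
    n_tested <- nrow(results)
    threshold <- bonferroni_threshold(n_tested, alpha)
    results <- results |>
      mutate(significant = .data$neg_log10_p >= threshold) |>
      arrange(.data$chrom, .data$pos)
  }
  if (is.null(skipped) || ncol(skipped) == 0)
    skipped <- tibble(chrom = character(), pos = integer(),
                      reason = character())
  structure(list(results = results,
                 skipped = arrange(skipped, .data$chrom, .data$pos),
                 n_tested = n_tested, threshold = threshold,
                 alpha = alpha, min_maf = min_maf),
            class = "gbs_scan")
}

#' @export
print.gbs_scan <- function(x, ...) {
  cat("Allele-group Wilcoxon scan\n")
  cat("  SNPs tested:     ", x$n_tested, "\n")
  cat("  SNPs skipped:    ", nrow(x$skipped), "\n")
  cat("  -log10 threshold:", format(x$threshold, digits = 4),
      sprintf("(alpha = %g)\n", x$alpha))
  if (x$n_tested > 0) {
    top <- x$results[which.max(x$results$neg_log10_p), ]
    cat(sprintf("  top SNP: %s  -log10(p) = %.2f  (%s)\n", top$snp_id,
                top$neg_log10_p,
                if (top$significant) "significant" else "not significant"))
  }
  invisible(x)
}

#' @rdname run_scan
#' @param x A `gbs_scan` object.
#' @param ... Unused.
#' @method tidy gbs_scan
#' @export
tidy.gbs_scan <- function(x, ...) x$results

#' @rdname run_scan
#' @method glance gbs_scan
#' @export
glance.gbs_scan <- function(x, ...) {
  top <- if (x$n_tested > 0) x$results[which.max(x$results$neg_log10_p), ] else NULL
  tibble(n_tested = x$n_tested,
         n_skipped = nrow(x$skipped),
         n_significant = sum(x$results$significant),
         threshold = x$threshold,
         alpha = x$alpha,
         min_maf = x$min_maf,
         top_snp = if (is.null(top)) NA_character_ else top$snp_id,
         top_neg_log10_p = if (is.null(top)) NA_real_ else top$neg_log10_p)
}

#' Manhattan plot of a scan
#'
#' Per-SNP -log10(p) against cumulative genomic position, chromosomes in
#' alternating shades, with the Bonferroni threshold as a dashed line.
#'
#' @param object A `gbs_scan` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gbs_scan <- function(object, ...) {
  res <- object$results
  if (nrow(res) == 0) abort("nothing to plot: no SNPs were tested")
  offsets <- res |>
    group_by(.data$chrom) |>
    summarise(len = max(.data$pos), .groups = "drop") |>
    arrange(.data$chrom) |>
    mutate(offset = cumsum(dplyr::lag(.data$len, default = 0)))
  dat <- res |>
    left_join(offsets, by = "chrom") |>
    mutate(x = .data$pos + .data$offset,
           shade = factor(as.integer(factor(.data$chrom)) %% 2))
  centers <- dat |>
    group_by(.data$chrom) |>
    summarise(mid = mean(range(.data$x)), .groups = "drop")
  ggplot2::ggplot(dat, ggplot2::aes(.data$x, .data$neg_log10_p,
                                    colour = .data$shade)) +
    ggplot2::geom_point(size = 0.8, show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = object$threshold,
                        linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c("grey40", "steelblue")) +
    ggplot2::scale_x_continuous(breaks = centers$mid,
                                labels = centers$chrom) +
    ggplot2::labs(x = NULL, y = expression(-log[10](italic(p)))) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
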