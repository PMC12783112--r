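# Independent straight-line transcription of the printed two-step
# classification rules, used as the oracle for the vectorised caller.
# Homozygous: unique most-common allele supported by >= 5 reads making up
# >= 90% of all reads. Heterozygous: two most common alleles each with
# >= 2 reads, each strictly > 20% of all reads, combined >= 5 reads and
# >= 90% of all reads; an ambiguous top pair (a tie extending to a third
# allele) cannot be called. Otherwise missing.
oracle_call <- function(cnt, hom_reads = 5, hom_frac = 0.9,
                        het_reads = 2, het_frac_excl = 0.2,
                        comb_reads = 5, comb_frac = 0.9) {
  cnt <- cnt[cnt > 0]
  tot <- sum(cnt)
  if (length(cnt) == 0) return(list(state = "MISSING", alleles = character()))
  ord <- names(cnt)[order(-cnt, names(cnt))]
  n1 <- cnt[[ord[1]]]
  if ((length(ord) == 1 || n1 > cnt[[ord[2]]]) &&
      n1 >= hom_reads && n1 / tot >= hom_frac)
    return(list(state = "HOM", alleles = ord[1]))
  if (length(ord) >= 2) {
    n2 <- cnt[[ord[2]]]
    pair_unambiguous <- length(ord) < 3 || n2 > cnt[[ord[3]]]
    if (pair_unambiguous && n1 >= het_reads && n2 >= het_reads &&
        n1 / tot > het_frac_excl && n2 / tot > het_frac_excl &&
        (n1 + n2) >= comb_reads && (n1 + n2) / tot >= comb_frac)
      return(list(state = "HET", alleles = sort(ord[1:2])))
  }
  list(state = "MISSING", alleles = character())
}

# do the homozygous / heterozygous conditions fire, evaluated
# independently (no if/else shortcut) -- for the mutual-exclusivity check
oracle_conditions <- function(cnt) {
  cnt <- cnt[cnt > 0]
  tot <- sum(cnt)
  if (length(cnt) == 0) return(c(hom = FALSE, het = FALSE))
  ord <- names(cnt)[order(-cnt, names(cnt))]
  n1 <- cnt[[ord[1]]]
  hom <- (length(ord) == 1 || n1 > cnt[[ord[2]]]) &&
    n1 >= 5 && n1 / tot >= 0.9
  het <- FALSE
  if (length(ord) >= 2) {
    n2 <- cnt[[ord[2]]]
    het <- (length(ord) < 3 || n2 > cnt[[ord[3]]]) &&
      n1 >= 2 && n2 >= 2 && n1 / tot > 0.2 && n2 / tot > 0.2 &&
      (n1 + n2) >= 5 && (n1 + n2) / tot >= 0.9
  }
  c(hom = hom, het = het)
}

# every read-count vector over three alleles with total depth <= max_depth
enumerate_count_vectors <- function(max_depth = 15,
                                    alleles = c("A", "C", "G")) {
  grid <- expand.grid(a = 0:max_depth, b = 0:max_depth, c = 0:max_depth)
  grid <- grid[rowSums(grid) <= max_depth, ]
  lapply(seq_len(nrow(grid)), function(i) {
    v <- c(grid$a[i], grid$b[i], grid$c[i])
    names(v) <- alleles
    v
  })
}

# brute-force two-sided rank-sum p by explicit enumeration of all
# C(n1+n2, n1) rank assignments (tie-free data only)
brute_wilcox_p <- function(x, y) {
  n1 <- length(x)
  N <- n1 + length(y)
  W <- sum(rank(c(x, y))[seq_len(n1)])
  sums <- combn(N, n1, FUN = sum)
  min(1, 2 * min(mean(sums <= W), mean(sums >= W)))
}

# site-count tibble from a list of named per-sample count vectors,
# all at one site
make_counts <- function(per_sample, chrom = "Chr01", pos = 100L) {
  purrr::list_rbind(purrr::imap(per_sample, function(cnt, id) {
    tibble::tibble(sample_id = id, chrom = chrom, pos = pos,
                   allele = names(cnt), n = as.numeric(cnt))
  }))
}

# genotype-call tibble from compact strings like "A/G", "A/A", NA
make_calls <- function(gts, chrom = "Chr01", pos = 100L,
                       sample_ids = sprintf("s%02d", seq_along(gts))) {
  a <- stringr::str_split_fixed(ifelse(is.na(gts), "NA/NA", gts), "/", 2)
  a[a == "NA"] <- NA
  tibble::tibble(sample_id = sample_ids, chrom = chrom, pos = pos,
                 state = dplyr::case_when(is.na(gts) ~ "MISSING",
                                          a[, 1] == a[, 2] ~ "HOM",
                                          .default = "HET"),
                 allele1 = pmin(a[, 1], a[, 2]),
                 allele2 = pmax(a[, 1], a[, 2]))
}

# two-marker map with explicit parental genotypes, for segregation tests
make_map <- function(parent1_gt, parent2_gt, pos_cM = NULL,
                     chrom = "Chr01") {
  m <- length(parent1_gt)
  pos <- as.integer(seq(1e5, by = 1e6, length.out = m))
  tibble::tibble(marker_id = sprintf("m%02d", seq_len(m)), chrom = chrom,
                 pos_bp = pos,
                 pos_cM = pos_cM %||% (pos / 1e6 * 4),
                 parent1_gt = parent1_gt, parent2_gt = parent2_gt)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# one association-scan replicate on truth-derived (noiseless) genotype
# calls under a given simulation configuration
scan_truth_replicate <- function(cfg) {
  map <- sim_marker_map(cfg)
  truth <- simulate_cross(map, cfg)
  pheno <- simulate_phenotypes(truth, cfg)
  scan <- run_scan(genotypes_from_truth(truth), aggregate_pll(pheno),
                   susceptible_parent = cfg$parent_ids[1],
                   parents = cfg$parent_ids)
  qtl_id <- attr(truth, "qtl_marker_id")
  list(scan = scan,
       qtl_chrom = map$chrom[map$marker_id == qtl_id],
       qtl_pos = map$pos_bp[map$marker_id == qtl_id])
}
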