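obs_row <- function(offset_start = 10L, offset_end = 60L, phred = 30L,
                    allele = "A", sample_id = "s1") {
  tibble::tibble(sample_id = sample_id, chrom = "Chr01", pos = 100L,
                 allele = allele, offset_start = offset_start,
                 offset_end = offset_end, phred = phred)
}

test_that("read-edge mask and base-quality threshold are applied as printed", {
  obs <- dplyr::bind_rows(
    obs_row(offset_start = 3L),                 # within first 3 bp -> dropped
    obs_row(offset_start = 4L, offset_end = 70L, phred = 30L),  # kept
    obs_row(offset_end = 3L),                   # within last 3 bp -> dropped
    obs_row(phred = 19L),                       # below Q20 -> dropped
    obs_row(phred = 20L))                       # at Q20 -> kept
  counts <- filter_observations(obs)
  expect_equal(sum(counts$n), 2)
  # empty input stays empty
  expect_equal(nrow(filter_observations(obs[0, ])), 0)
  # non-ACGT alleles are rejected with a warning, not an error
  expect_warning(out <- filter_observations(dplyr::bind_rows(
    obs_row(), obs_row(allele = "N"))), "non-ACGT")
  expect_equal(sum(out$n), 1)
})

test_that("the genotype caller reproduces hand-applied printed rules", {
  expect_equal(call_genotype(c(A = 10)),
               list(state = "HOM", alleles = "A"))
  expect_equal(call_genotype(c(A = 9, G = 1)),   # 9/10 = 90%
               list(state = "HOM", alleles = "A"))
  expect_equal(call_genotype(c(A = 3, G = 3)),
               list(state = "HET", alleles = c("A", "G")))
  # hom 5/8 = 62.5% < 90%; het combined 7/8 = 87.5% < 90%
  expect_equal(call_genotype(c(A = 5, G = 2, C = 1))$state, "MISSING")
  expect_equal(call_genotype(integer(0))$state, "MISSING")
  expect_error(call_genotype(c(N = 5)), "A/C/G/T")
})

test_that("caller equals the rule transcription on every count vector", {
  vectors <- enumerate_count_vectors(10)
  for (v in vectors) {
    got <- call_genotype(v)
    want <- oracle_call(v)
    expect_identical(got, want,
                     label = paste0("counts ", paste(v, collapse = ",")))
  }
})

test_that("homozygous and heterozygous conditions never co-fire", {
  vectors <- enumerate_count_vectors(15)
  fired <- vapply(vectors, oracle_conditions, logical(2))
  expect_false(any(fired["hom", ] & fired["het", ]))
})

test_that("adding a major-allele read never degrades a homozygous call", {
  vectors <- enumerate_count_vectors(12)
  for (v in vectors) {
    if (call_genotype(v)$state != "HOM") next
    major <- call_genotype(v)$alleles
    v2 <- v
    v2[major] <- v2[major] + 1
    expect_equal(call_genotype(v2)$state, "HOM")
  }
})

test_that("calls are invariant to allele relabelling", {
  set.seed(8)
  for (i in 1:50) {
    v <- setNames(rpois(3, 4), c("A", "C", "G"))
    got <- call_genotype(v)
    # swap the A and G labels
    sw <- setNames(v, chartr("AG", "GA", names(v)))
    got_sw <- call_genotype(sw)
    expect_equal(got_sw$state, got$state)
    expect_setequal(got_sw$alleles, chartr("AG", "GA", got$alleles))
  }
})

test_that("discovery flags sites with two alleles across provisional calls", {
  # different homozygous calls in two samples
  c1 <- make_counts(list(s1 = c(A = 10), s2 = c(G = 8)))
  expect_equal(nrow(discover_polymorphic_sites(c1)), 1)
  # everyone homozygous for the same allele: monomorphic
  c2 <- make_counts(list(s1 = c(A = 6), s2 = c(A = 5), s3 = c(A = 12)))
  expect_equal(nrow(discover_polymorphic_sites(c2)), 0)
  # a single heterozygous sample suffices
  c3 <- make_counts(list(s1 = c(A = 6, G = 6), s2 = c(A = 9), s3 = c(A = 7)))
  expect_equal(nrow(discover_polymorphic_sites(c3)), 1)
  # weak support (below the 5-read / 30% discovery bar) does not count
  c4 <- make_counts(list(s1 = c(A = 10, G = 2), s2 = c(A = 9)))
  expect_equal(nrow(discover_polymorphic_sites(c4)), 0)
})

test_that("call_genotypes restricts to discovered sites, completes and orders", {
  counts <- dplyr::bind_rows(
    make_counts(list(s1 = c(A = 10), s2 = c(A = 5, G = 5)), pos = 100L),
    make_counts(list(s1 = c(A = 10), s2 = c(A = 12)), pos = 200L))
  calls <- call_genotypes(counts, samples = c("s1", "s2", "s3"))
  # monomorphic pos 200 dropped; s3 completed as MISSING
  expect_equal(unique(calls$pos), 100L)
  expect_equal(nrow(calls), 3)
  expect_equal(calls$state[calls$sample_id == "s3"], "MISSING")
  expect_equal(calls$sample_id, sort(calls$sample_id))
  # duplicate count rows are an error
  expect_error(call_genotypes(dplyr::bind_rows(counts, counts[1, ])),
               "duplicate")
})

test_that("error-free simulated reads recover the true genotypes", {
  cfg <- sim_config(n_progeny = 25, n_chromosomes = 2,
                    markers_per_chromosome = 5, base_error_rate = 0,
                    low_phred_rate = 0, mean_depth = 30, random_seed = 17)
  sim <- simulate_f1_dataset(cfg)
  counts <- filter_observations(sim$observations)
  calls <- call_genotypes(counts)
  per_site <- counts |>
    dplyr::group_by(sample_id, chrom, pos) |>
    dplyr::summarise(depth = sum(n), n_alleles = sum(n >= 2),
                     minor_ok = min(n) > 0.2 * sum(n), .groups = "drop")
  joined <- calls |>
    dplyr::inner_join(
      sim$truth |> dplyr::mutate(pos = as.integer(pos_bp)),
      by = c("sample_id", "chrom", "pos")) |>
    dplyr::inner_join(per_site, by = c("sample_id", "chrom", "pos"))
  hom_truth <- joined$allele1.y == joined$allele2.y
  # homozygous truth with depth >= 5: always called HOM for the true allele
  idx <- hom_truth & joined$depth >= 5
  expect_true(all(joined$state[idx] == "HOM"))
  expect_true(all(joined$allele1.x[idx] == joined$allele1.y[idx]))
  # heterozygous truth with both alleles seen >= 2 and minor > 20%:
  # called HET with the true pair
  idx <- !hom_truth & joined$n_alleles == 2 & joined$minor_ok &
    joined$depth >= 5
  expect_true(all(joined$state[idx] == "HET"))
  expect_true(all(joined$allele1.x[idx] == joined$allele1.y[idx] &
                    joined$allele2.x[idx] == joined$allele2.y[idx]))
})

test_that("VCF encodes reference-anchored unphased genotypes", {
  calls <- make_calls(c("A/A", "A/G"), sample_ids = c("s1", "s2"))
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(calls, path)
  body <- grep("^#", readLines(path), value = TRUE, invert = TRUE)
  fields <- strsplit(body, "\t")[[1]]
  expect_equal(fields[4], "A")    # lexicographically smallest REF
  expect_equal(fields[5], "G")
  expect_equal(fields[10:11], c("0/0", "0/1"))
})
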