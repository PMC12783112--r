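test_that("marker maps satisfy ordering and biallelism invariants", {
  set.seed(42)
  cfg <- sim_config(n_progeny = 10, n_chromosomes = 4,
                    markers_per_chromosome = 25)
  map <- sim_marker_map(cfg)
  expect_equal(nrow(map), 100)
  by_chrom <- split(map, map$chrom)
  for (m in by_chrom) {
    expect_false(is.unsorted(m$pos_bp, strictly = TRUE))
    expect_false(is.unsorted(m$pos_cM))
  }
  alleles <- mapply(function(g1, g2) {
    length(unique(unlist(strsplit(c(g1, g2), "/"))))
  }, map$parent1_gt, map$parent2_gt)
  expect_true(all(alleles == 2))
  # the QTL marker sits at the top of chromosome 3 and segregates from
  # the resistant parent only
  qtl <- attr(map, "qtl_marker_id")
  qrow <- map[map$marker_id == qtl, ]
  expect_equal(qrow$chrom, "Chr03")
  expect_equal(qrow$pos_bp, min(map$pos_bp[map$chrom == "Chr03"]))
  g1 <- strsplit(qrow$parent1_gt, "/")[[1]]
  g2 <- strsplit(qrow$parent2_gt, "/")[[1]]
  expect_equal(g1[1], g1[2])
  expect_true(g2[1] != g2[2])
})

test_that("config validation rejects out-of-range parameters", {
  expect_error(sim_config(n_progeny = 1), "n_progeny")
  expect_error(sim_config(base_error_rate = 0.6), "base_error_rate")
  expect_error(sim_config(missing_shoot_rate = 1.2), "rate")
  expect_error(sim_config(qtl_carrier_mean_pll = 120), "PLL")
  expect_error(sim_config(replicates_per_genotype = 6),
               "replicates_per_genotype")
})

test_that("segregation from one heterozygous parent is 1:1 Mendelian", {
  cfg <- sim_config(n_progeny = 10000, n_chromosomes = 1,
                    markers_per_chromosome = 1, random_seed = 101)
  map <- make_map("A/G", "A/A")
  set.seed(cfg$random_seed)
  truth <- simulate_cross(map, cfg)
  prog <- truth[!truth$is_parent, ]
  # allele G only ever comes from parent 1's heterozygous genotype:
  # expected frequency among all progeny alleles is 1/4
  f_g <- mean(c(prog$allele1, prog$allele2) == "G")
  se <- 1 / (4 * sqrt(nrow(prog)))
  expect_lt(abs(f_g - 0.25), 3 * se)
  # genotype classes aa:ag fit 1:1 (chi-square, alpha = 0.001)
  n_het <- sum(prog$allele1 != prog$allele2)
  chi <- stats::chisq.test(c(n_het, nrow(prog) - n_het), p = c(0.5, 0.5))
  expect_gt(chi$p.value, 0.001)
})

test_that("crossover fractions follow the Haldane mapping function", {
  set.seed(7)
  # zero map distance: never recombinant
  ori <- gbsmap:::sim_gamete_origins(c(10, 10), 5000)
  expect_equal(sum(ori[, 1] != ori[, 2]), 0)
  # 20 cM: r = (1 - exp(-0.4)) / 2 ~ 0.1648
  ori <- gbsmap:::sim_gamete_origins(c(0, 20), 10000)
  r_hat <- mean(ori[, 1] != ori[, 2])
  r_exp <- 0.5 * (1 - exp(-0.4))
  expect_lt(abs(r_hat - r_exp), 3 * sqrt(r_exp * (1 - r_exp) / 10000))
})

test_that("recombination fraction grows monotonically with map distance", {
  set.seed(11)
  d <- c(0, 2, 5, 10, 20, 40, 80)
  pos <- cumsum(d)
  est <- rowMeans(replicate(20, {
    ori <- gbsmap:::sim_gamete_origins(pos, 400)
    colMeans(ori[, -1, drop = FALSE] != ori[, -ncol(ori), drop = FALSE])
  }))
  expect_false(is.unsorted(est))
})

test_that("error-free observations reflect the true genotype exactly", {
  cfg <- sim_config(n_progeny = 2, n_chromosomes = 1,
                    markers_per_chromosome = 1, base_error_rate = 0,
                    mean_depth = 40, random_seed = 3)
  map <- make_map("A/A", "A/A")
  set.seed(3)
  truth <- simulate_cross(map, cfg)
  obs <- simulate_observations(truth, cfg)
  expect_true(all(obs$allele == "A"))
  expect_true(all(obs$offset_end == cfg$read_length - obs$offset_start + 1))

  # heterozygote: allele fraction tends to 1/2
  cfg_het <- sim_config(n_progeny = 2, n_chromosomes = 1,
                        markers_per_chromosome = 1, base_error_rate = 0,
                        mean_depth = 10000, depth_dispersion = Inf)
  truth_het <- tibble::tibble(sample_id = "s1", marker_id = "m1",
                              chrom = "Chr01", pos_bp = 100,
                              allele1 = "A", allele2 = "G",
                              is_parent = FALSE)
  set.seed(4)
  obs_het <- simulate_observations(truth_het, cfg_het)
  f_a <- mean(obs_het$allele == "A")
  expect_lt(abs(f_a - 0.5), 3 * 0.5 / sqrt(nrow(obs_het)))
})

test_that("zero mean depth yields an empty observation table", {
  cfg <- sim_config(n_progeny = 2, n_chromosomes = 1,
                    markers_per_chromosome = 1, mean_depth = 0)
  truth <- simulate_cross(make_map("A/G", "A/A"), cfg)
  obs <- simulate_observations(truth, cfg)
  expect_equal(nrow(obs), 0)
  expect_named(obs, c("sample_id", "chrom", "pos", "allele",
                      "offset_start", "offset_end", "phred"))
})

test_that("phenotypes respond to the QTL with the configured means", {
  cfg <- sim_config(n_progeny = 119, n_chromosomes = 3,
                    markers_per_chromosome = 2, phenotype_sd = 15,
                    missing_shoot_rate = 0, random_seed = 21)
  set.seed(21)
  map <- sim_marker_map(cfg)
  truth <- simulate_cross(map, cfg)
  pheno <- simulate_phenotypes(truth, cfg)
  qtl_id <- attr(truth, "qtl_marker_id")
  qtl_allele <- attr(truth, "qtl_allele")
  at_qtl <- truth[truth$marker_id == qtl_id & !truth$is_parent, ]
  carriers <- at_qtl$sample_id[at_qtl$allele1 == qtl_allele |
                                 at_qtl$allele2 == qtl_allele]
  pll_obs <- 100 * pheno$necrosis_length_mm / pheno$shoot_length_mm
  carr <- pheno$genotype_id %in% carriers
  prog <- !pheno$genotype_id %in% cfg$parent_ids
  m1 <- mean(pll_obs[carr & prog])
  m0 <- mean(pll_obs[!carr & prog])
  # closed-form mean of the [0, 100]-truncated normal
  etrunc <- function(mu, sd) {
    al <- (0 - mu) / sd
    be <- (100 - mu) / sd
    mu + sd * (dnorm(al) - dnorm(be)) / (pnorm(be) - pnorm(al))
  }
  expect_lt(abs(m1 - etrunc(25, 15)), 3 * 15 / sqrt(sum(carr & prog)))
  expect_lt(abs(m0 - etrunc(60, 15)), 3 * 15 / sqrt(sum(!carr & prog)))
})

test_that("degenerate phenotype settings behave as declared", {
  cfg0 <- sim_config(n_progeny = 5, n_chromosomes = 3,
                     markers_per_chromosome = 2, phenotype_sd = 0,
                     missing_shoot_rate = 0, random_seed = 31)
  set.seed(31)
  truth <- simulate_cross(sim_marker_map(cfg0), cfg0)
  ph <- simulate_phenotypes(truth, cfg0)
  pll_obs <- 100 * ph$necrosis_length_mm / ph$shoot_length_mm
  expect_true(all(round(pll_obs, 10) %in% c(25, 60)))

  cfg1 <- sim_config(n_progeny = 5, n_chromosomes = 3,
                     markers_per_chromosome = 2, missing_shoot_rate = 1)
  set.seed(31)
  truth1 <- simulate_cross(sim_marker_map(cfg1), cfg1)
  expect_equal(nrow(simulate_phenotypes(truth1, cfg1)), 0)
})

test_that("a fixed seed reproduces the dataset bit for bit", {
  cfg <- sim_config(n_progeny = 8, n_chromosomes = 2,
                    markers_per_chromosome = 4, random_seed = 99)
  s1 <- simulate_f1_dataset(cfg)
  s2 <- simulate_f1_dataset(cfg)
  expect_identical(s1$map, s2$map)
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$observations, s2$observations)
  expect_identical(s1$phenotypes, s2$phenotypes)
})

test_that("fixtures are byte-stable and round-trip exactly", {
  cfg <- sim_config(n_progeny = 6, n_chromosomes = 2,
                    markers_per_chromosome = 3, random_seed = 55)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  p1 <- write_fixtures(simulate_f1_dataset(cfg), d1)
  p2 <- write_fixtures(simulate_f1_dataset(cfg), d2)
  for (f in names(p1)) {
    expect_identical(unname(tools::md5sum(p1[[f]])),
                     unname(tools::md5sum(p2[[f]])), label = f)
  }
  sim <- simulate_f1_dataset(cfg)
  expect_equal(as.data.frame(read_marker_map(p1["marker_map"])),
               as.data.frame(sim$map), ignore_attr = TRUE)
  expect_equal(as.data.frame(read_observations(p1["observations"])),
               as.data.frame(sim$observations))
  expect_equal(as.data.frame(read_phenotypes(p1["phenotypes"])),
               as.data.frame(sim$phenotypes))
})

test_that("truth VCF has one column per sample including both parents", {
  cfg <- sim_config(n_progeny = 2, n_chromosomes = 1,
                    markers_per_chromosome = 1, random_seed = 12)
  dir <- withr::local_tempdir()
  paths <- write_fixtures(simulate_f1_dataset(cfg), dir)
  hdr <- grep("^#CHROM", readLines(paths["truth_vcf"]), value = TRUE)
  cols <- strsplit(hdr, "\t")[[1]]
  expect_length(cols, 9 + 4)
  expect_true(all(c("Idared", "Jackii", "F1_001", "F1_002") %in% cols))
})
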