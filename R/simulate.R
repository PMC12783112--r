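#' Configuration for the synthetic F1-cross generator
#'
#' Collects every tunable of the simulated experiment: a biparental F1
#' population (default 119 progeny, the size of a typical fire-blight
#' phenotyping population) genotyped by reduced-representation sequencing
#' and phenotyped for percent lesion length (PLL) in replicated trials
#' over two years.
#'
#' The defaults describe the study conditions the package's validation
#' runs under: 17 chromosomes, a single PLL QTL at the top of
#' chromosome 3 whose resistance allele segregates from the resistant
#' parent, carrier mean PLL 25% versus non-carrier 60% with residual
#' standard deviation 15, up to five replicates per genotype in 2024 and
#' 2025, negative-binomial read depth (mean 20), and a 0.2% per-base
#' sequencing error rate.
#'
#' @param n_progeny Number of F1 progeny (>= 2).
#' @param n_chromosomes Number of chromosomes.
#' @param markers_per_chromosome Markers simulated per chromosome.
#' @param chrom_length_bp Physical chromosome length in bp.
#' @param cm_per_mb Linear physical-to-genetic conversion rate (cM/Mb).
#' @param seg_type_probs Named probabilities for marker segregation types:
#'   `het_hom` (heterozygous in parent 1 only), `hom_het` (heterozygous in
#'   parent 2 only), `het_het` (heterozygous in both).
#' @param mean_depth Mean read depth per sample and site.
#' @param depth_dispersion Negative-binomial size parameter; `Inf` gives
#'   Poisson depth.
#' @param base_error_rate Per-base probability that a read reports a
#'   uniformly chosen wrong base (< 0.5).
#' @param read_length Read length in bp used to draw the variant's offset
#'   within the read.
#' @param low_phred_rate Fraction of base calls drawn with PHRED < 20.
#' @param qtl_marker_id Marker carrying the phenotype QTL; `NULL` places it
#'   at the first (topmost) marker of chromosome 3.
#' @param qtl_carrier_mean_pll,qtl_noncarrier_mean_pll Mean PLL (%) for
#'   progeny carrying / not carrying the resistance allele.
#' @param phenotype_sd Residual standard deviation of per-shoot PLL.
#' @param replicates_per_genotype Replicates per genotype and year (1-5).
#' @param years Trial years.
#' @param shoot_length_range_mm Uniform range for total shoot length.
#' @param missing_shoot_rate Probability a replicate shoot is missing.
#' @param parent_ids Sample ids for the susceptible (first) and resistant
#'   (second) parent.
#' @param random_seed Seed applied by [simulate_f1_dataset()] and
#'   [run_pipeline()]; `NULL` uses the current RNG state.
#'
#' @return A list of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(n_progeny = 20, markers_per_chromosome = 4,
#'                   n_chromosomes = 3, random_seed = 1)
sim_config <- function(n_progeny = 119,
                       n_chromosomes = 17,
                       markers_per_chromosome = 30,
                       chrom_length_bp = 35e6,
                       cm_per_mb = 4,
                       seg_type_probs = c(het_hom = 0.4, hom_het = 0.4,
                                          het_het = 0.2),
                       mean_depth = 20,
                       depth_dispersion = 5,
                       base_error_rate = 0.002,
                       read_length = 75,
                       low_phred_rate = 0.05,
                       qtl_marker_id = NULL,
                       qtl_carrier_mean_pll = 25,
                       qtl_noncarrier_mean_pll = 60,
                       phenotype_sd = 15,
                       replicates_per_genotype = 5,
                       years = c(2024L, 2025L),
                       shoot_length_range_mm = c(300, 800),
                       missing_shoot_rate = 0.1,
                       parent_ids = c("Idared", "Jackii"),
                       random_seed = NULL) {
  stopifnot(n_progeny >= 2, n_chromosomes >= 1, markers_per_chromosome >= 1,
            chrom_length_bp >= markers_per_chromosome, cm_per_mb > 0,
            mean_depth >= 0, depth_dispersion > 0,
            read_length >= 1, length(parent_ids) == 2,
            length(shoot_length_range_mm) == 2,
            shoot_length_range_mm[1] > 0,
            diff(shoot_length_range_mm) >= 0,
            replicates_per_genotype >= 1, replicates_per_genotype <= 5,
            phenotype_sd >= 0)
  rates <- c(base_error_rate, low_phred_rate, missing_shoot_rate)
  if (any(rates < 0 | rates > 1))
    abort("all rate parameters must lie in [0, 1]")
  if (base_error_rate >= 0.5)
    abort("base_error_rate must be < 0.5")
  means <- c(qtl_carrier_mean_pll, qtl_noncarrier_mean_pll)
  if (any(means < 0 | means > 100))
    abort("mean PLL values must lie in [0, 100]")
  if (!setequal(names(seg_type_probs), c("het_hom", "hom_het", "het_het")) ||
      any(seg_type_probs < 0) || sum(seg_type_probs) <= 0)
    abort("seg_type_probs must be non-negative and named het_hom/hom_het/het_het")
  structure(
    list(n_progeny = as.integer(n_progeny),
         n_chromosomes = as.integer(n_chromosomes),
         markers_per_chromosome = as.integer(markers_per_chromosome),
         chrom_length_bp = chrom_length_bp,
         cm_per_mb = cm_per_mb,
         seg_type_probs = seg_type_probs / sum(seg_type_probs),
         mean_depth = mean_depth,
         depth_dispersion = depth_dispersion,
         base_error_rate = base_error_rate,
         read_length = as.integer(read_length),
         low_phred_rate = low_phred_rate,
         qtl_marker_id = qtl_marker_id,
         qtl_carrier_mean_pll = qtl_carrier_mean_pll,
         qtl_noncarrier_mean_pll = qtl_noncarrier_mean_pll,
         phenotype_sd = phenotype_sd,
         replicates_per_genotype = as.integer(replicates_per_genotype),
         years = as.integer(years),
         shoot_length_range_mm = shoot_length_range_mm,
         missing_shoot_rate = missing_shoot_rate,
         parent_ids = parent_ids,
         random_seed = random_seed),
    class = "sim_config")
}

.bases <- c("A", "C", "G", "T")

#' Simulate a biparental marker map
#'
#' Draws an ordered marker panel: per chromosome, strictly increasing
#' physical positions with genetic positions from a linear cM/Mb
#' conversion, two distinct alleles per marker, and parental genotypes
#' assigned by segregation type. The QTL marker (see
#' [sim_config()]) is forced to segregate from the resistant parent only
#' (susceptible parent homozygous), so that carrier status is defined.
#'
#' @param cfg A [sim_config()].
#' @return A tibble with columns `marker_id`, `chrom`, `pos_bp`, `pos_cM`,
#'   `parent1_gt`, `parent2_gt` (genotypes as `"A/C"` strings), carrying
#'   attribute `qtl_marker_id`.
#' @export
sim_marker_map <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  chroms <- sprintf("Chr%02d", seq_len(cfg$n_chromosomes))
  m <- cfg$markers_per_chromosome
  map <- list_rbind(map(chroms, function(ch) {
    pos <- sort(sample.int(cfg$chrom_length_bp, m))
    tibble(marker_id = sprintf("%s_%04d", ch, seq_len(m)),
           chrom = ch, pos_bp = pos,
           pos_cM = pos / 1e6 * cfg$cm_per_mb)
  }))
  n <- nrow(map)
  a1 <- sample(.bases, n, replace = TRUE)
  a2 <- map_chr(a1, function(a) sample(setdiff(.bases, a), 1))
  type <- sample(names(cfg$seg_type_probs), n, replace = TRUE,
                 prob = cfg$seg_type_probs)
  qtl_id <- cfg$qtl_marker_id
  if (is.null(qtl_id)) {
    qtl_chrom <- chroms[min(3L, cfg$n_chromosomes)]
    qtl_id <- map$marker_id[map$chrom == qtl_chrom][1]
  }
  if (!qtl_id %in% map$marker_id)
    abort(paste0("qtl_marker_id '", qtl_id, "' is not in the marker map"))
  # resistance allele must come from parent 2 and be absent from parent 1
  type[map$marker_id == qtl_id] <- "hom_het"
  het <- paste(pmin(a1, a2), pmax(a1, a2), sep = "/")
  hom <- paste(a1, a1, sep = "/")
  map$parent1_gt <- ifelse(type == "hom_het", hom, het)
  map$parent2_gt <- ifelse(type == "het_hom", hom, het)
  attr(map, "qtl_marker_id") <- qtl_id
  map
}

# split "A/C" genotype strings into a 2-column matrix
parse_gt <- function(gt) str_split_fixed(gt, "/", 2)

# haplotype-origin indicators for n gametes along one chromosome:
# crossover between adjacent markers with Haldane probability
# r = (1 - exp(-2 d / 100)) / 2 for map distance d in cM
haldane_r <- function(d_cM) 0.5 * (1 - exp(-2 * d_cM / 100))

sim_gamete_origins <- function(pos_cM, n) {
  m <- length(pos_cM)
  origin <- matrix(0L, nrow = n, ncol = m)
  cur <- rbinom(n, 1L, 0.5)
  origin[, 1] <- cur
  if (m > 1) {
    r <- haldane_r(diff(pos_cM))
    for (j in 2:m) {
      cur <- (cur + rbinom(n, 1L, r[j - 1])) %% 2L
      origin[, j] <- cur
    }
  }
  origin
}

#' Simulate F1 genotypes by Mendelian segregation with recombination
#'
#' Each parent is phased into two haplotypes (random phase at
#' heterozygous markers, fixed for the cross); every progeny receives one
#' recombinant gamete per parent per chromosome, with crossover
#' probability between adjacent markers given by the Haldane mapping
#' function \eqn{r = (1 - e^{-2d/100})/2} for map distance d cM.
#'
#' @param map Marker map from [sim_marker_map()].
#' @param cfg A [sim_config()].
#' @return Truth-genotype tibble with one row per sample and marker:
#'   `sample_id`, `marker_id`, `chrom`, `pos_bp`, `allele1`, `allele2`
#'   (sorted allele pair) and `is_parent`. Parents are included as
#'   flagged rows. Attributes `qtl_marker_id` and `qtl_allele` identify
#'   the resistance allele (present in parent 2's pair, absent from
#'   parent 1's).
#' @export
simulate_cross <- function(map, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (nrow(map) < 1) abort("marker map must contain at least one marker")
  if (any(vapply(split(map$pos_bp, map$chrom), is.unsorted, logical(1),
                 strictly = TRUE)))
    abort("marker positions must be strictly increasing within chromosomes")
  p1 <- parse_gt(map$parent1_gt)
  p2 <- parse_gt(map$parent2_gt)
  # random phase per parent: swap haplotype assignment at het markers
  phase <- function(alle) {
    sw <- runif(nrow(alle)) < 0.5
    alle[sw, ] <- alle[sw, 2:1]
    alle
  }
  hap1 <- phase(p1)
  hap2 <- phase(p2)
  n <- cfg$n_progeny
  prog_ids <- sprintf("F1_%03d", seq_len(n))
  gamete <- function(hap) {
    out <- matrix("", nrow = n, ncol = nrow(map))
    for (ch in split(seq_len(nrow(map)), map$chrom)) {
      ori <- sim_gamete_origins(map$pos_cM[ch], n)
      out[, ch] <- ifelse(ori == 0L, rep(hap[ch, 1], each = n),
                          rep(hap[ch, 2], each = n))
    }
    out
  }
  g1 <- gamete(hap1)
  g2 <- gamete(hap2)
  prog <- tibble(
    sample_id = rep(prog_ids, times = nrow(map)),
    marker_id = rep(map$marker_id, each = n),
    chrom = rep(map$chrom, each = n),
    pos_bp = rep(map$pos_bp, each = n),
    allele1 = pmin(as.vector(g1), as.vector(g2)),
    allele2 = pmax(as.vector(g1), as.vector(g2)),
    is_parent = FALSE)
  par <- tibble(
    sample_id = rep(cfg$parent_ids, each = nrow(map)),
    marker_id = rep(map$marker_id, 2),
    chrom = rep(map$chrom, 2),
    pos_bp = rep(map$pos_bp, 2),
    allele1 = c(pmin(p1[, 1], p1[, 2]), pmin(p2[, 1], p2[, 2])),
    allele2 = c(pmax(p1[, 1], p1[, 2]), pmax(p2[, 1], p2[, 2])),
    is_parent = TRUE)
  truth <- bind_rows(prog, par) |> arrange(.data$chrom, .data$pos_bp,
                                           .data$sample_id)
  qtl_id <- attr(map, "qtl_marker_id") %||% cfg$qtl_marker_id
  if (!is.null(qtl_id)) {
    i <- match(qtl_id, map$marker_id)
    qtl_allele <- setdiff(p2[i, ], p1[i, ])
    attr(truth, "qtl_marker_id") <- qtl_id
    attr(truth, "qtl_allele") <- if (length(qtl_allele)) qtl_allele[1] else NA_character_
  }
  truth
}

#' Simulate per-read base observations (a pileup table)
#'
#' Draws, for every sample and marker, a read depth from a negative
#' binomial (mean `mean_depth`, size `depth_dispersion`; Poisson when the
#' dispersion is infinite), then one base observation per read: a true
#' allele chosen uniformly from the sample's pair, flipped to a uniformly
#' chosen different base with probability `base_error_rate`. Read offsets
#' are uniform on `[1, read_length]` with `offset_end = read_length -
#' offset_start + 1`, and PHRED values fall below 20 with probability
#' `low_phred_rate`.
#'
#' @param truth Truth genotypes from [simulate_cross()].
#' @param cfg A [sim_config()].
#' @return A base-observation tibble: `sample_id`, `chrom`, `pos`,
#'   `allele`, `offset_start`, `offset_end`, `phred`.
#' @export
simulate_observations <- function(truth, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  depth <- if (is.infinite(cfg$depth_dispersion)) {
    rpois(nrow(truth), cfg$mean_depth)
  } else {
    rnbinom(nrow(truth), size = cfg$depth_dispersion, mu = cfg$mean_depth)
  }
  idx <- rep.int(seq_len(nrow(truth)), depth)
  n <- length(idx)
  if (n == 0) {
    return(tibble(sample_id = character(), chrom = character(),
                  pos = integer(), allele = character(),
                  offset_start = integer(), offset_end = integer(),
                  phred = integer()))
  }
  pick2 <- runif(n) < 0.5
  allele <- ifelse(pick2, truth$allele2[idx], truth$allele1[idx])
  err <- runif(n) < cfg$base_error_rate
  if (any(err)) {
    # 4 x 3 lookup of the alternative bases for each true base
    others <- t(vapply(.bases, function(b) setdiff(.bases, b),
                       character(3)))
    allele[err] <- others[cbind(match(allele[err], .bases),
                                sample.int(3, sum(err), replace = TRUE))]
  }
  offset_start <- sample.int(cfg$read_length, n, replace = TRUE)
  low <- runif(n) < cfg$low_phred_rate
  phred <- ifelse(low, sample(0:19, n, replace = TRUE),
                  sample(20:41, n, replace = TRUE))
  tibble(sample_id = truth$sample_id[idx],
         chrom = truth$chrom[idx],
         pos = as.integer(truth$pos_bp[idx]),
         allele = allele,
         offset_start = offset_start,
         offset_end = cfg$read_length - offset_start + 1L,
         phred = as.integer(phred))
}

# truncated-normal PLL draws by rejection; avoids point masses at 0/100
rtrunc_pll <- function(mean, sd) {
  n <- length(mean)
  if (sd == 0) return(pmin(pmax(mean, 0), 100))
  x <- rnorm(n, mean, sd)
  bad <- which(x < 0 | x > 100)
  while (length(bad)) {
    x[bad] <- rnorm(length(bad), mean[bad], sd)
    bad <- bad[x[bad] < 0 | x[bad] > 100]
  }
  x
}

#' Simulate replicated shoot phenotypes driven by a single QTL
#'
#' Every genotype (progeny and parents) is assigned carrier status --
#' possession of at least one copy of the resistance allele at the QTL
#' marker -- and each replicate shoot draws a percent lesion length from
#' a normal distribution (carrier or non-carrier mean, common sd)
#' truncated to \[0, 100\] by rejection. Necrosis length is PLL/100 times
#' a uniformly drawn total shoot length; replicates go missing with
#' probability `missing_shoot_rate`.
#'
#' @param truth Truth genotypes from [simulate_cross()] (carries the QTL
#'   marker and resistance allele as attributes).
#' @param cfg A [sim_config()].
#' @return Phenotype tibble: `genotype_id`, `year`, `replicate`,
#'   `shoot_length_mm`, `necrosis_length_mm`.
#' @export
simulate_phenotypes <- function(truth, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  qtl_id <- attr(truth, "qtl_marker_id")
  qtl_allele <- attr(truth, "qtl_allele")
  if (is.null(qtl_id) || is.na(qtl_allele))
    abort("truth genotypes carry no resolvable QTL marker")
  at_qtl <- truth[truth$marker_id == qtl_id, ]
  if (nrow(at_qtl) == 0) abort("qtl_marker_id not present in truth table")
  carrier <- setNames(at_qtl$allele1 == qtl_allele |
                        at_qtl$allele2 == qtl_allele, at_qtl$sample_id)
  grid <- expand_grid(genotype_id = names(carrier),
                      year = cfg$years,
                      replicate = seq_len(cfg$replicates_per_genotype))
  keep <- runif(nrow(grid)) >= cfg$missing_shoot_rate
  grid <- grid[keep, ]
  if (nrow(grid) == 0) {
    return(tibble(genotype_id = character(), year = integer(),
                  replicate = integer(), shoot_length_mm = numeric(),
                  necrosis_length_mm = numeric()))
  }
  mu <- ifelse(carrier[grid$genotype_id],
               cfg$qtl_carrier_mean_pll, cfg$qtl_noncarrier_mean_pll)
  pll <- rtrunc_pll(mu, cfg$phenotype_sd)
  shoot <- runif(nrow(grid), cfg$shoot_length_range_mm[1],
                 cfg$shoot_length_range_mm[2])
  grid |>
    mutate(shoot_length_mm = shoot,
           necrosis_length_mm = pll / 100 * shoot) |>
    arrange(.data$genotype_id, .data$year, .data$replicate)
}

#' Run the whole synthetic experiment under one seed
#'
#' Convenience wrapper: seeds the RNG once from `cfg$random_seed`, then
#' draws map, cross, read observations and phenotypes in a fixed order,
#' so a fixed seed yields bit-identical outputs.
#'
#' @param cfg A [sim_config()].
#' @return A list with elements `cfg`, `map`, `truth`, `observations`,
#'   `phenotypes`.
#' @export
#' @examples
#' sim <- simulate_f1_dataset(sim_config(n_progeny = 10,
#'   n_chromosomes = 3, markers_per_chromosome = 4, random_seed = 7))
#' dplyr::count(sim$observations, sample_id)
simulate_f1_dataset <- function(cfg = sim_config()) {
  if (!is.null(cfg$random_seed)) set.seed(cfg$random_seed)
  map <- sim_marker_map(cfg)
  truth <- simulate_cross(map, cfg)
  obs <- simulate_observations(truth, cfg)
  pheno <- simulate_phenotypes(truth, cfg)
  list(cfg = cfg, map = map, truth = truth, observations = obs,
       phenotypes = pheno)
}

#' Convert truth genotypes to noiseless genotype calls
#'
#' Maps the simulator's truth table to the call format produced by
#' [call_genotypes()] (state HOM/HET with an explicit allele pair), i.e.
#' the calls an error-free caller at saturating depth would make. Used
#' for calibration and power studies that exercise the association scan
#' under the generator's genetic model without resimulating reads.
#'
#' @param truth Truth genotypes from [simulate_cross()].
#' @return A genotype-call tibble (`sample_id`, `chrom`, `pos`, `state`,
#'   `allele1`, `allele2`).
#' @export
genotypes_from_truth <- function(truth) {
  truth |>
    transmute(sample_id = .data$sample_id, chrom = .data$chrom,
              pos = as.integer(.data$pos_bp),
              state = ifelse(.data$allele1 == .data$allele2, "HOM", "HET"),
              allele1 = .data$allele1, allele2 = .data$allele2) |>
    arrange(.data$chrom, .data$pos, .data$sample_id)
}

#' Write the synthetic dataset to plain-text fixtures
#'
#' Emits the four interchange files consumed by the pipeline stages:
#' `marker_map.tsv`, `observations.tsv` (pileup table),
#' `phenotypes.csv`, and `truth.vcf` (unphased GT, VCF v4.2). Output is
#' byte-stable for a fixed simulation seed.
#'
#' @param sim Result of [simulate_f1_dataset()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, a named character vector of the file paths.
#' @export
write_fixtures <- function(sim, dir) {
  if (!dir.exists(dir) &&
      !dir.create(dir, recursive = TRUE, showWarnings = FALSE))
    abort(paste0("cannot create fixture directory '", dir, "'"))
  paths <- c(marker_map = file.path(dir, "marker_map.tsv"),
             observations = file.path(dir, "observations.tsv"),
             phenotypes = file.path(dir, "phenotypes.csv"),
             truth_vcf = file.path(dir, "truth.vcf"))
  write_tsv(sim$map, paths["marker_map"])
  write_tsv(sim$observations, paths["observations"])
  write_csv(sim$phenotypes, paths["phenotypes"])
  write_vcf(genotypes_from_truth(sim$truth), paths["truth_vcf"],
            susceptible_parent = sim$cfg$parent_ids[1],
            parents = sim$cfg$parent_ids)
  invisible(paths)
}
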