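#' Percent lesion length of a shoot
#'
#' PLL is the length of the necrotic shoot divided by the total shoot
#' length, expressed as a percentage.
#'
#' @param necrosis_length_mm Necrotic length(s), >= 0.
#' @param shoot_length_mm Total shoot length(s), > 0.
#' @return PLL in percent, in \[0, 100\].
#' @export
#' @examples
#' pll(12, 48)  # 25
pll <- function(necrosis_length_mm, shoot_length_mm) {
  if (any(shoot_length_mm <= 0)) abort("shoot_length_mm must be > 0")
  if (any(necrosis_length_mm < 0)) abort("necrosis_length_mm must be >= 0")
  if (any(necrosis_length_mm > shoot_length_mm))
    abort("necrosis_length_mm cannot exceed shoot_length_mm")
  100 * necrosis_length_mm / shoot_length_mm
}

#' Aggregate shoot measurements to per-genotype mean PLL
#'
#' Computes PLL per shoot, averages replicates within genotype and year,
#' then averages the available year means per genotype (so unequal
#' replicate counts cannot weight one year over the other). A pooled
#' mode averaging all shoots directly is available.
#'
#' @param measurements Tibble with columns `genotype_id`, `year`,
#'   `replicate`, `shoot_length_mm`, `necrosis_length_mm`.
#' @param method `"year_means"` (default) or `"pooled"`.
#' @return Tibble with one row per genotype: `genotype_id`, one
#'   `pll_<year>` column per year, and `pll_mean`.
#' @export
#' @examples
#' m <- tibble::tibble(genotype_id = "g1", year = c(2024, 2024, 2025),
#'   replicate = c(1, 2, 1), shoot_length_mm = 100,
#'   necrosis_length_mm = c(10, 30, 40))
#' aggregate_pll(m)  # pll_2024 = 20, pll_2025 = 40, pll_mean = 30
aggregate_pll <- function(measurements, method = c("year_means", "pooled")) {
  method <- match.arg(method)
  check_columns(measurements, c("genotype_id", "year", "replicate",
                                "shoot_length_mm", "necrosis_length_mm"),
                "phenotype table")
  shoots <- measurements |>
    mutate(pll = pll(.data$necrosis_length_mm, .data$shoot_length_mm))
  year_means <- shoots |>
    group_by(.data$genotype_id, .data$year) |>
    summarise(pll_year = mean(.data$pll), .groups = "drop")
  overall <- if (method == "year_means") {
    year_means |>
      group_by(.data$genotype_id) |>
      summarise(pll_mean = mean(.data$pll_year), .groups = "drop")
  } else {
    shoots |>
      group_by(.data$genotype_id) |>
      summarise(pll_mean = mean(.data$pll), .groups = "drop")
  }
  year_means |>
    pivot_wider(names_from = "year", values_from = "pll_year",
                names_prefix = "pll_", names_sort = TRUE) |>
    left_join(overall, by = "genotype_id") |>
    arrange(.data$genotype_id)
}

#' Between-year correlation of mean PLL
#'
#' Correlates per-genotype year means across two trial years, over the
#' genotypes measured in both.
#'
#' @param pll_table Output of [aggregate_pll()] (wide `pll_<year>`
#'   columns).
#' @param years Length-2 vector naming the years to correlate; defaults
#'   to the first two year columns present.
#' @param method Correlation method, `"pearson"` (default) or
#'   `"spearman"`.
#' @return The correlation coefficient.
#' @export
year_correlation <- function(pll_table, years = NULL,
                             method = c("pearson", "spearman")) {
  method <- match.arg(method)
  year_cols <- grep("^pll_\\d+$", names(pll_table), value = TRUE)
  if (!is.null(years)) year_cols <- paste0("pll_", years)
  if (length(year_cols) != 2 || !all(year_cols %in% names(pll_table)))
    abort("pll_table must contain exactly two pll_<year> columns to correlate")
  x <- pll_table[[year_cols[1]]]
  y <- pll_table[[year_cols[2]]]
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 3)
    abort("need at least 3 genotypes measured in both years")
  if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0)
    abort("year means are constant; correlation undefined")
  cor(x[ok], y[ok], method = method)
}
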