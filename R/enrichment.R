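#' Weighted average region length
#'
#' The average length of a region across the kinases considered, weighted by
#' the total number of SNPs each kinase harbours, so that kinases carrying
#' many SNPs do not bias the expected placement probability.
#'
#' @param lengths Per-kinase region lengths (residues).
#' @param weights Per-kinase SNP totals, aligned with `lengths`.
#' @return `sum(w * L) / sum(w)`.
#' @export
weighted_region_length <- function(lengths, weights) {
  if (length(lengths) != length(weights)) abort("lengths and weights must align")
  if (any(lengths < 0)) abort("region lengths must be nonnegative")
  if (any(weights < 0)) abort("weights must be nonnegative")
  if (sum(weights) <= 0) abort("at least one kinase must carry a SNP (all weights zero)")
  sum(weights * lengths) / sum(weights)
}

#' Expected per-region SNP probability
#'
#' The chance probability of a SNP falling in each region: its weighted
#' average length divided by the sum of every region's weighted average
#' length.
#'
#' @param region_weighted_lengths Named numeric vector of weighted average
#'   lengths, one per region.
#' @return Named vector of probabilities summing to 1.
#' @export
expected_probability <- function(region_weighted_lengths) {
  if (length(region_weighted_lengths) == 0L) abort("no regions supplied")
  if (any(region_weighted_lengths <= 0)) abort("weighted lengths must be > 0")
  region_weighted_lengths / sum(region_weighted_lengths)
}

#' Two-tailed binomial placement P value
#'
#' The probability of observing a region SNP count as extreme as `x` out of
#' `n` under chance placement probability `ep`, computed as the relevant
#' binomial tail (lower when `x/n < ep`, upper when `x/n > ep`) times two.
#' The tail is accumulated by exact summation of log-space terms. The
#' doubled tail can exceed 1; by default it is capped at 1 so that the
#' result remains a probability, and `x/n` exactly equal to `ep` returns 1.
#'
#' @param x Observed count, `0 <= x <= n`.
#' @param n Total number of SNPs considered (`>= 1`).
#' @param ep Expected probability, in (0, 1).
#' @param cap If `FALSE`, return the raw doubled tail (possibly > 1).
#' @return The two-tailed P value.
#' @export
binom_pvalue_two_tailed <- function(x, n, ep, cap = TRUE) {
  if (length(x) > 1 || length(n) > 1 || length(ep) > 1) {
    return(mapply(binom_pvalue_two_tailed, x, n, ep, MoreArgs = list(cap = cap)))
  }
  if (n < 1 || x < 0 || x > n) abort("need 0 <= x <= n and n >= 1")
  if (ep <= 0 || ep >= 1) abort("ep must lie strictly between 0 and 1")
  ratio <- x / n
  if (ratio == ep) return(1)
  i <- if (ratio < ep) 0:x else x:n
  log_terms <- lchoose(n, i) + i * log(ep) + (n - i) * log1p(-ep)
  p <- 2 * sum(exp(log_terms))
  if (cap) min(p, 1) else p
}

#' Pooled two-proportion z comparison of SNP sets
#'
#' Normal-approximation comparison of a count fraction between two SNP sets
#' (e.g. the number of SNPs falling in one region among common vs. disease
#' SNPs): pooled two-proportion z statistic with a two-sided standard-normal
#' P value.
#'
#' @param x1,n1 Count and total of the first set.
#' @param x2,n2 Count and total of the second set.
#' @return A tibble with `z`, `p_value`, `prop1`, `prop2`.
#' @export
compare_snp_sets <- function(x1, n1, x2, n2) {
  if (n1 < 1 || n2 < 1) abort("both sets need n >= 1")
  p1 <- x1 / n1
  p2 <- x2 / n2
  pool <- (x1 + x2) / (n1 + n2)
  if (pool <= 0 || pool >= 1) {
    warn("degenerate pooled proportion (0 or 1); returning z = 0, p = 1")
    return(tibble(z = 0, p_value = 1, prop1 = p1, prop2 = p2))
  }
  z <- (p1 - p2) / sqrt(pool * (1 - pool) * (1 / n1 + 1 / n2))
  tibble(z = z, p_value = 2 * pnorm(-abs(z)), prop1 = p1, prop2 = p2)
}

classify_enrichment_call <- function(p_value, observed_rate, expected_p, alpha) {
  case_when(
    p_value < alpha & observed_rate > expected_p ~ "enriched",
    p_value < alpha & observed_rate < expected_p ~ "devoid",
    .default = "neutral"
  )
}

#' Per-region SNP enrichment statistics
#'
#' The core region-level test: for each Hanks-Hunter region, the expected
#' placement probability E(p) is derived from SNP-weighted average region
#' lengths, the observed count `x` out of the `n` mapped SNPs is compared to
#' it with the two-tailed binomial test, and the region is called
#' `enriched`, `devoid` or `neutral` at level `alpha`. Records mapping
#' outside the catalytic domain are excluded from both `n` and the kinase
#' weights. When several categories are present the statistics are computed
#' separately per category.
#'
#' @param annotated Mutation tibble with a `region` column, as returned by
#'   [map_mutations()] (any `true_region`/`true_column` simulator columns
#'   are ignored).
#' @param map The `subdomain_map` used for annotation (provides per-kinase
#'   region lengths, including regions with zero observed SNPs).
#' @param alpha Significance level for the call (default 0.05).
#' @param adjust `"none"` (default; raw per-region P values) or `"BH"` for
#'   Benjamini-Hochberg adjustment before calling.
#' @return A tibble of class `kin_enrichment` with one row per
#'   (category, region): `category`, `region`, `weighted_length`,
#'   `expected_p`, `observed_x`, `total_n`, `p_value`, `call`.
#' @export
enrich_regions <- function(annotated, map, alpha = 0.05,
                           adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  if (!("region" %in% names(annotated))) {
    abort("annotated must carry a region column; run map_mutations() first")
  }
  region_lengths <- map$segments |>
    mutate(length = .data$end - .data$start) |>
    select("kinase_id", "region", "length")
  inside <- annotated |> filter(.data$region != "outside")
  out <- inside |>
    group_by(.data$category) |>
    group_modify(function(df, key) {
      weights <- df |> count(.data$kinase_id, name = "w")
      wl <- region_lengths |>
        inner_join(weights, by = "kinase_id") |>
        group_by(.data$region) |>
        summarise(
          weighted_length = weighted_region_length(.data$length, .data$w),
          .groups = "drop"
        )
      wl$expected_p <- expected_probability(
        setNames(wl$weighted_length, wl$region)
      )
      obs <- df |> count(.data$region, name = "observed_x")
      res <- wl |>
        left_join(obs, by = "region") |>
        mutate(
          observed_x = ifelse(is.na(.data$observed_x), 0L, .data$observed_x),
          total_n = nrow(df)
        )
      res$p_value <- binom_pvalue_two_tailed(res$observed_x, res$total_n,
                                             res$expected_p)
      res
    }) |>
    ungroup()
  p_for_call <- if (adjust == "BH") stats::p.adjust(out$p_value, "BH") else out$p_value
  out$call <- classify_enrichment_call(
    p_for_call, out$observed_x / out$total_n, out$expected_p, alpha
  )
  structure(out, class = c("kin_enrichment", class(out)),
            alpha = alpha, adjust = adjust)
}

#' @export
glance.kin_enrichment <- function(x, ...) {
  tibble(
    n_regions = nrow(x),
    n_enriched = sum(x$call == "enriched"),
    n_devoid = sum(x$call == "devoid"),
    alpha = attr(x, "alpha"),
    adjust = attr(x, "adjust")
  )
}

#' Plot per-region observed vs expected SNP rates
#'
#' Bars show observed per-region SNP fractions with the expected chance
#' probability overlaid; fill encodes the enrichment call (the conventional
#' red/green/blue map: enriched / neutral / devoid).
#'
#' @param object A `kin_enrichment` result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.kin_enrichment <- function(object, ...) {
  df <- as_tibble(object) |>
    mutate(region = factor(.data$region, levels = names(REGION_FRAMES)),
           observed_rate = .data$observed_x / .data$total_n)
  ggplot(df, aes(x = .data$region)) +
    geom_col(aes(y = .data$observed_rate, fill = .data$call)) +
    geom_point(aes(y = .data$expected_p), shape = 95, size = 8) +
    scale_fill_manual(values = c(enriched = "#c0392b", neutral = "#27ae60",
                                 devoid = "#2980b9")) +
    facet_wrap(~category) +
    labs(x = "Hanks-Hunter region", y = "SNP fraction",
         fill = "call",
         caption = "dash = expected chance probability E(p)") +
    theme_minimal()
}
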