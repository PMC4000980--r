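new_position_histogram <- function(per_column, histogram, n_positions, n_snps) {
  structure(
    list(per_column = per_column, histogram = histogram,
         n_positions = as.integer(n_positions), n_snps = as.integer(n_snps)),
    class = "position_histogram"
  )
}

#' @export
print.position_histogram <- function(x, ...) {
  cat("<position_histogram> ", x$n_snps, " SNPs over ", x$n_positions,
      " positions\n", sep = "")
  print(x$histogram)
  invisible(x)
}

#' @export
tidy.position_histogram <- function(x, ...) x$histogram

#' Per-position SNP count histogram
#'
#' Counts SNPs per structurally equivalent alignment column and derives the
#' multiplicity histogram: for each `k`, the number of positions carrying
#' exactly `k` SNPs. Columns of the supplied universe with no SNPs enter the
#' `k = 0` class, so the histogram satisfies the conservation identities
#' `sum_k histogram[k] = n_positions` and `sum_k k * histogram[k] = n_snps`.
#'
#' @param annotated Mutation tibble with a `column` field (from
#'   [map_mutations()] or the simulator's `true_column`).
#' @param columns The alignment-column universe: either an integer vector of
#'   all columns considered, or `NULL` to use the distinct columns observed
#'   in `annotated`.
#' @param strict If `TRUE`, rows with a missing column are an error;
#'   otherwise they are dropped with a warning.
#' @return A `position_histogram` object with elements `per_column` (tibble:
#'   `column`, `count`), `histogram` (tibble: `k`, `n_positions`),
#'   `n_positions`, `n_snps`.
#' @export
position_histogram <- function(annotated, columns = NULL, strict = FALSE) {
  if (!("column" %in% names(annotated))) {
    abort("annotated must carry a column field; run map_mutations() first")
  }
  miss <- is.na(annotated$column)
  if (any(miss)) {
    if (strict) abort(paste0(sum(miss), " mutation(s) carry no alignment column"))
    if (sum(miss) > 0) warn(paste0("dropping ", sum(miss),
                                   " mutation(s) with no alignment column"))
    annotated <- annotated[!miss, ]
  }
  columns <- sort(unique(as.integer(columns %||% annotated$column)))
  outside <- setdiff(unique(annotated$column), columns)
  if (length(outside) > 0) {
    abort(paste0("mutations at column(s) outside the supplied universe: ",
                 paste(head(outside, 3), collapse = ", ")))
  }
  counts <- table(factor(annotated$column, levels = columns))
  per_column <- tibble(column = columns, count = as.integer(counts))
  hist_tab <- per_column |> count(k = .data$count, name = "n_positions")
  new_position_histogram(per_column, hist_tab, length(columns), nrow(annotated))
}

#' Build a position histogram from a pre-tabulated k-table
#'
#' Constructs a `position_histogram` from an already-tabulated multiplicity
#' table (columns `k` and `n_positions`), such as the packaged observed
#' disease-SNP distribution from [observed_position_histogram()].
#'
#' @param k_table Tibble with columns `k` and `n_positions`.
#' @return A `position_histogram` (with an empty per-column table).
#' @export
as_position_histogram <- function(k_table) {
  stopifnot(all(c("k", "n_positions") %in% names(k_table)))
  hist_tab <- tibble(k = as.integer(k_table$k),
                     n_positions = as.integer(k_table$n_positions))
  new_position_histogram(
    tibble(column = integer(0), count = integer(0)),
    hist_tab,
    sum(hist_tab$n_positions),
    sum(hist_tab$k * hist_tab$n_positions)
  )
}

#' Monte Carlo random-assignment null for position-specific SNP counts
#'
#' Repeatedly drops `n_snps` SNPs at random onto `n_positions` alignment
#' positions (multinomially, with uniform or supplied placement weights) and
#' tallies the multiplicity histogram, returning the per-k mean, standard
#' deviation and standard error over iterations. This is the null against
#' which observed position-specific clustering is judged.
#'
#' @param n_snps Number of SNPs dropped per iteration.
#' @param n_positions Number of alignment positions.
#' @param weights Optional positive per-position placement weights
#'   (default uniform).
#' @param n_iter Number of Monte Carlo iterations (default 10000).
#' @param seed Integer seed, or `NULL`.
#' @return An object of class `mc_null_summary`: a tibble with columns `k`,
#'   `mean`, `sd`, `se`, plus attributes `n_iter`, `n_snps`, `n_positions`,
#'   `weights_mode`, `seed`.
#' @export
mc_position_null <- function(n_snps, n_positions, weights = NULL,
                             n_iter = 10000, seed = NULL) {
  if (n_iter < 1) abort("n_iter must be >= 1")
  if (n_positions < 1) abort("n_positions must be >= 1")
  if (!is.null(weights)) {
    if (length(weights) != n_positions || any(weights <= 0)) {
      abort("weights must be positive and of length n_positions")
    }
  }
  prob <- weights %||% rep(1, n_positions)
  tab <- with_seed_if(seed, {
    if (n_snps == 0L) {
      matrix(0L, nrow = n_positions, ncol = n_iter)
    } else {
      rmultinom(n_iter, n_snps, prob)
    }
  })
  kmax <- max(tab)
  per_k <- purrr::map(0:kmax, function(k) {
    cnt <- colSums(tab == k)
    c(mean = mean(cnt), sd = if (n_iter > 1) sd(cnt) else 0)
  })
  out <- tibble(
    k = 0:kmax,
    mean = purrr::map_dbl(per_k, "mean"),
    sd = purrr::map_dbl(per_k, "sd")
  ) |>
    mutate(se = .data$sd / sqrt(n_iter))
  structure(out, class = c("mc_null_summary", class(out)),
            n_iter = as.integer(n_iter), n_snps = as.integer(n_snps),
            n_positions = as.integer(n_positions),
            weights_mode = if (is.null(weights)) "uniform" else "weighted",
            seed = seed)
}

#' Compare an observed position histogram to its Monte Carlo null
#'
#' Joins the observed multiplicity histogram with the null summary and
#' reports, for each `k`, the observed number of positions, the null mean
#' +/- sd, and a z-like excess `(observed - mean) / sd`, flagging classes
#' with `|excess| > 3`.
#'
#' @param obs A `position_histogram`.
#' @param null An `mc_null_summary` run with the same `n_positions` and
#'   `n_snps`.
#' @return A tibble with columns `k`, `observed`, `null_mean`, `null_sd`,
#'   `null_se`, `excess`, `flagged`.
#' @export
compare_observed_to_null <- function(obs, null) {
  stopifnot(inherits(obs, "position_histogram"),
            inherits(null, "mc_null_summary"))
  if (obs$n_positions != attr(null, "n_positions") ||
      obs$n_snps != attr(null, "n_snps")) {
    abort(paste0(
      "observed (", obs$n_positions, " positions, ", obs$n_snps, " SNPs) and ",
      "null (", attr(null, "n_positions"), " positions, ", attr(null, "n_snps"),
      " SNPs) totals do not match"
    ))
  }
  ks <- sort(union(obs$histogram$k, null$k))
  tibble(k = ks) |>
    left_join(obs$histogram, by = "k") |>
    left_join(as_tibble(null), by = "k") |>
    mutate(
      observed = ifelse(is.na(.data$n_positions), 0L, .data$n_positions),
      null_mean = ifelse(is.na(.data$mean), 0, .data$mean),
      null_sd = ifelse(is.na(.data$sd), 0, .data$sd),
      null_se = ifelse(is.na(.data$se), 0, .data$se),
      excess = case_when(
        .data$null_sd > 0 ~ (.data$observed - .data$null_mean) / .data$null_sd,
        .data$observed == .data$null_mean ~ 0,
        .default = Inf * sign(.data$observed - .data$null_mean)
      ),
      flagged = abs(.data$excess) > 3
    ) |>
    select("k", "observed", "null_mean", "null_sd", "null_se", "excess",
           "flagged")
}

#' Detect cross-kinase mutational hotspots
#'
#' Finds alignment positions mutated in at least `min_kinases` different
#' kinase genes. Counting is over distinct kinase genes per position: a
#' kinase contributing several alternative substitutions at the same
#' position counts once. Hotspots are annotated with their structural
#' segment and a pooled activation status (majority over entries, `"mixed"`
#' on ties).
#'
#' @param annotated Mutation tibble with a grouping position column (an
#'   alignment `column` from [map_mutations()], or e.g. the
#'   `reference_position` of the packaged hotspot catalog).
#' @param min_kinases Hotspot threshold (default 3, the smallest recurrence
#'   reported for a conserved kinase hotspot).
#' @param position_col Name of the grouping column (default `"column"`).
#' @return A tibble with one row per hotspot, sorted by descending
#'   `n_kinases` then position: `position_col`, `segment` (if available),
#'   `n_kinases`, `kinases`, `activation_status`, `n_drivers`.
#' @export
find_hotspots <- function(annotated, min_kinases = 3, position_col = "column") {
  if (min_kinases < 1) abort("min_kinases must be >= 1")
  if (!(position_col %in% names(annotated))) {
    abort(paste0("annotated has no '", position_col, "' column"))
  }
  pos <- annotated[[position_col]]
  keep <- !is.na(pos)
  df <- annotated[keep, ]
  df$.pos <- pos[keep]
  has_segment <- "segment" %in% names(df)
  has_status <- "activation_status" %in% names(df)
  has_driver <- "driver" %in% names(df)
  out <- df |>
    group_by(.data$.pos) |>
    summarise(
      segment = if (has_segment) .data$segment[1] else NA_character_,
      n_kinases = n_distinct(.data$kinase_id),
      kinases = paste(sort(unique(.data$kinase_id)), collapse = ","),
      activation_status = if (has_status) {
        st <- .data$activation_status[!is.na(.data$activation_status) &
                                        .data$activation_status != "unknown"]
        if (length(st) == 0) "unknown" else {
          tt <- sort(table(st), decreasing = TRUE)
          if (length(tt) > 1 && tt[1] == tt[2]) "mixed" else names(tt)[1]
        }
      } else "unknown",
      n_drivers = if (has_driver) {
        n_distinct(.data$kinase_id[!is.na(.data$driver) & .data$driver])
      } else NA_integer_,
      .groups = "drop"
    ) |>
    filter(.data$n_kinases >= min_kinases) |>
    arrange(desc(.data$n_kinases), .data$.pos)
  names(out)[names(out) == ".pos"] <- position_col
  out
}

#' Plot observed vs null position-specific SNP multiplicities
#'
#' @param object Comparison table from [compare_observed_to_null()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_position_null <- function(object, ...) {
  df <- tidyr::pivot_longer(
    object |> select("k", "observed", "null_mean"),
    c("observed", "null_mean"),
    names_to = "source", values_to = "n_positions"
  )
  ggplot(df, aes(x = factor(.data$k), y = .data$n_positions,
                 fill = .data$source)) +
    geom_col(position = "dodge") +
    geom_errorbar(
      data = object,
      aes(x = factor(.data$k),
          ymin = .data$null_mean - .data$null_sd,
          ymax = .data$null_mean + .data$null_sd),
      inherit.aes = FALSE, width = 0.3
    ) +
    labs(x = "SNPs per position (k)", y = "number of positions",
         fill = NULL) +
    theme_minimal()
}
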