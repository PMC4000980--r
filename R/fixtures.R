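kinvar_extdata <- function(file) {
  path <- system.file("extdata", file, package = "kinvar")
  if (path == "") {
    # during in-source development (devtools::load_all) the file sits in inst/
    path <- file.path("inst", "extdata", file)
  }
  if (!file.exists(path)) abort(paste0("Packaged data file not found: ", file))
  path
}

#' Curated cross-kinase cancer mutation hotspot catalog
#'
#' A packaged transcription of a curated catalog of structurally conserved
#' cancer mutation hotspots in protein kinase genes: alignment positions
#' (labelled by their EGFR reference residue) at which somatic mutations
#' recur across several different kinase genes. One row per kinase entry.
#'
#' The printed per-hotspot mutation count equals the number of distinct
#' kinase genes carrying a mutation at the position (a kinase with several
#' alternative substitutions, e.g. FLT3 D835E/F/H/N/V/Y, counts once). The
#' catalog's P-loop G721 row is known to print a count of 5 while listing 6
#' kinase entries; both the printed and the recomputed value are retained
#' (columns `n_mutations_printed` vs. counting rows) rather than silently
#' resolving the discrepancy.
#'
#' @return A tibble with columns `reference_position`, `segment`
#'   (P-loop/Hinge/Activation), `kinase_id`, `mutation` (verbatim, possibly
#'   with `/`-separated alternative substitutions), `activation_status`,
#'   `n_mutations_printed`, `n_drivers_printed`.
#' @seealso [hotspot_catalog_mutations()] for the expanded per-substitution
#'   record view, [find_hotspots()].
#' @export
hotspot_catalog <- function() {
  raw <- read.delim(kinvar_extdata("hotspot_catalog.tsv"), sep = "\t",
                    stringsAsFactors = FALSE)
  as_tibble(raw) |> rename(kinase_id = "kinase")
}

# Expand "T315I/N" -> c("T315I", "T315N"); bare "G721" -> "G721X".
expand_mutation_token <- function(token) {
  m <- stringr::str_match(token, "^([A-Z])(\\d+)([A-Z]?(?:/[A-Z])*)$")
  if (is.na(m[1, 1])) return(tibble(wt_aa = NA_character_, position = NA_integer_,
                                    mut_aa = NA_character_))
  alts <- strsplit(m[1, 4], "/", fixed = TRUE)[[1]]
  alts <- alts[alts != ""]
  if (length(alts) == 0L) alts <- "X"
  tibble(wt_aa = m[1, 2], position = as.integer(m[1, 3]), mut_aa = alts)
}

#' Hotspot catalog as typed mutation records
#'
#' Expands the verbatim mutation strings of [hotspot_catalog()] into one
#' record per substitution (category `"cancer"`), keeping the hotspot grouping
#' columns. An entry printed without a mutant residue is given mutant `"X"`.
#'
#' @return A tibble of mutation records with the additional columns
#'   `reference_position` and `segment`.
#' @export
hotspot_catalog_mutations <- function() {
  hotspot_catalog() |>
    mutate(.parsed = purrr::map(.data$mutation, expand_mutation_token)) |>
    tidyr::unnest(".parsed") |>
    mutate(category = "cancer", driver = NA) |>
    select("reference_position", "segment", "kinase_id", "position",
           "wt_aa", "mut_aa", "category", "activation_status", "driver")
}

#' Curated activation-status labels for modelled somatic kinase mutations
#'
#' A packaged transcription of a curated summary of somatic kinase mutations
#' with their experimentally characterised effect on kinase activity
#' (activating / inactivating / no effect, coded `"none"`).
#'
#' @param expand If `TRUE` (default), expand `/`-separated alternative
#'   substitutions into one row each with parsed `wt_aa`, `position`,
#'   `mut_aa`; otherwise return the verbatim strings.
#' @return A tibble with columns `kinase_id`, `mutation`,
#'   `activation_status` and, when `expand = TRUE`, `position`, `wt_aa`,
#'   `mut_aa`.
#' @export
activation_catalog <- function(expand = TRUE) {
  raw <- as_tibble(read.delim(kinvar_extdata("activation_catalog.tsv"),
                              sep = "\t", stringsAsFactors = FALSE)) |>
    rename(kinase_id = "kinase")
  if (!expand) return(raw)
  raw |>
    mutate(.parsed = purrr::map(.data$mutation, expand_mutation_token)) |>
    tidyr::unnest(".parsed") |>
    select("kinase_id", "mutation", "position", "wt_aa", "mut_aa",
           "activation_status")
}

#' Observed per-position disease-SNP count histogram
#'
#' The packaged observed distribution of disease-associated SNP counts over
#' structurally equivalent catalytic-domain positions (207 positions, 359
#' SNPs): for each multiplicity `k`, the number of alignment positions
#' carrying exactly `k` SNPs, together with the originally reported Monte
#' Carlo random-assignment means and their standard errors.
#'
#' @return A tibble with columns `k`, `n_positions`, `sim_mean`, `sim_se`.
#' @seealso [as_position_histogram()], [mc_position_null()],
#'   [compare_observed_to_null()].
#' @export
observed_position_histogram <- function() {
  as_tibble(read.delim(kinvar_extdata("observed_position_histogram.tsv"),
                       sep = "\t", stringsAsFactors = FALSE))
}
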