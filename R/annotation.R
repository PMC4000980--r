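#' Default catalytic-motif patterns
#'
#' The five canonical anchor motifs of the kinase catalytic domain, as
#' regular expressions in their N-to-C order: the glycine-rich P-loop
#' (G-x-G-x-x-G), the beta3 VAIK motif carrying the catalytic lysine, the
#' catalytic-loop HRD, the activation-segment DFG and the closing APE.
#'
#' @return Named character vector of patterns (names are the anchor frames
#'   `ploop`, `vaik`, `hrd`, `dfg`, `ape`).
#' @export
kinase_motif_patterns <- function() {
  c(
    ploop = "G.G..G",
    vaik = "[VAI][AG][ILV]K",
    hrd = "HRD",
    dfg = "DFG",
    ape = "AP[ED]"
  )
}

#' Packaged subdomain segmentation scheme
#'
#' Reads the packaged YAML convention that turns the five motif anchors into
#' a partition of the catalytic domain into Hanks-Hunter subdomains I-XI
#' (X split into X(i)/X(ii)) and intervening regions. Boundaries between
#' anchors are a documented convention, not a measured quantity; pass a
#' modified list to [segment_subdomains()] to change it.
#'
#' @return A named list with the scheme parameters.
#' @export
subdomain_scheme <- function() {
  yaml::read_yaml(kinvar_extdata("subdomain_scheme.yaml"))
}

#' Locate the catalytic anchor motifs in a kinase sequence
#'
#' Scans left to right with the canonical order enforced: each motif is the
#' first match downstream of the end of the previous one (ties broken by the
#' leftmost match). Positions are reported in the kinase's own residue
#' numbering.
#'
#' @param sequence Amino-acid string (one-letter codes).
#' @param numbering_offset Residue number of the first character (default 1).
#' @param patterns Named, ordered character vector of motif regular
#'   expressions (default [kinase_motif_patterns()]).
#' @return A tibble with columns `motif`, `position` (match start, kinase
#'   numbering) and `length`.
#' @export
locate_motifs <- function(sequence, numbering_offset = 1L,
                          patterns = kinase_motif_patterns()) {
  if (length(patterns) == 0L) abort("patterns must be nonempty")
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  found <- integer(0)
  lens <- integer(0)
  cursor <- 1L  # first index allowed for the next motif (order constraint)
  for (i in seq_along(patterns)) {
    m <- regexpr(patterns[i], substr(sequence, cursor, n), perl = TRUE)
    if (m == -1L) {
      abort(paste0(
        "Motif '", names(patterns)[i], "' (", patterns[i], ") not found",
        if (length(found) > 0) {
          paste0(" downstream of ", names(patterns)[length(found)],
                 "; anchors found so far: ",
                 paste(names(patterns)[seq_along(found)],
                       found + numbering_offset - 1L,
                       sep = "=", collapse = ", "))
        } else ""
      ))
    }
    start <- cursor + as.integer(m) - 1L
    found <- c(found, start)
    lens <- c(lens, attr(m, "match.length"))
    cursor <- start + attr(m, "match.length")
  }
  tibble(
    motif = names(patterns),
    position = found + as.integer(numbering_offset) - 1L,
    length = as.integer(lens)
  )
}

# Region -> anchor frame of the shipped scheme, in catalytic-domain order.
REGION_FRAMES <- c(
  "I" = "ploop", "Ia" = "ploop",
  "II" = "vaik", "III" = "vaik", "IV" = "vaik", "V" = "vaik", "VIa" = "vaik",
  "VIb" = "hrd", "VIba" = "hrd",
  "VII" = "dfg", "VIII" = "dfg",
  "IX" = "ape", "X(i)" = "ape", "X(ii)" = "ape", "XI" = "ape"
)

# Coarse structural segment per Hanks-Hunter region.
REGION_SEGMENTS <- c(
  "I" = "P-loop", "Ia" = "N-lobe", "II" = "beta3", "III" = "alphaC",
  "IV" = "beta4-beta5", "V" = "Hinge", "VIa" = "alphaE",
  "VIb" = "Catalytic", "VIba" = "Catalytic",
  "VII" = "Activation", "VIII" = "Activation",
  "IX" = "C-lobe", "X(i)" = "C-lobe", "X(ii)" = "C-lobe", "XI" = "C-lobe"
)

#' Coarse structural segment of a Hanks-Hunter region
#'
#' Maps region labels (I..XI and intervening regions) to the coarse
#' structural segments used for hotspot reporting (P-loop, Hinge,
#' Activation, ...).
#'
#' @param region Character vector of region labels.
#' @return Character vector of segment labels (`"outside"` passes through).
#' @export
region_structural_segment <- function(region) {
  out <- unname(REGION_SEGMENTS[region])
  out[region == "outside"] <- "outside"
  out
}

#' Segment a kinase catalytic domain into Hanks-Hunter regions
#'
#' Turns located anchors into an ordered, gap-free partition of the
#' catalytic domain: subdomain I around the P-loop, II at the VAIK motif,
#' III/IV/V/VIa by proportional cuts of the VAIK-to-HRD span, VIb at the
#' catalytic loop, VII/VIII from DFG through APE (the activation segment),
#' and IX/X(i)/X(ii)/XI at fixed widths downstream of APE, truncated at the
#' end of the sequence. Intervening regions are suffixed `a` (`Ia`, `VIba`).
#'
#' @param anchors Tibble from [locate_motifs()].
#' @param seq_end Last residue number of the sequence (kinase numbering).
#' @param scheme Segmentation convention (default [subdomain_scheme()]).
#' @param numbering_offset Residue number of the first sequence character.
#' @return A tibble with columns `region`, `start`, `end` (half-open
#'   `[start, end)`, kinase numbering) and `frame` (anchor frame).
#' @export
segment_subdomains <- function(anchors, seq_end, scheme = subdomain_scheme(),
                               numbering_offset = 1L) {
  a <- setNames(anchors$position, anchors$motif)
  need <- c("ploop", "vaik", "hrd", "dfg", "ape")
  if (!all(need %in% names(a))) {
    abort(paste0("Anchors missing: ", paste(setdiff(need, names(a)), collapse = ", ")))
  }
  if (is.unsorted(a[need], strictly = TRUE)) {
    abort("Anchors out of canonical order (P-loop < VAIK < HRD < DFG < APE)")
  }
  g <- a[["ploop"]]; v <- a[["vaik"]]; h <- a[["hrd"]]; d <- a[["dfg"]]; ape <- a[["ape"]]
  pl <- scheme$ploop_len; vl <- scheme$vaik_len
  if (v < g + pl) abort("Anchors too close: VAIK overlaps the P-loop region")
  if (h < v + vl + 4L) abort("Anchors too close: VAIK-HRD span below minimum width")
  if (d < h + 3L) abort("Anchors too close: DFG overlaps the HRD motif")
  if (ape < d + 3L) abort("Anchors too close: APE overlaps the DFG motif")
  dom_start <- max(as.integer(numbering_offset), g - scheme$nterm_pad)
  span_start <- v + vl
  cuts <- span_start + round((h - span_start) * unlist(scheme$split_fractions))
  vib_end <- min(h + scheme$vib_width, d)
  cw <- scheme$cterm_widths
  c0 <- ape + 3L
  starts <- c(dom_start, g + pl, v, span_start, cuts, h, vib_end, d, d + 3L,
              c0, c0 + cw[["IX"]], c0 + cw[["IX"]] + cw[["X(i)"]],
              c0 + cw[["IX"]] + cw[["X(i)"]] + cw[["X(ii)"]])
  ends <- c(starts[-1], c0 + cw[["IX"]] + cw[["X(i)"]] + cw[["X(ii)"]] + cw[["XI"]])
  seg <- tibble(
    region = names(REGION_FRAMES),
    start = as.integer(starts),
    end = as.integer(pmin(ends, seq_end + 1L)),
    frame = unname(REGION_FRAMES)
  )
  seg <- seg[seg$end > seg$start, ]
  if (any(seg$start[-1] != seg$end[-nrow(seg)])) {
    abort("Internal error: segmentation is not a partition")
  }
  seg
}

#' Annotate a family of kinase sequences with subdomain maps
#'
#' Runs [locate_motifs()] and [segment_subdomains()] on every sequence and
#' bundles the result into a subdomain map object used by
#' [map_mutations()], [simulate_snp_table()] and the enrichment/clustering
#' stages.
#'
#' @param sequences Tibble from [read_kinase_fasta()] (columns `kinase_id`,
#'   `sequence`, `numbering_offset`).
#' @param patterns Motif patterns, see [locate_motifs()].
#' @param scheme Segmentation convention, see [subdomain_scheme()].
#' @return An object of class `subdomain_map` with components `segments`
#'   (tibble: `kinase_id`, `region`, `start`, `end`, `frame`), `anchors`
#'   (tibble: `kinase_id`, `motif`, `position`), `sequences` and `scheme`.
#' @export
annotate_subdomains <- function(sequences, patterns = kinase_motif_patterns(),
                                scheme = subdomain_scheme()) {
  anchors <- purrr::map2(sequences$sequence, sequences$numbering_offset,
                         locate_motifs, patterns = patterns)
  seq_end <- sequences$numbering_offset + nchar(sequences$sequence) - 1L
  segments <- purrr::pmap(
    list(anchors, seq_end, sequences$numbering_offset),
    function(an, se, off) segment_subdomains(an, se, scheme, off)
  )
  out <- list(
    segments = bind_rows(setNames(segments, sequences$kinase_id), .id = "kinase_id"),
    anchors = bind_rows(setNames(anchors, sequences$kinase_id), .id = "kinase_id"),
    sequences = as_tibble(sequences),
    scheme = scheme
  )
  class(out) <- "subdomain_map"
  out
}

#' @export
print.subdomain_map <- function(x, ...) {
  cat("<subdomain_map> ", length(unique(x$segments$kinase_id)), " kinase(s), ",
      nrow(x$segments), " segments\n", sep = "")
  invisible(x)
}

#' @export
tidy.subdomain_map <- function(x, ...) x$segments

#' Per-residue region and alignment-column lookup
#'
#' Expands a subdomain map into one row per catalytic-domain residue, with
#' its region and its anchor-frame alignment column. Columns are shared
#' across kinases: a residue's column is its region's frame base plus the
#' signed offset from that frame's anchor, so e.g. the DFG aspartate of
#' every kinase receives the same column.
#'
#' @param map A `subdomain_map`.
#' @return A tibble with `kinase_id`, `position`, `region`, `column`.
#' @export
domain_positions <- function(map) {
  seg <- map$segments
  lens <- seg$end - seg$start
  pos <- sequence(lens, from = seg$start)
  idx <- rep(seq_len(nrow(seg)), lens)
  anchor_key <- paste(map$anchors$kinase_id, map$anchors$motif)
  anchor <- map$anchors$position[
    match(paste(seg$kinase_id, seg$frame)[idx], anchor_key)
  ]
  base <- unlist(map$scheme$column_base)
  tibble(
    kinase_id = seg$kinase_id[idx],
    position = as.integer(pos),
    region = seg$region[idx],
    column = as.integer(unname(base[seg$frame[idx]]) + pos - anchor)
  )
}

#' Map mutation records to subdomain regions and alignment columns
#'
#' Joins a mutation table against a subdomain map: each record receives the
#' Hanks-Hunter `region` containing its position and the shared anchor-frame
#' alignment `column`. Positions outside the catalytic domain get region
#' `"outside"` and a missing column (no error). When the map carries
#' sequences, recorded wild-type residues are checked against them.
#'
#' @param mutations Mutation tibble (see [read_mutation_table()]).
#' @param map A `subdomain_map` covering every kinase in `mutations`.
#' @param strict_wt If `TRUE`, a wild-type residue that disagrees with the
#'   sequence is an error; default is a warning (numbering-offset
#'   discrepancies are common in the kinase literature).
#' @return `mutations` with `region`, `column` and `segment` (coarse
#'   structural label) columns appended.
#' @export
map_mutations <- function(mutations, map, strict_wt = FALSE) {
  missing_kin <- setdiff(unique(mutations$kinase_id), map$sequences$kinase_id)
  if (length(missing_kin) > 0) {
    abort(paste0("No subdomain map for kinase(s): ",
                 paste(missing_kin, collapse = ", ")))
  }
  lookup <- domain_positions(map)
  out <- mutations |>
    left_join(lookup, by = c("kinase_id", "position")) |>
    mutate(
      region = ifelse(is.na(.data$region), "outside", .data$region),
      segment = region_structural_segment(.data$region)
    )
  if (!is.null(map$sequences)) {
    seqs <- map$sequences
    idx <- match(out$kinase_id, seqs$kinase_id)
    chr <- out$position - seqs$numbering_offset[idx] + 1L
    inside <- chr >= 1L & chr <= nchar(seqs$sequence[idx])
    actual <- ifelse(inside, substr(seqs$sequence[idx], chr, chr), NA)
    bad <- which(!is.na(actual) & !is.na(out$wt_aa) & actual != out$wt_aa)
    if (length(bad) > 0) {
      msg <- paste0(
        length(bad), " mutation(s) whose recorded wild-type residue disagrees ",
        "with the sequence (first: ", out$kinase_id[bad[1]], " position ",
        out$position[bad[1]], ", recorded ", out$wt_aa[bad[1]],
        ", sequence has ", actual[bad[1]], ")"
      )
      if (strict_wt) abort(msg) else warn(msg)
    }
  }
  out
}

#' Synthetic EGFR-like catalytic-domain scaffold
#'
#' A deterministic synthetic sequence (not the real EGFR protein) that
#' plants the five canonical catalytic motifs at EGFR's published residue
#' numbers - GSGAFG at 719-724, VAIK with the catalytic lysine at K745, HRD
#' at 835, DFG at 855 (the catalytic aspartate) and APE at 877 - with
#' neutral linkers in between. It reproduces the residue arithmetic of the
#' well-known EGFR landmarks (gatekeeper T790 in the hinge, L858/L861 in the
#' activation segment) for examples and tests without shipping any
#' third-party sequence data.
#'
#' @return A one-row sequence tibble (`kinase_id = "EGFR"`,
#'   `numbering_offset = 712`).
#' @export
egfr_like_sequence <- function() {
  start <- 712L
  len <- 215L  # covers residues 712..926, through subdomain XI
  # linker alphabet excludes G/K/P/D/F/H/R so no spurious anchor motif can arise
  alphabet <- c("L", "S", "T", "N", "Q", "V", "M", "W", "Y", "I", "A", "E", "C")
  res <- rep(alphabet, length.out = len)
  put <- function(res, pos, aa) {
    aa <- strsplit(aa, "")[[1]]
    res[seq(pos - start + 1L, length.out = length(aa))] <- aa
    res
  }
  res <- put(res, 719L, "GSGAFG")
  res <- put(res, 742L, "VAIK")
  res <- put(res, 835L, "HRD")
  res <- put(res, 855L, "DFG")
  res <- put(res, 877L, "APE")
  # wild-type residues at well-known EGFR landmark positions
  for (lm in list(c(718, "L"), c(747, "L"), c(765, "V"), c(769, "V"),
                  c(790, "T"), c(796, "G"), c(833, "L"), c(854, "T"),
                  c(858, "L"), c(861, "L"))) {
    res <- put(res, as.integer(lm[1]), lm[2])
  }
  tibble(
    kinase_id = "EGFR",
    sequence = paste(res, collapse = ""),
    numbering_offset = start
  )
}
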