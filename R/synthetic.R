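#' Specification for simulated kinase families and SNP tables
#'
#' Bundles the parameters of the sequence-family and SNP-placement
#' simulators. The defaults emulate a mid-sized kinase family with
#' EGFR-like inter-motif spacing and a study-scale variant set: 20 kinases,
#' linker means (8, 17, 89, 17, 19, 50) residues with +/-3 jitter, 500 SNPs,
#' no region-level enrichment and near-uniform position weights.
#'
#' @param n_kinases Number of kinases in the family.
#' @param region_lengths Mean lengths (residues) of the six inter-motif
#'   stretches: before the P-loop, P-loop to VAIK, VAIK to HRD, HRD to DFG,
#'   DFG to APE, and the C-terminal tail.
#' @param length_jitter Maximum +/- deviation of each linker length.
#' @param enrichment Named per-region relative rate multipliers
#'   (1 = neutral); regions not named get 1.
#' @param clustering_concentration Symmetric Dirichlet concentration for
#'   per-column placement weights; large values approach uniform placement,
#'   small values (e.g. 0.05) concentrate SNPs on few columns.
#' @param n_snps Number of SNP records to draw.
#' @param seed Integer seed making the simulation a pure function of the
#'   spec, or `NULL` to use the current RNG stream.
#' @return A list of class `snp_sim_spec`.
#' @export
snp_sim_spec <- function(n_kinases = 20,
                         region_lengths = c(pre = 8, ploop_vaik = 17,
                                            vaik_hrd = 89, hrd_dfg = 17,
                                            dfg_ape = 19, tail = 50),
                         length_jitter = 3,
                         enrichment = numeric(0),
                         clustering_concentration = 100,
                         n_snps = 500,
                         seed = NULL) {
  stopifnot(n_kinases >= 1, length(region_lengths) == 6, all(region_lengths > 0),
            length_jitter >= 0, n_snps >= 0, clustering_concentration > 0)
  if (length(enrichment) > 0 && any(enrichment <= 0)) {
    abort("enrichment multipliers must be > 0")
  }
  structure(
    list(
      n_kinases = as.integer(n_kinases),
      region_lengths = region_lengths,
      length_jitter = as.integer(length_jitter),
      enrichment = enrichment,
      clustering_concentration = clustering_concentration,
      n_snps = as.integer(n_snps),
      seed = seed
    ),
    class = "snp_sim_spec"
  )
}

SIM_MOTIFS <- c(ploop = "GSGAFG", vaik = "VAIK", hrd = "HRD", dfg = "DFG",
                ape = "APE")
# Linker alphabet excludes G/K/P/D/F/H/R so linkers can never spell a motif.
SIM_LINKER_ALPHABET <- c("L", "S", "T", "N", "Q", "V", "M", "W", "Y", "I",
                         "A", "E", "C")

sim_linker <- function(len, forbid_last = character(0)) {
  if (len == 0L) return("")
  chars <- sample(SIM_LINKER_ALPHABET, len, replace = TRUE)
  if (length(forbid_last) > 0) {
    ok <- setdiff(SIM_LINKER_ALPHABET, forbid_last)
    chars[len] <- sample(ok, 1L)
  }
  paste(chars, collapse = "")
}

#' Simulate a kinase sequence family with known subdomain truth
#'
#' Generates `n_kinases` synthetic catalytic-domain sequences, each carrying
#' the five canonical anchor motifs (GSGAFG, VAIK, HRD, DFG, APE) in order,
#' separated by neutral random linkers of lengths `region_lengths` +/-
#' `length_jitter`. Linkers are drawn from an alphabet that cannot spell any
#' motif, so motif discovery is unambiguous. The ground-truth segmentation
#' (the subdomain map implied by the planted anchors) is returned alongside.
#'
#' @param spec A [snp_sim_spec()].
#' @param scheme Segmentation convention used for the truth map.
#' @return A list with `sequences` (tibble) and `truth` (a `subdomain_map`
#'   built from the planted anchor positions).
#' @export
simulate_kinase_family <- function(spec, scheme = subdomain_scheme()) {
  stopifnot(inherits(spec, "snp_sim_spec"))
  rl <- spec$region_lengths
  j <- spec$length_jitter
  if (rl[3] - j < 8) abort("vaik_hrd region length too short to host the subdomain split")
  if (any(rl[-1] - j < 0) || rl[1] - j < 0) {
    abort("region lengths too short for the requested jitter")
  }
  with_seed_if(spec$seed, {
    per_kinase <- purrr::map(seq_len(spec$n_kinases), function(i) {
      lens <- pmax(0L, round(rl) + sample(seq(-j, j), 6L, replace = TRUE))
      lens[3] <- max(lens[3], 8L)
      linkers <- c(
        sim_linker(lens[1]),
        sim_linker(lens[2], forbid_last = c("V", "A", "I")),
        sim_linker(lens[3]),
        sim_linker(lens[4]),
        sim_linker(lens[5]),
        sim_linker(lens[6])
      )
      seqc <- paste0(linkers[1], SIM_MOTIFS["ploop"], linkers[2],
                     SIM_MOTIFS["vaik"], linkers[3], SIM_MOTIFS["hrd"],
                     linkers[4], SIM_MOTIFS["dfg"], linkers[5],
                     SIM_MOTIFS["ape"], linkers[6])
      g <- lens[1] + 1L
      v <- g + 6L + lens[2]
      h <- v + 4L + lens[3]
      d <- h + 3L + lens[4]
      ape <- d + 3L + lens[5]
      list(
        sequence = seqc,
        anchors = tibble(motif = names(SIM_MOTIFS),
                         position = c(g, v, h, d, ape),
                         length = c(6L, 4L, 3L, 3L, 3L))
      )
    })
    ids <- sprintf("KIN%02d", seq_len(spec$n_kinases))
    sequences <- tibble(
      kinase_id = ids,
      sequence = purrr::map_chr(per_kinase, "sequence"),
      numbering_offset = 1L
    )
    anchors <- bind_rows(setNames(purrr::map(per_kinase, "anchors"), ids),
                         .id = "kinase_id")
    segments <- purrr::map(per_kinase, function(pk) {
      segment_subdomains(pk$anchors, nchar(pk$sequence), scheme, 1L)
    })
    truth <- structure(
      list(
        segments = bind_rows(setNames(segments, ids), .id = "kinase_id"),
        anchors = anchors,
        sequences = sequences,
        scheme = scheme
      ),
      class = "subdomain_map"
    )
    list(sequences = sequences, truth = truth)
  })
}

#' Simulate a SNP table with known region- and position-level structure
#'
#' Places `n_snps` variants on a kinase family. Each SNP (i) draws a region
#' with probability proportional to the family-mean region length times its
#' enrichment multiplier, (ii) draws an alignment column within the region
#' from per-column weights sampled once per table from a symmetric Dirichlet
#' with the spec's clustering concentration, and (iii) lands on a random
#' kinase carrying that column in that region. Wild-type residues are read
#' from the sequence; the mutant residue is a random different amino acid.
#'
#' @param truth A `subdomain_map` carrying the ground-truth segmentation
#'   (e.g. from [simulate_kinase_family()]).
#' @param spec A [snp_sim_spec()].
#' @param category Variant category recorded on every row.
#' @param stratify_by_kinase If `TRUE`, split SNP totals evenly across
#'   kinases first and place within each kinase (per-kinase-stratified
#'   placement); default pooled placement across the family.
#' @return A mutation tibble with the additional ground-truth columns
#'   `true_region` and `true_column`.
#' @export
simulate_snp_table <- function(truth, spec, category = "disease",
                               stratify_by_kinase = FALSE) {
  stopifnot(inherits(spec, "snp_sim_spec"))
  lookup <- domain_positions(truth)
  if (spec$n_snps == 0L) {
    return(as_mutation_table(tibble(
      kinase_id = character(0), position = integer(0), wt_aa = character(0),
      mut_aa = character(0), category = character(0),
      true_region = character(0), true_column = integer(0)
    )))
  }
  if (nrow(lookup) == 0L) abort("n_snps > 0 but the truth map covers no positions")
  regions <- lookup |>
    count(.data$kinase_id, .data$region) |>
    group_by(.data$region) |>
    summarise(mean_len = mean(.data$n), .groups = "drop")
  mult <- rep(1, nrow(regions))
  if (length(spec$enrichment) > 0) {
    hit <- match(regions$region, names(spec$enrichment))
    mult[!is.na(hit)] <- spec$enrichment[hit[!is.na(hit)]]
  }
  with_seed_if(spec$seed, {
    # per-(region, column) placement weights: symmetric Dirichlet, drawn once
    universe <- lookup |> distinct(.data$region, .data$column)
    universe$weight <- rgamma(nrow(universe), shape = spec$clustering_concentration)
    universe$weight <- universe$weight / sum(universe$weight)
    if (stratify_by_kinase) {
      kin_ids <- truth$sequences$kinase_id
      kin_draw <- kin_ids[1L + (seq_len(spec$n_snps) - 1L) %% length(kin_ids)]
      rows <- purrr::map(kin_ids, function(kid) {
        m <- sum(kin_draw == kid)
        if (m == 0L) return(NULL)
        sub <- lookup[lookup$kinase_id == kid, ]
        w <- universe$weight[match(paste(sub$region, sub$column),
                                   paste(universe$region, universe$column))]
        rm <- mult[match(sub$region, regions$region)]
        idx <- sample.int(nrow(sub), m, replace = TRUE, prob = w * rm)
        sub[idx, ]
      })
      placed <- bind_rows(rows)
    } else {
      region_draw <- sample(regions$region, spec$n_snps, replace = TRUE,
                            prob = regions$mean_len * mult)
      uni_by_region <- split(seq_len(nrow(universe)), universe$region)
      draw_row <- integer(spec$n_snps)
      for (r in unique(region_draw)) {
        hit <- region_draw == r
        ids <- uni_by_region[[r]]
        draw_row[hit] <- ids[sample.int(length(ids), sum(hit), replace = TRUE,
                                        prob = universe$weight[ids])]
      }
      # pick a random kinase among the carriers of each drawn (region, column)
      carr_key <- paste(lookup$region, lookup$column)
      ord <- order(carr_key, method = "radix")
      sorted_key <- carr_key[ord]
      grp_start <- which(!duplicated(sorted_key))
      grp_len <- diff(c(grp_start, length(sorted_key) + 1L))
      grp_names <- sorted_key[grp_start]
      draw_key <- paste(universe$region, universe$column)[draw_row]
      gi <- match(draw_key, grp_names)
      pick <- grp_start[gi] + floor(runif(spec$n_snps) * grp_len[gi])
      placed_idx <- ord[pick]
      placed <- tibble(
        kinase_id = lookup$kinase_id[placed_idx],
        region = lookup$region[placed_idx],
        column = lookup$column[placed_idx],
        position = lookup$position[placed_idx]
      )
    }
    seqs <- truth$sequences
    idx <- match(placed$kinase_id, seqs$kinase_id)
    chr <- placed$position - seqs$numbering_offset[idx] + 1L
    wt <- substr(seqs$sequence[idx], chr, chr)
    mut <- vapply(wt, function(w) sample(setdiff(AA_STANDARD, w), 1L),
                  character(1), USE.NAMES = FALSE)
    as_mutation_table(tibble(
      kinase_id = placed$kinase_id,
      position = placed$position,
      wt_aa = wt,
      mut_aa = mut,
      category = category,
      true_region = placed$region,
      true_column = placed$column
    ))
  })
}

#' Specification for simulated C-alpha trajectories
#'
#' Parameters of the trajectory simulator. The default emulates the planted
#' two-regime fluctuation condition used throughout the package's
#' calibration: 60 residues, the first half rigid (isotropic sd 0.1
#' Angstrom) and the second half flexible (sd 1.0 Angstrom), 400 frames, no
#' collective modes and no global rigid-body motion.
#'
#' @param n_residues Number of residues.
#' @param n_frames Number of frames (>= 2).
#' @param sigma_profile Per-residue isotropic fluctuation sd (Angstrom);
#'   recycled to `n_residues`.
#' @param mode_specs List of planted collective modes, each a list with
#'   `direction` (an `n_residues x 3` matrix, normalised internally) and
#'   `amplitude` (sd of the per-frame mode coordinate, Angstrom).
#' @param global_motion If `TRUE`, apply an independent random rigid-body
#'   rotation and translation to every frame.
#' @param seed Integer seed, or `NULL`.
#' @return A list of class `traj_sim_spec`.
#' @export
traj_sim_spec <- function(n_residues = 60,
                          n_frames = 400,
                          sigma_profile = c(rep(0.1, ceiling(n_residues / 2)),
                                            rep(1.0, floor(n_residues / 2))),
                          mode_specs = list(),
                          global_motion = FALSE,
                          seed = NULL) {
  stopifnot(n_residues >= 3, n_frames >= 2)
  sigma_profile <- rep_len(sigma_profile, n_residues)
  if (any(sigma_profile < 0)) abort("sigma_profile must be >= 0")
  for (ms in mode_specs) {
    if (is.null(ms$direction) || is.null(ms$amplitude) || ms$amplitude < 0) {
      abort("each mode spec needs a direction matrix and a nonnegative amplitude")
    }
  }
  structure(
    list(n_residues = as.integer(n_residues), n_frames = as.integer(n_frames),
         sigma_profile = sigma_profile, mode_specs = mode_specs,
         global_motion = isTRUE(global_motion), seed = seed),
    class = "traj_sim_spec"
  )
}

# Ideal helix-like backbone with ~3.8 Angstrom C-alpha spacing.
helix_backbone <- function(n) {
  i <- seq_len(n)
  theta <- i * 100 * pi / 180
  cbind(2.3 * cos(theta), 2.3 * sin(theta), 1.5 * i)
}

random_rotation <- function() {
  qr_out <- qr(matrix(rnorm(9), 3, 3))
  q <- qr.Q(qr_out)
  d <- diag(qr.R(qr_out))
  q <- q %*% diag(sign(d))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

#' Simulate a C-alpha trajectory with known mobility ground truth
#'
#' Frames are built as an ideal helix-like base structure plus per-residue
#' isotropic Gaussian noise (`sigma_profile`) plus the planted collective
#' modes, optionally wrapped in per-frame random rigid-body motion. The
#' rigid/flexible ground truth follows the sigma profile (threshold at the
#' midpoint of its range).
#'
#' @param spec A [traj_sim_spec()].
#' @return A list with `trajectory` (a [kin_trajectory()]), `truth` (tibble:
#'   `residue`, `sigma`, `label`) and `mode_directions` (list of the planted
#'   unit direction matrices).
#' @export
simulate_trajectory <- function(spec) {
  stopifnot(inherits(spec, "traj_sim_spec"))
  n <- spec$n_residues
  nf <- spec$n_frames
  base <- helix_backbone(n)
  dirs <- purrr::map(spec$mode_specs, function(ms) {
    dm <- as.matrix(ms$direction)
    if (!all(dim(dm) == c(n, 3))) abort("mode direction must be n_residues x 3")
    dm / sqrt(sum(dm^2))
  })
  with_seed_if(spec$seed, {
    coords <- array(0, dim = c(nf, n, 3))
    noise_sd <- spec$sigma_profile
    for (ax in 1:3) {
      coords[, , ax] <- matrix(rep(base[, ax], each = nf), nf, n) +
        matrix(rnorm(nf * n, sd = rep(noise_sd, each = nf)), nf, n)
    }
    for (k in seq_along(dirs)) {
      amp <- rnorm(nf, sd = spec$mode_specs[[k]]$amplitude)
      for (ax in 1:3) {
        coords[, , ax] <- coords[, , ax] + outer(amp, dirs[[k]][, ax])
      }
    }
    if (spec$global_motion) {
      for (f in seq_len(nf)) {
        rot <- random_rotation()
        shift <- rnorm(3, sd = 5)
        coords[f, , ] <- sweep(coords[f, , , drop = FALSE][1, , ] %*% t(rot),
                               2, -shift)
      }
    }
    sig <- spec$sigma_profile
    thr <- (min(sig) + max(sig)) / 2
    label <- if (max(sig) - min(sig) < 1e-12) {
      rep(NA_character_, n)
    } else {
      ifelse(sig > thr, "flexible", "rigid")
    }
    list(
      trajectory = kin_trajectory(coords),
      truth = tibble(residue = seq_len(n), sigma = sig, label = label),
      mode_directions = dirs
    )
  })
}
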