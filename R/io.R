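#' Read kinase catalytic-domain sequences from FASTA
#'
#' Each record becomes one row. Residue numbering of the first sequence
#' character defaults to 1; a record whose header carries a `start=<int>` tag
#' (e.g. `>EGFR start=712`) is numbered from that residue instead, so that
#' positions reported downstream match the kinase's own published numbering.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `kinase_id` (first whitespace-delimited token
#'   of the header, minus the tag), `sequence` (upper-case one-letter codes)
#'   and `numbering_offset` (integer, residue number of the first character).
#' @export
read_kinase_fasta <- function(path) {
  if (!file.exists(path)) abort(paste0("FASTA file not found: ", path))
  aas <- withCallingHandlers(
    Biostrings::readAAStringSet(path),
    warning = function(w) {
      if (grepl("invalid one-letter sequence codes", conditionMessage(w))) {
        abort(paste0("FASTA file ", path,
                     " contains illegal residue characters"))
      }
      invokeRestart("muffleWarning")
    }
  )
  if (length(aas) == 0L) abort(paste0("FASTA file is empty: ", path))
  headers <- names(aas)
  offset <- stringr::str_match(headers, "start=(\\d+)")[, 2]
  offset <- ifelse(is.na(offset), 1L, as.integer(offset))
  ids <- stringr::str_split_fixed(headers, "\\s+", 2)[, 1]
  seqs <- toupper(as.character(aas))
  for (i in seq_along(seqs)) {
    bad <- setdiff(unique(strsplit(seqs[i], "")[[1]]), c(AA_STANDARD, "X"))
    if (length(bad) > 0) {
      abort(paste0(
        "Record '", ids[i], "': illegal residue character(s): ",
        paste(bad, collapse = ", ")
      ))
    }
    if (nchar(seqs[i]) == 0L) abort(paste0("Record '", ids[i], "' is empty"))
    if (offset[i] < 1L) abort(paste0("Record '", ids[i], "': start= must be >= 1"))
  }
  if (anyDuplicated(ids)) {
    abort(paste0(
      "Duplicate kinase_id in FASTA: ",
      paste(unique(ids[duplicated(ids)]), collapse = ", ")
    ))
  }
  tibble(kinase_id = ids, sequence = unname(seqs), numbering_offset = offset)
}

#' Write kinase sequences to FASTA
#'
#' Inverse of [read_kinase_fasta()]: a `numbering_offset` other than 1 is
#' encoded as a `start=<int>` header tag.
#'
#' @param sequences Tibble with `kinase_id`, `sequence`, `numbering_offset`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_kinase_fasta <- function(sequences, path) {
  hdr <- ifelse(
    sequences$numbering_offset == 1L,
    paste0(">", sequences$kinase_id),
    paste0(">", sequences$kinase_id, " start=", sequences$numbering_offset)
  )
  writeLines(as.vector(rbind(hdr, sequences$sequence)), path)
  invisible(path)
}

MUTATION_CATEGORIES <- c("common", "disease", "cancer")
ACTIVATION_LEVELS <- c("activating", "inactivating", "none", "unknown")

#' Read a mutation/SNP table
#'
#' Reads a tab-separated table of amino-acid variants. Mandatory columns:
#' `kinase`, `position`, `wt`, `mut`, `category`; optional columns
#' `activation_status` and `driver` default to `"unknown"` and `NA`.
#'
#' @param path Path to a TSV file with a header row.
#' @param dedupe If `TRUE`, collapse to one record per
#'   (kinase, position, category) so that no site within a kinase is counted
#'   more than once (the non-redundancy rule used for enrichment statistics).
#' @return A tibble of validated records: `kinase_id`, `position`, `wt_aa`,
#'   `mut_aa`, `category`, `activation_status`, `driver`.
#' @export
read_mutation_table <- function(path, dedupe = FALSE) {
  if (!file.exists(path)) abort(paste0("Mutation table not found: ", path))
  raw <- read.delim(path, sep = "\t", stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("kinase", "position", "wt", "mut", "category")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0(
      "Mutation table is missing mandatory column(s): ",
      paste(missing_cols, collapse = ", ")
    ))
  }
  as_mutation_table(
    tibble(
      kinase_id = as.character(raw$kinase),
      position = raw$position,
      wt_aa = toupper(as.character(raw$wt)),
      mut_aa = toupper(as.character(raw$mut)),
      category = as.character(raw$category),
      activation_status = as.character(raw[["activation_status"]] %||% rep("unknown", nrow(raw))),
      driver = as.logical(raw[["driver"]] %||% rep(NA, nrow(raw)))
    ),
    dedupe = dedupe
  )
}

#' Validate (and optionally deduplicate) a mutation table
#'
#' @param x Data frame with columns `kinase_id`, `position`, `wt_aa`,
#'   `mut_aa`, `category` and optionally `activation_status`, `driver`.
#' @inheritParams read_mutation_table
#' @return A validated tibble (see [read_mutation_table()]).
#' @export
as_mutation_table <- function(x, dedupe = FALSE) {
  x <- as_tibble(x)
  if (!("activation_status" %in% names(x))) x$activation_status <- "unknown"
  if (!("driver" %in% names(x))) x$driver <- NA
  x$activation_status[is.na(x$activation_status) | x$activation_status == ""] <- "unknown"
  pos_num <- suppressWarnings(as.numeric(x$position))
  bad <- which(is.na(pos_num) | pos_num != round(pos_num) | pos_num < 1)
  if (length(bad) > 0) {
    abort(paste0("Row ", bad[1], ": position must be a positive integer (got '",
                 x$position[bad[1]], "')"))
  }
  x$position <- as.integer(pos_num)
  bad <- which(x$wt_aa == x$mut_aa)
  if (length(bad) > 0) {
    abort(paste0("Row ", bad[1], ": wild-type and mutant residue are identical ('",
                 x$wt_aa[bad[1]], "')"))
  }
  bad <- which(!(x$category %in% MUTATION_CATEGORIES))
  if (length(bad) > 0) {
    abort(paste0("Row ", bad[1], ": unknown category '", x$category[bad[1]],
                 "' (expected one of ", paste(MUTATION_CATEGORIES, collapse = ", "), ")"))
  }
  bad <- which(!(x$activation_status %in% ACTIVATION_LEVELS))
  if (length(bad) > 0) {
    abort(paste0("Row ", bad[1], ": unknown activation_status '",
                 x$activation_status[bad[1]], "'"))
  }
  x$driver <- as.logical(x$driver)
  if (dedupe) {
    x <- x |>
      group_by(.data$kinase_id, .data$position, .data$category) |>
      slice(1L) |>
      ungroup()
  }
  x
}

# ---- trajectories -----------------------------------------------------------

#' Construct a C-alpha trajectory object
#'
#' @param coords Numeric array of dimension `n_frames x n_residues x 3` (in
#'   Angstrom), or a list of per-frame `n_residues x 3` matrices.
#' @param residue_ids Integer residue numbers (default `1:n_residues`).
#' @return An object of class `kin_trajectory`.
#' @export
kin_trajectory <- function(coords, residue_ids = NULL) {
  if (is.list(coords)) {
    nr <- unique(vapply(coords, nrow, 1L))
    if (length(nr) != 1L) abort("All frames must have the same residue count")
    coords <- aperm(array(unlist(coords), dim = c(nr, 3L, length(coords))), c(3, 1, 2))
  }
  stopifnot(is.array(coords), length(dim(coords)) == 3L, dim(coords)[3] == 3L)
  if (!all(is.finite(coords))) abort("Trajectory coordinates must be finite")
  if (dim(coords)[1] < 2L) abort("A trajectory needs at least 2 frames")
  residue_ids <- as.integer(residue_ids %||% seq_len(dim(coords)[2]))
  if (length(residue_ids) != dim(coords)[2]) {
    abort("residue_ids length must equal the residue count")
  }
  structure(
    list(coords = coords, residue_ids = residue_ids),
    class = "kin_trajectory"
  )
}

#' @export
print.kin_trajectory <- function(x, ...) {
  d <- dim(x$coords)
  cat("<kin_trajectory> ", d[1], " frames x ", d[2], " residues\n", sep = "")
  invisible(x)
}

#' @export
dim.kin_trajectory <- function(x) dim(x$coords)[1:2]

#' @export
as_tibble.kin_trajectory <- function(x, ...) {
  d <- dim(x$coords)
  co <- x$coords
  tibble(
    frame = rep(seq_len(d[1]), times = d[2]),
    residue = rep(x$residue_ids, each = d[1]),
    x = as.vector(co[, , 1]),
    y = as.vector(co[, , 2]),
    z = as.vector(co[, , 3])
  ) |> arrange(.data$frame, .data$residue)
}

#' Read a C-alpha trajectory
#'
#' Two plain-text dialects are supported: multi-model PDB (frames delimited by
#' `MODEL`/`ENDMDL`; the first C-alpha of each residue is taken, alternate
#' locations and occupancies are ignored) and a whitespace XYZ table with
#' columns `frame`, `residue`, `x`, `y`, `z`.
#'
#' @param path Input file.
#' @param format `"multi_model_pdb"` or `"xyz_frames"`.
#' @return A [kin_trajectory()].
#' @export
read_trajectory <- function(path, format = c("multi_model_pdb", "xyz_frames")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("Trajectory file not found: ", path))
  if (format == "multi_model_pdb") read_trajectory_pdb(path) else read_trajectory_xyz(path)
}

read_trajectory_pdb <- function(path) {
  lines <- readLines(path)
  model_starts <- grep("^MODEL", lines)
  if (length(model_starts) < 2L) {
    abort("Multi-model PDB must contain at least 2 MODEL blocks")
  }
  model_ends <- grep("^ENDMDL", lines)
  if (length(model_ends) != length(model_starts)) {
    abort("Unbalanced MODEL/ENDMDL records")
  }
  frames <- purrr::map(seq_along(model_starts), function(i) {
    block <- lines[model_starts[i]:model_ends[i]]
    atom <- block[startsWith(block, "ATOM") | startsWith(block, "HETATM")]
    name <- trimws(substr(atom, 13, 16))
    atom <- atom[name == "CA"]
    if (length(atom) == 0L) abort(paste0("Frame ", i, ": no C-alpha atoms"))
    resno <- as.integer(trimws(substr(atom, 23, 26)))
    keep <- !duplicated(resno)  # first CA per residue (altloc copies dropped)
    resno <- resno[keep]
    atom <- atom[keep]
    list(
      resno = resno,
      xyz = cbind(
        as.numeric(substr(atom, 31, 38)),
        as.numeric(substr(atom, 39, 46)),
        as.numeric(substr(atom, 47, 54))
      )
    )
  })
  ref <- frames[[1]]$resno
  for (i in seq_along(frames)) {
    fr <- frames[[i]]$resno
    if (!identical(fr, ref)) {
      miss <- setdiff(ref, fr)
      extra <- setdiff(fr, ref)
      what <- if (length(miss) > 0) {
        paste0("missing residue ", miss[1])
      } else if (length(extra) > 0) {
        paste0("extra residue ", extra[1])
      } else {
        "residue order differs"
      }
      abort(paste0("Frame ", i, ": inconsistent residue set (", what, ")"))
    }
  }
  kin_trajectory(purrr::map(frames, "xyz"), residue_ids = ref)
}

read_trajectory_xyz <- function(path) {
  first <- readLines(path, n = 1L)
  has_header <- is.na(suppressWarnings(as.numeric(strsplit(trimws(first), "\\s+")[[1]][1])))
  tab <- read.table(path, header = has_header)
  if (ncol(tab) < 5L) abort("XYZ trajectory must have columns frame, residue, x, y, z")
  names(tab)[1:5] <- c("frame", "residue", "x", "y", "z")
  frames <- sort(unique(tab$frame))
  if (length(frames) < 2L) abort("A trajectory needs at least 2 frames")
  ref <- sort(unique(tab$residue[tab$frame == frames[1]]))
  mats <- purrr::map(frames, function(f) {
    sub <- tab[tab$frame == f, ]
    sub <- sub[order(sub$residue), ]
    if (!identical(as.integer(sub$residue), as.integer(ref))) {
      miss <- setdiff(ref, sub$residue)
      abort(paste0(
        "Frame ", f, ": inconsistent residue set",
        if (length(miss) > 0) paste0(" (missing residue ", miss[1], ")") else ""
      ))
    }
    as.matrix(sub[, c("x", "y", "z")])
  })
  kin_trajectory(mats, residue_ids = as.integer(ref))
}

#' Write a trajectory as a whitespace XYZ table
#'
#' @param traj A [kin_trajectory()].
#' @param path Output path.
#' @param digits Decimal places for coordinates (default 6).
#' @return `path`, invisibly.
#' @export
write_trajectory_xyz <- function(traj, path, digits = 6) {
  tab <- as_tibble(traj)
  tab$x <- formatC(tab$x, format = "f", digits = digits)
  tab$y <- formatC(tab$y, format = "f", digits = digits)
  tab$z <- formatC(tab$z, format = "f", digits = digits)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a trajectory as a multi-model PDB
#'
#' C-alpha-only `MODEL`/`ENDMDL` blocks, readable by [read_trajectory()] and
#' standard structure viewers.
#'
#' @inheritParams write_trajectory_xyz
#' @return `path`, invisibly.
#' @export
write_trajectory_pdb <- function(traj, path) {
  d <- dim(traj$coords)
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(d[1])) {
    writeLines(sprintf("MODEL     %4d", f), con)
    writeLines(sprintf(
      "ATOM  %5d  CA  ALA A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
      seq_len(d[2]), traj$residue_ids,
      traj$coords[f, , 1], traj$coords[f, , 2], traj$coords[f, , 3]
    ), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Write a structure with mobility encoded in the B-factor column
#'
#' Writes a C-alpha PDB whose B-factor column holds `100 * mobility` (rounded
#' to two decimals), the standard trick for blue-to-red mobility colouring in
#' molecular viewers.
#'
#' @param coords `n_residues x 3` matrix of C-alpha coordinates (Angstrom).
#' @param mobility Per-residue mobility values in `[0, 1]`.
#' @param path Output path.
#' @param residue_ids Integer residue numbers (default `1:n`).
#' @return `path`, invisibly.
#' @export
write_mobility_pdb <- function(coords, mobility, path, residue_ids = NULL) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (length(mobility) != n) {
    abort(paste0("mobility has length ", length(mobility),
                 " but the structure has ", n, " residues"))
  }
  if (any(mobility < 0 | mobility > 1)) abort("mobility values must lie in [0, 1]")
  residue_ids <- as.integer(residue_ids %||% seq_len(n))
  bio3d::write.pdb(
    file = path,
    xyz = as.vector(t(coords)),
    resno = residue_ids,
    resid = rep("ALA", n),
    elety = rep("CA", n),
    chain = rep("A", n),
    o = rep(1, n),
    b = round(100 * mobility, 2)
  )
  invisible(path)
}
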