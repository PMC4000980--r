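#' Optimal rigid-body superposition (Kabsch)
#'
#' Least-squares rotation (proper, no reflection) and translation mapping
#' the moving coordinates onto the reference.
#'
#' @param moving,reference `n x 3` coordinate matrices with matched rows.
#' @return The `n x 3` matrix of superposed moving coordinates.
#' @export
kabsch_superpose <- function(moving, reference) {
  if (nrow(moving) < 3) abort("superposition needs at least 3 residues")
  mbar <- colMeans(moving)
  rbar <- colMeans(reference)
  mc <- sweep(moving, 2, mbar)
  rc <- sweep(reference, 2, rbar)
  h <- crossprod(mc, rc)
  s <- svd(h)
  d <- sign(det(s$v %*% t(s$u)))
  if (d == 0) abort("degenerate (collinear) geometry; superposition undefined")
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  sweep(mc %*% t(rot), 2, rbar, "+")
}

#' Remove overall translation and rotation from a trajectory
#'
#' Least-squares rigid-body fits every frame to a common reference. With
#' `ref = "mean"` the reference is the ensemble mean structure, iterating
#' fit and mean recomputation until the mean moves by less than `tol`
#' Angstrom; with `ref = "first_frame"` a single pass against frame 1.
#'
#' @param traj A [kin_trajectory()].
#' @param ref `"mean"` (default) or `"first_frame"`.
#' @param tol Convergence tolerance on the mean structure (Angstrom).
#' @param max_iter Iteration cap for the mean-reference fit.
#' @return The superposed [kin_trajectory()].
#' @export
superpose_trajectory <- function(traj, ref = c("mean", "first_frame"),
                                 tol = 1e-6, max_iter = 50) {
  ref <- match.arg(ref)
  co <- traj$coords
  nf <- dim(co)[1]
  fit_all <- function(co, reference) {
    for (f in seq_len(nf)) {
      co[f, , ] <- kabsch_superpose(co[f, , ], reference)
    }
    co
  }
  if (ref == "first_frame") {
    co <- fit_all(co, co[1, , ])
  } else {
    reference <- co[1, , ]
    for (it in seq_len(max_iter)) {
      co <- fit_all(co, reference)
      new_ref <- apply(co, c(2, 3), mean)
      shift <- max(abs(new_ref - reference))
      reference <- new_ref
      if (shift < tol) break
    }
  }
  kin_trajectory(co, residue_ids = traj$residue_ids)
}

#' Essential dynamics of a superposed trajectory
#'
#' Computes the positional covariance matrix
#' `C_ij = <(r_i - <r_i>) . (r_j - <r_j>)>` over frames (ensemble-average
#' divisor `n_frames`), its normalisation to the residue-residue correlation
#' matrix in `[-1, 1]`, and the full symmetric eigendecomposition whose
#' eigenvectors are the collective motion modes and whose eigenvalues their
#' squared amplitudes.
#'
#' @param traj A superposed [kin_trajectory()] (see
#'   [superpose_trajectory()]; overall rotation/translation must already be
#'   removed for the covariance to be meaningful).
#' @return An object of class `essential_dynamics`: `mean_structure`
#'   (`n x 3`), `covariance` (`3n x 3n`), `correlation` (`n x n`),
#'   `eigenvalues` (descending), `eigenvectors` (columns, orthonormal),
#'   `residue_ids`, `n_frames`.
#' @export
essential_dynamics <- function(traj) {
  co <- traj$coords
  nf <- dim(co)[1]
  n <- dim(co)[2]
  if (nf < 2) abort("covariance needs at least 2 frames")
  # frame matrix with per-residue (x, y, z) triplets as adjacent columns
  x <- matrix(aperm(co, c(1, 3, 2)), nrow = nf)
  mu <- colMeans(x)
  xc <- sweep(x, 2, mu)
  covm <- crossprod(xc) / nf
  ax <- function(a) seq(a, 3 * n, by = 3)
  dots <- covm[ax(1), ax(1)] + covm[ax(2), ax(2)] + covm[ax(3), ax(3)]
  vars <- diag(dots)
  denom <- sqrt(outer(vars, vars))
  corr <- matrix(0, n, n)
  pos <- denom > 0
  corr[pos] <- dots[pos] / denom[pos]
  if (any(vars == 0)) {
    warn(paste0(sum(vars == 0), " residue(s) with zero variance; their ",
                "correlations are reported as 0"))
  }
  diag(corr) <- 1
  es <- eigen(covm, symmetric = TRUE)
  structure(
    list(
      mean_structure = matrix(mu, n, 3, byrow = TRUE),
      covariance = covm,
      correlation = corr,
      eigenvalues = es$values,
      eigenvectors = es$vectors,
      residue_ids = traj$residue_ids,
      n_frames = nf
    ),
    class = "essential_dynamics"
  )
}

#' @export
print.essential_dynamics <- function(x, ...) {
  cat("<essential_dynamics> ", length(x$residue_ids), " residues, ",
      x$n_frames, " frames\n", sep = "")
  top <- head(x$eigenvalues, 3)
  cat("  top eigenvalues (A^2): ", paste(signif(top, 4), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' @export
tidy.essential_dynamics <- function(x, ...) {
  tibble(
    mode = seq_along(x$eigenvalues),
    eigenvalue = x$eigenvalues,
    variance_fraction = x$eigenvalues / sum(x$eigenvalues)
  )
}

#' Per-residue mobility from the top collective modes
#'
#' Mobility of residue i is the eigenvalue-weighted squared amplitude of its
#' components in the `k` largest-amplitude (lowest-frequency, in the
#' quasi-harmonic sense) modes, min-max normalised to `[0, 1]` per
#' structure. The absolute per-residue RMSF (Angstrom) is carried alongside
#' for cross-structure work.
#'
#' @param ed An [essential_dynamics()] object.
#' @param k Number of top modes to average over (default 2).
#' @param weighted If `FALSE`, drop the eigenvalue weighting and use raw
#'   squared eigenvector amplitudes.
#' @return A tibble of class `mobility_profile` with columns `residue_id`,
#'   `raw` (A^2), `mobility` (normalised), `rmsf` (A).
#' @export
residue_mobility <- function(ed, k = 2, weighted = TRUE) {
  n <- length(ed$residue_ids)
  if (k < 1 || k > length(ed$eigenvalues)) {
    abort(paste0("k must lie in 1..", length(ed$eigenvalues)))
  }
  ridx <- rep(seq_len(n), each = 3)
  raw <- rep(0, n)
  for (m in seq_len(k)) {
    amp2 <- rowsum(ed$eigenvectors[, m]^2, ridx)[, 1]
    raw <- raw + (if (weighted) ed$eigenvalues[m] else 1) * amp2
  }
  vars <- rowsum(diag(ed$covariance), ridx)[, 1]
  rng <- max(raw) - min(raw)
  degenerate <- rng < 1e-12
  mobility <- if (degenerate) rep(0, n) else (raw - min(raw)) / rng
  out <- tibble(
    residue_id = ed$residue_ids,
    raw = raw,
    mobility = mobility,
    rmsf = sqrt(vars)
  )
  structure(out, class = c("mobility_profile", class(out)),
            k = k, weighted = weighted, degenerate = degenerate)
}

#' Classify residues as rigid, intermediate or flexible, and find hinges
#'
#' Labels residues by mobility quantiles: `rigid` at or below the `q_low`
#' quantile, `flexible` at or above the `q_high` quantile, `intermediate`
#' between. Hinge residues - sites at the border between regions of high
#' and low structural stability - are residues within `window` sequence
#' positions of both a rigid and a flexible residue. A degenerate flat
#' profile yields all-intermediate labels and no hinges.
#'
#' @param profile A [residue_mobility()] profile.
#' @param q_low,q_high Quantile thresholds (defaults 0.25 / 0.75).
#' @param window Hinge neighbourhood half-width in sequence positions
#'   (default 2).
#' @return The profile with `label` and `hinge` columns appended.
#' @export
classify_mobility <- function(profile, q_low = 0.25, q_high = 0.75,
                              window = 2) {
  if (q_low >= q_high) abort("q_low must be smaller than q_high")
  mob <- profile$mobility
  n <- length(mob)
  if (isTRUE(attr(profile, "degenerate")) || max(mob) - min(mob) < 1e-12) {
    profile$label <- rep("intermediate", n)
    profile$hinge <- rep(FALSE, n)
    return(profile)
  }
  thr <- quantile(mob, c(q_low, q_high), names = FALSE)
  label <- case_when(
    mob <= thr[1] ~ "rigid",
    mob >= thr[2] ~ "flexible",
    .default = "intermediate"
  )
  idx <- seq_len(n)
  rigid_idx <- idx[label == "rigid"]
  flex_idx <- idx[label == "flexible"]
  near <- function(i, set, w) {
    length(set) > 0 && min(abs(set - i)) <= w
  }
  hinge <- vapply(idx, function(i) {
    near(i, rigid_idx, window) && near(i, flex_idx, window)
  }, logical(1))
  profile$label <- label
  profile$hinge <- hinge
  profile
}

#' Mobility of mutation sites
#'
#' Joins mutation records onto a mobility profile by residue number,
#' attaching each site's mobility value and rigidity label. Positions
#' outside the profiled range are labelled `"unmapped"` (and also returned
#' via the `unmapped` attribute).
#'
#' @param mutations Mutation tibble (column `position`).
#' @param profile A classified [residue_mobility()] profile (run
#'   [classify_mobility()] first; an unclassified profile yields values
#'   only).
#' @return `mutations` with `mobility`, `rmsf` and `label` appended.
#' @export
mutation_site_mobility <- function(mutations, profile) {
  if (nrow(profile) == 0) abort("empty mobility profile")
  idx <- match(mutations$position, profile$residue_id)
  out <- mutations |>
    mutate(
      mobility = profile$mobility[idx],
      rmsf = profile$rmsf[idx],
      label = if ("label" %in% names(profile)) {
        ifelse(is.na(idx), "unmapped", profile$label[idx])
      } else {
        ifelse(is.na(idx), "unmapped", NA_character_)
      }
    )
  attr(out, "unmapped") <- out[is.na(idx), , drop = FALSE]
  out
}

#' Permutation contrast of activating vs inactivating site mobility
#'
#' Operationalises the qualitative observation that activating mutations
#' favour flexible or border sites while kinase-inactivating mutations
#' favour rigid sites: the statistic is the difference in mean normalised
#' mobility (activating minus inactivating), and its two-sided P value is
#' estimated by permuting the activating/inactivating labels over the
#' pooled sites (`(1 + #{|D*| >= |D|}) / (n_perm + 1)`).
#'
#' @param profile A [residue_mobility()] profile.
#' @param activating_sites,inactivating_sites Disjoint, nonempty integer
#'   vectors of residue numbers within the profiled range.
#' @param n_perm Number of label permutations (default 999).
#' @param seed Integer seed, or `NULL`.
#' @return An object of class `rigidity_contrast` with elements `delta`
#'   (mean mobility difference), `p_value`, `n_perm`, `n_activating`,
#'   `n_inactivating`, `mean_activating`, `mean_inactivating`.
#' @export
rigidity_contrast <- function(profile, activating_sites, inactivating_sites,
                              n_perm = 999, seed = NULL) {
  if (length(activating_sites) == 0 || length(inactivating_sites) == 0) {
    abort("both site sets must be nonempty")
  }
  if (length(intersect(activating_sites, inactivating_sites)) > 0) {
    abort("activating and inactivating site sets overlap")
  }
  ia <- match(activating_sites, profile$residue_id)
  ii <- match(inactivating_sites, profile$residue_id)
  if (anyNA(ia) || anyNA(ii)) {
    miss <- c(activating_sites[is.na(ia)], inactivating_sites[is.na(ii)])
    abort(paste0("site(s) outside the profiled range: ",
                 paste(head(miss, 5), collapse = ", ")))
  }
  ma <- profile$mobility[ia]
  mi <- profile$mobility[ii]
  delta <- mean(ma) - mean(mi)
  vals <- c(ma, mi)
  na <- length(ma)
  ntot <- length(vals)
  tot <- sum(vals)
  perm_delta <- with_seed_if(seed, {
    idx <- replicate(n_perm, sample.int(ntot, na))
    suma <- colSums(matrix(vals[idx], nrow = na))
    suma / na - (tot - suma) / (ntot - na)
  })
  p <- (1 + sum(abs(perm_delta) >= abs(delta) - 1e-12)) / (n_perm + 1)
  structure(
    list(delta = delta, p_value = p, n_perm = as.integer(n_perm),
         n_activating = na, n_inactivating = ntot - na,
         mean_activating = mean(ma), mean_inactivating = mean(mi)),
    class = "rigidity_contrast"
  )
}

#' @export
print.rigidity_contrast <- function(x, ...) {
  cat("<rigidity_contrast> mean mobility (activating - inactivating) = ",
      signif(x$delta, 4), ", permutation p = ", signif(x$p_value, 4),
      " (", x$n_perm, " permutations)\n", sep = "")
  invisible(x)
}

#' @export
tidy.rigidity_contrast <- function(x, ...) {
  tibble(
    statistic = x$delta,
    p_value = x$p_value,
    mean_activating = x$mean_activating,
    mean_inactivating = x$mean_inactivating,
    n_activating = x$n_activating,
    n_inactivating = x$n_inactivating,
    n_perm = x$n_perm
  )
}

#' @export
glance.rigidity_contrast <- function(x, ...) tidy(x)

#' Plot a per-residue mobility profile
#'
#' Mobility along the sequence, coloured by rigidity label when present,
#' with hinge residues marked.
#'
#' @param object A [residue_mobility()] (optionally classified) profile.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mobility_profile <- function(object, ...) {
  df <- as_tibble(object)
  p <- ggplot(df, aes(x = .data$residue_id, y = .data$mobility)) +
    geom_line(colour = "grey60")
  if ("label" %in% names(df)) {
    p <- p + geom_point(aes(colour = .data$label)) +
      scale_colour_manual(values = c(rigid = "#2980b9",
                                     intermediate = "#27ae60",
                                     flexible = "#c0392b"))
  } else {
    p <- p + geom_point()
  }
  if ("hinge" %in% names(df) && any(df$hinge)) {
    p <- p + geom_point(data = df[df$hinge, ], shape = 1, size = 3,
                        colour = "black")
  }
  p + labs(x = "residue", y = "normalised mobility", colour = NULL) +
    theme_minimal()
}
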