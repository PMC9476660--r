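#' Optimal rigid-body superposition (Kabsch)
#'
#' Least-squares superposition of `mobile` onto `reference` using the SVD
#' construction with the proper-rotation (det = +1) correction.
#'
#' @param mobile,reference n x 3 coordinate matrices, n >= 3
#' @return list with `rotation` (3 x 3), `translation` (length 3) and
#'   `aligned` coordinates; `aligned = mobile %*% rotation + translation`
#' @export
kabsch_align <- function(mobile, reference) {
  stopifnot(nrow(mobile) == nrow(reference), ncol(mobile) == 3)
  if (nrow(mobile) < 3) stop("need at least 3 points")
  cm <- colMeans(mobile); cr <- colMeans(reference)
  A <- sweep(mobile, 2, cm); B <- sweep(reference, 2, cr)
  if (qr(A)$rank < 2) stop("degenerate (collinear) point set")
  H <- t(A) %*% B
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$u %*% D %*% t(sv$v)
  trans <- cr - as.numeric(cm %*% R)
  list(rotation = R, translation = trans,
       aligned = sweep(mobile %*% R, 2, trans, "+"))
}

#' Root-mean-square deviation after superposition
#'
#' RMSD = sqrt(mean(d_i^2)) over the selected beads, after rigid
#' superposition of the frame onto the reference on that same selection
#' (by default the backbone beads).
#'
#' @param frame,reference n x 3 coordinate matrices
#' @param selection indices of the beads used for alignment and the
#'   deviation (default all rows)
#' @param align superpose before measuring (default `TRUE`)
#' @return RMSD in A
#' @export
rmsd <- function(frame, reference, selection = NULL, align = TRUE) {
  if (is.null(selection)) selection <- seq_len(nrow(frame))
  if (length(selection) == 0) stop("empty selection")
  a <- frame[selection, , drop = FALSE]
  b <- reference[selection, , drop = FALSE]
  if (align && nrow(a) >= 3) a <- kabsch_align(a, b)$aligned
  sqrt(mean(rowSums((a - b)^2)))
}

#' Radius of gyration
#'
#' Mass-weighted radius of gyration about the centre of mass.
#'
#' @param frame n x 3 coordinates
#' @param masses bead masses (default: equal)
#' @param selection optional row subset
#' @return Rgyr in A
#' @export
radius_of_gyration <- function(frame, masses = NULL, selection = NULL) {
  if (!is.null(selection)) {
    frame <- frame[selection, , drop = FALSE]
    if (!is.null(masses)) masses <- masses[selection]
  }
  n <- nrow(frame)
  if (n == 0) stop("no beads selected")
  if (is.null(masses)) masses <- rep(1, n)
  com <- colSums(frame * masses) / sum(masses)
  d2 <- rowSums(sweep(frame, 2, com)^2)
  sqrt(sum(masses * d2) / sum(masses))
}

#' Signed dihedral angle over four points
#' @param p 4 x 3 matrix
#' @return angle in degrees in (-180, 180]; `NA` for collinear geometry
#' @export
dihedral_angle <- function(p) {
  b1 <- p[2, ] - p[1, ]; b2 <- p[3, ] - p[2, ]; b3 <- p[4, ] - p[3, ]
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2], b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2], b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  if (sum(n1^2) < 1e-12 || sum(n2^2) < 1e-12) return(NA_real_)
  cx <- c(n1[2] * n2[3] - n1[3] * n2[2], n1[3] * n2[1] - n1[1] * n2[3],
          n1[1] * n2[2] - n1[2] * n2[1])
  s <- sum(cx * b2) / sqrt(sum(b2^2))
  atan2(s, sum(n1 * n2)) * 180 / pi
}

#' Secondary-structure geometry windows
#'
#' Enumerates the windows used by the 1-4 metrics: distance windows are
#' residue pairs (n, n+4) whose five residues share one secondary-structure
#' label and an unbroken backbone; dihedral windows are four consecutive
#' backbone beads with a uniform label.  Only helical (H) and extended (E)
#' labels generate windows.
#'
#' @param cg a `cg_structure`
#' @return list with data.frames `dist` (`i`, `j` backbone bead indices,
#'   `ss`) and `dih` (`i1..i4`, `ss`)
#' @export
ss_windows <- function(cg) {
  bb <- backbone_indices(cg)
  beads <- cg$beads
  ss <- cg$ss[paste(beads$chain[bb], beads$resid[bb])]
  chain <- beads$chain[bb]
  dist <- list(); dih <- list()
  nb <- length(bb)
  for (t in seq_len(max(nb - 4, 0))) {
    idx <- t:(t + 4)
    if (length(unique(chain[idx])) != 1) next
    lab <- unique(ss[idx])
    if (length(lab) == 1 && lab %in% c("H", "E"))
      dist[[length(dist) + 1]] <- data.frame(i = bb[t], j = bb[t + 4],
                                             ss = lab)
  }
  for (t in seq_len(max(nb - 3, 0))) {
    idx <- t:(t + 3)
    if (length(unique(chain[idx])) != 1) next
    lab <- unique(ss[idx])
    if (length(lab) == 1 && lab %in% c("H", "E"))
      dih[[length(dih) + 1]] <- data.frame(i1 = bb[t], i2 = bb[t + 1],
                                           i3 = bb[t + 2], i4 = bb[t + 3],
                                           ss = lab)
  }
  list(dist = if (length(dist)) do.call(rbind, dist) else
         data.frame(i = integer(), j = integer(), ss = character()),
       dih = if (length(dih)) do.call(rbind, dih) else
         data.frame(i1 = integer(), i2 = integer(), i3 = integer(),
                    i4 = integer(), ss = character()))
}

#' 1-4 backbone geometry
#'
#' `one_four_distance`: Euclidean distance between the backbone beads of
#' residues n and n+4 (one helix turn).  `one_four_dihedral`: signed
#' dihedral over the backbone beads of residues n..n+3.
#'
#' @param cg a `cg_structure`
#' @param frame n x 3 coordinates (default: the structure's own)
#' @param n 1-based residue position (in backbone order)
#' @return A (distance) or degrees (dihedral); dihedral is `NA` for
#'   collinear geometry
#' @export
one_four_distance <- function(cg, n, frame = NULL) {
  bb <- backbone_indices(cg)
  if (n + 4 > length(bb)) stop("window ", n, "..", n + 4, " out of range")
  if (is.null(frame)) frame <- cg_xyz(cg)
  sqrt(sum((frame[bb[n], ] - frame[bb[n + 4], ])^2))
}

#' @rdname one_four_distance
#' @export
one_four_dihedral <- function(cg, n, frame = NULL) {
  bb <- backbone_indices(cg)
  if (n + 3 > length(bb)) stop("window ", n, "..", n + 3, " out of range")
  if (is.null(frame)) frame <- cg_xyz(cg)
  dihedral_angle(frame[bb[n:(n + 3)], ])
}

#' Fitness configuration
#'
#' Weights and all-atom reference geometry constants of the structural
#' fitness score: w_RMSD = 1.0 A^-1, w_gyr = 3.0, w_dih = 2.0,
#' w_dist = 2.0; mean 1-4 dihedral 58.8 deg (helix) and 172 deg (sheet);
#' mean 1-4 distance 5.8 A (helix) and 10.3 A (sheet).  The gyration
#' reference r_gyr0 is taken from the reference structure at evaluation
#' time unless supplied.
#'
#' @param w_rmsd,w_gyr,w_dih,w_dist term weights
#' @param theta_helix,theta_beta reference 1-4 dihedral magnitudes, degrees
#' @param d_helix,d_beta reference 1-4 distances, A
#' @param r_gyr0 optional fixed gyration reference, A
#' @return a `fitness_config` list
#' @export
fitness_config <- function(w_rmsd = 1.0, w_gyr = 3.0, w_dih = 2.0,
                           w_dist = 2.0, theta_helix = 58.8,
                           theta_beta = 172, d_helix = 5.8, d_beta = 10.3,
                           r_gyr0 = NULL) {
  stopifnot(w_rmsd >= 0, w_gyr >= 0, w_dih >= 0, w_dist >= 0)
  structure(list(w_rmsd = w_rmsd, w_gyr = w_gyr, w_dih = w_dih,
                 w_dist = w_dist, theta_helix = theta_helix,
                 theta_beta = theta_beta, d_helix = d_helix,
                 d_beta = d_beta, r_gyr0 = r_gyr0),
            class = "fitness_config")
}

#' Structural fitness of a trajectory against its reference
#'
#' The per-protein fitness is F = 1 / (1 + S) with
#' S = w_RMSD <RMSD> + w_gyr <|Rgyr - r0|>/r0
#'   + w_dih sum_ss <|{|phi|} - theta_ss|>/theta_ss
#'   + w_dist sum_ss <|d - d_ss|>/d_ss,
#' where angle brackets average over saved frames (and windows), the ss sum
#' runs over the helix and sheet classes present in the annotation, RMSD is
#' measured on backbone beads after frame-wise superposition, and dihedrals
#' are compared as folded magnitudes.  F = 1 exactly when every deviation
#' vanishes and decreases strictly as any deviation grows.  Structures
#' without helix or sheet windows contribute no deviation for the missing
#' class.
#'
#' @param traj a `cg_trajectory`
#' @param reference a `cg_structure` (defines topology, SS labels, the
#'   reference frame and r_gyr0)
#' @param config a `fitness_config`
#' @return list with `fitness` and the component deviations
#' @export
protein_fitness <- function(traj, reference, config = fitness_config()) {
  ref_xyz <- cg_xyz(reference)
  bb <- backbone_indices(reference)
  masses <- reference$beads$mass
  win <- ss_windows(reference)
  r0 <- if (is.null(config$r_gyr0))
    radius_of_gyration(ref_xyz, masses) else config$r_gyr0
  nf <- n_frames(traj)
  rmsd_t <- numeric(nf); gyr_t <- numeric(nf)
  dih_dev <- c(H = 0, E = 0); dih_n <- c(H = 0, E = 0)
  dist_dev <- c(H = 0, E = 0); dist_n <- c(H = 0, E = 0)
  theta_ref <- c(H = config$theta_helix, E = config$theta_beta)
  d_ref <- c(H = config$d_helix, E = config$d_beta)
  for (f in seq_len(nf)) {
    x <- traj$coords[f, , , drop = TRUE]
    if (traj$n_beads == 1) x <- matrix(x, 1, 3)
    rmsd_t[f] <- rmsd(x, ref_xyz, selection = bb)
    gyr_t[f] <- radius_of_gyration(x, masses)
    if (nrow(win$dih)) {
      for (r in seq_len(nrow(win$dih))) {
        idx <- as.integer(win$dih[r, 1:4])
        phi <- dihedral_angle(x[idx, ])
        if (is.na(phi)) next
        lab <- win$dih$ss[r]
        dih_dev[lab] <- dih_dev[lab] + abs(abs(phi) - theta_ref[lab])
        dih_n[lab] <- dih_n[lab] + 1
      }
    }
    if (nrow(win$dist)) {
      for (r in seq_len(nrow(win$dist))) {
        d <- sqrt(sum((x[win$dist$i[r], ] - x[win$dist$j[r], ])^2))
        lab <- win$dist$ss[r]
        dist_dev[lab] <- dist_dev[lab] + abs(d - d_ref[lab])
        dist_n[lab] <- dist_n[lab] + 1
      }
    }
  }
  mean_or0 <- function(dev, n) ifelse(n > 0, dev / n, 0)
  dd <- mean_or0(dih_dev, dih_n) / theta_ref
  ds <- mean_or0(dist_dev, dist_n) / d_ref
  S <- config$w_rmsd * mean(rmsd_t) +
    config$w_gyr * mean(abs(gyr_t - r0)) / r0 +
    config$w_dih * sum(dd) + config$w_dist * sum(ds)
  list(fitness = 1 / (1 + S),
       rmsd = mean(rmsd_t), rgyr = mean(gyr_t), r_gyr0 = r0,
       dih_dev = dd, dist_dev = ds, S = S)
}

#' Geometric-mean aggregation of per-protein fitness values
#'
#' The training-set fitness is the geometric mean of the individual
#' protein fitness values, so a single collapsing protein (fitness 0)
#' annihilates the aggregate instead of being averaged away.
#'
#' @param values non-negative per-protein fitness values
#' @return geometric mean
#' @export
aggregate_fitness <- function(values) {
  if (length(values) == 0) stop("no fitness values")
  if (any(values < 0)) stop("negative fitness value")
  if (any(values == 0)) return(0)
  exp(mean(log(values)))
}

#' Trajectory observables report
#'
#' RMSD and radius-of-gyration time series plus pooled 1-4
#' distance/dihedral histograms split by secondary-structure class, with
#' the fitness reference constants attached.  Histogram densities sum to 1.
#'
#' @param traj a `cg_trajectory`
#' @param reference a `cg_structure`
#' @param config a `fitness_config` (for the reference markers)
#' @param breaks histogram bin count
#' @return a `trajectory_report` list
#' @export
trajectory_report <- function(traj, reference, config = fitness_config(),
                              breaks = 36) {
  ref_xyz <- cg_xyz(reference)
  bb <- backbone_indices(reference)
  masses <- reference$beads$mass
  win <- ss_windows(reference)
  nf <- n_frames(traj)
  rmsd_t <- numeric(nf); gyr_t <- numeric(nf)
  samples <- list(dist_H = numeric(), dist_E = numeric(),
                  dih_H = numeric(), dih_E = numeric())
  for (f in seq_len(nf)) {
    x <- traj$coords[f, , , drop = TRUE]
    if (traj$n_beads == 1) x <- matrix(x, 1, 3)
    rmsd_t[f] <- rmsd(x, ref_xyz, selection = bb)
    gyr_t[f] <- radius_of_gyration(x, masses)
    for (r in seq_len(nrow(win$dist))) {
      d <- sqrt(sum((x[win$dist$i[r], ] - x[win$dist$j[r], ]) ^ 2))
      key <- paste0("dist_", win$dist$ss[r])
      samples[[key]] <- c(samples[[key]], d)
    }
    for (r in seq_len(nrow(win$dih))) {
      phi <- dihedral_angle(x[as.integer(win$dih[r, 1:4]), ])
      if (is.na(phi)) next
      key <- paste0("dih_", win$dih$ss[r])
      samples[[key]] <- c(samples[[key]], abs(phi))
    }
  }
  mk_hist <- function(v, breaks) {
    if (length(v) == 0) return(NULL)
    h <- hist(v, breaks = breaks, plot = FALSE)
    list(mids = h$mids, prob = h$counts / sum(h$counts))
  }
  structure(list(
    times = traj$times, rmsd = rmsd_t, rgyr = gyr_t,
    hist = lapply(samples, mk_hist, breaks = breaks),
    reference = list(d_helix = config$d_helix, d_beta = config$d_beta,
                     theta_helix = config$theta_helix,
                     theta_beta = config$theta_beta)),
    class = "trajectory_report")
}

#' @export
print.trajectory_report <- function(x, ...) {
  cat("Trajectory report:", length(x$times), "frames\n")
  cat(sprintf("  RMSD  %.2f +- %.2f A (final %.2f)\n", mean(x$rmsd),
              sd(x$rmsd), tail(x$rmsd, 1)))
  cat(sprintf("  Rgyr  %.2f +- %.2f A\n", mean(x$rgyr), sd(x$rgyr)))
  invisible(x)
}

#' @importFrom graphics hist
NULL
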