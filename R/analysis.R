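# Trajectory analysis: optimal superposition (Kabsch), RMSD/RMSF, the
# velocity autocorrelation function used to characterise solvent dynamics,
# and an O-O radial distribution function normalised over the wall-bounded
# region by Monte Carlo volume integration.

#' Optimal superposition (Kabsch algorithm)
#'
#' Least-squares rigid-body superposition of one coordinate set onto
#' another via singular value decomposition, with the proper-rotation
#' (determinant +1) correction.
#'
#' @param x,ref `n x 3` coordinate matrices to align (x onto ref).
#' @param weights optional per-atom weights (e.g. masses).
#' @return list with `rotation` (3x3), `translation` (length 3), `xfit`
#'   (the transformed `x`) and `rmsd` (the post-fit weighted RMSD, nm).
#' @export
kabsch <- function(x, ref, weights = NULL) {
  stopifnot(nrow(x) == nrow(ref), ncol(x) == 3, ncol(ref) == 3)
  w <- if (is.null(weights)) rep(1, nrow(x)) else weights
  w <- w / sum(w)
  cx <- colSums(x * w)
  cr <- colSums(ref * w)
  xc <- sweep(x, 2, cx)
  rc <- sweep(ref, 2, cr)
  h <- t(xc * w) %*% rc
  sv <- svd(h)
  d <- sign(det(sv$v %*% t(sv$u)))
  rot <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  xfit <- sweep(xc %*% t(rot), 2, cr, `+`)
  dev <- xfit - ref
  list(rotation = rot, translation = cr - as.numeric(rot %*% cx),
       xfit = xfit, rmsd = sqrt(sum(w * rowSums(dev^2))))
}

#' Root-mean-square deviation per frame
#'
#' RMSD of each trajectory frame from a reference after optimal
#' superposition on the selected atoms.
#'
#' @param trajectory an `mmcg_trajectory`.
#' @param selection atom selection (see [select_atoms()]) used both for
#'   fitting and for the deviation; defaults to C-alpha atoms, falling back
#'   to all atoms when there are none.
#' @param reference reference coordinates (`n x 3`, nm); defaults to the
#'   first frame.
#' @param fit superpose before measuring (default TRUE).
#' @return data frame with columns `time` (ps) and `rmsd` (nm).
#' @export
rmsd <- function(trajectory, selection = "calpha", reference = NULL,
                 fit = TRUE) {
  idx <- select_atoms(trajectory$structure, selection)
  if (length(idx) == 0) idx <- seq_len(nrow(trajectory$structure$atoms))
  ref <- if (is.null(reference)) trajectory$frames[idx, , 1]
         else reference[idx, , drop = FALSE]
  nf <- n_frames(trajectory)
  val <- vapply(seq_len(nf), function(k) {
    x <- trajectory$frames[idx, , k]
    if (fit) kabsch(x, ref)$rmsd
    else sqrt(mean(rowSums((x - ref)^2)))
  }, numeric(1))
  data.frame(time = trajectory$times, rmsd = val)
}

#' Root-mean-square fluctuation per residue
#'
#' Atomic positional fluctuations about the trajectory mean, after
#' optionally superposing every frame on the mean structure (iterated once
#' from the first frame), aggregated per residue as the RMS over the
#' selected atoms.
#'
#' @param trajectory an `mmcg_trajectory`.
#' @param selection atom selection; per-residue values are computed over
#'   these atoms (default C-alpha, giving one atom per residue).
#' @param fit superpose frames before measuring (default TRUE).
#' @return data frame with columns `chain`, `resid` and `rmsf` (nm).
#' @export
rmsf <- function(trajectory, selection = "calpha", fit = TRUE) {
  st <- trajectory$structure
  idx <- select_atoms(st, selection)
  if (length(idx) == 0) stop("empty selection")
  nf <- n_frames(trajectory)
  xs <- lapply(seq_len(nf), function(k) trajectory$frames[idx, , k])
  if (fit && length(idx) >= 3) {
    ref <- xs[[1]]
    xs <- lapply(xs, function(x) kabsch(x, ref)$xfit)
    mu <- Reduce(`+`, xs) / nf
    xs <- lapply(xs, function(x) kabsch(x, mu)$xfit)
  }
  mu <- Reduce(`+`, xs) / nf
  msf <- Reduce(`+`, lapply(xs, function(x) rowSums((x - mu)^2))) / nf
  a <- st$atoms[idx, ]
  key <- paste(a$chain, a$resid)
  agg <- tapply(msf, key, mean)
  ord <- unique(key)
  data.frame(
    chain = a$chain[match(ord, key)],
    resid = a$resid[match(ord, key)],
    rmsf = sqrt(as.numeric(agg[ord])))
}

#' Velocity autocorrelation function
#'
#' Normalised VACF `C(t) = <v(t0) . v(t0+t)> / <v(t0) . v(t0)>` averaged
#' over atoms and all available time origins. `C(0) = 1` by construction.
#'
#' @param trajectory an `mmcg_trajectory` carrying stored velocities
#'   (`vel_stride > 0` in the run configuration), or an `n x 3 x nv`
#'   velocity array.
#' @param times sampling times (ps); taken from the trajectory if omitted.
#'   Must be uniformly spaced.
#' @param selection atom selection (trajectory input only); default water
#'   oxygens, falling back to all atoms.
#' @param max_lag maximum lag time (ps); default half the trace.
#' @return data frame with columns `t` (ps) and `vacf`, plus attribute
#'   `decorrelation_time`: the first lag at which `|C(t)| < threshold`
#'   (linearly interpolated), with `threshold` 0.05.
#' @param threshold decorrelation threshold on `|C|`.
#' @export
vacf <- function(trajectory, times = NULL, selection = "water_oxygen",
                 max_lag = NULL, threshold = 0.05) {
  if (inherits(trajectory, "mmcg_trajectory")) {
    if (is.null(trajectory$velocities))
      stop("trajectory has no stored velocities; rerun with vel_stride > 0")
    idx <- select_atoms(trajectory$structure, selection)
    if (length(idx) == 0) idx <- seq_len(dim(trajectory$velocities)[1])
    v <- trajectory$velocities[idx, , , drop = FALSE]
    times <- times %||% trajectory$vtimes
  } else {
    v <- trajectory
    if (is.null(times)) stop("`times` required for array input")
  }
  nv <- dim(v)[3]
  if (nv < 2) stop("need at least two velocity frames")
  dt <- diff(times)
  if (max(abs(dt - dt[1])) > 1e-9 * max(abs(dt)))
    stop("velocity frames are not uniformly spaced")
  dt <- dt[1]
  nlag <- if (is.null(max_lag)) nv %/% 2 else min(nv - 1, round(max_lag / dt))
  # flatten atoms x components into one ensemble; average over time origins
  vm <- matrix(v, nrow = dim(v)[1] * 3, ncol = nv)
  c0 <- mean(colMeans(vm^2))
  cc <- vapply(0:nlag, function(l) {
    o <- seq_len(nv - l)
    mean(vm[, o, drop = FALSE] * vm[, o + l, drop = FALSE])
  }, numeric(1)) / c0
  out <- data.frame(t = (0:nlag) * dt, vacf = cc)
  # first crossing of |C| below threshold, linearly interpolated
  dec <- NA_real_
  below <- which(abs(cc) < threshold)
  if (length(below) > 0) {
    k <- below[1]
    if (k == 1) dec <- 0
    else {
      a0 <- abs(cc[k - 1]); a1 <- abs(cc[k])
      f <- (a0 - threshold) / (a0 - a1)
      dec <- ((k - 2) + f) * dt
    }
  }
  attr(out, "decorrelation_time") <- dec
  out
}

#' Monte Carlo volume of the wall-bounded region
#'
#' Estimates the volume where all applicable boundary level sets are
#' non-negative, by uniform sampling of the wall set's bounding box.
#'
#' @param wallset an `mmcg_wallset`.
#' @param n_samples number of sample points.
#' @param seed RNG seed.
#' @return volume estimate (nm^3), with attribute `se` (standard error).
#' @export
mc_region_volume <- function(wallset, n_samples = 2e5, seed = 1L) {
  set.seed(seed)
  r <- max(wallset$r3, wallset$r4)
  cx <- (wallset$chi3[1:2] + wallset$chi4[1:2]) / 2
  lo <- c(cx[1] - r, cx[2] - r, wallset$z_lo - r)
  hi <- c(cx[1] + r, cx[2] + r, wallset$z_hi + r)
  pts <- cbind(stats::runif(n_samples, lo[1], hi[1]),
               stats::runif(n_samples, lo[2], hi[2]),
               stats::runif(n_samples, lo[3], hi[3]))
  inside <- wall_distance(pts, wallset)$d >= 0
  vbox <- prod(hi - lo)
  p <- mean(inside)
  structure(p * vbox, se = vbox * sqrt(p * (1 - p) / n_samples))
}

#' Water oxygen-oxygen radial distribution function
#'
#' Shell-count RDF for water oxygens with the ideal-gas normalisation
#' `rho * 4 pi r^2 dr`, where the number density `rho` uses the accessible
#' volume (from [mc_region_volume()] when a wall set is supplied, else a
#' supplied volume).
#'
#' @param trajectory an `mmcg_trajectory`.
#' @param wallset the run's `mmcg_wallset` (for the accessible volume), or
#'   NULL with `volume` given explicitly (nm^3).
#' @param r_max maximum distance (nm).
#' @param dr bin width (nm).
#' @param volume accessible volume override (nm^3).
#' @param frames frame indices to average over (default all).
#' @return data frame with columns `r` (bin centres, nm) and `g`. The first
#'   maximum and minimum beyond it are reported as attributes `r_peak` and
#'   `r_min`.
#' @export
rdf_oo <- function(trajectory, wallset = NULL, r_max = 1.0, dr = 0.02,
                   volume = NULL, frames = NULL) {
  idx <- select_atoms(trajectory$structure, "water_oxygen")
  if (length(idx) < 2) stop("need at least two water oxygens")
  if (is.null(volume)) {
    if (is.null(wallset)) stop("supply `wallset` or `volume`")
    volume <- as.numeric(mc_region_volume(wallset))
  }
  frames <- frames %||% seq_len(n_frames(trajectory))
  n <- length(idx)
  rho <- n / volume
  edges <- seq(0, r_max, by = dr)
  counts <- numeric(length(edges) - 1)
  for (k in frames) {
    d <- as.numeric(stats::dist(trajectory$frames[idx, , k]))
    d <- d[d < r_max]
    counts <- counts + tabulate(findInterval(d, edges), nbins = length(counts))
  }
  centre <- edges[-1] - dr / 2
  shell <- 4 * pi * centre^2 * dr
  # counts holds each pair once; per-particle pair density is 2 counts / n
  g <- (2 * counts / (length(frames) * n)) / (rho * shell)
  out <- data.frame(r = centre, g = g)
  pk <- which.max(g)
  attr(out, "r_peak") <- centre[pk]
  if (pk < length(g)) {
    mn <- pk + which.min(g[(pk + 1):length(g)])
    attr(out, "r_min") <- centre[mn]
  }
  out
}

#' Pairwise atom distances along a trajectory
#'
#' @param trajectory an `mmcg_trajectory`.
#' @param pairs two-column matrix or data frame of atom indices, or a list
#'   of two selection strings resolved with [resolve_atom()].
#' @return data frame with `time` plus one column per pair (`d1`, `d2`, ...),
#'   distances in nm.
#' @export
pair_distances <- function(trajectory, pairs) {
  if (is.list(pairs) && !is.data.frame(pairs) && length(pairs) == 2 &&
      is.character(pairs[[1]])) {
    st <- trajectory$structure
    pairs <- cbind(vapply(pairs[[1]], resolve_atom, 0L, structure = st),
                   vapply(pairs[[2]], resolve_atom, 0L, structure = st))
  }
  pm <- as.matrix(pairs)
  nf <- n_frames(trajectory)
  out <- vapply(seq_len(nrow(pm)), function(p) {
    vapply(seq_len(nf), function(k)
      sqrt(sum((trajectory$frames[pm[p, 1], , k] -
                trajectory$frames[pm[p, 2], , k])^2)), numeric(1))
  }, numeric(nf))
  out <- matrix(out, nrow = nf)
  colnames(out) <- paste0("d", seq_len(nrow(pm)))
  cbind(data.frame(time = trajectory$times), as.data.frame(out))
}
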