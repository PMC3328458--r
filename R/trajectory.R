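# Trajectory container and the synthetic coordinate-dynamics generator.

#' Construct a trajectory object
#'
#' @param xyz numeric matrix with one row per frame and 3 columns per atom
#'   (`x1, y1, z1, x2, ...`, Angstrom).
#' @param atoms topology data frame (as in `duplex_model$atoms`).
#' @param dt frame spacing in ps (> 0).
#' @param seed integer seed recorded for provenance, or `NA`.
#' @return an object of class `dyn_trajectory` with fields `xyz`, `atoms`,
#'   `dt`, `time` (ps) and `seed`.
#' @export
dyn_trajectory <- function(xyz, atoms, dt = 2, seed = NA_integer_) {
  xyz <- as.matrix(xyz)
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0)
    stop("dt must be a positive frame spacing in ps")
  if (ncol(xyz) != 3L * nrow(atoms))
    stop("xyz has ", ncol(xyz) / 3, " atoms per frame but the topology has ",
         nrow(atoms))
  structure(list(xyz = xyz, atoms = atoms, dt = dt,
                 time = (seq_len(nrow(xyz)) - 1L) * dt, seed = seed),
            class = "dyn_trajectory")
}

#' @export
print.dyn_trajectory <- function(x, ...) {
  cat(sprintf("Trajectory: %d frames x %d atoms, dt = %g ps (%g ps total)\n",
              nrow(x$xyz), ncol(x$xyz) / 3L, x$dt,
              (nrow(x$xyz) - 1L) * x$dt))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj a `dyn_trajectory`.
#' @return integer frame count.
#' @export
n_frames <- function(traj) nrow(traj$xyz)

#' Synthetic thermal trajectory around a reference structure
#'
#' Emulates the statistical structure that flexibility metrics assume:
#' every atom fluctuates independently about its reference position with
#' isotropic zero-mean Gaussian noise of standard deviation `sigma` per
#' axis, so the expected per-atom mean-square fluctuation is `3 sigma^2`
#' and the expected theoretical B-factor is `8 pi^2 sigma^2`.  No
#' correlated motion, anisotropy or sequence dependence is modelled.
#'
#' @param model a `duplex_model` reference structure.
#' @param n_frames number of frames (>= 1).
#' @param sigma per-axis Gaussian displacement SD in Angstrom (>= 0).
#' @param seed integer seed; fixed seed gives bit-identical trajectories.
#' @param dt frame spacing in ps.
#' @return a `dyn_trajectory`.
#' @examples
#' tr <- perturb_trajectory(build_duplex("GC", "B", 1), 10, 0.1, seed = 1)
#' @export
perturb_trajectory <- function(model, n_frames, sigma = 0.3, seed = 1L,
                               dt = 2) {
  if (!is.numeric(n_frames) || length(n_frames) != 1L || n_frames < 1)
    stop("n_frames must be >= 1")
  if (sigma < 0) stop("sigma must be >= 0")
  n_frames <- as.integer(n_frames)
  ref <- as.vector(t(duplex_xyz(model)))
  set.seed(seed)
  noise <- matrix(stats::rnorm(n_frames * length(ref), sd = sigma),
                  nrow = n_frames)
  xyz <- sweep(noise, 2L, ref, "+")
  dyn_trajectory(xyz, model$atoms, dt = dt, seed = as.integer(seed))
}
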