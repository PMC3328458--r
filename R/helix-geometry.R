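# Base-pair / base-pair-step parameters and flexibility metrics.

#' Reference frame of a base from its ring atoms
#'
#' Least-squares fits (Kabsch) the idealized planar base-ring template of
#' the given base type to the observed ring atoms and returns the implied
#' orthonormal base reference frame.  Strand-2 bases yield a frame whose
#' y and z axes are inverted relative to the pair frame; pairing code
#' flips them back before computing parameters.
#'
#' @param res_xyz matrix of residue coordinates with atom names as row
#'   names (only ring atoms are used).
#' @param base `"G"` or `"C"` (5-methylcytosine uses the cytosine ring).
#' @return a list with `R` (3 x 3 rotation; columns are the x, y, z axes)
#'   and `o` (origin, Angstrom), plus `rmsd` of the ring fit; `NULL` if
#'   fewer than three ring atoms are present.
#' @export
base_frame <- function(res_xyz, base) {
  ring <- if (base == "G") RING_ATOMS$purine else RING_ATOMS$pyrimidine
  have <- intersect(ring, rownames(res_xyz))
  if (length(have) < 3L) return(NULL)
  tmpl <- get_template(base, "B")[have, , drop = FALSE]
  fit <- superpose(tmpl, res_xyz[have, , drop = FALSE])
  list(R = fit$R, o = fit$t, rmsd = fit$rmsd)
}

#' Six base-pair-step parameters between two pair frames
#'
#' Mid-frame (CEHS-style) decomposition of the rigid motion between
#' consecutive base-pair reference frames.  Twist is positive for
#' right-handed stacking.
#'
#' @param f1,f2 base-pair frames (lists with `R`, `o`) of pair i and
#'   pair i+1.
#' @return named vector `shift`, `slide`, `rise` (Angstrom), `tilt`,
#'   `roll`, `twist` (degrees).
#' @export
step_parameters <- function(f1, f2) {
  if (is.null(f1) || is.null(f2)) {
    return(c(shift = NA_real_, slide = NA_real_, rise = NA_real_,
             tilt = NA_real_, roll = NA_real_, twist = NA_real_))
  }
  p <- frame_step_parameters(f1, f2)
  names(p) <- c("shift", "slide", "rise", "tilt", "roll", "twist")
  p
}

# base type of a residue name (DG -> G; DC / 5CM -> C)
base_of <- function(resid) ifelse(resid %in% c("DG", "G", "GUA"), "G", "C")

# split a topology + coordinate vector into per-residue coordinate
# matrices with atom-name rownames, ordered chain A 1..N then chain B
residue_xyz <- function(atoms, xyz_vec) {
  m <- matrix(xyz_vec, ncol = 3L, byrow = TRUE)
  key <- paste(atoms$chain, atoms$resno, sep = ":")
  idx <- split(seq_len(nrow(atoms)), factor(key, levels = unique(key)))
  lapply(idx, function(i) {
    mm <- m[i, , drop = FALSE]
    rownames(mm) <- atoms$elety[i]
    mm
  })
}

# base-pair frames of one coordinate set; returns list over pairs with
# frame, the two base frames, and the pair parameter vector
compute_pair_frames <- function(atoms, xyz_vec, n_bp) {
  res <- residue_xyz(atoms, xyz_vec)
  resmeta <- unique(atoms[, c("chain", "resno", "resid")])
  bases <- stats::setNames(base_of(resmeta$resid),
                           paste(resmeta$chain, resmeta$resno, sep = ":"))
  lapply(seq_len(n_bp), function(j) {
    k1 <- paste("A", j, sep = ":")
    k2 <- paste("B", 2L * n_bp + 1L - j, sep = ":")
    f1 <- base_frame(res[[k1]], bases[[k1]])
    f2 <- base_frame(res[[k2]], bases[[k2]])
    if (is.null(f1) || is.null(f2))
      return(list(frame = NULL, pair = rep(NA_real_, 6L)))
    f2f <- flip_frame(f2)
    p <- frame_step_parameters(f2f, f1)
    names(p) <- c("shear", "stretch", "stagger", "buckle", "propeller",
                  "opening")
    list(frame = mid_frame(f2f, f1), pair = p)
  })
}

#' Base-pair and base-pair-step parameters of a duplex or trajectory
#'
#' Computes base reference frames by template fitting, pairs them by the
#' duplex pairing rule (residue i on chain A with residue 2N+1-i on chain
#' B), and derives the six intra-pair parameters (shear, stretch, stagger
#' in Angstrom; buckle, propeller, opening in degrees) and the six step
#' parameters (shift, slide, rise in Angstrom; tilt, roll, twist in
#' degrees) with the mid-frame scheme.
#'
#' @param x a `duplex_model`, or a `dyn_trajectory` (in which case
#'   parameters are computed for every frame).
#' @param model for a trajectory: the `duplex_model` topology.
#' @return a list with data frames `pair` (columns `frame`, `pair`,
#'   `shear` ... `opening`) and `step` (columns `frame`, `step`, `type`,
#'   `shift` ... `twist`).  `type` is the dinucleotide step type on
#'   strand 1 (e.g. `GpC`).  For a single structure `frame` is 1.
#' @examples
#' b <- build_duplex("GC", "B", 5)
#' hp <- helix_parameters(b)
#' colMeans(hp$step[2:8, c("rise", "twist")])   # 3.38, 36
#' @export
helix_parameters <- function(x, model = NULL) {
  if (inherits(x, "duplex_model")) {
    atoms <- x$atoms
    frames_xyz <- matrix(t(as.matrix(atoms[, c("x", "y", "z")])), nrow = 1L)
    n_bp <- x$n_bp
    seq1 <- strsplit(x$sequence, "")[[1L]]
  } else if (inherits(x, "dyn_trajectory")) {
    if (is.null(model)) stop("a duplex_model topology is required")
    atoms <- x$atoms
    frames_xyz <- x$xyz
    n_bp <- model$n_bp
    seq1 <- strsplit(model$sequence, "")[[1L]]
  } else stop("x must be a duplex_model or dyn_trajectory")

  step_type <- if (n_bp > 1L) paste0(seq1[-n_bp], "p", seq1[-1L]) else
    character()
  pair_out <- vector("list", nrow(frames_xyz))
  step_out <- vector("list", nrow(frames_xyz))
  for (fr in seq_len(nrow(frames_xyz))) {
    pf <- compute_pair_frames(atoms, frames_xyz[fr, ], n_bp)
    pair_out[[fr]] <- data.frame(
      frame = fr, pair = seq_len(n_bp),
      do.call(rbind, lapply(pf, `[[`, "pair")), row.names = NULL)
    if (n_bp > 1L) {
      sp <- t(vapply(seq_len(n_bp - 1L), function(j)
        step_parameters(pf[[j]]$frame, pf[[j + 1L]]$frame), numeric(6L)))
      step_out[[fr]] <- data.frame(
        frame = fr, step = seq_len(n_bp - 1L), type = step_type,
        sp, row.names = NULL)
    }
  }
  list(pair = do.call(rbind, pair_out),
       step = if (n_bp > 1L) do.call(rbind, step_out) else NULL)
}

# ---- flexibility metrics ----------------------------------------------

# mean structure after iterative superposition onto the running mean
average_structure <- function(traj, n_iter = 2L, sel = NULL) {
  xyz <- traj$xyz
  if (is.null(sel)) sel <- seq_len(ncol(xyz) / 3L)
  cidx <- as.vector(t(outer(sel, 1:3, function(a, k) 3L * (a - 1L) + k)))
  ref <- matrix(xyz[1L, cidx], ncol = 3L, byrow = TRUE)
  fitted <- NULL
  for (it in seq_len(n_iter)) {
    fitted <- lapply(seq_len(nrow(xyz)), function(i) {
      superpose(matrix(xyz[i, cidx], ncol = 3L, byrow = TRUE), ref)$xyz
    })
    ref <- Reduce(`+`, fitted) / length(fitted)
  }
  list(mean = ref, fitted = fitted, sel = sel)
}

#' Theoretical B-factors from a trajectory
#'
#' Frames are superposed onto the trajectory-average structure (computed
#' by iterative superposition onto the running mean); the atomic B-factor
#' is then `(8 pi^2 / 3) <|r - <r>|^2>` and residue values average the
#' residue's heavy atoms.  Terminal residues are excluded by default, as
#' end fraying dominates them in real simulations.
#'
#' @param traj a `dyn_trajectory` with at least two frames.
#' @param model the `duplex_model` topology.
#' @param exclude_terminal drop the two terminal base pairs (default TRUE).
#' @return data frame with `chain`, `resno`, `resid` and `bfactor` (A^2),
#'   with per-atom values in attribute `"atom_bfactor"`.
#' @export
bfactors <- function(traj, model, exclude_terminal = TRUE) {
  if (nrow(traj$xyz) < 2L)
    stop("B-factors need at least two frames")
  atoms <- traj$atoms
  n <- model$n_bp
  keep <- rep(TRUE, nrow(atoms))
  if (exclude_terminal) {
    keep <- !((atoms$chain == "A" & atoms$resno %in% c(1L, n)) |
                (atoms$chain == "B" & atoms$resno %in% c(n + 1L, 2L * n)))
  }
  sel <- which(keep)
  avg <- average_structure(traj, sel = sel)
  dev2 <- vapply(avg$fitted, function(m) rowSums((m - avg$mean)^2),
                 numeric(length(sel)))
  msf <- rowMeans(dev2)
  b_atom <- (8 * pi^2 / 3) * msf
  sub <- atoms[sel, ]
  key <- paste(sub$chain, sub$resno, sep = ":")
  b_res <- tapply(b_atom, key, mean)
  meta <- unique(sub[, c("chain", "resno", "resid")])
  out <- data.frame(meta,
                    bfactor = as.numeric(b_res[paste(meta$chain, meta$resno,
                                                     sep = ":")]),
                    row.names = NULL)
  attr(out, "atom_bfactor") <- data.frame(sub[, c("chain", "resno",
                                                  "elety")],
                                          bfactor = b_atom,
                                          row.names = NULL)
  out
}

#' RMSD time series of a trajectory
#'
#' Root-mean-square deviation of each frame from a reference (by default
#' the iteratively superposed average structure), after least-squares
#' superposition, over non-terminal heavy atoms.
#'
#' @param traj a `dyn_trajectory`.
#' @param model the `duplex_model` topology.
#' @param reference `"average"` or `"first"`.
#' @param exclude_terminal drop terminal base pairs (default TRUE).
#' @return data frame with `time_ps` and `rmsd` (Angstrom).
#' @export
rmsd_series <- function(traj, model, reference = c("average", "first"),
                        exclude_terminal = TRUE) {
  reference <- match.arg(reference)
  atoms <- traj$atoms
  n <- model$n_bp
  keep <- rep(TRUE, nrow(atoms))
  if (exclude_terminal) {
    keep <- !((atoms$chain == "A" & atoms$resno %in% c(1L, n)) |
                (atoms$chain == "B" & atoms$resno %in% c(n + 1L, 2L * n)))
  }
  sel <- which(keep)
  cidx <- as.vector(t(outer(sel, 1:3, function(a, k) 3L * (a - 1L) + k)))
  ref <- if (reference == "average") average_structure(traj, sel = sel)$mean
  else matrix(traj$xyz[1L, cidx], ncol = 3L, byrow = TRUE)
  r <- vapply(seq_len(nrow(traj$xyz)), function(i) {
    superpose(matrix(traj$xyz[i, cidx], ncol = 3L, byrow = TRUE), ref)$rmsd
  }, numeric(1L))
  data.frame(time_ps = traj$time, rmsd = r)
}
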