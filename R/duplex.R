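# Construction of idealized B- and Z-form d(GC)n duplexes.

B_STEP <- c(shift = 0, slide = 0, rise = 3.38, tilt = 0, roll = 0, twist = 36)
# Z form: dinucleotide repeat, left-handed; the two step types carry
# alternating small/large negative twists summing to -60 per dinucleotide,
# and opposite small slides so the CpG/GpC bimodality of the zigzag
# backbone is present in the construction parameters.
Z_STEP_GpC <- c(shift = 0, slide = -1, rise = 3.7, tilt = 0, roll = 0,
                twist = -51)
Z_STEP_CpG <- c(shift = 0, slide = 1, rise = 3.7, tilt = 0, roll = 0,
                twist = -9)

#' Build an idealized d(GC)n B- or Z-form DNA duplex
#'
#' Constructs heavy-atom coordinates for a Watson-Crick paired duplex of an
#' alternating purine-pyrimidine repeat by placing rigid idealized
#' nucleotide templates on base-pair reference frames chained with fixed
#' construction step parameters.  The B form uses a 36-degree twist and
#' 3.38 A rise per step; the Z form uses a left-handed dinucleotide repeat
#' (twists of -9 and -51 degrees for CpG and GpC steps) with syn guanosine
#' (C3'-endo sugar) and anti cytosine (C2'-endo).  Because placement is by
#' exact frame algebra, regenerating the step parameters from the
#' coordinates with [helix_parameters()] recovers the construction values.
#'
#' Residues are numbered 1..N on chain A and N+1..2N on chain B, both in
#' 5' to 3' order, so residue i on chain A pairs with residue 2N+1-i on
#' chain B.  5'-terminal residues carry no phosphate group.
#'
#' @param sequence repeat unit for strand 1, 5' to 3'; must strictly
#'   alternate purines and pyrimidines (only G and C are supported).
#' @param form `"B"` or `"Z"`.
#' @param n_repeats number of copies of `sequence` per strand.
#' @return an object of class `duplex_model`: a list with `atoms` (a data
#'   frame with columns `eleno`, `elety`, `resid`, `chain`, `resno`,
#'   `x`, `y`, `z`), `form`, `n_bp`, `sequence` (full strand-1 sequence)
#'   and `step_parameters` (the construction parameters per step, with the
#'   step type).
#' @examples
#' b <- build_duplex("GC", form = "B", n_repeats = 5)
#' b$n_bp                      # 10
#' neutralizing_ion_count(b)   # 18
#' @export
build_duplex <- function(sequence = "GC", form = c("B", "Z"),
                         n_repeats = 5L) {
  form <- match.arg(form)
  if (!is.numeric(n_repeats) || length(n_repeats) != 1L || n_repeats < 1)
    stop("n_repeats must be a positive integer")
  n_repeats <- as.integer(n_repeats)
  unit <- strsplit(toupper(sequence), "")[[1L]]
  if (!all(unit %in% c("G", "C")))
    stop("sequence may only contain G and C")
  seq1 <- rep(unit, n_repeats)
  is_pur <- seq1 == "G"
  if (length(seq1) > 1L) {
    same <- which(is_pur[-1L] == is_pur[-length(is_pur)])
    if (length(same))
      stop(sprintf(paste0("sequence does not alternate purine/pyrimidine",
                          " at position %d"), same[1L] + 1L))
  }
  n <- length(seq1)
  comp <- ifelse(seq1 == "G", "C", "G")

  # chain pair frames with the construction step parameters
  steps <- if (n > 1L) lapply(seq_len(n - 1L), function(j) {
    if (form == "B") B_STEP
    else if (seq1[j] == "G") Z_STEP_GpC else Z_STEP_CpG
  }) else list()
  frames <- vector("list", n)
  frames[[1L]] <- new_frame(diag(3L), c(0, 0, 0))
  for (j in seq_len(n - 1L))
    frames[[j + 1L]] <- frame_step_apply(frames[[j]], steps[[j]])

  place <- function(tmpl, fr, flip) {
    R <- if (flip) fr$R %*% diag(c(1, -1, -1)) else fr$R
    tmpl %*% t(R) + rep(fr$o, each = nrow(tmpl))
  }
  res_list <- vector("list", 2L * n)
  for (j in seq_len(n)) {
    # strand 1 (chain A): pair j, residue j
    t1 <- get_template(seq1[j], form)
    x1 <- place(t1, frames[[j]], flip = FALSE)
    res_list[[j]] <- data.frame(
      elety = rownames(x1), resid = paste0("D", seq1[j]),
      chain = "A", resno = j, x = x1[, 1L], y = x1[, 2L], z = x1[, 3L],
      row.names = NULL)
    # strand 2 (chain B): pair j holds residue 2n+1-j
    t2 <- get_template(comp[j], form)
    x2 <- place(t2, frames[[j]], flip = TRUE)
    res_list[[2L * n + 1L - j]] <- data.frame(
      elety = rownames(x2), resid = paste0("D", comp[j]),
      chain = "B", resno = 2L * n + 1L - j,
      x = x2[, 1L], y = x2[, 2L], z = x2[, 3L], row.names = NULL)
  }
  atoms <- do.call(rbind, res_list)
  # 5'-terminal residues own no phosphate group
  five_prime <- (atoms$chain == "A" & atoms$resno == 1L) |
    (atoms$chain == "B" & atoms$resno == n + 1L)
  atoms <- atoms[!(five_prime & atoms$elety %in% c("P", "OP1", "OP2")), ]
  atoms <- atoms[order(atoms$chain, atoms$resno), ]
  atoms$eleno <- seq_len(nrow(atoms))
  atoms <- atoms[, c("eleno", "elety", "resid", "chain", "resno",
                     "x", "y", "z")]
  rownames(atoms) <- NULL

  sp <- if (n > 1L) {
    m <- do.call(rbind, steps)
    data.frame(step = seq_len(n - 1L),
               type = paste0(seq1[-n], "p", seq1[-1L]), m, row.names = NULL)
  } else NULL

  structure(list(atoms = atoms, form = form, n_bp = n,
                 sequence = paste(seq1, collapse = ""),
                 step_parameters = sp),
            class = "duplex_model")
}

#' @export
print.duplex_model <- function(x, ...) {
  n5mc <- sum(x$atoms$resid == "5CM" & x$atoms$elety == "N1")
  cat(sprintf("Idealized %s-form DNA duplex: %d bp, %d atoms\n",
              x$form, x$n_bp, nrow(x$atoms)))
  cat(sprintf("  strand 1 (5'->3'): %s\n", x$sequence))
  cat(sprintf("  methylated cytosines: %d; phosphate groups: %d\n",
              n5mc, neutralizing_ion_count(x)))
  invisible(x)
}

#' Coordinates of a duplex model as a matrix
#'
#' @param model a `duplex_model`.
#' @return an N x 3 matrix of coordinates (Angstrom), rows in atom order.
#' @export
duplex_xyz <- function(model) {
  as.matrix(model$atoms[, c("x", "y", "z")])
}

#' Methylate cytosines at ring carbon 5
#'
#' Converts the selected cytosines to 5-methylcytosine (residue name
#' `5CM`) by adding one methyl carbon (`C7`) in the base plane along the
#' external bisector at C5, at a standard 1.50 A bond length.  No other
#' atom moves.
#'
#' @param model a `duplex_model`.
#' @param rule `"all_non_terminal"` (every cytosine except those in the
#'   terminal base pairs, the paper's hypermethylation rule) or
#'   `"explicit"`.
#' @param positions for `rule = "explicit"`: data frame with columns
#'   `chain` and `resno` of the cytosines to methylate (may be empty).
#' @return the methylated `duplex_model`; the number of methylated
#'   cytosines is reported in attribute `"n_methylated"`.
#' @examples
#' b <- build_duplex("GC", "B", 5)
#' bm <- methylate(b)
#' attr(bm, "n_methylated")   # 8 of 10 cytosines
#' @export
methylate <- function(model, rule = c("all_non_terminal", "explicit"),
                      positions = NULL) {
  rule <- match.arg(rule)
  atoms <- model$atoms
  n <- model$n_bp
  cyt <- unique(atoms[atoms$resid %in% c("DC", "5CM"),
                      c("chain", "resno", "resid")])
  if (rule == "all_non_terminal") {
    terminal <- (cyt$chain == "A" & cyt$resno %in% c(1L, n)) |
      (cyt$chain == "B" & cyt$resno %in% c(n + 1L, 2L * n))
    sel <- cyt[!terminal, c("chain", "resno")]
  } else {
    if (is.null(positions)) positions <- data.frame(chain = character(),
                                                    resno = integer())
    key <- paste(atoms$chain, atoms$resno)
    pk <- paste(positions$chain, positions$resno)
    bad <- !(pk %in% paste(cyt$chain, cyt$resno))
    if (any(bad)) {
      off <- positions[bad, , drop = FALSE]
      stop(sprintf("cannot methylate non-cytosine residue %s:%d",
                   off$chain[1L], off$resno[1L]))
    }
    sel <- positions
  }
  n_done <- 0L
  for (i in seq_len(nrow(sel))) {
    idx <- atoms$chain == sel$chain[i] & atoms$resno == sel$resno[i]
    if (any(atoms$elety[idx] == "C7")) next    # already methylated
    res <- atoms[idx, ]
    g <- function(nm) unlist(res[res$elety == nm, c("x", "y", "z")])
    c5 <- g("C5")
    dir <- unitv(2 * c5 - g("C4") - g("C6"))
    c7 <- c5 + 1.50 * dir
    atoms$resid[idx] <- "5CM"
    new_row <- res[res$elety == "C5", ]
    new_row$elety <- "C7"; new_row$resid <- "5CM"
    new_row[, c("x", "y", "z")] <- as.list(c7)
    last <- max(which(idx))
    atoms <- rbind(atoms[seq_len(last), ], new_row,
                   atoms[-seq_len(last), , drop = FALSE])
    n_done <- n_done + 1L
  }
  atoms$eleno <- seq_len(nrow(atoms))
  rownames(atoms) <- NULL
  model$atoms <- atoms
  structure(model, n_methylated = n_done)
}

#' Number of neutralizing counterions for a duplex
#'
#' The net backbone charge magnitude of a DNA duplex equals its phosphate
#' count, so this is also the number of monovalent cations needed to
#' neutralize the system: 2(N-1) for an N-bp duplex with free 5' ends.
#'
#' @param model a `duplex_model`.
#' @return non-negative integer count of phosphate groups.
#' @examples
#' neutralizing_ion_count(build_duplex("GC", "B", 5))  # 18
#' @export
neutralizing_ion_count <- function(model) {
  sum(model$atoms$elety == "P")
}
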