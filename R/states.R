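# Discrete conformational-state analysis: BI/BII, alpha/gamma rotamers,
# fraction time series, dwell statistics and occupancy tables.

#' Classify the BI/BII backbone substate from epsilon and zeta
#'
#' The difference epsilon - zeta is reduced to the minimal circular
#' difference in `[-180, 180)` before the sign test: negative (or exactly
#' zero, a documented tie-break) is BI, positive is BII.  Undefined input
#' angles give an undefined (`NA`) label.
#'
#' @param epsilon,zeta backbone torsions in degrees (vectorised).
#' @return character vector of `"BI"` / `"BII"` labels (`NA` where
#'   undefined).
#' @examples
#' classify_bi_bii(-170, -100)  # "BI"
#' classify_bi_bii(-100, -170)  # "BII"
#' classify_bi_bii(170, -170)   # +340 wraps to -20: "BI"
#' @export
classify_bi_bii <- function(epsilon, zeta) {
  d <- wrap_angle(epsilon - zeta)
  ifelse(is.na(d), NA_character_, ifelse(d <= 0, "BI", "BII"))
}

#' Classify a torsion angle into gauche+/trans/gauche- rotamers
#'
#' Half-open 120-degree sectors on `[0, 360)`: g+ is `[0, 120)`, t is
#' `[120, 240)`, g- is `[240, 360)`.
#'
#' @param angle torsion in degrees (any range; vectorised).
#' @return character vector of `"g+"`, `"t"`, `"g-"` (`NA` preserved).
#' @examples
#' classify_rotamer(c(300, 60, 120, -60))  # g-, g+, t, g-
#' @export
classify_rotamer <- function(angle) {
  a <- wrap_angle(angle, lower = 0)
  out <- c("g+", "t", "g-")[pmin(floor(a / 120) + 1, 3L)]
  out[is.na(angle)] <- NA_character_
  out
}

#' Classify the glycosidic torsion as syn or anti
#'
#' syn is the half-open window `[-90, 90)`; anti otherwise.
#'
#' @param chi glycosidic torsion in degrees (vectorised).
#' @return character vector of `"syn"` / `"anti"` (`NA` preserved).
#' @export
classify_chi <- function(chi) {
  w <- wrap_angle(chi)
  ifelse(is.na(w), NA_character_, ifelse(w >= -90 & w < 90, "syn", "anti"))
}

#' Construct a state trajectory
#'
#' @param bi_bii character matrix (frames x residues) of BI/BII labels
#'   (`NA` allowed).
#' @param alpha_state,gamma_state,chi_state optional matrices of the same
#'   shape with rotamer / syn-anti labels.
#' @param dt frame spacing in ps.
#' @param residues optional data frame with one row per column of the
#'   matrices (`chain`, `resno`, `resid`, `terminal`); defaults to
#'   non-terminal placeholders.
#' @return an object of class `state_trajectory`.
#' @export
state_trajectory <- function(bi_bii, alpha_state = NULL, gamma_state = NULL,
                             chi_state = NULL, dt = 2, residues = NULL) {
  bi_bii <- as.matrix(bi_bii)
  if (is.null(residues))
    residues <- data.frame(chain = "A", resno = seq_len(ncol(bi_bii)),
                           resid = "DG", terminal = FALSE)
  if (nrow(residues) != ncol(bi_bii))
    stop("residue table does not match the state matrix")
  structure(list(bi_bii = bi_bii, alpha_state = alpha_state,
                 gamma_state = gamma_state, chi_state = chi_state,
                 dt = dt, time = (seq_len(nrow(bi_bii)) - 1L) * dt,
                 residues = residues),
            class = "state_trajectory")
}

#' Classify every residue-frame of a torsion series into discrete states
#'
#' Applies [classify_bi_bii()] to epsilon/zeta, [classify_rotamer()] to
#' alpha and gamma, and [classify_chi()] to chi.
#'
#' @param torsions a `torsion_series` from [backbone_torsions()].
#' @return a `state_trajectory`.
#' @export
classify_states <- function(torsions) {
  dt <- attr(torsions, "dt")
  rk <- paste(torsions$chain, torsions$resno, sep = ":")
  rlev <- unique(rk)
  tomat <- function(v) {
    m <- matrix(v, nrow = max(torsions$frame), ncol = length(rlev))
    colnames(m) <- rlev
    m
  }
  residues <- unique(torsions[, c("chain", "resno", "resid", "terminal")])
  state_trajectory(
    bi_bii = tomat(classify_bi_bii(torsions$epsilon, torsions$zeta)),
    alpha_state = tomat(classify_rotamer(torsions$alpha)),
    gamma_state = tomat(classify_rotamer(torsions$gamma)),
    chi_state = tomat(classify_chi(torsions$chi)),
    dt = if (is.null(dt)) 2 else dt, residues = residues)
}

#' @export
print.state_trajectory <- function(x, ...) {
  cat(sprintf("State trajectory: %d frames x %d residues, dt = %g ps\n",
              nrow(x$bi_bii), ncol(x$bi_bii), x$dt))
  occ <- table(x$bi_bii[, !x$residues$terminal])
  if (length(occ))
    cat("  BI/BII occupancy:",
        paste(sprintf("%s %.1f%%", names(occ), 100 * occ / sum(occ)),
              collapse = ", "), "\n")
  invisible(x)
}

.included_cols <- function(states) which(!states$residues$terminal)

#' Smoothed fraction-of-state time series
#'
#' For each frame, the fraction of included (non-terminal, defined)
#' residues carrying the given label, smoothed with a centred sliding
#' window; edge frames use the shrunken part of the window that exists.
#'
#' @param states a `state_trajectory`.
#' @param which state label to count (default `"BI"`).
#' @param window_ps sliding-window width in ps (>= dt; `window_ps = dt`
#'   reproduces the unsmoothed series).
#' @param field which label set to use: `"bi_bii"`, `"alpha_state"`,
#'   `"gamma_state"` or `"chi_state"`.
#' @return data frame with `time_ps`, `fraction` (raw) and `smoothed`.
#' @export
fraction_series <- function(states, which = "BI", window_ps = 500,
                            field = "bi_bii") {
  labels <- states[[field]]
  if (is.null(labels)) stop("state trajectory lacks field ", field)
  inc <- .included_cols(states)
  if (!length(inc)) stop("no included residues")
  if (window_ps < states$dt) stop("window_ps must be >= dt")
  lm <- labels[, inc, drop = FALSE]
  frac <- rowMeans(lm == which, na.rm = TRUE)
  h <- floor(window_ps / (2 * states$dt))
  n <- length(frac)
  cs <- cumsum(c(0, frac))
  lo <- pmax(seq_len(n) - h, 1L); hi <- pmin(seq_len(n) + h, n)
  sm <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  data.frame(time_ps = states$time, fraction = frac, smoothed = sm)
}

#' Cumulative mean of a series
#'
#' Element k is the mean of the first k values.
#'
#' @param x numeric vector (non-empty).
#' @return numeric vector of running means.
#' @examples
#' cumulative_mean(c(1, 0))  # 1.0 0.5
#' @export
cumulative_mean <- function(x) {
  if (!length(x)) stop("empty series")
  cumsum(x) / seq_along(x)
}

#' Residence-time (dwell) statistics and passage counts
#'
#' A dwell is a maximal run of one label times dt.  Runs truncated by the
#' trajectory ends are excluded from dwell means (they are censored) but
#' still contribute to occupancy; a passage is any change of label along
#' a residue's time series, summed over residues.
#'
#' @param states a `state_trajectory` (>= 2 frames).
#' @param field label set to analyse (default `"bi_bii"`).
#' @return data frame with one row per label: `label`, `mean_dwell_ps`,
#'   `sd_dwell_ps`, `n_dwells`, `occupancy`; attribute `"passages"` holds
#'   a list with the total passage count and the per-residue mean.
#' @examples
#' st <- state_trajectory(matrix(c("BI","BI","BII","BII","BII","BI"), 6, 1))
#' dwell_statistics(st)                     # one complete BII dwell, 6 ps
#' attr(dwell_statistics(st), "passages")$total   # 2
#' @export
dwell_statistics <- function(states, field = "bi_bii") {
  labels <- states[[field]]
  if (nrow(labels) < 2L) stop("dwell statistics need >= 2 frames")
  inc <- .included_cols(states)
  dt <- states$dt
  dwells <- list(); passages <- integer(length(inc))
  occ <- table(factor(labels[, inc, drop = FALSE]))
  for (k in seq_along(inc)) {
    v <- labels[, inc[k]]
    v <- v[!is.na(v)]
    if (length(v) < 2L) next
    r <- rle(v)
    passages[k] <- length(r$lengths) - 1L
    if (length(r$lengths) > 2L) {
      keep <- 2L:(length(r$lengths) - 1L)   # complete (uncensored) runs
      for (lab in unique(r$values[keep])) {
        d <- r$lengths[keep][r$values[keep] == lab] * dt
        dwells[[lab]] <- c(dwells[[lab]], d)
      }
    }
  }
  labs <- sort(unique(c(names(occ), names(dwells))))
  out <- data.frame(
    label = labs,
    mean_dwell_ps = vapply(labs, function(l)
      if (length(dwells[[l]])) mean(dwells[[l]]) else NA_real_, 1),
    sd_dwell_ps = vapply(labs, function(l)
      if (length(dwells[[l]]) > 1L) stats::sd(dwells[[l]]) else NA_real_, 1),
    n_dwells = vapply(labs, function(l) length(dwells[[l]]), 1L),
    occupancy = as.numeric(occ[labs]) / sum(occ),
    row.names = NULL)
  attr(out, "passages") <- list(total = sum(passages),
                                per_residue_mean = mean(passages))
  out
}

#' Occupancy table of alpha/gamma rotamer states
#'
#' Percentage of residue-frames in each (alpha state x gamma state) cell,
#' over non-terminal residues; percentages sum to 100.  With
#' `pairing = "step"` the table is split by dinucleotide step type: CpG
#' steps are read from the alpha/gamma angles of G residues and GpC steps
#' from those of C (or 5mC) residues.
#'
#' @param states a `state_trajectory` with rotamer labels.
#' @param pairing `"none"` for a single table or `"step"` for a CpG/GpC
#'   split.
#' @return data frame with `alpha_state`, `gamma_state`, `percent` (and
#'   `step_type` when split); percentages sum to 100 within each table.
#' @export
state_occupancy_table <- function(states, pairing = c("none", "step")) {
  pairing <- match.arg(pairing)
  inc <- .included_cols(states)
  if (!length(inc)) stop("no included residues after terminal exclusion")
  a <- states$alpha_state[, inc, drop = FALSE]
  g <- states$gamma_state[, inc, drop = FALSE]
  if (is.null(a) || is.null(g)) stop("rotamer labels are required")
  lev <- c("g+", "t", "g-")
  one_table <- function(ai, gi, extra = NULL) {
    ok <- !is.na(ai) & !is.na(gi)
    if (!sum(ok)) stop("no defined rotamer labels")
    tab <- table(factor(ai[ok], lev), factor(gi[ok], lev))
    df <- as.data.frame(tab, stringsAsFactors = FALSE)
    names(df) <- c("alpha_state", "gamma_state", "n")
    df$percent <- 100 * df$n / sum(df$n)
    df$n <- NULL
    if (!is.null(extra)) df <- cbind(step_type = extra, df)
    df
  }
  if (pairing == "none") return(one_table(a, g))
  base <- base_of(states$residues$resid[inc])
  isg <- base == "G"
  rbind(
    one_table(a[, isg, drop = FALSE], g[, isg, drop = FALSE], "CpG"),
    one_table(a[, !isg, drop = FALSE], g[, !isg, drop = FALSE], "GpC"))
}
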