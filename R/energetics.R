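# MM/PBSA-style free-energy bookkeeping.
#
# Per-snapshot identities (all kcal/mol):
#   E_MM    = E_ELE + E_VDW + E_INT
#   E_PBSUR = gamma * SA + b            (when only SA is given)
#   E_PBSOL = E_PBSUR + E_PBCAL
#   E_PBELE = E_ELE + E_PBCAL
#   E_PBTOT = E_MM + E_PBSOL
#   G       = E_PBTOT + (-T S)          (entropy is an input, never computed)

#' Nonpolar solvation term from a surface area
#'
#' `E_SA = gamma * SA + b` with the standard default coefficients
#' gamma = 0.00542 kcal/(A^2 mol) and b = 0.92 kcal/mol.
#'
#' @param SA solvent-accessible surface area in A^2 (>= 0, vectorised).
#' @param gamma surface-tension coefficient, kcal/(A^2 mol).
#' @param b intercept, kcal/mol.
#' @return nonpolar solvation energy in kcal/mol.
#' @examples
#' nonpolar_term(0)     # 0.92
#' nonpolar_term(1000)  # 6.34
#' @export
nonpolar_term <- function(SA, gamma = 0.00542, b = 0.92) {
  if (any(SA < 0, na.rm = TRUE)) stop("SA must be >= 0")
  gamma * SA + b
}

.DERIVED <- c("E_MM", "E_PBSOL", "E_PBELE", "E_PBTOT", "G")
.SUMMARY_COMPONENTS <- c("E_ELE", "E_VDW", "E_INT", "E_MM", "E_PBSUR",
                         "E_PBCAL", "E_PBSOL", "E_PBELE", "E_PBTOT",
                         "minus_TS", "G")

# per-snapshot component matrix with all derived columns recomputed
derived_components <- function(table) {
  d <- as.data.frame(table)
  if (!"E_PBSUR" %in% names(d)) d$E_PBSUR <- nonpolar_term(d$SA)
  out <- data.frame(E_ELE = d$E_ELE, E_VDW = d$E_VDW, E_INT = d$E_INT)
  out$E_MM <- d$E_ELE + d$E_VDW + d$E_INT
  out$E_PBSUR <- d$E_PBSUR
  out$E_PBCAL <- d$E_PBCAL
  out$E_PBSOL <- out$E_PBSUR + out$E_PBCAL
  out$E_PBELE <- out$E_ELE + out$E_PBCAL
  out$E_PBTOT <- out$E_MM + out$E_PBSOL
  if ("minus_TS" %in% names(d)) {
    out$minus_TS <- d$minus_TS
    out$G <- out$E_PBTOT + out$minus_TS
  }
  # flag derived columns supplied in the input that disagree with the
  # recomputation (printed tables are not always self-consistent)
  incons <- character(0)
  for (col in intersect(.DERIVED, names(d))) {
    dev <- max(abs(d[[col]] - out[[col]]))
    if (dev > 0.05)
      incons <- c(incons, sprintf("%s differs from components by %.2f",
                                  col, dev))
  }
  attr(out, "inconsistencies") <- incons
  out
}

#' Summarize an MM/PBSA energy table
#'
#' Recomputes all derived energy components per snapshot, then reports the
#' mean and standard error (sample SD over the square root of the snapshot
#' count) of every component.  If the input carries derived columns that
#' disagree with their recomputation from components, the discrepancy is
#' flagged in `$inconsistencies` rather than silently reproduced.  The
#' entropic term `-T<S>` is passed through when present; otherwise `G` is
#' omitted with a warning.
#'
#' @param table an `energy_table` (or data frame with the same columns).
#' @param temperature temperature in K (recorded; the entropy input is
#'   already a -TS term).
#' @return an object of class `energy_summary`: a list with `system`,
#'   `n`, `temperature`, `stats` (data frame `component`, `mean`, `se`)
#'   and `inconsistencies`.
#' @export
summarize_energies <- function(table, temperature = 300) {
  comp <- derived_components(table)
  n <- nrow(comp)
  if (!"G" %in% names(comp))
    warning("no entropy column (minus_TS): G not reported")
  comps <- intersect(.SUMMARY_COMPONENTS, names(comp))
  se <- function(x) if (n >= 2L) stats::sd(x) / sqrt(n) else NA_real_
  if (n < 2L) warning("fewer than 2 snapshots: standard errors undefined")
  stats_df <- data.frame(
    component = comps,
    mean = vapply(comps, function(cc) mean(comp[[cc]]), 1),
    se = vapply(comps, function(cc) se(comp[[cc]]), 1),
    row.names = NULL)
  structure(list(system = attr(table, "system"), n = n,
                 temperature = temperature, stats = stats_df,
                 components = comp,
                 inconsistencies = attr(comp, "inconsistencies")),
            class = "energy_summary")
}

#' @export
print.energy_summary <- function(x, digits = 2, ...) {
  cat(sprintf("MM/PBSA summary%s: %d snapshots\n",
              if (is.na(x$system)) "" else paste0(" [", x$system, "]"),
              x$n))
  df <- x$stats
  df$mean <- round(df$mean, digits); df$se <- round(df$se, digits + 1)
  print.data.frame(df, row.names = FALSE)
  if (length(x$inconsistencies))
    cat("flagged:", paste(x$inconsistencies, collapse = "; "), "\n")
  invisible(x)
}

#' Mean of one component from an energy summary
#'
#' @param summary an `energy_summary`.
#' @param component component name, e.g. `"E_MM"`.
#' @return the mean in kcal/mol.
#' @export
component_mean <- function(summary, component) {
  i <- match(component, summary$stats$component)
  if (is.na(i)) stop("no component ", component)
  summary$stats$mean[i]
}

#' Per-component contrast between two MM/PBSA summaries
#'
#' Differences of component means (a minus b) with propagated standard
#' errors `sqrt(se_a^2 + se_b^2)` and a Welch (unequal-variance)
#' two-sample t-test per component.
#'
#' @param a,b `energy_summary` objects with the same component schema.
#' @return data frame of class `energy_contrast` with `component`,
#'   `delta`, `se`, `t`, `df`, `p` and `neg_log10_p`.
#' @export
energy_contrast <- function(a, b) {
  if (!identical(a$stats$component, b$stats$component))
    stop("summaries have mismatched component schemas")
  delta <- a$stats$mean - b$stats$mean
  se <- sqrt(a$stats$se^2 + b$stats$se^2)
  # Welch-Satterthwaite from summary statistics
  va <- a$stats$se^2; vb <- b$stats$se^2
  df <- (va + vb)^2 / (va^2 / (a$n - 1) + vb^2 / (b$n - 1))
  t <- ifelse(se > 0, delta / se,
              ifelse(delta == 0, 0, sign(delta) * Inf))
  p <- ifelse(se > 0, 2 * stats::pt(-abs(t), df),
              ifelse(delta == 0, 1, 0))
  out <- data.frame(component = a$stats$component, delta = delta, se = se,
                    t = t, df = df, p = p,
                    neg_log10_p = -log10(pmax(p, .Machine$double.xmin)),
                    row.names = NULL)
  class(out) <- c("energy_contrast", "data.frame")
  out
}

#' Two-sample test on one energy component of two tables
#'
#' Welch (default) or paired t-test on the per-snapshot values of a
#' (possibly derived) component, recomputed from the tables' columns.
#'
#' @param table_a,table_b energy tables.
#' @param component component name (e.g. `"E_PBTOT"`).
#' @param paired use a paired t-test (snapshot k of a against snapshot k
#'   of b); default FALSE (Welch).
#' @return the `htest` object from [stats::t.test()].
#' @export
energy_ttest <- function(table_a, table_b, component, paired = FALSE) {
  ca <- derived_components(table_a); cb <- derived_components(table_b)
  if (!component %in% names(ca) || !component %in% names(cb))
    stop("no component ", component)
  stats::t.test(ca[[component]], cb[[component]], paired = paired,
                var.equal = FALSE)
}
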