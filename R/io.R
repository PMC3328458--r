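# File formats: multi-model PDB trajectories (via bio3d) and delimited
# tables for torsion series, state series and MM/PBSA energy components.

.ACCEPTED_RESID <- c("DG", "DC", "5CM", "G", "C", "GUA", "CYT", "5MC")

#' Write a duplex or trajectory as (multi-model) PDB
#'
#' Writes standard ATOM records with residue names `DG`, `DC` and `5CM`
#' and a TER record between chains; trajectories are written as
#' MODEL/ENDMDL blocks with one model per frame.
#'
#' @param x a `duplex_model` or `dyn_trajectory`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(x, path) {
  if (inherits(x, "duplex_model")) {
    atoms <- x$atoms
    xyz <- matrix(t(duplex_xyz(x)), nrow = 1L)
  } else if (inherits(x, "dyn_trajectory")) {
    atoms <- x$atoms
    xyz <- x$xyz
  } else stop("x must be a duplex_model or dyn_trajectory")
  bio3d::write.pdb(file = path, xyz = xyz,
                   type = rep("ATOM", nrow(atoms)),
                   resno = atoms$resno, resid = atoms$resid,
                   elety = atoms$elety, chain = atoms$chain,
                   eleno = atoms$eleno, chainter = TRUE)
  invisible(path)
}

#' Read a multi-model PDB trajectory
#'
#' Parses a (possibly multi-model) PDB file into a trajectory plus its
#' topology.  Atom names and residue names are preserved verbatim; every
#' model must contain the same number of atoms.
#'
#' @param path PDB file with one MODEL/ENDMDL block per frame (a plain
#'   single-structure file yields a one-frame trajectory).
#' @param dt frame spacing in ps attached to the trajectory.
#' @return a `dyn_trajectory`; the topology data frame is in `$atoms`.
#' @export
read_trajectory <- function(path, dt = 2) {
  lines <- readLines(path)
  is_atom <- startsWith(lines, "ATOM") | startsWith(lines, "HETATM")
  model_starts <- which(startsWith(lines, "MODEL"))
  if (length(model_starts) == 0L && !any(is_atom))
    stop("no models found in '", path, "'")
  if (length(model_starts) > 1L) {
    # per-model atom-count consistency check before handing off to bio3d
    model_ends <- which(startsWith(lines, "ENDMDL"))
    if (length(model_ends) != length(model_starts))
      stop("unpaired MODEL/ENDMDL records")
    counts <- mapply(function(s, e) sum(is_atom[s:e]), model_starts,
                     model_ends)
    if (length(unique(counts)) > 1L) {
      bad <- which(counts != counts[1L])[1L]
      stop(sprintf(
        "inconsistent atom count in model %d (%d atoms, expected %d)",
        bad, counts[bad], counts[1L]))
    }
  }
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  atoms <- data.frame(eleno = pdb$atom$eleno, elety = pdb$atom$elety,
                      resid = pdb$atom$resid, chain = pdb$atom$chain,
                      resno = pdb$atom$resno,
                      x = pdb$atom$x, y = pdb$atom$y, z = pdb$atom$z)
  unknown <- setdiff(unique(atoms$resid), .ACCEPTED_RESID)
  if (length(unknown))
    stop("unknown residue name(s) ", paste(unknown, collapse = ", "),
         "; accepted: ", paste(.ACCEPTED_RESID, collapse = ", "))
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  dyn_trajectory(unclass(xyz), atoms, dt = dt)
}

# ---- tabular I/O -------------------------------------------------------

.read_delim <- function(path) {
  l1 <- readLines(path, n = 1L)
  sep <- if (grepl("\t", l1)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                    stringsAsFactors = FALSE)
}

#' Read a per-snapshot MM/PBSA energy-component table
#'
#' Reads a comma- or tab-delimited table with one row per snapshot.
#' Required columns: `E_ELE`, `E_VDW`, `E_INT`, `E_PBCAL` and either `SA`
#' (solvent-accessible surface area, A^2) or a precomputed `E_PBSUR`
#' (kcal/mol).  If both are present `E_PBSUR` takes precedence and a
#' warning is issued.  An optional `minus_TS` column carries the entropic
#' term -T<S> (kcal/mol).  All energies are kcal/mol.
#'
#' @param path delimited text file with a header.
#' @param system optional system label (e.g. `"B"`, `"BM"`, `"Z"`, `"ZM"`);
#'   defaults to the `system` column if present.
#' @return a data frame of class `energy_table` with attributes `system`
#'   and `units` (`"kcal/mol"`).
#' @export
read_energy_table <- function(path, system = NULL) {
  tab <- .read_delim(path)
  energy_table(tab, system = system)
}

#' Construct an energy table from a data frame
#'
#' @param tab data frame of per-snapshot components (see
#'   [read_energy_table()] for the column contract).
#' @param system optional system label.
#' @return a validated `energy_table`.
#' @export
energy_table <- function(tab, system = NULL) {
  required <- c("E_ELE", "E_VDW", "E_INT", "E_PBCAL")
  for (col in required)
    if (!col %in% names(tab)) stop("missing column ", col)
  if (!("SA" %in% names(tab)) && !("E_PBSUR" %in% names(tab)))
    stop("missing column SA (or E_PBSUR)")
  if (all(c("SA", "E_PBSUR") %in% names(tab)))
    warning("both SA and E_PBSUR present; E_PBSUR takes precedence")
  num_cols <- intersect(c("E_ELE", "E_VDW", "E_INT", "E_PBCAL", "SA",
                          "E_PBSUR", "minus_TS"), names(tab))
  for (col in num_cols) {
    if (!is.numeric(tab[[col]])) stop("column ", col, " is not numeric")
    if (anyNA(tab[[col]])) stop("missing values in column ", col)
  }
  if (is.null(system) && "system" %in% names(tab))
    system <- unique(tab$system)[1L]
  structure(tab, class = c("energy_table", "data.frame"),
            system = if (is.null(system)) NA_character_ else system,
            units = "kcal/mol")
}

#' Write a torsion, state or parameter table as delimited text
#'
#' @param tab a data frame.
#' @param path output path.
#' @param format `"csv"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_table <- function(tab, path, format = c("csv", "tsv")) {
  format <- match.arg(format)
  utils::write.table(tab, path, sep = if (format == "csv") "," else "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
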