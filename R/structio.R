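# Structure / trajectory input-output and atom selections.
#
# Internal units follow the Gromacs convention throughout the package:
# lengths in nm, energies in kJ/mol, masses in amu, charges in e, times
# in ps.  PDB files are read and written in Angstrom and converted.

# Standard atomic masses (amu), keyed by element symbol.
.element_masses <- c(
  H = 1.008, D = 2.014, C = 12.011, N = 14.007, O = 15.999,
  F = 18.998, "NA" = 22.990, MG = 24.305, P = 30.974, S = 32.06,
  CL = 35.45, K = 39.098, CA = 40.078, MN = 54.938, FE = 55.845,
  ZN = 65.38, BR = 79.904, I = 126.904
)

.amino3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
             "HIS", "HID", "HIE", "HIP", "ILE", "LEU", "LYS", "MET",
             "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL")

.nucleic3 <- c("A", "C", "G", "U", "T", "I",
               "RA", "RC", "RG", "RU",
               "DA", "DC", "DG", "DT")

.protein_backbone_names <- c("N", "CA", "C")
.nucleic_backbone_names <- c("P", "O5'", "C5'", "C4'", "C3'", "O3'")

#' Infer element symbols from PDB atom names
#'
#' Strips leading digits and trailing digits/primes from the atom name and
#' matches the leading one or two characters against the known element
#' table (two-letter symbols such as `CL` or `FE` are recognised only when
#' the full cleaned name starts with them and the one-letter reading is not
#' a standard biopolymer element).
#'
#' @param names character vector of PDB atom names (e.g. `"CA"`, `"O5'"`,
#'   `"1HB"`).
#' @return character vector of element symbols.
#' @export
infer_element <- function(names) {
  cleaned <- toupper(gsub("^[0-9]+", "", trimws(names)))
  cleaned <- gsub("[0-9']+", "", cleaned)
  out <- character(length(names))
  bio <- c("H", "C", "N", "O", "P", "S")
  for (i in seq_along(cleaned)) {
    nm <- cleaned[i]
    if (nchar(nm) == 0L) {
      stop("cannot infer element from atom name '", names[i], "'")
    }
    one <- substr(nm, 1L, 1L)
    two <- substr(nm, 1L, 2L)
    if (one %in% bio) {
      out[i] <- one
    } else if (two %in% names(.element_masses)) {
      out[i] <- two
    } else if (one %in% names(.element_masses)) {
      out[i] <- one
    } else {
      stop("cannot infer element from atom name '", names[i], "'")
    }
  }
  out
}

#' Look up atomic masses by element
#'
#' @param element character vector of element symbols.
#' @return numeric vector of masses in amu; unknown elements are an error
#'   (no guessing).
#' @export
element_mass <- function(element) {
  m <- .element_masses[toupper(element)]
  if (anyNA(m)) {
    bad <- unique(element[is.na(m)])
    stop("no mass for element(s): ", paste(bad, collapse = ", "))
  }
  unname(m)
}

#' Construct an atom table
#'
#' @param serial integer atom serial numbers.
#' @param name PDB atom names.
#' @param resname residue names.
#' @param resid integer residue numbers.
#' @param chain single-character chain identifiers.
#' @param element element symbols; inferred from `name` when `NULL`.
#' @return a `data.frame` with columns serial, name, element, resname,
#'   resid, chain and mass (amu).
#' @export
atom_table <- function(serial, name, resname, resid, chain, element = NULL) {
  if (is.null(element)) element <- infer_element(name)
  at <- data.frame(
    serial = as.integer(serial),
    name = as.character(name),
    element = toupper(as.character(element)),
    resname = as.character(resname),
    resid = as.integer(resid),
    chain = as.character(chain),
    stringsAsFactors = FALSE
  )
  at$mass <- element_mass(at$element)
  key <- paste(at$chain, at$resid, at$name)
  if (anyDuplicated(key)) {
    stop("duplicate (chain, resid, name) in atom table: ",
         key[duplicated(key)][1L])
  }
  at
}

#' Construct a trajectory
#'
#' A trajectory is an ordered set of frames sharing one atom table.
#'
#' @param atoms atom table (see [atom_table()]).
#' @param coords coordinates in nm: an `n_atoms x 3` matrix (single frame),
#'   a list of such matrices, or an `n_atoms x 3 x n_frames` array.
#' @param timestep_ps frame spacing in ps (must be > 0).
#' @param time_origin_ps time of the first frame in ps.
#' @return an object of class `md_trajectory`.
#' @export
trajectory <- function(atoms, coords, timestep_ps = 2, time_origin_ps = 0) {
  if (is.list(coords) && !is.array(coords)) {
    coords <- array(unlist(coords), dim = c(nrow(coords[[1L]]), 3L, length(coords)))
  } else if (is.matrix(coords)) {
    coords <- array(coords, dim = c(nrow(coords), 3L, 1L))
  }
  stopifnot(length(dim(coords)) == 3L, dim(coords)[2L] == 3L)
  if (dim(coords)[1L] != nrow(atoms)) {
    stop("coordinate frames have ", dim(coords)[1L], " atoms; atom table has ",
         nrow(atoms))
  }
  if (!all(is.finite(coords))) stop("non-finite coordinates")
  if (!is.numeric(timestep_ps) || timestep_ps <= 0) {
    stop("timestep_ps must be > 0")
  }
  structure(
    list(atoms = atoms, coords = coords,
         timestep_ps = as.numeric(timestep_ps),
         time_origin_ps = as.numeric(time_origin_ps)),
    class = "md_trajectory"
  )
}

#' @export
print.md_trajectory <- function(x, ...) {
  cat("md_trajectory:", nrow(x$atoms), "atoms,", n_frames(x), "frames,",
      "dt =", x$timestep_ps, "ps\n")
  cat("  chains:", paste(unique(x$atoms$chain), collapse = " "), "\n")
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj an `md_trajectory`.
#' @return integer frame count.
#' @export
n_frames <- function(traj) dim(traj$coords)[3L]

#' Frame times in ps
#' @param traj an `md_trajectory`.
#' @return numeric vector of length `n_frames(traj)`.
#' @export
frame_times <- function(traj) {
  traj$time_origin_ps + (seq_len(n_frames(traj)) - 1L) * traj$timestep_ps
}

#' Extract one frame's coordinates
#' @param traj an `md_trajectory`.
#' @param i frame index (1-based).
#' @return an `n_atoms x 3` matrix in nm.
#' @export
frame_coords <- function(traj, i = 1L) {
  traj$coords[, , i, drop = TRUE]
}

#' Indices of frames inside a trailing time window
#'
#' The window covers frames with time strictly greater than
#' `t_end - window_ns`, inclusive of the final frame (so a 60-ns window on
#' a 100-ns trajectory keeps the last 60 ns).
#'
#' @param traj an `md_trajectory`.
#' @param window_ns window length in ns; `NULL` selects all frames.
#' @return integer vector of frame indices.
#' @export
frames_in_window <- function(traj, window_ns = NULL) {
  if (is.null(window_ns)) return(seq_len(n_frames(traj)))
  t <- frame_times(traj)
  idx <- which(t > t[length(t)] - window_ns * 1000)
  if (length(idx) == 0L) idx <- length(t)
  idx
}

#' Restrict a trajectory to a set of frames
#' @param traj an `md_trajectory`.
#' @param frames integer frame indices.
#' @return an `md_trajectory` holding only those frames.
#' @export
subset_frames <- function(traj, frames) {
  out <- traj
  out$coords <- traj$coords[, , frames, drop = FALSE]
  out$time_origin_ps <- frame_times(traj)[frames[1L]]
  out
}

# ---------------------------------------------------------------------------
# PDB reading / writing (fixed-column, multi-model)

.parse_pdb_atoms <- function(lines, line_no) {
  num <- function(cols, what) {
    txt <- trimws(substr(lines, cols[1L], cols[2L]))
    v <- suppressWarnings(as.numeric(txt))
    bad <- which(!is.finite(v))
    if (length(bad) > 0L) {
      stop("malformed ATOM record at line ", line_no[bad[1L]],
           ": bad ", what, " field '", txt[bad[1L]], "'")
    }
    v
  }
  data.frame(
    serial = as.integer(num(c(7, 11), "serial")),
    name = trimws(substr(lines, 13, 16)),
    resname = trimws(substr(lines, 18, 20)),
    chain = trimws(substr(lines, 22, 22)),
    resid = as.integer(num(c(23, 26), "resid")),
    x = num(c(31, 38), "x"),
    y = num(c(39, 46), "y"),
    z = num(c(47, 54), "z"),
    b = suppressWarnings(as.numeric(trimws(substr(lines, 61, 66)))),
    element = trimws(substr(lines, 77, 78)),
    stringsAsFactors = FALSE
  )
}

#' Read a (multi-model) PDB file as a trajectory
#'
#' `MODEL`/`ENDMDL` blocks become frames; a file without `MODEL` records is
#' a single-frame trajectory.  Coordinates are converted from Angstrom to
#' nm.  Element symbols are taken from columns 77-78 when present and
#' inferred from the atom name otherwise.  Models whose atom count differs
#' from the first model are rejected.
#'
#' @param path PDB file path.
#' @param timestep_ps frame spacing assigned to the resulting trajectory.
#' @param time_origin_ps time of the first frame.
#' @return an `md_trajectory`; per-atom B-factors of the first model are
#'   attached as attribute `bfactor`.
#' @export
read_pdb <- function(path, timestep_ps = 2, time_origin_ps = 0) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  if (!any(is_atom)) stop("no ATOM/HETATM records in ", path)
  model_id <- cumsum(substr(lines, 1, 5) == "MODEL")
  atom_lines <- which(is_atom)
  model_of_atom <- model_id[atom_lines]
  if (all(model_of_atom == 0L)) model_of_atom <- rep(1L, length(atom_lines))
  if (any(model_of_atom == 0L)) {
    stop("ATOM records outside MODEL blocks at line ",
         atom_lines[model_of_atom == 0L][1L])
  }
  parsed <- .parse_pdb_atoms(lines[atom_lines], atom_lines)
  split_idx <- split(seq_along(atom_lines), model_of_atom)
  n0 <- length(split_idx[[1L]])
  sizes <- vapply(split_idx, length, integer(1L))
  if (any(sizes != n0)) {
    bad <- names(split_idx)[sizes != n0][1L]
    stop("model ", bad, " has ", sizes[sizes != n0][1L],
         " atoms; expected ", n0)
  }
  first <- parsed[split_idx[[1L]], ]
  element <- ifelse(nchar(first$element) > 0L, toupper(first$element),
                    infer_element(first$name))
  atoms <- atom_table(first$serial, first$name, first$resname,
                      first$resid, first$chain, element)
  nf <- length(split_idx)
  coords <- array(NA_real_, dim = c(n0, 3L, nf))
  for (k in seq_len(nf)) {
    blk <- parsed[split_idx[[k]], ]
    coords[, , k] <- cbind(blk$x, blk$y, blk$z) / 10  # Angstrom -> nm
  }
  out <- trajectory(atoms, coords, timestep_ps = timestep_ps,
                    time_origin_ps = time_origin_ps)
  attr(out, "bfactor") <- first$b
  out
}

#' Write a trajectory to a (multi-model) PDB file
#'
#' Coordinates are converted from nm to Angstrom.  The B-factor column can
#' carry an arbitrary per-atom scalar (e.g. a centrality value scaled to
#' the column width); occupancy is written as 1.00.
#'
#' @param traj an `md_trajectory`.
#' @param path output file path.
#' @param bfactor optional per-atom numeric vector written to the B-factor
#'   column (recycled across frames); default 0.
#' @param model_records write `MODEL`/`ENDMDL` even for a single frame
#'   (`TRUE`); with `FALSE` a single-frame trajectory is written without
#'   model records.
#' @param remarks optional character vector written as `REMARK` lines.
#' @return the path, invisibly.
#' @export
write_pdb <- function(traj, path, bfactor = NULL, model_records = TRUE,
                      remarks = NULL) {
  at <- traj$atoms
  if (any(nchar(at$chain) > 1L)) {
    stop("chain identifiers longer than 1 character cannot be written: ",
         at$chain[nchar(at$chain) > 1L][1L])
  }
  if (is.null(bfactor)) bfactor <- rep(0, nrow(at))
  bfactor <- rep_len(bfactor, nrow(at))
  name_fmt <- ifelse(nchar(at$name) >= 4L, substr(at$name, 1L, 4L),
                     sprintf(" %-3s", at$name))
  nf <- n_frames(traj)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(remarks)) {
    writeLines(sprintf("REMARK %s", remarks), con)
  }
  use_models <- nf > 1L || model_records
  for (k in seq_len(nf)) {
    if (use_models) writeLines(sprintf("MODEL %8d", k), con)
    xyz <- traj$coords[, , k] * 10  # nm -> Angstrom
    writeLines(sprintf(
      "ATOM  %5d %s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      at$serial %% 100000L, name_fmt, "", substr(at$resname, 1L, 3L),
      at$chain, at$resid %% 10000L, "",
      xyz[, 1L], xyz[, 2L], xyz[, 3L], 1, bfactor,
      substr(at$element, 1L, 2L)), con)
    if (use_models) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Atom selection mini-language

.residue_class <- function(atoms) {
  key <- paste(atoms$chain, atoms$resid, sep = "\r")
  cls <- rep("other", nrow(atoms))
  for (k in unique(key)) {
    idx <- which(key == k)
    rn <- atoms$resname[idx[1L]]
    nm <- atoms$name[idx]
    if (rn %in% .amino3 || all(c("N", "CA", "C") %in% nm)) {
      cls[idx] <- "protein"
    } else if (rn %in% .nucleic3 ||
               any(c("O5'", "C4'") %in% nm)) {
      cls[idx] <- "nucleic"
    }
  }
  cls
}

.sel_tokenize <- function(expression) {
  expression <- gsub("\\(", " ( ", expression)
  expression <- gsub("\\)", " ) ", expression)
  toks <- strsplit(trimws(expression), "[[:space:]]+")[[1L]]
  if (length(toks) == 0L) stop("empty selection expression")
  toks
}

.sel_keywords <- c("all", "backbone", "heavy", "protein", "nucleic", "none")
.sel_fields <- c("chain", "resid", "name", "element", "resname")
.sel_ops <- c("and", "or", "not", "(", ")")

.sel_parse_resid_values <- function(vals) {
  out <- integer(0)
  for (v in vals) {
    if (grepl("^-?[0-9]+[:-][0-9]+$", v)) {
      parts <- as.integer(strsplit(v, "[:-]")[[1L]])
      out <- c(out, seq(parts[1L], parts[2L]))
    } else if (grepl("^-?[0-9]+$", v)) {
      out <- c(out, as.integer(v))
    } else {
      stop("bad resid token '", v, "' (expected number or a:b range)")
    }
  }
  out
}

# Recursive-descent parser returning a logical mask over atoms.
.sel_parse <- function(tokens, atoms, cls) {
  pos <- 1L
  peek <- function() if (pos <= length(tokens)) tokens[pos] else NA_character_
  advance <- function() { t <- tokens[pos]; pos <<- pos + 1L; t }

  primary <- function() {
    t <- peek()
    if (is.na(t)) stop("unexpected end of selection expression")
    if (t == "(") {
      advance()
      m <- or_expr()
      if (!identical(peek(), ")")) stop("missing ')' in selection")
      advance()
      return(m)
    }
    if (t %in% .sel_keywords) {
      advance()
      return(switch(t,
        all = rep(TRUE, nrow(atoms)),
        none = rep(FALSE, nrow(atoms)),
        heavy = atoms$element != "H" & atoms$element != "D",
        protein = cls == "protein",
        nucleic = cls == "nucleic",
        backbone = (cls == "protein" & atoms$name %in% .protein_backbone_names) |
                   (cls == "nucleic" & atoms$name %in% .nucleic_backbone_names)
      ))
    }
    if (t %in% .sel_fields) {
      advance()
      vals <- character(0)
      while (!is.na(peek()) && !(peek() %in% .sel_ops) &&
             !(peek() %in% .sel_fields) && !(peek() %in% .sel_keywords)) {
        vals <- c(vals, advance())
      }
      if (length(vals) == 0L) stop("field '", t, "' needs at least one value")
      return(switch(t,
        chain = atoms$chain %in% vals,
        name = atoms$name %in% vals,
        element = atoms$element %in% toupper(vals),
        resname = atoms$resname %in% toupper(vals),
        resid = atoms$resid %in% .sel_parse_resid_values(vals)
      ))
    }
    stop("unknown selection token '", t, "'; accepted keywords: ",
         paste(c(.sel_keywords, .sel_fields, "and", "or", "not"),
               collapse = ", "))
  }
  unary <- function() {
    if (identical(peek(), "not")) { advance(); return(!unary()) }
    primary()
  }
  and_expr <- function() {
    m <- unary()
    while (identical(peek(), "and")) { advance(); m <- m & unary() }
    m
  }
  or_expr <- function() {
    m <- and_expr()
    while (identical(peek(), "or")) { advance(); m <- m | and_expr() }
    m
  }
  m <- or_expr()
  if (!is.na(peek())) stop("trailing token '", peek(), "' in selection")
  m
}

#' Resolve an atom selection expression
#'
#' The mini-language combines keywords (`all`, `backbone`, `heavy`,
#' `protein`, `nucleic`, `none`), fields with values (`chain A B`,
#' `resid 39 60 108`, `resid 1:46`, `name CA P`, `element H`,
#' `resname HIS`) and the operators `and`, `or`, `not` with parentheses.
#' `backbone` means atom names N, CA, C of protein residues plus P, O5',
#' C5', C4', C3', O3' of nucleic residues; `heavy` means element not H.
#'
#' @param topology an atom table or an `md_trajectory`.
#' @param expression selection string.
#' @return strictly increasing integer vector of atom indices (possibly
#'   empty).
#' @export
select_atoms <- function(topology, expression) {
  atoms <- if (inherits(topology, "md_trajectory")) topology$atoms else topology
  cls <- .residue_class(atoms)
  mask <- .sel_parse(.sel_tokenize(expression), atoms, cls)
  which(mask)
}

# ---------------------------------------------------------------------------
# Nonbonded parameter tables

#' Construct per-atom nonbonded parameters
#'
#' @param charge per-atom partial charges (e).
#' @param sigma per-atom Lennard-Jones sigma (nm), all >= 0.
#' @param epsilon per-atom Lennard-Jones epsilon (kJ/mol), all >= 0.
#' @param combination_rule `"lorentz_berthelot"` (arithmetic sigma,
#'   geometric epsilon) or `"geometric"` (geometric both).
#' @return an object of class `nonbonded_params`.
#' @export
nonbonded_params <- function(charge, sigma, epsilon,
                             combination_rule = c("lorentz_berthelot",
                                                  "geometric")) {
  combination_rule <- match.arg(combination_rule)
  stopifnot(length(charge) == length(sigma),
            length(sigma) == length(epsilon))
  if (any(sigma < 0)) stop("negative sigma")
  if (any(epsilon < 0)) stop("negative epsilon")
  structure(
    data.frame(charge = charge, sigma = sigma, epsilon = epsilon),
    combination_rule = combination_rule,
    class = c("nonbonded_params", "data.frame")
  )
}

#' Load a nonbonded parameter table for a topology
#'
#' The table is whitespace-separated with a header, either
#' `resname name charge sigma epsilon` (keyed by residue and atom name) or
#' `serial charge sigma epsilon` (keyed by atom serial).  Every atom of the
#' topology must be covered; duplicate keys with conflicting values are an
#' error (no silent override).
#'
#' @param path table file path.
#' @param topology atom table or `md_trajectory`.
#' @param combination_rule see [nonbonded_params()].
#' @return a `nonbonded_params` object aligned with the topology's atom
#'   order.
#' @export
load_params <- function(path, topology,
                        combination_rule = c("lorentz_berthelot",
                                             "geometric")) {
  combination_rule <- match.arg(combination_rule)
  atoms <- if (inherits(topology, "md_trajectory")) topology$atoms else topology
  tab <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
  if (all(c("resname", "name", "charge", "sigma", "epsilon") %in% names(tab))) {
    key <- paste(tab$resname, tab$name)
    if (anyDuplicated(key)) {
      dup <- key[duplicated(key)]
      for (d in unique(dup)) {
        rows <- tab[key == d, c("charge", "sigma", "epsilon")]
        if (nrow(unique(rows)) > 1L) {
          stop("conflicting duplicate parameter entries for (", d, ")")
        }
      }
      tab <- tab[!duplicated(key), ]
      key <- key[!duplicated(key)]
    }
    want <- paste(atoms$resname, atoms$name)
    hit <- match(want, key)
    if (anyNA(hit)) {
      missing <- unique(want[is.na(hit)])
      stop("parameter table misses entries for: ",
           paste(missing, collapse = "; "))
    }
    out <- tab[hit, c("charge", "sigma", "epsilon")]
  } else if (all(c("serial", "charge", "sigma", "epsilon") %in% names(tab))) {
    if (anyDuplicated(tab$serial)) {
      stop("duplicate serial in parameter table")
    }
    hit <- match(atoms$serial, tab$serial)
    if (anyNA(hit)) {
      stop("parameter table misses serials: ",
           paste(atoms$serial[is.na(hit)], collapse = ", "))
    }
    out <- tab[hit, c("charge", "sigma", "epsilon")]
  } else {
    stop("parameter table must have columns (resname name charge sigma ",
         "epsilon) or (serial charge sigma epsilon)")
  }
  if (any(out$epsilon < 0)) stop("negative epsilon in parameter table")
  if (any(out$sigma < 0)) stop("negative sigma in parameter table")
  nonbonded_params(out$charge, out$sigma, out$epsilon, combination_rule)
}

#' Write a nonbonded parameter table
#'
#' @param params a `nonbonded_params` object.
#' @param topology the matching atom table or trajectory.
#' @param path output path (header `resname name charge sigma epsilon`).
#' @return the path, invisibly.
#' @export
write_params <- function(params, topology, path) {
  atoms <- if (inherits(topology, "md_trajectory")) topology$atoms else topology
  tab <- data.frame(resname = atoms$resname, name = atoms$name,
                    charge = params$charge, sigma = params$sigma,
                    epsilon = params$epsilon)
  tab <- tab[!duplicated(paste(tab$resname, tab$name)), ]
  utils::write.table(tab, path, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Shift residue numbering of one chain
#'
#' Utility for continuous renumbering across chains (e.g. presenting a
#' second identical chain as residues 697-1365 instead of repeating
#' 28-696).  Off by default everywhere; analyses use author numbering.
#'
#' @param traj an `md_trajectory`.
#' @param chain chain identifier to renumber.
#' @param offset integer added to that chain's residue numbers.
#' @return the modified trajectory.
#' @export
offset_resids <- function(traj, chain, offset) {
  traj$atoms$resid[traj$atoms$chain == chain] <-
    traj$atoms$resid[traj$atoms$chain == chain] + as.integer(offset)
  traj
}
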