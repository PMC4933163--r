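#' Van der Waals radii (Bondi set)
#'
#' Element to radius lookup used when reading structures and for all
#' clearance, surface and volume calculations. Values are the Bondi (1964)
#' compilation in angstroms, extended with a few common biological metals.
#'
#' @return Named numeric vector, element symbol to radius in angstroms.
#' @export
#' @examples
#' bondi_radii()[["C"]]
bondi_radii <- function() {
  c(
    H = 1.20, He = 1.40, Li = 1.82, B = 1.92, C = 1.70, N = 1.55,
    O = 1.52, F = 1.47, Ne = 1.54, Na = 2.27, Mg = 1.73, Si = 2.10,
    P = 1.80, S = 1.80, Cl = 1.75, Ar = 1.88, K = 2.75, Ca = 2.31,
    Fe = 2.05, Ni = 1.63, Cu = 1.40, Zn = 1.39, Se = 1.90, Br = 1.85,
    I = 1.98
  )
}

#' Kyte-Doolittle hydropathy scale
#'
#' Per-residue hydropathy for the 20 standard amino acids, from +4.5 (Ile,
#' most hydrophobic) to -4.5 (Arg, most hydrophilic). Used to weight tunnel
#' hydrophobicity profiles.
#'
#' @return Named numeric vector, 3-letter residue code to hydropathy.
#' @export
#' @examples
#' kyte_doolittle()[["ILE"]]
kyte_doolittle <- function() {
  c(
    ILE = 4.5, VAL = 4.2, LEU = 3.8, PHE = 2.8, CYS = 2.5, MET = 1.9,
    ALA = 1.8, GLY = -0.4, THR = -0.7, SER = -0.8, TRP = -0.9,
    TYR = -1.3, PRO = -1.6, HIS = -3.2, GLU = -3.5, GLN = -3.5,
    ASP = -3.5, ASN = -3.5, LYS = -3.9, ARG = -4.5
  )
}

#' Look up hydropathy values for residues
#'
#' @param residue Character vector of 3-letter residue codes.
#' @param scale Named numeric vector mapping codes to hydropathy values;
#'   defaults to the Kyte-Doolittle scale.
#' @return Numeric vector of hydropathy values. Unknown codes are an error,
#'   never a silent default.
#' @export
#' @examples
#' hydropathy(c("ILE", "ARG"))
hydropathy <- function(residue, scale = kyte_doolittle()) {
  residue <- toupper(residue)
  missing <- setdiff(unique(residue), names(scale))
  if (length(missing) > 0) {
    rlang::abort(paste0(
      "unknown residue code(s) in hydropathy scale: ",
      paste(missing, collapse = ", ")
    ))
  }
  unname(scale[residue])
}

# required columns of an atom table
.atom_cols <- c(
  "serial", "name", "element", "resname", "resseq", "chain",
  "x", "y", "z", "vdw_radius"
)

check_structure <- function(structure, require_radii = TRUE, arg = "structure") {
  if (!is.data.frame(structure)) {
    rlang::abort(paste0("`", arg, "` must be a data frame of atom records"))
  }
  need <- if (require_radii) .atom_cols else setdiff(.atom_cols, "vdw_radius")
  miss <- setdiff(need, names(structure))
  if (length(miss) > 0) {
    rlang::abort(paste0(
      "`", arg, "` is missing atom column(s): ", paste(miss, collapse = ", ")
    ))
  }
  if (nrow(structure) == 0) {
    rlang::abort(paste0("`", arg, "` contains no atoms"))
  }
  if (!all(is.finite(structure$x) & is.finite(structure$y) & is.finite(structure$z))) {
    rlang::abort(paste0("`", arg, "` has non-finite coordinates"))
  }
  if (require_radii && !all(is.finite(structure$vdw_radius) & structure$vdw_radius > 0)) {
    rlang::abort(paste0("`", arg, "` has missing or nonpositive vdW radii"))
  }
  invisible(structure)
}

coords <- function(structure) {
  cbind(structure$x, structure$y, structure$z)
}

# Derive an element symbol from a fixed-column atom name, for records that
# leave columns 77-78 blank. Leading digits (e.g. "1HB1") are stripped;
# two-letter elements are only inferred when the name starts in column 13.
guess_element <- function(name_raw) {
  nm <- gsub("[0-9']", "", name_raw)
  first <- substr(trimws(nm), 1, 1)
  toupper(first)
}

#' Read a PDB file into an atom table
#'
#' Parses fixed-column ATOM/HETATM records (PDB v3.3). All other record
#' types are ignored. Alternate locations other than blank or 'A' are
#' skipped. Van der Waals radii are assigned from the element via
#' `radius_table` at read time.
#'
#' @param file Path to a PDB file, or a character vector of PDB lines.
#' @param radius_table Named element-to-radius vector; see [bondi_radii()].
#' @param model For multi-model files, which MODEL to return (default 1).
#' @return A tibble with one row per atom: `serial`, `name`, `element`,
#'   `resname`, `resseq`, `chain`, `x`, `y`, `z` (angstroms), `vdw_radius`.
#' @seealso [write_pdb()], [read_pdb_trajectory()]
#' @export
read_pdb <- function(file, radius_table = bondi_radii(), model = 1L) {
  lines <- if (length(file) == 1 && file.exists(file)) readLines(file) else file
  parsed <- parse_pdb_lines(lines)
  if (length(parsed$models) == 0) {
    # no MODEL records: the whole file is one model
    atoms <- parsed$atoms
  } else {
    keep <- parsed$atoms$.model == model
    atoms <- parsed$atoms[keep, , drop = FALSE]
  }
  atoms$.model <- NULL
  if (nrow(atoms) == 0) {
    rlang::abort("no ATOM/HETATM records found")
  }
  assign_vdw_radii(tibble::as_tibble(atoms), radius_table)
}

#' Read a multi-model PDB file as a ligand/trajectory frame table
#'
#' Each MODEL block becomes one frame. Files without MODEL records yield a
#' single frame.
#'
#' @inheritParams read_pdb
#' @return A tibble of atom records with an extra leading `frame` column.
#' @export
read_pdb_trajectory <- function(file, radius_table = bondi_radii()) {
  lines <- if (length(file) == 1 && file.exists(file)) readLines(file) else file
  parsed <- parse_pdb_lines(lines)
  atoms <- parsed$atoms
  if (nrow(atoms) == 0) {
    rlang::abort("no ATOM/HETATM records found")
  }
  if (length(parsed$models) == 0) atoms$.model <- 1L
  atoms <- tibble::as_tibble(atoms)
  names(atoms)[names(atoms) == ".model"] <- "frame"
  atoms <- atoms[, c("frame", setdiff(names(atoms), "frame"))]
  assign_vdw_radii(atoms, radius_table)
}

parse_pdb_lines <- function(lines) {
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM") |
    trimws(rec) %in% c("ATOM", "HETATM")
  is_model <- startsWith(lines, "MODEL")
  model_of_line <- cumsum(is_model)
  models <- which(is_model)
  idx <- which(is_atom)
  if (length(idx) == 0) {
    return(list(
      atoms = data.frame(
        serial = integer(), name = character(), element = character(),
        resname = character(), resseq = integer(), chain = character(),
        x = double(), y = double(), z = double(), .model = integer()
      ),
      models = models
    ))
  }
  ln <- lines[idx]
  altloc <- substr(ln, 17, 17)
  keep <- altloc %in% c(" ", "", "A")
  idx <- idx[keep]
  ln <- ln[keep]

  num_field <- function(txt, what) {
    out <- suppressWarnings(as.numeric(txt))
    bad <- which(is.na(out) | trimws(txt) == "")
    if (length(bad) > 0) {
      rlang::abort(paste0(
        "malformed ", what, " field at line ", idx[bad[1]],
        ": '", trimws(txt[bad[1]]), "'"
      ))
    }
    out
  }

  element <- trimws(substr(ln, 77, 78))
  no_el <- element == ""
  if (any(no_el)) {
    element[no_el] <- guess_element(substr(ln[no_el], 13, 16))
  }
  # canonical capitalisation: first letter upper, second lower
  element <- paste0(
    toupper(substr(element, 1, 1)),
    tolower(substr(element, 2, 2))
  )

  atoms <- data.frame(
    serial = as.integer(num_field(substr(ln, 7, 11), "serial")),
    name = trimws(substr(ln, 13, 16)),
    element = element,
    resname = trimws(substr(ln, 18, 20)),
    resseq = as.integer(num_field(substr(ln, 23, 26), "residue number")),
    chain = substr(ln, 22, 22),
    x = num_field(substr(ln, 31, 38), "x-coordinate"),
    y = num_field(substr(ln, 39, 46), "y-coordinate"),
    z = num_field(substr(ln, 47, 54), "z-coordinate"),
    .model = pmax(model_of_line[idx], 1L),
    stringsAsFactors = FALSE
  )
  if (any(atoms$resname == "")) {
    rlang::abort(paste0(
      "empty residue name at line ", idx[which(atoms$resname == "")[1]]
    ))
  }
  list(atoms = atoms, models = models)
}

#' Write an atom table as fixed-column PDB records
#'
#' Coordinates are written to 3 decimals, so a [read_pdb()] round trip
#' preserves every atom field at that precision.
#'
#' @param structure Atom table (see [read_pdb()]).
#' @param file Output path. If `NULL`, the lines are returned invisibly
#'   instead of written.
#' @param frames Optional `frame` column handling: when the table has a
#'   `frame` column, each frame is wrapped in MODEL/ENDMDL records.
#' @return Invisibly, the character vector of PDB lines.
#' @export
write_pdb <- function(structure, file = NULL, frames = "frame" %in% names(structure)) {
  check_structure(structure, require_radii = FALSE)
  bad <- abs(coords(structure)) >= 1e5
  if (any(bad)) {
    rlang::abort("coordinate magnitude >= 1e5 angstroms overflows PDB columns")
  }
  fmt_one <- function(df) {
    # atom names starting in column 14 for 1-3 char names (PDB convention)
    nm <- ifelse(nchar(df$name) < 4, paste0(" ", df$name), df$name)
    sprintf(
      "ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
      df$serial, nm, df$resname, df$chain, df$resseq,
      df$x, df$y, df$z, toupper(df$element)
    )
  }
  if (frames) {
    parts <- lapply(split(structure, structure$frame), function(df) {
      c(sprintf("MODEL     %4d", df$frame[1]), fmt_one(df), "ENDMDL")
    })
    lines <- c(unlist(parts, use.names = FALSE), "END")
  } else {
    lines <- c(fmt_one(structure), "END")
  }
  if (!is.null(file)) writeLines(lines, file)
  invisible(lines)
}

#' Assign van der Waals radii from an element table
#'
#' @param structure Atom table; the `element` column is used for lookup.
#' @param radius_table Named element-to-radius vector (angstroms).
#' @return The structure with its `vdw_radius` column (re)filled.
#'   Elements absent from the table are an error listing the offending
#'   atoms.
#' @export
assign_vdw_radii <- function(structure, radius_table = bondi_radii()) {
  check_structure(structure, require_radii = FALSE)
  el <- structure$element
  known <- el %in% names(radius_table)
  if (!all(known)) {
    off <- structure[!known, , drop = FALSE]
    rlang::abort(paste0(
      "no vdW radius for element(s): ",
      paste(unique(off$element), collapse = ", "),
      " (atom serial ", paste(utils::head(off$serial, 5), collapse = ", "), ")"
    ))
  }
  structure$vdw_radius <- unname(radius_table[el])
  tibble::as_tibble(structure)
}

#' Per-residue index of a structure
#'
#' @param structure Atom table.
#' @return Tibble with one row per residue (`chain`, `resseq`, `resname`,
#'   `n_atoms`); the residue grouping partitions the atoms exactly.
#' @export
residue_index <- function(structure) {
  check_structure(structure, require_radii = FALSE)
  dplyr::count(
    structure, .data$chain, .data$resseq, .data$resname,
    name = "n_atoms"
  )
}

#' Read an element-to-radius table from a two-column text file
#'
#' Columns: element symbol and radius in angstroms, whitespace- or
#' tab-separated; lines starting with `#` are comments.
#'
#' @param file Path to the table.
#' @return Named numeric vector usable as a `radius_table`.
#' @export
read_radius_table <- function(file) {
  tbl <- utils::read.table(file, col.names = c("element", "radius"),
                           comment.char = "#", stringsAsFactors = FALSE)
  if (any(!is.finite(tbl$radius) | tbl$radius <= 0)) {
    rlang::abort("radii must be positive numbers")
  }
  stats::setNames(tbl$radius, tbl$element)
}
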