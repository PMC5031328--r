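#' Read a PDB file into chain structures
#'
#' Minimal fixed-column reader for PDB coordinate files. Only `ATOM` records
#' are kept (`HETATM`, waters and ligands are ignored); alternate locations
#' are resolved by keeping the blank or `'A'` altloc, first occurrence wins;
#' for multi-model (NMR-style) files one model is selected. Residue
#' three-letter names are mapped to one-letter codes, unknowns to `"X"`.
#'
#' @param path Path to a PDB-format text file.
#' @param model_index 1-based model to read from a multi-model file
#'   (default 1). Files without `MODEL` records are treated as one model.
#' @return Named list of [chain_structure()] objects, one per chain id, in
#'   order of first appearance.
#' @seealso [write_pdb()]
#' @export
read_pdb <- function(path, model_index = 1L) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readLines(path, warn = FALSE)

  # model selection: slice between the model_index-th MODEL and its ENDMDL
  model_starts <- grep("^MODEL", lines)
  if (length(model_starts) > 0) {
    if (model_index > length(model_starts)) {
      abort(sprintf("model %d requested but file has %d model(s)",
                    model_index, length(model_starts)))
    }
    start <- model_starts[model_index]
    ends <- grep("^ENDMDL", lines)
    end <- ends[ends > start][1]
    if (is.na(end)) end <- length(lines)
    lines <- lines[start:end]
  } else if (model_index != 1L) {
    abort("file has a single implicit model; model_index must be 1")
  }

  is_atom <- startsWith(lines, "ATOM  ") | startsWith(lines, "ATOM ")
  atom_lines <- lines[is_atom]
  atom_lineno <- which(is_atom)
  if (length(atom_lines) == 0) {
    abort("empty structure: no ATOM records in the selected model")
  }

  bad <- which(nchar(atom_lines) < 54)
  if (length(bad) > 0) {
    abort(sprintf("format error: ATOM record too short at line %d",
                  atom_lineno[bad[1]]))
  }
  sub_ <- function(a, b) substr(atom_lines, a, b)
  x <- suppressWarnings(as.numeric(sub_(31, 38)))
  y <- suppressWarnings(as.numeric(sub_(39, 46)))
  z <- suppressWarnings(as.numeric(sub_(47, 54)))
  resno <- suppressWarnings(as.integer(sub_(23, 26)))
  bad <- which(is.na(x) | is.na(y) | is.na(z) | is.na(resno))
  if (length(bad) > 0) {
    abort(sprintf("format error: unparseable ATOM record at line %d",
                  atom_lineno[bad[1]]))
  }

  atoms <- tibble(
    serial    = suppressWarnings(as.integer(sub_(7, 11))),
    atom_name = trimws(sub_(13, 16)),
    altloc    = sub_(17, 17),
    resname   = trimws(sub_(18, 20)),
    chain_id  = sub_(22, 22),
    resno     = resno,
    icode     = sub_(27, 27),
    x = x, y = y, z = z,
    element   = trimws(substr(paste0(atom_lines,
                                     strrep(" ", 80)), 77, 78))
  )

  # altloc: keep blank or 'A'; among those, first occurrence of each atom wins
  atoms <- atoms[atoms$altloc %in% c(" ", "", "A"), , drop = FALSE]
  atoms <- atoms[!duplicated(atoms[, c("chain_id", "resno", "icode",
                                       "atom_name")]), , drop = FALSE]
  if (nrow(atoms) == 0) {
    abort("empty structure: no usable ATOM records after altloc filtering")
  }

  chains <- unique(atoms$chain_id)
  out <- lapply(chains, function(cid) {
    a <- atoms[atoms$chain_id == cid, , drop = FALSE]
    key <- paste(a$resno, a$icode)
    a$res_index <- as.integer(match(key, unique(key)) - 1L)
    a$aa <- unname(AA3TO1[a$resname])
    a$aa[is.na(a$aa)] <- "X"
    chain_structure(cid, a[, c("serial", "atom_name", "element", "resno",
                               "res_index", "aa", "x", "y", "z")])
  })
  names(out) <- chains
  out
}

#' Write a complex or chain to a PDB file
#'
#' Writes fixed-column `ATOM` records (occupancy 1.00, B-factor 0.00), a
#' `TER` after each chain and a final `END`. Coordinates are written with 3
#' decimals, so a read/write round trip preserves them to 0.001 Angstrom and
#' the residue sequence exactly.
#'
#' @param x A [complex_structure()] or [chain_structure()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(x, path) {
  chains <- if (inherits(x, "complex_structure")) {
    c(list(x$receptor), if (!is.null(x$peptide)) list(x$peptide))
  } else if (inherits(x, "chain_structure")) {
    list(x)
  } else {
    abort("x must be a complex_structure or chain_structure")
  }
  con <- tryCatch(file(path, "w"),
                  error = function(e) abort(paste0("cannot write: ", path)))
  on.exit(close(con))
  serial <- 0L
  for (ch in chains) {
    a <- ch$atoms
    for (i in seq_len(nrow(a))) {
      serial <- serial + 1L
      nm <- a$atom_name[i]
      # PDB atom-name column convention: 1-letter elements start in column 14
      nm_fmt <- if (nchar(nm) < 4) sprintf(" %-3s", nm) else nm
      writeLines(sprintf(
        "ATOM  %5d %4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        serial, nm_fmt, " ", AA1TO3[[residue_aa(a$aa[i])]], ch$chain_id,
        a$resno[i], " ", a$x[i], a$y[i], a$z[i], 1, 0, a$element[i]), con)
    }
    writeLines(sprintf("TER   %5d      %3s %1s%4d",
                       serial + 1L, AA1TO3[[residue_aa(a$aa[nrow(a)])]],
                       ch$chain_id, a$resno[nrow(a)]), con)
    serial <- serial + 1L
  }
  writeLines("END", con)
  invisible(path)
}

residue_aa <- function(aa) if (aa %in% names(AA1TO3)) aa else "X"
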