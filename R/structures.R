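#' Chain and complex containers
#'
#' A `chain_structure` holds one polypeptide chain as a tibble of atom
#' records; a `complex_structure` pairs a receptor (PDZ domain) chain with an
#' optional bound peptide chain. These two objects are the unit of all
#' geometry in the package: superposition, grafting, contact detection and
#' scoring all operate on them.
#'
#' The atom table has one row per atom with columns `serial`, `atom_name`,
#' `element`, `resno` (residue number as in the source PDB file), `res_index`
#' (0-based internal residue index, strictly increasing along the chain),
#' `aa` (one-letter code, `"X"` for nonstandard residues) and Cartesian
#' coordinates `x`, `y`, `z` in Angstroms.
#'
#' @param chain_id Single-character chain identifier.
#' @param atoms Tibble/data frame of atom records (see Details).
#' @param receptor A `chain_structure` for the PDZ domain.
#' @param peptide Optional `chain_structure` for the bound peptide, or `NULL`
#'   for an apo structure.
#' @param pdz_id Optional identifier stored on the complex and propagated to
#'   binding scores.
#' @return `chain_structure()` and `complex_structure()` return validated
#'   objects of the corresponding class.
#' @examples
#' toy <- make_toy_complex(n_receptor_residues = 8, peptide_seq = "FETLV")
#' n_residues(toy$receptor)
#' chain_sequence(toy$peptide)
#' @name structures
NULL

#' @rdname structures
#' @export
chain_structure <- function(chain_id, atoms) {
  atoms <- as_tibble(atoms)
  needed <- c("serial", "atom_name", "element", "resno", "res_index",
              "aa", "x", "y", "z")
  missing_cols <- setdiff(needed, names(atoms))
  if (length(missing_cols) > 0) {
    abort(paste0("atom table is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (nrow(atoms) == 0) abort("chain must contain at least one atom")
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
    abort("all atom coordinates must be finite")
  }
  if (any(!nzchar(atoms$atom_name))) abort("atom names must be non-empty")
  if (!all(atoms$aa %in% c(AA20, "X"))) {
    abort("residue codes must be one-letter amino acids or 'X'")
  }
  idx <- unique(atoms$res_index)
  if (!identical(as.integer(idx), seq_along(idx) - 1L)) {
    abort("res_index must run 0,1,2,... in order of appearance")
  }
  structure(
    list(chain_id = as.character(chain_id), atoms = atoms),
    class = "chain_structure"
  )
}

#' @rdname structures
#' @export
complex_structure <- function(receptor, peptide = NULL, pdz_id = NULL) {
  stopifnot(inherits(receptor, "chain_structure"))
  if (!is.null(peptide)) {
    stopifnot(inherits(peptide, "chain_structure"))
    if (n_residues(peptide) < 1) abort("peptide chain must be non-empty")
  }
  structure(
    list(receptor = receptor, peptide = peptide, pdz_id = pdz_id),
    class = "complex_structure"
  )
}

#' @rdname structures
#' @export
n_residues <- function(chain) {
  stopifnot(inherits(chain, "chain_structure"))
  length(unique(chain$atoms$res_index))
}

#' One-letter sequence of a chain
#'
#' @param chain A `chain_structure`.
#' @return A single string, one letter per residue (`"X"` for nonstandard
#'   residues), in `res_index` order.
#' @examples
#' toy <- make_toy_complex(peptide_seq = "FETLV")
#' chain_sequence(toy$peptide)  # "FETLV"
#' @export
chain_sequence <- function(chain) {
  stopifnot(inherits(chain, "chain_structure"))
  res <- residue_table(chain)
  if (nrow(res) == 0) abort("chain is empty")
  paste(res$aa, collapse = "")
}

# One row per residue, in res_index order.
residue_table <- function(chain) {
  chain$atoms %>%
    distinct(.data$res_index, .data$resno, .data$aa) %>%
    arrange(.data$res_index)
}

# n_atoms x 3 coordinate matrix, optionally restricted to one atom name
# (e.g. "CA") or a residue index subset.
atom_coords <- function(chain, atom_name = NULL, res_index = NULL) {
  a <- chain$atoms
  if (!is.null(atom_name)) a <- a[a$atom_name %in% atom_name, , drop = FALSE]
  if (!is.null(res_index)) a <- a[a$res_index %in% res_index, , drop = FALSE]
  as.matrix(a[, c("x", "y", "z")])
}

#' @export
print.chain_structure <- function(x, ...) {
  cat(sprintf("<chain_structure> chain %s: %d residues, %d atoms\n",
              x$chain_id, n_residues(x), nrow(x$atoms)))
  cat(" ", chain_sequence(x), "\n")
  invisible(x)
}

#' @export
print.complex_structure <- function(x, ...) {
  cat("<complex_structure>\n")
  if (!is.null(x$pdz_id)) cat("  pdz_id:", x$pdz_id, "\n")
  cat(sprintf("  receptor: chain %s, %d residues\n",
              x$receptor$chain_id, n_residues(x$receptor)))
  if (is.null(x$peptide)) {
    cat("  peptide: absent (apo)\n")
  } else {
    cat(sprintf("  peptide: chain %s, %s\n",
                x$peptide$chain_id, chain_sequence(x$peptide)))
  }
  invisible(x)
}
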