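#' Atom selections
#'
#' A `selection_spec` filters atoms by chain, author residue numbers, atom
#' names, and an atom-class flag. Resolution against a structure is a pure
#' function: the same spec on the same structure always yields the same
#' ordered (possibly empty) index list, in topology order.
#'
#' Classes: `"all"` keeps every atom; `"heavy"` drops hydrogens (and
#' deuterium); `"backbone"` keeps N, CA, C, O; `"sidechain"` keeps heavy
#' atoms excluding the backbone four. HETATM records (cofactors, ions,
#' waters) are excluded from selections unless `include_het = TRUE` — the
#' protein-only convention of domain-motion descriptor analysis.
#'
#' @param chain optional chain identifier(s).
#' @param resno optional integer vector of author residue numbers (e.g.
#'   `42:48`); closed intervals are just ranges of this vector.
#' @param atom_names optional whitelist of atom names.
#' @param class atom-class flag, one of `"all"`, `"heavy"`, `"backbone"`,
#'   `"sidechain"`.
#' @param include_het keep HETATM records? Default `FALSE`.
#' @return an object of class `selection_spec`.
#' @examples
#' sp <- selection_spec(resno = 42:48, class = "heavy")
#' @export
selection_spec <- function(chain = NULL, resno = NULL, atom_names = NULL,
                           class = c("all", "heavy", "backbone", "sidechain"),
                           include_het = FALSE) {
  class <- match.arg(class)
  structure(list(chain = chain, resno = resno, atom_names = atom_names,
                 class = class, include_het = include_het),
            class = "selection_spec")
}

.backbone_names <- c("N", "CA", "C", "O")

#' Resolve a selection against a structure
#'
#' @param structure a `MolecularStructure`.
#' @param spec a [selection_spec()].
#' @return integer vector of atom indices (1-based, topology order); may be
#'   empty.
#' @export
resolve_selection <- function(structure, spec) {
  stopifnot(inherits(structure, "MolecularStructure"),
            inherits(spec, "selection_spec"))
  keep <- rep(TRUE, nrow(structure))
  if (!spec$include_het) keep <- keep & structure$record == "ATOM"
  if (!is.null(spec$chain)) keep <- keep & structure$chain %in% spec$chain
  if (!is.null(spec$resno)) keep <- keep & structure$resno %in% spec$resno
  if (!is.null(spec$atom_names)) keep <- keep & structure$atom_name %in% spec$atom_names
  heavy <- !(toupper(structure$element) %in% c("H", "D"))
  keep <- keep & switch(spec$class,
    all = TRUE,
    heavy = heavy,
    backbone = structure$atom_name %in% .backbone_names,
    sidechain = heavy & !(structure$atom_name %in% .backbone_names))
  which(keep)
}

#' @rdname resolve_selection
#' @param ... passed to [selection_spec()].
#' @export
atom_select <- function(structure, ...) {
  resolve_selection(structure, selection_spec(...))
}

#' Preset inter-domain distance selections
#'
#' The three descriptor distances used to monitor clamshell domain motion of
#' SMYD3-like methyltransferases: D1 spans the top of the substrate-binding
#' cleft (MYND-domain residues 42-48 vs CTD residues 298-302), D2 the bottom
#' (SET-domain residues 209-227 vs CTD residues 363-365), and D3 the
#' lysine-access channel width (sidechain centroids of residues 183 and 239).
#' D1/D2 use heavy atoms; D3 uses the sidechain class (heavy atoms excluding
#' the backbone four).
#'
#' @param chain optional chain restriction applied to both groups.
#' @return named list of lists with elements `a` and `b` (two
#'   [selection_spec()]s each).
#' @export
preset_distance_selections <- function(chain = NULL) {
  list(
    d1 = list(a = selection_spec(chain, 42:48,   class = "heavy"),
              b = selection_spec(chain, 298:302, class = "heavy")),
    d2 = list(a = selection_spec(chain, 209:227, class = "heavy"),
              b = selection_spec(chain, 363:365, class = "heavy")),
    d3 = list(a = selection_spec(chain, 183, class = "sidechain"),
              b = selection_spec(chain, 239, class = "sidechain"))
  )
}
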