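#' A single residue-range selection
#'
#' @param chain Chain identifier(s).
#' @param resno Integer vector of author residue numbers to keep, or `NULL`
#'   for all residues of the chain. Plain integers match any insertion code.
#' @param atom_class One of `"carbonyl_C"` (backbone C only), `"CA"`, `"CB"`,
#'   `"backbone"` (N, CA, C, O), `"all"`.
#' @param name Label used in messages and outputs.
#' @return A `sel_entry` list.
#' @export
sel_entry <- function(chain, resno = NULL, atom_class = "carbonyl_C",
                      name = NULL) {
  atom_class <- match.arg(atom_class,
                          c("carbonyl_C", "CA", "CB", "backbone", "all"))
  structure(list(chain = chain,
                 resno = if (is.null(resno)) NULL else as.integer(resno),
                 atom_class = atom_class,
                 name = name %||% paste0(paste(chain, collapse = "+"))),
            class = "sel_entry")
}

#' Named selections for a BAM-like complex
#'
#' Bundles the selections every metric needs: the BamA barrel (default
#' residues 425-810, the membrane-embedded 16-stranded domain), the accessory
#' lipoproteins BamB-E (one chain each), the POTRA5 domain (default 344-421,
#' immediately below the barrel) and the two lateral-seam strands (defaults
#' beta1 424-435 and beta16 800-810). All ranges are author numbering and
#' fully overridable; the defaults mirror the standard E. coli BamA
#' numbering.
#'
#' @param barrel_chain,barrel_resno Barrel chain and residue range.
#' @param accessory Named list mapping component name to chain id (may be a
#'   `sel_entry` for finer control); empty list for single-protein systems.
#' @param potra5_resno POTRA5 residue range (on the barrel chain).
#' @param seam1_resno,seam16_resno Seam strand ranges (on the barrel chain).
#' @return A `complex_selection` list with entries `barrel`, `accessory`,
#'   `potra5`, `seam1`, `seam16`.
#' @export
complex_selection <- function(barrel_chain = "A",
                              barrel_resno = 425:810,
                              accessory = list(BamB = "B", BamC = "C",
                                               BamD = "D", BamE = "E"),
                              potra5_resno = 344:421,
                              seam1_resno = 424:435,
                              seam16_resno = 800:810) {
  acc <- lapply(names(accessory), function(nm) {
    a <- accessory[[nm]]
    if (inherits(a, "sel_entry")) a
    else sel_entry(chain = a, resno = NULL, atom_class = "carbonyl_C",
                   name = nm)
  })
  names(acc) <- names(accessory)
  structure(list(
    barrel = sel_entry(barrel_chain, barrel_resno, "carbonyl_C", "barrel"),
    accessory = acc,
    potra5 = sel_entry(barrel_chain, potra5_resno, "CA", "POTRA5"),
    seam1 = sel_entry(barrel_chain, seam1_resno, "backbone", "seam_beta1"),
    seam16 = sel_entry(barrel_chain, seam16_resno, "backbone", "seam_beta16")),
    class = "complex_selection")
}

atom_class_filter <- function(atoms, atom_class) {
  switch(atom_class,
         carbonyl_C = atoms == "C",
         CA = atoms == "CA",
         CB = atoms == "CB",
         backbone = atoms %in% c("N", "CA", "C", "O"),
         all = rep(TRUE, length(atoms)))
}

#' Select atoms from a model
#'
#' Atoms come back in model order. Residues absent from the model are simply
#' skipped (deposited structures have gaps); an entirely empty selection is
#' an error.
#'
#' @param model A [structure_model()].
#' @param entry A [sel_entry()], or a `complex_selection` component name
#'   resolved against `selection`.
#' @return The selected atoms, still a `structure_model` tibble subset.
#' @export
select_atoms <- function(model, entry) {
  stopifnot(inherits(entry, "sel_entry"))
  keep <- model$chain %in% entry$chain
  if (!is.null(entry$resno)) keep <- keep & model$resno %in% entry$resno
  keep <- keep & atom_class_filter(model$atom, entry$atom_class)
  out <- model[keep, , drop = FALSE]
  if (nrow(out) == 0L) {
    stop(sprintf(
      "select_atoms: empty selection '%s' (chain %s, %s residues, class %s)",
      entry$name, paste(entry$chain, collapse = "/"),
      if (is.null(entry$resno)) "all"
      else sprintf("%d-%d", min(entry$resno), max(entry$resno)),
      entry$atom_class), call. = FALSE)
  }
  out
}

#' Unweighted geometric center of an atom set
#'
#' @param atoms A `structure_model` subset (or any table with x, y, z).
#' @return Length-3 numeric vector, angstrom.
#' @export
geometric_center <- function(atoms) {
  if (nrow(atoms) == 0L) {
    stop("geometric_center: empty atom set", call. = FALSE)
  }
  c(x = mean(atoms$x), y = mean(atoms$y), z = mean(atoms$z))
}
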