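#' Inter-residue distance for disulfide-crosslink design
#'
#' Euclidean distance between one named atom of each residue. The default
#' atom class is C-beta, the standard proxy for whether two cysteines could
#' form a disulfide; glycines have no C-beta and fall back to C-alpha, which
#' is flagged on the result.
#'
#' @param model A [structure_model()].
#' @param a,b Residues, each `c(chain, resno)` (resno coerced to integer).
#' @param atom_class `"CB"` (with Gly fallback to CA) or `"CA"`.
#' @return Distance in angstrom; attribute `fallback` is `TRUE` if either
#'   side used the C-alpha fallback.
#' @export
pair_distance <- function(model, a, b, atom_class = c("CB", "CA")) {
  atom_class <- match.arg(atom_class)
  pick <- function(res) {
    chain <- res[[1L]]; resno <- as.integer(res[[2L]])
    rows <- model[model$chain == chain & model$resno == resno, , drop = FALSE]
    if (nrow(rows) == 0L) {
      stop(sprintf("pair_distance: residue %s%d not in model", chain, resno),
           call. = FALSE)
    }
    hit <- rows[rows$atom == atom_class, , drop = FALSE]
    fallback <- FALSE
    if (nrow(hit) == 0L && atom_class == "CB") {
      hit <- rows[rows$atom == "CA", , drop = FALSE]
      fallback <- TRUE
    }
    if (nrow(hit) == 0L) {
      stop(sprintf("pair_distance: residue %s%d has no %s atom",
                   chain, resno, atom_class), call. = FALSE)
    }
    list(xyz = c(hit$x[1L], hit$y[1L], hit$z[1L]), fallback = fallback)
  }
  pa <- pick(a); pb <- pick(b)
  structure(sqrt(sum((pa$xyz - pb$xyz)^2)),
            fallback = pa$fallback || pb$fallback)
}

#' Screen residue pairs against conformational states
#'
#' For each candidate cysteine pair and each state structure, measures the
#' inter-residue distance and classifies it: `compatible` (a disulfide
#' could form and lock the state) at or below `compatible_max`,
#' `incompatible` at or above `incompatible_min`, `marginal` between. A
#' pair designed to lock a state should be compatible in that state and
#' incompatible in the other - the conformation-specific pairs reported
#' for BamA sit 15-23 A apart in their opposite conformation.
#'
#' @param models Named list of [structure_model()]s, one per state.
#' @param pairs Tibble as produced by [bundled_mutant_panels()]: columns
#'   `pair`, `chain_a`, `resno_a`, `chain_b`, `resno_b`, and optionally
#'   `intended_state` and `panel`.
#' @param compatible_max,incompatible_min Classification thresholds,
#'   angstrom.
#' @param atom_class Passed to [pair_distance()].
#' @return Long tibble: one row per pair per state with `distance`,
#'   `classification`, `ca_fallback`.
#' @export
screen_pairs <- function(models, pairs, compatible_max = 7,
                         incompatible_min = 12, atom_class = "CB") {
  if (compatible_max > incompatible_min) {
    stop("screen_pairs: compatible_max must not exceed incompatible_min",
         call. = FALSE)
  }
  if (is.null(names(models)) || any(names(models) == "")) {
    stop("screen_pairs: models must be a named list of states",
         call. = FALSE)
  }
  pairs <- tibble::as_tibble(pairs)
  purrr::map_dfr(names(models), function(state) {
    purrr::pmap_dfr(pairs, function(...) {
      row <- list(...)
      d <- pair_distance(models[[state]],
                         c(row$chain_a, row$resno_a),
                         c(row$chain_b, row$resno_b),
                         atom_class = atom_class)
      tibble::tibble(
        pair = row$pair,
        panel = row$panel %||% NA_character_,
        intended_state = row$intended_state %||% NA_character_,
        state = state,
        distance = as.numeric(d),
        classification = classify_distance(d, compatible_max,
                                           incompatible_min),
        ca_fallback = attr(d, "fallback"))
    })
  })
}

classify_distance <- function(d, compatible_max, incompatible_min) {
  if (d <= compatible_max) "compatible"
  else if (d >= incompatible_min) "incompatible"
  else "marginal"
}

#' The reported BamA mutant crosslink panels
#'
#' The cysteine-pair panels used to probe BAM's conformational states,
#' returned as data ready for [screen_pairs()]:
#'
#' * `inward_lock`: S502C/V706C (extracellular loops 3 and 6) and
#'   G431C/G807C (lateral seam), designed to lock the inward-open state.
#' * `outward_lock`: D503C/N681C (loops 3 and 6) and S425C/K808C (lateral
#'   seam), designed to lock the outward-open state.
#' * `potra5_t4`: E396C/R583C and G393C/G584C, pinning POTRA5 to turn 4.
#' * `bama_espp`: BamA seam sites 806 and 807 crossed with EspP beta-9
#'   sites 1226, 1228, 1230, 1232, 1234 (10 pairs), used to trap the
#'   hybrid-barrel folding intermediate.
#'
#' @param panels Which panels to return (default all).
#' @param bama_chain,espp_chain Chain ids used for BamA and EspP residues.
#' @return Tibble with columns `panel`, `pair`, `chain_a`, `resno_a`,
#'   `chain_b`, `resno_b`, `intended_state`.
#' @export
bundled_mutant_panels <- function(panels = c("inward_lock", "outward_lock",
                                             "potra5_t4", "bama_espp"),
                                  bama_chain = "A", espp_chain = "S") {
  panels <- match.arg(panels, several.ok = TRUE)
  build <- function(panel, ra, rb, state, chain_b = bama_chain) {
    tibble::tibble(panel = panel,
                   pair = sprintf("%d/%d", ra, rb),
                   chain_a = bama_chain, resno_a = ra,
                   chain_b = chain_b, resno_b = rb,
                   intended_state = state)
  }
  out <- list(
    inward_lock = build("inward_lock", c(502L, 431L), c(706L, 807L),
                        "inward_open"),
    outward_lock = build("outward_lock", c(503L, 425L), c(681L, 808L),
                         "outward_open"),
    potra5_t4 = build("potra5_t4", c(396L, 393L), c(583L, 584L),
                      "outward_open"),
    bama_espp = {
      grid <- expand.grid(a = c(806L, 807L),
                          b = c(1226L, 1228L, 1230L, 1232L, 1234L))
      build("bama_espp", grid$a, grid$b, "hybrid_barrel",
            chain_b = espp_chain)
    })
  dplyr::bind_rows(out[panels])
}
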