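# Elements tracked by the formula arithmetic. Order fixed so that formulas
# print in Hill-like notation (C, H, then alphabetical).
.FORMULA_ELEMENTS <- c("C", "H", "N", "O", "S", "Na")

# Monoisotopic atomic masses (u). These constants define every mass the
# package reports; they are deliberately centralised and immutable.
.MONO_MASS <- c(
  C  = 12.0,
  H  = 1.0078250319,
  N  = 14.0030740052,
  O  = 15.9949146221,
  S  = 31.97207069,
  Na = 22.98976928
)

#' Physical constants used for adduct arithmetic
#'
#' The proton mass is already electron-corrected, so protonated adducts add
#' `z` protons directly. Sodiated adducts add the mass of Na minus one
#' electron (a sodium cation).
#' @keywords internal
.PROTON_MASS <- 1.00727646688
.ELECTRON_MASS <- 0.00054857990946

#' Construct a molecular formula
#'
#' A molecular formula is a named integer vector over the supported elements
#' (C, H, N, O, S, Na). Final formulas must have non-negative counts, but
#' intermediate deltas (e.g. a dehydration, `-H2O`) may be signed; pass
#' `allow_negative = TRUE` for those.
#'
#' @param ... element counts, e.g. `mol_formula(C = 2, H = 5, N = 1, O = 2)`.
#' @param allow_negative permit signed counts (modification deltas).
#' @return an object of class `mol_formula`.
#' @examples
#' mol_formula(H = 2, O = 1)  # water
#' @export
mol_formula <- function(..., allow_negative = FALSE) {
  counts <- c(...)
  if (length(counts) == 0L) counts <- integer(0)
  if (length(counts) &&
      (is.null(names(counts)) || any(names(counts) == ""))) {
    stop("mol_formula(): all counts must be named by element", call. = FALSE)
  }
  bad <- setdiff(names(counts), .FORMULA_ELEMENTS)
  if (length(bad)) {
    stop("mol_formula(): unknown element(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  full <- stats::setNames(numeric(length(.FORMULA_ELEMENTS)), .FORMULA_ELEMENTS)
  full[names(counts)] <- full[names(counts)] + counts
  if (any(full != round(full))) {
    stop("mol_formula(): counts must be integers", call. = FALSE)
  }
  if (!allow_negative && any(full < 0)) {
    stop("mol_formula(): negative element count", call. = FALSE)
  }
  structure(full, class = "mol_formula")
}

.as_formula <- function(x) {
  if (inherits(x, "mol_formula")) return(x)
  do.call(mol_formula, c(as.list(x), allow_negative = TRUE))
}

#' @export
`+.mol_formula` <- function(e1, e2) {
  out <- unclass(.as_formula(e1)) + unclass(.as_formula(e2))
  structure(out, class = "mol_formula")
}

#' @export
`-.mol_formula` <- function(e1, e2) {
  if (missing(e2)) {
    structure(-unclass(.as_formula(e1)), class = "mol_formula")
  } else {
    structure(unclass(.as_formula(e1)) - unclass(.as_formula(e2)),
              class = "mol_formula")
  }
}

#' @export
format.mol_formula <- function(x, ...) formula_string(x)

#' @export
print.mol_formula <- function(x, ...) {
  cat("<formula> ", formula_string(x), "  (", format(monoisotopic_mass(x), nsmall = 4),
      " u)\n", sep = "")
  invisible(x)
}

#' Render a formula as a Hill-notation string
#'
#' Zero counts are omitted; a count of one is written without a number;
#' negative counts (deltas) are rendered with a leading minus per element.
#'
#' @param f a `mol_formula`.
#' @return a single string such as `"C28H42N10O8"`.
#' @export
formula_string <- function(f) {
  f <- .as_formula(f)
  parts <- character(0)
  for (el in .FORMULA_ELEMENTS) {
    n <- f[[el]]
    if (n == 0) next
    parts <- c(parts, paste0(if (n < 0) "-" else "", el,
                             if (abs(n) != 1) abs(n) else ""))
  }
  if (!length(parts)) return("")
  paste(parts, collapse = "")
}

#' Monoisotopic mass of a formula
#'
#' Sum of element counts times monoisotopic atomic masses, in unified atomic
#' mass units (u), double precision.
#'
#' @param f a `mol_formula` (non-negative counts).
#' @return neutral monoisotopic mass in u.
#' @examples
#' monoisotopic_mass(mol_formula(H = 2, O = 1))  # 18.0105646
#' @export
monoisotopic_mass <- function(f) {
  f <- .as_formula(f)
  if (any(unclass(f) < 0)) {
    stop("monoisotopic_mass(): formula has negative element counts", call. = FALSE)
  }
  sum(unclass(f) * .MONO_MASS[.FORMULA_ELEMENTS])
}

# Residue formulas: amino acid minus one water (the residue as it appears in
# a peptide chain). The free linear peptide adds one H2O for its termini.
.RESIDUE_FORMULAS <- list(
  G = c(C = 2,  H = 3,  N = 1, O = 1),
  A = c(C = 3,  H = 5,  N = 1, O = 1),
  S = c(C = 3,  H = 5,  N = 1, O = 2),
  P = c(C = 5,  H = 7,  N = 1, O = 1),
  V = c(C = 5,  H = 9,  N = 1, O = 1),
  T = c(C = 4,  H = 7,  N = 1, O = 2),
  C = c(C = 3,  H = 5,  N = 1, O = 1, S = 1),
  L = c(C = 6,  H = 11, N = 1, O = 1),
  I = c(C = 6,  H = 11, N = 1, O = 1),
  N = c(C = 4,  H = 6,  N = 2, O = 2),
  D = c(C = 4,  H = 5,  N = 1, O = 3),
  Q = c(C = 5,  H = 8,  N = 2, O = 2),
  K = c(C = 6,  H = 12, N = 2, O = 1),
  E = c(C = 5,  H = 7,  N = 1, O = 3),
  M = c(C = 5,  H = 9,  N = 1, O = 1, S = 1),
  H = c(C = 6,  H = 7,  N = 3, O = 1),
  F = c(C = 9,  H = 9,  N = 1, O = 1),
  R = c(C = 6,  H = 12, N = 4, O = 1),
  Y = c(C = 9,  H = 9,  N = 1, O = 2),
  W = c(C = 11, H = 10, N = 2, O = 1)
)

#' Residue formula table
#'
#' One-letter residue code to residue formula (amino acid minus water).
#' @return named list of `mol_formula` objects for the 20 canonical residues.
#' @export
residue_table <- function() lapply(.RESIDUE_FORMULAS, function(x) do.call(mol_formula, as.list(x)))

#' Molecular formula of a linear peptide
#'
#' Sum of residue formulas plus one water for the free N- and C-termini.
#'
#' @param sequence one-letter amino-acid string (canonical residues only).
#' @return a `mol_formula`.
#' @examples
#' formula_string(peptide_formula("HLSATH"))  # "C28H44N10O9"
#' @export
peptide_formula <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L, nchar(sequence) > 0L)
  aa <- strsplit(sequence, "", fixed = TRUE)[[1]]
  unknown <- which(!aa %in% names(.RESIDUE_FORMULAS))
  if (length(unknown)) {
    stop(sprintf("peptide_formula(): unknown residue '%s' at position %d",
                 aa[unknown[1]], unknown[1]), call. = FALSE)
  }
  total <- c(C = 0, H = 2, N = 0, O = 1, S = 0)  # start from H2O
  for (r in aa) {
    rf <- .RESIDUE_FORMULAS[[r]]
    total[names(rf)] <- total[names(rf)] + rf
  }
  do.call(mol_formula, as.list(total))
}

# ---- Modifications ----------------------------------------------------------

.H2O <- c(H = -2, O = -1)

#' Default post-translational modification library
#'
#' Each modification carries a signed formula delta, a site rule (a predicate
#' over the candidate sequence deciding how many copies are chemically
#' placeable), and a per-candidate maximum count. The default library covers
#' the chemistry expected around azoline/azole-forming, amidine-forming
#' YcaO-domain enzymes and N-terminal acetylation:
#'
#' * `dehydration` — net loss of H2O. This is the generic backbone
#'   cyclodehydration; amidine-ring formation and azoline formation are
#'   mass-degenerate with it (all are net -H2O). By default they are *not*
#'   enumerated as separate entries: candidates instead flag the named
#'   alternatives whose site rules hold (see [enumerate_candidates()]), so
#'   the report never asserts chemistry that intact mass cannot distinguish.
#' * `azole` — cyclodehydration plus oxidation (-H2O -H2), requires a
#'   Ser/Thr/Cys at position >= 2.
#' * `dehydrogenation` — net -H2.
#' * `acetylation` — N-terminal acetylation (+C2H2O), requires a free
#'   N-terminus and is therefore exclusive with amidine-ring formation.
#'
#' With `collapse_degenerate = FALSE`, `amidine` (free N-terminus) and
#' `azoline` (Ser/Thr/Cys at position >= 2) are included as explicit entries.
#'
#' @param collapse_degenerate collapse -H2O chemistry into the single
#'   `dehydration` entry (default) or list `amidine`/`azoline` explicitly.
#' @return a named list of modification definitions.
#' @export
modification_library <- function(collapse_degenerate = TRUE) {
  mods <- list(
    dehydration = list(
      name = "dehydration",
      delta = mol_formula(H = -2, O = -1, allow_negative = TRUE),
      max_count = 3,
      needs_free_nterm = FALSE,
      # backbone condensation: needs at least count+1 residues
      sites = function(seq) nchar(seq) - 1L
    ),
    azole = list(
      name = "azole",
      delta = mol_formula(H = -4, O = -1, allow_negative = TRUE),
      max_count = 2,
      needs_free_nterm = FALSE,
      sites = function(seq) .n_stc_internal(seq)
    ),
    dehydrogenation = list(
      name = "dehydrogenation",
      delta = mol_formula(H = -2, allow_negative = TRUE),
      max_count = 2,
      needs_free_nterm = FALSE,
      sites = function(seq) nchar(seq) - 1L
    ),
    acetylation = list(
      name = "acetylation",
      delta = mol_formula(C = 2, H = 2, O = 1, allow_negative = TRUE),
      max_count = 1,
      needs_free_nterm = TRUE,
      sites = function(seq) 1L
    )
  )
  if (!collapse_degenerate) {
    mods$amidine <- list(
      name = "amidine",
      delta = mol_formula(H = -2, O = -1, allow_negative = TRUE),
      max_count = 1,
      needs_free_nterm = TRUE,
      sites = function(seq) if (nchar(seq) >= 2L) 1L else 0L
    )
    mods$azoline <- list(
      name = "azoline",
      delta = mol_formula(H = -2, O = -1, allow_negative = TRUE),
      max_count = 2,
      needs_free_nterm = FALSE,
      sites = function(seq) .n_stc_internal(seq)
    )
  }
  mods
}

# Ser/Thr/Cys residues at positions >= 2 (heterocyclisation onto the
# preceding backbone carbonyl).
.n_stc_internal <- function(seq) {
  aa <- strsplit(seq, "", fixed = TRUE)[[1]]
  if (length(aa) < 2L) return(0L)
  sum(aa[-1] %in% c("S", "T", "C"))
}

# Validate a modification multiset against a sequence; returns NULL when
# legal or a string describing the first violation.
.check_mods <- function(sequence, mods, library) {
  counts <- table(mods)
  nterm_claims <- 0L
  for (name in names(counts)) {
    mod <- library[[name]]
    if (is.null(mod)) return(sprintf("unknown modification '%s'", name))
    n <- as.integer(counts[[name]])
    if (n > mod$max_count) {
      return(sprintf("modification '%s' exceeds max_count %d", name, mod$max_count))
    }
    if (n > mod$sites(sequence)) {
      return(sprintf("modification '%s' has no remaining site on '%s'", name, sequence))
    }
    if (mod$needs_free_nterm) nterm_claims <- nterm_claims + 1L
  }
  if (nterm_claims > 1L) {
    return("modifications competing for the free N-terminus are mutually exclusive")
  }
  NULL
}

#' Apply a modification multiset to a peptide formula
#'
#' Adds the signed formula deltas of each modification after verifying the
#' site rules: each modification must have enough placeable sites on the
#' sequence, respect its `max_count`, and at most one modification may claim
#' the free N-terminus.
#'
#' @param sequence the peptide (used only for site-rule checks).
#' @param formula the unmodified peptide formula, e.g. [peptide_formula()].
#' @param mods character vector naming modifications, with repeats for
#'   multiple copies (e.g. `c("dehydration", "dehydration")`).
#' @param library a modification library, see [modification_library()].
#' @return the modified `mol_formula`.
#' @examples
#' f <- apply_modifications("HLSATH", peptide_formula("HLSATH"), "dehydration")
#' formula_string(f)  # "C28H42N10O8"
#' @export
apply_modifications <- function(sequence, formula, mods,
                                library = modification_library()) {
  if (length(mods) == 0L) return(.as_formula(formula))
  err <- .check_mods(sequence, mods, library)
  if (!is.null(err)) stop("apply_modifications(): ", err, call. = FALSE)
  out <- .as_formula(formula)
  for (name in mods) out <- out + library[[name]]$delta
  if (any(unclass(out) < 0)) {
    stop("apply_modifications(): modifications drive an element count negative",
         call. = FALSE)
  }
  out
}

# ---- Adducts ----------------------------------------------------------------

#' Supported MS adducts
#'
#' `[M+H]+` and `[M+2H]2+` add one or two protons (proton mass is already
#' electron-corrected); `[M+Na]+` adds a sodium cation (Na minus one
#' electron).
#'
#' @return data.frame with columns `name`, `charge`, `shift` (mass added to
#'   the neutral molecule before dividing by charge).
#' @export
adduct_table <- function() {
  data.frame(
    name = c("[M+H]+", "[M+2H]2+", "[M+Na]+"),
    charge = c(1L, 2L, 1L),
    shift = c(.PROTON_MASS, 2 * .PROTON_MASS,
              .MONO_MASS[["Na"]] - .ELECTRON_MASS),
    stringsAsFactors = FALSE
  )
}

#' m/z of a neutral mass under an adduct
#'
#' @param neutral_mass neutral monoisotopic mass in u.
#' @param adduct adduct name: one of `"[M+H]+"`, `"[M+2H]2+"`, `"[M+Na]+"`.
#' @return m/z = (neutral mass + shift) / charge.
#' @examples
#' mz(monoisotopic_mass(peptide_formula("HLSATH") -
#'    mol_formula(H = 2, O = 1)), "[M+H]+")  # 647.3260
#' @export
mz <- function(neutral_mass, adduct = "[M+H]+") {
  stopifnot(neutral_mass > 0)
  tab <- adduct_table()
  i <- match(adduct, tab$name)
  if (is.na(i)) {
    stop("mz(): unknown adduct '", adduct, "'; supported: ",
         paste(tab$name, collapse = ", "), call. = FALSE)
  }
  (neutral_mass + tab$shift[i]) / tab$charge[i]
}

#' ppm error between an observed and theoretical m/z
#' @param observed,theoretical m/z values.
#' @return (observed - theoretical) / theoretical * 1e6.
#' @export
ppm_error <- function(observed, theoretical) {
  (observed - theoretical) / theoretical * 1e6
}
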