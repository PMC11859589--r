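#' @import methods
NULL

# Monoisotopic masses of the principal isotopes, loaded once from the packaged
# constants table (inst/extdata/atomic_masses.tsv). Values follow the CODATA /
# AME compilations at sub-mDa accuracy, which is what glycoside rule matching
# at <=10 ppm requires.
.mass_env <- new.env(parent = emptyenv())

.atomicMasses <- function() {
  if (is.null(.mass_env$masses)) {
    path <- system.file("extdata", "atomic_masses.tsv", package = "cerealmet",
                        mustWork = TRUE)
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    m <- tab$mass
    names(m) <- tab$element
    .mass_env$masses <- m
  }
  .mass_env$masses
}

#' Mass of the proton in Da
#'
#' Used for `[M+H]+` / `[M-H]-` ion arithmetic. The electron mass is not
#' tracked separately; the difference (~0.5 mDa) is far below the matching
#' tolerances used anywhere in the package.
#'
#' @return Proton mass in Da.
#' @export
protonMass <- function() {
  unname(.atomicMasses()[["proton"]])
}

#' Molecular formula with element counts
#'
#' An elemental composition: a named integer vector of non-negative counts,
#' stored in Hill order (C, H, then alphabetical). Formulas support `+` and
#' `-`; subtraction that would drive any element negative is an error, which
#' is what guarantees that fragmentation rules only ever subtract losses that
#' are actually contained in the precursor composition.
#'
#' @slot counts Named integer vector of element counts.
#' @export
setClass("MolecularFormula", representation(counts = "integer"))

setValidity("MolecularFormula", function(object) {
  cnt <- object@counts
  if (length(cnt) && is.null(names(cnt)))
    return("counts must be named by element symbol")
  if (any(is.na(cnt)) || any(cnt < 0L))
    return("element counts must be non-negative integers")
  if (anyDuplicated(names(cnt)))
    return("duplicated element symbol")
  TRUE
})

.hillOrder <- function(counts) {
  els <- names(counts)
  rest <- sort(setdiff(els, c("C", "H")))
  ord <- c(intersect(c("C", "H"), els), rest)
  counts[ord]
}

.newFormula <- function(counts) {
  counts <- counts[counts != 0L]
  new("MolecularFormula", counts = .hillOrder(counts))
}

#' Parse a molecular formula string
#'
#' Accepts Hill-notation strings such as `"C9H9NO4"`. Element symbols must be
#' present in the packaged atomic-mass table; anything else is rejected with
#' an error naming the offending token.
#'
#' @param text Formula string. `""` yields the empty formula.
#' @return A [MolecularFormula-class] object.
#' @examples
#' parseFormula("C8H7NO4")
#' @export
parseFormula <- function(text) {
  stopifnot(is.character(text), length(text) == 1L, !is.na(text))
  text <- trimws(text)
  if (text == "" || text == "0")
    return(.newFormula(integer(0)))
  masses <- .atomicMasses()
  known <- setdiff(names(masses), "proton")
  m <- gregexpr("[A-Z][a-z]?[0-9]*", text)[[1]]
  tokens <- regmatches(text, list(m))[[1]]
  if (sum(attr(m, "match.length")) != nchar(text))
    stop("malformed formula string: ", sQuote(text))
  counts <- integer(0)
  for (tok in tokens) {
    el <- sub("[0-9]*$", "", tok)
    if (!el %in% known)
      stop("unknown element ", sQuote(el), " in formula ", sQuote(text))
    n <- sub("^[A-Za-z]+", "", tok)
    n <- if (n == "") 1L else as.integer(n)
    counts[el] <- (if (el %in% names(counts)) counts[[el]] else 0L) + n
  }
  .newFormula(counts)
}

#' Format a molecular formula as a Hill-notation string
#'
#' @param f A [MolecularFormula-class].
#' @return A character scalar; the empty formula formats as `""`.
#' @export
formatFormula <- function(f) {
  stopifnot(is(f, "MolecularFormula"))
  cnt <- f@counts
  if (!length(cnt)) return("")
  paste0(names(cnt), ifelse(cnt == 1L, "", cnt), collapse = "")
}

setMethod("show", "MolecularFormula", function(object) {
  cat("MolecularFormula:", if (length(object@counts)) formatFormula(object)
      else "(empty)", "\n")
})

#' @rdname MolecularFormula-class
#' @param e1,e2 Formulas to combine element-wise.
#' @export
setMethod("+", signature("MolecularFormula", "MolecularFormula"),
          function(e1, e2) {
  cnt <- e1@counts
  for (el in names(e2@counts))
    cnt[el] <- (if (el %in% names(cnt)) cnt[[el]] else 0L) + e2@counts[[el]]
  .newFormula(cnt)
})

#' @rdname MolecularFormula-class
#' @export
setMethod("-", signature("MolecularFormula", "MolecularFormula"),
          function(e1, e2) {
  cnt <- e1@counts
  for (el in names(e2@counts)) {
    have <- if (el %in% names(cnt)) cnt[[el]] else 0L
    res <- have - e2@counts[[el]]
    if (res < 0L)
      stop("formula subtraction yields negative count for element ",
           sQuote(el), " (", formatFormula(e1), " - ", formatFormula(e2), ")")
    cnt[el] <- res
  }
  .newFormula(cnt)
})

#' Monoisotopic mass of a formula
#'
#' Sum of count times principal-isotope mass over the packaged atomic-mass
#' table. Additive: `formulaMass(a + b) == formulaMass(a) + formulaMass(b)`.
#'
#' @param f A [MolecularFormula-class] or a formula string.
#' @return Mass in Da; `0` for the empty formula.
#' @examples
#' formulaMass("C8H7NO4")  # DIBOA aglycone, 181.0375
#' @export
formulaMass <- function(f) {
  if (is.character(f)) f <- parseFormula(f)
  stopifnot(is(f, "MolecularFormula"))
  masses <- .atomicMasses()
  cnt <- f@counts
  if (!length(cnt)) return(0)
  missing <- setdiff(names(cnt), names(masses))
  if (length(missing))
    stop("no tabulated mass for element(s): ", paste(missing, collapse = ", "))
  sum(cnt * masses[names(cnt)])
}

#' Singly charged ion species
#'
#' Only protonation/deprotonation is modeled: `"[M+H]+"` (polarity +1, mass
#' shift +proton) and `"[M-H]-"` (polarity -1, mass shift -proton).
#'
#' @slot label Ion label.
#' @slot polarity `+1L` or `-1L`.
#' @slot massShift Signed mass shift in Da.
#' @export
setClass("IonSpecies", representation(label = "character",
                                      polarity = "integer",
                                      massShift = "numeric"))

setValidity("IonSpecies", function(object) {
  if (!object@polarity %in% c(1L, -1L)) return("polarity must be +1 or -1")
  if (abs(abs(object@massShift) - protonMass()) > 1e-6)
    return("mass shift magnitude must equal the proton mass")
  if (sign(object@massShift) != object@polarity)
    return("mass shift sign must match polarity")
  TRUE
})

#' Construct an ion species
#'
#' @param label `"[M+H]+"` or `"[M-H]-"` (a Unicode minus is tolerated), or a
#'   polarity given as `+1`/`-1`.
#' @return An [IonSpecies-class].
#' @export
ionSpecies <- function(label) {
  if (is.numeric(label))
    label <- if (label > 0) "[M+H]+" else "[M-H]-"
  label <- gsub("−", "-", label)
  label <- gsub(" ", "", label)
  pol <- switch(label, "[M+H]+" = 1L, "[M-H]-" = -1L,
                stop("unsupported ion species: ", sQuote(label)))
  new("IonSpecies", label = label, polarity = pol,
      massShift = pol * protonMass())
}

setMethod("show", "IonSpecies", function(object) {
  cat("IonSpecies ", object@label, " (shift ",
      sprintf("%+.6f", object@massShift), " Da)\n", sep = "")
})

#' m/z of a singly charged ion
#'
#' @param f Neutral formula ([MolecularFormula-class] or string).
#' @param ion An [IonSpecies-class], its label, or a polarity `+1`/`-1`.
#' @return m/z in Th: `formulaMass(f) + massShift`.
#' @examples
#' ionMz("C9H9NO4", "[M-H]-")  # HMBOA aglycone anion, 194.0459
#' @export
ionMz <- function(f, ion) {
  if (!is(ion, "IonSpecies")) ion <- ionSpecies(ion)
  formulaMass(f) + ion@massShift
}

#' Signed parts-per-million mass error
#'
#' @param observed Observed m/z.
#' @param theoretical Theoretical m/z; must be positive.
#' @return `1e6 * (observed - theoretical) / theoretical`.
#' @export
ppmError <- function(observed, theoretical) {
  if (any(theoretical <= 0))
    stop("theoretical m/z must be positive")
  1e6 * (observed - theoretical) / theoretical
}

#' Nominal (integer) mass of an m/z value
#'
#' Nearest integer with .5 rounding away from zero. This is the rounded
#' monoisotopic value, which is the convention under which the familiar
#' benzoxazinoid and C-glycoside diagnostic fragments come out at 134, 166,
#' 164, 153, 120, 150 and 90 Da.
#'
#' @param x m/z value(s), non-negative.
#' @return Integer vector.
#' @export
nominalMz <- function(x) {
  stopifnot(all(x >= 0))
  as.integer(sign(x) * floor(abs(x) + 0.5))
}
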