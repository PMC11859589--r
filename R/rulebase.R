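#' Fragmentation rulebase
#'
#' The declarative grammar driving glycoside annotation: a set of aglycone
#' skeleton definitions (formula, compound class, supported polarities,
#' characteristic neutral losses applied to the aglycone-retaining Y0 ion,
#' optional absolute diagnostic fragments) and a catalog of substituent
#' residues (formula, linkage semantics, multiplicity bound, trivial-name
#' aliases). O-linked substituents cleave to form Y ions; C-linked sugars
#' are never fully cleaved and instead fragment by cross-ring losses
#' (nominal 120/150 Da for a C-hexose, 90/120 Da for a C-pentose);
#' `mod` substituents (methylation) are retained in every fragment.
#'
#' @slot aglycones Named list of aglycone definitions.
#' @slot substituents Named list of substituent definitions.
#' @export
setClass("Rulebase", representation(aglycones = "list",
                                    substituents = "list"))

setValidity("Rulebase", function(object) {
  for (a in object@aglycones) {
    need <- c("name", "formula", "class", "polarities", "losses",
              "fragments", "mass")
    if (!all(need %in% names(a)))
      return(paste0("aglycone entry missing fields: ", a$name))
    if (!all(a$polarities %in% c(1L, -1L)))
      return("aglycone polarities must be +1/-1")
    for (l in a$losses) {
      ok <- tryCatch({ a$formula - l; TRUE }, error = function(e) FALSE)
      if (!ok)
        return(paste0("loss not subtractable from aglycone ", a$name))
    }
  }
  for (s in object@substituents) {
    need <- c("name", "formula", "linkage", "max_count", "cross_ring_losses",
              "aliases", "mass")
    if (!all(need %in% names(s)))
      return(paste0("substituent entry missing fields: ", s$name))
    if (!s$linkage %in% c("O", "C", "mod"))
      return("substituent linkage must be one of O, C, mod")
    if (s$mass <= 0) return("substituent residue mass must be positive")
    if (s$linkage == "C" && !length(s$cross_ring_losses))
      return(paste0("C-linked substituent ", s$name,
                    " needs cross-ring losses"))
  }
  TRUE
})

setMethod("show", "Rulebase", function(object) {
  cat("Rulebase:", length(object@aglycones), "aglycones (",
      paste(unique(vapply(object@aglycones, `[[`, "", "class")),
            collapse = ", "), "),",
      length(object@substituents), "substituents\n")
})

#' @describeIn Rulebase-class aglycone definition list accessor
#' @param x A `Rulebase`.
#' @export
aglycones <- function(x) x@aglycones

#' @describeIn Rulebase-class substituent definition list accessor
#' @export
substituents <- function(x) x@substituents

.parseAglycone <- function(a) {
  f <- parseFormula(a$formula)
  losses <- lapply(a$losses %||% list(), parseFormula)
  frags <- lapply(a$fragments %||% list(), parseFormula)
  list(name = a$name, formula = f, mass = formulaMass(f),
       class = a$class, polarities = as.integer(unlist(a$polarities)),
       losses = losses, fragments = frags)
}

.parseSubstituent <- function(s) {
  f <- parseFormula(s$formula)
  crl <- lapply(s$cross_ring_losses %||% list(), parseFormula)
  names(crl) <- vapply(crl, function(x) as.character(nominalMz(formulaMass(x))),
                       character(1))
  list(name = s$name, formula = f, mass = formulaMass(f),
       linkage = s$linkage, max_count = as.integer(s$max_count %||% 1L),
       cross_ring_losses = crl,
       aliases = as.character(unlist(s$aliases %||% character(0))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a fragmentation rulebase from a YAML file
#'
#' See the packaged `default_rules.yml` for the schema: top-level keys
#' `aglycones` and `substituents`, each a list of entries.
#'
#' @param path YAML file path.
#' @return A [Rulebase-class].
#' @export
readRulebase <- function(path) {
  if (!file.exists(path)) stop("no such file: ", sQuote(path))
  raw <- yaml::read_yaml(path)
  if (!all(c("aglycones", "substituents") %in% names(raw)))
    stop("rulebase file must define 'aglycones' and 'substituents'")
  ag <- lapply(raw$aglycones, .parseAglycone)
  names(ag) <- vapply(ag, `[[`, "", "name")
  su <- lapply(raw$substituents, .parseSubstituent)
  names(su) <- vapply(su, `[[`, "", "name")
  new("Rulebase", aglycones = ag, substituents = su)
}

#' The packaged default rulebase
#'
#' Covers the benzoxazinoid skeletons HBOA, HMBOA, DIBOA and DIMBOA
#' (negative mode) and the flavones apigenin, luteolin, tricetin and tricin
#' (positive mode, with the 5,7-dihydroxyflavonoid A-ring rule), plus
#' hexose/pentose/deoxyhexose/acetyl/malonyl O-linked substituents,
#' methylation as a retained modification, and C-linked hexose/pentose with
#' their cross-ring losses.
#'
#' @return A [Rulebase-class].
#' @export
defaultRulebase <- function() {
  readRulebase(system.file("extdata", "default_rules.yml",
                           package = "cerealmet", mustWork = TRUE))
}

#' Resolve a substituent trivial name to its catalog identity
#'
#' Maps e.g. `"glucose"` or `"rhamnose"` to the mass-level identities
#' (`"hexose"`, `"deoxyhexose"`) the annotator reports; names that are
#' already catalog identities pass through.
#'
#' @param rulebase A [Rulebase-class].
#' @param name Substituent or alias name(s).
#' @return Character vector of catalog substituent names.
#' @export
resolveSubstituent <- function(rulebase, name) {
  subs <- substituents(rulebase)
  vapply(name, function(nm) {
    if (nm %in% names(subs)) return(nm)
    for (s in subs) if (nm %in% s$aliases) return(s$name)
    stop("unknown substituent or alias: ", sQuote(nm))
  }, character(1), USE.NAMES = FALSE)
}
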