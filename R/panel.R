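#' Metabolite-by-species panel matrix
#'
#' A [SummarizedExperiment::SummarizedExperiment] subclass holding the
#' widely-targeted panel: an `abundance` assay (non-negative reals,
#' metabolites in rows, species in columns), a derived `presence` assay
#' (logical), and a `class` column in `rowData` giving each metabolite's
#' compound class. Detection is binary: presence is defined as
#' abundance > 0 after QC, with no detection-limit modeling.
#'
#' @export
#' @import SummarizedExperiment
#' @importFrom S4Vectors DataFrame metadata
setClass("PanelMatrix", contains = "SummarizedExperiment")

setValidity("PanelMatrix", function(object) {
  if (!all(c("abundance", "presence") %in% assayNames(object)))
    return("PanelMatrix needs 'abundance' and 'presence' assays")
  ab <- assay(object, "abundance")
  pr <- assay(object, "presence")
  if (any(ab < 0)) return("abundances must be non-negative")
  if (!identical(unname(pr), unname(ab > 0)))
    return("presence must equal abundance > 0")
  if (!"class" %in% names(rowData(object)))
    return("rowData must carry a 'class' column")
  if (anyDuplicated(colnames(object)))
    return("species names must be unique")
  if (anyDuplicated(rownames(object)))
    return("metabolite ids must be unique")
  TRUE
})

#' Construct a PanelMatrix
#'
#' @param abundance Numeric matrix, metabolites x species, with rownames
#'   (metabolite ids) and colnames (species).
#' @param class Character vector of compound-class labels, one per
#'   metabolite.
#' @return A [PanelMatrix-class].
#' @export
panelMatrix <- function(abundance, class) {
  abundance <- as.matrix(abundance)
  if (is.null(rownames(abundance)) || is.null(colnames(abundance)))
    stop("abundance matrix needs metabolite rownames and species colnames")
  if (length(class) != nrow(abundance))
    stop("one class label per metabolite required")
  se <- SummarizedExperiment(
    assays = list(abundance = abundance, presence = abundance > 0),
    rowData = S4Vectors::DataFrame(class = as.character(class),
                                   row.names = rownames(abundance)))
  new("PanelMatrix", se)
}

#' @describeIn PanelMatrix-class abundance assay accessor
#' @param x A `PanelMatrix`.
#' @export
abundances <- function(x) assay(x, "abundance")

#' @describeIn PanelMatrix-class logical presence assay accessor
#' @export
presence <- function(x) assay(x, "presence")

#' @describeIn PanelMatrix-class species (column) names
#' @export
speciesNames <- function(x) colnames(x)

#' @describeIn PanelMatrix-class compound-class label per metabolite
#' @export
classLabels <- function(x) {
  stats::setNames(as.character(rowData(x)$class), rownames(x))
}

setMethod("show", "PanelMatrix", function(object) {
  cat("PanelMatrix:", nrow(object), "metabolites x", ncol(object),
      "species;", length(unique(rowData(object)$class)), "classes\n")
  callNextMethod()
})

#' Read a panel from delimited text
#'
#' Expected header: `id`, `class`, then one abundance column per species;
#' tab- or comma-delimited.
#'
#' @param path File path.
#' @return A [PanelMatrix-class].
#' @export
readPanel <- function(path) {
  if (!file.exists(path)) stop("no such file: ", sQuote(path))
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  tab <- utils::read.table(path, sep = sep, header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("id", "class") %in% names(tab)))
    stop("panel file must have 'id' and 'class' columns")
  species <- setdiff(names(tab), c("id", "class"))
  ab <- as.matrix(tab[species])
  rownames(ab) <- tab$id
  panelMatrix(ab, tab$class)
}

#' Write a panel to tab-delimited text
#'
#' @param panel A [PanelMatrix-class].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writePanel <- function(panel, path) {
  df <- data.frame(id = rownames(panel), class = classLabels(panel),
                   abundances(panel), check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
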