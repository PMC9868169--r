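#' Default land-use naturalness scores (LNI table)
#'
#' The operative 0-10 naturalness scores per land-use class, following the
#' HAILS (Human Activity Intensity of Land Surface) evaluation applied to the
#' nine-class legend: fully natural covers (natural water, unused) score 0,
#' used-but-unconverted covers score below 2 (forest 0.67, grassland 1.33),
#' converted covers score 2 (arable), impermeable artificial surfaces score 6
#' (artificial water body) or 10 (urban, rural, industrial).
#'
#' The table is an input, not a constant of the method: supply a modified
#' table to \code{\link{assignNaturalness}} (or via CSV, columns class, sign,
#' score) to transfer the scoring to other regions.
#'
#' @return data.frame with columns \code{class}, \code{sign} (classification
#'   sign), \code{score} in [0, 10]; one row per canonical class.
#' @seealso \code{\link{hailsClassificationTable}} for the underlying
#'   classification metadata.
#' @export
defaultNaturalnessTable <- function() {
  data.frame(
    class = c("arable", "forest", "grassland", "artificial_water",
              "natural_water", "urban", "rural", "industrial", "unused"),
    sign = c(
      "natural cover changes and annual crops are planted",
      "natural cover does not change but is used",
      "natural cover does not change but is used",
      "artificial insulation layer; water exchanged, nutrients/air/heat impeded",
      "natural cover does not change and is not used",
      "artificial insulation layer; all exchanges impeded",
      "artificial insulation layer; all exchanges impeded",
      "artificial insulation layer; all exchanges impeded",
      "natural cover does not change and is not used"),
    score = c(2, 0.67, 1.33, 6, 0, 10, 10, 10, 0),
    stringsAsFactors = FALSE)
}

#' HAILS naturalness classification metadata
#'
#' The HAILS two-tier classification of land-surface naturalness carried as
#' documentation metadata: second-level categories (CS1..CS3) for surfaces
#' whose natural cover persists or is cropped, first-level categories
#' (FCS1..FCS5) for artificially sealed surfaces, with the scheme's own 0-2
#' scores. The operative 0-10 LNI scoring per class is
#' \code{\link{defaultNaturalnessTable}}; the two scales are intentionally
#' not reconciled.
#'
#' @return data.frame with columns \code{level}, \code{category},
#'   \code{sign}, \code{score}.
#' @export
hailsClassificationTable <- function() {
  data.frame(
    level = c("second", "second", "second", "second",
              "first", "first", "first", "first", "first", "first"),
    category = c("", "CS1", "CS2", "CS3",
                 "FCS1", "FCS2", "FCS3", "FCS4", "FCS5", ""),
    sign = c(
      "natural cover does not change and is not used",
      "natural cover does not change but is used",
      "natural cover changes and perennial crops are planted",
      "natural cover changes and annual crops are planted",
      "natural cover changes",
      "insulation layer; water exchanged; nutrients, air, heat impeded",
      "insulation layer; nutrients exchanged; water, air, heat impeded",
      "insulation layer; air exchanged; water, nutrients, heat impeded",
      "insulation layer; heat exchanged; water, air, nutrients impeded",
      "insulation layer; water, nutrients, air and heat all impeded"),
    score = c(0, 0.67, 1.33, 2, 2, 2, 2, 2, 2, 2),
    stringsAsFactors = FALSE)
}

#' Assign naturalness scores to a land-use grid
#'
#' Produces the LNI score surface: each cell receives the table score of its
#' land-use class, with no interpolation; nodata is preserved.
#'
#' @param landUse a \linkS4class{LandUseGrid}.
#' @param table naturalness table (data.frame with columns \code{class},
#'   \code{score}); defaults to \code{\link{defaultNaturalnessTable}}.
#' @return A \linkS4class{ValueGrid} of scores in [0, 10] (units "score").
#' @examples
#' lu <- landUseGrid(matrix(c(1, 6, 3, 5), 2, 2))
#' gridValues(assignNaturalness(lu))
#' @export
assignNaturalness <- function(landUse, table = defaultNaturalnessTable()) {
  stopifnot(is(landUse, "LandUseGrid"))
  if (!all(c("class", "score") %in% names(table)))
    stop("naturalness table must have columns 'class' and 'score'")
  if (any(table$score < 0 | table$score > 10))
    stop("naturalness scores must lie in [0, 10]")
  present <- names(landUse@legend)[landUse@legend %in%
                                     unique(landUse@codes[!is.na(landUse@codes)])]
  missing <- setdiff(present, table$class)
  if (length(missing))
    stop("scoring error: class(es) missing from naturalness table: ",
         paste(missing, collapse = ", "))
  scoreByCode <- stats::setNames(
    table$score[match(names(landUse@legend), table$class)],
    landUse@legend)
  v <- matrix(scoreByCode[as.character(landUse@codes)],
              nrow(landUse@codes), ncol(landUse@codes))
  valueGrid(v, spec = landUse@spec, units = "score")
}

#' Read / write a naturalness table as CSV
#'
#' @param path CSV path (columns class, sign, score).
#' @param table a naturalness table data.frame.
#' @return \code{readNaturalnessTable}: the table; \code{writeNaturalnessTable}:
#'   \code{path} invisibly.
#' @export
readNaturalnessTable <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("class", "score") %in% names(tab)))
    stop("naturalness CSV must have columns 'class' and 'score'")
  tab
}

#' @rdname readNaturalnessTable
#' @export
writeNaturalnessTable <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}
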