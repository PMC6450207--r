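#' Default synthetic cover-class table
#'
#' Six cover classes emulating a northern Wisconsin forest mosaic: four
#' forested classes that differ in the fraction of their stands falling in
#' nonavoided (preferred or neutral) cover/size types, plus two unforested
#' barrier classes (open water, urban/open land). The `nonavoided_fraction`
#' of a class is the suitability value assigned to its cells when no
#' stand-level record is available; cells that do carry a stand record
#' instead carry a per-cell binary nonavoided flag. Aspen's 0.17 reflects
#' the low fraction of aspen stands in the saw-log size class that martens
#' do not avoid; the remaining fractions are package defaults chosen to
#' yield a realistic gradient from high-quality northern hardwood down to
#' absolute barriers.
#'
#' @param weights optional numeric vector of landscape cover weights
#'   (proportions, recycled/renormalised); defaults to the built-in mix.
#' @return A `data.frame` with columns `id`, `name`, `forested`,
#'   `has_stand_data`, `nonavoided_fraction`, `weight`.
#' @export
default_cover_classes <- function(weights = NULL) {
  tab <- data.frame(
    id = 1:6,
    name = c("northern_hardwood", "mixed_conifer", "aspen",
             "lowland_conifer", "open_water", "urban_open"),
    forested = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE),
    has_stand_data = TRUE,
    nonavoided_fraction = c(0.70, 0.50, 0.17, 0.35, 0.00, 0.00),
    weight = c(0.30, 0.20, 0.20, 0.15, 0.05, 0.10),
    stringsAsFactors = FALSE
  )
  if (!is.null(weights)) {
    stopifnot(length(weights) == nrow(tab), all(weights >= 0), sum(weights) > 0)
    tab$weight <- weights / sum(weights)
  }
  tab
}

validate_class_table <- function(class_table) {
  if (is.null(class_table) || nrow(class_table) == 0)
    stop("class table must be non-empty")
  need <- c("id", "name", "forested", "has_stand_data",
            "nonavoided_fraction", "weight")
  miss <- setdiff(need, names(class_table))
  if (length(miss)) stop("class table missing columns: ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(class_table$id)) stop("duplicate class ids")
  f <- class_table$nonavoided_fraction
  if (any(f < 0 | f > 1)) stop("nonavoided_fraction must lie in [0, 1]")
  if (any(class_table$weight < 0)) stop("class weights must be nonnegative")
  invisible(class_table)
}
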