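#' Diet categories
#'
#' The nine food categories used to summarize diet composition, plus the
#' \code{nonfood} pseudo-category for incidentally ingested material (twigs,
#' debris, anthill material, grooming hair).
#'
#' @export
diet_categories <- function() {
  c("plants", "pine_nuts", "drupes", "berries", "acorns_nuts",
    "insects", "mammals", "salmon", "other", "nonfood")
}

#' Construct and validate a food-item table
#'
#' A food-item table maps every item that can be identified in a scat to one
#' of the nine diet categories (or \code{nonfood}), and carries the two
#' digestibility correction factors: \code{cf_d}, converting fecal volume to
#' ingested dry matter, and \code{cf_e}, converting ingested dry matter to
#' digestible energy. \code{is_bear_hair} marks hair items subject to the
#' per-scat grooming rule (see \code{\link{apply_nonfood_rules}}).
#'
#' @param items data.frame with columns \code{item_id}, \code{category},
#'   \code{cf_d}, \code{cf_e} and optionally \code{is_bear_hair}.
#' @return validated data.frame of class \code{food_item_table}.
#' @export
food_item_table <- function(items) {
  stopifnot(is.data.frame(items))
  req <- c("item_id", "category", "cf_d", "cf_e")
  miss <- setdiff(req, names(items))
  if (length(miss))
    stop("taxonomy is missing required column(s): ", paste(miss, collapse = ", "))
  if (is.null(items$is_bear_hair)) items$is_bear_hair <- FALSE
  items$item_id <- as.character(items$item_id)
  items$category <- as.character(items$category)
  items$is_bear_hair <- as.logical(items$is_bear_hair)
  if (anyDuplicated(items$item_id))
    stop("duplicated item_id in taxonomy: ",
         paste(unique(items$item_id[duplicated(items$item_id)]), collapse = ", "))
  bad <- setdiff(unique(items$category), diet_categories())
  if (length(bad))
    stop("unknown categories in taxonomy: ", paste(bad, collapse = ", "))
  food <- items$category != "nonfood"
  cfs <- c(items$cf_d[food], items$cf_e[food])
  if (any(!is.finite(cfs)) || any(cfs <= 0))
    stop("correction factors must be finite and > 0 for all food items")
  class(items) <- c("food_item_table", "data.frame")
  items
}

#' Example food-item taxonomy with placeholder correction factors
#'
#' A worked example of the taxonomy input covering all nine categories plus
#' nonfood items and a bear-hair item. The correction-factor values are
#' placeholders chosen within ranges typical of the bear-diet literature
#' (highly digestible items such as salmon and mammal tissue get large
#' factors, bulky foliage small ones); they are NOT authoritative values for
#' any particular study and should be replaced with study-specific factors
#' for real analyses.
#'
#' @return a \code{\link{food_item_table}}.
#' @export
example_taxonomy <- function() {
  food_item_table(data.frame(
    item_id = c("herbaceous_plants", "woody_plants", "seaweed",
                "pinus_pumila",
                "prunus_sargentii", "prunus_ssiori",
                "vitis_coignetiae", "actinidia_spp", "sorbus_commixta",
                "quercus_crispula", "juglans_mandshurica",
                "formicidae", "vespidae",
                "cervus_nippon", "ursus_arctos",
                "oncorhynchus_spp",
                "fungi", "amphipoda",
                "debris", "twigs"),
    category = c("plants", "plants", "plants",
                 "pine_nuts",
                 "drupes", "drupes",
                 "berries", "berries", "berries",
                 "acorns_nuts", "acorns_nuts",
                 "insects", "insects",
                 "mammals", "mammals",
                 "salmon",
                 "other", "other",
                 "nonfood", "nonfood"),
    cf_d = c(0.25, 0.25, 0.30,
             1.50,
             1.00, 1.00,
             1.00, 1.00, 1.00,
             1.60, 1.60,
             1.10, 1.10,
             2.00, 2.00,
             5.00,
             1.00, 1.00,
             1.00, 1.00),
    cf_e = c(0.60, 0.60, 0.50,
             1.70,
             1.00, 1.00,
             1.10, 1.10, 1.10,
             1.30, 1.30,
             1.30, 1.30,
             1.90, 1.90,
             2.00,
             1.00, 1.00,
             1.00, 1.00),
    is_bear_hair = c(rep(FALSE, 14), TRUE, rep(FALSE, 5)),
    stringsAsFactors = FALSE
  ))
}

#' Read a taxonomy CSV
#'
#' Expects columns \code{item_id, category, cf_d, cf_e} and optionally
#' \code{is_bear_hair}.
#'
#' @param path path to CSV file.
#' @return a \code{\link{food_item_table}}.
#' @export
read_taxonomy <- function(path) {
  food_item_table(read.csv(path, stringsAsFactors = FALSE, comment.char = "#"))
}

# internal lookup helpers ----------------------------------------------------

tax_lookup <- function(taxonomy, items, what) {
  idx <- match(items, taxonomy$item_id)
  out <- taxonomy[[what]][idx]
  names(out) <- items
  out
}
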