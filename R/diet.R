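#' Diet profile
#'
#' A diet profile is a named numeric vector of percent contributions on one
#' of four bases: \code{occupancy} (point-frame volumetric proportion),
#' \code{vfv} (visually estimated percent fecal volume), \code{edc}
#' (estimated dietary content, dry-matter corrected) or \code{edec}
#' (estimated digestible-energy content), at either \code{item} or
#' \code{category} level. Occupancy sums to 100 over all counted items;
#' EDC/EDEC sum to 100 over food items.
#'
#' @param values named non-negative numeric vector (percent).
#' @param basis one of \code{"occupancy"}, \code{"vfv"}, \code{"edc"},
#'   \code{"edec"}.
#' @param level \code{"item"} or \code{"category"}.
#' @param nonfood character vector of keys flagged nonfood (excluded from
#'   EDC/EDEC), if the nonfood rules have been applied.
#' @return an object of class \code{diet_profile}.
#' @export
diet_profile <- function(values, basis = c("occupancy", "vfv", "edc", "edec"),
                         level = c("item", "category"), nonfood = NULL) {
  basis <- match.arg(basis)
  level <- match.arg(level)
  if (is.null(names(values)) || any(!nzchar(names(values))))
    stop("diet profile values must be named")
  if (any(!is.finite(values)) || any(values < 0))
    stop("diet profile values must be finite and >= 0")
  if (basis %in% c("edc", "edec")) {
    if (abs(sum(values) - 100) > 1e-6)
      stop(sprintf("%s profile must sum to 100 (got %.8f)", basis, sum(values)))
  }
  structure(as.numeric(values),
            names = names(values),
            basis = basis, level = level, nonfood = nonfood,
            class = "diet_profile")
}

#' @export
print.diet_profile <- function(x, ...) {
  cat(sprintf("<diet_profile: %s, %s level>\n", attr(x, "basis"), attr(x, "level")))
  print(round(unclass(setNames(as.numeric(x), names(x))), 2))
  nf <- attr(x, "nonfood")
  if (length(nf)) cat("nonfood:", paste(nf, collapse = ", "), "\n")
  invisible(x)
}

profile_basis <- function(p) attr(p, "basis")
profile_level <- function(p) attr(p, "level")

#' Point-frame occupancy of each food item
#'
#' Converts raw point-frame counts into the percent occupancy of each item:
#' 100 times the number of grid intersections covered by the item divided by
#' the total number of intersections covered by any item in the sample.
#'
#' @param point_counts named vector of non-negative integer counts.
#' @return item-level \code{\link{diet_profile}} on the occupancy basis.
#' @export
compute_occupancy <- function(point_counts) {
  if (length(point_counts) == 0 || sum(point_counts) <= 0)
    stop("degenerate input: all point counts are zero")
  if (any(point_counts < 0) || any(point_counts != round(point_counts)))
    stop("point counts must be non-negative integers")
  diet_profile(100 * point_counts / sum(point_counts),
               basis = "occupancy", level = "item")
}

#' Scat acceptance rule for point-frame samples
#'
#' A point-frame sample is accepted when at least 200 points were counted.
#' Salmon-dominated scats rarely reach 200 points because salmon tissue is
#' almost fully digested and washes through the sieve, so a scat containing
#' salmon is also accepted when its wet weight is at least 50 g.
#'
#' @param point_counts named vector of point counts for one scat.
#' @param wet_weight_g wet weight of the scat in grams.
#' @param taxonomy a \code{\link{food_item_table}}.
#' @param min_points,salmon_min_weight_g rule thresholds (defaults 200, 50).
#' @return list with \code{accepted} (logical) and \code{reason} (string
#'   naming the rule applied).
#' @export
accept_scat <- function(point_counts, wet_weight_g, taxonomy,
                        min_points = 200, salmon_min_weight_g = 50) {
  total <- sum(point_counts)
  cats <- tax_lookup(taxonomy, names(point_counts), "category")
  if (anyNA(cats))
    stop("items missing from taxonomy: ",
         paste(names(point_counts)[is.na(cats)], collapse = ", "))
  has_salmon <- any(point_counts > 0 & cats == "salmon")
  if (total >= min_points)
    return(list(accepted = TRUE,
                reason = sprintf("total points %d >= %d", total, min_points)))
  if (has_salmon && isTRUE(wet_weight_g >= salmon_min_weight_g))
    return(list(accepted = TRUE,
                reason = sprintf("salmon present and wet weight %.1f g >= %.0f g",
                                 wet_weight_g, salmon_min_weight_g)))
  list(accepted = FALSE,
       reason = if (has_salmon)
         sprintf("total points %d < %d and wet weight %.1f g < %.0f g",
                 total, min_points, wet_weight_g, salmon_min_weight_g)
       else
         sprintf("total points %d < %d and no salmon exception", total, min_points))
}

#' Resolve the per-scat nonfood set
#'
#' Items whose taxonomy category is \code{nonfood} are always flagged.
#' Bear-hair items are flagged nonfood (grooming ingestion) when their
#' volumetric proportion in the scat is at most \code{hair_threshold}
#' percent; above that the hair is retained as food, i.e. evidence of
#' conspecific consumption, under the mammals category.
#'
#' @param profile item-level \code{\link{diet_profile}} (occupancy or vfv).
#' @param taxonomy a \code{\link{food_item_table}}.
#' @param hair_threshold percent threshold for the grooming rule (default 0.5).
#' @return the profile with its \code{nonfood} attribute set.
#' @export
apply_nonfood_rules <- function(profile, taxonomy, hair_threshold = 0.5) {
  if (profile_level(profile) != "item")
    stop("nonfood rules apply to item-level profiles")
  items <- names(profile)
  cats <- tax_lookup(taxonomy, items, "category")
  if (anyNA(cats))
    stop("items missing from taxonomy: ", paste(items[is.na(cats)], collapse = ", "))
  hair <- tax_lookup(taxonomy, items, "is_bear_hair")
  nonfood <- items[cats == "nonfood" | (hair & as.numeric(profile) <= hair_threshold)]
  attr(profile, "nonfood") <- nonfood
  profile
}

cf_weighted <- function(profile, taxonomy, weights, basis_out) {
  if (profile_level(profile) != "item")
    stop("correction factors apply to item-level profiles")
  if (!profile_basis(profile) %in% c("occupancy", "vfv"))
    stop("EDC/EDEC are computed from occupancy or vfv profiles")
  if (is.null(attr(profile, "nonfood")))
    profile <- apply_nonfood_rules(profile, taxonomy)
  v <- setNames(as.numeric(profile), names(profile))
  food <- setdiff(names(v)[v > 0], attr(profile, "nonfood"))
  if (length(food) == 0 || sum(v[food]) <= 0)
    stop("degenerate input: no food volume after nonfood exclusion")
  w <- weights[food]
  if (anyNA(w) || any(!is.finite(w)) || any(w <= 0))
    stop("missing or invalid correction factor for food item(s): ",
         paste(food[is.na(w) | !is.finite(w) | w <= 0], collapse = ", "))
  x <- v[food] * w
  diet_profile(100 * x / sum(x), basis = basis_out, level = "item",
               nonfood = attr(profile, "nonfood"))
}

#' Estimated dietary content (EDC)
#'
#' Corrects a volumetric profile for differential digestibility:
#' \code{EDC_i = 100 * V_i * CF_D_i / sum_j(V_j * CF_D_j)} over food items
#' only. Nonfood items are excluded before renormalization; the nonfood rules
#' are applied first if they have not been already.
#'
#' @inheritParams apply_nonfood_rules
#' @return item-level \code{\link{diet_profile}} on the EDC basis.
#' @export
compute_edc <- function(profile, taxonomy) {
  w <- setNames(taxonomy$cf_d, taxonomy$item_id)
  cf_weighted(profile, taxonomy, w, "edc")
}

#' Estimated digestible-energy content (EDEC)
#'
#' Weights each food item's volume by CF_D (volume to ingested dry matter)
#' and then CF_E (dry matter to digestible energy) before renormalizing:
#' \code{EDEC_i = 100 * V_i * CF_D_i * CF_E_i / sum_j(V_j * CF_D_j * CF_E_j)}.
#'
#' @inheritParams apply_nonfood_rules
#' @return item-level \code{\link{diet_profile}} on the EDEC basis.
#' @export
compute_edec <- function(profile, taxonomy) {
  w <- setNames(taxonomy$cf_d * taxonomy$cf_e, taxonomy$item_id)
  cf_weighted(profile, taxonomy, w, "edec")
}

#' Aggregate an item-level profile to the nine diet categories
#'
#' @inheritParams apply_nonfood_rules
#' @return category-level \code{\link{diet_profile}}; totals are conserved.
#' @export
aggregate_categories <- function(profile, taxonomy) {
  if (profile_level(profile) != "item")
    stop("profile is already at category level")
  items <- names(profile)
  cats <- tax_lookup(taxonomy, items, "category")
  if (anyNA(cats))
    stop("item with unknown category: ", paste(items[is.na(cats)], collapse = ", "))
  # hair retained as food stays in mammals; flagged-nonfood keys map to nonfood
  nf <- attr(profile, "nonfood")
  if (length(nf)) cats[items %in% nf] <- "nonfood"
  agg <- tapply(as.numeric(profile), cats, sum)
  diet_profile(setNames(as.numeric(agg), names(agg)),
               basis = profile_basis(profile), level = "category",
               nonfood = if (length(nf)) "nonfood" else NULL)
}
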