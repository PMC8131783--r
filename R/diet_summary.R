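#' Per-scat diet profiles for a whole study
#'
#' Applies the point-frame acceptance rule, the nonfood rules and the chosen
#' basis conversion to every scat in a long-format scat table, returning one
#' profile row per scat and item (or category). Visual-method scats can only
#' supply the \code{vfv} basis here; converting them to EDC requires the
#' through-origin calibration (see \code{\link{apply_calibration}}).
#'
#' @param scats long-format data.frame with columns \code{scat_id, year,
#'   month, day, method, wet_weight_g, item_id, value} (\code{day} may be NA).
#' @param taxonomy a \code{\link{food_item_table}}.
#' @param basis one of \code{"edc"}, \code{"edec"}, \code{"occupancy"},
#'   \code{"vfv"}.
#' @param level \code{"category"} (default) or \code{"item"}.
#' @return data.frame \code{scat_id, year, month, half, key, value} with an
#'   \code{audit} attribute recording the acceptance decision per scat.
#' @export
quantify_scats <- function(scats, taxonomy,
                           basis = c("edc", "edec", "occupancy", "vfv"),
                           level = c("category", "item")) {
  basis <- match.arg(basis)
  level <- match.arg(level)
  req <- c("scat_id", "year", "month", "method", "wet_weight_g", "item_id", "value")
  miss <- setdiff(req, names(scats))
  if (length(miss))
    stop("scats table is missing column(s): ", paste(miss, collapse = ", "))
  if (is.null(scats$day)) scats$day <- NA_integer_

  res <- vector("list", 0L)
  audit <- vector("list", 0L)
  for (sub in split(scats, scats$scat_id)) {
    id <- sub$scat_id[[1]]
    meta <- sub[1, c("scat_id", "year", "month", "day")]
    half <- if (is.na(meta$day)) "unknown" else if (meta$day <= 15) "early" else "late"
    method <- sub$method[[1]]
    v <- setNames(sub$value, sub$item_id)

    if (method == "point_frame") {
      dec <- accept_scat(v, sub$wet_weight_g[[1]], taxonomy)
      if (!dec$accepted) {
        audit[[id]] <- data.frame(scat_id = id, accepted = FALSE, reason = dec$reason)
        next
      }
      prof <- apply_nonfood_rules(compute_occupancy(v), taxonomy)
      prof <- switch(basis,
                     occupancy = prof,
                     vfv = prof,  # occupancy is the volumetric proportion
                     edc = compute_edc(prof, taxonomy),
                     edec = compute_edec(prof, taxonomy))
      audit[[id]] <- data.frame(scat_id = id, accepted = TRUE, reason = dec$reason)
    } else if (method == "visual") {
      if (basis %in% c("edc", "edec", "occupancy")) {
        audit[[id]] <- data.frame(scat_id = id, accepted = FALSE,
                                  reason = sprintf("visual scat cannot supply %s without calibration", basis))
        next
      }
      s <- sum(v)
      if (abs(s - 100) > 0.5) {
        audit[[id]] <- data.frame(scat_id = id, accepted = FALSE,
                                  reason = sprintf("vfv sums to %.2f, not 100 +/- 0.5", s))
        next
      }
      prof <- apply_nonfood_rules(
        diet_profile(v, basis = "vfv", level = "item"), taxonomy)
      audit[[id]] <- data.frame(scat_id = id, accepted = TRUE, reason = "visual record")
    } else {
      stop("unknown scat method: ", method)
    }

    if (level == "category") prof <- aggregate_categories(prof, taxonomy)
    res[[id]] <- data.frame(meta, half = half,
                            key = names(prof), value = as.numeric(prof),
                            row.names = NULL)
  }
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(scat_id = character(), year = integer(), month = character(),
               day = integer(), half = character(), key = character(),
               value = numeric())
  rownames(out) <- NULL
  attr(out, "audit") <- if (length(audit)) do.call(rbind, c(audit, make.row.names = FALSE)) else NULL
  attr(out, "basis") <- basis
  out
}

#' Period summaries of diet profiles
#'
#' Computes, per period group, the unweighted arithmetic mean of per-scat
#' percent profiles (each scat is the sampling unit, so scats are not pooled
#' by their point counts), the percent frequency of occurrence
#' \code{FO_i = 100 * (number of scats containing item i) / n}, and the
#' number of scats \code{n}.
#'
#' @param profiles long per-scat profile table from \code{\link{quantify_scats}}.
#' @param grouping \code{"month"}, \code{"semimonth"} or \code{"year_month"}.
#'   Scats with unknown collection day are excluded from semimonthly (but not
#'   monthly) summaries, with a warning.
#' @return data.frame with the grouping columns plus \code{key, mean, fo, n}.
#' @export
summarize_period <- function(profiles,
                             grouping = c("month", "semimonth", "year_month")) {
  grouping <- match.arg(grouping)
  if (grouping == "semimonth") {
    unk <- profiles$half == "unknown"
    if (any(unk)) {
      warning(sprintf("excluding %d scat(s) with unknown day from semimonthly summary",
                      length(unique(profiles$scat_id[unk]))))
      profiles <- profiles[!unk, , drop = FALSE]
    }
  }
  gcols <- switch(grouping,
                  month = "month",
                  semimonth = c("month", "half"),
                  year_month = c("year", "month"))
  if (nrow(profiles) == 0)
    return(data.frame(profiles[0, gcols, drop = FALSE],
                      key = character(), mean = numeric(), fo = numeric(),
                      n = integer()))
  gid <- interaction(profiles[gcols], drop = TRUE, sep = "\r")
  out <- lapply(split(profiles, gid), function(sub) {
    n <- length(unique(sub$scat_id))
    tot <- tapply(sub$value, sub$key, sum)          # absent key in a scat = 0
    occ <- tapply(sub$value > 0, sub$key, sum)
    data.frame(sub[1, gcols, drop = FALSE],
               key = names(tot),
               mean = as.numeric(tot) / n,
               fo = 100 * as.numeric(occ) / n,
               n = n, row.names = NULL)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Render diet percentages the way seasonal diet tables print them
#'
#' Exact zeros print as an em dash, positive contributions below 0.05 percent
#' print as \code{"tr"} (trace), everything else to one decimal place.
#'
#' @param x numeric vector of percentages.
#' @return character vector.
#' @export
format_diet_value <- function(x) {
  ifelse(x == 0, "—", ifelse(x < 0.05, "tr", sprintf("%.1f", x)))
}

#' Through-origin calibration of visual volume estimates
#'
#' Fits, per category, a linear regression with no intercept of EDC on the
#' visual (or point-frame) volumetric estimate, so that visually estimated
#' profiles can be used as equivalent to EDC. The through-origin least
#' squares slope has the closed form \code{sum(x*y) / sum(x^2)}.
#'
#' @param pairs data.frame with columns \code{category, vfv, edc}; one row
#'   per paired observation.
#' @param categories categories the model should cover; those without pairs
#'   (or with all-zero \code{vfv}) pass through with slope 1.
#' @return data.frame of class \code{vfv_calibration} with columns
#'   \code{category, slope, n_pairs}.
#' @export
fit_vfv_calibration <- function(pairs,
                                categories = setdiff(diet_categories(), "nonfood")) {
  stopifnot(all(c("category", "vfv", "edc") %in% names(pairs)))
  categories <- union(categories, unique(pairs$category))
  rows <- lapply(categories, function(cc) {
    sub <- pairs[pairs$category == cc, , drop = FALSE]
    if (nrow(sub) == 0)
      return(data.frame(category = cc, slope = 1, n_pairs = 0L))
    sxx <- sum(sub$vfv^2)
    if (sxx == 0) {
      warning("all visual estimates are zero for category '", cc,
              "'; slope set to 1")
      return(data.frame(category = cc, slope = 1, n_pairs = nrow(sub)))
    }
    data.frame(category = cc, slope = sum(sub$vfv * sub$edc) / sxx,
               n_pairs = nrow(sub))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("vfv_calibration", "data.frame")
  out
}

#' Apply a through-origin calibration to a visual profile
#'
#' Multiplies each category's visual percent volume by its calibration slope
#' and renormalizes to 100, yielding an EDC-equivalent profile.
#'
#' @param profile category-level \code{\link{diet_profile}} on the vfv basis.
#' @param model a \code{\link{fit_vfv_calibration}} result.
#' @return category-level \code{\link{diet_profile}} on the EDC basis.
#' @export
apply_calibration <- function(profile, model) {
  if (profile_level(profile) != "category")
    stop("calibration is applied to category-level profiles")
  slopes <- setNames(model$slope, model$category)
  s <- slopes[names(profile)]
  s[is.na(s)] <- 1
  v <- as.numeric(profile) * s
  keep <- names(profile) != "nonfood"
  v <- v[keep]
  if (sum(v) <= 0) stop("degenerate input: all calibrated values are zero")
  diet_profile(setNames(100 * v / sum(v), names(profile)[keep]),
               basis = "edc", level = "category")
}

#' Classify years by pine-nut and salmon consumption
#'
#' A year is a high pine-nut year when its August pine-nut EDC strictly
#' exceeds the mean over all study years, and analogously for September
#' salmon. \code{diet1} marks years high in both; \code{diet2} marks years
#' low in both. Values exactly equal to the mean are not "high".
#'
#' @param august_pine_edc named numeric vector, year -> August pine-nut EDC.
#' @param september_salmon_edc named numeric vector, year -> September
#'   salmon EDC. Must cover the same years.
#' @return data.frame \code{year, pine_edc, salmon_edc, pine_high,
#'   salmon_high, diet1, diet2}.
#' @export
classify_years <- function(august_pine_edc, september_salmon_edc) {
  ys <- names(august_pine_edc)
  if (is.null(ys) || is.null(names(september_salmon_edc)))
    stop("year mappings must be named by year")
  if (!setequal(ys, names(september_salmon_edc)))
    stop("pine and salmon mappings cover different year sets")
  if (length(ys) < 2) stop("need at least two years to classify")
  ys <- sort(ys)
  pine <- august_pine_edc[ys]
  salmon <- september_salmon_edc[ys]
  pine_high <- pine > mean(pine)
  salmon_high <- salmon > mean(salmon)
  data.frame(year = as.integer(ys),
             pine_edc = as.numeric(pine),
             salmon_edc = as.numeric(salmon),
             pine_high = as.logical(pine_high),
             salmon_high = as.logical(salmon_high),
             diet1 = as.logical(pine_high & salmon_high),
             diet2 = as.logical(!pine_high & !salmon_high),
             row.names = NULL)
}
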