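#' Synthetic study configuration
#'
#' Defines the conditions of a simulated scat-and-photograph study with known
#' ground truth: seasonal true-diet profiles distorted by differential
#' digestibility and counted with multinomial point-frame noise, and smooth
#' seasonal log TH:HTL trajectories per diet-year class with reproductive
#' status offsets, crossed year/bear random intercepts and gamma photo-level
#' noise. Defaults emulate a seven-year, twelve-bear coastal study: one
#' visual-method year followed by six point-frame years whose monthly scat
#' totals, August pine-nut shares and September salmon shares match the
#' published seasonal pattern; high years have flat condition curves with an
#' early (mid-July) minimum, other years a deeper minimum in late August.
#'
#' @param ... named overrides of any default field.
#' @return validated list of class \code{study_config}.
#' @export
study_config <- function(...) {
  sess <- session_codes()
  cfg <- list(
    years = 2012:2018,
    months = c("June", "July", "August", "September", "October"),
    taxonomy = example_taxonomy(),
    diet_profiles = default_diet_profiles(),
    item_weights = default_item_weights(),
    pine_august = c(`2012` = 20, `2013` = 47.4, `2014` = 47.5, `2015` = 20,
                    `2016` = 47.3, `2017` = 20, `2018` = 42.9),
    salmon_september = c(`2012` = 15, `2013` = 54.4, `2014` = 20, `2015` = 15,
                         `2016` = 65.4, `2017` = 18, `2018` = 72.2),
    dirichlet_conc = 60,
    scats_per_month = c(June = 242, July = 308, August = 476,
                        September = 466, October = 272),
    visual_year = 2012,
    visual_scats_per_month = c(June = 25, July = 95, August = 76,
                               September = 41, October = 78),
    points_per_scat = 300,
    salmon_point_deficit = TRUE,
    wet_weight_meanlog = log(120),
    wet_weight_sdlog = 0.4,
    nonfood_share = 2.5,
    hair_rate = 0.15,
    hair_share = 0.2,
    bears = sprintf("B%02d", 1:12),
    sessions = sess,
    log_curve_high = setNames(
      c(-0.370, -0.385, -0.380, -0.375, -0.365, -0.350, -0.335, -0.320), sess),
    log_curve_low = setNames(
      c(-0.360, -0.385, -0.405, -0.415, -0.405, -0.385, -0.355, -0.325), sess),
    rst_offset = -0.025,
    year_sd = 0.010,
    bear_sd = 0.015,
    photo_shape = 1000,
    photos_lambda = 3.6,
    unusable_rate = 0.10,
    with_young_rate = 0.5,
    loss_rate = 0.15,
    jitter_sd = 0.5,
    angle_range = 10,
    attributes = c("focus", "lateral_orientation", "posture",
                   "obstruction", "ground_visibility"),
    seed = 1
  )
  cfg <- modifyList(cfg, list(...))
  validate_study_config(cfg)
  class(cfg) <- "study_config"
  cfg
}

validate_study_config <- function(cfg) {
  if (is.null(cfg$seed) || !is.finite(cfg$seed)) stop("seed is mandatory")
  sums <- colSums(cfg$diet_profiles)
  if (any(abs(sums - 100) > 1e-6))
    stop("diet profile columns must sum to 100")
  if (any(c(cfg$year_sd, cfg$bear_sd, cfg$jitter_sd) < 0))
    stop("standard deviations must be >= 0")
  yrs <- as.character(cfg$years)
  if (!setequal(names(cfg$pine_august), yrs) ||
      !setequal(names(cfg$salmon_september), yrs))
    stop("pine_august and salmon_september must be named by every study year")
  for (w in cfg$item_weights)
    if (abs(sum(w) - 1) > 1e-9) stop("item weights must sum to 1 per category")
  invisible(cfg)
}

#' Default monthly true-diet profiles (category percent)
#'
#' Columns are months, rows the nine food categories. August pine-nut and
#' September salmon shares are baseline (low-year) values; per-year scenario
#' shares in the config override them.
#'
#' @return numeric matrix (9 categories x 5 months), columns summing to 100.
#' @export
default_diet_profiles <- function() {
  cats <- setdiff(diet_categories(), "nonfood")
  m <- cbind(
    June      = c(76.4, 0.0,  0.1,  0.3,  6.7,  6.3, 6.9,  0.0,  3.3),
    July      = c(47.7, 2.8,  6.9,  2.4,  5.2, 24.6, 3.0,  0.1,  7.3),
    August    = c(30.7, 20.0, 8.0,  5.0,  1.0, 15.0, 0.6, 14.7,  5.0),
    September = c(8.0,  8.0, 10.0, 20.0, 27.7,  0.5, 0.3, 25.0,  0.5),
    October   = c(2.4,  0.0,  0.3, 31.8, 47.4,  0.4, 1.0, 16.7,  0.0)
  )
  rownames(m) <- cats
  m
}

default_item_weights <- function() {
  list(
    plants = c(herbaceous_plants = 0.92, woody_plants = 0.06, seaweed = 0.02),
    pine_nuts = c(pinus_pumila = 1),
    drupes = c(prunus_sargentii = 0.5, prunus_ssiori = 0.5),
    berries = c(vitis_coignetiae = 0.5, actinidia_spp = 0.3, sorbus_commixta = 0.2),
    acorns_nuts = c(quercus_crispula = 0.9, juglans_mandshurica = 0.1),
    insects = c(formicidae = 0.93, vespidae = 0.07),
    mammals = c(cervus_nippon = 1),
    salmon = c(oncorhynchus_spp = 1),
    other = c(fungi = 0.5, amphipoda = 0.5)
  )
}

rdirichlet1 <- function(alpha) {
  g <- setNames(rgamma(length(alpha), shape = alpha, rate = 1), names(alpha))
  if (sum(g) <= 0) g[which.max(alpha)] <- 1
  g / sum(g)
}

distribute_counts <- function(total, n) {
  base <- total %/% n
  rem <- total %% n
  base + c(rep(1, rem), rep(0, n - rem))
}

month_profile <- function(cfg, year, month) {
  p <- cfg$diet_profiles[, month]
  y <- as.character(year)
  if (month == "August") {
    share <- cfg$pine_august[[y]]
    rest <- p[names(p) != "pine_nuts"]
    p[names(rest)] <- rest / sum(rest) * (100 - share)
    p["pine_nuts"] <- share
  } else if (month == "September") {
    share <- cfg$salmon_september[[y]]
    rest <- p[names(p) != "salmon"]
    p[names(rest)] <- rest / sum(rest) * (100 - share)
    p["salmon"] <- share
  }
  p
}

#' Generate synthetic scat records
#'
#' For each scat, a true ingested composition is drawn from a Dirichlet
#' around the month-year profile, converted to the expected fecal composition
#' by dividing each item by its dry-matter correction factor and
#' renormalizing (the inverse of the EDC correction), contaminated with a
#' small nonfood fraction, and counted as a multinomial draw of point-frame
#' points. The visual year produces percent-volume records instead of counts.
#'
#' @param config a \code{\link{study_config}}.
#' @param seed RNG seed (defaults to \code{config$seed}).
#' @return list with \code{truth} (data.frame \code{year, month, category,
#'   share}) and \code{scats} (long-format scat table).
#' @export
gen_diet <- function(config, seed = config$seed) {
  set.seed(seed)
  cfg <- config
  tax <- cfg$taxonomy
  cf_d <- setNames(tax$cf_d, tax$item_id)
  pf_years <- setdiff(cfg$years, cfg$visual_year)

  truth <- list(); scats <- list(); counter <- 0L
  for (month in cfg$months) {
    pf_counts <- distribute_counts(cfg$scats_per_month[[month]], length(pf_years))
    for (yi in seq_along(cfg$years)) {
      year <- cfg$years[yi]
      visual <- year == cfg$visual_year
      n <- if (visual) cfg$visual_scats_per_month[[month]]
      else pf_counts[[match(year, pf_years)]]
      prof <- month_profile(cfg, year, month)
      truth[[length(truth) + 1L]] <- data.frame(
        year = year, month = month, category = names(prof),
        share = as.numeric(prof), row.names = NULL)
      if (n == 0) next

      # expand category shares to item shares
      item_share <- unlist(lapply(names(prof), function(cc)
        prof[[cc]] * cfg$item_weights[[cc]]))
      names(item_share) <- unlist(lapply(names(prof),
                                         function(cc) names(cfg$item_weights[[cc]])))
      item_share <- item_share[item_share > 0]

      for (s in seq_len(n)) {
        counter <- counter + 1L
        true_comp <- 100 * rdirichlet1(cfg$dirichlet_conc * item_share / 100)
        fecal <- true_comp / cf_d[names(true_comp)]
        fecal <- 100 * fecal / sum(fecal)
        # nonfood contamination (debris/twigs, occasional grooming hair)
        nf <- c(debris = 0.7, twigs = 0.3) * cfg$nonfood_share
        if (runif(1) < cfg$hair_rate) nf <- c(nf, ursus_arctos = cfg$hair_share)
        fecal <- c(fecal * (100 - sum(nf)) / 100, nf)
        day <- sample(1:28, 1)
        wet <- rlnorm(1, cfg$wet_weight_meanlog, cfg$wet_weight_sdlog)
        id <- sprintf("S%05d", counter)
        if (visual) {
          vfv <- round(fecal, 1)
          vfv[which.max(vfv)] <- vfv[which.max(vfv)] + (100 - sum(vfv))
          keep <- vfv > 0
          scats[[counter]] <- data.frame(
            scat_id = id, year = year, month = month, day = day,
            method = "visual", wet_weight_g = round(wet, 1),
            item_id = names(vfv)[keep], value = as.numeric(vfv[keep]),
            row.names = NULL)
        } else {
          npts <- cfg$points_per_scat
          salmon_share <- sum(fecal[names(fecal) == "oncorhynchus_spp"])
          if (cfg$salmon_point_deficit && salmon_share > 30)
            npts <- round(runif(1, 120, 250))
          cnt <- drop(rmultinom(1, npts, fecal / 100))
          keep <- cnt > 0
          scats[[counter]] <- data.frame(
            scat_id = id, year = year, month = month, day = day,
            method = "point_frame", wet_weight_g = round(wet, 1),
            item_id = names(fecal)[keep], value = as.numeric(cnt[keep]),
            row.names = NULL)
        }
      }
    }
  }
  list(truth = do.call(rbind, truth), scats = do.call(rbind, scats))
}

#' Generate synthetic photographs and reproductive records
#'
#' Per bear-session the true TH:HTL is the exponential of the year-class
#' baseline curve plus the reproductive-status offset and the year and bear
#' random intercepts; each photo's ratio is a gamma draw with that mean.
#' Landmarks are constructed so that the rectified measurement returns the
#' drawn ratio exactly (axis-aligned points at the needed separations rotated
#' by the photo's ground angle), then jittered per replicate.
#'
#' @param config a \code{\link{study_config}}.
#' @param seed RNG seed (defaults to \code{config$seed + 1}).
#' @return list with \code{photos} (wide photo table), \code{repro}
#'   (reproductive events) and \code{truth} (curves, offsets, random
#'   intercepts, diet-year classes).
#' @export
gen_condition <- function(config, seed = config$seed + 1) {
  set.seed(seed)
  cfg <- config
  pine_high <- cfg$pine_august > mean(cfg$pine_august)
  salmon_high <- cfg$salmon_september > mean(cfg$salmon_september)
  diet1_years <- as.integer(names(cfg$pine_august)[pine_high & salmon_high])
  diet2_years <- as.integer(names(cfg$pine_august)[!pine_high & !salmon_high])

  year_re <- setNames(rnorm(length(cfg$years), 0, cfg$year_sd),
                      as.character(cfg$years))
  bear_re <- setNames(rnorm(length(cfg$bears), 0, cfg$bear_sd), cfg$bears)

  grid <- expand.grid(bear_id = cfg$bears, year = cfg$years,
                      stringsAsFactors = FALSE)
  with_young <- runif(nrow(grid)) < cfg$with_young_rate
  grid$status <- ifelse(with_young,
                        ifelse(runif(nrow(grid)) < 0.5, "with_cubs", "with_yearlings"),
                        "solitary")
  lost <- with_young & runif(nrow(grid)) < cfg$loss_rate
  grid$loss_session <- NA_real_
  grid$loss_session[lost] <- sample(cfg$sessions[-1], sum(lost), replace = TRUE)
  repro <- grid

  # photo-level table, one row per (bear, year, session, photo)
  bs <- expand.grid(bear_id = cfg$bears, year = cfg$years,
                    session = cfg$sessions, stringsAsFactors = FALSE)
  bs$n_photos <- rpois(nrow(bs), cfg$photos_lambda)
  bs <- bs[bs$n_photos > 0, , drop = FALSE]
  ph <- bs[rep(seq_len(nrow(bs)), bs$n_photos), c("bear_id", "year", "session")]
  ri <- match(paste(ph$bear_id, ph$year), paste(repro$bear_id, repro$year))
  curve <- ifelse(ph$year %in% diet1_years,
                  cfg$log_curve_high[as.character(ph$session)],
                  cfg$log_curve_low[as.character(ph$session)])
  eta <- curve +
    cfg$rst_offset * (repro$status[ri] != "solitary") +
    year_re[as.character(ph$year)] + bear_re[ph$bear_id]
  mu <- exp(eta)
  n <- nrow(ph)
  ratio <- rgamma(n, shape = cfg$photo_shape, rate = cfg$photo_shape / mu)

  htl <- runif(n, 350, 450)
  th <- ratio * htl
  angle <- runif(n, -cfg$angle_range, cfg$angle_range)
  base <- list(abdomen = cbind(250, 80), waist = cbind(250, 80 + th),
               tail = cbind(100, 150), shoulder = cbind(100 + htl, 150 + runif(n, -20, 20)))
  a <- angle * pi / 180
  photos <- data.frame(photo_id = sprintf("P%05d", seq_len(n)),
                       bear_id = ph$bear_id, year = ph$year,
                       session = ph$session,
                       ground_angle_deg = angle, row.names = NULL)
  # grading scores: unusable photos get a 3 on one random attribute
  unusable <- runif(n) < cfg$unusable_rate
  bad_attr <- sample(seq_along(cfg$attributes), n, replace = TRUE)
  for (j in seq_along(cfg$attributes)) {
    sc <- sample(1:2, n, replace = TRUE)
    sc[unusable & bad_attr == j] <- 3
    photos[[paste0("attr_", cfg$attributes[j])]] <- sc
  }
  for (p in names(base)) {
    x0 <- rep(base[[p]][, 1], length.out = n)
    y0 <- rep(base[[p]][, 2], length.out = n)
    xr <- x0 * cos(a) - y0 * sin(a)   # camera-frame tilt: rotate by +angle
    yr <- x0 * sin(a) + y0 * cos(a)
    for (r in 1:3) {
      photos[[sprintf("rep%d_%s_x", r, p)]] <- xr + rnorm(n, 0, cfg$jitter_sd)
      photos[[sprintf("rep%d_%s_y", r, p)]] <- yr + rnorm(n, 0, cfg$jitter_sd)
    }
  }
  list(photos = photos, repro = repro,
       truth = list(log_curve_high = cfg$log_curve_high,
                    log_curve_low = cfg$log_curve_low,
                    rst_offset = cfg$rst_offset,
                    year_re = year_re, bear_re = bear_re,
                    diet1_years = diet1_years, diet2_years = diet2_years))
}

#' Generate and write a complete synthetic study
#'
#' Writes \code{scats.csv} (long format), \code{taxonomy.csv},
#' \code{photos.csv}, \code{repro.csv} and \code{truth.json} to a directory.
#' Output is byte-identical for identical (config, seed).
#'
#' @param config a \code{\link{study_config}}.
#' @param out_dir output directory (created if absent).
#' @param seed RNG seed (defaults to \code{config$seed}).
#' @return (invisibly) list with the generated data and the file paths.
#' @export
gen_study <- function(config, out_dir, seed = config$seed) {
  diet <- gen_diet(config, seed = seed)
  cond <- gen_condition(config, seed = seed + 1)
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE))
    stop("cannot create output directory: ", out_dir)
  paths <- file.path(out_dir, c("scats.csv", "taxonomy.csv", "photos.csv",
                                "repro.csv", "truth.json"))
  names(paths) <- c("scats", "taxonomy", "photos", "repro", "truth")
  tax <- as.data.frame(config$taxonomy)
  write.csv(diet$scats, paths["scats"], row.names = FALSE)
  write.csv(tax, paths["taxonomy"], row.names = FALSE)
  write.csv(cond$photos, paths["photos"], row.names = FALSE)
  write.csv(cond$repro, paths["repro"], row.names = FALSE)
  truth <- list(seed = seed, diet = diet$truth, condition = cond$truth)
  jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(list(diet = diet, condition = cond, paths = paths))
}
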