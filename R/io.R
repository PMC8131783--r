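#' Read a scat table (wide or long format)
#'
#' Long format has columns \code{scat_id, year, month, day, method,
#' wet_weight_g, item_id, value}; wide format replaces \code{item_id/value}
#' by one column per item. Rows failing validation (negative values, unknown
#' method, unknown month) are rejected with a per-row reason, available as
#' \code{attr(x, "rejected")}.
#'
#' @param path path to CSV file.
#' @return long-format scat data.frame.
#' @export
read_scats <- function(path) {
  raw <- read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  meta <- c("scat_id", "year", "month", "method", "wet_weight_g")
  miss <- setdiff(meta, names(raw))
  if (length(miss))
    stop("scats file is missing required column(s): ", paste(miss, collapse = ", "))
  if (is.null(raw$day)) raw$day <- NA_integer_
  raw$.row <- seq_len(nrow(raw))

  if (all(c("item_id", "value") %in% names(raw))) {
    long <- raw
  } else {
    items <- setdiff(names(raw), c(meta, "day", ".row"))
    if (length(items) == 0) stop("scats file has no item columns")
    long <- do.call(rbind, lapply(items, function(it) {
      data.frame(raw[c(meta, "day", ".row")], item_id = it, value = raw[[it]],
                 row.names = NULL)
    }))
    long <- long[!is.na(long$value) & long$value != 0, , drop = FALSE]
  }

  reasons <- character(0); rows <- integer(0)
  flag <- function(bad, why) {
    if (any(bad)) {
      rows <<- c(rows, long$.row[bad]); reasons <<- c(reasons, rep(why, sum(bad)))
    }
    bad
  }
  bad <- flag(!is.finite(long$value) | long$value < 0, "negative or missing value") |
    flag(!long$method %in% c("point_frame", "visual"), "unknown method") |
    flag(!tolower(long$month) %in% tolower(month.name), "unknown month")
  out <- long[!bad, setdiff(names(long), ".row"), drop = FALSE]
  rownames(out) <- NULL
  rej <- unique(data.frame(row = rows, reason = reasons))
  attr(out, "rejected") <- rej[order(rej$row), , drop = FALSE]
  out
}

#' Read a photo table
#'
#' Requires \code{photo_id, bear_id, year, ground_angle_deg}, either a
#' \code{session} column or \code{month}/\code{day} columns to derive it,
#' at least one \code{attr_*} score column and the 24 replicate landmark
#' columns \code{rep\{1..3\}_\{abdomen,waist,tail,shoulder\}_\{x,y\}}. Rows
#' with scores outside \{1,2,3\} are rejected with a reason.
#'
#' @param path path to CSV file.
#' @return photo data.frame with a \code{rejected} attribute.
#' @export
read_photos <- function(path) {
  ph <- read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  req <- c("photo_id", "bear_id", "year", "ground_angle_deg")
  miss <- setdiff(req, names(ph))
  if (length(miss))
    stop("photos file is missing required column(s): ", paste(miss, collapse = ", "))
  if (is.null(ph$session)) {
    if (is.null(ph$month)) stop("photos file needs a session or month column")
    ph$session <- session_from_date(ph$month, ph$day)
  }
  attr_cols <- grep("^attr_", names(ph), value = TRUE)
  if (!length(attr_cols)) stop("photos file has no attr_* score columns")
  scores <- as.matrix(ph[attr_cols])
  bad <- apply(scores, 1, function(s) any(!s %in% c(1, 2, 3)))
  rej <- data.frame(row = which(bad),
                    reason = rep("attribute score outside 1..3", sum(bad)))
  ph <- ph[!bad, , drop = FALSE]
  rownames(ph) <- NULL
  attr(ph, "rejected") <- rej
  ph
}

#' Read a reproductive-status table
#'
#' @param path path to CSV with columns \code{bear_id, year, status} and
#'   optionally \code{loss_session}.
#' @return data.frame.
#' @export
read_repro <- function(path) {
  rp <- read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  miss <- setdiff(c("bear_id", "year", "status"), names(rp))
  if (length(miss))
    stop("repro file is missing required column(s): ", paste(miss, collapse = ", "))
  if (is.null(rp$loss_session)) rp$loss_session <- NA_real_
  rp
}

# stable string hash (djb2) for config provenance headers
hash_config <- function(config) {
  s <- paste(deparse(config), collapse = "\n")
  h <- 5381
  for (b in utf8ToInt(s)) h <- (h * 33 + b) %% 2^31
  sprintf("%08x", h)
}

write_output <- function(df, path, hash, seed) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# bearcond %s; config_hash=%s; seed=%s",
                     as.character(utils::packageVersion("bearcond")), hash, seed),
             con)
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a pipeline output CSV (skipping the provenance header)
#'
#' @param path path written by \code{\link{run_pipeline}}.
#' @return data.frame.
#' @export
read_output <- function(path) {
  read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
}

#' Pipeline configuration
#'
#' @param scats,taxonomy,photos,repro paths to the four input CSV files.
#' @param out_dir output directory.
#' @param grouping period grouping for the diet summary table.
#' @param calibrate correct visual-year profiles via the through-origin
#'   calibration so they enter the annual EDC series; when FALSE,
#'   visual-only years are excluded with a warning.
#' @param k session-smooth basis dimension.
#' @param models candidate model list (default \code{\link{candidate_models}}).
#' @param seed RNG seed recorded in output headers.
#' @param loss_rule offspring-loss truncation rule (see
#'   \code{\link{build_observations}}).
#' @return list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(scats, taxonomy, photos, repro, out_dir,
                            grouping = "month", calibrate = TRUE, k = 5,
                            models = candidate_models(), seed = 1,
                            loss_rule = "inclusive") {
  stopifnot(grouping %in% c("month", "semimonth", "year_month"),
            loss_rule %in% c("inclusive", "exclusive"))
  structure(list(scats = scats, taxonomy = taxonomy, photos = photos,
                 repro = repro, out_dir = out_dir, grouping = grouping,
                 calibrate = calibrate, k = k, models = models, seed = seed,
                 loss_rule = loss_rule),
            class = "pipeline_config")
}

#' Run the full diet-and-condition analysis pipeline
#'
#' Orchestrates the stages end to end: per-scat EDC/EDEC quantification and
#' period summaries; annual EDC series including calibrated visual-year
#' profiles; high/low consumption year classification; photo measurement and
#' the modelling observation table; candidate GAMM fits, AICc selection,
#' parameter estimates of the top model and its population-level prediction
#' curves. Writes seven CSV outputs, each with a provenance header carrying
#' the config hash and seed. On a stage failure all partial outputs are
#' removed and the error names the stage.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @return (invisibly) list with the in-memory results and output paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  for (f in c("scats", "taxonomy", "photos", "repro"))
    if (!file.exists(config[[f]])) stop("input file not found: ", config[[f]])
  if (!dir.exists(config$out_dir) && !dir.create(config$out_dir, recursive = TRUE))
    stop("cannot create output directory: ", config$out_dir)
  hash <- hash_config(config)
  written <- character(0)
  ok <- FALSE
  on.exit(if (!ok && length(written)) unlink(written), add = TRUE)
  set.seed(config$seed)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)), call. = FALSE))
  }
  emit <- function(df, file) {
    p <- file.path(config$out_dir, file)
    write_output(df, p, hash, config$seed)
    written <<- c(written, p)
    p
  }

  res <- list()
  stage("read", {
    scats <- read_scats(config$scats)
    tax <- read_taxonomy(config$taxonomy)
    photos <- read_photos(config$photos)
    repro <- read_repro(config$repro)
    message(sprintf("read: %d scat rows, %d taxonomy items, %d photos, %d repro records",
                    nrow(scats), nrow(tax), nrow(photos), nrow(repro)))
  })

  stage("diet", {
    edc <- quantify_scats(scats, tax, basis = "edc", level = "category")
    edec <- quantify_scats(scats, tax, basis = "edec", level = "category")
    audit <- attr(edc, "audit")
    message(sprintf("diet: %d/%d scats accepted for point-frame quantification",
                    sum(audit$accepted), nrow(audit)))
    s_edc <- summarize_period(edc, config$grouping)
    s_edec <- summarize_period(edec, config$grouping)
    gcols <- setdiff(names(s_edc), c("mean", "fo", "n"))
    names(s_edc)[names(s_edc) == "mean"] <- "edc"
    s_edc$edec <- s_edec$mean[match(do.call(paste, s_edc[gcols]),
                                    do.call(paste, s_edec[gcols]))]
    diet_summary <- s_edc[, c(setdiff(gcols, "key"), "key", "edc", "edec", "fo", "n")]
    res$diet_summary <- diet_summary
    emit(diet_summary, "diet_summary.csv")
  })

  stage("annual", {
    edc <- quantify_scats(scats, tax, basis = "edc", level = "category")
    annual <- summarize_period(edc, "year_month")
    annual <- annual[, c("year", "month", "key", "mean", "n")]
    names(annual)[names(annual) == "mean"] <- "edc"
    if (config$calibrate) {
      occ <- quantify_scats(scats, tax, basis = "occupancy", level = "category")
      pairs <- merge(occ[, c("scat_id", "key", "value")],
                     edc[, c("scat_id", "key", "value")],
                     by = c("scat_id", "key"), suffixes = c("_v", "_e"))
      calib <- fit_vfv_calibration(data.frame(category = pairs$key,
                                              vfv = pairs$value_v,
                                              edc = pairs$value_e))
      res$calibration <- calib
      vis <- quantify_scats(scats, tax, basis = "vfv", level = "category")
      vis <- vis[vis$scat_id %in% scats$scat_id[scats$method == "visual"], , drop = FALSE]
      if (nrow(vis)) {
        cal_rows <- lapply(split(vis, vis$scat_id), function(sub) {
          p <- diet_profile(setNames(sub$value, sub$key), basis = "vfv",
                            level = "category")
          ce <- apply_calibration(p, calib)
          data.frame(scat_id = sub$scat_id[1], year = sub$year[1],
                     month = sub$month[1], day = sub$day[1],
                     half = sub$half[1], key = names(ce),
                     value = as.numeric(ce), row.names = NULL)
        })
        cal_sum <- summarize_period(do.call(rbind, cal_rows), "year_month")
        cal_sum <- cal_sum[, c("year", "month", "key", "mean", "n")]
        names(cal_sum)[names(cal_sum) == "mean"] <- "edc"
        annual <- rbind(cal_sum, annual)
        annual <- annual[order(annual$year, match(annual$month, month.name),
                               annual$key), , drop = FALSE]
      }
    } else {
      vis_years <- unique(scats$year[scats$method == "visual"])
      excl <- setdiff(vis_years, unique(annual$year))
      if (length(excl))
        warning("calibration off: visual-only year(s) excluded from EDC outputs: ",
                paste(excl, collapse = ", "))
    }
    rownames(annual) <- NULL
    res$annual_edc <- annual
    emit(annual, "annual_edc.csv")
  })

  stage("classify", {
    aug <- res$annual_edc[res$annual_edc$month == "August" &
                            res$annual_edc$key == "pine_nuts", ]
    sep <- res$annual_edc[res$annual_edc$month == "September" &
                            res$annual_edc$key == "salmon", ]
    yrs <- sort(intersect(aug$year, sep$year))
    classes <- classify_years(setNames(aug$edc[match(yrs, aug$year)], yrs),
                              setNames(sep$edc[match(yrs, sep$year)], yrs))
    message(sprintf("classify: diet1 years %s; diet2 years %s",
                    paste(classes$year[classes$diet1], collapse = ","),
                    paste(classes$year[classes$diet2], collapse = ",")))
    res$year_classes <- classes
    emit(classes, "year_classification.csv")
  })

  stage("condition", {
    measured <- measure_photos(photos)
    message(sprintf("condition: %d/%d photos usable", sum(measured$usable),
                    nrow(measured)))
    cond <- session_conditions(measured)
    obs <- build_observations(cond, repro, res$year_classes,
                              loss_rule = config$loss_rule)
    message(sprintf("condition: %d session conditions -> %d modelling rows",
                    nrow(cond), nrow(obs)))
    res$observations <- obs
    emit(obs, "observations.csv")
  })

  stage("model", {
    frame <- condition_model_frame(res$observations)
    fits <- lapply(config$models, function(m)
      fit_condition_gamm(frame, smooth_by = m$smooth_by, fixed = m$fixed,
                         k = config$k))
    sel <- rank_models(fits)
    res$selection <- sel
    res$fits <- fits
    emit(as.data.frame(sel), "selection.csv")
    top <- fits[[which.min(vapply(fits, function(f) f$aicc, numeric(1)))]]
    res$top_fit <- top
    est_p <- coef_summary(top)
    est_s <- smooth_summary(top)
    est <- rbind(
      data.frame(type = "parametric", term = est_p$term, beta = est_p$beta,
                 se = est_p$se, t = est_p$t, p = est_p$p,
                 edf = NA_real_, f = NA_real_),
      data.frame(type = "smooth", term = est_s$term, beta = NA_real_,
                 se = NA_real_, t = NA_real_, p = est_s$p, edf = est_s$edf,
                 f = est_s$f))
    res$estimates <- est
    emit(est, "estimates.csv")
    curves <- predict_curve(top)
    res$curves <- curves
    emit(curves, "curves.csv")
    message(sprintf("model: top-ranked %s (AICc %.2f, weight %.2f)",
                    sel$model[1], sel$aicc[1], sel$weight[1]))
  })

  ok <- TRUE
  invisible(c(res, list(paths = written, config_hash = hash)))
}
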