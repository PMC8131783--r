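#' Session calendar
#'
#' Within-year sessions are coded 1 (June), 2 (July), 3 (early August),
#' 3.5 (late August), 4 (early September), 4.5 (late September), 5 (October)
#' and 6 (November). Half-months split at day 15.
#'
#' @return numeric vector of the eight session codes.
#' @export
session_codes <- function() c(1, 2, 3, 3.5, 4, 4.5, 5, 6)

#' Map a calendar date to its session code
#'
#' @param month month name or number (6--11).
#' @param day day of month (needed for August/September half-month splits).
#' @return session code.
#' @export
session_from_date <- function(month, day = NA) {
  m <- month_number(month)
  mapply(function(m, d) {
    switch(as.character(m),
           "6" = 1, "7" = 2,
           "8" = if (is.na(d)) stop("August session needs a day of month") else if (d <= 15) 3 else 3.5,
           "9" = if (is.na(d)) stop("September session needs a day of month") else if (d <= 15) 4 else 4.5,
           "10" = 5, "11" = 6,
           stop("no session is defined for month ", m))
  }, m, day)
}

month_number <- function(month) {
  if (is.numeric(month)) return(as.integer(month))
  idx <- match(tolower(month), tolower(month.name))
  if (anyNA(idx)) stop("unrecognized month: ", paste(month[is.na(idx)], collapse = ", "))
  idx
}

#' Photo quality grading rule
#'
#' Each photograph is scored 1 (good), 2 (medium) or 3 (poor) on a set of
#' quality/posture attributes; a photo with score 3 on any attribute is
#' unusable. The attribute set is configurable; only the "any 3 removes the
#' photo" rule is fixed.
#'
#' @param attribute_scores named numeric vector of scores in \{1, 2, 3\}.
#' @return logical: is the photo usable?
#' @export
grade_photo <- function(attribute_scores) {
  if (length(attribute_scores) == 0) stop("no attribute scores supplied")
  if (!all(attribute_scores %in% c(1, 2, 3)))
    stop("attribute scores must be 1, 2 or 3")
  !any(attribute_scores == 3)
}

#' Rotate landmarks so the ground line is horizontal
#'
#' Rotates all points by minus the ground angle about the origin, undoing the
#' camera-frame tilt. With a positive ground angle (ground rising to the
#' right in the photo), the point (1, 0) maps to (cos a, -sin a); pairwise
#' distances are preserved.
#'
#' @param landmarks numeric matrix with two columns (x, y), one row per point.
#' @param ground_angle_deg tilt of the ground line in degrees.
#' @return rotated matrix of the same shape.
#' @export
rectify_landmarks <- function(landmarks, ground_angle_deg) {
  landmarks <- as.matrix(landmarks)
  stopifnot(ncol(landmarks) == 2, all(is.finite(landmarks)))
  a <- -ground_angle_deg * pi / 180
  rot <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
  out <- landmarks %*% t(rot)
  dimnames(out) <- dimnames(landmarks)
  out
}

#' Torso height, torso length and their ratio from rectified landmarks
#'
#' Per replicate, the torso height TH is the vertical distance from the
#' lowest point of the abdomen to the highest point of the waist, and the
#' horizontal torso length HTL is the horizontal distance from the base of
#' the tail to the highest part of the shoulder. TH:HTL is the ratio of the
#' replicate means.
#'
#' @param replicates list of rectified landmark matrices (one per replicate,
#'   typically three), each with rows \code{abdomen_lowest, waist_highest,
#'   tail_base, shoulder_highest} and columns (x, y).
#' @return list with \code{th_px}, \code{htl_px} (per-replicate pixels) and
#'   \code{th_htl}.
#' @export
measure_th_htl <- function(replicates) {
  pts <- c("abdomen_lowest", "waist_highest", "tail_base", "shoulder_highest")
  th <- numeric(length(replicates))
  htl <- numeric(length(replicates))
  for (i in seq_along(replicates)) {
    m <- replicates[[i]]
    if (!all(pts %in% rownames(m)))
      stop("replicate ", i, " is missing landmark rows: ",
           paste(setdiff(pts, rownames(m)), collapse = ", "))
    th[i] <- abs(m["waist_highest", 2] - m["abdomen_lowest", 2])
    htl[i] <- abs(m["shoulder_highest", 1] - m["tail_base", 1])
  }
  if (any(th == 0) || any(htl == 0))
    stop("degenerate landmarks: zero TH or HTL in a replicate")
  list(th_px = th, htl_px = htl, th_htl = mean(th) / mean(htl))
}

#' Session-level body condition for one bear, year and session
#'
#' Requires at least two usable photographs; returns the median of the
#' photo-level TH:HTL ratios (mean of the central pair for an even count).
#'
#' @param ratios numeric vector of photo-level TH:HTL values.
#' @return the median ratio, or \code{NULL} when fewer than two photos.
#' @export
session_condition <- function(ratios) {
  ratios <- ratios[is.finite(ratios)]
  if (length(ratios) < 2) return(NULL)
  median(ratios)
}

#' Measure all photos in a photo table
#'
#' Applies the grading rule and the landmark measurements to a wide photo
#' table (see \code{\link{read_photos}} for the schema) and returns one row
#' per photo with \code{usable} and \code{th_htl}.
#'
#' @param photos wide-format photo data.frame.
#' @return data.frame \code{photo_id, bear_id, year, session, usable, th_htl}.
#' @export
measure_photos <- function(photos) {
  attr_cols <- grep("^attr_", names(photos), value = TRUE)
  if (length(attr_cols) == 0) stop("photo table has no attr_* score columns")
  lmk <- c("abdomen", "waist", "tail", "shoulder")
  lmk_names <- c(abdomen = "abdomen_lowest", waist = "waist_highest",
                 tail = "tail_base", shoulder = "shoulder_highest")
  reps <- 1:3
  need <- as.vector(outer(paste0("rep", reps), outer(lmk, c("x", "y"), paste, sep = "_"),
                          paste, sep = "_"))
  miss <- setdiff(need, names(photos))
  if (length(miss))
    stop("photo table is missing landmark column(s): ", paste(head(miss, 4), collapse = ", "),
         if (length(miss) > 4) sprintf(" (+%d more)", length(miss) - 4) else "")

  n <- nrow(photos)
  usable <- logical(n)
  ratio <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    usable[i] <- grade_photo(unlist(photos[i, attr_cols]))
    if (!usable[i]) next
    rl <- lapply(reps, function(r) {
      m <- t(vapply(lmk, function(p)
        c(photos[[paste0("rep", r, "_", p, "_x")]][i],
          photos[[paste0("rep", r, "_", p, "_y")]][i]), numeric(2)))
      rownames(m) <- lmk_names[lmk]
      rectify_landmarks(m, photos$ground_angle_deg[i])
    })
    ratio[i] <- measure_th_htl(rl)$th_htl
  }
  data.frame(photo_id = photos$photo_id, bear_id = photos$bear_id,
             year = photos$year, session = photos$session,
             usable = usable, th_htl = ratio)
}

#' Aggregate measured photos into session-level condition observations
#'
#' @param measured output of \code{\link{measure_photos}}.
#' @return data.frame \code{bear_id, year, session, th_htl, n_photos},
#'   keeping only bear-year-sessions with at least two usable photos.
#' @export
session_conditions <- function(measured) {
  m <- measured[measured$usable & is.finite(measured$th_htl), , drop = FALSE]
  if (nrow(m) == 0)
    return(data.frame(bear_id = character(), year = integer(),
                      session = numeric(), th_htl = numeric(),
                      n_photos = integer()))
  key <- interaction(m$bear_id, m$year, m$session, drop = TRUE)
  rows <- lapply(split(m, key), function(sub) {
    med <- session_condition(sub$th_htl)
    if (is.null(med)) return(NULL)
    data.frame(bear_id = sub$bear_id[1], year = sub$year[1],
               session = sub$session[1], th_htl = med,
               n_photos = nrow(sub))
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(bear_id = character(), year = integer(),
                      session = numeric(), th_htl = numeric(),
                      n_photos = integer()))
  out <- out[order(out$bear_id, out$year, out$session), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build the modelling observation table
#'
#' Applies the study inclusion rules: bear-years with condition data for
#' fewer than two sessions are dropped; for females that lost their dependent
#' young (or whose family broke up), the loss session and all later sessions
#' are dropped (configurable to exclusive, dropping strictly later sessions
#' only), after which the two-session rule is re-checked. Reproductive status
#' is collapsed to solitary versus with dependent young, and each year's
#' diet-class labels are attached.
#'
#' @param conditions output of \code{\link{session_conditions}}.
#' @param repro data.frame \code{bear_id, year, status, loss_session} with
#'   status in \{solitary, with_cubs, with_yearlings\} and
#'   \code{loss_session} NA when no loss was observed.
#' @param year_classes output of \code{\link{classify_years}} (optional; when
#'   omitted the diet columns are NA).
#' @param loss_rule \code{"inclusive"} drops the loss session itself (the
#'   default, conservative reading); \code{"exclusive"} keeps it.
#' @return data.frame \code{bear_id, year, session, th_htl, n_photos,
#'   status, diet1, diet2}.
#' @export
build_observations <- function(conditions, repro, year_classes = NULL,
                               loss_rule = c("inclusive", "exclusive")) {
  loss_rule <- match.arg(loss_rule)
  stopifnot(all(c("bear_id", "year", "status") %in% names(repro)))
  if (is.null(repro$loss_session)) repro$loss_session <- NA_real_
  bad <- !repro$status %in% c("solitary", "with_cubs", "with_yearlings")
  if (any(bad)) stop("unknown reproductive status: ",
                     paste(unique(repro$status[bad]), collapse = ", "))
  if (any(repro$status == "solitary" & !is.na(repro$loss_session)))
    stop("loss_session defined for a solitary bear-year")

  idx <- match(paste(conditions$bear_id, conditions$year),
               paste(repro$bear_id, repro$year))
  if (anyNA(idx)) {
    bad <- unique(paste(conditions$bear_id, conditions$year)[is.na(idx)])
    stop("no reproductive record for bear-year(s): ", paste(bad, collapse = ", "))
  }
  obs <- conditions
  obs$status <- ifelse(repro$status[idx] == "solitary", "solitary", "with_young")
  loss <- repro$loss_session[idx]
  keep <- is.na(loss) | (if (loss_rule == "inclusive") obs$session < loss
                         else obs$session <= loss)
  obs <- obs[keep, , drop = FALSE]

  by <- paste(obs$bear_id, obs$year)
  nsess <- tapply(obs$session, by, function(s) length(unique(s)))
  obs <- obs[nsess[by] >= 2, , drop = FALSE]

  if (!is.null(year_classes)) {
    yi <- match(obs$year, year_classes$year)
    obs$diet1 <- year_classes$diet1[yi]
    obs$diet2 <- year_classes$diet2[yi]
  } else {
    obs$diet1 <- NA
    obs$diet2 <- NA
  }
  rownames(obs) <- NULL
  obs
}
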