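# Shared fixtures and independent brute-force oracles used across test files.

# minimal two-food-item taxonomy with unit correction factors by default
tiny_taxonomy <- function(items = c("a", "b"), categories = NULL,
                          cf_d = 1, cf_e = 1, hair = FALSE) {
  n <- length(items)
  food_cats <- setdiff(diet_categories(), "nonfood")
  food_item_table(data.frame(
    item_id = items,
    category = if (is.null(categories)) rep(food_cats, length.out = n) else categories,
    cf_d = rep(cf_d, length.out = n),
    cf_e = rep(cf_e, length.out = n),
    is_bear_hair = rep(hair, length.out = n)
  ))
}

# axis-aligned landmark replicate with given TH and HTL, optionally rotated
# into a tilted camera frame
make_replicate <- function(th, htl, angle = 0, origin = c(0, 0)) {
  m <- rbind(abdomen_lowest = c(10, 0), waist_highest = c(10, th),
             tail_base = c(0, 20), shoulder_highest = c(htl, 25))
  m <- sweep(m, 2, origin, "+")
  if (angle != 0) {
    a <- angle * pi / 180
    m <- m %*% t(matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2))
    rownames(m) <- c("abdomen_lowest", "waist_highest", "tail_base",
                     "shoulder_highest")
  }
  m
}

# brute-force scat acceptance: direct transcription of the two rules
oracle_accept <- function(counts, weight, salmon_items) {
  total <- sum(counts)
  if (total >= 200) return(TRUE)
  has_salmon <- any(counts[names(counts) %in% salmon_items] > 0)
  has_salmon && weight >= 50
}

# brute-force observation-table row count: enumerate the session >=2-photo
# rule, the offspring-loss truncation and the >=2-session rule directly
oracle_observation_rows <- function(measured, repro, loss_rule = "inclusive") {
  kept <- 0L
  for (b in unique(measured$bear_id)) for (y in unique(measured$year)) {
    r <- repro[repro$bear_id == b & repro$year == y, ]
    if (nrow(r) == 0) next
    sessions <- c()
    for (s in unique(measured$session)) {
      sub <- measured[measured$bear_id == b & measured$year == y &
                        measured$session == s & measured$usable &
                        is.finite(measured$th_htl), ]
      if (nrow(sub) < 2) next
      if (!is.na(r$loss_session)) {
        dropped <- if (loss_rule == "inclusive") s >= r$loss_session
        else s > r$loss_session
        if (dropped) next
      }
      sessions <- c(sessions, s)
    }
    if (length(unique(sessions)) >= 2) kept <- kept + length(sessions)
  }
  kept
}

# small synthetic study used by io/pipeline tests (kept light on purpose)
small_study_config <- function(seed = 11) {
  study_config(
    scats_per_month = c(June = 30, July = 30, August = 60, September = 60,
                        October = 30),
    visual_scats_per_month = c(June = 5, July = 5, August = 8, September = 8,
                               October = 5),
    bears = sprintf("B%02d", 1:6),
    photos_lambda = 3,
    seed = seed
  )
}
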