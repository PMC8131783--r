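test_that("occupancy is the percent of counted intersections per item", {
  expect_equal(as.numeric(compute_occupancy(c(pine = 150, ants = 50))),
               c(75, 25))
  expect_equal(as.numeric(compute_occupancy(c(salmon = 200))), 100)
  expect_equal(as.numeric(compute_occupancy(c(a = 120, b = 60, c = 20))),
               c(60, 30, 10))
  expect_error(compute_occupancy(c(a = 0, b = 0)), "degenerate")
  expect_error(compute_occupancy(c(a = 1.5)), "integers")
})

test_that("scat acceptance follows the 200-point rule with the salmon-weight exception", {
  tax <- tiny_taxonomy(c("pine", "fish"), c("pine_nuts", "salmon"))
  expect_true(accept_scat(c(pine = 250), 120, tax)$accepted)
  dec <- accept_scat(c(pine = 180), 120, tax)
  expect_false(dec$accepted)
  expect_match(dec$reason, "no salmon")
  dec <- accept_scat(c(pine = 100, fish = 50), 60, tax)
  expect_true(dec$accepted)
  expect_match(dec$reason, "salmon")
  expect_false(accept_scat(c(pine = 100, fish = 50), 40, tax)$accepted)
})

test_that("nonfood rules flag nonfood items and apply the bear-hair grooming threshold", {
  tax <- tiny_taxonomy(c("grass", "hair", "grit"),
                       c("plants", "mammals", "nonfood"),
                       hair = c(FALSE, TRUE, FALSE))
  p <- diet_profile(c(grass = 97.7, hair = 0.3, grit = 2.0),
                    basis = "vfv", level = "item")
  expect_setequal(attr(apply_nonfood_rules(p, tax), "nonfood"),
                  c("hair", "grit"))
  p <- diet_profile(c(grass = 94, hair = 4, grit = 2), basis = "vfv",
                    level = "item")
  expect_identical(attr(apply_nonfood_rules(p, tax), "nonfood"), "grit")
  # conspecific hair above the threshold stays food, in the mammals category
  edc <- aggregate_categories(compute_edc(apply_nonfood_rules(p, tax), tax), tax)
  expect_true(edc[["mammals"]] > 0)
  p <- diet_profile(c(grass = 100), basis = "vfv", level = "item")
  expect_length(attr(apply_nonfood_rules(p, tax), "nonfood"), 0)
})

test_that("EDC reweights volumes by CF_D over food items only", {
  tax2 <- tiny_taxonomy(c("a", "b"))
  p <- diet_profile(c(a = 70, b = 30), basis = "vfv", level = "item")
  expect_equal(as.numeric(compute_edc(p, tax2)), c(70, 30))
  tax3 <- tiny_taxonomy(c("a", "b"), cf_d = c(0.5, 2))
  p <- diet_profile(c(a = 50, b = 50), basis = "vfv", level = "item")
  expect_equal(as.numeric(compute_edc(p, tax3)), c(20, 80))
  taxnf <- tiny_taxonomy(c("a", "b", "nf"), c("plants", "salmon", "nonfood"))
  p <- diet_profile(c(a = 45, b = 45, nf = 10), basis = "vfv", level = "item")
  expect_equal(as.numeric(compute_edc(p, taxnf)), c(50, 50))
  expect_error(compute_edc(diet_profile(c(nf = 100), basis = "vfv",
                                        level = "item"), taxnf),
               "degenerate")
  # an item absent from the taxonomy has no usable correction factor
  pmiss <- diet_profile(c(a = 50, b = 50), basis = "vfv", level = "item")
  expect_error(compute_edc(pmiss, tiny_taxonomy("a")), "missing")
})

test_that("EDEC applies both correction factors and reduces to EDC when CF_E is 1", {
  tax <- tiny_taxonomy(c("a", "b"), cf_d = c(0.5, 2))
  p <- diet_profile(c(a = 50, b = 50), basis = "vfv", level = "item")
  expect_equal(as.numeric(compute_edec(p, tax)),
               as.numeric(compute_edc(p, tax)))
  tax <- tiny_taxonomy(c("a", "b"), cf_d = 1, cf_e = c(3, 1))
  expect_equal(as.numeric(compute_edec(p, tax)), c(75, 25))
  expect_equal(as.numeric(compute_edec(
    diet_profile(c(a = 100), basis = "vfv", level = "item"),
    tiny_taxonomy("a", cf_d = 7, cf_e = 0.3))), 100)
})

test_that("category aggregation sums member items and conserves totals", {
  tax <- tiny_taxonomy(c("Formicidae", "Vespidae"), c("insects", "insects"))
  p <- diet_profile(c(Formicidae = 10, Vespidae = 2, other = 88),
                    basis = "vfv", level = "item")
  taxo <- tiny_taxonomy(c("Formicidae", "Vespidae", "other"),
                        c("insects", "insects", "other"))
  agg <- aggregate_categories(p, taxo)
  expect_equal(agg[["insects"]], 12)
  expect_equal(sum(agg), sum(p), tolerance = 1e-12)
  expect_error(aggregate_categories(p, tax), "unknown category")
})

test_that("profiles sum to 100 and unit correction factors leave them unchanged", {
  set.seed(42)
  for (i in 1:20) {
    n <- sample(3:8, 1)
    items <- paste0("it", 1:n)
    counts <- setNames(rmultinom(1, 300, rdirich <- runif(n) + 0.1)[, 1], items)
    counts[counts == 0] <- 1
    tax1 <- tiny_taxonomy(items)
    occ <- apply_nonfood_rules(compute_occupancy(counts), tax1)
    edc <- compute_edc(occ, tax1)
    edec <- compute_edec(occ, tax1)
    expect_equal(sum(occ), 100, tolerance = 1e-6)
    expect_equal(sum(edc), 100, tolerance = 1e-6)
    expect_equal(sum(edec), 100, tolerance = 1e-6)
    expect_equal(as.numeric(edc), as.numeric(occ)[match(names(edc), names(occ))],
                 tolerance = 1e-12)
    expect_equal(as.numeric(edec), as.numeric(edc), tolerance = 1e-12)
  }
})

test_that("raising one item's CF_D raises its EDC and lowers all others", {
  items <- c("a", "b", "c")
  p <- diet_profile(c(a = 50, b = 30, c = 20), basis = "vfv", level = "item")
  for (mult in c(1.5, 3, 10)) {
    base <- compute_edc(p, tiny_taxonomy(items, cf_d = c(1, 1, 1)))
    up <- compute_edc(p, tiny_taxonomy(items, cf_d = c(mult, 1, 1)))
    expect_gt(up[["a"]], base[["a"]])
    expect_lt(up[["b"]], base[["b"]])
    expect_lt(up[["c"]], base[["c"]])
  }
})
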