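# Brute-force largest-remainder check: among all feasible integer
# allocations, the returned one minimizes the L1 distance to the exact
# quotas (the defining optimality of Hamilton apportionment).
l1_optimal <- function(total_n, sizes) {
  quota <- total_n * sizes / sum(sizes)
  grids <- lapply(sizes, function(s) 0:min(s, total_n))
  best <- Inf
  grid <- expand.grid(grids)
  grid <- grid[rowSums(grid) == total_n, , drop = FALSE]
  min(apply(grid, 1, function(a) sum(abs(a - quota))))
}

test_that("proportional allocation reproduces the reference room allocation", {
  expect_equal(allocate_proportional(167, c(88, 174, 174, 200)),
               c(23L, 46L, 46L, 52L))
  expect_equal(allocate_proportional(10, c(50, 50)), c(5L, 5L))
  expect_equal(allocate_proportional(7, c(30, 30, 40)), c(2L, 2L, 3L))
  expect_error(allocate_proportional(101, c(50, 50)), "cannot allocate")
})

test_that("largest-remainder allocations are L1-optimal and respect stratum sizes", {
  set.seed(20)
  for (rep in 1:25) {
    k <- sample(2:4, 1)
    sizes <- sample(1:12, k, replace = TRUE)
    n <- sample.int(sum(sizes), 1)
    got <- allocate_proportional(n, sizes)
    expect_equal(sum(got), n)
    expect_true(all(got <= sizes))
    expect_true(all(got >= 0))
    quota <- n * sizes / sum(sizes)
    expect_equal(sum(abs(got - quota)), l1_optimal(n, sizes), tolerance = 1e-9)
  }
})

test_that("simple random sampling is a census at n = N and binary at n = 1", {
  h <- toy_herd(count = 8)
  d <- draw_s1(h, n_animals = 40)
  expect_equal(d$estimates[["lameness"]], 8 / 40)
  set.seed(2)
  d1 <- draw_s1(h, n_animals = 1)
  expect_true(d1$estimates[["lameness"]] %in% c(0, 1))
  expect_error(draw_s1(h, n_animals = 41), "exceeds herd size")
})

test_that("every design draws animals without replacement", {
  h <- reference_herd(seed = 3)
  set.seed(11)
  for (spec in default_strategies()) {
    d <- draw_sample(h, spec)
    for (ids in d$animal_ids) expect_false(anyDuplicated(ids) > 0)
    expect_true(all(d$estimates >= 0 & d$estimates <= 1))
    expect_true(all(d$counts == round(d$estimates * d$sample_size)))
  }
})

test_that("S1 affected counts follow the exact hypergeometric law", {
  h <- reference_herd(seed = 1)
  em <- simulate_strategy(h, strategy_spec("S1_simple", n_animals = REF_N),
                          20000, master_seed = 17)
  pmf <- exact_estimate_pmf(hypergeom_spec(636, 7, REF_N)) # runts
  obs <- table(factor(em$counts[, "runts"], levels = pmf$count))
  keep <- pmf$prob * 20000 >= 5 # merge sparse tail for the chi-square
  obs2 <- c(as.numeric(obs[keep]), sum(obs[!keep]))
  p2 <- c(pmf$prob[keep], sum(pmf$prob[!keep]))
  gof <- suppressWarnings(stats::chisq.test(obs2, p = p2 / sum(p2)))
  expect_gt(gof$p.value, 1e-4)
})

test_that("stratified sampling hits the proportional room allocation in every draw", {
  h <- reference_herd(seed = 2)
  set.seed(5)
  for (i in 1:5) {
    d <- draw_s2(h, n_animals = REF_N)
    rooms <- h$animals$room_id[match(d$animal_ids[[1]], h$animals$animal_id)]
    expect_equal(as.integer(table(rooms)), c(23L, 46L, 46L, 52L))
    expect_equal(unique(d$sample_size)[[1]], REF_N)
  }
  # degenerate stratification: one room -> same law as S1 (exact hypergeometric)
  h1 <- equal_pen_herd(n_pens = 4, pen_size = 10, count = 8)
  em <- simulate_strategy(h1, strategy_spec("S2_stratified", n_animals = 10),
                          10000, master_seed = 23)
  pmf <- exact_estimate_pmf(hypergeom_spec(40, 8, 10))
  obs <- table(factor(em$counts[, "lameness"], levels = pmf$count))
  keep <- pmf$prob * 10000 >= 5
  obs2 <- c(as.numeric(obs[keep]), sum(obs[!keep]))
  p2 <- c(pmf$prob[keep], sum(pmf$prob[!keep]))
  gof <- suppressWarnings(stats::chisq.test(obs2, p = p2 / sum(p2)))
  expect_gt(gof$p.value, 1e-4)
})

test_that("clustered sampling takes whole pens and degenerates to a census", {
  h <- toy_herd(count = 8)
  d <- draw_s3(h, n_pens = 4) # all pens
  expect_equal(d$estimates[["lameness"]], 8 / 40)
  expect_equal(d$sample_size[["lameness"]], 40L)

  heq <- equal_pen_herd(n_pens = 8, pen_size = 10, count = 12)
  set.seed(9)
  for (i in 1:5) {
    d <- draw_s3(heq, n_pens = 3)
    expect_equal(d$sample_size[["lameness"]], 30L) # equal pens: size fixed
    pens <- unique(heq$animals$pen_id[match(d$animal_ids[[1]],
                                            heq$animals$animal_id)])
    expect_length(pens, 3L)
    # whole pens: selection size equals total occupancy of those pens
    expect_equal(length(d$animal_ids[[1]]),
                 sum(heq$pens$size[heq$pens$pen_id %in% pens]))
  }
  expect_error(draw_s3(h, n_pens = 5), "more pens requested")
})

test_that("stratified clustered sampling takes a fixed pen count per room", {
  h <- reference_herd(seed = 4)
  set.seed(21)
  d <- draw_s4(h, pens_per_stratum = 2)
  sel <- h$animals[match(d$animal_ids[[1]], h$animals$animal_id), ]
  pens_by_room <- tapply(sel$pen_id, sel$room_id, function(x) length(unique(x)))
  expect_equal(as.integer(pens_by_room), rep(2L, 4))
  # all pens per room -> census
  dc <- draw_s4(h, pens_per_stratum = 8)
  expect_equal(dc$sample_size[["runts"]], 636L)
  expect_equal(dc$estimates[["runts"]], 7 / 636)
})

test_that("the KTBL design caps the lesion group at 15 animals per pen", {
  h <- big_even_herd() # 32 pens of 20 animals each
  set.seed(31)
  d <- draw_s5(h)
  # group A: all animals of the 10 chosen pens (10 x 20 = 200)
  expect_equal(d$sample_size[["runts"]], 200L)
  expect_equal(d$sample_size[["faecal_soiling"]], 200L)
  expect_equal(d$sample_size[["lameness"]], 200L)
  # group B: every pen is over the cap, so exactly 10 x 15 = 150
  expect_equal(d$sample_size[["skin_lesions"]], 150L)
  expect_equal(d$sample_size[["ear_lesions"]], 150L)
  expect_equal(d$sample_size[["tail_lesions"]], 150L)
  # group B animals are a subset of group A's pens
  expect_true(all(d$animal_ids$skin_lesions %in% d$animal_ids$runts))
  # pen structure: 10 distinct pens, at least 2 per room
  sel <- h$animals[match(d$animal_ids$runts, h$animals$animal_id), ]
  pens <- unique(sel$pen_id)
  expect_length(pens, 10L)
  per_room <- tapply(pens, h$pens$room_id[match(pens, h$pens$pen_id)], length)
  expect_true(all(per_room >= 2))
  expect_equal(sum(per_room), 10L)
})

test_that("the KTBL design leaves small pens uncapped and small herds censused", {
  h <- reference_herd(seed = 6) # pens of 11-25 animals; cap binds where > 15
  set.seed(33)
  d <- draw_s5(h)
  sel_a <- h$animals[match(d$animal_ids$runts, h$animals$animal_id), ]
  pens <- unique(sel_a$pen_id)
  sizes <- h$pens$size[match(pens, h$pens$pen_id)]
  expect_equal(d$sample_size[["runts"]], sum(sizes))
  expect_equal(d$sample_size[["tail_lesions"]], sum(pmin(sizes, 15L)))

  # herd at or below the 150-animal floor: full census for all indicators
  hs <- generate_herd(herd_config(c(60, 60), pens_per_room = 3,
                                  indicator_counts = c(tail_lesions = 6,
                                                       runts = 2),
                                  seed = 2))
  ds <- draw_s5(hs)
  expect_equal(ds$sample_size[["tail_lesions"]], 120L)
  expect_equal(ds$estimates[["tail_lesions"]], 6 / 120)

  # pens with <= 15 animals everywhere: group B equals group A
  heq <- generate_herd(herd_config(rep(40, 4), pens_per_room = 4,
                                   max_pen_size = 10,
                                   indicator_counts = c(tail_lesions = 10,
                                                        runts = 3),
                                   seed = 8))
  set.seed(12)
  de <- draw_s5(heq)
  expect_setequal(de$animal_ids$tail_lesions, de$animal_ids$runts)
})

test_that("fewer than ten pens triggers the raised per-pen quota branch", {
  # 2 rooms x 3 pens = 6 pens of 30 animals (180 > 150): quota ceil(150/6) = 25
  h <- generate_herd(herd_config(c(90, 90), pens_per_room = 3,
                                 max_pen_size = 30,
                                 indicator_counts = c(tail_lesions = 9,
                                                      runts = 2),
                                 seed = 4))
  set.seed(14)
  d <- draw_s5(h)
  expect_equal(d$sample_size[["runts"]], 180L) # group A: every pen
  expect_equal(d$sample_size[["tail_lesions"]], 6L * 25L)
})

test_that("prevalence estimation guards empty and invalid selections", {
  h <- toy_herd(count = 8)
  expect_equal(estimate_prevalence(h$animals$animal_id, h, "lameness"), 8 / 40)
  healthy <- h$animals$animal_id[h$animals$lameness == 0][1:15]
  expect_equal(estimate_prevalence(healthy, h, "lameness"), 0)
  affected3 <- c(h$animals$animal_id[h$animals$lameness == 1][1:3],
                 healthy[1:12])
  expect_equal(estimate_prevalence(affected3, h, "lameness"), 0.2)
  expect_error(estimate_prevalence(integer(0), h, "lameness"), "empty")
  expect_error(estimate_prevalence(c(1, 1), h, "lameness"), "duplicate")
  expect_error(estimate_prevalence(1:3, h, "tail_lesions"), "unknown indicator")
})
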