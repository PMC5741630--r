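test_that("encode_binary maps outcomes and block structure faithfully", {
  d <- make_fin(n = 3, regen = c(FALSE, TRUE, FALSE))
  s <- encode_binary(d, "regen_7dpi")
  expect_identical(s$values, c(0L, 1L, 0L))
  expect_equal(nrow(s$blocks), 1L)

  two <- bind_fins(make_fin(n = 2, regen = c(TRUE, FALSE), fish = "A"),
                   make_fin(n = 2, regen = c(FALSE, TRUE), fish = "B"))
  s2 <- encode_binary(two, "regen_7dpi", mode = "pooled")
  expect_identical(s2$values, c(1L, 0L, 0L, 1L))
  expect_equal(s2$blocks, data.frame(start = c(1L, 3L),
                                     length = c(2L, 2L)))

  expect_error(encode_binary(two, "regen_99dpi"), "unknown outcome field")
})

test_that("eligibility gaps inside a fin break adjacency in the encoding", {
  # rays 1..5, ray 3 injured: eligible rays are 1 and 5 (2 and 4 are
  # adjacent to the wound); 1 and 5 must not be treated as neighbors
  d <- make_fin(injury = c("none", "none", "epidermal_wound", "none",
                           "none"),
                regen = c(TRUE, FALSE, TRUE, FALSE, TRUE))
  s <- encode_binary(eligible_noninjured(d), "regen_7dpi", mode = "per_fin")
  expect_identical(s$values, c(1L, 1L))
  expect_equal(nrow(s$blocks), 2L)
  expect_equal(count_isolated(s)$isolated, 2L)
})

test_that("a long composition encodes with the stated one/zero counts", {
  values <- rep(c(1L, 0L), c(142L, 409L))
  s <- binary_sequence(values)
  expect_equal(sum(s$values), 142L)
  expect_equal(sum(s$values == 0L), 409L)
  expect_equal(mean(s$values), 142 / 551)
})

test_that("count_isolated matches hand enumeration on small cases", {
  expect_equal(count_isolated(binary_sequence(c(0, 1, 0))),
               list(isolated = 1L, ones = 1L))
  expect_equal(count_isolated(binary_sequence(c(1, 1))),
               list(isolated = 0L, ones = 2L))
  # positions 2 and 7 are isolated; the 4,5 pair is not
  expect_equal(count_isolated(binary_sequence(c(0, 1, 0, 1, 1, 0, 1))),
               list(isolated = 2L, ones = 4L))
})

test_that("count_isolated agrees with a brute-force scan everywhere", {
  set.seed(99)
  for (len in 1:10) {
    grid <- as.matrix(expand.grid(rep(list(0:1), len)))
    for (row in seq_len(nrow(grid))) {
      v <- as.integer(grid[row, ])
      s <- binary_sequence(v)
      expect_equal(count_isolated(s, respect_blocks = FALSE)$isolated,
                   naive_isolated(v))
      # a random block split of the same values
      if (len >= 2L) {
        cuts <- sort(sample(seq_len(len - 1L),
                            sample(0:(len - 1L), 1L)))
        lens <- diff(c(0L, cuts, len))
        blocks <- data.frame(start = cumsum(c(1L, lens[-length(lens)])),
                             length = lens)
        sb <- binary_sequence(v, blocks, mode = "per_fin")
        expect_equal(count_isolated(sb, respect_blocks = TRUE)$isolated,
                     naive_isolated(v, blocks))
      }
    }
  }
})

test_that("respecting blocks can only add isolated ones", {
  set.seed(7)
  for (rep in 1:50) {
    len <- sample(5:20, 1L)
    v <- as.integer(stats::runif(len) < 0.4)
    cuts <- sort(sample(seq_len(len - 1L), sample(1:3, 1L)))
    lens <- diff(c(0L, cuts, len))
    blocks <- data.frame(start = cumsum(c(1L, lens[-length(lens)])),
                         length = lens)
    s <- binary_sequence(v, blocks, mode = "per_fin")
    expect_gte(count_isolated(s, TRUE)$isolated,
               count_isolated(s, FALSE)$isolated)
  }
})

test_that("bystander fraction is the exact complement of isolation", {
  expect_equal(bystander_fraction(binary_sequence(c(1, 1, 0, 0))), 1.0)
  expect_equal(bystander_fraction(binary_sequence(c(0, 1, 0))), 0.0)
  expect_error(bystander_fraction(binary_sequence(c(0, 0))),
               class = "rayregen_undefined")
  set.seed(21)
  for (rep in 1:25) {
    v <- as.integer(stats::runif(12) < 0.5)
    if (sum(v) == 0L) v[3] <- 1L
    s <- binary_sequence(v)
    expect_equal(bystander_fraction(s) + isolated_frequency(s), 1.0)
  }
})

test_that("neighbor association rate reflects true adjacency", {
  d <- make_fin(escaper = c(FALSE, TRUE, FALSE),
                regen = c(TRUE, FALSE, TRUE), n = 3)
  expect_equal(neighbor_association_rate(d, "escaper"), 1.0)

  quiet <- make_fin(injury = c("re_amputation", "none", "none"), n = 3)
  expect_equal(neighbor_association_rate(quiet, "re_amputation"), 0.0)
  expect_error(neighbor_association_rate(quiet, "skin_wound"),
               class = "rayregen_undefined")
})

test_that("contagion raises the injured-focal association above baseline", {
  contagion <- simulate_dataset(sim_params(n_fish = 40L, seed = 31L))
  flat <- simulate_dataset(sim_params(n_fish = 40L, p_bystander = 0,
                                      spread_rounds = 0L,
                                      p_injured_regen = 0, seed = 31L))
  r_contagion <- neighbor_association_rate(contagion$dataset,
                                           "epidermal_wound")
  r_flat <- neighbor_association_rate(flat$dataset, "epidermal_wound")
  expect_gt(r_contagion, r_flat + 0.3)
})

test_that("regeneration fractions come out at full precision", {
  d <- make_fin(n = 84, regen = c(rep(TRUE, 62), rep(FALSE, 22)))
  expect_equal(regeneration_fraction(d), 62 / 84)
  expect_equal(regeneration_fraction(make_fin(n = 5)), 0.0)
  empty <- make_fin(n = 3)[0, ]
  expect_error(regeneration_fraction(empty), class = "rayregen_undefined")
})

test_that("chi-square matches the Pearson formula on hand-checked tables", {
  flat <- chi_square_test(contingency_table(c(10, 10, 10, 10)))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p_value, 1)
  expect_equal(flat$df, 1L)

  # expected counts all 2; X2 = 4 * (3-2)^2/2 ... = 2.0
  hand <- chi_square_test(contingency_table(c(3, 1, 1, 3)))
  expect_equal(hand$statistic, 2.0)

  yates <- chi_square_test(contingency_table(c(3, 1, 1, 3)), "yates")
  expect_lt(yates$statistic, hand$statistic)
})

test_that("chi-square is invariant to transposition and row swaps", {
  m <- contingency_table(c(62, 22, 49, 400))
  base <- chi_square_test(m)$statistic
  expect_equal(chi_square_test(contingency_table(t(unclass(m))))$statistic,
               base)
  expect_equal(chi_square_test(
    contingency_table(unclass(m)[2:1, ]))$statistic, base)
})

test_that("degenerate tables are refused", {
  expect_error(chi_square_test(contingency_table(c(5, 0, 3, 0))),
               "degenerate")
  expect_error(contingency_table(c(-1, 2, 3, 4)), "non-negative")
  expect_error(contingency_table(c(0, 0, 0, 0)), "positive entry")
})
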