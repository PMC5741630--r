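# Fixture builders and independent oracles used across the test files.

# One fin described compactly: injury classes, escaper flags, and outcomes.
make_fin <- function(injury = rep("none", n), escaper = rep(FALSE, n),
                     regen = rep(FALSE, n), regen3 = regen,
                     inadvertent = rep(FALSE, n),
                     n = length(injury), fish = "f1", fin = "caudal") {
  ray_dataset(data.frame(
    fish_id = fish, fin_id = fin, ray_index = seq_len(n),
    injury = injury, escaper = escaper, inadvertent_injury = inadvertent,
    regen_3dpi = regen3, regen_7dpi = regen, stringsAsFactors = FALSE))
}

bind_fins <- function(...) {
  parts <- lapply(list(...), as.data.frame)
  ray_dataset(do.call(rbind, parts))
}

# Brute-force isolated-"1" scan, written naively and independently of the
# package's vectorized implementation: walk every position, look up the
# neighbors that exist inside the same segment.
naive_isolated <- function(values, blocks = NULL) {
  if (is.null(blocks)) {
    blocks <- data.frame(start = 1L, length = length(values))
  }
  if (length(values) == 0L) return(0L)
  count <- 0L
  for (b in seq_len(nrow(blocks))) {
    lo <- blocks$start[b]
    hi <- lo + blocks$length[b] - 1L
    for (i in seq(lo, hi)) {
      if (values[i] != 1L) next
      left_ok <- if (i == lo) TRUE else values[i - 1L] == 0L
      right_ok <- if (i == hi) TRUE else values[i + 1L] == 0L
      if (left_ok && right_ok) count <- count + 1L
    }
  }
  count
}

# Exhaustive mean isolated frequency over all arrangements of n1 ones and
# n0 zeros (single unblocked sequence).
enum_mean_isolated <- function(n1, n0) {
  total <- n1 + n0
  pos_sets <- utils::combn(total, n1)
  freqs <- apply(pos_sets, 2L, function(pos) {
    v <- integer(total)
    v[pos] <- 1L
    naive_isolated(v) / n1
  })
  mean(freqs)
}

# Random valid dataset for round-trip properties: several fins of varying
# length with arbitrary flags (escapers kept uninjured by construction).
random_dataset <- function(seed, n_fins = 4L) {
  set.seed(seed)
  fins <- lapply(seq_len(n_fins), function(f) {
    n <- sample(3:12, 1L)
    injury <- sample(c("none", "re_amputation", "epidermal_wound",
                       "skin_wound"), n, replace = TRUE,
                     prob = c(0.7, 0.1, 0.1, 0.1))
    escaper <- ifelse(injury == "none", stats::runif(n) < 0.15, FALSE)
    data.frame(fish_id = sprintf("fish%02d", f), fin_id = "caudal",
               ray_index = seq_len(n), injury = injury, escaper = escaper,
               inadvertent_injury = stats::runif(n) < 0.1,
               regen_3dpi = stats::runif(n) < 0.2,
               regen_7dpi = stats::runif(n) < 0.3,
               note = sample(c("a", "b"), n, replace = TRUE),
               stringsAsFactors = FALSE)
  })
  ray_dataset(do.call(rbind, fins))
}

expect_same_dataset <- function(a, b) {
  expect_identical(names(a), names(b))
  for (col in names(a)) {
    expect_equal(as.vector(a[[col]]), as.vector(b[[col]]),
                 info = paste("column", col))
  }
}
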