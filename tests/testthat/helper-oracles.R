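# Independent brute-force oracle for the nine-trend rule table: a literal
# row-by-row transcription of the threshold table, with the uniform
# boundaries-to-Same policy. Scans all nine rows and asserts exactly one
# matches (totality/exclusivity).
trend_rule_table_oracle <- function(f1, f2, tau = 0.5) {
  d <- f2 - f1
  rows <- list(
    list("Up-Up",      function() f1 > tau              && d > tau),
    list("Up-Same",    function() f1 > tau              && d <= tau && d >= -tau),
    list("Up-Down",    function() f1 > tau              && d < -tau),
    list("Same-Up",    function() f1 <= tau && f1 >= -tau && d > tau),
    list("Same-Same",  function() f1 <= tau && f1 >= -tau && d <= tau && d >= -tau),
    list("Same-Down",  function() f1 <= tau && f1 >= -tau && d < -tau),
    list("Down-Up",    function() f1 < -tau             && d > tau),
    list("Down-Same",  function() f1 < -tau             && d <= tau && d >= -tau),
    list("Down-Down",  function() f1 < -tau             && d < -tau))
  hits <- vapply(rows, function(r) r[[2]](), logical(1))
  stopifnot(sum(hits) == 1)
  rows[[which(hits)]][[1]]
}

# planted simulator class -> expected combined trend label
planted_class_to_trend <- c(
  flat = "Same-Same", up_down = "Up-Down", up_same = "Up-Same",
  up_up = "Up-Up", down_down = "Down-Down", down_same = "Down-Same",
  down_up = "Down-Up", same_up = "Same-Up", same_down = "Same-Down")

# shared expensive fixtures, computed once per test run
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, make) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, make(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# 2000-gene study-condition simulation (default class mix, phi = 0.05,
# effect 2.0 log2, 3 replicates) plus its fitted wave model
shared_sim <- function() cached("sim2000", function()
  simulate_experiment(n_genes = 2000, seed = 5))

shared_fit <- function() cached("fit2000", function()
  wave_fit(shared_sim(), condition = "bzATP_LPS"))

# tiny deterministic expression matrix with named groups for unit tests
toy_expr <- function() {
  m <- matrix(c(10, 40, 0, 100,
                10, 44, 0, 104,
                40, 10, 0, 400,
                38, 12, 0, 396), nrow = 4,
              dimnames = list(paste0("g", 1:4),
                              c("base_r1", "base_r2", "trt_r1", "trt_r2")))
  m
}
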