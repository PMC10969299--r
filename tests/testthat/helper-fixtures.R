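# Shared, memoised fixtures: one small noise-free phantom patient and its
# mapped biomarker volumes, reused across test files to keep the suite fast.

.fixture_env <- new.env(parent = emptyenv())

small_spec <- function(seed = 7, label = "IDHwt",
                       protocol = "site_A_separate") {
  phantom_spec(grid_shape = c(32, 32, 32), tumor_center = c(20, 18, 16),
               tumor_radii = 6, class_label = label, seed = seed,
               protocol = protocol)
}

small_bundle <- function(noise_sd = 0, seed = 7, label = "IDHwt",
                         protocol = "site_A_separate") {
  key <- paste("bundle", noise_sd, seed, label, protocol, sep = "_")
  if (is.null(.fixture_env[[key]]))
    .fixture_env[[key]] <- simulate_patient(
      small_spec(seed, label, protocol), class_effect_model(),
      noise_sd = noise_sd)
  .fixture_env[[key]]
}

small_mapped <- function(noise_sd = 0, seed = 7, label = "IDHwt",
                         protocol = "site_A_separate") {
  key <- paste("maps", noise_sd, seed, label, protocol, sep = "_")
  if (is.null(.fixture_env[[key]]))
    .fixture_env[[key]] <- map_patient(small_bundle(noise_sd, seed, label,
                                                    protocol))
  .fixture_env[[key]]
}

# toy two-class feature data with a separating block of columns
toy_features <- function(n = 60, p = 6, shift = 1, seed = 1) {
  set.seed(seed)
  y <- rep(c("IDHwt", "IDHmut"), each = n / 2)
  x <- matrix(stats::rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("f", seq_len(p))))
  x[y == "IDHmut", 1] <- x[y == "IDHmut", 1] + shift
  list(x = x, y = y)
}

max_relerr <- function(a, b) max(abs(a - b) / pmax(abs(b), 1e-12))
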