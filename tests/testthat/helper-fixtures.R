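# Shared simulated experiments, built once per test run. The 151-accession
# run mirrors the scale of the real screen; smaller runs keep unit tests
# fast. Seeds are fixed so every expectation is reproducible.

.fixture_env <- new.env(parent = emptyenv())

shared_sim_151 <- function() {
  if (is.null(.fixture_env$sim151)) {
    .fixture_env$sim151 <- simulate_experiment(
      simulation_config(n_accessions = 151, seed = 101))
  }
  .fixture_env$sim151
}

shared_ind_151 <- function() {
  if (is.null(.fixture_env$ind151)) {
    s <- shared_sim_151()
    .fixture_env$ind151 <- build_indicator_table(s$plants, s$accessions)
  }
  .fixture_env$ind151
}

# salt-and-pepper corruption for segmentation tests: density d of pixels is
# replaced, half by the foreground colour, half by the background colour
salt_pepper <- function(img, density, seed,
                        fg = c(0.20, 0.65, 0.25), bg = c(0.82, 0.82, 0.86)) {
  set.seed(seed)
  h <- dim(img)[1]; w <- dim(img)[2]
  n <- round(density * h * w)
  px <- sample.int(h * w, n)
  salt <- px[seq_len(floor(n / 2))]
  pepper <- setdiff(px, salt)
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[salt] <- fg[ch]
    plane[pepper] <- bg[ch]
    img[, , ch] <- plane
  }
  img
}
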