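# shared fixtures, built in code at test time

# small symmetric IF matrix with one zero off-diagonal pair
toy_if_matrix <- function() {
  m <- matrix(c(
    0, 4, 1, 0,
    4, 0, 2, 1,
    1, 2, 0, 8,
    0, 1, 8, 0), 4L, 4L, byrow = TRUE)
  contact_matrix(m)
}

write_tmp <- function(lines) {
  path <- tempfile(fileext = ".txt")
  writeLines(lines, path)
  path
}

# default-scale fixture used by the recovery and consistency tests
helix_fixture <- function(n_bins = 20L) make_fixture("helix", n_bins)
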